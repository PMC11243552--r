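# synthetic fixtures: toy complexes with planted contact geometries, and
# landscapes with planted activity cliffs

# minimal residue templates (local coordinates, Angstrom); backbone plus
# enough side chain for donor/acceptor/apolar chemistry
residue_template <- function(resname) {
  # idealized bond lengths/angles so that covalent-distance bond inference
  # recovers exactly the intended connectivity
  base <- list(
    N  = c(0.000, 0.000, 0.000),
    CA = c(1.458, 0.000, 0.000),
    C  = c(2.003, 1.420, 0.000),
    O  = c(3.215, 1.634, 0.000))
  cb <- c(1.981, -1.438, 0.000)
  cg <- c(3.505, -1.571, 0.000)
  d3_cb <- c(-0.378, -0.492, 0.784)   # third tetrahedral direction at CB
  d3_cg <- c(0.377, 0.491, 0.785)     # and at CG
  side <- switch(resname,
    ALA = list(CB = cb),
    VAL = list(CB = cb,
               CG1 = cg,
               CG2 = cb + 1.53 * d3_cb),
    LEU = list(CB = cb,
               CG = cg,
               CD1 = cg + c(0.523, -1.438, 0.000),
               CD2 = cg + 1.53 * d3_cg),
    ASN = list(CB = cb,
               CG = cg,
               OD1 = cg + c(0.421, -1.156, 0.000),
               ND2 = cg + 1.33 * d3_cg),
    stop("unsupported scaffold residue: ", resname, call. = FALSE))
  c(base, side)
}

SYNTH_ELEMENT <- c(N = "N", CA = "C", C = "C", O = "O", CB = "C",
                   CG = "C", CG1 = "C", CG2 = "C", CD1 = "C", CD2 = "C",
                   OD1 = "O", ND2 = "N")

# place H so that angle D-H...A equals theta with |D-H| = 1.0 and |D-A| = d
solve_h_position <- function(p_d, p_a, theta_deg) {
  d <- vec_norm(p_a - p_d)
  th <- theta_deg * pi / 180
  # law of cosines at H: d^2 = 1 + ha^2 - 2*ha*cos(th)
  disc <- cos(th)^2 - 1 + d^2
  if (disc < 0) stop("infeasible hydrogen-bond geometry (d = ", d,
                     ", angle = ", theta_deg, ")", call. = FALSE)
  ha <- cos(th) + sqrt(disc)
  # angle at D between D->A and D->H
  cb <- (1 + d^2 - ha^2) / (2 * d)
  cb <- max(-1, min(1, cb))
  e1 <- unit(p_a - p_d)
  e2 <- perpendicular(e1)
  p_d + cb * e1 + sqrt(max(0, 1 - cb^2)) * e2
}

perpendicular <- function(v) {
  ref <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  unit(ref - sum(ref * v) * v)
}

#' Synthesize a complex with planted interaction geometries
#'
#' Builds a toy protein scaffold (one residue per plant, spaced far apart)
#' and positions ligand atoms so that each requested contact is realized
#' at exactly the prescribed distance and angle. The in-memory complex
#' carries full-precision coordinates (planted geometry reproducible to
#' better than 1e-6 Angstrom / 1e-4 degrees); the PDB file written
#' alongside follows the format's fixed 0.001-Angstrom precision.
#'
#' @param plants data.frame with columns `kind` (`"hbond"`,
#'   `"halogen_bond"`, `"hydrophobic"`), `distance` (Angstrom), `angle`
#'   (degrees; ignored for hydrophobic), `residue_name` (ALA/VAL/LEU/ASN);
#'   optional `element`: the halogen for `halogen_bond` plants (default
#'   Br) or the donor element for `hbond` plants (default N). May have
#'   zero rows.
#' @param path PDB output path (default: a tempfile).
#' @return list with `complex` (a `lig_complex`), `path` (the written
#'   PDB) and `plants`.
#' @export
synth_complex <- function(plants = data.frame(), path = tempfile(fileext = ".pdb")) {
  plants <- as.data.frame(plants)
  n_pl <- nrow(plants)
  if (n_pl > 0) {
    stopifnot(all(c("kind", "distance", "residue_name") %in% names(plants)))
    if (!"angle" %in% names(plants)) plants$angle <- NA_real_
    if (!"element" %in% names(plants)) plants$element <- "Br"
    if (any(plants$distance <= 0)) stop("plant distances must be > 0",
                                        call. = FALSE)
    bad_ang <- !is.na(plants$angle) & (plants$angle < 0 | plants$angle > 180)
    if (any(bad_ang)) stop("plant angles must lie in [0, 180]",
                           call. = FALSE)
  }
  prot <- data.frame()
  lig <- data.frame()
  add_atom <- function(df, elety, element, resid, resno, xyz, b = 20) {
    rbind(df, data.frame(elety = elety, element = element, resid = resid,
                         resno = resno, x = xyz[1], y = xyz[2], z = xyz[3],
                         b = b, stringsAsFactors = FALSE))
  }
  # an inert anchor residue so even an empty spec yields a protein
  anchor <- residue_template("ALA")
  for (nm in names(anchor))
    prot <- add_atom(prot, nm, SYNTH_ELEMENT[[nm]], "ALA", 1,
                     anchor[[nm]] + c(-30, 0, 0))
  # a neutral ligand core so the hetero group is never empty
  lig <- add_atom(lig, "C0A", "C", "LIG", 900, c(-30, 8, 0), b = 30)
  lig <- add_atom(lig, "C0B", "C", "LIG", 900, c(-28.5, 8, 0), b = 30)

  for (i in seq_len(n_pl)) {
    origin <- c(25 * i, 0, 0)
    resno <- i + 1
    resname <- toupper(plants$residue_name[i])
    tpl <- residue_template(resname)
    for (nm in names(tpl))
      prot <- add_atom(prot, nm, SYNTH_ELEMENT[[nm]], resname, resno,
                       tpl[[nm]] + origin, b = 20 + i)
    kind <- plants$kind[i]
    d <- plants$distance[i]
    th <- plants$angle[i]
    tag <- i  # unique ligand atom names per plant
    if (kind == "hbond") {
      # ligand donor (N by default, O/S via `element`) with explicit H,
      # donating to the residue's backbone O
      el_d <- if (plants$element[i] %in% c("N", "O", "S"))
        plants$element[i] else "N"
      p_a <- tpl$O + origin
      dir <- unit(c(0.5, 1.2, 0.3))
      p_d <- p_a + d * dir
      if (is.na(th)) th <- 165
      p_h <- solve_h_position(p_d, p_a, th)
      lig <- add_atom(lig, paste0(el_d, tag), el_d, "LIG", 900, p_d,
                      b = 30)
      lig <- add_atom(lig, paste0("H", tag), "H", "LIG", 900, p_h, b = 30)
    } else if (kind == "halogen_bond") {
      el <- plants$element[i]
      p_a <- tpl$O + origin
      dir <- unit(c(0.4, 1.3, 0.2))
      p_x <- p_a + d * dir
      if (is.na(th)) th <- 170
      e1 <- unit(p_a - p_x)
      e2 <- perpendicular(e1)
      thr <- th * pi / 180
      cx_len <- c(F = 1.35, Cl = 1.77, Br = 1.88, I = 2.10)[el] %||% 1.88
      if (is.na(cx_len)) cx_len <- 1.88
      p_c <- p_x + cx_len * (cos(thr) * e1 + sin(thr) * e2)
      lig <- add_atom(lig, paste0(toupper(el), tag), el, "LIG", 900, p_x,
                      b = 30)
      lig <- add_atom(lig, paste0("C", tag), "C", "LIG", 900, p_c, b = 30)
    } else if (kind == "hydrophobic") {
      # apolar ligand carbon near the residue's CB, aimed away from the
      # rest of the side chain so CB stays the nearest apolar partner
      p_p <- tpl$CB + origin
      dir <- unit(c(0.1, 0.9, -0.42))
      p_c <- p_p + d * dir
      lig <- add_atom(lig, paste0("C", tag), "C", "LIG", 900, p_c, b = 30)
    } else stop("unknown plant kind: ", kind, call. = FALSE)
  }
  # feasibility: no two distinct atoms may clash
  all_pos <- rbind(as.matrix(prot[, c("x", "y", "z")]),
                   as.matrix(lig[, c("x", "y", "z")]))
  if (nrow(all_pos) > 1) {
    dm <- stats::dist(all_pos)
    if (min(dm) < 0.9)
      stop("geometrically infeasible plant spec: atoms clash (min ",
           sprintf("%.2f", min(dm)), " A)", call. = FALSE)
  }
  all_at <- rbind(cbind(prot, type = "ATOM"), cbind(lig, type = "HETATM"))
  n <- nrow(all_at)
  bio3d::write.pdb(file = path,
                   type = all_at$type,
                   xyz = as.numeric(t(as.matrix(all_at[, c("x", "y", "z")]))),
                   resno = all_at$resno, resid = all_at$resid,
                   eleno = seq_len(n), elety = all_at$elety,
                   chain = rep("A", n), o = rep(1, n), b = all_at$b,
                   elesy = toupper(all_at$element))
  mk <- function(df) {
    data.frame(eleno = seq_len(nrow(df)), elety = df$elety,
               element = df$element, resid = df$resid, chain = "A",
               resno = df$resno, insert = "", x = df$x, y = df$y,
               z = df$z, o = 1, b = df$b, stringsAsFactors = FALSE)
  }
  cx <- structure(list(protein = mk(prot), ligand = mk(lig),
                       selector = list(resid = "LIG", chain = "A",
                                       resno = 900)),
                  class = "lig_complex")
  list(complex = cx, path = path, plants = plants)
}

#' Synthesize an affinity landscape with planted cliffs
#'
#' Draws background pairwise similarities and per-ligand binding
#' affinities uniformly from the given ranges, then realizes each
#' requested cliff on a dedicated ligand pair at exactly its `(s, d_ba)`.
#' Cliff similarities must exceed the background similarity range so that
#' detection thresholds can bracket the plants.
#'
#' @param n_ligands number of ligands (>= 2; at least two per cliff).
#' @param background_similarity length-2 range for non-cliff pair
#'   similarities (within `[0, 1)`).
#' @param background_affinity length-2 range (kcal/mol) for ligand
#'   affinities.
#' @param cliffs data.frame with columns `s` and `d_ba`, one row per
#'   planted cliff (may have zero rows).
#' @param seed mandatory integer seed; the output is a pure function of
#'   the spec and seed.
#' @return list with `records` (ligand_id, value, value_kind), `sim`
#'   (`similarity_matrix`, measure external) and `cliff_pairs` (the
#'   planted pair ids with their parameters).
#' @export
synth_landscape <- function(n_ligands,
                            background_similarity = c(0.2, 0.5),
                            background_affinity = c(-10, -5),
                            cliffs = data.frame(s = numeric(0),
                                                d_ba = numeric(0)),
                            seed) {
  if (missing(seed)) stop("seed is mandatory for stochastic generation",
                          call. = FALSE)
  cliffs <- as.data.frame(cliffs)
  n_cl <- nrow(cliffs)
  if (n_ligands < max(2, 2 * n_cl))
    stop("need at least 2 ligands per planted cliff", call. = FALSE)
  if (any(background_similarity < 0) || any(background_similarity >= 1))
    stop("background similarity range must lie in [0, 1)", call. = FALSE)
  if (n_cl > 0) {
    if (any(cliffs$s < 0 | cliffs$s > 1))
      stop("cliff similarities must lie in [0, 1]", call. = FALSE)
    if (any(cliffs$s <= max(background_similarity)))
      stop("cliffs incompatible with background ranges: cliff similarity ",
           "must exceed the background similarity maximum", call. = FALSE)
    if (any(cliffs$d_ba <= 0))
      stop("cliff d_ba must be > 0", call. = FALSE)
  }
  ids <- sprintf("L%03d", seq_len(n_ligands))
  with_seed(seed, {
    values <- runif(n_ligands, background_affinity[1],
                    background_affinity[2])
    n <- n_ligands
    s <- matrix(0, n, n, dimnames = list(ids, ids))
    ut <- upper.tri(s)
    s[ut] <- runif(sum(ut), background_similarity[1],
                   background_similarity[2])
    s <- s + t(s)
    diag(s) <- 1
    cliff_pairs <- data.frame(id_a = character(0), id_b = character(0),
                              s = numeric(0), d_ba = numeric(0))
    base <- mean(background_affinity)
    for (k in seq_len(n_cl)) {
      i <- 2 * k - 1; j <- 2 * k
      s[i, j] <- s[j, i] <- cliffs$s[k]
      values[i] <- base - cliffs$d_ba[k] / 2
      values[j] <- base + cliffs$d_ba[k] / 2
      cliff_pairs <- rbind(cliff_pairs,
                           data.frame(id_a = ids[i], id_b = ids[j],
                                      s = cliffs$s[k],
                                      d_ba = cliffs$d_ba[k]))
    }
    list(records = data.frame(ligand_id = ids, value = values,
                              value_kind = "binding_affinity",
                              stringsAsFactors = FALSE),
         sim = as_similarity_matrix(s, measure = "external"),
         cliff_pairs = cliff_pairs)
  })
}
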