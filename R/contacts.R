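# noncovalent contact detection: hydrogen bonds, halogen bonds,
# hydrophobic contacts

COVALENT_RADII <- c(H = 0.31, B = 0.84, C = 0.76, N = 0.71, O = 0.66,
                    F = 0.57, P = 1.07, S = 1.05, Cl = 1.02, Br = 1.20,
                    I = 1.39)

# infer covalent bonds inside one atom set (data.frame with element,x,y,z)
# by distance: d < r_a + r_b + tol
infer_bonds <- function(df, tol = 0.45) {
  n <- nrow(df)
  if (n < 2L) return(matrix(integer(0), ncol = 2))
  pos <- as.matrix(df[, c("x", "y", "z")])
  rad <- COVALENT_RADII[df$element]
  rad[is.na(rad)] <- 0.8
  dm <- as.matrix(stats::dist(pos))
  lim <- outer(rad, rad, "+") + tol
  hit <- which(dm < lim & upper.tri(dm), arr.ind = TRUE)
  hit[dm[hit] > 0.4, , drop = FALSE]  # guard against duplicated atoms
}

# per-atom list of bonded neighbour indices
bond_adj <- function(df, bonds) {
  adj <- vector("list", nrow(df))
  if (nrow(bonds)) {
    for (i in seq_len(nrow(bonds))) {
      a <- bonds[i, 1]; b <- bonds[i, 2]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  adj
}

# cell-grid neighbour search between two coordinate sets; returns candidate
# index pairs (i from A, j from B) with d <= cutoff. Brute-force equivalence
# is asserted in the test suite.
grid_pairs <- function(a, b, cutoff) {
  if (nrow(a) == 0L || nrow(b) == 0L)
    return(data.frame(i = integer(0), j = integer(0), d = numeric(0)))
  cell <- cutoff
  gb <- floor(b / cell)
  bkey <- paste(gb[, 1], gb[, 2], gb[, 3], sep = ",")
  bmap <- split(seq_len(nrow(b)), bkey)
  ga <- floor(a / cell)
  out_i <- integer(0); out_j <- integer(0); out_d <- numeric(0)
  offsets <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  for (i in seq_len(nrow(a))) {
    cand <- integer(0)
    for (k in seq_len(nrow(offsets))) {
      key <- paste(ga[i, 1] + offsets$dx[k], ga[i, 2] + offsets$dy[k],
                   ga[i, 3] + offsets$dz[k], sep = ",")
      cand <- c(cand, bmap[[key]])
    }
    if (!length(cand)) next
    dd <- sqrt(colSums((t(b[cand, , drop = FALSE]) - a[i, ])^2))
    keep <- dd <= cutoff
    out_i <- c(out_i, rep.int(i, sum(keep)))
    out_j <- c(out_j, cand[keep])
    out_d <- c(out_d, dd[keep])
  }
  data.frame(i = out_i, j = out_j, d = out_d)
}

atom_label <- function(df, i) {
  paste0(df$chain[i], "/", df$resid[i], df$resno[i], df$insert[i], "/",
         df$elety[i])
}

residue_key <- function(df, i) {
  paste0(title_case(df$resid[i]), df$resno[i], df$insert[i])
}

new_contacts <- function(kind, lig_df, lig_idx, prot_df, prot_idx,
                         distance, angle, strength_class,
                         angle_basis = "explicit_h") {
  data.frame(
    kind = kind,
    ligand_atom = if (length(lig_idx)) vapply(lig_idx, function(i)
      atom_label(lig_df, i), character(1)) else character(0),
    partner_atom = if (length(prot_idx)) vapply(prot_idx, function(i)
      atom_label(prot_df, i), character(1)) else character(0),
    res_name = prot_df$resid[prot_idx],
    res_no = prot_df$resno[prot_idx],
    chain = prot_df$chain[prot_idx],
    residue = if (length(prot_idx)) vapply(prot_idx, function(i)
      residue_key(prot_df, i), character(1)) else character(0),
    distance = distance,
    angle = angle,
    strength_class = strength_class,
    angle_basis = if (length(distance)) angle_basis else character(0),
    stringsAsFactors = FALSE)
}

empty_contacts <- function() {
  data.frame(kind = character(0), ligand_atom = character(0),
             partner_atom = character(0), res_name = character(0),
             res_no = integer(0), chain = character(0),
             residue = character(0), distance = numeric(0),
             angle = numeric(0), strength_class = character(0),
             angle_basis = character(0), stringsAsFactors = FALSE)
}

#' Detect hydrogen bonds between ligand and protein
#'
#' Donors are N/O/S atoms carrying at least one hydrogen (explicit, or
#' inferred from covalent geometry); acceptors are N/O atoms, plus
#' carbon-bound halogens which can only reach the weak class. The reported
#' distance is the heavy-atom donor...acceptor separation; the angle is the
#' best donor-H...acceptor angle over the donor's hydrogens. When the
#' structure carries no hydrogens and `infer_hydrogens = TRUE`, a
#' heavy-atom surrogate is used instead: the angle at the donor between its
#' bonded heavy-atom antecedent and the acceptor, compared against
#' `angle_min_noh`.
#'
#' Contacts with `d <= d_max` and angle `>= angle_min` are classed
#' `"strong"`; contacts only inside the wider envelope
#' (`d <= d_max_weak`, angle `>= angle_min_weak`) are `"weak"`.
#'
#' @param cx a `lig_complex` from [load_complex()].
#' @param d_max,angle_min strong-class cutoffs (3.6 Angstrom, 120 deg).
#' @param d_max_weak,angle_min_weak weak-envelope cutoffs (4.1, 90).
#' @param infer_hydrogens allow the heavy-atom surrogate angle when a donor
#'   has no hydrogens; if `FALSE` and no hydrogens exist, an error asks to
#'   enable inference.
#' @param angle_min_noh surrogate-angle cutoff (90 deg) used for donors
#'   without hydrogens.
#' @return data.frame of contacts sorted by distance (columns `kind,
#'   ligand_atom, partner_atom, res_name, res_no, chain, residue, distance,
#'   angle, strength_class`).
#' @export
detect_hbonds <- function(cx, d_max = 3.6, d_max_weak = 4.1,
                          angle_min = 120, angle_min_weak = 90,
                          infer_hydrogens = TRUE, angle_min_noh = 90) {
  lig <- cx$ligand; prot <- cx$protein
  lig_bonds <- infer_bonds(lig)
  lig_adj <- bond_adj(lig, lig_bonds)
  prot_bonds <- infer_bonds_protein(prot)
  prot_adj <- bond_adj(prot, prot_bonds)

  res <- empty_contacts()
  # both directions: ligand donor -> protein acceptor, and converse
  res <- rbind(res,
               hbond_pass(lig, lig_adj, prot, prot_adj, cx, "lig_donor",
                          d_max, d_max_weak, angle_min, angle_min_weak,
                          infer_hydrogens, angle_min_noh),
               hbond_pass(prot, prot_adj, lig, lig_adj, cx, "prot_donor",
                          d_max, d_max_weak, angle_min, angle_min_weak,
                          infer_hydrogens, angle_min_noh))
  # the two directed passes can report the same atom pair (donor/acceptor
  # roles are ambiguous without hydrogens); keep the better record: strong
  # before weak, a measured D-H...A angle before a heavy-atom surrogate
  if (nrow(res) > 1L) {
    res <- res[order(res$strength_class != "strong",
                     res$angle_basis != "explicit_h", -res$angle), ,
               drop = FALSE]
    res <- res[!duplicated(paste(res$ligand_atom, res$partner_atom,
                                 sep = "->")), , drop = FALSE]
  }
  res <- res[order(res$distance), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# residue-aware donor typing for the protein side: backbone and amide N
# donate; carbonyl/carboxylate O never do; hydroxyl O (Ser/Thr/Tyr) and
# Cys S do; water O does when waters are retained
protein_donor_ok <- function(df, i) {
  el <- df$element[i]
  if (df$resid[i] %in% c("HOH", "WAT", "DOD", "H2O")) return(el == "O")
  if (el == "N") return(TRUE)
  if (el == "S") return(df$resid[i] == "CYS")
  if (el == "O") return(df$elety[i] %in% c("OG", "OG1", "OH"))
  FALSE
}

# one directed donor->acceptor detection pass
hbond_pass <- function(ddf, dadj, adf, aadj, cx, direction,
                       d_max, d_max_weak, angle_min, angle_min_weak,
                       infer_hydrogens, angle_min_noh) {
  donors <- which(ddf$element %in% c("N", "O", "S"))
  if (length(donors)) {
    has_h <- vapply(donors, function(i)
      any(ddf$element[dadj[[i]]] == "H"), logical(1))
    if (direction == "prot_donor") {
      ok <- vapply(donors, function(i) protein_donor_ok(ddf, i),
                   logical(1))
      keep <- ok | has_h
    } else {
      # ligand chemistry is unknown: O donates only with an explicit H
      keep <- has_h | ddf$element[donors] != "O"
    }
    donors <- donors[keep]
    has_h <- has_h[keep]
  } else has_h <- logical(0)
  any_h_in_struct <- any(ddf$element == "H") || any(adf$element == "H")
  if (length(donors) && !any(has_h) && !any_h_in_struct &&
      !infer_hydrogens)
    stop("structure has no hydrogens; re-run with infer_hydrogens = TRUE ",
         "to use the heavy-atom surrogate angle", call. = FALSE)
  acc_strong <- which(adf$element %in% c("N", "O"))
  acc_weak <- which(adf$element %in% c("Cl", "Br", "I", "F"))
  acceptors <- c(acc_strong, acc_weak)
  if (!length(donors) || !length(acceptors)) return(empty_contacts())
  dpos <- as.matrix(ddf[donors, c("x", "y", "z"), drop = FALSE])
  apos <- as.matrix(adf[acceptors, c("x", "y", "z"), drop = FALSE])
  cand <- grid_pairs(dpos, apos, d_max_weak)
  out <- empty_contacts()
  for (k in seq_len(nrow(cand))) {
    di <- donors[cand$i[k]]; ai <- acceptors[cand$j[k]]
    d <- cand$d[k]
    if (d < 1.5) next  # covalent range, not an H-bond
    weak_only_acceptor <- adf$element[ai] %in% c("Cl", "Br", "I", "F")
    p_d <- as.numeric(ddf[di, c("x", "y", "z")])
    p_a <- as.numeric(adf[ai, c("x", "y", "z")])
    hs <- dadj[[di]][ddf$element[dadj[[di]]] == "H"]
    basis <- "explicit_h"
    if (length(hs)) {
      ang <- max(vapply(hs, function(h)
        angle_deg(p_d, as.numeric(ddf[h, c("x", "y", "z")]), p_a),
        numeric(1)))
      a_min_strong <- angle_min; a_min_weak <- angle_min_weak
    } else {
      heavies <- dadj[[di]][ddf$element[dadj[[di]]] != "H"]
      if (!length(heavies)) next
      if (!infer_hydrogens) next
      ang <- max(vapply(heavies, function(hv)
        angle_deg(as.numeric(ddf[hv, c("x", "y", "z")]), p_d, p_a),
        numeric(1)))
      a_min_strong <- angle_min_noh; a_min_weak <- angle_min_noh
      basis <- "surrogate"
    }
    strong <- d <= d_max && ang >= a_min_strong && !weak_only_acceptor
    weak <- d <= d_max_weak && ang >= a_min_weak
    if (!strong && !weak) next
    cls <- if (strong) "strong" else "weak"
    if (direction == "lig_donor") {
      out <- rbind(out, new_contacts("hbond", ddf, di, adf, ai, d, ang,
                                     cls, basis))
    } else {
      # ligand is the acceptor side; report ligand atom + protein residue
      out <- rbind(out, new_contacts("hbond", adf, ai, ddf, di, d, ang,
                                     cls, basis))
    }
  }
  out
}

# bonds in the protein inferred per residue (backbone O to C etc.); cheap
# and local, which is all the angle surrogates need
infer_bonds_protein <- function(prot) {
  if (nrow(prot) == 0L) return(matrix(integer(0), ncol = 2))
  key <- paste(prot$chain, prot$resno, prot$insert, sep = "|")
  out <- matrix(integer(0), ncol = 2)
  for (k in unique(key)) {
    idx <- which(key == k)
    sub <- prot[idx, , drop = FALSE]
    b <- infer_bonds(sub)
    if (nrow(b)) out <- rbind(out, cbind(idx[b[, 1]], idx[b[, 2]]))
  }
  out
}

#' Detect halogen bonds between ligand and protein
#'
#' Carbon-bound Cl/Br/I on the ligand acting through the sigma-hole toward
#' protein acceptors O/N/S: reported when the X...A distance is at most
#' `d_max` and the C-X...A angle is at least `angle_min`. Fluorine is
#' excluded by default (its sigma-hole is negligible).
#'
#' @inheritParams detect_hbonds
#' @param d_max X...acceptor distance cutoff (3.8 Angstrom).
#' @param angle_min C-X...A angle cutoff (140 deg).
#' @param halogens ligand halogen elements considered.
#' @return contact data.frame (strength class `"strong"`), sorted by
#'   distance; empty when the ligand has no eligible halogens.
#' @export
detect_halogen_bonds <- function(cx, d_max = 3.8, angle_min = 140,
                                 halogens = c("Cl", "Br", "I")) {
  lig <- cx$ligand; prot <- cx$protein
  xs <- which(lig$element %in% halogens)
  if (!length(xs)) return(empty_contacts())
  adj <- bond_adj(lig, infer_bonds(lig))
  acc <- which(prot$element %in% c("O", "N", "S"))
  if (!length(acc)) return(empty_contacts())
  xpos <- as.matrix(lig[xs, c("x", "y", "z"), drop = FALSE])
  apos <- as.matrix(prot[acc, c("x", "y", "z"), drop = FALSE])
  cand <- grid_pairs(xpos, apos, d_max)
  out <- empty_contacts()
  for (k in seq_len(nrow(cand))) {
    xi <- xs[cand$i[k]]; ai <- acc[cand$j[k]]
    carbons <- adj[[xi]][lig$element[adj[[xi]]] == "C"]
    if (!length(carbons)) next  # halogen must be carbon-bound
    p_x <- as.numeric(lig[xi, c("x", "y", "z")])
    p_a <- as.numeric(prot[ai, c("x", "y", "z")])
    ang <- max(vapply(carbons, function(ci)
      angle_deg(as.numeric(lig[ci, c("x", "y", "z")]), p_x, p_a),
      numeric(1)))
    if (ang < angle_min) next
    out <- rbind(out, new_contacts("halogen_bond", lig, xi, prot, ai,
                                   cand$d[k], ang, "strong"))
  }
  out <- out[order(out$distance), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect hydrophobic contacts between ligand and protein
#'
#' Apolar carbon (not bonded to N/O/S) to apolar carbon pairs within
#' `d_max`, aggregated to one record per (ligand atom, residue) at the
#' minimum observed distance. No angle is reported.
#'
#' @inheritParams detect_hbonds
#' @param d_max C...C cutoff (4.0 Angstrom).
#' @return contact data.frame (`angle` is `NA`), sorted by distance.
#' @export
detect_hydrophobic <- function(cx, d_max = 4.0) {
  lig <- cx$ligand; prot <- cx$protein
  lig_adj <- bond_adj(lig, infer_bonds(lig))
  prot_adj <- bond_adj(prot, infer_bonds_protein(prot))
  apolar <- function(df, adj) {
    which(vapply(seq_len(nrow(df)), function(i) {
      df$element[i] == "C" &&
        !any(df$element[adj[[i]]] %in% c("N", "O", "S"))
    }, logical(1)))
  }
  lc <- apolar(lig, lig_adj)
  pc <- apolar(prot, prot_adj)
  if (!length(lc) || !length(pc)) return(empty_contacts())
  cand <- grid_pairs(as.matrix(lig[lc, c("x", "y", "z"), drop = FALSE]),
                     as.matrix(prot[pc, c("x", "y", "z"), drop = FALSE]),
                     d_max)
  if (!nrow(cand)) return(empty_contacts())
  li <- lc[cand$i]; pi_ <- pc[cand$j]
  keys <- paste(li, prot$chain[pi_], prot$resno[pi_], prot$insert[pi_],
                sep = "|")
  keep <- vapply(split(seq_along(keys), keys), function(rows)
    rows[which.min(cand$d[rows])], integer(1))
  out <- new_contacts("hydrophobic", lig, li[keep], prot, pi_[keep],
                      cand$d[keep], NA_real_, "strong")
  out <- out[order(out$distance), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect all contact kinds at once (default criteria)
#' @inheritParams detect_hbonds
#' @return combined contact data.frame sorted by distance.
#' @export
detect_contacts <- function(cx) {
  out <- rbind(detect_hbonds(cx), detect_halogen_bonds(cx),
               detect_hydrophobic(cx))
  out <- out[order(out$distance), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Collapse contacts into a binding fingerprint
#'
#' @param contacts contact data.frame from the detectors.
#' @param perspective key by `"residue"` (residue name + number) or
#'   `"ligand_atom"`.
#' @param weighting `"count"` (number of contacts per key) or
#'   `"distance_weight"` (sum of 1/d per key).
#' @param ligand_id id stored on the fingerprint.
#' @return a [binding_fingerprint] with `source = "contacts"`; empty
#'   contacts give an empty fingerprint.
#' @export
contacts_to_fingerprint <- function(contacts,
                                    perspective = c("residue",
                                                    "ligand_atom"),
                                    weighting = c("count",
                                                  "distance_weight"),
                                    ligand_id = "") {
  perspective <- match.arg(perspective)
  weighting <- match.arg(weighting)
  if (nrow(contacts) == 0L)
    return(binding_fingerprint(numeric(0), ligand_id = ligand_id,
                               source = "contacts"))
  keys <- if (perspective == "residue") contacts$residue else
    contacts$ligand_atom
  w <- if (weighting == "count") rep(1, nrow(contacts)) else
    1 / contacts$distance
  vals <- vapply(split(w, keys), sum, numeric(1))
  binding_fingerprint(vals, ligand_id = ligand_id, source = "contacts")
}

#' Write a contact report as TSV or JSON
#' @param contacts contact data.frame.
#' @param path output path; format from extension (`.tsv`/`.json`).
#' @export
write_contacts <- function(contacts, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(contacts, path, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    utils::write.table(contacts, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
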