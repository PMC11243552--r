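#' Load a protein-ligand complex from a PDB file
#'
#' Reads a PDB file (via bio3d), resolves alternate locations to the
#' highest-occupancy copy (ties broken by altloc letter order), excludes
#' waters by default, and splits the atoms into the protein and the
#' selected hetero (ligand) group.
#'
#' @param path PDB file path.
#' @param ligand_selector list with `resid` (hetero residue name) and
#'   optionally `chain` and `resno`; must match exactly one hetero group.
#' @param keep_waters retain water molecules among the protein-side atoms
#'   (enables water-bridge reporting in [detect_hbonds]).
#' @return object of class `lig_complex` with data.frames `protein` and
#'   `ligand` (columns `eleno, elety, element, resid, chain, resno, insert,
#'   x, y, z, o, b`).
#' @export
load_complex <- function(path, ligand_selector, keep_waters = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.character(ligand_selector))
    ligand_selector <- list(resid = ligand_selector)
  if (is.null(ligand_selector$resid))
    stop("ligand_selector needs at least a 'resid'", call. = FALSE)
  pdb <- suppressWarnings(bio3d::read.pdb(path, verbose = FALSE,
                                          rm.alt = FALSE))
  at <- pdb$atom
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  at$b[is.na(at$b)] <- 0
  at$element <- derive_element(at$elesy, at$elety)
  if (any(!is.finite(at$x) | !is.finite(at$y) | !is.finite(at$z)))
    stop("non-finite coordinates in ", path, call. = FALSE)
  at <- resolve_altloc(at)
  water <- at$resid %in% c("HOH", "WAT", "DOD", "H2O")
  het <- at$type == "HETATM" & !water
  sel <- het & at$resid == ligand_selector$resid
  if (!is.null(ligand_selector$chain))
    sel <- sel & at$chain == ligand_selector$chain
  if (!is.null(ligand_selector$resno))
    sel <- sel & at$resno == ligand_selector$resno
  groups <- unique(at[sel, c("resid", "chain", "resno")])
  if (nrow(groups) != 1L) {
    cand <- unique(at[het, c("resid", "chain", "resno")])
    cand_str <- if (nrow(cand)) paste(apply(cand, 1, paste, collapse = "/"),
                                      collapse = ", ") else "none"
    stop("ligand selector matched ", nrow(groups),
         " hetero groups (need exactly 1); candidates: ", cand_str,
         call. = FALSE)
  }
  lig <- at[sel, , drop = FALSE]
  prot <- at[!sel & (at$type == "ATOM" | (keep_waters & water)), ,
             drop = FALSE]
  cols <- c("eleno", "elety", "element", "resid", "chain", "resno",
            "insert", "x", "y", "z", "o", "b")
  structure(list(protein = prot[, cols], ligand = lig[, cols],
                 selector = as.list(groups[1, ])),
            class = "lig_complex")
}

#' @export
print.lig_complex <- function(x, ...) {
  cat("<complex>", nrow(x$protein), "protein atoms;",
      nrow(x$ligand), "ligand atoms (",
      paste(x$selector$resid, x$selector$chain, x$selector$resno,
            sep = "/"), ")\n")
  invisible(x)
}

derive_element <- function(elesy, elety) {
  el <- toupper(trimws(elesy))
  miss <- is.na(el) | !nzchar(el)
  if (any(miss)) {
    guess <- gsub("[0-9']", "", toupper(trimws(elety[miss])))
    two <- substr(guess, 1, 2)
    el[miss] <- ifelse(two %in% c("CL", "BR", "FE", "ZN", "MG", "NA", "SE"),
                       two, substr(guess, 1, 1))
  }
  # normalize case: "BR" -> "Br"
  ifelse(nchar(el) == 2,
         paste0(substr(el, 1, 1), tolower(substr(el, 2, 2))), el)
}

# keep, per (chain, resno, insert, resid, elety), the highest-occupancy
# altloc; ties broken by altloc letter order
resolve_altloc <- function(at) {
  key <- paste(at$chain, at$resno, at$insert, at$resid, at$elety, sep = "|")
  if (!anyDuplicated(key)) return(at)
  ord <- order(key, -at$o, at$alt)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(key[ord]), , drop = FALSE]
  at[order(at$eleno), , drop = FALSE]
}

# atom reference: list(part = "ligand"|"protein", name = elety,
# resno = NULL, chain = NULL); or compact string "ligand:BR1",
# "protein:116:O", "protein:A:116:O"
find_atom <- function(cx, ref) {
  orig <- ref
  if (is.character(ref) && length(ref) == 1L) {
    parts <- strsplit(ref, ":")[[1]]
    ref <- switch(as.character(length(parts)),
      "2" = list(part = parts[1], name = parts[2]),
      "3" = list(part = parts[1], resno = as.integer(parts[2]),
                 name = parts[3]),
      "4" = list(part = parts[1], chain = parts[2],
                 resno = as.integer(parts[3]), name = parts[4]),
      stop("unparseable atom reference: ", orig, call. = FALSE))
  }
  df <- switch(ref$part, ligand = cx$ligand, protein = cx$protein,
               stop("atom reference part must be 'ligand' or 'protein'",
                    call. = FALSE))
  sel <- df$elety == ref$name
  if (!is.null(ref$resno)) sel <- sel & df$resno == ref$resno
  if (!is.null(ref$chain)) sel <- sel & df$chain == ref$chain
  hit <- which(sel)
  if (length(hit) == 0L)
    stop("atom not found: ", paste(unlist(orig), collapse = ":"),
         call. = FALSE)
  if (length(hit) > 1L)
    stop("ambiguous atom reference (", length(hit), " matches): ",
         paste(unlist(orig), collapse = ":"), call. = FALSE)
  df[hit, , drop = FALSE]
}

#' Measure a distance and optional angle in a complex
#'
#' Pure geometry, independent of any detection criteria: the Euclidean
#' distance a--b, and the angle a--b--c (vertex at b, degrees) when a
#' third reference is given.
#'
#' @param cx a `lig_complex`.
#' @param a,b,c atom references: either a list
#'   `list(part, name, resno, chain)` or a compact string such as
#'   `"ligand:BR1"` or `"protein:A:116:O"`. `c` is optional.
#' @return list with `distance` (Angstrom) and `angle` (degrees or NA).
#' @export
measure_geometry <- function(cx, a, b, c = NULL) {
  pa <- as.numeric(find_atom(cx, a)[, c("x", "y", "z")])
  pb <- as.numeric(find_atom(cx, b)[, c("x", "y", "z")])
  out <- list(distance = vec_norm(pa - pb), angle = NA_real_)
  if (!is.null(c)) {
    pc <- as.numeric(find_atom(cx, c)[, c("x", "y", "z")])
    out$angle <- angle_deg(pa, pb, pc)
  }
  out
}
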