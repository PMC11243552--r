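#' Per-residue flexibility profiles
#'
#' A flexibility profile holds one value per residue: crystallographic
#' B-factors (Angstrom^2) or simulation RMSF (Angstrom).
#'
#' @param structure_id structure label (e.g. a PDB accession).
#' @param kind `"bfactor"` or `"rmsf"`.
#' @param chain,resno,value parallel vectors (one entry per residue).
#' @return data.frame of class `flex_profile` with attributes
#'   `structure_id`, `kind` and `units`.
#' @export
flex_profile <- function(structure_id, kind = c("bfactor", "rmsf"),
                         chain, resno, value) {
  kind <- match.arg(kind)
  df <- data.frame(chain = as.character(chain), resno = as.integer(resno),
                   value = as.numeric(value), stringsAsFactors = FALSE)
  if (any(!is.finite(df$value)))
    stop("profile values must be finite", call. = FALSE)
  if (anyDuplicated(df[, c("chain", "resno")]))
    stop("duplicate residue keys in profile", call. = FALSE)
  structure(df, class = c("flex_profile", "data.frame"),
            structure_id = structure_id, kind = kind,
            units = if (kind == "bfactor") "A^2" else "A")
}

#' @export
print.flex_profile <- function(x, ...) {
  cat("<flex profile>", attr(x, "structure_id"), "-", attr(x, "kind"),
      "(", attr(x, "units"), "),", nrow(x), "residues\n")
  invisible(x)
}

#' Extract per-residue B-factors from a complex
#'
#' @param cx a `lig_complex` from [load_complex()].
#' @param per `"residue_mean"` (mean B over the residue's atoms) or
#'   `"calpha"` (the CA atom's B; residues without a CA are skipped with a
#'   warning).
#' @param structure_id label for the resulting profile.
#' @return a `flex_profile` of kind `"bfactor"`.
#' @export
extract_bfactors <- function(cx, per = c("residue_mean", "calpha"),
                             structure_id = "structure") {
  per <- match.arg(per)
  prot <- cx$protein
  if (nrow(prot) == 0L) stop("no protein atoms in complex", call. = FALSE)
  key <- paste(prot$chain, prot$resno, sep = "|")
  if (per == "residue_mean") {
    agg <- vapply(split(prot$b, key), mean, numeric(1))
    keys <- names(agg)
  } else {
    ca <- prot[prot$elety == "CA", , drop = FALSE]
    missing_ca <- setdiff(unique(key), paste(ca$chain, ca$resno, sep = "|"))
    if (length(missing_ca))
      warning(length(missing_ca),
              " residue(s) without a CA atom skipped", call. = FALSE)
    if (nrow(ca) == 0L) stop("no CA atoms in complex", call. = FALSE)
    agg <- setNames(ca$b, paste(ca$chain, ca$resno, sep = "|"))
    keys <- names(agg)
  }
  parts <- strsplit(keys, "|", fixed = TRUE)
  ord <- order(vapply(parts, `[`, character(1), 1),
               as.integer(vapply(parts, `[`, character(1), 2)))
  flex_profile(structure_id, "bfactor",
               chain = vapply(parts, `[`, character(1), 1)[ord],
               resno = as.integer(vapply(parts, `[`, character(1), 2))[ord],
               value = unname(agg)[ord])
}

#' Read an RMSF profile from a two-column CSV (residue, value)
#'
#' @param path CSV path; first column residue number, second RMSF in
#'   Angstrom. An optional `chain` column is honoured.
#' @param structure_id label for the profile.
#' @param chain chain assigned when the file has no chain column.
#' @return a `flex_profile` of kind `"rmsf"`.
#' @export
read_rmsf_profile <- function(path, structure_id = basename(path),
                              chain = "A") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("RMSF CSV needs two columns (residue, value)",
                          call. = FALSE)
  ch <- if ("chain" %in% names(df)) df$chain else chain
  resno_col <- setdiff(names(df), "chain")[1]
  value_col <- setdiff(names(df), c("chain", resno_col))[1]
  flex_profile(structure_id, "rmsf", chain = ch,
               resno = as.integer(df[[resno_col]]),
               value = parse_num(df[[value_col]]))
}

#' Normalize a flexibility profile to per-chain z-scores
#'
#' Standard crystallographic B-factor normalization: within each chain,
#' `(v - mean) / sd` with the population standard deviation, giving mean 0
#' and standard deviation 1 per chain. Idempotent on already-normalized
#' input.
#'
#' @param p a `flex_profile` with >= 2 residues and nonzero spread in
#'   every chain.
#' @return the normalized `flex_profile` (units become z-scores).
#' @export
normalize_profile <- function(p) {
  stopifnot(inherits(p, "flex_profile"))
  out <- p
  for (ch in unique(p$chain)) {
    i <- p$chain == ch
    v <- p$value[i]
    if (length(v) < 2L)
      stop("chain ", ch, ": need >= 2 residues to normalize",
           call. = FALSE)
    sdev <- sqrt(mean((v - mean(v))^2))
    if (sdev < 1e-12)
      stop("constant profile in chain ", ch, call. = FALSE)
    out$value[i] <- (v - mean(v)) / sdev
  }
  attr(out, "units") <- "z"
  out
}

#' Difference between two normalized flexibility profiles
#'
#' Computes `p - ref` on the intersection of (chain, residue) keys,
#' optionally after shifting `p`'s residue numbering by `offset` (for
#' structures whose numbering differs by a constant).
#'
#' @param p,ref normalized `flex_profile` objects of the same kind.
#' @param offset integer added to `p`'s residue numbers before matching.
#' @return a `flex_profile` of differences on the shared residues.
#' @export
delta_profile <- function(p, ref, offset = 0L) {
  stopifnot(inherits(p, "flex_profile"), inherits(ref, "flex_profile"))
  pk <- paste(p$chain, p$resno + as.integer(offset), sep = "|")
  rk <- paste(ref$chain, ref$resno, sep = "|")
  common <- intersect(pk, rk)
  if (length(common) == 0L)
    stop("profiles share no residues", call. = FALSE)
  pi_ <- match(common, pk)
  ri <- match(common, rk)
  flex_profile(paste0(attr(p, "structure_id"), "-",
                      attr(ref, "structure_id")),
               attr(p, "kind"),
               chain = ref$chain[ri], resno = ref$resno[ri],
               value = p$value[pi_] - ref$value[ri])
}

#' Flexibility-difference heatmap across structures
#'
#' One row per profile: its [delta_profile()] against the common
#' reference, on the residues shared by every profile and the reference.
#' Rendered with the red-blue diverging scheme (red = more rigid end by
#' the B-factor sign convention).
#'
#' @param profiles named list of normalized `flex_profile` objects.
#' @param ref normalized reference `flex_profile`.
#' @return `heatmap_matrix`: rows = structures, columns = residues.
#' @export
flex_heatmap <- function(profiles, ref) {
  if (!length(profiles)) stop("need >= 1 profile", call. = FALSE)
  deltas <- lapply(profiles, delta_profile, ref = ref)
  keysets <- lapply(deltas, function(d) paste(d$chain, d$resno, sep = "|"))
  common <- Reduce(intersect, keysets)
  if (!length(common))
    stop("profiles share no residues with the reference", call. = FALSE)
  ids <- names(profiles) %||% vapply(profiles, attr, character(1),
                                     "structure_id")
  if (is.null(ids) || any(!nzchar(ids)))
    ids <- vapply(profiles, attr, character(1), "structure_id")
  m <- t(vapply(deltas, function(d) {
    k <- paste(d$chain, d$resno, sep = "|")
    d$value[match(common, k)]
  }, numeric(length(common))))
  rownames(m) <- ids
  colnames(m) <- sub("^[^|]*\\|", "", common)
  structure(m, class = c("heatmap_matrix", "matrix"),
            normalization = "none", color_scheme = "red_yellow_blue")
}
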