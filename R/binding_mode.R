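#' Binding-mode fingerprints
#'
#' A binding fingerprint is a sparse named vector of interaction strengths
#' keyed by residue (or ligand atom): kcal/mol for energy-derived entries,
#' dimensionless for count/weight entries. The `source` field records which
#' of the two it is so the types are never mixed.
#'
#' @param entries named numeric vector (unique keys, finite values).
#' @param ligand_id ligand identifier.
#' @param source `"contacts"` or `"energy_table"`.
#' @return object of class `binding_fp`.
#' @export
binding_fingerprint <- function(entries, ligand_id = "",
                                source = c("contacts", "energy_table")) {
  source <- match.arg(source)
  entries <- unlist(entries)
  if (length(entries)) {
    if (is.null(names(entries)) || any(!nzchar(names(entries))))
      stop("all fingerprint entries must be named", call. = FALSE)
    if (anyDuplicated(names(entries)))
      stop("duplicate fingerprint keys", call. = FALSE)
    if (any(!is.finite(entries)))
      stop("fingerprint strengths must be finite", call. = FALSE)
  } else entries <- setNames(numeric(0), character(0))
  structure(list(ligand_id = ligand_id, entries = entries, source = source),
            class = "binding_fp")
}

#' @export
print.binding_fp <- function(x, ...) {
  cat("<binding fingerprint>", x$ligand_id, "-", length(x$entries),
      "keys (", x$source, ")\n")
  if (length(x$entries)) print(head(sort(x$entries), 6))
  invisible(x)
}

as_binding_fp <- function(x) {
  if (inherits(x, "binding_fp")) return(x)
  binding_fingerprint(x)
}

#' Align two binding fingerprints onto the union of their keys
#'
#' Missing entries are filled with 0 (an uncontacted residue contributes no
#' interaction strength). The key order is the deterministic sorted union.
#'
#' @param p,q `binding_fp` objects (or named numeric vectors).
#' @return list with numeric vectors `P`, `Q` and character `keys`.
#' @export
align_fingerprints <- function(p, q) {
  p <- as_binding_fp(p); q <- as_binding_fp(q)
  keys <- sort(union(names(p$entries), names(q$entries)))
  pv <- setNames(rep(0, length(keys)), keys)
  qv <- pv
  pv[names(p$entries)] <- p$entries
  qv[names(q$entries)] <- q$entries
  list(P = unname(pv), Q = unname(qv), keys = keys)
}

#' Root-mean-square deviation between binding modes (RMSD_BM)
#'
#' `sqrt((1/n) * sum_i (p_i - q_i)^2)` over the aligned union of keys;
#' symmetric and nonnegative. Equals the Euclidean mode distance divided
#' by `sqrt(n)`.
#'
#' @inheritParams align_fingerprints
#' @return a single nonnegative number.
#' @examples
#' p <- binding_fingerprint(c(A = 1, B = 2, C = 3))
#' q <- binding_fingerprint(c(A = 4, B = 2, C = 3))
#' rmsd_bm(p, q)  # sqrt(3)
#' @export
rmsd_bm <- function(p, q) {
  al <- align_fingerprints(p, q)
  if (length(al$keys) == 0L)
    stop("no interactions to compare", call. = FALSE)
  sqrt(mean((al$P - al$Q)^2))
}

#' Distance between binding modes
#'
#' Manhattan (`sum |p_i - q_i|`), Euclidean (`sqrt(sum (p_i - q_i)^2)`),
#' or the signed additive balance (`sum (p_i - q_i)`, whose sign reports
#' which mode binds more strongly overall).
#'
#' @inheritParams align_fingerprints
#' @param metric `"manhattan"`, `"euclidean"` or `"additive"`.
#' @return a single number (signed for `"additive"`).
#' @export
mode_distance <- function(p, q, metric = c("manhattan", "euclidean",
                                           "additive")) {
  metric <- match.arg(metric)
  al <- align_fingerprints(p, q)
  if (length(al$keys) == 0L)
    stop("no interactions to compare", call. = FALSE)
  diff <- al$P - al$Q
  switch(metric,
         manhattan = sum(abs(diff)),
         euclidean = sqrt(sum(diff^2)),
         additive = sum(diff))
}

#' Rank fingerprint keys by mean interaction magnitude
#'
#' Keys (residues or ligand atoms) sorted by descending mean absolute
#' strength across the given fingerprints (missing entries count as 0,
#' matching the alignment convention); ties broken lexicographically.
#' Energies are negative, so magnitude ordering is the "strongest first"
#' ordering.
#'
#' @param fingerprints list of `binding_fp` objects (>= 1).
#' @return character vector of keys, strongest first.
#' @export
rank_keys <- function(fingerprints) {
  if (length(fingerprints) < 1L) stop("need >= 1 fingerprint",
                                      call. = FALSE)
  fingerprints <- lapply(fingerprints, as_binding_fp)
  keys <- sort(unique(unlist(lapply(fingerprints, function(f)
    names(f$entries)))))
  if (!length(keys)) return(character(0))
  m <- sapply(fingerprints, function(f) {
    v <- setNames(rep(0, length(keys)), keys)
    v[names(f$entries)] <- f$entries
    v
  })
  m <- matrix(m, nrow = length(keys), dimnames = list(keys, NULL))
  score <- rowMeans(abs(m))
  keys[order(-score, keys)]
}

#' Build a heatmap matrix from fingerprints or an energy table
#'
#' For a list of binding fingerprints the rows are keys ordered by
#' [rank_keys()] and the columns are ligands. For an energy table the rows
#' are the energy components (`e_protein_ligand, steric, vdw, hbond`) and
#' the columns are ligand ids, preserving the table's values exactly.
#'
#' @param x list of `binding_fp`, or an energy table data.frame from
#'   [ingest_energy_table()].
#' @param rows,cols optional explicit row/column label subsets (applied
#'   after construction).
#' @param normalization `"none"`, `"per_matrix"` (divide by the global max
#'   absolute value) or `"per_row"` (each row scaled to max |value| = 1).
#' @param color_scheme `"red_yellow_green"` or `"red_yellow_blue"` (plot
#'   metadata only).
#' @return object of class `heatmap_matrix`: a numeric matrix with
#'   `normalization` and `color_scheme` attributes.
#' @export
build_heatmap <- function(x, rows = NULL, cols = NULL,
                          normalization = c("none", "per_matrix",
                                            "per_row"),
                          color_scheme = c("red_yellow_green",
                                           "red_yellow_blue")) {
  normalization <- match.arg(normalization)
  color_scheme <- match.arg(color_scheme)
  if (is.data.frame(x)) {
    comp <- c("e_protein_ligand", "steric", "vdw", "hbond")
    missing_cols <- setdiff(c("id", comp), names(x))
    if (length(missing_cols))
      stop("energy table lacks column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    m <- t(as.matrix(x[, comp]))
    colnames(m) <- x$id
    rownames(m) <- comp
  } else {
    fps <- lapply(x, as_binding_fp)
    ids <- vapply(seq_along(fps), function(i) {
      id <- fps[[i]]$ligand_id
      if (nzchar(id)) id else paste0("fp_", i)
    }, character(1))
    keys <- rank_keys(fps)
    m <- vapply(fps, function(f) {
      v <- setNames(rep(0, length(keys)), keys)
      v[names(f$entries)] <- f$entries
      v
    }, numeric(length(keys)))
    m <- matrix(m, nrow = length(keys), dimnames = list(keys, ids))
  }
  if (!is.null(rows)) {
    if (!all(rows %in% rownames(m)))
      stop("unknown row label(s)", call. = FALSE)
    m <- m[rows, , drop = FALSE]
  }
  if (!is.null(cols)) {
    if (!all(cols %in% colnames(m)))
      stop("unknown column label(s)", call. = FALSE)
    m <- m[, cols, drop = FALSE]
  }
  if (any(!is.finite(m))) stop("heatmap values must be finite",
                               call. = FALSE)
  m <- switch(normalization,
              none = m,
              per_matrix = if (max(abs(m)) > 0) m / max(abs(m)) else m,
              per_row = t(apply(m, 1, function(r)
                if (max(abs(r)) > 0) r / max(abs(r)) else r)))
  if (is.null(dim(m))) m <- matrix(m, nrow = nrow(x))  # defensive
  structure(m, class = c("heatmap_matrix", "matrix"),
            normalization = normalization, color_scheme = color_scheme)
}

#' @export
print.heatmap_matrix <- function(x, ...) {
  cat("<heatmap>", nrow(x), "x", ncol(x), "(",
      attr(x, "normalization"), ",", attr(x, "color_scheme"), ")\n")
  print(unclass(x)[seq_len(min(6, nrow(x))),
                   seq_len(min(6, ncol(x))), drop = FALSE])
  invisible(x)
}

#' @param hm a `heatmap_matrix`.
#' @param path CSV path.
#' @rdname heatmap_io
#' @export
write_heatmap_csv <- function(hm, path) {
  df <- as.data.frame(apply(unclass(hm), 2, fmt_full))
  if (nrow(df) != nrow(hm)) df <- as.data.frame(t(df))  # 1-row matrices
  dimnames(df) <- dimnames(hm)
  df <- cbind(row = rownames(hm), df)
  utils::write.table(df, path, sep = ",", quote = TRUE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' Heatmap matrix CSV round trip
#'
#' `write_heatmap_csv()` serializes the matrix with full-precision
#' numerics so that `read_heatmap_csv()` restores the values bit-exactly.
#'
#' @rdname heatmap_io
#' @param normalization,color_scheme metadata restored on read.
#' @export
read_heatmap_csv <- function(path, normalization = "none",
                             color_scheme = "red_yellow_green") {
  df <- utils::read.csv(path, check.names = FALSE)
  rn <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- rn
  structure(m, class = c("heatmap_matrix", "matrix"),
            normalization = normalization, color_scheme = color_scheme)
}

#' @export
plot.heatmap_matrix <- function(x, main = "", ...) {
  scheme <- attr(x, "color_scheme") %||% "red_yellow_green"
  cols <- if (scheme == "red_yellow_green")
    colorRampPalette(c("darkgreen", "yellow", "darkred"))(64)
  else colorRampPalette(c("darkblue", "white", "darkred"))(64)
  m <- unclass(x)
  image(seq_len(ncol(m)), seq_len(nrow(m)), t(m[rev(seq_len(nrow(m))), ,
                                                drop = FALSE]),
        col = cols, axes = FALSE, xlab = "", ylab = "", main = main)
  axis(1, at = seq_len(ncol(m)), labels = colnames(m), las = 2,
       cex.axis = 0.6)
  axis(2, at = seq_len(nrow(m)), labels = rev(rownames(m)), las = 2,
       cex.axis = 0.6)
  invisible(x)
}
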