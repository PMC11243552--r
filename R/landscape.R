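#' Structure-activity and structure-binding-affinity landscape indices
#'
#' `sali()` computes the Structure-Activity Landscape Index
#' `|A1 - A2| / (1 - s)` for a ligand pair with activities `A1, A2` and
#' structural similarity `s`. `sbai()` is the same functional applied to
#' docking binding affinities (kcal/mol) instead of measured activities:
#' the Structure-Binding Affinity Index. Both flag "cliffs": pairs of very
#' similar structures whose activity or affinity differs sharply. At
#' `s = 1` with a nonzero difference the index is infinite (an identical
#' structure with a different value); with a zero difference it is 0.
#'
#' @param a1,a2 activities (any consistent scale) for `sali`.
#' @param s structural similarity in `[0, 1]` (vectorized).
#' @return nonnegative index value(s); `Inf` for `s = 1` with differing
#'   values.
#' @examples
#' sali(10, 2, 0.75)         # 32
#' sbai(-8.67, -9.59, 0)     # 0.92
#' @export
sali <- function(a1, a2, s) {
  if (any(!is.finite(s)) || any(s < 0) || any(s > 1))
    stop("similarity s must lie in [0, 1]", call. = FALSE)
  d <- abs(a1 - a2)
  ifelse(s == 1, ifelse(d > 0, Inf, 0), d / (1 - s))
}

#' @param ba1,ba2 binding affinities in kcal/mol for `sbai`.
#' @rdname sali
#' @export
sbai <- function(ba1, ba2, s) sali(ba1, ba2, s)

#' All-pairs landscape table
#'
#' Computes the landscape index for every unordered ligand pair from a
#' value table and a similarity matrix, together with a capped version of
#' the index (the cap mirrors the truncation used when plotting the
#' otherwise unbounded index; default 2000).
#'
#' @param records data.frame with columns `ligand_id`, `value` and
#'   optionally `value_kind` (`"activity"` or `"binding_affinity"`); an
#'   [ingest_energy_table()] result is also accepted (uses
#'   `binding_affinity`).
#' @param sim `similarity_matrix` (or plain named square matrix) covering
#'   every record id.
#' @param cap finite ceiling applied to `capped_index`.
#' @return data.frame of class `landscape_pairs` with columns
#'   `id_a, id_b, s, d_val, index, capped_index`, in deterministic
#'   (record-order) pair order; attributes `cap` and `value_kind`.
#' @export
pairwise_landscape <- function(records, sim, cap = 2000) {
  if (inherits(records, "energy_table"))
    records <- data.frame(ligand_id = records$id,
                          value = records$binding_affinity,
                          value_kind = "binding_affinity",
                          stringsAsFactors = FALSE)
  stopifnot(is.data.frame(records),
            all(c("ligand_id", "value") %in% names(records)))
  if (!is.finite(cap) || cap <= 0) stop("cap must be positive and finite",
                                        call. = FALSE)
  ids <- as.character(records$ligand_id)
  if (anyDuplicated(ids)) stop("duplicate ligand ids", call. = FALSE)
  sm <- unclass(sim)
  missing_ids <- setdiff(ids, rownames(sm))
  if (length(missing_ids))
    stop("ids missing from similarity matrix: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  n <- length(ids)
  if (n < 2L) stop("need >= 2 records", call. = FALSE)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  ia <- idx[, 1]; ib <- idx[, 2]
  s <- sm[cbind(ids[ia], ids[ib])]
  d_val <- abs(records$value[ia] - records$value[ib])
  index <- sali(records$value[ia], records$value[ib], s)
  out <- data.frame(id_a = ids[ia], id_b = ids[ib], s = s, d_val = d_val,
                    index = index, capped_index = pmin(index, cap),
                    stringsAsFactors = FALSE)
  structure(out, class = c("landscape_pairs", "data.frame"), cap = cap,
            value_kind = if ("value_kind" %in% names(records))
              as.character(records$value_kind[1]) else "activity")
}

#' @export
print.landscape_pairs <- function(x, ...) {
  cat("<landscape> ", nrow(x), " ligand pairs (",
      attr(x, "value_kind"), ", cap ", attr(x, "cap"), ")\n", sep = "")
  print.data.frame(head(x[order(-x$capped_index), ], 5))
  invisible(x)
}

#' @export
summary.landscape_pairs <- function(object, ...) {
  cat("landscape pairs:", nrow(object), "\n")
  cat("similarity range:", sprintf("%.3f..%.3f", min(object$s),
                                   max(object$s)), "\n")
  cat("infinite-index pairs:", sum(is.infinite(object$index)), "\n")
  cat("top finite index:",
      if (any(is.finite(object$index)))
        sprintf("%.4g", max(object$index[is.finite(object$index)]))
      else "none", "\n")
  invisible(object)
}

#' @export
plot.landscape_pairs <- function(x, s_min = NULL, ...) {
  cex <- 0.5 + 2 * x$capped_index / max(x$capped_index, 1)
  plot(x$s, x$d_val, cex = cex, pch = 21, bg = "steelblue",
       xlab = "structural similarity s", ylab = "|value difference|", ...)
  if (!is.null(s_min)) graphics::abline(v = s_min, lty = 2)
  invisible(x)
}

#' Detect activity/affinity cliffs
#'
#' Filters pairs to `s >= s_min`, ranks them by index descending
#' (infinite-index pairs first), and returns the top fraction.
#'
#' @param pairs a `landscape_pairs` table.
#' @param s_min minimum structural similarity for a pair to count as a
#'   cliff candidate.
#' @param top_fraction fraction (0, 1] of the passing pairs to return.
#' @return the selected rows, ranked; empty when no pair passes.
#' @export
detect_cliffs <- function(pairs, s_min = 0.8, top_fraction = 0.05) {
  stopifnot(top_fraction > 0, top_fraction <= 1)
  keep <- pairs[pairs$s >= s_min, , drop = FALSE]
  if (nrow(keep) == 0L) return(keep)
  keep <- keep[order(-keep$index, -keep$d_val, keep$id_a, keep$id_b), ,
               drop = FALSE]
  n_top <- ceiling(top_fraction * nrow(keep))
  out <- keep[seq_len(n_top), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Network-like similarity graph
#'
#' Ligands are nodes; edges connect pairs whose structural similarity
#' reaches `s_threshold`. Each node carries its value and a score
#' aggregating the capped landscape index over its incident edges (the
#' maximum by default, highlighting cliff partners; the mean as an
#' option). Isolated nodes are retained with score 0.
#'
#' @param pairs a `landscape_pairs` table.
#' @param records the value table used to build `pairs`.
#' @param s_threshold edge similarity threshold (default 0.65).
#' @param node_score `"max_index"` or `"mean_index"`.
#' @return an igraph graph with vertex attributes `value`, `node_score`
#'   and edge attributes `s`, `index` (capped), plus graph attribute
#'   `s_threshold`.
#' @export
build_graph <- function(pairs, records, s_threshold = 0.65,
                        node_score = c("max_index", "mean_index")) {
  node_score <- match.arg(node_score)
  if (inherits(records, "energy_table"))
    records <- data.frame(ligand_id = records$id,
                          value = records$binding_affinity,
                          stringsAsFactors = FALSE)
  ids <- as.character(records$ligand_id)
  ed <- pairs[pairs$s >= s_threshold, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    d = if (nrow(ed)) data.frame(from = ed$id_a, to = ed$id_b, s = ed$s,
                                 index = ed$capped_index)
        else data.frame(from = character(0), to = character(0),
                        s = numeric(0), index = numeric(0)),
    directed = FALSE,
    vertices = data.frame(name = ids, value = records$value))
  score <- vapply(ids, function(id) {
    inc <- ed$capped_index[ed$id_a == id | ed$id_b == id]
    if (!length(inc)) 0
    else if (node_score == "max_index") max(inc) else mean(inc)
  }, numeric(1))
  igraph::V(g)$node_score <- unname(score[match(igraph::V(g)$name, ids)])
  g <- igraph::set_graph_attr(g, "s_threshold", s_threshold)
  g
}

#' Export a similarity graph as GraphML plus node/edge CSVs
#' @param g graph from [build_graph()].
#' @param prefix output path prefix; writes `<prefix>.graphml`,
#'   `<prefix>_nodes.csv`, `<prefix>_edges.csv`.
#' @return invisibly, the three paths.
#' @export
write_graph_files <- function(g, prefix) {
  p1 <- paste0(prefix, ".graphml")
  igraph::write_graph(g, p1, format = "graphml")
  nodes <- data.frame(id = igraph::V(g)$name,
                      value = igraph::V(g)$value,
                      node_score = igraph::V(g)$node_score)
  p2 <- paste0(prefix, "_nodes.csv")
  utils::write.csv(nodes, p2, row.names = FALSE)
  el <- igraph::as_data_frame(g, what = "edges")
  p3 <- paste0(prefix, "_edges.csv")
  utils::write.csv(el, p3, row.names = FALSE)
  invisible(c(p1, p2, p3))
}

#' SBAI surface grid
#'
#' Evaluates the index `|d_BA| / (1 - s)` over a grid of similarity and
#' affinity-difference values, truncated at `cap` (the surface diverges as
#' `s -> 1`). Symmetric in the sign of `d_BA`.
#'
#' @param s_grid similarity values in `[0, 1)` (the open upper end: `s = 1`
#'   is an error).
#' @param dba_grid affinity-difference values (kcal/mol, may be signed).
#' @param cap truncation ceiling (default 2000).
#' @return `heatmap_matrix` with `dba_grid` rows and `s_grid` columns.
#' @export
sbai_surface <- function(s_grid = seq(0, 0.99, by = 0.01),
                         dba_grid = seq(-20, 20, by = 0.5), cap = 2000) {
  if (!length(s_grid) || !length(dba_grid))
    stop("grids must be nonempty", call. = FALSE)
  if (any(s_grid >= 1) || any(s_grid < 0))
    stop("s grid must lie in [0, 1): s = 1 diverges", call. = FALSE)
  m <- outer(abs(dba_grid), 1 - s_grid, "/")
  m <- pmin(m, cap)
  dimnames(m) <- list(fmt_full(dba_grid), fmt_full(s_grid))
  structure(m, class = c("heatmap_matrix", "matrix"),
            normalization = "none", color_scheme = "red_yellow_blue",
            cap = cap)
}

#' Read an activity/affinity value table from CSV
#'
#' Expected columns: `ligand_id`, `value`, optional `value_kind`.
#' @param path CSV path.
#' @return data.frame suitable for [pairwise_landscape()].
#' @export
read_activity_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("ligand_id", "value") %in% names(df)))
    stop("activity CSV needs columns ligand_id, value", call. = FALSE)
  df$value <- parse_num(df$value)
  if (any(is.na(df$value))) stop("non-numeric activity value",
                                 call. = FALSE)
  if (!"value_kind" %in% names(df)) df$value_kind <- "activity"
  df
}

#' @param pairs a `landscape_pairs` table.
#' @param path CSV path.
#' @rdname pairwise_landscape
#' @export
write_pairs_csv <- function(pairs, path) {
  out <- as.data.frame(pairs)
  out$index <- ifelse(is.infinite(out$index), "Inf", fmt_full(out$index))
  out$s <- fmt_full(out$s)
  out$d_val <- fmt_full(out$d_val)
  out$capped_index <- fmt_full(out$capped_index)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
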