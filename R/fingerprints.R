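#' Molecular fingerprints and similarity
#'
#' `circular_fingerprint()` computes a Morgan-style circular fingerprint:
#' every heavy atom's environment out to the requested bond radius is
#' encoded by iterated neighborhood hashing and folded into `n_bits` bits.
#' Identical structures give identical fingerprints; the hashing is fully
#' deterministic (no external library state).
#'
#' @param lig a [ligand] with a parseable structure (SMILES or retained SDF
#'   connectivity).
#' @param radius neighborhood radius in bonds (default 2).
#' @param n_bits folded length (default 2048).
#' @return object of class `lig_fp`: sorted integer `bits` in
#'   `[0, n_bits)`, per-bit `counts`, and metadata.
#' @examples
#' lig <- enumerate_designed_ligands()[["4567-tetraBr_ribose"]]
#' fp <- circular_fingerprint(lig)
#' length(fp$bits)
#' @export
circular_fingerprint <- function(lig, radius = 2, n_bits = 2048) {
  stopifnot(n_bits > 0, radius >= 0)
  g <- mol_graph_from_ligand(lig)
  heavy <- which(g$elements != "H")
  if (length(heavy) == 0L) stop("no heavy atoms in ligand", call. = FALSE)
  # initial invariants: element, degree, implicit+explicit H, aromatic flag,
  # ring membership
  inv <- vapply(seq_len(g$n), function(i) {
    deg <- if (is.null(g$adj[[i]])) 0L else
      sum(g$elements[g$adj[[i]][, 1]] != "H")
    hash_ints(c(ATOMIC_NUMBER[g$elements[i]] %||% 0,
                deg, g$implicit_h[i] + g$explicit_h[i],
                as.integer(g$aromatic[i]), as.integer(g$ring_member[i])))
  }, numeric(1))
  all_ids <- inv[heavy]
  cur <- inv
  if (radius > 0) {
    for (r in seq_len(radius)) {
      nxt <- cur
      for (i in heavy) {
        nb <- g$adj[[i]]
        if (!is.null(nb)) nb <- nb[g$elements[nb[, 1]] != "H", , drop = FALSE]
        if (is.null(nb) || nrow(nb) == 0L) {
          nxt[i] <- hash_ints(c(r, cur[i]))
          next
        }
        pairs <- cbind(nb[, 2], cur[nb[, 1]])
        ord <- order(pairs[, 1], pairs[, 2])
        nxt[i] <- hash_ints(c(r, cur[i], as.numeric(t(pairs[ord, , drop = FALSE]))))
      }
      cur <- nxt
      all_ids <- c(all_ids, cur[heavy])
    }
  }
  bits <- all_ids %% n_bits
  tab <- table(bits)
  new_lig_fp(sort(unique(as.integer(names(tab)))),
             counts = setNames(as.integer(tab), names(tab)),
             n_bits = n_bits, type = "circular")
}

#' Construct a fingerprint from raw bit indices
#'
#' @param bits integer bit indices in `[0, n_bits)`.
#' @param counts optional named count vector (names are bit indices).
#' @param n_bits folded length (> 0).
#' @param type descriptor family label.
#' @return a `lig_fp` object.
#' @export
new_lig_fp <- function(bits, counts = NULL, n_bits, type = "circular") {
  bits <- as.integer(bits)
  if (length(bits) && (min(bits) < 0 || max(bits) >= n_bits))
    stop("fingerprint bit index out of range", call. = FALSE)
  structure(list(bits = sort(unique(bits)), counts = counts,
                 n_bits = as.integer(n_bits), type = type),
            class = "lig_fp")
}

#' @export
print.lig_fp <- function(x, ...) {
  cat("<fingerprint>", x$type, "-", length(x$bits), "of", x$n_bits,
      "bits set\n")
  invisible(x)
}

PHARMACOPHORE_TYPES <- c("donor", "acceptor", "aromatic", "hydrophobic",
                         "halogen")

#' Pharmacophore feature-pair descriptor
#'
#' Encodes pairs of pharmacophore features (hydrogen-bond donor, acceptor,
#' aromatic-ring centroid, hydrophobic carbon, halogen) together with their
#' binned separation. With a 3D conformer the separation is the Euclidean
#' distance; without one a 2D fallback uses topological bond counts scaled
#' by a typical bond length of 1.5 Angstrom. Bins are 2 Angstrom wide from
#' 0 to 12 (pairs beyond 12 are dropped). Feature typing is mutually
#' exclusive for N/O: with at least one attached hydrogen an atom is a
#' donor, otherwise an acceptor.
#'
#' @param lig a [ligand]; a conformer is used when present, else the
#'   structure must be parseable for the topological fallback.
#' @param bin_width,max_dist bin geometry in Angstrom.
#' @return a `lig_fp` with directly indexed bits
#'   (`type_pair * n_bins + bin`); an empty descriptor (with a warning)
#'   when fewer than two features are found.
#' @export
feature_pair_descriptor <- function(lig, bin_width = 2, max_dist = 12) {
  n_bins <- ceiling(max_dist / bin_width)
  feats <- pharmacophore_features(lig)
  n_pair_types <- length(PHARMACOPHORE_TYPES) * (length(PHARMACOPHORE_TYPES) + 1) / 2
  n_bits <- n_pair_types * n_bins
  if (nrow(feats$table) < 2L) {
    warning("fewer than two pharmacophore features detected; ",
            "empty descriptor", call. = FALSE)
    return(new_lig_fp(integer(0), counts = NULL, n_bits = n_bits,
                      type = "feature_pair"))
  }
  ft <- feats$table
  bits <- integer(0)
  for (i in seq_len(nrow(ft) - 1L)) {
    for (j in seq((i + 1L), nrow(ft))) {
      d <- feats$dist[i, j]
      if (!is.finite(d) || d >= max_dist) next
      bin <- floor(d / bin_width)
      t1 <- match(ft$type[i], PHARMACOPHORE_TYPES)
      t2 <- match(ft$type[j], PHARMACOPHORE_TYPES)
      lo <- min(t1, t2); hi <- max(t1, t2)
      # unordered pair (lo, hi) -> dense index
      pair_idx <- (lo - 1L) * length(PHARMACOPHORE_TYPES) -
        (lo - 1L) * lo / 2 + (hi - lo)
      bits <- c(bits, pair_idx * n_bins + bin)
    }
  }
  tab <- table(bits)
  new_lig_fp(as.integer(names(tab)),
             counts = setNames(as.integer(tab), names(tab)),
             n_bits = n_bits, type = "feature_pair")
}

# locate typed features and a matching inter-feature distance matrix
pharmacophore_features <- function(lig) {
  has_conf <- !is.null(lig$conformer)
  g <- tryCatch(mol_graph_from_ligand(lig), error = function(e) NULL)
  if (is.null(g) && !has_conf)
    stop("ligand ", lig$id, " has neither structure nor conformer",
         call. = FALSE)
  if (!is.null(g)) {
    feats <- type_features_graph(g)
    if (has_conf && nrow(lig$conformer) == g$n) {
      pos <- as.matrix(lig$conformer[, c("x", "y", "z")])
    } else if (!is.null(g$coords)) {
      pos <- g$coords
    } else pos <- NULL
    if (!is.null(pos)) {
      centers <- t(vapply(feats$atoms, function(idx)
        colMeans(pos[idx, , drop = FALSE]), numeric(3)))
      dm <- as.matrix(stats::dist(centers))
    } else {
      td <- topo_dist(g)
      rep_atom <- vapply(feats$atoms, `[`, numeric(1), 1)
      dm <- td[rep_atom, rep_atom, drop = FALSE] * 1.5
    }
    return(list(table = feats$table, dist = dm))
  }
  # conformer-only path: type from elements and explicit-H geometry
  conf <- lig$conformer
  pos <- as.matrix(conf[, c("x", "y", "z")])
  el <- conf$element
  dmat <- as.matrix(stats::dist(pos))
  types <- character(0); atoms <- list(); k <- 0
  for (i in seq_along(el)) {
    if (el[i] %in% c("F", "Cl", "Br", "I")) t <- "halogen"
    else if (el[i] %in% c("N", "O")) {
      has_h <- any(el == "H" & dmat[i, ] < 1.25 & dmat[i, ] > 0)
      t <- if (has_h) "donor" else "acceptor"
    } else if (el[i] == "C") {
      polar <- any(el %in% c("N", "O", "S") & dmat[i, ] < 1.8 & dmat[i, ] > 0)
      if (polar) next
      t <- "hydrophobic"
    } else next
    k <- k + 1; types[k] <- t; atoms[[k]] <- i
  }
  tb <- data.frame(type = types, stringsAsFactors = FALSE)
  centers <- pos[unlist(atoms), , drop = FALSE]
  list(table = tb, dist = as.matrix(stats::dist(centers)))
}

type_features_graph <- function(g) {
  types <- character(0); atoms <- list(); k <- 0
  add <- function(t, idx) {
    k <<- k + 1; types[k] <<- t; atoms[[k]] <<- idx
  }
  # aromatic ring centroids as single features
  rr <- which_aromatic_rings(g)
  for (ring in rr) add("aromatic", ring)
  for (i in seq_len(g$n)) {
    el <- g$elements[i]
    if (el %in% c("F", "Cl", "Br", "I")) add("halogen", i)
    else if (el %in% c("N", "O")) {
      n_h <- g$implicit_h[i] + g$explicit_h[i]
      add(if (n_h > 0) "donor" else "acceptor", i)
    } else if (el == "C" && !g$aromatic[i]) {
      nb <- g$adj[[i]]
      polar <- !is.null(nb) && any(g$elements[nb[, 1]] %in% c("N", "O", "S"))
      if (!polar) add("hydrophobic", i)
    }
  }
  list(table = data.frame(type = types, stringsAsFactors = FALSE),
       atoms = atoms)
}

which_aromatic_rings <- function(g) {
  rr <- tryCatch(ChemmineR::rings, error = function(e) NULL)
  out <- list()
  if (!any(g$aromatic)) return(out)
  # reuse the aromatic flags: group maximal connected aromatic components
  arom <- which(g$aromatic)
  seen <- rep(FALSE, g$n)
  for (s in arom) {
    if (seen[s]) next
    comp <- integer(0); queue <- s; seen[s] <- TRUE
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      comp <- c(comp, cur)
      nb <- g$adj[[cur]]
      if (is.null(nb)) next
      for (j in nb[, 1]) if (g$aromatic[j] && !seen[j]) {
        seen[j] <- TRUE; queue <- c(queue, j)
      }
    }
    out[[length(out) + 1L]] <- sort(comp)
  }
  out
}

#' Tanimoto similarity between two fingerprints
#'
#' `|A intersect B| / |A union B|` over the set bits. Two empty
#' fingerprints compare as identical (similarity 1) with a warning.
#'
#' @param a,b `lig_fp` objects with equal `n_bits`.
#' @return similarity in `[0, 1]`.
#' @examples
#' f1 <- new_lig_fp(c(1, 2, 3), n_bits = 16)
#' f2 <- new_lig_fp(c(2, 3, 4), n_bits = 16)
#' tanimoto(f1, f2)  # 0.5
#' @export
tanimoto <- function(a, b) {
  stopifnot(inherits(a, "lig_fp"), inherits(b, "lig_fp"))
  if (a$n_bits != b$n_bits)
    stop("fingerprints have different n_bits (", a$n_bits, " vs ",
         b$n_bits, ")", call. = FALSE)
  if (length(a$bits) == 0L && length(b$bits) == 0L) {
    warning("both fingerprints empty; similarity defined as 1",
            call. = FALSE)
    return(1)
  }
  inter <- length(intersect(a$bits, b$bits))
  uni <- length(union(a$bits, b$bits))
  inter / uni
}

#' Pairwise similarity matrix over a ligand library
#'
#' @param ligands list of [ligand] objects (>= 2, unique ids).
#' @param measure `"circular"` (Morgan-style fingerprint + Tanimoto),
#'   `"feature_pair"` (pharmacophore pair descriptor + Tanimoto), or
#'   `"external"` (pass a precomputed matrix via `external`, e.g. from an
#'   external descriptor tool).
#' @param external square numeric matrix with ligand ids as dimnames
#'   (required for `measure = "external"`).
#' @param ... passed to the fingerprint function.
#' @return symmetric `similarity_matrix` with unit diagonal, entries in
#'   `[0, 1]`, and a `measure` attribute.
#' @export
similarity_matrix <- function(ligands,
                              measure = c("circular", "feature_pair",
                                          "external"),
                              external = NULL, ...) {
  measure <- match.arg(measure)
  if (measure == "external") {
    if (is.null(external)) stop("external matrix required", call. = FALSE)
    return(as_similarity_matrix(external, measure = "external"))
  }
  if (length(ligands) < 2L) stop("need >= 2 ligands", call. = FALSE)
  ids <- unname(vapply(ligands, `[[`, character(1), "id"))
  if (anyDuplicated(ids))
    stop("duplicate ligand ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  fps <- lapply(ligands, function(l) {
    if (measure == "circular") circular_fingerprint(l, ...)
    else feature_pair_descriptor(l, ...)
  })
  n <- length(ids)
  m <- diag(1, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      s <- tanimoto(fps[[i]], fps[[j]])
      m[i, j] <- s
      m[j, i] <- s
    }
  }
  dimnames(m) <- list(ids, ids)
  as_similarity_matrix(m, measure = measure)
}

as_similarity_matrix <- function(m, measure = "external") {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("similarity matrix must be square",
                               call. = FALSE)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("similarity matrix needs ligand ids as dimnames", call. = FALSE)
  if (!identical(rownames(m), colnames(m)))
    stop("row and column ids differ", call. = FALSE)
  if (any(!is.finite(m)) || any(m < -1e-9) || any(m > 1 + 1e-9))
    stop("similarity entries must lie in [0, 1]", call. = FALSE)
  if (max(abs(m - t(m))) > 1e-9)
    stop("similarity matrix must be symmetric", call. = FALSE)
  if (max(abs(diag(m) - 1)) > 1e-9)
    stop("similarity matrix must have unit diagonal", call. = FALSE)
  m[m < 0] <- 0
  m[m > 1] <- 1
  structure(m, class = c("similarity_matrix", "matrix"), measure = measure)
}

#' Read / write a similarity matrix as CSV (ids as header row and column)
#' @param path CSV path.
#' @param measure measure label attached on read.
#' @rdname similarity_io
#' @export
read_similarity_csv <- function(path, measure = "external") {
  df <- utils::read.csv(path, check.names = FALSE, row.names = 1)
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  as_similarity_matrix(m, measure = measure)
}

#' @param sim a `similarity_matrix`.
#' @rdname similarity_io
#' @export
write_similarity_csv <- function(sim, path) {
  df <- as.data.frame(apply(unclass(sim), 2, fmt_full))
  rownames(df) <- rownames(sim)
  utils::write.csv(df, path, quote = FALSE, row.names = TRUE)
  invisible(path)
}
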