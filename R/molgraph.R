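# internal molecular-graph machinery used by the fingerprint code

STANDARD_VALENCE <- c(H = 1, C = 4, N = 3, O = 2, S = 2, P = 3,
                      F = 1, Cl = 1, Br = 1, I = 1, B = 3)

# build a light graph representation from a ChemmineR SDF object:
# elements, adjacency (with bond orders), aromatic flags, implicit H
# counts, and coordinates (NULL when the record is 2D-only)
mol_graph <- function(sdf) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  n <- nrow(ab)
  elements <- gsub("_.*$", "", rownames(ab))
  if (length(bb) && !is.null(dim(bb)) && nrow(bb) > 0 && ncol(bb) >= 3) {
    bonds <- data.frame(a = as.integer(bb[, 1]), b = as.integer(bb[, 2]),
                        order = as.integer(bb[, 3]))
  } else {
    bonds <- data.frame(a = integer(0), b = integer(0),
                        order = integer(0))
  }
  # aromatic perception via ring detection
  aromatic <- rep(FALSE, n)
  ring_member <- rep(FALSE, n)
  rr <- tryCatch(ChemmineR::rings(sdf, type = "all", arom = TRUE),
                 error = function(e) NULL)
  if (!is.null(rr) && length(rr$RINGS)) {
    for (k in seq_along(rr$RINGS)) {
      idx <- as.integer(gsub("^.*_", "", rr$RINGS[[k]]))
      ring_member[idx] <- TRUE
      if (isTRUE(rr$AROMATIC[[k]])) aromatic[idx] <- TRUE
    }
  }
  adj <- vector("list", n)
  for (i in seq_len(nrow(bonds))) {
    adj[[bonds$a[i]]] <- rbind(adj[[bonds$a[i]]],
                               c(bonds$b[i], bonds$order[i]))
    adj[[bonds$b[i]]] <- rbind(adj[[bonds$b[i]]],
                               c(bonds$a[i], bonds$order[i]))
  }
  # implicit hydrogens from standard valence minus explicit bond order sum
  # (aromatic SDF bonds arrive Kekulized, so orders sum correctly)
  expl <- vapply(seq_len(n), function(i) {
    if (is.null(adj[[i]])) 0 else sum(adj[[i]][, 2])
  }, numeric(1))
  n_h_expl <- vapply(seq_len(n), function(i) {
    if (is.null(adj[[i]])) 0L
    else sum(elements[adj[[i]][, 1]] == "H")
  }, integer(1))
  val <- STANDARD_VALENCE[elements]
  val[is.na(val)] <- 0
  implicit_h <- pmax(0, round(val - expl))
  coords <- NULL
  if (ncol(ab) >= 3 && any(abs(ab[, 3]) > 1e-8))
    coords <- cbind(x = ab[, 1], y = ab[, 2], z = ab[, 3])
  list(n = n, elements = elements, bonds = bonds, adj = adj,
       aromatic = aromatic, ring_member = ring_member,
       implicit_h = implicit_h, explicit_h = n_h_expl, coords = coords)
}

mol_graph_from_ligand <- function(lig) {
  if (!is.null(lig$sdf)) return(mol_graph(lig$sdf))
  if (is.null(lig$structure) || !nzchar(lig$structure))
    stop("ligand ", lig$id, " has no parseable structure", call. = FALSE)
  sdf <- tryCatch(smiles_to_sdf(lig$structure),
                  error = function(e)
                    stop("unparseable structure for ligand ", lig$id, ": ",
                         conditionMessage(e), call. = FALSE))
  mol_graph(sdf[[1]])
}

ATOMIC_NUMBER <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, P = 15,
                   S = 16, Cl = 17, Br = 35, I = 53)

# deterministic polynomial hash of an integer vector; exact in doubles
# (all intermediates stay below 2^53), result in [0, 2^31 - 1)
hash_ints <- function(v) {
  p <- 2147483647
  h <- 17
  for (x in v) h <- (h * 31 + (x %% p)) %% p
  h
}

# all-pairs topological (bond-count) distances by BFS; Inf when disconnected
topo_dist <- function(g) {
  n <- g$n
  d <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d[s, s] <- 0
    queue <- s
    while (length(queue)) {
      cur <- queue[1]
      queue <- queue[-1]
      nb <- g$adj[[cur]]
      if (is.null(nb)) next
      for (j in nb[, 1]) {
        if (is.infinite(d[s, j])) {
          d[s, j] <- d[s, cur] + 1
          queue <- c(queue, j)
        }
      }
    }
  }
  d
}
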