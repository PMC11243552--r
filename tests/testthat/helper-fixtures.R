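# shared fixture builders for the test suite

# a random sparse binding fingerprint over a fixed residue vocabulary
random_fp <- function(n_keys = 6, vocab = paste0("Res", 1:12),
                      id = "lig") {
  keys <- sample(vocab, n_keys)
  binding_fingerprint(setNames(round(runif(n_keys, -10, 2), 3), keys),
                      ligand_id = id)
}

# random bit-set fingerprint
random_bits_fp <- function(n_bits = 64, p = 0.2) {
  bits <- which(runif(n_bits) < p) - 1L
  new_lig_fp(bits, n_bits = n_bits)
}

# a synthetic complex holding one plant of each interaction kind at the
# geometries narrated for the CK2alpha co-crystal
narrated_plants <- function() {
  data.frame(kind = c("hbond", "hbond", "halogen_bond"),
             distance = c(3.14, 3.81, 3.0),
             angle = c(165, 102.05, 172.68),
             residue_name = c("ASN", "ASN", "VAL"),
             element = c("N", "O", "Br"),
             stringsAsFactors = FALSE)
}

# brute-force all-pairs neighbour search (oracle for grid_pairs)
brute_pairs <- function(a, b, cutoff) {
  out <- data.frame(i = integer(0), j = integer(0), d = numeric(0))
  for (i in seq_len(nrow(a))) {
    dd <- sqrt(colSums((t(b) - a[i, ])^2))
    keep <- which(dd <= cutoff)
    if (length(keep))
      out <- rbind(out, data.frame(i = i, j = keep, d = dd[keep]))
  }
  out
}

# rigid rotation matrix from three angles (radians)
rotation_matrix <- function(ax, ay, az) {
  rx <- matrix(c(1, 0, 0, 0, cos(ax), -sin(ax), 0, sin(ax), cos(ax)),
               3, byrow = TRUE)
  ry <- matrix(c(cos(ay), 0, sin(ay), 0, 1, 0, -sin(ay), 0, cos(ay)),
               3, byrow = TRUE)
  rz <- matrix(c(cos(az), -sin(az), 0, sin(az), cos(az), 0, 0, 0, 1),
               3, byrow = TRUE)
  rz %*% ry %*% rx
}

# apply a rigid transform to every atom of a complex
transform_complex <- function(cx, rot, shift = c(0, 0, 0)) {
  tf <- function(df) {
    xyz <- as.matrix(df[, c("x", "y", "z")]) %*% t(rot)
    df$x <- xyz[, 1] + shift[1]
    df$y <- xyz[, 2] + shift[2]
    df$z <- xyz[, 3] + shift[3]
    df
  }
  cx$protein <- tf(cx$protein)
  cx$ligand <- tf(cx$ligand)
  cx
}
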