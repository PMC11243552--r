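# shared internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# run code with a local RNG state seeded from `seed`; restores global state
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite number", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# "VAL" -> "Val"; leaves mixed-case input alone
title_case <- function(x) {
  paste0(toupper(substr(x, 1, 1)), tolower(substr(x, 2, nchar(x))))
}

# normalize Unicode minus signs (U+2212, U+2013) to ASCII hyphen-minus
ascii_minus <- function(x) {
  x <- gsub("−", "-", x)
  gsub("–", "-", x)
}

# numeric parse that accepts Unicode minus; returns NA for non-numeric
parse_num <- function(x) {
  suppressWarnings(as.numeric(ascii_minus(trimws(as.character(x)))))
}

vec_norm <- function(v) sqrt(sum(v^2))

unit <- function(v) {
  n <- vec_norm(v)
  if (n < 1e-12) stop("cannot normalize zero-length vector", call. = FALSE)
  v / n
}

# angle a-b-c in degrees (vertex at b)
angle_deg <- function(a, b, c) {
  u <- unit(a - b)
  v <- unit(c - b)
  acos(max(-1, min(1, sum(u * v)))) * 180 / pi
}

# full-precision numeric formatting for bit-exact CSV round trips
fmt_full <- function(x) {
  vapply(x, function(v) format(v, digits = 17, scientific = FALSE, trim = TRUE),
         character(1))
}
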