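# Independent oracles used across the suite. These deliberately take the
# dumb route (explicit loops, direct counting) so they share no code with
# the implementation they check.

# Gotoh affine-gap global alignment score: gap of length L costs
# open + L * extend, terminal gaps penalized (global alignment).
oracle_align_score <- function(a, b, submat, open = 10, extend = 1) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)  # ends in a match/mismatch
  X <- matrix(NEG, n + 1, m + 1)  # ends in a gap in b (a consumed)
  Y <- matrix(NEG, n + 1, m + 1)  # ends in a gap in a (b consumed)
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(open + i * extend)
  for (j in seq_len(m)) Y[1, j + 1] <- -(open + j * extend)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- submat[ca[i], cb[j]]
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1, j + 1] <- max(M[i, j + 1] - open - extend,
                             X[i, j + 1] - extend)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open - extend,
                             Y[i + 1, j] - extend)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Brute-force minimum distance between one point and a set of points.
oracle_min_distance <- function(p, pts) {
  best <- Inf
  for (k in seq_len(nrow(pts))) {
    d <- sqrt(sum((p - as.numeric(pts[k, ]))^2))
    if (d < best) best <- d
  }
  best
}

# Scan-count oracle: alignment column of the pos-th non-gap reference char.
oracle_ref_column <- function(row, pos) {
  chars <- strsplit(row, "")[[1]]
  seen <- 0L
  for (k in seq_along(chars)) {
    if (chars[k] != "-") {
      seen <- seen + 1L
      if (seen == pos) return(k)
    }
  }
  NA_integer_
}

random_protein <- function(len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len,
               replace = TRUE), collapse = "")
}

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
})
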