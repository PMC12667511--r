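# Independent pure-R Jaro / Jaro-Winkler oracle, written directly from the
# metric's definition over explicit character vectors. Used to cross-check
# the package's C++ kernel.

oracle_jaro <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  la <- length(ca); lb <- length(cb)
  if (la == 0 && lb == 0) return(1)
  if (la == 0 || lb == 0) return(0)
  win <- max(floor(max(la, lb) / 2) - 1, 0)
  used_b <- rep(FALSE, lb)
  match_a <- integer(0); match_b <- integer(0)
  for (i in seq_len(la)) {
    lo <- max(1, i - win); hi <- min(lb, i + win)
    if (lo > hi) next
    for (j in seq(lo, hi)) {
      if (!used_b[j] && ca[i] == cb[j]) {
        used_b[j] <- TRUE
        match_a <- c(match_a, i)
        match_b <- c(match_b, j)
        break
      }
    }
  }
  m <- length(match_a)
  if (m == 0) return(0)
  transposed <- sum(ca[match_a] != cb[sort(match_b)]) / 2
  (m / la + m / lb + (m - transposed) / m) / 3
}

oracle_jaro_winkler <- function(a, b, p = 0.1, lmax = 4, boost = 0.7) {
  j <- oracle_jaro(a, b)
  if (j <= boost) return(j)
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  lim <- min(length(ca), length(cb), lmax)
  l <- 0
  while (l < lim && ca[l + 1] == cb[l + 1]) l <- l + 1
  j + l * p * (1 - j)
}

random_strings <- function(n, max_len = 12, alphabet = LETTERS[1:8]) {
  vapply(seq_len(n), function(i) {
    len <- sample(0:max_len, 1)
    paste(sample(alphabet, len, replace = TRUE), collapse = "")
  }, "")
}
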