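# Independent brute-force oracle: same MID criterion, recomputing every
# mutual information from scratch with table()-based entropies.
oracle_mrmr <- function(x, y, k, bins = 3) {
  disc <- function(v) {
    br <- unique(quantile(v, seq_len(bins - 1) / bins, type = 7, names = FALSE))
    findInterval(v, br, left.open = TRUE)
  }
  mi <- function(a, b) {
    tab <- table(a, b) / length(a)
    pa <- rowSums(tab)
    pb <- colSums(tab)
    s <- 0
    for (i in seq_along(pa)) {
      for (j in seq_along(pb)) {
        if (tab[i, j] > 0) s <- s + tab[i, j] * log(tab[i, j] / (pa[i] * pb[j]))
      }
    }
    s
  }
  d <- apply(x, 2, disc)
  chosen <- integer(0)
  for (step in seq_len(k)) {
    best <- -Inf
    best_j <- NA
    for (j in setdiff(seq_len(ncol(x)), chosen)) {
      rel <- mi(d[, j], y)
      red <- if (length(chosen)) {
        mean(vapply(chosen, function(s) mi(d[, j], d[, s]), numeric(1)))
      } else {
        0
      }
      score <- rel - red
      if (score > best + 1e-12) {
        best <- score
        best_j <- j
      }
    }
    chosen <- c(chosen, best_j)
  }
  colnames(x)[chosen]
}
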