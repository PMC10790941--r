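# Greedy minimum-redundancy maximum-relevance feature selection (MID
# criterion): the first feature maximizes I(f; class); each subsequent
# feature maximizes I(f; class) - mean over selected s of I(f; s). Mutual
# information is estimated on discretized features (equal-frequency bins).

# equal-frequency discretization into `bins` levels, 0-based integer codes
discretize_ef <- function(x, bins = 3) {
  br <- unique(quantile(x, probs = seq_len(bins - 1) / bins, type = 7, names = FALSE))
  findInterval(x, br, left.open = TRUE)
}

# MI (nats) of every column of code matrix `d` (values 0..(dl-1)) with a
# code vector `y` (values 0..(yl-1)), fully vectorized via one tabulate.
mi_columns <- function(d, dl, y, yl) {
  n <- nrow(d)
  p <- ncol(d)
  cell <- dl * yl
  codes <- as.vector(d) + dl * rep(y, p) + cell * rep(seq_len(p) - 1L, each = n)
  counts <- matrix(tabulate(codes + 1L, nbins = cell * p), cell, p)
  pj <- counts / n
  # marginals per column
  px <- rowsum(pj, rep(seq_len(dl), yl)) # dl x p, sums over y
  py <- rowsum(pj, rep(seq_len(yl), each = dl)) # yl x p
  ex <- pj * log(pj / (px[rep(seq_len(dl), yl), , drop = FALSE] *
    py[rep(seq_len(yl), each = dl), , drop = FALSE]))
  ex[!is.finite(ex)] <- 0
  colSums(ex)
}

#' mRMR feature selection
#'
#' Greedy mutual-information feature selection with the MID (difference)
#' criterion. Features are discretized into equal-frequency bins before MI
#' estimation; ties break toward the lowest feature index, making the
#' selection deterministic and invariant to row order.
#'
#' @param x Numeric matrix or data frame of features (rows = samples).
#' @param y Class vector (two or more levels).
#' @param k Number of features to select (default 10).
#' @param bins Discretization bins (default 3).
#' @return Character vector of `k` selected feature names, in selection
#'   order (falls back to column indices when `x` has no names).
#' @export
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(600), 200, 3,
#'   dimnames = list(NULL, c("signal", "copy", "noise"))
#' )
#' y <- as.integer(x[, 1] > 0)
#' x[, 2] <- x[, 1]
#' mrmr_select(x, y, k = 2) # "signal" then "noise": the copy is redundant
mrmr_select <- function(x, y, k = 10, bins = 3) {
  x <- as.matrix(x)
  if (k > ncol(x)) {
    abort(sprintf("cannot select k = %d features out of %d", k, ncol(x)))
  }
  if (is.null(colnames(x))) colnames(x) <- as.character(seq_len(ncol(x)))
  yf <- as.integer(factor(y)) - 1L
  yl <- max(yf) + 1L
  if (yl < 2) abort("`y` must have at least two classes")

  d <- apply(x, 2, discretize_ef, bins = bins)
  dl <- bins

  relevance <- mi_columns(d, dl, yf, yl)
  selected <- integer(k)
  selected[1] <- which.max(relevance)
  redundancy_sum <- numeric(ncol(x))
  remaining <- setdiff(seq_len(ncol(x)), selected[1])

  for (m in seq_len(k - 1)) {
    last <- selected[m]
    redundancy_sum <- redundancy_sum + mi_columns(d, dl, d[, last], dl)
    score <- relevance - redundancy_sum / m
    score[selected[seq_len(m)]] <- -Inf
    selected[m + 1] <- which.max(score)
  }
  colnames(x)[selected]
}
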