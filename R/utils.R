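## Internal helpers: classed conditions and small utilities.

stop_format     <- function(msg, ...) rlang::abort(msg, class = "pcpg_format_error", ...)
stop_validation <- function(msg, ...) rlang::abort(msg, class = "pcpg_validation_error", ...)
stop_metadata   <- function(msg, ...) rlang::abort(msg, class = "pcpg_metadata_error", ...)
stop_config     <- function(msg, ...) rlang::abort(msg, class = "pcpg_config_error", ...)
stop_parameter  <- function(msg, ...) rlang::abort(msg, class = "pcpg_parameter_error", ...)
stop_coordinate <- function(msg, ...) rlang::abort(msg, class = "pcpg_coordinate_error", ...)
stop_io         <- function(msg, ...) rlang::abort(msg, class = "pcpg_io_error", ...)

## seed derivation: stable small-integer sub-seeds below 2^31
derive_seed <- function(seed, offset = 0L) {
  (as.integer(seed) + 1103L * as.integer(offset)) %% .Machine$integer.max
}

## cosine distance between rows of x and rows of y (dense matrices)
cosine_distance <- function(x, y = x) {
  xn <- x / pmax(sqrt(rowSums(x^2)), .Machine$double.eps)
  yn <- y / pmax(sqrt(rowSums(y^2)), .Machine$double.eps)
  d <- 1 - tcrossprod(xn, yn)
  d[d < 0] <- 0
  d
}

## row-wise k nearest neighbours of query among reference rows (exact)
knn_index <- function(query, reference, k, metric = c("cosine", "euclidean"),
                      self = FALSE) {
  metric <- match.arg(metric)
  d <- if (metric == "cosine") {
    cosine_distance(query, reference)
  } else {
    qq <- rowSums(query^2)
    rr <- rowSums(reference^2)
    d2 <- outer(qq, rr, "+") - 2 * tcrossprod(query, reference)
    sqrt(pmax(d2, 0))
  }
  k <- min(k, ncol(d) - if (self) 0L else 1L)
  idx <- t(apply(d, 1L, function(row) order(row)[seq_len(k + !self)]))
  if (!self) idx <- t(vapply(seq_len(nrow(idx)), function(i) {
    r <- idx[i, ]
    r <- r[r != i]
    r[seq_len(k)]
  }, integer(k)))
  if (k == 1L) idx <- matrix(idx, ncol = 1L)
  idx
}

## centred moving average with symmetric edge shrinking, columns = positions.
## M is units x positions; window odd.
running_mean_cols <- function(M, window) {
  n <- ncol(M)
  if (window <= 1L || n == 1L) return(M)
  half <- (window - 1L) %/% 2L
  ## cumulative sums along positions, padded with a zero column
  cs <- cbind(0, t(apply(M, 1L, cumsum)))
  out <- M
  for (j in seq_len(n)) {
    h <- min(half, j - 1L, n - j)
    out[, j] <- (cs[, j + h + 1L] - cs[, j - h]) / (2L * h + 1L)
  }
  out
}

#' Adjusted Rand index between two partitions
#'
#' Hubert-Arabie adjusted Rand index; 1 = identical partitions, ~0 =
#' independent. Used throughout the tests to compare recovered clusterings
#' with simulation truth.
#' @param a,b Two label vectors of equal length.
#' @return Numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  exp_idx <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == exp_idx) return(1)
  (sum_ij - exp_idx) / (max_idx - exp_idx)
}
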