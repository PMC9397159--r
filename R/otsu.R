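#' Multi-level Otsu thresholds
#'
#' Partitions a sample of intensities into `k` classes by maximizing the
#' between-class variance, the multi-class generalization of Otsu's method,
#' solved exactly by dynamic programming over a value histogram.
#'
#' @param x numeric vector of intensities.
#' @param k number of classes (`>= 1`).
#' @param n_bins histogram resolution used when `x` has more distinct values
#'   than `n_bins`.
#' @return Numeric vector of `k - 1` increasing thresholds; class of a value
#'   `v` is `findInterval(v, thresholds)` (0-based). A class contains the
#'   values `>=` its lower threshold.
#' @export
multi_otsu <- function(x, k, n_bins = 256L) {
  stopifnot(length(x) > 0, k >= 1)
  vals <- sort(unique(x))
  if (k == 1L) return(numeric(0))
  if (length(vals) <= n_bins) {
    centers <- vals
    lowers <- vals
    counts <- tabulate(match(x, vals), nbins = length(vals))
  } else {
    br <- seq(min(x), max(x), length.out = n_bins + 1L)
    ix <- pmin(pmax(findInterval(x, br, rightmost.closed = TRUE), 1L), n_bins)
    counts <- tabulate(ix, nbins = n_bins)
    centers <- (br[-1] + br[-length(br)]) / 2
    lowers <- br[-length(br)]   # class cut at the bin's lower edge
    keep <- counts > 0
    centers <- centers[keep]
    lowers <- lowers[keep]
    counts <- counts[keep]
  }
  L <- length(centers)
  if (k > L) stop("more classes than distinct values")

  P <- c(0, cumsum(counts))
  S <- c(0, cumsum(counts * centers))
  # cost(i, j): contribution S^2/W of one class spanning bins i..j
  cost <- function(i, j) {
    w <- P[j + 1L] - P[i]
    s <- S[j + 1L] - S[i]
    ifelse(w > 0, s * s / w, 0)
  }

  # D[k, j]: best value for first j bins split into k classes
  D <- matrix(-Inf, k, L)
  A <- matrix(0L, k, L)        # argmax start bin of the last class
  D[1, ] <- cost(1L, seq_len(L))
  A[1, ] <- 1L
  for (kk in 2:k) {
    for (j in kk:L) {
      i <- kk:j
      v <- D[kk - 1L, i - 1L] + cost(i, j)
      best <- which.max(v)
      D[kk, j] <- v[best]
      A[kk, j] <- i[best]
    }
  }
  starts <- integer(k)
  j <- L
  for (kk in k:1) {
    starts[kk] <- A[kk, j]
    j <- starts[kk] - 1L
  }
  lowers[starts[-1]]
}
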