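#' Draw symbiont fitness effects from a truncated normal distribution
#'
#' Samples independent relative-fitness effects \eqn{w_i} from a normal
#' distribution conditioned on an interval, by rejection. The defaults
#' (mean 1, sd 0.3, truncated at 0 and 2.5) describe a pool of candidate
#' symbionts centred on neutrality with both deleterious (`w < 1`) and
#' beneficial (`w > 1`) members; the truncation bounds sit 3.3 and 5
#' standard deviations from the mean, so they shift the mean by well under
#' 1e-3.
#'
#' @param n Number of draws.
#' @param mean,sd Mean and standard deviation of the parent normal.
#' @param lo,hi Truncation bounds, `lo < hi`.
#' @param seed Optional integer seed; when supplied the R RNG is seeded
#'   before drawing, making the sequence reproducible.
#' @return Numeric vector of `n` draws, all inside `[lo, hi]`.
#' @examples
#' sample_w(5, seed = 1)
#' @export
sample_w <- function(n, mean = 1, sd = 0.3, lo = 0, hi = 2.5, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 0 || n != round(n))
    stop("`n` must be a non-negative integer")
  if (lo >= hi) stop("degenerate interval: `lo` must be strictly below `hi`")
  if (!is.null(seed)) set.seed(seed)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(16L, 2L * (n - length(out)))
    x <- rnorm(m, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}
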