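#' One-sided Wilcoxon signed-rank p-value
#'
#' Upper-tail p-value for the alternative "median difference > 0".
#' Zero differences are dropped (standard Wilcoxon convention) and
#' absolute values are midranked. For up to `exact_max` nonzero
#' differences the null distribution of the positive-rank sum is
#' enumerated exactly over all sign assignments by dynamic programming
#' (doubled midranks are integers, so the convolution is exact even
#' under ties); above that a tie-corrected normal approximation with
#' continuity correction is used.
#'
#' @param d numeric vector of differences.
#' @param exact_max largest number of nonzero differences handled
#'   exactly.
#' @return p-value in (0, 1\]; 1 if every difference is zero.
#' @examples
#' signed_rank_upper_p(c(4, 4, 4, 4))  # all-positive ties: 1/16
#' @export
signed_rank_upper_p <- function(d, exact_max = 25L) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(1)
  r <- rank(abs(d))
  W2 <- sum(2 * r[d > 0])          # doubled positive-rank sum (integer)
  if (n <= exact_max) {
    w <- as.integer(round(2 * r))  # doubled midranks
    tot <- sum(w)
    f <- numeric(tot + 1L)
    f[1L] <- 1
    for (wi in w) {
      shifted <- c(numeric(wi), f[seq_len(tot + 1L - wi)])
      f <- f + shifted
    }
    p <- sum(f[(W2 + 1L):(tot + 1L)]) / 2^n
    return(min(1, p))
  }
  W <- W2 / 2
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- (W - mu - 0.5) / sqrt(sigma2)
  stats::pnorm(z, lower.tail = FALSE)
}
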