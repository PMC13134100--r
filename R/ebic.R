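#' Extended Bayesian Information Criterion for a Gaussian fit
#'
#' \code{EBIC = n log(RSS/n) + df log(n) + 2 gamma df log(p)}, where
#' \code{df} is the number of nonzero coefficients and \code{p} the number
#' of candidate predictors. Lower is better; \code{gamma = 0} reduces to
#' the ordinary Gaussian BIC.
#'
#' @param rss Residual sum of squares (> 0).
#' @param n Number of observations.
#' @param df Number of nonzero coefficients selected (0 <= df <= p).
#' @param p_candidates Number of candidate predictors.
#' @param gamma EBIC hyperparameter (>= 0).
#' @return The EBIC score (may be vectorized over \code{rss} and \code{df}).
#' @examples
#' ebic_score(rss = 100, n = 100, df = 0, p_candidates = 40, gamma = 0.25)
#' @export
ebic_score <- function(rss, n, df, p_candidates, gamma) {
  if (n <= 0) stop("n must be positive")
  if (any(df < 0) || any(df > p_candidates))
    stop("df must lie in [0, p_candidates]")
  if (any(rss <= 0)) stop("RSS must be positive (degenerate fit)")
  n * log(rss / n) + df * log(n) + 2 * gamma * df * log(p_candidates)
}
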