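#' Estimator settings for nodewise LASSO fits
#'
#' Bundles the tuning choices of the nodewise regularised estimator: the
#' EBIC hyperparameter, the penalty path, the rule used to combine the two
#' directed estimates of each edge, and whether predictors are standardized
#' inside the penalised fit.
#'
#' @param gamma EBIC hyperparameter (>= 0, unitless). \code{gamma = 0}
#'   recovers the ordinary BIC; larger values penalise model size more
#'   heavily as the candidate-predictor count grows. Default 0.25.
#' @param lambda_path Optional explicit penalty path, a strictly decreasing
#'   non-negative numeric vector (a trailing 0 requests the unpenalised
#'   least-squares fit at the end of the path). When \code{NULL} the path is
#'   derived from the data: \code{lambda_max} is the largest absolute
#'   standardized predictor-response inner product divided by n, followed by
#'   \code{lambda_path_length} log-spaced values down to
#'   \code{lambda_max * lambda_min_ratio}.
#' @param lambda_path_length Number of path points when the path is derived
#'   from the data (>= 2). Default 50.
#' @param lambda_min_ratio Ratio of the smallest to the largest derived
#'   penalty. Default 1e-3.
#' @param nodewise_rule How the two directed nodewise estimates of an edge
#'   are combined: \code{"AND"} (edge present only if both are nonzero;
#'   conservative, the default) or \code{"OR"} (present if either is).
#' @param standardize Logical; standardize design columns inside the
#'   penalised fit so the L1 penalty is scale-equitable. Coefficients are
#'   always reported on the design-column scale. Default \code{TRUE}.
#' @param penalize_covariates Logical; when \code{FALSE} the age and gender
#'   columns (and group dummies) are left unpenalised. Default \code{TRUE},
#'   i.e. every coefficient is subject to the L1 penalty.
#' @return An object of class \code{"mnm_settings"} (a list).
#' @examples
#' mnm_settings()
#' mnm_settings(gamma = 0.5, nodewise_rule = "OR")
#' @export
mnm_settings <- function(gamma = 0.25, lambda_path = NULL,
                         lambda_path_length = 50L, lambda_min_ratio = 1e-3,
                         nodewise_rule = c("AND", "OR"), standardize = TRUE,
                         penalize_covariates = TRUE) {
  nodewise_rule <- match.arg(nodewise_rule)
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma < 0)
    stop("gamma must be a single non-negative number")
  if (!is.null(lambda_path)) {
    lambda_path <- as.numeric(lambda_path)
    if (any(lambda_path < 0)) stop("lambda_path values must be non-negative")
    if (length(lambda_path) > 1L && any(diff(lambda_path) >= 0))
      stop("lambda_path must be strictly decreasing")
  }
  lambda_path_length <- as.integer(lambda_path_length)
  if (lambda_path_length < 2L) stop("lambda_path_length must be >= 2")
  if (lambda_min_ratio <= 0 || lambda_min_ratio >= 1)
    stop("lambda_min_ratio must be in (0, 1)")
  structure(list(gamma = gamma, lambda_path = lambda_path,
                 lambda_path_length = lambda_path_length,
                 lambda_min_ratio = lambda_min_ratio,
                 nodewise_rule = nodewise_rule, standardize = standardize,
                 penalize_covariates = penalize_covariates),
            class = "mnm_settings")
}

#' @export
print.mnm_settings <- function(x, ...) {
  cat("Nodewise estimator settings\n")
  cat("  EBIC gamma          :", x$gamma, "\n")
  if (is.null(x$lambda_path)) {
    cat("  penalty path        :", x$lambda_path_length,
        "log-spaced values, min ratio", x$lambda_min_ratio, "\n")
  } else {
    cat("  penalty path        : explicit,", length(x$lambda_path),
        "values in [", min(x$lambda_path), ",", max(x$lambda_path), "]\n")
  }
  cat("  nodewise rule       :", x$nodewise_rule, "\n")
  cat("  standardize penalty :", x$standardize, "\n")
  cat("  penalize covariates :", x$penalize_covariates, "\n")
  invisible(x)
}

#' Permutation-test settings
#'
#' @param B Number of label permutations (>= 1). Default 100, which gives a
#'   smallest attainable empirical p-value of 1/101.
#' @param seed Master seed for the permutation stream.
#' @param alpha Significance level for declaring an empirical p-value
#'   significant, in (0, 1). Default 0.05.
#' @return An object of class \code{"perm_settings"}.
#' @examples
#' perm_settings(B = 50, seed = 7)
#' @export
perm_settings <- function(B = 100L, seed = 1L, alpha = 0.05) {
  B <- as.integer(B)
  if (B < 1L) stop("B must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  structure(list(B = B, seed = as.integer(seed), alpha = alpha),
            class = "perm_settings")
}

#' @export
print.perm_settings <- function(x, ...) {
  cat("Permutation settings: B =", x$B, ", seed =", x$seed,
      ", alpha =", x$alpha, "\n")
  cat("  smallest attainable p:", format(1 / (x$B + 1), digits = 4), "\n")
  invisible(x)
}

# coefficients below this magnitude are treated as exact zeros after path
# selection (floating-point dust guard)
.zero_tol <- 1e-10
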