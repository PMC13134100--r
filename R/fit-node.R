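#' Fit one nodewise LASSO regression with EBIC path selection
#'
#' Fits the full LASSO path for one node's regression and selects the path
#' point minimising [ebic_score()], ties broken toward the larger penalty
#' (the sparser model).  The positive part of the path is fit by
#' \code{glmnet}; a path value of exactly 0 is solved as the unpenalised
#' least-squares problem, which is the LASSO solution at zero penalty.
#' Coefficients are reported on the design-column scale regardless of the
#' internal penalty standardization.
#'
#' @param design Either the list returned by [design_matrix()] or a
#'   predictor matrix (named columns).
#' @param response Response vector; taken from \code{design} when that is a
#'   [design_matrix()] list.
#' @param settings An [mnm_settings()] object.
#' @return An object of class \code{"nodewise_fit"}: a list with
#'   \code{node}, \code{lambda} (selected penalty), \code{lambda_path},
#'   \code{intercept}, \code{coefficients} (named vector on the
#'   design-column scale), \code{roles}, \code{df} (nonzero count),
#'   \code{ebic} (score at the selected penalty), \code{ebic_path},
#'   \code{rss}, \code{n} and \code{p_candidates}.
#' @examples
#' tr <- build_truth(G = 2, seed = 1)
#' co <- sample_cohort(tr, c(200, 200), seed = 1)
#' d <- design_matrix(co, node = 1, reference_group = "A")
#' f <- fit_node(d, settings = mnm_settings())
#' f$df
#' @export
fit_node <- function(design, response = NULL, settings = mnm_settings()) {
  if (is.list(design) && !is.null(design$x)) {
    x <- design$x
    y <- design$y
    roles <- design$roles
    node <- design$node
  } else {
    x <- as.matrix(design)
    y <- response
    roles <- rep("node", ncol(x))
    names(roles) <- colnames(x)
    node <- NA_character_
  }
  if (is.null(y)) stop("response required")
  n <- length(y)
  p <- ncol(x)
  if (n != nrow(x)) stop("response length must match design rows")

  path <- settings$lambda_path
  if (is.null(path)) {
    # lambda_max from the standardized inner products |<x_j, y>|/n
    sx <- apply(x, 2, stats::sd) * sqrt((n - 1) / n)
    sy <- stats::sd(y) * sqrt((n - 1) / n)
    xc <- sweep(x, 2, colMeans(x))
    ok <- sx > 0
    ip <- abs(crossprod(xc[, ok, drop = FALSE], y - mean(y))) / n
    if (settings$standardize) ip <- ip / sx[ok]
    lambda_max <- max(ip)
    if (lambda_max <= 0) lambda_max <- sy
    path <- exp(seq(log(lambda_max), log(lambda_max * settings$lambda_min_ratio),
                    length.out = settings$lambda_path_length))
  }

  pf <- rep(1, p)
  if (!settings$penalize_covariates) pf[roles == "covariate"] <- 0

  coefs <- matrix(0, p, length(path), dimnames = list(colnames(x), NULL))
  b0 <- numeric(length(path))
  pos <- path > 0
  if (any(pos)) {
    fit <- glmnet::glmnet(x, y, family = "gaussian", lambda = path[pos],
                          standardize = settings$standardize,
                          intercept = TRUE, penalty.factor = pf,
                          thresh = 1e-12, maxit = 1e6)
    cf <- as.matrix(stats::coef(fit, s = path[pos], exact = FALSE))
    if (anyNA(cf))
      stop("nodewise LASSO did not converge; path diagnostics: lambda in [",
           min(path[pos]), ", ", max(path[pos]), "], n = ", n, ", p = ", p)
    b0[pos] <- cf[1, ]
    coefs[, pos] <- cf[-1, , drop = FALSE]
  }
  if (any(!pos)) {
    # exact least-squares solution: the LASSO at zero penalty
    ls <- stats::lm.fit(cbind(`(Intercept)` = 1, x), y)
    beta <- ls$coefficients
    beta[is.na(beta)] <- 0
    for (j in which(!pos)) {
      b0[j] <- beta[1]
      coefs[, j] <- beta[-1]
    }
  }

  yhat <- matrix(b0, n, length(path), byrow = TRUE) + x %*% coefs
  rss <- colSums((y - yhat)^2)
  df <- colSums(abs(coefs) > .zero_tol)
  ebic <- ebic_score(rss = pmax(rss, 1e-300), n = n, df = df,
                     p_candidates = p, gamma = settings$gamma)
  sel <- which.min(ebic)  # first minimum = largest penalty on decreasing path

  beta_sel <- coefs[, sel]
  beta_sel[abs(beta_sel) <= .zero_tol] <- 0
  structure(list(node = node, lambda = path[sel], lambda_path = path,
                 intercept = b0[sel], coefficients = beta_sel,
                 roles = roles, df = unname(df[sel]), ebic = unname(ebic[sel]),
                 ebic_path = unname(ebic), rss = unname(rss[sel]), n = n,
                 p_candidates = p),
            class = "nodewise_fit")
}

#' @export
print.nodewise_fit <- function(x, ...) {
  cat("Nodewise fit for", x$node, ": lambda =", format(x$lambda, digits = 4),
      ", df =", x$df, "of", x$p_candidates,
      ", EBIC =", format(x$ebic, digits = 6), "\n")
  invisible(x)
}
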