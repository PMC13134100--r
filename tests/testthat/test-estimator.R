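test_that("design matrix has the forced predictor layout", {
  d <- design_matrix(fix_null_cohort_g3, node = 1, reference_group = "A")
  # G = 3: 19 nodes + 2 dummies + 38 interactions + 2 covariates
  expect_equal(ncol(d$x), 19 + 2 + 38 + 2)
  expect_equal(unname(table(d$roles)[c("node", "dummy", "interaction",
                                       "covariate")]),
               c(19L, 2L, 38L, 2L), ignore_attr = TRUE)

  tr11 <- build_truth(G = 11, seed = 41)
  co11 <- sample_cohort(tr11, rep(30, 11), seed = 42)
  d11 <- design_matrix(co11, node = 5, reference_group = "K")
  expect_equal(ncol(d11$x), 19 + 10 + 190 + 2)

  tr2 <- build_truth(G = 2, seed = 43)
  co2 <- sample_cohort(tr2, c(40, 40), seed = 44)
  d2 <- design_matrix(co2, node = "gad3", reference_group = "B")
  expect_equal(ncol(d2$x), 19 + 1 + 19 + 2)
})

test_that("standardized design columns have mean 0 and variance 1", {
  d <- design_matrix(fix_null_cohort_g3, node = 2, reference_group = "B",
                     standardize = TRUE)
  cm <- colMeans(d$x)
  cv <- apply(d$x, 2, stats::var)
  nonconst <- cv > 0
  expect_lt(max(abs(cm)), 1e-10)
  expect_lt(max(abs(cv[nonconst] - 1)), 1e-10)
  expect_equal(mean(d$y), 0, tolerance = 1e-12)
  expect_equal(stats::var(d$y), 1, tolerance = 1e-12)
})

test_that("ebic score follows its closed form", {
  # gamma = 0 reduces to the Gaussian BIC
  expect_equal(ebic_score(50, 100, 3, 40, gamma = 0),
               100 * log(0.5) + 3 * log(100))
  # RSS = n with no coefficients scores exactly 0
  expect_equal(ebic_score(100, 100, 0, 40, gamma = 0.7), 0)
  # one extra coefficient costs log(n) + 2 gamma log(p)
  d <- ebic_score(50, 100, 4, 40, 0.25) - ebic_score(50, 100, 3, 40, 0.25)
  expect_equal(d, log(100) + 2 * 0.25 * log(40))
  expect_error(ebic_score(0, 100, 0, 40, 0.25), "degenerate")
  expect_error(ebic_score(50, 100, 41, 40, 0.25), "df")
})

test_that("a dominating penalty drives all coefficients to zero", {
  d <- design_matrix(fix_null_cohort_g3, node = 3, reference_group = "A")
  f <- fit_node(d, settings = mnm_settings(lambda_path = 1e3))
  expect_true(all(f$coefficients == 0))
  expect_equal(f$intercept, mean(d$y), tolerance = 1e-8)
  expect_equal(f$df, 0L, ignore_attr = TRUE)
})

test_that("zero penalty reproduces the least-squares solution", {
  set.seed(45)
  n <- 150; p <- 25
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("v", 1:p)))
  beta <- c(rep(1.5, 5), rep(0, p - 5))
  y <- drop(x %*% beta) + rnorm(n)
  f <- fit_node(x, y, settings = ols_settings)
  ols <- stats::lm.fit(cbind(1, x), y)$coefficients
  expect_rel_equal(c(f$intercept, f$coefficients), unname(ols), 1e-10)
})

test_that("orthonormal-design lasso equals analytic soft-thresholding", {
  set.seed(46)
  n <- 400; p <- 30
  raw <- scale(matrix(rnorm(n * p), n, p), center = TRUE, scale = FALSE)
  Q <- qr.Q(qr(raw)) * sqrt(n)      # columns: mean 0, crossprod(Q)/n = I
  colnames(Q) <- paste0("q", 1:p)
  y <- rnorm(n, sd = 2)
  b_ols <- drop(crossprod(Q, y)) / n
  for (lam in c(0.05, 0.12, 0.3)) {
    f <- fit_node(Q, y, settings = mnm_settings(lambda_path = lam,
                                                standardize = FALSE))
    soft <- sign(b_ols) * pmax(abs(b_ols) - lam, 0)
    expect_equal(unname(f$coefficients), unname(soft), tolerance = 1e-6)
  }
})

test_that("EBIC selection picks the path minimum, ties toward sparsity", {
  d <- design_matrix(fix_null_cohort_g3, node = 4, reference_group = "A")
  f <- fit_node(d, settings = fast_settings)
  expect_equal(f$ebic, min(f$ebic_path))
  expect_equal(which(f$lambda_path == f$lambda),
               which.min(f$ebic_path))
  # selected df never exceeds the df at the smallest penalty
  fit_small <- fit_node(d, settings = mnm_settings(
    lambda_path = min(f$lambda_path)))
  expect_lte(f$df, fit_small$df)
})

test_that("nodewise coefficient keys enumerate the full predictor set", {
  d <- design_matrix(fix_null_cohort_g3, node = 1, reference_group = "B")
  f <- fit_node(d, settings = fast_settings)
  items <- symptom_panel()$item
  expect_setequal(names(f$coefficients)[f$roles == "node"], items[-1])
  expect_setequal(names(f$coefficients)[f$roles == "dummy"],
                  paste0("grp_", c("A", "C")))
  expect_equal(sum(f$roles == "interaction"), 38L)
  expect_setequal(names(f$coefficients)[f$roles == "covariate"],
                  c("age", "gender"))
})

test_that("derived group edge matrices are symmetric with zero diagonal", {
  fit <- mnm(fix_null_cohort_g3, reference_group = "A",
             settings = fast_settings)
  for (g in fit$groups) {
    E <- fit$group_edges[g, , ]
    expect_identical(E, t(E))
    expect_true(all(diag(E) == 0))
    P <- fit$edge_presence[g, , ]
    expect_identical(P, t(P))
  }
})

test_that("AND-rule edges are a subset of OR-rule edges", {
  fit_and <- mnm(fix_null_cohort_g3, settings = fast_settings)
  or_set <- mnm_settings(lambda_path_length = 15, lambda_min_ratio = 0.05,
                         nodewise_rule = "OR")
  fit_or <- mnm(fix_null_cohort_g3, settings = or_set)
  expect_true(all(fit_or$edge_presence[fit_and$edge_presence]))
  expect_gte(sum(fit_or$edge_presence), sum(fit_and$edge_presence))
})

test_that("a strong planted edge is recovered with the right sign", {
  tr <- build_truth(G = 2, density = 1 / 190, seed = 47,
                    base_weight_range = c(0.4, 0.4),
                    covariate_effect_range = 0)
  co <- sample_cohort(tr, c(10000, 10000), ordinal = FALSE, seed = 48)
  fit <- mnm(co, reference_group = "A")
  idx <- which(upper.tri(tr$base_partial) & tr$base_partial != 0,
               arr.ind = TRUE)
  s <- idx[1, 1]; t <- idx[1, 2]
  truth_sign <- sign(tr$base_partial[s, t])
  for (g in c("A", "B")) {
    expect_true(fit$edge_presence[g, s, t])
    expect_equal(sign(fit$group_edges[g, s, t]), truth_sign)
  }
  # independent oracle: partial correlation from the inverted covariance
  a <- as.matrix(co[co$group == "A", symptom_panel()$item])
  P_hat <- -stats::cov2cor(solve(stats::cov(a)))
  expect_equal(sign(P_hat[s, t]), truth_sign)
  expect_lt(abs(fit$group_edges["A", s, t] - P_hat[s, t]), 0.1)
})

test_that("label-permuted data yields almost no group terms under AND", {
  perm <- permute_labels(fix_null_cohort_g3, seed = 49)
  ctr <- mnm_contrasts(rotate_references(perm, fast_settings))
  expect_lte(sum(ctr$detected), 3)
})

test_that("residuals and predictions are consistent on the training data", {
  fit <- mnm(fix_null_cohort_g3, settings = fast_settings)
  res <- residuals(fit, fix_null_cohort_g3)
  pred <- predict(fit, fix_null_cohort_g3)
  expect_equal(dim(res), c(nrow(fix_null_cohort_g3), 20))
  # z-scored observation = prediction + residual
  z1 <- (fix_null_cohort_g3$phq1 - fit$scaling$item_center[1]) /
    fit$scaling$item_scale[1]
  expect_equal(unname(pred[, "phq1"] + res[, "phq1"]), z1, tolerance = 1e-10)
})
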