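test_that("identical seeds and configs give bit-identical cohorts", {
  tr <- build_truth(G = 3, n_planted_mean = 1, effect_mean = 0.3, seed = 21)
  c1 <- sample_cohort(tr, c(50, 60, 70), seed = 22)
  c2 <- sample_cohort(tr, c(50, 60, 70), seed = 22)
  expect_identical(c1, c2)
  c3 <- sample_cohort(tr, c(50, 60, 70), seed = 23)
  expect_false(identical(c1$phq1, c3$phq1))
})

test_that("ordinal mode keeps every item inside its panel range", {
  tr <- build_truth(G = 2, n_planted_mean = 3, effect_mean = 1, seed = 24)
  co <- sample_cohort(tr, c(500, 500), ordinal = TRUE, seed = 25)
  panel <- symptom_panel()
  for (j in seq_len(nrow(panel))) {
    v <- co[[panel$item[j]]]
    expect_true(all(v >= panel$min[j] & v <= panel$max[j]))
    expect_true(all(v == round(v)))
  }
})

test_that("null truth gives exchangeable groups", {
  tr <- build_truth(G = 2, seed = 26)
  co <- sample_cohort(tr, c(5000, 5000), ordinal = FALSE, seed = 27)
  a <- co[co$group == "A", ]
  b <- co[co$group == "B", ]
  for (it in c("phq1", "gad4", "wsas3")) {
    se <- sqrt(stats::var(a[[it]]) / nrow(a) + stats::var(b[[it]]) / nrow(b))
    expect_lt(abs(mean(a[[it]]) - mean(b[[it]])), 4 * se)
  }
})

test_that("per-group sample means converge to configured means", {
  tr <- build_truth(G = 2, n_planted_mean = 2, effect_mean = 0.5, seed = 28)
  n <- 50000
  co <- sample_cohort(tr, c(n, 10), ordinal = FALSE, seed = 29)
  a <- co[co$group == "A", ]
  mu <- tr$base_mean + tr$group_mean_shift["A", ] +
    0.65 * tr$covariate_effects["gender", ]   # age is centred in expectation
  for (j in seq_along(mu)) {
    it <- names(mu)[j]
    se <- stats::sd(a[[it]]) / sqrt(n)
    expect_lt(abs(mean(a[[it]]) - mu[j]), 3 * se)
  }
})

test_that("sample partial correlations recover the configured network", {
  tr <- build_truth(G = 2, density = 25 / 190, seed = 30,
                    base_weight_range = c(0.15, 0.3),
                    covariate_effect_range = 0)  # keep the oracle exact
  co <- sample_cohort(tr, c(50000, 10), ordinal = FALSE, seed = 31)
  a <- as.matrix(co[co$group == "A", symptom_panel()$item])
  # independent oracle: partial correlations from the inverted sample
  # covariance must approximate the configured partials
  Omega_hat <- solve(stats::cov(a))
  P_hat <- -stats::cov2cor(Omega_hat)
  diag(P_hat) <- 0
  P_true <- -stats::cov2cor((diag(20) - tr$base_partial) * (1 + tr$ridge))
  diag(P_true) <- 0
  expect_lt(max(abs(P_hat - P_true)), 0.05)
})

test_that("permuting labels preserves the group multiset and is seeded", {
  co <- fix_null_cohort_g3
  p1 <- permute_labels(co, seed = 33)
  p2 <- permute_labels(co, seed = 33)
  p3 <- permute_labels(co, seed = 34)
  expect_identical(p1$group, p2$group)
  expect_equal(as.vector(table(p1$group)), as.vector(table(co$group)))
  expect_false(identical(p1$group, p3$group))
  # items stay attached to their rows
  expect_identical(p1$phq1, co$phq1)
})

test_that("cohort CSV round-trips and complete-case filtering works", {
  co <- fix_null_cohort_g3
  path <- tempfile(fileext = ".csv")
  write_cohort_csv(co, path)
  back <- suppressMessages(load_cohort_csv(path, verbose = FALSE))
  expect_equal(nrow(back), nrow(co))
  expect_equal(attr(back, "n_dropped"), 0L)
  expect_equal(back$phq5, co$phq5)

  # poke missing values into 2 of 10 rows spanning two groups
  raw <- utils::read.csv(path)[c(1:5, 121:125), ]
  raw$gad2[c(2, 7)] <- NA
  p2 <- tempfile(fileext = ".csv")
  utils::write.csv(raw, p2, row.names = FALSE)
  filtered <- suppressMessages(load_cohort_csv(p2, verbose = FALSE))
  expect_equal(nrow(filtered), 8L)
  expect_equal(attr(filtered, "n_dropped"), 2L)
})

test_that("range violations are reported and bad headers rejected", {
  co <- fix_null_cohort_g3[c(1:6, 121:126), ]
  co$phq1[3] <- 4   # depression items are scored 0-3
  path <- tempfile(fileext = ".csv")
  utils::write.csv(as.data.frame(co), path, row.names = FALSE)
  loaded <- suppressMessages(load_cohort_csv(path, verbose = FALSE))
  expect_equal(attr(loaded, "range_violations")[["phq1"]], 1L)

  # duplicate header
  lines <- readLines(path)
  lines[1] <- sub("phq2", "phq1", lines[1])
  writeLines(lines, path)
  expect_error(suppressMessages(load_cohort_csv(path)), "duplicate")

  # missing column
  p3 <- tempfile(fileext = ".csv")
  utils::write.csv(as.data.frame(co)[, -1], p3, row.names = FALSE)
  expect_error(suppressMessages(load_cohort_csv(p3)), "header mismatch")
})

test_that("cohort contract is enforced", {
  co <- as.data.frame(fix_null_cohort_g3)
  co$group <- "A"
  expect_error(as_cohort(co), "at least 2 groups")
  co2 <- as.data.frame(fix_null_cohort_g3)
  co2$phq3[1] <- NA
  expect_error(as_cohort(co2), "complete-case")
})
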