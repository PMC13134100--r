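test_that("percent difference matches its closed form and range", {
  expect_equal(percent_difference(1, 1), 0)
  expect_equal(percent_difference(1, 0), 200)
  expect_equal(percent_difference(0, 1), -200)
  expect_equal(percent_difference(0, 0), 0)
  set.seed(51)
  x <- rnorm(200); y <- rnorm(200)
  pd <- percent_difference(x, y)
  expect_true(all(pd >= -200 & pd <= 200))
  expect_equal(percent_difference(y, x), -pd)
  expect_equal(pd, pmin(pmax(200 * (x - y) / (abs(x) + abs(y)), -200), 200))
})

test_that("comparison universe counts follow the combinatorics", {
  u <- comparison_universe(11, 20)
  expect_equal(u$group_pairs, 55)
  expect_equal(u$ordered_cooccurrence_slots, 380)
  expect_equal(u$unordered_cooccurrence_slots, 190)
  u2 <- comparison_universe(2, 2)
  expect_equal(u2$group_pairs, 1)
  expect_equal(u2$ordered_cooccurrence_slots, 2)
  expect_equal(u2$unordered_cooccurrence_slots, 1)
  expect_error(comparison_universe(1, 20), "G >= 2")
})

test_that("rotation produces one fit per group, deterministically", {
  ens <- rotate_references(fix_null_cohort_g3, fast_settings)
  expect_length(ens$fits, 3L)
  expect_equal(names(ens$fits), c("A", "B", "C"))
  for (g in ens$groups)
    expect_equal(ens$fits[[g]]$reference_group, g)
  ens2 <- rotate_references(fix_null_cohort_g3, fast_settings)
  expect_equal(ens$fits[["B"]]$group_edges, ens2$fits[["B"]]$group_edges)
  expect_equal(ens$fingerprint, ens2$fingerprint)
})

test_that("at zero penalty the two rotation estimates agree exactly", {
  tr <- build_truth(G = 3, n_planted_mean = 2, effect_mean = 0.4, seed = 52)
  co <- sample_cohort(tr, c(180, 150, 120), ordinal = FALSE, seed = 53)
  ens <- rotate_references(co, ols_settings)
  for (pr in list(c("A", "B"), c("A", "C"), c("B", "C"))) {
    ctr <- pairwise_contrast(ens, pr[1], pr[2])
    # linear reparameterization invariance: est from fit(ref=a) equals the
    # sign-flipped est from fit(ref=b), both oriented b - a
    expect_equal(ctr$est_ref_a, ctr$est_ref_b, tolerance = 1e-8)
  }
})

test_that("contrasts are antisymmetric in the group order", {
  ens <- rotate_references(fix_null_cohort_g3, fast_settings)
  ab <- pairwise_contrast(ens, "A", "B")
  ba <- pairwise_contrast(ens, "B", "A")
  expect_equal(ab$detected, ba$detected)
  expect_equal(ab$estimate, -ba$estimate)
  expect_equal(ab$est_ref_a, -ba$est_ref_b)
  expect_equal(ab$percent_diff, -ba$percent_diff)
})

test_that("AND-rule detections are a subset of OR-rule detections", {
  or_set <- mnm_settings(lambda_path_length = 15, lambda_min_ratio = 0.05,
                         nodewise_rule = "OR")
  tr <- build_truth(G = 2, n_planted_mean = 2, n_planted_edge = 1,
                    effect_mean = 0.5, effect_edge = 0.25, seed = 54)
  co <- sample_cohort(tr, c(800, 800), seed = 55)
  c_and <- mnm_contrasts(rotate_references(co, fast_settings))
  c_or <- mnm_contrasts(rotate_references(co, or_set))
  expect_true(all(c_or$detected[c_and$detected]))
})

test_that("a planted intercept shift is detected with the right sign", {
  tr <- build_truth(G = 2, n_planted_mean = 1, effect_mean = 0.5, seed = 56)
  co <- sample_cohort(tr, c(1500, 1500), seed = 57)
  ctr <- mnm_contrasts(rotate_references(co))
  pd <- planted_differences(tr)
  hit <- ctr$type == "intercept" & ctr$param == pd$param[1]
  expect_true(ctr$detected[hit])
  # estimates are oriented b - a, matching the oracle's convention
  expect_equal(sign(ctr$estimate[hit]), sign(pd$difference[1]))
})

test_that("null cohorts yield empty detected sets", {
  ctr <- mnm_contrasts(rotate_references(fix_null_cohort_g3, fast_settings))
  expect_lte(sum(ctr$detected), 3)
  expect_equal(nrow(ctr), 3 * (20 + 190))
  # AND-rule flag is the conjunction of the two rotations by construction
  expect_equal(ctr$detected,
               abs(ctr$est_ref_a) > 1e-10 & abs(ctr$est_ref_b) > 1e-10)
  # combined estimate is the mean of the rotations when detected, else 0
  expect_equal(ctr$estimate,
               ifelse(ctr$detected, (ctr$est_ref_a + ctr$est_ref_b) / 2, 0))
})
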