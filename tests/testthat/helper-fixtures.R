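# shared small fixtures, built once per test run

fix_null_truth_g3 <- build_truth(G = 3, seed = 301)
fix_null_cohort_g3 <- sample_cohort(fix_null_truth_g3,
                                    group_sizes = c(120, 100, 80), seed = 302)

# a fast settings object for tests that only exercise plumbing
fast_settings <- mnm_settings(lambda_path_length = 15, lambda_min_ratio = 0.05)

# unpenalised fit: single path point at zero penalty
ols_settings <- mnm_settings(lambda_path = 0)

expect_rel_equal <- function(x, y, tol) {
  expect_lt(max(abs(x - y)) / max(max(abs(y)), 1e-12), tol)
}
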