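# construct a synthetic contrast set with known significance pattern
make_fake_contrasts <- function(groups, sig, p_items = 4) {
  items <- paste0("it", seq_len(p_items))
  prs <- utils::combn(groups, 2)
  rows <- list()
  for (k in seq_len(ncol(prs))) {
    a <- prs[1, k]; b <- prs[2, k]
    ic <- data.frame(group_a = a, group_b = b, type = "intercept",
                     param = items, stringsAsFactors = FALSE)
    ut <- utils::combn(items, 2)
    ec <- data.frame(group_a = a, group_b = b, type = "edge",
                     param = paste(ut[1, ], ut[2, ], sep = "--"),
                     stringsAsFactors = FALSE)
    rows[[k]] <- rbind(ic, ec)
  }
  out <- do.call(rbind, rows)
  key <- paste(out$group_a, out$group_b, out$type, out$param)
  out$detected <- key %in% sig
  out$estimate <- ifelse(out$detected, 0.3, 0)
  out$value_a <- ifelse(out$detected, 0.4, 0.1)
  out$value_b <- ifelse(out$detected, 0.1, 0.1)
  out$percent_diff <- percent_difference(out$value_a, out$value_b)
  out$p <- ifelse(out$detected, 0.01, 1)
  attr(out, "groups") <- groups
  class(out) <- c("mnm_contrasts", "data.frame")
  out
}

test_that("proportion tables divide kind-matched counts by the denominator", {
  sig <- c("A B intercept it1", "A B intercept it2", "A C edge it1--it3")
  ctr <- make_fake_contrasts(c("A", "B", "C"), sig)
  ti <- proportion_table(ctr, "intercept")
  expect_equal(ti$denominator, 4)
  expect_equal(ti$counts["A", "B"], 2)
  expect_equal(ti$proportions["A", "B"], 0.5)
  expect_equal(ti$counts["B", "C"], 0)
  expect_true(all(is.na(ti$proportions[lower.tri(ti$proportions, diag = TRUE)])))

  te <- proportion_table(ctr, "edge")           # ordered convention
  expect_equal(te$denominator, 4 * 3)
  expect_equal(te$counts["A", "C"], 2)          # one unordered edge, 2 slots
  teu <- proportion_table(ctr, "edge", ordered = FALSE)
  expect_equal(teu$counts["A", "C"], 1)
  expect_equal(te$proportions["A", "C"], teu$proportions["A", "C"])

  # conservation: counts equal a recount of the significance flags
  sig_flags <- significant_contrasts(ctr)
  for (pr in list(c("A", "B"), c("A", "C"), c("B", "C"))) {
    sel <- ctr$group_a == pr[1] & ctr$group_b == pr[2] &
      ctr$type == "intercept"
    expect_equal(ti$counts[pr[1], pr[2]], sum(sig_flags[sel]))
  }
})

test_that("missing pairs are rejected", {
  sig <- character(0)
  ctr <- make_fake_contrasts(c("A", "B", "C"), sig)
  broken <- ctr[!(ctr$group_a == "B" & ctr$group_b == "C"), ]
  attr(broken, "groups") <- c("A", "B", "C")
  class(broken) <- c("mnm_contrasts", "data.frame")
  expect_error(proportion_table(broken, "intercept"), "missing group pair")
})

test_that("significance combines AND-rule detection with the p criterion", {
  ctr <- make_fake_contrasts(c("A", "B"), "A B intercept it1")
  # detected but p just above alpha -> not significant under "both"
  ctr$p[ctr$detected] <- 0.06
  expect_equal(sum(significant_contrasts(ctr, alpha = 0.05,
                                         criterion = "both")), 0L)
  expect_equal(sum(significant_contrasts(ctr, criterion = "detected")), 1L)
  ctr$p <- NA_real_
  expect_equal(sum(significant_contrasts(ctr)), 1L)  # falls back to detected
  expect_error(significant_contrasts(ctr, criterion = "both"), "no permutation")
})

test_that("group ranking totals count significant differences per group", {
  sig <- c("A B intercept it1", "A B intercept it2", "A C intercept it1")
  ctr <- make_fake_contrasts(c("A", "B", "C"), sig)
  tb <- proportion_table(ctr, "intercept")
  rk <- group_difference_ranking(tb)
  expect_equal(rk$group[1], "A")
  expect_equal(rk$total[1], 3)
  expect_equal(rk$total[rk$group == "B"], 2)
  expect_equal(rk$total[rk$group == "C"], 1)
  expect_false(any(rk$tied))

  # null table: all totals 0, everything tied
  ctr0 <- make_fake_contrasts(c("A", "B", "C"), character(0))
  rk0 <- group_difference_ranking(proportion_table(ctr0, "intercept"))
  expect_true(all(rk0$total == 0))
  expect_true(all(rk0$tied))
})

test_that("heatmap emptiness pattern equals the significance pattern", {
  sig <- c("A B intercept it2", "B C edge it1--it2")
  ctr <- make_fake_contrasts(c("A", "B", "C"), sig)
  hm <- heatmap_matrix(ctr, "intercept")
  expect_equal(sum(!is.na(hm$values)), 1L)
  expect_false(is.na(hm$values["A vs B", "it2"]))
  expect_true(all(abs(hm$values[!is.na(hm$values)]) <= 200))
  he <- heatmap_matrix(ctr, "edge")
  expect_equal(sum(!is.na(he$values)), 1L)
  expect_false(is.na(he$values["B vs C", "it1--it2"]))

  path <- tempfile(fileext = ".csv")
  write_heatmap_csv(he, path)
  back <- utils::read.csv(path)
  expect_equal(nrow(back), 1L)
  expect_equal(back$percent_diff, 200 * (0.4 - 0.1) / 0.5)
})

test_that("demographics rows are computed from counts", {
  co <- fix_null_cohort_g3
  dt <- demographics_table(co)
  expect_equal(dt$group, c("A", "B", "C", "Overall"))
  expect_equal(sum(dt$percent[1:3]), 100, tolerance = 1e-10)
  expect_equal(dt$n[4], nrow(co))
  expect_equal(dt$pct_gender1 + dt$pct_gender0, rep(100, 4))
  expect_equal(dt$n_gender1[4], sum(co$gender == 1))

  # two identical groups produce identical descriptive rows
  half <- as.data.frame(co[co$group == "A", ])
  twin <- rbind(transform(half, group = "X"), transform(half, group = "Y"))
  dt2 <- demographics_table(as_cohort(twin))
  expect_equal(unlist(dt2[1, -1]), unlist(dt2[2, -1]))
})

test_that("large-sample demographic means match the configured truth", {
  tr <- build_truth(G = 2, seed = 71, covariate_effect_range = 0)
  co <- sample_cohort(tr, c(50000, 20), ordinal = FALSE, seed = 72)
  dt <- demographics_table(co)
  mu <- tr$base_mean
  for (it in c("phq2", "gad5", "wsas4")) {
    se <- dt[[paste0(it, "_sd")]][1] / sqrt(dt$n[1])
    expect_lt(abs(dt[[paste0(it, "_mean")]][1] - mu[[it]]), 3 * se)
  }
})

test_that("markdown rendering rounds to two decimals", {
  ctr <- make_fake_contrasts(c("A", "B"), "A B intercept it1")
  md <- format_markdown(proportion_table(ctr, "intercept"))
  expect_match(md[3], "0.25")
  expect_length(md, 4L)
})
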