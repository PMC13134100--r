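#' Smoothed empirical p-value
#'
#' \code{p = (1 + #\{|null| >= |observed|\}) / (B + 1)}: the add-one
#' smoothed permutation p-value, valid at finite B, with ties counted as at
#' least as extreme. The smallest attainable value is \code{1/(B+1)} and an
#' observed statistic of 0 always gives p = 1.
#'
#' @param observed Observed statistic (scalar).
#' @param null_samples Vector of B null statistics (B >= 1).
#' @return The empirical p-value in \code{[1/(B+1), 1]}.
#' @examples
#' empirical_pvalue(5, rep(0, 100))  # 1/101
#' empirical_pvalue(0, rnorm(100))   # 1
#' @export
empirical_pvalue <- function(observed, null_samples) {
  B <- length(null_samples)
  if (B < 1) stop("need at least one null sample")
  (1 + sum(abs(null_samples) >= abs(observed))) / (B + 1)
}

perm_seed <- function(master, b) {
  as.integer((as.numeric(master) + 7919 * b) %% 2147483629)
}

#' Permutation null distribution for all pairwise group differences
#'
#' For each of B label permutations, shuffles group labels across rows
#' ([permute_labels()]), refits the full reference-rotation ensemble, and
#' records every pairwise combined difference statistic (intercepts and
#' edges) together with the per-pair counts of AND-rule-detected
#' differences.  Per-permutation seeds are derived deterministically from
#' the master seed, so individual permutations can be reproduced.
#'
#' @param cohort An \code{mnm_cohort}.
#' @param settings An [mnm_settings()] object (shared with the observed
#'   analysis).
#' @param psettings A [perm_settings()] object.
#' @param verbose Print progress every 10 permutations.
#' @return An object of class \code{"mnm_permnull"}: a list with
#'   \code{params} (data frame indexing the parameter rows), \code{stats}
#'   (parameters x B matrix of null combined estimates),
#'   \code{counts_intercept} and \code{counts_edge} (group pairs x B
#'   matrices of null detected counts), \code{pairs}, \code{B},
#'   \code{seed}, \code{alpha} and \code{status} (per-permutation "ok").
#' @seealso [attach_pvalues()], [empirical_pvalue()]
#' @export
null_distribution <- function(cohort, settings = mnm_settings(),
                              psettings = perm_settings(),
                              verbose = FALSE) {
  stopifnot(inherits(cohort, "mnm_cohort"))
  B <- psettings$B
  groups <- levels(cohort$group)
  prs <- utils::combn(groups, 2)
  pair_id <- paste(prs[1, ], prs[2, ], sep = ":")

  template <- NULL
  stats <- NULL
  counts_i <- matrix(NA_real_, ncol(prs), B,
                     dimnames = list(pair_id, NULL))
  counts_e <- counts_i
  status <- character(B)
  for (b in seq_len(B)) {
    perm <- permute_labels(cohort, seed = perm_seed(psettings$seed, b))
    ctr <- tryCatch(mnm_contrasts(rotate_references(perm, settings)),
                    error = function(e) e)
    if (inherits(ctr, "error")) {
      status[b] <- conditionMessage(ctr)
      stop("permutation ", b, " failed: ", conditionMessage(ctr))
    }
    status[b] <- "ok"
    if (is.null(template)) {
      template <- ctr[, c("group_a", "group_b", "type", "param")]
      stats <- matrix(NA_real_, nrow(ctr), B)
    }
    stats[, b] <- ctr$estimate
    key <- paste(ctr$group_a, ctr$group_b, sep = ":")
    for (k in seq_along(pair_id)) {
      sel <- key == pair_id[k]
      counts_i[k, b] <- sum(ctr$detected[sel & ctr$type == "intercept"])
      counts_e[k, b] <- sum(ctr$detected[sel & ctr$type == "edge"])
    }
    if (verbose && b %% 10 == 0)
      message("permutation ", b, " of ", B, " done")
  }
  structure(list(params = template, stats = stats,
                 counts_intercept = counts_i, counts_edge = counts_e,
                 pairs = pair_id, B = B, seed = psettings$seed,
                 alpha = psettings$alpha, status = status),
            class = "mnm_permnull")
}

#' @export
print.mnm_permnull <- function(x, ...) {
  cat("Permutation null distribution: B =", x$B, "permutations,",
      nrow(x$params), "parameters,", length(x$pairs), "group pairs\n")
  cat("  mean null detected counts per pair: intercept",
      format(mean(x$counts_intercept), digits = 3), ", edge",
      format(mean(x$counts_edge), digits = 3), "\n")
  invisible(x)
}

#' Attach permutation p-values to observed contrasts
#'
#' Computes the smoothed empirical p-value of every observed combined
#' difference against its own permutation null sample, and aggregate
#' p-values for the per-pair counts of AND-rule-detected differences.
#'
#' @param contrasts Observed [mnm_contrasts()].
#' @param null An [null_distribution()] object built from the same cohort
#'   and settings.
#' @return \code{contrasts} with the \code{p} column filled; the aggregate
#'   table (one row per group pair and kind, with the observed count and
#'   its empirical p-value) is attached as attribute \code{"aggregate"}
#'   and \code{alpha} as attribute \code{"alpha"}.
#' @export
attach_pvalues <- function(contrasts, null) {
  stopifnot(inherits(contrasts, "mnm_contrasts"),
            inherits(null, "mnm_permnull"))
  key_obs <- with(contrasts, paste(group_a, group_b, type, param))
  key_null <- with(null$params, paste(group_a, group_b, type, param))
  idx <- match(key_obs, key_null)
  if (anyNA(idx)) stop("contrast parameters do not match the null object")
  contrasts$p <- vapply(seq_len(nrow(contrasts)), function(i)
    empirical_pvalue(contrasts$estimate[i], null$stats[idx[i], ]), 0)

  key_pair <- paste(contrasts$group_a, contrasts$group_b, sep = ":")
  agg <- do.call(rbind, lapply(null$pairs, function(pr) {
    sel <- key_pair == pr
    oi <- sum(contrasts$detected[sel & contrasts$type == "intercept"])
    oe <- sum(contrasts$detected[sel & contrasts$type == "edge"])
    k <- match(pr, null$pairs)
    data.frame(pair = pr, type = c("intercept", "edge"),
               observed_count = c(oi, oe),
               p = c((1 + sum(null$counts_intercept[k, ] >= oi)) / (null$B + 1),
                     (1 + sum(null$counts_edge[k, ] >= oe)) / (null$B + 1)),
               stringsAsFactors = FALSE)
  }))
  attr(contrasts, "aggregate") <- agg
  attr(contrasts, "alpha") <- null$alpha
  contrasts
}

#' Chi-square goodness-of-fit test on per-group edge counts
#'
#' Tests whether the numbers of estimated edges are uniformly distributed
#' across groups.  Given a rotation ensemble, each group's edge count is
#' first averaged over the G rotated fits; the statistic is
#' \code{sum((c_g - e)^2 / e)} with uniform expectation \code{e = total/G},
#' df = G - 1, and the p-value from the upper chi-square tail.
#'
#' @param x A [rotate_references()] ensemble, an [mnm()] fit, or a named
#'   numeric vector of per-group edge counts.
#' @return A list with \code{statistic}, \code{df}, \code{p_value} and
#'   \code{counts}.
#' @examples
#' edge_count_chisq(c(A = 10, B = 20))  # statistic 10/3 on 1 df
#' @export
edge_count_chisq <- function(x) {
  counts <- if (inherits(x, "mnm_ensemble")) {
    rowMeans(vapply(x$fits, edge_counts, numeric(length(x$groups))))
  } else if (inherits(x, "mnm")) {
    edge_counts(x)
  } else if (is.numeric(x)) {
    x
  } else stop("x must be an ensemble, a fit, or a vector of counts")
  G <- length(counts)
  if (G < 2) stop("need counts for at least 2 groups")
  total <- sum(counts)
  if (total == 0) stop("zero total edge count: nothing to test")
  expected <- total / G
  statistic <- sum((counts - expected)^2 / expected)
  df <- G - 1
  list(statistic = statistic, df = df,
       p_value = stats::pchisq(statistic, df, lower.tail = FALSE),
       counts = counts)
}

#' Write a permutation run manifest
#'
#' Records B, seeds, settings and per-permutation status as JSON.
#'
#' @param null An [null_distribution()] object.
#' @param settings The [mnm_settings()] used.
#' @param path JSON path.
#' @return \code{path}, invisibly.
#' @export
write_permutation_manifest <- function(null, settings, path) {
  stopifnot(inherits(null, "mnm_permnull"))
  jsonlite::write_json(
    list(B = null$B, master_seed = null$seed, alpha = null$alpha,
         per_permutation_seeds = vapply(seq_len(null$B), function(b)
           perm_seed(null$seed, b), 0L),
         estimator_settings = unclass(settings), status = null$status),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
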