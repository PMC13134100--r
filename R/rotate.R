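#' Fit the reference-rotation ensemble
#'
#' Refits the moderated network once per group, systematically rotating
#' which group serves as the dummy-coding reference.  Because a single
#' regularised fit only contrasts each group with the reference, the
#' rotation yields two direct estimates of every pairwise group difference
#' (one from each pair member's fit), later synthesised by the AND-rule in
#' [pairwise_contrast()].
#'
#' @param cohort An \code{mnm_cohort} with at least 2 groups.
#' @param settings An [mnm_settings()] object, shared by all fits.
#' @return An object of class \code{"mnm_ensemble"}: a list with
#'   \code{fits} (one [mnm()] per group, named by reference group),
#'   \code{groups}, \code{settings} and \code{fingerprint} (row count,
#'   group sizes and item checksums identifying the cohort).
#' @examples
#' tr <- build_truth(G = 2, seed = 1)
#' co <- sample_cohort(tr, c(200, 200), seed = 1)
#' ens <- rotate_references(co)
#' length(ens$fits)  # one fit per group
#' @export
rotate_references <- function(cohort, settings = mnm_settings()) {
  stopifnot(inherits(cohort, "mnm_cohort"))
  groups <- levels(cohort$group)
  fits <- lapply(groups, function(g) mnm(cohort, reference_group = g,
                                         settings = settings))
  names(fits) <- groups
  structure(list(fits = fits, groups = groups, settings = settings,
                 fingerprint = cohort_fingerprint(cohort)),
            class = "mnm_ensemble")
}

cohort_fingerprint <- function(cohort) {
  items <- cohort_panel(cohort)$item
  list(n = nrow(cohort), group_sizes = as.integer(table(cohort$group)),
       checksum = signif(sum(vapply(items, function(it)
         sum(cohort[[it]] * seq_len(nrow(cohort))), 0)), 12))
}

#' @export
print.mnm_ensemble <- function(x, ...) {
  cat("Reference-rotation ensemble:", length(x$fits), "moderated network",
      "fits (one per reference group)\n")
  cat("  groups:", paste(x$groups, collapse = ", "), "\n")
  cat("  cohort: n =", x$fingerprint$n, ", sizes =",
      paste(x$fingerprint$group_sizes, collapse = "/"), "\n")
  invisible(x)
}

# combine two values under the nodewise rule
combine_two <- function(v1, v2, rule) {
  nz1 <- abs(v1) > .zero_tol
  nz2 <- abs(v2) > .zero_tol
  if (rule == "AND") ifelse(nz1 & nz2, (v1 + v2) / 2, 0)
  else ifelse(nz1 | nz2, (v1 + v2) / pmax(nz1 + nz2, 1), 0)
}

#' Contrast one group pair from the rotation ensemble
#'
#' For groups a and b, the intercept difference for each symptom is
#' estimated twice: as b's dummy coefficient in the fit with reference a,
#' and as the sign-flipped a dummy coefficient in the fit with reference b.
#' Edge differences come analogously from the item-by-dummy interaction
#' coefficients, with the two directed interaction estimates per edge first
#' combined by the settings' nodewise rule within each fit.  A genuine
#' difference is declared (AND-rule) only when both rotation estimates are
#' nonzero; the combined estimate is then their arithmetic mean, otherwise
#' 0.  Estimates are oriented as group b minus group a; the percent
#' difference compares the two groups' parameter values (positive when
#' stronger in group a, the first-listed group).
#'
#' @param ensemble A [rotate_references()] ensemble.
#' @param a,b Distinct group labels present in the ensemble.
#' @return A data frame of class \code{"pairwise_contrast"} with columns
#'   \code{group_a}, \code{group_b}, \code{type} (\code{"intercept"} or
#'   \code{"edge"}), \code{param}, \code{est_ref_a}, \code{est_ref_b},
#'   \code{detected} (AND-rule flag), \code{estimate} (combined),
#'   \code{value_a}, \code{value_b} (the groups' parameter values averaged
#'   over the two fits), \code{percent_diff} and \code{p} (NA until
#'   permutation p-values are attached).
#' @export
pairwise_contrast <- function(ensemble, a, b) {
  stopifnot(inherits(ensemble, "mnm_ensemble"))
  if (identical(a, b)) stop("a and b must be distinct groups")
  if (!all(c(a, b) %in% ensemble$groups))
    stop("both groups must be present in the ensemble")
  fitA <- ensemble$fits[[a]]
  fitB <- ensemble$fits[[b]]
  if (is.null(fitA) || is.null(fitB)) stop("misconfigured ensemble")
  rule <- ensemble$settings$nodewise_rule
  items <- fitA$panel$item
  p <- length(items)

  # intercepts: dummy coefficients
  est_a <- vapply(seq_len(p), function(j)
    fitA$nodes[[j]]$coefficients[[paste0("grp_", b)]], 0)
  est_b <- vapply(seq_len(p), function(j)
    -fitB$nodes[[j]]$coefficients[[paste0("grp_", a)]], 0)
  det_i <- abs(est_a) > .zero_tol & abs(est_b) > .zero_tol
  comb_i <- ifelse(det_i, (est_a + est_b) / 2, 0)
  val_a_i <- (fitA$group_intercepts[a, ] + fitB$group_intercepts[a, ]) / 2
  val_b_i <- (fitA$group_intercepts[b, ] + fitB$group_intercepts[b, ]) / 2
  ic <- data.frame(group_a = a, group_b = b, type = "intercept",
                   param = items, est_ref_a = est_a, est_ref_b = est_b,
                   detected = det_i, estimate = comb_i,
                   value_a = unname(val_a_i), value_b = unname(val_b_i),
                   stringsAsFactors = FALSE)

  # edges: interaction coefficients, nodewise-combined within each fit
  intA <- fitA$directed[b, , ] - fitA$directed[a, , ]  # b's interactions
  intB <- fitB$directed[a, , ] - fitB$directed[b, , ]  # a's interactions
  ut <- which(upper.tri(intA), arr.ind = TRUE)
  eA <- combine_two(intA[ut], intA[ut[, c(2, 1)]], rule)
  eB <- -combine_two(intB[ut], intB[ut[, c(2, 1)]], rule)
  det_e <- abs(eA) > .zero_tol & abs(eB) > .zero_tol
  comb_e <- ifelse(det_e, (eA + eB) / 2, 0)
  val_a_e <- (fitA$group_edges[a, , ][ut] + fitB$group_edges[a, , ][ut]) / 2
  val_b_e <- (fitA$group_edges[b, , ][ut] + fitB$group_edges[b, , ][ut]) / 2
  ec <- data.frame(group_a = a, group_b = b, type = "edge",
                   param = paste(items[ut[, 1]], items[ut[, 2]], sep = "--"),
                   est_ref_a = eA, est_ref_b = eB, detected = det_e,
                   estimate = comb_e, value_a = val_a_e, value_b = val_b_e,
                   stringsAsFactors = FALSE)

  out <- rbind(ic, ec)
  out$percent_diff <- percent_difference(out$value_a, out$value_b)
  out$p <- NA_real_
  rownames(out) <- NULL
  class(out) <- c("pairwise_contrast", "data.frame")
  out
}

#' All pairwise group contrasts of an ensemble
#'
#' Applies [pairwise_contrast()] to every unordered group pair (with
#' \code{a} before \code{b} in group-level order).
#'
#' @param ensemble A [rotate_references()] ensemble.
#' @return A data frame of class \code{"mnm_contrasts"} stacking all
#'   [pairwise_contrast()] results; the group vector and settings are kept
#'   as attributes.
#' @examples
#' \donttest{
#' tr <- build_truth(G = 3, seed = 1)
#' co <- sample_cohort(tr, rep(200, 3), seed = 1)
#' ctr <- mnm_contrasts(rotate_references(co))
#' head(ctr)
#' }
#' @export
mnm_contrasts <- function(ensemble) {
  stopifnot(inherits(ensemble, "mnm_ensemble"))
  prs <- utils::combn(ensemble$groups, 2)
  out <- do.call(rbind, lapply(seq_len(ncol(prs)), function(k)
    pairwise_contrast(ensemble, prs[1, k], prs[2, k])))
  rownames(out) <- NULL
  attr(out, "groups") <- ensemble$groups
  attr(out, "settings") <- ensemble$settings
  class(out) <- c("mnm_contrasts", "data.frame")
  out
}

#' @export
print.mnm_contrasts <- function(x, ...) {
  cat("Pairwise group contrasts:",
      length(unique(paste(x$group_a, x$group_b))), "group pairs,",
      nrow(x), "parameter contrasts\n")
  cat("  AND-rule detected:", sum(x$detected & x$type == "intercept"),
      "intercept,", sum(x$detected & x$type == "edge"), "edge\n")
  if (!all(is.na(x$p)))
    cat("  significant (detected & p < 0.05):",
        sum(x$detected & x$p < 0.05, na.rm = TRUE), "\n")
  invisible(x)
}

#' Symmetric percent difference between two parameter estimates
#'
#' \code{200 (x - y) / (|x| + |y|)}, the symmetric percent difference with
#' range [-200, 200]; defined as 0 when both arguments are 0. Values at
#' least 100 in magnitude indicate that one group's estimate is
#' substantially larger than, or the other is close to, zero.
#'
#' @param x,y Parameter estimates (vectorized).
#' @return Percent differences in [-200, 200].
#' @examples
#' percent_difference(1, 1)   # 0
#' percent_difference(1, 0)   # 200
#' @export
percent_difference <- function(x, y) {
  denom <- abs(x) + abs(y)
  out <- ifelse(denom == 0, 0, 200 * ((x - y) / denom))
  # guard the closed range against one-ulp overshoot at the +-200 endpoints
  pmin(pmax(out, -200), 200)
}

#' The comparison universe for G groups and p nodes
#'
#' @param G Number of groups (>= 2).
#' @param p Number of nodes (>= 2).
#' @return A list: \code{group_pairs} = G(G-1)/2, \code{symptoms} = p,
#'   \code{ordered_cooccurrence_slots} = p(p-1) (the reporting default) and
#'   \code{unordered_cooccurrence_slots} = p(p-1)/2.
#' @examples
#' comparison_universe(11, 20)  # 55 pairs, 380 ordered slots
#' @export
comparison_universe <- function(G, p) {
  if (G < 2 || p < 2) stop("need G >= 2 and p >= 2")
  list(group_pairs = G * (G - 1) / 2, symptoms = p,
       ordered_cooccurrence_slots = p * (p - 1),
       unordered_cooccurrence_slots = p * (p - 1) / 2)
}

#' Export contrasts as long-format CSV
#'
#' @param contrasts An [mnm_contrasts()] data frame.
#' @param path CSV path.
#' @return \code{path}, invisibly.
#' @export
write_contrasts_csv <- function(contrasts, path) {
  utils::write.csv(as.data.frame(contrasts), path, row.names = FALSE)
  invisible(path)
}
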