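#' Decide which contrasts count as significant
#'
#' A contrast is "significant" when BOTH its AND-rule detected flag is true
#' AND its permutation empirical p-value is below alpha; the two criteria
#' are also available separately.
#'
#' @param contrasts An [mnm_contrasts()] data frame.
#' @param alpha Significance level for the p-value criterion.
#' @param criterion \code{"both"} (default when p-values are present),
#'   \code{"detected"} (AND-rule only; the fallback when no p-values are
#'   attached), \code{"pvalue"}, or \code{"auto"}.
#' @return Logical vector, one entry per contrast row.
#' @export
significant_contrasts <- function(contrasts, alpha = 0.05,
                                  criterion = c("auto", "both", "detected",
                                                "pvalue")) {
  criterion <- match.arg(criterion)
  has_p <- !all(is.na(contrasts$p))
  if (criterion == "auto") criterion <- if (has_p) "both" else "detected"
  if (criterion %in% c("both", "pvalue") && !has_p)
    stop("no permutation p-values attached; use attach_pvalues() first")
  switch(criterion,
         both = contrasts$detected & contrasts$p < alpha,
         detected = contrasts$detected,
         pvalue = contrasts$p < alpha)
}

#' Proportion-of-significant-differences table
#'
#' Upper-triangular group-by-group matrix of the proportion of parameters
#' with a significant difference for each pair: intercept differences out
#' of the 20 symptoms, or edge differences out of the ordered co-occurrence
#' slots (p(p-1) = 380 for 20 nodes; each detected unordered edge occupies
#' two ordered slots, so the proportion equals the unordered count over
#' p(p-1)/2).
#'
#' @param contrasts An [mnm_contrasts()] covering all group pairs.
#' @param kind \code{"intercept"} or \code{"edge"}.
#' @param alpha,criterion Passed to [significant_contrasts()].
#' @param ordered For \code{kind = "edge"}: use the ordered-slot denominator
#'   (default \code{TRUE}); proportions are identical either way, only the
#'   reported counts and denominator differ.
#' @return An object of class \code{"proportion_table"}: a list with
#'   \code{kind}, \code{proportions} and \code{counts} (G x G matrices,
#'   upper triangle populated, lower triangle and diagonal NA),
#'   \code{denominator}, and \code{criterion}.
#' @export
proportion_table <- function(contrasts, kind = c("intercept", "edge"),
                             alpha = 0.05, criterion = "auto",
                             ordered = TRUE) {
  kind <- match.arg(kind)
  groups <- attr(contrasts, "groups")
  if (is.null(groups))
    groups <- sort(unique(c(contrasts$group_a, contrasts$group_b)))
  G <- length(groups)
  sig <- significant_contrasts(contrasts, alpha = alpha,
                               criterion = criterion)
  sub <- contrasts[contrasts$type == kind, , drop = FALSE]
  sig <- sig[contrasts$type == kind]
  p <- length(unique(contrasts$param[contrasts$type == "intercept"]))
  denom <- if (kind == "intercept") p else
    if (ordered) p * (p - 1) else p * (p - 1) / 2
  mult <- if (kind == "edge" && ordered) 2L else 1L

  counts <- matrix(NA_real_, G, G, dimnames = list(groups, groups))
  expected_pairs <- utils::combn(groups, 2)
  for (k in seq_len(ncol(expected_pairs))) {
    a <- expected_pairs[1, k]; b <- expected_pairs[2, k]
    sel <- sub$group_a == a & sub$group_b == b
    if (!any(sel))
      stop("contrast set is missing group pair ", a, ":", b)
    counts[a, b] <- mult * sum(sig[sel])
  }
  structure(list(kind = kind, proportions = counts / denom,
                 counts = counts, denominator = denom,
                 criterion = criterion, groups = groups),
            class = "proportion_table")
}

#' @export
print.proportion_table <- function(x, digits = 2, ...) {
  cat("Proportion of significant", x$kind, "differences (out of",
      x$denominator, "slots; criterion:", x$criterion, ")\n")
  print(round(x$proportions, digits), na.print = "")
  invisible(x)
}

#' Rank groups by how much they differ from all others
#'
#' Sums each group's significant-difference counts across all pairs it
#' belongs to and sorts in decreasing order; ties are broken alphabetically
#' and flagged. Totals use counts, not proportions, so unequal denominators
#' cannot distort the ordering.
#'
#' @param table A [proportion_table()].
#' @return Data frame with columns \code{group}, \code{total} and
#'   \code{tied}.
#' @export
group_difference_ranking <- function(table) {
  stopifnot(inherits(table, "proportion_table"))
  groups <- table$groups
  totals <- vapply(groups, function(g) {
    sum(table$counts[g, ], na.rm = TRUE) + sum(table$counts[, g], na.rm = TRUE)
  }, 0)
  ord <- order(-totals, groups)
  out <- data.frame(group = groups[ord], total = unname(totals[ord]),
                    stringsAsFactors = FALSE)
  out$tied <- duplicated(out$total) | duplicated(out$total, fromLast = TRUE)
  out
}

#' Heatmap matrix of percent differences for significant contrasts
#'
#' Rows are group pairs, columns parameters (the 20 symptoms, or the
#' unordered co-occurrence slots); a cell holds the symmetric percent
#' difference (in [-200, 200]) where the contrast is significant and is NA
#' otherwise, so the emptiness pattern equals the significance pattern.
#'
#' @param contrasts An [mnm_contrasts()].
#' @param kind \code{"intercept"} or \code{"edge"}.
#' @param alpha,criterion Passed to [significant_contrasts()].
#' @return An object of class \code{"heatmap_matrix"}: a list with
#'   \code{kind} and \code{values} (pairs x parameters matrix).
#' @export
heatmap_matrix <- function(contrasts, kind = c("intercept", "edge"),
                           alpha = 0.05, criterion = "auto") {
  kind <- match.arg(kind)
  sig <- significant_contrasts(contrasts, alpha = alpha,
                               criterion = criterion)
  sub <- contrasts[contrasts$type == kind, , drop = FALSE]
  sig <- sig[contrasts$type == kind]
  pairs <- unique(paste(sub$group_a, sub$group_b, sep = " vs "))
  params <- unique(sub$param)
  values <- matrix(NA_real_, length(pairs), length(params),
                   dimnames = list(pairs, params))
  pr <- paste(sub$group_a, sub$group_b, sep = " vs ")
  keep <- which(sig)
  values[cbind(match(pr[keep], pairs), match(sub$param[keep], params))] <-
    sub$percent_diff[keep]
  structure(list(kind = kind, values = values), class = "heatmap_matrix")
}

#' @export
print.heatmap_matrix <- function(x, ...) {
  cat("Heatmap matrix (", x$kind, "): ", nrow(x$values), " group pairs x ",
      ncol(x$values), " parameters, ", sum(!is.na(x$values)),
      " significant cells\n", sep = "")
  invisible(x)
}

#' Plot a heatmap matrix of significant percent differences
#'
#' @param x A [heatmap_matrix()].
#' @param ... Passed to [graphics::image()].
#' @return \code{x}, invisibly.
#' @export
plot.heatmap_matrix <- function(x, ...) {
  V <- x$values
  cols <- grDevices::colorRampPalette(c("#2166AC", "white", "#B2182B"))(101)
  graphics::image(seq_len(ncol(V)), seq_len(nrow(V)), t(V[rev(seq_len(nrow(V))), ,
                  drop = FALSE]), zlim = c(-200, 200), col = cols,
                  axes = FALSE, xlab = "", ylab = "",
                  main = paste("Percent differences:", x$kind), ...)
  graphics::axis(1, at = seq_len(ncol(V)), labels = colnames(V), las = 2,
                 cex.axis = 0.5)
  graphics::axis(2, at = seq_len(nrow(V)), labels = rev(rownames(V)), las = 2,
                 cex.axis = 0.6)
  invisible(x)
}

#' Export a heatmap matrix as long-format CSV
#'
#' @param hm A [heatmap_matrix()].
#' @param path CSV path.
#' @return \code{path}, invisibly.
#' @export
write_heatmap_csv <- function(hm, path) {
  stopifnot(inherits(hm, "heatmap_matrix"))
  idx <- which(!is.na(hm$values), arr.ind = TRUE)
  out <- data.frame(pair = rownames(hm$values)[idx[, 1]],
                    param = colnames(hm$values)[idx[, 2]],
                    percent_diff = hm$values[idx], stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Per-group descriptive statistics
#'
#' For every group and for the overall sample: n, percent of total, counts
#' and percents for gender (coded 0/1; percents always computed from the
#' counts), age mean (SD), and each item's mean (SD).
#'
#' @param cohort An \code{mnm_cohort}.
#' @return A data frame with one row per group plus an \code{Overall} row.
#' @export
demographics_table <- function(cohort) {
  stopifnot(inherits(cohort, "mnm_cohort"))
  panel <- cohort_panel(cohort)
  blocks <- c(split(seq_len(nrow(cohort)), cohort$group),
              list(Overall = seq_len(nrow(cohort))))
  total <- nrow(cohort)
  rows <- lapply(names(blocks), function(g) {
    sub <- cohort[blocks[[g]], , drop = FALSE]
    n <- nrow(sub)
    row <- data.frame(group = g, n = n, percent = 100 * n / total,
                      n_gender1 = sum(sub$gender == 1),
                      pct_gender1 = 100 * mean(sub$gender == 1),
                      n_gender0 = sum(sub$gender == 0),
                      pct_gender0 = 100 * mean(sub$gender == 0),
                      age_mean = mean(sub$age), age_sd = stats::sd(sub$age),
                      stringsAsFactors = FALSE)
    for (it in panel$item) {
      row[[paste0(it, "_mean")]] <- mean(sub[[it]])
      row[[paste0(it, "_sd")]] <- stats::sd(sub[[it]])
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Render a proportion table as Markdown
#'
#' Proportions rounded to 2 decimals, matching the usual reporting style;
#' full precision stays in the object and its CSV export.
#'
#' @param x A [proportion_table()].
#' @return Character vector of Markdown lines.
#' @export
format_markdown <- function(x) {
  stopifnot(inherits(x, "proportion_table"))
  M <- round(x$proportions, 2)
  g <- x$groups
  lines <- c(paste0("| | ", paste(g, collapse = " | "), " |"),
             paste0("|", paste(rep("---", length(g) + 1), collapse = "|"), "|"))
  for (i in seq_along(g)) {
    vals <- ifelse(is.na(M[i, ]), "", format(M[i, ]))
    lines <- c(lines, paste0("| ", g[i], " | ",
                             paste(vals, collapse = " | "), " |"))
  }
  lines
}
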