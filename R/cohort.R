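#' Draw a synthetic cohort from a ground truth
#'
#' Per group, item scores are drawn from the multivariate Gaussian whose
#' precision matrix is implied by that group's partial-association matrix,
#' with person-level means \code{base_mean + group shift + covariate
#' contributions}. Age is uniform on [18, 80] (standardized internally by
#' the distribution's own mean and SD before entering the mean model);
#' gender is Bernoulli(0.65), coded 0/1. With \code{ordinal = TRUE} each
#' item is rounded and clipped to its panel range.
#'
#' @param truth A [build_truth()] object.
#' @param group_sizes Integer vector, one size per group (all >= 1).
#' @param ordinal Round and clip items to their panel ranges. Default
#'   \code{TRUE}.
#' @param seed Integer seed; identical seeds and configurations give
#'   bit-identical cohorts.
#' @return An object of class \code{"mnm_cohort"}: a data frame with the 20
#'   item columns in panel order, then \code{group} (factor), \code{age},
#'   \code{gender}; complete-case by construction. The panel is attached as
#'   attribute \code{"panel"}.
#' @examples
#' tr <- build_truth(G = 2, seed = 1)
#' co <- sample_cohort(tr, group_sizes = c(100, 80), seed = 2)
#' table(co$group)
#' @export
sample_cohort <- function(truth, group_sizes, ordinal = TRUE, seed = 1L) {
  stopifnot(inherits(truth, "mnm_truth"))
  G <- length(truth$groups)
  if (length(group_sizes) != G) stop("need one group size per group")
  group_sizes <- as.integer(group_sizes)
  if (any(group_sizes < 1L)) stop("all group sizes must be >= 1")
  panel <- truth$panel
  p <- nrow(panel)
  set.seed(as.integer(seed))
  age_mean <- 49; age_sd <- (80 - 18) / sqrt(12)
  blocks <- vector("list", G)
  for (g in seq_len(G)) {
    n <- group_sizes[g]
    Omega <- truth_precision(truth, g)
    ev <- min(eigen(Omega, symmetric = TRUE, only.values = TRUE)$values)
    if (ev <= 0) stop("group precision matrix not positive definite")
    Sigma <- solve(Omega)
    R <- chol(Sigma)
    age <- stats::runif(n, 18, 80)
    gender <- stats::rbinom(n, 1L, 0.65)
    mu <- matrix(truth_means(truth, g), n, p, byrow = TRUE) +
      outer((age - age_mean) / age_sd, truth$covariate_effects["age", ]) +
      outer(gender, truth$covariate_effects["gender", ])
    X <- mu + matrix(stats::rnorm(n * p), n, p) %*% R
    if (ordinal) {
      X <- round(X)
      X <- pmax(X, matrix(panel$min, n, p, byrow = TRUE))
      X <- pmin(X, matrix(panel$max, n, p, byrow = TRUE))
    }
    colnames(X) <- panel$item
    blocks[[g]] <- data.frame(X, group = truth$groups[g], age = age,
                              gender = gender, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out$group <- factor(out$group, levels = truth$groups)
  as_cohort(out, panel = panel)
}

#' Mark and validate a data frame as a cohort table
#'
#' Checks the cohort contract: the 20 panel item columns plus \code{group},
#' \code{age} and \code{gender}; no missing values (complete-case); at
#' least two groups present.
#'
#' @param data A data frame.
#' @param panel Symptom panel the item columns must match.
#' @param check_ranges Also require every item score to lie within its
#'   panel range (use for ordinal-mode data). Default \code{FALSE}.
#' @return The validated data frame with class \code{"mnm_cohort"}.
#' @export
as_cohort <- function(data, panel = symptom_panel(), check_ranges = FALSE) {
  stopifnot_panel(panel)
  need <- c(panel$item, "group", "age", "gender")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols))
    stop("cohort is missing columns: ", paste(missing_cols, collapse = ", "))
  data <- data[, need]
  if (anyNA(data)) stop("cohort contains missing values; complete-case data required")
  if (!is.factor(data$group)) data$group <- factor(data$group)
  data$group <- droplevels(data$group)
  if (nlevels(data$group) < 2L) stop("cohort must contain at least 2 groups")
  if (!all(data$gender %in% c(0, 1))) stop("gender must be coded 0/1")
  if (check_ranges) {
    for (j in seq_len(nrow(panel))) {
      v <- data[[panel$item[j]]]
      if (any(v < panel$min[j] | v > panel$max[j]))
        stop("item ", panel$item[j], " has scores outside [",
             panel$min[j], ", ", panel$max[j], "]")
    }
  }
  attr(data, "panel") <- panel
  class(data) <- unique(c("mnm_cohort", class(data)))
  data
}

cohort_panel <- function(cohort) {
  p <- attr(cohort, "panel")
  if (is.null(p)) p <- symptom_panel()
  p
}

#' @export
print.mnm_cohort <- function(x, ...) {
  cat("Symptom cohort:", nrow(x), "persons,", nlevels(x$group), "groups\n")
  print(table(group = x$group))
  invisible(x)
}

#' Shuffle group labels across rows
#'
#' Builds one permutation-null replicate: group labels are permuted
#' uniformly at random across persons while item scores and covariates stay
#' attached to their rows, so the group-size multiset is preserved exactly
#' and any covariate-group structure is broken.
#'
#' @param cohort An \code{mnm_cohort}.
#' @param seed Integer seed.
#' @return The cohort with permuted \code{group} column.
#' @examples
#' tr <- build_truth(G = 2, seed = 1)
#' co <- sample_cohort(tr, c(50, 50), seed = 1)
#' pe <- permute_labels(co, seed = 3)
#' identical(sort(table(co$group)), sort(table(pe$group)))
#' @export
permute_labels <- function(cohort, seed = 1L) {
  stopifnot(inherits(cohort, "mnm_cohort"))
  set.seed(as.integer(seed))
  cohort$group <- cohort$group[sample.int(nrow(cohort))]
  cohort
}

#' Write a cohort to CSV
#'
#' Header row: the 20 item columns in panel order, then \code{group},
#' \code{age}, \code{gender}; UTF-8, comma-separated.
#'
#' @param cohort An \code{mnm_cohort}.
#' @param path File path.
#' @return \code{path}, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(inherits(cohort, "mnm_cohort"))
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Load a cohort from CSV with complete-case filtering
#'
#' Reads a person-level CSV whose header must contain every panel item plus
#' \code{group}, \code{age} and \code{gender}. Rows with any missing item,
#' group, age or gender value are dropped (complete-case rule) and the drop
#' count is reported; item scores outside their panel range are reported
#' per item.
#'
#' @param path CSV file path.
#' @param panel Symptom panel defining expected items and ranges.
#' @param verbose Print drop counts and range-violation reports. Default
#'   \code{TRUE}.
#' @return An \code{mnm_cohort} with attributes \code{"n_dropped"} (rows
#'   removed by complete-case filtering) and \code{"range_violations"}
#'   (named count per item, possibly empty).
#' @export
load_cohort_csv <- function(path, panel = symptom_panel(), verbose = TRUE) {
  stopifnot_panel(panel)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (anyDuplicated(names(raw)))
    stop("duplicate column header(s): ",
         paste(unique(names(raw)[duplicated(names(raw))]), collapse = ", "))
  need <- c(panel$item, "group", "age", "gender")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stop("header mismatch; missing columns: ",
         paste(missing_cols, collapse = ", "))
  raw <- raw[, need]
  keep <- stats::complete.cases(raw) & raw$group != ""
  n_dropped <- sum(!keep)
  raw <- raw[keep, , drop = FALSE]
  if (nrow(raw) == 0L) stop("no complete-case rows remain after filtering")
  violations <- integer(0)
  for (j in seq_len(nrow(panel))) {
    v <- raw[[panel$item[j]]]
    bad <- sum(v < panel$min[j] | v > panel$max[j])
    if (bad > 0) violations[panel$item[j]] <- bad
  }
  if (verbose) {
    message("load_cohort_csv: dropped ", n_dropped,
            " incomplete row(s); retained ", nrow(raw))
    if (length(violations))
      message("range violations: ",
              paste(names(violations), violations, sep = "=", collapse = ", "))
  }
  out <- as_cohort(raw, panel = panel)
  attr(out, "n_dropped") <- n_dropped
  attr(out, "range_violations") <- violations
  out
}
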