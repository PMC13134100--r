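#' Construct a ground-truth moderated network
#'
#' Builds the data-generating truth for synthetic cohorts: a base sparse
#' partial-association network over the 20 panel items, group-specific
#' intercept (mean) shifts and edge shifts planted on uniformly sampled
#' (group pair, parameter) slots, and linear covariate effects.  Every
#' group's implied precision matrix is made positive definite by a single
#' deterministic diagonal-ridge repair shared across groups, so realized
#' partial associations in all groups are the configured values divided by
#' one common factor \code{1 + ridge}; the stored matrices and the planted
#' registry always hold the realized (post-repair) values.
#'
#' @param G Number of groups (>= 2). Labels are \code{LETTERS[1:G]}.
#' @param n_planted_mean Number of planted intercept (mean) differences.
#' @param n_planted_edge Number of planted edge (partial association)
#'   differences.
#' @param effect_mean Magnitude of each planted mean shift, in item SD units
#'   (the generator's item variances are ~1).
#' @param effect_edge Magnitude of each planted partial-association shift.
#' @param density Fraction of the 190 possible item pairs carrying a base
#'   edge, in (0, 1]. Default 0.15.
#' @param seed Integer seed; the construction is deterministic given it.
#' @param base_weight_range Range of absolute base edge weights (partial
#'   associations), signs random. Default \code{c(0.1, 0.25)}.
#' @param covariate_effect_range Covariate slopes on item means are drawn
#'   uniformly from \code{[-r, r]} with \code{r = covariate_effect_range}.
#'   Default 0.15.
#' @param eig_floor Minimum eigenvalue enforced for every group's precision
#'   matrix. Default 0.05.
#' @param max_ridge Largest acceptable diagonal ridge; a configuration
#'   needing more is rejected as infeasible. Default 1.
#' @param panel Symptom panel, see [symptom_panel()].
#'
#' @details Each planted mean difference occupies a distinct item and each
#' planted edge difference a distinct item pair; the shift is applied to the
#' first group of the sampled pair, so the designated slot carries a
#' difference of exactly the configured magnitude. Because a shift on one
#' group also moves that group away from every third group, the full set of
#' implied pairwise differences (returned by [planted_differences()]) is a
#' superset of the designated registry.
#'
#' @return An object of class \code{"mnm_truth"}: a list with elements
#'   \code{groups}, \code{base_mean}, \code{group_mean_shift} (G x 20),
#'   \code{base_partial} (20 x 20, realized), \code{group_edge_shift}
#'   (G x 20 x 20, realized), \code{covariate_effects} (2 x 20, rows age and
#'   gender), \code{planted_registry} (data frame of designated slots),
#'   \code{ridge}, and \code{panel}.
#' @examples
#' tr <- build_truth(G = 3, n_planted_mean = 2, n_planted_edge = 1,
#'                   effect_mean = 0.5, effect_edge = 0.2, seed = 1)
#' tr$planted_registry
#' @seealso [sample_cohort()], [planted_differences()]
#' @export
build_truth <- function(G, n_planted_mean = 0L, n_planted_edge = 0L,
                        effect_mean = 0, effect_edge = 0, density = 0.15,
                        seed = 1L, base_weight_range = c(0.1, 0.25),
                        covariate_effect_range = 0.15, eig_floor = 0.05,
                        max_ridge = 1, panel = symptom_panel()) {
  stopifnot_panel(panel)
  if (G < 2) stop("G must be >= 2")
  if (density <= 0 || density > 1) stop("density must be in (0, 1]")
  if (effect_mean < 0 || effect_edge < 0) stop("effect magnitudes must be >= 0")
  p <- nrow(panel)
  items <- panel$item
  groups <- LETTERS[seq_len(G)]
  set.seed(as.integer(seed))

  # base means at instrument midpoint-ish levels (item SDs are ~1)
  base_mean <- ifelse(panel$instrument == "functioning", 4, 1.6)
  names(base_mean) <- items

  # base sparse partial-association network
  ut <- which(upper.tri(matrix(0, p, p)))
  K <- max(1L, round(density * length(ut)))
  slots <- sample(ut, K)
  base_partial <- matrix(0, p, p, dimnames = list(items, items))
  w <- stats::runif(K, base_weight_range[1], base_weight_range[2]) *
    sample(c(-1, 1), K, replace = TRUE)
  base_partial[slots] <- w
  base_partial <- base_partial + t(base_partial)

  group_mean_shift <- matrix(0, G, p, dimnames = list(groups, items))
  group_edge_shift <- array(0, c(G, p, p),
                            dimnames = list(groups, items, items))
  pairs <- utils::combn(groups, 2)
  registry <- list()

  if (n_planted_mean > 0) {
    if (n_planted_mean > p) stop("at most one planted mean shift per item")
    mitems <- sample(items, n_planted_mean)
    for (k in seq_len(n_planted_mean)) {
      pr <- pairs[, sample(ncol(pairs), 1L)]
      sgn <- sample(c(-1, 1), 1L)
      group_mean_shift[pr[1], mitems[k]] <- sgn * effect_mean
      registry[[length(registry) + 1L]] <- data.frame(
        group_a = pr[1], group_b = pr[2], type = "intercept",
        param = mitems[k], difference = -sgn * effect_mean,
        stringsAsFactors = FALSE)
    }
  }
  if (n_planted_edge > 0) {
    if (n_planted_edge > length(ut)) stop("too many planted edge shifts")
    eslots <- sample(ut, n_planted_edge)
    for (k in seq_len(n_planted_edge)) {
      pr <- pairs[, sample(ncol(pairs), 1L)]
      sgn <- sample(c(-1, 1), 1L)
      idx <- arrayInd(eslots[k], c(p, p))
      s <- idx[1]; t <- idx[2]
      g <- match(pr[1], groups)
      group_edge_shift[g, s, t] <- group_edge_shift[g, s, t] + sgn * effect_edge
      group_edge_shift[g, t, s] <- group_edge_shift[g, s, t]
      registry[[length(registry) + 1L]] <- data.frame(
        group_a = pr[1], group_b = pr[2], type = "edge",
        param = paste(items[s], items[t], sep = "--"),
        difference = -sgn * effect_edge, stringsAsFactors = FALSE)
    }
  }

  # positive-definiteness repair: one common diagonal ridge
  min_eig <- Inf
  for (g in seq_len(G)) {
    P <- base_partial + group_edge_shift[g, , ]
    min_eig <- min(min_eig, min(eigen(diag(p) - P, symmetric = TRUE,
                                      only.values = TRUE)$values))
  }
  ridge <- if (min_eig < eig_floor) eig_floor - min_eig else 0
  if (ridge > max_ridge)
    stop("infeasible configuration: positive-definiteness repair needs ridge ",
         format(ridge, digits = 3), " > max_ridge ", max_ridge)
  scale <- 1 / (1 + ridge)
  base_partial <- base_partial * scale
  group_edge_shift <- group_edge_shift * scale
  registry <- if (length(registry)) do.call(rbind, registry) else
    data.frame(group_a = character(), group_b = character(),
               type = character(), param = character(),
               difference = numeric(), stringsAsFactors = FALSE)
  registry$difference[registry$type == "edge"] <-
    registry$difference[registry$type == "edge"] * scale

  covariate_effects <- matrix(
    stats::runif(2 * p, -covariate_effect_range, covariate_effect_range),
    2, p, dimnames = list(c("age", "gender"), items))

  structure(list(groups = groups, base_mean = base_mean,
                 group_mean_shift = group_mean_shift,
                 base_partial = base_partial,
                 group_edge_shift = group_edge_shift,
                 covariate_effects = covariate_effects,
                 planted_registry = registry, ridge = ridge,
                 eig_floor = eig_floor, panel = panel, seed = as.integer(seed)),
            class = "mnm_truth")
}

#' @export
print.mnm_truth <- function(x, ...) {
  cat("Ground-truth moderated network\n")
  cat("  groups      :", paste(x$groups, collapse = ", "), "\n")
  cat("  base edges  :", sum(x$base_partial[upper.tri(x$base_partial)] != 0),
      "of", choose(nrow(x$panel), 2), "\n")
  cat("  planted     :", sum(x$planted_registry$type == "intercept"),
      "intercept,", sum(x$planted_registry$type == "edge"), "edge slots\n")
  cat("  PD ridge    :", format(x$ridge, digits = 4), "\n")
  invisible(x)
}

# group g's partial-association matrix and precision matrix
truth_partials <- function(truth, g) {
  gi <- if (is.character(g)) match(g, truth$groups) else g
  truth$base_partial + truth$group_edge_shift[gi, , ]
}

truth_precision <- function(truth, g) {
  P <- truth_partials(truth, g)
  (diag(nrow(P)) - P) * (1 + truth$ridge)
}

truth_means <- function(truth, g) {
  gi <- if (is.character(g)) match(g, truth$groups) else g
  truth$base_mean + truth$group_mean_shift[gi, ]
}

#' Enumerate all true pairwise group differences
#'
#' Lists, for every unordered group pair, every nonzero true intercept and
#' edge difference implied by the truth's group shifts — both the designated
#' planted slots and the collateral differences a shift on one group creates
#' with every third group. This is the recovery oracle for detection tests.
#'
#' @param truth An [build_truth()] object.
#' @param tol Differences below this magnitude count as zero.
#' @return A data frame with columns \code{group_a}, \code{group_b} (with
#'   \code{a} before \code{b} in group order), \code{type}
#'   (\code{"intercept"} or \code{"edge"}), \code{param}, and
#'   \code{difference}, the true value in group \code{b} minus group
#'   \code{a} (matching the sign convention of [pairwise_contrast()]).
#' @examples
#' tr <- build_truth(G = 3, n_planted_mean = 1, effect_mean = 0.5, seed = 2)
#' planted_differences(tr)
#' @export
planted_differences <- function(truth, tol = 1e-12) {
  stopifnot(inherits(truth, "mnm_truth"))
  items <- truth$panel$item
  p <- length(items)
  out <- list()
  pairs <- utils::combn(truth$groups, 2)
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1, k]; b <- pairs[2, k]
    dm <- truth_means(truth, b) - truth_means(truth, a)
    nz <- which(abs(dm) > tol)
    if (length(nz))
      out[[length(out) + 1L]] <- data.frame(
        group_a = a, group_b = b, type = "intercept", param = items[nz],
        difference = unname(dm[nz]), stringsAsFactors = FALSE)
    de <- truth_partials(truth, b) - truth_partials(truth, a)
    idx <- which(upper.tri(de) & abs(de) > tol, arr.ind = TRUE)
    if (nrow(idx))
      out[[length(out) + 1L]] <- data.frame(
        group_a = a, group_b = b, type = "edge",
        param = paste(items[idx[, 1]], items[idx[, 2]], sep = "--"),
        difference = de[idx], stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(group_a = character(), group_b = character(),
                      type = character(), param = character(),
                      difference = numeric(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Serialize a ground truth to JSON
#'
#' @param truth An [build_truth()] object.
#' @param path File path to write.
#' @return \code{path}, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "mnm_truth"))
  obj <- list(groups = truth$groups, base_mean = truth$base_mean,
              group_mean_shift = truth$group_mean_shift,
              base_partial = truth$base_partial,
              group_edge_shift = truth$group_edge_shift,
              covariate_effects = truth$covariate_effects,
              planted_registry = truth$planted_registry,
              ridge = truth$ridge, seed = truth$seed)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
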