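#' Build the nodewise design matrix for one item
#'
#' For a target node, the response is that item's (z-scored) score vector
#' and the predictors are, in order: the 19 other items, the G-1 group
#' dummies (reference group omitted), all 19 x (G-1) item-by-dummy
#' interaction columns, and the two covariates (age, gender).  Items and
#' age are z-scored cohort-wide; dummies and gender stay 0/1 and
#' interactions are z-scored item times dummy, so coefficients for group
#' terms are directly comparable across reference rotations.  With
#' \code{standardize = TRUE} every column (and the response) is additionally
#' centred and scaled to unit variance, constant columns left at zero.
#'
#' @param cohort An \code{mnm_cohort}.
#' @param node Target item: index in 1..20 or item name.
#' @param reference_group Group label used as the dummy-coding reference.
#' @param standardize Centre/scale all design columns and the response.
#'   Default \code{FALSE} (the model-fitting layer standardizes internally
#'   instead and reports coefficients on these column scales).
#' @param scaling Optional list of item/age centres and scales (as stored in
#'   a fitted \code{mnm} object) to z-score against instead of this
#'   cohort's own moments; used when building designs for new data.
#' @return A list with \code{x} (matrix, named columns), \code{y}
#'   (response), \code{roles} (character vector: \code{"node"},
#'   \code{"dummy"}, \code{"interaction"}, \code{"covariate"}), and
#'   \code{node}, \code{reference_group}.
#' @examples
#' tr <- build_truth(G = 2, seed = 1)
#' co <- sample_cohort(tr, c(60, 60), seed = 1)
#' d <- design_matrix(co, node = 1, reference_group = "A")
#' ncol(d$x)  # 19 + 1 + 19 + 2 = 41
#' @export
design_matrix <- function(cohort, node, reference_group,
                          standardize = FALSE, scaling = NULL) {
  stopifnot(inherits(cohort, "mnm_cohort"))
  panel <- cohort_panel(cohort)
  items <- panel$item
  if (is.character(node)) node <- match(node, items)
  if (is.na(node) || node < 1 || node > length(items))
    stop("node must identify one of the panel items")
  groups <- levels(cohort$group)
  if (!reference_group %in% groups)
    stop("reference group ", reference_group, " not present in cohort")
  if (any(table(cohort$group) < 2L))
    stop("every group needs at least 2 members")

  z <- function(v, center = mean(v), scale = stats::sd(v)) {
    if (scale == 0) rep(0, length(v)) else (v - center) / scale
  }
  Z <- if (is.null(scaling)) {
    vapply(items, function(it) z(cohort[[it]]), numeric(nrow(cohort)))
  } else {
    vapply(seq_along(items), function(j)
      z(cohort[[items[j]]], scaling$item_center[j], scaling$item_scale[j]),
      numeric(nrow(cohort)))
  }
  colnames(Z) <- items
  y <- Z[, node]
  others <- items[-node]
  x_nodes <- Z[, others, drop = FALSE]

  nonref <- setdiff(groups, reference_group)
  x_dum <- vapply(nonref, function(g) as.numeric(cohort$group == g),
                  numeric(nrow(cohort)))
  colnames(x_dum) <- paste0("grp_", nonref)

  x_int <- matrix(0, nrow(cohort), length(others) * length(nonref))
  int_names <- character(ncol(x_int))
  k <- 0L
  for (g in nonref) {
    d <- as.numeric(cohort$group == g)
    for (it in others) {
      k <- k + 1L
      x_int[, k] <- Z[, it] * d
      int_names[k] <- paste0(it, ":grp_", g)
    }
  }
  colnames(x_int) <- int_names

  x_cov <- if (is.null(scaling)) {
    cbind(age = z(cohort$age), gender = as.numeric(cohort$gender))
  } else {
    cbind(age = z(cohort$age, scaling$age_center, scaling$age_scale),
          gender = as.numeric(cohort$gender))
  }
  x <- cbind(x_nodes, x_dum, x_int, x_cov)
  roles <- c(rep("node", ncol(x_nodes)), rep("dummy", ncol(x_dum)),
             rep("interaction", ncol(x_int)), rep("covariate", 2L))
  names(roles) <- colnames(x)

  if (standardize) {
    y <- z(y)
    x <- apply(x, 2, z)
  }
  list(x = x, y = y, roles = roles, node = items[node],
       reference_group = reference_group)
}
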