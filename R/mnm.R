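#' Fit a moderated network model
#'
#' Fits the full moderated network for a fixed reference group by running
#' one nodewise LASSO regression per panel item (disjoint pseudolikelihood)
#' and assembling the results: for each unordered item pair and each group,
#' the two directed estimates (t's coefficient in s's regression and s's in
#' t's) are combined by the settings' nodewise rule — \code{AND}: the edge
#' is present only when both are nonzero, with value their arithmetic mean;
#' \code{OR}: present when either is nonzero, with value the mean of the
#' nonzero entries.  Group-specific intercepts and edges are obtained by
#' adding each group's dummy and interaction coefficients to the
#' reference-level terms.
#'
#' Items are analysed as z-scored Gaussian nodes; coefficients are on the
#' standardized item scale and group intercepts on the standardized
#' response scale.
#'
#' @param cohort An \code{mnm_cohort} (complete-case, all 20 items).
#' @param reference_group Group label used as dummy-coding reference;
#'   defaults to the first group level.
#' @param settings An [mnm_settings()] object.
#' @return An object of class \code{"mnm"}: a list with
#'   \code{reference_group}, \code{groups}, \code{settings}, \code{nodes}
#'   (20 [fit_node()] objects), \code{group_intercepts} (G x 20),
#'   \code{group_edges} (G x 20 x 20 symmetric, zero diagonal),
#'   \code{edge_presence} (logical G x 20 x 20), \code{directed}
#'   (G x 20 x 20 array of directed group-level coefficients, row = response
#'   node), \code{scaling}, \code{n} and \code{panel}.
#' @examples
#' tr <- build_truth(G = 2, seed = 1)
#' co <- sample_cohort(tr, c(300, 300), seed = 1)
#' fit <- mnm(co, reference_group = "A")
#' fit
#' @seealso [rotate_references()], [mnm_settings()]
#' @export
mnm <- function(cohort, reference_group = levels(cohort$group)[1],
                settings = mnm_settings()) {
  stopifnot(inherits(cohort, "mnm_cohort"))
  panel <- cohort_panel(cohort)
  items <- panel$item
  p <- length(items)
  groups <- levels(cohort$group)
  G <- length(groups)
  if (!reference_group %in% groups)
    stop("reference group not present in cohort")

  nodes <- vector("list", p)
  names(nodes) <- items
  for (j in seq_len(p)) {
    d <- design_matrix(cohort, node = j, reference_group = reference_group)
    nodes[[j]] <- fit_node(d, settings = settings)
  }

  nonref <- setdiff(groups, reference_group)
  group_intercepts <- matrix(0, G, p, dimnames = list(groups, items))
  directed <- array(0, c(G, p, p), dimnames = list(groups, items, items))
  for (j in seq_len(p)) {
    cf <- nodes[[j]]$coefficients
    group_intercepts[, j] <- nodes[[j]]$intercept
    for (g in nonref)
      group_intercepts[g, j] <- group_intercepts[g, j] +
        cf[[paste0("grp_", g)]]
    for (t in items[-j]) {
      main <- cf[[t]]
      directed[, j, t] <- main
      for (g in nonref)
        directed[g, j, t] <- main + cf[[paste0(t, ":grp_", g)]]
    }
  }

  comb <- combine_directed(directed, settings$nodewise_rule)
  structure(list(reference_group = reference_group, groups = groups,
                 settings = settings, nodes = nodes,
                 group_intercepts = group_intercepts,
                 group_edges = comb$edges, edge_presence = comb$presence,
                 directed = directed,
                 scaling = cohort_scaling(cohort), n = nrow(cohort),
                 panel = panel, call = match.call()),
            class = "mnm")
}

# combine the two directed group-level coefficients per item pair
combine_directed <- function(directed, rule) {
  dn <- dimnames(directed)
  G <- dim(directed)[1]; p <- dim(directed)[2]
  edges <- array(0, dim(directed), dimnames = dn)
  presence <- array(FALSE, dim(directed), dimnames = dn)
  for (g in seq_len(G)) {
    A <- directed[g, , ]
    nzA <- abs(A) > .zero_tol
    both <- nzA & t(nzA)
    either <- nzA | t(nzA)
    if (rule == "AND") {
      val <- (A + t(A)) / 2
      val[!both] <- 0
      pres <- both
    } else {
      val <- (A + t(A)) / pmax(nzA + t(nzA), 1)
      val[!either] <- 0
      pres <- either
    }
    diag(val) <- 0; diag(pres) <- FALSE
    edges[g, , ] <- val
    presence[g, , ] <- pres
  }
  list(edges = edges, presence = presence)
}

cohort_scaling <- function(cohort) {
  panel <- cohort_panel(cohort)
  items <- panel$item
  list(item_center = vapply(items, function(it) mean(cohort[[it]]), 0),
       item_scale = vapply(items, function(it) stats::sd(cohort[[it]]), 0),
       age_center = mean(cohort$age), age_scale = stats::sd(cohort$age))
}

#' @export
print.mnm <- function(x, ...) {
  cat("Moderated network model (nodewise LASSO, EBIC gamma =",
      x$settings$gamma, ")\n")
  cat("  reference group :", x$reference_group, "of",
      paste(x$groups, collapse = ", "), "\n")
  cat("  n =", x$n, ",", length(x$nodes), "nodes\n")
  ec <- edge_counts(x)
  cat("  edges per group :", paste(names(ec), ec, sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
summary.mnm <- function(object, ...) {
  nodes <- object$nodes
  tab <- data.frame(node = names(nodes),
                    lambda = vapply(nodes, function(f) f$lambda, 0),
                    df = vapply(nodes, function(f) f$df, 0L),
                    ebic = vapply(nodes, function(f) f$ebic, 0),
                    rss = vapply(nodes, function(f) f$rss, 0),
                    row.names = NULL)
  out <- list(reference_group = object$reference_group,
              groups = object$groups, nodes = tab,
              edge_counts = edge_counts(object), n = object$n)
  class(out) <- "summary.mnm"
  out
}

#' @export
print.summary.mnm <- function(x, ...) {
  cat("Moderated network model summary (reference:", x$reference_group,
      ", n =", x$n, ")\n\nNodewise fits:\n")
  print(x$nodes, digits = 4)
  cat("\nEstimated edges per group (nodewise-rule combined):\n")
  print(x$edge_counts)
  invisible(x)
}

#' Per-group estimated edge counts of a fitted model
#'
#' @param fit An \code{mnm} object.
#' @return Named integer vector: the number of present (unordered) edges in
#'   each group's network.
#' @export
edge_counts <- function(fit) {
  stopifnot(inherits(fit, "mnm"))
  vapply(fit$groups, function(g) {
    M <- fit$edge_presence[g, , ]
    sum(M[upper.tri(M)])
  }, 0L)
}

#' @export
coef.mnm <- function(object, ...) {
  out <- lapply(names(object$nodes), function(nm) {
    f <- object$nodes[[nm]]
    data.frame(node = nm,
               predictor = c("(Intercept)", names(f$coefficients)),
               role = c("intercept", unname(f$roles)),
               estimate = c(f$intercept, unname(f$coefficients)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' @export
predict.mnm <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) stop("newdata (an mnm_cohort) is required")
  stopifnot(inherits(newdata, "mnm_cohort"))
  items <- object$panel$item
  sc <- object$scaling
  fitted <- matrix(NA_real_, nrow(newdata), length(items),
                   dimnames = list(NULL, items))
  for (j in seq_along(items)) {
    d <- design_matrix(newdata, node = j,
                       reference_group = object$reference_group,
                       scaling = sc)
    f <- object$nodes[[j]]
    fitted[, j] <- f$intercept + as.vector(d$x %*% f$coefficients)
  }
  fitted
}

#' @export
residuals.mnm <- function(object, newdata = NULL, cohort = newdata, ...) {
  if (is.null(cohort)) stop("the cohort the model was fit to is required")
  fitted <- predict(object, newdata = cohort)
  items <- object$panel$item
  sc <- object$scaling
  obs <- vapply(seq_along(items), function(j) {
    s <- sc$item_scale[j]
    if (s == 0) rep(0, nrow(cohort)) else
      (cohort[[items[j]]] - sc$item_center[j]) / s
  }, numeric(nrow(cohort)))
  colnames(obs) <- items
  obs - fitted
}

#' Plot a fitted group network as an edge-weight heatmap
#'
#' @param x An \code{mnm} object.
#' @param group Group whose network to draw; defaults to the reference.
#' @param ... Passed to [graphics::image()].
#' @return Invisibly, the plotted weight matrix.
#' @export
plot.mnm <- function(x, group = x$reference_group, ...) {
  M <- x$group_edges[group, , ]
  p <- ncol(M)
  lim <- max(abs(M), 1e-6)
  cols <- grDevices::colorRampPalette(c("#2166AC", "white", "#B2182B"))(101)
  graphics::image(seq_len(p), seq_len(p), t(M[p:1, ]),
                  zlim = c(-lim, lim), col = cols, axes = FALSE,
                  xlab = "", ylab = "",
                  main = paste("Partial-association network:", group), ...)
  graphics::axis(1, at = seq_len(p), labels = colnames(M), las = 2,
                 cex.axis = 0.6)
  graphics::axis(2, at = seq_len(p), labels = rev(rownames(M)), las = 2,
                 cex.axis = 0.6)
  invisible(M)
}

#' Export a fitted model's group networks as a weighted edge list
#'
#' One row per present (unordered) edge per group:
#' \code{nodeA,nodeB,weight,group}.
#'
#' @param fit An \code{mnm} object.
#' @param path Optional CSV path; when given the data frame is also written.
#' @return The edge-list data frame, invisibly when \code{path} is given.
#' @export
edge_list <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "mnm"))
  items <- fit$panel$item
  rows <- list()
  for (g in fit$groups) {
    pres <- fit$edge_presence[g, , ]
    idx <- which(upper.tri(pres) & pres, arr.ind = TRUE)
    if (nrow(idx))
      rows[[g]] <- data.frame(nodeA = items[idx[, 1]], nodeB = items[idx[, 2]],
                              weight = fit$group_edges[g, , ][idx],
                              group = g, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(nodeA = character(), nodeB = character(), weight = numeric(),
               group = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE)
    return(invisible(out))
  }
  out
}

#' Serialize a fitted model to JSON
#'
#' @param fit An \code{mnm} object.
#' @param path File path to write.
#' @return \code{path}, invisibly.
#' @export
write_mnm_json <- function(fit, path) {
  stopifnot(inherits(fit, "mnm"))
  obj <- list(reference_group = fit$reference_group, groups = fit$groups,
              settings = unclass(fit$settings), n = fit$n,
              group_intercepts = fit$group_intercepts,
              group_edges = fit$group_edges,
              edge_presence = fit$edge_presence,
              nodewise = lapply(fit$nodes, function(f)
                list(node = f$node, lambda = f$lambda, df = f$df,
                     ebic = f$ebic, intercept = f$intercept,
                     coefficients = as.list(f$coefficients))))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
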