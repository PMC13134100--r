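#' Assemble a pipeline run configuration
#'
#' Collects everything one end-to-end analysis needs: the cohort source
#' (either a synthetic-cohort specification or a CSV path), estimator and
#' permutation settings, the output directory, the master seed and the
#' verbosity.  Stage seeds are derived from the master seed by a fixed
#' counter scheme (cohort = seed + 1, truth = seed + 2, permutation b =
#' seed + 7919 b, all modulo 2^31 - 19), so stages can be rerun
#' independently.
#'
#' @param cohort Either a list describing a synthetic cohort (fields
#'   \code{G}, \code{group_sizes}, and optionally \code{n_planted_mean},
#'   \code{n_planted_edge}, \code{effect_mean}, \code{effect_edge},
#'   \code{density}, \code{ordinal}) or a single string: the path of a
#'   cohort CSV.
#' @param settings An [mnm_settings()] object.
#' @param psettings A [perm_settings()] object; set \code{B = 0} via
#'   \code{permute = FALSE} to skip permutation inference.
#' @param outdir Output directory (created if needed).
#' @param seed Master seed recorded in every output manifest.
#' @param permute Run the permutation stage. Default \code{TRUE}.
#' @param verbose Print per-stage progress.
#' @return A list of class \code{"run_config"}.
#' @export
run_config <- function(cohort, settings = mnm_settings(),
                       psettings = perm_settings(), outdir = tempfile("mnmrun"),
                       seed = 1L, permute = TRUE, verbose = TRUE) {
  if (is.character(cohort) && length(cohort) == 1L) {
    source <- list(kind = "csv", path = cohort)
  } else if (is.list(cohort)) {
    if (is.null(cohort$G) || is.null(cohort$group_sizes))
      stop("synthetic cohort spec needs G and group_sizes")
    source <- c(list(kind = "synthetic"), cohort)
  } else stop("cohort must be a CSV path or a synthetic spec list")
  stopifnot(inherits(settings, "mnm_settings"),
            inherits(psettings, "perm_settings"))
  structure(list(source = source, settings = settings, psettings = psettings,
                 outdir = outdir, seed = as.integer(seed),
                 permute = isTRUE(permute), verbose = isTRUE(verbose)),
            class = "run_config")
}

#' Read a run configuration from a YAML or JSON file
#'
#' Declarative counterpart of [run_config()]: the file may contain the
#' keys \code{cohort}, \code{settings}, \code{psettings}, \code{outdir},
#' \code{seed}, \code{permute}, \code{verbose}; arguments passed through
#' \code{...} override file values.
#'
#' @param path YAML (requires the yaml package) or JSON file.
#' @param ... Overrides, as for [run_config()].
#' @return A \code{"run_config"}.
#' @export
read_run_config <- function(path, ...) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the yaml package")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  over <- list(...)
  for (k in names(over)) raw[[k]] <- over[[k]]
  args <- list(cohort = raw$cohort)
  if (!is.null(raw$settings)) args$settings <- do.call(mnm_settings, raw$settings)
  if (!is.null(raw$psettings)) args$psettings <- do.call(perm_settings, raw$psettings)
  for (k in c("outdir", "seed", "permute", "verbose"))
    if (!is.null(raw[[k]])) args[[k]] <- raw[[k]]
  do.call(run_config, args)
}

stage_seed <- function(master, offset) {
  as.integer((as.numeric(master) + offset) %% 2147483629)
}

#' Run the full analysis pipeline
#'
#' Executes generate/load cohort, reference-rotation estimation, pairwise
#' contrasts, permutation inference (optional) and reporting, writing every
#' artifact (CSV tables, JSON manifests) under the configured output
#' directory.  The run is idempotent given the config and master seed; a
#' manifest listing every artifact with its MD5 hash, the seeds, settings
#' and per-stage wall times is written last.
#'
#' @param config A [run_config()] (or a path accepted by
#'   [read_run_config()]).
#' @return An object of class \code{"mnm_pipeline"}: a list with
#'   \code{cohort}, \code{truth} (synthetic runs only), \code{ensemble},
#'   \code{contrasts}, \code{null}, \code{tables}, \code{chisq},
#'   \code{manifest} and \code{outdir}.
#' @examples
#' \donttest{
#' cfg <- run_config(cohort = list(G = 3, group_sizes = c(150, 120, 100)),
#'                   psettings = perm_settings(B = 5, seed = 9),
#'                   seed = 9, verbose = FALSE)
#' run <- run_pipeline(cfg)
#' run$tables$intercept
#' }
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (config$verbose) message(...)
  timings <- c()
  clock <- function(stage, expr) {
    t0 <- Sys.time()
    out <- tryCatch(force(expr), error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
    timings[[stage]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    say(sprintf("stage %-12s %.1fs", stage, timings[[stage]]))
    out
  }
  art <- function(name) file.path(config$outdir, name)
  artifacts <- character(0)

  truth <- NULL
  cohort <- clock("cohort", {
    if (config$source$kind == "csv") {
      load_cohort_csv(config$source$path, verbose = config$verbose)
    } else {
      src <- config$source
      truth <- build_truth(
        G = src$G,
        n_planted_mean = src$n_planted_mean %||% 0L,
        n_planted_edge = src$n_planted_edge %||% 0L,
        effect_mean = src$effect_mean %||% 0,
        effect_edge = src$effect_edge %||% 0,
        density = src$density %||% 0.15,
        seed = stage_seed(config$seed, 2L))
      sample_cohort(truth, group_sizes = src$group_sizes,
                    ordinal = src$ordinal %||% TRUE,
                    seed = stage_seed(config$seed, 1L))
    }
  })
  write_cohort_csv(cohort, art("cohort.csv"))
  artifacts <- c(artifacts, "cohort.csv")
  if (!is.null(truth)) {
    write_truth_json(truth, art("truth.json"))
    artifacts <- c(artifacts, "truth.json")
  }

  ensemble <- clock("estimate", rotate_references(cohort, config$settings))
  for (g in ensemble$groups) {
    edge_list(ensemble$fits[[g]], art(paste0("edges_ref_", g, ".csv")))
    artifacts <- c(artifacts, paste0("edges_ref_", g, ".csv"))
  }

  contrasts <- clock("contrast", mnm_contrasts(ensemble))

  null <- NULL
  if (config$permute) {
    null <- clock("permute", null_distribution(
      cohort, settings = config$settings, psettings = config$psettings,
      verbose = config$verbose))
    contrasts <- attach_pvalues(contrasts, null)
    write_permutation_manifest(null, config$settings,
                               art("permutation_manifest.json"))
    utils::write.csv(attr(contrasts, "aggregate"),
                     art("aggregate_pvalues.csv"), row.names = FALSE)
    artifacts <- c(artifacts, "permutation_manifest.json",
                   "aggregate_pvalues.csv")
  }
  write_contrasts_csv(contrasts, art("contrasts.csv"))
  artifacts <- c(artifacts, "contrasts.csv")

  tables <- clock("report", {
    tb <- list(intercept = proportion_table(contrasts, "intercept"),
               edge = proportion_table(contrasts, "edge"),
               demographics = demographics_table(cohort))
    tb$ranking <- group_difference_ranking(tb$intercept)
    tb$heatmap_intercept <- heatmap_matrix(contrasts, "intercept")
    tb$heatmap_edge <- heatmap_matrix(contrasts, "edge")
    tb
  })
  utils::write.csv(tables$intercept$proportions,
                   art("proportions_intercept.csv"))
  utils::write.csv(tables$edge$proportions, art("proportions_edge.csv"))
  utils::write.csv(tables$demographics, art("demographics.csv"),
                   row.names = FALSE)
  utils::write.csv(tables$ranking, art("ranking.csv"), row.names = FALSE)
  write_heatmap_csv(tables$heatmap_intercept, art("heatmap_intercept.csv"))
  write_heatmap_csv(tables$heatmap_edge, art("heatmap_edge.csv"))
  writeLines(format_markdown(tables$intercept),
             art("proportions_intercept.md"))
  artifacts <- c(artifacts, "proportions_intercept.csv",
                 "proportions_edge.csv", "demographics.csv", "ranking.csv",
                 "heatmap_intercept.csv", "heatmap_edge.csv",
                 "proportions_intercept.md")

  chisq <- edge_count_chisq(ensemble)

  manifest <- list(
    master_seed = config$seed,
    stage_seeds = list(cohort = stage_seed(config$seed, 1L),
                       truth = stage_seed(config$seed, 2L),
                       permutation_master = config$psettings$seed),
    settings = unclass(config$settings),
    psettings = unclass(config$psettings),
    group_sizes = as.list(table(cohort$group)),
    selected_lambda = lapply(ensemble$fits, function(f)
      vapply(f$nodes, function(nd) nd$lambda, 0)),
    edge_count_chisq = chisq[c("statistic", "df", "p_value")],
    stage_seconds = as.list(timings),
    artifacts = as.list(tools::md5sum(file.path(config$outdir, artifacts))))
  jsonlite::write_json(manifest, art("manifest.json"), digits = NA,
                       auto_unbox = TRUE)

  structure(list(cohort = cohort, truth = truth, ensemble = ensemble,
                 contrasts = contrasts, null = null, tables = tables,
                 chisq = chisq, manifest = manifest, outdir = config$outdir),
            class = "mnm_pipeline")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.mnm_pipeline <- function(x, ...) {
  cat("Moderated-network pipeline run ->", x$outdir, "\n")
  print(x$tables$intercept)
  cat("\n")
  print(x$tables$edge)
  cat("\nEdge-count chi-square: statistic =",
      format(x$chisq$statistic, digits = 4), ", df =", x$chisq$df,
      ", p =", format(x$chisq$p_value, digits = 4), "\n")
  invisible(x)
}
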