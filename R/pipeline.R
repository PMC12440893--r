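#' Assemble a pipeline run configuration
#'
#' Collects every stage setting in one validated list. All protocol
#' constants are defaults here, never hard-coded downstream: split
#' fraction 0.8, split seed 2025, 5 folds, boosted preset (learning
#' rate 0.05, 200 estimators, depth 3), LOWESS span 0.3, bootstrap
#' level 0.95.
#'
#' @param input path to a panel CSV, or \code{NULL} when \code{panel}
#'   is supplied directly to [run_pipeline()].
#' @param output_dir directory for the report bundle; \code{NULL} keeps
#'   results in memory only.
#' @param directions named vector of \code{"positive"}/\code{"negative"}
#'   tags for the health indicator columns, or \code{NULL} when the
#'   panel already carries the outcome column.
#' @param outcome outcome column name (default \code{"HLI"}).
#' @param features feature column names; \code{NULL} selects every
#'   numeric column that is not an identifier, indicator or outcome.
#' @param families model families to benchmark.
#' @param primary_family family used for the explanation stages.
#' @param params per-family hyperparameter overrides.
#' @param train_fraction,seed,k split and cross-validation protocol.
#' @param search \code{NULL} for the reproduction preset, or
#'   \code{list(space =, budget =)} to tune the primary family by random
#'   search.
#' @param span,n_boot,level,threshold_top threshold-stage settings:
#'   LOWESS span, bootstrap resamples, confidence level, and how many
#'   top-ranked features get a threshold estimate.
#' @param pdp_top number of top-ranked features paired into two-way
#'   partial dependence surfaces.
#' @param pdp_grid_n quantile-grid size for partial dependence.
#' @param attribution_rows \code{"full"}, \code{"train"} or
#'   \code{"test"}: rows the attributions are computed on.
#' @return classed list \code{"pipeline_config"}.
#' @export
pipeline_config <- function(input = NULL, output_dir = NULL,
                            directions = NULL, outcome = "HLI",
                            features = NULL, families = model_families(),
                            primary_family = "xgboost", params = list(),
                            train_fraction = 0.8, seed = 2025L, k = 5L,
                            search = NULL, span = 0.3, n_boot = 1000L,
                            level = 0.95, threshold_top = 6L,
                            pdp_top = 4L, pdp_grid_n = 20L,
                            attribution_rows = c("full", "train", "test")) {
  attribution_rows <- match.arg(attribution_rows)
  stopifnot(train_fraction > 0, train_fraction < 1, span > 0, span <= 1,
            n_boot >= 1, level > 0, level < 1)
  structure(list(input = input, output_dir = output_dir,
                 directions = directions, outcome = outcome,
                 features = features, families = families,
                 primary_family = match.arg(primary_family, model_families()),
                 params = params, train_fraction = train_fraction,
                 seed = as.integer(seed), k = as.integer(k), search = search,
                 span = span, n_boot = as.integer(n_boot), level = level,
                 threshold_top = as.integer(threshold_top),
                 pdp_top = as.integer(pdp_top),
                 pdp_grid_n = as.integer(pdp_grid_n),
                 attribution_rows = attribution_rows),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the [pipeline_config()]
#'   arguments; \code{directions} may be a mapping from column name to
#'   tag.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$directions)) raw$directions <- unlist(raw$directions)
  do.call(pipeline_config, raw)
}

stage_log <- function(name, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- withCallingHandlers(
    tryCatch(force(expr), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)),
    warning = function(w) {
      message("  [", name, "] warning: ", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  message(sprintf("  [%s] done in %.2fs", name, proc.time()[["elapsed"]] - t0))
  res
}

#' Run the full analysis pipeline
#'
#' End-to-end, seeded, logged run: load the panel, construct the
#' composite index when direction tags are given, benchmark the model
#' families on the seeded split, explain the primary model with
#' Shapley attributions and importance shares, estimate zero-crossing
#' thresholds with bootstrap confidence intervals for the top-ranked
#' features, compute two-way partial dependence surfaces for the
#' leading pairs, and (optionally) write the bundle as CSV/JSON files
#' plus a manifest of every seed and setting. Identical configurations
#' produce identical bundles.
#'
#' @param config a [pipeline_config()] (or path to a YAML file).
#' @param panel optional data frame overriding \code{config$input}.
#' @return invisible list (the report bundle) with elements \code{hli},
#'   \code{benchmark}, \code{attribution}, \code{importance},
#'   \code{thresholds}, \code{pdp}, \code{manifest}.
#' @export
run_pipeline <- function(config, panel = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config")) stop("`config` must be a pipeline_config")
  if (is.null(panel)) {
    if (is.null(config$input)) stop("no panel: set config$input or pass `panel`")
    panel <- stage_log("load", read_panel_csv(config$input))
  }
  hli <- NULL
  if (!is.null(config$directions)) {
    miss <- setdiff(names(config$directions), names(panel))
    if (length(miss))
      stop("direction tag(s) name column(s) missing from the panel: ",
           paste(miss, collapse = ", "))
    hli <- stage_log("build-index",
                     build_hli(panel, config$directions, column = config$outcome))
    panel <- hli$panel
  }
  if (!config$outcome %in% names(panel))
    stop("outcome column '", config$outcome, "' missing and no direction tags given")
  features <- config$features
  if (is.null(features)) {
    num <- names(panel)[vapply(panel, is.numeric, logical(1))]
    features <- setdiff(num, c(config$outcome, "year", "province",
                               names(config$directions)))
  }
  miss <- setdiff(features, names(panel))
  if (length(miss)) stop("feature column(s) missing: ", paste(miss, collapse = ", "))
  fml <- stats::as.formula(paste(config$outcome, "~",
                                 paste(sprintf("`%s`", features), collapse = "+")))
  params <- config$params
  if (!is.null(config$search)) {
    tuned <- stage_log("random-search", {
      sp <- split_panel(panel, config$train_fraction, config$seed)
      random_search(sp$train, fml, config$primary_family,
                    space = config$search$space,
                    budget = config$search$budget %||% 20L,
                    k = config$k, seed = config$seed)
    })
    params[[config$primary_family]] <- tuned$best_params
  }
  bench <- stage_log("benchmark",
    run_benchmark(panel, fml, families = config$families, params = params,
                  train_fraction = config$train_fraction, seed = config$seed,
                  k = config$k))
  primary <- bench$models[[config$primary_family]]
  if (is.null(primary)) stop("primary family '", config$primary_family,
                             "' is not among the fitted models")
  rows <- switch(config$attribution_rows,
                 full = panel, train = bench$split$train, test = bench$split$test)
  attr_mat <- stage_log("attribution",
    compute_attributions(primary, rows, seed = config$seed))
  importance <- stage_log("importance", importance_shares(attr_mat))
  top_thr <- utils::head(importance$feature, config$threshold_top)
  thresholds <- stage_log("thresholds", {
    out <- list()
    for (f in top_thr) {
      sc <- attribution_scatter(attr_mat, f)
      out[[f]] <- tryCatch(
        bootstrap_threshold(sc, span = config$span, n_boot = config$n_boot,
                            seed = config$seed, level = config$level),
        error = function(e) {
          message("  [thresholds] ", f, ": ", conditionMessage(e))
          NULL
        })
    }
    out
  })
  top_pdp <- utils::head(importance$feature, config$pdp_top)
  pdp <- stage_log("interactions", {
    out <- list()
    if (length(top_pdp) >= 2L) {
      pairs <- utils::combn(top_pdp, 2L)
      for (j in seq_len(ncol(pairs)))
        out[[paste(pairs[, j], collapse = ":")]] <-
          pdp_2d(primary, rows, pairs[1L, j], pairs[2L, j],
                 grid_n = config$pdp_grid_n)
    }
    out
  })
  manifest <- list(
    package_version = as.character(utils::packageVersion("settlehealth")),
    n_rows = nrow(panel), features = features, outcome = config$outcome,
    families = config$families, primary_family = config$primary_family,
    train_fraction = config$train_fraction, seed = config$seed, k = config$k,
    span = config$span, n_boot = config$n_boot, level = config$level,
    attribution_rows = config$attribution_rows,
    attribution_engine = attr_mat$engine,
    threshold_features = top_thr, pdp_features = top_pdp)
  bundle <- list(hli = hli, benchmark = bench, attribution = attr_mat,
                 importance = importance, thresholds = thresholds, pdp = pdp,
                 manifest = manifest, panel = panel)
  if (!is.null(config$output_dir))
    stage_log("write-bundle", write_bundle(bundle, config$output_dir))
  invisible(bundle)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a pipeline report bundle to disk
#'
#' Emits plain-text artifacts: the panel with its index column, the
#' benchmark metrics table, importance shares and the attribution
#' matrix as CSV; thresholds, entropy weights, the attribution base
#' value and the run manifest as JSON; each partial dependence surface
#' as long-format CSV.
#'
#' @param bundle a [run_pipeline()] result.
#' @param dir output directory (created if needed).
#' @return invisible vector of written paths.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  w <- function(fn) { paths <<- c(paths, file.path(dir, fn)); file.path(dir, fn) }
  utils::write.csv(bundle$panel, w("panel_with_index.csv"), row.names = FALSE)
  utils::write.csv(bundle$benchmark$table, w("benchmark_metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$importance, w("importance_shares.csv"),
                   row.names = FALSE)
  utils::write.csv(cbind(as.data.frame(bundle$attribution$X),
                         stats::setNames(as.data.frame(bundle$attribution$phi),
                                         paste0("phi_", colnames(bundle$attribution$phi)))),
                   w("attributions.csv"), row.names = FALSE)
  jsonlite::write_json(list(base_value = bundle$attribution$phi0,
                            engine = bundle$attribution$engine),
                       w("attribution_base.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(bundle$hli))
    jsonlite::write_json(list(weights = as.list(bundle$hli$weights),
                              entropy = as.list(bundle$hli$entropy),
                              ideal = as.list(bundle$hli$ideal),
                              anti_ideal = as.list(bundle$hli$anti_ideal)),
                         w("index_weights.json"), auto_unbox = TRUE, digits = NA)
  thr <- lapply(bundle$thresholds, function(t) if (is.null(t)) NULL else
    list(point = t$point, ci_low = t$ci_low, ci_high = t$ci_high,
         direction = t$direction, n_boot = t$n_boot,
         unstable_fraction = t$unstable_fraction))
  jsonlite::write_json(thr, w("thresholds.json"), auto_unbox = TRUE, digits = NA)
  for (nm in names(bundle$pdp))
    utils::write.csv(as.data.frame(bundle$pdp[[nm]]),
                     w(paste0("pdp_", gsub("[^A-Za-z0-9]+", "_", nm), ".csv")),
                     row.names = FALSE)
  jsonlite::write_json(bundle$manifest, w("manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
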