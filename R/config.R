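#' Pipeline configuration
#'
#' Collects every tunable constant of the pipeline in one validated list.
#' Defaults are the study constants where one exists: location area
#' 5000 m^2, DASS stress z-score norms mean 11.19 / sd 8.25 (general
#' population aged 20-29), 70/30 train/test split, and 3-fold
#' cross-validation repeated 5 times.
#'
#' @param area_m2 area of one location node in square meters. Fixes within
#'   radius `sqrt(area_m2 / pi)` (about 39.9 m at the default) of a node's
#'   anchor belong to that node.
#' @param visit_gap_minutes a stay at one node is broken into two visits
#'   when consecutive fixes are more than this many minutes apart.
#' @param relevance_min_visits nodes with fewer visits are flagged
#'   irrelevant (the home node is never flagged).
#' @param percentile_method quantile rule for path-weight and step
#'   summaries; `"linear"` is linear interpolation between closest ranks
#'   (R quantile type 7).
#' @param zscore_mean,zscore_sd population norms for the doubled DASS
#'   stress raw score.
#' @param scheme stress discretization scheme: `"three_class"`,
#'   `"binary"` (mild/moderate excluded) or `"binary_polarized"`
#'   (severe requires z > 2.2; 0.5 <= z <= 2.2 excluded).
#' @param split_fraction training fraction of the train/test split.
#' @param cv_folds,cv_repeats cross-validation geometry used for tuning.
#' @param seed master seed; every stochastic stage derives a sub-stream
#'   seed from it via [derive_seed()].
#' @param timezone IANA timezone defining local midnight for day-level
#'   features (single cohort zone by default).
#' @param include_self_loops keep same-node transitions created by the
#'   visit gap rule as self-loop edges.
#' @param include_irrelevant keep irrelevant-flagged nodes when building
#'   the mobility multigraph.
#' @param accuracy_max_m optional ceiling on reported GPS accuracy;
#'   fixes above it are rejected. `Inf` (default) disables the filter.
#' @param dass_wave which DASS administration defines the outcome when a
#'   user has several waves.
#' @param threshold probability threshold for the confusion matrix.
#' @param grids named list of tuning-grid overrides per model family.
#' @return A validated list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(area_m2 = 5000,
                            visit_gap_minutes = 30,
                            relevance_min_visits = 2,
                            percentile_method = "linear",
                            zscore_mean = 11.19,
                            zscore_sd = 8.25,
                            scheme = c("three_class", "binary",
                                       "binary_polarized"),
                            split_fraction = 0.7,
                            cv_folds = 3,
                            cv_repeats = 5,
                            seed = 1L,
                            timezone = "Australia/Sydney",
                            include_self_loops = FALSE,
                            include_irrelevant = FALSE,
                            accuracy_max_m = Inf,
                            dass_wave = 1L,
                            threshold = 0.5,
                            grids = list()) {
  scheme <- match.arg(scheme)
  cfg <- list(
    area_m2 = area_m2,
    visit_gap_minutes = visit_gap_minutes,
    relevance_min_visits = relevance_min_visits,
    percentile_method = percentile_method,
    zscore_mean = zscore_mean,
    zscore_sd = zscore_sd,
    scheme = scheme,
    split_fraction = split_fraction,
    cv_folds = cv_folds,
    cv_repeats = cv_repeats,
    seed = as.integer(seed),
    timezone = timezone,
    include_self_loops = isTRUE(include_self_loops),
    include_irrelevant = isTRUE(include_irrelevant),
    accuracy_max_m = accuracy_max_m,
    dass_wave = as.integer(dass_wave),
    threshold = threshold,
    grids = grids
  )
  class(cfg) <- "pipeline_config"
  validate_config(cfg)
}

validate_config <- function(cfg) {
  for (nm in c("area_m2", "visit_gap_minutes", "relevance_min_visits",
               "zscore_sd", "cv_folds", "cv_repeats", "threshold")) {
    stopifnot_scalar_number(cfg[[nm]], nm)
  }
  stopifnot_scalar_number(cfg$zscore_mean, "zscore_mean", positive = FALSE)
  if (cfg$split_fraction <= 0 || cfg$split_fraction >= 1) {
    stop("`split_fraction` must lie in (0, 1)", call. = FALSE)
  }
  if (!cfg$percentile_method %in% "linear") {
    stop("unsupported percentile_method: ", cfg$percentile_method,
         call. = FALSE)
  }
  if (!cfg$timezone %in% OlsonNames()) {
    stop("unknown timezone: ", cfg$timezone, call. = FALSE)
  }
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys absent from the file keep their [pipeline_config()] defaults;
#' unknown keys are an error.
#'
#' @param path YAML file of key/value overrides.
#' @return A `"pipeline_config"` list.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  do.call(pipeline_config, raw)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (nm in setdiff(names(x), "grids")) {
    cat(sprintf("  %-22s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  if (length(x$grids)) {
    cat("  grid overrides:", paste(names(x$grids), collapse = ", "), "\n")
  }
  invisible(x)
}
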