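# End-to-end feature extraction: GPS + step streams -> per-user feature
# table (Stage 1, Stage 2, steps, engineered combination).

extract_features_user <- function(gps, steps, config) {
  tz <- config$timezone
  out <- list()
  if (!is.null(gps) && nrow(gps) > 0) {
    if (is.finite(config$accuracy_max_m)) {
      gps <- gps[is.na(gps$accuracy_m) | gps$accuracy_m <= config$accuracy_max_m, ,
                 drop = FALSE]
    }
    cl <- cluster_fixes(gps, config$area_m2)
    visits <- segment_visits(cl$assignment, config$visit_gap_minutes)
    nodes <- annotate_nodes(cl$nodes, visits, config$relevance_min_visits)
    n_days <- length(unique(local_date(gps$timestamp, tz)))
    s1 <- stage1_features(nodes, visits, n_days)
    mm <- build_mobility_matrix(visits, tz)
    g <- build_multigraph(mm, nodes,
                          include_irrelevant = config$include_irrelevant,
                          include_self_loops = config$include_self_loops)
    pw <- path_weight_features(g)
    vr <- visit_rate_features(mm, pw$n_relevant_places, n_days)
    vr$visits_per_day <- NULL # already emitted among the Stage-1 features
    out <- c(list(n_tracked_days = n_days), s1, pw, vr)
  } else {
    out <- list(n_tracked_days = NA_real_, n_places = NA_real_,
                visits_per_day = NA_real_, visits_per_place_per_day = NA_real_,
                mean_distance_m = NA_real_, max_distance_m = NA_real_,
                min_distance_m = NA_real_, n_relevant_places = NA_real_,
                n_paths = NA_real_, mean_path_weight = NA_real_,
                min_path_weight = NA_real_, max_path_weight = NA_real_,
                q75_path_weight = NA_real_, avg_node_visits_per_day = NA_real_)
  }
  sf <- if (!is.null(steps) && nrow(steps) > 0) {
    step_features(steps, tz)
  } else {
    list(step_q25 = NA_real_, step_q50 = NA_real_, step_q75 = NA_real_,
         step_min = NA_real_, step_max = NA_real_, step_mean = NA_real_)
  }
  c(out, sf)
}

#' Extract the per-user mobility feature table
#'
#' Runs the whole pipeline for every user: fixed-area clustering, visit
#' segmentation, home/irrelevance annotation, Stage-1 distance and visit
#' features, mobility matrix, directed multigraph with path-weight
#' summaries, per-place visit rates, daily step quantiles, and the
#' engineered combination of the per-place visit rate with the
#' 75th-percentile path weight (standardized product across the cohort).
#' Users present in only one stream get explicit missing values for the
#' other stream's features.
#'
#' @param gps GPS fixes data.frame (from [read_gps()] or
#'   [simulate_cohort()]); may be `NULL`.
#' @param steps step records data.frame; may be `NULL`.
#' @param config a [pipeline_config()].
#' @return data.frame, one row per user, `user_id` first.
#' @export
extract_features <- function(gps, steps, config = pipeline_config()) {
  users <- sort(unique(c(
    if (!is.null(gps)) unique(gps$user_id),
    if (!is.null(steps)) unique(steps$user_id))))
  rows <- lapply(users, function(u) {
    g <- if (!is.null(gps)) gps[gps$user_id == u, , drop = FALSE]
    s <- if (!is.null(steps)) steps[steps$user_id == u, , drop = FALSE]
    feats <- extract_features_user(g, s, config)
    cbind(data.frame(user_id = u, stringsAsFactors = FALSE),
          as.data.frame(feats))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$combo_rate_q75w <- engineer_combined_feature(
    out$avg_node_visits_per_day, out$q75_path_weight, mode = "product")
  out
}
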