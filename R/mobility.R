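# Stage 2: the dated mobility matrix, the directed edge-weighted
# multigraph, and path-weight / visit-rate / step features.

q_linear <- function(x, p) {
  # linear interpolation between closest ranks (R type 7); the study's
  # fractional printed quantiles on integer weights imply this rule
  unname(stats::quantile(x, p, type = 7, names = FALSE))
}

#' Build the mobility matrix
#'
#' One row per visit, keyed by the arrival instant rendered in the user's
#' local timezone: date of visit, time of day (minutes since local
#' midnight, in \[0, 1440)), node id, and the order of visited places
#' within each day (consecutive from 1).
#'
#' @param visits visit table from [segment_visits()].
#' @param timezone IANA timezone defining local midnight.
#' @return data.frame `date, time_of_day, node_id, order_index, arrive`
#'   sorted by `(date, time_of_day)`.
#' @export
build_mobility_matrix <- function(visits, timezone = "Australia/Sydney") {
  if (nrow(visits) == 0) {
    return(data.frame(date = as.Date(character()), time_of_day = numeric(),
                      node_id = integer(), order_index = integer(),
                      arrive = parse_timestamp(character())))
  }
  m <- data.frame(
    date = local_date(visits$arrive, timezone),
    time_of_day = local_minutes(visits$arrive, timezone),
    node_id = visits$node_id,
    arrive = visits$arrive
  )
  m <- m[order(m$date, m$time_of_day), , drop = FALSE]
  m$order_index <- stats::ave(seq_len(nrow(m)), m$date,
                              FUN = seq_along)
  rownames(m) <- NULL
  m[, c("date", "time_of_day", "node_id", "order_index", "arrive")]
}

#' Build the directed edge-weighted mobility multigraph
#'
#' Every pair of consecutive visits (u -> v) across the whole trace
#' increments the weight of the directed edge (u, v); transitions span
#' midnight (routes are not day-bounded). Nodes flagged irrelevant are
#' excluded by default; transitions touching an excluded node are dropped
#' (not bridged) and the exact drop count is reported. Self-loops — same-
#' node transitions created by the visit gap rule — are dropped unless
#' `include_self_loops`.
#'
#' @param matrix mobility matrix from [build_mobility_matrix()].
#' @param nodes annotated node table (for the irrelevance flags); `NULL`
#'   treats every node as relevant.
#' @param include_irrelevant keep irrelevant-flagged nodes.
#' @param include_self_loops keep same-node transitions as self-loops.
#' @return An object of class `"mobility_graph"`: list with `edges`
#'   (data.frame `from, to, weight`), `node_ids` (retained nodes),
#'   `n_dropped_excluded`, `n_dropped_self_loops`, `n_visits_retained`.
#' @export
build_multigraph <- function(matrix, nodes = NULL,
                             include_irrelevant = FALSE,
                             include_self_loops = FALSE) {
  seqn <- matrix$node_id
  if (!is.null(nodes) && !include_irrelevant) {
    retained_ids <- nodes$node_id[!nodes$is_irrelevant]
  } else if (!is.null(nodes)) {
    retained_ids <- nodes$node_id
  } else {
    retained_ids <- unique(seqn)
  }
  ok <- seqn %in% retained_ids
  n_pairs <- max(0L, length(seqn) - 1L)
  from <- seqn[-length(seqn)]
  to <- seqn[-1L]
  pair_ok <- if (n_pairs) ok[-length(ok)] & ok[-1L] else logical(0)
  dropped_excluded <- sum(!pair_ok)
  from <- from[pair_ok]; to <- to[pair_ok]
  self <- from == to
  dropped_self <- 0L
  if (!include_self_loops && any(self)) {
    dropped_self <- sum(self)
    from <- from[!self]; to <- to[!self]
  }
  if (length(from)) {
    key <- paste(from, to, sep = "->")
    tab <- table(key)
    parts <- strsplit(names(tab), "->", fixed = TRUE)
    edges <- data.frame(
      from = as.integer(vapply(parts, `[`, "", 1L)),
      to = as.integer(vapply(parts, `[`, "", 2L)),
      weight = as.integer(tab)
    )
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(from = integer(), to = integer(), weight = integer())
  }
  structure(list(
    edges = edges,
    node_ids = sort(intersect(retained_ids, unique(seqn))),
    n_dropped_excluded = as.integer(dropped_excluded),
    n_dropped_self_loops = as.integer(dropped_self),
    n_visits_retained = sum(ok)
  ), class = "mobility_graph")
}

#' @export
print.mobility_graph <- function(x, ...) {
  cat(sprintf("<mobility_graph> %d nodes, %d directed edges, total weight %d\n",
              length(x$node_ids), nrow(x$edges), sum(x$edges$weight)))
  if (x$n_dropped_excluded || x$n_dropped_self_loops) {
    cat(sprintf("  dropped transitions: %d at excluded nodes, %d self-loops\n",
                x$n_dropped_excluded, x$n_dropped_self_loops))
  }
  invisible(x)
}

#' Path-weight features of a mobility multigraph
#'
#' Number of relevant places, number of paths (distinct directed edges),
#' and mean / minimum / maximum / 75th-percentile path weight over the
#' multiset of edge weights. The 75th percentile uses linear interpolation
#' between closest ranks.
#'
#' @param graph a `"mobility_graph"`.
#' @return Named list `n_relevant_places, n_paths, mean_path_weight,
#'   min_path_weight, max_path_weight, q75_path_weight` (weight summaries
#'   missing for an empty edge set).
#' @export
path_weight_features <- function(graph) {
  w <- graph$edges$weight
  if (length(w) == 0) {
    s <- list(mean = NA_real_, min = NA_real_, max = NA_real_, q75 = NA_real_)
  } else {
    s <- list(mean = mean(w), min = min(w), max = max(w),
              q75 = q_linear(w, 0.75))
  }
  list(
    n_relevant_places = length(graph$node_ids),
    n_paths = nrow(graph$edges),
    mean_path_weight = s$mean,
    min_path_weight = s$min,
    max_path_weight = s$max,
    q75_path_weight = s$q75
  )
}

#' Visit-rate features
#'
#' The per-place daily visit rate — total visits divided by
#' (relevant places x tracked days) — plus the total visits-per-day
#' variant.
#'
#' @param matrix mobility matrix (rows = visits).
#' @param n_relevant_places count of relevant places.
#' @param n_tracked_days number of tracked days.
#' @return Named list `avg_node_visits_per_day, visits_per_day`.
#' @export
visit_rate_features <- function(matrix, n_relevant_places, n_tracked_days) {
  n <- nrow(matrix)
  if (n == 0 || n_relevant_places == 0 || n_tracked_days == 0) {
    return(list(avg_node_visits_per_day = NA_real_,
                visits_per_day = NA_real_))
  }
  list(
    avg_node_visits_per_day = n / (n_relevant_places * n_tracked_days),
    visits_per_day = n / n_tracked_days
  )
}

#' Daily step features
#'
#' Steps are treated as a separate stream (step and GPS timestamps need
#' not overlap): counts are summed per local day, and the daily sums are
#' summarized by their 25/50/75% quantiles, minimum, maximum and mean.
#' Days with no record contribute no daily sum (missing, not zero).
#'
#' @param steps data.frame `timestamp, steps` for one user.
#' @param timezone IANA timezone defining local midnight.
#' @return Named list `step_q25, step_q50, step_q75, step_min, step_max,
#'   step_mean` (all missing when there are no records).
#' @export
step_features <- function(steps, timezone = "Australia/Sydney") {
  if (nrow(steps) == 0) {
    return(list(step_q25 = NA_real_, step_q50 = NA_real_, step_q75 = NA_real_,
                step_min = NA_real_, step_max = NA_real_, step_mean = NA_real_))
  }
  day <- local_date(steps$timestamp, timezone)
  daily <- as.numeric(tapply(steps$steps, day, sum))
  list(
    step_q25 = q_linear(daily, 0.25),
    step_q50 = q_linear(daily, 0.50),
    step_q75 = q_linear(daily, 0.75),
    step_min = min(daily),
    step_max = max(daily),
    step_mean = mean(daily)
  )
}

#' Combine two features into an engineered feature
#'
#' Cohort-level feature engineering: both inputs are standardized
#' (cohort mean 0, sd 1) and then combined — multiplied under the default
#' `"product"` mode, added under `"sum"`. A missing value in either input
#' yields a missing combined value.
#'
#' @param fA,fB numeric vectors over the cohort (same length).
#' @param mode `"product"` or `"sum"`.
#' @param standardize standardize inputs first (default `TRUE`).
#' @return Numeric vector of combined feature values.
#' @export
engineer_combined_feature <- function(fA, fB, mode = c("product", "sum"),
                                      standardize = TRUE) {
  mode <- match.arg(mode)
  stopifnot(length(fA) == length(fB))
  std <- function(x) {
    s <- stats::sd(x, na.rm = TRUE)
    if (is.na(s) || s == 0) return(x - mean(x, na.rm = TRUE))
    (x - mean(x, na.rm = TRUE)) / s
  }
  if (standardize) {
    fA <- std(fA); fB <- std(fB)
  }
  if (mode == "product") fA * fB else fA + fB
}
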