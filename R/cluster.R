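# Stage 1: collapse noisy GPS fixes into fixed-area location nodes,
# segment visits, identify home, and compute distance/visit features.

#' Great-circle distance in meters
#'
#' Haversine distance on a sphere of radius 6371.0088 km (IUGG mean Earth
#' radius). Vectorized over its arguments.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees.
#' @return Distance(s) in meters.
#' @export
haversine_m <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90, na.rm = TRUE) ||
      any(abs(c(lon1, lon2)) > 180, na.rm = TRUE)) {
    stop("coordinates out of bounds", call. = FALSE)
  }
  r <- 6371008.8
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad / 2
  dlon <- (lon2 - lon1) * to_rad / 2
  a <- sin(dlat)^2 + cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

#' Cluster a user's GPS fixes into fixed-area location nodes
#'
#' Each location is a disc of area `area_m2` (radius `sqrt(area_m2/pi)`,
#' about 39.9 m at the 5000 m^2 default): all coordinates falling into the
#' area count as one location. Assignment is greedy and sequential over the
#' time-sorted fixes: a fix joins the first existing node whose anchor lies
#' within the radius, otherwise it founds a new node anchored at the fix.
#' Anchors are frozen at founding so the result is deterministic and
#' order-stable; centroids (mean of member fixes) are reported for display.
#'
#' @param fixes time-sorted data.frame of one user's fixes
#'   (`timestamp, lat, lon`).
#' @param area_m2 node area in square meters.
#' @return A list with `nodes` (data.frame `node_id, anchor_lat,
#'   anchor_lon, centroid_lat, centroid_lon, fix_count, visit_count,
#'   is_home, is_irrelevant`; visit/home/irrelevant fields filled in by
#'   later stages) and `assignment` (the input fixes with a `node_id`
#'   column). Empty input gives an empty node set.
#' @export
cluster_fixes <- function(fixes, area_m2 = 5000) {
  stopifnot_scalar_number(area_m2, "area_m2")
  radius <- sqrt(area_m2 / pi)
  n <- nrow(fixes)
  node_id <- integer(n)
  anchor_lat <- numeric(0)
  anchor_lon <- numeric(0)
  for (i in seq_len(n)) {
    if (length(anchor_lat)) {
      d <- haversine_m(fixes$lat[i], fixes$lon[i], anchor_lat, anchor_lon)
      hit <- which(d <= radius)
    } else {
      hit <- integer(0)
    }
    if (length(hit)) {
      node_id[i] <- hit[1L]
    } else {
      anchor_lat <- c(anchor_lat, fixes$lat[i])
      anchor_lon <- c(anchor_lon, fixes$lon[i])
      node_id[i] <- length(anchor_lat)
    }
  }
  k <- length(anchor_lat)
  nodes <- data.frame(
    node_id = seq_len(k),
    anchor_lat = anchor_lat,
    anchor_lon = anchor_lon,
    centroid_lat = if (k) as.numeric(tapply(fixes$lat, node_id, mean)) else numeric(),
    centroid_lon = if (k) as.numeric(tapply(fixes$lon, node_id, mean)) else numeric(),
    fix_count = if (k) as.integer(tabulate(node_id, k)) else integer(),
    visit_count = NA_integer_,
    is_home = FALSE,
    is_irrelevant = FALSE
  )
  assignment <- fixes
  assignment$node_id <- node_id
  list(nodes = nodes, assignment = assignment)
}

#' Segment an assigned fix stream into visits
#'
#' Consecutive fixes at the same node merge into one visit; a new visit at
#' the same node starts only after a visit to a different node or a time
#' gap longer than `gap_minutes`. Visits are time-ordered and
#' non-overlapping.
#'
#' @param assignment time-sorted fixes with a `node_id` column
#'   (from [cluster_fixes()]).
#' @param gap_minutes maximal within-visit gap between fixes.
#' @return data.frame `node_id, arrive, depart, n_fixes`, one row per visit.
#' @export
segment_visits <- function(assignment, gap_minutes = 30) {
  n <- nrow(assignment)
  if (n == 0) {
    return(data.frame(node_id = integer(),
                      arrive = parse_timestamp(character()),
                      depart = parse_timestamp(character()),
                      n_fixes = integer()))
  }
  ts <- assignment$timestamp
  node <- assignment$node_id
  gap <- c(Inf, as.numeric(difftime(ts[-1], ts[-n], units = "mins")))
  new_visit <- node != c(-1L, node[-n]) | gap > gap_minutes
  visit_id <- cumsum(new_visit)
  data.frame(
    node_id = node[new_visit],
    arrive = ts[!duplicated(visit_id)],
    depart = ts[rev(!duplicated(rev(visit_id)))],
    n_fixes = as.integer(tabulate(visit_id))
  )
}

#' Identify the likely home node
#'
#' Home is the node with the highest number of visits; ties are broken by
#' the higher fix count, then the lower node id.
#'
#' @param nodes node table with `visit_count` and `fix_count` filled in.
#' @return The home `node_id` (or `NA` for an empty node set).
#' @export
identify_home <- function(nodes) {
  if (nrow(nodes) == 0) return(NA_integer_)
  o <- order(-nodes$visit_count, -nodes$fix_count, nodes$node_id)
  nodes$node_id[o[1L]]
}

#' Flag irrelevant location nodes
#'
#' Nodes visited fewer than `min_visits` times are flagged irrelevant;
#' the home node is never flagged, whatever its count.
#'
#' @param nodes node table with `visit_count` and `is_home` filled in.
#' @param min_visits minimal visit count for relevance.
#' @return The node table with `is_irrelevant` updated.
#' @export
flag_irrelevant <- function(nodes, min_visits = 2) {
  nodes$is_irrelevant <- nodes$visit_count < min_visits & !nodes$is_home
  nodes
}

# Fill visit counts, home flag and irrelevance flag from a visit table.
annotate_nodes <- function(nodes, visits, min_visits = 2) {
  nodes$visit_count <- as.integer(tabulate(visits$node_id, nrow(nodes)))
  nodes$is_home <- FALSE
  home <- identify_home(nodes)
  if (!is.na(home)) nodes$is_home[nodes$node_id == home] <- TRUE
  flag_irrelevant(nodes, min_visits)
}

#' Stage-1 mobility features
#'
#' Number of places visited, frequency of visits (total visits per tracked
#' day, plus a mean per-place variant), and mean/maximum/minimum distance
#' between places. Distances are computed over all unordered node-anchor
#' pairs and are missing when fewer than two places exist.
#'
#' @param nodes annotated node table.
#' @param visits visit table from [segment_visits()].
#' @param n_tracked_days number of distinct local days with data.
#' @return Named list: `n_places, visits_per_day, visits_per_place_per_day,
#'   mean_distance_m, max_distance_m, min_distance_m`.
#' @export
stage1_features <- function(nodes, visits, n_tracked_days) {
  stopifnot_scalar_number(n_tracked_days, "n_tracked_days")
  k <- nrow(nodes)
  if (k >= 2) {
    pairs <- utils::combn(k, 2)
    d <- haversine_m(nodes$anchor_lat[pairs[1, ]], nodes$anchor_lon[pairs[1, ]],
                     nodes$anchor_lat[pairs[2, ]], nodes$anchor_lon[pairs[2, ]])
    dist_mean <- mean(d); dist_max <- max(d); dist_min <- min(d)
  } else {
    dist_mean <- dist_max <- dist_min <- NA_real_
  }
  list(
    n_places = k,
    visits_per_day = nrow(visits) / n_tracked_days,
    visits_per_place_per_day =
      if (k) nrow(visits) / (k * n_tracked_days) else NA_real_,
    mean_distance_m = dist_mean,
    max_distance_m = dist_max,
    min_distance_m = dist_min
  )
}
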