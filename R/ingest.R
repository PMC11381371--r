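# Readers and writers for the pipeline's CSV interchange formats.
#
# All readers share the same contract: malformed rows are rejected with a
# logged reason, never fatal (real 30-day streams contain glitches), and
# accepted + rejected row counts always sum to the input row count. The
# reject log travels with the result as the "rejects" attribute.

finish_read <- function(accepted, rejects_df, n_input) {
  stopifnot(nrow(accepted) + nrow(rejects_df) == n_input)
  attr(accepted, "rejects") <- rejects_df
  attr(accepted, "n_rejected") <- nrow(rejects_df)
  if (nrow(rejects_df) > 0) {
    message(nrow(rejects_df), " row(s) rejected: ",
            paste(utils::head(unique(rejects_df$reason), 3), collapse = "; "))
  }
  accepted
}

reject_log <- function(row = integer(), reason = character()) {
  data.frame(row = row, reason = reason, stringsAsFactors = FALSE)
}

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop("file ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
}

#' Read a GPS fix stream
#'
#' Expects a CSV with header `user_id,timestamp,lat,lon` and an optional
#' `accuracy_m` column; timestamps ISO-8601, stored internally as UTC.
#' Rows with unparseable timestamps, out-of-bounds coordinates
#' (`|lat| > 90`, `|lon| > 180`) or negative accuracy are rejected and
#' counted, never fatal. Output is grouped by user and sorted by timestamp
#' with stable tie order (file order).
#'
#' @param path CSV file path.
#' @return A data.frame `user_id, timestamp, lat, lon, accuracy_m` with a
#'   `"rejects"` attribute logging dropped rows.
#' @export
read_gps <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(user_id = "character"))
  require_columns(df, c("user_id", "timestamp", "lat", "lon"), path)
  if (!"accuracy_m" %in% names(df)) df$accuracy_m <- NA_real_
  n <- nrow(df)
  if (n == 0) {
    out <- data.frame(user_id = character(), timestamp = parse_timestamp(character()),
                      lat = numeric(), lon = numeric(), accuracy_m = numeric())
    return(finish_read(out, reject_log(), 0L))
  }
  ts <- parse_timestamp(df$timestamp)
  lat <- suppressWarnings(as.numeric(df$lat))
  lon <- suppressWarnings(as.numeric(df$lon))
  acc <- suppressWarnings(as.numeric(df$accuracy_m))
  reason <- rep(NA_character_, n)
  reason[is.na(ts)] <- "unparseable timestamp"
  reason[is.na(reason) & (is.na(lat) | lat < -90 | lat > 90)] <-
    "latitude out of [-90, 90]"
  reason[is.na(reason) & (is.na(lon) | lon < -180 | lon > 180)] <-
    "longitude out of [-180, 180]"
  reason[is.na(reason) & !is.na(acc) & acc < 0] <- "negative accuracy"
  keep <- is.na(reason)
  out <- data.frame(user_id = df$user_id[keep], timestamp = ts[keep],
                    lat = lat[keep], lon = lon[keep],
                    accuracy_m = acc[keep], stringsAsFactors = FALSE)
  # stable sort: file order breaks timestamp ties
  out <- out[order(out$user_id, out$timestamp), , drop = FALSE]
  rownames(out) <- NULL
  finish_read(out, reject_log(which(!keep), reason[!keep]), n)
}

#' Read a step-count stream
#'
#' CSV with header `user_id,timestamp,steps`; negative or non-numeric step
#' counts and unparseable timestamps are rejected.
#'
#' @inheritParams read_gps
#' @return A data.frame `user_id, timestamp, steps` sorted per user by
#'   timestamp, with a `"rejects"` attribute.
#' @export
read_steps <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(user_id = "character"))
  require_columns(df, c("user_id", "timestamp", "steps"), path)
  n <- nrow(df)
  if (n == 0) {
    out <- data.frame(user_id = character(),
                      timestamp = parse_timestamp(character()),
                      steps = integer())
    return(finish_read(out, reject_log(), 0L))
  }
  ts <- parse_timestamp(df$timestamp)
  steps <- suppressWarnings(as.numeric(df$steps))
  reason <- rep(NA_character_, n)
  reason[is.na(ts)] <- "unparseable timestamp"
  reason[is.na(reason) & (is.na(steps) | steps < 0)] <- "negative or missing steps"
  keep <- is.na(reason)
  out <- data.frame(user_id = df$user_id[keep], timestamp = ts[keep],
                    steps = as.integer(round(steps[keep])),
                    stringsAsFactors = FALSE)
  out <- out[order(out$user_id, out$timestamp), , drop = FALSE]
  rownames(out) <- NULL
  finish_read(out, reject_log(which(!keep), reason[!keep]), n)
}

#' Read DASS stress-subscale responses
#'
#' CSV with header `user_id,wave,s1..s7`; each of the seven items must be
#' an integer in 0..3 (the DASS 4-point rating scale) and `wave` in 1..3.
#' Rows violating either are rejected. Wave order within a user is
#' preserved.
#'
#' @inheritParams read_gps
#' @return A data.frame `user_id, wave, s1..s7` with a `"rejects"`
#'   attribute.
#' @export
read_dass <- function(path) {
  item_cols <- paste0("s", 1:7)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(user_id = "character"))
  require_columns(df, c("user_id", "wave", item_cols), path)
  n <- nrow(df)
  if (n == 0) {
    out <- df[, c("user_id", "wave", item_cols)]
    return(finish_read(out, reject_log(), 0L))
  }
  items <- as.matrix(df[, item_cols])
  storage.mode(items) <- "numeric"
  wave <- suppressWarnings(as.numeric(df$wave))
  bad_item <- apply(items, 1, function(r) {
    any(is.na(r) | r < 0 | r > 3 | r != round(r))
  })
  reason <- rep(NA_character_, n)
  reason[is.na(wave) | !wave %in% 1:3] <- "wave not in 1..3"
  reason[is.na(reason) & bad_item] <- "item outside 0..3"
  keep <- is.na(reason)
  out <- data.frame(user_id = df$user_id[keep], wave = as.integer(wave[keep]),
                    stringsAsFactors = FALSE)
  out[item_cols] <- as.data.frame(items[keep, , drop = FALSE])
  rownames(out) <- NULL
  finish_read(out, reject_log(which(!keep), reason[!keep]), n)
}

#' Write / read a per-user feature table
#'
#' One row per user, deterministic column order (`user_id` first, then
#' feature columns in their table order). Missing features are written as
#' the explicit token `NA`, never silently zeroed, and the written file
#' round-trips losslessly through [read_feature_table()].
#'
#' @param features data.frame with a `user_id` column.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  stopifnot(is.data.frame(features), "user_id" %in% names(features))
  cols <- c("user_id", setdiff(names(features), "user_id"))
  utils::write.csv(format_numeric_df(features[, cols, drop = FALSE]),
                   path, row.names = FALSE, na = "NA", quote = FALSE)
  invisible(path)
}

# full-precision rendering so the round trip is lossless
format_numeric_df <- function(df) {
  for (nm in names(df)) {
    if (is.numeric(df[[nm]])) {
      x <- format(df[[nm]], digits = 17, trim = TRUE, scientific = FALSE)
      x[is.na(df[[nm]])] <- NA
      df[[nm]] <- x
    }
  }
  df
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(user_id = "character"))
  rownames(df) <- NULL
  df
}

#' Write a mobility multigraph to edge-list and node CSVs
#'
#' Serializes a graph built by [build_multigraph()] as
#' `from_node,to_node,weight` plus a node table, the package's interchange
#' format for multigraph renderings.
#'
#' @param graph a `"mobility_graph"` object.
#' @param edge_path,node_path output CSV paths (`node_path = NULL` skips
#'   the node table).
#' @param nodes optional node data.frame (from [cluster_fixes()]).
#' @return `edge_path`, invisibly.
#' @export
write_graph_csv <- function(graph, edge_path, node_path = NULL, nodes = NULL) {
  edges <- graph$edges
  names(edges) <- c("from_node", "to_node", "weight")
  utils::write.csv(edges, edge_path, row.names = FALSE)
  if (!is.null(node_path) && !is.null(nodes)) {
    utils::write.csv(nodes, node_path, row.names = FALSE)
  }
  invisible(edge_path)
}
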