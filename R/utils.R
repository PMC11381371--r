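# Internal helpers shared across the pipeline.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-stream seed from a master seed
#'
#' All randomness in the package flows from one master seed; independent
#' stages (splitting, oversampling, fold assignment, model initialisation,
#' per-user simulation) draw their own seeds through this function so that
#' changing one stage never perturbs another.
#'
#' @param master integer master seed.
#' @param stream character label of the sub-stream (e.g. `"split"`), or an
#'   integer index.
#' @return An integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, stream) {
  if (is.character(stream)) {
    stream <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  }
  m <- 2147483647 # 2^31 - 1, keeps derived seeds valid R integers
  x <- (as.numeric(master) %% m) * 48271 + as.numeric(stream) * 16807
  as.integer(x %% (m - 1) + 1)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Parse ISO-8601 timestamps to POSIXct stored as UTC; NA on failure.
parse_timestamp <- function(x) {
  lubridate::ymd_hms(x, tz = "UTC", quiet = TRUE)
}

# Local calendar date of an instant under an IANA timezone.
local_date <- function(ts, timezone) {
  as.Date(format(ts, tz = timezone, format = "%Y-%m-%d"))
}

# Minutes since local midnight, in [0, 1440).
local_minutes <- function(ts, timezone) {
  h <- as.integer(format(ts, tz = timezone, format = "%H"))
  m <- as.integer(format(ts, tz = timezone, format = "%M"))
  s <- as.numeric(format(ts, tz = timezone, format = "%OS"))
  h * 60 + m + s / 60
}

stopifnot_scalar_number <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be a single number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be positive", name), call. = FALSE)
  }
  invisible(x)
}
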