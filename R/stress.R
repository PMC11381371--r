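# DASS stress-subscale scoring, population z-standardization, and
# severity discretization.

#' Score the DASS stress subscale
#'
#' Raw score = 2 x sum of the seven stress items (each rated 0..3), so the
#' raw score is an even integer in \[0, 42\].
#'
#' @param items numeric vector of 7 item responses in 0..3, or a matrix /
#'   data.frame with 7 columns (one row per response).
#' @return Raw score(s).
#' @export
score_stress <- function(items) {
  m <- if (is.null(dim(items))) matrix(as.numeric(items), nrow = 1) else
    as.matrix(items)
  if (ncol(m) != 7) stop("exactly 7 stress items are required", call. = FALSE)
  if (any(is.na(m)) || any(m < 0 | m > 3 | m != round(m))) {
    stop("items must be integers in 0..3", call. = FALSE)
  }
  out <- 2 * rowSums(m)
  if (is.null(dim(items))) out <- unname(out[1])
  out
}

#' Standardize a raw stress score to the population z-score
#'
#' z = (raw - mean) / sd against young-adult general-population norms
#' (mean 11.19, sd 8.25 by default).
#'
#' @param raw raw stress score(s).
#' @param mean,sd population norms.
#' @return z-score(s).
#' @export
stress_zscore <- function(raw, mean = 11.19, sd = 8.25) {
  (raw - mean) / sd
}

#' Discretize stress z-scores into severity classes
#'
#' Three schemes:
#' \describe{
#'   \item{three_class}{`none` (z < 0.5), `mild_moderate` (0.5 <= z <= 2),
#'     `severe_extreme` (z > 2). Inner boundaries closed, outer strict.}
#'   \item{binary}{as `three_class` but `mild_moderate` mapped to
#'     `excluded`, leaving a none-vs-severe contrast.}
#'   \item{binary_polarized}{severity-polarized contrast: `severe_extreme`
#'     requires z > 2.2; 0.5 <= z <= 2.2 is `excluded` (removing users on
#'     the cusp of severe, e.g. z = 2.1); `none` still z < 0.5.}
#' }
#'
#' @param z numeric z-score(s).
#' @param scheme discretization scheme.
#' @return Character vector of labels in
#'   `none, mild_moderate, severe_extreme, excluded`.
#' @export
discretize_stress <- function(z, scheme = c("three_class", "binary",
                                            "binary_polarized")) {
  scheme <- match.arg(scheme)
  out <- character(length(z))
  out[z < 0.5] <- "none"
  out[z >= 0.5 & z <= 2.0] <- "mild_moderate"
  out[z > 2.0] <- "severe_extreme"
  if (scheme == "binary") {
    out[out == "mild_moderate"] <- "excluded"
  } else if (scheme == "binary_polarized") {
    out[z >= 0.5 & z <= 2.2] <- "excluded"
    out[z > 2.2] <- "severe_extreme"
  }
  out[is.na(z)] <- NA_character_
  out
}

#' Score a DASS response table
#'
#' Applies [score_stress()], [stress_zscore()] and [discretize_stress()]
#' to a validated response table (from [read_dass()]), one output row per
#' response.
#'
#' @param dass data.frame `user_id, wave, s1..s7`.
#' @param config a [pipeline_config()]; supplies the norms and scheme.
#' @param wave restrict to one administration (default
#'   `config$dass_wave`); `NULL` keeps all waves.
#' @return data.frame `user_id, wave, raw, z, class`.
#' @export
score_dass <- function(dass, config = pipeline_config(), wave = config$dass_wave) {
  if (!is.null(wave)) dass <- dass[dass$wave == wave, , drop = FALSE]
  raw <- score_stress(dass[paste0("s", 1:7)])
  z <- stress_zscore(raw, config$zscore_mean, config$zscore_sd)
  data.frame(
    user_id = dass$user_id,
    wave = dass$wave,
    raw = unname(raw),
    z = unname(z),
    class = discretize_stress(z, config$scheme),
    stringsAsFactors = FALSE
  )
}
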