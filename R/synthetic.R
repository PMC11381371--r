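# Synthetic cohort generator: GPS / step / DASS streams with the
# statistical structure the analysis assumes — a latent stress z-score
# coupled positively to place counts and visit rates and negatively to
# daily steps — so every pipeline stage is testable without real data.

#' Simulation profile
#'
#' Bundles the cohort-generator parameters. Defaults emulate a 30-day
#' screened, distressed student cohort: latent z truncated to
#' \[-1.5, 3.5\] so all severity classes are populated, places laid on a
#' grid whose spacing (500 m) far exceeds the cluster diameter, GPS jitter
#' well under the cluster radius, and coupling signs (+, +, -) for place
#' count, visit rate and daily steps.
#'
#' @param n_users cohort size.
#' @param days tracked days per user.
#' @param z_mean,z_sd,z_trunc latent stress z distribution (truncated
#'   normal).
#' @param places_base,places_per_z,places_sd,places_range expected number
#'   of distinct places: `places_base + places_per_z * z` plus noise,
#'   rounded and clamped.
#' @param rate_base,rate_per_z,rate_sd,rate_min per-place daily visit
#'   rate: `rate_base + rate_per_z * z` plus noise, floored.
#' @param steps_base,steps_per_z,steps_user_sd,steps_day_sd daily steps:
#'   a per-user level `steps_base + steps_per_z * z` plus user noise, with
#'   day-to-day noise around it.
#' @param jitter_sd_m GPS noise scale (half-normal radial displacement).
#' @param jitter_max_m hard cap on the radial displacement; keeping it
#'   under half the cluster radius (about 19.9 m) guarantees fixed-area
#'   clustering recovers the planted place count exactly.
#' @param spacing_m grid spacing between true places.
#' @param home_lat,home_lon coordinates of the home place.
#' @param timezone cohort timezone.
#' @param seed master seed; per-user streams derive from it.
#' @return list of class `"sim_profile"`.
#' @export
sim_profile <- function(n_users = 150, days = 30,
                        z_mean = 0.9, z_sd = 1.0, z_trunc = c(-1.5, 3.5),
                        places_base = 12, places_per_z = 3, places_sd = 7.5,
                        places_range = c(3, 40),
                        rate_base = 1.3, rate_per_z = 0.35, rate_sd = 0.85,
                        rate_min = 0.4,
                        steps_base = 7500, steps_per_z = -900,
                        steps_user_sd = 3500, steps_day_sd = 1200,
                        jitter_sd_m = 10, jitter_max_m = 18, spacing_m = 500,
                        home_lat = -33.89, home_lon = 151.19,
                        timezone = "Australia/Sydney", seed = 1L) {
  prof <- as.list(environment())
  radius <- sqrt(5000 / pi)
  if (jitter_max_m >= radius) stop("jitter_max_m must be below the cluster radius",
                                   call. = FALSE)
  if (spacing_m <= 2 * radius) stop("spacing_m must exceed the cluster diameter",
                                    call. = FALSE)
  class(prof) <- "sim_profile"
  prof
}

meters_per_deg_lat <- 111194.93 # 2*pi*6371008.8 / 360

place_grid <- function(n, home_lat, home_lon, spacing_m) {
  j <- seq_len(n) - 1L
  dlat <- spacing_m / meters_per_deg_lat
  dlon <- spacing_m / (meters_per_deg_lat * cos(home_lat * pi / 180))
  data.frame(place = seq_len(n),
             lat = home_lat + (j %/% 6) * dlat,
             lon = home_lon + (j %% 6) * dlon)
}

# bounded radial GPS jitter: half-normal radius capped at max_m, uniform
# direction; the cap keeps every fix inside its true place's cluster disc
jitter_offsets <- function(n, sd_m, max_m, lat0) {
  radius <- pmin(abs(stats::rnorm(n, 0, sd_m)), max_m)
  theta <- stats::runif(n, 0, 2 * pi)
  list(dlat = radius * sin(theta) / meters_per_deg_lat,
       dlon = radius * cos(theta) / (meters_per_deg_lat * cos(lat0 * pi / 180)))
}

local_instant <- function(date, minutes, timezone) {
  as.POSIXct(paste(format(date), sprintf("%02d:%02d:%06.3f",
                                         floor(minutes / 60) %% 24,
                                         floor(minutes %% 60),
                                         (minutes %% 1) * 60)),
             tz = timezone)
}

#' Simulate one user's sensor streams
#'
#' Generates a home-anchored Markov visit schedule over a grid of places
#' (each day starts at home; successive places are drawn by popularity,
#' never repeating the current place), emits 1-3 jittered GPS fixes per
#' visit, a daily step record whose mean decreases in z, and DASS items
#' whose score reproduces the latent z up to the raw-score lattice. Every
#' planted place is guaranteed at least one visit, so fixed-area
#' clustering recovers the planted place count exactly.
#'
#' @param profile a [sim_profile()].
#' @param z latent stress z-score for this user.
#' @param seed integer seed for this user's stream.
#' @param user_id user identifier.
#' @return list `gps, steps, dass, truth` (data.frames; `truth` has one
#'   row with the planted quantities and the DASS-scored z).
#' @export
simulate_user <- function(profile, z, seed, user_id = "u001") {
  p <- profile
  with_seed(seed, {
    n_places <- round(p$places_base + p$places_per_z * z +
                        stats::rnorm(1, 0, p$places_sd))
    n_places <- min(max(n_places, p$places_range[1]), p$places_range[2])
    rate <- max(p$rate_min,
                p$rate_base + p$rate_per_z * z + stats::rnorm(1, 0, p$rate_sd))
    grid <- place_grid(n_places, p$home_lat, p$home_lon, p$spacing_m)
    pop <- c(3, 1 / seq_len(n_places - 1)) # home is the heavy hub
    dates <- as.Date("2023-05-01") + seq_len(p$days) - 1L
    day_seq <- vector("list", p$days)
    for (d in seq_len(p$days)) {
      v <- max(2L, stats::rpois(1, rate * n_places))
      s <- integer(v)
      s[1] <- 1L # mornings anchored at home
      for (k in seq_len(v - 1L)) {
        w <- pop
        w[s[k]] <- 0
        s[k + 1L] <- sample.int(n_places, 1L, prob = w)
      }
      day_seq[[d]] <- s
    }
    # guarantee coverage of every planted place
    missing <- setdiff(seq_len(n_places), unique(unlist(day_seq)))
    for (m in missing) {
      d <- sample.int(p$days, 1L)
      s <- day_seq[[d]]
      pos <- sample.int(length(s), 1L)
      if (s[pos] != m && (pos == length(s) || s[pos + 1L] != m)) {
        day_seq[[d]] <- append(s, m, after = pos)
      } else {
        day_seq[[d]] <- c(s, if (s[length(s)] == m) 1L else integer(0), m)
      }
    }
    # vectorized fix emission: one flat table across all days
    v_per_day <- lengths(day_seq)
    place <- unlist(day_seq)
    day_of_visit <- rep(seq_len(p$days), v_per_day)
    # visits spread over 08:00-22:00 local
    within <- unlist(lapply(v_per_day, function(v) (seq_len(v) - 1) / v))
    arrive <- 8 * 60 + (14 * 60) * within + stats::runif(length(place), 0, 8)
    nf <- sample.int(3L, length(place), replace = TRUE)
    fix_visit <- rep(seq_along(place), nf)
    t_fix <- arrive[fix_visit] + (sequence(nf) - 1) * 3
    n_fix <- length(fix_visit)
    jit <- jitter_offsets(n_fix, p$jitter_sd_m, p$jitter_max_m, p$home_lat)
    gps <- data.frame(
      user_id = user_id,
      timestamp = local_instant(dates[day_of_visit[fix_visit]], t_fix,
                                p$timezone),
      lat = grid$lat[place[fix_visit]] + jit$dlat,
      lon = grid$lon[place[fix_visit]] + jit$dlon,
      accuracy_m = round(stats::runif(n_fix, 5, 25), 1),
      stringsAsFactors = FALSE)
    attr(gps$timestamp, "tzone") <- "UTC"

    user_level <- p$steps_base + p$steps_per_z * z +
      stats::rnorm(1, 0, p$steps_user_sd)
    daily <- pmax(0, round(stats::rnorm(p$days, user_level, p$steps_day_sd)))
    steps <- data.frame(
      user_id = user_id,
      timestamp = local_instant(dates, 21 * 60, p$timezone),
      steps = as.integer(daily), stringsAsFactors = FALSE)
    attr(steps$timestamp, "tzone") <- "UTC"

    s_sum <- min(max(round((11.19 + 8.25 * z) / 2), 0), 21)
    items <- rep(s_sum %/% 7, 7) + c(rep(1, s_sum %% 7), rep(0, 7 - s_sum %% 7))
    dass <- data.frame(user_id = user_id, wave = 1L, stringsAsFactors = FALSE)
    dass[paste0("s", 1:7)] <- as.list(as.integer(items))

    truth <- data.frame(
      user_id = user_id, z_latent = z,
      z = stress_zscore(2 * s_sum),
      n_places_planted = n_places,
      rate_planted = rate,
      visits_planted = length(unlist(day_seq)),
      steps_level_planted = user_level,
      stringsAsFactors = FALSE)
    list(gps = gps, steps = steps, dass = dass, truth = truth)
  })
}

#' Simulate a cohort
#'
#' Draws per-user latent z from the truncated normal, simulates each
#' user's streams from a derived seed, and records the truth table
#' (latent z, DASS-scored z, planted place counts and rates). A pure
#' function of (profile, seed).
#'
#' @param profile a [sim_profile()].
#' @return list `gps, steps, dass, truth` (row-bound over users).
#' @export
simulate_cohort <- function(profile) {
  p <- profile
  n <- p$n_users
  if (n == 0) {
    return(list(gps = NULL, steps = NULL, dass = NULL,
                truth = data.frame(user_id = character())))
  }
  z <- with_seed(derive_seed(p$seed, "latent_z"), {
    out <- numeric(n)
    for (i in seq_len(n)) {
      repeat {
        v <- stats::rnorm(1, p$z_mean, p$z_sd)
        if (v >= p$z_trunc[1] && v <= p$z_trunc[2]) break
      }
      out[i] <- v
    }
    out
  })
  users <- lapply(seq_len(n), function(i) {
    simulate_user(p, z[i], derive_seed(p$seed, paste0("user", i)),
                  sprintf("u%03d", i))
  })
  list(
    gps = do.call(rbind, lapply(users, `[[`, "gps")),
    steps = do.call(rbind, lapply(users, `[[`, "steps")),
    dass = do.call(rbind, lapply(users, `[[`, "dass")),
    truth = do.call(rbind, lapply(users, `[[`, "truth"))
  )
}

iso_utc <- function(ts) {
  format(ts, tz = "UTC", format = "%Y-%m-%dT%H:%M:%SZ")
}

#' Write a simulated cohort to CSV files
#'
#' Writes `gps.csv`, `steps.csv`, `dass.csv` and `truth.csv` into a
#' directory in the pipeline's interchange formats (ISO-8601 UTC
#' timestamps). Byte-identical for identical (profile, seed).
#'
#' @param cohort output of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gps <- cohort$gps
  gps$timestamp <- iso_utc(gps$timestamp)
  gps$lat <- sprintf("%.7f", gps$lat)
  gps$lon <- sprintf("%.7f", gps$lon)
  utils::write.csv(gps, file.path(dir, "gps.csv"), row.names = FALSE,
                   quote = FALSE)
  steps <- cohort$steps
  steps$timestamp <- iso_utc(steps$timestamp)
  utils::write.csv(steps, file.path(dir, "steps.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(cohort$dass, file.path(dir, "dass.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(format_numeric_df(cohort$truth),
                   file.path(dir, "truth.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(dir)
}
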