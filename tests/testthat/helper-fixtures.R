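# Shared fixtures, built once per test run and cached.

.cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .cache)) assign(name, expr, envir = .cache)
  get(name, envir = .cache)
}

# The default synthetic cohort (the study conditions: 150 users, 30 days)
# plus its extracted feature table and truth labels.
test_cohort <- function() {
  cached("cohort", simulate_cohort(sim_profile(n_users = 150, seed = 1)))
}

test_features <- function() {
  cached("features", {
    co <- test_cohort()
    extract_features(co$gps, co$steps)
  })
}

# Figure-style representative-user fixtures.
test_fixtures <- function() {
  cached("fixtures", make_figure4_fixtures(seed = 2024))
}

# small deterministic GPS table (one user, three tight places)
toy_gps <- function() {
  base <- as.POSIXct("2023-05-01 08:00:00", tz = "UTC")
  mk <- function(lat, lon, mins) {
    data.frame(user_id = "u1", timestamp = base + mins * 60,
               lat = lat, lon = lon, accuracy_m = 10)
  }
  # places ~1 km apart; sequence A, B, A, C with two fixes per stay
  rbind(
    mk(-33.8900, 151.1900, c(0, 5)),     # A
    mk(-33.8990, 151.1900, c(60, 65)),   # B
    mk(-33.8900, 151.1900, c(120, 125)), # A again
    mk(-33.8810, 151.1900, c(180, 185))  # C
  )
}

write_temp_csv <- function(df, name = "tmp.csv") {
  path <- file.path(withr::local_tempdir(.local_envir = parent.frame()), name)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
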