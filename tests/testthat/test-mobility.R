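# Stage 2: mobility matrix, multigraph construction, path-weight /
# visit-rate / step features, engineered combinations.

visits_at <- function(nodes, times_utc) {
  ts <- as.POSIXct(times_utc, tz = "UTC")
  data.frame(node_id = as.integer(nodes), arrive = ts, depart = ts + 300,
             n_fixes = rep(1L, length(nodes)))
}

test_that("mobility matrix keys visits by local date and orders within day", {
  expect_equal(nrow(build_mobility_matrix(visits_at(integer(), character()))), 0)

  v <- visits_at(c(1, 2), c("2023-05-01 22:00:00", "2023-05-01 23:30:00"))
  m <- build_mobility_matrix(v, "UTC")
  expect_equal(m$order_index, c(1L, 2L))
  expect_equal(m$time_of_day, c(22 * 60, 23.5 * 60))

  # 23:50 then 00:10 next day land on different local dates
  v2 <- visits_at(c(1, 2), c("2023-05-01 23:50:00", "2023-05-02 00:10:00"))
  m2 <- build_mobility_matrix(v2, "UTC")
  expect_equal(as.integer(diff(m2$date)), 1L)
  expect_equal(m2$order_index, c(1L, 1L))

  # timezone oracle: 13:50 UTC is 23:50 in Sydney (UTC+10 in May);
  # 14:10 UTC crosses local midnight
  v3 <- visits_at(c(1, 2), c("2023-05-01 13:50:00", "2023-05-01 14:10:00"))
  m3 <- build_mobility_matrix(v3, "Australia/Sydney")
  expect_equal(as.integer(diff(m3$date)), 1L)
  expect_equal(m3$time_of_day, c(23 * 60 + 50, 10))
})

test_that("multigraph counts directed transitions with hand-enumerated weights", {
  v <- visits_at(c(1, 2, 1, 2, 3),
                 sprintf("2023-05-01 %02d:00:00", 8:12))
  m <- build_mobility_matrix(v, "UTC")
  g <- build_multigraph(m)
  # A,B,A,B,C -> A->B:2, B->A:1, B->C:1
  expect_equal(g$edges$weight[g$edges$from == 1 & g$edges$to == 2], 2L)
  expect_equal(g$edges$weight[g$edges$from == 2 & g$edges$to == 1], 1L)
  expect_equal(g$edges$weight[g$edges$from == 2 & g$edges$to == 3], 1L)
  expect_equal(nrow(g$edges), 3)
  expect_equal(sum(g$edges$weight), nrow(m) - 1L)

  single <- build_multigraph(build_mobility_matrix(
    visits_at(1, "2023-05-01 08:00:00"), "UTC"))
  expect_equal(nrow(single$edges), 0)
})

test_that("self-loops from the gap rule follow the configuration branch", {
  v <- visits_at(c(1, 1), c("2023-05-01 08:00:00", "2023-05-01 20:00:00"))
  m <- build_mobility_matrix(v, "UTC")
  off <- build_multigraph(m, include_self_loops = FALSE)
  expect_equal(nrow(off$edges), 0)
  expect_equal(off$n_dropped_self_loops, 1L)
  on <- build_multigraph(m, include_self_loops = TRUE)
  expect_equal(on$edges$weight, 1L)
  expect_equal(on$edges$from, on$edges$to)
})

test_that("excluded nodes drop transitions with exact accounting", {
  nodes <- data.frame(node_id = 1:3, is_irrelevant = c(FALSE, FALSE, TRUE))
  v <- visits_at(c(1, 3, 2, 1, 2),
                 sprintf("2023-05-01 %02d:00:00", 8:12))
  m <- build_mobility_matrix(v, "UTC")
  g <- build_multigraph(m, nodes)
  # pairs: 1-3 (dropped), 3-2 (dropped), 2-1, 1-2
  expect_equal(g$n_dropped_excluded, 2L)
  expect_equal(sum(g$edges$weight), 2L)
  # conservation: weights + drops = visits - 1
  expect_equal(sum(g$edges$weight) + g$n_dropped_excluded +
                 g$n_dropped_self_loops, nrow(m) - 1L)
  # retention flag restores everything
  g_all <- build_multigraph(m, nodes, include_irrelevant = TRUE)
  expect_equal(sum(g_all$edges$weight), nrow(m) - 1L)
})

test_that("reversing the visit order transposes the edge-weight matrix", {
  fx <- test_fixtures()
  cl <- cluster_fixes(fx$a$gps)
  vis <- segment_visits(cl$assignment, 30)
  m <- build_mobility_matrix(vis, "Australia/Sydney")
  g <- build_multigraph(m)
  m_rev <- m
  m_rev$node_id <- rev(m$node_id) # same instants, reversed itinerary
  g_rev <- build_multigraph(m_rev)
  key <- function(e) paste(e$from, e$to)
  rev_key <- function(e) paste(e$to, e$from)
  o1 <- order(key(g$edges)); o2 <- order(rev_key(g_rev$edges))
  expect_equal(key(g$edges)[o1], rev_key(g_rev$edges)[o2])
  expect_equal(g$edges$weight[o1], g_rev$edges$weight[o2])
})

test_that("path-weight features use linear-interpolation percentiles", {
  mk_graph <- function(w) structure(list(
    edges = data.frame(from = seq_along(w), to = seq_along(w) + 1,
                       weight = w),
    node_ids = seq_len(length(w) + 1)), class = "mobility_graph")
  f <- path_weight_features(mk_graph(c(2, 2)))
  expect_equal(f$mean_path_weight, 2)
  expect_equal(f$q75_path_weight, 2)
  # interpolation oracle: h = (n-1)p + 1 = 3.25 -> 8 + 0.25*(9-8) = 8.25
  f2 <- path_weight_features(mk_graph(c(3, 5, 8, 9)))
  expect_equal(f2$q75_path_weight, 8.25)
  expect_equal(f2$n_paths, 4)
  # all-equal weights: interpolation degeneracy
  f3 <- path_weight_features(mk_graph(rep(7, 9)))
  expect_equal(f3$q75_path_weight, 7)
  expect_true(f3$min_path_weight <= f3$mean_path_weight)
  expect_true(f3$mean_path_weight <= f3$max_path_weight)
})

test_that("visit rates give the per-place daily rate", {
  m <- data.frame(node_id = rep(1:7, 30))
  vr <- visit_rate_features(m, 7, 30)
  expect_equal(vr$avg_node_visits_per_day, 1)
  expect_equal(vr$visits_per_day, 7)
  expect_true(is.na(visit_rate_features(m[0, , drop = FALSE], 7, 30)$avg_node_visits_per_day))
  m25 <- data.frame(node_id = rep(1:25, 90))
  expect_equal(visit_rate_features(m25, 25, 30)$avg_node_visits_per_day, 3)
})

test_that("step features summarize daily sums with missing days absent", {
  mk <- function(days, steps) data.frame(
    timestamp = as.POSIXct("2023-05-01 12:00:00", tz = "UTC") +
      (days - 1) * 86400,
    steps = steps)
  s <- step_features(mk(1:30, rep(8000, 30)), "UTC")
  expect_equal(unlist(s), c(step_q25 = 8000, step_q50 = 8000, step_q75 = 8000,
                            step_min = 8000, step_max = 8000, step_mean = 8000))
  empty <- step_features(mk(integer(), integer()), "UTC")
  expect_true(all(is.na(unlist(empty))))
  # quantile interpolation oracle on daily sums {1000,2000,3000,4000}
  s4 <- step_features(mk(1:4, c(1000, 2000, 3000, 4000)), "UTC")
  expect_equal(s4$step_q25, 1750)
  expect_equal(s4$step_q50, 2500)
  expect_equal(s4$step_q75, 3250)
  # multiple records in a day are summed; a skipped day contributes nothing
  s5 <- step_features(mk(c(1, 1, 3), c(500, 700, 2000)), "UTC")
  expect_equal(s5$step_min, 1200)
  expect_equal(s5$step_max, 2000)
  expect_equal(s5$step_mean, 1600)
})

test_that("engineered combination propagates missingness and supports both modes", {
  expect_true(is.na(engineer_combined_feature(NA_real_, 2, standardize = FALSE)))
  expect_equal(engineer_combined_feature(1, 2, mode = "product",
                                         standardize = FALSE), 2)
  # cohort where fA = fB: sum mode correlates with fA exactly
  set.seed(5)
  fa <- rnorm(60)
  comb <- engineer_combined_feature(fa, fa, mode = "sum")
  expect_equal(cor(comb, fa), 1)
})
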