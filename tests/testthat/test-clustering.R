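# Stage 1: haversine, fixed-area clustering, visit segmentation, home and
# irrelevance annotation, distance/visit features.

test_that("haversine distance matches its analytic properties and geosphere", {
  expect_equal(haversine_m(-33.89, 151.19, -33.89, 151.19), 0)
  # 1 degree of longitude at the equator: spherical law-of-cosines oracle
  r <- 6371008.8
  loc <- r * acos(sin(0) * sin(0) + cos(0) * cos(0) * cos(1 * pi / 180))
  expect_equal(haversine_m(0, 0, 0, 1), loc, tolerance = 1e-9)
  expect_equal(round(haversine_m(0, 0, 0, 1)), 111195)
  # symmetry on random pairs
  set.seed(3)
  la1 <- runif(20, -80, 80); lo1 <- runif(20, -170, 170)
  la2 <- runif(20, -80, 80); lo2 <- runif(20, -170, 170)
  expect_equal(haversine_m(la1, lo1, la2, lo2), haversine_m(la2, lo2, la1, lo1))
  # independent implementation (geosphere) at the same Earth radius
  expect_equal(haversine_m(la1, lo1, la2, lo2),
               geosphere::distHaversine(cbind(lo1, la1), cbind(lo2, la2),
                                        r = 6371008.8),
               tolerance = 1e-6)
  expect_error(haversine_m(91, 0, 0, 0), "out of bounds")
})

test_that("clustering collapses identical fixes and separates distant clouds", {
  base <- as.POSIXct("2023-05-01 08:00:00", tz = "UTC")
  same <- data.frame(user_id = "u", timestamp = base + 1:5,
                     lat = -33.89, lon = 151.19)
  cl <- cluster_fixes(same)
  expect_equal(nrow(cl$nodes), 1)
  expect_equal(cl$nodes$centroid_lat, -33.89)
  expect_equal(cl$nodes$fix_count, 5L)

  # two tight clouds (jitter <= 20 m) 1 km apart -> 2 nodes; brute-force
  # oracle: no cross-cloud pair within twice the radius
  set.seed(11)
  jit <- function(n) runif(n, -20, 20) / 111194.93
  cloud <- rbind(
    data.frame(lat = -33.89 + jit(10), lon = 151.19 + jit(10)),
    data.frame(lat = -33.89 + 1000 / 111194.93 + jit(10), lon = 151.19 + jit(10)))
  cloud <- data.frame(user_id = "u", timestamp = base + seq_len(20), cloud)
  r2 <- 2 * sqrt(5000 / pi)
  cross <- outer(1:10, 11:20, function(i, j)
    haversine_m(cloud$lat[i], cloud$lon[i], cloud$lat[j], cloud$lon[j]))
  expect_true(all(cross > r2))
  cl2 <- cluster_fixes(cloud)
  expect_equal(nrow(cl2$nodes), 2)
  expect_equal(sum(cl2$nodes$fix_count), 20L)
})

test_that("clustering invariants: partition, radius bound, determinism, monotonicity", {
  fx <- test_fixtures()
  gps <- fx$a$gps
  cl <- cluster_fixes(gps, 5000)
  # partition: every accepted fix in exactly one node
  expect_equal(sum(cl$nodes$fix_count), nrow(gps))
  # radius bound relative to the frozen anchors
  d <- haversine_m(cl$assignment$lat, cl$assignment$lon,
                   cl$nodes$anchor_lat[cl$assignment$node_id],
                   cl$nodes$anchor_lon[cl$assignment$node_id])
  expect_true(all(d <= sqrt(5000 / pi) + 1e-9))
  # determinism
  cl_again <- cluster_fixes(gps, 5000)
  expect_identical(cl$assignment$node_id, cl_again$assignment$node_id)
  # monotonicity: shrinking the area never decreases the node count
  areas <- c(5000, 2000, 500, 100)
  counts <- vapply(areas, function(a) nrow(cluster_fixes(gps, a)$nodes), 0)
  expect_true(all(diff(counts) >= 0))
})

test_that("visit segmentation merges stays and applies the gap rule", {
  base <- as.POSIXct("2023-05-01 08:00:00", tz = "UTC")
  mk <- function(node, mins) data.frame(
    user_id = "u", timestamp = base + mins * 60, lat = 0, lon = 0,
    node_id = node)
  # A,A,A (within gap) -> one visit
  v <- segment_visits(mk(c(1, 1, 1), c(0, 10, 20)), 30)
  expect_equal(nrow(v), 1)
  expect_equal(v$n_fixes, 3L)
  # A,A,B,A -> 3 visits (A,B,A)
  v <- segment_visits(mk(c(1, 1, 2, 1), c(0, 10, 20, 30)), 30)
  expect_equal(v$node_id, c(1, 2, 1))
  # A then A after a 10-hour gap -> 2 visits
  v <- segment_visits(mk(c(1, 1), c(0, 600)), 30)
  expect_equal(nrow(v), 2)
  # empty input
  empty <- data.frame(user_id = character(), timestamp = base[0],
                      lat = numeric(), lon = numeric(), node_id = integer())
  expect_equal(nrow(segment_visits(empty, 30)), 0)
})

test_that("home identification uses visits then fixes then node id", {
  nd <- function(id, visits, fixes) data.frame(
    node_id = id, visit_count = visits, fix_count = fixes)
  expect_equal(identify_home(nd(1, 5, 9)), 1)
  expect_equal(identify_home(nd(1:2, c(10, 3), c(5, 50))), 1)
  # tie on visits -> higher fix count wins
  expect_equal(identify_home(nd(1:2, c(4, 4), c(80, 100))), 2)
  # full tie -> lowest node id
  expect_equal(identify_home(nd(1:2, c(4, 4), c(80, 80))), 1)
  expect_true(is.na(identify_home(nd(integer(), integer(), integer()))))
})

test_that("irrelevance flagging spares home and respects min_visits", {
  nodes <- data.frame(node_id = 1:3, visit_count = c(30L, 1L, 1L),
                      fix_count = c(60L, 2L, 2L),
                      is_home = c(TRUE, FALSE, FALSE))
  expect_false(any(flag_irrelevant(nodes, 1)$is_irrelevant))
  f <- flag_irrelevant(nodes, 2)
  expect_equal(f$is_irrelevant, c(FALSE, TRUE, TRUE))
  # home below the threshold is still never flagged
  solo <- data.frame(node_id = 1, visit_count = 1L, fix_count = 1L,
                     is_home = TRUE)
  expect_false(flag_irrelevant(solo, 2)$is_irrelevant)
})

test_that("stage-1 features: degenerate node sets and collinear distances", {
  one <- data.frame(node_id = 1, anchor_lat = 0, anchor_lon = 0,
                    visit_count = 3L, fix_count = 3L)
  visits <- data.frame(node_id = rep(1, 3))
  s <- stage1_features(one, visits, 3)
  expect_equal(s$n_places, 1)
  expect_true(is.na(s$mean_distance_m))
  expect_equal(s$visits_per_day, 1)

  # 3 collinear nodes 100 m apart: pairs 100, 100, 200
  dlat <- 100 / 111194.93
  three <- data.frame(node_id = 1:3, anchor_lat = c(0, dlat, 2 * dlat),
                      anchor_lon = 0, visit_count = 1L, fix_count = 1L)
  s3 <- stage1_features(three, data.frame(node_id = 1:3), 1)
  expect_equal(s3$min_distance_m, 100, tolerance = 1e-4)
  expect_equal(s3$max_distance_m, 200, tolerance = 1e-4)
  expect_equal(s3$mean_distance_m, 400 / 3, tolerance = 1e-4)
})

test_that("an end-to-end toy trace clusters into its three places", {
  gps <- toy_gps()
  cl <- cluster_fixes(gps)
  expect_equal(nrow(cl$nodes), 3)
  visits <- segment_visits(cl$assignment, 30)
  expect_equal(visits$node_id, c(1, 2, 1, 3))
  nodes <- mobstress:::annotate_nodes(cl$nodes, visits, 2)
  expect_true(nodes$is_home[1]) # A visited twice, others once
  expect_equal(nodes$is_irrelevant, c(FALSE, TRUE, TRUE))
})
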