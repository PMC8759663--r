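test_that("density map matches brute-force disc membership", {
  g <- 24
  expect_true(all(local_density_map(matrix(numeric(0), ncol = 2), 3, g) == 0L))
  # one agent exactly at a pixel center
  dm <- local_density_map(cbind(10.5, 12.5), 3, g)
  hits <- which(dm == 1L, arr.ind = TRUE)
  expected <- oracle_disc_pixels(10.5, 12.5, 3, g)
  expect_equal(sum(dm), nrow(expected))
  expect_setequal(paste(hits[, 1], hits[, 2]),
                  paste(expected$i, expected$j))
  # off-center position, non-trivial radius
  dm2 <- local_density_map(cbind(7.3, 4.9), 2.6, g)
  expected2 <- oracle_disc_pixels(7.3, 4.9, 2.6, g)
  expect_equal(sum(dm2), nrow(expected2))
  # linearity: two coincident agents double the map
  dm3 <- local_density_map(rbind(c(7.3, 4.9), c(7.3, 4.9)), 2.6, g)
  expect_equal(dm3, dm2 * 2L)
  expect_error(local_density_map(cbind(1, 1), -1, g), "radius")
})

test_that("radius-0 density is containing-pixel binning and sums to n", {
  set.seed(4)
  pos <- cbind(runif(500, 0, 32), runif(500, 0, 32))
  dm <- local_density_map(pos, 0, 32)
  expect_equal(sum(dm), 500L)
  expect_equal(dm[5, 9], sum(floor(pos[, 1]) == 4 & floor(pos[, 2]) == 8))
})

test_that("segmentation thresholds strictly, labels 8-connected, drops small components", {
  # uniform below (and exactly at) threshold: nothing detected
  expect_equal(nrow(segment_aggregates(matrix(40L, 20, 20))), 0L)
  # a 9-pixel supra-threshold component is discarded, a 10-pixel one kept
  m <- matrix(0L, 20, 20)
  m[3, 3:11] <- 41L
  expect_equal(nrow(segment_aggregates(m, min_area = 10)), 0L)
  m[3, 12] <- 41L
  det <- segment_aggregates(m, min_area = 10)
  expect_equal(nrow(det), 1L)
  expect_equal(det$area, 10L)
  # 8-connectivity: a diagonal chain is one component
  d <- matrix(0L, 20, 20)
  diag(d)[2:13] <- 41L
  expect_equal(nrow(segment_aggregates(d, min_area = 10)), 1L)
  # deterministic and idempotent
  expect_identical(segment_aggregates(m), segment_aggregates(m))
})

test_that("segmentation finds a planted dense cluster at its centroid", {
  set.seed(9)
  th <- runif(200, 0, 2 * pi)
  r <- 3 * sqrt(runif(200))
  pos <- cbind(40.2 + r * cos(th), 25.7 + r * sin(th))
  dm <- local_density_map(pos, 3, 96)
  det <- segment_aggregates(dm)
  expect_equal(nrow(det), 1L)
  expect_lt(sqrt((det$x - 40.2)^2 + (det$y - 25.7)^2), 1)
  # area cannot exceed the supra-threshold pixel count
  expect_lte(sum(det$area), sum(dm > 40))
})

test_that("linking: persistence, separation, and merge recording", {
  # one stationary detection over 10 frames -> one 10-point track
  d1 <- data.frame(frame = 1:10, x = 5, y = 5, area = 20)
  r1 <- link_tracks(d1, max_link_distance = 2)
  expect_equal(length(unique(r1$tracks$track_id)), 1L)
  expect_equal(nrow(r1$tracks), 10L)
  expect_equal(nrow(r1$merge_events), 0L)

  # two detections always farther apart than the gate -> two tracks, no merges
  d2 <- rbind(data.frame(frame = rep(1:5, each = 1), x = 0, y = 0, area = 1),
              data.frame(frame = 1:5, x = 30, y = 0, area = 1))
  r2 <- link_tracks(d2, max_link_distance = 3)
  expect_equal(length(unique(r2$tracks$track_id)), 2L)
  expect_equal(nrow(r2$merge_events), 0L)

  # two tracks converging onto one detection -> one 2-participant merge event
  d3 <- rbind(data.frame(frame = 1, x = c(0, 6), y = 0, area = 1),
              data.frame(frame = 2, x = c(1, 5), y = 0, area = 1),
              data.frame(frame = 3, x = 3, y = 0, area = 2),
              data.frame(frame = 4, x = 3, y = 0, area = 2))
  r3 <- link_tracks(d3, max_link_distance = 3)
  expect_equal(length(unique(r3$merge_events$event_id)), 1L)
  expect_equal(sum(r3$merge_events$event_id == 1), 2L)

  # three tracks converging -> one 3-participant event
  d4 <- rbind(data.frame(frame = 1, x = c(0, 4, 8), y = 0, area = 1),
              data.frame(frame = 2, x = 4, y = 0, area = 3))
  r4 <- link_tracks(d4, max_link_distance = 5)
  expect_equal(sum(r4$merge_events$event_id == 1), 3L)

  # track-count bookkeeping: final = initial - sum(participants - 1)
  for (r in list(r1, r2, r3, r4)) {
    ids <- unique(r$tracks$track_id)
    last_frame <- max(r$tracks$frame)
    final <- length(unique(r$tracks$track_id[r$tracks$frame == last_frame]))
    lost <- if (nrow(r$merge_events) > 0) {
      sum(tapply(r$merge_events$participant, r$merge_events$event_id,
                 function(p) length(p) - 1L))
    } else 0L
    expect_equal(final, length(ids) - lost)
  }
})

test_that("merge classification assigns cohorts and counts reduction", {
  # no merge events: everyone is a non-merger
  d1 <- data.frame(frame = rep(1:4, each = 2), x = rep(c(0, 20), 4),
                   y = 0, area = 1)
  r1 <- link_tracks(d1, max_link_distance = 3)
  c1 <- classify_merging(r1$tracks, r1$merge_events)
  expect_equal(unname(c1$fractions["non_merger"]), 1)
  expect_equal(c1$count_reduction, 0)

  # 10 tracks, one two-party merge: 2 two-spot mergers, 8 non-mergers
  xs <- seq(0, 90, by = 10)
  det <- do.call(rbind, lapply(1:3, function(f) {
    x <- xs
    if (f >= 2) x[2] <- x[1] # track 2 walks onto track 1's detection
    data.frame(frame = f, x = x[!duplicated(x)], y = 0, area = 1)
  }))
  r2 <- link_tracks(det, max_link_distance = 15)
  c2 <- classify_merging(r2$tracks, r2$merge_events)
  expect_equal(sum(c2$classes == "two_spot_merger"), 2L)
  expect_equal(sum(c2$classes == "non_merger"), 8L)
  expect_equal(c2$count_reduction, 1 / 10)

  # three-way convergence: all three are three-spot mergers
  d3 <- rbind(data.frame(frame = 1, x = c(0, 4, 8), y = 0, area = 1),
              data.frame(frame = 2, x = 4, y = 0, area = 3))
  r3 <- link_tracks(d3, max_link_distance = 5)
  c3 <- classify_merging(r3$tracks, r3$merge_events)
  expect_equal(unname(c3$classes), rep("three_spot_merger", 3))

  # survivor chain: B merges into A, then A drifts over and merges into C
  dch <- rbind(data.frame(frame = 1, x = c(0, 6, 30), y = 0, area = 1),
               data.frame(frame = 2, x = c(3, 30), y = 0, area = 1),
               data.frame(frame = 3, x = c(10, 30), y = 0, area = 1),
               data.frame(frame = 4, x = c(17, 30), y = 0, area = 1),
               data.frame(frame = 5, x = c(24, 30), y = 0, area = 1),
               data.frame(frame = 6, x = 28, y = 0, area = 2))
  rch <- link_tracks(dch, max_link_distance = 8)
  cch <- classify_merging(rch$tracks, rch$merge_events)
  expect_equal(sum(cch$classes == "three_spot_merger"), 1L)
  expect_equal(sum(cch$classes == "two_spot_merger"), 2L)
})
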