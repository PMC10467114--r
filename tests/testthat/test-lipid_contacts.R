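test_that("minimum distances honour the minimum-image convention", {
  topo <- protein_lipid_topology()
  coords <- array(0, c(1, 2, 3))
  coords[1, 2, ] <- c(0.3, 0, 0)
  expect_equal(min_distance_series(Trajectory(coords), topo,
                                   "role protein", "role lipid"), 0.3)
  coords[1, 2, ] <- c(0.4, 0, 0)
  traj <- Trajectory(coords, box = c(0.5, 10, 10))
  expect_equal(min_distance_series(traj, topo,
                                   "role protein", "role lipid"), 0.1)
})

test_that("group minimum distance equals a brute-force pair scan", {
  set.seed(23)
  atoms <- rbind(
    data.frame(name = "CA", element = "C", residue_seq = 1,
               residue_name = "GLY", chain = "A", protein = TRUE,
               lipid = FALSE)[rep(1, 10), ],
    data.frame(name = "C1", element = "C", residue_seq = 2,
               residue_name = "DOPC", chain = "L", protein = FALSE,
               lipid = TRUE)[rep(1, 10), ])
  topo <- Topology(atoms)
  for (rep_i in 1:5) {
    co <- array(rnorm(60, sd = 1), c(1, 20, 3))
    box <- c(2, 2, 2)
    traj <- Trajectory(co, box = box)
    got <- min_distance_series(traj, topo, 0:9, 10:19)
    # exhaustive O(n^2) oracle
    best <- Inf
    for (i in 1:10) for (j in 11:20) {
      dd <- co[1, i, ] - co[1, j, ]
      dd <- dd - box * round(dd / box)
      best <- min(best, sqrt(sum(dd^2)))
    }
    expect_equal(got, best, tolerance = 1e-12)
  }
})

test_that("dual-cutoff booking follows the hysteresis rule", {
  # hand-traced: enters below 0.55 at frame 0, survives 0.60 and 0.90
  # (below upper cutoff), ends at 1.20 >= 1.0
  ev <- book_events(c(0.40, 0.60, 0.90, 1.20))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$start_frame, 0L)
  expect_equal(ev$end_frame, 3L)
  # never below the lower cutoff: no event despite being under the upper
  expect_equal(nrow(book_events(c(0.80, 0.95, 0.90))), 0L)
  # always bound: one event closed at trajectory end
  ev <- book_events(rep(0.30, 7))
  expect_equal(ev, data.frame(start_frame = 0L, end_frame = 7L))
  # re-entry after an excursion above the upper cutoff starts a new event
  ev <- book_events(c(0.4, 1.2, 0.4, 0.7, 1.5))
  expect_equal(ev$start_frame, c(0L, 2L))
  expect_equal(ev$end_frame, c(1L, 4L))
})

test_that("booking degenerates to simple thresholding at equal cutoffs", {
  set.seed(4)
  d <- runif(500, 0.2, 2)
  crit <- contact_criteria(0.7, 0.7 + 1e-12)
  ev <- book_events(d, crit)
  inside <- logical(length(d))
  for (i in seq_len(nrow(ev)))
    inside[(ev$start_frame[i] + 1):ev$end_frame[i]] <- TRUE
  expect_equal(inside, d < 0.7)
})

test_that("booking is monotone in the cutoffs", {
  set.seed(8)
  for (i in 1:20) {
    d <- runif(200, 0.2, 1.6)
    base <- book_events(d, contact_criteria(0.55, 1.0))
    wider <- book_events(d, contact_criteria(0.55, 1.3))
    stricter <- book_events(d, contact_criteria(0.35, 1.0))
    # total in-contact frames never exceeds n_frames, events disjoint
    expect_lte(sum(base$end_frame - base$start_frame), length(d))
    if (nrow(base) > 1)
      expect_true(all(base$start_frame[-1] >= base$end_frame[-nrow(base)]))
    # raising the upper cutoff never shortens the total booked time
    expect_gte(sum(wider$end_frame - wider$start_frame),
               sum(base$end_frame - base$start_frame))
    # lowering the lower cutoff can only drop entry points
    expect_lte(nrow(stricter), nrow(base))
  }
})

test_that("contact statistics count occupancy and residence directly", {
  ev <- data.frame(residue = "A:1", species = "DOPC", molecule = "L:1",
                   start_frame = 0L, end_frame = 3L)
  st <- contact_stats(ev, n_frames = 10)
  expect_equal(st$occupancy_pct, 30)
  expect_equal(st$residence_frames, 3)
  expect_equal(st$n_events, 1L)
  # union-of-frames over two molecules of the same species
  ev2 <- data.frame(residue = "A:1", species = "DOPC",
                    molecule = c("L:1", "L:2"),
                    start_frame = c(0L, 5L), end_frame = c(2L, 7L))
  st2 <- contact_stats(ev2, n_frames = 10)
  expect_equal(st2$occupancy_pct, 40)
  expect_equal(st2$residence_frames, 2)
  expect_equal(st2$n_events, 2L)
  expect_error(contact_stats(ev, n_frames = 0), "empty trajectory")
})

test_that("Markov fixture statistics recover the analytic ground truth", {
  spec <- contact_kinetics_spec(p_on = 0.05, p_off = 0.10,
                                n_frames = 50000, seed = 31)
  sim <- make_contact_series(spec)
  ev <- book_events(sim$distances[, 1])
  ev$residue <- "A:1"; ev$species <- "DOPC"; ev$molecule <- "L:1"
  st <- contact_stats(ev, spec$n_frames)
  expect_lt(abs(st$occupancy_pct - 100 / 3), 1.5)
  expect_lt(abs(st$residence_frames - 10), 0.5)
  # survival-exponential estimator agrees on a memoryless process
  st2 <- contact_stats(ev, spec$n_frames, estimator = "survival-exp")
  expect_lt(abs(st2$residence_frames - 10), 1.5)
})

test_that("hotspot flags isolate a planted high-affinity population", {
  set.seed(77)
  stats_list <- list()
  for (r in 1:50) {
    hot <- r <= 5
    spec <- contact_kinetics_spec(p_on = if (hot) 0.10 else 0.01,
                                  p_off = if (hot) 0.05 else 0.30,
                                  n_frames = 5000, seed = 1000 + r)
    sim <- make_contact_series(spec)
    ev <- book_events(sim$distances[, 1])
    if (!nrow(ev)) next
    ev$residue <- sprintf("A:%d", r); ev$species <- "DOPC"
    ev$molecule <- "L:1"
    stats_list[[r]] <- contact_stats(ev, spec$n_frames)
  }
  st <- do.call(rbind, stats_list)
  # thresholds placed between the two planted populations:
  # hot ~ 66% occupancy / 20-frame dwell, cold ~ 3% / 3.3 frames
  flagged <- hotspot_flags(st, occ_threshold = 30, res_threshold = 10)
  expect_setequal(flagged$residue, sprintf("A:%d", 1:5))
  # degenerate thresholds
  expect_equal(nrow(hotspot_flags(st, 0, 0)), nrow(st))
  expect_equal(nrow(hotspot_flags(st, 101, 0)), 0L)
})

test_that("full trajectory driver books the same events as the series path", {
  topo <- protein_lipid_topology()
  d <- c(0.40, 0.60, 0.90, 1.20, 0.30, 0.30)
  coords <- array(0, c(length(d), 2, 3))
  coords[, 2, 1] <- d
  st <- lipid_contact_analysis(Trajectory(coords), topo)
  expect_equal(st$species, "DOPC")
  expect_equal(st$n_events, 2L)
  expect_equal(st$occupancy_pct, 100 * 5 / 6)
  expect_equal(st$residence_frames, 2.5)
})
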