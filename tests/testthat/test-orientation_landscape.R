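test_that("Kabsch recovers exact transforms and rejects degenerate input", {
  set.seed(2)
  ref <- matrix(rnorm(30), 10, 3)
  fit0 <- kabsch_superpose(ref, ref)
  expect_equal(fit0$R, diag(3), tolerance = 1e-12)
  expect_lt(fit0$rmsd, 1e-12)
  R25 <- rot_y(25)
  mob <- sweep(ref %*% t(R25), 2, c(0.3, -1, 2), `+`)
  fit <- kabsch_superpose(mob, ref)
  # recovered rotation undoes Ry(25): R %*% R25 = I
  expect_equal(fit$R %*% R25, diag(3), tolerance = 1e-8)
  expect_lt(fit$rmsd, 1e-8)
  expect_equal(abs(det(fit$R)), 1, tolerance = 1e-10)
  # collinear points are underdetermined
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(kabsch_superpose(line, line), "degenerate body")
  expect_error(kabsch_superpose(ref[1:4, ], ref), "pairing error")
})

test_that("Kabsch RMSD beats random probe rotations on noisy data", {
  set.seed(5)
  ref <- matrix(rnorm(30), 10, 3)
  mob <- sweep(ref %*% t(random_rotation()), 2, rnorm(3), `+`) +
    matrix(rnorm(30, sd = 0.01), 10, 3)
  fit <- kabsch_superpose(mob, ref)
  probe_rmsd <- function(R) {
    M <- sweep(mob, 2, colMeans(mob))
    P <- sweep(ref, 2, colMeans(ref))
    sqrt(mean(rowSums((M %*% t(R) - P)^2)))
  }
  probes <- replicate(1000, probe_rmsd(random_rotation()))
  expect_lte(fit$rmsd, min(probes) + 1e-12)
})

test_that("Euler decomposition matches elementary rotations", {
  e <- euler_from_rotation(diag(3))
  expect_equal(c(e$theta, e$psi), c(0, 0))
  e <- euler_from_rotation(rot_y(30))
  expect_equal(c(e$theta, e$psi), c(30, 0), tolerance = 1e-12)
  e <- euler_from_rotation(rot_x(45))
  expect_equal(c(e$theta, e$psi), c(0, 45), tolerance = 1e-12)
  expect_error(euler_from_rotation(matrix(1, 3, 3)), "invariant violation")
})

test_that("the z-rotation is invisible to the (theta, psi) pair", {
  set.seed(6)
  for (i in 1:250) {
    th <- runif(1, -89, 89)
    ps <- runif(1, -179.9, 180)
    ph <- runif(1, -180, 180)
    e <- euler_from_rotation(rot_z(ph) %*% rot_y(th) %*% rot_x(ps))
    expect_lt(abs(e$theta - th), 1e-9)
    expect_lt(abs(e$psi - ps), 1e-9)
    expect_false(e$gimbal)
  }
})

test_that("gimbal lock at |theta| = 90 is flagged, not mis-decomposed", {
  e <- euler_from_rotation(rot_y(90))
  expect_true(e$gimbal)
  expect_equal(e$theta, 90, tolerance = 1e-6)
  expect_equal(e$psi, 0)
})

test_that("an identity trajectory collapses to a single origin mode", {
  spec <- orientation_mixture_spec(
    data.frame(mean_theta = 0, mean_psi = 0, stdev = 1e-5, weight = 1),
    n_frames = 40, seed = 14)
  sim <- make_orientation_trajectory(spec)
  # overwrite with exact copies of the reference: poses must be (0, 0)
  co <- array(rep(spec$reference_coords, each = 40), c(40, 5, 3))
  ls <- build_landscape(Trajectory(co), sim$topology, reference = 0L,
                        align_sel = "name CA")
  expect_true(all(abs(ls$poses$theta_deg) < 1e-6))
  expect_true(all(abs(ls$poses$psi_deg) < 1e-6))
  expect_equal(nrow(ls$modes), 1L)
  expect_equal(c(ls$modes$theta_deg, ls$modes$psi_deg), c(0, 0))
})

test_that("two planted orientation clusters are recovered pure", {
  spec <- orientation_mixture_spec(
    data.frame(mean_theta = c(-30, 45), mean_psi = c(40, -120),
               stdev = c(5, 5), weight = c(0.5, 0.5)),
    n_frames = 600, seed = 8)
  sim <- make_orientation_trajectory(spec)
  ls <- build_landscape(sim$trajectory, sim$topology,
                        reference = spec$reference_coords,
                        align_sel = "name CA")
  expect_equal(nrow(ls$modes), 2L)
  got <- ls$modes[order(ls$modes$theta_deg), ]
  expect_lt(max(abs(got$theta_deg - c(-30, 45))), 3)
  expect_lt(max(abs(got$psi_deg - c(40, -120))), 3)
  for (m in seq_len(nrow(ls$modes))) {
    comp <- sim$truth$component[ls$members[[m]] + 1L]
    expect_gte(max(table(comp)) / length(comp), 0.95)
  }
  # per-frame poses equal the planted angles up to numerical noise
  expect_lt(max(abs(ls$poses$theta_deg - sim$truth$theta)), 1e-6)
  expect_lt(max(abs(ls$poses$psi_deg - sim$truth$psi)), 1e-6)
})

test_that("landscape density integrates to one", {
  spec <- orientation_mixture_spec(
    data.frame(mean_theta = 10, mean_psi = -30, stdev = 8, weight = 1),
    n_frames = 300, seed = 19)
  sim <- make_orientation_trajectory(spec)
  ls <- build_landscape(sim$trajectory, sim$topology,
                        reference = spec$reference_coords,
                        align_sel = "name CA")
  wt <- rep(1, length(ls$theta_grid)); wt[c(1, length(wt))] <- 0.5
  wp <- rep(1, length(ls$psi_grid)); wp[c(1, length(wp))] <- 0.5
  mass <- sum(outer(wt, wp) * ls$density)
  expect_equal(mass, 1, tolerance = 1e-3)
  expect_true(all(ls$density >= 0))
})

test_that("KDE agrees with an independent kernel density implementation", {
  skip_if_not_installed("MASS")
  spec <- orientation_mixture_spec(
    data.frame(mean_theta = 5, mean_psi = 15, stdev = 6, weight = 1),
    n_frames = 200, seed = 33)
  sim <- make_orientation_trajectory(spec)
  ls <- build_landscape(sim$trajectory, sim$topology,
                        reference = spec$reference_coords,
                        align_sel = "name CA", bandwidth = c(4, 4))
  # MASS::kde2d parameterises its normal kernel with h = 4 * sd
  k <- MASS::kde2d(ls$poses$theta_deg, ls$poses$psi_deg, h = c(16, 16),
                   n = c(181, 361), lims = c(-90, 90, -180, 180))
  expect_equal(max(abs(ls$density - k$z)), 0, tolerance = 1e-6)
})

test_that("frames_near uses the wrapped pose metric", {
  poses <- data.frame(replicate = 1, frame = 0:2,
                      theta_deg = c(0, 0, 50), psi_deg = c(-179, 10, 170),
                      rmsd_nm = 0, gimbal_flag = FALSE)
  ls <- list(poses = poses)
  # (0, 179) is 2 degrees from (0, -179) across the wrap, not 358
  hit <- frames_near(ls, 0, 179, k = 1)
  expect_equal(hit$frame, 0L)
  expect_equal(hit$distance_deg, 2)
  # exact pose query returns that frame
  expect_equal(frames_near(ls, 50, 170, k = 1)$frame, 2L)
  # k = n returns all, ordered as a brute-force sort
  expect_warning(all_hits <- frames_near(ls, 0, 0, k = 10), "k exceeds")
  brute <- order(angular_pose_distance(poses$theta_deg, poses$psi_deg, 0, 0))
  expect_equal(all_hits$frame, poses$frame[brute])
})
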