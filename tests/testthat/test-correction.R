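test_that("move executes commands exactly on an ideal manipulator and quantizes otherwise", {
  ideal <- ideal_manipulator()
  p <- move(ideal, position_xyz(1, 2, 3), c(0.5, -0.25, 0))
  expect_equal(c(p$x, p$y, p$z), c(1.5, 1.75, 3))
  # encoder quantization is round-half-to-even, before offset/noise
  q <- manipulator_model(c(0, 0, 0), c(0, 0, 0), encoder_step_um = 0.1)
  p1 <- move(q, position_xyz(0, 0, 0), c(0.14, 0, 0))
  expect_equal(p1$x, 0.1)
  # half-step commands resolve to the even step (dyadic step avoids FP ties)
  q2 <- manipulator_model(c(0, 0, 0), c(0, 0, 0), encoder_step_um = 0.5)
  p2 <- move(q2, position_xyz(0, 0, 0), c(1.25, 1.75, 0))
  expect_equal(p2$x, 1.0) # 2.5 steps -> even 2 -> 1.0 um
  expect_equal(p2$y, 2.0) # 3.5 steps -> even 4 -> 2.0 um
  # systematic offset shifts every executed move
  off <- manipulator_model(c(2, -1, 0.5), c(0, 0, 0), encoder_step_um = 0)
  p3 <- move(off, position_xyz(0, 0, 0), c(1, 1, 1))
  expect_equal(c(p3$x, p3$y, p3$z), c(3, 0, 1.5))
})

test_that("executed-move noise matches the configured SD in Monte Carlo", {
  m <- manipulator_model(c(0, 0, 0), c(3, 2, 1), encoder_step_um = 0)
  pf_seed <- 99
  xs <- pipettefix:::with_local_seed(pf_seed, {
    t(vapply(1:10000, function(i) {
      p <- move(m, position_xyz(0, 0, 0), c(5, 5, 5))
      c(p$x, p$y, p$z)
    }, numeric(3)))
  })
  sds <- apply(xs, 2, sd)
  expect_equal(sds, c(3, 2, 1), tolerance = 0.05)
  expect_equal(colMeans(xs), c(5, 5, 5), tolerance = 0.1)
})

test_that("a perfect estimator on an ideal manipulator converges in exactly one iteration", {
  tr <- correct_iteratively(
    ideal_manipulator(), oracle_estimator(), identity,
    initial_true = position_xyz(12, -7, 4), n_iters = 3
  )
  expect_equal(nrow(tr), 4)
  expect_equal(tr$t_xy[1], sqrt(12^2 + 7^2))
  expect_equal(tr$t_xy[2:4], rep(0, 3))
  expect_equal(tr$t_z_abs[2:4], rep(0, 3))
})

test_that("a fixed estimator bias leaves exactly that bias as the converged error", {
  b <- c(1.5, -0.5, 2)
  tr <- correct_iteratively(
    ideal_manipulator(), oracle_estimator(bias_um = b), identity,
    initial_true = position_xyz(20, 10, -5), n_iters = 3
  )
  for (k in 2:4) {
    expect_equal(c(tr$t_x[k], tr$t_y[k], tr$t_z[k]), b, tolerance = 1e-12)
  }
})

test_that("an xy-only estimator corrects xy but never touches z", {
  est_xy <- function(scene) {
    tibble::tibble(x = scene$x, y = scene$y, z = NA_real_, detected = TRUE)
  }
  tr <- correct_iteratively(ideal_manipulator(), est_xy, identity,
                            initial_true = position_xyz(5, 5, 4), n_iters = 2)
  expect_equal(tr$t_xy[3], 0)
  expect_equal(tr$t_z, rep(4, 3))
})

test_that("a detection failure marks the trajectory failed and stops corrections", {
  est_fail <- function(scene) {
    tibble::tibble(x = scene$x, y = scene$y, z = scene$z, detected = FALSE)
  }
  tr <- correct_iteratively(ideal_manipulator(), est_fail, identity,
                            initial_true = position_xyz(5, 0, 0), n_iters = 3)
  expect_true(all(tr$failed))
  expect_equal(nrow(tr), 1) # no moves were commanded
  expect_equal(tr$t_xy, 5)
})

test_that("convergence summaries report quartiles and SD-radius fractions", {
  # all-zero trajectories: every fraction 1, every quartile 0
  zero <- tibble::tibble(
    trial = rep(1:3, each = 2), iteration = rep(0:1, 3),
    t_x = 0, t_y = 0, t_z = 0, t_xy = 0, t_z_abs = 0, failed = FALSE
  )
  s0 <- convergence_summary(zero)
  expect_true(all(s0$median_t_xy == 0 & s0$q3_t_xy == 0))
  expect_true(all(s0$frac_within_xy == 1 & s0$frac_within_z == 1))
  # isotropic Gaussian xy errors: radial fractions approach the Rayleigh
  # values 1 - exp(-1/2) and 1 - exp(-2) (distinguishing the radial from the
  # per-axis convention)
  set.seed(17)
  n <- 20000
  g <- tibble::tibble(
    trial = seq_len(n), iteration = 0L,
    t_x = rnorm(n, 0, 0.7), t_y = rnorm(n, 0, 0.7), t_z = rnorm(n, 0, 0.5)
  )
  g$t_xy <- sqrt(g$t_x^2 + g$t_y^2)
  g$t_z_abs <- abs(g$t_z)
  g$failed <- FALSE
  sg <- convergence_summary(g)
  expect_equal(sg$frac_within_1sd_xy, 1 - exp(-1 / 2), tolerance = 0.02)
  expect_equal(sg$frac_within_2sd_xy, 1 - exp(-2), tolerance = 0.02)
  # per-axis z convention: ~68% / 95% for a Gaussian
  expect_equal(sg$frac_within_1sd_z, 0.683, tolerance = 0.02)
  expect_equal(sg$frac_within_2sd_z, 0.954, tolerance = 0.02)
})

test_that("correction trials are reproducible and medians shrink across iterations", {
  est <- oracle_estimator(noise_sd_um = 0.4, noise_scale_per_um = 0.05)
  man <- encoder_limited_manipulator()
  t1 <- run_correction_trials(100, man, est, identity, n_iters = 3, seed = 23)
  t2 <- run_correction_trials(100, man, est, identity, n_iters = 3, seed = 23)
  expect_identical(t1, t2)
  s <- convergence_summary(t1)
  expect_true(all(diff(s$median_t_xy[1:3]) < 0))
  expect_lt(s$median_t_xy[s$iteration == 2], 2.5)
})
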