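#' Simulated micromanipulator error model
#'
#' A commanded move is quantized to the encoder step (round half to even),
#' then perturbed by a fixed systematic offset and per-move Gaussian noise.
#' The defaults model the long-move regime (e.g., returning from a cleaning
#' bath), where three-axis manipulators accumulate errors on the order of
#' 10 um; short corrective moves on a well-calibrated stage are better
#' described by a near-[ideal_manipulator()] with only encoder quantization.
#'
#' @param systematic_offset_um Length-3 fixed offset added to every executed
#'   move (um).
#' @param move_noise_sd_um Length-3 per-move Gaussian SD (um).
#' @param encoder_step_um Encoder quantization of commanded moves (um);
#'   0 disables quantization.
#' @param seed Integer seed recorded with the model (draws are taken from the
#'   caller's seeded RNG stream; top-level simulation entry points seed it).
#' @return An object of class `manipulator_model`.
#' @export
manipulator_model <- function(systematic_offset_um = c(2, 2, 2),
                              move_noise_sd_um = c(3, 3, 3),
                              encoder_step_um = 0.1, seed = 1L) {
  stopifnot(length(systematic_offset_um) == 3, length(move_noise_sd_um) == 3,
            all(move_noise_sd_um >= 0), encoder_step_um >= 0)
  structure(list(systematic_offset_um = as.numeric(systematic_offset_um),
                 move_noise_sd_um = as.numeric(move_noise_sd_um),
                 encoder_step_um = encoder_step_um, seed = as.integer(seed)),
            class = "manipulator_model")
}

#' An error-free manipulator (no offset, no noise, no quantization)
#' @return A `manipulator_model`.
#' @export
ideal_manipulator <- function() {
  manipulator_model(c(0, 0, 0), c(0, 0, 0), encoder_step_um = 0)
}

#' Encoder-limited manipulator for short corrective moves
#'
#' No systematic offset, 0.1 um per-move noise, and 0.1 um encoder step —
#' the regime in which the only visible positioning floor is the stepper
#' encoder discretization.
#'
#' @param encoder_step_um Encoder step (um).
#' @param move_noise_sd_um Scalar per-axis noise SD (um).
#' @return A `manipulator_model`.
#' @export
encoder_limited_manipulator <- function(encoder_step_um = 0.1,
                                        move_noise_sd_um = 0.1) {
  manipulator_model(c(0, 0, 0), rep(move_noise_sd_um, 3), encoder_step_um)
}

#' Execute a commanded move on the simulated manipulator
#'
#' `executed = quantize(command, encoder_step) + systematic_offset + noise`;
#' the new true position is `current_true + executed`. Noise is drawn from
#' the current RNG stream (seed at the simulation entry point).
#'
#' @param manipulator A [manipulator_model()].
#' @param current_true Current true position (one-row tibble from
#'   [position_xyz()] or length-3 numeric).
#' @param command Length-3 commanded displacement (um).
#' @return The new true position as a one-row [position_xyz()] tibble.
#' @export
move <- function(manipulator, current_true, command) {
  stopifnot(length(command) == 3, all(is.finite(command)))
  cur <- if (is.data.frame(current_true)) {
    c(current_true$x, current_true$y, current_true$z)
  } else {
    as.numeric(current_true)
  }
  step <- manipulator$encoder_step_um
  executed <- if (step > 0) round(command / step) * step else command
  executed <- executed + manipulator$systematic_offset_um +
    stats::rnorm(3, 0, manipulator$move_noise_sd_um)
  position_xyz(cur[1] + executed[1], cur[2] + executed[2], cur[3] + executed[3])
}

#' Iterative proportional feedback correction of the pipette position
#'
#' Runs the closed loop: render the scene at the current true position,
#' estimate the tip, form the measured error `m = desired - estimate` (the
#' only observable error — the true error never enters the loop), command a
#' move of `gain * m`, and repeat. The trajectory records the pre-correction
#' state, so it has `n_iters + 1` rows.
#'
#' An estimator that reports `detected = FALSE` (the template-matching
#' baseline's failure state) marks the trajectory failed from that iteration
#' on; no further moves are commanded. An estimator with `z = NA` (xy-only
#' baseline) leaves z uncorrected.
#'
#' @param manipulator A [manipulator_model()].
#' @param estimator Function mapping a scene to a one-row tibble with `x`,
#'   `y`, `z` (um) and optionally `detected`; see [oracle_estimator()],
#'   [cnn_estimator()], [xcorr_estimator()].
#' @param scene_renderer Function mapping a true position to the scene the
#'   estimator sees (an image, or the position itself for
#'   [oracle_estimator()]); see [make_scene_renderer()].
#' @param desired Target position (one-row tibble).
#' @param initial_true True position before correction (one-row tibble).
#' @param n_iters Number of correction iterations (the published loop ran
#'   1-4 and settled on 2).
#' @param gain Proportional gain on the measured error (1 = full correction).
#' @return A tibble with one row per iteration 0..n_iters: true and
#'   estimated positions, true-error components `t_x, t_y, t_z`, magnitudes
#'   `t_xy`, `t_z_abs`, and `failed`.
#' @export
correct_iteratively <- function(manipulator, estimator, scene_renderer,
                                desired = position_xyz(0, 0, 0),
                                initial_true, n_iters = 2, gain = 1) {
  stopifnot(n_iters >= 1)
  d <- c(desired$x, desired$y, desired$z)
  true_pos <- position_xyz(initial_true$x, initial_true$y, initial_true$z)
  rec <- matrix(NA_real_, n_iters + 1, 9)
  failed_at <- rep(FALSE, n_iters + 1)
  n_rec <- 0L
  for (k in 0:n_iters) {
    est <- estimator(scene_renderer(true_pos))
    detected <- if (!is.null(est$detected)) isTRUE(est$detected) else TRUE
    n_rec <- n_rec + 1L
    failed_at[n_rec] <- !detected || (n_rec > 1L && failed_at[n_rec - 1L])
    rec[n_rec, ] <- c(k, true_pos$x, true_pos$y, true_pos$z,
                      est$x, est$y, est$z,
                      true_pos$x - d[1], true_pos$y - d[2])
    if (k == n_iters || failed_at[n_rec]) break
    m <- c(d[1] - est$x, d[2] - est$y,
           if (is.na(est$z)) 0 else d[3] - est$z)
    true_pos <- move(manipulator, true_pos, gain * m)
  }
  rec <- rec[seq_len(n_rec), , drop = FALSE]
  t_x <- rec[, 8]; t_y <- rec[, 9]; t_z <- rec[, 4] - d[3]
  out <- tibble::tibble(
    iteration = as.integer(rec[, 1]),
    true_x = rec[, 2], true_y = rec[, 3], true_z = rec[, 4],
    est_x = rec[, 5], est_y = rec[, 6], est_z = rec[, 7],
    t_x = t_x, t_y = t_y, t_z = t_z,
    t_xy = sqrt(t_x^2 + t_y^2), t_z_abs = abs(t_z),
    failed = failed_at[seq_len(n_rec)]
  )
  attr(out, "desired") <- d
  out
}

#' Run many seeded correction trials
#'
#' Draws initial true-position errors uniformly in the
#' `±xy_range_um x ±z_range_um` box around `desired` (the randomized initial
#' placement of the testing workflow) and runs [correct_iteratively()] for
#' each.
#'
#' @inheritParams correct_iteratively
#' @param n_trials Number of trials.
#' @param xy_range_um,z_range_um Half-widths of the initial-error box (um).
#' @param seed Integer seed covering initial draws, manipulator noise, and
#'   any estimator noise.
#' @return A tibble of stacked trajectories with a `trial` column.
#' @export
run_correction_trials <- function(n_trials, manipulator, estimator,
                                  scene_renderer,
                                  desired = position_xyz(0, 0, 0),
                                  xy_range_um = 27, z_range_um = 6,
                                  n_iters = 2, gain = 1, seed = 1L) {
  with_local_seed(seed, {
    inits <- tibble::tibble(
      x = desired$x + stats::runif(n_trials, -xy_range_um, xy_range_um),
      y = desired$y + stats::runif(n_trials, -xy_range_um, xy_range_um),
      z = desired$z + stats::runif(n_trials, -z_range_um, z_range_um)
    )
    purrr::map_dfr(seq_len(n_trials), function(i) {
      tr <- correct_iteratively(manipulator, estimator, scene_renderer,
                                desired, inits[i, ], n_iters, gain)
      dplyr::mutate(tr, trial = i, .before = 1)
    })
  })
}

#' Per-iteration convergence summary of correction trajectories
#'
#' Summarizes stacked trajectories the way the convergence figures report
#' them: per-iteration quartiles and medians of the true-error magnitudes,
#' the fraction of attempts within the patch-clamp-relevant windows (default
#' 2.5 um in xy — half a typical 10 um cell — and 3 um in z), and the
#' fraction within one and two SDs of the target, where the SD radius is the
#' pooled per-axis SD at that iteration (for isotropic Gaussian xy errors the
#' 1-SD and 2-SD fractions approach the Rayleigh values `1 - exp(-1/2)` and
#' `1 - exp(-2)`).
#'
#' @param trajectories Tibble from [run_correction_trials()] (or a single
#'   trajectory).
#' @param xy_threshold_um,z_threshold_um Success windows (um).
#' @return A tibble with one row per iteration.
#' @export
convergence_summary <- function(trajectories, xy_threshold_um = 2.5,
                                z_threshold_um = 3) {
  stopifnot(nrow(trajectories) >= 1)
  trajectories |>
    dplyr::group_by(.data$iteration) |>
    dplyr::summarise(
      n = dplyr::n(),
      q1_t_xy = stats::quantile(.data$t_xy, 0.25),
      median_t_xy = stats::median(.data$t_xy),
      q3_t_xy = stats::quantile(.data$t_xy, 0.75),
      q1_t_z = stats::quantile(.data$t_z_abs, 0.25),
      median_t_z = stats::median(.data$t_z_abs),
      q3_t_z = stats::quantile(.data$t_z_abs, 0.75),
      frac_within_xy = mean(.data$t_xy <= xy_threshold_um),
      frac_within_z = mean(.data$t_z_abs <= z_threshold_um),
      sd_xy_axis = stats::sd(c(.data$t_x, .data$t_y)),
      sd_z_axis = stats::sd(.data$t_z),
      frac_within_1sd_xy = mean(.data$t_xy <= stats::sd(c(.data$t_x, .data$t_y))),
      frac_within_2sd_xy = mean(.data$t_xy <= 2 * stats::sd(c(.data$t_x, .data$t_y))),
      frac_within_1sd_z = mean(.data$t_z_abs <= stats::sd(.data$t_z)),
      frac_within_2sd_z = mean(.data$t_z_abs <= 2 * stats::sd(.data$t_z)),
      frac_failed = mean(.data$failed),
      .groups = "drop"
    )
}

#' Estimators for the correction loop
#'
#' `oracle_estimator()` reads the true position directly (optionally with a
#' fixed bias and Gaussian noise — a stand-in for an estimator of known error
#' scale; use with `scene_renderer = identity`). `cnn_estimator()` wraps
#' [predict_tip()]; `xcorr_estimator()` wraps [detect_tip_xcorr()] (xy only:
#' z is reported `NA` because template matching carries no depth cue).
#'
#' @param bias_um,noise_sd_um Length-3 (or scalar) estimator error bias and
#'   SD in um; the estimator error is `c = true - estimate = bias + noise`.
#' @param noise_scale_per_um Optional state-dependent noise: the per-axis SD
#'   grows by this fraction of the distance from the origin (an image-based
#'   estimator degrades with eccentricity and defocus; near focus the SD is
#'   just `noise_sd_um`). Default 0 (homogeneous noise).
#' @return A function `scene -> one-row tibble (x, y, z, detected)`.
#' @export
oracle_estimator <- function(bias_um = c(0, 0, 0), noise_sd_um = c(0, 0, 0),
                             noise_scale_per_um = 0) {
  bias <- rep_len(as.numeric(bias_um), 3)
  sd <- rep_len(as.numeric(noise_sd_um), 3)
  function(scene) {
    r <- sqrt(scene$x^2 + scene$y^2 + scene$z^2)
    err <- bias + stats::rnorm(3, 0, sd + noise_scale_per_um * r)
    tibble::tibble(x = scene$x - err[1], y = scene$y - err[2],
                   z = scene$z - err[3], detected = TRUE)
  }
}

#' @rdname oracle_estimator
#' @param model A trained [pipette_cnn][build_model()].
#' @param camera The [camera_model()] of the rendered scenes.
#' @param spec The [preproc_spec()] used at training time.
#' @export
cnn_estimator <- function(model, camera, spec) {
  function(scene) {
    p <- predict_tip(model, scene, camera, spec)
    tibble::tibble(x = p$x, y = p$y, z = p$z, detected = TRUE)
  }
}

#' @rdname oracle_estimator
#' @param template An [xcorr_template()].
#' @param threshold Detection threshold on the peak NCC score.
#' @export
xcorr_estimator <- function(template, camera, threshold = 0.6) {
  function(scene) {
    det <- detect_tip_xcorr(scene, template, threshold)
    um <- px_to_um(
      tibble::tibble(
        col_px = min(max(det$col_px, 0), camera$cols_px - 1),
        row_px = min(max(det$row_px, 0), camera$rows_px - 1)
      ), camera)
    tibble::tibble(x = um$x, y = um$y, z = NA_real_, detected = det$detected)
  }
}

#' Scene renderer for closed-loop simulations
#'
#' Returns a function mapping a true pipette position to a rendered image.
#' Each call draws a fresh background (seeded from `seed` plus an internal
#' counter), emulating the frame-to-frame variation of a live rig.
#'
#' @param camera A [camera_model()].
#' @param background A [background_spec()].
#' @param pipette A [pipette_spec()]; its tip is overridden per call.
#' @param defocus A [defocus_model()].
#' @param seed Integer base seed for the per-frame background draws.
#' @return A function `position -> intensity matrix`.
#' @export
make_scene_renderer <- function(camera, background = background_spec(),
                                pipette = pipette_spec(),
                                defocus = defocus_model(), seed = 1L) {
  counter <- new.env(parent = emptyenv())
  counter$i <- 0L
  function(true_pos) {
    counter$i <- counter$i + 1L
    p <- pipette
    p$tip <- position_xyz(true_pos$x, true_pos$y, true_pos$z)
    frame_seed <- as.integer((as.numeric(seed) * 7919 + counter$i) %% 2147483647)
    render_pipette_image(p, background, camera, seed = frame_seed,
                         defocus = defocus)$image
  }
}
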