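# Shared fixtures. The desk-scale study conditions (camera, background,
# placement ranges) are defined once here; the trained model is built lazily
# and cached so the model and acceptance tests share one training run.

desk_cam <- function() desk_camera()

desk_background <- function() background_spec("slice", texture_sd = 0.15)

desk_preproc <- function() preproc_spec(out_side_px = 64L)

desk_protocol <- function(seed) acquisition_protocol(xy_range_um = 9, seed = seed)

.fixture_cache <- new.env(parent = emptyenv())

# 2000-image (500 positions x 4 flips) training run over mixed plain/slice
# backgrounds, 10 epochs, fixed seeds; also renders the 200-image held-out
# test set.
desk_experiment <- function() {
  if (!is.null(.fixture_cache$experiment)) return(.fixture_cache$experiment)
  cam <- desk_cam()
  bg <- desk_background()
  spec <- desk_preproc()
  mk <- function(n, seed) {
    generate_mixed_dataset(desk_protocol(seed), n, "test", cam,
                           slice_background = bg)
  }
  tr_ds <- mk(500, 101L)
  va_ds <- mk(100, 102L)
  te_ds <- mk(200, 103L)
  tr <- build_model_set(tr_ds$manifest, tr_ds$images, spec, cam, augment = TRUE)
  va <- build_model_set(va_ds$manifest, va_ds$images, spec, cam)
  model <- build_model("small", 64L, seed = 7L)
  model <- train_cnn(model, tr, va,
                     train_config(max_epochs = 10L, lr0 = 3e-3,
                                  lr_drop_factor = 0.3,
                                  lr_drop_period_epochs = 4L, seed = 7L))
  pred <- predict_tip(model, te_ds$images, cam, spec)
  truth <- px_to_um(te_ds$manifest, cam)
  errors <- tibble::tibble(
    x = pred$x - truth$x,
    y = pred$y - truth$y,
    z = pred$z - te_ds$manifest$z_um,
    xy = sqrt((pred$x - truth$x)^2 + (pred$y - truth$y)^2),
    z_true = te_ds$manifest$z_um
  )
  .fixture_cache$experiment <- list(
    model = model, camera = cam, spec = spec, background = bg,
    test_ds = te_ds, pred = pred, errors = errors
  )
  .fixture_cache$experiment
}

# Brute-force two-sided Fisher p: enumerate admissible tables with the
# observed margins and sum the probabilities (products of binomial
# coefficients over the margin total) of those no more probable than the
# observed table.
fisher_enum <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c; total <- m + n
  if (m == 0 || n == 0 || k == 0 || (b + d) == 0) return(1)
  support <- max(0, k - n):min(k, m)
  prob <- vapply(support, function(x) {
    choose(m, x) * choose(n, k - x) / choose(total, k)
  }, numeric(1))
  p_obs <- choose(m, a) * choose(n, k - a) / choose(total, k)
  min(1, sum(prob[prob <= p_obs * (1 + 1e-7)]))
}

# Direct double-loop zero-normalized cross-correlation (oracle for ncc_map).
ncc_direct <- function(image, template) {
  ht <- nrow(template); wt <- ncol(template)
  nr <- nrow(image) - ht + 1L; nc <- ncol(image) - wt + 1L
  out <- matrix(0, nr, nc)
  tc <- template - mean(template)
  for (r in seq_len(nr)) {
    for (cc in seq_len(nc)) {
      win <- image[r:(r + ht - 1L), cc:(cc + wt - 1L)]
      wc <- win - mean(win)
      den <- sqrt(sum(wc^2) * sum(tc^2))
      out[r, cc] <- if (den <= 1e-12) 0 else sum(wc * tc) / den
    }
  }
  out
}
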