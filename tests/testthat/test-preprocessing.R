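test_that("contrast stretch maps the mean +/- k sigma window onto [0, 1]", {
  # sigma = 0 rule
  expect_true(all(contrast_stretch(matrix(0.3, 5, 5)) == 0.5))
  # hand-evaluated example with population SD
  v <- c(0, 0.25, 0.5, 0.75, 1)
  out <- contrast_stretch(matrix(v, 1))
  s <- sqrt(mean((v - 0.5)^2)) # 0.35355...
  expect_equal(as.vector(out), (v - (0.5 - 2 * s)) / (4 * s))
  expect_equal(as.vector(out), c(0.14645, 0.32322, 0.5, 0.67678, 0.85355),
               tolerance = 1e-4)
  # endpoints: an image built to have mean 0.5 and population SD 0.25, so
  # its window is exactly [0, 1]: the endpoint pixels map to 0 and 1 and the
  # mean pixel to 0.5
  img2 <- matrix(c(0, 1, rep(0.5, 6)), 2)
  out2 <- contrast_stretch(img2)
  expect_equal(out2[1, 1], 0)
  expect_equal(out2[2, 1], 1)
  expect_equal(out2[1, 2], 0.5)
})

test_that("contrast stretch is affine-invariant and monotone", {
  set.seed(2)
  img <- matrix(runif(30 * 40), 30)
  for (a in c(0.5, 3)) {
    for (b in c(-1, 0.7)) {
      expect_lt(max(abs(contrast_stretch(a * img + b) - contrast_stretch(img))),
                1e-9)
    }
  }
  ord <- order(as.vector(img))
  out <- as.vector(contrast_stretch(img))
  expect_true(all(diff(out[ord]) >= -1e-12))
})

test_that("centre crop and resize transform annotations exactly", {
  cam <- camera_model()
  spec <- preproc_spec(out_side_px = 224L)
  img <- matrix(0.5, cam$rows_px, cam$cols_px)
  ann <- tibble::tibble(image_id = "a", col_px = 639.5, row_px = 511.5,
                        z_um = 2, split = "test")
  out <- crop_resize(img, ann, spec, cam)
  expect_equal(dim(out$image), c(224, 224))
  expect_equal(out$annotation$col_px, (639.5 - 128) * 224 / 1024) # 111.890625
  expect_equal(out$annotation$row_px, 511.5 * 224 / 1024)
  expect_equal(out$annotation$z_um, 2)
  expect_false(out$annotation$off_crop)
  # a tip inside the cropped-away margin is flagged, not dropped
  ann2 <- dplyr::mutate(ann, col_px = 100)
  expect_true(crop_resize(img, ann2, spec, cam)$annotation$off_crop)
  # inverse mapping restores the original pixel coordinates
  restored <- invert_crop_resize(out$annotation, spec, cam)
  expect_lt(abs(restored$col_px - 639.5), 1e-9)
  expect_lt(abs(restored$row_px - 511.5), 1e-9)
})

test_that("flip augmentation transforms coordinates and is a Klein four-group", {
  set.seed(4)
  img <- matrix(runif(224 * 224), 224)
  ann <- tibble::tibble(image_id = "a", col_px = 10, row_px = 20, z_um = -3)
  aug <- flip_augment(img, ann)
  expect_named(aug, c("identity", "h", "v", "hv"))
  expect_equal(aug$h$annotation$col_px, 213)
  expect_equal(aug$h$annotation$row_px, 20)
  expect_equal(aug$v$annotation$col_px, 10)
  expect_equal(aug$v$annotation$row_px, 203)
  expect_equal(aug$hv$annotation$col_px, 213)
  expect_equal(aug$hv$annotation$row_px, 203)
  expect_true(all(vapply(aug, function(p) p$annotation$z_um, numeric(1)) == -3))
  # involution: flipping twice restores image and annotation
  for (f in c("h", "v", "hv")) {
    again <- flip_augment(aug[[f]]$image, aug[[f]]$annotation)[[f]]
    expect_identical(again$image, img)
    expect_equal(again$annotation$col_px, ann$col_px)
    expect_equal(again$annotation$row_px, ann$row_px)
  }
  # closure: h then v equals hv
  hv_via_compose <- flip_augment(aug$h$image, aug$h$annotation)$v
  expect_identical(hv_via_compose$image, aug$hv$image)
  expect_equal(hv_via_compose$annotation$col_px, aug$hv$annotation$col_px)
  expect_equal(hv_via_compose$annotation$row_px, aug$hv$annotation$row_px)
})

test_that("augmentation yields 4n pairs and the renderer commutes with flips", {
  cam <- desk_cam()
  bg <- background_spec("plain", illumination_tilt = 0)
  ds <- generate_dataset(desk_protocol(21L), 3, "test", cam, bg)
  spec <- desk_preproc()
  ms <- build_model_set(ds$manifest, ds$images, spec, cam, augment = TRUE)
  expect_equal(dim(ms$x)[4], 12) # 3 raw -> identity + three flips each
  # rendering at the hv-mirrored position ~ hv-flipping the rendered image:
  # the desk frame centre pixel is ((cols-1)/2, (rows-1)/2), so mirroring a
  # tip through the stage origin mirrors its pixel annotation
  p <- pipette_spec(tip = position_xyz(3, 2, 0))
  sc <- render_pipette_image(p, bg, cam, seed = 9)
  p_m <- pipette_spec(tip = position_xyz(-3, -2, 0),
                      approach_angle_deg = 24 + 180)
  sc_m <- render_pipette_image(p_m, bg, cam, seed = 9)
  flipped <- pipettefix:::flip_image(sc$image, "hv")
  expect_lt(mean(abs(sc_m$image - flipped)), 0.02)
})
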