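test_that("rendering is deterministic and annotated at the sharpest point", {
  cam <- desk_cam()
  p <- pipette_spec(tip = position_xyz(2, -3, 0))
  bg <- background_spec("plain")
  sc1 <- render_pipette_image(p, bg, cam, seed = 5)
  sc2 <- render_pipette_image(p, bg, cam, seed = 5)
  expect_identical(sc1$image, sc2$image)
  expect_true(all(sc1$image >= 0 & sc1$image <= 1))
  expect_false(sc1$annotation$off_frame)
  # the maximal intensity gradient lies within 1 px of the annotated tip
  img <- sc1$image
  gx <- img[, -1] - img[, -ncol(img)]
  gy <- img[-1, ] - img[-nrow(img), ]
  gm <- gx[-nrow(gx), ]^2 + gy[, -ncol(gy)]^2
  pk <- which(gm == max(gm), arr.ind = TRUE)[1, ]
  expect_lt(abs(pk[["col"]] - 0.5 - sc1$annotation$col_px), 1)
  expect_lt(abs(pk[["row"]] - 0.5 - sc1$annotation$row_px), 1)
})

test_that("defocus blurs the image monotonically and asymmetry encodes the sign", {
  cam <- desk_cam()
  bg <- background_spec("plain")
  mag <- function(i) mean(abs(i[, -1] - i[, -ncol(i)]))
  grads <- vapply(c(0, 3, 6, 10), function(z) {
    mag(render_pipette_image(pipette_spec(tip = position_xyz(0, 0, z)),
                             bg, cam, seed = 3)$image)
  }, numeric(1))
  expect_true(all(diff(grads) < 0))
  # above vs below focus differ (defocus sign is identifiable)
  up <- render_pipette_image(pipette_spec(tip = position_xyz(0, 0, 4)),
                             bg, cam, seed = 3)$image
  dn <- render_pipette_image(pipette_spec(tip = position_xyz(0, 0, -4)),
                             bg, cam, seed = 3)$image
  expect_gt(mean(up) - mean(dn), 1e-4)
})

test_that("an off-frame tip is flagged but the image still renders", {
  cam <- desk_cam()
  p <- pipette_spec(tip = position_xyz(50, 0, 0))
  sc <- render_pipette_image(p, background_spec("plain"), cam, seed = 1)
  expect_true(sc$annotation$off_frame)
  expect_equal(dim(sc$image), c(cam$rows_px, cam$cols_px))
})

test_that("train-style acquisition steps z down to a limit and back up", {
  pf <- asNamespace("pipettefix")
  pro <- acquisition_protocol(z_step_range_um = c(10, 10), z_train_max_um = 35,
                              z_train_up_max_um = 25, seed = 4)
  zs <- pipettefix:::with_local_seed(4, pf$train_z_sequence(pro))
  expect_equal(zs[1], 0)
  down <- zs[zs < 0]
  up <- zs[zs > 0]
  expect_equal(down, -seq(10, by = 10, length.out = length(down)))
  expect_true(length(down) >= 1 && min(down) >= -35)
  expect_true(all(up == seq(10, by = 10, length.out = length(up))))
  expect_lte(max(c(up, 0)), 25)
  # a full train-style dataset shares xy within each position series
  cam <- desk_cam()
  ds <- generate_dataset(acquisition_protocol(xy_range_um = 9, seed = 6), 2,
                         "train", cam, background_spec("plain"))
  man <- ds$manifest
  expect_true(all(man$split == "train"))
  xy_per_pos <- unique(round(man$col_px, 6))
  expect_equal(length(xy_per_pos), 2) # one xy per position, many z
})

test_that("test-style datasets cover the stated box uniformly and reproducibly", {
  cam <- desk_cam()
  ds <- generate_dataset(desk_protocol(31L), 300, "test", cam,
                         background_spec("plain"))
  expect_equal(nrow(ds$manifest), 300)
  um <- px_to_um(ds$manifest, cam)
  expect_true(all(abs(um$x) <= 9 & abs(um$y) <= 9))
  expect_true(all(abs(ds$manifest$z_um) <= 6))
  # same protocol seed, same manifest
  ds2 <- generate_dataset(desk_protocol(31L), 300, "test", cam,
                          background_spec("plain"))
  expect_identical(ds$manifest, ds2$manifest)
  # x positions are uniform on the box (KS on the protocol draws themselves)
  pro <- acquisition_protocol(seed = 77)
  xs <- pipettefix:::with_local_seed(pro$seed, runif(5000, -27, 27))
  ks <- stats::ks.test(xs, "punif", -27, 27)
  expect_gt(ks$p.value, 0.01)
})

test_that("manifests round-trip bit-exactly through CSV and JSON", {
  cam <- desk_cam()
  ds <- generate_dataset(desk_protocol(41L), 5, "test", cam,
                         background_spec("plain"),
                         out_dir = file.path(tempdir(), "pfx_ds"))
  man <- ds$manifest
  csv <- read_manifest(file.path(tempdir(), "pfx_ds", "manifest.csv"))
  expect_equal(as.data.frame(csv), as.data.frame(man))
  jpath <- file.path(tempdir(), "pfx_ds", "manifest.json")
  write_manifest(man, jpath)
  jman <- read_manifest(jpath)
  expect_equal(as.data.frame(jman), as.data.frame(man))
  # images were quantized to 8 bits on disk
  img <- read_image(ds$manifest$path[1])
  expect_true(all(abs(img * 255 - round(img * 255)) < 1e-9))
  unlink(file.path(tempdir(), "pfx_ds"), recursive = TRUE)
})

test_that("the renderer's ground truth is recoverable by exhaustive NCC search", {
  cam <- desk_cam()
  tpl <- render_template(cam)
  for (seed in 1:3) {
    set.seed(seed)
    p <- pipette_spec(tip = position_xyz(runif(1, -8, 8), runif(1, -8, 8), 0))
    sc <- render_pipette_image(p, background_spec("plain"), cam, seed = seed)
    det <- detect_tip_xcorr(sc$image, tpl)
    expect_true(det$detected)
    expect_lt(abs(det$col_px - sc$annotation$col_px), 1)
    expect_lt(abs(det$row_px - sc$annotation$row_px), 1)
  }
})
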