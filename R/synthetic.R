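#' Pipette appearance parameters
#'
#' Geometry and contrast of the rendered pipette. The shaft runs from the tip
#' toward the image border at `approach_angle_deg` above the +x axis; the two
#' walls open at `taper_half_angle_deg` around the shaft axis and carry a
#' bipolar (bright/dark) relief profile emulating DIC shading. A bipolar
#' intensity dipole at the apex models the tip aperture itself; it is the
#' sharpest feature in the rendered image, so the point of maximal intensity
#' gradient coincides with the annotated tip.
#'
#' @param tip Tip position in microns, as from [position_xyz()].
#' @param approach_angle_deg In-plane shaft orientation (degrees).
#' @param taper_half_angle_deg Half-angle of the taper (degrees).
#' @param tip_width_um Tip opening width in microns (patch pipettes: 1-2 um).
#' @param contrast Relative amplitude of the edge relief, in (0, 1].
#' @return An object of class `pipette_spec`.
#' @export
pipette_spec <- function(tip = position_xyz(0, 0, 0), approach_angle_deg = 24,
                         taper_half_angle_deg = 4, tip_width_um = 1.5,
                         contrast = 0.4) {
  stopifnot(tip_width_um > 0, contrast > 0, contrast <= 1)
  structure(list(
    tip = position_xyz(tip$x, tip$y, tip$z),
    approach_angle_deg = approach_angle_deg,
    taper_half_angle_deg = taper_half_angle_deg,
    tip_width_um = tip_width_um, contrast = contrast
  ), class = "pipette_spec")
}

#' Background appearance parameters
#'
#' `kind = "plain"` is a uniform field; `kind = "slice"` adds spatially
#' correlated intensity fluctuations emulating the mottled appearance of an
#' acute brain slice under DIC. Both kinds carry a random linear illumination
#' tilt across the frame.
#'
#' @param kind `"plain"` or `"slice"`.
#' @param mean_intensity Mean background level in \[0, 1\].
#' @param texture_sd SD of the slice texture (intensity units).
#' @param correlation_length_um Correlation length of the texture, microns.
#' @param illumination_tilt Maximum fractional intensity gradient across the
#'   frame (per axis).
#' @param cell_density_per_1000um2 Slice only: expected number of cell
#'   somata per 1000 square microns. Somata render as DIC-shaded relief
#'   blobs of roughly neuronal size (~10 um) whose dipole shading locally
#'   resembles a pipette tip — the false targets that plague template
#'   matching over tissue.
#' @param cell_contrast Maximum relief amplitude of a soma.
#' @param seed Optional integer; when `NULL` the seed passed to
#'   [render_pipette_image()] drives the background draw.
#' @return An object of class `background_spec`.
#' @export
background_spec <- function(kind = c("plain", "slice"), mean_intensity = 0.5,
                            texture_sd = 0.15, correlation_length_um = 5,
                            illumination_tilt = 0.1,
                            cell_density_per_1000um2 = 6,
                            cell_contrast = 0.3, seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(mean_intensity >= 0, mean_intensity <= 1, texture_sd >= 0,
            correlation_length_um > 0, illumination_tilt >= 0,
            cell_density_per_1000um2 >= 0, cell_contrast >= 0)
  structure(list(
    kind = kind, mean_intensity = mean_intensity, texture_sd = texture_sd,
    correlation_length_um = correlation_length_um,
    illumination_tilt = illumination_tilt,
    cell_density_per_1000um2 = cell_density_per_1000um2,
    cell_contrast = cell_contrast, seed = seed
  ), class = "background_spec")
}

# DIC-shaded somata: each cell is a bipolar relief blob along the shear
# axis, the scene element template matching most often locks onto.
render_cells <- function(background, camera) {
  rows <- camera$rows_px; cols <- camera$cols_px
  sx <- camera$um_per_px_x; sy <- camera$um_per_px_y
  area_um2 <- (cols * sx) * (rows * sy)
  n_cells <- stats::rpois(1, background$cell_density_per_1000um2 * area_um2 / 1000)
  layer <- matrix(0, rows, cols)
  if (n_cells == 0) return(layer)
  xs_um <- matrix(rep((seq_len(cols) - 1) * sx, each = rows), rows, cols)
  ys_um <- matrix(rep((seq_len(rows) - 1) * sy, times = cols), rows, cols)
  shear <- pi / 4 # DIC shear axis
  for (i in seq_len(n_cells)) {
    cx <- stats::runif(1, 0, cols * sx)
    cy <- stats::runif(1, 0, rows * sy)
    r_cell <- stats::runif(1, 3.5, 6.5)          # um, ~neuronal radius
    amp <- stats::runif(1, 0.3, 1) * background$cell_contrast
    d <- (xs_um - cx) * cos(shear) + (ys_um - cy) * sin(shear)
    rr2 <- (xs_um - cx)^2 + (ys_um - cy)^2
    layer <- layer + amp * (d / (r_cell / 2)) * exp(-rr2 / (2 * (r_cell / 2)^2))
  }
  layer
}

#' Defocus model for rendering
#'
#' The pipette layer is blurred with a Gaussian kernel of width
#' `sigma_px = sigma0_px + k_px_per_um * |z|`. Symmetric blur alone makes the
#' sign of z unidentifiable, so a small asymmetry is applied: above focus the
#' bright lobes are amplified and the dark lobes attenuated (and vice versa
#' below), emulating the focus-dependent halo reversal of real DIC optics.
#'
#' @param sigma0_px Blur at focus (pixels).
#' @param k_px_per_um Blur growth per micron of defocus (1.0 px/um at a
#'   0.09 um/px scale is conservative for a high-NA water objective).
#' @param asym Fractional lobe asymmetry at large |z| (0 disables). The
#'   asymmetry is structural (bright/dark lobe ratio), so it survives
#'   per-image affine intensity normalization.
#' @return A list of class `defocus_model`.
#' @export
defocus_model <- function(sigma0_px = 1, k_px_per_um = 1.0, asym = 0.3) {
  stopifnot(sigma0_px > 0, k_px_per_um >= 0, asym >= 0, asym < 1)
  structure(list(sigma0_px = sigma0_px, k_px_per_um = k_px_per_um, asym = asym),
            class = "defocus_model")
}

# Gaussian blur that stays defined for arbitrarily large sigma (deep
# defocus): the kernel must fit inside the frame, and beyond that width the
# pipette layer is featureless smear anyway, so sigma saturates there.
blur_any <- function(x, sigma) {
  if (sigma <= 0) return(x)
  max_sigma <- (min(dim(x)) - 1) / 8 # gblur kernel 2*ceil(3*sigma)+1 must fit
  EBImage::gblur(x, sigma = min(sigma, max_sigma))
}

# Run expr with a local, restored RNG state seeded by `seed`.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}

# Correlated-noise field: white noise on a grid whose spacing matches the
# correlation length, bilinearly upsampled and lightly smoothed.
render_texture <- function(rows, cols, sigma_px, sd_out) {
  step <- max(1L, as.integer(round(sigma_px)))
  cr <- ceiling(rows / step) + 2L
  cc <- ceiling(cols / step) + 2L
  field <- matrix(stats::rnorm(cr * cc), cr, cc)
  if (step > 1L) {
    field <- EBImage::resize(field, w = cr * step, h = cc * step)
    smooth <- min(step / 3, (min(rows, cols) - 1) / 8)
    if (smooth >= 0.5) field <- EBImage::gblur(field, sigma = smooth)
  }
  field <- field[seq_len(rows), seq_len(cols)]
  s <- stats::sd(as.vector(field))
  if (s > 0) field <- field / s * sd_out
  field
}

render_background <- function(background, camera) {
  rows <- camera$rows_px; cols <- camera$cols_px
  xn <- matrix(rep(seq_len(cols) / cols - 0.5, each = rows), rows, cols)
  yn <- matrix(rep(seq_len(rows) / rows - 0.5, times = cols), rows, cols)
  tilt <- stats::runif(2, -background$illumination_tilt,
                       background$illumination_tilt)
  bg <- background$mean_intensity * (1 + tilt[1] * xn + tilt[2] * yn)
  if (background$kind == "slice" && background$texture_sd > 0) {
    px <- mean(c(camera$um_per_px_x, camera$um_per_px_y))
    sigma_px <- background$correlation_length_um / px
    # two-scale texture: coarse tissue mottle at the stated correlation
    # length plus subcellular granularity at a quarter of it
    bg <- bg + render_texture(rows, cols, sigma_px, 0.8 * background$texture_sd)
    bg <- bg + render_texture(rows, cols, sigma_px / 4, 0.6 * background$texture_sd)
    if (background$cell_density_per_1000um2 > 0) {
      bg <- bg + render_cells(background, camera)
    }
  }
  bg
}

# Unblurred pipette intensity layer on the pixel grid (micron-space profile).
render_pipette_layer <- function(pipette, camera, tip_px) {
  rows <- camera$rows_px; cols <- camera$cols_px
  sx <- camera$um_per_px_x; sy <- camera$um_per_px_y
  # micron offsets from the tip, stage orientation (y up)
  dx <- matrix(rep((seq_len(cols) - 1 - tip_px[1]) * sx, each = rows), rows, cols)
  dy <- matrix(rep((tip_px[2] - (seq_len(rows) - 1)) * sy, times = cols), rows, cols)
  th <- pipette$approach_angle_deg * pi / 180
  a <- dx * cos(th) + dy * sin(th)       # axial, toward the body
  l <- -dx * sin(th) + dy * cos(th)      # lateral
  w <- pipette$tip_width_um / 2 + pmax(a, 0) * tan(pipette$taper_half_angle_deg * pi / 180)
  s_edge <- 0.8                          # um, DIC relief width
  g <- function(d) (d / s_edge) * exp(-d^2 / (2 * s_edge^2))
  onset <- 1 / (1 + exp(-a / 0.2))       # shaft starts at the apex
  layer <- pipette$contrast * onset * (g(l - w) - g(l + w))
  # apex dipole: bipolar along the shaft axis; its gradient peaks exactly at
  # the tip and dominates the edge relief, so the sharpest point of the
  # rendered image is the annotated tip. Amplitude kept below the clipping
  # range so the bright/dark lobe ratio (the z-sign cue) survives compositing.
  s_apex <- pipette$tip_width_um / 3
  r2 <- dx^2 + dy^2
  layer <- layer + 2 * pipette$contrast * (a / s_apex) * exp(-r2 / (2 * s_apex^2))
  layer
}

#' Render a synthetic DIC-like pipette image with known ground truth
#'
#' Deterministic for a fixed (pipette, background, camera, defocus, seed)
#' tuple. The pipette layer is drawn at the sub-pixel tip position implied by
#' the micron-space tip, blurred according to the defocus model at the tip's
#' z, given a small z-sign asymmetry, and composited over the background;
#' intensities are clipped to \[0, 1\].
#'
#' @param pipette A [pipette_spec()].
#' @param background A [background_spec()].
#' @param camera A [camera_model()].
#' @param seed Integer seed for the background draw.
#' @param defocus A [defocus_model()].
#' @param image_id Identifier recorded in the annotation.
#' @return A list with `image` (rows x cols matrix in \[0, 1\]) and
#'   `annotation` (one-row tibble: `image_id`, `col_px`, `row_px`, `z_um`,
#'   `split`, `off_frame`). A tip outside the frame is flagged, not an error.
#' @export
#' @examples
#' sc <- render_pipette_image(camera = desk_camera(), seed = 1)
#' dim(sc$image)
render_pipette_image <- function(pipette = pipette_spec(),
                                 background = background_spec(),
                                 camera = camera_model(),
                                 seed = 1L,
                                 defocus = defocus_model(),
                                 image_id = "img") {
  tip <- pipette$tip
  px <- um_to_px(tip, camera)
  bg_seed <- if (!is.null(background$seed)) background$seed else seed
  bg <- with_local_seed(bg_seed, render_background(background, camera))
  layer <- render_pipette_layer(pipette, camera, c(px$col_px, px$row_px))
  sigma <- defocus$sigma0_px + defocus$k_px_per_um * abs(tip$z)
  layer <- blur_any(layer, sigma)
  if (defocus$asym > 0 && tip$z != 0) {
    bias <- defocus$asym * tanh(tip$z / 3)
    layer <- layer + bias * abs(layer)
  }
  img <- pmin(pmax(bg + layer, 0), 1)
  ann <- tibble::tibble(
    image_id = image_id, col_px = px$col_px, row_px = px$row_px,
    z_um = tip$z, split = NA_character_, off_frame = px$off_frame
  )
  list(image = img, annotation = ann)
}

#' Per-position pipette appearance variation
#'
#' Real datasets image many physical pipettes: tip widths span the 1-2 um
#' range of 3-5 MOhm patch pipettes, relief contrast varies with
#' illumination and depth, and the mounted angle wobbles slightly around the
#' nominal approach angle. Dataset generation draws one appearance per xy
#' position (the same physical pipette serves a whole z-series) from these
#' ranges. A fixed template cannot absorb this variation; a trained network
#' can — which is a large part of why learning outperforms template
#' matching on real rigs.
#'
#' @param tip_width_range_um Min/max tip width (um).
#' @param contrast_range Min/max edge-relief contrast.
#' @param angle_jitter_deg SD of the Gaussian jitter on the approach angle.
#' @return An object of class `pipette_variation`.
#' @export
pipette_variation <- function(tip_width_range_um = c(1, 2),
                              contrast_range = c(0.25, 0.55),
                              angle_jitter_deg = 1.5) {
  stopifnot(length(tip_width_range_um) == 2,
            tip_width_range_um[1] > 0,
            tip_width_range_um[1] <= tip_width_range_um[2],
            length(contrast_range) == 2, contrast_range[1] > 0,
            contrast_range[2] <= 1, angle_jitter_deg >= 0)
  structure(list(tip_width_range_um = tip_width_range_um,
                 contrast_range = contrast_range,
                 angle_jitter_deg = angle_jitter_deg),
            class = "pipette_variation")
}

# Draw n pipette appearances (one per xy position).
draw_pipette_appearance <- function(vary, base, n) {
  tibble::tibble(
    tip_width_um = stats::runif(n, vary$tip_width_range_um[1],
                                vary$tip_width_range_um[2]),
    contrast = stats::runif(n, vary$contrast_range[1], vary$contrast_range[2]),
    approach_angle_deg = base$approach_angle_deg +
      stats::rnorm(n, 0, vary$angle_jitter_deg)
  )
}

#' Acquisition protocol parameters
#'
#' Placement ranges emulating the data-collection protocol: random xy
#' positions within `±xy_range_um`; test-style z uniform within
#' `±z_test_range_um`; train-style z stepped from focus down to a random
#' limit of up to `z_train_max_um` and back up above focus to a random limit
#' of up to `z_train_up_max_um`, with a constant per-position step size drawn
#' from `z_step_range_um`.
#'
#' @param xy_range_um Half-width of the uniform xy placement box (um).
#' @param z_test_range_um Half-width of test-style z placement (um).
#' @param z_train_max_um Maximum descent depth for train-style stepping (um).
#' @param z_step_range_um Length-2 bounds on the constant step size (um).
#' @param z_train_up_max_um Maximum ascent above focus (um).
#' @param seed Integer seed.
#' @return An object of class `acquisition_protocol`.
#' @export
acquisition_protocol <- function(xy_range_um = 27, z_test_range_um = 6,
                                 z_train_max_um = 100,
                                 z_step_range_um = c(5, 20),
                                 z_train_up_max_um = 30, seed = 1L) {
  stopifnot(xy_range_um > 0, z_test_range_um > 0, z_train_max_um > 0,
            length(z_step_range_um) == 2, z_step_range_um[1] > 0,
            z_step_range_um[1] <= z_step_range_um[2], z_train_up_max_um > 0)
  structure(list(
    xy_range_um = xy_range_um, z_test_range_um = z_test_range_um,
    z_train_max_um = z_train_max_um, z_step_range_um = z_step_range_um,
    z_train_up_max_um = z_train_up_max_um, seed = as.integer(seed)
  ), class = "acquisition_protocol")
}

# z sequence for one train-style xy position: 0, descent, then ascent.
train_z_sequence <- function(protocol) {
  step <- stats::runif(1, protocol$z_step_range_um[1], protocol$z_step_range_um[2])
  lower <- stats::runif(1, step, protocol$z_train_max_um)
  upper <- stats::runif(1, step, protocol$z_train_up_max_um)
  down <- -seq(step, lower, by = step)
  up <- seq(step, upper, by = step)
  c(0, down, if (length(up)) up)
}

#' Generate a synthetic annotated dataset
#'
#' `style = "test"` draws independent uniform positions in the protocol's
#' `±xy_range x ±z_test_range` box, one image per position. `style = "train"`
#' emulates the stepped acquisition protocol: for each xy position, an
#' in-focus image followed by constant-step descent to a random lower limit
#' and ascent to a random upper limit, all sharing the xy annotation. Fully
#' deterministic for a fixed protocol seed.
#'
#' @param protocol An [acquisition_protocol()].
#' @param n_positions Number of xy positions (test: = number of images).
#' @param style `"test"` or `"train"`.
#' @param camera A [camera_model()].
#' @param background A [background_spec()] (its `seed` is ignored; per-image
#'   seeds derive from the protocol seed).
#' @param pipette A [pipette_spec()] whose tip is overridden per image.
#' @param defocus A [defocus_model()].
#' @param out_dir Directory for 8-bit PNG images plus `manifest.csv`; when
#'   `NULL` images are kept in memory.
#' @param val_fraction For train style: fraction of xy positions relabelled
#'   `"val"` (whole positions, so no z-series straddles the split).
#' @param vary A [pipette_variation()] drawn once per xy position, or `NULL`
#'   to image the identical pipette throughout.
#' @return A list with `manifest` (tibble: `image_id`, `path`, `col_px`,
#'   `row_px`, `z_um`, `split`) and `images` (named list of matrices, or
#'   `NULL` when written to disk).
#' @export
generate_dataset <- function(protocol, n_positions, style = c("test", "train"),
                             camera = camera_model(),
                             background = background_spec(),
                             pipette = pipette_spec(),
                             defocus = defocus_model(),
                             out_dir = NULL, val_fraction = 0,
                             vary = pipette_variation()) {
  style <- match.arg(style)
  stopifnot(n_positions >= 1)
  positions <- with_local_seed(protocol$seed, {
    xs <- stats::runif(n_positions, -protocol$xy_range_um, protocol$xy_range_um)
    ys <- stats::runif(n_positions, -protocol$xy_range_um, protocol$xy_range_um)
    looks <- if (!is.null(vary)) {
      draw_pipette_appearance(vary, pipette, n_positions)
    } else {
      tibble::tibble(tip_width_um = rep(pipette$tip_width_um, n_positions),
                     contrast = rep(pipette$contrast, n_positions),
                     approach_angle_deg = rep(pipette$approach_angle_deg,
                                              n_positions))
    }
    if (style == "test") {
      zs <- stats::runif(n_positions, -protocol$z_test_range_um,
                         protocol$z_test_range_um)
      tibble::tibble(pos = seq_len(n_positions), x = xs, y = ys, z = zs,
                     split = "test", looks)
    } else {
      split <- rep("train", n_positions)
      if (val_fraction > 0) {
        n_val <- round(val_fraction * n_positions)
        split[sample.int(n_positions, n_val)] <- "val"
      }
      purrr::map_dfr(seq_len(n_positions), function(i) {
        tibble::tibble(pos = i, x = xs[i], y = ys[i],
                       z = train_z_sequence(protocol),
                       split = split[i], looks[i, ])
      })
    }
  })
  n_img <- nrow(positions)
  ids <- sprintf("img_%05d", seq_len(n_img))
  write_out <- !is.null(out_dir)
  if (write_out) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  images <- if (!write_out) vector("list", n_img)
  rows <- vector("list", n_img)
  for (i in seq_len(n_img)) {
    p <- pipette
    p$tip <- position_xyz(positions$x[i], positions$y[i], positions$z[i])
    p$tip_width_um <- positions$tip_width_um[i]
    p$contrast <- positions$contrast[i]
    p$approach_angle_deg <- positions$approach_angle_deg[i]
    img_seed <- as.integer((as.numeric(protocol$seed) * 100003 + i) %% 2147483647)
    sc <- render_pipette_image(p, background, camera, seed = img_seed,
                               defocus = defocus, image_id = ids[i])
    path <- if (write_out) file.path(out_dir, paste0(ids[i], ".png")) else NA_character_
    if (write_out) {
      png::writePNG(round(sc$image * 255) / 255, path)
    } else {
      images[[i]] <- sc$image
    }
    rows[[i]] <- dplyr::mutate(sc$annotation, path = path,
                               split = positions$split[i])
  }
  manifest <- dplyr::bind_rows(rows)
  manifest <- manifest[, c("image_id", "path", "col_px", "row_px", "z_um", "split")]
  if (write_out) {
    write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  } else {
    names(images) <- ids
  }
  list(manifest = manifest, images = if (!write_out) images)
}

#' Generate a dataset over both plain and slice backgrounds
#'
#' The acquisition protocol this emulates collected pipette images both over
#' a plain background and above a brain slice, so that a detector trained on
#' the data works in either scene. Half the positions (rounded up) are
#' rendered over `plain_background`, half over `slice_background`; manifests
#' are concatenated and image ids disambiguated by a `plain_`/`slice_`
#' prefix.
#'
#' @inheritParams generate_dataset
#' @param plain_background,slice_background The two [background_spec()]s.
#' @return As [generate_dataset()], with an extra `background` column in the
#'   manifest.
#' @export
generate_mixed_dataset <- function(protocol, n_positions,
                                   style = c("test", "train"),
                                   camera = camera_model(),
                                   plain_background = background_spec("plain"),
                                   slice_background = background_spec("slice"),
                                   pipette = pipette_spec(),
                                   defocus = defocus_model(),
                                   out_dir = NULL, val_fraction = 0,
                                   vary = pipette_variation()) {
  style <- match.arg(style)
  n_plain <- ceiling(n_positions / 2)
  n_slice <- n_positions - n_plain
  pro2 <- protocol
  pro2$seed <- protocol$seed + 500009L
  relabel <- function(ds, prefix) {
    ds$manifest$background <- prefix
    ds$manifest$image_id <- paste0(prefix, "_", ds$manifest$image_id)
    if (!is.null(ds$images)) names(ds$images) <- ds$manifest$image_id
    ds
  }
  a <- relabel(generate_dataset(protocol, n_plain, style, camera,
                                plain_background, pipette, defocus,
                                out_dir = if (is.null(out_dir)) NULL else
                                  file.path(out_dir, "plain"),
                                val_fraction = val_fraction, vary = vary),
               "plain")
  b <- relabel(generate_dataset(pro2, n_slice, style, camera,
                                slice_background, pipette, defocus,
                                out_dir = if (is.null(out_dir)) NULL else
                                  file.path(out_dir, "slice"),
                                val_fraction = val_fraction, vary = vary),
               "slice")
  manifest <- dplyr::bind_rows(a$manifest, b$manifest)
  images <- if (!is.null(a$images)) c(a$images, b$images)
  if (!is.null(out_dir)) write_manifest(manifest,
                                        file.path(out_dir, "manifest.csv"))
  list(manifest = manifest, images = images)
}

#' Read and write dataset manifests
#'
#' The manifest schema is `image_id, path, col_px, row_px, z_um, split`
#' (pixel coordinates 0-based, sub-pixel; z in microns). CSV and JSON forms
#' are equivalent; the format is inferred from the file extension.
#'
#' @param manifest A manifest tibble.
#' @param path File path ending in `.csv` or `.json`.
#' @return `read_manifest()` returns the manifest tibble;
#'   `write_manifest()` returns `path` invisibly.
#' @export
write_manifest <- function(manifest, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(manifest, path, digits = NA, na = "null")
  } else {
    readr::write_csv(manifest, path)
  }
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  m <- if (grepl("\\.json$", path)) {
    tibble::as_tibble(jsonlite::fromJSON(path))
  } else {
    readr::read_csv(path, col_types = readr::cols(
      image_id = readr::col_character(), path = readr::col_character(),
      col_px = readr::col_double(), row_px = readr::col_double(),
      z_um = readr::col_double(), split = readr::col_character()
    ))
  }
  m
}

#' Read a stored 8-bit grayscale image as an intensity matrix
#'
#' @param path PNG file path.
#' @return A rows x cols matrix in \[0, 1\].
#' @export
read_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img
}
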