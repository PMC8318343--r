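#' Preprocessing parameters
#'
#' @param k_sigma SD multiplier for the contrast-stretch window.
#' @param crop `"center_square"` or `"none"`.
#' @param out_side_px Side of the square network input after resizing.
#' @return An object of class `preproc_spec`.
#' @export
preproc_spec <- function(k_sigma = 2, crop = c("center_square", "none"),
                         out_side_px = 224L) {
  crop <- match.arg(crop)
  stopifnot(k_sigma > 0, out_side_px > 0)
  structure(list(k_sigma = k_sigma, crop = crop,
                 out_side_px = as.integer(out_side_px)),
            class = "preproc_spec")
}

#' Per-image contrast stretch
#'
#' Linearly remaps intensities so that the window `mean ± k_sigma * sd`
#' (population SD over the image) spans \[0, 1\], clipping values that fall
#' outside after mapping. A constant image maps to a uniform 0.5. The
#' operation is invariant to positive affine intensity changes and monotone
#' in pixel value.
#'
#' @param image Intensity matrix.
#' @param k_sigma SD multiplier (default 2).
#' @return Matrix of the same shape with values in \[0, 1\].
#' @export
#' @examples
#' contrast_stretch(matrix(c(0, .25, .5, .75, 1), 1))
contrast_stretch <- function(image, k_sigma = 2) {
  stopifnot(length(image) > 0)
  m <- mean(image)
  s <- sqrt(mean((image - m)^2))
  if (s == 0) {
    out <- image
    out[] <- 0.5
    return(out)
  }
  pmin(pmax((image - (m - k_sigma * s)) / (2 * k_sigma * s), 0), 1)
}

crop_margins <- function(camera) {
  rows <- camera$rows_px; cols <- camera$cols_px
  list(col = (cols - min(rows, cols)) %/% 2L,
       row = (rows - min(rows, cols)) %/% 2L,
       side = min(rows, cols))
}

#' Centre-crop to a square and resize to the network input size
#'
#' The crop removes `(cols - rows) / 2` columns from each side (for the
#' default landscape frame), then the square is resized to
#' `out_side_px x out_side_px` by bilinear interpolation (with a Gaussian
#' prefilter when downsampling). Annotations are transformed with the exact
#' ratio `out_side_px / crop_side` — no rounding — and tips that fall inside
#' the cropped-away margin are flagged in `off_crop`, never dropped.
#'
#' @param image Intensity matrix matching `camera`'s frame.
#' @param annotation Annotation tibble with `col_px`, `row_px` (may be `NULL`).
#' @param spec A [preproc_spec()].
#' @param camera The [camera_model()] the image was taken with.
#' @return A list with `image` (out_side x out_side) and `annotation` (with
#'   transformed coordinates and an `off_crop` flag), or just the image when
#'   `annotation` is `NULL`.
#' @export
crop_resize <- function(image, annotation = NULL, spec = preproc_spec(),
                        camera = camera_model()) {
  stopifnot(nrow(image) == camera$rows_px, ncol(image) == camera$cols_px)
  mg <- crop_margins(camera)
  if (spec$crop == "center_square") {
    image <- image[mg$row + seq_len(mg$side), mg$col + seq_len(mg$side),
                   drop = FALSE]
  }
  side_in <- nrow(image)
  factor <- side_in / spec$out_side_px
  out <- image
  if (spec$out_side_px != side_in) {
    if (factor > 1) out <- EBImage::gblur(out, sigma = factor / 2)
    out <- EBImage::resize(out, w = spec$out_side_px, h = spec$out_side_px)
  }
  if (is.null(annotation)) return(out)
  scale <- spec$out_side_px / side_in
  ann <- annotation
  use_margin <- spec$crop == "center_square"
  cm <- if (use_margin) mg$col else 0L
  rm_ <- if (use_margin) mg$row else 0L
  col_new <- (ann$col_px - cm) * scale
  row_new <- (ann$row_px - rm_) * scale
  ann$off_crop <- ann$col_px < cm | ann$col_px > cm + side_in - 1L |
    ann$row_px < rm_ | ann$row_px > rm_ + side_in - 1L
  ann$col_px <- col_new
  ann$row_px <- row_new
  list(image = out, annotation = ann)
}

#' Map annotation coordinates from the network frame back to the camera frame
#'
#' Exact inverse of the coordinate transform applied by [crop_resize()].
#'
#' @param annotation Tibble with `col_px`, `row_px` in the preprocessed frame.
#' @inheritParams crop_resize
#' @return The annotation with camera-frame coordinates.
#' @export
invert_crop_resize <- function(annotation, spec = preproc_spec(),
                               camera = camera_model()) {
  mg <- crop_margins(camera)
  scale <- spec$out_side_px / mg$side
  cm <- if (spec$crop == "center_square") mg$col else 0L
  rm_ <- if (spec$crop == "center_square") mg$row else 0L
  annotation$col_px <- annotation$col_px / scale + cm
  annotation$row_px <- annotation$row_px / scale + rm_
  annotation
}

flip_image <- function(image, flip) {
  switch(flip,
    identity = image,
    h = image[, rev(seq_len(ncol(image))), drop = FALSE],
    v = image[rev(seq_len(nrow(image))), , drop = FALSE],
    hv = image[rev(seq_len(nrow(image))), rev(seq_len(ncol(image))), drop = FALSE]
  )
}

flip_annotation <- function(annotation, flip, side) {
  ann <- annotation
  if (flip %in% c("h", "hv")) ann$col_px <- side - 1 - ann$col_px
  if (flip %in% c("v", "hv")) ann$row_px <- side - 1 - ann$row_px
  ann
}

#' Flip augmentation of a square image and its annotation
#'
#' Returns the identity plus the three flips (horizontal, vertical, both);
#' annotation coordinates follow `col' = S - 1 - col` / `row' = S - 1 - row`
#' and z is unchanged, so n annotated images become 4n training pairs.
#' Each flip is an involution and the set is closed under composition.
#'
#' @param image Square intensity matrix (post [crop_resize()]).
#' @param annotation Annotation tibble with `col_px`, `row_px`.
#' @return A named list (`identity`, `h`, `v`, `hv`) of
#'   `list(image, annotation)` pairs; each annotation gains a `flip` column.
#' @export
flip_augment <- function(image, annotation) {
  stopifnot(nrow(image) == ncol(image))
  side <- nrow(image)
  flips <- c("identity", "h", "v", "hv")
  out <- lapply(flips, function(f) {
    ann <- flip_annotation(annotation, f, side)
    ann$flip <- f
    list(image = flip_image(image, f), annotation = ann)
  })
  names(out) <- flips
  out
}

#' Preprocess a manifest of images into a model-ready set
#'
#' Applies [contrast_stretch()] and [crop_resize()] to every image, and
#' (optionally) the four-fold flip augmentation; targets are the preprocessed
#' pixel coordinates of the tip plus z in microns. Images whose tip falls
#' outside the crop are excluded (they carry no valid target) and counted in
#' the `dropped` attribute.
#'
#' @param manifest Manifest tibble (see [generate_dataset()]).
#' @param images Named list of intensity matrices keyed by `image_id`, or
#'   `NULL` to read from the `path` column.
#' @param spec A [preproc_spec()].
#' @param camera The source [camera_model()].
#' @param augment Apply flip augmentation (training sets only).
#' @return A list with `x` (array `side x side x 1 x n`), `y` (n x 3 matrix:
#'   `col_px`, `row_px`, `z_um`) and `manifest` (transformed annotations).
#' @export
build_model_set <- function(manifest, images = NULL, spec = preproc_spec(),
                            camera = camera_model(), augment = FALSE) {
  n <- nrow(manifest)
  get_img <- function(i) {
    if (!is.null(images)) images[[manifest$image_id[i]]] else read_image(manifest$path[i])
  }
  xs <- list(); ys <- list(); anns <- list()
  for (i in seq_len(n)) {
    img <- contrast_stretch(get_img(i))
    cr <- crop_resize(img, manifest[i, ], spec, camera)
    if (cr$annotation$off_crop) next
    pairs <- if (augment) flip_augment(cr$image, cr$annotation) else {
      list(list(image = cr$image,
                annotation = dplyr::mutate(cr$annotation, flip = "identity")))
    }
    for (p in pairs) {
      xs[[length(xs) + 1L]] <- p$image
      ys[[length(ys) + 1L]] <- c(p$annotation$col_px, p$annotation$row_px,
                                 p$annotation$z_um)
      anns[[length(anns) + 1L]] <- p$annotation
    }
  }
  m <- length(xs)
  side <- spec$out_side_px
  x <- array(unlist(xs, use.names = FALSE), dim = c(side, side, 1L, m))
  y <- do.call(rbind, ys)
  colnames(y) <- c("col_px", "row_px", "z_um")
  out <- list(x = x, y = y, manifest = dplyr::bind_rows(anns))
  attr(out, "dropped") <- n - if (augment) m / 4L else m
  out
}
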