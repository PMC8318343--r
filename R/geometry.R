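#' Camera model for the microscopy frame
#'
#' Describes the acquisition geometry: frame size in pixels, the microns
#' spanned by the field of view, and the bit depth of the raw images. The
#' defaults correspond to a 1024 x 1280 eight-bit camera imaging a
#' 116 x 92 micron field of view through a 40x objective, giving lateral
#' scales of about 0.0906 um/px (columns) and 0.0898 um/px (rows).
#'
#' The stage-frame origin (0, 0, 0) is the centre of the field of view with
#' the pipette tip in focus; x runs along columns, y along rows (stage +y is
#' decreasing row index), and z along the optical axis (0 = in focus).
#'
#' @param rows_px,cols_px Frame size in pixels.
#' @param fov_x_um,fov_y_um Microns spanned by the columns and rows.
#' @param bit_depth Bits per pixel of the raw images.
#'
#' @return An object of class `camera_model`: a list with the arguments plus
#'   the derived scales `um_per_px_x` and `um_per_px_y`.
#' @export
#' @examples
#' cam <- camera_model()
#' cam$um_per_px_x # ~0.0906
camera_model <- function(rows_px = 1024L, cols_px = 1280L,
                         fov_x_um = 116, fov_y_um = 92, bit_depth = 8L) {
  stopifnot(rows_px > 0, cols_px > 0, fov_x_um > 0, fov_y_um > 0, bit_depth > 0)
  out <- list(
    rows_px = as.integer(rows_px), cols_px = as.integer(cols_px),
    fov_x_um = fov_x_um, fov_y_um = fov_y_um, bit_depth = as.integer(bit_depth),
    um_per_px_x = fov_x_um / cols_px, um_per_px_y = fov_y_um / rows_px
  )
  stopifnot(is.finite(out$um_per_px_x), is.finite(out$um_per_px_y))
  class(out) <- "camera_model"
  out
}

#' Desk-scale camera: a 256 x 320 crop of the full frame
#'
#' Same micron-per-pixel scale as [camera_model()] but a quarter-size frame
#' (field of view about 29 x 23 um), suitable for CPU-scale training
#' experiments.
#'
#' @return A `camera_model`.
#' @export
desk_camera <- function() {
  full <- camera_model()
  camera_model(
    rows_px = 256L, cols_px = 320L,
    fov_x_um = 320 * full$um_per_px_x,
    fov_y_um = 256 * full$um_per_px_y
  )
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf(
    "<camera_model> %d x %d px, FOV %.3g x %.3g um (%.4f / %.4f um/px), %d-bit\n",
    x$rows_px, x$cols_px, x$fov_x_um, x$fov_y_um,
    x$um_per_px_x, x$um_per_px_y, x$bit_depth
  ))
  invisible(x)
}

#' Construct stage-frame positions
#'
#' @param x,y,z Coordinates in microns (recycled to a common length).
#' @return A tibble with columns `x`, `y`, `z`.
#' @export
#' @examples
#' position_xyz(1, 2, 0)
position_xyz <- function(x = 0, y = 0, z = 0) {
  out <- tibble::tibble(x = as.numeric(x), y = as.numeric(y), z = as.numeric(z))
  if (!all(is.finite(out$x) & is.finite(out$y) & is.finite(out$z))) {
    stop("positions must be finite", call. = FALSE)
  }
  out
}

#' Convert pixel coordinates to stage-frame microns
#'
#' Pixel coordinates are 0-based `(col, row)` pairs with sub-pixel values
#' allowed; the frame centre is `((cols-1)/2, (rows-1)/2)` and maps to the
#' origin. Stage +y corresponds to decreasing row index.
#'
#' @param px A data frame with columns `col_px` and `row_px` (or a numeric
#'   vector `c(col, row)` for a single point).
#' @param camera A [camera_model()].
#' @return A tibble with columns `x` and `y` in microns.
#' @export
#' @examples
#' px_to_um(c(639.5, 511.5), camera_model()) # origin
px_to_um <- function(px, camera = camera_model()) {
  px <- as_pixel_tbl(px)
  if (any(px$col_px < 0 | px$col_px > camera$cols_px - 1L |
          px$row_px < 0 | px$row_px > camera$rows_px - 1L)) {
    stop("pixel coordinates outside the camera frame", call. = FALSE)
  }
  tibble::tibble(
    x = (px$col_px - (camera$cols_px - 1) / 2) * camera$um_per_px_x,
    y = ((camera$rows_px - 1) / 2 - px$row_px) * camera$um_per_px_y
  )
}

#' Convert stage-frame microns to pixel coordinates
#'
#' Exact inverse of [px_to_um()] on its range. Positions that map outside the
#' frame are flagged in the `off_frame` column rather than clamped.
#'
#' @param pos A data frame with columns `x` and `y` in microns (a `z` column,
#'   if present, is ignored), or a numeric vector `c(x, y)`.
#' @param camera A [camera_model()].
#' @return A tibble with columns `col_px`, `row_px`, `off_frame`.
#' @export
#' @examples
#' um_to_px(c(0, 0), camera_model()) # frame centre
um_to_px <- function(pos, camera = camera_model()) {
  if (is.numeric(pos) && is.null(dim(pos))) {
    pos <- tibble::tibble(x = pos[1], y = pos[2])
  }
  col_px <- pos$x / camera$um_per_px_x + (camera$cols_px - 1) / 2
  row_px <- (camera$rows_px - 1) / 2 - pos$y / camera$um_per_px_y
  tibble::tibble(
    col_px = col_px, row_px = row_px,
    off_frame = col_px < 0 | col_px > camera$cols_px - 1L |
      row_px < 0 | row_px > camera$rows_px - 1L
  )
}

as_pixel_tbl <- function(px) {
  if (is.numeric(px) && is.null(dim(px))) {
    return(tibble::tibble(col_px = px[1], row_px = px[2]))
  }
  stopifnot(all(c("col_px", "row_px") %in% names(px)))
  tibble::as_tibble(px[c("col_px", "row_px")])
}

#' Build error records from desired, true, and estimated positions
#'
#' For each attempt, three error vectors are defined in microns:
#' the true error `t = true - desired` (unobservable on a rig), the estimator
#' error `c = true - estimated`, and the measured error `m = desired -
#' estimated` (the only observable one, used as the feedback signal). They
#' satisfy the identity `t = c - m` exactly, by construction.
#'
#' @param desired,true_pos,est_pos Data frames of positions with columns
#'   `x`, `y`, `z` (see [position_xyz()]); rows are matched attempts.
#' @return A tibble with the input positions (prefixed `desired_`, `true_`,
#'   `est_`) and the error components `t_x .. t_z`, `c_x .. c_z`,
#'   `m_x .. m_z`.
#' @export
#' @examples
#' make_error_record(position_xyz(0, 0, 0), position_xyz(3, 1, 0),
#'                   position_xyz(2, 1, 0))
make_error_record <- function(desired, true_pos, est_pos) {
  d <- position_xyz(desired$x, desired$y, desired$z)
  tr <- position_xyz(true_pos$x, true_pos$y, true_pos$z)
  e <- position_xyz(est_pos$x, est_pos$y, est_pos$z)
  stopifnot(nrow(d) == nrow(tr), nrow(tr) == nrow(e))
  tibble::tibble(
    desired_x = d$x, desired_y = d$y, desired_z = d$z,
    true_x = tr$x, true_y = tr$y, true_z = tr$z,
    est_x = e$x, est_y = e$y, est_z = e$z,
    t_x = tr$x - d$x, t_y = tr$y - d$y, t_z = tr$z - d$z,
    c_x = tr$x - e$x, c_y = tr$y - e$y, c_z = tr$z - e$z,
    m_x = d$x - e$x, m_y = d$y - e$y, m_z = d$z - e$z
  )
}
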