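#' Create a template for cross-correlation tip detection
#'
#' @param patch Intensity matrix (smaller than any search image).
#' @param tip_offset_px 0-based `(col, row)` of the tip within the patch.
#' @return An object of class `xcorr_template`.
#' @export
xcorr_template <- function(patch, tip_offset_px) {
  stopifnot(is.matrix(patch), length(tip_offset_px) == 2,
            tip_offset_px[1] >= 0, tip_offset_px[1] <= ncol(patch) - 1,
            tip_offset_px[2] >= 0, tip_offset_px[2] <= nrow(patch) - 1)
  structure(list(patch = patch, tip_offset_px = as.numeric(tip_offset_px)),
            class = "xcorr_template")
}

#' Render an in-focus reference template for the baseline detector
#'
#' The baseline's template is an idealized view of the pipette: the tip at
#' focus over a plain, untilted background. A square patch of half-size
#' `half_px` is cut around the tip.
#'
#' @param camera A [camera_model()].
#' @param pipette A [pipette_spec()]; its tip is moved to the origin.
#' @param half_px Patch half-side in pixels. The default covers the tip and
#'   a stretch of shaft: small patches are nearly ramp-like at the scale of
#'   tissue texture and correlate spuriously with it, so a template needs
#'   enough structure to separate matches from background.
#' @param defocus A [defocus_model()].
#' @return An [xcorr_template()].
#' @export
render_template <- function(camera = camera_model(), pipette = pipette_spec(),
                            half_px = 48L, defocus = defocus_model()) {
  p <- pipette
  p$tip <- position_xyz(0, 0, 0)
  bg <- background_spec("plain", mean_intensity = 0.5, illumination_tilt = 0)
  sc <- render_pipette_image(p, bg, camera, seed = 1L, defocus = defocus)
  c0 <- round(sc$annotation$col_px) + 1L
  r0 <- round(sc$annotation$row_px) + 1L
  patch <- sc$image[(r0 - half_px):(r0 + half_px), (c0 - half_px):(c0 + half_px)]
  xcorr_template(patch, c(half_px + (sc$annotation$col_px + 1 - c0),
                          half_px + (sc$annotation$row_px + 1 - r0)))
}

#' Zero-normalized cross-correlation surface
#'
#' At every valid placement `(u, v)` of the template's top-left corner, the
#' zero-normalized cross-correlation coefficient
#' `NCC = sum((I - mean(I)) (T - mean(T))) / sqrt(sum((I - mean(I))^2) *
#' sum((T - mean(T))^2))` over the overlap window, in \[-1, 1\]. Placements
#' where either the window or the template is constant are defined as 0.
#' The cross term is evaluated by FFT; window sums use integral images.
#'
#' @param image Search intensity matrix.
#' @param template An [xcorr_template()] or plain matrix.
#' @return A `(rows_I - rows_T + 1) x (cols_I - cols_T + 1)` matrix;
#'   element `[r, c]` is the placement with top-left at 0-based pixel
#'   `(col = c - 1, row = r - 1)`.
#' @export
ncc_map <- function(image, template) {
  t_patch <- if (inherits(template, "xcorr_template")) template$patch else template
  hi <- nrow(image); wi <- ncol(image)
  ht <- nrow(t_patch); wt <- ncol(t_patch)
  if (ht > hi || wt > wi) stop("template larger than image", call. = FALSE)
  tc <- t_patch - mean(t_patch)
  t_ss <- sum(tc^2)
  # cross-correlation sum(I * Tc) over each window, via FFT
  tp <- matrix(0, hi, wi)
  tp[seq_len(ht), seq_len(wt)] <- tc
  cross <- Re(stats::fft(stats::fft(image) * Conj(stats::fft(tp)),
                         inverse = TRUE)) / (hi * wi)
  cross <- cross[seq_len(hi - ht + 1L), seq_len(wi - wt + 1L), drop = FALSE]
  # windowed sums of I and I^2 via integral images
  win_sum <- function(x) {
    s <- apply(apply(x, 2, cumsum), 1, cumsum) # transposed integral image
    s <- t(s)
    s <- rbind(0, cbind(0, s))
    nr <- hi - ht + 1L; nc <- wi - wt + 1L
    s[(ht + 1):(hi + 1), (wt + 1):(wi + 1), drop = FALSE] -
      s[1:nr, (wt + 1):(wi + 1), drop = FALSE] -
      s[(ht + 1):(hi + 1), 1:nc, drop = FALSE] +
      s[1:nr, 1:nc, drop = FALSE]
  }
  s1 <- win_sum(image)
  s2 <- win_sum(image^2)
  n_win <- ht * wt
  i_var <- pmax(s2 - s1^2 / n_win, 0)
  denom2 <- i_var * t_ss
  eps <- 1e-12 * n_win * max(1, max(abs(image))^2) * max(t_ss, 1e-30)
  out <- cross / sqrt(pmax(denom2, .Machine$double.xmin))
  out[denom2 <= eps] <- 0
  pmin(pmax(out, -1), 1)
}

parabolic_offset <- function(m1, m0, p1) {
  den <- m1 - 2 * m0 + p1
  if (den >= 0) return(0) # not a strict local max
  off <- 0.5 * (m1 - p1) / den
  max(min(off, 0.5), -0.5)
}

#' Detect the pipette tip by template matching
#'
#' Locates the peak of [ncc_map()], refines it to sub-pixel precision with a
#' three-point parabola per axis (ties broken toward the smallest
#' `(col, row)`), and offsets by the template's tip position. Detection
#' failure is a return state, not an error: `detected` is `FALSE` when the
#' peak correlation falls below `threshold`.
#'
#' @param image Search intensity matrix.
#' @param template An [xcorr_template()].
#' @param threshold Detection threshold on the peak NCC score, in (0, 1).
#'   The default is calibrated on the synthetic null distribution (peak
#'   scores of pipette-free slice texture stay below it, in-focus matches
#'   well above).
#' @return A one-row tibble: `col_px`, `row_px` (0-based, sub-pixel),
#'   `score`, `detected`.
#' @export
detect_tip_xcorr <- function(image, template, threshold = 0.6) {
  stopifnot(threshold > 0, threshold < 1)
  m <- ncc_map(image, template)
  peak <- which.max(m) # column-major: ties resolve to smallest (col, row)
  pr <- (peak - 1L) %% nrow(m) + 1L
  pc <- (peak - 1L) %/% nrow(m) + 1L
  dr <- dc <- 0
  if (pr > 1L && pr < nrow(m)) {
    dr <- parabolic_offset(m[pr - 1L, pc], m[pr, pc], m[pr + 1L, pc])
  }
  if (pc > 1L && pc < ncol(m)) {
    dc <- parabolic_offset(m[pr, pc - 1L], m[pr, pc], m[pr, pc + 1L])
  }
  tibble::tibble(
    col_px = pc - 1 + dc + template$tip_offset_px[1],
    row_px = pr - 1 + dr + template$tip_offset_px[2],
    score = m[pr, pc],
    detected = m[pr, pc] >= threshold
  )
}

#' Store and load templates as PNG plus a JSON sidecar
#'
#' @param template An [xcorr_template()].
#' @param path PNG file path; the sidecar is `<path>.json`.
#' @return `read_template()` returns the template; `write_template()`
#'   returns `path` invisibly.
#' @export
write_template <- function(template, path) {
  png::writePNG(pmin(pmax(template$patch, 0), 1), path)
  jsonlite::write_json(list(tip_offset_px = template$tip_offset_px),
                       paste0(path, ".json"), digits = NA)
  invisible(path)
}

#' @rdname write_template
#' @export
read_template <- function(path) {
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  xcorr_template(read_image(path), as.numeric(meta$tip_offset_px))
}
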