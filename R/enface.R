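#' Per-B-scan EZ thickness profile
#'
#' Converts paired EZ/RPE boundary positions of one B-scan into an EZ
#' thickness profile in micrometres: `(rpe - ez) * axial_scale`. A position
#' where either boundary is missing is missing in the output. Negative raw
#' differences (segmentation crossings) are clamped to zero; the number of
#' clamped samples is returned in the `"n_clamped"` attribute so callers can
#' track segmentation quality.
#'
#' @param ez_row,rpe_row Numeric vectors of axial boundary positions in
#'   pixels (`NA` = missing); must have equal length.
#' @param axial_scale Axial sampling, micrometres per pixel.
#' @return Numeric vector of thicknesses in micrometres with attribute
#'   `n_clamped`.
#' @export
bscan_thickness <- function(ez_row, rpe_row, axial_scale) {
  if (length(ez_row) != length(rpe_row))
    stopf("boundary vectors differ in length (%d vs %d)",
          length(ez_row), length(rpe_row))
  th <- (rpe_row - ez_row) * axial_scale
  neg <- !is.na(th) & th < 0
  th[neg] <- 0
  attr(th, "n_clamped") <- sum(neg)
  th
}

#' Fill missing values in a profile by linear interpolation
#'
#' Interior gaps are linearly interpolated between the nearest observed
#' neighbours; leading and trailing gaps are filled by nearest-value
#' extension. The `"filled"` attribute marks which positions were filled.
#'
#' @param profile Numeric vector with `NA` gaps; at least one observed value
#'   is required.
#' @return The gap-filled vector with logical attribute `filled`.
#' @export
fill_missing_linear <- function(profile) {
  obs <- which(!is.na(profile))
  if (length(obs) == 0) stopf("profile has no observed values")
  filled <- is.na(profile)
  if (length(obs) == 1) {
    profile[] <- profile[obs]
  } else if (any(filled)) {
    profile <- stats::approx(obs, profile[obs], xout = seq_along(profile),
                             method = "linear", rule = 2)$y
  }
  attr(profile, "filled") <- filled
  profile
}

#' Build an en face EZ thickness map
#'
#' Computes the per-B-scan EZ-to-RPE thickness profiles of a volume, fills
#' missing samples by linear interpolation along each B-scan, interpolates
#' B-scans that are entirely missing from their neighbours, and resamples the
#' slow axis from `n_bscans` rows to `out_rows` rows by linear interpolation
#' between adjacent B-scans (pixel-centre convention, so
#' `out_rows = n_bscans` reproduces the raw grid exactly). The default
#' `out_rows = n_ascans` yields a square, near-isotropic map suitable for
#' texture classification.
#'
#' @param volume A [layer_volume()].
#' @param out_rows Number of output rows (slow axis); must be at least
#'   `n_bscans`. Default: `n_ascans`.
#' @return A `ThicknessMap`: list with `values` (`out_rows x n_ascans`
#'   matrix, micrometres), `pixel_dx_mm`, `pixel_dy_mm`, `eye_id`,
#'   `visit_id`, `provenance` (`"observed"`/`"interpolated"` per cell on the
#'   native grid), and QC counters `n_clamped`, `n_missing_rows`.
#' @export
build_enface <- function(volume, out_rows = volume$metadata$n_ascans) {
  stopifnot(inherits(volume, "LayerVolume"))
  m <- volume$metadata
  out_rows <- as.integer(out_rows)
  if (out_rows < m$n_bscans)
    stopf("out_rows (%d) must be >= n_bscans (%d)", out_rows, m$n_bscans)

  native <- matrix(NA_real_, m$n_bscans, m$n_ascans)
  provenance <- matrix("observed", m$n_bscans, m$n_ascans)
  n_clamped <- 0L
  empty_rows <- logical(m$n_bscans)
  for (b in seq_len(m$n_bscans)) {
    th <- bscan_thickness(volume$ez_surface[b, ], volume$rpe_surface[b, ],
                          m$axial_scale_um_per_px)
    n_clamped <- n_clamped + attr(th, "n_clamped")
    if (all(is.na(th))) {
      empty_rows[b] <- TRUE
      provenance[b, ] <- "interpolated"
    } else {
      fth <- fill_missing_linear(as.numeric(th))
      provenance[b, attr(fth, "filled")] <- "interpolated"
      native[b, ] <- fth
    }
  }
  if (sum(empty_rows) > m$n_bscans / 2)
    stopf("ungradable input: %d of %d B-scans entirely missing",
          sum(empty_rows), m$n_bscans)
  if (any(empty_rows)) {
    # interpolate whole rows from neighbouring B-scans, column by column
    for (a in seq_len(m$n_ascans))
      native[, a] <- fill_missing_linear(native[, a])
  }

  # slow-axis resampling, pixel-centre convention
  if (out_rows == m$n_bscans) {
    values <- native
  } else {
    pos <- (seq_len(out_rows) - 0.5) * m$n_bscans / out_rows + 0.5
    pos <- pmin(pmax(pos, 1), m$n_bscans)
    values <- apply(native, 2, function(col)
      stats::approx(seq_len(m$n_bscans), col, xout = pos,
                    method = "linear", rule = 2)$y)
  }

  structure(
    list(values = values,
         pixel_dx_mm = m$scan_width_mm / m$n_ascans,
         pixel_dy_mm = m$scan_depth_mm / out_rows,
         eye_id = volume$eye_id, visit_id = volume$visit_id,
         provenance = provenance,
         n_clamped = n_clamped, n_missing_rows = sum(empty_rows)),
    class = "ThicknessMap"
  )
}

#' @export
print.ThicknessMap <- function(x, ...) {
  cat(sprintf("ThicknessMap %s/%s: %d x %d px (%.4f x %.4f mm/px)\n",
              x$eye_id, x$visit_id, nrow(x$values), ncol(x$values),
              x$pixel_dy_mm, x$pixel_dx_mm))
  cat(sprintf("  thickness range %.1f-%.1f um; clamped %d; missing B-scans %d\n",
              min(x$values), max(x$values), x$n_clamped, x$n_missing_rows))
  invisible(x)
}

#' Render a thickness map as an 8-bit grayscale image
#'
#' Linearly maps a thickness window to intensities 0-255 (clipped), so
#' absent/thin EZ appears dark against the brighter background of intact EZ.
#' The default window (0, 64) um places normal EZ-to-RPE thickness
#' (~30-40 um) mid-range and keeps intensities comparable across eyes.
#' Rounding is half-away-from-zero.
#'
#' @param map A `ThicknessMap`.
#' @param window_um Length-2 numeric `(low, high)` thickness window in um.
#' @return A `GrayscaleImage`: list with integer matrix `pixels` in
#'   `[0, 255]`, `window_um`, and the map geometry.
#' @export
render_grayscale <- function(map, window_um = c(0, 64)) {
  stopifnot(inherits(map, "ThicknessMap"))
  if (length(window_um) != 2 || window_um[1] >= window_um[2])
    stopf("window_um must be (low, high) with low < high")
  scaled <- (map$values - window_um[1]) / diff(window_um) * 255
  px <- matrix(as.integer(pmin(pmax(round_half_away(scaled), 0), 255)),
               nrow(map$values), ncol(map$values))
  structure(
    list(pixels = px, window_um = window_um,
         pixel_dx_mm = map$pixel_dx_mm, pixel_dy_mm = map$pixel_dy_mm,
         eye_id = map$eye_id, visit_id = map$visit_id),
    class = "GrayscaleImage"
  )
}

#' Persist a thickness map to disk
#'
#' Writes a PNG holding thickness in tenths of a micrometre as a 16-bit
#' quantity split across two 8-bit channels (high byte in red, low byte in
#' green; values above 6553.5 um saturate), plus a JSON sidecar with the
#' geometry and identifiers.
#'
#' @param map A `ThicknessMap`.
#' @param path Output PNG path; the sidecar is written at `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_thickness_png <- function(map, path) {
  stopifnot(inherits(map, "ThicknessMap"))
  tenths <- pmin(pmax(round_half_away(map$values * 10), 0), 65535)
  img <- array(0, c(nrow(tenths), ncol(tenths), 3))
  img[, , 1] <- (tenths %/% 256L) / 255
  img[, , 2] <- (tenths %% 256L) / 255
  png::writePNG(img, path)
  side <- list(eye_id = map$eye_id, visit_id = map$visit_id,
               pixel_dx_mm = map$pixel_dx_mm, pixel_dy_mm = map$pixel_dy_mm,
               units = "tenths_of_um", n_clamped = map$n_clamped,
               n_missing_rows = map$n_missing_rows)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a thickness map written by [write_thickness_png()]
#'
#' @param path PNG path (sidecar expected at `<path>.json`).
#' @return A `ThicknessMap`.
#' @export
read_thickness_png <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  img <- png::readPNG(path)
  tenths <- round(img[, , 1] * 255) * 256 + round(img[, , 2] * 255)
  structure(
    list(values = tenths / 10,
         pixel_dx_mm = side$pixel_dx_mm, pixel_dy_mm = side$pixel_dy_mm,
         eye_id = side$eye_id, visit_id = side$visit_id,
         provenance = NULL,
         n_clamped = side$n_clamped, n_missing_rows = side$n_missing_rows),
    class = "ThicknessMap"
  )
}
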