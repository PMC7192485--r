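#' Specification for a synthetic cohort
#'
#' Describes a cohort of synthetic macular volumes with known defect
#' geometry. Surfaces emulate the shapes the segmentation export produces:
#' a smooth RPE with low-frequency wobble, an EZ boundary offset by a
#' thickness field that drops to a residual inside elliptical defects, plus
#' per-A-scan boundary jitter and missing samples. Defaults follow typical
#' gradable post-treatment macular scans: 35 um baseline EZ-to-RPE
#' thickness, one defect per eye with area uniform in 0.05-0.6 mm^2, 2 um
#' boundary jitter, 2% missing samples, and no shadow bands (gradable scans
#' are the measurement population; shadowed, ungradable scans are excluded
#' upstream).
#'
#' @param device Device preset name (see [device_metadata()]).
#' @param n_eyes Number of eyes in the cohort.
#' @param baseline_thickness_um Mean EZ-to-RPE thickness outside defects.
#' @param surface_wobble_um Amplitude of low-frequency RPE undulation.
#' @param defect_model Optional list of blob lists
#'   (`center_mm`, `semi_axes_mm`, `rotation`, `residual_thickness_um`)
#'   applied to every eye; `NULL` draws one random blob per eye.
#' @param defect_area_range_mm2 Range the per-eye random blob area is drawn
#'   from when `defect_model` is `NULL`.
#' @param boundary_noise_um Per-A-scan jitter SD on each boundary.
#' @param missing_fraction Probability a boundary sample is missing.
#' @param shadow_fraction Probability an eye carries a contrast-degrading
#'   shadow band (thickness compressed toward mid-window).
#' @param taper_mm Width of the soft (linear) defect margin outside the
#'   true boundary.
#' @param seed Integer base seed; each eye derives its own stream from it.
#' @return A list with class `"SyntheticSpec"`.
#' @export
synthetic_spec <- function(device = "cirrus", n_eyes = 30L,
                           baseline_thickness_um = 35,
                           surface_wobble_um = 5,
                           defect_model = NULL,
                           defect_area_range_mm2 = c(0.05, 0.6),
                           boundary_noise_um = 2,
                           missing_fraction = 0.02,
                           shadow_fraction = 0,
                           taper_mm = 0.05,
                           seed = 1L) {
  if (missing_fraction < 0 || missing_fraction > 1 ||
      shadow_fraction < 0 || shadow_fraction > 1)
    stopf("fractions must lie in [0, 1]")
  if (baseline_thickness_um < 0 || boundary_noise_um < 0)
    stopf("thicknesses and noise must be non-negative")
  structure(
    list(device = device, n_eyes = as.integer(n_eyes),
         baseline_thickness_um = baseline_thickness_um,
         surface_wobble_um = surface_wobble_um,
         defect_model = defect_model,
         defect_area_range_mm2 = defect_area_range_mm2,
         boundary_noise_um = boundary_noise_um,
         missing_fraction = missing_fraction,
         shadow_fraction = shadow_fraction,
         taper_mm = taper_mm,
         seed = as.integer(seed)),
    class = "SyntheticSpec"
  )
}

# Normalized elliptical radius of points (x, y) for one blob.
blob_radius <- function(blob, x_mm, y_mm) {
  dx <- x_mm - blob$center_mm[1]
  dy <- y_mm - blob$center_mm[2]
  ct <- cos(blob$rotation); st <- sin(blob$rotation)
  u <- dx * ct + dy * st
  v <- -dx * st + dy * ct
  sqrt((u / blob$semi_axes_mm[1])^2 + (v / blob$semi_axes_mm[2])^2)
}

draw_random_blob <- function(spec, md) {
  area <- stats::runif(1, spec$defect_area_range_mm2[1],
                       spec$defect_area_range_mm2[2])
  aspect <- stats::runif(1, 1, 2)
  # area = pi * a * b with a = aspect * b
  b <- sqrt(area / (pi * aspect))
  a <- aspect * b
  center <- c(md$scan_width_mm / 2 + stats::runif(1, -0.1, 0.1),
              md$scan_depth_mm / 2 + stats::runif(1, -0.1, 0.1))
  list(center_mm = center, semi_axes_mm = c(a, b),
       rotation = stats::runif(1, 0, pi), residual_thickness_um = 0)
}

#' Generate one synthetic eye
#'
#' Deterministic given `(spec$seed, eye_index)`: the same eye is produced
#' whether generated alone or within a cohort, in any order.
#'
#' @param spec A [synthetic_spec()].
#' @param eye_index 1-based index of the eye within the cohort.
#' @return A `SyntheticEye`: list with `volume` ([layer_volume()]),
#'   `truth_mask` (logical en face grid matching [build_enface()] defaults),
#'   `blobs`, `csf_record`, and `true_csf_area_mm2` (fine-grid oracle).
#' @export
generate_eye <- function(spec, eye_index) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  md <- device_metadata(spec$device)
  with_local_seed(derive_seed(spec$seed, eye_index), {
    blobs <- if (is.null(spec$defect_model)) list(draw_random_blob(spec, md))
             else spec$defect_model
    for (bl in blobs) {
      if (any(bl$center_mm - max(bl$semi_axes_mm) < 0) ||
          bl$center_mm[1] + max(bl$semi_axes_mm) > md$scan_width_mm ||
          bl$center_mm[2] + max(bl$semi_axes_mm) > md$scan_depth_mm)
        stopf("defect blob extends outside the %.1f x %.1f mm scan",
              md$scan_width_mm, md$scan_depth_mm)
    }

    x_mm <- (seq_len(md$n_ascans) - 0.5) * md$scan_width_mm / md$n_ascans
    y_mm <- (seq_len(md$n_bscans) - 0.5) * md$scan_depth_mm / md$n_bscans
    xg <- matrix(rep(x_mm, each = md$n_bscans), md$n_bscans)
    yg <- matrix(rep(y_mm, times = md$n_ascans), md$n_bscans)

    thickness <- thickness_field(spec, blobs, xg, yg)

    if (spec$shadow_fraction > 0 && stats::runif(1) < spec$shadow_fraction) {
      x0 <- stats::runif(1, 0, md$scan_width_mm - 0.8)
      w <- stats::runif(1, 0.3, 0.8)
      band <- x_mm >= x0 & x_mm <= x0 + w
      mid <- spec$baseline_thickness_um * 32 / 35
      thickness[, band] <- mid + (thickness[, band] - mid) * 0.3
    }

    phi <- stats::runif(2, 0, 2 * pi)
    ax <- md$axial_scale_um_per_px
    wob <- spec$surface_wobble_um / ax
    rpe <- 300 +
      wob * sin(2 * pi * 1.5 * xg / md$scan_width_mm + phi[1]) *
            sin(2 * pi * 1.3 * yg / md$scan_depth_mm + phi[2])
    n <- length(rpe)
    rpe <- rpe + matrix(stats::rnorm(n, 0, spec$boundary_noise_um / ax),
                        md$n_bscans)
    ez <- rpe - thickness / ax +
      matrix(stats::rnorm(n, 0, spec$boundary_noise_um / ax), md$n_bscans)

    if (spec$missing_fraction > 0) {
      ez[stats::runif(n) < spec$missing_fraction] <- NA
      rpe[stats::runif(n) < spec$missing_fraction] <- NA
    }

    eye_id <- sprintf("E%03d", eye_index)
    volume <- layer_volume(md, ez, rpe, eye_id = eye_id, visit_id = "V01")

    out_rows <- md$n_ascans
    yo_mm <- (seq_len(out_rows) - 0.5) * md$scan_depth_mm / out_rows
    xo <- matrix(rep(x_mm, each = out_rows), out_rows)
    yo <- matrix(rep(yo_mm, times = md$n_ascans), out_rows)
    truth <- matrix(FALSE, out_rows, md$n_ascans)
    for (bl in blobs) truth <- truth | (blob_radius(bl, xo, yo) <= 1)

    rec <- csf_record(eye_id, "V01",
                      center_x = (md$n_ascans - 1) / 2,
                      center_y = (out_rows - 1) / 2,
                      diameter_mm = 1.0)
    eye <- structure(
      list(volume = volume, truth_mask = truth, blobs = blobs,
           csf_record = rec, eye_index = eye_index,
           base_seed = spec$seed, out_rows = out_rows,
           pixel_dx_mm = md$scan_width_mm / md$n_ascans,
           pixel_dy_mm = md$scan_depth_mm / out_rows),
      class = "SyntheticEye"
    )
    eye$true_csf_area_mm2 <- true_area_oracle(eye)
    eye
  })
}

# Thickness field: baseline outside blobs, residual inside, with a linear
# edge ramp of width taper_mm centred on the true boundary (r = 1), the way
# partial-volume blur straddles a real edge. The 50% thickness level then
# coincides with the analytic boundary.
thickness_field <- function(spec, blobs, xg, yg) {
  thickness <- matrix(spec$baseline_thickness_um, nrow(xg), ncol(xg))
  for (bl in blobs) {
    r <- blob_radius(bl, xg, yg)
    w <- spec$taper_mm / min(bl$semi_axes_mm)
    ramp <- pmin(pmax((r - (1 - w / 2)) / w, 0), 1)
    lvl <- bl$residual_thickness_um +
      (spec$baseline_thickness_um - bl$residual_thickness_um) * ramp
    thickness <- pmin(thickness, lvl)
  }
  thickness
}

#' Fine-grid oracle for the true defect area within the CSF
#'
#' Rasterizes the analytic defect geometry intersected with the CSF disc at
#' 10x the en face grid resolution and sums subpixel areas. Serves as the
#' independent reference for [measure_defect()].
#'
#' @param eye A `SyntheticEye`.
#' @param factor Linear refinement factor (default 10).
#' @return True defect area within the CSF, mm^2.
#' @export
true_area_oracle <- function(eye, factor = 10L) {
  rec <- eye$csf_record
  r_mm <- rec$diameter_mm / 2
  cx <- (rec$center_x + 0.5) * eye$pixel_dx_mm
  cy <- (rec$center_y + 0.5) * eye$pixel_dy_mm
  fdx <- eye$pixel_dx_mm / factor
  fdy <- eye$pixel_dy_mm / factor
  xs <- seq(cx - r_mm, cx + r_mm, by = fdx)
  ys <- seq(cy - r_mm, cy + r_mm, by = fdy)
  xg <- matrix(rep(xs, each = length(ys)), length(ys))
  yg <- matrix(rep(ys, times = length(xs)), length(ys))
  in_disc <- (xg - cx)^2 + (yg - cy)^2 <= r_mm^2
  in_defect <- matrix(FALSE, nrow(xg), ncol(xg))
  for (bl in eye$blobs)
    in_defect <- in_defect | (blob_radius(bl, xg, yg) <= 1)
  sum(in_disc & in_defect) * fdx * fdy
}

#' Label scribbles for one synthetic eye
#'
#' Sparse training labels consistent with the ground truth by construction:
#' "absent" samples are drawn well inside the defect (normalized radius
#' below 0.8), "intact" samples well outside it (radius above 1.3).
#'
#' @param eye A `SyntheticEye`.
#' @param n_absent,n_intact Maximum scribble pixels per class.
#' @return Integer matrix (0 unlabeled, 1 intact, 2 absent) on the en face
#'   grid.
#' @export
generate_labels <- function(eye, n_absent = 800L, n_intact = 1600L) {
  stopifnot(inherits(eye, "SyntheticEye"))
  with_local_seed(derive_seed(derive_seed(eye$base_seed, eye$eye_index),
                              999L), {
    out_rows <- eye$out_rows
    n_asc <- ncol(eye$truth_mask)
    x_mm <- (seq_len(n_asc) - 0.5) * eye$pixel_dx_mm
    y_mm <- (seq_len(out_rows) - 0.5) * eye$pixel_dy_mm
    xg <- matrix(rep(x_mm, each = out_rows), out_rows)
    yg <- matrix(rep(y_mm, times = n_asc), out_rows)
    rmin <- matrix(Inf, out_rows, n_asc)
    for (bl in eye$blobs) rmin <- pmin(rmin, blob_radius(bl, xg, yg))
    labels <- matrix(0L, out_rows, n_asc)
    absent_pool <- which(rmin < 0.8)
    intact_pool <- which(rmin > 1.3)
    labels[sample(absent_pool, min(n_absent, length(absent_pool)))] <- 2L
    labels[sample(intact_pool, min(n_intact, length(intact_pool)))] <- 1L
    labels
  })
}

#' Emulated manual trace of a defect boundary
#'
#' Polygonal outline of each blob boundary with small radial jitter,
#' standing in for a human grader's trace of the defect margin.
#'
#' @param eye A `SyntheticEye`.
#' @param n_vertices Vertices per blob outline.
#' @param jitter_mm SD of radial tracing jitter.
#' @return List of [polygon_trace()] objects (one per blob), coordinates in
#'   en face pixels.
#' @export
generate_manual_trace <- function(eye, n_vertices = 64L, jitter_mm = 0.01) {
  stopifnot(inherits(eye, "SyntheticEye"))
  with_local_seed(derive_seed(derive_seed(eye$base_seed, eye$eye_index),
                              555L), {
    lapply(eye$blobs, function(bl) {
      t <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
      jit <- 1 + stats::rnorm(n_vertices, 0, jitter_mm /
                                mean(bl$semi_axes_mm))
      u <- bl$semi_axes_mm[1] * cos(t) * jit
      v <- bl$semi_axes_mm[2] * sin(t) * jit
      ct <- cos(bl$rotation); st <- sin(bl$rotation)
      x_mm <- bl$center_mm[1] + u * ct - v * st
      y_mm <- bl$center_mm[2] + u * st + v * ct
      polygon_trace(x = x_mm / eye$pixel_dx_mm - 0.5,
                    y = y_mm / eye$pixel_dy_mm - 0.5)
    })
  })
}

#' Generate a synthetic cohort on disk
#'
#' Writes per-eye layer XML files, one CSF coordinate CSV, per-eye truth
#' masks (PNG), label scribbles for a ~10% training subset, manual-trace
#' CSVs, and a JSON manifest with the oracle defect areas.
#'
#' @param spec A [synthetic_spec()].
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly (list with per-eye entries).
#' @export
generate_cohort <- function(spec, out_dir) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  n_train <- max(1L, ceiling(0.10 * spec$n_eyes))
  records <- list()
  entries <- list()
  for (i in seq_len(spec$n_eyes)) {
    eye <- generate_eye(spec, i)
    xml_path <- file.path(out_dir, sprintf("%s.xml", eye$volume$eye_id))
    write_layer_xml(eye$volume, xml_path)
    truth_path <- file.path(out_dir,
                            sprintf("truth_%s.png", eye$volume$eye_id))
    png::writePNG(eye$truth_mask * 1, truth_path)
    entry <- list(eye_id = eye$volume$eye_id, visit_id = eye$volume$visit_id,
                  xml = basename(xml_path), truth = basename(truth_path),
                  true_csf_area_mm2 = eye$true_csf_area_mm2,
                  training = i <= n_train)
    if (i <= n_train) {
      lab_path <- file.path(out_dir,
                            sprintf("labels_%s.png", eye$volume$eye_id))
      png::writePNG(generate_labels(eye) / 255, lab_path)
      entry$labels <- basename(lab_path)
    }
    traces <- generate_manual_trace(eye)
    trace_path <- file.path(out_dir,
                            sprintf("trace_%s.csv", eye$volume$eye_id))
    tdf <- do.call(rbind, lapply(seq_along(traces), function(k)
      data.frame(polygon = k, x = traces[[k]]$x, y = traces[[k]]$y)))
    utils::write.csv(tdf, trace_path, row.names = FALSE, quote = FALSE)
    entry$trace <- basename(trace_path)
    records[[length(records) + 1]] <- eye$csf_record
    entries[[length(entries) + 1]] <- entry
  }
  write_csf_table(records, file.path(out_dir, "csf.csv"))
  manifest <- list(device = spec$device, n_eyes = spec$n_eyes,
                   seed = spec$seed, n_training = n_train, eyes = entries)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read a label-scribble PNG written by [generate_cohort()]
#'
#' @param path PNG path.
#' @return Integer label matrix (0/1/2).
#' @export
read_labels_png <- function(path) {
  img <- png::readPNG(path)
  matrix(as.integer(round(img * 255)), nrow(img))
}

#' Read a manual-trace CSV written by [generate_cohort()]
#'
#' @param path CSV with columns `polygon`, `x`, `y`.
#' @return List of [polygon_trace()] objects.
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path)
  lapply(split(df, df$polygon), function(g) polygon_trace(g$x, g$y))
}
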