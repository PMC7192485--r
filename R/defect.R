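#' Analytic central-subfield disc area
#'
#' @param diameter_mm Disc diameter in mm (default 1.0, the ETDRS central
#'   subfield).
#' @return Disc area `pi * (d/2)^2` in mm^2.
#' @export
csf_analytic_area <- function(diameter_mm = 1.0) pi * (diameter_mm / 2)^2

#' Reported measurement ceiling for a CSF disc
#'
#' The ceiling quoted in exported tables is the analytic disc area truncated
#' (not rounded) to two decimals, the convention used in reading-center
#' grading reports; for the standard 1-mm disc this is 0.78 mm^2.
#'
#' @inheritParams csf_analytic_area
#' @return The analytic area floored to two decimal places, in mm^2.
#' @export
csf_reported_bound <- function(diameter_mm = 1.0) {
  floor(csf_analytic_area(diameter_mm) * 100) / 100
}

map_geometry <- function(x) {
  if (inherits(x, c("ThicknessMap", "GrayscaleImage"))) {
    v <- if (inherits(x, "ThicknessMap")) x$values else x$pixels
    list(rows = nrow(v), cols = ncol(v),
         pixel_dx_mm = x$pixel_dx_mm, pixel_dy_mm = x$pixel_dy_mm)
  } else {
    stopifnot(all(c("rows", "cols", "pixel_dx_mm", "pixel_dy_mm") %in%
                    names(x)))
    x
  }
}

#' Rasterize the central-subfield disc on a map grid
#'
#' A pixel belongs to the disc iff its centre lies within `diameter_mm / 2`
#' of the disc centre, in physical units. The analytic disc area is attached
#' as the `"csf_area_mm2"` attribute.
#'
#' @param record A [csf_record()].
#' @param geometry A `ThicknessMap`, `GrayscaleImage`, or list with `rows`,
#'   `cols`, `pixel_dx_mm`, `pixel_dy_mm`.
#' @return Logical matrix mask with attribute `csf_area_mm2`.
#' @export
csf_mask <- function(record, geometry) {
  stopifnot(inherits(record, "CSFRecord"))
  g <- map_geometry(geometry)
  if (record$center_x < 0 || record$center_x > g$cols - 1 ||
      record$center_y < 0 || record$center_y > g$rows - 1)
    stopf("CSF centre (%.1f, %.1f) lies outside the %d x %d map",
          record$center_x, record$center_y, g$cols, g$rows)
  r_mm <- record$diameter_mm / 2
  # pixel-centre coordinates in mm; 0-based index i has centre (i + 0.5) * d
  cx_mm <- (record$center_x + 0.5) * g$pixel_dx_mm
  cy_mm <- (record$center_y + 0.5) * g$pixel_dy_mm
  x_mm <- (seq_len(g$cols) - 0.5) * g$pixel_dx_mm
  y_mm <- (seq_len(g$rows) - 0.5) * g$pixel_dy_mm
  d2 <- outer((y_mm - cy_mm)^2, (x_mm - cx_mm)^2, "+")
  if (cx_mm - r_mm < 0 || cx_mm + r_mm > g$cols * g$pixel_dx_mm ||
      cy_mm - r_mm < 0 || cy_mm + r_mm > g$rows * g$pixel_dy_mm)
    warnf("CSF disc extends beyond the map and is clipped")
  mask <- d2 <= r_mm^2
  attr(mask, "csf_area_mm2") <- csf_analytic_area(record$diameter_mm)
  mask
}

#' Binary defect mask from a classified map
#'
#' @param classmap A `ClassMap` from [predict_classmap()].
#' @return Logical matrix, `TRUE` where the EZ is classified absent.
#' @export
defect_mask_from_classmap <- function(classmap) {
  stopifnot(inherits(classmap, "ClassMap"))
  classmap$labels == 2L
}

#' Construct a polygon trace
#'
#' A closed manual outline in en face pixel coordinates (`x` = 0-based
#' column, `y` = 0-based row). Validated to have at least 3 vertices and no
#' self-intersections.
#'
#' @param x,y Numeric vertex coordinates (the closing edge back to the first
#'   vertex is implicit).
#' @return A list with class `"PolygonTrace"`.
#' @export
polygon_trace <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stopf("a polygon trace needs at least 3 (x, y) vertices")
  v <- cbind(as.numeric(x), as.numeric(y))
  if (polygon_self_intersects(v))
    stopf("polygon trace is self-intersecting")
  structure(list(x = v[, 1], y = v[, 2]), class = "PolygonTrace")
}

# Proper-intersection test between non-adjacent edges (shared endpoints of
# adjacent edges are not intersections).
polygon_self_intersects <- function(v) {
  n <- nrow(v)
  seg <- cbind(v, v[c(2:n, 1), , drop = FALSE])
  cross <- function(ox, oy, ax, ay, bx, by)
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      if (j == i + 1 || (i == 1 && j == n)) next
      p <- seg[i, ]; q <- seg[j, ]
      d1 <- cross(p[1], p[2], p[3], p[4], q[1], q[2])
      d2 <- cross(p[1], p[2], p[3], p[4], q[3], q[4])
      d3 <- cross(q[1], q[2], q[3], q[4], p[1], p[2])
      d4 <- cross(q[1], q[2], q[3], q[4], p[3], p[4])
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
        return(TRUE)
    }
  }
  FALSE
}

#' Rasterize a manual trace to a binary mask
#'
#' Even-odd fill: a pixel is inside iff its centre (0-based integer
#' coordinates) is inside the polygon. Portions outside the map are clipped
#' with a warning.
#'
#' @param trace A [polygon_trace()].
#' @param geometry As in [csf_mask()].
#' @return Logical matrix mask.
#' @export
rasterize_polygon <- function(trace, geometry) {
  stopifnot(inherits(trace, "PolygonTrace"))
  g <- map_geometry(geometry)
  mask <- matrix(FALSE, g$rows, g$cols)
  if (max(trace$x) < 0 || min(trace$x) > g$cols - 1 ||
      max(trace$y) < 0 || min(trace$y) > g$rows - 1) {
    warnf("polygon lies entirely outside the map; empty mask returned")
    return(mask)
  }
  if (min(trace$x) < 0 || max(trace$x) > g$cols - 1 ||
      min(trace$y) < 0 || max(trace$y) > g$rows - 1)
    warnf("polygon extends beyond the map and is clipped")
  c0 <- max(0L, floor(min(trace$x)))
  c1 <- min(g$cols - 1L, ceiling(max(trace$x)))
  r0 <- max(0L, floor(min(trace$y)))
  r1 <- min(g$rows - 1L, ceiling(max(trace$y)))
  px <- rep(c0:c1, each = r1 - r0 + 1)
  py <- rep(r0:r1, times = c1 - c0 + 1)
  inside <- rep(FALSE, length(px))
  n <- length(trace$x)
  xv <- trace$x; yv <- trace$y
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((yv[i] > py) != (yv[j] > py)) &
      (px < (xv[j] - xv[i]) * (py - yv[i]) / (yv[j] - yv[i]) + xv[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  mask[cbind(py + 1L, px + 1L)] <- inside
  mask
}

#' 8-connected component labeling
#'
#' Labels connected components of a binary mask under 8-connectivity
#' (diagonal neighbours connect), matching common ImageJ-style region
#' behaviour.
#'
#' @param mask Logical or 0/1 matrix.
#' @return Integer matrix of component labels (0 = background) with
#'   attribute `n_components`.
#' @export
label_components <- function(mask) {
  m <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  lab <- EBImage::bwlabel(m)   # 4-connected
  lab <- matrix(as.integer(lab), nrow(m), ncol(m))
  nlab <- max(lab)
  if (nlab > 1) {
    # merge labels that touch diagonally
    parent <- seq_len(nlab)
    find <- function(i) {
      while (parent[i] != i) {
        parent[i] <<- parent[parent[i]]
        i <- parent[i]
      }
      i
    }
    nr <- nrow(lab); nc <- ncol(lab)
    pairs <- rbind(
      cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),
      cbind(as.vector(lab[-nr, -1]), as.vector(lab[-1, -nc]))
    )
    pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                     pairs[, 1] != pairs[, 2], , drop = FALSE]
    for (k in seq_len(nrow(pairs))) {
      a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
    roots <- vapply(seq_len(nlab), find, integer(1))
    remap <- match(roots, sort(unique(roots)))
    lab[lab > 0] <- remap[lab[lab > 0]]
    nlab <- max(lab)
  }
  attr(lab, "n_components") <- nlab
  lab
}

#' Measure EZ defect area within the central subfield
#'
#' Intersects a binary defect mask with the CSF disc mask, labels
#' 8-connected components, drops components whose area is less than or equal
#' to `min_area_mm2` (such measurements are considered absent), and sums the
#' retained component areas. The total is capped at the analytic CSF disc
#' area, the measurement ceiling. A zero total is a valid measurement
#' (no defect).
#'
#' @param defect Binary defect mask.
#' @param csf Binary CSF disc mask of the same shape (from [csf_mask()]).
#' @param pixel_area_mm2 Area of one map pixel in mm^2.
#' @param min_area_mm2 Minimum measurable component area (default 0.004,
#'   the lowest limit of area measurability in reading-centre grading).
#' @param csf_area_mm2 Analytic CSF area used for the ceiling; taken from
#'   the `csf` mask attribute when present.
#' @param eye_id,visit_id,method Identifiers carried into the result.
#' @return A `DefectMeasurement`: list with `total_area_mm2`, `components`
#'   (data frame of retained `pixel_count`/`area_mm2`), `below_min_dropped`,
#'   `csf_area_mm2` and the identifiers.
#' @export
measure_defect <- function(defect, csf, pixel_area_mm2,
                           min_area_mm2 = 0.004, csf_area_mm2 = NULL,
                           eye_id = "eye", visit_id = "visit",
                           method = c("automated", "manual")) {
  method <- match.arg(method)
  if (!identical(dim(defect), dim(csf)))
    stopf("defect mask %d x %d and CSF mask %d x %d differ in shape",
          nrow(defect), ncol(defect), nrow(csf), ncol(csf))
  if (is.null(csf_area_mm2))
    csf_area_mm2 <- attr(csf, "csf_area_mm2")
  if (is.null(csf_area_mm2))
    csf_area_mm2 <- sum(csf != 0) * pixel_area_mm2

  lab <- label_components((defect != 0) & (csf != 0))
  counts <- tabulate(lab[lab > 0], nbins = attr(lab, "n_components"))
  areas <- counts * pixel_area_mm2
  keep <- areas > min_area_mm2
  components <- data.frame(pixel_count = counts[keep],
                           area_mm2 = areas[keep])
  total <- min(sum(components$area_mm2), csf_area_mm2)
  structure(
    list(eye_id = as.character(eye_id), visit_id = as.character(visit_id),
         method = method, components = components,
         total_area_mm2 = total,
         below_min_dropped = sum(!keep),
         csf_area_mm2 = csf_area_mm2),
    class = "DefectMeasurement"
  )
}

#' @export
print.DefectMeasurement <- function(x, ...) {
  cat(sprintf(
    "DefectMeasurement %s/%s (%s): %.4f mm^2 in %d component(s), %d dropped\n",
    x$eye_id, x$visit_id, x$method, x$total_area_mm2,
    nrow(x$components), x$below_min_dropped))
  invisible(x)
}

#' Tabulate defect measurements
#'
#' @param measurements List of `DefectMeasurement` objects.
#' @return Tidy data frame with one row per measurement.
#' @export
measurements_to_df <- function(measurements) {
  do.call(rbind, lapply(measurements, function(m)
    data.frame(eye_id = m$eye_id, visit_id = m$visit_id, method = m$method,
               total_area_mm2 = m$total_area_mm2,
               n_components = nrow(m$components),
               below_min_dropped = m$below_min_dropped,
               csf_area_mm2 = m$csf_area_mm2)))
}

#' Write measurements as CSV
#'
#' @param measurements List of `DefectMeasurement` objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements_csv <- function(measurements, path) {
  utils::write.csv(measurements_to_df(measurements), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Review overlay image
#'
#' Renders the grayscale map with the defect mask tinted red and the CSF
#' disc boundary drawn in green, for visual review of each segmentation.
#'
#' @param image A `GrayscaleImage`.
#' @param defect Binary defect mask.
#' @param csf Binary CSF mask.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_overlay_png <- function(image, defect, csf, path) {
  stopifnot(inherits(image, "GrayscaleImage"))
  base <- image$pixels / 255
  r <- base; g <- base; b <- base
  r[defect] <- pmin(0.6 * base[defect] + 0.4, 1)
  g[defect] <- 0.4 * base[defect]
  b[defect] <- 0.4 * base[defect]
  # CSF boundary: disc pixels with at least one non-disc 4-neighbour
  nr <- nrow(csf); nc <- ncol(csf)
  inner <- csf
  inner[-1, ] <- inner[-1, ] & csf[-nr, ]
  inner[-nr, ] <- inner[-nr, ] & csf[-1, ]
  inner[, -1] <- inner[, -1] & csf[, -nc]
  inner[, -nc] <- inner[, -nc] & csf[, -1]
  ring <- csf & !inner
  r[ring] <- 0; g[ring] <- 1; b[ring] <- 0
  png::writePNG(array(c(r, g, b), c(nr, nc, 3)), path)
  invisible(path)
}
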