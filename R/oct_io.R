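#' Device acquisition presets
#'
#' Scan-geometry metadata for the two SD-OCT devices used in macular volume
#' imaging: Zeiss Cirrus (6 x 6 mm cube, 512 A-scans x 128 B-scans) and
#' Heidelberg Spectralis (20 x 20 degrees, 512 A-scans x 97 B-scans). The
#' Spectralis angular field is converted to millimetres with the emmetropic
#' convention 0.29 mm/degree, so 20 degrees maps to 5.8 mm; with 97 B-scans
#' the resulting spacing places 17 B-scans across the central 1 mm, matching
#' the central-subfield B-scan count for that device.
#'
#' @param name `"cirrus"` or `"spectralis"`.
#' @param axial_scale_um_per_px Axial sampling in micrometres per pixel.
#'   Defaults to 1.9531 (Cirrus: 2 mm depth over 1024 px) or 3.87
#'   (Spectralis) depending on the device.
#' @return A `VolumeMetadata` object (see [volume_metadata()]).
#' @export
#' @examples
#' device_metadata("cirrus")
device_metadata <- function(name, axial_scale_um_per_px = NULL) {
  presets <- list(
    cirrus = list(n_ascans = 512L, n_bscans = 128L,
                  scan_width_mm = 6.0, scan_depth_mm = 6.0,
                  axial = 2000 / 1024),
    spectralis = list(n_ascans = 512L, n_bscans = 97L,
                      scan_width_mm = 20 * 0.29, scan_depth_mm = 20 * 0.29,
                      axial = 3.87)
  )
  if (!name %in% names(presets)) {
    stopf("unknown device preset '%s'; valid presets: %s", name,
          paste(names(presets), collapse = ", "))
  }
  p <- presets[[name]]
  volume_metadata(
    device_name = name,
    n_ascans = p$n_ascans, n_bscans = p$n_bscans,
    scan_width_mm = p$scan_width_mm, scan_depth_mm = p$scan_depth_mm,
    axial_scale_um_per_px =
      if (is.null(axial_scale_um_per_px)) p$axial else axial_scale_um_per_px
  )
}

#' Construct volume metadata
#'
#' @param device_name One of `"cirrus"`, `"spectralis"`, `"custom"`.
#' @param n_ascans,n_bscans Grid dimensions (A-scans per B-scan, B-scans per
#'   volume); both must be at least 2.
#' @param scan_width_mm Lateral extent along a B-scan, mm.
#' @param scan_depth_mm Extent across B-scans (slow axis), mm.
#' @param axial_scale_um_per_px Axial sampling, micrometres per pixel.
#' @return A list with class `"VolumeMetadata"`.
#' @export
volume_metadata <- function(device_name, n_ascans, n_bscans,
                            scan_width_mm, scan_depth_mm,
                            axial_scale_um_per_px) {
  device_name <- match.arg(device_name, c("cirrus", "spectralis", "custom"))
  n_ascans <- as.integer(n_ascans)
  n_bscans <- as.integer(n_bscans)
  if (n_ascans < 2L || n_bscans < 2L)
    stopf("n_ascans and n_bscans must both be >= 2")
  if (scan_width_mm <= 0 || scan_depth_mm <= 0 || axial_scale_um_per_px <= 0)
    stopf("physical extents and axial scale must be positive")
  structure(
    list(device_name = device_name, n_ascans = n_ascans, n_bscans = n_bscans,
         scan_width_mm = scan_width_mm, scan_depth_mm = scan_depth_mm,
         axial_scale_um_per_px = axial_scale_um_per_px),
    class = "VolumeMetadata"
  )
}

#' Construct a layer volume
#'
#' Bundles the EZ and RPE boundary grids of one macular volume scan. Each
#' grid is `n_bscans x n_ascans`; entry `[b, a]` is the axial boundary
#' position (pixels, increasing with depth) of A-scan `a` in B-scan `b`.
#' The EZ grid holds the inner border of the ellipsoid zone band and the RPE
#' grid the inner border of the retinal pigment epithelium band, so wherever
#' both are defined `rpe >= ez`. `NA` marks a missing boundary sample.
#'
#' @param metadata A `VolumeMetadata`.
#' @param ez_surface,rpe_surface Numeric matrices `n_bscans x n_ascans`,
#'   `NA` for missing samples.
#' @param eye_id,visit_id Identifier strings.
#' @return A list with class `"LayerVolume"`.
#' @export
layer_volume <- function(metadata, ez_surface, rpe_surface,
                         eye_id = "eye", visit_id = "visit") {
  stopifnot(inherits(metadata, "VolumeMetadata"))
  dims <- c(metadata$n_bscans, metadata$n_ascans)
  if (!identical(dim(ez_surface), as.integer(dims)) ||
      !identical(dim(rpe_surface), as.integer(dims)))
    stopf("surface grids must be %d x %d to match metadata", dims[1], dims[2])
  both <- !is.na(ez_surface) & !is.na(rpe_surface)
  n_crossed <- sum(rpe_surface[both] < ez_surface[both])
  structure(
    list(metadata = metadata,
         ez_surface = ez_surface, rpe_surface = rpe_surface,
         eye_id = as.character(eye_id), visit_id = as.character(visit_id),
         n_crossed = n_crossed),
    class = "LayerVolume"
  )
}

#' @export
print.LayerVolume <- function(x, ...) {
  m <- x$metadata
  cat(sprintf("LayerVolume %s/%s: %s, %d B-scans x %d A-scans (%.2f x %.2f mm)\n",
              x$eye_id, x$visit_id, m$device_name, m$n_bscans, m$n_ascans,
              m$scan_width_mm, m$scan_depth_mm))
  cat(sprintf("  missing: EZ %d, RPE %d; crossed samples: %d\n",
              sum(is.na(x$ez_surface)), sum(is.na(x$rpe_surface)),
              x$n_crossed))
  invisible(x)
}

# Format axial positions losslessly; NA becomes the "NaN" sentinel.
fmt_axial <- function(v) {
  out <- sprintf("%.17g", v)
  out[is.na(v)] <- "NaN"
  paste(out, collapse = " ")
}

#' Write a layer volume to XML
#'
#' Serializes a [layer_volume()] to a self-describing XML file: one root
#' element carrying the scan metadata as attributes, one `<bscan>` element
#' per B-scan with whitespace-separated axial values per layer, and the
#' sentinel `NaN` for missing samples. The format round-trips losslessly
#' through [read_layer_xml()].
#'
#' @param volume A `LayerVolume`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_layer_xml <- function(volume, path) {
  stopifnot(inherits(volume, "LayerVolume"))
  m <- volume$metadata
  doc <- xml2::xml_new_root(
    "layer_volume",
    device_name = m$device_name,
    n_ascans = as.character(m$n_ascans),
    n_bscans = as.character(m$n_bscans),
    scan_width_mm = sprintf("%.17g", m$scan_width_mm),
    scan_depth_mm = sprintf("%.17g", m$scan_depth_mm),
    axial_scale_um_per_px = sprintf("%.17g", m$axial_scale_um_per_px),
    eye_id = volume$eye_id,
    visit_id = volume$visit_id
  )
  for (b in seq_len(m$n_bscans)) {
    bn <- xml2::xml_add_child(doc, "bscan", index = as.character(b - 1L))
    xml2::xml_add_child(bn, "ez", fmt_axial(volume$ez_surface[b, ]))
    xml2::xml_add_child(bn, "rpe", fmt_axial(volume$rpe_surface[b, ]))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

parse_axial <- function(text, n_expected, what, index) {
  vals <- suppressWarnings(as.numeric(strsplit(trimws(text), "\\s+")[[1]]))
  if (length(vals) != n_expected)
    stopf("schema error: bscan %d has %d %s values, expected %d",
          index, length(vals), what, n_expected)
  vals[is.nan(vals)] <- NA_real_
  vals
}

#' Read a layer volume from XML
#'
#' Parses a file written by [write_layer_xml()] (or produced by any exporter
#' following the same schema). Unparseable per-A-scan entries become `NA`.
#'
#' @param path Path to the XML file.
#' @return A `LayerVolume`.
#' @export
read_layer_xml <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stopf("malformed XML in %s: %s", path, conditionMessage(e)))
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "layer_volume")
    stopf("schema error: root element is <%s>, expected <layer_volume>",
          xml2::xml_name(root))
  att <- function(a) xml2::xml_attr(root, a)
  md <- volume_metadata(
    device_name = att("device_name"),
    n_ascans = as.integer(att("n_ascans")),
    n_bscans = as.integer(att("n_bscans")),
    scan_width_mm = as.numeric(att("scan_width_mm")),
    scan_depth_mm = as.numeric(att("scan_depth_mm")),
    axial_scale_um_per_px = as.numeric(att("axial_scale_um_per_px"))
  )
  bscans <- xml2::xml_find_all(root, "./bscan")
  if (length(bscans) != md$n_bscans)
    stopf("schema error: %d <bscan> elements, metadata declares %d",
          length(bscans), md$n_bscans)
  ez <- matrix(NA_real_, md$n_bscans, md$n_ascans)
  rpe <- matrix(NA_real_, md$n_bscans, md$n_ascans)
  idx <- as.integer(xml2::xml_attr(bscans, "index"))
  if (anyNA(idx) || !setequal(idx, 0:(md$n_bscans - 1L)))
    stopf("schema error: bscan indices must cover 0..%d exactly",
          md$n_bscans - 1L)
  for (i in seq_along(bscans)) {
    b <- idx[i] + 1L
    ez[b, ] <- parse_axial(
      xml2::xml_text(xml2::xml_find_first(bscans[[i]], "./ez")),
      md$n_ascans, "ez", idx[i])
    rpe[b, ] <- parse_axial(
      xml2::xml_text(xml2::xml_find_first(bscans[[i]], "./rpe")),
      md$n_ascans, "rpe", idx[i])
  }
  layer_volume(md, ez, rpe, eye_id = att("eye_id"), visit_id = att("visit_id"))
}

#' Construct a central-subfield record
#'
#' Location of the ETDRS central subfield (CSF) on the en face map of one
#' eye/visit. Coordinates are 0-based en face pixel indices (`center_x` =
#' column along the A-scan axis, `center_y` = row along the B-scan axis) and
#' may be fractional. The default disc diameter is the ETDRS central
#' subfield, 1 mm.
#'
#' @param eye_id,visit_id Identifier strings.
#' @param center_x,center_y Disc centre in 0-based en face pixels.
#' @param diameter_mm Disc diameter in mm (default 1.0).
#' @return A list with class `"CSFRecord"`.
#' @export
csf_record <- function(eye_id, visit_id, center_x, center_y,
                       diameter_mm = 1.0) {
  if (diameter_mm <= 0) stopf("diameter_mm must be positive")
  structure(
    list(eye_id = as.character(eye_id), visit_id = as.character(visit_id),
         center_x = as.numeric(center_x), center_y = as.numeric(center_y),
         diameter_mm = as.numeric(diameter_mm)),
    class = "CSFRecord"
  )
}

#' Read a central-subfield coordinate table
#'
#' Reads a CSV with header columns `eye_id`, `visit_id`, `center_x`,
#' `center_y` and optional `diameter_mm` (missing values default to 1.0 mm).
#' Each (`eye_id`, `visit_id`) pair must be unique.
#'
#' @param path Path to the CSV file.
#' @return A named list of [csf_record()] objects, keyed `"eye_id/visit_id"`.
#' @export
read_csf_table <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("eye_id", "visit_id", "center_x", "center_y")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0)
    stopf("schema error: missing column(s) %s; columns found: %s",
          paste(missing_cols, collapse = ", "),
          paste(names(df), collapse = ", "))
  if (!"diameter_mm" %in% names(df)) df$diameter_mm <- NA_real_
  df$diameter_mm[is.na(df$diameter_mm)] <- 1.0
  keys <- paste(df$eye_id, df$visit_id, sep = "/")
  dup <- keys[duplicated(keys)]
  if (length(dup) > 0)
    stopf("duplicate (eye_id, visit_id) key(s): %s",
          paste(unique(dup), collapse = ", "))
  out <- lapply(seq_len(nrow(df)), function(i)
    csf_record(df$eye_id[i], df$visit_id[i], df$center_x[i], df$center_y[i],
               df$diameter_mm[i]))
  names(out) <- keys
  out
}

#' Write a central-subfield coordinate table
#'
#' @param records A list of `CSFRecord` objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_csf_table <- function(records, path) {
  df <- do.call(rbind, lapply(records, function(r)
    data.frame(eye_id = r$eye_id, visit_id = r$visit_id,
               center_x = r$center_x, center_y = r$center_y,
               diameter_mm = r$diameter_mm)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
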