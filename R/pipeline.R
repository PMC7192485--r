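#' Dice overlap between two binary masks
#'
#' @param a,b Logical matrices of equal shape.
#' @return `2|A n B| / (|A| + |B|)`; 1 when both masks are empty.
#' @export
dice <- function(a, b) {
  if (!identical(dim(a), dim(b))) stopf("masks differ in shape")
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

log_line <- function(log_path, fmt, ...) {
  if (!is.null(log_path))
    cat(sprintf(paste0(fmt, "\n"), ...), file = log_path, append = TRUE)
}

#' Batch en face map generation
#'
#' Reads every layer XML in `input_dir`, builds the en face thickness map
#' and its grayscale rendering, rasterizes the CSF disc from the coordinate
#' table, and writes the three artifacts per volume plus a run log.
#' Per-file failures are logged and skipped; the batch continues.
#'
#' @param input_dir Directory of layer XML files.
#' @param csf_table_path CSV of CSF centres (see [read_csf_table()]).
#' @param out_dir Output directory.
#' @param window_um Grayscale rendering window.
#' @return List with `n_ok`, `n_failed`, `failed` (file names).
#' @export
run_map <- function(input_dir, csf_table_path, out_dir,
                    window_um = c(0, 64)) {
  files <- list.files(input_dir, pattern = "\\.xml$", full.names = TRUE)
  files <- files[!grepl("^(truth_|labels_)", basename(files))]
  if (length(files) == 0) stopf("no layer XML files found in %s", input_dir)
  records <- read_csf_table(csf_table_path)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run_map.log")
  cat("", file = log_path)
  failed <- character()
  for (f in files) {
    ok <- tryCatch({
      vol <- read_layer_xml(f)
      key <- paste(vol$eye_id, vol$visit_id, sep = "/")
      rec <- records[[key]]
      if (is.null(rec)) stopf("no CSF record for %s", key)
      map <- build_enface(vol)
      gray <- render_grayscale(map, window_um)
      mask <- csf_mask(rec, map)
      stem <- file.path(out_dir, vol$eye_id)
      write_thickness_png(map, paste0(stem, "_thickness.png"))
      png::writePNG(gray$pixels / 255, paste0(stem, "_gray.png"))
      png::writePNG(mask * 1, paste0(stem, "_csf.png"))
      log_line(log_path, "ok %s (clamped %d, missing rows %d)",
               basename(f), map$n_clamped, map$n_missing_rows)
      TRUE
    }, error = function(e) {
      log_line(log_path, "FAILED %s: %s", basename(f), conditionMessage(e))
      FALSE
    })
    if (!ok) failed <- c(failed, basename(f))
  }
  list(n_ok = length(files) - length(failed), n_failed = length(failed),
       failed = failed)
}

#' Train a classifier from an on-disk cohort
#'
#' Pairs each `labels_<eye>.png` scribble file with the corresponding
#' thickness map in `map_dir`, extracts feature stacks, trains the random
#' forest, and saves the model archive.
#'
#' @param map_dir Directory produced by [run_map()].
#' @param labels_dir Directory holding `labels_<eye>.png` files.
#' @param model_path Output model file.
#' @param config A [feature_config()].
#' @param seed Training seed.
#' @param window_um Grayscale window (must match the mapping step).
#' @return The trained `RFModel`, invisibly.
#' @export
run_train <- function(map_dir, labels_dir, model_path,
                      config = feature_config(), seed = 1L,
                      window_um = c(0, 64)) {
  lab_files <- list.files(labels_dir, pattern = "^labels_.*\\.png$",
                          full.names = TRUE)
  if (length(lab_files) == 0)
    stopf("no labels_*.png files found in %s", labels_dir)
  examples <- lapply(lab_files, function(lf) {
    eye <- sub("^labels_(.*)\\.png$", "\\1", basename(lf))
    map_path <- file.path(map_dir, paste0(eye, "_thickness.png"))
    if (!file.exists(map_path)) stopf("no thickness map for labels %s", lf)
    map <- read_thickness_png(map_path)
    gray <- render_grayscale(map, window_um)
    list(stack = feature_stack(gray, config), labels = read_labels_png(lf))
  })
  model <- train_classifier(examples, seed = seed)
  save_model(model, model_path)
  invisible(model)
}

#' Measure defect areas for an on-disk cohort
#'
#' Applies either the trained classifier (`method = "automatic"`) or manual
#' trace polygons (`method = "manual"`) to every thickness map in
#' `map_dir`, measures the defect area within the CSF, writes a tidy CSV
#' and per-eye review overlays. Eyes without a CSF record or trace are
#' skipped and logged.
#'
#' @param map_dir Directory produced by [run_map()].
#' @param csf_table_path CSF coordinate CSV.
#' @param out_dir Output directory for the CSV and overlays.
#' @param method `"automatic"` or `"manual"`.
#' @param model_path Model file (automatic method).
#' @param traces_dir Directory of `trace_<eye>.csv` files (manual method).
#' @param min_area_mm2 Minimum measurable component area.
#' @param window_um Grayscale window.
#' @return List of `DefectMeasurement` objects, invisibly; CSV at
#'   `<out_dir>/measurements_<method>.csv`.
#' @export
run_measure <- function(map_dir, csf_table_path, out_dir,
                        method = c("automatic", "manual"),
                        model_path = NULL, traces_dir = NULL,
                        min_area_mm2 = 0.004, window_um = c(0, 64)) {
  method <- match.arg(method)
  if (method == "automatic" && is.null(model_path))
    stopf("automatic method requires model_path")
  if (method == "manual" && is.null(traces_dir))
    stopf("manual method requires traces_dir")
  records <- read_csf_table(csf_table_path)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, sprintf("run_measure_%s.log", method))
  cat("", file = log_path)
  model <- if (method == "automatic") load_model(model_path) else NULL
  map_files <- list.files(map_dir, pattern = "_thickness\\.png$",
                          full.names = TRUE)
  measurements <- list()
  for (mf in map_files) {
    res <- tryCatch({
      map <- read_thickness_png(mf)
      key <- paste(map$eye_id, map$visit_id, sep = "/")
      rec <- records[[key]]
      if (is.null(rec)) stopf("no CSF record for %s", key)
      gray <- render_grayscale(map, window_um)
      mask <- csf_mask(rec, map)
      defect <- if (method == "automatic") {
        stack <- feature_stack(gray, model$config)
        defect_mask_from_classmap(predict_classmap(model, stack))
      } else {
        tf <- file.path(traces_dir, sprintf("trace_%s.csv", map$eye_id))
        if (!file.exists(tf)) stopf("no trace file for %s", map$eye_id)
        traces <- read_trace_csv(tf)
        d <- matrix(FALSE, nrow(map$values), ncol(map$values))
        for (tr in traces) d <- d | rasterize_polygon(tr, map)
        d
      }
      meas <- measure_defect(
        defect, mask, pixel_area_mm2 = map$pixel_dx_mm * map$pixel_dy_mm,
        min_area_mm2 = min_area_mm2, eye_id = map$eye_id,
        visit_id = map$visit_id,
        method = if (method == "automatic") "automated" else "manual")
      write_overlay_png(gray, defect, mask,
                        file.path(out_dir, sprintf("overlay_%s_%s.png",
                                                   method, map$eye_id)))
      log_line(log_path, "ok %s: %.4f mm^2", map$eye_id,
               meas$total_area_mm2)
      meas
    }, error = function(e) {
      log_line(log_path, "FAILED %s: %s", basename(mf),
               conditionMessage(e))
      NULL
    })
    if (!is.null(res)) measurements[[length(measurements) + 1]] <- res
  }
  if (length(measurements) == 0) stopf("no maps could be measured")
  write_measurements_csv(
    measurements,
    file.path(out_dir, sprintf("measurements_%s.csv", method)))
  invisible(measurements)
}

#' Compare manual and automated measurement CSVs
#'
#' Joins two measurement CSVs on (eye_id, visit_id), computes the agreement
#' statistics, and writes a stats JSON plus Bland-Altman and scatter plots.
#'
#' @param manual_csv,automated_csv Measurement CSVs from [run_measure()].
#' @param out_dir Output directory.
#' @return The `AgreementStats`, invisibly.
#' @export
run_compare <- function(manual_csv, automated_csv, out_dir) {
  man <- utils::read.csv(manual_csv, stringsAsFactors = FALSE)
  aut <- utils::read.csv(automated_csv, stringsAsFactors = FALSE)
  man$key <- paste(man$eye_id, man$visit_id, sep = "/")
  aut$key <- paste(aut$eye_id, aut$visit_id, sep = "/")
  keys <- intersect(man$key, aut$key)
  if (length(keys) < 3)
    stopf("need at least 3 overlapping (eye, visit) pairs, have %d",
          length(keys))
  pairs <- paired_areas(
    x = man$total_area_mm2[match(keys, man$key)],
    y = aut$total_area_mm2[match(keys, aut$key)],
    keys = keys)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  st <- agreement_stats(pairs)
  jsonlite::write_json(unclass(st), file.path(out_dir, "agreement.json"),
                       auto_unbox = TRUE, digits = NA)
  plot_agreement(pairs, file.path(out_dir, "bland_altman.png"),
                 file.path(out_dir, "scatter.png"))
  invisible(st)
}

#' End-to-end synthetic validation of the classification pipeline
#'
#' Mirrors the measurement protocol at cohort scale, entirely in memory:
#' generates `n_eyes` synthetic volumes, builds their en face maps, trains
#' the classifier on the scribbles of a ~10% subset, applies it to the
#' remaining eyes, and measures defect areas automatically and from the
#' emulated manual traces. Returns per-eye results and the summary
#' statistics used to validate recovery of the known ground truth.
#'
#' @param seed Integer seed controlling cohort generation and training.
#' @param n_eyes Cohort size (default 30).
#' @param spec Optional [synthetic_spec()]; overrides `n_eyes`/`seed`.
#' @param verbose Print per-eye progress.
#' @return List with `per_eye` (data frame: eye_id, dice, automated,
#'   manual, truth areas), `model`, and summary statistics
#'   (`median_abs_error_mm2`, `icc_vs_truth`, `stats_auto_vs_manual`).
#' @export
run_synthetic_benchmark <- function(seed = 1L, n_eyes = 30L, spec = NULL,
                                    verbose = FALSE) {
  if (is.null(spec)) spec <- synthetic_spec(n_eyes = n_eyes, seed = seed)
  n_train <- max(1L, ceiling(0.10 * spec$n_eyes))
  config <- feature_config()

  examples <- list()
  test_idx <- integer()
  eyes <- vector("list", spec$n_eyes)
  grays <- vector("list", spec$n_eyes)
  masks <- vector("list", spec$n_eyes)
  for (i in seq_len(spec$n_eyes)) {
    eye <- generate_eye(spec, i)
    map <- build_enface(eye$volume)
    gray <- render_grayscale(map)
    eyes[[i]] <- eye
    grays[[i]] <- gray
    masks[[i]] <- csf_mask(eye$csf_record, map)
    if (i <= n_train) {
      examples[[length(examples) + 1]] <-
        list(stack = feature_stack(gray, config),
             labels = generate_labels(eye))
    } else {
      test_idx <- c(test_idx, i)
    }
    if (verbose) message(sprintf("prepared eye %d/%d", i, spec$n_eyes))
  }

  model <- train_classifier(examples, seed = derive_seed(spec$seed, 31L))

  res <- data.frame(eye_id = character(), dice = numeric(),
                    automated_mm2 = numeric(), manual_mm2 = numeric(),
                    true_mm2 = numeric())
  for (i in test_idx) {
    eye <- eyes[[i]]
    gray <- grays[[i]]
    mask <- masks[[i]]
    stack <- feature_stack(gray, config)
    cm <- predict_classmap(model, stack)
    defect <- defect_mask_from_classmap(cm)
    px_area <- gray$pixel_dx_mm * gray$pixel_dy_mm
    auto <- measure_defect(defect, mask, px_area, eye_id = eye$volume$eye_id,
                           method = "automated")
    man_mask <- matrix(FALSE, nrow(defect), ncol(defect))
    for (tr in generate_manual_trace(eye))
      man_mask <- man_mask | rasterize_polygon(tr, gray)
    man <- measure_defect(man_mask, mask, px_area,
                          eye_id = eye$volume$eye_id, method = "manual")
    res <- rbind(res, data.frame(
      eye_id = eye$volume$eye_id,
      dice = dice(defect, eye$truth_mask),
      automated_mm2 = auto$total_area_mm2,
      manual_mm2 = man$total_area_mm2,
      true_mm2 = eye$true_csf_area_mm2))
    if (verbose) message(sprintf("measured eye %d: dice %.3f", i,
                                 res$dice[nrow(res)]))
  }

  pairs_truth <- paired_areas(res$true_mm2, res$automated_mm2,
                              keys = res$eye_id)
  pairs_methods <- paired_areas(res$manual_mm2, res$automated_mm2,
                                keys = res$eye_id)
  list(per_eye = res, model = model,
       median_abs_error_mm2 = stats::median(abs(res$automated_mm2 -
                                                  res$true_mm2)),
       icc_vs_truth = icc(pairs_truth)$icc,
       stats_auto_vs_manual = agreement_stats(pairs_methods))
}
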