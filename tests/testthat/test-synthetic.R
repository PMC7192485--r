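test_that("a noise-free, defect-free eye yields constant thickness and zero defect", {
  spec <- synthetic_spec(n_eyes = 1, defect_model = list(),
                         surface_wobble_um = 0, boundary_noise_um = 0,
                         missing_fraction = 0, seed = 4)
  eye <- generate_eye(spec, 1)
  map <- build_enface(eye$volume)
  expect_equal(max(abs(map$values - 35)), 0, tolerance = 1e-9)
  expect_identical(sum(eye$truth_mask), 0L)
  mask <- csf_mask(eye$csf_record, map)
  m <- measure_defect(eye$truth_mask, mask,
                      map$pixel_dx_mm * map$pixel_dy_mm)
  expect_equal(m$total_area_mm2, 0)
  expect_equal(eye$true_csf_area_mm2, 0)
})

test_that("a centred ellipse recovers its analytic area from the oracle", {
  blob <- list(center_mm = c(3, 3), semi_axes_mm = c(0.4, 0.3),
               rotation = 0, residual_thickness_um = 0)
  spec <- synthetic_spec(n_eyes = 1, defect_model = list(blob),
                         boundary_noise_um = 0, missing_fraction = 0,
                         seed = 4)
  eye <- generate_eye(spec, 1)
  analytic <- pi * 0.4 * 0.3
  expect_equal(eye$true_csf_area_mm2, analytic, tolerance = 0.005)
  px_area <- eye$pixel_dx_mm * eye$pixel_dy_mm
  expect_equal(sum(eye$truth_mask) * px_area, analytic, tolerance = 0.005)
})

test_that("an ellipse fully inside the CSF matches pi*a*b within 0.5%", {
  blob <- list(center_mm = c(3, 3), semi_axes_mm = c(0.3, 0.2),
               rotation = 0.7, residual_thickness_um = 0)
  spec <- synthetic_spec(n_eyes = 1, defect_model = list(blob), seed = 4)
  eye <- generate_eye(spec, 1)
  analytic <- pi * 0.3 * 0.2
  expect_lt(abs(eye$true_csf_area_mm2 - analytic) / analytic, 0.005)
})

test_that("a defect covering the whole CSF measures the full disc area", {
  blob <- list(center_mm = c(3, 3), semi_axes_mm = c(0.9, 0.9),
               rotation = 0, residual_thickness_um = 0)
  spec <- synthetic_spec(n_eyes = 1, defect_model = list(blob), seed = 4)
  eye <- generate_eye(spec, 1)
  expect_equal(eye$true_csf_area_mm2, pi * 0.25, tolerance = 0.002)
})

test_that("a blob outside the CSF contributes zero oracle area", {
  blob <- list(center_mm = c(1, 1), semi_axes_mm = c(0.3, 0.2),
               rotation = 0, residual_thickness_um = 0)
  spec <- synthetic_spec(n_eyes = 1, defect_model = list(blob), seed = 4)
  eye <- generate_eye(spec, 1)
  expect_equal(eye$true_csf_area_mm2, 0)
  bad <- list(center_mm = c(0.1, 3), semi_axes_mm = c(0.3, 0.2),
              rotation = 0, residual_thickness_um = 0)
  expect_error(
    generate_eye(synthetic_spec(defect_model = list(bad), seed = 4), 1),
    "outside")
})

test_that("generation is deterministic per (seed, eye) and order-independent", {
  spec <- synthetic_spec(n_eyes = 3, seed = 123)
  a <- generate_eye(spec, 2)
  b <- generate_eye(spec, 2)
  expect_identical(a$volume$ez_surface, b$volume$ez_surface)
  expect_identical(a$truth_mask, b$truth_mask)
  # a different eye index gives a different defect
  c3 <- generate_eye(spec, 3)
  expect_false(identical(a$blobs, c3$blobs))
  # and the global RNG stream is left untouched
  set.seed(1); before <- runif(3)
  set.seed(1); generate_eye(spec, 1); after <- runif(3)
  expect_identical(before, after)
})

test_that("label scribbles never contradict the ground truth", {
  spec <- synthetic_spec(n_eyes = 2, seed = 9)
  for (i in 1:2) {
    eye <- generate_eye(spec, i)
    labels <- generate_labels(eye)
    expect_true(all(eye$truth_mask[labels == 2L]))
    expect_true(!any(eye$truth_mask[labels == 1L]))
    expect_gt(sum(labels == 2L), 50)
    expect_gt(sum(labels == 1L), 50)
  }
})

test_that("manual traces enclose approximately the true defect area", {
  spec <- synthetic_spec(n_eyes = 1, seed = 77)
  eye <- generate_eye(spec, 1)
  g <- list(rows = eye$out_rows, cols = ncol(eye$truth_mask),
            pixel_dx_mm = eye$pixel_dx_mm, pixel_dy_mm = eye$pixel_dy_mm)
  m <- matrix(FALSE, g$rows, g$cols)
  for (tr in generate_manual_trace(eye)) m <- m | rasterize_polygon(tr, g)
  expect_gt(dice(m, eye$truth_mask), 0.95)
})

test_that("cohort generation writes a complete, parseable file tree", {
  out <- withr::local_tempdir()
  spec <- synthetic_spec(n_eyes = 4, seed = 5,
                         defect_area_range_mm2 = c(0.1, 0.4))
  manifest <- generate_cohort(spec, out)
  expect_length(list.files(out, pattern = "^E\\d+\\.xml$"), 4)
  expect_length(list.files(out, pattern = "^truth_.*\\.png$"), 4)
  expect_length(list.files(out, pattern = "^labels_.*\\.png$"), 1)  # ~10%
  expect_length(list.files(out, pattern = "^trace_.*\\.csv$"), 4)
  expect_true(file.exists(file.path(out, "csf.csv")))
  expect_true(file.exists(file.path(out, "manifest.json")))

  # everything parses back through the I/O layer
  recs <- read_csf_table(file.path(out, "csf.csv"))
  expect_length(recs, 4)
  vol <- read_layer_xml(file.path(out, manifest$eyes[[2]]$xml))
  expect_identical(vol$eye_id, manifest$eyes[[2]]$eye_id)

  # manifest areas equal an oracle recomputation
  for (i in c(1, 3)) {
    eye <- generate_eye(spec, i)
    expect_equal(manifest$eyes[[i]]$true_csf_area_mm2,
                 true_area_oracle(eye))
  }
})

test_that("heavier boundary noise degrades thickness-map fidelity monotonically", {
  rmse <- sapply(c(0, 3, 10), function(noise) {
    spec <- synthetic_spec(n_eyes = 1, boundary_noise_um = noise,
                           missing_fraction = 0, seed = 11)
    eye <- generate_eye(spec, 1)
    clean <- synthetic_spec(n_eyes = 1, boundary_noise_um = 0,
                            missing_fraction = 0, seed = 11)
    ref <- build_enface(generate_eye(clean, 1)$volume)$values
    sqrt(mean((build_enface(eye$volume)$values - ref)^2))
  })
  expect_true(all(diff(rmse) > 0))
})
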