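grid512 <- list(rows = 512L, cols = 512L,
                pixel_dx_mm = 6 / 512, pixel_dy_mm = 6 / 512)

test_that("the 1-mm CSF disc has the analytic ceiling area", {
  expect_equal(csf_analytic_area(1.0), pi * 0.25)
  expect_equal(csf_reported_bound(1.0), 0.78)
})

test_that("rasterized disc area converges to the analytic value", {
  rec <- csf_record("E", "V", 255.5, 255.5)
  mask <- csf_mask(rec, grid512)
  px_area <- grid512$pixel_dx_mm * grid512$pixel_dy_mm
  expect_lt(abs(sum(mask) * px_area - pi * 0.25) / (pi * 0.25), 0.01)
  expect_equal(attr(mask, "csf_area_mm2"), pi * 0.25)
})

test_that("degenerate and out-of-bounds discs are handled", {
  tiny <- csf_mask(csf_record("E", "V", 255.5, 255.5,
                              diameter_mm = 1e-4), grid512)
  expect_identical(sum(tiny), 0L)
  expect_error(csf_mask(csf_record("E", "V", 600, 255.5), grid512),
               "outside")
  expect_warning(csf_mask(csf_record("E", "V", 2, 255.5), grid512),
                 "clipped")
})

test_that("defect masks mirror classmap labels exactly", {
  labels <- matrix(rep_len(c(1L, 2L), 36), 6)
  cm <- structure(list(labels = labels,
                       probabilities = array(0.5, c(6, 6, 2)),
                       classes = ez_classes()), class = "ClassMap")
  expect_identical(defect_mask_from_classmap(cm), labels == 2L)
})

test_that("axis-aligned rectangles rasterize to exact pixel counts", {
  g <- list(rows = 30L, cols = 30L, pixel_dx_mm = 0.1, pixel_dy_mm = 0.1)
  # covers pixel centres 5..9 x 3..10 -> 5 x 8
  tr <- polygon_trace(x = c(4.5, 9.5, 9.5, 4.5), y = c(2.5, 2.5, 10.5, 10.5))
  m <- rasterize_polygon(tr, g)
  expect_identical(sum(m), 5L * 8L)
  expect_true(all(which(m, arr.ind = TRUE)[, "col"] %in% 6:10))
})

test_that("triangle rasterization matches a half-plane oracle", {
  g <- list(rows = 24L, cols = 24L, pixel_dx_mm = 1, pixel_dy_mm = 1)
  vx <- c(1.4, 20.6, 4.3)
  vy <- c(2.2, 5.7, 21.5)
  m <- rasterize_polygon(polygon_trace(vx, vy), g)
  oracle <- matrix(FALSE, 24, 24)
  cross <- function(ax, ay, bx, by, px, py)
    (bx - ax) * (py - ay) - (by - ay) * (px - ax)
  for (r in 1:24) for (c in 1:24) {
    px <- c - 1; py <- r - 1
    d1 <- cross(vx[1], vy[1], vx[2], vy[2], px, py)
    d2 <- cross(vx[2], vy[2], vx[3], vy[3], px, py)
    d3 <- cross(vx[3], vy[3], vx[1], vy[1], px, py)
    oracle[r, c] <- all(c(d1, d2, d3) > 0) || all(c(d1, d2, d3) < 0)
  }
  expect_identical(m, oracle)
})

test_that("polygons outside the map clip to empty with a warning", {
  g <- list(rows = 10L, cols = 10L, pixel_dx_mm = 1, pixel_dy_mm = 1)
  expect_warning(
    m <- rasterize_polygon(polygon_trace(c(20, 25, 22), c(20, 20, 25)), g),
    "outside")
  expect_identical(sum(m), 0L)
  expect_error(polygon_trace(c(0, 4, 4, 0), c(0, 4, 0, 4)),
               "self-intersecting")
  expect_error(polygon_trace(c(0, 1), c(0, 1)), "at least 3")
})

test_that("component labeling is 8-connected and matches a flood-fill oracle", {
  diag_mask <- matrix(0, 4, 4)
  diag_mask[cbind(1:4, 1:4)] <- 1
  lab <- label_components(diag_mask)
  expect_identical(attr(lab, "n_components"), 1L)

  set.seed(77)
  for (i in 1:100) {
    m <- matrix(runif(15 * 15) < 0.35, 15)
    lab <- label_components(m)
    sizes <- sort(tabulate(lab[lab > 0], nbins = attr(lab, "n_components")))
    expect_identical(sizes, sort(flood_components(m)))
  }
})

test_that("the minimum-area rule drops 29-pixel and keeps 30-pixel components", {
  px_area <- (6 / 512)^2
  csf <- matrix(TRUE, 40, 40)
  attr(csf, "csf_area_mm2") <- pi * 0.25
  m29 <- matrix(FALSE, 40, 40); m29[2:30, 2] <- TRUE
  m30 <- matrix(FALSE, 40, 40); m30[2:31, 2] <- TRUE
  r29 <- measure_defect(m29, csf, px_area)
  r30 <- measure_defect(m30, csf, px_area)
  expect_equal(29 * px_area, 0.00398, tolerance = 1e-3)
  expect_identical(r29$below_min_dropped, 1L)
  expect_equal(r29$total_area_mm2, 0)
  expect_identical(r30$below_min_dropped, 0L)
  expect_equal(r30$total_area_mm2, 30 * px_area)
})

test_that("a defect covering the whole CSF measures the analytic disc area", {
  rec <- csf_record("E", "V", 255.5, 255.5)
  csf <- csf_mask(rec, grid512)
  full <- matrix(TRUE, 512, 512)
  r <- measure_defect(full, csf, grid512$pixel_dx_mm * grid512$pixel_dy_mm)
  expect_equal(r$total_area_mm2, pi * 0.25)   # capped at the ceiling
  expect_lte(floor(r$total_area_mm2 * 100) / 100, csf_reported_bound(1.0))
})

test_that("pixels outside the CSF never affect measurements; growth is monotone", {
  rec <- csf_record("E", "V", 255.5, 255.5)
  csf <- csf_mask(rec, grid512)
  px_area <- grid512$pixel_dx_mm * grid512$pixel_dy_mm
  inside <- matrix(FALSE, 512, 512); inside[250:260, 250:260] <- TRUE
  outside_extra <- inside; outside_extra[1:50, 1:50] <- TRUE
  a <- measure_defect(inside, csf, px_area)$total_area_mm2
  b <- measure_defect(outside_extra, csf, px_area)$total_area_mm2
  expect_equal(a, b)

  set.seed(12)
  base <- matrix(runif(512 * 512) < 0.001, 512)
  grown <- base
  grown[255:258, 240:280] <- TRUE   # add defect inside the CSF
  expect_gte(measure_defect(grown, csf, px_area)$total_area_mm2,
             measure_defect(base, csf, px_area)$total_area_mm2)
})

test_that("shape mismatches error and measurements tabulate tidily", {
  csf <- matrix(TRUE, 4, 4)
  expect_error(measure_defect(matrix(TRUE, 3, 4), csf, 1), "shape")
  m <- measure_defect(matrix(c(TRUE, rep(FALSE, 15)), 4), csf, 0.01,
                      eye_id = "E1", visit_id = "M01")
  df <- measurements_to_df(list(m))
  expect_identical(df$eye_id, "E1")
  expect_equal(df$total_area_mm2, 0.01)
  f <- withr::local_tempfile(fileext = ".csv")
  write_measurements_csv(list(m), f)
  expect_equal(utils::read.csv(f)$total_area_mm2, 0.01)
})
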