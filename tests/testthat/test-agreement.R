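test_that("paired series validate lengths, sign, and missingness", {
  expect_error(paired_areas(1:3, 1:4), "length")
  expect_error(paired_areas(c(-1, 2, 3), c(1, 2, 3)), "non-negative")
  p <- paired_areas(c(0.1, NA, 0.3, 0.4), c(0.2, 0.2, NA, 0.5))
  expect_identical(p$n_dropped, 2L)
  expect_length(p$x, 2)
})

test_that("ICC(A,1) is 1 for identity, below 1 for a constant offset", {
  x <- c(0.1, 0.25, 0.4, 0.05, 0.3, 0.2)
  expect_equal(icc(paired_areas(x, x))$icc, 1)
  shifted <- icc(paired_areas(x, x + 0.5))$icc
  expect_lt(shifted, 1)   # absolute agreement penalizes the offset
  expect_error(icc(paired_areas(rep(2, 4), rep(2, 4))), "zero variance")
  expect_error(icc(paired_areas(1:2, 2:3)), "at least 3")
})

test_that("ICC(A,1) matches the independent mean-squares oracle", {
  x <- c(0.12, 0.31, 0.05, 0.44, 0.27, 0.18)
  y <- c(0.15, 0.28, 0.09, 0.40, 0.31, 0.14)
  res <- icc(paired_areas(x, y))
  expect_equal(res$icc, icc_a1_oracle(x, y), tolerance = 1e-12)
  expect_identical(res$icc_form, "ICC(A,1)")

  set.seed(88)
  for (i in 1:20) {
    n <- sample(4:15, 1)
    a <- runif(n, 0, 0.7)
    b <- a + rnorm(n, 0.02, 0.05)
    b <- pmax(b, 0)
    expect_equal(icc(paired_areas(a, b))$icc, icc_a1_oracle(a, b),
                 tolerance = 1e-10)
  }
})

test_that("Bland-Altman bias and limits of agreement are correct", {
  x <- c(0.1, 0.2, 0.3)
  r0 <- bland_altman(paired_areas(x, x))
  expect_equal(c(r0$bias, r0$loa_low, r0$loa_high), c(0, 0, 0))

  r1 <- bland_altman(paired_areas(c(1, 2, 3, 4), c(2, 3, 4, 5)))
  expect_equal(r1$bias, 1)
  expect_equal(r1$loa_low, 1)   # zero SD of differences

  r2 <- bland_altman(paired_areas(c(2, 1), c(1, 2)))
  expect_equal(r2$bias, 0)
  expect_equal(r2$loa_high, 1.96 * sqrt(2), tolerance = 1e-12)
  expect_equal(r2$loa_low, -2.772, tolerance = 1e-3)
})

test_that("Wilcoxon exact p matches brute-force sign enumeration", {
  w <- wilcoxon_signed_rank(paired_areas(c(1, 1, 1), c(2, 3, 4)))
  expect_equal(w$statistic, 6)
  expect_equal(w$p_value, 0.25)   # enumeration over 2^3 sign patterns
  expect_true(w$exact)

  set.seed(41)
  for (i in 1:5) {
    x <- runif(12, 0, 1)
    y <- pmax(x + rnorm(12, 0.05, 0.2), 0)
    # regenerate on the rare event of ties or zero differences
    while (anyDuplicated(abs(y - x)) || any(y == x))
      y <- pmax(x + rnorm(12, 0.05, 0.2), 0)
    mine <- wilcoxon_signed_rank(paired_areas(x, y))
    expect_true(mine$exact)
    expect_equal(mine$p_value, brute_force_signrank_p(y - x),
                 tolerance = 1e-12)
  }
})

test_that("Wilcoxon handles degenerate and tied inputs", {
  x <- c(0.1, 0.2, 0.3)
  d <- wilcoxon_signed_rank(paired_areas(x, x))
  expect_true(d$degenerate)
  expect_equal(d$p_value, 1)

  # ties in |d| force the corrected normal approximation
  tied <- wilcoxon_signed_rank(paired_areas(rep(0, 6),
                                            c(1, 1, 2, 2, 3, 3)))
  expect_false(tied$exact)
  expect_gt(tied$p_value, 0)
  expect_lte(tied$p_value, 1)
})

test_that("exact and normal-approximation p agree within 0.01 for tie-free n 15-25", {
  set.seed(19)
  for (n in c(15, 20, 25)) {
    x <- runif(n)
    y <- pmax(x + rnorm(n, 0.03, 0.15), 0)
    while (anyDuplicated(abs(y - x)) || any(y == x))
      y <- pmax(x + rnorm(n, 0.03, 0.15), 0)
    res <- wilcoxon_signed_rank(paired_areas(x, y))
    expect_true(res$exact)
    d <- y - x
    r <- rank(abs(d))
    w <- sum(r[d > 0])
    mu <- n * (n + 1) / 4
    s2 <- n * (n + 1) * (2 * n + 1) / 24
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(s2)
    p_norm <- 2 * stats::pnorm(-abs(z))
    expect_lt(abs(res$p_value - p_norm), 0.01)
  }
})

test_that("Wilcoxon agrees with the standard library routine on tie-free data", {
  set.seed(23)
  x <- runif(10)
  y <- pmax(x + rnorm(10, 0, 0.2), 0)
  while (anyDuplicated(abs(y - x)) || any(y == x))
    y <- pmax(x + rnorm(10, 0, 0.2), 0)
  mine <- wilcoxon_signed_rank(paired_areas(x, y))
  ref <- stats::wilcox.test(y, x, paired = TRUE, exact = TRUE)
  expect_equal(mine$statistic, unname(ref$statistic))
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
})

test_that("agreement statistics obey exchange and scaling symmetries", {
  set.seed(31)
  x <- runif(10, 0, 0.6)
  y <- pmax(x + rnorm(10, 0.01, 0.05), 0)
  a <- agreement_stats(paired_areas(x, y))
  b <- agreement_stats(paired_areas(y, x))
  expect_equal(a$icc, b$icc, tolerance = 1e-12)
  expect_equal(a$bias, -b$bias, tolerance = 1e-12)
  expect_equal(a$loa_high, -b$loa_low, tolerance = 1e-12)

  s <- agreement_stats(paired_areas(3 * x, 3 * y))
  expect_equal(s$icc, a$icc, tolerance = 1e-12)
  expect_equal(s$bias, 3 * a$bias, tolerance = 1e-12)
  expect_equal(s$loa_high, 3 * a$loa_high, tolerance = 1e-12)
})

test_that("noisier automated measurements lower the ICC toward truth", {
  set.seed(53)
  x <- runif(30, 0, 0.6)
  iccs <- sapply(c(0.005, 0.05, 0.2), function(s)
    icc(paired_areas(x, pmax(x + rnorm(30, 0, s), 0)))$icc)
  expect_true(all(diff(iccs) < 0))
  expect_gt(iccs[1], 0.99)
})

test_that("per-visit summaries report n, spread, and nonzero fraction", {
  mk <- function(eye, visit, method, area)
    structure(list(eye_id = eye, visit_id = visit, method = method,
                   components = data.frame(), total_area_mm2 = area,
                   below_min_dropped = 0L, csf_area_mm2 = pi * 0.25),
              class = "DefectMeasurement")
  ms <- list(mk("E1", "M01", "manual", 0.1), mk("E2", "M01", "manual", 0.3),
             mk("E1", "M06", "manual", 0.2),
             mk("E1", "M01", "automated", 0), mk("E2", "M01", "automated", 0))
  s <- summarize_measurements(ms)
  m01 <- s[s$visit_id == "M01" & s$method == "manual", ]
  expect_equal(m01$mean, 0.2)
  expect_equal(m01$sd, sd(c(0.1, 0.3)))
  expect_equal(m01$sd, 0.1414, tolerance = 1e-3)
  single <- s[s$visit_id == "M06", ]
  expect_equal(single$sd, 0)
  expect_true(single$sd_flagged)
  auto <- s[s$method == "automated", ]
  expect_equal(auto$frac_nonzero, 0)
})
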