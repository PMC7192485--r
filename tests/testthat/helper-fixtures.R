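# Small in-code fixtures and independent oracles shared across tests.

# A tiny custom-geometry metadata for fast unit tests.
tiny_metadata <- function(n_ascans = 8L, n_bscans = 4L,
                          width = 2, depth = 1, axial = 2) {
  volume_metadata("custom", n_ascans = n_ascans, n_bscans = n_bscans,
                  scan_width_mm = width, scan_depth_mm = depth,
                  axial_scale_um_per_px = axial)
}

# Constant-thickness volume: rpe at `base`, ez offset by thickness/axial.
const_volume <- function(md = tiny_metadata(), base = 100,
                         thickness_um = 20) {
  rpe <- matrix(base, md$n_bscans, md$n_ascans)
  ez <- rpe - thickness_um / md$axial_scale_um_per_px
  layer_volume(md, ez, rpe, eye_id = "T01", visit_id = "V01")
}

# Independent 8-connected component oracle: queue-based flood fill.
flood_components <- function(mask) {
  mask <- mask != 0
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  sizes <- integer()
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (!mask[r0, c0] || seen[r0, c0]) next
    queue <- list(c(r0, c0))
    seen[r0, c0] <- TRUE
    size <- 0L
    while (length(queue) > 0) {
      p <- queue[[length(queue)]]
      queue[[length(queue)]] <- NULL
      size <- size + 1L
      for (dr in -1:1) for (dc in -1:1) {
        r <- p[1] + dr; c <- p[2] + dc
        if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
            mask[r, c] && !seen[r, c]) {
          seen[r, c] <- TRUE
          queue[[length(queue) + 1]] <- c(r, c)
        }
      }
    }
    sizes <- c(sizes, size)
  }
  sizes
}

# Brute-force two-tailed signed-rank p over all 2^n sign assignments.
brute_force_signrank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs)))
}

# ICC(A,1) oracle from an independent ANOVA decomposition.
icc_a1_oracle <- function(x, y) {
  n <- length(x)
  d <- data.frame(v = c(x, y), subj = factor(rep(seq_len(n), 2)),
                  meth = factor(rep(1:2, each = n)))
  a <- stats::anova(stats::aov(v ~ subj + meth, data = d))
  msr <- a["subj", "Mean Sq"]
  msc <- a["meth", "Mean Sq"]
  mse <- a["Residuals", "Mean Sq"]
  (msr - mse) / (msr + mse + 2 / n * (msc - mse))
}
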