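#' Multiscale feature configuration
#'
#' Configuration of the texture feature stack used for pixel classification:
#' scale set (Gaussian sigmas in pixels, powers of two up to a maximum of 32
#' by default) and the enabled feature families. The defaults mirror the
#' standard trainable-segmentation feature set with the maximum sigma raised
#' to 32 so that coarse, smoothly varying defects are captured.
#'
#' @param scales Strictly increasing numeric vector of sigma values (px).
#' @param feature_families Character subset of `"gaussian_blur"`, `"sobel"`,
#'   `"hessian"`, `"dog"`, `"membrane_projections"`, `"variance"`.
#' @param membrane_kernel_size Side of the square membrane kernel (odd).
#' @param membrane_rotations Number of line-kernel rotations over 180 deg.
#' @return A list with class `"FeatureConfig"`.
#' @export
feature_config <- function(scales = c(1, 2, 4, 8, 16, 32),
                           feature_families = c("gaussian_blur", "sobel",
                                                "hessian", "dog",
                                                "membrane_projections",
                                                "variance"),
                           membrane_kernel_size = 19L,
                           membrane_rotations = 30L) {
  if (length(feature_families) == 0)
    stopf("at least one feature family is required")
  families <- match.arg(feature_families,
                        c("gaussian_blur", "sobel", "hessian", "dog",
                          "membrane_projections", "variance"),
                        several.ok = TRUE)
  if (is.unsorted(scales, strictly = TRUE) || any(scales <= 0))
    stopf("scales must be strictly increasing and positive")
  if (membrane_kernel_size %% 2 == 0)
    stopf("membrane_kernel_size must be odd")
  structure(
    list(scales = as.numeric(scales), feature_families = families,
         membrane_kernel_size = as.integer(membrane_kernel_size),
         membrane_rotations = as.integer(membrane_rotations)),
    class = "FeatureConfig"
  )
}

#' Feature channel names implied by a configuration
#'
#' Deterministic, unique channel labels in stack order: the raw image first,
#' then per-family channels in configuration order.
#'
#' @param config A `FeatureConfig`.
#' @return Character vector of channel names.
#' @export
feature_names <- function(config) {
  s <- config$scales
  nm <- "raw"
  for (fam in config$feature_families) {
    nm <- c(nm, switch(
      fam,
      gaussian_blur = sprintf("gaussian_s%g", s),
      sobel = sprintf("sobel_s%g", s),
      hessian = as.vector(t(outer(
        s, c("eig1", "eig2", "trace", "det"),
        function(si, w) sprintf("hessian_%s_s%g", w, si)))),
      dog = {
        pairs <- which(upper.tri(matrix(0, length(s), length(s))),
                       arr.ind = TRUE)
        pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
        sprintf("dog_s%g_s%g", s[pairs[, 1]], s[pairs[, 2]])
      },
      membrane_projections = sprintf(
        "membrane_%s", c("sum", "mean", "std", "median", "max", "min")),
      variance = sprintf("variance_s%g", s)
    ))
  }
  nm
}

# --- kernels -----------------------------------------------------------

# Sampled, sum-normalized isotropic Gaussian kernel, radius ceiling(3 sigma).
gaussian_kernel <- function(sigma) {
  r <- ceiling(3 * sigma)
  d <- seq(-r, r)
  k <- exp(-outer(d^2, d^2, "+") / (2 * sigma^2))
  k / sum(k)
}

# Disc kernel of given pixel radius, sum-normalized (local-mean filter).
disc_kernel <- function(radius) {
  r <- ceiling(radius)
  d <- seq(-r, r)
  k <- 1 * (outer(d^2, d^2, "+") <= radius^2)
  k / sum(k)
}

# 1-pixel-wide line through the kernel centre at `theta` radians,
# sum-normalized so a flat field gives identical responses at every angle.
membrane_kernel <- function(size, theta) {
  h <- (size - 1) / 2
  d <- seq(-h, h)
  xx <- matrix(rep(d, each = size), size)   # column offset
  yy <- matrix(rep(d, times = size), size)  # row offset
  dist <- abs(xx * sin(theta) - yy * cos(theta))
  half_len <- abs(xx * cos(theta) + yy * sin(theta))
  k <- 1 * (dist < 0.5 & half_len <= h + 1e-9)
  k / sum(k)
}

sobel_x <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, byrow = TRUE)

# --- FFT convolution engine --------------------------------------------
#
# All large-kernel convolutions go through one padded FFT grid. The kernel
# transforms depend only on (grid size, config), so they are computed once
# per geometry and cached for the session; each convolution then costs a
# single inverse transform.

# Reflection (mirror) padding with period 2n-2, valid for any pad width.
reflect_pad <- function(x, pad) {
  fold <- function(i, n) {
    if (n == 1) return(rep(1L, length(i)))
    j <- (i - 1L) %% (2L * n - 2L)
    ifelse(j >= n, 2L * n - 2L - j, j) + 1L
  }
  ri <- fold(seq(1L - pad, nrow(x) + pad), nrow(x))
  ci <- fold(seq(1L - pad, ncol(x) + pad), ncol(x))
  x[ri, ci, drop = FALSE]
}

# Smallest n >= x with only small prime factors (fast mixed-radix FFT).
good_fft_size <- function(x) {
  n <- as.integer(x)
  repeat {
    m <- n
    for (p in c(2L, 3L, 5L, 7L, 11L, 13L)) while (m %% p == 0L) m <- m %/% p
    if (m == 1L) return(n)
    n <- n + 1L
  }
}

# FFT of a kernel embedded centred-at-origin in an Nr x Nc grid.
kernel_fft <- function(k, Nr, Nc) {
  h <- (dim(k) - 1L) %/% 2L
  K <- matrix(0, Nr, Nc)
  ri <- ((seq_len(nrow(k)) - 1L - h[1]) %% Nr) + 1L
  ci <- ((seq_len(ncol(k)) - 1L - h[2]) %% Nc) + 1L
  K[ri, ci] <- k
  stats::fft(K)
}

the_plan_cache <- new.env(parent = emptyenv())

# Precompute kernel FFTs for a (rows, cols, config) geometry.
conv_plan <- function(nr, nc, config) {
  key <- paste(nr, nc, object_digest(config), sep = "_")
  if (!is.null(the_plan_cache[[key]])) return(the_plan_cache[[key]])
  s <- config$scales
  pad <- max(ceiling(3 * max(s)), (config$membrane_kernel_size - 1L) %/% 2L,
             ceiling(max(s)))
  Nr <- good_fft_size(nr + 2L * pad)
  Nc <- good_fft_size(nc + 2L * pad)
  kernels <- list()
  fam <- config$feature_families
  if (any(c("gaussian_blur", "sobel", "hessian", "dog") %in% fam))
    for (si in s)
      kernels[[sprintf("gauss_%g", si)]] <- kernel_fft(gaussian_kernel(si),
                                                       Nr, Nc)
  if ("variance" %in% fam)
    for (si in s)
      kernels[[sprintf("disc_%g", si)]] <- kernel_fft(disc_kernel(si), Nr, Nc)
  if ("membrane_projections" %in% fam)
    for (k in seq_len(config$membrane_rotations))
      kernels[[sprintf("memb_%d", k)]] <- kernel_fft(
        membrane_kernel(config$membrane_kernel_size,
                        (k - 1) * pi / config$membrane_rotations), Nr, Nc)
  plan <- list(pad = pad, Nr = Nr, Nc = Nc, nr = nr, nc = nc,
               kernels = kernels)
  the_plan_cache[[key]] <- plan
  plan
}

# Forward transform of a reflect-padded image embedded in the plan grid.
plan_forward <- function(x, plan) {
  xp <- reflect_pad(x, plan$pad)
  X <- matrix(0, plan$Nr, plan$Nc)
  X[seq_len(nrow(xp)), seq_len(ncol(xp))] <- xp
  stats::fft(X)
}

# One convolution: inverse transform of X * K, cropped to the image region.
plan_conv <- function(X, plan, kname) {
  y <- Re(stats::fft(X * plan$kernels[[kname]], inverse = TRUE)) /
    (plan$Nr * plan$Nc)
  p <- plan$pad
  y[(p + 1):(p + plan$nr), (p + 1):(p + plan$nc), drop = FALSE]
}

# Direct 3x3 stencil convolution on a matrix with 1-pixel mirror border.
conv3 <- function(x, k) {
  xp <- reflect_pad(x, 1L)
  nr <- nrow(x); nc <- ncol(x)
  out <- matrix(0, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    w <- k[dr + 2, dc + 2]
    if (w != 0)
      out <- out + w * xp[(2 + dr):(1 + dr + nr), (2 + dc):(1 + dc + nc)]
  }
  out
}

#' Compute the multiscale feature stack of a grayscale map
#'
#' Builds the per-pixel feature channels used by the random-forest pixel
#' classifier: the raw image, Gaussian blurs at each scale, Sobel gradient
#' magnitude of each blur, Hessian eigenvalues/trace/determinant of each
#' blur, differences of Gaussians for every ordered scale pair, membrane
#' projections (statistics over rotated line-kernel responses), and local
#' variance in a disc of radius sigma. Borders are handled by mirror
#' reflection.
#'
#' @param image A `GrayscaleImage` (from [render_grayscale()]) or a numeric
#'   matrix of intensities.
#' @param config A [feature_config()].
#' @return A `FeatureStack`: list with `channels`
#'   (`rows x cols x n_features` array), `names`, and `config`.
#' @export
feature_stack <- function(image, config = feature_config()) {
  x <- if (inherits(image, "GrayscaleImage")) image$pixels else image
  x <- matrix(as.numeric(x), nrow(x), ncol(x))
  min_side <- config$membrane_kernel_size
  if (min(dim(x)) < min_side)
    stopf("image %d x %d is smaller than the largest kernel; minimum side is %d",
          nrow(x), ncol(x), min_side)

  s <- config$scales
  fam <- config$feature_families
  nms <- feature_names(config)
  plan <- conv_plan(nrow(x), ncol(x), config)
  X <- plan_forward(x, plan)

  need_blur <- any(c("gaussian_blur", "sobel", "hessian", "dog") %in% fam)
  blurs <- if (need_blur)
    lapply(s, function(si) plan_conv(X, plan, sprintf("gauss_%g", si)))

  channels <- array(NA_real_, c(nrow(x), ncol(x), length(nms)))
  ch <- 1L
  put <- function(v) {
    channels[, , ch] <<- v
    ch <<- ch + 1L
  }
  put(x)

  for (f in fam) {
    if (f == "gaussian_blur") {
      for (b in blurs) put(b)
    } else if (f == "sobel") {
      for (b in blurs) {
        gx <- conv3(b, sobel_x)
        gy <- conv3(b, t(sobel_x))
        put(sqrt(gx^2 + gy^2))
      }
    } else if (f == "hessian") {
      kxx <- matrix(c(0, 0, 0, 1, -2, 1, 0, 0, 0), 3, byrow = TRUE)
      kxy <- matrix(c(1, 0, -1, 0, 0, 0, -1, 0, 1), 3, byrow = TRUE) / 4
      for (b in blurs) {
        dxx <- conv3(b, kxx)
        dyy <- conv3(b, t(kxx))
        dxy <- conv3(b, kxy)
        disc <- sqrt(((dxx - dyy) / 2)^2 + dxy^2)
        mid <- (dxx + dyy) / 2
        put(mid + disc)                 # larger eigenvalue
        put(mid - disc)                 # smaller eigenvalue
        put(dxx + dyy)                  # trace
        put(dxx * dyy - dxy^2)          # determinant
      }
    } else if (f == "dog") {
      for (i in seq_along(s)) for (j in seq_along(s)) if (i < j)
        put(blurs[[i]] - blurs[[j]])
    } else if (f == "membrane_projections") {
      nrot <- config$membrane_rotations
      resp <- matrix(0, length(x), nrot)
      for (k in seq_len(nrot))
        resp[, k] <- as.vector(plan_conv(X, plan, sprintf("memb_%d", k)))
      # row-wise order statistics via a single radix sort
      sorted <- matrix(resp[order(row(resp), resp)], nrow(resp),
                       byrow = TRUE)
      mid <- nrot %/% 2
      med <- if (nrot %% 2 == 1) sorted[, mid + 1]
             else (sorted[, mid] + sorted[, mid + 1]) / 2
      sums <- rowSums(resp)
      means <- sums / nrot
      stds <- sqrt(pmax(rowSums(resp^2) / nrot - means^2, 0))
      dims <- dim(x)
      put(matrix(sums, dims[1], dims[2]))
      put(matrix(means, dims[1], dims[2]))
      put(matrix(stds, dims[1], dims[2]))
      put(matrix(med, dims[1], dims[2]))
      put(matrix(sorted[, nrot], dims[1], dims[2]))
      put(matrix(sorted[, 1], dims[1], dims[2]))
    } else if (f == "variance") {
      X2 <- plan_forward(x^2, plan)
      for (si in s) {
        kn <- sprintf("disc_%g", si)
        mu <- plan_conv(X, plan, kn)
        mu2 <- plan_conv(X2, plan, kn)
        put(pmax(mu2 - mu^2, 0))
      }
    }
  }

  structure(list(channels = channels, names = nms, config = config),
            class = "FeatureStack")
}

#' @export
print.FeatureStack <- function(x, ...) {
  d <- dim(x$channels)
  cat(sprintf("FeatureStack: %d channels of %d x %d px\n", d[3], d[1], d[2]))
  invisible(x)
}

# Flatten a stack to a pixels x features matrix with channel names.
stack_matrix <- function(stack) {
  d <- dim(stack$channels)
  m <- matrix(stack$channels, d[1] * d[2], d[3])
  colnames(m) <- stack$names
  m
}
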