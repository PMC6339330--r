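#' Brain-like phantom generation
#'
#' A seeded stand-in for simulated brain MR data: nested smooth blobs assign
#' piecewise-constant tissue intensities (background < CSF < GM < WM, with
#' optional lesions), in-plane Gaussian smoothing emulates slice thickness,
#' a low-order polynomial bias field supplies multiplicative intensity
#' non-uniformity, and magnitude (Rician) noise is added at a percent-of-
#' `MAX_I` level. The regimes mirror the simulated-database design the
#' automation is trained on: noise levels 1/3/5/7/9%, non-uniformity
#' 0/20/40%, slice thickness 1/3/5 mm.
#'
#' @param spec a [phantom_spec()].
#' @return `make_anatomy()`: a clean [image2d] (deterministic per seed).
#' @export
make_anatomy <- function(spec = phantom_spec()) {
  with_seed(spec$seed, {
    m <- spec$size[1]; n <- spec$size[2]
    maxI <- spec$max_intensity
    rr <- (row(matrix(0, m, n)) - (m + 1) / 2) / (m / 2)
    cc <- (col(matrix(0, m, n)) - (n + 1) / 2) / (n / 2)
    rad <- sqrt(rr^2 + cc^2)
    phi <- atan2(cc, rr)
    # Fourier-perturbed nested boundaries: outer CSF shell, GM ring, WM core
    perturb <- function(amp) {
      k <- 2:4
      a <- stats::runif(3, 0, amp)
      ps <- stats::runif(3, 0, 2 * pi)
      1 + a[1] * cos(k[1] * phi + ps[1]) + a[2] * cos(k[2] * phi + ps[2]) +
        a[3] * cos(k[3] * phi + ps[3])
    }
    r_csf <- 0.92 * perturb(0.05)
    r_gm <- 0.78 * perturb(0.08)
    r_wm <- 0.55 * perturb(0.10)
    img <- matrix(spec$intensities[["background"]] * maxI, m, n)
    img[rad < r_csf] <- spec$intensities[["csf"]] * maxI
    img[rad < r_gm] <- spec$intensities[["gm"]] * maxI
    img[rad < r_wm] <- spec$intensities[["wm"]] * maxI
    if (spec$n_lesions > 0) {
      for (l in seq_len(spec$n_lesions)) {
        # lesion blob inside the WM core, hyper- or hypo-intense
        ctr_r <- stats::runif(1, 0, 0.35)
        ctr_a <- stats::runif(1, 0, 2 * pi)
        lr <- ctr_r * cos(ctr_a); lc <- ctr_r * sin(ctr_a)
        lrad <- stats::runif(1, 0.04, 0.10)
        lev <- sample(c(spec$intensities[["lesion"]],
                        spec$intensities[["csf"]]), 1)
        img[(rr - lr)^2 + (cc - lc)^2 < lrad^2] <- lev * maxI
      }
    }
    if (spec$thickness_smoothing > 0)
      img <- gaussian_blur(img, spec$thickness_smoothing)
    img <- pmin(pmax(img, 0), maxI)
    image2d(img, maxI)
  })
}

#' @rdname make_anatomy
#' @param size image dimensions `c(rows, cols)`.
#' @param intensities named tissue levels as fractions of `max_intensity`.
#' @param thickness slice thickness in mm, one of 1/3/5; mapped to an
#'   in-plane Gaussian blur of `thickness / 2` pixels.
#' @param bias_amplitude multiplicative non-uniformity amplitude (0, 0.2,
#'   0.4 are the stated regimes).
#' @param noise_level Rician noise level as a fraction of `max_intensity`
#'   (0.01, 0.03, 0.05, 0.07, 0.09 are the stated regimes).
#' @param n_lesions number of lesion blobs (0 = normal anatomy).
#' @param max_intensity intensity ceiling, default 255 (8-bit).
#' @param seed integer seed; the anatomy is deterministic given the seed.
#' @export
phantom_spec <- function(size = c(64, 64),
                         intensities = c(background = 0.02, csf = 0.15,
                                         gm = 0.45, wm = 0.75,
                                         lesion = 0.90),
                         thickness = 3, bias_amplitude = 0.2,
                         noise_level = 0.05, n_lesions = 0,
                         max_intensity = 255, seed = 1L) {
  stopifnot(length(size) == 2L, all(size >= 8),
            all(c("background", "csf", "gm", "wm") %in% names(intensities)),
            bias_amplitude >= 0, bias_amplitude < 1, noise_level >= 0)
  if (!"lesion" %in% names(intensities))
    intensities[["lesion"]] <- 0.9
  list(size = as.integer(size), intensities = intensities,
       thickness = thickness, thickness_smoothing = thickness / 2,
       bias_amplitude = bias_amplitude, noise_level = noise_level,
       n_lesions = n_lesions, max_intensity = max_intensity,
       seed = as.integer(seed))
}

# separable Gaussian blur with edge replication
gaussian_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  conv1 <- function(v) {
    # replicate-padded 1-D convolution along the first dim of a matrix
    m <- nrow(v)
    vp <- v[pmin(pmax(seq_len(m + 2 * r) - r, 1L), m), , drop = FALSE]
    out <- matrix(0, m, ncol(v))
    for (t in seq_along(k))
      out <- out + k[t] * vp[(t - 1) + seq_len(m), , drop = FALSE]
    out
  }
  t(conv1(t(conv1(x))))
}

#' Multiplicative intensity non-uniformity (bias field)
#'
#' Multiplies the image by a smooth field in `[1 - a/2, 1 + a/2]` built from
#' a seeded random 2-D quadratic, rescaled so its mean is ~1 and its range
#' is ~`a`. `amplitude = 0` is the identity.
#'
#' @param img an [image2d].
#' @param amplitude non-uniformity amplitude `a` in `[0, 1)`.
#' @param seed integer seed for the polynomial coefficients.
#' @return the biased [image2d], clipped to `[0, MAX_I]`.
#' @export
apply_bias_field <- function(img, amplitude, seed = 1L) {
  img <- as_image2d(img)
  stopifnot(amplitude >= 0, amplitude < 1)
  if (amplitude == 0) return(img)
  f <- bias_field(dim(img), amplitude, seed)
  restamp(pmin(pmax(as.matrix(img) * f, 0), max_intensity(img)), img)
}

# the field itself, exposed for testing its statistics
bias_field <- function(dim, amplitude, seed = 1L) {
  with_seed(seed, {
    m <- dim[1]; n <- dim[2]
    u <- (row(matrix(0, m, n)) - 1) / (m - 1) - 0.5
    v <- (col(matrix(0, m, n)) - 1) / (n - 1) - 0.5
    co <- stats::runif(5, -1, 1)
    f <- co[1] * u + co[2] * v + co[3] * u * v + co[4] * u^2 + co[5] * v^2
    # rank-equalize the quadratic profile: a monotone remap keeping the
    # shading smooth while fixing the field mean at 1 and its range at
    # the declared amplitude
    g <- matrix((rank(f, ties.method = "average") - 0.5) / length(f), m, n)
    1 - amplitude / 2 + amplitude * g
  })
}

#' Rician (magnitude MR) noise
#'
#' Adds magnitude noise `sqrt((I + g1)^2 + g2^2)` with `g1, g2` i.i.d.
#' zero-mean Gaussians of standard deviation `level * MAX_I` — the
#' percent-of-maximum convention of the simulated database. Background
#' (zero-signal) regions become Rayleigh-distributed. Output is clipped to
#' `[0, MAX_I]`.
#'
#' @param img an [image2d].
#' @param level noise level as a fraction of `MAX_I` (`>= 0`).
#' @param seed integer seed.
#' @return the noisy [image2d].
#' @export
add_rician_noise <- function(img, level, seed = 1L) {
  img <- as_image2d(img)
  stopifnot(level >= 0)
  if (level == 0) return(img)
  with_seed(seed, {
    s <- level * max_intensity(img)
    m <- nrow(img); n <- ncol(img)
    g1 <- matrix(stats::rnorm(m * n, 0, s), m, n)
    g2 <- matrix(stats::rnorm(m * n, 0, s), m, n)
    out <- sqrt((as.matrix(img) + g1)^2 + g2^2)
    restamp(pmin(out, max_intensity(img)), img)
  })
}

#' Phantom corpus with anatomy shared across noise levels
#'
#' Generates a full factorial over noise levels, bias amplitudes and slice
#' thicknesses with `n_per_cell` distinct anatomies per (bias, thickness)
#' cell. Each anatomy is rendered clean once and corrupted at every noise
#' level, so anatomy ids pair observations across levels (the design the
#' paired t-test ranking needs). Anatomy ids are split 2:1 into train/test,
#' which stratifies exactly by noise class since every anatomy carries all
#' levels.
#'
#' @param n_per_cell anatomies per (bias, thickness) cell, `>= 1`.
#' @param noise_levels,bias_amplitudes,thicknesses factorial axes.
#' @param size,max_intensity passed to [phantom_spec()].
#' @param n_lesions lesion blobs per anatomy (0 = normal model).
#' @param seed master seed; anatomy and noise seeds are derived from it.
#' @return a list with `pairs` (list of `list(clean, noisy, spec,
#'   anatomy_id)`) and `labels` (data.frame: `anatomy_id`, `noise_level`
#'   in percent, `noise_class`, `bias`, `thickness`, `split`).
#' @export
make_corpus <- function(n_per_cell, noise_levels = c(1, 3, 5, 7, 9) / 100,
                        bias_amplitudes = c(0, 0.2, 0.4),
                        thicknesses = c(1, 3, 5), size = c(64, 64),
                        n_lesions = 0, max_intensity = 255, seed = 1L) {
  stopifnot(n_per_cell >= 1)
  cells <- expand.grid(bias = bias_amplitudes, thickness = thicknesses,
                       rep = seq_len(n_per_cell))
  n_anat <- nrow(cells)
  # derived seeds kept below 2^31
  aseed <- (as.integer(seed) * 1009L + seq_len(n_anat) * 7L) %% 2147483587L
  pairs <- vector("list", n_anat * length(noise_levels))
  labels <- vector("list", n_anat * length(noise_levels))
  train_ids <- with_seed(seed,
    sample(seq_len(n_anat), size = round(2 / 3 * n_anat)))
  k <- 0L
  for (a in seq_len(n_anat)) {
    spec0 <- phantom_spec(size = size, thickness = cells$thickness[a],
                          bias_amplitude = cells$bias[a],
                          n_lesions = n_lesions,
                          max_intensity = max_intensity, seed = aseed[a])
    clean <- make_anatomy(spec0)
    clean <- apply_bias_field(clean, cells$bias[a], seed = aseed[a] + 1L)
    for (lv in noise_levels) {
      k <- k + 1L
      spec <- spec0
      spec$noise_level <- lv
      noisy <- add_rician_noise(clean, lv,
                                seed = (aseed[a] + round(1e4 * lv)) %%
                                  2147483587L)
      pairs[[k]] <- list(clean = clean, noisy = noisy, spec = spec,
                         anatomy_id = a)
      labels[[k]] <- data.frame(
        anatomy_id = a, noise_level = round(lv * 100, 6),
        noise_class = noise_class(lv * 100),
        bias = cells$bias[a], thickness = cells$thickness[a],
        split = if (a %in% train_ids) "train" else "test")
    }
  }
  list(pairs = pairs, labels = do.call(rbind, labels))
}

#' @rdname make_corpus
#' @param level_percent noise level(s) in percent.
#' @return `noise_class()`: `"low"` (1 and 3%), `"median"` (5 and 7%) or
#'   `"high"` (9%).
#' @export
noise_class <- function(level_percent) {
  cut(level_percent, breaks = c(-Inf, 4, 8, Inf),
      labels = c("low", "median", "high")) |> as.character()
}
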