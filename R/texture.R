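#' @title Texture and noise feature bank
#' @description Computes the 95 named scalar descriptors used by the
#'   parameter automation: 9 statistical/histogram features, 8 gray-level
#'   co-occurrence (GLCM) features in 4 directions, 11 gray-level run-length
#'   (GLRLM) features in 4 directions, 3 Tamura features, and 7 noise-level
#'   estimators. Feature names carry a direction suffix where applicable
#'   (e.g. `RLN_0`, `RP_135`).
#' @name feature_bank
NULL

GLCM_NAMES <- c("SDi", "SDj", "ASM", "CON", "DIS", "HOM", "ENT", "COR")
GLRLM_NAMES <- c("SRE", "LRE", "GLN", "RLN", "RP", "LGRE", "HGRE",
                 "SRLGE", "SRHGE", "LRLGE", "LRHGE")
STAT_NAMES <- c("Mean", "SD", "VAR", "ENT", "skewness", "kurtosis",
                "hist_VAR", "hist_ENT", "hist_energy")
TAMURA_NAMES <- c("CRS", "CON", "DIR")
NOISE_NAMES <- c("LAP", "LOG", "GTFLAP", "AJA", "BRUM", "SIJ", "ACF")
DIRECTIONS <- c(0, 45, 90, 135)

#' @rdname feature_bank
#' @return `feature_names()`: the 95 names in bank order.
#' @export
feature_names <- function() {
  c(STAT_NAMES,
    as.vector(t(outer(DIRECTIONS, GLCM_NAMES,
                      function(d, f) paste0(f, "_", d)))),
    as.vector(t(outer(DIRECTIONS, GLRLM_NAMES,
                      function(d, f) paste0(f, "_", d)))),
    TAMURA_NAMES, NOISE_NAMES)
}

#' @rdname feature_bank
#' @return `feature_subset_default()`: the five-feature working subset used
#'   by the automation by default — `RLN_0`, `RP_135`, `RP_90`, `AJA` and
#'   `kurtosis`.
#' @export
feature_subset_default <- function() {
  c("RLN_0", "RP_135", "RP_90", "AJA", "kurtosis")
}

# min-max quantization to levels 1..L (constant image -> all 1)
quantize_levels <- function(x, levels) {
  rng <- range(x)
  if (rng[2] <= rng[1]) return(matrix(1L, nrow(x), ncol(x)))
  q <- 1L + as.integer(floor((x - rng[1]) / (rng[2] - rng[1]) * levels))
  q[q > levels] <- as.integer(levels)
  matrix(q, nrow(x), ncol(x))
}

dir_offset <- function(direction) {
  # (row, col) steps; 0 deg = horizontal, angles counterclockwise
  switch(as.character(direction),
         "0" = c(0L, 1L), "45" = c(-1L, 1L), "90" = c(-1L, 0L),
         "135" = c(-1L, -1L),
         stop("direction must be one of 0, 45, 90, 135", call. = FALSE))
}

#' Gray-level co-occurrence matrix
#'
#' Counts pairs of quantized gray levels at distance 1 along a direction,
#' accumulated bidirectionally (symmetric) and normalized to sum to 1.
#'
#' @param img an [image2d] or matrix.
#' @param direction one of 0, 45, 90, 135 (degrees).
#' @param levels number of quantization levels (min-max based).
#' @return an `L x L` normalized matrix with attributes `direction` and
#'   `levels`.
#' @export
glcm <- function(img, direction = 0, levels = 32) {
  x <- as.matrix(img)
  if (levels < 2) stop("`levels` must be >= 2", call. = FALSE)
  q <- quantize_levels(x, levels)
  off <- dir_offset(direction)
  m <- nrow(q); n <- ncol(q)
  ri <- seq_len(m); ci <- seq_len(n)
  ri <- ri[ri + off[1] >= 1 & ri + off[1] <= m]
  ci <- ci[ci + off[2] >= 1 & ci + off[2] <= n]
  if (length(ri) == 0L || length(ci) == 0L)
    stop("image is smaller than the co-occurrence offset", call. = FALSE)
  a <- q[ri, ci, drop = FALSE]
  b <- q[ri + off[1], ci + off[2], drop = FALSE]
  counts <- matrix(tabulate((a - 1L) * as.integer(levels) + b,
                            nbins = levels * levels),
                   levels, levels, byrow = TRUE)
  counts <- counts + t(counts)
  structure(counts / sum(counts), direction = direction, levels = levels)
}

#' @rdname glcm
#' @param M a normalized co-occurrence matrix from [glcm()].
#' @return `glcm_features()`: named vector `SDi`, `SDj`, `ASM`, `CON`,
#'   `DIS`, `HOM`, `ENT`, `COR` (Haralick's definitions; natural-log
#'   entropy; correlation is 0 with a warning when a marginal has zero
#'   variance).
#' @export
glcm_features <- function(M) {
  L <- nrow(M)
  i <- row(M); j <- col(M)
  mu_i <- sum(i * M); mu_j <- sum(j * M)
  v_i <- sum((i - mu_i)^2 * M); v_j <- sum((j - mu_j)^2 * M)
  ent <- -sum(ifelse(M > 0, M * log(M), 0))
  cor <- if (v_i <= 0 || v_j <= 0) {
    warning("zero-variance GLCM marginal: correlation set to 0")
    0
  } else sum((i - mu_i) * (j - mu_j) * M) / sqrt(v_i * v_j)
  c(SDi = sqrt(v_i), SDj = sqrt(v_j), ASM = sum(M^2),
    CON = sum((i - j)^2 * M), DIS = sum(abs(i - j) * M),
    HOM = sum(M / (1 + (i - j)^2)), ENT = ent, COR = cor)
}

#' Gray-level run-length matrix
#'
#' Decomposes every scan line of the direction into maximal runs of equal
#' quantized gray level.
#'
#' @inheritParams glcm
#' @return a list with `counts[g, r]` (runs of level `g`, length `r`),
#'   `n_pixels`, `direction` and `levels`.
#' @export
glrlm <- function(img, direction = 0, levels = 32) {
  x <- as.matrix(img)
  if (levels < 2) stop("`levels` must be >= 2", call. = FALSE)
  q <- quantize_levels(x, levels)
  lines <- switch(as.character(direction),
                  "0" = split(q, row(q)),
                  "90" = split(q, col(q)),
                  "45" = split(q, row(q) + col(q)),
                  "135" = split(q, row(q) - col(q)),
                  stop("direction must be one of 0, 45, 90, 135",
                       call. = FALSE))
  gl <- integer(0); rl <- integer(0)
  for (v in lines) {
    r <- rle(as.integer(v))
    gl <- c(gl, r$values); rl <- c(rl, r$lengths)
  }
  counts <- matrix(0L, levels, max(rl))
  for (k in seq_along(gl))
    counts[gl[k], rl[k]] <- counts[gl[k], rl[k]] + 1L
  list(counts = counts, n_pixels = length(q), direction = direction,
       levels = levels)
}

#' @rdname glrlm
#' @param R a run-length matrix from [glrlm()].
#' @return `glrlm_features()`: named vector of Galloway's 11 statistics
#'   (`SRE`, `LRE`, `GLN`, `RLN`, `RP`, `LGRE`, `HGRE`, `SRLGE`, `SRHGE`,
#'   `LRLGE`, `LRHGE`), with gray level indexed from 1 for the squared-level
#'   terms.
#' @export
glrlm_features <- function(R) {
  cnt <- R$counts
  Nr <- sum(cnt)
  if (Nr == 0) stop("run-length matrix is empty", call. = FALSE)
  g <- row(cnt); r <- col(cnt)
  c(SRE = sum(cnt / r^2) / Nr,
    LRE = sum(cnt * r^2) / Nr,
    GLN = sum(rowSums(cnt)^2) / Nr,
    RLN = sum(colSums(cnt)^2) / Nr,
    RP = Nr / R$n_pixels,
    LGRE = sum(cnt / g^2) / Nr,
    HGRE = sum(cnt * g^2) / Nr,
    SRLGE = sum(cnt / (g^2 * r^2)) / Nr,
    SRHGE = sum(cnt * g^2 / r^2) / Nr,
    LRLGE = sum(cnt * r^2 / g^2) / Nr,
    LRHGE = sum(cnt * g^2 * r^2) / Nr)
}

#' Statistical and histogram features
#'
#' Pixel statistics (population moments) plus moments of the 256-bin
#' gray-level histogram over `[0, MAX_I]`: `Mean`, `SD`, `VAR`, `ENT`
#' (histogram Shannon entropy in bits), histogram `skewness`, `kurtosis`
#' (non-excess, normal = 3), `hist_VAR` (in bin units), `hist_ENT` (bits)
#' and `hist_energy`. A constant image has undefined skewness/kurtosis;
#' they are returned as 0 with a warning.
#'
#' @param img an [image2d].
#' @return named numeric vector of 9 entries.
#' @export
statistical_features <- function(img) {
  img <- as_image2d(img)
  x <- as.vector(as.matrix(img))
  maxI <- max_intensity(img)
  mu <- mean(x)
  va <- mean((x - mu)^2)
  breaks <- seq(0, maxI, length.out = 257)
  bins <- pmin(pmax(findInterval(x, breaks, rightmost.closed = TRUE), 1L),
               256L)
  h <- tabulate(bins, 256L) / length(x)
  hmu <- sum(seq_len(256) * h)
  hva <- sum((seq_len(256) - hmu)^2 * h)
  if (hva > 0) {
    skw <- sum((seq_len(256) - hmu)^3 * h) / hva^1.5
    krt <- sum((seq_len(256) - hmu)^4 * h) / hva^2
  } else {
    warning("constant image: histogram skewness/kurtosis undefined, set to 0")
    skw <- 0; krt <- 0
  }
  hent <- -sum(ifelse(h > 0, h * log2(h), 0))
  c(Mean = mu, SD = sqrt(va), VAR = va, ENT = hent,
    skewness = skw, kurtosis = krt, hist_VAR = hva, hist_ENT = hent,
    hist_energy = sum(h^2))
}

# 'valid'-mode 2-D convolution (kernel applied as cross-correlation)
conv_valid <- function(x, k) {
  m <- nrow(x) - nrow(k) + 1L
  n <- ncol(x) - ncol(k) + 1L
  if (m < 1L || n < 1L) stop("image smaller than kernel", call. = FALSE)
  out <- matrix(0, m, n)
  for (a in seq_len(nrow(k)))
    for (b in seq_len(ncol(k)))
      if (k[a, b] != 0)
        out <- out + k[a, b] * x[a + seq_len(m) - 1L, b + seq_len(n) - 1L,
                                 drop = FALSE]
  out
}

#' Tamura texture features
#'
#' Canonical formulations of the first three perceptual Tamura descriptors:
#' coarseness `CRS` (best-window-size averaging pyramid, depth 5), contrast
#' `CON` = `sigma / kurtosis^(1/4)` with non-excess kurtosis, and
#' directionality `DIR` from the sharpness of the 16-bin gradient
#' orientation histogram (Prewitt gradients, magnitude threshold 12 on a
#' 0-255 scale, rescaled by `MAX_I / 255`). `DIR` is normalized to `[0, 1]`:
#' 1 when all gradient orientations coincide.
#'
#' @param img an [image2d].
#' @param pyramid_depth coarseness pyramid depth (windows `2^k`).
#' @param bins orientation histogram bins.
#' @param threshold gradient magnitude threshold on a 0-255 scale.
#' @return named vector `CRS`, `CON`, `DIR`.
#' @export
tamura_features <- function(img, pyramid_depth = 5, bins = 16,
                            threshold = 12) {
  img <- as_image2d(img)
  x <- as.matrix(img)
  m <- nrow(x); n <- ncol(x)
  # contrast
  mu <- mean(x); va <- mean((x - mu)^2)
  if (va > 0) {
    krt <- mean((x - mu)^4) / va^2
    con <- sqrt(va) / krt^0.25
  } else {
    warning("constant image: Tamura contrast/directionality set to 0")
    return(c(CRS = 2, CON = 0, DIR = 0))
  }
  # coarseness: box averages at dyadic scales; a scale is only eligible at
  # a pixel when both shifted averaging windows lie fully inside the image,
  # otherwise border replication fakes structure at large scales
  kmax <- max(1L, min(pyramid_depth, floor(log2(min(m, n))) - 1L))
  shiftf <- function(M, di, dj, fill) {
    out <- matrix(fill, m, n)
    rs <- seq_len(m) + di; cs <- seq_len(n) + dj
    ok_r <- rs >= 1L & rs <= m; ok_c <- cs >= 1L & cs <= n
    out[ok_r, ok_c] <- M[rs[ok_r], cs[ok_c]]
    out
  }
  ebest <- matrix(-Inf, m, n); sbest <- matrix(2, m, n)
  for (k in seq_len(kmax)) {
    w <- 2L^k; half <- 2L^(k - 1L); r1 <- (w - 1L) %/% 2L
    A <- box_mean(x, w)
    V <- matrix(FALSE, m, n)
    V[seq_len(m) - r1 >= 1L & seq_len(m) - r1 + w - 1L <= m,
      seq_len(n) - r1 >= 1L & seq_len(n) - r1 + w - 1L <= n] <- TRUE
    eh <- abs(shiftf(A, 0L, half, 0) - shiftf(A, 0L, -half, 0))
    vh <- shiftf(V, 0L, half, FALSE) & shiftf(V, 0L, -half, FALSE)
    ev <- abs(shiftf(A, half, 0L, 0) - shiftf(A, -half, 0L, 0))
    vv <- shiftf(V, half, 0L, FALSE) & shiftf(V, -half, 0L, FALSE)
    e <- pmax(ifelse(vh, eh, -Inf), ifelse(vv, ev, -Inf))
    upd <- e > ebest
    ebest[upd] <- e[upd]
    sbest[upd] <- w
  }
  crs <- mean(sbest)
  # directionality
  pk <- matrix(rep(c(-1, 0, 1), each = 3), 3, 3)   # Prewitt, horizontal
  dh <- conv_valid(x, pk)
  dv <- conv_valid(x, t(pk))
  mag <- (abs(dh) + abs(dv)) / 2
  keep <- mag >= threshold * max_intensity(img) / 255
  if (!any(keep)) {
    warning("no gradient magnitudes above threshold: directionality set to 0")
    return(c(CRS = crs, CON = con, DIR = 0))
  }
  theta <- atan2(dv[keep], dh[keep]) %% pi   # orientation in [0, pi)
  bin <- pmin(1L + floor(theta / pi * bins), bins)
  hst <- tabulate(bin, bins) / sum(keep)
  centers <- (seq_len(bins) - 0.5) * pi / bins
  phi_p <- centers[which.max(hst)]
  d <- abs(centers - phi_p)
  d <- pmin(d, pi - d)                       # wrapped orientation distance
  dirv <- 1 - (4 / pi^2) * sum(hst * d^2)
  c(CRS = crs, CON = con, DIR = dirv)
}

# edge-replicated w x w box mean
box_mean <- function(x, w) {
  m <- nrow(x); n <- ncol(x)
  r1 <- floor((w - 1) / 2); r2 <- w - 1 - r1
  xp <- x[pmin(pmax(seq_len(m + w - 1L) - r1, 1L), m),
          pmin(pmax(seq_len(n + w - 1L) - r1, 1L), n), drop = FALSE]
  out <- matrix(0, m, n)
  for (a in seq_len(w))
    for (b in seq_len(w))
      out <- out + xp[a + seq_len(m) - 1L, b + seq_len(n) - 1L,
                      drop = FALSE]
  out / (w * w)
}

# Otsu threshold on a 256-bin histogram; returns the intensity cut
otsu_threshold <- function(x, maxI) {
  breaks <- seq(0, maxI, length.out = 257)
  bins <- pmin(pmax(findInterval(x, breaks, rightmost.closed = TRUE), 1L),
               256L)
  h <- tabulate(bins, 256L) / length(x)
  omega <- cumsum(h)
  mu <- cumsum(h * seq_len(256))
  mu_t <- mu[256]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  breaks[which.max(sigma_b) + 1L]
}

#' Noise-level estimators
#'
#' Seven scalar estimates of the noise standard deviation, each normalized
#' by `MAX_I`: `LAP` (Immerkaer 3x3 Laplacian-difference), `LOG` (the same
#' scheme with a 5x5 Laplacian-of-Gaussian mask), `GTFLAP` (Laplacian
#' residuals downweighted by a generic transfer function of gradient
#' magnitude, suppressing structure), `AJA` (mode of the background
#' local-means distribution, Rayleigh mean inverted), `BRUM` (least-squares
#' Rayleigh fit to the background histogram), `SIJ` (maximum-likelihood
#' Rayleigh fit to background pixels) and `ACF` (autocovariance peak minus
#' its smooth neighborhood). Background is segmented by an Otsu threshold;
#' if either side is (nearly) empty the estimators fall back to the whole
#' image with a warning.
#'
#' @param img an [image2d], at least 16 x 16.
#' @return named vector of 7 entries (all on the `sigma / MAX_I` scale).
#' @export
noise_estimators <- function(img) {
  img <- as_image2d(img)
  x <- as.matrix(img)
  if (nrow(x) < 16 || ncol(x) < 16)
    stop("noise estimation needs an image of at least 16 x 16",
         call. = FALSE)
  maxI <- max_intensity(img)
  # mask-based estimators: for a zero-sum mask K and i.i.d. Gaussian noise,
  # E|I * K| = sigma * ||K||_2 * sqrt(2/pi)
  lapk <- matrix(c(1, -2, 1, -2, 4, -2, 1, -2, 1), 3, 3)
  lr <- conv_valid(x, lapk)
  lap <- sqrt(pi / 2) * mean(abs(lr)) / sqrt(sum(lapk^2))
  logk <- matrix(c(0, 0, 1, 0, 0,
                   0, 1, 2, 1, 0,
                   1, 2, -16, 2, 1,
                   0, 1, 2, 1, 0,
                   0, 0, 1, 0, 0), 5, 5)
  lg <- sqrt(pi / 2) * mean(abs(conv_valid(x, logk))) / sqrt(sum(logk^2))
  # GTFLAP: transfer function g = 1 / (1 + (|grad| / tau)^2) downweights
  # structural (edge) responses before averaging
  gx <- conv_valid(x, matrix(c(-1, 0, 1), 1, 3))[2:(nrow(x) - 1), ,
                                                 drop = FALSE]
  gy <- conv_valid(x, matrix(c(-1, 0, 1), 3, 1))[, 2:(ncol(x) - 1),
                                                 drop = FALSE]
  gmag <- sqrt(gx^2 + gy^2)
  tau <- 2 * stats::median(gmag) + 1e-8 * maxI
  g <- 1 / (1 + (gmag / tau)^2)
  gtflap <- sqrt(pi / 2) * sum(abs(lr) * g) / (sqrt(sum(lapk^2)) * sum(g))
  # Rayleigh-background estimators
  thr <- otsu_threshold(as.vector(x), maxI)
  bg <- as.vector(x)[as.vector(x) < thr]
  if (length(bg) < 16 || length(bg) > length(x) - 16) {
    warning("background segmentation failed: using the whole image")
    bg <- as.vector(x)
    bgm <- as.vector(box_mean(x, 3))
  } else {
    mloc <- box_mean(x, 3)
    bgm <- as.vector(mloc)[as.vector(x) < thr]
  }
  # AJA: local-means mode; Rayleigh mean = sigma * sqrt(pi/2)
  aja <- hist_mode(bgm) / sqrt(pi / 2)
  # SIJ: Rayleigh maximum likelihood
  sij <- sqrt(mean(bg^2) / 2)
  # BRUM: least-squares Rayleigh fit to the background histogram
  brum <- rayleigh_lsq(bg)
  # ACF: variance minus short-lag autocovariance extrapolated to lag 0
  xd <- x - mean(x)
  c00 <- mean(xd^2)
  c10 <- mean(xd[-1, ] * xd[-nrow(xd), ])
  c01 <- mean(xd[, -1] * xd[, -ncol(xd)])
  acf_est <- sqrt(max(0, c00 - (c10 + c01) / 2))
  out <- c(LAP = lap, LOG = lg, GTFLAP = gtflap, AJA = aja, BRUM = brum,
           SIJ = sij, ACF = acf_est) / maxI
  out
}

hist_mode <- function(v, bins = 64) {
  rng <- range(v)
  if (rng[2] <= rng[1]) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = bins + 1)
  h <- tabulate(pmin(pmax(findInterval(v, br, rightmost.closed = TRUE), 1L),
                     bins), bins)
  (br[which.max(h)] + br[which.max(h) + 1L]) / 2
}

rayleigh_lsq <- function(bg, bins = 64) {
  rng <- range(bg)
  if (rng[2] <= rng[1]) return(0)
  br <- seq(rng[1], rng[2], length.out = bins + 1)
  h <- tabulate(pmin(pmax(findInterval(bg, br, rightmost.closed = TRUE), 1L),
                     bins), bins) / length(bg)
  ctr <- (br[-1] + br[-length(br)]) / 2
  obj <- function(s) {
    f0 <- ctr * exp(-ctr^2 / (2 * s^2))
    a <- sum(h * f0) / sum(f0^2)
    sum((h - a * f0)^2)
  }
  stats::optimize(obj, c(max(1e-6, rng[2] / 200), rng[2]))$minimum
}

#' @rdname feature_bank
#' @param img an [image2d].
#' @param features character vector of feature names to compute (any subset
#'   of [feature_names()]); only the groups needed are evaluated.
#' @param levels quantization levels for GLCM/GLRLM.
#' @return `extract_features()`: named numeric vector in the requested
#'   order.
#' @export
extract_features <- function(img, features = feature_names(), levels = 32) {
  img <- as_image2d(img)
  unknown <- setdiff(features, feature_names())
  if (length(unknown))
    stop("unknown feature(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  out <- c()
  if (any(features %in% STAT_NAMES))
    out <- c(out, statistical_features(img))
  for (d in DIRECTIONS) {
    gn <- paste0(GLCM_NAMES, "_", d)
    if (any(features %in% gn)) {
      v <- glcm_features(glcm(img, d, levels))
      names(v) <- gn
      out <- c(out, v)
    }
    rn <- paste0(GLRLM_NAMES, "_", d)
    if (any(features %in% rn)) {
      v <- glrlm_features(glrlm(img, d, levels))
      names(v) <- rn
      out <- c(out, v)
    }
  }
  if (any(features %in% TAMURA_NAMES))
    out <- c(out, tamura_features(img))
  if (any(features %in% NOISE_NAMES))
    out <- c(out, noise_estimators(img))
  out[features]
}
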