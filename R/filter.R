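#' Collateral filter parameters
#'
#' The collateral filter combines three Gaussian kernels — spatial (width
#' `sigma_s`, pixels), radiometric (width `sigma_r`, intensity units) and
#' median-filtered (width `sigma_m`, intensity units) — over a
#' `(2 radius + 1)^2` window, and blends the input with its median-filtered
#' version with weight `beta` before averaging. `beta_mode = "scalar"` uses
#' the single `beta` value; `"adaptive"` uses the per-pixel map
#' `beta(x, y) = 1 - p(x, y)`, trusting the median more where the pixel
#' disagrees with it (see [agreement_probability()]).
#'
#' @param radius integer filter radius `N >= 1`; the default 1 gives the
#'   3 x 3 window used throughout.
#' @param sigma_s,sigma_r,sigma_m positive kernel widths.
#' @param beta_mode `"scalar"` or `"adaptive"`.
#' @param beta blend weight in `[0, 1]` (scalar mode).
#' @return an object of class `filter_params`.
#' @export
filter_params <- function(radius = 1L, sigma_s = 1, sigma_r = 25,
                          sigma_m = 25, beta_mode = c("scalar", "adaptive"),
                          beta = 0.5) {
  beta_mode <- match.arg(beta_mode)
  radius <- as.integer(radius)
  if (is.na(radius) || radius < 1L)
    stop("`radius` must be an integer >= 1", call. = FALSE)
  for (s in c(sigma_s = sigma_s, sigma_r = sigma_r, sigma_m = sigma_m))
    if (!is.finite(s) || s <= 0)
      stop("kernel widths `sigma_s`, `sigma_r`, `sigma_m` must be > 0",
           call. = FALSE)
  if (!is.finite(beta) || beta < 0 || beta > 1)
    stop("`beta` must lie in [0, 1]", call. = FALSE)
  structure(list(radius = radius, sigma_s = sigma_s, sigma_r = sigma_r,
                 sigma_m = sigma_m, beta_mode = beta_mode, beta = beta),
            class = "filter_params")
}

#' @export
print.filter_params <- function(x, ...) {
  cat(sprintf(
    "<filter_params> N = %d (window %d x %d), sigma_s = %g, sigma_r = %g, sigma_m = %g, beta = %s\n",
    x$radius, 2 * x$radius + 1, 2 * x$radius + 1, x$sigma_s, x$sigma_r,
    x$sigma_m,
    if (x$beta_mode == "adaptive") "adaptive (1 - p)" else format(x$beta)))
  invisible(x)
}

#' Median-filtered image
#'
#' Each output pixel is the median of the `(2 radius + 1)^2` window around
#' it, with edge replication at the borders.
#'
#' @param img an [image2d] (or matrix).
#' @param radius window radius, integer `>= 1`.
#' @return an [image2d] with the same `MAX_I`.
#' @export
median_image <- function(img, radius = 1L) {
  img <- as_image2d(img)
  radius <- as.integer(radius)
  if (is.na(radius) || radius < 1L)
    stop("`radius` must be an integer >= 1", call. = FALSE)
  restamp(cpp_median_filter(as.matrix(img), radius), img)
}

#' Weight components of the collateral filter
#'
#' These helpers expose the filter's ingredients individually: the
#' spatial-weight buffer `WSB(d_x, d_y) = exp(-(d_x^2 + d_y^2) / (2
#' sigma_s^2))`, the radiometric and median range kernels, the per-pixel
#' image/median agreement probability `p = (1 - |I - I^M| / MAX_I)^2 / 2 +
#' 0.5`, the windowed entropy `H` of `p`, and the ensemble weight `W = W^S
#' (W^R)^{1/(1+H)} (W^M)^H` (evaluated in log space so large `H` cannot
#' underflow the intermediate factors).
#'
#' @param params a [filter_params].
#' @return `spatial_weight_buffer()`: an `(N+1) x (N+1)` matrix indexed by
#'   absolute offsets `0..N` (dimnames give the offsets).
#' @export
spatial_weight_buffer <- function(params) {
  N <- params$radius
  d <- 0:N
  wsb <- exp(-outer(d^2, d^2, `+`) / (2 * params$sigma_s^2))
  dimnames(wsb) <- list(d_x = d, d_y = d)
  wsb
}

#' @rdname spatial_weight_buffer
#' @param center_val,neighbor_val intensities (vectorized).
#' @param sigma_r,sigma_m positive kernel widths.
#' @export
radiometric_weight <- function(center_val, neighbor_val, sigma_r) {
  if (any(sigma_r <= 0)) stop("`sigma_r` must be > 0", call. = FALSE)
  exp(-(neighbor_val - center_val)^2 / (2 * sigma_r^2))
}

#' @rdname spatial_weight_buffer
#' @param center_med,neighbor_med median-filtered intensities (vectorized).
#' @export
median_weight <- function(center_med, neighbor_med, sigma_m) {
  if (any(sigma_m <= 0)) stop("`sigma_m` must be > 0", call. = FALSE)
  exp(-(neighbor_med - center_med)^2 / (2 * sigma_m^2))
}

#' @rdname spatial_weight_buffer
#' @param img,med the input image and its median-filtered version, same
#'   shape and `MAX_I`.
#' @export
agreement_probability <- function(img, med) {
  img <- as_image2d(img)
  med <- as.matrix(med)
  if (!all(dim(img) == dim(med)))
    stop("`img` and `med` must share their shape", call. = FALSE)
  maxI <- max_intensity(img)
  if (maxI <= 0) stop("invalid image: MAX_I must be > 0", call. = FALSE)
  (1 - abs(as.matrix(img) - med) / maxI)^2 / 2 + 0.5
}

#' @rdname spatial_weight_buffer
#' @param p_map matrix of agreement probabilities in `[0.5, 1]`.
#' @export
entropy_map <- function(p_map, params = filter_params()) {
  p_map <- as.matrix(p_map)
  if (any(p_map < 0.5 - 1e-12) || any(p_map > 1 + 1e-12))
    stop("`p_map` values must lie in [0.5, 1]", call. = FALSE)
  N <- params$radius
  q <- 1 - p_map
  h <- ifelse(p_map > 0, p_map * log(p_map), 0) +
    ifelse(q > 0, q * log(q), 0)
  m <- nrow(h); n <- ncol(h)
  # edge-replicated window sum, consistent with the filter's border policy
  hp <- h[pmin(pmax(seq_len(m + 2 * N) - N, 1L), m),
          pmin(pmax(seq_len(n + 2 * N) - N, 1L), n), drop = FALSE]
  H <- matrix(0, m, n)
  for (dj in 0:(2 * N)) for (di in 0:(2 * N))
    H <- H + hp[di + seq_len(m), dj + seq_len(n), drop = FALSE]
  pmax(-H, 0)
}

#' @rdname spatial_weight_buffer
#' @param ws,wr,wm spatial, radiometric and median weights (vectorized).
#' @param H_at_center entropy value(s) at the window center, `>= 0`.
#' @export
ensemble_weight <- function(ws, wr, wm, H_at_center) {
  ws <- pmax(ws, 1e-300); wr <- pmax(wr, 1e-300); wm <- pmax(wm, 1e-300)
  exp(log(ws) + log(wr) / (1 + H_at_center) + H_at_center * log(wm))
}

#' @rdname spatial_weight_buffer
#' @param img_val,med_val intensities of the image and its median (vectorized).
#' @param p optional agreement probabilities, required in adaptive mode.
#' @export
blend_value <- function(img_val, med_val, params, p = NULL) {
  if (params$beta_mode == "adaptive") {
    if (is.null(p))
      stop("adaptive blending needs the agreement probabilities `p`",
           call. = FALSE)
    beta <- 1 - p
  } else {
    beta <- params$beta
    if (beta < 0 || beta > 1) stop("`beta` must lie in [0, 1]", call. = FALSE)
  }
  (1 - beta) * img_val + beta * med_val
}

# per-pixel blend map for the compiled backends
beta_map <- function(img, med, params) {
  if (params$beta_mode == "adaptive")
    1 - agreement_probability(img, med)
  else
    matrix(params$beta, nrow(img), ncol(img))
}

#' Apply the collateral filter
#'
#' Filters a 2-D image with the collateral filter. Two algebraically
#' equivalent backends are available: `"reference"` evaluates the filter
#' definition per pixel, `"tiled"` (default) processes `tile_side x
#' tile_side` output tiles with an `N`-pixel apron, staging the spatial
#' weight buffer, entropy terms and blend values once per tile — the
#' CPU-side contract of the shared-memory acceleration scheme. Both return
#' the same result to within floating-point roundoff.
#'
#' @param img an [image2d] (or matrix).
#' @param params a [filter_params].
#' @param backend `"tiled"` or `"reference"`.
#' @param tile_side output tile side `S >= 1`; the default 16 mirrors the
#'   16 x 16 thread-block geometry the scheme was designed for.
#' @return the restored [image2d]; values stay within the range of the
#'   window blend values, hence in `[0, MAX_I]`.
#' @examples
#' img <- image2d(matrix(runif(64, 0, 255), 8, 8), 255)
#' out <- collateral_filter(img, filter_params(sigma_r = 30, sigma_m = 30))
#' @export
collateral_filter <- function(img, params = filter_params(),
                              backend = c("tiled", "reference"),
                              tile_side = 16L) {
  backend <- match.arg(backend)
  img <- as_image2d(img)
  if (!inherits(params, "filter_params"))
    stop("`params` must be a `filter_params` object", call. = FALSE)
  tile_side <- as.integer(tile_side)
  if (is.na(tile_side) || tile_side < 1L)
    stop("`tile_side` must be an integer >= 1", call. = FALSE)
  med <- median_image(img, params$radius)
  bmap <- beta_map(img, med, params)
  px <- as.matrix(img); mx <- as.matrix(med)
  maxI <- max_intensity(img)
  out <- if (backend == "reference")
    cpp_collateral_reference(px, mx, params$radius, params$sigma_s,
                             params$sigma_r, params$sigma_m, bmap, maxI)
  else
    cpp_collateral_tiled(px, mx, params$radius, params$sigma_s,
                         params$sigma_r, params$sigma_m, bmap, maxI,
                         tile_side)
  restamp(out, img)
}

#' @rdname collateral_filter
#' @param vol a 3-D numeric array, filtered one slice (third index) at a
#'   time, as volumes are processed slice-by-slice.
#' @param max_intensity intensity ceiling shared by all slices.
#' @export
collateral_filter_volume <- function(vol, params = filter_params(),
                                     backend = c("tiled", "reference"),
                                     tile_side = 16L, max_intensity = 255) {
  stopifnot(is.array(vol), length(dim(vol)) == 3L)
  out <- vol
  for (k in seq_len(dim(vol)[3]))
    out[, , k] <- as.matrix(collateral_filter(
      image2d(vol[, , k], max_intensity), params, backend, tile_side))
  out
}
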