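#' Image restoration quality metrics
#'
#' `psnr()` is the peak signal-to-noise ratio
#' `10 log10(MAX_I^2 / MSE)` in dB, with the mean squared error taken over
#' all pixels. `ssim()` is the structural similarity index with stabilizing
#' constants `C1 = (0.01 MAX_I)^2`, `C2 = (0.03 MAX_I)^2`; `mode = "global"`
#' evaluates the single-statistic form over the whole image, `mode =
#' "windowed"` (the reporting default in the comparison literature) averages
#' it over sliding `window x window` patches. `relative_error()` is
#' `|PSNR_T - PSNR_A| / PSNR_T * 100`, the percent gap between a brute-force
#' optimal restoration and an automatically parameterized one.
#'
#' @param reference the noise-free [image2d] `F`.
#' @param restored the restored [image2d] `R`, same shape and `MAX_I`.
#' @return `psnr()`: dB scalar (`+Inf` with a warning for identical images,
#'   so grid searches containing a perfect restoration do not crash).
#' @export
psnr <- function(reference, restored) {
  reference <- as_image2d(reference)
  restored <- as.matrix(restored)
  if (!all(dim(reference) == dim(restored)))
    stop("images must share their shape", call. = FALSE)
  maxI <- max_intensity(reference)
  mse <- mean((as.matrix(reference) - restored)^2)
  if (mse == 0) {
    warning("identical images: PSNR is infinite")
    return(Inf)
  }
  10 * log10(maxI^2 / mse)
}

# population statistics of the global SSIM form
ssim_stat <- function(f, r, C1, C2) {
  muF <- mean(f); muR <- mean(r)
  vF <- mean((f - muF)^2); vR <- mean((r - muR)^2)
  cFR <- mean((f - muF) * (r - muR))
  ((2 * muF * muR + C1) * (2 * cFR + C2)) /
    ((muF^2 + muR^2 + C1) * (vF + vR + C2))
}

#' @rdname psnr
#' @param mode `"windowed"` (mean over sliding patches) or `"global"` (the
#'   whole-image single statistic).
#' @param window side of the sliding window in windowed mode.
#' @export
ssim <- function(reference, restored, mode = c("windowed", "global"),
                 window = 7L) {
  mode <- match.arg(mode)
  reference <- as_image2d(reference)
  restored <- as.matrix(restored)
  if (!all(dim(reference) == dim(restored)))
    stop("images must share their shape", call. = FALSE)
  maxI <- max_intensity(reference)
  C1 <- (0.01 * maxI)^2
  C2 <- (0.03 * maxI)^2
  f <- as.matrix(reference)
  if (mode == "global") return(ssim_stat(f, restored, C1, C2))
  w <- as.integer(window)
  m <- nrow(f); n <- ncol(f)
  if (m < w || n < w) return(ssim_stat(f, restored, C1, C2))
  # sliding uniform windows via summed-area tables
  sat <- function(x) {
    s <- rbind(0, cbind(0, x))
    s <- apply(s, 2, cumsum)
    t(apply(s, 1, cumsum))
  }
  win_sum <- function(x) {
    s <- sat(x)
    ii <- seq_len(m - w + 1L); jj <- seq_len(n - w + 1L)
    s[ii + w, jj + w, drop = FALSE] - s[ii, jj + w, drop = FALSE] -
      s[ii + w, jj, drop = FALSE] + s[ii, jj, drop = FALSE]
  }
  nw <- w * w
  sF <- win_sum(f) / nw
  sR <- win_sum(restored) / nw
  sFF <- win_sum(f * f) / nw - sF^2
  sRR <- win_sum(restored * restored) / nw - sR^2
  sFR <- win_sum(f * restored) / nw - sF * sR
  mean(((2 * sF * sR + C1) * (2 * sFR + C2)) /
         ((sF^2 + sR^2 + C1) * (sFF + sRR + C2)))
}

#' @rdname psnr
#' @param psnr_t brute-force optimal PSNR (dB), must be `> 0`.
#' @param psnr_a PSNR of the automatically parameterized restoration (dB).
#' @export
relative_error <- function(psnr_t, psnr_a) {
  if (any(!is.finite(psnr_t)) || any(psnr_t <= 0))
    stop("`psnr_t` must be finite and > 0", call. = FALSE)
  abs(psnr_t - psnr_a) / psnr_t * 100
}
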