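#' 2-D grayscale image with a declared intensity ceiling
#'
#' `image2d()` wraps a numeric matrix of nonnegative intensities together with
#' the maximum possible intensity `MAX_I` of its acquisition range. `MAX_I`
#' enters the agreement probability of the collateral filter, the PSNR/SSIM
#' stabilizing constants, and the normalization of the noise-level features,
#' so it is carried explicitly rather than recomputed from the data.
#'
#' @param pixels numeric matrix, all values in `[0, max_intensity]`.
#' @param max_intensity positive scalar; the maximum *possible* intensity
#'   (e.g. 255 for 8-bit data). Defaults to `max(pixels)` with a message,
#'   which is only appropriate when the brightest tissue reaches the ceiling.
#' @return an object of class `image2d`: the matrix with a `max_intensity`
#'   attribute.
#' @examples
#' img <- image2d(matrix(0:24, 5, 5), max_intensity = 255)
#' max_intensity(img)
#' @export
image2d <- function(pixels, max_intensity = NULL) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("image must have at least one row and one column", call. = FALSE)
  if (anyNA(pixels) || any(!is.finite(pixels)))
    stop("image contains non-finite values", call. = FALSE)
  if (any(pixels < 0))
    stop("image intensities must be nonnegative", call. = FALSE)
  if (is.null(max_intensity)) {
    max_intensity <- max(pixels)
    if (max_intensity <= 0) max_intensity <- 1
  }
  if (!is.numeric(max_intensity) || length(max_intensity) != 1L ||
      !is.finite(max_intensity) || max_intensity <= 0)
    stop("`max_intensity` must be a positive finite scalar", call. = FALSE)
  if (any(pixels > max_intensity))
    stop("image intensities exceed `max_intensity`", call. = FALSE)
  structure(unclass(pixels), max_intensity = as.numeric(max_intensity),
            class = "image2d")
}

#' @rdname image2d
#' @param x an object to coerce or query.
#' @export
as_image2d <- function(x, max_intensity = NULL) {
  if (is_image2d(x)) {
    if (!is.null(max_intensity)) attr(x, "max_intensity") <- max_intensity
    return(x)
  }
  image2d(as.matrix(x), max_intensity)
}

#' @rdname image2d
#' @export
is_image2d <- function(x) inherits(x, "image2d")

#' @rdname image2d
#' @export
max_intensity <- function(x) {
  m <- attr(x, "max_intensity")
  if (is.null(m)) max(x) else m
}

#' @export
as.matrix.image2d <- function(x, ...) {
  attr(x, "max_intensity") <- NULL
  class(x) <- NULL
  x
}

#' @export
print.image2d <- function(x, ...) {
  cat(sprintf("<image2d> %d x %d, MAX_I = %g, range [%g, %g]\n",
              nrow(x), ncol(x), max_intensity(x), min(x), max(x)))
  invisible(x)
}

# rebuild an image2d around new pixel values, keeping MAX_I
restamp <- function(pixels, template) {
  structure(pixels, max_intensity = max_intensity(template),
            class = "image2d")
}

#' Read and write 2-D images as plain text
#'
#' Supported formats are ASCII PGM (`P2`, 8- or 16-bit) and headerless CSV
#' matrices. The format is chosen from the file extension (`.pgm`, `.csv`).
#' PGM carries its own maximum gray value, which becomes `MAX_I`; for CSV the
#' `max_intensity` argument (default 255) is used.
#'
#' @param path file path ending in `.pgm` or `.csv`.
#' @param max_intensity ceiling for CSV input; ignored for PGM.
#' @return `read_image()` returns an [image2d]; `write_image()` invisibly
#'   returns `path`.
#' @export
read_image <- function(path, max_intensity = 255) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "pgm") {
    tok <- scan(path, what = character(), comment.char = "#", quiet = TRUE)
    if (length(tok) < 4L || tok[1] != "P2")
      stop("only ASCII PGM (magic 'P2') is supported", call. = FALSE)
    w <- as.integer(tok[2]); h <- as.integer(tok[3])
    maxval <- as.numeric(tok[4])
    px <- as.numeric(tok[-(1:4)])
    if (length(px) != w * h) stop("PGM pixel count mismatch", call. = FALSE)
    # PGM is row-major (english reading order)
    image2d(matrix(px, nrow = h, ncol = w, byrow = TRUE), maxval)
  } else if (ext %in% c("csv", "txt")) {
    m <- as.matrix(utils::read.csv(path, header = FALSE))
    dimnames(m) <- NULL
    image2d(m, max_intensity)
  } else {
    stop(sprintf("unsupported image format '.%s' (use .pgm or .csv)", ext),
         call. = FALSE)
  }
}

#' @rdname read_image
#' @param img an [image2d] (or matrix coercible to one).
#' @export
write_image <- function(img, path) {
  img <- as_image2d(img)
  ext <- tolower(tools::file_ext(path))
  if (ext == "pgm") {
    maxval <- round(max_intensity(img))
    px <- round(as.matrix(img))
    px[px < 0] <- 0; px[px > maxval] <- maxval
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", paste(ncol(img), nrow(img)), as.character(maxval)),
               con)
    write(t(px), file = con, ncolumns = min(ncol(img), 16L))
  } else if (ext %in% c("csv", "txt")) {
    utils::write.table(as.matrix(img), path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  } else {
    stop(sprintf("unsupported image format '.%s' (use .pgm or .csv)", ext),
         call. = FALSE)
  }
  invisible(path)
}

# run `expr` under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
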