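# --- components -----------------------------------------------------------

test_that("median_image matches the sort-and-pick oracle and its examples", {
  flat <- image2d(matrix(7, 4, 4), 255)
  expect_equal(as.matrix(median_image(flat)), matrix(7, 4, 4))
  spike <- image2d(matrix(c(0, 0, 0, 0, 255, 0, 0, 0, 0), 3, 3), 255)
  expect_equal(as.matrix(median_image(spike))[2, 2], 0)
  set.seed(11)
  img <- image2d(matrix(sample(0:255, 25, TRUE), 5, 5), 255)
  expect_equal(as.matrix(median_image(img, 1)), oracle_median(img, 1))
  expect_equal(as.matrix(median_image(img, 2)), oracle_median(img, 2))
  expect_error(median_image(img, 0), ">= 1")
})

test_that("spatial weight buffer reproduces the spatial kernel", {
  p <- filter_params(radius = 2, sigma_s = 1)
  wsb <- spatial_weight_buffer(p)
  expect_equal(wsb[1, 1], 1.0)              # zero offset
  expect_equal(wsb["1", "0"], exp(-0.5), ignore_attr = TRUE)
  expect_equal(unname(wsb), unname(t(wsb)))   # symmetric in d_x, d_y
  # buffer lookup equals the per-pixel kernel on random offsets
  set.seed(4)
  for (k in 1:20) {
    dx <- sample(0:2, 1); dy <- sample(0:2, 1)
    expect_identical(wsb[dx + 1, dy + 1],
                     exp(-(dx^2 + dy^2) / (2 * p$sigma_s^2)))
  }
})

test_that("range kernels match the scalar definition", {
  expect_equal(radiometric_weight(10, 10, 5), 1.0)
  expect_equal(radiometric_weight(0, 5, 5), exp(-0.5))
  expect_equal(median_weight(0, 10, 5), exp(-2))
  set.seed(5)
  a <- runif(50, 0, 255); b <- runif(50, 0, 255); s <- runif(50, 1, 60)
  expect_equal(radiometric_weight(a, b, s), exp(-(b - a)^2 / (2 * s^2)))
  expect_equal(median_weight(a, b, s), exp(-(b - a)^2 / (2 * s^2)))
  expect_error(radiometric_weight(1, 2, 0), "> 0")
})

test_that("agreement probability follows its closed form", {
  img <- image2d(matrix(c(0, 100, 200, 100), 2, 2), 200)
  med <- matrix(c(200, 100, 100, 0), 2, 2)
  p <- agreement_probability(img, med)
  expect_equal(p[1, 1], 0.5)        # |I - I^M| = MAX_I
  expect_equal(p[2, 1], 1)          # I = I^M
  expect_equal(p[1, 2], 0.625)      # |I - I^M| = MAX_I / 2
  expect_true(all(p >= 0.5 & p <= 1))
})

test_that("entropy map matches closed forms and the windowed oracle", {
  ones <- matrix(1, 5, 5)
  expect_equal(entropy_map(ones), matrix(0, 5, 5))
  half <- matrix(0.5, 5, 5)
  expect_equal(entropy_map(half), matrix(9 * log(2), 5, 5))
  set.seed(6)
  p <- matrix(runif(30, 0.5, 1), 5, 6)
  expect_equal(entropy_map(p), oracle_entropy(p, 1), tolerance = 1e-12)
  expect_equal(entropy_map(p, filter_params(radius = 2)),
               oracle_entropy(p, 2), tolerance = 1e-12)
  expect_true(all(entropy_map(p) >= 0))
})

test_that("ensemble weight: limits and the naive power oracle", {
  expect_equal(ensemble_weight(0.8, 0.6, 0.3, 0), 0.8 * 0.6)
  expect_equal(ensemble_weight(0.8, 1, 1, 17), 0.8)
  set.seed(7)
  ws <- runif(100, 0.01, 1); wr <- runif(100, 0.01, 1)
  wm <- runif(100, 0.01, 1); H <- runif(100, 0, 7)
  expect_equal(ensemble_weight(ws, wr, wm, H),
               ws * wr^(1 / (1 + H)) * wm^H, tolerance = 1e-12)
})

test_that("blend value covers both modes and rejects bad beta", {
  p0 <- filter_params(beta = 0); p1 <- filter_params(beta = 1)
  ph <- filter_params(beta = 0.5)
  expect_equal(blend_value(10, 20, p0), 10)
  expect_equal(blend_value(10, 20, p1), 20)
  expect_equal(blend_value(10, 20, ph), 15)
  pa <- filter_params(beta_mode = "adaptive")
  expect_equal(blend_value(10, 20, pa, p = 0.75), 0.75 * 10 + 0.25 * 20)
  expect_error(blend_value(1, 2, pa), "agreement")
  expect_error(filter_params(beta = 1.5), "\\[0, 1\\]")
})

# --- full filter ----------------------------------------------------------

test_that("reference backend matches the quadruple-loop oracle", {
  for (seed in 1:3) {
    img <- rand_image(7, 7, seed = seed)
    prm <- filter_params(sigma_s = runif(1, 0.5, 2),
                         sigma_r = runif(1, 10, 80),
                         sigma_m = runif(1, 10, 80), beta = runif(1))
    out <- collateral_filter(img, prm, backend = "reference")
    expect_lt(max(abs(out - oracle_collateral(img, prm))),
              1e-12 * max_intensity(img))
  }
  # adaptive blending, larger radius
  img <- rand_image(9, 8, seed = 9)
  prm <- filter_params(radius = 2, sigma_s = 1.3, sigma_r = 40,
                       sigma_m = 30, beta_mode = "adaptive")
  out <- collateral_filter(img, prm, backend = "reference")
  expect_lt(max(abs(out - oracle_collateral(img, prm))), 1e-12 * 255)
})

test_that("tiled backend is algebraically equivalent to the reference", {
  set.seed(21)
  for (k in 1:12) {
    m <- sample(5:64, 1); n <- sample(5:64, 1)
    img <- rand_image(m, n)
    prm <- filter_params(radius = sample(1:2, 1),
                         sigma_s = runif(1, 0.3, 3),
                         sigma_r = runif(1, 5, 120),
                         sigma_m = runif(1, 5, 120), beta = runif(1))
    S <- sample(c(1, 3, 16, 70), 1)
    expect_lt(max(abs(collateral_filter(img, prm, "tiled", tile_side = S) -
                        collateral_filter(img, prm, "reference"))),
              1e-10 * max_intensity(img))
  }
  # a single tile covering the image degenerates to the reference path
  img <- rand_image(12, 15, seed = 3)
  prm <- filter_params(sigma_r = 30, sigma_m = 30)
  expect_equal(as.matrix(collateral_filter(img, prm, "tiled", 64)),
               as.matrix(collateral_filter(img, prm, "reference")),
               tolerance = 1e-14)
})

test_that("flat images are fixed points, exactly", {
  flat <- image2d(matrix(123.25, 19, 23), 255)
  prm <- filter_params(sigma_r = 20, sigma_m = 20, beta = 0.7)
  expect_identical(as.matrix(collateral_filter(flat, prm, "reference")),
                   matrix(123.25, 19, 23))
  expect_identical(as.matrix(collateral_filter(flat, prm, "tiled")),
                   matrix(123.25, 19, 23))
})

test_that("output stays inside the window blend range", {
  set.seed(31)
  for (k in 1:5) {
    img <- rand_image(16, 16)
    prm <- filter_params(sigma_s = runif(1, 0.3, 3),
                         sigma_r = runif(1, 5, 120),
                         sigma_m = runif(1, 5, 120), beta = runif(1))
    out <- collateral_filter(img, prm)
    expect_true(all(out >= 0 - 1e-12 & out <= 255 + 1e-12))
    expect_true(min(out) >= min(img) - 1e-9)
    expect_true(max(out) <= max(img) + 1e-9)
  }
})

test_that("wide range kernels with beta = 0 reduce to Gaussian smoothing", {
  img <- rand_image(14, 11, seed = 41)
  prm <- filter_params(sigma_s = 1.1, sigma_r = 1e12, sigma_m = 1e12,
                       beta = 0)
  ref <- oracle_gaussian_window(img, 1.1, 1)
  expect_lt(max(abs(collateral_filter(img, prm, "reference") - ref)) / 255,
            1e-8)
  expect_lt(max(abs(collateral_filter(img, prm, "tiled") - ref)) / 255,
            1e-8)
})

test_that("entropy is zero iff image and median agree over the window", {
  img <- rand_image(10, 10, seed = 51)
  med <- median_image(img)
  H <- entropy_map(agreement_probability(img, med))
  expect_true(all(H >= 0))
  expect_equal(entropy_map(agreement_probability(med, med)),
               matrix(0, 10, 10))
  disagree <- abs(as.matrix(img) - as.matrix(med)) > 0
  # wherever some window pixel disagrees, H must be strictly positive
  widened <- collfilt:::box_mean(disagree * 1, 3) > 0
  expect_true(all(H[widened] > 0))
})

test_that("volumes are processed slice by slice", {
  set.seed(61)
  vol <- array(runif(8 * 8 * 3, 0, 255), c(8, 8, 3))
  prm <- filter_params(sigma_r = 30, sigma_m = 30)
  out <- collateral_filter_volume(vol, prm)
  expect_equal(dim(out), dim(vol))
  expect_equal(out[, , 2],
               as.matrix(collateral_filter(image2d(vol[, , 2], 255), prm)))
})

test_that("invalid parameters are rejected", {
  expect_error(filter_params(sigma_r = 0), "> 0")
  expect_error(filter_params(radius = 0), ">= 1")
  img <- rand_image(5, 5, seed = 1)
  expect_error(collateral_filter(img, filter_params(), tile_side = 0),
               ">= 1")
  expect_error(collateral_filter(img, params = list()), "filter_params")
})
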