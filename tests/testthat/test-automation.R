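test_that("brute force returns the grid argmax (contract and oracle)", {
  clean <- make_anatomy(phantom_spec(seed = 31))
  noisy <- add_rician_noise(clean, 0.05, seed = 32)
  # small grid: compare against an independent loop-and-compare oracle
  g <- parameter_grid(255, sigma_s = c(0.6, 1.2, 1.8),
                      sigma_r = c(15, 30, 60), sigma_m = c(25, 50),
                      beta = c(0, 0.5))
  bf <- brute_force_optimize(noisy, clean, g)
  ps <- vapply(seq_len(nrow(g)), function(i)
    psnr(clean, collateral_filter(noisy, filter_params(
      sigma_s = g$sigma_s[i], sigma_r = g$sigma_r[i],
      sigma_m = g$sigma_m[i], beta = g$beta[i]), "reference")),
    numeric(1))
  expect_equal(bf$psnr_all, ps, tolerance = 1e-10)
  expect_equal(bf$index, which.max(ps))
  expect_equal(bf$psnr_t, max(ps), tolerance = 1e-10)
  expect_equal(bf$params$sigma_r, g$sigma_r[which.max(ps)])
  # 2-point grid returns the larger, ties by first occurrence
  g2 <- g[c(bf$index, bf$index), ]
  bf2 <- brute_force_optimize(noisy, clean, g2)
  expect_equal(bf2$index, 1L)
  expect_error(brute_force_optimize(noisy, clean, g[0, ]), "empty")
})

test_that("the LM engine solves a Rosenbrock-style least-squares toy", {
  fn <- function(w) c(10 * (w[2] - w[1]^2), 1 - w[1])
  jc <- function(w) matrix(c(-20 * w[1], -1, 10, 0), 2, 2)
  fit <- collfilt:::lm_least_squares(fn, jc, c(-1.2, 1), max_iter = 200)
  expect_lt(fit$sse, 1e-6)
  expect_equal(fit$w, c(1, 1), tolerance = 1e-3)
})

test_that("networks recover a linear map and separate easy classes", {
  set.seed(41)
  # small-magnitude inputs keep one tanh unit in its linear regime
  X <- matrix(runif(240, -0.2, 0.2), 120, 2)
  Y <- X %*% c(0.3, -0.2) + 0.05
  net <- train_network(X, Y, hidden = 1, max_iter = 300, val_frac = 0,
                       seed = 3)
  expect_lt(sqrt(mean((predict_network(net, X) - Y)^2)), 1e-3)
  # linearly separable 3-class toy: 100% training accuracy
  cls <- rep(c("low", "median", "high"), each = 40)
  Xc <- cbind(rnorm(120, rep(c(0, 5, 10), each = 40), 0.3), rnorm(120))
  Yc <- t(vapply(cls, function(cc)
    as.numeric(c("low", "median", "high") == cc), numeric(3)))
  netc <- train_network(Xc, Yc, hidden = 5, max_iter = 100, val_frac = 0,
                        seed = 5)
  expect_equal(mean(max.col(predict_network(netc, Xc),
                            ties.method = "first") ==
                      max.col(Yc, ties.method = "first")), 1)
  # determinism under a fixed seed
  net2 <- train_network(Xc, Yc, hidden = 5, max_iter = 100, val_frac = 0,
                        seed = 5)
  expect_identical(netc$W1, net2$W1)
})

# a compact synthetic training table (no images): features carry the class
# and the optimal parameters are a smooth function of the features
fake_samples <- function(n_per_class = 40, seed = 1, noise = 0.05) {
  set.seed(seed)
  lv <- rep(c(1, 3, 5, 7, 9), each = n_per_class)
  f1 <- lv / 9 + rnorm(length(lv), 0, noise)
  f2 <- sqrt(lv / 9) + rnorm(length(lv), 0, noise)
  s <- data.frame(f1 = f1, f2 = f2,
                  noise_class = noise_class(lv),
                  noise_level = lv,
                  anatomy_id = seq_along(lv),
                  sigma_s = 0.5 + 1.5 * lv / 9,
                  sigma_r = (0.05 + 0.35 * lv / 9) * 255,
                  sigma_m = (0.05 + 0.2 * lv / 9) * 255,
                  beta = 0.25 + 0.5 * lv / 9,
                  psnr_t = 30)
  attr(s, "features") <- c("f1", "f2")
  s
}

test_that("two-stage model: training, routing, memorization, clipping", {
  s <- fake_samples(40, seed = 7)
  model <- train_two_stage(s, hidden = 6, max_iter = 120, seed = 2)
  # memorization: training samples come back near their own optima
  idx <- c(5, 60, 110, 170)
  for (i in idx) {
    pr <- predict_parameters(model, c(f1 = s$f1[i], f2 = s$f2[i]))
    expect_equal(pr$noise_class, s$noise_class[i])
    expect_lt(abs(pr$params$sigma_s - s$sigma_s[i]), 0.5)     # grid step
    expect_lt(abs(pr$params$sigma_r - s$sigma_r[i]), 0.1 * 255)
    expect_lt(abs(pr$params$beta - s$beta[i]), 0.25)
  }
  # features at the normalizer mean follow the bias pathway exactly
  mu <- model$normalizer$mean
  pr0 <- predict_parameters(model, c(f1 = mu[["f1"]], f2 = mu[["f2"]]))
  st1 <- model$stage1
  cls0 <- model$classes[which.max(st1$W2 %*% tanh(st1$b1) + st1$b2)]
  expect_equal(pr0$noise_class, cls0)
  net0 <- model$stage2[[cls0]]
  y0 <- as.numeric(net0$W2 %*% tanh(net0$b1) + net0$b2)
  p0 <- pmin(pmax(y0, 0), 1) * model$param_range + model$param_min
  expect_equal(pr0$params$sigma_s, p0[[1]])
  # predictions are clipped into the grid hull
  far <- c(f1 = 100, f2 = -100)
  pf <- predict_parameters(model, far)$params
  axes <- attr(parameter_grid(255), "axes")
  expect_gte(pf$sigma_s, min(axes$sigma_s))
  expect_lte(pf$sigma_s, max(axes$sigma_s))
  expect_gte(pf$beta, 0); expect_lte(pf$beta, 1)
  expect_error(predict_parameters(model, c(f1 = 1)), "f2")
  expect_error(train_two_stage(fake_samples(8), min_per_class = 30),
               "high")
})

test_that("training is deterministic and the model round-trips JSON", {
  s <- fake_samples(35, seed = 11)
  m1 <- train_two_stage(s, hidden = 4, max_iter = 60, seed = 3)
  m2 <- train_two_stage(s, hidden = 4, max_iter = 60, seed = 3)
  expect_identical(m1$stage1$W1, m2$stage1$W1)
  expect_identical(m1$stage2$high$W2, m2$stage2$high$W2)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m1, path)
  m3 <- read_model(path)
  x <- c(f1 = 0.4, f2 = 0.6)
  expect_equal(predict_parameters(m1, x), predict_parameters(m3, x),
               tolerance = 1e-12)
  # identical seeds give byte-identical model files
  path2 <- withr::local_tempfile(fileext = ".json")
  write_model(m2, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("evaluation reports eps_r per its definition, on-grid bound", {
  clean <- make_anatomy(phantom_spec(seed = 61))
  noisy <- add_rician_noise(clean, 0.07, seed = 62)
  g <- parameter_grid(255, sigma_s = c(0.8, 1.5), sigma_r = c(20, 50),
                      sigma_m = c(30,  60), beta = c(0.25, 0.75))
  bf <- brute_force_optimize(noisy, clean, g)
  # a model predicting exactly the optimum has eps_r = 0; PSNR_A <= PSNR_T
  # holds for any on-grid prediction
  ps <- psnr(clean, collateral_filter(noisy, bf$params))
  expect_lte(ps, bf$psnr_t + 1e-9)
  expect_equal(relative_error(bf$psnr_t, bf$psnr_t), 0)
  for (i in c(1, 7, 16)) {
    pa <- psnr(clean, collateral_filter(noisy, filter_params(
      sigma_s = g$sigma_s[i], sigma_r = g$sigma_r[i],
      sigma_m = g$sigma_m[i], beta = g$beta[i])))
    expect_lte(pa, bf$psnr_t + 1e-9)
  }
})
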