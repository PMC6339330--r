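#' Filter parameter grid
#'
#' The search space of the brute-force optimizer. Defaults span under- to
#' over-smoothing on phantoms normalized to `MAX_I`: `sigma_s` in
#' {0.5, 1, 1.5, 2} pixels, `sigma_r` and `sigma_m` in {0.05, 0.1, 0.2,
#' 0.4} `MAX_I`, `beta` in {0, 0.25, 0.5, 0.75, 1}; the radius stays fixed
#' at 1 (3 x 3 window).
#'
#' @param max_intensity intensity ceiling used to scale the range axes.
#' @param sigma_s,sigma_r,sigma_m,beta axis values.
#' @return a data.frame of grid points (class `parameter_grid`) with an
#'   `axes` attribute.
#' @export
parameter_grid <- function(max_intensity = 255,
                           sigma_s = c(0.5, 1, 1.5, 2),
                           sigma_r = c(0.05, 0.1, 0.2, 0.4) * max_intensity,
                           sigma_m = c(0.05, 0.1, 0.2, 0.4) * max_intensity,
                           beta = c(0, 0.25, 0.5, 0.75, 1)) {
  axes <- list(sigma_s = sigma_s, sigma_r = sigma_r, sigma_m = sigma_m,
               beta = beta)
  stopifnot(all(sigma_s > 0), all(sigma_r > 0), all(sigma_m > 0),
            all(beta >= 0 & beta <= 1))
  g <- expand.grid(axes, KEEP.OUT.ATTRS = FALSE)
  structure(g, axes = axes, class = c("parameter_grid", "data.frame"))
}

#' Brute-force PSNR-optimal filter parameters
#'
#' Filters `noisy` with every grid point and returns the parameters with
#' the highest PSNR against the noise-free reference, ties broken by first
#' occurrence in grid order. This is the "optimal outcome" the automatic
#' prediction is measured against.
#'
#' @param noisy,clean same-shape [image2d]s.
#' @param grid a [parameter_grid()].
#' @param radius filter radius (fixed, not searched).
#' @return list with `params` (a [filter_params]), `psnr_t` (dB), `index`
#'   (grid row) and `psnr_all` (PSNR per grid row).
#' @export
brute_force_optimize <- function(noisy, clean, grid = parameter_grid(),
                                 radius = 1L) {
  noisy <- as_image2d(noisy)
  clean <- as.matrix(clean)
  if (!all(dim(noisy) == dim(clean)))
    stop("images must share their shape", call. = FALSE)
  if (nrow(grid) == 0) stop("empty parameter grid", call. = FALSE)
  med <- as.matrix(median_image(noisy, radius))
  ps <- cpp_collateral_grid(as.matrix(noisy), med, clean, as.integer(radius),
                            grid$sigma_s, grid$sigma_r, grid$sigma_m,
                            grid$beta, max_intensity(noisy))
  i <- which.max(ps)
  list(params = filter_params(radius = radius, sigma_s = grid$sigma_s[i],
                              sigma_r = grid$sigma_r[i],
                              sigma_m = grid$sigma_m[i],
                              beta = grid$beta[i]),
       psnr_t = ps[i], index = i, psnr_all = ps)
}

## ---- Levenberg-Marquardt engine -----------------------------------------

# Damped Gauss-Newton minimization of 0.5 ||r(w)||^2. `fn(w)` returns the
# residual vector, `jac(w)` its Jacobian. lambda starts at 1e-3, is divided
# by 10 on an accepted step and multiplied by 10 on a rejected one; stops
# after `max_iter` iterations or when the gradient infinity norm drops
# below `grad_tol`.
lm_least_squares <- function(fn, jac, w0, max_iter = 200, grad_tol = 1e-8,
                             lambda0 = 1e-3, monitor = NULL) {
  w <- w0
  r <- fn(w)
  sse <- sum(r^2)
  lambda <- lambda0
  best <- list(w = w, sse = sse, monitor = if (is.null(monitor)) NULL
               else monitor(w))
  stall <- 0L
  for (it in seq_len(max_iter)) {
    J <- jac(w)
    g <- crossprod(J, r)
    if (max(abs(g)) < grad_tol) break
    A <- crossprod(J)
    accepted <- FALSE
    for (tries in 1:25) {
      step <- tryCatch(
        solve(A + lambda * diag(nrow(A)), -g),
        error = function(e) NULL)
      if (!is.null(step)) {
        w_new <- w + as.vector(step)
        r_new <- fn(w_new)
        sse_new <- sum(r_new^2)
        if (is.finite(sse_new) && sse_new < sse) {
          w <- w_new; r <- r_new; sse <- sse_new
          lambda <- max(lambda / 10, 1e-12)
          accepted <- TRUE
          break
        }
      }
      lambda <- lambda * 10
      if (lambda > 1e12) break
    }
    if (!accepted) break
    if (!is.null(monitor)) {
      mv <- monitor(w)
      if (mv < best$monitor) {
        best <- list(w = w, sse = sse, monitor = mv)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= 15L) break   # early stopping on the held-out split
      }
    }
  }
  if (is.null(monitor)) list(w = w, sse = sse)
  else list(w = best$w, sse = best$sse)
}

## ---- single-hidden-layer feed-forward networks --------------------------

# weights packed as c(W1, b1, W2, b2); tanh hidden, linear output
unpack_net <- function(w, n_in, n_hid, n_out) {
  i1 <- n_in * n_hid
  W1 <- matrix(w[seq_len(i1)], n_hid, n_in)
  b1 <- w[i1 + seq_len(n_hid)]
  i2 <- i1 + n_hid
  W2 <- matrix(w[i2 + seq_len(n_hid * n_out)], n_out, n_hid)
  b2 <- w[i2 + n_hid * n_out + seq_len(n_out)]
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
}

net_forward <- function(nt, X) {
  A <- tanh(X %*% t(nt$W1) + matrix(nt$b1, nrow(X), length(nt$b1),
                                    byrow = TRUE))
  list(A = A,
       Y = A %*% t(nt$W2) + matrix(nt$b2, nrow(X), length(nt$b2),
                                   byrow = TRUE))
}

# Jacobian of the stacked residual vector (samples x outputs, column-major
# over outputs) with respect to the packed weights
net_jacobian <- function(nt, X, n_out) {
  n <- nrow(X); n_in <- ncol(X); n_hid <- nrow(nt$W1)
  fw <- net_forward(nt, X)
  A <- fw$A
  D <- 1 - A^2                       # tanh'
  np <- n_in * n_hid + n_hid + n_hid * n_out + n_out
  J <- matrix(0, n * n_out, np)
  for (o in seq_len(n_out)) {
    rows <- (o - 1L) * n + seq_len(n)
    S <- D * matrix(nt$W2[o, ], n, n_hid, byrow = TRUE)  # dy_o/dz
    # dW1[h, i] blocks, column-major in h then i
    for (i in seq_len(n_in))
      J[rows, (i - 1L) * n_hid + seq_len(n_hid)] <- S * X[, i]
    J[rows, n_in * n_hid + seq_len(n_hid)] <- S
    # W2 is packed column-major: W2[o, h] sits at offset (h-1) * n_out + o
    J[rows, n_in * n_hid + n_hid + (seq_len(n_hid) - 1L) * n_out + o] <- A
    J[rows, n_in * n_hid + n_hid + n_hid * n_out + o] <- 1
  }
  J
}

#' Train a feed-forward network with Levenberg-Marquardt
#'
#' A single hidden layer with hyperbolic-tangent activation and linear
#' output, trained on the sum of squared errors by damped Gauss-Newton
#' (Levenberg-Marquardt) with optional early stopping on a held-out
#' fraction of the rows. Fully deterministic given `seed`.
#'
#' @param X numeric matrix of inputs (rows = samples); callers are expected
#'   to z-normalize.
#' @param Y numeric matrix of targets.
#' @param hidden hidden-layer width.
#' @param max_iter LM iteration cap.
#' @param val_frac held-out fraction for early stopping (0 disables).
#' @param seed initialization (and split) seed.
#' @return a `ff_network` list (`W1`, `b1`, `W2`, `b2`, dims).
#' @export
train_network <- function(X, Y, hidden = 10, max_iter = 200, val_frac = 0.2,
                          seed = 1L) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X); n_in <- ncol(X); n_out <- ncol(Y)
  stopifnot(n == nrow(Y), n >= 4)
  idx_val <- if (val_frac > 0 && n >= 10)
    with_seed(seed, sample(n, max(2, round(val_frac * n)))) else integer(0)
  tr <- setdiff(seq_len(n), idx_val)
  Xt <- X[tr, , drop = FALSE]; Yt <- Y[tr, , drop = FALSE]
  np <- n_in * hidden + hidden + hidden * n_out + n_out
  w0 <- with_seed(seed + 1L, stats::runif(np, -0.5, 0.5) / sqrt(n_in))
  fn <- function(w) {
    nt <- unpack_net(w, n_in, hidden, n_out)
    as.vector(net_forward(nt, Xt)$Y - Yt)
  }
  jc <- function(w) net_jacobian(unpack_net(w, n_in, hidden, n_out), Xt,
                                 n_out)
  mon <- if (length(idx_val)) {
    Xv <- X[idx_val, , drop = FALSE]; Yv <- Y[idx_val, , drop = FALSE]
    function(w) {
      nt <- unpack_net(w, n_in, hidden, n_out)
      sum((net_forward(nt, Xv)$Y - Yv)^2)
    }
  } else NULL
  fit <- lm_least_squares(fn, jc, w0, max_iter = max_iter, monitor = mon)
  nt <- unpack_net(fit$w, n_in, hidden, n_out)
  structure(c(nt, list(n_in = n_in, n_hid = hidden, n_out = n_out)),
            class = "ff_network")
}

#' @rdname train_network
#' @param net a trained `ff_network`.
#' @export
predict_network <- function(net, X) {
  net_forward(net, as.matrix(X))$Y
}

## ---- two-stage model -----------------------------------------------------

#' Two-stage parameter prediction model
#'
#' Stage 1 classifies an image's features into three noise classes — low
#' (1 and 3%), median (5 and 7%) and high (9%) — and routes them to one of
#' three stage-2 regressors, each trained only on its class's samples to
#' predict the brute-force-optimal filter parameters (`sigma_s`, `sigma_r`,
#' `sigma_m`, `beta`; the radius is fixed at 1). All networks are
#' single-hidden-layer tanh/linear and trained by Levenberg-Marquardt.
#'
#' @param samples a data.frame from [build_training_samples()]: feature
#'   columns (named in its `features` attribute), `noise_class`, the
#'   optimal parameter columns and `psnr_t`.
#' @param grid the [parameter_grid()] whose convex hull bounds predictions.
#' @param hidden hidden width for both stages.
#' @param max_iter LM iteration cap.
#' @param min_per_class minimum training samples required per class.
#' @param seed master seed.
#' @return a `two_stage_model` list.
#' @export
train_two_stage <- function(samples, grid = parameter_grid(), hidden = 10,
                            max_iter = 200, min_per_class = 30, seed = 1L) {
  feats <- attr(samples, "features")
  if (is.null(feats)) stop("`samples` lacks a `features` attribute",
                           call. = FALSE)
  classes <- c("low", "median", "high")
  cnt <- table(factor(samples$noise_class, classes))
  lacking <- names(cnt)[cnt < min_per_class]
  if (length(lacking))
    stop("too few training samples for class(es): ",
         paste(lacking, collapse = ", "), call. = FALSE)
  X <- as.matrix(samples[, feats, drop = FALSE])
  mu <- colMeans(X)
  sdv <- pmax(apply(X, 2, stats::sd), 1e-12)
  Xs <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  Y1 <- t(vapply(samples$noise_class,
                 function(cc) as.numeric(classes == cc), numeric(3)))
  stage1 <- train_network(Xs, Y1, hidden = hidden, max_iter = max_iter,
                          seed = seed)
  axes <- attr(grid, "axes")
  pnames <- c("sigma_s", "sigma_r", "sigma_m", "beta")
  pmin_ <- vapply(axes[pnames], min, numeric(1))
  pmax_ <- vapply(axes[pnames], max, numeric(1))
  prange <- pmax(pmax_ - pmin_, 1e-12)
  stage2 <- lapply(seq_along(classes), function(ci) {
    sel <- samples$noise_class == classes[ci]
    Yp <- sweep(sweep(as.matrix(samples[sel, pnames, drop = FALSE]),
                      2, pmin_), 2, prange, "/")
    train_network(Xs[sel, , drop = FALSE], Yp, hidden = hidden,
                  max_iter = max_iter, seed = seed + ci)
  })
  names(stage2) <- classes
  structure(list(normalizer = list(mean = mu, sd = sdv), stage1 = stage1,
                 stage2 = stage2, classes = classes, features = feats,
                 param_names = pnames, param_min = pmin_,
                 param_range = prange, seed = as.integer(seed),
                 hidden = hidden),
            class = "two_stage_model")
}

#' @rdname train_two_stage
#' @param model a trained `two_stage_model`.
#' @param features a named feature vector containing the model's features.
#' @return `predict_parameters()`: list with `noise_class` and `params`
#'   (a [filter_params], clipped into the grid's convex hull).
#' @export
predict_parameters <- function(model, features) {
  missing_f <- setdiff(model$features, names(features))
  if (length(missing_f))
    stop("missing feature(s): ", paste(missing_f, collapse = ", "),
         call. = FALSE)
  x <- (as.numeric(features[model$features]) - model$normalizer$mean) /
    model$normalizer$sd
  x <- matrix(x, 1)
  cls <- model$classes[max.col(predict_network(model$stage1, x),
                               ties.method = "first")]
  y <- as.numeric(predict_network(model$stage2[[cls]], x))
  p <- pmin(pmax(y, 0), 1) * model$param_range + model$param_min
  names(p) <- model$param_names
  list(noise_class = cls,
       params = filter_params(radius = 1L, sigma_s = p[["sigma_s"]],
                              sigma_r = p[["sigma_r"]],
                              sigma_m = p[["sigma_m"]],
                              beta = min(max(p[["beta"]], 0), 1)))
}

#' Build training samples from a phantom corpus
#'
#' Runs the brute-force optimizer on every clean/noisy pair and extracts
#' the working feature subset from the noisy image, producing the rows the
#' two-stage model trains on.
#'
#' @param corpus a [make_corpus()] result.
#' @param grid a [parameter_grid()].
#' @param features feature names to extract (default the five-feature
#'   working subset).
#' @param split restrict to `"train"`, `"test"`, or `"all"` rows.
#' @return data.frame with the feature columns, `noise_class`,
#'   `noise_level`, `anatomy_id`, the optimal parameter columns, and
#'   `psnr_t`; attribute `features` names the feature columns.
#' @export
build_training_samples <- function(corpus, grid = parameter_grid(),
                                   features = feature_subset_default(),
                                   split = c("all", "train", "test")) {
  split <- match.arg(split)
  keep <- if (split == "all") seq_len(nrow(corpus$labels))
          else which(corpus$labels$split == split)
  rows <- lapply(keep, function(k) {
    pr <- corpus$pairs[[k]]
    fv <- extract_features(pr$noisy, features)
    bf <- brute_force_optimize(pr$noisy, pr$clean, grid)
    cbind(as.data.frame(as.list(fv)),
          data.frame(noise_class = corpus$labels$noise_class[k],
                     noise_level = corpus$labels$noise_level[k],
                     anatomy_id = corpus$labels$anatomy_id[k],
                     sigma_s = bf$params$sigma_s,
                     sigma_r = bf$params$sigma_r,
                     sigma_m = bf$params$sigma_m,
                     beta = bf$params$beta, psnr_t = bf$psnr_t))
  })
  out <- do.call(rbind, rows)
  names(out)[seq_along(features)] <- features
  attr(out, "features") <- features
  out
}

#' Evaluate the automatic restoration against the brute-force optimum
#'
#' Predicts parameters from the image's features, filters with them
#' (`PSNR_A`), runs the brute-force search (`PSNR_T`), and reports the
#' relative error `eps_r = |PSNR_T - PSNR_A| / PSNR_T * 100`.
#'
#' @param model a `two_stage_model`.
#' @param noisy,clean the image pair.
#' @param grid the brute-force [parameter_grid()].
#' @param features optional precomputed named feature vector.
#' @return an `automation_report` list: `psnr_a`, `psnr_t`, `epsilon_r`,
#'   `noise_class`, `predicted_params`, `optimal_params`.
#' @export
evaluate_automation <- function(model, noisy, clean, grid = parameter_grid(),
                                features = NULL) {
  noisy <- as_image2d(noisy)
  if (is.null(features)) features <- extract_features(noisy, model$features)
  pred <- predict_parameters(model, features)
  restored <- collateral_filter(noisy, pred$params)
  psnr_a <- psnr(clean, restored)
  bf <- brute_force_optimize(noisy, clean, grid)
  structure(list(psnr_a = psnr_a, psnr_t = bf$psnr_t,
                 epsilon_r = relative_error(bf$psnr_t, psnr_a),
                 noise_class = pred$noise_class,
                 predicted_params = pred$params,
                 optimal_params = bf$params),
            class = "automation_report")
}

#' @export
print.automation_report <- function(x, ...) {
  cat(sprintf(
    "<automation_report> class = %s, PSNR_A = %.3f dB, PSNR_T = %.3f dB, eps_r = %.4f%%\n",
    x$noise_class, x$psnr_a, x$psnr_t, x$epsilon_r))
  invisible(x)
}

## ---- model serialization -------------------------------------------------

net_to_list <- function(net) {
  list(W1 = unclass(net$W1), b1 = net$b1, W2 = unclass(net$W2), b2 = net$b2,
       n_in = net$n_in, n_hid = net$n_hid, n_out = net$n_out)
}

net_from_list <- function(l) {
  structure(list(W1 = matrix(unlist(l$W1), l$n_hid, l$n_in),
                 b1 = as.numeric(unlist(l$b1)),
                 W2 = matrix(unlist(l$W2), l$n_out, l$n_hid),
                 b2 = as.numeric(unlist(l$b2)),
                 n_in = l$n_in, n_hid = l$n_hid, n_out = l$n_out),
            class = "ff_network")
}

#' Serialize a two-stage model to and from JSON
#'
#' The full model — weights, normalizer, parameter hull, feature list and
#' seed — round-trips through a single JSON document.
#'
#' @param model a `two_stage_model`.
#' @param path file path.
#' @export
write_model <- function(model, path) {
  doc <- list(normalizer = model$normalizer,
              stage1 = net_to_list(model$stage1),
              stage2 = lapply(model$stage2, net_to_list),
              classes = model$classes, features = model$features,
              param_names = model$param_names,
              param_min = as.list(model$param_min),
              param_range = as.list(model$param_range),
              seed = model$seed, hidden = model$hidden)
  # I(17) significant digits round-trips IEEE doubles exactly, so a stored
  # model reproduces its in-memory predictions bit for bit
  jsonlite::write_json(doc, path, digits = I(17), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  nmz <- list(mean = unlist(doc$normalizer$mean),
              sd = unlist(doc$normalizer$sd))
  names(nmz$mean) <- doc$features; names(nmz$sd) <- doc$features
  pm <- unlist(doc$param_min); pr <- unlist(doc$param_range)
  names(pm) <- doc$param_names; names(pr) <- doc$param_names
  structure(list(normalizer = nmz, stage1 = net_from_list(doc$stage1),
                 stage2 = lapply(doc$stage2, net_from_list),
                 classes = doc$classes, features = doc$features,
                 param_names = doc$param_names, param_min = pm,
                 param_range = pr, seed = doc$seed, hidden = doc$hidden),
            class = "two_stage_model")
}
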