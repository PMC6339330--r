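# Independent brute-force oracles. These deliberately re-derive every
# quantity from its definition (plain loops, naive power form) and share no
# code with the package's computational paths.

clampv <- function(v, lo, hi) pmin(pmax(v, lo), hi)

rand_image <- function(m, n, maxI = 255, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  image2d(matrix(runif(m * n, 0, maxI), m, n), maxI)
}

# per-pixel sort-and-pick median with replicated edges
oracle_median <- function(x, r) {
  x <- as.matrix(x)
  m <- nrow(x); n <- ncol(x)
  out <- x
  for (i in seq_len(m)) for (j in seq_len(n)) {
    vals <- c()
    for (di in -r:r) for (dj in -r:r)
      vals <- c(vals, x[clampv(i + di, 1, m), clampv(j + dj, 1, n)])
    out[i, j] <- sort(vals)[(length(vals) + 1) / 2]
  }
  out
}

# windowed double-loop entropy of an agreement-probability map
oracle_entropy <- function(p, N) {
  m <- nrow(p); n <- ncol(p)
  hf <- function(pp) {
    a <- if (pp > 0) pp * log(pp) else 0
    b <- if (pp < 1) (1 - pp) * log(1 - pp) else 0
    a + b
  }
  out <- matrix(0, m, n)
  for (i in seq_len(m)) for (j in seq_len(n)) {
    s <- 0
    for (di in -N:N) for (dj in -N:N)
      s <- s + hf(p[clampv(i + di, 1, m), clampv(j + dj, 1, n)])
    out[i, j] <- -s
  }
  out
}

# quadruple-loop collateral filter straight from the defining equations,
# using the naive power form of the ensemble weight
oracle_collateral <- function(img, params) {
  x <- as.matrix(img)
  maxI <- max_intensity(img)
  N <- params$radius
  m <- nrow(x); n <- ncol(x)
  med <- oracle_median(x, N)
  p <- (1 - abs(x - med) / maxI)^2 / 2 + 0.5
  H <- oracle_entropy(p, N)
  out <- x
  for (i in seq_len(m)) for (j in seq_len(n)) {
    num <- 0; den <- 0
    for (di in -N:N) for (dj in -N:N) {
      ci <- clampv(i + di, 1, m); cj <- clampv(j + dj, 1, n)
      ws <- exp(-(di^2 + dj^2) / (2 * params$sigma_s^2))
      wr <- exp(-(x[ci, cj] - x[i, j])^2 / (2 * params$sigma_r^2))
      wm <- exp(-(med[ci, cj] - med[i, j])^2 / (2 * params$sigma_m^2))
      W <- ws * wr^(1 / (1 + H[i, j])) * wm^H[i, j]
      b <- if (params$beta_mode == "adaptive") 1 - p[ci, cj] else params$beta
      num <- num + W * ((1 - b) * x[ci, cj] + b * med[ci, cj])
      den <- den + W
    }
    out[i, j] <- num / den
  }
  out
}

# normalized Gaussian-weighted window average (the sigma_r, sigma_m -> Inf,
# beta = 0 limit), replicated edges
oracle_gaussian_window <- function(x, sigma_s, N) {
  x <- as.matrix(x)
  m <- nrow(x); n <- ncol(x)
  out <- x
  for (i in seq_len(m)) for (j in seq_len(n)) {
    num <- 0; den <- 0
    for (di in -N:N) for (dj in -N:N) {
      w <- exp(-(di^2 + dj^2) / (2 * sigma_s^2))
      num <- num + w * x[clampv(i + di, 1, m), clampv(j + dj, 1, n)]
      den <- den + w
    }
    out[i, j] <- num / den
  }
  out
}

# definitional double-loop GLCM features from a normalized matrix
oracle_glcm_features <- function(M) {
  L <- nrow(M)
  mu_i <- 0; mu_j <- 0
  for (i in 1:L) for (j in 1:L) {
    mu_i <- mu_i + i * M[i, j]; mu_j <- mu_j + j * M[i, j]
  }
  v_i <- 0; v_j <- 0; asm <- 0; con <- 0; dis <- 0; hom <- 0; ent <- 0
  cov <- 0
  for (i in 1:L) for (j in 1:L) {
    pij <- M[i, j]
    v_i <- v_i + (i - mu_i)^2 * pij
    v_j <- v_j + (j - mu_j)^2 * pij
    asm <- asm + pij^2
    con <- con + (i - j)^2 * pij
    dis <- dis + abs(i - j) * pij
    hom <- hom + pij / (1 + (i - j)^2)
    if (pij > 0) ent <- ent - pij * log(pij)
    cov <- cov + (i - mu_i) * (j - mu_j) * pij
  }
  c(SDi = sqrt(v_i), SDj = sqrt(v_j), ASM = asm, CON = con, DIS = dis,
    HOM = hom, ENT = ent,
    COR = if (v_i > 0 && v_j > 0) cov / sqrt(v_i * v_j) else 0)
}

# enumerate maximal runs by walking each scan line explicitly
oracle_runs <- function(q, direction) {
  m <- nrow(q); n <- ncol(q)
  step <- switch(as.character(direction),
                 "0" = c(0, 1), "45" = c(-1, 1), "90" = c(-1, 0),
                 "135" = c(-1, -1))
  starts <- list()
  for (i in seq_len(m)) for (j in seq_len(n)) {
    pi <- i - step[1]; pj <- j - step[2]
    if (pi < 1 || pi > m || pj < 1 || pj > n)
      starts[[length(starts) + 1]] <- c(i, j)
  }
  runs <- list()
  for (s in starts) {
    i <- s[1]; j <- s[2]
    line <- c()
    while (i >= 1 && i <= m && j >= 1 && j <= n) {
      line <- c(line, q[i, j])
      i <- i + step[1]; j <- j + step[2]
    }
    r <- rle(line)
    for (k in seq_along(r$values))
      runs[[length(runs) + 1]] <- c(level = r$values[k],
                                    length = r$lengths[k])
  }
  do.call(rbind, runs)
}

oracle_glrlm_features <- function(runs, n_pixels) {
  Nr <- nrow(runs)
  g <- runs[, "level"]; r <- runs[, "length"]
  c(SRE = mean(1 / r^2), LRE = mean(r^2),
    GLN = sum(tapply(rep(1, Nr), g, sum)^2) / Nr,
    RLN = sum(tapply(rep(1, Nr), r, sum)^2) / Nr,
    RP = Nr / n_pixels,
    LGRE = mean(1 / g^2), HGRE = mean(g^2),
    SRLGE = mean(1 / (g^2 * r^2)), SRHGE = mean(g^2 / r^2),
    LRLGE = mean(r^2 / g^2), LRHGE = mean(g^2 * r^2))
}

# textbook direct-summation image moments
oracle_moments <- function(x) {
  v <- as.vector(x)
  mu <- sum(v) / length(v)
  va <- sum((v - mu)^2) / length(v)
  c(Mean = mu, SD = sqrt(va), VAR = va)
}
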