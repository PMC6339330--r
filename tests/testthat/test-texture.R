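test_that("statistical features: closed forms and the moment oracle", {
  suppressWarnings(v <- statistical_features(image2d(matrix(42, 8, 8), 255)))
  expect_equal(v[["Mean"]], 42)
  expect_equal(v[["SD"]], 0)
  expect_equal(v[["VAR"]], 0)
  expect_equal(v[["hist_energy"]], 1)
  expect_equal(v[["hist_ENT"]], 0)
  expect_warning(statistical_features(image2d(matrix(42, 8, 8), 255)),
                 "undefined")
  # two-level image: uniform two-bin histogram
  two <- image2d(matrix(rep(c(0, 255), each = 32), 8, 8), 255)
  v2 <- statistical_features(two)
  expect_equal(v2[["hist_ENT"]], 1)       # 1 bit
  expect_equal(v2[["hist_energy"]], 0.5)
  set.seed(13)
  img <- rand_image(16, 16)
  v3 <- statistical_features(img)
  mo <- oracle_moments(as.matrix(img))
  expect_equal(v3[c("Mean", "SD", "VAR")], mo)
})

test_that("GLCM construction matches enumerated pairs", {
  flat <- matrix(5, 4, 4)
  M <- glcm(flat, 0, levels = 8)
  expect_equal(sum(M != 0), 1)
  expect_equal(M[1, 1], 1)                # single normalized cell
  # 2 x 2 toy: two horizontal pairs, accumulated symmetrically
  toy <- matrix(c(0, 0, 1, 1), 2, 2)
  M2 <- glcm(toy, 0, levels = 2)
  expect_equal(M2[1, 2], 0.5)
  expect_equal(M2[2, 1], 0.5)
  expect_equal(M2[1, 1] + M2[2, 2], 0)
  set.seed(17)
  img <- matrix(sample(0:255, 100, TRUE), 10, 10)
  for (d in c(0, 45, 90, 135))
    expect_equal(sum(glcm(img, d)), 1)
  expect_error(glcm(matrix(1, 1, 1), 0), "smaller")
  expect_error(glcm(img, 30), "direction")
})

test_that("GLCM features: flats, checkerboard, and definitional oracle", {
  expect_warning(f <- glcm_features(glcm(matrix(5, 4, 4), 0, 8)),
                 "zero-variance")
  expect_equal(f[["ASM"]], 1)
  expect_equal(f[["CON"]], 0)
  expect_equal(f[["ENT"]], 0)
  expect_equal(f[["HOM"]], 1)
  chk <- outer(1:8, 1:8, function(i, j) (i + j) %% 2)
  fc <- glcm_features(glcm(chk, 0, levels = 2))
  expect_equal(fc[["CON"]], 1)
  expect_equal(fc[["ASM"]], 0.5)
  set.seed(19)
  img <- matrix(sample(0:255, 144, TRUE), 12, 12)
  for (d in c(0, 45, 90, 135)) {
    M <- glcm(img, d, levels = 8)
    expect_equal(glcm_features(M), oracle_glcm_features(M))
  }
})

test_that("GLRLM runs and features match the run-enumeration oracle", {
  flat <- matrix(3, 4, 4)
  R <- glrlm(flat, 0, levels = 8)
  expect_equal(sum(R$counts), 4)          # one run per row
  expect_equal(R$counts[1, 4], 4)         # constant -> level 1, length 4
  fr <- glrlm_features(R)
  expect_equal(fr[["RP"]], 0.25)
  expect_equal(fr[["LGRE"]], 1)
  expect_equal(fr[["HGRE"]], 1)
  # strictly alternating row: all runs have length 1
  alt <- matrix(rep(c(0, 255), 8), 1, 16)
  fa <- glrlm_features(glrlm(alt, 0, levels = 2))
  expect_equal(fa[["SRE"]], 1)
  expect_equal(fa[["RP"]], 1)
  one <- glrlm_features(list(counts = matrix(c(0, 1), 2, 1), n_pixels = 1))
  expect_equal(one[["SRE"]], 1)
  expect_equal(one[["LRE"]], 1)
  expect_equal(one[["RP"]], 1)
  set.seed(23)
  img <- matrix(sample(0:3, 80, TRUE), 8, 10) * 85
  for (d in c(0, 45, 90, 135)) {
    R <- glrlm(img, d, levels = 4)
    runs <- oracle_runs(collfilt:::quantize_levels(img, 4), d)
    # run lengths conserve the pixel count
    expect_equal(sum(R$counts * col(R$counts)), 80)
    expect_equal(glrlm_features(R),
                 oracle_glrlm_features(runs, 80), tolerance = 1e-12)
  }
  expect_error(glrlm_features(list(counts = matrix(0, 2, 2),
                                   n_pixels = 4)), "empty")
})

test_that("GLCM/GLRLM are invariant to adding a constant", {
  set.seed(29)
  img <- matrix(sample(0:200, 100, TRUE), 10, 10)
  for (d in c(0, 90)) {
    expect_equal(glcm_features(glcm(img, d)),
                 glcm_features(glcm(img + 30, d)))
    expect_equal(glrlm_features(glrlm(img, d)),
                 glrlm_features(glrlm(img + 30, d)))
  }
})

test_that("Tamura features behave as the perceptual axes dictate", {
  suppressWarnings(v <- tamura_features(image2d(matrix(9, 32, 32), 255)))
  expect_equal(v[["CON"]], 0)
  expect_equal(v[["DIR"]], 0)
  # vertical stripes: one dominant orientation
  stripes <- image2d(matrix(rep(c(0, 255), each = 2, length.out = 64 * 64),
                            64, 64), 255)
  vs <- tamura_features(stripes)
  expect_gt(vs[["DIR"]], 0.95)
  # coarse vs fine checkerboards
  fine <- outer(1:64, 1:64, function(i, j) ((i + j) %% 2) * 255)
  coarse <- outer(1:64, 1:64,
                  function(i, j) ((floor(i / 8) + floor(j / 8)) %% 2) * 255)
  expect_gt(tamura_features(image2d(coarse, 255))[["CRS"]],
            tamura_features(image2d(fine, 255))[["CRS"]])
})

test_that("the feature bank is complete and deterministic", {
  expect_length(feature_names(), 95)
  expect_true(all(feature_subset_default() %in% feature_names()))
  img <- add_rician_noise(make_anatomy(phantom_spec(seed = 2)), 0.05, 3)
  v1 <- extract_features(img, feature_names())
  v2 <- extract_features(img, feature_names())
  expect_identical(v1, v2)
  expect_length(v1, 95)
  expect_true(all(is.finite(v1)))
  expect_named(v1, feature_names())
  # subsets come back in the requested order
  sub <- extract_features(img, c("AJA", "RP_90", "kurtosis"))
  expect_named(sub, c("AJA", "RP_90", "kurtosis"))
  expect_equal(sub[["AJA"]], v1[["AJA"]])
  expect_error(extract_features(img, "nope"), "unknown")
})
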