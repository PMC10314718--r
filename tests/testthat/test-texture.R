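cfg4 <- texture_config(n_gray_levels = 4)

test_that("quantization bins uniformly and is idempotent", {
  expect_true(all(quantize_gray_levels(matrix(5, 3, 3), 8) == 1L))
  ramp <- matrix(rep(1:8, each = 8), 8, 8)
  q <- quantize_gray_levels(ramp, 8)
  expect_equal(as.vector(table(q)), rep(8L, 8))
  set.seed(1)
  for (i in 1:20) {
    img <- random_label_image(5, 5, 4)
    img[1:2] <- c(1L, 4L)             # pin the full label range
    q1 <- quantize_gray_levels(img, 4)
    expect_identical(quantize_gray_levels(q1, 4), q1)
  }
})

test_that("first-order features match direct summation", {
  expect_equal(first_order_features(matrix(c(0, 0, 255, 255), 2, 2))[1:2],
               c(mean = 127.5, std = 127.5))
  sym <- matrix(c(1, 2, 2, 3, 1, 3), 2, 3)
  expect_lt(abs(first_order_features(sym)[["skewness"]]), 1e-12)
  fo <- first_order_features(matrix(7, 2, 2))
  expect_true(is.na(fo[["skewness"]]) && is.na(fo[["kurtosis"]]))
  set.seed(2)
  for (i in 1:20) {
    img <- matrix(runif(25), 5, 5)
    expect_equal(first_order_features(img), oracle_moments(as.vector(img)))
  }
})

test_that("GLCM matches exhaustive pair enumeration", {
  const <- quantize_gray_levels(matrix(1, 4, 4), 4)
  P <- glcm(const, cfg4)
  expect_equal(sum(P), 1)
  expect_equal(P[1, 1], 1)

  checker <- matrix(c(1L, 2L, 2L, 1L), 2, 2)
  P2 <- glcm(checker, texture_config(n_gray_levels = 2, glcm_angles = 0))
  expect_equal(sum(diag(P2)), 0)      # mass entirely off-diagonal

  set.seed(3)
  for (i in 1:25) {
    img <- random_label_image(4, 4, 4)
    expect_equal(glcm(img, cfg4), oracle_glcm(img, 4))
  }
})

test_that("GLCM is symmetric and features match the oracle", {
  set.seed(4)
  img <- random_label_image(6, 6, 4)
  P <- glcm(img, cfg4)
  expect_equal(P, t(P))
  expect_equal(unname(glcm_features(P)), oracle_glcm_features(P))
  # constant image limits
  Pc <- glcm(matrix(1L, 4, 4), cfg4)
  f <- glcm_features(Pc)
  expect_equal(unname(f[c("glcm_energy", "glcm_entropy", "glcm_maximum",
                          "glcm_contrast", "glcm_homogeneity")]),
               c(1, 0, 1, 0, 1))
  # uniform P over k^2 cells
  k <- 3
  Pu <- matrix(1 / k^2, k, k)
  fu <- glcm_features(Pu)
  expect_equal(unname(fu[["glcm_energy"]]), 1 / k^2)
  expect_equal(unname(fu[["glcm_entropy"]]), log(k^2))
  expect_error(glcm_features(Pu * 2), "normalized")
})

test_that("run-length matrices match exhaustive run enumeration", {
  row8 <- matrix(1L, 1, 8)
  g <- glrm(row8, texture_config(n_gray_levels = 2, glrm_directions = 0))
  expect_equal(g$matrix[1, 8], 1)
  expect_equal(g$n_runs, 1)

  alt <- matrix(rep(c(1L, 2L), 4), 1, 8)
  g2 <- glrm(alt, texture_config(n_gray_levels = 2, glrm_directions = 0))
  expect_equal(g2$n_runs, 8)
  expect_true(all(g2$matrix[, -1] == 0))

  set.seed(5)
  for (i in 1:25) {
    img <- random_label_image(4, 4, 4)
    got <- glrm(img, cfg4)
    want <- oracle_glrm(img, 4)
    expect_equal(got$matrix, want$matrix)
    expect_equal(got$n_runs, want$n_runs)
  }
})

test_that("run-length features follow the canonical definitions", {
  r <- matrix(0, 2, 8); r[1, 1] <- 5; r[2, 1] <- 3   # all runs length 1
  f <- glrm_features(r, sum(r))
  expect_equal(unname(f[["glrm_spe"]]), 1)
  expect_equal(unname(f[["glrm_lpe"]]), 1)

  r2 <- matrix(0, 2, 8); r2[1, 6] <- 1               # one run, length 6
  f2 <- glrm_features(r2, 1)
  expect_equal(unname(f2[["glrm_spe"]]), 1 / 36)
  expect_equal(unname(f2[["glrm_lpe"]]), 36)

  set.seed(6)
  img <- random_label_image(5, 5, 3)
  g <- glrm(img, texture_config(n_gray_levels = 3))
  expect_equal(unname(glrm_features(g)),
               oracle_glrm_features(g$matrix, g$n_runs))
  expect_error(glrm_features(matrix(0, 2, 2), 0), "N_r")
})

test_that("NGTDM matches a direct sliding-window oracle", {
  const <- matrix(2L, 5, 5)
  nt <- ngtdm(const, cfg4)
  expect_true(all(nt$s == 0))

  # single bright centre in a flat field, hand-computed 5x5 case:
  # interior pixels: 9; the centre (level 4) sees neighbourhood mean 1,
  # its 8 interior neighbours (level 1) each see (7*1 + 4)/8
  img <- matrix(1L, 5, 5); img[3, 3] <- 4L
  nt2 <- ngtdm(img, cfg4)
  expect_equal(nt2$p[c(1, 4)], c(8, 1) / 9)
  expect_equal(nt2$s[4], 3)
  expect_equal(nt2$s[1], 8 * abs(1 - 11 / 8))

  set.seed(7)
  for (i in 1:25) {
    img <- random_label_image(6, 6, 4)
    got <- ngtdm(img, cfg4)
    want <- oracle_ngtdm(img, 4)
    expect_equal(got$p, want$p)
    expect_equal(got$s, want$s)
  }
  expect_error(ngtdm(matrix(1L, 2, 2), cfg4), "smaller than")
})

test_that("NGTDM features handle limits and match the oracle", {
  # constant image: contrast 0, strength 0, coarseness capped at 1/epsilon
  nt <- ngtdm(matrix(3L, 5, 5), cfg4)
  f <- ngtdm_features(nt$p, nt$s, nt$n_interior, epsilon = 1e-6)
  expect_equal(unname(f[["ngtdm_contrast"]]), 0)
  expect_equal(unname(f[["ngtdm_strength"]]), 0)
  expect_equal(unname(f[["ngtdm_coarseness"]]), 1e6)

  chk <- matrix(rep(c(1L, 2L), 13)[1:25], 5, 5)      # two-level checkerboard
  nt2 <- ngtdm(chk, texture_config(n_gray_levels = 2))
  expect_equal(unname(ngtdm_features(nt2$p, nt2$s, nt2$n_interior)),
               oracle_ngtdm_features(nt2$p, nt2$s, nt2$n_interior))
  expect_error(ngtdm_features(c(0.7, 0.7), c(0, 0), 4), "sum to 1")
})

test_that("the composed vector has 17 named finite entries", {
  set.seed(8)
  img <- matrix(runif(256), 16, 16)
  v <- texture_feature_vector(img)
  expect_length(v, 17L)
  expect_named(v)
  expect_true(all(is.finite(v)))
  expect_length(attr(v, "flags"), 0L)
  expect_identical(texture_feature_vector(img), v)

  # composition equals the individually verified parts
  cfg <- texture_config()
  q <- quantize_gray_levels(img, cfg$n_gray_levels)
  expect_equal(v[1:4], first_order_features(img))
  expect_equal(v[5:9], glcm_features(glcm(q, cfg)))
  expect_equal(v[10:13], glrm_features(glrm(q, cfg)))
  nt <- ngtdm(q, cfg)
  expect_equal(v[14:17], ngtdm_features(nt$p, nt$s, nt$n_interior,
                                        cfg$epsilon))
})

test_that("features over the full angle set are rotation invariant", {
  set.seed(9)
  img <- matrix(runif(64), 8, 8)
  rot <- t(img)[, nrow(img):1]         # 90 degree rotation
  cfg <- texture_config(n_gray_levels = 8)
  v1 <- texture_feature_vector(img, cfg)
  v2 <- texture_feature_vector(rot, cfg)
  expect_equal(v1, v2, ignore_attr = TRUE)
})

test_that("degenerate images flag missing values instead of NaN", {
  v <- texture_feature_vector(matrix(1, 8, 8))
  expect_length(v, 17L)
  expect_setequal(attr(v, "flags"), c("skewness", "kurtosis"))
  expect_true(all(is.finite(v[setdiff(names(v), attr(v, "flags"))])))
})

test_that("feature tables carry one row per image", {
  e <- image_ensemble(list(matrix(runif(64), 8, 8), matrix(runif(64), 8, 8)))
  tab <- texture_feature_table(e)
  expect_identical(dim(tab), c(2L, 18L))
  expect_identical(colnames(tab)[-1], simeval:::texture_feature_names())
})
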