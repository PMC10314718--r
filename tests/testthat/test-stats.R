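test_that("empirical PDFs are normalized densities", {
  set.seed(1)
  p <- empirical_pdf(rnorm(2000), bins = 32)
  expect_equal(sum(p$density * diff(p$breaks)), 1)
  expect_true(all(p$density >= 0))
  expect_error(empirical_pdf(numeric(0)), "empty")

  e <- image_ensemble(list(matrix(5, 4, 4)))
  g <- gray_level_pdf(e, bins = 10, range = c(0, 10))
  expect_equal(sum(g$counts > 0), 1L)
  expect_equal(sum(g$density * diff(g$breaks)), 1)
})

test_that("the Papoulis window is a valid taper", {
  expect_equal(papoulis_window(0), 1)
  expect_equal(papoulis_window(1), 0)
  expect_equal(papoulis_window(1.5), 0)
  r <- seq(0, 1, 0.01)
  w <- papoulis_window(r)
  expect_true(all(w >= -1e-12 & w <= 1))
})

test_that("white noise decorrelates beyond lag zero", {
  set.seed(2)
  e <- image_ensemble(lapply(1:20, function(i) matrix(rnorm(64^2), 64, 64)))
  prof <- radial_autocorrelation(e, max_lag = 10)
  expect_equal(prof$value[1], 1)                 # exact normalization
  expect_true(all(abs(prof$value[-1]) < 0.05))
  expect_error(radial_autocorrelation(
    image_ensemble(list(matrix(1, 8, 8)))), "constant")
})

test_that("blur widens the autocorrelation as the Gaussian theory predicts", {
  # white noise blurred with a Gaussian of s.d. sigma has autocorrelation
  # exp(-r^2 / (4 sigma^2)); its half-maximum lag is 2 sigma sqrt(log 2)
  blur <- function(m, sigma) {
    n <- nrow(m)
    f <- ((0:(n - 1) + n %/% 2) %% n - n %/% 2) / n
    H <- exp(-2 * pi^2 * sigma^2 * outer(f^2, f^2, "+"))
    Re(fft(fft(m) * H, inverse = TRUE)) / n^2
  }
  set.seed(3)
  for (sigma in c(2, 3)) {
    e <- image_ensemble(lapply(1:12, function(i)
      blur(matrix(rnorm(96^2), 96, 96), sigma)))
    prof <- radial_autocorrelation(e, max_lag = 24)
    above <- which(prof$value >= 0.5)
    i <- max(above)                              # last lag above half max
    # linear interpolation of the half-maximum crossing
    r_half <- prof$lag[i] + (prof$value[i] - 0.5) /
      (prof$value[i] - prof$value[i + 1])
    expect_lt(abs(r_half / (2 * sigma * sqrt(log(2))) - 1), 0.10)
  }
})

test_that("JS divergence has its exact identities and bounds", {
  set.seed(4)
  x <- rnorm(500)
  expect_equal(js_divergence(x, x), 0)
  expect_equal(js_divergence(runif(400), runif(400) + 10), log(2))
  a <- rnorm(300); b <- rnorm(300, 1)
  expect_identical(js_divergence(a, b), js_divergence(b, a))
  for (i in 1:10) {
    j <- js_divergence(rnorm(100), rnorm(100, i / 3))
    expect_gte(j, 0)
    expect_lte(j, log(2))
  }
  expect_error(js_divergence(numeric(0), 1), "empty")
})

test_that("SNR and Nhat follow the intensity-moment definitions", {
  set.seed(5)
  for (i in 1:10) {
    img <- matrix(rexp(256), 16, 16)
    s <- snr_and_nhat(img)
    mu <- sum(img) / length(img)
    sig <- sqrt(sum((img - mu)^2) / (length(img) - 1))
    expect_equal(s$snr, mu / sig)
    if (s$nhat_defined) {
      expect_equal(s$nhat, s$snr2 / (1 - s$snr2))
      # inverse relation round-trips to machine precision
      expect_equal(s$nhat / (1 + s$nhat), s$snr2)
    }
  }
  expect_error(snr_and_nhat(matrix(3, 4, 4)), "constant")
  big <- snr_and_nhat(matrix(100 + runif(64, 0, 1e-3), 8, 8))
  expect_false(big$nhat_defined)
  expect_true(is.na(big$nhat))
})

test_that("Nhat is monotone in SNR^2", {
  s2 <- seq(0.05, 0.95, by = 0.05)
  nh <- s2 / (1 - s2)
  expect_true(all(diff(nh) > 0))
  expect_equal(nh[s2 == 0.5], 1)
})

test_that("the Gaussian fit recovers parameters of Gaussian data", {
  # samples laid out exactly on the Gaussian quantile grid
  x <- qnorm(ppoints(20000), mean = 3, sd = 0.5)
  fit <- fit_gaussian_pdf(x, bins = 64)
  expect_lt(abs(fit$mu - 3), 0.01)
  expect_lt(abs(fit$sigma - 0.5), 0.01)
  expect_lt(fit$mse, 1e-4)

  set.seed(6)
  y <- rnorm(10000, mean = 1, sd = 2)
  fit2 <- fit_gaussian_pdf(y)
  expect_lt(abs(fit2$mu - 1), 3 * 2 / sqrt(10000))
  expect_lt(abs(fit2$mu - mean(y)), 0.1)
  expect_equal(unname(coef(fit2)), c(fit2$mu, fit2$sigma))
  expect_error(fit_gaussian_pdf(rep(1, 100)), "degenerate")
  expect_error(fit_gaussian_pdf(rnorm(10)), "at least 30")
})

test_that("the two-component feature PDF detects shifts, not rescales", {
  set.seed(7)
  e <- image_ensemble(lapply(1:300, function(i) matrix(runif(256), 16, 16)))
  tab <- texture_feature_table(e)
  same <- pca_feature_pdf(tab, tab, bins = 8)
  expect_equal(same$js, 0)
  expect_gte(same$explained_variance[1], same$explained_variance[2])

  # affine rescaling of one feature (in both tables) leaves the JS unchanged
  ra <- tab[1:150, ]; rb <- tab[151:300, ]
  js0 <- pca_feature_pdf(ra, rb, bins = 8)$js
  ra2 <- ra; rb2 <- rb
  ra2$glcm_entropy <- 5 * ra2$glcm_entropy - 2
  rb2$glcm_entropy <- 5 * rb2$glcm_entropy - 2
  expect_equal(pca_feature_pdf(ra2, rb2, bins = 8)$js, js0,
               tolerance = 1e-8)

  # a 5-pooled-sigma shift of one feature displaces the candidate mode
  rb3 <- rb
  rb3$glrm_spe <- rb3$glrm_spe + 5 * sd(rb3$glrm_spe)
  shift <- pca_feature_pdf(ra, rb3, bins = 8)$js
  expect_gt(shift, 2 * js0)
  expect_gt(shift, 0.15)
  expect_error(pca_feature_pdf(tab[1:4, ], tab[5:8, ]), "underdetermined")
})
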