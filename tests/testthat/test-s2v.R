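tab <- attenuation_table()
labs <- s2v_labels()

test_that("attenuation assignment is an exact pixelwise lookup", {
  all_fat <- matrix(labs[["fat"]], 8, 8)
  img <- assign_attenuation(all_fat, tab)
  expect_true(all(img == tab$values[["fat"]]))

  two <- matrix(rep(c(labs[["fat"]], labs[["glandular"]]), 32), 8, 8)
  img2 <- assign_attenuation(two, tab)
  expect_length(unique(as.vector(img2)), 2L)

  bad <- matrix(42L, 4, 4)
  expect_error(assign_attenuation(bad, tab), "42")
})

test_that("slice extraction follows the 40-70% / 50-pixel rule exactly", {
  vol100 <- array(labs[["fat"]], c(6, 6, 100))
  s <- extract_slices(vol100, out_size = 6)
  expect_length(s, 1L)            # indices {40}; next candidate 90 > 70
  vol200 <- array(labs[["fat"]], c(6, 6, 200))
  s2 <- extract_slices(vol200, out_size = 6)
  expect_length(s2, 2L)           # indices {80, 130}
  # direct check of the index rule
  expect_equal(seq(ceiling(0.4 * 100), floor(0.7 * 100), by = 50), 40)
  expect_equal(seq(ceiling(0.4 * 200), floor(0.7 * 200), by = 50),
               c(80, 130))
  expect_error(extract_slices(array(0L, c(4, 4, 10))), "spacing")
  expect_warning(out <- extract_slices(array(0L, c(4, 4, 60)),
                                       inner_fraction_range = c(0.505, 0.515),
                                       spacing = 50, out_size = 4),
                 "no coronal plane")
  expect_length(out, 0L)
})

test_that("downsampling preserves the label set", {
  set.seed(2)
  vol <- array(sample(unname(labs), 6 * 6 * 60, replace = TRUE), c(6, 6, 60))
  s <- extract_slices(vol, spacing = 10, out_size = 17)
  for (sl in s) {
    expect_identical(dim(sl), c(17L, 17L))
    expect_true(all(sl %in% labs))
  }
})

test_that("fat and glandular counts are exact on constructed images", {
  fat <- tab$values[["fat"]]; gla <- tab$values[["glandular"]]
  img <- matrix(c(rep(fat, 60), rep(gla, 30), rep(0, 10)), 10, 10)
  rs <- fat_glandular_ratio(img, tab)
  expect_identical(rs$F, 60L)
  expect_identical(rs$G, 30L)
  expect_equal(rs$ratio, 2)
  expect_equal(rs$log_ratio, log(2))

  # 2% off the fat coefficient falls outside the 1.5% tolerance
  img2 <- matrix(fat * 1.02, 5, 5)
  expect_identical(fat_glandular_ratio(img2, tab)$F, 0L)

  # G = 0 is flagged, not an error
  img3 <- matrix(fat, 4, 4)
  rs3 <- fat_glandular_ratio(img3, tab)
  expect_true(rs3$undefined)
  expect_true(is.na(rs3$ratio))
})

test_that("counts are invariant to a global attenuation rescale", {
  set.seed(3)
  sl <- matrix(sample(c(labs[["fat"]], labs[["glandular"]], labs[["skin"]]),
                      400, replace = TRUE), 20, 20)
  img <- assign_attenuation(sl, tab)
  r1 <- fat_glandular_ratio(img, tab)
  scaled <- attenuation_table(tab$values * 3)
  r2 <- fat_glandular_ratio(img * 3, scaled)
  expect_identical(r1$F, r2$F)
  expect_identical(r1$G, r2$G)
})

test_that("thresholding recovers label counts through attenuation", {
  set.seed(4)
  for (i in 1:5) {
    sl <- matrix(sample(unname(labs), 15 * 15, replace = TRUE), 15, 15)
    img <- assign_attenuation(sl, tab)
    rs <- fat_glandular_ratio(img, tab)
    expect_identical(rs$F, sum(sl == labs[["fat"]]))
    expect_identical(rs$G, sum(sl == labs[["glandular"]]))
  }
})

test_that("attenuation tables enforce fat/glandular separability", {
  v <- tab$values
  v[["glandular"]] <- v[["fat"]] * 1.01
  expect_error(attenuation_table(v), "separable")
  expect_error(attenuation_table(tab$values[-2]), "missing labels")
})

test_that("surrogate slices are seeded, labelled and ratio-accurate", {
  cfg <- surrogate_phantom_config(image_size = 96)
  a <- sample_surrogate_phantom_slice(cfg, seed = 10)
  b <- sample_surrogate_phantom_slice(cfg, seed = 10)
  expect_identical(a, b)
  expect_true(all(a %in% labs))
  tl <- attr(a, "target_log_ratio")
  rl <- attr(a, "realized_log_ratio")
  expect_lt(abs(exp(rl) / exp(tl) - 1), cfg$ratio_tolerance)
  # skin rim present, background outside
  expect_true(any(a == labs[["skin"]]))
  expect_true(any(a == labs[["background"]]))
})

test_that("surrogate mode prevalences match the configured mixture", {
  cfg <- surrogate_phantom_config(image_size = 64, n_vessels = 0)
  n <- 300L
  modes <- vapply(seq_len(n), function(i) {
    attr(sample_surrogate_phantom_slice(cfg, seed = 7000 + i), "mode")
  }, 0L)
  ct <- tabulate(modes, 4) / n
  for (m in 1:4) {
    p <- cfg$mode_prevalence[m]
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(ct[m] - p), 4 * se + 1e-9)
  }
})

test_that("the log-ratio PDF recovers the generator's four-mode structure", {
  cfg <- surrogate_phantom_config(image_size = 64, n_vessels = 0,
                                  mode_log_ratio_sd = rep(0.15, 4))
  n <- 240L
  lr <- vapply(seq_len(n), function(i) {
    attr(sample_surrogate_phantom_slice(cfg, seed = 8000 + i),
         "realized_log_ratio")
  }, 0)
  # classify each realized log-ratio to its nearest configured mode centre
  cls <- apply(abs(outer(lr, cfg$mode_log_ratio_mean, "-")), 1, which.min)
  within <- abs(lr - cfg$mode_log_ratio_mean[cls])
  expect_gt(mean(within < 3 * 0.15), 0.95)   # tight, well-separated modes
  expect_equal(sort(unique(cls)), 1:4)       # all four modes realized
})
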