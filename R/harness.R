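#' Degrade an image by Gaussian blur plus ideal low-pass filtering
#'
#' Applies a Gaussian blur of standard deviation `blur_sigma` pixels
#' (spectral multiplication) followed by an ideal radial low-pass mask
#' with cutoff at half the image bandwidth (0.25 cycles/pixel): all
#' spectral components beyond the cutoff are zeroed exactly.  Used to
#' construct the "degraded" class of multi-class study ensembles.
#'
#' @param img numeric matrix.
#' @param blur_sigma Gaussian blur standard deviation, pixels (> 0).
#' @return real-valued matrix, same shape.
#' @export
degrade_image <- function(img, blur_sigma = 2) {
  if (blur_sigma <= 0) stop("'blur_sigma' must be > 0")
  n <- nrow(img); m <- ncol(img)
  fr <- ((0:(n - 1) + n %/% 2) %% n - n %/% 2) / n
  fc <- ((0:(m - 1) + m %/% 2) %% m - m %/% 2) / m
  F2 <- outer(fr^2, fc^2, "+")
  H <- exp(-2 * pi^2 * blur_sigma^2 * F2)
  H[F2 > 0.25^2] <- 0
  Re(stats::fft(stats::fft(img) * H, inverse = TRUE)) / (n * m)
}

#' Degrade every image of an ensemble
#'
#' @param e an [image_ensemble()].
#' @param blur_sigma see [degrade_image()].
#' @return degraded [image_ensemble()].
#' @export
degrade_ensemble <- function(e, blur_sigma = 2) {
  stopifnot(inherits(e, "image_ensemble"))
  image_ensemble(lapply(e$images, degrade_image, blur_sigma = blur_sigma),
                 pixel_pitch = e$pixel_pitch,
                 provenance = c(e$provenance,
                                list(degraded = TRUE,
                                     blur_sigma = blur_sigma)),
                 validate = FALSE)
}

#' Mix component ensembles into a multi-class ensemble
#'
#' Draws `n` class labels from the categorical law given by `fractions`
#' (seeded) and takes images sequentially from the corresponding
#' component ensembles.  Class labels are retained in the provenance for
#' diagnostics but are not exposed to any metric.
#'
#' @param components list of [image_ensemble()] objects.
#' @param fractions class probabilities, summing to 1.
#' @param n total number of images.
#' @param seed integer seed for the label draw.
#' @return an [image_ensemble()]; provenance records the realized
#'   labels.
#' @export
mix_ensembles <- function(components, fractions, n, seed) {
  if (length(components) != length(fractions)) {
    stop("'components' and 'fractions' must have equal length")
  }
  if (abs(sum(fractions) - 1) > 1e-8 || any(fractions <= 0)) {
    stop("'fractions' must be positive and sum to 1")
  }
  if (n < 1) stop("'n' must be >= 1")
  labels <- with_seed(seed, {
    sample.int(length(fractions), n, replace = TRUE, prob = fractions)
  })
  counts <- tabulate(labels, length(components))
  avail <- vapply(components, length, 0L)
  if (any(counts > avail)) {
    stop("component ensemble(s) too small for the realized class counts: ",
         paste(which(counts > avail), collapse = ", "))
  }
  taken <- integer(length(components))
  imgs <- vector("list", n)
  for (i in seq_len(n)) {
    k <- labels[i]
    taken[k] <- taken[k] + 1L
    imgs[[i]] <- components[[k]]$images[[taken[k]]]
  }
  image_ensemble(imgs, pixel_pitch = components[[1L]]$pixel_pitch,
                 provenance = list(model = "mixture",
                                   fractions = fractions, n = n,
                                   seed = seed, labels = labels),
                 validate = FALSE)
}

#' Compare a candidate ensemble against a reference ensemble
#'
#' Runs the metric suite appropriate to the model family on both
#' ensembles identically and reports the Jensen-Shannon divergence of
#' every pertinent statistic:
#'
#' * all suites: pooled gray-level-PDF JS and the maximum absolute
#'   difference of the radial autocorrelation profiles;
#' * `"clb"`: per-feature JS for the 17 texture features, their
#'   aggregate (mean or max), and the 2-D JS over the first two pooled
#'   principal components;
#' * `"uss"`: JS of the per-image `SNR^2` distributions (computed on
#'   intensity, i.e. squared pixel values -- pass 8-bit quantized
#'   envelope ensembles to match the canonical preprocessing);
#' * `"s2v"`: JS of the per-image natural-log fat-to-glandular ratio
#'   distributions (requires the attenuation `table`).
#'
#' @param ref,cand [image_ensemble()] objects of identical image shape.
#' @param suite `"clb"`, `"uss"` or `"s2v"`.
#' @param bins shared histogram bin count for every JS estimate.
#' @param texture_cfg [texture_config()] for the `"clb"` suite.
#' @param table [attenuation_table()] for the `"s2v"` suite.
#' @param aggregate aggregation of the 17 per-feature divergences.
#' @param max_lag autocorrelation profile length (pixels).
#' @return object of class `comparison_report`.
#' @export
compare_ensembles <- function(ref, cand, suite = c("clb", "uss", "s2v"),
                              bins = 64L, texture_cfg = texture_config(),
                              table = NULL,
                              aggregate = c("mean", "max"),
                              max_lag = NULL) {
  suite <- match.arg(suite)
  aggregate <- match.arg(aggregate)
  stopifnot(inherits(ref, "image_ensemble"),
            inherits(cand, "image_ensemble"))
  if (!identical(dim(ref$images[[1L]]), dim(cand$images[[1L]]))) {
    stop("reference and candidate image shapes differ")
  }
  metrics <- list()

  metrics$graylevel_js <- js_divergence(
    unlist(ref$images, use.names = FALSE),
    unlist(cand$images, use.names = FALSE), bins = bins)

  ac_r <- radial_autocorrelation(ref, max_lag = max_lag)
  ac_c <- radial_autocorrelation(cand, max_lag = max_lag)
  metrics$acf_max_abs_diff <- max(abs(ac_r$value - ac_c$value))

  if (suite == "clb") {
    fr <- texture_feature_table(ref, texture_cfg)
    fc <- texture_feature_table(cand, texture_cfg)
    feat <- texture_feature_names()
    per <- vapply(feat, function(f) {
      a <- fr[[f]]; b <- fc[[f]]
      a <- a[is.finite(a)]; b <- b[is.finite(b)]
      if (!length(a) || !length(b)) return(NA_real_)
      js_divergence(a, b, bins = bins)
    }, 0)
    metrics$per_feature_js <- per
    metrics$feature_js <- if (aggregate == "mean") {
      mean(per, na.rm = TRUE)
    } else max(per, na.rm = TRUE)
    metrics$pca_js <- pca_feature_pdf(fr, fc, bins = bins)$js
  } else if (suite == "uss") {
    sr <- speckle_stats_table(ref)
    sc <- speckle_stats_table(cand)
    metrics$snr2_js <- js_divergence(sr$snr2, sc$snr2, bins = bins)
  } else {
    if (is.null(table)) stop("the 's2v' suite requires an attenuation table")
    lr <- vapply(ref$images, function(m)
      fat_glandular_ratio(m, table)$log_ratio, 0)
    lc <- vapply(cand$images, function(m)
      fat_glandular_ratio(m, table)$log_ratio, 0)
    metrics$ratio_js <- js_divergence(lr[is.finite(lr)],
                                      lc[is.finite(lc)], bins = bins)
  }

  structure(list(suite = suite, bins = bins, aggregate = aggregate,
                 n_ref = length(ref), n_cand = length(cand),
                 metrics = metrics,
                 provenance = list(ref = ref$provenance,
                                   cand = cand$provenance)),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> suite '%s' (%d vs %d images, %d bins)\n",
              x$suite, x$n_ref, x$n_cand, x$bins))
  for (k in names(x$metrics)) {
    v <- x$metrics[[k]]
    if (length(v) == 1L) {
      cat(sprintf("  %-18s %.5f\n", k, v))
    } else {
      cat(sprintf("  %s:\n", k))
      for (f in names(v)) cat(sprintf("    %-18s %.5f\n", f, v[[f]]))
    }
  }
  invisible(x)
}

# dispatchable ensemble generation used by noise_floor
generate_ensemble <- function(config, n, seed, ...) {
  UseMethod("generate_ensemble")
}

#' @export
generate_ensemble.clb_config <- function(config, n, seed, ...) {
  generate_clb_ensemble(config, n, seed)
}

#' @export
generate_ensemble.uss_physics <- function(config, n, seed,
                                          quantize = TRUE, ...) {
  e <- generate_uss_ensemble(config, n, seed)
  if (quantize) suppressMessages(quantize_ensemble_8bit(e)) else e
}

#' @export
generate_ensemble.surrogate_phantom_config <- function(config, n, seed,
                                                       table = NULL, ...) {
  if (is.null(table)) table <- attenuation_table()
  generate_s2v_ensemble(config, table, n, seed)
}

#' Noise floor of the comparison metrics
#'
#' Applies [compare_ensembles()] to two independent ensembles drawn from
#' the same configuration with different seeds.  The resulting report is
#' the attainable lower reference ("noise floor") for every metric at
#' this ensemble size; its keys match any comparison report of the same
#' suite.
#'
#' @param config a [clb_config()], [uss_physics()] or
#'   [surrogate_phantom_config()].
#' @param n images per ensemble.
#' @param seed_a,seed_b distinct master seeds.
#' @param suite,... passed to [compare_ensembles()].
#' @return a `comparison_report`.
#' @export
noise_floor <- function(config, n, seed_a, seed_b, suite, ...) {
  if (identical(seed_a, seed_b)) {
    stop("seeds must differ: an identical-seed floor is degenerately 0")
  }
  args <- list(...)
  gen_args <- args[names(args) %in% "table"]
  ea <- do.call(generate_ensemble,
                c(list(config = config, n = n, seed = seed_a), gen_args))
  eb <- do.call(generate_ensemble,
                c(list(config = config, n = n, seed = seed_b), gen_args))
  do.call(compare_ensembles,
          c(list(ref = ea, cand = eb, suite = suite), args))
}

#' Serialize / restore a comparison report
#'
#' Reports round-trip losslessly through JSON.
#'
#' @param report a `comparison_report`.
#' @param path JSON file path.
#' @return `write_report()` returns `path` invisibly; `read_report()`
#'   returns the restored `comparison_report`.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "comparison_report"))
  x <- unclass(report)
  # named vectors must become JSON objects, not bare arrays
  x$metrics <- lapply(x$metrics, function(v) {
    if (length(v) > 1L && !is.null(names(v))) as.list(v) else v
  })
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$metrics <- lapply(x$metrics, function(v) {
    if (is.list(v)) unlist(v) else v
  })
  structure(x, class = "comparison_report")
}
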