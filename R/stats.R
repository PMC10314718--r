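#' Empirical probability density function
#'
#' Histogram-based density estimate over equal-width bins; the density
#' integrates to 1 over the binned range.
#'
#' @param samples numeric vector.
#' @param bins number of equal-width bins, or an explicit vector of
#'   break points.
#' @param range optional `c(lo, hi)` range for the bins (defaults to the
#'   sample range).
#' @return object of class `empirical_pdf` with fields `breaks`,
#'   `density`, `counts`, `n`.
#' @export
empirical_pdf <- function(samples, bins = 64L, range = NULL) {
  samples <- samples[is.finite(samples)]
  if (length(samples) == 0L) stop("empty sample")
  if (length(bins) == 1L) {
    if (is.null(range)) range <- base::range(samples)
    if (diff(range) == 0) range <- range + c(-0.5, 0.5)
    breaks <- seq(range[1L], range[2L], length.out = bins + 1L)
  } else {
    breaks <- bins
  }
  idx <- findInterval(samples, breaks, rightmost.closed = TRUE)
  idx <- idx[idx >= 1L & idx <= length(breaks) - 1L]
  counts <- tabulate(idx, length(breaks) - 1L)
  width <- diff(breaks)
  dens <- counts / sum(counts) / width
  structure(list(breaks = breaks, density = dens, counts = counts,
                 n = length(samples)),
            class = "empirical_pdf")
}

#' @export
print.empirical_pdf <- function(x, ...) {
  cat(sprintf("<empirical_pdf> %d bins over [%g, %g], n = %d\n",
              length(x$density), x$breaks[1L],
              x$breaks[length(x$breaks)], x$n))
  invisible(x)
}

#' @export
plot.empirical_pdf <- function(x, ...) {
  mid <- (x$breaks[-1L] + x$breaks[-length(x$breaks)]) / 2
  graphics::plot(mid, x$density, type = "s", xlab = "value",
                 ylab = "density", ...)
  invisible(x)
}

#' Pooled gray-level PDF of an ensemble
#'
#' @param e an [image_ensemble()].
#' @param bins bin count or explicit breaks (see [empirical_pdf()]).
#' @param range optional binning range.
#' @return an [empirical_pdf()] of all pixels pooled over the ensemble.
#' @export
gray_level_pdf <- function(e, bins = 64L, range = NULL) {
  stopifnot(inherits(e, "image_ensemble"))
  empirical_pdf(unlist(e$images, use.names = FALSE), bins = bins,
                range = range)
}

#' Papoulis window
#'
#' The Papoulis (Bohman-family) taper
#' `w(r) = (1/pi) * |sin(pi r)| + (1 - r) * cos(pi r)` for `r` in
#' `[0, 1]`, zero outside; `w(0) = 1`.
#'
#' @param r nonnegative normalized radius.
#' @return window values, same shape as `r`.
#' @export
papoulis_window <- function(r) {
  w <- abs(sin(pi * r)) / pi + (1 - r) * cos(pi * r)
  w[r >= 1] <- 0
  w
}

#' Ensemble radial autocorrelation profile
#'
#' Per image: subtract the image mean, multiply by a centred 2-D radial
#' Papoulis taper, compute the spectral autocorrelation
#' `Re(ifft(|fft|^2))`; the per-image autocorrelations are averaged over
#' the ensemble, normalized so the zero-lag value is 1, and radially
#' averaged over integer-lag annuli.
#'
#' @param e an [image_ensemble()].
#' @param max_lag largest radial lag (pixels); default a quarter of the
#'   image side.
#' @return object of class `radial_profile` with fields `lag` and
#'   `value` (`value[1] = 1` at lag 0).
#' @export
radial_autocorrelation <- function(e, max_lag = NULL) {
  stopifnot(inherits(e, "image_ensemble"))
  d <- dim(e$images[[1L]])
  n <- d[1L]; m <- d[2L]
  if (is.null(max_lag)) max_lag <- floor(min(n, m) / 4)
  cx <- (n + 1) / 2; cy <- (m + 1) / 2
  X <- matrix(seq_len(n), n, m) - cx
  Y <- t(matrix(seq_len(m), m, n)) - cy
  rr <- sqrt((X / (n / 2))^2 + (Y / (m / 2))^2)
  W <- papoulis_window(rr)
  acc <- matrix(0, n, m)
  any_var <- FALSE
  for (img in e$images) {
    v <- img - mean(img)
    if (any(v != 0)) any_var <- TRUE
    F <- stats::fft(v * W)
    acc <- acc + Re(stats::fft(F * Conj(F), inverse = TRUE)) / (n * m)
  }
  if (!any_var) stop("constant images: autocorrelation undefined")
  if (acc[1L, 1L] <= 0) stop("zero-variance ensemble")
  acc <- acc / acc[1L, 1L]
  # wrapped lag distances
  dr <- pmin(0:(n - 1), n - (0:(n - 1)))
  dc <- pmin(0:(m - 1), m - (0:(m - 1)))
  lagd <- sqrt(outer(dr^2, dc^2, "+"))
  bin <- round(lagd)
  keep <- bin <= max_lag
  prof <- vapply(0:max_lag, function(l) mean(acc[keep & bin == l]), 0)
  structure(list(lag = 0:max_lag, value = prof), class = "radial_profile")
}

#' @export
print.radial_profile <- function(x, ...) {
  cat(sprintf("<radial_profile> lags 0..%d, value[0] = %g\n",
              max(x$lag), x$value[1L]))
  invisible(x)
}

#' @export
plot.radial_profile <- function(x, ...) {
  graphics::plot(x$lag, x$value, type = "b", xlab = "lag (pixels)",
                 ylab = "autocorrelation", ...)
  invisible(x)
}

#' Empirical Jensen-Shannon divergence between two samples
#'
#' Histograms both samples on shared equal-width bins spanning the
#' pooled range and computes
#' `JS = KL(p || m)/2 + KL(q || m)/2` with `m = (p + q)/2`, in natural
#' log units; the result lies in `[0, log 2]`.  Zero-count bins
#' contribute 0 to their KL terms.
#'
#' @param samples_p,samples_q numeric sample vectors.
#' @param bins number of shared bins.
#' @return scalar divergence in nats.
#' @export
js_divergence <- function(samples_p, samples_q, bins = 64L) {
  samples_p <- samples_p[is.finite(samples_p)]
  samples_q <- samples_q[is.finite(samples_q)]
  if (!length(samples_p) || !length(samples_q)) stop("empty sample")
  rng <- range(c(samples_p, samples_q))
  if (diff(rng) == 0) return(0)
  breaks <- seq(rng[1L], rng[2L], length.out = bins + 1L)
  h <- function(s) {
    i <- findInterval(s, breaks, rightmost.closed = TRUE)
    i[i < 1L] <- 1L; i[i > bins] <- bins
    tabulate(i, bins) / length(s)
  }
  js_from_pmf(h(samples_p), h(samples_q))
}

# JS divergence of two probability mass vectors (shared support)
js_from_pmf <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(a) {
    nz <- a > 0
    sum(a[nz] * log(a[nz] / m[nz]))
  }
  (kl(p) + kl(q)) / 2
}

#' Per-image speckle SNR and scatterer-count estimate
#'
#' For an intensity image computes `SNR = mu_I / sigma_I` from the
#' per-image mean and standard deviation, and the scatterers-per-
#' resolution-cell estimate `Nhat = SNR^2 / (1 - SNR^2)`, defined only
#' when `SNR^2 < 1` (otherwise flagged `NA`).
#'
#' @param img nonconstant numeric matrix of intensities.
#' @return object of class `speckle_stats`: list with `snr`, `snr2`,
#'   `nhat` and logical `nhat_defined`.
#' @export
snr_and_nhat <- function(img) {
  mu <- mean(img)
  sig <- stats::sd(img)
  if (sig == 0) stop("constant image: SNR undefined")
  snr <- mu / sig
  snr2 <- snr^2
  defined <- snr2 < 1
  structure(list(snr = snr, snr2 = snr2,
                 nhat = if (defined) snr2 / (1 - snr2) else NA_real_,
                 nhat_defined = defined),
            class = "speckle_stats")
}

#' @export
print.speckle_stats <- function(x, ...) {
  cat(sprintf("<speckle_stats> SNR = %.4f, SNR^2 = %.4f, Nhat = %s\n",
              x$snr, x$snr2,
              if (x$nhat_defined) sprintf("%.4f", x$nhat)
              else "undefined (SNR^2 >= 1)"))
  invisible(x)
}

#' Per-image speckle statistics of an ensemble
#'
#' Applies [snr_and_nhat()] to the squared pixel values (intensity) of
#' every image.
#'
#' @param e an [image_ensemble()] of envelope images (intensity is the
#'   elementwise square).
#' @return data frame with columns `image`, `snr`, `snr2`, `nhat`.
#' @export
speckle_stats_table <- function(e) {
  stopifnot(inherits(e, "image_ensemble"))
  rows <- lapply(seq_along(e$images), function(i) {
    s <- snr_and_nhat(e$images[[i]]^2)
    data.frame(image = i, snr = s$snr, snr2 = s$snr2, nhat = s$nhat)
  })
  do.call(rbind, rows)
}

#' Least-squares Gaussian fit to an empirical PDF
#'
#' Bins the samples into a density-normalized histogram and fits a
#' Gaussian density `dnorm(x, mu, sigma)` to the bin densities by least
#' squares (Nelder-Mead on `(mu, log sigma)`, initialized at the sample
#' mean and standard deviation).  The fit is to the binned empirical
#' PDF, not to the raw samples.
#'
#' @param samples numeric vector (>= 30 values).
#' @param bins histogram bin count.
#' @return object of class `gaussian_pdf_fit`: list with `mu`, `sigma`,
#'   `mse` (mean squared error between the empirical densities and the
#'   fitted curve), plus the underlying `pdf`.
#' @export
fit_gaussian_pdf <- function(samples, bins = 64L) {
  samples <- samples[is.finite(samples)]
  if (length(samples) < 30L) stop("need at least 30 samples")
  if (stats::sd(samples) == 0) stop("degenerate (constant) sample")
  pdf <- empirical_pdf(samples, bins = bins)
  mid <- (pdf$breaks[-1L] + pdf$breaks[-length(pdf$breaks)]) / 2
  dens <- pdf$density
  obj <- function(par) {
    mean((dens - stats::dnorm(mid, par[1L], exp(par[2L])))^2)
  }
  start <- c(mean(samples), log(stats::sd(samples)))
  opt <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  structure(list(mu = opt$par[1L], sigma = exp(opt$par[2L]),
                 mse = opt$value, pdf = pdf),
            class = "gaussian_pdf_fit")
}

#' @export
print.gaussian_pdf_fit <- function(x, ...) {
  cat(sprintf("<gaussian_pdf_fit> mu = %.4f, sigma = %.4f, MSE = %.4g\n",
              x$mu, x$sigma, x$mse))
  invisible(x)
}

#' @export
coef.gaussian_pdf_fit <- function(object, ...) {
  c(mu = object$mu, sigma = object$sigma)
}

#' @export
plot.gaussian_pdf_fit <- function(x, ...) {
  plot(x$pdf, ...)
  mid <- (x$pdf$breaks[-1L] +
            x$pdf$breaks[-length(x$pdf$breaks)]) / 2
  graphics::lines(mid, stats::dnorm(mid, x$mu, x$sigma), col = 2)
  invisible(x)
}

#' Joint PDF over the first two principal texture components
#'
#' Standardizes every feature using the pooled mean and standard
#' deviation over both tables (so the comparison is symmetric and
#' invariant to affine rescaling of any feature), computes the principal
#' axes of the pooled standardized data, projects both tables onto the
#' first two components, and bins both projections on a shared 2-D grid.
#'
#' @param features_ref,features_cand feature tables from
#'   [texture_feature_table()] (or any data frames sharing the same 17
#'   feature columns).
#' @param bins per-axis bin count of the shared 2-D grid.
#' @return object of class `pca_feature_pdf`: list with `pdf_ref` and
#'   `pdf_cand` (2-D probability mass matrices on the shared grid),
#'   `js` (their 2-D Jensen-Shannon divergence), `explained_variance`
#'   of the first two components, and the axis `breaks`.
#' @export
pca_feature_pdf <- function(features_ref, features_cand, bins = 64L) {
  cols <- intersect(texture_feature_names(), colnames(features_ref))
  if (length(cols) < 2L) stop("feature tables lack the texture columns")
  if (!all(cols %in% colnames(features_cand))) {
    stop("candidate table misses feature columns present in the reference")
  }
  A <- as.matrix(features_ref[, cols])
  B <- as.matrix(features_cand[, cols])
  keep <- stats::complete.cases(A)
  A <- A[keep, , drop = FALSE]
  keep <- stats::complete.cases(B)
  B <- B[keep, , drop = FALSE]
  pooled <- rbind(A, B)
  if (nrow(pooled) < length(cols)) {
    stop("fewer pooled rows than features: PCA underdetermined")
  }
  # symmetric standardization: centre on the midpoint of the two table
  # means and scale by the root-mean within-table variance, so that a
  # between-ensemble displacement of a feature is not absorbed into its
  # scale and remains visible to the principal axes
  mu <- (colMeans(A) + colMeans(B)) / 2
  sig <- sqrt((apply(A, 2L, stats::var) + apply(B, 2L, stats::var)) / 2)
  use <- sig > 0
  Z <- sweep(sweep(pooled[, use, drop = FALSE], 2L, mu[use]), 2L,
             sig[use], "/")
  pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  proj <- Z %*% pc$rotation[, 1:2]
  pa <- proj[seq_len(nrow(A)), , drop = FALSE]
  pb <- proj[nrow(A) + seq_len(nrow(B)), , drop = FALSE]
  bx <- seq(min(proj[, 1L]), max(proj[, 1L]), length.out = bins + 1L)
  by <- seq(min(proj[, 2L]), max(proj[, 2L]), length.out = bins + 1L)
  h2 <- function(p) {
    i <- findInterval(p[, 1L], bx, rightmost.closed = TRUE)
    j <- findInterval(p[, 2L], by, rightmost.closed = TRUE)
    i[i < 1L] <- 1L; i[i > bins] <- bins
    j[j < 1L] <- 1L; j[j > bins] <- bins
    matrix(tabulate((j - 1L) * bins + i, bins * bins), bins,
           bins) / nrow(p)
  }
  Hp <- h2(pa); Hq <- h2(pb)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(pdf_ref = Hp, pdf_cand = Hq,
                 js = js_from_pmf(as.vector(Hp), as.vector(Hq)),
                 explained_variance = ev[1:2],
                 breaks = list(x = bx, y = by)),
            class = "pca_feature_pdf")
}

#' @export
print.pca_feature_pdf <- function(x, ...) {
  cat(sprintf("<pca_feature_pdf> 2-D JS = %.4f nats; explained variance = %.2f, %.2f\n",
              x$js, x$explained_variance[1L], x$explained_variance[2L]))
  invisible(x)
}
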