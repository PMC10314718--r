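#' B-mode ultrasound speckle physics configuration
#'
#' Parameterizes the speckle simulator: a random phasor sum of
#' unit-amplitude scatterers convolved with a complex point spread
#' function whose Gaussian envelope is set by the axial and lateral
#' resolutions, modulated axially by the carrier.
#'
#' @param wave_speed speed of sound, m/s.
#' @param carrier_frequency carrier frequency `fc`, Hz.
#' @param cycles_fwhm number of carrier cycles within the pulse FWHM,
#'   `Nc` (dimensionless).
#' @param f_number_y,f_number_z lateral f-numbers (focal distance over
#'   aperture) for the in-plane (y) and elevational (z) directions.
#' @param pixel_pitch pixel size, metres per pixel.
#' @param image_size pixels per side.
#' @param snd scatterer number density, scatterers per cubic millimetre
#'   (>= 0; zero is a valid degenerate case yielding an empty field).
#' @param propagation_axis image axis along which the wave propagates
#'   (`"x"` = rows).
#' @return an object of class `uss_physics`.
#' @examples
#' p <- uss_physics(snd = 1)
#' resolution_cell(p)
#' @export
uss_physics <- function(wave_speed = 1556, carrier_frequency = 3.5e6,
                        cycles_fwhm = 2, f_number_y = 2, f_number_z = 3,
                        pixel_pitch = 1e-4, image_size = 256L,
                        snd = 1, propagation_axis = "x") {
  num <- c(wave_speed = wave_speed, carrier_frequency = carrier_frequency,
           cycles_fwhm = cycles_fwhm, f_number_y = f_number_y,
           f_number_z = f_number_z, pixel_pitch = pixel_pitch,
           image_size = image_size)
  if (any(!is.finite(num)) || any(num <= 0)) {
    stop("all physical quantities must be strictly positive")
  }
  if (!is.finite(snd) || snd < 0) stop("'snd' must be >= 0")
  if (!identical(propagation_axis, "x")) {
    stop("only propagation along the x (row) axis is supported")
  }
  structure(list(wave_speed = wave_speed,
                 carrier_frequency = carrier_frequency,
                 cycles_fwhm = cycles_fwhm,
                 f_number_y = f_number_y, f_number_z = f_number_z,
                 pixel_pitch = pixel_pitch,
                 image_size = as.integer(image_size),
                 snd = snd, propagation_axis = propagation_axis),
            class = "uss_physics")
}

#' @export
print.uss_physics <- function(x, ...) {
  cat(sprintf("<uss_physics> v=%g m/s, fc=%g MHz, Nc=%g, f#=(%g,%g), pitch=%g um, %dx%d, SND=%g /mm^3\n",
              x$wave_speed, x$carrier_frequency / 1e6, x$cycles_fwhm,
              x$f_number_y, x$f_number_z, x$pixel_pitch * 1e6,
              x$image_size, x$image_size, x$snd))
  invisible(x)
}

#' Resolution-cell geometry of a speckle configuration
#'
#' Computes the wavelength `lambda = v / fc`, the axial resolution
#' `AR = Nc * lambda / 2` (pulse-echo), the lateral resolutions
#' `LR = lambda * f-number` in each lateral direction, the resolution
#' cell volume `AR * LR_y * LR_z`, and the expected number of scatterers
#' per resolution cell `N = snd * cell_volume`.  All lengths are in
#' millimetres.
#'
#' @param p a [uss_physics()].
#' @return an object of class `cell_geometry` with fields
#'   `wavelength`, `axial_resolution`, `lateral_resolution_y`,
#'   `lateral_resolution_z` (mm), `cell_volume` (mm^3) and
#'   `expected_scatterers_per_cell`.
#' @export
resolution_cell <- function(p) {
  stopifnot(inherits(p, "uss_physics"))
  lam <- p$wave_speed / p$carrier_frequency * 1e3      # mm
  ar <- p$cycles_fwhm * lam / 2
  lry <- lam * p$f_number_y
  lrz <- lam * p$f_number_z
  vol <- ar * lry * lrz
  structure(list(wavelength = lam, axial_resolution = ar,
                 lateral_resolution_y = lry, lateral_resolution_z = lrz,
                 cell_volume = vol,
                 expected_scatterers_per_cell = p$snd * vol),
            class = "cell_geometry")
}

#' @export
print.cell_geometry <- function(x, ...) {
  cat(sprintf("<cell_geometry> lambda=%.4f mm, AR=%.4f, LRy=%.4f, LRz=%.4f mm; cell=%.4f mm^3; N=%.4f\n",
              x$wavelength, x$axial_resolution, x$lateral_resolution_y,
              x$lateral_resolution_z, x$cell_volume,
              x$expected_scatterers_per_cell))
  invisible(x)
}

#' PSF envelope standard deviations and scatterer areal density
#'
#' The mapping from the resolution-cell geometry to the 2-D Gaussian PSF
#' standard deviations, isolated here so the convention can be swapped.
#' The default, `"cell-matched"`, sets `sigma_x = AR / sqrt(2*pi)` and
#' `sigma_y = LR_y / sqrt(2*pi)`, which makes the coherence-cell area of
#' the PSF (`2*pi*sigma_x*sigma_y`) equal the resolution-cell area
#' `AR * LR_y`.  Together with the elevational collapse of the scatterer
#' density (areal density `rho = snd * LR_z`), the effective number of
#' scatterers governing the speckle statistics equals
#' `N = snd * cell_volume` exactly, so the per-image estimate from
#' [snr_and_nhat()] is a calibrated estimator of `N`.  The alternative
#' `"fwhm"` convention reads AR/LR as the full width at half maximum of
#' the PSF envelope (`sigma = AR / 2.3548`).
#'
#' @param cell a `cell_geometry` from [resolution_cell()].
#' @param convention `"cell-matched"` (default) or `"fwhm"`.
#' @return list with `sigma_x_mm`, `sigma_y_mm` (PSF envelope standard
#'   deviations, mm) and `rho_area` multiplier such that the areal
#'   scatterer density is `snd * rho_area` per mm^2.
#' @export
speckle_psf_geometry <- function(cell, convention = c("cell-matched", "fwhm")) {
  convention <- match.arg(convention)
  if (convention == "cell-matched") {
    list(sigma_x_mm = cell$axial_resolution / sqrt(2 * pi),
         sigma_y_mm = cell$lateral_resolution_y / sqrt(2 * pi),
         rho_area = cell$lateral_resolution_z)
  } else {
    list(sigma_x_mm = cell$axial_resolution / (2 * sqrt(2 * log(2))),
         sigma_y_mm = cell$lateral_resolution_y / (2 * sqrt(2 * log(2))),
         rho_area = cell$lateral_resolution_z)
  }
}

# complex PSF spectrum on the wrapped image grid (rows = axial)
uss_psf_fft <- function(p, convention = "cell-matched") {
  cell <- resolution_cell(p)
  geo <- speckle_psf_geometry(cell, convention)
  n <- p$image_size
  pitch_mm <- p$pixel_pitch * 1e3
  d <- (((0:(n - 1)) + n %/% 2) %% n) - n %/% 2       # signed wrapped offsets
  x <- matrix(d * pitch_mm, n, n)                     # axial (rows)
  y <- t(x)
  env <- exp(-x^2 / (2 * geo$sigma_x_mm^2) - y^2 / (2 * geo$sigma_y_mm^2))
  carrier <- exp(2i * pi * (2 / cell$wavelength) * x)  # two-way carrier
  stats::fft(env * carrier)
}

#' Sample one complex speckle field
#'
#' Scatterers are placed as a Poisson point process over the image plane
#' (areal density `snd * LR_z`, the elevational resolution collapsing the
#' third dimension), each with unit amplitude and an independent phase
#' uniform on `[0, 2*pi)`.  The scatterer map is convolved (spectrally,
#' with periodic wrap-around) with a complex PSF whose Gaussian envelope
#' is set by [speckle_psf_geometry()] and which is modulated axially by
#' the two-way carrier.
#'
#' @param p a [uss_physics()].
#' @param seed integer seed; required.
#' @param convention PSF convention, see [speckle_psf_geometry()].
#' @param psf_fft optional precomputed PSF spectrum (internal use, for
#'   ensemble generation).
#' @return complex `image_size x image_size` matrix with attribute
#'   `n_scatterers`.
#' @export
sample_speckle_field <- function(p, seed, convention = "cell-matched",
                                 psf_fft = NULL) {
  stopifnot(inherits(p, "uss_physics"))
  n <- p$image_size
  if (p$snd == 0) {
    message("snd = 0: returning an all-zero field")
    z <- matrix(complex(real = 0), n, n)
    attr(z, "n_scatterers") <- 0L
    return(z)
  }
  if (is.null(psf_fft)) psf_fft <- uss_psf_fft(p, convention)
  cell <- resolution_cell(p)
  geo <- speckle_psf_geometry(cell, convention)
  pitch_mm <- p$pixel_pitch * 1e3
  area_mm2 <- (n * pitch_mm)^2
  with_seed(seed, {
    ns <- stats::rpois(1L, p$snd * geo$rho_area * area_mm2)
    re <- numeric(n * n); im <- numeric(n * n)
    if (ns > 0) {
      idx <- sample.int(n * n, ns, replace = TRUE)
      ph <- stats::runif(ns, 0, 2 * pi)
      agg_r <- rowsum(cos(ph), idx)
      agg_i <- rowsum(sin(ph), idx)
      at <- as.integer(rownames(agg_r))
      re[at] <- agg_r; im[at] <- agg_i
    }
    m <- matrix(complex(real = re, imaginary = im), n, n)
    E <- stats::fft(stats::fft(m) * psf_fft, inverse = TRUE) / (n * n)
    attr(E, "n_scatterers") <- ns
    E
  })
}

#' Envelope and intensity of a complex field
#'
#' @param field complex matrix (for example from
#'   [sample_speckle_field()]).
#' @return list with `envelope` (modulus) and `intensity` (squared
#'   modulus), both nonnegative real matrices.
#' @export
envelope_intensity <- function(field) {
  if (!all(is.finite(Re(field))) || !all(is.finite(Im(field)))) {
    stop("field contains non-finite entries")
  }
  env <- Mod(field)
  list(envelope = env, intensity = env^2)
}

#' Generate an ultrasound speckle ensemble
#'
#' Returns `n` raw (pre-quantization) envelope images, each from an
#' independently seeded speckle field; per-image seeds derive from the
#' master seed.  Apply [quantize_ensemble_8bit()] to obtain the 8-bit
#' representation used for the pertinent per-image statistics.
#'
#' @param p a [uss_physics()].
#' @param n number of images (>= 1).
#' @param seed master seed.
#' @param convention PSF convention, see [speckle_psf_geometry()].
#' @return an [image_ensemble()] of raw envelopes.
#' @export
generate_uss_ensemble <- function(p, n, seed, convention = "cell-matched") {
  if (n < 1) stop("'n' must be >= 1")
  psfF <- uss_psf_fft(p, convention)
  imgs <- lapply(seq_len(n), function(i) {
    E <- sample_speckle_field(p, derive_stream_seed(seed, i),
                              convention = convention, psf_fft = psfF)
    Mod(E)
  })
  image_ensemble(imgs, pixel_pitch = p$pixel_pitch,
                 provenance = list(model = "uss", snd = p$snd, n = n,
                                   seed = seed, convention = convention),
                 validate = FALSE)
}

#' Convert an ensemble to unsigned 8-bit grayscale
#'
#' Maps pixel values linearly so that 255 corresponds to the 99th
#' percentile of all pixel values pooled over the ensemble (the "top 1%"
#' value, linear-interpolation percentile), rounding to integers and
#' saturating at 255.  The realized saturation fraction (approximately 1%
#' of pixels) is reported via `message()` and stored in the provenance.
#'
#' @param e an [image_ensemble()] of nonnegative images.
#' @return an [image_ensemble()] of integer-valued images in `[0, 255]`,
#'   with `quantized = TRUE`, the scale value `p99` and the saturation
#'   fraction recorded in the provenance.
#' @export
quantize_ensemble_8bit <- function(e) {
  stopifnot(inherits(e, "image_ensemble"))
  pool <- unlist(e$images, use.names = FALSE)
  if (min(pool) < 0) stop("quantization requires nonnegative images")
  p99 <- stats::quantile(pool, 0.99, names = FALSE)
  if (p99 <= 0 || stats::sd(pool) == 0) {
    stop("degenerate ensemble (constant or all-zero): 8-bit scale undefined")
  }
  sat <- mean(pool > p99)
  rm(pool)
  imgs <- lapply(e$images, function(m) {
    q <- round(255 * m / p99)
    q[q > 255] <- 255
    storage.mode(q) <- "integer"
    q
  })
  message(sprintf("8-bit conversion: p99 = %.4g, saturation fraction = %.4f",
                  p99, sat))
  image_ensemble(imgs, pixel_pitch = e$pixel_pitch,
                 provenance = c(e$provenance,
                                list(quantized = TRUE, p99 = p99,
                                     saturation_fraction = sat)),
                 validate = FALSE)
}
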