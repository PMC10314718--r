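#' Tissue labels of the stylized breast-slice model
#'
#' Integer codes for the ten tissue classes of a labelled breast slice.
#' @return named integer vector.
#' @export
s2v_labels <- function() {
  c(background = 0L, fat = 1L, glandular = 2L, skin = 3L, artery = 4L,
    vein = 5L, muscle = 6L, ligament = 7L, nipple = 8L, tdlu = 9L)
}

#' X-ray linear attenuation table
#'
#' Maps each tissue label to a linear attenuation coefficient (cm^-1) at
#' a stated photon energy.  The packaged default table
#' (`attenuation_30keV_default.csv`) holds editable default values at
#' 30 keV in the range reported for breast tissues in the standard
#' attenuation literature; the only property the package's statistics
#' rely on is that the fat and glandular coefficients are separated by
#' more than twice the thresholding tolerance, which is validated here.
#'
#' @param values named numeric vector (cm^-1) covering every label of
#'   [s2v_labels()]; `NULL` loads the packaged default table.
#' @param energy_keV photon energy the coefficients refer to.
#' @param tolerance relative thresholding tolerance used downstream by
#'   [fat_glandular_ratio()]; the fat/glandular separation is validated
#'   against `2 * tolerance`.
#' @return an object of class `attenuation_table`.
#' @export
attenuation_table <- function(values = NULL, energy_keV = 30,
                              tolerance = 0.015) {
  if (is.null(values)) {
    path <- system.file("extdata", "attenuation_30keV_default.csv",
                        package = "simeval")
    tab <- utils::read.table(path, header = TRUE, sep = ",",
                             stringsAsFactors = FALSE)
    values <- stats::setNames(tab$mu_cm1, tab$tissue)
    energy_keV <- tab$energy_keV[1L]
  }
  labs <- s2v_labels()
  missing <- setdiff(names(labs), names(values))
  if (length(missing)) {
    stop("attenuation table is missing labels: ",
         paste(missing, collapse = ", "))
  }
  if (any(values < 0)) stop("attenuation coefficients must be >= 0")
  sep <- abs(values[["fat"]] - values[["glandular"]])
  if (sep <= 2 * tolerance * max(values[["fat"]], values[["glandular"]])) {
    stop("fat and glandular coefficients are not separable at the ",
         "thresholding tolerance")
  }
  structure(list(values = values[names(labs)], energy_keV = energy_keV,
                 tolerance = tolerance),
            class = "attenuation_table")
}

#' @export
print.attenuation_table <- function(x, ...) {
  cat(sprintf("<attenuation_table> %g keV (cm^-1):\n", x$energy_keV))
  print(round(x$values, 4))
  invisible(x)
}

#' Assign attenuation coefficients to a label slice
#'
#' Pixelwise lookup of the attenuation coefficient for each tissue
#' label; the output image is in cm^-1.
#'
#' @param slice integer matrix of tissue labels (codes of
#'   [s2v_labels()]).
#' @param table an [attenuation_table()].
#' @return numeric matrix (cm^-1), same shape as `slice`.
#' @export
assign_attenuation <- function(slice, table) {
  stopifnot(inherits(table, "attenuation_table"))
  labs <- s2v_labels()
  u <- unique(as.vector(slice))
  unknown <- setdiff(u, unname(labs))
  if (length(unknown)) {
    stop("unknown tissue label(s): ", paste(unknown, collapse = ", "))
  }
  lut <- numeric(max(labs) + 1L)
  lut[labs + 1L] <- unname(table$values)
  out <- lut[slice + 1L]
  dim(out) <- dim(slice)
  out
}

#' Extract coronal slices from a labelled volume
#'
#' Selects coronal planes within a fractional depth range (measured from
#' the outermost plane), stepping by a fixed spacing, and downsamples
#' each selected slice to `out_size x out_size` by nearest-neighbour
#' (label-preserving) resampling.  The index rule is
#' `seq(ceiling(f1 * depth), floor(f2 * depth), by = spacing)`.
#'
#' @param volume 3-D integer array of labels; the third dimension indexes
#'   coronal planes from outermost to innermost.
#' @param inner_fraction_range fractional depth range, default
#'   `c(0.40, 0.70)`.
#' @param spacing minimum index spacing between consecutively extracted
#'   slices (pixels/planes), default 50.
#' @param out_size output side length, default 512.
#' @return list of integer label matrices (possibly empty, with a
#'   warning, when no plane falls in the range).
#' @export
extract_slices <- function(volume, inner_fraction_range = c(0.40, 0.70),
                           spacing = 50L, out_size = 512L) {
  if (length(dim(volume)) != 3L) stop("'volume' must be a 3-D array")
  depth <- dim(volume)[3L]
  if (depth < spacing) stop("volume depth must be >= spacing")
  lo <- ceiling(inner_fraction_range[1L] * depth)
  hi <- floor(inner_fraction_range[2L] * depth)
  if (lo > hi) {
    warning("no coronal plane falls inside the fractional range")
    return(list())
  }
  idx <- seq(lo, hi, by = spacing)
  lapply(idx, function(k) resample_labels(volume[, , k], out_size))
}

# nearest-neighbour label-preserving resampling to out x out
resample_labels <- function(m, out) {
  sr <- pmin(nrow(m), pmax(1L, round((seq_len(out) - 0.5) * nrow(m) / out + 0.5)))
  sc <- pmin(ncol(m), pmax(1L, round((seq_len(out) - 0.5) * ncol(m) / out + 0.5)))
  m[sr, sc, drop = FALSE]
}

#' Fat-to-glandular ratio of an attenuation image
#'
#' Counts pixels whose attenuation lies within a relative tolerance of
#' the fat coefficient (`F`) and of the glandular coefficient (`G`) and
#' returns the ratio `rho = F / G`.  The default tolerance is 1.5%
#' relative, matching the extent of the fat peak in the gray-level
#' histogram of labelled slices.
#'
#' @param img numeric matrix in cm^-1 (for example from
#'   [assign_attenuation()]).
#' @param table an [attenuation_table()].
#' @param tolerance relative tolerance; default taken from `table`.
#' @return object of class `ratio_stats`: list with `F`, `G`, `ratio`
#'   (`NA` and flagged when `G = 0`) and `log_ratio` (natural log).
#' @export
fat_glandular_ratio <- function(img, table, tolerance = NULL) {
  stopifnot(inherits(table, "attenuation_table"))
  if (is.null(tolerance)) tolerance <- table$tolerance
  fat <- table$values[["fat"]]
  gla <- table$values[["glandular"]]
  F_ <- sum(abs(img - fat) <= tolerance * fat)
  G_ <- sum(abs(img - gla) <= tolerance * gla)
  ratio <- if (G_ > 0) F_ / G_ else NA_real_
  structure(list(F = F_, G = G_, ratio = ratio,
                 log_ratio = if (is.na(ratio) || ratio == 0) NA_real_
                             else log(ratio),
                 undefined = G_ == 0),
            class = "ratio_stats")
}

#' @export
print.ratio_stats <- function(x, ...) {
  cat(sprintf("<ratio_stats> F=%d, G=%d, rho=%s\n", x$F, x$G,
              if (is.na(x$ratio)) "undefined (G=0)" else
                sprintf("%.4f (log %.4f)", x$ratio, x$log_ratio)))
  invisible(x)
}

#' Surrogate breast-phantom configuration
#'
#' Configuration of the package's own 2-D surrogate label-map generator.
#' It is a synthetic stand-in for an external 3-D anthropomorphic
#' phantom tool: it generates labelled coronal-slice-like maps directly,
#' with a controllable four-component mixture of target log
#' fat-to-glandular ratios mimicking the four clinical breast-density
#' types, so the ratio statistics are testable hermetically.  It makes
#' no claim to anatomical realism beyond a breast-interior mask, a skin
#' rim, blob-scale glandular/fat structure and optional thin vessels.
#'
#' @param image_size slice side in pixels.
#' @param skin_thickness skin rim thickness, pixels.
#' @param mode_prevalence prevalences of the four breast-type modes
#'   (fatty, scattered, heterogeneously dense, extremely dense); must
#'   sum to 1.
#' @param mode_log_ratio_mean,mode_log_ratio_sd per-mode mean and
#'   standard deviation of the target natural-log fat-to-glandular
#'   ratio.
#' @param blob_scale Gaussian correlation length (pixels) of the random
#'   field whose level set separates glandular from fat tissue.
#' @param ratio_tolerance maximum relative deviation of the realized
#'   from the target ratio.
#' @param n_vessels number of thin vessel structures (arteries/veins).
#' @return object of class `surrogate_phantom_config`.
#' @export
surrogate_phantom_config <- function(image_size = 512L, skin_thickness = 3L,
                                     mode_prevalence = c(0.10, 0.40, 0.40, 0.10),
                                     mode_log_ratio_mean = c(2.2, 1.1, 0.1, -1.0),
                                     mode_log_ratio_sd = rep(0.25, 4),
                                     blob_scale = NULL,
                                     ratio_tolerance = 0.05,
                                     n_vessels = 3L) {
  if (abs(sum(mode_prevalence) - 1) > 1e-8) {
    stop("'mode_prevalence' must sum to 1")
  }
  if (length(mode_log_ratio_mean) != length(mode_prevalence) ||
      length(mode_log_ratio_sd) != length(mode_prevalence)) {
    stop("mode parameter vectors must have equal length")
  }
  if (is.null(blob_scale)) blob_scale <- image_size / 64
  structure(list(image_size = as.integer(image_size),
                 skin_thickness = as.integer(skin_thickness),
                 mode_prevalence = mode_prevalence,
                 mode_log_ratio_mean = mode_log_ratio_mean,
                 mode_log_ratio_sd = mode_log_ratio_sd,
                 blob_scale = blob_scale,
                 ratio_tolerance = ratio_tolerance,
                 n_vessels = as.integer(n_vessels)),
            class = "surrogate_phantom_config")
}

# smooth Gaussian random field via spectral filtering
gaussian_random_field <- function(n, scale) {
  w <- matrix(stats::rnorm(n * n), n, n)
  d <- (((0:(n - 1)) + n %/% 2) %% n) - n %/% 2
  fx <- matrix(d / n, n, n); fy <- t(fx)
  H <- exp(-2 * pi^2 * scale^2 * (fx^2 + fy^2))
  Re(stats::fft(stats::fft(w) * H, inverse = TRUE)) / (n * n)
}

#' Sample one surrogate breast-slice label map
#'
#' Deterministic in the seed: draws a breast-type mode and a target log
#' fat-to-glandular ratio from the configured mixture, builds a
#' perturbed-ellipse interior mask with a skin rim, lays optional thin
#' vessels, and partitions the remaining interior into fat and glandular
#' tissue by thresholding a smooth random field at the empirical
#' quantile that realizes the target ratio (within
#' `ratio_tolerance`, enforced; an error is raised if the geometry
#' cannot accommodate the target).
#'
#' @param cfg a [surrogate_phantom_config()].
#' @param seed integer seed.
#' @return integer label matrix with attributes `mode` (drawn breast
#'   type, 1..4), `target_log_ratio` and `realized_log_ratio`.
#' @export
sample_surrogate_phantom_slice <- function(cfg, seed) {
  stopifnot(inherits(cfg, "surrogate_phantom_config"))
  labs <- s2v_labels()
  with_seed(seed, {
    n <- cfg$image_size
    mode <- sample.int(length(cfg$mode_prevalence), 1L,
                       prob = cfg$mode_prevalence)
    target_log <- stats::rnorm(1L, cfg$mode_log_ratio_mean[mode],
                               cfg$mode_log_ratio_sd[mode])
    target <- exp(target_log)

    # perturbed-ellipse interior mask
    cx <- (n + 1) / 2; cy <- (n + 1) / 2
    X <- matrix(seq_len(n), n, n) - cx
    Y <- t(matrix(seq_len(n), n, n)) - cy
    th <- atan2(Y, X)
    pert <- 1
    for (k in 2:5) {
      pert <- pert + stats::rnorm(1L, 0, 0.04) * cos(k * th +
                                                     stats::runif(1L, 0, 2 * pi))
    }
    ax <- 0.42 * n * stats::runif(1L, 0.9, 1.1)
    ay <- 0.42 * n * stats::runif(1L, 0.9, 1.1)
    r2 <- (X / ax)^2 + (Y / ay)^2
    mask <- r2 <= pert^2

    # skin rim: pixels of the mask eroded away by `skin_thickness` steps
    inner <- mask
    for (i in seq_len(cfg$skin_thickness)) inner <- erode4(inner)
    out <- matrix(labs[["background"]], n, n)
    out[mask & !inner] <- labs[["skin"]]

    # thin vessels as random walks across the interior
    vessel_mask <- matrix(FALSE, n, n)
    if (cfg$n_vessels > 0) {
      for (v in seq_len(cfg$n_vessels)) {
        pos <- c(round(cx + stats::runif(1, -0.2, 0.2) * n),
                 round(cy + stats::runif(1, -0.2, 0.2) * n))
        ang <- stats::runif(1, 0, 2 * pi)
        for (s in seq_len(n)) {
          ang <- ang + stats::rnorm(1, 0, 0.2)
          pos <- pos + c(cos(ang), sin(ang))
          ij <- round(pos)
          if (any(ij < 1) || any(ij > n) || !inner[ij[1], ij[2]]) break
          vessel_mask[ij[1], ij[2]] <- TRUE
        }
      }
    }
    vlab <- rep_len(c(labs[["artery"]], labs[["vein"]]),
                    max(cfg$n_vessels, 1L))

    # fat/glandular partition of the remaining interior
    tissue <- inner & !vessel_mask
    nt <- sum(tissue)
    if (nt < 10L) stop("interior too small for the requested geometry")
    f_frac <- target / (1 + target)
    n_fat <- round(f_frac * nt)
    if (n_fat == 0L || n_fat == nt) {
      stop("target fat-to-glandular ratio infeasible for this geometry")
    }
    field <- gaussian_random_field(n, cfg$blob_scale)[tissue]
    thr <- sort(field, partial = nt - n_fat)[nt - n_fat]
    lab_t <- ifelse(field > thr, labs[["fat"]], labs[["glandular"]])
    out[tissue] <- lab_t
    if (cfg$n_vessels > 0 && any(vessel_mask)) {
      # alternate artery/vein labels over the vessels drawn
      vi <- which(vessel_mask)
      out[vi] <- vlab[(seq_along(vi) %% length(vlab)) + 1L]
    }

    realized <- sum(out == labs[["fat"]]) / sum(out == labs[["glandular"]])
    if (abs(realized / target - 1) > cfg$ratio_tolerance) {
      stop(sprintf("realized ratio %.3f misses target %.3f beyond tolerance",
                   realized, target))
    }
    attr(out, "mode") <- mode
    attr(out, "target_log_ratio") <- target_log
    attr(out, "realized_log_ratio") <- log(realized)
    out
  })
}

# 4-neighbour binary erosion
erode4 <- function(m) {
  n <- nrow(m); p <- ncol(m)
  up <- rbind(m[-1, , drop = FALSE], FALSE)
  dn <- rbind(FALSE, m[-n, , drop = FALSE])
  lf <- cbind(m[, -1, drop = FALSE], FALSE)
  rt <- cbind(FALSE, m[, -p, drop = FALSE])
  m & up & dn & lf & rt
}

#' Generate an ensemble of surrogate attenuation slices
#'
#' Samples `n` surrogate label maps (per-image seeds derived from the
#' master seed) and converts each to an attenuation image via
#' [assign_attenuation()].
#'
#' @param cfg a [surrogate_phantom_config()].
#' @param table an [attenuation_table()].
#' @param n number of slices.
#' @param seed master seed.
#' @return an [image_ensemble()] of attenuation images (cm^-1); the
#'   drawn modes are recorded in the provenance.
#' @export
generate_s2v_ensemble <- function(cfg, table, n, seed) {
  if (n < 1) stop("'n' must be >= 1")
  modes <- integer(n)
  imgs <- vector("list", n)
  for (i in seq_len(n)) {
    sl <- sample_surrogate_phantom_slice(cfg, derive_stream_seed(seed, i))
    modes[i] <- attr(sl, "mode")
    imgs[[i]] <- assign_attenuation(sl, table)
  }
  image_ensemble(imgs, pixel_pitch = NA_real_,
                 provenance = list(model = "s2v", n = n, seed = seed,
                                   modes = modes),
                 validate = FALSE)
}

#' Write a label map with its legend
#'
#' Label maps are stored as 8-bit PNG (label codes as pixel values) with
#' a sidecar text legend mapping codes to tissue names.
#'
#' @param slice integer label matrix.
#' @param path output PNG path; the legend is written next to it as
#'   `<path>.legend.txt`.
#' @return `path`, invisibly.
#' @export
write_label_slice <- function(slice, path) {
  png::writePNG(slice / 255, path)
  labs <- s2v_labels()
  writeLines(paste(unname(labs), names(labs), sep = "\t"),
             paste0(path, ".legend.txt"))
  invisible(path)
}
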