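#' Parameters of one clustered lumpy background layer
#'
#' The clustered lumpy background (CLB) model builds mammography-like
#' texture as a two-level Poisson process: cluster centres are uniform
#' over an extended field, each cluster receives a Poisson number of
#' blobs placed with Gaussian offsets about its centre, and every blob
#' contributes an exponential-of-power radial profile
#' `exp(-alpha * ((u/Lx)^2 + (v/Ly)^2)^(beta/2))` in its own (possibly
#' rotated) coordinates.
#'
#' @param mean_cluster_count expected number of clusters per image area
#'   (dimensionless; the simulator extends the field beyond the image
#'   border at the same density so edge statistics are stationary).
#' @param mean_blobs_per_cluster expected blobs per cluster.
#' @param cluster_spread standard deviation (pixels) of blob offsets
#'   about the cluster centre.
#' @param blob_length_x,blob_length_y characteristic blob half-lengths
#'   `Lx`, `Ly` in pixels.
#' @param blob_alpha radial decay coefficient `alpha`.
#' @param blob_beta radial decay exponent `beta`.
#' @param orientation_mode `"isotropic"` (each blob's orientation drawn
#'   independently, uniform over the angle grid) or `"oriented"` (one
#'   preferred direction per cluster plus Gaussian angular jitter).
#' @param orientation_jitter standard deviation (radians) of the
#'   per-blob angular jitter about the cluster direction; used only in
#'   `"oriented"` mode.
#' @param n_orientations size of the discrete orientation grid over
#'   `[0, pi)`.  Blob profiles are splatted from precomputed kernels,
#'   one per grid angle; drawn angles are snapped to the nearest grid
#'   angle.
#' @return an object of class `clb_layer_params`.
#' @export
clb_layer_params <- function(mean_cluster_count, mean_blobs_per_cluster,
                             cluster_spread, blob_length_x, blob_length_y,
                             blob_alpha, blob_beta,
                             orientation_mode = c("isotropic", "oriented"),
                             orientation_jitter = 0.2,
                             n_orientations = 16L) {
  orientation_mode <- match.arg(orientation_mode)
  num <- c(mean_blobs_per_cluster = mean_blobs_per_cluster,
           cluster_spread = cluster_spread,
           blob_length_x = blob_length_x, blob_length_y = blob_length_y,
           blob_alpha = blob_alpha, blob_beta = blob_beta)
  if (any(!is.finite(num)) || any(num <= 0)) {
    stop("all CLB scale/shape parameters must be strictly positive")
  }
  if (!is.finite(mean_cluster_count) || mean_cluster_count < 0) {
    stop("'mean_cluster_count' must be nonnegative")
  }
  if (orientation_jitter < 0) stop("'orientation_jitter' must be >= 0")
  structure(list(mean_cluster_count = mean_cluster_count,
                 mean_blobs_per_cluster = mean_blobs_per_cluster,
                 cluster_spread = cluster_spread,
                 blob_length_x = blob_length_x,
                 blob_length_y = blob_length_y,
                 blob_alpha = blob_alpha, blob_beta = blob_beta,
                 orientation_mode = orientation_mode,
                 orientation_jitter = orientation_jitter,
                 n_orientations = as.integer(n_orientations)),
            class = "clb_layer_params")
}

#' CLB model configuration
#'
#' A full parameterization of the clustered lumpy background simulator:
#' one or two layers, the image size, and the monotone gray mapping
#' `g = clip(offset + scale * raw, clip[1], clip[2])` applied to the raw
#' (summed) texture.  Five named configurations ship with the package as
#' editable config files: `opex99` (the original single-layer
#' parameterization), `simpiso`/`simpori` (single layer, isotropic /
#' oriented clusters) and `doubiso`/`doubori` (double layer, isotropic /
#' oriented).  Their numeric defaults are documented placeholders -- the
#' historical parameter tables are not part of this package -- and can be
#' edited freely; all package invariants hold for any valid setting.
#'
#' @param name configuration name.  If `layers` is `NULL` the
#'   configuration is loaded from the packaged config file of that name.
#' @param layers list of one or two [clb_layer_params()].
#' @param image_size pixels per side.
#' @param gray_offset,gray_scale,gray_clip gray mapping parameters.
#' @return an object of class `clb_config`.
#' @examples
#' cfg <- clb_config("doubiso")
#' img <- sample_clb_image(cfg, seed = 1)
#' @export
clb_config <- function(name = "custom", layers = NULL, image_size = 256L,
                       gray_offset = 0, gray_scale = 1,
                       gray_clip = c(0, 255)) {
  if (is.null(layers)) {
    path <- system.file("extdata", paste0("clb_", name, ".cfg"),
                        package = "simeval")
    if (!nzchar(path)) {
      stop("unknown CLB configuration '", name,
           "'; packaged: opex99, simpiso, simpori, doubiso, doubori")
    }
    return(read_clb_config(path))
  }
  if (!length(layers) %in% 1:2) {
    stop("CLB configurations have exactly one or two layers")
  }
  if (!all(vapply(layers, inherits, logical(1), "clb_layer_params"))) {
    stop("'layers' must be clb_layer_params objects")
  }
  if (image_size < 8) stop("'image_size' must be >= 8")
  if (length(gray_clip) != 2L || diff(gray_clip) <= 0) {
    stop("'gray_clip' must be an increasing pair")
  }
  structure(list(name = name, layers = layers,
                 image_size = as.integer(image_size),
                 gray_offset = gray_offset, gray_scale = gray_scale,
                 gray_clip = gray_clip),
            class = "clb_config")
}

#' @export
print.clb_config <- function(x, ...) {
  cat(sprintf("<clb_config> '%s': %d layer(s), %dx%d, gray %g + %g*raw clip [%g, %g]\n",
              x$name, length(x$layers), x$image_size, x$image_size,
              x$gray_offset, x$gray_scale, x$gray_clip[1], x$gray_clip[2]))
  for (i in seq_along(x$layers)) {
    l <- x$layers[[i]]
    cat(sprintf("  layer %d: K=%g, N=%g, spread=%g, L=(%g,%g), alpha=%g, beta=%g, %s\n",
                i, l$mean_cluster_count, l$mean_blobs_per_cluster,
                l$cluster_spread, l$blob_length_x, l$blob_length_y,
                l$blob_alpha, l$blob_beta, l$orientation_mode))
  }
  invisible(x)
}

#' Read / write a CLB configuration file
#'
#' Flat `key=value` text format with `layerN.` prefixes for per-layer
#' parameters; see the packaged files under `inst/extdata` for examples.
#'
#' @param path file path.
#' @return `read_clb_config()` returns a [clb_config()];
#'   `write_clb_config()` returns `path` invisibly.
#' @export
read_clb_config <- function(path) {
  kv <- read_flat_config(path)
  nlay <- as.integer(kv[["layers"]])
  layers <- lapply(seq_len(nlay), function(i) {
    p <- function(key, as = as.numeric) as(kv[[paste0("layer", i, ".", key)]])
    clb_layer_params(
      mean_cluster_count = p("mean_cluster_count"),
      mean_blobs_per_cluster = p("mean_blobs_per_cluster"),
      cluster_spread = p("cluster_spread"),
      blob_length_x = p("blob_length_x"),
      blob_length_y = p("blob_length_y"),
      blob_alpha = p("blob_alpha"),
      blob_beta = p("blob_beta"),
      orientation_mode = p("orientation_mode", identity),
      orientation_jitter = p("orientation_jitter"),
      n_orientations = p("n_orientations", as.integer))
  })
  clb_config(name = kv[["name"]], layers = layers,
             image_size = as.integer(kv[["image_size"]]),
             gray_offset = as.numeric(kv[["gray_offset"]]),
             gray_scale = as.numeric(kv[["gray_scale"]]),
             gray_clip = as.numeric(strsplit(kv[["gray_clip"]], ",")[[1]]))
}

#' @rdname read_clb_config
#' @param cfg a [clb_config()].
#' @export
write_clb_config <- function(cfg, path) {
  lines <- c(paste0("name=", cfg$name),
             paste0("image_size=", cfg$image_size),
             paste0("gray_offset=", cfg$gray_offset),
             paste0("gray_scale=", cfg$gray_scale),
             paste0("gray_clip=", paste(cfg$gray_clip, collapse = ",")),
             paste0("layers=", length(cfg$layers)))
  for (i in seq_along(cfg$layers)) {
    l <- cfg$layers[[i]]
    pre <- paste0("layer", i, ".")
    lines <- c(lines,
               paste0(pre, "mean_cluster_count=", l$mean_cluster_count),
               paste0(pre, "mean_blobs_per_cluster=", l$mean_blobs_per_cluster),
               paste0(pre, "cluster_spread=", l$cluster_spread),
               paste0(pre, "blob_length_x=", l$blob_length_x),
               paste0(pre, "blob_length_y=", l$blob_length_y),
               paste0(pre, "blob_alpha=", l$blob_alpha),
               paste0(pre, "blob_beta=", l$blob_beta),
               paste0(pre, "orientation_mode=", l$orientation_mode),
               paste0(pre, "orientation_jitter=", l$orientation_jitter),
               paste0(pre, "n_orientations=", l$n_orientations))
  }
  writeLines(lines, path)
  invisible(path)
}

read_flat_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), "")
  names(vals) <- vapply(kv, `[[`, "", 1L)
  as.list(trimws(vals))
}

# precompute one blob kernel per grid orientation; profiles truncated
# where the amplitude falls below `cut` of the peak
make_blob_kernels <- function(params, cut = 0.01) {
  Lx <- params$blob_length_x; Ly <- params$blob_length_y
  a <- params$blob_alpha; b <- params$blob_beta
  r_cut <- (log(1 / cut) / a)^(1 / b)
  half <- ceiling(r_cut * max(Lx, Ly))
  d <- seq(-half, half)
  DX <- matrix(d, length(d), length(d))           # row offset (image x)
  DY <- t(DX)
  lapply(seq_len(params$n_orientations), function(k) {
    th <- (k - 1) * pi / params$n_orientations
    u <- cos(th) * DX + sin(th) * DY
    v <- -sin(th) * DX + cos(th) * DY
    r <- sqrt((u / Lx)^2 + (v / Ly)^2)
    K <- exp(-a * r^b)
    K[r > r_cut] <- 0
    K
  })
}

# margin so that clusters whose blobs can reach the image are all sampled:
# blob kernel reach plus three cluster-spread standard deviations
clb_margin <- function(params, cut = 0.01) {
  r_cut <- (log(1 / cut) / params$blob_alpha)^(1 / params$blob_beta)
  ceiling(r_cut * max(params$blob_length_x, params$blob_length_y) +
            3 * params$cluster_spread)
}

#' Sample one raw CLB texture layer
#'
#' Draws the cluster process (Poisson count, uniform centres over a field
#' extended beyond the image border so that edge statistics are
#' stationary), the per-cluster blob process (Poisson count, Gaussian
#' offsets), and the per-blob orientations, then accumulates every blob's
#' truncated exponential-of-power profile.  The result is the raw,
#' pre-gray-mapping texture.
#'
#' @param params a [clb_layer_params()].
#' @param size image side in pixels (>= 8).
#' @param seed integer seed; required (all sampling is reproducible).
#' @return numeric `size x size` matrix with attributes `n_clusters` and
#'   `n_blobs` recording the realized process counts.
#' @export
sample_clb_layer <- function(params, size, seed) {
  stopifnot(inherits(params, "clb_layer_params"))
  if (size < 8) stop("'size' must be >= 8")
  with_seed(seed, {
    m <- clb_margin(params)
    fs <- size + 2L * m
    lambda <- params$mean_cluster_count * (fs / size)^2
    K <- stats::rpois(1L, lambda)
    nth <- params$n_orientations
    if (K == 0L) {
      out <- matrix(0, size, size)
      attr(out, "n_clusters") <- 0L
      attr(out, "n_blobs") <- 0L
      return(out)
    }
    cx <- stats::runif(K, 0.5, fs + 0.5)
    cy <- stats::runif(K, 0.5, fs + 0.5)
    nb <- stats::rpois(K, params$mean_blobs_per_cluster)
    tot <- sum(nb)
    if (tot == 0L) {
      out <- matrix(0, size, size)
    } else {
      ic <- rep.int(seq_len(K), nb)
      bx <- cx[ic] + stats::rnorm(tot, 0, params$cluster_spread)
      by <- cy[ic] + stats::rnorm(tot, 0, params$cluster_spread)
      if (params$orientation_mode == "isotropic") {
        kid <- sample.int(nth, tot, replace = TRUE)
      } else {
        th0 <- stats::runif(K, 0, pi)
        th <- th0[ic] + stats::rnorm(tot, 0, params$orientation_jitter)
        kid <- (round(th / (pi / nth)) %% nth) + 1L
      }
      kernels <- make_blob_kernels(params)
      field <- clb_splat(fs, fs, as.integer(round(bx)),
                         as.integer(round(by)), as.integer(kid), kernels)
      out <- field[(m + 1L):(m + size), (m + 1L):(m + size)]
    }
    attr(out, "n_clusters") <- K
    attr(out, "n_blobs") <- as.integer(tot)
    out
  })
}

# gray mapping shared by sample_clb_image and tests
clb_gray_map <- function(cfg, raw) {
  g <- cfg$gray_offset + cfg$gray_scale * raw
  pmin(pmax(g, cfg$gray_clip[1]), cfg$gray_clip[2])
}

#' Sample one CLB image
#'
#' Sums the configuration's independently seeded layers (per-layer seeds
#' derived from `seed` via [derive_stream_seed()]) and applies the gray
#' mapping with clipping.
#'
#' @param config a [clb_config()].
#' @param seed integer seed.
#' @param raw if `TRUE`, return the pre-gray-mapping layer sum.
#' @return numeric matrix; values lie within the configured clip range
#'   unless `raw = TRUE`.
#' @export
sample_clb_image <- function(config, seed, raw = FALSE) {
  stopifnot(inherits(config, "clb_config"))
  acc <- 0
  for (l in seq_along(config$layers)) {
    acc <- acc + sample_clb_layer(config$layers[[l]], config$image_size,
                                  derive_stream_seed(seed, l))
  }
  acc <- unclass(acc)
  attributes(acc) <- list(dim = dim(acc))
  if (raw) acc else clb_gray_map(config, acc)
}

#' Generate a CLB image ensemble
#'
#' @param config a [clb_config()].
#' @param n number of images (>= 1).
#' @param seed master seed; per-image seeds are
#'   `derive_stream_seed(seed, i)`.
#' @return an [image_ensemble()] with provenance.
#' @export
generate_clb_ensemble <- function(config, n, seed) {
  if (n < 1) stop("'n' must be >= 1")
  imgs <- lapply(seq_len(n), function(i) {
    sample_clb_image(config, derive_stream_seed(seed, i))
  })
  image_ensemble(imgs, pixel_pitch = NA_real_,
                 provenance = list(model = "clb", config = config$name,
                                   n = n, seed = seed),
                 validate = FALSE)
}
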