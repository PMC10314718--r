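#' Texture analysis configuration
#'
#' Parameters shared by the gray-level matrix builders.  The matrix
#' parameters (quantization levels, two-point distances and angles,
#' neighbourhood radius) are shipped as overridable defaults: 32 levels,
#' distance 1, the four principal angles, radius-1 neighbourhood.
#'
#' @param n_gray_levels number of quantization levels (>= 2).
#' @param glcm_distances integer pixel distances for co-occurrence
#'   pairs.
#' @param glcm_angles co-occurrence directions in degrees.
#' @param glrm_directions run directions in degrees (subset of
#'   0, 45, 90, 135).
#' @param ngtdm_radius neighbourhood window radius (window side
#'   `2 * radius + 1`).
#' @param epsilon small positive stabilizer for the NGTDM coarseness.
#' @return object of class `texture_config`.
#' @export
texture_config <- function(n_gray_levels = 32L, glcm_distances = 1L,
                           glcm_angles = c(0, 45, 90, 135),
                           glrm_directions = c(0, 45, 90, 135),
                           ngtdm_radius = 1L, epsilon = 1e-6) {
  if (n_gray_levels < 2) stop("'n_gray_levels' must be >= 2")
  if (!length(glcm_distances) || !length(glcm_angles) ||
      !length(glrm_directions)) {
    stop("direction/distance lists must be nonempty")
  }
  if (!all(glrm_directions %in% c(0, 45, 90, 135))) {
    stop("'glrm_directions' must be among 0, 45, 90, 135 degrees")
  }
  if (epsilon <= 0) stop("'epsilon' must be > 0")
  structure(list(n_gray_levels = as.integer(n_gray_levels),
                 glcm_distances = as.integer(glcm_distances),
                 glcm_angles = glcm_angles,
                 glrm_directions = glrm_directions,
                 ngtdm_radius = as.integer(ngtdm_radius),
                 epsilon = epsilon),
            class = "texture_config")
}

#' Quantize an image to discrete gray levels
#'
#' Uniform binning of the image's own value range into `n_levels` labels
#' `1..n_levels`; a constant image maps to a single label.
#'
#' @param img numeric matrix.
#' @param n_levels number of levels (>= 2).
#' @return integer matrix of labels in `1..n_levels`.
#' @export
quantize_gray_levels <- function(img, n_levels) {
  if (n_levels < 2) stop("'n_levels' must be >= 2")
  lo <- min(img); hi <- max(img)
  if (hi == lo) {
    q <- matrix(1L, nrow(img), ncol(img))
    return(q)
  }
  q <- floor((img - lo) / (hi - lo) * n_levels) + 1L
  q[q > n_levels] <- n_levels
  storage.mode(q) <- "integer"
  q
}

#' First-order statistics of an image
#'
#' Mean, standard deviation, skewness and kurtosis of the pixel
#' population (population moment convention, i.e. divisor `n`; kurtosis
#' is the raw fourth standardized moment, 3 for a Gaussian).  On a
#' constant image the standard deviation is 0 and skewness/kurtosis are
#' returned as flagged `NA`.
#'
#' @param img numeric matrix.
#' @return named numeric vector `(mean, std, skewness, kurtosis)`.
#' @export
first_order_features <- function(img) {
  v <- as.vector(img)
  m <- mean(v)
  m2 <- mean((v - m)^2)
  if (m2 == 0) {
    return(c(mean = m, std = 0, skewness = NA_real_, kurtosis = NA_real_))
  }
  s <- sqrt(m2)
  c(mean = m, std = s,
    skewness = mean((v - m)^3) / s^3,
    kurtosis = mean((v - m)^4) / m2^2)
}

# (dr, dc) offset for an angle in degrees at distance d; angle convention:
# 0 = along a row (to the right), 90 = up a column
angle_offset <- function(angle, d) {
  switch(as.character(angle %% 180),
         "0"   = c(0L, d),
         "45"  = c(-d, d),
         "90"  = c(-d, 0L),
         "135" = c(-d, -d),
         round(c(-d * sin(angle * pi / 180), d * cos(angle * pi / 180))))
}

#' Gray-level co-occurrence matrix
#'
#' Counts ordered pairs of labels at every configured
#' (distance, angle) offset, symmetrizes each matrix, normalizes it to
#' sum 1, and averages the normalized matrices over offsets (joint
#' aggregation across angles, making the downstream features invariant
#' to image rotation by multiples of the angle step).
#'
#' @param img_q integer label matrix from [quantize_gray_levels()].
#' @param cfg a [texture_config()].
#' @return `k x k` matrix summing to 1 (`k = n_gray_levels`).
#' @export
glcm <- function(img_q, cfg) {
  if (!length(cfg$glcm_distances) || !length(cfg$glcm_angles)) {
    stop("empty GLCM offset list")
  }
  k <- cfg$n_gray_levels
  acc <- matrix(0, k, k)
  n_off <- 0L
  for (d in cfg$glcm_distances) for (a in cfg$glcm_angles) {
    off <- angle_offset(a, d)
    P <- glcm_one_offset(img_q, off[1L], off[2L], k)
    if (sum(P) > 0) {
      acc <- acc + P / sum(P)
      n_off <- n_off + 1L
    }
  }
  if (n_off == 0L) stop("image too small for the configured offsets")
  acc / n_off
}

# symmetrized pair counts for one (dr, dc) offset
glcm_one_offset <- function(img_q, dr, dc, k) {
  nr <- nrow(img_q); nc <- ncol(img_q)
  r1 <- max(1L, 1L + dr):min(nr, nr + dr)
  c1 <- max(1L, 1L + dc):min(nc, nc + dc)
  if (length(r1) == 0L || length(c1) == 0L) return(matrix(0, k, k))
  a <- img_q[r1, c1, drop = FALSE]
  b <- img_q[r1 - dr, c1 - dc, drop = FALSE]
  idx <- (as.vector(b) - 1L) * k + as.vector(a)
  cnt <- tabulate(idx, k * k)
  P <- matrix(cnt, k, k)
  P + t(P)
}

#' Features of a normalized co-occurrence matrix
#'
#' Energy `sum(p^2)`, entropy `-sum(p log p)` (natural log, with
#' `0 log 0 = 0`), maximum probability, contrast
#' `sum((i - j)^2 p)` and homogeneity `sum(p / (1 + |i - j|))`.
#'
#' @param P normalized co-occurrence matrix (sums to 1).
#' @return named numeric vector of the five features.
#' @export
glcm_features <- function(P) {
  if (abs(sum(P) - 1) > 1e-8) stop("'P' must be normalized to sum 1")
  i <- row(P); j <- col(P)
  nz <- P[P > 0]
  c(glcm_energy = sum(P^2),
    glcm_entropy = -sum(nz * log(nz)),
    glcm_maximum = max(P),
    glcm_contrast = sum((i - j)^2 * P),
    glcm_homogeneity = sum(P / (1 + abs(i - j))))
}

#' Gray-level run-length (primitives) matrix
#'
#' Counts maximal runs of equal labels along each configured direction;
#' counts are pooled (summed) over directions.
#'
#' @param img_q integer label matrix.
#' @param cfg a [texture_config()].
#' @return list with `matrix` (`k x max_run_length` counts, gray level
#'   by run length) and `n_runs` (total run count).
#' @export
glrm <- function(img_q, cfg) {
  k <- cfg$n_gray_levels
  maxlen <- max(nrow(img_q), ncol(img_q))
  acc <- matrix(0, k, maxlen)
  for (a in cfg$glrm_directions) {
    seqs <- direction_sequences(img_q, a)
    r <- rle(seqs)
    keep <- !is.na(r$values)
    g <- r$values[keep]; l <- r$lengths[keep]
    idx <- (l - 1L) * k + g
    cnt <- tabulate(idx, k * maxlen)
    acc <- acc + matrix(cnt, k, maxlen)
  }
  list(matrix = acc, n_runs = sum(acc))
}

# serialize the image along a direction as one vector with NA separators
direction_sequences <- function(m, angle) {
  sep <- NA_integer_
  switch(as.character(angle %% 180),
         "0" = as.vector(t(cbind(m, sep))),
         "90" = as.vector(rbind(m, sep)),
         "45" = {
           v <- split(m, row(m) + col(m))
           # within an anti-diagonal, increasing col = decreasing row: the
           # split order along `row` ascending equals direction (-1, +1)
           unlist(lapply(v, function(x) c(rev(x), sep)), use.names = FALSE)
         },
         "135" = {
           v <- split(m, col(m) - row(m))
           unlist(lapply(v, function(x) c(x, sep)), use.names = FALSE)
         },
         stop("unsupported run direction"))
}

#' Run-length features
#'
#' Short primitive emphasis, long primitive emphasis, gray-level
#' uniformity and primitive-length uniformity (canonical run-length
#' definitions).
#'
#' @param r run-length matrix, or the list returned by [glrm()].
#' @param n_runs total run count (ignored when `r` is a [glrm()] list).
#' @return named numeric vector `(glrm_spe, glrm_lpe, glrm_glu,
#'   glrm_plu)`.
#' @export
glrm_features <- function(r, n_runs = NULL) {
  if (is.list(r)) { n_runs <- r$n_runs; r <- r$matrix }
  if (is.null(n_runs) || n_runs <= 0) stop("no runs (N_r = 0)")
  l <- col(r)
  c(glrm_spe = sum(r / l^2) / n_runs,
    glrm_lpe = sum(r * l^2) / n_runs,
    glrm_glu = sum(rowSums(r)^2) / n_runs,
    glrm_plu = sum(colSums(r)^2) / n_runs)
}

#' Neighbourhood gray tone difference matrix
#'
#' For each gray level `i` present among interior pixels, accumulates
#' `s_i`, the sum over interior pixels of level `i` of the absolute
#' difference between `i` and the mean of the surrounding window
#' (excluding the centre), and `p_i`, the fraction of interior pixels at
#' level `i`.  Interior pixels are those whose full window fits inside
#' the image.
#'
#' @param img_q integer label matrix.
#' @param cfg a [texture_config()].
#' @return list with `p` (occurrence probabilities, length
#'   `n_gray_levels`), `s` (difference sums), and `n_interior`.
#' @export
ngtdm <- function(img_q, cfg) {
  d <- cfg$ngtdm_radius
  nr <- nrow(img_q); nc <- ncol(img_q)
  if (nr < 2 * d + 1 || nc < 2 * d + 1) {
    stop("image smaller than the NGTDM window")
  }
  w <- 2L * d + 1L
  # windowed sum via cumulative sums
  S <- window_sum(img_q, d)
  ri <- (d + 1L):(nr - d); ci <- (d + 1L):(nc - d)
  centre <- img_q[ri, ci, drop = FALSE]
  nb_mean <- (S - centre) / (w * w - 1)
  diffs <- abs(centre - nb_mean)
  k <- cfg$n_gray_levels
  lev <- as.vector(centre)
  s <- vapply(seq_len(k), function(i) sum(diffs[centre == i]), 0)
  cnt <- tabulate(lev, k)
  n_int <- length(lev)
  list(p = cnt / n_int, s = s, n_interior = n_int)
}

# sum over (2d+1)^2 windows, returned for interior pixels only
window_sum <- function(m, d) {
  cs <- apply(m, 2L, cumsum)
  cs <- rbind(0, cs)
  rowband <- cs[(2L * d + 2L):nrow(cs), , drop = FALSE] -
    cs[1L:(nrow(cs) - 2L * d - 1L), , drop = FALSE]
  cs2 <- t(apply(rowband, 1L, cumsum))
  cs2 <- cbind(0, cs2)
  cs2[, (2L * d + 2L):ncol(cs2), drop = FALSE] -
    cs2[, 1L:(ncol(cs2) - 2L * d - 1L), drop = FALSE]
}

#' NGTDM features
#'
#' Coarseness, contrast, complexity and strength from the per-level
#' occurrence probabilities `p` and difference sums `s`, with `epsilon`
#' stabilizing the coarseness; a constant image yields contrast 0,
#' strength 0 and coarseness `1 / epsilon`.
#'
#' @param p occurrence probabilities (must sum to 1).
#' @param s difference sums, same length as `p`.
#' @param n_interior number of interior pixels.
#' @param epsilon stabilizer (see [texture_config()]).
#' @return named numeric vector `(ngtdm_coarseness, ngtdm_contrast,
#'   ngtdm_complexity, ngtdm_strength)`.
#' @export
ngtdm_features <- function(p, s, n_interior, epsilon = 1e-6) {
  if (abs(sum(p) - 1) > 1e-8) stop("'p' must sum to 1")
  present <- which(p > 0)
  np <- length(present)
  coarseness <- 1 / (epsilon + sum(p * s))
  if (np < 2) {
    return(c(ngtdm_coarseness = coarseness, ngtdm_contrast = 0,
             ngtdm_complexity = 0, ngtdm_strength = 0))
  }
  pi_ <- p[present]; si <- s[present]; gi <- present
  D2 <- outer(gi, gi, function(a, b) (a - b)^2)
  PP <- outer(pi_, pi_)
  contrast <- sum(PP * D2) / (np * (np - 1)) * sum(si) / n_interior
  AD <- abs(outer(gi, gi, "-"))
  PS <- outer(pi_ * si, pi_ * si, "+")
  SumP <- outer(pi_, pi_, "+")
  complexity <- sum(AD * PS / SumP) / n_interior
  strength <- sum(SumP * D2) / (epsilon + sum(si))
  c(ngtdm_coarseness = coarseness, ngtdm_contrast = contrast,
    ngtdm_complexity = complexity, ngtdm_strength = strength)
}

#' The 17-element texture feature vector of an image
#'
#' Composes the four first-order statistics, five co-occurrence
#' features, four run-length features and four neighbourhood gray tone
#' difference features into one named vector.  First-order statistics
#' are computed on the raw pixel values; the matrix families operate on
#' the quantized image.  Degenerate inputs yield flagged `NA` entries
#' (attribute `flags`), never silent zeros.
#'
#' @param img numeric matrix.
#' @param cfg a [texture_config()].
#' @return named numeric vector of length 17 with attribute `flags`
#'   naming any undefined entries.
#' @export
texture_feature_vector <- function(img, cfg = texture_config()) {
  fo <- first_order_features(img)
  q <- quantize_gray_levels(img, cfg$n_gray_levels)
  gf <- glcm_features(glcm(q, cfg))
  rf <- glrm_features(glrm(q, cfg))
  nt <- ngtdm(q, cfg)
  nf <- ngtdm_features(nt$p, nt$s, nt$n_interior, cfg$epsilon)
  v <- c(fo, gf, rf, nf)
  flags <- names(v)[is.na(v)]
  attr(v, "flags") <- flags
  v
}

#' Texture feature table of an ensemble
#'
#' @param e an [image_ensemble()].
#' @param cfg a [texture_config()].
#' @return data frame with an `image` identifier column and the 17
#'   feature columns, one row per image.
#' @export
texture_feature_table <- function(e, cfg = texture_config()) {
  stopifnot(inherits(e, "image_ensemble"))
  rows <- lapply(e$images, texture_feature_vector, cfg = cfg)
  tab <- as.data.frame(do.call(rbind, rows))
  cbind(image = seq_along(e$images), tab)
}

# the 17 canonical feature names, in table order
texture_feature_names <- function() {
  c("mean", "std", "skewness", "kurtosis",
    "glcm_energy", "glcm_entropy", "glcm_maximum", "glcm_contrast",
    "glcm_homogeneity",
    "glrm_spe", "glrm_lpe", "glrm_glu", "glrm_plu",
    "ngtdm_coarseness", "ngtdm_contrast", "ngtdm_complexity",
    "ngtdm_strength")
}
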