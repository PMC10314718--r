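# Brute-force oracles, written as plain loops independent of the package
# implementations they check.

oracle_moments <- function(v) {
  n <- length(v)
  m <- sum(v) / n
  m2 <- sum((v - m)^2) / n
  m3 <- sum((v - m)^3) / n
  m4 <- sum((v - m)^4) / n
  c(mean = m, std = sqrt(m2), skewness = m3 / m2^1.5, kurtosis = m4 / m2^2)
}

# symmetrized, offset-averaged co-occurrence matrix by pair enumeration
oracle_glcm <- function(q, k, angles = c(0, 45, 90, 135), dists = 1L) {
  offs <- list()
  for (d in dists) for (a in angles) {
    offs[[length(offs) + 1L]] <- switch(as.character(a),
      "0" = c(0, d), "45" = c(-d, d), "90" = c(-d, 0), "135" = c(-d, -d))
  }
  acc <- matrix(0, k, k)
  used <- 0L
  for (off in offs) {
    P <- matrix(0, k, k)
    for (r in seq_len(nrow(q))) for (c in seq_len(ncol(q))) {
      r2 <- r + off[1L]; c2 <- c + off[2L]
      if (r2 >= 1 && r2 <= nrow(q) && c2 >= 1 && c2 <= ncol(q)) {
        a <- q[r, c]; b <- q[r2, c2]
        P[a, b] <- P[a, b] + 1
        P[b, a] <- P[b, a] + 1
      }
    }
    if (sum(P) > 0) { acc <- acc + P / sum(P); used <- used + 1L }
  }
  acc / used
}

oracle_glcm_features <- function(P) {
  energy <- 0; entropy <- 0; mx <- 0; contrast <- 0; homo <- 0
  for (i in seq_len(nrow(P))) for (j in seq_len(ncol(P))) {
    p <- P[i, j]
    energy <- energy + p * p
    if (p > 0) entropy <- entropy - p * log(p)
    if (p > mx) mx <- p
    contrast <- contrast + (i - j)^2 * p
    homo <- homo + p / (1 + abs(i - j))
  }
  c(energy, entropy, mx, contrast, homo)
}

# run-length matrix by explicit line walking
oracle_glrm <- function(q, k, directions = c(0, 45, 90, 135)) {
  nr <- nrow(q); nc <- ncol(q)
  maxlen <- max(nr, nc)
  r <- matrix(0, k, maxlen)
  add_line <- function(vals) {
    i <- 1L
    while (i <= length(vals)) {
      j <- i
      while (j < length(vals) && vals[j + 1L] == vals[i]) j <- j + 1L
      len <- j - i + 1L
      r[vals[i], len] <<- r[vals[i], len] + 1
      i <- j + 1L
    }
  }
  for (a in directions) {
    if (a == 0) {
      for (i in seq_len(nr)) add_line(q[i, ])
    } else if (a == 90) {
      for (j in seq_len(nc)) add_line(q[, j])
    } else if (a == 45) {
      for (s in 2:(nr + nc)) {
        rs <- seq(min(nr, s - 1), max(1L, s - nc))   # decreasing row
        add_line(q[cbind(rs, s - rs)])
      }
    } else if (a == 135) {
      for (dd in (1 - nr):(nc - 1)) {
        rs <- seq(max(1L, 1 - dd), min(nr, nc - dd))
        add_line(q[cbind(rs, rs + dd)])
      }
    }
  }
  list(matrix = r, n_runs = sum(r))
}

oracle_glrm_features <- function(r, n_runs) {
  spe <- 0; lpe <- 0
  for (g in seq_len(nrow(r))) for (l in seq_len(ncol(r))) {
    spe <- spe + r[g, l] / l^2
    lpe <- lpe + r[g, l] * l^2
  }
  glu <- sum(sapply(seq_len(nrow(r)), function(g) sum(r[g, ])^2))
  plu <- sum(sapply(seq_len(ncol(r)), function(l) sum(r[, l])^2))
  c(spe, lpe, glu, plu) / n_runs
}

# NGTDM by sliding-window loops
oracle_ngtdm <- function(q, k, d = 1L) {
  nr <- nrow(q); nc <- ncol(q)
  s <- numeric(k); cnt <- numeric(k)
  for (r in (d + 1):(nr - d)) for (c in (d + 1):(nc - d)) {
    win <- q[(r - d):(r + d), (c - d):(c + d)]
    nb <- (sum(win) - q[r, c]) / (length(win) - 1)
    i <- q[r, c]
    s[i] <- s[i] + abs(i - nb)
    cnt[i] <- cnt[i] + 1
  }
  n_int <- sum(cnt)
  list(p = cnt / n_int, s = s, n_interior = n_int)
}

oracle_ngtdm_features <- function(p, s, n_int, eps = 1e-6) {
  k <- length(p)
  pres <- which(p > 0)
  coars <- 1 / (eps + sum(p * s))
  if (length(pres) < 2) return(c(coars, 0, 0, 0))
  con1 <- 0; comp <- 0; str1 <- 0
  for (i in pres) for (j in pres) {
    con1 <- con1 + p[i] * p[j] * (i - j)^2
    comp <- comp + abs(i - j) * (p[i] * s[i] + p[j] * s[j]) / (p[i] + p[j])
    str1 <- str1 + (p[i] + p[j]) * (i - j)^2
  }
  np <- length(pres)
  c(coars,
    con1 / (np * (np - 1)) * sum(s[pres]) / n_int,
    comp / n_int,
    str1 / (eps + sum(s[pres])))
}

# small random label image
random_label_image <- function(nr, nc, k) {
  matrix(sample.int(k, nr * nc, replace = TRUE), nr, nc)
}

# image vector with an exactly prescribed intensity SNR^2 (sample s.d.)
image_with_snr2 <- function(snr2, n = 64L) {
  z <- stats::rnorm(n * n)
  z <- (z - mean(z)) / stats::sd(z)       # mean 0, sample sd exactly 1
  matrix(sqrt(snr2) + z, n, n)            # mean sqrt(snr2), sd 1
}

# small fast CLB config for harness tests: same texture density as the
# packaged doubiso but on a smaller canvas
small_doubiso <- function(size = 128L) {
  cfg <- clb_config("doubiso")
  sc <- (size / cfg$image_size)^2
  layers <- lapply(cfg$layers, function(l) {
    l$mean_cluster_count <- l$mean_cluster_count * sc
    l
  })
  clb_config("doubiso-small", layers = layers, image_size = size,
             gray_offset = cfg$gray_offset, gray_scale = cfg$gray_scale,
             gray_clip = cfg$gray_clip)
}
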