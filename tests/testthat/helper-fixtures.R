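# Shared fixtures and independent brute-force oracles.

# Vertical step edge (columns 1..w/2 low, rest high) with optional
# multiplicative speckle; used for edge-preservation checks.
make_step_image <- function(seed = 1, size = 64L, lo = 0.2, hi = 0.7,
                            speckle = 0) {
  clean <- cbind(matrix(lo, size, size / 2), matrix(hi, size, size / 2))
  if (speckle > 0) {
    set.seed(seed)
    clean <- pmin(pmax(clean * matrix(pmax(rnorm(size * size, 1, speckle), 0),
                                      size, size), 0), 1)
  }
  clean
}

# Dense-loop normalized spatial-Gaussian convolution with mirror padding over
# the same square window the bilateral filter uses; independent of the
# package's shift-and-accumulate implementation.
brute_gaussian_window_mean <- function(u, sigma_c, radius) {
  n <- nrow(u); m <- ncol(u)
  out <- matrix(0, n, m)
  mirror <- function(i, lim) {
    if (i < 1) 2 - i else if (i > lim) 2 * lim - i else i
  }
  for (i in seq_len(n)) for (j in seq_len(m)) {
    num <- 0; den <- 0
    for (di in -radius:radius) for (dj in -radius:radius) {
      w <- exp(-(di^2 + dj^2) / (2 * sigma_c^2))
      v <- u[mirror(i + di, n), mirror(j + dj, m)]
      num <- num + w * v
      den <- den + w
    }
    out[i, j] <- num / den
  }
  out
}

# Dictionary-style confusion-count oracle, independent of confusion().
oracle_confusion <- function(true, pred, k = 5L) {
  tab <- new.env(parent = emptyenv())
  for (i in seq_along(true)) {
    key <- paste(true[i], pred[i])
    tab[[key]] <- (tab[[key]] %||% 0L) + 1L
  }
  cm <- matrix(0L, k, k)
  for (key in ls(tab)) {
    ij <- as.integer(strsplit(key, " ")[[1]])
    cm[ij[1] + 1L, ij[2] + 1L] <- tab[[key]]
  }
  cm
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force local-extrema scan used as the oracle for histogram mode
# detection (strict comparisons, no plateau handling needed by its callers)
oracle_extrema <- function(v) {
  idx <- which(diff(sign(diff(v))) != 0) + 1L
  maxima <- idx[v[idx] > v[idx - 1] & v[idx] > v[idx + 1]]
  minima <- idx[v[idx] < v[idx - 1] & v[idx] < v[idx + 1]]
  list(maxima = maxima, minima = minima)
}

# small network configuration for fast unit tests
tiny_net_config <- function(input_size = 16L, seed = 1L)
  net_config(input_size = input_size, block_channels = c(8L, 8L, 8L, 8L),
             reduction_ratio = 4L, spatial_kernel = 3L, seed = seed)
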