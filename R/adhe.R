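#' Gaussian smoothing of a 256-bin histogram
#'
#' Convolves raw 8-bit histogram counts with a normalized Gaussian kernel,
#' then locates the local extrema of the smoothed curve. The Gaussian is
#' applied along the intensity-bin axis; boundary columns are renormalized
#' (each source bin redistributes all of its mass inside the valid range) so
#' total mass is conserved exactly.
#'
#' @param hist numeric vector of 256 non-negative bin counts
#' @param sigma Gaussian standard deviation in bins (> 0); default 2 removes
#'   single-bin noise peaks without merging genuine modes
#' @return a `smoothed_histogram` list: `counts`, `sigma`, `maxima`, `minima`
#' @export
smooth_histogram <- function(hist, sigma = 2) {
  if (length(hist) != 256L) stop("smooth_histogram: expected 256 bins")
  if (any(hist < 0) || any(!is.finite(hist))) stop("smooth_histogram: counts must be finite and >= 0")
  if (!is.finite(sigma) || sigma <= 0) stop("smooth_histogram: sigma must be > 0")
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  n <- 256L
  sm <- numeric(n)
  # redistribute each source bin's mass with a truncated, renormalized kernel
  for (j in seq_len(n)) {
    if (hist[j] == 0) next
    lo <- max(1L, j - r); hi <- min(n, j + r)
    w <- k[(lo - j + r + 1L):(hi - j + r + 1L)]
    sm[lo:hi] <- sm[lo:hi] + hist[j] * w / sum(w)
  }
  ex <- find_extrema_counts(sm)
  structure(list(counts = sm, sigma = sigma,
                 maxima = ex$maxima, minima = ex$minima),
            class = "smoothed_histogram")
}

# Local extrema of a 1-D series with plateau runs resolved to their midpoint.
find_extrema_counts <- function(counts) {
  n <- length(counts)
  # compress equal-valued runs
  run_end <- c(which(diff(counts) != 0), n)
  run_start <- c(1L, head(run_end, -1L) + 1L)
  vals <- counts[run_start]
  m <- length(vals)
  maxima <- integer(0); minima <- integer(0)
  if (m >= 3) {
    for (i in 2:(m - 1)) {
      mid <- as.integer(floor((run_start[i] + run_end[i]) / 2))
      if (vals[i] > vals[i - 1] && vals[i] > vals[i + 1]) maxima <- c(maxima, mid)
      if (vals[i] < vals[i - 1] && vals[i] < vals[i + 1]) minima <- c(minima, mid)
    }
  }
  list(maxima = maxima, minima = minima)
}

#' Local extrema of a smoothed histogram
#'
#' Indices (1-based bins) where the smoothed counts exceed both neighbors
#' (maxima) or fall below both (minima); plateaus count once, at their
#' midpoint. Monotone histograms legitimately have no interior extrema.
#'
#' @param sh a `smoothed_histogram` from [smooth_histogram()]
#' @return list with `maxima` and `minima` integer vectors
#' @export
find_extrema <- function(sh) {
  stopifnot(inherits(sh, "smoothed_histogram"))
  find_extrema_counts(sh$counts)
}

#' Grouped median of binned data
#'
#' Classical grouped-median interpolation: with `L_m` the lower boundary of
#' the median class, `N` the total count, `F_{m-1}` the cumulative count
#' below the median class, `f_m` the median class frequency and `C` the
#' class width, the median is `L_m + ((N/2 - F_{m-1}) / f_m) * C`.
#'
#' @param counts per-class frequencies
#' @param lower lower boundary of each class
#' @param width common class width `C`
#' @return the interpolated median
#' @export
grouped_median <- function(counts, lower, width) {
  stopifnot(length(counts) == length(lower), all(counts >= 0))
  N <- sum(counts)
  if (N == 0) return(NA_real_)
  cum <- cumsum(counts)
  m <- which(cum >= N / 2)[1]
  Fm1 <- if (m == 1) 0 else cum[m - 1]
  lower[m] + ((N / 2 - Fm1) / counts[m]) * width
}

#' Partition the intensity axis at histogram modes
#'
#' Cuts the 8-bit intensity axis between consecutive local maxima of the
#' smoothed histogram: at the interior local minimum when one lies between
#' the two maxima, otherwise at their midpoint. Boundaries always include
#' the declared range endpoints. Each partition's representative intensity
#' is its grouped median (class width 1 intensity level).
#'
#' @param image an [intensity_image()] (unit range; quantized to 8 bits
#'   internally) or a numeric matrix in `[0, 1]`
#' @param extrema list with `maxima`/`minima` bin indices (1-based), e.g.
#'   from [find_extrema()]; an empty maxima set yields the degenerate single
#'   partition spanning the full range
#' @return a `partition_set` list: `boundaries` (intensity levels 0-255,
#'   first 0 and last 255), `medians` (per-partition grouped medians),
#'   `counts` (pixels per partition)
#' @export
partition_by_median <- function(image, extrema) {
  q <- quantize8(image)
  hist <- tabulate(q + 1L, nbins = 256L)
  maxima <- sort(extrema$maxima)
  minima <- sort(extrema$minima)
  cuts <- integer(0)
  if (length(maxima) >= 2) {
    for (i in seq_len(length(maxima) - 1L)) {
      lo <- maxima[i]; hi <- maxima[i + 1L]
      inner_min <- minima[minima > lo & minima < hi]
      cuts <- c(cuts, if (length(inner_min)) inner_min[1] else
        as.integer(floor((lo + hi) / 2)))
    }
  }
  boundaries <- unique(c(0L, sort(cuts) - 1L, 255L))  # intensity levels
  P <- length(boundaries) - 1L
  medians <- numeric(P); counts <- numeric(P)
  for (p in seq_len(P)) {
    lo <- boundaries[p] + (p > 1)  # partitions are [b_{p-1}+1, b_p] except the first
    hi <- boundaries[p + 1L]
    levs <- lo:hi
    cts <- hist[levs + 1L]
    counts[p] <- sum(cts)
    medians[p] <- if (counts[p] > 0) grouped_median(cts, levs - 0.5, 1) else NA_real_
  }
  structure(list(boundaries = boundaries, medians = medians, counts = counts),
            class = "partition_set")
}

# Quantize a unit-range image (or pass through an 8-bit one) to levels 0..255.
quantize8 <- function(image) {
  x <- img_pixels(image)
  rng <- if (inherits(image, "intensity_image")) img_range(image) else c(0, 1)
  if (rng[2] > 1.5) round(x) else floor(clip01(x) * 255 + 0.5)
}

#' Per-partition histogram equalization
#'
#' Applies classical histogram equalization independently inside each
#' intensity partition, remapping each partition onto its own contiguous
#' output sub-range. Output sub-range widths are allocated proportionally to
#' partition pixel counts (the "dynamic" range allocation), so dense
#' partitions receive more of the 8-bit axis. Pixel rank order is preserved
#' within every partition. Images whose partition holds a single distinct
#' intensity are passed through unchanged.
#'
#' @param image an [intensity_image()] or matrix in `[0, 1]`
#' @param parts a `partition_set` from [partition_by_median()]
#' @return equalized [intensity_image()] on the same `[0, 1]` range
#' @export
equalize_partitions <- function(image, parts) {
  stopifnot(inherits(parts, "partition_set"))
  q <- quantize8(image)
  hist <- tabulate(q + 1L, nbins = 256L)
  b <- parts$boundaries
  P <- length(b) - 1L
  n_total <- sum(hist)
  lut <- 0:255
  # allocate contiguous output sub-ranges proportional to pixel counts
  counts <- parts$counts
  if (n_total > 0 && sum(counts) > 0) {
    edges <- round(255 * cumsum(counts) / sum(counts))
    lo_out <- c(0, head(edges, -1L) + 1)
    hi_out <- edges
    for (p in seq_len(P)) {
      lo_in <- b[p] + (p > 1); hi_in <- b[p + 1L]
      levs <- lo_in:hi_in
      cts <- hist[levs + 1L]
      np <- sum(cts)
      if (np == 0) next
      if (sum(cts > 0) <= 1) { lut[levs + 1L] <- levs; next }  # degenerate
      cdf <- cumsum(cts) / np
      width <- max(hi_out[p] - lo_out[p], 0)
      lut[levs + 1L] <- round(lo_out[p] + width * cdf)
    }
    lut <- pmin(pmax(lut, 0), 255)  # rounding can push a tiny partition past the top
  }
  out <- matrix(lut[q + 1L], nrow(q), ncol(q)) / 255
  intensity_image(out, modality = img_modality(image))
}

#' Adaptive dynamic histogram equalization
#'
#' Full enhancement pass for CT/MRI-style images: smooth the histogram,
#' detect its modes, cut the intensity axis between consecutive modes,
#' equalize each partition within a count-proportional sub-range, and repeat
#' until the detected mode set is stable between iterations (the operational
#' reading of "no more clustered regions") or `max_iter` is reached.
#'
#' @param image an [intensity_image()] or matrix in `[0, 1]`
#' @param sigma histogram smoothing standard deviation in bins
#' @param max_iter iteration cap (default 5)
#' @return enhanced [intensity_image()]; attribute `"iterations"` records
#'   the number of passes performed
#' @export
adhe <- function(image, sigma = 2, max_iter = 5L) {
  cur <- intensity_image(clip01(img_pixels(image)), modality = img_modality(image))
  if (diff(range(img_pixels(cur))) == 0) {
    attr(cur, "iterations") <- 1L
    return(cur)
  }
  prev_maxima <- NULL
  iter <- 0L
  repeat {
    iter <- iter + 1L
    q <- quantize8(cur)
    hist <- tabulate(q + 1L, nbins = 256L)
    sh <- smooth_histogram(hist, sigma)
    if (!is.null(prev_maxima) && identical(prev_maxima, sh$maxima)) {
      iter <- iter - 1L
      break
    }
    parts <- partition_by_median(cur, find_extrema(sh))
    cur <- equalize_partitions(cur, parts)
    prev_maxima <- sh$maxima
    if (iter >= max_iter) break
  }
  attr(cur, "iterations") <- iter
  cur
}
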