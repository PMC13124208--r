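#' Phantom specification
#'
#' Describes one synthetic multimodal brain phantom: an elliptical "brain"
#' foreground on a dark background, a class-dependent cortical band signature
#' (none for the control class), a modality-dependent global intensity
#' profile, and a two-stage noise model (multiplicative speckle field of mean
#' 1, then additive Gaussian noise).
#'
#' @param class_label one of `"normal"`, `"ALS"`, `"PLS"`, `"PBP"`, `"PMA"`
#' @param modality one of `"MRI"`, `"CT"`, `"PET"`, `"DTI"`
#' @param size image side length in pixels (square image)
#' @param contrast scalar in `(0, 1]`; 1 keeps the full foreground/background
#'   separation, smaller values compress intensities towards mid-grey
#'   (the low-contrast regime the histogram equalizer is designed for)
#' @param speckle_sigma standard deviation of the multiplicative speckle
#'   field (mean 1); 0 disables speckle
#' @param additive_sigma standard deviation of additive Gaussian noise
#' @param seed integer RNG seed; identical specs give bit-identical images
#' @return an object of class `phantom_spec`
#' @export
phantom_spec <- function(class_label = "normal", modality = "MRI", size = 128L,
                         contrast = 1, speckle_sigma = 0, additive_sigma = 0,
                         seed = 1L) {
  class_label <- match.arg(class_label, MND_CLASSES)
  modality <- match.arg(modality, MND_MODALITIES)
  size <- as.integer(size)
  if (is.na(size) || size <= 0) stop("phantom_spec: size must be positive")
  if (!is.finite(contrast) || contrast <= 0 || contrast > 1)
    stop("phantom_spec: contrast must be in (0, 1]")
  if (speckle_sigma < 0 || additive_sigma < 0)
    stop("phantom_spec: noise standard deviations must be >= 0")
  structure(list(class_label = class_label, modality = modality, size = size,
                 contrast = contrast, speckle_sigma = speckle_sigma,
                 additive_sigma = additive_sigma, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Geometry of the class signature band in normalized [-1,1] coordinates.
# Each disease class perturbs a different cortical band, with its own
# intensity factor and texture, echoing the hypointense "motor band"
# appearance described for ALS imaging; the control class has no band.
phantom_band_geometry <- function(class_label) {
  switch(class_label,
    normal = NULL,
    ALS = list(y0 = -0.45, hw = 0.10, factor = 0.40, texture = "none"),
    PLS = list(y0 = -0.20, hw = 0.11, factor = 1.65, texture = "none"),
    PBP = list(y0 = 0.15, hw = 0.10, factor = 0.55, texture = "sine"),
    PMA = list(y0 = 0.40, hw = 0.11, factor = 1.55, texture = "dots")
  )
}

#' Signature-region mask of a phantom
#'
#' Logical mask of the pixels carrying the class-dependent band perturbation,
#' derived from the generator's own geometry parameters. Empty for the
#' control class.
#'
#' @param spec a [phantom_spec()]
#' @return logical matrix of the same size as the phantom
#' @export
phantom_signature_mask <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$size
  ax <- seq(-1, 1, length.out = n)
  xg <- matrix(ax, n, n, byrow = TRUE)
  yg <- matrix(ax, n, n)
  inside <- (xg / 0.78)^2 + (yg / 0.88)^2 <= 1
  g <- phantom_band_geometry(spec$class_label)
  if (is.null(g)) return(matrix(FALSE, n, n))
  inside & abs(yg - g$y0) <= 2.5 * g$hw
}

#' Generate one synthetic multimodal brain phantom
#'
#' Deterministic function of its spec: builds the noiseless anatomy
#' (ellipse, ventricles, modality profile, class band), applies the contrast
#' compression, then multiplies by a speckle field of mean 1 and standard
#' deviation `speckle_sigma` and adds Gaussian noise, clipping to `[0, 1]`.
#'
#' @param spec a [phantom_spec()]
#' @return an [intensity_image()] of `size x size` pixels in `[0, 1]`
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$size
  ax <- seq(-1, 1, length.out = n)
  xg <- matrix(ax, n, n, byrow = TRUE)
  yg <- matrix(ax, n, n)
  r2 <- (xg / 0.78)^2 + (yg / 0.88)^2
  inside <- r2 <= 1

  img <- with_seed(spec$seed, {
    base <- switch(spec$modality,
      MRI = 0.58 + 0.10 * (1 - r2),
      CT  = 0.72 + 0.00 * r2,
      PET = 0.52 + 0.08 * cos(pi * 1.5 * xg) * cos(pi * 1.5 * yg),
      DTI = 0.48 + 0.08 * xg
    )
    img <- matrix(0.05, n, n)
    img[inside] <- base[inside]
    # CT-like skull rim: thin bright ring just inside the ellipse boundary
    if (spec$modality == "CT") img[inside & r2 > 0.90] <- 0.95
    # ventricles: two small dark ellipses near the center (all classes)
    v1 <- ((xg + 0.16) / 0.10)^2 + (yg / 0.26)^2 <= 1
    v2 <- ((xg - 0.16) / 0.10)^2 + (yg / 0.26)^2 <= 1
    img[(v1 | v2) & inside] <- img[(v1 | v2) & inside] * 0.35

    g <- phantom_band_geometry(spec$class_label)
    if (!is.null(g)) {
      profile <- exp(-((yg - g$y0)^2) / (2 * g$hw^2))
      mult <- 1 + (g$factor - 1) * profile
      tex <- switch(g$texture,
        none = 0,
        sine = 0.10 * sin(2 * pi * 9 * xg) * profile,
        dots = {
          dots <- matrix(runif(n * n) > 0.75, n, n)
          0.16 * dots * profile
        })
      img[inside] <- img[inside] * mult[inside] + if (length(tex) > 1)
        tex[inside] else 0
    }
    img <- clip01(img)
    img <- 0.5 + spec$contrast * (img - 0.5)
    if (spec$speckle_sigma > 0) {
      field <- matrix(pmax(rnorm(n * n, mean = 1, sd = spec$speckle_sigma), 0), n, n)
      img <- img * field
    }
    if (spec$additive_sigma > 0)
      img <- img + matrix(rnorm(n * n, 0, spec$additive_sigma), n, n)
    clip01(img)
  })
  intensity_image(img, modality = spec$modality)
}

#' Generate a balanced labeled phantom dataset
#'
#' Produces `5 * n_per_class` phantoms (classes in the fixed order normal,
#' ALS, PLS, PBP, PMA), each with a per-image seed derived deterministically
#' from the master seed. Modalities are either fixed (that of `base_spec`)
#' or cycled MRI/CT/PET/DTI across images.
#'
#' @param n_per_class images per class (>= 1)
#' @param base_spec a [phantom_spec()] providing size, contrast and noise
#' @param seed master seed for the per-image seed stream
#' @param modality_mode `"cycle"` (default) or `"fixed"`
#' @return a list with `images` (list of [intensity_image()]), `labels`
#'   (integer class indices 0-4), and `manifest` (one data-frame row per
#'   image recording its full spec)
#' @export
make_dataset <- function(n_per_class, base_spec = phantom_spec(), seed = 1L,
                         modality_mode = c("cycle", "fixed")) {
  modality_mode <- match.arg(modality_mode)
  n_per_class <- as.integer(n_per_class)
  if (is.na(n_per_class) || n_per_class < 1) stop("make_dataset: n_per_class must be >= 1")
  total <- 5L * n_per_class
  images <- vector("list", total)
  labels <- integer(total)
  rows <- vector("list", total)
  idx <- 0L
  for (ci in seq_along(MND_CLASSES)) {
    for (k in seq_len(n_per_class)) {
      idx <- idx + 1L
      mod <- if (modality_mode == "cycle")
        MND_MODALITIES[(idx - 1L) %% 4L + 1L] else base_spec$modality
      sp <- phantom_spec(class_label = MND_CLASSES[ci], modality = mod,
                         size = base_spec$size, contrast = base_spec$contrast,
                         speckle_sigma = base_spec$speckle_sigma,
                         additive_sigma = base_spec$additive_sigma,
                         seed = derive_seed(seed, idx))
      images[[idx]] <- make_phantom(sp)
      labels[idx] <- ci - 1L
      rows[[idx]] <- data.frame(
        filename = sprintf("phantom_%03d_%s_%s.png", idx, sp$class_label, sp$modality),
        class_label = sp$class_label, class_index = ci - 1L, modality = mod,
        size = sp$size, contrast = sp$contrast,
        speckle_sigma = sp$speckle_sigma, additive_sigma = sp$additive_sigma,
        seed = sp$seed, stringsAsFactors = FALSE)
    }
  }
  list(images = images, labels = labels, manifest = do.call(rbind, rows))
}

#' Write a phantom dataset to disk
#'
#' Writes 8-bit grayscale PNGs plus a `manifest.csv` with per-image
#' provenance (filename, class, modality, seed, noise parameters).
#'
#' @param dataset result of [make_dataset()]
#' @param dir output directory (created if missing)
#' @return the manifest path, invisibly
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(dataset$images))
    write_image_png(dataset$images[[i]],
                    file.path(dir, dataset$manifest$filename[i]))
  mpath <- file.path(dir, "manifest.csv")
  write.csv(dataset$manifest, mpath, row.names = FALSE)
  invisible(mpath)
}

#' Synthetic feature table with known informative columns
#'
#' Builds a numeric table for exercising wrapper feature selection: exactly
#' `n_informative` randomly chosen columns carry class-dependent mean shifts
#' (class means spaced `gap` noise standard deviations apart, in a
#' per-column random class order); all remaining columns are pure standard
#' normal noise. The ground-truth informative index set is returned.
#'
#' @param n_samples number of rows (labels balanced over 5 classes)
#' @param n_features number of columns
#' @param n_informative number of informative columns, `1 <= n_informative <= n_features`
#' @param seed RNG seed
#' @param gap class-mean spacing in noise standard deviations (default 2)
#' @return a list with `x` (matrix), `labels` (0-4), `informative`
#'   (sorted column indices)
#' @export
make_feature_table <- function(n_samples, n_features, n_informative, seed = 1L,
                               gap = 2) {
  if (n_informative < 1 || n_informative > n_features)
    stop("make_feature_table: need 1 <= n_informative <= n_features")
  with_seed(seed, {
    labels <- sort(rep_len(0:4, n_samples))
    x <- matrix(rnorm(n_samples * n_features), n_samples, n_features)
    informative <- sort(sample.int(n_features, n_informative))
    for (j in informative) {
      class_means <- gap * sample(c(-2, -1, 0, 1, 2))
      x[, j] <- x[, j] + class_means[labels + 1L]
    }
    list(x = x, labels = labels, informative = informative)
  })
}
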