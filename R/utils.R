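#' @useDynLib mndpipe, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif rbinom sd median quantile
#' @importFrom utils write.csv read.csv head
NULL

# Class labels and modalities are closed sets used throughout the pipeline.
MND_CLASSES <- c("normal", "ALS", "PLS", "PBP", "PMA")
MND_MODALITIES <- c("MRI", "CT", "PET", "DTI")

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded generators are pure functions of their arguments.
#'
#' @param seed integer seed
#' @param code expression to evaluate
#' @return the value of `code`
#' @keywords internal
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic per-item seed stream derived from a master seed; stays < 2^31.
derive_seed <- function(master, index) {
  m <- as.double(master) %% 2147483647
  s <- (m * 48271 + as.double(index) * 30269 + 11939) %% 2147483629
  as.integer(s + 1)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Peak signal-to-noise ratio
#'
#' @param x image to score
#' @param ref reference (clean) image on the same scale
#' @param peak dynamic-range peak (1 for unit-range images)
#' @return PSNR in dB
#' @export
psnr <- function(x, ref, peak = 1) {
  mse <- mean((as.numeric(x) - as.numeric(ref))^2)
  if (mse == 0) return(Inf)
  10 * log10(peak^2 / mse)
}

# Shannon entropy (bits) of an 8-bit quantized image.
entropy8 <- function(img) {
  q <- floor(clip01(as.numeric(img)) * 255 + 0.5)
  p <- tabulate(q + 1L, nbins = 256L)
  p <- p / sum(p)
  p <- p[p > 0]
  -sum(p * log2(p))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
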