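# Parametric noise families and the doubling intensity ladder.
#
# Robustness is probed with three noise families typical of ultrasound:
# additive Gaussian noise (electronic interference), multiplicative speckle
# (coherent imaging granularity, I <- I + I*n), and salt & pepper impulse
# noise (transmission errors). Each family is applied at levels 0..n_levels
# where level 0 is the clean image and the intensity doubles with each
# ascending level: intensity(k) = base * 2^(k-1). The top level can be
# calibrated so a reference model drops to chance accuracy (~1/3).

#' Specification for a noise family ladder
#'
#' @param family `"gaussian"`, `"speckle"`, or `"salt_pepper"`.
#' @param base_intensity level-1 intensity: the noise standard deviation (in
#'   intensity units) for gaussian/speckle, the per-pixel corruption
#'   probability for salt_pepper. Defaults (0.02 / 0.05 / 0.005) are chosen
#'   so the top of the ladder is severely degraded; use
#'   [calibrate_base_intensity()] for a principled choice.
#' @param n_levels number of perturbed levels (default 6; level 0 is clean).
#' @return an object of class `noise_spec`.
#' @export
noise_spec <- function(family = c("gaussian", "speckle", "salt_pepper"),
                       base_intensity = NULL, n_levels = 6L) {
  family <- match.arg(family)
  if (is.null(base_intensity))
    base_intensity <- switch(family, gaussian = 0.02, speckle = 0.05,
                             salt_pepper = 0.005)
  stopifnot(base_intensity > 0, n_levels >= 1)
  if (family == "salt_pepper" && base_intensity * 2^(n_levels - 1) > 1)
    stop("salt_pepper density at the top level exceeds 1", call. = FALSE)
  structure(list(family = family, base_intensity = base_intensity,
                 n_levels = as.integer(n_levels)),
            class = "noise_spec")
}

#' Noise intensity at a ladder level
#'
#' Level 0 is clean (intensity 0); level `k >= 1` has intensity
#' `base_intensity * 2^(k-1)`, i.e. the intensity doubles with each level.
#'
#' @param spec a [noise_spec()].
#' @param level integer in `0..n_levels`.
#' @return scalar intensity.
#' @export
intensity_for_level <- function(spec, level) {
  stopifnot(inherits(spec, "noise_spec"))
  if (level < 0 || level > spec$n_levels)
    stop("level must be in 0..", spec$n_levels, call. = FALSE)
  if (level == 0) 0 else spec$base_intensity * 2^(level - 1)
}

#' Apply parametric noise to one image
#'
#' Gaussian: adds i.i.d. `N(0, intensity^2)` deviates. Speckle: multiplicative,
#' `pixel + pixel * n` with `n ~ N(0, intensity^2)`. Salt & pepper: each pixel
#' independently corrupted with probability `intensity`, corrupted pixels set
#' to 0 or 1 with equal probability. Output is clipped to `[0,1]`. Labels and
#' masks are untouched by construction (noise operates on pixels only).
#'
#' @param image H x W matrix in `[0,1]`.
#' @param family noise family name.
#' @param intensity non-negative scalar (`<= 1` for salt_pepper).
#' @param seed integer seed; the corruption is deterministic per seed.
#' @return the corrupted H x W matrix.
#' @export
apply_noise <- function(image, family = c("gaussian", "speckle",
                                          "salt_pepper"),
                        intensity, seed = 1L) {
  family <- match.arg(family)
  if (intensity < 0) stop("intensity must be non-negative", call. = FALSE)
  if (family == "salt_pepper" && intensity > 1)
    stop("salt_pepper intensity is a probability (<= 1)", call. = FALSE)
  if (intensity == 0) return(image)
  with_seed(seed, {
    out <- switch(family,
      gaussian = image + matrix(rnorm(length(image), 0, intensity),
                                nrow(image)),
      speckle = image * (1 + matrix(rnorm(length(image), 0, intensity),
                                    nrow(image))),
      salt_pepper = {
        hit <- matrix(runif(length(image)) < intensity, nrow(image))
        val <- matrix(ifelse(runif(length(image)) < 0.5, 0, 1), nrow(image))
        ifelse(hit, val, image)
      })
    clip01(out)
  })
}

#' Build the noisy test-set grid
#'
#' For each noise family, produces manifests at levels `0..n_levels`; level 0
#' is the shared clean test set. Each image's corruption seed is derived
#' deterministically from `(seed, family, level, image index)`, so the grid
#' is reproducible image-by-image.
#'
#' @param test_ds clean test `image_dataset`.
#' @param specs list of [noise_spec()]s.
#' @param seed master integer seed.
#' @return nested named list: `sets[[family]][[as.character(level)]]` is an
#'   `image_dataset`; with an empty `specs` list, only
#'   `sets$clean` is returned.
#' @export
build_noise_test_sets <- function(test_ds, specs, seed = 1L) {
  if (length(test_ds) == 0) stop("empty test set", call. = FALSE)
  if (length(specs) == 0) return(list(clean = test_ds))
  out <- list()
  for (spec in specs) {
    fam <- spec$family
    per_level <- list()
    per_level[["0"]] <- test_ds
    for (lev in seq_len(spec$n_levels)) {
      sig <- intensity_for_level(spec, lev)
      noisy <- test_ds
      noisy$images <- lapply(seq_len(length(test_ds)), function(i)
        apply_noise(test_ds$images[[i]], fam, sig,
                    derive_seed(seed, "noise", fam, lev, i)))
      per_level[[as.character(lev)]] <- noisy
    }
    out[[fam]] <- per_level
  }
  out
}

#' Calibrate the base intensity so the top level is at chance
#'
#' Bisects the base intensity within `bounds` until the reference model's
#' balanced accuracy on the test set corrupted at the top ladder level falls
#' inside `chance_band` (a band around 1/3). Accuracy is assumed to be
#' non-increasing in intensity. If the model is already inside the band at
#' the lower bound (e.g. a constant predictor), the lower bound is returned.
#'
#' @param model an object with a [predict()] method returning per-sample
#'   class-probability rows for an `image_dataset`.
#' @param clean_test clean test `image_dataset`.
#' @param family noise family name.
#' @param chance_band `c(low, high)` containing 1/3.
#' @param seed integer seed used for the noise draws.
#' @param bounds search interval for the base intensity.
#' @param n_levels ladder depth (top level = `base * 2^(n_levels-1)`).
#' @param tol stop when the interval is narrower than this (intensity units).
#' @param max_iter bisection iteration cap.
#' @param accuracy_fn optional override: a function `f(top_intensity)`
#'   returning the accuracy directly, used for calibration diagnostics in
#'   place of model evaluation.
#' @return list with `base_intensity` and `achieved_accuracy`.
#' @export
calibrate_base_intensity <- function(model, clean_test, family,
                                     chance_band = c(0.28, 0.40), seed = 1L,
                                     bounds = NULL, n_levels = 6L,
                                     tol = 1e-3, max_iter = 20L,
                                     accuracy_fn = NULL) {
  if (chance_band[1] >= 1 / 3 || chance_band[2] <= 1 / 3)
    stop("chance_band must contain 1/3", call. = FALSE)
  if (is.null(bounds))
    bounds <- if (identical(family, "salt_pepper"))
      c(1e-5, 1 / 2^(n_levels - 1)) else c(1e-4, 0.5)
  top <- function(base) base * 2^(n_levels - 1)
  acc <- if (!is.null(accuracy_fn)) {
    function(base) accuracy_fn(top(base))
  } else {
    function(base) {
      noisy <- clean_test
      noisy$images <- lapply(seq_len(length(clean_test)), function(i)
        apply_noise(clean_test$images[[i]], family, top(base),
                    derive_seed(seed, "calibrate", family, i)))
      probs <- predict(model, noisy)
      balanced_accuracy(dominant_class(clean_test$labels), probs)
    }
  }
  lo <- bounds[1]; hi <- bounds[2]
  a_lo <- acc(lo)
  if (a_lo >= chance_band[1] && a_lo <= chance_band[2])
    return(list(base_intensity = lo, achieved_accuracy = a_lo))
  if (a_lo < chance_band[1])
    stop("calibration failure: accuracy ", signif(a_lo, 3),
         " already below the band at the lower bound", call. = FALSE)
  a_hi <- acc(hi)
  if (a_hi > chance_band[2])
    stop("calibration failure: band unreachable; closest accuracy ",
         signif(a_hi, 3), call. = FALSE)
  best <- list(base_intensity = hi, achieved_accuracy = a_hi)
  for (it in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    a <- acc(mid)
    if (a >= chance_band[1] && a <= chance_band[2])
      return(list(base_intensity = mid, achieved_accuracy = a))
    if (a > chance_band[2]) lo <- mid else { hi <- mid; best <-
      list(base_intensity = mid, achieved_accuracy = a) }
    if (hi - lo < tol) break
  }
  best
}
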