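# Synthetic breast-ultrasound-like phantoms.
#
# Real sonography cannot be shipped with the package, so these phantoms
# emulate the *statistical structure* the pipeline assumes: speckle-textured
# grayscale images in three classes at configurable proportions, with binary
# lesion masks (blank for the normal class), one-hot labels, and a
# train/test/val split that holds class proportions constant. Benign lesions
# are smooth hypoechoic ellipses; malignant lesions are irregular
# jagged-boundary regions with a posterior shadow column, the two canonical
# sonographic cues. No beamforming or attenuation physics is modelled.

#' Specification for a phantom dataset
#'
#' @param n_images number of images (>= 1).
#' @param image_size pixels per side, square images (>= 16).
#' @param class_proportions length-3 non-negative vector summing to 1
#'   (normal, benign, malignant); default matches the reference breast
#'   ultrasound corpus: 17% / 56% / 27%.
#' @param speckle_contrast texture amplitude in `[0,1]`.
#' @param lesion_size_range lesion diameter as a fraction of the image side,
#'   `c(min, max)`.
#' @param seed integer seed; the whole dataset is a pure function of the spec.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(n_images = 780, image_size = 128,
                         class_proportions = c(0.17, 0.56, 0.27),
                         speckle_contrast = 0.35,
                         lesion_size_range = c(0.18, 0.45),
                         seed = 1L) {
  stopifnot(n_images >= 1, image_size >= 16,
            speckle_contrast >= 0, speckle_contrast <= 1,
            length(lesion_size_range) == 2,
            lesion_size_range[1] <= lesion_size_range[2],
            lesion_size_range[1] > 0)
  check_class_weights(class_proportions, tol = 1e-9)
  if (lesion_size_range[1] * image_size < 3)
    stop("image_size too small to place the minimum lesion", call. = FALSE)
  structure(list(n_images = as.integer(n_images),
                 image_size = as.integer(image_size),
                 class_proportions = as.numeric(class_proportions),
                 speckle_contrast = speckle_contrast,
                 lesion_size_range = lesion_size_range,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# speckle-textured background: a slowly varying field times granular
# multiplicative noise, the standard first-order speckle approximation
speckle_background <- function(size, contrast) {
  coarse <- EBImage::gblur(matrix(rnorm(size^2), size, size),
                           sigma = size / 8)
  coarse <- coarse / max(abs(coarse), 1e-8)
  fine <- EBImage::gblur(matrix(rnorm(size^2), size, size), sigma = 0.8)
  fine <- fine / stats::sd(fine)
  base <- 0.45 + 0.1 * coarse
  clip01(base * (1 + contrast * fine))
}

ellipse_mask <- function(size, cx, cy, a, b, theta) {
  xs <- matrix(seq_len(size), size, size)          # row coordinate
  ys <- matrix(seq_len(size), size, size, byrow = TRUE)
  dx <- xs - cx; dy <- ys - cy
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

# irregular region: radial polygon r(theta) with random harmonics
jagged_mask <- function(size, cx, cy, r0) {
  k <- 3:7
  amp <- runif(length(k), 0.05, 0.18)
  phase <- runif(length(k), 0, 2 * pi)
  xs <- matrix(seq_len(size), size, size)
  ys <- matrix(seq_len(size), size, size, byrow = TRUE)
  dx <- xs - cx; dy <- ys - cy
  ang <- atan2(dy, dx)
  rr <- r0 * (1 + Reduce(`+`, lapply(seq_along(k), function(i)
    amp[i] * sin(k[i] * ang + phase[i]))))
  sqrt(dx^2 + dy^2) <= rr
}

render_phantom <- function(class_idx, size, contrast, size_range) {
  img <- speckle_background(size, contrast)
  if (class_idx == 1) return(list(pixels = img, mask = NULL))
  margin <- ceiling(size_range[2] * size / 2) + 1
  cx <- runif(1, margin, size - margin)
  cy <- runif(1, margin, size - margin)
  half <- runif(2, size_range[1], size_range[2]) * size / 2
  if (class_idx == 2) {
    mask <- ellipse_mask(size, cx, cy, max(half[1], 2), max(half[2], 2),
                         runif(1, 0, pi))
    depth <- 0.55
  } else {
    mask <- jagged_mask(size, cx, cy, max(mean(half), 2.5))
    depth <- 0.75
  }
  soft <- EBImage::gblur(mask * 1, sigma = max(size / 64, 0.7))
  img <- img * (1 - depth * clip01(soft))
  if (class_idx == 3) {
    # posterior acoustic shadow below the mass
    cols <- which(colSums(mask) > 0)
    if (length(cols)) {
      bottom <- max(which(rowSums(mask[, cols, drop = FALSE]) > 0))
      if (bottom < size) {
        fade <- seq(0.55, 0.85, length.out = size - bottom)
        img[(bottom + 1):size, cols] <-
          img[(bottom + 1):size, cols] * fade
      }
    }
  }
  list(pixels = clip01(img), mask = mask * 1)
}

#' Generate a synthetic phantom dataset
#'
#' Class counts are the largest-remainder apportionment of
#' `n_images * class_proportions` (so 780 images at 0.17/0.56/0.27 give
#' 133/437/210). All labels are one-hot; normal-class samples carry a blank
#' (absent) mask. Deterministic for a fixed spec.
#'
#' @param spec a [phantom_spec()].
#' @return an `image_dataset` with `source = "original"`.
#' @export
#' @examples
#' ds <- generate_phantom_dataset(phantom_spec(n_images = 6, image_size = 16))
#' table(CLASSES[dominant_class(ds$labels)])
generate_phantom_dataset <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  counts <- largest_remainder(spec$n_images, spec$class_proportions)
  cls <- rep(1:3, counts)
  with_seed(spec$seed, {
    cls <- sample(cls)   # interleave classes deterministically
    out <- lapply(seq_along(cls), function(i) {
      set.seed(derive_seed(spec$seed, "phantom", i))
      render_phantom(cls[i], spec$image_size, spec$speckle_contrast,
                     spec$lesion_size_range)
    })
  })
  labels <- matrix(0, length(cls), 3)
  labels[cbind(seq_along(cls), cls)] <- 1
  image_dataset(lapply(out, `[[`, "pixels"), labels,
                lapply(out, `[[`, "mask"), source = "original")
}

# per-class apportionment across splits with a repair pass that enforces the
# exact split totals while keeping each class within one unit of its
# largest-remainder share
stratified_counts <- function(class_n, sizes) {
  n <- sum(class_n)
  counts <- t(vapply(class_n, function(nc)
    largest_remainder(nc, sizes / n), integer(length(sizes))))
  target <- largest_remainder(n, sizes / n)  # == sizes when they sum to n
  repeat {
    colsum <- colSums(counts)
    over <- which(colsum > target)
    under <- which(colsum < target)
    if (!length(over)) break
    s <- over[1]; t <- under[1]
    # move one unit of the class whose split-s share most exceeds quota
    excess <- counts[, s] - class_n * sizes[s] / n
    k <- which.max(ifelse(counts[, s] > 0, excess, -Inf))
    counts[k, s] <- counts[k, s] - 1L
    counts[k, t] <- counts[k, t] + 1L
  }
  counts
}

#' Split a dataset into train/test/validation subsets
#'
#' @param ds an `image_dataset`.
#' @param sizes integer vector `c(train, test, val)` summing to `length(ds)`.
#' @param seed integer seed for the (stratified) random assignment.
#' @param stratified if `TRUE` (default) per-class proportions in each split
#'   match the whole dataset within rounding.
#' @return named list of `image_dataset`s (`train`, `test`, `val`) with the
#'   `split` field set.
#' @export
split_dataset <- function(ds, sizes, seed = 1L, stratified = TRUE) {
  n <- length(ds)
  sizes <- as.integer(sizes)
  if (length(sizes) != 3 || sum(sizes) != n)
    stop("sizes must be c(train, test, val) summing to length(ds)",
         call. = FALSE)
  labs <- c("train", "test", "val")
  assign <- character(n)
  if (stratified) {
    dom <- dominant_class(ds$labels)
    class_n <- tabulate(dom, 3)
    active <- which(class_n > 0)
    if (any(class_n[active] < sum(sizes > 0)) && all(sizes > 0))
      stop("a class has fewer samples than splits under stratification",
           call. = FALSE)
    counts <- matrix(0L, 3, 3)
    counts[active, ] <- stratified_counts(class_n[active], sizes)
    with_seed(seed, {
      for (k in active) {
        idx <- sample(which(dom == k))
        assign[idx] <- rep(labs, counts[k, ])
      }
    })
  } else {
    with_seed(seed, {
      assign <- sample(rep(labs, sizes))
    })
  }
  out <- lapply(labs, function(l) {
    sub <- ds[assign == l]
    sub$split <- rep(l, length(sub))
    sub
  })
  stats::setNames(out, labs)
}
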