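# Comparison augmentation strategies and training-set composition.
#
# Three baselines accompany the generative augmentation: standard data
# augmentation (SDA: random rotation within +/-15 degrees, random horizontal
# flip, brightness and contrast jitter; never vertical flips, which would be
# inconsistent with ultrasound geometry), pixel-space Mixup (convex
# combination of image pairs and their labels with lambda ~ Beta(alpha,
# alpha)), and Manifold Mixup (the same combination applied to hidden
# representations during training). Every non-vanilla training set is the
# 600 originals plus a same-size augmented set (1,200 images in total).

#' Standard-data-augmentation configuration
#'
#' @param rotation_range maximum absolute rotation in degrees (default 15).
#' @param hflip_prob horizontal-flip probability (default 0.5).
#' @param brightness_range,contrast_range multiplicative jitter half-widths
#'   (default 0.2, i.e. +/-20%).
#' @return an object of class `sda_config`.
#' @export
sda_config <- function(rotation_range = 15, hflip_prob = 0.5,
                       brightness_range = 0.2, contrast_range = 0.2) {
  stopifnot(abs(rotation_range) <= 180, hflip_prob >= 0, hflip_prob <= 1,
            brightness_range >= 0, brightness_range < 1,
            contrast_range >= 0, contrast_range < 1)
  structure(list(rotation_range = rotation_range, hflip_prob = hflip_prob,
                 brightness_range = brightness_range,
                 contrast_range = contrast_range), class = "sda_config")
}

#' Mixup configuration
#'
#' @param alpha shape parameter of the symmetric Beta distribution for the
#'   mixing weight lambda (default 0.8).
#' @param mixed_fraction fraction of the final training set that is mixed
#'   (default 0.5: 600 mixed images on top of 600 originals).
#' @return an object of class `mixup_config`.
#' @export
mixup_config <- function(alpha = 0.8, mixed_fraction = 0.5) {
  stopifnot(alpha > 0, mixed_fraction >= 0, mixed_fraction <= 1)
  structure(list(alpha = alpha, mixed_fraction = mixed_fraction),
            class = "mixup_config")
}

#' Apply standard data augmentation to one image
#'
#' Applies, in order: rotation by an angle drawn uniformly from
#' `[-rotation_range, rotation_range]` about the image centre with zero
#' padding, horizontal flip with probability `hflip_prob`, multiplicative
#' brightness jitter, contrast jitter about the image mean, and a final clip
#' to `[0,1]`. Vertical flips are never applied. Deterministic per seed.
#'
#' @param image H x W matrix in `[0,1]`.
#' @param config an [sda_config()].
#' @param seed integer seed.
#' @return the augmented H x W matrix.
#' @export
standard_augment <- function(image, config = sda_config(), seed = 1L) {
  with_seed(seed, {
    ang <- runif(1, -config$rotation_range, config$rotation_range)
    if (abs(ang) > 1e-12) {
      image <- EBImage::rotate(image, ang, output.dim = dim(image),
                               bg.col = 0)
      image <- matrix(as.numeric(image), nrow(image))
    }
    if (runif(1) < config$hflip_prob)
      image <- image[, rev(seq_len(ncol(image))), drop = FALSE]
    if (config$brightness_range > 0)
      image <- image * runif(1, 1 - config$brightness_range,
                             1 + config$brightness_range)
    if (config$contrast_range > 0) {
      m <- mean(image)
      image <- (image - m) * runif(1, 1 - config$contrast_range,
                                   1 + config$contrast_range) + m
    }
    clip01(image)
  })
}

#' Draw a Mixup mixing weight
#'
#' One draw of lambda ~ Beta(alpha, alpha) from the current RNG stream.
#'
#' @param config a [mixup_config()].
#' @param n number of draws.
#' @return numeric vector in `[0,1]`.
#' @export
sample_lambda <- function(config = mixup_config(), n = 1L) {
  rbeta(n, config$alpha, config$alpha)
}

#' Pixel-space Mixup of two samples
#'
#' Returns the convex combination `lambda * x + (1 - lambda) * y` of the two
#' images, with the label interpolated by the same rule; the masks are
#' dropped (a mixed image has no single lesion geometry) and the source is
#' tagged `pixel_mixup`.
#'
#' @param x,y samples: lists with elements `pixels` (matrix) and `label`
#'   (length-3 weight vector).
#' @param lambda mixing weight in `[0,1]`.
#' @return a sample list with `pixels`, `label`, `mask = NULL`,
#'   `source = "pixel_mixup"`.
#' @export
pixel_mixup <- function(x, y, lambda) {
  stopifnot(lambda >= 0, lambda <= 1)
  if (!all(dim(x$pixels) == dim(y$pixels)))
    stop("pixel_mixup inputs must share dimensions", call. = FALSE)
  list(pixels = lambda * x$pixels + (1 - lambda) * y$pixels,
       label = lambda * x$label + (1 - lambda) * y$label,
       mask = NULL, source = "pixel_mixup")
}

#' One Manifold-Mixup training step (loss and gradients)
#'
#' Runs both batches forward to the chosen mixing point (0 = raw input,
#' `s` = output of residual stage `s`), mixes the hidden representations
#' with weight `lambda`, continues the forward pass on the mixture, and
#' computes soft-label cross-entropy against the lambda-mixed labels. The
#' computation uses the model's current weights, as during on-line training.
#'
#' @param model a `dream_classifier` (trained or in-training).
#' @param batch_a,batch_b lists with `X` (n x D input matrix, rows already
#'   preprocessed) and `T` (n x 3 target weights).
#' @param lambda mixing weight in `[0,1]`.
#' @param layer_index mixing point in `0..n_stages`.
#' @return list with `loss` (numeric) and `grads` (parameter-shaped list).
#' @export
manifold_mixup_step <- function(model, batch_a, batch_b, lambda,
                                layer_index) {
  p <- model$params
  S <- length(p$stages)
  if (layer_index < 0 || layer_index > S)
    stop("layer_index must be in 0..", S, call. = FALSE)
  Tmix <- lambda * batch_a$T + (1 - lambda) * batch_b$T
  if (layer_index == 0) {
    Xmix <- lambda * batch_a$X + (1 - lambda) * batch_b$X
    fwd <- clf_forward(p, Xmix)
    ce <- soft_ce(fwd$logits, Tmix)
    bwd <- clf_backward_from(p, fwd, ce$dlogits)
    return(list(loss = ce$loss, grads = bwd$grads))
  }
  pre_a <- clf_forward_to(p, batch_a$X, layer_index)
  pre_b <- clf_forward_to(p, batch_b$X, layer_index)
  hmix <- lambda * pre_a$h + (1 - lambda) * pre_b$h
  fwd <- clf_forward_from(p, hmix, layer_index)
  ce <- soft_ce(fwd$logits, Tmix)
  bwd <- clf_backward_from(p, fwd, ce$dlogits)
  ga <- clf_backward_prefix(p, pre_a, lambda * bwd$dh)
  gb <- clf_backward_prefix(p, pre_b, (1 - lambda) * bwd$dh)
  list(loss = ce$loss, grads = acc_grads(bwd$grads, acc_grads(ga, gb)))
}

#' Compose a training dataset for a given augmentation strategy
#'
#' Implements the composition rule under which every strategy except
#' `vanilla` trains on the originals plus a same-size augmented set:
#' \describe{
#'   \item{vanilla}{the originals only.}
#'   \item{sda}{originals + SDA-transformed copies of the originals.}
#'   \item{pixel_mixup}{originals + mixed pairs drawn from the originals,
#'     each pairing two (possibly different-class) samples, labels convex.}
#'   \item{manifold_mixup}{originals + copies flagged `manifold_flag`; the
#'     actual mixing happens on-line during training.}
#'   \item{dreamon, dreamoff}{originals + the supplied generated set.}
#'   \item{dreamon_sda}{originals + SDA applied on top of the generated set.}
#' }
#'
#' @param strategy one of `r paste(STRATEGIES, collapse=", ")`.
#' @param originals training-split `image_dataset` (e.g. 600 images).
#' @param generated generated `image_dataset` (required for the dream
#'   strategies), same size as `originals`.
#' @param seed integer seed for the stochastic augmentations.
#' @param sda an [sda_config()].
#' @param mixup a [mixup_config()].
#' @return an `image_dataset` of `length(originals)` (vanilla) or
#'   `2 * length(originals)` records.
#' @export
build_training_dataset <- function(strategy, originals, generated = NULL,
                                   seed = 1L, sda = sda_config(),
                                   mixup = mixup_config()) {
  strategy <- match.arg(strategy, STRATEGIES)
  n <- length(originals)
  if (strategy == "vanilla") return(originals)
  if (strategy %in% c("dreamon", "dreamon_sda", "dreamoff")) {
    if (is.null(generated))
      stop("strategy '", strategy, "' requires a generated set",
           call. = FALSE)
    aug <- generated
    if (strategy == "dreamon_sda") {
      aug$images <- lapply(seq_len(length(aug)), function(i)
        standard_augment(aug$images[[i]], sda,
                         derive_seed(seed, "dreamon_sda", i)))
      aug$masks <- vector("list", length(aug))
    }
  } else if (strategy == "sda") {
    aug <- originals
    aug$images <- lapply(seq_len(n), function(i)
      standard_augment(originals$images[[i]], sda, derive_seed(seed, "sda", i)))
    aug$source <- rep("sda", n)
    aug$parents <- as.character(seq_len(n))
  } else if (strategy == "pixel_mixup") {
    n_mix <- n   # same-size augmented set (mixed_fraction of the final 2n)
    with_seed(derive_seed(seed, "mixup"), {
      i1 <- sample(n, n_mix, replace = TRUE)
      i2 <- vapply(i1, function(i) sample(setdiff(seq_len(n), i), 1L), 1L)
      lam <- sample_lambda(mixup, n_mix)
    })
    mixed <- lapply(seq_len(n_mix), function(k)
      pixel_mixup(list(pixels = originals$images[[i1[k]]],
                       label = originals$labels[i1[k], ]),
                  list(pixels = originals$images[[i2[k]]],
                       label = originals$labels[i2[k], ]),
                  lam[k]))
    aug <- image_dataset(lapply(mixed, `[[`, "pixels"),
                         do.call(rbind, lapply(mixed, `[[`, "label")),
                         source = "pixel_mixup", split = originals$split[1],
                         parents = paste(i1, i2, sep = ";"))
  } else { # manifold_mixup
    aug <- originals
    aug$source <- rep("manifold_flag", n)
    aug$parents <- as.character(seq_len(n))
  }
  out <- dataset_bind(originals, aug)
  out$split <- rep(originals$split[1], length(out))
  out
}
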