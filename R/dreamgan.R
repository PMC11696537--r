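# The DreamOn generative pipeline.
#
# Two separately trained GANs are combined at synthesis time: an
# unconditional mask generator G_m trained only on binary lesion masks
# (blank masks included, so the mask prior covers the normal class), and a
# conditional image generator G_s(mask, class vector, noise vector) trained
# on (image, mask, one-hot label) triples. Interpolation happens only after
# training: the generator is fed a class-weight vector with exactly two
# non-zero entries summing to 1, and that vector becomes the ground-truth
# soft label of the synthesized image. A control set (DreamOff) uses the
# identical pipeline with one-hot inputs, isolating the effect of
# interpolation from merely adding GAN imagery.

#' GAN training configuration
#'
#' @param image_size square image side, a power of two >= 16.
#' @param latent_dim length of the noise vector fed to the image generator
#'   (default 400).
#' @param mask_latent_dim latent size of the mask generator (default 64).
#' @param hidden integer vector of hidden-layer widths (default `c(256)`).
#' @param learning_rate Adam learning rate (default 2e-4).
#' @param adam_betas Adam moment decays (default `c(0.5, 0.999)`, the usual
#'   GAN setting).
#' @param batch_size minibatch size.
#' @param steps number of generator/discriminator update steps.
#' @param seed integer seed; training is a deterministic function of it.
#' @return an object of class `gan_config`.
#' @export
gan_config <- function(image_size = 32, latent_dim = 400,
                       mask_latent_dim = 64, hidden = c(256),
                       learning_rate = 2e-4, adam_betas = c(0.5, 0.999),
                       batch_size = 32, steps = 400, seed = 1L) {
  stopifnot(image_size >= 16, bitwAnd(image_size, image_size - 1L) == 0,
            latent_dim >= 1, mask_latent_dim >= 1, learning_rate > 0,
            batch_size >= 1, steps >= 1)
  structure(list(image_size = as.integer(image_size),
                 latent_dim = as.integer(latent_dim),
                 mask_latent_dim = as.integer(mask_latent_dim),
                 hidden = as.integer(hidden),
                 learning_rate = learning_rate, adam_betas = adam_betas,
                 batch_size = as.integer(batch_size),
                 steps = as.integer(steps), seed = as.integer(seed)),
            class = "gan_config")
}

blank_if_null <- function(mask, size) {
  if (is.null(mask)) matrix(0, size, size) else mask
}

# one adversarial update: returns new nets/optimizers and the two losses.
# Non-saturating GAN loss on discriminator logits.
gan_step <- function(G, D, optG, optD, real_in, g_in, d_extra, lr, betas) {
  nb <- nrow(real_in)
  gfwd <- net_forward(G, g_in)
  fake <- gfwd$out
  # discriminator update
  d_real_in <- cbind(real_in, d_extra)
  d_fake_in <- cbind(fake, d_extra)
  fr <- net_forward(D, d_real_in)
  ff <- net_forward(D, d_fake_in)
  d_loss <- mean(softplus(-fr$out)) + mean(softplus(ff$out))
  dz_r <- -(1 - 1 / (1 + exp(-fr$out))) / nb     # d softplus(-z)/dz
  dz_f <- (1 / (1 + exp(-ff$out))) / nb
  gr <- net_backward(D, fr, dz_r)$grads
  gf <- net_backward(D, ff, dz_f)$grads
  dgrads <- map_params(`+`, gr, gf)
  upd <- adam_step(net_params(D), dgrads, optD, lr, betas)
  D <- net_set_params(D, upd$params); optD <- upd$state
  # generator update (through the updated discriminator)
  ff2 <- net_forward(D, d_fake_in)
  g_loss <- mean(softplus(-ff2$out))
  dz <- -(1 - 1 / (1 + exp(-ff2$out))) / nb
  bD <- net_backward(D, ff2, dz)
  d_fake <- bD$dX[, seq_len(ncol(fake)), drop = FALSE]
  ggrads <- net_backward(G, gfwd, d_fake)$grads
  upd <- adam_step(net_params(G), ggrads, optG, lr, betas)
  G <- net_set_params(G, upd$params); optG <- upd$state
  list(G = G, D = D, optG = optG, optD = optD,
       d_loss = d_loss, g_loss = g_loss)
}

check_history <- function(history) {
  if (!all(is.finite(history$d_loss)) || !all(is.finite(history$g_loss)))
    stop("non-finite GAN loss; lower the learning rate or widen the net",
         call. = FALSE)
}

#' Train the unconditional mask generator G_m
#'
#' An adversarial generator mapping a latent vector to a binary lesion mask
#' (sigmoid output thresholded at 0.5 when sampling). Blank masks are
#' legitimate training samples: they are what the normal class looks like.
#'
#' @param masks list of binary H x W matrices (`NULL` entries are treated as
#'   blank masks).
#' @param config a [gan_config()].
#' @return an object of class `mask_gan` with the generator, the training
#'   history (`step`, `d_loss`, `g_loss`), and the config.
#' @export
train_mask_gan <- function(masks, config = gan_config()) {
  if (length(masks) == 0) stop("empty mask training set", call. = FALSE)
  size <- config$image_size
  X <- do.call(rbind, lapply(masks, function(m)
    flat(blank_if_null(m, size))))
  if (ncol(X) != size^2) stop("mask size does not match config image_size",
                              call. = FALSE)
  D2 <- size^2
  with_seed(config$seed, {
    G <- net_new(c(config$mask_latent_dim, config$hidden, D2),
                 c(rep("lrelu", length(config$hidden)), "sigmoid"))
    D <- net_new(c(D2, rev(config$hidden), 1),
                 c(rep("lrelu", length(config$hidden)), "linear"))
    optG <- adam_new(net_params(G)); optD <- adam_new(net_params(D))
    hist <- data.frame(step = seq_len(config$steps), d_loss = NA_real_,
                       g_loss = NA_real_)
    for (s in seq_len(config$steps)) {
      idx <- sample(nrow(X), min(config$batch_size, nrow(X)))
      z <- matrix(rnorm(length(idx) * config$mask_latent_dim), length(idx))
      st <- gan_step(G, D, optG, optD, X[idx, , drop = FALSE], z,
                     matrix(0, length(idx), 0), config$learning_rate,
                     config$adam_betas)
      G <- st$G; D <- st$D; optG <- st$optG; optD <- st$optD
      hist$d_loss[s] <- st$d_loss; hist$g_loss[s] <- st$g_loss
    }
  })
  check_history(hist)
  structure(list(G = G, config = config, history = hist),
            class = "mask_gan")
}

#' Sample binary masks from a trained mask generator
#'
#' @param gan a `mask_gan`.
#' @param z n x mask_latent_dim latent matrix (the deterministic input).
#' @return list of binary H x W matrices (sigmoid output thresholded at 0.5).
#' @export
sample_masks <- function(gan, z) {
  stopifnot(inherits(gan, "mask_gan"))
  out <- net_forward(gan$G, z)$out
  size <- gan$config$image_size
  lapply(seq_len(nrow(out)), function(i)
    unflat(as.numeric(out[i, ] >= 0.5), size))
}

#' @export
print.mask_gan <- function(x, ...) {
  cat(sprintf("<mask_gan> %dpx, latent %d, %d steps (final d=%.3f g=%.3f)\n",
              x$config$image_size, x$config$mask_latent_dim,
              x$config$steps, utils::tail(x$history$d_loss, 1),
              utils::tail(x$history$g_loss, 1)))
  invisible(x)
}

#' Train the conditional image generator G_s
#'
#' `G_s(mask, class vector, z)` maps a lesion mask, a 3-class weight vector,
#' and a latent noise vector to an image in `[0,1]`; the discriminator is
#' conditioned on `(image, mask, class vector)`. Training sees only one-hot
#' class vectors — interpolated vectors are introduced only at synthesis
#' time, after training.
#'
#' @param ds `image_dataset` whose samples all carry one-hot labels; `NULL`
#'   masks are treated as blank.
#' @param config a [gan_config()].
#' @return an object of class `image_gan`.
#' @export
train_image_gan <- function(ds, config = gan_config()) {
  if (length(ds) == 0) stop("empty training set", call. = FALSE)
  if (!all(apply(ds$labels, 1, max) == 1))
    stop("image GAN training labels must be one-hot", call. = FALSE)
  size <- config$image_size
  if (any(dim(ds$images[[1]]) != size))
    stop("image size does not match config image_size", call. = FALSE)
  D2 <- size^2
  X <- do.call(rbind, lapply(ds$images, flat))
  M <- do.call(rbind, lapply(ds$masks, function(m)
    flat(blank_if_null(m, size))))
  Y <- ds$labels
  g_in_dim <- config$latent_dim + 3 + D2
  with_seed(config$seed, {
    G <- net_new(c(g_in_dim, config$hidden, D2),
                 c(rep("lrelu", length(config$hidden)), "sigmoid"))
    D <- net_new(c(D2 + D2 + 3, rev(config$hidden), 1),
                 c(rep("lrelu", length(config$hidden)), "linear"))
    optG <- adam_new(net_params(G)); optD <- adam_new(net_params(D))
    hist <- data.frame(step = seq_len(config$steps), d_loss = NA_real_,
                       g_loss = NA_real_)
    for (s in seq_len(config$steps)) {
      idx <- sample(nrow(X), min(config$batch_size, nrow(X)))
      z <- matrix(rnorm(length(idx) * config$latent_dim), length(idx))
      g_in <- cbind(z, Y[idx, , drop = FALSE], M[idx, , drop = FALSE])
      d_extra <- cbind(M[idx, , drop = FALSE], Y[idx, , drop = FALSE])
      st <- gan_step(G, D, optG, optD, X[idx, , drop = FALSE], g_in,
                     d_extra, config$learning_rate, config$adam_betas)
      G <- st$G; D <- st$D; optG <- st$optG; optD <- st$optD
      hist$d_loss[s] <- st$d_loss; hist$g_loss[s] <- st$g_loss
    }
  })
  check_history(hist)
  structure(list(G = G, config = config, history = hist),
            class = "image_gan")
}

#' @export
print.image_gan <- function(x, ...) {
  cat(sprintf(
    "<image_gan> %dpx, latent %d, %d steps (final d=%.3f g=%.3f)\n",
    x$config$image_size, x$config$latent_dim, x$config$steps,
    utils::tail(x$history$d_loss, 1), utils::tail(x$history$g_loss, 1)))
  invisible(x)
}

#' Beta means for the interpolated-weight sampler
#'
#' With the three unordered class pairs chosen uniformly, the pair-wise Beta
#' means `mu` must satisfy the linear system `E[w] = proportions`. One degree
#' of freedom remains; it is fixed symmetrically by `mu_nb = mu_nm` (the
#' weight of "normal" has the same mean in both pairs containing it). For
#' proportions (0.17, 0.56, 0.27) this gives mu = (0.255, 0.255, 0.935).
#'
#' @param proportions strictly positive length-3 simplex vector.
#' @return named vector `c(nb, nm, bm)`: the mean of the *first* class's
#'   weight within pairs (normal,benign), (normal,malignant),
#'   (benign,malignant).
#' @export
weight_pair_means <- function(proportions) {
  check_class_weights(proportions, tol = 1e-9)
  if (any(proportions <= 0))
    stop("proportions must be strictly positive", call. = FALSE)
  mu_nb <- 3 * proportions[1] / 2
  mu_nm <- mu_nb
  mu_bm <- 3 * proportions[2] - (1 - mu_nb)
  mu <- c(nb = mu_nb, nm = mu_nm, bm = unname(mu_bm))
  if (any(mu <= 0 | mu >= 1))
    stop("infeasible pair means for these proportions; ",
         "reconfigure the pair probabilities", call. = FALSE)
  mu
}

#' Sample interpolated class-weight vectors
#'
#' Draws 2-sparse points on the 3-class simplex: one of the three unordered
#' class pairs is picked uniformly, and the first class's weight is drawn
#' from a Beta distribution whose pair-conditional mean solves
#' `E[w] = proportions` (see [weight_pair_means()]), so the *average* weight
#' per class across a generated dataset matches the true class proportions.
#' Weights are clamped to `(1e-3, 1 - 1e-3)` so both entries stay non-zero.
#'
#' @param proportions strictly positive length-3 simplex vector.
#' @param n number of draws.
#' @param concentration Beta concentration kappa; shape = `(kappa * mu,
#'   kappa * (1 - mu))`.
#' @return n x 3 weight matrix; every row has exactly two non-zero entries
#'   summing to 1.
#' @export
sample_interpolated_weights <- function(proportions, n = 1L,
                                        concentration = 2) {
  mu <- weight_pair_means(proportions)
  pairs <- rbind(c(1, 2), c(1, 3), c(2, 3))
  pick <- sample.int(3, n, replace = TRUE)
  w1 <- rbeta(n, concentration * mu[pick], concentration * (1 - mu[pick]))
  w1 <- pmin(pmax(w1, 1e-3), 1 - 1e-3)
  W <- matrix(0, n, 3, dimnames = list(NULL, WEIGHT_COLS))
  W[cbind(seq_len(n), pairs[pick, 1])] <- w1
  W[cbind(seq_len(n), pairs[pick, 2])] <- 1 - w1
  W
}

# batched rendering shared by synthesize_image / generate_*_set
render_synthetic <- function(G_m, G_s, W) {
  n <- nrow(W)
  zm <- matrix(rnorm(n * G_m$config$mask_latent_dim), n)
  masks <- sample_masks(G_m, zm)
  M <- do.call(rbind, lapply(masks, flat))
  z <- matrix(rnorm(n * G_s$config$latent_dim), n)
  imgs <- net_forward(G_s$G, cbind(z, W, M))$out
  size <- G_s$config$image_size
  list(images = lapply(seq_len(n), function(i) unflat(imgs[i, ], size)),
       masks = masks)
}

#' Synthesize one image from the combined DreamOn pipeline
#'
#' Draws a mask from `G_m`, a latent noise vector, and renders
#' `G_s(mask, weights, z)`. The class-weight vector becomes the ground-truth
#' label of the sample, exactly; the source tag is `dreamon` for 2-sparse
#' weights and `dreamoff` for one-hot weights.
#'
#' @param G_m a trained `mask_gan`.
#' @param G_s a trained `image_gan`.
#' @param weights length-3 class-weight vector on the simplex.
#' @return a sample list with `pixels`, `mask`, `label`, `source`.
#' @export
synthesize_image <- function(G_m, G_s, weights) {
  if (!inherits(G_m, "mask_gan") || !inherits(G_s, "image_gan"))
    stop("trained mask_gan and image_gan handles are required",
         call. = FALSE)
  check_class_weights(weights)
  out <- render_synthetic(G_m, G_s, matrix(weights, 1))
  list(pixels = out$images[[1]], mask = out$masks[[1]],
       label = as.numeric(weights),
       source = if (sum(weights > 0) == 1) "dreamoff" else "dreamon")
}

#' Generate a DreamOn dataset of interpolated synthetic images
#'
#' Draws `n` 2-sparse weight vectors via [sample_interpolated_weights()],
#' re-drawing the whole list (up to `max_attempts` times) until the
#' dataset-mean weight of every class is within `tol` of `proportions`, then
#' renders the images. All labels are 2-sparse and the source is `dreamon`.
#'
#' @param G_m,G_s trained generator handles.
#' @param n number of images.
#' @param proportions target per-class mean weights.
#' @param seed integer seed.
#' @param tol mean-matching tolerance per class (default 0.02).
#' @param max_attempts regeneration attempts for the weight list.
#' @return an `image_dataset` with `source = "dreamon"`.
#' @export
generate_dreamon_set <- function(G_m, G_s, n, proportions = c(0.17, 0.56,
                                                              0.27),
                                 seed = 1L, tol = 0.02, max_attempts = 10L) {
  stopifnot(n >= 1)
  with_seed(seed, {
    W <- NULL
    for (att in seq_len(max_attempts)) {
      cand <- sample_interpolated_weights(proportions, n)
      if (all(abs(colMeans(cand) - proportions) < tol)) { W <- cand; break }
    }
    if (is.null(W))
      stop("mean-matching not achieved in ", max_attempts,
           " attempts; achieved means ",
           paste(signif(colMeans(cand), 3), collapse = ", "), call. = FALSE)
    out <- render_synthetic(G_m, G_s, W)
  })
  image_dataset(out$images, W, out$masks, source = "dreamon",
                split = "train")
}

#' Generate a DreamOff control dataset (one-hot inputs)
#'
#' The identical pipeline with one class per image: per-class counts are the
#' largest-remainder apportionment of `n * proportions` and every label is
#' one-hot, isolating the effect of interpolation from synthetic-data
#' addition.
#'
#' @inheritParams generate_dreamon_set
#' @return an `image_dataset` with `source = "dreamoff"`.
#' @export
generate_dreamoff_set <- function(G_m, G_s, n, proportions = c(0.17, 0.56,
                                                               0.27),
                                  seed = 1L) {
  stopifnot(n >= 1)
  counts <- largest_remainder(n, proportions)
  cls <- rep(1:3, counts)
  W <- matrix(0, n, 3)
  W[cbind(seq_len(n), cls)] <- 1
  with_seed(seed, {
    W <- W[sample(n), , drop = FALSE]
    out <- render_synthetic(G_m, G_s, W)
  })
  image_dataset(out$images, W, out$masks, source = "dreamoff",
                split = "train")
}
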