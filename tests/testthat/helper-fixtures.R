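# Shared fixtures, built once per test session and cached. Two scales:
# 16 px phantoms for GAN-backed tests (fast adversarial training) and
# 32 px phantoms for classifier tests.

.fixtures <- new.env(parent = emptyenv())

phantoms_16 <- function() {
  if (is.null(.fixtures$ph16)) {
    spec <- phantom_spec(n_images = 60, image_size = 16,
                         lesion_size_range = c(0.25, 0.5), seed = 11)
    ds <- generate_phantom_dataset(spec)
    .fixtures$ph16 <- list(spec = spec, ds = ds,
                           splits = split_dataset(ds, c(44, 8, 8), seed = 2))
  }
  .fixtures$ph16
}

phantoms_32 <- function() {
  if (is.null(.fixtures$ph32)) {
    spec <- phantom_spec(n_images = 150, image_size = 32, seed = 3)
    ds <- generate_phantom_dataset(spec)
    .fixtures$ph32 <- list(spec = spec, ds = ds,
                           splits = split_dataset(ds, c(110, 20, 20),
                                                  seed = 1))
  }
  .fixtures$ph32
}

gan_config_16 <- function(seed = 7)
  gan_config(image_size = 16, mask_latent_dim = 32, hidden = 64,
             steps = 120, batch_size = 16, seed = seed)

gans_16 <- function() {
  if (is.null(.fixtures$gans16)) {
    ph <- phantoms_16()
    .fixtures$gans16 <- list(
      G_m = train_mask_gan(ph$splits$train$masks, gan_config_16()),
      G_s = train_image_gan(ph$splits$train, gan_config_16(seed = 8)))
  }
  .fixtures$gans16
}

# a reference model that ignores its input: constant uniform prediction
constant_model <- function() structure(list(), class = "constant_model")

registerS3method("predict", "constant_model",
                 function(object, newdata, ...)
                   matrix(1 / 3, length(newdata), 3),
                 envir = asNamespace("stats"))

entropy <- function(w) -sum(ifelse(w > 0, w * log(w), 0))
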