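test_that("pair-conditional Beta means solve the mean-matching system", {
  expect_equal(unname(weight_pair_means(rep(1, 3) / 3)), rep(0.5, 3))
  mu <- weight_pair_means(c(0.17, 0.56, 0.27))
  expect_equal(unname(mu), c(0.255, 0.255, 0.935))
  # the solved means reproduce E[w] = proportions analytically
  Ew <- c((mu["nb"] + mu["nm"]) / 3,
          ((1 - mu["nb"]) + mu["bm"]) / 3,
          ((1 - mu["nm"]) + (1 - mu["bm"])) / 3)
  expect_equal(unname(Ew), c(0.17, 0.56, 0.27))
  expect_error(weight_pair_means(c(0.8, 0.1, 0.1)), "pair probabilities")
  expect_error(weight_pair_means(c(0.5, 0.5, 0)), "strictly positive")
})

test_that("interpolated weights are 2-sparse and mean-match by class", {
  set.seed(10)
  W <- sample_interpolated_weights(c(0.17, 0.56, 0.27), 1e5)
  expect_true(all(rowSums(W > 0) == 2))
  expect_equal(rowSums(W), rep(1, nrow(W)))
  se <- apply(W, 2, sd) / sqrt(nrow(W))
  expect_true(all(abs(colMeans(W) - c(0.17, 0.56, 0.27)) < 3 * se))
  # symmetric case
  set.seed(11)
  Wu <- sample_interpolated_weights(rep(1, 3) / 3, 1e5)
  seu <- apply(Wu, 2, sd) / sqrt(nrow(Wu))
  expect_true(all(abs(colMeans(Wu) - 1 / 3) < 3 * seu))
})

test_that("the mask GAN emits binary masks deterministically", {
  gans <- gans_16()
  expect_error(train_mask_gan(list(), gan_config_16()), "empty")
  expect_true(all(is.finite(gans$G_m$history$d_loss)))
  expect_true(all(is.finite(gans$G_m$history$g_loss)))
  set.seed(5)
  z <- matrix(rnorm(3 * 32), 3)
  masks <- sample_masks(gans$G_m, z)
  for (m in masks) {
    expect_identical(dim(m), c(16L, 16L))
    expect_true(all(m %in% c(0, 1)))
  }
  expect_identical(masks, sample_masks(gans$G_m, z))
  # retraining with the same seed reproduces the generator bit-for-bit
  G2 <- train_mask_gan(phantoms_16()$splits$train$masks, gan_config_16())
  expect_identical(sample_masks(G2, z), masks)
  expect_identical(G2$history, gans$G_m$history)
})

test_that("the conditional image GAN respects its contracts", {
  gans <- gans_16()
  ph <- phantoms_16()
  expect_true(all(is.finite(gans$G_s$history$d_loss)))
  # outputs in [0,1] at the requested size, deterministic per input
  s <- dreamon:::with_seed(1, synthesize_image(gans$G_m, gans$G_s,
                                               c(0, 0.2, 0.8)))
  expect_identical(dim(s$pixels), c(16L, 16L))
  expect_true(all(s$pixels >= 0 & s$pixels <= 1))
  expect_identical(s$label, c(0, 0.2, 0.8))   # label = weights exactly
  expect_identical(s$source, "dreamon")
  s2 <- dreamon:::with_seed(1, synthesize_image(gans$G_m, gans$G_s,
                                                c(0, 0.2, 0.8)))
  expect_identical(s$pixels, s2$pixels)
  one_hot <- dreamon:::with_seed(2, synthesize_image(gans$G_m, gans$G_s,
                                                     c(0, 1, 0)))
  expect_identical(one_hot$source, "dreamoff")
  # conditioning is not ignored: same mask and z, different class vector
  nn <- asNamespace("dreamon")
  set.seed(3)
  z <- matrix(rnorm(400), 1)
  m <- matrix(as.numeric(ph$ds$masks[[which(!sapply(ph$ds$masks,
                                                    is.null))[1]]]), 1)
  img_a <- nn$net_forward(gans$G_s$G, cbind(z, matrix(c(1, 0, 0), 1), m))$out
  img_b <- nn$net_forward(gans$G_s$G, cbind(z, matrix(c(0, 0, 1), 1), m))$out
  expect_gt(mean(abs(img_a - img_b)), 0)
  # training labels must be one-hot
  soft <- ph$splits$train
  soft$labels[1, ] <- c(0.5, 0.5, 0)
  expect_error(train_image_gan(soft, gan_config_16()), "one-hot")
})

test_that("DreamOn sets are 2-sparse with dataset-mean weights on target", {
  gans <- gans_16()
  dre <- generate_dreamon_set(gans$G_m, gans$G_s, 600,
                              proportions = c(0.17, 0.56, 0.27), seed = 31)
  expect_identical(length(dre), 600L)
  expect_true(all(rowSums(dre$labels > 0) == 2))   # no one-hot labels
  expect_true(all(abs(rowSums(dre$labels) - 1) < 1e-9))
  expect_true(all(abs(colMeans(dre$labels) - c(0.17, 0.56, 0.27)) < 0.02))
  expect_true(all(dre$source == "dreamon"))
  one <- generate_dreamon_set(gans$G_m, gans$G_s, 1, seed = 32,
                              tol = 1)      # n = 1 cannot mean-match tightly
  expect_identical(length(one), 1L)
  expect_identical(sum(one$labels[1, ] > 0), 2L)
  # regeneration gives identical output for identical seed
  dre2 <- generate_dreamon_set(gans$G_m, gans$G_s, 600,
                               proportions = c(0.17, 0.56, 0.27), seed = 31)
  expect_identical(dre, dre2)
  # unattainable tolerance fails with the achieved means
  expect_error(generate_dreamon_set(gans$G_m, gans$G_s, 5, seed = 33,
                                    tol = 1e-6, max_attempts = 3),
               "mean-matching")
})

test_that("DreamOff sets are one-hot at apportioned class counts", {
  gans <- gans_16()
  off <- generate_dreamoff_set(gans$G_m, gans$G_s, 600,
                               proportions = c(0.17, 0.56, 0.27), seed = 41)
  expect_identical(length(off), 600L)
  expect_true(all(rowSums(off$labels > 0) == 1))
  expect_identical(unname(colSums(off$labels)), c(102, 336, 162))
  expect_true(all(off$source == "dreamoff"))
  tiny <- generate_dreamoff_set(gans$G_m, gans$G_s, 3,
                                proportions = rep(1, 3) / 3, seed = 42)
  expect_identical(unname(colSums(tiny$labels)), c(1, 1, 1))
})
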