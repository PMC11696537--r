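test_that("degenerate SDA config is the identity and flips are involutions", {
  img <- phantoms_16()$ds$images[[2]]
  idn <- sda_config(rotation_range = 0, hflip_prob = 0,
                    brightness_range = 0, contrast_range = 0)
  expect_identical(standard_augment(img, idn, seed = 1), img)
  # forced flip twice returns the original
  flip <- sda_config(rotation_range = 0, hflip_prob = 1,
                     brightness_range = 0, contrast_range = 0)
  once <- standard_augment(img, flip, seed = 1)
  expect_false(identical(once, img))
  expect_identical(standard_augment(once, flip, seed = 2), img)
  # deterministic per seed, never out of range
  full <- sda_config()
  a <- standard_augment(img, full, seed = 9)
  expect_identical(a, standard_augment(img, full, seed = 9))
  expect_true(all(a >= 0 & a <= 1))
})

test_that("rotation matches a rotation-matrix oracle on a dot centroid", {
  size <- 33
  img <- matrix(0, size, size)
  img[10, 22] <- 1
  rot15 <- sda_config(rotation_range = 15, hflip_prob = 0,
                      brightness_range = 0, contrast_range = 0)
  # find a seed whose drawn angle is close to +15 degrees, then check the
  # centroid against the closed-form rotation about the image centre
  for (seed in 1:200) {
    ang <- dreamon:::with_seed(seed, runif(1, -15, 15))
    if (ang > 14) {
      out <- standard_augment(img, rot15, seed = seed)
      th <- ang * pi / 180
      ctr <- (size + 1) / 2
      v <- c(10, 22) - ctr
      expected <- c(cos(th) * v[1] - sin(th) * v[2],
                    sin(th) * v[1] + cos(th) * v[2]) + ctr
      rows <- matrix(seq_len(size), size, size)
      cols <- t(rows)
      centroid <- c(sum(rows * out), sum(cols * out)) / sum(out)
      expect_lt(max(abs(centroid - expected)), 1)
      break
    }
  }
})

test_that("lambda draws follow Beta(alpha, alpha)", {
  set.seed(1)
  lam <- sample_lambda(mixup_config(alpha = 0.8), 1e5)
  expect_true(all(lam >= 0 & lam <= 1))
  expect_lt(abs(mean(lam) - 0.5), 3 * sd(lam) / sqrt(length(lam)))
  conc <- sample_lambda(mixup_config(alpha = 1e4), 1e4)
  expect_lt(var(conc), 1e-4)
})

test_that("pixel mixup interpolates pixels and labels convexly", {
  ds <- phantoms_16()$ds
  x <- list(pixels = ds$images[[1]], label = c(1, 0, 0))
  y <- list(pixels = ds$images[[2]], label = c(0, 1, 0))
  expect_identical(pixel_mixup(x, y, 1)$pixels, x$pixels)
  expect_identical(pixel_mixup(x, y, 1)$label, x$label)
  m <- pixel_mixup(x, y, 0.2)
  expect_equal(m$label, c(0.2, 0.8, 0))
  expect_equal(m$pixels, 0.2 * x$pixels + 0.8 * y$pixels)
  expect_null(m$mask)
  expect_identical(m$source, "pixel_mixup")
  # symmetry at lambda = 1/2
  expect_equal(pixel_mixup(x, y, 0.5)$pixels, pixel_mixup(y, x, 0.5)$pixels)
  expect_error(pixel_mixup(x, list(pixels = matrix(0, 2, 2),
                                   label = c(0, 0, 1)), 0.5),
               "dimensions")
})

test_that("manifold mixup reduces to pixel mixup at the input layer", {
  nn <- asNamespace("dreamon")
  set.seed(7)
  p <- nn$clf_new(8, 6, 1, 2)
  model <- list(params = p)
  A <- list(X = matrix(runif(4 * 8), 4),
            T = matrix(c(1, 0, 0), 4, 3, byrow = TRUE))
  B <- list(X = matrix(runif(4 * 8), 4),
            T = matrix(c(0, 1, 0), 4, 3, byrow = TRUE))
  lam <- 0.3
  mm0 <- manifold_mixup_step(model, A, B, lam, 0)
  fwd <- nn$clf_forward(p, lam * A$X + (1 - lam) * B$X)
  ref <- nn$soft_ce(fwd$logits, lam * A$T + (1 - lam) * B$T)
  expect_equal(mm0$loss, ref$loss)
  # lambda = 1 is the unmixed loss on batch_a at any layer
  for (layer in 0:2) {
    mm1 <- manifold_mixup_step(model, A, B, 1, layer)
    plain <- nn$soft_ce(nn$clf_forward(p, A$X)$logits, A$T)
    expect_equal(mm1$loss, plain$loss)
  }
  expect_error(manifold_mixup_step(model, A, B, 0.5, 5), "layer_index")
})

test_that("manifold mixup gradients match numerical differentiation", {
  nn <- asNamespace("dreamon")
  set.seed(8)
  p <- nn$clf_new(5, 4, 1, 2)
  A <- list(X = matrix(rnorm(3 * 5), 3),
            T = t(apply(matrix(runif(9), 3), 1, function(r) r / sum(r))))
  B <- list(X = matrix(rnorm(3 * 5), 3), T = A$T[c(2, 3, 1), ])
  lam <- 0.4
  for (layer in 0:2) {
    mm <- manifold_mixup_step(list(params = p), A, B, lam, layer)
    loss_at <- function(pp)
      manifold_mixup_step(list(params = pp), A, B, lam, layer)$loss
    eps <- 1e-6
    for (probe in list(c("Win", 2, 3), c("Wout", 1, 2))) {
      p1 <- p; p2 <- p
      p1[[probe[1]]][as.integer(probe[2]), as.integer(probe[3])] <-
        p1[[probe[1]]][as.integer(probe[2]), as.integer(probe[3])] + eps
      p2[[probe[1]]][as.integer(probe[2]), as.integer(probe[3])] <-
        p2[[probe[1]]][as.integer(probe[2]), as.integer(probe[3])] - eps
      num <- (loss_at(p1) - loss_at(p2)) / (2 * eps)
      ana <- mm$grads[[probe[1]]][as.integer(probe[2]), as.integer(probe[3])]
      expect_equal(ana, num, tolerance = 1e-5)
    }
    # a block weight inside stage 1 (upstream of layer-2 mixing)
    p1 <- p; p2 <- p
    p1$stages[[1]][[1]]$W1[2, 2] <- p1$stages[[1]][[1]]$W1[2, 2] + eps
    p2$stages[[1]][[1]]$W1[2, 2] <- p2$stages[[1]][[1]]$W1[2, 2] - eps
    num <- (loss_at(p1) - loss_at(p2)) / (2 * eps)
    expect_equal(mm$grads$stages[[1]][[1]]$W1[2, 2], num, tolerance = 1e-5)
  }
})

test_that("training-set composition follows the 600 + 600 rule", {
  ph <- phantoms_16()
  train <- ph$splits$train
  n <- length(train)
  gans <- gans_16()
  gen <- generate_dreamon_set(gans$G_m, gans$G_s, n, seed = 21)
  off <- generate_dreamoff_set(gans$G_m, gans$G_s, n, seed = 22)
  expect_identical(length(build_training_dataset("vanilla", train)), n)
  expect_identical(build_training_dataset("vanilla", train), train)
  for (strat in c("sda", "pixel_mixup", "manifold_mixup")) {
    out <- build_training_dataset(strat, train, seed = 3)
    expect_identical(length(out), 2L * n)
    # originals come first and untouched
    expect_identical(out$images[seq_len(n)], train$images)
    # label conservation: every label stays on the simplex
    expect_true(all(abs(rowSums(out$labels) - 1) < 1e-9))
  }
  for (strat in c("dreamon", "dreamoff")) {
    g <- if (strat == "dreamon") gen else off
    out <- build_training_dataset(strat, train, g, seed = 3)
    expect_identical(length(out), 2L * n)
    expect_identical(sum(out$source == strat), n)
  }
  out <- build_training_dataset("dreamon_sda", train, gen, seed = 3)
  expect_identical(length(out), 2L * n)
  # SDA on top of generated images transforms them
  expect_false(identical(out$images[(n + 1):(2 * n)], gen$images))
  expect_error(build_training_dataset("dreamon", train), "generated")
})

test_that("mixed records pair two source classes with convex labels", {
  train <- phantoms_16()$splits$train
  out <- build_training_dataset("pixel_mixup", train, seed = 11)
  mixed <- out[out$source == "pixel_mixup"]
  expect_identical(length(mixed), length(train))
  expect_true(all(abs(rowSums(mixed$labels) - 1) < 1e-9))
  # each mixed label is a convex combination of at most 2 one-hot parents
  expect_true(all(rowSums(mixed$labels > 0) <= 2))
  # parent bookkeeping: two distinct parents recorded per mixed record
  parents <- strsplit(mixed$parents, ";")
  expect_true(all(vapply(parents, length, 1L) == 2L))
  expect_true(all(vapply(parents, function(p) p[1] != p[2], TRUE)))
  # sda never changes labels
  sda_out <- build_training_dataset("sda", train, seed = 11)
  expect_identical(sda_out$labels,
                   rbind(train$labels, train$labels))
})
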