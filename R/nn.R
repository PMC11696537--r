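# Minimal dense neural-network engine.
#
# Both GAN pairs and the classifier run on this engine: fully connected
# layers, ReLU / leaky-ReLU / sigmoid / tanh activations, hand-derived
# backpropagation, and Adam. Everything is plain base-R matrix algebra
# (rows = samples), deterministic given the RNG state, and sized for
# desk-scale images (16-64 px). Gradients are verified against numerical
# differentiation in the test suite.

act_apply <- function(z, act) {
  switch(act,
    linear = z,
    relu = pmax(z, 0),
    lrelu = ifelse(z > 0, z, 0.2 * z),
    sigmoid = 1 / (1 + exp(-z)),
    tanh = tanh(z),
    stop("unknown activation ", act))
}

act_grad <- function(z, h, act) {
  switch(act,
    linear = 1,
    relu = (z > 0) * 1,
    lrelu = ifelse(z > 0, 1, 0.2),
    sigmoid = h * (1 - h),
    tanh = 1 - h^2)
}

softplus <- function(z) pmax(z, 0) + log1p(exp(-abs(z)))

# -- generic dense net ------------------------------------------------------

net_new <- function(sizes, acts) {
  stopifnot(length(acts) == length(sizes) - 1)
  layers <- lapply(seq_along(acts), function(l) {
    fan_in <- sizes[l]
    list(W = matrix(rnorm(fan_in * sizes[l + 1], 0, sqrt(2 / fan_in)),
                    fan_in, sizes[l + 1]),
         b = numeric(sizes[l + 1]))
  })
  list(layers = layers, acts = acts)
}

add_bias <- function(Z, b) Z + matrix(b, nrow(Z), length(b), byrow = TRUE)

net_forward <- function(net, X) {
  L <- length(net$layers)
  h <- vector("list", L + 1); z <- vector("list", L)
  h[[1]] <- X
  for (l in seq_len(L)) {
    z[[l]] <- add_bias(h[[l]] %*% net$layers[[l]]$W, net$layers[[l]]$b)
    h[[l + 1]] <- act_apply(z[[l]], net$acts[l])
  }
  list(out = h[[L + 1]], h = h, z = z)
}

net_backward <- function(net, cache, dout) {
  L <- length(net$layers)
  grads <- vector("list", L)
  dh <- dout
  for (l in rev(seq_len(L))) {
    dz <- dh * act_grad(cache$z[[l]], cache$h[[l + 1]], net$acts[l])
    grads[[l]] <- list(W = crossprod(cache$h[[l]], dz), b = colSums(dz))
    dh <- tcrossprod(dz, net$layers[[l]]$W)
  }
  list(grads = grads, dX = dh)
}

# -- Adam over nested parameter lists --------------------------------------

map_params <- function(f, a, b = NULL) {
  if (is.numeric(a)) return(if (is.null(b)) f(a) else f(a, b))
  out <- lapply(seq_along(a), function(i)
    map_params(f, a[[i]], if (is.null(b)) NULL else b[[i]]))
  names(out) <- names(a)
  out
}

adam_new <- function(params) {
  zeros <- map_params(function(p) p * 0, params)
  list(m = zeros, v = zeros, t = 0L)
}

adam_step <- function(params, grads, st, lr, betas = c(0.9, 0.999),
                      eps = 1e-8) {
  st$t <- st$t + 1L
  st$m <- map_params(function(m, g) betas[1] * m + (1 - betas[1]) * g,
                     st$m, grads)
  st$v <- map_params(function(v, g) betas[2] * v + (1 - betas[2]) * g^2,
                     st$v, grads)
  c1 <- 1 - betas[1]^st$t; c2 <- 1 - betas[2]^st$t
  upd <- map_params(function(m, v) lr * (m / c1) / (sqrt(v / c2) + eps),
                    st$m, st$v)
  list(params = map_params(`-`, params, upd), state = st)
}

net_params <- function(net) lapply(net$layers, function(l) l[c("W", "b")])

net_set_params <- function(net, params) {
  for (l in seq_along(params)) {
    net$layers[[l]]$W <- params[[l]]$W
    net$layers[[l]]$b <- params[[l]]$b
  }
  net
}

# -- residual classifier network -------------------------------------------
#
# x -> dense embed (ReLU) -> S residual stages -> linear head -> softmax.
# Each stage is a chain of pre-activation residual blocks
# h <- h + W2 relu(W1 h + b1) + b2. The enumerable manifold-mixup points are
# the raw input (0) and the output of each stage (1..S).

clf_new <- function(input_dim, hidden, n_blocks_per_stage, n_stages,
                    n_classes = 3) {
  stages <- lapply(seq_len(n_stages), function(s)
    lapply(seq_len(n_blocks_per_stage), function(b)
      list(W1 = matrix(rnorm(hidden^2, 0, sqrt(2 / hidden)), hidden, hidden),
           b1 = numeric(hidden),
           W2 = matrix(rnorm(hidden^2, 0, sqrt(1 / hidden) * 0.5),
                       hidden, hidden),
           b2 = numeric(hidden))))
  list(Win = matrix(rnorm(input_dim * hidden, 0, sqrt(2 / input_dim)),
                    input_dim, hidden),
       bin = numeric(hidden),
       stages = stages,
       Wout = matrix(rnorm(hidden * n_classes, 0, sqrt(1 / hidden)),
                     hidden, n_classes),
       bout = numeric(n_classes))
}

clf_embed <- function(p, X) {
  z <- add_bias(X %*% p$Win, p$bin)
  list(h = pmax(z, 0), z = z, X = X)
}

clf_block_fwd <- function(blk, h) {
  z1 <- add_bias(h %*% blk$W1, blk$b1)
  a1 <- pmax(z1, 0)
  z2 <- add_bias(a1 %*% blk$W2, blk$b2)
  list(h = h + z2, z1 = z1, a1 = a1, h_in = h)
}

clf_block_bwd <- function(blk, cache, dout) {
  gW2 <- crossprod(cache$a1, dout); gb2 <- colSums(dout)
  da1 <- tcrossprod(dout, blk$W2)
  dz1 <- da1 * (cache$z1 > 0)
  gW1 <- crossprod(cache$h_in, dz1); gb1 <- colSums(dz1)
  list(grads = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2),
       dh = dout + tcrossprod(dz1, blk$W1))
}

# forward from mixing point `from` (0 = raw input, s = after stage s).
# When from = 0, `h` is the raw (already mixed) input matrix.
clf_forward_from <- function(p, h, from) {
  caches <- list()
  if (from == 0) {
    caches$embed <- clf_embed(p, h)
    h <- caches$embed$h
  }
  S <- length(p$stages)
  caches$stages <- list()
  for (s in seq_len(S)) {
    if (s <= from) next
    st_cache <- list()
    for (b in seq_along(p$stages[[s]])) {
      bc <- clf_block_fwd(p$stages[[s]][[b]], h)
      h <- bc$h
      st_cache[[b]] <- bc
    }
    caches$stages[[as.character(s)]] <- st_cache
  }
  logits <- add_bias(h %*% p$Wout, p$bout)
  caches$h_last <- h
  list(logits = logits, caches = caches, from = from)
}

clf_forward <- function(p, X) clf_forward_from(p, X, 0)

# forward only up to mixing point `upto` (>= 1), returning hidden + caches
clf_forward_to <- function(p, X, upto) {
  caches <- list(embed = clf_embed(p, X))
  h <- caches$embed$h
  caches$stages <- list()
  for (s in seq_len(upto)) {
    st_cache <- list()
    for (b in seq_along(p$stages[[s]])) {
      bc <- clf_block_fwd(p$stages[[s]][[b]], h)
      h <- bc$h
      st_cache[[b]] <- bc
    }
    caches$stages[[as.character(s)]] <- st_cache
  }
  list(h = h, caches = caches)
}

zero_clf_grads <- function(p) map_params(function(x) x * 0, p)

acc_grads <- function(a, b) map_params(`+`, a, b)

# backward of clf_forward_from; returns grads (full structure, zeros for
# untouched layers) and the gradient wrt the input hidden state / raw input
clf_backward_from <- function(p, fwd, dlogits) {
  grads <- zero_clf_grads(p)
  grads$Wout <- crossprod(fwd$caches$h_last, dlogits)
  grads$bout <- colSums(dlogits)
  dh <- tcrossprod(dlogits, p$Wout)
  S <- length(p$stages)
  for (s in rev(seq_len(S))) {
    key <- as.character(s)
    if (is.null(fwd$caches$stages[[key]])) next
    for (b in rev(seq_along(p$stages[[s]]))) {
      bb <- clf_block_bwd(p$stages[[s]][[b]], fwd$caches$stages[[key]][[b]],
                          dh)
      grads$stages[[s]][[b]] <- bb$grads
      dh <- bb$dh
    }
  }
  if (fwd$from == 0) {
    ec <- fwd$caches$embed
    dz <- dh * (ec$z > 0)
    grads$Win <- crossprod(ec$X, dz)
    grads$bin <- colSums(dz)
    dh <- tcrossprod(dz, p$Win)
  }
  list(grads = grads, dh = dh)
}

# backward through a prefix built by clf_forward_to
clf_backward_prefix <- function(p, prefix, dh) {
  grads <- zero_clf_grads(p)
  for (s in rev(seq_along(prefix$caches$stages))) {
    for (b in rev(seq_along(prefix$caches$stages[[s]]))) {
      bb <- clf_block_bwd(p$stages[[s]][[b]], prefix$caches$stages[[s]][[b]],
                          dh)
      grads$stages[[s]][[b]] <- bb$grads
      dh <- bb$dh
    }
  }
  ec <- prefix$caches$embed
  dz <- dh * (ec$z > 0)
  grads$Win <- crossprod(ec$X, dz)
  grads$bin <- colSums(dz)
  grads
}

softmax_rows <- function(logits) {
  e <- exp(logits - apply(logits, 1, max))
  e / rowSums(e)
}

# soft-target cross-entropy: -mean_i sum_c T log P; dlogits = (P - T)/n
soft_ce <- function(logits, targets) {
  P <- softmax_rows(logits)
  loss <- -sum(targets * log(pmax(P, 1e-12))) / nrow(logits)
  list(loss = loss, dlogits = (P - targets) / nrow(logits))
}
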