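# Desk-scale neural-network primitives: a dense classification head with
# manual backpropagation, first-order optimizers, a tiny frozen
# convolutional feature extractor, and a tiny transformer encoder whose
# multi-head self-attention (MHSA) parameters can be fine-tuned.
#
# These stand in for ImageNet-pretrained backbones: the machinery under
# test (head search, training contracts, screening, pipeline wiring) is
# identical, only the representational power is scaled down to a single
# CPU. All initialization is seeded, so a backbone's features are a pure
# function of its name.

## ---- dense head -----------------------------------------------------------

mlp_init <- function(widths, seed) {
  with_seed(seed, {
    n_layers <- length(widths) - 1L
    W <- vector("list", n_layers)
    b <- vector("list", n_layers)
    for (i in seq_len(n_layers)) {
      W[[i]] <- matrix(
        stats::rnorm(widths[i] * widths[i + 1L], sd = sqrt(2 / widths[i])),
        widths[i], widths[i + 1L]
      )
      b[[i]] <- rep(0, widths[i + 1L])
    }
    list(W = W, b = b, widths = widths)
  })
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# Forward pass; dropout (inverted) is applied to the topmost hidden layer
# only, matching the "dropout at the top" head design.
mlp_forward <- function(head, X, dropout = 0, training = FALSE) {
  n_layers <- length(head$W)
  acts <- vector("list", n_layers + 1L)
  acts[[1L]] <- X
  drop_mask <- NULL
  for (i in seq_len(n_layers)) {
    z <- sweep(acts[[i]] %*% head$W[[i]], 2L, head$b[[i]], `+`)
    if (i < n_layers) {
      z[z < 0] <- 0
      if (training && dropout > 0 && i == n_layers - 1L) {
        drop_mask <- matrix(stats::runif(length(z)) >= dropout, nrow(z), ncol(z))
        z <- z * drop_mask / (1 - dropout)
      }
    }
    acts[[i + 1L]] <- z
  }
  probs <- softmax_rows(acts[[n_layers + 1L]])
  list(acts = acts, probs = probs, drop_mask = drop_mask, dropout = dropout)
}

# Mean cross-entropy against 0/1 labels (columns: negative, positive).
# Kullback-Leibler divergence against one-hot targets has the same
# gradient, so both loss names share this path.
mlp_loss <- function(probs, y) {
  p <- probs[cbind(seq_along(y), y + 1L)]
  -mean(log(pmax(p, 1e-12)))
}

# Backward pass; returns parameter gradients and the gradient w.r.t. the
# input features (needed when a transformer backbone is fine-tuned below
# the head).
mlp_backward <- function(head, fwd, y) {
  n <- length(y)
  n_layers <- length(head$W)
  Y <- matrix(0, n, 2L)
  Y[cbind(seq_len(n), y + 1L)] <- 1
  delta <- (fwd$probs - Y) / n
  dW <- vector("list", n_layers)
  db <- vector("list", n_layers)
  for (i in rev(seq_len(n_layers))) {
    dW[[i]] <- crossprod(fwd$acts[[i]], delta)
    db[[i]] <- colSums(delta)
    if (i > 1L) {
      delta <- delta %*% t(head$W[[i]])
      if (!is.null(fwd$drop_mask) && i - 1L == n_layers - 1L) {
        delta <- delta * fwd$drop_mask / (1 - fwd$dropout)
      }
      delta[fwd$acts[[i]] <= 0] <- 0
    } else {
      delta <- delta %*% t(head$W[[1L]])
    }
  }
  list(dW = dW, db = db, dX = delta)
}

## ---- optimizers -----------------------------------------------------------

# A flat-vector optimizer: parameters are concatenated into one numeric
# vector by the caller. Supported: sgd (momentum 0.9), adam, adamw (0.01
# decoupled weight decay), adamax, rmsprop.
optimizer_new <- function(name, n_params, lr) {
  name <- tolower(name)
  if (!name %in% c("sgd", "adam", "adamw", "adamax", "rmsprop")) {
    stop("unknown optimizer: ", name)
  }
  env <- new.env(parent = emptyenv())
  env$name <- name
  env$lr <- lr
  env$t <- 0L
  env$m <- numeric(n_params)
  env$v <- numeric(n_params)
  env
}

optimizer_step <- function(opt, theta, grad) {
  opt$t <- opt$t + 1L
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  switch(opt$name,
    sgd = {
      opt$m <- b1 * opt$m + grad
      theta - opt$lr * opt$m
    },
    adam = ,
    adamw = {
      opt$m <- b1 * opt$m + (1 - b1) * grad
      opt$v <- b2 * opt$v + (1 - b2) * grad^2
      mhat <- opt$m / (1 - b1^opt$t)
      vhat <- opt$v / (1 - b2^opt$t)
      out <- theta - opt$lr * mhat / (sqrt(vhat) + eps)
      if (opt$name == "adamw") out <- out - opt$lr * 0.01 * theta
      out
    },
    adamax = {
      opt$m <- b1 * opt$m + (1 - b1) * grad
      opt$v <- pmax(b2 * opt$v, abs(grad))
      theta - opt$lr / (1 - b1^opt$t) * opt$m / (opt$v + eps)
    },
    rmsprop = {
      opt$v <- 0.9 * opt$v + 0.1 * grad^2
      theta - opt$lr * grad / (sqrt(opt$v) + eps)
    }
  )
}

# Helpers to flatten/unflatten a head's parameters for the optimizer.
head_flatten <- function(head) {
  unlist(c(head$W, head$b), use.names = FALSE)
}

head_unflatten <- function(head, theta) {
  pos <- 0L
  for (i in seq_along(head$W)) {
    n <- length(head$W[[i]])
    head$W[[i]][] <- theta[pos + seq_len(n)]
    pos <- pos + n
  }
  for (i in seq_along(head$b)) {
    n <- length(head$b[[i]])
    head$b[[i]][] <- theta[pos + seq_len(n)]
    pos <- pos + n
  }
  head
}

## ---- tiny frozen CNN backbone ---------------------------------------------

# 3x3 valid convolution of a matrix with one kernel, via shift-and-add.
conv3x3 <- function(m, k) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h - 2L, w - 2L)
  for (dy in 0:2) {
    for (dx in 0:2) {
      out <- out + k[dy + 1L, dx + 1L] *
        m[(1L + dy):(h - 2L + dy), (1L + dx):(w - 2L + dx)]
    }
  }
  out
}

pool2x2 <- function(m) {
  h <- 2L * (nrow(m) %/% 2L); w <- 2L * (ncol(m) %/% 2L)
  m <- m[1:h, 1:w, drop = FALSE]
  0.25 * (m[seq(1, h, 2), seq(1, w, 2), drop = FALSE] +
          m[seq(2, h, 2), seq(1, w, 2), drop = FALSE] +
          m[seq(1, h, 2), seq(2, w, 2), drop = FALSE] +
          m[seq(2, h, 2), seq(2, w, 2), drop = FALSE])
}

tiny_cnn_init <- function(seed, output_width = 1000L, n_filters = 8L,
                          input_size = 32L) {
  with_seed(seed, {
    filters <- lapply(seq_len(n_filters), function(i) {
      k <- matrix(stats::rnorm(9L), 3L, 3L)
      k - mean(k)   # zero-mean kernels respond to texture, not offset
    })
    # keep one DC-preserving filter so global luminance stays linearly
    # decodable from the feature vector
    filters[[1L]] <- matrix(1 / 9, 3L, 3L)
    fdim <- n_filters * ((input_size - 2L) %/% 2L)^2
    proj <- matrix(stats::rnorm(fdim * output_width, sd = 1 / sqrt(fdim)),
                   fdim, output_width)
    list(filters = filters, proj = proj, input_size = input_size,
         output_width = output_width)
  })
}

tiny_cnn_featurize_one <- function(p, img) {
  y <- luminance(img) / 255
  if (!all(dim(y) == p$input_size)) {
    y <- area_resample(y, p$input_size, p$input_size)
  }
  maps <- lapply(p$filters, function(k) {
    r <- conv3x3(y, k)
    r[r < 0] <- 0
    pool2x2(r)
  })
  as.vector(vapply(maps, as.vector, numeric(length(as.vector(maps[[1L]]))))) %*%
    p$proj
}

tiny_cnn_featurize <- function(p, imgs) {
  t(vapply(imgs, function(im) as.numeric(tiny_cnn_featurize_one(p, im)),
           numeric(p$output_width)))
}

## ---- tiny transformer backbone --------------------------------------------

# Configuration: 16 patch tokens (input resampled to 64x64, 16x16
# patches), embedding dim 16, 2 encoder blocks, 2 attention heads, no
# layer norm (a documented desk-scale simplification). Only Wq/Wk/Wv/Wo
# are treated as MHSA parameters; patch embedding, position embeddings,
# class token, feed-forward layers, and the final 1000-wide projection
# are frozen.
tiny_vit_config <- function() {
  list(img = 64L, patch = 16L, d = 16L, heads = 2L, layers = 2L,
       ffn_hidden = 32L, output_width = 1000L)
}

tiny_vit_init <- function(seed, cfg = tiny_vit_config()) {
  with_seed(seed, {
    pdim <- cfg$patch^2
    n_tok <- (cfg$img %/% cfg$patch)^2 + 1L
    rm_ <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)
    layers <- lapply(seq_len(cfg$layers), function(i) {
      list(
        Wq = rm_(cfg$d, cfg$d, 1 / sqrt(cfg$d)),
        Wk = rm_(cfg$d, cfg$d, 1 / sqrt(cfg$d)),
        Wv = rm_(cfg$d, cfg$d, 1 / sqrt(cfg$d)),
        Wo = rm_(cfg$d, cfg$d, 1 / sqrt(cfg$d)),
        W1 = rm_(cfg$d, cfg$ffn_hidden, 1 / sqrt(cfg$d)),
        b1 = rep(0, cfg$ffn_hidden),
        W2 = rm_(cfg$ffn_hidden, cfg$d, 1 / sqrt(cfg$ffn_hidden)),
        b2 = rep(0, cfg$d)
      )
    })
    list(
      cfg = cfg,
      embed = rm_(pdim, cfg$d, 1 / sqrt(pdim)),
      embed_b = rep(0, cfg$d),
      cls = rm_(1L, cfg$d, 0.02),
      pos = rm_(n_tok, cfg$d, 0.02),
      layers = layers,
      proj = rm_(cfg$d, cfg$output_width, 1 / sqrt(cfg$d)),
      proj_b = rep(0, cfg$output_width)
    )
  })
}

vit_tokens <- function(vp, img) {
  cfg <- vp$cfg
  y <- luminance(img) / 255
  if (!all(dim(y) == cfg$img)) y <- area_resample(y, cfg$img, cfg$img)
  g <- cfg$img %/% cfg$patch
  X0 <- matrix(0, g * g, cfg$patch^2)
  idx <- 1L
  for (r in seq_len(g)) {
    for (c in seq_len(g)) {
      patch <- y[((r - 1L) * cfg$patch + 1L):(r * cfg$patch),
                 ((c - 1L) * cfg$patch + 1L):(c * cfg$patch)]
      X0[idx, ] <- as.vector(patch)
      idx <- idx + 1L
    }
  }
  T0 <- sweep(X0 %*% vp$embed, 2L, vp$embed_b, `+`)
  rbind(vp$cls, T0) + vp$pos
}

attn_forward <- function(layer, X, heads) {
  d <- ncol(X); dh <- d %/% heads
  Q <- X %*% layer$Wq; K <- X %*% layer$Wk; V <- X %*% layer$Wv
  O <- matrix(0, nrow(X), d)
  Pr <- vector("list", heads)
  for (h in seq_len(heads)) {
    cols <- ((h - 1L) * dh + 1L):(h * dh)
    S <- tcrossprod(Q[, cols, drop = FALSE], K[, cols, drop = FALSE]) / sqrt(dh)
    P <- softmax_rows(S)
    O[, cols] <- P %*% V[, cols, drop = FALSE]
    Pr[[h]] <- P
  }
  list(A = O %*% layer$Wo, Q = Q, K = K, V = V, O = O, Pr = Pr)
}

# Backward through one attention sub-layer. Returns gradients of the four
# projection matrices and of the input X.
attn_backward <- function(layer, X, cache, dA, heads) {
  d <- ncol(X); dh <- d %/% heads
  dO <- dA %*% t(layer$Wo)
  dWo <- crossprod(cache$O, dA)
  dQ <- matrix(0, nrow(X), d); dK <- dQ; dV <- dQ
  for (h in seq_len(heads)) {
    cols <- ((h - 1L) * dh + 1L):(h * dh)
    P <- cache$Pr[[h]]
    dOh <- dO[, cols, drop = FALSE]
    Vh <- cache$V[, cols, drop = FALSE]
    dP <- tcrossprod(dOh, Vh)
    dV[, cols] <- crossprod(P, dOh)
    dS <- P * (dP - rowSums(dP * P))
    dS <- dS / sqrt(dh)
    dQ[, cols] <- dS %*% cache$K[, cols, drop = FALSE]
    dK[, cols] <- crossprod(dS, cache$Q[, cols, drop = FALSE])
  }
  list(
    dWq = crossprod(X, dQ), dWk = crossprod(X, dK), dWv = crossprod(X, dV),
    dWo = dWo,
    dX = dQ %*% t(layer$Wq) + dK %*% t(layer$Wk) + dV %*% t(layer$Wv)
  )
}

vit_forward_one <- function(vp, img, keep_cache = FALSE) {
  cfg <- vp$cfg
  X <- vit_tokens(vp, img)
  caches <- if (keep_cache) vector("list", cfg$layers) else NULL
  for (i in seq_len(cfg$layers)) {
    l <- vp$layers[[i]]
    at <- attn_forward(l, X, cfg$heads)
    X1 <- X + at$A
    Z <- sweep(X1 %*% l$W1, 2L, l$b1, `+`)
    H <- Z; H[H < 0] <- 0
    X2 <- X1 + sweep(H %*% l$W2, 2L, l$b2, `+`)
    if (keep_cache) caches[[i]] <- list(X = X, at = at, X1 = X1, Z = Z, H = H)
    X <- X2
  }
  feat <- as.numeric(X[1L, , drop = FALSE] %*% vp$proj + vp$proj_b)
  list(feat = feat, caches = caches)
}

# Backward from a gradient on the 1000-wide feature vector down to the
# MHSA parameter gradients of every layer.
vit_backward_one <- function(vp, caches, dfeat) {
  cfg <- vp$cfg
  n_tok <- nrow(caches[[1L]]$X)
  dX <- matrix(0, n_tok, cfg$d)
  dX[1L, ] <- as.numeric(vp$proj %*% dfeat)
  grads <- vector("list", cfg$layers)
  for (i in rev(seq_len(cfg$layers))) {
    l <- vp$layers[[i]]
    ca <- caches[[i]]
    dH <- dX %*% t(l$W2)
    dZ <- dH * (ca$Z > 0)
    dX1 <- dX + dZ %*% t(l$W1)
    ab <- attn_backward(l, ca$X, ca$at, dX1, cfg$heads)
    grads[[i]] <- ab[c("dWq", "dWk", "dWv", "dWo")]
    dX <- dX1 + ab$dX
  }
  grads
}

vit_featurize <- function(vp, imgs) {
  t(vapply(imgs, function(im) vit_forward_one(vp, im)$feat,
           numeric(vp$cfg$output_width)))
}

vit_mhsa_flatten <- function(vp) {
  unlist(lapply(vp$layers, function(l) c(l$Wq, l$Wk, l$Wv, l$Wo)),
         use.names = FALSE)
}

vit_mhsa_unflatten <- function(vp, theta) {
  pos <- 0L
  n <- vp$cfg$d^2
  for (i in seq_along(vp$layers)) {
    for (nm in c("Wq", "Wk", "Wv", "Wo")) {
      vp$layers[[i]][[nm]][] <- theta[pos + seq_len(n)]
      pos <- pos + n
    }
  }
  vp
}

vit_mhsa_grad_flatten <- function(grads) {
  unlist(lapply(grads, function(g) c(g$dWq, g$dWk, g$dWv, g$dWo)),
         use.names = FALSE)
}
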