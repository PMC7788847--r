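# Minimal encoder-decoder (U-style) segmentation network on base-R matrix
# algebra. Feature maps live as (batch * height * width) x channels matrices
# in column-major raster order, images stacked along rows; 3x3 "same"
# convolutions are gather + GEMM (im2col), so the heavy lifting is BLAS.

# Gather/scatter index tables for a given spatial size and batch, cached per
# (h, w, batch) in the model's private environment.
conv_indices <- function(h, w, batch) {
  n <- h * w
  guard <- batch * n + 1L
  rr <- rep.int(seq_len(h), w)            # 1-based row of each raster position
  cc <- rep(seq_len(w), each = h)
  offs <- cbind(rep(c(-1L, 0L, 1L), 3L), rep(c(-1L, 0L, 1L), each = 3L))
  idx <- vector("list", 9L)
  valid <- vector("list", 9L)
  for (k in 1:9) {
    nr <- rr + offs[k, 1L]; nc <- cc + offs[k, 2L]
    ok <- nr >= 1L & nr <= h & nc >= 1L & nc <= w
    base <- ifelse(ok, (nc - 1L) * h + nr, NA_integer_)
    full <- integer(batch * n)
    for (b in seq_len(batch)) {
      seg <- base + (b - 1L) * n
      seg[is.na(seg)] <- guard
      full[((b - 1L) * n + 1L):(b * n)] <- seg
    }
    idx[[k]] <- full
    valid[[k]] <- which(full != guard)
  }
  list(idx = idx, valid = valid, n = batch * n)
}

pool_indices <- function(h, w, batch) {
  h2 <- h %/% 2L; w2 <- w %/% 2L
  n_in <- h * w
  rr <- rep.int(seq_len(h2), w2)
  cc <- rep(seq_len(w2), each = h2)
  ch <- vector("list", 4L)
  k <- 0L
  for (dc in 0:1) for (dr in 0:1) {
    k <- k + 1L
    base <- (2L * cc - 2L + dc) * h + (2L * rr - 1L + dr)
    ch[[k]] <- as.vector(outer(base, (seq_len(batch) - 1L) * n_in, `+`))
  }
  ch
}

he_init <- function(fan_in, n_out) {
  matrix(stats::rnorm(fan_in * n_out, 0, sqrt(2 / fan_in)), fan_in, n_out)
}

new_conv <- function(c_in, c_out, ksize = 3L) {
  fan <- ksize * ksize * c_in
  list(W = he_init(fan, c_out), b = numeric(c_out), k = ksize)
}

# Build the parameter list for a U-shaped net: `depth` pooling levels with
# `convs` 3x3 conv+ReLU layers per block, channels doubling per level, skip
# concatenation on the way up, 1x1 output conv to a single logit channel.
unet_params <- function(depth, base_channels, convs = 2L) {
  ch <- base_channels * 2L^(0:(depth))      # enc channels + bottleneck
  enc <- vector("list", depth)
  c_prev <- 1L
  for (i in seq_len(depth)) {
    blk <- vector("list", convs)
    for (j in seq_len(convs)) {
      blk[[j]] <- new_conv(if (j == 1L) c_prev else ch[i], ch[i])
    }
    enc[[i]] <- blk
    c_prev <- ch[i]
  }
  bott <- vector("list", convs)
  for (j in seq_len(convs))
    bott[[j]] <- new_conv(if (j == 1L) ch[depth] else ch[depth + 1L], ch[depth + 1L])
  dec <- vector("list", depth)
  for (i in depth:1) {
    c_below <- if (i == depth) ch[depth + 1L] else ch[i + 1L]
    blk <- vector("list", convs)
    for (j in seq_len(convs))
      blk[[j]] <- new_conv(if (j == 1L) c_below + ch[i] else ch[i], ch[i])
    dec[[i]] <- blk
  }
  list(enc = enc, bott = bott, dec = dec,
       out = new_conv(ch[1L], 1L, ksize = 1L),
       depth = depth, convs = convs, channels = ch)
}

conv3_forward <- function(Xa, layer, gi) {
  cin <- ncol(Xa)
  patches <- matrix(0, gi$n, 9L * cin)
  for (k in 1:9)
    patches[, ((k - 1L) * cin + 1L):(k * cin)] <- Xa[gi$idx[[k]], , drop = FALSE]
  Y <- patches %*% layer$W
  Y <- sweep_add(Y, layer$b)
  list(Y = Y, patches = patches)
}

conv3_backward <- function(dY, cache, layer, gi, need_dX = TRUE) {
  dW <- crossprod(cache$patches, dY)
  db <- colSums(dY)
  dX <- NULL
  if (need_dX) {
    cin <- ncol(cache$patches) / 9L
    dpatch <- dY %*% t(layer$W)
    dXa <- matrix(0, gi$n + 1L, cin)
    for (k in 1:9) {
      v <- gi$valid[[k]]
      rows <- gi$idx[[k]][v]
      dXa[rows, ] <- dXa[rows, ] + dpatch[v, ((k - 1L) * cin + 1L):(k * cin), drop = FALSE]
    }
    dX <- dXa[-(gi$n + 1L), , drop = FALSE]
  }
  list(dW = dW, db = db, dX = dX)
}

sweep_add <- function(M, b) {
  if (length(b) == 1L) M + b else M + rep(b, each = nrow(M))
}

relu_forward <- function(X) {
  mask <- X > 0
  list(Y = X * mask, mask = mask)
}

maxpool_forward <- function(X, ch) {
  g1 <- X[ch[[1L]], , drop = FALSE]; g2 <- X[ch[[2L]], , drop = FALSE]
  g3 <- X[ch[[3L]], , drop = FALSE]; g4 <- X[ch[[4L]], , drop = FALSE]
  M <- pmax(g1, g2, g3, g4)
  a1 <- g1 == M
  a2 <- (g2 == M) & !a1
  a3 <- (g3 == M) & !(a1 | a2)
  a4 <- !(a1 | a2 | a3)
  list(Y = M, a = list(a1, a2, a3, a4))
}

maxpool_backward <- function(dM, cache, ch, n_in, nc) {
  dX <- matrix(0, n_in, nc)
  for (k in 1:4) dX[ch[[k]], ] <- dM * cache$a[[k]]
  dX
}

upsample_forward <- function(X, ch, n_out) {
  Y <- matrix(0, n_out, ncol(X))
  for (k in 1:4) Y[ch[[k]], ] <- X
  Y
}

upsample_backward <- function(dY, ch) {
  dY[ch[[1L]], , drop = FALSE] + dY[ch[[2L]], , drop = FALSE] +
    dY[ch[[3L]], , drop = FALSE] + dY[ch[[4L]], , drop = FALSE]
}

augment_guard <- function(X) rbind(X, 0)

block_forward <- function(X, block, gi) {
  caches <- vector("list", length(block))
  for (j in seq_along(block)) {
    cf <- conv3_forward(augment_guard(X), block[[j]], gi)
    rf <- relu_forward(cf$Y)
    caches[[j]] <- list(conv = cf, relu = rf)
    X <- rf$Y
  }
  list(Y = X, caches = caches)
}

block_backward <- function(dY, block, caches, gi, need_dX = TRUE) {
  grads <- vector("list", length(block))
  for (j in rev(seq_along(block))) {
    dY <- dY * caches[[j]]$relu$mask
    gb <- conv3_backward(dY, caches[[j]]$conv, block[[j]], gi,
                         need_dX = need_dX || j > 1L)
    grads[[j]] <- list(dW = gb$dW, db = gb$db)
    dY <- gb$dX
  }
  list(dX = dY, grads = grads)
}

# Full forward pass; sizes = list of per-level (h, w); tabs = cached index
# tables. Returns logits plus all caches needed for backprop.
unet_forward <- function(par, X, tabs) {
  d <- par$depth
  skips <- vector("list", d)
  enc_caches <- vector("list", d)
  pool_caches <- vector("list", d)
  for (i in seq_len(d)) {
    bf <- block_forward(X, par$enc[[i]], tabs$conv[[i]])
    enc_caches[[i]] <- bf$caches
    skips[[i]] <- bf$Y
    pf <- maxpool_forward(bf$Y, tabs$pool[[i]])
    pool_caches[[i]] <- pf
    X <- pf$Y
  }
  bb <- block_forward(X, par$bott, tabs$conv[[d + 1L]])
  X <- bb$Y
  dec_caches <- vector("list", d)
  for (i in d:1) {
    X <- upsample_forward(X, tabs$pool[[i]], tabs$n[[i]])
    X <- cbind(X, skips[[i]])
    bf <- block_forward(X, par$dec[[i]], tabs$conv[[i]])
    dec_caches[[i]] <- bf$caches
    X <- bf$Y
  }
  z <- X %*% par$out$W
  z <- z + par$out$b
  list(z = as.vector(z), last = X, enc = enc_caches, pool = pool_caches,
       bott = bb$caches, dec = dec_caches)
}

ncol_below <- function(par, i) {
  if (i == par$depth) par$channels[par$depth + 1L] else par$channels[i + 1L]
}

# Reverse-mode pass mirroring unet_forward. The decoder runs levels 1..d
# (innermost skip last), then the bottleneck, then the encoder d..1 where the
# skip gradient joins the pooled-path gradient.
unet_backward <- function(par, fw, dz, tabs) {
  d <- par$depth
  g <- list(enc = vector("list", d), dec = vector("list", d))
  g$out <- list(dW = crossprod(fw$last, matrix(dz)), db = sum(dz))
  dU <- matrix(dz) %*% t(par$out$W)      # grad at decoder block 1 output
  d_skip <- vector("list", d)
  for (i in 1:d) {
    bb <- block_backward(dU, par$dec[[i]], fw$dec[[i]], tabs$conv[[i]])
    g$dec[[i]] <- bb$grads
    c_below <- ncol_below(par, i)
    d_up <- bb$dX[, seq_len(c_below), drop = FALSE]
    d_skip[[i]] <- bb$dX[, -seq_len(c_below), drop = FALSE]
    dU <- upsample_backward(d_up, tabs$pool[[i]])
  }
  bb <- block_backward(dU, par$bott, fw$bott, tabs$conv[[d + 1L]])
  g$bott <- bb$grads
  dP <- bb$dX                             # grad at pool_d output
  for (i in d:1) {
    dS <- d_skip[[i]] +
      maxpool_backward(dP, fw$pool[[i]], tabs$pool[[i]], tabs$n[[i]],
                       ncol(d_skip[[i]]))
    bb <- block_backward(dS, par$enc[[i]], fw$enc[[i]], tabs$conv[[i]],
                         need_dX = i > 1L)
    g$enc[[i]] <- bb$grads
    if (i > 1L) dP <- bb$dX
  }
  g
}

# --- Adam optimiser over the nested parameter list ---

flatten_convs <- function(par) {
  out <- list()
  for (i in seq_along(par$enc)) for (j in seq_along(par$enc[[i]]))
    out[[length(out) + 1L]] <- c("enc", i, j)
  for (j in seq_along(par$bott))
    out[[length(out) + 1L]] <- c("bott", 0L, j)
  for (i in seq_along(par$dec)) for (j in seq_along(par$dec[[i]]))
    out[[length(out) + 1L]] <- c("dec", i, j)
  out[[length(out) + 1L]] <- c("out", 0L, 0L)
  out
}

get_layer <- function(par, key) {
  if (key[1L] == "out") par$out
  else if (key[1L] == "bott") par$bott[[as.integer(key[3L])]]
  else par[[key[1L]]][[as.integer(key[2L])]][[as.integer(key[3L])]]
}

set_layer <- function(par, key, layer) {
  if (key[1L] == "out") par$out <- layer
  else if (key[1L] == "bott") par$bott[[as.integer(key[3L])]] <- layer
  else par[[key[1L]]][[as.integer(key[2L])]][[as.integer(key[3L])]] <- layer
  par
}

get_grad <- function(g, key) {
  if (key[1L] == "out") g$out
  else if (key[1L] == "bott") g$bott[[as.integer(key[3L])]]
  else g[[key[1L]]][[as.integer(key[2L])]][[as.integer(key[3L])]]
}

adam_init <- function(par) {
  keys <- flatten_convs(par)
  st <- lapply(keys, function(k) {
    l <- get_layer(par, k)
    list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0)
  })
  list(keys = keys, st = st, t = 0L)
}

adam_step <- function(par, g, opt, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (ki in seq_along(opt$keys)) {
    k <- opt$keys[[ki]]
    l <- get_layer(par, k)
    gr <- get_grad(g, k)
    s <- opt$st[[ki]]
    s$mW <- beta1 * s$mW + (1 - beta1) * gr$dW
    s$vW <- beta2 * s$vW + (1 - beta2) * gr$dW^2
    s$mb <- beta1 * s$mb + (1 - beta1) * gr$db
    s$vb <- beta2 * s$vb + (1 - beta2) * gr$db^2
    l$W <- l$W - lr * (s$mW / bc1) / (sqrt(s$vW / bc2) + eps)
    l$b <- l$b - lr * (s$mb / bc1) / (sqrt(s$vb / bc2) + eps)
    opt$st[[ki]] <- s
    par <- set_layer(par, k, l)
  }
  list(par = par, opt = opt)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# Loss and gradient wrt logits for a batch; z, t are vectors of length
# batch*h*w grouped by image. Dice loss is computed per image and averaged.
seg_loss <- function(z, t, n_per_image, loss = c("sum", "dice", "cross-entropy")) {
  loss <- match.arg(loss)
  p <- sigmoid(z)
  n <- length(z)
  L <- 0; dz <- numeric(n)
  if (loss %in% c("sum", "cross-entropy")) {
    # numerically stable BCE on logits
    L <- L + mean(pmax(z, 0) - z * t + log1p(exp(-abs(z))))
    dz <- dz + (p - t) / n
  }
  if (loss %in% c("sum", "dice")) {
    eps <- 1e-6
    n_img <- n / n_per_image
    for (b in seq_len(n_img)) {
      ii <- ((b - 1L) * n_per_image + 1L):(b * n_per_image)
      pb <- p[ii]; tb <- t[ii]
      A <- sum(pb * tb); B <- sum(pb) + sum(tb)
      L <- L + (1 - (2 * A + eps) / (B + eps)) / n_img
      dLdp <- -(2 * tb * (B + eps) - (2 * A + eps)) / (B + eps)^2 / n_img
      dz[ii] <- dz[ii] + dLdp * pb * (1 - pb)
    }
  }
  list(loss = L, dz = dz)
}
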