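# Compact U-Net internals: parameter initialisation, forward/backward pass
# and Adam. Convolution/pool/upsample primitives live in src/conv_net.cpp
# (im2col + GEMM). Parameters are a flat named list of arrays so the
# optimiser can walk them generically.
#
# Architecture (depth d, base channels c): encoder levels l = 1..d with two
# 3x3 conv+ReLU (channels c*2^(l-1)) and 2x2 max pooling; a two-conv
# bottleneck at c*2^d; decoder levels with nearest-neighbour upsampling, a
# 3x3 conv, skip concatenation and two 3x3 conv+ReLU; a 1x1 conv head to
# class logits with per-pixel softmax.

unet_init <- function(depth, base, in_ch = 1L, n_classes = 3L) {
  conv_par <- function(cin, cout) {
    list(W = matrix(rnorm(cout * 9 * cin, 0, sqrt(2 / (9 * cin))),
                    cout, 9 * cin),
         b = numeric(cout))
  }
  ch <- base * 2^(0:depth)  # enc channels c_1..c_d, bottleneck c_{d+1}
  p <- list()
  cin <- in_ch
  for (l in seq_len(depth)) {
    cp <- conv_par(cin, ch[l]); p[[sprintf("e%dc1W", l)]] <- cp$W
    p[[sprintf("e%dc1b", l)]] <- cp$b
    cp <- conv_par(ch[l], ch[l]); p[[sprintf("e%dc2W", l)]] <- cp$W
    p[[sprintf("e%dc2b", l)]] <- cp$b
    cin <- ch[l]
  }
  cp <- conv_par(ch[depth], ch[depth + 1])
  p$bc1W <- cp$W; p$bc1b <- cp$b
  cp <- conv_par(ch[depth + 1], ch[depth + 1])
  p$bc2W <- cp$W; p$bc2b <- cp$b
  for (l in seq_len(depth)) {
    cp <- conv_par(ch[l + 1], ch[l])
    p[[sprintf("d%duW", l)]] <- cp$W; p[[sprintf("d%dub", l)]] <- cp$b
    cp <- conv_par(2 * ch[l], ch[l])
    p[[sprintf("d%dc1W", l)]] <- cp$W; p[[sprintf("d%dc1b", l)]] <- cp$b
    cp <- conv_par(ch[l], ch[l])
    p[[sprintf("d%dc2W", l)]] <- cp$W; p[[sprintf("d%dc2b", l)]] <- cp$b
  }
  cp <- list(W = matrix(rnorm(n_classes * ch[1], 0, sqrt(2 / ch[1])),
                        n_classes, ch[1]),
             b = numeric(n_classes))
  p$hW <- cp$W; p$hb <- cp$b
  list(params = p,
       arch = list(depth = depth, base = base, in_ch = in_ch,
                   n_classes = n_classes))
}

unet_forward <- function(params, arch, x, want_cache = FALSE) {
  depth <- arch$depth
  cache <- if (want_cache) new.env(parent = emptyenv()) else NULL
  conv_relu <- function(h, key) {
    z <- .conv2d_forward_cpp(h, params[[paste0(key, "W")]],
                             params[[paste0(key, "b")]])
    if (want_cache) {
      assign(paste0(key, "_in"), h, envir = cache)
      assign(paste0(key, "_z"), z, envir = cache)
    }
    array(pmax(z, 0), dim(z))
  }
  skips <- vector("list", depth)
  h <- x
  for (l in seq_len(depth)) {
    h <- conv_relu(h, sprintf("e%dc1", l))
    h <- conv_relu(h, sprintf("e%dc2", l))
    skips[[l]] <- h
    mp <- .maxpool2_forward_cpp(h)
    if (want_cache)
      assign(sprintf("pool%d", l),
             list(idx = mp$idx, H = dim(h)[1], W = dim(h)[2]), envir = cache)
    h <- mp$y
  }
  h <- conv_relu(h, "bc1")
  h <- conv_relu(h, "bc2")
  for (l in rev(seq_len(depth))) {
    h <- .upsample2_forward_cpp(h)
    h <- conv_relu(h, sprintf("d%du", l))
    sk <- skips[[l]]
    h <- array(c(sk, h), c(dim(sk)[1], dim(sk)[2], dim(sk)[3] + dim(h)[3]))
    if (want_cache)
      assign(sprintf("d%d_ncat", l), dim(sk)[3], envir = cache)
    h <- conv_relu(h, sprintf("d%dc1", l))
    h <- conv_relu(h, sprintf("d%dc2", l))
  }
  if (want_cache) assign("head_in", h, envir = cache)
  hw <- dim(h)[1] * dim(h)[2]
  xm <- matrix(h, hw, dim(h)[3])
  logits <- sweep(xm %*% t(params$hW), 2, params$hb, "+")
  lm <- logits - apply(logits, 1, max)
  el <- exp(lm)
  prob <- el / rowSums(el)
  dim(prob) <- c(dim(h)[1], dim(h)[2], arch$n_classes)
  list(prob = prob, cache = cache)
}

# glogits: (H*W x n_classes) matrix of the loss gradient w.r.t. the logits
unet_backward <- function(params, arch, fwd, glogits) {
  depth <- arch$depth
  cache <- fwd$cache
  grads <- list()
  conv_relu_bwd <- function(g, key) {
    z <- get(paste0(key, "_z"), envir = cache)
    g <- array(g * (z > 0), dim(z))
    bw <- .conv2d_backward_cpp(get(paste0(key, "_in"), envir = cache),
                               params[[paste0(key, "W")]], g)
    grads[[paste0(key, "W")]] <<- bw$gw
    grads[[paste0(key, "b")]] <<- as.numeric(bw$gb)
    bw$gx
  }
  h <- get("head_in", envir = cache)
  hw <- dim(h)[1] * dim(h)[2]
  xm <- matrix(h, hw, dim(h)[3])
  grads$hW <- t(glogits) %*% xm
  grads$hb <- colSums(glogits)
  g <- array(glogits %*% params$hW, dim(h))
  gskips <- vector("list", depth)
  for (l in seq_len(depth)) {
    g <- conv_relu_bwd(g, sprintf("d%dc2", l))
    g <- conv_relu_bwd(g, sprintf("d%dc1", l))
    ncat <- get(sprintf("d%d_ncat", l), envir = cache)
    gskips[[l]] <- g[, , seq_len(ncat), drop = FALSE]
    g <- g[, , -seq_len(ncat), drop = FALSE]
    g <- conv_relu_bwd(g, sprintf("d%du", l))
    g <- .upsample2_backward_cpp(g)
  }
  g <- conv_relu_bwd(g, "bc2")
  g <- conv_relu_bwd(g, "bc1")
  for (l in rev(seq_len(depth))) {
    pl <- get(sprintf("pool%d", l), envir = cache)
    g <- .maxpool2_backward_cpp(g, pl$idx, pl$H, pl$W)
    g <- g + gskips[[l]]
    g <- conv_relu_bwd(g, sprintf("e%dc2", l))
    g <- conv_relu_bwd(g, sprintf("e%dc1", l))
  }
  grads
}

# weighted cross-entropy + soft Dice (equal weights by default); returns the
# scalar loss and the gradient w.r.t. the logits
seg_loss_grad <- function(prob, y, class_w, loss_w = c(0.5, 0.5),
                          eps = 1e-7) {
  d <- dim(prob)
  npix <- d[1] * d[2]
  nc <- d[3]
  yoh <- array(0, d)
  for (c in seq_len(nc)) yoh[, , c] <- (y == c - 1)
  wmap <- array(class_w[y + 1], d[1:2])
  py <- array(0, d[1:2])
  for (c in seq_len(nc)) py <- py + prob[, , c] * yoh[, , c]
  ce <- -sum(wmap * log(pmax(py, eps))) / npix
  gce <- prob - yoh
  for (c in seq_len(nc)) gce[, , c] <- gce[, , c] * wmap / npix
  dl <- 0
  dldp <- array(0, d)
  for (c in seq_len(nc)) {
    pc <- prob[, , c]; yc <- yoh[, , c]
    num <- 2 * sum(pc * yc)
    den <- sum(pc^2) + sum(yc^2) + eps
    dl <- dl + (1 - num / den) / nc
    dldp[, , c] <- -((2 * yc) * den - num * 2 * pc) / den^2 / nc
  }
  s <- array(0, d[1:2])
  for (c in seq_len(nc)) s <- s + prob[, , c] * dldp[, , c]
  gdice <- array(0, d)
  for (c in seq_len(nc)) gdice[, , c] <- prob[, , c] * (dldp[, , c] - s)
  list(loss = loss_w[1] * ce + loss_w[2] * dl,
       grad = loss_w[1] * gce + loss_w[2] * gdice)
}

adam_init <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (n in names(grads)) {
    state$m[[n]] <- b1 * state$m[[n]] + (1 - b1) * grads[[n]]
    state$v[[n]] <- b2 * state$v[[n]] + (1 - b2) * grads[[n]]^2
    mh <- state$m[[n]] / (1 - b1^state$t)
    vh <- state$v[[n]] / (1 - b2^state$t)
    params[[n]] <- params[[n]] - lr * mh / (sqrt(vh) + eps)
  }
  list(params = params, state = state)
}

# one full training run over `idx`; returns updated params and per-epoch
# curves (train loss, and validation loss/accuracy when val indices given)
unet_fit <- function(images, labels, net, spec, idx, val_idx = integer(0)) {
  params <- net$params
  arch <- net$arch
  st <- adam_init(params)
  curves <- vector("list", spec$epochs)
  cw <- spec$class_weights
  for (ep in seq_len(spec$epochs)) {
    ord <- sample(idx)
    tl <- 0
    for (i in ord) {
      x <- images[[i]]
      dim(x) <- c(dim(x), 1L)
      fwd <- unet_forward(params, arch, x, want_cache = TRUE)
      lg <- seg_loss_grad(fwd$prob, labels[[i]], cw, spec$loss_weights)
      tl <- tl + lg$loss
      hw <- dim(lg$grad)[1] * dim(lg$grad)[2]
      grads <- unet_backward(params, arch, fwd, matrix(lg$grad, hw, 3))
      upd <- adam_step(params, grads, st, spec$lr)
      params <- upd$params
      st <- upd$state
    }
    vl <- NA_real_; va <- NA_real_
    if (length(val_idx) > 0) {
      vl <- 0; va <- 0
      for (i in val_idx) {
        x <- images[[i]]
        dim(x) <- c(dim(x), 1L)
        fwd <- unet_forward(params, arch, x)
        vl <- vl + seg_loss_grad(fwd$prob, labels[[i]], cw,
                                 spec$loss_weights)$loss
        pred <- apply(fwd$prob, c(1, 2), which.max) - 1L
        va <- va + mean(pred == labels[[i]])
      }
      vl <- vl / length(val_idx)
      va <- va / length(val_idx)
    }
    curves[[ep]] <- tibble::tibble(epoch = ep, train_loss = tl / length(idx),
                                   val_loss = vl, val_accuracy = va)
  }
  list(params = params, curves = dplyr::bind_rows(curves))
}
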