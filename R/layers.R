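# Internal layer primitives: parameter constructors, forward passes with
# caches, and hand-derived backward passes. All activations are (H, W, C)
# arrays; fully-connected activations are plain vectors. Initialisation is
# He-style (scaled Gaussian) from the caller's RNG stream.

conv_param <- function(k, cin, cout, stride = 1L, pad = (k - 1L) %/% 2L,
                       sd = sqrt(2 / (k * k * cin))) {
  list(W = array(rnorm(k * k * cin * cout, sd = sd), c(k, k, cin, cout)),
       b = numeric(cout), stride = as.integer(stride), pad = as.integer(pad))
}

# Transposed convolution storing the weights of the virtual forward
# convolution: dim (k, k, cout_t, cin_t). Stride fixed to 2 (x2 upsampling).
convt_param <- function(k, cin_t, cout_t, sd = sqrt(2 / (k * k * cin_t))) {
  list(W = array(rnorm(k * k * cout_t * cin_t, sd = sd),
                 c(k, k, cout_t, cin_t)),
       b = numeric(cout_t), stride = 2L, pad = (k - 1L) %/% 2L)
}

fc_param <- function(nin, nout, sd = sqrt(2 / nin)) {
  list(W = matrix(rnorm(nin * nout, sd = sd), nout, nin), b = numeric(nout))
}

conv_f <- function(p, x) cpp_conv2d_fw(x, p$W, p$b, p$stride, p$pad)
conv_b <- function(p, x, dy) {
  g <- cpp_conv2d_bw(x, p$W, dy, p$stride, p$pad)
  list(dx = g$dx, grads = list(W = g$dW, b = g$db))
}
convt_f <- function(p, x) {
  d <- dim(x)
  cpp_convt2d_fw(x, p$W, p$b, p$stride, p$pad, 2L * d[1], 2L * d[2])
}
convt_b <- function(p, x, dy) {
  g <- cpp_convt2d_bw(x, p$W, dy, p$stride, p$pad)
  list(dx = g$dx, grads = list(W = g$dW, b = g$db))
}
fc_f <- function(p, v) as.vector(p$W %*% v) + p$b
fc_b <- function(p, v, dy) {
  list(dx = as.vector(crossprod(p$W, dy)),
       grads = list(W = tcrossprod(dy, v), b = dy))
}

# --- stem: conv(stride 2) + ReLU + 2x2 max-pool ----------------------------

stem_f <- function(p, x) {
  a <- conv_f(p$conv, x)
  r <- a * (a > 0)
  mp <- cpp_maxpool2_fw(r)
  list(out = mp$y,
       cache = list(x = x, apos = a > 0, idx = mp$idx, dimr = dim(r)))
}

stem_b <- function(p, cache, dout) {
  dr <- cpp_maxpool2_bw(dout, cache$idx, cache$dimr)
  da <- dr * cache$apos
  g <- conv_b(p$conv, cache$x, da)
  list(dx = g$dx, grads = list(conv = g$grads))
}

# --- residual blocks -------------------------------------------------------

res_block_param <- function(cin, cout, stride) {
  p <- list(conv1 = conv_param(3L, cin, cout, stride = stride),
            conv2 = conv_param(3L, cout, cout))
  if (stride != 1L || cin != cout) {
    p$proj <- conv_param(1L, cin, cout, stride = stride, pad = 0L)
  }
  p
}

res_block_f <- function(p, x) {
  a1 <- conv_f(p$conv1, x)
  r1 <- a1 * (a1 > 0)
  a2 <- conv_f(p$conv2, r1)
  sc <- if (!is.null(p$proj)) conv_f(p$proj, x) else x
  s <- a2 + sc
  list(out = s * (s > 0),
       cache = list(x = x, a1pos = a1 > 0, r1 = r1, spos = s > 0))
}

res_block_b <- function(p, cache, dout) {
  ds <- dout * cache$spos
  g2 <- conv_b(p$conv2, cache$r1, ds)
  da1 <- g2$dx * cache$a1pos
  g1 <- conv_b(p$conv1, cache$x, da1)
  grads <- list(conv1 = g1$grads, conv2 = g2$grads)
  if (!is.null(p$proj)) {
    gp <- conv_b(p$proj, cache$x, ds)
    grads$proj <- gp$grads
    dx <- g1$dx + gp$dx
  } else {
    dx <- g1$dx + ds
  }
  list(dx = dx, grads = grads)
}

# Stage of two residual blocks; the first carries the stride/width change
# through a projection shortcut.
stage_param <- function(cin, cout, stride) {
  list(b1 = res_block_param(cin, cout, stride),
       b2 = res_block_param(cout, cout, 1L))
}

stage_f <- function(p, x) {
  f1 <- res_block_f(p$b1, x)
  f2 <- res_block_f(p$b2, f1$out)
  list(out = f2$out, cache = list(c1 = f1$cache, c2 = f2$cache))
}

stage_b <- function(p, cache, dout) {
  g2 <- res_block_b(p$b2, cache$c2, dout)
  g1 <- res_block_b(p$b1, cache$c1, g2$dx)
  list(dx = g1$dx, grads = list(b1 = g1$grads, b2 = g2$grads))
}

# --- tracking decoder ------------------------------------------------------

# n_tconv stride-2 transpose convolutions (3x3), ReLU between, sigmoid
# output; with `upsample = TRUE` a final non-learned x2 bilinear resize
# bridges the remaining factor of the backbone stride. The final bias is
# initialised to the logit of a small prior foreground rate so the sigmoid
# starts near the background level of the sparse reconstruction target.
decoder_param <- function(cin, channels, prior = 0.05) {
  chans <- c(cin, channels)
  out <- lapply(seq_along(channels), function(i) {
    convt_param(3L, chans[i], chans[i + 1],
                sd = if (i == length(channels)) 0.05 else sqrt(2 / (9 * chans[i])))
  })
  n <- length(out)
  out[[n]]$b[] <- log(prior / (1 - prior))
  out
}

decoder_f <- function(p, f, upsample) {
  n <- length(p)
  acts <- vector("list", n)
  x <- f
  pre <- NULL
  for (i in seq_len(n)) {
    a <- convt_f(p[[i]], x)
    if (i < n) {
      x <- a * (a > 0)
      acts[[i]] <- list(inp = if (i == 1) f else NULL, apos = a > 0, out = x)
    } else {
      pre <- a
    }
  }
  if (upsample) pre <- cpp_upsample2_fw(pre)
  track <- sigmoid(pre)
  # keep the inputs of each t-conv for the backward pass
  list(track = track,
       cache = list(f = f, acts = acts, dim_pre = dim(pre),
                    upsample = upsample))
}

decoder_b <- function(p, cache, dpre) {
  n <- length(p)
  if (cache$upsample) {
    inp_last <- if (n == 1) cache$f else cache$acts[[n - 1]]$out
    dpre <- cpp_upsample2_bw(dpre, c(dim(inp_last)[1] * 2L,
                                     dim(inp_last)[2] * 2L,
                                     dim(p[[n]]$W)[3]))
  }
  grads <- vector("list", n)
  names(grads) <- paste0("t", seq_len(n))
  dy <- dpre
  for (i in rev(seq_len(n))) {
    xin <- if (i == 1) cache$f else cache$acts[[i - 1]]$out
    g <- convt_b(p[[i]], xin, dy)
    grads[[paste0("t", i)]] <- g$grads
    dy <- g$dx
    if (i > 1) dy <- dy * cache$acts[[i - 1]]$apos
  }
  list(dx = dy, grads = grads)
}

# --- classification head ---------------------------------------------------

# 3x3 conv + ReLU + 2x2 max-pool + flatten (the embedding) + two
# fully-connected layers ending in n_class sigmoid units.
head_param <- function(cin, filters, flat, hidden, n_class) {
  list(conv = conv_param(3L, cin, filters),
       fc1 = fc_param(flat, hidden),
       fc2 = fc_param(hidden, n_class, sd = 0.01))
}

head_f <- function(p, f) {
  a <- conv_f(p$conv, f)
  r <- a * (a > 0)
  mp <- cpp_maxpool2_fw(r)
  emb <- as.vector(mp$y)
  h1 <- fc_f(p$fc1, emb)
  r1 <- h1 * (h1 > 0)
  s <- fc_f(p$fc2, r1)
  list(scores = sigmoid(s), embedding = emb,
       cache = list(f = f, apos = a > 0, idx = mp$idx, dimr = dim(r),
                    emb = emb, h1pos = h1 > 0, r1 = r1))
}

head_b <- function(p, cache, ds_pre) {
  g2 <- fc_b(p$fc2, cache$r1, ds_pre)
  dh1 <- g2$dx * cache$h1pos
  g1 <- fc_b(p$fc1, cache$emb, dh1)
  dmp <- array(g1$dx, c(cache$dimr[1] %/% 2L, cache$dimr[2] %/% 2L,
                        cache$dimr[3]))
  dr <- cpp_maxpool2_bw(dmp, cache$idx, cache$dimr)
  da <- dr * cache$apos
  gc <- conv_b(p$conv, cache$f, da)
  list(dx = gc$dx,
       grads = list(conv = gc$grads, fc1 = g1$grads, fc2 = g2$grads))
}

# --- gradient bookkeeping --------------------------------------------------

acc_grads <- function(a, b) {
  if (is.null(a)) return(b)
  for (nm in names(b)) {
    a[[nm]] <- if (is.list(b[[nm]])) acc_grads(a[[nm]], b[[nm]])
               else a[[nm]] + b[[nm]]
  }
  a
}

scale_grads <- function(g, s) {
  rapply(g, function(x) x * s, how = "replace")
}

# SGD with momentum over the gradient tree; only entries present in `grads`
# are touched, so non-trainable fields in `params` are left alone.
sgd_apply <- function(params, grads, vel, lr, momentum) {
  for (nm in names(grads)) {
    if (is.list(grads[[nm]])) {
      r <- sgd_apply(params[[nm]], grads[[nm]], vel[[nm]], lr, momentum)
      params[[nm]] <- r$params
      vel[[nm]] <- r$vel
    } else {
      v <- momentum * vel[[nm]] - lr * grads[[nm]]
      vel[[nm]] <- v
      params[[nm]] <- params[[nm]] + v
    }
  }
  list(params = params, vel = vel)
}

# Adam over the gradient tree (bias-corrected first/second moments). `st` is
# list(m = <tree>, v = <tree>); the bias-correction step count is handled by
# the caller passing the correction factors directly.
adam_apply <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8, c1 = 1, c2 = 1) {
  for (nm in names(grads)) {
    if (is.list(grads[[nm]])) {
      r <- adam_apply(params[[nm]], grads[[nm]],
                      list(m = st$m[[nm]], v = st$v[[nm]]),
                      lr, beta1, beta2, eps, c1, c2)
      params[[nm]] <- r$params
      st$m[[nm]] <- r$st$m
      st$v[[nm]] <- r$st$v
    } else {
      g <- grads[[nm]]
      st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
      st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g * g
      params[[nm]] <- params[[nm]] -
        lr * (st$m[[nm]] / c1) / (sqrt(st$v[[nm]] / c2) + eps)
    }
  }
  list(params = params, st = st)
}
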