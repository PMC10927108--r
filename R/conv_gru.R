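# Convolutional gated recurrent unit. Gates follow the standard Cho-style
# formulation with same-padded 2-D convolutions replacing the matrix
# products, blending convention h = (1 - z) * h_prev + z * h_tilde.
# Hidden and input channel counts are equal; spatial dims are preserved.

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Create parameters for a convolutional GRU
#'
#' The unit has an update gate `z`, a reset gate `r` and a candidate state
#' `h_tilde`, each computed from one input-to-hidden and one hidden-to-hidden
#' same-padded convolution plus a bias. Input and hidden channel counts are
#' equal, so the unit never changes the dimensionality of the feature maps it
#' sits on.
#'
#' @param channels number of feature channels (input and hidden).
#' @param kernel odd spatial kernel size (default 3).
#' @param init `"he"` for random initialisation (scaled Gaussian) or
#'   `"zero"` for all-zero parameters (useful for the closed-form fixed
#'   point: a zero-parameter step halves the hidden state).
#' @return an object of class `conv_gru_params`.
#' @export
conv_gru_params <- function(channels, kernel = 3L, init = c("he", "zero")) {
  init <- match.arg(init)
  if (kernel %% 2 == 0) stop("conv_gru_params: kernel must be odd")
  if (channels < 1) stop("conv_gru_params: channels must be >= 1")
  mk <- function() {
    if (init == "zero") {
      array(0, c(kernel, kernel, channels, channels))
    } else {
      sd <- sqrt(1 / (kernel * kernel * channels))
      array(rnorm(kernel^2 * channels^2, sd = sd),
            c(kernel, kernel, channels, channels))
    }
  }
  structure(
    list(Wxz = mk(), Whz = mk(), bz = numeric(channels),
         Wxr = mk(), Whr = mk(), br = numeric(channels),
         Wxh = mk(), Whh = mk(), bh = numeric(channels),
         kernel = as.integer(kernel), channels = as.integer(channels)),
    class = "conv_gru_params")
}

gru_check_shapes <- function(params, x, h_prev) {
  if (length(dim(x)) != 3 || length(dim(h_prev)) != 3) {
    stop("gru_step: x and h_prev must be (H, W, C) arrays")
  }
  if (!identical(dim(x), dim(h_prev))) {
    stop("gru_step: x and h_prev must have identical shapes")
  }
  if (dim(x)[3] != params$channels) {
    stop("gru_step: channel count does not match the parameter spec")
  }
}

# Internal step returning the full cache needed for backpropagation.
gru_step_cache <- function(params, x, h_prev) {
  pad <- (params$kernel - 1L) %/% 2L
  zb <- numeric(params$channels)
  az <- cpp_conv2d_fw(x, params$Wxz, params$bz, 1L, pad) +
        cpp_conv2d_fw(h_prev, params$Whz, zb, 1L, pad)
  ar <- cpp_conv2d_fw(x, params$Wxr, params$br, 1L, pad) +
        cpp_conv2d_fw(h_prev, params$Whr, zb, 1L, pad)
  z <- sigmoid(az)
  r <- sigmoid(ar)
  rh <- r * h_prev
  ah <- cpp_conv2d_fw(x, params$Wxh, params$bh, 1L, pad) +
        cpp_conv2d_fw(rh, params$Whh, zb, 1L, pad)
  hc <- tanh(ah)
  h <- (1 - z) * h_prev + z * hc
  list(h = h, z = z, r = r, hc = hc, rh = rh, x = x, h_prev = h_prev)
}

# Backward pass of one GRU step. dh is the gradient wrt the step output.
# Returns gradients wrt the inputs and a params-shaped list of gradients.
gru_step_bw <- function(params, cache, dh) {
  pad <- (params$kernel - 1L) %/% 2L
  z <- cache$z; r <- cache$r; hc <- cache$hc
  dz <- dh * (hc - cache$h_prev)
  dhc <- dh * z
  dhp <- dh * (1 - z)

  dah <- dhc * (1 - hc^2)
  g1 <- cpp_conv2d_bw(cache$x, params$Wxh, dah, 1L, pad)
  g2 <- cpp_conv2d_bw(cache$rh, params$Whh, dah, 1L, pad)
  dx <- g1$dx
  drh <- g2$dx
  dr <- drh * cache$h_prev
  dhp <- dhp + drh * r

  dar <- dr * r * (1 - r)
  g3 <- cpp_conv2d_bw(cache$x, params$Wxr, dar, 1L, pad)
  g4 <- cpp_conv2d_bw(cache$h_prev, params$Whr, dar, 1L, pad)
  dx <- dx + g3$dx
  dhp <- dhp + g4$dx

  daz <- dz * z * (1 - z)
  g5 <- cpp_conv2d_bw(cache$x, params$Wxz, daz, 1L, pad)
  g6 <- cpp_conv2d_bw(cache$h_prev, params$Whz, daz, 1L, pad)
  dx <- dx + g5$dx
  dhp <- dhp + g6$dx

  list(dx = dx, dh_prev = dhp,
       grads = list(Wxz = g5$dW, Whz = g6$dW, bz = g5$db,
                    Wxr = g3$dW, Whr = g4$dW, br = g3$db,
                    Wxh = g1$dW, Whh = g2$dW, bh = g1$db))
}

#' One convolutional GRU step
#'
#' Computes the update gate `z = sigmoid(conv(x) + conv(h_prev) + b_z)`, the
#' reset gate `rg = sigmoid(conv(x) + conv(h_prev) + b_r)`,
#' `h_tilde = tanh(conv(x) + conv(rg * h_prev) + b_h)` and returns
#' `h = (1 - z) * h_prev + z * h_tilde`. Spatial dimensions are preserved.
#'
#' @param params a [conv_gru_params()] object.
#' @param x input feature map, array of dim `(H, W, C)`.
#' @param h_prev previous hidden state, same shape as `x`.
#' @return the new hidden state, same shape as `x`.
#' @export
gru_step <- function(params, x, h_prev) {
  gru_check_shapes(params, x, h_prev)
  gru_step_cache(params, x, h_prev)$h
}

#' Run a convolutional GRU over a sequence of feature maps
#'
#' Applies [gru_step()] iteratively. The hidden state is never carried
#' between different sequences: each call starts from the explicit `h0`
#' (zeros by default).
#'
#' @param params a [conv_gru_params()] object.
#' @param xs list of input feature maps sharing one shape.
#' @param h0 initial hidden state; `NULL` means all zeros.
#' @return list of hidden states, one per input.
#' @export
gru_run <- function(params, xs, h0 = NULL) {
  if (length(xs) == 0) stop("gru_run: empty sequence")
  if (is.null(h0)) h0 <- array(0, dim(xs[[1]]))
  hs <- vector("list", length(xs))
  h <- h0
  for (t in seq_along(xs)) {
    h <- gru_step(params, xs[[t]], h)
    hs[[t]] <- h
  }
  hs
}
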