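# From-scratch neural-network core shared by the landmark CNN and the
# morphology BPNN: layer forward/backward passes (convolution via im2col
# lowering, max pooling, dense, ReLU, sigmoid, dropout, global average
# pooling), an Adam/SGD optimizer, and finite-difference gradient checking.
# Reference (loop-based) implementations are provided for oracle testing.

#' Normalize pixel intensities
#'
#' `out = (in / 255 - 0.5) / sigma` elementwise: intensities are mapped to
#' `[-0.5, 0.5]` and divided by a standard-deviation scale. Shape preserved;
#' invertible for `sigma > 0`.
#'
#' @param image Numeric array with values in `[0, 255]`.
#' @param sigma Positive scale (typically the per-dataset pixel SD).
#' @return Normalized array of the same shape.
#' @export
normalize_image <- function(image, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1 || !is.finite(sigma) || sigma <= 0)
    stop_nf("nf_parameter_error", "sigma must be a positive finite scalar")
  if (any(image < 0 | image > 255))
    stop_nf("nf_parameter_error", "pixel values must lie in [0, 255]")
  (image / 255 - 0.5) / sigma
}

#' Rectified linear unit
#'
#' `f(x) = x` if `x > 0`, else `0`, elementwise.
#'
#' @param x Numeric array.
#' @return Array of the same shape.
#' @export
relu <- function(x) pmax(x, 0)

#' Reference 2D convolution (loop-based)
#'
#' Valid convolution of a single-channel input with an `m x m` filter:
#' `out[a, b] = act(sum_ij w[i, j] * x[a+i-1, b+j-1] + bias)`, output side
#' `input side - filter side + 1`. Deliberately written as an explicit
#' quadruple loop: it is the independent oracle against which the fast
#' im2col-based convolution layer is tested.
#'
#' @param input_map Numeric matrix.
#' @param w Filter matrix (must fit inside the input).
#' @param bias Scalar bias.
#' @param activation `"relu"` or `"identity"`.
#' @return Output matrix of side `nrow(input) - nrow(w) + 1`.
#' @export
conv_forward_reference <- function(input_map, w, bias = 0,
                                   activation = c("identity", "relu")) {
  activation <- match.arg(activation)
  H <- nrow(input_map); W <- ncol(input_map)
  kh <- nrow(w); kw <- ncol(w)
  if (kh > H || kw > W)
    stop_nf("nf_shape_error", "filter (", kh, "x", kw,
            ") larger than input (", H, "x", W, ")")
  oh <- H - kh + 1; ow <- W - kw + 1
  out <- matrix(0, oh, ow)
  for (a in seq_len(oh)) {
    for (b in seq_len(ow)) {
      acc <- bias
      for (i in seq_len(kh)) {
        for (j in seq_len(kw)) {
          acc <- acc + w[i, j] * input_map[a + i - 1, b + j - 1]
        }
      }
      out[a, b] <- acc
    }
  }
  if (activation == "relu") out <- relu(out)
  out
}

# --- layer constructors ----------------------------------------------------

.nf_he_init <- function(fan_in, dims) {
  array(rnorm(prod(dims), 0, sqrt(2 / fan_in)), dims)
}

nn_conv_layer <- function(in_ch, out_ch, k = 3, stride = 1, pad = (k - 1) %/% 2) {
  list(type = "conv", k = k, stride = stride, pad = pad,
       in_ch = in_ch, out_ch = out_ch,
       W = matrix(.nf_he_init(k * k * in_ch, c(k * k * in_ch, out_ch)),
                  k * k * in_ch, out_ch),
       b = rep(0, out_ch))
}

nn_dense_layer <- function(n_in, n_out) {
  list(type = "dense", n_in = n_in, n_out = n_out,
       W = matrix(.nf_he_init(n_in, c(n_in, n_out)), n_in, n_out),
       b = rep(0, n_out))
}

nn_relu_layer <- function() list(type = "relu")
nn_sigmoid_layer <- function() list(type = "sigmoid")
nn_gap_layer <- function() list(type = "gap")
nn_maxpool_layer <- function(k, stride, pad = (k - 1) %/% 2)
  list(type = "maxpool", k = k, stride = stride, pad = pad)
nn_dropout_layer <- function(rate) list(type = "dropout", rate = rate)

.nf_as_cube <- function(x) {
  if (is.matrix(x)) array(x, c(dim(x), 1)) else x
}

# forward pass; returns list(out, caches)
nn_forward <- function(layers, x, train = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$type == "conv") {
      x <- .nf_as_cube(x)
      cols <- cpp_im2col(x, l$k, l$k, l$stride, l$pad)
      outm <- cols %*% l$W
      outm <- sweep(outm, 2, l$b, `+`)
      d <- dim(x)
      oh <- (d[1] + 2 * l$pad - l$k) %/% l$stride + 1
      ow <- (d[2] + 2 * l$pad - l$k) %/% l$stride + 1
      caches[[i]] <- list(cols = cols, in_dim = d)
      x <- array(outm, c(oh, ow, l$out_ch))
    } else if (l$type == "maxpool") {
      x <- .nf_as_cube(x)
      r <- cpp_maxpool_fwd(x, l$k, l$stride, l$pad)
      caches[[i]] <- list(idx = r$idx, in_dim = dim(x))
      x <- r$out
    } else if (l$type == "relu") {
      caches[[i]] <- list(mask = x > 0)
      x <- relu(x)
    } else if (l$type == "sigmoid") {
      x <- 1 / (1 + exp(-x))
      caches[[i]] <- list(y = x)
    } else if (l$type == "gap") {
      x <- .nf_as_cube(x)
      caches[[i]] <- list(in_dim = dim(x))
      x <- apply(x, 3, mean)
    } else if (l$type == "dense") {
      x <- as.numeric(x)
      caches[[i]] <- list(x = x)
      x <- drop(crossprod(l$W, x)) + l$b
    } else if (l$type == "dropout") {
      if (train && l$rate > 0) {
        mask <- (runif(length(x)) >= l$rate) / (1 - l$rate)
        dim(mask) <- dim(x)
        caches[[i]] <- list(mask = mask)
        x <- x * mask
      } else {
        caches[[i]] <- list(mask = NULL)
      }
    } else stop("unknown layer type: ", l$type)
  }
  list(out = x, caches = caches)
}

# backward pass; dout matches the forward output shape.
# returns list(dx, grads) where grads[[i]] has dW/db for parametric layers.
nn_backward <- function(layers, caches, dout) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    l <- layers[[i]]; cache <- caches[[i]]
    if (l$type == "conv") {
      d <- cache$in_dim
      oh <- (d[1] + 2 * l$pad - l$k) %/% l$stride + 1
      ow <- (d[2] + 2 * l$pad - l$k) %/% l$stride + 1
      doutm <- matrix(dout, oh * ow, l$out_ch)
      grads[[i]] <- list(dW = crossprod(cache$cols, doutm),
                         db = colSums(doutm))
      dcols <- tcrossprod(doutm, l$W)
      dout <- cpp_col2im(dcols, d[1], d[2], d[3], l$k, l$k, l$stride, l$pad)
    } else if (l$type == "maxpool") {
      d <- cache$in_dim
      dout <- cpp_maxpool_bwd(.nf_as_cube(dout), cache$idx, d[1], d[2], d[3])
    } else if (l$type == "relu") {
      dout <- dout * cache$mask
    } else if (l$type == "sigmoid") {
      dout <- dout * cache$y * (1 - cache$y)
    } else if (l$type == "gap") {
      d <- cache$in_dim
      dx <- array(0, d)
      for (c in seq_len(d[3])) dx[, , c] <- dout[c] / (d[1] * d[2])
      dout <- dx
    } else if (l$type == "dense") {
      dv <- as.numeric(dout)
      grads[[i]] <- list(dW = outer(cache$x, dv), db = dv)
      dout <- drop(l$W %*% dv)
    } else if (l$type == "dropout") {
      if (!is.null(cache$mask)) dout <- dout * cache$mask
    }
  }
  list(dx = dout, grads = grads)
}

# --- optimizer -------------------------------------------------------------

nn_adam_init <- function(layers) {
  lapply(layers, function(l) {
    if (!is.null(l$W)) list(mW = l$W * 0, vW = l$W * 0,
                            mb = l$b * 0, vb = l$b * 0)
    else NULL
  })
}

# one optimizer step; grads already averaged over the batch
nn_update <- function(layers, grads, state, lr, t,
                      optimizer = c("adam", "sgd"),
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  optimizer <- match.arg(optimizer)
  for (i in seq_along(layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    if (optimizer == "sgd") {
      layers[[i]]$W <- layers[[i]]$W - lr * g$dW
      layers[[i]]$b <- layers[[i]]$b - lr * g$db
    } else {
      s <- state[[i]]
      s$mW <- beta1 * s$mW + (1 - beta1) * g$dW
      s$vW <- beta2 * s$vW + (1 - beta2) * g$dW^2
      s$mb <- beta1 * s$mb + (1 - beta1) * g$db
      s$vb <- beta2 * s$vb + (1 - beta2) * g$db^2
      mhW <- s$mW / (1 - beta1^t); vhW <- s$vW / (1 - beta2^t)
      mhb <- s$mb / (1 - beta1^t); vhb <- s$vb / (1 - beta2^t)
      layers[[i]]$W <- layers[[i]]$W - lr * mhW / (sqrt(vhW) + eps)
      layers[[i]]$b <- layers[[i]]$b - lr * mhb / (sqrt(vhb) + eps)
      state[[i]] <- s
    }
  }
  list(layers = layers, state = state)
}

# accumulate gradient lists (same structure), scaled
nn_grads_add <- function(acc, g, scale = 1) {
  if (is.null(acc)) {
    return(lapply(g, function(gi)
      if (is.null(gi)) NULL else list(dW = gi$dW * scale, db = gi$db * scale)))
  }
  for (i in seq_along(g)) {
    if (is.null(g[[i]])) next
    acc[[i]]$dW <- acc[[i]]$dW + g[[i]]$dW * scale
    acc[[i]]$db <- acc[[i]]$db + g[[i]]$db * scale
  }
  acc
}

# MSE loss and its gradient wrt predictions
nn_mse <- function(pred, target) {
  d <- as.numeric(pred) - as.numeric(target)
  list(loss = mean(d^2), dpred = 2 * d / length(d))
}

#' Finite-difference gradient check
#'
#' Compares the analytic back-propagated gradients of a small network
#' against central finite differences of the loss over every weight and
#' bias, returning the maximum relative discrepancy
#' `|g_a - g_n| / max(|g_a| + |g_n|, 1e-8)`.
#'
#' @param layers A layer list (from [build_keypoint_network()]'s `$layers`
#'   or constructed directly); keep it small (<= ~1e4 parameters).
#' @param x Input array/vector.
#' @param target Target vector matching the network output.
#' @param eps Perturbation size in `(0, 1e-2]`.
#' @return Maximum relative gradient error.
#' @export
finite_difference_gradcheck <- function(layers, x, target, eps = 1e-5) {
  if (eps <= 0 || eps > 1e-2)
    stop_nf("nf_parameter_error", "eps must be in (0, 1e-2]")
  fw <- nn_forward(layers, x, train = FALSE)
  l0 <- nn_mse(fw$out, target)
  analytic <- nn_backward(layers, fw$caches, array(l0$dpred, dim = .nf_dim_of(fw$out)))$grads
  worst <- 0
  for (i in seq_along(layers)) {
    if (is.null(layers[[i]]$W)) next
    for (field in c("W", "b")) {
      P <- layers[[i]][[field]]
      gA <- if (field == "W") analytic[[i]]$dW else analytic[[i]]$db
      for (j in seq_along(P)) {
        layers[[i]][[field]][j] <- P[j] + eps
        lp <- nn_mse(nn_forward(layers, x)$out, target)$loss
        layers[[i]][[field]][j] <- P[j] - eps
        lm <- nn_mse(nn_forward(layers, x)$out, target)$loss
        layers[[i]][[field]][j] <- P[j]
        gN <- (lp - lm) / (2 * eps)
        rel <- abs(gA[j] - gN) / max(abs(gA[j]) + abs(gN), 1e-8)
        if (rel > worst) worst <- rel
      }
    }
  }
  worst
}

.nf_dim_of <- function(x) if (is.null(dim(x))) length(x) else dim(x)
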