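# Framework-free convolutional primitives.
#
# Feature maps are plain 3D arrays (height x width x maps); a single matrix is
# accepted anywhere and treated as one map. All convolutions are "valid"
# (no padding): out_dim = floor((in_dim - kernel)/stride) + 1.

#' Create a convolution kernel set
#'
#' Bundles the weights and biases of one convolutional layer. Weights are
#' indexed `[u, v, k_in, k_out]` (kernel row, kernel column, input map, output
#' map); there is one bias per output map.
#'
#' @param weights Numeric 4D array `K_h x K_w x K_in x K_out`.
#' @param biases Numeric vector of length `K_out`.
#' @param strides Integer vector `c(h_s, w_s)`, both positive.
#' @return An object of class `conv_kernels`.
#' @export
conv_kernels <- function(weights, biases, strides = c(1L, 1L)) {
  if (length(dim(weights)) != 4L)
    stop("`weights` must be a 4D array [K_h, K_w, K_in, K_out]")
  if (length(biases) != dim(weights)[4L])
    stop("`biases` must have one entry per output map")
  strides <- as.integer(strides)
  if (length(strides) != 2L || any(strides < 1L))
    stop("`strides` must be two positive integers")
  structure(list(weights = weights, biases = as.numeric(biases),
                 strides = strides),
            class = "conv_kernels")
}

as_feature_maps <- function(x) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  if (length(dim(x)) != 3L) stop("feature maps must be a matrix or 3D array")
  x
}

conv_out_dim <- function(n, k, s) as.integer((n - k) %/% s + 1L)

# Unroll sliding kernel patches into a matrix: one row per output position
# (row index varying fastest), one column per (u, v, k_in) weight slot in
# column-major weight order, so that forward conv is a single matmul.
im2col <- function(x, kh, kw, hs, ws) {
  d <- dim(x)
  h_out <- conv_out_dim(d[1L], kh, hs)
  w_out <- conv_out_dim(d[2L], kw, ws)
  out <- matrix(0, h_out * w_out, kh * kw * d[3L])
  col <- 0L
  for (ki in seq_len(d[3L])) for (v in seq_len(kw)) for (u in seq_len(kh)) {
    col <- col + 1L
    out[, col] <- x[seq.int(u, by = hs, length.out = h_out),
                    seq.int(v, by = ws, length.out = w_out), ki]
  }
  out
}

# Scatter-add patch-space gradients back onto the input grid (adjoint of
# im2col). Within one (u, v, k_in) slot the target indices are distinct, so
# the strided submatrix addition is a safe accumulation.
col2im_add <- function(g_col, dim_x, kh, kw, hs, ws) {
  gx <- array(0, dim_x)
  h_out <- conv_out_dim(dim_x[1L], kh, hs)
  w_out <- conv_out_dim(dim_x[2L], kw, ws)
  col <- 0L
  for (ki in seq_len(dim_x[3L])) for (v in seq_len(kw)) for (u in seq_len(kh)) {
    col <- col + 1L
    rows <- seq.int(u, by = hs, length.out = h_out)
    cols <- seq.int(v, by = ws, length.out = w_out)
    gx[rows, cols, ki] <- gx[rows, cols, ki] + matrix(g_col[, col], h_out, w_out)
  }
  gx
}

#' 2D convolution, forward pass
#'
#' Valid (no-padding) strided cross-correlation: output map `k` at position
#' `(i, j)` is the sum over input maps and kernel offsets of
#' `a[u, v, k_in, k] * x[(i-1)*h_s + u, (j-1)*w_s + v, k_in]` plus the map's
#' bias. Output height is `floor((h_in - K_h)/h_s) + 1`, analogously width.
#'
#' @param x Input feature maps (matrix or 3D array `h x w x K_in`).
#' @param k A [conv_kernels] object whose `K_in` matches `x`.
#' @return 3D array `h_out x w_out x K_out` of pre-activations.
#' @export
conv2d_forward <- function(x, k) {
  x <- as_feature_maps(x)
  d <- dim(x); dw <- dim(k$weights)
  if (dw[3L] != d[3L])
    stop("kernel expects ", dw[3L], " input maps, got ", d[3L])
  if (dw[1L] > d[1L] || dw[2L] > d[2L])
    stop("kernel (", dw[1L], "x", dw[2L], ") larger than input (",
         d[1L], "x", d[2L], ")")
  xc <- im2col(x, dw[1L], dw[2L], k$strides[1L], k$strides[2L])
  z <- xc %*% matrix(k$weights, ncol = dw[4L])
  z <- sweep(z, 2L, k$biases, "+")
  array(z, c(conv_out_dim(d[1L], dw[1L], k$strides[1L]),
             conv_out_dim(d[2L], dw[2L], k$strides[2L]), dw[4L]))
}

#' 1D (time-axis) convolution, forward pass
#'
#' Convolution along the time axis only, used for scalar-channel pictures:
#' the kernel height must be 1, so each row of the input is filtered
#' independently of the others. Same contract as [conv2d_forward] otherwise.
#'
#' @inheritParams conv2d_forward
#' @return 3D array of pre-activations; height equals the input height.
#' @export
conv1d_forward <- function(x, k) {
  if (dim(k$weights)[1L] != 1L)
    stop("conv1d requires kernel height 1, got ", dim(k$weights)[1L])
  conv2d_forward(x, k)
}

#' ReLU activation and its derivative
#'
#' Elementwise `max(z, 0)`; the derivative is 1 for positive pre-activations
#' and 0 elsewhere (the kink at 0 is assigned derivative 0).
#'
#' @param z Numeric array of pre-activations.
#' @return Array of the same shape.
#' @export
activate <- function(z) {
  z[z < 0] <- 0
  z
}

#' @rdname activate
#' @export
activate_grad <- function(z) {
  (z > 0) + 0
}

#' Max pooling, forward pass
#'
#' Tiles each map into disjoint `p_h x p_w` blocks (the pool must divide the
#' map dimensions exactly) and keeps the maximum of each block. The linear
#' index of each within-block maximum is recorded for backpropagation
#' routing; ties go to the first index in column-major order.
#'
#' @param x Feature maps (matrix or 3D array).
#' @param pool Integer vector `c(p_h, p_w)`.
#' @return 3D array of pooled maps with an `"argmax"` attribute: an integer
#'   array of the same pooled shape holding, per output cell, the linear
#'   index (within its input map) of the selected element.
#' @export
maxpool_forward <- function(x, pool) {
  x <- as_feature_maps(x)
  d <- dim(x)
  pool <- as.integer(pool)
  if (d[1L] %% pool[1L] != 0L || d[2L] %% pool[2L] != 0L)
    stop("pool dims (", pool[1L], "x", pool[2L],
         ") must divide map dims (", d[1L], "x", d[2L], ")")
  h_out <- d[1L] %/% pool[1L]; w_out <- d[2L] %/% pool[2L]
  out <- array(0, c(h_out, w_out, d[3L]))
  amx <- array(0L, c(h_out, w_out, d[3L]))
  for (ki in seq_len(d[3L])) {
    # one column per tile, rows ordered column-major within the tile
    tiles <- im2col(x[, , ki, drop = FALSE], pool[1L], pool[2L],
                    pool[1L], pool[2L])
    sel <- max.col(tiles, ties.method = "first")
    out[, , ki] <- matrix(tiles[cbind(seq_len(nrow(tiles)), sel)], h_out, w_out)
    # translate (tile, within-tile slot) back to an input linear index
    i_out <- rep(seq_len(h_out), times = w_out)
    j_out <- rep(seq_len(w_out), each = h_out)
    u <- (sel - 1L) %% pool[1L] + 1L
    v <- (sel - 1L) %/% pool[1L] + 1L
    ii <- (i_out - 1L) * pool[1L] + u
    jj <- (j_out - 1L) * pool[2L] + v
    amx[, , ki] <- matrix(ii + (jj - 1L) * d[1L], h_out, w_out)
  }
  attr(out, "argmax") <- amx
  out
}

#' Route pooled-layer deltas back to the pre-pooling maps
#'
#' @param delta Deltas of the pooled maps (same shape as the pooled output).
#' @param argmax The `"argmax"` attribute produced by [maxpool_forward].
#' @param dim_in Dimensions of the pre-pooling maps.
#' @return Array of `dim_in` with each delta placed at its argmax position.
#' @export
maxpool_backward <- function(delta, argmax, dim_in) {
  delta <- as_feature_maps(delta); argmax <- as_feature_maps(argmax)
  gx <- array(0, dim_in)
  for (ki in seq_len(dim_in[3L])) {
    g <- matrix(0, dim_in[1L], dim_in[2L])
    g[as.vector(argmax[, , ki])] <- as.vector(delta[, , ki])
    gx[, , ki] <- g
  }
  gx
}

#' Backpropagate residual terms through a convolutional layer
#'
#' Computes the previous layer's residual (delta) from the current one: the
#' deltas are full-correlated with the 180-degree-rotated kernels (the
#' adjoint of the strided forward convolution) and multiplied elementwise by
#' the activation derivative at the previous layer's pre-activations.
#'
#' @param delta 3D array of deltas for this layer's output maps.
#' @param k The [conv_kernels] used in the forward pass.
#' @param z_prev Pre-activations of the previous layer (same shape as the
#'   forward input). Pass `NULL` to omit the activation-derivative factor
#'   (i.e. obtain the raw input gradient).
#' @return Array shaped like the forward input.
#' @export
conv_backward_delta <- function(delta, k, z_prev) {
  delta <- as_feature_maps(delta)
  dw <- dim(k$weights)
  dd <- dim(delta)
  if (dd[3L] != dw[4L])
    stop("delta has ", dd[3L], " maps; kernel produces ", dw[4L])
  if (is.null(z_prev)) {
    dim_in <- c((dd[1L] - 1L) * k$strides[1L] + dw[1L],
                (dd[2L] - 1L) * k$strides[2L] + dw[2L], dw[3L])
  } else {
    z_prev <- as_feature_maps(z_prev)
    dim_in <- dim(z_prev)
  }
  g_col <- matrix(delta, ncol = dw[4L]) %*% t(matrix(k$weights, ncol = dw[4L]))
  gx <- col2im_add(g_col, dim_in, dw[1L], dw[2L], k$strides[1L], k$strides[2L])
  if (is.null(z_prev)) gx else gx * activate_grad(z_prev)
}

#' Gradient of the loss with respect to a layer's kernel weights and biases
#'
#' `dL/da[u, v, k_in, k_out] = sum_{i,j} x[(i-1)h_s+u, (j-1)w_s+v, k_in] *
#' delta[i, j, k_out]`; the bias gradient is the sum of each map's deltas.
#'
#' @param delta 3D array of deltas for the layer's output maps.
#' @param x_prev Forward input of the layer (activations of the previous
#'   layer, or the raw picture for the first layer).
#' @param k The layer's [conv_kernels] (for kernel geometry and strides).
#' @return List with `weights` (4D array like `k$weights`) and `biases`.
#' @export
conv_weight_grad <- function(delta, x_prev, k) {
  delta <- as_feature_maps(delta); x_prev <- as_feature_maps(x_prev)
  dw <- dim(k$weights)
  xc <- im2col(x_prev, dw[1L], dw[2L], k$strides[1L], k$strides[2L])
  dm <- matrix(delta, ncol = dw[4L])
  if (nrow(xc) != nrow(dm)) stop("delta shape inconsistent with input shape")
  list(weights = array(crossprod(xc, dm), dw), biases = colSums(dm))
}

#' Dense layer with softmax output
#'
#' Computes class probabilities `softmax(W f + b)`, numerically stabilised by
#' subtracting the maximum logit before exponentiating.
#'
#' @param features Numeric vector of flattened features.
#' @param weights Matrix `C x length(features)`.
#' @param biases Numeric vector of length `C`.
#' @return Probability vector of length `C` (positive, sums to 1).
#' @export
dense_softmax_forward <- function(features, weights, biases) {
  logits <- as.vector(weights %*% features + biases)
  e <- exp(logits - max(logits))
  e / sum(e)
}

#' Central finite-difference gradient of a scalar function
#'
#' Generic verification oracle: perturbs each coordinate by `+eps` and `-eps`
#' and returns `(f(x+eps) - f(x-eps)) / (2 eps)` per coordinate.
#'
#' @param f Function from a numeric vector to a scalar.
#' @param x Numeric vector at which to differentiate.
#' @param eps Positive step size.
#' @return Numeric vector of the same length as `x`.
#' @export
finite_difference_grads <- function(f, x, eps = 1e-6) {
  stopifnot(eps > 0)
  vapply(seq_along(x), function(i) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    (f(xp) - f(xm)) / (2 * eps)
  }, numeric(1L))
}
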