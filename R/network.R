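# Model assembly: layer specs, exact parameter accounting, branch wiring with
# optional cross-picture weight sharing, training, and gradient verification.

#' Specify one convolutional layer
#'
#' @param kh,kw Kernel height (position axis) and width (time axis).
#' @param n_in,n_out Input and output feature-map counts.
#' @param strides Integer vector `c(h_s, w_s)`.
#' @param conv_dim `"2d"` or `"1d"`; a 1D layer convolves along time only and
#'   must have `kh = 1`.
#' @return An object of class `conv_layer_spec`.
#' @export
conv_layer_spec <- function(kh, kw, n_in, n_out, strides = c(1L, 1L),
                            conv_dim = "2d") {
  if (any(c(kh, kw, n_in, n_out) < 1L)) stop("all layer dims must be >= 1")
  if (conv_dim == "1d" && kh != 1L) stop("1d layers require kh = 1")
  structure(list(kh = as.integer(kh), kw = as.integer(kw),
                 n_in = as.integer(n_in), n_out = as.integer(n_out),
                 strides = as.integer(strides), conv_dim = conv_dim),
            class = "conv_layer_spec")
}

#' Trainable parameters of one convolutional layer
#'
#' `n_in * n_out * kh * kw` weights plus one bias per output map.
#'
#' @param spec A [conv_layer_spec].
#' @return Integer parameter count.
#' @export
count_layer_params <- function(spec) {
  spec$n_in * spec$n_out * spec$kh * spec$kw + spec$n_out
}

#' The reference four-layer convolutional stack
#'
#' Kernels 3x3 (1 to `maps`), 3x3, 5x1, 5x1 (`maps` to `maps`), stride 1.
#' With `maps = 64` the per-layer parameter counts are 640, 36928, 20544,
#' 20544; three independent per-axis stacks hold 235968 parameters and one
#' shared stack 78656. This geometry needs input pictures at least 13
#' positions tall; see [compact_stack] for small position counts.
#'
#' @param maps Feature maps per layer (default 64).
#' @return List of four [conv_layer_spec]s.
#' @export
reference_stack <- function(maps = 64L) {
  list(conv_layer_spec(3L, 3L, 1L, maps),
       conv_layer_spec(3L, 3L, maps, maps),
       conv_layer_spec(5L, 1L, maps, maps),
       conv_layer_spec(5L, 1L, maps, maps))
}

#' A geometry-adapted stack for pictures with few positions
#'
#' Keeps the reference pattern — two mixed position-time kernels followed by
#' two single-axis kernels — but sizes kernel heights to the picture height
#' so that valid (no-padding) convolution is feasible on `P x T` inputs with
#' small `P`. Layers 1-2 use `min(3, h) x 3` kernels; layers 3-4 use `5 x 1`
#' when at least 5 rows remain, else `1 x 5` time-axis kernels.
#'
#' @param positions Picture height `P` (number of tri-axial positions).
#' @param maps Feature maps per layer.
#' @return List of four [conv_layer_spec]s.
#' @export
compact_stack <- function(positions, maps = 8L) {
  h <- as.integer(positions)
  specs <- list()
  n_in <- 1L
  for (l in 1:2) {
    kh <- min(3L, h)
    specs[[l]] <- conv_layer_spec(kh, 3L, n_in, maps)
    h <- h - kh + 1L
    n_in <- maps
  }
  for (l in 3:4) {
    if (h >= 5L) {
      specs[[l]] <- conv_layer_spec(5L, 1L, maps, maps)
      h <- h - 4L
    } else {
      specs[[l]] <- conv_layer_spec(1L, 5L, maps, maps)
    }
  }
  specs
}

#' The scalar-channel (1D) convolutional stack
#'
#' Four time-axis-only layers (kernels 1x3, 1x3, 1x5, 1x5) mirroring the
#' tri-axial stack's widths, used for the scalar picture of the M-variants
#' and for the per-channel 1D baseline.
#'
#' @param maps Feature maps per layer.
#' @return List of four [conv_layer_spec]s.
#' @export
scalar_stack <- function(maps = 8L) {
  list(conv_layer_spec(1L, 3L, 1L, maps, conv_dim = "1d"),
       conv_layer_spec(1L, 3L, maps, maps, conv_dim = "1d"),
       conv_layer_spec(1L, 5L, maps, maps, conv_dim = "1d"),
       conv_layer_spec(1L, 5L, maps, maps, conv_dim = "1d"))
}

#' Specify a multi-picture activity-recognition network
#'
#' Variants: `"T"` — one independent 2D stack per axis picture; `"TS"` — one
#' 2D stack shared by the three axis pictures; `"M"`/`"MS"` — T/TS plus a
#' 1D stack over the scalar picture (the scalar branch always has its own
#' parameters, as its geometry differs); `"1D"` — the per-channel baseline:
#' all channels stacked into one picture convolved with time-axis-only
#' kernels at matched depth. Each branch ends in a flatten; the concatenated
#' features feed a single dense softmax layer.
#'
#' @param variant One of `"T"`, `"TS"`, `"M"`, `"MS"`, `"1D"`.
#' @param positions Number of tri-axial positions `P` (picture height).
#' @param window Window length `T` (picture width).
#' @param classes Character vector of class labels (defines output order).
#' @param maps Feature maps per conv layer (64 in the reference model).
#' @param scalars Number of scalar channels `S` (required for M/MS).
#' @param conv_stack Optional explicit stack for the tri-axial branches;
#'   default [compact_stack] sized to `positions` (use
#'   [reference_stack] for tall pictures).
#' @param scalar_conv_stack Optional explicit stack for the scalar branch.
#' @return An object of class `har_spec`.
#' @export
har_spec <- function(variant, positions, window, classes, maps = 8L,
                     scalars = 0L, conv_stack = NULL,
                     scalar_conv_stack = NULL) {
  variant <- match.arg(variant, c("T", "TS", "M", "MS", "1D"))
  if (variant %in% c("M", "MS") && scalars < 1L)
    stop("M variants need at least one scalar channel")
  if (length(classes) < 2L) stop("need at least two classes")
  if (variant == "1D") {
    conv_stack <- conv_stack %||% scalar_stack(maps)
  } else {
    conv_stack <- conv_stack %||% compact_stack(positions, maps)
  }
  if (variant %in% c("M", "MS"))
    scalar_conv_stack <- scalar_conv_stack %||% scalar_stack(maps)
  structure(list(variant = variant, positions = as.integer(positions),
                 window = as.integer(window),
                 classes = as.character(classes), maps = as.integer(maps),
                 scalars = as.integer(scalars), conv_stack = conv_stack,
                 scalar_conv_stack = scalar_conv_stack),
            class = "har_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Total convolutional-layer parameters of a network
#'
#' Sums [count_layer_params] over the tri-axial stack, multiplied by the
#' number of axis pictures (3) when the stacks are independent and counted
#' once when shared; the scalar branch's own stack (M variants) is added
#' once. Dense-layer parameters are excluded: the accounting covers the
#' convolutional layers, where sharing acts.
#'
#' @param spec A [har_spec], or a list of [conv_layer_spec]s together with
#'   `shared` and `picture_count`.
#' @param shared,picture_count Used when `spec` is a plain stack.
#' @return Integer parameter count.
#' @export
count_conv_params <- function(spec, shared = FALSE, picture_count = 3L) {
  if (inherits(spec, "har_spec")) {
    stack_total <- sum(vapply(spec$conv_stack, count_layer_params, numeric(1)))
    if (spec$variant == "1D") return(as.integer(stack_total))
    shared <- spec$variant %in% c("TS", "MS")
    n <- if (shared) stack_total else 3L * stack_total
    if (!is.null(spec$scalar_conv_stack))
      n <- n + sum(vapply(spec$scalar_conv_stack, count_layer_params,
                          numeric(1)))
    return(as.integer(n))
  }
  stack_total <- sum(vapply(spec, count_layer_params, numeric(1)))
  as.integer(if (shared) stack_total else picture_count * stack_total)
}

# run expr with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", globalenv())
  on.exit(if (has) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

init_stack <- function(stack) {
  lapply(stack, function(sp) {
    fan_in <- sp$kh * sp$kw * sp$n_in
    conv_kernels(array(stats::rnorm(fan_in * sp$n_out, 0, sqrt(2 / fan_in)),
                       c(sp$kh, sp$kw, sp$n_in, sp$n_out)),
                 numeric(sp$n_out), sp$strides)
  })
}

stack_out_shape <- function(stack, h, w) {
  for (sp in stack) {
    if (sp$kh > h || sp$kw > w)
      stop("stack geometry infeasible: kernel ", sp$kh, "x", sp$kw,
           " on a ", h, "x", w, " map")
    h <- conv_out_dim(h, sp$kh, sp$strides[1L])
    w <- conv_out_dim(w, sp$kw, sp$strides[2L])
  }
  c(h, w)
}

branch_plan <- function(spec) {
  switch(spec$variant,
    "T"  = list(list(input = "x", store = 1L), list(input = "y", store = 2L),
                list(input = "z", store = 3L)),
    "TS" = list(list(input = "x", store = 1L), list(input = "y", store = 1L),
                list(input = "z", store = 1L)),
    "M"  = list(list(input = "x", store = 1L), list(input = "y", store = 2L),
                list(input = "z", store = 3L),
                list(input = "scalar", store = 4L)),
    "MS" = list(list(input = "x", store = 1L), list(input = "y", store = 1L),
                list(input = "z", store = 1L),
                list(input = "scalar", store = 2L)),
    "1D" = list(list(input = "all", store = 1L)))
}

branch_input_shape <- function(spec, input) {
  switch(input,
    x = , y = , z = c(spec$positions, spec$window),
    scalar = c(spec$scalars, spec$window),
    all = c(3L * spec$positions + spec$scalars, spec$window))
}

branch_stack_spec <- function(spec, input) {
  if (input == "scalar") spec$scalar_conv_stack else spec$conv_stack
}

#' Build a network from a specification
#'
#' Initializes weights with He-scaled zero-mean Gaussians (biases zero) from
#' a seeded generator; the same seed always yields bit-identical weights. In
#' shared variants the three axis branches reference one parameter store, so
#' they remain identical under any training.
#'
#' @param spec A [har_spec].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `har_network`.
#' @export
build_network <- function(spec, seed = 1L) {
  plan <- branch_plan(spec)
  n_stores <- max(vapply(plan, `[[`, integer(1), "store"))
  store_stack <- character(n_stores)
  for (b in plan) store_stack[b$store] <- b$input
  feat_len <- 0L
  for (b in plan) {
    shp <- branch_input_shape(spec, b$input)
    stk <- branch_stack_spec(spec, b$input)
    if (stk[[1L]]$n_in != 1L)
      stop("first layer of each stack must take 1 input map")
    out <- stack_out_shape(stk, shp[1L], shp[2L])
    feat_len <- feat_len + out[1L] * out[2L] * stk[[length(stk)]]$n_out
  }
  C <- length(spec$classes)
  with_seed(seed, {
    stores <- lapply(seq_len(n_stores), function(i)
      init_stack(branch_stack_spec(spec, store_stack[i])))
    dense <- list(W = matrix(stats::rnorm(C * feat_len, 0, sqrt(2 / feat_len)),
                             C, feat_len),
                  b = numeric(C))
    structure(list(spec = spec, branches = plan, stores = stores,
                   dense = dense, feature_len = feat_len, seed = seed,
                   history = numeric()),
              class = "har_network")
  })
}

#' @export
print.har_network <- function(x, ...) {
  cat("<har_network> variant ", x$spec$variant, ", ",
      length(x$branches), " branch(es), ",
      length(x$spec$classes), " classes\n",
      "  conv parameters: ", count_conv_params(x$spec),
      " (dense: ", length(x$dense$W) + length(x$dense$b), ")\n", sep = "")
  invisible(x)
}

branch_input_matrix <- function(ap, input) {
  switch(input,
    x = ap$x, y = ap$y, z = ap$z, scalar = ap$scalar,
    all = rbind(ap$x, ap$y, ap$z, ap$scalar))
}

# forward pass with per-layer caches for backprop
forward_cache <- function(net, ap) {
  feats <- vector("list", length(net$branches))
  caches <- vector("list", length(net$branches))
  for (bi in seq_along(net$branches)) {
    b <- net$branches[[bi]]
    x <- as_feature_maps(branch_input_matrix(ap, b$input))
    stack <- net$stores[[b$store]]
    inputs <- vector("list", length(stack))
    zs <- vector("list", length(stack))
    for (l in seq_along(stack)) {
      inputs[[l]] <- x
      z <- conv2d_forward(x, stack[[l]])
      zs[[l]] <- z
      x <- activate(z)
    }
    feats[[bi]] <- as.vector(x)
    caches[[bi]] <- list(inputs = inputs, zs = zs, out_dim = dim(x))
  }
  features <- unlist(feats)
  probs <- dense_softmax_forward(features, net$dense$W, net$dense$b)
  list(probs = probs, features = features, caches = caches,
       feat_lens = lengths(feats))
}

#' Forward pass of a network on one picture set
#'
#' Per picture: four convolution+ReLU stages, then flatten; the concatenated
#' branch features pass through the dense softmax head.
#'
#' @param net A `har_network` from [build_network].
#' @param ap An `action_pictures` object.
#' @return Named probability vector over the spec's classes.
#' @export
network_forward <- function(net, ap) {
  p <- forward_cache(net, ap)$probs
  names(p) <- net$spec$classes
  p
}

zero_like_stack <- function(stack) {
  lapply(stack, function(k) list(weights = array(0, dim(k$weights)),
                                 biases = numeric(length(k$biases))))
}

#' Loss and analytic gradients for one labeled picture set
#'
#' Cross-entropy loss of the softmax output against the true class, with
#' gradients for every convolutional store and the dense head. Branches that
#' share a store contribute the *sum* of their per-branch gradients (the
#' chain rule over shared parameters).
#'
#' @param net A `har_network`.
#' @param ap An `action_pictures` object.
#' @param y_index 1-based index of the true class in `net$spec$classes`.
#' @return List with `loss`, `probs`, and `grads` (stores + dense, shaped
#'   like the network's parameters).
#' @export
network_gradients <- function(net, ap, y_index) {
  fc <- forward_cache(net, ap)
  loss <- -log(fc$probs[y_index])
  d_logits <- fc$probs
  d_logits[y_index] <- d_logits[y_index] - 1
  g_dense <- list(W = outer(d_logits, fc$features), b = d_logits)
  d_feat <- as.vector(crossprod(net$dense$W, d_logits))
  g_stores <- lapply(net$stores, zero_like_stack)
  offset <- 0L
  for (bi in seq_along(net$branches)) {
    b <- net$branches[[bi]]
    cache <- fc$caches[[bi]]
    stack <- net$stores[[b$store]]
    len <- fc$feat_lens[bi]
    slice <- d_feat[seq.int(offset + 1L, offset + len)]
    offset <- offset + len
    L <- length(stack)
    delta <- array(slice, cache$out_dim) * activate_grad(cache$zs[[L]])
    for (l in seq.int(L, 1L)) {
      g <- conv_weight_grad(delta, cache$inputs[[l]], stack[[l]])
      g_stores[[b$store]][[l]]$weights <-
        g_stores[[b$store]][[l]]$weights + g$weights
      g_stores[[b$store]][[l]]$biases <-
        g_stores[[b$store]][[l]]$biases + g$biases
      if (l > 1L)
        delta <- conv_backward_delta(delta, stack[[l]], cache$zs[[l - 1L]])
    }
  }
  list(loss = as.numeric(loss), probs = fc$probs,
       grads = list(stores = g_stores, dense = g_dense))
}

#' Flatten network parameters to a vector / restore them from one
#'
#' Order: stores (in index order, per layer: weights then biases), then the
#' dense weights and biases.
#'
#' @param net A `har_network`.
#' @return `network_params` returns a numeric vector; `set_network_params`
#'   returns the updated network.
#' @export
network_params <- function(net) {
  c(unlist(lapply(net$stores, function(st)
      unlist(lapply(st, function(k) c(k$weights, k$biases))))),
    as.vector(net$dense$W), net$dense$b)
}

#' @rdname network_params
#' @param params Numeric vector as produced by `network_params`.
#' @export
set_network_params <- function(net, params) {
  pos <- 0L
  take <- function(n) {
    out <- params[seq.int(pos + 1L, pos + n)]
    pos <<- pos + n
    out
  }
  for (si in seq_along(net$stores)) for (li in seq_along(net$stores[[si]])) {
    k <- net$stores[[si]][[li]]
    net$stores[[si]][[li]]$weights <- array(take(length(k$weights)),
                                            dim(k$weights))
    net$stores[[si]][[li]]$biases <- take(length(k$biases))
  }
  net$dense$W <- matrix(take(length(net$dense$W)), nrow(net$dense$W))
  net$dense$b <- take(length(net$dense$b))
  if (pos != length(params)) stop("parameter vector length mismatch")
  net
}

grads_as_vector <- function(net, grads) {
  c(unlist(lapply(grads$stores, function(st)
      unlist(lapply(st, function(g) c(g$weights, g$biases))))),
    as.vector(grads$dense$W), grads$dense$b)
}

#' Training configuration
#'
#' @param learning_rate SGD step size (default 0.01, the reference setting).
#' @param epochs Maximum number of passes over the data.
#' @param batch_size Mini-batch size (default 32).
#' @param threshold Stop when the maximum absolute parameter change over an
#'   epoch falls below this value (default 0: run all epochs).
#' @param seed Seed for the epoch shuffling.
#' @return An object of class `training_config`.
#' @export
training_config <- function(learning_rate = 0.01, epochs = 20L,
                            batch_size = 32L, threshold = 0, seed = 1L) {
  if (learning_rate < 0) stop("learning_rate must be >= 0")
  if (threshold < 0) stop("threshold must be >= 0")
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), threshold = threshold,
                 seed = as.integer(seed)),
            class = "training_config")
}

#' Train a network by mini-batch gradient descent
#'
#' Minimizes the mean cross-entropy over the samples with plain SGD (batch
#' gradients averaged). Training stops when the epoch budget is exhausted or
#' when the largest absolute parameter change over an epoch drops below
#' `cfg$threshold`. In shared variants the one store receives the summed
#' gradient of the three axis branches.
#'
#' @param net A `har_network`.
#' @param pics List of `action_pictures` with labels drawn from the spec's
#'   classes.
#' @param cfg A [training_config].
#' @return The trained network; `$history` holds the per-epoch mean loss.
#' @export
train_network <- function(net, pics, cfg = training_config()) {
  if (!length(pics)) stop("need at least one training sample")
  labels <- vapply(pics, `[[`, character(1), "label")
  y <- match(labels, net$spec$classes)
  if (anyNA(y))
    stop("unknown label(s): ",
         paste(unique(labels[is.na(y)]), collapse = ", "))
  n <- length(pics)
  lr <- cfg$learning_rate
  history <- numeric(0)
  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      before <- network_params(net)
      ord <- sample.int(n)
      losses <- numeric(n)
      for (bstart in seq.int(1L, n, by = cfg$batch_size)) {
        idx <- ord[seq.int(bstart, min(bstart + cfg$batch_size - 1L, n))]
        acc <- NULL
        for (i in idx) {
          gi <- network_gradients(net, pics[[i]], y[i])
          losses[i] <- gi$loss
          acc <- if (is.null(acc)) gi$grads else add_grads(acc, gi$grads)
        }
        net <- apply_update(net, acc, lr / length(idx))
      }
      history <- c(history, mean(losses))
      if (!is.finite(history[epoch]))
        stop("training diverged at epoch ", epoch, " (non-finite loss)")
      if (max(abs(network_params(net) - before)) < cfg$threshold) break
    }
  })
  net$history <- history
  net
}

add_grads <- function(a, b) {
  for (si in seq_along(a$stores)) for (li in seq_along(a$stores[[si]])) {
    a$stores[[si]][[li]]$weights <-
      a$stores[[si]][[li]]$weights + b$stores[[si]][[li]]$weights
    a$stores[[si]][[li]]$biases <-
      a$stores[[si]][[li]]$biases + b$stores[[si]][[li]]$biases
  }
  a$dense$W <- a$dense$W + b$dense$W
  a$dense$b <- a$dense$b + b$dense$b
  a
}

apply_update <- function(net, grads, step) {
  for (si in seq_along(net$stores)) for (li in seq_along(net$stores[[si]])) {
    net$stores[[si]][[li]]$weights <-
      net$stores[[si]][[li]]$weights - step * grads$stores[[si]][[li]]$weights
    net$stores[[si]][[li]]$biases <-
      net$stores[[si]][[li]]$biases - step * grads$stores[[si]][[li]]$biases
  }
  net$dense$W <- net$dense$W - step * grads$dense$W
  net$dense$b <- net$dense$b - step * grads$dense$b
  net
}

#' Predict class labels for picture sets
#'
#' @param object A trained `har_network`.
#' @param pics List of `action_pictures`.
#' @param ... Unused.
#' @return Character vector of predicted class labels (argmax probability).
#' @export
predict.har_network <- function(object, pics, ...) {
  vapply(pics, function(ap)
    object$spec$classes[which.max(forward_cache(object, ap)$probs)],
    character(1))
}

#' Save / load a network checkpoint
#'
#' The checkpoint is a single file holding the spec, seed, weights and
#' training history; reloading reproduces forward outputs bit-exactly.
#'
#' @param net A `har_network`.
#' @param path Checkpoint file path.
#' @return `save_network` returns `path` invisibly; `load_network` the
#'   restored network.
#' @export
save_network <- function(net, path) {
  saveRDS(net, path)
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  net <- readRDS(path)
  if (!inherits(net, "har_network")) stop("not a network checkpoint: ", path)
  net
}

#' Check analytic gradients against central finite differences
#'
#' Treats the full parameter vector as the argument of the cross-entropy
#' loss on one sample and compares [network_gradients] with
#' [finite_difference_grads]. The relative error uses a floored denominator
#' `max(|analytic|, |numeric|, floor)` so that near-zero gradients are
#' compared absolutely.
#'
#' @param net A `har_network`.
#' @param ap A labeled `action_pictures` sample.
#' @param y_index 1-based true-class index.
#' @param eps Finite-difference step.
#' @param floor Denominator floor for the relative error.
#' @return List with `max_rel_err`, `n_params`, and `min_abs_z` (the closest
#'   approach of any pre-activation to the ReLU kink; finite-difference
#'   comparisons are only meaningful when `min_abs_z` comfortably exceeds
#'   the perturbation that `eps` can induce).
#' @export
gradient_check <- function(net, ap, y_index, eps = 1e-6, floor = 1e-3) {
  analytic <- network_gradients(net, ap, y_index)
  ga <- grads_as_vector(net, analytic$grads)
  theta <- network_params(net)
  f <- function(v) network_gradients(set_network_params(net, v), ap,
                                     y_index)$loss
  gn <- finite_difference_grads(f, theta, eps)
  fc <- forward_cache(net, ap)
  min_z <- min(vapply(fc$caches, function(cc)
    min(vapply(cc$zs, function(z) min(abs(z)), numeric(1))), numeric(1)))
  list(max_rel_err = max(abs(ga - gn) / pmax(abs(ga), abs(gn), floor)),
       n_params = length(theta), min_abs_z = min_z)
}

#' Run gradient checks on a batch of random small networks
#'
#' Builds `n_networks` random two-conv-layer networks (4-position, 12-sample
#' pictures, 3 classes), alternating independent-stack and shared-stack
#' variants (the shared case exercises the summed gradient through all three
#' branches), feeds each a random labeled picture set, and gradient-checks
#' it. Draws whose pre-activations pass within `10 * eps` of the ReLU kink
#' are redrawn, since the finite-difference oracle is only valid where no
#' kink is crossed.
#'
#' @param n_networks Number of networks to check.
#' @param seed Base seed.
#' @param eps Finite-difference step.
#' @return Data frame with one row per network: `variant`, `n_params`,
#'   `max_rel_err`.
#' @export
gradient_check_suite <- function(n_networks = 20L, seed = 1L, eps = 1e-6) {
  small_stack <- list(conv_layer_spec(3L, 3L, 1L, 2L),
                      conv_layer_spec(2L, 3L, 2L, 2L))
  res <- vector("list", n_networks)
  for (i in seq_len(n_networks)) {
    variant <- if (i %% 2L == 0L) "TS" else "T"
    spec <- har_spec(variant, positions = 4L, window = 12L,
                     classes = c("a", "b", "c"), conv_stack = small_stack)
    draw <- 0L
    repeat {
      s <- seed + 1000L * i + draw
      net <- build_network(spec, seed = s)
      ap <- with_seed(s + 7L, structure(
        list(x = matrix(stats::rnorm(48), 4, 12),
             y = matrix(stats::rnorm(48), 4, 12),
             z = matrix(stats::rnorm(48), 4, 12),
             scalar = NULL, label = "a"),
        class = "action_pictures"))
      y_index <- 1L + (i %% 3L)
      chk <- gradient_check(net, ap, y_index, eps = eps)
      if (chk$min_abs_z > 10 * eps || draw >= 20L) break
      draw <- draw + 1L
    }
    res[[i]] <- data.frame(variant = variant, n_params = chk$n_params,
                           max_rel_err = chk$max_rel_err)
  }
  do.call(rbind, res)
}
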