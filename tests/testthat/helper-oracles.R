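# Independent brute-force oracles and small fixture builders. The oracles
# use explicit nested loops and never touch the package's im2col path.

brute_conv <- function(x, weights, biases, strides = c(1L, 1L)) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  d <- dim(x); dw <- dim(weights)
  h_out <- (d[1L] - dw[1L]) %/% strides[1L] + 1L
  w_out <- (d[2L] - dw[2L]) %/% strides[2L] + 1L
  out <- array(0, c(h_out, w_out, dw[4L]))
  for (ko in seq_len(dw[4L])) for (i in seq_len(h_out)) for (j in seq_len(w_out)) {
    acc <- biases[ko]
    for (ki in seq_len(dw[3L])) for (u in seq_len(dw[1L])) for (v in seq_len(dw[2L])) {
      acc <- acc + weights[u, v, ki, ko] *
        x[(i - 1L) * strides[1L] + u, (j - 1L) * strides[2L] + v, ki]
    }
    out[i, j, ko] <- acc
  }
  out
}

brute_maxpool <- function(x, pool) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  d <- dim(x)
  h_out <- d[1L] %/% pool[1L]; w_out <- d[2L] %/% pool[2L]
  out <- array(0, c(h_out, w_out, d[3L]))
  for (k in seq_len(d[3L])) for (i in seq_len(h_out)) for (j in seq_len(w_out)) {
    tile <- x[seq.int((i - 1L) * pool[1L] + 1L, i * pool[1L]),
              seq.int((j - 1L) * pool[2L] + 1L, j * pool[2L]), k]
    out[i, j, k] <- max(tile)
  }
  out
}

random_kernels <- function(kh, kw, kin, kout, strides = c(1L, 1L)) {
  conv_kernels(array(rnorm(kh * kw * kin * kout), c(kh, kw, kin, kout)),
               rnorm(kout), strides)
}

random_pictures <- function(P = 4L, T = 12L, S = 0L, label = "a") {
  scalar <- if (S >= 1L) matrix(rnorm(S * T), S, T) else NULL
  structure(list(x = matrix(rnorm(P * T), P, T),
                 y = matrix(rnorm(P * T), P, T),
                 z = matrix(rnorm(P * T), P, T),
                 scalar = scalar, label = label),
            class = "action_pictures")
}

tiny_recording <- function(n = 60L, P = 2L, S = 0L, seed = 1L) {
  profiles <- list(
    a = activity_profile("a", 0.5, 0.10, 0.8, 0.02,
                         c("screen-up", "upright")),
    b = activity_profile("b", 0.7, 0.21, 0.8, 0.02,
                         c("upright", "left-side-down")))
  k <- max(2L, as.integer(round(n / 30)))
  lens <- rep(n %/% k, k)
  lens[1L] <- lens[1L] + n - sum(lens)
  plan <- data.frame(label = rep(c("a", "b"), length.out = k),
                     length = lens)
  simulate_recording(profiles, P, plan, scalars = S, seed = seed)
}
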