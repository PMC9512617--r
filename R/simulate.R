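# Synthetic multi-position accelerometer simulator.
#
# Each channel is gravity (from an axis-aligned device pose) plus activity
# oscillation split into a component shared across positions on the same axis
# (weight kappa) and a position-private component (weight 1 - kappa), plus
# Gaussian noise. Readings are in units of g.

.poses <- c("left-side-down", "right-side-down", "upright", "head-down",
            "screen-up", "screen-down")

#' Static accelerometer reading for an axis-aligned device pose
#'
#' A resting tri-axial accelerometer reports the gravity reaction along the
#' axis pointing away from the ground: lying on its left side the x axis
#' reads `+g`; on its right side `-g`; upright (head up) `+g` on y; head
#' down `-g` on y; screen up `+g` on z; screen down `-g` on z. The Euclidean
#' norm is `g` in every pose.
#'
#' @param pose One of `"left-side-down"`, `"right-side-down"`, `"upright"`,
#'   `"head-down"`, `"screen-up"`, `"screen-down"`.
#' @param g Gravitational constant (default 1: readings in units of g).
#' @return Numeric vector `c(a_x, a_y, a_z)`.
#' @export
gravity_vector <- function(pose, g = 1) {
  switch(match.arg(pose, .poses),
    "left-side-down"  = c(g, 0, 0),
    "right-side-down" = c(-g, 0, 0),
    "upright"         = c(0, g, 0),
    "head-down"       = c(0, -g, 0),
    "screen-up"       = c(0, 0, g),
    "screen-down"     = c(0, 0, -g))
}

#' Define a synthetic activity
#'
#' @param name Activity label.
#' @param amplitude Oscillation amplitude in g (0 for a static activity).
#' @param frequency Oscillation frequency in cycles/sample, in `[0, 0.5)`.
#' @param kappa Axis-coupling factor in `[0, 1]`: the weight of the
#'   oscillation component shared by all positions on the same axis.
#'   `kappa = 1` makes same-axis channels perfectly coherent across
#'   positions.
#' @param noise_sd Gaussian noise standard deviation in g.
#' @param orientations Character vector of device poses, one per position
#'   (recycled), setting each position's gravity baseline during the
#'   activity.
#' @return An object of class `activity_profile`.
#' @export
activity_profile <- function(name, amplitude, frequency, kappa = 0.8,
                             noise_sd = 0.05,
                             orientations = "screen-up") {
  if (amplitude < 0) stop("amplitude must be >= 0")
  if (frequency < 0 || frequency >= 0.5)
    stop("frequency must be in [0, 0.5) cycles/sample")
  if (kappa < 0 || kappa > 1) stop("kappa must be in [0, 1]")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  orientations <- vapply(orientations, match.arg, character(1),
                         choices = .poses)
  structure(list(name = name, amplitude = amplitude, frequency = frequency,
                 kappa = kappa, noise_sd = noise_sd,
                 orientations = unname(orientations)),
            class = "activity_profile")
}

#' Default activity set: five activities plus a NULL class
#'
#' Five oscillatory activities with distinct frequencies, amplitudes and
#' pose signatures, plus a static background ("null") class, mimicking the
#' structure of mid-level gesture labels with a NULL class in body-worn
#' activity datasets.
#'
#' @param kappa Axis-coupling factor applied to all activities.
#' @param noise_sd Noise level in g applied to all activities.
#' @return Named list of [activity_profile]s.
#' @export
default_profiles <- function(kappa = 0.8, noise_sd = 0.08) {
  mk <- function(name, amp, freq, ori)
    activity_profile(name, amp, freq, kappa, noise_sd, ori)
  list(
    null  = mk("null",  0.00, 0.00, c("screen-up")),
    walk  = mk("walk",  0.60, 0.05, c("upright", "screen-up")),
    run   = mk("run",   0.90, 0.09, c("upright", "screen-down")),
    reach = mk("reach", 0.50, 0.14, c("left-side-down", "upright")),
    stir  = mk("stir",  0.45, 0.20, c("screen-up", "right-side-down")),
    wave  = mk("wave",  0.70, 0.27, c("head-down", "left-side-down")))
}

#' Default imbalanced segment plan
#'
#' A label track plan mimicking the class imbalance of real activity
#' datasets (a sizeable NULL share, a few dominant activities, a rare one).
#' Each class's total duration is split into several contiguous segments and
#' the segments are interleaved in a seeded random order.
#'
#' @param n_samples Total number of timestamps.
#' @param seed Seed for the interleaving order.
#' @return Data frame with columns `label` and `length` (segment plan).
#' @export
default_segment_plan <- function(n_samples = 24000L, seed = 1L) {
  shares <- c(null = 0.25, walk = 0.28, run = 0.18, reach = 0.13,
              stir = 0.10, wave = 0.06)
  totals <- round(n_samples * shares)
  totals[1L] <- totals[1L] + (n_samples - sum(totals))
  segs <- do.call(rbind, lapply(names(totals), function(lb) {
    k <- max(1L, round(totals[[lb]] / 600))
    lens <- rep(totals[[lb]] %/% k, k)
    lens[1L] <- lens[1L] + totals[[lb]] %% k
    data.frame(label = lb, length = lens)
  }))
  with_seed(seed, segs[sample.int(nrow(segs)), , drop = FALSE])
}

#' Simulate a multi-position recording
#'
#' Concatenates activity segments. Within a segment with profile `pr`, the
#' channel of position `p`, axis `a` is
#' `gravity + pr$amplitude * (kappa * shared_a(t) + (1-kappa) * private_pa(t))
#'  + noise`, where `shared_a` is one sinusoid per axis (axis-specific
#' incommensurate frequency multipliers keep different axes uncorrelated)
#' and `private_pa` a sinusoid of the same frequency with a random phase per
#' position. Scalar channels are smoothed Gaussian random walks. Identical
#' seeds give identical recordings.
#'
#' @param profiles Named list of [activity_profile]s covering every label in
#'   the plan.
#' @param positions Character vector of position names, or a count.
#' @param segment_plan Data frame with columns `label`, `length`.
#' @param scalars Character vector of scalar-channel names, or a count.
#' @param seed Integer seed.
#' @param g Gravitational constant (default 1).
#' @return An [mp_recording].
#' @export
simulate_recording <- function(profiles, positions = 4L,
                               segment_plan = default_segment_plan(),
                               scalars = 0L, seed = 1L, g = 1) {
  if (length(profiles) < 2L) stop("need at least two activity profiles")
  if (is.numeric(positions))
    positions <- paste0("p", seq_len(positions))
  if (length(positions) < 1L) stop("need at least one position")
  if (is.numeric(scalars))
    scalars <- if (scalars >= 1L) paste0("s", seq_len(scalars)) else character()
  if (!nrow(segment_plan)) stop("empty segment plan")
  missing <- setdiff(unique(segment_plan$label), names(profiles))
  if (length(missing))
    stop("segment plan uses label(s) without a profile: ",
         paste(missing, collapse = ", "))
  layout <- sensor_layout(positions, scalars)
  P <- length(positions)
  n <- sum(segment_plan$length)
  axis_mult <- c(1, 1.31, 1.73)  # incommensurate: axes stay uncorrelated
  with_seed(seed, {
    ch <- matrix(0, n, 3L * P + length(scalars),
                 dimnames = list(NULL, layout_channel_names(layout)))
    labels <- character(n)
    at <- 0L
    for (si in seq_len(nrow(segment_plan))) {
      len <- segment_plan$length[si]
      pr <- profiles[[segment_plan$label[si]]]
      idx <- seq.int(at + 1L, at + len)
      labels[idx] <- pr$name
      tt <- seq_len(len) - 1L
      shared_phase <- stats::runif(3L, 0, 2 * pi)
      for (a in 1:3) {
        fa <- pr$frequency * axis_mult[a]
        shared <- pr$amplitude * sin(2 * pi * fa * tt + shared_phase[a])
        for (p in seq_len(P)) {
          pose <- pr$orientations[(p - 1L) %% length(pr$orientations) + 1L]
          priv <- pr$amplitude *
            sin(2 * pi * fa * tt + stats::runif(1L, 0, 2 * pi))
          col <- paste(positions[p], c("x", "y", "z")[a], sep = "_")
          ch[idx, col] <- gravity_vector(pose, g)[a] +
            pr$kappa * shared + (1 - pr$kappa) * priv +
            stats::rnorm(len, 0, pr$noise_sd)
        }
      }
      at <- at + len
    }
    for (s in scalars) {
      walk <- cumsum(stats::rnorm(n, 0, 0.1))
      ch[, s] <- as.numeric(stats::filter(walk, rep(1 / 9, 9), sides = 2L))
      ch[is.na(ch[, s]), s] <- walk[is.na(ch[, s])]
    }
    mp_recording(ch, layout, labels)
  })
}

#' Per-label sample counts of a recording
#'
#' @param rec An [mp_recording].
#' @return Named integer vector; the counts sum to the recording length.
#' @export
class_balance <- function(rec) {
  tab <- table(rec$labels)
  stats::setNames(as.integer(tab), names(tab))
}
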