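# Sliding-window segmentation and action-picture construction.

#' Cut a recording into labeled sliding windows
#'
#' Windows of `window` timestamps start at 0, `step`, `2*step`, ... with
#' `step = round(window * (1 - overlap))` (minimum 1), using 0-based,
#' half-open indexing. When the recording has `n >= window` samples the
#' window count is `floor((n - window)/step) + 1`; shorter recordings give an
#' empty result. Each window is labeled with the activity label at its final
#' timestamp.
#'
#' @param rec An [mp_recording].
#' @param window Window length in timestamps (default 24).
#' @param overlap Fractional overlap between consecutive windows in `[0, 1)`
#'   (default 0.5, i.e. a step of half the window).
#' @return List of `windowed_sample` objects, each with `start` (0-based),
#'   `length`, `data` (a `window x channels` matrix) and `label`.
#' @export
segment_windows <- function(rec, window = 24L, overlap = 0.5) {
  window <- as.integer(window)
  if (window < 1L) stop("window must be >= 1")
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)")
  step <- max(1L, as.integer(round(window * (1 - overlap))))
  n <- nrow(rec$channels)
  if (n < window) return(list())
  starts <- seq.int(0L, n - window, by = step)
  lapply(starts, function(s) {
    idx <- seq.int(s + 1L, s + window)
    structure(list(start = s, length = window,
                   data = rec$channels[idx, , drop = FALSE],
                   label = rec$labels[s + window]),
              class = "windowed_sample")
  })
}

#' Assemble per-axis action pictures from a window
#'
#' Rearranges one window into the 2D-CNN input unit: three matrices (one per
#' accelerometer axis) of shape `P x T` whose row `p` is position `p`'s
#' channel for that axis over the window, plus, when the layout has scalar
#' channels, an `S x T` scalar picture ("3 or 4 action pictures"). Row order
#' is the layout's configured position order; every picture value is a pure
#' re-indexing of a raw channel value, with no aggregation.
#'
#' @param w A `windowed_sample` from [segment_windows].
#' @param layout The recording's [sensor_layout].
#' @return An object of class `action_pictures` with fields `x`, `y`, `z`
#'   (each `P x T`), `scalar` (`S x T` or `NULL`) and `label`.
#' @export
build_action_pictures <- function(w, layout) {
  P <- length(layout$positions)
  pic <- function(axis) {
    m <- t(w$data[, paste(layout$positions, axis, sep = "_"), drop = FALSE])
    rownames(m) <- layout$positions
    m
  }
  scalar <- NULL
  if (length(layout$scalars)) {
    scalar <- t(w$data[, layout$scalars, drop = FALSE])
    rownames(scalar) <- layout$scalars
  }
  structure(list(x = pic("x"), y = pic("y"), z = pic("z"),
                 scalar = scalar, label = w$label),
            class = "action_pictures")
}

#' Windowing plus picture construction for a whole recording
#'
#' @param rec An [mp_recording].
#' @inheritParams segment_windows
#' @return List of `action_pictures`.
#' @export
recording_to_pictures <- function(rec, window = 24L, overlap = 0.5) {
  lapply(segment_windows(rec, window, overlap),
         build_action_pictures, layout = rec$layout)
}
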