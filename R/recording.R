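# Multi-position recordings: container, validation, CSV and Feather I/O,
# per-channel normalization.

#' Describe the sensor layout of a recording
#'
#' @param positions Character vector of body-position identifiers, each
#'   carrying one tri-axial accelerometer (channels `<pos>_x/_y/_z`).
#' @param scalars Character vector of scalar channel names (e.g. a
#'   heart-rate-like stream); may be empty.
#' @param label_col Name of the activity-label column.
#' @return An object of class `sensor_layout`.
#' @export
sensor_layout <- function(positions, scalars = character(), label_col = "label") {
  positions <- as.character(positions)
  scalars <- as.character(scalars)
  if (length(positions) < 1L) stop("at least one position is required")
  if (anyDuplicated(c(positions, scalars)))
    stop("position and scalar names must be unique")
  structure(list(positions = positions, scalars = scalars,
                 label_col = label_col),
            class = "sensor_layout")
}

layout_channel_names <- function(layout) {
  c(as.vector(t(outer(layout$positions, c("x", "y", "z"),
                      function(p, a) paste(p, a, sep = "_")))),
    layout$scalars)
}

#' Construct a multi-position recording
#'
#' A recording holds, per timestamp (uniform sampling, indexed 0-based), one
#' tri-axial sample per body position (in units of g), optional scalar
#' channels, and an activity label (a finite label set that may include a
#' NULL/background class).
#'
#' @param channels Numeric matrix, one row per timestamp; columns named
#'   `<pos>_x, <pos>_y, <pos>_z` for every position, then one column per
#'   scalar channel.
#' @param layout A [sensor_layout] matching the columns.
#' @param labels Character vector of per-timestamp activity labels.
#' @return An object of class `mp_recording`.
#' @export
mp_recording <- function(channels, layout, labels) {
  channels <- as.matrix(channels)
  expect_cols <- layout_channel_names(layout)
  missing <- setdiff(expect_cols, colnames(channels))
  if (length(missing))
    stop("recording format error: missing channel column(s): ",
         paste(missing, collapse = ", "))
  channels <- channels[, expect_cols, drop = FALSE]
  if (length(labels) != nrow(channels))
    stop("recording integrity error: ", nrow(channels), " samples but ",
         length(labels), " labels")
  if (!is.numeric(channels) || anyNA(channels) || any(!is.finite(channels)))
    stop("recording integrity error: channels must be finite numeric, no gaps")
  structure(list(channels = channels, layout = layout,
                 labels = as.character(labels)),
            class = "mp_recording")
}

#' @export
print.mp_recording <- function(x, ...) {
  cat("<mp_recording> ", nrow(x$channels), " samples, ",
      length(x$layout$positions), " tri-axial position(s)",
      if (length(x$layout$scalars))
        paste0(" + ", length(x$layout$scalars), " scalar channel(s)"),
      "\n  positions: ", paste(x$layout$positions, collapse = ", "),
      "\n  labels: ", paste(names(table(x$labels)), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' @export
length.mp_recording <- function(x) nrow(x$channels)

#' Extract one channel of a recording
#'
#' @param rec An [mp_recording].
#' @param position Position name (tri-axial channels) or `NULL` for scalars.
#' @param axis One of `"x"`, `"y"`, `"z"`, or a scalar channel name when
#'   `position` is `NULL`.
#' @return Numeric vector of samples.
#' @export
channel <- function(rec, position, axis) {
  nm <- if (is.null(position)) axis else paste(position, axis, sep = "_")
  if (!nm %in% colnames(rec$channels)) stop("no such channel: ", nm)
  rec$channels[, nm]
}

#' Read a recording from delimited text
#'
#' Expects the package CSV dialect: a header row, one row per timestamp, and
#' columns `t, <pos>_x, <pos>_y, <pos>_z, ..., <scalar>..., <label_col>`.
#'
#' @param path Path to a CSV file.
#' @param layout The expected [sensor_layout]; columns are validated against
#'   it and a missing column raises a format error naming the column.
#' @return An [mp_recording].
#' @export
read_recording <- function(path, layout) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c(layout_channel_names(layout), layout$label_col)
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("recording format error: missing column(s): ",
         paste(missing, collapse = ", "))
  mp_recording(as.matrix(df[layout_channel_names(layout)]), layout,
               df[[layout$label_col]])
}

#' Write a recording as delimited text
#'
#' @param rec An [mp_recording].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(rec, path) {
  df <- data.frame(t = seq_len(nrow(rec$channels)) - 1L,
                   rec$channels, check.names = FALSE)
  df[[rec$layout$label_col]] <- rec$labels
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write the binary columnar fixture format
#'
#' Recordings are stored as Arrow/Feather tables (one column per channel plus
#' the label track) with the layout embedded in the column names, giving a
#' compact, typed, language-neutral fixture container.
#'
#' @param rec An [mp_recording].
#' @param path Feather file path.
#' @return `write_recording_fixture` returns `path` invisibly;
#'   `read_recording_fixture` returns an [mp_recording].
#' @export
write_recording_fixture <- function(rec, path) {
  df <- data.frame(rec$channels, check.names = FALSE)
  df[[rec$layout$label_col]] <- rec$labels
  arrow::write_feather(df, path)
  invisible(path)
}

#' @rdname write_recording_fixture
#' @param layout The expected [sensor_layout].
#' @export
read_recording_fixture <- function(path, layout) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- as.data.frame(arrow::read_feather(path))
  need <- c(layout_channel_names(layout), layout$label_col)
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("recording format error: missing column(s): ",
         paste(missing, collapse = ", "))
  mp_recording(as.matrix(df[layout_channel_names(layout)]), layout,
               df[[layout$label_col]])
}

#' Per-channel statistics for normalization
#'
#' @param rec An [mp_recording] (typically the training split only, so that
#'   held-out data is scaled with training statistics).
#' @return List with numeric vectors `mean` and `sd` (population standard
#'   deviation, i.e. root-mean-square deviation), one entry per channel.
#' @export
channel_stats <- function(rec) {
  m <- colMeans(rec$channels)
  list(mean = m,
       sd = sqrt(colMeans(sweep(rec$channels, 2L, m, "-")^2)))
}

#' Z-score the channels of a recording
#'
#' Centers every channel to mean 0 and scales non-constant channels to unit
#' population standard deviation (so a two-point channel `c(1, 3)` maps to
#' `c(-1, 1)`); constant channels map to all-zero rather than dividing
#' by zero. Raw accelerometer channels carry pose-dependent gravity offsets
#' of order 1 g, so unnormalized inputs would be dominated by those offsets.
#'
#' @param rec An [mp_recording] with at least 2 samples.
#' @param stats Optional precomputed [channel_stats] (use the training
#'   split's statistics to scale a held-out split).
#' @return A normalized [mp_recording].
#' @export
normalize_channels <- function(rec, stats = NULL) {
  if (nrow(rec$channels) < 2L) stop("need at least 2 samples per channel")
  if (is.null(stats)) stats <- channel_stats(rec)
  sds <- ifelse(stats$sd > 0, stats$sd, 1)
  ch <- sweep(rec$channels, 2L, stats$mean, "-")
  ch <- sweep(ch, 2L, sds, "/")
  # a constant channel equal to a *different* constant than the training mean
  # still gets centered; a channel constant at the training mean becomes 0
  out <- rec
  out$channels <- ch
  out
}

#' Split a recording into contiguous time blocks
#'
#' Used for train/test splitting: contiguous blocks avoid information leakage
#' between overlapping windows that a shuffled window-level split would cause.
#'
#' @param rec An [mp_recording].
#' @param fraction Fraction of samples in the first (training) block.
#' @return List with elements `train` and `test`, both [mp_recording]s.
#' @export
split_recording <- function(rec, fraction = 0.7) {
  stopifnot(fraction > 0, fraction < 1)
  n <- nrow(rec$channels)
  cut <- floor(n * fraction)
  idx1 <- seq_len(cut); idx2 <- seq.int(cut + 1L, n)
  mk <- function(idx) mp_recording(rec$channels[idx, , drop = FALSE],
                                   rec$layout, rec$labels[idx])
  list(train = mk(idx1), test = mk(idx2))
}
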