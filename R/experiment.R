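# Run configuration and the end-to-end experiment pipeline: simulate ->
# window -> pictures -> train -> evaluate, plus the variant/sensor-subset
# comparison.

#' Build a run configuration
#'
#' All pipeline entry points consume this structure; [save_run_config] /
#' [load_run_config] round-trip it through YAML without loss. Every run
#' writes its resolved configuration next to its outputs, so any artifact is
#' reproducible from its manifest.
#'
#' @param seed Master seed for simulation, initialization and training.
#' @param positions Number of simulated tri-axial positions.
#' @param scalars Number of scalar channels.
#' @param n_samples Recording length in timestamps.
#' @param kappa Axis-coupling factor of the simulator.
#' @param noise_sd Simulator noise level in g.
#' @param window,overlap Sliding-window length and fractional overlap.
#' @param train_fraction Fraction of the recording in the training block
#'   (contiguous split).
#' @param variant Model variant (see [har_spec]).
#' @param maps Feature maps per convolutional layer.
#' @param subset Optional character vector or count of positions to use
#'   (sensor-subset experiments); default all.
#' @param learning_rate,epochs,batch_size,threshold Training settings
#'   (see [training_config]).
#' @param out_dir Optional output directory.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1L, positions = 4L, scalars = 0L,
                       n_samples = 24000L, kappa = 0.8, noise_sd = 0.08,
                       window = 24L, overlap = 0.5, train_fraction = 0.7,
                       variant = "TS", maps = 8L, subset = NULL,
                       learning_rate = 0.01, epochs = 12L, batch_size = 32L,
                       threshold = 0, out_dir = NULL) {
  structure(list(seed = as.integer(seed), positions = as.integer(positions),
                 scalars = as.integer(scalars),
                 n_samples = as.integer(n_samples), kappa = kappa,
                 noise_sd = noise_sd, window = as.integer(window),
                 overlap = overlap, train_fraction = train_fraction,
                 variant = variant, maps = as.integer(maps), subset = subset,
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), threshold = threshold,
                 out_dir = out_dir),
            class = "run_config")
}

#' Save / load a run configuration (YAML)
#'
#' @param cfg A [run_config].
#' @param path YAML file path.
#' @return `save_run_config` returns `path` invisibly; `load_run_config` the
#'   restored `run_config`.
#' @export
save_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname save_run_config
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals[!vapply(vals, is.null, logical(1))])
}

config_recording <- function(cfg) {
  simulate_recording(default_profiles(kappa = cfg$kappa,
                                      noise_sd = cfg$noise_sd),
                     positions = cfg$positions,
                     segment_plan = default_segment_plan(cfg$n_samples,
                                                         seed = cfg$seed),
                     scalars = cfg$scalars, seed = cfg$seed)
}

subset_recording <- function(rec, subset) {
  if (is.null(subset)) return(rec)
  if (is.numeric(subset)) subset <- rec$layout$positions[seq_len(subset)]
  bad <- setdiff(subset, rec$layout$positions)
  if (length(bad)) stop("unknown position(s): ", paste(bad, collapse = ", "))
  layout <- sensor_layout(subset, rec$layout$scalars, rec$layout$label_col)
  mp_recording(rec$channels[, layout_channel_names(layout), drop = FALSE],
               layout, rec$labels)
}

#' Simulate a recording and write it to disk
#'
#' Writes the CSV dialect, the Feather fixture, and a JSON manifest holding
#' the resolved configuration, per-class counts, and the MD5 of the config
#' file, so the artifact is reproducible from the manifest alone.
#'
#' @param cfg A [run_config] with `out_dir` set (or pass `out_dir`).
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the recording and the written paths.
#' @export
run_simulate <- function(cfg = run_config(), out_dir = cfg$out_dir) {
  if (is.null(out_dir)) stop("an output directory is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rec <- config_recording(cfg)
  paths <- list(csv = file.path(out_dir, "recording.csv"),
                fixture = file.path(out_dir, "recording.feather"),
                config = file.path(out_dir, "config.yaml"),
                manifest = file.path(out_dir, "manifest.json"))
  write_recording_csv(rec, paths$csv)
  write_recording_fixture(rec, paths$fixture)
  save_run_config(cfg, paths$config)
  manifest <- list(seed = cfg$seed,
                   config_md5 = unname(tools::md5sum(paths$config)),
                   n_samples = nrow(rec$channels),
                   positions = rec$layout$positions,
                   scalars = rec$layout$scalars,
                   class_balance = as.list(class_balance(rec)))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(recording = rec, paths = paths))
}

#' Train and evaluate one model on a synthetic task
#'
#' Runs the full pipeline: simulate (or take `recording`), select the
#' position subset, split into contiguous train/test blocks, z-score with
#' training-block statistics, window both blocks, build pictures, train the
#' configured variant, and evaluate on the held-out block. When `out_dir`
#' is set, writes the checkpoint, the evaluation report, the loss history
#' and the resolved config.
#'
#' @param cfg A [run_config].
#' @param recording Optional pre-built [mp_recording] (skips simulation).
#' @return List of class `har_run`: `net`, `report` ([evaluation_report]),
#'   `history`, `conv_params`, `n_train`, `n_test`.
#' @export
run_train <- function(cfg = run_config(), recording = NULL) {
  rec <- subset_recording(recording %||% config_recording(cfg), cfg$subset)
  halves <- split_recording(rec, cfg$train_fraction)
  stats <- channel_stats(halves$train)
  train_pics <- recording_to_pictures(normalize_channels(halves$train, stats),
                                      cfg$window, cfg$overlap)
  test_pics <- recording_to_pictures(normalize_channels(halves$test, stats),
                                     cfg$window, cfg$overlap)
  if (!length(train_pics) || !length(test_pics))
    stop("recording too short for the requested window")
  classes <- sort(unique(rec$labels))
  spec <- har_spec(cfg$variant, positions = length(rec$layout$positions),
                   window = cfg$window, classes = classes, maps = cfg$maps,
                   scalars = length(rec$layout$scalars))
  net <- build_network(spec, seed = cfg$seed)
  tc <- training_config(cfg$learning_rate, cfg$epochs, cfg$batch_size,
                        cfg$threshold, seed = cfg$seed)
  before <- network_params(net)
  net <- train_network(net, train_pics, tc)
  if (cfg$learning_rate == 0 ||
      isTRUE(all.equal(before, network_params(net), tolerance = 0)))
    warning("weights unchanged by training (learning rate 0?)")
  y_true <- vapply(test_pics, `[[`, character(1), "label")
  report <- evaluation_report(y_true, predict(net, test_pics), classes)
  out <- structure(list(net = net, report = report, history = net$history,
                        conv_params = count_conv_params(spec),
                        n_train = length(train_pics),
                        n_test = length(test_pics), config = cfg),
                   class = "har_run")
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    save_network(net, file.path(cfg$out_dir, "checkpoint.rds"))
    save_run_config(cfg, file.path(cfg$out_dir, "config.yaml"))
    writeLines(c(utils::capture.output(print(report)),
                 "",
                 paste("conv parameters:", out$conv_params),
                 paste("per-epoch mean loss:",
                       paste(signif(net$history, 6), collapse = " "))),
               file.path(cfg$out_dir, "report.txt"))
  }
  out
}

#' @export
print.har_run <- function(x, ...) {
  cat("<har_run> variant ", x$config$variant, ": ", x$n_train,
      " train / ", x$n_test, " test windows, ",
      x$conv_params, " conv parameters\n", sep = "")
  cat(sprintf("held-out weighted F1: %.4f, accuracy: %.4f\n",
              x$report$weighted_f1, x$report$accuracy))
  invisible(x)
}

#' Compare model variants across sensor subsets
#'
#' Trains every requested variant on every position-subset size (1..P,
#' taking the first k positions) of one simulated recording and tabulates
#' held-out weighted F1 and convolutional parameter count — the
#' sensor-count versus accuracy trade-off, with the shared variants showing
#' the threefold parameter reduction at matched scores.
#'
#' @param cfg A [run_config]; `variant` is ignored.
#' @param variants Character vector from `c("1D", "T", "TS", "M", "MS")`
#'   (M/MS require `cfg$scalars >= 1`).
#' @param subset_sizes Integer vector of position-subset sizes.
#' @return Data frame: `variant`, `n_positions`, `weighted_f1`, `accuracy`,
#'   `conv_params`.
#' @export
run_compare <- function(cfg = run_config(),
                        variants = c("1D", "T", "TS"),
                        subset_sizes = seq_len(cfg$positions)) {
  if (any(variants %in% c("M", "MS")) && cfg$scalars < 1L)
    stop("M variants need scalars >= 1 in the config")
  rec <- config_recording(cfg)
  rows <- list()
  for (k in subset_sizes) for (v in variants) {
    ck <- cfg
    ck$variant <- v
    ck$subset <- k
    ck$out_dir <- NULL
    run <- run_train(ck, recording = rec)
    rows[[length(rows) + 1L]] <- data.frame(
      variant = v, n_positions = as.integer(k),
      weighted_f1 = run$report$weighted_f1,
      accuracy = run$report$accuracy,
      conv_params = run$conv_params)
  }
  do.call(rbind, rows)
}
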