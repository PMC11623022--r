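#' Pipeline run configuration
#'
#' One nested, JSON-serializable record driving [run_pipeline()]:
#' simulation, preprocessing (0.5 Hz high-pass, 70 Hz target rate),
#' windowing (training windows use 50% overlap, test windows 0% — test
#' decision windows must not share samples), the alpha band, the GAN
#' training settings, the 80/20 train/test split fraction, and the master
#' seed. Every run writes its resolved config next to its outputs.
#'
#' @param out_dir artifact directory.
#' @param seed master seed.
#' @param n_per_class simulated trials per class.
#' @param lateralization,snr,duration_s,n_channels simulation parameters
#'   (see [simulation_config()]).
#' @param window_s,train_overlap decision-window length and training-set
#'   overlap (test windows never overlap).
#' @param band_low,band_high analysis band in Hz.
#' @param train_fraction fraction of trials assigned to training.
#' @param mode `"gan"` (adversarial training + generation) or
#'   `"classifier"` (discriminator-only supervised training).
#' @param epochs,batch_size,width_scale,lr_generator,lr_discriminator GAN
#'   settings (see [train_config()]).
#' @param generated_per_class GAN samples generated per class afterwards.
#' @param noise_levels additive perturbation levels for the robustness
#'   table.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir = tempfile("ssfgan_run_"), seed = 1L,
                       n_per_class = 10L, lateralization = 3, snr = 5,
                       duration_s = 20, n_channels = 64L,
                       window_s = 2, train_overlap = 0.5,
                       band_low = 8, band_high = 13,
                       train_fraction = 0.8, mode = c("classifier", "gan"),
                       epochs = 5L, batch_size = 8L, width_scale = 0.25,
                       lr_generator = 2e-4, lr_discriminator = 1e-4,
                       generated_per_class = 25L,
                       noise_levels = c(1, 3, 5, 7, 9, 11)) {
  mode <- match.arg(mode)
  cfg <- list(out_dir = out_dir, seed = as.integer(seed),
              simulate = list(n_per_class = as.integer(n_per_class),
                              lateralization = lateralization, snr = snr,
                              duration_s = duration_s,
                              n_channels = as.integer(n_channels)),
              preprocess = list(hp_cutoff_hz = 0.5, target_fs = 70),
              window = list(length_s = window_s,
                            train_overlap = train_overlap,
                            test_overlap = 0),
              band = list(low_hz = band_low, high_hz = band_high),
              train = list(mode = mode, epochs = as.integer(epochs),
                           batch_size = as.integer(batch_size),
                           width_scale = width_scale,
                           lr_generator = lr_generator,
                           lr_discriminator = lr_discriminator),
              split = list(train_fraction = train_fraction),
              evaluate = list(generated_per_class =
                                as.integer(generated_per_class),
                              noise_levels = noise_levels))
  structure(cfg, class = "run_config")
}

#' Run the end-to-end pipeline
#'
#' simulate -> preprocess -> trial-level 80/20 split -> SSF extraction
#' (overlapping windows for training, non-overlapping for test) -> GAN or
#' classifier training -> generation (GAN mode) -> evaluation. All artifacts
#' (config, SSF datasets, training history, metric tables, summary) land in
#' `config$out_dir` as CSV/JSON. The split happens at the trial level before
#' windowing, so no test-trial sample can leak into training through window
#' overlap; every map carries trial provenance and the split is recorded.
#' Reruns with the same config are byte-identical.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with the trained model, map sets and metric
#'   tables.
#' @export
run_pipeline <- function(config = run_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(unclass(config),
                       file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  set.seed(config$seed)
  montage <- project_montage(standard_montage(config$simulate$n_channels))
  band <- frequency_band(config$band$low_hz, config$band$high_hz)
  sim <- config$simulate
  labels <- rep(c("left", "right"), sim$n_per_class)
  n_trials <- length(labels)
  # trial-level split before windowing (no window-overlap leakage)
  n_train <- round(config$split$train_fraction * n_trials)
  perm <- sample.int(n_trials)
  train_trials <- sort(perm[seq_len(n_train)])
  spec_train <- decision_window_spec(config$window$length_s,
                                     config$window$train_overlap)
  spec_test <- decision_window_spec(config$window$length_s,
                                    config$window$test_overlap)
  train_maps <- list(); test_maps <- list(); split_rec <- NULL
  for (i in seq_len(n_trials)) {
    cfg_i <- simulation_config(
      n_channels = sim$n_channels, fs = config$preprocess$target_fs,
      duration_s = sim$duration_s, label = labels[i],
      lateralization = sim$lateralization, snr = sim$snr,
      seed = config$seed * 1000L + i)
    rec <- simulate_recording(cfg_i, montage, subject_id = "sim",
                              trial_id = sprintf("trial%03d", i))
    rec <- preprocess_recording(rec, config$preprocess$hp_cutoff_hz,
                                config$preprocess$target_fs)
    in_train <- i %in% train_trials
    maps <- extract_ssf(rec, if (in_train) spec_train else spec_test,
                        band, montage)
    if (in_train) train_maps <- c(train_maps, maps)
    else test_maps <- c(test_maps, maps)
    split_rec <- rbind(split_rec,
                       data.frame(trial_id = rec$trial_id, label = labels[i],
                                  set = if (in_train) "train" else "test",
                                  n_windows = length(maps)))
  }
  utils::write.csv(split_rec, file.path(config$out_dir, "split.csv"),
                   row.names = FALSE)
  write_ssf_dataset(train_maps, file.path(config$out_dir, "ssf_train"))
  write_ssf_dataset(test_maps, file.path(config$out_dir, "ssf_test"))
  tc <- train_config(lr_generator = config$train$lr_generator,
                     lr_discriminator = config$train$lr_discriminator,
                     batch_size = config$train$batch_size,
                     epochs = config$train$epochs,
                     width_scale = config$train$width_scale,
                     seed = config$seed + 1L)
  generated <- NULL; similarity <- NULL
  if (config$train$mode == "gan") {
    model <- train_adgan(train_maps, tc)
    utils::write.csv(model$history,
                     file.path(config$out_dir, "training_history.csv"),
                     row.names = FALSE)
    generated <- generate_maps(model,
                               2L * config$evaluate$generated_per_class,
                               seed = config$seed + 2L)
    write_ssf_dataset(generated, file.path(config$out_dir, "generated"))
    similarity <- similarity_metrics(train_maps, generated)
    utils::write.csv(as.data.frame(similarity),
                     file.path(config$out_dir, "similarity.csv"),
                     row.names = FALSE)
  } else {
    model <- train_classifier(train_maps, tc)
    utils::write.csv(model$history,
                     file.path(config$out_dir, "training_history.csv"),
                     row.names = FALSE)
  }
  pred <- classify_maps(model, test_maps)$labels
  truth <- ssf_labels(test_maps)
  mets <- classification_metrics(confusion_counts(pred, truth))
  metrics_df <- data.frame(precision = mets$precision, recall = mets$recall,
                           f_score = mets$f_score, accuracy = mets$accuracy)
  utils::write.csv(metrics_df, file.path(config$out_dir, "metrics.csv"),
                   row.names = FALSE)
  rob <- robustness_curve(model, test_maps,
                          levels = config$evaluate$noise_levels,
                          seed = config$seed + 3L)
  utils::write.csv(rob, file.path(config$out_dir, "robustness.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(metrics = metrics_df, similarity = similarity,
         n_train_maps = length(train_maps),
         n_test_maps = length(test_maps)),
    file.path(config$out_dir, "summary.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(list(model = model, train_maps = train_maps,
                 test_maps = test_maps, generated = generated,
                 metrics = metrics_df, robustness = rob,
                 similarity = similarity, split = split_rec))
}

#' Augmentation sweep: accuracy over (real fraction x generated count)
#'
#' For every combination of a fraction of the available real training maps
#' and a number of GAN-generated maps added to them, trains a fresh
#' classifier and records test accuracy — the scan behind
#' "how much does augmentation buy when real data is scarce".
#'
#' @param train_maps,test_maps labeled real map sets.
#' @param gan_model trained [train_adgan()] result used to generate samples.
#' @param real_fractions fractions in (0, 1] of the training maps used.
#' @param generated_counts numbers of generated maps added.
#' @param config a [train_config()] for the per-cell classifier.
#' @param seed controls subsampling, generation and training.
#' @return `data.frame` with `real_fraction`, `generated_count`,
#'   `accuracy`; one row per grid cell.
#' @export
augmentation_sweep <- function(train_maps, test_maps, gan_model,
                               real_fractions = c(0.25, 0.5, 1),
                               generated_counts = c(0, 50, 100),
                               config = train_config(epochs = 4L,
                                                     width_scale = 0.25),
                               seed = 1L) {
  truth <- ssf_labels(test_maps)
  labels <- ssf_labels(train_maps)
  out <- NULL
  for (fr in real_fractions) {
    set.seed(seed)
    keep <- unlist(lapply(unique(labels), function(cl) {
      idx <- which(labels == cl)
      sort(sample(idx, max(2L, round(fr * length(idx)))))
    }))
    for (gc in generated_counts) {
      tr <- train_maps[keep]
      if (gc > 0)
        tr <- c(tr, generate_maps(gan_model, gc, seed = seed + gc))
      cfg <- config
      cfg$seed <- seed + round(1000 * fr) + gc
      model <- train_classifier(tr, cfg)
      acc <- mean(classify_maps(model, test_maps)$labels == truth)
      out <- rbind(out, data.frame(real_fraction = fr,
                                   generated_count = gc, accuracy = acc))
    }
  }
  out
}
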