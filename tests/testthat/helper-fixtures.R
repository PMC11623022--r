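# Shared fixtures, built once per session and cached. Everything is
# generated in code; no binary fixtures.

.fx <- new.env(parent = emptyenv())

# High-SNR lateralized dataset: 10 trials/class x 20 s, T = 2 s, 50% overlap
# -> 19 windows/trial, 380 maps total (the parameter-recovery world:
# lateralization 3, snr 5).
fixture_dataset <- function() {
  if (is.null(.fx$ds)) {
    .fx$ds <- make_dataset(10, simulation_config(duration_s = 20,
                                                 lateralization = 3, snr = 5),
                           decision_window_spec(2, 0.5), seed = 100)
  }
  .fx$ds
}

# Chance-level dataset: snr ~ 0; one 2 s window per simulated trial so all
# 500 maps are statistically independent (windows cut from a common trial
# share its noise and would inflate the variance of any chance estimate).
fixture_null_dataset <- function() {
  if (is.null(.fx$null_ds)) {
    .fx$null_ds <- make_dataset(250, simulation_config(duration_s = 2,
                                                       lateralization = 3,
                                                       snr = 1e-8),
                                decision_window_spec(2, 0), seed = 200)
  }
  .fx$null_ds
}

fixture_montage <- function() {
  if (is.null(.fx$mont)) .fx$mont <- project_montage(standard_montage(64))
  .fx$mont
}

# Trial-level 80/20 split of a make_dataset() result (19 windows/trial).
split_by_trial <- function(ds, train_fraction = 0.8, seed = 1) {
  trials <- vapply(ds$maps, function(m) m$trial_id, "")
  ids <- unique(trials)
  set.seed(seed)
  tr_ids <- sample(ids, round(train_fraction * length(ids)))
  list(train = ds$maps[trials %in% tr_ids],
       test = ds$maps[!trials %in% tr_ids])
}

# A tiny labeled recording for window/SSF tests.
toy_recording <- function(duration_s = 60, fs = 70, n_ch = 8, seed = 5,
                          label = "left") {
  set.seed(seed)
  mont <- montage_subset(standard_montage(64),
                         c("F3", "F4", "C3", "C4", "P3", "P4", "O1", "O2"))
  eeg_recording(matrix(rnorm(n_ch * duration_s * fs), n_ch), fs,
                mont$names, subject_id = "s1", trial_id = "t1",
                label = label)
}

toy_montage_8 <- function() {
  project_montage(montage_subset(standard_montage(64),
                                 c("F3", "F4", "C3", "C4",
                                   "P3", "P4", "O1", "O2")))
}

# Random maps with random labels (for leakage / plumbing tests).
noise_maps <- function(n, seed = 3, gn = 28) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    ssf_map(matrix(runif(gn * gn, -1, 1), gn, gn),
            label = sample(c("left", "right"), 1),
            subject_id = "noise", trial_id = sprintf("n%02d", i),
            window_index = i - 1L))
}

# Independent softmax used by loss-oracle tests.
softmax_cols_oracle <- function(m) apply(m, 2, function(col) exp(col) / sum(exp(col)))
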