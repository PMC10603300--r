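# Shared fixtures, built lazily and cached for the whole run.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

# small session: 8 trials, short durations -> fast generation and epoching
mini_cfg <- function(encoding = "none", seed = 42, ...) {
  session_config(n_trials = 8L, trials_per_condition = 2L,
                 trial_duration_mean = 4.5, trial_duration_sd = 0.5,
                 trial_duration_min = 3.5,
                 encoding_mode = encoding, seed = seed, ...)
}

mini_session <- function(encoding = "none", seed = 42) {
  cached(paste0("mini_", encoding, "_", seed),
         function() generate_session(mini_cfg(encoding, seed)))
}

# one bandpassed epoch set from the mini session
mini_epochs <- function() {
  cached("mini_epochs", function() {
    s <- mini_session()
    epoch_trials(bandpass_filter(s$eeg), pre_s = 2)
  })
}

# deterministic synthetic epoch carrying arbitrary signals, for unit tests
make_epoch <- function(data, sfreq = 256, t0 = -2) {
  list(trial_id = 1L, condition = "line-line", data = data,
       t_rel = t0 + (seq_len(nrow(data)) - 1L) / sfreq)
}

make_session <- function(signals, sfreq = 256, events = NULL) {
  if (is.null(events)) {
    events <- data.frame(trial_id = 1L, condition = "line-line",
                         onset_s = 3, offset_s = nrow(signals) / sfreq - 1)
  }
  structure(list(signals = signals, sfreq = sfreq,
                 channels = colnames(signals), events = events),
            class = "eeg_session")
}
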