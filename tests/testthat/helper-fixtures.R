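# Shared fixtures, built in code and memoized for the test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# Noiseless constant-saturation synthesis: the workhorse for inversion and
# morphology oracles.
constant_s_ppg <- function(spo2, seconds = 12, camera = camera_model(),
                           optical = optical_model(noise_sd = 0),
                           callus = 0, dc_offset = 0, phase = 0) {
  trace <- oximeter_trace(seq_len(seconds) - 1, rep(spo2, seconds))
  prof <- subject_profile("const", optical = optical, callus_factor = callus,
                          dc_offset_factor = dc_offset, phase = phase, seed = 1L)
  synthesize_ppg(trace, prof, camera)
}

# Tiny 3-subject cohort (2 min each) for fast pipeline and leakage tests.
tiny_samples <- function() {
  fixture("tiny_samples", function() {
    proto <- protocol_config(plateau_hold_s = 10, step_interval_s = 27,
                             total_duration_s = 120,
                             transition_time_constant_s = 5)
    coh <- generate_cohort(3, proto, camera_model(), seed = 404)
    cohort_samples(coh)
  })
}

# Very small but trainable network configuration for smoke tests.
tiny_spec <- function() model_spec(conv_channels = c(4, 6, 8), fc_width = 8)
tiny_train_config <- function(epochs = 3, seed = 9L) {
  train_config(learning_rate = 3e-3, batch_size = 64, max_epochs = epochs,
               seed = seed)
}
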