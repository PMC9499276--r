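# Shared simulation configurations.
# `clean_config()`: no sensor noise, no gyro bias -- used together with
# `sway_scale = 0` for exact-recovery contracts.
clean_config <- function(...) {
  sim_config(noise_sd_acc = 0, noise_sd_gyro = 0, noise_sd_mag = 0,
             noise_sd_grf = 0, gyro_bias = c(0, 0, 0), ...)
}

# event times (s) -> 1-based sample indices
truth_idx <- function(truth, fs) unlist(truth$event_times) * fs + 1
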