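# Small cohorts used across the unit tests. Frame sizes are reduced so a
# single session renders in milliseconds; geometry scales with the frame.

tiny_params <- function(...) {
  defaults <- list(n_per_group = 2, frame_shape = c(96, 96),
                   biopsy_n = c("0" = 2, "6" = 2),
                   stack_shape = c(32, 32, 16), seed = 42)
  do.call(cohort_params, utils::modifyList(defaults, list(...)))
}

quiet_params <- function(...) {
  # noise and drift off: frames hold exact mean intensities
  args <- utils::modifyList(list(noise = FALSE, lamp_drift_sigma = 0),
                            list(...))
  do.call(tiny_params, args)
}

# a calibrated frame wrapper for hand-built pixel matrices
cal_frame <- function(px, channel = "NADH") {
  channel_frame(px, channel, 40, calibrated = TRUE)
}
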