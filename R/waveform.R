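#' Default pulse waveform shape parameters
#'
#' The cardiac pulse is modeled as a sum of two wrapped Gaussians per beat:
#' a dominant systolic upstroke and a smaller dicrotic (reflected) wave.
#' Centers and widths are expressed as fractions of the beat period, so the
#' shape is heart-rate independent.
#'
#' @param systolic_center,systolic_width,systolic_amp position, width and
#'   amplitude of the systolic peak (phase units / unitless amplitude).
#' @param dicrotic_center,dicrotic_width,dicrotic_amp same for the dicrotic
#'   wave.
#' @return A list of class `waveform_params`.
#' @export
waveform_params <- function(systolic_center = 0.18, systolic_width = 0.07,
                            systolic_amp = 1.0,
                            dicrotic_center = 0.45, dicrotic_width = 0.10,
                            dicrotic_amp = 0.35) {
  stopifnot(systolic_width > 0, dicrotic_width > 0,
            systolic_amp > 0, dicrotic_amp >= 0)
  structure(list(systolic_center = systolic_center,
                 systolic_width = systolic_width,
                 systolic_amp = systolic_amp,
                 dicrotic_center = dicrotic_center,
                 dicrotic_width = dicrotic_width,
                 dicrotic_amp = dicrotic_amp),
            class = "waveform_params")
}

# Wrapped Gaussian: periodic extension over phase in [0, 1). Three shifted
# copies are enough because the widths used here are << 1.
wrapped_gaussian <- function(phase, center, width, amp) {
  out <- 0
  for (k in -1:1) {
    out <- out + amp * exp(-0.5 * ((phase - center + k) / width)^2)
  }
  out
}

#' Evaluate the pulse waveform at a cardiac phase
#'
#' Returns a nonnegative, periodic pulse value with a single dominant
#' systolic maximum per period. `zero_mean = TRUE` subtracts the analytic
#' period mean (each wrapped Gaussian integrates to `amp * width * sqrt(2*pi)`
#' over one period), which is the variant used by the optical forward model so
#' that the pulsatile term does not pollute the DC level.
#'
#' @param phase cardiac phase; any real number, used modulo 1.
#' @param params a [waveform_params()] list.
#' @param zero_mean subtract the analytic period mean?
#' @return Numeric vector of pulse values, same length as `phase`.
#' @export
ppg_waveform <- function(phase, params = waveform_params(), zero_mean = FALSE) {
  p <- phase %% 1
  w <- wrapped_gaussian(p, params$systolic_center, params$systolic_width,
                        params$systolic_amp) +
       wrapped_gaussian(p, params$dicrotic_center, params$dicrotic_width,
                        params$dicrotic_amp)
  if (zero_mean) {
    m <- sqrt(2 * pi) * (params$systolic_amp * params$systolic_width +
                         params$dicrotic_amp * params$dicrotic_width)
    w <- w - m
  }
  w
}
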