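#' Optical model of the finger-over-camera measurement
#'
#' A two-chromophore Beer-Lambert reflectance model at three effective
#' wavelengths (red ~660 nm, green ~530 nm, blue ~470 nm). Per channel `c`
#' the pulsatile fraction is
#' `AC_c / DC_c = pulsatility * mu_c(S) / mu_ref`, where
#' `mu_c(S) = eps_hbo2[c] * S + eps_hb[c] * (1 - S)` mixes the extinction
#' coefficients of oxy- and deoxyhemoglobin by the oxygen saturation fraction
#' `S`, and `mu_ref` is the largest coefficient in the model (a channel-common
#' normalizer). Because the normalizer is shared across channels, the
#' two-wavelength ratio-of-ratios inversion ([spo2_from_ratio()]) is the
#' exact inverse of this forward model in the noiseless limit.
#'
#' Default extinction coefficients are published whole-blood molar extinction
#' values (1/cm/M) at the effective wavelengths; oxygenated and deoxygenated
#' hemoglobin absorb roughly two orders of magnitude more strongly in green
#' and blue than in red, which is why camera oximetry needs heavy blue/green
#' gain. They are configuration, not constants: effective camera wavelengths
#' differ between sensors.
#'
#' @param eps_hbo2,eps_hb length-3 extinction coefficients (red, green, blue)
#'   for HbO2 and Hb; strictly positive.
#' @param dc_level baseline reflectance per channel, pre-gain, in (0, 1).
#' @param pulsatility fractional AC scale in (0, 0.5).
#' @param heart_rate_bpm cardiac frequency (default 70).
#' @param waveform_params beat morphology, see [waveform_params()].
#' @param noise_sd per-channel additive sensor noise, 8-bit units,
#'   pre-quantization.
#' @return List of class `optical_model`.
#' @export
optical_model <- function(eps_hbo2 = c(red = 319.6, green = 39956.8, blue = 33209.2),
                          eps_hb = c(red = 3226.6, green = 39036.4, blue = 16156.4),
                          dc_level = c(red = 0.55, green = 0.26, blue = 0.045),
                          pulsatility = 0.2,
                          heart_rate_bpm = 70,
                          waveform_params = oxicam::waveform_params(),
                          noise_sd = c(red = 0.5, green = 0.5, blue = 0.5)) {
  stopifnot(length(eps_hbo2) == 3, length(eps_hb) == 3,
            all(eps_hbo2 > 0), all(eps_hb > 0),
            length(dc_level) == 3, all(dc_level > 0), all(dc_level <= 1),
            pulsatility > 0, pulsatility < 0.5,
            heart_rate_bpm > 0)
  noise_sd <- rep_len(noise_sd, 3)
  stopifnot(all(noise_sd >= 0))
  structure(list(eps_hbo2 = unname(eps_hbo2), eps_hb = unname(eps_hb),
                 dc_level = unname(dc_level), pulsatility = pulsatility,
                 heart_rate_bpm = heart_rate_bpm,
                 waveform_params = waveform_params,
                 noise_sd = unname(noise_sd)),
            class = "optical_model")
}

#' Camera model
#'
#' Fixed-exposure smartphone camera: per-channel amplifier gains applied
#' before 8-bit storage, with clipping at the representable range. Defaults
#' mirror a locked-settings capture configuration: 30 fps, 176 x 144 frames,
#' gains (1, 3, 18) for (red, green, blue).
#'
#' @param fps frames per second.
#' @param resolution `c(width, height)` in pixels.
#' @param gains per-channel multipliers (red, green, blue).
#' @param bit_depth bits per pixel channel (default 8).
#' @param spatial_noise_sd per-pixel Gaussian noise, 8-bit units.
#' @return List of class `camera_model`.
#' @export
camera_model <- function(fps = 30, resolution = c(176, 144),
                         gains = c(red = 1, green = 3, blue = 18),
                         bit_depth = 8, spatial_noise_sd = 2) {
  stopifnot(fps > 0, length(resolution) == 2, all(resolution >= 1),
            length(gains) == 3, all(gains > 0), bit_depth >= 1,
            spatial_noise_sd >= 0)
  structure(list(fps = fps, resolution = as.integer(resolution),
                 gains = unname(gains), bit_depth = as.integer(bit_depth),
                 spatial_noise_sd = spatial_noise_sd,
                 max_value = 2^as.integer(bit_depth) - 1),
            class = "camera_model")
}

#' Subject profile
#'
#' Per-record identity and tissue properties. `callus_factor` dampens the
#' pulsatile (AC) component and `dc_offset_factor` raises the baseline (DC)
#' level, emulating thickened fingertip skin; the conventional callus preset
#' is (0.5, 0.5) - about half the oscillation amplitude at about 1.5x the
#' baseline.
#'
#' @param subject_id identifier (character).
#' @param hand `"left"` or `"right"`.
#' @param optical an [optical_model()].
#' @param callus_factor AC damping fraction in \[0, 1).
#' @param dc_offset_factor DC elevation fraction, >= 0.
#' @param phase initial cardiac phase in \[0, 1).
#' @param seed integer seed for this record's sensor noise.
#' @return List of class `subject_profile`.
#' @export
subject_profile <- function(subject_id, hand = c("left", "right"),
                            optical = optical_model(),
                            callus_factor = 0, dc_offset_factor = 0,
                            phase = 0, seed = 1L) {
  hand <- match.arg(hand)
  stopifnot(callus_factor >= 0, callus_factor < 1, dc_offset_factor >= 0)
  structure(list(subject_id = as.character(subject_id), hand = hand,
                 optical = optical, callus_factor = callus_factor,
                 dc_offset_factor = dc_offset_factor,
                 phase = phase %% 1, seed = as.integer(seed)),
            class = "subject_profile")
}

# mu_c(S): effective absorption of pulsatile blood per channel at saturation
# fraction S in [0, 1]. Vectorized over S; returns length(S) x 3.
effective_absorption <- function(S, optical) {
  outer(S, optical$eps_hbo2) + outer(1 - S, optical$eps_hb)
}

# Channel-common AC normalizer (largest coefficient in the model) so that
# AC/DC <= pulsatility for every channel and saturation.
absorption_normalizer <- function(optical) {
  max(optical$eps_hbo2, optical$eps_hb)
}
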