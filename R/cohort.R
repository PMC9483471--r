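#' Generate a synthetic varied-FiO2 cohort
#'
#' Simulates `n_subjects` study participants. Each subject receives one
#' stair-stepped SpO2 trajectory and two hand-records (left and right) that
#' share that trajectory but carry independent sensor noise and independent
#' cardiac phase, mirroring a protocol that instruments both index fingers.
#' Optional seeded between-subject amplitude variation (common-factor
#' brightness and pulsatility jitter, `subject_variation`) is available to
#' study cross-subject calibration confounds; it is off by default because a
#' subject-level amplitude factor is unidentifiable from small training
#' cohorts and deliberately limits cross-subject recovery (see the
#' vignette's limitations discussion). The explicitly modeled tissue
#' perturbation is the callus profile, injected via `profiles`.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param protocol a [protocol_config()]; its `seed` field is overridden per
#'   subject (derived from `seed`) so subjects get distinct trajectories.
#' @param camera a [camera_model()].
#' @param profiles optional list of lists of [subject_profile()] overrides;
#'   element `[[s]][[hand]]` replaces the auto-generated profile for subject
#'   `s`. Mostly used to inject callused-finger records.
#' @param seed master seed; every record is a pure function of it.
#' @param subject_variation `c(brightness, pulsatility)`: half-widths of the
#'   uniform per-subject jitter factors applied (as common factors across
#'   channels) to baseline reflectance and pulsatility. Default `c(0, 0)`.
#' @param output `"ppg"` (default) returns per-channel traces;
#'   `"frames"` additionally renders camera frames for each record.
#' @param reference_noise add noise to the reference readings? Off by
#'   default so inversion oracles are exact.
#' @param reference_arms accuracy (root-mean-square error, % SpO2) of the
#'   reference oximeter when `reference_noise = TRUE`; default 2, the rated
#'   accuracy of a tight-tolerance transfer-standard device over 70-100%.
#' @return List of class `cohort`: one element per hand-record, each with
#'   `ppg` ([ppg_record()]), `trace` ([oximeter_trace()]), `profile`, and
#'   (for `output = "frames"`) `frames`.
#' @export
generate_cohort <- function(n_subjects, protocol = protocol_config(),
                            camera = camera_model(), profiles = NULL,
                            seed = 1L, output = c("ppg", "frames"),
                            reference_noise = FALSE, reference_arms = 2,
                            subject_variation = c(0, 0)) {
  stopifnot(n_subjects >= 1, length(subject_variation) == 2,
            all(subject_variation >= 0), all(subject_variation < 1))
  output <- match.arg(output)
  records <- list()
  for (s in seq_len(n_subjects)) {
    sid <- sprintf("s%02d", s)
    subj_seed <- derive_seed(seed, paste0("trajectory/", sid))
    proto_s <- protocol
    proto_s$seed <- subj_seed
    trace <- simulate_spo2_trajectory(proto_s)
    ref_trace <- trace
    if (reference_noise) {
      ref_trace$spo2 <- with_seed(
        derive_seed(seed, paste0("reference/", sid)),
        clamp(trace$spo2 + stats::rnorm(nrow(trace), sd = reference_arms), 60, 100))
    }
    # optional between-subject variation: brightness and pulse strength as
    # common factors across channels - tissue does not reshape the relative
    # channel spectrum to first order
    jitter <- with_seed(derive_seed(seed, paste0("subject/", sid)),
                        list(dc = stats::runif(1, 1 - subject_variation[1],
                                               1 + subject_variation[1]),
                             pulse = stats::runif(1, 1 - subject_variation[2],
                                                  1 + subject_variation[2]),
                             phase = stats::runif(2)))
    for (hand in c("left", "right")) {
      prof <- profiles[[s]][[hand]] %||% {
        opt <- optical_model()
        opt$dc_level <- clamp(opt$dc_level * jitter$dc, 0.01, 1)
        opt$pulsatility <- min(opt$pulsatility * jitter$pulse, 0.49)
        subject_profile(
          subject_id = sid, hand = hand, optical = opt,
          phase = jitter$phase[[match(hand, c("left", "right"))]],
          seed = derive_seed(seed, paste0("noise/", sid, "/", hand)))
      }
      # the optics respond to the true physiology; the labels come from the
      # (possibly noisy) reference oximeter
      rec <- list(ppg = synthesize_ppg(trace, prof, camera),
                  trace = ref_trace, profile = prof)
      if (output == "frames") {
        rec$frames <- synthesize_frames(
          rec$ppg, camera,
          seed = derive_seed(seed, paste0("frames/", sid, "/", hand)))
      }
      records[[paste(sid, hand, sep = "_")]] <- rec
    }
  }
  structure(records, class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  subs <- unique(vapply(x, function(r) r$profile$subject_id, character(1)))
  cat(sprintf("<cohort> %d subjects, %d hand-records\n", length(subs), length(x)))
  invisible(x)
}
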