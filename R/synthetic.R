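#' Synthetic sEMG generator configuration
#'
#' Defines the study conditions the generator emulates: four lower-limb
#' muscle channels sampled at 1000 Hz, band-limited (20-460 Hz) stochastic
#' activity amplitude-modulated by a periodic gait-burst envelope, with
#' additive white Gaussian sensor noise, 50 Hz power-line interference and
#' sub-5 Hz baseline wander, and a class imbalance driven by recording
#' duration (abnormal subjects walk slower, so their recordings are longer).
#'
#' Defaults: 11 subjects per class; healthy recordings of 6.016 s with the
#' abnormal class 4.48 times longer, so that 256 ms windows with 25%
#' overlap yield per-class window totals of 341 and 1540 (a ~4.5:1 window
#' imbalance); burst rate 1 gait cycle/s with 35% duty; abnormal class
#' effect of a 1.3x amplitude scale plus a 0.1-cycle burst-phase shift;
#' 15 dB white-noise SNR, power-line amplitude 0.1 and baseline-wander RMS
#' 0.2 relative to unit-RMS burst activity.
#'
#' @param sampling_rate Hz (default 1000).
#' @param duration_s healthy-class recording duration in seconds.
#' @param duration_ratio abnormal:healthy duration ratio (default 4.48).
#' @param n_subjects subjects per class (default 11).
#' @param burst_rate gait cycles per second (default 1).
#' @param burst_duty active fraction of each cycle, in (0, 1) (default 0.35).
#' @param band two-element numeric, low/high edge (Hz) of the activity
#'   process (default `c(20, 460)`, the acquisition hardware band).
#' @param class_effect list with `amplitude` (multiplicative scale applied
#'   to abnormal-class activity) and `phase` (burst-phase shift in cycle
#'   fractions). `list(amplitude = 1, phase = 0)` makes the classes
#'   distributionally identical.
#' @param noise list with `wgn_snr_db` (white-noise SNR in dB relative to
#'   the clean activity; `Inf` disables), `pli_amplitude` (50 Hz sinusoid
#'   amplitude; 0 disables) and `baseline_amplitude` (RMS of the <5 Hz
#'   wander; 0 disables).
#' @param seed integer master seed.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(sampling_rate = 1000, duration_s = 6.016,
                         duration_ratio = 4.48, n_subjects = 11,
                         burst_rate = 1, burst_duty = 0.35,
                         band = c(20, 460),
                         class_effect = list(amplitude = 1.3, phase = 0.1),
                         noise = list(wgn_snr_db = 15, pli_amplitude = 0.1,
                                      baseline_amplitude = 0.2),
                         seed = 1) {
  assert_scalar_num(sampling_rate, "sampling_rate", lower = 1e-9)
  assert_scalar_num(duration_s, "duration_s", lower = 0.5)
  assert_scalar_num(duration_ratio, "duration_ratio", lower = 1e-9)
  assert_scalar_num(n_subjects, "n_subjects", lower = 1)
  assert_scalar_num(burst_duty, "burst_duty", lower = 1e-9, upper = 1 - 1e-9)
  if (length(band) != 2L || band[1] <= 0 || band[2] <= band[1] ||
      band[2] >= sampling_rate / 2) {
    stop("band must satisfy 0 < low < high < sampling_rate / 2", call. = FALSE)
  }
  noise <- utils::modifyList(
    list(wgn_snr_db = 15, pli_amplitude = 0.1, baseline_amplitude = 0.2), noise)
  class_effect <- utils::modifyList(list(amplitude = 1.3, phase = 0.1),
                                    class_effect)
  structure(
    list(sampling_rate = sampling_rate, duration_s = duration_s,
         duration_ratio = duration_ratio, n_subjects = as.integer(n_subjects),
         burst_rate = burst_rate, burst_duty = burst_duty, band = band,
         class_effect = class_effect, noise = noise, seed = as.integer(seed)),
    class = "synth_config"
  )
}

# brickwall zero-phase band-pass via the DFT: exactly zero outside the band
fft_bandpass <- function(x, fs, low, high) {
  n <- length(x)
  freqs <- (seq_len(n) - 1) * fs / n
  freqs <- pmin(freqs, fs - freqs)  # two-sided spectrum folded to [0, fs/2]
  spec <- stats::fft(x)
  spec[freqs < low | freqs > high] <- 0
  Re(stats::fft(spec, inverse = TRUE)) / n
}

# raised-cosine burst envelope: one bump per gait cycle over the duty
# fraction, on a small tonic floor so no window is exactly silent
burst_envelope <- function(n, fs, rate, duty, phase = 0, floor_level = 0.1) {
  t <- (seq_len(n) - 1) / fs
  p <- (t * rate + phase) %% 1
  env <- rep(floor_level, n)
  active <- p < duty
  env[active] <- floor_level + (1 - floor_level) *
    0.5 * (1 - cos(2 * pi * p[active] / duty))
  env
}

#' Generate one synthetic multi-channel sEMG recording
#'
#' The clean component of each channel is zero-mean Gaussian noise
#' band-limited to `cfg$band` by a zero-phase (DFT brickwall) band-pass,
#' normalised to unit RMS, then amplitude-modulated by a raised-cosine
#' gait-burst envelope. Abnormal-class recordings are longer
#' (`duration_ratio`), amplitude-scaled and burst-phase-shifted per
#' `cfg$class_effect`. Contaminants per `cfg$noise` are then added: white
#' Gaussian noise at the configured SNR, a 50 Hz power-line sinusoid with
#' a random (seeded) phase, and low-pass (<5 Hz) filtered noise as
#' baseline wander. Fully reproducible from `seed`.
#'
#' @param cfg a [synth_config()].
#' @param label class of the recording, `"healthy"` or `"abnormal"`.
#' @param seed integer seed for this recording.
#' @param subject_id identifier stored on the recording.
#' @param clean_only logical; if `TRUE` return only the clean burst
#'   process, ignoring `cfg$noise` (used by contaminant-free checks).
#' @return an [recording()] object.
#' @export
#' @examples
#' rec <- gen_recording(synth_config(duration_s = 2), "healthy", seed = 7)
#' rec
gen_recording <- function(cfg, label = c("healthy", "abnormal"), seed,
                          subject_id = "synthetic", clean_only = FALSE) {
  stopifnot(inherits(cfg, "synth_config"))
  label <- match.arg(label)
  fs <- cfg$sampling_rate
  dur <- if (label == "abnormal") cfg$duration_s * cfg$duration_ratio else cfg$duration_s
  n <- round(dur * fs)
  n_ch <- 4L
  amp <- if (label == "abnormal") cfg$class_effect$amplitude else 1
  phase <- if (label == "abnormal") cfg$class_effect$phase else 0
  samples <- with_seed(seed, {
    out <- matrix(0, nrow = n, ncol = n_ch)
    for (ch in seq_len(n_ch)) {
      act <- fft_bandpass(stats::rnorm(n), fs, cfg$band[1], cfg$band[2])
      act <- act / stats::sd(act)
      env <- burst_envelope(n, fs, cfg$burst_rate, cfg$burst_duty,
                            phase = phase + (ch - 1) * 0.05)
      clean <- amp * env * act
      x <- clean
      if (!clean_only) {
        if (is.finite(cfg$noise$wgn_snr_db)) {
          noise_sd <- sqrt(mean(clean^2)) * 10^(-cfg$noise$wgn_snr_db / 20)
          x <- x + stats::rnorm(n, sd = noise_sd)
        }
        if (cfg$noise$pli_amplitude > 0) {
          pli_phase <- stats::runif(1, 0, 2 * pi)
          x <- x + cfg$noise$pli_amplitude *
            sin(2 * pi * 50 * (seq_len(n) - 1) / fs + pli_phase)
        }
        if (cfg$noise$baseline_amplitude > 0) {
          bw <- fft_bandpass(stats::rnorm(n), fs, 1e-9, 5)
          x <- x + cfg$noise$baseline_amplitude * bw / stats::sd(bw)
        }
      }
      out[, ch] <- x
    }
    out
  })
  recording(samples, sampling_rate = fs, label = label, subject_id = subject_id)
}

#' Generate a labelled synthetic dataset
#'
#' `cfg$n_subjects` recordings per class, abnormal recordings longer by
#' `cfg$duration_ratio` so that downstream windowing yields a
#' duration-driven class imbalance. Subject ids are unique (`H01..`,
#' `A01..`); per-recording seeds are derived deterministically from
#' `cfg$seed`.
#'
#' @param cfg a [synth_config()].
#' @return list of [recording()] objects, healthy first.
#' @export
gen_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  n_per <- cfg$n_subjects
  seeds <- derive_seeds(cfg$seed, 2L * n_per)
  recs <- vector("list", 2L * n_per)
  for (i in seq_len(n_per)) {
    recs[[i]] <- gen_recording(cfg, "healthy", seed = seeds[i],
                               subject_id = sprintf("H%02d", i))
    recs[[n_per + i]] <- gen_recording(cfg, "abnormal", seed = seeds[n_per + i],
                                       subject_id = sprintf("A%02d", i))
  }
  recs
}
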