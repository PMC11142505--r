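#' Sliding-window configuration
#'
#' @param window_ms window length in milliseconds (default 256).
#' @param overlap_fraction fraction of a window overlapped by the next
#'   (default 0.25, i.e. a 192-sample step at 1000 Hz).
#' @param sampling_rate Hz (default 1000).
#' @return list of class `window_config` with derived `window_samples` and
#'   `step_samples`.
#' @export
window_config <- function(window_ms = 256, overlap_fraction = 0.25,
                          sampling_rate = 1000) {
  assert_scalar_num(window_ms, "window_ms", lower = 1e-9)
  assert_scalar_num(overlap_fraction, "overlap_fraction", lower = 0,
                    upper = 1 - 1e-12)
  assert_scalar_num(sampling_rate, "sampling_rate", lower = 1e-9)
  w <- round(window_ms * sampling_rate / 1000)
  if (w < 2) stop("window shorter than 2 samples", call. = FALSE)
  s <- max(1, round(w * (1 - overlap_fraction)))
  structure(
    list(window_ms = window_ms, overlap_fraction = overlap_fraction,
         sampling_rate = sampling_rate, window_samples = as.integer(w),
         step_samples = as.integer(s)),
    class = "window_config"
  )
}

#' Segment a signal into sliding windows
#'
#' Windows of `cfg$window_samples` samples starting at 1, 1 + step,
#' 1 + 2*step, ... while the window still fits; a trailing partial window
#' is dropped. Signals shorter than one window give zero windows.
#'
#' @param signal numeric vector.
#' @param cfg a [window_config()].
#' @return numeric matrix with one column per window (zero columns for
#'   short signals); attribute `"starts"` holds the 1-based start indices.
#' @export
#' @examples
#' ncol(window_signal(numeric(1000), window_config()))  # 4
window_signal <- function(signal, cfg = window_config()) {
  n <- length(signal)
  w <- cfg$window_samples
  s <- cfg$step_samples
  if (n < w) {
    out <- matrix(numeric(0), nrow = w, ncol = 0)
    attr(out, "starts") <- integer(0)
    return(out)
  }
  starts <- seq.int(1L, n - w + 1L, by = s)
  out <- vapply(starts, function(st) signal[st:(st + w - 1L)], numeric(w))
  out <- matrix(out, nrow = w)
  attr(out, "starts") <- starts
  out
}

# ---- time-domain feature bank ----------------------------------------------
# Each feature is the literal windowed statistic used in the sEMG
# literature; y is the window, M its length.

feat_MAV <- function(y) mean(abs(y))
feat_RMS <- function(y) sqrt(mean(y^2))
feat_ZC <- function(y) {
  a <- y[-length(y)]; b <- y[-1]
  sum((a > 0 & b < 0) | (a < 0 & b > 0))
}
feat_SSC <- function(y) {
  m <- length(y)
  mid <- y[2:(m - 1)]; lo <- y[1:(m - 2)]; hi <- y[3:m]
  sum((mid > lo & mid > hi) | (mid < lo & mid < hi))
}
# literal mean-power form with an M-1 divisor (no mean subtraction)
feat_VAR <- function(y) sum(y^2) / (length(y) - 1)
feat_DASDV <- function(y) sqrt(sum(diff(y)^2) / (length(y) - 1))
feat_AAC <- function(y) sum(abs(diff(y))) / length(y)
feat_Skew <- function(y) {
  mu <- mean(y); s <- sqrt(mean((y - mu)^2))
  if (s == 0) return(NA_real_)  # flagged upstream
  mean((y - mu)^3) / s^3
}
feat_Kurt <- function(y) {
  mu <- mean(y); s <- sqrt(mean((y - mu)^2))
  if (s == 0) return(NA_real_)
  mean((y - mu)^4) / s^4
}
# optional extensions for an 11-feature bank
feat_WL <- function(y) sum(abs(diff(y)))
feat_IEMG <- function(y) sum(abs(y))

.feature_registry <- list(
  MAV = feat_MAV, RMS = feat_RMS, ZC = feat_ZC, SSC = feat_SSC,
  VAR = feat_VAR, DASDV = feat_DASDV, AAC = feat_AAC,
  Skew = feat_Skew, Kurt = feat_Kurt, WL = feat_WL, IEMG = feat_IEMG
)

#' Names of the default time-domain feature bank
#'
#' The nine formula-defined window statistics: mean absolute value, root
#' mean square, zero crossings, slope sign changes, (uncentred) variance,
#' difference absolute standard deviation value, average amplitude change,
#' skewness and kurtosis. `"WL"` (waveform length) and `"IEMG"`
#' (integrated EMG) are also registered so an eleven-feature bank
#' (4 channels x 11 = 44 columns) can be configured.
#'
#' @return character vector of feature names.
#' @export
default_feature_bank <- function() {
  c("MAV", "RMS", "ZC", "SSC", "VAR", "DASDV", "AAC", "Skew", "Kurt")
}

#' Time-domain features of one window
#'
#' @param window finite numeric vector, length >= 3.
#' @param features ordered feature names from the registry (default the
#'   nine-feature bank of [default_feature_bank()]).
#' @return named numeric vector. Zero-variance windows make skewness and
#'   kurtosis undefined; both are reported as 0 and the attribute
#'   `"degenerate"` is set to `TRUE`.
#' @export
#' @examples
#' extract_features(c(1, -1, 2, -2))[c("MAV", "ZC", "AAC")]
extract_features <- function(window, features = default_feature_bank()) {
  window <- as.numeric(window)
  if (length(window) < 3L) stop("window must hold at least 3 samples", call. = FALSE)
  if (!all(is.finite(window))) stop("window must be finite", call. = FALSE)
  unknown <- setdiff(features, names(.feature_registry))
  if (length(unknown)) {
    stop(sprintf("unknown features: %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  vals <- vapply(features, function(f) .feature_registry[[f]](window), numeric(1))
  degenerate <- anyNA(vals)
  vals[is.na(vals)] <- 0
  names(vals) <- features
  attr(vals, "degenerate") <- degenerate
  vals
}

#' WD-EEMD preprocessing of one channel
#'
#' The hybrid denoising chain: wavelet denoising ([wd_denoise()]) removes
#' high-frequency noise, then EEMD decomposes the reconstructed signal and
#' the three highest-frequency intrinsic mode functions are summed as the
#' denoised signal - low-frequency contaminants (power-line residue,
#' baseline wander) land in the discarded low-order IMFs and residual.
#' When fewer than `n_imfs` IMFs are produced, all available IMFs are
#' summed and a warning is emitted.
#'
#' @param signal numeric vector.
#' @param wd_cfg a [wd_config()].
#' @param eemd_cfg an [eemd_config()].
#' @param n_imfs number of leading IMFs to keep (default 3).
#' @return denoised numeric vector, same length as `signal`.
#' @export
preprocess_wd_eemd <- function(signal, wd_cfg = wd_config(),
                               eemd_cfg = eemd_config(), n_imfs = 3) {
  den <- wd_denoise(signal, wd_cfg)
  dec <- eemd(den, eemd_cfg)
  sum_leading_imfs(dec, n_imfs)
}

sum_leading_imfs <- function(dec, n_imfs) {
  k <- length(dec$imfs)
  if (k == 0L) {
    warning("EEMD produced no IMFs; returning the residual trend")
    return(dec$residual * 0)
  }
  if (k < n_imfs) {
    warning(sprintf("only %d IMFs produced (%d requested); summing all", k, n_imfs))
  }
  Reduce(`+`, dec$imfs[seq_len(min(k, n_imfs))])
}

#' Preprocess a channel under a named arm
#'
#' The pre-processing arms of the study grid: `"raw"` (identity), `"wd"`
#' (wavelet denoising only), `"emd"` (EEMD of the raw signal, leading-IMF
#' sum) and `"wd-eemd"` (the hybrid chain).
#'
#' @param signal numeric vector.
#' @param arm one of `"raw"`, `"wd"`, `"emd"`, `"wd-eemd"`.
#' @param wd_cfg,eemd_cfg,n_imfs stage configurations, as in
#'   [preprocess_wd_eemd()].
#' @return numeric vector, same length as `signal`.
#' @export
preprocess_signal <- function(signal, arm = c("wd-eemd", "raw", "wd", "emd"),
                              wd_cfg = wd_config(), eemd_cfg = eemd_config(),
                              n_imfs = 3) {
  arm <- match.arg(arm)
  switch(arm,
         raw = as.numeric(signal),
         wd = wd_denoise(signal, wd_cfg),
         emd = sum_leading_imfs(eemd(signal, eemd_cfg), n_imfs),
         `wd-eemd` = preprocess_wd_eemd(signal, wd_cfg, eemd_cfg, n_imfs))
}

#' Build the windows-by-features matrix from a set of recordings
#'
#' For every recording and channel: preprocess under `arm`, segment with
#' the shared window grid (identical window boundaries across channels of
#' a recording), and extract the feature bank per window. Feature vectors
#' are concatenated channel-major (`RF_MAV .. RF_Kurt, BF_MAV, ...`), so
#' the default 4 channels x 9 features give 36 columns (44 with an
#' 11-feature bank). Rows carry the recording's label and subject id; the
#' classes differ only in row counts, never in columns.
#'
#' @param recordings list of [recording()] objects with a consistent
#'   channel count.
#' @param arm pre-processing arm, see [preprocess_signal()].
#' @param wd_cfg,eemd_cfg stage configurations.
#' @param win_cfg a [window_config()].
#' @param features ordered feature bank names.
#' @param n_imfs leading IMFs kept by the EMD-based arms.
#' @return an [feature_matrix()] object.
#' @export
build_feature_matrix <- function(recordings, arm = "wd-eemd",
                                 wd_cfg = wd_config(),
                                 eemd_cfg = eemd_config(),
                                 win_cfg = window_config(),
                                 features = default_feature_bank(),
                                 n_imfs = 3) {
  if (length(recordings) == 0L) {
    cols <- as.vector(t(outer(c("RF", "BF", "VM", "ST"), features, paste, sep = "_")))
    return(feature_matrix(matrix(numeric(0), ncol = length(cols),
                                 dimnames = list(NULL, cols)),
                          label = character(0), subject_id = character(0)))
  }
  n_ch <- vapply(recordings, function(r) ncol(r$samples), integer(1))
  if (length(unique(n_ch)) != 1L) {
    stop("recordings have inconsistent channel counts", call. = FALSE)
  }
  ch_names <- recordings[[1]]$channel_names
  col_names <- as.vector(t(outer(ch_names, features, paste, sep = "_")))
  # one deterministic EEMD seed per recording x channel
  sub_seeds <- derive_seeds(eemd_cfg$seed, length(recordings) * n_ch[1])
  blocks <- vector("list", length(recordings))
  labels <- character(0)
  subjects <- character(0)
  flags <- character(0)
  for (ri in seq_along(recordings)) {
    rec <- recordings[[ri]]
    win_count <- ncol(window_signal(rec$samples[, 1], win_cfg))
    if (win_count == 0L) {
      blocks[[ri]] <- matrix(numeric(0), ncol = length(col_names))
      next
    }
    chan_feats <- vector("list", ncol(rec$samples))
    degen <- matrix(FALSE, nrow = win_count, ncol = ncol(rec$samples))
    for (ch in seq_len(ncol(rec$samples))) {
      cfg_ch <- eemd_cfg
      cfg_ch$seed <- sub_seeds[(ri - 1L) * n_ch[1] + ch]
      pre <- preprocess_signal(rec$samples[, ch], arm = arm, wd_cfg = wd_cfg,
                               eemd_cfg = cfg_ch, n_imfs = n_imfs)
      wins <- window_signal(pre, win_cfg)
      fv <- t(apply(wins, 2, function(w) {
        v <- extract_features(w, features)
        c(v, degenerate = as.numeric(attr(v, "degenerate")))
      }))
      degen[, ch] <- fv[, ncol(fv)] > 0
      chan_feats[[ch]] <- fv[, -ncol(fv), drop = FALSE]
    }
    blocks[[ri]] <- do.call(cbind, chan_feats)
    labels <- c(labels, rep(rec$label, win_count))
    subjects <- c(subjects, rep(rec$subject_id, win_count))
    flags <- c(flags, ifelse(rowSums(degen) > 0, "zero_variance_window", ""))
  }
  x <- do.call(rbind, blocks)
  colnames(x) <- col_names
  feature_matrix(x, label = labels, subject_id = subjects,
                 quality_flags = flags)
}
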