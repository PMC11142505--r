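# Independent brute-force evaluation of the nine window statistics,
# written as literal loops over the defining sums so it shares no code
# path with the package implementation.
brute_features <- function(y) {
  M <- length(y)
  mav <- 0
  for (v in y) mav <- mav + abs(v)
  mav <- mav / M
  rms <- 0
  for (v in y) rms <- rms + v^2
  rms <- sqrt(rms / M)
  zc <- 0
  for (j in 1:(M - 1)) {
    if ((y[j] > 0 && y[j + 1] < 0) || (y[j] < 0 && y[j + 1] > 0)) zc <- zc + 1
  }
  ssc <- 0
  for (j in 2:(M - 1)) {
    if ((y[j] > y[j - 1] && y[j] > y[j + 1]) ||
        (y[j] < y[j - 1] && y[j] < y[j + 1])) ssc <- ssc + 1
  }
  va <- 0
  for (v in y) va <- va + v^2
  va <- va / (M - 1)
  dasdv <- 0
  for (j in 1:(M - 1)) dasdv <- dasdv + (y[j + 1] - y[j])^2
  dasdv <- sqrt(dasdv / (M - 1))
  aac <- 0
  for (j in 1:(M - 1)) aac <- aac + abs(y[j + 1] - y[j])
  aac <- aac / M
  mu <- sum(y) / M
  sig <- sqrt(sum((y - mu)^2) / M)
  if (sig > 0) {
    skew <- sum((y - mu)^3) / M / sig^3
    kurt <- sum((y - mu)^4) / M / sig^4
  } else {
    skew <- 0
    kurt <- 0
  }
  c(MAV = mav, RMS = rms, ZC = zc, SSC = ssc, VAR = va, DASDV = dasdv,
    AAC = aac, Skew = skew, Kurt = kurt)
}

# periodogram band power via the DFT (Parseval), on [lo, hi] Hz
band_power <- function(x, fs, lo, hi) {
  n <- length(x)
  spec <- abs(stats::fft(x))^2 / n
  freqs <- (seq_len(n) - 1) * fs / n
  freqs <- pmin(freqs, fs - freqs)
  sum(spec[freqs >= lo & freqs <= hi])
}

# a tiny labelled feature matrix for resampling/evaluation tests
toy_feature_matrix <- function(n_min = 20, n_maj = 90, p = 6, seed = 1,
                               shift = 2) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_maj * p), ncol = p),
             matrix(rnorm(n_min * p, mean = shift), ncol = p))
  colnames(x) <- paste0("f", seq_len(p))
  feature_matrix(x,
                 label = rep(c("abnormal", "healthy"), c(n_maj, n_min)),
                 subject_id = rep(c("A", "H"), c(n_maj, n_min)))
}
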