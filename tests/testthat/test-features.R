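test_that("windowing follows the start/step arithmetic exactly", {
  cfg <- window_config()  # 256 ms, 25% overlap, 1000 Hz
  expect_identical(cfg$window_samples, 256L)
  expect_identical(cfg$step_samples, 192L)
  w <- window_signal(seq_len(1000), cfg)
  expect_identical(ncol(w), 4L)
  expect_identical(attr(w, "starts"), c(1L, 193L, 385L, 577L))
  expect_identical(ncol(window_signal(seq_len(256), cfg)), 1L)
  expect_identical(ncol(window_signal(seq_len(255), cfg)), 0L)
  # windows are faithful slices
  x <- rnorm(1000)
  w2 <- window_signal(x, cfg)
  expect_identical(w2[, 3], x[385:640])
  # non-overlapping configuration tiles the signal
  cfg0 <- window_config(overlap_fraction = 0)
  expect_identical(attr(window_signal(seq_len(1024), cfg0), "starts"),
                   c(1L, 257L, 513L, 769L))
})

test_that("features match hand-evaluated examples", {
  v <- extract_features(c(1, -1, 2, -2))
  expect_equal(v[["MAV"]], 1.5)
  expect_equal(v[["ZC"]], 3)
  expect_equal(v[["AAC"]], 2.25)
  # constant window: degenerate moments flagged as zero
  vc <- extract_features(rep(2, 8))
  expect_equal(vc[["MAV"]], 2)
  expect_equal(vc[["RMS"]], 2)
  expect_identical(vc[["ZC"]], 0)
  expect_identical(vc[["SSC"]], 0)
  expect_identical(vc[["DASDV"]], 0)
  expect_identical(vc[["AAC"]], 0)
  expect_equal(vc[["VAR"]], 8 * 4 / 7)
  expect_identical(vc[["Skew"]], 0)
  expect_true(attr(vc, "degenerate"))
  # the uncentred variance form: ones give M/(M-1), not 0
  expect_equal(extract_features(rep(1, 4))[["VAR"]], 4 / 3)
  expect_error(extract_features(c(1, 2)), "3 samples")
  expect_error(extract_features(c(1, 2, Inf)), "finite")
})

test_that("all nine features agree with the brute-force oracle", {
  set.seed(314)
  for (i in 1:300) {
    m <- sample(3:64, 1)
    y <- switch(sample(3, 1),
                rnorm(m),
                round(rnorm(m), 1),          # exercises ties and zeros
                rnorm(m, sd = 10^sample(-3:3, 1)))
    expect_equal(as.numeric(extract_features(y)), as.numeric(brute_features(y)),
                 tolerance = 1e-10)
  }
})

test_that("moment features converge to their Gaussian values", {
  set.seed(99)
  v <- extract_features(rnorm(1e5))
  expect_lt(abs(v[["Skew"]]), 0.03)
  expect_lt(abs(v[["Kurt"]] - 3), 0.1)
})

test_that("features scale as expected with amplitude", {
  set.seed(5)
  y <- rnorm(128)
  a <- 3.7
  v1 <- extract_features(y)
  v2 <- extract_features(a * y)
  for (f in c("MAV", "RMS", "DASDV", "AAC")) {
    expect_equal(v2[[f]], a * v1[[f]], tolerance = 1e-10)
  }
  expect_equal(v2[["VAR"]], a^2 * v1[["VAR"]], tolerance = 1e-10)
  for (f in c("ZC", "SSC", "Skew", "Kurt")) {
    expect_equal(v2[[f]], v1[[f]], tolerance = 1e-10)
  }
  # counting identities
  alt <- rep(c(1, -1), 10)
  expect_identical(extract_features(alt)[["ZC"]], 19)
  expect_identical(extract_features(cumsum(abs(rnorm(50))))[["SSC"]], 0)
})

test_that("wd-eemd preprocessing is the leading-IMF sum of its own EEMD", {
  set.seed(8)
  x <- rnorm(1200)
  wd_cfg <- wd_config()
  ec <- eemd_config(ensemble_size = 3, seed = 42)
  out <- preprocess_wd_eemd(x, wd_cfg, ec)
  dec <- eemd(wd_denoise(x, wd_cfg), ec)
  expect_equal(out, dec$imfs[[1]] + dec$imfs[[2]] + dec$imfs[[3]],
               tolerance = 1e-12)
  # equivalently: everything minus the discarded tail, via the identity
  total <- Reduce(`+`, dec$imfs) + dec$residual
  tail_part <- if (length(dec$imfs) > 3) {
    Reduce(`+`, dec$imfs[-(1:3)]) + dec$residual
  } else dec$residual
  expect_lt(max(abs(out - (total - tail_part))), 1e-10)
  expect_identical(length(out), length(x))
  # zero signal passes through as zero (no IMFs to keep)
  expect_equal(suppressWarnings(preprocess_wd_eemd(numeric(600), wd_cfg, ec)),
               numeric(600))
})

test_that("wd-eemd preprocessing strips sub-5 Hz contamination", {
  cfg <- synth_config(duration_s = 3,
                      noise = list(wgn_snr_db = 10, pli_amplitude = 0.3,
                                   baseline_amplitude = 0.8),
                      seed = 3)
  x <- gen_recording(cfg, "healthy", seed = 44)$samples[, 1]
  out <- preprocess_wd_eemd(x, eemd_cfg = eemd_config(ensemble_size = 5,
                                                      max_imfs = 6, seed = 9))
  expect_lt(band_power(out, 1000, 0, 5), 0.2 * band_power(x, 1000, 0, 5))
})

test_that("feature matrices assemble channel-major with aligned windows", {
  cfg <- synth_config(duration_s = 1)
  rec <- gen_recording(cfg, "healthy", seed = 3, subject_id = "H1")
  fm <- build_feature_matrix(list(rec), arm = "raw")
  expect_identical(dim(fm$x), c(4L, 36L))
  expect_identical(colnames(fm$x)[1:2], c("RF_MAV", "RF_RMS"))
  expect_identical(colnames(fm$x)[10], "BF_MAV")
  expect_identical(unique(fm$label), "healthy")
  # rows reproduce a direct windowed extraction of each channel
  wins <- window_signal(rec$samples[, 2])
  direct <- t(apply(wins, 2, function(w) extract_features(w)))
  expect_equal(unname(fm$x[, 10:18]), unname(direct), tolerance = 1e-12)
  # row count composes over recordings
  rec2 <- gen_recording(cfg, "abnormal", seed = 4, subject_id = "A1")
  fm2 <- build_feature_matrix(list(rec, rec2), arm = "raw")
  n2 <- ncol(window_signal(rec2$samples[, 1]))
  expect_identical(nrow(fm2$x), 4L + n2)
  expect_identical(sum(fm2$label == "abnormal"), n2)
  # mismatched channel counts are rejected
  bad <- recording(matrix(rnorm(600), ncol = 2), channel_names = c("a", "b"))
  expect_error(build_feature_matrix(list(rec, bad), arm = "raw"),
               "channel counts")
})
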