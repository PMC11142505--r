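# Reference values below are frozen outputs of an independent wavelet
# implementation (db7, symmetric padding), used to anchor both the band
# lengths and the coefficient values of the transform.
pywt_band_lengths <- list(
  # signal length -> c(A4, D4, D3, D2, D1)
  `300` = c(30, 30, 48, 84, 156),
  `512` = c(44, 44, 75, 137, 262),
  `731` = c(57, 57, 102, 192, 372),
  `1000` = c(74, 74, 136, 259, 506),
  `2048` = c(140, 140, 267, 521, 1030),
  `3571` = c(235, 235, 457, 902, 1792),
  `5000` = c(324, 324, 636, 1259, 2506)
)

test_that("db7 coefficients match the independent reference transform", {
  t <- 0:63
  x <- sin(2 * pi * t / 16) + 0.05 * t
  dec <- wd_decompose(x, level = 2)
  expect_equal(dec$approx[1:4],
               c(0.701472504475, 2.363203922828, 0.318527259384, 2.116352448437),
               tolerance = 1e-10)
  expect_equal(dec$details$D2[1:4],
               c(0.152769510551, -0.327582275072, 0.044760251340, 0.354603451161),
               tolerance = 1e-10)
  expect_equal(dec$details$D1[1:4],
               c(0.074859240701, -0.132361773170, 0.078180013955, -0.021258719649),
               tolerance = 1e-10)
})

test_that("level-4 band lengths match the reference for a grid of lengths", {
  for (n in names(pywt_band_lengths)) {
    dec <- wd_decompose(numeric(as.integer(n)), level = 4)
    got <- unname(c(length(dec$approx), rev(lengths(dec$details))))
    expect_identical(got, as.integer(pywt_band_lengths[[n]]),
                     label = sprintf("lengths for n = %s", n))
  }
})

test_that("decompose/reconstruct is an identity and inputs are validated", {
  set.seed(42)
  for (n in c(300, 1024, 2500)) {
    x <- rnorm(n)
    dec <- wd_decompose(x)
    expect_lt(max(abs(wd_reconstruct(dec) - x)), 1e-8)
    expect_identical(length(dec$details), 4L)
  }
  expect_error(wd_decompose(rnorm(8)), "shorter")
  expect_error(wd_decompose(c(1, NA, rep(1, 50))), "finite")
  expect_error(wd_decompose(rnorm(100), wavelet_name = "sym4"), "unknown wavelet")
})

test_that("details of a constant signal vanish (vanishing moments)", {
  dec <- wd_decompose(rep(3.5, 1000))
  for (band in dec$details) expect_lt(max(abs(band)), 1e-8 * 3.5)
})

test_that("universal threshold reproduces the closed-form rule", {
  # all-zero band: sigma = 0, lambda = 0
  spec0 <- universal_threshold(numeric(10), n = 1000)
  expect_identical(spec0$sigma, 0)
  expect_identical(spec0$lambda, 0)
  # MAD of +-0.6745 about median 0 is 0.6745 => sigma = 1
  spec1 <- universal_threshold(c(0.6745, -0.6745, 0.6745, -0.6745), n = 1000)
  expect_equal(spec1$sigma, 1, tolerance = 1e-12)
  expect_equal(spec1$lambda, sqrt(2 * log(1000)), tolerance = 1e-12)
  expect_equal(spec1$lambda, 3.7169, tolerance = 1e-4)
  # doubling the coefficients doubles sigma
  spec2 <- universal_threshold(2 * c(0.6745, -0.6745, 0.6745, -0.6745), n = 100)
  expect_equal(spec2$lambda, 2 * sqrt(2 * log(100)), tolerance = 1e-12)
  expect_equal(spec2$lambda, 6.0697, tolerance = 1e-4)
  expect_error(universal_threshold(1:3, n = 1), "n")
})

test_that("garrote shrinkage matches hand values, is odd and contractive", {
  expect_identical(shrink_garrote(0.5, 1), 0)
  expect_equal(shrink_garrote(2, 1), 1.5, tolerance = 1e-12)
  expect_equal(shrink_garrote(-3, 1), -3 + 1 / 3, tolerance = 1e-12)
  set.seed(3)
  c0 <- rnorm(200, sd = 2)
  lam <- 0.7
  out <- shrink_garrote(c0, lam)
  expect_equal(shrink_garrote(-c0, lam), -out, tolerance = 1e-12)
  expect_true(all(abs(out) <= abs(c0) + 1e-12))
  expect_true(all(out * c0 >= 0))
  # continuity at |c| = lambda: limit from above is 0
  eps <- 10^seq(-3, -8)
  expect_true(all(abs(shrink_garrote(lam + eps, lam)) < 2.2 * eps + 1e-12))
  # lambda = 0 is the identity
  expect_equal(shrink_garrote(c0, 0), c0, tolerance = 0)
})

test_that("soft and hard rules stay selectable behind the config", {
  expect_equal(emglearn:::shrink_soft(c(-2, 0.3, 2), 1), c(-1, 0, 1))
  expect_equal(emglearn:::shrink_hard(c(-2, 0.3, 2), 1), c(-2, 0, 2))
  expect_error(shrink_garrote(1, -0.1), "lambda")
})

test_that("wd_denoise shrinks only D2 and equals the manual-band oracle", {
  expect_identical(wd_denoise(numeric(600)), numeric(600))
  # a smooth polynomial trend has (near-)zero details: lambda ~ 0, identity
  t <- seq(0, 1, length.out = 800)
  ramp <- 2 * t - t^2
  expect_lt(max(abs(wd_denoise(ramp) - ramp)), 1e-8)
  # when every D2 coefficient sits below lambda the result must equal a
  # reconstruction with D2 zeroed out by hand
  set.seed(9)
  x <- sin(2 * pi * 8 * seq(0, 2, length.out = 2000)) + rnorm(2000, sd = 0.05)
  dec <- wd_decompose(x)
  lam <- universal_threshold(dec$details$D2, n = length(x))$lambda
  stopifnot(max(abs(dec$details$D2)) <= lam)  # construction check
  dec$details$D2 <- dec$details$D2 * 0
  expect_equal(wd_denoise(x), wd_reconstruct(dec), tolerance = 1e-12)
})

test_that("denoising never adds energy and helps on noisy sinusoids", {
  set.seed(100)
  for (i in 1:25) {
    x <- rnorm(sample(300:2000, 1))
    expect_lte(sqrt(sum(wd_denoise(x)^2)), sqrt(sum(x^2)) + 1e-8)
  }
  t <- seq(0, 4, length.out = 4000)
  clean <- sin(2 * pi * 10 * t)
  improved <- 0
  for (i in 1:20) {
    set.seed(i)
    noisy <- clean + rnorm(4000, sd = sqrt(mean(clean^2)) * 10^(-5 / 20))
    improved <- improved +
      (sqrt(mean((wd_denoise(noisy) - clean)^2)) <
         sqrt(mean((noisy - clean)^2)))
  }
  expect_gte(improved, 19)
})
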