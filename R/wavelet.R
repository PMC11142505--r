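# Decomposition low-pass (scaling) filters of the Daubechies family, the
# standard published constants. High-pass and reconstruction filters follow
# from the quadrature-mirror relations.
.db_filters <- list(
  db1 = c(7.07106781186547573e-01, 7.07106781186547573e-01),
  db2 = c(-1.29409522551260370e-01, 2.24143868042013389e-01, 8.36516303737807942e-01, 4.82962913144534156e-01),
  db3 = c(3.52262918857095333e-02, -8.54412738820266582e-02, -1.35011020010254584e-01, 4.59877502118491543e-01, 8.06891509311092547e-01, 3.32670552950082632e-01),
  db4 = c(-1.05974017850690317e-02, 3.28830116668851966e-02, 3.08413818355607640e-02, -1.87034811719093086e-01, -2.79837694168598543e-02, 6.30880767929858921e-01, 7.14846570552915672e-01, 2.30377813308896506e-01),
  db5 = c(3.33572528547377125e-03, -1.25807519990819988e-02, -6.24149021279827437e-03, 7.75714938400457188e-02, -3.22448695846383748e-02, -2.42294887066382025e-01, 1.38428145901320743e-01, 7.24308528437772936e-01, 6.03829269797189649e-01, 1.60102397974192928e-01),
  db6 = c(-1.07730108530847959e-03, 4.77725751094551076e-03, 5.53842201161496126e-04, -3.15820393174860298e-02, 2.75228655303057269e-02, 9.75016055873230425e-02, -1.29766867567261940e-01, -2.26264693965439828e-01, 3.15250351709197629e-01, 7.51133908021095364e-01, 4.94623890398453059e-01, 1.11540743350109467e-01),
  db7 = c(3.53713799974520241e-04, -1.80164070404749085e-03, 4.29577972921366515e-04, 1.25509985560998405e-02, -1.65745416306668815e-02, -3.80299369350144134e-02, 8.06126091510830783e-02, 7.13092192668302594e-02, -2.24036184993874982e-01, -1.43906003928564979e-01, 4.69782287405193122e-01, 7.29132090846235092e-01, 3.96539319481917285e-01, 7.78520540850091841e-02),
  db8 = c(-1.17476784124769535e-04, 6.75449406450569331e-04, -3.91740373376947050e-04, -4.87035299345157414e-03, 8.74609404740577662e-03, 1.39810279173982824e-02, -4.40882539307947546e-02, -1.73693010018075474e-02, 1.28747426620478472e-01, 4.72484573913282795e-04, -2.84015542961546907e-01, -1.58291052563493059e-02, 5.85354683654206731e-01, 6.75630736297289758e-01, 3.12871590914299946e-01, 5.44158422431040081e-02),
  db9 = c(3.93473203162716026e-05, -2.51963188942710124e-04, 2.30385763523195973e-04, 1.84764688305622655e-03, -4.28150368246343026e-03, -4.72320475775139716e-03, 2.23616621236790956e-02, 2.50947114831451973e-04, -6.76328290613299743e-02, 3.07256814793333798e-02, 1.48540749338106376e-01, -9.68407832229764565e-02, -2.93273783279174916e-01, 1.33197385825007564e-01, 6.57288078051300517e-01, 6.04823123690111153e-01, 2.43834674612590341e-01, 3.80779473638783450e-02),
  db10 = c(-1.32642028945212443e-05, 9.35886703200695919e-05, -1.16466855129285449e-04, -6.85856694959711619e-04, 1.99240529518505613e-03, 1.39535174705290106e-03, -1.07331754833305745e-02, 3.60655356695616970e-03, 3.32126740593410019e-02, -2.94575368218758134e-02, -7.13941471663970817e-02, 9.30573646035723484e-02, 1.27369340335793252e-01, -1.95946274377377050e-01, -2.49846424327315381e-01, 2.81172343660577473e-01, 6.88459039453603538e-01, 5.27201188931725628e-01, 1.88176800077691497e-01, 2.66700579005555542e-02)
)

#' Filter bank of an orthogonal Daubechies wavelet
#'
#' @param wavelet_name one of `"db1"` .. `"db10"`.
#' @return list with decomposition (`dec_lo`, `dec_hi`) and reconstruction
#'   (`rec_lo`, `rec_hi`) filters and the filter length `length`.
#' @export
wavelet_filters <- function(wavelet_name = "db7") {
  dec_lo <- .db_filters[[wavelet_name]]
  if (is.null(dec_lo)) {
    stop(sprintf("unknown wavelet '%s' (supported: %s)", wavelet_name,
                 paste(names(.db_filters), collapse = ", ")), call. = FALSE)
  }
  len <- length(dec_lo)
  dec_hi <- rev(dec_lo) * rep_len(c(-1, 1), len)
  list(dec_lo = dec_lo, dec_hi = dec_hi,
       rec_lo = rev(dec_lo), rec_hi = rev(dec_hi), length = len)
}

# half-point symmetric reflection for 1-based indices extended beyond [1, n]
sym_idx <- function(i, n) {
  j <- (i - 1L) %% (2L * n)
  ifelse(j < n, j + 1L, 2L * n - j)
}

# correlation of the symmetric extension with rev(h), downsampled by 2
# starting at the second output: the standard single-level analysis step
dwt_step <- function(x, h) {
  n <- length(x)
  len <- length(h)
  ext <- x[sym_idx((1L - (len - 1L)):(n + len - 1L), n)]
  yf <- as.numeric(stats::filter(ext, h, method = "convolution", sides = 1))
  yf <- yf[len:length(ext)]
  yf[seq(2L, n + len - 1L, by = 2L)]
}

# single-level synthesis: zero-stuff both bands, convolve with the
# reconstruction filters, trim the filter ramp from both ends
idwt_step <- function(cA, cD, flt, out_len) {
  la <- length(cA)
  len <- flt$length
  up <- function(coef) {
    u <- numeric(2L * la)
    u[seq(1L, 2L * la, by = 2L)] <- coef
    u
  }
  fullconv <- function(u, h) {
    padded <- c(numeric(len - 1L), u, numeric(len - 1L))
    as.numeric(stats::filter(padded, h, method = "convolution",
                             sides = 1))[len:(length(u) + 2L * len - 2L)]
  }
  y <- fullconv(up(cA), flt$rec_lo) + fullconv(up(cD), flt$rec_hi)
  y <- y[(len - 1L):(length(y) - (len - 2L))]
  y[seq_len(out_len)]
}

#' Multilevel discrete wavelet decomposition
#'
#' Decomposes a 1-D signal into one approximation band at the coarsest
#' level and `level` detail bands, using symmetric (half-point) boundary
#' extension. Band lengths follow the usual
#' `floor((n + filter_length - 1) / 2)` cascade.
#'
#' @param signal numeric vector, length at least the wavelet filter length.
#' @param wavelet_name Daubechies wavelet name (default `"db7"`).
#' @param level number of decomposition levels (default 4).
#' @param padding_mode boundary extension; only `"symmetric"` is provided.
#' @return an object of class `wavelet_decomposition` with fields `approx`
#'   (coarsest approximation coefficients), `details` (list `D1`..`Dlevel`,
#'   `D1` the finest), `wavelet_name`, `level`, `padding_mode`,
#'   `original_length` and the per-level input lengths needed for exact
#'   reconstruction.
#' @seealso [wd_reconstruct()], [wd_denoise()]
#' @export
#' @examples
#' x <- sin(2 * pi * 25 * seq(0, 1, length.out = 1000))
#' dec <- wd_decompose(x)
#' lengths(dec$details)
wd_decompose <- function(signal, wavelet_name = "db7", level = 4,
                         padding_mode = "symmetric") {
  signal <- as.numeric(signal)
  if (!all(is.finite(signal))) stop("signal must be finite", call. = FALSE)
  if (padding_mode != "symmetric") {
    stop("only symmetric padding is implemented", call. = FALSE)
  }
  flt <- wavelet_filters(wavelet_name)
  level <- as.integer(level)
  if (level < 1L) stop("level must be >= 1", call. = FALSE)
  if (length(signal) < flt$length) {
    stop(sprintf("signal length %d shorter than the %s filter (%d taps)",
                 length(signal), wavelet_name, flt$length), call. = FALSE)
  }
  approx <- signal
  details <- vector("list", level)
  input_lengths <- integer(level)
  for (lev in seq_len(level)) {
    if (length(approx) < flt$length) {
      stop(sprintf("signal too short for %d-level decomposition with %s",
                   level, wavelet_name), call. = FALSE)
    }
    input_lengths[lev] <- length(approx)
    details[[lev]] <- dwt_step(approx, flt$dec_hi)
    approx <- dwt_step(approx, flt$dec_lo)
  }
  names(details) <- paste0("D", seq_len(level))
  structure(
    list(approx = approx, details = details, wavelet_name = wavelet_name,
         level = level, padding_mode = padding_mode,
         original_length = length(signal), input_lengths = input_lengths),
    class = "wavelet_decomposition"
  )
}

#' @export
print.wavelet_decomposition <- function(x, ...) {
  cat(sprintf("<wavelet_decomposition> %s, level %d, %s padding, n = %d\n",
              x$wavelet_name, x$level, x$padding_mode, x$original_length))
  cat(sprintf("  A%d: %d coefficients; %s\n", x$level, length(x$approx),
              paste(sprintf("%s: %d", names(x$details), lengths(x$details)),
                    collapse = "; ")))
  invisible(x)
}

#' Inverse multilevel wavelet transform
#'
#' Reconstructs the signal from a [wd_decompose()] object; with unmodified
#' coefficients the round trip is exact to numerical precision.
#'
#' @param dec a `wavelet_decomposition`.
#' @return numeric vector of length `dec$original_length`.
#' @export
wd_reconstruct <- function(dec) {
  stopifnot(inherits(dec, "wavelet_decomposition"))
  flt <- wavelet_filters(dec$wavelet_name)
  approx <- dec$approx
  for (lev in rev(seq_len(dec$level))) {
    approx <- idwt_step(approx, dec$details[[lev]], flt, dec$input_lengths[lev])
  }
  approx
}

#' Universal threshold with MAD noise-scale estimate
#'
#' The Donoho-Johnstone universal rule `lambda = sigma * sqrt(2 * ln(n))`,
#' with the noise scale `sigma` estimated from the coefficient band being
#' thresholded as the median absolute deviation about the median divided by
#' the Gaussian consistency constant 0.6745. A mean-absolute-deviation
#' estimator is selectable via `sigma_estimator = "mean_ad"`.
#'
#' @param coeffs numeric coefficient band (non-empty).
#' @param n the original signal length `N` entering the `ln N` term.
#' @param sigma_estimator `"mad"` (default) or `"mean_ad"`.
#' @param shrinkage shrinkage rule recorded on the returned object:
#'   `"garrote"` (default), `"soft"` or `"hard"`.
#' @return an object of class `threshold_spec` with fields `lambda`,
#'   `sigma`, `n`, `rule = "universal"` and `shrinkage`.
#' @export
#' @examples
#' universal_threshold(c(0.6745, -0.6745, 0.6745, -0.6745), n = 1000)$lambda
universal_threshold <- function(coeffs, n, sigma_estimator = c("mad", "mean_ad"),
                                shrinkage = c("garrote", "soft", "hard")) {
  sigma_estimator <- match.arg(sigma_estimator)
  shrinkage <- match.arg(shrinkage)
  coeffs <- as.numeric(coeffs)
  if (length(coeffs) == 0L) stop("empty coefficient band", call. = FALSE)
  assert_scalar_num(n, "n", lower = 2)
  dev <- abs(coeffs - stats::median(coeffs))
  sigma <- switch(sigma_estimator,
                  mad = stats::median(dev) / 0.6745,
                  mean_ad = mean(dev) / 0.6745)
  structure(
    list(lambda = sigma * sqrt(2 * log(n)), sigma = sigma, n = n,
         rule = "universal", shrinkage = shrinkage,
         sigma_estimator = sigma_estimator),
    class = "threshold_spec"
  )
}

#' Non-negative garrote shrinkage
#'
#' Coefficients with magnitude at or below `lambda` are zeroed; the rest
#' shrink to `c - lambda^2 / c`, preserving sign and never increasing
#' magnitude. Continuous at `|c| = lambda`, intermediate between hard and
#' soft thresholding.
#'
#' @param coeffs numeric coefficients.
#' @param lambda nonnegative threshold.
#' @return shrunken coefficients, same length.
#' @export
#' @examples
#' shrink_garrote(c(0.5, 2, -3), 1)  # 0, 1.5, -8/3
shrink_garrote <- function(coeffs, lambda) {
  assert_scalar_num(lambda, "lambda", lower = 0)
  out <- ifelse(abs(coeffs) <= lambda, 0, coeffs - lambda^2 / coeffs)
  as.numeric(out)
}

# soft and hard rules kept selectable behind the threshold spec
shrink_soft <- function(coeffs, lambda) {
  assert_scalar_num(lambda, "lambda", lower = 0)
  sign(coeffs) * pmax(abs(coeffs) - lambda, 0)
}

shrink_hard <- function(coeffs, lambda) {
  assert_scalar_num(lambda, "lambda", lower = 0)
  ifelse(abs(coeffs) <= lambda, 0, coeffs)
}

apply_shrinkage <- function(coeffs, lambda, shrinkage) {
  switch(shrinkage,
         garrote = shrink_garrote(coeffs, lambda),
         soft = shrink_soft(coeffs, lambda),
         hard = shrink_hard(coeffs, lambda),
         stop(sprintf("unknown shrinkage rule '%s'", shrinkage), call. = FALSE))
}

#' Wavelet-denoising stage configuration
#'
#' @param wavelet mother wavelet (default `"db7"`).
#' @param level decomposition depth (default 4).
#' @param threshold_band detail band to shrink (default `"D2"`, the
#'   second-finest).
#' @param rule threshold selection rule; only `"universal"` is provided.
#' @param shrinkage `"garrote"` (default), `"soft"` or `"hard"`.
#' @param sigma_estimator noise-scale estimator passed to
#'   [universal_threshold()].
#' @return list of class `wd_config`.
#' @export
wd_config <- function(wavelet = "db7", level = 4, threshold_band = "D2",
                      rule = "universal",
                      shrinkage = c("garrote", "soft", "hard"),
                      sigma_estimator = c("mad", "mean_ad")) {
  if (rule != "universal") stop("only the universal rule is implemented", call. = FALSE)
  structure(
    list(wavelet = wavelet, level = as.integer(level),
         threshold_band = threshold_band, rule = rule,
         shrinkage = match.arg(shrinkage),
         sigma_estimator = match.arg(sigma_estimator)),
    class = "wd_config"
  )
}

#' Wavelet denoising of one signal
#'
#' Decomposes the signal (default `db7`, level 4, symmetric padding),
#' shrinks the configured detail band (default D2) with the configured rule
#' (default garrote under the universal threshold, with the noise scale
#' estimated from that band's own coefficients and `N` the signal length),
#' and reconstructs. All other bands pass through untouched.
#'
#' @param signal numeric vector.
#' @param cfg a [wd_config()].
#' @return denoised numeric vector, same length as `signal`.
#' @export
#' @examples
#' set.seed(1)
#' x <- sin(2 * pi * 10 * seq(0, 1, length.out = 1000)) + rnorm(1000, sd = 0.3)
#' d <- wd_denoise(x)
#' length(d) == length(x)
wd_denoise <- function(signal, cfg = wd_config()) {
  stopifnot(inherits(cfg, "wd_config"))
  dec <- wd_decompose(signal, wavelet_name = cfg$wavelet, level = cfg$level,
                      padding_mode = "symmetric")
  band <- cfg$threshold_band
  if (!band %in% names(dec$details)) {
    stop(sprintf("band '%s' not present in a level-%d decomposition",
                 band, dec$level), call. = FALSE)
  }
  spec <- universal_threshold(dec$details[[band]], n = dec$original_length,
                              sigma_estimator = cfg$sigma_estimator,
                              shrinkage = cfg$shrinkage)
  dec$details[[band]] <- apply_shrinkage(dec$details[[band]], spec$lambda,
                                         spec$shrinkage)
  wd_reconstruct(dec)
}
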