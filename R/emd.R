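# local extrema of a 1-D signal; plateaus are collapsed to their midpoint
find_extrema <- function(x) {
  n <- length(x)
  if (n < 3L) return(list(maxima = integer(0), minima = integer(0)))
  s <- sign(diff(x))
  nz <- which(s != 0)
  if (length(nz) < 2L) return(list(maxima = integer(0), minima = integer(0)))
  sv <- s[nz]
  turn <- which(sv[-1L] != sv[-length(sv)])  # sign flips between nonzero runs
  if (length(turn) == 0L) return(list(maxima = integer(0), minima = integer(0)))
  pos <- as.integer((nz[turn] + 1L + nz[turn + 1L]) %/% 2L)
  is_max <- sv[turn] > 0
  list(maxima = pos[is_max], minima = pos[!is_max])
}

# zero crossings: strict sign alternation of consecutive nonzero samples,
# with exact zeros treated as crossing points
count_zero_crossings <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  if (length(s) < 2L) return(0L)
  sum(s[-1] != s[-length(s)])
}

# the defining IMF property: extrema and zero-crossing counts differ by <= 1
imf_property_holds <- function(x, tol = 1L) {
  ex <- find_extrema(x)
  n_ext <- length(ex$maxima) + length(ex$minima)
  abs(n_ext - count_zero_crossings(x)) <= tol
}

# natural-cubic-spline envelope through extrema, with the two edge extrema
# mirrored beyond each end to tame border artifacts
spline_envelope <- function(idx, val, n) {
  if (length(idx) >= 2L) {
    lpos <- 2L - rev(utils::head(idx, 2L))
    lval <- rev(utils::head(val, 2L))
    rpos <- 2L * n - rev(utils::tail(idx, 2L))
    rval <- rev(utils::tail(val, 2L))
    keep_l <- lpos < idx[1]
    keep_r <- rpos > idx[length(idx)]
    idx <- c(lpos[keep_l], idx, rpos[keep_r])
    val <- c(lval[keep_l], val, rval[keep_r])
  }
  stats::splinefun(idx, val, method = "natural")(seq_len(n))
}

#' Mean envelope of a signal (one sifting step)
#'
#' Fits cubic-spline envelopes through the local maxima and the local
#' minima (edge extrema mirrored past the borders) and returns their
#' pointwise mean. Signals with fewer than two maxima or two minima are
#' monotone trends for the purpose of sifting and return `NULL`.
#'
#' @param signal numeric vector.
#' @return numeric vector the same length as `signal`, or `NULL` when the
#'   signal has too few extrema to envelope.
#' @export
mean_envelope <- function(signal) {
  ex <- find_extrema(signal)
  if (length(ex$maxima) < 2L || length(ex$minima) < 2L) return(NULL)
  n <- length(signal)
  upper <- spline_envelope(ex$maxima, signal[ex$maxima], n)
  lower <- spline_envelope(ex$minima, signal[ex$minima], n)
  (upper + lower) / 2
}

#' EEMD / EMD configuration
#'
#' @param ensemble_size number of noise-perturbed ensemble members `T`
#'   (default 100, the canonical literature value).
#' @param noise_scale standard deviation of the added white noise as a
#'   fraction of the signal's standard deviation (default 0.2).
#' @param max_imfs cap on the number of extracted IMFs (`Inf` = until the
#'   residual is a monotone trend).
#' @param sd_threshold Cauchy-type sifting stop: sifting ends once the
#'   normalised squared change between successive siftings drops below this
#'   (default 0.2, Huang's convention).
#' @param max_sifts hard cap on sifting iterations per IMF (default 50).
#' @param seed integer seed driving the ensemble noise streams.
#' @return list of class `eemd_config`.
#' @export
eemd_config <- function(ensemble_size = 100, noise_scale = 0.2, max_imfs = Inf,
                        sd_threshold = 0.2, max_sifts = 50, seed = 1) {
  assert_scalar_num(ensemble_size, "ensemble_size", lower = 1)
  assert_scalar_num(noise_scale, "noise_scale", lower = 0)
  assert_scalar_num(sd_threshold, "sd_threshold", lower = 1e-12)
  assert_scalar_num(max_sifts, "max_sifts", lower = 1)
  structure(
    list(ensemble_size = as.integer(ensemble_size), noise_scale = noise_scale,
         max_imfs = max_imfs, sd_threshold = sd_threshold,
         max_sifts = as.integer(max_sifts), seed = as.integer(seed)),
    class = "eemd_config"
  )
}

new_imf_set <- function(imfs, residual, source_length, meta = list()) {
  structure(
    list(imfs = imfs, residual = residual, source_length = source_length,
         meta = meta),
    class = "imf_set"
  )
}

#' @export
print.imf_set <- function(x, ...) {
  cat(sprintf("<imf_set> %d IMFs + residual, %d samples%s\n",
              length(x$imfs), x$source_length,
              if (!is.null(x$meta$ensemble_size))
                sprintf(" (EEMD, T = %d, noise %.2g)", x$meta$ensemble_size,
                        x$meta$noise_scale) else ""))
  invisible(x)
}

#' Empirical mode decomposition by sifting
#'
#' Iteratively subtracts the mean envelope from the running signal until
#' the sifting-stop criterion is met (normalised squared change below
#' `cfg$sd_threshold` and the extrema/zero-crossing IMF property holding,
#' or `cfg$max_sifts` reached); the result is one intrinsic mode function,
#' highest-frequency first. Extraction repeats on the remainder until it is
#' a monotone trend or `cfg$max_imfs` is hit. The IMFs plus the residual
#' sum back to the input exactly.
#'
#' @param signal finite numeric vector, length >= 16.
#' @param cfg an [eemd_config()]; only the sifting fields are used.
#' @return an `imf_set` with fields `imfs` (list, IMF1 first), `residual`
#'   and `source_length`.
#' @export
#' @examples
#' t <- seq(0, 1, length.out = 500)
#' dec <- emd(sin(2 * pi * 30 * t) + sin(2 * pi * 4 * t))
#' length(dec$imfs)
emd <- function(signal, cfg = eemd_config()) {
  signal <- as.numeric(signal)
  if (!all(is.finite(signal))) stop("signal must be finite", call. = FALSE)
  if (length(signal) < 16L) stop("signal too short for sifting", call. = FALSE)
  residual <- signal
  imfs <- list()
  # extrema/zero-crossing discrepancy tolerated in the stop rule: one per
  # 1000 samples, so sifting effort does not scale with signal length
  prop_tol <- max(1L, as.integer(round(length(signal) / 1000)))
  while (length(imfs) < cfg$max_imfs) {
    h <- residual
    m <- mean_envelope(h)
    if (is.null(m)) break  # monotone trend: nothing left to sift
    for (sift in seq_len(cfg$max_sifts)) {
      h_new <- h - m
      sd_crit <- sum(m^2) / (sum(h^2) + .Machine$double.eps)
      h <- h_new
      if (sd_crit < cfg$sd_threshold && imf_property_holds(h, prop_tol)) break
      m <- mean_envelope(h)
      if (is.null(m)) break
    }
    imfs[[length(imfs) + 1L]] <- h
    residual <- residual - h
  }
  new_imf_set(imfs, residual, length(signal))
}

#' Ensemble empirical mode decomposition
#'
#' Runs [emd()] on `ensemble_size` copies of the signal, each perturbed by
#' an independent seeded white-Gaussian-noise realisation of standard
#' deviation `noise_scale * sd(signal)`, and averages IMFs across members
#' by ordinal position (members producing fewer IMFs contribute zeros).
#' Averaging over noise realisations suppresses mode mixing and border
#' artifacts of plain EMD; with `noise_scale = 0` and `ensemble_size = 1`
#' the result reduces exactly to [emd()].
#'
#' @param signal finite numeric vector, length >= 16.
#' @param cfg an [eemd_config()].
#' @return an `imf_set`; `meta` records `ensemble_size`, `noise_scale` and
#'   `seed`.
#' @export
eemd <- function(signal, cfg = eemd_config()) {
  signal <- as.numeric(signal)
  if (!all(is.finite(signal))) stop("signal must be finite", call. = FALSE)
  n <- length(signal)
  t_ens <- cfg$ensemble_size
  if (t_ens < 1L) stop("ensemble_size must be >= 1", call. = FALSE)
  noise_sd <- cfg$noise_scale * stats::sd(signal)
  members <- with_seed(cfg$seed, {
    lapply(seq_len(t_ens), function(i) {
      noisy <- if (noise_sd > 0) signal + stats::rnorm(n, sd = noise_sd) else signal
      emd(noisy, cfg)
    })
  })
  q_max <- max(vapply(members, function(m) length(m$imfs), integer(1)))
  imfs <- vector("list", q_max)
  for (q in seq_len(q_max)) {
    acc <- numeric(n)
    for (m in members) {
      if (length(m$imfs) >= q) acc <- acc + m$imfs[[q]]
    }
    imfs[[q]] <- acc / t_ens
  }
  residual <- Reduce(`+`, lapply(members, `[[`, "residual")) / t_ens
  new_imf_set(imfs, residual, n,
              meta = list(ensemble_size = t_ens, noise_scale = cfg$noise_scale,
                          seed = cfg$seed))
}
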