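#' SMOTE configuration
#'
#' @param k_neighbors number of minority-class nearest neighbours to
#'   interpolate toward (default 5, the conventional value).
#' @param target_ratio desired minority/majority row ratio after
#'   oversampling, in (0, 1] (default 1, i.e. fully balanced).
#' @param seed integer seed for neighbour choice and interpolation weights.
#' @param standardize_before_knn scale columns to unit variance before the
#'   neighbour search (off by default; feature magnitudes are used as-is).
#' @param per_feature_u draw an independent interpolation weight per
#'   feature instead of the classic single weight per synthetic row
#'   (off by default).
#' @return list of class `smote_config`.
#' @export
smote_config <- function(k_neighbors = 5, target_ratio = 1, seed = 1,
                         standardize_before_knn = FALSE,
                         per_feature_u = FALSE) {
  assert_scalar_num(k_neighbors, "k_neighbors", lower = 1)
  assert_scalar_num(target_ratio, "target_ratio", lower = 1e-12, upper = 1)
  structure(
    list(k_neighbors = as.integer(k_neighbors), target_ratio = target_ratio,
         seed = as.integer(seed),
         standardize_before_knn = isTRUE(standardize_before_knn),
         per_feature_u = isTRUE(per_feature_u)),
    class = "smote_config"
  )
}

#' SMOTE oversampling of the minority class
#'
#' Appends synthetic minority rows until the minority count reaches
#' `round(target_ratio * majority_count)`. Base rows are visited
#' round-robin over the minority rows (uniform coverage, exact counts);
#' for each, one of its `k` nearest minority neighbours (Euclidean) is
#' drawn uniformly and the synthetic row is `x + u * (neighbour - x)` with
#' a single `u ~ Uniform(0, 1)` shared across features. Original rows are
#' never modified; synthetic rows carry `synthetic = TRUE` provenance.
#' Deterministic given `cfg$seed`.
#'
#' @param mat an [feature_matrix()] with two classes, minority count >= 2.
#' @param cfg a [smote_config()]. `k` is clamped to `minority - 1` with a
#'   warning when the minority class is small.
#' @return an [feature_matrix()] with the original rows first, synthetic
#'   rows appended.
#' @export
smote_oversample <- function(mat, cfg = smote_config()) {
  stopifnot(inherits(mat, "emg_features"), inherits(cfg, "smote_config"))
  if (nrow(mat$x) == 0L) stop("empty feature matrix", call. = FALSE)
  counts <- table(mat$label)
  if (length(counts) != 2L) {
    stop("SMOTE needs exactly two classes", call. = FALSE)
  }
  minority <- names(counts)[which.min(counts)]
  n_min <- min(counts)
  n_maj <- max(counts)
  if (n_min < 2L) stop("minority class needs at least 2 rows", call. = FALSE)
  target <- round(cfg$target_ratio * n_maj)
  n_new <- target - n_min
  if (n_new <= 0L) return(mat)
  k <- cfg$k_neighbors
  if (k > n_min - 1L) {
    warning(sprintf("k_neighbors = %d clamped to %d (minority size %d)",
                    k, n_min - 1L, n_min))
    k <- n_min - 1L
  }
  min_idx <- which(mat$label == minority)
  xm <- mat$x[min_idx, , drop = FALSE]
  xs <- if (cfg$standardize_before_knn) {
    sds <- apply(xm, 2, stats::sd)
    sds[sds == 0] <- 1
    sweep(xm, 2, sds, "/")
  } else xm
  d <- as.matrix(stats::dist(xs))
  diag(d) <- Inf
  nn <- do.call(rbind, lapply(seq_len(n_min),
                              function(i) order(d[i, ])[seq_len(k)]))
  p <- ncol(xm)
  synth <- with_seed(cfg$seed, {
    base <- rep_len(seq_len(n_min), n_new)
    out <- matrix(0, nrow = n_new, ncol = p)
    for (i in seq_len(n_new)) {
      b <- base[i]
      nbr <- nn[b, sample.int(k, 1L)]
      u <- if (cfg$per_feature_u) stats::runif(p) else stats::runif(1)
      out[i, ] <- xm[b, ] + u * (xm[nbr, ] - xm[b, ])
    }
    list(x = out, base = base)
  })
  colnames(synth$x) <- colnames(mat$x)
  feature_matrix(
    rbind(mat$x, synth$x),
    label = c(mat$label, rep(minority, n_new)),
    subject_id = c(mat$subject_id,
                   paste0("syn:", mat$subject_id[min_idx][synth$base])),
    synthetic = c(mat$synthetic, rep(TRUE, n_new)),
    quality_flags = c(mat$quality_flags, rep("", n_new))
  )
}
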