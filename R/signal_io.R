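#' sEMG recording container
#'
#' A recording is the raw unit of input: a rectangular numeric matrix of
#' samples (rows) by muscle channels (columns), a sampling rate, ordered
#' channel names, a two-level class label and a subject identifier.
#'
#' @param samples numeric matrix or data frame, one column per channel,
#'   no missing values.
#' @param sampling_rate sampling frequency in Hz (default 1000).
#' @param channel_names ordered channel labels; default the four lower-limb
#'   muscles rectus femoris, biceps femoris, vastus medialis and
#'   semitendinosus, `c("RF","BF","VM","ST")`.
#' @param label class label, `"healthy"` or `"abnormal"`.
#' @param subject_id opaque subject identifier string.
#' @return an object of class `emg_recording`.
#' @export
#' @examples
#' rec <- recording(matrix(rnorm(400), ncol = 4), label = "healthy",
#'                  subject_id = "S1")
#' dim(rec$samples)
recording <- function(samples, sampling_rate = 1000,
                      channel_names = c("RF", "BF", "VM", "ST"),
                      label = c("healthy", "abnormal"),
                      subject_id = "unknown") {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  label <- match.arg(label)
  if (nrow(samples) < 1L) stop("recording needs at least one sample", call. = FALSE)
  if (anyNA(samples) || !all(is.finite(samples))) {
    stop("recording samples must be finite with no missing values", call. = FALSE)
  }
  assert_scalar_num(sampling_rate, "sampling_rate", lower = 1e-12)
  if (length(channel_names) != ncol(samples)) {
    stop(sprintf("%d channel names supplied for %d channels",
                 length(channel_names), ncol(samples)), call. = FALSE)
  }
  colnames(samples) <- channel_names
  structure(
    list(samples = samples, sampling_rate = sampling_rate,
         channel_names = as.character(channel_names), label = label,
         subject_id = as.character(subject_id)),
    class = "emg_recording"
  )
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording> subject %s (%s): %d samples x %d channels @ %g Hz (%.2f s)\n",
              x$subject_id, x$label, nrow(x$samples), ncol(x$samples),
              x$sampling_rate, nrow(x$samples) / x$sampling_rate))
  invisible(x)
}

#' Read a multi-channel sEMG recording from delimited text
#'
#' Reads a comma-separated numeric file with one sample per row and one
#' column per channel. Channel order is taken from `schema` (never inferred
#' from the file) because downstream feature-column semantics depend on it.
#'
#' @param path CSV file path.
#' @param schema character vector naming the channels in column order, or a
#'   named integer vector mapping channel name to column index.
#' @param sampling_rate sampling frequency in Hz.
#' @param label,subject_id recording metadata (see [recording()]).
#' @return an [recording()] object.
#' @export
load_recording <- function(path, schema = c("RF", "BF", "VM", "ST"),
                           sampling_rate = 1000,
                           label = c("healthy", "abnormal"),
                           subject_id = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  widths <- utils::count.fields(path, sep = ",")
  if (length(unique(widths)) != 1L) {
    stop(sprintf("ragged rows in '%s': %d fields on some lines, %d on others",
                 path, min(widths), max(widths)), call. = FALSE)
  }
  dt <- tryCatch(
    suppressWarnings(
      data.table::fread(path, header = TRUE, sep = ",", colClasses = "numeric",
                        fill = FALSE, data.table = FALSE)),
    error = function(e) stop(sprintf("failed to parse '%s': %s", path,
                                     conditionMessage(e)), call. = FALSE)
  )
  if (is.null(names(schema))) {
    cols <- seq_along(schema)
    ch <- as.character(schema)
  } else {
    cols <- as.integer(schema)
    ch <- names(schema)
  }
  if (max(cols) > ncol(dt)) {
    stop(sprintf("schema refers to column %d but '%s' has %d columns",
                 max(cols), path, ncol(dt)), call. = FALSE)
  }
  m <- as.matrix(dt[, cols, drop = FALSE])
  if (!is.numeric(m) || anyNA(m)) {
    stop(sprintf("non-numeric or missing cells in '%s'", path), call. = FALSE)
  }
  if (is.null(subject_id)) {
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  }
  recording(m, sampling_rate = sampling_rate, channel_names = ch,
            label = match.arg(label), subject_id = subject_id)
}

#' Write a recording to delimited text
#'
#' Comma-separated, UTF-8, `"."` decimal separator, one sample per row,
#' header row of channel names; full double precision so that
#' `load_recording(save_recording(x))` round-trips exactly.
#'
#' @param rec an [recording()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_recording <- function(rec, path) {
  stopifnot(inherits(rec, "emg_recording"))
  df <- as.data.frame(apply(rec$samples, 2, format_full, simplify = FALSE))
  data.table::fwrite(df, path, sep = ",", quote = FALSE)
  invisible(path)
}

# 17 significant digits: enough for an exact double -> text -> double trip
format_full <- function(x) sprintf("%.17g", x)

#' Feature matrix container
#'
#' Windows-by-(channels x features) table with per-row class labels,
#' subject provenance and a synthetic-row flag (set by SMOTE for generated
#' rows; all `FALSE` for extracted rows).
#'
#' @param x numeric matrix, one row per analysis window; column names
#'   `"<channel>_<feature>"`.
#' @param label character/factor vector of per-row class labels.
#' @param subject_id character vector of per-row subject provenance.
#' @param synthetic logical vector flagging interpolated (SMOTE) rows.
#' @param quality_flags optional character vector of per-row quality notes
#'   (e.g. degenerate zero-variance windows).
#' @return an object of class `emg_features`.
#' @export
feature_matrix <- function(x, label, subject_id,
                           synthetic = rep(FALSE, nrow(x)),
                           quality_flags = rep("", nrow(x))) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  label <- as.character(label)
  if (nrow(x) != length(label) || nrow(x) != length(subject_id) ||
      nrow(x) != length(synthetic)) {
    stop("rows, labels, subject ids and synthetic flags must align", call. = FALSE)
  }
  structure(
    list(x = x, label = label, subject_id = as.character(subject_id),
         synthetic = as.logical(synthetic),
         quality_flags = as.character(quality_flags)),
    class = "emg_features"
  )
}

#' @export
print.emg_features <- function(x, ...) {
  tab <- table(x$label)
  cat(sprintf("<emg_features> %d windows x %d columns (%s)%s\n",
              nrow(x$x), ncol(x$x),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
              if (any(x$synthetic)) sprintf("; %d synthetic", sum(x$synthetic)) else ""))
  invisible(x)
}

#' @export
dim.emg_features <- function(x) dim(x$x)

#' Coerce a feature matrix to a data frame
#'
#' @param x an [feature_matrix()] object.
#' @param ... unused.
#' @return data frame of feature columns plus `label`, `subject_id` and
#'   `synthetic` metadata columns.
#' @export
as.data.frame.emg_features <- function(x, ...) {
  cbind(as.data.frame(x$x),
        label = x$label, subject_id = x$subject_id, synthetic = x$synthetic,
        stringsAsFactors = FALSE)
}

#' Write a feature matrix to delimited text
#'
#' Header row holds the `"<channel>_<feature>"` columns followed by the
#' `label`, `subject_id` and `synthetic` metadata columns. Values keep full
#' double precision (>= 15 significant digits) so a round trip through
#' [load_feature_matrix()] is faithful.
#'
#' @param mat an [feature_matrix()] object with at least one row.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_feature_matrix <- function(mat, path) {
  stopifnot(inherits(mat, "emg_features"))
  if (nrow(mat$x) == 0L) {
    stop("refusing to write an empty feature matrix", call. = FALSE)
  }
  df <- as.data.frame(apply(mat$x, 2, format_full, simplify = FALSE))
  df$label <- mat$label
  df$subject_id <- mat$subject_id
  df$synthetic <- mat$synthetic
  data.table::fwrite(df, path, sep = ",", quote = FALSE)
  invisible(path)
}

#' Read a feature matrix written by [save_feature_matrix()]
#'
#' @param path CSV file path.
#' @return an [feature_matrix()] object.
#' @export
load_feature_matrix <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- data.table::fread(path, header = TRUE, sep = ",", data.table = FALSE)
  meta <- c("label", "subject_id", "synthetic")
  if (!all(meta %in% names(df))) {
    stop("not a feature-matrix file: missing metadata columns", call. = FALSE)
  }
  feats <- setdiff(names(df), meta)
  feature_matrix(as.matrix(df[, feats, drop = FALSE]),
                 label = df$label, subject_id = df$subject_id,
                 synthetic = df$synthetic)
}
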