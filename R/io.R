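# Readers/writers and the cohort data model: belt recordings, anxiety
# scores, behavioral logs, and the wide feature table. CSV (comma, dot
# decimal, UTF-8, header row) is the single interchange format.

#' Construct a breathing-belt recording
#'
#' @param samples numeric vector of belt displacement values (arbitrary
#'   units), sampled at a constant rate.
#' @param fs sampling rate in Hz.
#' @param subject_id subject identifier.
#' @param condition `"rest"` or `"task"`.
#' @param site_id recording-site label.
#' @param t0 start offset in seconds.
#' @return A `breath_recording` object.
#' @export
breath_recording <- function(samples, fs = 10, subject_id = "s1",
                             condition = c("rest", "task"), site_id = "site1",
                             t0 = 0) {
  condition <- match.arg(condition)
  samples <- as.numeric(samples)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("fs must be a positive number")
  if (length(samples) < 2L) stop("recording needs at least 2 samples")
  if (anyNA(samples)) stop("recording contains missing values")
  structure(
    list(samples = samples, fs = fs, subject_id = as.character(subject_id),
         condition = condition, site_id = as.character(site_id), t0 = t0),
    class = "breath_recording")
}

#' @export
print.breath_recording <- function(x, ...) {
  cat(sprintf("<breath_recording> subject=%s condition=%s site=%s\n",
              x$subject_id, x$condition, x$site_id))
  cat(sprintf("  %d samples at %g Hz (%.1f s)\n",
              length(x$samples), x$fs, length(x$samples) / x$fs))
  invisible(x)
}

#' Read a belt recording from CSV
#'
#' The file holds either a single signal column, or a time column (seconds)
#' followed by the signal. With a time column the sampling rate is inferred
#' from the median step and the column is checked for monotonicity. Rows
#' with unparseable signal values are dropped and counted in the
#' `n_dropped` attribute.
#'
#' @param path CSV path.
#' @param fs sampling rate in Hz; ignored (re-inferred) when the file has a
#'   time column.
#' @param subject_id,condition,site_id metadata attached to the recording.
#' @return A [breath_recording()] with attributes `n_read` and `n_dropped`.
#' @export
read_recording <- function(path, fs = 10, subject_id = "s1",
                           condition = c("rest", "task"), site_id = "site1") {
  condition <- match.arg(condition)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty recording file: ", path)
  time_col <- intersect(c("time", "time_s", "t"), names(df))
  if (length(time_col)) {
    tt <- suppressWarnings(as.numeric(df[[time_col[1L]]]))
    sig_name <- setdiff(names(df), time_col[1L])[1L]
  } else {
    tt <- NULL
    sig_name <- names(df)[1L]
  }
  raw <- df[[sig_name]]
  sig <- suppressWarnings(as.numeric(raw))
  if (all(is.na(sig))) stop("non-numeric signal column in ", path)
  keep <- !is.na(sig)
  n_dropped <- sum(!keep)
  if (!is.null(tt)) {
    keep <- keep & !is.na(tt)
    tt <- tt[keep]
    if (is.unsorted(tt, strictly = TRUE)) stop("non-monotonic time column")
    fs <- 1 / median(diff(tt))
  }
  rec <- breath_recording(sig[keep], fs = fs, subject_id = subject_id,
                          condition = condition, site_id = site_id,
                          t0 = if (is.null(tt)) 0 else tt[1L])
  attr(rec, "n_read") <- nrow(df)
  attr(rec, "n_dropped") <- nrow(df) - sum(keep)
  rec
}

#' Read a Beck Anxiety Inventory table
#'
#' Expects `subject` (or `subject_id`) plus either a `bai_total` column, 21
#' `item_1..item_21` columns, or both. Items must lie in 0..3; when both
#' totals and items are present the total must equal the item sum.
#'
#' @param path CSV path.
#' @return data.frame with `subject`, `bai_total`, and item columns when
#'   present.
#' @export
read_anxiety_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  names(df)[names(df) == "subject_id"] <- "subject"
  if (!"subject" %in% names(df)) stop("anxiety table needs a subject column")
  item_cols <- paste0("item_", 1:21)
  has_items <- all(item_cols %in% names(df))
  has_total <- "bai_total" %in% names(df)
  if (!has_items && !has_total)
    stop("anxiety table needs bai_total or item_1..item_21")
  if (has_items) {
    items <- as.matrix(df[item_cols])
    if (any(!items %in% 0:3)) stop("BAI item outside 0-3")
    item_sum <- rowSums(items)
    if (has_total && any(df$bai_total != item_sum))
      stop("bai_total does not equal the item sum")
    df$bai_total <- item_sum
  }
  if (any(df$bai_total < 0 | df$bai_total > 63)) stop("bai_total outside 0-63")
  df$subject <- as.character(df$subject)
  df
}

#' Read an N-back behavioral log
#'
#' One row per trial with `subject`, `load` (1/2/3), `correct` (0/1), `rt`
#' (seconds), and optionally `speed` (slow/fast; set to `"unknown"` when the
#' column is absent — speeds are pooled within load downstream).
#'
#' @param path CSV path.
#' @return data.frame of trials.
#' @export
read_behavior_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  names(df)[names(df) == "subject_id"] <- "subject"
  need <- c("subject", "load", "correct", "rt")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("behavior table missing columns: ",
                         paste(miss, collapse = ", "))
  if (!all(df$load %in% c(1, 2, 3))) stop("unknown load label (must be 1/2/3)")
  if (!all(df$correct %in% c(0, 1))) stop("correct must be 0/1")
  rt <- as.numeric(df$rt)
  if (any(is.finite(rt) & rt < 0)) stop("negative reaction time")
  if (!"speed" %in% names(df)) df$speed <- "unknown"
  df$subject <- as.character(df$subject)
  df
}

#' Canonical feature column order
#'
#' The 16 dynamics features, metric-major with rate before amplitude:
#' mean, sd, cv, acw50, psd_slope, lzc, sampen, mse.
#'
#' @return Character vector of 16 column names.
#' @export
feature_names <- function() {
  metrics <- c("mean", "sd", "cv", "acw50", "psd_slope", "lzc", "sampen", "mse")
  as.vector(t(outer(metrics, c("rate", "amp"), paste, sep = "_")))
}

#' Assemble a feature table
#'
#' A feature table is a data.frame with `subject`, `condition`, `site` and
#' the 16 dynamics features in canonical order, carrying a
#' `transform_state` attribute that moves raw -> logged -> harmonized.
#'
#' @param df data.frame with the required columns.
#' @param transform_state one of `"raw"`, `"logged"`, `"harmonized"`.
#' @return The validated `feature_table`.
#' @export
feature_table <- function(df, transform_state = "raw") {
  cols <- c("subject", "condition", "site", feature_names())
  miss <- setdiff(cols, names(df))
  if (length(miss)) stop("feature table missing columns: ",
                         paste(miss, collapse = ", "))
  df <- df[cols]
  if (anyDuplicated(df[c("subject", "condition")]))
    stop("duplicate subject x condition rows")
  stopifnot(transform_state %in% c("raw", "logged", "harmonized"))
  attr(df, "transform_state") <- transform_state
  class(df) <- c("feature_table", "data.frame")
  df
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d rows (%s), %d sites\n", nrow(x),
              attr(x, "transform_state"), length(unique(x$site))))
  print(head(as.data.frame(x)), ...)
  invisible(x)
}

#' Write / read a feature table
#'
#' Round-trips values to full double precision (15 significant digits in
#' the file) with the canonical column order.
#'
#' @param table a [feature_table()].
#' @param path CSV path.
#' @return `read_feature_table` returns the table; `write_feature_table`
#'   returns `path` invisibly.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  df <- as.data.frame(table)
  for (fn in feature_names()) df[[fn]] <- sprintf("%.15g", df[[fn]])
  df$transform_state <- rep(attr(table, "transform_state"), nrow(df))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(subject = "character", site = "character"))
  state <- if ("transform_state" %in% names(df) && nrow(df) > 0)
    df$transform_state[1L] else "raw"
  df$transform_state <- NULL
  if (nrow(df) == 0L) {
    for (fn in feature_names()) df[[fn]] <- numeric(0)
    df$subject <- character(0); df$condition <- character(0)
    df$site <- character(0)
  }
  feature_table(df, transform_state = state)
}
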