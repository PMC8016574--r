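#' Read and write multichannel signal files
#'
#' Signal files are plain comma-delimited text with a `#`-prefixed
#' `key=value` header declaring the sampling rate, channel names, and an
#' optional label:
#'
#' ```
#' # fs=1000
#' # channels=biceps,extensor
#' # label=left_turn
#' 0.013,-0.002
#' ...
#' ```
#'
#' Values are written with 17 significant digits so that
#' `read_signal(write_signal(x))` reproduces the stored doubles exactly.
#'
#' @param path Path to a signal file.
#' @return `read_signal()` returns a [signal_record]; `write_signal()`
#'   invisibly returns `path`.
#' @export
read_signal <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  is_header <- grepl("^\\s*#", lines)
  n_head <- match(FALSE, is_header, nomatch = length(lines) + 1L) - 1L
  header <- lines[seq_len(n_head)]
  body <- lines[setdiff(seq_along(lines), seq_len(n_head))]
  body <- body[nzchar(trimws(body))]

  meta <- list()
  for (ln in header) {
    kv <- sub("^\\s*#\\s*", "", ln)
    if (!nzchar(kv)) next
    if (!grepl("=", kv, fixed = TRUE)) {
      stop("malformed header line (expected key=value): ", ln, call. = FALSE)
    }
    key <- trimws(sub("=.*$", "", kv))
    val <- trimws(sub("^[^=]*=", "", kv))
    meta[[key]] <- val
  }
  if (is.null(meta$fs)) stop("header is missing 'fs'", call. = FALSE)
  fs <- suppressWarnings(as.numeric(meta$fs))
  if (is.na(fs)) stop("malformed header line: fs=", meta$fs, call. = FALSE)
  if (fs <= 0) stop("declared fs must be > 0, got ", fs, call. = FALSE)
  if (is.null(meta$channels)) stop("header is missing 'channels'", call. = FALSE)
  channels <- trimws(strsplit(meta$channels, ",", fixed = TRUE)[[1]])
  if (length(body) == 0L) stop("signal file has no sample rows", call. = FALSE)

  cells <- strsplit(body, ",", fixed = TRUE)
  ncell <- lengths(cells)
  if (any(ncell != length(channels))) {
    bad <- which(ncell != length(channels))[1L]
    stop(sprintf(
      "ragged rows: body row %d has %d columns, expected %d",
      bad, ncell[bad], length(channels)
    ), call. = FALSE)
  }
  vals <- suppressWarnings(as.numeric(unlist(cells, use.names = FALSE)))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1L]
    stop(sprintf("non-numeric value in body (row %d)",
                 (bad - 1L) %/% length(channels) + 1L), call. = FALSE)
  }
  samples <- matrix(vals, ncol = length(channels), byrow = TRUE)
  signal_record(samples, fs = fs, channel_names = channels, label = meta$label)
}

#' @rdname read_signal
#' @param record A [signal_record] to write.
#' @export
write_signal <- function(record, path) {
  assert_signal_record(record)
  m <- sig_matrix(record)
  header <- c(
    sprintf("# fs=%s", format(sig_fs(record), digits = 17)),
    sprintf("# channels=%s", paste(sig_channels(record), collapse = ","))
  )
  if (!is.null(sig_label(record))) {
    header <- c(header, sprintf("# label=%s", sig_label(record)))
  }
  body <- apply(m, 1L, function(r) paste(sprintf("%.17g", r), collapse = ","))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read and write labelled feature tables
#'
#' A labelled dataset is a plain CSV whose first column is `label`
#' (class strings) and whose remaining columns are numeric features. In R it
#' is a tibble with the same layout; feature order is preserved on
#' round-trip and non-finite feature values are rejected.
#'
#' @param path Path to a CSV feature table.
#' @return `read_dataset()` returns a tibble with a `label` column followed
#'   by numeric feature columns; `write_dataset()` invisibly returns `path`.
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"label" %in% names(df)) {
    stop("feature table is missing a 'label' column", call. = FALSE)
  }
  df <- df[, c("label", setdiff(names(df), "label")), drop = FALSE]
  ds <- tibble::as_tibble(df)
  ds$label <- as.character(ds$label)
  validate_dataset(ds)
  ds
}

#' @rdname read_dataset
#' @param ds A labelled dataset tibble (first column `label`).
#' @export
write_dataset <- function(ds, path) {
  validate_dataset(ds)
  utils::write.csv(as.data.frame(ds), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_dataset <- function(ds) {
  if (!is.data.frame(ds) || !"label" %in% names(ds)) {
    stop("a labelled dataset needs a 'label' column", call. = FALSE)
  }
  feats <- dataset_features(ds)
  if (ncol(feats) < 1L) stop("dataset has no feature columns", call. = FALSE)
  if (!all(vapply(feats, is.numeric, logical(1)))) {
    bad <- names(feats)[!vapply(feats, is.numeric, logical(1))][1L]
    stop("non-numeric feature column: ", bad, call. = FALSE)
  }
  if (!all(vapply(feats, function(v) all(is.finite(v)), logical(1)))) {
    bad <- names(feats)[!vapply(feats, function(v) all(is.finite(v)), logical(1))][1L]
    stop("non-finite values in feature column: ", bad, call. = FALSE)
  }
  invisible(ds)
}

# `trial` is an identifier column (trial provenance for leakage-free
# splitting), never a feature
dataset_features <- function(ds) {
  ds[, setdiff(names(ds), c("label", "trial")), drop = FALSE]
}
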