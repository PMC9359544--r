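#' Read a marker-trajectory file
#'
#' Reads a motion sample from CSV or TRC.  CSV files carry one header row of
#' `<marker>_x, <marker>_y, <marker>_z` columns; TRC is the usual
#' tab-separated format with five header rows and `Frame#`/`Time` columns.
#' Non-finite or empty fields become missing observations; because gaps have
#' whole-marker granularity, a missing coordinate masks all three
#' coordinates of that marker at that frame.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"csv"` or `"trc"`.
#' @return a `motion_sample` (values 0 and mask 0 at missing entries).
#' @seealso [write_motion()]
#' @export
read_motion <- function(path, format = c("auto", "csv", "trc")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("no such file: %s", path)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "csv", trc = "trc",
                     stopf("cannot infer format from extension of '%s'", path))
  }
  switch(format, csv = read_motion_csv(path), trc = read_motion_trc(path))
}

read_motion_csv <- function(path) {
  df <- tryCatch(
    utils::read.csv(path, check.names = FALSE),
    error = function(e) stopf("cannot parse '%s' as CSV: %s", path,
                              conditionMessage(e))
  )
  if (ncol(df) %% 3L != 0L) {
    stopf("'%s' has %d columns, not divisible by 3", path, ncol(df))
  }
  values <- as.matrix(df)
  if (!is.numeric(values)) {
    bad <- which(!vapply(df, is.numeric, logical(1)))[1]
    stopf("non-numeric column '%s' in '%s'", names(df)[bad], path)
  }
  marker_names <- unique(sub("_[xyz]$", "", names(df)))
  if (length(marker_names) != ncol(df) %/% 3L) marker_names <- NULL
  motion_sample(values, marker_names = marker_names)
}

read_motion_trc <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 6L) stopf("'%s' is too short to be a TRC file", path)
  meta_keys <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  meta_vals <- strsplit(lines[3], "\t", fixed = TRUE)[[1]]
  meta <- stats::setNames(as.list(meta_vals), meta_keys[seq_along(meta_vals)])
  frame_rate <- suppressWarnings(as.numeric(meta[["DataRate"]] %||% NA))
  if (!is.finite(frame_rate)) frame_rate <- NULL
  header <- strsplit(lines[4], "\t", fixed = TRUE)[[1]]
  marker_names <- header[-(1:2)]
  marker_names <- marker_names[marker_names != ""]
  if (length(marker_names) == 0L) {
    stopf("no marker names on line 4 of '%s'", path)
  }
  data_lines <- lines[-(1:5)]
  data_lines <- data_lines[trimws(data_lines) != ""]
  n <- length(marker_names)
  values <- matrix(NA_real_, length(data_lines), 3L * n)
  for (i in seq_along(data_lines)) {
    fields <- strsplit(data_lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 2L) {
      stopf("malformed TRC data record %d in '%s'", i, path)
    }
    coords <- suppressWarnings(as.numeric(fields[-(1:2)]))
    if (length(coords) > 3L * n) coords <- coords[seq_len(3L * n)]
    values[i, seq_along(coords)] <- coords
  }
  motion_sample(values, marker_names = marker_names, frame_rate = frame_rate)
}

#' Write a marker-trajectory file
#'
#' Inverse of [read_motion()]: missing entries (mask 0) are encoded as `NaN`
#' (CSV) or empty fields (TRC).  A round trip reproduces observed values to
#' numerical precision.
#'
#' @param sample a `motion_sample`.
#' @param path output file path.
#' @param format `"auto"` (by extension), `"csv"` or `"trc"`.
#' @param units coordinate units recorded in the TRC header (default mm).
#' @return `invisible(path)`.
#' @export
write_motion <- function(sample, path, format = c("auto", "csv", "trc"),
                         units = "mm") {
  stopifnot(inherits(sample, "motion_sample"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "csv", trc = "trc",
                     stopf("cannot infer format from extension of '%s'", path))
  }
  values <- sample$values
  values[sample$mask == 0] <- NA_real_
  if (format == "csv") {
    df <- as.data.frame(values)
    names(df) <- coordinate_names(sample$marker_names)
    utils::write.csv(df, path, row.names = FALSE, na = "NaN")
  } else {
    write_motion_trc(sample, values, path, units)
  }
  invisible(path)
}

write_motion_trc <- function(sample, values, path, units) {
  m <- n_frames(sample)
  n <- n_markers(sample)
  rate <- sample$frame_rate %||% 120
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("PathFileType\t4\t(X/Y/Z)\t%s", basename(path)), con)
  writeLines(paste(c("DataRate", "CameraRate", "NumFrames", "NumMarkers",
                     "Units", "OrigDataRate", "OrigDataStartFrame",
                     "OrigNumFrames"), collapse = "\t"), con)
  writeLines(paste(c(format(rate), format(rate), m, n, units, format(rate),
                     1, m), collapse = "\t"), con)
  name_row <- c("Frame#", "Time",
                as.vector(rbind(sample$marker_names, "", "")))
  writeLines(paste(name_row, collapse = "\t"), con)
  # per-marker X<i> Y<i> Z<i> labels
  coord_row <- c("", "", as.vector(vapply(seq_len(n), function(i)
    paste0(c("X", "Y", "Z"), i), character(3))))
  writeLines(paste(coord_row, collapse = "\t"), con)
  times <- (seq_len(m) - 1) / rate
  for (i in seq_len(m)) {
    fields <- formatC(values[i, ], format = "g", digits = 10)
    fields[!is.finite(values[i, ])] <- ""
    writeLines(paste(c(i, formatC(times[i], format = "g", digits = 10),
                       fields), collapse = "\t"), con)
  }
}
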