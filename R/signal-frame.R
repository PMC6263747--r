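#' Build a labeled triaxial signal frame
#'
#' A signal frame is a tibble with one accelerometer sample per row
#' (`user_id`, `activity`, `timestamp`, `x`, `y`, `z`) plus a sampling-rate
#' attribute `fs` in Hz. Timestamps must be nondecreasing within each user's
#' stream.
#'
#' @param data A data frame with columns `user_id`, `activity`, `timestamp`,
#'   `x`, `y`, `z`.
#' @param fs Sampling rate in Hz (> 0).
#' @return A tibble of class `signal_frame` with attribute `fs`.
#' @export
signal_frame <- function(data, fs) {
  needed <- c("user_id", "activity", "timestamp", "x", "y", "z")
  missing <- setdiff(needed, names(data))
  if (length(missing) > 0) {
    stop_parameter(paste0("signal frame is missing columns: ",
                          paste(missing, collapse = ", ")))
  }
  if (!is.numeric(fs) || length(fs) != 1 || !is.finite(fs) || fs <= 0) {
    stop_parameter("`fs` must be a single positive number (Hz)")
  }
  out <- tibble::as_tibble(data[needed])
  bad <- out |>
    dplyr::group_by(.data$user_id) |>
    dplyr::summarise(ok = !is.unsorted(.data$timestamp), .groups = "drop")
  if (any(!bad$ok)) {
    stop_parameter("timestamps must be nondecreasing within each user's stream")
  }
  attr(out, "fs") <- fs
  class(out) <- c("signal_frame", class(out))
  out
}

#' Sampling rate of a signal frame
#' @param frame A `signal_frame`.
#' @return Sampling rate in Hz.
#' @export
sampling_rate <- function(frame) {
  fs <- attr(frame, "fs")
  if (is.null(fs)) stop_parameter("object carries no `fs` attribute")
  fs
}

#' Read a raw accelerometer log
#'
#' Parses delimited text sensor logs in either the clean header dialect
#' (`user,activity,timestamp,x,y,z`) or the raw WISDM-style dialect (no
#' header, trailing `;` per line). Malformed lines are skipped and counted in
#' the attached load report.
#'
#' @param path Path to a delimited text file.
#' @param dialect `"clean"` (header line) or `"wisdm"` (headerless, trailing
#'   semicolon tolerated).
#' @param fs Sampling rate in Hz; when `NULL` it is inferred as the reciprocal
#'   of the median timestamp spacing, and spacing that varies by more than 20%
#'   from the median is rejected as irregular.
#' @return A [signal_frame()] whose `"load_report"` attribute records the
#'   numbers of parsed and skipped lines.
#' @export
read_har_csv <- function(path, dialect = c("clean", "wisdm"), fs = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_io(paste0("cannot read file: ", path))
  lines <- readLines(path, warn = FALSE)
  if (dialect == "clean" && length(lines) > 0) lines <- lines[-1]
  lines <- trimws(lines)
  if (dialect == "wisdm") lines <- sub(";\\s*$", "", lines)
  lines <- lines[nzchar(lines)]

  fields <- strsplit(lines, ",", fixed = TRUE)
  n_fields <- lengths(fields)
  keep <- n_fields == 6L
  rows <- fields[keep]
  skipped <- sum(!keep)

  if (length(rows) > 0) {
    m <- matrix(trimws(unlist(rows)), ncol = 6, byrow = TRUE)
    num <- apply(m[, 3:6, drop = FALSE], 2, function(col) {
      suppressWarnings(as.numeric(col))
    })
    num <- matrix(num, ncol = 4)
    ok <- rowSums(is.na(num)) == 0
    skipped <- skipped + sum(!ok)
    m <- m[ok, , drop = FALSE]
    num <- num[ok, , drop = FALSE]
  } else {
    m <- matrix(character(), ncol = 6)
    num <- matrix(numeric(), ncol = 4)
  }
  if (nrow(m) == 0) stop_insufficient("no parseable samples in input")

  data <- tibble::tibble(
    user_id = m[, 1], activity = m[, 2],
    timestamp = num[, 1], x = num[, 2], y = num[, 3], z = num[, 4]
  )
  if (is.null(fs)) {
    spacing <- unlist(tapply(data$timestamp, data$user_id,
                             function(t) diff(sort(t)), simplify = FALSE))
    spacing <- spacing[spacing > 0]
    if (length(spacing) == 0) {
      stop_parameter("cannot infer `fs`: no positive timestamp spacing")
    }
    med <- median(spacing)
    if (any(abs(spacing - med) > 0.2 * med)) {
      stop_parameter("irregular sampling: spacing varies > 20% from median; pass `fs` explicitly only for regular streams")
    }
    fs <- 1 / med
  }
  out <- signal_frame(data, fs)
  attr(out, "load_report") <- list(parsed = nrow(data), skipped = skipped)
  out
}

#' Write a signal frame in the clean dialect
#' @param frame A `signal_frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_har_csv <- function(frame, path) {
  utils::write.csv(
    as.data.frame(frame)[c("user_id", "activity", "timestamp", "x", "y", "z")],
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
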