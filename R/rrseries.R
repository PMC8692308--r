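#' Beat-to-beat RR interval series
#'
#' Lightweight container for a sequence of RR intervals (milliseconds) with
#' derived beat times and optional recording metadata. Beat times are the
#' cumulative time elapsed before each beat, in seconds, with the first beat
#' at t = 0.
#'
#' @param intervals numeric vector of RR intervals in milliseconds; all must
#'   be strictly positive and finite.
#' @param subject,condition,context optional metadata labels.
#' @return An object of class `rr_series`: a list with elements `intervals`,
#'   `beat_times` (seconds), `subject`, `condition`, `context`.
#' @examples
#' s <- rr_series(c(800, 810, 805))
#' s$beat_times  # 0.000 0.800 1.610
#' @export
rr_series <- function(intervals, subject = NA_character_,
                      condition = NA_character_, context = NA_character_) {
  intervals <- as.numeric(intervals)
  if (length(intervals) < 1L)
    stop("an RR series needs at least one interval", call. = FALSE)
  if (any(!is.finite(intervals)) || any(intervals <= 0))
    stop("all RR intervals must be finite and > 0 ms", call. = FALSE)
  structure(
    list(intervals = intervals,
         beat_times = c(0, cumsum(intervals[-length(intervals)])) / 1000,
         subject = as.character(subject),
         condition = as.character(condition),
         context = as.character(context)),
    class = "rr_series")
}

#' @export
print.rr_series <- function(x, ...) {
  n <- length(x$intervals)
  cat(sprintf("<rr_series> %d beats, %.1f s, mean RR %.1f ms\n",
              n, sum(x$intervals) / 1000, mean(x$intervals)))
  meta <- c(subject = x$subject, condition = x$condition, context = x$context)
  meta <- meta[!is.na(meta)]
  if (length(meta))
    cat("  ", paste(names(meta), meta, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' @export
length.rr_series <- function(x) length(x$intervals)

#' Write an RR series to a plain-text interval file
#'
#' The plain format is one interval value (ms) per line, UTF-8, with `#`
#' comment lines. The `"hrm"` format emulates the Polar HRM dialect: a
#' `[Params]` header section followed by a `[HRData]` section containing the
#' interval values, as produced by Polar heart-rate monitors in RR mode.
#'
#' @param series an [rr_series()] object.
#' @param path output file path.
#' @param format `"plain"` (default) or `"hrm"`.
#' @return `path`, invisibly.
#' @seealso [read_rr_file()]
#' @export
write_rr_file <- function(series, path, format = c("plain", "hrm")) {
  format <- match.arg(format)
  stopifnot(inherits(series, "rr_series"))
  vals <- formatC(series$intervals, format = "fg", digits = 15)
  meta <- sprintf("# subject=%s condition=%s context=%s",
                  series$subject, series$condition, series$context)
  lines <- switch(format,
    plain = c(meta, vals),
    hrm = c("[Params]", "Version=106", "Mode=3 0 0", "SMode=00000000",
            meta, "", "[HRData]", vals))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read an RR interval file
#'
#' Reads the plain one-value-per-line format written by [write_rr_file()],
#' skipping blank lines and `#` comments. If a `[HRData]` section marker is
#' present (Polar HRM dialect) only the lines after the marker are parsed and
#' everything before it is treated as header.
#'
#' @param path file path.
#' @param subject,condition,context optional metadata to attach; if missing,
#'   an attempt is made to recover them from a `# subject=... ` comment.
#' @return An [rr_series()].
#' @export
read_rr_file <- function(path, subject = NULL, condition = NULL,
                         context = NULL) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (length(lines) == 0L || all(!nzchar(trimws(lines))))
    stop("empty RR file: ", path, call. = FALSE)

  meta <- grep("^#\\s*subject=", lines, value = TRUE)
  if (length(meta) >= 1L) {
    kv <- regmatches(meta[1L],
                     gregexpr("(subject|condition|context)=\\S+", meta[1L]))[[1L]]
    kvs <- strsplit(kv, "=", fixed = TRUE)
    for (p in kvs) {
      if (is.null(subject) && p[1L] == "subject") subject <- p[2L]
      if (is.null(condition) && p[1L] == "condition") condition <- p[2L]
      if (is.null(context) && p[1L] == "context") context <- p[2L]
    }
  }

  hr <- grep("^\\[HRData\\]", trimws(lines))
  if (length(hr)) {
    offset <- hr[1L]
    lines <- lines[seq.int(offset + 1L, length.out = length(lines) - offset)]
  } else {
    offset <- 0L
  }

  keep <- nzchar(trimws(lines)) & !grepl("^\\s*#", lines)
  idx <- which(keep)
  if (!length(idx)) stop("no interval values found in ", path, call. = FALSE)
  vals <- suppressWarnings(as.numeric(trimws(lines[idx])))
  if (anyNA(vals)) {
    bad <- idx[which(is.na(vals))[1L]] + offset
    stop(sprintf("non-numeric RR value at line %d of %s", bad, path),
         call. = FALSE)
  }
  rr_series(vals,
            subject = if (is.null(subject)) NA else subject,
            condition = if (is.null(condition)) NA else condition,
            context = if (is.null(context)) NA else context)
}
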