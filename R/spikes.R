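#' Spike sequences
#'
#' A `spike_sequence` is an ordered set of event times on an observation
#' interval `(0, T]`: the universal currency between the Langevin simulator,
#' the synthetic generator and the statistics pipeline. Times are in seconds
#' (or dimensionless rescaled units after time-rescaling), strictly
#' increasing, and positive.
#'
#' @param times numeric vector of event times, strictly increasing, all in
#'   `(0, duration]`.
#' @param duration observation-interval length `T`. Defaults to the last
#'   event time.
#' @param label free-text provenance tag.
#' @return An object of class `spike_sequence` with elements `times`,
#'   `duration` and `label`.
#' @export
spike_sequence <- function(times, duration = NULL, label = "") {
  times <- as.numeric(times)
  if (length(times) == 0L && is.null(duration)) {
    stop("empty spike sequence: a duration must be supplied when there are no events")
  }
  if (is.null(duration)) duration <- times[length(times)]
  duration <- as.numeric(duration)
  if (length(duration) != 1L || !is.finite(duration) || duration <= 0) {
    stop("duration must be a single positive number")
  }
  if (length(times) > 0L) {
    if (anyNA(times) || any(!is.finite(times))) {
      stop("event times must be finite; offending entry ",
           which(!is.finite(times))[1L])
    }
    if (any(times <= 0)) {
      stop("event times must be positive; offending entry ",
           which(times <= 0)[1L])
    }
    if (is.unsorted(times, strictly = TRUE)) {
      bad <- which(diff(times) <= 0)[1L] + 1L
      stop("event times must be strictly increasing; offending entry ", bad)
    }
    if (times[length(times)] > duration) {
      stop("event times exceed the stated duration")
    }
  }
  structure(list(times = times, duration = duration, label = label),
            class = "spike_sequence")
}

#' @export
print.spike_sequence <- function(x, ...) {
  cat(sprintf("spike_sequence: %d events on (0, %.6g]%s\n",
              length(x$times), x$duration,
              if (nzchar(x$label)) paste0("  [", x$label, "]") else ""))
  invisible(x)
}

#' @export
length.spike_sequence <- function(x) length(x$times)

#' Read a spike sequence from a plain-text file
#'
#' Accepts one numeric event time per line (seconds), or a single-column CSV
#' with a header. Lines starting with `#` are comments; a comment of the form
#' `# duration=<T>` carries the observation-interval length.
#'
#' @param path file path.
#' @param duration optional observation length overriding any header value.
#' @return A [spike_sequence].
#' @export
read_spikes <- function(path, duration = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  is_comment <- grepl("^\\s*#", raw)
  hdr <- regmatches(raw, regexpr("#\\s*duration\\s*=\\s*[0-9.eE+-]+", raw))
  hdr <- unlist(hdr)
  if (is.null(duration) && length(hdr) > 0L) {
    duration <- as.numeric(sub(".*=\\s*", "", hdr[1L]))
  }
  body_idx <- which(!is_comment & nzchar(trimws(raw)))
  body <- trimws(raw[body_idx])
  # single-column CSV: take the first field of each line
  body <- vapply(strsplit(body, ","), function(f) trimws(f[1L]), character(1L))
  vals <- suppressWarnings(as.numeric(body))
  if (length(vals) > 0L && is.na(vals[1L])) {
    # header row of a CSV
    body_idx <- body_idx[-1L]
    vals <- vals[-1L]
  }
  if (anyNA(vals)) {
    stop("non-numeric event time at line ", body_idx[which(is.na(vals))[1L]],
         " of ", path)
  }
  if (length(vals) > 0L) {
    if (any(vals <= 0)) {
      stop("non-positive event time at line ", body_idx[which(vals <= 0)[1L]],
           " of ", path)
    }
    if (is.unsorted(vals, strictly = TRUE)) {
      bad <- which(diff(vals) <= 0)[1L] + 1L
      stop("non-monotone event time at line ", body_idx[bad], " of ", path)
    }
  }
  spike_sequence(vals, duration = duration, label = basename(path))
}

#' Write a spike sequence to a plain-text file
#'
#' Emits a `# duration=<T>` header followed by one event time per line at
#' full precision, so that [read_spikes()] reproduces the times bit-exactly.
#'
#' @param seq a [spike_sequence].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_spikes <- function(seq, path) {
  stopifnot(inherits(seq, "spike_sequence"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# duration=%.17g", seq$duration), con)
  if (length(seq$times)) writeLines(sprintf("%.17g", seq$times), con)
  invisible(path)
}

#' Interspike times
#'
#' Consecutive differences of the event times: the renewal variable of the
#' analysis.
#'
#' @param seq a [spike_sequence] with at least two events.
#' @return An object of class `interspike_times`: a numeric vector of
#'   `N - 1` positive values.
#' @export
interspike_times <- function(seq) {
  stopifnot(inherits(seq, "spike_sequence"))
  if (length(seq$times) < 2L) stop("insufficient events: need N >= 2")
  structure(diff(seq$times), class = "interspike_times")
}

#' Spike counts in fixed windows
#'
#' Partitions `[0, T)` into `M = floor(T / window)` full bins and counts the
#' events in each. The trailing partial bin is discarded (not rescaled) so
#' that all counts are identically distributed; events at a bin edge fall in
#' the right bin.
#'
#' @param seq a [spike_sequence].
#' @param window bin width, seconds (or rescaled units).
#' @return An object of class `count_series` with elements `window`,
#'   `counts` (length `M`) and `tail_count` (events in the discarded tail).
#' @export
spike_counts <- function(seq, window) {
  stopifnot(inherits(seq, "spike_sequence"))
  if (!is.numeric(window) || length(window) != 1L || window <= 0) {
    stop("window must be a positive number")
  }
  if (window >= seq$duration) stop("window exceeds duration")
  m <- floor(seq$duration / window)
  idx <- floor(seq$times / window) + 1L  # edge -> right bin
  counts <- tabulate(idx[idx <= m], nbins = m)
  structure(list(window = window, counts = counts,
                 tail_count = sum(idx > m)),
            class = "count_series")
}

#' @export
print.count_series <- function(x, ...) {
  cat(sprintf("count_series: %d windows of width %.4g (%d events in discarded tail)\n",
              length(x$counts), x$window, x$tail_count))
  invisible(x)
}
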