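#' Construct a fluorescence trace
#'
#' A `fluorescence_trace` holds the raw intensity time series recorded from
#' one cell in one channel, together with its sampling metadata. Times are
#' carried explicitly in seconds from the start of the recording; frame
#' indices are internal only, because acquisitions alternate between 2 s and
#' 3 s frame intervals.
#'
#' @param plant_id,cell_id Character labels identifying the plant and cell.
#' @param channel Either `"nuclear"` or `"cytosolic"`.
#' @param times Numeric vector of acquisition times in seconds, strictly
#'   increasing.
#' @param intensities Numeric vector of non-negative raw fluorescence values,
#'   same length as `times`.
#' @param frame_interval Nominal frame interval in seconds. If `NULL`
#'   (default) it is inferred as the median successive time difference.
#' @param position_um Optional axial distance of the cell from the root tip,
#'   in micrometres (`NA` if unknown).
#' @param rel_tol Relative tolerance on the deviation of successive time
#'   steps from `frame_interval`. Sampling that is non-uniform beyond this
#'   tolerance is rejected rather than resampled, since resampling would
#'   silently change gradient estimates.
#'
#' @return An object of class `fluorescence_trace`.
#' @seealso [read_traces()], [validate_sampling()], [detect_spikes()]
#' @export
fluorescence_trace <- function(plant_id, cell_id, channel, times, intensities,
                               frame_interval = NULL, position_um = NA_real_,
                               rel_tol = 0.01) {
  channel <- match.arg(channel, c("nuclear", "cytosolic"))
  times <- as.numeric(times)
  intensities <- as.numeric(intensities)
  if (length(times) != length(intensities)) {
    stop("`times` and `intensities` must have equal length", call. = FALSE)
  }
  if (length(times) == 0L) {
    stop("trace must contain at least one frame", call. = FALSE)
  }
  if (anyNA(times) || anyNA(intensities)) {
    stop("times and intensities must not contain NA", call. = FALSE)
  }
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop(sprintf("times must be strictly increasing in trace (%s, %s, %s)",
                 plant_id, cell_id, channel), call. = FALSE)
  }
  if (any(intensities < 0)) {
    stop("intensities must be non-negative", call. = FALSE)
  }
  if (is.null(frame_interval)) {
    if (length(times) < 2L) {
      stop("frame_interval must be given for a single-frame trace",
           call. = FALSE)
    }
    frame_interval <- stats::median(diff(times))
  }
  if (!is.numeric(frame_interval) || frame_interval <= 0) {
    stop("frame_interval must be a positive number", call. = FALSE)
  }
  x <- structure(
    list(plant_id = as.character(plant_id),
         cell_id = as.character(cell_id),
         channel = channel,
         times = times,
         intensities = intensities,
         frame_interval = as.numeric(frame_interval),
         position_um = as.numeric(position_um)),
    class = "fluorescence_trace")
  rep_ <- validate_sampling(x, rel_tol = rel_tol)
  if (!rep_$pass) {
    stop(sprintf(
      "non-uniform sampling in trace (%s, %s, %s): %d step(s) deviate from %g s by more than %g%%",
      plant_id, cell_id, channel, length(rep_$flagged), frame_interval,
      100 * rel_tol), call. = FALSE)
  }
  x
}

#' @export
print.fluorescence_trace <- function(x, ...) {
  cat(sprintf("<fluorescence_trace> plant %s, cell %s, %s channel\n",
              x$plant_id, x$cell_id, x$channel))
  cat(sprintf("  %d frames every %g s (%.1f s total)",
              length(x$times), x$frame_interval,
              max(x$times) - min(x$times)))
  if (!is.na(x$position_um)) cat(sprintf(", %g um from tip", x$position_um))
  cat("\n")
  invisible(x)
}

#' @export
length.fluorescence_trace <- function(x) length(x$times)

trace_key <- function(plant_id, cell_id, channel) {
  paste(plant_id, cell_id, channel, sep = "|")
}

#' Bundle fluorescence traces into a collection
#'
#' @param traces A list of [fluorescence_trace] objects with unique
#'   (plant, cell, channel) keys.
#' @param recording_duration_s Duration of the recording session in seconds;
#'   defaults to the largest time observed across traces.
#'
#' @return An object of class `trace_collection`; traces are stored in a
#'   named list keyed by `"plant|cell|channel"`.
#' @export
trace_collection <- function(traces, recording_duration_s = NULL) {
  stopifnot(is.list(traces))
  if (!all(vapply(traces, inherits, logical(1), "fluorescence_trace"))) {
    stop("all elements must be fluorescence_trace objects", call. = FALSE)
  }
  keys <- vapply(traces, function(tr)
    trace_key(tr$plant_id, tr$cell_id, tr$channel), character(1))
  if (anyDuplicated(keys)) {
    stop(sprintf("duplicate trace key(s): %s",
                 paste(unique(keys[duplicated(keys)]), collapse = ", ")),
         call. = FALSE)
  }
  names(traces) <- keys
  tmax <- if (length(traces)) max(vapply(traces, function(tr)
    max(tr$times), numeric(1))) else 0
  if (is.null(recording_duration_s)) recording_duration_s <- tmax
  if (recording_duration_s < tmax) {
    stop("recording_duration_s must cover the latest observed time",
         call. = FALSE)
  }
  structure(list(traces = traces,
                 recording_duration_s = as.numeric(recording_duration_s)),
            class = "trace_collection")
}

#' @export
print.trace_collection <- function(x, ...) {
  cat(sprintf("<trace_collection> %d trace(s), %.1f s recording\n",
              length(x$traces), x$recording_duration_s))
  invisible(x)
}

#' @export
length.trace_collection <- function(x) length(x$traces)

#' Check a trace against its nominal sampling grid
#'
#' The boundary detector differentiates the detrended signal on the
#' assumption of a uniform sampling grid; this report flags time steps whose
#' deviation from the nominal frame interval exceeds a relative tolerance.
#'
#' @param trace A [fluorescence_trace].
#' @param rel_tol Relative tolerance (fraction of `frame_interval`).
#'
#' @return A list with elements `pass` (logical), `flagged` (integer indices
#'   of offending steps, where step `i` joins frames `i` and `i + 1`) and
#'   `single_frame` (logical; `TRUE` for the degenerate one-frame trace,
#'   which passes with a warning flag).
#' @export
validate_sampling <- function(trace, rel_tol = 0.01) {
  stopifnot(inherits(trace, "fluorescence_trace"))
  if (length(trace$times) < 2L) {
    return(list(pass = TRUE, flagged = integer(0), single_frame = TRUE))
  }
  dt <- diff(trace$times)
  bad <- which(abs(dt - trace$frame_interval) >
                 rel_tol * trace$frame_interval)
  list(pass = length(bad) == 0L, flagged = bad, single_frame = FALSE)
}

.trace_csv_cols <- c("time_s", "plant_id", "cell_id", "channel", "intensity")

#' Read fluorescence traces from a long-format CSV file
#'
#' The canonical exchange format is long (tidy) CSV with one row per frame
#' per cell per channel and a mandatory header:
#' `time_s, plant_id, cell_id, channel, intensity` with an optional
#' `position_um` column (blank allowed). Rows are grouped by
#' (plant, cell, channel), sorted by time within each group, and the frame
#' interval of each trace is inferred as the median successive time
#' difference.
#'
#' @param path Path to the CSV file.
#' @param dialect Input dialect; only `"long_csv"` is supported.
#' @param rel_tol Sampling-uniformity tolerance passed to
#'   [fluorescence_trace()].
#'
#' @return A [trace_collection].
#' @export
read_traces <- function(path, dialect = "long_csv", rel_tol = 0.01) {
  dialect <- match.arg(dialect, "long_csv")
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.trace_csv_cols, names(df))
  if (length(missing_cols)) {
    stop(sprintf("trace CSV is missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  bad_chan <- setdiff(unique(df$channel), c("nuclear", "cytosolic"))
  if (length(bad_chan)) {
    stop(sprintf("unknown channel label(s): %s",
                 paste(bad_chan, collapse = ", ")), call. = FALSE)
  }
  has_pos <- "position_um" %in% names(df)
  key <- trace_key(df$plant_id, df$cell_id, df$channel)
  traces <- lapply(split(seq_len(nrow(df)), key), function(idx) {
    g <- df[idx, , drop = FALSE]
    g <- g[order(g$time_s), , drop = FALSE]
    if (anyDuplicated(g$time_s)) {
      stop(sprintf("duplicated time point(s) in trace group (%s, %s, %s)",
                   g$plant_id[1], g$cell_id[1], g$channel[1]), call. = FALSE)
    }
    fluorescence_trace(
      plant_id = g$plant_id[1], cell_id = g$cell_id[1],
      channel = g$channel[1], times = g$time_s,
      intensities = g$intensity,
      position_um = if (has_pos) g$position_um[1] else NA_real_,
      rel_tol = rel_tol)
  })
  trace_collection(unname(traces))
}

#' Write a trace collection to long-format CSV
#'
#' @param collection A [trace_collection].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(collection, path) {
  stopifnot(inherits(collection, "trace_collection"))
  rows <- lapply(collection$traces, function(tr) {
    data.frame(time_s = tr$times,
               plant_id = tr$plant_id,
               cell_id = tr$cell_id,
               channel = tr$channel,
               intensity = tr$intensities,
               position_um = tr$position_um,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(df)) {
    df <- data.frame(time_s = numeric(0), plant_id = character(0),
                     cell_id = character(0), channel = character(0),
                     intensity = numeric(0), position_um = numeric(0))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Extract per-cell positions from a trace collection
#'
#' @param collection A [trace_collection].
#' @return A data frame with columns `plant_id`, `cell_id`, `position_um`
#'   (one row per cell; positions are shared across channels).
#' @export
trace_positions <- function(collection) {
  stopifnot(inherits(collection, "trace_collection"))
  rows <- lapply(collection$traces, function(tr)
    data.frame(plant_id = tr$plant_id, cell_id = tr$cell_id,
               position_um = tr$position_um, stringsAsFactors = FALSE))
  df <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(df)) {
    return(data.frame(plant_id = character(0), cell_id = character(0),
                      position_um = numeric(0)))
  }
  unique(df)
}

.spike_call_cols <- c("plant_id", "cell_id", "channel", "t_on_s", "t_peak_s",
                      "t_off_s", "rise_s", "fall_s", "duration_s",
                      "amplitude_dff", "censored")

#' Create an empty spike-call table
#'
#' @return A zero-row data frame of class `spike_call_table` with the
#'   canonical call schema.
#' @export
empty_spike_calls <- function() {
  df <- data.frame(plant_id = character(0), cell_id = character(0),
                   channel = character(0), t_on_s = numeric(0),
                   t_peak_s = numeric(0), t_off_s = numeric(0),
                   rise_s = numeric(0), fall_s = numeric(0),
                   duration_s = numeric(0), amplitude_dff = numeric(0),
                   censored = logical(0), stringsAsFactors = FALSE)
  class(df) <- c("spike_call_table", "data.frame")
  df
}

as_spike_call_table <- function(df) {
  missing_cols <- setdiff(.spike_call_cols, names(df))
  if (length(missing_cols)) {
    stop(sprintf("spike-call table is missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  df <- df[, .spike_call_cols, drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("spike_call_table", "data.frame")
  df
}

#' Write spike calls to CSV
#'
#' One row per detected call; the `censored` flag is serialised as
#' `true`/`false`. [read_spike_calls()] inverts the operation exactly.
#'
#' @param table A spike-call table (as returned by [spike_calls()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spike_calls <- function(table, path) {
  df <- as_spike_call_table(as.data.frame(table))
  out <- as.data.frame(df)
  out$censored <- ifelse(out$censored, "true", "false")
  con <- tryCatch(file(path, "w"), error = function(e)
    stop(sprintf("cannot open '%s' for writing", path), call. = FALSE))
  on.exit(close(con))
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read spike calls from CSV
#'
#' @param path Path to a CSV written by [write_spike_calls()].
#' @return A `spike_call_table` data frame.
#' @export
read_spike_calls <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(censored = "character"))
  if (nrow(df) == 0) {
    out <- empty_spike_calls()
    missing_cols <- setdiff(.spike_call_cols, names(df))
    if (length(missing_cols)) {
      stop(sprintf("spike-call CSV is missing column(s): %s",
                   paste(missing_cols, collapse = ", ")), call. = FALSE)
    }
    return(out)
  }
  df$censored <- df$censored == "true"
  for (col in c("plant_id", "cell_id", "channel")) {
    df[[col]] <- as.character(df[[col]])
  }
  as_spike_call_table(df)
}
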