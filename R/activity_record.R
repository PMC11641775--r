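#' Construct a binned wheel-running activity record
#'
#' An activity record holds the per-bin wheel revolution counts of one animal,
#' the sampling interval, the record start time and the light schedule the
#' animal was housed under. Counts must be complete: gaps have to be zero
#' filled explicitly before construction (the readers do this on request).
#'
#' @param counts Numeric vector of non-negative per-bin counts.
#' @param bin_minutes Width of one bin in minutes (> 0).
#' @param start_time Record start, `POSIXct` or an ISO-8601 string (UTC).
#' @param schedule A [light_schedule()].
#' @param animal_id Identifier carried through to output tables.
#' @return An object of class `activity_record`.
#' @examples
#' sched <- light_schedule("LD12_12")
#' rec <- activity_record(rpois(1440, 2), 1, "2024-01-01 08:00:00", sched, "m1")
#' rec
#' @export
activity_record <- function(counts, bin_minutes, start_time, schedule,
                            animal_id = "animal") {
  if (length(counts) == 0L) stop("'counts' must be non-empty")
  if (anyNA(counts)) stop("'counts' contains missing bins; zero-fill gaps explicitly")
  if (any(counts < 0)) stop("'counts' must be non-negative")
  stopifnot_scalar(bin_minutes, "bin_minutes", lower = 1e-9)
  if (!inherits(schedule, "light_schedule")) stop("'schedule' must be a light_schedule")
  if (!inherits(start_time, "POSIXct"))
    start_time <- as.POSIXct(start_time, tz = "UTC")
  if (is.na(start_time)) stop("unparseable 'start_time'")
  structure(
    list(animal_id = as.character(animal_id),
         start_time = start_time,
         bin_minutes = bin_minutes,
         counts = as.numeric(counts),
         schedule = schedule),
    class = "activity_record")
}

#' @export
print.activity_record <- function(x, ...) {
  cat(sprintf("Activity record '%s': %d bins of %g min (%.1f h) under %s\n",
              x$animal_id, length(x$counts), x$bin_minutes,
              record_duration_h(x), x$schedule$regime))
  cat(sprintf("  start %s, total %g revolutions\n",
              format(x$start_time, "%Y-%m-%d %H:%M", tz = "UTC"), sum(x$counts)))
  invisible(x)
}

#' Record duration in hours
#' @param record An [activity_record()].
#' @return Hours spanned by the record.
#' @export
record_duration_h <- function(record) {
  length(record$counts) * record$bin_minutes / 60
}

# Bin start times in hours from record start.
bin_start_h <- function(record) {
  (seq_along(record$counts) - 1) * record$bin_minutes / 60
}

#' Extract a time window from a record
#'
#' @param record An [activity_record()].
#' @param from_h,to_h Window in hours from record start (half-open,
#'   `[from_h, to_h)`); `to_h = Inf` keeps everything to the end.
#' @return A shorter `activity_record` whose start time is shifted accordingly.
#' @export
window_record <- function(record, from_h = 0, to_h = Inf) {
  t0 <- bin_start_h(record)
  keep <- t0 >= from_h - 1e-9 & t0 < to_h - 1e-9
  if (!any(keep)) stop("empty window")
  activity_record(record$counts[keep], record$bin_minutes,
                  record$start_time + from_h * 3600,
                  record$schedule, record$animal_id)
}

#' Re-bin an activity record to a coarser bin
#'
#' Counts are summed within consecutive windows of the target width; the total
#' is conserved (a trailing partial window is kept as a final, shorter bin's
#' sum).
#'
#' @param record An [activity_record()].
#' @param target_bin_minutes Target bin width; must be an integer multiple of
#'   the source bin.
#' @return A new `activity_record` at the target bin width.
#' @examples
#' sched <- light_schedule("DD")
#' r <- activity_record(rep(1, 6), 1, "2024-01-01", sched)
#' bin_activity(r, 6)$counts  # 6
#' @export
bin_activity <- function(record, target_bin_minutes) {
  f <- target_bin_minutes / record$bin_minutes
  if (abs(f - round(f)) > 1e-9 || f < 1)
    stop("target bin must be an integer multiple of the source bin")
  f <- as.integer(round(f))
  if (f == 1L) return(record)
  idx <- (seq_along(record$counts) - 1L) %/% f
  counts <- as.numeric(tapply(record$counts, idx, sum))
  activity_record(counts, target_bin_minutes, record$start_time,
                  record$schedule, record$animal_id)
}

#' Write / read an activity record as timestamped CSV
#'
#' Two columns: `timestamp` (ISO-8601, UTC, one row per bin start) and
#' `counts`.
#'
#' @param record An [activity_record()].
#' @param path File path.
#' @param schedule Light schedule to attach on read.
#' @param animal_id Identifier to attach on read.
#' @param zero_fill On read, fill interior gaps in the timestamp grid with
#'   zero-count bins; if `FALSE` (default) gaps are an error.
#' @return `write_activity_csv` returns `path` invisibly;
#'   `read_activity_csv` returns an `activity_record`.
#' @export
write_activity_csv <- function(record, path) {
  ts <- record$start_time + (seq_along(record$counts) - 1) * record$bin_minutes * 60
  utils::write.csv(
    data.frame(timestamp = format(ts, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
               counts = record$counts),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_activity_csv
#' @export
read_activity_csv <- function(path, schedule, animal_id = "animal",
                              zero_fill = FALSE) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("timestamp", "counts") %in% names(d)))
    stop("CSV must have columns 'timestamp' and 'counts'")
  ts <- as.POSIXct(d$timestamp, tz = "UTC", format = "%Y-%m-%dT%H:%M:%S")
  if (anyNA(ts)) stop("unparseable timestamps")
  dt <- as.numeric(diff(ts), units = "mins")
  bin <- min(dt)
  if (any(abs(dt - bin) > 1e-6)) {
    if (!zero_fill) stop("gaps in timestamp grid; pass zero_fill = TRUE to fill them")
    grid <- seq(ts[1], ts[length(ts)], by = bin * 60)
    counts <- numeric(length(grid))
    counts[match(round(as.numeric(ts)), round(as.numeric(grid)))] <- d$counts
  } else counts <- d$counts
  activity_record(counts, bin, ts[1], schedule, animal_id)
}

#' Write / read the per-epoch single-column text dialect
#'
#' A minimal plain-text dialect used by wheel-running counters: one header line
#' `# id=<id> start=<ISO-8601> epoch_min=<minutes>` followed by one count per
#' line.
#'
#' @inheritParams write_activity_csv
#' @return `write_awd` returns `path` invisibly; `read_awd` an
#'   `activity_record`.
#' @export
write_awd <- function(record, path) {
  header <- sprintf("# id=%s start=%s epoch_min=%g", record$animal_id,
                    format(record$start_time, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
                    record$bin_minutes)
  writeLines(c(header, format(record$counts, trim = TRUE, scientific = FALSE)), path)
  invisible(path)
}

#' @rdname write_awd
#' @export
read_awd <- function(path, schedule) {
  lines <- readLines(path)
  h <- lines[1]
  m <- regmatches(h, regexec("id=(\\S+) start=(\\S+) epoch_min=([0-9.]+)", h))[[1]]
  if (length(m) != 4) stop("malformed header line")
  activity_record(as.numeric(lines[-1]), as.numeric(m[4]),
                  as.POSIXct(m[3], tz = "UTC", format = "%Y-%m-%dT%H:%M:%S"),
                  schedule, m[2])
}
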