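#' Construct a pen recording
#'
#' A pen recording is one participant's one-stroke tracing of one guide
#' shape: an ordered series of samples `(t, x, y, pressure)` plus metadata.
#' Timestamps are stored relative to first pen contact (`t[1] == 0` after
#' construction), so the drawing time equals the last timestamp.
#' Coordinates are screen points in the tablet convention (origin top-left,
#' x rightward, y downward); pressure is in device units on
#' `[0, pressure_max()]`.
#'
#' @param t Numeric vector of timestamps in seconds, strictly increasing.
#' @param x,y Numeric vectors of screen coordinates (points).
#' @param pressure Numeric vector of stylus pressures (device units).
#' @param participant_id Opaque participant identifier.
#' @param shape One of `"spiral"`, `"square"`, `"triangular"`.
#' @param group Optional group label, `"CM"` or `"nonCM"`; `NULL` for
#'   unlabeled screening input.
#' @param nominal_rate Nominal sampling rate in Hz (default 120, the tablet
#'   frame rate).
#' @param meta Optional named list of extra metadata (e.g. `age`, `sex`,
#'   `joa_score`, `seed`), carried through file round-trips.
#'
#' @return An object of class `pen_recording`: a list with elements
#'   `samples` (data.frame `t,x,y,pressure`), `participant_id`, `shape`,
#'   `group`, `nominal_rate`, `meta`.
#' @export
#' @examples
#' rec <- pen_recording(t = (0:3) / 120, x = 0:3, y = rep(0, 4),
#'                      pressure = rep(1, 4), participant_id = "P1",
#'                      shape = "spiral")
#' drawing_time(rec)
pen_recording <- function(t, x, y, pressure, participant_id, shape,
                          group = NULL, nominal_rate = DEVICE_RATE,
                          meta = list()) {
  n <- length(t)
  if (n < 2) stop_validation("recording must have at least 2 samples")
  if (length(x) != n || length(y) != n || length(pressure) != n)
    stop_validation("t, x, y, pressure must have equal length")
  if (!all(is.finite(t)) || !all(is.finite(x)) || !all(is.finite(y)) ||
      !all(is.finite(pressure)))
    stop_validation("recording contains non-finite values")
  if (any(diff(t) <= 0)) {
    bad <- which(diff(t) <= 0)[1] + 1
    stop_validation("timestamps not strictly increasing at row %d", bad)
  }
  if (any(pressure < 0 | pressure > pressure_max())) {
    bad <- which(pressure < 0 | pressure > pressure_max())[1]
    stop_validation(
      "pressure out of device range [0, %g] at row %d (value %g)",
      pressure_max(), bad, pressure[bad])
  }
  shape <- match.arg(shape, SHAPES)
  if (!is.null(group)) group <- match.arg(group, c("CM", "nonCM"))
  structure(
    list(samples = data.frame(t = t - t[1], x = x, y = y,
                              pressure = pressure),
         participant_id = as.character(participant_id), shape = shape,
         group = group, nominal_rate = nominal_rate, meta = meta),
    class = "pen_recording")
}

#' @export
print.pen_recording <- function(x, ...) {
  cat(sprintf("<pen_recording> %s / %s%s: %d samples, %.3f s, rate %g Hz\n",
              x$participant_id, x$shape,
              if (is.null(x$group)) "" else paste0(" [", x$group, "]"),
              nrow(x$samples), drawing_time(x), x$nominal_rate))
  invisible(x)
}

#' Read a pen recording from a CSV file and its JSON sidecar
#'
#' The recording CSV has header `t,x,y,pressure`, one row per sample, UTF-8,
#' `.` decimal separator. Metadata lives in a sidecar JSON with the same
#' basename and extension `.meta.json` (fields `participant_id`, `shape`,
#' optional `group`, `age`, `sex`, `joa_score`, `nominal_rate`, `seed`).
#'
#' @param path Path to the recording CSV.
#' @return A validated [pen_recording()].
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop_validation("no such recording file: %s", path)
  df <- utils::read.csv(path, colClasses = "numeric")
  need <- c("t", "x", "y", "pressure")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop_validation("%s: missing column(s) %s", path,
                    paste(missing_cols, collapse = ", "))
  meta_path <- sidecar_path(path)
  meta <- if (file.exists(meta_path))
    jsonlite::read_json(meta_path, simplifyVector = TRUE) else list()
  rec <- tryCatch(
    pen_recording(df$t, df$x, df$y, df$pressure,
                  participant_id = meta$participant_id %||% basename(path),
                  shape = meta$shape %||% "spiral",
                  group = meta$group,
                  nominal_rate = meta$nominal_rate %||% DEVICE_RATE,
                  meta = meta[setdiff(names(meta),
                                      c("participant_id", "shape", "group",
                                        "nominal_rate"))]),
    error = function(e) stop_validation("%s: %s", path, conditionMessage(e)))
  rec
}

sidecar_path <- function(path) sub("\\.csv$", ".meta.json", path)

#' Write a pen recording to CSV plus JSON sidecar
#'
#' Numeric fields are written with 12 significant digits so that
#' `read_recording(write_recording(rec, p))` reproduces `rec` to text
#' precision. The sidecar omits `group` when the recording is unlabeled.
#'
#' @param rec A [pen_recording()].
#' @param path Destination CSV path (sidecar written alongside).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "pen_recording"))
  s <- rec$samples
  out <- data.frame(t = sprintf("%.12g", s$t), x = sprintf("%.12g", s$x),
                    y = sprintf("%.12g", s$y),
                    pressure = sprintf("%.12g", s$pressure))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  meta <- c(list(participant_id = rec$participant_id, shape = rec$shape),
            if (!is.null(rec$group)) list(group = rec$group),
            list(nominal_rate = rec$nominal_rate), rec$meta)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Validate a pen recording
#'
#' Reports violated invariants without throwing: strict timestamp
#' monotonicity, pressure within the device range, minimum sample count, and
#' the single-stroke rule — an inter-sample gap larger than `gap_tolerance`
#' flags the recording as multi-stroke (a likely pen lift).
#'
#' @param rec A `pen_recording` (or a bare list with a `samples` element,
#'   so that recordings that would fail construction can still be examined).
#' @param gap_tolerance Maximum allowed inter-sample gap in seconds.
#'   Default: 3 nominal sample periods, tolerating occasional dropped
#'   frames at 120 fps while catching pen lifts.
#' @return A list with `ok` (logical), `multi_stroke` (logical) and
#'   `violations` (character vector naming each violated rule).
#' @export
validate_recording <- function(rec, gap_tolerance = NULL) {
  s <- rec$samples
  rate <- rec$nominal_rate %||% DEVICE_RATE
  if (is.null(gap_tolerance)) gap_tolerance <- 3 / rate
  v <- character()
  if (nrow(s) < 2) v <- c(v, "fewer than 2 samples")
  if (nrow(s) >= 2 && any(diff(s$t) <= 0))
    v <- c(v, sprintf("timestamps not strictly increasing at row %d",
                      which(diff(s$t) <= 0)[1] + 1))
  bad_p <- which(s$pressure < 0 | s$pressure > pressure_max())
  if (length(bad_p))
    v <- c(v, sprintf("pressure out of range at row %d", bad_p[1]))
  if (any(!is.finite(as.matrix(s)))) v <- c(v, "non-finite values")
  multi <- nrow(s) >= 2 && !any(diff(s$t) <= 0) &&
    any(diff(s$t) > gap_tolerance)
  if (multi) v <- c(v, sprintf("inter-sample gap > %g s (multi-stroke?)",
                               gap_tolerance))
  list(ok = length(v) == 0, multi_stroke = isTRUE(multi), violations = v)
}

#' Keep the longest contiguous stroke of a recording
#'
#' Splits the sample series at gaps larger than `gap_tolerance` and returns
#' the longest contiguous segment as a new recording (ingestion policy for
#' real-world multi-stroke captures; simulated cohorts are single-stroke).
#'
#' @inheritParams validate_recording
#' @return A `pen_recording` containing only the longest segment.
#' @export
keep_longest_stroke <- function(rec, gap_tolerance = NULL) {
  s <- rec$samples
  rate <- rec$nominal_rate %||% DEVICE_RATE
  if (is.null(gap_tolerance)) gap_tolerance <- 3 / rate
  brk <- c(0, which(diff(s$t) > gap_tolerance), nrow(s))
  lens <- diff(brk)
  k <- which.max(lens)
  idx <- (brk[k] + 1):brk[k + 1]
  pen_recording(s$t[idx], s$x[idx], s$y[idx], s$pressure[idx],
                rec$participant_id, rec$shape, rec$group, rec$nominal_rate,
                rec$meta)
}

#' Write a cohort to a directory of recording files plus manifest
#'
#' One CSV + sidecar pair per recording (named
#' `<participant>_<shape>.csv`), a `manifest.csv` with one row per
#' recording (relative path + metadata), and a `participants.csv` with the
#' per-participant table.
#'
#' @param cohort A `cm_cohort` from [simulate_cohort()].
#' @param dir Destination directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cm_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cohort$recordings, function(rec) {
    fn <- sprintf("%s_%s.csv", rec$participant_id, rec$shape)
    write_recording(rec, file.path(dir, fn))
    data.frame(path = fn, participant_id = rec$participant_id,
               shape = rec$shape,
               group = rec$group %||% NA_character_,
               n_samples = nrow(rec$samples),
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$participants, file.path(dir, "participants.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Cohort directory containing `manifest.csv`.
#' @return A `cm_cohort` object.
#' @export
read_cohort <- function(dir) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf)) stop_validation("no manifest.csv in %s", dir)
  manifest <- utils::read.csv(mf, stringsAsFactors = FALSE)
  recs <- lapply(manifest$path, function(p)
    read_recording(file.path(dir, p)))
  pf <- file.path(dir, "participants.csv")
  participants <- if (file.exists(pf))
    utils::read.csv(pf, stringsAsFactors = FALSE) else NULL
  new_cohort(recs, participants)
}

new_cohort <- function(recordings, participants) {
  key <- vapply(recordings, function(r)
    paste(r$participant_id, r$shape), character(1))
  if (anyDuplicated(key))
    stop_validation("duplicate (participant, shape) pair: %s",
                    key[anyDuplicated(key)][1])
  if (!is.null(participants) && "joa_score" %in% names(participants)) {
    joa <- participants$joa_score[participants$group == "CM"]
    joa <- joa[!is.na(joa)]
    if (any(joa < 0 | joa > 17))
      stop_validation("JOA score outside [0, 17]")
  }
  structure(list(recordings = recordings, participants = participants),
            class = "cm_cohort")
}

#' @export
print.cm_cohort <- function(x, ...) {
  grp <- table(vapply(x$recordings, function(r) r$group %||% "unlabeled",
                      character(1)))
  cat(sprintf("<cm_cohort> %d recordings (%s), %d participants\n",
              length(x$recordings),
              paste(names(grp), grp, sep = ": ", collapse = ", "),
              if (is.null(x$participants)) NA_integer_
              else nrow(x$participants)))
  invisible(x)
}
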