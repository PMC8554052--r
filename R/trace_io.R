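#' Construct a per-fly position trace
#'
#' A `position_trace` holds one fly's 1-D coordinate series sampled once per
#' second, with its time origin expressed as an offset from ZT 0 (lights-on).
#' Coordinates are pixels along the tube axis, 0 at the cotton end and
#' increasing toward the food end. Dropped frames are carried as missing
#' samples (`NA` position plus a `TRUE` entry in `missing_mask`); they are
#' never interpolated at ingest, so downstream event segmentation decides
#' their semantics.
#'
#' @param positions numeric vector of coordinates (pixels), `NA` for dropped
#'   frames.
#' @param fly_id character scalar identifying the fly.
#' @param start_zt offset in seconds of the first sample from ZT 0 of day 1.
#' @param sample_rate samples per second; all regular-recording analysis
#'   paths require 1.
#' @param missing_mask logical vector marking dropped frames; defaults to
#'   `is.na(positions)`.
#' @param excluded_days integer vector of day indices (1-based) excluded
#'   from analysis (see [drop_zeroed_day_traces()]).
#' @return An object of class `position_trace`.
#' @export
position_trace <- function(positions, fly_id = "fly", start_zt = 0L,
                           sample_rate = 1L,
                           missing_mask = is.na(positions),
                           excluded_days = integer(0)) {
  positions <- as.numeric(positions)
  if (length(missing_mask) != length(positions)) {
    stop("missing_mask must have the same length as positions")
  }
  if (!identical(as.integer(sample_rate), 1L)) {
    stop("only 1 sample per second is supported for regular-recording analysis")
  }
  if (any(is.na(positions) & !missing_mask)) {
    stop("non-missing positions must be numeric; found NA outside missing_mask")
  }
  positions[missing_mask] <- NA_real_
  structure(
    list(
      fly_id = as.character(fly_id),
      positions = positions,
      start_zt = as.integer(start_zt),
      sample_rate = 1L,
      missing_mask = as.logical(missing_mask),
      excluded_days = as.integer(excluded_days)
    ),
    class = "position_trace"
  )
}

#' @export
print.position_trace <- function(x, ...) {
  cat(sprintf(
    "<position_trace> fly %s: %d samples (%.1f h), %d missing, start ZT %+d s\n",
    x$fly_id, length(x$positions), length(x$positions) / 3600,
    sum(x$missing_mask), x$start_zt
  ))
  if (length(x$excluded_days)) {
    cat("  excluded days:", paste(x$excluded_days, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Construct a plate recording
#'
#' One recording plate carries up to 18 tubes, each with one fly. All traces
#' on a plate must share the same start offset and duration.
#'
#' @param traces list of [position_trace()] objects (at most 18).
#' @param tube_length_px tube length in pixels.
#' @param light_schedule character vector, one `"LD"` or `"DD"` flag per
#'   recording day (recycled to the number of full days if length 1).
#' @return An object of class `plate_recording`.
#' @export
plate_recording <- function(traces, tube_length_px = 260, light_schedule = "LD") {
  if (length(traces) == 0) stop("a plate recording needs at least one trace")
  if (length(traces) > PLATE_CAPACITY) {
    stop(sprintf("plate capacity exceeded: %d traces (max %d)",
                 length(traces), PLATE_CAPACITY))
  }
  ok <- vapply(traces, inherits, logical(1), what = "position_trace")
  if (!all(ok)) stop("all elements of traces must be position_trace objects")
  n <- vapply(traces, function(tr) length(tr$positions), integer(1))
  if (length(unique(n)) != 1) {
    bad <- traces[[which(n != n[1])[1]]]$fly_id
    stop(sprintf("traces must share one duration; fly %s differs", bad))
  }
  zt <- vapply(traces, function(tr) tr$start_zt, integer(1))
  if (length(unique(zt)) != 1) {
    stop("all traces on a plate must share start_zt alignment")
  }
  bad_range <- vapply(traces, function(tr) {
    p <- tr$positions[!tr$missing_mask]
    length(p) && (min(p) < 0 || max(p) > tube_length_px)
  }, logical(1))
  if (any(bad_range)) {
    stop(sprintf("fly %s has positions outside [0, tube_length_px]",
                 traces[[which(bad_range)[1]]]$fly_id))
  }
  if (!all(light_schedule %in% c("LD", "DD"))) {
    stop("light_schedule entries must be 'LD' or 'DD'")
  }
  structure(
    list(traces = traces, tube_length_px = tube_length_px,
         light_schedule = light_schedule),
    class = "plate_recording"
  )
}

#' @export
print.plate_recording <- function(x, ...) {
  cat(sprintf("<plate_recording> %d flies, %d samples each, tube %g px\n",
              length(x$traces), length(x$traces[[1]]$positions),
              x$tube_length_px))
  invisible(x)
}

#' Describe the layout of a position table on disk
#'
#' The default dialect matches the package convention: headerless CSV, one
#' fly per column, one row per second, first row at ZT `start_zt`.
#'
#' @param orientation `"columns"` (one fly per column) or `"rows"` (one fly
#'   per row).
#' @param delimiter field separator.
#' @param header does the file carry a header of fly ids?
#' @param time_col optional 1-based index of a time column to drop
#'   (column orientation only).
#' @param na_strings cell values to read as missing samples.
#' @return A `table_dialect` list.
#' @export
table_dialect <- function(orientation = c("columns", "rows"), delimiter = ",",
                          header = FALSE, time_col = NULL,
                          na_strings = c("", "NA", "NaN")) {
  orientation <- match.arg(orientation)
  structure(list(orientation = orientation, delimiter = delimiter,
                 header = header, time_col = time_col,
                 na_strings = na_strings),
            class = "table_dialect")
}

#' Read a per-second position table into a plate recording
#'
#' Ingests a barycenter-coordinate export (one coordinate per fly per
#' second). Non-numeric or absent cells become missing samples. All flies in
#' one file must have the same number of samples; more than 18 flies exceeds
#' the plate capacity and is an error.
#'
#' @param path CSV file path.
#' @param dialect a [table_dialect()] describing the layout.
#' @param start_zt offset (s) of the first sample from ZT 0.
#' @param tube_length_px tube length in pixels.
#' @param light_schedule per-day light flags, see [plate_recording()].
#' @return A [plate_recording()].
#' @export
read_position_table <- function(path, dialect = table_dialect(),
                                start_zt = 0L, tube_length_px = 260,
                                light_schedule = "LD") {
  if (!file.exists(path)) stop("position table not found: ", path)
  raw <- tryCatch(
    utils::read.table(path, sep = dialect$delimiter,
                      header = dialect$header,
                      colClasses = "character",
                      na.strings = dialect$na_strings,
                      strip.white = TRUE,
                      stringsAsFactors = FALSE),
    error = function(e) {
      # ragged files: read.table reports the offending line; in row
      # orientation that line is the offending fly
      who <- if (dialect$orientation == "rows") "fly (row)" else "row"
      stop("unequal trace lengths in ", path, " [", who, "]: ",
           conditionMessage(e), call. = FALSE)
    }
  )
  if (dialect$orientation == "rows") {
    ids <- if (dialect$header) names(raw) else NULL
    raw <- as.data.frame(t(as.matrix(raw)), stringsAsFactors = FALSE)
    if (!is.null(ids)) names(raw) <- ids
  }
  if (!is.null(dialect$time_col)) raw <- raw[, -dialect$time_col, drop = FALSE]
  if (ncol(raw) == 0 || nrow(raw) == 0) stop("position table contains no flies")
  if (ncol(raw) > PLATE_CAPACITY) {
    stop(sprintf("plate capacity exceeded: %d coordinate columns (max %d)",
                 ncol(raw), PLATE_CAPACITY))
  }
  ids <- if (dialect$header && dialect$orientation == "columns") {
    names(raw)
  } else if (dialect$orientation == "rows" && !is.null(names(raw))) {
    names(raw)
  } else {
    sprintf("fly%02d", seq_len(ncol(raw)))
  }
  traces <- lapply(seq_len(ncol(raw)), function(j) {
    cell <- raw[[j]]
    pos <- suppressWarnings(as.numeric(cell))
    position_trace(pos, fly_id = ids[j], start_zt = start_zt)
  })
  plate_recording(traces, tube_length_px = tube_length_px,
                  light_schedule = light_schedule)
}

#' Exclude fly-days whose trace starts parked at zero
#'
#' When a fly is not moving at the beginning of a day the tracker reports the
#' first-second-of-ZT-0 coordinate as 0 (the cotton side). Such fly-days are
#' unreliable and are excluded from all downstream analysis. The rule is
#' applied per fly-day: other days of the same fly are retained. Days whose
#' ZT-0 sample falls outside the recording (e.g. the partial first day of a
#' recording started mid-day) cannot be evaluated and are kept.
#'
#' @param plate a [plate_recording()].
#' @return The plate with affected fly-days recorded in each trace's
#'   `excluded_days` and their samples masked as missing.
#' @export
drop_zeroed_day_traces <- function(plate) {
  stopifnot(inherits(plate, "plate_recording"))
  n_removed <- 0L
  plate$traces <- lapply(plate$traces, function(tr) {
    n <- length(tr$positions)
    last_t <- tr$start_zt + n - 1L
    days <- seq.int(tr$start_zt %/% DAY_S + 1L, last_t %/% DAY_S + 1L)
    for (d in days) {
      # sample index of the first second of ZT 0 of day d
      idx <- (d - 1L) * DAY_S - tr$start_zt + 1L
      if (idx < 1L || idx > n) next
      p <- tr$positions[idx]
      if (!is.na(p) && p == 0) {
        tr$excluded_days <- sort(unique(c(tr$excluded_days, d)))
        day_idx <- seq.int(max(1L, idx), min(n, idx + DAY_S - 1L))
        tr$positions[day_idx] <- NA_real_
        tr$missing_mask[day_idx] <- TRUE
        n_removed <<- n_removed + 1L
      }
    }
    tr
  })
  if (n_removed > 0) {
    warning(sprintf("removed %d zero-parked fly-day trace(s)", n_removed))
  }
  plate
}

# ---- recording / analysis configuration --------------------------------

#' Read or write an analysis configuration
#'
#' Configuration files are plain YAML key-value mappings with the keys
#' `tube_length_px`, `body_length_px`, `zt0_offset_s`, `light_schedule`,
#' `low_cutoff_s` and `high_cutoff_s`. Unknown keys are preserved.
#'
#' @param path file path.
#' @return `read_config()` returns a named list; `write_config()` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  defaults <- list(tube_length_px = 260, body_length_px = 11,
                   zt0_offset_s = 0L, light_schedule = "LD",
                   low_cutoff_s = 7, high_cutoff_s = 300)
  utils::modifyList(defaults, cfg)
}

#' @rdname read_config
#' @param config named list of configuration values.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
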