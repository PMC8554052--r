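# Food-surface detection, feeding-zone geometry and event segmentation.
#
# A food-approaching event (FAE) is a maximal run of consecutive seconds the
# fly spends within one body length of the food surface. Zone membership is
# inclusive: position >= zone boundary counts as inside, so a fly touching
# the boundary is in the zone.

#' Build an event table
#'
#' Events are stored as a plain data frame of class `fae_events` with columns
#' `fly_id`, `day_index` (1-based), `onset_zt_s` (seconds from ZT 0 of its
#' day, in `[0, 86400)`), `duration_s` (integer seconds, >= 1), `label`
#' (`"feeding"`, `"no_feeding"` or `"unlabeled"`) and `retained` (logical,
#' set by [apply_band_filter()]; `TRUE` until a filter is applied).
#'
#' @param fly_id,day_index,onset_zt_s,duration_s,label,retained column
#'   vectors, recycled where length 1.
#' @return A `fae_events` data frame.
#' @export
fae_events <- function(fly_id = character(0), day_index = integer(0),
                       onset_zt_s = integer(0), duration_s = integer(0),
                       label = "unlabeled", retained = TRUE) {
  n <- max(length(fly_id), length(day_index), length(onset_zt_s),
           length(duration_s))
  if (length(onset_zt_s) == 0) n <- 0L
  df <- data.frame(
    fly_id = rep_len(as.character(fly_id), n),
    day_index = rep_len(as.integer(day_index), n),
    onset_zt_s = rep_len(as.integer(onset_zt_s), n),
    duration_s = rep_len(as.integer(duration_s), n),
    label = rep_len(as.character(label), n),
    retained = rep_len(as.logical(retained), n),
    stringsAsFactors = FALSE
  )
  validate_fae_events(df)
}

validate_fae_events <- function(df) {
  need <- c("fly_id", "day_index", "onset_zt_s", "duration_s", "label",
            "retained")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("event table lacks columns: ",
                         paste(miss, collapse = ", "))
  if (nrow(df)) {
    if (any(df$duration_s < 1)) stop("event durations must be >= 1 s")
    if (any(df$onset_zt_s < 0 | df$onset_zt_s >= DAY_S)) {
      stop("event onsets must lie in [0, 86400) ZT seconds")
    }
    if (!all(df$label %in% c("feeding", "no_feeding", "unlabeled"))) {
      stop("event labels must be feeding / no_feeding / unlabeled")
    }
    # per fly-day: time-ordered and non-overlapping
    key <- paste(df$fly_id, df$day_index)
    for (k in unique(key)) {
      e <- df[key == k, ]
      e <- e[order(e$onset_zt_s), ]
      if (nrow(e) > 1 &&
          any(e$onset_zt_s[-1] < head(e$onset_zt_s + e$duration_s, -1))) {
        stop("overlapping events within fly-day ", k)
      }
    }
  }
  class(df) <- unique(c("fae_events", class(df)))
  df
}

# Sample-index window of day `d` (1-based) within a trace; zero-length if
# the day is outside the recording.
day_sample_range <- function(trace, d) {
  n <- length(trace$positions)
  from <- (d - 1L) * DAY_S - trace$start_zt + 1L
  to <- from + DAY_S - 1L
  from <- max(1L, from)
  to <- min(n, to)
  if (from > to) integer(0) else seq.int(from, to)
}

trace_days <- function(trace) {
  n <- length(trace$positions)
  seq.int(trace$start_zt %/% DAY_S + 1L,
          (trace$start_zt + n - 1L) %/% DAY_S + 1L)
}

#' Build a feeding-zone geometry table directly
#'
#' Bypasses trace-based food-surface detection for cases where the surface
#' coordinate is known (calibration rigs, synthetic data).
#'
#' @param day_index integer day indices (1-based).
#' @param food_surface_px food-surface coordinate per day (recycled).
#' @param body_length_px body length in pixels.
#' @return A `fae_geometry` data frame, as from [food_geometry()].
#' @export
fae_geometry <- function(day_index, food_surface_px, body_length_px = 11) {
  stopifnot(body_length_px > 0)
  out <- data.frame(day_index = as.integer(day_index),
                    food_surface_px = rep_len(food_surface_px,
                                              length(day_index)))
  out$zone_boundary_px <- out$food_surface_px - body_length_px
  attr(out, "body_length_px") <- body_length_px
  class(out) <- c("fae_geometry", class(out))
  out
}

#' Detect the food-surface coordinate of one fly-day
#'
#' The food surface is estimated per fly and per 24-h day from the trace
#' itself. `method = "max"` uses the farthest (largest) non-missing
#' coordinate the fly reached that day — the definition used for all default
#' analysis. `method = "peak_mode"` is a robust variant for traces with
#' single-sample tracking glitches: it builds a 1-px histogram of the day's
#' positions and returns the highest-coordinate local maximum supported by at
#' least `min_peak_count` samples (falling back to the best-supported bin if
#' no local maximum qualifies).
#'
#' @param trace a [position_trace()].
#' @param day_index 1-based recording day.
#' @param method `"max"` (default) or `"peak_mode"`.
#' @param min_peak_count minimum samples supporting a histogram peak
#'   (`peak_mode` only). A real food visit occupies at least several seconds
#'   of a day, so the default of 5 ignores sub-5-sample glitches.
#' @return The food-surface coordinate (pixels).
#' @export
detect_food_surface <- function(trace, day_index,
                                method = c("max", "peak_mode"),
                                min_peak_count = 5L) {
  method <- match.arg(method)
  idx <- day_sample_range(trace, day_index)
  pos <- trace$positions[idx]
  pos <- pos[!is.na(pos)]
  if (length(pos) == 0) {
    stop(sprintf("fly %s day %d has no usable samples; no geometry available",
                 trace$fly_id, day_index))
  }
  if (method == "max") return(max(pos))
  counts <- tabulate(as.integer(round(pos)) + 1L)
  coord <- seq_along(counts) - 1L
  left <- c(0L, head(counts, -1))
  right <- c(tail(counts, -1), 0L)
  is_peak <- counts >= left & counts >= right & counts >= min_peak_count
  if (any(is_peak)) max(coord[is_peak]) else max(coord[counts == max(counts)])
}

#' Feeding-zone geometry for every day of a trace
#'
#' Computes the per-day food-surface coordinate (see
#' [detect_food_surface()]) and the feeding-zone boundary, one body length
#' below it. Default body length is 11 px (males); use 12 px for females.
#' Days listed in the trace's `excluded_days` are skipped.
#'
#' @inheritParams detect_food_surface
#' @param body_length_px fly body length in pixels (default 11, male).
#' @param ... passed to [detect_food_surface()].
#' @return A data frame of class `fae_geometry` with columns `day_index`,
#'   `food_surface_px`, `zone_boundary_px`; body length kept as an attribute.
#' @export
food_geometry <- function(trace, body_length_px = 11,
                          method = c("max", "peak_mode"), ...) {
  method <- match.arg(method)
  stopifnot(body_length_px > 0)
  days <- setdiff(trace_days(trace), trace$excluded_days)
  if (length(days) == 0) {
    stop(sprintf("fly %s has no usable day; no geometry available",
                 trace$fly_id))
  }
  surf <- vapply(days, function(d) {
    detect_food_surface(trace, d, method = method, ...)
  }, numeric(1))
  out <- data.frame(day_index = as.integer(days), food_surface_px = surf,
                    zone_boundary_px = surf - body_length_px)
  attr(out, "body_length_px") <- body_length_px
  attr(out, "fly_id") <- trace$fly_id
  class(out) <- c("fae_geometry", class(out))
  out
}

# Bridge missing-sample runs of length <= k flanked by in-zone runs.
# state: 1 in zone, 0 out, 2 missing.
bridge_missing <- function(state, k) {
  r <- rle(state)
  v <- r$values
  nrun <- length(v)
  if (nrun >= 3) {
    for (i in 2:(nrun - 1)) {
      if (v[i] == 2 && r$lengths[i] <= k && v[i - 1] == 1 && v[i + 1] == 1) {
        v[i] <- 1
      }
    }
  }
  r$values <- v
  inverse.rle(r)
}

#' Segment a trace into food-approaching events
#'
#' Scans each fly-day for maximal runs of consecutive samples at or beyond
#' the feeding-zone boundary. Each run becomes one event; its duration is
#' the run length in samples (seconds at 1 fps). Runs never span the ZT-0
#' day boundary — the geometry is per-day, so a run crossing midnight is
#' split and each part assigned to its own day. Missing samples end a run
#' under the default `"break"` policy (presence in the zone is never
#' invented); `"bridge"` tolerates up to `bridge_k` consecutive missing
#' samples inside a run, counting them toward its duration.
#'
#' @param trace a [position_trace()].
#' @param geometry a [food_geometry()] table for this trace.
#' @param missing_policy `"break"` (default) or `"bridge"`.
#' @param bridge_k maximum missing samples bridged inside a run.
#' @return A [fae_events()] data frame ordered by day and onset.
#' @export
segment_events <- function(trace, geometry = food_geometry(trace),
                           missing_policy = c("break", "bridge"),
                           bridge_k = 1L) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(inherits(geometry, "fae_geometry"))
  out <- vector("list", nrow(geometry))
  for (i in seq_len(nrow(geometry))) {
    d <- geometry$day_index[i]
    boundary <- geometry$zone_boundary_px[i]
    idx <- day_sample_range(trace, d)
    if (!length(idx)) next
    pos <- trace$positions[idx]
    state <- ifelse(is.na(pos), 2L, as.integer(pos >= boundary))
    if (missing_policy == "bridge") state <- bridge_missing(state, bridge_k)
    r <- rle(state == 1L)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    if (!any(keep)) next
    # within-day onset of the first sample of each run
    t0 <- trace$start_zt + idx[1] - 1L  # absolute ZT time of first day sample
    onset <- (t0 + starts[keep] - 1L) %% DAY_S
    out[[i]] <- data.frame(
      fly_id = trace$fly_id, day_index = d,
      onset_zt_s = as.integer(onset),
      duration_s = as.integer(r$lengths[keep]),
      label = "unlabeled", retained = TRUE,
      stringsAsFactors = FALSE
    )
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) return(fae_events())
  df <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  df <- df[order(df$day_index, df$onset_zt_s), , drop = FALSE]
  rownames(df) <- NULL
  validate_fae_events(df)
}

#' Feeding indices over a ZT interval
#'
#' Computes the three feeding indices on an event table: FAEn (the number of
#' events whose onset falls in the half-open interval), FAErt (their summed
#' residence time, seconds) and FAErt/n (mean residence time per event).
#' Events are assigned to intervals by onset time, which keeps FAEn additive
#' across a partition of the day. With no events in the interval FAErt/n is
#' reported as 0 and flagged undefined.
#'
#' @param events a [fae_events()] table; only rows with `retained = TRUE`
#'   are counted unless `use_all = TRUE`.
#' @param interval half-open ZT interval `c(start, end)` in seconds within
#'   the day (default the whole day).
#' @param use_all count rejected events too (the "no cut-off" view).
#' @return A list with `faen`, `faert_s`, `faert_per_event` and
#'   `faert_defined`.
#' @export
compute_indices <- function(events, interval = c(0, DAY_S), use_all = FALSE) {
  stopifnot(length(interval) == 2, interval[1] < interval[2])
  e <- if (use_all) events else events[events$retained, , drop = FALSE]
  inside <- e$onset_zt_s >= interval[1] & e$onset_zt_s < interval[2]
  faen <- sum(inside)
  faert <- sum(e$duration_s[inside])
  list(
    faen = as.integer(faen),
    faert_s = as.integer(faert),
    faert_per_event = if (faen > 0) faert / faen else 0,
    faert_defined = faen > 0
  )
}
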