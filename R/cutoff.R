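# Calibration of the duration band filter against manually labeled visits.
#
# Short visits to the food end are dominated by exploration without feeding;
# long quiescence at the food end shades into sleep (5 min or more of
# immobility is the standard fly sleep definition). The band filter keeps
# events whose duration lies within [low, high], both edges inclusive; the
# calibrated default is 7-300 s.

#' Duration band filter
#'
#' @param low_cutoff_s low edge in seconds (default 7).
#' @param high_cutoff_s high edge in seconds (default 300; use `Inf` with
#'   `low_cutoff_s = 1` for the "no cut-off" view).
#' @return An `event_filter` object.
#' @export
event_filter <- function(low_cutoff_s = 7, high_cutoff_s = 300) {
  if (low_cutoff_s < 1 || low_cutoff_s > high_cutoff_s) {
    stop("need 1 <= low_cutoff_s <= high_cutoff_s")
  }
  structure(list(low_cutoff_s = low_cutoff_s, high_cutoff_s = high_cutoff_s),
            class = "event_filter")
}

#' Apply a duration band filter to events
#'
#' Sets each event's `retained` flag: retained iff
#' `low_cutoff_s <= duration_s <= high_cutoff_s` (both edges inclusive, so a
#' 7-s event survives the default 7-300 s band). Applying the same filter
#' twice is a no-op.
#'
#' @param events a [fae_events()] table.
#' @param filter an [event_filter()].
#' @return The events with updated `retained` flags.
#' @export
apply_band_filter <- function(events, filter = event_filter()) {
  stopifnot(inherits(filter, "event_filter"))
  events$retained <- events$duration_s >= filter$low_cutoff_s &
    events$duration_s <= filter$high_cutoff_s
  events
}

#' Attach manual feeding / no-feeding labels to events
#'
#' Annotations come from high-magnification video scoring (an event counts
#' as feeding when the fly extends its proboscis at least twice during the
#' visit). Each annotation row carries `fly_id`, `day`, `onset_zt_s` and
#' `label`; it is matched to the event of the same fly-day whose onset lies
#' within `tolerance_s` (the high-magnification clock runs at a different
#' frame rate, so onsets may disagree by a second). Two annotations landing
#' on one event is an error; annotations matching no event are reported and
#' the run continues.
#'
#' @param events a [fae_events()] table.
#' @param annotations data frame with columns `fly_id`, `day`, `onset_zt_s`,
#'   `label` (values `feeding` / `no_feeding`), e.g. from
#'   [read_annotations_csv()].
#' @param tolerance_s onset matching tolerance in seconds (default 1).
#' @return A list: `events` (with labels filled in) and
#'   `unmatched` (annotation rows that matched no event).
#' @export
merge_annotations <- function(events, annotations, tolerance_s = 1) {
  need <- c("fly_id", "day", "onset_zt_s", "label")
  miss <- setdiff(need, names(annotations))
  if (length(miss)) stop("annotation table lacks columns: ",
                         paste(miss, collapse = ", "))
  if (!all(annotations$label %in% c("feeding", "no_feeding"))) {
    stop("annotation labels must be 'feeding' or 'no_feeding'")
  }
  matched_by <- rep(NA_integer_, nrow(events))
  unmatched <- integer(0)
  for (a in seq_len(nrow(annotations))) {
    cand <- which(events$fly_id == annotations$fly_id[a] &
                    events$day_index == annotations$day[a])
    if (length(cand)) {
      off <- abs(events$onset_zt_s[cand] - annotations$onset_zt_s[a])
      cand <- cand[off <= tolerance_s]
      off <- off[off <= tolerance_s]
    }
    if (!length(cand)) {
      unmatched <- c(unmatched, a)
      next
    }
    hit <- cand[which.min(off)]
    if (!is.na(matched_by[hit])) {
      stop(sprintf(
        "duplicate annotation for event fly %s day %d onset %d (rows %d and %d)",
        events$fly_id[hit], events$day_index[hit], events$onset_zt_s[hit],
        matched_by[hit], a))
    }
    matched_by[hit] <- a
    events$label[hit] <- annotations$label[a]
  }
  list(events = events,
       unmatched = annotations[unmatched, , drop = FALSE])
}

#' Duration-bin proportion table of labeled events
#'
#' Cross-tabulates labeled events by duration bin and label, reporting per
#' cell the event count, the residence time and their shares of the labeled
#' grand totals. Shares over all bins and labels sum to 1 for counts and for
#' residence time separately. Default bins are 1-3, 4-6, 7-9 and >= 10 s.
#'
#' @param labeled a [fae_events()] table; only rows labeled `feeding` or
#'   `no_feeding` enter the table (at least one required).
#' @param bin_edges increasing integer lower bin edges; the last bin is
#'   open-ended.
#' @return A data frame with one row per (bin, label) cell: `bin`, `label`,
#'   `n_events`, `rt_s`, `share_n`, `share_rt`. Labeled grand totals are kept
#'   in attributes `total_n` and `total_rt_s`.
#' @export
proportion_table <- function(labeled, bin_edges = c(1, 4, 7, 10)) {
  stopifnot(length(bin_edges) >= 1, all(diff(bin_edges) > 0))
  e <- labeled[labeled$label %in% c("feeding", "no_feeding"), , drop = FALSE]
  if (nrow(e) == 0) stop("proportion_table requires at least one labeled event")
  nb <- length(bin_edges)
  bin_names <- c(
    if (nb > 1) sprintf("%d-%d", bin_edges[-nb], bin_edges[-1] - 1L),
    sprintf(">=%d", bin_edges[nb])
  )
  bin_of <- findInterval(e$duration_s, bin_edges)
  if (any(bin_of == 0)) stop("event duration below the first bin edge")
  grid <- expand.grid(bin = bin_names, label = c("feeding", "no_feeding"),
                      stringsAsFactors = FALSE)
  grid$n_events <- 0L
  grid$rt_s <- 0L
  for (i in seq_len(nrow(grid))) {
    sel <- bin_names[bin_of] == grid$bin[i] & e$label == grid$label[i]
    grid$n_events[i] <- sum(sel)
    grid$rt_s[i] <- sum(e$duration_s[sel])
  }
  total_n <- sum(grid$n_events)
  total_rt <- sum(grid$rt_s)
  grid$share_n <- grid$n_events / total_n
  grid$share_rt <- grid$rt_s / total_rt
  grid$bin <- factor(grid$bin, levels = bin_names)
  attr(grid, "total_n") <- total_n
  attr(grid, "total_rt_s") <- total_rt
  grid
}

#' Sweep low cut-off thresholds over labeled events
#'
#' For each candidate low cut-off `t`, an event survives when
#' `t <= duration_s <= high_cutoff_s`. Retention is reported per label, both
#' as a fraction of labeled event counts and as a fraction of labeled
#' residence time — the quantities used to pick the operating low cut-off
#' (eliminate no-feeding visits, keep feeding visits). The default grid is
#' 2-9 s in 1-s steps.
#'
#' @param labeled a [fae_events()] table with both labels present.
#' @param thresholds candidate low cut-offs in seconds.
#' @param high_cutoff_s fixed high cut-off (default 300).
#' @return A data frame of class `fae_sweep`, one row per threshold, with
#'   retention fractions `feeding_event_retention`,
#'   `no_feeding_event_retention`, `feeding_rt_retention`,
#'   `no_feeding_rt_retention`; labeled denominators are kept in the
#'   `denominators` attribute.
#' @export
sweep_thresholds <- function(labeled, thresholds = 2:9, high_cutoff_s = 300) {
  stopifnot(length(thresholds) >= 1, all(thresholds >= 1))
  for (lab in c("feeding", "no_feeding")) {
    if (!any(labeled$label == lab)) {
      stop("no labeled events of class '", lab, "'")
    }
  }
  e <- labeled[labeled$label %in% c("feeding", "no_feeding"), , drop = FALSE]
  denom <- list(
    feeding_n = sum(e$label == "feeding"),
    no_feeding_n = sum(e$label == "no_feeding"),
    feeding_rt_s = sum(e$duration_s[e$label == "feeding"]),
    no_feeding_rt_s = sum(e$duration_s[e$label == "no_feeding"])
  )
  rows <- lapply(thresholds, function(t) {
    kept <- e$duration_s >= t & e$duration_s <= high_cutoff_s
    data.frame(
      threshold_s = t,
      feeding_event_retention =
        sum(kept & e$label == "feeding") / denom$feeding_n,
      no_feeding_event_retention =
        sum(kept & e$label == "no_feeding") / denom$no_feeding_n,
      feeding_rt_retention =
        sum(e$duration_s[kept & e$label == "feeding"]) / denom$feeding_rt_s,
      no_feeding_rt_retention =
        sum(e$duration_s[kept & e$label == "no_feeding"]) / denom$no_feeding_rt_s
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "denominators") <- denom
  attr(out, "high_cutoff_s") <- high_cutoff_s
  class(out) <- c("fae_sweep", class(out))
  out
}
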