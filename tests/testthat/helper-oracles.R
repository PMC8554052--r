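# Independent brute-force oracles. These deliberately share no code with
# the package implementations: plain sample-by-sample / event-by-event
# loops against which the vectorised paths are checked.

# walk a trace one sample at a time and emit in-zone runs
# (break-on-missing policy; runs close at day boundaries)
brute_segment <- function(positions, start_zt, geometry) {
  boundary <- stats::setNames(geometry$zone_boundary_px, geometry$day_index)
  acc_day <- integer(0)
  acc_onset <- integer(0)
  acc_len <- integer(0)
  run_day <- NA_integer_
  run_onset <- NA_integer_
  run_len <- 0L
  close_run <- function() {
    if (run_len > 0L) {
      acc_day[length(acc_day) + 1L] <<- run_day
      acc_onset[length(acc_onset) + 1L] <<- run_onset
      acc_len[length(acc_len) + 1L] <<- run_len
    }
    run_len <<- 0L
  }
  for (t in seq_along(positions)) {
    t_abs <- start_zt + t - 1L
    day <- t_abs %/% 86400L + 1L
    p <- positions[t]
    in_zone <- !is.na(p) && as.character(day) %in% names(boundary) &&
      p >= boundary[[as.character(day)]]
    if (in_zone) {
      if (run_len > 0L && day != run_day) close_run()
      if (run_len == 0L) {
        run_day <- day
        run_onset <- t_abs %% 86400L
      }
      run_len <- run_len + 1L
    } else {
      close_run()
    }
  }
  close_run()
  data.frame(day_index = acc_day, onset_zt_s = acc_onset,
             duration_s = acc_len)
}

# per-hour tallies by explicit iteration over events
brute_hourly <- function(events) {
  e <- events[events$retained, , drop = FALSE]
  out <- list()
  for (f in sort(unique(events$fly_id))) {
    for (d in sort(unique(events$day_index[events$fly_id == f]))) {
      faen <- integer(24)
      faert <- integer(24)
      for (i in seq_len(nrow(e))) {
        if (e$fly_id[i] == f && e$day_index[i] == d) {
          h <- e$onset_zt_s[i] %/% 3600L + 1L
          faen[h] <- faen[h] + 1L
          faert[h] <- faert[h] + e$duration_s[i]
        }
      }
      out[[length(out) + 1L]] <- data.frame(
        fly_id = f, day_index = d, hour = 0:23, faen = faen, faert_s = faert)
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# exhaustive per-bin tally of labeled events
brute_proportions <- function(events, edges = c(1, 4, 7, 10)) {
  e <- events[events$label %in% c("feeding", "no_feeding"), , drop = FALSE]
  nb <- length(edges)
  res <- list()
  for (b in seq_len(nb)) {
    lo <- edges[b]
    hi <- if (b < nb) edges[b + 1] - 1 else Inf
    for (lab in c("feeding", "no_feeding")) {
      n <- 0L
      rt <- 0L
      for (i in seq_len(nrow(e))) {
        if (e$label[i] == lab && e$duration_s[i] >= lo &&
            e$duration_s[i] <= hi) {
          n <- n + 1L
          rt <- rt + e$duration_s[i]
        }
      }
      res[[length(res) + 1L]] <- data.frame(bin = b, label = lab,
                                            n_events = n, rt_s = rt)
    }
  }
  tab <- do.call(rbind, res)
  tab$share_n <- tab$n_events / sum(tab$n_events)
  tab$share_rt <- tab$rt_s / sum(tab$rt_s)
  tab
}

# per-threshold retention by filtering one event at a time
brute_sweep <- function(events, thresholds, high) {
  e <- events[events$label %in% c("feeding", "no_feeding"), , drop = FALSE]
  out <- list()
  for (t in thresholds) {
    acc <- c(fn = 0, nn = 0, frt = 0, nrt = 0,
             FN = 0, NN = 0, FRT = 0, NRT = 0)
    for (i in seq_len(nrow(e))) {
      feeding <- e$label[i] == "feeding"
      d <- e$duration_s[i]
      kept <- d >= t && d <= high
      if (feeding) {
        acc["FN"] <- acc["FN"] + 1
        acc["FRT"] <- acc["FRT"] + d
        if (kept) { acc["fn"] <- acc["fn"] + 1; acc["frt"] <- acc["frt"] + d }
      } else {
        acc["NN"] <- acc["NN"] + 1
        acc["NRT"] <- acc["NRT"] + d
        if (kept) { acc["nn"] <- acc["nn"] + 1; acc["nrt"] <- acc["nrt"] + d }
      }
    }
    out[[length(out) + 1L]] <- data.frame(
      threshold_s = t,
      feeding_event_retention = acc[["fn"]] / acc[["FN"]],
      no_feeding_event_retention = acc[["nn"]] / acc[["NN"]],
      feeding_rt_retention = acc[["frt"]] / acc[["FRT"]],
      no_feeding_rt_retention = acc[["nrt"]] / acc[["NRT"]])
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# random labeled event sets on one fly-day, non-overlapping by construction
random_labeled_events <- function(n = 40, max_dur = 320) {
  durs <- sample.int(max_dur, n, replace = TRUE)
  gaps <- sample.int(50, n, replace = TRUE)
  onsets <- cumsum(gaps + durs) - durs
  keep <- onsets + durs <= 86400
  fae_events(fly_id = "f1", day_index = 1L, onset_zt_s = onsets[keep],
             duration_s = durs[keep],
             label = sample(c("feeding", "no_feeding"), sum(keep),
                            replace = TRUE))
}

# short random trace plus its geometry (day length fits in day 1)
random_trace <- function(n = 3600, start_zt = 0L, missing_rate = 0.02) {
  p <- runif(n, 0, 100)
  p[runif(n) < missing_rate] <- NA
  position_trace(p, fly_id = "f1", start_zt = start_zt)
}
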