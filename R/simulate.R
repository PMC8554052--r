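# Synthetic tube-behavior generator: 1-fps traces with programmable
# circadian visit rates and labeled feeding / no-feeding visits. Ground
# truth is exact, so every downstream module can be validated end-to-end.

#' Simulation configuration
#'
#' Defaults emulate the behavioral regime the package targets: a bimodal
#' circadian visit profile peaking after lights-on (ZT 0-1) and around
#' lights-off (ZT 12-13); feeding visits with log-normal durations (median
#' 15 s) capped at 250 s — the longest manually scored visit on record —
#' and no-feeding exploratory visits with geometric-like durations (median
#' 2 s, almost all under 7 s). Between visits the fly performs a bounded
#' random walk strictly below the feeding-zone boundary.
#'
#' @param seed integer seed; every simulation with the same seed is
#'   bit-identical.
#' @param n_flies,n_days cohort size (defaults 18 flies, 2 days).
#' @param tube_length_px,food_surface_px,body_length_px geometry in pixels
#'   (defaults 260 / 250 / 11; the feeding-zone boundary is
#'   `food_surface_px - body_length_px`).
#' @param rate_profile 24 non-negative per-hour visit intensities
#'   (visits/hour).
#' @param feeding_fraction probability that a visit is a feeding visit
#'   (default 0.36, the labeled feeding share of visits).
#' @param feeding_meanlog,feeding_sdlog log-normal parameters of feeding
#'   visit durations (default median 15 s, sdlog 0.8).
#' @param no_feeding_geom_prob success probability of the geometric
#'   no-feeding duration model, durations `1 + rgeom(prob)` (default 0.4,
#'   median 2 s).
#' @param duration_cap_s hard cap on any visit duration (default 250 s).
#' @param step_sd_px random-walk step SD outside the zone (default 6).
#' @param ld_mode `"LD"`, `"DD"` (same profile, dark phase flagged) or
#'   `"mutant_flat"` — a clock-defective mode replacing the profile by a
#'   constant rate equal to its daily mean.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = NULL, n_flies = 18L, n_days = 2L,
                              tube_length_px = 260, food_surface_px = 250,
                              body_length_px = 11,
                              rate_profile = default_rate_profile(),
                              feeding_fraction = 0.36,
                              feeding_meanlog = log(15), feeding_sdlog = 0.8,
                              no_feeding_geom_prob = 0.4,
                              duration_cap_s = 250,
                              step_sd_px = 6,
                              ld_mode = c("LD", "DD", "mutant_flat")) {
  ld_mode <- match.arg(ld_mode)
  stopifnot(length(rate_profile) == 24, all(rate_profile >= 0),
            n_flies >= 1, n_days >= 1,
            food_surface_px > body_length_px,
            food_surface_px <= tube_length_px,
            duration_cap_s >= 1)
  structure(list(
    seed = seed, n_flies = as.integer(n_flies), n_days = as.integer(n_days),
    tube_length_px = tube_length_px, food_surface_px = food_surface_px,
    body_length_px = body_length_px, rate_profile = rate_profile,
    feeding_fraction = feeding_fraction,
    feeding_meanlog = feeding_meanlog, feeding_sdlog = feeding_sdlog,
    no_feeding_geom_prob = no_feeding_geom_prob,
    duration_cap_s = duration_cap_s, step_sd_px = step_sd_px,
    ld_mode = ld_mode
  ), class = "simulation_config")
}

#' Default bimodal circadian visit profile
#'
#' Visits per hour: 12 at the morning peak (ZT 0-1) and the evening peak
#' (ZT 12-13), 4 through the rest of the day (ZT 2-11) and 3 at night
#' (ZT 14-23) — about 120 food visits per fly per day.
#'
#' @return Numeric vector of 24 hourly intensities.
#' @export
default_rate_profile <- function() {
  c(12, 12, rep(4, 10), 12, 12, rep(3, 10))
}

# fold x into [lo, hi] by reflection (triangle wave)
reflect_into <- function(x, lo, hi) {
  L <- hi - lo
  y <- (x - lo) %% (2 * L)
  lo + ifelse(y <= L, y, 2 * L - y)
}

draw_duration <- function(n, label, config) {
  d <- ifelse(
    label == "feeding",
    round(stats::rlnorm(n, config$feeding_meanlog, config$feeding_sdlog)),
    1 + stats::rgeom(n, config$no_feeding_geom_prob)
  )
  pmin(pmax(d, 1), config$duration_cap_s)
}

#' Simulate a cohort of tube recordings with known ground truth
#'
#' Visits are drawn from an inhomogeneous Poisson process with the hourly
#' rate profile; each visit is placed at a uniform onset within its hour,
#' rejected and redrawn if it would come within one second of another visit
#' of the same fly-day (so segmentation can separate neighbours), and
#' realised as a contiguous in-zone run of exactly its drawn duration with
#' at least one sample touching the food surface. Between visits the fly
#' random-walks strictly below the zone boundary. Identical seeds give
#' bit-identical traces and ground truth.
#'
#' @param config a [simulation_config()].
#' @param render_traces build full position traces (`TRUE`, default) or
#'   only the ground-truth visit table (`FALSE`; much faster for
#'   statistical studies of the summary layer).
#' @return A list with `traces` (list of [position_trace()], or `NULL`),
#'   `truth` (data frame `fly_id`, `day`, `onset_zt_s`, `duration_s`,
#'   `label` — the annotation schema plus duration) and `config`.
#' @export
simulate_cohort <- function(config = simulation_config(),
                            render_traces = TRUE) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  profile <- config$rate_profile
  if (config$ld_mode == "mutant_flat") profile <- rep(mean(profile), 24)
  boundary <- config$food_surface_px - config$body_length_px
  n_s <- config$n_days * DAY_S
  fly_ids <- sprintf("fly%02d", seq_len(config$n_flies))
  truth <- list()
  traces <- if (render_traces) vector("list", config$n_flies) else NULL

  for (f in seq_len(config$n_flies)) {
    v_day <- integer(0)
    v_onset <- integer(0)
    v_dur <- integer(0)
    v_label <- character(0)
    for (d in seq_len(config$n_days)) {
      starts <- integer(0)
      ends <- integer(0)
      for (h in 0:23) {
        n_vis <- stats::rpois(1, profile[h + 1])
        if (n_vis == 0) next
        labels <- ifelse(stats::runif(n_vis) < config$feeding_fraction,
                         "feeding", "no_feeding")
        durs <- draw_duration(n_vis, labels, config)
        for (v in seq_len(n_vis)) {
          dur <- durs[v]
          hi <- min(3600L * (h + 1L) - 1L, DAY_S - dur)
          lo <- 3600L * h
          if (hi < lo) next  # duration cannot fit before midnight
          placed <- FALSE
          for (try in 1:200) {
            o <- lo + sample.int(hi - lo + 1L, 1L) - 1L
            # keep >= 1 s out-of-zone gap to neighbouring visits
            if (!any(o <= ends + 1L & (o + dur - 1L) >= starts - 1L)) {
              placed <- TRUE
              break
            }
          }
          if (!placed) {
            stop("could not place a visit without overlap; lower rate_profile")
          }
          starts <- c(starts, o)
          ends <- c(ends, o + dur - 1L)
          v_day <- c(v_day, d)
          v_onset <- c(v_onset, o)
          v_dur <- c(v_dur, as.integer(dur))
          v_label <- c(v_label, labels[v])
        }
      }
    }
    ord <- order(v_day, v_onset)
    vis <- data.frame(fly_id = rep(fly_ids[f], length(ord)),
                      day = v_day[ord], onset_zt_s = v_onset[ord],
                      duration_s = v_dur[ord], label = v_label[ord],
                      stringsAsFactors = FALSE)
    truth[[f]] <- vis

    if (render_traces) {
      steps <- stats::rnorm(n_s, 0, config$step_sd_px)
      pos <- reflect_into(boundary / 2 + cumsum(steps), 0, boundary - 1)
      for (v in seq_len(nrow(vis))) {
        i0 <- (vis$day[v] - 1L) * DAY_S + vis$onset_zt_s[v] + 1L
        dur <- vis$duration_s[v]
        offs <- floor(stats::runif(dur, 0, config$body_length_px))
        offs[sample.int(dur, 1L)] <- 0
        pos[seq.int(i0, i0 + dur - 1L)] <- config$food_surface_px - offs
      }
      traces[[f]] <- position_trace(pos, fly_id = fly_ids[f], start_zt = 0L)
    }
  }
  truth <- do.call(rbind, c(truth, list(make.row.names = FALSE)))
  list(traces = traces, truth = truth, config = config)
}

#' Draw per-fly daily residence-time totals without trace synthesis
#'
#' Samples each fly's daily filtered FAErt total directly from the
#' configured visit-rate and duration models (visit count Poisson with the
#' profile's daily total; durations from the feeding / no-feeding mixture;
#' the band filter applied to each visit). Statistically equivalent to
#' summing a simulated cohort's retained visit durations, but orders of
#' magnitude faster — intended for replicate-heavy studies of the
#' group-comparison layer.
#'
#' @param config a [simulation_config()]; its `seed` is honoured.
#' @param n_flies number of flies to draw (default from `config`).
#' @param filter an [event_filter()] applied to visit durations.
#' @return Numeric vector of per-fly daily FAErt totals (seconds).
#' @export
simulate_daily_totals <- function(config = simulation_config(),
                                  n_flies = config$n_flies,
                                  filter = event_filter()) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  lambda <- sum(config$rate_profile)
  vapply(seq_len(n_flies), function(i) {
    n <- stats::rpois(1, lambda)
    if (n == 0) return(0)
    labels <- ifelse(stats::runif(n) < config$feeding_fraction,
                     "feeding", "no_feeding")
    d <- draw_duration(n, labels, config)
    sum(d[d >= filter$low_cutoff_s & d <= filter$high_cutoff_s])
  }, numeric(1))
}

#' Render a trace as a synthetic grayscale frame stack
#'
#' One frame per sample: a dark Gaussian blob at the fly position on a
#' constant bright background, with optional pixel noise. Missing samples
#' render as blank frames. A fixture generator for
#' [extract_positions_from_frames()]; deterministic given the RNG state.
#'
#' @param trace a [position_trace()].
#' @param width frame width in pixels (default tube length 260 + 1).
#' @param height frame height (default 9 rows; blob on the middle row).
#' @param bg background intensity (default 200).
#' @param amplitude blob depth below background (default 150).
#' @param sigma blob Gaussian radius in pixels (default 1.2).
#' @param noise_sd SD of additive Gaussian pixel noise (default 0).
#' @return A 3-D array `[height, width, n_samples]`.
#' @export
render_frames <- function(trace, width = 261L, height = 9L, bg = 200,
                          amplitude = 150, sigma = 1.2, noise_sd = 0) {
  n <- length(trace$positions)
  if (n == 0) stop("cannot render an empty trace")
  frames <- array(bg, dim = c(height, width, n))
  ry <- seq_len(height) - (height + 1) / 2
  for (t in seq_len(n)) {
    p <- trace$positions[t]
    if (is.na(p)) next
    rx <- (seq_len(width) - 1) - p
    blob <- amplitude * outer(exp(-ry^2 / (2 * sigma^2)),
                              exp(-rx^2 / (2 * sigma^2)))
    frames[, , t] <- bg - blob
  }
  if (noise_sd > 0) {
    frames <- frames + stats::rnorm(length(frames), 0, noise_sd)
  }
  frames
}
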