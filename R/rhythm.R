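# Hourly curves, ZT-window summaries, group aggregation and comparisons.
#
# Events are binned by onset time into half-open ZT intervals; hour h covers
# [3600*h, 3600*(h+1)). Multi-day recordings yield one summary row per
# fly-day; group statistics first average days within each fly so that each
# fly is one independent unit.

#' Hourly feeding indices per fly-day
#'
#' For each fly-day, counts the retained events (FAEn) and sums their
#' residence time (FAErt) in every ZT hour, plus the per-event ratio
#' (FAErt/n, reported as 0 and flagged undefined where FAEn = 0).
#'
#' Fly-days without events produce all-zero rows only when listed via
#' `flies` / `days`; by default the fly-day universe is taken from the
#' events themselves.
#'
#' @param events a [fae_events()] table.
#' @param flies fly ids to summarize (default: those present in `events`).
#' @param days day indices to summarize (default: those present), either a
#'   vector shared by all flies or a named list per fly.
#' @param use_all include events rejected by the band filter.
#' @return A data frame of class `fae_hourly`: `fly_id`, `day_index`, `hour`
#'   (0-23), `faen`, `faert_s`, `faert_per_event`, `faert_defined`.
#' @export
hourly_summarize <- function(events, flies = NULL, days = NULL,
                             use_all = FALSE) {
  e <- if (use_all) events else events[events$retained, , drop = FALSE]
  if (is.null(flies)) flies <- sort(unique(events$fly_id))
  if (is.null(days)) {
    days_of <- function(f) sort(unique(events$day_index[events$fly_id == f]))
  } else if (is.list(days)) {
    days_of <- function(f) sort(unique(as.integer(days[[f]])))
  } else {
    days_of <- function(f) sort(unique(as.integer(days)))
  }
  pairs_f <- character(0)
  pairs_d <- integer(0)
  for (f in flies) {
    dd <- days_of(f)
    pairs_f <- c(pairs_f, rep(f, length(dd)))
    pairs_d <- c(pairs_d, dd)
  }
  np <- length(pairs_f)
  row_of <- split(seq_len(nrow(e)), paste(e$fly_id, e$day_index))
  faen <- integer(np * 24L)
  faert <- integer(np * 24L)
  for (p in seq_len(np)) {
    rows <- row_of[[paste(pairs_f[p], pairs_d[p])]]
    slice <- seq.int((p - 1L) * 24L + 1L, p * 24L)
    if (!is.null(rows)) {
      hr <- e$onset_zt_s[rows] %/% 3600L
      faen[slice] <- tabulate(hr + 1L, nbins = 24L)
      rt <- integer(24)
      agg <- rowsum(e$duration_s[rows], hr)
      rt[as.integer(rownames(agg)) + 1L] <- agg[, 1]
      faert[slice] <- rt
    }
  }
  out <- data.frame(
    fly_id = rep(pairs_f, each = 24L),
    day_index = rep(pairs_d, each = 24L),
    hour = rep(0:23, times = np),
    faen = faen, faert_s = faert,
    faert_per_event = ifelse(faen > 0L, faert / faen, 0),
    faert_defined = faen > 0L,
    stringsAsFactors = FALSE
  )
  class(out) <- c("fae_hourly", class(out))
  out
}

#' Canonical ZT analysis windows
#'
#' The four windows partition the day: ZT 0-2 (morning peak), ZT 3-11
#' (day time), ZT 12-14 (evening peak) and ZT 15-23 (night time). Bounds
#' are hours; each window is the half-open interval
#' `[3600 * start_h, 3600 * (end_h + 1))`.
#'
#' @return Named list of `c(start_h, end_h)` inclusive hour pairs.
#' @export
canonical_windows <- function() {
  list(morning_peak = c(0, 2), day_time = c(3, 11),
       evening_peak = c(12, 14), night_time = c(15, 23))
}

#' Feeding indices over named ZT windows
#'
#' @param events a [fae_events()] table.
#' @param windows named list of inclusive hour pairs `c(start_h, end_h)`;
#'   default [canonical_windows()].
#' @param allow_overlap permit overlapping windows (default `FALSE`: an
#'   overlap is an error).
#' @param use_all include events rejected by the band filter.
#' @return A data frame of class `fae_windows`: `fly_id`, `day_index`,
#'   `window`, `faen`, `faert_s`, `faert_per_event`, `faert_defined`.
#' @export
window_summarize <- function(events, windows = canonical_windows(),
                             allow_overlap = FALSE, use_all = FALSE) {
  stopifnot(is.list(windows), length(windows) >= 1,
            !is.null(names(windows)))
  iv <- lapply(windows, function(w) c(w[1] * 3600, (w[2] + 1) * 3600))
  if (!allow_overlap && length(iv) > 1) {
    ord <- order(vapply(iv, `[`, numeric(1), 1))
    s <- iv[ord]
    for (i in seq_len(length(s) - 1)) {
      if (s[[i + 1]][1] < s[[i]][2]) {
        stop("windows overlap: ", names(s)[i], " and ", names(s)[i + 1])
      }
    }
  }
  e <- if (use_all) events else events[events$retained, , drop = FALSE]
  rows <- list()
  for (f in sort(unique(events$fly_id))) {
    for (d in sort(unique(events$day_index[events$fly_id == f]))) {
      sel <- e[e$fly_id == f & e$day_index == d, , drop = FALSE]
      for (w in names(windows)) {
        inside <- sel$onset_zt_s >= iv[[w]][1] & sel$onset_zt_s < iv[[w]][2]
        faen <- sum(inside)
        faert <- sum(sel$duration_s[inside])
        rows[[length(rows) + 1L]] <- data.frame(
          fly_id = f, day_index = d, window = w,
          faen = as.integer(faen), faert_s = as.integer(faert),
          faert_per_event = if (faen > 0) faert / faen else 0,
          faert_defined = faen > 0,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- if (length(rows)) {
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else {
    data.frame(fly_id = character(0), day_index = integer(0),
               window = character(0), faen = integer(0),
               faert_s = integer(0), faert_per_event = numeric(0),
               faert_defined = logical(0))
  }
  class(out) <- c("fae_windows", class(out))
  out
}

#' Group mean +/- SEM curves across flies
#'
#' Aggregates hourly summaries into per-group hourly curves. Days are first
#' averaged within each fly, so the group n counts flies (each fly one
#' independent unit); SEM = sample SD / sqrt(n). Undefined FAErt/n cells
#' (hours with FAEn = 0) are excluded from the ratio's fly-level day average.
#' Groups of one fly get a mean but an `NA` SEM.
#'
#' @param hourly a [hourly_summarize()] result.
#' @param groups named character vector mapping `fly_id` to a group label;
#'   default puts every fly in one group `"all"`.
#' @return A data frame of class `fae_group_curve`: `group`, `hour`,
#'   `metric` (`faen`, `faert_s`, `faert_per_event`), `mean`, `sem`, `n`.
#' @export
group_aggregate <- function(hourly, groups = NULL) {
  flies <- sort(unique(hourly$fly_id))
  if (is.null(groups)) groups <- setNames(rep("all", length(flies)), flies)
  if (!all(flies %in% names(groups))) {
    stop("groups must name every fly in the summary")
  }
  # fly-level hourly means across days: one n_flies x 24 matrix per metric
  nf <- length(flies)
  m_faen <- matrix(NA_real_, nf, 24)
  m_faert <- matrix(NA_real_, nf, 24)
  m_ratio <- matrix(NA_real_, nf, 24)
  for (i in seq_len(nf)) {
    h <- hourly[hourly$fly_id == flies[i], , drop = FALSE]
    for (hr in 0:23) {
      sel <- h$hour == hr
      m_faen[i, hr + 1] <- mean(h$faen[sel])
      m_faert[i, hr + 1] <- mean(h$faert_s[sel])
      rv <- h$faert_per_event[sel & h$faert_defined]
      if (length(rv)) m_ratio[i, hr + 1] <- mean(rv)
    }
  }
  fly_group <- unname(groups[flies])
  metrics <- list(faen = m_faen, faert_s = m_faert,
                  faert_per_event = m_ratio)
  g_levels <- sort(unique(fly_group))
  acc <- list()
  for (g in g_levels) {
    rows_g <- fly_group == g
    for (metric in names(metrics)) {
      m <- metrics[[metric]][rows_g, , drop = FALSE]
      n <- colSums(!is.na(m))
      mu <- suppressWarnings(colMeans(m, na.rm = TRUE))
      mu[n == 0] <- NA_real_  # ratio metric with no events that hour
      sdv <- apply(m, 2, stats::sd, na.rm = TRUE)
      sem <- ifelse(n > 1, sdv / sqrt(n), NA_real_)
      acc[[length(acc) + 1L]] <- data.frame(
        group = g, hour = 0:23, metric = metric,
        mean = unname(mu), sem = unname(sem), n = unname(n),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, c(acc, list(make.row.names = FALSE)))
  # hours cycle fastest within (group, metric), metrics in declared order
  out <- out[order(match(out$group, g_levels),
                   match(out$metric, names(metrics)), out$hour), ]
  rownames(out) <- NULL
  class(out) <- c("fae_group_curve", class(out))
  out
}

significance_stars <- function(p) {
  ifelse(p < 1e-4, "****",
         ifelse(p < 1e-3, "***",
                ifelse(p < 1e-2, "**",
                       ifelse(p < 0.05, "*", "n.s."))))
}

#' Compare per-fly totals between groups
#'
#' Standard group comparisons on per-fly totals (e.g. window FAErt):
#' `two_sample` runs a two-tailed independent-samples t test;
#' `one_way` a one-way ANOVA with Tukey HSD pairwise comparisons;
#' `two_way` a two-factor ANOVA with interaction and Tukey HSD.
#' Significance stars follow the usual levels
#' (0.05 / 0.01 / 0.001 / 0.0001). Numerics are delegated to
#' [stats::t.test()], [stats::aov()] and [stats::TukeyHSD()]; this function
#' fixes the result schema.
#'
#' @param a numeric vector (first group) or, for ANOVA designs, the full
#'   response vector.
#' @param b numeric vector (second group, `two_sample` only).
#' @param design `"two_sample"`, `"one_way"` or `"two_way"`.
#' @param groups factor of group labels for `one_way` / `two_way`.
#' @param groups2 second factor for `two_way`.
#' @param var_equal assume equal variances in the t test (classical
#'   independent-samples t; default `TRUE`).
#' @return A list of class `fae_test`: `design`, `statistic`, `df`,
#'   `p_value`, `stars`, plus `anova_table` and `tukey` for ANOVA designs.
#' @export
compare_groups <- function(a, b = NULL,
                           design = c("two_sample", "one_way", "two_way"),
                           groups = NULL, groups2 = NULL, var_equal = TRUE) {
  design <- match.arg(design)
  if (design == "two_sample") {
    if (is.null(b)) stop("two_sample design needs both a and b")
    if (length(a) < 2 || length(b) < 2) stop("need >= 2 observations per group")
    tt <- stats::t.test(a, b, var.equal = var_equal)
    res <- list(design = design,
                statistic = unname(tt$statistic),
                df = unname(tt$parameter),
                p_value = tt$p.value,
                stars = significance_stars(tt$p.value))
  } else {
    if (is.null(groups)) stop(design, " design needs a groups factor")
    groups <- factor(groups)
    if (any(table(groups) < 2)) stop("need >= 2 observations per group")
    if (design == "one_way") {
      fit <- stats::aov(a ~ groups)
    } else {
      if (is.null(groups2)) stop("two_way design needs groups2")
      groups2 <- factor(groups2)
      if (any(table(groups, groups2) == 0)) {
        stop("two_way design has an empty cell")
      }
      fit <- stats::aov(a ~ groups * groups2)
    }
    tab <- summary(fit)[[1]]
    tuk <- stats::TukeyHSD(fit)
    p_main <- tab[["Pr(>F)"]][1]
    res <- list(design = design,
                statistic = tab[["F value"]][1],
                df = tab[["Df"]],
                p_value = p_main,
                stars = significance_stars(p_main),
                anova_table = tab,
                tukey = lapply(tuk, as.data.frame))
  }
  class(res) <- "fae_test"
  res
}

#' @export
print.fae_test <- function(x, ...) {
  cat(sprintf("<fae_test %s> statistic = %.4g, p = %.4g %s\n",
              x$design, x$statistic, x$p_value, x$stars))
  invisible(x)
}
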