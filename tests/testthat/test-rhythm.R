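test_that("hourly binning is half-open on hour boundaries", {
  # onset 3599 still belongs to hour 0; onset 3600 opens hour 1
  ev <- fae_events(fly_id = "A", day_index = 1L,
                   onset_zt_s = c(10L, 3599L, 3600L),
                   duration_s = c(10L, 1L, 20L))
  h <- hourly_summarize(ev)
  h0 <- h[h$hour == 0, ]
  h1 <- h[h$hour == 1, ]
  expect_equal(h0$faen, 2L)
  expect_equal(h0$faert_s, 11L)
  expect_equal(h1$faen, 1L)
  expect_equal(h1$faert_s, 20L)
  expect_equal(h0$faert_per_event, 5.5)
  expect_true(all(h$faen[h$hour > 1] == 0))
  expect_false(any(h$faert_defined[h$hour > 1]))
})

test_that("hourly summaries equal the brute-force tally", {
  set.seed(31)
  for (i in 1:10) {
    ev <- random_labeled_events(80)
    ev <- apply_band_filter(ev, event_filter(7, 300))
    h <- hourly_summarize(ev)
    o <- brute_hourly(ev)
    expect_equal(h$faen, o$faen)
    expect_equal(h$faert_s, o$faert_s)
  }
})

test_that("window summaries respect half-open windows and partitions", {
  ev <- fae_events(fly_id = "A", day_index = 1L, onset_zt_s = 3600L,
                   duration_s = 100L)
  w <- window_summarize(ev)
  expect_equal(w$faert_s[w$window == "morning_peak"], 100L)
  expect_true(all(w$faert_s[w$window != "morning_peak"] == 0))

  set.seed(32)
  ev <- apply_band_filter(random_labeled_events(90), event_filter(7, 300))
  h <- hourly_summarize(ev)
  w <- window_summarize(ev)
  # canonical windows reproduce sums of their hourly cells
  for (win in names(canonical_windows())) {
    hrs <- canonical_windows()[[win]]
    expect_equal(w$faert_s[w$window == win],
                 sum(h$faert_s[h$hour >= hrs[1] & h$hour <= hrs[2]]))
  }
  # day/night split partitions the whole day
  dn <- window_summarize(ev, list(day = c(0, 11), night = c(12, 23)))
  expect_equal(sum(dn$faen), sum(h$faen))
  expect_equal(sum(dn$faert_s), sum(h$faert_s))
})

test_that("overlapping windows are rejected unless allowed", {
  ev <- fae_events(fly_id = "A", day_index = 1L, onset_zt_s = 10L,
                   duration_s = 10L)
  expect_error(window_summarize(ev, list(a = c(0, 5), b = c(5, 10))),
               "overlap")
  w <- window_summarize(ev, list(a = c(0, 5), b = c(5, 10)),
                        allow_overlap = TRUE)
  expect_equal(nrow(w), 2)
})

test_that("group curves compute mean and SEM across flies", {
  ev <- fae_events(fly_id = c("A", "A", "B", "B", "B", "B"),
                   day_index = 1L,
                   onset_zt_s = c(10L, 20L, 5L, 15L, 25L, 35L),
                   duration_s = 10L)
  curve <- group_aggregate(hourly_summarize(ev))
  c0 <- curve[curve$hour == 0 & curve$metric == "faen", ]
  expect_equal(c0$mean, 3)           # flies saw 2 and 4 events
  expect_equal(c0$sem, 1)            # two-point SEM = |a - b| / 2
  expect_equal(c0$n, 2)
})

test_that("identical flies give zero SEM; singletons an undefined SEM", {
  ev <- fae_events(fly_id = c("A", "B"), day_index = 1L,
                   onset_zt_s = c(10L, 10L), duration_s = c(7L, 7L))
  curve <- group_aggregate(hourly_summarize(ev))
  expect_equal(curve$sem[curve$hour == 0 & curve$metric == "faen"], 0)

  solo <- group_aggregate(hourly_summarize(ev[ev$fly_id == "A", ]))
  expect_true(is.na(solo$sem[solo$hour == 0 & solo$metric == "faen"]))
  expect_equal(solo$n[1], 1)
})

test_that("days are averaged within fly before group statistics", {
  # fly A: 2 then 4 events in hour 0 across days -> fly mean 3
  ev <- fae_events(fly_id = c("A", "A", "A", "A", "A", "A", "B"),
                   day_index = c(1L, 1L, 2L, 2L, 2L, 2L, 1L),
                   onset_zt_s = c(10L, 20L, 5L, 15L, 25L, 35L, 40L),
                   duration_s = 10L)
  curve <- group_aggregate(hourly_summarize(ev))
  c0 <- curve[curve$hour == 0 & curve$metric == "faen", ]
  expect_equal(c0$mean, 2)  # mean of fly means 3 (A) and 1 (B)
  expect_equal(c0$n, 2)
})

test_that("group curves are invariant to fly ordering", {
  set.seed(41)
  evs <- lapply(sprintf("f%02d", 1:6), function(f) {
    e <- random_labeled_events(30)
    e$fly_id <- f
    e
  })
  ev <- do.call(rbind, evs)
  shuffled <- ev[sample(nrow(ev)), ]
  a <- group_aggregate(hourly_summarize(ev))
  b <- group_aggregate(hourly_summarize(shuffled))
  expect_equal(a, b)
})

test_that("18 simulated flies match a brute-force group curve", {
  sim <- simulate_cohort(simulation_config(seed = 99, n_flies = 18,
                                           n_days = 1),
                         render_traces = FALSE)
  ev <- apply_band_filter(
    fae_events(fly_id = sim$truth$fly_id, day_index = sim$truth$day,
               onset_zt_s = sim$truth$onset_zt_s,
               duration_s = sim$truth$duration_s),
    event_filter(7, 300))
  h <- hourly_summarize(ev, flies = sprintf("fly%02d", 1:18), days = 1L)
  curve <- group_aggregate(h)
  for (hr in c(0, 7, 13)) {
    v <- h$faert_s[h$hour == hr]
    expect_equal(curve$mean[curve$metric == "faert_s" & curve$hour == hr],
                 mean(v))
    expect_equal(curve$sem[curve$metric == "faert_s" & curve$hour == hr],
                 sd(v) / sqrt(length(v)))
  }
})

test_that("identical samples give t = 0 and p = 1", {
  res <- compare_groups(c(1, 2, 3), c(1, 2, 3), design = "two_sample")
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_equal(res$stars, "n.s.")
})

test_that("extreme separation earns four stars", {
  res <- compare_groups(c(1, 2, 3), c(101, 102, 103), design = "two_sample")
  expect_lt(res$p_value, 1e-4)
  expect_equal(res$stars, "****")
})

test_that("one-way ANOVA reports an F table and Tukey pairs", {
  set.seed(51)
  y <- c(rnorm(8, 0), rnorm(8, 0), rnorm(8, 5))
  g <- rep(c("a", "b", "c"), each = 8)
  res <- compare_groups(y, design = "one_way", groups = g)
  expect_lt(res$p_value, 0.001)
  expect_s3_class(res$tukey$groups, "data.frame")
  expect_equal(nrow(res$tukey$groups), 3)  # three pairwise comparisons
})

test_that("two-way ANOVA rejects designs with an empty cell", {
  y <- rnorm(12)
  g1 <- rep(c("a", "b"), each = 6)
  g2 <- c(rep(c("x", "y"), 3), rep("x", 6))  # b:y never observed
  expect_error(compare_groups(y, design = "two_way", groups = g1,
                              groups2 = g2),
               "empty cell")
})

test_that("two-way ANOVA detects an interaction", {
  set.seed(52)
  g1 <- rep(c("wt", "mut"), each = 20)
  g2 <- rep(rep(c("LD", "DD"), each = 10), 2)
  y <- rnorm(40, sd = 0.5) + ifelse(g1 == "mut" & g2 == "DD", 4, 0)
  res <- compare_groups(y, design = "two_way", groups = g1, groups2 = g2)
  inter_p <- res$anova_table[["Pr(>F)"]][3]
  expect_lt(inter_p, 1e-4)
})
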