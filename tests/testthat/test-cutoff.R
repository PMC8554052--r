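events_with_durations <- function(durations, labels = "unlabeled") {
  n <- length(durations)
  onsets <- cumsum(durations + 5) - durations
  fae_events(fly_id = "f1", day_index = 1L, onset_zt_s = onsets,
             duration_s = durations, label = labels)
}

test_that("the band filter keeps durations inside both inclusive edges", {
  ev <- events_with_durations(c(1L, 5L, 7L, 50L, 300L, 301L))
  ev <- apply_band_filter(ev, event_filter(7, 300))
  expect_equal(ev$duration_s[ev$retained], c(7L, 50L, 300L))
  idx <- compute_indices(ev)
  expect_equal(idx$faen, 3L)
  expect_equal(idx$faert_s, 357L)
})

test_that("a 1-to-infinity band retains everything", {
  ev <- events_with_durations(c(1L, 2L, 500L, 10000L))
  ev <- apply_band_filter(ev, event_filter(1, Inf))
  expect_true(all(ev$retained))
})

test_that("band filtering is idempotent", {
  set.seed(5)
  ev <- random_labeled_events(80)
  once <- apply_band_filter(ev, event_filter(7, 300))
  twice <- apply_band_filter(once, event_filter(7, 300))
  expect_identical(once, twice)
})

test_that("invalid band edges are rejected", {
  expect_error(event_filter(0, 300))
  expect_error(event_filter(10, 9))
})

test_that("annotations label events within the onset tolerance", {
  ev <- fae_events(fly_id = "A", day_index = 1L,
                   onset_zt_s = c(100L, 200L, 300L),
                   duration_s = c(10L, 5L, 8L))
  ann <- data.frame(fly_id = "A", day = 1L,
                    onset_zt_s = c(100L, 201L, 300L),
                    label = c("feeding", "no_feeding", "feeding"),
                    stringsAsFactors = FALSE)
  res <- merge_annotations(ev, ann, tolerance_s = 1)
  expect_equal(res$events$label, c("feeding", "no_feeding", "feeding"))
  expect_equal(nrow(res$unmatched), 0)
})

test_that("annotations beyond tolerance are reported, not fatal", {
  ev <- fae_events(fly_id = "A", day_index = 1L, onset_zt_s = 100L,
                   duration_s = 10L)
  ann <- data.frame(fly_id = "A", day = 1L, onset_zt_s = c(100L, 5000L),
                    label = c("feeding", "feeding"),
                    stringsAsFactors = FALSE)
  res <- merge_annotations(ev, ann)
  expect_equal(nrow(res$unmatched), 1)
  expect_equal(res$unmatched$onset_zt_s, 5000L)
})

test_that("two annotations for one event are a hard error", {
  ev <- fae_events(fly_id = "A", day_index = 1L, onset_zt_s = 100L,
                   duration_s = 10L)
  ann <- data.frame(fly_id = "A", day = 1L, onset_zt_s = c(100L, 101L),
                    label = c("feeding", "no_feeding"),
                    stringsAsFactors = FALSE)
  expect_error(merge_annotations(ev, ann), "duplicate annotation")
})

test_that("proportion tables match hand-computed shares", {
  ev <- events_with_durations(c(8L, 12L, 2L, 2L),
                              c("feeding", "feeding",
                                "no_feeding", "no_feeding"))
  tab <- proportion_table(ev)
  cell <- function(bin, lab) tab[tab$bin == bin & tab$label == lab, ]
  expect_equal(cell("1-3", "no_feeding")$share_n, 0.5)
  expect_equal(cell("7-9", "feeding")$share_n, 0.25)
  expect_equal(cell(">=10", "feeding")$share_n, 0.25)
  expect_equal(attr(tab, "total_n"), 4L)
  expect_equal(attr(tab, "total_rt_s"), 24L)

  single <- proportion_table(events_with_durations(5L, "feeding"))
  expect_equal(single[single$bin == "4-6" & single$label == "feeding",
                      "share_n"], 1)
  expect_equal(sum(single$share_n[!(single$bin == "4-6" &
                                      single$label == "feeding")]), 0)
})

test_that("proportion shares sum to one for counts and residence time", {
  set.seed(9)
  for (i in 1:10) {
    tab <- proportion_table(random_labeled_events(60))
    expect_equal(sum(tab$share_n), 1, tolerance = 1e-9)
    expect_equal(sum(tab$share_rt), 1, tolerance = 1e-9)
  }
})

test_that("proportion tables equal the exhaustive tally", {
  set.seed(10)
  for (i in 1:10) {
    ev <- random_labeled_events(100)
    tab <- proportion_table(ev)
    tab$bin_i <- as.integer(tab$bin)
    tab <- tab[order(tab$label, tab$bin_i), ]
    oracle <- brute_proportions(ev)
    oracle <- oracle[order(oracle$label, oracle$bin), ]
    for (col in c("n_events", "rt_s", "share_n", "share_rt")) {
      expect_equal(unname(tab[[col]]), unname(oracle[[col]]))
    }
  }
})

test_that("unlabeled-only event sets cannot be tabulated", {
  ev <- events_with_durations(c(5L, 9L))
  expect_error(proportion_table(ev), "labeled")
})

test_that("threshold sweeps match hand-worked retentions", {
  ev <- events_with_durations(c(8L, 12L, 2L, 9L),
                              c("feeding", "feeding",
                                "no_feeding", "no_feeding"))
  sw <- sweep_thresholds(ev, 2:9, 300)
  expect_equal(nrow(sw), 8)
  at <- function(t) sw[sw$threshold_s == t, ]
  expect_equal(at(9)$feeding_event_retention, 0.5)
  expect_equal(at(9)$no_feeding_event_retention, 0.5)
  expect_equal(at(3)$feeding_event_retention, 1.0)
  expect_equal(at(3)$no_feeding_event_retention, 0.5)
})

test_that("all-long event sets retain everything at every threshold", {
  ev <- events_with_durations(c(20L, 30L, 40L, 50L),
                              c("feeding", "no_feeding",
                                "feeding", "no_feeding"))
  sw <- sweep_thresholds(ev, 2:9, 300)
  expect_true(all(sw$feeding_event_retention == 1))
  expect_true(all(sw$no_feeding_rt_retention == 1))
})

test_that("sweeps require both label classes", {
  ev <- events_with_durations(c(5L, 9L), "feeding")
  expect_error(sweep_thresholds(ev), "no_feeding")
})

test_that("retention fractions are monotone non-increasing in threshold", {
  set.seed(12)
  for (i in 1:15) {
    sw <- sweep_thresholds(random_labeled_events(70), 2:9, 300)
    for (col in c("feeding_event_retention", "no_feeding_event_retention",
                  "feeding_rt_retention", "no_feeding_rt_retention")) {
      expect_true(all(diff(sw[[col]]) <= 1e-12))
      expect_true(all(sw[[col]] >= 0 & sw[[col]] <= 1))
    }
  }
})

test_that("the 7-s cut-off eliminates more no-feeding than feeding signal", {
  sim <- simulate_cohort(simulation_config(seed = 301, n_flies = 10,
                                           n_days = 1),
                         render_traces = FALSE)
  ev <- fae_events(fly_id = sim$truth$fly_id, day_index = sim$truth$day,
                   onset_zt_s = sim$truth$onset_zt_s,
                   duration_s = sim$truth$duration_s,
                   label = sim$truth$label)
  sw <- sweep_thresholds(ev, 7, 300)
  # no-feeding elimination exceeds feeding elimination, for counts and time
  expect_gt(1 - sw$no_feeding_event_retention,
            1 - sw$feeding_event_retention)
  expect_gt(1 - sw$no_feeding_rt_retention, 1 - sw$feeding_rt_retention)
})
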