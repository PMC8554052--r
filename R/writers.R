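# The three per-fly output tables and their readers, plus annotation,
# sweep-report and group-curve CSV round-trips. All files are RFC-4180 CSV,
# UTF-8, with deterministic column order; hour columns are ZT00-ZT23.

hour_cols <- sprintf("ZT%02d", 0:23)

hourly_to_wide <- function(hourly, value_col) {
  keys <- unique(hourly[, c("fly_id", "day_index")])
  keys <- keys[order(keys$fly_id, keys$day_index), , drop = FALSE]
  wide <- data.frame(fly_id = keys$fly_id, day = keys$day_index,
                     stringsAsFactors = FALSE)
  m <- matrix(0L, nrow = nrow(keys), ncol = 24,
              dimnames = list(NULL, hour_cols))
  for (i in seq_len(nrow(keys))) {
    h <- hourly[hourly$fly_id == keys$fly_id[i] &
                  hourly$day_index == keys$day_index[i], , drop = FALSE]
    m[i, h$hour + 1L] <- as.integer(h[[value_col]])
  }
  cbind(wide, as.data.frame(m))
}

write_wide_csv <- function(wide, path) {
  ok <- tryCatch({
    utils::write.csv(wide, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok || !file.exists(path)) stop("cannot write file: ", path)
  invisible(wide)
}

#' Write and read the three per-fly output tables
#'
#' `Activity.csv` holds the hourly event count (FAEn) per fly-day, one row
#' per fly-day with columns `fly_id`, `day`, `ZT00`-`ZT23`. `Feeding.csv`
#' has the same shape with the hourly residence time (FAErt, seconds).
#' `FeedingPDF.csv` lists every event (`fly_id`, `day`, `onset_zt_s`,
#' `duration_s`, `label`, `retained`) — retained and rejected alike, so the
#' unfiltered duration distribution stays recoverable from one file. Each
#' writer has a matching reader that inverts it exactly.
#'
#' @param hourly a [hourly_summarize()] result.
#' @param events a [fae_events()] table.
#' @param path output file path.
#' @return Writers return the written data frame invisibly; readers return
#'   the corresponding table.
#' @name output_tables
NULL

#' @rdname output_tables
#' @export
write_activity_csv <- function(hourly, path) {
  write_wide_csv(hourly_to_wide(hourly, "faen"), path)
}

#' @rdname output_tables
#' @export
read_activity_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        check.names = FALSE,
                        colClasses = c(fly_id = "character"))
  stopifnot(identical(names(df), c("fly_id", "day", hour_cols)))
  df
}

#' @rdname output_tables
#' @export
write_feeding_csv <- function(hourly, path) {
  write_wide_csv(hourly_to_wide(hourly, "faert_s"), path)
}

#' @rdname output_tables
#' @export
read_feeding_csv <- function(path) read_activity_csv(path)

#' @rdname output_tables
#' @export
write_feeding_pdf_csv <- function(events, path) {
  cols <- c("fly_id", "day_index", "onset_zt_s", "duration_s", "label",
            "retained")
  out <- as.data.frame(events)[, cols]
  names(out)[2] <- "day"
  write_wide_csv(out, path)
}

#' @rdname output_tables
#' @export
read_feeding_pdf_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(fly_id = "character"))
  fae_events(fly_id = df$fly_id, day_index = df$day,
             onset_zt_s = df$onset_zt_s, duration_s = df$duration_s,
             label = df$label, retained = df$retained)
}

#' Read and write annotation tables
#'
#' Annotations are CSV with columns `fly_id`, `day`, `onset_zt_s`, `label`
#' (`feeding` / `no_feeding`), as consumed by [merge_annotations()]. The
#' simulator's ground truth is written in the same schema (with an extra
#' `duration_s` column, which the reader preserves when present).
#'
#' @param path file path.
#' @param annotations annotation data frame.
#' @return `read_annotations_csv()` returns a data frame.
#' @export
read_annotations_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(fly_id = "character"))
  need <- c("fly_id", "day", "onset_zt_s", "label")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("annotation CSV lacks columns: ",
                         paste(miss, collapse = ", "))
  df
}

#' @rdname read_annotations_csv
#' @export
write_annotations_csv <- function(annotations, path) {
  write_wide_csv(as.data.frame(annotations), path)
}

#' Read and write threshold-sweep reports
#'
#' One row per candidate threshold with the four retention fractions, as
#' produced by [sweep_thresholds()].
#'
#' @param sweep a [sweep_thresholds()] result.
#' @param path file path.
#' @export
write_sweep_csv <- function(sweep, path) {
  write_wide_csv(as.data.frame(sweep), path)
}

#' @rdname write_sweep_csv
#' @export
read_sweep_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read and write group hourly curves
#'
#' One row per (group, metric, hour) with mean, SEM and n, as produced by
#' [group_aggregate()].
#'
#' @param curve a [group_aggregate()] result.
#' @param path file path.
#' @export
write_group_curve_csv <- function(curve, path) {
  write_wide_csv(as.data.frame(curve), path)
}

#' @rdname write_group_curve_csv
#' @export
read_group_curve_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Plot a group curve
#'
#' Thin convenience layer over ggplot2 (no pixel-level contract): hourly
#' group mean with a +/- SEM ribbon, one panel per metric.
#'
#' @param curve a [group_aggregate()] result.
#' @param metrics metrics to show.
#' @return A ggplot object.
#' @export
plot_group_curve <- function(curve, metrics = c("faen", "faert_s")) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_group_curve needs the ggplot2 package")
  }
  d <- curve[curve$metric %in% metrics, , drop = FALSE]
  d$lo <- d$mean - d$sem
  d$hi <- d$mean + d$sem
  ggplot2::ggplot(d, ggplot2::aes(x = .data$hour, y = .data$mean,
                                  colour = .data$group,
                                  fill = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "ZT (h)", y = "mean ± SEM")
}
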