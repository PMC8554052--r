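# Minimal centroid tracker for grayscale frame stacks: median-frame
# background subtraction followed by an intensity-weighted centroid inside a
# per-tube ROI, projected onto the tube axis. This is deliberately simple
# plumbing for single dark flies on a bright background.

#' Extract a position trace from a grayscale frame stack
#'
#' The background is the per-pixel median across the stack; each frame's
#' foreground is the background minus the frame, clipped at zero (a dark fly
#' on a bright background). Inside the ROI, the fly position is the
#' foreground-intensity-weighted centroid projected onto the tube axis,
#' returned in the package's 0-based pixel convention (0 at the low edge of
#' the frame along the axis). Frames whose peak foreground stays below
#' `threshold` contain no detectable fly and become missing samples.
#'
#' @param frames 3-D numeric array `[rows, cols, n_frames]` (or a list of
#'   equal-size matrices), 8- or 16-bit grayscale values.
#' @param roi rectangle `list(row = c(r0, r1), col = c(c0, c1))` (1-based,
#'   inclusive) bounding one tube; default the whole frame.
#' @param axis `"col"` if the tube runs along columns (x, default) or
#'   `"row"`.
#' @param threshold minimum peak foreground intensity for a detection.
#' @param fly_id,start_zt passed to [position_trace()].
#' @return A [position_trace()].
#' @export
extract_positions_from_frames <- function(frames, roi = NULL,
                                          axis = c("col", "row"),
                                          threshold = 10,
                                          fly_id = "fly", start_zt = 0L) {
  axis <- match.arg(axis)
  if (is.list(frames)) {
    frames <- simplify2array(frames)
  }
  if (length(dim(frames)) != 3 || dim(frames)[3] == 0) {
    stop("frames must be a non-empty stack of equal-size grayscale images")
  }
  d <- dim(frames)
  if (is.null(roi)) roi <- list(row = c(1L, d[1]), col = c(1L, d[2]))
  if (roi$row[1] < 1 || roi$row[2] > d[1] ||
      roi$col[1] < 1 || roi$col[2] > d[2]) {
    stop("roi outside frame bounds")
  }
  rows <- seq.int(roi$row[1], roi$row[2])
  cols <- seq.int(roi$col[1], roi$col[2])
  sub <- frames[rows, cols, , drop = FALSE]
  # per-pixel temporal median, floored at the global median intensity so a
  # fly that never moves is not absorbed into its own background estimate
  bg <- apply(sub, c(1, 2), stats::median)
  bg <- pmax(bg, stats::median(sub))
  n <- d[3]
  pos <- rep(NA_real_, n)
  for (t in seq_len(n)) {
    fg <- bg - sub[, , t]
    # sub-threshold residuals (noise) carry no weight in the centroid
    fg[fg < threshold] <- 0
    if (max(fg) <= 0) next
    if (axis == "col") {
      w <- colSums(fg)
      pos[t] <- sum(w * (cols - 1)) / sum(w)
    } else {
      w <- rowSums(fg)
      pos[t] <- sum(w * (rows - 1)) / sum(w)
    }
  }
  position_trace(pos, fly_id = fly_id, start_zt = start_zt)
}
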