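# Black level and baseline fluorescence (F0) -----------------------------
#
# Two-stage baseline machinery: (1) a per-frame "black" set-point estimated
# from a region known to have zero fluorescence (e.g. a blood-vessel lumen),
# subtracted from all signals before anything else; (2) a per-pixel baseline
# distribution (mean F0 and its s.d.) estimated from chosen source frames
# (typically blank periods) and assigned to a half-open range of stack
# frames per channel. dF/F0 and FRET channel ratios build on these.

#' Estimate the per-frame black level from a zero-fluorescence region
#'
#' For every frame the black level is the mean raw value over the given
#' pixels of the chosen channel. The resulting trace is attached to the
#' stack and subtracted by all processed-frame access.
#'
#' The per-frame trace exists to track slow drifts of the detector offset.
#' When the recording's set-point is stable, re-estimating it every frame
#' only injects region-sampling noise into every downstream dF/F0 value;
#' `statistic = "constant"` instead assigns the median of the per-frame
#' means as a single set-point for the whole stack.
#'
#' @param stack a `stim_stack`.
#' @param pixel_indices 1-based linear pixel indices into the (rows x cols)
#'   frame grid, column-major.
#' @param channel channel measured.
#' @param assign attach the trace via [set_black_trace()].
#' @param statistic `"frame"` for the per-frame trace, `"constant"` for a
#'   stack-wide median set-point.
#' @return numeric vector of per-frame black levels (class `black_trace`).
#' @export
define_black_region <- function(stack, pixel_indices, channel = 1,
                                assign = TRUE,
                                statistic = c("frame", "constant")) {
  statistic <- match.arg(statistic)
  d <- dim(stack$data)
  pixel_indices <- as.integer(pixel_indices)
  if (length(pixel_indices) == 0)
    calima_error("calima_value_error", "black region must contain >= 1 pixel")
  if (any(pixel_indices < 1 | pixel_indices > d[1] * d[2]))
    calima_error("calima_bounds_error",
                 "black region pixel index outside the %dx%d frame", d[1], d[2])
  nf <- d[3]
  trace <- numeric(nf)
  chunk <- max(1L, min(nf, floor(4e6 / (d[1] * d[2]))))
  for (start in seq(1L, nf, by = chunk)) {
    idx <- start:min(nf, start + chunk - 1L)
    arr <- read_region(stack$data, list(NULL, NULL, idx, channel))
    flat <- matrix(arr, nrow = d[1] * d[2])
    trace[idx] <- colMeans(flat[pixel_indices, , drop = FALSE])
  }
  if (statistic == "constant") trace <- rep(stats::median(trace), nf)
  class(trace) <- c("black_trace", class(trace))
  if (assign) set_black_trace(stack, as.numeric(trace))
  trace
}

#' Estimate a per-pixel baseline distribution and assign it to frames
#'
#' The baseline mean frame is the per-pixel mean over the source frames of
#' the aligned, black-subtracted values; the s.d. frame is the per-pixel
#' sample (n-1) standard deviation. The entry covers the half-open target
#' frame range `[target_range[1], target_range[2])` for one channel; ranges
#' of different entries must not overlap within a channel.
#'
#' @param stack a `stim_stack`.
#' @param source_frames >= 2 frame indices to estimate from (typically blank
#'   frames).
#' @param target_range integer `c(first, one_past_last)`, 1-based half-open.
#' @param channel channel the entry applies to.
#' @return the new baseline entry (list with `range`, `channel`, `mean`,
#'   `sd`), invisibly; the entry is appended to `stack$baseline`.
#' @export
assign_blank_frames <- function(stack, source_frames, target_range,
                                channel = 1) {
  source_frames <- as.integer(source_frames)
  if (length(source_frames) < 2)
    calima_error("calima_value_error",
                 "need >= 2 source frames to estimate the baseline s.d.")
  target_range <- as.integer(target_range)
  if (length(target_range) != 2 || target_range[1] >= target_range[2])
    calima_error("calima_value_error",
                 "target_range must be c(first, one_past_last) with first < one_past_last")
  for (e in stack$baseline) {
    if (e$channel == channel &&
        target_range[1] < e$range[2] && e$range[1] < target_range[2])
      calima_error("calima_overlap_error",
                   "target range [%d, %d) overlaps existing baseline entry [%d, %d) on channel %d",
                   target_range[1], target_range[2], e$range[1], e$range[2],
                   channel)
  }
  frames <- get_frames(stack, source_frames, channel, processed = TRUE)
  n <- length(source_frames)
  mu <- apply(frames, c(1, 2), mean)
  sdv <- sqrt(apply(frames, c(1, 2), stats::var))
  entry <- list(range = target_range, channel = channel, mean = mu, sd = sdv,
                source_frames = source_frames)
  stack$baseline <- c(stack$baseline, list(entry))
  invisible(entry)
}

#' Baseline frames covering given stack frames
#'
#' @param stack a `stim_stack` with baseline entries assigned.
#' @param frames 1-based frame indices.
#' @param channel channel.
#' @return list with `mean` and `sd`: lists (one element per requested
#'   frame) of per-pixel matrices, plus `entry_index` per frame.
#' @export
get_blank_frames <- function(stack, frames, channel = 1) {
  frames <- as.integer(frames)
  which_entry <- integer(length(frames))
  for (k in seq_along(frames)) {
    hit <- 0L
    for (i in seq_along(stack$baseline)) {
      e <- stack$baseline[[i]]
      if (e$channel == channel && frames[k] >= e$range[1] &&
          frames[k] < e$range[2]) { hit <- i; break }
    }
    if (hit == 0L)
      calima_error("calima_baseline_error",
                   "no baseline assignment covers frame %d (channel %d)",
                   frames[k], channel)
    which_entry[k] <- hit
  }
  list(mean = lapply(which_entry, function(i) stack$baseline[[i]]$mean),
       sd = lapply(which_entry, function(i) stack$baseline[[i]]$sd),
       entry_index = which_entry)
}

#' Differential fluorescence response dF/F0
#'
#' Both arguments must already be black-subtracted. Where `F0 <= 0` the
#' response is undefined and `NA` is returned for that element (with a
#' warning summarising how many).
#'
#' @param f fluorescence value(s).
#' @param f0 baseline fluorescence value(s).
#' @return `(f - f0) / f0`, elementwise.
#' @export
dff <- function(f, f0) {
  bad <- !is.na(f0) & f0 <= 0
  if (any(bad)) {
    f0[bad] <- NA
    calima_warning("calima_baseline_warning",
                   "%d element(s) had F0 <= 0; dF/F0 undefined there (NA)",
                   sum(bad))
  }
  (f - f0) / f0
}

#' FRET channel ratio
#'
#' Ratio of two black-subtracted channel signals. Where the denominator is
#' `<= 0` the ratio is undefined and `NA` is returned.
#'
#' @param fa numerator channel value(s).
#' @param fb denominator channel value(s).
#' @export
channel_ratio <- function(fa, fb) {
  bad <- !is.na(fb) & fb <= 0
  if (any(bad)) {
    fb[bad] <- NA
    calima_warning("calima_baseline_warning",
                   "%d element(s) had denominator <= 0; ratio undefined there (NA)",
                   sum(bad))
  }
  fa / fb
}

#' Write / read a baseline store
#'
#' One directory per stack: a JSON index of entries (half-open frame ranges,
#' channels, source frames) plus one little-endian f64 file per entry
#' holding the mean frame followed by the s.d. frame.
#'
#' @param stack a `stim_stack` with baseline entries.
#' @param dir directory to create/read.
#' @rdname baseline_io
#' @export
write_baseline_store <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(stack$data)
  index <- lapply(seq_along(stack$baseline), function(i) {
    e <- stack$baseline[[i]]
    fn <- sprintf("baseline_%03d.bin", i)
    con <- file(file.path(dir, fn), "wb")
    writeBin(as.double(e$mean), con, endian = "little")
    writeBin(as.double(e$sd), con, endian = "little")
    close(con)
    list(file = fn, range = e$range, channel = e$channel,
         source_frames = e$source_frames)
  })
  jsonlite::write_json(list(n_rows = d[1], n_cols = d[2], entries = index),
                       file.path(dir, "index.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname baseline_io
#' @export
read_baseline_store <- function(stack, dir) {
  j <- jsonlite::fromJSON(file.path(dir, "index.json"),
                          simplifyDataFrame = FALSE)
  np <- j$n_rows * j$n_cols
  stack$baseline <- lapply(j$entries, function(e) {
    con <- file(file.path(dir, e$file), "rb")
    mu <- matrix(readBin(con, "double", np, endian = "little"),
                 j$n_rows, j$n_cols)
    sdv <- matrix(readBin(con, "double", np, endian = "little"),
                  j$n_rows, j$n_cols)
    close(con)
    list(range = unlist(e$range), channel = e$channel, mean = mu, sd = sdv,
         source_frames = unlist(e$source_frames))
  })
  invisible(stack)
}
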