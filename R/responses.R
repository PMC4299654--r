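# Derandomised trial response extraction ----------------------------------
#
# The workhorse of the toolchain: averages processed pixel values within
# each ROI into per-frame traces, regroups frames acquired under randomised
# stimulus order into per-stimulus, per-trial segments, applies a response
# measure (mean / peak / FRET ratio, on raw or dF/F0 signals) inside each
# stimulus's analysis-use window, and assembles trial-average matrices and
# PSTHs.

#' Extract per-ROI fluorescence traces
#'
#' For every frame, processed pixel values (re-registered and
#' black-subtracted) are averaged over each ROI's valid pixels; pixels
#' marked invalid by shift borders are excluded rather than zero-filled. A
#' frame in which an ROI has no valid pixel yields `NA`.
#'
#' @param stack a `stim_stack`.
#' @param rois a [roi_set()] matching the stack's frame dimensions.
#' @param channels channels to extract (default: all).
#' @param processed use aligned, black-subtracted frames (default) or raw.
#' @return list with `values` (n_rois x n_frames x n_channels array) and
#'   `frame_info` (the full [frame_stimulus_info()] table).
#' @export
extract_region_traces <- function(stack, rois, channels = NULL,
                                  processed = TRUE) {
  d <- dim(stack$data)
  if (length(rois) == 0)
    calima_error("calima_value_error", "roi set is empty")
  if (any(rois$dims != d[1:2]))
    calima_error("calima_dimension_error",
                 "roi grid %dx%d does not match stack frames %dx%d",
                 rois$dims[1], rois$dims[2], d[1], d[2])
  if (is.null(channels)) channels <- seq_len(d[4])
  nf <- d[3]
  values <- array(NA_real_, dim = c(length(rois), nf, length(channels)))
  chunk <- max(1L, min(nf, floor(4e6 / (d[1] * d[2]))))
  for (ci in seq_along(channels)) {
    for (start in seq(1L, nf, by = chunk)) {
      idx <- start:min(nf, start + chunk - 1L)
      fr <- get_frames(stack, idx, channels[ci], processed = processed)
      flat <- matrix(fr, nrow = d[1] * d[2])
      for (ri in seq_along(rois$regions))
        values[ri, idx, ci] <-
          colMeans(flat[rois$regions[[ri]], , drop = FALSE], na.rm = TRUE)
    }
  }
  values[is.nan(values)] <- NA
  list(values = values, frame_info = frame_stimulus_info(stack))
}

#' Derandomise frames into per-stimulus trials
#'
#' Builds the injective mapping (stimulus, trial, frame-in-trial) -> global
#' frame. Trials of each stimulus are numbered by presentation time, so
#' composing the mapping with the recorded presentation order reproduces the
#' original randomised frame sequence.
#'
#' @param frame_info a [frame_stimulus_info()] table covering the stack.
#' @param timeline the stack's presentation timeline ([build_timeline()]).
#' @return data.frame with columns `stim_id`, `trial`, `frame_in_trial`,
#'   `frame` (global, 1-based) and `presentation`.
#' @export
derandomize <- function(frame_info, timeline) {
  if (nrow(timeline) == 0)
    return(data.frame(stim_id = integer(0), trial = integer(0),
                      frame_in_trial = integer(0), frame = integer(0),
                      presentation = integer(0)))
  tl <- timeline[order(timeline$t_start), ]
  trial_of_pres <- stats::ave(tl$stim_id, tl$stim_id, FUN = seq_along)
  trial_lut <- integer(max(tl$presentation))
  trial_lut[tl$presentation] <- trial_of_pres
  fi <- frame_info[!is.na(frame_info$presentation_index), ]
  fi <- fi[order(fi$frame), ]
  if (nrow(fi) == 0)
    return(data.frame(stim_id = integer(0), trial = integer(0),
                      frame_in_trial = integer(0), frame = integer(0),
                      presentation = integer(0)))
  fit <- stats::ave(fi$frame, fi$presentation_index, FUN = seq_along)
  out <- data.frame(stim_id = fi$stim_seq_id,
                    trial = trial_lut[fi$presentation_index],
                    frame_in_trial = as.integer(fit),
                    frame = fi$frame,
                    presentation = fi$presentation_index)
  out[order(out$stim_id, out$trial, out$frame_in_trial), ]
}

roi_baseline_means <- function(stack, rois, channel) {
  # per (entry, roi): mean baseline F0 over the ROI's pixels
  vapply(stack$baseline, function(e) {
    if (e$channel != channel) return(rep(NA_real_, length(rois)))
    vapply(rois$regions, function(r) mean(e$mean[r], na.rm = TRUE),
           numeric(1))
  }, numeric(length(rois)))
}

#' Extract derandomised per-trial stimulus responses
#'
#' Per (ROI, stimulus, trial): the trace is restricted to frames inside the
#' stimulus's analysis-use window, optionally converted frame-by-frame to
#' dF/F0 using the baseline assignment covering each frame, and summarised
#' by the response measure: `"mean"` (window average), `"peak"` (window
#' maximum of the unsmoothed trace) or `"ratio"` (mean of the channel-ratio
#' trace of `ratio_channels`). PSTHs cover the whole presentation, not just
#' the use window.
#'
#' @param stack a `stim_stack` with its stimulus protocol; baseline entries
#'   must cover all analysed frames when `scale = "dff"`.
#' @param rois a [roi_set()].
#' @param measure `"mean"`, `"peak"` or `"ratio"`.
#' @param scale `"raw"` or `"dff"`.
#' @param channel channel for mean/peak measures.
#' @param ratio_channels numerator and denominator channels for the ratio
#'   measure.
#' @return a `response_matrix`: list with `responses` (n_rois x n_stimuli x
#'   n_trials, `NA`-padded), `trial_avg` (n_rois x n_stimuli), `psth` (per
#'   stimulus, n_rois x min-trial-length), `trial_traces` (nested
#'   stimulus/trial list of n_rois x n_frames segments), `t_frame` (s) and
#'   the measure/scale used.
#' @export
extract_region_responses <- function(stack, rois,
                                     measure = c("mean", "peak", "ratio"),
                                     scale = c("raw", "dff"),
                                     channel = 1, ratio_channels = c(1, 2)) {
  measure <- match.arg(measure)
  scale <- match.arg(scale)
  channels <- if (measure == "ratio") ratio_channels else channel
  tr <- extract_region_traces(stack, rois, channels = channels)
  fi <- tr$frame_info
  map <- derandomize(fi, stack$timeline)
  if (nrow(map) == 0)
    calima_error("calima_value_error", "stack has no tagged stimulus frames")
  n_rois <- length(rois)
  n_stim <- max(attr(stack$timeline, "n_stimuli"), map$stim_id)
  use_lut <- fi$use_frame[order(fi$frame)]

  # per-frame ROI trace for the measure
  if (measure == "ratio") {
    num <- tr$values[, , 1, drop = FALSE][, , 1]
    den <- tr$values[, , 2, drop = FALSE][, , 1]
    trace <- suppressWarnings(channel_ratio(num, den))
  } else {
    trace <- tr$values[, , 1, drop = FALSE][, , 1]
  }
  trace <- matrix(trace, nrow = n_rois)

  if (scale == "dff") {
    if (length(stack$baseline) == 0)
      calima_error("calima_baseline_error",
                   "scale = \"dff\" requires baseline assignments (assign_blank_frames)")
    frames_used <- sort(unique(map$frame))
    cover <- get_blank_frames(stack, frames_used, channels[1])
    entry_of_frame <- integer(dim(stack$data)[3])
    entry_of_frame[frames_used] <- cover$entry_index
    f0a <- roi_baseline_means(stack, rois, channels[1])
    f0a <- matrix(f0a, nrow = n_rois)
    if (measure == "ratio") {
      f0b <- matrix(roi_baseline_means(stack, rois, channels[2]),
                    nrow = n_rois)
      f0a <- f0a / f0b                     # baseline of the ratio trace
    }
    f0_frame <- f0a[, entry_of_frame[map$frame], drop = FALSE]
    # dF/F0 applied frame-by-frame before the measure
    tagged <- trace[, map$frame, drop = FALSE]
    tagged <- (tagged - f0_frame) / f0_frame
  } else {
    tagged <- trace[, map$frame, drop = FALSE]
  }

  trials_per_stim <- tapply(map$trial, map$stim_id, max)
  n_trials <- max(trials_per_stim)
  responses <- array(NA_real_, dim = c(n_rois, n_stim, n_trials))
  trial_traces <- rep(list(list()), n_stim)
  key <- paste(map$stim_id, map$trial)
  groups <- split(seq_len(nrow(map)), key)
  n_empty <- 0L
  for (g in groups) {
    s <- map$stim_id[g[1]]; t <- map$trial[g[1]]
    seg <- tagged[, g, drop = FALSE]
    trial_traces[[s]][[t]] <- seg
    in_use <- use_lut[map$frame[g]]
    win <- seg[, in_use, drop = FALSE]
    if (ncol(win) == 0 || all(is.na(win))) {
      n_empty <- n_empty + 1L
      next
    }
    responses[, s, t] <- switch(measure,
      mean = rowMeans(win, na.rm = TRUE),
      peak = apply(win, 1, max, na.rm = TRUE),
      ratio = rowMeans(win, na.rm = TRUE))
  }
  if (n_empty > 0)
    calima_warning("calima_response_warning",
                   "%d trial(s) had no usable frames; responses set to NA",
                   n_empty)
  responses[is.infinite(responses) | is.nan(responses)] <- NA
  trial_avg <- apply(responses, c(1, 2), function(v)
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
  rm <- structure(list(responses = responses, trial_avg = trial_avg,
                       trial_traces = trial_traces,
                       measure = measure, scale = scale,
                       t_frame = stack$header$t_frame_duration,
                       n_stimuli = n_stim), class = "response_matrix")
  rm$psth <- psth(rm)
  rm
}

#' Peri-stimulus time histograms
#'
#' Frame-wise mean across trials of each stimulus's single-trial segments,
#' after truncating all trials of a stimulus to their minimum frame count.
#'
#' @param x a `response_matrix`.
#' @return list (one element per stimulus) of n_rois x n_frames matrices;
#'   frame `k` is centred `(k - 1) * t_frame` seconds after stimulus onset.
#' @export
psth <- function(x) {
  lapply(x$trial_traces, function(trials) {
    trials <- Filter(Negate(is.null), trials)
    if (length(trials) == 0) return(NULL)
    len <- min(vapply(trials, ncol, integer(1)))
    acc <- 0
    for (tt in trials) acc <- acc + tt[, seq_len(len), drop = FALSE]
    acc / length(trials)
  })
}

#' @export
print.response_matrix <- function(x, ...) {
  d <- dim(x$responses)
  cat(sprintf("<response_matrix: %d ROI(s) x %d stimuli x %d trial(s); measure=%s scale=%s>\n",
              d[1], d[2], d[3], x$measure, x$scale))
  invisible(x)
}

#' Write responses in long format
#'
#' External format: CSV with columns `roi`, `stimulus`, `trial`, `measure`,
#' `scale`, `value` (0-based roi index).
#'
#' @param rm a `response_matrix`; `path` a CSV file.
#' @export
write_responses_csv <- function(rm, path) {
  d <- dim(rm$responses)
  df <- expand.grid(roi = seq_len(d[1]) - 1L, stimulus = seq_len(d[2]),
                    trial = seq_len(d[3]))
  df$measure <- rm$measure
  df$scale <- rm$scale
  df$value <- as.vector(rm$responses)
  utils::write.csv(df[!is.na(df$value), ], path, row.names = FALSE)
  invisible(path)
}
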