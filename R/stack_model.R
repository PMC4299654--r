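# Stimulus-aware stack object --------------------------------------------
#
# A stim_stack couples a lazy pixel tensor with acquisition calibration and
# the stimulus protocol: which stimulus sequence ran in each data block, how
# long each stimulus lasted, how much blank time separated presentations,
# and which window of each presentation should enter analysis. From these
# the presentation timeline is derived and every frame can be tagged with
# the stimulus being shown while it was acquired.

#' Construct a stack header
#'
#' The header carries everything needed to interpret a multi-file stack:
#' geometry, element type, spatial/temporal calibration, and the stimulus
#' protocol. It is stored as a single JSON sidecar shared by all data blocks
#' (see [write_stack_header()]); field names below follow the package's
#' external header format documented in the vignette.
#'
#' @param n_rows,n_cols,n_channels frame geometry.
#' @param dtype element type (`"u8"`, `"u16"`, `"i16"`, `"f32"`, `"f64"`).
#' @param frames_per_file integer vector, frames in each data block file.
#' @param f_pixels_per_um spatial calibration, pixels per micrometre.
#' @param t_frame_duration acquisition time per frame, seconds.
#' @param f_z_step axial spacing between frames, micrometres.
#' @param t_blank_time blank screen time between stimulus presentations,
#'   seconds.
#' @param sequence_ids_per_block list with one integer vector per block: the
#'   stimulus sequence IDs in the order they were presented in that block.
#' @param stimulus_durations numeric vector; entry `i` is the presentation
#'   duration (s) of stimulus sequence ID `i`.
#' @param use_times numeric matrix (one row per stimulus sequence ID) of
#'   `[t_start, t_stop)` offsets (s) from presentation onset delimiting the
#'   analysis window.
#' @param stimulus_ids_per_block optional integer vector, one block-level
#'   stimulus ID per data file.
#' @param byte_offset offset of pixel data within each raw block file.
#' @return a validated `stack_header` list.
#' @export
stack_header <- function(n_rows, n_cols, n_channels, dtype, frames_per_file,
                         f_pixels_per_um = NA_real_,
                         t_frame_duration = 1 / 7.81,
                         f_z_step = 0,
                         t_blank_time = 0,
                         sequence_ids_per_block = vector("list", length(frames_per_file)),
                         stimulus_durations = numeric(0),
                         use_times = NULL,
                         stimulus_ids_per_block = NULL,
                         byte_offset = 0) {
  n_stim <- length(stimulus_durations)
  if (is.null(use_times)) {
    use_times <- cbind(rep(0, n_stim), stimulus_durations)
  }
  h <- structure(list(
    n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
    n_channels = as.integer(n_channels), dtype = dtype,
    frames_per_file = as.integer(frames_per_file),
    f_pixels_per_um = f_pixels_per_um,
    t_frame_duration = t_frame_duration,
    f_z_step = f_z_step,
    t_blank_time = t_blank_time,
    sequence_ids_per_block = lapply(sequence_ids_per_block, as.integer),
    stimulus_durations = as.numeric(stimulus_durations),
    use_times = matrix(as.numeric(use_times), ncol = 2),
    stimulus_ids_per_block = stimulus_ids_per_block,
    byte_offset = byte_offset
  ), class = "stack_header")
  validate_stack_header(h)
  h
}

validate_stack_header <- function(h) {
  if (h$t_frame_duration <= 0)
    calima_error("calima_validation_error", "t_frame_duration must be > 0")
  if (h$t_blank_time < 0)
    calima_error("calima_validation_error", "t_blank_time must be >= 0")
  if (length(h$stimulus_durations) && any(h$stimulus_durations <= 0))
    calima_error("calima_validation_error", "stimulus durations must be > 0")
  n_stim <- length(h$stimulus_durations)
  if (n_stim) {
    if (nrow(h$use_times) != n_stim)
      calima_error("calima_validation_error",
                   "use_times must have one row per stimulus (have %d, need %d)",
                   nrow(h$use_times), n_stim)
    bad <- h$use_times[, 1] < 0 | h$use_times[, 1] >= h$use_times[, 2] |
      h$use_times[, 2] > h$stimulus_durations + 1e-9
    if (any(bad))
      calima_error("calima_validation_error",
                   "use_times rows must satisfy 0 <= t_start < t_stop <= duration (rows: %s)",
                   paste(which(bad), collapse = ", "))
  }
  if (length(h$sequence_ids_per_block) != length(h$frames_per_file))
    calima_error("calima_validation_error",
                 "sequence_ids_per_block must have one entry per data block")
  ids <- unlist(h$sequence_ids_per_block)
  if (length(ids) && (any(ids < 1) || any(ids > n_stim)))
    calima_error("calima_validation_error",
                 "every sequence ID needs a stimulus_durations entry (IDs 1..%d)",
                 n_stim)
  invisible(h)
}

#' Write / read the JSON sidecar header
#'
#' @param header a [stack_header()].
#' @param path JSON file path.
#' @rdname stack_header_io
#' @export
write_stack_header <- function(header, path) {
  jsonlite::write_json(unclass(header), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname stack_header_io
#' @export
read_stack_header <- function(path) {
  if (!file.exists(path))
    calima_error("calima_io_error", "header file not found: %s", path)
  j <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  ut <- if (length(j$use_times)) do.call(rbind, j$use_times) else NULL
  stack_header(
    n_rows = j$n_rows, n_cols = j$n_cols, n_channels = j$n_channels,
    dtype = j$dtype, frames_per_file = unlist(j$frames_per_file),
    f_pixels_per_um = j$f_pixels_per_um %||% NA_real_,
    t_frame_duration = j$t_frame_duration,
    f_z_step = j$f_z_step %||% 0,
    t_blank_time = j$t_blank_time %||% 0,
    sequence_ids_per_block = lapply(j$sequence_ids_per_block, unlist),
    stimulus_durations = unlist(j$stimulus_durations) %||% numeric(0),
    use_times = ut,
    stimulus_ids_per_block = unlist(j$stimulus_ids_per_block),
    byte_offset = j$byte_offset %||% 0
  )
}

#' Build the stimulus presentation timeline from a header
#'
#' Within each data block, presentations of that block's stimulus sequence
#' are laid back-to-back starting at the time of the block's first frame,
#' each presentation followed by `t_blank_time` of untagged gap. Blocks abut
#' with no additional dead time. Presentation intervals are half-open
#' `[t_start, t_end)`.
#'
#' @param header a [stack_header()].
#' @return data.frame with one row per presentation: `presentation`
#'   (1-based, stack-wide), `stim_id`, `block`, `t_start`, `t_end`; the
#'   number of distinct stimulus IDs is attached as attribute `n_stimuli`.
#' @export
build_timeline <- function(header) {
  dt <- header$t_frame_duration
  block_start <- c(0, cumsum(header$frames_per_file)) * dt
  rows <- list()
  for (b in seq_along(header$frames_per_file)) {
    seq_ids <- header$sequence_ids_per_block[[b]]
    if (length(seq_ids) == 0) next
    durs <- header$stimulus_durations[seq_ids]
    starts <- block_start[b] +
      cumsum(c(0, (durs + header$t_blank_time)[-length(durs)]))
    ends <- starts + durs
    if (ends[length(ends)] > block_start[b + 1] + 1e-9)
      calima_error("calima_timeline_error",
                   "presentations overrun block %d: last ends at %.3f s but the block ends at %.3f s",
                   b, ends[length(ends)], block_start[b + 1])
    rows[[length(rows) + 1]] <- data.frame(
      stim_id = seq_ids, block = b, t_start = starts, t_end = ends)
  }
  tl <- if (length(rows)) do.call(rbind, rows)
        else data.frame(stim_id = integer(0), block = integer(0),
                        t_start = numeric(0), t_end = numeric(0))
  tl <- cbind(presentation = seq_len(nrow(tl)), tl)
  rownames(tl) <- NULL
  attr(tl, "n_stimuli") <- length(unique(unlist(header$sequence_ids_per_block)))
  tl
}

#' Open a multi-file imaging stack with its sidecar header
#'
#' Dispatches on file extension: `.bin`/`.raw`/`.dat` open through the
#' raw-binary backend, `.tif`/`.tiff` through the TIFF backend. The stimulus
#' timeline is built immediately from the header; no pixel data are read.
#'
#' @param paths ordered data block files.
#' @param header_path path to the JSON sidecar header, or an already-parsed
#'   [stack_header()].
#' @return a `stim_stack` object (environment semantics: alignment shifts,
#'   black trace and baseline assignments attach to it in place).
#' @export
open_stack <- function(paths, header_path) {
  header <- if (inherits(header_path, "stack_header")) header_path
            else read_stack_header(header_path)
  ext <- tolower(tools::file_ext(paths[1]))
  if (ext %in% c("bin", "raw", "dat")) {
    data <- open_binary_stack(paths, header)
  } else if (ext %in% c("tif", "tiff")) {
    data <- open_tiff_stack(paths)
    if (data$native_dim[1] != header$n_rows || data$native_dim[2] != header$n_cols ||
        data$native_dim[4] != header$n_channels)
      calima_error("calima_dimension_error",
                   "TIFF geometry %dx%dx%d disagrees with header %dx%dx%d",
                   data$native_dim[1], data$native_dim[2], data$native_dim[4],
                   header$n_rows, header$n_cols, header$n_channels)
    if (data$native_dim[3] != sum(header$frames_per_file))
      calima_error("calima_size_error",
                   "TIFF files hold %d frames but the header declares %d",
                   data$native_dim[3], sum(header$frames_per_file))
  } else {
    calima_error("calima_format_error",
                 "unsupported stack format '.%s' (supported: .bin/.raw/.dat, .tif/.tiff)",
                 ext)
  }
  s <- new.env(parent = emptyenv())
  s$data <- data
  s$header <- header
  s$timeline <- build_timeline(header)
  s$frame_shifts <- NULL
  s$black_trace <- NULL
  s$baseline <- list()
  s$cache_dir <- NULL
  s$shift_compute_count <- 0L
  class(s) <- "stim_stack"
  s
}

#' @export
dim.stim_stack <- function(x) dim(x$data)

#' @export
print.stim_stack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<stim_stack %s %s, %d block(s), %d presentation(s) of %d stimuli>\n",
              paste(d, collapse = "x"), x$data$dtype, nrow(x$data$blocks),
              nrow(x$timeline), attr(x$timeline, "n_stimuli")))
  cat(sprintf("  frame duration %.4f s; blank time %.2f s; shifts %s; black %s; %d baseline entr%s\n",
              x$header$t_frame_duration, x$header$t_blank_time,
              if (is.null(x$frame_shifts)) "unset" else "set",
              if (is.null(x$black_trace)) "unset" else "set",
              length(x$baseline), if (length(x$baseline) == 1) "y" else "ies"))
  invisible(x)
}

n_frames <- function(stack) dim(stack$data)[3]

#' Per-frame stimulus metadata
#'
#' Tags each requested frame with its acquisition time, containing block and
#' presentation. A frame belongs to a presentation when its onset time falls
#' in the half-open interval `[t_start, t_end)`; frames in blank gaps carry
#' `NA` stimulus IDs. `use_frame` is `TRUE` when the frame's time within the
#' stimulus lies inside that stimulus's analysis-use window.
#'
#' Block, frame-in-block and presentation indices are 1-based, matching the
#' stack metadata conventions of the acquisition tables.
#'
#' @param stack a `stim_stack`.
#' @param frames 1-based global frame indices (default: all frames).
#' @return data.frame with columns `frame`, `t_global`, `block_index`,
#'   `frame_in_block`, `t_in_block`, `stim_seq_id`, `t_in_stim`,
#'   `presentation_index`, `use_frame`.
#' @export
frame_stimulus_info <- function(stack, frames = NULL) {
  header_frame_info(stack$header, frames, stack$timeline,
                    n_frames = n_frames(stack))
}

#' Frame metadata as a pure function of the header
#'
#' [frame_stimulus_info()] without a stack object: the same table computed
#' directly from a header and its timeline, since frame tagging depends only
#' on metadata, never on pixel data.
#'
#' @param header a [stack_header()].
#' @param frames 1-based frame indices (default: all declared frames).
#' @param timeline the presentation timeline (default: rebuilt from the
#'   header).
#' @param n_frames total frames (default: sum of `frames_per_file`).
#' @export
header_frame_info <- function(header, frames = NULL,
                              timeline = build_timeline(header),
                              n_frames = sum(header$frames_per_file)) {
  nf <- n_frames
  if (is.null(frames)) frames <- seq_len(nf)
  frames <- as.integer(frames)
  if (any(frames < 1 | frames > nf))
    calima_error("calima_bounds_error", "frame index out of range 1..%d", nf)
  h <- header
  dt <- h$t_frame_duration
  t_global <- (frames - 1) * dt
  ends_f <- cumsum(h$frames_per_file)
  starts_f <- c(0L, ends_f[-length(ends_f)])
  block <- findInterval(frames - 1, ends_f) + 1L
  fib <- frames - starts_f[block]
  tl <- timeline
  stim <- rep(NA_integer_, length(frames))
  pres <- rep(NA_integer_, length(frames))
  t_in_stim <- rep(NA_real_, length(frames))
  use <- rep(FALSE, length(frames))
  if (nrow(tl)) {
    idx <- findInterval(t_global, tl$t_start)
    ok <- idx >= 1 & idx <= nrow(tl)
    ok[ok] <- t_global[ok] < tl$t_end[idx[ok]] - 1e-12
    stim[ok] <- tl$stim_id[idx[ok]]
    pres[ok] <- tl$presentation[idx[ok]]
    t_in_stim[ok] <- t_global[ok] - tl$t_start[idx[ok]]
    ut <- h$use_times
    use[ok] <- t_in_stim[ok] >= ut[stim[ok], 1] - 1e-12 &
               t_in_stim[ok] <  ut[stim[ok], 2] - 1e-12
  }
  data.frame(frame = frames, t_global = t_global, block_index = block,
             frame_in_block = fib, t_in_block = (fib - 1) * dt,
             stim_seq_id = stim, t_in_stim = t_in_stim,
             presentation_index = pres, use_frame = use)
}

#' Read raw or processed frames from a stimulus stack
#'
#' Processed access applies, per frame: sub-pixel re-registration with the
#' negated stored misalignment shift (when shifts are assigned), then
#' subtraction of that frame's black level (when a black trace is assigned).
#' Pixels shifted in from outside the frame are `NA`. Raw access returns the
#' stored dtype values unchanged.
#'
#' @param stack a `stim_stack`.
#' @param frames 1-based global frame indices.
#' @param channel 1-based channel.
#' @param processed logical.
#' @return numeric array (n_rows, n_cols, length(frames)).
#' @export
get_frames <- function(stack, frames, channel = 1, processed = FALSE) {
  d <- dim(stack$data)
  if (channel < 1 || channel > d[4])
    calima_error("calima_bounds_error", "channel %d out of range 1..%d",
                 channel, d[4])
  frames <- as.integer(frames)
  raw <- read_region(stack$data, list(NULL, NULL, frames, channel))
  out <- array(as.numeric(raw), dim = c(d[1], d[2], length(frames)))
  if (!processed) return(out)
  for (k in seq_along(frames)) {
    f <- frames[k]
    frame <- out[, , k]
    if (!is.null(stack$frame_shifts)) {
      sh <- stack$frame_shifts[f, ]
      if (any(sh != 0)) frame <- apply_shift(frame, sh)
    }
    if (!is.null(stack$black_trace)) frame <- frame - stack$black_trace[f]
    out[, , k] <- frame
  }
  out
}

#' Assign per-frame misalignment shifts to a stack
#'
#' @param stack a `stim_stack`.
#' @param shifts numeric matrix (n_frames x 2) of (dy, dx) content
#'   displacements in fractional pixels, as returned by [align_stack()].
#'   `NULL` clears the assignment. Any cached aligned frames are invalidated.
#' @export
set_frame_shifts <- function(stack, shifts) {
  if (!is.null(shifts)) {
    shifts <- as.matrix(shifts)
    if (nrow(shifts) != n_frames(stack) || ncol(shifts) != 2 ||
        any(!is.finite(shifts)))
      calima_error("calima_value_error",
                   "shifts must be a finite %d x 2 matrix", n_frames(stack))
  }
  stack$frame_shifts <- shifts
  invisible(stack)
}

#' Assign a per-frame black level trace
#'
#' @param stack a `stim_stack`.
#' @param trace numeric vector of length n_frames (raw units), or `NULL`.
#' @seealso [define_black_region()] which estimates the trace from a
#'   zero-fluorescence region.
#' @export
set_black_trace <- function(stack, trace) {
  if (!is.null(trace)) {
    trace <- as.numeric(trace)
    if (length(trace) != n_frames(stack) || any(!is.finite(trace)))
      calima_error("calima_value_error",
                   "black trace must be finite with length %d", n_frames(stack))
  }
  stack$black_trace <- trace
  invisible(stack)
}
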