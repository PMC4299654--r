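# Regions of interest -----------------------------------------------------
#
# ROIs are connected-region pixel-index lists over the frame grid, the same
# shape of structure a connected-components labelling returns: a list of
# 1-based column-major linear indices per region plus the image dimensions.

#' Construct an ROI set
#'
#' @param regions list of integer vectors: 1-based column-major linear pixel
#'   indices into the (rows x cols) frame grid, one vector per region.
#' @param dims integer `c(n_rows, n_cols)`.
#' @param labels optional character names, one per region.
#' @export
roi_set <- function(regions, dims, labels = NULL) {
  dims <- as.integer(dims)
  regions <- lapply(regions, function(r) sort(unique(as.integer(r))))
  np <- prod(dims)
  for (i in seq_along(regions)) {
    r <- regions[[i]]
    if (length(r) == 0)
      calima_error("calima_value_error", "region %d is empty", i)
    if (any(r < 1 | r > np))
      calima_error("calima_bounds_error",
                   "region %d has pixel indices outside the %dx%d grid",
                   i, dims[1], dims[2])
  }
  if (!is.null(labels) && length(labels) != length(regions))
    calima_error("calima_value_error", "need one label per region")
  structure(list(regions = regions, dims = dims, labels = labels),
            class = "roi_set")
}

#' @export
length.roi_set <- function(x) length(x$regions)

#' @export
print.roi_set <- function(x, ...) {
  sizes <- lengths(x$regions)
  cat(sprintf("<roi_set: %d region(s) on a %dx%d grid; %s px per region>\n",
              length(x$regions), x$dims[1], x$dims[2],
              if (length(sizes)) paste0(min(sizes), "-", max(sizes)) else "0"))
  invisible(x)
}

#' Centroids of an ROI set
#'
#' @param rois a [roi_set()].
#' @return matrix with columns `row`, `col` (fractional pixel centroids).
#' @export
roi_centroids <- function(rois) {
  t(vapply(rois$regions, function(r) {
    c(row = mean((r - 1) %% rois$dims[1] + 1),
      col = mean((r - 1) %/% rois$dims[1] + 1))
  }, numeric(2)))
}

#' Detection parameters for the intensity-peak cell finders
#'
#' @param smooth_sigma Gaussian smoothing sigma (px) applied to the
#'   detection image.
#' @param cell_radius radius (px) of the disc ROI placed at each accepted
#'   peak.
#' @param min_separation minimum distance (px) between accepted peaks;
#'   lower peaks within this distance of an accepted one are suppressed.
#' @param threshold_z minimum peak height, in robust standard deviations
#'   (MAD-based) above the median of the smoothed detection image.
#' @export
detect_config <- function(smooth_sigma = 2, cell_radius = 6,
                          min_separation = 2 * cell_radius, threshold_z = 4) {
  if (any(c(smooth_sigma, cell_radius, min_separation, threshold_z) <= 0))
    calima_error("calima_value_error", "all detection parameters must be > 0")
  structure(list(smooth_sigma = smooth_sigma, cell_radius = cell_radius,
                 min_separation = min_separation, threshold_z = threshold_z),
            class = "detect_config")
}

disc_indices <- function(center, radius, dims) {
  r0 <- max(1L, floor(center[1] - radius)); r1 <- min(dims[1], ceiling(center[1] + radius))
  c0 <- max(1L, floor(center[2] - radius)); c1 <- min(dims[2], ceiling(center[2] + radius))
  rr <- r0:r1; cc <- c0:c1
  d2 <- outer((rr - center[1])^2, (cc - center[2])^2, `+`)
  keep <- which(d2 <= radius^2, arr.ind = TRUE)
  as.integer((cc[keep[, 2]] - 1) * dims[1] + rr[keep[, 1]])
}

# Peak detection on a smoothed detection image: local maxima (8-neighbour)
# above median + threshold_z * robust sd, greedily accepted in decreasing
# height with a min_separation exclusion zone.
detect_peaks <- function(det, cfg) {
  sm <- gaussian_blur(det, cfg$smooth_sigma)
  # robust spread floored at 1% of the dynamic range so that noise-free
  # images (MAD 0) do not admit quantisation ripples as peaks
  spread <- max(stats::mad(sm), 0.01 * diff(range(sm)))
  thr <- stats::median(sm) + cfg$threshold_z * spread
  nr <- nrow(sm); nc <- ncol(sm)
  pad <- matrix(-Inf, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- sm
  is_max <- sm > thr
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    is_max <- is_max & sm >= pad[(2 + dy):(nr + 1 + dy), (2 + dx):(nc + 1 + dx)]
  }
  pk <- which(is_max, arr.ind = TRUE)
  if (nrow(pk) == 0) return(matrix(numeric(0), 0, 2))
  ord <- order(sm[pk], decreasing = TRUE)
  pk <- pk[ord, , drop = FALSE]
  accepted <- matrix(numeric(0), 0, 2)
  for (i in seq_len(nrow(pk))) {
    p <- pk[i, ]
    if (nrow(accepted) == 0 ||
        min(sqrt((accepted[, 1] - p[1])^2 + (accepted[, 2] - p[2])^2)) >=
          cfg$min_separation)
      accepted <- rbind(accepted, p)
  }
  unname(accepted)
}

mean_detection_image <- function(stack, channel, frame_range) {
  if (length(frame_range) == 0)
    calima_error("calima_value_error", "frame_range must not be empty")
  d <- dim(stack$data)
  acc <- matrix(0, d[1], d[2]); wt <- matrix(0, d[1], d[2])
  chunk <- max(1L, min(length(frame_range), floor(4e6 / (d[1] * d[2]))))
  for (start in seq(1L, length(frame_range), by = chunk)) {
    idx <- frame_range[start:min(length(frame_range), start + chunk - 1L)]
    fr <- get_frames(stack, idx, channel, processed = TRUE)
    ok <- !is.na(fr)
    fr[!ok] <- 0
    acc <- acc + rowSums(fr, dims = 2)
    wt <- wt + rowSums(ok, dims = 2)
  }
  out <- acc / pmax(wt, 1)
  out[wt == 0] <- 0
  out
}

#' Detect cells as intensity peaks in channel 1
#'
#' Forms the mean aligned, black-subtracted image of channel 1 over
#' `frame_range`, smooths it, finds local maxima above a robust threshold,
#' accepts them greedily in decreasing height with a minimum-separation
#' exclusion zone, and places a disc ROI of `cell_radius` (clipped to the
#' image) at each accepted peak. Suited to indicators that brightly label
#' cell somata or nuclei.
#'
#' @param stack a `stim_stack`.
#' @param cfg a [detect_config()].
#' @param frame_range frames averaged into the detection image (default:
#'   all frames).
#' @return a [roi_set()]; peak positions are attached as attribute `peaks`.
#' @export
find_cells_g <- function(stack, cfg = detect_config(), frame_range = NULL) {
  d <- dim(stack$data)
  if (is.null(frame_range)) frame_range <- seq_len(d[3])
  det <- mean_detection_image(stack, 1, frame_range)
  peaks_to_rois(detect_peaks(det, cfg), cfg, d[1:2])
}

#' Detect cells on the channel-1 minus channel-2 difference image
#'
#' Identical to [find_cells_g()] but the detection image is
#' `mean(channel 1) - mean(channel 2)`, which suppresses structures present
#' in both channels (useful when channel 2 carries a neuron-excluding
#' counterstain such as an astrocyte/vessel label).
#'
#' @inheritParams find_cells_g
#' @export
find_cells_gr <- function(stack, cfg = detect_config(), frame_range = NULL) {
  d <- dim(stack$data)
  if (d[4] < 2)
    calima_error("calima_value_error",
                 "find_cells_gr needs a 2-channel stack (have %d)", d[4])
  if (is.null(frame_range)) frame_range <- seq_len(d[3])
  det <- mean_detection_image(stack, 1, frame_range) -
         mean_detection_image(stack, 2, frame_range)
  peaks_to_rois(detect_peaks(det, cfg), cfg, d[1:2])
}

peaks_to_rois <- function(peaks, cfg, dims) {
  regions <- lapply(seq_len(nrow(peaks)), function(i)
    disc_indices(peaks[i, ], cfg$cell_radius, dims))
  rs <- roi_set(regions, dims,
                labels = if (nrow(peaks)) sprintf("cell%03d", seq_len(nrow(peaks))))
  attr(rs, "peaks") <- peaks
  rs
}

#' Write / read an ROI set as JSON
#'
#' External format: `{"dims": [rows, cols], "regions": [[...], ...],
#' "labels": [...]}` with 0-based linear pixel indices (column-major), the
#' package's cross-tool exchange convention.
#'
#' @param rois a [roi_set()]; `path` a JSON file.
#' @rdname roi_io
#' @export
write_roi_set <- function(rois, path) {
  jsonlite::write_json(
    list(dims = rois$dims,
         regions = lapply(rois$regions, function(r) r - 1L),
         labels = rois$labels),
    path, auto_unbox = FALSE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname roi_io
#' @export
read_roi_set <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                          simplifyMatrix = FALSE)
  roi_set(lapply(j$regions, function(r) unlist(r) + 1L),
          unlist(j$dims), labels = unlist(j$labels))
}
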