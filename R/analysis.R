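# Example analyses --------------------------------------------------------
#
# Receptive-field estimation from coarse stimulus grids, direction tuning
# curves from drifting-grating responses, and response sparseness measured
# as skewness -- the standard downstream summaries the extraction engine
# feeds.

#' Smoothed receptive-field map from gridded responses
#'
#' Each stimulus-grid pixel contributes a circular Gaussian field centred
#' on it, weighted by the pixel's trial-averaged response; the map is the
#' sum of these fields on a fine grid. The Gaussian width is set so its
#' full width at half maximum equals the stated pixel `diameter`
#' (`sigma = diameter / (2 sqrt(2 ln 2))`). The RF centre estimate is the
#' argmax of the summed field.
#'
#' @param centers matrix (n_pixels x 2) of grid-pixel centres, columns
#'   `(x, y)` in visual degrees.
#' @param responses trial-averaged response per grid pixel.
#' @param diameter stimulus pixel diameter in degrees (FWHM of the field).
#' @param resolution output grid step in degrees.
#' @param pad margin in degrees around the outermost centres.
#' @return list with `x`, `y` (axes, deg), `field` (matrix indexed
#'   `[y, x]`), `center` (`c(x, y)` argmax, `NA` when the field is flat)
#'   and `sigma`.
#' @export
rf_map <- function(centers, responses, diameter = 12, resolution = 0.25,
                   pad = diameter) {
  centers <- matrix(as.numeric(centers), ncol = 2)
  if (nrow(centers) != length(responses))
    calima_error("calima_value_error",
                 "need one response per grid pixel (%d centres, %d responses)",
                 nrow(centers), length(responses))
  if (any(!is.finite(responses)))
    calima_error("calima_value_error", "responses must be finite")
  sigma <- diameter / (2 * sqrt(2 * log(2)))
  xs <- seq(min(centers[, 1]) - pad, max(centers[, 1]) + pad, by = resolution)
  ys <- seq(min(centers[, 2]) - pad, max(centers[, 2]) + pad, by = resolution)
  field <- matrix(0, length(ys), length(xs))
  for (i in seq_len(nrow(centers))) {
    if (responses[i] == 0) next
    dx2 <- (xs - centers[i, 1])^2
    dy2 <- (ys - centers[i, 2])^2
    field <- field + responses[i] * exp(-outer(dy2, dx2, `+`) / (2 * sigma^2))
  }
  if (all(field == field[1])) {
    center <- c(NA_real_, NA_real_)
  } else {
    p <- arrayInd(which.max(field), dim(field))
    center <- c(xs[p[2]], ys[p[1]])
  }
  list(x = xs, y = ys, field = field, center = center, sigma = sigma)
}

#' Regular stimulus-grid centres
#'
#' Builds the centres of a g x g stimulus grid in visual degrees, given the
#' pixel diameter and the fractional overlap between adjacent pixels
#' (spacing = diameter * (1 - overlap)). Row-major order: x varies fastest.
#'
#' @param g grid side length.
#' @param diameter pixel diameter, degrees.
#' @param overlap fractional overlap between adjacent pixels.
#' @param origin `c(x, y)` of the grid's first (top-left) pixel centre.
#' @export
rf_grid_centers <- function(g = 5, diameter = 12, overlap = 0.4,
                            origin = c(0, 0)) {
  spacing <- diameter * (1 - overlap)
  offs <- (seq_len(g) - 1) * spacing
  as.matrix(expand.grid(x = origin[1] + offs, y = origin[2] + offs))
}

#' Direction tuning curve for one ROI
#'
#' Trial-averaged response and its standard error per drift direction, in
#' direction order. Stimulus `i` of the response matrix is taken to be
#' `directions[i]`.
#'
#' @param rm a `response_matrix`.
#' @param roi 1-based ROI index.
#' @param directions distinct directions in degrees within `[0, 360)`, one
#'   per stimulus.
#' @return data.frame with `direction`, `mean`, `sem`, `n_trials`.
#' @export
tuning_curve <- function(rm, roi, directions) {
  d <- dim(rm$responses)
  if (length(directions) != d[2])
    calima_error("calima_value_error",
                 "%d directions given for %d stimuli", length(directions), d[2])
  if (anyDuplicated(directions) || any(directions < 0 | directions >= 360))
    calima_error("calima_value_error",
                 "directions must be distinct and in [0, 360)")
  vals <- rm$responses[roi, , , drop = FALSE]
  means <- apply(vals, 2, mean, na.rm = TRUE)
  ns <- apply(vals, 2, function(v) sum(!is.na(v)))
  sems <- apply(vals, 2, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2) 0 else stats::sd(v) / sqrt(length(v))
  })
  ord <- order(directions)
  data.frame(direction = directions[ord], mean = means[ord],
             sem = sems[ord], n_trials = ns[ord])
}

#' Response sparseness as skewness
#'
#' Lifetime sparseness is the skewness of one unit's responses over time;
#' population sparseness is the skewness of simultaneous responses across
#' units at one time point. Skewness is the biased (divisor-n) sample
#' coefficient `g1 = m3 / m2^(3/2)` with central moments about the mean.
#' Units (rows or columns) with fewer than 3 finite values or zero variance
#' yield `NA`.
#'
#' @param values matrix of responses, units (neurons) in rows, time points
#'   (or stimuli) in columns.
#' @param axis `"lifetime"` (per row) or `"population"` (per column).
#' @return numeric vector: one value per neuron (lifetime) or per time
#'   point (population).
#' @export
sparseness <- function(values, axis = c("lifetime", "population")) {
  axis <- match.arg(axis)
  values <- as.matrix(values)
  skew1 <- function(v) {
    v <- v[is.finite(v)]
    if (length(v) < 3) return(NA_real_)
    m <- mean(v)
    m2 <- mean((v - m)^2)
    if (m2 == 0) return(NA_real_)
    mean((v - m)^3) / m2^1.5
  }
  if (axis == "lifetime") apply(values, 1, skew1) else apply(values, 2, skew1)
}
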