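# Synthetic experiment generator ------------------------------------------
#
# Writes disk-format stacks with complete ground truth: planted cell somata
# (Gaussian blobs), cosine direction tuning, calcium transients with
# instantaneous rise and exponential decay, a black instrument offset,
# Gaussian read-out noise, rigid motion, and randomised per-block stimulus
# sequences. Everything validation needs (true shifts, true amplitudes,
# clean blank frames, a zero-fluorescence region) is recorded so expected
# values can be computed in closed form, independently of the pipeline
# under test.

#' Configuration of a synthetic imaging experiment
#'
#' Defaults emulate a typical small-animal cortical recording: 128 x 128 px
#' frames at 7.81 Hz, 16 drift directions presented for 2 s each in
#' randomised order per block, 2 s of blank between presentations (at least
#' three decay constants, so successive trials are independent), one
#' block per trial, somata of 4 px Gaussian sigma (a ~6 um FWHM cell body at
#' the default 1.5 px/um calibration) with unit peak dF/F0
#' at the preferred direction, a GCaMP-like decay constant of 0.6 s, and an
#' 8-bit detector with a black offset.
#'
#' @param dims frame `c(rows, cols)`.
#' @param n_channels 1 or 2. With 2 channels and `fret_gain = NULL`,
#'   channel 2 carries the shared structures (vessels) but no cells; with
#'   `fret_gain = g`, the two channels report `1 + g * s(t)` and
#'   `1 - g * s(t)` of each cell's transient `s`.
#' @param dtype stored element type.
#' @param frame_rate acquisition rate, Hz.
#' @param n_blocks number of data block files (= trials when each block
#'   presents the full sequence once).
#' @param n_stimuli number of distinct stimuli; stimulus `i` is a drift
#'   direction of `(i - 1) * 360 / n_stimuli` degrees.
#' @param stim_duration_s,blank_time_s presentation and inter-stimulus
#'   blank durations, seconds.
#' @param tail_blank_s extra blank at the end of each block (lets
#'   transients decay; the source of clean baseline frames).
#' @param frames_per_block frames in each block file; default fits the
#'   presentations plus the tail.
#' @param n_cells,cell_sigma_px,amplitude planted cell count, soma Gaussian
#'   sigma (px), and peak dF/F0 at the preferred direction.
#' @param f0_level baseline fluorescence at a soma centre, raw units.
#' @param background constant fluorescence offset outside cells, raw units.
#' @param tau_s transient decay time constant, seconds.
#' @param black_level instrument offset added to every pixel, raw units.
#' @param noise_sd Gaussian noise s.d., raw units.
#' @param motion `NULL` (none), an n_frames x 2 matrix of (dy, dx) content
#'   displacements, or `list(max_px = m)` for a smooth random drift of
#'   amplitude up to `m` px.
#' @param vessel_level fluorescence of the shared vessel structures
#'   (2-channel, non-FRET stacks).
#' @param fret_gain FRET modulation gain `g`, or `NULL`.
#' @param format `"raw"` (binary dialect + sidecar header) or `"tiff"`
#'   (single-channel only).
#' @param seed RNG seed; identical configurations and seeds give
#'   byte-identical files.
#' @export
sim_config <- function(dims = c(128, 128), n_channels = 1, dtype = "u8",
                       frame_rate = 7.81, n_blocks = 5, n_stimuli = 16,
                       stim_duration_s = 2, blank_time_s = 2,
                       tail_blank_s = 3, frames_per_block = NULL,
                       n_cells = 20, cell_sigma_px = 4, amplitude = 1,
                       f0_level = 60, background = 0, tau_s = 0.6,
                       black_level = 10, noise_sd = 2, motion = NULL,
                       vessel_level = 40, fret_gain = NULL,
                       format = c("raw", "tiff"), seed = 1) {
  format <- match.arg(format)
  if (frame_rate <= 0 || stim_duration_s <= 0 || blank_time_s < 0 ||
      tau_s <= 0 || amplitude < 0 || noise_sd < 0)
    calima_error("calima_validation_error",
                 "rates, durations and tau must be > 0; amplitude and noise_sd >= 0")
  if (!n_channels %in% 1:2)
    calima_error("calima_validation_error", "n_channels must be 1 or 2")
  if (format == "tiff" && n_channels != 1)
    calima_error("calima_validation_error",
                 "tiff output supports a single channel")
  dt <- 1 / frame_rate
  if (is.null(frames_per_block)) {
    block_s <- n_stimuli * (stim_duration_s + blank_time_s) + tail_blank_s
    frames_per_block <- ceiling(block_s / dt)
  }
  structure(as.list(environment()), class = "sim_config")
}

smooth_drift <- function(nf, max_px) {
  # smoothed random walk rescaled to the requested amplitude
  w <- apply(matrix(stats::rnorm(2 * nf), ncol = 2), 2, cumsum)
  k <- stats::dnorm(seq(-3, 3, length.out = 21)); k <- k / sum(k)
  w <- apply(w, 2, function(v)
    stats::filter(c(rep(v[1], 10), v, rep(v[nf], 10)), k)[11:(10 + nf)])
  w <- sweep(w, 2, w[1, ])                    # start registered
  m <- max(abs(w))
  if (m > 0) w <- w * (max_px / m)
  w
}

#' Generate a synthetic experiment on disk
#'
#' Writes the block files (raw dialect or TIFF), the JSON sidecar header
#' recording the true randomised stimulus orders, and a ground-truth JSON
#' holding everything needed to compute expected outputs in closed form.
#'
#' Pixel model, channel 1:
#' `black + background + sum_i F0_i(x) * (1 + s_i(t)) + noise`, where
#' `F0_i` is cell `i`'s Gaussian soma profile scaled to `f0_level` and
#' `s_i(t)` sums one transient per presentation with amplitude
#' `amplitude * max(0, cos(direction - preferred_i))`, instantaneous rise
#' at stimulus onset and exponential decay `tau_s`. The composed frame is
#' then rigidly displaced along the motion path (bilinear, black fill) and
#' quantised to the output dtype with clipping.
#'
#' @param cfg a [sim_config()].
#' @param dir output directory (created).
#' @return list with `paths` (block files), `header_path`, `header`,
#'   `truth` (ground-truth list) and `truth_path`.
#' @export
generate_experiment <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(cfg$seed, generate_experiment_impl(cfg, dir))
}

generate_experiment_impl <- function(cfg, dir) {
  nr <- cfg$dims[1]; nc <- cfg$dims[2]; nch <- cfg$n_channels
  dt <- 1 / cfg$frame_rate
  fpb <- rep_len(cfg$frames_per_block, cfg$n_blocks)
  nf <- sum(fpb)
  n_stim <- cfg$n_stimuli
  directions <- (seq_len(n_stim) - 1) * 360 / max(1, n_stim)

  # randomised order per block (one full sequence per block)
  orders <- replicate(cfg$n_blocks, sample.int(n_stim), simplify = FALSE)
  if (n_stim == 0) orders <- rep(list(integer(0)), cfg$n_blocks)

  header <- stack_header(
    n_rows = nr, n_cols = nc, n_channels = nch, dtype = cfg$dtype,
    frames_per_file = fpb, f_pixels_per_um = 1.5,
    t_frame_duration = dt, t_blank_time = cfg$blank_time_s,
    sequence_ids_per_block = orders,
    stimulus_durations = rep(cfg$stim_duration_s, n_stim))
  timeline <- build_timeline(header)

  # motion path (content displacement per frame)
  shifts <- matrix(0, nf, 2)
  if (!is.null(cfg$motion)) {
    shifts <- if (is.matrix(cfg$motion)) cfg$motion
              else smooth_drift(nf, cfg$motion$max_px)
    if (nrow(shifts) != nf)
      calima_error("calima_validation_error",
                   "motion path must have one row per frame (%d)", nf)
  }
  margin <- ceiling(4 * cfg$cell_sigma_px + max(abs(shifts)) + 2)
  margin <- max(1, min(margin, floor(min(nr, nc) / 2) - 1))

  # planted cells: rejection-sampled centres with a minimum separation that
  # adapts to the usable interior (and relaxes if the packing is too tight)
  span <- min(nr, nc) - 2 * margin
  min_sep <- min(max(8, 5 * cfg$cell_sigma_px),
                 max(2, span / max(1, ceiling(sqrt(cfg$n_cells)))))
  centers <- matrix(numeric(0), 0, 2)
  while (nrow(centers) < cfg$n_cells && min_sep >= 1) {
    centers <- matrix(numeric(0), 0, 2)
    tries <- 0
    while (nrow(centers) < cfg$n_cells && tries < 20000) {
      tries <- tries + 1
      p <- c(stats::runif(1, margin, max(margin, nr - margin)),
             stats::runif(1, margin, max(margin, nc - margin)))
      if (nrow(centers) == 0 ||
          min(sqrt((centers[, 1] - p[1])^2 + (centers[, 2] - p[2])^2)) >= min_sep)
        centers <- rbind(centers, p)
    }
    if (nrow(centers) < cfg$n_cells) min_sep <- min_sep * 0.8
  }
  if (nrow(centers) < cfg$n_cells)
    calima_error("calima_validation_error",
                 "could not place %d cells on a %dx%d frame",
                 cfg$n_cells, nr, nc)
  prefs <- if (cfg$n_cells > 0 && n_stim > 0)
    directions[((seq_len(cfg$n_cells) - 1) %% n_stim) + 1] else numeric(0)

  # per-cell soma patches (truncated at 4 sigma)
  hw <- ceiling(4 * cfg$cell_sigma_px)
  patches <- lapply(seq_len(cfg$n_cells), function(i) {
    rr <- (round(centers[i, 1]) - hw):(round(centers[i, 1]) + hw)
    cc <- (round(centers[i, 2]) - hw):(round(centers[i, 2]) + hw)
    rr <- rr[rr >= 1 & rr <= nr]
    cc <- cc[cc >= 1 & cc <= nc]
    d2 <- outer((rr - centers[i, 1])^2, (cc - centers[i, 2])^2, `+`)
    list(rr = rr, cc = cc,
         img = cfg$f0_level * exp(-d2 / (2 * cfg$cell_sigma_px^2)))
  })

  # per-cell transient amplitude per presentation and dF/F0 time course
  amp <- matrix(0, max(1, cfg$n_cells), max(1, nrow(timeline)))
  D <- matrix(0, max(1, cfg$n_cells), nf)
  t_frames <- (seq_len(nf) - 1) * dt
  block_end_f <- cumsum(fpb)
  if (cfg$n_cells > 0 && nrow(timeline) > 0) {
    for (p in seq_len(nrow(timeline))) {
      dir_p <- directions[timeline$stim_id[p]]
      a_p <- cfg$amplitude * pmax(0, cos((dir_p - prefs) * pi / 180))
      amp[, p] <- a_p
      k0 <- which(t_frames >= timeline$t_start[p] - 1e-9)[1]
      k1 <- block_end_f[timeline$block[p]]
      if (is.na(k0) || k0 > k1) next
      decay <- exp(-(t_frames[k0:k1] - timeline$t_start[p]) / cfg$tau_s)
      D[, k0:k1] <- D[, k0:k1] + outer(a_p, decay)
    }
  }

  # static scenery: background, optional vessels (both channels)
  base <- matrix(cfg$black_level + cfg$background, nr, nc)
  vessels <- matrix(0, nr, nc)
  if (nch == 2 && is.null(cfg$fret_gain)) {
    for (v in 1:3) {
      cy <- stats::runif(1, margin, nr - margin)
      cx <- stats::runif(1, margin, nc - margin)
      ang <- stats::runif(1, 0, pi)
      d <- abs((row(vessels) - cy) * cos(ang) + (col(vessels) - cx) * sin(ang))
      vessels <- pmax(vessels, cfg$vessel_level * exp(-d^2 / (2 * 2^2)))
    }
  }

  # a zero-fluorescence region for black-level estimation: a 10 x 10 px
  # corner patch (a vessel-lumen-sized area at the default calibration),
  # kept clear of cells by the margin and carved to the black level
  br <- 3:min(12, nr - 1); bc <- 3:min(12, nc - 1)
  black_region <- as.integer(outer(br, (bc - 1) * nr, `+`))

  paths <- file.path(dir, sprintf("block%02d.%s", seq_len(cfg$n_blocks),
                                  if (cfg$format == "raw") "bin" else "tif"))
  frame0 <- 0L
  for (b in seq_len(cfg$n_blocks)) {
    tif_pages <- if (cfg$format == "tiff") vector("list", fpb[b])
    con <- if (cfg$format == "raw") file(paths[b], "wb")
    for (k in seq_len(fpb[b])) {
      f <- frame0 + k
      frame <- array(0, dim = c(nr, nc, nch))
      ch1 <- base + vessels
      g <- cfg$fret_gain
      for (i in seq_len(cfg$n_cells)) {
        pt <- patches[[i]]
        s <- D[i, f]
        mod <- if (is.null(g)) 1 + s else 1 + g * s
        ch1[pt$rr, pt$cc] <- ch1[pt$rr, pt$cc] + pt$img * mod
      }
      ch1[black_region] <- cfg$black_level
      frame[, , 1] <- ch1
      if (nch == 2) {
        ch2 <- base + vessels
        if (!is.null(g)) {
          for (i in seq_len(cfg$n_cells)) {
            pt <- patches[[i]]
            ch2[pt$rr, pt$cc] <- ch2[pt$rr, pt$cc] + pt$img * (1 - g * D[i, f])
          }
        }
        ch2[black_region] <- cfg$black_level
        frame[, , 2] <- ch2
      }
      if (any(shifts[f, ] != 0))
        for (ch in seq_len(nch))
          frame[, , ch] <- apply_shift(frame[, , ch], -shifts[f, ],
                                       fill = cfg$black_level)
      if (cfg$noise_sd > 0)
        frame <- frame + stats::rnorm(length(frame), 0, cfg$noise_sd)
      frame <- suppressWarnings(dtype_clip(frame, cfg$dtype))
      if (cfg$format == "raw") {
        write_dtype_bin(con, as.vector(aperm(frame, c(3, 2, 1))), cfg$dtype)
      } else {
        tif_pages[[k]] <- frame[, , 1] / dtype_info(cfg$dtype)$max
      }
    }
    if (cfg$format == "raw") close(con)
    else tiff::writeTIFF(tif_pages, paths[b],
                         bits.per.sample = dtype_info(cfg$dtype)$bits,
                         compression = "none")
    frame0 <- frame0 + fpb[b]
  }

  header_path <- file.path(dir, "stack_header.json")
  write_stack_header(header, header_path)

  # frames safe for baseline estimation: untagged and residual transient
  # below 0.2% of the planted amplitude
  residual <- if (cfg$n_cells > 0) apply(D, 2, max) else rep(0, nf)
  fi_tagged <- rep(FALSE, nf)
  if (nrow(timeline) > 0)
    for (p in seq_len(nrow(timeline)))
      fi_tagged <- fi_tagged | (t_frames >= timeline$t_start[p] - 1e-9 &
                                t_frames < timeline$t_end[p] - 1e-9)
  clean_blank <- which(!fi_tagged & residual < 0.002 * max(cfg$amplitude, 1e-9))

  truth <- list(
    config = unclass(cfg),
    directions = directions,
    orders = orders,
    cell_centers = centers,
    preferred_direction = prefs,
    amplitudes = amp,          # cell x presentation transient amplitude
    shifts = shifts,           # true content displacement per frame
    timeline = timeline,
    clean_blank_frames = clean_blank,
    black_region = black_region,
    black_level = cfg$black_level
  )
  truth_path <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(
    list(directions = directions, orders = orders,
         cell_centers = centers, preferred_direction = prefs,
         amplitudes = amp, shifts = shifts,
         clean_blank_frames = clean_blank, black_region = black_region,
         black_level = cfg$black_level, seed = cfg$seed),
    truth_path, auto_unbox = TRUE, digits = NA)
  list(paths = paths, header_path = header_path, header = header,
       truth = truth, truth_path = truth_path)
}
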