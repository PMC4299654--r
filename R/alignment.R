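# Sub-pixel rigid translation registration --------------------------------
#
# Shift estimation follows the two-stage efficient subpixel registration
# scheme (Fourier cross-correlation matching): the energy-normalised
# cross-power spectrum is inverse-transformed on a 2x zero-padded grid for
# a half-pixel initial peak, then refined by a matrix-multiply discrete
# Fourier transform evaluated on a 1.5 x 1.5 px neighbourhood at 1/kappa px
# resolution. The cross-power spectrum is normalised by total spectral
# energy rather than whitened per frequency: per-frequency whitening
# weights signal-free high frequencies equally and destroys sub-pixel
# accuracy on smooth, noisy fluorescence images.
#
# Shift convention: the stored (dy, dx) is the displacement of the frame's
# content relative to the reference; applying the negated shift
# re-registers the frame ([apply_shift()] does this internally).

fft_freqs <- function(n) {
  k <- 0:(n - 1)
  k[k >= ceiling(n / 2)] <- k[k >= ceiling(n / 2)] - n
  k
}

#' Estimate the translation between two images
#'
#' @param ref,moving numeric matrices of identical dimensions, at least 8x8.
#' @param upsample integer upsampling factor `kappa >= 1`; the returned
#'   shift has resolution `1/kappa` pixels.
#' @return numeric `c(dy, dx)`: displacement of `moving`'s content relative
#'   to `ref`, in fractional pixels, resolved to `(-n/2, n/2]` per axis.
#' @examples
#' img <- matrix(rnorm(64 * 64), 64)
#' estimate_shift(img, roll2(img, c(3, -2)))   # c(3, -2)
#' @export
estimate_shift <- function(ref, moving, upsample = 20) {
  if (!all(dim(ref) == dim(moving)))
    calima_error("calima_dimension_error", "images must have equal dimensions")
  nr <- nrow(ref); nc <- ncol(ref)
  if (nr < 8 || nc < 8)
    calima_error("calima_value_error", "images must be at least 8x8")
  if (stats::sd(ref) == 0 || stats::sd(moving) == 0)
    calima_error("calima_degenerate_error",
                 "constant (zero-variance) image: shift is undefined")
  upsample <- max(1L, as.integer(upsample))
  F1 <- stats::fft(ref); F2 <- stats::fft(moving)
  R <- Conj(F1) * F2 / sqrt(sum(Mod(F1)^2) * sum(Mod(F2)^2))
  kr <- fft_freqs(nr); kc <- fft_freqs(nc)
  if (upsample == 1) {
    cc <- Re(stats::fft(R, inverse = TRUE))
    p <- arrayInd(which.max(cc), dim(cc)) - 1L   # 0-based peak
    dy <- if (p[1] > nr / 2) p[1] - nr else p[1]
    dx <- if (p[2] > nc / 2) p[2] - nc else p[2]
    return(c(dy = dy, dx = dx))
  }
  # stage 1: global cross-correlation on a 2x zero-padded spectrum gives a
  # half-pixel initial estimate
  big <- matrix(0 + 0i, 2 * nr, 2 * nc)
  big[(kr %% (2 * nr)) + 1, (kc %% (2 * nc)) + 1] <- R
  cc2 <- Re(stats::fft(big, inverse = TRUE))
  p <- arrayInd(which.max(cc2), dim(cc2)) - 1L
  dy <- (if (p[1] > nr) p[1] - 2 * nr else p[1]) / 2
  dx <- (if (p[2] > nc) p[2] - 2 * nc else p[2]) / 2
  # stage 2: matrix-multiply DFT at 1/kappa resolution on a 1.5 x 1.5 px
  # neighbourhood of the stage-1 peak
  nup <- ceiling(1.5 * upsample)
  ys <- dy - 0.75 + (0:(nup - 1)) / upsample
  xs <- dx - 0.75 + (0:(nup - 1)) / upsample
  Er <- exp(2i * pi * outer(ys, kr) / nr)        # nup x nr
  Ec <- exp(2i * pi * outer(kc, xs) / nc)        # nc x nup
  ccu <- Re(Er %*% R %*% Ec)
  q <- arrayInd(which.max(ccu), dim(ccu))
  # wrap to (-n/2, n/2] per axis
  dy <- ys[q[1]]; dx <- xs[q[2]]
  if (dy > nr / 2) dy <- dy - nr
  if (dx > nc / 2) dx <- dx - nc
  c(dy = dy, dx = dx)
}

#' Circularly roll a matrix
#'
#' Utility used throughout tests and the synthetic generator: shifts content
#' by integer `(dy, dx)` with wrap-around.
#'
#' @param m matrix; `v` integer `c(dy, dx)`.
#' @export
roll2 <- function(m, v) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- ((seq_len(nr) - 1 - v[1]) %% nr) + 1
  ci <- ((seq_len(nc) - 1 - v[2]) %% nc) + 1
  m[ri, ci, drop = FALSE]
}

#' Re-register a frame by a sub-pixel shift
#'
#' Translates the frame by the *negated* shift using bilinear interpolation,
#' undoing a content displacement of `(dy, dx)`. Output pixels whose sample
#' point falls outside the frame take `fill` (default `NA`, the invalid
#' marker propagated by downstream ROI averaging).
#'
#' @param frame numeric matrix.
#' @param shift numeric `c(dy, dx)` in fractional pixels.
#' @param fill value for pixels sampled from outside the frame.
#' @export
apply_shift <- function(frame, shift, fill = NA_real_) {
  if (any(!is.finite(shift)))
    calima_error("calima_value_error", "shift must be finite")
  if (all(shift == 0)) return(frame)
  nr <- nrow(frame); nc <- ncol(frame)
  ys <- seq_len(nr) + shift[1]
  xs <- seq_len(nc) + shift[2]
  y0 <- floor(ys); x0 <- floor(xs)
  wy <- ys - y0;   wx <- xs - x0
  corner <- function(yi, xi) {
    ok_y <- yi >= 1 & yi <= nr; ok_x <- xi >= 1 & xi <= nc
    M <- frame[pmin(pmax(yi, 1), nr), pmin(pmax(xi, 1), nc), drop = FALSE]
    M[!ok_y, ] <- NA; M[, !ok_x] <- NA
    M
  }
  term <- function(W, M) { T <- W * M; T[W == 0] <- 0; T }
  out <- term((1 - wy) %o% (1 - wx), corner(y0,     x0)) +
         term((1 - wy) %o% wx,       corner(y0,     x0 + 1)) +
         term(wy       %o% (1 - wx), corner(y0 + 1, x0)) +
         term(wy       %o% wx,       corner(y0 + 1, x0 + 1))
  if (!is.na(fill)) out[is.na(out)] <- fill
  out
}

#' Alignment configuration
#'
#' @param channel channel used for registration.
#' @param mode `"progressive"` (each frame registered against the previous
#'   frame, shifts accumulated into frame 1's coordinate system),
#'   `"fixed"` (all frames against `reference`, a frame index), or
#'   `"external"` (all frames against `reference`, an image matrix).
#' @param reference frame index (fixed mode) or reference image (external).
#' @param upsample sub-pixel upsampling factor kappa; shifts are resolved to
#'   1/kappa px.
#' @param prefilter_sigma optional Gaussian low-pass sigma (px) applied to
#'   frames before registration; `NULL` disables.
#' @param window_len odd sliding-window length: each moving frame is
#'   averaged with its `window_len - 1` neighbours (truncated at the stack
#'   ends) before registration. 1 disables.
#' @param max_shift rejection threshold (px): frames whose estimated shift
#'   magnitude exceeds this are discarded and repaired by linear
#'   interpolation between the nearest accepted frames.
#' @export
align_config <- function(channel = 1, mode = c("progressive", "fixed", "external"),
                         reference = 1, upsample = 20, prefilter_sigma = NULL,
                         window_len = 1, max_shift = 10) {
  mode <- match.arg(mode)
  if (window_len < 1 || window_len %% 2 == 0)
    calima_error("calima_value_error", "window_len must be odd and >= 1")
  if (upsample < 1)
    calima_error("calima_value_error", "upsample must be >= 1")
  structure(list(channel = channel, mode = mode, reference = reference,
                 upsample = as.integer(upsample),
                 prefilter_sigma = prefilter_sigma,
                 window_len = as.integer(window_len), max_shift = max_shift),
            class = "align_config")
}

gaussian_blur <- function(img, sigma) {
  if (is.null(sigma) || sigma <= 0) return(img)
  EBImage::gblur(img, sigma = sigma)
}

#' Estimate per-frame misalignment shifts for a stack
#'
#' Registration pipeline per frame: optional Gaussian pre-filtering, then
#' sliding-window averaging of the moving frame with its neighbours, then
#' phase-correlation shift estimation against the reference (previous frame
#' in progressive mode). Estimated shifts whose magnitude exceeds
#' `max_shift` are rejected and repaired by linear interpolation between the
#' nearest accepted frames (nearest accepted value at the ends).
#'
#' @param stack a `stim_stack`.
#' @param cfg an [align_config()].
#' @param assign attach the result to the stack via [set_frame_shifts()].
#' @return an n_frames x 2 matrix of (dy, dx) shifts (class `frame_shifts`).
#' @export
align_stack <- function(stack, cfg = align_config(), assign = TRUE) {
  nf <- n_frames(stack)
  frames <- get_frames(stack, seq_len(nf), channel = cfg$channel)
  if (!is.null(cfg$prefilter_sigma))
    for (k in seq_len(nf))
      frames[, , k] <- gaussian_blur(frames[, , k], cfg$prefilter_sigma)
  mov <- frames
  if (cfg$window_len > 1) {
    h <- (cfg$window_len - 1) %/% 2
    for (k in seq_len(nf)) {
      win <- max(1, k - h):min(nf, k + h)
      mov[, , k] <- apply(frames[, , win, drop = FALSE], c(1, 2), mean)
    }
  }
  est <- matrix(0, nf, 2)
  if (cfg$mode == "progressive") {
    for (k in 2:nf)
      est[k, ] <- estimate_shift(mov[, , k - 1], mov[, , k], cfg$upsample)
  } else {
    ref <- if (cfg$mode == "fixed") frames[, , cfg$reference]
           else gaussian_blur(as.matrix(cfg$reference), cfg$prefilter_sigma)
    for (k in seq_len(nf))
      est[k, ] <- estimate_shift(ref, mov[, , k], cfg$upsample)
  }
  # single-frame shift-size rejection + interpolation repair, applied to the
  # per-step estimates (progressive) or per-frame estimates (reference modes)
  mag <- sqrt(rowSums(est^2))
  ok <- mag <= cfg$max_shift
  if (!any(ok))
    calima_error("calima_alignment_error",
                 "alignment failed: all %d frames exceeded max_shift = %g px",
                 nf, cfg$max_shift)
  if (any(!ok)) {
    xi <- which(!ok)
    for (j in 1:2)
      est[xi, j] <- stats::approx(which(ok), est[ok, j], xout = xi,
                                  rule = 2)$y
  }
  shifts <- if (cfg$mode == "progressive") apply(est, 2, cumsum) else est
  colnames(shifts) <- c("dy", "dx")
  class(shifts) <- c("frame_shifts", class(shifts))
  attr(shifts, "rejected") <- which(!ok)
  if (assign) set_frame_shifts(stack, shifts)
  shifts
}

#' Read / write a shifts CSV
#'
#' External format: columns `frame` (0-based), `dy_px`, `dx_px`.
#'
#' @param shifts an n x 2 shift matrix; `path` a CSV file.
#' @rdname shifts_io
#' @export
write_shifts_csv <- function(shifts, path) {
  utils::write.csv(data.frame(frame = seq_len(nrow(shifts)) - 1L,
                              dy_px = shifts[, 1], dx_px = shifts[, 2]),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname shifts_io
#' @export
read_shifts_csv <- function(path) {
  df <- utils::read.csv(path)
  m <- as.matrix(df[order(df$frame), c("dy_px", "dx_px")])
  dimnames(m) <- list(NULL, c("dy", "dx"))
  m
}

#' Lazily computed, disk-cached aligned frame
#'
#' The first request computes the re-registered, black-subtracted frame and
#' stores it in an on-disk cache keyed by frame index, channel, the frame's
#' shift values and its black level; later requests with unchanged metadata
#' return the cached bytes without recomputation. Changing the shifts or
#' black trace changes the key, so stale entries are never served. If the
#' cache directory cannot be written the frame is computed uncached with a
#' warning.
#'
#' @param stack a `stim_stack` with shifts assigned.
#' @param frame 1-based frame index.
#' @param channel 1-based channel.
#' @return numeric matrix (n_rows x n_cols).
#' @export
cached_aligned_frame <- function(stack, frame, channel = 1) {
  if (is.null(stack$frame_shifts))
    calima_error("calima_value_error",
                 "no shifts assigned; run align_stack() or set_frame_shifts()")
  sh <- stack$frame_shifts[frame, ]
  blk <- if (is.null(stack$black_trace)) 0 else stack$black_trace[frame]
  if (is.null(stack$cache_dir))
    stack$cache_dir <- tempfile("calima_cache_")
  ok <- dir.exists(stack$cache_dir) || dir.create(stack$cache_dir,
                                                  showWarnings = FALSE)
  key <- file.path(stack$cache_dir,
                   sprintf("f%06d_c%d_%.9g_%.9g_b%.9g.bin",
                           frame, channel, sh[1], sh[2], blk))
  d <- dim(stack$data)
  if (ok && file.exists(key)) {
    con <- file(key, "rb")
    v <- readBin(con, "double", d[1] * d[2])
    close(con)
    return(matrix(v, d[1], d[2]))
  }
  stack$shift_compute_count <- stack$shift_compute_count + 1L
  out <- get_frames(stack, frame, channel, processed = TRUE)[, , 1]
  if (ok) {
    wrote <- tryCatch({
      con <- file(key, "wb"); writeBin(as.double(out), con); close(con); TRUE
    }, error = function(e) FALSE)
    ok <- wrote
  }
  if (!ok)
    calima_warning("calima_cache_warning",
                   "aligned-frame cache is unwritable; returning uncached result")
  out
}
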