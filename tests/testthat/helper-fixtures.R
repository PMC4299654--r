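# Fixture builders kept independent of the package's own writers: raw stacks
# are serialised here with plain writeBin so that lazy reads can be checked
# against the in-memory array that produced the files.

# Write an array [rows, cols, frames, channels] to n_files raw blocks using
# the dialect's storage order (channel fastest, then column, then row, then
# frame), little-endian. Returns paths + a header list.
write_raw_fixture <- function(arr, dtype = "u8", n_files = 1,
                              dir = tempfile("rawfix_")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(arr)
  stopifnot(d[3] %% n_files == 0)
  fpf <- rep(d[3] %/% n_files, n_files)
  paths <- file.path(dir, sprintf("block%02d.bin", seq_len(n_files)))
  size <- switch(dtype, u8 = 1L, u16 = 2L, i16 = 2L, f32 = 4L, f64 = 8L)
  int <- dtype %in% c("u8", "u16", "i16")
  f0 <- 0L
  for (b in seq_len(n_files)) {
    con <- file(paths[b], "wb")
    for (k in seq_len(fpf[b])) {
      v <- as.vector(aperm(array(arr[, , f0 + k, ], dim = d[c(1, 2, 4)]),
                           c(3, 2, 1)))
      if (int) {
        v <- as.integer(v)
        if (dtype != "i16") {
          half <- 2^(8 * size - 1)
          v <- ifelse(v >= half, v - 2 * half, v)
        }
        writeBin(as.integer(v), con, size = size, endian = "little")
      } else writeBin(as.double(v), con, size = size, endian = "little")
    }
    close(con)
    f0 <- f0 + fpf[b]
  }
  list(paths = paths, arr = arr,
       header = list(n_rows = d[1], n_cols = d[2], n_channels = d[4],
                     dtype = dtype, frames_per_file = fpf))
}

random_u8_array <- function(dims, seed) {
  set.seed(seed)
  array(sample(0:255, prod(dims), replace = TRUE), dim = dims)
}

# Sub-pixel translation through the Fourier phase ramp: the band-limited
# reference shift used to plant known fractional displacements.
fourier_shift <- function(m, v) {
  nr <- nrow(m); nc <- ncol(m)
  kr <- 0:(nr - 1); kr[kr >= ceiling(nr / 2)] <- kr[kr >= ceiling(nr / 2)] - nr
  kc <- 0:(nc - 1); kc[kc >= ceiling(nc / 2)] <- kc[kc >= ceiling(nc / 2)] - nc
  ph <- exp(-2i * pi * (outer(kr, rep(1, nc)) * v[1] / nr +
                        outer(rep(1, nr), kc) * v[2] / nc))
  Re(stats::fft(stats::fft(m) * ph, inverse = TRUE)) / (nr * nc)
}

# A textured test image: a sum of Gaussian blobs, smooth enough for
# sub-pixel work but with unambiguous structure.
blob_image <- function(n = 64, n_blobs = 12, seed = 7, amp = c(50, 100),
                       sigma = 3) {
  set.seed(seed)
  img <- matrix(0, n, n)
  for (i in seq_len(n_blobs)) {
    cy <- runif(1, n * 0.15, n * 0.85); cx <- runif(1, n * 0.15, n * 0.85)
    a <- runif(1, amp[1], amp[2])
    img <- img + a * exp(-((row(img) - cy)^2 + (col(img) - cx)^2) /
                           (2 * sigma^2))
  }
  img
}

# Disc pixel indices (1-based, column-major) — oracle for ROI placement.
disc_pixels <- function(center, radius, dims) {
  idx <- c()
  for (cc in 1:dims[2]) for (rr in 1:dims[1])
    if ((rr - center[1])^2 + (cc - center[2])^2 <= radius^2)
      idx <- c(idx, (cc - 1) * dims[1] + rr)
  as.integer(idx)
}

# Greedy matching of detected peaks to true centres within tol px; returns
# counts for recall/precision accounting.
match_detections <- function(peaks, centers, tol = 4) {
  used <- rep(FALSE, nrow(peaks))
  hits <- 0L
  for (i in seq_len(nrow(centers))) {
    if (nrow(peaks) == 0) break
    d <- sqrt((peaks[, 1] - centers[i, 1])^2 + (peaks[, 2] - centers[i, 2])^2)
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && d[j] <= tol) { hits <- hits + 1L; used[j] <- TRUE }
  }
  list(tp = hits, fp = nrow(peaks) - hits, fn = nrow(centers) - hits)
}
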