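# Disk-backed 4-D stacks -------------------------------------------------
#
# A lazy_stack maps one or more files on disk to a single (rows, cols,
# frames, channels) tensor. Pixel data are only read when a region is
# requested; opening, permuting axes and composing affine value transforms
# are O(1) and never touch the files. Two backends exist:
#
#   * "raw": a documented raw-binary dialect. Little-endian elements, laid
#     out channel-fastest, then columns, then rows, then frames, so one
#     frame is a single contiguous span. Several files concatenate along the
#     frame axis. Geometry comes from a sidecar header (see stack_header()).
#   * "tiff": baseline grayscale multi-frame TIFF (uncompressed or
#     deflate/LZW as supported by libtiff), up to 2 samples per pixel,
#     read-only. Page geometry is read once at open time.

new_lazy_stack <- function(native_dim, dtype, blocks, writable) {
  state <- new.env(parent = emptyenv())
  state$io_read_count <- 0L
  state$max_read_elements <- 0
  structure(list(
    native_dim = as.integer(native_dim),
    dtype = dtype,
    blocks = blocks,
    axis_order = 1:4,
    transform = c(a = 1, b = 0),
    writable = writable,
    state = state
  ), class = "lazy_stack")
}

#' @export
dim.lazy_stack <- function(x) x$native_dim[x$axis_order]

#' Number of block reads performed so far
#'
#' Instrumentation counter: incremented once per file block touched by each
#' read. Structural operations (axis permutation, value transforms) never
#' change it, which is how laziness is asserted in tests.
#'
#' @param stack a [lazy_stack][open_binary_stack] object.
#' @return integer count of block reads.
#' @export
io_read_count <- function(stack) stack$state$io_read_count

#' @export
print.lazy_stack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<lazy_stack %s [%s] %s, %d block(s), transform %g*x%+g%s>\n",
              paste(d, collapse = "x"),
              paste(c("rows", "cols", "frames", "channels")[x$axis_order],
                    collapse = ","),
              x$dtype, nrow(x$blocks), x$transform[1], x$transform[2],
              if (x$writable) ", writable" else ""))
  invisible(x)
}

frame_elements <- function(stack)
  prod(stack$native_dim[c(1, 2, 4)])

#' Open raw-binary files as one lazy stack
#'
#' Concatenates the given files along the frame axis. No pixel data are read;
#' file sizes are checked against the declared geometry.
#'
#' @param paths ordered character vector of raw-binary block files.
#' @param header a list (typically a [stack_header()]) with at least
#'   `n_rows`, `n_cols`, `n_channels`, `dtype` and `frames_per_file`
#'   (one entry per path). An optional `byte_offset` (scalar or per file)
#'   gives the offset of the pixel data within each file.
#' @param writable open the files for in-place writing as well as reading.
#' @return a `lazy_stack` of shape (n_rows, n_cols, total frames, n_channels).
#' @seealso [read_region()], [open_tiff_stack()], [create_binary_stack()]
#' @export
open_binary_stack <- function(paths, header, writable = FALSE) {
  n_rows <- as.integer(header$n_rows); n_cols <- as.integer(header$n_cols)
  n_ch <- as.integer(header$n_channels)
  dtype <- header$dtype
  info <- dtype_info(dtype)
  fpf <- as.integer(header$frames_per_file)
  if (length(fpf) != length(paths))
    calima_error("calima_dimension_error",
                 "frames_per_file has %d entries but %d files were given",
                 length(fpf), length(paths))
  if (any(fpf < 1) || n_rows < 1 || n_cols < 1 || n_ch < 1)
    calima_error("calima_value_error", "stack dimensions must all be >= 1")
  offs <- rep_len(as.numeric(header$byte_offset %||% 0), length(paths))
  frame_bytes <- as.numeric(n_rows) * n_cols * n_ch * info$size
  for (i in seq_along(paths)) {
    if (!file.exists(paths[i]))
      calima_error("calima_io_error", "file not found: %s", paths[i])
    need <- offs[i] + fpf[i] * frame_bytes
    have <- file.size(paths[i])
    if (have < need)
      calima_error("calima_size_error",
                   "file %s holds %.0f bytes but %.0f are required for %d frames of %dx%dx%d %s",
                   paths[i], have, need, fpf[i], n_rows, n_cols, n_ch, dtype)
  }
  blocks <- data.frame(path = as.character(paths), byte_offset = offs,
                       n_frames = fpf, backend = "raw",
                       stringsAsFactors = FALSE)
  new_lazy_stack(c(n_rows, n_cols, sum(fpf), n_ch), dtype, blocks, writable)
}

#' Create a zero-filled raw-binary stack on disk
#'
#' Allocates a single-block writable stack, the disk-backed equivalent of
#' `array(0, dim)`. Used as scratch space by [slice_apply()] and available
#' for building fixtures.
#'
#' @param path file to create (overwritten if present).
#' @param dim integer vector (rows, cols, frames, channels).
#' @param dtype element type; one of `"u8"`, `"u16"`, `"i16"`, `"f32"`, `"f64"`.
#' @return a writable `lazy_stack`.
#' @export
create_binary_stack <- function(path, dim, dtype = "f64") {
  info <- dtype_info(dtype)
  dim <- as.integer(dim)
  if (length(dim) != 4 || any(dim < 1))
    calima_error("calima_value_error", "dim must be 4 integers >= 1")
  con <- file(path, "wb")
  on.exit(close(con))
  chunk <- as.numeric(dim[1]) * dim[2] * dim[4]
  zeros <- numeric(chunk)
  for (k in seq_len(dim[3])) write_dtype_bin(con, zeros, dtype)
  close(con); on.exit()
  open_binary_stack(path, list(n_rows = dim[1], n_cols = dim[2],
                               n_channels = dim[4], dtype = dtype,
                               frames_per_file = dim[3]),
                    writable = TRUE)
}

#' Open multi-frame TIFF files as one lazy stack
#'
#' Page geometry (dimensions, bit depth, page count) is read once at open
#' time; pixel data are read page by page on demand. TIFF-backed stacks are
#' always read-only.
#'
#' @param paths ordered character vector of TIFF files, concatenated along
#'   the frame axis.
#' @return a read-only `lazy_stack`.
#' @export
open_tiff_stack <- function(paths) {
  ref <- NULL
  blocks <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    if (!file.exists(paths[i]))
      calima_error("calima_io_error", "file not found: %s", paths[i])
    pg <- tiff::readTIFF(paths[i], all = TRUE, payload = FALSE)
    if (is.null(dim(pg))) pg <- as.data.frame(as.list(pg))  # single page
    geom <- unique(pg[, c("width", "length", "bits.per.sample",
                          "samples.per.pixel")])
    if (nrow(geom) != 1)
      calima_error("calima_dimension_error",
                   "file %s mixes frame dimensions or bit depths", paths[i])
    if (is.null(ref)) ref <- geom
    else if (!identical(unlist(ref), unlist(geom)))
      calima_error("calima_dimension_error",
                   "file %s (%dx%d %d-bit) does not match %s (%dx%d %d-bit)",
                   paths[i], geom$length, geom$width, geom$bits.per.sample,
                   paths[1], ref$length, ref$width, ref$bits.per.sample)
    blocks[[i]] <- data.frame(path = paths[i], byte_offset = 0,
                              n_frames = nrow(pg), backend = "tiff",
                              stringsAsFactors = FALSE)
  }
  if (!ref$bits.per.sample %in% c(8L, 16L))
    calima_error("calima_format_error",
                 "only 8- or 16-bit grayscale TIFF is supported (got %d-bit)",
                 ref$bits.per.sample)
  if (ref$samples.per.pixel > 2)
    calima_error("calima_format_error",
                 "at most 2 samples per pixel are supported (got %d)",
                 ref$samples.per.pixel)
  blocks <- do.call(rbind, blocks)
  dtype <- if (ref$bits.per.sample == 8L) "u8" else "u16"
  new_lazy_stack(c(ref$length, ref$width, sum(blocks$n_frames),
                   ref$samples.per.pixel),
                 dtype, blocks, writable = FALSE)
}

# Resolve a user index list (current axis order, NULL = everything) to
# native-axis integer indices. Bounds-checked; errors name the axis.
resolve_index <- function(stack, index) {
  if (is.null(index)) index <- vector("list", 4)
  if (length(index) != 4)
    calima_error("calima_value_error", "index must be a list of 4 axis ranges")
  d <- dim(stack)
  native <- vector("list", 4)
  for (i in 1:4) {
    idx <- index[[i]]
    if (is.null(idx)) idx <- seq_len(d[i])
    idx <- as.integer(idx)
    if (length(idx) == 0 || anyNA(idx) || any(idx < 1 | idx > d[i]))
      calima_error("calima_bounds_error",
                   "index out of range on axis %d (extent %d)", i, d[i])
    native[[stack$axis_order[i]]] <- idx
  }
  native
}

# Read raw frames from disk into an array [rows, cols, frames, channels]
# restricted to the requested native indices. Holds at most the output plus
# one frame buffer in memory. `frames` may be unordered / repeated.
read_native <- function(stack, rows, cols, frames, chans, transform = TRUE) {
  uf <- sort(unique(frames))
  out <- array(0, dim = c(length(rows), length(cols), length(uf), length(chans)))
  ends <- cumsum(stack$blocks$n_frames)
  starts <- c(0L, ends[-length(ends)])
  info <- dtype_info(stack$dtype)
  nr <- stack$native_dim[1]; nc <- stack$native_dim[2]; nch <- stack$native_dim[4]
  fe <- frame_elements(stack)
  touched <- 0L
  for (b in seq_len(nrow(stack$blocks))) {
    sel <- which(uf > starts[b] & uf <= ends[b])
    if (length(sel) == 0) next
    touched <- touched + 1L
    blk <- stack$blocks[b, ]
    fib <- uf[sel] - starts[b]          # frame index within block, 1-based
    if (blk$backend == "raw") {
      con <- file(blk$path, "rb")
      # read runs of consecutive frames in one request (capped so the
      # transient buffer stays a small constant number of frames)
      run_id <- cumsum(c(1L, diff(fib) != 1L))
      runs <- unlist(lapply(split(seq_along(sel), run_id), function(r)
        split(r, ceiling(seq_along(r) / 16))), recursive = FALSE,
        use.names = FALSE)
      for (run in runs) {
        seek(con, where = blk$byte_offset + (fib[run[1]] - 1) * fe * info$size)
        v <- read_dtype_bin(con, stack$dtype, fe * length(run))
        arr <- array(v, dim = c(nch, nc, nr, length(run)))  # storage order
        out[, , sel[run], ] <- aperm(arr[chans, cols, rows, , drop = FALSE],
                                     c(3, 2, 4, 1))
      }
      close(con)
    } else {
      for (k in seq_along(sel)) {
        pg <- tiff::readTIFF(blk$path, all = fib[k], as.is = TRUE)[[1]]
        if (length(dim(pg)) == 2) dim(pg) <- c(dim(pg), 1L)
        out[, , sel[k], ] <- pg[rows, cols, chans, drop = FALSE]
      }
    }
  }
  st <- stack$state
  st$io_read_count <- st$io_read_count + touched
  st$max_read_elements <- max(st$max_read_elements, length(out) + 16 * fe)
  if (transform && (stack$transform[1] != 1 || stack$transform[2] != 0))
    out <- stack$transform[1] * out + stack$transform[2]
  if (identical(uf, frames)) out
  else out[, , match(frames, uf), , drop = FALSE]
}

#' Read a region of a lazy stack
#'
#' Returns the requested region as an in-memory array, applying the stack's
#' deferred affine value transform. Only file blocks overlapping the
#' requested frames are touched.
#'
#' @param stack a `lazy_stack`.
#' @param index list of 4 index vectors in the stack's *current* axis order;
#'   `NULL` entries select the whole axis. Omit for the full stack.
#' @return numeric array with one dimension per requested axis range.
#' @export
read_region <- function(stack, index = NULL) {
  nat <- resolve_index(stack, index)
  out <- read_native(stack, nat[[1]], nat[[2]], nat[[3]], nat[[4]])
  aperm(out, stack$axis_order)
}

#' Write a region of a writable raw-binary stack
#'
#' Values are stored as raw dtype values: the stack's read-side affine
#' transform is deliberately not inverted, so the on-disk representation is
#' independent of any transforms composed onto the handle. Out-of-range
#' values for integer dtypes are clipped to the representable range with a
#' warning.
#'
#' @param stack a writable raw-binary `lazy_stack`.
#' @param index as for [read_region()].
#' @param values array (or scalar) matching the region's extent.
#' @return the stack, invisibly.
#' @export
write_region <- function(stack, index, values) {
  if (!stack$writable)
    calima_error("calima_readonly_error",
                 "stack is read-only; writes require a writable raw-binary stack")
  nat <- resolve_index(stack, index)
  rows <- nat[[1]]; cols <- nat[[2]]; frames <- nat[[3]]; chans <- nat[[4]]
  # `want` is the region extent in the stack's current axis order
  want <- vapply(1:4, function(i)
    c(length(rows), length(cols), length(frames), length(chans))[stack$axis_order[i]],
    integer(1))
  if (length(values) != prod(want) && length(values) != 1)
    calima_error("calima_dimension_error",
                 "values length %d does not match the addressed region [%s]",
                 length(values), paste(want, collapse = "x"))
  vals <- array(as.numeric(values), dim = want)
  # bring values from current axis order to native order
  vals <- aperm(vals, order(stack$axis_order))
  vals <- dtype_clip(vals, stack$dtype)
  info <- dtype_info(stack$dtype)
  nr <- stack$native_dim[1]; nc <- stack$native_dim[2]; nch <- stack$native_dim[4]
  fe <- frame_elements(stack)
  full_frame <- length(rows) == nr && length(cols) == nc && length(chans) == nch &&
    identical(rows, seq_len(nr)) && identical(cols, seq_len(nc)) &&
    identical(chans, seq_len(nch))
  ends <- cumsum(stack$blocks$n_frames)
  starts <- c(0L, ends[-length(ends)])
  for (k in seq_along(frames)) {
    f <- frames[k]
    b <- which(f > starts & f <= ends)[1]
    blk <- stack$blocks[b, ]
    pos <- blk$byte_offset + (f - starts[b] - 1) * fe * info$size
    if (full_frame) {
      frame <- vals[, , k, ]
      dim(frame) <- c(nr, nc, nch)
    } else {
      con <- file(blk$path, "rb")
      seek(con, where = pos)
      frame <- aperm(array(read_dtype_bin(con, stack$dtype, fe),
                           dim = c(nch, nc, nr)), c(3, 2, 1))
      close(con)
      frame[rows, cols, chans] <- vals[, , k, ]
    }
    con <- file(blk$path, "r+b")
    seek(con, where = pos, rw = "write")
    write_dtype_bin(con, as.vector(aperm(frame, c(3, 2, 1))), stack$dtype)
    close(con)
  }
  invisible(stack)
}

#' Permute the axes of a lazy stack in O(1)
#'
#' Returns a view with reordered axes; no pixel data are read and the
#' underlying files are shared with the input.
#'
#' @param stack a `lazy_stack`.
#' @param order permutation of 1:4 in the stack's current axis order.
#' @export
permute_axes <- function(stack, order) {
  order <- as.integer(order)
  if (length(order) != 4 || !identical(sort(order), 1:4))
    calima_error("calima_value_error", "order must be a permutation of 1:4")
  stack$axis_order <- stack$axis_order[order]
  stack
}

#' Compose an affine value transform onto a lazy stack in O(1)
#'
#' Reads from the result return `a * v + b` where `v` is the value the input
#' stack would return. Composes with any existing transform; no data are
#' read. Negation is `scale_offset(stack, -1)`.
#'
#' @param stack a `lazy_stack`.
#' @param a,b scale and offset.
#' @export
scale_offset <- function(stack, a, b = 0) {
  stack$transform <- c(a = a * stack$transform[["a"]],
                       b = a * stack$transform[["b"]] + b)
  stack
}

#' Apply a function slice-wise over one axis of a lazy stack
#'
#' Iterates over the given axis reading one slice at a time, so peak resident
#' memory is one slice plus a single frame buffer regardless of stack size.
#' In `"map"` mode `fn` must return a slice of identical shape and the result
#' is written to a temporary disk-backed stack; in `"reduce"` mode the
#' per-slice results are collected and simplified.
#'
#' @param stack a `lazy_stack`.
#' @param fn function of one slice (array with the remaining 3 axes).
#' @param axis axis to iterate over, in current axis order.
#' @param mode `"map"` or `"reduce"`.
#' @param out_path file backing the result in map mode (default: tempfile).
#' @return a writable `lazy_stack` (map mode) or simplified array/list
#'   (reduce mode).
#' @export
slice_apply <- function(stack, fn, axis, mode = c("map", "reduce"),
                        out_path = tempfile(fileext = ".bin")) {
  mode <- match.arg(mode)
  axis <- as.integer(axis)
  if (axis < 1 || axis > 4)
    calima_error("calima_value_error", "axis must be in 1..4")
  d <- dim(stack)
  idx <- vector("list", 4)
  out <- if (mode == "map") create_binary_stack(out_path, d, "f64")
         else vector("list", d[axis])
  for (k in seq_len(d[axis])) {
    idx[[axis]] <- k
    slice <- read_region(stack, idx)
    sl_dim <- dim(slice)[-axis]
    slice <- array(slice, dim = sl_dim)
    res <- fn(slice)
    if (mode == "map") {
      if (!identical(dim(res) %||% length(res), sl_dim) &&
          !(is.null(dim(res)) && length(res) == prod(sl_dim)))
        calima_error("calima_dimension_error",
                     "fn returned shape [%s] for slice %d (expected [%s])",
                     paste(dim(res) %||% length(res), collapse = "x"), k,
                     paste(sl_dim, collapse = "x"))
      full <- sl_dim; full <- append(full, 1, after = axis - 1)
      write_region(out, idx, array(res, dim = full))
    } else {
      out[[k]] <- res
    }
  }
  if (mode == "map") out else simplify2array(out)
}
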