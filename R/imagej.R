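# ImageJ ROI interchange --------------------------------------------------
#
# Minimal reader and writer for the ImageJ .roi binary format ("Iout"
# magic, big-endian) covering the rectangle, oval, polygon and freehand
# types, plus .zip containers of several ROIs. Shapes are rasterised to
# pixel-index sets: a pixel belongs to the ROI iff its centre lies inside
# the shape, with the format's top-left pixel origin mapped to R's 1-based
# (row, col) grid.

IJ_TYPES <- c(polygon = 0L, rect = 1L, oval = 2L, line = 3L, freeline = 4L,
              polyline = 5L, noroi = 6L, freehand = 7L, traced = 8L,
              angle = 9L, point = 10L)

read_be <- function(raw, offset, n = 1, size = 2, signed = TRUE)
  readBin(raw[(offset + 1):length(raw)], "integer", n = n, size = size,
          signed = signed, endian = "big")

parse_imagej_roi <- function(raw, name = "<roi>") {
  if (length(raw) < 64 || rawToChar(raw[1:4]) != "Iout")
    calima_error("calima_format_error",
                 "%s: not an ImageJ ROI file (bad magic bytes)", name)
  type <- as.integer(raw[7])
  top <- read_be(raw, 8); left <- read_be(raw, 10)
  bottom <- read_be(raw, 12); right <- read_be(raw, 14)
  n_coords <- read_be(raw, 16)
  if (type == IJ_TYPES[["rect"]]) {
    list(kind = "rect", left = left, top = top, right = right, bottom = bottom)
  } else if (type == IJ_TYPES[["oval"]]) {
    list(kind = "oval", left = left, top = top, right = right, bottom = bottom)
  } else if (type %in% c(IJ_TYPES[["polygon"]], IJ_TYPES[["freehand"]],
                         IJ_TYPES[["traced"]])) {
    xs <- read_be(raw, 64, n = n_coords) + left
    ys <- read_be(raw, 64 + 2 * n_coords, n = n_coords) + top
    list(kind = "polygon", x = xs, y = ys)
  } else {
    calima_warning("calima_format_warning",
                   "%s: unsupported ROI type %d skipped", name, type)
    NULL
  }
}

# Even-odd (crossing-number) point-in-polygon test, vectorised over points.
# Vertices are in (x, y) image coordinates.
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    x1 <- vx[j]; y1 <- vy[j]; x2 <- vx[i]; y2 <- vy[i]
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

rasterize_shape <- function(shape, dims) {
  if (shape$kind == "rect") {
    rows <- (shape$top + 1):shape$bottom
    cols <- (shape$left + 1):shape$right
    rows <- rows[rows >= 1 & rows <= dims[1]]
    cols <- cols[cols >= 1 & cols <= dims[2]]
    as.integer(outer(rows, (cols - 1) * dims[1], `+`))
  } else if (shape$kind == "oval") {
    cx <- (shape$left + shape$right) / 2; cy <- (shape$top + shape$bottom) / 2
    a <- (shape$right - shape$left) / 2;  b <- (shape$bottom - shape$top) / 2
    rows <- max(1, shape$top + 1):min(dims[1], shape$bottom)
    cols <- max(1, shape$left + 1):min(dims[2], shape$right)
    grid <- expand.grid(r = rows, c = cols)
    x <- grid$c - 0.5; y <- grid$r - 0.5      # pixel centres, 0-based coords
    keep <- ((x - cx) / a)^2 + ((y - cy) / b)^2 <= 1
    as.integer((grid$c[keep] - 1) * dims[1] + grid$r[keep])
  } else {
    rows <- max(1, floor(min(shape$y)) + 1):min(dims[1], ceiling(max(shape$y)))
    cols <- max(1, floor(min(shape$x)) + 1):min(dims[2], ceiling(max(shape$x)))
    grid <- expand.grid(r = rows, c = cols)
    keep <- point_in_polygon(grid$c - 0.5, grid$r - 0.5, shape$x, shape$y)
    as.integer((grid$c[keep] - 1) * dims[1] + grid$r[keep])
  }
}

#' Import ImageJ ROI definitions
#'
#' Reads a single `.roi` file or a `.zip` container of several, rasterising
#' each shape (rectangle, oval, polygon, freehand) to a pixel-index region:
#' a pixel is included iff its centre lies inside the shape. Unsupported ROI
#' types produce a warning and are skipped.
#'
#' @param path `.roi` or `.zip` file.
#' @param dims image `c(n_rows, n_cols)`; when `NULL`, the smallest grid
#'   containing all ROI bounding boxes is used.
#' @return a [roi_set()] labelled with the source entry names.
#' @export
import_imagej <- function(path, dims = NULL) {
  if (!file.exists(path))
    calima_error("calima_io_error", "file not found: %s", path)
  is_zip <- grepl("\\.zip$", path, ignore.case = TRUE) ||
    identical(as.integer(readBin(path, "raw", 2)), c(0x50L, 0x4bL))
  if (is_zip) {
    exdir <- tempfile("ij_unzip_")
    files <- utils::unzip(path, exdir = exdir)
    files <- sort(files[grepl("\\.roi$", files, ignore.case = TRUE)])
    shapes <- list(); nms <- character(0)
    for (f in files) {
      sh <- parse_imagej_roi(readBin(f, "raw", file.size(f)), basename(f))
      if (!is.null(sh)) {
        shapes[[length(shapes) + 1]] <- sh
        nms <- c(nms, sub("\\.roi$", "", basename(f), ignore.case = TRUE))
      }
    }
    unlink(exdir, recursive = TRUE)
  } else {
    sh <- parse_imagej_roi(readBin(path, "raw", file.size(path)),
                           basename(path))
    shapes <- if (is.null(sh)) list() else list(sh)
    nms <- sub("\\.roi$", "", basename(path), ignore.case = TRUE)[length(shapes)]
  }
  if (is.null(dims)) {
    if (length(shapes) == 0) dims <- c(1L, 1L)
    else {
      ext <- vapply(shapes, function(s) {
        if (s$kind %in% c("rect", "oval")) c(s$bottom, s$right)
        else c(ceiling(max(s$y)), ceiling(max(s$x)))
      }, numeric(2))
      dims <- c(max(ext[1, ]), max(ext[2, ]))
    }
  }
  regions <- lapply(shapes, rasterize_shape, dims = dims)
  keep <- lengths(regions) > 0
  roi_set(regions[keep], dims,
          labels = if (length(nms)) nms[keep] else NULL)
}

# --- writer (fixture support) -------------------------------------------

be16 <- function(v) writeBin(as.integer(v), raw(), size = 2, endian = "big")

encode_imagej_roi <- function(shape) {
  kind <- shape$kind
  if (kind %in% c("rect", "oval")) {
    top <- shape$top; left <- shape$left
    bottom <- shape$bottom; right <- shape$right
    n <- 0L; coords <- raw(0)
  } else if (kind %in% c("polygon", "freehand")) {
    left <- floor(min(shape$x)); top <- floor(min(shape$y))
    right <- ceiling(max(shape$x)); bottom <- ceiling(max(shape$y))
    n <- length(shape$x)
    coords <- c(be16(round(shape$x - left)), be16(round(shape$y - top)))
  } else {
    calima_error("calima_value_error", "unsupported ROI shape '%s'", kind)
  }
  header <- c(charToRaw("Iout"), be16(227),
              as.raw(IJ_TYPES[[if (kind == "polygon") "polygon"
                               else if (kind == "freehand") "freehand"
                               else kind]]), as.raw(0),
              be16(top), be16(left), be16(bottom), be16(right), be16(n))
  c(header, raw(64 - length(header)), coords)
}

#' Write ImageJ ROI fixture files
#'
#' Emits `.roi` files (or a store-only `.zip` container) readable by
#' [import_imagej()] and by ImageJ itself. Shapes are lists with
#' `kind = "rect"|"oval"` plus 0-based `left`, `top`, `right`, `bottom`
#' bounds, or `kind = "polygon"|"freehand"` plus vertex vectors `x`, `y` in
#' 0-based image coordinates.
#'
#' @param shapes list of shape descriptions (a single shape for `.roi`
#'   output, any number for `.zip`).
#' @param path output file; extension selects the container.
#' @return `path`, invisibly.
#' @export
write_imagej_fixture <- function(shapes, path) {
  if (!is.null(shapes$kind)) shapes <- list(shapes)
  if (grepl("\\.roi$", path, ignore.case = TRUE)) {
    if (length(shapes) != 1)
      calima_error("calima_value_error",
                   "a .roi file holds exactly one ROI; use .zip for %d",
                   length(shapes))
    writeBin(encode_imagej_roi(shapes[[1]]), path)
  } else {
    names <- sprintf("roi_%03d.roi", seq_along(shapes))
    payloads <- lapply(shapes, encode_imagej_roi)
    write_store_zip(path, names, payloads)
  }
  invisible(path)
}

# --- store-only ZIP writer ----------------------------------------------

crc32_table <- local({
  tab <- integer(256)
  for (n in 0:255) {
    c <- n
    for (k in 1:8)
      c <- if (bitwAnd(c, 1L)) bitwXor(-306674912L, bitwShiftR(c, 1))
           else bitwShiftR(c, 1)
    tab[n + 1] <- c
  }
  tab
})

crc32 <- function(bytes) {
  crc <- -1L
  for (b in as.integer(bytes))
    crc <- bitwXor(bitwShiftR(crc, 8),
                   crc32_table[bitwAnd(bitwXor(crc, b), 255L) + 1])
  bitwXor(crc, -1L)
}

le_int <- function(v, size) {
  v <- as.numeric(v)
  half <- 2^(8 * size - 1)
  writeBin(as.integer(ifelse(v >= half, v - 2 * half, v)), raw(),
           size = size, endian = "little")
}

write_store_zip <- function(path, names, payloads) {
  con <- file(path, "wb")
  on.exit(close(con))
  offsets <- numeric(length(names))
  crcs <- integer(length(names))
  pos <- 0
  for (i in seq_along(names)) {
    data <- payloads[[i]]
    fn <- charToRaw(names[i])
    crcs[i] <- crc32(data)
    offsets[i] <- pos
    hdr <- c(le_int(0x04034b50, 4), le_int(20, 2), le_int(0, 2), le_int(0, 2),
             le_int(0, 2), le_int(33, 2),           # DOS time 0, date 1980-01-01
             writeBin(crcs[i], raw(), size = 4, endian = "little"),
             le_int(length(data), 4), le_int(length(data), 4),
             le_int(length(fn), 2), le_int(0, 2), fn)
    writeBin(c(hdr, data), con)
    pos <- pos + length(hdr) + length(data)
  }
  cd_start <- pos
  for (i in seq_along(names)) {
    fn <- charToRaw(names[i])
    data <- payloads[[i]]
    cd <- c(le_int(0x02014b50, 4), le_int(20, 2), le_int(20, 2), le_int(0, 2),
            le_int(0, 2), le_int(0, 2), le_int(33, 2),
            writeBin(crcs[i], raw(), size = 4, endian = "little"),
            le_int(length(data), 4), le_int(length(data), 4),
            le_int(length(fn), 2), le_int(0, 2), le_int(0, 2), le_int(0, 2),
            le_int(0, 2), le_int(0, 4), le_int(offsets[i], 4), fn)
    writeBin(cd, con)
    pos <- pos + length(cd)
  }
  eocd <- c(le_int(0x06054b50, 4), le_int(0, 2), le_int(0, 2),
            le_int(length(names), 2), le_int(length(names), 2),
            le_int(pos - cd_start, 4), le_int(cd_start, 4), le_int(0, 2))
  writeBin(eocd, con)
  invisible(path)
}
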