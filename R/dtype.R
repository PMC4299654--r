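# Supported element types for disk-backed stacks. Raw-binary files are always
# little-endian; see the raw dialect description in the package vignette.

DTYPES <- list(
  u8  = list(what = "integer", size = 1L, signed = FALSE, min = 0,      max = 255,   bits = 8L),
  u16 = list(what = "integer", size = 2L, signed = FALSE, min = 0,      max = 65535, bits = 16L),
  i16 = list(what = "integer", size = 2L, signed = TRUE,  min = -32768, max = 32767, bits = 16L),
  f32 = list(what = "double",  size = 4L, signed = TRUE,  min = -Inf,   max = Inf,   bits = 32L),
  f64 = list(what = "double",  size = 8L, signed = TRUE,  min = -Inf,   max = Inf,   bits = 64L)
)

dtype_info <- function(dtype) {
  info <- DTYPES[[dtype]]
  if (is.null(info))
    calima_error("calima_dtype_error", "unsupported dtype '%s' (supported: %s)",
                 dtype, paste(names(DTYPES), collapse = ", "))
  info
}

# Clip values to the representable range of an integer dtype, warning when any
# value was out of range (mirrors detector saturation; avoids wraparound).
dtype_clip <- function(values, dtype) {
  info <- dtype_info(dtype)
  if (info$what == "double") return(values)
  out <- round(values)
  n_clip <- sum(out < info$min | out > info$max, na.rm = TRUE)
  if (n_clip > 0) {
    out <- pmin(pmax(out, info$min), info$max)
    calima_warning("calima_clip_warning",
                   "%d value(s) outside %s range [%g, %g] were clipped",
                   n_clip, dtype, info$min, info$max)
  }
  out
}

read_dtype_bin <- function(con, dtype, n) {
  info <- dtype_info(dtype)
  readBin(con, what = info$what, n = n, size = info$size,
          signed = if (info$what == "integer") info$signed else TRUE,
          endian = "little")
}

write_dtype_bin <- function(con, values, dtype) {
  info <- dtype_info(dtype)
  if (info$what == "integer") {
    v <- as.integer(round(values))
    # writeBin() refuses out-of-range narrowing for signed sizes; u8/u16 values
    # above the signed max are re-expressed as their two's-complement bit pattern.
    if (!info$signed) {
      half <- 2^(8 * info$size - 1)
      v <- ifelse(v >= half, v - 2 * half, v)
    }
    writeBin(as.integer(v), con, size = info$size, endian = "little")
  } else {
    writeBin(as.double(values), con, size = info$size, endian = "little")
  }
  invisible(NULL)
}

#' Bytes required to store a stack of a given shape
#'
#' Plain size accounting for raw pixel data: the product of the four stack
#' dimensions times bytes per element. Useful for checking that files on disk
#' match their declared geometry.
#'
#' @param shape integer vector of length 4 (rows, cols, frames, channels),
#'   all >= 1.
#' @param bits_per_element bits per stored element; one of 8, 16, 32, 64.
#' @return total number of bytes as a double (exact for any realistic stack).
#' @examples
#' storage_bytes(c(128, 128, 7378, 2), 8)
#' @export
storage_bytes <- function(shape, bits_per_element) {
  if (length(shape) != 4 || any(shape < 1))
    calima_error("calima_value_error", "shape must be 4 integers >= 1")
  if (!bits_per_element %in% c(8, 16, 32, 64))
    calima_error("calima_value_error", "bits_per_element must be 8, 16, 32 or 64")
  prod(as.numeric(shape)) * bits_per_element / 8
}
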