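test_that("binary stacks open lazily with a concatenated frame axis and size checks", {
  fix <- write_raw_fixture(random_u8_array(c(8, 10, 6, 2), seed = 11),
                           n_files = 3)
  s <- open_binary_stack(fix$paths, fix$header)
  expect_equal(dim(s), c(8, 10, 6, 2))
  expect_identical(io_read_count(s), 0L)

  one <- write_raw_fixture(array(7, c(1, 1, 1, 1)))
  expect_equal(dim(open_binary_stack(one$paths, one$header)), c(1, 1, 1, 1))

  # truncate the last block by one byte: error must name the file
  bad <- readBin(fix$paths[3], "raw", file.size(fix$paths[3]) - 1)
  writeBin(bad, fix$paths[3])
  expect_error(open_binary_stack(fix$paths, fix$header),
               class = "calima_size_error")
  expect_error(open_binary_stack(fix$paths, fix$header), "block03")

  expect_error(open_binary_stack(fix$paths[1:2], fix$header),
               class = "calima_dimension_error")
})

test_that("lazy reads equal eager reads bit-exactly across random index patterns", {
  dims <- c(16, 20, 30, 2)
  fix <- write_raw_fixture(random_u8_array(dims, seed = 21), n_files = 3)
  s <- open_binary_stack(fix$paths, fix$header)
  set.seed(22)
  for (i in 1:300) {
    idx <- lapply(dims, function(n) {
      if (runif(1) < 0.5) {                 # contiguous span
        a <- sample(n, 1); b <- sample(a:n, 1); a:b
      } else sort(sample(n, sample(n, 1)))  # arbitrary subset
    })
    got <- read_region(s, idx)
    want <- fix$arr[idx[[1]], idx[[2]], idx[[3]], idx[[4]], drop = FALSE]
    expect_identical(as.vector(got), as.vector(as.numeric(want)))
  }
  # single-pixel trace
  tr <- read_region(s, list(3, 4, NULL, 1))
  expect_identical(as.vector(tr), as.numeric(fix$arr[3, 4, , 1]))
  # out-of-range errors name the axis
  expect_error(read_region(s, list(NULL, NULL, 31, NULL)), "axis 3")
  expect_error(read_region(s, list(17, NULL, NULL, NULL)),
               class = "calima_bounds_error")
})

test_that("permute_axes and scale_offset are O(1) views matching eager equivalents", {
  dims <- c(6, 7, 8, 2)
  fix <- write_raw_fixture(random_u8_array(dims, seed = 31))
  s <- open_binary_stack(fix$paths, fix$header)
  set.seed(32)
  for (i in 1:20) {
    p <- sample(4)
    ps <- permute_axes(s, p)
    expect_equal(dim(ps), dims[p])
    expect_identical(as.vector(read_region(ps)),
                     as.vector(as.numeric(aperm(fix$arr, p))))
  }
  # permuting twice by inverse orders restores the original view
  p <- c(3, 1, 2, 4)
  back <- permute_axes(permute_axes(s, p), order(p))
  expect_identical(read_region(back), read_region(s))
  expect_error(permute_axes(s, c(1, 1, 2, 3)), class = "calima_value_error")

  # laziness: none of the structural ops read a block
  n0 <- io_read_count(s)
  invisible(permute_axes(scale_offset(permute_axes(s, p), -2, 5), order(p)))
  expect_identical(io_read_count(s), n0)

  # transform algebra: composition equals a single affine on eager data
  sc <- scale_offset(scale_offset(s, 2, 3), 0.5, -1.5)
  expect_lt(max(abs(read_region(sc) - fix$arr)), 1e-12)
  expect_equal(read_region(scale_offset(s, -1), list(1, 1, 1, 1))[1],
               -fix$arr[1, 1, 1, 1])
  a <- runif(1, 0.5, 2); b <- runif(1, -5, 5)
  expect_lt(max(abs(read_region(scale_offset(s, a, b)) -
                      (a * fix$arr + b))), 1e-12)
})

test_that("writes round-trip raw values, clip out-of-range with a warning, and reads are pure", {
  fix <- write_raw_fixture(random_u8_array(c(5, 6, 4, 1), seed = 41))
  s <- open_binary_stack(fix$paths, fix$header, writable = TRUE)
  set.seed(42)
  frame <- matrix(sample(0:255, 30, TRUE), 5, 6)
  write_region(s, list(NULL, NULL, 2, 1), array(frame, c(5, 6, 1, 1)))
  expect_identical(as.vector(read_region(s, list(NULL, NULL, 2, 1))),
                   as.numeric(frame))
  # repeated reads with no intervening write are identical
  expect_identical(read_region(s), read_region(s))

  expect_warning(write_region(s, list(1, 1, 1, 1), 300),
                 class = "calima_clip_warning")
  expect_equal(read_region(s, list(1, 1, 1, 1))[1], 255)

  # writes store raw dtype values: the read-side transform is not inverted
  st <- scale_offset(s, 2, 3)
  suppressWarnings(write_region(st, list(1, 1, 3, 1), 5))
  expect_equal(read_region(st, list(1, 1, 3, 1))[1], 2 * 5 + 3)
  expect_equal(read_region(s, list(1, 1, 3, 1))[1], 5)

  expect_error(write_region(open_binary_stack(fix$paths, fix$header),
                            list(1, 1, 1, 1), 0),
               class = "calima_readonly_error")
})

test_that("slice_apply maps and reduces with per-slice memory bounds", {
  dims <- c(12, 14, 40, 1)
  fix <- write_raw_fixture(random_u8_array(dims, seed = 51))
  s <- open_binary_stack(fix$paths, fix$header)

  ident <- slice_apply(s, function(x) x, axis = 3)
  expect_equal(as.vector(read_region(ident)), as.vector(as.numeric(fix$arr)))

  means <- slice_apply(s, mean, axis = 3, mode = "reduce")
  expect_equal(means, apply(fix$arr, 3, mean))

  expect_error(slice_apply(s, function(x) x[1:2, , , drop = FALSE], axis = 3),
               "slice 1")

  # memory instrumentation: peak elements materialised per read stays at
  # one slice plus the constant frame-buffer overhead, far below the stack
  s2 <- open_binary_stack(fix$paths, fix$header)
  invisible(slice_apply(s2, function(x) sum(x), axis = 3, mode = "reduce"))
  slice_elems <- prod(dims[c(1, 2, 4)])
  expect_lte(s2$state$max_read_elements, slice_elems * 17)
  expect_lt(s2$state$max_read_elements, prod(dims))
})

test_that("TIFF stacks are lazy read-only views with geometry cached at open", {
  dir <- tempfile("tiffs_"); dir.create(dir)
  set.seed(61)
  pages1 <- lapply(1:4, function(i) matrix(runif(15 * 12), 15, 12))
  pages2 <- lapply(1:3, function(i) matrix(runif(15 * 12), 15, 12))
  p1 <- file.path(dir, "a.tif"); p2 <- file.path(dir, "b.tif")
  tiff::writeTIFF(pages1, p1, bits.per.sample = 16, compression = "none")
  tiff::writeTIFF(pages2, p2, bits.per.sample = 16, compression = "deflate")
  s <- open_tiff_stack(c(p1, p2))
  expect_equal(dim(s), c(15, 12, 7, 1))
  expect_false(s$writable)
  expect_identical(io_read_count(s), 0L)

  # reads match the raw integer page values (frame 6 lives in file 2)
  want <- tiff::readTIFF(p2, all = 2, as.is = TRUE)[[1]]
  got <- read_region(s, list(NULL, NULL, 6, 1))
  expect_identical(as.vector(got), as.numeric(as.vector(want)))

  expect_error(write_region(s, list(1, 1, 1, 1), 0),
               class = "calima_readonly_error")

  single <- file.path(dir, "one.tif")
  tiff::writeTIFF(matrix(runif(64), 8, 8), single, bits.per.sample = 8)
  expect_equal(dim(open_tiff_stack(single)), c(8, 8, 1, 1))

  odd <- file.path(dir, "odd.tif")
  tiff::writeTIFF(matrix(runif(100), 10, 10), odd, bits.per.sample = 16)
  expect_error(open_tiff_stack(c(p1, odd)), class = "calima_dimension_error")
})

test_that("storage accounting reproduces the raw on-disk byte layout", {
  expect_equal(storage_bytes(c(128, 128, 7378, 2), 8), 241762304)
  expect_equal(storage_bytes(c(1, 1, 1, 1), 8), 1)
  expect_equal(storage_bytes(c(512, 512, 1800, 1), 16), 943718400)
  fix <- write_raw_fixture(random_u8_array(c(9, 11, 4, 2), seed = 71),
                           n_files = 2)
  expect_equal(sum(file.size(fix$paths)), storage_bytes(c(9, 11, 4, 2), 8))
  expect_error(storage_bytes(c(0, 1, 1, 1), 8), class = "calima_value_error")
})
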