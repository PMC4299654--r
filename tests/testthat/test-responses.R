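proto_stack <- function(arr, seqs, durs, t_frame = 0.125, blank = 0,
                        use_times = NULL, dtype = "u8") {
  fix <- write_raw_fixture(arr, dtype = dtype, n_files = length(seqs))
  d <- dim(arr)
  h <- stack_header(n_rows = d[1], n_cols = d[2], n_channels = d[4],
                    dtype = dtype, frames_per_file = fix$header$frames_per_file,
                    t_frame_duration = t_frame, t_blank_time = blank,
                    sequence_ids_per_block = seqs, stimulus_durations = durs,
                    use_times = use_times)
  hp <- tempfile(fileext = ".json"); write_stack_header(h, hp)
  open_stack(fix$paths, hp)
}

test_that("region traces equal brute-force eager averaging", {
  arr <- random_u8_array(c(10, 10, 20, 2), seed = 23)
  s <- proto_stack(arr, list(c(1L, 2L)), c(1, 1))
  rois <- roi_set(list(c(5, 6, 15), 42, disc_pixels(c(5, 5), 2, c(10, 10))),
                  c(10, 10))
  tr <- extract_region_traces(s, rois)
  for (ch in 1:2) for (f in 1:20) {
    flat <- as.vector(arr[, , f, ch])
    for (r in 1:3)
      expect_equal(tr$values[r, f, ch], mean(flat[rois$regions[[r]]]))
  }
  # a constant stack gives constant traces; a single-pixel ROI gives the
  # pixel's own trace
  cs <- proto_stack(array(44, c(6, 6, 8, 1)), list(1L), 0.5)
  ct <- extract_region_traces(cs, roi_set(list(c(1, 8, 20), 17), c(6, 6)))
  expect_true(all(ct$values == 44))
  expect_equal(as.vector(extract_region_traces(
    s, roi_set(list(42), c(10, 10)))$values[1, , 1]),
    as.numeric(arr[2, 5, , 1]))    # linear index 42 = (row 2, col 5)

  expect_error(extract_region_traces(s, roi_set(list(), c(10, 10))),
               class = "calima_value_error")
})

test_that("invalid border pixels are excluded from ROI means, not zero-filled", {
  arr <- array(100, c(8, 8, 3, 1))
  s <- proto_stack(arr, list(1L), 0.25)
  sh <- matrix(0, 3, 2); sh[2, ] <- c(6, 0)    # frame 2: 6-row border
  set_frame_shifts(s, sh)
  rois <- roi_set(list(c(1, 2, 61, 62)), c(8, 8))  # spans valid + invalid rows
  tr <- extract_region_traces(s, rois)
  expect_equal(tr$values[1, 2, 1], 100)        # mean over the valid pixels only
  # an ROI fully inside the invalid border yields NA
  rois2 <- roi_set(list(c(5, 6)), c(8, 8))     # rows 5,6 of col 1 -> invalid
  expect_true(is.na(extract_region_traces(s, rois2)$values[1, 2, 1]))
})

test_that("derandomisation regroups randomised presentations into ordered trials", {
  # hand example: block orders [3,1,2] and [2,3,1]
  arr <- array(0, c(8, 8, 48, 1))
  s <- proto_stack(arr, list(c(3L, 1L, 2L), c(2L, 3L, 1L)), durs = c(1, 1, 1))
  fi <- frame_stimulus_info(s)
  map <- derandomize(fi, s$timeline)
  s1 <- map[map$stim_id == 1, ]
  expect_equal(unique(s1$presentation[s1$trial == 1]), 2)  # block 1, 2nd slot
  expect_equal(unique(s1$presentation[s1$trial == 2]), 6)  # block 2, 3rd slot

  # identity order, one block: the mapping is the identity segmentation
  si <- proto_stack(arr[, , 1:24, , drop = FALSE], list(c(1L, 2L, 3L)),
                    durs = c(1, 1, 1))
  mi <- derandomize(frame_stimulus_info(si), si$timeline)
  expect_equal(mi$frame, seq_len(24))
  expect_equal(mi$stim_id, rep(1:3, each = 8))

  # seeded random orders vs a brute-force per-stimulus scan; bijectivity
  set.seed(24)
  for (i in 1:10) {
    orders <- list(sample(4L), sample(4L), sample(4L))
    sp <- proto_stack(array(0, c(8, 8, 3 * 4 * 8, 1)), orders,
                      durs = rep(1, 4))
    fi <- frame_stimulus_info(sp)
    tl <- sp$timeline
    map <- derandomize(fi, tl)
    expect_false(anyDuplicated(map$frame) > 0)           # injective
    expect_equal(sort(map$frame), fi$frame[!is.na(fi$presentation_index)])
    for (sid in 1:4) {
      pres <- tl$presentation[tl$stim_id == sid][order(tl$t_start[tl$stim_id == sid])]
      for (tr in seq_along(pres)) {
        want <- fi$frame[!is.na(fi$presentation_index) &
                           fi$presentation_index == pres[tr]]
        got <- map$frame[map$stim_id == sid & map$trial == tr]
        expect_equal(got, sort(want))
      }
    }
    # composing the mapping with the presentation order reproduces the
    # original frame sequence
    recomposed <- map$frame[order(map$presentation, map$frame_in_trial)]
    expect_equal(recomposed, fi$frame[!is.na(fi$presentation_index)])
  }
})

test_that("responses are measured inside the use window on dF/F0 or raw traces", {
  # planted flat dF/F0 of a: mean and peak both recover a
  a <- 0.8; f0 <- 50; black <- 10
  arr <- array(black + f0, c(8, 8, 32, 1))
  arr[, , 9:16, 1] <- black + f0 * (1 + a)     # stimulus 2's presentation
  arr[1, 1, , 1] <- black                      # black region
  s <- proto_stack(arr, list(c(1L, 2L)), durs = c(1, 1), t_frame = 0.125,
                   blank = 0)
  # frames 17..32 are untagged? no: back-to-back 1 s each then nothing
  define_black_region(s, 1)
  assign_blank_frames(s, c(17, 18), c(1L, 33L))
  rois <- roi_set(list(c(20, 21, 28)), c(8, 8))
  for (meas in c("mean", "peak")) {
    rm <- extract_region_responses(s, rois, measure = meas, scale = "dff")
    expect_equal(rm$responses[1, 2, 1], a, tolerance = 1e-9)
    expect_equal(rm$responses[1, 1, 1], 0, tolerance = 1e-9)
  }
  expect_error(extract_region_responses(proto_stack(arr, list(c(1L, 2L)),
                                                    c(1, 1)), rois,
                                        scale = "dff"),
               class = "calima_baseline_error")

  # a transient confined to the first 0.3 s vanishes under use window [0.5, 2)
  cfg <- sim_config(dims = c(48, 48), n_blocks = 2, n_stimuli = 2,
                    stim_duration_s = 2, blank_time_s = 0.5, tail_blank_s = 4,
                    frame_rate = 8, n_cells = 2, f0_level = 80, noise_sd = 0,
                    amplitude = 1, tau_s = 0.05, seed = 25)
  gen <- generate_experiment(cfg, tempfile("usewin_"))
  s2 <- open_stack(gen$paths, gen$header_path)
  define_black_region(s2, gen$truth$black_region)
  assign_blank_frames(s2, gen$truth$clean_blank_frames, c(1L, dim(s2)[3] + 1L))
  rois2 <- roi_set(lapply(1:2, function(i)
    disc_pixels(gen$truth$cell_centers[i, ], 2, c(48, 48))), c(48, 48))
  full <- extract_region_responses(s2, rois2, "mean", "dff")
  s2$header$use_times <- rbind(c(0.5, 2), c(0.5, 2))
  windowed <- extract_region_responses(s2, rois2, "mean", "dff")
  expect_gt(max(full$trial_avg, na.rm = TRUE), 0.05)
  expect_lt(max(abs(windowed$trial_avg), na.rm = TRUE), 0.02)
})

test_that("a 16-direction, 5-trial protocol yields the full response geometry", {
  cfg <- sim_config(dims = c(16, 16), n_blocks = 5, n_stimuli = 16,
                    stim_duration_s = 0.25, blank_time_s = 0.25,
                    tail_blank_s = 2, frame_rate = 8, n_cells = 2,
                    cell_sigma_px = 1.2, f0_level = 90, noise_sd = 0,
                    amplitude = 1, tau_s = 0.3, seed = 26)
  gen <- generate_experiment(cfg, tempfile("geom_"))
  s <- open_stack(gen$paths, gen$header_path)
  rois <- roi_set(lapply(1:2, function(i)
    disc_pixels(gen$truth$cell_centers[i, ], 1.5, c(16, 16))), c(16, 16))
  rm <- extract_region_responses(s, rois, measure = "mean", scale = "raw")
  expect_equal(dim(rm$responses), c(2, 16, 5))
  expect_equal(dim(rm$trial_avg), c(2, 16))
  expect_equal(length(rm$psth), 16)
})

test_that("the mean measure on raw traces is linear in pixel values", {
  dims <- c(8, 8, 16, 1)
  set.seed(27)
  A <- array(runif(prod(dims), 0, 100), dims)
  B <- array(runif(prod(dims), 0, 100), dims)
  mk <- function(arr) proto_stack(arr, list(c(2L, 1L)), c(1, 1),
                                  dtype = "f32")
  rois <- roi_set(list(1:10, disc_pixels(c(4, 4), 2, c(8, 8))), c(8, 8))
  ra <- extract_region_responses(mk(A), rois, "mean", "raw")$responses
  rb <- extract_region_responses(mk(B), rois, "mean", "raw")$responses
  rab <- extract_region_responses(mk(A + B), rois, "mean", "raw")$responses
  expect_equal(rab, ra + rb, tolerance = 1e-5)
})

test_that("PSTHs are trial means truncated to the shortest trial", {
  seg <- function(n, v) matrix(v, 1, n)
  x <- structure(list(trial_traces = list(list(seg(15, 2), seg(16, 4)))),
                 class = "response_matrix")
  p <- psth(x)
  expect_equal(ncol(p[[1]]), 15)
  expect_equal(as.vector(p[[1]]), rep(3, 15))
  # identical trials: the PSTH equals any single trial
  y <- structure(list(trial_traces = list(list(seg(10, 7), seg(10, 7)))),
                 class = "response_matrix")
  expect_equal(as.vector(psth(y)[[1]]), rep(7, 10))

  # brute-force stacked mean on extracted data
  cfg <- sim_config(dims = c(16, 16), n_blocks = 3, n_stimuli = 2,
                    stim_duration_s = 0.5, blank_time_s = 0.25,
                    tail_blank_s = 2, frame_rate = 8, n_cells = 1,
                    cell_sigma_px = 1.2, noise_sd = 1, seed = 28)
  gen <- generate_experiment(cfg, tempfile("psth_"))
  s <- open_stack(gen$paths, gen$header_path)
  rois <- roi_set(list(disc_pixels(gen$truth$cell_centers[1, ], 1.5,
                                   c(16, 16))), c(16, 16))
  rm <- extract_region_responses(s, rois, "mean", "raw")
  for (sid in 1:2) {
    trials <- rm$trial_traces[[sid]]
    len <- min(vapply(trials, ncol, integer(1)))
    stacked <- sapply(trials, function(m) m[1, seq_len(len)])
    expect_equal(as.vector(rm$psth[[sid]][1, ]), rowMeans(stacked))
  }
})
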