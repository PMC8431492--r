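test_that("OpenPose JSON dir parses into a skeleton sequence", {
  dir <- make_json_dir(list(
    list(kp_block(list("1" = c(100, 100, 0.9), "2" = c(150, 100, 0.9))))))
  seq <- read_openpose_json_dir(dir)
  expect_s3_class(seq, "skeleton_sequence")
  expect_equal(n_frames(seq), 1L)
  expect_true(all(seq$valid[1, c(2, 3)]))       # joints 1, 2 (0-based)
  expect_equal(sum(seq$valid[1, ]), 2L)          # remaining 23 missing
  expect_equal(seq$x[1, 3], 150)
})

test_that("empty people array yields an all-missing frame", {
  dir <- make_json_dir(list(
    list(axis_posture_block()),
    list(),                       # no detections
    list(axis_posture_block())))
  seq <- read_openpose_json_dir(dir)
  expect_equal(n_frames(seq), 3L)
  expect_false(any(seq$valid[2, ]))
  expect_true(all(seq$x[2, ] == 0))
})

test_that("person selection: max summed confidence, then centroid tracking", {
  strong <- axis_posture_block(conf = 0.9)
  weak <- axis_posture_block(offset = c(300, 0), conf = 0.2)
  dir <- make_json_dir(list(list(weak, strong), list(strong, weak)))
  seq <- read_openpose_json_dir(dir)
  # frame 1: strong skeleton (total conf 6.3 > 1.4) regardless of order
  expect_equal(seq$x[1, 2], 100)
  # frame 2: tracking keeps the same (non-displaced) skeleton
  expect_equal(seq$x[2, 2], 100)
})

test_that("centroid tracking follows the subject, not a higher-conf intruder", {
  # subject drifts 20 px/frame; a parent with higher confidence appears later
  frames <- lapply(0:4, function(t) {
    subj <- axis_posture_block(offset = c(20 * t, 0), conf = 0.6)
    if (t < 2) list(subj)
    else list(axis_posture_block(offset = c(350, 0), conf = 0.95), subj)
  })
  dir <- make_json_dir(frames)
  seq <- read_openpose_json_dir(dir)
  expect_equal(seq$x[, 2], 100 + 20 * (0:4))  # neck x follows the subject
})

test_that("format errors are classed and name the offending file", {
  dir <- withr::local_tempdir()
  writeLines("{ not json", file.path(dir, "frame_000000.json"))
  expect_error(read_openpose_json_dir(dir),
               class = "skelquant_parse_error")
  expect_error(read_openpose_json_dir(dir), "frame_000000")

  dir2 <- withr::local_tempdir()
  jsonlite::write_json(
    list(people = list(list(pose_keypoints_2d = as.list(rep(0, 74))))),
    file.path(dir2, "frame_000000.json"), auto_unbox = TRUE)
  expect_error(read_openpose_json_dir(dir2),
               class = "skelquant_format_error")

  expect_error(read_openpose_json_dir(withr::local_tempdir()),
               class = "skelquant_input_error")
})

test_that("keypoint CSV round-trips bit-exactly through write/read/write", {
  cfg <- motion_config(T = 7, seed = 42, dropout_rate = 0.1)
  seq <- generate_sequence(cfg)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_keypoints_csv(seq, f1)
  back <- read_keypoints_csv(f1)
  expect_identical(back$x, seq$x)
  expect_identical(back$y, seq$y)
  expect_identical(back$conf, seq$conf)
  expect_identical(back$frame_index, seq$frame_index)
  write_keypoints_csv(back, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("keypoint CSV with a missing column is a format error", {
  cfg <- motion_config(T = 3, seed = 1)
  f <- withr::local_tempfile(fileext = ".csv")
  write_keypoints_csv(generate_sequence(cfg), f)
  lines <- readLines(f)
  lines[1] <- sub(",c24$", ",zz24", lines[1])
  writeLines(lines, f)
  expect_error(read_keypoints_csv(f), class = "skelquant_format_error")
  expect_error(read_keypoints_csv(f), "c24")
})

test_that("JSON fixture -> CSV -> re-read gives an identical sequence", {
  dir <- make_json_dir(list(list(axis_posture_block()),
                            list(axis_posture_block(offset = c(5, -3)))))
  seq <- read_openpose_json_dir(dir)
  f <- withr::local_tempfile(fileext = ".csv")
  write_keypoints_csv(seq, f)
  back <- read_keypoints_csv(f)
  expect_identical(back$x, seq$x)
  expect_identical(back$valid, seq$valid)
})

test_that("clean_sequence interpolates internal gaps linearly", {
  seq <- static_axis_sequence(T = 5)
  # knock out joint 9 (right hip) in frame 3; neighbours stay valid
  seq$x[3, 10] <- 0; seq$y[3, 10] <- 0; seq$conf[3, 10] <- 0
  seq$valid[3, 10] <- FALSE
  # give frames 2 and 4 different positions so the midpoint is informative
  seq$x[2, 10] <- 110; seq$x[4, 10] <- 130
  cleaned <- clean_sequence(seq)
  expect_equal(n_frames(cleaned), 5L)
  expect_equal(cleaned$x[3, 10], 120)  # midpoint of 110 and 130
  expect_equal(cleaned$y[3, 10], 200)
  expect_true(cleaned$valid[3, 10])
  expect_equal(cleaned$conf[3, 10], 0)
  expect_equal(attr(cleaned, "n_interpolated"), 1L)
})

test_that("clean_sequence trims leading/trailing frames missing required joints", {
  seq <- static_axis_sequence(T = 6)
  seq$valid[1:2, 2] <- FALSE  # neck missing in first two frames
  seq$valid[6, 9] <- FALSE    # mid hip missing in last frame
  cleaned <- clean_sequence(seq)
  expect_equal(n_frames(cleaned), 3L)
  expect_equal(attr(cleaned, "n_trimmed"), 3L)
  expect_equal(cleaned$frame_index, 2:4)
})

test_that("clean_sequence errors when no frame is usable", {
  seq <- static_axis_sequence(T = 4)
  seq$valid[, 9] <- FALSE  # mid hip never valid
  expect_error(clean_sequence(seq),
               class = "skelquant_unusable_recording_error")
})

test_that("clean_sequence is idempotent and never invents frames", {
  cfg <- motion_config(T = 60, seed = 11, dropout_rate = 0.15)
  seq <- generate_sequence(cfg)
  c1 <- clean_sequence(seq)
  c2 <- clean_sequence(c1)
  expect_lte(n_frames(c1), n_frames(seq))
  expect_identical(c1$x, c2$x)
  expect_identical(c1$y, c2$y)
  expect_identical(c1$valid, c2$valid)
  req <- default_required_joints() + 1L
  expect_true(all(c1$valid[, req]))
})
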