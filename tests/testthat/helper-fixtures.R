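# Programmatic fixtures: tiny OpenPose-dialect JSON frame files and
# hand-built skeleton sequences. Everything is generated at test time.

# a 25 x 3 keypoint block: all joints (0,0,0) except those given in `set`,
# a named list index -> c(x, y, conf) with 0-based joint indices
kp_block <- function(set) {
  m <- matrix(0, 25, 3)
  for (j in names(set)) m[as.integer(j) + 1L, ] <- set[[j]]
  m
}

write_openpose_frame <- function(path, people_blocks) {
  doc <- list(version = 1.3,
              people = lapply(people_blocks, function(m)
                list(pose_keypoints_2d = as.vector(t(m)))))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
}

# directory of per-frame JSONs; frames is a list of lists of 25x3 blocks
# (one block per person; an empty list means no detections that frame)
make_json_dir <- function(frames, dir = withr::local_tempdir(
                            .local_envir = parent.frame())) {
  for (t in seq_along(frames)) {
    write_openpose_frame(file.path(dir, sprintf("frame_%06d_keypoints.json",
                                                t - 1L)),
                         frames[[t]])
  }
  dir
}

# axis-aligned seated posture with all required joints valid; conf 0.9
axis_posture_block <- function(offset = c(0, 0), conf = 0.9) {
  kp_block(list(
    "1" = c(100 + offset[1], 100 + offset[2], conf),   # neck
    "2" = c(130 + offset[1], 100 + offset[2], conf),   # right shoulder
    "5" = c(70 + offset[1], 100 + offset[2], conf),    # left shoulder
    "8" = c(100 + offset[1], 200 + offset[2], conf),   # mid hip
    "9" = c(120 + offset[1], 200 + offset[2], conf),   # right hip
    "10" = c(120 + offset[1], 260 + offset[2], conf),  # right knee
    "12" = c(80 + offset[1], 200 + offset[2], conf)    # left hip
  ))
}

# skeleton_sequence with the axis posture repeated T times
static_axis_sequence <- function(T = 5, subject_id = "fix",
                                 session = "before") {
  b <- axis_posture_block()
  skeleton_sequence(matrix(rep(b[, 1], each = T), T, 25),
                    matrix(rep(b[, 2], each = T), T, 25),
                    matrix(rep(b[, 3], each = T), T, 25),
                    subject_id = subject_id, session = session)
}

# expected feature values of the axis posture (for structural checks)
axis_parameter_values <- c(
  left_shoulder_angle = 0, left_shoulder_length = 30,
  right_shoulder_angle = 0, right_shoulder_length = 30,
  left_hip_angle = 0, left_hip_length = 20,
  right_hip_angle = 0, right_hip_length = 20,
  right_thigh_angle = 90, right_thigh_length = 60,
  trunk_angle = 90)

# naive two-pass Pearson correlation: the independent oracle for acf_lag
naive_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}
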