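# Keypoint containers and readers for the OpenPose BODY_25 dialect and the
# flat keypoint CSV. A skeleton_sequence stores one subject's recording as
# T x 25 matrices (x, y, confidence) plus a validity mask; joint indices are
# 0-based throughout the user-facing API, matching the BODY_25 convention.

#' Construct a skeleton sequence
#'
#' Container for one recording: `T` frames of 25 BODY_25 joints. A joint is
#' flagged missing when it is encoded `(0, 0, 0)` (the pose-estimator
#' convention for an undetected joint) or when its confidence falls below
#' `conf_threshold`.
#'
#' @param x,y,conf Numeric `T x 25` matrices of pixel coordinates (image
#'   convention: origin top-left, y increases downward) and unitless
#'   confidences in `[0, 1]`.
#' @param frame_index Integer vector of length `T`, strictly increasing.
#' @param subject_id,session Recording identity; `session` is typically
#'   `"before"` or `"after"`.
#' @param fps Frames per second (metadata only).
#' @param conf_threshold Confidence below which a joint is treated as
#'   missing (default 0.1).
#' @param valid Optional `T x 25` logical matrix overriding the derived
#'   validity mask (used to preserve interpolated joints whose stored
#'   confidence is 0).
#' @return An object of class `skeleton_sequence`.
#' @export
skeleton_sequence <- function(x, y, conf, frame_index = seq_len(nrow(x)) - 1L,
                              subject_id = "subject", session = "before",
                              fps = 25, conf_threshold = 0.1, valid = NULL) {
  x <- as.matrix(x); y <- as.matrix(y); conf <- as.matrix(conf)
  if (ncol(x) != 25L || ncol(y) != 25L || ncol(conf) != 25L)
    sq_stop("a skeleton_sequence requires exactly 25 joints per frame",
            "skelquant_format_error")
  if (!all(dim(x) == dim(y)) || !all(dim(x) == dim(conf)))
    sq_stop("x, y and conf must have identical dimensions", "skelquant_format_error")
  if (any(conf < 0 | conf > 1, na.rm = TRUE))
    sq_stop("confidences must lie in [0, 1]", "skelquant_format_error")
  frame_index <- as.integer(frame_index)
  if (length(frame_index) != nrow(x) || anyNA(frame_index) ||
      (length(frame_index) > 1L && any(diff(frame_index) <= 0L)))
    sq_stop("frame_index must be strictly increasing and match the frame count",
            "skelquant_format_error")
  if (is.null(valid)) {
    valid <- conf >= conf_threshold & !(x == 0 & y == 0 & conf == 0)
  }
  structure(list(x = x, y = y, conf = conf, valid = valid,
                 frame_index = frame_index,
                 subject_id = as.character(subject_id),
                 session = as.character(session),
                 fps = fps, conf_threshold = conf_threshold),
            class = "skeleton_sequence")
}

#' @export
print.skeleton_sequence <- function(x, ...) {
  cat(sprintf("<skeleton_sequence> subject=%s session=%s T=%d fps=%s\n",
              x$subject_id, x$session, n_frames(x), format(x$fps)))
  cat(sprintf("  valid joints: %.1f%% of %d slots\n",
              100 * mean(x$valid), length(x$valid)))
  invisible(x)
}

#' Number of frames in a skeleton sequence
#' @param seq A `skeleton_sequence`.
#' @return Integer frame count `T`.
#' @export
n_frames <- function(seq) nrow(seq$x)

#' Extract one frame's keypoints
#'
#' @param seq A `skeleton_sequence`.
#' @param i Frame position (1-based row within the sequence).
#' @return A `25 x 3` matrix (columns x, y, conf) with a `valid` attribute;
#'   rows are BODY_25 joints 0..24.
#' @export
keypoint_frame <- function(seq, i) {
  m <- cbind(x = seq$x[i, ], y = seq$y[i, ], conf = seq$conf[i, ])
  rownames(m) <- body25_joint_names()
  attr(m, "valid") <- seq$valid[i, ]
  m
}

# order files by the last run of digits in the filename (frame index);
# falls back to lexicographic order when no digits are present
order_by_frame_index <- function(files) {
  idx <- suppressWarnings(as.integer(sub(".*?(\\d+)\\D*$", "\\1", basename(files))))
  if (anyNA(idx)) order(basename(files)) else order(idx, basename(files))
}

#' Read a directory of per-frame OpenPose BODY_25 JSON files
#'
#' Each file holds one frame: `{"people": [{"pose_keypoints_2d": [x0, y0,
#' c0, ..., x24, y24, c24]}]}`. Files are ordered by the frame index embedded
#' in the filename. Frames with an empty `people` array yield 25 missing
#' joints. When several people are detected, one is selected per frame: the
#' skeleton with maximal summed confidence over `required_joints` in the
#' first usable frame, then nearest-centroid tracking against the previously
#' selected skeleton, falling back to maximal confidence whenever the
#' centroid jumps more than `jump_threshold` pixels (a clinic scene may
#' contain a parent whose skeleton must not be picked up mid-recording).
#'
#' @param path Directory containing `*.json` files, one per frame.
#' @param person_policy Person-selection rule; only `"max-confidence"`
#'   (with centroid tracking, as above) is implemented.
#' @param conf_threshold Joint validity threshold passed to
#'   [skeleton_sequence()].
#' @param required_joints 0-based joint indices used for person scoring;
#'   defaults to [default_required_joints()].
#' @param jump_threshold Centroid jump (pixels) beyond which tracking falls
#'   back to max confidence. Default 150.
#' @param subject_id,session,fps Metadata stored on the result.
#' @return A `skeleton_sequence`.
#' @export
read_openpose_json_dir <- function(path, person_policy = "max-confidence",
                                   conf_threshold = 0.1,
                                   required_joints = default_required_joints(),
                                   jump_threshold = 150,
                                   subject_id = basename(path),
                                   session = "before", fps = 25) {
  if (!dir.exists(path))
    sq_stop(sprintf("directory not found: %s", path), "skelquant_input_error")
  files <- list.files(path, pattern = "\\.json$", full.names = TRUE)
  if (length(files) == 0L)
    sq_stop(sprintf("no JSON files in %s", path), "skelquant_input_error")
  files <- files[order_by_frame_index(files)]
  if (!identical(person_policy, "max-confidence"))
    sq_stop(sprintf("unknown person_policy: %s", person_policy),
            "skelquant_input_error")

  T_ <- length(files)
  X <- matrix(0, T_, 25L); Y <- matrix(0, T_, 25L); C <- matrix(0, T_, 25L)
  req <- required_joints + 1L
  prev_centroid <- NULL

  for (t in seq_len(T_)) {
    doc <- tryCatch(jsonlite::fromJSON(files[t], simplifyVector = FALSE),
                    error = function(e)
                      sq_stop(sprintf("malformed JSON in %s: %s",
                                      files[t], conditionMessage(e)),
                              "skelquant_parse_error"))
    people <- doc[["people"]]
    if (is.null(people))
      sq_stop(sprintf("no top-level 'people' array in %s", files[t]),
              "skelquant_format_error")
    if (length(people) == 0L) next  # frame stays (0,0,0) = all missing

    cand <- lapply(people, function(p) {
      kp <- unlist(p[["pose_keypoints_2d"]], use.names = FALSE)
      if (length(kp) != 75L)
        sq_stop(sprintf("pose_keypoints_2d has %d values (expected 75) in %s",
                        length(kp), files[t]), "skelquant_format_error")
      matrix(kp, ncol = 3L, byrow = TRUE)  # 25 x (x, y, conf)
    })
    score <- vapply(cand, function(m) sum(m[req, 3L]), numeric(1))
    centroids <- lapply(cand, function(m) {
      ok <- m[req, 3L] >= conf_threshold & !(m[req, 1L] == 0 & m[req, 2L] == 0)
      if (!any(ok)) return(c(NA_real_, NA_real_))
      c(mean(m[req, 1L][ok]), mean(m[req, 2L][ok]))
    })

    pick <- which.max(score)
    if (!is.null(prev_centroid)) {
      d <- vapply(centroids, function(ct)
        if (anyNA(ct)) Inf else sqrt(sum((ct - prev_centroid)^2)), numeric(1))
      if (any(is.finite(d)) && min(d) <= jump_threshold) pick <- which.min(d)
    }
    m <- cand[[pick]]
    X[t, ] <- m[, 1L]; Y[t, ] <- m[, 2L]; C[t, ] <- m[, 3L]
    if (!anyNA(centroids[[pick]])) prev_centroid <- centroids[[pick]]
  }

  skeleton_sequence(X, Y, C, frame_index = seq_len(T_) - 1L,
                    subject_id = subject_id, session = session, fps = fps,
                    conf_threshold = conf_threshold)
}

csv_header_names <- function() {
  c("frame", paste0(rep(c("x", "y", "c"), 25), rep(0:24, each = 3)))
}

#' Read a flat keypoint CSV
#'
#' Columns `frame, x0, y0, c0, ..., x24, y24, c24`, one row per frame.
#' Round-trips bit-exactly with [write_keypoints_csv()] (coordinates are
#' written with 17 significant digits).
#'
#' @param path CSV file path.
#' @param conf_threshold,subject_id,session,fps As in
#'   [read_openpose_json_dir()].
#' @return A `skeleton_sequence`.
#' @export
read_keypoints_csv <- function(path, conf_threshold = 0.1,
                               subject_id = sub("\\.csv$", "", basename(path)),
                               session = "before", fps = 25) {
  if (!file.exists(path))
    sq_stop(sprintf("file not found: %s", path), "skelquant_input_error")
  df <- utils::read.csv(path, check.names = FALSE)
  want <- csv_header_names()
  if (!all(want %in% names(df)))
    sq_stop(sprintf("keypoint CSV %s lacks columns: %s", path,
                    paste(setdiff(want, names(df)), collapse = ", ")),
            "skelquant_format_error")
  xs <- as.matrix(df[paste0("x", 0:24)])
  ys <- as.matrix(df[paste0("y", 0:24)])
  cs <- as.matrix(df[paste0("c", 0:24)])
  storage.mode(xs) <- storage.mode(ys) <- storage.mode(cs) <- "double"
  dimnames(xs) <- dimnames(ys) <- dimnames(cs) <- NULL
  skeleton_sequence(xs, ys, cs, frame_index = as.integer(df$frame),
                    subject_id = subject_id, session = session, fps = fps,
                    conf_threshold = conf_threshold)
}

#' Write a skeleton sequence to the flat keypoint CSV dialect
#'
#' @param seq A `skeleton_sequence`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_keypoints_csv <- function(seq, path) {
  T_ <- n_frames(seq)
  body <- matrix("", T_, 76L)
  body[, 1L] <- as.character(seq$frame_index)
  num <- matrix(NA_real_, T_, 75L)
  num[, seq(1, 75, by = 3)] <- seq$x
  num[, seq(2, 75, by = 3)] <- seq$y
  num[, seq(3, 75, by = 3)] <- seq$conf
  body[, 2:76] <- sprintf("%.17g", num)  # %.17g round-trips doubles exactly
  lines <- c(paste(csv_header_names(), collapse = ","),
             apply(body, 1L, paste, collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Write a skeleton sequence as per-frame OpenPose JSON files
#'
#' Emits one `<prefix>_<%06d>_keypoints.json` file per frame in the BODY_25
#' dialect consumed by [read_openpose_json_dir()]. Missing joints are encoded
#' `(0, 0, 0)`.
#'
#' @param seq A `skeleton_sequence`.
#' @param path Output directory (created if needed).
#' @param prefix Filename prefix; default the subject id.
#' @return `path`, invisibly.
#' @export
write_openpose_json_dir <- function(seq, path, prefix = seq$subject_id) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  T_ <- n_frames(seq)
  for (t in seq_len(T_)) {
    kp <- as.vector(rbind(seq$x[t, ], seq$y[t, ], seq$conf[t, ]))
    doc <- list(version = 1.3,
                people = list(list(pose_keypoints_2d = kp)))
    jsonlite::write_json(doc, file.path(path,
      sprintf("%s_%06d_keypoints.json", prefix, seq$frame_index[t])),
      auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Trim and gap-fill a skeleton sequence
#'
#' Leading and trailing frames in which any required joint is missing are
#' trimmed. Internal gaps in required joints are filled by per-coordinate
#' linear interpolation between the nearest valid frames; interpolated
#' joints keep confidence 0 but are marked valid. Gaps of any length are
#' interpolated rather than segmented, preserving the temporal adjacency the
#' differencing and lag-1 autocorrelation features rely on. Idempotent.
#'
#' @param seq A `skeleton_sequence`.
#' @param required_joints 0-based joint indices that must be present in
#'   every output frame; defaults to [default_required_joints()].
#' @return A `skeleton_sequence` with no missing required joints and
#'   `T >= 2`; an `n_interpolated` attribute counts filled joint slots.
#' @export
clean_sequence <- function(seq, required_joints = default_required_joints()) {
  req <- required_joints + 1L
  usable <- which(rowSums(seq$valid[, req, drop = FALSE]) == length(req))
  if (length(usable) == 0L)
    sq_stop(sprintf("recording %s/%s: no frame has all required joints valid",
                    seq$subject_id, seq$session),
            "skelquant_unusable_recording_error")
  first <- usable[1L]; last <- usable[length(usable)]
  keep <- first:last
  if (length(keep) < 2L)
    sq_stop(sprintf("recording %s/%s: fewer than 2 usable frames after trimming",
                    seq$subject_id, seq$session),
            "skelquant_unusable_recording_error")

  X <- seq$x[keep, , drop = FALSE]; Y <- seq$y[keep, , drop = FALSE]
  C <- seq$conf[keep, , drop = FALSE]; V <- seq$valid[keep, , drop = FALSE]
  n_interp <- 0L
  for (j in req) {
    bad <- which(!V[, j])
    if (length(bad) == 0L) next
    good <- which(V[, j])  # trimming guarantees first/last rows are good
    X[bad, j] <- stats::approx(good, X[good, j], xout = bad)$y
    Y[bad, j] <- stats::approx(good, Y[good, j], xout = bad)$y
    C[bad, j] <- 0
    V[bad, j] <- TRUE
    n_interp <- n_interp + length(bad)
  }
  out <- skeleton_sequence(X, Y, C, frame_index = seq$frame_index[keep],
                           subject_id = seq$subject_id, session = seq$session,
                           fps = seq$fps, conf_threshold = seq$conf_threshold,
                           valid = V)
  attr(out, "n_trimmed") <- n_frames(seq) - length(keep)
  attr(out, "n_interpolated") <- n_interp
  out
}
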