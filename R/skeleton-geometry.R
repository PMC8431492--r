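# Eleven per-frame skeleton parameters computed from BODY_25 joints in raw
# image coordinates (origin top-left, y down, pixels). Angles come from the
# absolute arctangent of the segment slope (range [0, 90] degrees), except
# the trunk angle which keeps orientation over [0, 180). Lengths are plain
# 2D Euclidean distances in pixels — no pixel-to-metric calibration exists,
# so lengths are camera-geometry dependent across subjects.

#' Canonical skeleton parameter names
#'
#' Fixed row/column order used by every output: left shoulder angle/length,
#' right shoulder angle/length, left hip angle/length, right hip
#' angle/length, right thigh angle/length, trunk angle. Only the right thigh
#' is defined; the asymmetry is deliberate.
#'
#' @return Character vector of length 11.
#' @export
parameter_names <- function() {
  c("left_shoulder_angle", "left_shoulder_length",
    "right_shoulder_angle", "right_shoulder_length",
    "left_hip_angle", "left_hip_length",
    "right_hip_angle", "right_hip_length",
    "right_thigh_angle", "right_thigh_length",
    "trunk_angle")
}

# joint pairings (0-based BODY_25 indices): segment endpoint a, reference b
parameter_joint_pairs <- function() {
  list(left_shoulder  = c(5L, 1L),
       right_shoulder = c(2L, 1L),
       left_hip       = c(12L, 8L),
       right_hip      = c(9L, 8L),
       right_thigh    = c(10L, 9L),
       trunk          = c(1L, 8L))
}

# vectorised |atan(dy/dx)| in degrees; dx == 0 -> exactly 90
abs_slope_angle <- function(dx, dy, what = "segment") {
  if (any(dx == 0 & dy == 0))
    sq_stop(sprintf("%s: coincident endpoints, angle undefined", what),
            "skelquant_degenerate_segment_error")
  ifelse(dx == 0, 90, abs(atan(dy / dx)) * 180 / pi)
}

#' Angle of a skeleton segment
#'
#' Absolute arctangent of the slope between two joints, in degrees:
#' `|atan((y_a - y_b) / (x_a - x_b))| * 180 / pi`, in `[0, 90]`. A vertical
#' segment (`x_a == x_b`) returns exactly 90, the arctangent limit.
#' Symmetric under endpoint swap.
#'
#' @param a,b Numeric length-2 joint coordinates `(x, y)` in pixels.
#' @return Angle in degrees.
#' @export
#' @examples
#' segment_angle(c(3, 4), c(0, 0))  # atan(4/3) in degrees, 53.13
segment_angle <- function(a, b) {
  abs_slope_angle(a[1] - b[1], a[2] - b[2])
}

#' Length of a skeleton segment
#'
#' 2D Euclidean distance between two joints, in pixels.
#'
#' @inheritParams segment_angle
#' @return Non-negative length in pixels.
#' @export
segment_length <- function(a, b) {
  sqrt((a[1] - b[1])^2 + (a[2] - b[2])^2)
}

#' Trunk angle from neck and mid-hip joints
#'
#' Let `phi = atan((y_neck - y_hip) / (x_neck - x_hip))` in degrees,
#' `phi` in `(-90, 90]` with the vertical limit mapped to exactly 90. The
#' trunk angle is `phi` when `phi >= 0` and `phi + 180` otherwise, giving a
#' full orientation in `[0, 180)` (an upright seated trunk in image
#' coordinates is 90).
#'
#' @param neck,mid_hip Numeric length-2 joint coordinates `(x, y)` in pixels.
#' @return Angle in degrees in `[0, 180)`.
#' @export
trunk_angle <- function(neck, mid_hip) {
  dx <- neck[1] - mid_hip[1]; dy <- neck[2] - mid_hip[2]
  if (any(dx == 0 & dy == 0))
    sq_stop("trunk: coincident neck and mid-hip, angle undefined",
            "skelquant_degenerate_segment_error")
  phi <- ifelse(dx == 0, 90, atan(dy / dx) * 180 / pi)
  ifelse(phi < 0, phi + 180, phi)
}

#' Compute the eleven skeleton parameters for one frame
#'
#' Pairings: shoulders (2,1) and (5,1) about the neck; hips (9,8) and (12,8)
#' about the mid hip; right thigh (10,9); trunk (1,8).
#'
#' @param frame A `25 x k` numeric matrix (`k >= 2`; columns x, y first), as
#'   returned by [keypoint_frame()], with rows in BODY_25 index order.
#' @return Named numeric vector of length 11 in [parameter_names()] order;
#'   angles in degrees, lengths in pixels.
#' @export
compute_parameter_frame <- function(frame) {
  frame <- as.matrix(frame)
  if (nrow(frame) != 25L)
    sq_stop("expected 25 joint rows", "skelquant_format_error")
  pairs <- parameter_joint_pairs()
  out <- numeric(0)
  for (nm in names(pairs)) {
    a <- frame[pairs[[nm]][1] + 1L, 1:2]
    b <- frame[pairs[[nm]][2] + 1L, 1:2]
    if (identical(nm, "trunk")) {
      ang <- tryCatch(trunk_angle(a, b), skelquant_degenerate_segment_error =
        function(e) sq_stop(sprintf("trunk_angle: %s", conditionMessage(e)),
                            "skelquant_degenerate_segment_error"))
      out <- c(out, trunk_angle = ang)
    } else {
      ang <- tryCatch(segment_angle(a, b), skelquant_degenerate_segment_error =
        function(e) sq_stop(sprintf("%s_angle: %s", nm, conditionMessage(e)),
                            "skelquant_degenerate_segment_error"))
      out <- c(out, stats::setNames(c(ang, segment_length(a, b)),
                                    paste0(nm, c("_angle", "_length"))))
    }
  }
  out[parameter_names()]
}

#' Compute the eleven parameter time series for a recording
#'
#' Vectorised over frames. The input should be a cleaned sequence (see
#' [clean_sequence()]); missing required joints raise an error naming the
#' offending frame.
#'
#' @param seq A `skeleton_sequence`.
#' @return An object of class `parameter_series_set`: list with `values`
#'   (a `T x 11` matrix, columns in [parameter_names()] order) plus
#'   `subject_id`, `session` and `fps`.
#' @export
compute_parameter_series <- function(seq) {
  req <- default_required_joints() + 1L
  if (!all(seq$valid[, req]))
    sq_stop(sprintf(
      "recording %s/%s has missing required joints (first at frame row %d); run clean_sequence() first",
      seq$subject_id, seq$session,
      which(rowSums(!seq$valid[, req, drop = FALSE]) > 0L)[1L]),
      "skelquant_input_error")

  T_ <- n_frames(seq)
  pairs <- parameter_joint_pairs()
  vals <- matrix(NA_real_, T_, 11L, dimnames = list(NULL, parameter_names()))
  for (nm in names(pairs)) {
    ai <- pairs[[nm]][1] + 1L; bi <- pairs[[nm]][2] + 1L
    dx <- seq$x[, ai] - seq$x[, bi]
    dy <- seq$y[, ai] - seq$y[, bi]
    if (any(dx == 0 & dy == 0))
      sq_stop(sprintf("%s: coincident joints at frame row %d", nm,
                      which(dx == 0 & dy == 0)[1L]),
              "skelquant_degenerate_segment_error")
    if (identical(nm, "trunk")) {
      phi <- ifelse(dx == 0, 90, atan(dy / dx) * 180 / pi)
      vals[, "trunk_angle"] <- ifelse(phi < 0, phi + 180, phi)
    } else {
      vals[, paste0(nm, "_angle")] <- ifelse(dx == 0, 90,
                                             abs(atan(dy / dx)) * 180 / pi)
      vals[, paste0(nm, "_length")] <- sqrt(dx^2 + dy^2)
    }
  }
  structure(list(values = vals, subject_id = seq$subject_id,
                 session = seq$session, fps = seq$fps),
            class = "parameter_series_set")
}

#' @export
print.parameter_series_set <- function(x, ...) {
  cat(sprintf("<parameter_series_set> subject=%s session=%s T=%d, 11 parameters\n",
              x$subject_id, x$session, nrow(x$values)))
  invisible(x)
}

#' @export
as.data.frame.parameter_series_set <- function(x, ...) {
  data.frame(subject_id = x$subject_id, session = x$session,
             frame = seq_len(nrow(x$values)) - 1L, x$values,
             check.names = FALSE)
}

#' Write / read the per-frame parameter-series CSV
#'
#' Columns: `subject_id, session, frame`, then the 11 canonical parameter
#' names, one row per frame.
#'
#' @param params A `parameter_series_set`.
#' @param path CSV file path.
#' @return `write_parameter_csv()` returns `path` invisibly;
#'   `read_parameter_csv()` returns a `parameter_series_set`.
#' @export
write_parameter_csv <- function(params, path) {
  utils::write.csv(as.data.frame(params), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_parameter_csv
#' @export
read_parameter_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  want <- c("subject_id", "session", "frame", parameter_names())
  if (!all(want %in% names(df)))
    sq_stop(sprintf("parameter CSV %s lacks columns: %s", path,
                    paste(setdiff(want, names(df)), collapse = ", ")),
            "skelquant_format_error")
  structure(list(values = as.matrix(df[parameter_names()]),
                 subject_id = as.character(df$subject_id[1L]),
                 session = as.character(df$session[1L]), fps = NA_real_),
            class = "parameter_series_set")
}
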