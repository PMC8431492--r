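# Synthetic seated-child keypoint streams. Each joint coordinate jitters as
# an independent stationary AR(1) process around a fixed seated base
# posture; two correlated, body-plausible motion modes are layered on top:
# a sinusoidal horizontal sway of the head/shoulder girdle (swaying back
# and forth as seen by a frontal camera) and a sinusoidal rotation of the
# lower body about the mid hip (swiveling on the chair). Optional dropout
# replaces joints with the (0,0,0) undetected encoding. All randomness is
# seeded, so identical configs reproduce identical sequences bit for bit.

# run expr with a private RNG stream, restoring the caller's state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Hard-coded seated base posture
#'
#' A plausible frontal-view seated child in a 640 x 480 image (origin
#' top-left, y down, pixels): head around y = 140, shoulders y = 185, hips
#' y = 300, knees y = 370. Stable across versions so fixtures stay stable.
#'
#' @return A `25 x 2` matrix (columns x, y) in BODY_25 index order.
#' @export
base_posture <- function() {
  m <- matrix(c(
    320, 140,   # 0  nose
    320, 180,   # 1  neck
    270, 185,   # 2  right shoulder
    255, 235,   # 3  right elbow
    250, 280,   # 4  right wrist
    370, 185,   # 5  left shoulder
    385, 235,   # 6  left elbow
    390, 280,   # 7  left wrist
    320, 300,   # 8  mid hip
    285, 300,   # 9  right hip
    275, 370,   # 10 right knee
    270, 440,   # 11 right ankle
    355, 300,   # 12 left hip
    365, 370,   # 13 left knee
    370, 440,   # 14 left ankle
    308, 132,   # 15 right eye
    332, 132,   # 16 left eye
    296, 140,   # 17 right ear
    344, 140,   # 18 left ear
    372, 465,   # 19 left big toe
    380, 463,   # 20 left small toe
    368, 452,   # 21 left heel
    268, 465,   # 22 right big toe
    260, 463,   # 23 right small toe
    272, 452    # 24 right heel
  ), ncol = 2, byrow = TRUE)
  colnames(m) <- c("x", "y")
  rownames(m) <- body25_joint_names()
  m
}

#' Motion simulation configuration
#'
#' The jitter is parameterised by its stationary standard deviation
#' `jitter_sd` (not the innovation SD): the AR(1) displacement
#' `u(t) = ar_coefficient * u(t-1) + e(t)` uses innovation SD
#' `jitter_sd * sqrt(1 - ar_coefficient^2)`, so the marginal SD equals
#' `jitter_sd` for every `ar_coefficient` and ground truth is directly
#' comparable across persistence levels.
#'
#' Defaults describe the pre-treatment condition of the simulated cohort:
#' strong persistence (`ar_coefficient = 0.95`), 3 px jitter, 4 px sway and
#' 3 degrees of swivel over T = 3000 frames at 25 fps.
#'
#' @param T Frame count (>= 2). Default 3000 (two minutes at 25 fps).
#' @param fps Frames per second. Default 25.
#' @param ar_coefficient Temporal persistence `phi` of the jitter,
#'   in `[0, 1)`.
#' @param jitter_sd Stationary SD of per-joint displacement, pixels.
#' @param sway_amplitude Pixels of sinusoidal horizontal offset applied to
#'   nose, neck, shoulders, eyes and ears (joints 0, 1, 2, 5, 15-18).
#' @param swivel_amplitude Degrees of sinusoidal rotation of the lower body
#'   (joints 9-14 and 19-24) about the mid hip.
#' @param sway_freq,swivel_freq Oscillation frequencies in Hz; defaults 0.2
#'   and 0.35 (slow postural oscillations). Phases are drawn per sequence.
#' @param dropout_rate Per-joint per-frame probability of an undetected
#'   `(0, 0, 0)` joint, in `[0, 1)`. Default 0: detector dropouts are opt-in
#'   so motion ground truth stays exact.
#' @param base `25 x 2` base posture matrix; default [base_posture()].
#' @param seed Integer RNG seed.
#' @param subject_id,session Metadata stored on generated sequences.
#' @return A list of class `motion_config`.
#' @export
motion_config <- function(T = 3000L, fps = 25, ar_coefficient = 0.95,
                          jitter_sd = 3, sway_amplitude = 4,
                          swivel_amplitude = 3, sway_freq = 0.2,
                          swivel_freq = 0.35, dropout_rate = 0,
                          base = base_posture(), seed = 1L,
                          subject_id = "sim", session = "before") {
  T <- as.integer(T)
  if (is.na(T) || T < 2L)
    sq_stop("T must be an integer >= 2", "skelquant_input_error")
  if (ar_coefficient < 0 || ar_coefficient >= 1)
    sq_stop("ar_coefficient must lie in [0, 1)", "skelquant_input_error")
  if (jitter_sd < 0)
    sq_stop("jitter_sd must be >= 0", "skelquant_input_error")
  if (dropout_rate < 0 || dropout_rate >= 1)
    sq_stop("dropout_rate must lie in [0, 1)", "skelquant_input_error")
  base <- as.matrix(base)
  if (!all(dim(base) == c(25L, 2L)))
    sq_stop("base posture must be a 25 x 2 matrix", "skelquant_input_error")
  structure(list(T = T, fps = fps, ar_coefficient = ar_coefficient,
                 jitter_sd = jitter_sd, sway_amplitude = sway_amplitude,
                 swivel_amplitude = swivel_amplitude, sway_freq = sway_freq,
                 swivel_freq = swivel_freq, dropout_rate = dropout_rate,
                 base = base, seed = as.integer(seed),
                 subject_id = subject_id, session = session),
            class = "motion_config")
}

sway_joints <- function() c(0L, 1L, 2L, 5L, 15L, 16L, 17L, 18L)
swivel_joints <- function() c(9L, 10L, 11L, 12L, 13L, 14L, 19L:24L)

# one stationary AR(1) path of length T with marginal SD sigma
ar1_path <- function(T, phi, sigma) {
  if (sigma == 0) return(numeric(T))
  innov_sd <- sigma * sqrt(1 - phi^2)
  e <- stats::rnorm(T, 0, innov_sd)
  if (phi == 0) return(e)  # iid N(0, sigma)
  as.numeric(stats::filter(e, phi, method = "recursive",
                           init = stats::rnorm(1, 0, sigma)))
}

#' Generate a synthetic seated-motion skeleton sequence
#'
#' Per-joint, per-coordinate displacements follow independent stationary
#' AR(1) processes (see [motion_config()]); sway and swivel add correlated
#' oscillations; dropout replaces joints with `(0, 0, 0)`. Confidences of
#' detected joints are drawn uniformly in `[0.55, 0.95]`. Identical
#' configurations (including seed) reproduce identical sequences.
#'
#' @param cfg A [motion_config()].
#' @return A `skeleton_sequence` of `cfg$T` frames.
#' @export
generate_sequence <- function(cfg) {
  if (!inherits(cfg, "motion_config"))
    sq_stop("cfg must be a motion_config", "skelquant_input_error")
  with_seed(cfg$seed, {
    T_ <- cfg$T
    tt <- (seq_len(T_) - 1L) / cfg$fps  # seconds

    jit_x <- vapply(1:25, function(j)
      ar1_path(T_, cfg$ar_coefficient, cfg$jitter_sd), numeric(T_))
    jit_y <- vapply(1:25, function(j)
      ar1_path(T_, cfg$ar_coefficient, cfg$jitter_sd), numeric(T_))

    # base positions, swivel applied to lower body about the mid hip
    X <- matrix(rep(cfg$base[, 1], each = T_), T_, 25L)
    Y <- matrix(rep(cfg$base[, 2], each = T_), T_, 25L)
    if (cfg$swivel_amplitude != 0) {
      phase <- stats::runif(1, 0, 2 * pi)
      alpha <- cfg$swivel_amplitude * pi / 180 *
        sin(2 * pi * cfg$swivel_freq * tt + phase)
      ctr <- cfg$base[9L, ]  # mid hip, joint 8
      for (j in swivel_joints() + 1L) {
        dx <- cfg$base[j, 1] - ctr[1]; dy <- cfg$base[j, 2] - ctr[2]
        X[, j] <- ctr[1] + cos(alpha) * dx - sin(alpha) * dy
        Y[, j] <- ctr[2] + sin(alpha) * dx + cos(alpha) * dy
      }
    }
    if (cfg$sway_amplitude != 0) {
      phase <- stats::runif(1, 0, 2 * pi)
      sway <- cfg$sway_amplitude * sin(2 * pi * cfg$sway_freq * tt + phase)
      X[, sway_joints() + 1L] <- X[, sway_joints() + 1L] + sway
    }
    X <- X + jit_x
    Y <- Y + jit_y

    C <- matrix(stats::runif(T_ * 25L, 0.55, 0.95), T_, 25L)
    if (cfg$dropout_rate > 0) {
      drop <- matrix(stats::runif(T_ * 25L) < cfg$dropout_rate, T_, 25L)
      X[drop] <- 0; Y[drop] <- 0; C[drop] <- 0
    }
    skeleton_sequence(X, Y, C, frame_index = seq_len(T_) - 1L,
                      subject_id = cfg$subject_id, session = cfg$session,
                      fps = cfg$fps)
  })
}

#' Paired-cohort simulation configuration
#'
#' @param n_subjects Number of paired subjects, >= 2. Default 25, the study
#'   size the simulator stands in for.
#' @param before,after [motion_config()] templates for the two sessions;
#'   they should differ only in motion parameters. Defaults: before
#'   `phi = 0.95, jitter 3 px, sway 4 px, swivel 3 deg`; after
#'   `phi = 0.7, jitter 1.5 px, sway 1 px, swivel 1 deg` — amplitude and
#'   persistence both reduced, the direction a calming medication effect
#'   implies.
#' @param posture_scale_range Per-subject uniform body-proportion scale
#'   range (distinct body sizes). Default `c(0.85, 1.15)`.
#' @param posture_shift Max per-subject uniform position offset, pixels.
#'   Default 40.
#' @param seed Integer master seed; per-subject and per-session seeds are
#'   derived as `seed * 10000 + k` (keep `seed` below ~200000).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 25L,
                          before = motion_config(),
                          after = motion_config(ar_coefficient = 0.7,
                                                jitter_sd = 1.5,
                                                sway_amplitude = 1,
                                                swivel_amplitude = 1,
                                                session = "after"),
                          posture_scale_range = c(0.85, 1.15),
                          posture_shift = 40, seed = 1L) {
  n_subjects <- as.integer(n_subjects)
  if (is.na(n_subjects) || n_subjects < 2L)
    sq_stop("n_subjects must be an integer >= 2", "skelquant_input_error")
  structure(list(n_subjects = n_subjects, before = before, after = after,
                 posture_scale_range = posture_scale_range,
                 posture_shift = posture_shift, seed = as.integer(seed)),
            class = "cohort_config")
}

#' Generate a paired before/after cohort of keypoint sequences
#'
#' Each subject gets a persistent identity: a base posture perturbed by a
#' random body-proportion scale (about the mid hip) and a position offset,
#' shared by both sessions. The before/after session templates differ only
#' in motion parameters, so any downstream before/after difference is the
#' built-in effect. Fully determined by `cfg$seed`.
#'
#' @param cfg A [cohort_config()].
#' @return List with `before` and `after` (lists of `skeleton_sequence`)
#'   and `manifest`, a data frame of per-recording generating parameters.
#' @export
generate_paired_cohort <- function(cfg) {
  if (!inherits(cfg, "cohort_config"))
    sq_stop("cfg must be a cohort_config", "skelquant_input_error")
  base_seed <- cfg$seed * 10000
  seqs_b <- vector("list", cfg$n_subjects)
  seqs_a <- vector("list", cfg$n_subjects)
  manifest <- list()
  for (i in seq_len(cfg$n_subjects)) {
    sid <- sprintf("S%02d", i)
    posture <- with_seed(base_seed + i, {
      sc <- stats::runif(1, cfg$posture_scale_range[1],
                         cfg$posture_scale_range[2])
      off <- stats::runif(2, -cfg$posture_shift, cfg$posture_shift)
      b <- base_posture()
      ctr <- b[9L, ]  # mid hip
      sweep((b - matrix(ctr, 25, 2, byrow = TRUE)) * sc, 2,
            -(ctr + off))  # scale about mid hip, then shift
    })
    for (ses in c("before", "after")) {
      tmpl <- cfg[[ses]]
      tmpl$base <- posture
      tmpl$subject_id <- sid
      tmpl$session <- ses
      tmpl$seed <- base_seed + (if (ses == "before") 1000L else 2000L) + i
      sq <- generate_sequence(tmpl)
      if (ses == "before") seqs_b[[i]] <- sq else seqs_a[[i]] <- sq
      manifest[[length(manifest) + 1L]] <- data.frame(
        subject_id = sid, session = ses, T = tmpl$T, fps = tmpl$fps,
        ar_coefficient = tmpl$ar_coefficient, jitter_sd = tmpl$jitter_sd,
        sway_amplitude = tmpl$sway_amplitude,
        swivel_amplitude = tmpl$swivel_amplitude,
        dropout_rate = tmpl$dropout_rate, seed = tmpl$seed)
    }
  }
  list(before = seqs_b, after = seqs_a, manifest = do.call(rbind, manifest))
}

#' Extract feature tables for a simulated (or loaded) paired cohort
#'
#' Runs [quantify_recording()] over both sessions and assembles the two
#' feature tables.
#'
#' @param cohort List with `before` and `after` lists of
#'   `skeleton_sequence`, e.g. from [generate_paired_cohort()].
#' @param config An [analysis_config()].
#' @return A [paired_cohort()] of feature tables, ready for
#'   [compare_cohort()].
#' @export
cohort_features <- function(cohort, config = analysis_config()) {
  fb <- feature_table(lapply(cohort$before, quantify_recording,
                             config = config))
  fa <- feature_table(lapply(cohort$after, quantify_recording,
                             config = config))
  paired_cohort(fb, fa)
}
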