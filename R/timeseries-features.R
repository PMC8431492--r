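# Per-recording movement features: lag-1 autocorrelation of each parameter
# series, lag-1 autocorrelation of its first difference, and a windowed
# averaged variance. 11 parameters x 3 summaries = 33 features.
#
# The autocorrelation is the Pearson correlation over the T - tau
# overlapping pairs, each sub-series centred by its own mean. The classical
# stationary estimator (common mean, full-series variance in the
# denominator) is available behind method = "stationary" for sensitivity
# analysis; the two agree closely for long series.

#' Analysis configuration
#'
#' @param window_size Window size `W` in frames for [averaged_variance()];
#'   must be >= 2 (a window of one frame has zero variance by definition).
#'   Default 30, roughly one second at common clinic-camera frame rates.
#' @param lag Autocorrelation lag `tau` in frames; default 1.
#' @param acf_method `"pairwise"` (default) or `"stationary"`, see
#'   [acf_lag()].
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(window_size = 30L, lag = 1L,
                            acf_method = c("pairwise", "stationary")) {
  window_size <- as.integer(window_size); lag <- as.integer(lag)
  if (is.na(window_size) || window_size < 2L)
    sq_stop("window_size must be an integer >= 2", "skelquant_input_error")
  if (is.na(lag) || lag < 1L)
    sq_stop("lag must be an integer >= 1", "skelquant_input_error")
  structure(list(window_size = window_size, lag = lag,
                 acf_method = match.arg(acf_method),
                 variance_denominator = "population"),
            class = "analysis_config")
}

#' First difference of a series
#'
#' `s'(i) = s(i+1) - s(i)`, length `T - 1`. Removes level and exposes
#' frame-to-frame motion.
#'
#' @param s Numeric vector, length >= 2.
#' @return Numeric vector of length `length(s) - 1`.
#' @export
difference <- function(s) {
  if (length(s) < 2L)
    sq_stop("difference() needs a series of length >= 2",
            "skelquant_series_too_short_error")
  diff(s)
}

#' Lag-tau autocorrelation coefficient
#'
#' Pearson correlation between the `T - tau` overlapping pairs
#' `(s(t), s(t + tau))`, each sub-series centred by its own mean
#' (`method = "pairwise"`, the default). `method = "stationary"` uses the
#' classical estimator with a common mean and the full-series sum of squares
#' in the denominator. Result in `[-1, 1]`.
#'
#' @param s Numeric vector.
#' @param tau Positive integer lag (default 1).
#' @param method `"pairwise"` or `"stationary"`.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
#' @examples
#' acf_lag(1:100)            # linear ramp: exactly 1
#' acf_lag(rep(c(1, -1), 50)) # alternating: exactly -1
acf_lag <- function(s, tau = 1L, method = c("pairwise", "stationary")) {
  method <- match.arg(method)
  n <- length(s); tau <- as.integer(tau)
  if (n - tau < 2L)
    sq_stop(sprintf("series of length %d too short for lag %d", n, tau),
            "skelquant_series_too_short_error")
  x1 <- s[seq_len(n - tau)]
  x2 <- s[seq.int(tau + 1L, n)]
  if (method == "pairwise") {
    if (stats::sd(x1) == 0 || stats::sd(x2) == 0)
      sq_stop("zero variance in an overlapping sub-series: autocorrelation undefined",
              "skelquant_undefined_acf_error")
    r <- stats::cor(x1, x2)
  } else {
    m <- mean(s)
    denom <- sum((s - m)^2)
    if (denom == 0)
      sq_stop("constant series: autocorrelation undefined",
              "skelquant_undefined_acf_error")
    r <- sum((x1 - m) * (x2 - m)) / denom
  }
  min(1, max(-1, r))
}

#' First autocorrelation coefficient of the original series
#'
#' `acf_lag(s, 1)`. Near +1 for slowly varying, persistent series.
#'
#' @inheritParams acf_lag
#' @return Coefficient in `[-1, 1]`.
#' @export
first_acf_original <- function(s, method = c("pairwise", "stationary")) {
  acf_lag(s, 1L, method = match.arg(method))
}

#' First autocorrelation coefficient of the differenced series
#'
#' `acf_lag(difference(s), 1)`. For an AR(1) parameter series with
#' coefficient `phi` this converges to `-(1 - phi) / 2`: jittery,
#' low-persistence motion drives it toward -0.5, smooth motion toward 0.
#'
#' @inheritParams acf_lag
#' @return Coefficient in `[-1, 1]`.
#' @export
first_acf_differenced <- function(s, method = c("pairwise", "stationary")) {
  if (length(s) < 4L)
    sq_stop("differenced-series autocorrelation needs length >= 4",
            "skelquant_series_too_short_error")
  acf_lag(difference(s), 1L, method = match.arg(method))
}

#' Averaged variance over non-overlapping windows
#'
#' The series is cut into `I = floor(T / W)` consecutive non-overlapping
#' windows of `W` frames; trailing remainder frames are discarded. The
#' population variance (denominator `W`) is computed per window and the `I`
#' variances are averaged. A movement-amplitude measure that, unlike the
#' whole-series variance, discounts slow drifts longer than the window.
#'
#' @param s Numeric vector, `length(s) >= W`.
#' @param W Window size in frames, >= 2.
#' @return Non-negative scalar.
#' @export
#' @examples
#' averaged_variance(c(0, 2, 0, 2), W = 2)  # each window variance 1 -> 1
averaged_variance <- function(s, W) {
  W <- as.integer(W)
  if (is.na(W) || W < 2L)
    sq_stop("W must be an integer >= 2", "skelquant_input_error")
  T_ <- length(s)
  if (T_ < W)
    sq_stop(sprintf("series of length %d shorter than window %d", T_, W),
            "skelquant_series_too_short_error")
  I <- T_ %/% W
  m <- matrix(s[seq_len(I * W)], nrow = W)
  mu <- colMeans(m)
  mean(colMeans(m * m) - mu * mu)
}

#' Canonical names of the 33 per-recording features
#'
#' `acf_orig_<param>`, `acf_diff_<param>`, `avgvar_<param>` for each of the
#' 11 canonical parameters, grouped by family.
#'
#' @return Character vector of length 33.
#' @export
feature_names <- function() {
  c(paste0("acf_orig_", parameter_names()),
    paste0("acf_diff_", parameter_names()),
    paste0("avgvar_", parameter_names()))
}

#' Extract the 33-feature vector of a recording
#'
#' For each of the 11 parameter series: lag-1 autocorrelation of the
#' original series, lag-1 autocorrelation of the differenced series, and
#' the averaged variance. An undefined autocorrelation (constant series,
#' e.g. a perfectly frozen parameter) is surfaced as `NA` with a warning
#' rather than an error, so one frozen parameter does not abort a cohort
#' run.
#'
#' @param params A `parameter_series_set` from [compute_parameter_series()],
#'   or a `T x 11` numeric matrix with [parameter_names()] columns.
#' @param config An [analysis_config()].
#' @return Named numeric vector of length 33 (class `feature_vector`) with
#'   attributes `subject_id`, `session`, `window_size` and `lag`.
#' @export
extract_features <- function(params, config = analysis_config()) {
  if (inherits(params, "parameter_series_set")) {
    vals <- params$values
    subject_id <- params$subject_id; session <- params$session
  } else {
    vals <- as.matrix(params)
    subject_id <- attr(params, "subject_id") %||% "subject"
    session <- attr(params, "session") %||% "before"
  }
  if (ncol(vals) != 11L)
    sq_stop(sprintf("expected 11 parameter series, got %d", ncol(vals)),
            "skelquant_input_error")
  if (is.null(colnames(vals))) colnames(vals) <- parameter_names()
  if (!setequal(colnames(vals), parameter_names()))
    sq_stop("parameter series columns do not match the canonical names",
            "skelquant_input_error")
  vals <- vals[, parameter_names(), drop = FALSE]

  acf_or_na <- function(s, fn, what) {
    tryCatch(fn(s, method = config$acf_method),
             skelquant_undefined_acf_error = function(e) {
               warning(sprintf("%s undefined (constant series); recorded as NA",
                               what), call. = FALSE)
               NA_real_
             })
  }
  acf_o <- vapply(parameter_names(), function(p)
    acf_or_na(vals[, p], first_acf_original, paste0("acf_orig_", p)),
    numeric(1))
  acf_d <- vapply(parameter_names(), function(p)
    acf_or_na(vals[, p], first_acf_differenced, paste0("acf_diff_", p)),
    numeric(1))
  avv <- vapply(parameter_names(), function(p)
    averaged_variance(vals[, p], config$window_size), numeric(1))

  out <- stats::setNames(c(acf_o, acf_d, avv), feature_names())
  structure(out, subject_id = subject_id, session = session,
            window_size = config$window_size, lag = config$lag,
            class = c("feature_vector", "numeric"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assemble feature vectors into a per-recording feature table
#'
#' @param feature_list List of `feature_vector` objects.
#' @return Data frame with columns `subject_id`, `session` and the 33
#'   canonical feature names, one row per recording.
#' @export
feature_table <- function(feature_list) {
  rows <- lapply(feature_list, function(fv) {
    data.frame(subject_id = attr(fv, "subject_id"),
               session = attr(fv, "session"),
               as.list(stats::setNames(as.numeric(fv), names(fv))),
               check.names = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the cleaning, geometry and feature stages for one recording
#'
#' Convenience wrapper: [clean_sequence()] then
#' [compute_parameter_series()] then [extract_features()].
#'
#' @param seq A `skeleton_sequence`.
#' @param config An [analysis_config()].
#' @param required_joints Passed to [clean_sequence()].
#' @return A `feature_vector` of length 33.
#' @export
quantify_recording <- function(seq, config = analysis_config(),
                               required_joints = default_required_joints()) {
  cleaned <- clean_sequence(seq, required_joints = required_joints)
  extract_features(compute_parameter_series(cleaned), config = config)
}
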