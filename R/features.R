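#' Feature-extraction configuration
#'
#' Operational definitions the feature catalog needs but the field leaves to
#' the implementer; every choice is exposed here and locked by oracle tests.
#'
#' @param cv_percent multiply the coefficient of variation (SD / |mean|) by
#'   100 (default TRUE).
#' @param activation_threshold threshold (g) on the rectified, lowpass-filtered
#'   signal for the activation features (default 0.01).
#' @param band dominant-frequency search band in Hz, endpoints inclusive
#'   (default c(0.25, 5)).
#' @param log_eps epsilon inside the log-energy sum (default 1e-10).
#' @param butter_order,butter_cutoff_hz Butterworth lowpass used (zero-phase)
#'   before activation detection: order 4, cutoff 5 Hz.
#' @return list of feature parameters.
#' @export
feature_config <- function(cv_percent = TRUE, activation_threshold = 0.01,
                           band = c(0.25, 5), log_eps = 1e-10,
                           butter_order = 4, butter_cutoff_hz = 5) {
  list(cv_percent = cv_percent, activation_threshold = activation_threshold,
       band = band, log_eps = log_eps, butter_order = butter_order,
       butter_cutoff_hz = butter_cutoff_hz)
}

#' Per-sample vector magnitude
#'
#' Element-wise Euclidean norm of the three acceleration axes.
#'
#' @param x,y,z equal-length numeric vectors (g).
#' @return numeric vector of the same length.
#' @export
vector_magnitude <- function(x, y, z) {
  if (length(x) != length(y) || length(y) != length(z))
    stop("axes must have equal length")
  sqrt(x^2 + y^2 + z^2)
}

#' Segment a recording into complete non-overlapping windows
#'
#' Consecutive windows of `window_s` seconds; a trailing partial window is
#' discarded, so the window count is `floor(n_samples / (fs * window_s))`.
#'
#' @param recording data.frame with columns `time_s`, `x`, `y`, `z` sampled at
#'   `fs` Hz.
#' @param fs sampling rate, Hz.
#' @param window_s window length, seconds (default 10).
#' @return list of windows; each is a list with `start_s` and the sample
#'   matrix `xyz` (n x 3).
#' @export
segment_windows <- function(recording, fs = 100, window_s = 10) {
  if (is.null(recording) || nrow(recording) == 0L) stop("empty recording")
  if (fs <= 0) stop("sampling rate must be positive")
  wlen <- as.integer(round(fs * window_s))
  nwin <- floor(nrow(recording) / wlen)
  if (nwin == 0L) return(list())
  lapply(seq_len(nwin), function(i) {
    rows <- ((i - 1L) * wlen + 1L):(i * wlen)
    list(start_s = recording$time_s[rows[1L]],
         xyz = cbind(x = recording$x[rows], y = recording$y[rows],
                     z = recording$z[rows]))
  })
}

#' Names of the full per-window feature catalog
#'
#' 28 statistics per axis (x, y, z) and VM, plus 3 cross-axis correlations and
#' 3 orientation angles: 118 features. The order here is the catalog order
#' used for deterministic tie-breaking in feature selection.
#'
#' @return character vector of feature names.
#' @export
feature_catalog <- function() {
  per_axis <- c("mean", "sd", "cv", "p10", "p25", "p50", "p75", "p90",
                "skew", "kurt", "max", "min", "p2p", "mcross", "zcross",
                "sum", "mad", "power", "acf1", "logenergy", "iqr", "var",
                "active", "n_act", "act_mean", "act_sd", "domfreq", "dommag")
  c(as.vector(t(outer(c("x", "y", "z", "vm"), per_axis, paste, sep = "_"))),
    "corr_xy", "corr_xz", "corr_yz", "tilt", "roll", "pitch")
}

# count sign changes of a centred signal; zeros carry the previous sign
count_crossings <- function(s) {
  sg <- sign(s)
  nz <- sg != 0
  if (!any(nz)) return(0L)
  # carry previous non-zero sign into zeros (leading zeros take first sign)
  idx <- cumsum(nz)
  first <- sg[nz][1L]
  carried <- c(first, sg[nz])[idx + 1L]
  sum(carried[-1L] != carried[-length(carried)])
}

# supra-threshold run statistics on the rectified, lowpass-filtered signal
activation_stats <- function(s, fs, cfg) {
  r <- abs(s - mean(s))
  wn <- cfg$butter_cutoff_hz / (fs / 2)
  if (wn < 1) {
    bf <- signal::butter(cfg$butter_order, wn, type = "low")
    r <- signal::filtfilt(bf, r)
  }
  above <- r > cfg$activation_threshold
  runs <- rle(above)
  act_len <- runs$lengths[runs$values]
  n_act <- length(act_len)
  c(active = sum(above),
    n_act = n_act,
    act_mean = if (n_act > 0) mean(act_len) / fs else 0,
    act_sd = if (n_act > 1) stats::sd(act_len / fs) else 0)
}

# dominant frequency/magnitude of the mean-removed signal in [band] Hz;
# rectangular taper; ties and argmax resolve toward the lower frequency
dominant_spectrum <- function(s, fs, band) {
  n <- length(s)
  s0 <- s - mean(s)
  if (all(s0 == 0)) return(c(domfreq = 0, dommag = 0))
  mag <- Mod(stats::fft(s0))
  k <- seq_len(floor(n / 2)) # positive frequencies, k/n*fs
  freq <- k * fs / n
  inband <- freq >= band[1] & freq <= band[2]
  if (!any(inband)) return(c(domfreq = 0, dommag = 0))
  fi <- freq[inband]
  mi <- mag[k + 1L][inband]
  j <- which.max(mi)
  c(domfreq = fi[j], dommag = mi[j])
}

# Pearson correlation with a 0 sentinel for zero-variance inputs
safe_cor <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
  stats::cor(a, b)
}

# the 28 per-axis statistics for one signal
axis_features <- function(s, fs, cfg) {
  n <- length(s)
  m <- mean(s)
  sdev <- stats::sd(s)
  q <- stats::quantile(s, c(0.10, 0.25, 0.50, 0.75, 0.90), names = FALSE,
                       type = 7)
  cen <- s - m
  m2 <- sum(cen^2) / n
  skew <- if (m2 > 0) (sum(cen^3) / n) / m2^1.5 else 0
  kurt <- if (m2 > 0) (sum(cen^4) / n) / m2^2 else 0
  acf1 <- safe_cor(s[-n], s[-1L])
  act <- activation_stats(s, fs, cfg)
  spec <- dominant_spectrum(s, fs, cfg$band)
  c(mean = m, sd = sdev,
    cv = if (m != 0) (sdev / abs(m)) * (if (cfg$cv_percent) 100 else 1) else 0,
    p10 = q[1], p25 = q[2], p50 = q[3], p75 = q[4], p90 = q[5],
    skew = skew, kurt = kurt, max = max(s), min = min(s),
    p2p = max(s) - min(s),
    mcross = count_crossings(s - stats::median(s)),
    zcross = count_crossings(cen),
    sum = sum(s), mad = mean(abs(cen)), power = mean(s^2), acf1 = acf1,
    logenergy = sum(log(s^2 + cfg$log_eps)), iqr = q[4] - q[2],
    var = sdev^2, act, spec)
}

#' Extract the full feature vector for one window
#'
#' Computes the 118-feature catalog ([feature_catalog()]) from a window's
#' tri-axial samples: 28 time/frequency statistics per axis and for the vector
#' magnitude, the three cross-axis Pearson correlations (0 sentinel when an
#' axis is constant), and mean orientation angles. Definitions: CV = SD/|mean|
#' (x100 by default); percentiles by linear interpolation; skewness/kurtosis
#' as standardized third/fourth central moments (kurtosis not excess-
#' corrected); median/zero crossings count sign changes of the median-/mean-
#' centred signal with zeros carrying the previous sign; MAD = mean absolute
#' deviation about the mean; power = mean squared sample; log energy =
#' sum(log(s^2 + 1e-10)); lag-1 autocorrelation = Pearson r of the signal
#' against its one-sample shift; activation features per
#' `activation_threshold` on the rectified, zero-phase Butterworth-filtered
#' signal; dominant frequency/magnitude of the mean-removed spectrum in the
#' 0.25-5 Hz band, ties toward the lower frequency.
#'
#' @param window one element of [segment_windows()] output, or an n x 3
#'   matrix.
#' @param fs sampling rate, Hz.
#' @param config [feature_config()] list.
#' @return named numeric vector over [feature_catalog()].
#' @export
extract_features <- function(window, fs = 100, config = feature_config()) {
  xyz <- if (is.list(window) && !is.data.frame(window)) window$xyz else
    as.matrix(window)
  stopifnot(ncol(xyz) == 3L, nrow(xyz) >= 2L)
  x <- xyz[, 1L]; y <- xyz[, 2L]; z <- xyz[, 3L]
  vm <- vector_magnitude(x, y, z)
  out <- c(x = axis_features(x, fs, config),
           y = axis_features(y, fs, config),
           z = axis_features(z, fs, config),
           vm = axis_features(vm, fs, config),
           corr_xy = safe_cor(x, y), corr_xz = safe_cor(x, z),
           corr_yz = safe_cor(y, z),
           orientation_angles(colMeans(xyz)))
  names(out) <- feature_catalog()
  out
}

#' Mean orientation angles of a window
#'
#' From the per-axis mean vector (mx, my, mz): tilt = acos(mz / ||m||),
#' roll = atan2(my, mz), pitch = atan2(-mx, sqrt(my^2 + mz^2)), in degrees.
#' A zero-norm mean vector returns the 0 sentinel for all three.
#'
#' @param m length-3 mean acceleration vector, or an n x 3 window matrix
#'   whose column means are used.
#' @return named vector `tilt`, `roll`, `pitch` in degrees.
#' @export
orientation_angles <- function(m) {
  if (is.matrix(m)) m <- colMeans(m)
  nrm <- sqrt(sum(m^2))
  if (nrm == 0) return(c(tilt = 0, roll = 0, pitch = 0))
  r2d <- 180 / pi
  c(tilt = acos(min(1, max(-1, m[[3]] / nrm))) * r2d,
    roll = atan2(m[[2]], m[[3]]) * r2d,
    pitch = atan2(-m[[1]], sqrt(m[[2]]^2 + m[[3]]^2)) * r2d)
}

#' Feature table for one recording
#'
#' Segments the recording into 10 s windows and extracts the full catalog for
#' each; one row per window.
#'
#' @inheritParams segment_windows
#' @param config [feature_config()].
#' @return data.frame with `window_start` plus one column per catalog feature.
#' @export
extract_feature_table <- function(recording, fs = 100, window_s = 10,
                                  config = feature_config()) {
  wins <- segment_windows(recording, fs = fs, window_s = window_s)
  if (length(wins) == 0L)
    stop("recording shorter than one window")
  feats <- t(vapply(wins, extract_features, numeric(length(feature_catalog())),
                    fs = fs, config = config))
  out <- data.frame(window_start = vapply(wins, `[[`, numeric(1), "start_s"))
  cbind(out, as.data.frame(feats))
}

#' Synchronize feature windows with the EE criterion series
#'
#' Matches each feature window to the smoothed-EE bin whose start time agrees
#' with the window start (exact alignment by default; `tolerance_s` allows
#' nearest-neighbour matching for shifted grids). Unmatched windows are
#' dropped; the number dropped is recorded in the `"n_dropped"` attribute.
#'
#' @param features data.frame from [extract_feature_table()] (column
#'   `window_start`).
#' @param ee data.frame with `start_s`, `ee_kcal_min` (and optionally `met`).
#' @param tolerance_s matching tolerance in seconds (default 1e-6: exact grid
#'   alignment).
#' @return the feature table with `ee_kcal_min` (and `met`) appended; windows
#'   without a matching EE bin removed.
#' @export
synchronize <- function(features, ee, tolerance_s = 1e-6) {
  if (nrow(features) == 0L || nrow(ee) == 0L) stop("nothing to synchronize")
  lo <- max(min(features$window_start), min(ee$start_s))
  hi <- min(max(features$window_start), max(ee$start_s))
  if (hi < lo) stop("feature and EE time ranges do not overlap")
  idx <- vapply(features$window_start, function(t) {
    d <- abs(ee$start_s - t)
    j <- which.min(d)
    if (d[j] <= tolerance_s) j else NA_integer_
  }, integer(1))
  keep <- !is.na(idx)
  out <- features[keep, , drop = FALSE]
  out$ee_kcal_min <- ee$ee_kcal_min[idx[keep]]
  if (!is.null(ee$met)) out$met <- ee$met[idx[keep]]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!keep)
  out
}
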