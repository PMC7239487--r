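#' Generator configuration for synthetic free-play sessions
#'
#' All noise levels and physiological constants of the generator in one place.
#'
#' @param sigma_ee lognormal SD of per-slot biological EE variability
#'   (default 0.10).
#' @param sigma_breath lognormal SD of breath-level measurement noise
#'   (default 0.03).
#' @param tau_s time constant (s) of first-order EE on/off kinetics at bout
#'   transitions (default 30).
#' @param rer respiratory exchange ratio used to split EE into VO2/VCO2
#'   (default 0.85).
#' @param fs accelerometer sampling rate, Hz (default 100).
#' @param dynamic_range_g accelerometer clip level, g (default 8).
#' @param accel_noise_g white accelerometer noise SD, g (default 0.02).
#' @param hip_amp,wrist_amp site-specific oscillation amplitude per MET above
#'   rest, g.
#' @param hip_gravity,wrist_gravity unit-norm device orientation of gravity
#'   per site.
#' @return a list of generator parameters.
#' @export
generator_config <- function(sigma_ee = 0.10, sigma_breath = 0.03,
                             tau_s = 30, rer = 0.85, fs = 100,
                             dynamic_range_g = 8, accel_noise_g = 0.02,
                             hip_amp = 0.16, wrist_amp = 0.28,
                             hip_gravity = c(0.08, 0.05, 0.995),
                             wrist_gravity = c(0.45, 0.25, 0.86)) {
  norm <- function(v) v / sqrt(sum(v^2))
  list(sigma_ee = sigma_ee, sigma_breath = sigma_breath, tau_s = tau_s,
       rer = rer, fs = fs, dynamic_range_g = dynamic_range_g,
       accel_noise_g = accel_noise_g, hip_amp = hip_amp,
       wrist_amp = wrist_amp, hip_gravity = norm(hip_gravity),
       wrist_gravity = norm(wrist_gravity))
}

# per-second MET trajectory: activity targets filtered by first-order kinetics
met_trajectory <- function(schedule, session_length, tau_s) {
  tgt <- rep(schedule$target_met, schedule$duration_s)
  stopifnot(length(tgt) == session_length)
  if (tau_s <= 0) return(tgt)
  a <- exp(-1 / tau_s)
  met <- numeric(session_length)
  met[1] <- tgt[1]
  for (t in 2:session_length) met[t] <- a * met[t - 1] + (1 - a) * tgt[t]
  met
}

# Weir inversion at fixed RER: EE = (3.941 + 1.106 * rer) * VO2
vo2_from_ee <- function(ee_kcal_min, rer) ee_kcal_min / (3.941 + 1.106 * rer)

#' Synthesize one free-play session
#'
#' Builds, fully deterministically given `seed`, the three coupled streams the
#' study records for one child:
#'
#' * `truth_ee`: per-10 s energy expenditure (kcal/min). The per-second MET
#'   trajectory follows the schedule's activity targets through first-order
#'   on/off kinetics (time constant `tau_s`); slot EE = Schofield resting EE x
#'   slot-mean MET x a lognormal slot factor (`sigma_ee`) representing
#'   biological variability. This series is exact ground truth: the breath
#'   stream encodes it before measurement noise.
#' * `breaths`: breath-by-breath VO2/VCO2. Breath spacing follows a
#'   MET-dependent respiratory rate; VO2 inverts the Weir equation at fixed
#'   RER from the truth EE interpolated at the breath time, times lognormal
#'   breath noise (`sigma_breath`); VCO2 = RER x VO2.
#' * `hip` / `wrist`: 100 Hz tri-axial acceleration (g) = static gravity in
#'   the site's device orientation + a band-limited oscillation whose
#'   amplitude and dominant frequency both increase with the activity's MET
#'   target + white noise, clipped to the +/- 8 g dynamic range. Movement
#'   tracks the activity target instantly (mechanics lead metabolism).
#'
#' @param participant one-row data.frame (see [make_cohort()]).
#' @param schedule data.frame from [default_schedule()].
#' @param seed integer seed.
#' @param config list from [generator_config()].
#' @return a list of class `"play_session"` with elements `participant`,
#'   `schedule`, `hip`, `wrist`, `breaths`, `truth_ee`, `ree`, `seed`.
#' @export
synthesize_session <- function(participant, schedule, seed = 1L,
                               config = generator_config()) {
  check_participant(participant)
  session_length <- sum(schedule$duration_s)
  stopifnot(session_length %% 10 == 0, all(schedule$duration_s > 0))
  ree <- schofield_ree(participant$sex, participant$height_m,
                       participant$mass_kg)
  with_seed(seed, {
    met_s <- met_trajectory(schedule, session_length, config$tau_s)
    nslot <- session_length / 10
    slot_met <- colMeans(matrix(met_s, nrow = 10))
    slot_noise <- if (config$sigma_ee > 0)
      exp(stats::rnorm(nslot, -config$sigma_ee^2 / 2, config$sigma_ee)) else 1
    truth <- data.frame(start_s = (seq_len(nslot) - 1L) * 10,
                        ee_kcal_min = ree$ree_kcal_min * slot_met * slot_noise)

    # breaths: respiratory rate rises with intensity (~26 at rest for 3-5 y)
    ee_s <- rep(truth$ee_kcal_min, each = 10) # step series breaths encode
    t <- 0
    bt <- numeric(0)
    while (t < session_length) {
      met_now <- met_s[min(session_length, floor(t) + 1L)]
      rr <- 22 + 5.5 * met_now # breaths/min
      gap <- (60 / rr) * exp(stats::rnorm(1, 0, 0.08))
      t <- t + gap
      if (t < session_length) bt <- c(bt, t)
    }
    ee_b <- ee_s[floor(bt) + 1L]
    bnoise <- if (config$sigma_breath > 0)
      exp(stats::rnorm(length(bt), -config$sigma_breath^2 / 2,
                       config$sigma_breath)) else 1
    vo2 <- vo2_from_ee(ee_b, config$rer) * bnoise
    breaths <- data.frame(time_s = bt, vo2_lpm = vo2,
                          vco2_lpm = config$rer * vo2,
                          rr = 22 + 5.5 * met_s[floor(bt) + 1L])

    hip <- simulate_accel(met_s, "hip", config)
    wrist <- simulate_accel(met_s, "wrist", config)
    structure(list(participant = participant, schedule = schedule,
                   hip = hip, wrist = wrist, breaths = breaths,
                   truth_ee = truth, ree = ree, seed = as.integer(seed)),
              class = "play_session")
  })
}

# band-limited oscillation + gravity + noise for one wear site
simulate_accel <- function(met_s, site = c("hip", "wrist"), config) {
  site <- match.arg(site)
  fs <- config$fs
  n <- length(met_s) * fs
  met <- rep(met_s, each = fs)
  amp0 <- if (site == "hip") config$hip_amp else config$wrist_amp
  amp <- amp0 * pmax(met - 1, 0.05)
  # dominant frequency grows with intensity, stays inside the 0.25-5 Hz band
  f <- 0.6 + 0.33 * met
  phase <- cumsum(2 * pi * f / fs) + stats::runif(1, 0, 2 * pi)
  base <- amp * sin(phase)
  harm <- 0.35 * amp * sin(2 * phase + stats::runif(1, 0, 2 * pi))
  g <- if (site == "hip") config$hip_gravity else config$wrist_gravity
  # axis weights: oscillation mostly along the longitudinal axis, some spill
  wgt <- if (site == "hip") c(0.35, 0.25, 1) else c(1, 0.5, 0.4)
  sig <- matrix(stats::rnorm(3 * n, 0, config$accel_noise_g), ncol = 3)
  for (k in 1:3) {
    jitter <- stats::rnorm(1, 1, 0.05)
    sig[, k] <- sig[, k] + g[k] + wgt[k] * jitter * base +
      (wgt[3 - (k %% 3)] * 0.3) * harm
  }
  dr <- config$dynamic_range_g
  sig[sig > dr] <- dr
  sig[sig < -dr] <- -dr
  data.frame(time_s = (seq_len(n) - 1L) / fs,
             x = sig[, 1], y = sig[, 2], z = sig[, 3])
}

#' Write a synthetic session to disk as the documented CSV dialects
#'
#' Emits one raw-acceleration CSV per wear site (`<id>_hip.csv`,
#' `<id>_wrist.csv`, header `timestamp,x,y,z`, ISO-8601 timestamps, g units),
#' a breath CSV (`<id>_breaths.csv`, header `timestamp,vo2_lpm,vco2_lpm,rr`),
#' a truth-EE CSV and a participant metadata CSV. Numeric columns are written
#' with 15 significant digits so readers round-trip to well under 1e-6 g.
#'
#' @param session a `"play_session"`.
#' @param dir output directory (created if needed).
#' @param start_time session start as POSIXct (default a fixed epoch;
#'   timestamps are start_time + internal seconds).
#' @return invisibly, the named character vector of files written.
#' @export
write_session <- function(session, dir,
                          start_time = as.POSIXct("2019-06-01 09:00:00",
                                                  tz = "UTC")) {
  if (!inherits(session, "play_session")) stop("not a play_session")
  if (nrow(session$hip) == 0L) stop("empty session")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  id <- session$participant$id
  stamp <- function(secs) {
    # millisecond precision with explicit rounding (%OS3 would truncate)
    ms_total <- round(secs * 1000)
    paste0(format(start_time + ms_total %/% 1000, "%Y-%m-%dT%H:%M:%S",
                  tz = "UTC"),
           sprintf(".%03d", ms_total %% 1000))
  }
  files <- c(hip = file.path(dir, paste0(id, "_hip.csv")),
             wrist = file.path(dir, paste0(id, "_wrist.csv")),
             breaths = file.path(dir, paste0(id, "_breaths.csv")),
             truth = file.path(dir, paste0(id, "_truth_ee.csv")),
             meta = file.path(dir, paste0(id, "_participant.csv")))
  for (site in c("hip", "wrist")) {
    d <- session[[site]]
    data.table::fwrite(
      data.frame(timestamp = stamp(d$time_s), x = d$x, y = d$y, z = d$z),
      files[[site]])
  }
  b <- session$breaths
  data.table::fwrite(
    data.frame(timestamp = stamp(b$time_s), vo2_lpm = b$vo2_lpm,
               vco2_lpm = b$vco2_lpm, rr = b$rr), files[["breaths"]])
  data.table::fwrite(
    data.frame(timestamp = stamp(session$truth_ee$start_s),
               ee_kcal_min = session$truth_ee$ee_kcal_min), files[["truth"]])
  data.table::fwrite(session$participant, files[["meta"]])
  invisible(files)
}

#' Synthesize a whole cohort of sessions
#'
#' One session per participant, each with its own schedule and a subject seed
#' derived from `seed` via [derive_seed()].
#'
#' @param cohort data.frame from [make_cohort()].
#' @param seed master integer seed.
#' @param session_length seconds (default 1200).
#' @param config [generator_config()] list.
#' @return named list of `"play_session"` objects, one per participant id.
#' @export
synthesize_cohort <- function(cohort, seed = 1L, session_length = 1200,
                              config = generator_config()) {
  out <- vector("list", nrow(cohort))
  names(out) <- cohort$id
  for (i in seq_len(nrow(cohort))) {
    sch <- default_schedule(derive_seed(seed, 2L * i), session_length)
    out[[i]] <- synthesize_session(cohort[i, , drop = FALSE], sch,
                                   derive_seed(seed, 2L * i + 1L), config)
  }
  out
}
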