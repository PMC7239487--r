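# Independent brute-force oracles and small fixtures shared across tests.
# The oracle code deliberately avoids the package's implementation paths:
# explicit loops, manual interpolation formulas, and a naive DFT.

# ---- feature oracle ---------------------------------------------------

oracle_percentile <- function(s, p) {
  # linear interpolation (type-7) written out by hand
  x <- sort(s)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  if (lo >= n) return(x[n])
  x[lo] + (h - lo) * (x[lo + 1] - x[lo])
}

oracle_crossings <- function(s) {
  sg <- integer(length(s))
  prev <- 0L
  for (i in seq_along(s)) {
    cur <- if (s[i] > 0) 1L else if (s[i] < 0) -1L else prev
    sg[i] <- cur
    if (cur != 0L) prev <- cur
  }
  # leading zeros adopt the first non-zero sign
  firstnz <- which(sg != 0L)
  if (length(firstnz) == 0L) return(0L)
  sg[seq_len(firstnz[1])] <- sg[firstnz[1]]
  n <- 0L
  for (i in 2:length(sg)) if (sg[i] != sg[i - 1]) n <- n + 1L
  n
}

oracle_pearson <- function(a, b) {
  ma <- sum(a) / length(a); mb <- sum(b) / length(b)
  num <- sum((a - ma) * (b - mb))
  den <- sqrt(sum((a - ma)^2)) * sqrt(sum((b - mb)^2))
  if (den == 0) 0 else num / den
}

oracle_dominant <- function(s, fs, band = c(0.25, 5)) {
  n <- length(s)
  s0 <- s - sum(s) / n
  if (all(s0 == 0)) return(c(domfreq = 0, dommag = 0))
  ks <- seq_len(floor(n / 2))
  freqs <- ks * fs / n
  keep <- freqs >= band[1] & freqs <= band[2]
  ks <- ks[keep]; freqs <- freqs[keep]
  if (length(ks) == 0L) return(c(domfreq = 0, dommag = 0))
  t <- seq_len(n) - 1
  mags <- vapply(ks, function(k) {
    re <- sum(s0 * cos(2 * pi * k * t / n))
    im <- -sum(s0 * sin(2 * pi * k * t / n))
    sqrt(re^2 + im^2)
  }, numeric(1))
  best <- which(mags == max(mags))[1] # first max = lower frequency
  c(domfreq = freqs[best], dommag = mags[best])
}

oracle_activation <- function(s, fs, threshold = 0.01, order = 4,
                              cutoff = 5) {
  r <- abs(s - sum(s) / length(s))
  wn <- cutoff / (fs / 2)
  if (wn < 1) r <- signal::filtfilt(signal::butter(order, wn, "low"), r)
  above <- r > threshold
  runs <- numeric(0)
  cur <- 0L
  for (i in seq_along(above)) {
    if (above[i]) cur <- cur + 1L
    else if (cur > 0L) { runs <- c(runs, cur); cur <- 0L }
  }
  if (cur > 0L) runs <- c(runs, cur)
  nr <- length(runs)
  sd_run <- if (nr > 1) {
    m <- sum(runs) / nr
    sqrt(sum((runs / fs - m / fs)^2) / (nr - 1))
  } else 0
  c(active = sum(above), n_act = nr,
    act_mean = if (nr > 0) sum(runs) / nr / fs else 0, act_sd = sd_run)
}

oracle_axis <- function(s, fs, cfg = feature_config()) {
  n <- length(s)
  mu <- sum(s) / n
  sdv <- sqrt(sum((s - mu)^2) / (n - 1))
  m2 <- sum((s - mu)^2) / n
  m3 <- sum((s - mu)^3) / n
  m4 <- sum((s - mu)^4) / n
  c(mean = mu, sd = sdv,
    cv = if (mu != 0) sdv / abs(mu) * (if (cfg$cv_percent) 100 else 1) else 0,
    p10 = oracle_percentile(s, 0.10), p25 = oracle_percentile(s, 0.25),
    p50 = oracle_percentile(s, 0.50), p75 = oracle_percentile(s, 0.75),
    p90 = oracle_percentile(s, 0.90),
    skew = if (m2 > 0) m3 / m2^1.5 else 0,
    kurt = if (m2 > 0) m4 / m2^2 else 0,
    max = max(s), min = min(s), p2p = max(s) - min(s),
    mcross = oracle_crossings(s - oracle_percentile(s, 0.5)),
    zcross = oracle_crossings(s - mu),
    sum = sum(s), mad = sum(abs(s - mu)) / n, power = sum(s^2) / n,
    acf1 = oracle_pearson(s[-n], s[-1]),
    logenergy = sum(log(s^2 + cfg$log_eps)),
    iqr = oracle_percentile(s, 0.75) - oracle_percentile(s, 0.25),
    var = sdv^2,
    oracle_activation(s, fs, cfg$activation_threshold, cfg$butter_order,
                      cfg$butter_cutoff_hz),
    oracle_dominant(s, fs, cfg$band))
}

oracle_features <- function(xyz, fs, cfg = feature_config()) {
  x <- xyz[, 1]; y <- xyz[, 2]; z <- xyz[, 3]
  vm <- sqrt(x^2 + y^2 + z^2)
  m <- c(sum(x), sum(y), sum(z)) / nrow(xyz)
  nrm <- sqrt(sum(m^2))
  ang <- if (nrm == 0) c(0, 0, 0) else c(
    acos(m[3] / nrm) * 180 / pi,
    atan2(m[2], m[3]) * 180 / pi,
    atan2(-m[1], sqrt(m[2]^2 + m[3]^2)) * 180 / pi)
  out <- c(oracle_axis(x, fs, cfg), oracle_axis(y, fs, cfg),
           oracle_axis(z, fs, cfg), oracle_axis(vm, fs, cfg),
           oracle_pearson(x, y), oracle_pearson(x, z), oracle_pearson(y, z),
           ang)
  names(out) <- feature_catalog()
  out
}

# a varied random window: noise + sinusoids + offset, occasionally constant
# or integer-valued to exercise ties and sentinels
random_window <- function(seed, n = 200, fs = 20) {
  set.seed(seed)
  t <- (seq_len(n) - 1) / fs
  kind <- seed %% 5
  base <- switch(as.character(kind),
    "0" = rnorm(n, 0, 0.3),
    "1" = 0.5 * sin(2 * pi * runif(1, 0.5, 4) * t + runif(1, 0, 2 * pi)) +
      rnorm(n, 0, 0.05),
    "2" = cumsum(rnorm(n, 0, 0.05)),
    "3" = round(rnorm(n, 0, 0.5), 1), # ties and exact zeros
    "4" = rnorm(n, 2, 0.02))
  xyz <- cbind(base + rnorm(n, 0, 0.1),
               0.5 * base + rnorm(n, 0.2, 0.1),
               rnorm(n, 1, 0.1))
  colnames(xyz) <- c("x", "y", "z")
  xyz
}

expect_rel_equal <- function(value, oracle, tol = 1e-9, label = NULL) {
  scale <- pmax(abs(oracle), 1)
  expect_true(all(abs(value - oracle) <= tol * scale),
              info = paste("max rel deviation",
                           max(abs(value - oracle) / scale),
                           if (!is.null(label)) label else ""))
}

# ---- small fixtures ---------------------------------------------------

# a compact labeled cohort table, cached per test run
small_cohort_table <- local({
  cache <- new.env()
  function(n = 4, seed = 11, session_length = 300, sites = "hip") {
    key <- paste(n, seed, session_length, paste(sites, collapse = "+"))
    if (!is.null(cache[[key]])) return(cache[[key]])
    co <- make_cohort(n, seed = seed)
    sess <- synthesize_cohort(co, seed = seed + 1,
                              session_length = session_length)
    tab <- cohort_feature_table(sess, sites = sites)
    cache[[key]] <- tab
    tab
  }
})
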