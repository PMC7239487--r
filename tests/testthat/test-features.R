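test_that("vector magnitude is the element-wise Euclidean norm", {
  expect_equal(vector_magnitude(0, 0, 1), 1)
  expect_equal(vector_magnitude(0.3, 0.4, 0), 0.5)
  set.seed(1)
  x <- rnorm(50); y <- rnorm(50); z <- rnorm(50)
  oracle <- vapply(1:50, function(i) sqrt(x[i]^2 + y[i]^2 + z[i]^2),
                   numeric(1))
  expect_equal(vector_magnitude(x, y, z), oracle, tolerance = 1e-12)
  expect_error(vector_magnitude(1:2, 1:3, 1:3), "equal length")
})

test_that("windowing keeps only complete non-overlapping windows", {
  rec <- function(n) data.frame(time_s = (seq_len(n) - 1) / 100,
                                x = numeric(n), y = numeric(n),
                                z = rep(1, n))
  expect_length(segment_windows(rec(999)), 0)
  w <- segment_windows(rec(2500))
  expect_length(w, 2)
  expect_equal(w[[2]]$start_s, 10)
  expect_equal(nrow(w[[1]]$xyz), 1000)
  expect_error(segment_windows(rec(0)), "empty")
})

test_that("a constant window yields the documented sentinels", {
  xyz <- matrix(rep(c(0, 0, 1), each = 100), ncol = 3)
  f <- extract_features(xyz, fs = 10)
  for (ax in c("x", "y", "z")) {
    expect_equal(unname(f[paste0(ax, "_sd")]), 0)
    expect_equal(unname(f[paste0(ax, "_p2p")]), 0)
    expect_equal(unname(f[paste0(ax, "_zcross")]), 0)
  }
  expect_equal(unname(f["corr_xy"]), 0) # zero-variance sentinel
  expect_equal(unname(f["x_acf1"]), 0)
  expect_equal(unname(f["tilt"]), 0)
  expect_equal(unname(f["vm_mean"]), 1)
})

test_that("a 2 Hz sinusoid crosses zero 40 times in 10 s", {
  t <- (0:999) / 100
  # phase chosen so all 40 crossing times fall inside the sampled span
  xyz <- cbind(sin(2 * pi * 2 * t + 0.8), rnorm(1000, 0, 0.01),
               rep(1, 1000))
  f <- extract_features(xyz, fs = 100)
  expect_equal(unname(f["x_zcross"]), 40)
  expect_equal(unname(f["x_domfreq"]), 2.0, tolerance = 1e-9)
})

test_that("dominant frequency honours the 0.25-5 Hz band", {
  t <- (0:999) / 100
  # strong 7 Hz outside the band, weak 1 Hz inside: band wins
  x <- sin(2 * pi * 7 * t) + 0.2 * sin(2 * pi * 1 * t)
  xyz <- cbind(x, x, rep(1, 1000))
  f <- extract_features(xyz, fs = 100)
  expect_equal(unname(f["x_domfreq"]), 1.0, tolerance = 1e-9)
  set.seed(4)
  noisy <- cbind(rnorm(1000), rnorm(1000), rnorm(1000))
  g <- extract_features(noisy, fs = 100)
  expect_gte(unname(g["x_domfreq"]), 0.25)
  expect_lte(unname(g["x_domfreq"]), 5.0)
})

test_that("activation features count supra-threshold runs of the filtered signal", {
  n <- 1000
  t <- (0:999) / 100
  # two identical zero-mean 1 s oscillation bursts, quiet elsewhere; at
  # 20 Hz the rectified burst is a flat envelope after the 5 Hz lowpass
  burst <- sin(2 * pi * 20 * (0:99) / 100 + 0.3) * 0.5
  x <- rep(0, n)
  x[201:300] <- burst
  x[601:700] <- burst
  xyz <- cbind(x, rep(0, n), rep(1, n))
  f <- extract_features(xyz, fs = 100)
  o <- oracle_activation(x, 100)
  expect_equal(unname(f["x_n_act"]), 2)
  expect_equal(unname(f["x_n_act"]), unname(o["n_act"]))
  expect_equal(unname(f["x_act_mean"]), unname(o["act_mean"]),
               tolerance = 1e-9)
  expect_equal(unname(f["x_act_sd"]), unname(o["act_sd"]), tolerance = 1e-9)
  expect_lt(unname(f["x_act_sd"]), 0.05) # near-identical run lengths
  expect_gt(unname(f["x_act_mean"]), 0.8)

  allzero <- cbind(rep(0, n), rep(0, n), rep(0, n))
  g <- extract_features(allzero, fs = 100)
  expect_equal(unname(g[c("x_active", "x_n_act", "x_act_mean", "x_act_sd")]),
               c(0, 0, 0, 0))
  # threshold above the signal maximum: no activations
  cfg <- feature_config(activation_threshold = 10)
  h <- extract_features(xyz, fs = 100, config = cfg)
  expect_equal(unname(h["x_n_act"]), 0)
})

test_that("orientation angles follow the stated conventions", {
  expect_equal(orientation_angles(c(0, 0, 1)),
               c(tilt = 0, roll = 0, pitch = 0))
  a <- orientation_angles(c(0, 1, 0))
  expect_equal(unname(a["tilt"]), 90)
  expect_equal(unname(a["roll"]), 90)
  b <- orientation_angles(c(1, 0, 0))
  expect_equal(unname(b["pitch"]), -90)
  expect_equal(orientation_angles(c(0, 0, 0)),
               c(tilt = 0, roll = 0, pitch = 0))
  # rotating the mean vector about x by 30 degrees moves tilt accordingly
  th <- 30 * pi / 180
  v <- c(0, sin(th), cos(th))
  r <- orientation_angles(v)
  expect_equal(unname(r["tilt"]), 30, tolerance = 1e-9)
  expect_equal(unname(r["roll"]), 30, tolerance = 1e-9)
})

test_that("every catalog feature matches the brute-force oracle", {
  for (seed in 1:40) {
    xyz <- random_window(seed)
    got <- extract_features(xyz, fs = 20)
    want <- oracle_features(xyz, fs = 20)
    expect_rel_equal(got, want, tol = 1e-9, label = paste("seed", seed))
  }
  # and at the deployed sampling rate
  for (seed in 101:105) {
    xyz <- random_window(seed, n = 1000, fs = 100)
    got <- extract_features(xyz, fs = 100)
    want <- oracle_features(xyz, fs = 100)
    expect_rel_equal(got, want, tol = 1e-9, label = paste("seed", seed))
  }
})

test_that("features transform correctly under translation and scaling", {
  xyz <- random_window(12)
  f0 <- extract_features(xyz, fs = 20)
  f_shift <- extract_features(xyz + 0.7, fs = 20)
  for (nm in c("x_mean", "x_p10", "x_p50", "x_max", "x_min"))
    expect_equal(unname(f_shift[nm] - f0[nm]), 0.7, tolerance = 1e-9)
  for (nm in c("x_sd", "x_iqr", "x_p2p", "x_acf1"))
    expect_equal(unname(f_shift[nm]), unname(f0[nm]), tolerance = 1e-9)

  f_scale <- extract_features(xyz * 3, fs = 20)
  for (nm in c("x_sd", "x_mad", "x_p2p"))
    expect_equal(unname(f_scale[nm]), 3 * unname(f0[nm]), tolerance = 1e-9)
  expect_equal(unname(f_scale["x_power"]), 9 * unname(f0["x_power"]),
               tolerance = 1e-9)
  for (nm in c("x_cv", "corr_xy", "x_domfreq"))
    expect_equal(unname(f_scale[nm]), unname(f0[nm]), tolerance = 1e-9)
})

test_that("synchronization matches window starts to EE bins", {
  feats <- data.frame(window_start = seq(0, 110, by = 10),
                      vm_mean = rnorm(12))
  ee <- data.frame(start_s = seq(0, 110, by = 10), ee_kcal_min = 1:12)
  lab <- synchronize(feats, ee)
  expect_equal(nrow(lab), 12)
  expect_equal(lab$ee_kcal_min, 1:12)
  expect_equal(attr(lab, "n_dropped"), 0)

  lab2 <- synchronize(feats, ee[1:9, ])
  expect_equal(nrow(lab2), 9)
  expect_equal(attr(lab2, "n_dropped"), 3)

  ee_shift <- transform(ee, start_s = start_s + 5)
  lab3 <- synchronize(feats, ee_shift)
  expect_equal(nrow(lab3), 0)
  lab4 <- synchronize(feats, ee_shift, tolerance_s = 5)
  expect_equal(nrow(lab4), 12)
  expect_error(synchronize(feats, data.frame(start_s = 500,
                                             ee_kcal_min = 1)),
               "overlap")
})
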