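test_that("cohort generation respects the age mix and is deterministic", {
  co <- make_cohort(25, seed = 1)
  expect_equal(nrow(co), 25)
  expect_true(all(co$age %in% 3:5))
  expect_true(all(co$height_m > 0) && all(co$mass_kg > 0))
  expect_identical(co, make_cohort(25, seed = 1))

  big <- make_cohort(10000, seed = 7, age_mix = c(0.36, 0.28, 0.36))
  props <- as.numeric(table(factor(big$age, levels = 3:5)) / 10000)
  expect_true(all(abs(props - c(0.36, 0.28, 0.36)) <= 0.02))

  expect_error(make_cohort(0), "positive")
  expect_error(make_cohort(5, age_mix = c(0.5, 0.5, 0.5)), "summing to 1")
})

test_that("schedules conserve session length and reproduce bout structure", {
  sch <- default_schedule(3, 1200)
  expect_equal(sum(sch$duration_s), 1200)
  expect_true(all(sch$duration_s > 0))
  expect_identical(sch, default_schedule(3, 1200))
  expect_error(default_schedule(1, 20), "shorter")

  # sampling mean of total seated time across many seeded schedules sits in
  # the band observed for 20-minute free-play sessions
  seated <- vapply(1:1000, function(s) {
    d <- default_schedule(s, 1200)
    sum(d$duration_s[d$activity == "seated"]) / 60
  }, numeric(1))
  expect_true(abs(mean(seated) - 4.3) <= 0.3)
})

test_that("sessions are reproducible and carry activity-dependent dynamics", {
  co <- make_cohort(1, seed = 5)
  sch <- default_schedule(2, 300)
  s1 <- synthesize_session(co[1, ], sch, seed = 9)
  s2 <- synthesize_session(co[1, ], sch, seed = 9)
  expect_identical(s1, s2)
  expect_equal(nrow(s1$hip), 300 * 100)
  expect_true(all(abs(c(s1$hip$x, s1$hip$y, s1$hip$z)) <= 8))

  # windows in running bouts move more than windows in seated bouts
  sch2 <- data.frame(activity = c("seated", "running", "seated"),
                     duration_s = c(60, 60, 60),
                     target_met = c(1.3, 6.0, 1.3),
                     start_s = c(0, 60, 120))
  for (seed in 1:20) {
    s <- synthesize_session(co[1, ], sch2, seed = seed)
    vm <- vector_magnitude(s$hip$x, s$hip$y, s$hip$z)
    w <- matrix(vm, nrow = 1000) # 18 windows of 10 s
    sds <- apply(w, 2, sd)
    expect_gt(mean(sds[7:12]), mean(sds[1:6]))
  }
})

test_that("seated-only zero-noise sessions settle at REE x seated MET", {
  co <- make_cohort(1, seed = 3)
  sch <- data.frame(activity = "seated", duration_s = 300, target_met = 1.3,
                    start_s = 0)
  cfg <- generator_config(sigma_ee = 0, sigma_breath = 0)
  s <- synthesize_session(co[1, ], sch, seed = 1, config = cfg)
  expected <- s$ree$ree_kcal_min * 1.3
  # no transition in a single-bout schedule: constant from the start
  expect_equal(s$truth_ee$ee_kcal_min, rep(expected, 30), tolerance = 1e-12)
})

test_that("window-level movement variance tracks truth EE (planted signal)", {
  co <- make_cohort(9, seed = 21)
  sess <- synthesize_cohort(co, seed = 22, session_length = 600)
  vmvar <- ee <- numeric(0)
  for (s in sess) {
    vm <- vector_magnitude(s$hip$x, s$hip$y, s$hip$z)
    w <- matrix(vm, nrow = 1000)
    vmvar <- c(vmvar, apply(w, 2, var))
    ee <- c(ee, s$truth_ee$ee_kcal_min)
  }
  expect_gte(length(ee), 500)
  expect_gt(cor(vmvar, ee), 0.5)
})

test_that("sessions round-trip through the CSV writers and readers", {
  co <- make_cohort(1, seed = 4)
  sch <- default_schedule(5, 60)
  s <- synthesize_session(co[1, ], sch, seed = 6)
  dir <- tempfile("roundtrip_")
  write_session(s, dir)
  back <- read_session(dir, s$participant$id)
  expect_equal(nrow(back$hip), nrow(s$hip))
  expect_equal(nrow(back$breaths), nrow(s$breaths))
  expect_lt(max(abs(cbind(back$hip$x, back$hip$y, back$hip$z) -
                    cbind(s$hip$x, s$hip$y, s$hip$z))), 1e-6)
  expect_lt(max(abs(back$breaths$vo2_lpm - s$breaths$vo2_lpm)), 1e-6)
  expect_equal(back$truth_ee$ee_kcal_min, s$truth_ee$ee_kcal_min,
               tolerance = 1e-9)

  s$hip <- s$hip[0, ]
  expect_error(write_session(s, dir), "empty")
  unlink(dir, recursive = TRUE)
})
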