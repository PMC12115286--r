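test_that("action scripts validate events", {
  expect_error(action_script(c(1, 1), c("rest", "rest"), 4), "non-overlapping")
  expect_error(action_script(5, "rest", 4), "within")
  expect_error(action_script(0, "jump", 4), "unknown action")
  sc <- action_script(c(0.5, 2), c("wink_left", "blink"), 4)
  expect_equal(nrow(sc$events), 2L)
})

test_that("piezo generator places normalised bursts on the mapped sensors", {
  quiet <- subject_model(piezo_noise_sd = 0)
  z <- generate_piezo(action_script(numeric(0), character(0), 2), quiet)
  expect_equal(z$channels$pz1, rep(0, 2000))

  tr <- generate_piezo(action_script(0.5, "wink_left", 2), quiet)
  expect_equal(max(tr$channels$pz1), quiet$piezo_amp)
  expect_equal(tr$channels$pz2, rep(0, 2000))
  expect_equal(tr$channels$pz3, rep(0, 2000))

  bl <- generate_piezo(action_script(0.5, "blink", 2),
                       subject_model(piezo_noise_sd = 0, blink_amp_factor = 0.8))
  expect_equal(max(bl$channels$pz1), 0.8)
  expect_equal(max(bl$channels$pz2), 0.8)
  expect_equal(bl$channels$pz3, rep(0, 2000))

  expect_error(generate_piezo(action_script(0.5, "tilt_left", 2), quiet),
               "head action")
})

test_that("accel generator produces plateaus of sin(tilt_angle) g", {
  quiet <- subject_model(accel_noise_sd = 0, tilt_angle = 30)
  z <- generate_accel(action_script(numeric(0), character(0), 2), quiet)
  expect_equal(z$channels$ax, rep(0, 400))
  expect_equal(z$channels$az, rep(0, 400))

  tr <- generate_accel(action_script(0.2, "tilt_left", 2), quiet)
  expect_equal(max(tr$channels$ax), 0.5, tolerance = 1e-12)
  expect_equal(tr$channels$az, rep(0, 400))
  # plateau (not just a peak): held at 0.5 for tilt_hold seconds
  plateau <- tr$channels$ax[tr$channels$ax > 0.499]
  expect_gte(length(plateau), round(0.99 * quiet$tilt_hold * 200))

  dn <- generate_accel(action_script(0.2, "tilt_back", 2), quiet)
  expect_equal(min(dn$channels$az), -0.5, tolerance = 1e-12)
  expect_error(generate_accel(action_script(0.2, "blink", 2), quiet),
               "face action")
})

test_that("generation is deterministic under a fixed seed", {
  subj <- subject_model(piezo_noise_sd = 0.1, accel_noise_sd = 0.05, seed = 99L)
  sc <- command_script(evaluation_sequence(), "face")
  expect_identical(generate_piezo(sc, subj)$channels,
                   generate_piezo(sc, subj)$channels)
  sch <- command_script(evaluation_sequence(), "head")
  expect_identical(generate_accel(sch, subj)$channels,
                   generate_accel(sch, subj)$channels)
  subj2 <- subj; subj2$seed <- 100L
  expect_false(identical(generate_piezo(sc, subj)$channels,
                         generate_piezo(sc, subj2)$channels))
  # different seeds keep the same event skeleton (noise-free parts differ only by noise)
  d <- generate_piezo(sc, subj)$channels$pz1 - generate_piezo(sc, subj2)$channels$pz1
  expect_lt(max(abs(d)), 6 * 0.1 * sqrt(2))
})

test_that("sessions carry the prescribed repetition counts and a scripted trace", {
  ses <- make_session("face", noise = 0.01)
  expect_named(ses$calibration, c("pz1", "pz2", "pz3"))
  expect_true(all(vapply(ses$calibration, length, integer(1)) == 5L))
  expect_equal(duration(ses$trace), 24)

  sesh <- make_session("head", noise = 0.01)
  expect_named(sesh$calibration, c("left", "right", "forward", "back"))
  expect_true(all(vapply(sesh$calibration, length, integer(1)) == 3L))
  expect_true(all(vapply(sesh$calibration$left,
                         function(w) n_samples(w) == 200L, logical(1))))
})

test_that("calibration recovers generator amplitudes from raw repetitions", {
  # noise-free: baselines equal the burst amplitude exactly
  ses <- make_session("face", noise = 0)
  fit <- fit_face_hmi(ses$calibration)
  expect_equal(fit$BP, rep(1.0, 3))
  # 1% noise floor: within 5%
  ses1 <- make_session("face", noise = 0.01, seed = 3L)
  fit1 <- fit_face_hmi(ses1$calibration)
  expect_true(all(abs(fit1$BP - 1.0) < 0.05))
})

test_that("end-to-end accuracy does not increase with the piezo noise floor", {
  long <- rep(evaluation_sequence(), length.out = 200)
  acc <- vapply(c(0.05, 0.3, 0.6), function(ns) {
    ep <- run_session("face", long, noise = ns, seed = 7L)
    mean(ep$command == long)
  }, numeric(1))
  expect_true(all(diff(acc) <= 0))
})

test_that("scripts, subjects and routes round-trip through JSON", {
  sc <- command_script(evaluation_sequence(), "face")
  p <- withr::local_tempfile(fileext = ".json")
  write_script(sc, p)
  back <- read_script(p)
  expect_equal(back$events, sc$events)
  expect_equal(back$duration, sc$duration)

  subj <- subject_model(piezo_amp = 1.5, seed = 12L)
  write_subject(subj, p)
  expect_equal(read_subject(p), subj)

  write_route(route_2(), p)
  r <- read_route(p)
  expect_equal(r$waypoints, route_2()$waypoints)
  expect_equal(r$time_limit, 720)
})

test_that("bundled extdata fixtures load through the same readers", {
  d <- system.file("extdata", package = "hmikit")
  sc <- read_script(file.path(d, "evaluation_script_face.json"))
  expect_equal(nrow(sc$events), 12L)
  expect_equal(sc$duration, 24)
  subj <- read_subject(file.path(d, "default_subject.json"))
  expect_s3_class(subj, "subject_model")
  expect_equal(read_route(file.path(d, "route_1.json"))$time_limit, 360)
})
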