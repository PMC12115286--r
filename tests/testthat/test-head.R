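make_head_reps <- function(xl = 1, xr = -1, zf = 1, zb = -1, n = 200) {
  win <- function(ax, az) accel_trace(rep(ax, n), rep(az, n))
  list(left = lapply(1:3, function(i) win(xl, 0)),
       right = lapply(1:3, function(i) win(xr, 0)),
       forward = lapply(1:3, function(i) win(0, zf)),
       back = lapply(1:3, function(i) win(0, zb)))
}

test_that("tilt thresholds sit 80% of the half-range inward from the extremes", {
  fit <- fit_head_hmi(make_head_reps())
  expect_equal(fit$Xmax, 1); expect_equal(fit$Xmin, -1)
  expect_equal(fit$Tx_minus, -0.2)   # Xmin + 0.8 (Xmax - Xmin) / 2
  expect_equal(fit$Tx_plus, 0.2)     # Xmax - 0.8 (Xmax - Xmin) / 2
  expect_equal(fit$Tz_minus, -0.2)
  expect_equal(fit$Tz_plus, 0.2)
  expect_lt(fit$Tx_minus, fit$Tx_plus)
  expect_lt(fit$Tz_minus, fit$Tz_plus)
})

test_that("degenerate calibration ranges are rejected", {
  expect_error(fit_head_hmi(make_head_reps(zf = 0.5, zb = 0.5)),
               "degenerate z")
  # inverted mounting polarity: the literal printed rule cannot calibrate,
  # the auto label map resolves it by swapping the attribution
  expect_error(fit_head_hmi(make_head_reps(xl = -1, xr = 1), label_map = "printed"),
               "degenerate x")
  flipped <- fit_head_hmi(make_head_reps(xl = -1, xr = 1))
  expect_equal(flipped$label_map[["low_x"]], "TURN_LEFT")
  reps <- make_head_reps()
  reps$left <- reps$left[1:2]
  expect_error(fit_head_hmi(reps), "exactly 3")
})

test_that("calibration extremes equal brute-force global min/max", {
  set.seed(21)
  for (i in 1:20) {
    reps <- list(
      left = lapply(1:3, function(j) accel_trace(rnorm(200, 1), rnorm(200))),
      right = lapply(1:3, function(j) accel_trace(rnorm(200, -1), rnorm(200))),
      forward = lapply(1:3, function(j) accel_trace(rnorm(200), rnorm(200, 1))),
      back = lapply(1:3, function(j) accel_trace(rnorm(200), rnorm(200, -1))))
    fit <- fit_head_hmi(reps)
    bf_max <- -Inf
    for (w in reps$left) for (v in w$channels$ax) if (v > bf_max) bf_max <- v
    bf_min <- Inf
    for (w in reps$right) for (v in w$channels$ax) if (v < bf_min) bf_min <- v
    expect_equal(fit$Xmax, bf_max)
    expect_equal(fit$Xmin, bf_min)
    expect_equal(fit$Zmax, max(sapply(reps$forward, function(w) max(w$channels$az))))
    expect_equal(fit$Zmin, min(sapply(reps$back, function(w) min(w$channels$az))))
  }
})

test_that("decision chain evaluates x rules before z rules", {
  fit <- fit_head_hmi(make_head_reps(), label_map = "printed")
  # printed rule: Ax < Tx- is TURN_LEFT
  expect_equal(classify_head(-0.5, 0, fit), "TURN_LEFT")
  expect_equal(classify_head(0.5, 0, fit), "TURN_RIGHT")
  expect_equal(classify_head(0, -0.5, fit), "FORWARD")
  expect_equal(classify_head(0, 0.5, fit), "BACKWARD")
  expect_equal(classify_head(0, 0, fit), "IDLE")
  # simultaneous excursions resolve to the x command
  expect_equal(classify_head(-0.5, -0.5, fit), "TURN_LEFT")
  expect_equal(classify_head(0.5, 0.5, fit), "TURN_RIGHT")
})

test_that("decision regions partition the (Ax, Az) plane", {
  fit <- fit_head_hmi(make_head_reps())
  set.seed(31)
  for (i in 1:200) {
    cmd <- classify_head(runif(1, -2, 2), runif(1, -2, 2), fit)
    expect_length(cmd, 1L)
    expect_true(cmd %in% command_levels())
  }
})

test_that("self-consistency: a calibration action's own window yields its command", {
  reps <- make_head_reps(xl = 0.9, xr = -0.7, zf = 0.8, zb = -0.6)
  fit <- fit_head_hmi(reps)  # label_map = "auto"
  expect_equal(predict(fit, reps$left[[1]]), "TURN_LEFT")
  expect_equal(predict(fit, reps$right[[1]]), "TURN_RIGHT")
  expect_equal(predict(fit, reps$forward[[1]]), "FORWARD")
  expect_equal(predict(fit, reps$back[[1]]), "BACKWARD")
  # with inverted mounting polarity the auto map still self-recovers
  flip <- list(left = reps$right, right = reps$left,
               forward = reps$back, back = reps$forward)
  # (tilting left now drives the x-axis negative)
  fit2 <- fit_head_hmi(list(left = lapply(flip$left, identity),
                            right = flip$right, forward = flip$forward,
                            back = flip$back))
  expect_equal(predict(fit2, flip$left[[1]]), "TURN_LEFT")
  expect_equal(predict(fit2, flip$forward[[1]]), "FORWARD")
})

test_that("adding a constant x offset to calibration and live data changes nothing", {
  set.seed(41)
  reps <- make_head_reps(xl = 0.9, xr = -0.7, zf = 0.8, zb = -0.6)
  probes <- lapply(1:20, function(i) c(runif(1, -1.5, 1.5), runif(1, -1.5, 1.5)))
  base <- vapply(probes, function(p) classify_head(p[1], p[2], fit_head_hmi(reps)),
                 character(1))
  for (off in c(-0.37, 2.1)) {
    reps_o <- reps
    for (a in c("left", "right", "forward", "back"))
      reps_o[[a]] <- lapply(reps[[a]], function(w)
        accel_trace(w$channels$ax + off, w$channels$az))
    fit_o <- fit_head_hmi(reps_o)
    got <- vapply(probes, function(p) classify_head(p[1] + off, p[2], fit_o),
                  character(1))
    expect_equal(got, base)
  }
})

test_that("head calibration profiles round-trip through JSON", {
  fit <- fit_head_hmi(make_head_reps(xl = 0.93, xr = -0.71, zf = 0.82, zb = -0.64))
  p <- withr::local_tempfile(fileext = ".json")
  write_calibration(fit, p)
  back <- read_calibration(p)
  expect_s3_class(back, "head_hmi")
  expect_equal(coef(back), coef(fit))
  expect_equal(back$label_map, fit$label_map)
})
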