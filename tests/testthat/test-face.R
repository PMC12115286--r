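test_that("window_max matches a brute-force scan", {
  expect_equal(window_max(c(0.1, 0.9, 0.4)), 0.9)
  expect_equal(window_max(rep(2.5, 10)), 2.5)
  expect_error(window_max(numeric(0)), "non-empty")
  set.seed(123)
  x <- rnorm(1000)
  bf <- x[1]
  for (v in x) if (v > bf) bf <- v
  expect_equal(window_max(x), bf)
})

test_that("face calibration arithmetic places thresholds 25% below baselines", {
  reps <- list(
    pz1 = lapply(1:5, function(i) c(0, 2.0, 0.5)),
    pz2 = lapply(1:5, function(i) c(0, 4.0, 1)),
    pz3 = lapply(1:5, function(i) c(0.3, 1.0))
  )
  fit <- fit_face_hmi(reps)
  expect_equal(fit$BP, c(2.0, 4.0, 1.0))
  expect_equal(fit$TP[1], 1.5)           # TP = BP - 0.25 BP
  expect_equal(fit$TP12, 4.5)            # (2 + 4) - 0.25 (2 + 4)
  # mean of distinct per-repetition maxima
  reps$pz1 <- lapply(1:5, function(i) c(0, i))
  expect_equal(fit_face_hmi(reps)$BP[1], 3.0)
})

test_that("face calibration rejects bad repetition sets", {
  ok <- lapply(1:5, function(i) c(0, 1))
  expect_error(fit_face_hmi(list(pz1 = ok[1:4], pz2 = ok, pz3 = ok)),
               "exactly 5")
  expect_error(fit_face_hmi(list(pz1 = c(ok, ok[1]), pz2 = ok, pz3 = ok)),
               "exactly 5")
  zero <- lapply(1:5, function(i) c(-1, 0))
  expect_error(fit_face_hmi(list(pz1 = zero, pz2 = ok, pz3 = ok)),
               "calibration failure")
})

test_that("features rectify threshold excesses and match brute force", {
  reps <- list(pz1 = lapply(1:5, function(i) 2.0),
               pz2 = lapply(1:5, function(i) 2.0),
               pz3 = lapply(1:5, function(i) 2.0))
  fit <- fit_face_hmi(reps)   # TP = 1.5 each, TP12 = 3.0
  f <- face_features(peak_window(1.2, 0.1, 0.1), fit)
  expect_equal(unname(f$EP["ep1"]), 0)          # below threshold rectifies to 0
  f2 <- face_features(peak_window(2.0, 0, 0), fit)
  expect_equal(unname(f2$EP["ep2"]), 0)
  expect_equal(unname(f2$EP["ep1"]), 0.5)

  set.seed(77)
  for (i in 1:25) {
    w <- piezo_trace(rnorm(1000), rnorm(1000), rnorm(1000))
    got <- face_features(w, fit)
    DP <- c(max(w$channels$pz1), max(w$channels$pz2), max(w$channels$pz3))
    EP <- c(max(DP[1] - fit$TP[1], 0), max(DP[2] - fit$TP[2], 0),
            max(DP[3] - fit$TP[3], 0), max(DP[1] + DP[2] - fit$TP12, 0))
    expect_equal(unname(got$EP), EP)
    expect_true(all(got$EP >= 0))
  }
  expect_error(face_features(piezo_trace(1:500, 1:500, 1:500, 1000), fit),
               "1 s window")
})

test_that("argmax classification maps sensors to commands, idle when silent", {
  expect_equal(classify_face(c(0, 0, 0, 0)), "IDLE")
  expect_equal(classify_face(c(0.5, 0, 0, 0.2)), "TURN_LEFT")
  expect_equal(classify_face(c(0, 0.1, 0, 0)), "TURN_RIGHT")
  expect_equal(classify_face(c(0, 0, 0.4, 0)), "FORWARD")
  expect_equal(classify_face(c(0.3, 0.3, 0, 0.9)), "BACKWARD")
  # ties break towards the lowest index
  expect_equal(classify_face(c(0.3, 0.3, 0.3, 0.3)), "TURN_LEFT")
  expect_equal(classify_face(c(0, 0.2, 0.2, 0.2)), "TURN_RIGHT")
})

test_that("classification is invariant to a common positive rescaling", {
  base <- list(pz1 = lapply(1:5, function(i) c(0, 1.8)),
               pz2 = lapply(1:5, function(i) c(0, 2.2)),
               pz3 = lapply(1:5, function(i) c(0, 1.4)))
  w <- peak_window(2.0, 0.4, 1.2)
  for (c_scale in c(0.01, 1, 250)) {
    scaled <- lapply(base, function(r) lapply(r, function(v) c_scale * v))
    fitc <- fit_face_hmi(scaled)
    wc <- peak_window(2.0 * c_scale, 0.4 * c_scale, 1.2 * c_scale)
    expect_equal(classify_face(face_features(wc, fitc)),
                 classify_face(face_features(w, fit_face_hmi(base))))
  }
})

test_that("replaying a calibration repetition recovers its own command", {
  fit <- fit_face_hmi(list(pz1 = lapply(1:5, function(i) 2.0),
                           pz2 = lapply(1:5, function(i) 3.0),
                           pz3 = lapply(1:5, function(i) 1.0)))
  for (n in 1:3) {
    peaks <- c(0, 0, 0); peaks[n] <- fit$BP[n]
    f <- face_features(peak_window(peaks[1], peaks[2], peaks[3]), fit)
    expect_equal(unname(f$EP[n]), 0.25 * fit$BP[n])
    expect_equal(classify_face(f), command_levels()[n])
  }
})

test_that("windows entirely below threshold always classify idle", {
  fit <- fit_face_hmi(list(pz1 = lapply(1:5, function(i) 2.0),
                           pz2 = lapply(1:5, function(i) 2.0),
                           pz3 = lapply(1:5, function(i) 2.0)))
  set.seed(99)
  for (i in 1:20) {
    peaks <- runif(3, 0, 0.99) * fit$TP
    # also keep the summed channel below the combined threshold
    if (peaks[1] + peaks[2] >= fit$TP12) next
    expect_equal(classify_face(face_features(
      peak_window(peaks[1], peaks[2], peaks[3]), fit)), "IDLE")
  }
})

test_that("face calibration profiles round-trip through JSON", {
  fit <- fit_face_hmi(list(pz1 = lapply(1:5, function(i) c(0, 1.23456789)),
                           pz2 = lapply(1:5, function(i) 2.0),
                           pz3 = lapply(1:5, function(i) 3.0)))
  p <- withr::local_tempfile(fileext = ".json")
  write_calibration(fit, p)
  back <- read_calibration(p)
  expect_s3_class(back, "face_hmi")
  expect_equal(back$BP, fit$BP)
  expect_equal(back$TP12, fit$TP12)
})
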