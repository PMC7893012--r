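make_motion <- function(params, tr = 2) motion_trace(params, tr)

test_that("framewise displacement follows the rotation-arc convention", {
  m <- matrix(0.7, 11, 6)                      # constant offset
  expect_equal(framewise_displacement(make_motion(m))$mean_fd, 0)
  m2 <- matrix(0, 11, 6)
  m2[6:11, 1] <- 0.3                           # one 0.3 mm x-step
  fd <- framewise_displacement(make_motion(m2))
  expect_equal(fd$mean_fd, 0.03)
  expect_equal(sum(fd$fd_series > 0), 1)
  m3 <- matrix(0, 3, 6)
  m3[2:3, 4] <- 0.02                           # one 0.02 rad pitch step
  expect_equal(framewise_displacement(make_motion(m3))$fd_series[1], 1.0)
  # offset invariance
  m4 <- matrix(rnorm(60), 10, 6)
  shifted <- sweep(m4, 2, c(1, -2, 3, 0.1, -0.1, 0.2), "+")
  expect_equal(framewise_displacement(make_motion(m4))$fd_series,
               framewise_displacement(make_motion(shifted))$fd_series)
})

test_that("motion traces with non-finite entries are rejected by frame", {
  m <- matrix(0, 5, 6); m[3, 2] <- NA
  expect_error(motion_trace(m, 2), "frame 3")
})

test_that("inclusion rule excludes any subject at or above threshold", {
  s <- function(fd) structure(list(mean_fd = fd), class = "motion_summary")
  ok <- list(a = list(natural = s(0.1), built = s(0.1)),
             b = list(natural = s(0.1), built = s(0.1)))
  expect_equal(apply_inclusion_rule(ok)$kept, c("a", "b"))
  one_bad <- ok
  one_bad$b$built <- s(0.6)
  expect_equal(apply_inclusion_rule(one_bad)$excluded, "b")
  boundary <- ok
  boundary$a$natural <- s(0.5)
  expect_equal(apply_inclusion_rule(boundary)$excluded, "a")
  missing_cond <- list(a = list(natural = s(0.1)),
                       b = list(natural = s(0.1), built = s(0.1)))
  expect_error(apply_inclusion_rule(missing_cond), "missing condition")
})

test_that("leading-volume discard drops rows and refuses empty output", {
  ts <- roi_timeseries(matrix(rnorm(150 * 3), 150, 3), 2)
  out <- discard_initial_volumes(ts, 10)
  expect_equal(nrow(out$data), 140)
  expect_equal(out$volumes_discarded, 10L)
  expect_identical(discard_initial_volumes(ts, 0), ts)
  short <- roi_timeseries(matrix(rnorm(30), 10, 3), 2)
  expect_error(discard_initial_volumes(short, 10), "cannot discard")
})

test_that("nuisance regression returns OLS residuals orthogonal to design", {
  n <- 60
  ramp <- roi_timeseries(cbind(3 + 0.5 * seq_len(n)), 2)
  out <- regress_nuisance(ramp, detrend = TRUE)
  expect_lt(max(abs(out$data)), 1e-10)
  reg <- cbind(sin(seq_len(n)))
  same <- roi_timeseries(cbind(reg), 2)
  expect_lt(max(abs(regress_nuisance(same, reg)$data)), 1e-10)
  set.seed(5)
  ts <- roi_timeseries(matrix(rnorm(n * 4), n, 4), 2)
  regs <- matrix(rnorm(n * 3), n, 3)
  resid <- regress_nuisance(ts, regs)$data
  expect_lt(max(abs(crossprod(regs, resid))), 1e-8)
  expect_lt(max(abs(colSums(resid))), 1e-8)
  expect_error(regress_nuisance(ts, cbind(regs, regs[, 1])),
               "collinear")
})

test_that("band-pass keeps the passband, kills stopband and DC", {
  tt <- seq(0, by = 2, length.out = 1000)
  in_band <- roi_timeseries(cbind(sin(2 * pi * 0.05 * tt)), 2)
  out <- bandpass(in_band)
  expect_gt(sd(out$data) / sd(in_band$data), 0.95)
  expect_lt(abs(sd(out$data) / sd(in_band$data) - 1), 0.05)
  high <- roi_timeseries(cbind(sin(2 * pi * 0.2 * tt)), 2)
  expect_lt(sd(bandpass(high)$data) / sd(high$data), 0.10)
  flat <- roi_timeseries(cbind(rep(5, 500)), 2)
  expect_lt(max(abs(bandpass(flat)$data)) / 5, 1e-3)
  expect_error(bandpass(in_band, low_hz = 0.01, high_hz = 0.3), "Nyquist")
})

test_that("band-pass is approximately idempotent on its own output", {
  # exact idempotence would need a brick-wall filter; for the Butterworth
  # design repeated application must leave passband content essentially
  # unchanged: a passband tone keeps its amplitude, and refiltered noise
  # stays nearly perfectly correlated with the once-filtered version
  tt <- seq(0, by = 2, length.out = 800)
  tone <- roi_timeseries(cbind(sin(2 * pi * 0.05 * tt)), 2)
  once_t <- bandpass(tone)
  twice_t <- bandpass(once_t)
  expect_lt(abs(sd(twice_t$data) / sd(once_t$data) - 1), 0.05)
  set.seed(8)
  ts <- roi_timeseries(matrix(rnorm(500 * 2), 500, 2), 2)
  once <- bandpass(ts)
  twice <- bandpass(once)
  mid <- 100:400   # away from the padded edges
  expect_gt(cor(as.vector(once$data[mid, ]), as.vector(twice$data[mid, ])),
            0.98)
})

test_that("ROI mean extraction averages voxels per label", {
  v <- matrix(c(1, 2, 3), 1, 3)
  out <- extract_roi_means(v, c("a", "a", "a"))
  expect_equal(unname(out$data[1, 1]), 2)
  set.seed(2)
  vox <- matrix(rnorm(20), 5, 4)
  one_per <- extract_roi_means(vox, c("r1", "r2", "r3", "r4"))
  expect_equal(unname(one_per$data), unname(vox))
  dup <- extract_roi_means(vox[, c(1, 1, 2, 2)], c("a", "a", "b", "b"))
  expect_equal(unname(dup$data), unname(vox[, 1:2]))
})

test_that("GSF is the temporal SD of the global mean signal", {
  flat <- roi_timeseries(matrix(1, 20, 4), 2)
  expect_equal(global_signal_fluctuation(flat), 0)
  s <- sin(seq_len(100))
  all_same <- roi_timeseries(cbind(s, s, s), 2)
  expect_equal(global_signal_fluctuation(all_same), sd(s))
  set.seed(4)
  x <- matrix(rnorm(200), 50, 4)
  expect_equal(global_signal_fluctuation(roi_timeseries(x, 2)),
               sd(rowMeans(x)))
})
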