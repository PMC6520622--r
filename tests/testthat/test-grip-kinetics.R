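make_trace <- function(digit, F, M = NULL, pad = 0, fs = 1000, n_min = 10) {
  F <- as.matrix(F)
  if (nrow(F) < n_min) F <- F[rep(seq_len(nrow(F)), length.out = n_min), ]
  if (is.null(M)) M <- matrix(0, nrow(F), 3)
  M <- as.matrix(M)
  if (nrow(M) < nrow(F)) M <- M[rep(seq_len(nrow(M)), length.out = nrow(F)), ]
  ft_trace(digit, (seq_len(nrow(F)) - 1) / fs, F, M,
           calibration = list(rotation = diag(3), pad_offset_x = pad),
           aligned = TRUE)
}

test_that("grip and load force series follow the opposing-digit convention", {
  n <- 10
  th <- make_trace("thumb", cbind(3, 0, 1.96))
  ix <- make_trace("index", cbind(-3, 0, 1.96))
  ser <- grip_load_series(th, ix)
  expect_equal(ser$gf_thumb, rep(3, n))
  expect_equal(ser$gf_index, rep(3, n))
  expect_equal(ser$gf_mean, rep(3, n))
  expect_equal(ser$lf_total, rep(3.92, n))
  # 3.92 N is below the weight force of the 450-g lifted assembly
  expect_lt(ser$lf_total[1], object_mass(object_spec(0.2, 0.2)) * 9.81)

  z <- make_trace("thumb", cbind(0, 0, 0))
  expect_true(all(grip_load_series(z, make_trace("index", cbind(0, 0, 0)))$lf_total == 0))
  expect_error(grip_load_series(th, make_trace("index", cbind(-3, 0, 0),
                                               n_min = 5)),
               "length")
})

test_that("vertical CoP inverts forward-generated moments exactly", {
  # forward model: M_y = z_c * F_x - d * F_z at pad offset d
  tr <- make_trace("thumb", cbind(4, 0, 0), cbind(0, 0.008, 0), pad = 0)
  expect_equal(vertical_cop(tr), rep(0.002, 10))

  tr2 <- make_trace("thumb", cbind(4, 0, 2), cbind(0, 0, 0), pad = 0.005)
  expect_equal(vertical_cop(tr2), rep(0.0025, 10))

  tr3 <- make_trace("thumb", cbind(4, 0, 0), cbind(0, 0, 0), pad = 0)
  expect_equal(vertical_cop(tr3), rep(0, 10))

  # round-trip recovery on random contact points, < 1e-12 m
  set.seed(5)
  z_true <- runif(200, -0.01, 0.01)
  Fx <- runif(200, 0.5, 8); Fz <- runif(200, -2, 4); d <- -0.007
  My <- z_true * Fx - d * Fz
  tr4 <- make_trace("index", cbind(Fx, 0, Fz), cbind(0, My, 0), pad = d)
  expect_lt(max(abs(vertical_cop(tr4) - z_true)), 1e-12)

  # samples below the force floor are masked; all-below is an error
  trm <- make_trace("thumb", cbind(c(0.05, 4), 0, 0), cbind(0, 0.004, 0))
  expect_true(is.na(vertical_cop(trm)[1]) && !is.na(vertical_cop(trm)[2]))
  trz <- make_trace("thumb", cbind(0.01, 0, 0))
  expect_error(vertical_cop(trz), "force floor")
})

test_that("pipeline torque equals the generator's imposed profile everywhere", {
  cases <- list(
    list(obj = object_spec(0.2, 0.2), p = lift_params(anticipatory_torque = 0.01)),
    list(obj = object_spec(0.150, 0.250), p = lift_params()),
    list(obj = object_spec(0.150, 0.250),
         p = lift_params(correction = "none", cop_height = c(0.002, -0.002))))
  for (cs in cases) {
    s <- simulate_trial(cs$obj, cs$p, seed = 8)
    tau <- net_torque_y(s$thumb, s$index, cs$obj)
    expect_lt(max(abs(as.numeric(tau) - s$torque_profile)), 1e-9)
  }
})

test_that("counterbalanced recordings align to identical torque series", {
  obj <- object_spec(0.2, 0.2, appearance = c("styrofoam", "granite"))
  p <- lift_params(anticipatory_torque = 0.008)
  can <- simulate_trial(obj, p, seed = 6, emit = "canonical")
  fl <- simulate_trial(obj, p, seed = 6, emit = "flipped")
  th <- align_to_common_frame(fl$thumb, flip_x = TRUE)
  ix <- align_to_common_frame(fl$index, flip_x = TRUE)
  tau_can <- net_torque_y(can$thumb, can$index, obj)
  tau_al <- net_torque_y(th, ix, obj)
  expect_equal(as.numeric(tau_al), as.numeric(tau_can), tolerance = 1e-12)
  # without alignment the torque is sign-flipped, magnitudes unchanged
  tau_raw <- net_torque_y(fl$thumb, fl$index, swap_halves(obj))
  expect_equal(as.numeric(tau_raw), -as.numeric(tau_can), tolerance = 1e-12)
})

test_that("loading-phase detection matches ground truth and reports failures", {
  obj <- object_spec(0.2, 0.2)
  p <- lift_params(anticipatory_torque = 0.01)
  s <- simulate_trial(obj, p, seed = 21)
  ser <- grip_load_series(s$thumb, s$index)
  tau <- filter_lowpass_zero_phase(as.numeric(net_torque_y(s$thumb, s$index, obj)), 1000)
  m <- detect_loading_phase(ser$gf_thumb, ser$gf_index, ser$lf_thumb,
                            ser$lf_index, ser$lf_total, tau,
                            object_mass(obj) * 9.81)
  expect_lte(abs(m$onset - s$marks$onset), 2)
  expect_lte(abs(m$loading_end - s$marks$loading_end), 2)
  expect_identical(m$liftoff, s$marks$liftoff)

  z <- rep(0, 1000)
  err <- tryCatch(detect_loading_phase(z, z, z, z, z, z, 4.4),
                  error = function(e) e)
  expect_s3_class(err, "heftr_no_onset")
  expect_match(conditionMessage(err), "criterion never met")
})

test_that("the median-LF fallback defines loading end when liftoff never occurs", {
  # hand-built: rises to a 4.0-N peak (below the 4.4-N weight force, so
  # the object is never lifted), dips to 3.4 N, settles at a 3.7-N plateau
  W <- 4.4
  lf <- c(seq(0, 4.0, length.out = 200), seq(4.0, 3.4, length.out = 100),
          seq(3.4, 3.7, length.out = 50), rep(3.7, 650))
  gf <- rep(2, 1000); tau <- rep(0.01, 1000)
  m <- detect_loading_phase(gf, gf, lf, lf, lf, tau, W)
  med <- median(lf[m$onset:1000])
  expect_equal(med, 3.7)  # analytically known median (plateau value)
  expected_end <- 200L + which(lf[201:1000] < med)[1]
  expect_identical(m$loading_end, expected_end)
  expect_true(is.na(m$liftoff))
})

test_that("zero-phase filter has unit DC gain, no lag, and strong stopband", {
  fs <- 1000
  # constant passes unchanged
  expect_lt(max(abs(filter_lowpass_zero_phase(rep(7, 500), fs) - 7)), 1e-9)
  # 5 Hz passband: amplitude within 1%, peak shift <= 1 sample
  t <- seq(0, 2, by = 1 / fs)
  x5 <- sin(2 * pi * 5 * t)
  y5 <- filter_lowpass_zero_phase(x5, fs)
  mid <- 300:1700
  expect_lt(abs(max(y5[mid]) / max(x5[mid]) - 1), 0.01)
  pk_in <- mid[which.max(x5[mid])]; pk_out <- mid[which.max(y5[mid])]
  expect_lte(abs(pk_in - pk_out), 1)
  # 200 Hz (4x cutoff): squared single-pass Butterworth bound 1/(1+4^8)
  x200 <- sin(2 * pi * 200 * t)
  y200 <- filter_lowpass_zero_phase(x200, fs)
  expect_lt(max(abs(y200[mid])), 1 / (1 + 4^8))
  expect_lt(max(abs(y200[mid])), 0.01)  # > 99% attenuation
  # zero cross-correlation lag on a band-limited signal
  set.seed(3)
  xb <- filter_lowpass_zero_phase(rnorm(2001), fs, cutoff = 30)
  yb <- filter_lowpass_zero_phase(xb, fs)
  cc <- ccf(yb[mid], xb[mid], lag.max = 10, plot = FALSE)
  expect_equal(as.integer(cc$lag[which.max(cc$acf)]), 0L)
  # configuration guard
  expect_error(filter_lowpass_zero_phase(1:10, 100, cutoff = 50), "Nyquist")
})

test_that("first torque extremum is the first, not the largest", {
  fs <- 1000
  t <- seq(0, 0.999, by = 1 / fs)
  marks <- phase_marks(1, 1000, 500, c(900, 1000), 1000)
  # two bumps: -3 N mm then +6 N mm
  tau <- -0.003 * exp(-((t - 0.2) / 0.05)^2) + 0.006 * exp(-((t - 0.6) / 0.05)^2)
  expect_equal(first_local_extremum_torque(tau, marks), -3, tolerance = 1e-3)
  # single negative bump then correction
  tau1 <- -0.004 * exp(-((t - 0.3) / 0.07)^2)
  expect_equal(first_local_extremum_torque(tau1, marks), -4, tolerance = 1e-3)
  # null signal: no extremum, endpoint exposed, never substituted
  err <- tryCatch(first_local_extremum_torque(rep(0, 1000), marks),
                  error = function(e) e)
  expect_s3_class(err, "heftr_no_extremum")
  expect_identical(err$endpoint_value, 0)
  # monotone ramp has no interior extremum either
  err2 <- tryCatch(first_local_extremum_torque(seq(0, 0.01, length.out = 1000),
                                               marks),
                   error = function(e) e)
  expect_s3_class(err2, "heftr_no_extremum")
})

test_that("peak force follows the landmark chain, not the global maximum", {
  fs <- 1000
  t <- seq(0, 1.999, by = 1 / fs)
  # sigmoid onto a flat plateau -> plateau level
  sig <- 7 / (1 + exp(-(t - 0.4) / 0.04))
  expect_equal(peak_force(sig, fs), 7, tolerance = 0.01)
  # overshoot: rise to 9, settle at 7 -> 9 (first peak)
  over <- 7 / (1 + exp(-(t - 0.4) / 0.04)) +
    2 * exp(-((t - 0.55) / 0.06)^2)
  expect_equal(peak_force(over, fs), max(over), tolerance = 0.02)
  expect_equal(peak_force(over, fs), 9, tolerance = 0.15)
  # double peak: first 8, later global 10 -> 8
  dbl <- 8 * exp(-((t - 0.5) / 0.08)^2) + 10 * exp(-((t - 1.4) / 0.08)^2)
  expect_equal(peak_force(dbl, fs), 8, tolerance = 0.02)
  # result always within the range of the original signal
  set.seed(9)
  for (k in 1:20) {
    x <- cumsum(rnorm(600, 0.01)) + 3 * exp(-((seq_len(600) - 300) / 60)^2)
    pk <- tryCatch(peak_force(x, fs), error = function(e) NA)
    if (!is.na(pk)) {
      expect_gte(pk, min(x)); expect_lte(pk, max(x))
    }
  }
  expect_error(peak_force(rep(1, 500), fs), "flat")
})

test_that("peak rate recovers analytic slopes and is linear", {
  fs <- 1000
  ramp <- pmin(seq(0, 2, by = 1 / fs) * 40, 60)
  pr <- peak_rate(ramp, fs)
  expect_equal(pr, 40, tolerance = 0.005 * 40)
  expect_equal(peak_rate(rep(3, 1000), fs), 0, tolerance = 1e-9)
  expect_equal(peak_rate(2 * ramp, fs), 2 * pr, tolerance = 1e-9)
})

test_that("holding-phase torque median is robust", {
  marks <- phase_marks(1, 100, 50, c(101, 1100), 1100)
  tau <- rep(0.005, 1100)
  expect_equal(holding_median_torque(tau, marks), 5)
  # zero-mean noise: median close to zero
  set.seed(13)
  taun <- c(rep(0, 100), rnorm(1000, 0, 0.002))
  expect_lt(abs(holding_median_torque(taun, marks)),
            3 * 2 / sqrt(1000))  # N mm scale
  # a 50-sample spike leaves the median unchanged
  sp <- tau; sp[400:449] <- 0.05
  expect_equal(holding_median_torque(sp, marks), 5)
})

test_that("full trial analysis recovers generator ground truth", {
  obj <- object_spec(0.2, 0.2, appearance = c("styrofoam", "granite"))
  p <- lift_params(anticipatory_torque = -0.004)
  s <- simulate_trial(obj, p, seed = 31)
  res <- analyze_trial(s$thumb, s$index, obj)
  expect_lte(abs(res$marks$onset - s$marks$onset), 2)
  # anticipatory rotation toward the lighter-looking side -> negative peak
  expect_lt(res$peak_torque_y, 0)
  expect_equal(res$peak_torque_y, -4, tolerance = 0.3)
  # grip force plateau: grip_to_load * weight force
  expect_equal(res$peak_gf, 1.7 * 0.45 * 9.81, tolerance = 0.05)
  # balanced hold: median torque ~ 0
  expect_lt(abs(res$holding_median_torque_y), 1e-6)
  # flipped recording gives the same result after internal alignment
  s2 <- simulate_trial(obj, p, seed = 31, emit = "flipped")
  res2 <- analyze_trial(s2$thumb, s2$index, obj, presented_flipped = TRUE)
  expect_equal(res2$peak_torque_y, res$peak_torque_y, tolerance = 1e-9)
})
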