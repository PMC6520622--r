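heftr_error <- function(class, message, ...) {
  stop(structure(class = c(class, "heftr_error", "error", "condition"),
                 list(message = message, call = sys.call(-1), ...)))
}

#' Movement-phase marks of one lift
#'
#' Sample indices (1-based) of the detected movement events: loading onset,
#' end of the loading phase, liftoff (total load force first exceeds the
#' weight force) and the holding window.
#'
#' @param onset,loading_end,liftoff sample indices (may be `NA`).
#' @param hold_window integer(2), first and last sample of the hold.
#' @param n trace length.
#' @return object of class `phase_marks`.
#' @export
phase_marks <- function(onset, loading_end, liftoff, hold_window, n) {
  ok <- function(i) is.na(i) || (i >= 1 && i <= n)
  if (!ok(onset) || !ok(loading_end) || !ok(liftoff)) {
    stop("phase marks must lie within the trace")
  }
  if (!is.na(onset) && !is.na(loading_end) && onset > loading_end) {
    stop("onset must not follow loading_end")
  }
  structure(list(onset = onset, loading_end = loading_end,
                 liftoff = liftoff, hold_window = hold_window, n = n),
            class = "phase_marks")
}

#' @export
print.phase_marks <- function(x, ...) {
  cat(sprintf("<phase_marks> onset %s, loading end %s, liftoff %s, hold [%s, %s] / %d\n",
              x$onset, x$loading_end, x$liftoff,
              x$hold_window[1], x$hold_window[2], x$n))
  invisible(x)
}

# interior local extrema with first-index tie-breaking on plateaus
local_extrema <- function(x) {
  n <- length(x)
  out <- data.frame(index = integer(), type = character(),
                    stringsAsFactors = FALSE)
  if (n < 3) return(out)
  s <- sign(diff(x))
  nz <- which(s != 0)
  if (length(nz) < 2) return(out)
  idx <- integer(); typ <- character()
  prev_sign <- s[nz[1]]; prev_pos <- nz[1]
  for (k in nz[-1]) {
    if (s[k] != prev_sign) {
      idx <- c(idx, prev_pos + 1L)   # first sample of the turning plateau
      typ <- c(typ, if (prev_sign > 0) "max" else "min")
    }
    prev_sign <- s[k]; prev_pos <- k
  }
  data.frame(index = idx, type = typ, stringsAsFactors = FALSE)
}

first_local_max_index <- function(x, from = 1L) {
  ex <- local_extrema(x)
  ex <- ex[ex$type == "max" & ex$index >= from, , drop = FALSE]
  if (nrow(ex)) ex$index[1] else NA_integer_
}

#' Grip- and load-force series of a two-digit lift
#'
#' In the common frame the grip force (GF) of each digit is the force along
#' x, with the index finger's GF multiplied by -1 because the two digits
#' press in opposite directions; the load force (LF) is the force along z.
#'
#' @param thumb,index aligned [ft_trace()]s of equal length.
#' @return `data.frame` with columns `gf_thumb`, `gf_index`, `gf_mean`,
#'   `lf_thumb`, `lf_index`, `lf_total`.
#' @export
grip_load_series <- function(thumb, index) {
  if (length(thumb$t) != length(index$t)) {
    heftr_error("heftr_alignment_error", "digit traces differ in length")
  }
  data.frame(gf_thumb = thumb$F[, "x"],
             gf_index = -index$F[, "x"],
             gf_mean = (thumb$F[, "x"] - index$F[, "x"]) / 2,
             lf_thumb = thumb$F[, "z"],
             lf_index = index$F[, "z"],
             lf_total = thumb$F[, "z"] + index$F[, "z"])
}

#' Vertical center of pressure of one digit
#'
#' Inverts the sensor moment about y into the vertical position of the
#' digit's center of pressure on the grip pad:
#' `z_c = (M_y + d_x * F_z) / F_x`, where `d_x` is the signed x-offset of
#' the pad plane from the sensor origin. Samples whose grip (normal) force
#' magnitude is below `floor` are masked (`NA`) because the division is
#' unstable without firm contact.
#'
#' @param trace an aligned [ft_trace()].
#' @param floor normal-force floor (N).
#' @return numeric vector of CoP heights (m) with `NA` where masked.
#' @export
vertical_cop <- function(trace, floor = 0.1) {
  Fx <- trace$F[, "x"]; Fz <- trace$F[, "z"]; My <- trace$M[, "y"]
  d <- trace$calibration$pad_offset_x
  valid <- abs(Fx) > floor
  if (!any(valid)) {
    heftr_error("heftr_no_contact",
                sprintf("no sample of digit '%s' exceeds the %.2g N force floor",
                        trace$digit, floor))
  }
  z <- rep(NA_real_, length(Fx))
  z[valid] <- (My[valid] + d * Fz[valid]) / Fx[valid]
  z
}

#' Net torque about the object's y-axis
#'
#' The four-term torque sum about the center of mass: for each digit the
#' cross-product of its force with the vector from the CoM to its center of
#' pressure, plus the gravitational torque of each object half (the weight
#' of each half acting at +/- L/4). The handle weight term (centered at
#' x = 0) is included so that the gravitational terms close exactly for
#' shifted-CoM objects; for equal-mass halves every gravitational term is
#' zero and the sum reduces to the two digit terms. Where a digit's grip
#' force is below the CoP floor, the algebraically identical
#' moment-transport form `M_y + x_com * F_z` is used so the torque series
#' is defined at every sample; the attribute `"cop_valid"` records where
#' the CoP inversion itself was usable.
#'
#' @param thumb,index aligned [ft_trace()]s.
#' @param object the [object_spec()] *expressed in the trace frame* (half 2
#'   on the positive-x side).
#' @param floor CoP normal-force floor (N), see [vertical_cop()].
#' @return numeric vector of net tau_y (N m), positive toward half 2.
#' @export
net_torque_y <- function(thumb, index, object, floor = 0.1) {
  n <- length(thumb$t)
  if (n != length(index$t)) {
    heftr_error("heftr_alignment_error", "digit traces differ in length")
  }
  x_c <- object_com(object)
  g <- 9.81
  digit_tau <- function(tr) {
    Fx <- tr$F[, "x"]; Fz <- tr$F[, "z"]; My <- tr$M[, "y"]
    d <- tr$calibration$pad_offset_x
    valid <- abs(Fx) > floor
    tau <- My + x_c * Fz                       # moment transport to the CoM
    if (any(valid)) {                          # documented CoP route
      z_c <- (My[valid] + d * Fz[valid]) / Fx[valid]
      tau[valid] <- z_c * Fx[valid] - (d - x_c) * Fz[valid]
    }
    list(tau = tau, valid = valid)
  }
  th <- digit_tau(thumb); ix <- digit_tau(index)
  L4 <- object$length / 4
  tau_grav <- g * (object$half_mass_1 * (-L4 - x_c) +
                   object$half_mass_2 * (L4 - x_c) +
                   object$handle_mass * (0 - x_c))
  out <- th$tau + ix$tau + tau_grav
  attr(out, "cop_valid") <- cbind(thumb = th$valid, index = ix$valid)
  out
}

#' Zero-phase low-pass Butterworth filter
#'
#' Fourth-order (by default) low-pass Butterworth applied forward and
#' backward so the net phase lag is zero and the DC gain is exactly one.
#' The signal is extended by odd reflection at both ends and each pass is
#' initialized at the steady state of its first value, which suppresses
#' startup transients.
#'
#' @param x numeric signal.
#' @param fs sampling rate (Hz).
#' @param cutoff cutoff frequency (Hz), must be below the Nyquist rate.
#' @param order filter order.
#' @return filtered signal, same length as `x`.
#' @export
filter_lowpass_zero_phase <- function(x, fs, cutoff = 50, order = 4) {
  if (cutoff >= fs / 2) {
    heftr_error("heftr_config_error",
                sprintf("cutoff (%g Hz) must be below the Nyquist rate (%g Hz)",
                        cutoff, fs / 2))
  }
  n <- length(x)
  bf <- signal::butter(order, cutoff / (fs / 2))
  p <- min(3 * (length(bf$a) + 1), n - 1)
  xp <- c(2 * x[1] - x[(p + 1):2], x, 2 * x[n] - x[(n - 1):(n - p)])
  run <- function(z) {
    as.numeric(signal::filter(bf$b, bf$a, z,
                              init.x = rep(z[1], length(bf$b) - 1),
                              init.y = rep(z[1], length(bf$a) - 1)))
  }
  y <- run(xp)
  y <- rev(run(rev(y)))
  y[(p + 1):(p + n)]
}

# central differences at the native sampling rate; one-sided at the ends
central_diff <- function(x, fs) {
  n <- length(x)
  d <- numeric(n)
  if (n >= 3) d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * fs / 2
  d[1] <- (x[2] - x[1]) * fs
  d[n] <- (x[n] - x[n - 1]) * fs
  d
}

gaussian_smooth <- function(x, fs, sd = 0.030) {
  n <- length(x)
  sd_samp <- sd * fs
  half <- max(1L, ceiling(4 * sd_samp))
  k <- stats::dnorm(seq(-half, half), sd = sd_samp)
  k <- k / sum(k)
  p <- min(half, n - 1)
  xp <- c(2 * x[1] - x[(p + 1):2], x, 2 * x[n] - x[(n - 1):(n - p)])
  y <- stats::filter(xp, k, sides = 2)
  as.numeric(y)[(p + 1):(p + n)]
}

#' Detect the loading phase of a lift
#'
#' Loading onset is the first sample at which the grip force of at least
#' one digit and the load force of at least one digit exceed `thr_force`
#' (0.01 N) while the absolute torque about y exceeds `thr_torque`
#' (1.5 N mm). The end of the loading phase is the first sample after the
#' initial peak of the total load force at which the total load force
#' falls below the weight force of the object or, if the weight force was
#' never reached (the object was never lifted), below the median of the
#' total load force (taken from onset onward).
#'
#' @param gf_thumb,gf_index,lf_thumb,lf_index,lf_total,tau_y numeric
#'   series of equal length (forces N, torque N m).
#' @param weight_force weight of the lifted assembly (N).
#' @param thr_force force threshold (N).
#' @param thr_torque torque threshold (N m).
#' @return a [phase_marks()] object.
#' @export
detect_loading_phase <- function(gf_thumb, gf_index, lf_thumb, lf_index,
                                 lf_total, tau_y, weight_force,
                                 thr_force = 0.01, thr_torque = 1.5e-3) {
  n <- length(lf_total)
  stopifnot(length(gf_thumb) == n, length(lf_thumb) == n,
            length(tau_y) == n)
  c_gf <- (gf_thumb > thr_force) | (gf_index > thr_force)
  c_lf <- (lf_thumb > thr_force) | (lf_index > thr_force)
  c_tau <- abs(tau_y) > thr_torque
  onset <- which(c_gf & c_lf & c_tau)[1]
  if (is.na(onset)) {
    failed <- c("grip force", "load force", "torque")[!c(any(c_gf), any(c_lf), any(c_tau))]
    heftr_error("heftr_no_onset",
                if (length(failed)) {
                  paste0("no loading onset: criterion never met for ",
                         paste(failed, collapse = ", "))
                } else {
                  "no loading onset: criteria never met simultaneously"
                })
  }
  pk <- first_local_max_index(lf_total, from = onset)
  if (is.na(pk)) pk <- onset - 1L + which.max(lf_total[onset:n])
  loading_end <- NA_integer_
  if (pk < n) {
    # reference level: the weight force if it was ever reached (the object
    # was lifted), otherwise the median of the total load force
    ref <- if (max(lf_total[onset:n]) > weight_force) weight_force else
      stats::median(lf_total[onset:n])
    below <- which(lf_total[(pk + 1):n] < ref)
    if (length(below)) loading_end <- pk + below[1]
  }
  if (is.na(loading_end)) {
    heftr_error("heftr_no_loading_end",
                "total load force never fell below the weight force or its median")
  }
  liftoff <- onset - 1L + which(lf_total[onset:n] > weight_force)[1]
  if (length(liftoff) == 0 || is.na(liftoff)) liftoff <- NA_integer_
  phase_marks(onset = onset, loading_end = loading_end, liftoff = liftoff,
              hold_window = c(min(loading_end + 1L, n), n), n = n)
}

#' First local torque extremum during the loading phase
#'
#' The signed value (N mm) of the first strict local maximum or minimum of
#' the filtered torque series inside the loading window. The sign follows
#' the frame convention (+ = rotation toward the heavier-looking side once
#' aligned). A monotone window has no interior extremum; this is reported
#' as an error condition (`heftr_no_extremum`) carrying the window
#' endpoint value rather than silently substituting it.
#'
#' @param tau_y filtered torque series (N m).
#' @param marks a [phase_marks()] with a nonempty loading window.
#' @return signed torque (N mm).
#' @export
first_local_extremum_torque <- function(tau_y, marks) {
  if (is.na(marks$onset) || is.na(marks$loading_end)) {
    heftr_error("heftr_no_extremum", "loading window is not defined")
  }
  w <- tau_y[marks$onset:marks$loading_end]
  ex <- local_extrema(w)
  if (!nrow(ex)) {
    heftr_error("heftr_no_extremum",
                "no interior torque extremum in the loading window",
                endpoint_value = 1000 * w[length(w)])
  }
  1000 * w[ex$index[1]]
}

#' First peak of a force signal
#'
#' Implements the landmark chain used for peak grip/load force: smooth the
#' signal with a Gaussian kernel (`smooth_sd`), differentiate, find the
#' first time at which the derivative reaches `frac` of its maximum, then
#' the first subsequent time the derivative becomes negative (or the end
#' of the trial if it never does). Within that window, locate the first
#' local maximum and the first following local minimum of the smoothed
#' signal (falling back to the window end when a landmark is absent, as
#' for a ramp onto a flat plateau), and return the maximum of the
#' *original* signal between those two landmarks.
#'
#' @param x force series (N).
#' @param fs sampling rate (Hz).
#' @param smooth_sd Gaussian smoothing SD (s).
#' @param frac fraction of the maximum derivative defining the window
#'   start.
#' @return first peak force (N); always within `[min(x), max(x)]`.
#' @export
peak_force <- function(x, fs, smooth_sd = 0.030, frac = 0.70) {
  if (length(x) <= ceiling(8 * smooth_sd * fs)) {
    heftr_error("heftr_config_error", "series shorter than the smoothing kernel")
  }
  sm <- gaussian_smooth(x, fs, smooth_sd)
  dsm <- central_diff(sm, fs)
  dmax <- max(dsm)
  if (dmax <= 0) {
    heftr_error("heftr_no_peak", "flat signal: maximum derivative is not positive")
  }
  i70 <- which(dsm >= frac * dmax)[1]
  after <- which(dsm[i70:length(x)] < 0)
  ineg <- if (length(after)) i70 - 1L + after[1] else length(x)
  win <- sm[i70:ineg]
  ex <- local_extrema(win)
  lmax <- ex$index[ex$type == "max"][1]
  if (is.na(lmax) || !length(lmax)) lmax <- length(win)
  lmin <- ex$index[ex$type == "min" & ex$index > lmax][1]
  if (is.na(lmin) || !length(lmin)) lmin <- length(win)
  a <- i70 - 1L + lmax
  b <- i70 - 1L + lmin
  max(x[a:b])
}

#' Peak rate of change of a force signal
#'
#' Maximum of the time derivative of the zero-phase low-pass filtered
#' signal (central differences at the native sampling rate).
#'
#' @inheritParams filter_lowpass_zero_phase
#' @return peak rate (N/s).
#' @export
peak_rate <- function(x, fs, cutoff = 50, order = 4) {
  xf <- filter_lowpass_zero_phase(x, fs, cutoff, order)
  max(central_diff(xf, fs))
}

#' Median torque during the holding phase
#'
#' @param tau_y torque series (N m).
#' @param marks a [phase_marks()] with a nonempty hold window.
#' @return median torque (N mm).
#' @export
holding_median_torque <- function(tau_y, marks) {
  hw <- marks$hold_window
  if (is.na(hw[1]) || is.na(hw[2]) || hw[1] > hw[2]) {
    heftr_error("heftr_empty_window", "hold window is empty")
  }
  1000 * stats::median(tau_y[hw[1]:hw[2]])
}

#' Swap the two halves of an object specification
#'
#' Relabels the object description for a frame in which the halves change
#' sides (used when the orientation relabeling flips the x-axis).
#' @param spec an [object_spec()].
#' @return the swapped `object_spec`.
#' @export
swap_halves <- function(spec) {
  out <- spec
  out$half_mass_1 <- spec$half_mass_2
  out$half_mass_2 <- spec$half_mass_1
  out$appearance <- rev(spec$appearance)
  out$orientation <- 3L - spec$orientation
  out
}

#' Full kinetic analysis of one trial
#'
#' Runs the processing chain on a pair of digit traces: alignment into the
#' common frame (positive torque toward the heavier-looking side), GF/LF
#' extraction, net torque about the CoM, zero-phase filtering, loading
#' phase detection, and the six kinetic dependent variables.
#'
#' @param thumb,index [ft_trace()]s (raw or already in the object frame).
#' @param object the [object_spec()] that was lifted.
#' @param presented_flipped was the object presented rotated by 180
#'   degrees relative to its canonical frame (half 2 toward negative x in
#'   the recording)? Applied only to raw (unaligned) traces.
#' @param catalog material catalog for the heavier-looking-side convention.
#' @param cutoff,order torque/rate filter settings (Hz, -).
#' @param cop_floor CoP normal-force floor (N).
#' @param smooth_sd Gaussian smoothing SD for the peak-force procedure (s).
#' @return object of class `kinetics_result`: list with `peak_torque_y`,
#'   `peak_gf`, `peak_gfr`, `peak_lf`, `peak_lfr`,
#'   `holding_median_torque_y` (N mm, N, N/s; torques signed positive
#'   toward the heavier-looking side), the `marks`, and `no_extremum`
#'   flag with `endpoint_torque` when the loading-window torque was
#'   monotone.
#' @export
analyze_trial <- function(thumb, index, object, presented_flipped = FALSE,
                          catalog = material_catalog(), cutoff = 50,
                          order = 4, cop_floor = 0.1, smooth_sd = 0.030) {
  if (!thumb$aligned || !index$aligned) {
    # restore the object frame (+x toward half 2) from the recording
    thumb <- align_to_common_frame(thumb, flip_x = presented_flipped)
    index <- align_to_common_frame(index, flip_x = presented_flipped)
  }
  fs <- sample_rate(thumb)
  ser <- grip_load_series(thumb, index)
  tau <- net_torque_y(thumb, index, object, floor = cop_floor)
  # sign convention: positive torque = toward the heavier-looking side
  sgn <- if (heavier_looking_side(object$appearance, catalog) == 1L) -1 else 1
  tau <- sgn * as.numeric(tau)
  tau_f <- filter_lowpass_zero_phase(as.numeric(tau), fs, cutoff, order)
  W <- object_mass(object) * 9.81
  marks <- detect_loading_phase(ser$gf_thumb, ser$gf_index, ser$lf_thumb,
                                ser$lf_index, ser$lf_total, tau_f, W)
  peak_tau <- tryCatch(first_local_extremum_torque(tau_f, marks),
                       heftr_no_extremum = function(e) e)
  no_ext <- inherits(peak_tau, "condition")
  structure(list(
    peak_torque_y = if (no_ext) NA_real_ else peak_tau,
    no_extremum = no_ext,
    endpoint_torque = if (no_ext) peak_tau$endpoint_value else NA_real_,
    peak_gf = peak_force(ser$gf_mean, fs, smooth_sd),
    peak_gfr = peak_rate(ser$gf_mean, fs, cutoff, order),
    peak_lf = peak_force(ser$lf_total, fs, smooth_sd),
    peak_lfr = peak_rate(ser$lf_total, fs, cutoff, order),
    holding_median_torque_y = holding_median_torque(tau_f, marks),
    marks = marks), class = "kinetics_result")
}

#' @export
print.kinetics_result <- function(x, ...) {
  cat(sprintf(paste0("<kinetics_result> peak tau_y %.2f N mm, GF %.2f N, ",
                     "GFR %.1f N/s, LF %.2f N, LFR %.1f N/s, hold tau_y %.2f N mm\n"),
              x$peak_torque_y, x$peak_gf, x$peak_gfr, x$peak_lf, x$peak_lfr,
              x$holding_median_torque_y))
  invisible(x)
}
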