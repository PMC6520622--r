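#' Experiment design specification
#'
#' Describes a lifting session: a set of objects, the number of recorded
#' lifts per object, practice trials with a neutral object, and the block
#' constraint used in the original paradigm (every object is lifted once
#' before any is repeated). Object orientation is constant within a
#' participant and counterbalanced across participants.
#'
#' @param objects list of [object_spec()]s.
#' @param lifts_per_object lifts of each object in the main phase.
#' @param practice_trials number of practice lifts (listed separately).
#' @param block_constraint logical; if TRUE each consecutive block of
#'   `length(objects)` trials contains each object exactly once.
#' @param n_participants number of participants.
#' @param seed integer seed; identical seeds give identical designs.
#' @return object of class `design_spec`.
#' @export
design_spec <- function(objects, lifts_per_object = 10, practice_trials = 5,
                        block_constraint = TRUE, n_participants = 1,
                        seed = 1L) {
  stopifnot(is.list(objects), length(objects) >= 1)
  if (lifts_per_object < 1) stop("empty design: lifts_per_object must be >= 1")
  structure(list(objects = objects,
                 lifts_per_object = as.integer(lifts_per_object),
                 practice_trials = as.integer(practice_trials),
                 block_constraint = isTRUE(block_constraint),
                 n_participants = as.integer(n_participants),
                 seed = as.integer(seed)),
            class = "design_spec")
}

# deterministic per-unit seed stream derived from one global seed
derive_seed <- function(seed, ...) {
  ix <- c(...)
  s <- as.double(seed) %% 2147483647
  for (k in ix) s <- (s * 48271 + as.double(k) * 16807 + 11) %% 2147483647
  as.integer(s)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate an ordered trial list
#'
#' Produces the per-participant trial order. With the block constraint each
#' consecutive block of `n_objects` trials is a random permutation of the
#' objects, so every object is lifted once before any is repeated. Object
#' orientation is drawn once per participant x object and counterbalanced
#' across participants.
#'
#' @param spec a [design_spec()].
#' @return `data.frame` with columns `participant`, `trial`, `block`,
#'   `object_id`, `object_index`, `orientation`, plus practice trials
#'   flagged in column `phase` (`"practice"` or `"main"`).
#' @examples
#' d <- make_design(design_spec(list(object_spec(0.2, 0.2)), 1, 0))
#' @export
make_design <- function(spec) {
  stopifnot(inherits(spec, "design_spec"))
  n_obj <- length(spec$objects)
  ids <- vapply(spec$objects, function(o) o$id, "")
  rows <- list()
  for (p in seq_len(spec$n_participants)) {
    ord <- with_seed(derive_seed(spec$seed, p, 1), {
      if (spec$block_constraint) {
        as.vector(vapply(seq_len(spec$lifts_per_object),
                         function(b) sample.int(n_obj), integer(n_obj)))
      } else {
        sample(rep(seq_len(n_obj), spec$lifts_per_object))
      }
    })
    # orientation: constant within participant, counterbalanced across
    orient <- with_seed(derive_seed(spec$seed, p, 2),
                        (seq_len(n_obj) + p) %% 2L + 1L)
    n_main <- n_obj * spec$lifts_per_object
    main <- data.frame(
      participant = p,
      trial = seq_len(n_main),
      block = rep(seq_len(spec$lifts_per_object), each = n_obj),
      object_index = ord,
      object_id = ids[ord],
      orientation = orient[ord],
      phase = "main",
      stringsAsFactors = FALSE)
    if (spec$practice_trials > 0) {
      prac <- data.frame(
        participant = p, trial = seq_len(spec$practice_trials),
        block = NA_integer_, object_index = NA_integer_,
        object_id = "practice", orientation = 1L, phase = "practice",
        stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- prac
    }
    rows[[length(rows) + 1L]] <- main
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Parameters of one synthetic lift
#'
#' The trace model: forces are zero while the hand is at rest, rise along a
#' C2 smoothstep ramp during the loading phase, overshoot the object's
#' weight with a decaying-sinusoid settle at liftoff, and then hold steady
#' (total load force exactly equal to the weight force, net torque exactly
#' zero) for `hold_duration`. Anticipatory torque is injected by asymmetric
#' load-force sharing between the digits (one of the strategies available
#' to a lifter for counteracting an expected tilt).
#'
#' @param sample_rate sampling rate (Hz), >= 200.
#' @param pre_duration quiet baseline before force onset (s).
#' @param loading_duration duration of the loading ramp (s).
#' @param hold_duration stable hold after the settle (s).
#' @param grip_to_load ratio of target grip force to weight force.
#' @param overshoot fractional load-force overshoot at liftoff.
#' @param settle_freq,settle_tau frequency (Hz) and decay constant (s) of
#'   the liftoff settle oscillation.
#' @param expected_mass mass the lifter plans for (kg); `NULL` = actual.
#' @param expectation_scaling 0..1, how strongly planning follows the
#'   expected rather than the actual mass (scales initial force rates).
#' @param anticipatory_torque amplitude (N m) of an anticipatory torque
#'   bump injected during loading; sign: + = toward half 2.
#' @param correction one of `"ramp"` (the gravitational imbalance is
#'   compensated progressively during loading) or `"none"` (digits share
#'   load symmetrically until liftoff, then correct during the settle).
#' @param cop_height length-2 vector, vertical CoP of thumb and index
#'   relative to the object center (m).
#' @param pad_offset x-distance of each grip-pad plane from the object
#'   center (m); thumb at -pad_offset, index at +pad_offset.
#' @param force_noise_sd,moment_noise_sd additive white Gaussian channel
#'   noise SDs (N, N m); 0 = noise-free.
#' @param g gravitational acceleration (m/s^2).
#' @return object of class `lift_params`.
#' @export
lift_params <- function(sample_rate = 1000, pre_duration = 0.3,
                        loading_duration = 0.4, hold_duration = 3,
                        grip_to_load = 1.7, overshoot = 0.08,
                        settle_freq = 6, settle_tau = 0.05,
                        expected_mass = NULL, expectation_scaling = 1,
                        anticipatory_torque = 0,
                        correction = c("ramp", "none"),
                        cop_height = c(0, 0), pad_offset = 0.01,
                        force_noise_sd = 0, moment_noise_sd = 0,
                        g = 9.81) {
  correction <- match.arg(correction)
  if (sample_rate < 200) stop("sample_rate must be >= 200 Hz")
  if (pre_duration < 0 || loading_duration <= 0 || hold_duration <= 0) {
    stop("durations must be > 0")
  }
  if (force_noise_sd < 0 || moment_noise_sd < 0) stop("noise SDs must be >= 0")
  if (grip_to_load <= 0) stop("grip_to_load must be > 0")
  if (expectation_scaling < 0 || expectation_scaling > 1) {
    stop("expectation_scaling must be in [0, 1]")
  }
  structure(as.list(environment()), class = "lift_params")
}

# C2 smoothstep: 0 for u <= 0, 1 for u >= 1
smoothstep <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u * u * u * (u * (u * 6 - 15) + 10)
}

#' Simulate one precision-grip lift
#'
#' Generates thumb and index six-axis traces for a lift of `object`, the
#' ground-truth movement-phase marks, and the imposed net-torque profile
#' (the oracle the analysis pipeline should recover). Noise-free traces
#' satisfy statics exactly during the hold window: the summed load force
#' equals the weight force and the net torque about the CoM is zero.
#'
#' @param object an [object_spec()].
#' @param params a [lift_params()].
#' @param seed integer seed for the channel noise.
#' @param emit one of `"canonical"` (traces in the object frame: positive x
#'   toward half 2) or `"flipped"` (traces as recorded with the object
#'   presented the other way round, to be aligned downstream). With the
#'   default object specs the heavier-looking material is half 2, so
#'   canonical emission already follows the heavier-looking-side-positive
#'   sign convention.
#' @return list with `thumb`, `index` ([ft_trace()]s), `t`, `marks`
#'   (ground-truth [phase_marks()]), `torque_profile` (imposed net tau_y,
#'   N m, positive toward half 2), `lf_total`, `object`, `params`.
#' @export
simulate_trial <- function(object, params = lift_params(), seed = 1L,
                           emit = c("canonical", "flipped")) {
  emit <- match.arg(emit)
  stopifnot(inherits(object, "object_spec"), inherits(params, "lift_params"))
  p <- params
  fs <- p$sample_rate
  g <- p$g
  M_act <- object_mass(object)
  W <- M_act * g
  x_c <- object_com(object)                # CoM offset (+ toward half 2)
  M_exp <- if (is.null(p$expected_mass)) M_act else p$expected_mass
  M_plan <- p$expectation_scaling * M_exp + (1 - p$expectation_scaling) * M_act
  if (M_plan <= 0) stop("infeasible params: planned mass must be > 0")
  # planning a heavier object -> steeper ramp (shorter effective loading)
  load_dur <- p$loading_duration * M_act / M_plan
  t_total <- p$pre_duration + load_dur + p$hold_duration
  n <- floor(t_total * fs) + 1L
  t <- (seq_len(n) - 1L) / fs
  t0 <- p$pre_duration
  t1 <- t0 + load_dur

  s <- smoothstep((t - t0) / load_dur)     # loading ramp, exactly 0/1 outside
  # liftoff settle: starts at 0 (sin), overshoots, decays; envelope truncated
  # to exactly zero once negligible so hold statics close to machine precision
  u <- pmax(t - t1, 0)
  env <- p$overshoot * W * exp(-u / p$settle_tau)
  env[t < t1 | env < 1e-12 * W] <- 0
  settle <- env * sin(2 * pi * p$settle_freq * u)
  lf_tot <- W * s + settle

  gf_target <- p$grip_to_load * M_plan * g
  gf <- gf_target * s

  # anticipatory torque bump during loading (zero at ramp ends)
  tau_ant <- p$anticipatory_torque * sin(pi * pmin(pmax((t - t0) / load_dur, 0), 1))^2
  # correction of the gravitational imbalance x_c * lf_tot
  cc <- switch(p$correction,
               ramp = s,
               none = smoothstep((t - t1) / (3 / p$settle_freq)))
  # digit torque needed so that net tau_y = tau_ant + (1 - cc) * x_c * lf_tot
  dz <- p$cop_height[1] - p$cop_height[2]
  t_req <- tau_ant - cc * x_c * lf_tot
  delta_pair <- (t_req - gf * dz) / p$pad_offset   # LF_thumb - LF_index
  lf_T <- (lf_tot + delta_pair) / 2
  lf_I <- (lf_tot - delta_pair) / 2
  if (min(lf_T, lf_I) < -0.5 * W) {
    stop("infeasible params: required digit load force strongly negative; ",
         "reduce anticipatory_torque or increase pad_offset")
  }
  torque_profile <- tau_ant + (1 - cc) * x_c * lf_tot

  d <- p$pad_offset
  z_T <- p$cop_height[1]; z_I <- p$cop_height[2]
  # sensor moments at the object-center origin, consistent with the CoPs
  mk_FM <- function(Fx, Fz, pad_x, z_cop) {
    My <- z_cop * Fx - pad_x * Fz
    list(F = cbind(x = Fx, y = 0, z = Fz),
         M = cbind(x = 0, y = My, z = 0))
  }
  thumbFM <- mk_FM(gf, lf_T, -d, z_T)
  indexFM <- mk_FM(-gf, lf_I, +d, z_I)

  # ground-truth marks from the noise-free series (documented criteria)
  gf_on <- gf > 0.01
  lf_on <- (lf_T > 0.01) | (lf_I > 0.01)
  tau_on <- abs(torque_profile) > 1.5e-3
  onset <- which(gf_on & lf_on & tau_on)[1]
  liftoff <- which(lf_tot > W)[1]
  loading_end <- NA_integer_
  if (!is.na(onset)) {
    pk <- first_local_max_index(lf_tot, onset)
    if (!is.na(pk)) {
      below <- which(lf_tot[(pk + 1):n] < W)
      if (length(below)) loading_end <- pk + below[1]
    }
  }
  hold_start <- which(t >= t1 & env == 0)[1]
  marks <- phase_marks(onset = onset, loading_end = loading_end,
                       liftoff = liftoff,
                       hold_window = c(hold_start, n), n = n)

  add_noise <- function(FM, which_seed) {
    if (p$force_noise_sd == 0 && p$moment_noise_sd == 0) return(FM)
    with_seed(which_seed, {
      FM$F <- FM$F + matrix(stats::rnorm(3 * n, 0, p$force_noise_sd), n, 3)
      FM$M <- FM$M + matrix(stats::rnorm(3 * n, 0, p$moment_noise_sd), n, 3)
    })
    FM
  }
  thumbFM <- add_noise(thumbFM, derive_seed(seed, 1))
  indexFM <- add_noise(indexFM, derive_seed(seed, 2))

  thumb <- ft_trace("thumb", t, thumbFM$F, thumbFM$M,
                    calibration = list(rotation = diag(3), pad_offset_x = -d),
                    aligned = TRUE)
  index <- ft_trace("index", t, indexFM$F, indexFM$M,
                    calibration = list(rotation = diag(3), pad_offset_x = +d),
                    aligned = TRUE)
  if (emit == "flipped") {
    flip <- function(tr) {
      tr$F <- tr$F %*% t(rotation_z_180())
      tr$M <- tr$M %*% t(rotation_z_180())
      colnames(tr$F) <- colnames(tr$M) <- c("x", "y", "z")
      tr$calibration$pad_offset_x <- -tr$calibration$pad_offset_x
      tr$aligned <- FALSE
      tr
    }
    thumb <- flip(thumb); index <- flip(index)
  }
  list(thumb = thumb, index = index, t = t, marks = marks,
       torque_profile = torque_profile, lf_total = lf_tot,
       object = object, params = params, seed = seed)
}

#' Synthetic perceptual observer
#'
#' A rating model in which the reported heaviness of each object half is a
#' mixture of the visually expected half mass (from the material catalog)
#' and the physically sensed half mass:
#' `psi = w * expected + (1 - w) * true + noise` for an integrating
#' observer. A contrast observer is repelled from the expectation:
#' `psi = true - w * (expected - true) + noise`. Before the first lift only
#' the expectation is available (`w = 1` regardless of mode).
#'
#' @param w prior weight in `[0, 1]`.
#' @param rating_noise_sd SD of the additive rating noise (kg-equivalent
#'   units on the internal heaviness scale).
#' @param task `"numeric"` (per-half magnitude estimates), `"com"`
#'   (CoM-pointing converted to a position), or `"whole"` (whole-object
#'   rating = sum of the half percepts).
#' @param mode `"integrate"` or `"contrast"`.
#' @param catalog material catalog supplying the expectations.
#' @param context_anchor_gain >= 0; 0 (default) disables divisive
#'   normalization of reported differences by the session range.
#' @return object of class `synthetic_observer`.
#' @export
synthetic_observer <- function(w = 0.3, rating_noise_sd = 0.02,
                               task = c("numeric", "com", "whole"),
                               mode = c("integrate", "contrast"),
                               catalog = material_catalog(),
                               context_anchor_gain = 0) {
  task <- match.arg(task); mode <- match.arg(mode)
  if (w < 0 || w > 1) stop("w must be in [0, 1]")
  if (rating_noise_sd < 0) stop("rating_noise_sd must be >= 0")
  if (context_anchor_gain < 0) stop("context_anchor_gain must be >= 0")
  structure(list(w = w, rating_noise_sd = rating_noise_sd, task = task,
                 mode = mode, catalog = catalog,
                 context_anchor_gain = context_anchor_gain),
            class = "synthetic_observer")
}

expected_half_masses <- function(object, catalog) {
  half_vol <- (object$length / 2) * prod(object$cross_section)
  catalog_density(catalog, object$appearance) * half_vol
}

#' Simulate perceptual ratings for one object
#'
#' Produces one row per rated target (each half for `"numeric"`/`"com"`
#' tasks, the whole object for `"whole"`). Pre-lift ratings use `w = 1`
#' (pure expectation). The CoM task reports the balance point of the two
#' half percepts, clipped to `[0, L]`, with position measured from the
#' half-1 end of the object.
#'
#' @param observer a [synthetic_observer()].
#' @param object an [object_spec()].
#' @param phase `"pre"` or `"post"`.
#' @param n_trials number of repeated ratings.
#' @param seed integer seed.
#' @param participant participant id stored in the output.
#' @return a `data.frame` rating table with columns `participant`, `trial`,
#'   `phase`, `object_id`, `target`, `task`, `raw`.
#' @export
simulate_ratings <- function(observer, object, phase = c("post", "pre"),
                             n_trials = 1, seed = 1L, participant = 1L) {
  phase <- match.arg(phase)
  stopifnot(inherits(observer, "synthetic_observer"),
            inherits(object, "object_spec"))
  E <- expected_half_masses(object, observer$catalog)
  m_true <- c(object$half_mass_1, object$half_mass_2)
  w <- if (phase == "pre") 1 else observer$w
  psi0 <- if (phase == "pre" || observer$mode == "integrate") {
    w * E + (1 - w) * m_true
  } else {
    m_true - w * (E - m_true)
  }
  rows <- list()
  for (tr in seq_len(n_trials)) {
    noise <- with_seed(derive_seed(seed, participant, tr,
                                   if (phase == "pre") 7 else 8),
                       stats::rnorm(2, 0, observer$rating_noise_sd))
    psi <- psi0 + noise
    if (observer$task == "numeric") {
      rows[[tr]] <- data.frame(participant = participant, trial = tr,
                               phase = phase, object_id = object$id,
                               target = c("half1", "half2"),
                               material = object$appearance,
                               task = "numeric", raw = psi,
                               stringsAsFactors = FALSE)
    } else if (observer$task == "com") {
      psi_pos <- pmax(psi, 0)
      L <- object$length
      x <- if (sum(psi_pos) > 0) {
        (psi_pos[1] * L / 4 + psi_pos[2] * 3 * L / 4) / sum(psi_pos)
      } else L / 2
      x <- min(max(x, 0), L)
      rows[[tr]] <- data.frame(participant = participant, trial = tr,
                               phase = phase, object_id = object$id,
                               target = "com", material = NA_character_,
                               task = "com", raw = x,
                               stringsAsFactors = FALSE)
    } else {
      rows[[tr]] <- data.frame(participant = participant, trial = tr,
                               phase = phase, object_id = object$id,
                               target = "whole", material = NA_character_,
                               task = "whole", raw = sum(psi),
                               stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
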