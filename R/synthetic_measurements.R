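# Breath-by-breath capnography synthesis and the three SvO2 recording
# modalities (CO-oximetry spot samples, fiberoptic trace, capnodynamic
# stream) with their distinct noise models.

#' Synthesize volumetric-capnography breaths from a hemodynamic truth
#'
#' Forward model of the single-compartment alveolar CO2 store under the
#' 6-normal + 3-pause breathing pattern.  Per breath, perfusion delivers
#' CO2 at `epbf * (CvCO2' - b * F)` while expiration removes
#' `VT_alv * F`; the expiratory pauses let CO2 accumulate, producing the
#' small end-tidal fluctuations the EPBF fit relies on.  The venous CO2
#' offset is calibrated per breath so the periodic solution eliminates
#' exactly `vo2_true * RQ`, keeping the breath stream mass-balanced
#' against the metabolic truth.
#'
#' @param states truth data frame from [run_scenario()].
#' @param seed RNG seed used for the breath-level noise (ignored when
#'   `noise_cv = 0`).
#' @param noise_cv multiplicative coefficient of variation applied to
#'   expired CO2 volume and end-tidal fraction per breath.
#' @param pattern list with `n_normal`, `n_pause` breaths per cycle.
#' @return A breath-record data frame: `breath_index`, `t_start_s`,
#'   `duration_s`, `breath_type`, `vt_ml`, `vtco2_ml`, `fet_co2`,
#'   `fio2`.
#' @export
synthesize_breaths <- function(states, seed = NULL, noise_cv = 0,
                               pattern = list(n_normal = 6, n_pause = 3)) {
  bl <- attr(states, "baseline")
  k <- attr(states, "constants")
  if (is.null(bl) || is.null(k)) {
    stop("states must come from run_scenario()", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)

  dt_norm <- 60 / bl$resp_rate
  dt_pause <- dt_norm + bl$pause_s
  cyc <- c(rep(dt_norm, pattern$n_normal), rep(dt_pause, pattern$n_pause))
  types <- c(rep("normal", pattern$n_normal), rep("pause", pattern$n_pause))
  t_total <- max(states$t_s) + 1
  n_cycles <- ceiling(t_total / sum(cyc)) + 1L
  dur <- rep(cyc, n_cycles)
  btype <- rep(types, n_cycles)
  t_start <- cumsum(c(0, dur[-length(dur)]))
  keep <- (t_start + dur) <= t_total
  dur <- dur[keep]; btype <- btype[keep]; t_start <- t_start[keep]
  nb <- length(dur)

  vt <- bl$vt_ml_per_kg * bl$weight_kg
  vt_alv <- vt * (1 - bl$dead_space_fraction)
  elv <- bl$elv_ml_per_kg * bl$weight_kg
  b <- k$co2_blood_slope
  vco2_rate <- bl$vo2 * k$respiratory_quotient  # ml/min, metabolic truth

  # unit response of the periodic cycle: mean elimination per unit CvCO2'
  # at a given EPBF, used to calibrate CvCO2' so that the periodic
  # solution eliminates exactly vco2_rate
  cycle_gain <- function(epbf) {
    dts <- cyc / 60
    den <- elv + dts * epbf * b + vt_alv
    alpha <- elv / den
    beta <- dts * epbf / den
    # periodic fixed point for CvCO2' = 1
    g <- prod(alpha)
    acc <- 0
    for (j in seq_along(dts)) {
      tail_gain <- if (j < length(dts)) prod(alpha[(j + 1):length(dts)]) else 1
      acc <- acc + beta[j] * tail_gain
    }
    f0 <- acc / (1 - g)
    fvals <- numeric(length(dts))
    fp <- f0
    for (j in seq_along(dts)) {
      fp <- alpha[j] * fp + beta[j]
      fvals[j] <- fp
    }
    sum(vt_alv * fvals) / (sum(cyc) / 60)  # ml/min eliminated per unit CvCO2'
  }

  # state lookup per breath (epbf and fio2 at the breath start)
  idx <- pmin(pmax(floor(t_start), 0) + 1L, nrow(states))
  epbf_b <- states$epbf_true[idx]
  fio2_b <- states$fio2[idx]

  fet <- numeric(nb)
  vtco2 <- numeric(nb)
  f_tgt <- vco2_rate * (dt_norm / 60) / vt_alv
  f_prev <- f_tgt
  gain_cache <- new.env(parent = emptyenv())
  for (i in seq_len(nb)) {
    e <- epbf_b[i]
    if (e <= 0) {
      fet[i] <- f_prev  # no perfusion: store neither fed nor, once
      vtco2[i] <- 0     # washed out, elimination collapses
      next
    }
    keyn <- format(e, digits = 10)
    gain <- gain_cache[[keyn]]
    if (is.null(gain)) {
      gain <- cycle_gain(e)
      gain_cache[[keyn]] <- gain
    }
    cvco2p <- vco2_rate / gain
    dts <- dur[i] / 60
    den <- elv + dts * e * b + vt_alv
    f_new <- (elv * f_prev + dts * e * cvco2p) / den
    fet[i] <- f_new
    vtco2[i] <- vt_alv * f_new
    f_prev <- f_new
  }

  if (noise_cv > 0) {
    vtco2 <- vtco2 * (1 + stats::rnorm(nb, 0, noise_cv))
    fet <- fet * (1 + stats::rnorm(nb, 0, noise_cv))
    vtco2 <- pmax(vtco2, 0)
    fet <- pmin(pmax(fet, 0), 0.149)
  }

  data.frame(
    breath_index = seq_len(nb),
    t_start_s = t_start,
    duration_s = dur,
    breath_type = btype,
    vt_ml = vt,
    vtco2_ml = vtco2,
    fet_co2 = fet,
    fio2 = fio2_b,
    stringsAsFactors = FALSE
  )
}

#' Measurement model for the three SvO2 modalities
#'
#' Noise and response characteristics of the three recording streams.
#' The CVs are chosen so that two times the sample CV of five baseline
#' repeats reproduces, in expectation, the inherent precision reported
#' for each modality (about 11 percent for CO-oximetry, 7 for
#' fiberoptic, 6 for the capnodynamic stream); the small upward
#' adjustment compensates the finite-sample bias of the SD estimator
#' (c4 correction for n = 5).
#'
#' @param co_oximetry_cv multiplicative CV of CO-oximetry spot samples.
#' @param fiberoptic_cv multiplicative CV of fiberoptic readings.
#' @param fiberoptic_drift_rate fractional drift per hour between
#'   calibrations (negative: the module slowly under-reads).
#' @param capno_extra_cv extra multiplicative CV on the capnodynamic
#'   readings beyond the estimator's own breath-level variability.
#' @param lag_fiberoptic response lag of the fiberoptic trace, seconds.
#' @param breath_noise_cv per-breath capnography noise handed to
#'   [synthesize_breaths()].
#' @return A named list of class `measurement_model`.
#' @export
measurement_model <- function(co_oximetry_cv = 0.0585,
                              fiberoptic_cv = 0.0372,
                              fiberoptic_drift_rate = -0.02,
                              capno_extra_cv = 0.0319,
                              lag_fiberoptic = 40,
                              breath_noise_cv = 0.002) {
  m <- as.list(environment())
  if (any(unlist(m[c("co_oximetry_cv", "fiberoptic_cv", "capno_extra_cv",
                     "breath_noise_cv")]) < 0)) {
    stop("measurement CVs must be >= 0", call. = FALSE)
  }
  class(m) <- "measurement_model"
  m
}

#' @rdname measurement_model
#' @details `noiseless_model()` zeroes every noise, drift and lag term;
#'   all three streams then reproduce the simulated truth exactly (up to
#'   the estimator's own numerics).
#' @export
noiseless_model <- function() {
  measurement_model(co_oximetry_cv = 0, fiberoptic_cv = 0,
                    fiberoptic_drift_rate = 0, capno_extra_cv = 0,
                    lag_fiberoptic = 0, breath_noise_cv = 0)
}

#' Sample the three SvO2 recording streams
#'
#' Produces the simultaneous recording table of the virtual experiment:
#' CO-oximetry spot samples of the true saturation with multiplicative
#' noise; a lagged, slowly drifting fiberoptic trace reset at each
#' calibration; and the capnodynamic stream, i.e. the actual estimator
#' run on the synthesized breath sequence and read off at the recording
#' times.
#'
#' @param states truth data frame from [run_scenario()].
#' @param model a [measurement_model()].
#' @param plan sampling plan (`phase`, `slot`, `t_s`); defaults to
#'   [default_sampling_plan()].
#' @param seed RNG seed for all measurement noise.
#' @param animal_id identifier written into the output rows.
#' @param estimates optional precomputed estimator output (from
#'   [estimate_capno_svo2()]); when `NULL` breaths are synthesized and
#'   the estimator is run internally.
#' @return A list with `recordings` (columns `animal_id`, `phase`,
#'   `slot`, `t_s`, `method`, `svo2_pct`), `breaths`, and `estimates`.
#' @export
sample_measurements <- function(states, model = measurement_model(),
                                plan = default_sampling_plan(),
                                seed = NULL, animal_id = "animal01",
                                estimates = NULL) {
  if (!is.null(seed)) set.seed(seed)
  k <- attr(states, "constants")
  bl <- attr(states, "baseline")
  breaths <- NULL
  if (is.null(estimates)) {
    breaths <- synthesize_breaths(states, noise_cv = model$breath_noise_cv)
    # hemoglobin is an external blood-gas input to the capnodynamic
    # calculation; the simulator supplies the current value per breath
    hb_b <- states$hb[pmin(floor(breaths$t_start_s) + 1L, nrow(states))]
    estimates <- estimate_capno_svo2(breaths, hb = hb_b, constants = k)
  }
  np <- nrow(plan)
  truth_at <- function(t) {
    i <- pmin(pmax(floor(t), 0) + 1L, nrow(states))
    100 * states$svo2_true[i]
  }

  co_ox <- truth_at(plan$t_s) * (1 + stats::rnorm(np, 0, model$co_oximetry_cv))

  cal <- attr(plan, "calibration_times")
  if (is.null(cal)) cal <- 0
  last_cal <- vapply(plan$t_s, function(t) {
    c0 <- cal[cal <= t]
    if (length(c0)) max(c0) else 0
  }, numeric(1))
  drift <- 1 + model$fiberoptic_drift_rate * (plan$t_s - last_cal) / 3600
  fiber <- truth_at(pmax(plan$t_s - model$lag_fiberoptic, 0)) * drift *
    (1 + stats::rnorm(np, 0, model$fiberoptic_cv))

  # capnodynamic stream: filtered estimator value at the last completed
  # breath before each recording time
  est_idx <- findInterval(plan$t_s, estimates$t_s)
  est_idx[est_idx < 1L] <- 1L
  capno <- estimates$svo2_filt_pct[est_idx] *
    (1 + stats::rnorm(np, 0, model$capno_extra_cv))

  clamp <- function(x) pmin(pmax(x, 0), 100)
  recordings <- rbind(
    data.frame(animal_id = animal_id, phase = plan$phase, slot = plan$slot,
               t_s = plan$t_s, method = "co_oximetry",
               svo2_pct = clamp(co_ox), stringsAsFactors = FALSE),
    data.frame(animal_id = animal_id, phase = plan$phase, slot = plan$slot,
               t_s = plan$t_s, method = "fiberoptic",
               svo2_pct = clamp(fiber), stringsAsFactors = FALSE),
    data.frame(animal_id = animal_id, phase = plan$phase, slot = plan$slot,
               t_s = plan$t_s, method = "capno",
               svo2_pct = clamp(capno), stringsAsFactors = FALSE)
  )
  list(recordings = recordings, breaths = breaths, estimates = estimates)
}

#' Simulate the full multi-animal experiment
#'
#' Runs the complete virtual study: per animal, a jittered baseline
#' (log-normal spread on cardiac output and oxygen consumption, normal
#' spread on hemoglobin, uniform spread on LPS severity), the scenario
#' trajectory, breath synthesis, the capnodynamic estimator, and the
#' three recording streams.  All randomness flows from one seeded
#' generator, so a given seed reproduces the experiment exactly.
#'
#' @param n_animals number of virtual animals.
#' @param seed integer seed.
#' @param model a [measurement_model()]; use [noiseless_model()] for
#'   noise-free runs.
#' @param constants a [physio_constants()] object.
#' @param baseline baseline physiology shared by all animals before
#'   jitter.
#' @param jitter logical; disable to make all animals identical.
#' @return A list with `recordings`, `truth`, `breaths`, `estimates`
#'   (all row-bound across animals with an `animal_id` column).
#' @export
simulate_experiment <- function(n_animals = 10, seed = 1,
                                model = measurement_model(),
                                constants = physio_constants(),
                                baseline = scenario_baseline(),
                                jitter = TRUE) {
  set.seed(seed)
  rec <- tru <- bre <- est <- vector("list", n_animals)
  for (a in seq_len(n_animals)) {
    id <- sprintf("animal%02d", a)
    bl <- baseline
    sev <- 1
    if (jitter) {
      bl$cardiac_output <- bl$cardiac_output * exp(stats::rnorm(1, 0, 0.08))
      bl$vo2 <- bl$vo2 * exp(stats::rnorm(1, 0, 0.08))
      bl$hb <- bl$hb + stats::rnorm(1, 0, 5)
      sev <- stats::runif(1, 0.7, 1.3)
    }
    states <- run_scenario(default_scenario(severity = sev), bl, constants)
    breaths <- synthesize_breaths(states, noise_cv = model$breath_noise_cv)
    hb_b <- states$hb[pmin(floor(breaths$t_start_s) + 1L, nrow(states))]
    estimates <- estimate_capno_svo2(breaths, hb = hb_b, constants = constants)
    sm <- sample_measurements(states, model, animal_id = id,
                              estimates = estimates)
    sm$recordings$animal_id <- id
    states$animal_id <- id
    breaths$animal_id <- id
    estimates$animal_id <- id
    rec[[a]] <- sm$recordings
    tru[[a]] <- states
    bre[[a]] <- breaths
    est[[a]] <- estimates
  }
  list(recordings = do.call(rbind, rec), truth = do.call(rbind, tru),
       breaths = do.call(rbind, bre), estimates = do.call(rbind, est))
}
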