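# Virtual porcine endotoxemia experiment: hemodynamic ground truth for
# an LPS induction followed by the standard stabilization challenges.

#' Baseline physiology of the virtual animal
#'
#' Plausible values for a juvenile domestic pig around 31.5 kg under
#' general anesthesia and volume-controlled ventilation.  The baseline
#' yields a true mixed venous saturation of about 60 percent, with the
#' endotoxemic nadir near 40 percent.
#'
#' @param weight_kg body weight, kg.
#' @param cardiac_output L per min.
#' @param shunt_fraction fraction of cardiac output bypassing gas
#'   exchange (venous admixture).
#' @param vo2 oxygen consumption, ml per min.
#' @param hb hemoglobin, g per L.
#' @param fio2 inspired oxygen fraction.
#' @param peep cm H2O.
#' @param vt_ml_per_kg tidal volume setting, ml per kg.
#' @param dead_space_fraction airway dead space as a fraction of tidal
#'   volume.
#' @param elv_ml_per_kg effective lung volume (CO2 store), ml per kg.
#' @param resp_rate normal-breath respiratory rate, per min.
#' @param pause_s expiratory pause added to pause breaths, seconds.
#' @return A named list.
#' @export
scenario_baseline <- function(weight_kg = 31.5, cardiac_output = 4.0,
                              shunt_fraction = 0.10, vo2 = 180, hb = 90,
                              fio2 = 0.30, peep = 5, vt_ml_per_kg = 10,
                              dead_space_fraction = 0.30,
                              elv_ml_per_kg = 35, resp_rate = 15,
                              pause_s = 2.5) {
  as.list(environment())
}

#' Default endotoxemia study scenario
#'
#' Event list reproducing the protocol structure: a stable baseline with
#' five precision readings, LPS infusion driving cardiac output down and
#' pulmonary shunt up over the first hour, partial stabilization, then
#' seven challenges -- crystalloid bolus, stepwise FiO2
#' 0.3-0.5-0.8-1.0-0.3, PEEP 5-10-15-5, dobutamine, norepinephrine,
#' 15 ml per kg hemorrhage, and whole-blood retransfusion.
#'
#' @param severity scaling of the LPS response (1 = nominal).
#' @return A data frame `t_start_s`, `kind`, `magnitude`, time-ordered.
#' @export
default_scenario <- function(severity = 1) {
  ev <- function(t, kind, mag) data.frame(t_start_s = t, kind = kind,
                                          magnitude = mag,
                                          stringsAsFactors = FALSE)
  events <- rbind(
    ev(1800, "lps_start", severity),
    ev(5400, "lps_stabilize", 0.35),       # partial recovery under rescue care
    ev(9300, "crystalloid_bolus", 15),     # ml/kg
    ev(11100, "fio2_step", 0.5),
    ev(11400, "fio2_step", 0.8),
    ev(11700, "fio2_step", 1.0),
    ev(12000, "fio2_step", 0.3),
    ev(12300, "peep_step", 10),
    ev(12420, "peep_step", 15),
    ev(12540, "peep_step", 5),
    ev(12900, "dobutamine", 0.40),         # fractional CO increase
    ev(13800, "dobutamine", 0),
    ev(14700, "norepinephrine", 0.12),
    ev(15300, "norepinephrine", 0),
    ev(15900, "hemorrhage", 15),           # ml/kg withdrawn
    ev(17100, "retransfusion", 15)
  )
  events[order(events$t_start_s), ]
}

#' Recording schedule matched to the default scenario
#'
#' Simultaneous readings of all three modalities: five baseline
#' precision readings five minutes apart, every-10-min readings during
#' the LPS hour, and pre/post readings bracketing each challenge at its
#' anticipated extremes (e.g. FiO2 0.3 versus 1.0, PEEP 5 versus 15,
#' just before versus after retransfusion).
#'
#' @return A data frame `phase`, `slot`, `t_s` with attribute
#'   `calibration_times` (fiberoptic calibration resets).
#' @export
default_sampling_plan <- function() {
  p <- function(phase, slot, t) data.frame(phase = phase, slot = slot,
                                           t_s = t, stringsAsFactors = FALSE)
  plan <- rbind(
    p("baseline", paste0("bl", 1:5), c(300, 600, 900, 1200, 1500)),
    p("induction", "pre", 1790),
    p("induction", paste0("mid", 1:5), seq(2400, 4800, by = 600)),
    p("induction", "post", 5400),
    p("crystalloid", "pre", 9290),
    p("crystalloid", "post", 10740),
    p("fio2", "pre", 11095),               # at FiO2 0.3
    p("fio2", "mid1", 11395),              # 0.5
    p("fio2", "mid2", 11695),              # 0.8
    p("fio2", "post", 11995),              # 1.0, the anticipated extreme
    p("peep", "pre", 12295),               # PEEP 5, FiO2 back at 0.3
    p("peep", "mid1", 12415),              # PEEP 10
    p("peep", "post", 12535),              # PEEP 15, the extreme
    p("dobutamine", "pre", 12895),
    p("dobutamine", "post", 13795),
    p("norepinephrine", "pre", 14695),
    p("norepinephrine", "post", 15295),
    p("hemorrhage", "pre", 15895),
    p("hemorrhage", "post", 16800),
    p("retransfusion", "pre", 17090),      # just before transfusion
    p("retransfusion", "post", 18180)
  )
  attr(plan, "calibration_times") <- c(0, 9000)
  plan
}

#' Run the hemodynamic scenario
#'
#' Integrates a piecewise-smooth hemodynamic trajectory at 1 s
#' resolution.  Each event moves a target (cardiac output multiplier,
#' shunt fraction, hemoglobin, FiO2, PEEP); the state relaxes toward its
#' target with first-order dynamics (`tau`, default 120 s; inspired gas
#' uses a faster 30 s constant).  At every time step the true mixed
#' venous saturation is solved from the whole-body Fick relation with
#' venous admixture: end-capillary content from the alveolar gas
#' equation, venous content `Cc - VO2 / EPBF` with
#' `EPBF = CO * (1 - shunt)`, and saturation by inverting the oxygen
#' content relation.
#'
#' @param events event data frame as from [default_scenario()].
#' @param baseline a [scenario_baseline()] list.
#' @param constants a [physio_constants()] object.
#' @param duration_s total duration, seconds.
#' @param tau relaxation time constant for hemodynamic targets, s.
#' @param tau_gas relaxation time constant for inspired-gas effects, s.
#' @return A data frame with one row per second: `t_s`,
#'   `cardiac_output`, `shunt_fraction`, `vo2_true`, `hb`, `fio2`,
#'   `peep`, `paco2`, `svo2_true`, `epbf_true`; `baseline` and
#'   `constants` attached as attributes.
#' @export
run_scenario <- function(events = default_scenario(),
                         baseline = scenario_baseline(),
                         constants = physio_constants(),
                         duration_s = 18300, tau = 120, tau_gas = 30) {
  if (nrow(events) > 0) {
    if (is.unsorted(events$t_start_s)) {
      stop("events must be time-ordered", call. = FALSE)
    }
    dup <- duplicated(events[, c("t_start_s", "kind")])
    if (any(dup)) stop("conflicting events: same kind at the same time",
                       call. = FALSE)
  }
  tt <- seq(0, duration_s - 1)
  n <- length(tt)

  # --- build per-second targets from the event list -------------------
  known <- c("lps_start", "lps_stabilize", "crystalloid_bolus", "fio2_step",
             "peep_step", "dobutamine", "norepinephrine", "hemorrhage",
             "retransfusion")
  bad <- setdiff(events$kind, known)
  if (length(bad)) stop("unknown event kind: ", bad[1L], call. = FALSE)

  lps_t0 <- NA_real_; lps_sev <- 0; lps_resid <- NA_real_; lps_tstab <- NA_real_
  fio2_tgt <- rep(baseline$fio2, n)
  peep_tgt <- rep(baseline$peep, n)
  for (i in seq_len(nrow(events))) {
    e <- events[i, ]
    idx <- tt >= e$t_start_s
    if (e$kind == "lps_start") { lps_t0 <- e$t_start_s; lps_sev <- e$magnitude }
    if (e$kind == "lps_stabilize") { lps_resid <- e$magnitude
                                     lps_tstab <- e$t_start_s }
    if (e$kind == "fio2_step") fio2_tgt[idx] <- e$magnitude
    if (e$kind == "peep_step") peep_tgt[idx] <- e$magnitude
  }

  # per-second level of each scalar effect (piecewise constant between
  # its events)
  level_track <- function(kind, init = 0) {
    lv <- rep(init, n)
    es <- events[events$kind == kind, ]
    for (i in seq_len(nrow(es))) {
      lv[tt >= es$t_start_s[i]] <- es$magnitude[i]
    }
    lv
  }
  dobu_lv <- level_track("dobutamine")
  norepi_lv <- level_track("norepinephrine")
  hemo_lv <- level_track("hemorrhage")
  retrans_lv <- level_track("retransfusion")
  cryst_lv <- level_track("crystalloid_bolus")

  # LPS severity: linear ramp over one hour, then exponential partial
  # recovery once rescue stabilization starts
  lps_lv <- rep(0, n)
  if (!is.na(lps_t0)) {
    ramp <- pmin(pmax((tt - lps_t0) / 3600, 0), 1) * lps_sev
    lps_lv <- ramp
    if (!is.na(lps_tstab)) {
      after <- tt >= lps_tstab
      at_stab <- min(max((lps_tstab - lps_t0) / 3600, 0), 1) * lps_sev
      target <- lps_resid * lps_sev
      lps_lv[after] <- target + (at_stab - target) *
        exp(-(tt[after] - lps_tstab) / 900)
    }
  }

  hemo_active <- pmax(hemo_lv - retrans_lv, 0)
  co_target <- baseline$cardiac_output *
    (1 - 0.25 * lps_lv) *
    (1 + dobu_lv) *
    (1 + norepi_lv) *
    (1 - 0.02 * hemo_active) *
    (1 + 0.003 * cryst_lv) *
    (1 - 0.025 * (peep_tgt - baseline$peep))
  shunt_target <- baseline$shunt_fraction + 0.08 * lps_lv
  hb_target <- baseline$hb * (1 - 0.006 * cryst_lv)

  relax <- function(target, init, tc) {
    a <- 1 - exp(-1 / tc)
    as.numeric(stats::filter(a * target, 1 - a, method = "recursive",
                             init = init))
  }
  co <- relax(co_target, baseline$cardiac_output, tau)
  shunt <- relax(shunt_target, baseline$shunt_fraction, tau)
  hb <- relax(hb_target, baseline$hb, tau)
  fio2 <- relax(fio2_tgt, baseline$fio2, tau_gas)
  fio2 <- pmin(pmax(fio2, 0.21), 1)

  # alveolar CO2 tension set by the ventilation: at steady state one
  # normal breath eliminates vco2 * dt, so the end-tidal fraction is
  # vco2 * dt / alveolar tidal volume
  k <- constants
  vt_alv <- baseline$vt_ml_per_kg * baseline$weight_kg *
    (1 - baseline$dead_space_fraction)
  dt_normal <- 60 / baseline$resp_rate
  vco2_true <- baseline$vo2 * k$respiratory_quotient
  f_tgt <- vco2_true * (dt_normal / 60) / vt_alv
  paco2 <- f_tgt * (k$barometric_pressure - k$water_vapor_pressure)

  epbf <- co * (1 - shunt)
  pao2 <- alveolar_po2(fio2, paco2, k)
  cc <- oxygen_content(hb, 1, pmax(pao2, 0), k)
  cv <- cc - baseline$vo2 / epbf
  svo2 <- saturation_from_content(pmax(cv, 0), hb, k,
                                  po2_cap = pmax(pao2, 1))

  states <- data.frame(
    t_s = tt, cardiac_output = co, shunt_fraction = shunt,
    vo2_true = baseline$vo2, hb = hb, fio2 = fio2, peep = peep_tgt,
    paco2 = paco2, svo2_true = svo2, epbf_true = epbf
  )
  attr(states, "baseline") <- baseline
  attr(states, "constants") <- constants
  attr(states, "events") <- events
  states
}
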