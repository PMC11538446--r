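# Breath-stream processing: volumetric capnography + FiO2 + hemoglobin
# -> breath-by-breath EPBF and capnodynamic SvO2.

# cs[lo - 1] with cs[0] treated as 0 (safe against zero indices)
cumsum_before <- function(cs, lo) {
  out <- numeric(length(lo))
  pos <- lo > 1L
  out[pos] <- cs[lo[pos] - 1L]
  out
}

#' Trailing-window mean with a time window
#'
#' Mean of `x` over the trailing `window` seconds (inclusive of the
#' current sample).  `NA` values are ignored.  Used for the 50 s display
#' filter on capnodynamic SvO2.
#'
#' @param t sample times, seconds, non-decreasing.
#' @param x values, same length as `t`.
#' @param window trailing window length, seconds.
#' @return Filtered vector, same length as `x`.
#' @export
moving_mean_filter <- function(t, x, window = 50) {
  n <- length(x)
  stopifnot(length(t) == n, window > 0)
  if (n == 0L) return(numeric(0))
  if (is.unsorted(t)) stop("t must be non-decreasing", call. = FALSE)
  ok <- !is.na(x)
  cs <- cumsum(ifelse(ok, x, 0))
  cn <- cumsum(as.numeric(ok))
  # first index inside the half-open window (t_i - window, t_i]
  lo <- findInterval(t - window, t) + 1L
  i <- seq_len(n)
  sums <- cs[i] - cumsum_before(cs, lo)
  cnts <- cn[i] - cumsum_before(cn, lo)
  out <- sums / cnts
  out[cnts == 0] <- NA_real_
  out
}

#' Windowed CO2 elimination rate
#'
#' Per-breath CO2 elimination as a moving mean over a trailing time
#' window (default 20 min): the summed expired CO2 volume divided by the
#' summed breath durations, scaled to ml per minute.  Before the window
#' has filled, all available breaths are used and the value is flagged
#' as warm-up.
#'
#' @param breaths a breath-record data frame (see [synthesize_breaths()]
#'   for the schema); needs columns `t_start_s`, `duration_s`,
#'   `vtco2_ml`.
#' @param window trailing window, seconds.
#' @return A data frame with columns `vco2_mlpm` and `warmup` (logical).
#' @export
windowed_vco2 <- function(breaths, window = 1200) {
  if (nrow(breaths) == 0L) stop("no breaths supplied", call. = FALSE)
  stopifnot(window > 0)
  t_end <- breaths$t_start_s + breaths$duration_s
  if (is.unsorted(breaths$t_start_s)) {
    stop("breaths must be time-ordered", call. = FALSE)
  }
  cv <- cumsum(breaths$vtco2_ml)
  cd <- cumsum(breaths$duration_s)
  lo <- findInterval(t_end - window, t_end) + 1L
  i <- seq_along(t_end)
  sv <- cv[i] - cumsum_before(cv, lo)
  sd_ <- cd[i] - cumsum_before(cd, lo)
  data.frame(
    vco2_mlpm = 60 * sv / sd_,
    warmup = (t_end - breaths$t_start_s[1L]) < window
  )
}

#' Oxygen consumption from CO2 elimination
#'
#' `vco2 / rq`: the respiratory quotient links steady-state CO2
#' elimination to oxygen consumption.
#'
#' @param vco2 CO2 elimination, ml per minute (>= 0).
#' @param rq respiratory quotient (> 0).
#' @return VO2, ml per minute.
#' @export
vo2_from_vco2 <- function(vco2, rq) {
  if (any(rq <= 0)) stop("rq must be > 0", call. = FALSE)
  if (any(vco2 < 0)) stop("vco2 must be >= 0", call. = FALSE)
  vco2 / rq
}

#' Fit effective pulmonary blood flow over one breathing-pattern cycle
#'
#' Least-squares fit of a single-compartment alveolar CO2 mass balance
#' over a window of breaths (default: the nine breaths of one
#' 6-normal + 3-pause pattern cycle).  For breath *n* the model is
#'
#' \deqn{ELV (F_n - F_{n-1}) = \Delta t_n\, EPBF\, (C_vCO_2' - b F_n) - VTCO_2_n}
#'
#' where `F` is the end-tidal (alveolar) CO2 fraction, `ELV` the
#' effective lung volume (ml), `b` the linearized blood CO2 dissociation
#' slope and `CvCO2'` the venous CO2 content offset.  The expiratory
#' pauses perturb the alveolar CO2 store, which makes the three unknowns
#' (`ELV`, `EPBF`, `EPBF * CvCO2'`) jointly identifiable breath by
#' breath.
#'
#' @param fet end-tidal CO2 fractions for the window breaths.
#' @param fet_prev end-tidal CO2 fraction of the breath preceding the
#'   window.
#' @param vtco2 expired CO2 volume per breath, ml.
#' @param duration breath durations, seconds.
#' @param constants a [physio_constants()] object (supplies `b`).
#' @param cvco2_fixed optional known venous CO2 offset (ml per L); when
#'   supplied only `ELV` and `EPBF` are fitted (carry-forward mode).
#' @return A list with `epbf` (L per min, clamped at 0), `elv` (ml),
#'   `cvco2` (ml per L, `NA` in degenerate fits), and `flag` (`""`,
#'   `"degenerate"`, or `"epbf_clamped"`).
#' @export
fit_epbf_window <- function(fet, fet_prev, vtco2, duration,
                            constants = physio_constants(),
                            cvco2_fixed = NULL) {
  nw <- length(fet)
  stopifnot(length(vtco2) == nw, length(duration) == nw)
  f_prev <- c(fet_prev, fet[-nw])
  dt <- duration / 60
  b <- constants$co2_blood_slope
  if (is.null(cvco2_fixed)) {
    A <- cbind(f_prev - fet, -b * dt * fet, dt)
  } else {
    A <- cbind(f_prev - fet, dt * (cvco2_fixed - b * fet))
  }
  fit <- stats::.lm.fit(A, vtco2)
  p <- ncol(A)
  if (fit$rank < p || !all(is.finite(fit$coefficients))) {
    return(list(epbf = NA_real_, elv = NA_real_, cvco2 = NA_real_,
                flag = "degenerate"))
  }
  co <- fit$coefficients
  elv <- co[1L]
  epbf <- co[2L]
  cvco2 <- if (is.null(cvco2_fixed)) {
    if (abs(epbf) > 1e-12) co[3L] / epbf else NA_real_
  } else cvco2_fixed
  flag <- ""
  if (epbf <= 0) {
    epbf <- 0
    flag <- "epbf_clamped"
  }
  list(epbf = epbf, elv = elv, cvco2 = cvco2, flag = flag)
}

#' Pulmonary end-capillary and mixed venous oxygen content chain
#'
#' Implements the differential Fick chain: end-capillary content assumes
#' fully saturated blood in equilibrium with alveolar oxygen tension;
#' venous content is `cco2 - vo2 / epbf` (ml per min divided by L per
#' min gives ml per L); venous saturation is recovered by inverting the
#' oxygen content relation.  Zero flow or negative venous content are
#' clamped to SvO2 = 0 with a quality flag, mirroring the transient
#' zeros the method displays during circulatory collapse.
#'
#' @param epbf effective pulmonary blood flow, L per min (vectorized).
#' @param vo2 oxygen consumption, ml per min.
#' @param fio2 inspired oxygen fraction.
#' @param paco2_alv alveolar CO2 tension, mmHg.
#' @param hb hemoglobin, g per L.
#' @param constants a [physio_constants()] object.
#' @return A data frame with `cco2`, `cvo2`, `svo2` and `quality_flag`.
#' @export
capno_svo2_chain <- function(epbf, vo2, fio2, paco2_alv, hb,
                             constants = physio_constants()) {
  n <- max(length(epbf), length(vo2), length(fio2), length(paco2_alv))
  epbf <- rep_len(epbf, n); vo2 <- rep_len(vo2, n)
  fio2 <- rep_len(fio2, n); paco2_alv <- rep_len(paco2_alv, n)
  hb <- rep_len(hb, n)
  if (any(vo2 < 0, na.rm = TRUE)) stop("vo2 must be >= 0", call. = FALSE)

  pao2 <- alveolar_po2(fio2, paco2_alv, constants)
  flag <- character(n)
  flag[!is.na(pao2) & pao2 <= 0] <- "nonphysiologic_pao2"
  pao2_pos <- pmax(pao2, 0)
  cco2 <- oxygen_content(hb, 1, pao2_pos, constants)

  cvo2 <- ifelse(epbf > 0, cco2 - vo2 / epbf, -Inf)
  no_flow <- !is.na(epbf) & epbf <= 0
  clamped <- !no_flow & !is.na(cvo2) & cvo2 < 0
  flag[no_flow] <- paste0(flag[no_flow], ifelse(nzchar(flag[no_flow]), ";", ""),
                          "no_flow")
  flag[clamped] <- paste0(flag[clamped], ifelse(nzchar(flag[clamped]), ";", ""),
                          "clamped_low")

  svo2 <- rep(NA_real_, n)
  calc <- !is.na(cvo2)
  svo2[calc] <- saturation_from_content(pmax(cvo2[calc], 0), hb[calc],
                                        constants, po2_cap = pao2_pos[calc])
  svo2[no_flow] <- 0
  cvo2[no_flow] <- NA_real_
  data.frame(cco2 = cco2, cvo2 = cvo2, svo2 = pmin(pmax(svo2, 0), 1),
             quality_flag = flag, stringsAsFactors = FALSE)
}

#' Run the full capnodynamic SvO2 estimator over a breath stream
#'
#' For each breath (once a full pattern cycle is available) EPBF is
#' refitted from the trailing `window_breaths` breaths, CO2 elimination
#' is averaged over the trailing `vco2_window` seconds, oxygen
#' consumption follows from the respiratory quotient, and the Fick chain
#' converts flow and consumption into mixed venous oxygen content and
#' saturation.  A trailing 50 s moving mean provides the filtered
#' display value.
#'
#' @param breaths breath-record data frame with columns `breath_index`,
#'   `t_start_s`, `duration_s`, `breath_type`, `vt_ml`, `vtco2_ml`,
#'   `fet_co2`, `fio2`.
#' @param hb hemoglobin, g per L (scalar, or per-breath vector).
#' @param constants a [physio_constants()] object.
#' @param window_breaths EPBF fit window (breaths); default one full
#'   6 + 3 pattern cycle.
#' @param vco2_window VCO2 averaging window, seconds.
#' @param filter_window SvO2 display filter window, seconds.
#' @param carry_cvco2 if `TRUE`, the venous CO2 offset from the previous
#'   fit is treated as known in the next one instead of being refitted.
#' @return A data frame with one row per breath: `breath_index`, `t_s`,
#'   `epbf_lpm`, `vco2_mlpm`, `vo2_mlpm`, `cco2_mll`, `cvo2_mll`,
#'   `svo2_pct`, `svo2_filt_pct`, `quality_flag`.
#' @export
estimate_capno_svo2 <- function(breaths, hb, constants = physio_constants(),
                                window_breaths = 9, vco2_window = 1200,
                                filter_window = 50, carry_cvco2 = FALSE) {
  validate_breaths(breaths)
  n <- nrow(breaths)
  fet <- breaths$fet_co2
  dur <- breaths$duration_s
  vt <- breaths$vtco2_ml

  epbf <- rep(NA_real_, n)
  flags <- character(n)
  last_valid <- NA_real_
  last_cvco2 <- NULL
  start <- window_breaths + 1L
  if (n >= start) {
    for (i in start:n) {
      k <- (i - window_breaths + 1L):i
      fit <- fit_epbf_window(fet[k], fet[i - window_breaths], vt[k], dur[k],
                             constants,
                             cvco2_fixed = if (carry_cvco2) last_cvco2 else NULL)
      if (identical(fit$flag, "degenerate")) {
        epbf[i] <- last_valid
        flags[i] <- "degenerate"
      } else {
        epbf[i] <- fit$epbf
        flags[i] <- fit$flag
        if (fit$epbf > 0) {
          last_valid <- fit$epbf
          if (is.finite(fit$cvco2)) last_cvco2 <- fit$cvco2
        }
      }
    }
  }
  flags[seq_len(min(window_breaths, n))] <- "warmup_epbf"

  vc <- windowed_vco2(breaths, window = vco2_window)
  flags <- ifelse(vc$warmup,
                  paste0(flags, ifelse(nzchar(flags), ";", ""), "warmup_vco2"),
                  flags)
  vo2 <- vo2_from_vco2(vc$vco2_mlpm, constants$respiratory_quotient)

  paco2 <- fet * (constants$barometric_pressure - constants$water_vapor_pressure)
  chain <- capno_svo2_chain(epbf, vo2, breaths$fio2, paco2, hb, constants)
  flags <- ifelse(nzchar(chain$quality_flag),
                  paste0(flags, ifelse(nzchar(flags), ";", ""),
                         chain$quality_flag),
                  flags)

  t_s <- breaths$t_start_s + breaths$duration_s
  svo2 <- ifelse(is.na(epbf), NA_real_, chain$svo2)
  data.frame(
    breath_index = breaths$breath_index,
    t_s = t_s,
    epbf_lpm = epbf,
    vco2_mlpm = vc$vco2_mlpm,
    vo2_mlpm = vo2,
    cco2_mll = chain$cco2,
    cvo2_mll = chain$cvo2,
    svo2_pct = 100 * svo2,
    svo2_filt_pct = 100 * moving_mean_filter(t_s, svo2, filter_window),
    quality_flag = flags,
    stringsAsFactors = FALSE
  )
}

validate_breaths <- function(breaths) {
  need <- c("breath_index", "t_start_s", "duration_s", "breath_type",
            "vt_ml", "vtco2_ml", "fet_co2", "fio2")
  miss <- setdiff(need, names(breaths))
  if (length(miss)) {
    stop("breath table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(breaths) == 0L) stop("breath table is empty", call. = FALSE)
  if (is.unsorted(breaths$t_start_s)) {
    bad <- which(diff(breaths$t_start_s) < 0)[1L] + 1L
    stop("breaths out of time order at row ", bad, call. = FALSE)
  }
  if (any(breaths$duration_s <= 0)) {
    stop("breath durations must be > 0", call. = FALSE)
  }
  if (any(breaths$vtco2_ml < 0)) stop("vtco2_ml must be >= 0", call. = FALSE)
  if (any(breaths$fet_co2 < 0 | breaths$fet_co2 >= 0.15)) {
    stop("fet_co2 must lie in [0, 0.15)", call. = FALSE)
  }
  invisible(breaths)
}
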