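# Gas-exchange and blood oxygen-content arithmetic shared by the
# capnodynamic estimator and the hemodynamic simulator.

#' Physiologic constants for oxygen-content calculations
#'
#' Bundles the constants used throughout the package: Hüfner's constant
#' (ml O2 bound per g of fully saturated hemoglobin), the solubility of
#' oxygen in blood plasma, barometric and water-vapor pressures for the
#' alveolar gas equation, the P50 of the oxygen-hemoglobin dissociation
#' curve (ODC), the respiratory quotient used to convert CO2 elimination
#' into oxygen consumption, and the linearized slope of the blood CO2
#' dissociation curve used by the capnodynamic lung model.
#'
#' @param huefner_capacity ml O2 per g hemoglobin at full saturation.
#' @param o2_solubility ml O2 per L blood per mmHg of oxygen tension.
#' @param barometric_pressure ambient pressure, mmHg.
#' @param water_vapor_pressure saturated water vapor pressure at body
#'   temperature, mmHg.
#' @param odc_p50 oxygen tension at 50 percent hemoglobin saturation,
#'   mmHg.  The default is the native P50 of the Severinghaus human-blood
#'   curve; porcine blood is right-shifted (see [porcine_constants()]).
#' @param respiratory_quotient dimensionless VCO2/VO2 ratio.
#' @param odc_model `"severinghaus"` (default) or `"hill"`.
#' @param hill_n Hill coefficient, used only when `odc_model = "hill"`.
#' @param co2_blood_slope linearized slope of blood CO2 content versus
#'   alveolar CO2 fraction, ml CO2 per L blood per unit fraction.  The
#'   default corresponds to about 5 ml L^-1 mmHg^-1 around a normal
#'   alveolar CO2 tension.
#'
#' @return A list of class `physio_constants`.
#' @export
#' @examples
#' k <- physio_constants()
#' oxygen_content(130, 0.97, 90, k)
physio_constants <- function(huefner_capacity = 1.34,
                             o2_solubility = 0.03,
                             barometric_pressure = 760,
                             water_vapor_pressure = 47,
                             odc_p50 = NULL,
                             respiratory_quotient = 0.97,
                             odc_model = c("severinghaus", "hill"),
                             hill_n = 2.7,
                             co2_blood_slope = 3565) {
  odc_model <- match.arg(odc_model)
  if (is.null(odc_p50)) {
    odc_p50 <- if (odc_model == "severinghaus") .sev_p50 else 26.86
  }
  k <- list(
    huefner_capacity = huefner_capacity,
    o2_solubility = o2_solubility,
    barometric_pressure = barometric_pressure,
    water_vapor_pressure = water_vapor_pressure,
    odc_p50 = odc_p50,
    respiratory_quotient = respiratory_quotient,
    odc_model = odc_model,
    hill_n = hill_n,
    co2_blood_slope = co2_blood_slope
  )
  class(k) <- "physio_constants"
  validate_constants(k)
  k
}

#' @rdname physio_constants
#' @param ... further arguments passed to `physio_constants()`.
#' @details `porcine_constants()` is the same set with a right-shifted
#'   P50 (35 mmHg), reflecting the lower hemoglobin-oxygen affinity of
#'   pig blood.
#' @export
porcine_constants <- function(...) {
  physio_constants(odc_p50 = 35, ...)
}

validate_constants <- function(k) {
  num <- c("huefner_capacity", "o2_solubility", "barometric_pressure",
           "water_vapor_pressure", "odc_p50", "respiratory_quotient",
           "hill_n", "co2_blood_slope")
  for (f in num) {
    v <- k[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("constant '", f, "' must be a single positive number", call. = FALSE)
    }
  }
  if (k$respiratory_quotient <= 0.6 || k$respiratory_quotient >= 1.3) {
    stop("respiratory_quotient must lie in (0.6, 1.3)", call. = FALSE)
  }
  if (k$odc_p50 <= 15 || k$odc_p50 >= 50) {
    stop("odc_p50 must lie in (15, 50) mmHg", call. = FALSE)
  }
  invisible(k)
}

# Native P50 of the Severinghaus curve: the PO2 where
# (x^3 + 150 x) / (x^3 + 150 x + 23400) = 0.5, i.e. x^3 + 150 x = 23400.
.sev_cubic_root <- function(K) {
  # one real root of x^3 + 150 x - K = 0 (discriminant always positive)
  disc <- sqrt(K^2 / 4 + 125000)
  a <- K / 2 + disc
  b <- K / 2 - disc
  sign(a) * abs(a)^(1 / 3) + sign(b) * abs(b)^(1 / 3)
}
.sev_p50 <- .sev_cubic_root(23400)

#' Oxygen-hemoglobin dissociation curve
#'
#' `odc_saturation()` maps oxygen tension to hemoglobin saturation and
#' `odc_po2()` is its exact inverse.  The default is the Severinghaus
#' human-blood formulation, rescaled so that its P50 equals
#' `constants$odc_p50`; a Hill curve with configurable coefficient is
#' available via `odc_model = "hill"`.  Both are strictly monotone, so
#' `odc_saturation(odc_po2(s)) == s` to numerical precision.
#'
#' @param po2 oxygen tension, mmHg (vectorized, >= 0).
#' @param sat saturation fraction in (0, 1) (vectorized).
#' @param constants a [physio_constants()] object.
#' @return Saturation fraction in `[0, 1)`, or oxygen tension in mmHg.
#' @export
#' @examples
#' k <- physio_constants()
#' odc_saturation(k$odc_p50, k)  # 0.5 by definition of P50
odc_saturation <- function(po2, constants = physio_constants()) {
  if (any(po2 < 0)) stop("po2 must be >= 0", call. = FALSE)
  if (constants$odc_model == "severinghaus") {
    x <- po2 * (.sev_p50 / constants$odc_p50)
    q <- x^3 + 150 * x
    q / (q + 23400)
  } else {
    x <- (po2 / constants$odc_p50)^constants$hill_n
    x / (1 + x)
  }
}

#' @rdname odc_saturation
#' @export
odc_po2 <- function(sat, constants = physio_constants()) {
  if (any(sat <= 0) || any(sat >= 1)) {
    stop("odc_po2 is defined for saturations strictly inside (0, 1)",
         call. = FALSE)
  }
  if (constants$odc_model == "severinghaus") {
    K <- 23400 * sat / (1 - sat)
    x <- .sev_cubic_root(K)
    x * (constants$odc_p50 / .sev_p50)
  } else {
    constants$odc_p50 * (sat / (1 - sat))^(1 / constants$hill_n)
  }
}

#' Oxygen content of blood
#'
#' Hemoglobin-bound plus physically dissolved oxygen:
#' `hb * huefner * sat + solubility * po2`, in ml O2 per L blood.
#'
#' @param hb hemoglobin, g per L.
#' @param sat hemoglobin saturation fraction in `[0, 1]`.
#' @param po2 oxygen tension, mmHg.
#' @param constants a [physio_constants()] object.
#' @return Oxygen content, ml O2 per L blood.
#' @export
oxygen_content <- function(hb, sat, po2, constants = physio_constants()) {
  if (any(hb < 0) || any(po2 < 0)) {
    stop("hb and po2 must be non-negative", call. = FALSE)
  }
  if (any(sat < 0) || any(sat > 1)) {
    stop("sat must lie in [0, 1]", call. = FALSE)
  }
  hb * constants$huefner_capacity * sat + constants$o2_solubility * po2
}

#' Alveolar oxygen tension from the alveolar gas equation
#'
#' `fio2 * (Pb - PH2O) - paco2 / RQ`.  A non-positive result indicates a
#' non-physiologic regime (e.g. extreme hypercapnia at low FiO2); the
#' value is returned as-is so the caller can decide how to handle it.
#'
#' @param fio2 inspired oxygen fraction in `[0.21, 1]`.
#' @param paco2 alveolar CO2 tension, mmHg.
#' @param constants a [physio_constants()] object.
#' @return Alveolar oxygen tension, mmHg.
#' @export
alveolar_po2 <- function(fio2, paco2, constants = physio_constants()) {
  if (any(fio2 < 0.21 - 1e-9) || any(fio2 > 1 + 1e-9)) {
    stop("fio2 must lie in [0.21, 1]", call. = FALSE)
  }
  if (any(paco2 < 0)) stop("paco2 must be >= 0", call. = FALSE)
  fio2 * (constants$barometric_pressure - constants$water_vapor_pressure) -
    paco2 / constants$respiratory_quotient
}

#' Invert oxygen content to hemoglobin saturation
#'
#' Solves `cvo2 = hb * huefner * s + solubility * po2(s)` for the
#' saturation `s`, where `po2(s)` follows the dissociation curve.  When
#' `po2_cap` is supplied the dissolved term is capped at that tension
#' (physically, venous PO2 cannot exceed the alveolar PO2 that
#' equilibrated the blood).  Contents at or below zero return a
#' saturation of 0 and contents at or above the capped maximum return 1:
#' the capnodynamic method clamps rather than fails in extreme states,
#' which is why transient zeros appear after circulatory arrest.
#'
#' @param cvo2 oxygen content, ml O2 per L blood (vectorized).
#' @param hb hemoglobin, g per L (scalar or same length as `cvo2`).
#' @param constants a [physio_constants()] object.
#' @param po2_cap optional maximum oxygen tension for the dissolved term,
#'   mmHg (scalar or vectorized).  `Inf` disables the cap.
#' @return Saturation fraction in `[0, 1]`.
#' @export
saturation_from_content <- function(cvo2, hb, constants = physio_constants(),
                                    po2_cap = Inf) {
  if (any(hb <= 0)) stop("hb must be > 0", call. = FALSE)
  n <- length(cvo2)
  hb <- rep_len(hb, n)
  po2_cap <- rep_len(po2_cap, n)
  bind <- hb * constants$huefner_capacity
  sol <- constants$o2_solubility

  s <- pmin(pmax(cvo2 / bind, 1e-9), 1 - 1e-9)
  out <- numeric(n)
  lo_mask <- cvo2 <= 0
  hi_mask <- is.finite(po2_cap) & (cvo2 >= bind + sol * po2_cap)
  active <- !(lo_mask | hi_mask)
  out[lo_mask] <- 0
  out[hi_mask] <- 1

  if (any(active)) {
    sa <- s[active]
    ca <- cvo2[active]
    ba <- bind[active]
    pa <- po2_cap[active]
    # fixed-point iteration: the dissolved term is a small, bounded
    # perturbation, so this contracts rapidly except at the extremes
    converged <- FALSE
    for (it in 1:60) {
      po2 <- pmin(odc_po2(pmin(pmax(sa, 1e-9), 1 - 1e-9), constants), pa)
      s_new <- pmin(pmax((ca - sol * po2) / ba, 1e-9), 1 - 1e-9)
      if (max(abs(s_new - sa)) < 1e-13) {
        sa <- s_new
        converged <- TRUE
        break
      }
      sa <- s_new
    }
    if (!converged) {
      # fall back to bracketed root-finding on the stragglers
      f <- function(sv, cv, bv, pv) {
        bv * sv + sol * min(odc_po2(sv, constants), pv) - cv
      }
      for (i in seq_along(sa)) {
        lo <- 1e-9; hi <- 1 - 1e-9
        flo <- f(lo, ca[i], ba[i], pa[i])
        fhi <- f(hi, ca[i], ba[i], pa[i])
        if (flo >= 0) { sa[i] <- 0 } else if (fhi <= 0) { sa[i] <- 1 } else {
          sa[i] <- stats::uniroot(f, c(lo, hi), cv = ca[i], bv = ba[i],
                                  pv = pa[i], tol = 1e-12)$root
        }
      }
    }
    out[active] <- sa
  }
  pmin(pmax(out, 0), 1)
}
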