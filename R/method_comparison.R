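# Agreement and trending statistics for SvO2 monitors: inherent
# precision, least significant change, Bland-Altman corrected for
# repeated measurements, and four-quadrant concordance.

#' Inherent precision of repeated measurements
#'
#' Two times the coefficient of variation (CV = SD / mean, with the
#' n - 1 SD) of repeated measurements taken under stable conditions,
#' expressed in percent.
#'
#' @param repeats numeric vector of at least two repeated measurements,
#'   all positive.
#' @return Precision in percent.
#' @export
#' @examples
#' inherent_precision(c(60, 62, 58, 61, 59))
inherent_precision <- function(repeats) {
  if (length(repeats) < 2L) stop("need at least two repeats", call. = FALSE)
  m <- mean(repeats)
  if (m <= 0) stop("mean of repeats must be > 0", call. = FALSE)
  2 * stats::sd(repeats) / m * 100
}

#' Least significant change
#'
#' The smallest relative change a method can distinguish from its own
#' measurement noise: `precision * sqrt(2)`, conventionally reported
#' rounded to the nearest integer percent.
#'
#' @param precision inherent precision, percent (>= 0).
#' @param rounded report rounded to the nearest integer percent
#'   (default), or the raw value.
#' @return LSC in percent.
#' @export
#' @examples
#' least_significant_change(11)  # 16
least_significant_change <- function(precision, rounded = TRUE) {
  if (any(precision < 0)) stop("precision must be >= 0", call. = FALSE)
  lsc <- precision * sqrt(2)
  if (rounded) round(lsc) else lsc
}

#' Bland-Altman analysis corrected for repeated measurements
#'
#' Agreement between a test and a reference method when each subject
#' contributes multiple paired measurements and the true value varies
#' within subjects.  Bias is the mean of all paired differences; the
#' total variance of differences is decomposed by one-way variance
#' components (between-subject plus within-subject, from the
#' unequal-group-size ANOVA identity) and the 95% limits of agreement
#' are `bias +/- 1.96 * SD_total`.  Confidence intervals: the bias CI
#' uses the between-subject mean square (t, k - 1 df); the LoA CIs use
#' the standard large-sample approximation combining the bias SE with
#' the SD uncertainty.
#'
#' With a single subject the function falls back to a simple
#' Bland-Altman analysis and flags the result.
#'
#' @param test,reference paired measurements (same units, e.g. SvO2 in
#'   percentage points).
#' @param animal_id subject identifier for each pair.
#' @return A list of class `svo2_agreement`: `bias`, `loa_low`,
#'   `loa_high`, `bias_ci`, `loa_low_ci`, `loa_high_ci`, `sd_total`,
#'   `var_between`, `var_within`, `n_pairs`, `n_animals`, `variant`.
#' @export
bland_altman_repeated <- function(test, reference, animal_id) {
  n <- length(test)
  stopifnot(length(reference) == n, length(animal_id) == n)
  keep <- stats::complete.cases(test, reference, animal_id)
  d <- (test - reference)[keep]
  id <- factor(animal_id[keep])
  N <- length(d)
  if (N < 2L) stop("need at least two pairs", call. = FALSE)
  k <- nlevels(id)
  bias <- mean(d)

  if (k < 2L) {
    sd_tot <- stats::sd(d)
    se_bias <- sd_tot / sqrt(N)
    se_loa <- sd_tot * sqrt(1 / N + 1.96^2 / (2 * (N - 1)))
    tq <- stats::qt(0.975, N - 1)
    res <- list(bias = bias, loa_low = bias - 1.96 * sd_tot,
                loa_high = bias + 1.96 * sd_tot,
                bias_ci = bias + c(-1, 1) * tq * se_bias,
                loa_low_ci = bias - 1.96 * sd_tot + c(-1, 1) * tq * se_loa,
                loa_high_ci = bias + 1.96 * sd_tot + c(-1, 1) * tq * se_loa,
                sd_total = sd_tot, var_between = NA_real_,
                var_within = sd_tot^2, n_pairs = N, n_animals = k,
                variant = "simple")
    class(res) <- "svo2_agreement"
    warning("single subject: falling back to simple Bland-Altman",
            call. = FALSE)
    return(res)
  }

  ni <- as.numeric(table(id))
  gm <- tapply(d, id, mean)
  ssb <- sum(ni * (gm[levels(id)] - bias)^2)
  ssw <- sum((d - gm[id])^2)
  msb <- ssb / (k - 1)
  msw <- ssw / (N - k)
  n0 <- (N - sum(ni^2) / N) / (k - 1)
  var_b <- max(0, (msb - msw) / n0)
  var_tot <- var_b + msw
  sd_tot <- sqrt(var_tot)

  se_bias <- sqrt(msb / N)
  tq <- stats::qt(0.975, k - 1)
  # SD uncertainty approximated on the within-subject df
  se_loa <- sqrt(se_bias^2 + 1.96^2 * var_tot / (2 * (N - k)))
  res <- list(
    bias = bias,
    loa_low = bias - 1.96 * sd_tot,
    loa_high = bias + 1.96 * sd_tot,
    bias_ci = bias + c(-1, 1) * tq * se_bias,
    loa_low_ci = bias - 1.96 * sd_tot + c(-1, 1) * 1.96 * se_loa,
    loa_high_ci = bias + 1.96 * sd_tot + c(-1, 1) * 1.96 * se_loa,
    sd_total = sd_tot, var_between = var_b, var_within = msw,
    n_pairs = N, n_animals = k, variant = "repeated"
  )
  class(res) <- "svo2_agreement"
  res
}

#' @export
print.svo2_agreement <- function(x, ...) {
  cat(sprintf("Bland-Altman (%s): bias %+0.1f, LoA %0.1f to %0.1f\n",
              x$variant, x$bias, x$loa_low, x$loa_high))
  cat(sprintf("  bias 95%% CI %0.1f to %0.1f; LoA CIs [%0.1f, %0.1f] / [%0.1f, %0.1f]\n",
              x$bias_ci[1], x$bias_ci[2], x$loa_low_ci[1], x$loa_low_ci[2],
              x$loa_high_ci[1], x$loa_high_ci[2]))
  cat(sprintf("  %d pairs from %d subjects\n", x$n_pairs, x$n_animals))
  invisible(x)
}

#' Select intervention extremes and form change pairs
#'
#' For each animal and intervention, the recordings at the designated
#' extremes (the `pre` and `post` slots, e.g. FiO2 0.3 versus 1.0, or
#' just before versus after retransfusion) are paired and differenced,
#' producing one change value per animal, intervention and method.
#' Animals missing either slot for an intervention contribute nothing
#' for it.
#'
#' @param recordings recording data frame with columns `animal_id`,
#'   `phase`, `slot`, `t_s`, `method`, `svo2_pct`.  If `slot` is
#'   absent, the first and last recording time within each phase are
#'   used as the extremes.
#' @param interventions phases to difference; defaults to every phase
#'   that has both slots, excluding `"baseline"`.
#' @return A data frame `animal_id`, `phase`, `method`, `delta`
#'   (post minus pre, percentage points).
#' @export
select_intervention_extremes <- function(recordings, interventions = NULL) {
  r <- recordings
  if (!"slot" %in% names(r)) {
    r$slot <- stats::ave(r$t_s, r$animal_id, r$phase, r$method,
                         FUN = function(t) {
                           s <- rep("mid", length(t))
                           s[which.min(t)] <- "pre"
                           s[which.max(t)] <- "post"
                           s
                         })
  }
  r <- r[r$slot %in% c("pre", "post"), ]
  if (is.null(interventions)) {
    interventions <- setdiff(unique(r$phase), "baseline")
  }
  r <- r[r$phase %in% interventions, ]
  if (nrow(r) == 0L) {
    return(data.frame(animal_id = character(0), phase = character(0),
                      method = character(0), delta = numeric(0)))
  }
  key <- interaction(r$animal_id, r$phase, r$method, drop = TRUE)
  parts <- split(r, key)
  out <- lapply(parts, function(g) {
    pre <- g$svo2_pct[g$slot == "pre"]
    post <- g$svo2_pct[g$slot == "post"]
    if (length(pre) != 1L || length(post) != 1L) return(NULL)
    data.frame(animal_id = g$animal_id[1L], phase = g$phase[1L],
               method = g$method[1L], delta = post - pre,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

#' Four-quadrant concordance rate with an exclusion zone
#'
#' Pairs whose reference change lies inside the exclusion zone (derived
#' from the reference method's least significant change, in percentage
#' points) are dropped; the concordance rate is the percentage of the
#' retained pairs in which both methods changed in the same direction.
#' The 95% CI is a Wilson score interval.
#'
#' @param delta_test,delta_reference paired change values, percentage
#'   points.
#' @param exclusion_zone half-width of the exclusion zone, percentage
#'   points (>= 0); only `|delta_reference| > exclusion_zone` pairs are
#'   retained.
#' @return A list of class `svo2_concordance`: `n_outside`,
#'   `n_concordant`, `rate` (percent), `rate_ci`, `exclusion_zone`.
#'   With no retained pairs `rate` is `NA`.
#' @export
concordance <- function(delta_test, delta_reference, exclusion_zone = 0) {
  stopifnot(length(delta_test) == length(delta_reference))
  if (exclusion_zone < 0) stop("exclusion_zone must be >= 0", call. = FALSE)
  keep <- !is.na(delta_test) & !is.na(delta_reference) &
    abs(delta_reference) > exclusion_zone
  n_out <- sum(keep)
  if (n_out == 0L) {
    res <- list(n_outside = 0L, n_concordant = 0L, rate = NA_real_,
                rate_ci = c(NA_real_, NA_real_),
                exclusion_zone = exclusion_zone)
    class(res) <- "svo2_concordance"
    return(res)
  }
  conc <- sum(sign(delta_test[keep]) == sign(delta_reference[keep]))
  res <- list(
    n_outside = n_out,
    n_concordant = conc,
    rate = 100 * conc / n_out,
    rate_ci = 100 * wilson_ci(conc, n_out),
    exclusion_zone = exclusion_zone
  )
  class(res) <- "svo2_concordance"
  res
}

#' @export
print.svo2_concordance <- function(x, ...) {
  if (is.na(x$rate)) {
    cat("Concordance: no pairs outside the exclusion zone\n")
  } else {
    cat(sprintf(
      "Concordance: %d/%d = %0.0f%% (95%% CI %0.0f-%0.0f%%), zone %0.0f points\n",
      x$n_concordant, x$n_outside, x$rate, x$rate_ci[1], x$rate_ci[2],
      x$exclusion_zone))
  }
  invisible(x)
}

# Wilson score interval for a binomial proportion (no continuity
# correction), returned as a fraction.
wilson_ci <- function(x, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  mid <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, mid - half), min(1, mid + half))
}

#' Full method-comparison report for a recording table
#'
#' Runs the complete statistical analysis on a three-modality recording
#' table: per-method inherent precision from the baseline repeats, the
#' reference method's least significant change and the derived
#' exclusion zone, Bland-Altman (repeated measurements) of each test
#' method against the reference, and four-quadrant concordance of the
#' intervention change pairs.
#'
#' @param recordings data frame with columns `animal_id`, `phase`,
#'   `slot` (optional), `t_s`, `method`, `svo2_pct`.
#' @param reference reference method name (default `"co_oximetry"`).
#' @param baseline_phase phase holding the stable repeated baseline
#'   readings used for precision.
#' @param exclusion_zone override for the concordance exclusion zone in
#'   percentage points; by default it is the reference LSC (percent)
#'   times the mean baseline reference SvO2, rounded to integer points.
#' @param interventions phases used for the change-pair analysis (see
#'   [select_intervention_extremes()]).
#' @return A list of class `svo2_comparison`: `precision` (per-method,
#'   percent), `lsc`, `lsc_raw`, `exclusion_zone`, `agreement` (one
#'   [bland_altman_repeated()] result per test method), `concordance`
#'   (one [concordance()] result per test method), `deltas`, `pairs`.
#' @export
compare_methods <- function(recordings, reference = "co_oximetry",
                            baseline_phase = "baseline",
                            exclusion_zone = NULL, interventions = NULL) {
  need <- c("animal_id", "phase", "t_s", "method", "svo2_pct")
  miss <- setdiff(need, names(recordings))
  if (length(miss)) {
    stop("recordings are missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  methods <- unique(recordings$method)
  if (!reference %in% methods) {
    stop("no rows for reference method '", reference, "'", call. = FALSE)
  }
  tests <- setdiff(methods, reference)

  # per-animal precision from the baseline repeats, averaged over animals
  bl <- recordings[recordings$phase == baseline_phase, ]
  precision <- sapply(methods, function(m) {
    x <- bl[bl$method == m, ]
    per <- tapply(x$svo2_pct, x$animal_id, function(v) {
      v <- v[!is.na(v)]
      if (length(v) >= 2L && mean(v) > 0) inherent_precision(v) else NA_real_
    })
    mean(unlist(per), na.rm = TRUE)
  })

  lsc_raw <- least_significant_change(precision[[reference]], rounded = FALSE)
  lsc <- round(lsc_raw)
  if (is.null(exclusion_zone)) {
    mean_ref_bl <- mean(bl$svo2_pct[bl$method == reference])
    exclusion_zone <- round(lsc_raw / 100 * mean_ref_bl)
  }

  # paired absolute values: same animal, phase and timestamp
  ref_rows <- recordings[recordings$method == reference, ]
  pairs <- do.call(rbind, lapply(tests, function(m) {
    t_rows <- recordings[recordings$method == m, ]
    mg <- merge(t_rows, ref_rows,
                by = c("animal_id", "phase", "t_s"),
                suffixes = c("_test", "_ref"))
    if (nrow(mg) == 0L) return(NULL)
    data.frame(animal_id = mg$animal_id, phase = mg$phase, t_s = mg$t_s,
               method = m, test = mg$svo2_pct_test,
               reference = mg$svo2_pct_ref, stringsAsFactors = FALSE)
  }))

  agreement <- lapply(stats::setNames(tests, tests), function(m) {
    p <- pairs[pairs$method == m, ]
    bland_altman_repeated(p$test, p$reference, p$animal_id)
  })

  deltas <- select_intervention_extremes(recordings, interventions)
  conc <- lapply(stats::setNames(tests, tests), function(m) {
    dt <- deltas[deltas$method == m, ]
    dr <- deltas[deltas$method == reference, ]
    mg <- merge(dt, dr, by = c("animal_id", "phase"),
                suffixes = c("_test", "_ref"))
    concordance(mg$delta_test, mg$delta_ref, exclusion_zone)
  })

  res <- list(precision = precision, lsc = lsc, lsc_raw = lsc_raw,
              exclusion_zone = exclusion_zone, reference = reference,
              agreement = agreement, concordance = conc,
              deltas = deltas, pairs = pairs)
  class(res) <- "svo2_comparison"
  res
}

#' @export
print.svo2_comparison <- function(x, ...) {
  cat("SvO2 method comparison (reference:", x$reference, ")\n")
  cat("Inherent precision (2 x CV, %):\n")
  for (m in names(x$precision)) {
    cat(sprintf("  %-12s %5.1f\n", m, x$precision[[m]]))
  }
  cat(sprintf("LSC (reference): %d%%; exclusion zone: %d points\n",
              x$lsc, x$exclusion_zone))
  for (m in names(x$agreement)) {
    cat(m, "vs", x$reference, "- ")
    print(x$agreement[[m]])
  }
  for (m in names(x$concordance)) {
    cat(m, "vs", x$reference, "- ")
    print(x$concordance[[m]])
  }
  invisible(x)
}
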