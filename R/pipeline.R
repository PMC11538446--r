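# Orchestration: simulate -> estimate -> compare with a flat key=value
# config, a seed recorded in every manifest, and CSV outputs.

#' Default run configuration
#'
#' Flat list of every tunable in the pipeline, grouped by dotted prefix:
#' `constants.*` (physiologic constants), `baseline.*` (virtual-animal
#' physiology), `measurement.*` (noise model), `analysis.*`
#' (method-comparison options), plus `n_animals` and `seed`.  The
#' configuration round-trips losslessly through
#' [write_run_config()] / [read_run_config()].
#'
#' @param seed integer seed (required for any simulation).
#' @param n_animals number of virtual animals.
#' @return A named list of class `run_config`.
#' @export
default_run_config <- function(seed = NULL, n_animals = 10) {
  k <- physio_constants()
  bl <- scenario_baseline()
  mm <- measurement_model()
  cfg <- c(
    list(seed = seed, n_animals = n_animals),
    stats::setNames(k[names(k) != "odc_model"],
                    paste0("constants.", names(k)[names(k) != "odc_model"])),
    list(constants.odc_model = k$odc_model),
    stats::setNames(bl, paste0("baseline.", names(bl))),
    stats::setNames(unclass(mm), paste0("measurement.", names(mm))),
    list(analysis.reference = "co_oximetry",
         analysis.exclusion_zone = NA,
         analysis.baseline_phase = "baseline")
  )
  class(cfg) <- "run_config"
  cfg
}

#' Read and write flat key=value configuration files
#'
#' One `key=value` pair per line; `#` starts a comment.  Numeric-looking
#' values are parsed as numbers, `TRUE`/`FALSE` as logicals, `NA` as
#' missing; everything else stays character.
#'
#' @param cfg a configuration list.
#' @param path file path.
#' @return `read_run_config()` returns a `run_config` list;
#'   `write_run_config()` returns `path` invisibly.
#' @export
write_run_config <- function(cfg, path) {
  fmt <- vapply(cfg, function(v) {
    if (is.null(v)) "NA"
    else if (is.numeric(v)) format(v, digits = 17)
    else as.character(v)
  }, character(1))
  writeLines(paste0(names(cfg), "=", fmt), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexpr("=", lines), invert = TRUE)
  keys <- vapply(kv, `[`, character(1), 1L)
  vals <- vapply(kv, `[`, character(1), 2L)
  parse1 <- function(v) {
    if (v == "NA") return(NA)
    if (v %in% c("TRUE", "FALSE")) return(as.logical(v))
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  }
  cfg <- stats::setNames(lapply(vals, parse1), trimws(keys))
  class(cfg) <- "run_config"
  cfg
}

cfg_section <- function(cfg, prefix) {
  pre <- paste0(prefix, ".")
  sel <- startsWith(names(cfg), pre)
  stats::setNames(cfg[sel], substring(names(cfg)[sel], nchar(pre) + 1L))
}

cfg_constants <- function(cfg) {
  s <- cfg_section(cfg, "constants")
  do.call(physio_constants, s)
}

cfg_baseline <- function(cfg) do.call(scenario_baseline, cfg_section(cfg, "baseline"))

cfg_measurement <- function(cfg) do.call(measurement_model, cfg_section(cfg, "measurement"))

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  write_run_config(cfg, tmp)
  unname(tools::md5sum(tmp))
}

write_manifest <- function(out_dir, cfg, extra = character(0)) {
  lines <- c(
    paste0("seed=", cfg$seed),
    paste0("config_hash=", config_hash(cfg)),
    extra
  )
  writeLines(lines, file.path(out_dir, "manifest.txt"))
}

#' Simulate the virtual experiment and write its CSV outputs
#'
#' Writes `truth.csv` (hemodynamic state per second), `breaths.csv`
#' (volumetric capnography), `recordings.csv` (the three SvO2 streams),
#' the resolved configuration (`config.txt`) and a manifest with the
#' seed and a configuration hash.  Reruns with the same configuration
#' produce byte-identical files.
#'
#' @param out_dir output directory (created if needed).
#' @param config a `run_config`; `config$seed` must be set.
#' @return Invisibly, the [simulate_experiment()] result.
#' @export
pipeline_simulate <- function(out_dir, config = default_run_config(seed = 1)) {
  if (is.null(config$seed) || is.na(config$seed)) {
    stop("config$seed must be set: simulations must be reproducible",
         call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_experiment(
    n_animals = config$n_animals, seed = config$seed,
    model = cfg_measurement(config), constants = cfg_constants(config),
    baseline = cfg_baseline(config)
  )
  wcsv <- function(df, f) utils::write.csv(df, file.path(out_dir, f),
                                           row.names = FALSE)
  wcsv(sim$truth, "truth.csv")
  wcsv(sim$breaths, "breaths.csv")
  wcsv(sim$recordings, "recordings.csv")
  write_run_config(config, file.path(out_dir, "config.txt"))
  write_manifest(out_dir, config)
  invisible(sim)
}

#' Run the capnodynamic estimator over a breaths CSV
#'
#' Validates the schema and time ordering (malformed input is rejected
#' with the offending row number) and writes one estimate row per
#' breath, warm-up rows flagged.
#'
#' @param breaths_csv input CSV with the breath-record schema.
#' @param out_csv output CSV path.
#' @param hb hemoglobin, g per L, used for the oxygen-content chain.
#' @param config a `run_config` (constants block).
#' @return Invisibly, the estimates data frame.
#' @export
pipeline_estimate <- function(breaths_csv, out_csv,
                              hb = scenario_baseline()$hb,
                              config = default_run_config(seed = 1)) {
  breaths <- utils::read.csv(breaths_csv, stringsAsFactors = FALSE)
  k <- cfg_constants(config)
  ids <- unique(breaths$animal_id)
  if (is.null(ids)) {
    est <- estimate_capno_svo2(breaths, hb = hb, constants = k)
  } else {
    est <- do.call(rbind, lapply(ids, function(id) {
      e <- estimate_capno_svo2(breaths[breaths$animal_id == id, ],
                               hb = hb, constants = k)
      e$animal_id <- id
      e
    }))
  }
  utils::write.csv(est, out_csv, row.names = FALSE)
  invisible(est)
}

#' Compare the three recording streams and write the report
#'
#' Runs [compare_methods()] on a recordings CSV and writes a
#' machine-readable key=value report (`report.txt`) plus tidy CSVs
#' backing the Bland-Altman (`bland_altman.csv`: pair means and
#' differences) and four-quadrant (`four_quadrant.csv`: paired deltas)
#' plots.
#'
#' @param recordings_csv input CSV with the recording schema.
#' @param out_dir output directory.
#' @param config a `run_config` (analysis block).
#' @return Invisibly, the [compare_methods()] result.
#' @export
pipeline_compare <- function(recordings_csv, out_dir,
                             config = default_run_config(seed = 1)) {
  rec <- utils::read.csv(recordings_csv, stringsAsFactors = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  zone <- config$analysis.exclusion_zone
  cmp <- compare_methods(
    rec, reference = config$analysis.reference,
    baseline_phase = config$analysis.baseline_phase,
    exclusion_zone = if (is.null(zone) || is.na(zone)) NULL else zone
  )

  kvs <- c(
    vapply(names(cmp$precision), function(m)
      paste0("precision.", m, "=", format(cmp$precision[[m]])), character(1)),
    paste0("lsc=", cmp$lsc),
    paste0("lsc_raw=", format(cmp$lsc_raw)),
    paste0("exclusion_zone=", cmp$exclusion_zone)
  )
  for (m in names(cmp$agreement)) {
    a <- cmp$agreement[[m]]
    kvs <- c(kvs,
      paste0("bias.", m, "=", format(a$bias)),
      paste0("loa_low.", m, "=", format(a$loa_low)),
      paste0("loa_high.", m, "=", format(a$loa_high)),
      paste0("loa_low_ci.", m, "=", paste(format(a$loa_low_ci), collapse = ",")),
      paste0("loa_high_ci.", m, "=", paste(format(a$loa_high_ci), collapse = ",")),
      paste0("n_pairs.", m, "=", a$n_pairs))
  }
  for (m in names(cmp$concordance)) {
    cc <- cmp$concordance[[m]]
    kvs <- c(kvs,
      paste0("concordance_rate.", m, "=", format(cc$rate)),
      paste0("concordance_n.", m, "=", cc$n_outside),
      paste0("concordance_ci.", m, "=", paste(format(cc$rate_ci), collapse = ",")))
  }
  writeLines(kvs, file.path(out_dir, "report.txt"))

  ba <- cmp$pairs
  if (!is.null(ba) && nrow(ba)) {
    ba$mean <- (ba$test + ba$reference) / 2
    ba$diff <- ba$test - ba$reference
    utils::write.csv(ba, file.path(out_dir, "bland_altman.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(cmp$deltas, file.path(out_dir, "four_quadrant.csv"),
                   row.names = FALSE)
  invisible(cmp)
}

#' Run the full pipeline end-to-end
#'
#' simulate -> estimate -> compare into one output directory.
#'
#' @param out_dir output directory.
#' @param config a `run_config` with `seed` set.
#' @return Invisibly, a list with the simulation and the comparison.
#' @export
pipeline_run <- function(out_dir, config = default_run_config(seed = 1)) {
  sim <- pipeline_simulate(out_dir, config)
  utils::write.csv(sim$estimates, file.path(out_dir, "estimates.csv"),
                   row.names = FALSE)
  cmp <- pipeline_compare(file.path(out_dir, "recordings.csv"), out_dir,
                          config)
  invisible(list(simulation = sim, comparison = cmp))
}
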