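# Shared fixture builders: constant-state scenarios, hand-built breath
# tables, and recording tables with known structure.

# steady hemodynamic state at a chosen true EPBF (no events)
constant_states <- function(epbf = 3.5, vo2 = 180, hb = 90, fio2 = 0.3,
                            shunt = 0.1, duration_s = 600,
                            constants = physio_constants()) {
  bl <- scenario_baseline(cardiac_output = epbf / (1 - shunt),
                          shunt_fraction = shunt, vo2 = vo2, hb = hb,
                          fio2 = fio2)
  run_scenario(events = default_scenario()[0, ], baseline = bl,
               constants = constants, duration_s = duration_s)
}

# minimal hand-built breath table
make_breaths <- function(vtco2, duration = 3, fet = 0.05, fio2 = 0.3) {
  n <- length(vtco2)
  duration <- rep_len(duration, n)
  data.frame(
    breath_index = seq_len(n),
    t_start_s = if (n) cumsum(c(0, duration[-n])) else numeric(0),
    duration_s = duration,
    breath_type = "normal",
    vt_ml = 300,
    vtco2_ml = vtco2,
    fet_co2 = rep_len(fet, n),
    fio2 = rep_len(fio2, n),
    stringsAsFactors = FALSE
  )
}

# recording table where each method reads a supplied function of time
make_recordings <- function(animals, plan, fns) {
  out <- list()
  for (a in animals) {
    for (m in names(fns)) {
      out[[paste(a, m)]] <- data.frame(
        animal_id = a, phase = plan$phase, slot = plan$slot, t_s = plan$t_s,
        method = m, svo2_pct = fns[[m]](plan$t_s), stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}
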