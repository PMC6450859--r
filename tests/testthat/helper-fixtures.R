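# Shared fixtures: a compact noise-free simulated subject is the workhorse
# for kinetics and indices tests. Cached per session because the RK4
# integration is the slow part.

default_protocol <- clamp_protocol()

fixture_subject <- function() subject("S01", "BAM", weight_kg = 90,
                                      height_cm = 175, vat_kg = 3.7,
                                      sat_kg = 11, muscle_kg = 20)

.sim_cache <- new.env(parent = emptyenv())

fixture_sim <- function(noise = FALSE, seed = 101) {
  key <- paste0("sim_", noise, "_", seed)
  if (is.null(.sim_cache[[key]])) {
    set.seed(seed)
    .sim_cache[[key]] <- simulate_subject(fixture_subject(),
                                          default_protocol,
                                          simulation_truth(), noise = noise)
  }
  .sim_cache[[key]]
}

# hand-built series: linear channels, known GIR steps
fixture_series_linear <- function() {
  t <- c(-30, -20, -10, 0, 30, 60, 90, 100, 110, 120, 150, 180, 210, 220,
         230, 240)
  sample_series(
    t = t,
    glucose_mmol_l = rep(5, length(t)),
    insulin_pmol_l = 50 + 0.5 * (t + 30),
    nefa_mmol_l = rep(0.5, length(t)),
    glucose_ttr = rep(0.0125, length(t)),
    glycerol_umol_l = rep(70, length(t)),
    glycerol_ttr = ifelse(t <= 120, 0.0485, NA_real_),
    gir = data.frame(t = c(0, 120), rate_mg_kg_min = c(2, 4))
  )
}
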