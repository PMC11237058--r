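# shared fixtures, built in code at test time

glu <- "C5H9NO4"
gsh <- "C10H17N3O6S"

# simulate one scenario and observe it on the default 25-injection schedule
observe_scenario <- function(scenario, seed, t_max = 84, n_inj = 25,
                             tracer = "13C15N", background = NULL, ...) {
  inj <- seq(0, t_max, length.out = n_inj)
  grid <- sort(unique(c(seq(0, t_max, by = 0.5), inj)))
  cfg <- simulation_config(scenario, seed = seed, tracer = tracer, ...)
  tc <- simulate_timecourse(build_transaminase_system(cfg), grid)
  observe_injection_series(tc, cfg, injection_times_hr = inj,
                           drop_empty = FALSE, background = background)
}

run_scenario <- function(scenario, seed = 1, t_max = 84, by = 0.5, ...) {
  cfg <- simulation_config(scenario, seed = seed, ...)
  simulate_timecourse(build_transaminase_system(cfg), seq(0, t_max, by = by))
}

# brute-force self-convolution of an isotopologue pool (independent oracle)
brute_force_dipeptide <- function(shifts, fractions) {
  acc <- list()
  for (i in seq_along(shifts)) {
    for (j in seq_along(shifts)) {
      k <- as.character(shifts[i] + shifts[j])
      acc[[k]] <- (acc[[k]] %||% 0) + fractions[i] * fractions[j]
    }
  }
  out <- unlist(acc)
  out[order(as.numeric(names(out)))]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
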