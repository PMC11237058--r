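test_that("label-transition rules follow transamination chemistry", {
  sys <- build_transaminase_system(simulation_config("active"))
  sp <- sys$species
  # D5-Glu (alpha-D) donor yields D4-aKG: alpha-deuterium lost to solvent
  g_d5 <- which(sp$metabolite == "Glu" & sp$nD == 5 & sp$n13C == 0 & sp$n15N == 0)
  j <- match(g_d5, sys$glu_i)
  akg_col <- which(sys$stoich[sys$akg_i, j] > 0)
  expect_identical(sp$nD[sys$akg_i[akg_col]], 4L)
  # dual-label donor: aKG gains 13C5, Asp gains 15N
  g_cn <- which(sp$metabolite == "Glu" & sp$n13C == 5 & sp$n15N == 1 & sp$nD == 0)
  j <- match(g_cn, sys$glu_i)
  akg_col <- which(sys$stoich[sys$akg_i, j] > 0)
  asp_col <- which(sys$stoich[sys$asp_i, j] > 0)
  expect_identical(sp$n13C[sys$akg_i[akg_col]], 5L)
  expect_identical(sp$n15N[sys$asp_i[asp_col]], 1L)
  # re-aminated glutamate never carries alpha-D
  for (k in seq_len(nrow(sys$rev_pairs))) {
    col <- length(sys$glu_i) + k
    glu_prod <- intersect(which(sys$stoich[, col] > 0), sys$glu_i)
    expect_false(sp$alphaD[glu_prod])
  }
})

test_that("interventions set the enzyme schedule", {
  sys <- build_transaminase_system(simulation_config("active"))
  expect_identical(apply_intervention(sys, "filtered")$E(10), 0)
  expect_identical(apply_intervention(sys, "active")$E(10), sys$E0)
  aoa <- apply_intervention(sys, "AOA")
  expect_equal(aoa$E(0), sys$E0)
  expect_lt(aoa$E(1), 1e-6)
  expect_error(apply_intervention(sys, "boiled"))
})

test_that("no enzyme means frozen concentrations and zero events", {
  tc <- run_scenario("filtered", t_max = 24)
  expect_equal(max(abs(sweep(tc$conc, 2, tc$conc[1, ]))), 0, tolerance = 1e-12)
  expect_equal(max(tc$true_cycle_events), 0, tolerance = 1e-12)
})

test_that("tracer conservation and deuterium monotonicity hold", {
  for (scn in c("active", "AOA")) {
    tc <- run_scenario(scn, t_max = 84)
    tt <- tracer_totals(tc)
    expect_lt(max(abs(tt$c13_skeletons_uM / tt$c13_skeletons_uM[1] - 1)), 1e-8)
    expect_lt(max(abs(tt$n15_uM / tt$n15_uM[1] - 1)), 1e-8)
  }
  tcd <- run_scenario("active", tracer = "D5", t_max = 84)
  ad <- tracer_totals(tcd)$alpha_d_uM
  expect_true(all(diff(ad) <= 1e-10))
  expect_lt(ad[length(ad)], ad[1])
})

test_that("clamped symmetric exchange matches the closed-form solution", {
  # equal buffered acceptor pools make Glu-skeleton <-> aKG-skeleton exchange
  # an exactly linear two-pool system: x(t) = x_inf + (x0 - x_inf) e^(-2kt)
  ini <- c(glu_unlabeled = 100, glu_tracer = 0, akg = 0, oaa = 1000, asp = 1000)
  k <- 1e-4
  cfg <- simulation_config("active", initial_uM = ini, k_fwd = k, k_rev = k,
                           clamp_acceptors = TRUE)
  tc <- simulate_timecourse(build_transaminase_system(cfg), seq(0, 24, by = 0.5))
  glu_tot <- rowSums(tc$conc[, tc$species$metabolite == "Glu"])
  rate <- k * 1000
  analytic <- 50 + 50 * exp(-2 * rate * tc$time)
  expect_lt(max(abs(glu_tot - analytic)), 1e-6)
  # approaching the 50/50 partition of the symmetric exchange
  expect_equal(glu_tot[length(glu_tot)], 50, tolerance = 0.02)
})

test_that("pseudo-first-order decay rate is recovered from noisy data", {
  # large buffered acceptor pool, forward-only: D5-Glu decays ~ exp(-k*E*OAA*t)
  ini <- c(glu_unlabeled = 82, glu_tracer = 82, akg = 0, oaa = 5000, asp = 0)
  kf <- 2e-5
  cfg <- simulation_config("active", tracer = "D5", initial_uM = ini,
                           k_fwd = kf, k_rev = 0, clamp_acceptors = TRUE)
  tc <- simulate_timecourse(build_transaminase_system(cfg), seq(0, 24, by = 1))
  d5 <- species_concentration(tc, "Glu", nD = 5)
  set.seed(7)
  obs <- d5 * stats::rlnorm(length(d5), 0, 0.01)  # 1% noise CV
  fit <- stats::lm(log(obs) ~ tc$time)
  expect_equal(unname(-stats::coef(fit)[2]), kf * 5000, tolerance = 0.05)
})

test_that("scenario ordering preserves the tracer: filtered ~ AOA > active", {
  d5_left <- vapply(c("active", "filtered", "AOA"), function(scn) {
    tc <- run_scenario(scn, tracer = "D5", t_max = 24)
    species_concentration(tc, "Glu", nD = 5)[49]
  }, numeric(1))
  expect_gt(d5_left[["filtered"]], d5_left[["active"]])
  expect_gt(d5_left[["AOA"]], d5_left[["active"]])
  # AOA with fast onset leaves D5-Glu within 2% of its initial value
  expect_gt(d5_left[["AOA"]], 0.98 * 82)
  expect_identical(d5_left[["filtered"]], 82)
})

test_that("label-based cycling estimate is a lower bound with known edge cases", {
  tc0 <- run_scenario("filtered", t_max = 24)
  est0 <- label_based_cycle_estimate(tc0)
  expect_identical(est0$estimate_uM, 0)
  expect_equal(est0$true_events_uM, 0, tolerance = 1e-12)
  # forward-only: events accumulate but no singly labeled Glu can form
  tcf <- run_scenario("active", t_max = 24, k_rev = 0)
  estf <- label_based_cycle_estimate(tcf)
  expect_equal(estf$estimate_uM, 0, tolerance = 1e-9)
  expect_gt(estf$true_events_uM, 0)
  # default active run: strict underestimation
  tca <- run_scenario("active", t_max = 24)
  esta <- label_based_cycle_estimate(tca)
  expect_gt(esta$estimate_uM, 0)
  expect_lt(esta$estimate_uM, esta$true_events_uM)
})

test_that("solver errors on negative concentrations from oversized steps", {
  cfg <- simulation_config("active", k_fwd = 50, k_rev = 50,
                           solver_step_hr = 1)
  expect_error(simulate_timecourse(build_transaminase_system(cfg),
                                   seq(0, 10, by = 1)),
               "step too large")
  expect_error(simulate_timecourse(build_transaminase_system(
    simulation_config("active")), c(1, 2)), "start at 0")
})

test_that("observation model is deterministic, scaled and complete", {
  inj <- seq(0, 84, length.out = 25)
  grid <- sort(unique(c(seq(0, 84, by = 0.5), inj)))
  cfg <- simulation_config("active", seed = 11)
  tc <- simulate_timecourse(build_transaminase_system(cfg), grid)
  s1 <- observe_injection_series(tc, cfg, inj)
  s2 <- observe_injection_series(tc, cfg, inj)
  expect_identical(s1$table, s2$table)  # same seed, same table
  expect_identical(length(unique(s1$table$injection_index)), 25L)
  expect_true(all(s1$table$area >= 0))
  # noiseless limit: areas exactly proportional to concentrations
  cfg0 <- simulation_config("active", seed = 11, noise_cv = 0,
                            mass_error_ppm_sd = 0, rt_jitter_sd_min = 0)
  s0 <- observe_injection_series(tc, cfg0, inj)
  tracer_rows <- s0$table[s0$table$feature_id == "Glu[13C5,15N]", ]
  conc <- stats::approx(tc$time, species_concentration(tc, "Glu", 5, 1),
                        xout = inj)$y
  expect_equal(tracer_rows$area, conc * 1e4, tolerance = 1e-12)
  expect_equal(tracer_rows$mz, rep(ion_mz(glu, label_spec(n_13C = 5, n_15N = 1)),
                                   25), tolerance = 1e-12)
})

test_that("background catalogue drifts only under enzyme activity", {
  bg <- background_features(n = 40, seed = 5)
  act <- observe_scenario("active", seed = 1, background = bg)
  fil <- observe_scenario("filtered", seed = 2, background = bg)
  aoa <- observe_scenario("AOA", seed = 3, background = bg)
  cv0 <- function(s, id) {
    a <- s$table$area[s$table$feature_id == id]
    stats::sd(a) / mean(a)
  }
  drifting <- bg$feature_id[bg$drifting & bg$drift_log10 > 0.5][1]
  expect_gt(cv0(act, drifting), 3 * cv0(fil, drifting))
  expect_gt(cv0(act, drifting), 3 * cv0(aoa, drifting))
  # catalogue identity shared across scenarios
  expect_identical(act$features$feature_id, fil$features$feature_id)
})

test_that("MS2 fixture generator plants exactly the configured conjugates", {
  recs <- generate_ms2_fixtures(n_conjugates = 14, n_decoys = 0, seed = 3)
  expect_length(recs, 14)
  frag_in <- vapply(recs, function(r) {
    any(abs(ppm_delta(r$fragments$mz, 308.0912)) <= 10)
  }, logical(1))
  expect_true(all(frag_in))
  # planted error bounded by the generator parameter
  errs <- vapply(recs, function(r) {
    min(abs(ppm_delta(r$fragments$mz, 308.0912)))
  }, numeric(1))
  expect_true(all(errs <= 5))
  none <- generate_ms2_fixtures(n_conjugates = 0, n_decoys = 30, seed = 4)
  frag_in <- vapply(none, function(r) {
    any(abs(ppm_delta(r$fragments$mz, 308.0912)) <= 10)
  }, logical(1))
  expect_false(any(frag_in))
})
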