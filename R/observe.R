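#' Observe a time course as a repeat-injection LC-MS series
#'
#' Samples the simulated concentrations at the injection times and applies
#' the LC-MS observation model: peak area = concentration x per-feature
#' response factor x multiplicative lognormal noise (unit mean, CV from
#' the config); observed m/z = theoretical [M-H]- m/z x (1 + eps * 1e-6)
#' with eps ~ Normal(0, ppm sd); observed RT = canonical RT +/- jitter.
#' Output is reproducible under the config seed.
#'
#' @param tc a `timecourse` from [simulate_timecourse()]. Its time grid
#'   must cover the injection times (values are linearly interpolated).
#' @param config a [simulation_config()]; its `seed`, `noise_cv`,
#'   `mass_error_ppm_sd` and `rt_jitter_sd_min` drive the observation.
#' @param injection_times_hr injection schedule; default 25 injections
#'   evenly spaced over 0-84 hr (every 3.5 hr).
#' @param response_factor area counts per uM, a single value or a vector
#'   named by species id.
#' @param drop_empty drop species whose concentration never exceeds
#'   1e-9 uM (never-populated label states).
#' @param background optional [background_features()] catalogue of
#'   untargeted matrix features with protein-dependent drift. Pass the
#'   same catalogue to every scenario you intend to compare: the
#'   catalogue fixes each feature's identity and drift parameters, while
#'   the realized drift amplitude is scaled by the scenario's mean
#'   enzyme activity (1 in active, 0 when filtered, ~0 under AOA).
#' @return Object of class `injection_series`: a list with `table` (long
#'   data frame: feature_id, mz, rt_min, injection_index, time_hr, area),
#'   `features` (metadata: feature_id, formula, label columns, true m/z,
#'   observed m/z), `injection_times_hr` and `seed`.
#' @export
observe_injection_series <- function(tc, config,
                                     injection_times_hr = seq(0, 84, length.out = 25),
                                     response_factor = 1e4,
                                     drop_empty = TRUE,
                                     background = NULL) {
  stopifnot(inherits(tc, "timecourse"), inherits(config, "simulation_config"))
  if (any(diff(injection_times_hr) <= 0)) {
    stop("injection times must be strictly increasing", call. = FALSE)
  }
  if (max(injection_times_hr) > max(tc$time) + 1e-9) {
    stop("timecourse does not cover the injection schedule", call. = FALSE)
  }
  sp <- tc$species
  keep <- if (drop_empty) apply(tc$conc, 2, max) > 1e-9 else rep(TRUE, ncol(tc$conc))
  sp <- sp[keep, , drop = FALSE]
  conc <- tc$conc[, keep, drop = FALSE]
  n_inj <- length(injection_times_hr)

  # concentration at each injection time (linear interpolation on the grid)
  at_inj <- vapply(seq_len(nrow(sp)), function(j) {
    stats::approx(tc$time, conc[, j], xout = injection_times_hr)$y
  }, numeric(n_inj))

  theo_mz <- vapply(seq_len(nrow(sp)), function(j) {
    ion_mz(sp$formula[j],
           label_spec(n_13C = sp$n13C[j], n_15N = sp$n15N[j],
                      n_D = sp$nD[j], alpha_D = sp$alphaD[j]))
  }, numeric(1))

  feats <- data.frame(feature_id = sp$species_id, formula = sp$formula,
                      n13C = sp$n13C, n15N = sp$n15N, nD = sp$nD,
                      alphaD = sp$alphaD, theoretical_mz = theo_mz,
                      rt_min = sp$rt_min, stringsAsFactors = FALSE)

  if (!is.null(background)) {
    stopifnot(inherits(background, "background_features"))
    # realized drift scales with the scenario's mean enzyme activity
    E0 <- tc$system$E0
    act <- if (E0 <= 0) 0 else {
      tf <- seq(0, max(injection_times_hr), length.out = 200)
      mean(vapply(tf, tc$system$E, numeric(1))) / E0
    }
    bg_conc <- vapply(seq_len(nrow(background)), function(j) {
      b <- background[j, ]
      drift <- b$drift_sign * b$drift_log10 * act *
        (1 - exp(-injection_times_hr / b$tau_hr))
      b$c0_uM * 10^drift
    }, numeric(n_inj))
    at_inj <- cbind(at_inj, bg_conc)
    theo_mz <- c(theo_mz, background$mz)
    feats <- rbind(feats, data.frame(
      feature_id = background$feature_id, formula = NA_character_,
      n13C = 0L, n15N = 0L, nD = 0L, alphaD = FALSE,
      theoretical_mz = background$mz, rt_min = background$rt_min,
      stringsAsFactors = FALSE))
  }
  n_feat <- nrow(feats)

  rf <- if (length(response_factor) == 1L) {
    rep(response_factor, n_feat)
  } else {
    rf <- response_factor[feats$feature_id]
    if (anyNA(rf)) stop("response_factor must name every feature", call. = FALSE)
    rf
  }

  set.seed(config$seed)
  sdlog <- sqrt(log(1 + config$noise_cv^2))
  noise <- matrix(stats::rlnorm(n_inj * n_feat, meanlog = -sdlog^2 / 2,
                                sdlog = sdlog), n_inj, n_feat)
  if (config$noise_cv == 0) noise[] <- 1
  areas <- at_inj * matrix(rf, n_inj, n_feat, byrow = TRUE) * noise
  eps_ppm <- stats::rnorm(n_feat, 0, config$mass_error_ppm_sd)
  obs_mz <- theo_mz * (1 + eps_ppm * 1e-6)
  rt_obs <- matrix(feats$rt_min, n_inj, n_feat, byrow = TRUE) +
    matrix(stats::rnorm(n_inj * n_feat, 0, config$rt_jitter_sd_min), n_inj, n_feat)

  tab <- data.frame(
    feature_id = rep(feats$feature_id, each = n_inj),
    mz = rep(obs_mz, each = n_inj),
    rt_min = as.numeric(rt_obs),
    injection_index = rep(seq_len(n_inj), n_feat),
    time_hr = rep(injection_times_hr, n_feat),
    area = as.numeric(areas),
    stringsAsFactors = FALSE
  )
  feats$observed_mz <- obs_mz
  structure(list(table = tab, features = feats,
                 injection_times_hr = injection_times_hr,
                 scenario = tc$system$scenario, seed = config$seed),
            class = "injection_series")
}

#' @export
print.injection_series <- function(x, ...) {
  cat("<injection_series> ", nrow(x$features), " features x ",
      length(x$injection_times_hr), " injections (", x$scenario,
      " scenario, seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Synthetic catalogue of untargeted matrix features
#'
#' Emulates the breadth of an untargeted feature table: `n` background
#' features with random m/z, retention time and baseline concentration,
#' of which a fraction drift over time when protein is present. Each
#' drifting feature follows
#' `c(t) = c0 * 10^(sign * amplitude * a * (1 - exp(-t / tau)))`, where
#' `a` is the scenario's mean enzyme activity (so drift vanishes in
#' filtered extracts and under immediate inhibition). The catalogue is a
#' property of the sample matrix, not of a run: build it once and pass
#' the same object to [observe_injection_series()] for every scenario.
#'
#' @param n number of background features (default 300, the scale of an
#'   untargeted post-filter table).
#' @param frac_drifting fraction given a protein-dependent drift
#'   (default 0.9).
#' @param seed RNG seed for the catalogue.
#' @param amplitude_log10 range of drift amplitudes (log10 units).
#' @param tau_hr range of drift time constants (hours).
#' @return Data frame of class `background_features`: feature_id, mz,
#'   rt_min, c0_uM, drifting, drift_sign, drift_log10, tau_hr.
#' @export
background_features <- function(n = 300, frac_drifting = 0.9, seed = 1L,
                                amplitude_log10 = c(0.2, 1.2),
                                tau_hr = c(5, 40)) {
  stopifnot(n >= 1, frac_drifting >= 0, frac_drifting <= 1)
  set.seed(seed)
  drifting <- stats::runif(n) < frac_drifting
  out <- data.frame(
    feature_id = sprintf("bg_%03d", seq_len(n)),
    mz = stats::runif(n, 80, 800),
    rt_min = stats::runif(n, 1, 14),
    c0_uM = 10^stats::runif(n, -1, 2),
    drifting = drifting,
    drift_sign = ifelse(stats::runif(n) < 0.5, -1, 1) * as.integer(drifting),
    drift_log10 = stats::runif(n, amplitude_log10[1], amplitude_log10[2]) *
      as.integer(drifting),
    tau_hr = stats::runif(n, tau_hr[1], tau_hr[2]),
    stringsAsFactors = FALSE
  )
  class(out) <- c("background_features", class(out))
  out
}

#' Assemble a feature matrix from injection series
#'
#' Binds one or more injection series (e.g. active and filtered runs of
#' the same system) into a features x samples area matrix with sample
#' metadata, the container used by the drift statistics.
#'
#' @param series a single `injection_series` or a named list of them;
#'   names become group labels.
#' @return Object of class `feature_matrix`: list with `areas` (features
#'   x samples matrix), `samples` (sample_id, group, injection_index,
#'   time_hr) and `features` metadata.
#' @export
as_feature_matrix <- function(series) {
  if (inherits(series, "injection_series")) {
    series <- stats::setNames(list(series), series$scenario)
  }
  if (is.null(names(series)) || any(!nzchar(names(series)))) {
    names(series) <- vapply(series, function(s) s$scenario, character(1))
  }
  ids <- lapply(series, function(s) s$features$feature_id)
  common <- Reduce(intersect, ids)
  if (!length(common)) stop("series share no features", call. = FALSE)
  blocks <- lapply(names(series), function(g) {
    s <- series[[g]]
    tab <- s$table
    m <- matrix(NA_real_, length(common), length(s$injection_times_hr),
                dimnames = list(common, NULL))
    for (f in common) {
      rows <- tab[tab$feature_id == f, ]
      m[f, rows$injection_index] <- rows$area
    }
    colnames(m) <- paste0(g, "_inj", seq_len(ncol(m)))
    list(areas = m,
         samples = data.frame(sample_id = colnames(m), group = g,
                              injection_index = seq_len(ncol(m)),
                              time_hr = s$injection_times_hr,
                              stringsAsFactors = FALSE))
  })
  areas <- do.call(cbind, lapply(blocks, `[[`, "areas"))
  samples <- do.call(rbind, lapply(blocks, `[[`, "samples"))
  rownames(samples) <- NULL
  feats <- series[[1]]$features
  feats <- feats[match(common, feats$feature_id), , drop = FALSE]
  feature_matrix(areas, samples, feats)
}

#' Feature matrix container
#'
#' @param areas features x samples numeric matrix of peak areas (>= 0),
#'   rownames = feature ids.
#' @param samples data frame of per-sample metadata with at least
#'   `sample_id`; rows match matrix columns.
#' @param features optional data frame of per-feature metadata with
#'   `feature_id` matching the rownames.
#' @return Object of class `feature_matrix`.
#' @export
feature_matrix <- function(areas, samples, features = NULL) {
  areas <- as.matrix(areas)
  if (any(areas < 0, na.rm = TRUE)) stop("negative peak areas", call. = FALSE)
  if (nrow(samples) != ncol(areas)) {
    stop("samples rows must match area columns", call. = FALSE)
  }
  if (!is.null(features) && !all(rownames(areas) %in% features$feature_id)) {
    stop("feature metadata must cover all matrix rows", call. = FALSE)
  }
  if ("group" %in% names(samples) && "injection_index" %in% names(samples)) {
    dup <- any(duplicated(samples[c("group", "injection_index")]))
    if (dup) stop("injection order must be unique within group", call. = FALSE)
  }
  structure(list(areas = areas, samples = samples, features = features),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("<feature_matrix> ", nrow(x$areas), " features x ", ncol(x$areas),
      " samples\n", sep = "")
  if ("group" %in% names(x$samples)) {
    cat("  groups:", paste(unique(x$samples$group), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Generate MS2 fixture spectra with planted glutathione conjugates
#'
#' Emits `n_conjugates` precursors whose fragment lists contain the
#' diagnostic glutathione fragment (default m/z 308.0912, positive mode)
#' with a small planted ppm error, plus `n_decoys` precursors whose
#' fragments are kept well away from it. Ground truth is retained in the
#' record field `is_conjugate` so screening can be scored.
#'
#' @param n_conjugates,n_decoys numbers of planted and decoy precursors.
#' @param fragment_mz diagnostic fragment m/z.
#' @param max_fragment_ppm_error planted fragment mass error is uniform
#'   in +/- this many ppm.
#' @param decoy_exclusion_ppm decoy fragments are kept at least this far
#'   (ppm) from `fragment_mz`.
#' @param seed RNG seed.
#' @return List of `ms2_record` objects (see [ms2_record()]).
#' @export
generate_ms2_fixtures <- function(n_conjugates = 14, n_decoys = 50,
                                  fragment_mz = 308.0912,
                                  max_fragment_ppm_error = 2,
                                  decoy_exclusion_ppm = 50,
                                  seed = 1L) {
  set.seed(seed)
  n <- n_conjugates + n_decoys
  is_conj <- rep(c(TRUE, FALSE), c(n_conjugates, n_decoys))
  prec <- stats::runif(n, fragment_mz + 10, 650)
  rt <- stats::runif(n, 1, 14)
  records <- vector("list", n)
  for (i in seq_len(n)) {
    nf <- sample(5:15, 1)
    fmz <- stats::runif(nf, 50, prec[i] - 1)
    # keep random fragments out of the diagnostic window
    near <- abs(ppm_delta(fmz, fragment_mz)) < decoy_exclusion_ppm
    while (any(near)) {
      fmz[near] <- stats::runif(sum(near), 50, prec[i] - 1)
      near <- abs(ppm_delta(fmz, fragment_mz)) < decoy_exclusion_ppm
    }
    int <- stats::rlnorm(nf, log(1e4), 1)
    if (is_conj[i]) {
      err <- stats::runif(1, -max_fragment_ppm_error, max_fragment_ppm_error)
      fmz <- c(fmz, fragment_mz * (1 + err * 1e-6))
      int <- c(int, stats::rlnorm(1, log(1e5), 0.5))
    }
    o <- order(fmz)
    records[[i]] <- ms2_record(
      precursor_mz = prec[i], rt_min = rt[i],
      fragments = data.frame(mz = fmz[o], intensity = int[o]),
      id = sprintf("%s_%02d", if (is_conj[i]) "conjugate" else "decoy", i),
      is_conjugate = is_conj[i])
  }
  records
}

#' MS2 record
#'
#' A fragment spectrum tied to a precursor ion.
#'
#' @param precursor_mz precursor m/z.
#' @param rt_min retention time, minutes.
#' @param fragments data frame with columns `mz` and `intensity`;
#'   fragment m/z must be below precursor m/z + 1 and intensities >= 0.
#' @param id record identifier.
#' @param is_conjugate optional ground-truth flag (synthetic fixtures).
#' @return Object of class `ms2_record`.
#' @export
ms2_record <- function(precursor_mz, rt_min, fragments, id = NA_character_,
                       is_conjugate = NA) {
  stopifnot(is.data.frame(fragments), all(c("mz", "intensity") %in% names(fragments)))
  if (any(fragments$mz >= precursor_mz + 1)) {
    stop("fragment m/z must be below precursor m/z + 1", call. = FALSE)
  }
  if (any(fragments$intensity < 0)) stop("intensities must be >= 0", call. = FALSE)
  structure(list(precursor_mz = precursor_mz, rt_min = rt_min,
                 fragments = fragments, id = id, is_conjugate = is_conjugate),
            class = "ms2_record")
}

#' @export
print.ms2_record <- function(x, ...) {
  cat("<ms2_record> ", x$id, " precursor ", round_half_up(x$precursor_mz),
      " m/z, RT ", round(x$rt_min, 2), " min, ", nrow(x$fragments),
      " fragments\n", sep = "")
  invisible(x)
}

#' Simulate an extracted-ion chromatogram with planted Gaussian peaks
#'
#' @param peaks data frame with columns `apex_s` (apex time, seconds),
#'   `height` (apex intensity) and `sigma_s` (Gaussian width, seconds).
#' @param t_s time grid in seconds (default 0-600 at 1 s).
#' @param noise_sd additive baseline noise sd (counts), default 0.
#' @param precursor_mz,id optional trace metadata.
#' @param seed RNG seed (used when `noise_sd > 0`).
#' @return Object of class `chromatogram`: list with `time_s`,
#'   `intensity`, `precursor_mz`, `id`, and the planted `peaks`.
#' @export
simulate_chromatogram <- function(peaks, t_s = seq(0, 600, by = 1),
                                  noise_sd = 0, precursor_mz = NA_real_,
                                  id = NA_character_, seed = 1L) {
  stopifnot(all(c("apex_s", "height", "sigma_s") %in% names(peaks)))
  y <- numeric(length(t_s))
  for (i in seq_len(nrow(peaks))) {
    y <- y + peaks$height[i] *
      exp(-(t_s - peaks$apex_s[i])^2 / (2 * peaks$sigma_s[i]^2))
  }
  if (noise_sd > 0) {
    set.seed(seed)
    y <- pmax(y + stats::rnorm(length(t_s), 0, noise_sd), 0)
  }
  chromatogram(t_s, y, precursor_mz = precursor_mz, id = id, planted = peaks)
}

#' Chromatogram container
#'
#' @param time_s strictly increasing time in seconds.
#' @param intensity non-negative intensities, same length as `time_s`.
#' @param precursor_mz,id optional metadata.
#' @param planted optional data frame of planted ground-truth peaks.
#' @return Object of class `chromatogram`.
#' @export
chromatogram <- function(time_s, intensity, precursor_mz = NA_real_,
                         id = NA_character_, planted = NULL) {
  if (length(time_s) != length(intensity)) {
    stop("time and intensity must have equal length", call. = FALSE)
  }
  if (length(time_s) && any(diff(time_s) <= 0)) {
    stop("time must be strictly increasing", call. = FALSE)
  }
  if (any(intensity < 0)) stop("intensities must be >= 0", call. = FALSE)
  structure(list(time_s = time_s, intensity = intensity,
                 precursor_mz = precursor_mz, id = id, planted = planted),
            class = "chromatogram")
}
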