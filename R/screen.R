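#' Detect chromatographic peaks with width and intensity filters
#'
#' Finds local maxima in an extracted-ion chromatogram, delimits each
#' peak region, and retains peaks whose base width exceeds `min_width_s`
#' and whose apex intensity is at least `min_intensity` (the filters used
#' to count distinct conjugate peaks).
#'
#' Peak bounds: on each side of an apex the boundary is the nearer of
#' (a) the minimum of the trace between this apex and the adjacent
#' candidate apex and (b) the first point whose intensity falls below
#' `boundary_frac` x apex. With the default `boundary_frac = 0.05` the
#' width is a base width; `boundary_frac = 0.5` gives FWHM-style widths.
#'
#' @param xic a [chromatogram()].
#' @param min_width_s retain peaks with base width strictly greater than
#'   this (seconds).
#' @param min_intensity retain peaks with apex intensity >= this.
#' @param boundary_frac boundary threshold as a fraction of apex height.
#' @return Data frame of class `chrom_peaks`: `apex_s`,
#'   `apex_intensity`, `width_s`, `left_s`, `right_s`, sorted by apex
#'   time. Empty traces give an empty frame.
#' @export
detect_chrom_peaks <- function(xic, min_width_s = 6, min_intensity = 1e5,
                               boundary_frac = 0.05) {
  stopifnot(inherits(xic, "chromatogram"))
  t <- xic$time_s; y <- xic$intensity
  empty <- data.frame(apex_s = numeric(0), apex_intensity = numeric(0),
                      width_s = numeric(0), left_s = numeric(0),
                      right_s = numeric(0))
  class(empty) <- c("chrom_peaks", class(empty))
  n <- length(y)
  if (n < 3 || all(y == 0)) return(empty)
  # strict-left / non-strict-right local maxima (plateaus keep one apex)
  apex <- which(y[-c(1, n)] > y[-c(n - 1, n)] & y[-c(1, n)] >= y[-(1:2)]) + 1L
  apex <- apex[y[apex] > 0]
  if (!length(apex)) return(empty)

  bound <- function(i, a) {
    # i: apex index; a: +1 right / -1 left; limit: adjacent apex or trace end
    neighbors <- if (a > 0) apex[apex > i] else apex[apex < i]
    lim <- if (length(neighbors)) {
      adj <- if (a > 0) min(neighbors) else max(neighbors)
      seg <- if (a > 0) i:adj else adj:i
      seg[which.min(y[seg])]
    } else if (a > 0) n else 1L
    thr <- boundary_frac * y[i]
    j <- i
    while (j != lim && y[j + a] >= thr) j <- j + a
    j
  }
  left <- vapply(apex, bound, integer(1), a = -1L)
  right <- vapply(apex, bound, integer(1), a = 1L)
  out <- data.frame(apex_s = t[apex], apex_intensity = y[apex],
                    width_s = t[right] - t[left],
                    left_s = t[left], right_s = t[right])
  out <- out[out$width_s > min_width_s & out$apex_intensity >= min_intensity, ,
             drop = FALSE]
  out <- out[order(out$apex_s), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("chrom_peaks", class(out))
  out
}

#' Screen MS2 spectra for precursors carrying a diagnostic fragment
#'
#' Selects records containing a fragment within `fragment_tol_ppm` of
#' `fragment_mz` (default: the glutathione-conjugate diagnostic fragment
#' at m/z 308.0912), then groups the selected precursors by
#' single-linkage within `precursor_group_ppm` (isobaric grouping). When
#' XICs are supplied, each hit also reports the number of
#' chromatographic peaks passing [detect_chrom_peaks()] filters across
#' the XICs belonging to its precursor group.
#'
#' @param records list of [ms2_record()]s.
#' @param fragment_mz diagnostic fragment m/z.
#' @param fragment_tol_ppm fragment match tolerance (ppm).
#' @param precursor_group_ppm isobaric grouping tolerance (ppm,
#'   single-linkage).
#' @param xics optional list of [chromatogram()]s with `precursor_mz`
#'   set; matched to groups within `precursor_group_ppm`.
#' @param ... passed to [detect_chrom_peaks()].
#' @return Data frame of class `screen_hits`: `group_mz` (mean precursor
#'   m/z of the group), `n_records`, `example_rt_min`,
#'   `fragment_ppm_error` (smallest-|error| match in the group),
#'   `n_peaks` (NA without XICs), plus `record_ids`.
#' @export
fragment_precursor_screen <- function(records, fragment_mz = 308.0912,
                                      fragment_tol_ppm = 10,
                                      precursor_group_ppm = 2,
                                      xics = NULL, ...) {
  if (fragment_tol_ppm <= 0 || precursor_group_ppm <= 0) {
    stop("tolerances must be positive", call. = FALSE)
  }
  empty <- data.frame(group_mz = numeric(0), n_records = integer(0),
                      example_rt_min = numeric(0),
                      fragment_ppm_error = numeric(0), n_peaks = integer(0),
                      record_ids = character(0))
  class(empty) <- c("screen_hits", class(empty))
  if (!length(records)) return(empty)
  err <- lapply(records, function(r) {
    e <- ppm_delta(r$fragments$mz, fragment_mz)
    e[abs(e) <= fragment_tol_ppm]
  })
  hit <- lengths(err) > 0
  if (!any(hit)) return(empty)
  sel <- records[hit]
  best_err <- vapply(err[hit], function(e) e[which.min(abs(e))], numeric(1))
  pmz <- vapply(sel, `[[`, numeric(1), "precursor_mz")
  o <- order(pmz)
  # single-linkage in 1-D: break groups where the consecutive ppm gap exceeds tol
  gaps <- ppm_delta(pmz[o][-1], pmz[o][-length(pmz)])
  grp <- cumsum(c(1, gaps > precursor_group_ppm))
  rows <- lapply(split(seq_along(o), grp), function(ix) {
    idx <- o[ix]
    gm <- mean(pmz[idx])
    n_peaks <- NA_integer_
    if (!is.null(xics)) {
      xmz <- vapply(xics, `[[`, numeric(1), "precursor_mz")
      match_x <- which(abs(ppm_delta(xmz, gm)) <= precursor_group_ppm)
      n_peaks <- sum(vapply(xics[match_x], function(x) {
        nrow(detect_chrom_peaks(x, ...))
      }, integer(1)))
    }
    e <- best_err[idx]
    data.frame(group_mz = gm, n_records = length(idx),
               example_rt_min = sel[[idx[1]]]$rt_min,
               fragment_ppm_error = e[which.min(abs(e))],
               n_peaks = n_peaks,
               record_ids = paste(vapply(sel[idx], `[[`, character(1), "id"),
                                  collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$group_mz), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("screen_hits", class(out))
  out
}

#' Find coeluting light/heavy label pairs in a feature list
#'
#' All ordered pairs (light, heavy) of features whose m/z difference
#' matches `mass_shift_da` within a ppm tolerance (relative to the heavy
#' m/z) and whose retention times agree within `rt_tol_min`. This is how
#' an unknown drifting feature is recognized as the D4-labeled partner
#' of a known compound.
#'
#' @param features data frame with columns `mz`, `rt_min` and optionally
#'   `feature_id`, `area`.
#' @param mass_shift_da expected mass difference (e.g.
#'   `label_mass_shift(label_spec(n_D = 4))`).
#' @param mz_tol_ppm tolerance on the shift, ppm of the heavy m/z.
#' @param rt_tol_min coelution tolerance, minutes.
#' @return Data frame of pairs (`light_*`, `heavy_*` columns plus
#'   `shift_da`, `shift_error_ppm`, `delta_rt_min`), ordered by light
#'   m/z.
#' @export
find_label_pairs <- function(features, mass_shift_da, mz_tol_ppm = 5,
                             rt_tol_min = 0.1) {
  stopifnot(all(c("mz", "rt_min") %in% names(features)))
  if (!"feature_id" %in% names(features)) {
    features$feature_id <- sprintf("F%03d", seq_len(nrow(features)))
  }
  n <- nrow(features)
  out <- list()
  if (n >= 2) {
    idx <- expand.grid(light = seq_len(n), heavy = seq_len(n))
    idx <- idx[idx$light != idx$heavy, ]
    dmz <- features$mz[idx$heavy] - features$mz[idx$light]
    err_ppm <- 1e6 * (dmz - mass_shift_da) / features$mz[idx$heavy]
    drt <- features$rt_min[idx$heavy] - features$rt_min[idx$light]
    ok <- abs(err_ppm) <= mz_tol_ppm & abs(drt) <= rt_tol_min
    if (any(ok)) {
      li <- idx$light[ok]; hi <- idx$heavy[ok]
      out <- data.frame(
        light_id = features$feature_id[li], light_mz = features$mz[li],
        light_rt_min = features$rt_min[li],
        heavy_id = features$feature_id[hi], heavy_mz = features$mz[hi],
        heavy_rt_min = features$rt_min[hi],
        shift_da = dmz[ok], shift_error_ppm = err_ppm[ok],
        delta_rt_min = drt[ok], stringsAsFactors = FALSE)
      out <- out[order(out$light_mz, out$heavy_mz), , drop = FALSE]
      rownames(out) <- NULL
      return(out)
    }
  }
  data.frame(light_id = character(0), light_mz = numeric(0),
             light_rt_min = numeric(0), heavy_id = character(0),
             heavy_mz = numeric(0), heavy_rt_min = numeric(0),
             shift_da = numeric(0), shift_error_ppm = numeric(0),
             delta_rt_min = numeric(0), stringsAsFactors = FALSE)
}

#' Blank filter on feature means
#'
#' Retains features whose mean sample area is at least `min_ratio` times
#' the mean blank area (boundary inclusive); features absent from the
#' blank (mean 0) are kept whenever present in samples.
#'
#' @param sample_means,blank_means aligned per-feature mean areas; names
#'   of `sample_means` (if any) are used as feature ids.
#' @param min_ratio sample/blank ratio threshold (default 3, a
#'   conventional choice).
#' @return Retained feature ids (names or indices).
#' @export
blank_filter <- function(sample_means, blank_means, min_ratio = 3) {
  if (length(sample_means) != length(blank_means)) {
    stop("sample and blank vectors must align", call. = FALSE)
  }
  keep <- ifelse(blank_means > 0,
                 sample_means >= min_ratio * blank_means,
                 sample_means > 0)
  ids <- names(sample_means) %||% seq_along(sample_means)
  ids[keep]
}
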