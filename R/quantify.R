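#' Fit an internal-standard calibration curve
#'
#' Ordinary least-squares line of the ISTD area ratio on known
#' concentration, the standard single-ISTD calibration used to
#' interpolate endogenous concentrations. Weighted fits (1/x, 1/x^2) are
#' available through `weighting` but are off by default.
#'
#' @param standards data frame with columns `known_uM` and `ratio`
#'   (peak-area ratio, e.g. 13C ISTD to unlabeled compound or vice
#'   versa), one row per standard; at least 3 standards spanning at
#'   least 2 distinct concentrations.
#' @param analyte,istd identifiers stored with the model.
#' @param weighting `"none"`, `"1/x"` or `"1/x2"`; zero-concentration
#'   standards get unit weight under the reciprocal schemes.
#' @return Object of class `calibration_model`: slope, intercept, r
#'   squared, standard range and the standards used.
#' @export
fit_calibration <- function(standards, analyte = NA_character_,
                            istd = NA_character_,
                            weighting = c("none", "1/x", "1/x2")) {
  stopifnot(is.data.frame(standards),
            all(c("known_uM", "ratio") %in% names(standards)))
  weighting <- match.arg(weighting)
  x <- standards$known_uM; y <- standards$ratio
  if (length(x) < 3) stop("need at least 3 standards", call. = FALSE)
  if (length(unique(x)) < 2) {
    stop("degenerate design: all standard concentrations equal", call. = FALSE)
  }
  w <- switch(weighting,
              none = rep(1, length(x)),
              `1/x` = ifelse(x > 0, 1 / x, 1),
              `1/x2` = ifelse(x > 0, 1 / x^2, 1))
  fit <- stats::lm(y ~ x, weights = w)
  # noiseless standards are legitimate: silence lm's perfect-fit warning
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2, analyte = analyte, istd = istd,
                 weighting = weighting,
                 range_uM = range(x), standards = standards),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat("<calibration_model> ", if (!is.na(x$analyte)) paste0(x$analyte, " "),
      "ratio = ", signif(x$slope, 6), " * uM + ", signif(x$intercept, 6),
      "  (R2 = ", signif(x$r_squared, 6), ", n = ", nrow(x$standards), ")\n",
      sep = "")
  invisible(x)
}

#' Interpolate a concentration from a calibration model
#'
#' Inverts the fitted line: `(ratio - intercept) / slope`. Ratios that
#' interpolate below zero are clamped to 0 and flagged; ratios outside
#' the standard range are flagged as extrapolated.
#'
#' @param model a [fit_calibration()] model; slope must be positive.
#' @param ratio observed area ratio(s).
#' @return A `quant_result` data frame: analyte, concentration_uM,
#'   method, flags (`clamped`, `extrapolated`).
#' @export
concentration_from_ratio <- function(model, ratio) {
  stopifnot(inherits(model, "calibration_model"))
  if (model$slope <= 0) {
    stop("calibration slope must be positive for interpolation", call. = FALSE)
  }
  conc <- (ratio - model$intercept) / model$slope
  clamped <- conc < 0
  if (any(clamped)) {
    warning("negative interpolated concentration clamped to 0", call. = FALSE)
    conc[clamped] <- 0
  }
  extrap <- conc < model$range_uM[1] | conc > model$range_uM[2]
  quant_result(analyte = model$analyte, concentration_uM = conc,
               method = "calibration", reference = model$istd,
               clamped = clamped, extrapolated = extrap)
}

#' Label-ratio quantitation against a reference pool
#'
#' The workaround for quantifying labeled species when the ISTD itself is
#' enzymatically interconverted: concentration = (labeled area /
#' unlabeled area) x mean endogenous concentration of the unlabeled
#' compound measured in a protein-free reference (filtered) sample set.
#' Scale-invariant in the areas.
#'
#' @param labeled_area,unlabeled_area peak areas; `unlabeled_area` must
#'   be positive.
#' @param reference_endogenous_uM mean endogenous concentration (uM) of
#'   the unlabeled compound in the reference samples.
#' @param analyte identifier.
#' @return A `quant_result` data frame with `method = "label_ratio"`.
#' @export
quantify_by_label_ratio <- function(labeled_area, unlabeled_area,
                                    reference_endogenous_uM,
                                    analyte = NA_character_) {
  if (any(unlabeled_area <= 0)) {
    stop("unlabeled area must be positive (undefined ratio)", call. = FALSE)
  }
  if (any(reference_endogenous_uM < 0)) {
    stop("reference concentration must be >= 0", call. = FALSE)
  }
  if (any(labeled_area < 0)) stop("areas must be >= 0", call. = FALSE)
  conc <- labeled_area / unlabeled_area * reference_endogenous_uM
  quant_result(analyte = analyte, concentration_uM = conc,
               method = "label_ratio", reference = "unlabeled pool",
               clamped = FALSE, extrapolated = FALSE)
}

#' Quantitation result container
#'
#' @param analyte analyte id.
#' @param concentration_uM concentration(s), uM (>= 0).
#' @param method `"calibration"` or `"label_ratio"`.
#' @param reference reference used (ISTD id or reference pool).
#' @param clamped,extrapolated logical flags.
#' @return Data frame of class `quant_result`.
#' @export
quant_result <- function(analyte, concentration_uM, method, reference = NA,
                         clamped = FALSE, extrapolated = FALSE) {
  stopifnot(all(concentration_uM >= 0), method %in% c("calibration", "label_ratio"))
  out <- data.frame(analyte = analyte, concentration_uM = concentration_uM,
                    method = method, reference = reference,
                    clamped = clamped, extrapolated = extrapolated,
                    stringsAsFactors = FALSE)
  class(out) <- c("quant_result", class(out))
  out
}

#' Tissue normalization of a concentration
#'
#' Converts a resuspension concentration (uM) to tissue-equivalent
#' content referenced to a standard tissue input:
#' `uM * solvent_mL * (reference_mg / sample_mg)` gives nmol per
#' reference tissue amount (default 40 mg). A documented unit-conversion
#' helper, not a separate quantitation method.
#'
#' @param concentration_uM concentration in the resuspension (uM).
#' @param sample_mg tissue mass extracted (mg).
#' @param solvent_mL resuspension volume (mL).
#' @param reference_mg reference tissue amount (mg), default 40.
#' @return nmol per `reference_mg` of tissue.
#' @export
tissue_normalize <- function(concentration_uM, sample_mg, solvent_mL,
                             reference_mg = 40) {
  if (any(sample_mg <= 0) || any(solvent_mL <= 0)) {
    stop("sample mass and solvent volume must be positive", call. = FALSE)
  }
  concentration_uM * solvent_mL * reference_mg / sample_mg
}

#' Tracer-atom molar balance table
#'
#' Sums skeleton-equivalents of a tracer element across metabolic
#' neighbors, per replicate: each molecule carrying the element's label
#' counts once regardless of how many atoms it carries (a [13C5]
#' skeleton is one unit; a doubly labeled [13C5,15N] species counts once
#' for 13C and once for 15N). The total per replicate is compared
#' against the known tracer input to demonstrate (or refute) molar
#' conservation after interconversion.
#'
#' @param quants data frame with columns `replicate`, `species`,
#'   `concentration_uM` and `tracer_units` (0 or 1 skeleton-equivalents
#'   per molecule for the chosen element; see [tracer_units()]).
#' @param element `"13C"` or `"15N"` (recorded in the output).
#' @param reference_input_uM known tracer input (uM), used for the
#'   deviation columns; NA skips them.
#' @return Object of class `balance_table`: `entries` (rows with
#'   `tracer_units > 0`), `totals` per replicate (with deviation from
#'   reference), `group_mean` total, `element`, `reference_input_uM`.
#' @export
mole_balance <- function(quants, element = c("13C", "15N"),
                         reference_input_uM = NA_real_) {
  element <- match.arg(element)
  need <- c("replicate", "species", "concentration_uM", "tracer_units")
  missing_cols <- setdiff(need, names(quants))
  if (length(missing_cols)) {
    stop("quants missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(quants$tracer_units)) {
    stop("tracer_units annotation missing (NA) for some species", call. = FALSE)
  }
  if (any(quants$concentration_uM < 0)) {
    stop("concentrations must be >= 0", call. = FALSE)
  }
  entries <- quants[quants$tracer_units > 0, , drop = FALSE]
  amount <- entries$concentration_uM * entries$tracer_units
  if (nrow(entries)) {
    totals <- stats::aggregate(list(total_uM = amount),
                               by = list(replicate = entries$replicate), sum)
  } else {
    totals <- data.frame(replicate = character(0), total_uM = numeric(0))
  }
  if (!is.na(reference_input_uM)) {
    totals$deviation_uM <- totals$total_uM - reference_input_uM
    totals$deviation_frac <- ifelse(reference_input_uM > 0,
                                    totals$deviation_uM / reference_input_uM, NA)
  }
  structure(list(entries = entries, totals = totals,
                 group_mean_uM = if (nrow(totals)) mean(totals$total_uM) else 0,
                 element = element, reference_input_uM = reference_input_uM),
            class = "balance_table")
}

#' @export
print.balance_table <- function(x, ...) {
  cat("<balance_table> element ", x$element, ", ", nrow(x$totals),
      " replicate(s), group mean total ", signif(x$group_mean_uM, 6), " uM",
      if (!is.na(x$reference_input_uM))
        paste0(" (reference input ", x$reference_input_uM, " uM)"),
      "\n", sep = "")
  invisible(x)
}

#' Skeleton-equivalent annotation for a label state
#'
#' 1 if the species carries the chosen tracer element's label (once per
#' molecule, however many atoms), else 0.
#'
#' @param labels a [label_spec()].
#' @param element `"13C"` or `"15N"`.
#' @return 0 or 1.
#' @export
tracer_units <- function(labels, element = c("13C", "15N")) {
  element <- match.arg(element)
  stopifnot(inherits(labels, "label_spec"))
  if (element == "13C") as.integer(labels$n_13C > 0) else as.integer(labels$n_15N > 0)
}
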