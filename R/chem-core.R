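#' Molecular formulas
#'
#' A molecular formula is a named integer vector of element counts
#' (elements C, H, N, O, S, P). Formulas can be given as a Hill-like
#' string (`"C5H9NO4"`, case-sensitive element symbols) or as a named
#' vector/list of counts.
#'
#' @param x a formula string such as `"C5H9NO4"`, a named numeric vector
#'   of element counts, or an existing `molform` object.
#' @return An object of class `molform`: named integer vector of counts.
#' @examples
#' molecular_formula("C5H9NO4")      # glutamate
#' molecular_formula(c(C = 10, H = 17, N = 3, O = 6, S = 1))  # glutathione
#' @export
molecular_formula <- function(x) {
  if (inherits(x, "molform")) return(x)
  if (is.character(x)) {
    stopifnot(length(x) == 1L)
    counts <- .parse_formula_string(x)
  } else if (is.numeric(x) || is.list(x)) {
    counts <- unlist(x)
    if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
      stop("element counts must be named", call. = FALSE)
    }
  } else {
    stop("cannot interpret formula of class ", paste(class(x), collapse = "/"),
         call. = FALSE)
  }
  bad <- setdiff(names(counts), .KNOWN_ELEMENTS)
  if (length(bad)) {
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("element counts must be non-negative integers", call. = FALSE)
  }
  counts <- counts[counts > 0]
  if (!length(counts)) stop("formula must contain at least one atom", call. = FALSE)
  # canonical element order (Hill-like: C, H, then alphabetical)
  ord <- intersect(c("C", "H", "N", "O", "P", "S"), names(counts))
  out <- as.integer(counts[ord])
  names(out) <- ord
  structure(out, class = "molform")
}

.parse_formula_string <- function(s) {
  s <- gsub("[[:space:]]", "", s)
  if (!nzchar(s)) stop("empty formula string", call. = FALSE)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", s)[[1]]
  toks <- regmatches(s, gregexpr("([A-Z][a-z]?)([0-9]*)", s))[[1]]
  if (sum(attr(m, "match.length")) != nchar(s)) {
    stop("cannot parse formula string: ", s, call. = FALSE)
  }
  el <- sub("[0-9]*$", "", toks)
  n <- sub("^[A-Za-z]+", "", toks)
  n <- ifelse(nzchar(n), as.numeric(n), 1)
  counts <- tapply(n, el, sum)
  stats::setNames(as.numeric(counts), names(counts))
}

#' @export
format.molform <- function(x, ...) {
  paste0(names(x), ifelse(unclass(x) > 1, unclass(x), ""), collapse = "")
}

#' @export
print.molform <- function(x, ...) {
  cat("<molecular formula> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Isotope label specification
#'
#' Counts of heavy-isotope substitutions on a molecule: `n_13C`
#' (12C -> 13C), `n_15N` (14N -> 15N) and `n_D` (H -> 2H), plus a single
#' position flag `alpha_D`, TRUE when one of the deuteriums sits on the
#' alpha-carbon of an amino acid. The alpha position is the only
#' position-specific chemistry the transamination model needs: that
#' deuterium is lost to solvent on deamination.
#'
#' @param n_13C,n_15N,n_D non-negative integer substitution counts.
#' @param alpha_D logical; requires `n_D >= 1`.
#' @return Object of class `label_spec`.
#' @examples
#' label_spec(n_D = 5, alpha_D = TRUE)       # D5-glutamate label
#' label_spec(n_13C = 5, n_15N = 1)          # [U-13C,15N] label
#' @export
label_spec <- function(n_13C = 0, n_15N = 0, n_D = 0, alpha_D = FALSE) {
  counts <- c(n_13C = n_13C, n_15N = n_15N, n_D = n_D)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("label counts must be non-negative integers", call. = FALSE)
  }
  if (isTRUE(alpha_D) && n_D < 1) {
    stop("alpha_D = TRUE requires n_D >= 1", call. = FALSE)
  }
  structure(list(n_13C = as.integer(n_13C), n_15N = as.integer(n_15N),
                 n_D = as.integer(n_D), alpha_D = isTRUE(alpha_D)),
            class = "label_spec")
}

#' @export
format.label_spec <- function(x, ...) {
  parts <- character(0)
  if (x$n_13C > 0) parts <- c(parts, paste0("13C", x$n_13C))
  if (x$n_15N > 0) parts <- c(parts, paste0("15N", if (x$n_15N > 1) x$n_15N else ""))
  if (x$n_D > 0) parts <- c(parts, paste0("D", x$n_D, if (x$alpha_D) "(alpha)" else ""))
  if (!length(parts)) parts <- "unlabeled"
  paste(parts, collapse = ",")
}

#' @export
print.label_spec <- function(x, ...) {
  cat("<label spec> ", format(x), "\n", sep = "")
  invisible(x)
}

.validate_labels <- function(formula, labels) {
  formula <- molecular_formula(formula)
  n_of <- function(el) if (el %in% names(formula)) formula[[el]] else 0L
  if (labels$n_13C > n_of("C")) {
    stop("n_13C (", labels$n_13C, ") exceeds formula carbon count (",
         n_of("C"), ")", call. = FALSE)
  }
  if (labels$n_15N > n_of("N")) {
    stop("n_15N (", labels$n_15N, ") exceeds formula nitrogen count (",
         n_of("N"), ")", call. = FALSE)
  }
  if (labels$n_D > n_of("H")) {
    stop("n_D (", labels$n_D, ") exceeds formula hydrogen count (",
         n_of("H"), ")", call. = FALSE)
  }
  invisible(formula)
}

#' Ion species for singly charged +/- H adducts
#'
#' Only the singly charged deprotonated (`"[M-H]-"`, negative mode) and
#' protonated (`"[M+H]+"`, positive mode) adducts are supported; anything
#' else is rejected rather than silently mishandled.
#'
#' @param adduct `"[M-H]-"` or `"[M+H]+"` (aliases `"M-H"`, `"M+H"`).
#' @param charge must be 1.
#' @return Object of class `ion_species`.
#' @export
ion_species <- function(adduct = c("[M-H]-", "[M+H]+", "M-H", "M+H"),
                        charge = 1L) {
  adduct <- match.arg(adduct)
  adduct <- c(`[M-H]-` = "[M-H]-", `[M+H]+` = "[M+H]+",
              `M-H` = "[M-H]-", `M+H` = "[M+H]+")[[adduct]]
  if (!identical(as.integer(charge), 1L)) {
    stop("only singly charged ions are supported", call. = FALSE)
  }
  structure(list(adduct = adduct,
                 polarity = if (adduct == "[M-H]-") "negative" else "positive",
                 charge = 1L),
            class = "ion_species")
}

#' Monoisotopic mass of a (labeled) molecule
#'
#' Sum of element counts times monoisotopic atomic masses, plus the label
#' shifts for 13C, 15N and 2H substitutions.
#'
#' @param formula molecular formula (string or [molecular_formula()]).
#' @param labels optional [label_spec()].
#' @return Neutral monoisotopic mass in Da (full precision).
#' @examples
#' monoisotopic_mass("C5H9NO4")                        # 147.0532 (glutamate)
#' monoisotopic_mass("C5H9NO4", label_spec(n_D = 5, alpha_D = TRUE))
#' @export
monoisotopic_mass <- function(formula, labels = label_spec()) {
  formula <- .validate_labels(formula, labels)
  base <- sum(.MONOISOTOPIC_MASS[names(formula)] * unclass(formula))
  base + label_mass_shift(labels)
}

#' Mass shift of a label specification
#'
#' Total mass added relative to the unlabeled molecule; additive and
#' linear in the substitution counts. The `alpha_D` flag does not change
#' the mass (it marks position, not count).
#'
#' @param labels a [label_spec()].
#' @return Shift in Da.
#' @examples
#' label_mass_shift(label_spec(n_D = 4))    # 4.0251 Da
#' label_mass_shift(label_spec(n_13C = 5))  # 5.0168 Da
#' @export
label_mass_shift <- function(labels) {
  stopifnot(inherits(labels, "label_spec"))
  labels$n_13C * .LABEL_SHIFT[["13C"]] +
    labels$n_15N * .LABEL_SHIFT[["15N"]] +
    labels$n_D * .LABEL_SHIFT[["2H"]]
}

#' m/z of a singly charged +/- H ion
#'
#' `[M-H]-` is M minus the proton mass 1.007276 Da and `[M+H]+` is M plus
#' it (the proton mass, i.e. the electron is accounted for). Values are
#' returned at full precision; report with [round_half_up()] at 4
#' decimals, the convention used throughout.
#'
#' @inheritParams monoisotopic_mass
#' @param ion an [ion_species()] (or adduct string accepted by it).
#' @return m/z in Th (= Da for charge 1), full precision.
#' @examples
#' round_half_up(ion_mz("C5H9NO4"))                       # 146.0459
#' round_half_up(ion_mz("C10H17N3O6S"))                   # 306.0765 (GSH)
#' @export
ion_mz <- function(formula, labels = label_spec(), ion = ion_species()) {
  if (is.character(ion)) ion <- ion_species(ion)
  stopifnot(inherits(ion, "ion_species"))
  m <- monoisotopic_mass(formula, labels)
  if (ion$adduct == "[M-H]-") m - .PROTON_MASS else m + .PROTON_MASS
}

#' Signed mass error in parts per million
#'
#' @param observed_mz,theoretical_mz m/z values; `theoretical_mz` must be
#'   positive.
#' @return `1e6 * (observed - theoretical) / theoretical`.
#' @export
ppm_delta <- function(observed_mz, theoretical_mz) {
  if (any(theoretical_mz <= 0)) {
    stop("theoretical m/z must be positive", call. = FALSE)
  }
  1e6 * (observed_mz - theoretical_mz) / theoretical_mz
}

#' Condense two formulas with loss of a small molecule
#'
#' Elementwise `a + b - loss`; the default loss is water, i.e. peptide-bond
#' style condensation (builds Glu-Glu from two glutamates).
#'
#' @param a,b,loss molecular formulas (strings accepted).
#' @return A `molform`.
#' @examples
#' condense_formulas("C5H9NO4", "C5H9NO4")  # C10H16N2O7, Glu-Glu
#' @export
condense_formulas <- function(a, b, loss = "H2O") {
  a <- molecular_formula(a); b <- molecular_formula(b)
  loss <- molecular_formula(loss)
  els <- union(union(names(a), names(b)), names(loss))
  get <- function(f) {
    v <- stats::setNames(numeric(length(els)), els)
    v[names(f)] <- unclass(f)
    v
  }
  res <- get(a) + get(b) - get(loss)
  if (any(res < 0)) {
    stop("condensation loss not contained in a + b", call. = FALSE)
  }
  molecular_formula(res[res > 0])
}

#' Isotopologue distributions
#'
#' A discrete distribution over nominal mass shifts (integer Da above the
#' unlabeled species, "M+n"), stored as a named numeric vector of
#' fractions summing to one.
#'
#' @param shifts integer mass shifts (>= 0), or a named numeric vector of
#'   fractions whose names are the shifts.
#' @param fractions fractions matching `shifts`; must sum to 1 (tolerance
#'   1e-9).
#' @return Object of class `isotopologue_distribution`.
#' @examples
#' isotopologue_distribution(c(0, 4, 5), c(0.5, 0.25, 0.25))
#' @export
isotopologue_distribution <- function(shifts, fractions = NULL) {
  if (is.null(fractions)) {
    fractions <- as.numeric(shifts)
    shifts <- as.numeric(names(shifts))
  }
  if (anyNA(shifts) || any(shifts < 0) || any(shifts != round(shifts))) {
    stop("shifts must be non-negative integers", call. = FALSE)
  }
  if (any(fractions < 0)) stop("fractions must be non-negative", call. = FALSE)
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop("fractions must sum to 1 (got ", format(sum(fractions)), ")",
         call. = FALSE)
  }
  o <- order(shifts)
  structure(stats::setNames(fractions[o], as.character(shifts[o])),
            class = "isotopologue_distribution")
}

#' @export
print.isotopologue_distribution <- function(x, ...) {
  cat("<isotopologue distribution>\n")
  print(stats::setNames(unclass(x), paste0("M+", names(x))))
  invisible(x)
}

#' Label distribution of a dipeptide drawn from a residue pool
#'
#' Distribution of the total nominal mass shift of a dipeptide whose two
#' residues are drawn independently from the same free pool: the discrete
#' self-convolution of the pool's isotopologue distribution. Used as the
#' null model for whether both residues of a dipeptide are sourced from
#' the free pool (e.g. whether Glu-Glu made from a ~50% deuterated free
#' glutamate pool should show M+8/M+9/M+10 species).
#'
#' @param pool an [isotopologue_distribution()] (or named fraction vector).
#' @return An `isotopologue_distribution` over summed shifts.
#' @examples
#' pool <- isotopologue_distribution(c(0, 4, 5), c(0.5, 0.25, 0.25))
#' d <- dipeptide_label_distribution(pool)
#' sum(d[c("8", "9", "10")])  # 0.25
#' @export
dipeptide_label_distribution <- function(pool) {
  if (!inherits(pool, "isotopologue_distribution")) {
    pool <- isotopologue_distribution(pool)
  }
  shifts <- as.numeric(names(pool))
  fr <- unclass(pool)
  sums <- outer(shifts, shifts, `+`)
  probs <- outer(fr, fr, `*`)
  agg <- tapply(as.numeric(probs), as.numeric(sums), sum)
  out <- as.numeric(agg) / sum(agg)  # renormalize against roundoff
  isotopologue_distribution(as.numeric(names(agg)), out)
}
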