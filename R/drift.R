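#' Spline trend test for one feature's injection series
#'
#' Fits a natural cubic regression spline (default df = 4) of
#' log10(area + 1) on time and F-tests it against the intercept-only
#' model; two-sided p-value. The flexible-basis-plus-F-test construction
#' plays the role of a generalized additive trend test with a fixed,
#' transparent basis.
#'
#' @param areas peak areas ordered by time (>= 8 values).
#' @param times matching time points (hours).
#' @param df spline degrees of freedom (default 4).
#' @param log_transform apply log10(x + 1) first (default TRUE).
#' @return Object of class `trend_result` (a one-row data frame):
#'   `p_value`, `f_stat`, `df_model`, `df_resid`, `delta_log10` (fitted
#'   end minus fitted start, a signed drift summary) and `flag`
#'   (`"ok"`, `"constant"`).
#' @export
trend_test <- function(areas, times, df = 4, log_transform = TRUE) {
  if (length(areas) != length(times)) {
    stop("areas and times must have equal length", call. = FALSE)
  }
  if (length(areas) < 8) stop("need at least 8 time points", call. = FALSE)
  if (length(areas) < df + 2) {
    stop("need at least df + 2 points for the F test", call. = FALSE)
  }
  if (any(areas < 0)) stop("negative peak areas", call. = FALSE)
  y <- if (log_transform) log10(areas + 1) else areas
  if (stats::var(y) == 0) {
    return(.trend_row(p = 1, f = 0, dfm = df, dfr = length(y) - df - 1,
                      delta = 0, flag = "constant"))
  }
  basis <- splines::ns(times, df = df)
  fit <- stats::lm(y ~ basis)
  fs <- summary(fit)$fstatistic
  p <- stats::pf(fs[["value"]], fs[["numdf"]], fs[["dendf"]], lower.tail = FALSE)
  fv <- stats::fitted(fit)
  .trend_row(p = p, f = fs[["value"]], dfm = fs[["numdf"]], dfr = fs[["dendf"]],
             delta = fv[length(fv)] - fv[1], flag = "ok")
}

.trend_row <- function(p, f, dfm, dfr, delta, flag) {
  out <- data.frame(p_value = p, f_stat = f, df_model = dfm, df_resid = dfr,
                    delta_log10 = delta, flag = flag, stringsAsFactors = FALSE)
  class(out) <- c("trend_result", class(out))
  out
}

#' Trend tests across a feature matrix
#'
#' Runs [trend_test()] for every feature within every group of a
#' [feature_matrix()] and appends a Benjamini-Hochberg FDR column per
#' group. Features are called drifting at raw p < alpha within each
#' group (the BH column is reported alongside for stricter use).
#'
#' @param fm a `feature_matrix` whose samples carry `group` and
#'   `time_hr`.
#' @param df,alpha spline df and significance threshold.
#' @return Data frame: feature_id, group, p_value, f_stat, delta_log10,
#'   flag, p_bh, significant.
#' @export
trend_test_matrix <- function(fm, df = 4, alpha = 0.05) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (!all(c("group", "time_hr") %in% names(fm$samples))) {
    stop("samples must carry group and time_hr", call. = FALSE)
  }
  res <- list()
  for (g in unique(fm$samples$group)) {
    cols <- which(fm$samples$group == g)
    t_hr <- fm$samples$time_hr[cols]
    for (f in rownames(fm$areas)) {
      r <- trend_test(fm$areas[f, cols], t_hr, df = df)
      r$feature_id <- f; r$group <- g
      res[[length(res) + 1L]] <- r
    }
  }
  out <- do.call(rbind, res)
  out <- out[c("feature_id", "group", "p_value", "f_stat", "delta_log10", "flag")]
  out$p_bh <- stats::ave(out$p_value, out$group,
                         FUN = function(p) stats::p.adjust(p, "BH"))
  out$significant <- out$p_value < alpha
  rownames(out) <- NULL
  out
}

#' PCA of a feature matrix
#'
#' MetaboAnalyst-style preprocessing: log10(x + 1) transform, per-feature
#' mean centering and unit-variance scaling (each step switchable),
#' followed by SVD-based PCA of the samples. Zero-variance features are
#' dropped with a warning.
#'
#' @param fm a `feature_matrix`, or a bare features x samples matrix.
#' @param log_transform,center,scale. preprocessing switches.
#' @return Object of class `pca_result`: `scores` (samples x PCs),
#'   `loadings` (features x PCs), `explained_variance` (fractions),
#'   `samples` metadata.
#' @export
pca_scores <- function(fm, log_transform = TRUE, center = TRUE, scale. = TRUE) {
  if (inherits(fm, "feature_matrix")) {
    x <- fm$areas; samples <- fm$samples
  } else {
    x <- as.matrix(fm)
    samples <- data.frame(sample_id = colnames(x) %||% paste0("s", seq_len(ncol(x))))
  }
  if (nrow(x) < 2 || ncol(x) < 2) {
    stop("need at least 2 features and 2 samples", call. = FALSE)
  }
  if (log_transform) x <- log10(x + 1)
  if (scale.) {
    # unit-variance scaling is undefined for flat features
    v <- apply(x, 1, stats::var)
    if (any(v == 0)) {
      warning(sum(v == 0), " zero-variance feature(s) dropped", call. = FALSE)
      x <- x[v > 0, , drop = FALSE]
      if (nrow(x) < 2) stop("fewer than 2 informative features", call. = FALSE)
    }
  }
  p <- stats::prcomp(t(x), center = center, scale. = scale.)
  ev <- p$sdev^2 / sum(p$sdev^2)
  structure(list(scores = p$x, loadings = p$rotation,
                 explained_variance = ev, samples = samples),
            class = "pca_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pca_result <- function(x, ...) {
  cat("<pca_result> ", nrow(x$scores), " samples, PC1 ",
      round(100 * x$explained_variance[1], 1), "%, PC2 ",
      round(100 * x$explained_variance[2], 1), "%\n", sep = "")
  invisible(x)
}

#' Accumulated path length of an injection trajectory in score space
#'
#' Sum of Euclidean distances between consecutive injections' scores,
#' restricted to the first `dims` principal components (default 2: the
#' scores-plot plane). A long path means the sample kept moving in
#' composition space from first to last injection.
#'
#' @param scores samples x PCs score matrix ordered by injection, a
#'   `pca_result`, or (with `group`) a `pca_result` whose samples carry
#'   group/injection metadata.
#' @param dims number of leading components to use.
#' @param group optional group label: restrict to that group's samples
#'   (ordered by `injection_index`).
#' @return Path length (score-space units).
#' @export
accumulated_path_length <- function(scores, dims = 2, group = NULL) {
  if (inherits(scores, "pca_result")) {
    sc <- scores$scores
    if (!is.null(group)) {
      meta <- scores$samples
      sel <- which(meta$group == group)
      if (!length(sel)) stop("unknown group: ", group, call. = FALSE)
      sel <- sel[order(meta$injection_index[sel])]
      sc <- sc[sel, , drop = FALSE]
    }
  } else {
    sc <- as.matrix(scores)
  }
  if (dims > ncol(sc)) stop("dims exceeds available components", call. = FALSE)
  sc <- sc[, seq_len(dims), drop = FALSE]
  if (nrow(sc) < 2) {
    warning("single injection: path length 0", call. = FALSE)
    return(0)
  }
  steps <- diff(sc)
  sum(sqrt(rowSums(steps^2)))
}

#' Spearman correlation of hydrophobicity with recovery fold change
#'
#' Spearman rank correlation (average ranks for ties) between compound
#' LogP and log2 fold change of mean pool size versus the control
#' condition, with a two-sided p-value from the t approximation.
#'
#' @param table data frame with columns `logp` and `log2fc` (finite).
#' @return List: `r_s`, `p_value`, `n`.
#' @export
logp_recovery_correlation <- function(table) {
  stopifnot(all(c("logp", "log2fc") %in% names(table)))
  x <- table$logp; y <- table$log2fc
  if (length(x) < 4) stop("need at least 4 compounds", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("logp and log2fc must be finite", call. = FALSE)
  }
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    stop("undefined correlation: a column is all tied", call. = FALSE)
  }
  rs <- stats::cor(rank(x), rank(y))
  n <- length(x)
  if (abs(rs) >= 1) {
    p <- 0
  } else {
    tstat <- rs * sqrt((n - 2) / (1 - rs^2))
    p <- 2 * stats::pt(abs(tstat), n - 2, lower.tail = FALSE)
  }
  list(r_s = rs, p_value = p, n = n)
}

#' Log2 fold change of mean pool size versus control
#'
#' `log2(mean(condition) / mean(control))` per feature, the
#' mean-of-replicates convention (not the mean of per-replicate ratios).
#' A pseudo-count keeps the ratio finite when a mean is zero.
#'
#' @param condition,control features x replicates matrices (aligned rows).
#' @param pseudo pseudo-count added to both means (default 1).
#' @return Named numeric vector of log2 fold changes.
#' @export
log2fc_means <- function(condition, control, pseudo = 1) {
  condition <- as.matrix(condition); control <- as.matrix(control)
  if (nrow(condition) != nrow(control)) {
    stop("condition and control must have matching features", call. = FALSE)
  }
  log2((rowMeans(condition) + pseudo) / (rowMeans(control) + pseudo))
}

#' Deduplicate compounds measured by multiple methods using pooled-QC CV
#'
#' For compounds measured by more than one analytical method, keeps
#' exactly the row whose pooled-QC coefficient of variation is smallest;
#' ties are broken by lexicographic method name. One row per compound
#' comes out; row count never increases.
#'
#' @param catalogue data frame with columns `compound`, `method`,
#'   `qc_cv` (no missing CVs) plus any payload columns.
#' @return The deduplicated data frame (original column set).
#' @export
dedupe_by_qc_cv <- function(catalogue) {
  need <- c("compound", "method", "qc_cv")
  missing_cols <- setdiff(need, names(catalogue))
  if (length(missing_cols)) {
    stop("catalogue missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(catalogue$qc_cv)) {
    stop("qc_cv missing for some (compound, method) pairs", call. = FALSE)
  }
  o <- order(catalogue$compound, catalogue$qc_cv, catalogue$method)
  sorted <- catalogue[o, , drop = FALSE]
  out <- sorted[!duplicated(sorted$compound), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Exclusive set intersections (UpSet semantics)
#'
#' Counts every non-empty region of the set partition: each element is
#' tallied under its exact membership pattern across the input sets.
#'
#' @param sets named list of character/numeric vectors (feature sets
#'   over a common universe).
#' @return Data frame: one row per observed pattern with logical
#'   membership columns (one per set), `pattern` (e.g. `"A&B"`) and
#'   `count`; sorted by decreasing count.
#' @export
significant_set_intersections <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 1)
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("sets must be named", call. = FALSE)
  }
  universe <- unique(unlist(sets))
  if (!length(universe)) {
    out <- data.frame(pattern = character(0), count = integer(0))
    return(out)
  }
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  member <- matrix(member, nrow = length(universe),
                   dimnames = list(NULL, names(sets)))
  pat <- apply(member, 1, function(m) paste(names(sets)[m], collapse = "&"))
  tab <- table(pat)
  patterns <- names(tab)
  memcols <- vapply(names(sets), function(nm) {
    vapply(strsplit(patterns, "&", fixed = TRUE), function(p) nm %in% p, logical(1))
  }, logical(length(patterns)))
  memcols <- matrix(memcols, nrow = length(patterns),
                    dimnames = list(NULL, names(sets)))
  out <- data.frame(memcols, pattern = patterns, count = as.integer(tab),
                    stringsAsFactors = FALSE, check.names = FALSE)
  out <- out[order(-out$count, out$pattern), , drop = FALSE]
  rownames(out) <- NULL
  out
}
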