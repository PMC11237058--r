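#' Read a feature table from CSV/TSV
#'
#' Two dialects are supported. `"long"` (tidy): one row per
#' feature/sample with required columns `feature_id`, `sample_id`,
#' `area` and optional metadata columns (`group`, `injection_index`,
#' `time_hr`, `mz`, `rt_min`). `"wide"`: one row per feature with
#' `feature_id` first, optional `mz`/`rt_min` metadata columns, and one
#' area column per sample. Units are fixed package-wide: RT minutes,
#' time hours, chromatogram time seconds, masses Da, areas counts.
#'
#' @param path file path (comma- or tab-separated, sniffed from the
#'   extension: `.tsv`/`.txt` = tab).
#' @param dialect `"long"` or `"wide"`.
#' @return A [feature_matrix()].
#' @export
load_feature_table <- function(path, dialect = c("long", "wide")) {
  dialect <- match.arg(dialect)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (dialect == "long") {
    need <- c("feature_id", "sample_id", "area")
    miss <- setdiff(need, names(df))
    if (length(miss)) {
      stop("feature table missing required column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    feats <- unique(df$feature_id)
    samps <- unique(df$sample_id)
    m <- matrix(NA_real_, length(feats), length(samps),
                dimnames = list(feats, samps))
    m[cbind(match(df$feature_id, feats), match(df$sample_id, samps))] <- df$area
    meta_cols <- intersect(c("group", "injection_index", "time_hr"), names(df))
    samples <- unique(df[c("sample_id", meta_cols)])
    samples <- samples[match(samps, samples$sample_id), , drop = FALSE]
    rownames(samples) <- NULL
    fcols <- intersect(c("mz", "rt_min"), names(df))
    features <- unique(df[c("feature_id", fcols)])
    features <- features[match(feats, features$feature_id), , drop = FALSE]
    rownames(features) <- NULL
    feature_matrix(m, samples, features)
  } else {
    if (!"feature_id" %in% names(df)) {
      stop("feature table missing required column(s): feature_id",
           call. = FALSE)
    }
    meta <- intersect(c("feature_id", "mz", "rt_min"), names(df))
    sample_cols <- setdiff(names(df), meta)
    if (!length(sample_cols)) stop("wide table has no sample columns", call. = FALSE)
    m <- as.matrix(df[sample_cols])
    rownames(m) <- df$feature_id
    feature_matrix(m, data.frame(sample_id = sample_cols,
                                 stringsAsFactors = FALSE),
                   df[meta])
  }
}

#' Write a feature matrix to CSV
#'
#' Writes either dialect accepted by [load_feature_table()]. Numeric
#' values are written with 17 significant digits so a write/read
#' round-trip reproduces them to full double precision.
#'
#' @param fm a [feature_matrix()].
#' @param path output path.
#' @param dialect `"long"` or `"wide"`.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(fm, path, dialect = c("long", "wide")) {
  stopifnot(inherits(fm, "feature_matrix"))
  dialect <- match.arg(dialect)
  if (dialect == "long") {
    samp <- fm$samples
    df <- data.frame(
      feature_id = rep(rownames(fm$areas), times = ncol(fm$areas)),
      sample_id = rep(samp$sample_id, each = nrow(fm$areas)),
      area = as.numeric(fm$areas), stringsAsFactors = FALSE)
    for (cn in intersect(c("group", "injection_index", "time_hr"), names(samp))) {
      df[[cn]] <- rep(samp[[cn]], each = nrow(fm$areas))
    }
    if (!is.null(fm$features)) {
      for (cn in intersect(c("mz", "rt_min"), names(fm$features))) {
        df[[cn]] <- fm$features[[cn]][match(df$feature_id, fm$features$feature_id)]
      }
    }
  } else {
    df <- data.frame(feature_id = rownames(fm$areas), stringsAsFactors = FALSE)
    if (!is.null(fm$features)) {
      for (cn in intersect(c("mz", "rt_min"), names(fm$features))) {
        df[[cn]] <- fm$features[[cn]][match(df$feature_id, fm$features$feature_id)]
      }
    }
    df <- cbind(df, as.data.frame(fm$areas, check.names = FALSE))
  }
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write MS2 records to an MGF file
#'
#' Minimal Mascot Generic Format writer: one BEGIN IONS/END IONS block
#' per record with TITLE, PEPMASS, RTINSECONDS and the fragment peak
#' list (m/z, intensity per line).
#'
#' @param records list of [ms2_record()]s.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (r in records) {
    writeLines(c(
      "BEGIN IONS",
      paste0("TITLE=", if (is.na(r$id)) "spectrum" else r$id),
      sprintf("PEPMASS=%.17g", r$precursor_mz),
      sprintf("RTINSECONDS=%.17g", r$rt_min * 60),
      sprintf("%.17g %.17g", r$fragments$mz, r$fragments$intensity),
      "END IONS", ""), con)
  }
  invisible(path)
}

#' Read MS2 records from an MGF file
#'
#' @param path MGF file path.
#' @return List of [ms2_record()]s (RT converted back to minutes).
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  starts <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(starts) != length(ends)) stop("malformed MGF", call. = FALSE)
  lapply(seq_along(starts), function(i) {
    block <- lines[(starts[i] + 1):(ends[i] - 1)]
    kv <- grepl("=", block, fixed = TRUE)
    keys <- sub("=.*$", "", block[kv])
    vals <- sub("^[^=]*=", "", block[kv])
    pk <- block[!kv & nzchar(block)]
    parts <- strsplit(trimws(pk), "[ \t]+")
    frag <- data.frame(mz = as.numeric(vapply(parts, `[`, "", 1)),
                       intensity = as.numeric(vapply(parts, `[`, "", 2)))
    rt <- if ("RTINSECONDS" %in% keys) {
      as.numeric(vals[match("RTINSECONDS", keys)]) / 60
    } else NA_real_
    pep <- as.numeric(strsplit(vals[match("PEPMASS", keys)], "[ \t]+")[[1]][1])
    ms2_record(precursor_mz = pep, rt_min = rt, fragments = frag,
               id = if ("TITLE" %in% keys) vals[match("TITLE", keys)] else NA)
  })
}
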