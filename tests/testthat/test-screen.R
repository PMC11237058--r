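test_that("peak detection applies width and intensity filters", {
  # flat / empty traces
  expect_identical(nrow(detect_chrom_peaks(chromatogram(1:10, rep(0, 10)))), 0L)
  expect_identical(nrow(detect_chrom_peaks(chromatogram(numeric(0), numeric(0)))), 0L)
  # one wide tall Gaussian passes both filters
  one <- simulate_chromatogram(data.frame(apex_s = 300, height = 1e6, sigma_s = 2.5))
  pk <- detect_chrom_peaks(one)
  expect_identical(nrow(pk), 1L)
  expect_equal(pk$apex_s, 300, tolerance = 1)
  expect_gt(pk$width_s, 6)
  # planted mixture: 5 wide/tall pass, 3 narrow-or-dim fail
  mix <- simulate_chromatogram(data.frame(
    apex_s = c(100, 180, 260, 340, 420, 140, 220, 480),
    height = c(rep(1e6, 5), 5e4, 1e6, 2e6),
    sigma_s = c(rep(3, 5), 3, 0.8, 0.7)))
  got <- detect_chrom_peaks(mix)
  expect_identical(nrow(got), 5L)
  expect_equal(got$apex_s, c(100, 180, 260, 340, 420), tolerance = 1)
})

test_that("peak filters are monotone and intensity-rescaling invariant", {
  mix <- simulate_chromatogram(data.frame(
    apex_s = c(100, 200, 300, 400), height = c(2e5, 5e5, 1e6, 3e6),
    sigma_s = c(1, 2, 3, 4)))
  n_prev <- Inf
  for (w in c(2, 6, 10, 14)) {
    n <- nrow(detect_chrom_peaks(mix, min_width_s = w))
    expect_lte(n, n_prev)
    n_prev <- n
  }
  a <- detect_chrom_peaks(mix)
  scaled <- chromatogram(mix$time_s, mix$intensity * 10)
  b <- detect_chrom_peaks(scaled, min_intensity = 1e6)
  expect_equal(a$apex_s, b$apex_s)
  expect_equal(a$width_s, b$width_s)
})

test_that("fragment screen attains perfect precision and recall on fixtures", {
  recs <- generate_ms2_fixtures(n_conjugates = 14, n_decoys = 50, seed = 17)
  hits <- fragment_precursor_screen(recs)
  ids <- unlist(strsplit(hits$record_ids, ";"))
  all_ids <- vapply(recs, `[[`, character(1), "id")
  truth <- all_ids[vapply(recs, function(r) isTRUE(r$is_conjugate), logical(1))]
  expect_setequal(ids, truth)            # recall 1, precision 1
  expect_identical(sum(hits$n_records), 14L)
  expect_identical(nrow(fragment_precursor_screen(list())), 0L)
  expect_error(fragment_precursor_screen(recs, fragment_tol_ppm = 0), "positive")
})

test_that("screen hits grow monotonically with fragment tolerance", {
  recs <- generate_ms2_fixtures(n_conjugates = 10, n_decoys = 30,
                                max_fragment_ppm_error = 8, seed = 23)
  n_prev <- 0L
  for (tol in c(1, 3, 6, 10, 20)) {
    n <- sum(fragment_precursor_screen(recs, fragment_tol_ppm = tol)$n_records)
    expect_gte(n, n_prev)
    n_prev <- n
  }
})

test_that("near-isobaric precursors group by single linkage", {
  mk <- function(mz, id) ms2_record(mz, 5, data.frame(mz = 308.0912,
                                                      intensity = 1e5), id)
  recs <- list(mk(464.2061, "a"), mk(464.2061 * (1 + 1e-6), "b"),
               mk(464.2061 * (1 + 2.1e-6) * (1 + 2.1e-6), "c"))
  hits <- fragment_precursor_screen(recs, precursor_group_ppm = 2)
  expect_identical(nrow(hits), 2L)
  expect_identical(hits$n_records, c(2L, 1L))
})

test_that("screen counts chromatographic peaks for matched XICs", {
  rec <- ms2_record(464.2061, 9.0,
                    data.frame(mz = 308.0912, intensity = 2e5), "gsx")
  xic <- simulate_chromatogram(data.frame(apex_s = c(200, 400),
                                          height = c(1e6, 5e6),
                                          sigma_s = c(3, 4)),
                               precursor_mz = 464.2061)
  hits <- fragment_precursor_screen(list(rec), xics = list(xic))
  expect_identical(hits$n_peaks, 2L)
})

test_that("label-pair search matches the double-loop oracle", {
  shift <- label_mass_shift(label_spec(n_D = 4))
  # the drifting unknown coelutes with Glu-Glu at a D4 shift
  feats <- data.frame(mz = c(275.0886, 279.1137), rt_min = c(12.085, 12.066))
  pairs <- find_label_pairs(feats, shift, mz_tol_ppm = 20, rt_tol_min = 0.1)
  expect_identical(nrow(pairs), 1L)
  expect_equal(pairs$light_mz, 275.0886)
  expect_identical(nrow(find_label_pairs(feats, shift, mz_tol_ppm = 20,
                                         rt_tol_min = 0.001)), 0L)
  # random cloud vs brute force
  set.seed(41)
  n <- 120
  cloud <- data.frame(mz = stats::runif(n, 100, 600),
                      rt_min = stats::runif(n, 1, 14))
  some <- sample(n, 15)
  cloud <- rbind(cloud, data.frame(mz = cloud$mz[some] + shift,
                                   rt_min = cloud$rt_min[some] +
                                     stats::rnorm(15, 0, 0.02)))
  got <- find_label_pairs(cloud, shift, mz_tol_ppm = 5, rt_tol_min = 0.1)
  oracle <- 0L
  for (i in seq_len(nrow(cloud))) {
    for (j in seq_len(nrow(cloud))) {
      if (i == j) next
      dmz <- cloud$mz[j] - cloud$mz[i]
      if (abs(1e6 * (dmz - shift) / cloud$mz[j]) <= 5 &&
          abs(cloud$rt_min[j] - cloud$rt_min[i]) <= 0.1) oracle <- oracle + 1L
    }
  }
  expect_identical(nrow(got), oracle)
  expect_gte(nrow(got), 15L)
})

test_that("blank filter keeps real features and drops blank-dominated ones", {
  expect_identical(blank_filter(300, 100), 1L)  # boundary inclusive
  expect_identical(length(blank_filter(100, 100)), 0L)
  s <- c(real = 5e5, weak = 2e5, blankish = 1e5, absent = 0)
  b <- c(real = 0, weak = 5e4, blankish = 1e5, absent = 0)
  expect_setequal(blank_filter(s, b), c("real", "weak"))
  # planted 20 real + 10 blank-only
  set.seed(6)
  real <- stats::runif(20, 1e5, 1e6); blank_only <- stats::runif(10, 1e4, 1e5)
  sm <- c(real, blank_only * 0.5)
  bm <- c(rep(0, 20), blank_only)
  names(sm) <- names(bm) <- sprintf("f%02d", 1:30)
  expect_identical(blank_filter(sm, bm), sprintf("f%02d", 1:20))
  expect_error(blank_filter(1:3, 1:2), "align")
})
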