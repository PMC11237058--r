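test_that("trend test flags ramps, passes constants and validates input", {
  t_hr <- seq(0, 84, length.out = 25)
  # strong noiseless monotone ramp
  ramp <- 1e5 * 10^(t_hr / 40)
  expect_lt(trend_test(ramp, t_hr)$p_value, 1e-6)
  # constant series is a clean null
  const <- rep(2e5, 25)
  r <- trend_test(const, t_hr)
  expect_identical(r$p_value, 1)
  expect_identical(r$flag, "constant")
  expect_error(trend_test(const[1:6], t_hr[1:6]), "at least 8")
  expect_error(trend_test(rep(1, 9), seq_len(9), df = 8), "df \\+ 2")
})

test_that("null trend-test p-values are uniform (type I error calibrated)", {
  set.seed(2024)
  t_hr <- seq(0, 84, length.out = 25)
  n_feat <- 2000
  p <- vapply(seq_len(n_feat), function(i) {
    a <- 10^(5 + stats::rnorm(25, 0, 0.1))  # null: lognormal area noise
    trend_test(a, t_hr)$p_value
  }, numeric(1))
  expect_gt(mean(p < 0.05), 0.03)
  expect_lt(mean(p < 0.05), 0.07)
  ks <- stats::ks.test(p, "punif")
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("pca_scores agrees with an eigendecomposition oracle", {
  set.seed(5)
  x <- matrix(stats::rlnorm(30 * 8, 5, 1), 30, 8,
              dimnames = list(paste0("f", 1:30), paste0("s", 1:8)))
  p <- pca_scores(x)
  # oracle: eigen of covariance of the preprocessed sample matrix
  z <- scale(t(log10(x + 1)))
  ev <- eigen(stats::cov(z))
  for (k in 1:3) {
    a <- p$scores[, k]; b <- (z %*% ev$vectors)[, k]
    expect_equal(abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2)), 1,
                 tolerance = 1e-8)  # collinear up to sign
  }
  expect_equal(p$explained_variance[1:5],
               (ev$values / sum(ev$values))[1:5], tolerance = 1e-8)
  expect_lte(sum(p$explained_variance), 1 + 1e-12)
})

test_that("pca handles degenerate matrices per contract", {
  x <- matrix(c(1, 2, 4, 8), 2, 2)  # rank-1
  p <- pca_scores(x, log_transform = FALSE, scale. = FALSE)
  expect_equal(p$explained_variance[1], 1, tolerance = 1e-12)
  xz <- rbind(a = c(1, 1, 1), b = c(1, 2, 3), c = c(2, 4, 6))
  expect_warning(pca_scores(xz, log_transform = FALSE), "zero-variance")
  # identical samples: all scores equal
  xi <- matrix(rep(c(1, 5, 9), 3), 3, 3)
  pi2 <- pca_scores(xi, scale. = FALSE)
  expect_lt(max(abs(diff(pi2$scores))), 1e-12)
})

test_that("path length follows geometry and its invariances", {
  expect_equal(accumulated_path_length(rbind(c(0, 0), c(3, 4))), 5)
  expect_equal(accumulated_path_length(matrix(1, 5, 2)), 0)
  expect_warning(l1 <- accumulated_path_length(matrix(1, 1, 2)), "single")
  expect_identical(l1, 0)
  set.seed(8)
  sc <- matrix(stats::rnorm(20), 10, 2)
  l <- accumulated_path_length(sc)
  th <- 0.7; R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  expect_equal(accumulated_path_length(sc %*% R), l, tolerance = 1e-12)
  expect_equal(accumulated_path_length(sweep(sc, 2, c(5, -3), `+`)), l,
               tolerance = 1e-12)
  expect_equal(accumulated_path_length(2.5 * sc), 2.5 * l, tolerance = 1e-12)
  expect_error(accumulated_path_length(sc, dims = 3), "exceeds")
})

test_that("active extracts drift further than filtered in PCA score space", {
  bg <- background_features(n = 150, seed = 77)
  act <- observe_scenario("active", seed = 21, background = bg)
  fil <- observe_scenario("filtered", seed = 22, background = bg)
  fm <- as_feature_matrix(list(active = act, filtered = fil))
  p <- suppressWarnings(pca_scores(fm))
  expect_gt(accumulated_path_length(p, group = "active"),
            accumulated_path_length(p, group = "filtered"))
})

test_that("spearman correlation matches rank-then-pearson brute force", {
  expect_equal(logp_recovery_correlation(
    data.frame(logp = 1:6, log2fc = -(1:6)))$r_s, -1)
  expect_equal(logp_recovery_correlation(
    data.frame(logp = 1:6, log2fc = (1:6)^2))$r_s, 1)
  set.seed(3)
  x <- sample(20, replace = TRUE); y <- stats::rnorm(20)  # ties in x
  got <- logp_recovery_correlation(data.frame(logp = x, log2fc = y))
  expect_equal(got$r_s, stats::cor(rank(x), rank(y)), tolerance = 1e-12)
  ref <- stats::cor.test(x, y, method = "spearman", exact = FALSE)
  expect_equal(got$r_s, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-9)
  expect_error(logp_recovery_correlation(
    data.frame(logp = rep(1, 5), log2fc = 1:5)), "tied")
})

test_that("planted hydrophobicity effect is recovered with the right sign", {
  set.seed(31)
  logp <- stats::runif(60, -4, 4)
  log2fc <- -0.4 * logp + stats::rnorm(60, 0, 0.5)
  r <- logp_recovery_correlation(data.frame(logp = logp, log2fc = log2fc))
  expect_lt(r$r_s, 0)
  expect_lt(r$p_value, 0.01)
})

test_that("log2 fold change uses mean-of-replicates", {
  cond <- rbind(f1 = c(9, 11, 10), f2 = c(1, 1, 1))
  ctrl <- rbind(f1 = c(4, 5, 6), f2 = c(3, 3, 3))
  got <- log2fc_means(cond, ctrl, pseudo = 0)
  expect_equal(unname(got), c(1, log2(1 / 3)), tolerance = 1e-12)
})

test_that("QC-CV deduplication keeps the best method per compound", {
  cat242 <- data.frame(
    compound = c(sprintf("c%03d", 1:195), sprintf("c%03d", 1:47)),
    method = c(rep("amide", 195), rep("t3", 47)),
    qc_cv = c(stats::runif(195, 0.05, 0.3), stats::runif(47, 0.01, 0.4)))
  out <- dedupe_by_qc_cv(cat242)
  expect_identical(nrow(out), 195L)
  expect_false(any(duplicated(out$compound)))
  # minimal-CV row kept; lexicographic tie-break
  d <- data.frame(compound = c("x", "x", "y"), method = c("b", "a", "a"),
                  qc_cv = c(0.1, 0.2, 0.3))
  expect_identical(dedupe_by_qc_cv(d)$method, c("b", "a"))  # CV 0.1 wins
  tie <- data.frame(compound = "x", method = c("zeta", "alpha"),
                    qc_cv = c(0.1, 0.1))
  expect_identical(dedupe_by_qc_cv(tie)$method, "alpha")
  no_dup <- data.frame(compound = c("a", "b"), method = "m", qc_cv = 0.1)
  expect_identical(dedupe_by_qc_cv(no_dup)$compound, c("a", "b"))
  d$qc_cv[1] <- NA
  expect_error(dedupe_by_qc_cv(d), "missing")
})

test_that("set intersections match a brute-force membership tally", {
  ab <- significant_set_intersections(list(A = c("x", "y"), B = c("x", "y")))
  expect_identical(ab$pattern, "A&B")
  expect_identical(ab$count, 2L)
  dj <- significant_set_intersections(list(A = "x", B = "y"))
  expect_setequal(dj$pattern, c("A", "B"))
  set.seed(13)
  u <- sprintf("f%02d", 1:40)
  sets <- lapply(1:4, function(i) sample(u, sample(5:30, 1)))
  names(sets) <- LETTERS[1:4]
  got <- significant_set_intersections(sets)
  # oracle: tally exact membership pattern of each element
  pat <- vapply(u, function(e) {
    paste(names(sets)[vapply(sets, function(s) e %in% s, logical(1))],
          collapse = "&")
  }, character(1))
  pat <- pat[nzchar(pat)]
  oracle <- table(pat)
  expect_identical(sum(got$count), length(pat))
  for (p in names(oracle)) {
    expect_identical(got$count[got$pattern == p], as.integer(oracle[[p]]))
  }
})
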