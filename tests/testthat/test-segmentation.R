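# PCA + k-means screening of scan grids and outlier-sample flagging.

test_that("a homogeneous noiseless scan collapses into one subset with identical representatives", {
  sp <- scan_spec(n_rows = 5, n_cols = 5, noise = "none",
                  q_grid = seq(0.1, 1.1, length.out = 150))
  g <- generate_scan(sp)
  seg <- segment_scan(g, k = 4)
  expect_length(seg$abundance, 4)
  expect_equal(sum(seg$abundance), 1)
  expect_equal(max(seg$abundance), 1)
  expect_length(seg$representatives, 4)
  for (r in seg$representatives) {
    expect_equal(r$intensity, seg$representatives[[1]]$intensity)
  }
})

test_that("planted two-region scans are recovered exactly", {
  qg <- seq(0.1, 1.1, length.out = 150)
  out_tr <- ground_truth(step = default_truth_params(D = 60))
  sp <- scan_spec(n_rows = 6, n_cols = 6, noise = "none", q_grid = qg,
                  outlier_regions = list(list(rows = 1:3, cols = 1:6,
                                              truth = out_tr)))
  g <- generate_scan(sp)
  seg <- segment_scan(g, k = 2)
  planted <- ifelse(g$index$row <= 3, 1L, 2L)
  expect_equal(rand_index(seg$labels, planted), 1)
})

test_that("a pair of structureless outlier pixels is isolated in its own subset", {
  qg <- seq(0.1, 1.1, length.out = 150)
  dried <- ground_truth(step = default_truth_params(delta_rho = 0))
  sp <- scan_spec(n_rows = 6, n_cols = 6, noise = "none", q_grid = qg,
                  outlier_regions = list(list(rows = 2, cols = 2:3,
                                              truth = dried)))
  g <- generate_scan(sp)
  seg <- segment_scan(g, k = 4)
  out_px <- which(g$index$row == 2 & g$index$col %in% 2:3)
  lab <- seg$labels[out_px]
  expect_identical(lab[1], lab[2])
  expect_identical(sum(seg$labels == lab[1]), 2L)
})

test_that("segmentation is deterministic under a fixed seed", {
  g <- generate_scan(scan_spec(n_rows = 5, n_cols = 5,
                               q_grid = seq(0.1, 1.1, length.out = 150)))
  s1 <- segment_scan(g, k = 3, seed = 9)
  s2 <- segment_scan(g, k = 3, seed = 9)
  expect_identical(s1$labels, s2$labels)
  expect_identical(s1$representative_pixels, s2$representative_pixels)
})

test_that("requesting more subsets than pixels errors", {
  g <- generate_scan(scan_spec(n_rows = 2, n_cols = 2,
                               q_grid = seq(0.1, 1.1, length.out = 80)))
  expect_error(segment_scan(g, k = 5), "exceeds")
})

test_that("the first three components capture at least as much variance as any other basis", {
  set.seed(4)
  qg <- seq(0.1, 1.1, length.out = 60)
  X <- do.call(rbind, lapply(1:20, function(i) {
    tr <- ground_truth(step = default_truth_params(D = 63 + 0.2 * i),
                       seed = i)
    generate_saxs_profile(tr, q_grid = qg)$intensity
  }))
  Xn <- X / rowSums(X)
  Xl <- scale(log(Xn + 1e-12), center = TRUE, scale = FALSE)
  pca_var <- sum(sort(stats::prcomp(Xl)$sdev^2, decreasing = TRUE)[1:3])
  # brute-force eigendecomposition oracle
  ev <- eigen(stats::cov(Xl), symmetric = TRUE)$values
  expect_equal(pca_var, sum(ev[1:3]) * (nrow(Xl) - 1) / (nrow(Xl) - 1),
               tolerance = 1e-8)
  # no random 3-dimensional basis does better
  for (i in 1:5) {
    B <- qr.Q(qr(matrix(rnorm(ncol(Xl) * 3), ncol = 3)))
    expect_lte(sum(apply(Xl %*% B, 2, stats::var)), pca_var + 1e-12)
  }
})

test_that("anomalous samples are flagged against the control and thresholds behave", {
  qg <- seq(0.1, 1.1, length.out = 150)
  mk <- function(D, seed, scale = 1) {
    p <- generate_saxs_profile(ground_truth(step = default_truth_params(D = D),
                                            seed = seed), q_grid = qg)
    qprofile(qg, p$intensity * scale)
  }
  control <- mk(65.5, 99)
  normals <- lapply(1:6, function(s) mk(65.5, s))
  fl <- flag_outlier_samples(normals, control)
  expect_false(any(fl$flagged))
  # one sample with shifted periodicity and different intensity
  shifted <- c(normals, list(mk(59, 7, scale = 3)))
  fl2 <- flag_outlier_samples(shifted, control)
  expect_identical(which(fl2$flagged), 7L)
  expect_false(any(flag_outlier_samples(shifted, control,
                                        threshold = Inf)$flagged))
})

test_that("the rand index compares partitions, not label values", {
  a <- c(1, 1, 2, 2)
  expect_equal(rand_index(a, c(2, 2, 1, 1)), 1)
  expect_equal(rand_index(a, c(1, 2, 1, 2)), 1 / 3)
  expect_error(rand_index(a, 1:3), "mismatch")
})
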