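test_that("ROI extraction averages voxels per label", {
  geom <- make_geometry(4, seed = 1)
  n_t <- 6
  img <- array(0, dim = c(2, 4, 1, n_t))
  lab <- array(0L, dim = c(2, 4, 1))
  series <- matrix(rnorm(4 * n_t), n_t, 4)
  for (j in 1:4) {
    img[1, j, 1, ] <- series[, j]
    img[2, j, 1, ] <- series[, j] + 1  # second voxel offset: mean = series + 0.5
    lab[, j, 1] <- j
  }
  ts <- extract_roi_timeseries(img, lab, geom)
  expect_equal(unname(ts), series + 0.5)

  lab1 <- lab; lab1[2, 1, 1] <- 99L  # ROI 1 becomes single-voxel
  ts1 <- extract_roi_timeseries(img, lab1, geom)
  expect_equal(unname(ts1[, 1]), series[, 1])

  bad <- geom; bad$roi_id[1] <- 50L; bad$partner_id[2] <- 50L
  expect_error(extract_roi_timeseries(img, lab, bad), "50")
})

test_that("synthetic NIfTI round-trips through the image path exactly", {
  cfg <- tiny_config(n_scans = 1, n_frames = 20, n_rois = 4)
  scan <- make_scan(cfg, seed = 5)
  prefix <- file.path(withr::local_tempdir(), "scan")
  paths <- write_scan_nifti(scan, prefix)
  img <- RNifti::readNifti(paths["bold"])
  lab <- RNifti::readNifti(paths["parcellation"])
  ts <- extract_roi_timeseries(img, lab, scan$ground_truth$roi_geometry)
  expect_equal(unname(ts), unname(scan$ts), tolerance = 1e-6)
})

test_that("fc_matrix applies Pearson + atanh with clamping and NA diagonal", {
  set.seed(31)
  n <- 5000
  a <- rnorm(n)
  b <- rnorm(n)
  z <- fc_matrix(cbind(a, b))
  expect_lt(abs(z[1, 2]), 0.05)        # z(0) ~ 0
  expect_true(is.na(z[1, 1]))

  # exact r = 0.5 by construction
  x <- rep(c(1, 2, 3, 4), 25)
  y <- x; y[seq(1, 100, 2)] <- mean(x)  # engineered below instead
  xc <- scale(rnorm(400))[, 1]
  resid <- scale(residuals(lm(rnorm(400) ~ xc)))[, 1]
  y5 <- 0.5 * xc + sqrt(1 - 0.25) * resid
  expect_equal(cor(xc, y5), 0.5, tolerance = 1e-12)
  z5 <- fc_matrix(cbind(xc, y5))
  expect_equal(z5[1, 2], atanh(0.5), tolerance = 1e-12)

  dup <- fc_matrix(cbind(a, a))
  expect_equal(dup[1, 2], atanh(1 - 1e-12))

  ts <- matrix(rnorm(60), 20, 3)
  m <- unclass(fc_matrix(ts))
  oracle <- atanh(cor(ts))
  diag(oracle) <- NA
  expect_equal(unclass(m), oracle, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("zero-variance ROIs are flagged, not silently zeroed", {
  set.seed(32)
  ts <- cbind(rnorm(30), rnorm(30), rep(2, 30))
  fc <- fc_matrix(ts)
  expect_equal(attr(fc, "zero_variance"), 3L)
  expect_true(all(is.na(unclass(fc)[3, ])))
  expect_false(is.na(unclass(fc)[1, 2]))
})

test_that("masked FC equals FC of the physically truncated series", {
  set.seed(33)
  ts <- matrix(rnorm(200), 50, 4)
  mask <- rep(c(TRUE, TRUE, FALSE, TRUE, TRUE), 10)
  expect_equal(unclass(fc_matrix(ts, keep_mask = mask)),
               unclass(fc_matrix(ts[mask, ])), ignore_attr = TRUE)
  expect_error(fc_matrix(ts, keep_mask = c(TRUE, TRUE, rep(FALSE, 48))),
               class = "neomotion_validation_error")
})

test_that("fc_matrix is invariant to per-ROI affine rescaling", {
  set.seed(34)
  ts <- matrix(rnorm(300), 60, 5)
  scaled <- sweep(sweep(ts, 2, runif(5, 0.5, 4), `*`), 2, rnorm(5), `+`)
  expect_equal(unclass(fc_matrix(ts)), unclass(fc_matrix(scaled)),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("homotopic strengths come from the explicit partner mapping", {
  cfg <- tiny_config(n_rois = 6, artifact_gain = 0, dropout_gain = 0,
                     n_frames = 5000, pma_slope = 0)
  scan <- make_scan(cfg, seed = 9)
  geom <- scan$ground_truth$roi_geometry
  fc <- fc_matrix(scan$ts)
  hom <- homotopic_fc(fc, geom)
  expect_equal(nrow(hom), 3L)
  truth <- scan$ground_truth$true_covariance
  for (k in seq_len(nrow(hom))) {
    i <- match(hom$roi_a[k], geom$roi_id); j <- match(hom$roi_b[k], geom$roi_id)
    expect_equal(hom$z[k], atanh(truth[i, j]), tolerance = 0.08)
  }

  # partner involution
  partner <- setNames(geom$partner_id, geom$roi_id)
  expect_equal(unname(partner[as.character(partner[as.character(geom$roi_id)])]),
               geom$roi_id)

  expect_error(homotopic_fc(fc, geom, pair_ids = 42), "unknown pair")

  dup <- fc_matrix(cbind(scan$ts[, 1], scan$ts[, 1],
                         scan$ts[, 3:6]))
  expect_equal(unclass(dup)[1, 2], atanh(1 - 1e-12))
})

test_that("roi_distances is a metric consistent with hand geometry", {
  geom <- make_geometry(4, seed = 2)
  geom$x_mm <- c(0, 3, 1, -1); geom$y_mm <- c(0, 4, 1, 1); geom$z_mm <- rep(0, 4)
  d <- roi_distances(geom)
  expect_equal(d[1, 2], 5)
  expect_equal(diag(d), rep(0, 4), ignore_attr = TRUE)
  expect_equal(d, t(d))
  for (k in 1:4) for (l in 1:4) for (m in 1:4) {
    expect_lte(d[k, m], d[k, l] + d[l, m] + 1e-12)
  }

  set.seed(35)
  geom$x_mm <- rnorm(4); geom$y_mm <- rnorm(4); geom$z_mm <- rnorm(4)
  d <- roi_distances(geom)
  oracle <- matrix(0, 4, 4)
  for (k in 1:4) for (l in 1:4) {
    oracle[k, l] <- sqrt(sum((c(geom$x_mm[k], geom$y_mm[k], geom$z_mm[k]) -
                              c(geom$x_mm[l], geom$y_mm[l], geom$z_mm[l]))^2))
  }
  expect_equal(unname(d), oracle, tolerance = 1e-12)

  perm <- sample(4)
  dp <- roi_distances(geom[perm, ])
  expect_equal(unname(dp), unname(d[perm, perm]))
})

test_that("seed maps correlate targets with the (averaged) seed", {
  set.seed(36)
  n <- 4000
  seed_ts <- rnorm(n)
  orth <- residuals(lm(rnorm(n) ~ seed_ts))
  targets <- cbind(same = seed_ts, orth = orth, noise = rnorm(n))
  z <- seed_map(targets, seed_ts)
  expect_equal(unname(z["same"]), atanh(1 - 1e-12))
  expect_equal(unname(z["orth"]), 0, tolerance = 1e-12)
  expect_equal(unname(z["noise"]), atanh(cor(seed_ts, targets[, "noise"])),
               tolerance = 1e-12)

  # bilateral seed averaged before correlation
  s2 <- cbind(seed_ts, rnorm(n))
  z2 <- seed_map(targets, s2)
  expect_equal(unname(z2["noise"]),
               atanh(cor(rowMeans(s2), targets[, "noise"])), tolerance = 1e-12)

  expect_error(seed_map(targets, rep(1, n)),
               class = "neomotion_degenerate_error")
})

test_that("ROI tables and FC matrices round-trip through TSV", {
  geom <- make_geometry(6, seed = 3)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_roi_table(geom, f)
  back <- read_roi_table(f)
  expect_equal(as.data.frame(back), as.data.frame(geom), tolerance = 1e-9)

  fc <- fc_matrix(matrix(rnorm(80), 20, 4))
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_fc_matrix(fc, f2)
  expect_equal(nrow(read.delim(f2)), 4L)
})
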