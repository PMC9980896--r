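make_assoc_table <- function(n, f = function(fd) fd, seed = 1) {
  set.seed(seed)
  fd <- runif(n, 0.02, 0.4)
  tibble::tibble(scan_id = sprintf("s%03d", seq_len(n)), mean_fd = fd,
                 z_net = f(fd))
}

test_that("fd_fc_association matches the closed-form Pearson statistic", {
  tab <- make_assoc_table(30, function(fd) 2 * fd + 1)
  res <- fd_fc_association(tab, "net")
  expect_equal(res$r, 1)

  tab5 <- tibble::tibble(scan_id = letters[1:5], mean_fd = c(.1, .2, .3, .4, .5),
                         z_net = c(.3, .1, .4, .2, .6))
  res5 <- fd_fc_association(tab5, "net")
  x <- tab5$mean_fd; y <- tab5$z_net
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t_oracle <- r_oracle * sqrt(3 / (1 - r_oracle^2))
  expect_equal(res5$r, r_oracle, tolerance = 1e-12)
  expect_equal(res5$p, 2 * pt(-abs(t_oracle), 3), tolerance = 1e-12)

  expect_error(fd_fc_association(tab5[1:3, ], "net"),
               class = "neomotion_validation_error")
  const <- tab5; const$z_net <- 1
  expect_error(fd_fc_association(const, "net"),
               class = "neomotion_degenerate_error")
})

test_that("fd_fc_association p-values are calibrated under independence", {
  set.seed(41)
  p <- replicate(400, {
    tab <- tibble::tibble(scan_id = 1:20, mean_fd = rnorm(20), z_net = rnorm(20))
    fd_fc_association(tab, "net")$p
  })
  rate <- mean(p < 0.05)
  se <- sqrt(0.05 * 0.95 / 400)
  expect_lt(abs(rate - 0.05), 3 * se)
  # p roughly uniform: KS against U(0,1)
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.001)
})

test_that("edgewise associations count 4005 edges for 90 ROIs", {
  set.seed(42)
  fcs <- lapply(1:8, function(k) matrix(rnorm(90 * 90), 90, 90))
  stack <- fc_stack_from_matrices(fcs)
  res <- edgewise_fd_association(stack, runif(8))
  expect_equal(attr(res, "n_edges"), 4005L)
  expect_equal(nrow(res), 4005L)
})

test_that("edgewise significance is calibrated on null cohorts", {
  set.seed(43)
  n_scans <- 25; n_edges <- 300
  stack <- matrix(rnorm(n_scans * n_edges), n_scans, n_edges)
  res <- edgewise_fd_association(stack, rnorm(n_scans), alpha = 0.05)
  expect_lt(abs(attr(res, "frac_significant") - 0.05),
            3 * sqrt(0.05 * 0.95 / n_edges))
  # r/p agree with cor.test edge by edge
  fd <- rnorm(n_scans)
  res2 <- edgewise_fd_association(stack[, 1:5], fd)
  for (e in 1:5) {
    ct <- cor.test(fd, stack[, e])
    expect_equal(res2$r[e], unname(ct$estimate), tolerance = 1e-12)
    expect_equal(res2$p[e], ct$p.value, tolerance = 1e-12)
  }
})

test_that("motion splits take floor(fraction n) per extreme with stable ties", {
  tab <- make_assoc_table(149)
  sp <- split_by_motion(tab, fraction = 0.25)
  expect_equal(sp$n_per_group, 37L)
  expect_equal(length(intersect(sp$low, sp$high)), 0L)
  expect_lt(sp$mean_fd_low, sp$mean_fd_high)

  tab8 <- make_assoc_table(8)
  sp8 <- split_by_motion(tab8, fraction = 0.25)
  expect_equal(sp8$n_per_group, 2L)
  ord <- tab8$scan_id[order(tab8$mean_fd)]
  expect_setequal(sp8$low, ord[1:2])
  expect_setequal(sp8$high, ord[7:8])

  ties <- tibble::tibble(scan_id = sprintf("s%02d", 1:10), mean_fd = rep(0.1, 10))
  spt <- split_by_motion(ties, fraction = 0.3)
  expect_equal(spt$low, sprintf("s%02d", 1:3))
  expect_equal(spt$high, sprintf("s%02d", 8:10))

  expect_error(split_by_motion(tab, fraction = 0.6),
               class = "neomotion_validation_error")
  expect_error(split_by_motion(make_assoc_table(5)),
               class = "neomotion_validation_error")
})

test_that("group contrasts match t.test and behave under the null", {
  set.seed(44)
  low <- matrix(rnorm(9), 3, 3); high <- matrix(rnorm(9), 3, 3)
  gc <- group_contrast(low, high)
  for (u in 1:3) {
    tt <- t.test(high[, u], low[, u], var.equal = TRUE)
    expect_equal(gc$t[u], unname(tt$statistic), tolerance = 1e-12)
    expect_equal(gc$p[u], tt$p.value, tolerance = 1e-12)
  }
  gw <- group_contrast(low, high, var_equal = FALSE)
  tt <- t.test(high[, 1], low[, 1])
  expect_equal(gw$t[1], unname(tt$statistic), tolerance = 1e-12)

  same <- matrix(rnorm(40), 4, 10)
  gid <- group_contrast(same, same)
  expect_equal(attr(gid, "n_sig_unc"), 0L)

  flat <- cbind(matrix(rnorm(30), 10, 3), rep(1, 10))
  gcf <- group_contrast(flat, flat)
  expect_true(gcf$degenerate[4])
  expect_equal(attr(gcf, "frac_sig_unc"), 0)
})

test_that("null group contrasts reject at the nominal uncorrected rate", {
  set.seed(45)
  fracs <- replicate(200, {
    maps <- matrix(rnorm(20 * 30), 20, 30)
    gc <- group_contrast(maps[1:10, ], maps[11:20, ], alpha_unc = 0.01)
    attr(gc, "frac_sig_unc")
  })
  expect_lt(abs(mean(fracs) - 0.01), 3 * sd(fracs) / sqrt(200))
})

test_that("within-group maps control FDR and detect constant offsets", {
  set.seed(46)
  maps <- matrix(rnorm(10 * 20), 10, 20)
  maps[, 5] <- maps[, 5] + 3
  wm <- within_group_map(maps, fdr_q = 0.05)
  expect_true(wm$sig[5])

  zero <- matrix(0, 5, 6)
  expect_equal(sum(within_group_map(zero)$sig), 0L)

  # false-discovery proportion <= q in expectation: 10 signal + 40 null units
  fdp <- replicate(200, {
    m <- matrix(rnorm(8 * 50), 8, 50)
    m[, 1:10] <- m[, 1:10] + 4
    wm <- within_group_map(m, fdr_q = 0.05)
    rej <- which(wm$sig)
    if (length(rej) == 0) 0 else mean(rej > 10)
  })
  expect_lte(mean(fdp), 0.05)
})

test_that("strength comparison reproduces textbook ANOVA and F = t^2", {
  set.seed(47)
  two <- list(a = rnorm(12), b = rnorm(12, 0.5))
  res <- strength_comparison(two)
  tt <- t.test(two$a, two$b, var.equal = TRUE)
  expect_equal(res$anova$F, unname(tt$statistic)^2, tolerance = 1e-10)

  same <- list(a = c(1, 2, 3), b = c(1, 2, 3))
  expect_lt(strength_comparison(same)$anova$F, 1e-20)

  three <- list(a = rnorm(10), b = rnorm(15, 0.3), c = rnorm(8, -0.2))
  res3 <- strength_comparison(three)
  oracle <- anova_oracle(three)
  expect_equal(res3$anova$F, oracle$F, tolerance = 1e-10)
  expect_equal(res3$anova$df1, oracle$df1)
  expect_equal(res3$anova$df2, oracle$df2)
  expect_equal(res3$anova$p, oracle$p, tolerance = 1e-10)
  expect_equal(nrow(res3$posthoc), 3L)
})

test_that("distance dependence recovers the built-in decay and flags degeneracy", {
  cfg <- tiny_config(n_rois = 20, artifact_gain = 0, dropout_gain = 0,
                     n_frames = 2000)
  scan <- make_scan(cfg, seed = 21)
  geom <- scan$ground_truth$roi_geometry
  dd <- distance_dependence(unclass(fc_matrix(scan$ts)), roi_distances(geom))
  expect_lt(dd$r, 0)
  expect_false(dd$degenerate)

  fc <- fc_matrix(scan$ts)
  zero <- censor_distance_shift(fc, fc, roi_distances(geom))
  expect_true(zero$degenerate)

  # 4-ROI hand case against a direct Pearson
  m <- matrix(0, 4, 4)
  m[upper.tri(m)] <- c(.5, .4, .3, .2, .1, .05)
  m <- m + t(m)
  g4 <- make_geometry(4, seed = 2)
  d4 <- roi_distances(g4)
  res4 <- distance_dependence(m, d4)
  expect_equal(res4$r, cor(m[upper.tri(m)], d4[upper.tri(d4)]),
               tolerance = 1e-12)
})

test_that("bootstrap draws are deterministic and respect preconditions", {
  tab <- make_assoc_table(40, seed = 3)
  tab$pma_weeks <- runif(40, 38, 45)
  a <- pma_association(tab, "net", n_boot = 50, seed = 9)
  b <- pma_association(tab, "net", n_boot = 50, seed = 9)
  expect_identical(a$z_simple, b$z_simple)
  expect_identical(a$z_partial, b$z_partial)
  expect_equal(length(a$z_simple), 50L)

  expect_error(pma_association(tab[1:8, ], "net"),
               class = "neomotion_validation_error")
  expect_error(pma_association(tab, "net", subset_frac = 0.05),
               class = "neomotion_validation_error")
})

test_that("controlling FD recovers the age effect under a linear confound", {
  hits <- 0
  for (s in 1:20) {
    set.seed(300 + s)
    n <- 200
    pma <- runif(n, 38, 45)
    fd <- runif(n, 0.02, 0.5)
    strength <- 0.05 * pma + 1.2 * fd + rnorm(n, sd = 0.25)
    tab <- tibble::tibble(scan_id = seq_len(n), pma_weeks = pma,
                          mean_fd = fd, z_net = strength)
    res <- pma_association(tab, "net", n_boot = 200, seed = s)
    if (res$mean_partial > res$mean_simple) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("partial equals simple correlation when motion is no confound", {
  set.seed(48)
  n <- 200
  pma <- runif(n, 38, 45)
  fd <- runif(n, 0.02, 0.5)   # independent of both
  strength <- 0.05 * pma + rnorm(n, sd = 0.25)
  tab <- tibble::tibble(scan_id = seq_len(n), pma_weeks = pma,
                        mean_fd = fd, z_net = strength)
  res <- pma_association(tab, "net", n_boot = 1000, seed = 5)
  expect_lt(abs(res$mean_partial - res$mean_simple), 0.02)
})

test_that("fdr_bh agrees with the hand step-up rule exactly", {
  r <- fdr_bh(c(0.001, 0.5, 0.9), q = 0.05)
  expect_equal(r$mask, c(TRUE, FALSE, FALSE))
  expect_equal(sum(fdr_bh(rep(1, 10))$mask), 0L)

  set.seed(49)
  for (k in 1:100) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    q <- sample(c(0.01, 0.05, 0.1), 1)
    res <- fdr_bh(p, q)
    expect_identical(res$mask, bh_oracle_mask(p, q))
    expect_true(all(diff(res$q_values[order(p)]) >= -1e-15))
  }
  expect_error(fdr_bh(c(0.1, 1.2)), class = "neomotion_validation_error")
})
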