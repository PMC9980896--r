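# Cohort-level motion-connectivity association statistics.

#' Pearson association between mean FD and a network strength
#'
#' @param cohort cohort table (one row per scan for the chosen censoring
#'   condition) with a `mean_fd` column and a strength column.
#' @param network strength column name, with or without the `z_` prefix used
#'   by the pipeline tables.
#' @param condition optional censoring tag; when the table has a `condition`
#'   column, rows are filtered to it.
#' @return tibble `r`, `p`, `n`, `condition`, `variable_pair`.
#' @export
fd_fc_association <- function(cohort, network, condition = NULL) {
  rows <- cohort
  if (!is.null(condition) && "condition" %in% names(rows)) {
    rows <- rows[rows$condition == condition, , drop = FALSE]
  }
  col <- if (network %in% names(rows)) network else paste0("z_", network)
  if (!col %in% names(rows)) {
    abort_validation(paste("no strength column for network", network))
  }
  x <- rows$mean_fd
  y <- rows[[col]]
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4) abort_validation("need >= 4 scans with both variables")
  if (stats::sd(x) < .Machine$double.eps || stats::sd(y) < .Machine$double.eps) {
    abort_degenerate("constant variable; FD-FC correlation undefined")
  }
  ct <- stats::cor.test(x, y)
  tibble::tibble(r = unname(ct$estimate), p = ct$p.value, n = length(x),
                 condition = condition %||% NA_character_,
                 variable_pair = paste0("mean_fd~", col))
}

#' Edgewise FD-connectivity association over the whole connectome
#'
#' Correlates each connectome edge's Fisher-z value with per-scan mean FD
#' across the cohort and reports the fraction of edges significant at
#' `alpha`.
#'
#' @param fc_stack scans x edges matrix of Fisher-z edge values (see
#'   [fc_stack_from_matrices]), or a 3-D array (roi x roi x scan).
#' @param fd_values per-scan mean FD (mm).
#' @param alpha edge-level significance level (default 0.05).
#' @return tibble `edge`, `i`, `j`, `r`, `p`; attributes `frac_significant`,
#'   `n_edges`, `alpha`.
#' @export
edgewise_fd_association <- function(fc_stack, fd_values, alpha = 0.05) {
  if (length(dim(fc_stack)) == 3) fc_stack <- fc_stack_from_matrices(fc_stack)
  x <- as.matrix(fc_stack)
  if (nrow(x) != length(fd_values)) {
    abort_validation("fd_values length must equal the number of scans")
  }
  n <- nrow(x)
  r <- suppressWarnings(as.vector(stats::cor(fd_values, x)))
  tval <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tval), df = n - 2)
  idx <- attr(fc_stack, "edge_index")
  if (is.null(idx)) {
    m <- (1 + sqrt(1 + 8 * ncol(x))) / 2
    idx <- if (m == round(m)) edge_index(m) else
      data.frame(i = NA_integer_, j = NA_integer_)[rep(1, ncol(x)), ]
  }
  out <- tibble::tibble(edge = seq_len(ncol(x)), i = idx$i, j = idx$j,
                        r = r, p = p)
  attr(out, "frac_significant") <- mean(p < alpha, na.rm = TRUE)
  attr(out, "n_edges") <- ncol(x)
  attr(out, "alpha") <- alpha
  out
}

#' Stack FC matrices into a scans x edges matrix
#'
#' @param fcs list of [fc_matrix] objects (or a 3-D roi x roi x scan array).
#' @return scans x edges matrix with attribute `"edge_index"`.
#' @export
fc_stack_from_matrices <- function(fcs) {
  if (is.array(fcs) && length(dim(fcs)) == 3) {
    fcs <- lapply(seq_len(dim(fcs)[3]), function(k) fcs[, , k])
  }
  n <- nrow(fcs[[1]])
  stack <- t(vapply(fcs, function(m) edge_vector(unclass(m)), numeric(n * (n - 1) / 2)))
  attr(stack, "edge_index") <- edge_index(n)
  stack
}

#' Split a cohort into low- and high-motion groups
#'
#' The `fraction` of scans with the lowest mean FD forms the low-motion
#' group and the same number with the highest FD the high-motion group.
#' Group size is `floor(fraction * n)`; ties in mean FD are broken by scan
#' id, so the split is deterministic and the groups disjoint.
#'
#' @param cohort table with `scan_id` and `mean_fd` (one row per scan).
#' @param condition optional censoring tag filter (needs a `condition`
#'   column).
#' @param fraction group fraction in (0, 0.5] (default 0.25, a quartile
#'   split).
#' @return list `low`, `high` (scan ids), `n_per_group`, and per-group mean
#'   FD.
#' @export
split_by_motion <- function(cohort, condition = NULL, fraction = 0.25) {
  if (!is_number(fraction) || fraction <= 0 || fraction > 0.5) {
    abort_validation("fraction must lie in (0, 0.5]")
  }
  rows <- cohort
  if (!is.null(condition) && "condition" %in% names(rows)) {
    rows <- rows[rows$condition == condition, , drop = FALSE]
  }
  n <- nrow(rows)
  if (n < 8) abort_validation("need >= 8 scans for a motion split")
  ord <- order(rows$mean_fd, rows$scan_id)
  k <- floor(fraction * n)
  low <- rows$scan_id[ord[seq_len(k)]]
  high <- rows$scan_id[ord[seq(n - k + 1, n)]]
  list(low = low, high = high, n_per_group = k,
       mean_fd_low = mean(rows$mean_fd[rows$scan_id %in% low]),
       mean_fd_high = mean(rows$mean_fd[rows$scan_id %in% high]))
}

# Vectorized per-unit two-sample t (pooled or Welch).
unit_t_stats <- function(a, b, var_equal = TRUE) {
  n1 <- nrow(a); n2 <- nrow(b)
  m1 <- colMeans(a); m2 <- colMeans(b)
  v1 <- apply(a, 2, stats::var); v2 <- apply(b, 2, stats::var)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(m1))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  t <- (m2 - m1) / se   # direction: high > low when b is the high group
  p <- 2 * stats::pt(-abs(t), df = df)
  list(t = t, p = p, df = df, delta = m2 - m1, se = se)
}

#' Group contrast of connectivity maps (high- vs low-motion)
#'
#' Per-unit two-sample t test (Student pooled-variance by default, Welch by
#' flag), reported in the high > low direction with two-sided p values,
#' Benjamini-Hochberg q values, significance masks at the uncorrected and
#' FDR thresholds, and the mean z difference over significant units. Units
#' with zero variance in both groups are flagged and excluded from counts.
#'
#' @param maps_low,maps_high scans x units matrices of Fisher-z maps.
#' @param alpha_unc uncorrected threshold (default .01).
#' @param fdr_q FDR threshold (default .05).
#' @param var_equal pooled-variance t (default) or Welch (`FALSE`).
#' @return tibble per unit (`t`, `p`, `q`, `delta_z`, masks, `degenerate`);
#'   attributes `n_sig_unc`, `frac_sig_unc`, `n_sig_fdr`, `frac_sig_fdr`,
#'   `mean_delta_sig_unc`, `mean_delta_sig_fdr`, `group_sizes`.
#' @export
group_contrast <- function(maps_low, maps_high, alpha_unc = 0.01,
                           fdr_q = 0.05, var_equal = TRUE) {
  a <- as.matrix(maps_low); b <- as.matrix(maps_high)
  if (ncol(a) != ncol(b)) abort_validation("map unit counts differ")
  if (nrow(a) < 2 || nrow(b) < 2) abort_validation("need >= 2 maps per group")
  st <- unit_t_stats(a, b, var_equal)
  degen <- !is.finite(st$t)
  p <- st$p
  q <- rep(NA_real_, length(p))
  ok <- !degen
  if (any(ok)) q[ok] <- fdr_bh(p[ok], fdr_q)$q_values
  sig_unc <- ok & p < alpha_unc
  sig_fdr <- ok & !is.na(q) & q <= fdr_q
  out <- tibble::tibble(unit = seq_along(p), t = st$t, p = p, q = q,
                        delta_z = st$delta, sig_unc = sig_unc,
                        sig_fdr = sig_fdr, degenerate = degen)
  n_ok <- sum(ok)
  attr(out, "n_sig_unc") <- sum(sig_unc)
  attr(out, "frac_sig_unc") <- if (n_ok) sum(sig_unc) / n_ok else NA_real_
  attr(out, "n_sig_fdr") <- sum(sig_fdr)
  attr(out, "frac_sig_fdr") <- if (n_ok) sum(sig_fdr) / n_ok else NA_real_
  attr(out, "mean_delta_sig_unc") <-
    if (any(sig_unc)) mean(st$delta[sig_unc]) else NA_real_
  attr(out, "mean_delta_sig_fdr") <-
    if (any(sig_fdr)) mean(st$delta[sig_fdr]) else NA_real_
  attr(out, "group_sizes") <- c(low = nrow(a), high = nrow(b))
  out
}

#' Within-group significance map (one-sample t with FDR)
#'
#' @param maps scans x units matrix of Fisher-z maps.
#' @param fdr_q FDR threshold (default .05).
#' @return tibble `unit`, `t`, `p`, `q`, `sig`.
#' @export
within_group_map <- function(maps, fdr_q = 0.05) {
  m <- as.matrix(maps)
  if (nrow(m) < 2) abort_validation("need >= 2 maps")
  n <- nrow(m)
  mu <- colMeans(m)
  se <- apply(m, 2, stats::sd) / sqrt(n)
  t <- ifelse(se > 0, mu / se, ifelse(mu == 0, 0, Inf))
  p <- 2 * stats::pt(-abs(t), df = n - 1)
  p[!is.finite(t)] <- 0
  bh <- fdr_bh(p, fdr_q)
  tibble::tibble(unit = seq_along(p), t = t, p = p, q = bh$q_values,
                 sig = bh$mask)
}

#' Compare censoring conditions: one-way ANOVA with post hoc t tests
#'
#' Takes the per-unit z differences (high minus low motion) obtained under
#' each censoring condition and tests whether censoring changes the strength
#' of the motion effect: a one-way ANOVA across conditions followed by all
#' pairwise two-sample t tests (pooled variance).
#'
#' @param delta_sets named list of numeric vectors, one per condition.
#' @return list `anova` (tibble `F`, `df1`, `df2`, `p`) and `posthoc`
#'   (tibble `a`, `b`, `t`, `df`, `p`).
#' @export
strength_comparison <- function(delta_sets) {
  if (length(delta_sets) < 2) abort_validation("need >= 2 conditions")
  if (any(vapply(delta_sets, length, 0L) < 2)) {
    abort_validation("need >= 2 values per condition")
  }
  if (is.null(names(delta_sets))) {
    names(delta_sets) <- sprintf("cond%d", seq_along(delta_sets))
  }
  df <- data.frame(
    value = unlist(delta_sets, use.names = FALSE),
    condition = factor(rep(names(delta_sets),
                           vapply(delta_sets, length, 0L))))
  fit <- stats::aov(value ~ condition, data = df)
  s <- summary(fit)[[1]]
  anova_tab <- tibble::tibble(F = s[["F value"]][1], df1 = s[["Df"]][1],
                              df2 = s[["Df"]][2], p = s[["Pr(>F)"]][1])
  combos <- utils::combn(names(delta_sets), 2)
  posthoc <- do.call(rbind, lapply(seq_len(ncol(combos)), function(k) {
    a <- combos[1, k]; b <- combos[2, k]
    tt <- stats::t.test(delta_sets[[a]], delta_sets[[b]], var.equal = TRUE)
    data.frame(a = a, b = b, t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value)
  }))
  list(anova = anova_tab, posthoc = tibble::as_tibble(posthoc))
}

#' Distance dependence of connectivity
#'
#' `distance_dependence` correlates cohort-mean edge z values with inter-ROI
#' distance; `censor_distance_shift` correlates the censoring-induced change
#' (uncensored minus censored) with distance, the signature of
#' distance-dependent motion artifact removal.
#'
#' @param mean_fc ROIs x ROIs matrix of cohort-mean Fisher-z values (or
#'   [fc_matrix]).
#' @param distances ROIs x ROIs distance matrix (mm).
#' @return tibble `r`, `p`, `n`, `degenerate`.
#' @export
distance_dependence <- function(mean_fc, distances) {
  z <- edge_vector(unclass(as.matrix(mean_fc)))
  d <- edge_vector(as.matrix(distances))
  ok <- is.finite(z) & is.finite(d)
  z <- z[ok]; d <- d[ok]
  if (length(z) < 3 || stats::sd(z) < .Machine$double.eps ||
      stats::sd(d) < .Machine$double.eps) {
    return(tibble::tibble(r = NA_real_, p = NA_real_, n = length(z),
                          degenerate = TRUE))
  }
  ct <- stats::cor.test(z, d)
  tibble::tibble(r = unname(ct$estimate), p = ct$p.value, n = length(z),
                 degenerate = FALSE)
}

#' @param fc_uncensored,fc_censored matched FC matrices.
#' @rdname distance_dependence
#' @export
censor_distance_shift <- function(fc_uncensored, fc_censored, distances) {
  diff <- unclass(as.matrix(fc_uncensored)) - unclass(as.matrix(fc_censored))
  distance_dependence(diff, distances)
}

# First-order partial correlation via double residualization.
partial_cor <- function(x, y, z) {
  rx <- stats::lm.fit(cbind(1, z), x)$residuals
  ry <- stats::lm.fit(cbind(1, z), y)$residuals
  stats::cor(rx, ry)
}

#' Bootstrap comparison of simple and partial age-connectivity correlation
#'
#' Each replicate draws `floor(subset_frac * n)` scans (without replacement
#' by default: subsampling) and computes the Fisher-z of the simple Pearson
#' correlation between PMA and network strength and, when `control_fd`, of
#' the first-order partial correlation controlling mean FD (double
#' residualization). Reports both distributions, a one-sample t test of the
#' mean z against 0, and a paired t test of the partial-minus-simple
#' increment across replicates.
#'
#' @param cohort table with `pma_weeks`, `mean_fd`, and the strength column
#'   (one row per scan; filtered by `condition` when given).
#' @param network strength column name (with or without `z_` prefix).
#' @param condition optional censoring tag filter.
#' @param control_fd also compute the partial correlation (default `TRUE`).
#' @param n_boot replicates (default 5000).
#' @param subset_frac subset fraction per replicate (default 0.5).
#' @param seed RNG seed for the replicate draws.
#' @param replace draw with replacement (classic bootstrap) instead of
#'   subsampling.
#' @return `bootstrap_result` list: `z_simple`, `z_partial`, their means and
#'   SDs, `p_simple`, `p_partial` (one-sample), `p_paired`, `n_boot`,
#'   `subset_frac`, `seed`, `n`.
#' @export
pma_association <- function(cohort, network, condition = NULL,
                            control_fd = TRUE, n_boot = 5000,
                            subset_frac = 0.5, seed = 1L, replace = FALSE) {
  rows <- cohort
  if (!is.null(condition) && "condition" %in% names(rows)) {
    rows <- rows[rows$condition == condition, , drop = FALSE]
  }
  col <- if (network %in% names(rows)) network else paste0("z_", network)
  if (!col %in% names(rows)) {
    abort_validation(paste("no strength column for network", network))
  }
  if (!"pma_weeks" %in% names(rows)) abort_validation("missing pma_weeks column")
  pma <- rows$pma_weeks
  strength <- rows[[col]]
  fd <- rows$mean_fd
  ok <- is.finite(pma) & is.finite(strength) & (!control_fd | is.finite(fd))
  pma <- pma[ok]; strength <- strength[ok]
  if (control_fd) fd <- fd[ok]
  n <- length(pma)
  if (n < 10) abort_validation("need >= 10 scans for the bootstrap analysis")
  m <- floor(subset_frac * n)
  if (m < 4) abort_validation("subset too small for partial correlation (< 4)")
  z_simple <- numeric(n_boot)
  z_partial <- if (control_fd) numeric(n_boot) else NULL
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, m, replace = replace)
      z_simple[b] <- fisher_z(stats::cor(pma[idx], strength[idx]))
      if (control_fd) {
        z_partial[b] <- fisher_z(partial_cor(pma[idx], strength[idx], fd[idx]))
      }
    }
  })
  t_simple <- stats::t.test(z_simple)
  res <- list(z_simple = z_simple, z_partial = z_partial,
              mean_simple = mean(z_simple), sd_simple = stats::sd(z_simple),
              p_simple = t_simple$p.value,
              mean_partial = if (control_fd) mean(z_partial) else NA_real_,
              sd_partial = if (control_fd) stats::sd(z_partial) else NA_real_,
              p_partial = if (control_fd) stats::t.test(z_partial)$p.value
                          else NA_real_,
              p_paired = if (control_fd)
                stats::t.test(z_partial, z_simple, paired = TRUE)$p.value
                else NA_real_,
              n_boot = n_boot, subset_frac = subset_frac, seed = seed, n = n)
  class(res) <- "bootstrap_result"
  res
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("bootstrap (%d reps, %.0f%% subsets, n = %d):\n",
              x$n_boot, 100 * x$subset_frac, x$n))
  cat(sprintf("  simple  z(PMA, strength)      = %.3f +/- %.3f\n",
              x$mean_simple, x$sd_simple))
  if (!is.null(x$z_partial)) {
    cat(sprintf("  partial z(PMA, strength | FD) = %.3f +/- %.3f (paired p = %.2g)\n",
                x$mean_partial, x$sd_partial, x$p_paired))
  }
  invisible(x)
}

#' Benjamini-Hochberg false-discovery-rate control
#'
#' Step-up procedure: monotone q values (via [stats::p.adjust]) and the
#' rejection mask at level `q`.
#'
#' @param p_values numeric p values in `[0, 1]`.
#' @param q FDR level (default .05).
#' @return list `mask` (logical rejections), `q_values`.
#' @export
fdr_bh <- function(p_values, q = 0.05) {
  p <- as.numeric(p_values)
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    abort_validation("p values must lie in [0, 1]")
  }
  qv <- stats::p.adjust(p, method = "BH")
  list(mask = qv <= q, q_values = qv)
}
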