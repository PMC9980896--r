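# Shared fixtures: tiny configs and independent oracles.

tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(n_scans = 6, n_frames = 120, tr_seconds = 2, n_rois = 8,
                   seed = 7L)
  do.call(synthetic_config, utils::modifyList(defaults, args))
}

# Independent straight-loop oracle for frame-wise displacement.
fd_oracle <- function(params, r = 30) {
  n <- nrow(params)
  fd <- numeric(n)
  for (i in seq_len(n)[-1]) {
    s <- 0
    for (j in 1:3) s <- s + abs(params[i - 1, j] - params[i, j])
    for (j in 4:6) s <- s + r * abs(params[i - 1, j] - params[i, j])
    fd[i] <- s / 6
  }
  fd
}

# Hand-computed Benjamini-Hochberg step-up: reject all p <= p_(k) with
# k = max{ i : p_(i) <= i q / m }.
bh_oracle_mask <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  sorted <- p[ord]
  k <- 0
  for (i in seq_len(m)) if (sorted[i] <= i * q / m) k <- i
  mask <- rep(FALSE, m)
  if (k > 0) mask[p <= sorted[k]] <- TRUE
  mask
}

# Textbook one-way ANOVA oracle.
anova_oracle <- function(groups) {
  all_v <- unlist(groups)
  grand <- mean(all_v)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2, 0))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  df1 <- length(groups) - 1
  df2 <- length(all_v) - length(groups)
  f <- (ssb / df1) / (ssw / df2)
  list(F = f, df1 = df1, df2 = df2, p = stats::pf(f, df1, df2, lower.tail = FALSE))
}

# Amplitude of a sinusoid at frequency f recovered by least squares.
sinusoid_amplitude <- function(x, f, tr) {
  t <- (seq_along(x) - 1) * tr
  fit <- stats::lm(x ~ sin(2 * pi * f * t) + cos(2 * pi * f * t))
  sqrt(sum(stats::coef(fit)[2:3]^2))
}
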