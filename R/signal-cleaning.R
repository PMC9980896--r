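# Nuisance designs, simultaneous regression + band-pass filtering, tSNR.

#' Friston 24-parameter motion regressor set
#'
#' Expands six rigid-body motion estimates into 24 regressors: the six
#' parameters, their backward differences (first row 0), and the squares of
#' both sets, in that column order.
#'
#' @param motion a [motion_params] object or frames x 6 matrix.
#' @return frames x 24 matrix with labelled columns.
#' @export
friston24 <- function(motion) {
  m <- as_motion_matrix(motion)
  if (nrow(m) < 2) abort_validation("friston24 needs >= 2 frames")
  d <- rbind(0, diff(m))
  out <- cbind(m, d, m^2, d^2)
  base <- c("dx", "dy", "dz", "roll", "pitch", "yaw")
  colnames(out) <- c(base, paste0("d_", base), paste0(base, "_sq"),
                     paste0("d_", base, "_sq"))
  out
}

#' White-matter mean and CSF principal-component regressors
#'
#' One column is the per-frame mean across white-matter voxels; `n_pcs`
#' columns are the leading principal components of the column-centred CSF
#' signals (aCompCor-style). PC signs are fixed deterministically so the
#' largest-magnitude voxel loading is positive. Components with near-zero
#' variance are flagged via the `"near_zero_variance"` attribute.
#'
#' @param wm_timeseries frames x voxels white-matter matrix.
#' @param csf_timeseries frames x voxels CSF matrix.
#' @param n_pcs number of CSF components (default 3).
#' @return frames x (1 + n_pcs) matrix, columns `wm_mean`, `csf_pc1`, ...
#' @export
tissue_regressors <- function(wm_timeseries, csf_timeseries, n_pcs = 3) {
  wm <- as.matrix(wm_timeseries)
  csf <- as.matrix(csf_timeseries)
  if (nrow(wm) != nrow(csf)) abort_validation("WM and CSF frame counts differ")
  if (ncol(csf) < n_pcs + 1) {
    abort_validation(sprintf("need at least %d CSF voxels for %d components",
                             n_pcs + 1, n_pcs))
  }
  centred <- sweep(csf, 2, colMeans(csf))
  sv <- svd(centred, nu = n_pcs, nv = n_pcs)
  pcs <- sv$u[, seq_len(n_pcs), drop = FALSE] %*%
    diag(sv$d[seq_len(n_pcs)], n_pcs)
  # deterministic sign: largest-|loading| voxel positive
  for (k in seq_len(n_pcs)) {
    v <- sv$v[, k]
    if (v[which.max(abs(v))] < 0) pcs[, k] <- -pcs[, k]
  }
  tot <- sum(sv$d^2)
  nz <- if (tot > 0) (sv$d[seq_len(n_pcs)]^2 / tot) < 1e-10 else rep(TRUE, n_pcs)
  out <- cbind(rowMeans(wm), pcs)
  colnames(out) <- c("wm_mean", paste0("csf_pc", seq_len(n_pcs)))
  attr(out, "near_zero_variance") <- which(nz)
  out
}

#' Global (gray-matter mean) signal
#'
#' @param gray_timeseries frames x units matrix of gray-matter signals
#'   (voxels or ROIs).
#' @return numeric per-frame mean.
#' @export
global_signal <- function(gray_timeseries) {
  g <- as.matrix(gray_timeseries)
  if (ncol(g) < 1) abort_validation("need >= 1 gray-matter unit")
  rowMeans(g)
}

#' Assemble a labelled nuisance design matrix
#'
#' Always includes an intercept and a linear drift term; optional groups are
#' the 24 motion regressors, the white-matter mean, CSF principal components,
#' and the global signal.
#'
#' @param n_frames number of frames.
#' @param motion optional [motion_params] (adds [friston24] columns).
#' @param wm,csf optional tissue matrices (adds [tissue_regressors] columns).
#' @param n_csf_pcs CSF components when `csf` given (default 3).
#' @param gray optional gray-matter matrix; with `gsr = TRUE` its mean is
#'   added as a `global` column.
#' @param gsr enable global signal regression.
#' @return frames x K matrix, labelled columns, attribute `"rank"`.
#' @export
nuisance_design <- function(n_frames, motion = NULL, wm = NULL, csf = NULL,
                            n_csf_pcs = 3, gray = NULL, gsr = FALSE) {
  cols <- list(intercept = rep(1, n_frames),
               drift = seq_len(n_frames) - (n_frames + 1) / 2)
  x <- do.call(cbind, cols)
  if (!is.null(motion)) x <- cbind(x, friston24(motion))
  if (!is.null(wm) || !is.null(csf)) {
    if (is.null(wm) || is.null(csf)) {
      abort_validation("supply both wm and csf (or neither)")
    }
    x <- cbind(x, tissue_regressors(wm, csf, n_csf_pcs))
  }
  if (gsr) {
    if (is.null(gray)) abort_validation("gsr = TRUE requires gray-matter signals")
    x <- cbind(x, global = global_signal(gray))
  }
  if (nrow(x) != n_frames) abort_validation("design row count mismatch")
  zero <- apply(x, 2, function(v) all(v == 0))
  if (any(zero)) {
    warning(sprintf("dropping all-zero design column(s): %s",
                    paste(colnames(x)[zero], collapse = ", ")))
    x <- x[, !zero, drop = FALSE]
  }
  attr(x, "rank") <- qr(x)$rank
  x
}

# Sine/cosine regressors at every DFT frequency outside [low, high] Hz
# (band edges inclusive on the retained side). DC is handled by the
# intercept; for even N the Nyquist bin contributes only a cosine.
spectral_regressors <- function(n_frames, band_hz, tr_seconds) {
  low <- band_hz[1]; high <- band_hz[2]
  nyquist <- 1 / (2 * tr_seconds)
  if (!(low >= 0 && low < high && high < nyquist)) {
    abort_validation("band must satisfy 0 <= low < high < Nyquist")
  }
  t <- seq_len(n_frames) - 1
  ks <- seq_len(floor(n_frames / 2))
  freqs <- ks / (n_frames * tr_seconds)
  out_of_band <- freqs < low | freqs > high
  ks <- ks[out_of_band]
  if (length(ks) == 0) return(matrix(0, n_frames, 0))
  cols <- lapply(ks, function(k) {
    ang <- 2 * pi * k * t / n_frames
    if (n_frames %% 2 == 0 && k == n_frames / 2) {
      m <- cbind(cos(ang)); colnames(m) <- sprintf("cos_k%d", k); m
    } else {
      m <- cbind(sin(ang), cos(ang))
      colnames(m) <- sprintf(c("sin_k%d", "cos_k%d"), k); m
    }
  })
  do.call(cbind, cols)
}

#' Simultaneous nuisance regression and band-pass filtering
#'
#' Removes the nuisance design and all out-of-band frequencies in a single
#' least-squares projection: sine/cosine regressors at every discrete Fourier
#' frequency outside `band_hz` are appended to the design and the residuals
#' are returned. Doing both in one projection avoids reintroducing filtered
#' frequencies through the regression step. An intercept and linear drift are
#' always removed, even with an empty nuisance set.
#'
#' @param ts frames x units numeric matrix.
#' @param design optional nuisance matrix from [nuisance_design] (or any
#'   frames x K matrix).
#' @param band_hz retained passband, `c(low, high)` in Hz
#'   (default `c(0.009, 0.08)`).
#' @param tr_seconds repetition time in seconds.
#' @return residual matrix (same shape as `ts`) with attributes
#'   `"n_freq_regressors"`, `"design_rank"` and `"rank_deficient"`.
#' @export
clean_timeseries <- function(ts, design = NULL, band_hz = c(0.009, 0.08),
                             tr_seconds) {
  y <- as.matrix(ts)
  n <- nrow(y)
  if (!is_number(tr_seconds) || tr_seconds <= 0) {
    abort_validation("tr_seconds must be a positive number")
  }
  base <- cbind(intercept = rep(1, n), drift = seq_len(n) - (n + 1) / 2)
  x <- base
  if (!is.null(design)) {
    design <- as.matrix(design)
    if (nrow(design) != n) abort_validation("design frame count mismatch")
    keep <- if (is.null(colnames(design))) rep(TRUE, ncol(design)) else
      !colnames(design) %in% c("intercept", "drift")
    x <- cbind(x, design[, keep, drop = FALSE])
  }
  spec <- spectral_regressors(n, band_hz, tr_seconds)
  x <- cbind(x, spec)
  if (ncol(x) >= n) {
    abort_validation(sprintf(
      "combined design has %d columns for %d frames; nothing would remain",
      ncol(x), n))
  }
  qx <- qr(x)
  deficient <- qx$rank < ncol(x)
  if (deficient) {
    warning(sprintf("combined design is rank deficient (rank %d of %d columns); %s",
                    qx$rank, ncol(x),
                    "projecting onto its column space"))
  }
  res <- qr.resid(qx, y)
  dimnames(res) <- dimnames(y)
  structure(res,
            n_freq_regressors = ncol(spec),
            design_rank = qx$rank,
            rank_deficient = deficient)
}

#' Temporal signal-to-noise ratio
#'
#' Per-unit temporal mean divided by temporal standard deviation (denominator
#' n - 1), computed on raw (pre-regression) data; the summary is the mean over
#' the masked units. Zero-variance units are excluded from the summary and
#' counted.
#'
#' @param raw_ts frames x units matrix.
#' @param mask optional logical/index selection of units.
#' @return list with `tsnr` (per-unit, `NA` where SD is 0), `mean_tsnr`,
#'   and `n_zero_sd`.
#' @export
compute_tsnr <- function(raw_ts, mask = NULL) {
  y <- as.matrix(raw_ts)
  if (nrow(y) < 2) abort_validation("tSNR needs >= 2 frames")
  if (!is.null(mask)) y <- y[, mask, drop = FALSE]
  mu <- colMeans(y)
  sdv <- apply(y, 2, stats::sd)
  zero <- sdv < .Machine$double.eps
  if (all(zero)) abort_degenerate("all units have zero temporal variance")
  tsnr <- ifelse(zero, NA_real_, mu / sdv)
  list(tsnr = tsnr, mean_tsnr = mean(tsnr[!zero]), n_zero_sd = sum(zero))
}
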