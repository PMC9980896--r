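# Synthetic multi-scan cohort with known ground truth: mirrored ROI geometry,
# distance-decaying covariance, burst-like motion, motion-coupled artifacts
# and noise, and an age covariate independent of motion.

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the acquisition and cohort statistics of a neonatal
#' resting-state study: 149 scans of 200 volumes at TR 2 s over a 90-region
#' parcellation, postmenstrual ages 37.7-47.7 weeks, and a motion profile of
#' long quiet stretches broken by sudden surges whose frequency varies
#' strongly between scans (cohort mean FD ~ 0.13 mm with between-scan SD of
#' the same order).
#'
#' @param n_scans number of scans in the cohort.
#' @param n_frames volumes per scan (>= 2).
#' @param tr_seconds repetition time in seconds.
#' @param n_rois even number of ROIs (>= 4), arranged as mirrored
#'   left/right homotopic pairs.
#' @param homotopic_strength weight in (-1, 1) of the shared factor driving
#'   each homotopic pair; the realized homotopic correlation is
#'   `h + (1 - h) * k` where `k` is the distance-kernel value for the pair.
#' @param distance_decay_mm length scale (mm) of the `exp(-d / lambda)`
#'   baseline covariance decay.
#' @param burst_rate mean per-frame probability of a motion surge. Scan-level
#'   rates are log-normal around this value but capped at `2 * burst_rate`,
#'   which keeps every scan's surviving data above the 4-minute cap even at
#'   the strict 0.2 mm threshold (matching cohorts where nearly all scans
#'   retain a full analysis window).
#' @param burst_rate_log_sd SD of the log-normal scan-level multiplier on
#'   `burst_rate` (between-scan motion heterogeneity; 0 disables it).
#' @param burst_amp_mm scale (mm) of the half-normal total displacement of a
#'   surge, split across a random subset of the six parameters.
#' @param burst_amp_log_sd SD of the log-normal scan-level multiplier on
#'   `burst_amp_mm`; the amplitude tail is what produces rare scans with very
#'   large mean FD at a modest censored fraction.
#' @param baseline_jitter_mm random-walk step SD (mm) of the quiet-breathing
#'   baseline drift of each parameter.
#' @param artifact_gain coupling of the shared artifact to motion: the
#'   artifact added at frame i is `artifact_gain * FD_i^2 * w` with per-ROI
#'   signed weights `w` (quadratic in FD: artifacts are dominated by large
#'   excursions, so sub-threshold frames carry little).
#' @param dropout_gain coupling of white-noise SD to FD: noise SD at frame i
#'   is `dropout_gain * FD_i` (signal loss in high-motion frames, which is
#'   what couples tSNR to motion).
#' @param pma_range_weeks postmenstrual-age interval sampled uniformly.
#' @param pma_slope change of the homotopic pair-factor weight per week, on
#'   the Fisher-z scale about the range midpoint.
#' @param seed master seed; all cohort randomness derives from it.
#' @return a validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_scans = 149, n_frames = 200, tr_seconds = 2,
                             n_rois = 90, homotopic_strength = 0.5,
                             distance_decay_mm = 40, burst_rate = 0.08,
                             burst_rate_log_sd = 1.2, burst_amp_mm = 2.2,
                             burst_amp_log_sd = 0.8,
                             baseline_jitter_mm = 0.06, artifact_gain = 16,
                             dropout_gain = 1,
                             pma_range_weeks = c(37.7, 47.7),
                             pma_slope = 0.02, seed = 1L) {
  cfg <- list(n_scans = n_scans, n_frames = n_frames, tr_seconds = tr_seconds,
              n_rois = n_rois, homotopic_strength = homotopic_strength,
              distance_decay_mm = distance_decay_mm, burst_rate = burst_rate,
              burst_rate_log_sd = burst_rate_log_sd,
              burst_amp_mm = burst_amp_mm,
              burst_amp_log_sd = burst_amp_log_sd,
              baseline_jitter_mm = baseline_jitter_mm,
              artifact_gain = artifact_gain, dropout_gain = dropout_gain,
              pma_range_weeks = pma_range_weeks, pma_slope = pma_slope,
              seed = as.integer(seed))
  if (!is_count(cfg$n_scans) || cfg$n_scans < 1) {
    abort_validation("n_scans must be a positive count")
  }
  if (!is_count(cfg$n_frames) || cfg$n_frames < 2) {
    abort_validation("n_frames must be >= 2")
  }
  if (!is_count(cfg$n_rois) || cfg$n_rois < 4 || cfg$n_rois %% 2 != 0) {
    abort_validation("n_rois must be an even count >= 4")
  }
  if (!is_number(cfg$homotopic_strength) || abs(cfg$homotopic_strength) >= 1) {
    abort_validation("homotopic_strength must lie in (-1, 1)")
  }
  if (!is_number(cfg$distance_decay_mm) || cfg$distance_decay_mm <= 0) {
    abort_validation("distance_decay_mm must be > 0")
  }
  if (!is_number(cfg$burst_rate) || cfg$burst_rate < 0 || cfg$burst_rate > 1) {
    abort_validation("burst_rate must lie in [0, 1]")
  }
  nonneg <- c("burst_rate_log_sd", "burst_amp_mm", "burst_amp_log_sd",
              "baseline_jitter_mm", "artifact_gain", "dropout_gain")
  for (f in nonneg) {
    if (!is_number(cfg[[f]]) || cfg[[f]] < 0) {
      abort_validation(paste(f, "must be a nonnegative number"))
    }
  }
  if (!(length(cfg$pma_range_weeks) == 2 &&
        all(is.finite(cfg$pma_range_weeks)) &&
        cfg$pma_range_weeks[1] <= cfg$pma_range_weeks[2])) {
    abort_validation("pma_range_weeks must be an ordered interval")
  }
  if (!is_number(cfg$tr_seconds) || cfg$tr_seconds <= 0) {
    abort_validation("tr_seconds must be > 0")
  }
  class(cfg) <- "synthetic_config"
  cfg
}

#' Mirrored homotopic ROI geometry
#'
#' Draws `n_rois / 2` centroids in the right hemisphere (x > 0 within a
#' brain-sized box, in mm) and mirrors each across the midsagittal plane
#' (x -> -x) to create its homotopic partner. ROI `2k - 1` is the right
#' member and ROI `2k` its left mirror; the partner mapping is recorded
#' explicitly.
#'
#' @param n_rois even number of ROIs.
#' @param seed RNG seed.
#' @return an ROI table (see [validate_roi_table]).
#' @export
make_geometry <- function(n_rois, seed = 1L) {
  if (!is_count(n_rois) || n_rois < 2 || n_rois %% 2 != 0) {
    abort_validation("n_rois must be an even count >= 2")
  }
  half <- n_rois / 2
  # x >= 20 mm keeps mirrored partners >= 40 mm apart, as for real
  # homotopic cortical pairs
  cent <- with_seed(seed, cbind(stats::runif(half, 20, 60),
                                stats::runif(half, -70, 50),
                                stats::runif(half, -40, 60)))
  xyz <- matrix(NA_real_, n_rois, 3)
  xyz[seq(1, n_rois, 2), ] <- cent
  xyz[seq(2, n_rois, 2), ] <- cbind(-cent[, 1], cent[, 2:3])
  ids <- seq_len(n_rois)
  partner <- ifelse(ids %% 2 == 1, ids + 1L, ids - 1L)
  tab <- tibble::tibble(
    roi_id = ids,
    name = sprintf("roi%02d_%s", (ids + 1) %/% 2, ifelse(ids %% 2 == 1, "R", "L")),
    hemi = ifelse(ids %% 2 == 1, "R", "L"),
    partner_id = partner,
    x_mm = xyz[, 1], y_mm = xyz[, 2], z_mm = xyz[, 3])
  validate_roi_table(tab)
  tab
}

#' Named networks of the synthetic parcellation
#'
#' The first homotopic pairs carry fixed artifact couplings emulating the
#' network-specific motion effects seen in neonatal data: `motor` (pair 1,
#' same-sign weights, connectivity inflated by motion), `auditory` (pair 2,
#' opposite-sign weights, connectivity deflated), `visual` (pair 3, zero
#' weights, unaffected) and `dmn` (pair 4).
#'
#' @return named list mapping network name to the two `roi_id`s of its pair.
#' @export
synthetic_networks <- function() {
  list(motor = c(1L, 2L), auditory = c(3L, 4L), visual = c(5L, 6L),
       dmn = c(7L, 8L))
}

# Per-ROI signed artifact weights: fixed couplings on the named networks,
# mild random couplings elsewhere.
make_artifact_weights <- function(n_rois, seed) {
  w <- with_seed(seed, stats::rnorm(n_rois, 0, 0.5))
  w[1:2] <- c(1, 1)      # motor: shared artifact inflates homotopic FC
  w[3:4] <- c(1, -1)     # auditory: opposite signs deflate it
  if (n_rois >= 6) w[5:6] <- 0  # visual: clean
  w
}

#' Ground-truth inter-ROI covariance for one scan
#'
#' Positive definite by construction:
#' `Sigma = h * P + (1 - h) * K`, where `K = exp(-d / lambda)` is the
#' distance-decay kernel and `P` the block matrix of homotopic pair factors
#' (1 within a pair, 0 elsewhere). `h` is the pair-factor weight, shifted on
#' the Fisher-z scale by `pma_slope * (pma - midpoint)`. Unit diagonal.
#'
#' @param geometry ROI table from [make_geometry].
#' @param config a [synthetic_config].
#' @param pma_weeks scan age in weeks (defaults to the range midpoint).
#' @return correlation matrix with attribute `"homotopic_weight"`.
#' @export
true_covariance <- function(geometry, config,
                            pma_weeks = mean(config$pma_range_weeks)) {
  d <- roi_distances(geometry)
  k <- exp(-d / config$distance_decay_mm)
  mid <- mean(config$pma_range_weeks)
  h <- tanh(atanh(config$homotopic_strength) +
              config$pma_slope * (pma_weeks - mid))
  n <- nrow(k)
  p <- matrix(0, n, n)
  pos <- stats::setNames(seq_len(n), geometry$roi_id)
  p[cbind(seq_len(n), pos[as.character(geometry$partner_id)])] <- 1
  diag(p) <- 1
  sigma <- h * p + (1 - h) * k
  dimnames(sigma) <- dimnames(d)
  attr(sigma, "homotopic_weight") <- h
  sigma
}

#' Burst-like synthetic motion trace
#'
#' Six-parameter trace built as a small random walk (quiet baseline) plus
#' sparse single-frame surges: with per-frame probability `burst_rate` a
#' total displacement drawn half-normal with scale `burst_amp_mm` is split
#' across a random subset of parameters (rotations converted through the
#' 30 mm sphere). A surge at frame i elevates FD at frames i and i + 1.
#'
#' @param config a [synthetic_config].
#' @param seed RNG seed.
#' @param burst_rate per-frame surge probability (defaults to
#'   `config$burst_rate`; [make_cohort] passes scan-specific rates).
#' @param burst_amp_mm surge displacement scale (defaults to
#'   `config$burst_amp_mm`; [make_cohort] passes scan-specific scales).
#' @return a [motion_params] object; attribute `"burst_frames"` records the
#'   injected high-motion frame indices (1-based).
#' @export
make_motion_trace <- function(config, seed = config$seed,
                              burst_rate = config$burst_rate,
                              burst_amp_mm = config$burst_amp_mm) {
  n <- config$n_frames
  with_seed(seed, {
    steps <- matrix(stats::rnorm((n - 1) * 6, 0, config$baseline_jitter_mm),
                    n - 1, 6)
    steps[, 4:6] <- steps[, 4:6] / 30  # radians equivalent to mm at r = 30
    p <- rbind(0, apply(steps, 2, cumsum))
    burst <- stats::runif(n) < burst_rate
    burst[1] <- FALSE
    for (i in which(burst)) {
      k <- sample.int(6, 1)
      idx <- sample.int(6, k)
      total <- abs(stats::rnorm(1, 0, burst_amp_mm))
      share <- as.vector(stats::rmultinom(1, 100L, rep(1 / k, k))) / 100
      a <- total * share
      p[i, idx] <- p[i, idx] + ifelse(idx > 3, a / 30, a)
    }
    out <- motion_params(p, tr_seconds = config$tr_seconds)
    attr(out, "burst_frames") <- which(burst)
    out
  })
}

#' Generate one synthetic scan
#'
#' Latent ROI signals are drawn from a multivariate normal with the
#' ground-truth covariance (homotopic weight shifted by the scan's PMA);
#' each frame then receives a shared artifact `artifact_gain * FD^2 * w`
#' (per-ROI signed weights `w`) and white noise with SD
#' `dropout_gain * FD`, and a constant offset of 100 so tSNR is finite and
#' positive.
#'
#' @param config a [synthetic_config].
#' @param pma_weeks postmenstrual age of the scan.
#' @param seed RNG seed for this scan.
#' @param geometry,weights optionally precomputed cohort geometry/artifact
#'   weights (derived from `config$seed` when `NULL`).
#' @param burst_rate scan-specific surge probability.
#' @param burst_amp_mm scan-specific surge displacement scale.
#' @return list with `ts` (frames x ROIs), `motion`, `fd`, and
#'   `ground_truth` (true covariance, geometry, artifact weights, injected
#'   high-motion frames).
#' @export
make_scan <- function(config, pma_weeks = mean(config$pma_range_weeks),
                      seed = config$seed, geometry = NULL, weights = NULL,
                      burst_rate = config$burst_rate,
                      burst_amp_mm = config$burst_amp_mm) {
  if (is.null(geometry)) geometry <- make_geometry(config$n_rois, config$seed)
  if (is.null(weights)) {
    weights <- make_artifact_weights(config$n_rois, config$seed)
  }
  sigma <- true_covariance(geometry, config, pma_weeks)
  ch <- tryCatch(chol(sigma), error = function(e) {
    abort_validation("requested ground-truth covariance is not positive definite")
  })
  motion <- make_motion_trace(config, seed = seed, burst_rate = burst_rate,
                              burst_amp_mm = burst_amp_mm)
  fd <- compute_fd(motion)
  n <- config$n_frames
  p <- config$n_rois
  ts <- with_seed(seed + 500000L, {
    latent <- matrix(stats::rnorm(n * p), n, p) %*% ch
    artifact <- (config$artifact_gain * as.numeric(fd)^2) %o% weights
    noise <- matrix(stats::rnorm(n * p), n, p) *
      (config$dropout_gain * as.numeric(fd))
    100 + latent + artifact + noise
  })
  colnames(ts) <- as.character(geometry$roi_id)
  list(ts = ts, motion = motion, fd = fd,
       ground_truth = list(true_covariance = sigma,
                           roi_geometry = geometry,
                           artifact_weights = weights,
                           injected_high_motion_frames =
                             attr(motion, "burst_frames")))
}

#' Generate a synthetic cohort
#'
#' Per-scan seeds are `config$seed + scan index`, so any single scan is
#' regenerable. PMA is drawn uniformly over `pma_range_weeks` from the master
#' seed, independently of every motion draw; scan-level motion heterogeneity
#' comes from a log-normal multiplier on `burst_rate`.
#'
#' @param config a [synthetic_config].
#' @param timeseries generate ROI timeseries (`TRUE`) or motion traces only
#'   (`FALSE`, cheap mode for motion-level analyses).
#' @return `synthetic_cohort`: list with `scans`, `table`
#'   (scan_id, pma_weeks, sex), `geometry`, `weights`, `config`.
#' @export
make_cohort <- function(config, timeseries = TRUE) {
  geometry <- make_geometry(config$n_rois, config$seed)
  weights <- make_artifact_weights(config$n_rois, config$seed)
  n <- config$n_scans
  draws <- with_seed(config$seed, list(
    pma = stats::runif(n, config$pma_range_weeks[1], config$pma_range_weeks[2]),
    sex = sample(c("M", "F"), n, replace = TRUE),
    rate_mult = exp(stats::rnorm(n, 0, config$burst_rate_log_sd)),
    amp_mult = exp(stats::rnorm(n, 0, config$burst_amp_log_sd))
  ))
  # rate capped at twice the nominal value: censored fractions then stay
  # below the 4-minute cap's headroom, so no scan ends up under-length
  rates <- pmin(2 * config$burst_rate, config$burst_rate * draws$rate_mult)
  amps <- config$burst_amp_mm * draws$amp_mult
  scans <- lapply(seq_len(n), function(i) {
    if (timeseries) {
      make_scan(config, pma_weeks = draws$pma[i], seed = config$seed + i,
                geometry = geometry, weights = weights,
                burst_rate = rates[i], burst_amp_mm = amps[i])
    } else {
      motion <- make_motion_trace(config, seed = config$seed + i,
                                  burst_rate = rates[i],
                                  burst_amp_mm = amps[i])
      list(ts = NULL, motion = motion, fd = compute_fd(motion),
           ground_truth = NULL)
    }
  })
  table <- tibble::tibble(scan_id = sprintf("scan%03d", seq_len(n)),
                          pma_weeks = draws$pma, sex = draws$sex)
  names(scans) <- table$scan_id
  structure(list(scans = scans, table = table, geometry = geometry,
                 weights = weights, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic cohort: %d scans x %d frames (TR %gs), %d ROIs, seed %d\n",
              x$config$n_scans, x$config$n_frames, x$config$tr_seconds,
              x$config$n_rois, x$config$seed))
  invisible(x)
}

#' Write a synthetic scan and cohort to disk
#'
#' `write_scan_tsv` emits the ROI-by-time table; `write_motion_txt` the
#' 6-column whitespace-delimited motion parameters; `write_cohort_tsv` the
#' cohort table (`scan_id pma_weeks sex`); `write_scan_nifti` a small 4-D
#' NIfTI in which each ROI occupies a 2-voxel block, plus the matching
#' integer-label parcellation, to exercise the image path.
#'
#' @param scan a [make_scan] result.
#' @param path,prefix output location.
#' @rdname synthetic_io
#' @export
write_scan_tsv <- function(scan, path) {
  out <- data.frame(frame = seq_len(nrow(scan$ts)) - 1L, scan$ts,
                    check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname synthetic_io
#' @export
write_motion_txt <- function(scan, path) {
  utils::write.table(format(unclass(scan$motion), digits = 10), path,
                     sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @param cohort a [make_cohort] result.
#' @rdname synthetic_io
#' @export
write_cohort_tsv <- function(cohort, path) {
  utils::write.table(cohort$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname synthetic_io
#' @export
write_scan_nifti <- function(scan, prefix) {
  ts <- scan$ts
  geom <- scan$ground_truth$roi_geometry
  n_rois <- ncol(ts)
  n_t <- nrow(ts)
  img <- array(0, dim = c(2, n_rois, 1, n_t))
  for (j in seq_len(n_rois)) {
    img[1, j, 1, ] <- ts[, j]
    img[2, j, 1, ] <- ts[, j]
  }
  lab <- array(0L, dim = c(2, n_rois, 1))
  for (j in seq_len(n_rois)) lab[, j, 1] <- geom$roi_id[j]
  bold_path <- paste0(prefix, "_bold.nii.gz")
  parc_path <- paste0(prefix, "_parc.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(img), bold_path)
  RNifti::writeNifti(RNifti::asNifti(lab), parc_path)
  invisible(c(bold = bold_path, parcellation = parc_path))
}
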