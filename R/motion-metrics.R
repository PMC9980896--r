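# Frame-wise displacement and volume censoring.

#' Construct a motion-parameter object
#'
#' Wraps a frames x 6 matrix of rigid-body motion estimates: translations
#' along x, y, z in millimetres and rotations (roll, pitch, yaw) in radians.
#'
#' @param params numeric matrix with 6 columns
#'   (`dx`, `dy`, `dz`, `roll`, `pitch`, `yaw`).
#' @param tr_seconds repetition time in seconds (one value per frame period).
#' @return a `motion_params` object (a classed matrix with a `tr_seconds`
#'   attribute).
#' @export
motion_params <- function(params, tr_seconds = NA_real_) {
  params <- as.matrix(params)
  if (ncol(params) != 6) {
    abort_validation("motion parameters must have exactly 6 columns")
  }
  if (nrow(params) < 1) abort_validation("motion parameters need >= 1 frame")
  if (!all(is.finite(params))) {
    abort_validation("motion parameters contain non-finite values")
  }
  colnames(params) <- c("dx", "dy", "dz", "roll", "pitch", "yaw")
  attr(params, "tr_seconds") <- tr_seconds
  class(params) <- c("motion_params", class(params))
  params
}

as_motion_matrix <- function(motion) {
  m <- unclass(as.matrix(motion))
  if (ncol(m) != 6) abort_validation("expected a frames x 6 motion matrix")
  if (!all(is.finite(m))) abort_validation("motion parameters contain non-finite values")
  m
}

#' Frame-wise displacement from rigid-body motion estimates
#'
#' Converts rotations to a millimetre scale by modelling the head as a sphere
#' (neonatal default radius 30 mm) and summarises each frame-to-frame change
#' as the mean of the six absolute displacement terms:
#' \deqn{FD_i = (|\Delta d_x| + |\Delta d_y| + |\Delta d_z| +
#'   r|\Delta\phi| + r|\Delta\theta| + r|\Delta\psi|)/6}
#' with \eqn{\Delta} the backward difference and \eqn{FD_0 = 0}. Note the
#' division by 6 (a mean of terms): some widely used variants of this index
#' sum the six terms instead, so values here are one sixth of those.
#'
#' @param motion a [motion_params] object or frames x 6 matrix (rotations in
#'   radians).
#' @param head_radius_mm sphere radius used to convert radians to mm.
#' @return an `fd_trace`: numeric vector of per-frame displacement in mm,
#'   first element 0, with attributes `head_radius_mm` and `tr_seconds`.
#' @export
compute_fd <- function(motion, head_radius_mm = 30) {
  m <- as_motion_matrix(motion)
  if (!is_number(head_radius_mm) || head_radius_mm < 0) {
    abort_validation("head_radius_mm must be a single nonnegative number")
  }
  n <- nrow(m)
  fd <- if (n == 1) 0 else {
    d <- abs(diff(m))  # |value(i-1) - value(i)|; sign immaterial under abs
    c(0, (rowSums(d[, 1:3, drop = FALSE]) +
            head_radius_mm * rowSums(d[, 4:6, drop = FALSE])) / 6)
  }
  structure(fd,
            head_radius_mm = head_radius_mm,
            tr_seconds = attr(motion, "tr_seconds"),
            class = "fd_trace")
}

#' Mean frame-wise displacement, optionally over surviving frames
#'
#' @param fd an `fd_trace` or numeric vector of per-frame FD (mm).
#' @param keep_mask optional logical vector (same length) selecting the
#'   surviving frames to average over.
#' @return mean FD in mm.
#' @export
mean_fd <- function(fd, keep_mask = NULL) {
  x <- as.numeric(fd)
  if (is.null(keep_mask)) return(mean(x))
  if (length(keep_mask) != length(x)) {
    abort_validation("keep_mask length must match the FD trace")
  }
  if (!any(keep_mask)) {
    abort_degenerate("no surviving frames selected; mean FD undefined")
  }
  mean(x[keep_mask])
}

#' Build a censoring (scrubbing) plan for one scan
#'
#' Two optional stages: (1) drop every frame whose FD exceeds `threshold_mm`
#' (the first frame, with FD defined as 0, is never dropped on FD grounds);
#' (2) cap the scan length by retaining the earliest surviving frames up to
#' `floor(cap_seconds / tr_seconds)` volumes, so censoring conditions compared
#' downstream use equal numbers of frames.
#'
#' @param fd an `fd_trace` or numeric FD vector (mm).
#' @param threshold_mm positive FD threshold in mm, or `NULL` for no
#'   thresholding.
#' @param cap_seconds maximum retained scan length in seconds, or `NULL`.
#' @param tr_seconds repetition time; required when `cap_seconds` is set
#'   (defaults to the trace's own `tr_seconds` attribute).
#' @return a `censor_plan` with fields `threshold_mm`, `cap_frames`,
#'   `keep_mask`, `survivor_indices` (1-based), `n_frames`, `n_survivors`,
#'   `censored_fraction` (overall) and `threshold_censored_fraction`
#'   (threshold stage only).
#' @export
make_censor_plan <- function(fd, threshold_mm = NULL, cap_seconds = NULL,
                             tr_seconds = attr(fd, "tr_seconds")) {
  x <- as.numeric(fd)
  n <- length(x)
  if (!is.null(threshold_mm)) {
    if (!is_number(threshold_mm) || threshold_mm <= 0) {
      abort_validation("threshold_mm must be a single positive number")
    }
    keep <- x <= threshold_mm
    keep[1] <- TRUE
  } else {
    keep <- rep(TRUE, n)
  }
  thr_frac <- mean(!keep)
  cap_frames <- NULL
  survivors <- which(keep)
  if (!is.null(cap_seconds)) {
    if (is.null(tr_seconds) || !is_number(tr_seconds) || tr_seconds <= 0) {
      abort_validation("tr_seconds must be a positive number when capping")
    }
    cap_frames <- floor(cap_seconds / tr_seconds)
    survivors <- utils::head(survivors, cap_frames)
  }
  keep_mask <- rep(FALSE, n)
  keep_mask[survivors] <- TRUE
  structure(list(
    threshold_mm = threshold_mm,
    cap_frames = cap_frames,
    keep_mask = keep_mask,
    survivor_indices = survivors,
    n_frames = n,
    n_survivors = length(survivors),
    censored_fraction = 1 - length(survivors) / n,
    threshold_censored_fraction = thr_frac
  ), class = "censor_plan")
}

#' @export
print.censor_plan <- function(x, ...) {
  thr <- if (is.null(x$threshold_mm)) "none" else paste0(x$threshold_mm, " mm")
  cap <- if (is.null(x$cap_frames)) "none" else paste0(x$cap_frames, " frames")
  cat(sprintf("censor plan: threshold %s, cap %s; %d/%d frames survive (%.1f%% censored)\n",
              thr, cap, x$n_survivors, x$n_frames, 100 * x$censored_fraction))
  invisible(x)
}

#' Cohort summary of censoring plans
#'
#' @param plans list of [make_censor_plan] results, one per scan (names used
#'   as scan ids when present).
#' @return list with `per_scan` (tibble: scan, survivors, censored fractions,
#'   under-cap flag) and `stats` (mean/sd/max threshold-censored fraction and
#'   the count of scans whose survivors fall short of the cap).
#' @export
censor_summary <- function(plans) {
  if (length(plans) < 1) abort_validation("need at least one censoring plan")
  ids <- names(plans)
  if (is.null(ids)) ids <- sprintf("scan%03d", seq_along(plans))
  per <- tibble::tibble(
    scan_id = ids,
    n_frames = unname(vapply(plans, function(p) p$n_frames, 0L)),
    n_survivors = unname(vapply(plans, function(p) p$n_survivors, 0L)),
    threshold_censored_fraction =
      unname(vapply(plans, function(p) p$threshold_censored_fraction, 0)),
    censored_fraction = unname(vapply(plans, function(p) p$censored_fraction, 0)),
    under_cap = unname(vapply(plans, function(p) {
      !is.null(p$cap_frames) && p$n_survivors < p$cap_frames
    }, TRUE))
  )
  list(
    per_scan = per,
    stats = list(
      mean_censored = mean(per$threshold_censored_fraction),
      sd_censored = stats::sd(per$threshold_censored_fraction),
      max_censored = max(per$threshold_censored_fraction),
      n_under_cap = sum(per$under_cap)
    )
  )
}

#' Read 6-parameter motion estimates from text
#'
#' Reads whitespace- or comma-delimited 6-column motion files. Two dialects
#' are handled explicitly and never guessed: rotations reported in degrees
#' (`rot_unit = "deg"`, AFNI-style) are converted to radians, and files with
#' rotations first (`col_order = "rpy-txyz"`) are reordered to
#' translations-then-rotations.
#'
#' @param path file path.
#' @param rot_unit `"rad"` (default) or `"deg"`.
#' @param col_order `"txyz-rpy"` (dx dy dz roll pitch yaw, default) or
#'   `"rpy-txyz"` (roll pitch yaw dx dy dz).
#' @param tr_seconds optional repetition time stored on the result.
#' @return a [motion_params] object.
#' @export
read_motion_params <- function(path, rot_unit = c("rad", "deg"),
                               col_order = c("txyz-rpy", "rpy-txyz"),
                               tr_seconds = NA_real_) {
  rot_unit <- match.arg(rot_unit)
  col_order <- match.arg(col_order)
  first <- readLines(path, n = 1)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  m <- tryCatch(
    as.matrix(utils::read.table(path, sep = sep, header = FALSE)),
    error = function(e) abort_validation(
      sprintf("malformed motion file '%s': %s", path, conditionMessage(e))))
  if (ncol(m) != 6) {
    abort_validation(sprintf("motion file '%s' has %d columns; expected 6",
                             path, ncol(m)))
  }
  if (!is.numeric(m) || !all(is.finite(m))) {
    bad <- which(!is.finite(suppressWarnings(apply(m, 1, sum))))[1]
    abort_validation(sprintf("motion file '%s': non-numeric value at line %d",
                             path, if (is.na(bad)) 1L else bad))
  }
  if (col_order == "rpy-txyz") m <- m[, c(4:6, 1:3), drop = FALSE]
  if (rot_unit == "deg") m[, 4:6] <- m[, 4:6] * pi / 180
  motion_params(m, tr_seconds = tr_seconds)
}

#' Read a dHCP-style motion table carrying precomputed FD
#'
#' Tab-separated files with a `framewise_displacement` column bypass
#' [compute_fd]; a leading missing value (no predecessor frame) is set to 0.
#'
#' @param path file path to a `*_motion.tsv` file.
#' @return an `fd_trace` (mm).
#' @export
read_dhcp_motion <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE)
  if (!"framewise_displacement" %in% names(tab)) {
    abort_validation(sprintf(
      "'%s' has no framewise_displacement column; use read_motion_params()", path))
  }
  raw <- tab$framewise_displacement
  raw[raw %in% c("n/a", "NA", "")] <- NA  # BIDS-style missing marker
  fd <- as.numeric(raw)
  if (length(fd) >= 1 && is.na(fd[1])) fd[1] <- 0
  if (!all(is.finite(fd)) || any(fd < 0)) {
    abort_validation(sprintf("'%s': framewise_displacement must be finite and >= 0", path))
  }
  structure(fd, head_radius_mm = NA_real_, tr_seconds = NA_real_,
            class = "fd_trace")
}

#' Write a per-scan FD trace with keep flags
#'
#' Writes a TSV with columns `frame` (0-based), `fd_mm` and one `keep_*`
#' column per threshold.
#'
#' @param fd an `fd_trace`.
#' @param path output file.
#' @param thresholds_mm thresholds for the keep columns (default 0.5, 0.2).
#' @export
write_fd_trace <- function(fd, path, thresholds_mm = c(0.5, 0.2)) {
  x <- as.numeric(fd)
  out <- data.frame(frame = seq_along(x) - 1L, fd_mm = x)
  for (t in thresholds_mm) {
    plan <- make_censor_plan(fd, threshold_mm = t)
    out[[sprintf("keep_%02d", round(100 * t))]] <- as.integer(plan$keep_mask)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
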