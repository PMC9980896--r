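# ROI extraction, Fisher-z connectivity, homotopic strengths, seed maps.

#' Validate an ROI table
#'
#' An ROI table has one row per region: `roi_id` (integer label), `name`,
#' `hemi`, `partner_id` (homotopic partner's `roi_id`) and centroid columns
#' `x_mm`, `y_mm`, `z_mm`. The partner mapping must be a symmetric involution.
#'
#' @param roi_table data frame as above.
#' @return the table, invisibly, after validation.
#' @export
validate_roi_table <- function(roi_table) {
  need <- c("roi_id", "name", "hemi", "partner_id", "x_mm", "y_mm", "z_mm")
  missing <- setdiff(need, names(roi_table))
  if (length(missing)) {
    abort_validation(paste("ROI table missing columns:",
                           paste(missing, collapse = ", ")))
  }
  cent <- as.matrix(roi_table[, c("x_mm", "y_mm", "z_mm")])
  if (!all(is.finite(cent))) abort_validation("ROI centroids must be finite")
  partner_of <- stats::setNames(roi_table$partner_id, roi_table$roi_id)
  back <- partner_of[as.character(roi_table$partner_id)]
  if (!all(back == roi_table$roi_id)) {
    abort_validation("homotopic partner mapping is not symmetric")
  }
  invisible(roi_table)
}

#' Extract per-ROI mean timeseries from a 4-D image and parcellation
#'
#' Averages the signal over the voxels of each label, frame by frame, in the
#' ROI order of `roi_table`.
#'
#' @param image_4d 4-D array (x, y, z, time) or NIfTI image.
#' @param parcellation 3-D integer label array/image on the same grid.
#' @param roi_table ROI table (see [validate_roi_table]).
#' @return frames x ROIs matrix, columns named by `roi_id`.
#' @export
extract_roi_timeseries <- function(image_4d, parcellation, roi_table) {
  validate_roi_table(roi_table)
  img <- unclass(as.array(image_4d))
  lab <- unclass(as.array(parcellation))
  if (length(dim(img)) != 4) abort_validation("image must be 4-D (x, y, z, t)")
  dl <- dim(lab)
  if (length(dl) < 3) dim(lab) <- dl <- c(dl, rep(1L, 3 - length(dl)))
  if (!all(dim(img)[1:3] == dl[1:3])) {
    abort_validation("image and parcellation grids differ")
  }
  n_t <- dim(img)[4]
  vox <- matrix(img, ncol = n_t)  # voxels x time
  lab_vec <- as.vector(lab)
  absent <- setdiff(roi_table$roi_id, unique(lab_vec))
  if (length(absent)) {
    abort_validation(paste("ROI labels absent from parcellation:",
                           paste(absent, collapse = ", ")))
  }
  ts <- vapply(roi_table$roi_id, function(id) {
    sel <- lab_vec == id
    if (sum(sel) == 1) vox[sel, ] else colMeans(vox[sel, , drop = FALSE])
  }, numeric(n_t))
  colnames(ts) <- as.character(roi_table$roi_id)
  ts
}

#' Fisher-z connectivity matrix
#'
#' Pearson correlation between every pair of ROI timeseries over the
#' surviving frames, Fisher z-transformed (`atanh`, with `|r| >= 1 - 1e-12`
#' clamped). The diagonal is `NA` (undefined). Zero-variance ROIs yield `NA`
#' entries and are reported in the `"zero_variance"` attribute rather than
#' silently zeroed.
#'
#' @param ts frames x ROIs matrix.
#' @param keep_mask optional logical frame selection (e.g. from a
#'   [make_censor_plan] `keep_mask`).
#' @param condition optional tag recorded on the result.
#' @return `fc_matrix`: symmetric ROIs x ROIs z-value matrix with attributes
#'   `n_frames_used`, `condition`, `zero_variance`.
#' @export
fc_matrix <- function(ts, keep_mask = NULL, condition = NULL) {
  y <- as.matrix(ts)
  if (!is.null(keep_mask)) {
    if (length(keep_mask) != nrow(y)) {
      abort_validation("keep_mask length must match frame count")
    }
    y <- y[keep_mask, , drop = FALSE]
  }
  if (nrow(y) < 3) abort_validation("need >= 3 surviving frames for correlation")
  sds <- apply(y, 2, stats::sd)
  zv <- which(sds < .Machine$double.eps)
  r <- suppressWarnings(stats::cor(y))
  z <- fisher_z(r)
  attributes(z) <- attributes(r)[c("dim", "dimnames")]
  if (length(zv)) {
    z[zv, ] <- NA_real_
    z[, zv] <- NA_real_
  }
  diag(z) <- NA_real_
  structure(z,
            n_frames_used = nrow(y),
            condition = condition,
            zero_variance = zv,
            class = c("fc_matrix", "matrix"))
}

#' Homotopic (cross-hemispheric) connectivity strengths
#'
#' Returns the Fisher-z value of each left-right ROI pair from the explicit
#' partner mapping in the ROI table (never inferred from label parity).
#'
#' @param fc an [fc_matrix].
#' @param roi_table ROI table; ROI order must match the matrix.
#' @param pair_ids optional subset: `roi_id`s (one per pair, either member)
#'   selecting named pairs.
#' @return tibble with `pair`, `roi_a`, `roi_b`, `z`.
#' @export
homotopic_fc <- function(fc, roi_table, pair_ids = NULL) {
  validate_roi_table(roi_table)
  ids <- roi_table$roi_id
  pos <- stats::setNames(seq_along(ids), ids)
  a <- ids
  b <- roi_table$partner_id
  keep <- a < b  # one row per unordered pair
  pairs <- data.frame(roi_a = a[keep], roi_b = b[keep])
  pairs$pair <- sub("_[LR]$", "", roi_table$name[keep])
  if (!is.null(pair_ids)) {
    unknown <- setdiff(pair_ids, c(pairs$roi_a, pairs$roi_b))
    if (length(unknown)) {
      abort_validation(paste("unknown pair id(s):", paste(unknown, collapse = ", ")))
    }
    sel <- pairs$roi_a %in% pair_ids | pairs$roi_b %in% pair_ids
    pairs <- pairs[sel, , drop = FALSE]
  }
  pairs$z <- unclass(fc)[cbind(pos[as.character(pairs$roi_a)],
                               pos[as.character(pairs$roi_b)])]
  tibble::as_tibble(pairs[, c("pair", "roi_a", "roi_b", "z")])
}

#' Euclidean distances between ROI centroids
#'
#' @param roi_table ROI table with centroid columns in mm.
#' @return symmetric ROIs x ROIs distance matrix (mm), zero diagonal.
#' @export
roi_distances <- function(roi_table) {
  validate_roi_table(roi_table)
  d <- as.matrix(stats::dist(as.matrix(roi_table[, c("x_mm", "y_mm", "z_mm")])))
  dimnames(d) <- list(roi_table$roi_id, roi_table$roi_id)
  d
}

#' Seed-based Fisher-z connectivity map
#'
#' Correlates a seed timeseries with every target unit and Fisher
#' z-transforms the result. Bilateral seeds (a frames x k matrix) are averaged
#' into a single seed series before correlation.
#'
#' @param ts_targets frames x units matrix of target signals.
#' @param seed_ts seed series: numeric vector or frames x k matrix.
#' @return numeric per-unit z values (named from `ts_targets` columns).
#' @export
seed_map <- function(ts_targets, seed_ts) {
  y <- as.matrix(ts_targets)
  s <- if (is.matrix(seed_ts)) rowMeans(seed_ts) else as.numeric(seed_ts)
  if (length(s) != nrow(y)) abort_validation("seed and target frame counts differ")
  if (stats::sd(s) < .Machine$double.eps) {
    abort_degenerate("seed timeseries has zero variance")
  }
  r <- suppressWarnings(as.vector(stats::cor(s, y)))
  z <- fisher_z(r)
  names(z) <- colnames(y)
  z
}

#' Read / write ROI tables and FC matrices as TSV
#'
#' @param path file path.
#' @rdname roi_io
#' @export
read_roi_table <- function(path) {
  tab <- tibble::as_tibble(utils::read.delim(path, check.names = FALSE))
  validate_roi_table(tab)
  tab
}

#' @param roi_table,fc objects to write.
#' @rdname roi_io
#' @export
write_roi_table <- function(roi_table, path) {
  utils::write.table(roi_table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname roi_io
#' @export
write_fc_matrix <- function(fc, path) {
  m <- unclass(fc)
  out <- data.frame(roi_id = rownames(m) %||% seq_len(nrow(m)), m,
                    check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
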