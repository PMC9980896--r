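# Orchestration: configuration, the three experiment runners, manifests.

#' Build a run configuration
#'
#' @param synthetic a [synthetic_config] (the input source for simulated
#'   runs); alternatively set `input_dir` to a directory of on-disk scans.
#' @param thresholds_mm censoring thresholds; `NA` means no threshold
#'   (default `c(NA, 0.5, 0.2)`).
#' @param cap_seconds scan-length cap applied to every condition (default
#'   240 s), equalizing frame counts so conditions share one
#'   signal-to-noise level.
#' @param band_hz passband for cleaning (default `c(0.009, 0.08)` Hz).
#' @param gsr enable global signal regression in the cleaning design.
#' @param networks named ROI-pair list (default [synthetic_networks]).
#' @param alpha_unc,fdr_q,edge_alpha significance levels.
#' @param n_boot,subset_frac bootstrap settings (defaults 5000 and 0.5).
#' @param group_fraction motion-split fraction (default 0.25).
#' @param seed master seed.
#' @param out_dir output directory (`NULL` = no files written).
#' @return a `run_config` list.
#' @export
run_config <- function(synthetic = synthetic_config(),
                       input_dir = NULL,
                       thresholds_mm = c(NA, 0.5, 0.2),
                       cap_seconds = 240,
                       band_hz = c(0.009, 0.08),
                       gsr = FALSE,
                       networks = synthetic_networks(),
                       alpha_unc = 0.01, fdr_q = 0.05, edge_alpha = 0.05,
                       n_boot = 5000, subset_frac = 0.5,
                       group_fraction = 0.25,
                       seed = 1L, out_dir = NULL) {
  ok <- is.na(thresholds_mm) | thresholds_mm > 0
  if (!all(ok)) abort_validation("censoring thresholds must be positive (or NA)")
  structure(list(synthetic = synthetic, input_dir = input_dir,
                 thresholds_mm = thresholds_mm, cap_seconds = cap_seconds,
                 band_hz = band_hz, gsr = gsr, networks = networks,
                 alpha_unc = alpha_unc, fdr_q = fdr_q,
                 edge_alpha = edge_alpha, n_boot = n_boot,
                 subset_frac = subset_frac, group_fraction = group_fraction,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Recognized keys mirror the [run_config] arguments; a `synthetic:` block
#' holds [synthetic_config] fields. Config lists round-trip losslessly
#' through [yaml::write_yaml].
#'
#' @param path YAML file.
#' @param seed optional seed override (e.g. from the command line).
#' @return a `run_config`.
#' @export
read_run_config <- function(path, seed = NULL) {
  raw <- yaml::read_yaml(path)
  syn_args <- raw$synthetic %||% list()
  if (!is.null(seed)) syn_args$seed <- seed
  syn <- do.call(synthetic_config, syn_args)
  args <- raw[setdiff(names(raw), "synthetic")]
  if (!is.null(args$thresholds_mm)) {
    args$thresholds_mm <- as.numeric(args$thresholds_mm)
  }
  if (!is.null(seed)) args$seed <- seed
  do.call(run_config, c(list(synthetic = syn), args))
}

condition_tag <- function(threshold_mm) {
  if (is.na(threshold_mm)) "none" else format(threshold_mm)
}

# Per-scan processing shared by the runners: clean once, censor per
# condition, and assemble the long cohort table plus FC stacks.
process_cohort <- function(config) {
  cohort <- make_cohort(config$synthetic)
  tr <- config$synthetic$tr_seconds
  conditions <- vapply(config$thresholds_mm, condition_tag, "")
  nets <- config$networks
  rows <- list()
  fcs <- stats::setNames(vector("list", length(conditions)), conditions)
  for (cond in conditions) fcs[[cond]] <- list()
  tsnr <- numeric(length(cohort$scans))
  for (s in seq_along(cohort$scans)) {
    scan <- cohort$scans[[s]]
    id <- cohort$table$scan_id[s]
    tsnr[s] <- compute_tsnr(scan$ts)$mean_tsnr
    design <- nuisance_design(nrow(scan$ts), motion = scan$motion,
                              gray = if (config$gsr) scan$ts else NULL,
                              gsr = config$gsr)
    cleaned <- clean_timeseries(scan$ts, design = design,
                                band_hz = config$band_hz, tr_seconds = tr)
    for (k in seq_along(conditions)) {
      thr <- config$thresholds_mm[k]
      plan <- make_censor_plan(scan$fd,
                               threshold_mm = if (is.na(thr)) NULL else thr,
                               cap_seconds = config$cap_seconds,
                               tr_seconds = tr)
      fc <- fc_matrix(cleaned, keep_mask = plan$keep_mask,
                      condition = conditions[k])
      fcs[[conditions[k]]][[id]] <- fc
      strengths <- lapply(nets, function(pr) {
        unclass(fc)[match(pr[1], cohort$geometry$roi_id),
                    match(pr[2], cohort$geometry$roi_id)]
      })
      rows[[length(rows) + 1]] <- tibble::tibble(
        scan_id = id, condition = conditions[k],
        mean_fd = mean_fd(scan$fd, plan$keep_mask),
        n_survivors = plan$n_survivors,
        censored_fraction = plan$threshold_censored_fraction,
        pma_weeks = cohort$table$pma_weeks[s],
        sex = cohort$table$sex[s],
        tsnr = tsnr[s],
        !!!stats::setNames(strengths, paste0("z_", names(nets))))
    }
  }
  list(cohort = cohort, table = do.call(rbind, rows), fcs = fcs,
       conditions = conditions)
}

write_manifest <- function(config, path, stage) {
  cfg <- rapply(unclass(config), function(x) x, how = "replace")
  manifest <- list(stage = stage,
                   package = "neomotion",
                   version = as.character(utils::packageVersion("neomotion")),
                   seed = config$seed,
                   config = cfg)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  invisible(path)
}

ensure_out <- function(config) {
  if (is.null(config$out_dir)) return(NULL)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  config$out_dir
}

write_tsv <- function(x, dir, name) {
  if (is.null(dir)) return(invisible(NULL))
  utils::write.table(x, file.path(dir, name), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file.path(dir, name))
}

#' Quality-control experiment: FD, censoring, tSNR
#'
#' Recomputes per-scan FD summaries and censored fractions at each
#' threshold, temporal SNR, and the cohort-level association between tSNR
#' and mean motion.
#'
#' @param config a [run_config].
#' @return list with `per_scan` (long table), `fd_summary` (per-condition
#'   mean/SD/median/max of mean FD, censored-fraction statistics, under-cap
#'   counts), `tsnr_fd` (per-condition r/p), and `fd_pma` (independence
#'   check). Writes `qc_per_scan.tsv`, `qc_summary.tsv`, `qc_manifest.json`
#'   under `out_dir` when set.
#' @export
run_qc <- function(config) {
  proc <- process_cohort(config)
  tab <- proc$table
  per_cond <- lapply(proc$conditions, function(cond) {
    rows <- tab[tab$condition == cond, ]
    tibble::tibble(
      condition = cond,
      n_scans = nrow(rows),
      mean_fd = mean(rows$mean_fd), sd_fd = stats::sd(rows$mean_fd),
      median_fd = stats::median(rows$mean_fd),
      min_fd = min(rows$mean_fd), max_fd = max(rows$mean_fd),
      mean_censored_fraction = mean(rows$censored_fraction),
      sd_censored_fraction = stats::sd(rows$censored_fraction),
      max_censored_fraction = max(rows$censored_fraction),
      n_under_cap = sum(rows$n_survivors <
                          floor(config$cap_seconds / config$synthetic$tr_seconds)))
  })
  fd_summary <- do.call(rbind, per_cond)
  assoc <- lapply(proc$conditions, function(cond) {
    rows <- tab[tab$condition == cond, ]
    ct <- stats::cor.test(rows$mean_fd, rows$tsnr)
    cp <- stats::cor.test(rows$mean_fd, rows$pma_weeks)
    tibble::tibble(condition = cond,
                   r_tsnr_fd = unname(ct$estimate), p_tsnr_fd = ct$p.value,
                   r_fd_pma = unname(cp$estimate), p_fd_pma = cp$p.value)
  })
  assoc <- do.call(rbind, assoc)
  dir <- ensure_out(config)
  write_tsv(tab, dir, "qc_per_scan.tsv")
  write_tsv(fd_summary, dir, "qc_summary.tsv")
  write_tsv(assoc, dir, "qc_association.tsv")
  if (!is.null(dir)) write_manifest(config, file.path(dir, "qc_manifest.json"), "qc")
  list(per_scan = tab, fd_summary = fd_summary, tsnr_fd = assoc,
       conditions = proc$conditions)
}

#' Censoring-vs-connectivity experiment
#'
#' For every censoring condition: FD-connectivity associations per network,
#' edgewise associations with contaminated-edge fractions, motion-group
#' seed-map contrasts with FDR, distance-dependence analyses, and the ANOVA
#' comparing the group effect across conditions.
#'
#' @param config a [run_config].
#' @return list with `associations`, `edgewise` (per-condition fractions),
#'   `contrasts`, `anova`, `distance`, `per_scan`. TSVs and a manifest are
#'   written under `out_dir` when set.
#' @export
run_censoring_eval <- function(config) {
  proc <- process_cohort(config)
  tab <- proc$table
  geom <- proc$cohort$geometry
  dmat <- roi_distances(geom)
  nets <- config$networks
  n_scans <- config$synthetic$n_scans
  associations <- do.call(rbind, lapply(proc$conditions, function(cond) {
    do.call(rbind, lapply(names(nets), function(nm) {
      res <- fd_fc_association(tab, nm, condition = cond)
      res$network <- nm
      res
    }))
  }))
  edgewise <- list(); edge_frac <- list()
  mean_fcs <- list()
  for (cond in proc$conditions) {
    stack <- fc_stack_from_matrices(proc$fcs[[cond]])
    rows <- tab[tab$condition == cond, ]
    ew <- edgewise_fd_association(stack, rows$mean_fd,
                                  alpha = config$edge_alpha)
    ew$condition <- cond
    edgewise[[cond]] <- ew
    edge_frac[[cond]] <- attr(ew, "frac_significant")
    mz <- Reduce(`+`, lapply(proc$fcs[[cond]], unclass)) /
      length(proc$fcs[[cond]])
    mean_fcs[[cond]] <- mz
  }
  contrasts <- list()
  can_group <- n_scans >= 8
  if (can_group) {
    for (cond in proc$conditions) {
      rows <- tab[tab$condition == cond, ]
      split <- split_by_motion(rows, fraction = config$group_fraction)
      maps <- t(vapply(rows$scan_id, function(id) {
        fc <- unclass(proc$fcs[[cond]][[id]])
        # seed map at ROI scale: bilateral first-network seed vs all ROIs
        seed_rois <- match(nets[[1]], geom$roi_id)
        rowMeans(fc[, seed_rois, drop = FALSE], na.rm = TRUE)
      }, numeric(nrow(geom))))
      rownames(maps) <- rows$scan_id
      keep_units <- setdiff(seq_len(nrow(geom)), match(nets[[1]], geom$roi_id))
      gc <- group_contrast(maps[split$low, keep_units, drop = FALSE],
                           maps[split$high, keep_units, drop = FALSE],
                           alpha_unc = config$alpha_unc,
                           fdr_q = config$fdr_q)
      gc$condition <- cond
      contrasts[[cond]] <- gc
    }
  }
  # ANOVA compares the group effect across conditions over a common unit
  # set: units significant (uncorrected) in the uncensored contrast, all
  # units when fewer than two reach significance there
  anova_res <- NULL
  if (can_group && length(contrasts) >= 2) {
    ref <- contrasts[[1]]
    sel <- which(ref$sig_unc)
    if (length(sel) < 2) sel <- seq_len(nrow(ref))
    deltas <- lapply(contrasts, function(gc) gc$delta_z[sel])
    if (all(vapply(deltas, length, 0L) >= 2)) {
      anova_res <- strength_comparison(deltas)
    }
  }
  distance <- do.call(rbind, lapply(proc$conditions, function(cond) {
    dd <- distance_dependence(mean_fcs[[cond]], dmat)
    dd$condition <- cond
    dd$analysis <- "mean_fc_vs_distance"
    dd
  }))
  strict <- proc$conditions[length(proc$conditions)]
  if (proc$conditions[1] != strict) {
    shift <- censor_distance_shift(mean_fcs[[proc$conditions[1]]],
                                   mean_fcs[[strict]], dmat)
    shift$condition <- paste0(proc$conditions[1], "-", strict)
    shift$analysis <- "censor_shift_vs_distance"
    distance <- rbind(distance, shift)
  }
  dir <- ensure_out(config)
  write_tsv(associations, dir, "association.tsv")
  write_tsv(do.call(rbind, edgewise), dir, "edgewise.tsv")
  if (length(contrasts)) {
    write_tsv(do.call(rbind, contrasts), dir, "group_contrast.tsv")
  }
  write_tsv(distance, dir, "distance.tsv")
  if (!is.null(dir)) {
    write_manifest(config, file.path(dir, "censor_eval_manifest.json"),
                   "censor-eval")
  }
  list(associations = associations, edgewise = edgewise,
       edge_frac = unlist(edge_frac), contrasts = contrasts,
       anova = anova_res, distance = distance, per_scan = tab,
       mean_fcs = mean_fcs, ground_truth_z =
         fisher_z(true_covariance(geom, config$synthetic)))
}

#' Bootstrap age-association experiment
#'
#' For each named network, compares the simple PMA-connectivity correlation
#' with the partial correlation controlling mean FD, over bootstrap subsets.
#'
#' @param config a [run_config].
#' @param condition censoring condition analysed (default the uncensored
#'   tag `"none"`).
#' @return list with `results` (per-network [pma_association] objects) and
#'   `summary` tibble. Writes `bootstrap.tsv` and a manifest when `out_dir`
#'   is set.
#' @export
run_pma_analysis <- function(config, condition = "none") {
  proc <- process_cohort(config)
  tab <- proc$table
  if (!"pma_weeks" %in% names(tab) || all(!is.finite(tab$pma_weeks))) {
    abort_validation("cohort table has no usable pma_weeks column")
  }
  nets <- names(config$networks)
  results <- stats::setNames(lapply(seq_along(nets), function(k) {
    pma_association(tab, nets[k], condition = condition, control_fd = TRUE,
                    n_boot = config$n_boot, subset_frac = config$subset_frac,
                    seed = config$seed + k)
  }), nets)
  summary <- do.call(rbind, lapply(nets, function(nm) {
    r <- results[[nm]]
    tibble::tibble(network = nm, condition = condition,
                   mean_simple_z = r$mean_simple, sd_simple_z = r$sd_simple,
                   p_simple = r$p_simple,
                   mean_partial_z = r$mean_partial,
                   sd_partial_z = r$sd_partial, p_partial = r$p_partial,
                   p_paired = r$p_paired, n_boot = r$n_boot, n = r$n)
  }))
  dir <- ensure_out(config)
  write_tsv(summary, dir, "bootstrap.tsv")
  if (!is.null(dir)) {
    write_manifest(config, file.path(dir, "pma_manifest.json"), "pma")
  }
  list(results = results, summary = summary)
}
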