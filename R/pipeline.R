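#' Configuration for a synthetic replication run
#'
#' Defaults reproduce the two-session delayed-recall design with six
#' orientations and six locations: 108 3O trials (each orientation probed
#' at each location three times) and 360 1O trials (ten times per cell),
#' 400 simulated voxels with a 400-voxel ROI, 14 low and 13 high
#' swap-error subjects, 2500 bootstrap iterations, the recall-epoch TR of
#' interest at TR10 and the delay-epoch TRs at TR6-TR7. The group
#' behavioral profiles default to the fitted group means of the
#' median-split groups (low: pT 0.896, pN 0.012, pU 0.092; high: pT 0.700,
#' pN 0.169, pU 0.131); recall-epoch signal gains default to a strong,
#' well-differentiated probed representation in the low group (1.0 vs 0.1)
#' and a weak, poorly differentiated one in the high group (0.5 vs 0.4),
#' with delay-period location signal likewise stronger in the low group.
#'
#' @param n_orientations,n_locations design counts.
#' @param repeats_3O,repeats_1O probed repeats per (orientation x location)
#'   cell for the two conditions.
#' @param n_voxels simulated voxels; `roi_k` of them are selected by the
#'   delay-contrast GLM.
#' @param roi_k ROI size.
#' @param n_low,n_high subjects per group.
#' @param noise_sd voxel noise SD.
#' @param profile_low,profile_high [group_profile()] objects.
#' @param n_boot bootstrap iterations.
#' @param tr_recall recall-epoch TR of interest.
#' @param tr_delay delay-epoch TRs (averaged).
#' @param n_shift_iters shifted bases per reconstruction.
#' @param n_starts mixture-fit random starts.
#' @param use_roi if FALSE, skip the GLM/ROI stage and use all voxels
#'   (useful at reduced problem sizes).
#' @param seed master seed; all stage seeds derive from it.
#' @return a list of class `replica_config`.
#' @export
replica_config <- function(n_orientations = 6, n_locations = 6,
                           repeats_3O = 3, repeats_1O = 10,
                           n_voxels = 400, roi_k = 400,
                           n_low = 14, n_high = 13,
                           noise_sd = 0.5,
                           profile_low = group_profile(
                             "low_swap", pT = 0.896, pN = 0.012, pU = 0.092,
                             kappa_mix = 10,
                             probed_gain = 1.0, nonprobed_gain = 0.1,
                             delay_location_gain = 1.0),
                           profile_high = group_profile(
                             "high_swap", pT = 0.700, pN = 0.169, pU = 0.131,
                             kappa_mix = 10,
                             probed_gain = 0.5, nonprobed_gain = 0.4,
                             delay_location_gain = 0.4),
                           n_boot = 2500, tr_recall = 10, tr_delay = c(6, 7),
                           n_shift_iters = 180, n_starts = 10,
                           use_roi = TRUE, seed = 1L) {
  structure(as.list(environment()), class = "replica_config")
}

#' Run the full synthetic replication pipeline
#'
#' Simulates every subject's behavior and voxel time series, fits the
#' three-factor mixture model, splits subjects into low and high
#' swap-error groups by the median of the fitted swap rates, selects a
#' delay-contrast ROI, reconstructs orientation and location CTFs at the
#' recall-epoch TR (probed and randomly selected non-probed items) and the
#' probed location CTF averaged over the delay-epoch TRs, and runs the
#' four hypothesis tests: (1) group difference in orientation recall
#' specificity, (2) group difference in location recall specificity,
#' (3) Spearman correlation of delay-epoch location amplitude with the
#' fitted swap rate, and (4) correlation of delay-epoch location amplitude
#' with location recall specificity (Pearson unless a Shapiro-Wilk gate
#' recommends Spearman). The four p-values are FDR-corrected.
#'
#' @param config a [replica_config()].
#' @param out_dir optional directory: the report is serialized there as
#'   JSON + TSV plus a summary figure.
#' @return a list of class `replica_report` with elements `subjects`
#'   (per-subject estimates), `hypotheses` (statistic, p, p_fdr per test),
#'   `group_ctfs`, `psc`, `config`.
#' @export
run_replica <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "replica_config"))
  cfg <- config
  base_seed <- (cfg$seed %% 1000000L) * 1000L
  basis_ori <- make_basis(cfg$n_orientations, 180)
  basis_loc <- make_basis(cfg$n_locations, 360)
  n_subj <- cfg$n_low + cfg$n_high
  true_group <- rep(c("low", "high"), c(cfg$n_low, cfg$n_high))

  subj <- vector("list", n_subj)
  for (i in seq_len(n_subj)) {
    prof <- if (true_group[i] == "low") cfg$profile_low else cfg$profile_high
    s <- base_seed + i * 20L
    sch3 <- make_schedule(cfg$n_orientations, cfg$n_locations, 3,
                          cfg$repeats_3O, "3O", seed = s + 1L)
    sch1 <- make_schedule(cfg$n_orientations, cfg$n_locations, 1,
                          cfg$repeats_1O, "1O", seed = s + 2L)
    beh3 <- simulate_behavior(sch3, prof, seed = s + 3L)
    mfit <- fit_mixture(beh3, n_factors = 3, n_starts = cfg$n_starts,
                        seed = s + 4L)
    d3 <- simulate_bold(sch3, prof, cfg$n_voxels, basis_ori, basis_loc,
                        noise_sd = cfg$noise_sd, seed = s + 5L)
    d1 <- simulate_bold(sch1, prof, cfg$n_voxels, basis_ori, basis_loc,
                        noise_sd = cfg$noise_sd, seed = s + 6L,
                        weights = d3$truth)
    dat <- concat_datasets(d3, d1)
    if (cfg$use_roi) {
      design <- build_design_matrix(list(sch3, sch1))
      cv <- contrast_vector(design, "Delay_3O", "Delay_1O")
      tmap <- fit_glm_contrast(dat, design, cv)
      roi <- select_roi_topk(tmap, k = min(cfg$roi_k, cfg$n_voxels),
                             contrast_label = "Delay_3O - Delay_1O")
      dat <- subset_voxels(dat, roi)
    } else {
      roi <- NULL
    }
    sel_o <- select_nonprobed(sch3, seed = s + 7L)
    sel_l <- select_nonprobed(sch3, seed = s + 8L)
    probed_idx <- sch3$probed_index
    ct_ori <- reconstruct_ctf(dat, basis_ori, cfg$tr_recall, "1O", "3O",
                              "orientation",
                              test_selection = list(probed = probed_idx,
                                                    nonprobed = sel_o),
                              n_shift_iters = cfg$n_shift_iters,
                              seed = s + 9L)
    ct_loc <- reconstruct_ctf(dat, basis_loc, cfg$tr_recall, "1O", "3O",
                              "location",
                              test_selection = list(probed = probed_idx,
                                                    nonprobed = sel_l),
                              n_shift_iters = cfg$n_shift_iters,
                              seed = s + 10L)
    delay_vals <- rowMeans(vapply(cfg$tr_delay, function(tr) {
      reconstruct_ctf(dat, basis_loc, tr, "1O", "3O", "location",
                      test_selection = probed_idx,
                      n_shift_iters = cfg$n_shift_iters,
                      seed = s + 11L)$values
    }, numeric(180)))
    psc3 <- trial_average_psc(dat, seq_len(nrow(dat$signal)), "3O")
    psc1 <- trial_average_psc(dat, seq_len(nrow(dat$signal)), "1O")
    subj[[i]] <- list(pN = mfit$pN, pT = mfit$pT, pU = mfit$pU,
                      kappa = mfit$kappa,
                      ori_probed = ct_ori$probed$values,
                      ori_nonprobed = ct_ori$nonprobed$values,
                      loc_probed = ct_loc$probed$values,
                      loc_nonprobed = ct_loc$nonprobed$values,
                      delay_loc = delay_vals,
                      delay_amp = amplitude(fit_exp_cosine(delay_vals)),
                      psc_3O = psc3, psc_1O = psc1)
  }

  pN_hat <- vapply(subj, `[[`, numeric(1), "pN")
  groups <- classify_groups(pN_hat, "median_split")
  low <- which(groups == "low"); high <- which(groups == "high")

  stackm <- function(field, idx) {
    do.call(rbind, lapply(subj[idx], `[[`, field))
  }
  h1 <- bootstrap_specificity_difference(
    list(probed = stackm("ori_probed", low),
         nonprobed = stackm("ori_nonprobed", low)),
    list(probed = stackm("ori_probed", high),
         nonprobed = stackm("ori_nonprobed", high)),
    n_iters = cfg$n_boot, seed = base_seed + 3L)
  h2 <- bootstrap_specificity_difference(
    list(probed = stackm("loc_probed", low),
         nonprobed = stackm("loc_nonprobed", low)),
    list(probed = stackm("loc_probed", high),
         nonprobed = stackm("loc_nonprobed", high)),
    n_iters = cfg$n_boot, seed = base_seed + 4L)

  delay_amp <- vapply(subj, `[[`, numeric(1), "delay_amp")
  spec_ori <- recall_specificity(stackm("ori_probed", seq_len(n_subj)),
                                 stackm("ori_nonprobed", seq_len(n_subj)),
                                 "orientation")
  spec_loc <- recall_specificity(stackm("loc_probed", seq_len(n_subj)),
                                 stackm("loc_nonprobed", seq_len(n_subj)),
                                 "location")
  h3 <- rank_correlation(delay_amp, pN_hat, "spearman")
  h4_method <- recommend_correlation_method(delay_amp, spec_loc$difference)
  h4 <- rank_correlation(delay_amp, spec_loc$difference, h4_method)

  raw_p <- c(h1 = h1$p, h2 = h2$p, h3 = h3$p, h4 = h4$p)
  fdr <- fdr_bh(raw_p)
  hypotheses <- data.frame(
    hypothesis = c("orientation_recall_specificity_group_diff",
                   "location_recall_specificity_group_diff",
                   "delay_location_amp_vs_pN_spearman",
                   paste0("delay_location_amp_vs_location_specificity_",
                          h4_method)),
    statistic = c(mean(h1$values), mean(h2$values), h3$R2, h4$R2),
    p = unname(raw_p),
    p_fdr = fdr$p_adjusted,
    reject = fdr$reject)

  subjects <- data.frame(subject = seq_len(n_subj),
                         true_group = true_group, group = as.character(groups),
                         pN = pN_hat,
                         pT = vapply(subj, `[[`, numeric(1), "pT"),
                         kappa = vapply(subj, `[[`, numeric(1), "kappa"),
                         spec_ori = spec_ori$difference,
                         spec_loc = spec_loc$difference,
                         delay_amp = delay_amp)

  report <- structure(list(
    subjects = subjects,
    hypotheses = hypotheses,
    group_ctfs = list(
      low_ori_probed = colMeans(stackm("ori_probed", low)),
      high_ori_probed = colMeans(stackm("ori_probed", high)),
      low_ori_nonprobed = colMeans(stackm("ori_nonprobed", low)),
      high_ori_nonprobed = colMeans(stackm("ori_nonprobed", high))),
    psc = list(`3O` = colMeans(stackm("psc_3O", seq_len(n_subj))),
               `1O` = colMeans(stackm("psc_1O", seq_len(n_subj)))),
    bootstrap = list(h1 = h1, h2 = h2),
    config = cfg,
    run_log = run_log()),
    class = "replica_report")

  if (!is.null(out_dir)) write_replica_report(report, out_dir)
  report
}

#' @export
print.replica_report <- function(x, ...) {
  cat("synthetic replication report\n")
  cat(sprintf("  %d subjects (%d low / %d high by median split of fitted pN)\n",
              nrow(x$subjects), sum(x$subjects$group == "low"),
              sum(x$subjects$group == "high")))
  print(x$hypotheses[, c("hypothesis", "statistic", "p", "p_fdr")],
        row.names = FALSE)
  invisible(x)
}

write_replica_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(report$subjects, file.path(out_dir, "subjects.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$hypotheses, file.path(out_dir, "hypotheses.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  json <- list(hypotheses = report$hypotheses,
               subjects = report$subjects,
               seed = report$config$seed,
               n_boot = report$config$n_boot,
               psc = report$psc)
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       pretty = TRUE)
  grDevices::pdf(file.path(out_dir, "group_ctfs.pdf"), width = 6, height = 4)
  offs <- seq(-90, 89)
  g <- report$group_ctfs
  rng <- range(unlist(g))
  graphics::plot(offs, g$low_ori_probed, type = "l", ylim = rng,
                 xlab = "offset from probed orientation (deg)",
                 ylab = "channel response", col = 1)
  graphics::lines(offs, g$high_ori_probed, col = 2)
  graphics::lines(offs, g$low_ori_nonprobed, col = 1, lty = 2)
  graphics::lines(offs, g$high_ori_nonprobed, col = 2, lty = 2)
  graphics::legend("topright", bty = "n", cex = 0.7, col = c(1, 2, 1, 2),
                   lty = c(1, 1, 2, 2),
                   legend = c("low / probed", "high / probed",
                              "low / non-probed", "high / non-probed"))
  grDevices::dev.off()
  invisible(out_dir)
}
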