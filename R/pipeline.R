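# End-to-end orchestration: simulate -> filter -> call chromothripsis ->
# train CPS -> genomic covariates -> immune scores -> survival, from one
# config, with every output table written to a run directory and
# checksummed.  All randomness flows from the config's root seed through
# named substreams, so a rerun with the same config reproduces every table
# byte-identically.

#' Default pipeline configuration
#'
#' @param n_samples cohort size for the demo run.
#' @param seed root seed.
#' @param outdir output directory.
#' @return nested config list (see [run_pipeline()]).
#' @export
default_run_config <- function(n_samples = 80, seed = 1,
                               outdir = tempfile("chromoscore_run_")) {
  list(
    simulate = list(n_samples = n_samples, n_genes = 600,
                    n_cell_signatures = 28, seed = seed),
    chromothripsis = as.list(ct_thresholds()),
    cps = list(K = 3, folds = 10),
    mutations = list(nonsilent_rate = 2, exome_size_mb = 30),
    survival = list(time_grid = c(12, 24, 36)),
    outdir = outdir
  )
}

validate_run_config <- function(cfg) {
  required <- c("simulate", "chromothripsis", "cps", "mutations",
                "survival", "outdir")
  missing <- setdiff(required, names(cfg))
  if (length(missing))
    stop("config missing required block(s): ", paste(missing, collapse = ", "))
  if (is.null(cfg$survival$time_grid)) stop("survival block needs time_grid")
  if (is.null(cfg$cps$K) || is.null(cfg$cps$folds))
    stop("cps block needs K and folds")
  invisible(cfg)
}

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order, writes tab-delimited tables,
#' the CPS model JSON and a parameter log into `config$outdir`, and
#' records an md5 checksum manifest.  The config may be a list (see
#' [default_run_config()]) or the path to a YAML file with the same
#' structure.  Stage failures abort with the stage name.
#'
#' @param config config list or YAML path.
#' @return invisibly, a list with the run `outdir`, per-stage results and
#'   the checksum manifest.
#' @export
run_pipeline <- function(config = default_run_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  validate_run_config(config)
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  cfg_echo <- config
  cfg_echo$outdir <- NULL  # keep the log invariant to where the run lands
  log_lines <- c("chromoscore pipeline run",
                 paste0("config: ", jsonlite::toJSON(cfg_echo, auto_unbox = TRUE)))

  sim_args <- config$simulate
  scfg <- stage("simulate", do.call(sim_config, sim_args))
  cohort <- stage("simulate", simulate_cohort_profiles(scfg))
  write_seg(cohort$profiles, file.path(outdir, "profiles.seg"))
  write_tsv(data.frame(sample_id = names(cohort$labels),
                       planted_ct = cohort$labels),
            file.path(outdir, "truth_labels.tsv"))

  filtered <- stage("filter", lapply(cohort$profiles, filter_profile))

  thr <- do.call(ct_thresholds, config$chromothripsis)
  calls <- stage("chromothripsis", {
    per_sample <- lapply(seq_along(filtered), function(i) {
      call_chromothripsis(filtered[[i]], thr,
                          seed = substream_seed(scfg$seed, 50000 + i))
    })
    do.call(rbind, per_sample)
  })
  ct_flags <- stage("chromothripsis", vapply(
    split(calls$is_chromothripsis, calls$sample_id)[names(filtered)],
    any, logical(1)
  ))
  write_tsv(calls, file.path(outdir, "chromothripsis_calls.tsv"))
  write_tsv(data.frame(sample_id = names(ct_flags), is_chromothripsis = ct_flags),
            file.path(outdir, "chromothripsis_labels.tsv"))
  log_lines <- c(log_lines, paste0(
    "detector: sensitivity=",
    signif(mean(ct_flags[cohort$labels]), 4),
    " specificity=", signif(mean(!ct_flags[!cohort$labels]), 4)
  ))

  cps_model <- stage("cps", train_cps(
    filtered, ct_flags, K = config$cps$K, folds = config$cps$folds,
    seed = scfg$seed
  ))
  cps <- stage("cps", score_cps(cps_model, filtered))
  save_cps_model(cps_model, file.path(outdir, "cps_model.json"))
  write_tsv(data.frame(sample_id = names(cps), cps = cps),
            file.path(outdir, "cps_scores.tsv"))
  log_lines <- c(log_lines, paste0("cps: cv_auc=", signif(cps_model$cv_auc, 4)))

  maf <- stage("covariates", simulate_mutations(
    scfg, nonsilent_rate = config$mutations$nonsilent_rate,
    exome_size_mb = config$mutations$exome_size_mb
  ))
  maf_f <- stage("covariates", filter_variants(maf))
  tmb <- compute_tmb(maf_f, config$mutations$exome_size_mb,
                     sample_ids = names(filtered))
  genes_bed <- stage("covariates", synthetic_gene_intervals(scfg))
  cov <- stage("covariates", {
    rows <- lapply(names(filtered), function(sid) {
      p <- filtered[[sid]]
      pl <- tumor_ploidy(p)
      burden <- cna_burden(p, genes_bed, ploidy = pl)
      data.frame(sample_id = sid, tmb = tmb[sid], ploidy = pl,
                 cna_gain = burden["gain"], cna_loss = burden["loss"],
                 wgii = compute_wgii(p, ploidy = pl))
    })
    do.call(rbind, rows)
  })
  rownames(cov) <- NULL
  write_tsv(cov, file.path(outdir, "genomic_covariates.tsv"))

  exprsim <- stage("immune", simulate_expression(scfg, cohort$labels))
  write_gmt(exprsim$sets, file.path(outdir, "cell_signatures.gmt"))
  gm <- stage("immune", geometric_mean_scores(exprsim$expr, exprsim$sets,
                                              expr_scale = "log2"))
  ss <- stage("immune", ssgsea(exprsim$expr, exprsim$sets))
  ratios <- stage("immune", cell_ratios(gm))
  cyto <- stage("immune", cytokine_ratio(exprsim$expr, expr_scale = "log2"))
  diffs <- stage("immune", pathway_differential(ss, cohort$labels))
  write_tsv(as.data.frame(ss), file.path(outdir, "ssgsea_scores.tsv"))
  write_tsv(ratios, file.path(outdir, "cell_ratios.tsv"))
  write_tsv(data.frame(sample_id = names(cyto), log2_pro_anti = cyto),
            file.path(outdir, "cytokine_ratio.tsv"))
  write_tsv(diffs, file.path(outdir, "pathway_differential.tsv"))

  clinical <- stage("survival", simulate_survival(cps, scfg))
  clinical$cd8a <- exprsim$expr["CD8A", clinical$sample_id]
  clinical$pdl1 <- exprsim$expr["CD274", clinical$sample_id]
  write_tsv(clinical, file.path(outdir, "clinical.tsv"))
  biomarkers <- list(CPS = cps, TMB = cov$tmb, wGII = cov$wgii,
                     CNA_gain = cov$cna_gain, CNA_loss = cov$cna_loss,
                     CD8A = clinical$cd8a, PDL1 = clinical$pdl1)
  surv_stats <- stage("survival", {
    rows <- lapply(names(biomarkers), function(nm) {
      v <- as.numeric(biomarkers[[nm]])
      grp <- median_groups(v)
      cx <- cox_univariate(clinical$os_time, clinical$os_event, grp)
      km <- km_logrank(clinical$os_time, clinical$os_event, grp)
      data.frame(biomarker = nm, hr = cx$hr, ci_low = cx$ci[1],
                 ci_high = cx$ci[2], cox_p = cx$p_value,
                 logrank_p = km$p_value,
                 median_low = km$median_survival["FALSE"],
                 median_high = km$median_survival["TRUE"])
    })
    do.call(rbind, rows)
  })
  rownames(surv_stats) <- NULL
  write_tsv(surv_stats, file.path(outdir, "survival_stats.tsv"))
  auc_t <- stage("survival", {
    rows <- lapply(names(biomarkers), function(nm) {
      d <- time_dependent_auc(clinical$os_time, clinical$os_event,
                              as.numeric(biomarkers[[nm]]),
                              config$survival$time_grid)
      cbind(biomarker = nm, d)
    })
    do.call(rbind, rows)
  })
  write_tsv(auc_t, file.path(outdir, "auc_t.tsv"))
  rr <- stage("survival", response_rates(clinical$response,
                                         clinical$sd_duration,
                                         median_groups(cps)))
  write_tsv(data.frame(
    definition = c("responder", "objective"),
    rate_low = c(rr$responder$rates["low"], rr$objective$rates["low"]),
    rate_high = c(rr$responder$rates["high"], rr$objective$rates["high"]),
    fisher_p = c(rr$responder$p_value, rr$objective$p_value)
  ), file.path(outdir, "response_rates.tsv"))

  writeLines(log_lines, file.path(outdir, "run_log.txt"))
  outputs <- setdiff(list.files(outdir, full.names = TRUE),
                     file.path(outdir, "checksums.txt"))
  checks <- tools::md5sum(sort(outputs))
  manifest <- data.frame(file = basename(names(checks)), md5 = unname(checks))
  write_tsv(manifest, file.path(outdir, "checksums.txt"))
  invisible(list(outdir = outdir, checksums = manifest,
                 detector = ct_flags, cps = cps, cv_auc = cps_model$cv_auc,
                 covariates = cov, survival_stats = surv_stats))
}

#' Synthetic protein-coding gene intervals for the simulator genome
#'
#' Evenly spaced 20 kb gene intervals along each autosome (one per 2 Mb),
#' used for CNA-burden computation on synthetic cohorts.
#'
#' @param cfg a [sim_config()].
#' @return data.frame with `chrom`, `start`, `end`, `gene`.
#' @export
synthetic_gene_intervals <- function(cfg) {
  autos <- cfg$genome[is_autosome(cfg$genome$chrom), , drop = FALSE]
  rows <- lapply(seq_len(nrow(autos)), function(i) {
    starts <- seq(1e6, autos$length[i] - 2e4, by = 2e6)
    data.frame(chrom = autos$chrom[i], start = starts, end = starts + 2e4 - 1,
               gene = sprintf("%s_g%03d", autos$chrom[i], seq_along(starts)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
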