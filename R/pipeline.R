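#' Pipeline configuration
#'
#' Collects every stage parameter with the analysis defaults: call rate 0.95,
#' MAF 0.05, SNP missingness 0.01, HWE exact p 1e-5, pi_hat 0.1875, the
#' 10-threshold scoring grid, term cutoff 37 weeks, extremes tail 20%, SNP
#' scan cutoff 0.01, minimum pathway overlap 4, 1000 resampling runs, FDR
#' 0.05.
#'
#' @param sim a [sim_config()] describing the synthetic study (used when no
#'   input paths are given).
#' @param inputs optional named list of file paths (`geno` VCF, `sumstats`,
#'   `volumes`, `covars`, `annotation`, `gmt`) read instead of simulating.
#' @param min_call_rate,maf_min,max_missing,hwe_p_min,pi_hat_cutoff sample
#'   and SNP QC thresholds.
#' @param prune_window,prune_step,prune_r2 LD pruning parameters.
#' @param clump_window_kb,clump_r2 clumping parameters.
#' @param thresholds scoring p-value grid.
#' @param n_ancestry_pcs ancestry components used as covariates, default 3.
#' @param outlier_sd PC outlier cutoff in standard deviations, default 3.
#' @param min_ga term-birth gestational age cutoff (weeks), default 37.
#' @param n_split_reps split-half replicates, default 1000.
#' @param extremes_tail score-extremes tail fraction, default 0.2.
#' @param scan_cutoff SNP scan p cutoff, default 0.01.
#' @param min_overlap minimum pathway overlap, default 4.
#' @param n_null_runs specificity-null draws, default 1000.
#' @param fdr_alpha FDR level, default 0.05.
#' @param run_stability,run_enrichment stage toggles.
#' @param out_dir optional output directory for stage tables.
#' @param seed master seed; per-stage seeds are derived from it.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), inputs = NULL,
                            min_call_rate = 0.95, maf_min = 0.05,
                            max_missing = 0.01, hwe_p_min = 1e-5,
                            pi_hat_cutoff = 0.1875,
                            prune_window = 50, prune_step = 5,
                            prune_r2 = 0.2,
                            clump_window_kb = 250, clump_r2 = 0.1,
                            thresholds = default_thresholds(),
                            n_ancestry_pcs = 3, outlier_sd = 3,
                            min_ga = 37, n_split_reps = 1000,
                            extremes_tail = 0.2, scan_cutoff = 0.01,
                            min_overlap = 4, n_null_runs = 1000,
                            fdr_alpha = 0.05,
                            run_stability = TRUE, run_enrichment = TRUE,
                            out_dir = NULL, seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes, in order: input generation (or reading), sample call-rate
#' filtering, LD pruning + relatedness resolution, SNP filtering, ancestry
#' PCA with outlier exclusion, clumping + multi-threshold scoring + score
#' PCA, cohort filtering and lobe aggregation, the primary six-lobe
#' regression with FDR, the three stability tests, and the gene-set
#' enrichment analysis. Returns all stage results plus a manifest of counts
#' and seeds; writes stage tables under `out_dir` when configured.
#'
#' @param config a [pipeline_config()].
#' @return list with `results` (per stage) and `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  manifest <- list(seed = config$seed, stages = list(),
                  parameters = config[setdiff(names(config),
                                              c("sim", "inputs", "out_dir"))])
  note <- function(stage, ...) {
    manifest$stages[[stage]] <<- list(...)
  }

  # -- inputs
  if (is.null(config$inputs)) {
    study <- generate_study(config$sim)
  } else {
    ip <- config$inputs
    study <- list(geno = read_vcf(ip$geno),
                  stats = read_sumstats(ip$sumstats),
                  volumes = read_tsv(ip$volumes),
                  covars = read_tsv(ip$covars),
                  annotation = if (!is.null(ip$annotation))
                    read_annotation(ip$annotation) else NULL,
                  db = if (!is.null(ip$gmt)) read_gmt(ip$gmt) else NULL,
                  truth = NULL)
  }
  note("inputs", n_samples = nrow(study$geno$samples),
       n_snps = nrow(study$geno$variants))

  # -- sample QC
  cr <- sample_call_rate_filter(study$geno, config$min_call_rate)
  geno <- cr$geno
  pruned <- ld_prune(geno, config$prune_window, config$prune_step,
                     config$prune_r2)
  rel <- estimate_relatedness(geno, pruned)
  rf <- relatedness_filter(rel, config$pi_hat_cutoff,
                           seed = derive_seed(config$seed, "pipeline_rel"))
  geno <- subset_geno(geno, samples = rf$keep_ids)
  sf <- snp_filter(geno, config$maf_min, config$max_missing,
                   config$hwe_p_min)
  geno <- sf$geno
  note("qc", call_rate = cr$report, relatedness = rf$report,
       snp_filter = sf$report, n_pruned = length(pruned))

  # -- ancestry components and outliers
  k_pc <- max(config$n_ancestry_pcs, 3)
  pcs <- pca_genotypes(geno, k = k_pc)
  of <- pc_outlier_filter(pcs, n_components = 3, n_sd = config$outlier_sd)
  geno <- subset_geno(geno, samples = of$keep_ids)
  pcs <- pca_genotypes(geno, k = k_pc)   # recomputed on the retained cohort
  note("ancestry", outliers = of$report)

  # -- polygenic scores
  clumped <- clump(study$stats, geno, config$clump_window_kb,
                   config$clump_r2)
  prs <- prs_score(geno, study$stats, clumped, config$thresholds)
  note("prs", n_clumped = length(clumped), n_snps_used = prs$n_snps_used)

  # -- phenotype cohort
  cf <- cohort_filter(study$volumes, study$covars, config$min_ga)
  lobes_all <- aggregate_lobes(cf$volumes)
  ids <- intersect(geno$samples$id, lobes_all$sample_id)
  if (length(ids) < 40) stop("analysis cohort too small: ", length(ids),
                             call. = FALSE)
  li <- match(ids, lobes_all$sample_id)
  ci <- match(ids, cf$covars$sample_id)
  lobes <- lobes_all[li, , drop = FALSE]
  pc_cov <- pcs$coordinates[ids, seq_len(config$n_ancestry_pcs),
                            drop = FALSE]
  covars <- data.frame(ga = cf$covars$ga[ci], pma = cf$covars$pma[ci],
                       sex = cf$covars$sex[ci], tbv = lobes$tbv, pc_cov)
  prs_sub <- structure(list(scores = prs$scores[ids, , drop = FALSE],
                            thresholds = prs$thresholds,
                            n_snps_used = prs$n_snps_used),
                       class = "prs_matrix")
  pc1 <- prs_pca(prs_sub)
  note("cohort", filters = cf$reports, n_analysis = length(ids),
       prs_pc1_variance = pc1$variance_explained)

  # -- primary association
  primary <- run_primary(pc1$values, lobes, covars, alpha = config$fdr_alpha)

  stability <- NULL
  if (config$run_stability) {
    stability <- list(
      split_half = split_half_stability(prs_sub, lobes, covars,
                                        full_results = primary,
                                        n_reps = config$n_split_reps,
                                        seed = derive_seed(config$seed,
                                                           "pipeline_split")),
      extremes = extremes_test(prs_sub, lobes, covars,
                               tail = config$extremes_tail),
      per_threshold = per_threshold_regression(prs_sub, lobes, covars))
  }
  note("stability", run = config$run_stability)

  enrichment <- NULL
  if (config$run_enrichment) {
    if (is.null(study$annotation) || is.null(study$db))
      stop("enrichment stage requires annotation and pathway inputs",
           call. = FALSE)
    panel <- subset_geno(geno, samples = ids, snps = clumped)
    enrichment <- enrich_analysis(panel, lobes, covars, study$annotation,
                                  study$db, cutoff = config$scan_cutoff,
                                  min_overlap = config$min_overlap,
                                  n_runs = config$n_null_runs,
                                  seed = derive_seed(config$seed,
                                                     "pipeline_enrich"))
  }
  note("enrichment", run = config$run_enrichment)

  manifest$wall_clock_sec <- as.numeric(difftime(Sys.time(), t0,
                                                 units = "secs"))
  results <- list(truth = study$truth, primary = primary, prs_pc1 = pc1,
                  prs = prs_sub, lobes = lobes, covars = covars,
                  stability = stability, enrichment = enrichment,
                  analysis_ids = ids)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(primary, file.path(config$out_dir, "primary_association.tsv"))
    write_tsv(data.frame(sample_id = names(pc1$values),
                         prs_pc1 = unname(pc1$values)),
              file.path(config$out_dir, "prs_pc1.tsv"))
    write_tsv(data.frame(sample_id = rownames(prs_sub$scores),
                         prs_sub$scores, check.names = FALSE),
              file.path(config$out_dir, "prs_matrix.tsv"))
    if (!is.null(stability)) {
      write_tsv(data.frame(lobe = names(stability$split_half$consistency),
                           consistency =
                             unname(stability$split_half$consistency)),
                file.path(config$out_dir, "split_half.tsv"))
      write_tsv(stability$extremes,
                file.path(config$out_dir, "extremes.tsv"))
      write_tsv(stability$per_threshold,
                file.path(config$out_dir, "per_threshold.tsv"))
    }
    if (!is.null(enrichment)) {
      for (nm in names(enrichment$tables))
        write_tsv(enrichment$tables[[nm]],
                  file.path(config$out_dir, paste0("enrichment_", nm,
                                                   ".tsv")))
    }
    jsonlite::write_json(
      list(seed = manifest$seed,
           stages = rapply(manifest$stages, unclass, how = "replace"),
           wall_clock_sec = manifest$wall_clock_sec),
      file.path(config$out_dir, "manifest.json"), auto_unbox = TRUE,
      digits = NA, force = TRUE)
  }

  list(results = results, manifest = manifest)
}
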