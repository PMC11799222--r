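#' Simulation configuration
#'
#' Bundles every knob of the synthetic cohort generator. Defaults describe the
#' study conditions the pipeline is designed for: a term-born neonatal cohort
#' of 600 with LD-block genotypes, a large external discovery GWAS, and
#' opposite-sign planted polygenic effects on the fronto-temporal (+0.2) and
#' parieto-occipital (-0.2) lobe composites.
#'
#' @param n_samples number of cohort individuals.
#' @param n_snps number of biallelic autosomal SNPs.
#' @param n_blocks number of LD blocks; SNPs are split as evenly as possible.
#' @param maf_range length-2 numeric in (0, 0.5]; per-SNP allele frequencies
#'   are drawn uniformly from this range.
#' @param ld_rho within-block adjacent-SNP haplotype correlation, in [0, 1).
#' @param missing_rate independent missing-call rate, in [0, 0.1].
#' @param n_causal number of causal SNPs (at most one per LD block, so that
#'   clumping cannot merge two causal loci).
#' @param discovery_n effective sample size of the simulated discovery GWAS.
#' @param h2 variance of the genetic value on the standardized-genotype scale;
#'   per-causal-SNP effects are N(0, h2 / n_causal).
#' @param beta_ft,beta_po planted standardized effects of the genetic value on
#'   the fronto-temporal and parieto-occipital lobe composites.
#' @param region_noise per-region noise standard deviation as a fraction of
#'   the region's mean volume.
#' @param n_pathways number of random decoy pathways in the gene-set database.
#' @param pathway_size_range length-2 integer range of decoy pathway sizes.
#' @param radiology5_rate fraction of scans flagged with radiology score 5.
#' @param dup_session_rate fraction of subjects with a duplicate second scan.
#' @param equal_effects draw causal effects with fixed magnitude
#'   sqrt(h2 / n_causal) and random sign instead of a normal prior; used when
#'   a known per-SNP effect size must be realized exactly.
#' @param seed master seed; identical seeds give bit-identical outputs.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 600, n_snps = 2000, n_blocks = 100,
                       maf_range = c(0.05, 0.5), ld_rho = 0.3,
                       missing_rate = 0.002, n_causal = 20,
                       discovery_n = 2e5, h2 = 0.5,
                       beta_ft = 0.2, beta_po = -0.2,
                       region_noise = 0.1, n_pathways = 50,
                       pathway_size_range = c(10, 40),
                       radiology5_rate = 0.05, dup_session_rate = 0.02,
                       equal_effects = FALSE, seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples), n_snps = as.integer(n_snps),
              n_blocks = as.integer(n_blocks), maf_range = as.numeric(maf_range),
              ld_rho = ld_rho, missing_rate = missing_rate,
              n_causal = as.integer(n_causal), discovery_n = discovery_n,
              h2 = h2, beta_ft = beta_ft, beta_po = beta_po,
              region_noise = region_noise, n_pathways = as.integer(n_pathways),
              pathway_size_range = as.integer(pathway_size_range),
              radiology5_rate = radiology5_rate,
              dup_session_rate = dup_session_rate,
              equal_effects = isTRUE(equal_effects), seed = as.integer(seed))
  if (cfg$n_samples < 1 || cfg$n_snps < 1 || cfg$n_blocks < 1)
    stop("n_samples, n_snps and n_blocks must be positive", call. = FALSE)
  if (cfg$n_blocks > cfg$n_snps)
    stop("n_blocks cannot exceed n_snps", call. = FALSE)
  if (length(cfg$maf_range) != 2 || cfg$maf_range[1] <= 0 ||
      cfg$maf_range[2] > 0.5 || cfg$maf_range[1] > cfg$maf_range[2])
    stop("maf_range must be within (0, 0.5]", call. = FALSE)
  if (cfg$ld_rho < 0 || cfg$ld_rho >= 1)
    stop("ld_rho must be in [0, 1)", call. = FALSE)
  if (cfg$missing_rate < 0 || cfg$missing_rate > 0.1)
    stop("missing_rate must be in [0, 0.1]", call. = FALSE)
  if (cfg$n_causal > cfg$n_snps)
    stop("n_causal cannot exceed n_snps", call. = FALSE)
  if (cfg$n_causal > cfg$n_blocks)
    stop("n_causal cannot exceed n_blocks (one causal locus per block)",
         call. = FALSE)
  if (cfg$discovery_n <= 0)
    stop("discovery_n must be positive", call. = FALSE)
  class(cfg) <- "sim_config"
  cfg
}

# Non-ambiguous ref/alt pairs (no A/T or C/G), so no scored SNP is dropped as
# strand-ambiguous during allele harmonization.
.allele_pairs <- matrix(c("A","C", "A","G", "C","A", "C","T",
                          "G","A", "G","T", "T","C", "T","G"),
                        ncol = 2, byrow = TRUE)

#' Generate LD-block genotypes
#'
#' Haplotypes are drawn per LD block from a first-order Markov chain whose
#' transition probabilities give each SNP its drawn allele frequency exactly
#' and an adjacent-SNP correlation of `ld_rho` (clamped to the Frechet bounds
#' where the frequency pair makes `ld_rho` infeasible). Blocks are independent
#' and are laid out across autosomes 1-22 with 5 kb spacing within a block and
#' a 500 kb gap between blocks.
#'
#' @param config a [sim_config()].
#' @return A [genotype_matrix()]; `variants$freq` records each SNP's drawn
#'   alt-allele frequency.
#' @export
generate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, "genotypes"), {
    n <- config$n_samples
    m <- config$n_snps
    block_of <- sort(rep_len(seq_len(config$n_blocks), m))
    f <- stats::runif(m, config$maf_range[1], config$maf_range[2])
    n_hap <- 2L * n
    hap <- matrix(0L, n_hap, m)
    rho <- config$ld_rho
    for (b in seq_len(config$n_blocks)) {
      idx <- which(block_of == b)
      hap[, idx[1]] <- stats::rbinom(n_hap, 1L, f[idx[1]])
      if (length(idx) > 1) for (k in 2:length(idx)) {
        jp <- idx[k - 1]; j <- idx[k]
        fp <- f[jp]; fj <- f[j]
        p11 <- fp * fj + rho * sqrt(fp * (1 - fp) * fj * (1 - fj))
        p11 <- min(max(p11, max(0, fp + fj - 1)), min(fp, fj))
        prev <- hap[, jp]
        pr <- ifelse(prev == 1L, p11 / fp, (fj - p11) / (1 - fp))
        hap[, j] <- stats::rbinom(n_hap, 1L, pr)
      }
    }
    dos <- hap[seq(1, n_hap, by = 2), , drop = FALSE] +
           hap[seq(2, n_hap, by = 2), , drop = FALSE]
    if (config$missing_rate > 0) {
      miss <- matrix(stats::runif(n * m) < config$missing_rate, n, m)
      dos[miss] <- NA_real_
    }
    # layout: blocks round-robin over chromosomes, coordinates 1-based
    chrom_of_block <- ((seq_len(config$n_blocks) - 1L) %% 22L) + 1L
    chrom <- chrom_of_block[block_of]
    pos <- integer(m)
    for (ch in unique(chrom)) {
      on_ch <- which(chrom == ch)
      blocks_here <- block_of[on_ch]
      offset_within <- stats::ave(seq_along(on_ch), blocks_here,
                                  FUN = seq_along)
      block_rank <- match(blocks_here, sort(unique(blocks_here)))
      pos[on_ch] <- 1e6L + (block_rank - 1L) * 5e5L +
        (offset_within - 1L) * 5e3L
    }
    pair <- .allele_pairs[sample.int(nrow(.allele_pairs), m, replace = TRUE), ,
                          drop = FALSE]
    variants <- data.frame(id = sprintf("rs%05d", seq_len(m)),
                           chrom = as.character(chrom), pos = pos,
                           ref = pair[, 1], alt = pair[, 2],
                           freq = f, block = block_of,
                           stringsAsFactors = FALSE)
    samples <- data.frame(id = sprintf("S%04d", seq_len(n)),
                          sex = stats::rbinom(n, 1L, 0.5),
                          stringsAsFactors = FALSE)
    genotype_matrix(dos, variants, samples)
  })
}

#' Simulate discovery-GWAS summary statistics with planted causal SNPs
#'
#' Picks `n_causal` causal SNPs (one LD block each), draws their standardized
#' effects from N(0, h2 / n_causal), and reports for every SNP a per-allele
#' effect estimate equal to the true effect plus noise with standard error
#' 1 / sqrt(discovery_n * 2 f (1 - f)), together with the two-sided normal
#' p-value. The alt allele is the effect allele.
#'
#' @param geno a [genotype_matrix()] from [generate_genotypes()].
#' @param config the same [sim_config()].
#' @return list with `stats` (data.frame SNP/CHR/BP/A1/A2/BETA/P) and `truth`
#'   (causal ids, standardized and per-allele true effects).
#' @export
generate_summary_stats <- function(geno, config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$discovery_n <= 0)
    stop("discovery_n must be positive", call. = FALSE)
  if (is.null(geno$variants$freq) || is.null(geno$variants$block))
    stop("geno must come from generate_genotypes()", call. = FALSE)
  with_seed(derive_seed(config$seed, "sumstats"), {
    v <- geno$variants
    m <- nrow(v)
    causal_idx <- integer(0)
    u <- numeric(0)
    if (config$n_causal > 0) {
      # causal variants sit at intermediate frequencies (0.1-0.45): the
      # discovery GWAS has power there and genotype QC cannot silently drop
      # a planted signal at the MAF boundary
      lo <- max(0.1, config$maf_range[1])
      hi <- min(0.45, config$maf_range[2])
      eligible <- v$freq >= lo & v$freq <= hi
      if (!any(eligible)) eligible <- rep(TRUE, nrow(v))
      elig_blocks <- unique(v$block[eligible])
      if (length(elig_blocks) < config$n_causal)
        stop("too few LD blocks with causal-eligible SNPs", call. = FALSE)
      blocks <- sample(elig_blocks, config$n_causal)
      causal_idx <- vapply(blocks, function(b) {
        cand <- which(v$block == b & eligible)
        cand[sample.int(length(cand), 1L)]
      }, integer(1))
      causal_idx <- sort(causal_idx)
      u <- if (config$equal_effects)
        sample(c(-1, 1), config$n_causal, replace = TRUE) *
          sqrt(config$h2 / config$n_causal)
      else
        stats::rnorm(config$n_causal, 0, sqrt(config$h2 / config$n_causal))
    }
    f <- v$freq
    het <- 2 * f * (1 - f)
    beta_true <- numeric(m)
    beta_true[causal_idx] <- u / sqrt(het[causal_idx])
    se <- 1 / sqrt(config$discovery_n * het)
    beta_hat <- beta_true + stats::rnorm(m, 0, se)
    p <- 2 * stats::pnorm(-abs(beta_hat / se))
    p <- pmax(p, .Machine$double.xmin)   # keep p in (0, 1]
    stats <- data.frame(SNP = v$id, CHR = v$chrom, BP = v$pos,
                        A1 = v$alt, A2 = v$ref,
                        BETA = beta_hat, P = p, stringsAsFactors = FALSE)
    truth <- list(causal_snp_ids = v$id[causal_idx],
                  true_betas_std = u,
                  true_betas_allelic = beta_true[causal_idx],
                  planted_lobe_effects = c(fronto_temporal = config$beta_ft,
                                           parieto_occipital = config$beta_po),
                  planted_pathway_id = "PW_PLANTED")
    list(stats = stats, truth = truth)
  })
}

# Parcellation regions emulated by the generator: name, lobe membership and
# share of total brain tissue volume. Shares sum to 1 so TBV is the row sum.
.region_table <- function() {
  data.frame(
    region = c("frontal_gm", "frontal_wm",
               "stg_middle", "stg_posterior", "itg_anterior", "itg_posterior",
               "atl_medial", "atl_lateral",
               "parietal_gm", "parietal_wm",
               "occipital_gm", "occipital_wm", "lat_occipitotemporal_gyrus",
               "fusiform_anterior", "fusiform_posterior",
               "cingulate_gm", "insula_gm", "other_wm",
               "deep_gm", "cerebellum", "brainstem"),
    lobe = c("frontal", "frontal",
             rep("temporal", 6),
             "parietal", "parietal",
             rep("occipital", 5),
             "other", "other", "other",
             "deep", "cerebellum", "brainstem"),
    share = c(0.11, 0.07,
              0.016, 0.014, 0.013, 0.014, 0.011, 0.012,
              0.09, 0.06,
              0.05, 0.03, 0.012, 0.009, 0.009,
              0.03, 0.02, 0.27,
              0.08, 0.06, 0.02),
    stringsAsFactors = FALSE)
}

#' Default lobe map for the synthetic parcellation
#'
#' Maps the four cortical lobes to their constituent regions. The temporal
#' lobe is built from the superior temporal gyrus (middle, posterior), the
#' inferior temporal gyri (anterior, posterior) and the anterior temporal
#' lobe (medial, lateral); the occipital lobe includes the lateral
#' occipitotemporal gyrus and the fusiform gyrus (anterior, posterior).
#' Composites: fronto-temporal = frontal + temporal, parieto-occipital =
#' parietal + occipital.
#'
#' @return named list of character vectors, one per lobe.
#' @export
default_lobe_map <- function() {
  rt <- .region_table()
  lapply(split(rt$region, rt$lobe)[c("frontal", "temporal", "parietal",
                                     "occipital")], identity)
}

# Regions whose sum defines total brain tissue volume: cortical grey + white
# matter, deep grey matter, cerebellum and brainstem = all emulated regions.
.tbv_regions <- function() .region_table()$region

#' Generate regional volumes and covariates with planted lobe effects
#'
#' Emulates a term-born neonatal cohort: GA ~ N(40.16, 1.22^2) truncated at
#' 37 weeks, PMA = GA + U(0, 4), sex balanced. A latent total-brain-volume
#' (mean 380,251 mm^3) grows linearly in GA, PMA and sex; each parcellation
#' region is its share of that latent volume plus Gaussian noise. The genetic
#' value (standardized true polygenic score) is planted on the
#' fronto-temporal and parieto-occipital composites at standardized effects
#' `beta_ft` and `beta_po`, split evenly between each composite's two lobes,
#' calibrated so the composite's total-SD-standardized regression coefficient
#' equals the planted value. Radiology-score-5 scans and duplicate sessions
#' are included so cohort filters are exercisable.
#'
#' @param geno a [genotype_matrix()] from [generate_genotypes()].
#' @param truth ground truth from [generate_summary_stats()].
#' @param config the same [sim_config()].
#' @return list with `volumes` (sample_id, session, one column per region),
#'   `covars` (sample_id, session, ga, pma, sex, radiology_score) and
#'   `genetic_value` (the planted standardized score, for diagnostics).
#' @export
generate_phenotypes <- function(geno, truth, config) {
  stopifnot(inherits(config, "sim_config"))
  missing_truth <- setdiff(truth$causal_snp_ids, geno$variants$id)
  if (length(missing_truth))
    stop("truth causal SNPs absent from genotype panel: ",
         paste(missing_truth, collapse = ", "), call. = FALSE)
  with_seed(derive_seed(config$seed, "phenotypes"), {
    n <- config$n_samples
    ids <- geno$samples$id
    # genetic value on standardized genotypes of the causal SNPs
    g <- rep(0, n)
    if (length(truth$causal_snp_ids)) {
      ci <- match(truth$causal_snp_ids, geno$variants$id)
      X <- geno$dosages[, ci, drop = FALSE]
      f <- geno$variants$freq[ci]
      for (k in seq_along(ci)) {
        x <- X[, k]
        x[is.na(x)] <- 2 * f[k]
        g <- g + truth$true_betas_std[k] * (x - 2 * f[k]) /
          sqrt(2 * f[k] * (1 - f[k]))
      }
      if (stats::sd(g) > 0) g <- zscore(g)
    }
    ga <- stats::qnorm(stats::runif(n, stats::pnorm(37, 40.16, 1.22), 1),
                       40.16, 1.22)
    pma <- ga + stats::runif(n, 0, 4)
    sex <- geno$samples$sex
    tbv_mean <- 380251
    tbv_lat <- tbv_mean + 5000 * (ga - 40.16) + 20000 * (pma - 41.75) +
      15000 * (sex - 0.5) + stats::rnorm(n, 0, 30000)
    var_lat <- stats::var(tbv_lat)

    rt <- .region_table()
    shares <- stats::setNames(rt$share, rt$region)
    noise_sd <- config$region_noise * shares * tbv_mean

    # per-composite raw genetic coefficient calibrated to the planted
    # standardized effect: var_total = (share^2 var_lat + var_noise)/(1 - b^2)
    comp <- list(fronto_temporal = c("frontal", "temporal"),
                 parieto_occipital = c("parietal", "occipital"))
    betas <- c(fronto_temporal = config$beta_ft,
               parieto_occipital = config$beta_po)
    g_coef <- stats::setNames(rep(0, nrow(rt)), rt$region)
    for (cn in names(comp)) {
      rsel <- rt$lobe %in% comp[[cn]]
      b <- betas[[cn]]
      if (abs(b) >= 1) stop("planted |beta| must be < 1", call. = FALSE)
      base_var <- sum(shares[rsel])^2 * var_lat + sum(noise_sd[rsel]^2)
      c_comp <- b * sqrt(base_var / (1 - b^2))
      # split evenly between the two lobes, then by share within lobe
      for (lb in comp[[cn]]) {
        lsel <- rt$lobe == lb
        g_coef[lsel] <- (c_comp / 2) * shares[lsel] / sum(shares[lsel])
      }
    }

    vol <- matrix(0, n, nrow(rt), dimnames = list(NULL, rt$region))
    for (j in seq_len(nrow(rt))) {
      vol[, j] <- shares[j] * tbv_lat + g_coef[j] * g +
        (if (noise_sd[j] > 0) stats::rnorm(n, 0, noise_sd[j]) else 0)
    }

    radiology <- ifelse(stats::runif(n) < config$radiology5_rate, 5L,
                        sample(1:4, n, replace = TRUE))
    volumes <- data.frame(sample_id = ids, session = 1L, vol,
                          stringsAsFactors = FALSE)
    covars <- data.frame(sample_id = ids, session = 1L, ga = ga, pma = pma,
                         sex = sex, radiology_score = radiology,
                         stringsAsFactors = FALSE)

    # duplicate second scans for a small fraction of subjects
    n_dup <- round(config$dup_session_rate * n)
    if (n_dup > 0) {
      di <- sample.int(n, n_dup)
      v2 <- volumes[di, , drop = FALSE]
      v2$session <- 2L
      v2[, rt$region] <- v2[, rt$region] * 1.01
      c2 <- covars[di, , drop = FALSE]
      c2$session <- 2L
      c2$pma <- c2$pma + 0.5
      volumes <- rbind(volumes, v2)
      covars <- rbind(covars, c2)
    }
    rownames(volumes) <- rownames(covars) <- NULL
    list(volumes = volumes, covars = covars,
         genetic_value = stats::setNames(g, ids))
  })
}

#' Generate gene annotation and a pathway database with a planted pathway
#'
#' Lays non-overlapping genes along each chromosome: one 20 kb gene centred on
#' every causal SNP, then 20 kb genes tiled across the remaining span with
#' 15 kb intergenic gaps (so some SNPs map to no gene). The planted pathway
#' `PW_PLANTED` contains exactly the causal-host genes plus a few random
#' members; decoy pathways are random gene subsets.
#'
#' @param geno a [genotype_matrix()].
#' @param truth ground truth from [generate_summary_stats()].
#' @param config the same [sim_config()].
#' @return list with `annotation` (data.frame gene_id, chrom, start, stop;
#'   1-based inclusive) and `db` (a pathway database: `pathways` named list,
#'   `background_n`).
#' @export
generate_annotation <- function(geno, truth, config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, "annotation"), {
    v <- geno$variants
    span <- 20000L; gap <- 15000L
    rows <- list()
    causal_pos <- v[v$id %in% truth$causal_snp_ids, c("chrom", "pos")]
    for (ch in unique(v$chrom)) {
      lo <- min(v$pos[v$chrom == ch]) - span
      hi <- max(v$pos[v$chrom == ch]) + span
      cp <- sort(causal_pos$pos[causal_pos$chrom == ch])
      anchored <- if (length(cp))
        data.frame(start = cp - span %/% 2L, stop = cp + span %/% 2L)
      else data.frame(start = integer(0), stop = integer(0))
      # tile the gaps around anchored genes
      bounds <- rbind(data.frame(start = lo - 1L, stop = lo - 1L), anchored,
                      data.frame(start = hi + 1L, stop = hi + 1L))
      tiled <- list()
      for (k in seq_len(nrow(bounds) - 1L)) {
        cur <- bounds$stop[k] + gap + 1L
        while (cur + span <= bounds$start[k + 1L] - gap - 1L) {
          tiled[[length(tiled) + 1L]] <- c(cur, cur + span)
          cur <- cur + span + gap + 1L
        }
      }
      genes <- rbind(anchored,
                     if (length(tiled))
                       stats::setNames(as.data.frame(do.call(rbind, tiled)),
                                       c("start", "stop"))
                     else NULL)
      genes <- genes[order(genes$start), , drop = FALSE]
      genes$chrom <- ch
      genes$causal <- genes$start %in% (anchored$start)
      rows[[ch]] <- genes
    }
    ann <- do.call(rbind, rows)
    ord <- order(as.integer(ann$chrom), ann$start)
    ann <- ann[ord, , drop = FALSE]
    ann$gene_id <- sprintf("GENE%04d", seq_len(nrow(ann)))
    annotation <- data.frame(gene_id = ann$gene_id, chrom = ann$chrom,
                             start = as.integer(ann$start),
                             stop = as.integer(ann$stop),
                             stringsAsFactors = FALSE)
    rownames(annotation) <- NULL

    causal_genes <- ann$gene_id[ann$causal]
    all_genes <- annotation$gene_id
    szr <- config$pathway_size_range
    if (max(szr) > length(all_genes))
      stop("pathway size exceeds gene count", call. = FALSE)
    planted_extra <- sample(setdiff(all_genes, causal_genes),
                            min(5L, length(all_genes) - length(causal_genes)))
    pathways <- list(PW_PLANTED = sort(unique(c(causal_genes, planted_extra))))
    for (k in seq_len(config$n_pathways)) {
      sz <- sample(seq(szr[1], szr[2]), 1L)
      pathways[[sprintf("PW_%04d", k)]] <- sort(sample(all_genes, sz))
    }
    list(annotation = annotation,
         db = pathway_db(pathways, background_n = length(all_genes)))
  })
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper running all four generators in order.
#'
#' @param config a [sim_config()].
#' @return list with `geno`, `stats`, `truth`, `volumes`, `covars`,
#'   `genetic_value`, `annotation`, `db`.
#' @export
generate_study <- function(config = sim_config()) {
  geno <- generate_genotypes(config)
  ss <- generate_summary_stats(geno, config)
  ph <- generate_phenotypes(geno, ss$truth, config)
  an <- generate_annotation(geno, ss$truth, config)
  list(geno = geno, stats = ss$stats, truth = ss$truth,
       volumes = ph$volumes, covars = ph$covars,
       genetic_value = ph$genetic_value,
       annotation = an$annotation, db = an$db)
}
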