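#' Construct a pathway database
#'
#' @param pathways named list of character gene-id vectors; all non-empty.
#' @param background_n number of background genes; must be at least the size
#'   of the union of pathway genes.
#' @param background_genes optional character vector of the background gene
#'   universe; when supplied, gene lists are restricted to it before testing.
#' @return list of class `pathway_db`.
#' @export
pathway_db <- function(pathways, background_n, background_genes = NULL) {
  if (!length(pathways) || is.null(names(pathways)) ||
      any(!nzchar(names(pathways))))
    stop("pathways must be a non-empty named list", call. = FALSE)
  if (any(vapply(pathways, length, integer(1)) == 0))
    stop("every pathway must be non-empty", call. = FALSE)
  union_n <- length(unique(unlist(pathways, use.names = FALSE)))
  if (background_n < union_n)
    stop("background_n (", background_n, ") smaller than pathway gene union (",
         union_n, ")", call. = FALSE)
  if (!is.null(background_genes) && background_n != length(background_genes))
    stop("background_n must equal length(background_genes)", call. = FALSE)
  structure(list(pathways = pathways, background_n = as.integer(background_n),
                 background_genes = background_genes),
            class = "pathway_db")
}

#' Bonferroni significance cut for pathway enrichment
#'
#' The family-wise threshold on the raw hypergeometric p-value when testing
#' `n_pathways` pathways against `n_gene_lists` gene lists.
#'
#' @param n_pathways number of pathways tested, default 13159.
#' @param n_gene_lists number of gene lists, default 3.
#' @param alpha family-wise error rate, default 0.05.
#' @return the threshold alpha / (n_pathways * n_gene_lists).
#' @export
bonferroni_cut <- function(n_pathways = 13159, n_gene_lists = 3,
                           alpha = 0.05) {
  alpha / (n_pathways * n_gene_lists)
}

#' Per-SNP association scan against two lobe composites
#'
#' For every SNP, ordinary least squares of the standardized fronto-temporal
#' and parieto-occipital composite volumes on the SNP's effect-allele dosage
#' plus covariates (GA, PMA, sex, TBV, ancestry components — the numeric
#' columns of `covars`), reporting the two-sided p-value of the dosage term.
#' Missing dosages are imputed at twice the allele frequency; monomorphic
#' SNPs are flagged and given p = 1. Computed by residualizing phenotype and
#' dosage on the covariates (Frisch-Waugh), which is algebraically the full
#' multiple regression.
#'
#' @param geno [genotype_matrix()] of the clumped SNP panel.
#' @param lobes aligned lobe table from [aggregate_lobes()].
#' @param covars aligned numeric covariate data.frame.
#' @return data.frame with id, p_ft, p_po, beta_ft, beta_po, monomorphic.
#' @export
snp_scan <- function(geno, lobes, covars) {
  D <- geno$dosages
  n <- nrow(D)
  f <- colMeans(D, na.rm = TRUE) / 2
  col_var <- apply(D, 2, stats::var, na.rm = TRUE)
  mono <- is.na(f) | f <= 0 | f >= 1 | is.na(col_var) | col_var == 0
  for (j in seq_len(ncol(D))) {
    nas <- is.na(D[, j])
    if (any(nas)) D[nas, j] <- 2 * f[j]
  }
  X <- cbind(1, as.matrix(covars))
  qx <- qr(X)
  rank <- qx$rank
  RX <- qr.resid(qx, D)
  s2x <- colSums(RX^2)
  degenerate <- mono | s2x < n * 1e-12
  res_df <- n - rank - 1
  one_pheno <- function(y) {
    ry <- qr.resid(qx, zscore(y))
    num <- drop(crossprod(RX, ry))
    beta <- ifelse(!degenerate, num / s2x, 0)
    rss <- sum(ry^2) - beta^2 * s2x
    sigma2 <- pmax(rss, 0) / res_df
    tval <- ifelse(!degenerate & sigma2 > 0, beta / sqrt(sigma2 / s2x), 0)
    p <- 2 * stats::pt(-abs(tval), res_df)
    p[degenerate] <- 1
    list(beta = beta, p = p)
  }
  ft <- one_pheno(lobes$fronto_temporal)
  po <- one_pheno(lobes$parieto_occipital)
  data.frame(id = geno$variants$id,
             p_ft = pmax(ft$p, .Machine$double.xmin),
             p_po = pmax(po$p, .Machine$double.xmin),
             beta_ft = ft$beta, beta_po = po$beta,
             monomorphic = degenerate, stringsAsFactors = FALSE)
}

#' Partition scanned SNPs into phenotype-specific subsets
#'
#' Splits SNPs at a strict p-value cutoff into three disjoint sets:
#' fronto-temporal only, parieto-occipital only, and both.
#'
#' @param scan result of [snp_scan()].
#' @param cutoff p-value cutoff (strict), default 0.01.
#' @return list with `ft_only`, `po_only`, `both` (character id vectors).
#' @export
partition_snps <- function(scan, cutoff = 0.01) {
  ft <- scan$p_ft < cutoff
  po <- scan$p_po < cutoff
  out <- list(ft_only = scan$id[ft & !po],
              po_only = scan$id[po & !ft],
              both = scan$id[ft & po])
  stopifnot(!anyDuplicated(unlist(out)),
            length(unlist(out)) == sum(ft | po))
  out
}

#' Map SNPs to genes by genomic coordinates
#'
#' A gene is selected when it contains a SNP within its start and stop
#' coordinates, both ends inclusive (1-based). SNPs falling in no gene
#' contribute nothing; the result is a deduplicated gene set.
#'
#' @param snp_ids SNP ids to map.
#' @param variants variant table with id, chrom, pos.
#' @param annotation gene table with gene_id, chrom, start, stop.
#' @return character vector of gene ids.
#' @export
map_snps_to_genes <- function(snp_ids, variants, annotation) {
  v <- variants[variants$id %in% snp_ids, , drop = FALSE]
  if (!nrow(v)) return(character(0))
  hits <- character(0)
  for (ch in unique(v$chrom)) {
    pos <- v$pos[v$chrom == ch]
    ann <- annotation[annotation$chrom == ch, , drop = FALSE]
    if (!nrow(ann)) next
    hit <- vapply(seq_len(nrow(ann)), function(g)
      any(pos >= ann$start[g] & pos <= ann$stop[g]), logical(1))
    hits <- c(hits, ann$gene_id[hit])
  }
  sort(unique(hits))
}

#' Hypergeometric pathway overrepresentation
#'
#' For each pathway, the upper-tail hypergeometric probability of observing
#' at least the attained overlap between the gene list and the pathway when
#' drawing the list at random from the background universe, with Bonferroni
#' adjustment over `n_pathways * n_gene_lists` tests. A pathway passes the
#' enrichment criteria when its Bonferroni-adjusted p is below `alpha` and
#' the overlap has at least `min_overlap` genes.
#'
#' @param gene_list character vector of gene ids.
#' @param db a [pathway_db()].
#' @param n_gene_lists number of gene lists in the testing family, default 3.
#' @param min_overlap minimum overlap for a pass, default 4.
#' @param alpha family-wise level for the Bonferroni criterion, default 0.05.
#' @return data.frame sorted by p_bonf: pathway, pathway_size, overlap,
#'   overlap_genes (comma-joined), p_hyper, p_bonf, passes_bonf.
#' @export
hypergeom_enrich <- function(gene_list, db, n_gene_lists = 3,
                             min_overlap = 4, alpha = 0.05) {
  stopifnot(inherits(db, "pathway_db"))
  gene_list <- unique(gene_list)
  if (!is.null(db$background_genes)) {
    outside <- setdiff(gene_list, db$background_genes)
    if (length(outside)) {
      warning("dropping ", length(outside),
              " gene(s) outside the background universe")
      gene_list <- intersect(gene_list, db$background_genes)
    }
  }
  N <- db$background_n
  sizes <- vapply(db$pathways, length, integer(1))
  if (any(sizes > N))
    stop("a pathway is larger than the background universe", call. = FALSE)
  nl <- length(gene_list)
  n_tests <- length(db$pathways) * n_gene_lists
  res <- data.frame(pathway = names(db$pathways), pathway_size = sizes,
                    overlap = 0L, overlap_genes = "",
                    p_hyper = 1, stringsAsFactors = FALSE)
  for (i in seq_along(db$pathways)) {
    ov <- intersect(gene_list, db$pathways[[i]])
    res$overlap[i] <- length(ov)
    res$overlap_genes[i] <- paste(ov, collapse = ",")
    res$p_hyper[i] <- stats::phyper(length(ov) - 1, sizes[i], N - sizes[i],
                                    nl, lower.tail = FALSE)
  }
  res$p_bonf <- pmin(1, res$p_hyper * n_tests)
  res$passes_bonf <- res$p_bonf < alpha & res$overlap >= min_overlap
  res <- res[order(res$p_hyper, res$pathway), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Empirical specificity null for top-enriched pathways
#'
#' Repeatedly samples `n_snps` SNPs without replacement from the full panel,
#' maps them to genes, runs the hypergeometric enrichment, and records the
#' single most-enriched pathway (smallest p; ties to the smallest pathway
#' id). A pathway is specific to the observed gene list when it tops fewer
#' than 5\% of the random runs.
#'
#' @param n_snps number of SNPs per random draw (the observed subset size).
#' @param all_snp_ids the full clumped SNP panel to sample from.
#' @param variants variant table (id, chrom, pos).
#' @param annotation gene annotation table.
#' @param db a [pathway_db()].
#' @param n_runs number of random draws, default 1000.
#' @param seed integer seed.
#' @return named numeric vector: per-pathway fraction of runs in which it was
#'   the top-enriched pathway. Sums to at most 1 (runs with empty gene lists
#'   record no pathway).
#' @export
specificity_null <- function(n_snps, all_snp_ids, variants, annotation, db,
                             n_runs = 1000, seed = 1L) {
  if (n_runs < 1) stop("n_runs must be at least 1", call. = FALSE)
  if (n_snps > length(all_snp_ids))
    stop("n_snps exceeds the panel size", call. = FALSE)
  # precompute the SNP -> gene map and the pathway incidence matrix once;
  # each run is then a set union plus one vectorized hypergeometric scan
  snp_genes <- .snp_gene_sets(all_snp_ids, variants, annotation)
  gene_univ <- unique(c(unlist(snp_genes, use.names = FALSE),
                        unlist(db$pathways, use.names = FALSE)))
  inc <- vapply(db$pathways, function(p) gene_univ %in% p,
                logical(length(gene_univ)))
  sizes <- vapply(db$pathways, length, integer(1))
  N <- db$background_n
  ord_names <- order(names(db$pathways))
  counts <- stats::setNames(integer(length(db$pathways)), names(db$pathways))
  with_seed(derive_seed(seed, "specificity"), {
    for (r in seq_len(n_runs)) {
      ids <- sample(all_snp_ids, n_snps)
      gl <- unique(unlist(snp_genes[ids], use.names = FALSE))
      if (!length(gl)) next
      k <- colSums(inc[match(gl, gene_univ), , drop = FALSE])
      p <- stats::phyper(k - 1, sizes, N - sizes, length(gl),
                         lower.tail = FALSE)
      top <- order(p, names(db$pathways))[1]  # ties: smallest pathway id
      counts[top] <- counts[top] + 1L
    }
  })
  counts / n_runs
}

# per-SNP gene sets: named list mapping each SNP id to the gene ids whose
# (1-based, inclusive) span contains it
.snp_gene_sets <- function(snp_ids, variants, annotation) {
  v <- variants[match(snp_ids, variants$id), , drop = FALSE]
  out <- stats::setNames(vector("list", nrow(v)), v$id)
  for (ch in unique(v$chrom)) {
    vi <- which(v$chrom == ch)
    ann <- annotation[annotation$chrom == ch, , drop = FALSE]
    if (!nrow(ann)) { out[vi] <- list(character(0)); next }
    for (i in vi) {
      hit <- ann$start <= v$pos[i] & ann$stop >= v$pos[i]
      out[[i]] <- ann$gene_id[hit]
    }
  }
  out
}

#' Full SNP-ranked gene-set enrichment analysis
#'
#' Runs the per-SNP scan, partitions SNPs at `cutoff`, maps each subset to a
#' gene list, tests each list for pathway overrepresentation with Bonferroni
#' control over all pathways x lists, and attaches the random-sampling
#' specificity frequency for each list. A pathway passes for a list when it
#' meets the Bonferroni criterion, has at least `min_overlap` overlapping
#' genes, and tops fewer than `specificity_alpha` of the random runs.
#'
#' @param geno clumped-panel [genotype_matrix()].
#' @param lobes,covars aligned lobe and covariate tables.
#' @param annotation gene annotation table.
#' @param db a [pathway_db()].
#' @param cutoff SNP scan p-value cutoff, default 0.01.
#' @param min_overlap minimum gene overlap, default 4.
#' @param n_runs specificity-null draws per list, default 1000.
#' @param specificity_alpha specificity frequency threshold, default 0.05.
#' @param seed integer seed.
#' @return list with `scan`, `subsets`, `gene_lists`, and `tables` (one
#'   enrichment table per subset with `specificity_freq` and `passes`).
#' @export
enrich_analysis <- function(geno, lobes, covars, annotation, db,
                            cutoff = 0.01, min_overlap = 4, n_runs = 1000,
                            specificity_alpha = 0.05, seed = 1L) {
  scan <- snp_scan(geno, lobes, covars)
  subsets <- partition_snps(scan, cutoff)
  gene_lists <- lapply(subsets, map_snps_to_genes, variants = geno$variants,
                       annotation = annotation)
  tables <- list()
  for (nm in names(subsets)) {
    tab <- hypergeom_enrich(gene_lists[[nm]], db,
                            n_gene_lists = length(subsets),
                            min_overlap = min_overlap)
    freq <- if (length(subsets[[nm]]))
      specificity_null(length(subsets[[nm]]), geno$variants$id,
                       geno$variants, annotation, db, n_runs = n_runs,
                       seed = derive_seed(seed, nm))
    else stats::setNames(rep(0, length(db$pathways)), names(db$pathways))
    tab$specificity_freq <- unname(freq[tab$pathway])
    tab$passes <- tab$passes_bonf & tab$specificity_freq < specificity_alpha
    tables[[nm]] <- tab
  }
  list(scan = scan, subsets = subsets, gene_lists = gene_lists,
       tables = tables)
}
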