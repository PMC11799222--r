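# -- sample- and SNP-level quality control ----------------------------------

#' Filter samples on genotype call rate
#'
#' Removes samples whose fraction of non-missing genotype calls is strictly
#' below `min_rate` (a call rate of exactly `min_rate` is retained).
#'
#' @param geno a [genotype_matrix()].
#' @param min_rate minimum per-sample call rate, default 0.95.
#' @return list with `geno` (filtered) and `report` (a [qc_report()]).
#' @export
sample_call_rate_filter <- function(geno, min_rate = 0.95) {
  rate <- rowMeans(!is.na(geno$dosages))
  keep <- rate >= min_rate
  if (!any(keep)) stop("empty cohort: all samples below call rate ",
                       min_rate, call. = FALSE)
  out <- subset_geno(geno, samples = keep)
  list(geno = out,
       report = qc_report("sample_call_rate", length(keep), sum(keep),
                          geno$samples$id[!keep],
                          list(min_rate = min_rate)))
}

#' Filter SNPs on autosome, MAF, missingness and Hardy-Weinberg equilibrium
#'
#' Removes SNPs that are non-autosomal (chromosome label outside 1-22), have
#' minor allele frequency below `maf_min`, are missing in more than
#' `max_missing` of samples, or deviate from Hardy-Weinberg equilibrium with
#' an exact-test p-value below `hwe_p_min`. MAF is computed on non-missing
#' dosages.
#'
#' @param geno a [genotype_matrix()].
#' @param maf_min minimum minor allele frequency, default 0.05.
#' @param max_missing maximum per-SNP missing fraction, default 0.01.
#' @param hwe_p_min minimum Hardy-Weinberg exact p-value, default 1e-5.
#' @return list with `geno` (filtered) and `report`.
#' @export
snp_filter <- function(geno, maf_min = 0.05, max_missing = 0.01,
                       hwe_p_min = 1e-5) {
  d <- geno$dosages
  autosomal <- geno$variants$chrom %in% as.character(1:22)
  miss <- colMeans(is.na(d))
  af <- colMeans(d, na.rm = TRUE) / 2
  af[is.nan(af)] <- 0
  maf <- pmin(af, 1 - af)
  hwe_p <- vapply(seq_len(ncol(d)), function(j) {
    x <- d[, j]
    x <- x[!is.na(x)]
    if (!length(x)) return(1)
    hwe_exact_test(sum(x == 0), sum(x == 1), sum(x == 2))
  }, numeric(1))
  keep <- autosomal & maf >= maf_min & miss <= max_missing & hwe_p >= hwe_p_min
  if (!any(keep)) warning("all SNPs removed by snp_filter")
  out <- subset_geno(geno, snps = keep)
  list(geno = out,
       report = qc_report("snp_filter", length(keep), sum(keep),
                          geno$variants$id[!keep],
                          list(maf_min = maf_min, max_missing = max_missing,
                               hwe_p_min = hwe_p_min)))
}

#' Hardy-Weinberg equilibrium exact test
#'
#' Two-sided exact test of Hardy-Weinberg proportions from genotype counts.
#' Conditional on the observed allele counts, the number of heterozygotes
#' under HWE follows a hypergeometric-type distribution over all heterozygote
#' counts of the same parity; the p-value sums the probabilities of all
#' configurations no more probable than the observed one.
#'
#' Probabilities are computed on the log scale and normalized, so the test is
#' stable up to tens of thousands of genotypes.
#'
#' @param n_hom_ref,n_het,n_hom_alt genotype counts.
#' @return exact two-sided p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  if (n_hom_ref < 0 || n_het < 0 || n_hom_alt < 0)
    stop("genotype counts must be non-negative", call. = FALSE)
  n <- n_hom_ref + n_het + n_hom_alt
  if (n == 0) stop("no genotypes", call. = FALSE)
  n_minor <- 2 * min(n_hom_ref, n_hom_alt) + n_het  # minor allele count
  # attainable heterozygote counts share the parity of the minor allele count
  hets <- seq(n_minor %% 2, min(n_minor, 2 * n - n_minor), by = 2)
  if (length(hets) == 1) return(1)
  # log P(het = h | allele counts) up to a constant:
  # n! / (h! hom_min! hom_maj!) * 2^h over genotype arrangements
  hom_min <- (n_minor - hets) / 2
  hom_maj <- n - hets - hom_min
  logp <- lgamma(n + 1) - lgamma(hets + 1) - lgamma(hom_min + 1) -
    lgamma(hom_maj + 1) + hets * log(2)
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- pr[match(n_het, hets)]
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

# -- linkage-disequilibrium pruning and relatedness -------------------------

#' Greedy windowed LD pruning
#'
#' Slides a window of `window_snps` SNPs along each chromosome in steps of
#' `step`; within each window, for every pair with squared genotype
#' correlation above `r2_max`, the later-positioned SNP is removed. Returns
#' the ids of retained SNPs.
#'
#' @param geno a [genotype_matrix()].
#' @param window_snps window size in SNPs, default 50.
#' @param step slide step in SNPs, default 5.
#' @param r2_max maximum squared correlation, default 0.2.
#' @return character vector of retained SNP ids.
#' @export
ld_prune <- function(geno, window_snps = 50, step = 5, r2_max = 0.2) {
  if (window_snps < 2) stop("window_snps must be at least 2", call. = FALSE)
  if (step < 1) stop("step must be at least 1", call. = FALSE)
  v <- geno$variants
  d <- geno$dosages
  if (anyNA(d)) {           # mean imputation: r2 here only steers pruning
    f <- colMeans(d, na.rm = TRUE)
    nas <- which(is.na(d), arr.ind = TRUE)
    d[nas] <- f[nas[, 2]]
  }
  keep <- rep(TRUE, nrow(v))
  for (ch in unique(v$chrom)) {
    idx <- which(v$chrom == ch)
    idx <- idx[order(v$pos[idx])]
    start <- 1L
    repeat {
      win <- idx[seq(start, min(start + window_snps - 1L, length(idx)))]
      win <- win[keep[win]]
      if (length(win) >= 2) {
        r2 <- suppressWarnings(stats::cor(d[, win, drop = FALSE]))^2
        for (a in seq_len(length(win) - 1L)) {
          if (!keep[win[a]]) next
          for (b in seq((a + 1L), length(win))) {
            if (!keep[win[b]]) next
            if (!is.na(r2[a, b]) && r2[a, b] > r2_max) keep[win[b]] <- FALSE
          }
        }
      }
      if (start + window_snps - 1L >= length(idx)) break
      start <- start + step
    }
  }
  geno$variants$id[keep]
}

# squared Pearson correlation of two dosage vectors over complete pairs
.geno_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) return(NA_real_)
  sx <- stats::sd(x[ok]); sy <- stats::sd(y[ok])
  if (sx == 0 || sy == 0) return(NA_real_)
  stats::cor(x[ok], y[ok])^2
}

#' Method-of-moments IBD relatedness (PI_HAT)
#'
#' For every sample pair, estimates the probabilities of sharing 0, 1 or 2
#' alleles identical by descent from the counts of identity-by-state 0/1/2
#' SNPs, using in-sample allele frequencies (the PLINK `--genome` moment
#' estimator with the small-sample allele-count corrections). Negative
#' component estimates are truncated at zero before combining into
#' pi_hat = P(IBD=2) + P(IBD=1) / 2.
#'
#' @param geno a [genotype_matrix()].
#' @param pruned_ids SNP ids to use (typically from [ld_prune()]).
#' @return data.frame with `sample_a`, `sample_b`, `pi_hat`.
#' @export
estimate_relatedness <- function(geno, pruned_ids) {
  if (nrow(geno$samples) < 2) stop("need at least 2 samples", call. = FALSE)
  if (!length(pruned_ids)) stop("pruned_ids is empty", call. = FALSE)
  g <- subset_geno(geno, snps = as.character(pruned_ids))
  d <- g$dosages
  p <- colMeans(d, na.rm = TRUE) / 2   # alt allele frequency
  poly <- !is.na(p) & p > 0 & p < 1
  if (!any(poly))
    stop("cannot estimate relatedness from a monomorphic-only panel",
         call. = FALSE)
  d <- d[, poly, drop = FALSE]
  p <- p[poly]
  q <- 1 - p
  n <- nrow(d)

  # expected IBS counts per SNP under IBD state 0/1/2 (PLINK-style, with
  # sample-size bias corrections on allele-frequency powers)
  nchr <- 2 * colSums(!is.na(d))            # alleles observed per SNP
  a1 <- nchr; a2 <- a1 - 1; a3 <- a2 - 1; a4 <- a3 - 1
  x1 <- p * a1; y1 <- q * a1
  # unbiased estimators of p^2 q^2 etc. via factorial moments of counts
  e00 <- 2 * (x1 * (x1 - 1) * y1 * (y1 - 1)) / (a1 * a2 * a3 * a4)
  e10 <- 4 * (x1 * (x1 - 1) * (x1 - 2) * y1) / (a1 * a2 * a3 * a4) +
         4 * (y1 * (y1 - 1) * (y1 - 2) * x1) / (a1 * a2 * a3 * a4)
  e20 <- (x1 * (x1 - 1) * (x1 - 2) * (x1 - 3)) / (a1 * a2 * a3 * a4) +
         (y1 * (y1 - 1) * (y1 - 2) * (y1 - 3)) / (a1 * a2 * a3 * a4) +
         4 * (x1 * (x1 - 1) * y1 * (y1 - 1)) / (a1 * a2 * a3 * a4)
  e11 <- 2 * (x1 * (x1 - 1) * y1) / (a1 * a2 * a3) +
         2 * (y1 * (y1 - 1) * x1) / (a1 * a2 * a3)
  e21 <- (x1 * (x1 - 1) * (x1 - 2)) / (a1 * a2 * a3) +
         (y1 * (y1 - 1) * (y1 - 2)) / (a1 * a2 * a3) +
         (x1 * (x1 - 1) * y1) / (a1 * a2 * a3) +
         (y1 * (y1 - 1) * x1) / (a1 * a2 * a3)

  # pairwise IBS counts via indicator cross-products (upper triangle used)
  M <- (!is.na(d)) * 1
  A0 <- (d == 0 & !is.na(d)) * 1
  A1 <- (d == 1 & !is.na(d)) * 1
  A2 <- (d == 2 & !is.na(d)) * 1
  Nok <- tcrossprod(M)
  N2m <- tcrossprod(A0) + tcrossprod(A1) + tcrossprod(A2)
  N0m <- tcrossprod(A0, A2) + tcrossprod(A2, A0)
  N1m <- Nok - N2m - N0m
  # per-pair expectation sums over the SNPs observed in both members
  esum <- function(e) tcrossprod(sweep(M, 2, e, "*"), M)
  E00 <- esum(e00); E10 <- esum(e10); E20 <- esum(e20)
  E11 <- esum(e11); E21 <- esum(e21)

  pairs <- utils::combn(n, 2)
  i <- pairs[1, ]; j <- pairs[2, ]
  lin <- cbind(i, j)
  P0 <- N0m[lin] / E00[lin]
  P1 <- (N1m[lin] - P0 * E10[lin]) / E11[lin]
  P2 <- (N2m[lin] - P0 * E20[lin] - P1 * E21[lin]) / Nok[lin]
  P0 <- pmax(P0, 0); P1 <- pmax(P1, 0); P2 <- pmax(P2, 0)
  s <- P0 + P1 + P2
  over <- s > 1
  P1[over] <- P1[over] / s[over]
  P2[over] <- P2[over] / s[over]
  pi_hat <- pmin(P2 + 0.5 * P1, 1.05)
  pi_hat[Nok[lin] == 0] <- NA_real_
  data.frame(sample_a = g$samples$id[i], sample_b = g$samples$id[j],
             pi_hat = pi_hat, stringsAsFactors = FALSE)
}

#' Resolve related sample pairs
#'
#' Iteratively removes one random member of the highest-pi_hat pair at or
#' above `cutoff`, re-checking remaining pairs after each removal, until no
#' pair remains. Deterministic given `seed`.
#'
#' @param table relatedness table from [estimate_relatedness()].
#' @param cutoff pi_hat at or above which a pair is resolved, default 0.1875.
#' @param seed integer seed for the random choice of which member to drop.
#' @return list with `keep_ids` (retained sample ids) and `report`.
#' @export
relatedness_filter <- function(table, cutoff = 0.1875, seed = 1L) {
  ids <- sort(unique(c(table$sample_a, table$sample_b)))
  removed <- character(0)
  tab <- table[!is.na(table$pi_hat), , drop = FALSE]
  with_seed(derive_seed(seed, "relatedness"), {
    repeat {
      live <- !(tab$sample_a %in% removed) & !(tab$sample_b %in% removed)
      cand <- tab[live & tab$pi_hat >= cutoff, , drop = FALSE]
      if (!nrow(cand)) break
      top <- cand[order(-cand$pi_hat, cand$sample_a, cand$sample_b), ][1, ]
      drop <- if (stats::runif(1) < 0.5) top$sample_a else top$sample_b
      removed <- c(removed, drop)
    }
  })
  keep <- setdiff(ids, removed)
  list(keep_ids = keep,
       report = qc_report("relatedness", length(ids), length(keep), removed,
                          list(pi_hat_cutoff = cutoff)))
}

# -- ancestry PCA -----------------------------------------------------------

#' Principal components of a genotype matrix
#'
#' Mean-imputes missing dosages per SNP, centers at 2f and scales by
#' sqrt(2 f (1 - f)), then takes the top-k components of the sample
#' covariance. Sign convention: within each component the loading of largest
#' magnitude is positive. Constant SNPs are dropped before decomposition.
#'
#' @param geno a [genotype_matrix()].
#' @param k number of components.
#' @return list of class `pc_projection`: `coordinates` (samples x k,
#'   rownames = sample ids), `loadings` (SNPs x k, rownames = SNP ids),
#'   `explained_variance` (k fractions), `center`, `scale`.
#' @export
pca_genotypes <- function(geno, k = 10) {
  d <- geno$dosages
  f <- colMeans(d, na.rm = TRUE) / 2
  use <- !is.na(f) & f > 0 & f < 1
  d <- d[, use, drop = FALSE]
  f <- f[use]
  for (j in seq_len(ncol(d))) d[is.na(d[, j]), j] <- 2 * f[j]
  Z <- sweep(sweep(d, 2, 2 * f), 2, sqrt(2 * f * (1 - f)), "/")
  if (k > min(dim(Z)) - 1)
    stop("k exceeds the rank of the genotype matrix", call. = FALSE)
  sv <- svd(Z, nu = k, nv = k)
  # deterministic sign: largest-|loading| entry positive per component
  for (j in seq_len(k)) {
    l <- sv$v[, j]
    if (l[which.max(abs(l))] < 0) {
      sv$v[, j] <- -sv$v[, j]
      sv$u[, j] <- -sv$u[, j]
    }
  }
  coords <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  rownames(coords) <- geno$samples$id
  colnames(coords) <- paste0("PC", seq_len(k))
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  rownames(loadings) <- geno$variants$id[use]
  colnames(loadings) <- paste0("PC", seq_len(k))
  ev <- sv$d[seq_len(k)]^2 / sum(sv$d^2)
  structure(list(coordinates = coords, loadings = loadings,
                 explained_variance = ev,
                 center = 2 * f, scale = sqrt(2 * f * (1 - f))),
            class = "pc_projection")
}

#' Project a cohort into a reference PC space
#'
#' Applies the reference panel's SNP centering/scaling and loadings to the
#' cohort dosages (intersecting SNPs by id; missing dosages imputed at the
#' reference frequency).
#'
#' @param geno cohort [genotype_matrix()].
#' @param reference_pcs a `pc_projection` from [pca_genotypes()] on the
#'   reference panel.
#' @return samples x k coordinate matrix.
#' @export
project_onto_reference <- function(geno, reference_pcs) {
  common <- intersect(rownames(reference_pcs$loadings), geno$variants$id)
  if (!length(common)) stop("no SNPs shared with the reference", call. = FALSE)
  ri <- match(common, rownames(reference_pcs$loadings))
  gi <- match(common, geno$variants$id)
  d <- geno$dosages[, gi, drop = FALSE]
  ctr <- reference_pcs$center[ri]
  scl <- reference_pcs$scale[ri]
  for (j in seq_along(common)) d[is.na(d[, j]), j] <- ctr[j]
  Z <- sweep(sweep(d, 2, ctr), 2, scl, "/")
  coords <- Z %*% reference_pcs$loadings[ri, , drop = FALSE]
  rownames(coords) <- geno$samples$id
  coords
}

#' Assign cohort samples to reference ancestry clusters
#'
#' Nearest-centroid classification in the first two components of the
#' reference space; ties go to the lexicographically smallest label.
#'
#' @param cohort_coords samples x k matrix from [project_onto_reference()].
#' @param reference_pcs reference `pc_projection`.
#' @param reference_labels ancestry label per reference sample.
#' @param target_label the label whose members are returned.
#' @return list with `ids` (cohort samples assigned `target_label`),
#'   `assignments` (named label vector) and `report`.
#' @export
assign_ancestry <- function(cohort_coords, reference_pcs, reference_labels,
                            target_label) {
  labs <- sort(unique(as.character(reference_labels)))
  if (!target_label %in% labs)
    stop("unknown target label: ", target_label, call. = FALSE)
  ref2 <- reference_pcs$coordinates[, 1:2, drop = FALSE]
  centroids <- do.call(rbind, lapply(labs, function(l)
    colMeans(ref2[reference_labels == l, , drop = FALSE])))
  rownames(centroids) <- labs
  co2 <- cohort_coords[, 1:2, drop = FALSE]
  assignments <- vapply(seq_len(nrow(co2)), function(i) {
    dist2 <- rowSums(sweep(centroids, 2, co2[i, ])^2)
    labs[which.min(dist2)]   # which.min takes the first = smallest label on ties
  }, character(1))
  names(assignments) <- rownames(co2)
  ids <- names(assignments)[assignments == target_label]
  list(ids = ids, assignments = assignments,
       report = qc_report("ancestry_assignment", nrow(co2), length(ids),
                          setdiff(names(assignments), ids),
                          list(target_label = target_label)))
}

#' Remove principal-component outliers
#'
#' Removes samples lying more than `n_sd` standard deviations from the mean
#' on any of the first `n_components` components.
#'
#' @param pcs a `pc_projection`, or a coordinate matrix with sample rownames.
#' @param n_components number of components examined, default 3.
#' @param n_sd standard-deviation multiplier, default 3.
#' @return list with `keep_ids` and `report`.
#' @export
pc_outlier_filter <- function(pcs, n_components = 3, n_sd = 3) {
  coords <- if (inherits(pcs, "pc_projection")) pcs$coordinates else pcs
  k <- min(n_components, ncol(coords))
  z <- scale(coords[, seq_len(k), drop = FALSE])
  out <- apply(abs(z) > n_sd, 1, any)
  keep <- rownames(coords)[!out]
  list(keep_ids = keep,
       report = qc_report("pc_outlier", nrow(coords), length(keep),
                          rownames(coords)[out],
                          list(n_components = n_components, n_sd = n_sd)))
}
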