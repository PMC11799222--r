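#' Default GWAS p-value threshold grid
#'
#' The ten inclusion thresholds used for multi-threshold scoring.
#' @return numeric vector of 10 thresholds.
#' @export
default_thresholds <- function() {
  c(1e-8, 1e-6, 1e-5, 1e-4, 1e-3, 0.01, 0.05, 0.1, 0.5, 1)
}

# Harmonize summary statistics to the LD reference / cohort panel: intersect
# by SNP id, drop strand-ambiguous (A/T, C/G) SNPs, and record whether the
# effect allele is the panel's alt (flip = FALSE) or ref (flip = TRUE).
harmonize_stats <- function(stats, geno) {
  m <- match(stats$SNP, geno$variants$id)
  keep <- !is.na(m)
  if (!any(keep)) stop("no summary-stat SNPs found in the panel", call. = FALSE)
  st <- stats[keep, , drop = FALSE]
  v <- geno$variants[m[keep], , drop = FALSE]
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  ambiguous <- st$A1 == comp[st$A2]
  straight <- st$A1 == v$alt & st$A2 == v$ref
  flipped <- st$A1 == v$ref & st$A2 == v$alt
  ok <- !ambiguous & (straight | flipped)
  n_drop <- sum(!ok)
  if (n_drop > 0)
    message("harmonize_stats: dropped ", n_drop,
            " SNP(s) (strand-ambiguous or allele mismatch)")
  st <- st[ok, , drop = FALSE]
  st$flip <- flipped[ok]
  rownames(st) <- NULL
  st
}

#' Greedy LD clumping of summary statistics
#'
#' Sorts SNPs by ascending discovery p-value (ties by chromosome then
#' position); repeatedly takes the best unassigned SNP as an index SNP and
#' removes every SNP within `window_kb` of it on the same chromosome whose
#' squared genotype correlation with it in the LD reference exceeds `r2_max`.
#' Strand-ambiguous SNPs and SNPs absent from the reference are dropped
#' before clumping.
#'
#' @param stats summary statistics data.frame (SNP/CHR/BP/A1/A2/BETA/P).
#' @param ld_reference [genotype_matrix()] used to estimate LD.
#' @param window_kb clump window half-width in kilobases, default 250.
#' @param r2_max squared-correlation threshold, default 0.1.
#' @param p_index_max only SNPs with p below this may become index SNPs,
#'   default 1 (all).
#' @return character vector of index-SNP ids.
#' @export
clump <- function(stats, ld_reference, window_kb = 250, r2_max = 0.1,
                  p_index_max = 1) {
  st <- harmonize_stats(stats, ld_reference)
  st <- st[order(st$P, as.integer(st$CHR), st$BP), , drop = FALSE]
  gi <- match(st$SNP, ld_reference$variants$id)
  # standardized mean-imputed dosages: r2 = squared crossprod / (n - 1)
  Z <- ld_reference$dosages[, gi, drop = FALSE]
  if (anyNA(Z)) {
    f <- colMeans(Z, na.rm = TRUE)
    nas <- which(is.na(Z), arr.ind = TRUE)
    Z[nas] <- f[nas[, 2]]
  }
  Z <- scale(Z)
  Z[, !is.finite(colSums(Z))] <- 0   # constant columns: r2 treated as 0
  n1 <- nrow(Z) - 1
  alive <- rep(TRUE, nrow(st))
  index <- character(0)
  for (i in seq_len(nrow(st))) {
    if (!alive[i]) next
    if (st$P[i] > p_index_max) next
    index <- c(index, st$SNP[i])
    alive[i] <- FALSE
    near <- which(alive & st$CHR == st$CHR[i] &
                    abs(st$BP - st$BP[i]) <= window_kb * 1000)
    if (length(near)) {
      r2 <- drop(crossprod(Z[, near, drop = FALSE], Z[, i]) / n1)^2
      alive[near[r2 > r2_max]] <- FALSE
    }
  }
  index
}

#' Multi-threshold polygenic scores
#'
#' For each p-value threshold, scores every sample as the mean per-allele
#' effect: sum of effect-size x effect-allele dosage over the clumped SNPs
#' with discovery p below the threshold, divided by twice the number of
#' non-missing scored SNPs for that sample (set `normalize = FALSE` for the
#' raw weighted sum). Missing dosages are imputed at twice the effect-allele
#' frequency.
#'
#' @param geno cohort [genotype_matrix()].
#' @param stats summary statistics data.frame.
#' @param clumped_ids index SNPs from [clump()].
#' @param thresholds p-value grid, default [default_thresholds()].
#' @param normalize divide by the non-missing allele count, default TRUE.
#' @return list of class `prs_matrix`: `scores` (samples x thresholds),
#'   `thresholds`, `n_snps_used` per threshold.
#' @export
prs_score <- function(geno, stats, clumped_ids,
                      thresholds = default_thresholds(), normalize = TRUE) {
  st <- harmonize_stats(stats, geno)
  st <- st[st$SNP %in% clumped_ids, , drop = FALSE]
  if (!nrow(st)) stop("no clumped SNPs available for scoring", call. = FALSE)
  gi <- match(st$SNP, geno$variants$id)
  d <- geno$dosages[, gi, drop = FALSE]
  # effect-allele dosage: flip when the effect allele is the panel ref
  flip <- st$flip
  d[, flip] <- 2 - d[, flip]
  eaf <- colMeans(d, na.rm = TRUE) / 2
  obs <- !is.na(d)
  dimp <- d
  for (j in seq_len(ncol(d))) dimp[!obs[, j], j] <- 2 * eaf[j]

  n <- nrow(d)
  scores <- matrix(0, n, length(thresholds),
                   dimnames = list(geno$samples$id,
                                   paste0("PT_", signif(thresholds, 3))))
  n_used <- integer(length(thresholds))
  for (t in seq_along(thresholds)) {
    sel <- st$P < thresholds[t] | thresholds[t] >= 1  # P in (0,1]; PT=1 takes all
    n_used[t] <- sum(sel)
    if (!any(sel)) {
      warning("threshold ", thresholds[t], ": no qualifying SNPs; zero column")
      next
    }
    raw <- dimp[, sel, drop = FALSE] %*% st$BETA[sel]
    if (normalize) {
      m_i <- rowSums(obs[, sel, drop = FALSE])
      raw <- ifelse(m_i > 0, raw / (2 * m_i), 0)
    }
    scores[, t] <- raw
  }
  structure(list(scores = scores, thresholds = thresholds,
                 n_snps_used = n_used),
            class = "prs_matrix")
}

#' Aggregate threshold scores into a single component (PRS-PC1)
#'
#' Standardizes each threshold column, extracts the first principal
#' component, and aligns its sign so that the sum of its correlations with
#' the standardized columns is positive. Constant columns (thresholds with no
#' qualifying SNPs) are excluded with a warning.
#'
#' @param prs a `prs_matrix` from [prs_score()].
#' @return list of class `prs_pc1`: `values` (per-sample score, named),
#'   `loadings` (per retained threshold), `variance_explained`,
#'   `correlations` (with each retained threshold column), `used_thresholds`.
#' @export
prs_pca <- function(prs) {
  S <- prs$scores
  if (nrow(S) < 2) stop("need at least 2 samples", call. = FALSE)
  sds <- apply(S, 2, stats::sd)
  use <- is.finite(sds) & sds > 0
  if (sum(use) < 2) {
    if (!any(use)) stop("degenerate input: all threshold columns constant",
                        call. = FALSE)
    stop("need at least 2 non-constant threshold columns", call. = FALSE)
  }
  if (any(!use))
    warning("excluding constant threshold column(s): ",
            paste(colnames(S)[!use], collapse = ", "))
  Z <- scale(S[, use, drop = FALSE])
  sv <- svd(Z, nu = 1, nv = 1)
  pc1 <- drop(Z %*% sv$v[, 1])
  cors <- drop(stats::cor(pc1, Z))
  if (sum(cors) < 0) {
    pc1 <- -pc1
    sv$v[, 1] <- -sv$v[, 1]
    cors <- -cors
  }
  structure(list(values = stats::setNames(pc1, rownames(S)),
                 loadings = stats::setNames(drop(sv$v[, 1]),
                                            colnames(S)[use]),
                 variance_explained = sv$d[1]^2 / sum(sv$d^2),
                 correlations = stats::setNames(cors, colnames(S)[use]),
                 used_thresholds = prs$thresholds[use]),
            class = "prs_pc1")
}
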