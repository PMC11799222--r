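# Hand-buildable genotype fixture: dosage matrix + sequential positions.
make_geno <- function(dosages, chrom = NULL, pos = NULL, ids = NULL,
                      sample_ids = NULL) {
  dosages <- as.matrix(dosages)
  m <- ncol(dosages); n <- nrow(dosages)
  chrom <- chrom %||% rep("1", m)
  pos <- pos %||% stats::ave(seq_len(m), chrom, FUN = function(i)
    1000L * seq_along(i))
  ids <- ids %||% sprintf("snp%02d", seq_len(m))
  sample_ids <- sample_ids %||% sprintf("I%03d", seq_len(n))
  genotype_matrix(dosages,
                  data.frame(id = ids, chrom = chrom, pos = pos,
                             ref = "A", alt = "G",
                             stringsAsFactors = FALSE),
                  data.frame(id = sample_ids, stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One moderate synthetic study shared by read-mostly tests (built once per
# test run).
shared_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_study(sim_config(n_samples = 250, n_snps = 600,
                                          n_blocks = 40, n_causal = 10,
                                          seed = 42L))
    cache
  }
})

# Brute-force HWE oracle: enumerate every heterozygote configuration
# attainable from the allele counts and sum the probabilities of those no
# more likely than the observed one. Independent of the package's log-scale
# path (direct factorial ratios; valid for the small totals used in tests).
hwe_oracle <- function(a, b, c) {
  n <- a + b + c
  m <- 2 * min(a, c) + b
  hets <- seq(m %% 2, min(m, 2 * n - m), by = 2)
  if (length(hets) == 1) return(1)
  pr <- vapply(hets, function(h) {
    hom_min <- (m - h) / 2
    hom_maj <- n - h - hom_min
    exp(lfactorial(n) - lfactorial(h) - lfactorial(hom_min) -
          lfactorial(hom_maj)) * 2^h
  }, numeric(1))
  pr <- pr / sum(pr)
  obs <- pr[hets == b]
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

# Brute-force clumping oracle: literal restatement of the greedy rule using
# a full pairwise r2 matrix (no windowing shortcuts).
clump_oracle <- function(stats, geno, window_kb = 250, r2_max = 0.1) {
  d <- geno$dosages
  f <- colMeans(d, na.rm = TRUE)
  for (j in seq_len(ncol(d))) d[is.na(d[, j]), j] <- f[j]
  r2 <- suppressWarnings(stats::cor(d))^2
  ord <- order(stats$P, as.integer(stats$CHR), stats$BP)
  st <- stats[ord, , drop = FALSE]
  gi <- match(st$SNP, geno$variants$id)
  alive <- rep(TRUE, nrow(st))
  index <- character(0)
  for (i in seq_len(nrow(st))) {
    if (!alive[i]) next
    index <- c(index, st$SNP[i])
    alive[i] <- FALSE
    for (j in which(alive)) {
      same_chr <- st$CHR[j] == st$CHR[i]
      near <- abs(st$BP[j] - st$BP[i]) <= window_kb * 1000
      rr <- r2[gi[i], gi[j]]
      if (same_chr && near && !is.na(rr) && rr > r2_max) alive[j] <- FALSE
    }
  }
  sort(index)
}

# Hypergeometric upper-tail oracle by full enumeration of overlap outcomes.
hyper_oracle <- function(k, pathway_size, bg, list_size) {
  ks <- max(0, list_size + pathway_size - bg):min(pathway_size, list_size)
  pr <- vapply(ks, function(x)
    choose(pathway_size, x) * choose(bg - pathway_size, list_size - x),
    numeric(1))
  pr <- pr / choose(bg, list_size)
  sum(pr[ks >= k])
}

# Random summary-stats table for a fixture panel (no effect structure).
random_stats <- function(geno, seed = 1) {
  v <- geno$variants
  set.seed(seed)
  data.frame(SNP = v$id, CHR = v$chrom, BP = v$pos, A1 = v$alt, A2 = v$ref,
             BETA = stats::rnorm(nrow(v), 0, 0.05),
             P = stats::runif(nrow(v)), stringsAsFactors = FALSE)
}
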