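test_that("sample call-rate filter applies a strict less-than rule at 95%", {
  set.seed(1)
  base <- matrix(rbinom(3 * 100, 2, 0.4), nrow = 3)
  base[1, 1:4] <- NA   # 96/100 called -> retained
  base[2, 1:6] <- NA   # 94/100 -> removed
  base[3, 1:5] <- NA   # exactly 95/100 -> retained
  g <- make_geno(base)
  out <- sample_call_rate_filter(g, min_rate = 0.95)
  expect_identical(out$geno$samples$id, c("I001", "I003"))
  expect_identical(out$report$removed_ids, "I002")
  expect_equal(out$report$n_before - out$report$n_after, 1)

  all_bad <- make_geno(matrix(NA_real_, 2, 10))
  expect_error(sample_call_rate_filter(all_bad), "empty cohort")
})

test_that("SNP filter removes non-autosomal, rare, missing and HWE-failing SNPs", {
  # col1: common SNP in HWE -> passes
  # col2: MAF just under 0.05 -> removed
  # col3: chromosome X -> removed
  # col4: too much missingness -> removed
  # col5: gross HWE violation (all hets) -> removed
  n <- 400
  set.seed(8)
  d1 <- rbinom(n, 2, 0.4)
  d2 <- c(rep(1, round(2 * n * 0.049)), rep(0, n - round(2 * n * 0.049)))
  d3 <- rbinom(n, 2, 0.5)
  d4 <- rbinom(n, 2, 0.5); d4[1:20] <- NA
  d5 <- rep(1, n)
  g <- make_geno(cbind(d1, d2, d3, d4, d5),
                 chrom = c("1", "1", "X", "2", "2"))
  out <- snp_filter(g)
  expect_identical(out$geno$variants$id, "snp01")
  expect_setequal(out$report$removed_ids, c("snp02", "snp03", "snp04",
                                            "snp05"))
  # MAF arithmetic on the worked example: dosages 0,1,2,2 over 4 samples
  af <- mean(c(0, 1, 2, 2)) / 2
  expect_equal(min(af, 1 - af), 0.375)
})

test_that("HWE exact test matches the enumeration oracle and is symmetric", {
  expect_equal(hwe_exact_test(50, 0, 0), 1)
  expect_equal(hwe_exact_test(57, 78, 13), hwe_oracle(57, 78, 13),
               tolerance = 1e-12)
  cases <- rbind(c(3, 5, 10), c(20, 50, 30), c(0, 10, 0), c(1, 0, 1),
                 c(68, 28, 4), c(0, 0, 7))
  for (i in seq_len(nrow(cases))) {
    a <- cases[i, 1]; b <- cases[i, 2]; c <- cases[i, 3]
    expect_equal(hwe_exact_test(a, b, c), hwe_oracle(a, b, c),
                 tolerance = 1e-12)
    expect_equal(hwe_exact_test(a, b, c), hwe_exact_test(c, b, a))
  }
  expect_error(hwe_exact_test(-1, 2, 3), "non-negative")
  # stable at large counts, close to the chi-square for common alleles
  p_big <- hwe_exact_test(4000, 4400, 1600)
  expect_true(is.finite(p_big) && p_big > 0 && p_big <= 1)
})

test_that("LD pruning removes duplicated columns and keeps independent ones", {
  set.seed(4)
  x <- rbinom(200, 2, 0.3)
  g_dup <- make_geno(cbind(x, x, rbinom(200, 2, 0.4)))
  kept <- ld_prune(g_dup, window_snps = 3, step = 1, r2_max = 0.2)
  expect_identical(kept, c("snp01", "snp03"))

  ind <- sapply(1:6, function(i) rbinom(500, 2, 0.5))
  g_ind <- make_geno(ind)
  expect_identical(ld_prune(g_ind), g_ind$variants$id)
  expect_error(ld_prune(g_ind, window_snps = 1), "window_snps")
})

test_that("LD pruning equals a direct windowed restatement on a 12-SNP instance", {
  prune_oracle <- function(geno, window_snps, step, r2_max) {
    d <- geno$dosages
    r2 <- suppressWarnings(stats::cor(d))^2
    keep <- rep(TRUE, ncol(d))
    start <- 1
    repeat {
      win <- seq(start, min(start + window_snps - 1, ncol(d)))
      win <- win[keep[win]]
      if (length(win) >= 2)
        for (a in seq_len(length(win) - 1)) for (b in seq(a + 1, length(win)))
          if (keep[win[a]] && keep[win[b]] &&
              !is.na(r2[win[a], win[b]]) && r2[win[a], win[b]] > r2_max)
            keep[win[b]] <- FALSE
      if (start + window_snps - 1 >= ncol(d)) break
      start <- start + step
    }
    geno$variants$id[keep]
  }
  for (s in 1:20) {
    set.seed(s)
    base <- rbinom(120, 2, 0.5)
    d <- sapply(1:12, function(i)
      ifelse(runif(120) < 0.4, base, rbinom(120, 2, 0.5)))
    g <- make_geno(d)
    expect_identical(ld_prune(g, window_snps = 5, step = 2, r2_max = 0.3),
                     prune_oracle(g, 5, 2, 0.3))
  }
})

test_that("relatedness estimation recovers duplicates, parent-offspring and unrelated pairs", {
  set.seed(7)
  m <- 5000
  f <- runif(m, 0.1, 0.5)
  draw_hap <- function() rbinom(m, 1, f)
  # parent-offspring: child inherits one transmitted allele per parent
  p1a <- draw_hap(); p1b <- draw_hap()
  p2a <- draw_hap(); p2b <- draw_hap()
  child <- ifelse(runif(m) < 0.5, p1a, p1b) + ifelse(runif(m) < 0.5, p2a, p2b)
  parent1 <- p1a + p1b
  unrel1 <- draw_hap() + draw_hap()
  unrel2 <- draw_hap() + draw_hap()
  dup <- parent1
  d <- rbind(parent1, child, unrel1, unrel2, dup)
  g <- make_geno(d, chrom = rep("1", m))
  rel <- estimate_relatedness(g, g$variants$id)
  ph <- function(a, b) rel$pi_hat[(rel$sample_a == a & rel$sample_b == b) |
                                    (rel$sample_a == b & rel$sample_b == a)]
  expect_gte(ph("I001", "I005"), 0.95)            # duplicate
  expect_true(abs(ph("I001", "I002") - 0.5) < 0.05)  # parent-offspring
  expect_lt(abs(ph("I003", "I004")), 0.05)        # unrelated
  expect_true(all(rel$pi_hat >= 0 & rel$pi_hat <= 1.05))
})

test_that("relatedness filter retains one member per related group", {
  pair <- data.frame(sample_a = "A", sample_b = "B", pi_hat = 0.5)
  out <- relatedness_filter(pair, seed = 1)
  expect_length(out$keep_ids, 1)
  expect_true(out$keep_ids %in% c("A", "B"))

  none <- data.frame(sample_a = c("A", "B"), sample_b = c("B", "C"),
                     pi_hat = c(0.1, 0.05))
  expect_setequal(relatedness_filter(none, seed = 1)$keep_ids,
                  c("A", "B", "C"))

  tri <- data.frame(sample_a = c("A", "A", "B"),
                    sample_b = c("B", "C", "C"),
                    pi_hat = c(0.5, 0.4, 0.45))
  # removal rule by hand: resolve (A,B) first, then the survivor's remaining
  # pairs, until exactly one of the triangle remains
  out_tri <- relatedness_filter(tri, seed = 3)
  expect_length(out_tri$keep_ids, 1)

  # deterministic given the seed
  expect_identical(relatedness_filter(tri, seed = 5)$keep_ids,
                   relatedness_filter(tri, seed = 5)$keep_ids)
})

test_that("genotype PCA separates two diverged populations and reports valid variance", {
  set.seed(11)
  m <- 2000; n_per <- 100
  f0 <- runif(m, 0.2, 0.8)
  # allele-frequency divergence around Fst ~ 0.1
  fa <- pmin(pmax(f0 + rnorm(m, 0, sqrt(0.1 * f0 * (1 - f0))), 0.02), 0.98)
  fb <- pmin(pmax(f0 + rnorm(m, 0, sqrt(0.1 * f0 * (1 - f0))), 0.02), 0.98)
  da <- sapply(seq_len(m), function(j) rbinom(n_per, 2, fa[j]))
  db <- sapply(seq_len(m), function(j) rbinom(n_per, 2, fb[j]))
  g <- make_geno(rbind(da, db), chrom = rep("1", m))
  pcs <- pca_genotypes(g, k = 4)
  pc1 <- pcs$coordinates[, 1]
  expect_true(max(pc1[1:n_per]) < min(pc1[(n_per + 1):(2 * n_per)]) ||
                min(pc1[1:n_per]) > max(pc1[(n_per + 1):(2 * n_per)]))
  expect_lte(sum(pcs$explained_variance), 1)
  expect_true(all(diff(pcs$explained_variance) <= 1e-12))
  expect_true(all(abs(colMeans(pcs$coordinates)) < 1e-8))
})

test_that("ancestry assignment uses nearest centroids with a lexicographic tie-break", {
  set.seed(2)
  ref_coords <- rbind(matrix(rnorm(40, mean = -10, sd = 0.5), 20, 2),
                      matrix(rnorm(40, mean = 0, sd = 0.5), 20, 2),
                      matrix(rnorm(40, mean = 10, sd = 0.5), 20, 2))
  rownames(ref_coords) <- sprintf("R%02d", 1:60)
  ref <- structure(list(coordinates = ref_coords), class = "pc_projection")
  labels <- rep(c("AFR", "EAS", "EUR"), each = 20)

  centroid_b <- colMeans(ref_coords[21:40, ])
  cohort <- rbind(centroid_b, centroid_b + c(0.1, 0))
  rownames(cohort) <- c("S1", "S2")
  out <- assign_ancestry(cohort, ref, labels, "EAS")
  expect_setequal(out$ids, c("S1", "S2"))
  expect_error(assign_ancestry(cohort, ref, labels, "OCE"), "unknown")

  # cohort drawn from one cluster is assigned to it
  draw <- matrix(rnorm(400, mean = 10, sd = 0.5), 200, 2)
  rownames(draw) <- sprintf("C%03d", 1:200)
  out2 <- assign_ancestry(draw, ref, labels, "EUR")
  expect_gte(length(out2$ids) / 200, 0.99)

  # exactly equidistant point goes to the lexicographically smallest label
  ref2_coords <- rbind(c(-1, 0.5), c(-1, -0.5), c(1, 0.5), c(1, -0.5))
  rownames(ref2_coords) <- sprintf("Q%d", 1:4)
  ref2 <- structure(list(coordinates = ref2_coords), class = "pc_projection")
  mid <- matrix(c(0, 0), 1, 2, dimnames = list("M", NULL))
  out3 <- assign_ancestry(mid, ref2, c("ZZZ", "ZZZ", "AAA", "AAA"), "AAA")
  expect_identical(out3$assignments[["M"]], "AAA")
})

test_that("PC outlier filter removes only planted outliers", {
  set.seed(5)
  # bounded coordinates: max |z| of a uniform is sqrt(3) < 3, so no removals
  coords <- matrix(runif(300 * 4, -1, 1), 300, 4)
  rownames(coords) <- sprintf("P%03d", 1:300)
  out <- pc_outlier_filter(coords, n_components = 3, n_sd = 3)
  expect_length(out$keep_ids, 300)

  coords[7, 2] <- coords[7, 2] + 10 * sd(coords[, 2])
  out2 <- pc_outlier_filter(coords, n_components = 3, n_sd = 3)
  expect_identical(out2$report$removed_ids, "P007")
})

test_that("filters are idempotent and reports reconcile", {
  st <- shared_study()
  f1 <- snp_filter(st$geno)
  f2 <- snp_filter(f1$geno)
  expect_identical(f1$geno$variants$id, f2$geno$variants$id)
  expect_length(f2$report$removed_ids, 0)
  expect_equal(f1$report$n_before - f1$report$n_after,
               length(f1$report$removed_ids))

  c1 <- sample_call_rate_filter(st$geno)
  c2 <- sample_call_rate_filter(c1$geno)
  expect_identical(c1$geno$samples$id, c2$geno$samples$id)
})
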