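make_pheno <- function(n = 8) {
  rt_regions <- setdiff(names(shared_study()$volumes),
                        c("sample_id", "session"))
  vol <- data.frame(sample_id = sprintf("X%02d", seq_len(n)), session = 1L)
  for (r in rt_regions) vol[[r]] <- runif(n, 900, 1100)
  cov <- data.frame(sample_id = vol$sample_id, session = 1L,
                    ga = runif(n, 37, 42), pma = runif(n, 38, 45),
                    sex = rbinom(n, 1, 0.5),
                    radiology_score = sample(1:4, n, replace = TRUE))
  list(volumes = vol, covars = cov)
}

test_that("cohort filter applies term, radiology and first-session rules in order", {
  set.seed(2)
  ph <- make_pheno(3)
  ph$covars$ga <- c(36.5, 37.0, 40.0)
  out <- cohort_filter(ph$volumes, ph$covars)
  expect_identical(out$covars$sample_id, c("X02", "X03"))
  expect_identical(out$reports$term$removed_ids, "X01::1")

  ph2 <- make_pheno(3)
  ph2$covars$radiology_score <- c(2, 5, 3)
  out2 <- cohort_filter(ph2$volumes, ph2$covars)
  expect_identical(out2$covars$sample_id, c("X01", "X03"))

  ph3 <- make_pheno(3)
  dup_v <- ph3$volumes[2, ]; dup_v$session <- 2L
  dup_c <- ph3$covars[2, ]; dup_c$session <- 2L
  ph3$volumes <- rbind(ph3$volumes, dup_v)
  ph3$covars <- rbind(ph3$covars, dup_c)
  out3 <- cohort_filter(ph3$volumes, ph3$covars)
  expect_equal(nrow(out3$covars), 3)
  expect_true(all(out3$covars$session == 1))

  ph4 <- make_pheno(2)
  ph4$covars$ga <- c(30, 31)
  expect_error(cohort_filter(ph4$volumes, ph4$covars), "empty cohort")
})

test_that("lobe aggregation sums constituents and builds composites", {
  set.seed(3)
  ph <- make_pheno(5)
  lob <- aggregate_lobes(ph$volumes)
  map <- default_lobe_map()
  expect_equal(lob$frontal,
               rowSums(ph$volumes[, map$frontal]))
  expect_equal(lob$fronto_temporal, lob$frontal + lob$temporal)
  expect_equal(lob$parieto_occipital, lob$parietal + lob$occipital)
  region_cols <- setdiff(names(ph$volumes), c("sample_id", "session"))
  expect_equal(lob$tbv, rowSums(ph$volumes[, region_cols]))

  # column order is irrelevant
  shuffled <- ph$volumes[, c(1, 2, sample(3:ncol(ph$volumes)))]
  expect_equal(aggregate_lobes(shuffled), lob)

  broken <- ph$volumes[, setdiff(names(ph$volumes), "frontal_gm")]
  expect_error(aggregate_lobes(broken), "frontal_gm")
})

test_that("the lobe regression matches the closed-form normal-equations solution", {
  # 6-row hand dataset, solved independently via solve(X'X, X'y)
  y <- c(10, 12, 9, 15, 11, 13)
  s <- c(0.5, -1, 0.2, 2, -0.3, 0.9)
  cv <- data.frame(ga = c(38, 39, 40, 41, 37, 42),
                   sex = c(0, 1, 0, 1, 1, 0))
  fit <- fit_lobe_model(y, s, cv)
  X <- cbind(1, scale(s)[, 1], cv$ga, cv$sex)
  ys <- scale(y)[, 1]
  beta_hat <- solve(t(X) %*% X, t(X) %*% ys)
  resid <- ys - X %*% beta_hat
  sigma2 <- sum(resid^2) / (6 - 4)
  se <- sqrt(sigma2 * solve(t(X) %*% X)[2, 2])
  expect_equal(fit$beta, beta_hat[2], tolerance = 1e-10)
  expect_equal(fit$se, se, tolerance = 1e-10)
  expect_equal(fit$t, beta_hat[2] / se, tolerance = 1e-10)
  expect_equal(fit$p, 2 * pt(-abs(fit$t), 2), tolerance = 1e-12)
})

test_that("noise-free volumes give exact coefficient recovery and unit invariance", {
  set.seed(8)
  n <- 60
  s <- rnorm(n)
  cv <- data.frame(ga = runif(n, 37, 42), sex = rbinom(n, 1, 0.5))
  y <- 5000 + 0.5 * sd(5000 + 30 * cv$ga) * 0 + 30 * cv$ga + 10 * cv$sex
  y <- y + 0.5 * sd(y) * scale(s)[, 1]
  fit <- fit_lobe_model(y, s, cv)
  expect_gt(fit$beta, 0)

  # affine rescaling of the volume (mm^3 -> cm^3) leaves beta unchanged
  fit_cm <- fit_lobe_model(y / 1000, s, cv)
  expect_equal(fit$beta, fit_cm$beta, tolerance = 1e-12)
  expect_equal(fit$p, fit_cm$p, tolerance = 1e-12)

  # collinear design is refused with the offending column named
  cv_bad <- cv; cv_bad$ga2 <- 2 * cv$ga
  expect_error(fit_lobe_model(y, s, cv_bad), "collinear")
})

test_that("regression p-values are uniform under permutation of the volume", {
  set.seed(21)
  n <- 300
  s <- rnorm(n)
  cv <- data.frame(ga = runif(n, 37, 42), pma = runif(n, 38, 45),
                   sex = rbinom(n, 1, 0.5), tbv = rnorm(n, 38e4, 5e4))
  y <- rnorm(n, 1000, 50)
  ps <- replicate(500, fit_lobe_model(sample(y), s, cv)$p)
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_lt(unname(ks$statistic), 0.1)
})

test_that("BH adjustment follows the step-up rule over exactly six p-values", {
  set.seed(5)
  n <- 80
  lob_fake <- as.data.frame(matrix(rnorm(n * 6, 1000, 30), n, 6))
  names(lob_fake) <- c("frontal", "temporal", "parietal", "occipital",
                       "fronto_temporal", "parieto_occipital")
  cv <- data.frame(ga = runif(n, 37, 42), sex = rbinom(n, 1, 0.5))
  res <- run_primary(rnorm(n), lob_fake, cv)
  expect_equal(res$p_fdr, p.adjust(res$p, "BH"))
  expect_true(all(res$p_fdr >= res$p))
  expect_equal(nrow(res), 6)

  # worked step-up example and the tie case
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04, 0.05, 0.06), "BH"),
               rep(0.06, 6))
  expect_equal(p.adjust(rep(0.03, 6), "BH"), rep(0.03, 6))
})

test_that("t statistics reconcile with beta and se", {
  st <- shared_study()
  keep <- st$covars$session == 1 & st$covars$radiology_score != 5 &
    st$covars$ga >= 37
  lob <- aggregate_lobes(st$volumes[keep, ])
  cv <- data.frame(ga = st$covars$ga[keep], pma = st$covars$pma[keep],
                   sex = st$covars$sex[keep], tbv = lob$tbv)
  res <- run_primary(st$genetic_value[keep], lob, cv)
  expect_equal(abs(res$t), abs(res$beta) / res$se, tolerance = 1e-12)
})

test_that("split-half consistency is near 1 for a strong planted effect and near 0.5 under the null", {
  build <- function(beta, seed) {
    cfg <- sim_config(n_samples = 300, n_snps = 400, n_blocks = 40,
                      n_causal = 8, beta_ft = beta, beta_po = -beta,
                      missing_rate = 0, radiology5_rate = 0,
                      dup_session_rate = 0, seed = seed)
    g <- generate_genotypes(cfg)
    ss <- generate_summary_stats(g, cfg)
    ph <- generate_phenotypes(g, ss$truth, cfg)
    clumped <- suppressMessages(clump(ss$stats, g))
    prs <- suppressMessages(prs_score(g, ss$stats, clumped))
    lob <- aggregate_lobes(ph$volumes)
    cv <- data.frame(ga = ph$covars$ga, pma = ph$covars$pma,
                     sex = ph$covars$sex, tbv = lob$tbv)
    list(prs = prs, lob = lob, cv = cv)
  }
  strong <- build(0.4, 91)
  rep_strong <- split_half_stability(strong$prs, strong$lob, strong$cv,
                                     n_reps = 60, seed = 7)
  expect_gte(rep_strong$consistency[["fronto_temporal"]], 0.9)
  expect_gte(rep_strong$consistency[["parieto_occipital"]], 0.9)

  # under the null, per-cohort consistency is extreme (the two halves are
  # anti-correlated around the full-sample estimate) but its expectation
  # over fresh cohorts is exactly 0.5: averaging across replicate cohorts
  # recovers it
  cons <- sapply(1:25, function(s) {
    nul <- build(0, 200 + s)
    split_half_stability(nul$prs, nul$lob, nul$cv, n_reps = 4,
                         seed = s)$consistency
  })
  expect_lt(abs(mean(cons["fronto_temporal", ]) - 0.5), 0.2)
  expect_lt(abs(mean(cons) - 0.5), 0.12)

  null <- build(0, 92)
  rep_null <- split_half_stability(null$prs, null$lob, null$cv,
                                   n_reps = 20, seed = 8)
  rep_again <- split_half_stability(null$prs, null$lob, null$cv,
                                    n_reps = 20, seed = 8)
  expect_identical(rep_null, rep_again)
})

test_that("the extremes test uses floor-sized tails and detects planted effects", {
  set.seed(10)
  n <- 273
  S <- matrix(rnorm(n * 10), n, 10)
  prs <- structure(list(scores = S, thresholds = default_thresholds(),
                        n_snps_used = 1:10), class = "prs_matrix")
  lob <- as.data.frame(matrix(rnorm(n * 6, 1000, 40), n, 6))
  names(lob) <- c("frontal", "temporal", "parietal", "occipital",
                  "fronto_temporal", "parieto_occipital")
  cv <- data.frame(ga = runif(n, 37, 42), sex = rbinom(n, 1, 0.5))
  res <- extremes_test(prs, lob, cv, tail = 0.2)
  expect_true(all(res$n_per_tail == floor(0.2 * 273)))
  expect_equal(unique(res$n_per_tail), 54)
  expect_equal(nrow(res), 10 * 6)

  # planted monotone effect on one lobe: top tail mean exceeds bottom
  lob2 <- lob
  lob2$fronto_temporal <- lob2$fronto_temporal + 60 * S[, 5]
  res2 <- extremes_test(prs, lob2, cv, tail = 0.2)
  row <- res2[res2$lobe == "fronto_temporal" &
                res2$threshold == default_thresholds()[5], ]
  expect_gt(row$mean_top, row$mean_bottom)
  expect_lt(row$p, 0.001)
})

test_that("per-threshold regression builds a 10 x 6 grid and drops constant columns", {
  set.seed(13)
  n <- 120
  S <- matrix(rnorm(n * 10), n, 10)
  prs <- structure(list(scores = S, thresholds = default_thresholds(),
                        n_snps_used = 1:10), class = "prs_matrix")
  lob <- as.data.frame(matrix(rnorm(n * 6, 1000, 40), n, 6))
  names(lob) <- c("frontal", "temporal", "parietal", "occipital",
                  "fronto_temporal", "parieto_occipital")
  cv <- data.frame(ga = runif(n, 37, 42), sex = rbinom(n, 1, 0.5))
  grid <- per_threshold_regression(prs, lob, cv)
  expect_equal(nrow(grid), 60)
  expect_equal(length(unique(grid$threshold)), 10)

  prs$scores[, 1] <- 0
  expect_warning(grid2 <- per_threshold_regression(prs, lob, cv),
                 "constant")
  expect_equal(nrow(grid2), 54)
})
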