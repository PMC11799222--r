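# -- cohort filtering and lobe aggregation ----------------------------------

#' Cohort inclusion filters
#'
#' Applies, in order: (1) keep term-born scans (GA >= `min_ga` weeks), (2)
#' drop scans with radiology score 5 (major lesions), (3) of duplicate scans
#' per subject, keep the earliest session. Volumes and covariates are filtered
#' together on the (sample_id, session) key.
#'
#' @param volumes regional volume table (sample_id, session, regions...).
#' @param covars covariate table (sample_id, session, ga, pma, sex,
#'   radiology_score).
#' @param min_ga minimum gestational age in weeks, default 37 (inclusive).
#' @return list with filtered `volumes`, `covars`, and `reports` (one
#'   [qc_report()] per stage).
#' @export
cohort_filter <- function(volumes, covars, min_ga = 37) {
  key <- function(df) paste(df$sample_id, df$session, sep = "::")
  if (!identical(key(volumes), key(covars)))
    stop("volumes and covars must share (sample_id, session) rows",
         call. = FALSE)
  reports <- list()

  keep <- covars$ga >= min_ga
  reports$term <- qc_report("term_born", nrow(covars), sum(keep),
                            key(covars)[!keep], list(min_ga = min_ga))
  volumes <- volumes[keep, , drop = FALSE]; covars <- covars[keep, , drop = FALSE]

  keep <- covars$radiology_score != 5
  reports$radiology <- qc_report("radiology", nrow(covars), sum(keep),
                                 key(covars)[!keep],
                                 list(excluded_score = 5))
  volumes <- volumes[keep, , drop = FALSE]; covars <- covars[keep, , drop = FALSE]

  first <- stats::ave(covars$session, covars$sample_id, FUN = min)
  keep <- covars$session == first
  reports$session <- qc_report("first_session", nrow(covars), sum(keep),
                               key(covars)[!keep], list())
  volumes <- volumes[keep, , drop = FALSE]; covars <- covars[keep, , drop = FALSE]

  if (!nrow(covars)) stop("empty cohort after filtering", call. = FALSE)
  rownames(volumes) <- rownames(covars) <- NULL
  list(volumes = volumes, covars = covars, reports = reports)
}

#' Aggregate parcellation regions into lobe volumes
#'
#' Sums constituent region volumes into the four lobes, the two composites
#' (fronto-temporal = frontal + temporal, parieto-occipital = parietal +
#' occipital) and total brain tissue volume.
#'
#' @param volumes regional volume table (sample_id, session, regions...).
#' @param map named list of region vectors for frontal, temporal, parietal,
#'   occipital (see [default_lobe_map()]).
#' @param tbv_regions regions summed into TBV; default: every region column.
#' @return data.frame with sample_id and columns frontal, temporal, parietal,
#'   occipital, fronto_temporal, parieto_occipital, tbv.
#' @export
aggregate_lobes <- function(volumes, map = default_lobe_map(),
                            tbv_regions = NULL) {
  region_cols <- setdiff(names(volumes), c("sample_id", "session"))
  for (lb in c("frontal", "temporal", "parietal", "occipital")) {
    missing_r <- setdiff(map[[lb]], region_cols)
    if (length(missing_r))
      stop("lobe map region(s) absent from the volume table: ",
           paste(missing_r, collapse = ", "), call. = FALSE)
  }
  tbv_regions <- tbv_regions %||% region_cols
  bad <- setdiff(tbv_regions, region_cols)
  if (length(bad))
    stop("TBV region(s) absent from the volume table: ",
         paste(bad, collapse = ", "), call. = FALSE)
  sum_of <- function(cols) rowSums(volumes[, cols, drop = FALSE])
  out <- data.frame(sample_id = volumes$sample_id,
                    frontal = sum_of(map$frontal),
                    temporal = sum_of(map$temporal),
                    parietal = sum_of(map$parietal),
                    occipital = sum_of(map$occipital),
                    stringsAsFactors = FALSE)
  out$fronto_temporal <- out$frontal + out$temporal
  out$parieto_occipital <- out$parietal + out$occipital
  out$tbv <- sum_of(tbv_regions)
  out
}

lobe_names <- function() c("frontal", "temporal", "parietal", "occipital",
                           "fronto_temporal", "parieto_occipital")

# -- primary regression ------------------------------------------------------

# internal: design-matrix OLS of standardized y on standardized score plus
# covariates; returns beta/se/t/p for the score term
.fit_ols <- function(y, score, covars) {
  df <- data.frame(y = y, score = score, covars)
  cc <- stats::complete.cases(df)
  n_dropped <- sum(!cc)
  if (n_dropped > 0)
    message("listwise deletion: dropped ", n_dropped, " incomplete row(s)")
  df <- df[cc, , drop = FALSE]
  if (nrow(df) <= ncol(df) + 1)
    stop("too few complete observations (", nrow(df), ") for ",
         ncol(df) - 1, " predictors", call. = FALSE)
  df$y <- zscore(df$y)
  df$score <- zscore(df$score)
  X <- cbind(`(Intercept)` = 1, as.matrix(df[, -1, drop = FALSE]))
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    drop_cols <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(drop_cols, collapse = ", "), call. = FALSE)
  }
  fit <- stats::lm.fit(X, df$y)
  res_df <- nrow(X) - ncol(X)
  sigma2 <- sum(fit$residuals^2) / res_df
  XtX_inv <- chol2inv(qr.R(qr_x))
  se <- sqrt(sigma2 * diag(XtX_inv))
  j <- match("score", colnames(X))
  beta <- fit$coefficients[j]
  se_b <- se[j]
  tval <- if (se_b > 0) beta / se_b else 0
  p <- if (se_b > 0) 2 * stats::pt(-abs(tval), res_df) else 1
  list(beta = unname(beta), se = unname(se_b), t = unname(tval), p = p,
       n = nrow(X), df = res_df)
}

#' Covariate-adjusted association of one lobe volume with a polygenic score
#'
#' Ordinary least squares of the standardized lobe volume on the standardized
#' score with gestational age, postmenstrual age, sex, total brain volume and
#' the leading ancestry components as covariates (whatever numeric columns
#' `covars` carries). Rows with missing values are dropped listwise.
#'
#' @param volume numeric vector of one lobe's volumes.
#' @param score numeric vector (e.g. PRS-PC1 values), aligned with `volume`.
#' @param covars data.frame of numeric covariates, aligned rows.
#' @param lobe label recorded in the result.
#' @return one-row data.frame: lobe, beta, se, t, p, n.
#' @export
fit_lobe_model <- function(volume, score, covars, lobe = "lobe") {
  f <- .fit_ols(volume, score, covars)
  data.frame(lobe = lobe, beta = f$beta, se = f$se, t = f$t, p = f$p,
             n = f$n, stringsAsFactors = FALSE)
}

#' Primary six-lobe association with FDR control
#'
#' Fits [fit_lobe_model()] for the six lobe volumes and adjusts the six
#' p-values by Benjamini-Hochberg; associations with adjusted p below
#' `alpha` are flagged significant.
#'
#' @param score numeric vector (PRS-PC1), aligned with `lobes` rows.
#' @param lobes lobe volume table from [aggregate_lobes()].
#' @param covars aligned covariate data.frame (numeric columns only).
#' @param alpha FDR significance level, default 0.05.
#' @return data.frame with one row per lobe: beta, se, t, p, p_fdr,
#'   significant.
#' @export
run_primary <- function(score, lobes, covars, alpha = 0.05) {
  res <- do.call(rbind, lapply(lobe_names(), function(lb)
    fit_lobe_model(lobes[[lb]], score, covars, lobe = lb)))
  res$p_fdr <- stats::p.adjust(res$p, method = "BH")
  res$significant <- res$p_fdr < alpha
  res
}

# -- stability tests ---------------------------------------------------------

#' Split-half stability of the primary association
#'
#' Repeatedly splits the cohort into random halves; within each half the
#' threshold-score PCA and the six lobe regressions are recomputed
#' independently. A replicate is consistent for a lobe when both halves
#' reproduce the sign of the full-sample coefficient.
#'
#' @param prs a `prs_matrix` for the analysis cohort.
#' @param lobes lobe table from [aggregate_lobes()], aligned with `prs` rows.
#' @param covars aligned numeric covariate data.frame.
#' @param full_results full-sample results from [run_primary()] (for the
#'   reference signs); computed internally when NULL.
#' @param n_reps number of random splits, default 1000.
#' @param seed integer seed.
#' @return list with `consistency` (named per-lobe fraction of consistent
#'   replicates) and `n_reps`.
#' @export
split_half_stability <- function(prs, lobes, covars, full_results = NULL,
                                 n_reps = 1000, seed = 1L) {
  n <- nrow(prs$scores)
  if (n < 40) stop("cohort too small for split-half testing", call. = FALSE)
  if (is.null(full_results)) {
    full_pc1 <- prs_pca(prs)
    full_results <- run_primary(full_pc1$values, lobes, covars)
  }
  ref_sign <- sign(full_results$beta)
  names(ref_sign) <- full_results$lobe
  half_fit <- function(idx) {
    sub <- structure(list(scores = prs$scores[idx, , drop = FALSE],
                          thresholds = prs$thresholds,
                          n_snps_used = prs$n_snps_used),
                     class = "prs_matrix")
    pc1 <- prs_pca(sub)
    run_primary(pc1$values, lobes[idx, , drop = FALSE],
                covars[idx, , drop = FALSE])
  }
  consistent <- matrix(FALSE, n_reps, length(lobe_names()),
                       dimnames = list(NULL, lobe_names()))
  with_seed(derive_seed(seed, "split_half"), {
    for (r in seq_len(n_reps)) {
      perm <- sample.int(n)
      h1 <- perm[seq_len(n %/% 2)]
      h2 <- perm[(n %/% 2 + 1):n]
      r1 <- suppressMessages(half_fit(h1))
      r2 <- suppressMessages(half_fit(h2))
      consistent[r, ] <- sign(r1$beta) == ref_sign[r1$lobe] &
        sign(r2$beta) == ref_sign[r2$lobe]
    }
  })
  list(consistency = colMeans(consistent), n_reps = n_reps)
}

#' Score-extremes comparison of lobe volumes
#'
#' For each p-value threshold, compares covariate-adjusted lobe volumes
#' between the top and bottom `tail` fraction of that threshold's score
#' distribution with a Welch two-sample t-test. Tail membership is by rank
#' (floor(tail * n) samples per tail; rank ties broken by sample order).
#' Volumes are residualized on the covariates first; set
#' `residualize = FALSE` to compare raw volumes.
#'
#' @param prs a `prs_matrix`.
#' @param lobes aligned lobe table.
#' @param covars aligned numeric covariate data.frame.
#' @param tail tail fraction, default 0.2.
#' @param residualize adjust volumes for covariates first, default TRUE.
#' @return data.frame with threshold, lobe, t, p, mean_top, mean_bottom.
#' @export
extremes_test <- function(prs, lobes, covars, tail = 0.2,
                          residualize = TRUE) {
  n <- nrow(prs$scores)
  k <- floor(tail * n)
  if (k < 3) stop("each tail must contain at least 3 samples", call. = FALSE)
  X <- cbind(1, as.matrix(covars))
  resid_of <- function(y) {
    if (!residualize) return(y)
    stats::lm.fit(X, y)$residuals
  }
  rows <- list()
  for (t in seq_along(prs$thresholds)) {
    s <- prs$scores[, t]
    if (stats::sd(s) == 0) next  # degenerate threshold column
    ord <- order(s, seq_along(s))       # ties broken by sample order
    bottom <- ord[seq_len(k)]
    top <- ord[seq(n - k + 1, n)]
    for (lb in lobe_names()) {
      rv <- resid_of(lobes[[lb]])
      if (stats::sd(rv[top]) == 0 && stats::sd(rv[bottom]) == 0)
        stop("degenerate extremes test: zero residual variance in both tails",
             call. = FALSE)
      tt <- stats::t.test(rv[top], rv[bottom])
      rows[[length(rows) + 1]] <-
        data.frame(threshold = prs$thresholds[t], lobe = lb,
                   t = unname(tt$statistic), p = tt$p.value,
                   mean_top = mean(rv[top]), mean_bottom = mean(rv[bottom]),
                   n_per_tail = k, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Per-threshold regression grid
#'
#' Repeats the primary covariate-adjusted regression with each standardized
#' threshold score in place of the aggregate component; descriptive (no
#' multiplicity adjustment). Constant score columns are excluded with a
#' warning.
#'
#' @param prs a `prs_matrix`.
#' @param lobes aligned lobe table.
#' @param covars aligned numeric covariate data.frame.
#' @return data.frame with threshold, lobe, beta, se, t, p.
#' @export
per_threshold_regression <- function(prs, lobes, covars) {
  rows <- list()
  for (t in seq_along(prs$thresholds)) {
    s <- prs$scores[, t]
    if (stats::sd(s) == 0) {
      warning("threshold ", prs$thresholds[t],
              " has a constant score column; excluded from the grid")
      next
    }
    for (lb in lobe_names()) {
      f <- fit_lobe_model(lobes[[lb]], s, covars, lobe = lb)
      f$threshold <- prs$thresholds[t]
      rows[[length(rows) + 1]] <- f[, c("threshold", "lobe", "beta", "se",
                                        "t", "p", "n")]
    }
  }
  do.call(rbind, rows)
}
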