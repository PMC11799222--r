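#' Construct a genotype matrix object
#'
#' Container for biallelic SNP dosages (0/1/2, `NA` = missing) with variant
#' and sample metadata, the common currency of the QC, scoring and scan
#' stages.
#'
#' @param dosages numeric matrix, samples x SNPs; entries in \{0, 1, 2, NA\}.
#' @param variants data.frame with columns `id`, `chrom`, `pos` (1-based),
#'   `ref`, `alt`; one row per SNP, positions strictly increasing within
#'   chromosome.
#' @param samples data.frame with at least a column `id`; one row per sample.
#' @param validate run the full invariant checks; internal subsetting of an
#'   already-validated object may skip them.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, variants, samples, validate = TRUE) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (nrow(dosages) != nrow(samples))
    stop("dosage rows (", nrow(dosages), ") != samples (", nrow(samples), ")",
         call. = FALSE)
  if (ncol(dosages) != nrow(variants))
    stop("dosage columns (", ncol(dosages), ") != variants (", nrow(variants),
         ")", call. = FALSE)
  need_v <- c("id", "chrom", "pos", "ref", "alt")
  if (!all(need_v %in% names(variants)))
    stop("variants must have columns: ", paste(need_v, collapse = ", "),
         call. = FALSE)
  if (!"id" %in% names(samples))
    stop("samples must have an 'id' column", call. = FALSE)
  if (validate) {
    if (anyDuplicated(variants$id))
      stop("variant ids must be unique", call. = FALSE)
    if (anyDuplicated(samples$id))
      stop("sample ids must be unique", call. = FALSE)
    if (any(!is.na(dosages) & (dosages < 0 | dosages > 2 |
                               dosages != round(dosages))))
      stop("dosages must be 0, 1, 2 or NA", call. = FALSE)
    for (ch in unique(variants$chrom)) {
      p <- variants$pos[variants$chrom == ch]
      if (any(diff(p) <= 0))
        stop("positions must be strictly increasing within chromosome ", ch,
             call. = FALSE)
    }
  }
  rownames(dosages) <- samples$id
  colnames(dosages) <- variants$id
  structure(list(dosages = dosages,
                 variants = as.data.frame(variants),
                 samples = as.data.frame(samples)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosages), "samples x", ncol(x$dosages),
      "SNPs;", sum(is.na(x$dosages)), "missing calls\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

# Subset helper: keep given samples (ids, or logical/integer index) and/or SNPs.
subset_geno <- function(geno, samples = NULL, snps = NULL) {
  d <- geno$dosages
  si <- seq_len(nrow(d))
  vi <- seq_len(ncol(d))
  if (!is.null(samples)) {
    si <- if (is.character(samples)) match(samples, geno$samples$id)
          else seq_len(nrow(d))[samples]
    if (anyNA(si)) stop("unknown sample id in subset", call. = FALSE)
  }
  if (!is.null(snps)) {
    vi <- if (is.character(snps)) match(snps, geno$variants$id)
          else seq_len(ncol(d))[snps]
    if (anyNA(vi)) stop("unknown variant id in subset", call. = FALSE)
    vi <- sort(vi)   # variants keep panel (chromosome, position) order
  }
  genotype_matrix(d[si, vi, drop = FALSE],
                  geno$variants[vi, , drop = FALSE],
                  geno$samples[si, , drop = FALSE], validate = FALSE)
}

#' Build a QC stage report
#'
#' Bookkeeping record emitted by every filtering step: counts before/after,
#' the removed ids, and the thresholds used. The invariant
#' `n_before - n_after == length(removed_ids)` is enforced.
#'
#' @param stage character label of the QC stage.
#' @param n_before,n_after unit counts before/after the filter.
#' @param removed_ids character vector of removed unit ids.
#' @param parameters named list of threshold values applied.
#' @return An object of class `qc_report`.
#' @export
qc_report <- function(stage, n_before, n_after, removed_ids,
                      parameters = list()) {
  removed_ids <- as.character(removed_ids)
  if (n_before - n_after != length(removed_ids))
    stop("QC report does not reconcile: ", n_before, " - ", n_after,
         " != ", length(removed_ids), call. = FALSE)
  structure(list(stage = stage, n_before = n_before, n_after = n_after,
                 removed_ids = removed_ids, parameters = parameters),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("[%s] %d -> %d (removed %d)\n", x$stage, x$n_before,
              x$n_after, length(x$removed_ids)))
  invisible(x)
}
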