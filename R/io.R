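# All tables are tab-separated UTF-8 with a header row; missing numeric
# fields are written "NA".

#' Write / read a generic tab-separated table
#' @param x data.frame to write.
#' @param path file path.
#' @return `read_tsv()` returns a data.frame.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, comment.char = "#",
                    colClasses = NA)
}

#' Write genotypes as a minimal VCF
#'
#' Biallelic sites with GT-only FORMAT; dosage 0/1/2 encoded as 0/0, 0/1,
#' 1/1 and missing as "./.".
#'
#' @param geno a [genotype_matrix()].
#' @param path output path (.vcf).
#' @export
write_vcf <- function(geno, path) {
  v <- geno$variants
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=neuroprs",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", geno$samples$id),
                     collapse = "\t")), con)
  gt_code <- c("0/0", "0/1", "1/1")
  for (k in seq_len(nrow(v))) {
    dd <- geno$dosages[, k]
    gt <- ifelse(is.na(dd), "./.", gt_code[dd + 1])
    writeLines(paste(c(v$chrom[k], v$pos[k], v$id[k], v$ref[k], v$alt[k],
                       ".", "PASS", ".", "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a GT-only VCF into a genotype matrix
#'
#' Accepts unphased or phased diploid GT fields; any allele marked "." makes
#' the call missing. Records out of positional order are sorted with a
#' warning.
#'
#' @param path VCF path.
#' @return a [genotype_matrix()].
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (!length(hdr)) stop("malformed VCF: no #CHROM header line in ", path,
                         call. = FALSE)
  cols <- strsplit(lines[hdr[1]], "\t", fixed = TRUE)[[1]]
  if (length(cols) < 10 || cols[9] != "FORMAT")
    stop("VCF must carry a FORMAT column with GT sample fields: ", path,
         call. = FALSE)
  sample_ids <- cols[-(1:9)]
  body <- lines[-seq_len(hdr[1])]
  body <- body[nzchar(body)]
  if (!length(body)) stop("VCF has no records: ", path, call. = FALSE)
  parts <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != nf[1]))
    stop("malformed VCF record at line ", hdr[1] + which(nf != nf[1])[1],
         call. = FALSE)
  tab <- do.call(rbind, parts)
  if (ncol(tab) != 9 + length(sample_ids))
    stop("VCF body/header column mismatch in ", path, call. = FALSE)
  gt_cols <- seq(10, ncol(tab))
  gt <- tab[, gt_cols, drop = FALSE]
  gt <- sub(":.*$", "", gt)
  dos <- matrix(NA_real_, nrow(tab), length(gt_cols))
  a <- sub("^([^/|]*)[/|].*$", "\\1", gt)
  b <- sub("^[^/|]*[/|](.*)$", "\\1", gt)
  okc <- a %in% c("0", "1") & b %in% c("0", "1")
  dos[okc] <- as.numeric(a[okc]) + as.numeric(b[okc])
  variants <- data.frame(id = tab[, 3], chrom = tab[, 1],
                         pos = as.integer(tab[, 2]), ref = tab[, 4],
                         alt = tab[, 5], stringsAsFactors = FALSE)
  ord <- order(suppressWarnings(as.integer(variants$chrom)), variants$chrom,
               variants$pos)
  if (!identical(ord, seq_len(nrow(variants)))) {
    warning("VCF records out of positional order; sorting internally")
    variants <- variants[ord, , drop = FALSE]
    dos <- dos[ord, , drop = FALSE]
  }
  genotype_matrix(t(dos), variants,
                  data.frame(id = sample_ids, stringsAsFactors = FALSE))
}

#' Write genotypes in PLINK text (.ped/.map) dialect
#'
#' @param geno a [genotype_matrix()].
#' @param prefix output prefix; writes `prefix.ped` and `prefix.map`.
#' @export
write_plink <- function(geno, prefix) {
  v <- geno$variants
  write_map <- data.frame(v$chrom, v$id, 0, v$pos)
  utils::write.table(write_map, paste0(prefix, ".map"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  n <- nrow(geno$samples)
  sex_col <- if ("sex" %in% names(geno$samples))
    geno$samples$sex + 1 else rep(0, n)
  lines <- character(n)
  for (i in seq_len(n)) {
    d <- geno$dosages[i, ]
    a1 <- ifelse(is.na(d), "0", ifelse(d >= 1, v$alt, v$ref))
    a2 <- ifelse(is.na(d), "0", ifelse(d == 2, v$alt, v$ref))
    lines[i] <- paste(c(geno$samples$id[i], geno$samples$id[i], 0, 0,
                        sex_col[i], -9, rbind(a1, a2)), collapse = "\t")
  }
  writeLines(lines, paste0(prefix, ".ped"))
  invisible(prefix)
}

#' Read PLINK text (.ped/.map) genotypes
#'
#' Alleles are oriented against the first non-zero allele observed per SNP
#' unless a reference/alt pair can be inferred; the minor allele becomes alt
#' when both alleles are seen.
#'
#' @param prefix path prefix of the `.ped` and `.map` files.
#' @return a [genotype_matrix()] (ref/alt inferred from the data).
#' @export
read_plink <- function(prefix) {
  map <- utils::read.table(paste0(prefix, ".map"), sep = "\t",
                           stringsAsFactors = FALSE)
  names(map) <- c("chrom", "id", "cm", "pos")
  ped <- utils::read.table(paste0(prefix, ".ped"), sep = "\t",
                           stringsAsFactors = FALSE, colClasses = "character")
  m <- nrow(map)
  if (ncol(ped) != 6 + 2 * m)
    stop("ped/map mismatch: expected ", 6 + 2 * m, " columns, found ",
         ncol(ped), call. = FALSE)
  ids <- ped[[2]]
  al1 <- as.matrix(ped[, 6 + seq(1, 2 * m, by = 2), drop = FALSE])
  al2 <- as.matrix(ped[, 6 + seq(2, 2 * m, by = 2), drop = FALSE])
  dos <- matrix(NA_real_, nrow(ped), m)
  ref <- alt <- character(m)
  for (j in seq_len(m)) {
    a <- c(al1[, j], al2[, j])
    seen <- setdiff(unique(a), "0")
    if (!length(seen)) { ref[j] <- "N"; alt[j] <- "N"; next }
    counts <- table(factor(a[a != "0"], levels = seen))
    ref[j] <- names(sort(counts, decreasing = TRUE))[1]
    alt[j] <- if (length(seen) > 1) setdiff(seen, ref[j])[1] else "N"
    ok <- al1[, j] != "0" & al2[, j] != "0"
    dos[ok, j] <- (al1[ok, j] == alt[j]) + (al2[ok, j] == alt[j])
  }
  variants <- data.frame(id = map$id, chrom = as.character(map$chrom),
                         pos = map$pos, ref = ref, alt = alt,
                         stringsAsFactors = FALSE)
  genotype_matrix(dos, variants,
                  data.frame(id = ids, stringsAsFactors = FALSE))
}

#' Write / read GWAS summary statistics (SNP/CHR/BP/A1/A2/BETA/P)
#' @param stats summary statistics data.frame.
#' @param path file path.
#' @export
write_sumstats <- function(stats, path) {
  need <- c("SNP", "CHR", "BP", "A1", "A2", "BETA", "P")
  stopifnot(all(need %in% names(stats)))
  write_tsv(stats[, need], path)
}

#' @rdname write_sumstats
#' @export
read_sumstats <- function(path) {
  st <- read_tsv(path)
  need <- c("SNP", "CHR", "BP", "A1", "A2", "BETA", "P")
  miss <- setdiff(need, names(st))
  if (length(miss))
    stop("summary statistics file ", path, " lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  st$CHR <- as.character(st$CHR)
  st
}

#' Write / read gene annotation (BED-like, 1-based inclusive)
#'
#' Four tab-separated columns (chrom, start, stop, gene_id) after a comment
#' header declaring the coordinate convention.
#'
#' @param annotation data.frame with gene_id, chrom, start, stop.
#' @param path file path.
#' @export
write_annotation <- function(annotation, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# coordinates: 1-based, inclusive start and stop", con)
  utils::write.table(annotation[, c("chrom", "start", "stop", "gene_id")],
                     con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = c("chrom", "start", "stop", "gene_id"))
  invisible(path)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(path) {
  ann <- read_tsv(path)
  need <- c("chrom", "start", "stop", "gene_id")
  if (!all(need %in% names(ann)))
    stop("annotation file must have columns chrom/start/stop/gene_id",
         call. = FALSE)
  if (any(ann$start > ann$stop))
    stop("annotation has start > stop", call. = FALSE)
  ann$chrom <- as.character(ann$chrom)
  ann[, c("gene_id", "chrom", "start", "stop")]
}

#' Write / read a GMT gene-set file
#'
#' Tab-separated lines: set id, description, then member gene ids.
#'
#' @param db a [pathway_db()] (write) or path (read).
#' @param path file path.
#' @param background_n background gene count to use when reading (GMT carries
#'   none); defaults to the union of member genes.
#' @export
write_gmt <- function(db, path) {
  lines <- vapply(names(db$pathways), function(nm)
    paste(c(nm, "na", db$pathways[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path, background_n = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad))
    stop("malformed GMT line ", bad[1], " in ", path,
         " (need id, description, >=1 gene)", call. = FALSE)
  pathways <- stats::setNames(lapply(parts, function(p) p[-(1:2)]),
                              vapply(parts, `[[`, character(1), 1))
  n_bg <- background_n %||% length(unique(unlist(pathways)))
  pathway_db(pathways, background_n = n_bg)
}
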