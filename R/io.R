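#' Read a genotype matrix from a VCF file
#'
#' Retains biallelic SNP records only (single-base REF and ALT); multiallelic
#' and indel records are skipped and counted. Entries are alternate-allele
#' counts per sample. Loci failing the minor-allele-frequency or missingness
#' filters are dropped; remaining missing genotypes are imputed by the locus
#' mean rounded to the nearest valid count (or rejected with
#' `impute = "fail"`).
#'
#' @param path path to a VCF or bgzipped VCF with GT fields.
#' @param maf_min minimum minor allele frequency in `[0, 0.5)`.
#' @param max_missing maximum per-locus fraction of missing genotypes.
#' @param impute `"mean"` (default) or `"fail"`.
#' @return A `genotype_matrix` (ploidy inferred from the GT field) with
#'   attribute `vcf_log`: counts of skipped/filtered records.
#' @export
read_vcf <- function(path, maf_min = 0, max_missing = 0.05,
                     impute = c("mean", "fail")) {
  impute <- match.arg(impute)
  if (!file.exists(path)) stop("cannot read VCF: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  snp <- !is.na(ref) & !is.na(alt) & nchar(ref) == 1 & nchar(alt) == 1 &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_skipped <- sum(!snp)
  if (!any(snp))
    stop("zero biallelic SNPs in ", path, " (", n_skipped, " records skipped)")
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[snp, , drop = FALSE]
  fix <- fix[snp, , drop = FALSE]
  # allele counts from GT strings; NA for missing
  ploidy <- if (any(grepl("[/|]", gt[!is.na(gt)]))) 2L else 1L
  count_alt <- function(s) {
    al <- strsplit(s, "[/|]")
    vapply(al, function(a) {
      if (any(a == "." | is.na(a))) return(NA_integer_)
      sum(a == "1")
    }, integer(1))
  }
  cnt <- t(apply(gt, 1, count_alt))
  if (ncol(gt) == 1) cnt <- matrix(as.integer(cnt), ncol = 1)
  miss_frac <- rowMeans(is.na(cnt))
  P <- rowMeans(cnt, na.rm = TRUE) / ploidy
  maf_ok <- !is.na(P) & pmin(P, 1 - P) >= maf_min
  miss_ok <- miss_frac <= max_missing
  keep <- maf_ok & miss_ok
  if (!any(keep))
    stop("zero biallelic SNPs after filters in ", path, ": ",
         n_skipped, " non-biallelic-SNP records skipped, ",
         sum(!maf_ok), " below MAF ", maf_min, ", ",
         sum(!miss_ok), " above missingness ", max_missing)
  cnt <- cnt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  if (anyNA(cnt)) {
    if (impute == "fail") stop("missing genotypes remain after filtering")
    for (i in which(rowSums(is.na(cnt)) > 0)) {
      fill <- min(ploidy, max(0L, as.integer(round(mean(cnt[i, ], na.rm = TRUE)))))
      cnt[i, is.na(cnt[i, ])] <- fill
    }
  }
  ids <- paste(fix[, "CHROM"], fix[, "POS"], fix[, "REF"], fix[, "ALT"], sep = ":")
  g <- genotype_matrix(t(cnt), colnames(gt), ids, ploidy = ploidy)
  attr(g, "vcf_log") <- c(skipped_non_biallelic_snp = n_skipped,
                          below_maf = sum(!maf_ok),
                          above_missing = sum(!miss_ok & maf_ok),
                          kept = sum(keep))
  g
}

#' Write a genotype matrix as a minimal VCF
#'
#' Emits a VCF 4.2 text file with synthetic coordinates (`chrom` `1`, positions
#' `1..L`) unless locus ids follow the `chrom:pos:ref:alt` convention, in which
#' case those are used. Intended for simulated data and round-tripping.
#'
#' @param g a `genotype_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  X <- g$values
  ids <- colnames(X)
  parts <- strsplit(ids, ":", fixed = TRUE)
  std <- all(lengths(parts) == 4)
  chrom <- if (std) vapply(parts, `[`, "", 1) else rep("1", ncol(X))
  pos <- if (std) vapply(parts, `[`, "", 2) else as.character(seq_len(ncol(X)))
  ref <- if (std) vapply(parts, `[`, "", 3) else rep("A", ncol(X))
  alt <- if (std) vapply(parts, `[`, "", 4) else rep("T", ncol(X))
  gt_of <- if (g$ploidy == 1) c("0" = "0", "1" = "1")
           else c("0" = "0/0", "1" = "0/1", "2" = "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(X)), collapse = "\t")), con)
  body <- vapply(seq_len(ncol(X)), function(j) {
    paste(c(chrom[j], pos[j], ids[j], ref[j], alt[j], ".", "PASS", ".", "GT",
            gt_of[as.character(X[, j])]), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' Read/write a delimited genotype matrix
#'
#' Tab-separated text: first column `sample_id`, header row of locus ids,
#' integer genotype cells.
#'
#' @param path file path.
#' @param ploidy 1 or 2.
#' @return `read_geno`: a `genotype_matrix`. `write_geno`: `path`, invisibly.
#' @export
read_geno <- function(path, ploidy = 1) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) < 2) stop("genotype table needs a sample_id column plus loci")
  ids <- as.character(d[[1]])
  m <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  genotype_matrix(m, ids, colnames(d)[-1], ploidy = ploidy)
}

#' @rdname read_geno
#' @param g a `genotype_matrix`.
#' @export
write_geno <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  d <- data.frame(sample_id = rownames(g$values), g$values,
                  check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write population labels
#'
#' Two-column tab-separated file: `sample_id`, `population`. The returned
#' assignment covers exactly the samples of `g`, in matrix order.
#'
#' @param path file path.
#' @param g the `genotype_matrix` the labels refer to.
#' @param ignore_unknown if `TRUE`, rows for samples absent from `g` are
#'   dropped with a warning; if `FALSE` (default) they are an error.
#' @return `read_labels`: a `pop_assignment`. `write_labels`: `path`.
#' @export
read_labels <- function(path, g, ignore_unknown = FALSE) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(d) < 2) stop("label file needs two columns: sample_id, population")
  ids <- as.character(d[[1]])
  if (anyDuplicated(ids))
    stop("duplicate sample rows in label file: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  unknown <- setdiff(ids, sample_ids(g))
  if (length(unknown)) {
    if (!ignore_unknown)
      stop("label file references unknown samples: ",
           paste(unknown, collapse = ", "))
    warning("ignoring ", length(unknown), " unknown samples in label file")
    keep <- !(ids %in% unknown)
    d <- d[keep, , drop = FALSE]; ids <- ids[keep]
  }
  miss <- setdiff(sample_ids(g), ids)
  if (length(miss))
    stop("samples missing from label file: ", paste(miss, collapse = ", "))
  lab <- as.character(d[[2]]); names(lab) <- ids
  pop_assignment(lab[sample_ids(g)], sample_ids(g))
}

#' @rdname read_labels
#' @param a a `pop_assignment`.
#' @export
write_labels <- function(a, path) {
  utils::write.table(data.frame(sample_id = names(a$labels),
                                population = as.character(a$labels)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
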