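#' Genotype matrix container
#'
#' Builds a validated genotype matrix for `n` samples (rows) genotyped at `L`
#' biallelic loci (columns). Entries count copies of the alternate (derived)
#' allele: 0/1 for haploid data, 0/1/2 for diploid data. All downstream
#' statistics are invariant to a global allele flip `x -> ploidy - x`, so
#' ancestral polarization of the counted allele is not required.
#'
#' @param values integer matrix, samples x loci. `NA` marks missing calls.
#' @param sample_ids character vector of unique sample identifiers; defaults to
#'   existing rownames or `sample_1..n`.
#' @param locus_ids character vector of unique locus identifiers; defaults to
#'   existing colnames or `locus_1..L`.
#' @param ploidy 1 or 2.
#' @return An object of class `genotype_matrix`: a list with elements `values`
#'   (integer matrix with dimnames) and `ploidy`.
#' @examples
#' g <- genotype_matrix(matrix(c(0L, 1L, 1L, 0L), 2, 2), ploidy = 1)
#' n_samples(g)
#' @export
genotype_matrix <- function(values, sample_ids = NULL, locus_ids = NULL,
                            ploidy = 1) {
  if (!is.matrix(values)) stop("'values' must be a matrix")
  if (!ploidy %in% c(1, 2)) stop("'ploidy' must be 1 or 2")
  storage.mode(values) <- "integer"
  if (is.null(sample_ids)) {
    sample_ids <- rownames(values)
    if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_len(nrow(values)))
  }
  if (is.null(locus_ids)) {
    locus_ids <- colnames(values)
    if (is.null(locus_ids)) locus_ids <- paste0("locus_", seq_len(ncol(values)))
  }
  if (length(sample_ids) != nrow(values))
    stop("number of sample_ids (", length(sample_ids),
         ") does not match number of rows (", nrow(values), ")")
  if (length(locus_ids) != ncol(values))
    stop("number of locus_ids (", length(locus_ids),
         ") does not match number of columns (", ncol(values), ")")
  if (anyDuplicated(sample_ids)) stop("sample_ids must be unique")
  if (anyDuplicated(locus_ids)) stop("locus_ids must be unique")
  rng <- range(values, na.rm = TRUE)
  if (length(values) && (rng[1] < 0 || rng[2] > ploidy))
    stop("genotype entries must lie in [0, ", ploidy, "]")
  dimnames(values) <- list(sample_ids, locus_ids)
  structure(list(values = values, ploidy = ploidy), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d loci (ploidy %d)\n",
              nrow(x$values), ncol(x$values), x$ploidy))
  nm <- sum(is.na(x$values))
  if (nm > 0) cat(sprintf("  missing entries: %d\n", nm))
  invisible(x)
}

#' @rdname genotype_matrix
#' @param g a `genotype_matrix`.
#' @export
n_samples <- function(g) nrow(g$values)

#' @rdname genotype_matrix
#' @export
n_loci <- function(g) ncol(g$values)

#' @rdname genotype_matrix
#' @export
sample_ids <- function(g) rownames(g$values)

#' @rdname genotype_matrix
#' @export
locus_ids <- function(g) colnames(g$values)

#' Population assignment
#'
#' Maps each sample to one of `K` discrete populations and precomputes the
#' per-population haploid counts `n_k` and sample proportions `c_k = n_k / n`
#' used as weights throughout (Nei's formulation with correction for unequal
#' sample sizes). Populations are ordered by first appearance.
#'
#' @param labels character (or factor) vector of population labels, one per
#'   sample, optionally named by sample id.
#' @param sample_ids sample identifiers; defaults to `names(labels)`.
#' @return An object of class `pop_assignment` with elements `labels` (factor,
#'   levels in order of first appearance, named by sample id), `pops` (level
#'   names), `K`, `n_k`, `c_k`.
#' @examples
#' a <- pop_assignment(c(s1 = "A", s2 = "A", s3 = "B", s4 = "B"))
#' a$c_k
#' @export
pop_assignment <- function(labels, sample_ids = names(labels)) {
  force(sample_ids)
  labels <- as.character(labels)
  if (is.null(sample_ids))
    sample_ids <- paste0("sample_", seq_along(labels))
  if (length(sample_ids) != length(labels))
    stop("'labels' and 'sample_ids' lengths differ")
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids in assignment")
  if (anyNA(labels)) stop("missing population labels")
  lev <- unique(labels)
  f <- factor(labels, levels = lev)
  names(f) <- sample_ids
  n_k <- as.vector(table(f))
  n <- length(f)
  structure(list(labels = f, pops = lev, K = length(lev),
                 n_k = n_k, c_k = n_k / n),
            class = "pop_assignment")
}

#' @export
print.pop_assignment <- function(x, ...) {
  cat(sprintf("pop_assignment: %d samples in K = %d populations\n",
              length(x$labels), x$K))
  print(data.frame(population = x$pops, n_k = x$n_k, c_k = round(x$c_k, 4)),
        row.names = FALSE)
  invisible(x)
}

# match an assignment against a genotype matrix; returns assignment restricted
# and ordered to the matrix's samples
align_assignment <- function(a, g) {
  ids <- sample_ids(g)
  miss <- setdiff(ids, names(a$labels))
  if (length(miss))
    stop("samples without population label: ", paste(miss, collapse = ", "))
  pop_assignment(as.character(a$labels[ids]), ids)
}

#' Convert diploid genotypes to the haploid representation
#'
#' The spectral theory is stated for 0/1 matrices, with a diploid sample
#' represented by twice as many haploid rows. Each diploid genotype is split
#' into two haploid alleles; heterozygotes are assigned a random phase (each
#' order with probability 1/2 under the seeded generator). Per-locus allele
#' counts are preserved exactly.
#'
#' @param g a `genotype_matrix` with ploidy 2 and no missing entries.
#' @param seed integer seed for the random phase.
#' @return A `genotype_matrix` with ploidy 1 and `2 n` rows; row ids are the
#'   original ids suffixed with `.1` / `.2`.
#' @export
haploidize <- function(g, seed = 1L) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (g$ploidy != 2) stop("haploidize() expects ploidy-2 input")
  X <- g$values
  if (anyNA(X)) stop("missing entries present; filter or impute first")
  n <- nrow(X); L <- ncol(X)
  set.seed(seed)
  # first allele: 0 for genotype 0, 1 for genotype 2, Bernoulli(1/2) for hets
  A1 <- matrix(0L, n, L)
  A1[X == 2L] <- 1L
  het <- which(X == 1L)
  if (length(het)) A1[het] <- as.integer(stats::rbinom(length(het), 1, 0.5))
  A2 <- X - A1
  H <- matrix(0L, 2 * n, L)
  H[seq(1, 2 * n, by = 2), ] <- A1
  H[seq(2, 2 * n, by = 2), ] <- A2
  ids <- as.vector(rbind(paste0(rownames(X), ".1"), paste0(rownames(X), ".2")))
  genotype_matrix(H, ids, colnames(X), ploidy = 1)
}

#' Filter loci on polymorphism and minor allele frequency
#'
#' Removes loci that are monomorphic in the total sample (allele frequency 0 or
#' 1) and/or below a minor allele frequency threshold. Locus order is
#' preserved; removal counts are attached as attribute `filter_counts` and
#' reported via `message()`.
#'
#' @param g a `genotype_matrix` without missing entries.
#' @param drop_monomorphic drop loci with total frequency in \{0, 1\}.
#' @param maf_min drop loci with `min(P, 1 - P) < maf_min`.
#' @param quiet suppress the log message.
#' @return The filtered `genotype_matrix`.
#' @export
filter_loci <- function(g, drop_monomorphic = TRUE, maf_min = 0, quiet = FALSE) {
  stopifnot(inherits(g, "genotype_matrix"))
  X <- g$values
  if (anyNA(X)) stop("missing entries present; impute or drop them first")
  P <- colMeans(X) / g$ploidy
  mono <- P <= 0 | P >= 1
  low <- pmin(P, 1 - P) < maf_min & !mono
  keep <- if (drop_monomorphic) !(mono | low) else !low
  if (!any(keep))
    stop("all ", length(keep), " loci removed (",
         sum(mono), " monomorphic, ", sum(low), " below maf_min)")
  if (!quiet)
    message(sprintf("filter_loci: kept %d of %d loci (%d monomorphic, %d below MAF %.3g)",
                    sum(keep), length(keep),
                    if (drop_monomorphic) sum(mono) else 0L, sum(low), maf_min))
  out <- genotype_matrix(X[, keep, drop = FALSE], rownames(X),
                         colnames(X)[keep], g$ploidy)
  attr(out, "filter_counts") <- c(monomorphic = if (drop_monomorphic) sum(mono) else 0L,
                                  below_maf = sum(low), kept = sum(keep))
  out
}
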