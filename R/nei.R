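#' Per-locus allele frequencies and Nei statistics
#'
#' For a haploid genotype matrix and a population assignment, computes the
#' within-population derived-allele frequencies `p_kl`, the total-sample
#' frequencies `P_l = sum_k c_k p_kl` (the grand column means), and the Nei
#' diversity statistics per locus:
#' \deqn{H_S = 2 \sum_k c_k p_k (1 - p_k), \quad H_T = 2 P (1 - P),}
#' \deqn{D_{ST} = H_T - H_S, \quad F_{ST} = D_{ST} / H_T,}
#' with `F_ST` defined (unmasked) only on loci polymorphic in the total sample.
#' Weights `c_k` are sample proportions, i.e. Nei's formulation with
#' correction for unequal sample sizes.
#'
#' `allele_frequencies()` returns the frequency part only; `nei_stats()`
#' completes it with the diversity statistics.
#'
#' @param g haploid `genotype_matrix` without missing entries.
#' @param a `pop_assignment` covering the samples of `g`.
#' @return An object of class `per_locus_stats`: list with `p` (K x L), `P`,
#'   `H_S`, `H_T`, `D_ST`, `F_ST` (all length L; `F_ST` is `NA` off the
#'   polymorphic mask), `polymorphic`, `c_k`, `n_k`, `pops`, `K`, `n`,
#'   `locus_ids`.
#' @examples
#' g <- genotype_matrix(rbind(c(1L, 1L), c(1L, 0L), c(0L, 0L), c(0L, 1L)))
#' a <- pop_assignment(c("A", "A", "B", "B"), sample_ids(g))
#' s <- nei_stats(g, a)
#' mean_fst(s)
#' @export
allele_frequencies <- function(g, a) {
  stopifnot(inherits(g, "genotype_matrix"), inherits(a, "pop_assignment"))
  if (g$ploidy != 1)
    stop("statistics are defined on the haploid representation; haploidize() first")
  X <- g$values
  if (anyNA(X)) stop("missing entries present")
  a <- align_assignment(a, g)
  if (any(a$n_k < 1)) stop("empty population")
  p <- rowsum(X, a$labels, reorder = FALSE) / a$n_k
  P <- colMeans(X)
  structure(list(p = p, P = P, H_S = NULL, H_T = NULL, D_ST = NULL,
                 F_ST = NULL, polymorphic = P > 0 & P < 1,
                 c_k = a$c_k, n_k = a$n_k, pops = a$pops, K = a$K,
                 n = nrow(X), locus_ids = colnames(X)),
            class = "per_locus_stats")
}

#' @rdname allele_frequencies
#' @param s a `per_locus_stats` with frequencies present.
#' @export
nei_per_locus <- function(s) {
  stopifnot(inherits(s, "per_locus_stats"))
  s$H_S <- 2 * colSums(s$c_k * s$p * (1 - s$p))
  s$H_T <- 2 * s$P * (1 - s$P)
  s$D_ST <- s$H_T - s$H_S
  s$F_ST <- ifelse(s$polymorphic, s$D_ST / s$H_T, NA_real_)
  s
}

#' @rdname allele_frequencies
#' @export
nei_stats <- function(g, a) nei_per_locus(allele_frequencies(g, a))

#' @export
print.per_locus_stats <- function(x, ...) {
  cat(sprintf("per_locus_stats: %d loci, K = %d populations, n = %d\n",
              length(x$P), x$K, x$n))
  if (!is.null(x$F_ST))
    cat(sprintf("  mean F_ST = %.4f over %d polymorphic loci; mean D_ST = %.4f\n",
                mean_fst(x), sum(x$polymorphic), mean(x$D_ST)))
  invisible(x)
}

#' Mean per-locus F_ST and D_ST
#'
#' `mean_fst()` is the arithmetic mean of the per-locus ratios
#' `D_ST / H_T` over loci polymorphic in the total sample — an average of
#' ratios, not the ratio of averages. `mean_dst()` averages `D_ST` over all
#' loci.
#'
#' @param s a completed `per_locus_stats` (see [nei_stats()]).
#' @return A single fraction.
#' @export
mean_fst <- function(s) {
  stopifnot(inherits(s, "per_locus_stats"))
  if (is.null(s$F_ST)) stop("run nei_per_locus() first")
  if (!any(s$polymorphic)) stop("no polymorphic loci")
  mean(s$F_ST[s$polymorphic])
}

#' @rdname mean_fst
#' @export
mean_dst <- function(s) {
  stopifnot(inherits(s, "per_locus_stats"))
  if (is.null(s$D_ST)) stop("run nei_per_locus() first")
  mean(s$D_ST)
}

#' @export
as.data.frame.per_locus_stats <- function(x, ...) {
  d <- data.frame(locus_id = x$locus_ids, t(x$p), P = x$P,
                  check.names = FALSE, stringsAsFactors = FALSE)
  colnames(d)[1 + seq_len(x$K)] <- paste0("p_", x$pops)
  if (!is.null(x$H_S)) {
    d$H_S <- x$H_S; d$H_T <- x$H_T; d$D_ST <- x$D_ST; d$F_ST <- x$F_ST
  }
  d
}

#' Export per-locus statistics as TSV
#'
#' @param s a `per_locus_stats`.
#' @param path output path.
#' @export
write_per_locus_stats <- function(s, path) {
  utils::write.table(as.data.frame(s), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
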