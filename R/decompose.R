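#' Between/within decomposition of the genotype matrix
#'
#' Decomposes the column-centered genotype matrix as `Z = Z_ST + Z_S`:
#' the between-population matrix `Z_ST` has entry `p_kl - P_l` for every
#' sample of population `k` (rank at most `K - 1`), and the within-population
#' (residual) matrix `Z_S` has entry `x_il - p_kl`. Scaled variants divide
#' each column by `sqrt(P_l (1 - P_l))`; they are defined on the loci
#' polymorphic in the total sample (`L_eff` columns). The matrices satisfy the
#' Pythagorean identity `||Z||^2 = ||Z_ST||^2 + ||Z_S||^2` and, for 0/1 input,
#' `||Z_ST_sc||^2 / (n L_eff)` equals the mean per-locus F_ST exactly.
#'
#' @param g haploid `genotype_matrix` without missing entries.
#' @param a `pop_assignment` covering the samples of `g`.
#' @return An object of class `geno_decomp`: list with matrices `Z`, `Z_ST`,
#'   `Z_S` (all loci) and `Z_sc`, `Z_ST_sc`, `Z_S_sc` (polymorphic loci),
#'   the `stats` (`per_locus_stats`), `assign`, `n`, `K`, `L`, `L_eff`.
#' @examples
#' g <- genotype_matrix(matrix(rbinom(40, 1, 0.4), 8, 5))
#' a <- pop_assignment(rep(c("A", "B"), each = 4), sample_ids(g))
#' d <- decompose_genotypes(g, a)
#' max(abs(d$Z - d$Z_ST - d$Z_S))
#' @export
decompose_genotypes <- function(g, a) {
  stopifnot(inherits(g, "genotype_matrix"))
  a <- align_assignment(a, g)
  s <- nei_stats(g, a)
  X <- g$values
  storage.mode(X) <- "double"
  Z <- sweep(X, 2, s$P)
  Zst <- sweep(s$p[as.integer(a$labels), , drop = FALSE], 2, s$P)
  dimnames(Zst) <- dimnames(Z)
  Zs <- Z - Zst
  poly <- s$polymorphic
  sd_col <- sqrt(s$P[poly] * (1 - s$P[poly]))
  scale_cols <- function(M) sweep(M[, poly, drop = FALSE], 2, sd_col, "/")
  structure(list(Z = Z, Z_ST = Zst, Z_S = Zs,
                 Z_sc = scale_cols(Z), Z_ST_sc = scale_cols(Zst),
                 Z_S_sc = scale_cols(Zs),
                 stats = s, assign = a, n = nrow(X), K = a$K,
                 L = ncol(X), L_eff = sum(poly)),
            class = "geno_decomp")
}

#' @export
print.geno_decomp <- function(x, ...) {
  cat(sprintf("geno_decomp: n = %d, K = %d, L = %d (%d polymorphic)\n",
              x$n, x$K, x$L, x$L_eff))
  invisible(x)
}
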