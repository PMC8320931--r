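# Shared fixtures: random binary matrices with random partitions, and a tiny
# fixed-difference toy where every statistic is known in closed form.

# random haploid genotype matrix with a random K-way partition; every
# population non-empty, unequal sizes allowed
random_binary_case <- function(n_max = 30, L_max = 200, K_max = 5) {
  n <- sample(4:n_max, 1)
  L <- sample(10:L_max, 1)
  K <- sample(2:min(K_max, n - 1), 1)
  repeat {
    X <- matrix(rbinom(n * L, 1, runif(L, 0.05, 0.95)[rep(1:L, each = n)]),
                n, L)
    P <- colMeans(X)
    keep <- P > 0 & P < 1
    if (sum(keep) >= 5) break
  }
  X <- X[, keep, drop = FALSE]
  lab <- c(paste0("p", seq_len(K)),
           sample(paste0("p", seq_len(K)), n - K, replace = TRUE))
  g <- genotype_matrix(X, ploidy = 1)
  list(g = g, a = pop_assignment(sample(lab), sample_ids(g)))
}

# two populations of two haploids each, one locus fixed for opposite alleles:
# p = (1, 0), H_T = 0.5, H_S = 0, F_ST = 1, D_ST = 0.5
fixed_difference_toy <- function() {
  g <- genotype_matrix(matrix(c(1L, 1L, 0L, 0L), 4, 1),
                       sample_ids = c("a1", "a2", "b1", "b2"),
                       locus_ids = "chr1:1:A:T", ploidy = 1)
  list(g = g, a = pop_assignment(c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")))
}

# brute-force per-locus oracle used against the matrix implementations:
# plain loops over loci and populations, no linear algebra
oracle_nei <- function(X, labels) {
  pops <- unique(labels)
  n <- nrow(X)
  c_k <- vapply(pops, function(p) sum(labels == p), 0) / n
  t(vapply(seq_len(ncol(X)), function(l) {
    p_k <- vapply(pops, function(p) mean(X[labels == p, l]), 0)
    P <- sum(c_k * p_k)
    H_S <- 2 * sum(c_k * p_k * (1 - p_k))
    H_T <- 2 * P * (1 - P)
    c(P = P, H_S = H_S, H_T = H_T, D_ST = H_T - H_S,
      F_ST = if (H_T > 0) (H_T - H_S) / H_T else NA_real_)
  }, numeric(5)))
}

write_toy_vcf <- function(path) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", "s3", sep = "\t"),
    paste("1", "100", ".", "A", "T", ".", "PASS", ".", "GT",
          "0/0", "0/1", "1/1", sep = "\t"),
    paste("1", "200", ".", "C", "G,T", ".", "PASS", ".", "GT",
          "0/0", "0/2", "1/1", sep = "\t"),  # triallelic: skipped
    paste("1", "300", ".", "G", "A", ".", "PASS", ".", "GT",
          "0/1", "0/0", "0/0", sep = "\t"),
    paste("1", "400", ".", "T", "C", ".", "PASS", ".", "GT",
          "1/1", "0/1", "0/1", sep = "\t"))
  writeLines(lines, path)
  path
}
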