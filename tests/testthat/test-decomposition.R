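test_that("allele frequencies use sample-proportion weights", {
  toy <- fixed_difference_toy()
  s <- allele_frequencies(toy$g, toy$a)
  expect_equal(unname(s$p[, 1]), c(1, 0))
  expect_equal(unname(s$P), 0.5)
  # c = (0.75, 0.25), p = (0.2, 0.6): P = 0.75*0.2 + 0.25*0.6 = 0.3
  g <- genotype_matrix(matrix(c(1L, 0L, 0L, 0L, 0L, 1L, 1L, 1L), 8, 1),
                       ploidy = 1)
  a <- pop_assignment(rep(c("A", "B"), c(6, 2)), sample_ids(g))
  # pop A frequency 1/6... build instead exact 0.2/0.6: 5 A-samples 1 carrier,
  # 5 B-samples 3 carriers
  g <- genotype_matrix(matrix(c(1L, 0L, 0L, 0L, 0L,
                                1L, 1L, 1L, 0L, 0L), 10, 1), ploidy = 1)
  a <- pop_assignment(rep(c("A", "B"), each = 5), sample_ids(g))
  s <- allele_frequencies(g, a)
  expect_equal(unname(s$p[, 1]), c(0.2, 0.6))
  expect_equal(unname(s$P), 0.4)
  # K = 1: P is the single population's frequency
  a1 <- pop_assignment(rep("A", 10), sample_ids(g))
  s1 <- allele_frequencies(g, a1)
  expect_equal(unname(s1$p[1, ]), unname(s1$P))
})

test_that("Nei statistics match hand arithmetic and the brute-force oracle", {
  toy <- fixed_difference_toy()
  s <- nei_stats(toy$g, toy$a)
  expect_equal(unname(s$H_T), 0.5)
  expect_equal(unname(s$H_S), 0)
  expect_equal(unname(s$F_ST), 1)
  expect_equal(unname(s$D_ST), 0.5)
  # no differentiation: p = (0.5, 0.5) -> F_ST = 0
  g0 <- genotype_matrix(matrix(c(1L, 0L, 1L, 0L), 4, 1), ploidy = 1)
  a0 <- pop_assignment(c("A", "A", "B", "B"), sample_ids(g0))
  expect_equal(unname(nei_stats(g0, a0)$F_ST), 0)
  # weighted case c = (0.75, 0.25), p = (0.2, 0.6):
  # H_T = 2*0.3*0.7 = 0.42, H_S = 2*(0.75*0.16 + 0.25*0.24) = 0.36,
  # F_ST = 0.06/0.42 = 1/7
  X <- matrix(c(rep(1L, 3), rep(0L, 12), rep(1L, 3), rep(0L, 2)), 20, 1)
  g <- genotype_matrix(X, ploidy = 1)
  a <- pop_assignment(rep(c("A", "B"), c(15, 5)), sample_ids(g))
  s <- nei_stats(g, a)
  expect_equal(unname(s$p[, 1]), c(0.2, 0.6))
  expect_equal(unname(s$H_T), 0.42, tolerance = 1e-12)
  expect_equal(unname(s$H_S), 0.36, tolerance = 1e-12)
  expect_equal(unname(s$D_ST), 0.06, tolerance = 1e-12)
  expect_equal(unname(s$F_ST), 0.06 / 0.42, tolerance = 1e-12)
  expect_equal(mean_fst(s), 0.142857, tolerance = 1e-5)
  # brute-force loop oracle on random cases
  set.seed(11)
  for (i in 1:5) {
    cs <- random_binary_case()
    s <- nei_stats(cs$g, cs$a)
    o <- oracle_nei(cs$g$values, as.character(cs$a$labels[sample_ids(cs$g)]))
    expect_equal(unname(s$P), unname(o[, "P"]), tolerance = 1e-12)
    expect_equal(unname(s$H_S), unname(o[, "H_S"]), tolerance = 1e-12)
    expect_equal(unname(s$D_ST), unname(o[, "D_ST"]), tolerance = 1e-12)
    # D_ST >= 0 and equals 2 sum_k c_k (p_k - P)^2
    expect_true(all(s$D_ST >= -1e-12))
    dst2 <- 2 * colSums(cs$a$c_k * sweep(s$p, 2, s$P)^2)
    expect_equal(unname(s$D_ST), unname(dst2), tolerance = 1e-12)
    expect_true(all(s$F_ST[s$polymorphic] >= 0 & s$F_ST[s$polymorphic] <= 1))
  }
})

test_that("mean_fst averages ratios over the polymorphic mask", {
  # two loci: one fixed difference (F_ST = 1), one undifferentiated (F_ST = 0)
  g <- genotype_matrix(cbind(c(1L, 1L, 0L, 0L), c(1L, 0L, 1L, 0L)), ploidy = 1)
  a <- pop_assignment(c("A", "A", "B", "B"), sample_ids(g))
  expect_equal(mean_fst(nei_stats(g, a)), 0.5)
  # monomorphic loci are masked, not averaged as zeros
  g2 <- genotype_matrix(cbind(c(1L, 1L, 0L, 0L), c(0L, 0L, 0L, 0L)), ploidy = 1)
  expect_equal(mean_fst(nei_stats(g2, a)), 1)
})

test_that("the between/within decomposition satisfies its exact identities", {
  # closed form p_k - P equals the pairwise sum form sum_{j != k} c_j (p_k - p_j)
  X <- matrix(c(rep(1L, 3), rep(0L, 12), rep(1L, 3), rep(0L, 2)), 20, 1)
  g <- genotype_matrix(X, ploidy = 1)
  a <- pop_assignment(rep(c("A", "B"), c(15, 5)), sample_ids(g))
  d <- decompose_genotypes(g, a)
  expect_equal(d$Z_ST[1, 1], -0.1, tolerance = 1e-12)   # p_A - P = 0.2 - 0.3
  expect_equal(d$Z_ST[1, 1], sum(0.25 * (0.2 - 0.6)), tolerance = 1e-12)
  set.seed(21)
  for (i in 1:8) {
    cs <- random_binary_case()
    d <- decompose_genotypes(cs$g, cs$a)
    a <- d$assign
    # sum-form oracle for the between matrix
    lab <- as.integer(a$labels)
    Zst_oracle <- sapply(seq_len(ncol(d$Z)), function(l) {
      p <- d$stats$p[, l]
      vapply(lab, function(k) sum(a$c_k[-k] * (p[k] - p[-k])), 0)
    })
    expect_equal(unname(d$Z_ST), unname(Zst_oracle), tolerance = 1e-12)
    # additivity and centering
    expect_lt(max(abs(d$Z - d$Z_ST - d$Z_S)), 1e-12)
    expect_lt(max(abs(d$Z_sc - d$Z_ST_sc - d$Z_S_sc)), 1e-12)
    expect_lt(max(abs(colMeans(d$Z))), 1e-12)
    for (k in seq_len(a$K))
      expect_lt(max(abs(colMeans(d$Z_S[lab == k, , drop = FALSE]))), 1e-12)
    # rank(Z_ST) <= K - 1
    expect_lte(qr(d$Z_ST)$rank, a$K - 1)
    # Pythagorean identity, scaled and unscaled
    expect_equal(sum(d$Z^2), sum(d$Z_ST^2) + sum(d$Z_S^2),
                 tolerance = 1e-10)
    expect_equal(sum(d$Z_sc^2), sum(d$Z_ST_sc^2) + sum(d$Z_S_sc^2),
                 tolerance = 1e-10)
    # binary input: scaled columns have unit variance under divisor n
    expect_equal(sum(d$Z_sc^2), d$n * d$L_eff, tolerance = 1e-8)
    # module-level oracle equivalence
    s <- nei_stats(cs$g, cs$a)
    expect_equal(sum(d$Z_ST_sc^2) / (d$n * d$L_eff), mean_fst(s),
                 tolerance = 1e-10)
  }
})

test_that("single population decomposes into a zero between matrix", {
  set.seed(3)
  g <- genotype_matrix(matrix(rbinom(60, 1, 0.5), 6, 10), ploidy = 1)
  a <- pop_assignment(rep("only", 6), sample_ids(g))
  d <- decompose_genotypes(g, a)
  expect_equal(max(abs(d$Z_ST)), 0)
  expect_equal(d$Z_S, d$Z)
})

test_that("per-locus statistics export as a TSV table", {
  toy <- fixed_difference_toy()
  s <- nei_stats(toy$g, toy$a)
  path <- tempfile(fileext = ".tsv")
  write_per_locus_stats(s, path)
  d <- read.delim(path)
  expect_equal(names(d), c("locus_id", "p_A", "p_B", "P", "H_S", "H_T",
                           "D_ST", "F_ST"))
  expect_equal(d$F_ST, 1)
})
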