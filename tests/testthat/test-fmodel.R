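test_that("expected ancestral heterozygosity follows 2ab/((a+b)(a+b+1))", {
  expect_equal(expected_ha(1, 1), 1 / 3)
  expect_equal(expected_ha(1, 4), 4 / 15)
  expect_equal(expected_ha(1, 9), 18 / 110)
  expect_error(expected_ha(0, 1), "positive")
})

test_that("expected D_ST combines drift and sampling weights", {
  p0 <- fmodel_params(K = 2, F = c(0, 0), a = 1, b = 4, n_k = 10, L = 10)
  expect_equal(expected_dst(p0), 0)
  p1 <- fmodel_params(K = 2, F = c(0.1, 0.1), a = 1, b = 4, n_k = 10, L = 10)
  expect_equal(expected_dst(p1), 4 / 15 * 0.05, tolerance = 1e-12)  # 0.013333
  p2 <- fmodel_params(K = 3, F = c(0.05, 0.10, 0.30), a = 1, b = 4,
                      n_k = 10, L = 10)
  expect_equal(expected_dst(p2), 4 / 15 * (2 / 9) * 0.45, tolerance = 1e-12)
  expect_equal(expected_dst(p2), 0.026667, tolerance = 1e-4)
})

test_that("closed-form Lambda eigenvalues for K = 3 match their identities", {
  expect_equal(lambda_eigen_k3(0.1, 0.1, 0.1), c(0.3, 0.3) / 54)
  lam <- lambda_eigen_k3(0.05, 0.10, 0.30)
  expect_equal(lam, c(0.012576, 0.0040902), tolerance = 1e-4)
  # E[D_ST] = 2 (lambda_1 + lambda_2) under uniform ancestral frequencies
  p <- fmodel_params(K = 3, F = c(0.05, 0.10, 0.30), a = 1, b = 1,
                     n_k = 10, L = 10)
  expect_equal(2 * sum(lam), expected_dst(p), tolerance = 1e-12)
  expect_equal(lambda_eigen_k3(0, 0, 0), c(0, 0))
})

test_that("the simulator respects its distributional contract", {
  # no-drift limit: population frequencies track the ancestral frequency
  p <- fmodel_params(K = 2, F = c(1e-9, 1e-9), a = 1, b = 1, n_k = 20,
                     L = 400, drop_monomorphic = FALSE)
  sim <- simulate_fmodel(p, seed = 3)
  expect_gt(cor(sim$p_true[1, ], sim$p_anc), 0.999)
  expect_gt(cor(sim$p_true[2, ], sim$p_anc), 0.999)
  # ancestral mean: Beta(1, 4) has mean 0.2, sd sqrt(0.2*0.8/6)
  p2 <- fmodel_params(K = 1, F = 0.2, a = 1, b = 4, n_k = 2, L = 50000,
                      drop_monomorphic = FALSE)
  sim2 <- simulate_fmodel(p2, seed = 4)
  se <- sqrt(0.2 * 0.8 / 6) / sqrt(50000)
  expect_lt(abs(mean(sim2$p_anc) - 0.2), 3 * se)
  # genotype columns have expectation p_true within each population
  p3 <- fmodel_params(K = 2, F = c(0.3, 0.3), a = 1, b = 1, n_k = 50, L = 500)
  sim3 <- simulate_fmodel(p3, seed = 5)
  lab <- as.integer(sim3$labels$labels)
  for (k in 1:2) {
    obs <- colMeans(sim3$genotypes$values[lab == k, ])
    expect_gt(cor(obs, sim3$p_true[k, ]), 0.95)
    expect_lt(abs(mean(obs - sim3$p_true[k, ])), 0.01)
  }
  # reproducibility and monomorphic filtering
  simA <- simulate_fmodel(p3, seed = 9)
  simB <- simulate_fmodel(p3, seed = 9)
  expect_identical(simA$genotypes$values, simB$genotypes$values)
  expect_lte(n_loci(simA$genotypes), simA$L_before_filter)
  P <- colMeans(simA$genotypes$values)
  expect_true(all(P > 0 & P < 1))
  # simulate() method produces independent replicates
  sims <- simulate(p3, nsim = 2, seed = 100)
  expect_length(sims, 2)
  expect_false(identical(sims[[1]]$genotypes$values,
                         sims[[2]]$genotypes$values))
})

test_that("Lambda matrix Monte Carlo matches structure and closed form", {
  # K = 1: Lambda is the zero matrix (P = p_1)
  l1 <- lambda_matrix(fmodel_params(K = 1, F = 0.2, a = 1, b = 1, n_k = 10,
                                    L = 10), ndraws = 1000, seed = 1)
  expect_equal(unname(l1$Lambda), matrix(0, 1, 1))
  # K = 2 symmetric: off-diagonal negative (deviations anti-correlate)
  l2 <- lambda_matrix(fmodel_params(K = 2, F = c(0.2, 0.2), a = 1, b = 1,
                                    n_k = 10, L = 10), ndraws = 5000, seed = 2)
  expect_lt(l2$Lambda[1, 2], 0)
  expect_true(isSymmetric(l2$Lambda))
  expect_true(all(l2$eigenvalues > -1e-12))
  # K = 3 uniform ancestral: eigenvalues match the closed form within 3 SE
  p3 <- fmodel_params(K = 3, F = c(0.05, 0.10, 0.30), a = 1, b = 1,
                      n_k = 10, L = 10)
  l3 <- lambda_matrix(p3, ndraws = 5e4, seed = 3)
  lam <- lambda_eigen_k3(0.05, 0.10, 0.30)
  # eigenvalue MC error is bounded by the entrywise errors (Weyl); the trace
  # error accumulates across the diagonal
  tol <- 3 * max(l3$se) * 3
  expect_lt(abs(l3$eigenvalues[1] - lam[1]), tol)
  expect_lt(abs(l3$eigenvalues[2] - lam[2]), tol)
  # twice the eigenvalue sum is E[D_ST], up to trace-level MC error
  expect_lt(abs(2 * sum(l3$eigenvalues) - expected_dst(p3)),
            2 * 3 * sqrt(sum(diag(l3$se)^2)))
})

test_that("Monte-Carlo mean F_ST behaves at the drift limits", {
  pz <- fmodel_params(K = 2, F = c(1e-6, 1e-6), a = 1, b = 4, n_k = 10, L = 10)
  expect_lt(as.numeric(expected_fst_mc(pz, ndraws = 5000, seed = 1)), 1e-3)
  # strictly increasing in the drift coefficient
  efst <- vapply(c(0.05, 0.2, 0.5), function(F)
    as.numeric(expected_fst_mc(fmodel_params(K = 2, F = c(F, F), a = 1, b = 4,
                                             n_k = 10, L = 10),
                               ndraws = 2e4, seed = 2)), 0)
  expect_true(all(diff(efst) > 0))
  v <- expected_fst_mc(fmodel_params(K = 2, F = c(0.1, 0.1), a = 1, b = 4,
                                     n_k = 10, L = 10), ndraws = 2e4, seed = 3)
  expect_gt(attr(v, "se"), 0)
})

test_that("simulation and theory close the loop at moderate size", {
  # the theory is stated at the level of population frequencies: realized
  # per-locus D_ST and F_ST computed from the simulated p_k close on their
  # expectations within Monte-Carlo error
  params <- fmodel_params(K = 2, F = c(0.1, 0.1), a = 1, b = 4,
                          n_k = c(50, 50), L = 20000,
                          drop_monomorphic = FALSE)
  sim <- simulate_fmodel(params, seed = 17)
  P <- colSums(params$c_k * sim$p_true)
  HT <- 2 * P * (1 - P)
  HS <- 2 * colSums(params$c_k * sim$p_true * (1 - sim$p_true))
  dst <- HT - HS
  se_dst <- sd(dst) / sqrt(length(dst))
  expect_lt(abs(mean(dst) - expected_dst(params)), 3 * se_dst)
  fst <- (dst / HT)[HT > 0]
  thr <- expected_fst_mc(params, ndraws = 5e5, seed = 18)
  se <- sqrt(sd(fst)^2 / length(fst) + attr(thr, "se")^2)
  expect_lt(abs(mean(fst) - as.numeric(thr)), 4 * se)
  # the genotype-level plug-in estimate carries an O(1/n) upward bias:
  # present, but bounded at this sample size
  fit <- fst_fit(sim$genotypes, sim$labels, keep_matrices = FALSE)
  expect_gt(fit$fst, as.numeric(thr))
  expect_lt(fit$fst - as.numeric(thr), 0.025)
})
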