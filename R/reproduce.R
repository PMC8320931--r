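#' Run a named simulation experiment
#'
#' Named presets encoding the package's reference simulation studies. Each
#' preset simulates under the F-model, runs the spectral analysis and returns
#' the summary quantities; all randomness derives from `seed`.
#'
#' Presets:
#' \describe{
#' \item{`fig1`}{Three populations, `F = (5, 10, 30)%`, `p_anc ~ Beta(1, 4)`,
#'   `n_k = 100` haploids, 10,000 loci simulated, monomorphic removed. Returns
#'   mean F_ST, the scaled-PCA ladder, between/within eigenvalues and the
#'   separation verdict.}
#' \item{`fig2`}{The `fig1` dataset re-analysed with populations 2 and 3
#'   merged (K = 2, 200 vs 100).}
#' \item{`fig3`}{`reps` two-population models (n = 100) with equal drift
#'   coefficients drawn in `[0.01, 0.75]` and first-population proportion in
#'   `[0.1, 0.5]`; compares leading eigenvalues with mean D_ST/2 and mean
#'   F_ST and the second eigenvalues with their RMT predictions.}
#' \item{`fig4a`}{Two populations, `F = 7%`, `Beta(1, 9)`, 100+100 haploids,
#'   100,000 loci simulated. Returns the eigenvalue ladder, mean F_ST, RMT
#'   prediction for the second eigenvalue, and the KS distance of the
#'   residual spectrum to the Marchenko-Pastur law.}
#' \item{`fig4c`}{As `fig4a` with 20+20 haploids and 15,000 simulated loci.}
#' \item{`s2`}{`reps` single-population datasets (`F = 15%`, `Beta(1, 9)`;
#'   `n = 100`, 15,400 simulated loci, about 10,000 polymorphic — or
#'   `n = 10`, 2,500 simulated, about 1,000 polymorphic, with
#'   `small = TRUE`), each split into two artificial groups by the sign of
#'   PC1. Returns the average split F_ST and the fraction of replicates in
#'   which the separation condition is (erroneously) verified.}
#' \item{`s5`}{Two-population models, `n = 150`, `F = 2%`, `Beta(1, 4)`;
#'   `reps` replicates at each of `n_L` locus counts log-spaced in
#'   `[1e3, 1e5]`. Returns the slope of log |mean F_ST - leading eigenvalue|
#'   on log L.}
#' \item{`s6`}{`reps` two-population models with `F = 10%`, `Beta(1, 4)`,
#'   100 simulated loci and 5+5 haploids. Returns the fraction of replicates
#'   verifying the separation condition.}
#' }
#'
#' @param experiment preset name.
#' @param seed integer seed.
#' @param reps replicate count for the replicated presets (defaults: fig3 50,
#'   s2 200, s5 3 per locus count, s6 200).
#' @param small for `s2`: use the small design (n = 10, about 1,000 loci).
#' @return A named list of results; always contains `seed` and `config`.
#' @export
reproduce_experiment <- function(experiment = c("fig1", "fig2", "fig3",
                                                "fig4a", "fig4c", "s2",
                                                "s5", "s6"),
                                 seed = 1, reps = NULL, small = FALSE) {
  experiment <- match.arg(experiment)
  switch(experiment,
         fig1 = exp_fig1(seed, merged = FALSE),
         fig2 = exp_fig1(seed, merged = TRUE),
         fig3 = exp_fig3(seed, reps %||% 50),
         fig4a = exp_fig4(seed, n_k = c(100, 100), L = 100000),
         fig4c = exp_fig4(seed, n_k = c(20, 20), L = 15000),
         s2 = exp_s2(seed, reps %||% 200, small),
         s5 = exp_s5(seed, reps %||% 3),
         s6 = exp_s6(seed, reps %||% 200))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

exp_fig1 <- function(seed, merged) {
  params <- fmodel_params(K = 3, F = c(0.05, 0.10, 0.30), a = 1, b = 4,
                          n_k = 100, L = 10000)
  sim <- simulate_fmodel(params, seed)
  a <- sim$labels
  if (merged) {
    lab <- ifelse(as.character(a$labels) == "pop1", "pop1", "pop23")
    a <- pop_assignment(lab, names(a$labels))
  }
  fit <- fst_fit(sim$genotypes, a, keep_matrices = FALSE)
  list(seed = seed,
       config = list(experiment = if (merged) "fig2" else "fig1",
                     params = unclass(params), merged = merged),
       L_retained = fit$L_eff,
       mean_fst = fit$fst, mean_dst = fit$dst,
       pca_eigenvalues = utils::head(fit$rho2_full, 5),
       between_eigenvalues = fit$rho2_between,
       leading_within = fit$rho2_within[1],
       fst_pca = fit$fst_pca,
       separation_verified = fit$separation$verified,
       separation_margin = fit$separation$margin)
}

exp_fig3 <- function(seed, reps) {
  set.seed(seed)
  res <- t(vapply(seq_len(reps), function(i) {
    F <- stats::runif(1, 0.01, 0.75)
    c1 <- stats::runif(1, 0.1, 0.5)
    n1 <- max(1, round(100 * c1))
    params <- fmodel_params(K = 2, F = c(F, F), a = 1, b = 4,
                            n_k = c(n1, 100 - n1), L = 10000)
    sim <- simulate_fmodel(params, sample.int(.Machine$integer.max, 1))
    fit <- fst_fit(sim$genotypes, sim$labels, keep_matrices = FALSE)
    c(F = F, c1 = c1,
      mean_dst_half = fit$dst / 2, sigma2_1 = fit$sigma2_full[1],
      mean_fst = fit$fst, rho2_1 = fit$rho2_full[1],
      rho2_2 = fit$rho2_full[2],
      rmt_scaled = fit$rmt$predicted_within_scaled,
      sigma2_2 = fit$sigma2_full[2],
      rmt_unscaled = fit$rmt$predicted_within_unscaled,
      expected_dst = expected_dst(params),
      separation = fit$separation$verified)
  }, numeric(12)))
  list(seed = seed, config = list(experiment = "fig3", reps = reps),
       replicates = as.data.frame(res),
       slope_fst = unname(stats::coef(stats::lm(rho2_1 ~ mean_fst,
                                                data = as.data.frame(res)))[2]),
       slope_dst = unname(stats::coef(stats::lm(sigma2_1 ~ mean_dst_half,
                                                data = as.data.frame(res)))[2]))
}

exp_fig4 <- function(seed, n_k, L) {
  params <- fmodel_params(K = 2, F = c(0.07, 0.07), a = 1, b = 9,
                          n_k = n_k, L = L)
  sim <- simulate_fmodel(params, seed)
  fit <- fst_fit(sim$genotypes, sim$labels, keep_matrices = FALSE)
  n <- fit$n; K <- fit$K
  law <- mp_law(n - K, fit$L_eff, scale = 1 - fit$fst)
  resev <- fit$rho2_within[seq_len(n - K)] *
    divisor_value(n, fit$divisor) / (n - K)
  ks <- mp_fit(resev, law)
  list(seed = seed,
       config = list(experiment = "fig4", params = unclass(params)),
       L_retained = fit$L_eff,
       mean_fst = fit$fst,
       pca_eigenvalues = utils::head(fit$rho2_full, 5),
       ev1 = fit$rho2_full[1], ev2 = fit$rho2_full[2],
       rmt_prediction = fit$rmt$predicted_within_scaled,
       ks_distance = ks,
       separation_verified = fit$separation$verified)
}

# single-population models split on the sign of PC1
exp_s2 <- function(seed, reps, small) {
  n <- if (small) 10 else 100
  L_sim <- if (small) 2500 else 15400
  params <- fmodel_params(K = 1, F = 0.15, a = 1, b = 9, n_k = n, L = L_sim)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, reps)
  res <- t(vapply(seq_len(reps), function(i) {
    sim <- simulate_fmodel(params, seeds[i])
    g <- sim$genotypes
    X <- g$values
    P <- colMeans(X)
    Zsc <- sweep(sweep(X, 2, P), 2, sqrt(P * (1 - P)), "/")
    u <- eigen(tcrossprod(Zsc), symmetric = TRUE)$vectors[, 1]
    grp <- ifelse(u > 0, "g1", "g2")
    if (length(unique(grp)) < 2) return(c(NA_real_, NA_real_, NA_real_))
    a <- pop_assignment(grp, sample_ids(g))
    fit <- fst_fit(g, a, keep_matrices = FALSE)
    c(fit$fst, as.numeric(fit$separation$verified), fit$L_eff)
  }, numeric(3)))
  ok <- stats::complete.cases(res)
  list(seed = seed,
       config = list(experiment = "s2", n = n, L_sim = L_sim, reps = reps),
       mean_split_fst = mean(res[ok, 1]),
       separation_rate = mean(res[ok, 2]),
       mean_L_retained = mean(res[ok, 3]),
       reps_used = sum(ok))
}

exp_s5 <- function(seed, reps, n_L = 8) {
  Ls <- round(10^seq(3, 5, length.out = n_L))
  set.seed(seed)
  rows <- list()
  for (L in Ls) for (r in seq_len(reps)) {
    params <- fmodel_params(K = 2, F = c(0.02, 0.02), a = 1, b = 4,
                            n_k = c(75, 75), L = L)
    sim <- simulate_fmodel(params, sample.int(.Machine$integer.max, 1))
    fit <- fst_fit(sim$genotypes, sim$labels, keep_matrices = FALSE)
    rows[[length(rows) + 1]] <- c(L = fit$L_eff,
                                  err = abs(fit$fst - fit$rho2_full[1]))
  }
  d <- as.data.frame(do.call(rbind, rows))
  slope <- unname(stats::coef(stats::lm(log(err) ~ log(L), data = d))[2])
  list(seed = seed,
       config = list(experiment = "s5", L_grid = Ls, reps = reps),
       errors = d, slope = slope)
}

exp_s6 <- function(seed, reps) {
  params <- fmodel_params(K = 2, F = c(0.10, 0.10), a = 1, b = 4,
                          n_k = c(5, 5), L = 100)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, reps)
  ver <- vapply(seq_len(reps), function(i) {
    sim <- simulate_fmodel(params, seeds[i])
    if (n_loci(sim$genotypes) < 2) return(NA)
    fit <- fst_fit(sim$genotypes, sim$labels, keep_matrices = FALSE)
    fit$separation$verified
  }, logical(1))
  list(seed = seed, config = list(experiment = "s6", reps = reps),
       separation_rate = mean(ver, na.rm = TRUE),
       reps_used = sum(!is.na(ver)))
}
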