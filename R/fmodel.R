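#' F-model parameters
#'
#' The F-model describes `K` discrete populations diverging from an ancestral
#' gene pool. Per locus, the ancestral derived-allele frequency is drawn
#' `p_anc ~ Beta(a, b)`; conditional on it, population `k`'s frequency is
#' `p_k ~ Beta(p_anc (1 - F_k)/F_k, (1 - p_anc)(1 - F_k)/F_k)` (variance
#' `F_k p_anc (1 - p_anc)`), and haploid genotypes are Bernoulli draws.
#' `F_k = 0` means no drift (`p_k = p_anc`).
#'
#' @param K number of populations (`>= 1`).
#' @param F drift coefficients in `[0, 1)`, recycled to length `K`.
#' @param a,b ancestral Beta shape parameters (`> 0`).
#' @param n_k haploid sample sizes per population, recycled to length `K`.
#' @param L number of loci to simulate (before any filtering).
#' @param drop_monomorphic remove loci monomorphic in the simulated total
#'   sample (default `TRUE`, matching the scaled analyses).
#' @return An object of class `fmodel_params`.
#' @examples
#' p <- fmodel_params(K = 3, F = c(0.05, 0.10, 0.30), a = 1, b = 4,
#'                    n_k = 100, L = 1000)
#' expected_dst(p)
#' @export
fmodel_params <- function(K, F, a = 1, b = 1, n_k, L,
                          drop_monomorphic = TRUE) {
  if (K < 1) stop("K must be >= 1")
  F <- rep_len(as.numeric(F), K)
  n_k <- rep_len(as.integer(n_k), K)
  if (any(F < 0 | F >= 1)) stop("drift coefficients must lie in [0, 1)")
  if (a <= 0 || b <= 0) stop("Beta shape parameters must be positive")
  if (any(n_k < 1) || sum(n_k) < 2) stop("need n_k >= 1 and total n >= 2")
  if (L < 1) stop("L must be >= 1")
  structure(list(K = K, F = F, a = a, b = b, n_k = n_k, L = as.integer(L),
                 n = sum(n_k), c_k = n_k / sum(n_k),
                 drop_monomorphic = drop_monomorphic),
            class = "fmodel_params")
}

#' @export
print.fmodel_params <- function(x, ...) {
  cat(sprintf("F-model: K = %d, F = (%s), p_anc ~ Beta(%g, %g), n_k = (%s), L = %d\n",
              x$K, paste(format(x$F), collapse = ", "), x$a, x$b,
              paste(x$n_k, collapse = ", "), x$L))
  invisible(x)
}

# guard against numerically degenerate Beta shapes
clamp01 <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1 - eps)

#' Simulate a genotype matrix under the F-model
#'
#' Draws ancestral frequencies, population frequencies and Bernoulli haploid
#' genotypes per the model in [fmodel_params()]. Fully reproducible from the
#' seed. When `drop_monomorphic` is set, loci with total-sample frequency 0
#' or 1 are removed and the pre-filter count recorded.
#'
#' @param params an `fmodel_params`.
#' @param seed integer seed.
#' @return An object of class `fmodel_sim`: list with `genotypes` (haploid
#'   `genotype_matrix`), `labels` (`pop_assignment`, populations `pop1..popK`),
#'   `p_true` (K x L population frequencies, retained loci), `p_anc`
#'   (retained loci), `seed`, `L_before_filter`.
#' @export
simulate_fmodel <- function(params, seed) {
  stopifnot(inherits(params, "fmodel_params"))
  set.seed(seed)
  L <- params$L; K <- params$K
  p_anc <- clamp01(stats::rbeta(L, params$a, params$b))
  p <- matrix(0, K, L)
  for (k in seq_len(K)) {
    Fk <- params$F[k]
    p[k, ] <- if (Fk > 0)
      stats::rbeta(L, p_anc * (1 - Fk) / Fk, (1 - p_anc) * (1 - Fk) / Fk)
    else p_anc
  }
  n <- params$n
  X <- matrix(0L, n, L)
  row0 <- cumsum(c(0L, params$n_k))
  for (k in seq_len(K)) {
    nk <- params$n_k[k]
    X[(row0[k] + 1):row0[k + 1], ] <-
      matrix(stats::rbinom(nk * L, 1L, rep(p[k, ], each = nk)), nk, L)
  }
  keep <- rep(TRUE, L)
  if (params$drop_monomorphic) {
    P <- colMeans(X)
    keep <- P > 0 & P < 1
  }
  ids <- paste0("ind_", seq_len(n))
  g <- genotype_matrix(X[, keep, drop = FALSE], ids,
                       paste0("locus_", which(keep)), ploidy = 1)
  labels <- pop_assignment(rep(paste0("pop", seq_len(K)), params$n_k), ids)
  structure(list(genotypes = g, labels = labels,
                 p_true = p[, keep, drop = FALSE],
                 p_anc = p_anc[keep], seed = seed, L_before_filter = L),
            class = "fmodel_sim")
}

#' @export
print.fmodel_sim <- function(x, ...) {
  cat(sprintf("F-model simulation (seed %d): %d haploid samples, %d/%d loci retained\n",
              x$seed, n_samples(x$genotypes), n_loci(x$genotypes),
              x$L_before_filter))
  invisible(x)
}

#' @rdname simulate_fmodel
#' @param object an `fmodel_params`.
#' @param nsim number of datasets.
#' @param ... unused.
#' @return `simulate()`: a list of `nsim` `fmodel_sim` objects.
#' @export
simulate.fmodel_params <- function(object, nsim = 1, seed = 1, ...) {
  lapply(seq_len(nsim) - 1L, function(i) simulate_fmodel(object, seed + i))
}

#' Closed-form F-model expectations
#'
#' `expected_ha()` is the expected ancestral heterozygosity
#' `E[H_A] = 2ab / ((a+b)(a+b+1))`. `expected_dst()` is the expected
#' among-population diversity `E[D_ST] = E[H_A] sum_k c_k (1 - c_k) F_k`.
#'
#' @param a,b ancestral Beta shapes.
#' @return A fraction.
#' @examples
#' expected_ha(1, 1)  # 1/3
#' @export
expected_ha <- function(a, b) {
  if (a <= 0 || b <= 0) stop("Beta shape parameters must be positive")
  2 * a * b / ((a + b) * (a + b + 1))
}

#' @rdname expected_ha
#' @param params an `fmodel_params`.
#' @export
expected_dst <- function(params) {
  stopifnot(inherits(params, "fmodel_params"))
  expected_ha(params$a, params$b) *
    sum(params$c_k * (1 - params$c_k) * params$F)
}

#' Monte-Carlo expectation of mean F_ST under the F-model
#'
#' The infinite-sample mean F_ST: the average over locus draws of
#' `(H_T - H_S) / H_T` computed from population frequencies with weights
#' `c_k` (no genotype sampling). Returned with its Monte-Carlo standard
#' error.
#'
#' @param params an `fmodel_params`.
#' @param ndraws number of locus draws (`>= 1e5` recommended for a standard
#'   error below 0.05 percentage points at typical parameter values).
#' @param seed integer seed.
#' @return The expectation, with attribute `se`.
#' @export
expected_fst_mc <- function(params, ndraws = 1e5, seed = 1) {
  stopifnot(inherits(params, "fmodel_params"))
  set.seed(seed)
  p_anc <- clamp01(stats::rbeta(ndraws, params$a, params$b))
  HS <- numeric(ndraws); P <- numeric(ndraws)
  p <- matrix(0, ndraws, params$K)
  for (k in seq_len(params$K)) {
    Fk <- params$F[k]
    p[, k] <- if (Fk > 0)
      stats::rbeta(ndraws, p_anc * (1 - Fk) / Fk, (1 - p_anc) * (1 - Fk) / Fk)
    else p_anc
  }
  P <- as.vector(p %*% params$c_k)
  HS <- 2 * as.vector((p * (1 - p)) %*% params$c_k)
  HT <- 2 * P * (1 - P)
  ok <- HT > 0
  fst <- (HT[ok] - HS[ok]) / HT[ok]
  structure(mean(fst), se = stats::sd(fst) / sqrt(length(fst)))
}

#' Theoretical between-population covariance matrix (Lambda)
#'
#' Monte-Carlo estimate of the K x K matrix
#' `Lambda[j, k] = sqrt(c_j c_k) E[(p_j - P)(p_k - P)]` over locus draws
#' (population frequencies only). Its off-diagonal entries are the drift
#' statistic F3 (times the weight), diagonal entries F2; twice the sum of its
#' eigenvalues equals `E[D_ST]`.
#'
#' @param params an `fmodel_params`.
#' @param ndraws number of locus draws (`>= 1e4` recommended).
#' @param seed integer seed.
#' @return List with `Lambda`, per-entry standard errors `se`, and
#'   `eigenvalues` (decreasing).
#' @export
lambda_matrix <- function(params, ndraws = 1e4, seed = 1) {
  stopifnot(inherits(params, "fmodel_params"))
  set.seed(seed)
  p_anc <- clamp01(stats::rbeta(ndraws, params$a, params$b))
  p <- matrix(0, ndraws, params$K)
  for (k in seq_len(params$K)) {
    Fk <- params$F[k]
    p[, k] <- if (Fk > 0)
      stats::rbeta(ndraws, p_anc * (1 - Fk) / Fk, (1 - p_anc) * (1 - Fk) / Fk)
    else p_anc
  }
  P <- as.vector(p %*% params$c_k)
  Zc <- sweep(p, 1, P) * rep(sqrt(params$c_k), each = ndraws)
  Lambda <- crossprod(Zc) / ndraws
  # standard error of each mean of products
  se <- matrix(0, params$K, params$K)
  for (j in seq_len(params$K)) for (k in j:params$K) {
    v <- Zc[, j] * Zc[, k]
    se[j, k] <- se[k, j] <- stats::sd(v) / sqrt(ndraws)
  }
  dimnames(Lambda) <- dimnames(se) <-
    list(paste0("pop", seq_len(params$K)), paste0("pop", seq_len(params$K)))
  list(Lambda = Lambda, se = se,
       eigenvalues = sort(eigen(Lambda, symmetric = TRUE,
                                only.values = TRUE)$values,
                          decreasing = TRUE))
}

#' Exact Lambda eigenvalues for three equally sampled populations
#'
#' For `K = 3`, equal sample proportions and uniform ancestral frequencies
#' (`a = b = 1`), the two non-null eigenvalues of the Lambda matrix are
#' \deqn{\lambda_i = (F_1 + F_2 + F_3 \pm
#'   \sqrt{F_1^2+F_2^2+F_3^2 - F_1F_2 - F_2F_3 - F_3F_1}) / 54,}
#' and `E[D_ST] = 2 (lambda_1 + lambda_2)`.
#'
#' @param F1,F2,F3 drift coefficients in `[0, 1)`.
#' @return Numeric vector `c(lambda1, lambda2)`, decreasing.
#' @export
lambda_eigen_k3 <- function(F1, F2, F3) {
  F <- c(F1, F2, F3)
  if (any(F < 0 | F >= 1)) stop("drift coefficients must lie in [0, 1)")
  disc <- sqrt(sum(F^2) - F1 * F2 - F2 * F3 - F3 * F1)
  c((sum(F) + disc) / 54, (sum(F) - disc) / 54)
}
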