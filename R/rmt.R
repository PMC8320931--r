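#' Marchenko-Pastur law on the proportion-of-variance scale
#'
#' The limiting bulk distribution of the eigenvalues of a pure-noise sample
#' correlation structure, expressed on the scale used for PCA scree plots:
#' eigenvalues of `Z Z^T / n_eff` divided by `L`. For aspect ratio
#' `gamma = L / n_eff` the support is
#' `[(1 - sqrt(gamma))^2 / L, (1 + sqrt(gamma))^2 / L]` and the density is
#' proportional to `sqrt((x_M - x)(x - x_m)) / x`, normalized numerically.
#' An optional variance multiplier `scale` shrinks the support (used with
#' `1 - E[F_ST]` for the residual spectrum of a K-population fit).
#'
#' @param n_eff effective sample size (bulk dimension): `n - 1` for a single
#'   population (centering), `n - K` for the residual matrix of a
#'   K-population decomposition.
#' @param L number of loci.
#' @param scale variance multiplier (default 1).
#' @return An object of class `mp_law`: list with `gamma`, `x_m`, `x_M`
#'   (support endpoints, including `scale`), `scale`, `n_eff`, `L`,
#'   `norm_const`.
#' @examples
#' law <- mp_law(99, 10000)
#' mp_density(mean(c(law$x_m, law$x_M)), law)
#' @export
mp_law <- function(n_eff, L, scale = 1) {
  if (n_eff < 2 || L < 1) stop("need n_eff >= 2 and L >= 1")
  if (scale <= 0) stop("'scale' must be positive")
  s <- mp_support(n_eff, L) * scale
  law <- structure(list(gamma = L / n_eff, x_m = s[1], x_M = s[2],
                        scale = scale, n_eff = n_eff, L = L,
                        norm_const = 1),
                   class = "mp_law")
  raw <- stats::integrate(function(x) mp_shape(x, law), law$x_m, law$x_M,
                          rel.tol = 1e-10)$value
  law$norm_const <- 1 / raw
  law
}

# unnormalized density shape
mp_shape <- function(x, law) {
  out <- numeric(length(x))
  inside <- x > law$x_m & x < law$x_M
  xi <- x[inside]
  out[inside] <- sqrt((law$x_M - xi) * (xi - law$x_m)) / xi
  out
}

#' @rdname mp_law
#' @export
mp_support <- function(n_eff, L) {
  if (n_eff < 2 || L < 1) stop("need n_eff >= 2 and L >= 1")
  g <- L / n_eff
  c(x_m = (1 - sqrt(g))^2 / L, x_M = (1 + sqrt(g))^2 / L)
}

#' @rdname mp_law
#' @param x evaluation points (density) .
#' @param law an `mp_law`.
#' @export
mp_density <- function(x, law) {
  stopifnot(inherits(law, "mp_law"))
  law$norm_const * mp_shape(x, law)
}

#' @rdname mp_law
#' @param q quantiles (CDF).
#' @export
mp_cdf <- function(q, law) {
  stopifnot(inherits(law, "mp_law"))
  vapply(q, function(qq) {
    if (qq <= law$x_m) return(0)
    if (qq >= law$x_M) return(1)
    law$norm_const *
      stats::integrate(function(x) mp_shape(x, law), law$x_m, qq,
                       rel.tol = 1e-9)$value
  }, numeric(1))
}

#' @rdname mp_law
#' @param p probabilities (quantile function).
#' @export
mp_quantile <- function(p, law) {
  stopifnot(inherits(law, "mp_law"), all(p >= 0 & p <= 1))
  vapply(p, function(pp) {
    if (pp <= 0) return(law$x_m)
    if (pp >= 1) return(law$x_M)
    stats::uniroot(function(x) mp_cdf(x, law) - pp,
                   lower = law$x_m, upper = law$x_M, tol = 1e-12)$root
  }, numeric(1))
}

#' @export
print.mp_law <- function(x, ...) {
  cat(sprintf("Marchenko-Pastur law: gamma = %.4g (n_eff = %d, L = %d, scale = %.4g)\n",
              x$gamma, x$n_eff, x$L, x$scale))
  cat(sprintf("  support [%.6g, %.6g] on the proportion-of-variance scale\n",
              x$x_m, x$x_M))
  invisible(x)
}

#' RMT threshold for evidence of population structure
#'
#' `theta = (1/sqrt(L) + 1/sqrt(n-1))^2`: the Marchenko-Pastur edge of a
#' structureless sample on the proportion-of-variance scale. A mean F_ST (or
#' a leading eigenvalue) below `theta` carries no evidence of population
#' structure.
#'
#' @param n haploid sample size (`>= 2`).
#' @param L number of loci.
#' @return The threshold value.
#' @export
structure_threshold <- function(n, L) {
  if (n < 2) stop("need n >= 2")
  (1 / sqrt(L) + 1 / sqrt(n - 1))^2
}

#' RMT predictions for the leading residual eigenvalue
#'
#' Under the separation condition, the proportion of variance on the K-th
#' axis of scaled PCA (the leading residual eigenvalue) is approximated by
#' `(1 - mean_fst) * (1/sqrt(L) + 1/sqrt(n-K))^2`; for unscaled PCA the
#' prediction for `sigma_1^2(Z_S)/L` is
#' `mean_HS * (1/sqrt(L) + 1/sqrt(n-K))^2 / 2`.
#'
#' @param n haploid sample size.
#' @param L number of loci.
#' @param K number of populations (`n > K`).
#' @param mean_fst mean per-locus F_ST.
#' @param mean_HS mean per-locus within-population diversity H_S.
#' @return The predicted value.
#' @export
predicted_within_scaled <- function(n, L, K, mean_fst) {
  if (n <= K) stop("need n > K")
  (1 - mean_fst) * (1 / sqrt(L) + 1 / sqrt(n - K))^2
}

#' @rdname predicted_within_scaled
#' @export
predicted_within_unscaled <- function(n, L, K, mean_HS) {
  if (n <= K) stop("need n > K")
  mean_HS * (1 / sqrt(L) + 1 / sqrt(n - K))^2 / 2
}

#' Kolmogorov-Smirnov distance of a residual spectrum to the MP law
#'
#' Sup-norm distance between the empirical CDF of the bulk (residual)
#' eigenvalues and the Marchenko-Pastur CDF — an informal test of whether a
#' K-population model accounts for the structure in the data (the residual
#' spectrum of a correctly specified model is MP-distributed; misspecified
#' grouping leaves structure in the residual and inflates the distance).
#'
#' @param residual_eigenvalues at least 10 bulk eigenvalues on the
#'   proportion-of-variance scale (same divisor as `law$n_eff`).
#' @param law an `mp_law`.
#' @return The KS sup distance.
#' @export
mp_fit <- function(residual_eigenvalues, law) {
  stopifnot(inherits(law, "mp_law"))
  ev <- sort(residual_eigenvalues)
  m <- length(ev)
  if (m < 10) stop("need at least 10 residual eigenvalues")
  cdf <- mp_cdf(ev, law)
  i <- seq_len(m)
  max(pmax(abs(i / m - cdf), abs((i - 1) / m - cdf)))
}
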