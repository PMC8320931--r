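#' Center a covariate matrix
#'
#' Column-centers a numeric sample x variable matrix and drops constant
#' (zero-variance) columns with a warning.
#'
#' @param Y numeric matrix or data frame, samples x variables.
#' @return Centered numeric matrix.
#' @export
center_covariates <- function(Y) {
  Y <- as.matrix(Y)
  storage.mode(Y) <- "double"
  Y <- sweep(Y, 2, colMeans(Y))
  keep <- colSums(Y^2) > 0
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " constant covariate(s): ",
            paste(colnames(Y)[!keep], collapse = ", "))
    Y <- Y[, keep, drop = FALSE]
  }
  Y
}

#' Read a covariate table
#'
#' Tab-separated file with a `sample_id` column followed by numeric columns;
#' returned centered and ordered to the samples of `g`.
#'
#' @param path file path.
#' @param g the `genotype_matrix` the covariates refer to.
#' @export
read_covariates <- function(path, g) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  ids <- as.character(d[[1]])
  miss <- setdiff(sample_ids(g), ids)
  if (length(miss))
    stop("samples missing from covariate file: ", paste(miss, collapse = ", "))
  m <- as.matrix(d[match(sample_ids(g), ids), -1, drop = FALSE])
  rownames(m) <- sample_ids(g)
  center_covariates(m)
}

#' Latent factor regression of genotypes on covariates
#'
#' Fits `Z = Y B^T + W + eps` by alternating minimization of
#' `||Z - Y B^T - W||^2 + ridge ||B||^2`: the ridge update
#' `B^T <- (Y^T Y + ridge I)^{-1} Y^T (Z - W)` alternates with the truncated
#' SVD update of `W` (best rank-`k` approximation of `Z - Y B^T`). The first
#' half-step is the covariate regression on the full `Z` (`W` starts at
#' zero), so covariate effects collinear with the leading principal
#' directions are attributed to `Y` rather than absorbed by the latent
#' factors. The objective is non-increasing; iteration stops when its
#' relative change falls below `tol`.
#'
#' @param Z column-centered numeric matrix, samples x loci.
#' @param Y covariate matrix, samples x variables (centered internally).
#' @param k latent rank, `0 <= k <= n - d`.
#' @param ridge ridge penalty; default `1e-6 * trace(Y^T Y) / d`.
#' @param tol relative objective-change stopping threshold.
#' @param max_iter maximum alternations.
#' @return An object of class `latent_fit`: list with `B` (loci x variables),
#'   `W`, `k`, `ridge`, `objective` (trace), `n_iter`, `converged`, `Y`
#'   (centered).
#' @export
fit_latent_regression <- function(Z, Y, k, ridge = NULL, tol = 1e-8,
                                  max_iter = 500) {
  Z <- as.matrix(Z)
  Y <- center_covariates(Y)
  n <- nrow(Z); d <- ncol(Y)
  if (nrow(Y) != n) stop("Z and Y have different numbers of samples")
  if (d >= n) stop("need fewer covariates than samples")
  if (k < 0 || k > n - d)
    stop("latent rank k must lie in [0, n - d] = [0, ", n - d, "]")
  if (is.null(ridge)) ridge <- 1e-6 * sum(Y^2) / d
  if (ridge < 0) stop("'ridge' must be non-negative")
  YtY <- crossprod(Y)
  A <- YtY + diag(ridge, d)
  if (ridge == 0 && rcond(A) < 1e-12)
    stop("Y^T Y is numerically singular; use a positive ridge")
  rank_trunc <- function(M, k) {
    if (k == 0) return(matrix(0, nrow(M), ncol(M)))
    sv <- svd(M, nu = k, nv = k)
    sv$u %*% (sv$d[seq_len(k)] * t(sv$v))
  }
  W <- matrix(0, n, ncol(Z))
  obj <- numeric(0)
  Bt <- matrix(0, d, ncol(Z))
  for (it in seq_len(max_iter)) {
    Bt <- solve(A, crossprod(Y, Z - W))
    R <- Z - Y %*% Bt
    W <- rank_trunc(R, k)
    o <- sum((R - W)^2) + ridge * sum(Bt^2)
    obj <- c(obj, o)
    if (it > 1 && abs(obj[it - 1] - o) <= tol * max(obj[it - 1], 1e-300))
      break
  }
  structure(list(B = t(Bt), W = W, k = k, ridge = ridge,
                 objective = obj, n_iter = length(obj),
                 converged = length(obj) < max_iter, Y = Y),
            class = "latent_fit")
}

#' @export
print.latent_fit <- function(x, ...) {
  cat(sprintf("latent factor regression: %d covariates, latent rank k = %d, ridge = %.3g\n",
              ncol(x$B), x$k, x$ridge))
  cat(sprintf("  %d iterations, final objective %.6g (%s)\n",
              x$n_iter, x$objective[x$n_iter],
              if (x$converged) "converged" else "max_iter reached"))
  invisible(x)
}

#' Surrogate (adjusted) genotypes
#'
#' Removes the covariate component from the genotype matrix:
#' `Z_adj = Z - Y B^T = W + eps`. The scaled variant re-centers each column
#' and divides by its standard deviation (divisor `n`), the unique scaling
#' under which the adjusted-F_ST / mean-R^2 equivalence is exact; columns
#' with zero adjusted variance are dropped and listed.
#'
#' @param fit a `latent_fit`.
#' @param Z the matrix the fit was computed on.
#' @return An object of class `adjusted_genotypes`: list with `Z_adj`,
#'   `Z_adj_sc`, `dropped_loci` (indices into columns of `Z`).
#' @export
adjusted_genotypes <- function(fit, Z) {
  stopifnot(inherits(fit, "latent_fit"))
  Z <- as.matrix(Z)
  Z_adj <- Z - fit$Y %*% t(fit$B)
  n <- nrow(Z_adj)
  Zc <- sweep(Z_adj, 2, colMeans(Z_adj))
  v <- colMeans(Zc^2)
  drop <- which(v <= .Machine$double.eps * max(v, 1))
  keep <- setdiff(seq_len(ncol(Zc)), drop)
  Z_adj_sc <- sweep(Zc[, keep, drop = FALSE], 2, sqrt(v[keep]), "/")
  structure(list(Z_adj = Z_adj, Z_adj_sc = Z_adj_sc, dropped_loci = drop),
            class = "adjusted_genotypes")
}

#' Adjusted F_ST and its mean-R^2 equivalent
#'
#' `adjusted_fst()` builds the between-population matrix of the scaled
#' adjusted genotypes (population means of each column, repeated within
#' blocks) and returns its squared norm over `n L` — the analogue of the
#' spectral F_ST for surrogate genotypes. `mean_r2()` averages, over loci,
#' the coefficient of determination of the regression of each scaled
#' adjusted column on the population indicators. The two definitions are
#' algebraically equivalent.
#'
#' @param adj an `adjusted_genotypes`.
#' @param a a `pop_assignment` for the rows of the adjusted matrix.
#' @return A fraction; `adjusted_fst` carries the between-matrix eigenvalue
#'   ladder as attribute `eigenvalues`.
#' @export
adjusted_fst <- function(adj, a) {
  stopifnot(inherits(adj, "adjusted_genotypes"), inherits(a, "pop_assignment"))
  M <- adj$Z_adj_sc
  if (a$K < 2) stop("adjusted F_ST requires K >= 2 populations")
  if (length(a$labels) != nrow(M)) stop("labels do not cover the samples")
  n <- nrow(M); L <- ncol(M)
  pm <- rowsum(M, a$labels, reorder = FALSE) / a$n_k
  B <- pm[as.integer(a$labels), , drop = FALSE]  # columns already mean 0
  ev <- pca_eigenvalues(B, "n", how_many = a$K - 1) / L
  structure(sum(ev), eigenvalues = ev)
}

#' @rdname adjusted_fst
#' @export
mean_r2 <- function(adj, a) {
  stopifnot(inherits(adj, "adjusted_genotypes"), inherits(a, "pop_assignment"))
  M <- adj$Z_adj_sc
  if (a$K < 2) stop("mean R^2 requires K >= 2 populations")
  if (length(a$labels) != nrow(M)) stop("labels do not cover the samples")
  n <- nrow(M)
  grand <- colMeans(M)
  pm <- rowsum(M, a$labels, reorder = FALSE) / a$n_k
  bss <- colSums(a$n_k * sweep(pm, 2, grand)^2)
  tss <- colSums(sweep(M, 2, grand)^2)
  mean(bss / tss)
}
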