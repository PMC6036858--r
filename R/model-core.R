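## Core parametrization and likelihood of the joint mean / constant
## covariance model.  The precision matrix K of y | x is written through the
## modified Cholesky decomposition K = C(phi)' D(tau) C(phi), with C unit
## upper triangular (above-diagonal entries -phi_jk) and D = diag(tau),
## tau_j > 0.  Any (phi, tau) in the parameter space then yields a
## symmetric positive-definite K, and the log-likelihood decomposes into a
## sum of per-row terms in phi_j and tau_j.

.TAU_MIN <- 1e-12

#' Construct Cholesky-factor parameters of a precision matrix
#'
#' Bundles the free parameters of the modified Cholesky decomposition
#' \eqn{K = C(\phi)' D(\tau) C(\phi)}: the strictly upper-triangular factor
#' matrix `phi` (entry (j,k), j < k, is the regression coefficient of gene j
#' on gene k in the sequential-regression reading of the decomposition), the
#' positive innovation precisions `tau`, and the logical activity mask that
#' pins inactive entries of `phi` at exactly zero.
#'
#' @param phi m x m numeric matrix; only the strict upper triangle is used.
#' @param tau numeric vector of length m, all entries strictly positive.
#' @param active m x m logical matrix marking active entries of `phi` in its
#'   strict upper triangle.  Defaults to the nonzero pattern of `phi`.
#' @return An object of class `chol_params`.
#' @export
chol_params <- function(phi, tau, active = NULL) {
  m <- length(tau)
  phi <- as.matrix(phi)
  if (!all(dim(phi) == c(m, m)))
    stop("'phi' must be an m x m matrix matching length(tau)")
  if (any(!is.finite(tau)))
    stop("'tau' must be finite")
  bad <- which(tau <= .TAU_MIN)
  if (length(bad))
    stop(sprintf("tau[%d] = %g is not positive (must exceed %g)",
                 bad[1L], tau[bad[1L]], .TAU_MIN))
  up <- upper.tri(phi)
  if (is.null(active)) {
    active <- matrix(FALSE, m, m)
    active[up] <- phi[up] != 0
  }
  active <- active & up
  ## zero out everything outside the active strict upper triangle
  phi[!active] <- 0
  structure(list(phi = phi, tau = as.numeric(tau), active = active, m = m),
            class = "chol_params")
}

#' Build a precision matrix from its modified Cholesky parameters
#'
#' Computes \eqn{K = C' D C} with C unit upper triangular whose (j,k) entry,
#' j < k, is \eqn{-\phi_{jk}}, and D = diag(tau).  The result is symmetric
#' positive definite for every admissible parameter value.
#'
#' @param chol_par a [chol_params()] object.
#' @return m x m symmetric positive-definite matrix.
#' @export
build_precision <- function(chol_par) {
  stopifnot(inherits(chol_par, "chol_params"))
  m <- chol_par$m
  bad <- which(chol_par$tau <= .TAU_MIN)
  if (length(bad))
    stop(sprintf("tau[%d] is not positive", bad[1L]))
  C <- diag(1, m)
  C[chol_par$active] <- -chol_par$phi[chol_par$active]
  K <- crossprod(C, chol_par$tau * C)  # C' D C with D applied as row scaling
  (K + t(K)) / 2
}

#' Assemble an eQTL data set
#'
#' Pairs an N x p genotype matrix with an N x m expression matrix on aligned
#' samples and validates them (equal row counts, N >= 2, no missing values,
#' all finite).  Cross-products of the intercept-augmented genotype matrix
#' are cached for repeated generalized-least-squares solves.
#'
#' @param X N x p numeric genotype matrix (SNPs typically coded 0/1 or 0/1/2).
#' @param Y N x m numeric expression matrix.
#' @param snp_ids,gene_ids,sample_ids optional label vectors; defaults are
#'   taken from dimnames or generated.
#' @return An object of class `jmccm_data` with elements `X`, `Y`, `N`, `p`,
#'   `m` and the label vectors.
#' @export
jmccm_data <- function(X, Y, snp_ids = NULL, gene_ids = NULL,
                       sample_ids = NULL) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (!is.numeric(X) || !is.numeric(Y))
    stop("'X' and 'Y' must be numeric matrices")
  if (nrow(X) != nrow(Y))
    stop(sprintf("sample counts differ: X has %d rows, Y has %d",
                 nrow(X), nrow(Y)))
  if (nrow(X) < 2L)
    stop("at least two samples are required")
  if (anyNA(X) || anyNA(Y) || any(!is.finite(X)) || any(!is.finite(Y)))
    stop("missing or non-finite values in X or Y; impute or drop explicitly")
  N <- nrow(X)
  snp_ids <- snp_ids %||% colnames(X) %||% paste0("snp", seq_len(ncol(X)))
  gene_ids <- gene_ids %||% colnames(Y) %||% paste0("gene", seq_len(ncol(Y)))
  sample_ids <- sample_ids %||% rownames(Y) %||% paste0("s", seq_len(N))
  X1 <- cbind(1, X)
  structure(list(X = X, Y = Y, N = N, p = ncol(X), m = ncol(Y),
                 snp_ids = snp_ids, gene_ids = gene_ids,
                 sample_ids = sample_ids,
                 XtX1 = crossprod(X1),        # (p+1) x (p+1)
                 XtY1 = crossprod(X1, Y)),    # (p+1) x m
            class = "jmccm_data")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct per-response mean-model parameters
#'
#' The mean model of response j regresses y_j on an always-present intercept
#' plus the SNPs in the active set G_j.  `beta[[j]]` holds the intercept
#' followed by the coefficients of `G[[j]]` in order.
#'
#' @param G list of m integer vectors of active SNP column indices (the
#'   intercept is implicit and never listed).
#' @param beta list of m numeric vectors, each of length `1 + length(G[[j]])`.
#' @return An object of class `mean_params` with the total parameter count
#'   `g` (intercepts included).
#' @export
mean_params <- function(G, beta) {
  m <- length(G)
  if (length(beta) != m) stop("'G' and 'beta' must have equal length")
  for (j in seq_len(m)) {
    if (length(beta[[j]]) != 1L + length(G[[j]]))
      stop(sprintf("beta[[%d]] must have length 1 + |G_j|", j))
  }
  structure(list(G = lapply(G, as.integer), beta = beta,
                 g = sum(vapply(G, length, 1L)) + m),
            class = "mean_params")
}

## Fitted means mu(x; beta), N x m.
predict_mean <- function(mean_par, data) {
  M <- matrix(0, data$N, data$m)
  for (j in seq_len(data$m)) {
    b <- mean_par$beta[[j]]
    Gj <- mean_par$G[[j]]
    M[, j] <- b[1L]
    if (length(Gj))
      M[, j] <- M[, j] + data$X[, Gj, drop = FALSE] %*% b[-1L]
  }
  M
}

#' Residual cross-product matrix V(beta)
#'
#' Computes \eqn{V(\beta) = N^{-1} \sum_i (y^i - \mu^i)(y^i - \mu^i)'}, the
#' mean outer product of residuals around the fitted mean.  V is symmetric
#' positive semidefinite; it is the sufficient statistic through which the
#' likelihood depends on the data given beta.
#'
#' @param mean_par a [mean_params()] object.
#' @param data a [jmccm_data()] object.
#' @return m x m symmetric matrix.
#' @export
compute_V <- function(mean_par, data) {
  E <- data$Y - predict_mean(mean_par, data)
  V <- crossprod(E) / data$N
  (V + t(V)) / 2
}

#' Partition the lower principal submatrix of V at row j
#'
#' The lower jth principal submatrix of V is V restricted to indices
#' j, j+1, ..., m.  Returns its (1,1) scalar, its first column below the
#' (1,1) entry, and the remaining block; for j = m the latter two are empty.
#'
#' @param V m x m matrix.
#' @param j row index, 1 <= j <= m.
#' @return list with elements `Vjj` (scalar), `V21` (length m - j vector)
#'   and `V22` ((m-j) x (m-j) matrix).
#' @export
partition_V <- function(V, j) {
  m <- nrow(V)
  if (j < 1L || j > m) stop(sprintf("j = %d out of range 1..%d", j, m))
  idx <- if (j < m) (j + 1L):m else integer(0)
  list(Vjj = V[j, j],
       V21 = V[idx, j],
       V22 = V[idx, idx, drop = FALSE])
}

#' Log-likelihood of the joint model
#'
#' Evaluates \eqn{\ell(\theta) = (N/2)[-m \log 2\pi + \sum_j \log\tau_j
#' - \mathrm{tr}(K V(\beta))]}, the exact Gaussian log-likelihood of the
#' N observations under mean x'beta and precision K(phi, tau).
#'
#' @param theta list with components `mean` ([mean_params()]) and `chol`
#'   ([chol_params()]).
#' @param data a [jmccm_data()] object.
#' @return scalar log-likelihood.
#' @export
log_likelihood <- function(theta, data) {
  V <- compute_V(theta$mean, data)
  loglik_from_V(theta$chol, V, data$N)
}

## Likelihood given the residual cross-product matrix (V carries all data
## dependence once beta is fixed).
loglik_from_V <- function(chol_par, V, N) {
  K <- build_precision(chol_par)
  m <- chol_par$m
  (N / 2) * (-m * log(2 * pi) + sum(log(chol_par$tau)) - sum(K * V))
}

#' Per-row term of the decomposed log-likelihood
#'
#' The modified Cholesky parametrization decomposes the log-likelihood into
#' a sum over rows: \eqn{\ell_j = (N/2)[-\log 2\pi + \log\tau_j -
#' \tau_j(V_{jj} - 2\phi_j'V_{j,21} + \phi_j'V_{j,22}\phi_j)]}.  The total
#' over j = 1..m equals [log_likelihood()].
#'
#' @param j row index.
#' @param chol_par a [chol_params()] object.
#' @param V residual cross-product matrix from [compute_V()].
#' @param N sample count.
#' @return scalar.
#' @export
loglik_row <- function(j, chol_par, V, N) {
  pv <- partition_V(V, j)
  tau_j <- chol_par$tau[j]
  if (tau_j <= .TAU_MIN) stop(sprintf("tau[%d] is not positive", j))
  quad <- pv$Vjj
  if (length(pv$V21)) {
    ph <- chol_par$phi[j, (j + 1L):chol_par$m]
    quad <- quad - 2 * sum(ph * pv$V21) +
      drop(ph %*% pv$V22 %*% ph)
  }
  (N / 2) * (-log(2 * pi) + log(tau_j) - tau_j * quad)
}
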