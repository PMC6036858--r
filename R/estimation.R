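## Closed-form maximum-likelihood estimation given the active sets, and the
## alternating joint estimation loop.  Given K, beta(G) is the generalized
## least-squares solution of the stacked system with weight K (x) I_N; given
## V(beta), each row's (phi_j, tau_j) has a closed form.  Alternating the
## two exact coordinate maximizations drives the likelihood monotonically
## upward.

## Column indices of response j's design within the intercept-augmented
## genotype matrix cbind(1, X).
.design_idx <- function(Gj) c(1L, Gj + 1L)

## Normal-equations matrix X' (K (x) I_N) X of the stacked GLS system,
## assembled block-wise from cached cross-products; never materializes the
## mN x mN weight matrix.
gls_normal_matrix <- function(G, K, data) {
  m <- data$m
  gj <- vapply(G, length, 1L) + 1L
  off <- cumsum(c(0L, gj))
  g <- off[m + 1L]
  A <- matrix(0, g, g)
  idx <- lapply(G, .design_idx)
  ## iterate only the nonzero upper-triangle entries of (sparse) K
  nz <- which(K != 0 & upper.tri(K, diag = TRUE), arr.ind = TRUE)
  for (r in seq_len(nrow(nz))) {
    j <- nz[r, 1L]; k <- nz[r, 2L]
    blk <- K[j, k] * data$XtX1[idx[[j]], idx[[k]], drop = FALSE]
    rows <- (off[j] + 1L):off[j + 1L]
    cols <- (off[k] + 1L):off[k + 1L]
    A[rows, cols] <- blk
    if (k > j) A[cols, rows] <- t(blk)
  }
  list(A = A, off = off, idx = idx)
}

#' Generalized-least-squares estimate of the mean coefficients
#'
#' Solves the stacked normal equations of the joint model for beta(G) with
#' weight matrix K Kronecker I_N, exploiting the Kronecker structure: the
#' (j,k) block of the system is K_jk X(G_j)'X(G_k).  With K = I this
#' decouples into per-response ordinary least squares.
#'
#' @param G list of m active SNP index sets (intercepts implicit).
#' @param K m x m symmetric positive-definite precision matrix.
#' @param data a [jmccm_data()] object.
#' @return A [mean_params()] object.
#' @export
estimate_beta <- function(G, K, data) {
  .estimate_beta_full(G, K, data)$mean
}

## As estimate_beta, but also returns the Cholesky factor of the
## normal-equations matrix and the block offsets (reused for joint Wald
## variances without re-factorizing).
.estimate_beta_full <- function(G, K, data) {
  m <- data$m
  ne <- gls_normal_matrix(G, K, data)
  ## right-hand side: b_j = sum_k K_jk X(G_j)' y_k
  rhs <- unlist(lapply(seq_len(m), function(j) {
    drop(data$XtY1[ne$idx[[j]], , drop = FALSE] %*% K[, j])
  }), use.names = FALSE)
  R <- tryCatch(chol(ne$A), error = function(e)
    stop("singular normal equations; active sets may contain collinear SNPs",
         call. = FALSE))
  bhat <- backsolve(R, backsolve(R, rhs, transpose = TRUE))
  beta <- lapply(seq_len(m), function(j)
    bhat[(ne$off[j] + 1L):ne$off[j + 1L]])
  list(mean = mean_params(G, beta), R = R, off = ne$off)
}

#' Maximum-likelihood Cholesky parameters given V
#'
#' For each row j < m solves the restricted score equations of the per-row
#' likelihood: phi_j over its active entries satisfies
#' V_j22[A,A] phi_j[A] = V_j21[A], inactive entries stay exactly zero, and
#' 1/tau_j = V_jj - 2 phi_j'V_j21 + phi_j'V_j22 phi_j (the Schur complement
#' of the active block); 1/tau_m = V_mm.  With the full active set this is
#' the unrestricted MLE and build_precision() of the result inverts V.
#'
#' @param V m x m symmetric positive (semi)definite matrix from
#'   [compute_V()].
#' @param active m x m logical activity mask for the strict upper triangle
#'   of phi.
#' @param N sample count (unused in the point estimate but kept for
#'   interface symmetry and validation).
#' @return A [chol_params()] object.
#' @export
estimate_phi_tau <- function(V, active, N) {
  m <- nrow(V)
  phi <- matrix(0, m, m)
  tau <- numeric(m)
  for (j in seq_len(m)) {
    if (j < m) {
      act <- which(active[j, (j + 1L):m]) + j  # absolute indices
    } else act <- integer(0)
    sol <- .solve_phi_row(V, j, act)
    if (length(act)) phi[j, act] <- sol$phi_act
    tau[j] <- sol$tau
  }
  chol_params(phi, tau, active = active)
}

## Restricted per-row solve: active set given as absolute column indices
## (> j).  Returns active phi values and tau_j.
.solve_phi_row <- function(V, j, act) {
  if (length(act)) {
    Vaa <- V[act, act, drop = FALSE]
    ph <- tryCatch(solve(Vaa, V[act, j]), error = function(e)
      stop(sprintf("singular restricted V_j22 for row %d", j), call. = FALSE))
    inv_tau <- V[j, j] - 2 * sum(ph * V[act, j]) + drop(ph %*% Vaa %*% ph)
    if (inv_tau <= .TAU_MIN)
      stop(sprintf("non-positive residual variance in row %d (degenerate or collinear responses)", j),
           call. = FALSE)
    list(phi_act = drop(ph), tau = 1 / inv_tau)
  } else {
    if (V[j, j] <= .TAU_MIN)
      stop(sprintf("non-positive residual variance in row %d", j),
           call. = FALSE)
    list(phi_act = numeric(0), tau = 1 / V[j, j])
  }
}

#' Alternating joint estimation of mean and precision parameters
#'
#' Given fixed active sets, alternates the two exact coordinate
#' maximizations -- beta by generalized least squares given K, then
#' (phi, tau) in closed form given V(beta) -- until the relative
#' log-likelihood change drops below `tol` or `max_iter` sweeps are done.
#' Each half-step maximizes the same likelihood exactly, so the recorded
#' log-likelihood sequence is non-decreasing.
#'
#' @param G list of m active SNP index sets.
#' @param active logical activity mask for phi.
#' @param data a [jmccm_data()] object.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum number of alternation sweeps.
#' @param K_init optional starting precision matrix (defaults to the
#'   identity); a warm start from a neighbouring model shortens the sweep
#'   count without changing the fixed point.
#' @return An object of class `jmccm_fit` with elements `mean`, `chol`,
#'   `K_hat`, `V`, `loglik`, `ll_trace`, `n_iter`, `converged`.
#' @export
joint_fit <- function(G, active, data, tol = 1e-6, max_iter = 100L,
                      K_init = NULL) {
  m <- data$m
  K <- K_init %||% diag(1, m)
  ll_old <- -Inf
  ll_trace <- numeric(0)
  converged <- FALSE
  mean_par <- NULL; chol_par <- NULL; V <- NULL
  eb <- NULL
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    eb <- .estimate_beta_full(G, K, data)
    mean_par <- eb$mean
    V <- compute_V(mean_par, data)
    chol_par <- estimate_phi_tau(V, active, data$N)
    K <- build_precision(chol_par)
    ll <- loglik_from_V(chol_par, V, data$N)
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) / (1 + abs(ll)) < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  structure(list(mean = mean_par, chol = chol_par, K_hat = K, V = V,
                 loglik = ll_trace[length(ll_trace)], ll_trace = ll_trace,
                 n_iter = iter, converged = converged, G = G,
                 active = active,
                 beta_R = eb$R, beta_off = eb$off),
            class = "jmccm_fit")
}

#' @export
print.jmccm_fit <- function(x, ...) {
  m <- x$chol$m
  n_phi <- sum(x$active)
  n_beta <- sum(vapply(x$G, length, 1L))
  cat("Joint mean / constant covariance model fit\n")
  cat(sprintf("  genes: %d   active SNP coefficients: %d   active Cholesky factors: %d\n",
              m, n_beta, n_phi))
  cat(sprintf("  log-likelihood: %.4f   iterations: %d   converged: %s\n",
              x$loglik, x$n_iter, x$converged))
  K <- x$K_hat
  links <- sum(K[upper.tri(K)] != 0)
  cat(sprintf("  network links (nonzero off-diagonal precision entries): %d\n",
              links))
  invisible(x)
}
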