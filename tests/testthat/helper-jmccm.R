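# Shared fixtures and independent oracles.  Everything is generated in code
# under fixed seeds; oracles deliberately take the naive route (dense
# Kronecker products, double loops, finite differences, generic optimizers)
# so they stay independent of the implementation they check.

# random Cholesky parameters with a sparse active pattern
rand_chol <- function(m, density = 0.4) {
  phi <- matrix(0, m, m)
  active <- matrix(FALSE, m, m)
  up <- which(upper.tri(phi))
  on <- up[runif(length(up)) < density]
  active[on] <- TRUE
  phi[on] <- runif(length(on), -0.6, 0.6)
  chol_params(phi, tau = runif(m, 0.5, 2), active = active)
}

# random positive-definite residual cross-product matrix
rand_V <- function(m, N = 4 * m) {
  E <- matrix(rnorm(N * m), N, m)
  crossprod(E) / N
}

# small simulated dataset with known structure
rand_data <- function(N, m, p, beta = NULL, K = NULL) {
  X <- matrix(rbinom(N * p, 1, 0.5), N, p)
  if (is.null(beta)) beta <- matrix(0, p, m)
  if (is.null(K)) K <- diag(m)
  Sigma <- solve(K)
  L <- chol((Sigma + t(Sigma)) / 2)
  Y <- X %*% beta + matrix(rnorm(N * m), N, m) %*% L
  jmccm_data(X, Y)
}

# intercept-free zero mean model (residuals = Y)
null_mean <- function(m) mean_params(rep(list(integer(0)), m),
                                     rep(list(0), m))

# multivariate-normal log density via base determinant/solve (independent
# of the package's likelihood path)
dmvnorm_log <- function(y, mu, K) {
  m <- length(y)
  ld <- as.numeric(determinant(K, logarithm = TRUE)$modulus)
  -0.5 * m * log(2 * pi) + 0.5 * ld -
    0.5 * drop(t(y - mu) %*% K %*% (y - mu))
}

# finite-difference score/information oracle for the mean-model Rao
# statistic: profile log-likelihood in the candidate coefficient with the
# nuisance coefficients re-fitted and the error variance fixed at the
# restricted MLE rss0/N.  The profiled objective is exactly quadratic in
# the candidate coefficient, so a wide step keeps the central differences
# exact while staying clear of floating-point cancellation.
fd_rao_mean <- function(X, y, G_j, l, h = 0.05) {
  N <- length(y)
  D0 <- cbind(1, X[, G_j, drop = FALSE])
  rss_at <- function(b) {
    r <- stats::lm.fit(D0, y - b * X[, l])$residuals
    sum(r^2)
  }
  sigma2 <- rss_at(0) / N
  ll <- function(b) -rss_at(b) / (2 * sigma2)
  U <- (ll(h) - ll(-h)) / (2 * h)
  I <- -(ll(h) - 2 * ll(0) + ll(-h)) / h^2
  if (I <= 0) return(0)
  U^2 / I
}

# finite-difference oracle for the factor Rao/Wald statistics: central
# differences of the row log-likelihood in phi_lb alone, tau fixed; the
# row likelihood is quadratic in phi_lb, so a wide step is exact
fd_phi_stat <- function(l, b, chol_par, V, N, at = 0, h = 0.05) {
  ll <- function(v) {
    cp <- chol_par
    cp$phi[l, b] <- v
    cp$active[l, b] <- TRUE
    loglik_row(l, cp, V, N)
  }
  U <- (ll(at + h) - ll(at - h)) / (2 * h)
  I <- -(ll(at + h) - 2 * ll(at) + ll(at - h)) / h^2
  list(U = U, I = I)
}
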