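test_that("estimate_beta with identity weights decouples into per-response OLS", {
  set.seed(21)
  d <- rand_data(30, 3, 4)
  G <- list(c(1L, 3L), 2L, integer(0))
  mp <- estimate_beta(G, diag(3), d)
  for (j in 1:3) {
    D <- cbind(1, d$X[, G[[j]], drop = FALSE])
    ref <- unname(stats::lm.fit(D, d$Y[, j])$coefficients)
    expect_equal(mp$beta[[j]], ref, tolerance = 1e-10)
  }
})

test_that("estimate_beta matches a dense Kronecker-product GLS oracle", {
  set.seed(22)
  N <- 10; m <- 3; p <- 2
  d <- rand_data(N, m, p)
  cp <- rand_chol(m, density = 1)
  K <- build_precision(cp)
  G <- list(1:2, 2L, 1L)
  mp <- estimate_beta(G, K, d)
  # brute force: stack the responses, materialize W = K (x) I_N
  Xblocks <- lapply(G, function(Gj) cbind(1, d$X[, Gj, drop = FALSE]))
  gj <- vapply(Xblocks, ncol, 1L)
  Xbig <- matrix(0, m * N, sum(gj))
  off <- cumsum(c(0, gj))
  for (j in 1:m)
    Xbig[((j - 1) * N + 1):(j * N), (off[j] + 1):off[j + 1]] <- Xblocks[[j]]
  W <- kronecker(K, diag(N))
  bref <- solve(t(Xbig) %*% W %*% Xbig, t(Xbig) %*% W %*% as.vector(d$Y))
  expect_equal(unlist(mp$beta), as.vector(bref), tolerance = 1e-8)
})

test_that("estimate_beta recovers generating coefficients at large N", {
  set.seed(23)
  N <- 2000; m <- 3; p <- 4
  beta <- matrix(0, p, m)
  beta[1, 1] <- 0.8; beta[3, 2] <- -0.6; beta[c(2, 4), 3] <- c(0.5, -0.9)
  d <- rand_data(N, m, p, beta = beta)
  G <- lapply(1:m, function(j) which(beta[, j] != 0))
  mp <- estimate_beta(G, diag(m), d)
  err <- max(abs(unlist(lapply(1:m, function(j)
    mp$beta[[j]][-1] - beta[G[[j]], j]))))
  expect_lt(err, 0.1)
})

test_that("estimate_phi_tau solves the row-wise score equations", {
  # V = I: phi = 0, tau = 1
  all_on <- upper.tri(matrix(0, 3, 3))
  cp <- estimate_phi_tau(diag(3), all_on, 10)
  expect_equal(cp$phi, matrix(0, 3, 3))
  expect_equal(cp$tau, rep(1, 3))

  # m = 2 correlation example
  rho <- 0.3
  V <- matrix(c(1, rho, rho, 1), 2, 2)
  cp <- estimate_phi_tau(V, upper.tri(V), 10)
  expect_equal(cp$phi[1, 2], rho, tolerance = 1e-12)
  expect_equal(cp$tau, c(1 / (1 - rho^2), 1), tolerance = 1e-12)
})

test_that("with the full active set the estimated precision inverts V", {
  set.seed(24)
  for (i in 1:5) {
    m <- sample(3:6, 1)
    V <- rand_V(m)
    cp <- estimate_phi_tau(V, upper.tri(V), 20)
    expect_equal(build_precision(cp), solve(V), tolerance = 1e-8)
  }
})

test_that("restricted estimation keeps inactive factors at exactly zero", {
  set.seed(25)
  V <- rand_V(4)
  act <- matrix(FALSE, 4, 4); act[1, 3] <- TRUE; act[2, 4] <- TRUE
  cp <- estimate_phi_tau(V, act, 20)
  expect_true(all(cp$phi[!act] == 0))
  expect_true(all(cp$phi[act] != 0))
  # the active-coordinate score equations hold exactly
  expect_equal(V[3, 3] * cp$phi[1, 3], V[3, 1], tolerance = 1e-10)
})

test_that("joint_fit with a diagonal precision reduces to per-response OLS", {
  set.seed(26)
  d <- rand_data(40, 3, 2)
  G <- list(1L, 2L, integer(0))
  fit <- joint_fit(G, matrix(FALSE, 3, 3), d)
  expect_true(fit$converged)
  expect_lte(fit$n_iter, 3L)
  ols <- estimate_beta(G, diag(3), d)
  expect_equal(fit$mean$beta, ols$beta, tolerance = 1e-10)
  V <- compute_V(ols, d)
  expect_equal(fit$chol$tau, 1 / diag(V), tolerance = 1e-10)
})

test_that("joint_fit log-likelihood is non-decreasing and hits the MLE", {
  set.seed(27)
  N <- 50; m <- 3; p <- 2
  beta <- matrix(rnorm(p * m, 0, 0.5), p, m)
  cp0 <- rand_chol(m, density = 1)
  d <- rand_data(N, m, p, beta = beta, K = build_precision(cp0))
  G <- rep(list(1:p), m)
  act <- upper.tri(matrix(0, m, m))
  fit <- joint_fit(G, act, d)
  expect_true(fit$converged)
  expect_true(all(diff(fit$ll_trace) >= -1e-8))
  # full-model fixed point: K equals the inverse of V at the fit
  expect_equal(fit$K_hat, solve(fit$V), tolerance = 1e-6)

  # black-box optimizer oracle on the same instance: maximize over
  # (beta, phi, log tau) jointly with BFGS from a neutral start
  nb <- (p + 1) * m
  np <- m * (m - 1) / 2
  up <- which(upper.tri(matrix(0, m, m)))
  obj <- function(par) {
    beta_l <- split(par[1:nb], rep(1:m, each = p + 1))
    phi <- matrix(0, m, m); phi[up] <- par[nb + 1:np]
    tau <- exp(pmin(pmax(par[nb + np + 1:m], -20), 20))
    cp <- chol_params(phi, tau, active = upper.tri(phi))
    -log_likelihood(list(mean = mean_params(G, beta_l), chol = cp), d)
  }
  o <- stats::optim(rep(0, nb + np + m), obj, method = "BFGS",
                    control = list(maxit = 500, reltol = 1e-12))
  expect_equal(fit$loglik, -o$value, tolerance = 1e-4)
})

test_that("full-active-set estimation is equivariant under gene permutation", {
  set.seed(28)
  m <- 4
  d <- rand_data(30, m, 2)
  act <- upper.tri(matrix(0, m, m))
  G <- rep(list(1:2), m)
  K1 <- joint_fit(G, act, d)$K_hat
  perm <- c(3, 1, 4, 2)
  d2 <- jmccm_data(d$X, d$Y[, perm])
  K2 <- joint_fit(G, act, d2)$K_hat
  expect_equal(K2[order(perm), order(perm)], K1, tolerance = 1e-8)
})
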