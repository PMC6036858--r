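test_that("information criteria match their closed forms", {
  expect_equal(gcv(100, 100, 0), 1.0)
  expect_equal(gcv(10, 100, 5), (10 / 100) / (1 - 5 / 100)^2)
  expect_error(gcv(10, 100, 100), "smaller than N")
  # monotone in model size at fixed fit
  g <- 0:10
  expect_true(all(diff(vapply(g, function(k) gcv(10, 100, k), 0)) > 0))

  expect_equal(bic(0, 100, 0), 0)
  expect_equal(bic(-100, 100, 10), 200 + 10 * log(100))
  # a parameter buying less than log(N)/2 log-likelihood raises BIC
  expect_gt(bic(-100 + log(100) / 2 - 0.01, 100, 11), bic(-100, 100, 10))
})

test_that("mean-model Rao statistic matches its finite-difference oracle", {
  set.seed(31)
  for (i in 1:25) {
    N <- 40; p <- 5
    d <- rand_data(N, 2, p,
                   beta = matrix(rnorm(2 * p, 0, 0.4), p, 2))
    G_j <- sort(sample(p, 2))
    l <- sample(setdiff(1:p, G_j), 1)
    got <- rao_mean(d, 1, l, G_j)
    ref <- fd_rao_mean(d$X, d$Y[, 1], G_j, l)
    expect_equal(got, ref, tolerance = 1e-6)
    expect_gte(got, 0)
  }
})

test_that("a candidate uncorrelated with the residuals scores zero", {
  set.seed(32)
  N <- 20
  x <- rnorm(N)
  y <- rnorm(N)
  # orthogonalize the candidate against the centred response exactly
  yc <- y - mean(y)
  x2 <- x - mean(x)
  x2 <- x2 - sum(x2 * yc) / sum(yc^2) * yc
  d <- jmccm_data(cbind(x2, rnorm(N)), cbind(y, rnorm(N)))
  expect_equal(rao_mean(d, 1, 1, integer(0)), 0, tolerance = 1e-16)
})

test_that("the mean-model Wald statistic matches the textbook OLS form", {
  set.seed(33)
  N <- 30
  d <- rand_data(N, 1, 1, beta = matrix(1.2, 1, 1))
  f <- stats::lm(d$Y[, 1] ~ d$X[, 1])
  tval <- summary(f)$coefficients[2, "t value"]
  expect_equal(wald_mean(d, 1, 1, 1L), tval^2, tolerance = 1e-10)
})

test_that("Rao and Wald statistics of the same term agree asymptotically", {
  set.seed(34)
  N <- 5000
  d <- rand_data(N, 1, 1)  # null SNP
  r <- rao_mean(d, 1, 1, integer(0))
  w <- wald_mean(d, 1, 1, 1L)
  expect_gt(w / max(r, 1e-12), 0.8)
  expect_lt(w / max(r, 1e-12), 1.25)
})

test_that("a strong true SNP attains the maximal Rao statistic", {
  set.seed(35)
  N <- 500; p <- 10
  beta <- matrix(0, p, 1); beta[4, 1] <- 1
  d <- rand_data(N, 1, p, beta = beta)
  raos <- vapply(1:p, function(l) rao_mean(d, 1, l, integer(0)), 0)
  expect_equal(which.max(raos), 4L)
})

test_that("factor Rao statistic matches closed forms and finite differences", {
  # m = 2, phi = 0, tau = 1: statistic is N rho^2
  rho <- 0.4; N <- 200
  V <- matrix(c(1, rho, rho, 1), 2, 2)
  cp <- chol_params(matrix(0, 2, 2), c(1, 1 / V[2, 2]),
                    active = matrix(FALSE, 2, 2))
  expect_equal(rao_phi(1, 2, cp, V, N), N * rho^2, tolerance = 1e-10)

  # diagonal V with phi = 0 scores zero
  cp3 <- chol_params(matrix(0, 3, 3), rep(1, 3),
                     active = matrix(FALSE, 3, 3))
  expect_equal(rao_phi(1, 3, cp3, diag(3), 50), 0)

  # finite-difference oracle at restricted estimates
  set.seed(36)
  for (i in 1:25) {
    m <- sample(3:5, 1); N <- 60
    V <- rand_V(m, N)
    act <- matrix(FALSE, m, m)
    l <- sample(m - 1, 1)
    cand <- (l + 1):m
    if (length(cand) > 1 && runif(1) < 0.5)
      act[l, sample(cand, 1)] <- TRUE
    cp <- estimate_phi_tau(V, act, N)
    ok <- cand[!act[l, cand]]
    b <- ok[sample.int(length(ok), 1)]
    fd <- fd_phi_stat(l, b, cp, V, N, at = 0)
    expect_equal(rao_phi(l, b, cp, V, N), fd$U^2 / fd$I, tolerance = 1e-6)
  }
})

test_that("factor Wald statistic matches scalar information and numeric Hessians", {
  set.seed(37)
  # single active factor: information is N tau V_bb
  V <- rand_V(3, 40)
  act <- matrix(FALSE, 3, 3); act[1, 2] <- TRUE
  cp <- estimate_phi_tau(V, act, 40)
  expect_equal(wald_phi(1, 2, cp, V, 40),
               cp$phi[1, 2]^2 * 40 * cp$tau[1] * V[2, 2], tolerance = 1e-10)

  # a zero-valued active factor scores zero
  cp0 <- chol_params(matrix(0, 3, 3), rep(1, 3), active = act)
  expect_equal(wald_phi(1, 2, cp0, V, 40), 0)

  # with several active factors per row, the variance is the diagonal of
  # the inverse restricted information; cross-check with a numeric Hessian
  for (i in 1:25) {
    m <- sample(4:6, 1); N <- 80
    V <- rand_V(m, N)
    act <- matrix(FALSE, m, m)
    l <- 1L
    bs <- sample(2:m, 3)
    act[l, bs] <- TRUE
    cp <- estimate_phi_tau(V, act, N)
    b <- bs[1]
    # numeric observed information over the active row coordinates
    A <- sort(bs)
    H <- matrix(0, 3, 3)
    h <- 0.05  # the row likelihood is quadratic: wide steps are exact
    llv <- function(v) {
      cpp <- cp; cpp$phi[l, A] <- v
      loglik_row(l, cpp, V, N)
    }
    v0 <- cp$phi[l, A]
    for (a in 1:3) for (bb in 1:3) {
      e1 <- e2 <- numeric(3); e1[a] <- h; e2[bb] <- h
      H[a, bb] <- (llv(v0 + e1 + e2) - llv(v0 + e1 - e2) -
                   llv(v0 - e1 + e2) + llv(v0 - e1 - e2)) / (4 * h^2)
    }
    ref <- cp$phi[l, b]^2 / solve(-H)[match(b, A), match(b, A)]
    expect_equal(wald_phi(l, b, cp, V, N), ref, tolerance = 1e-4)
  }
})

test_that("mean-stage selection is conservative under pure noise", {
  set.seed(38)
  hits <- 0L
  for (r in 1:50) {
    d <- rand_data(500, 1, 1)
    s <- select_mean(d)
    if (length(s$G[[1]]) == 0L) hits <- hits + 1L
  }
  expect_gte(hits, 45L)  # intercept-only in at least 90% of null replicates
})

test_that("mean-stage selection recovers planted supports", {
  set.seed(39)
  tpr <- numeric(20)
  for (r in 1:20) {
    sim <- simulate_dataset(scenario(10, 10, 1000, 2 / 10, 3.5 / 10,
                                     seed = 500 + r))
    s <- select_mean(sim$data)
    sup <- sim$truth$support_beta
    hit <- sum(vapply(1:10, function(j) sum(sup[s$G[[j]], j]), 0L))
    tpr[r] <- if (sum(sup) > 0) hit / sum(sup) else 1
  }
  expect_gt(mean(tpr), 0.8)
})

test_that("a zero-variance response yields an intercept-only model without error", {
  set.seed(40)
  X <- matrix(rbinom(40, 1, 0.5), 20, 2)
  Y <- cbind(rep(2, 20), rnorm(20))
  s <- select_mean(jmccm_data(X, Y))
  expect_length(s$G[[1]], 0)
})

test_that("precision-stage selection finds planted correlation structure", {
  # diagonal V: nothing to add
  s <- select_precision(diag(c(1, 2, 3)), 100)
  expect_equal(sum(s$active), 0L)
  expect_equal(build_precision(s$chol), diag(1 / c(1, 2, 3)))

  # m = 2 with strong correlation: the single factor is activated and the
  # BIC drop matches the two-model comparison computed from the row
  # likelihoods directly
  V <- matrix(c(1, 0.6, 0.6, 1), 2, 2)
  N <- 500
  s <- select_precision(V, N)
  expect_true(s$active[1, 2])
  expect_equal(s$chol$phi[1, 2], 0.6, tolerance = 1e-10)
  ll_diag <- sum(vapply(1:2, function(j)
    loglik_row(j, chol_params(matrix(0, 2, 2), 1 / diag(V)), V, N), 0))
  cp_full <- estimate_phi_tau(V, upper.tri(V), N)
  ll_full <- sum(vapply(1:2, function(j) loglik_row(j, cp_full, V, N), 0))
  expect_equal(s$bic, bic(ll_full, N, 1L), tolerance = 1e-8)
  expect_lt(s$bic, bic(ll_diag, N, 0L))
})

test_that("joint-stage deletion removes a planted spurious factor", {
  set.seed(43)
  m <- 4; p <- 2; N <- 1000
  phi <- matrix(0, m, m); phi[1, 2] <- 0.5; phi[3, 4] <- -0.4
  cp <- chol_params(phi, rep(1, m))
  beta <- matrix(0, p, m); beta[1, 1] <- 0.8; beta[2, 3] <- -0.7
  d <- rand_data(N, m, p, beta = beta, K = build_precision(cp))
  G <- list(1L, integer(0), 2L, integer(0))
  act <- cp$active
  act[1, 4] <- TRUE  # spurious factor, truly zero
  fit <- select_joint(d, G, act, selection_config())
  expect_false(fit$active[1, 4])
  expect_true(fit$active[1, 2] && fit$active[3, 4])
  tr <- fit$trace
  expect_true(any(tr$term == "phi[1,4]" & tr$accepted))
})

test_that("joint-stage estimation improves on identity-weighted fitting", {
  set.seed(44)
  m <- 3; p <- 2; N <- 200
  phi <- matrix(0, m, m); phi[1, 2] <- 0.6
  cp <- chol_params(phi, rep(1, m))
  beta <- matrix(0, p, m); beta[1, 1] <- 1
  d <- rand_data(N, m, p, beta = beta, K = build_precision(cp))
  G <- list(1L, integer(0), integer(0))
  fit <- select_joint(d, G, cp$active, selection_config())
  # identity-weight comparison on the same final active sets
  mp <- estimate_beta(fit$G, diag(m), d)
  V <- compute_V(mp, d)
  cpI <- estimate_phi_tau(V, fit$active, N)
  llI <- sum(vapply(1:m, function(j) loglik_row(j, cpI, V, N), 0))
  expect_gte(fit$loglik + 1e-8, llI)
})

test_that("selection is deterministic and stage 3 never adds parameters", {
  sim <- simulate_dataset(scenario(8, 6, 300, 0.25, 0.4, seed = 77))
  f1 <- jmccm(sim$data)
  f2 <- jmccm(sim$data)
  expect_identical(f1$trace, f2$trace)
  expect_identical(f1$K_hat, f2$K_hat)

  s1 <- select_mean(sim$data)
  s2 <- select_precision(s1$V, sim$data$N)
  f3 <- select_joint(sim$data, s1$G, s2$active, selection_config())
  expect_lte(sum(vapply(f3$G, length, 1L)), sum(vapply(s1$G, length, 1L)))
  expect_lte(sum(f3$active), sum(s2$active))
})

test_that("statistics enforce their activity preconditions", {
  set.seed(45)
  d <- rand_data(20, 2, 2)
  expect_error(rao_mean(d, 1, 1, G_j = 1L), "already active")
  expect_error(wald_mean(d, 1, 2, G_j = 1L), "not in the active set")
  V <- rand_V(3)
  act <- matrix(FALSE, 3, 3); act[1, 2] <- TRUE
  cp <- estimate_phi_tau(V, act, 20)
  expect_error(rao_phi(1, 2, cp, V, 20), "already active")
  expect_error(wald_phi(1, 3, cp, V, 20), "not active")
})
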