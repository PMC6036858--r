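## Consecutive stepwise variable selection.  Stage 1 selects SNPs per
## response (Rao score to add, Wald to delete, GCV as criterion, per-response
## ordinary least squares).  Stage 2 selects Cholesky factors of the
## precision matrix on V from stage 1 (Rao add, Wald delete, BIC).  Stage 3
## runs the alternating joint fit and prunes all remaining parameters by
## Wald deletion under BIC.  No parameter is ever added after stage 2.

#' Selection configuration
#'
#' Tuning knobs of the stepwise stages.  `gcv_patience`/`bic_patience` give
#' the number of consecutive non-improving steps tolerated before a stage
#' stops; the returned model is always the criterion minimizer along the
#' whole visited path, so patience > 1 only widens the search.
#'
#' @param max_terms_mean cap on per-response mean-model size including the
#'   intercept; default `min(p + 1, floor(N/2))`, resolved at fit time.
#' @param max_terms_phi cap on the number of active Cholesky factors;
#'   default `m(m-1)/2`.
#' @param gcv_patience,bic_patience consecutive non-improving steps allowed.
#' @param gcv_cost effective degrees of freedom charged per selected SNP in
#'   the GCV denominator (the intercept costs 1); Friedman's
#'   cost-complexity recommendation for adaptively selected terms is about
#'   3, the default here.  Set to 1 for the plain parameter-count GCV.
#' @param tol,max_iter convergence controls passed to [joint_fit()].
#' @param verbose print per-stage progress.
#' @return An object of class `selection_config`.
#' @export
selection_config <- function(max_terms_mean = NULL, max_terms_phi = NULL,
                             gcv_patience = 1L, bic_patience = 1L,
                             gcv_cost = 3, tol = 1e-6, max_iter = 100L,
                             verbose = FALSE) {
  stopifnot(gcv_patience >= 1L, bic_patience >= 1L, gcv_cost >= 1,
            is.null(max_terms_mean) || max_terms_mean >= 1,
            is.null(max_terms_phi) || max_terms_phi >= 1)
  structure(list(max_terms_mean = max_terms_mean,
                 max_terms_phi = max_terms_phi,
                 gcv_patience = as.integer(gcv_patience),
                 bic_patience = as.integer(bic_patience),
                 gcv_cost = gcv_cost,
                 tol = tol, max_iter = as.integer(max_iter),
                 verbose = isTRUE(verbose)),
            class = "selection_config")
}

#' Generalized cross-validation criterion
#'
#' `(rss/N) / (1 - g/N)^2`, penalizing the per-response residual sum of
#' squares by the model size g (intercept included).
#'
#' @param rss residual sum of squares.
#' @param N sample count.
#' @param g number of mean-model terms including the intercept; must be < N.
#' @return scalar criterion (smaller is better).
#' @export
gcv <- function(rss, N, g) {
  if (g >= N) stop("model size g must be smaller than N")
  (rss / N) / (1 - g / N)^2
}

#' Bayesian information criterion
#'
#' `-2 loglik + df log N` (smaller is better).
#'
#' @param loglik log-likelihood of the fitted model.
#' @param N sample count.
#' @param df number of free parameters.
#' @return scalar.
#' @export
bic <- function(loglik, N, df) {
  stopifnot(df >= 0)
  -2 * loglik + df * log(N)
}

## ---- per-response OLS machinery -------------------------------------------

## OLS of y on cbind(1, X[, cur]); returns coefficients, residuals, rss and
## the thin Q factor used to project candidate columns.
.ols <- function(X, y, cur) {
  D <- cbind(1, X[, cur, drop = FALSE])
  qrD <- qr(D)
  if (qrD$rank < ncol(D))
    stop("collinear design in mean-model fit", call. = FALSE)
  cf <- qr.coef(qrD, y)
  r <- qr.resid(qrD, y)
  list(coef = cf, resid = r, rss = sum(r^2), Q = qr.Q(qrD), D = D)
}

## Rao score statistics for all candidate SNPs at once, at the restricted
## MLE of the current model: score s = x'r over sigma2 = rss/N, expected
## information of the candidate after partialling the current design is
## x'Mx / sigma2 with M the residual-projection.  Statistic = s^2/(sigma2 q).
.rao_mean_all <- function(X, cand, Q, r, rss, N) {
  if (!length(cand)) return(numeric(0))
  if (rss <= 1e-12) return(numeric(length(cand)))
  Xc <- X[, cand, drop = FALSE]
  s <- drop(crossprod(Xc, r))
  qfull <- colSums(Xc^2)
  pr <- crossprod(Q, Xc)
  qres <- qfull - colSums(pr^2)
  sigma2 <- rss / N
  out <- numeric(length(cand))
  ok <- qres > 1e-10 * pmax(qfull, 1)
  out[ok] <- s[ok]^2 / (sigma2 * qres[ok])
  out
}

#' Rao score statistic for adding a SNP to a mean model
#'
#' Score statistic for H0: beta_j^l = 0 in the regression of response j on
#' the intercept plus `G_j` and candidate l, evaluated at the restricted MLE
#' (candidate coefficient fixed at zero, error variance at its MLE rss/N).
#' Equals score^2 over the expected information of the candidate after
#' partialling out the current design; asymptotically chi-squared(1) under
#' H0.  A candidate that is constant or collinear with the current design
#' scores 0.
#'
#' @param data a [jmccm_data()] object.
#' @param j response index.
#' @param l candidate SNP index, not in `G_j`.
#' @param G_j current active SNP set of response j.
#' @return non-negative scalar.
#' @export
rao_mean <- function(data, j, l, G_j = integer(0)) {
  if (l %in% G_j) stop("candidate l is already active")
  f <- .ols(data$X, data$Y[, j], G_j)
  .rao_mean_all(data$X, l, f$Q, f$resid, f$rss, data$N)
}

#' Wald statistic of an active SNP coefficient in a mean model
#'
#' `betahat_l^2 / Var(betahat_l)` from the per-response OLS fit of response
#' j on the intercept plus `G_j`, with the variance estimated as
#' `sigma2 (X'X)^{-1}_{ll}`, `sigma2 = rss / (N - g)`.
#'
#' @inheritParams rao_mean
#' @param l active SNP index, member of `G_j`.
#' @return non-negative scalar.
#' @export
wald_mean <- function(data, j, l, G_j) {
  if (!(l %in% G_j)) stop("l is not in the active set")
  f <- .ols(data$X, data$Y[, j], G_j)
  g <- 1L + length(G_j)
  if (data$N <= g) stop("no residual degrees of freedom")
  sigma2 <- f$rss / (data$N - g)
  XtXinv <- tryCatch(solve(crossprod(f$D)), error = function(e)
    stop("ill-conditioned information in Wald statistic", call. = FALSE))
  pos <- 1L + match(l, G_j)
  f$coef[pos]^2 / (sigma2 * XtXinv[pos, pos])
}

## Stepwise SNP selection for one response: forward by maximal Rao under a
## GCV stopping rule, backward from the forward-final model by minimal Wald;
## the returned active set is the GCV minimizer over the whole path.
.select_mean_one <- function(X, y, N, p, cap, patience, j, cost = 3) {
  tr_stage <- character(0); tr_term <- character(0)
  tr_stat <- numeric(0); tr_crit <- numeric(0); tr_acc <- logical(0)
  push <- function(stage, term, stat, crit, acc) {
    tr_stage <<- c(tr_stage, stage); tr_term <<- c(tr_term, term)
    tr_stat <<- c(tr_stat, stat); tr_crit <<- c(tr_crit, crit)
    tr_acc <<- c(tr_acc, acc)
  }
  cur <- integer(0)
  f <- .ols(X, y, cur)
  dfe <- function(k) 1 + cost * k        # effective df: intercept + costed SNPs
  best_gcv <- gcv(f$rss, N, dfe(0L))
  best_G <- cur
  miss <- 0L
  ## forward additions
  while (1L + length(cur) < cap && length(cur) < p && f$rss > 1e-12 &&
         dfe(length(cur) + 1L) < N) {
    cand <- setdiff(seq_len(p), cur)
    rao <- .rao_mean_all(X, cand, f$Q, f$resid, f$rss, N)
    if (!length(rao) || max(rao) <= 0) break
    l <- cand[which.max(rao)]           # ties -> smallest index
    cur <- sort(c(cur, l))
    f <- .ols(X, y, cur)
    gc_new <- gcv(f$rss, N, dfe(length(cur)))
    improved <- gc_new < best_gcv
    push("mean_add", sprintf("beta[%d,%d]", j, l), max(rao), gc_new, improved)
    if (improved) { best_gcv <- gc_new; best_G <- cur; miss <- 0L }
    else miss <- miss + 1L
    if (miss >= patience) break
  }
  ## backward deletions from the forward-final model
  miss <- 0L
  while (length(cur) >= 1L) {
    g <- 1L + length(cur)
    sigma2 <- if (N > g) f$rss / (N - g) else NA_real_
    if (!is.finite(sigma2) || sigma2 <= 0) sigma2 <- .Machine$double.eps
    XtXinv <- solve(crossprod(f$D))
    w <- f$coef[-1L]^2 / (sigma2 * diag(XtXinv)[-1L])
    l <- cur[which.min(w)]              # ties -> smallest index (cur sorted)
    wmin <- min(w)
    cur <- setdiff(cur, l)
    f <- .ols(X, y, cur)
    gc_new <- gcv(f$rss, N, dfe(length(cur)))
    improved <- gc_new < best_gcv
    push("mean_del", sprintf("beta[%d,%d]", j, l), wmin, gc_new, improved)
    if (improved) { best_gcv <- gc_new; best_G <- cur; miss <- 0L }
    else miss <- miss + 1L
    if (miss >= patience) break
  }
  f <- .ols(X, y, best_G)
  list(G = best_G, beta = unname(f$coef), gcv = best_gcv,
       trace = if (length(tr_stage))
         data.frame(stage = tr_stage, term = tr_term, statistic = tr_stat,
                    criterion = tr_crit, accepted = tr_acc,
                    stringsAsFactors = FALSE) else NULL)
}

#' Stage-1 stepwise selection of mean-model SNPs
#'
#' For each response independently: forward additions by maximal Rao score
#' with GCV as the stopping rule, then backward deletions by minimal Wald
#' statistic; the final per-response model is the GCV minimizer along the
#' whole addition + deletion path.  The intercept is always present and is
#' never a deletion candidate.
#'
#' @param data a [jmccm_data()] object.
#' @param config a [selection_config()] object.
#' @return list with `G` (active sets), `mean` ([mean_params()]), `V`
#'   (residual cross-products of the selected fit) and `trace`.
#' @export
select_mean <- function(data, config = selection_config()) {
  cap <- config$max_terms_mean %||% min(data$p + 1L, floor(data$N / 2))
  res <- lapply(seq_len(data$m), function(j)
    .select_mean_one(data$X, data$Y[, j], data$N, data$p, cap,
                     config$gcv_patience, j, cost = config$gcv_cost))
  mp <- mean_params(lapply(res, `[[`, "G"), lapply(res, `[[`, "beta"))
  traces <- Filter(Negate(is.null), lapply(res, `[[`, "trace"))
  list(G = mp$G, mean = mp, V = compute_V(mp, data),
       trace = if (length(traces)) do.call(rbind, traces) else NULL)
}

## ---- Cholesky-factor statistics -------------------------------------------

#' Rao score statistic for adding a Cholesky factor
#'
#' Score statistic for H0: phi_lb = 0 in the row-l likelihood at the current
#' restricted MLE: the score is `U = N tau_l (V_bl - [V_l22 phi_l]_b)` and
#' the expected information `I = N tau_l V_bb`; returns `U^2 / I`.
#'
#' @param l row index (l < b).
#' @param b column candidate, currently inactive.
#' @param chol_par a [chol_params()] object holding the current restricted
#'   estimates.
#' @param V residual cross-product matrix.
#' @param N sample count.
#' @return non-negative scalar.
#' @export
rao_phi <- function(l, b, chol_par, V, N) {
  m <- chol_par$m
  stopifnot(l >= 1, l < b, b <= m)
  if (chol_par$active[l, b]) stop("phi[l,b] is already active")
  idx <- (l + 1L):m
  ph <- chol_par$phi[l, idx]
  U <- N * chol_par$tau[l] *
    (V[b, l] - sum(V[b, idx] * ph))
  I <- N * chol_par$tau[l] * V[b, b]
  if (I <= 0) return(0)
  U^2 / I
}

#' Wald statistic of an active Cholesky factor
#'
#' `phihat_lb^2` divided by the (b,b) entry of the inverse information of
#' the row-l likelihood restricted to the active phi coordinates, i.e.
#' `phihat_lb^2 N tau_l / [(V_l22[A,A])^{-1}]_bb`.
#'
#' @inheritParams rao_phi
#' @param b active column index of row l.
#' @return non-negative scalar.
#' @export
wald_phi <- function(l, b, chol_par, V, N) {
  if (!chol_par$active[l, b]) stop("phi[l,b] is not active")
  A <- which(chol_par$active[l, ])
  Vinv <- tryCatch(solve(V[A, A, drop = FALSE]), error = function(e)
    stop("singular restricted information in Wald statistic", call. = FALSE))
  pos <- match(b, A)
  chol_par$phi[l, b]^2 * N * chol_par$tau[l] / Vinv[pos, pos]
}

## Rao statistics of all inactive candidates in row l at once.
.rao_phi_row <- function(V, phi_row, tau_l, l, m, N, active_row) {
  idx <- (l + 1L):m
  ph <- phi_row[idx]
  U <- N * tau_l * (V[idx, l] - drop(V[idx, idx, drop = FALSE] %*% ph))
  I <- N * tau_l * diag(V)[idx]
  r <- numeric(length(idx))
  ok <- I > 0
  r[ok] <- U[ok]^2 / I[ok]
  r[active_row[idx]] <- -Inf  # active entries are not candidates
  r
}

#' Stage-2 stepwise selection of Cholesky factors
#'
#' Starting from an empty factor set (diagonal precision, tau_j = 1/V_jj),
#' repeatedly activates the inactive factor with the maximal Rao score over
#' all rows, re-solving the affected row's restricted MLE, with BIC
#' (df = number of active factors) as the stopping rule; then deletes
#' factors with minimal Wald statistic from the forward-final set.  Returns
#' the BIC minimizer along the whole path, re-solved on its mask.
#'
#' @param V residual cross-product matrix from the stage-1 fit.
#' @param N sample count.
#' @param config a [selection_config()] object.
#' @return list with `chol` ([chol_params()]), `active`, `bic` and `trace`.
#' @export
select_precision <- function(V, N, config = selection_config()) {
  m <- nrow(V)
  cap <- config$max_terms_phi %||% (m * (m - 1L) / 2L)
  patience <- config$bic_patience
  if (any(diag(V) <= .TAU_MIN))
    stop("zero-variance response; cannot initialize tau")
  active <- matrix(FALSE, m, m)
  phi <- matrix(0, m, m)
  tau <- 1 / diag(V)
  llrow <- (N / 2) * (-log(2 * pi) + log(tau) - 1)  # rows at restricted MLE
  nact <- 0L
  cur_bic <- bic(sum(llrow), N, 0L)
  best <- list(active = active, bic = cur_bic)
  tr_stage <- character(0); tr_term <- character(0)
  tr_stat <- numeric(0); tr_crit <- numeric(0); tr_acc <- logical(0)
  push <- function(stage, term, stat, crit, acc) {
    tr_stage <<- c(tr_stage, stage); tr_term <<- c(tr_term, term)
    tr_stat <<- c(tr_stat, stat); tr_crit <<- c(tr_crit, crit)
    tr_acc <<- c(tr_acc, acc)
  }
  ## cached Rao statistics; S[l, b] for inactive candidates, -Inf otherwise
  S <- matrix(-Inf, m, m)
  for (l in seq_len(m - 1L))
    S[l, (l + 1L):m] <- .rao_phi_row(V, phi[l, ], tau[l], l, m, N, active[l, ])
  resolve_row <- function(l) {
    act <- which(active[l, ])
    sol <- .solve_phi_row(V, l, act)
    phi[l, ] <<- 0
    if (length(act)) phi[l, act] <<- sol$phi_act
    tau[l] <<- sol$tau
    llrow[l] <<- (N / 2) * (-log(2 * pi) + log(sol$tau) - 1)
    S[l, (l + 1L):m] <<- .rao_phi_row(V, phi[l, ], tau[l], l, m, N,
                                      active[l, ])
  }
  ## forward additions
  miss <- 0L
  while (nact < cap && m > 1L) {
    mx <- max(S)
    if (!is.finite(mx) || mx <= 0) break
    hit <- which(S == mx, arr.ind = TRUE)
    hit <- hit[order(hit[, 1L], hit[, 2L]), , drop = FALSE]  # (l,b) lexicographic
    l <- hit[1L, 1L]; b <- hit[1L, 2L]
    active[l, b] <- TRUE; nact <- nact + 1L
    resolve_row(l)
    cur_bic <- bic(sum(llrow), N, nact)
    improved <- cur_bic < best$bic
    push("phi_add", sprintf("phi[%d,%d]", l, b), mx, cur_bic, improved)
    if (improved) { best <- list(active = active, bic = cur_bic); miss <- 0L }
    else miss <- miss + 1L
    if (miss >= patience) break
  }
  ## backward deletions from the forward-final mask
  miss <- 0L
  while (nact > 0L) {
    wbest <- Inf; wl <- 0L; wb <- 0L
    for (l in which(rowSums(active) > 0L)) {
      A <- which(active[l, ])
      Vinv <- solve(V[A, A, drop = FALSE])
      w <- phi[l, A]^2 * N * tau[l] / diag(Vinv)
      k <- which.min(w)
      if (w[k] < wbest) { wbest <- w[k]; wl <- l; wb <- A[k] }
    }
    active[wl, wb] <- FALSE; nact <- nact - 1L
    resolve_row(wl)
    cur_bic <- bic(sum(llrow), N, nact)
    improved <- cur_bic < best$bic
    push("phi_del", sprintf("phi[%d,%d]", wl, wb), wbest, cur_bic, improved)
    if (improved) { best <- list(active = active, bic = cur_bic); miss <- 0L }
    else miss <- miss + 1L
    if (miss >= patience) break
  }
  chol_best <- estimate_phi_tau(V, best$active, N)
  list(chol = chol_best, active = best$active, bic = best$bic,
       trace = if (length(tr_stage))
         data.frame(stage = tr_stage, term = tr_term, statistic = tr_stat,
                    criterion = tr_crit, accepted = tr_acc,
                    stringsAsFactors = FALSE) else NULL)
}

## ---- stage 3: joint estimation with Wald pruning --------------------------

## Wald statistics of all active mean coefficients (intercepts excluded)
## under the joint GLS information X'(K (x) I_N)X.  When the Cholesky
## factor of the normal-equations matrix is already available (from the
## fit's final beta step) it is reused; diag(A^-1) = rowSums((R^-1)^2).
.joint_mean_walds <- function(mean_par, K, data, R = NULL, off = NULL) {
  G <- mean_par$G
  if (is.null(R)) {
    ne <- gls_normal_matrix(G, K, data)
    R <- chol(ne$A)
    off <- ne$off
  }
  dAinv <- diag(chol2inv(R))
  jj <- ll <- ww <- vector("list", length(G))
  for (j in seq_along(G)) {
    Gj <- G[[j]]
    if (!length(Gj)) next
    pos <- off[j] + 1L + seq_along(Gj)  # skip the intercept slot
    jj[[j]] <- rep.int(j, length(Gj))
    ll[[j]] <- Gj
    ww[[j]] <- mean_par$beta[[j]][-1L]^2 / dAinv[pos]
  }
  list(j = unlist(jj), l = unlist(ll), w = unlist(ww))
}

#' Stage-3 joint estimation with secondary Wald deletion
#'
#' Runs the alternating joint fit on the stage-1/stage-2 active sets, then
#' repeatedly deletes the single active parameter (SNP coefficient or
#' Cholesky factor) with the minimal Wald statistic -- mean coefficients
#' under the joint GLS information, factors under the row-likelihood
#' information -- re-fitting jointly after each deletion, with BIC
#' (df = g + number of active factors + m) as the stopping rule.  No
#' parameter is ever added in this stage.  Returns the BIC minimizer along
#' the deletion path, fully re-fitted.
#'
#' @param data a [jmccm_data()] object.
#' @param G stage-1 active SNP sets.
#' @param active stage-2 Cholesky-factor mask.
#' @param config a [selection_config()] object.
#' @return A `jmccm_fit` with `bic` and `trace` fields added.
#' @export
select_joint <- function(data, G, active, config = selection_config()) {
  N <- data$N; m <- data$m
  dfree <- function(G, active)
    sum(vapply(G, length, 1L)) + m + sum(active) + m
  fit <- joint_fit(G, active, data, config$tol, config$max_iter)
  cur_bic <- bic(fit$loglik, N, dfree(G, active))
  best <- list(G = G, active = active, bic = cur_bic)
  tr_term <- character(0); tr_stat <- numeric(0); tr_crit <- numeric(0)
  tr_acc <- logical(0)
  miss <- 0L
  repeat {
    mw <- .joint_mean_walds(fit$mean, fit$K_hat, data,
                            R = fit$beta_R, off = fit$beta_off)
    pj <- pl <- pwv <- NULL
    if (sum(active) > 0L) {
      ## batch the factor Wald statistics per row of phi
      rows <- which(rowSums(active) > 0L)
      pj <- pl <- pwv <- vector("list", length(rows))
      for (i in seq_along(rows)) {
        l <- rows[i]
        A <- which(active[l, ])
        Vinv <- solve(fit$V[A, A, drop = FALSE])
        pj[[i]] <- rep.int(l, length(A)); pl[[i]] <- A
        pwv[[i]] <- fit$chol$phi[l, A]^2 * N * fit$chol$tau[l] / diag(Vinv)
      }
      pj <- unlist(pj); pl <- unlist(pl); pwv <- unlist(pwv)
    }
    n_mean <- length(mw$w)
    wald_all <- c(mw$w, pwv)
    if (!length(wald_all)) break
    k <- which.min(wald_all)            # ties -> mean terms first, then (j,l)
    hit_wald <- wald_all[k]
    if (k <= n_mean) {
      hj <- mw$j[k]; hl <- mw$l[k]
      G[[hj]] <- setdiff(G[[hj]], hl)
      term <- sprintf("beta[%d,%d]", hj, hl)
    } else {
      hj <- pj[k - n_mean]; hl <- pl[k - n_mean]
      active[hj, hl] <- FALSE
      term <- sprintf("phi[%d,%d]", hj, hl)
    }
    fit <- joint_fit(G, active, data, config$tol, config$max_iter,
                     K_init = fit$K_hat)
    cur_bic <- bic(fit$loglik, N, dfree(G, active))
    improved <- cur_bic < best$bic
    tr_term <- c(tr_term, term); tr_stat <- c(tr_stat, hit_wald)
    tr_crit <- c(tr_crit, cur_bic); tr_acc <- c(tr_acc, improved)
    if (improved) { best <- list(G = G, active = active, bic = cur_bic); miss <- 0L }
    else miss <- miss + 1L
    if (miss >= config$bic_patience) break
  }
  out <- joint_fit(best$G, best$active, data, config$tol, config$max_iter,
                   K_init = fit$K_hat)
  out$bic <- bic(out$loglik, N, dfree(best$G, best$active))
  out$trace <- if (length(tr_term))
    data.frame(stage = "joint_del", term = tr_term, statistic = tr_stat,
               criterion = tr_crit, accepted = tr_acc,
               stringsAsFactors = FALSE) else NULL
  out
}

#' Fit the joint mean / constant covariance model with full selection
#'
#' Runs the three consecutive selection stages: per-response stepwise SNP
#' selection (Rao/Wald/GCV), stepwise Cholesky-factor selection on the
#' resulting residual cross-products (Rao/Wald/BIC), and alternating joint
#' estimation with secondary Wald deletion under BIC.
#'
#' @param X N x p genotype matrix, or a [jmccm_data()] object (then `Y` is
#'   ignored).
#' @param Y N x m expression matrix.
#' @param config a [selection_config()] object.
#' @return A `jmccm_fit` with the estimated precision matrix `K_hat`, mean
#'   parameters, log-likelihood, BIC and the full selection trace.
#' @export
jmccm <- function(X, Y = NULL, config = selection_config()) {
  data <- if (inherits(X, "jmccm_data")) X else jmccm_data(X, Y)
  if (config$verbose) message("stage 1: mean-model selection")
  s1 <- select_mean(data, config)
  if (config$verbose) message("stage 2: Cholesky-factor selection")
  s2 <- select_precision(s1$V, data$N, config)
  if (config$verbose) message("stage 3: joint estimation and pruning")
  out <- select_joint(data, s1$G, s2$active, config)
  out$G_stage1 <- s1$G
  out$trace <- do.call(rbind, Filter(Negate(is.null),
                                     list(s1$trace, s2$trace, out$trace)))
  out$gene_ids <- data$gene_ids
  out$snp_ids <- data$snp_ids
  dimnames(out$K_hat) <- list(data$gene_ids, data$gene_ids)
  out
}
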