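## Synthetic sparse-eQTL data generation.  A random sparse precision matrix
## (unit diagonal, row-rescaled off-diagonals, symmetric PD), a sparse
## genotype-effect matrix with magnitudes bounded away from zero, Bernoulli
## genotypes with optional linkage-disequilibrium blocks, and Gaussian
## responses Y | X ~ N(X beta, K^{-1}).  All draws use R's global RNG, so
## callers control reproducibility with set.seed() or a scenario seed.

#' Generate a sparse precision matrix
#'
#' Every off-diagonal entry of a working matrix is made nonzero
#' independently with probability `link_prob`; nonzero entries are drawn
#' uniformly from \[-1,-0.5\] U \[0.5,1\]; each row's off-diagonal entries
#' are divided by 1.5 times their absolute sum; the matrix is symmetrized
#' as (A + A')/2 and the diagonal set to 1.  An unordered pair is therefore
#' linked with probability `1 - (1 - link_prob)^2`.  The construction is
#' re-drawn in the rare event that the result is not positive definite
#' (possible only when one column collects links from many rows).
#'
#' @param m dimension.
#' @param link_prob probability that an off-diagonal entry of the working
#'   matrix is nonzero, typically c1/m.
#' @return list with `K` (m x m symmetric PD, unit diagonal), logical
#'   `support` (symmetric, off-diagonal link pattern) and `d_m`, the
#'   smallest absolute nonzero off-diagonal entry of K (0.5 when K has no
#'   links).
#' @export
generate_precision <- function(m, link_prob) {
  stopifnot(m >= 1, link_prob > 0, link_prob <= 1)
  for (try in seq_len(100L)) {
    A <- matrix(0, m, m)
    off <- which(row(A) != col(A))
    link <- runif(length(off)) < link_prob
    nl <- sum(link)
    if (nl > 0) {
      A[off[link]] <- runif(nl, 0.5, 1) * sample(c(-1, 1), nl, replace = TRUE)
      rs <- rowSums(abs(A))
      pos <- rs > 0
      A[pos, ] <- A[pos, , drop = FALSE] / (1.5 * rs[pos])
    }
    K <- (A + t(A)) / 2
    diag(K) <- 1
    if (min(eigen(K, symmetric = TRUE, only.values = TRUE)$values) > 1e-8) {
      ## support from the realized K: opposite-sign assignments at (i,j)
      ## and (j,i) can cancel exactly in the symmetrization
      support <- K != 0 & !diag(TRUE, m)
      offdiag <- K[upper.tri(K)]
      nz <- abs(offdiag[offdiag != 0])
      return(list(K = K, support = support,
                  d_m = if (length(nz)) min(nz) else 0.5))
    }
  }
  stop("failed to generate a positive-definite precision matrix")
}

#' Generate a sparse genotype-effect matrix
#'
#' A p x m indicator matrix with i.i.d. Bernoulli(`coef_prob`) entries;
#' where the indicator is 1 the coefficient is drawn uniformly from
#' \[d_m, 1\] U \[-1, -d_m\], keeping effect sizes bounded away from zero by
#' the smallest precision-matrix magnitude.
#'
#' @param p,m dimensions (SNPs x genes).
#' @param coef_prob probability of a nonzero coefficient, typically c2/p.
#' @param d_m lower magnitude bound, 0 < d_m < 1.
#' @return list with `beta` (p x m) and logical `support`.
#' @export
generate_beta <- function(p, m, coef_prob, d_m) {
  stopifnot(coef_prob > 0, coef_prob <= 1)
  if (d_m >= 1 || d_m <= 0) stop("'d_m' must lie strictly between 0 and 1")
  ind <- matrix(runif(p * m) < coef_prob, p, m)
  beta <- matrix(0, p, m)
  n1 <- sum(ind)
  if (n1 > 0)
    beta[ind] <- runif(n1, d_m, 1) * sample(c(-1, 1), n1, replace = TRUE)
  list(beta = beta, support = ind)
}

#' Specify linkage-disequilibrium blocks for the genotype generator
#'
#' @param n_blocks number of LD blocks.
#' @param block_size SNPs per block.
#' @param floor required minimum pairwise within-block correlation,
#'   in (0, 1).
#' @return list passed to [generate_genotypes()].
#' @export
ld_spec <- function(n_blocks, block_size, floor = 0.9) {
  stopifnot(n_blocks >= 1, block_size >= 2, floor > 0, floor < 1)
  list(n_blocks = n_blocks, block_size = block_size, floor = floor)
}

#' Generate Bernoulli genotypes, optionally with LD blocks
#'
#' Independent columns are i.i.d. Bernoulli(0.5).  Each LD block draws one
#' anchor Bernoulli(0.5) column and copies it into the block's columns with
#' independent per-entry flips; the flip rate is set so the expected
#' pairwise correlation between block members, (1 - 2 eps)^2, sits halfway
#' between the requested floor and 1.  Realized within-block sample
#' correlations are checked and the block re-drawn until every pair exceeds
#' the floor.  Blocks occupy the leading columns.
#'
#' @param N sample count.
#' @param p SNP count.
#' @param ld optional [ld_spec()].
#' @return N x p matrix of 0/1 genotypes.
#' @export
generate_genotypes <- function(N, p, ld = NULL) {
  X <- matrix(rbinom(N * p, 1L, 0.5), N, p)
  if (is.null(ld)) return(X)
  need <- ld$n_blocks * ld$block_size
  if (need > p) stop("LD blocks do not fit within p SNPs")
  ## member-member correlation is (1-2*eps)^2; target the midpoint of
  ## [floor, 1] to keep the redraw loop short at moderate N
  eps <- (1 - sqrt((1 + ld$floor) / 2)) / 2
  for (bk in seq_len(ld$n_blocks)) {
    cols <- ((bk - 1L) * ld$block_size + 1L):(bk * ld$block_size)
    for (try in seq_len(200L)) {
      anchor <- rbinom(N, 1L, 0.5)
      flips <- matrix(rbinom(N * ld$block_size, 1L, eps), N, ld$block_size)
      blk <- (anchor + flips) %% 2L
      if (N < 2L) { X[, cols] <- blk; break }
      if (any(apply(blk, 2L, stats::sd) == 0)) next
      cors <- stats::cor(blk)
      if (min(cors[upper.tri(cors)]) > ld$floor) { X[, cols] <- blk; break }
      if (try == 200L) stop("could not realize the requested LD correlations")
    }
  }
  X
}

#' Define a simulation scenario
#'
#' @param m,p,N gene, SNP and sample counts.
#' @param link_prob precision-matrix link probability (c1/m).
#' @param coef_prob coefficient probability (c2/p).
#' @param ld optional [ld_spec()].
#' @param seed optional integer seed for full reproducibility.
#' @param name optional label.
#' @return An object of class `jmccm_scenario`.
#' @export
scenario <- function(m, p, N, link_prob, coef_prob, ld = NULL, seed = NULL,
                     name = NULL) {
  stopifnot(m >= 1, p >= 1, N >= 1,
            link_prob > 0, link_prob <= 1, coef_prob > 0, coef_prob <= 1)
  structure(list(name = name %||% sprintf("m%d_p%d", m, p), m = m, p = p,
                 N = N, link_prob = link_prob, coef_prob = coef_prob,
                 ld = ld, seed = seed),
            class = "jmccm_scenario")
}

#' Named scenario presets of the simulation study
#'
#' `model1`..`model6` are the small-scale designs, `model7`..`model9` the
#' large-scale ones (all with link probability c1/m and coefficient
#' probability c2/p as tabulated); `ld500`/`ld1000` add two 5-SNP LD blocks
#' (pairwise correlation > 0.9) alongside 10 independent SNPs at m = p = 20.
#'
#' @param name one of `"model1"`..`"model9"`, `"ld500"`, `"ld1000"`.
#' @param N sample count; required for `model*`, fixed for `ld*`.
#' @param seed optional seed.
#' @return A [scenario()] object.
#' @export
scenario_preset <- function(name, N = NULL, seed = NULL) {
  tab <- list(
    model1 = list(m = 10,  p = 10,  c1 = 2,   c2 = 3.5),
    model2 = list(m = 20,  p = 10,  c1 = 2,   c2 = 3.5),
    model3 = list(m = 40,  p = 10,  c1 = 2,   c2 = 3.5),
    model4 = list(m = 20,  p = 20,  c1 = 2,   c2 = 4),
    model5 = list(m = 30,  p = 30,  c1 = 2,   c2 = 4),
    model6 = list(m = 40,  p = 40,  c1 = 2,   c2 = 4),
    model7 = list(m = 100, p = 100, c1 = 2,   c2 = 3),
    model8 = list(m = 200, p = 200, c1 = 2.5, c2 = 15),
    model9 = list(m = 400, p = 200, c1 = 1.5, c2 = 20))
  if (name %in% c("ld500", "ld1000")) {
    N <- if (name == "ld500") 500L else 1000L
    return(scenario(m = 20, p = 20, N = N, link_prob = 2 / 20,
                    coef_prob = 4 / 20, ld = ld_spec(2L, 5L, 0.9),
                    seed = seed, name = name))
  }
  if (!name %in% names(tab)) stop("unknown scenario preset: ", name)
  if (is.null(N)) stop("'N' is required for preset ", name)
  s <- tab[[name]]
  scenario(m = s$m, p = s$p, N = N, link_prob = s$c1 / s$m,
           coef_prob = s$c2 / s$p, seed = seed, name = name)
}

#' Simulate a data set from a scenario
#'
#' Chains the generators: precision matrix, effect matrix (with `d_m` taken
#' from the realized K), genotypes, then each response row drawn from
#' N(x'beta, K^{-1}).
#'
#' @param scen a [scenario()] object.
#' @return list with `data` ([jmccm_data()]), `truth` (K, beta, supports,
#'   d_m) and the scenario.
#' @export
simulate_dataset <- function(scen) {
  stopifnot(inherits(scen, "jmccm_scenario"))
  if (!is.null(scen$seed)) set.seed(scen$seed)
  gp <- generate_precision(scen$m, scen$link_prob)
  gb <- generate_beta(scen$p, scen$m, scen$coef_prob, gp$d_m)
  X <- generate_genotypes(scen$N, scen$p, scen$ld)
  ## noise ~ N(0, K^{-1}): with K = R'R (Cholesky), z R^{-T}... use
  ## Sigma = K^{-1} and its Cholesky factor L: rows z %*% L, L'L = Sigma
  Sigma <- chol2inv(chol(gp$K))
  L <- chol((Sigma + t(Sigma)) / 2)
  Y <- X %*% gb$beta + matrix(rnorm(scen$N * scen$m), scen$N, scen$m) %*% L
  list(data = jmccm_data(X, Y),
       truth = list(K = gp$K, beta = gb$beta, support_K = gp$support,
                    support_beta = gb$support, d_m = gp$d_m),
       scenario = scen)
}

#' Run replicated simulations and score the fitted networks
#'
#' For each replicate: simulate the scenario, run the full three-stage fit,
#' and score the estimated precision matrix against the generating one
#' (Stein loss, Frobenius distance, specificity, sensitivity, Youden's
#' index) plus the mean-model support recovery (true/false positive rates
#' over SNP coefficients).  Replicate r uses seed `base_seed + r`.
#'
#' @param scen a [scenario()] object (its own seed, if any, is ignored in
#'   favour of per-replicate seeds).
#' @param n_reps number of replicates.
#' @param config a [selection_config()] passed to [jmccm()].
#' @param base_seed integer; replicate r is seeded with `base_seed + r`.
#' @return list with `per_rep` (one row per replicate) and `summary`
#'   (mean and standard error, SD/sqrt(n), of each metric; SEs are NA when
#'   `n_reps` is 1).
#' @export
run_replicates <- function(scen, n_reps, config = selection_config(),
                           base_seed = 0L) {
  stopifnot(n_reps >= 1)
  rows <- vector("list", n_reps)
  fails <- 0L
  for (r in seq_len(n_reps)) {
    s <- scen
    s$seed <- base_seed + r
    res <- tryCatch({
      sim <- simulate_dataset(s)
      fit <- jmccm(sim$data, config = config)
      sc <- score_network(sim$truth$K, fit$K_hat)
      bs <- sim$truth$support_beta
      beta_rates <- function(G) {
        bhat <- matrix(FALSE, s$p, s$m)
        for (j in seq_len(s$m)) bhat[G[[j]], j] <- TRUE
        tp <- sum(bhat & bs); fn <- sum(!bhat & bs)
        fp <- sum(bhat & !bs); tn <- sum(!bhat & !bs)
        c(tpr = if (tp + fn > 0) tp / (tp + fn) else 1,
          fpr = if (fp + tn > 0) fp / (fp + tn) else 0)
      }
      final <- beta_rates(fit$G)
      stage1 <- beta_rates(fit$G_stage1 %||% fit$G)
      data.frame(rep = r, stein = sc$stein, frob = sc$frob, spe = sc$spe,
                 sen = sc$sen, youden = sc$youden,
                 beta_tpr = final[["tpr"]], beta_fpr = final[["fpr"]],
                 beta_tpr_stage1 = stage1[["tpr"]])
    }, error = function(e) {
      warning(sprintf("replicate %d failed: %s", r, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
    if (is.null(res)) fails <- fails + 1L else rows[[r]] <- res
    if (fails > max(1L, 0.1 * n_reps))
      stop("more than 10% of replicates failed; aborting")
  }
  per_rep <- do.call(rbind, Filter(Negate(is.null), rows))
  metrics <- c("stein", "frob", "spe", "sen", "youden", "beta_tpr",
               "beta_fpr", "beta_tpr_stage1")
  n_ok <- nrow(per_rep)
  summary <- data.frame(
    method = "JMCCM", metric = metrics,
    mean = vapply(metrics, function(k) mean(per_rep[[k]]), 0),
    se = vapply(metrics, function(k)
      if (n_ok > 1L) stats::sd(per_rep[[k]]) / sqrt(n_ok) else NA_real_, 0),
    row.names = NULL)
  list(per_rep = per_rep, summary = summary, n_reps = n_ok,
       scenario = scen$name)
}
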