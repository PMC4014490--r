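# The sparse-partitioning mapper: closed-form evidence, the MH sampler over
# partitions, posterior summaries and QTL calling.

# numeric-integration oracle for the null evidence: integrate the
# sigma2-conditional density (intercept profiled out analytically) against
# the scale-free prior
null_evidence_numeric <- function(y) {
  n <- length(y)
  S0 <- sum(y^2) - sum(y)^2 / n
  f <- function(s2) {
    s2^(-1) * (2 * pi * s2)^(-(n - 1) / 2) * n^(-1 / 2) * exp(-S0 / (2 * s2))
  }
  log(stats::integrate(f, 0, Inf, rel.tol = 1e-10)$value)
}

# dense-matrix oracle for an arbitrary state: no Woodbury identity, the
# n x n covariance is formed explicitly and sigma2 integrated numerically
state_evidence_dense <- function(state, y, dat, tau2) {
  n <- length(y)
  X1 <- gxsmap:::.state_design(state, dat)
  V <- diag(n) + tau2 * tcrossprod(X1)
  Vi <- solve(V)
  one <- rep(1, n)
  oVo <- as.numeric(t(one) %*% Vi %*% one)
  oVy <- as.numeric(t(one) %*% Vi %*% y)
  S <- as.numeric(t(y) %*% Vi %*% y) - oVy^2 / oVo
  ldV <- determinant(V)$modulus[1]
  f <- function(s2) {
    exp(-(n - 1) / 2 * log(2 * pi * s2) - 0.5 * ldV - 0.5 * log(oVo) -
          S / (2 * s2) - log(s2))
  }
  log(stats::integrate(f, 0, Inf, rel.tol = 1e-10)$value)
}

test_that("evidence of the empty model matches numeric integration", {
  set.seed(1)
  y <- std(rnorm(100))
  dat <- sp_predictors(matrix(rbinom(200, 2, 0.4), 100, 2))
  expect_equal(sp_log_evidence(list(), y, dat), null_evidence_numeric(y),
               tolerance = 1e-6)
})

test_that("evidence of grouped states matches a dense-matrix oracle", {
  set.seed(2)
  n <- 60
  tp <- toy_predictors(n, 4, seed = 22)
  y <- std(0.5 * tp$G[, 2] + rnorm(n))
  dat <- sp_predictors(tp$G, tp$sex)
  for (state in list(list(2L), list(c(2L, 5L)), list(2L, c(1L, 3L)))) {
    expect_equal(sp_log_evidence(state, y, dat, tau2 = 0.2),
                 state_evidence_dense(state, y, dat, 0.2), tolerance = 1e-6)
  }
})

test_that("evidence is invariant to group listing order", {
  set.seed(3)
  n <- 80
  tp <- toy_predictors(n, 5, seed = 33)
  y <- std(rnorm(n))
  dat <- sp_predictors(tp$G, tp$sex)
  a <- sp_log_evidence(list(c(1L, 2L), 4L), y, dat)
  b <- sp_log_evidence(list(4L, c(2L, 1L)), y, dat)
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("a single-level predictor is handled without error", {
  set.seed(4)
  n <- 50
  G <- cbind(allhet = rep(1L, n), snp = rbinom(n, 2, 0.4))
  y <- std(rnorm(n))
  dat <- sp_predictors(G)
  ev <- sp_log_evidence(list(1L), y, dat)
  expect_true(is.finite(ev))
  # cross-check the redundant-level penalty against the dense oracle
  expect_equal(ev, state_evidence_dense(list(1L), y, dat, 0.2), tolerance = 1e-6)
})

test_that("default schedule retains 1500 samples with integer-count probabilities", {
  set.seed(5)
  tp <- toy_predictors(60, 2, seed = 55)
  y <- std(0.8 * tp$G[, 1] + rnorm(60))
  chain <- sp_mcmc(y, sp_predictors(tp$G, tp$sex), sp_config(seed = 9))
  post <- sp_posterior(chain)
  expect_identical(post$retained_samples, 1500L)
  counts <- post$inclusion * post$retained_samples
  expect_equal(counts, round(counts), tolerance = 1e-9)
  pw <- post$pairwise * post$retained_samples
  expect_equal(pw, round(pw), tolerance = 1e-9)
})

test_that("pairwise probability never exceeds either inclusion", {
  set.seed(6)
  n <- 150
  tp <- toy_predictors(n, 5, seed = 66)
  y <- std(0.4 * tp$G[, 1] + 0.5 * tp$G[, 2] * tp$sex + rnorm(n))
  post <- sp_posterior(sp_mcmc(y, sp_predictors(tp$G, tp$sex),
                               sp_config(iterations = 1000, burn_in = 200, seed = 3)))
  p <- length(post$inclusion)
  for (i in seq_len(p - 1)) {
    for (j in seq(i + 1, p)) {
      expect_lte(post$pairwise[i, j],
                 min(post$inclusion[i], post$inclusion[j]) + 1e-12)
    }
  }
})

test_that("null data keeps all inclusion probabilities below the call threshold", {
  for (s in 1:3) {
    tp <- toy_predictors(200, 20, seed = 700 + s)
    set.seed(s)
    y <- std(rnorm(200))
    post <- sp_posterior(sp_mcmc(y, sp_predictors(tp$G, tp$sex),
                                 sp_config(iterations = 600, burn_in = 150, seed = s)))
    expect_lt(max(post$inclusion), 0.2)
  }
})

test_that("MCMC posteriors approach the exhaustive enumeration", {
  set.seed(8)
  n <- 300
  tp <- toy_predictors(n, 5, seed = 88)
  y <- std(0.5 * tp$G[, 2] + 0.6 * tp$G[, 4] * tp$sex + rnorm(n))
  dat <- sp_predictors(tp$G, tp$sex)      # p = 6 predictors
  cfg <- sp_config(iterations = 15000, burn_in = 2000, seed = 17)
  exact <- sp_enumerate_posterior(y, dat, cfg)
  mc <- sp_posterior(sp_mcmc(y, dat, cfg))
  expect_lt(max(abs(exact$inclusion - mc$inclusion)), 0.05)
  expect_lt(max(abs(exact$pairwise - mc$pairwise)), 0.05)
})

test_that("snp_only mode forbids SEX from interacting", {
  set.seed(9)
  n <- 250
  tp <- toy_predictors(n, 4, seed = 99)
  y <- std(0.8 * tp$G[, 1] * tp$sex + rnorm(n))   # strong GxS signal
  dat <- sp_predictors(tp$G, tp$sex)
  post <- sp_posterior(sp_mcmc(y, dat,
                               sp_config(iterations = 800, burn_in = 200,
                                         interaction_mode = "snp_only", seed = 4)))
  expect_true(all(post$pairwise[, "SEX"] == 0))
  post_none <- sp_posterior(sp_mcmc(y, dat,
                                    sp_config(iterations = 400, burn_in = 100,
                                              interaction_mode = "none", seed = 4)))
  expect_true(all(post_none$pairwise == 0))
})

test_that("sweep transitions are empirically reversible on a frozen instance", {
  set.seed(10)
  n <- 40
  tp <- toy_predictors(n, 3, seed = 110)
  y <- std(0.5 * tp$G[, 1] + rnorm(n))
  dat <- sp_predictors(tp$G[, 1:3])
  cfg <- sp_config(iterations = 30000, burn_in = 1, moves_per_iter = 1, seed = 12)
  chain <- sp_mcmc(y, dat, cfg)
  keys <- vapply(chain$states, gxsmap:::.state_key, character(1))
  trans <- table(from = keys[-length(keys)], to = keys[-1])
  states <- rownames(trans)
  zmax <- 0
  for (i in seq_along(states)) {
    for (j in seq_along(states)) {
      if (i >= j) next
      nab <- trans[i, j]; nba <- trans[j, i]
      if (nab + nba >= 50) {
        zmax <- max(zmax, abs(nab - nba) / sqrt(nab + nba))
      }
    }
  }
  expect_lt(zmax, 5)
})

test_that("identical seeds give identical chains", {
  tp <- toy_predictors(80, 4, seed = 120)
  y <- std(rnorm(80))
  cfg <- sp_config(iterations = 300, burn_in = 50, seed = 77)
  a <- sp_mcmc(y, sp_predictors(tp$G, tp$sex), cfg)
  b <- sp_mcmc(y, sp_predictors(tp$G, tp$sex), cfg)
  expect_identical(a$states, b$states)
  expect_identical(a$log_post, b$log_post)
})

test_that("QTL calling classifies main, GxS and GxG at the threshold", {
  nm <- c("snpA", "snpB", "snpC", "SEX")
  incl <- stats::setNames(c(0.6, 0.53, 0.19, 0.7), nm)
  pw <- matrix(0, 4, 4, dimnames = list(nm, nm))
  pw["snpB", "SEX"] <- pw["SEX", "snpB"] <- 0.53
  pw["snpA", "snpC"] <- pw["snpC", "snpA"] <- 0.19
  post <- structure(list(inclusion = incl, pairwise = pw,
                         retained_samples = 1500L), class = "sp_posterior")
  map <- data.frame(marker = nm[1:3], chrom = c(1, 13, 2), pos_mb = c(30, 27.77, 50))
  maf <- stats::setNames(c(0.3, 0.247, 0.1), nm[1:3])
  calls <- sp_call_qtl(post, map, maf, threshold = 0.2)
  gxs <- calls[calls$class == "GxS", ]
  expect_equal(nrow(gxs), 1L)
  expect_equal(gxs$posterior, 0.53)
  expect_identical(gxs$partner, "SEX")
  expect_false("snpC" %in% calls$snp)          # 0.19 < 0.2 everywhere
  expect_setequal(calls$class, c("main", "GxS"))

  # all-below-threshold posterior yields an empty call set
  post0 <- post
  post0$inclusion[] <- 0.19
  post0$pairwise[] <- 0.19
  expect_equal(nrow(sp_call_qtl(post0, map, maf, threshold = 0.2)), 0L)
  expect_error(sp_call_qtl(post, map[1:2, ], maf), "absent")
})
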