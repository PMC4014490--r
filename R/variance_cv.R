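# Cross-validated GxS variance decomposition.
#
# The contribution of gene-by-sex interactions to a phenotype is measured
# as the difference in out-of-sample percent variance explained between two
# sparse-partitioning configurations: one in which sex may interact with
# SNPs ("all") and one in which sex is a marginal effect only while SNPs
# may still interact with each other ("snp_only").

#' k-fold cross-validation assignment
#'
#' Random partition of `n` individuals into `k` folds whose sizes differ by
#' at most one; deterministic under `seed`.
#'
#' @param n number of individuals (>= k).
#' @param k number of folds (default 10).
#' @param seed integer seed.
#' @return integer vector of fold labels in `1..k`.
#' @export
cv_folds <- function(n, k = 10L, seed = 1L) {
  if (k <= 1) stop("`k` must be > 1", call. = FALSE)
  if (n < k) stop("`n` must be >= `k`", call. = FALSE)
  with_seed(seed, sample(rep_len(seq_len(k), n)))
}

# posterior-mean fit of one state: ridge solution for the joint-level means
# with a flat intercept, plus the lookup tables needed to score new data
.state_fit <- function(state, y, dat, tau2) {
  n <- length(y)
  groups <- list()
  X1 <- NULL
  for (gr in state) {
    code <- dat$levels[[gr[1L]]]
    range <- dat$nlev[gr[1L]]
    for (g in gr[-1L]) {
      code <- code + range * (dat$levels[[g]] - 1L)
      range <- range * dat$nlev[g]
    }
    obs <- sort(unique(code))
    Xg <- matrix(0, n, length(obs))
    Xg[cbind(seq_len(n), match(code, obs))] <- 1
    groups[[length(groups) + 1L]] <- list(members = gr, obs_codes = obs)
    X1 <- if (is.null(X1)) Xg else cbind(X1, Xg)
  }
  if (is.null(X1)) {
    return(list(intercept = mean(y), groups = list(), theta = numeric(0)))
  }
  q <- ncol(X1)
  A <- rbind(
    c(n, colSums(X1)),
    cbind(colSums(X1), crossprod(X1) + diag(q) / tau2)
  )
  rhs <- c(sum(y), as.numeric(crossprod(X1, y)))
  beta <- solve(A, rhs)
  list(intercept = beta[1L], groups = groups, theta = beta[-1L])
}

.state_predict <- function(fit, dat_new) {
  n <- dat_new$n
  pred <- rep(fit$intercept, n)
  off <- 0L
  for (g in fit$groups) {
    gr <- g$members
    code <- dat_new$levels[[gr[1L]]]
    range <- dat_new$nlev[gr[1L]]
    for (gg in gr[-1L]) {
      code <- code + range * (dat_new$levels[[gg]] - 1L)
      range <- range * dat_new$nlev[gg]
    }
    idx <- match(code, g$obs_codes)
    seen <- !is.na(idx)
    pred[seen] <- pred[seen] + fit$theta[off + idx[seen]]
    off <- off + length(g$obs_codes)
  }
  pred
}

#' Model-averaged prediction from a sparse-partitioning chain
#'
#' Averages, over the retained states of the chain, each state's
#' posterior-mean fitted value: joint-level means are shrunk by the
#' conjugate prior (ridge with precision `1/tau2`), the intercept is flat,
#' and joint levels unseen in training contribute nothing (such individuals
#' fall back toward the state's intercept).  States are weighted by their
#' visit frequency in the retained chain.
#'
#' @param chain an `sp_chain` trained on the training individuals only.
#' @param dat_new an [sp_predictors()] object for the individuals to score.
#' @return numeric vector of predictions (on the scale of the training
#'   phenotype).
#' @export
sp_predict <- function(chain, dat_new) {
  stopifnot(inherits(chain, "sp_chain"))
  cfg <- chain$config
  keep <- seq(cfg$burn_in + 1L, cfg$iterations)
  keys <- vapply(chain$states[keep], .state_key, character(1))
  tab <- table(keys)
  first_idx <- keep[match(names(tab), keys)]
  pred <- numeric(dat_new$n)
  for (i in seq_along(tab)) {
    st <- chain$states[[first_idx[i]]]
    fit <- .state_fit(st, chain$y, chain$dat, cfg$tau2)
    pred <- pred + as.numeric(tab[i]) * .state_predict(fit, dat_new)
  }
  pred / length(keep)
}

#' Assemble a cross-validated variance result
#'
#' @param phenotype phenotype label.
#' @param pve_with out-of-sample percent variance explained with GxS
#'   permitted.
#' @param pve_without the same with GxS prohibited (sex marginal only).
#' @param folds optional data.frame of per-fold records.
#' @return object of class `cv_variance_result` with `difference =
#'   pve_with - pve_without`.
#' @export
cv_result <- function(phenotype, pve_with, pve_without, folds = NULL) {
  structure(
    list(phenotype = phenotype, pve_with = pve_with,
         pve_without = pve_without,
         difference = pve_with - pve_without, folds = folds),
    class = "cv_variance_result"
  )
}

#' Cross-validated variance explained with and without GxS
#'
#' Ten-fold (by default) cross-validation of the sparse-partitioning mapper
#' under two configurations differing only in `interaction_mode`:
#' `config_with` permits GxS interactions, `config_without` prohibits them
#' (sex remains available as a marginal effect and SNP-SNP interactions are
#' allowed in both).  For each fold the chain is trained on the other
#' folds' standardized phenotype and scored on the held-out fold; percent
#' variance explained pools squared errors across folds:
#' `pve = 100 * (1 - sum(SSE) / sum(SST))`, with SST taken about the
#' training mean (the intercept-only predictor).  Values can be negative
#' when a configuration predicts worse than the training mean.
#'
#' @param y numeric phenotype vector.
#' @param dat an [sp_predictors()] object for all individuals.
#' @param config_with [sp_config()] with `interaction_mode = "all"`.
#' @param config_without [sp_config()] with `interaction_mode = "snp_only"`;
#'   must otherwise equal `config_with`.
#' @param k number of folds (default 10).
#' @param seed integer seed for the fold assignment and the per-fold chains.
#' @param phenotype label for the result.
#' @return a [cv_result()] with per-fold records.
#' @export
cv_variance_explained <- function(y, dat, config_with = sp_config(interaction_mode = "all"),
                                  config_without = sp_config(interaction_mode = "snp_only"),
                                  k = 10L, seed = 1L, phenotype = NA_character_) {
  stopifnot(inherits(dat, "sp_predictors"))
  a <- config_with; b <- config_without
  a$interaction_mode <- b$interaction_mode <- NULL
  if (!identical(a, b)) {
    stop("configs must be identical apart from `interaction_mode`", call. = FALSE)
  }
  n <- length(y)
  folds <- cv_folds(n, k, seed = child_seed(seed, 11L))

  subset_dat <- function(idx) {
    structure(
      list(levels = lapply(dat$levels, `[`, idx), nlev = dat$nlev,
           names = dat$names, n = length(idx), sex_idx = dat$sex_idx),
      class = "sp_predictors"
    )
  }

  run_cfg <- function(cfg) {
    sse <- sst <- 0
    rec <- vector("list", k)
    skipped <- integer(0)
    for (f in seq_len(k)) {
      te <- which(folds == f)
      tr <- which(folds != f)
      if (stats::var(y[te]) == 0) {
        warning(sprintf("fold %d has zero test variance; skipped", f), call. = FALSE)
        skipped <- c(skipped, f)
        next
      }
      mu_tr <- mean(y[tr]); sd_tr <- stats::sd(y[tr])
      cfg_f <- cfg
      cfg_f$seed <- child_seed(seed, 100L + f)
      chain <- sp_mcmc((y[tr] - mu_tr) / sd_tr, subset_dat(tr), cfg_f)
      pred <- mu_tr + sd_tr * sp_predict(chain, subset_dat(te))
      sse_f <- sum((y[te] - pred)^2)
      sst_f <- sum((y[te] - mu_tr)^2)
      sse <- sse + sse_f
      sst <- sst + sst_f
      rec[[f]] <- data.frame(fold = f, test_mse = sse_f / length(te),
                             test_var = stats::var(y[te]))
    }
    list(pve = 100 * (1 - sse / sst), rec = do.call(rbind, rec))
  }

  with_res <- run_cfg(config_with)
  without_res <- run_cfg(config_without)
  out <- cv_result(phenotype, with_res$pve, without_res$pve,
                   folds = with_res$rec)
  out$folds_without <- without_res$rec
  out
}
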