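# Sparse-partitioning QTL mapper.
#
# A model ("state") is a partition of a small subset of the predictors
# (SNPs, coded as 3-level factors, plus the distinguished predictor SEX)
# into disjoint groups of size 1-3.  Predictors in the same group interact:
# the group contributes one mean parameter per observed joint level of its
# members.  A Metropolis-Hastings chain explores model space; posterior
# inclusion probabilities are fractions of the retained samples.
#
# Likelihood: y | state ~ N(mu * 1 + X1 theta, sigma2 I) with a flat prior
# on mu, theta ~ N(0, tau2 * sigma2 * I) on the joint-level means, and the
# scale-free prior p(sigma2) ~ 1/sigma2.  All three are integrated in
# closed form, so the evidence of any state is exact -- which is what makes
# the exhaustive enumeration cross-check possible for small predictor sets.

SEX_ID <- "SEX"

#' Bundle predictors for the sparse-partitioning mapper
#'
#' @param genotypes n x p SNP matrix coded 0/1/2 (treated as unordered
#'   3-level factors, not dosages).
#' @param sex binary vector (1 = male) or NULL to map without sex.
#' @return object of class `sp_predictors`.
#' @export
sp_predictors <- function(genotypes, sex = NULL) {
  G <- as.matrix(genotypes)
  if (is.null(colnames(G))) colnames(G) <- paste0("snp", seq_len(ncol(G)))
  levels <- lapply(seq_len(ncol(G)), function(j) as.integer(G[, j]) + 1L)
  nlev <- rep(3L, ncol(G))
  nm <- colnames(G)
  if (!is.null(sex)) {
    if (length(sex) != nrow(G)) stop("`sex` must align with genotype rows", call. = FALSE)
    levels <- c(levels, list(as.integer(sex) + 1L))
    nlev <- c(nlev, 2L)
    nm <- c(nm, SEX_ID)
  }
  structure(
    list(levels = levels, nlev = nlev, names = nm, n = nrow(G),
         sex_idx = if (is.null(sex)) NA_integer_ else length(nm)),
    class = "sp_predictors"
  )
}

#' MCMC configuration for sparse partitioning
#'
#' @param iterations total chain length (default 2000).
#' @param burn_in discarded initial iterations (default 500); posterior
#'   probabilities are fractions of `iterations - burn_in` retained samples
#'   (1500 under the defaults).
#' @param max_predictors maximum distinct predictors in a model (default 10).
#' @param max_three_way maximum number of three-member groups (default 2).
#' @param interaction_mode `"all"` (any predictors may co-group),
#'   `"snp_only"` (SEX restricted to singleton groups, i.e. GxS prohibited
#'   while GxG remains allowed) or `"none"` (main effects only).
#' @param tau2 prior variance of a joint-level mean relative to the residual
#'   variance (default 0.2).
#' @param incl_rate prior inclusion rate per predictor; default `2/p` at run
#'   time, putting the expected model size near 2.
#' @param moves_per_iter elementary Metropolis-Hastings proposals per
#'   recorded iteration; default (`NULL`) is the number of predictors, so
#'   one iteration is one full proposal sweep and consecutive recorded
#'   states are decorrelated enough for the short default schedule.
#' @param seed integer RNG seed for the chain.
#' @return object of class `sp_config`.
#' @export
sp_config <- function(iterations = 2000L, burn_in = 500L,
                      max_predictors = 10L, max_three_way = 2L,
                      interaction_mode = c("all", "snp_only", "none"),
                      tau2 = 0.2, incl_rate = NULL,
                      moves_per_iter = NULL, seed = 1L) {
  interaction_mode <- match.arg(interaction_mode)
  if (burn_in >= iterations) stop("`burn_in` must be < `iterations`", call. = FALSE)
  structure(
    list(iterations = as.integer(iterations), burn_in = as.integer(burn_in),
         max_predictors = as.integer(max_predictors),
         max_three_way = as.integer(max_three_way),
         interaction_mode = interaction_mode,
         tau2 = tau2, incl_rate = incl_rate,
         moves_per_iter = moves_per_iter, seed = as.integer(seed)),
    class = "sp_config"
  )
}

# canonical form: groups sorted internally and by first member
.canon <- function(state) {
  state <- lapply(state, sort)
  state[order(vapply(state, `[`, integer(1), 1L))]
}

.state_key <- function(state) {
  paste0("s:", paste(vapply(state, paste, character(1), collapse = ","),
                     collapse = "|"))
}

# joint-level codes of a group: integer in 1..prod(nlev), then compressed to
# the observed levels
.group_codes <- function(group, dat) {
  code <- dat$levels[[group[1L]]]
  range <- dat$nlev[group[1L]]
  for (g in group[-1L]) {
    code <- code + range * (dat$levels[[g]] - 1L)
    range <- range * dat$nlev[g]
  }
  match(code, sort(unique(code)))
}

# design matrix of joint-level indicators for all groups (no intercept)
.state_design <- function(state, dat) {
  n <- dat$n
  cols <- lapply(state, function(gr) {
    code <- .group_codes(gr, dat)
    q <- max(code)
    X <- matrix(0, n, q)
    X[cbind(seq_len(n), code)] <- 1
    X
  })
  if (!length(cols)) matrix(0, n, 0) else do.call(cbind, cols)
}

#' Log marginal likelihood (evidence) of a sparse-partitioning model
#'
#' Closed-form integrated likelihood of the grouped-means model described in
#' the package overview: flat intercept, joint-level means with
#' `N(0, tau2 * sigma2)` priors, and `sigma2` under the scale-free prior
#' `1/sigma2`.  Joint levels unobserved in the data simply contribute no
#' term.  Deterministic in its inputs.
#'
#' @param state list of integer vectors: disjoint predictor groups.
#' @param y standardized phenotype vector.
#' @param dat an [sp_predictors()] object.
#' @param tau2 prior scale of the joint-level means.
#' @return log evidence (numeric scalar).
#' @export
sp_log_evidence <- function(state, y, dat, tau2 = 0.2) {
  n <- length(y)
  X1 <- .state_design(state, dat)
  q <- ncol(X1)
  yy <- sum(y * y)
  sy <- sum(y)
  if (q == 0) {
    S <- yy - sy^2 / n
    return(-((n - 1) / 2) * log(2 * pi) - 0.5 * log(n) +
             lgamma((n - 1) / 2) - ((n - 1) / 2) * log(S / 2))
  }
  M <- crossprod(X1) + diag(q) / tau2
  a <- crossprod(X1, y)
  b <- crossprod(X1, rep(1, n))
  ch <- chol(M)
  Mia <- backsolve(ch, forwardsolve(t(ch), a))
  Mib <- backsolve(ch, forwardsolve(t(ch), b))
  yVy <- yy - sum(a * Mia)
  oneVy <- sy - sum(b * Mia)
  oneVone <- n - sum(b * Mib)
  S <- yVy - oneVy^2 / oneVone
  logdetV <- 2 * sum(log(diag(ch))) + q * log(tau2)
  -((n - 1) / 2) * log(2 * pi) - 0.5 * logdetV - 0.5 * log(oneVone) +
    lgamma((n - 1) / 2) - ((n - 1) / 2) * log(S / 2)
}

# number of set partitions of k labeled items into blocks of size <= 3 with
# at most `max3` blocks of size 3
.npart <- local({
  memo <- new.env(parent = emptyenv())
  function(k, max3) {
    if (k < 0) return(0)
    if (k == 0) return(1)
    key <- paste(k, max3)
    if (!is.null(memo[[key]])) return(memo[[key]])
    v <- Recall(k - 1, max3) + (k - 1) * Recall(k - 2, max3)
    if (max3 > 0 && k >= 3) v <- v + choose(k - 1, 2) * Recall(k - 3, max3 - 1)
    memo[[key]] <- v
    v
  }
})

# log prior of a state: independent inclusion at `rate`, uniform over the
# legal partitions of the included set; -Inf on any constraint violation
.sp_log_prior <- function(state, p, rate, config, sex_idx) {
  sizes <- lengths(state)
  k <- sum(sizes)
  if (k > config$max_predictors) return(-Inf)
  if (any(sizes > 3L)) return(-Inf)
  n3 <- sum(sizes == 3L)
  if (n3 > config$max_three_way) return(-Inf)
  mode <- config$interaction_mode
  if (mode == "none" && any(sizes > 1L)) return(-Inf)
  sex_in <- !is.na(sex_idx) && any(vapply(state, function(g) sex_idx %in% g, logical(1)))
  if (mode == "snp_only" && sex_in) {
    sex_grp <- state[[which(vapply(state, function(g) sex_idx %in% g, logical(1)))]]
    if (length(sex_grp) > 1L) return(-Inf)
  }
  k_free <- k
  if (mode == "snp_only" && sex_in) k_free <- k - 1L  # SEX pinned to a singleton
  np <- if (mode == "none") 1 else .npart(k_free, config$max_three_way)
  k * log(rate) + (p - k) * log(1 - rate) - log(np)
}

#' Run the sparse-partitioning MCMC
#'
#' Metropolis-Hastings over model states with four move types -- insert an
#' excluded predictor (into a new singleton or an existing group), remove an
#' included predictor, move a predictor between groups (merge/split), and
#' swap an included predictor for an excluded one -- proposed with weights
#' 0.3/0.3/0.2/0.2 and uniform choices among candidates.  Proposals that
#' violate the model-size, three-way or interaction-mode constraints carry
#' zero prior and are rejected.  Evidence values are memoized per state.
#'
#' @param y standardized phenotype vector.
#' @param dat an [sp_predictors()] object (or a genotype matrix, in which
#'   case `sex` must be given separately).
#' @param config an [sp_config()].
#' @param sex optional sex vector when `dat` is a plain matrix.
#' @return object of class `sp_chain`: list with `states` (one canonical
#'   state per iteration), `log_post` (per-iteration unnormalized log
#'   posterior trace), `y`, `dat`, `config`.
#' @export
sp_mcmc <- function(y, dat, config = sp_config(), sex = NULL) {
  if (!inherits(dat, "sp_predictors")) dat <- sp_predictors(dat, sex)
  p <- length(dat$levels)
  if (p < 2) stop("need at least 2 predictors", call. = FALSE)
  if (length(y) != dat$n) stop("`y` must align with predictors", call. = FALSE)
  rate <- if (is.null(config$incl_rate)) min(0.5, 2 / p) else config$incl_rate
  tau2 <- config$tau2

  cache <- new.env(parent = emptyenv(), size = 4096L)
  evidence <- function(state) {
    key <- .state_key(state)
    v <- cache[[key]]
    if (is.null(v)) {
      v <- sp_log_evidence(state, y, dat, tau2)
      cache[[key]] <- v
    }
    v
  }
  lprior <- function(state) .sp_log_prior(state, p, rate, config, dat$sex_idx)

  included <- function(state) unlist(state, use.names = FALSE)
  n_small <- function(state) sum(lengths(state) <= 2L)

  sweep_len <- if (is.null(config$moves_per_iter)) p else as.integer(config$moves_per_iter)

  with_seed(config$seed, {
    state <- list()
    lp_cur <- evidence(state) + lprior(state)
    states <- vector("list", config$iterations)
    log_post <- numeric(config$iterations)
    w <- c(insert = 0.3, remove = 0.3, move = 0.2, swap = 0.2)

    for (it in seq_len(config$iterations)) {
     for (sweep in seq_len(sweep_len)) {
      mv <- sample.int(4L, 1L, prob = w)
      inc <- included(state)
      k <- length(inc)
      prop <- NULL
      lqf <- lqr <- 0

      if (mv == 1L && k < p) {                      # insert
        excl <- setdiff(seq_len(p), inc)
        j <- excl[sample.int(length(excl), 1L)]
        ndest <- 1L + n_small(state)
        d <- sample.int(ndest, 1L) - 1L             # 0 = new singleton
        prop <- state
        if (d == 0L) {
          prop[[length(prop) + 1L]] <- j
        } else {
          small <- which(lengths(state) <= 2L)
          prop[[small[d]]] <- c(prop[[small[d]]], j)
        }
        prop <- .canon(prop)
        lqf <- log(w[1L]) - log(length(excl)) - log(ndest)
        lqr <- log(w[2L]) - log(k + 1L)
      } else if (mv == 2L && k > 0L) {              # remove
        j <- inc[sample.int(k, 1L)]
        prop <- .drop_pred(state, j)
        lqf <- log(w[2L]) - log(k)
        lqr <- log(w[1L]) - log(p - k + 1L) - log(1L + n_small(prop))
      } else if (mv == 3L && k > 0L) {              # move between groups
        j <- inc[sample.int(k, 1L)]
        base <- .drop_pred(state, j)
        gi <- which(vapply(state, function(g) j %in% g, logical(1)))
        origin_single <- length(state[[gi]]) == 1L
        # all placements of j in `base`, minus the one recreating `state`
        small <- which(lengths(base) <= 2L)
        placements <- list()
        if (!origin_single) placements <- list(0L)  # new singleton
        if (origin_single) {
          cand <- small
        } else {
          rest <- sort(setdiff(state[[gi]], j))
          cand <- small[!vapply(small, function(s) identical(base[[s]], rest), logical(1))]
        }
        placements <- c(placements, as.list(cand))
        if (length(placements)) {
          pl <- placements[[sample.int(length(placements), 1L)]]
          prop <- base
          if (pl == 0L) prop[[length(prop) + 1L]] <- j
          else prop[[pl]] <- c(prop[[pl]], j)
          prop <- .canon(prop)
          lqf <- log(w[3L]) - log(k) - log(length(placements))
          lqr <- lqf                               # same candidate count both ways
        }
      } else if (mv == 4L && k > 0L && k < p) {     # swap included/excluded
        j <- inc[sample.int(k, 1L)]
        excl <- setdiff(seq_len(p), inc)
        r <- excl[sample.int(length(excl), 1L)]
        prop <- lapply(state, function(g) {
          g[g == j] <- r
          g
        })
        prop <- .canon(prop)
        lqf <- log(w[4L]) - log(k) - log(length(excl))
        lqr <- lqf
      }

      if (!is.null(prop)) {
        lp_prior <- lprior(prop)
        if (is.finite(lp_prior)) {
          lp_prop <- evidence(prop) + lp_prior
          if (log(stats::runif(1)) < lp_prop - lp_cur + lqr - lqf) {
            state <- prop
            lp_cur <- lp_prop
          }
        }
      }
     }
      states[[it]] <- state
      log_post[it] <- lp_cur
    }

    structure(
      list(states = states, log_post = log_post, y = y, dat = dat,
           config = config, incl_rate = rate),
      class = "sp_chain"
    )
  })
}

.drop_pred <- function(state, j) {
  out <- lapply(state, function(g) g[g != j])
  .canon(out[lengths(out) > 0L])
}

#' Posterior inclusion and interaction probabilities from a chain
#'
#' Inclusion of a predictor is the fraction of retained (post burn-in)
#' states that contain it; the interaction probability of a pair is the
#' fraction of retained states in which the two share a group.  Every
#' probability is therefore an integer count over `retained_samples`.
#'
#' @param chain an `sp_chain` from [sp_mcmc()].
#' @return object of class `sp_posterior`: list with `inclusion` (named
#'   vector), `pairwise` (p x p symmetric matrix of co-grouping
#'   probabilities), `retained_samples`, `chain_log`.
#' @export
sp_posterior <- function(chain) {
  stopifnot(inherits(chain, "sp_chain"))
  cfg <- chain$config
  keep <- seq(cfg$burn_in + 1L, cfg$iterations)
  p <- length(chain$dat$levels)
  nm <- chain$dat$names
  incl <- numeric(p)
  pair <- matrix(0, p, p, dimnames = list(nm, nm))
  for (it in keep) {
    for (g in chain$states[[it]]) {
      incl[g] <- incl[g] + 1
      if (length(g) > 1L) {
        cmb <- utils::combn(g, 2L)
        for (c_i in seq_len(ncol(cmb))) {
          a <- cmb[1L, c_i]; b <- cmb[2L, c_i]
          pair[a, b] <- pair[a, b] + 1
          pair[b, a] <- pair[b, a] + 1
        }
      }
    }
  }
  retained <- length(keep)
  structure(
    list(inclusion = stats::setNames(incl / retained, nm),
         pairwise = pair / retained,
         retained_samples = retained,
         chain_log = chain$log_post[keep]),
    class = "sp_posterior"
  )
}

# all partitions of `items` into blocks of size <= 3 (unconstrained count;
# mode/cap filtering happens in the prior)
.partitions_le3 <- function(items) {
  if (!length(items)) return(list(list()))
  first <- items[1L]
  rest <- items[-1L]
  out <- list()
  # singleton block
  for (sub in .partitions_le3(rest)) out[[length(out) + 1L]] <- c(list(first), sub)
  # pair blocks
  for (i in seq_along(rest)) {
    for (sub in .partitions_le3(rest[-i])) {
      out[[length(out) + 1L]] <- c(list(c(first, rest[i])), sub)
    }
  }
  # triple blocks
  if (length(rest) >= 2L) {
    cmb <- utils::combn(seq_along(rest), 2L)
    for (c_i in seq_len(ncol(cmb))) {
      pick <- cmb[, c_i]
      for (sub in .partitions_le3(rest[-pick])) {
        out[[length(out) + 1L]] <- c(list(c(first, rest[pick])), sub)
      }
    }
  }
  out
}

#' Exact posterior by exhaustive enumeration of model space
#'
#' Enumerates every legal state (all subsets of the predictors, partitioned
#' into groups of size 1-3 subject to the configured constraints), weights
#' each by prior x evidence, and normalizes.  Feasible for small predictor
#' counts (roughly p <= 8); used to validate the MCMC sampler.
#'
#' @inheritParams sp_mcmc
#' @return object of class `sp_posterior` with exact probabilities
#'   (`retained_samples = NA`).
#' @export
sp_enumerate_posterior <- function(y, dat, config = sp_config(), sex = NULL) {
  if (!inherits(dat, "sp_predictors")) dat <- sp_predictors(dat, sex)
  p <- length(dat$levels)
  if (p > 12) stop("enumeration is infeasible beyond ~12 predictors", call. = FALSE)
  rate <- if (is.null(config$incl_rate)) min(0.5, 2 / p) else config$incl_rate

  states <- list()
  for (mask in 0:(2^p - 1)) {
    items <- which(bitwAnd(mask, 2^(seq_len(p) - 1L)) > 0L)
    if (length(items) > config$max_predictors) next
    for (part in .partitions_le3(items)) {
      st <- .canon(part)
      if (is.finite(.sp_log_prior(st, p, rate, config, dat$sex_idx))) {
        states[[length(states) + 1L]] <- st
      }
    }
  }
  lw <- vapply(states, function(st) {
    sp_log_evidence(st, y, dat, config$tau2) +
      .sp_log_prior(st, p, rate, config, dat$sex_idx)
  }, numeric(1))
  wts <- exp(lw - max(lw))
  wts <- wts / sum(wts)

  nm <- dat$names
  incl <- numeric(p)
  pair <- matrix(0, p, p, dimnames = list(nm, nm))
  for (s_i in seq_along(states)) {
    for (g in states[[s_i]]) {
      incl[g] <- incl[g] + wts[s_i]
      if (length(g) > 1L) {
        cmb <- utils::combn(g, 2L)
        for (c_i in seq_len(ncol(cmb))) {
          a <- cmb[1L, c_i]; b <- cmb[2L, c_i]
          pair[a, b] <- pair[a, b] + wts[s_i]
          pair[b, a] <- pair[b, a] + wts[s_i]
        }
      }
    }
  }
  structure(
    list(inclusion = stats::setNames(incl, nm), pairwise = pair,
         retained_samples = NA_integer_, chain_log = lw),
    class = "sp_posterior"
  )
}

#' Call QTL from a sparse-partitioning posterior
#'
#' Main-effect calls are SNP predictors with inclusion probability at or
#' above the threshold; GxS calls are (SNP, SEX) pairs and GxG calls are
#' SNP-SNP pairs with co-grouping probability at or above it.  Calls are
#' annotated with map position and minor-allele frequency.
#'
#' @param post an `sp_posterior`.
#' @param marker_map data.frame with `marker`, `chrom`, `pos_mb`; must cover
#'   every SNP predictor name.
#' @param maf named numeric vector of minor-allele frequencies (optional).
#' @param threshold posterior probability threshold (default 0.2, the
#'   operating point above which the posterior histogram thins out).
#' @param phenotype optional phenotype label carried into the calls.
#' @return data.frame with columns `phenotype`, `snp`, `chrom`, `pos_mb`,
#'   `posterior`, `maf`, `class` (main/GxS/GxG), `partner`.
#' @export
sp_call_qtl <- function(post, marker_map, maf = NULL, threshold = 0.2,
                        phenotype = NA_character_) {
  stopifnot(inherits(post, "sp_posterior"))
  if (threshold <= 0 || threshold > 1) stop("`threshold` must be in (0, 1]", call. = FALSE)
  nm <- names(post$inclusion)
  snps <- setdiff(nm, SEX_ID)
  missing <- setdiff(snps, marker_map$marker)
  if (length(missing)) {
    stop(sprintf("markers absent from map: %s",
                 paste(utils::head(missing, 5), collapse = ", ")), call. = FALSE)
  }
  row_of <- match(snps, marker_map$marker)
  look <- function(s, what) marker_map[[what]][row_of[match(s, snps)]]
  maf_of <- function(s) if (is.null(maf)) NA_real_ else unname(maf[s])

  calls <- list()
  add <- function(s, pp, cls, partner) {
    calls[[length(calls) + 1L]] <<- data.frame(
      phenotype = phenotype, snp = s, chrom = look(s, "chrom"),
      pos_mb = look(s, "pos_mb"), posterior = pp, maf = maf_of(s),
      class = cls, partner = partner, stringsAsFactors = FALSE
    )
  }
  for (s in snps) {
    if (post$inclusion[s] >= threshold) add(s, unname(post$inclusion[s]), "main", NA_character_)
  }
  if (SEX_ID %in% nm) {
    for (s in snps) {
      pp <- post$pairwise[s, SEX_ID]
      if (pp >= threshold) add(s, pp, "GxS", SEX_ID)
    }
  }
  if (length(snps) > 1L) {
    cmb <- utils::combn(snps, 2L)
    for (c_i in seq_len(ncol(cmb))) {
      a <- cmb[1L, c_i]; b <- cmb[2L, c_i]
      pp <- post$pairwise[a, b]
      if (pp >= threshold) add(a, pp, "GxG", b)
    }
  }
  if (!length(calls)) {
    return(data.frame(phenotype = character(0), snp = character(0),
                      chrom = integer(0), pos_mb = numeric(0),
                      posterior = numeric(0), maf = numeric(0),
                      class = character(0), partner = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}

#' Minor-allele frequencies of a genotype matrix
#'
#' @param G genotype matrix coded 0/1/2.
#' @return named vector of per-marker minor-allele frequencies.
#' @export
minor_allele_freq <- function(G) {
  p <- colMeans(as.matrix(G), na.rm = TRUE) / 2
  stats::setNames(pmin(p, 1 - p), colnames(G))
}
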