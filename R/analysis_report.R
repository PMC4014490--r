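# Downstream analyses: permutation-based false-discovery calibration,
# cross-mapper QTL matching, GxS vs single-sex classification, rank-sum and
# correlation statistics, sex-effect variance, and posterior-probability
# histograms.

#' Permutation-based expected false-positive count for interaction calls
#'
#' Re-runs the sparse-partitioning mapper once per phenotype on permuted
#' response values (destroying all genotype-phenotype association while
#' keeping the predictor structure) and counts the interaction
#' probabilities that still reach the calling threshold.  The summed count
#' estimates the number of interaction false positives expected across the
#' phenotype panel at that threshold.
#'
#' @param phenotypes list (or single vector) of standardized phenotype
#'   vectors.
#' @param dat an [sp_predictors()] object shared by all phenotypes.
#' @param config an [sp_config()].
#' @param threshold posterior probability threshold (default 0.2).
#' @param seed integer seed for the permutations.
#' @param permutations permutations per phenotype (default 1).
#' @return list with `expected_false_positives` (integer count) and
#'   `max_interaction_prob` (per phenotype x permutation, the largest
#'   permuted-run interaction probability).
#' @export
permutation_fdr <- function(phenotypes, dat, config = sp_config(),
                            threshold = 0.2, seed = 1L, permutations = 1L) {
  if (is.numeric(phenotypes)) phenotypes <- list(phenotypes)
  if (!length(phenotypes)) stop("need at least one phenotype", call. = FALSE)
  count <- 0L
  maxima <- matrix(NA_real_, length(phenotypes), permutations)
  for (i in seq_along(phenotypes)) {
    for (r in seq_len(permutations)) {
      sd_perm <- child_seed(seed, 1000L * i + r)
      yp <- with_seed(sd_perm, sample(phenotypes[[i]]))
      cfg <- config
      cfg$seed <- child_seed(sd_perm, 1L)
      post <- sp_posterior(sp_mcmc(yp, dat, cfg))
      pw <- post$pairwise[upper.tri(post$pairwise)]
      count <- count + sum(pw >= threshold)
      maxima[i, r] <- if (length(pw)) max(pw) else 0
    }
  }
  list(expected_false_positives = as.integer(count),
       max_interaction_prob = maxima)
}

#' Match sparse-partitioning calls against RMIP peaks
#'
#' A call matches a peak when both lie on the same chromosome (and carry
#' the same phenotype label, when labels are present on both sides) and the
#' call position falls within the peak's 95% confidence interval expanded
#' by `window_mb` on each side.  Assignment is greedy nearest-first and
#' each peak is used at most once.
#'
#' @param sp_calls data.frame as returned by [sp_call_qtl()] (rows to
#'   match; typically the main-effect calls).
#' @param rmip an `rmip_result` (or its `peaks` data.frame).
#' @param window_mb expansion of the CI in Mbp (default 2).
#' @return object of class `match_report`: list with `matched` (data.frame
#'   pairing call rows and peak rows with their distance), `unmatched_calls`,
#'   `unmatched_peaks`, `window_mb`.
#' @export
match_qtl <- function(sp_calls, rmip, window_mb = 2) {
  peaks <- if (inherits(rmip, "rmip_result")) rmip$peaks else rmip
  dist_to <- function(pos, lo, hi) {
    if (pos < lo) lo - pos else if (pos > hi) pos - hi else 0
  }
  cand <- list()
  for (i in seq_len(nrow(sp_calls))) {
    for (j in seq_len(nrow(peaks))) {
      if (sp_calls$chrom[i] != peaks$chrom[j]) next
      if (!is.null(sp_calls$phenotype) && !is.null(peaks$phenotype) &&
          !all(is.na(c(sp_calls$phenotype[i], peaks$phenotype[j]))) &&
          !identical(sp_calls$phenotype[i], peaks$phenotype[j])) next
      lo <- peaks$ci_lo[j]; hi <- peaks$ci_hi[j]
      if (is.na(lo) || is.na(hi)) {
        d <- abs(sp_calls$pos_mb[i] - peaks$pos_mb[j])
        if (d <= window_mb) cand[[length(cand) + 1L]] <- c(i, j, d)
        next
      }
      d <- dist_to(sp_calls$pos_mb[i], lo, hi)
      if (d <= window_mb) cand[[length(cand) + 1L]] <- c(i, j, d)
    }
  }
  matched <- data.frame(call = integer(0), peak = integer(0), dist_mb = numeric(0))
  if (length(cand)) {
    cm <- do.call(rbind, cand)
    cm <- cm[order(cm[, 3]), , drop = FALSE]
    used_call <- used_peak <- logical(0)
    for (r in seq_len(nrow(cm))) {
      ci <- cm[r, 1]; pj <- cm[r, 2]
      if (ci %in% matched$call || pj %in% matched$peak) next
      matched <- rbind(matched,
                       data.frame(call = ci, peak = pj, dist_mb = cm[r, 3]))
    }
  }
  structure(
    list(matched = matched,
         unmatched_calls = setdiff(seq_len(nrow(sp_calls)), matched$call),
         unmatched_peaks = setdiff(seq_len(nrow(peaks)), matched$peak),
         window_mb = window_mb),
    class = "match_report"
  )
}

#' Classify GxS calls by single-sex main-effect support
#'
#' For each GxS call, checks each sex's single-sex RMIP scan for an
#' above-threshold peak within `window_mb` on the same chromosome, yielding
#' `"male-only"`, `"female-only"`, `"both"` or `"neither"`.
#'
#' @param gxs_calls data.frame of GxS calls (needs `chrom`, `pos_mb`).
#' @param male_scan,female_scan `rmip_result` objects from
#'   [single_sex_scan()].
#' @param window_mb matching window in Mbp (default 5).
#' @param rmip_threshold peak strength required (default 0.25, the
#'   conventional one-false-positive-per-scan operating point).
#' @return the `gxs_calls` data.frame with a `single_sex_support` column.
#' @export
match_gxs_single_sex <- function(gxs_calls, male_scan, female_scan,
                                 window_mb = 5, rmip_threshold = 0.25) {
  stopifnot(inherits(male_scan, "rmip_result"), inherits(female_scan, "rmip_result"))
  if (!identical(male_scan$sex_subset, "male") ||
      !identical(female_scan$sex_subset, "female")) {
    stop("scans must be tagged with sex_subset male/female", call. = FALSE)
  }
  near_peak <- function(scan, chrom, pos) {
    pk <- scan$peaks
    pk <- pk[pk$rmip >= rmip_threshold & pk$chrom == chrom, , drop = FALSE]
    any(abs(pk$pos_mb - pos) <= window_mb)
  }
  cls <- character(nrow(gxs_calls))
  for (i in seq_len(nrow(gxs_calls))) {
    m <- near_peak(male_scan, gxs_calls$chrom[i], gxs_calls$pos_mb[i])
    f <- near_peak(female_scan, gxs_calls$chrom[i], gxs_calls$pos_mb[i])
    cls[i] <- if (m && f) "both" else if (m) "male-only" else if (f) "female-only" else "neither"
  }
  gxs_calls$single_sex_support <- cls
  gxs_calls
}

#' Wilcoxon rank-sum comparison (rank-sum form)
#'
#' `W` is the sum of the pooled mid-ranks of the first group.  For combined
#' sizes up to 12 the two-sided p-value is exact, by enumeration of all
#' group assignments of the pooled values; otherwise the normal
#' approximation with tie correction is used.
#'
#' @param a,b numeric vectors (both non-empty).
#' @return list with `W` (rank sum of `a`) and `p` (two-sided).
#' @export
rank_sum_compare <- function(a, b) {
  if (!length(a) || !length(b)) stop("both groups must be non-empty", call. = FALSE)
  na <- length(a); nb <- length(b); N <- na + nb
  pooled <- c(a, b)
  rk <- rank(pooled)
  W <- sum(rk[seq_len(na)])
  if (N <= 12) {
    combos <- utils::combn(N, na)
    Ws <- colSums(matrix(rk[combos], nrow = na))
    p <- 2 * min(mean(Ws <= W), mean(Ws >= W))
  } else {
    ties <- table(rk)
    muW <- na * (N + 1) / 2
    varW <- na * nb / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (varW <= 0) return(list(W = W, p = 1))
    z <- (W - muW) / sqrt(varW)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(W = W, p = min(p, 1))
}

#' Percent variance explained by sex as a main effect
#'
#' `100 * R^2` of the simple linear regression of the phenotype on sex.
#'
#' @param y numeric phenotype vector.
#' @param sex binary vector with both sexes present.
#' @return percent of variance explained (numeric scalar).
#' @export
sex_effect_variance <- function(y, sex) {
  if (length(unique(sex)) < 2) stop("both sexes must be present", call. = FALSE)
  100 * summary(stats::lm(y ~ sex))$r.squared
}

#' Pearson correlation with a t-test
#'
#' `t = r * sqrt((n - 2) / (1 - r^2))`, two-sided p from the t distribution
#' on `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors of equal length `n >= 3`.
#' @return object of class `correlation_report`: list with `r`, `t_stat`,
#'   `df`, `p`, `n`.
#' @export
correlate_with_t <- function(x, y) {
  n <- length(x)
  if (length(y) != n || n < 3) stop("need equal lengths >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in an input", call. = FALSE)
  }
  r <- stats::cor(x, y)
  df <- n - 2L
  t_stat <- r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(-abs(t_stat), df)
  structure(list(r = r, t_stat = t_stat, df = df, p = p, n = n),
            class = "correlation_report")
}

#' Histogram of posterior probabilities
#'
#' Bins values in `[floor, 1]` at the given width; values below the floor
#' (dominated by near-zero noise) are excluded.  The calling threshold is
#' carried along for annotation.
#'
#' @param values numeric vector of probabilities in `[0, 1]`.
#' @param floor lower bound of the histogram (default 0.05).
#' @param threshold annotated calling threshold (default 0.2).
#' @param bin_width bin width (default 0.05).
#' @return data.frame with `bin_lo`, `bin_hi`, `count` and attribute
#'   `threshold`.
#' @export
probability_histogram <- function(values, floor = 0.05, threshold = 0.2,
                                  bin_width = 0.05) {
  if (any(values < 0 | values > 1)) stop("values must lie in [0, 1]", call. = FALSE)
  lo <- seq(floor, 1, by = bin_width)
  if (utils::tail(lo, 1) >= 1) lo <- lo[lo < 1]
  hi <- pmin(lo + bin_width, 1)
  v <- values[values >= floor]
  count <- vapply(seq_along(lo), function(i) {
    # right-open bins, except the last which is closed at 1
    if (i == length(lo)) sum(v >= lo[i] & v <= hi[i]) else sum(v >= lo[i] & v < hi[i])
  }, numeric(1))
  out <- data.frame(bin_lo = lo, bin_hi = hi, count = count)
  attr(out, "threshold") <- threshold
  out
}
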