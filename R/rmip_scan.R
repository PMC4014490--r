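# Bootstrap resample model averaging over forward-selected multiple-QTL
# regressions on founder-ancestry dosages.
#
# Each locus is represented by its 8 founder-dosage columns (one dropped
# for identifiability).  Forward selection adds, at each step, the locus
# whose block most reduces the residual sum of squares, gated by the
# partial F-test at `alpha`.  Repeating the selection over bootstrap
# resamples of the individuals yields, per locus, a resample model
# inclusion probability (RMIP): the fraction of resamples in which the
# locus entered the model.

# per-locus design blocks: drop the last founder column and any column
# with (near-)zero variance, center the rest
.locus_blocks <- function(ancestry) {
  stopifnot(length(dim(ancestry)) == 3L)
  L <- dim(ancestry)[2L]
  lapply(seq_len(L), function(j) {
    B <- ancestry[, j, -dim(ancestry)[3L], drop = TRUE]
    B <- as.matrix(B)
    keep <- apply(B, 2, function(v) stats::sd(v) > 1e-10)
    B[, keep, drop = FALSE]
  })
}

# forward selection core on a list of blocks; returns integer locus indices
# in selection order
.forward_select <- function(y, blocks, alpha, max_model = 20L) {
  n <- length(y)
  X <- matrix(1, n, 1)
  qrX <- qr(X)
  rss <- sum(qr.resid(qrX, y)^2)
  selected <- integer(0)
  repeat {
    if (length(selected) >= max_model) break
    cand <- setdiff(seq_along(blocks), selected)
    if (!length(cand)) break
    res_y <- qr.resid(qrX, y)
    best <- NULL
    for (j in cand) {
      B <- blocks[[j]]
      if (!ncol(B)) next
      Br <- qr.resid(qrX, B)
      qb <- qr(Br)
      df1 <- qb$rank
      if (df1 == 0) next
      gain <- sum(qr.fitted(qb, res_y)^2)
      if (is.null(best) || gain > best$gain) {
        best <- list(j = j, gain = gain, df1 = df1)
      }
    }
    if (is.null(best)) break
    df2 <- n - ncol(X) - best$df1
    if (df2 <= 0) break
    rss_new <- rss - best$gain
    Fstat <- (best$gain / best$df1) / (rss_new / df2)
    pval <- stats::pf(Fstat, best$df1, df2, lower.tail = FALSE)
    # genome-wide (Bonferroni) adjustment over the candidates scanned this
    # step: without it a scan over many loci would admit a spurious locus in
    # nearly every resample and inclusion probabilities would not be
    # comparable across scans of different size
    pval_adj <- min(1, pval * length(cand))
    if (pval_adj > alpha) break
    selected <- c(selected, best$j)
    X <- cbind(X, blocks[[best$j]])
    qrX <- qr(X)
    rss <- sum(qr.resid(qrX, y)^2)
  }
  selected
}

#' Forward selection of QTL on founder-ancestry dosages
#'
#' Greedy multiple-QTL regression: at each step the candidate locus whose
#' dosage block (8 founder columns, one dropped for identifiability) most
#' reduces the residual sum of squares is added, provided its partial
#' F-test p-value, Bonferroni-adjusted for the number of candidate loci
#' scanned at that step, is at or below `alpha`; selection stops when no
#' candidate qualifies or the model-size cap is reached.
#'
#' @param y numeric phenotype vector.
#' @param ancestry n x L x 8 founder-dosage array (or a list of n x 7
#'   blocks).
#' @param alpha partial F-test significance gate (default 0.05).
#' @param max_model maximum number of loci in the model (default 20).
#' @return integer vector of selected locus indices, in selection order.
#' @export
forward_select_qtl <- function(y, ancestry, alpha = 0.05, max_model = 20L) {
  if (alpha <= 0 || alpha > 1) stop("`alpha` must be in (0, 1]", call. = FALSE)
  blocks <- if (is.list(ancestry)) ancestry else .locus_blocks(ancestry)
  if (length(y) != nrow(blocks[[1L]])) stop("`y` must align with ancestry rows", call. = FALSE)
  .forward_select(y, blocks, alpha, max_model)
}

#' Tally RMIPs from a bootstrap inclusion record
#'
#' The RMIP of a locus is its inclusion count divided by the number of
#' bootstrap resamples; a locus selected in 70 of 100 resamples has
#' RMIP 0.70.
#'
#' @param inclusions integer vector of per-locus inclusion counts.
#' @param n_boot number of bootstrap resamples.
#' @return numeric vector of RMIPs (each an integer multiple of
#'   `1/n_boot`).
#' @export
rmip_from_inclusions <- function(inclusions, n_boot) {
  if (n_boot < 1) stop("`n_boot` must be >= 1", call. = FALSE)
  if (any(inclusions < 0 | inclusions > n_boot)) {
    stop("inclusion counts must lie in [0, n_boot]", call. = FALSE)
  }
  inclusions / n_boot
}

# peak finding: local maxima of the RMIP profile above `floor`, merged
# within `merge_mb`; CI from the positions selected across bootstraps
.rmip_peaks <- function(rmip, map, sel_positions, floor, merge_mb) {
  peaks <- list()
  for (ci in unique(map$chrom)) {
    jj <- which(map$chrom == ci)
    jj <- jj[order(map$pos_mb[jj])]
    r <- rmip[jj]
    above <- which(r >= floor)
    if (!length(above)) next
    # local maxima among the above-floor loci
    is_max <- vapply(above, function(i) {
      (i == 1L || r[i] >= r[i - 1L]) && (i == length(r) || r[i] >= r[i + 1L])
    }, logical(1))
    cand <- jj[above[is_max]]
    # merge candidates within merge_mb, keeping the strongest
    cand <- cand[order(-rmip[cand])]
    kept <- numeric(0)
    for (j in cand) {
      if (!length(kept) || all(abs(map$pos_mb[kept] - map$pos_mb[j]) > merge_mb |
                               map$chrom[kept] != map$chrom[j])) {
        kept <- c(kept, j)
      }
    }
    for (j in kept) {
      # positions of selections attributable to this peak
      pos <- sel_positions[[as.character(ci)]]
      pos <- pos[abs(pos - map$pos_mb[j]) <= merge_mb]
      ci_lo <- if (length(pos)) unname(stats::quantile(pos, 0.025)) else map$pos_mb[j]
      ci_hi <- if (length(pos)) unname(stats::quantile(pos, 0.975)) else map$pos_mb[j]
      peaks[[length(peaks) + 1L]] <- data.frame(
        locus = j, chrom = ci, pos_mb = map$pos_mb[j], rmip = rmip[j],
        ci_lo = min(ci_lo, map$pos_mb[j]), ci_hi = max(ci_hi, map$pos_mb[j])
      )
    }
  }
  if (!length(peaks)) {
    return(data.frame(locus = integer(0), chrom = integer(0),
                      pos_mb = numeric(0), rmip = numeric(0),
                      ci_lo = numeric(0), ci_hi = numeric(0)))
  }
  out <- do.call(rbind, peaks)
  out[order(out$chrom, out$pos_mb), , drop = FALSE]
}

#' Bootstrap resample model inclusion probabilities
#'
#' Runs [forward_select_qtl()] on `n_boot` bootstrap resamples (individuals
#' drawn with replacement) and tallies, per locus, the fraction of resamples
#' in which it entered the model.  Peaks are local maxima of the RMIP
#' profile above `peak_floor`, merged within `merge_mb`; each peak's 95%
#' confidence interval spans the 2.5th-97.5th percentiles of the selected
#' positions attributed to it across resamples.
#'
#' @inheritParams forward_select_qtl
#' @param map data.frame with `chrom`, `pos_mb` for each locus.
#' @param n_boot number of bootstrap resamples (default 100).
#' @param peak_floor minimum RMIP for a reported peak (default 0.1).
#' @param merge_mb merge window for neighbouring peaks in Mbp (default 5).
#' @param seed integer seed driving the resampling.
#' @param sex_subset label recorded on the result (`"both"` unless set by
#'   [single_sex_scan()]).
#' @return object of class `rmip_result`: list with `rmip` (per-locus),
#'   `peaks` (data.frame incl. CI), `n_boot`, `inclusions`, `sex_subset`,
#'   `map`.
#' @export
compute_rmip <- function(y, ancestry, map, n_boot = 100L, alpha = 0.05,
                         max_model = 20L, peak_floor = 0.1, merge_mb = 5,
                         seed = 1L, sex_subset = "both") {
  if (n_boot < 1) stop("`n_boot` must be >= 1", call. = FALSE)
  if (n_boot < 20) warning("fewer than 20 bootstraps: peak CIs are unstable", call. = FALSE)
  blocks <- if (is.list(ancestry)) ancestry else .locus_blocks(ancestry)
  L <- length(blocks)
  if (nrow(map) != L) stop("`map` must have one row per locus", call. = FALSE)
  n <- length(y)

  incl <- integer(L)
  sel_positions <- lapply(unique(map$chrom), function(ci) numeric(0))
  names(sel_positions) <- as.character(unique(map$chrom))

  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      yb <- y[idx]
      bb <- lapply(blocks, function(B) B[idx, , drop = FALSE])
      sel <- .forward_select(yb, bb, alpha, max_model)
      incl[sel] <- incl[sel] + 1L
      for (j in sel) {
        ch <- as.character(map$chrom[j])
        sel_positions[[ch]] <- c(sel_positions[[ch]], map$pos_mb[j])
      }
    }
  })

  rmip <- rmip_from_inclusions(incl, n_boot)
  peaks <- .rmip_peaks(rmip, map, sel_positions, peak_floor, merge_mb)
  structure(
    list(rmip = rmip, peaks = peaks, n_boot = as.integer(n_boot),
         inclusions = incl, sex_subset = sex_subset, map = map),
    class = "rmip_result"
  )
}

#' Single-sex RMIP scan
#'
#' Restricts the data to one sex and runs [compute_rmip()]; the result is
#' tagged with the subset so GxS candidates can be checked for sex-specific
#' main effects.
#'
#' @inheritParams compute_rmip
#' @param sex binary vector (1 = male) aligned with `y`.
#' @param subset `"male"` or `"female"`.
#' @param ... passed to [compute_rmip()].
#' @return an `rmip_result` with `sex_subset` set.
#' @export
single_sex_scan <- function(y, ancestry, map, sex, subset = c("male", "female"),
                            ...) {
  subset <- match.arg(subset)
  keep <- if (subset == "male") sex == 1L else sex == 0L
  if (!any(keep)) stop(sprintf("no %s individuals in the data", subset), call. = FALSE)
  if (sum(keep) < 50) warning("fewer than 50 individuals in the subset", call. = FALSE)
  blocks <- if (is.list(ancestry)) ancestry else .locus_blocks(ancestry)
  blocks <- lapply(blocks, function(B) B[keep, , drop = FALSE])
  compute_rmip(y[keep], blocks, map, sex_subset = subset, ...)
}
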