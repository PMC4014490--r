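# Phenotype preprocessing: Box-Cox normalization, covariate screening,
# relatedness adjustment, and concordance pruning of redundant SNPs.
# The stages are applied in that order; each returns a standardized vector
# so downstream mappers always see mean-0, variance-1 input.

#' Box-Cox normalization by profile likelihood
#'
#' Selects the Box-Cox power on the grid `lambda = -2, -1.9, ..., 2` by
#' maximizing the profile log-likelihood (via [MASS::boxcox()]), applying a
#' shift of `1 - min(y)` first whenever any value is non-positive.
#' `lambda = 0` means the log transform.  The transformed vector is
#' standardized to mean 0, variance 1.
#'
#' @param y numeric vector with at least 10 finite values and nonzero
#'   variance.
#' @return list with `y` (transformed, standardized) and `record` (list:
#'   `lambda`, `shift`, `applied`).
#' @export
boxcox_transform <- function(y) {
  y <- as.numeric(y)
  if (sum(is.finite(y)) < 10) stop("need >= 10 finite values", call. = FALSE)
  if (stats::sd(y) == 0) stop("constant phenotype", call. = FALSE)
  shift <- if (min(y) <= 0) 1 - min(y) else 0
  ys <- y + shift
  grid <- seq(-2, 2, by = 0.1)
  prof <- MASS::boxcox(ys ~ 1, lambda = grid, plotit = FALSE)
  lambda <- prof$x[which.max(prof$y)]
  yt <- if (abs(lambda) < 1e-12) log(ys) else (ys^lambda - 1) / lambda
  list(
    y = standardize(yt),
    record = list(lambda = lambda, shift = shift, applied = TRUE)
  )
}

#' Screen and regress out significant covariates
#'
#' Each covariate is tested marginally (simple regression of `y` on that
#' covariate); those with p < `alpha` are retained and jointly regressed
#' out.  Residuals are re-standardized.  Known covariates such as body
#' weight enter the mapping only through this removal step.
#'
#' @param y numeric phenotype vector.
#' @param covariates numeric matrix or data.frame, rows aligned with `y`.
#' @param alpha marginal significance level for retention (default 0.05).
#' @return list with `y` (residual, standardized), `retained` (names or
#'   indices of retained covariates).
#' @export
regress_covariates <- function(y, covariates, alpha = 0.05) {
  X <- as.matrix(covariates)
  if (nrow(X) != length(y)) stop("rows of `covariates` must align with `y`", call. = FALSE)
  if (is.null(colnames(X))) colnames(X) <- paste0("cov", seq_len(ncol(X)))
  # drop constants before testing
  keepc <- apply(X, 2, function(v) stats::sd(v) > 0)
  X <- X[, keepc, drop = FALSE]
  if (ncol(X) == 0) return(list(y = standardize(y), retained = character(0)))

  pvals <- apply(X, 2, function(v) {
    stats::summary.lm(stats::lm(y ~ v))$coefficients[2, 4]
  })
  retained <- colnames(X)[pvals < alpha]
  if (!length(retained)) return(list(y = standardize(y), retained = character(0)))

  Xr <- X[, retained, drop = FALSE]
  qrX <- qr(cbind(1, Xr))
  if (qrX$rank < ncol(Xr) + 1L) {
    dropped <- retained[qrX$pivot[seq(qrX$rank + 1L, ncol(Xr) + 1L)] - 1L]
    stop(sprintf("retained covariates are rank deficient (offending: %s)",
                 paste(dropped, collapse = ", ")), call. = FALSE)
  }
  res <- stats::lm.fit(cbind(1, Xr), y)$residuals
  list(y = standardize(res), retained = retained)
}

#' Adjust a phenotype for relatedness
#'
#' Fits the single-kinship mixed model by REML ([reml_h2()]) and whitens the
#' phenotype by the inverse square root of the fitted covariance
#' `sigma_g^2 K + sigma_e^2 I` (a generalized-least-squares rotation), then
#' re-standardizes.  With `K = I`, or when the genetic component is
#' estimated at zero, the phenotype is returned unchanged up to
#' standardization.
#'
#' @param y numeric phenotype vector.
#' @param K a `kinship_matrix` or symmetric PSD matrix matching `y`.
#' @param eig_tol negative-eigenvalue clipping tolerance (default 1e-8).
#' @return list with `y` (adjusted, standardized) and `vc` (the fitted
#'   `variance_components`).
#' @export
adjust_relatedness <- function(y, K, eig_tol = 1e-8) {
  if (inherits(K, "kinship_matrix")) K <- K$K
  K <- as.matrix(K)
  vc <- suppressWarnings(reml_h2(y, K, eig_tol = eig_tol))
  if (!vc$converged || vc$sigma_g2 <= 0) {
    return(list(y = standardize(y), vc = vc))
  }
  eig <- eigen(K, symmetric = TRUE)
  d <- pmax(eig$values, 0)
  scale <- 1 / sqrt(vc$sigma_g2 * d + vc$sigma_e2)
  yw <- as.numeric(eig$vectors %*% (scale * crossprod(eig$vectors, y)))
  list(y = standardize(yw), vc = vc)
}

#' Prune near-duplicate SNPs by genotype concordance
#'
#' Within each chromosome, markers are clustered greedily left to right: a
#' marker joins an existing cluster when its genotype vector agrees with the
#' cluster's representative (the leftmost member) in at least `threshold` of
#' the pairwise non-missing individuals; otherwise it founds a new cluster.
#' The representatives, in map order, are retained.
#'
#' @param G genotype matrix (individuals x markers, 0/1/2, NA allowed).
#' @param marker_map data.frame with columns `chrom` and `pos_mb`, rows
#'   aligned with the columns of `G` and ordered by position within
#'   chromosome.
#' @param threshold concordance threshold in `(0.5, 1]` (default 0.99).
#' @return integer vector of retained column indices, in map order.
#' @export
prune_concordant_snps <- function(G, marker_map, threshold = 0.99) {
  G <- as.matrix(G)
  if (ncol(G) == 0 || nrow(G) == 0) stop("empty genotype matrix", call. = FALSE)
  if (threshold <= 0.5 || threshold > 1) {
    stop("`threshold` must be in (0.5, 1]", call. = FALSE)
  }
  if (nrow(marker_map) != ncol(G)) {
    stop("`marker_map` must have one row per marker", call. = FALSE)
  }
  concord <- function(a, b) {
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) return(0)
    mean(a[ok] == b[ok])
  }
  retained <- integer(0)
  for (ci in unique(marker_map$chrom)) {
    jj <- which(marker_map$chrom == ci)
    jj <- jj[order(marker_map$pos_mb[jj])]
    reps <- integer(0)
    for (j in jj) {
      placed <- FALSE
      for (r in reps) {
        if (concord(G[, j], G[, r]) >= threshold) {
          placed <- TRUE
          break
        }
      }
      if (!placed) reps <- c(reps, j)
    }
    retained <- c(retained, reps)
  }
  sort(retained)
}
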