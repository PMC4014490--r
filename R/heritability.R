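# Allelic-correlation kinship and single-component REML heritability.
#
# The mixed model is y = 1*mu + g + e with cov(g) = sigma_g^2 * K and
# cov(e) = sigma_e^2 * I.  K is built from standardized genotypes so that
# its diagonal averages ~1 and h2 = sigma_g^2 / (sigma_g^2 + sigma_e^2) is
# the narrow-sense heritability tagged by the markers.

#' Allelic-correlation kinship matrix
#'
#' Computes `K = Z Z' / m` where `Z` standardizes each genotype column by
#' its sample allele frequency: `z = (g - 2p) / sqrt(2 p (1 - p))`.
#' Monomorphic markers carry no relatedness information and are dropped
#' (and counted).
#'
#' @param G genotype matrix, individuals x markers, values 0/1/2.
#' @return object of class `kinship_matrix`: list with `K` (n x n),
#'   `m_used` (polymorphic marker count) and `freq` (allele frequencies of
#'   the markers used).
#' @export
kinship_allelic_corr <- function(G) {
  G <- as.matrix(G)
  if (nrow(G) < 2 || ncol(G) < 2) {
    stop("need >= 2 individuals and >= 2 markers", call. = FALSE)
  }
  p <- colMeans(G) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("all markers are monomorphic", call. = FALSE)
  Gp <- G[, poly, drop = FALSE]
  pp <- p[poly]
  Z <- sweep(Gp, 2, 2 * pp, `-`)
  Z <- sweep(Z, 2, sqrt(2 * pp * (1 - pp)), `/`)
  K <- tcrossprod(Z) / ncol(Z)
  K <- (K + t(K)) / 2
  structure(
    list(K = K, m_used = ncol(Z), freq = unname(pp)),
    class = "kinship_matrix"
  )
}

# REML log-likelihood profile in the variance ratio lambda = sg2/se2,
# on the eigenbasis of K.  `d` are K's eigenvalues, `yr` the rotated
# phenotype, `xr` the rotated intercept column.
.reml_profile <- function(log_lambda, d, yr, xr) {
  lam <- exp(log_lambda)
  w <- lam * d + 1          # V = se2 * diag(w) on the eigenbasis
  xwx <- sum(xr^2 / w)
  xwy <- sum(xr * yr / w)
  beta <- xwy / xwx
  r <- yr - beta * xr
  rss <- sum(r^2 / w)
  n <- length(yr)
  se2 <- rss / (n - 1)      # REML estimate given lambda
  -0.5 * ((n - 1) * log(2 * pi * se2) + sum(log(w)) + log(xwx) + (n - 1))
}

#' REML heritability under a single-kinship mixed model
#'
#' Maximizes the restricted likelihood of `y ~ intercept + g + e`,
#' `cov(g) = sigma_g^2 K`, `cov(e) = sigma_e^2 I`, over the variance ratio
#' `lambda = sigma_g^2 / sigma_e^2`.  One eigendecomposition of K reduces
#' every likelihood evaluation to O(n); lambda is profiled on a log2 grid
#' spanning `2^-14 .. 2^14` and refined by golden-section search.  When the
#' profile is flat (e.g. K = I) the ratio is unidentifiable: the function
#' warns, reports `h2 = 0` and sets `converged = FALSE`.
#'
#' @param y numeric phenotype vector (standardized or not; h2 is scale
#'   invariant).
#' @param K a `kinship_matrix` or a plain symmetric PSD matrix.
#' @param eig_tol negative-eigenvalue tolerance before K is rejected;
#'   eigenvalues in `(-eig_tol, 0)` are clipped to 0. Default 1e-8.
#' @return object of class `variance_components`: list with `sigma_g2`,
#'   `sigma_e2`, `h2`, `reml_loglik`, `converged`.
#' @export
reml_h2 <- function(y, K, eig_tol = 1e-8) {
  if (inherits(K, "kinship_matrix")) K <- K$K
  K <- as.matrix(K)
  if (any(!is.finite(y))) stop("`y` contains non-finite values", call. = FALSE)
  n <- length(y)
  if (nrow(K) != n) stop("dimensions of `y` and `K` disagree", call. = FALSE)

  eig <- eigen(K, symmetric = TRUE)
  if (min(eig$values) < -eig_tol * max(1, max(abs(eig$values)))) {
    stop("kinship matrix is not positive semi-definite", call. = FALSE)
  }
  d <- pmax(eig$values, 0)
  yr <- as.numeric(crossprod(eig$vectors, y))
  xr <- as.numeric(crossprod(eig$vectors, rep(1, n)))

  grid <- seq(-14, 14, by = 0.5) * log(2)
  ll <- vapply(grid, .reml_profile, numeric(1), d = d, yr = yr, xr = xr)

  if (diff(range(ll)) < 1e-8) {
    warning("REML profile is flat in the variance ratio; h2 unidentifiable",
            call. = FALSE)
    se2 <- stats::var(y)
    return(structure(
      list(sigma_g2 = 0, sigma_e2 = se2, h2 = 0,
           reml_loglik = ll[1L], converged = FALSE),
      class = "variance_components"
    ))
  }

  i <- which.max(ll)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(.reml_profile, c(lo, hi), d = d, yr = yr, xr = xr,
                         maximum = TRUE, tol = 1e-8)
  # boundary behaviour: if the grid maximum sits at an endpoint and beats the
  # interior refinement, h2 is effectively 0 or 1
  if (ll[i] > opt$objective) {
    opt <- list(maximum = grid[i], objective = ll[i])
  }
  lam <- exp(opt$maximum)
  w <- lam * d + 1
  xwx <- sum(xr^2 / w)
  beta <- sum(xr * yr / w) / xwx
  rss <- sum((yr - beta * xr)^2 / w)
  se2 <- rss / (n - 1)
  sg2 <- lam * se2
  structure(
    list(sigma_g2 = sg2, sigma_e2 = se2, h2 = sg2 / (sg2 + se2),
         reml_loglik = opt$objective, converged = TRUE),
    class = "variance_components"
  )
}

# Dense-matrix REML log-likelihood (no eigen shortcut); used as an
# independent numerical cross-check on small problems.
reml_loglik_dense <- function(y, K, lambda) {
  n <- length(y)
  V <- lambda * K + diag(n)
  x <- matrix(1, n, 1)
  Vi <- solve(V)
  xvx <- as.numeric(t(x) %*% Vi %*% x)
  beta <- as.numeric(t(x) %*% Vi %*% y) / xvx
  r <- y - beta
  rss <- as.numeric(t(r) %*% Vi %*% r)
  se2 <- rss / (n - 1)
  -0.5 * ((n - 1) * log(2 * pi * se2) + determinant(V)$modulus[1] +
            log(xvx) + (n - 1))
}
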