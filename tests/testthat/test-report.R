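# Downstream report statistics: permutation calibration, cross-mapper
# matching, rank-sum and correlation kernels, histograms.

test_that("permutation calibration is deterministic and respects the threshold", {
  set.seed(1)
  tp <- toy_predictors(120, 6, seed = 11)
  y <- std(0.6 * tp$G[, 1] + rnorm(120))
  dat <- sp_predictors(tp$G, tp$sex)
  cfg <- sp_config(iterations = 150, burn_in = 30, seed = 2)
  a <- permutation_fdr(y, dat, cfg, threshold = 0.2, seed = 3)
  b <- permutation_fdr(y, dat, cfg, threshold = 0.2, seed = 3)
  expect_identical(a$expected_false_positives, b$expected_false_positives)
  expect_gte(a$expected_false_positives, 0L)
  # an unattainable threshold counts nothing
  z <- permutation_fdr(y, dat, cfg, threshold = 1.01, seed = 3)
  expect_identical(z$expected_false_positives, 0L)
})

test_that("QTL matching honours the expanded confidence-interval window", {
  peaks <- data.frame(locus = 1L, chrom = 1L, pos_mb = 28, rmip = 0.8,
                      ci_lo = 27.5, ci_hi = 28.5)
  call_in <- data.frame(snp = "a", chrom = 1L, pos_mb = 30.0)
  call_out <- data.frame(snp = "b", chrom = 1L, pos_mb = 31.0)
  m_in <- match_qtl(call_in, peaks, window_mb = 2)
  expect_equal(nrow(m_in$matched), 1L)
  m_out <- match_qtl(call_out, peaks, window_mb = 2)
  expect_equal(nrow(m_out$matched), 0L)
  expect_equal(m_out$unmatched_calls, 1L)
  # different chromosome never matches
  call_chr <- data.frame(snp = "c", chrom = 2L, pos_mb = 28)
  expect_equal(nrow(match_qtl(call_chr, peaks, window_mb = 2)$matched), 0L)
})

test_that("greedy matching assigns each peak once, nearest first", {
  peaks <- data.frame(locus = 1L, chrom = 1L, pos_mb = 50, rmip = 0.9,
                      ci_lo = 49, ci_hi = 51)
  calls <- data.frame(snp = c("near", "far"), chrom = 1L, pos_mb = c(51.5, 52.9))
  m <- match_qtl(calls, peaks, window_mb = 2)
  expect_equal(nrow(m$matched), 1L)
  expect_equal(m$matched$call, 1L)          # the nearer call wins the peak
  expect_equal(m$unmatched_calls, 2L)
  # shrinking the window never increases the matched count
  m_small <- match_qtl(calls, peaks, window_mb = 0.2)
  expect_lte(nrow(m_small$matched), nrow(m$matched))
})

test_that("a peak without a CI falls back to plain distance matching", {
  peaks <- data.frame(locus = 1L, chrom = 1L, pos_mb = 28, rmip = 0.5,
                      ci_lo = NA_real_, ci_hi = NA_real_)
  call <- data.frame(snp = "a", chrom = 1L, pos_mb = 29.5)
  expect_equal(nrow(match_qtl(call, peaks, window_mb = 2)$matched), 1L)
  expect_equal(nrow(match_qtl(call, peaks, window_mb = 1)$matched), 0L)
})

test_that("GxS calls are classified by single-sex peak support", {
  mk_scan <- function(subset, pos, rmip = 0.6) {
    structure(list(
      peaks = data.frame(locus = 1L, chrom = 1L, pos_mb = pos, rmip = rmip,
                         ci_lo = pos - 1, ci_hi = pos + 1),
      sex_subset = subset, n_boot = 100L
    ), class = "rmip_result")
  }
  gxs <- data.frame(snp = "g", chrom = 1L, pos_mb = 50)
  out <- match_gxs_single_sex(gxs, mk_scan("male", 54), mk_scan("female", 80))
  expect_identical(out$single_sex_support, "male-only")
  out2 <- match_gxs_single_sex(gxs, mk_scan("male", 54), mk_scan("female", 47))
  expect_identical(out2$single_sex_support, "both")
  out3 <- match_gxs_single_sex(gxs, mk_scan("male", 80), mk_scan("female", 80))
  expect_identical(out3$single_sex_support, "neither")
  # weak peaks below the RMIP threshold do not count
  out4 <- match_gxs_single_sex(gxs, mk_scan("male", 50, rmip = 0.1),
                               mk_scan("female", 80))
  expect_identical(out4$single_sex_support, "neither")
  expect_error(match_gxs_single_sex(gxs, mk_scan("both", 50), mk_scan("female", 80)),
               "sex_subset")
})

test_that("rank-sum statistic and exact p match full enumeration", {
  r <- rank_sum_compare(c(1, 2), c(3, 4))
  expect_equal(r$W, 3)
  expect_equal(r$p, 2 / 6, tolerance = 1e-12)
  r2 <- rank_sum_compare(c(5, 6, 7), c(1, 2, 3))
  expect_equal(r2$W, 15)
  expect_equal(r2$p, 0.1, tolerance = 1e-12)
  # identical groups are unremarkable
  expect_gte(rank_sum_compare(c(1, 2, 3), c(1, 2, 3))$p, 0.9)
  expect_error(rank_sum_compare(numeric(0), 1), "non-empty")
})

test_that("exact p agrees with an independent enumeration for all small splits", {
  set.seed(2)
  for (na in 1:5) {
    for (nb in 1:(10 - na)) {
      if (nb < 1) next
      a <- sample(20, na)
      b <- sample(20, nb)
      got <- rank_sum_compare(a, b)
      # independent oracle: enumerate every assignment of pooled values
      pooled <- c(a, b)
      rk <- rank(pooled)
      N <- na + nb
      combos <- utils::combn(N, na)
      Ws <- apply(combos, 2, function(ix) sum(rk[ix]))
      W_obs <- sum(rk[seq_len(na)])
      p_exact <- min(1, 2 * min(mean(Ws <= W_obs), mean(Ws >= W_obs)))
      expect_equal(got$W, W_obs)
      expect_equal(got$p, p_exact, tolerance = 1e-12)
    }
  }
})

test_that("large-sample rank-sum p approximates the exact tail", {
  set.seed(3)
  a <- rnorm(30); b <- rnorm(25, mean = 1)
  got <- rank_sum_compare(a, b)
  ref <- stats::wilcox.test(a, b, exact = FALSE, correct = FALSE)
  expect_equal(got$p, ref$p.value, tolerance = 1e-10)
})

test_that("sex-effect variance spans its extremes and complements residual", {
  set.seed(4)
  sex <- rbinom(1000, 1, 0.5)
  y_null <- rnorm(1000)
  expect_lt(sex_effect_variance(y_null, sex), 1)
  # lm warns about the perfect fit; the value itself is what matters here
  expect_equal(suppressWarnings(sex_effect_variance(as.numeric(sex), sex)),
               100, tolerance = 1e-9)
  y <- 0.8 * sex + rnorm(1000)
  fit <- stats::lm(y ~ sex)
  pve <- sex_effect_variance(y, sex)
  resid_share <- 100 * sum(stats::resid(fit)^2) / sum((y - mean(y))^2)
  expect_equal(pve + resid_share, 100, tolerance = 1e-9)
  expect_error(sex_effect_variance(y, rep(1, 1000)), "both sexes")
})

test_that("correlation report computes r, t and df = n - 2", {
  x <- 1:15
  expect_equal(correlate_with_t(x, x)$r, 1, tolerance = 1e-12)
  set.seed(5)
  a <- rnorm(15); b <- 0.6 * a + rnorm(15, sd = 0.8)
  rep <- correlate_with_t(a, b)
  expect_equal(rep$df, 13L)
  expect_equal(rep$t_stat, rep$r * sqrt(13 / (1 - rep$r^2)), tolerance = 1e-12)
  # cross-check the parametric p against a permutation null
  perm <- vapply(1:4000, function(i) abs(stats::cor(a, sample(b))), numeric(1))
  p_perm <- mean(perm >= abs(rep$r))
  expect_lt(abs(rep$p - p_perm), 0.05)
  expect_error(correlate_with_t(a, rep(1, 15)), "zero variance")
})

test_that("null correlations reject at close to the nominal 5% rate", {
  set.seed(6)
  rejections <- mean(vapply(1:1000, function(i) {
    correlate_with_t(rnorm(15), rnorm(15))$p < 0.05
  }, logical(1)))
  expect_lt(abs(rejections - 0.05), 0.02)
})

test_that("probability histogram applies its floor and binning rules", {
  h0 <- probability_histogram(c(0.04))
  expect_equal(sum(h0$count), 0)
  h <- probability_histogram(c(0.21, 0.22), bin_width = 0.05)
  hit <- h[h$count > 0, ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$bin_lo, 0.20)
  expect_equal(hit$count, 2)
  set.seed(7)
  v <- runif(200)
  hh <- probability_histogram(v, floor = 0.05)
  expect_equal(sum(hh$count), sum(v >= 0.05))
  expect_error(probability_histogram(c(-0.1)), "0, 1")
})
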