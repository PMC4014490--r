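# Shared small fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

# a small HS population reused across unit tests
small_pop <- function() {
  if (is.null(.fixture_env$pop)) {
    fp <- simulate_founders(50, 0.15, 0.5, chrom_sizes = c(60, 40), seed = 101)
    .fixture_env$pop <- simulate_hs_population(fp, n = 160, generations = 12,
                                               seed = 102)
  }
  .fixture_env$pop
}

# independent SNPs + sex for mapper tests (no linkage, fast)
toy_predictors <- function(n, p, seed, freq = 0.4) {
  set.seed(seed)
  G <- matrix(stats::rbinom(n * p, 2, freq), n, p,
              dimnames = list(NULL, sprintf("s%02d", seq_len(p))))
  sex <- stats::rbinom(n, 1, 0.5)
  list(G = G, sex = sex)
}

toy_map <- function(G, spacing_mb = 10, chrom = 1L) {
  data.frame(marker = colnames(G), chrom = chrom,
             pos_mb = spacing_mb * seq_len(ncol(G)))
}

std <- function(y) (y - mean(y)) / stats::sd(y)
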