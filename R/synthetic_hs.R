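# Synthetic heterogeneous-stock (HS) population generator.
#
# An HS population descends from 8 inbred founders through many generations
# of pseudo-random mating, so each chromosome is a fine-grained mosaic of
# founder haplotypes.  The generator simulates that pedigree forward and
# records, for every individual and marker, the true founder of origin of
# both homologues.  Downstream mappers can therefore be validated against
# exact ground truth.

#' Simulate a biallelic founder panel
#'
#' Draws allele assignments for 8 inbred founders at `m` markers placed on
#' chromosomes of the given sizes.  For each marker a target population
#' minor-allele frequency is drawn uniformly from `[maf_low, maf_high]` and
#' rounded to the nearest achievable founder count: because every HS
#' chromosome is (marginally) a uniform draw from the 8 founders, the
#' expected population allele frequency equals the founder-panel frequency,
#' which is granular in eighths.  The rounded count is clamped to 1..7 so no
#' marker is monomorphic in the panel.
#'
#' @param m number of markers (>= 1).
#' @param maf_low,maf_high bounds for the target minor-allele frequency,
#'   `0 < maf_low <= maf_high <= 0.5`.
#' @param chrom_sizes numeric vector of chromosome lengths in Mbp; markers
#'   are apportioned proportionally to length.
#' @param seed integer master seed.
#' @return an object of class `founder_panel`: list with `alleles`
#'   (8 x m 0/1 matrix), `marker_map` (data.frame: `marker`, `chrom`,
#'   `pos_mb`, strictly increasing within chromosome) and `chrom_sizes`.
#' @export
simulate_founders <- function(m, maf_low = 0.05, maf_high = 0.5,
                              chrom_sizes = c(100), seed = 1L) {
  stopifnot_scalar_number(m, "m")
  if (m < 1) stop("`m` must be >= 1", call. = FALSE)
  if (!(maf_low > 0 && maf_low <= maf_high && maf_high <= 0.5)) {
    stop("need 0 < maf_low <= maf_high <= 0.5", call. = FALSE)
  }
  if (any(chrom_sizes <= 0)) stop("chromosome sizes must be positive", call. = FALSE)
  m <- as.integer(m)

  with_seed(child_seed(seed, 1L), {
    # apportion markers to chromosomes by length (largest remainder)
    frac <- chrom_sizes / sum(chrom_sizes)
    m_c <- floor(frac * m)
    rem <- m - sum(m_c)
    if (rem > 0) {
      extra <- order(frac * m - m_c, decreasing = TRUE)[seq_len(rem)]
      m_c[extra] <- m_c[extra] + 1L
    }
    # at least one marker on every chromosome that got zero by rounding
    while (any(m_c == 0) && m >= length(chrom_sizes)) {
      donor <- which.max(m_c)
      recip <- which(m_c == 0)[1L]
      m_c[donor] <- m_c[donor] - 1L
      m_c[recip] <- 1L
    }

    chrom <- rep(seq_along(chrom_sizes), m_c)
    pos <- unlist(lapply(seq_along(chrom_sizes), function(ci) {
      if (m_c[ci] == 0) return(numeric(0))
      p <- sort(stats::runif(m_c[ci], 0, chrom_sizes[ci]))
      # enforce strict increase (ties have probability zero, but be safe)
      while (anyDuplicated(p)) p <- sort(stats::runif(m_c[ci], 0, chrom_sizes[ci]))
      p
    }))

    u <- stats::runif(m, maf_low, maf_high)
    carriers <- pmin(7L, pmax(1L, as.integer(round(8 * u))))
    alleles <- matrix(0L, nrow = 8L, ncol = m)
    for (j in seq_len(m)) {
      alleles[sample.int(8L, carriers[j]), j] <- 1L
    }

    map <- data.frame(
      marker = sprintf("snp%05d", seq_len(m)),
      chrom = chrom,
      pos_mb = pos,
      stringsAsFactors = FALSE
    )
    structure(
      list(alleles = alleles, marker_map = map, chrom_sizes = chrom_sizes),
      class = "founder_panel"
    )
  })
}

# -- chromosome mosaics -------------------------------------------------------
# A homologue is a run-length mosaic: list(ends, founder), where segment k
# covers (ends[k-1], ends[k]] with ends[0] = 0 and ends[last] = chromosome
# length.

# slice a homologue over the interval (a, b]
.slice_homolog <- function(h, a, b) {
  ends <- h$ends
  j0 <- findInterval(a, ends, left.open = FALSE) + 1L
  j1 <- findInterval(b, ends, left.open = TRUE) + 1L
  j1 <- min(j1, length(ends))
  idx <- j0:j1
  list(ends = c(utils::head(ends[idx], -1L), b), founder = h$founder[idx])
}

# one meiosis: recombine two homologues into a gamete
.gamete <- function(h1, h2, len, recomb_per_mb) {
  ncx <- stats::rpois(1L, recomb_per_mb * len)
  if (ncx == 0L) {
    return(if (stats::runif(1) < 0.5) h1 else h2)
  }
  cx <- sort(stats::runif(ncx, 0, len))
  bounds <- c(0, cx, len)
  cur <- sample.int(2L, 1L)
  ends <- numeric(0)
  founder <- integer(0)
  for (k in seq_len(length(bounds) - 1L)) {
    src <- if ((cur + k) %% 2L == 0L) h1 else h2
    sl <- .slice_homolog(src, bounds[k], bounds[k + 1L])
    ends <- c(ends, sl$ends)
    founder <- c(founder, sl$founder)
  }
  # merge adjacent segments with the same founder
  keep <- c(founder[-length(founder)] != founder[-1L], TRUE)
  list(ends = ends[keep], founder = founder[keep])
}

# founder of origin at marker positions for one homologue
.founder_at <- function(h, pos) {
  idx <- findInterval(pos, h$ends, left.open = TRUE) + 1L
  h$founder[pmin(idx, length(h$founder))]
}

#' Simulate an HS population of founder mosaics
#'
#' Runs a discrete-generation random-mating pedigree seeded from the 8
#' founders.  Each offspring chromosome is produced by meiosis from a random
#' pair of distinct parents, with crossovers Poisson in map distance
#' (`recomb_per_mb` x interval length).  After `generations` rounds every
#' chromosome is a mosaic of founder haplotypes whose expected block length
#' shrinks as generations accumulate.  The true founder of origin of both
#' homologues is recorded at every marker.
#'
#' @param founders a `founder_panel` from [simulate_founders()].
#' @param n number of individuals (>= 2); population size is held constant
#'   across generations.
#' @param generations number of random-mating generations (>= 1); the default
#'   50 gives block lengths comparable to a real HS at 1 cM/Mb.
#' @param recomb_per_mb expected crossovers per Mbp per meiosis (> 0);
#'   0.01 corresponds to the rough mouse genome-wide average of 1 cM/Mb.
#' @param pct_male probability that an individual is male.
#' @param ancestry_noise optional mixing weight in `[0, 1)`: soft ancestry
#'   dosages are `(1 - w) * truth + w * 2 * Dirichlet(1, ..., 1)`, emulating
#'   probabilistic haplotype reconstruction. Default 0 (exact dosages).
#' @param seed integer master seed.
#' @return an object of class `hs_population`: list with `genotypes`
#'   (n x m integer 0/1/2), `ancestry` (n x m x 8 dosage array, every slice
#'   summing to 2), `founder_of_origin` (list of two n x m integer matrices,
#'   the true homologue assignments), `sex` (0/1, 1 = male), `marker_map`,
#'   `founders`, `pedigree_depth` and `duplicate_of` (NA for all markers
#'   until [add_redundant_snps()] is used).
#' @export
simulate_hs_population <- function(founders, n, generations = 50L,
                                   recomb_per_mb = 0.01, pct_male = 0.519,
                                   ancestry_noise = 0, seed = 1L) {
  if (!inherits(founders, "founder_panel")) {
    stop("`founders` must be a founder_panel", call. = FALSE)
  }
  stopifnot_scalar_number(n, "n")
  if (n < 2) stop("`n` must be >= 2", call. = FALSE)
  if (generations < 1) stop("`generations` must be >= 1", call. = FALSE)
  if (recomb_per_mb <= 0) stop("`recomb_per_mb` must be > 0", call. = FALSE)
  if (ancestry_noise < 0 || ancestry_noise >= 1) {
    stop("`ancestry_noise` must be in [0, 1)", call. = FALSE)
  }
  n <- as.integer(n)
  generations <- as.integer(generations)
  map <- founders$marker_map
  m <- nrow(map)
  chrom_ids <- seq_along(founders$chrom_sizes)

  pop <- with_seed(child_seed(seed, 2L), {
    # haplotypes[[chrom]][[ind]] = list(h1, h2)
    haplotypes <- lapply(chrom_ids, function(ci) {
      len <- founders$chrom_sizes[ci]
      lapply(seq_len(n), function(i) {
        list(
          list(ends = len, founder = sample.int(8L, 1L)),
          list(ends = len, founder = sample.int(8L, 1L))
        )
      })
    })
    for (g in seq_len(generations)) {
      # one shared pedigree per generation: the same parent pairs are used
      # for every chromosome, so relatedness is genome-wide
      dams <- sample.int(n, n, replace = TRUE)
      sires <- vapply(dams, function(d) {
        s <- sample.int(n, 1L)
        while (s == d && n > 1L) s <- sample.int(n, 1L)
        s
      }, integer(1))
      for (ci in chrom_ids) {
        len <- founders$chrom_sizes[ci]
        old <- haplotypes[[ci]]
        haplotypes[[ci]] <- lapply(seq_len(n), function(i) {
          p1 <- old[[dams[i]]]
          p2 <- old[[sires[i]]]
          list(
            .gamete(p1[[1L]], p1[[2L]], len, recomb_per_mb),
            .gamete(p2[[1L]], p2[[2L]], len, recomb_per_mb)
          )
        })
      }
    }
    haplotypes
  })

  # true founder of origin at each marker
  f1 <- matrix(0L, n, m)
  f2 <- matrix(0L, n, m)
  for (ci in chrom_ids) {
    jj <- which(map$chrom == ci)
    if (!length(jj)) next
    pos <- map$pos_mb[jj]
    for (i in seq_len(n)) {
      f1[i, jj] <- .founder_at(pop[[ci]][[i]][[1L]], pos)
      f2[i, jj] <- .founder_at(pop[[ci]][[i]][[2L]], pos)
    }
  }

  geno <- matrix(0L, n, m, dimnames = list(NULL, map$marker))
  for (j in seq_len(m)) {
    al <- founders$alleles[, j]
    geno[, j] <- al[f1[, j]] + al[f2[, j]]
  }

  ancestry <- array(0, dim = c(n, m, 8L))
  for (k in 1:8) {
    ancestry[, , k] <- (f1 == k) + (f2 == k)
  }
  if (ancestry_noise > 0) {
    ancestry <- with_seed(child_seed(seed, 3L), {
      e <- array(stats::rgamma(n * m * 8L, shape = 1), dim = c(n, m, 8L))
      tot <- array(rep(apply(e, c(1, 2), sum), times = 8L), dim = dim(e))
      (1 - ancestry_noise) * ancestry + ancestry_noise * 2 * e / tot
    })
  }

  sex <- with_seed(child_seed(seed, 4L), stats::rbinom(n, 1L, pct_male))

  structure(
    list(
      genotypes = geno,
      ancestry = ancestry,
      founder_of_origin = list(f1, f2),
      sex = as.integer(sex),
      marker_map = map,
      founders = founders,
      pedigree_depth = generations,
      duplicate_of = rep(NA_integer_, m)
    ),
    class = "hs_population"
  )
}

#' Plant near-duplicate markers in an HS population
#'
#' Duplicates a fraction of markers, flipping a small share of genotype
#' entries in each copy, so that concordance-based pruning has realistic
#' redundant SNPs to remove.  Duplicates are placed immediately after their
#' originals on the map.  Flipped entries deliberately break the
#' ancestry-genotype identity for the copies, as genotyping redundancy
#' would in real data.
#'
#' @param pop an `hs_population`.
#' @param fraction fraction of markers to duplicate (in `[0, 1]`).
#' @param discordance per-entry probability of a discordant genotype in the
#'   copy; default 0.005 keeps expected discordance below 1%.
#' @param seed integer seed.
#' @return the augmented `hs_population`; `duplicate_of` holds the column
#'   index of the original for every planted copy.
#' @export
add_redundant_snps <- function(pop, fraction = 0.2, discordance = 0.005,
                               seed = 1L) {
  stopifnot(inherits(pop, "hs_population"))
  if (fraction < 0 || fraction > 1) stop("`fraction` must be in [0, 1]", call. = FALSE)
  m <- ncol(pop$genotypes)
  ndup <- as.integer(floor(fraction * m))
  if (ndup == 0L) return(pop)
  n <- nrow(pop$genotypes)

  with_seed(child_seed(seed, 5L), {
    originals <- sort(sample.int(m, ndup))
    newg <- pop$genotypes[, originals, drop = FALSE]
    for (k in seq_len(ndup)) {
      flip <- which(stats::runif(n) < discordance)
      for (i in flip) {
        newg[i, k] <- sample(setdiff(0:2, newg[i, k]), 1L)
      }
    }
    # interleave copies right after originals
    order_idx <- order(c(seq_len(m), originals + 0.5))
    map <- pop$marker_map
    dup_map <- map[originals, , drop = FALSE]
    # nudge the copy between its original and the next marker
    next_pos <- vapply(originals, function(j) {
      same <- which(map$chrom == map$chrom[j] & map$pos_mb > map$pos_mb[j])
      if (length(same)) min(map$pos_mb[same]) else map$pos_mb[j] + 0.02
    }, numeric(1))
    dup_map$pos_mb <- (map$pos_mb[originals] + next_pos) / 2
    dup_map$marker <- paste0(map$marker[originals], "_dup")

    all_g <- cbind(pop$genotypes, newg)[, order_idx, drop = FALSE]
    all_map <- rbind(map, dup_map)[order_idx, , drop = FALSE]
    rownames(all_map) <- NULL
    colnames(all_g) <- all_map$marker
    all_anc <- array(0, dim = c(n, m + ndup, 8L))
    all_anc[, , ] <- pop$ancestry[, c(seq_len(m), originals)[order_idx], , drop = FALSE]
    f1 <- pop$founder_of_origin[[1]][, c(seq_len(m), originals)[order_idx], drop = FALSE]
    f2 <- pop$founder_of_origin[[2]][, c(seq_len(m), originals)[order_idx], drop = FALSE]
    dup_of <- c(rep(NA_integer_, m), originals)[order_idx]
    # re-express original indices in the new column order
    dup_of <- match(pop$marker_map$marker[dup_of], all_map$marker)

    pop$genotypes <- all_g
    pop$ancestry <- all_anc
    pop$founder_of_origin <- list(f1, f2)
    pop$marker_map <- all_map
    pop$duplicate_of <- dup_of
    pop
  })
}

#' Specify a generative phenotype model for an HS population
#'
#' Collects the effect classes a phenotype can carry: a sex main effect,
#' additive QTL, sex-specific (GxS) QTL whose additive effect applies in one
#' sex only, epistatic (GxG) pairs with an arbitrary 3 x 3 joint-genotype
#' effect table, a polygenic component with covariance proportional to the
#' allelic-correlation kinship, and independent Gaussian noise.
#'
#' @param mu intercept.
#' @param beta_sex additive effect of being male.
#' @param main_qtl data.frame with columns `marker` (column index) and
#'   `effect` (additive effect per allele copy), or NULL.
#' @param gxs_qtl data.frame with columns `marker`, `effect` and `sex`
#'   (0 or 1: the sex in which the additive effect applies), or NULL.
#' @param gxg_qtl list of `list(a =, b =, table =)` entries, `table` a 3 x 3
#'   matrix indexed by (genotype a + 1, genotype b + 1), or NULL.
#' @param h2_polygenic polygenic variance fraction relative to
#'   polygenic-plus-noise, in `[0, 1)`.
#' @param sigma_e residual standard deviation (> 0).
#' @param seed integer seed for the stochastic components.
#' @return an object of class `phenotype_spec`.
#' @export
phenotype_spec <- function(mu = 0, beta_sex = 0, main_qtl = NULL,
                           gxs_qtl = NULL, gxg_qtl = NULL,
                           h2_polygenic = 0, sigma_e = 1, seed = 1L) {
  if (h2_polygenic < 0 || h2_polygenic >= 1) {
    stop("`h2_polygenic` must be in [0, 1)", call. = FALSE)
  }
  if (sigma_e <= 0) stop("`sigma_e` must be > 0", call. = FALSE)
  structure(
    list(mu = mu, beta_sex = beta_sex, main_qtl = main_qtl,
         gxs_qtl = gxs_qtl, gxg_qtl = gxg_qtl,
         h2_polygenic = h2_polygenic, sigma_e = sigma_e, seed = as.integer(seed)),
    class = "phenotype_spec"
  )
}

#' Simulate a phenotype with known architecture
#'
#' Realizes `y = mu + beta_sex * sex + sum(additive QTL) + sum(GxS terms) +
#' sum(GxG joint-genotype terms) + polygenic + noise` on an HS population.
#' The polygenic component is multivariate normal with covariance
#' `sigma_g^2 * K` where `K` is the allelic-correlation kinship of the
#' population's genotypes and `sigma_g^2 = sigma_e^2 * h2 / (1 - h2)`.
#'
#' @param pop an `hs_population`.
#' @param spec a [phenotype_spec()].
#' @return list with `y` (numeric length n), `components` (matrix of the
#'   realized effect-class contributions) and `var_share` (each component's
#'   realized share of `var(y)`).
#' @export
simulate_phenotype <- function(pop, spec) {
  stopifnot(inherits(pop, "hs_population"), inherits(spec, "phenotype_spec"))
  n <- nrow(pop$genotypes)
  m <- ncol(pop$genotypes)
  check_idx <- function(ix) {
    if (any(ix < 1 | ix > m)) stop("marker index out of range", call. = FALSE)
  }

  comp <- list()
  comp$sex <- spec$beta_sex * pop$sex

  main <- numeric(n)
  if (!is.null(spec$main_qtl) && nrow(spec$main_qtl)) {
    check_idx(spec$main_qtl$marker)
    for (r in seq_len(nrow(spec$main_qtl))) {
      main <- main + spec$main_qtl$effect[r] * pop$genotypes[, spec$main_qtl$marker[r]]
    }
  }
  comp$main <- main

  gxs <- numeric(n)
  if (!is.null(spec$gxs_qtl) && nrow(spec$gxs_qtl)) {
    check_idx(spec$gxs_qtl$marker)
    for (r in seq_len(nrow(spec$gxs_qtl))) {
      in_sex <- as.numeric(pop$sex == spec$gxs_qtl$sex[r])
      gxs <- gxs + spec$gxs_qtl$effect[r] * pop$genotypes[, spec$gxs_qtl$marker[r]] * in_sex
    }
  }
  comp$gxs <- gxs

  gxg <- numeric(n)
  if (length(spec$gxg_qtl)) {
    for (term in spec$gxg_qtl) {
      check_idx(c(term$a, term$b))
      ga <- pop$genotypes[, term$a] + 1L
      gb <- pop$genotypes[, term$b] + 1L
      gxg <- gxg + term$table[cbind(ga, gb)]
    }
  }
  comp$gxg <- gxg

  comp$polygenic <- numeric(n)
  if (spec$h2_polygenic > 0) {
    K <- kinship_allelic_corr(pop$genotypes)$K
    eig <- eigen(K, symmetric = TRUE)
    sd_g <- spec$sigma_e * sqrt(spec$h2_polygenic / (1 - spec$h2_polygenic))
    comp$polygenic <- with_seed(child_seed(spec$seed, 6L), {
      z <- stats::rnorm(n)
      as.numeric(eig$vectors %*% (sqrt(pmax(eig$values, 0)) * z)) * sd_g
    })
  }

  comp$noise <- with_seed(child_seed(spec$seed, 7L),
                          stats::rnorm(n, 0, spec$sigma_e))

  y <- spec$mu + Reduce(`+`, comp)
  cm <- do.call(cbind, comp)
  vy <- stats::var(y)
  var_share <- apply(cm, 2, stats::var) / vy
  list(y = y, components = cm, var_share = var_share)
}

#' Write an HS dataset as delimited text
#'
#' Emits `genotypes.tsv` (individuals x markers), `map.tsv`
#' (marker, chrom, pos_mb), one `ancestry_chr<k>.tsv` per chromosome
#' (columns `<marker>_f<founder>`), `phenotypes.csv` (id, sex and any
#' phenotype columns) and a `manifest.yaml` recording the generation seed
#' and dimensions.
#'
#' @param pop an `hs_population`.
#' @param dir output directory, created if needed.
#' @param phenotypes optional data.frame of phenotype columns (length n).
#' @param manifest optional named list merged into the manifest.
#' @return `dir`, invisibly.
#' @export
write_hs_data <- function(pop, dir, phenotypes = NULL, manifest = list()) {
  stopifnot(inherits(pop, "hs_population"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- nrow(pop$genotypes)

  utils::write.table(pop$genotypes, file.path(dir, "genotypes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(pop$marker_map, file.path(dir, "map.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (ci in unique(pop$marker_map$chrom)) {
    jj <- which(pop$marker_map$chrom == ci)
    wide <- matrix(pop$ancestry[, jj, , drop = FALSE], nrow = n)
    colnames(wide) <- as.vector(outer(pop$marker_map$marker[jj], 1:8,
                                      function(a, b) paste0(a, "_f", b)))
    utils::write.table(round(wide, 6), file.path(dir, sprintf("ancestry_chr%d.tsv", ci)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  ph <- data.frame(id = seq_len(n), sex = pop$sex)
  if (!is.null(phenotypes)) ph <- cbind(ph, phenotypes)
  utils::write.csv(ph, file.path(dir, "phenotypes.csv"), row.names = FALSE)

  man <- utils::modifyList(list(
    n = n, markers = ncol(pop$genotypes),
    chromosomes = length(unique(pop$marker_map$chrom)),
    pedigree_depth = pop$pedigree_depth
  ), manifest)
  yaml::write_yaml(man, file.path(dir, "manifest.yaml"))
  invisible(dir)
}
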