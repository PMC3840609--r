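test_that("pedigree structure follows the F2 design", {
  cfg <- sim_config(n_founders_per_breed = 2, n_f1 = 2, n_f2 = 4,
                    n_chromosomes = 1, snps_per_chromosome = 4, seed = 7)
  set.seed(7)
  ped <- simulate_pedigree(cfg)
  expect_equal(nrow(ped), 2 + 2 + 2 + 4)
  f2 <- ped[ped$generation == 2, ]
  f1 <- ped$id[ped$generation == 1]
  expect_true(all(f2$sire %in% f1) && all(f2$dam %in% f1))
  f1r <- ped[ped$generation == 1, ]
  expect_true(all(f1r$sire %in% ped$id[ped$pool == "A"]))
  expect_true(all(f1r$dam %in% ped$id[ped$pool == "B"]))

  # degenerate: no F2 generation is allowed
  set.seed(1)
  ped0 <- simulate_pedigree(sim_config(n_f2 = 0))
  expect_true(all(ped0$generation <= 1))

  expect_error(sim_config(n_founders_per_breed = 0))
})

test_that("simulated pedigrees are acyclic (ancestor-walk oracle)", {
  set.seed(11)
  for (i in 1:100) {
    cfg <- sim_config(n_founders_per_breed = sample(1:4, 1),
                      n_f1 = sample(1:6, 1), n_f2 = sample(0:10, 1))
    ped <- simulate_pedigree(cfg)
    for (id in ped$id)
      expect_false(id %in% ancestors_of(ped, id))
  }
})

test_that("gene drop is Mendelian-consistent at every SNP", {
  cfg <- sim_config(n_founders_per_breed = 4, n_f1 = 6, n_f2 = 20,
                    n_chromosomes = 2, snps_per_chromosome = 30, seed = 3)
  set.seed(3)
  ped <- simulate_pedigree(cfg)
  map <- make_snp_map(cfg)
  g <- simulate_genotypes(ped, map, cfg)
  kids <- ped[ped$sire != "0", ]
  for (i in seq_len(nrow(kids))) {
    gk <- g[kids$id[i], ]
    gs <- g[kids$sire[i], ]
    gd <- g[kids$dam[i], ]
    # an offspring allele count must be attainable from one allele per parent
    lo <- (gs == 1) + (gd == 1)   # minimum minor alleles transmissible
    hi <- 2 - ((gs == -1) + (gd == -1))
    expect_true(all(gk + 1 >= lo & gk + 1 <= hi))
  }
})

test_that("founder frequency 1/2 yields 1:2:1 F2 genotype proportions", {
  cfg <- sim_config(n_founders_per_breed = 50, n_f1 = 2000, n_f2 = 10000,
                    n_chromosomes = 1, snps_per_chromosome = 2,
                    founder_allele_freq_range = c(0.4999, 0.5001),
                    founder_divergent = FALSE, modules = list(), seed = 5)
  set.seed(5)
  ped <- simulate_pedigree(cfg)
  map <- make_snp_map(cfg)
  g <- simulate_genotypes(ped, map, cfg)
  z <- g[ped$id[ped$generation == 2], 1]
  props <- as.numeric(table(factor(z, levels = -1:1)) / length(z))
  expect_true(all(abs(props - c(0.25, 0.5, 0.25)) < 0.02))
})

test_that("zero map distance never recombines; LD decays with distance", {
  # two loci 0 cM apart always travel together in a gamete
  map0 <- data.frame(snp = c("a", "b"), chrom = "1", pos = c(1L, 2L),
                     cM = c(10, 10))
  chrs <- list(`1` = 1:2)
  set.seed(42)
  for (i in 1:200) {
    gam <- growthnet:::make_gamete(c(0L, 0L), c(1L, 1L), map0, chrs)
    expect_true(gam[1] == gam[2])
  }

  # pairwise r^2 falls with map distance (rank-monotone over distance bins)
  cfg <- sim_config(n_f1 = 40, n_f2 = 500, n_chromosomes = 1,
                    snps_per_chromosome = 50, modules = list(), seed = 9)
  set.seed(9)
  ped <- simulate_pedigree(cfg)
  map <- make_snp_map(cfg)
  g <- simulate_genotypes(ped, map, cfg)
  z <- g[ped$id[ped$generation == 2], ]
  r2 <- cor(z)^2
  d <- abs(outer(map$cM, map$cM, "-"))
  ut <- upper.tri(r2)
  bins <- cut(d[ut], c(0, 10, 30, 60, 101), include.lowest = TRUE)
  mr2 <- tapply(r2[ut], bins, mean)
  expect_true(all(diff(mr2) < 0))
})

test_that("zero-variance limit gives level-wise constant phenotypes", {
  cfg <- sim_config(n_f2 = 40, n_chromosomes = 1, snps_per_chromosome = 10,
                    modules = list(), polygenic_variance = 0,
                    residual_variance = 0, seed = 2)
  sim <- simulate_study(cfg)
  ph <- sim$phenotypes
  # with no genetic or residual variance, y is a pure fixed-effect shift
  grp <- interaction(ph$year_birth, ph$year_sampling, ph$meas_day)
  for (tr in cfg$traits) {
    spread <- tapply(ph[[tr]], grp, function(v) diff(range(v)))
    expect_true(all(spread[!is.na(spread)] < 1e-12))
  }
})

test_that("a single planted SNP effect is recovered by OLS regression", {
  traits <- default_trait_names()
  ev <- setNames(rep(1, length(traits)), traits)
  mod <- planted_module("G1_005", "snp_c1_005", ev)
  cfg <- sim_config(n_f1 = 40, n_f2 = 2000, n_chromosomes = 1,
                    snps_per_chromosome = 20, modules = list(mod),
                    founder_allele_freq_range = c(0.3, 0.5),
                    founder_divergent = FALSE, residual_variance = 0.25,
                    polygenic_variance = 0, seed = 13)
  sim <- simulate_study(cfg)
  truth <- sim$ground_truth$effects
  b_true <- truth$effect[truth$snp == "snp_c1_005" & truth$trait == "tw273"]
  z <- sim$genotypes[sim$phenotypes$id, "snp_c1_005"]
  slope <- coef(lm(sim$phenotypes$tw273 ~ z + sim$phenotypes$year_birth))[2]
  expect_lt(abs(slope - b_true) / abs(b_true), 0.05)
})

test_that("within-block trait correlations exceed between-block ones", {
  cfg <- sim_config(n_f2 = 500, n_f1 = 40, seed = 21)
  sim <- simulate_study(cfg)
  r <- trait_correlation_matrix(sim$phenotypes)
  blocks <- cfg$trait_blocks
  within <- between <- c()
  for (i in seq_along(blocks)) for (j in seq_along(blocks)) {
    if (i > j) next
    vals <- r[blocks[[i]], blocks[[j]]]
    if (i == j) within <- c(within, vals[upper.tri(vals)])
    else between <- c(between, as.numeric(vals))
  }
  expect_gt(mean(within), mean(between))
  expect_gt(min(within), max(between))
})

test_that("polygenic deviates reproduce sigma_u^2 * diag(A) across replicates", {
  cfg <- sim_config(n_founders_per_breed = 2, n_f1 = 4, n_f2 = 10,
                    n_chromosomes = 1, snps_per_chromosome = 4,
                    modules = list(), polygenic_variance = 1,
                    residual_variance = 0, seed = 31)
  set.seed(31)
  ped <- simulate_pedigree(cfg)
  map <- make_snp_map(cfg)
  g <- simulate_genotypes(ped, map, cfg)
  A <- build_a_matrix(ped)
  ids <- ped$id[ped$generation == 2]
  set.seed(99)
  reps <- replicate(400, {
    ph <- simulate_phenotypes(g, cfg, ped)
    # subtract the known fixed-effect shift to isolate u
    ph$traits$tw273 - attr(ph$traits, "fixed_effect_values")[, "tw273"]
  })
  emp <- apply(reps, 1, var)
  expect_true(mean(abs(emp - diag(A)[ids])) < 0.2)
  # sib covariance follows the relationship matrix too
  sibs <- which(ids %in% ped$id[ped$sire == ped$sire[ped$id == ids[1]]])[1:2]
  expect_lt(abs(cov(reps[sibs[1], ], reps[sibs[2], ]) -
                  A[ids[sibs[1]], ids[sibs[2]]]), 0.2)
})

test_that("simulation is bit-identical under a fixed seed", {
  cfg <- sim_config(n_f2 = 30, n_chromosomes = 2, snps_per_chromosome = 20,
                    seed = 17)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$genotypes, s2$genotypes)
  expect_identical(s1$phenotypes, s2$phenotypes)
  expect_identical(s1$pedigree, s2$pedigree)
  cfg2 <- cfg
  cfg2$seed <- 18L
  s3 <- simulate_study(cfg2)
  expect_false(identical(s1$genotypes, s3$genotypes))
})

test_that("missing causal SNPs and missingness injection are handled", {
  traits <- default_trait_names()
  ev <- setNames(rep(0.2, length(traits)), traits)
  cfg <- sim_config(n_f2 = 20, n_chromosomes = 1, snps_per_chromosome = 10,
                    modules = list(planted_module("GX", "not_a_snp", ev)),
                    seed = 4)
  set.seed(4)
  ped <- simulate_pedigree(cfg)
  map <- make_snp_map(cfg)
  g <- simulate_genotypes(ped, map, cfg)
  expect_error(simulate_phenotypes(g, cfg, ped), "not_a_snp")

  cfg2 <- sim_config(n_f2 = 50, n_chromosomes = 1, snps_per_chromosome = 40,
                     modules = list(), missing_rate = 0.1, seed = 8)
  sim2 <- simulate_study(cfg2)
  expect_gt(mean(is.na(sim2$genotypes)), 0.05)
  expect_lt(mean(is.na(sim2$genotypes)), 0.15)
})
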