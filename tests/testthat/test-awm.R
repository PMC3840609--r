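# A long gwas_table built from explicit effect and p matrices.
toy_gwas <- function(eff, p) {
  stopifnot(identical(dim(eff), dim(p)))
  out <- data.frame(snp = rep(rownames(eff), ncol(eff)),
                    trait = rep(colnames(eff), each = nrow(eff)),
                    effect = as.vector(eff), lrt = 1,
                    p = as.vector(p), n_used = 100L,
                    stringsAsFactors = FALSE)
  attr(out, "traits") <- colnames(eff)
  class(out) <- c("gwas_table", "data.frame")
  out
}

rand_grid <- function(n_snp = 20, traits = c("k1", "k2", "m1", "m2", "m3"),
                      seed = 1) {
  set.seed(seed)
  eff <- matrix(rnorm(n_snp * length(traits)), n_snp,
                dimnames = list(sprintf("s%02d", 1:n_snp), traits))
  p <- matrix(runif(n_snp * length(traits)), n_snp,
              dimnames = dimnames(eff))
  list(eff = eff, p = p, gwas = toy_gwas(eff, p))
}

test_that("standardization is column-wise with the sample SD", {
  eff <- cbind(t1 = c(1, 2, 3), t2 = c(0, 10, 20))
  rownames(eff) <- c("a", "b", "c")
  std <- standardize_effects(toy_gwas(eff, eff * 0 + 0.5))
  expect_equal(unname(std[, "t1"]), c(-1, 0, 1))
  expect_equal(unname(std[, "t2"]), c(-1, 0, 1))
  expect_lt(max(abs(colMeans(std))), 1e-10)
  expect_lt(max(abs(apply(std, 2, sd) - 1)), 1e-10)

  # an already standardized column is unchanged
  z <- (c(1, 2, 3) - 2) / 1
  m0 <- cbind(t1 = z, t2 = z, t3 = z)
  rownames(m0) <- c("a", "b", "c")
  std2 <- standardize_effects(toy_gwas(m0, m0 * 0 + 0.5))
  expect_lt(max(abs(std2[, 1] - z)), 1e-12)

  const <- matrix(1, 3, 2, dimnames = list(c("a", "b", "c"), c("t1", "t2")))
  const[, "t2"] <- 1:3
  expect_error(standardize_effects(toy_gwas(const, const * 0 + 0.5)), "t1")
})

test_that("key selection uses an inclusive threshold", {
  g <- rand_grid(seed = 2)
  p <- g$p
  p["s01", "k1"] <- 0.05    # exactly at the threshold: included
  p["s02", c("k1", "k2")] <- 0.9
  p["s02", "m1"] <- 0.001   # supportive-only: excluded
  gw <- toy_gwas(g$eff, p)
  sel <- select_key_snps(gw, c("k1", "k2"))
  expect_true("s01" %in% sel)
  expect_false("s02" %in% sel)
  brute <- rownames(p)[apply(p[, c("k1", "k2")] <= 0.05, 1, any)]
  expect_setequal(sel, brute)
})

test_that("A_P is the unrounded mean supportive count", {
  eff <- matrix(0, 3, 6, dimnames = list(c("a", "b", "c"),
                                         c("k1", paste0("m", 1:5))))
  p <- eff + 1
  p[, "k1"] <- 0.01
  p["a", c("m1", "m2")] <- 0.01            # count 2
  p["b", c("m1", "m2", "m3")] <- 0.01      # count 3
  p["c", c("m1", "m2", "m3", "m4")] <- 0.01  # count 4
  gw <- toy_gwas(eff, p)
  s_key <- select_key_snps(gw, "k1")
  expect_equal(compute_ap(gw, s_key, paste0("m", 1:5)), 3.0)

  p2 <- eff + 1
  p2[, "k1"] <- 0.01
  expect_warning(ap0 <- compute_ap(toy_gwas(eff, p2), c("a", "b", "c"),
                                   paste0("m", 1:5)), "admit every")
  expect_equal(ap0, 0)
  expect_error(compute_ap(gw, character(0), paste0("m", 1:5)), "no key")

  # brute force on a random grid
  g <- rand_grid(seed = 3)
  s <- select_key_snps(g$gwas, c("k1", "k2"))
  cnt <- rowSums(g$p[s, c("m1", "m2", "m3")] <= 0.05)
  expect_equal(suppressWarnings(compute_ap(g$gwas, s, c("m1", "m2", "m3"))),
               mean(cnt))
})

test_that("supportive selection compares unrounded counts to A_P", {
  g <- rand_grid(seed = 4)
  p <- g$p
  p["s01", c("m1", "m2", "m3")] <- 0.01  # count 3
  gw <- toy_gwas(g$eff, p)
  expect_true("s01" %in% select_supportive_snps(gw, 3.0, c("m1", "m2", "m3")))
  expect_false("s01" %in% select_supportive_snps(gw, 3.4, c("m1", "m2", "m3")))
  expect_false("s01" %in% select_supportive_snps(gw, 3.0, c("m1", "m2", "m3"),
                                                 comparator = ">"))
  cnt <- rowSums(p[, c("m1", "m2", "m3")] <= 0.05)
  expect_setequal(select_supportive_snps(gw, 1, c("m1", "m2", "m3")),
                  names(cnt)[cnt >= 1])
})

test_that("gene proximity mapping honours the 2500-bp inclusive window", {
  genes <- data.frame(gene = c("gA", "gB"), chrom = c("1", "1"),
                      start = c(10000L, 50000L), end = c(12000L, 52000L),
                      stringsAsFactors = FALSE)
  sm <- data.frame(snp = c("in_gene", "at_2500", "at_2501", "far"),
                   chrom = "1",
                   pos = c(11000L, 10000L - 2500L, 10000L - 2501L, 30000L),
                   stringsAsFactors = FALSE)
  m <- map_snps_to_genes(sm$snp, sm, genes)
  expect_equal(m$gene[m$snp == "in_gene"], "gA")
  expect_equal(m$distance[m$snp == "in_gene"], 0)
  expect_true("at_2500" %in% m$snp)
  expect_false("at_2501" %in% m$snp)
  expect_false("far" %in% m$snp)

  # random SNPs against an exhaustive nearest-gene scan
  set.seed(6)
  genes2 <- data.frame(gene = sprintf("g%02d", 1:10),
                       chrom = sample(c("1", "2"), 10, TRUE),
                       start = sample.int(2e5, 10), stringsAsFactors = FALSE)
  genes2$end <- genes2$start + sample.int(5000, 10)
  sm2 <- data.frame(snp = sprintf("s%03d", 1:100),
                    chrom = sample(c("1", "2"), 100, TRUE),
                    pos = sample.int(2e5, 100), stringsAsFactors = FALSE)
  m2 <- map_snps_to_genes(sm2$snp, sm2, genes2, max_dist = 2500)
  for (i in seq_len(nrow(sm2))) {
    gg <- genes2[genes2$chrom == sm2$chrom[i], ]
    d <- ifelse(sm2$pos[i] >= gg$start & sm2$pos[i] <= gg$end, 0,
                pmin(abs(sm2$pos[i] - gg$start), abs(sm2$pos[i] - gg$end)))
    if (!nrow(gg) || min(d) > 2500) {
      expect_false(sm2$snp[i] %in% m2$snp)
    } else {
      expect_equal(m2$gene[m2$snp == sm2$snp[i]],
                   gg$gene[which.min(d)])
    }
  }
})

test_that("one-gene-one-SNP keeps the best-supported SNP", {
  eff <- matrix(0, 4, 5, dimnames = list(sprintf("s%d", 1:4),
                                         c("k1", "m1", "m2", "m3", "m4")))
  p <- eff + 1
  p["s1", 1:4] <- 0.01            # 4 associations
  p["s2", 1:2] <- 0.01            # 2 associations
  p["s3", 1:2] <- 0.001           # 2 associations, lower mean p
  p["s4", 1:2] <- c(0.02, 0.02)
  gw <- toy_gwas(eff, p)
  mp <- data.frame(snp = sprintf("s%d", 1:4), gene = c("G", "G", "H", "H"),
                   distance = 0, chrom = "1", pos = c(4L, 3L, 2L, 1L),
                   stringsAsFactors = FALSE)
  r <- resolve_one_gene_one_snp(mp, gw)
  expect_equal(r$snp[r$gene == "G"], "s1")   # higher count wins
  expect_equal(r$snp[r$gene == "H"], "s3")   # tie on count: lower mean p

  # randomized fixtures vs an exhaustive comparator
  set.seed(8)
  for (rep in 1:10) {
    g <- rand_grid(n_snp = 12, seed = 100 + rep)
    mp2 <- data.frame(snp = rownames(g$p),
                      gene = sample(c("G1", "G2", "G3"), 12, TRUE),
                      distance = 0, chrom = "1", pos = sample.int(1000, 12),
                      stringsAsFactors = FALSE)
    r2 <- resolve_one_gene_one_snp(mp2, g$gwas)
    cnt <- rowSums(g$p <= 0.05)
    mnp <- rowMeans(g$p)
    for (gene in unique(mp2$gene)) {
      cand <- mp2[mp2$gene == gene, ]
      o <- order(-cnt[cand$snp], mnp[cand$snp], cand$pos, cand$snp)
      expect_equal(r2$snp[r2$gene == gene], cand$snp[o[1]])
    }
  }
})

test_that("injected SNPs are ordinary rows of the grid", {
  g <- rand_grid(n_snp = 50, seed = 9)
  extra <- data.frame(snp = rep(c("inj1", "inj2"), each = 5),
                      gene = rep(c("GI1", "GI2"), each = 5),
                      trait = rep(colnames(g$eff), 2),
                      effect = rnorm(10), p = runif(10),
                      chrom = "9", pos = rep(c(100L, 200L), each = 5),
                      stringsAsFactors = FALSE)
  aug <- inject_custom_snps(g$gwas, extra)
  std <- standardize_effects(aug)
  expect_equal(nrow(std), 52)
  # standardization is recomputed over all 52 rows
  expect_lt(max(abs(colMeans(std))), 1e-10)

  # missing trait columns are rejected
  expect_error(inject_custom_snps(g$gwas, extra[-1, ]), "all trait")

  # injection order never changes the outcome
  aug2 <- inject_custom_snps(g$gwas, extra[sample(10), ])
  expect_equal(standardize_effects(aug2)[rownames(std), ], std)
})

test_that("trait correlations are Spearman with rank-transform invariance", {
  set.seed(10)
  y <- data.frame(a = rnorm(20), b = rnorm(20), c = rnorm(20), d = rnorm(20))
  r <- trait_correlation_matrix(y)
  expect_equal(diag(r), setNames(rep(1, 4), names(y)))
  # invariance under a rank-preserving transform
  y2 <- y
  y2$b <- exp(y$b)
  expect_equal(trait_correlation_matrix(y2)["a", "b"], r["a", "b"])
  # rank-then-Pearson oracle
  oracle <- cor(apply(y, 2, rank))
  expect_lt(max(abs(r - oracle)), 1e-12)

  y$e <- 1
  expect_warning(r2 <- trait_correlation_matrix(y), "constant")
  expect_true(all(is.na(r2["e", setdiff(names(y), "e")])))
})

test_that("build_awm composes the cascade on a hand-walked fixture", {
  # 8 SNPs x (1 key + 3 supportive); designed so that:
  #   s1, s2: key-significant (s1 also 2 supportive hits; s2 none)
  #   s3: 1 supportive hit -> A_P = mean(c(2, 0)) = 1 admits it
  #   s4: nothing; s5: key-significant but unmapped (too far);
  #   s6: supportive hit but maps to s1's gene and loses the count contest;
  #   s7, s8: nothing
  traits <- c("k1", "m1", "m2", "m3")
  eff <- matrix(seq(-2, 2, length.out = 32), 8, 4,
                dimnames = list(paste0("s", 1:8), traits))
  p <- matrix(1, 8, 4, dimnames = dimnames(eff))
  p["s1", ] <- c(0.01, 0.02, 0.03, 0.9)
  p["s2", "k1"] <- 0.04
  p["s3", "m2"] <- 0.01
  p["s6", "m3"] <- 0.04
  gw <- toy_gwas(eff, p)
  sm <- data.frame(snp = paste0("s", 1:8), chrom = "1",
                   pos = c(1000L, 5000L, 9000L, 13000L, 40000L, 1100L,
                           17000L, 21000L), stringsAsFactors = FALSE)
  genes <- data.frame(gene = c("gA", "gB", "gC", "gD", "gE"), chrom = "1",
                      start = c(900L, 4900L, 8900L, 12900L, 16900L),
                      end = c(1200L, 5100L, 9100L, 13100L, 17100L),
                      stringsAsFactors = FALSE)
  awm <- build_awm(gw, sm, genes, key_traits = "k1",
                   supportive_traits = c("m1", "m2", "m3"))
  expect_equal(awm$a_p, 1)
  # s5 is key-significant? no: only s1, s2 are. A_P from {s1: 2, s2: 0} = 1.
  # supportive-selected at >= 1: s1, s3, s6. candidates = {s1, s2, s3, s6};
  # s6 maps to gA where s1 wins (2 vs 1 associations at p <= 0.05... s1 has 3)
  expect_setequal(awm$genes$gene, c("gA", "gB", "gC"))
  expect_equal(awm$genes$snp[awm$genes$gene == "gA"], "s1")
  expect_equal(awm$genes$provenance[awm$genes$gene == "gB"], "key_selected")
  expect_equal(awm$genes$provenance[awm$genes$gene == "gC"],
               "supportive_selected")
  # cells are the standardized effects of the chosen SNPs
  std <- standardize_effects(gw)
  expect_equal(unname(awm$effects["gC", ]), unname(std["s3", traits]))

  # vacuous filter: every mapped gene enters
  awm_all <- build_awm(gw, sm, genes, key_traits = "k1",
                       supportive_traits = c("m1", "m2", "m3"), p_thresh = 1)
  expect_setequal(awm_all$genes$gene, c("gA", "gB", "gC", "gD", "gE"))

  # p_thresh = 0 yields the documented empty-AWM error path
  expect_error(build_awm(gw, sm, genes, key_traits = "k1",
                         supportive_traits = c("m1", "m2", "m3"),
                         p_thresh = 0), "no key")
})

test_that("selection grows monotonically with the p threshold", {
  g <- rand_grid(n_snp = 40, seed = 12)
  prev <- character(0)
  for (th in c(0.01, 0.05, 0.2, 0.5, 1)) {
    cur <- select_key_snps(g$gwas, c("k1", "k2"), p_thresh = th)
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("AWM rows come out sorted by genome position and deterministic", {
  sim <- simulate_study(sim_config(n_f2 = 80, n_chromosomes = 2,
                                   snps_per_chromosome = 60, seed = 14))
  gq <- qc_filter(sim$genotypes[sim$phenotypes$id, ])
  roles <- attr(sim$phenotypes, "roles")
  gw <- run_gwas(gq, sim$phenotypes, sim$pedigree)
  awm <- build_awm(gw, sim$snp_map, sim$genes,
                   names(roles)[roles == "key"],
                   names(roles)[roles == "supportive"])
  o <- order(awm$genes$chrom, awm$genes$pos, awm$genes$gene)
  expect_equal(o, seq_len(nrow(awm$genes)))
  awm2 <- build_awm(gw, sim$snp_map, sim$genes,
                    names(roles)[roles == "key"],
                    names(roles)[roles == "supportive"])
  expect_identical(awm$effects, awm2$effects)
})
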