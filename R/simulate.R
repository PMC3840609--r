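#' Simulation configuration for a synthetic F2 resource population
#'
#' Builds the configuration object consumed by [simulate_study()] and the
#' lower-level simulators. The defaults describe a desk-scale F2 cross
#' (two divergent founder pools, 150 male F2), five 100-cM chromosomes with
#' 200 evenly spaced SNPs each, and 13 traits: two key growth traits plus
#' eleven supportive serum metabolites falling into four correlation blocks
#' (weights; amino acids and short-chain acylcarnitines; medium/long-chain
#' acylcarnitines; phospho- and sphingolipids). Three pleiotropic gene modules
#' of ten genes each are planted on chromosomes 1-3; their within-module gene
#' pairs are the ground-truth co-association edges the downstream network is
#' expected to recover.
#'
#' @param n_founders_per_breed founders in each of the two pools (>= 1).
#' @param n_f1 number of F1 animals.
#' @param n_f2 number of F2 animals (0 allowed).
#' @param n_chromosomes,snps_per_chromosome,chromosome_length_cM marker map.
#' @param founder_allele_freq_range range the pool-A per-SNP allele-1
#'   frequencies are drawn from (uniform).
#' @param founder_divergent when TRUE (default) pool-B frequencies are the
#'   mirror `1 - p` of pool A, so the two founder breeds are enriched for
#'   alternative alleles with consistent phase -- the strongly divergent line
#'   cross that gives an F2 its long-range LD; when FALSE both pools draw
#'   independently from the range (no systematic LD).
#' @param modules list of planted modules, see [planted_module()]. May be
#'   an empty list for a pure-null simulation.
#' @param polygenic_variance,residual_variance per-trait variance components
#'   (sigma_u^2, sigma_e^2) in squared trait units; defaults give h2 = 0.35
#'   for the unplanted part of each trait.
#' @param residual_block_cor residual correlation between traits that share a
#'   block (0 between blocks); this is what produces the four trait clusters.
#' @param traits character vector of trait names.
#' @param trait_blocks named list partitioning `traits` into blocks.
#' @param key_traits traits used as key phenotypes downstream.
#' @param missing_rate genotype missingness injected uniformly at random.
#' @param seed integer master seed.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_founders_per_breed = 8,
                       n_f1 = 20,
                       n_f2 = 150,
                       n_chromosomes = 5,
                       snps_per_chromosome = 200,
                       chromosome_length_cM = 100,
                       founder_allele_freq_range = c(0.02, 0.15),
                       founder_divergent = TRUE,
                       modules = NULL,
                       polygenic_variance = 0.35,
                       residual_variance = 0.65,
                       residual_block_cor = 0.6,
                       traits = default_trait_names(),
                       trait_blocks = default_trait_blocks(),
                       key_traits = c("tw273", "dwg273"),
                       missing_rate = 0,
                       seed = 1L) {
  stopifnot(n_founders_per_breed >= 1, n_f1 >= 1, n_f2 >= 0,
            n_chromosomes >= 1, snps_per_chromosome >= 2,
            chromosome_length_cM > 0)
  if (length(founder_allele_freq_range) != 2L ||
      any(founder_allele_freq_range <= 0) || any(founder_allele_freq_range >= 1))
    stop("founder_allele_freq_range must be an interval inside (0, 1)")
  if (polygenic_variance < 0) stop("polygenic_variance must be >= 0")
  if (residual_variance < 0) stop("residual_variance must be >= 0")
  blk <- unlist(trait_blocks, use.names = FALSE)
  if (!setequal(blk, traits) || anyDuplicated(blk))
    stop("trait_blocks must partition the trait set exactly once")
  if (!all(key_traits %in% traits)) stop("key_traits must be a subset of traits")
  if (is.null(modules))
    modules <- default_modules(n_chromosomes, snps_per_chromosome, traits,
                               trait_blocks)
  gene_ids <- unlist(lapply(modules, `[[`, "member_genes"))
  if (anyDuplicated(gene_ids)) stop("module gene lists must be disjoint")
  for (m in modules) {
    if (length(m$effect_vector) != length(traits))
      stop("module effect_vector length must equal the number of traits")
  }
  cfg <- list(n_founders_per_breed = as.integer(n_founders_per_breed),
              n_f1 = as.integer(n_f1), n_f2 = as.integer(n_f2),
              n_chromosomes = as.integer(n_chromosomes),
              snps_per_chromosome = as.integer(snps_per_chromosome),
              chromosome_length_cM = chromosome_length_cM,
              founder_allele_freq_range = founder_allele_freq_range,
              founder_divergent = isTRUE(founder_divergent),
              modules = modules,
              polygenic_variance = polygenic_variance,
              residual_variance = residual_variance,
              residual_block_cor = residual_block_cor,
              traits = traits, trait_blocks = trait_blocks,
              key_traits = key_traits,
              missing_rate = missing_rate,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("F2 simulation config:",
      x$n_founders_per_breed, "+", x$n_founders_per_breed, "founders,",
      x$n_f1, "F1,", x$n_f2, "F2;",
      x$n_chromosomes, "chromosomes x", x$snps_per_chromosome, "SNPs;",
      length(x$traits), "traits;", length(x$modules), "planted modules\n")
  invisible(x)
}

#' @rdname sim_config
#' @export
default_trait_names <- function() {
  c("tw273", "dwg273", "arg", "lys", "C0", "C5",
    "C2", "C81", "C14", "C18", "PC_aa_C32_0", "PC_ae_C36_1", "SM_C20_2")
}

#' @rdname sim_config
#' @export
default_trait_blocks <- function() {
  list(weights = c("tw273", "dwg273"),
       amino   = c("arg", "lys", "C0", "C5"),
       acyl    = c("C2", "C81", "C14", "C18"),
       lipids  = c("PC_aa_C32_0", "PC_ae_C36_1", "SM_C20_2"))
}

#' A planted pleiotropic gene module
#'
#' @param member_genes gene ids belonging to the module.
#' @param causal_snps one SNP id per gene (the SNP lying inside the gene).
#' @param effect_vector per-trait additive allele-substitution effects.
#' @param description free text.
#' @export
planted_module <- function(member_genes, causal_snps, effect_vector,
                           description = "") {
  stopifnot(length(member_genes) == length(causal_snps))
  list(member_genes = member_genes, causal_snps = causal_snps,
       effect_vector = effect_vector, description = description)
}

## Block-sign effect patterns: every trait carries |b|, the sign is constant
## within a trait block and the 3 module sign patterns over the 4 blocks are
## chosen near-orthogonal so cross-module effect profiles are weakly
## correlated while within-block genetic covariance stays positive.
module_sign_matrix <- function() {
  rbind(c(1,  1, -1, -1),
        c(1, -1,  1, -1),
        c(1, -1, -1,  1))
}

#' @rdname sim_config
#' @export
default_modules <- function(n_chromosomes, snps_per_chromosome,
                            traits = default_trait_names(),
                            trait_blocks = default_trait_blocks(),
                            n_modules = 3, genes_per_module = 10,
                            effect_size = 0.3) {
  n_modules <- min(n_modules, n_chromosomes)
  signs <- module_sign_matrix()
  ## gene-bearing SNPs sit at odd indices (see make_gene_annotation); module
  ## members are spread along one chromosome arm at regular genetic spacing
  idx <- round(seq(snps_per_chromosome * 0.15, snps_per_chromosome * 0.85,
                   length.out = genes_per_module))
  idx <- unique(pmax(1L, idx - (idx + 1) %% 2))  # odd (gene-bearing) indices
  lapply(seq_len(n_modules), function(m) {
    chr <- m
    genes <- sprintf("G%d_%03d", chr, idx)
    snps <- sprintf("snp_c%d_%03d", chr, idx)
    ev <- numeric(length(traits))
    names(ev) <- traits
    for (b in seq_along(trait_blocks))
      ev[trait_blocks[[b]]] <- effect_size * signs[m, b]
    ## modules are ascertained through growth, so their effect on the key
    ## weight block is stronger than on the supportive metabolites
    ev[trait_blocks[[1L]]] <- 1.5 * ev[trait_blocks[[1L]]]
    planted_module(genes, snps, ev,
                   sprintf("module %d on chromosome %d", m, chr))
  })
}

#' Marker map for the simulated genome
#'
#' SNPs are evenly spaced in genetic distance; physical positions assume
#' 1 cM per Mb. SNP ids encode chromosome and index.
#' @param config a `sim_config`.
#' @return data.frame with columns snp, chrom, pos (bp, 1-based), cM.
#' @export
make_snp_map <- function(config) {
  out <- do.call(rbind, lapply(seq_len(config$n_chromosomes), function(chr) {
    s <- config$snps_per_chromosome
    g <- seq(0, config$chromosome_length_cM, length.out = s)
    data.frame(snp = sprintf("snp_c%d_%03d", chr, seq_len(s)),
               chrom = as.character(chr),
               pos = as.integer(round(g * 1e6)) + 1L,
               cM = g, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Gene annotation for the simulated genome
#'
#' Every other SNP (odd index) carries a gene spanning +/- 1 kb around it, so
#' gene-bearing SNPs map at distance 0 while the remaining SNPs are far beyond
#' the 2.5-kb proximity window and exercise the discard path.
#' @param snp_map output of [make_snp_map()].
#' @return data.frame with columns gene, chrom, start, end.
#' @export
make_gene_annotation <- function(snp_map) {
  idx_in_chr <- as.integer(sub(".*_(\\d+)$", "\\1", snp_map$snp))
  keep <- idx_in_chr %% 2L == 1L
  g <- snp_map[keep, ]
  data.frame(gene = sprintf("G%s_%03d", g$chrom, idx_in_chr[keep]),
             chrom = g$chrom,
             start = pmax(1L, g$pos - 1000L),
             end = g$pos + 1000L, stringsAsFactors = FALSE)
}

#' Simulate a three-generation F2 pedigree
#'
#' F0 founders come from two pools (the divergent breeds), F1 animals are
#' pool-A x pool-B crosses, and F2 animals are produced by mating pairs of F1
#' animals (full-sib families, round-robin over F1 couples).
#'
#' @param config a `sim_config`. Uses the current RNG state.
#' @return data.frame with columns id, sire, dam ("0" = unknown), generation,
#'   pool, of class `c("gn_pedigree", "data.frame")`.
#' @export
simulate_pedigree <- function(config) {
  f <- config$n_founders_per_breed
  if (f < 1) stop("invalid config: each founder pool needs at least one animal")
  pa <- sprintf("A%02d", seq_len(f))
  pb <- sprintf("B%02d", seq_len(f))
  f0 <- data.frame(id = c(pa, pb), sire = "0", dam = "0",
                   generation = 0L, pool = rep(c("A", "B"), each = f),
                   stringsAsFactors = FALSE)
  f1_id <- sprintf("F1_%02d", seq_len(config$n_f1))
  f1 <- data.frame(id = f1_id,
                   sire = pa[(seq_len(config$n_f1) - 1L) %% f + 1L],
                   dam = pb[sample.int(f, config$n_f1, replace = TRUE)],
                   generation = 1L, pool = "F1", stringsAsFactors = FALSE)
  ped <- rbind(f0, f1)
  if (config$n_f2 > 0) {
    n_cpl <- max(1L, config$n_f1 %/% 2L)
    cpl_s <- f1_id[2L * seq_len(n_cpl) - 1L]
    cpl_d <- f1_id[pmin(2L * seq_len(n_cpl), config$n_f1)]
    k <- (seq_len(config$n_f2) - 1L) %% n_cpl + 1L
    f2 <- data.frame(id = sprintf("F2_%03d", seq_len(config$n_f2)),
                     sire = cpl_s[k], dam = cpl_d[k],
                     generation = 2L, pool = "F2", stringsAsFactors = FALSE)
    ped <- rbind(ped, f2)
  }
  rownames(ped) <- NULL
  class(ped) <- c("gn_pedigree", "data.frame")
  validate_pedigree(ped)
  ped
}

#' Validate a pedigree table
#'
#' Checks id uniqueness, parent resolvability and acyclicity.
#' @param ped pedigree data.frame (id, sire, dam).
#' @return the pedigree, invisibly; errors on violations.
#' @export
validate_pedigree <- function(ped) {
  if (anyDuplicated(ped$id)) stop("duplicate animal ids in pedigree")
  for (col in c("sire", "dam")) {
    known <- ped[[col]] != "0" & !is.na(ped[[col]])
    bad <- !(ped[[col]][known] %in% ped$id)
    if (any(bad))
      stop("unknown parent id(s) in pedigree: ",
           paste(unique(ped[[col]][known][bad]), collapse = ", "))
  }
  pedigree_order(ped)  # errors on cycles
  invisible(ped)
}

## Topological order (parents before offspring); errors on cycles.
pedigree_order <- function(ped) {
  n <- nrow(ped)
  pos <- seq_len(n)
  names(pos) <- ped$id
  si <- ifelse(ped$sire == "0", NA_integer_, pos[ped$sire])
  di <- ifelse(ped$dam == "0", NA_integer_, pos[ped$dam])
  parent_ok <- function(p, placed) is.na(p) | placed[replace(p, is.na(p), 1L)]
  placed <- logical(n)
  order <- integer(0)
  repeat {
    ready <- !placed & parent_ok(si, placed) & parent_ok(di, placed)
    if (!any(ready)) {
      if (all(placed)) break
      stop("pedigree contains a cycle (animal among its own ancestors): ",
           paste(ped$id[!placed][seq_len(min(5, sum(!placed)))], collapse = ", "))
    }
    order <- c(order, which(ready))
    placed[ready] <- TRUE
  }
  order
}

#' Gene-drop genotype simulation
#'
#' Founder haplotypes are drawn from Hardy-Weinberg proportions at per-SNP,
#' per-pool allele frequencies; descendants inherit recombinant gametes with
#' Haldane (no-interference) crossover probabilities
#' `r = (1 - exp(-2 d / 100)) / 2` between adjacent SNPs `d` cM apart.
#' Genotypes are coded as minor-allele counts minus one, i.e. {-1, 0, +1}
#' with +1 the minor-allele homozygote (the minor allele is determined across
#' all simulated animals; at a 50/50 tie allele 1 stays the counted allele).
#'
#' @param pedigree a pedigree from [simulate_pedigree()].
#' @param snp_map marker map sorted by chromosome and position.
#' @param config a `sim_config`. Uses the current RNG state.
#' @return integer matrix animals x SNPs in {-1, 0, 1, NA}.
#' @export
simulate_genotypes <- function(pedigree, snp_map, config) {
  ord <- pedigree_order(pedigree)
  if (!identical(ord, seq_len(nrow(pedigree))))
    pedigree <- pedigree[ord, ]
  for (chr in unique(snp_map$chrom)) {
    p <- snp_map$cM[snp_map$chrom == chr]
    if (is.unsorted(p)) stop("snp map must be sorted within chromosome")
  }
  n <- nrow(pedigree)
  m <- nrow(snp_map)
  h1 <- matrix(0L, n, m, dimnames = list(pedigree$id, snp_map$snp))
  h2 <- h1
  idx <- seq_len(n)
  names(idx) <- pedigree$id
  fr <- config$founder_allele_freq_range
  chrs <- split(seq_len(m), snp_map$chrom)[unique(snp_map$chrom)]
  ## divergent line cross: pool B allele-1 frequencies mirror pool A, so the
  ## two breeds are enriched for alternative alleles with consistent phase
  ## (the source of the long-range LD characteristic of an F2 resource
  ## population)
  fA <- runif(m, fr[1], fr[2])
  fB <- if (isTRUE(config$founder_divergent)) 1 - fA else runif(m, fr[1], fr[2])
  freq <- list(A = fA, B = fB)
  for (i in seq_len(n)) {
    if (pedigree$sire[i] == "0" && pedigree$dam[i] == "0") {
      f <- freq[[pedigree$pool[i]]]
      if (is.null(f)) f <- runif(m, fr[1], fr[2])
      h1[i, ] <- as.integer(runif(m) < f)
      h2[i, ] <- as.integer(runif(m) < f)
    } else {
      if (pedigree$sire[i] == "0" || pedigree$dam[i] == "0")
        stop("non-founder with a single known parent: ", pedigree$id[i])
      s <- idx[[pedigree$sire[i]]]
      d <- idx[[pedigree$dam[i]]]
      h1[i, ] <- make_gamete(h1[s, ], h2[s, ], snp_map, chrs)
      h2[i, ] <- make_gamete(h1[d, ], h2[d, ], snp_map, chrs)
    }
  }
  g <- h1 + h2 - 1L
  if (config$missing_rate > 0) {
    miss <- runif(length(g)) < config$missing_rate
    g[miss] <- NA_integer_
  }
  ## recode so +1 counts the minor allele (among observed genotypes);
  ## remember which SNPs were flipped, since planted effects are phased on
  ## allele 1, the pool-B-enriched allele
  f1 <- colMeans(g + 1L, na.rm = TRUE) / 2
  flip <- !is.na(f1) & f1 > 0.5
  g[, flip] <- -g[, flip]
  attr(g, "flipped") <- flip
  g
}

## One meiosis: Haldane-map recombination along each chromosome.
make_gamete <- function(hap1, hap2, snp_map, chrs) {
  out <- integer(length(hap1))
  for (ix in chrs) {
    d <- diff(snp_map$cM[ix])
    r <- (1 - exp(-2 * d / 100)) / 2
    switches <- c(runif(1) < 0.5, runif(length(r)) < r)
    strand <- cumsum(as.integer(switches)) %% 2L
    out[ix] <- ifelse(strand == 0L, hap1[ix], hap2[ix])
  }
  out
}

#' Simulate multi-trait phenotypes with planted gene modules
#'
#' Each trait is built as fixed-effect level shifts + sum of planted SNP
#' effects + a pedigree polygenic deviate (covariance `A * sigma_u^2`) + a
#' residual with block-structured correlation across traits. Weight traits
#' carry one categorical fixed effect (birth-year-like, 3 levels); metabolite
#' traits carry two (sampling year, 2 levels; measurement day, 3 levels).
#'
#' @param genotypes matrix from [simulate_genotypes()] (all animals).
#' @param config a `sim_config`.
#' @param pedigree the pedigree the genotypes were dropped through.
#' @return list with `traits` (data.frame: id, covariates, trait columns,
#'   with attributes `roles` and `fixed_effects`) for the F2 animals, and
#'   `ground_truth` (planted edges and causal effects).
#' @export
simulate_phenotypes <- function(genotypes, config, pedigree) {
  traits <- config$traits
  causal <- do.call(rbind, lapply(config$modules, function(m)
    data.frame(snp = m$causal_snps, stringsAsFactors = FALSE)))
  if (!is.null(causal)) {
    absent <- setdiff(causal$snp, colnames(genotypes))
    if (length(absent))
      stop("causal SNP(s) absent from genotype matrix: ",
           paste(absent, collapse = ", "))
  }
  ids <- pedigree$id[pedigree$generation == max(pedigree$generation)]
  if (!length(ids)) ids <- pedigree$id
  n <- length(ids)
  A <- build_a_matrix(pedigree)[ids, ids, drop = FALSE]

  yob <- factor(sample(c("y1", "y2", "y3"), n, replace = TRUE))
  ysmp <- factor(sample(c("s1", "s2"), n, replace = TRUE))
  mday <- factor(sample(c("d1", "d2", "d3"), n, replace = TRUE))
  fx_yob <- c(y1 = -0.5, y2 = 0, y3 = 0.5)
  fx_ysmp <- c(s1 = -0.3, s2 = 0.3)
  fx_mday <- c(d1 = -0.4, d2 = 0, d3 = 0.4)

  nt <- length(traits)
  ## polygenic deviates: independent across traits, Cov = A * sigma_u2
  U <- matrix(0, n, nt)
  if (config$polygenic_variance > 0) {
    L <- t(chol(A + diag(1e-10, n)))
    U <- sqrt(config$polygenic_variance) *
      (L %*% matrix(rnorm(n * nt), n, nt))
  }
  ## block-correlated residuals
  R <- diag(nt)
  dimnames(R) <- list(traits, traits)
  for (b in config$trait_blocks)
    R[b, b] <- config$residual_block_cor
  diag(R) <- 1
  E <- if (config$residual_variance > 0)
    matrix(rnorm(n * nt), n, nt) %*% chol(config$residual_variance * R)
  else matrix(0, n, nt)

  Y <- U + E
  colnames(Y) <- traits
  flipped <- attr(genotypes, "flipped")
  eff_sign <- function(s)
    if (!is.null(flipped) && isTRUE(flipped[[s]])) -1 else 1
  truth_eff <- NULL
  for (m in config$modules) {
    for (s in m$causal_snps) {
      z <- genotypes[ids, s]
      z[is.na(z)] <- 0L
      ## effects are phased on allele 1 (pre-flip coding); on the stored
      ## minor-allele coding the sign follows the flip
      bv <- eff_sign(s) * m$effect_vector[traits]
      Y <- Y + z %o% bv
      truth_eff <- rbind(truth_eff,
                         data.frame(snp = s, trait = traits,
                                    effect = unname(bv),
                                    stringsAsFactors = FALSE))
    }
  }
  is_key <- traits %in% config$key_traits
  Y[, is_key] <- Y[, is_key] + fx_yob[yob]
  Y[, !is_key] <- Y[, !is_key] + fx_ysmp[ysmp] + fx_mday[mday]

  tab <- data.frame(id = ids, year_birth = yob, year_sampling = ysmp,
                    meas_day = mday, stringsAsFactors = FALSE)
  tab <- cbind(tab, as.data.frame(Y))
  roles <- ifelse(is_key, "key", "supportive")
  names(roles) <- traits
  fixed_effects <- lapply(seq_along(traits), function(i)
    if (is_key[i]) "year_birth" else c("year_sampling", "meas_day"))
  names(fixed_effects) <- traits
  attr(tab, "roles") <- roles
  attr(tab, "fixed_effects") <- fixed_effects
  fx_shift <- matrix(0, n, nt, dimnames = list(ids, traits))
  fx_shift[, is_key] <- fx_yob[yob]
  fx_shift[, !is_key] <- fx_ysmp[ysmp] + fx_mday[mday]
  attr(tab, "fixed_effect_values") <- fx_shift

  edges <- NULL
  for (m in config$modules) {
    gs <- sort(m$member_genes)
    if (length(gs) > 1) {
      pr <- t(combn(gs, 2))
      edges <- rbind(edges, data.frame(gene_a = pr[, 1], gene_b = pr[, 2],
                                       stringsAsFactors = FALSE))
    }
  }
  list(traits = tab,
       ground_truth = list(edges = edges, effects = truth_eff,
                           modules = config$modules))
}

#' Simulate a complete study dataset
#'
#' Seeds the RNG from `config$seed` and runs pedigree, marker-map, genotype
#' and phenotype simulation; repeated calls with the same config are
#' bit-identical.
#'
#' @param config a `sim_config`.
#' @return list of class `growth_sim`: pedigree, snp_map, genes, genotypes,
#'   phenotypes (TraitTable), ground_truth, config.
#' @export
simulate_study <- function(config = sim_config()) {
  set.seed(config$seed)
  ped <- simulate_pedigree(config)
  map <- make_snp_map(config)
  genes <- make_gene_annotation(map)
  geno <- simulate_genotypes(ped, map, config)
  ph <- simulate_phenotypes(geno, config, ped)
  out <- list(pedigree = ped, snp_map = map, genes = genes,
              genotypes = geno, phenotypes = ph$traits,
              ground_truth = ph$ground_truth, config = config)
  class(out) <- "growth_sim"
  out
}

#' @export
print.growth_sim <- function(x, ...) {
  cat("Simulated F2 study:", nrow(x$pedigree), "animals (",
      sum(x$pedigree$generation == 2L), "F2),",
      ncol(x$genotypes), "SNPs,", nrow(x$genes), "annotated genes,",
      length(x$config$traits), "traits,",
      length(x$config$modules), "planted modules\n")
  invisible(x)
}
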