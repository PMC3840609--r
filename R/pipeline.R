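#' Default end-to-end run configuration
#'
#' @param seed master seed; every stochastic stage derives its seed from it.
#' @param sim a `sim_config` describing the synthetic dataset (ignored when
#'   `paths` point at user data).
#' @param paths optional named list (geno_prefix, ped, pheno, genes, roles)
#'   of input files; when NULL the dataset is simulated.
#' @param p_thresh,max_dist,pc_threshold,n_random,comparator pipeline
#'   thresholds (nominal significance, gene proximity in bp, edge magnitude,
#'   random replicates, supportive-count comparator).
#' @return list of class `run_config`.
#' @export
default_run_config <- function(seed = 1L, sim = NULL, paths = NULL,
                               p_thresh = 0.05, max_dist = 2500,
                               pc_threshold = 0.80, n_random = 10,
                               comparator = ">=") {
  stopifnot(p_thresh >= 0, p_thresh <= 1,
            max_dist >= 0, pc_threshold >= 0, pc_threshold <= 1,
            n_random >= 0)
  if (is.null(sim)) sim <- sim_config(seed = seed + 1000L)
  cfg <- list(seed = as.integer(seed), sim = sim, paths = paths,
              p_thresh = p_thresh, max_dist = max_dist,
              pc_threshold = pc_threshold, n_random = as.integer(n_random),
              comparator = comparator)
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML
#'
#' Top-level keys mirror the arguments of [default_run_config()]; `sim` may
#' override individual [sim_config()] fields.
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- if (!is.null(y$sim)) do.call(sim_config, y$sim) else NULL
  args <- y[setdiff(names(y), "sim")]
  do.call(default_run_config, c(args, list(sim = sim)))
}

#' Run the full co-association analysis
#'
#' Executes simulate-or-load, QC, mixed-model GWAS, AWM assembly, PCIT,
#' network construction, random-network validation, the metabolite-only
#' network and its overlap with the full network, hub tables and MCODE
#' clustering, and writes every artefact plus a machine-readable summary to
#' `out_dir`. With a fixed seed the run directory contents are bit-identical
#' across repeats.
#'
#' @param config a `run_config`.
#' @param out_dir output directory; NULL runs in memory only.
#' @param verbose print stage progress.
#' @return invisible list with every intermediate object and `summary`
#'   (counts: AWM genes, A_P, network genes/edges/max degree, random means,
#'   metabolite-only and overlap sizes, thresholds used).
#' @export
run_pipeline <- function(config = default_run_config(), out_dir = NULL,
                         verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  if (is.null(config$paths)) {
    say("simulating dataset")
    simc <- config$sim
    simc$seed <- config$seed + 1000L
    sim <- simulate_study(simc)
    geno <- sim$genotypes
    ped <- sim$pedigree
    pheno <- sim$phenotypes
    genes <- sim$genes
    snp_map <- sim$snp_map
  } else {
    say("loading dataset")
    sim <- NULL
    gg <- read_genotypes(paste0(config$paths$geno_prefix, ".ped"),
                         paste0(config$paths$geno_prefix, ".map"))
    geno <- gg$genotypes
    snp_map <- gg$snp_map
    ped <- read_pedigree(config$paths$ped)
    ry <- yaml::read_yaml(config$paths$roles)
    roles <- unlist(ry$roles)
    pheno <- read_phenotypes(config$paths$pheno, roles,
                             fixed_effects = ry$fixed_effects)
    genes <- read_annotation(config$paths$genes)
  }
  roles <- attr(pheno, "roles")
  key_traits <- names(roles)[roles == "key"]
  supp_traits <- names(roles)[roles == "supportive"]

  say("QC filtering")
  f2 <- intersect(rownames(geno), pheno$id)
  geno_f2 <- qc_filter(geno[f2, , drop = FALSE])

  say("mixed-model GWAS")
  gwas <- run_gwas(geno_f2, pheno, ped)

  say("building AWM")
  awm <- build_awm(gwas, snp_map, genes, key_traits, supp_traits,
                   p_thresh = config$p_thresh, max_dist = config$max_dist,
                   comparator = config$comparator)

  say("PCIT and network")
  net <- network_from_awm(awm, config$pc_threshold)

  say("random-network validation")
  rand <- if (config$n_random > 0)
    random_validation(awm, config$n_random, config$pc_threshold,
                      seed = config$seed) else NULL

  say("metabolite-only network and overlap")
  met <- metabolite_only_network(gwas, snp_map, genes, key_traits,
                                 supp_traits, awm$a_p,
                                 p_thresh = config$p_thresh,
                                 comparator = config$comparator,
                                 pc_threshold = config$pc_threshold)
  ovl <- network_overlap(net, met$network)

  say("hubs and clusters")
  hubs <- utils::head(degree_table(net), 10L)
  clusters <- mcode_clusters(net)

  summary <- list(
    seed = config$seed,
    thresholds = list(p_thresh = config$p_thresh, max_dist = config$max_dist,
                      pc_threshold = config$pc_threshold,
                      comparator = config$comparator,
                      n_random = config$n_random),
    n_snps_qc = ncol(geno_f2),
    n_animals = length(f2),
    a_p = awm$a_p,
    awm_genes = nrow(awm$effects),
    network_genes = sum(net$nodes$degree > 0),
    network_edges = nrow(net$edges),
    max_degree = if (nrow(net$nodes)) max(net$nodes$degree) else 0L,
    random_mean_genes = if (!is.null(rand)) rand$mean_nodes else NA,
    random_mean_edges = if (!is.null(rand)) rand$mean_edges else NA,
    random_max_degree = if (!is.null(rand))
      max(rand$replicates$max_degree) else NA,
    metabolite_genes = sum(met$network$nodes$degree > 0),
    metabolite_edges = nrow(met$network$edges),
    overlap_genes = length(ovl$nodes),
    overlap_edges = nrow(ovl$edges),
    n_clusters = length(clusters))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(sim)) write_dataset(sim, file.path(out_dir, "data"))
    write.table(gwas, file.path(out_dir, "gwas.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    awm_tab <- cbind(awm$genes, as.data.frame(awm$effects))
    write.table(awm_tab, file.path(out_dir, "awm.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_network(net, file.path(out_dir, "network"))
    write_network(met$network, file.path(out_dir, "metabolite_network"))
    write.table(hubs, file.path(out_dir, "hubs.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (!is.null(rand))
      write.table(rand$replicates, file.path(out_dir, "random_networks.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    yaml::write_yaml(list(seed = config$seed,
                          thresholds = summary$thresholds,
                          r_version = as.character(getRversion())),
                     file.path(out_dir, "run_config.yaml"))
  }
  invisible(list(sim = sim, genotypes_qc = geno_f2, gwas = gwas, awm = awm,
                 network = net, random = rand, metabolite = met,
                 overlap = ovl, hubs = hubs, clusters = clusters,
                 summary = summary))
}
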