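#' Per-gene connectivity table
#'
#' @param network a `coassoc_network`.
#' @return data.frame(gene, degree) sorted by degree (desc) then gene id;
#'   empty networks give an empty table.
#' @export
degree_table <- function(network) {
  nd <- network$nodes[network$nodes$degree > 0, c("gene", "degree"),
                      drop = FALSE]
  nd <- nd[order(-nd$degree, nd$gene), , drop = FALSE]
  rownames(nd) <- NULL
  nd
}

#' Column-wise permutation of an AWM
#'
#' Independently permutes each trait column of the standardized effects
#' across genes, leaving row and column labels in place: SNP-trait
#' associations become independent of the observed GWAS while every column's
#' value multiset (hence mean and SD) is preserved exactly.
#'
#' @param awm an `awm` object.
#' @param seed integer seed (sets the RNG).
#' @return the randomized `awm`.
#' @export
randomize_awm <- function(awm, seed) {
  stopifnot(nrow(awm$effects) > 0)
  set.seed(seed)
  eff <- awm$effects
  for (j in seq_len(ncol(eff)))
    eff[, j] <- eff[sample.int(nrow(eff)), j]
  awm$effects <- eff
  awm
}

#' Random-network validation of a co-association network
#'
#' Builds `n_replicates` independent random networks by column-permuting the
#' AWM and re-running PCIT and the edge filter, then summarizes node counts
#' (genes with at least one edge), edge counts and maximum degree. A
#' structured network should contain far more genes and edges than its
#' permuted counterparts. Replicate seeds are `seed + replicate index`.
#'
#' @param awm an `awm` object.
#' @param n_replicates number of random networks (default 10).
#' @param pc_threshold edge magnitude threshold.
#' @param seed master seed.
#' @param method PCIT implementation.
#' @return object of class `randomization_summary`: per-replicate stats,
#'   their means, and the per-gene mean degree across replicates.
#' @export
random_validation <- function(awm, n_replicates = 10, pc_threshold = 0.80,
                              seed = 1L, method = "fast") {
  stats <- vector("list", n_replicates)
  degsum <- setNames(numeric(nrow(awm$effects)), rownames(awm$effects))
  for (i in seq_len(n_replicates)) {
    rnd <- randomize_awm(awm, seed + i)
    net <- network_from_awm(rnd, pc_threshold, method)
    deg <- setNames(net$nodes$degree, net$nodes$gene)
    degsum[names(deg)] <- degsum[names(deg)] + deg
    stats[[i]] <- data.frame(replicate = i,
                             node_count = sum(net$nodes$degree > 0),
                             edge_count = nrow(net$edges),
                             max_degree = if (nrow(net$nodes))
                               max(net$nodes$degree) else 0L)
  }
  reps <- do.call(rbind, stats)
  out <- list(replicates = reps,
              mean_nodes = mean(reps$node_count),
              mean_edges = mean(reps$edge_count),
              mean_max_degree = mean(reps$max_degree),
              gene_mean_degree = degsum / n_replicates,
              n_replicates = n_replicates, seed = seed)
  class(out) <- "randomization_summary"
  out
}

#' @export
print.randomization_summary <- function(x, ...) {
  cat(sprintf(
    "Random networks (%d replicates): mean %.1f connected genes, %.1f edges, mean max degree %.1f\n",
    x$n_replicates, x$mean_nodes, x$mean_edges, x$mean_max_degree))
  invisible(x)
}

#' Metabolite-only co-association network
#'
#' Rebuilds the AWM after removing the key-trait columns, selecting SNPs by
#' their supportive-phenotype count against the *supplied* A_P (taken from
#' the full analysis), then runs PCIT and the edge filter as usual.
#'
#' @param gwas full `gwas_table`.
#' @param snp_map,genes as in [build_awm()].
#' @param key_traits traits to remove.
#' @param supportive_traits metabolite traits retained.
#' @param a_p A_P value from the full analysis.
#' @param p_thresh,comparator,pc_threshold,method cascade parameters.
#' @return list(network, awm); an empty selection yields a warning and an
#'   empty network.
#' @export
metabolite_only_network <- function(gwas, snp_map, genes, key_traits,
                                    supportive_traits, a_p,
                                    p_thresh = 0.05, comparator = ">=",
                                    pc_threshold = 0.80, method = "fast") {
  red <- drop_traits(gwas, key_traits)
  awm <- tryCatch(
    build_awm(red, snp_map, genes, key_traits = character(0),
              supportive_traits = supportive_traits, p_thresh = p_thresh,
              comparator = comparator, a_p_override = a_p),
    error = function(e) NULL)
  if (is.null(awm) || nrow(awm$effects) < 2L) {
    warning("metabolite-only selection admitted no usable SNPs; empty network")
    empty <- new_coassoc_network(
      nodes = data.frame(gene = character(0), degree = integer(0)),
      edges = data.frame(gene_a = character(0), gene_b = character(0),
                         correlation = numeric(0)))
    return(list(network = empty, awm = awm))
  }
  list(network = network_from_awm(awm, pc_threshold, method), awm = awm)
}

edge_keys <- function(network) {
  if (!nrow(network$edges)) return(character(0))
  paste(pmin(network$edges$gene_a, network$edges$gene_b),
        pmax(network$edges$gene_a, network$edges$gene_b), sep = "\r")
}

#' Overlap between two networks
#'
#' Intersection of connected node sets and of undirected edge sets
#' (order-insensitive pairs); the "Network merge" comparison.
#'
#' @param net_a,net_b `coassoc_network` objects over the same gene namespace.
#' @return list(nodes = shared gene ids, edges = data.frame(gene_a, gene_b)).
#' @export
network_overlap <- function(net_a, net_b) {
  na_ <- net_a$nodes$gene[net_a$nodes$degree > 0]
  nb_ <- net_b$nodes$gene[net_b$nodes$degree > 0]
  keys <- intersect(edge_keys(net_a), edge_keys(net_b))
  parts <- strsplit(keys, "\r", fixed = TRUE)
  edges <- data.frame(gene_a = vapply(parts, `[`, "", 1),
                      gene_b = vapply(parts, `[`, "", 2),
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  rownames(edges) <- NULL
  list(nodes = sort(intersect(na_, nb_)), edges = edges)
}

#' Gene-centric subnetwork
#'
#' The query gene, its direct partners, and *all* network edges among that
#' node set (the full induced subgraph, including partner-partner edges).
#'
#' @param network a `coassoc_network`.
#' @param gene query gene id.
#' @return a `coassoc_network`.
#' @export
gene_subnetwork <- function(network, gene) {
  if (!gene %in% network$nodes$gene)
    stop("gene ", gene, " is not in the network")
  e <- network$edges
  nb <- unique(c(e$gene_b[e$gene_a == gene], e$gene_a[e$gene_b == gene]))
  keep_nodes <- c(gene, sort(nb))
  sel <- e$gene_a %in% keep_nodes & e$gene_b %in% keep_nodes
  edges <- e[sel, , drop = FALSE]
  rownames(edges) <- NULL
  deg <- table(factor(c(edges$gene_a, edges$gene_b), levels = sort(keep_nodes)))
  new_coassoc_network(
    nodes = data.frame(gene = names(deg), degree = as.integer(deg),
                       stringsAsFactors = FALSE),
    edges = edges)
}

as_igraph <- function(network) {
  igraph::graph_from_data_frame(
    network$edges[, c("gene_a", "gene_b"), drop = FALSE],
    directed = FALSE,
    vertices = data.frame(name = network$nodes$gene))
}
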