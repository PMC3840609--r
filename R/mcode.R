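#' MCODE dense-cluster detection
#'
#' Molecular Complex Detection on a co-association network, with the
#' published default parameters. Stage 1 weights every vertex by the density
#' of the highest k-core of its closed neighbourhood times that core's k
#' (vertices below `degree_cutoff` score 0). Stage 2 seeds complexes from the
#' highest-weight unvisited vertex and grows them breadth-first, admitting a
#' neighbour whose weight is at least `seed_weight * (1 - node_score_cutoff)`
#' and has not been assigned to another complex, down to `max_depth` from the
#' seed. Stage 3 post-processes: complexes must contain a `k_core`-core;
#' `haircut` removes members with fewer than two within-complex connections
#' (`fluff` is off by default, matching MCODE's defaults).
#'
#' @param network a `coassoc_network`.
#' @param degree_cutoff minimum vertex degree to receive a weight.
#' @param node_score_cutoff admissible fractional weight drop from the seed.
#' @param k_core required core level inside a reported complex.
#' @param haircut remove singly-connected complex members.
#' @param fluff unused (kept for signature parity with MCODE defaults).
#' @param max_depth BFS depth bound from the seed.
#' @return list of `network_cluster` objects (members, seed, score =
#'   density x size, per-member within-cluster degree), sorted by score.
#' @export
mcode_clusters <- function(network, degree_cutoff = 2, node_score_cutoff = 0.2,
                           k_core = 2, haircut = TRUE, fluff = FALSE,
                           max_depth = 100) {
  if (!nrow(network$edges)) return(list())
  g <- as_igraph(network)
  n <- igraph::vcount(g)
  deg <- igraph::degree(g)
  w <- numeric(n)
  for (v in seq_len(n)) {
    if (deg[v] < degree_cutoff) next
    nb <- c(v, as.integer(igraph::neighbors(g, v)))
    sub <- igraph::induced_subgraph(g, nb)
    core <- igraph::coreness(sub)
    kmax <- max(core)
    core_sub <- igraph::induced_subgraph(sub, which(core == kmax))
    nv <- igraph::vcount(core_sub)
    dens <- if (nv > 1) 2 * igraph::ecount(core_sub) / (nv * (nv - 1)) else 0
    w[v] <- kmax * dens
  }
  names(w) <- igraph::V(g)$name
  visited <- logical(n)
  clusters <- list()
  for (seedv in order(-w)) {
    if (visited[seedv] || w[seedv] <= 0) next
    thr <- w[seedv] * (1 - node_score_cutoff)
    members <- seedv
    visited[seedv] <- TRUE
    frontier <- seedv
    depth <- 0
    while (length(frontier) && depth < max_depth) {
      nxt <- integer(0)
      for (v in frontier) {
        for (u in as.integer(igraph::neighbors(g, v))) {
          if (!visited[u] && w[u] >= thr) {
            visited[u] <- TRUE
            members <- c(members, u)
            nxt <- c(nxt, u)
          }
        }
      }
      frontier <- nxt
      depth <- depth + 1
    }
    sub <- igraph::induced_subgraph(g, members)
    core <- igraph::coreness(sub)
    if (max(core) < k_core) next
    if (haircut) {
      keep <- igraph::degree(sub) >= 2
      if (!any(keep)) next
      sub <- igraph::induced_subgraph(sub, which(keep))
    }
    nv <- igraph::vcount(sub)
    if (nv < 2) next
    dens <- 2 * igraph::ecount(sub) / (nv * (nv - 1))
    cl <- list(members = sort(igraph::V(sub)$name),
               seed = igraph::V(g)$name[seedv],
               score = dens * nv,
               within_degree = setNames(as.integer(igraph::degree(sub)),
                                        igraph::V(sub)$name))
    class(cl) <- "network_cluster"
    clusters[[length(clusters) + 1L]] <- cl
  }
  clusters[order(-vapply(clusters, `[[`, 0, "score"))]
}

#' @export
print.network_cluster <- function(x, ...) {
  cat("MCODE cluster: seed", x$seed, "|", length(x$members), "genes, score",
      format(x$score, digits = 4), "\n")
  invisible(x)
}

#' Dense cluster around a query gene
#'
#' Extracts the gene's ego network (see [gene_subnetwork()]), runs MCODE on
#' it, and returns the cluster containing the query gene; if the query is not
#' in any cluster the highest-scoring cluster is returned with a warning.
#'
#' @param network a `coassoc_network`.
#' @param gene query gene id.
#' @param ... passed on to [mcode_clusters()].
#' @return a `network_cluster`, or NULL (with a warning) when the ego
#'   network has no cluster at all.
#' @export
dense_subnetwork <- function(network, gene, ...) {
  ego <- gene_subnetwork(network, gene)
  cls <- mcode_clusters(ego, ...)
  if (!length(cls)) {
    warning("no dense cluster in the ego network of ", gene)
    return(NULL)
  }
  hit <- which(vapply(cls, function(cl) gene %in% cl$members, TRUE))
  if (!length(hit)) {
    warning("query gene ", gene,
            " is unclustered; returning the top-scoring cluster")
    return(cls[[1L]])
  }
  cls[[hit[1L]]]
}
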