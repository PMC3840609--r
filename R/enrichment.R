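#' Binomial over-representation test
#'
#' PANTHER-style enrichment of a gene list against a reference list: for each
#' term, the number of annotated network genes hitting the term is compared
#' with a Binomial(n = annotated network genes, p = term frequency in the
#' annotated reference) upper tail, `p_raw = P(X >= n_observed)` as an exact
#' tail sum, with Bonferroni correction over the number of terms tested.
#' Genes without any annotation are excluded from both totals; network genes
#' absent from the reference are dropped with a message.
#'
#' @param network_genes character vector of gene ids (the network nodes).
#' @param reference_genes character vector (the background list).
#' @param annotation data.frame(gene, term), many-to-many.
#' @return data.frame of class `enrichment_table`, one row per term:
#'   term, n_reference, n_observed, n_expected, p_raw, p_bonferroni,
#'   sorted by p_raw.
#' @export
binomial_enrichment <- function(network_genes, reference_genes, annotation) {
  stopifnot(nrow(annotation) > 0)
  names(annotation)[1:2] <- c("gene", "term")
  stray <- setdiff(network_genes, reference_genes)
  if (length(stray)) {
    message(length(stray), " network gene(s) not in the reference were dropped")
    network_genes <- intersect(network_genes, reference_genes)
  }
  ann <- annotation[annotation$gene %in% reference_genes, ]
  ref_ann <- unique(ann$gene)
  net_ann <- intersect(network_genes, ref_ann)
  n <- length(net_ann)
  if (n == 0L) stop("no annotated network genes")
  N <- length(ref_ann)
  terms <- sort(unique(ann$term))
  rows <- lapply(terms, function(tm) {
    ref_genes_tm <- unique(ann$gene[ann$term == tm])
    n_ref <- length(ref_genes_tm)
    obs <- sum(net_ann %in% ref_genes_tm)
    pr <- n_ref / N
    p_raw <- pbinom(obs - 1L, n, pr, lower.tail = FALSE)
    data.frame(term = tm, n_reference = n_ref, n_observed = obs,
               n_expected = n * pr, p_raw = p_raw,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p_raw * nrow(out))
  out <- out[order(out$p_raw, out$term), ]
  rownames(out) <- NULL
  class(out) <- c("enrichment_table", "data.frame")
  out
}
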