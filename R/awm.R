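## Reshape a long gwas_table into snp x trait matrices.
gwas_matrices <- function(gwas) {
  traits <- attr(gwas, "traits")
  if (is.null(traits)) traits <- unique(gwas$trait)
  snps <- unique(gwas$snp)
  eff <- matrix(NA_real_, length(snps), length(traits),
                dimnames = list(snps, traits))
  pm <- eff
  eff[cbind(match(gwas$snp, snps), match(gwas$trait, traits))] <- gwas$effect
  pm[cbind(match(gwas$snp, snps), match(gwas$trait, traits))] <- gwas$p
  list(effect = eff, p = pm)
}

#' Column-standardize additive effects
#'
#' Each trait column of the SNP x trait effect grid is centred and scaled to
#' unit sample standard deviation (n-1 denominator), computed over *all* SNPs
#' in the input grid, before any selection takes place. This makes additive
#' effects comparable across traits with different units.
#'
#' @param gwas a `gwas_table` (or an effect matrix snp x trait).
#' @return numeric matrix of standardized effects, SNPs x traits.
#' @export
standardize_effects <- function(gwas) {
  eff <- if (is.matrix(gwas)) gwas else gwas_matrices(gwas)$effect
  if (nrow(eff) < 2L) stop("need at least 2 SNPs to standardize")
  sds <- apply(eff, 2L, sd, na.rm = TRUE)
  if (any(!is.finite(sds) | sds == 0))
    stop("zero-variance effect column(s): ",
         paste(colnames(eff)[!is.finite(sds) | sds == 0], collapse = ", "))
  scale(eff)[, , drop = FALSE]
}

#' Select SNPs associated with a key phenotype
#'
#' @param gwas a `gwas_table`.
#' @param key_traits key phenotype names.
#' @param p_thresh inclusive significance threshold (p <= p_thresh).
#' @return character vector of SNP ids (input order).
#' @export
select_key_snps <- function(gwas, key_traits, p_thresh = 0.05) {
  if (!length(key_traits)) stop("need at least one key trait")
  p <- gwas_matrices(gwas)$p[, key_traits, drop = FALSE]
  hit <- rowSums(p <= p_thresh, na.rm = TRUE) > 0
  rownames(p)[hit]
}

## Per-SNP count of supportive phenotypes with p <= threshold.
supportive_counts <- function(gwas, supportive_traits, p_thresh = 0.05) {
  p <- gwas_matrices(gwas)$p[, supportive_traits, drop = FALSE]
  rowSums(p <= p_thresh, na.rm = TRUE)
}

#' Average supportive-phenotype association count (A_P)
#'
#' The mean, over the key-selected SNPs, of the number of supportive
#' phenotypes each is associated with at `p <= p_thresh`. Returned unrounded;
#' this is the admission bar for additional SNPs.
#'
#' @param gwas a `gwas_table`.
#' @param s_key key-selected SNP ids.
#' @param supportive_traits supportive phenotype names.
#' @param p_thresh significance threshold.
#' @return scalar A_P.
#' @export
compute_ap <- function(gwas, s_key, supportive_traits, p_thresh = 0.05) {
  if (!length(s_key)) stop("no key-associated SNPs: cannot compute A_P")
  cnt <- supportive_counts(gwas, supportive_traits, p_thresh)[s_key]
  a_p <- mean(cnt)
  if (a_p == 0)
    warning("A_P is 0: supportive selection will admit every SNP")
  a_p
}

#' Select SNPs by supportive-phenotype association count
#'
#' Grid-wide selection of SNPs whose supportive-significance count satisfies
#' `count <comparator> A_P` (default `>=`, unrounded comparison).
#'
#' @param gwas a `gwas_table`.
#' @param a_p admission bar (typically from [compute_ap()]).
#' @param supportive_traits supportive phenotype names.
#' @param p_thresh significance threshold.
#' @param comparator `">="` or `">"`.
#' @return character vector of SNP ids.
#' @export
select_supportive_snps <- function(gwas, a_p, supportive_traits,
                                   p_thresh = 0.05, comparator = c(">=", ">")) {
  comparator <- match.arg(comparator)
  stopifnot(a_p >= 0)
  cnt <- supportive_counts(gwas, supportive_traits, p_thresh)
  hit <- if (comparator == ">=") cnt >= a_p else cnt > a_p
  names(cnt)[hit]
}

#' Map SNPs to their nearest gene within a proximity window
#'
#' Distance is 0 for a SNP inside the gene span, otherwise the distance to
#' the nearer span boundary. A SNP is kept iff its nearest gene lies within
#' `max_dist` bp (inclusive: exactly 2500 bp away is kept); it is assigned to
#' that nearest gene. Ties on distance go to the gene earlier by (start, id).
#'
#' @param snps SNP ids to map.
#' @param snp_map data.frame(snp, chrom, pos).
#' @param genes data.frame(gene, chrom, start, end).
#' @param max_dist proximity window in bp.
#' @return data.frame(snp, gene, distance, chrom, pos), dropped SNPs absent.
#' @export
map_snps_to_genes <- function(snps, snp_map, genes, max_dist = 2500) {
  sm <- snp_map[match(snps, snp_map$snp), ]
  if (anyNA(sm$snp)) stop("SNP(s) missing from map: ",
                          paste(snps[is.na(sm$snp)], collapse = ", "))
  res <- lapply(seq_len(nrow(sm)), function(i) {
    g <- genes[genes$chrom == sm$chrom[i], ]
    if (!nrow(g)) return(NULL)
    d <- ifelse(sm$pos[i] >= g$start & sm$pos[i] <= g$end, 0,
                pmin(abs(sm$pos[i] - g$start), abs(sm$pos[i] - g$end)))
    k <- order(d, g$start, g$gene)[1L]
    if (d[k] > max_dist) return(NULL)
    data.frame(snp = sm$snp[i], gene = g$gene[k], distance = d[k],
               chrom = sm$chrom[i], pos = sm$pos[i], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(snp = character(0), gene = character(0),
                      distance = numeric(0), chrom = character(0),
                      pos = integer(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Enforce the one-gene-one-SNP rule
#'
#' When several candidate SNPs map to the same gene, keep the SNP with the
#' highest number of phenotype associations at `p <= p_thresh` (across all
#' traits); ties are broken by the lowest mean p-value across traits, then by
#' genomic position, then by SNP id.
#'
#' @param mapping data.frame(snp, gene, ...) from [map_snps_to_genes()].
#' @param gwas a `gwas_table`.
#' @param p_thresh significance threshold for the association count.
#' @return `mapping` reduced to one row per gene.
#' @export
resolve_one_gene_one_snp <- function(mapping, gwas, p_thresh = 0.05) {
  p <- gwas_matrices(gwas)$p
  cnt <- rowSums(p <= p_thresh, na.rm = TRUE)
  meanp <- rowMeans(p, na.rm = TRUE)
  pos <- if ("pos" %in% names(mapping)) mapping$pos else rep(NA_real_,
                                                             nrow(mapping))
  pos[is.na(pos)] <- Inf
  keep <- unlist(lapply(split(seq_len(nrow(mapping)), mapping$gene),
                        function(ix) {
    s <- mapping$snp[ix]
    o <- order(-cnt[s], meanp[s], pos[ix], s)
    ix[o[1L]]
  }))
  out <- mapping[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Inject manually computed SNPs into a GWAS grid
#'
#' Adds SNP rows (e.g. causal variants absent from the chip, with effects and
#' p-values computed separately under the same model) to the grid so they
#' participate in standardization and every selection step exactly like chip
#' SNPs. The injected SNP's gene assignment bypasses distance mapping.
#'
#' @param gwas a `gwas_table`.
#' @param extra data.frame with columns snp, gene, trait, effect, p and
#'   optionally chrom, pos.
#' @return the augmented `gwas_table`, with an `injected` attribute mapping
#'   snp -> gene (plus chrom/pos when given).
#' @export
inject_custom_snps <- function(gwas, extra) {
  traits <- attr(gwas, "traits")
  if (is.null(traits)) traits <- unique(gwas$trait)
  for (s in unique(extra$snp)) {
    have <- sort(extra$trait[extra$snp == s])
    if (!identical(have, sort(traits)))
      stop("injected SNP ", s, " must carry all trait columns")
  }
  add <- data.frame(snp = extra$snp, trait = extra$trait,
                    effect = extra$effect, lrt = NA_real_, p = extra$p,
                    n_used = NA_integer_, stringsAsFactors = FALSE)
  out <- rbind(as.data.frame(gwas), add)
  attr(out, "traits") <- traits
  inj <- unique(extra[, intersect(c("snp", "gene", "chrom", "pos"),
                                  names(extra))])
  prev <- attr(gwas, "injected")
  attr(out, "injected") <- unique(rbind(prev, inj[order(inj$snp), ]))
  class(out) <- c("gwas_table", "data.frame")
  out
}

#' Trait-trait correlation matrix
#'
#' Pairwise-complete Spearman (default) correlations between the numeric
#' trait columns; the tool used to judge phenotype redundancy when choosing
#' supportive traits.
#'
#' @param traits trait table (data.frame with `roles` attribute) or a numeric
#'   matrix/data.frame of traits.
#' @param method correlation method.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
trait_correlation_matrix <- function(traits, method = "spearman") {
  roles <- attr(traits, "roles")
  Y <- if (!is.null(roles)) traits[, names(roles), drop = FALSE] else traits
  Y <- as.matrix(as.data.frame(Y))
  const <- apply(Y, 2L, function(v) var(v, na.rm = TRUE) == 0)
  if (any(const))
    warning("constant trait(s) produce missing correlations: ",
            paste(colnames(Y)[const], collapse = ", "))
  r <- suppressWarnings(cor(Y, use = "pairwise.complete.obs",
                            method = method))
  diag(r)[!const] <- 1
  r
}

#' Build the Association Weight Matrix
#'
#' Composes the full cascade: column standardization over all input SNPs,
#' optional manual SNP injection, key-phenotype selection (`p <= p_thresh`),
#' A_P computation, supportive-phenotype selection (count vs A_P), gene
#' proximity mapping (<= `max_dist` bp), and the one-gene-one-SNP rule.
#' Rows are genes sorted by chromosome and position; cells are the
#' standardized additive effects of each gene's chosen SNP.
#'
#' For a metabolite-only matrix pass `key_traits = character(0)` together
#' with `a_p_override` (the A_P from the full analysis): selection then uses
#' only the supportive-count rule.
#'
#' @param gwas a `gwas_table`.
#' @param snp_map data.frame(snp, chrom, pos).
#' @param genes gene annotation data.frame.
#' @param key_traits,supportive_traits trait role assignment.
#' @param p_thresh,max_dist,comparator cascade parameters.
#' @param round_ap round A_P to the nearest integer before comparison.
#' @param inject optional data.frame for [inject_custom_snps()].
#' @param a_p_override use this A_P instead of computing one.
#' @return object of class `awm`: list(effects = gene x trait matrix,
#'   genes = data.frame(gene, snp, chrom, pos, provenance), a_p, key_traits,
#'   supportive_traits).
#' @export
build_awm <- function(gwas, snp_map, genes, key_traits, supportive_traits,
                      p_thresh = 0.05, max_dist = 2500,
                      comparator = c(">=", ">"), round_ap = FALSE,
                      inject = NULL, a_p_override = NULL) {
  comparator <- match.arg(comparator)
  if (!is.null(inject)) gwas <- inject_custom_snps(gwas, inject)
  std <- standardize_effects(gwas)
  if (length(key_traits)) {
    s_key <- select_key_snps(gwas, key_traits, p_thresh)
    a_p <- if (is.null(a_p_override))
      compute_ap(gwas, s_key, supportive_traits, p_thresh) else a_p_override
  } else {
    if (is.null(a_p_override))
      stop("without key traits an a_p_override must be supplied")
    s_key <- character(0)
    a_p <- a_p_override
  }
  a_p_cmp <- if (round_ap) round(a_p) else a_p
  s_supp <- select_supportive_snps(gwas, a_p_cmp, supportive_traits,
                                   p_thresh, comparator)
  cand <- union(s_key, s_supp)
  injected <- attr(gwas, "injected")
  inj_snps <- intersect(cand, if (is.null(injected)) character(0)
                        else injected$snp)
  chip <- setdiff(cand, inj_snps)
  mapping <- map_snps_to_genes(chip, snp_map, genes, max_dist)
  if (length(inj_snps)) {
    im <- injected[match(inj_snps, injected$snp), ]
    mapping <- rbind(mapping,
                     data.frame(snp = im$snp, gene = im$gene, distance = 0,
                                chrom = if ("chrom" %in% names(im)) im$chrom
                                        else NA_character_,
                                pos = if ("pos" %in% names(im)) im$pos
                                      else NA_integer_,
                                stringsAsFactors = FALSE))
    if (anyDuplicated(mapping$gene))
      message("injected gene(s) collide with mapped genes; ",
              "one-gene-one-SNP resolution applies")
  }
  mapping <- resolve_one_gene_one_snp(mapping, gwas, p_thresh)
  if (!nrow(mapping)) stop("empty AWM: no SNP survived the selection cascade")
  prov <- ifelse(mapping$snp %in% inj_snps, "injected",
                 ifelse(mapping$snp %in% s_key, "key_selected",
                        "supportive_selected"))
  o <- order(mapping$chrom, mapping$pos, mapping$gene)
  mapping <- mapping[o, ]
  traits <- c(key_traits, supportive_traits)
  eff <- std[mapping$snp, traits, drop = FALSE]
  rownames(eff) <- mapping$gene
  out <- list(effects = eff,
              genes = data.frame(gene = mapping$gene, snp = mapping$snp,
                                 chrom = mapping$chrom, pos = mapping$pos,
                                 provenance = prov[o], stringsAsFactors = FALSE),
              a_p = a_p, key_traits = key_traits,
              supportive_traits = supportive_traits)
  class(out) <- "awm"
  out
}

#' @export
print.awm <- function(x, ...) {
  cat("Association Weight Matrix:", nrow(x$effects), "genes x",
      ncol(x$effects), "traits; A_P =", format(x$a_p, digits = 4), "\n")
  tb <- table(x$genes$provenance)
  cat("  provenance:", paste(names(tb), tb, sep = " = ", collapse = ", "),
      "\n")
  invisible(x)
}

#' @rdname build_awm
#' @param traits_to_drop traits (e.g. the key weight traits) removed from a
#'   `gwas_table` before building a metabolite-only AWM.
#' @export
drop_traits <- function(gwas, traits_to_drop) {
  keep <- !(gwas$trait %in% traits_to_drop)
  out <- as.data.frame(gwas)[keep, ]
  attr(out, "traits") <- setdiff(attr(gwas, "traits"), traits_to_drop)
  attr(out, "injected") <- attr(gwas, "injected")
  class(out) <- c("gwas_table", "data.frame")
  out
}
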