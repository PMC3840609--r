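#' Read PLINK-text genotypes
#'
#' Parses a `.ped`/`.map` pair, determines the minor allele of each biallelic
#' SNP from the data, and recodes genotypes to minor-allele counts minus one
#' ({-1, 0, +1}; "0 0" becomes missing). At an exact 50/50 allele-frequency
#' tie the alphabetically first allele is counted.
#'
#' @param path_ped,path_map file paths.
#' @return list(genotypes = integer matrix animals x SNPs, snp_map =
#'   data.frame(snp, chrom, pos, cM)).
#' @export
read_genotypes <- function(path_ped, path_map) {
  map <- read.table(path_map, header = FALSE, sep = "\t",
                    col.names = c("chrom", "snp", "cM", "pos"),
                    colClasses = c("character", "character", "numeric",
                                   "integer"))
  lines <- readLines(path_ped)
  lines <- lines[nzchar(lines)]
  toks <- strsplit(lines, "[ \t]+")
  m <- nrow(map)
  want <- 6L + 2L * m
  for (i in seq_along(toks))
    if (length(toks[[i]]) != want)
      stop("ragged .ped row at line ", i, ": expected ", want,
           " fields, found ", length(toks[[i]]))
  ids <- vapply(toks, `[[`, "", 2L)
  al <- matrix(unlist(lapply(toks, function(t) t[-(1:6)])),
               nrow = length(toks), byrow = TRUE)
  a1 <- al[, 2L * seq_len(m) - 1L, drop = FALSE]
  a2 <- al[, 2L * seq_len(m), drop = FALSE]
  g <- matrix(NA_integer_, length(ids), m,
              dimnames = list(ids, map$snp))
  for (j in seq_len(m)) {
    obs <- a1[, j] != "0" & a2[, j] != "0"
    alleles <- sort(unique(c(a1[obs, j], a2[obs, j])))
    if (length(alleles) > 2L)
      stop("SNP ", map$snp[j], " has more than two alleles: ",
           paste(alleles, collapse = "/"))
    if (length(alleles) == 0L) next  # all-missing column
    counted <- alleles[1L]
    if (length(alleles) == 2L) {
      f1 <- (sum(a1[obs, j] == alleles[1L]) + sum(a2[obs, j] == alleles[1L])) /
        (2 * sum(obs))
      counted <- if (f1 <= 0.5) alleles[1L] else alleles[2L]
    }
    g[obs, j] <- (a1[obs, j] == counted) + (a2[obs, j] == counted) - 1L
  }
  list(genotypes = g, snp_map = data.frame(snp = map$snp, chrom = map$chrom,
                                           pos = map$pos, cM = map$cM,
                                           stringsAsFactors = FALSE))
}

#' Write PLINK-text genotypes
#'
#' The counted (+1) allele is written as "A" and the other as "B", so a
#' matrix in minor-allele coding round-trips through [read_genotypes()]
#' unchanged. Missing genotypes become "0 0".
#'
#' @param genotypes integer matrix in {-1, 0, 1, NA}.
#' @param snp_map data.frame(snp, chrom, pos) with optional cM.
#' @param prefix output path prefix (writes `<prefix>.ped`, `<prefix>.map`).
#' @export
write_plink <- function(genotypes, snp_map, prefix) {
  stopifnot(ncol(genotypes) == nrow(snp_map))
  cM <- if ("cM" %in% names(snp_map)) snp_map$cM else 0
  map <- data.frame(snp_map$chrom, snp_map$snp, cM, snp_map$pos)
  write.table(map, paste0(prefix, ".map"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  pair <- c("B B", "A B", "A A")  # index = genotype + 2
  gtxt <- matrix("0 0", nrow(genotypes), ncol(genotypes))
  ok <- !is.na(genotypes)
  gtxt[ok] <- pair[genotypes[ok] + 2L]
  lines <- paste(rownames(genotypes), rownames(genotypes), 0, 0, 0, -9,
                 apply(gtxt, 1L, paste, collapse = " "))
  writeLines(lines, paste0(prefix, ".ped"))
  invisible(prefix)
}

#' Read a pedigree TSV (animal, sire, dam; 0 = unknown)
#' @param path file path.
#' @return validated pedigree data.frame.
#' @export
read_pedigree <- function(path) {
  ped <- read.table(path, header = TRUE, sep = "\t",
                    colClasses = "character")
  names(ped)[1:3] <- c("id", "sire", "dam")
  if (anyDuplicated(ped$id)) stop("duplicate animal ids in ", path)
  ped$sire[is.na(ped$sire) | ped$sire == ""] <- "0"
  ped$dam[is.na(ped$dam) | ped$dam == ""] <- "0"
  class(ped) <- c("gn_pedigree", "data.frame")
  validate_pedigree(ped)
  ped
}

#' @rdname read_pedigree
#' @param pedigree pedigree data.frame.
#' @export
write_pedigree <- function(pedigree, path) {
  write.table(pedigree[, c("id", "sire", "dam")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype TSV into a trait table
#'
#' First column is the animal id; `roles` assigns each analysed trait the
#' role "key" or "supportive"; remaining non-numeric columns are treated as
#' categorical covariates. Unparseable numeric cells become missing with a
#' warning.
#'
#' @param path file path.
#' @param roles named character vector trait -> role.
#' @param fixed_effects optional named list trait -> covariate columns.
#' @return trait table data.frame with attributes `roles`, `fixed_effects`.
#' @export
read_phenotypes <- function(path, roles, fixed_effects = NULL) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    colClasses = "character", check.names = FALSE)
  names(tab)[1] <- "id"
  if (anyDuplicated(tab$id)) stop("duplicate animal ids in ", path)
  missing_traits <- setdiff(names(roles), names(tab))
  if (length(missing_traits))
    stop("role refers to absent trait column(s): ",
         paste(missing_traits, collapse = ", "))
  if (!all(roles %in% c("key", "supportive")))
    stop("roles must be 'key' or 'supportive'")
  for (tr in names(roles)) {
    raw <- tab[[tr]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- is.na(num) & !is.na(raw) & raw != "" & raw != "NA"
    if (any(bad))
      warning(sum(bad), " unparseable value(s) in trait ", tr,
              " set to missing")
    tab[[tr]] <- num
  }
  for (cn in setdiff(names(tab), c("id", names(roles))))
    tab[[cn]] <- factor(tab[[cn]])
  attr(tab, "roles") <- roles
  attr(tab, "fixed_effects") <- fixed_effects
  tab
}

#' @rdname read_phenotypes
#' @param traits trait table.
#' @export
write_phenotypes <- function(traits, path) {
  write.table(traits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene annotation (TSV or BED)
#'
#' TSV columns: gene, chrom, start, end (1-based inclusive). BED input
#' (chrom, start, end, name; 0-based half-open) is converted to 1-based
#' inclusive on read.
#'
#' @param path file path.
#' @param format "tsv" or "bed".
#' @return data.frame(gene, chrom, start, end).
#' @export
read_annotation <- function(path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "bed") {
    b <- read.table(path, header = FALSE, sep = "\t",
                    colClasses = c("character", "integer", "integer",
                                   "character"))
    out <- data.frame(gene = b[[4]], chrom = b[[1]],
                      start = b[[2]] + 1L, end = b[[3]],
                      stringsAsFactors = FALSE)
  } else {
    out <- read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
    names(out)[1:4] <- c("gene", "chrom", "start", "end")
    out$chrom <- as.character(out$chrom)
  }
  if (anyDuplicated(out$gene)) stop("duplicate gene ids in ", path)
  if (any(out$start > out$end)) stop("gene with start > end in ", path)
  out
}

#' @rdname read_annotation
#' @param genes annotation data.frame.
#' @export
write_annotation <- function(genes, path) {
  write.table(genes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a co-association network
#'
#' SIF lines are `geneA pc geneB` with the lexicographically smaller gene
#' first and each undirected edge written once; the edge TSV carries the
#' signed correlation, and a node TSV the per-gene degree. Writers sort their
#' output so repeated runs are byte-identical.
#'
#' @param network a `coassoc_network`.
#' @param prefix output path prefix; writes `<prefix>.sif`,
#'   `<prefix>_edges.tsv`, `<prefix>_nodes.tsv`.
#' @export
write_network <- function(network, prefix) {
  e <- network$edges
  a <- pmin(e$gene_a, e$gene_b)
  b <- pmax(e$gene_a, e$gene_b)
  o <- order(a, b)
  writeLines(if (nrow(e)) paste(a[o], "pc", b[o]) else character(0),
             paste0(prefix, ".sif"))
  etab <- data.frame(gene_a = a, gene_b = b, correlation = e$correlation,
                     abs_correlation = abs(e$correlation))[o, ]
  write.table(etab, paste0(prefix, "_edges.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  nd <- network$nodes[order(network$nodes$gene), ]
  write.table(nd, paste0(prefix, "_nodes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(prefix)
}

#' @rdname write_network
#' @param path an `_edges.tsv` written by [write_network()].
#' @export
read_network_edges <- function(path) {
  e <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  nodes <- sort(unique(c(e$gene_a, e$gene_b)))
  deg <- table(factor(c(e$gene_a, e$gene_b), levels = nodes))
  new_coassoc_network(
    nodes = data.frame(gene = nodes, degree = as.integer(deg),
                       stringsAsFactors = FALSE),
    edges = e[, c("gene_a", "gene_b", "correlation")])
}

#' Write a simulated study to disk in the package's external formats
#'
#' @param sim a `growth_sim` from [simulate_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly. Writes PLINK .ped/.map, pedigree.tsv,
#'   phenotypes.tsv, genes.tsv, roles.yaml, truth_edges.tsv.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_plink(sim$genotypes, sim$snp_map, file.path(dir, "geno"))
  write_pedigree(sim$pedigree, file.path(dir, "pedigree.tsv"))
  write_phenotypes(sim$phenotypes, file.path(dir, "phenotypes.tsv"))
  write_annotation(sim$genes, file.path(dir, "genes.tsv"))
  roles <- attr(sim$phenotypes, "roles")
  yaml::write_yaml(list(roles = as.list(roles),
                        fixed_effects = attr(sim$phenotypes, "fixed_effects")),
                   file.path(dir, "roles.yaml"))
  gt <- sim$ground_truth$edges
  if (!is.null(gt))
    write.table(gt, file.path(dir, "truth_edges.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  invisible(dir)
}
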