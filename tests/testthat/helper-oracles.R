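# Independent oracles used across the suite. Each re-derives a quantity by a
# different route than the implementation it checks.

# Recursive kinship coefficients; the numerator relationship is 2 * kinship.
kinship_oracle <- function(ped) {
  ids <- ped$id
  n <- length(ids)
  sire <- setNames(ped$sire, ids)
  dam <- setNames(ped$dam, ids)
  depth <- setNames(rep(NA_integer_, n), ids)
  d_of <- function(i) {
    if (!is.na(depth[[i]])) return(depth[[i]])
    s <- sire[[i]]; d <- dam[[i]]
    v <- 1L + max(if (s == "0") 0L else d_of(s),
                  if (d == "0") 0L else d_of(d))
    depth[[i]] <<- v
    v
  }
  for (i in ids) d_of(i)
  memo <- new.env(parent = emptyenv())
  phi <- function(a, b) {
    if (a == "0" || b == "0") return(0)
    key <- paste(sort(c(a, b)), collapse = "\r")
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    val <- if (a == b) {
      0.5 * (1 + phi(sire[[a]], dam[[a]]))
    } else {
      # recurse on the animal that cannot be the other's ancestor
      y <- if (depth[[a]] >= depth[[b]]) a else b
      x <- setdiff(c(a, b), y)
      0.5 * (phi(sire[[y]], x) + phi(dam[[y]], x))
    }
    memo[[key]] <- val
    val
  }
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in i:n)
    A[i, j] <- A[j, i] <- 2 * phi(ids[i], ids[j])
  A
}

# Random valid pedigree: founders plus descendants with parents drawn from
# earlier animals.
random_pedigree <- function(n, n_founders = max(2L, n %/% 4L)) {
  id <- sprintf("ID%03d", seq_len(n))
  sire <- dam <- rep("0", n)
  for (i in (n_founders + 1L):n) {
    pa <- sample(i - 1L, 2L)
    sire[i] <- id[pa[1L]]
    dam[i] <- id[pa[2L]]
  }
  data.frame(id = id, sire = sire, dam = dam, stringsAsFactors = FALSE)
}

# Dense multivariate-normal REML log-likelihood, no rotation.
dense_reml_loglik <- function(y, X, A, sigma_u2, sigma_e2) {
  n <- length(y)
  p <- ncol(X)
  V <- sigma_u2 * A + sigma_e2 * diag(n)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  quad <- drop(t(r) %*% Vi %*% r)
  -0.5 * ((n - p) * log(2 * pi) + determinant(V)$modulus +
            determinant(XtViX)$modulus + quad)
}

# Partial correlation from the inverse of the 3x3 correlation matrix.
partial_via_inverse <- function(R) {
  P <- solve(R)
  -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
}

# A random well-conditioned correlation matrix of profile vectors.
random_cor_matrix <- function(n_genes, n_traits = 13) {
  cor(t(matrix(rnorm(n_genes * n_traits), n_genes, n_traits)))
}

# Exhaustive ancestor walk used by the pedigree acyclicity checks.
ancestors_of <- function(ped, id) {
  sire <- setNames(ped$sire, ped$id)
  dam <- setNames(ped$dam, ped$id)
  seen <- character(0)
  frontier <- id
  repeat {
    parents <- setdiff(unique(c(sire[frontier], dam[frontier])), c("0", seen))
    parents <- parents[!is.na(parents)]
    if (!length(parents)) return(seen)
    seen <- c(seen, parents)
    frontier <- parents
  }
}

# Small helper: a coassoc_network built directly from an edge list.
network_from_edges <- function(edges, all_genes = NULL) {
  genes <- sort(unique(c(edges$gene_a, edges$gene_b, all_genes)))
  deg <- table(factor(c(edges$gene_a, edges$gene_b), levels = genes))
  growthnet:::new_coassoc_network(
    nodes = data.frame(gene = genes, degree = as.integer(deg),
                       stringsAsFactors = FALSE),
    edges = edges)
}
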