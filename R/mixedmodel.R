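#' Genotype and sample quality control
#'
#' Samples with call rate not exceeding `min_sample_call` are removed first;
#' then SNPs with call rate at or below `min_snp_call` or minor-allele
#' frequency at or below `min_maf` are removed (i.e. survivors must be
#' strictly above every threshold).
#'
#' @param genotypes matrix in {-1, 0, 1, NA}, animals x SNPs.
#' @param min_snp_call,min_maf,min_sample_call thresholds in (0, 1].
#' @return filtered genotype matrix with a `qc_report` attribute listing the
#'   removal counts.
#' @export
qc_filter <- function(genotypes, min_snp_call = 0.85, min_maf = 0.01,
                      min_sample_call = 0.98) {
  stopifnot(min_snp_call > 0, min_snp_call <= 1,
            min_maf >= 0, min_maf <= 1,
            min_sample_call > 0, min_sample_call <= 1)
  sample_call <- rowMeans(!is.na(genotypes))
  keep_s <- sample_call > min_sample_call
  g <- genotypes[keep_s, , drop = FALSE]
  snp_call <- colMeans(!is.na(g))
  f <- colMeans((g + 1) / 2, na.rm = TRUE)
  maf <- pmin(f, 1 - f)
  maf[is.nan(maf)] <- 0
  keep_m <- snp_call > min_snp_call & maf > min_maf
  out <- g[, keep_m, drop = FALSE]
  if (ncol(out) == 0L)
    warning("QC removed every SNP; returning an empty genotype matrix")
  attr(out, "qc_report") <- list(
    n_samples_in = nrow(genotypes), n_samples_removed = sum(!keep_s),
    n_snps_in = ncol(genotypes), n_snps_removed = sum(!keep_m),
    min_snp_call = min_snp_call, min_maf = min_maf,
    min_sample_call = min_sample_call)
  out
}

## Rank check with offender names for fixed-effect designs.
check_full_rank <- function(X) {
  q <- qr(X)
  if (q$rank < ncol(X)) {
    bad <- colnames(X)[q$pivot[(q$rank + 1L):ncol(X)]]
    stop("singular fixed-effect design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  invisible(q)
}

#' REML fit of the polygenic animal model (no SNP term)
#'
#' Fits `y = X beta + u + e` with `Cov(u) = A sigma_u^2`, `Cov(e) = I
#' sigma_e^2` by a single eigendecomposition of `A` followed by 1-D
#' optimisation of the REML criterion over the variance ratio
#' `lambda = sigma_u^2 / sigma_e^2`; `beta` is the GLS estimate at the
#' optimum. The returned object carries the rotated design so per-SNP
#' association tests can reuse the fit.
#'
#' @param y numeric response vector.
#' @param X fixed-effect design matrix (including intercept).
#' @param A numerator relationship matrix aligned with `y`.
#' @param eig optional precomputed `eigen(A, symmetric = TRUE)`.
#' @param lambda optional fixed variance ratio (e.g. 0 for a pure
#'   fixed-effect fit); when NULL (default) it is estimated by REML.
#' @return object of class `reml_fit` with elements sigma_u2, sigma_e2,
#'   beta_hat, loglik (REML), lambda, h2, and the rotation internals.
#' @export
fit_null_model <- function(y, X, A, eig = NULL, lambda = NULL) {
  stopifnot(length(y) == nrow(X), length(y) == nrow(A))
  if (anyNA(y) || anyNA(X)) stop("y and X must be complete")
  check_full_rank(X)
  n <- length(y)
  p <- ncol(X)
  if (is.null(eig)) eig <- eigen(A, symmetric = TRUE)
  d <- pmax(eig$values, 0)
  U <- eig$vectors
  yt <- drop(crossprod(U, y))
  Xt <- crossprod(U, X)

  crit_lam <- function(lam) {
    w <- lam * d + 1
    sw <- sqrt(w)
    q <- qr(Xt / sw)
    res <- qr.resid(q, yt / sw)
    rss <- sum(res^2)
    s2 <- rss / (n - p)
    ldXX <- 2 * sum(log(abs(diag(qr.R(q)))))
    -0.5 * ((n - p) * log(2 * pi * s2) + (n - p) + sum(log(w)) + ldXX)
  }
  crit <- function(log_lambda) crit_lam(exp(log_lambda))
  if (is.null(lambda)) {
    grid <- seq(-12, 12, length.out = 49)
    vals <- vapply(grid, crit, 0)
    k <- which.max(vals)
    lo <- grid[max(1L, k - 1L)]
    hi <- grid[min(length(grid), k + 1L)]
    opt <- optimize(crit, c(lo, hi), maximum = TRUE, tol = 1e-8)
    ## allow the boundary lambda -> 0
    if (crit(-18) > opt$objective)
      opt <- list(maximum = -18, objective = crit(-18))
    lam <- exp(opt$maximum)
  } else {
    stopifnot(lambda >= 0)
    lam <- lambda
    opt <- list(objective = crit_lam(lam))
  }

  w <- lam * d + 1
  sw <- sqrt(w)
  Xw <- Xt / sw
  yw <- yt / sw
  qx <- qr(Xw)
  beta <- qr.coef(qx, yw)
  res <- qr.resid(qx, yw)
  rss <- sum(res^2)
  s2e <- rss / (n - p)
  out <- list(sigma_u2 = lam * s2e, sigma_e2 = s2e, lambda = lam,
              h2 = lam / (lam + 1),
              beta_hat = beta, loglik = opt$objective,
              n = n, p = p, eig = eig, w = w,
              qr_xw = qx, resid_w = res, rss_w = rss)
  class(out) <- "reml_fit"
  out
}

#' @export
print.reml_fit <- function(x, ...) {
  cat(sprintf(
    "Polygenic REML fit: n = %d, sigma_u2 = %.4f, sigma_e2 = %.4f (h2 = %.3f), REML loglik = %.3f\n",
    x$n, x$sigma_u2, x$sigma_e2, x$h2, x$loglik))
  invisible(x)
}

#' Single-SNP association under a fitted polygenic null
#'
#' The SNP enters as a fixed covariate estimated by GLS with the variance
#' components held at the null fit (EMMAX-style approximation; set
#' `exact_reml = TRUE` to re-estimate the variance ratio with the SNP in the
#' model). The likelihood-ratio statistic is `2 * (loglik_with -
#' loglik_without)` at the (shared or per-model) variance components, referred
#' to a 1-df chi-square. Missing genotypes are mean-imputed for the test;
#' monomorphic SNPs return `effect = NA, lrt = 0, p = 1`.
#'
#' @param snp genotype vector aligned with the null fit's observations.
#' @param null a `reml_fit` from [fit_null_model()].
#' @param y,X original response and design (needed only for `exact_reml`).
#' @param A relationship matrix (needed only for `exact_reml`).
#' @param exact_reml refit the variance ratio per SNP.
#' @return list(effect, lrt, p_value, n_used).
#' @export
snp_association <- function(snp, null, y = NULL, X = NULL, A = NULL,
                            exact_reml = FALSE) {
  g <- as.numeric(snp)
  n_used <- sum(!is.na(g))
  if (anyNA(g)) g[is.na(g)] <- mean(g, na.rm = TRUE)
  if (exact_reml) {
    if (is.null(y) || is.null(X) || is.null(A))
      stop("exact_reml = TRUE needs y, X and A")
    if (var(g) < 1e-12)
      return(list(effect = NA_real_, lrt = 0, p_value = 1, n_used = n_used))
    alt <- fit_null_model(y, cbind(X, snp = g), A, eig = null$eig)
    lrt <- max(0, 2 * (ml_loglik(y, cbind(X, snp = g), alt, null$eig) -
                         ml_loglik(y, X, null, null$eig)))
    eff <- unname(alt$beta_hat["snp"])
    return(list(effect = eff, lrt = lrt,
                p_value = pchisq(lrt, 1, lower.tail = FALSE), n_used = n_used))
  }
  gt <- drop(crossprod(null$eig$vectors, g)) / sqrt(null$w)
  gp <- qr.resid(null$qr_xw, gt)
  den <- sum(gp^2)
  if (den < 1e-10)
    return(list(effect = NA_real_, lrt = 0, p_value = 1, n_used = n_used))
  num <- sum(gp * null$resid_w)
  effect <- num / den
  lrt <- max(0, num^2 / den / null$sigma_e2)
  list(effect = effect, lrt = lrt,
       p_value = pchisq(lrt, 1, lower.tail = FALSE), n_used = n_used)
}

## Gaussian ML log-likelihood at the variance components of `fit`.
ml_loglik <- function(y, X, fit, eig) {
  n <- length(y)
  w <- fit$lambda * pmax(eig$values, 0) + 1
  sw <- sqrt(w)
  yt <- drop(crossprod(eig$vectors, y)) / sw
  Xt <- crossprod(eig$vectors, X) / sw
  res <- qr.resid(qr(Xt), yt)
  V_log_det <- n * log(fit$sigma_e2) + sum(log(w))
  -0.5 * (n * log(2 * pi) + V_log_det + sum(res^2) / fit$sigma_e2)
}

#' Multi-trait single-SNP mixed-model GWAS
#'
#' For every trait: intersect animals across genotypes, phenotypes and
#' pedigree, fit the polygenic null once by REML, then test every SNP as a
#' fixed GLS covariate (variance components held at the null; see
#' [snp_association()]). Fixed effects are taken per trait from the
#' `fixed_effects` attribute of the trait table (or the `fixed_effects`
#' argument): weight-like traits typically carry one categorical covariate,
#' metabolite-like traits two.
#'
#' @param genotypes QC-filtered genotype matrix (animals x SNPs).
#' @param traits trait table: data.frame with `id` first, covariate columns,
#'   numeric trait columns; attributes `roles`, `fixed_effects`.
#' @param pedigree pedigree data.frame.
#' @param fixed_effects optional named list trait -> covariate column names.
#' @param trait_names optional subset of traits to analyse.
#' @return data.frame of class `gwas_table` with columns snp, trait, effect,
#'   lrt, p, n_used; attribute `traits` preserves trait order.
#' @export
run_gwas <- function(genotypes, traits, pedigree, fixed_effects = NULL,
                     trait_names = NULL) {
  roles <- attr(traits, "roles")
  if (is.null(fixed_effects)) fixed_effects <- attr(traits, "fixed_effects")
  if (is.null(trait_names)) {
    trait_names <- names(roles)
    if (is.null(trait_names))
      trait_names <- names(traits)[vapply(traits, is.numeric, TRUE) &
                                     names(traits) != "id"]
  }
  ids0 <- intersect(intersect(traits$id, rownames(genotypes)), pedigree$id)
  A_full <- build_a_matrix(pedigree)
  res <- vector("list", length(trait_names))
  eig_cache <- list()
  for (ti in seq_along(trait_names)) {
    tr <- trait_names[ti]
    y_all <- traits[[tr]][match(ids0, traits$id)]
    ids <- ids0[!is.na(y_all)]
    y <- traits[[tr]][match(ids, traits$id)]
    if (length(unique(y)) < 2L || var(y) == 0) {
      warning("trait ", tr, " has zero variance; skipped")
      next
    }
    covs <- fixed_effects[[tr]]
    if (is.null(covs)) covs <- character(0)
    if (length(covs)) {
      fml <- as.formula(paste("~", paste(covs, collapse = " + ")))
      X <- model.matrix(fml, traits[match(ids, traits$id), covs, drop = FALSE])
    } else {
      X <- matrix(1, length(ids), 1, dimnames = list(NULL, "(Intercept)"))
    }
    key <- paste(c(ids, covs), collapse = "\r")
    if (is.null(eig_cache[[key]]))
      eig_cache[[key]] <- eigen(A_full[ids, ids], symmetric = TRUE)
    eig <- eig_cache[[key]]
    null <- fit_null_model(y, X, A_full[ids, ids], eig = eig)

    G <- genotypes[ids, , drop = FALSE]
    n_used <- colSums(!is.na(G))
    cm <- colMeans(G, na.rm = TRUE)
    nas <- which(is.na(G))
    if (length(nas)) G[nas] <- cm[(nas - 1L) %/% nrow(G) + 1L]
    Gt <- crossprod(eig$vectors, G) / sqrt(null$w)
    Gp <- qr.resid(null$qr_xw, Gt)
    den <- colSums(Gp^2)
    num <- drop(crossprod(Gp, null$resid_w))
    ok <- den >= 1e-10
    effect <- ifelse(ok, num / den, NA_real_)
    lrt <- ifelse(ok, pmax(0, num^2 / den / null$sigma_e2), 0)
    p <- pchisq(lrt, 1, lower.tail = FALSE)
    res[[ti]] <- data.frame(snp = colnames(genotypes), trait = tr,
                            effect = effect, lrt = lrt, p = p,
                            n_used = n_used, stringsAsFactors = FALSE,
                            row.names = NULL)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "traits") <- trait_names[trait_names %in% unique(out$trait)]
  class(out) <- c("gwas_table", "data.frame")
  out
}

#' @export
print.gwas_table <- function(x, ...) {
  cat("GWAS table:", length(unique(x$snp)), "SNPs x",
      length(unique(x$trait)), "traits;",
      sum(x$p <= 0.05, na.rm = TRUE), "cells with p <= 0.05\n")
  invisible(x)
}
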