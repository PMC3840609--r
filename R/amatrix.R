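#' Numerator relationship matrix from a pedigree
#'
#' Tabular (Henderson) method over animals sorted so parents precede
#' offspring: `A_ii = 1 + 0.5 * A_sd` (0 when a parent is unknown) and
#' `A_ij = 0.5 * (A_j,sire(i) + A_j,dam(i))`. Entries equal twice the kinship
#' coefficient; the founder block is the identity.
#'
#' @param pedigree data.frame with columns id, sire, dam ("0" = unknown).
#' @return symmetric matrix with animal ids as dimnames.
#' @export
build_a_matrix <- function(pedigree) {
  ord <- pedigree_order(pedigree)
  ped <- pedigree[ord, ]
  n <- nrow(ped)
  pos <- seq_len(n)
  names(pos) <- ped$id
  si <- ifelse(ped$sire == "0", 0L, pos[ped$sire])
  di <- ifelse(ped$dam == "0", 0L, pos[ped$dam])
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      as_ <- if (s > 0L) A[j, s] else numeric(i - 1L)
      ad_ <- if (d > 0L) A[j, d] else numeric(i - 1L)
      aij <- 0.5 * (as_ + ad_)
      A[j, i] <- aij
      A[i, j] <- aij
    }
    A[i, i] <- 1 + if (s > 0L && d > 0L) 0.5 * A[s, d] else 0
  }
  A[pedigree$id, pedigree$id, drop = FALSE]
}
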