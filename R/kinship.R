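#' Loiselle kinship coefficients
#'
#' Pairwise multilocus kinship following Loiselle et al. (1995). At locus l
#' with alternate-allele frequency p estimated from the analysis group and
#' n_l genotyped individuals, the per-locus kinship between i and j with
#' half-dosages x_i, x_j (genotype/2) is
#' \deqn{F_{ij,l} = (x_i - p)(x_j - p) / (p(1-p)) + 1/(2 n_l - 1),}
#' the second term being the finite-sample bias correction for reference
#' frequencies estimated from the 2 n_l sampled gene copies (it restores a
#' null expectation of ~0 for unrelated pairs). The multilocus
#' value is the average over loci genotyped in both individuals, weighted by
#' the per-locus polymorphic information p(1-p). Monomorphic loci carry zero
#' weight; pairs sharing no genotyped polymorphic locus are `NA`.
#'
#' @param gm A [genotype_matrix()] with >= 2 individuals and >= 1
#'   polymorphic locus; allele frequencies are computed from this matrix,
#'   so pass the analysis stratum, not the full panel, for
#'   stratum-autonomous estimates.
#' @return A list of class `kinship_matrix`: `fij` (symmetric n x n, `NA`
#'   diagonal), `n_loci` (per-pair usable polymorphic locus count).
#' @export
kinship_loiselle <- function(gm) {
  calls <- gm$calls
  n <- nrow(calls)
  if (n < 2) stop("need >= 2 individuals", call. = FALSE)
  x <- calls / 2
  n_l <- colSums(!is.na(x))
  p <- colMeans(x, na.rm = TRUE)
  w <- p * (1 - p)
  poly <- !is.na(w) & w > 0 & n_l >= 2
  if (!any(poly)) stop("all loci monomorphic", call. = FALSE)
  x <- x[, poly, drop = FALSE]
  p <- p[poly]; w <- w[poly]; n_l <- n_l[poly]

  m <- !is.na(x)                       # usable-call indicator
  xc <- sweep(x, 2, p, "-")
  xc[!m] <- 0
  mm <- m * 1
  # numerator: sum_l [ xc_i xc_j + w_l/(2 n_l - 1) ] over loci shared by i,j
  num <- tcrossprod(xc) + tcrossprod(sweep(mm, 2, w / (2 * n_l - 1), "*"), mm)
  den <- tcrossprod(sweep(mm, 2, w, "*"), mm)
  shared <- tcrossprod(mm)
  fij <- num / den
  fij[den == 0] <- NA_real_
  diag(fij) <- NA_real_
  dimnames(fij) <- list(rownames(calls), rownames(calls))
  fij <- (fij + t(fij)) / 2  # symmetrize exactly (den is symmetric anyway)
  structure(list(fij = fij, n_loci = shared), class = "kinship_matrix")
}

# Per-locus numerator/denominator contributions for jackknife-over-loci
# standard errors: returns, for the upper-triangle pair vector, a pairs x
# n_blocks matrix of numerator and denominator sums per locus block.
kinship_components <- function(gm, n_blocks = 100) {
  calls <- gm$calls
  x <- calls / 2
  n_l <- colSums(!is.na(x))
  p <- colMeans(x, na.rm = TRUE)
  w <- p * (1 - p)
  poly <- !is.na(w) & w > 0 & n_l >= 2
  x <- x[, poly, drop = FALSE]
  p <- p[poly]; w <- w[poly]; n_l <- n_l[poly]
  L <- ncol(x)
  blocks <- sort(rep_len(seq_len(min(n_blocks, L)), L))
  m <- !is.na(x); xc <- sweep(x, 2, p, "-"); xc[!m] <- 0
  mm <- m * 1
  ut <- upper.tri(matrix(0, nrow(x), nrow(x)))
  num_b <- den_b <- matrix(0, sum(ut), max(blocks))
  for (b in seq_len(max(blocks))) {
    idx <- which(blocks == b)
    nb <- tcrossprod(xc[, idx, drop = FALSE]) +
      tcrossprod(sweep(mm[, idx, drop = FALSE], 2,
                       (w / (2 * n_l - 1))[idx], "*"), mm[, idx, drop = FALSE])
    db <- tcrossprod(sweep(mm[, idx, drop = FALSE], 2, w[idx], "*"),
                     mm[, idx, drop = FALSE])
    num_b[, b] <- nb[ut]; den_b[, b] <- db[ut]
  }
  list(num = num_b, den = den_b)
}
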