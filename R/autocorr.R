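# Smouse-Peakall squared genotypic distance matrix, averaged over loci
# shared by each pair. For a biallelic codominant locus the pairwise
# squared distance equals the squared difference in alternate-allele
# dosage (AA-AA 0, AA-Aa 1, AA-aa 4, Aa-Aa 0, Aa-aa 1), so the per-pair
# mean over shared loci is computed by matrix products on the dosage codes.
genotypic_dist2 <- function(gm) {
  g <- gm$calls
  m <- (!is.na(g)) * 1
  g0 <- g; g0[is.na(g0)] <- 0L
  g2 <- g0^2
  shared <- tcrossprod(m)
  # sum over shared loci of (gi - gj)^2 = gi^2 + gj^2 - 2 gi gj,
  # each term restricted to loci genotyped in both individuals
  ss <- tcrossprod(g2, m) + tcrossprod(m, g2) - 2 * tcrossprod(g0)
  d2 <- ss / shared
  d2[shared == 0] <- NA_real_
  diag(d2) <- 0
  d2
}

# Gower-centered covariance matrix from a squared-distance matrix.
gower_center <- function(d2) {
  n <- nrow(d2)
  rm_ <- rowMeans(d2)
  gm_ <- mean(d2)
  -0.5 * (d2 - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + gm_)
}

# r per class from the centered matrix C and a class index per
# upper-triangle pair: r(h) = 2 sum c_ij / sum (c_ii + c_jj) over pairs in h.
r_from_c <- function(C, pair_i, pair_j, cls, nc) {
  cd <- diag(C)
  cij <- C[cbind(pair_i, pair_j)]
  r <- rep(NA_real_, nc)
  for (k in seq_len(nc)) {
    idx <- which(cls == k)
    if (!length(idx)) next
    den <- sum(cd[pair_i[idx]] + cd[pair_j[idx]])
    if (den > 0) r[k] <- 2 * sum(cij[idx]) / den
  }
  r
}

#' Multilocus spatial autocorrelation coefficient per distance class
#'
#' The Smouse & Peakall (1999) codominant autocorrelation: squared
#' multilocus genotypic distances between individuals are Gower-centered
#' into a covariance matrix, and r for a distance class is the ratio of the
#' summed between-individual covariance terms of pairs in the class to
#' their summed diagonal terms, cross-products summed across loci before
#' the ratio is formed. r is bounded in [-1, 1]; positive values mean
#' individuals in the class are genetically more similar than average.
#'
#' @param gm A [genotype_matrix()].
#' @param D Distance matrix in meters.
#' @param spec A [distance_classes()].
#' @return A list of class `autocorr_result` with `per_class` tibble
#'   (`class`, `lower`, `upper`, `midpoint`, `r`, `n_pairs`), `edges`,
#'   and `x_intercept` fields filled by [x_intercept()].
#' @export
multilocus_r <- function(gm, D, spec = distance_classes()) {
  stopifnot(nrow(gm$calls) == nrow(D))
  d2 <- genotypic_dist2(gm)
  if (any(is.na(d2)))
    stop("pairs sharing no genotyped locus; cannot center", call. = FALSE)
  C <- gower_center(d2)
  n <- nrow(D)
  ut <- which(upper.tri(D), arr.ind = TRUE)
  d <- D[upper.tri(D)]
  edges <- class_edges(spec, d[d > 0])
  cls <- assign_classes(d, edges)
  nc <- length(edges) - 1L
  r <- r_from_c(C, ut[, 1], ut[, 2], cls, nc)
  n_pairs <- vapply(seq_len(nc), function(k) sum(cls == k, na.rm = TRUE),
                    integer(1))
  if (any(n_pairs == 0))
    message(sprintf("multilocus_r: %d empty class(es); r missing there",
                    sum(n_pairs == 0)))
  res <- structure(list(
    per_class = tibble::tibble(class = seq_len(nc),
                               lower = edges[-length(edges)],
                               upper = edges[-1],
                               midpoint = class_midpoints(edges),
                               r = r, n_pairs = n_pairs),
    edges = edges, n_perm = 0L, n_boot = 0L, seed = NA_integer_),
    class = "autocorr_result")
  xi <- x_intercept(res)
  res$x_intercept <- xi$x_intercept
  res$x_intercept_flag <- xi$flag
  res
}

#' @export
print.autocorr_result <- function(x, ...) {
  cat(sprintf("<autocorr_result> %d classes, x-intercept %s\n",
              nrow(x$per_class),
              if (is.na(x$x_intercept)) paste0("absent (", x$x_intercept_flag, ")")
              else sprintf("%.1f m", x$x_intercept)))
  invisible(x)
}

#' Permutation envelope and bootstrap errors for the autocorrelogram
#'
#' Permutation: sample locations are shuffled among individuals and r
#' recomputed per class, giving a 2.5/97.5% null envelope. Bootstrap:
#' pairs within each class are resampled with replacement and r recomputed,
#' giving a standard error per class. Both are seeded and reproducible.
#'
#' @inheritParams multilocus_r
#' @param n_perm,n_boot Replicates (>= 99 each; default 999).
#' @param seed Integer seed.
#' @return An `autocorr_result` whose `per_class` gains `lo`, `hi`,
#'   `signif`, `se` columns.
#' @export
r_significance <- function(gm, D, spec = distance_classes(), n_perm = 999,
                           n_boot = 999, seed = 1L) {
  if (n_perm < 99 || n_boot < 99)
    stop("n_perm and n_boot must be >= 99", call. = FALSE)
  res <- multilocus_r(gm, D, spec)
  d2 <- genotypic_dist2(gm)
  C <- gower_center(d2)
  cd <- diag(C)
  n <- nrow(D)
  ut <- which(upper.tri(D), arr.ind = TRUE)
  edges <- res$edges
  nc <- nrow(res$per_class)

  set.seed(seed)
  perm_r <- matrix(NA_real_, n_perm, nc)
  for (i in seq_len(n_perm)) {
    ord <- sample.int(n)
    dp <- D[ord, ord][upper.tri(D)]
    cls <- assign_classes(dp, edges)
    perm_r[i, ] <- r_from_c(C, ut[, 1], ut[, 2], cls, nc)
  }
  res$per_class$lo <- apply(perm_r, 2, stats::quantile, 0.025, na.rm = TRUE)
  res$per_class$hi <- apply(perm_r, 2, stats::quantile, 0.975, na.rm = TRUE)
  res$per_class$signif <- res$per_class$r < res$per_class$lo |
    res$per_class$r > res$per_class$hi

  d <- D[upper.tri(D)]
  cls_obs <- assign_classes(d, edges)
  cij <- C[cbind(ut[, 1], ut[, 2])]
  se <- rep(NA_real_, nc)
  for (k in seq_len(nc)) {
    idx <- which(cls_obs == k)
    if (length(idx) < 2) next
    boot <- vapply(seq_len(n_boot), function(b) {
      take <- sample(idx, length(idx), replace = TRUE)
      den <- sum(cd[ut[take, 1]] + cd[ut[take, 2]])
      if (den <= 0) return(NA_real_)
      2 * sum(cij[take]) / den
    }, numeric(1))
    se[k] <- stats::sd(boot, na.rm = TRUE)
  }
  res$per_class$se <- se
  res$n_perm <- n_perm; res$n_boot <- n_boot; res$seed <- seed
  res
}

#' X-intercept of the autocorrelogram
#'
#' The distance at which the r curve first crosses zero, located by linear
#' interpolation between consecutive class midpoints; read as the extent of
#' positive genetic structure (the effective gene-dispersal neighborhood).
#' If r starts at or below zero the intercept is the first midpoint,
#' flagged `"immediate"`; with no sign change the intercept is absent.
#'
#' @param result An `autocorr_result` (or any list with a `per_class`
#'   tibble holding `midpoint` and `r`).
#' @return A list with `x_intercept` (meters or `NA`) and `flag`
#'   (`"interpolated"`, `"immediate"` or `"absent"`).
#' @export
x_intercept <- function(result) {
  pc <- result$per_class
  ok <- is.finite(pc$r)
  r <- pc$r[ok]; mid <- pc$midpoint[ok]
  if (length(r) < 2) return(list(x_intercept = NA_real_, flag = "absent"))
  if (r[1] <= 0) return(list(x_intercept = mid[1], flag = "immediate"))
  for (k in seq_len(length(r) - 1L)) {
    if (r[k] > 0 && r[k + 1] <= 0) {
      x0 <- mid[k] + r[k] * (mid[k + 1] - mid[k]) / (r[k] - r[k + 1])
      return(list(x_intercept = x0, flag = "interpolated"))
    }
  }
  list(x_intercept = NA_real_, flag = "absent")
}
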