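#' Sp statistic of spatial genetic structure intensity
#'
#' \deqn{Sp = -bF / (1 - F_{(1)})} where `bF` is the regression slope of
#' pairwise kinship on ln(distance) and `F1` the mean kinship in the first
#' distance class.
#'
#' @param bF Regression slope.
#' @param F1 First-distance-class mean kinship, must be < 1.
#' @return The Sp value.
#' @export
sp_statistic <- function(bF, F1) {
  if (any(F1 >= 1)) stop("F(1) must be < 1", call. = FALSE)
  -bF / (1 - F1)
}

#' Kinship-distance SGS profile
#'
#' Bins pairs into distance classes, averages kinship per class, regresses
#' pairwise kinship on ln(distance) over all pairs (pairs at distance 0 are
#' excluded and counted), and summarizes the profile by `bF` (the slope),
#' `F1` (first-class mean) and `Sp` ([sp_statistic()]). A delete-one-block
#' jackknife over loci gives a standard error for `bF` when `gm` is
#' supplied.
#'
#' @param K A `kinship_matrix` from [kinship_loiselle()].
#' @param D Distance matrix in meters, aligned with `K`.
#' @param spec A [distance_classes()] specification.
#' @param gm Optional [genotype_matrix()] (same one used for `K`) enabling
#'   the jackknife `se_bF`.
#' @param n_jackknife_blocks Locus blocks for the jackknife (default 100).
#' @return A list of class `sgs_result`: `per_class` tibble (`class`,
#'   `lower`, `upper`, `midpoint`, `mean_fij`, `n_pairs`), `bF`, `se_bF`,
#'   `F1`, `Sp`, `n_pairs_total`, `n_zero_distance_excluded`, `edges`.
#' @export
sgs_profile <- function(K, D, spec = distance_classes(), gm = NULL,
                        n_jackknife_blocks = 100) {
  fij_m <- if (inherits(K, "kinship_matrix")) K$fij else K
  stopifnot(all(dim(fij_m) == dim(D)))
  ut <- upper.tri(fij_m)
  fij <- fij_m[ut]
  d <- D[ut]
  zero <- d <= 0
  n_zero <- sum(zero)
  if (n_zero > 0)
    message(sprintf("sgs_profile: excluded %d zero-distance pair(s) from regression", n_zero))
  usable <- !zero & !is.na(fij)

  edges <- class_edges(spec, d[usable])
  cls <- assign_classes(d, edges)
  cls[!usable] <- NA_integer_
  nc <- length(edges) - 1L
  mean_fij <- vapply(seq_len(nc), function(k) mean(fij[which(cls == k)]),
                     numeric(1))
  n_pairs <- vapply(seq_len(nc), function(k) sum(cls == k, na.rm = TRUE),
                    integer(1))
  if (n_pairs[1] == 0)
    stop("first distance class is empty under the given class spec",
         call. = FALSE)

  ld <- log(d[usable])
  fit <- stats::lm.fit(cbind(1, ld), fij[usable])
  bF <- unname(fit$coefficients[2])
  F1 <- mean_fij[1]

  se_bF <- NA_real_
  if (!is.null(gm)) {
    comp <- kinship_components(gm, n_jackknife_blocks)
    pair_keep <- which(usable)
    num_tot <- rowSums(comp$num); den_tot <- rowSums(comp$den)
    ldc <- ld - mean(ld)
    ss <- sum(ldc^2)
    nb <- ncol(comp$num)
    slopes <- vapply(seq_len(nb), function(b) {
      f <- (num_tot - comp$num[, b]) / (den_tot - comp$den[, b])
      f <- f[pair_keep]
      ok <- is.finite(f)
      sum(ldc[ok] * f[ok]) / sum(ldc[ok]^2)
    }, numeric(1))
    se_bF <- sqrt((nb - 1) / nb * sum((slopes - mean(slopes))^2))
  }

  structure(list(
    per_class = tibble::tibble(class = seq_len(nc),
                               lower = edges[-length(edges)],
                               upper = edges[-1],
                               midpoint = class_midpoints(edges),
                               mean_fij = mean_fij, n_pairs = n_pairs),
    bF = bF, se_bF = se_bF, F1 = F1, Sp = sp_statistic(bF, F1),
    n_pairs_total = sum(!is.na(fij)), n_zero_distance_excluded = n_zero,
    edges = edges), class = "sgs_result")
}

#' @export
print.sgs_result <- function(x, ...) {
  cat(sprintf("<sgs_result> bF = %.5f, F(1) = %.5f, Sp = %.5f (%d classes)\n",
              x$bF, x$F1, x$Sp, nrow(x$per_class)))
  invisible(x)
}

#' Permutation envelopes for an SGS profile
#'
#' The SGS null of random spatial arrangement: sample locations are
#' permuted among individuals while the kinship matrix stays fixed. For
#' each permutation the per-class mean kinship and the regression slope are
#' recomputed against the permuted distances (class edges held at their
#' observed values). Envelopes are the 2.5% and 97.5% percentiles; a class
#' (or `bF`) is significant when the observed value falls outside its
#' envelope.
#'
#' @param K A `kinship_matrix`.
#' @param D Distance matrix, meters.
#' @param spec A [distance_classes()].
#' @param n_perm Number of permutations (>= 99; default 999).
#' @param seed Integer seed.
#' @return The [sgs_profile()] result augmented with per-class `lo`, `hi`,
#'   `signif` columns and `bF_lo`, `bF_hi`, `bF_signif`.
#' @export
sgs_permutation <- function(K, D, spec = distance_classes(), n_perm = 999,
                            seed = 1L) {
  if (n_perm < 99) stop("n_perm must be >= 99", call. = FALSE)
  res <- sgs_profile(K, D, spec)
  fij_m <- if (inherits(K, "kinship_matrix")) K$fij else K
  n <- nrow(fij_m)
  ut <- upper.tri(fij_m)
  fij <- fij_m[ut]
  edges <- res$edges
  nc <- nrow(res$per_class)

  set.seed(seed)
  perm_means <- matrix(NA_real_, n_perm, nc)
  perm_bF <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    ord <- sample.int(n)
    dp <- D[ord, ord][ut]
    usable <- dp > 0 & !is.na(fij)
    cls <- assign_classes(dp, edges)
    cls[!usable] <- NA_integer_
    for (k in seq_len(nc)) {
      idx <- which(cls == k)
      if (length(idx)) perm_means[i, k] <- mean(fij[idx])
    }
    ld <- log(dp[usable])
    ldc <- ld - mean(ld)
    perm_bF[i] <- sum(ldc * fij[usable]) / sum(ldc^2)
  }
  lo <- apply(perm_means, 2, stats::quantile, 0.025, na.rm = TRUE)
  hi <- apply(perm_means, 2, stats::quantile, 0.975, na.rm = TRUE)
  res$per_class$lo <- lo
  res$per_class$hi <- hi
  res$per_class$signif <- res$per_class$mean_fij < lo | res$per_class$mean_fij > hi
  res$bF_lo <- stats::quantile(perm_bF, 0.025, names = FALSE)
  res$bF_hi <- stats::quantile(perm_bF, 0.975, names = FALSE)
  res$bF_signif <- res$bF < res$bF_lo | res$bF > res$bF_hi
  res$n_perm <- n_perm
  res$seed <- seed
  res
}

#' SGS profiles by stratum
#'
#' Runs the kinship + profile (+ optional permutation) analysis
#' independently within each stratum (population, age class or patch),
#' with stratum-internal allele frequencies. Strata with fewer than
#' `min_n` individuals are skipped with a warning.
#'
#' @param gm A [genotype_matrix()] covering all samples.
#' @param samples Sample tibble aligned with `gm` rows (needs coordinate
#'   columns and the stratum column).
#' @param stratum Column of `samples` to stratify by: `"population"`,
#'   `"age_class"` or `"patch"`.
#' @param spec A [distance_classes()].
#' @param n_perm Permutations per stratum; 0 skips envelopes.
#' @param seed Integer seed (one per-stratum seed is derived from it).
#' @param min_n Minimum individuals per stratum (default 10).
#' @return Named list of `sgs_result`, one per retained stratum.
#' @export
sgs_by_stratum <- function(gm, samples, stratum = c("patch", "population",
                                                    "age_class"),
                           spec = distance_classes(), n_perm = 0,
                           seed = 1L, min_n = 10) {
  stratum <- match.arg(stratum)
  stopifnot(nrow(samples) == nrow(gm$calls))
  levels <- unique(as.character(samples[[stratum]]))
  out <- list()
  for (i in seq_along(levels)) {
    s <- levels[i]
    idx <- which(as.character(samples[[stratum]]) == s)
    if (length(idx) < min_n) {
      warning(sprintf("stratum %s: only %d individuals (< %d); skipped",
                      s, length(idx), min_n))
      next
    }
    sub_gm <- subset_gm(gm, samples = idx)
    sub_gm <- tryCatch(maf_filter(sub_gm), error = function(e) NULL)
    res <- tryCatch({
      K <- kinship_loiselle(sub_gm)
      D <- pairwise_distance(samples[idx, ])
      if (n_perm > 0) sgs_permutation(K, D, spec, n_perm,
                                      seed = seed + i)
      else sgs_profile(K, D, spec)
    }, error = function(e) {
      warning(sprintf("stratum %s skipped: %s", s, conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) out[[s]] <- res
  }
  out
}
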