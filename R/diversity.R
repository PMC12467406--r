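#' Per-group diversity statistics
#'
#' For each group (e.g. patch or population), computes per-locus observed
#' heterozygosity HO (heterozygote count over genotyped individuals),
#' unbiased expected heterozygosity HE = (2n/(2n-1)) * (1 - p^2 - q^2), and
#' Fis = 1 - HO/HE (for HE > 0), then averages over loci polymorphic within
#' the group. `num_indv` is the mean number of genotyped individuals per
#' locus, over the same loci.
#'
#' @param gm A [genotype_matrix()].
#' @param groups Character/factor vector, one entry per sample, naming the
#'   group of each sample (e.g. `samples$patch`).
#' @return A tibble with columns `group`, `num_indv`, `ho`, `he`, `fis`,
#'   `n_loci` (polymorphic loci used). Groups whose loci are all
#'   monomorphic get `ho = he = 0` and `fis = NA` with a warning.
#' @export
diversity <- function(gm, groups) {
  calls <- gm$calls
  if (length(groups) != nrow(calls))
    stop("`groups` must have one entry per sample", call. = FALSE)
  out <- lapply(unique(as.character(groups)), function(g) {
    sub <- calls[as.character(groups) == g, , drop = FALSE]
    if (nrow(sub) < 2) {
      warning(sprintf("group %s has < 2 individuals; skipped", g))
      return(NULL)
    }
    n_l <- colSums(!is.na(sub))
    ok <- n_l >= 2
    p <- colMeans(sub, na.rm = TRUE) / 2
    ho_l <- colMeans(sub == 1L, na.rm = TRUE)
    he_l <- (2 * n_l / (2 * n_l - 1)) * (1 - p^2 - (1 - p)^2)
    poly <- ok & !is.na(p) & p > 0 & p < 1
    if (!any(poly)) {
      warning(sprintf("group %s: all loci monomorphic; Fis undefined", g))
      return(tibble::tibble(group = g, num_indv = mean(n_l[ok]), ho = 0,
                            he = 0, fis = NA_real_, n_loci = 0L))
    }
    fis_l <- 1 - ho_l[poly] / he_l[poly]
    tibble::tibble(group = g,
                   num_indv = mean(n_l[poly]),
                   ho = mean(ho_l[poly]),
                   he = mean(he_l[poly]),
                   fis = mean(fis_l),
                   n_loci = sum(poly))
  })
  dplyr::bind_rows(out)
}

#' Patch-level t-test of observed vs expected heterozygosity
#'
#' Pooled-variance (equal-variance) independent two-sample t-test of the
#' per-patch HO values against the per-patch HE values of one population,
#' the test behind the study-level "HO < HE" significance calls. With three
#' patches per group the degrees of freedom are 4.
#'
#' @param ho_values,he_values Numeric vectors of per-patch HO and HE
#'   (length >= 2 each).
#' @return A tibble with `mean_difference` (mean HO - mean HE), `t_value`,
#'   `df`, `p_value` (two-sided) and `significance` (`***` p < 0.001,
#'   `**` p < 0.01, `*` p < 0.05, `ns` otherwise).
#' @export
ho_he_ttest <- function(ho_values, he_values) {
  if (length(ho_values) < 2 || length(he_values) < 2)
    stop("need at least two values per side", call. = FALSE)
  if (stats::var(ho_values) == 0 && stats::var(he_values) == 0)
    stop("zero pooled variance: degenerate t-test", call. = FALSE)
  tt <- stats::t.test(ho_values, he_values, var.equal = TRUE)
  p <- tt$p.value
  stars <- if (p < 0.001) "***" else if (p < 0.01) "**" else
    if (p < 0.05) "*" else "ns"
  tibble::tibble(mean_difference = mean(ho_values) - mean(he_values),
                 t_value = unname(tt$statistic),
                 df = unname(tt$parameter),
                 p_value = p,
                 significance = stars)
}
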