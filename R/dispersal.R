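#' Effective gene-dispersal distance
#'
#' Combines mean seed and pollen dispersal distances under the gene-
#' dispersal variance decomposition \deqn{\sigma_g^2 = \sigma_s^2 +
#' \sigma_p^2 / 2,} pollen contributing half because it moves a haploid
#' genome.
#'
#' @param seed_mean,pollen_mean Mean dispersal distances in meters (>= 0).
#' @return Effective gene-dispersal distance in meters.
#' @export
effective_gene_dispersal <- function(seed_mean, pollen_mean) {
  if (any(seed_mean < 0) || any(pollen_mean < 0))
    stop("dispersal distances must be >= 0", call. = FALSE)
  sqrt(seed_mean^2 + pollen_mean^2 / 2)
}

#' Direct dispersal summaries per patch
#'
#' Per patch: mean and maximum seed and pollen distances and the combined
#' effective gene-dispersal distance ([effective_gene_dispersal()] of the
#' patch means). A `means` row per population is the unweighted arithmetic
#' mean over patches with data; patches without events carry `NA`.
#'
#' @param events Tibble of dispersal events ([dispersal_events()]).
#' @param patch_population Optional named vector mapping patch to
#'   population; when given, one `means` row is appended per population.
#' @return A tibble: `population` (if mapped), `patch`, `seed_max`,
#'   `seed_mean`, `pollen_max`, `pollen_mean`, `gene_effective`, `n_events`.
#' @export
direct_summary <- function(events, patch_population = NULL) {
  stopifnot(all(c("kind", "distance_m", "patch") %in% names(events)))
  per_patch <- events |>
    dplyr::group_by(.data$patch, .data$kind) |>
    dplyr::summarise(mean = mean(.data$distance_m),
                     max = max(.data$distance_m),
                     n = dplyr::n(), .groups = "drop")
  patches <- unique(events$patch)
  rows <- lapply(patches, function(pk) {
    s <- per_patch[per_patch$patch == pk & per_patch$kind == "seed", ]
    p <- per_patch[per_patch$patch == pk & per_patch$kind == "pollen", ]
    sm <- if (nrow(s)) s$mean else NA_real_
    pm <- if (nrow(p)) p$mean else NA_real_
    tibble::tibble(patch = pk,
                   seed_max = if (nrow(s)) s$max else NA_real_,
                   seed_mean = sm,
                   pollen_max = if (nrow(p)) p$max else NA_real_,
                   pollen_mean = pm,
                   gene_effective = if (!is.na(sm) && !is.na(pm))
                     effective_gene_dispersal(sm, pm) else NA_real_,
                   n_events = sum(s$n, p$n))
  })
  out <- dplyr::bind_rows(rows)
  if (!is.null(patch_population)) {
    out$population <- unname(patch_population[out$patch])
    means <- out |>
      dplyr::group_by(.data$population) |>
      dplyr::summarise(patch = "means",
                       seed_max = NA_real_,
                       seed_mean = mean(.data$seed_mean, na.rm = TRUE),
                       pollen_max = NA_real_,
                       pollen_mean = mean(.data$pollen_mean, na.rm = TRUE),
                       gene_effective = mean(.data$gene_effective, na.rm = TRUE),
                       n_events = sum(.data$n_events), .groups = "drop")
    out <- dplyr::bind_rows(out, means)
    out <- out[order(out$population, out$patch == "means", out$patch), ]
    out <- dplyr::relocate(out, "population")
  }
  out
}

#' Fit the cubic ln-distance decay curve
#'
#' Least-squares fit of the class-level autocorrelation values F(r) on
#' \deqn{F(r) = a + b \ln r + c \ln^2 r + d \ln^3 r.} The companion
#' curvature statistic is reported in two forms: the literal
#' `K = 2c + 6 ln(r1)` and the second-derivative-consistent
#' `K = 2c + 6 d ln(r1)`, `r1` being the first class midpoint. Real roots
#' of the fitted cubic (in ln-space, mapped back to meters) are restricted
#' to the spanned midpoint range.
#'
#' @param class_midpoints Distance class midpoints in meters (>= 4 finite).
#' @param r_values Correlogram values per class.
#' @return A list of class `dispersal_curve_fit`: `coefficients` (a, b, c,
#'   d), `K_literal`, `K_dcorrected`, `r1`, `roots_m` (meters, ascending),
#'   `residual_norm`, `range_m`.
#' @export
fit_dispersal_curve <- function(class_midpoints, r_values) {
  ok <- is.finite(class_midpoints) & is.finite(r_values) & class_midpoints > 0
  x <- log(class_midpoints[ok]); y <- r_values[ok]
  if (length(x) < 4) stop("need >= 4 classes with finite r", call. = FALSE)
  X <- cbind(1, x, x^2, x^3)
  if (qr(X)$rank < 4) stop("collinear design: midpoints too few/repeated",
                           call. = FALSE)
  fit <- stats::lm.fit(X, y)
  cf <- unname(fit$coefficients)
  names(cf) <- c("a", "b", "c", "d")
  r1 <- min(class_midpoints[ok])
  rng <- range(class_midpoints[ok])
  roots <- polyroot(cf)
  real <- Re(roots[abs(Im(roots)) < 1e-8])
  roots_m <- sort(exp(real))
  roots_m <- roots_m[roots_m >= rng[1] & roots_m <= rng[2]]
  structure(list(coefficients = cf,
                 K_literal = 2 * cf["c"] + 6 * log(r1),
                 K_dcorrected = 2 * cf["c"] + 6 * cf["d"] * log(r1),
                 r1 = r1, roots_m = roots_m,
                 residual_norm = sqrt(sum(fit$residuals^2)),
                 range_m = rng),
            class = "dispersal_curve_fit")
}

#' @export
print.dispersal_curve_fit <- function(x, ...) {
  cat(sprintf("<dispersal_curve_fit> a=%.4g b=%.4g c=%.4g d=%.4g; %d root(s) in [%.1f, %.1f] m\n",
              x$coefficients[1], x$coefficients[2], x$coefficients[3],
              x$coefficients[4], length(x$roots_m), x$range_m[1], x$range_m[2]))
  invisible(x)
}

#' Indirect gene-dispersal distance range
#'
#' Combines the two readings of "where the correlogram crosses zero": the
#' linearly interpolated x-intercept and the first root of the fitted
#' cubic. The reported range is (min, max) of the two; when only one
#' exists the range collapses and is flagged; when neither exists the
#' patch is labeled spatially random.
#'
#' @param autocorr An `autocorr_result`.
#' @param fit A `dispersal_curve_fit` for the same correlogram.
#' @return A tibble: `min_m`, `max_m`, `flag` (`"both"`,
#'   `"intercept_only"`, `"root_only"`, `"random_variation"`).
#' @export
indirect_summary <- function(autocorr, fit) {
  xi <- autocorr$x_intercept
  root <- if (length(fit$roots_m)) fit$roots_m[1] else NA_real_
  have_xi <- is.finite(xi); have_root <- is.finite(root)
  if (!have_xi && !have_root)
    return(tibble::tibble(min_m = NA_real_, max_m = NA_real_,
                          flag = "random_variation"))
  if (have_xi && have_root)
    return(tibble::tibble(min_m = min(xi, root), max_m = max(xi, root),
                          flag = "both"))
  v <- if (have_xi) xi else root
  tibble::tibble(min_m = v, max_m = v,
                 flag = if (have_xi) "intercept_only" else "root_only")
}
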