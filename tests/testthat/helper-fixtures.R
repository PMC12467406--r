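# Shared fixtures, built in code and cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, .fixture_cache)) assign(key, builder(), .fixture_cache)
  get(key, .fixture_cache)
}

# A mid-sized error-free dataset reused by several files.
clean_dataset <- function() cached("clean", function() {
  simulate_population(sim_config(
    n_founders = 24, n_loci = 120, n_generations = 2,
    offspring_per_generation = 24, genotyping_error = 0, missing_rate = 0,
    rng_seed = 42))
})

# Hardy-Weinberg genotypes with uniform random positions: the spatial null.
null_panel <- function(n = 40, L = 50, seed = 1) {
  set.seed(seed)
  p <- stats::runif(L, 0.1, 0.5)
  calls <- vapply(p, function(pp) stats::rbinom(n, 2L, pp), integer(n))
  rownames(calls) <- sprintf("i%03d", seq_len(n))
  colnames(calls) <- sprintf("L%03d", seq_len(L))
  list(gm = genotype_matrix(calls),
       samples = tibble::tibble(id = rownames(calls),
                                x = stats::runif(n, 0, 500),
                                y = stats::runif(n, 0, 500)))
}

# Independent per-locus Loiselle oracle: explicit loops, no matrix algebra.
loiselle_oracle <- function(calls) {
  n <- nrow(calls); L <- ncol(calls)
  x <- calls / 2
  out <- matrix(NA_real_, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    num <- 0; den <- 0
    for (l in seq_len(L)) {
      xi <- x[i, l]; xj <- x[j, l]
      if (is.na(xi) || is.na(xj)) next
      xl <- x[, l]; xl <- xl[!is.na(xl)]
      nl <- length(xl); pl <- mean(xl); wl <- pl * (1 - pl)
      if (wl <= 0 || nl < 2) next
      fl <- (xi - pl) * (xj - pl) / wl + 1 / (2 * nl - 1)
      num <- num + wl * fl; den <- den + wl
    }
    out[i, j] <- out[j, i] <- if (den > 0) num / den else NA_real_
  }
  out
}

# Independent Smouse-Peakall oracle: per-locus squared genotypic distances
# summed across loci, Gower-centered, class ratio formed from sums.
smouse_peakall_oracle <- function(calls, D, edges) {
  n <- nrow(calls)
  d2 <- matrix(0, n, n)
  for (l in seq_len(ncol(calls)))
    d2 <- d2 + outer(calls[, l], calls[, l], function(a, b) (a - b)^2)
  rm_ <- rowMeans(d2); gm_ <- mean(d2)
  C <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    C[i, j] <- -0.5 * (d2[i, j] - rm_[i] - rm_[j] + gm_)
  nc <- length(edges) - 1
  r <- rep(NA_real_, nc)
  for (k in seq_len(nc)) {
    num <- 0; den <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      d <- D[i, j]
      inside <- d >= edges[k] &&
        (d < edges[k + 1] || (k == nc && d <= edges[k + 1]))
      if (inside) {
        num <- num + 2 * C[i, j]
        den <- den + C[i, i] + C[j, j]
      }
    }
    if (den > 0) r[k] <- num / den
  }
  r
}
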