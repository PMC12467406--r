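test_that("multilocus r matches the hand oracle on a 4x2 toy panel", {
  calls <- matrix(c(0L, 1L, 2L, 1L,
                    2L, 1L, 0L, 0L), 4, 2)
  rownames(calls) <- paste0("i", 1:4)
  s <- tibble::tibble(id = rownames(calls), x = c(0, 10, 100, 110), y = 0)
  D <- pairwise_distance(s)
  spec <- distance_classes("fixed_edges", edges = c(0, 50, 150))
  res <- multilocus_r(genotype_matrix(calls), D, spec)
  oracle <- smouse_peakall_oracle(calls, D, c(0, 50, 150))
  expect_equal(res$per_class$r, oracle, tolerance = 1e-12)
})

test_that("r agrees with the oracle on larger random panels", {
  set.seed(41)
  panel <- null_panel(n = 15, L = 12, seed = 41)
  D <- pairwise_distance(panel$samples)
  spec <- distance_classes(n_classes = 4)
  res <- multilocus_r(panel$gm, D, spec)
  oracle <- smouse_peakall_oracle(panel$gm$calls, D, res$edges)
  expect_equal(res$per_class$r, oracle, tolerance = 1e-10)
})

test_that("clone pairs give r = 1 in their class", {
  set.seed(6)
  base <- matrix(sample(0:2, 6 * 20, replace = TRUE), 6, 20)
  calls <- rbind(base, base)  # individual i and i+6 are clones
  rownames(calls) <- paste0("i", 1:12)
  # clone mates 5 m apart; distinct genotypes >= 100 m apart
  x <- c((0:5) * 200, (0:5) * 200 + 5)
  s <- tibble::tibble(id = rownames(calls), x = x, y = 0)
  spec <- distance_classes("fixed_edges", edges = c(0, 50, 1200))
  res <- multilocus_r(genotype_matrix(calls), pairwise_distance(s), spec)
  expect_equal(res$per_class$r[1], 1, tolerance = 1e-12)
})

test_that("r stays within [-1, 1] across random panels", {
  for (seed in 1:5) {
    panel <- null_panel(n = 20, L = 15, seed = seed)
    res <- multilocus_r(panel$gm, pairwise_distance(panel$samples),
                        distance_classes(n_classes = 5))
    r <- res$per_class$r
    expect_true(all(r >= -1 - 1e-12 & r <= 1 + 1e-12, na.rm = TRUE))
  }
})

test_that("permutation and bootstrap are reproducible under a fixed seed", {
  panel <- null_panel(n = 20, L = 25, seed = 9)
  D <- pairwise_distance(panel$samples)
  spec <- distance_classes(n_classes = 4)
  a <- r_significance(panel$gm, D, spec, n_perm = 99, n_boot = 99, seed = 2)
  b <- r_significance(panel$gm, D, spec, n_perm = 99, n_boot = 99, seed = 2)
  expect_identical(a$per_class, b$per_class)
  expect_error(r_significance(panel$gm, D, spec, n_perm = 10, n_boot = 99),
               ">= 99")
})

test_that("null data keep observed r inside an envelope that straddles zero", {
  # under random arrangement r centres on -1/(n-1), so the zero-containment
  # reading of the correlogram needs the envelope width (set by locus and
  # pair counts) to dominate that small bias, as it does at survey scale
  contains0 <- 0; inside <- 0; tot <- 0
  for (rep in 1:10) {
    panel <- null_panel(n = 60, L = 10, seed = 300 + rep)
    res <- r_significance(panel$gm, pairwise_distance(panel$samples),
                          distance_classes(n_classes = 8),
                          n_perm = 99, n_boot = 99, seed = rep)
    fin <- is.finite(res$per_class$r)
    contains0 <- contains0 +
      sum(res$per_class$lo[fin] <= 0 & res$per_class$hi[fin] >= 0)
    inside <- inside + sum(!res$per_class$signif[fin])
    tot <- tot + sum(fin)
  }
  expect_gte(contains0 / tot, 0.9)
  expect_gte(inside / tot, 0.85)   # ~95% nominal coverage, binomial noise
})

test_that("strong spatial structure lifts first-class r above its envelope", {
  ds <- simulate_population(sim_config(
    n_founders = 30, n_patches = 1, patch_size = 500, sigma_seed = 5,
    sigma_pollen = 50, n_loci = 80, n_generations = 2,
    offspring_per_generation = 30, genotyping_error = 0, missing_rate = 0,
    rng_seed = 77))
  gm <- suppressMessages(maf_filter(ds$genotypes))
  res <- r_significance(gm, pairwise_distance(ds$samples),
                        distance_classes(n_classes = 8),
                        n_perm = 99, n_boot = 99, seed = 1)
  expect_gt(res$per_class$r[1], res$per_class$hi[1])
})

test_that("the x-intercept interpolates the first sign change", {
  mk <- function(mid, r) list(per_class = tibble::tibble(midpoint = mid, r = r))
  expect_equal(x_intercept(mk(c(10, 30), c(0.1, -0.1)))$x_intercept, 20)
  res <- x_intercept(mk(c(10, 30, 50), c(0.2, 0.1, 0.05)))
  expect_true(is.na(res$x_intercept)); expect_equal(res$flag, "absent")
  res <- x_intercept(mk(c(10, 30), c(-0.05, 0.1)))
  expect_equal(res$x_intercept, 10); expect_equal(res$flag, "immediate")
  # piecewise-linear correlogram with root placed at 23.7 m
  res <- x_intercept(mk(c(10, 30, 60), c(0.137, -0.063, -0.1)))
  expect_equal(res$x_intercept, 23.7, tolerance = 0.01)
})
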