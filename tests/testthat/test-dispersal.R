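test_that("effective gene dispersal follows the variance decomposition", {
  expect_equal(effective_gene_dispersal(3, 0), 3)
  expect_equal(effective_gene_dispersal(0, 2), sqrt(2))
  expect_equal(effective_gene_dispersal(168.87, 201.89),
               sqrt(168.87^2 + 201.89^2 / 2))
  expect_error(effective_gene_dispersal(-1, 2), ">= 0")
})

test_that("direct summaries aggregate per patch with population means rows", {
  ev <- tibble::tibble(
    kind = rep(c("seed", "pollen"), each = 4),
    distance_m = c(10, 20, 30, 40, 5, 15, 25, 35),
    patch = rep(c("A", "A", "B", "B"), 2),
    offspring = paste0("o", 1:8))
  out <- direct_summary(ev, c(A = "POP", B = "POP"))
  a <- out[out$patch == "A", ]
  expect_equal(a$seed_mean, 15); expect_equal(a$seed_max, 20)
  expect_equal(a$pollen_mean, 10)
  expect_equal(a$gene_effective, effective_gene_dispersal(15, 10))
  means <- out[out$patch == "means", ]
  expect_equal(means$seed_mean, mean(c(15, 35)))
  expect_equal(means$gene_effective,
               mean(c(effective_gene_dispersal(15, 10),
                      effective_gene_dispersal(35, 30))))
  # permutation invariance
  out2 <- direct_summary(ev[sample(8), ], c(A = "POP", B = "POP"))
  expect_equal(out2[order(out2$patch), ], out[order(out$patch), ])
})

test_that("single events collapse mean and max", {
  ev <- tibble::tibble(kind = "seed", distance_m = 12.5, patch = "A",
                       offspring = "o")
  out <- direct_summary(ev)
  expect_equal(out$seed_mean, 12.5)
  expect_equal(out$seed_max, 12.5)
  expect_true(is.na(out$gene_effective))
})

test_that("noise-free cubic inputs are recovered exactly", {
  mids <- c(5, 10, 20, 40, 80, 160)
  cf <- c(a = 0.08, b = -0.05, c = 0.011, d = -0.0008)
  y <- cf[1] + cf[2] * log(mids) + cf[3] * log(mids)^2 + cf[4] * log(mids)^3
  fit <- fit_dispersal_curve(mids, y)
  expect_equal(unname(fit$coefficients), unname(cf), tolerance = 1e-9)
  expect_lt(fit$residual_norm, 1e-10)
  expect_equal(unname(fit$K_literal), unname(2 * cf[3] + 6 * log(5)))
  expect_equal(unname(fit$K_dcorrected), unname(2 * cf[3] + 6 * cf[4] * log(5)))
})

test_that("a constructed root at 25 m is found to 0.01 m", {
  mids <- c(5, 12, 25, 60, 140)
  u0 <- log(25)
  y <- sapply(log(mids), function(u) (u - u0) * (u^2 + 1)) * -0.01
  fit <- fit_dispersal_curve(mids, y)
  expect_equal(fit$roots_m[1], 25, tolerance = 0.01)
})

test_that("roots agree with a dense grid-scan oracle", {
  set.seed(17)
  for (rep in 1:5) {
    mids <- sort(runif(6, 3, 300))
    y <- runif(6, -0.05, 0.15)
    fit <- fit_dispersal_curve(mids, y)
    cf <- fit$coefficients
    grid <- seq(log(min(mids)), log(max(mids)), length.out = 200001)
    val <- cf[1] + cf[2] * grid + cf[3] * grid^2 + cf[4] * grid^3
    sign_change <- which(val[-1] * val[-length(val)] <= 0 & val[-1] != 0)
    roots_grid <- exp((grid[sign_change] + grid[sign_change + 1]) / 2)
    expect_equal(length(fit$roots_m), length(roots_grid))
    if (length(roots_grid))
      expect_equal(fit$roots_m, roots_grid, tolerance = 0.01)
  }
})

test_that("flat correlograms yield no roots and few classes error out", {
  mids <- c(5, 10, 20, 40, 80)
  fit <- fit_dispersal_curve(mids, rep(0.05, 5))
  expect_equal(length(fit$roots_m), 0)
  expect_error(fit_dispersal_curve(c(5, 10, 20), c(0.1, 0, -0.1)), ">= 4")
})

test_that("indirect summaries combine intercept and cubic root", {
  ac <- list(x_intercept = 23.0, x_intercept_flag = "interpolated")
  fit <- list(roots_m = 31.0)
  out <- indirect_summary(ac, fit)
  expect_equal(c(out$min_m, out$max_m), c(23, 31))
  expect_equal(out$flag, "both")
  out2 <- indirect_summary(list(x_intercept = NA_real_), list(roots_m = 31))
  expect_equal(c(out2$min_m, out2$max_m), c(31, 31))
  expect_equal(out2$flag, "root_only")
  out3 <- indirect_summary(list(x_intercept = NA_real_),
                           list(roots_m = numeric(0)))
  expect_equal(out3$flag, "random_variation")
})

test_that("synthetic correlogram crossings at 18 and 27 m are recovered", {
  # piecewise-linear r crossing zero at 18 (down) and 27 (up, second root of
  # the fitted cubic); build r from a cubic in ln r with roots 18 and 27
  mids <- c(8, 14, 22, 35, 60)
  u <- log(mids)
  y <- -(u - log(18)) * (u - log(27)) * (u - log(2000))
  ac_fit <- fit_dispersal_curve(mids, y)
  ac <- list(per_class = tibble::tibble(midpoint = mids, r = y))
  xi <- x_intercept(ac)
  out <- indirect_summary(c(ac, x_intercept = xi$x_intercept), ac_fit)
  expect_equal(ac_fit$roots_m, c(18, 27), tolerance = 1e-6)
  expect_lt(abs(out$min_m - 18), 1)   # interpolated intercept near the root
})
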