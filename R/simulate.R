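#' Configuration for the spatially explicit population simulator
#'
#' The simulator emulates the sampling universe the downstream analyses
#' assume: clustered patches of georeferenced trees, three DBH-defined age
#' classes, restricted bivariate-Gaussian seed and pollen dispersal, partial
#' selfing, founder allele frequencies drawn from a uniform band, per-allele
#' genotyping error and random missingness.
#'
#' Defaults mirror a single study population: three patches of roughly 30
#' trees each (founders plus two offspring generations), about 1 km apart,
#' 1,000 unlinked biallelic loci with founder minor-allele frequencies
#' uniform on [0.05, 0.5], a 20 m seed kernel, a 50 m pollen kernel, 10%
#' selfing, 1% per-allele genotyping error and 10% missing genotypes.
#'
#' @param n_founders Founders across all patches (assigned round-robin).
#' @param n_patches Number of square patches.
#' @param patch_size Side length of each patch in meters.
#' @param patch_spacing Distance between patch origins in meters (patches
#'   are laid out on a horizontal line).
#' @param sigma_seed,sigma_pollen Axial standard deviations (meters) of the
#'   isotropic bivariate Gaussian seed and pollen kernels.
#' @param selfing_rate Probability an offspring is selfed.
#' @param n_loci Number of unlinked biallelic loci.
#' @param founder_maf_range Founder alternate-allele frequencies are drawn
#'   uniformly from this interval.
#' @param n_generations Number of offspring generations.
#' @param offspring_per_generation Offspring produced per generation.
#' @param genotyping_error Per-allele flip probability in observed genotypes.
#' @param missing_rate Per-genotype missingness probability.
#' @param rng_seed Integer seed; identical configs reproduce identical
#'   datasets byte for byte.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_founders = 36, n_patches = 3, patch_size = 300,
                       patch_spacing = 1000, sigma_seed = 20,
                       sigma_pollen = 50, selfing_rate = 0.1, n_loci = 1000,
                       founder_maf_range = c(0.05, 0.5), n_generations = 2,
                       offspring_per_generation = 30,
                       genotyping_error = 0.01, missing_rate = 0.1,
                       rng_seed = 1L) {
  cfg <- list(n_founders = n_founders, n_patches = n_patches,
              patch_size = patch_size, patch_spacing = patch_spacing,
              sigma_seed = sigma_seed, sigma_pollen = sigma_pollen,
              selfing_rate = selfing_rate, n_loci = n_loci,
              founder_maf_range = founder_maf_range,
              n_generations = n_generations,
              offspring_per_generation = offspring_per_generation,
              genotyping_error = genotyping_error,
              missing_rate = missing_rate, rng_seed = as.integer(rng_seed))
  counts <- c("n_founders", "n_patches", "n_loci", "n_generations",
              "offspring_per_generation")
  for (f in counts)
    if (cfg[[f]] < 1) stop(sprintf("`%s` must be a positive count", f), call. = FALSE)
  if (cfg$sigma_seed < 0 || cfg$sigma_pollen <= 0)
    stop("`sigma_seed` must be >= 0 and `sigma_pollen` > 0", call. = FALSE)
  for (f in c("selfing_rate", "genotyping_error", "missing_rate"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop(sprintf("`%s` must be a probability in [0, 1]", f), call. = FALSE)
  if (length(cfg$founder_maf_range) != 2 ||
      any(cfg$founder_maf_range <= 0) || any(cfg$founder_maf_range >= 1))
    stop("`founder_maf_range` must be two frequencies in (0, 1)", call. = FALSE)
  structure(cfg, class = "sim_config")
}

# DBH is synthesized per age class so that classify_age() round-trips:
# saplings < 7.5 cm, adults in [7.5, 22.5), mature >= 22.5 cm.
dbh_for_class <- function(age_class, n) {
  switch(age_class,
         sapling = stats::runif(n, 1, 7.4),
         adult   = stats::runif(n, 7.5, 22.4),
         mature  = stats::runif(n, 22.5, 80))
}

#' Simulate a patchy tree population with known pedigree
#'
#' Forward-in-time, spatially explicit simulation. Founders are placed
#' uniformly at random inside their patch with Hardy-Weinberg genotypes at
#' frequencies drawn from `founder_maf_range`. Each offspring generation:
#' the mother is drawn uniformly from all previously existing individuals
#' in the same patch; the father is the mother with probability
#' `selfing_rate`, otherwise drawn from the other adults of the patch with
#' weight proportional to the pollen kernel density at the mother-candidate
#' distance; the offspring position is the mother's position plus an
#' isotropic Gaussian displacement (sd `sigma_seed` per axis), resampled
#' until it falls inside the patch; alleles are transmitted by Mendelian
#' sampling. Observed genotypes are the true genotypes with each allele
#' flipped independently with probability `genotyping_error`, then masked
#' with probability `missing_rate`. Founders are mature, intermediate
#' generations adults, and the last generation saplings.
#'
#' @param config A [sim_config()].
#' @return A list of class `simulated_dataset` with elements `samples`
#'   (tibble: id, population, patch, x, y, dbh, age_class, generation),
#'   `genotypes` (a [genotype_matrix()] of observed calls),
#'   `true_genotypes` (error-free calls, no missingness), and `pedigree`
#'   (tibble: offspring, mother, father, seed_dist_m, pollen_dist_m).
#' @export
simulate_population <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$rng_seed)
  cfg <- config

  n_total <- cfg$n_founders + cfg$n_generations * cfg$offspring_per_generation
  patch_ids <- paste0("P", seq_len(cfg$n_patches))
  patch_x0 <- (seq_len(cfg$n_patches) - 1) * cfg$patch_spacing

  id <- character(n_total)
  patch <- character(n_total)
  x <- numeric(n_total); y <- numeric(n_total)
  generation <- integer(n_total)

  # founders, round-robin across patches
  fi <- seq_len(cfg$n_founders)
  id[fi] <- sprintf("F%03d", fi)
  pidx <- ((fi - 1) %% cfg$n_patches) + 1L
  patch[fi] <- patch_ids[pidx]
  x[fi] <- patch_x0[pidx] + stats::runif(cfg$n_founders, 0, cfg$patch_size)
  y[fi] <- stats::runif(cfg$n_founders, 0, cfg$patch_size)
  generation[fi] <- 0L

  p_founder <- stats::runif(cfg$n_loci, cfg$founder_maf_range[1],
                            cfg$founder_maf_range[2])
  geno <- matrix(NA_integer_, n_total, cfg$n_loci)
  geno[fi, ] <- vapply(seq_len(cfg$n_loci), function(l)
    stats::rbinom(cfg$n_founders, 2L, p_founder[l]), integer(cfg$n_founders))

  ped <- vector("list", cfg$n_generations * cfg$offspring_per_generation)
  next_row <- cfg$n_founders + 1L

  transmit <- function(g) {
    # one allele per locus from a parent's true genotype (dose 0/1/2)
    ifelse(g == 1L, stats::rbinom(length(g), 1L, 0.5), as.integer(g / 2L))
  }

  for (gen in seq_len(cfg$n_generations)) {
    for (k in seq_len(cfg$offspring_per_generation)) {
      row <- next_row
      adults <- which(generation[seq_len(row - 1L)] < gen)  # prior generations only
      m <- sample(adults, 1L)
      pk <- patch[m]
      if (stats::runif(1) < cfg$selfing_rate) {
        f <- m
      } else {
        cand <- adults[patch[adults] == pk & adults != m]
        if (length(cand) == 0L) {
          f <- m  # lone adult in patch: forced selfing
        } else {
          dmf <- sqrt((x[cand] - x[m])^2 + (y[cand] - y[m])^2)
          w <- exp(-dmf^2 / (2 * cfg$sigma_pollen^2))
          if (sum(w) <= 0) w <- rep(1, length(cand))
          f <- if (length(cand) == 1L) cand else sample(cand, 1L, prob = w)
        }
      }
      # seed displacement truncated to the patch by resampling
      x0 <- patch_x0[match(pk, patch_ids)]
      repeat {
        ox <- x[m] + stats::rnorm(1, 0, cfg$sigma_seed)
        oy <- y[m] + stats::rnorm(1, 0, cfg$sigma_seed)
        if (ox >= x0 && ox <= x0 + cfg$patch_size && oy >= 0 && oy <= cfg$patch_size)
          break
        if (cfg$sigma_seed == 0) { ox <- x[m]; oy <- y[m]; break }
      }
      id[row] <- sprintf("O%d_%03d", gen, k)
      patch[row] <- pk; x[row] <- ox; y[row] <- oy; generation[row] <- gen
      geno[row, ] <- transmit(geno[m, ]) + transmit(geno[f, ])
      ped[[(gen - 1L) * cfg$offspring_per_generation + k]] <- list(
        offspring = id[row], mother = id[m], father = id[f],
        seed_dist_m = sqrt((ox - x[m])^2 + (oy - y[m])^2),
        pollen_dist_m = if (f == m) 0 else
          sqrt((x[f] - x[m])^2 + (y[f] - y[m])^2))
      next_row <- next_row + 1L
    }
  }

  # observation layer: per-allele flips, then missingness
  observed <- geno
  if (cfg$genotyping_error > 0) {
    flips <- matrix(stats::rbinom(2L * n_total * cfg$n_loci, 1L,
                                  cfg$genotyping_error),
                    n_total * 2L, cfg$n_loci)
    # genotype g = a1 + a2; flipping allele k replaces it by 1 - ak
    a1 <- ifelse(geno == 1L,
                 matrix(stats::rbinom(n_total * cfg$n_loci, 1L, 0.5),
                        n_total, cfg$n_loci),
                 as.integer(geno / 2L))
    a2 <- geno - a1
    o1 <- abs(a1 - flips[seq_len(n_total), , drop = FALSE])
    o2 <- abs(a2 - flips[n_total + seq_len(n_total), , drop = FALSE])
    observed <- o1 + o2
  }
  if (cfg$missing_rate > 0) {
    miss <- matrix(stats::runif(n_total * cfg$n_loci) < cfg$missing_rate,
                   n_total, cfg$n_loci)
    observed[miss] <- NA_integer_
  }

  age_class <- ifelse(generation == 0L, "mature",
                      ifelse(generation == cfg$n_generations, "sapling", "adult"))
  dbh <- numeric(n_total)
  for (ac in c("sapling", "adult", "mature")) {
    idx <- which(age_class == ac)
    if (length(idx)) dbh[idx] <- dbh_for_class(ac, length(idx))
  }

  samples <- tibble::tibble(id = id, population = "SIM", patch = patch,
                            x = x, y = y, dbh = round(dbh, 1),
                            age_class = age_class, generation = generation)
  locus_ids <- sprintf("snp%04d", seq_len(cfg$n_loci))
  rownames(observed) <- id; colnames(observed) <- locus_ids
  rownames(geno) <- id; colnames(geno) <- locus_ids

  structure(list(samples = samples,
                 genotypes = genotype_matrix(observed),
                 true_genotypes = genotype_matrix(geno),
                 pedigree = dplyr::bind_rows(lapply(ped, tibble::as_tibble)),
                 config = cfg),
            class = "simulated_dataset")
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf("<simulated_dataset> %d individuals (%d founders), %d loci, %d patches\n",
              nrow(x$samples), x$config$n_founders, x$config$n_loci,
              x$config$n_patches))
  invisible(x)
}

#' Per-locus Mendelian consistency of a parent-offspring trio
#'
#' A locus is inconsistent when the offspring genotype cannot be formed from
#' one allele of each parent (e.g. offspring 2 with a mother 0). Loci with a
#' missing call in any member are skipped (`NA`).
#'
#' @param offspring,mother,father Genotype vectors (0/1/2/`NA`) over the
#'   same loci.
#' @return Logical vector per locus: `TRUE` consistent, `FALSE` not, `NA`
#'   skipped.
#' @export
mendelian_check <- function(offspring, mother, father) {
  n <- length(offspring)
  if (length(mother) != n || length(father) != n)
    stop("genotype vectors must have equal length", call. = FALSE)
  # transmissible allele sets: 0 -> {0}; 1 -> {0,1}; 2 -> {1}
  lo_m <- ifelse(mother == 2L, 1L, 0L); hi_m <- ifelse(mother == 0L, 0L, 1L)
  lo_f <- ifelse(father == 2L, 1L, 0L); hi_f <- ifelse(father == 0L, 0L, 1L)
  ok <- offspring >= (lo_m + lo_f) & offspring <= (hi_m + hi_f)
  ok[is.na(offspring) | is.na(mother) | is.na(father)] <- NA
  ok
}

#' Write a simulated dataset to disk
#'
#' Emits three plain-text files: `genotypes.vcf` (VCF v4.2, biallelic sites,
#' GT field, INFO populated with pass-level FS/MQ/QD/ReadPosRankSum/
#' MQRankSum/HaplotypeScore values), `samples.tsv` (id, population, patch,
#' lon, lat, dbh; coordinates are planar meters, declared in a comment
#' line), and `pedigree.tsv` (offspring, mother, father, seed_dist_m,
#' pollen_dist_m). The pair round-trips losslessly through [read_vcf()].
#'
#' @param dataset A `simulated_dataset`.
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a named character vector of the three file paths.
#' @export
write_dataset <- function(dataset, out_dir) {
  stopifnot(inherits(dataset, "simulated_dataset"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  vcf_path <- file.path(out_dir, "genotypes.vcf")
  meta_path <- file.path(out_dir, "samples.tsv")
  ped_path <- file.path(out_dir, "pedigree.tsv")

  calls <- dataset$genotypes$calls
  n <- nrow(calls); L <- ncol(calls)
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=finesgs_simulator",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Phred-scaled strand bias Fisher test\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
    "##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description=\"Read position rank sum\">",
    "##INFO=<ID=MQRankSum,Number=1,Type=Float,Description=\"Mapping quality rank sum\">",
    "##INFO=<ID=HaplotypeScore,Number=1,Type=Float,Description=\"Haplotype score\">",
    "##contig=<ID=chr1>",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(calls)), collapse = "\t"))
  info <- "FS=1.0;MQ=60.0;QD=25.0;ReadPosRankSum=0.0;MQRankSum=0.0;HaplotypeScore=2.0"
  body <- if (L > 0) {
    gt <- matrix("./.", n, L)
    keep <- !is.na(calls)
    gt[keep] <- gt_code[as.character(calls[keep])]
    vapply(seq_len(L), function(l)
      paste(c("chr1", l * 100L, colnames(calls)[l], "A", "T", "100", "PASS",
              info, "GT", gt[, l]), collapse = "\t"), character(1))
  } else character(0)
  writeLines(c(header, body), vcf_path)

  meta <- dataset$samples
  con <- file(meta_path, "w")
  writeLines("#coord_system=planar_m", con)
  utils::write.table(
    data.frame(id = meta$id, population = meta$population, patch = meta$patch,
               lon = meta$x, lat = meta$y, dbh = meta$dbh),
    con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)

  utils::write.table(as.data.frame(dataset$pedigree), ped_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(vcf = vcf_path, meta = meta_path, pedigree = ped_path))
}
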