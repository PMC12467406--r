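#' Full-analysis pipeline configuration
#'
#' One structured configuration drives the whole analysis chain
#' (filter -> diversity -> SGS -> autocorrelation -> parentage ->
#' dispersal). All printed defaults of the method (999 permutations,
#' MAF > 0.05, genotyping error 0.01, 80% confidence, candidate proportion
#' 0.9) live here, never hard-coded downstream.
#'
#' @param vcf,metadata Input paths.
#' @param out_dir Output directory for the table bundle.
#' @param thresholds A [filter_thresholds()].
#' @param class_spec A [distance_classes()].
#' @param n_perm,n_boot Permutation/bootstrap counts (default 999).
#' @param parentage A [parentage_config()].
#' @param strata Stratification levels to run SGS at.
#' @param min_stratum_n Minimum individuals per stratum.
#' @param seed Global seed; all stage seeds derive from it.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(vcf, metadata, out_dir = "finesgs_out",
                            thresholds = filter_thresholds(),
                            class_spec = distance_classes(),
                            n_perm = 999, n_boot = 999,
                            parentage = parentage_config(),
                            strata = c("population", "age_class", "patch"),
                            min_stratum_n = 10, seed = 1L) {
  structure(list(vcf = vcf, metadata = metadata, out_dir = out_dir,
                 thresholds = thresholds, class_spec = class_spec,
                 n_perm = n_perm, n_boot = n_boot, parentage = parentage,
                 strata = strata, min_stratum_n = min_stratum_n,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Never throws; returns a character vector of problems (empty when the
#' configuration is valid), each naming the offending field.
#'
#' @param config A [pipeline_config()].
#' @return Character vector of problem descriptions.
#' @export
validate_config <- function(config) {
  problems <- character(0)
  add <- function(msg) problems <<- c(problems, msg)
  if (!is.character(config$vcf) || !file.exists(config$vcf))
    add(sprintf("vcf: path does not exist (%s)", config$vcf))
  if (!is.character(config$metadata) || !file.exists(config$metadata))
    add(sprintf("metadata: path does not exist (%s)", config$metadata))
  if (!inherits(config$thresholds, "filter_thresholds"))
    add("thresholds: not a filter_thresholds object")
  if (!inherits(config$class_spec, "distance_class_spec"))
    add("class_spec: not a distance_class_spec object")
  if (!is.numeric(config$n_perm) || config$n_perm < 99)
    add("n_perm: must be >= 99")
  if (!is.numeric(config$n_boot) || config$n_boot < 99)
    add("n_boot: must be >= 99")
  if (!inherits(config$parentage, "parentage_config"))
    add("parentage: not a parentage_config object")
  bad <- setdiff(config$strata, c("population", "age_class", "patch"))
  if (length(bad)) add(paste0("strata: unknown level(s) ",
                              paste(bad, collapse = ", ")))
  if (!is.numeric(config$seed)) add("seed: must be an integer")
  problems
}

# Deterministic per-stage seeds below 2^31, derived from the global seed.
stage_seed <- function(seed, stage) {
  (as.integer(seed) * 1009L + match(stage, c("sgs", "autocorr", "parentage",
                                             "calibration")) * 7919L) %% 2147483647L
}

write_stage_table <- function(df, path, seed, config_hash) {
  con <- file(path, "w")
  writeLines(c(sprintf("# finesgs %s", as.character(utils::packageVersion("finesgs"))),
               sprintf("# seed=%d config=%s", seed, config_hash)), con)
  df <- as.data.frame(df)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) format(v, digits = 12, trim = TRUE))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  path
}

#' Run the full analysis pipeline
#'
#' Executes all stages in dependency order and writes TSV tables (with
#' provenance headers: package version, seed, config hash) into
#' `config$out_dir`: diversity per patch and population with the HO-vs-HE
#' t-test, SGS summaries and correlograms at the requested strata,
#' patch-level autocorrelograms with intercepts, parentage assignments,
#' dispersal events and the direct and indirect dispersal summaries.
#' Failure inside one stratum is logged and does not abort the others.
#' Reruns under the same configuration are byte-identical.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the computed objects and a `log`
#'   character vector; tables are on disk under `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  problems <- validate_config(config)
  if (length(problems))
    stop("invalid configuration:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))
  cfg_for_hash <- unclass(config)
  cfg_for_hash$out_dir <- NULL  # hash the analysis, not where it lands
  chash <- rlang::hash(cfg_for_hash)

  wt <- function(df, name) write_stage_table(
    df, file.path(config$out_dir, name), config$seed, chash)

  inp <- read_vcf(config$vcf, config$metadata)
  gm <- inp$genotypes; samples <- inp$samples
  note("input: %d samples x %d loci", nrow(gm$calls), ncol(gm$calls))

  if (!is.null(gm$info)) {
    n0 <- ncol(gm$calls)
    gm <- withCallingHandlers(hard_filter(gm, config$thresholds),
                              warning = function(w) {
                                note("hard_filter: %s", conditionMessage(w))
                                invokeRestart("muffleWarning")
                              })
    note("hard_filter: %d -> %d loci", n0, ncol(gm$calls))
  } else note("hard_filter: no annotations, skipped")
  n0 <- ncol(gm$calls)
  gm <- maf_filter(gm, config$thresholds$maf_min)
  note("maf_filter: %d -> %d loci", n0, ncol(gm$calls))

  # diversity (per patch) + per-population t-test
  div <- diversity(gm, samples$patch)
  pop_of_patch <- samples$population[match(div$group, samples$patch)]
  div <- dplyr::mutate(div, population = pop_of_patch, .before = 1)
  wt(div, "diversity_patch.tsv")
  tt <- dplyr::bind_rows(lapply(unique(div$population), function(pp) {
    sub <- div[div$population == pp, ]
    if (nrow(sub) < 2) {
      note("t-test: population %s has < 2 patches, skipped", pp)
      return(NULL)
    }
    dplyr::mutate(ho_he_ttest(sub$ho, sub$he), population = pp, .before = 1)
  }))
  if (nrow(tt)) wt(tt, "diversity_ttest.tsv")

  # SGS by requested strata
  sgs_rows <- list(); corr_rows <- list()
  for (level in config$strata) {
    res <- withCallingHandlers(
      sgs_by_stratum(gm, samples, level, config$class_spec,
                     n_perm = config$n_perm,
                     seed = stage_seed(config$seed, "sgs"),
                     min_n = config$min_stratum_n),
      warning = function(w) {
        note("sgs[%s]: %s", level, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    for (s in names(res)) {
      r <- res[[s]]
      sgs_rows[[paste(level, s)]] <- tibble::tibble(
        level = level, stratum = s, bF = r$bF, se_bF = r$se_bF, F1 = r$F1,
        Sp = r$Sp, bF_signif = isTRUE(r$bF_signif))
      corr_rows[[paste(level, s)]] <- dplyr::mutate(
        r$per_class, level = level, stratum = s, .before = 1)
    }
  }
  if (length(sgs_rows)) {
    wt(dplyr::bind_rows(sgs_rows), "sgs_summary.tsv")
    wt(dplyr::bind_rows(corr_rows), "sgs_correlogram.tsv")
  }

  # patch-level autocorrelation + indirect dispersal
  auto_rows <- list(); indirect_rows <- list()
  for (pk in unique(samples$patch)) {
    idx <- which(samples$patch == pk)
    if (length(idx) < config$min_stratum_n) {
      note("autocorr: patch %s too small, skipped", pk)
      next
    }
    ok <- tryCatch({
      sub <- maf_filter(subset_gm(gm, samples = idx), config$thresholds$maf_min)
      D <- pairwise_distance(samples[idx, ])
      ac <- r_significance(sub, D, config$class_spec, config$n_perm,
                           config$n_boot,
                           seed = stage_seed(config$seed, "autocorr"))
      fit <- tryCatch(fit_dispersal_curve(ac$per_class$midpoint,
                                          ac$per_class$r),
                      error = function(e) NULL)
      ind <- if (is.null(fit))
        tibble::tibble(min_m = ac$x_intercept, max_m = ac$x_intercept,
                       flag = ac$x_intercept_flag)
      else indirect_summary(ac, fit)
      auto_rows[[pk]] <- dplyr::mutate(ac$per_class, patch = pk, .before = 1)
      indirect_rows[[pk]] <- dplyr::mutate(ind, patch = pk, .before = 1)
      TRUE
    }, error = function(e) {
      note("autocorr: patch %s failed: %s", pk, conditionMessage(e))
      FALSE
    })
  }
  if (length(auto_rows)) {
    wt(dplyr::bind_rows(auto_rows), "autocorr_correlogram.tsv")
    wt(dplyr::bind_rows(indirect_rows), "dispersal_indirect.tsv")
  }

  # parentage per patch: saplings are offspring, mature trees candidates
  assign_rows <- list()
  pcfg <- config$parentage
  pcfg$seed <- stage_seed(config$seed, "parentage")
  for (pk in unique(samples$patch)) {
    sub <- samples[samples$patch == pk, ]
    offspring <- sub$id[sub$age_class == "sapling"]
    cands <- sub$id[sub$age_class %in% c("adult", "mature")]
    if (!length(offspring) || length(cands) < 2) {
      note("parentage: patch %s lacks offspring or candidates, skipped", pk)
      next
    }
    ok <- tryCatch({
      asn <- assign_parents(offspring, cands, gm, pcfg)
      assign_rows[[pk]] <- dplyr::mutate(asn, patch = pk, .before = 1)
      TRUE
    }, error = function(e) {
      note("parentage: patch %s failed: %s", pk, conditionMessage(e))
      FALSE
    })
  }
  events <- NULL; direct <- NULL
  if (length(assign_rows)) {
    assignments <- dplyr::bind_rows(assign_rows)
    wt(assignments, "parentage_assignments.tsv")
    events <- dispersal_events(assignments, samples)
    if (nrow(events)) {
      wt(events, "dispersal_events.tsv")
      patch_pop <- stats::setNames(samples$population, samples$patch)
      direct <- direct_summary(events, patch_pop[unique(samples$patch)])
      wt(direct, "dispersal_direct.tsv")
    } else note("dispersal: no confident events")
  }

  writeLines(log, file.path(config$out_dir, "run_log.txt"))
  invisible(list(diversity = div, ttest = tt,
                 sgs = if (length(sgs_rows)) dplyr::bind_rows(sgs_rows) else NULL,
                 autocorr = if (length(auto_rows)) dplyr::bind_rows(auto_rows) else NULL,
                 indirect = if (length(indirect_rows)) dplyr::bind_rows(indirect_rows) else NULL,
                 events = events, direct = direct, log = log))
}
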