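#' Parentage analysis configuration
#'
#' Defaults follow the usual categorical-allocation settings: 90% of
#' candidate parents assumed sampled, 1% genotyping error in the likelihood
#' kernel, 1% of loci allowed to mismatch, and an 80% assignment confidence
#' level calibrated by simulation.
#'
#' @param prop_candidates_sampled Probability a true parent is in the
#'   candidate set.
#' @param genotyping_error Per-genotype error rate of the likelihood kernel.
#' @param mismatch_tolerance Fraction of loci allowed to be
#'   Mendelian-impossible in a confident trio.
#' @param confidence_level Required proportion of correct assignments among
#'   those exceeding the critical delta.
#' @param n_sim_offspring Simulated offspring for threshold calibration.
#' @param seed Integer seed.
#' @return A list of class `parentage_config`.
#' @export
parentage_config <- function(prop_candidates_sampled = 0.9,
                             genotyping_error = 0.01,
                             mismatch_tolerance = 0.01,
                             confidence_level = 0.80,
                             n_sim_offspring = 10000, seed = 1L) {
  for (v in c(prop_candidates_sampled, genotyping_error, mismatch_tolerance,
              confidence_level))
    if (v < 0 || v > 1) stop("probabilities must be in [0, 1]", call. = FALSE)
  structure(list(prop_candidates_sampled = prop_candidates_sampled,
                 genotyping_error = genotyping_error,
                 mismatch_tolerance = mismatch_tolerance,
                 confidence_level = confidence_level,
                 n_sim_offspring = n_sim_offspring, seed = as.integer(seed)),
            class = "parentage_config")
}

# Mendelian transmission probabilities P(offspring | mother, father),
# indexed [go + 1, gm + 1, gf + 1] for dosages 0/1/2.
mendel_array <- local({
  trans <- rbind(`0` = c(1, 0), `1` = c(0.5, 0.5), `2` = c(0, 1))
  a <- array(0, c(3, 3, 3))
  for (gm in 0:2) for (gf in 0:2) for (go in 0:2) {
    p <- 0
    for (am in 0:1) for (af in 0:1)
      if (am + af == go) p <- p + trans[gm + 1, am + 1] * trans[gf + 1, af + 1]
    a[go + 1, gm + 1, gf + 1] <- p
  }
  a
})

# Per-locus log likelihood-ratio table for an observed offspring genotype.
# The observed genotype is the true one with probability (1 - e)^2; with the
# complementary probability E = 1 - (1 - e)^2 it is a random Hardy-Weinberg
# draw. P(obs | parents) = (1 - E) T(obs | gm, gf) + E hwe(obs);
# P(obs | freqs) = hwe(obs). Returns a 3 x 3 matrix over parent genotypes.
trio_locus_llr <- function(g_obs, p, error) {
  hwe <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  E <- 1 - (1 - error)^2
  num <- (1 - E) * mendel_array[g_obs + 1, , ] + E * hwe[g_obs + 1]
  log(num) - log(hwe[g_obs + 1])
}

#' Trio LOD score of a candidate parent pair
#'
#' \deqn{LOD = \sum_l \ln \frac{P(g_o \mid g_{p1}, g_{p2}, \epsilon)}
#' {P(g_o \mid \text{freqs})}} summed over loci genotyped in all three
#' members, with the symmetric error kernel: the observed offspring
#' genotype is the true one with probability (1 - eps)^2, otherwise a
#' Hardy-Weinberg draw. At eps = 0 a Mendelian-impossible locus drives the
#' LOD to -Inf; the per-locus log-ratio is floored at -100 so impossible
#' trios stay strongly negative but finite and comparable.
#'
#' @param offspring,parent1,parent2 Genotype vectors (0/1/2/`NA`).
#' @param freqs Alternate-allele frequency per locus (analysis group).
#' @param error Per-genotype error rate in [0, 1).
#' @return The trio LOD (log-e), with attribute `n_loci` (loci used).
#' @export
trio_lod <- function(offspring, parent1, parent2, freqs, error = 0.01) {
  use <- !is.na(offspring) & !is.na(parent1) & !is.na(parent2) &
    freqs > 0 & freqs < 1
  if (!any(use)) {
    out <- NA_real_
    attr(out, "n_loci") <- 0L
    return(out)
  }
  ll <- vapply(which(use), function(l)
    trio_locus_llr(offspring[l], freqs[l], error)[parent1[l] + 1,
                                                  parent2[l] + 1],
    numeric(1))
  ll <- pmax(ll, -100)
  out <- sum(ll)
  attr(out, "n_loci") <- sum(use)
  out
}

# Vectorized trio LODs for one offspring against many candidate pairs.
# pairs: 2-column integer matrix of candidate row indices into cand_calls.
trio_lod_pairs <- function(off, cand_calls, pairs, freqs, error) {
  L <- length(off)
  lod <- numeric(nrow(pairs))
  n_loci <- integer(nrow(pairs))
  g1 <- cand_calls[pairs[, 1], , drop = FALSE]
  g2 <- cand_calls[pairs[, 2], , drop = FALSE]
  for (l in seq_len(L)) {
    if (is.na(off[l]) || freqs[l] <= 0 || freqs[l] >= 1) next
    tab <- pmax(trio_locus_llr(off[l], freqs[l], error), -100)
    a <- g1[, l]; b <- g2[, l]
    ok <- !is.na(a) & !is.na(b)
    lod[ok] <- lod[ok] + tab[cbind(a[ok] + 1L, b[ok] + 1L)]
    n_loci[ok] <- n_loci[ok] + 1L
  }
  list(lod = lod, n_loci = n_loci)
}

# Mendelian mismatch count of one offspring against a candidate pair.
mismatch_count <- function(off, g1, g2) {
  sum(!mendelian_check(off, g1, g2), na.rm = TRUE)
}

all_candidate_pairs <- function(n_cand) {
  # unordered pairs including selfed (i, i)
  idx <- which(upper.tri(matrix(0, n_cand, n_cand), diag = TRUE),
               arr.ind = TRUE)
  cbind(idx[, 1], idx[, 2])  # (i, j) with i <= j, column-major order
}

#' Calibrate the critical delta by offspring simulation
#'
#' Simulates offspring of random candidate parent pairs; each true parent
#' is independently "sampled" (present in the candidate set at assignment
#' time) with probability `prop_candidates_sampled`, otherwise its alleles
#' come from the background allele frequencies. Simulated offspring are
#' assigned by trio LOD over all candidate pairs; delta is the LOD gap to
#' the runner-up. The critical delta is the smallest value at which the
#' proportion of correct assignments among those with delta at or above it
#' reaches `confidence_level` (0 when the full set already qualifies).
#'
#' @param cand_gm [genotype_matrix()] of the candidate parents (>= 2).
#' @param freqs Allele frequencies of the analysis group.
#' @param config A [parentage_config()]; `n_sim_offspring` controls cost.
#' @return A list: `critical_delta`, `assignment_rate` (proportion of
#'   simulated offspring confidently assignable at the threshold), and the
#'   simulated `deltas`/`correct` vectors.
#' @export
calibrate_delta <- function(cand_gm, freqs, config = parentage_config()) {
  calls <- cand_gm$calls
  n_cand <- nrow(calls)
  if (n_cand < 2) stop("need >= 2 candidates", call. = FALSE)
  if (config$confidence_level == 0)
    return(list(critical_delta = 0, assignment_rate = 1,
                deltas = numeric(0), correct = logical(0)))
  set.seed(config$seed)
  L <- ncol(calls)
  pairs <- all_candidate_pairs(n_cand)
  nsim <- config$n_sim_offspring
  eps <- config$genotyping_error

  sim_parent_genotype <- function(true_g, sampled) {
    if (sampled) return(true_g)
    stats::rbinom(L, 2L, freqs)
  }
  transmit <- function(g) {
    g[is.na(g)] <- stats::rbinom(sum(is.na(g)), 2L, freqs[is.na(g)])
    ifelse(g == 1L, stats::rbinom(L, 1L, 0.5), as.integer(g / 2L))
  }

  deltas <- numeric(nsim)
  correct <- logical(nsim)
  for (s in seq_len(nsim)) {
    mi <- sample.int(n_cand, 1L)
    fi <- sample.int(n_cand, 1L)
    m_s <- stats::runif(1) < config$prop_candidates_sampled
    f_s <- stats::runif(1) < config$prop_candidates_sampled
    gm_ <- sim_parent_genotype(calls[mi, ], m_s)
    gf_ <- sim_parent_genotype(calls[fi, ], f_s)
    off <- transmit(gm_) + transmit(gf_)
    if (eps > 0) {
      flip1 <- stats::rbinom(L, 1L, eps); flip2 <- stats::rbinom(L, 1L, eps)
      a1 <- ifelse(off == 1L, stats::rbinom(L, 1L, 0.5), as.integer(off / 2L))
      a2 <- off - a1
      off <- abs(a1 - flip1) + abs(a2 - flip2)
    }
    sc <- trio_lod_pairs(off, calls, pairs, freqs, eps)
    ord <- order(sc$lod, decreasing = TRUE)
    best <- ord[1]
    deltas[s] <- sc$lod[best] - sc$lod[ord[2]]
    true_pair <- sort(c(mi, fi))
    correct[s] <- m_s && f_s && pairs[best, 1] == true_pair[1] &&
      pairs[best, 2] == true_pair[2]
  }

  ord <- order(deltas, decreasing = TRUE)
  prec <- cumsum(correct[ord]) / seq_len(nsim)
  qualifying <- which(prec >= config$confidence_level)
  if (!length(qualifying)) {
    warning("confidence level unreachable; critical delta set above all simulated deltas")
    crit <- max(deltas) + 1
  } else {
    k <- max(qualifying)  # largest top-set still meeting the confidence level
    crit <- if (k == nsim) 0 else deltas[ord[k]]
  }
  list(critical_delta = crit,
       assignment_rate = mean(deltas >= crit),
       deltas = deltas, correct = correct)
}

#' Assign parent pairs to offspring by trio LOD
#'
#' Every unordered candidate pair (selfed pairs included: one candidate
#' counted as both parents) is scored per offspring; the pair with the
#' highest trio LOD wins, ties broken toward the lowest pair index with a
#' `tie` flag. An assignment is confident when its delta (gap to the
#' runner-up) reaches the critical delta and its Mendelian mismatch
#' fraction stays within `mismatch_tolerance`.
#'
#' @param offspring_ids,candidate_ids Character vectors of sample ids
#'   (disjoint sets), both present in `gm`.
#' @param gm [genotype_matrix()] holding all offspring and candidates;
#'   allele frequencies are computed from this matrix.
#' @param config A [parentage_config()].
#' @param critical_delta Threshold from [calibrate_delta()]; when `NULL`
#'   it is calibrated here (seeded from `config`).
#' @return A tibble: `offspring`, `mother_candidate`, `father_candidate`
#'   (pair members in index order; maternal role is resolved later from
#'   geography by [dispersal_events()]), `trio_lod`, `delta`, `mismatches`,
#'   `n_loci`, `confident`, `tie`.
#' @export
assign_parents <- function(offspring_ids, candidate_ids, gm,
                           config = parentage_config(),
                           critical_delta = NULL) {
  if (length(intersect(offspring_ids, candidate_ids)))
    stop("offspring and candidate sets must be disjoint", call. = FALSE)
  calls <- gm$calls
  missing <- setdiff(c(offspring_ids, candidate_ids), rownames(calls))
  if (length(missing))
    stop("ids absent from genotype matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  freqs <- allele_freqs(gm)
  cand_calls <- calls[candidate_ids, , drop = FALSE]
  if (is.null(critical_delta)) {
    cal <- calibrate_delta(genotype_matrix(cand_calls), freqs, config)
    critical_delta <- cal$critical_delta
  }
  pairs <- all_candidate_pairs(length(candidate_ids))
  eps <- config$genotyping_error

  rows <- lapply(offspring_ids, function(oid) {
    off <- calls[oid, ]
    sc <- trio_lod_pairs(off, cand_calls, pairs, freqs, eps)
    if (all(sc$n_loci == 0))
      return(tibble::tibble(offspring = oid, mother_candidate = NA_character_,
                            father_candidate = NA_character_,
                            trio_lod = NA_real_, delta = NA_real_,
                            mismatches = NA_integer_, n_loci = 0L,
                            confident = FALSE, tie = FALSE))
    best_lod <- max(sc$lod)
    best_set <- which(sc$lod == best_lod)
    tie <- length(best_set) > 1
    best <- best_set[1]  # pairs are generated in index order: lowest wins
    runner <- if (length(sc$lod) > 1) max(sc$lod[-best]) else -Inf
    delta <- best_lod - runner
    p1 <- candidate_ids[pairs[best, 1]]; p2 <- candidate_ids[pairs[best, 2]]
    mm <- mismatch_count(off, calls[p1, ], calls[p2, ])
    nl <- sc$n_loci[best]
    tibble::tibble(offspring = oid, mother_candidate = p1,
                   father_candidate = p2, trio_lod = best_lod, delta = delta,
                   mismatches = as.integer(mm), n_loci = nl,
                   confident = !tie & delta >= critical_delta &
                     mm / max(nl, 1L) <= config$mismatch_tolerance,
                   tie = tie)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "critical_delta") <- critical_delta
  out
}

#' Seed and pollen dispersal events from confident assignments
#'
#' For each confident trio the mother is taken to be the assigned parent
#' nearer to the offspring (seeds of this gravity-dispersed tree travel
#' less far than pollen on average; recorded as an assumption in the
#' output). The seed distance is offspring-to-mother, the pollen distance
#' mother-to-father; selfed pairs have pollen distance 0.
#'
#' @param assignments Tibble from [assign_parents()].
#' @param samples Sample tibble with coordinates (and `patch`).
#' @return A tibble of events: `kind` (`"seed"`/`"pollen"`), `distance_m`,
#'   `patch`, `offspring`; attribute `maternal_rule = "nearer_parent"`.
#' @export
dispersal_events <- function(assignments, samples) {
  D <- pairwise_distance(samples)
  ids <- samples$id
  conf <- assignments[assignments$confident %in% TRUE, , drop = FALSE]
  rows <- lapply(seq_len(nrow(conf)), function(i) {
    o <- conf$offspring[i]
    p1 <- conf$mother_candidate[i]; p2 <- conf$father_candidate[i]
    if (!all(c(o, p1, p2) %in% ids)) {
      warning(sprintf("missing coordinates for trio of %s; skipped", o))
      return(NULL)
    }
    d1 <- D[o, p1]; d2 <- D[o, p2]
    mother <- if (d1 <= d2) p1 else p2
    father <- if (d1 <= d2) p2 else p1
    patch <- samples$patch[match(o, ids)]
    tibble::tibble(kind = c("seed", "pollen"),
                   distance_m = c(D[o, mother],
                                  if (mother == father) 0 else D[mother, father]),
                   patch = patch, offspring = o)
  })
  out <- dplyr::bind_rows(rows)
  if (!nrow(out))
    out <- tibble::tibble(kind = character(0), distance_m = numeric(0),
                          patch = character(0), offspring = character(0))
  attr(out, "maternal_rule") <- "nearer_parent"
  out
}
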