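#' Read a VCF and its sample metadata
#'
#' Parses a VCF (via vcfR), keeps biallelic SNP records only (multiallelic
#' and non-SNP records are dropped with a message), converts GT calls to
#' alternate-allele dosage (0/1/2, `NA` for missing or half-missing calls),
#' and extracts the per-site annotations used by [hard_filter()] when
#' present. Sample metadata is read from a TSV with columns
#' `id population patch lon lat dbh`; a leading `#coord_system=planar_m`
#' comment marks planar coordinates in meters, which are then exposed as
#' `x`/`y`. The `age_class` column is derived from DBH via [classify_age()].
#'
#' @param vcf_path Path to a VCF (v4.2, plain text or gzipped).
#' @param metadata_path Path to the metadata TSV.
#' @return A list with `genotypes` (a [genotype_matrix()]) and `samples`
#'   (a tibble, one row per VCF sample, in VCF sample order).
#' @export
read_vcf <- function(vcf_path, metadata_path) {
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf, getINFO = TRUE)
  fix <- matrix(fix, ncol = 8, dimnames = list(NULL, colnames(fix)))
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  biallelic_snp <- !is.na(alt) & !grepl(",", alt) &
    nchar(ref) == 1L & nchar(alt) == 1L
  n_drop <- sum(!biallelic_snp)
  if (n_drop > 0)
    message(sprintf("read_vcf: dropped %d multiallelic/non-SNP record(s)", n_drop))

  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- matrix(gt, nrow = nrow(vcf@gt), dimnames = dimnames(gt))
  gt <- gt[biallelic_snp, , drop = FALSE]
  ids <- fix[biallelic_snp, "ID"]
  ids[is.na(ids) | ids == "."] <-
    paste0(fix[biallelic_snp, "CHROM"], "_", fix[biallelic_snp, "POS"])[is.na(ids) | ids == "."]

  dose <- function(g) {
    a <- strsplit(gsub("\\|", "/", g), "/", fixed = TRUE)
    vapply(a, function(v) {
      if (length(v) != 2L || any(v == ".") || any(is.na(v)))
        return(NA_integer_)
      sum(as.integer(v != "0"))
    }, integer(1))
  }
  calls <- apply(gt, 2, function(col) {
    col[is.na(col)] <- "./."
    dose(col)
  })
  calls <- matrix(as.integer(calls), nrow = sum(biallelic_snp),
                  dimnames = list(ids, colnames(gt)))
  calls <- t(calls)

  ann_fields <- c("FS", "MQ", "QD", "ReadPosRankSum", "MQRankSum",
                  "HaplotypeScore")
  info_raw <- fix[biallelic_snp, "INFO"]
  info <- NULL
  if (!all(is.na(info_raw))) {
    info <- as.data.frame(lapply(ann_fields, function(f) {
      m <- regmatches(info_raw,
                      regexpr(paste0("(^|;)", f, "=[^;]+"), info_raw))
      v <- rep(NA_real_, length(info_raw))
      hit <- grepl(paste0("(^|;)", f, "="), info_raw)
      v[hit] <- as.numeric(sub(paste0("^;?", f, "="), "", m))
      v
    }))
    names(info) <- ann_fields
    if (all(vapply(info, function(v) all(is.na(v)), logical(1)))) info <- NULL
  }

  samples <- read_samples(metadata_path)
  missing_ids <- setdiff(rownames(calls), samples$id)
  if (length(missing_ids))
    stop("VCF samples absent from metadata: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  samples <- samples[match(rownames(calls), samples$id), ]

  list(genotypes = genotype_matrix(calls, info), samples = samples)
}

#' Read a sample metadata table
#'
#' @param path TSV with columns `id population patch lon lat dbh`; an
#'   optional leading comment `#coord_system=planar_m` declares the lon/lat
#'   columns to be planar meters (they are then renamed `x`/`y`).
#' @return A tibble with an added `age_class` column from [classify_age()].
#' @export
read_samples <- function(path) {
  first <- readLines(path, n = 1L)
  planar <- grepl("coord_system=planar", first)
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE)
  req <- c("id", "population", "patch", "lon", "lat", "dbh")
  if (!all(req %in% names(tab)))
    stop("metadata must have columns: ", paste(req, collapse = " "),
         call. = FALSE)
  tab$id <- as.character(tab$id)
  if (planar) {
    tab$x <- tab$lon; tab$y <- tab$lat
    tab$lon <- NULL; tab$lat <- NULL
  }
  tab$age_class <- classify_age(tab$dbh)
  tibble::as_tibble(tab)
}

#' Hard-filter thresholds for SNP site annotations
#'
#' Defaults are the standard GATK-style hard-filter criteria: FS <= 60,
#' HaplotypeScore <= 13.0, MQ >= 40, QD >= 2, ReadPosRankSum >= -8.0 and
#' MQRankSum > -12.5 (note the strict inequality on MQRankSum).
#'
#' @param fs_max,haplotype_score_max,mq_min,qd_min,read_pos_rank_sum_min,mq_rank_sum_min
#'   Numeric thresholds.
#' @param maf_min Minor-allele-frequency bound used by [maf_filter()]
#'   (strict: loci with MAF <= `maf_min` are removed).
#' @return A list of class `filter_thresholds`.
#' @export
filter_thresholds <- function(fs_max = 60, haplotype_score_max = 13.0,
                              mq_min = 40, qd_min = 2,
                              read_pos_rank_sum_min = -8.0,
                              mq_rank_sum_min = -12.5, maf_min = 0.05) {
  structure(list(fs_max = fs_max, haplotype_score_max = haplotype_score_max,
                 mq_min = mq_min, qd_min = qd_min,
                 read_pos_rank_sum_min = read_pos_rank_sum_min,
                 mq_rank_sum_min = mq_rank_sum_min, maf_min = maf_min),
            class = "filter_thresholds")
}

#' Apply site hard filters to a genotype matrix
#'
#' Retains loci with FS <= `fs_max`, HaplotypeScore <= `haplotype_score_max`,
#' MQ >= `mq_min`, QD >= `qd_min`, ReadPosRankSum >= `read_pos_rank_sum_min`
#' and MQRankSum strictly greater than `mq_rank_sum_min`. Annotation fields
#' that are entirely absent are skipped with a warning; a site-level `NA` in
#' a present field does not fail that site (the GATK convention).
#'
#' @param gm A [genotype_matrix()] with site annotations.
#' @param thresholds A [filter_thresholds()].
#' @return The filtered [genotype_matrix()]. Idempotent.
#' @export
hard_filter <- function(gm, thresholds = filter_thresholds()) {
  if (is.null(gm$info)) {
    warning("no site annotations present; hard_filter is a no-op")
    return(gm)
  }
  info <- gm$info
  keep <- rep(TRUE, ncol(gm$calls))
  crit <- list(
    FS = function(v) v <= thresholds$fs_max,
    HaplotypeScore = function(v) v <= thresholds$haplotype_score_max,
    MQ = function(v) v >= thresholds$mq_min,
    QD = function(v) v >= thresholds$qd_min,
    ReadPosRankSum = function(v) v >= thresholds$read_pos_rank_sum_min,
    MQRankSum = function(v) v > thresholds$mq_rank_sum_min)
  for (f in names(crit)) {
    v <- info[[f]]
    if (is.null(v) || all(is.na(v))) {
      warning(sprintf("annotation %s absent; criterion skipped", f))
      next
    }
    pass <- crit[[f]](v)
    pass[is.na(pass)] <- TRUE
    keep <- keep & pass
  }
  n_drop <- sum(!keep)
  if (n_drop > 0) message(sprintf("hard_filter: removed %d of %d loci",
                                  n_drop, length(keep)))
  subset_gm(gm, loci = which(keep))
}

#' Minor-allele-frequency filter
#'
#' Retains loci with MAF strictly greater than `maf_min`, the MAF computed
#' over non-missing calls of the analysis group. Loci with all calls
#' missing are dropped.
#'
#' @param gm A [genotype_matrix()].
#' @param maf_min Frequency bound (default 0.05, strict).
#' @return The filtered [genotype_matrix()]. Idempotent.
#' @export
maf_filter <- function(gm, maf_min = 0.05) {
  p <- allele_freqs(gm)
  maf <- pmin(p, 1 - p)
  keep <- !is.na(maf) & maf > maf_min
  n_drop <- sum(!keep)
  if (n_drop > 0) message(sprintf("maf_filter: removed %d of %d loci",
                                  n_drop, length(keep)))
  subset_gm(gm, loci = which(keep))
}

#' Age class from diameter at breast height
#'
#' Saplings have DBH < 7.5 cm, adults 7.5 <= DBH < 22.5 cm, mature trees
#' DBH >= 22.5 cm.
#'
#' @param dbh Numeric vector of DBH in cm (> 0).
#' @return Character vector in `c("sapling", "adult", "mature")`.
#' @export
classify_age <- function(dbh) {
  if (any(!is.na(dbh) & dbh <= 0))
    stop("DBH must be positive", call. = FALSE)
  out <- ifelse(dbh < 7.5, "sapling", ifelse(dbh < 22.5, "adult", "mature"))
  out[is.na(dbh)] <- NA_character_
  out
}
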