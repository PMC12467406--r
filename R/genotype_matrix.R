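#' Genotype matrix container
#'
#' A light S3 container for biallelic SNP genotypes: an integer matrix of
#' alternate-allele dosages (0, 1, 2, `NA` for missing) with samples in rows
#' and loci in columns, plus optional per-locus site annotations (FS, MQ,
#' QD, ReadPosRankSum, MQRankSum, HaplotypeScore) used by the hard filter.
#'
#' @param calls Integer matrix, samples x loci, values in 0/1/2/`NA`, with
#'   rownames (sample ids) and colnames (locus ids).
#' @param info Optional data frame of per-locus annotations, one row per
#'   locus in column order.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, info = NULL) {
  if (!is.matrix(calls)) stop("`calls` must be a matrix", call. = FALSE)
  storage.mode(calls) <- "integer"
  bad <- calls[!is.na(calls)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("genotype codes must be 0, 1, 2 or NA", call. = FALSE)
  if (is.null(rownames(calls)) && nrow(calls) > 0)
    rownames(calls) <- paste0("S", seq_len(nrow(calls)))
  if (is.null(colnames(calls)) && ncol(calls) > 0)
    colnames(calls) <- paste0("L", seq_len(ncol(calls)))
  if (!is.null(info)) {
    info <- as.data.frame(info)
    if (nrow(info) != ncol(calls))
      stop("`info` must have one row per locus", call. = FALSE)
  }
  structure(list(calls = calls, info = info), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d loci, %.1f%% missing%s\n",
              nrow(x$calls), ncol(x$calls),
              100 * mean(is.na(x$calls)),
              if (is.null(x$info)) "" else
                paste0("; annotations: ", paste(names(x$info), collapse = ", "))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

# Subset a genotype_matrix by sample and/or locus index/name.
subset_gm <- function(gm, samples = NULL, loci = NULL) {
  calls <- gm$calls
  info <- gm$info
  if (!is.null(samples)) calls <- calls[samples, , drop = FALSE]
  if (!is.null(loci)) {
    if (is.character(loci)) loci <- match(loci, colnames(calls))
    calls <- calls[, loci, drop = FALSE]
    if (!is.null(info)) info <- info[loci, , drop = FALSE]
  }
  genotype_matrix(calls, info)
}

# Alternate-allele frequency per locus over non-missing calls.
allele_freqs <- function(gm) {
  colMeans(gm$calls, na.rm = TRUE) / 2
}
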