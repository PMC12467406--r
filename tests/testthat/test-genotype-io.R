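write_toy_vcf <- function(path, records, sample_ids = c("s1", "s2")) {
  header <- c("##fileformat=VCFv4.2",
              "##contig=<ID=chr1>",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", sample_ids), collapse = "\t"))
  writeLines(c(header, records), path)
}

toy_meta <- function(path, ids) {
  con <- file(path, "w")
  writeLines("#coord_system=planar_m", con)
  utils::write.table(
    data.frame(id = ids, population = "X", patch = "p1",
               lon = seq_along(ids), lat = 0, dbh = 10),
    con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
}

test_that("multiallelic and non-SNP records are dropped", {
  td <- withr::local_tempdir()
  vcf <- file.path(td, "t.vcf"); meta <- file.path(td, "m.tsv")
  recs <- c(
    sprintf("chr1\t%d\tsnp%d\tA\tT\t50\tPASS\t.\tGT\t0/1\t1/1", 1:8 * 10, 1:8),
    "chr1\t100\ttri\tA\tT,G\t50\tPASS\t.\tGT\t0/1\t0/2",
    "chr1\t110\tindel\tAT\tA\t50\tPASS\t.\tGT\t0/1\t0/0")
  write_toy_vcf(vcf, recs)
  toy_meta(meta, c("s1", "s2"))
  inp <- suppressMessages(read_vcf(vcf, meta))
  expect_equal(ncol(inp$genotypes$calls), 8)
  expect_false(any(c("tri", "indel") %in% colnames(inp$genotypes$calls)))
})

test_that("genotype codes and missing calls are parsed as dosage", {
  td <- withr::local_tempdir()
  vcf <- file.path(td, "t.vcf"); meta <- file.path(td, "m.tsv")
  write_toy_vcf(vcf, c("chr1\t10\ta\tA\tT\t50\tPASS\t.\tGT\t0/0\t1/1",
                       "chr1\t20\tb\tA\tT\t50\tPASS\t.\tGT\t0|1\t./.",
                       "chr1\t30\tc\tA\tT\t50\tPASS\t.\tGT\t./1\t1/0"))
  toy_meta(meta, c("s1", "s2"))
  calls <- read_vcf(vcf, meta)$genotypes$calls
  expect_equal(unname(calls["s1", ]), c(0L, 1L, NA))
  expect_equal(unname(calls["s2", ]), c(2L, NA, 1L))
})

test_that("VCF samples missing from metadata raise a keyed error", {
  td <- withr::local_tempdir()
  vcf <- file.path(td, "t.vcf"); meta <- file.path(td, "m.tsv")
  write_toy_vcf(vcf, "chr1\t10\ta\tA\tT\t50\tPASS\t.\tGT\t0/0\t1/1")
  toy_meta(meta, "s1")
  expect_error(read_vcf(vcf, meta), "s2")
})

test_that("hard filter enforces each criterion including strict MQRankSum", {
  base <- list(FS = 1, HaplotypeScore = 2, MQ = 60, QD = 25,
               ReadPosRankSum = 0, MQRankSum = 0)
  # six sites, each failing exactly one criterion; plus one passing site
  fails <- list(c(FS = 70), c(HaplotypeScore = 13.5), c(MQ = 39),
                c(QD = 1.9), c(ReadPosRankSum = -8.5), c(MQRankSum = -12.5))
  info <- do.call(rbind, lapply(c(fails, list(c(FS = 60))), function(f) {
    row <- base; row[names(f)] <- f; as.data.frame(row)
  }))
  calls <- matrix(1L, 2, 7)
  gm <- genotype_matrix(calls, info)
  kept <- suppressMessages(hard_filter(gm))
  expect_equal(ncol(kept$calls), 1)          # only the boundary-passing site
  expect_equal(kept$info$FS, 60)             # FS <= 60 is inclusive
  again <- hard_filter(kept)
  expect_identical(again$calls, kept$calls)  # idempotent
})

test_that("absent annotation fields are skipped with a warning", {
  gm <- genotype_matrix(matrix(1L, 2, 3),
                        data.frame(FS = c(1, 70, 2), MQ = NA_real_))
  w <- capture_warnings(out <- suppressMessages(hard_filter(gm)))
  expect_true(any(grepl("MQ", w)))
  expect_true(any(grepl("HaplotypeScore", w)))
  expect_equal(ncol(out$calls), 2)
})

test_that("MAF filter is strict at the boundary and idempotent", {
  n <- 10
  calls <- cbind(
    at_bound = c(1L, rep(0L, n - 1)),        # p = 0.05 exactly -> dropped
    common   = rep(1L, n),                   # p = 0.5 -> retained
    rare     = c(rep(0L, n)),                # monomorphic -> dropped
    all_miss = rep(NA_integer_, n))
  gm <- genotype_matrix(calls)
  out <- suppressMessages(maf_filter(gm, 0.05))
  expect_equal(colnames(out$calls), "common")
  expect_identical(suppressMessages(maf_filter(out, 0.05))$calls, out$calls)
})

test_that("MAF removal fraction matches an independent recount", {
  ds <- clean_dataset()
  gm <- ds$genotypes
  out <- suppressMessages(maf_filter(gm, 0.05))
  p <- colMeans(gm$calls, na.rm = TRUE) / 2
  expect_equal(ncol(out$calls), sum(pmin(p, 1 - p) > 0.05, na.rm = TRUE))
})

test_that("DBH age classes use the 7.5 and 22.5 cm boundaries", {
  expect_equal(classify_age(5.0), "sapling")
  expect_equal(classify_age(7.5), "adult")
  expect_equal(classify_age(22.4), "adult")
  expect_equal(classify_age(22.5), "mature")
  expect_error(classify_age(-1), "positive")
})
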