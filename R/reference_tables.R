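#' Bundled reference summary tables
#'
#' Published patch-level summary statistics for the four surveyed
#' *Tetracentron sinense* populations (BMXS, GLGS, MGFD, SXFP), shipped as
#' plain TSV so the worked examples and desk-scale checks recompute from
#' them: `"diversity_patches"` (per-patch Num Indv, HO, unbiased HE, Fis),
#' `"sgs_population"` (population-level bF, F(1) and the printed Sp), and
#' `"dispersal_direct"` (per-patch maximum/mean seed and pollen dispersal
#' distances and the printed effective gene-dispersal distance, including
#' the per-population `means` rows).
#'
#' @param name One of `"diversity_patches"`, `"sgs_population"`,
#'   `"dispersal_direct"`.
#' @return A tibble.
#' @export
reference_table <- function(name = c("diversity_patches", "sgs_population",
                                     "dispersal_direct")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0("tsinense_", name, ".tsv"),
                      package = "finesgs", mustWork = TRUE)
  tibble::as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                                      stringsAsFactors = FALSE))
}
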