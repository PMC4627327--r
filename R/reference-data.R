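#' Published per-sample somatic variant counts (pPCL cohort)
#'
#' Transcription of the published per-sample table of coding somatic
#' non-silent variants in the 12-sample pPCL cohort: somatic and somatic
#' sub-clonal non-synonymous SNVs and indels, with per-sample totals.
#'
#' @return Tibble, one row per sample.
#' @export
ppcl_table1 <- function() {
  path <- system.file("extdata", "ppcl_table1.tsv", package = "pclexome")
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Published cohort-level variant class counts (pPCL cohort)
#'
#' The published cohort-wide breakdown of the coding somatic non-silent
#' variants: non-synonymous SNVs (missense and nonsense), indels, splice
#' site variants, and the total.
#'
#' @return Tibble with `class` and `count`.
#' @export
ppcl_variant_classes <- function() {
  path <- system.file("extdata", "ppcl_variant_classes.tsv",
                      package = "pclexome")
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
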