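#' @importFrom dplyr %>% arrange bind_rows distinct filter group_by left_join
#'   mutate n n_distinct pull rename select summarise ungroup across all_of
#'   anti_join semi_join slice row_number first if_else count inner_join
#' @importFrom tibble tibble as_tibble
#' @importFrom rlang .data
#' @importFrom stats pbinom phyper rbinom rhyper rpois runif sd var
NULL

# enums used throughout; order is load-bearing only where stated
VARIANT_CLASSES <- c("snv", "insertion", "deletion")
CONSEQUENCES <- c("missense", "nonsense", "synonymous", "frameshift",
                  "inframe_indel", "splice_site", "noncoding")
NON_SILENT <- c("missense", "nonsense", "frameshift", "inframe_indel",
                "splice_site")

VARIANT_COLUMNS <- c("sample_id", "chrom", "pos", "ref", "alt",
                     "total_depth", "alt_depth", "variant_class",
                     "consequence", "gene", "context3",
                     "in_polymorphism_db", "in_cosmic",
                     "cosmic_confirmed_somatic", "in_clinvar", "damaging")

#' Validate a variant table
#'
#' Checks the invariants of the variant record contract: column set and
#' types, `alt_depth <= total_depth`, SNV if and only if ref and alt are
#' single bases, `context3` centered on the reference base, and COSMIC
#' somatic confirmation implying COSMIC membership.
#'
#' @param variants A tibble of variant records.
#' @return The input, invisibly, if valid; otherwise an error.
#' @export
validate_variants <- function(variants) {
  missing_cols <- setdiff(VARIANT_COLUMNS, names(variants))
  if (length(missing_cols) > 0) {
    stop("variant table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(variants) == 0) return(invisible(variants))
  if (any(variants$alt_depth > variants$total_depth)) {
    stop("alt_depth exceeds total_depth for ",
         sum(variants$alt_depth > variants$total_depth), " record(s)")
  }
  if (!all(variants$variant_class %in% VARIANT_CLASSES)) {
    stop("unknown variant_class value(s)")
  }
  if (!all(variants$consequence %in% CONSEQUENCES)) {
    stop("unknown consequence value(s)")
  }
  is_snv <- nchar(variants$ref) == 1L & nchar(variants$alt) == 1L
  if (any(is_snv != (variants$variant_class == "snv"))) {
    stop("variant_class 'snv' must coincide with single-base ref and alt")
  }
  ctx <- variants$context3
  has_ctx <- !is.na(ctx)
  if (any(has_ctx & nchar(ctx) != 3L)) stop("context3 must be a 3-mer")
  bad_center <- has_ctx & is_snv & substr(ctx, 2, 2) != variants$ref
  if (any(bad_center)) {
    stop("context3 center base disagrees with ref for ",
         sum(bad_center), " record(s)")
  }
  if (any(variants$cosmic_confirmed_somatic & !variants$in_cosmic)) {
    stop("cosmic_confirmed_somatic requires in_cosmic")
  }
  invisible(variants)
}

#' Convert a 1-based variant position to 0-based half-open segment space
#'
#' Variants follow the VCF convention (1-based positions); segments and gene
#' models follow the BED convention (0-based half-open). All conversions go
#' through this function: a variant at `pos` overlaps the half-open interval
#' `[start, end)` iff `start <= pos - 1 < end`.
#'
#' @param pos Integer vector of 1-based positions.
#' @return Integer vector of 0-based positions.
#' @export
pos_to_zero_based <- function(pos) {
  as.integer(pos) - 1L
}

#' Test overlap of variant positions with a half-open interval
#'
#' @param pos 1-based variant position(s).
#' @param start,end 0-based half-open interval bounds.
#' @return Logical vector.
#' @export
variant_in_interval <- function(pos, start, end) {
  p0 <- pos_to_zero_based(pos)
  p0 >= start & p0 < end
}

#' Left-normalize indel representations
#'
#' Trims shared trailing then leading bases from ref/alt pairs (adjusting
#' the position for leading trims) so that equivalent indel representations
#' compare equal. Reference-free parsimony normalization: without a genome
#' sequence, full left-alignment across repeats is not possible, but all
#' padding introduced by callers is removed.
#'
#' @param pos,ref,alt Parallel vectors describing variants.
#' @return A list with normalized `pos`, `ref`, `alt`.
#' @export
normalize_indel <- function(pos, ref, alt) {
  pos <- as.integer(pos)
  n <- length(pos)
  for (i in seq_len(n)) {
    r <- ref[i]; a <- alt[i]; p <- pos[i]
    # trim shared suffix
    while (nchar(r) > 1L && nchar(a) > 1L &&
           substr(r, nchar(r), nchar(r)) == substr(a, nchar(a), nchar(a))) {
      r <- substr(r, 1L, nchar(r) - 1L)
      a <- substr(a, 1L, nchar(a) - 1L)
    }
    # trim shared prefix
    while (nchar(r) > 1L && nchar(a) > 1L &&
           substr(r, 1L, 1L) == substr(a, 1L, 1L)) {
      r <- substr(r, 2L, nchar(r))
      a <- substr(a, 2L, nchar(a))
      p <- p + 1L
    }
    ref[i] <- r; alt[i] <- a; pos[i] <- p
  }
  list(pos = pos, ref = ref, alt = alt)
}

# normalized site key used for germline matching and recurrence grouping
variant_key <- function(variants) {
  norm <- normalize_indel(variants$pos, variants$ref, variants$alt)
  paste(variants$chrom, norm$pos, norm$ref, norm$alt, sep = ":")
}

revcomp <- function(x) {
  chartr("ACGT", "TGCA",
         vapply(strsplit(x, ""), function(s) paste(rev(s), collapse = ""), ""))
}
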