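#' Select the largest transcript per gene
#'
#' Returns, per gene, the transcript maximizing span (end - start); ties
#' are broken by the lexicographically smallest transcript id.
#'
#' @param models Gene model tibble (gene, transcript, chrom, start, end).
#' @return One row per gene.
#' @export
largest_transcript <- function(models) {
  models %>%
    mutate(span = .data$end - .data$start) %>%
    arrange(.data$gene, dplyr::desc(.data$span), .data$transcript) %>%
    group_by(.data$gene) %>%
    slice(1) %>%
    ungroup() %>%
    select(-"span")
}

cn_class_of <- function(copy_number, baseline = 2L) {
  eff <- copy_number - (baseline - 2L)
  dplyr::case_when(
    eff <= 0L ~ "homozygous_del",
    eff == 1L ~ "hemizygous_del",
    eff == 2L ~ "neutral",
    eff <= 4L ~ "gain",
    TRUE ~ "amplification"
  )
}

#' Project copy-number segments onto genes
#'
#' For every sample-by-gene pair, overlaps the gene's largest-transcript
#' interval with the sample's segments (0-based half-open on both sides)
#' and assigns the copy number of the segment with the greatest overlap
#' length. Genes with no overlapping segment stay at the diploid baseline.
#' A gene overlapping segments with differing copy number is flagged
#' `mixed`. If ANY overlapping segment has copy number 0 the gene is
#' recorded as a homozygous deletion regardless of the greatest-overlap
#' assignment (a focal deletion inside a gene destroys it).
#'
#' Per-sample baselines (e.g. 4 for a basally tetraploid sample) shift the
#' class thresholds accordingly.
#'
#' @param segments Segment tibble (sample_id, chrom, start, end,
#'   copy_number).
#' @param gene_models Gene model tibble; reduced internally via
#'   [largest_transcript()].
#' @param diploid_baseline Default baseline copy number (2).
#' @param baseline_overrides Optional tibble (sample_id, baseline).
#' @return Tibble with sample_id, gene, copy_number, cn_class, mixed_flag.
#' @export
assign_gene_cn <- function(segments, gene_models, diploid_baseline = 2L,
                           baseline_overrides = NULL) {
  gm <- largest_transcript(gene_models)
  samples <- unique(segments$sample_id)
  baselines <- stats::setNames(rep(as.integer(diploid_baseline),
                                   length(samples)), samples)
  if (!is.null(baseline_overrides) && nrow(baseline_overrides) > 0) {
    idx <- match(baseline_overrides$sample_id, names(baselines))
    ok <- !is.na(idx)
    baselines[idx[ok]] <- as.integer(baseline_overrides$baseline[ok])
  }
  gene_gr <- GenomicRanges::GRanges(
    gm$chrom, IRanges::IRanges(start = gm$start + 1L, end = gm$end))
  out <- lapply(samples, function(sid) {
    seg <- segments %>% filter(.data$sample_id == sid)
    base <- baselines[[sid]]
    res <- tibble(
      sample_id = sid, gene = gm$gene,
      copy_number = base, mixed_flag = FALSE, any_zero = FALSE
    )
    if (nrow(seg) > 0) {
      seg_gr <- GenomicRanges::GRanges(
        seg$chrom, IRanges::IRanges(start = seg$start + 1L, end = seg$end))
      # tumor segment files legitimately cover fewer chromosomes than the
      # gene models; the seqlevel-mismatch warning is expected
      hits <- suppressWarnings(
        GenomicRanges::findOverlaps(gene_gr, seg_gr))
      if (length(hits) > 0) {
        qh <- S4Vectors::queryHits(hits)
        sh <- S4Vectors::subjectHits(hits)
        ov <- suppressWarnings(
          IRanges::width(IRanges::pintersect(gene_gr[qh], seg_gr[sh])))
        hit_df <- tibble(gi = qh, si = sh, overlap = ov,
                         cn = seg$copy_number[sh],
                         seg_start = seg$start[sh]) %>%
          arrange(.data$gi, dplyr::desc(.data$overlap), .data$seg_start)
        best <- hit_df %>% group_by(.data$gi) %>% slice(1) %>% ungroup()
        res$copy_number[best$gi] <- best$cn
        per_gene <- hit_df %>%
          group_by(.data$gi) %>%
          summarise(n_cn = n_distinct(.data$cn),
                    any0 = any(.data$cn == 0L), .groups = "drop")
        res$mixed_flag[per_gene$gi] <- per_gene$n_cn > 1
        res$any_zero[per_gene$gi] <- per_gene$any0
      }
    }
    res
  })
  res <- bind_rows(out) %>%
    mutate(base = baselines[.data$sample_id],
           cn_class = cn_class_of(.data$copy_number, .data$base),
           cn_class = if_else(.data$any_zero, "homozygous_del",
                              .data$cn_class),
           copy_number = if_else(.data$any_zero, 0L,
                                 as.integer(.data$copy_number))) %>%
    select("sample_id", "gene", "copy_number", "cn_class", "mixed_flag")
  res
}

#' Call biallelic (two-hit) inactivation events
#'
#' Emits a `homozygous_deletion` event for every sample-by-gene with copy
#' number class homozygous deletion, and a `mutation_plus_loss` event for
#' every sample-by-gene carrying at least one non-silent somatic call on a
#' hemizygous (one-copy-loss) background — the classic tumor-suppressor
#' pattern. Genes with two or more mutations but no copy loss are NOT
#' two-hit events (phase unknown); retrieve them with
#' [multi_mutated_genes()].
#'
#' @param gene_cn Output of [assign_gene_cn()].
#' @param somatic_calls Somatic call tibble (with `gene`, `consequence`).
#' @return Tibble with sample_id, gene, mechanism, variant fields of one
#'   supporting call (NA for pure deletions).
#' @export
call_two_hits <- function(gene_cn, somatic_calls) {
  homdel <- gene_cn %>%
    filter(.data$cn_class == "homozygous_del") %>%
    mutate(mechanism = "homozygous_deletion",
           chrom = NA_character_, pos = NA_integer_,
           ref = NA_character_, alt = NA_character_) %>%
    select("sample_id", "gene", "mechanism", "chrom", "pos", "ref", "alt")
  mut <- somatic_calls %>%
    filter(.data$consequence %in% NON_SILENT, !is.na(.data$gene)) %>%
    group_by(.data$sample_id, .data$gene) %>%
    slice(1) %>%
    ungroup()
  mutloss <- gene_cn %>%
    filter(.data$cn_class == "hemizygous_del") %>%
    inner_join(mut %>% select("sample_id", "gene", "chrom", "pos",
                              "ref", "alt"),
               by = c("sample_id", "gene")) %>%
    mutate(mechanism = "mutation_plus_loss") %>%
    select("sample_id", "gene", "mechanism", "chrom", "pos", "ref", "alt")
  bind_rows(homdel, mutloss) %>%
    arrange(.data$sample_id, .data$gene)
}

#' Genes with multiple mutations and no copy loss
#'
#' Reported separately from two-hit events because mutation phase is
#' unknown without copy loss.
#'
#' @param gene_cn Output of [assign_gene_cn()].
#' @param somatic_calls Somatic call tibble.
#' @return Tibble with sample_id, gene, n_variants.
#' @export
multi_mutated_genes <- function(gene_cn, somatic_calls) {
  somatic_calls %>%
    filter(.data$consequence %in% NON_SILENT, !is.na(.data$gene)) %>%
    count(.data$sample_id, .data$gene, name = "n_variants") %>%
    filter(.data$n_variants >= 2) %>%
    left_join(gene_cn %>% select("sample_id", "gene", "cn_class"),
              by = c("sample_id", "gene")) %>%
    filter(is.na(.data$cn_class) |
             !.data$cn_class %in% c("hemizygous_del", "homozygous_del"))
}

#' Per-sample somatic alteration burden
#'
#' Sums, per sample, the somatic variant calls (clonal plus sub-clonal,
#' SNVs and indels) and the copy-number segments departing from the
#' sample's baseline.
#'
#' @param somatic_calls Somatic call tibble.
#' @param segments Segment tibble.
#' @param diploid_baseline Baseline copy number (default 2).
#' @param baseline_overrides Optional tibble (sample_id, baseline).
#' @return Tibble with sample_id, n_variants, n_cna, total.
#' @export
burden_summary <- function(somatic_calls, segments, diploid_baseline = 2L,
                           baseline_overrides = NULL) {
  base_of <- function(sid) {
    if (!is.null(baseline_overrides) &&
        sid %in% baseline_overrides$sample_id) {
      as.integer(baseline_overrides$baseline[
        match(sid, baseline_overrides$sample_id)])
    } else as.integer(diploid_baseline)
  }
  nv <- somatic_calls %>% count(.data$sample_id, name = "n_variants")
  nc <- segments %>%
    group_by(.data$sample_id) %>%
    summarise(n_cna = sum(.data$copy_number !=
                            base_of(first(.data$sample_id))),
              .groups = "drop")
  dplyr::full_join(nv, nc, by = "sample_id") %>%
    mutate(n_variants = dplyr::coalesce(.data$n_variants, 0L),
           n_cna = dplyr::coalesce(.data$n_cna, 0L),
           total = .data$n_variants + .data$n_cna) %>%
    arrange(.data$sample_id)
}
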