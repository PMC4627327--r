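#' Per-gene recurrence counts with de-duplication of flagged variants
#'
#' Counts, per gene, the distinct samples and variants carrying somatic
#' calls. Any variant set sharing a normalized (chrom, pos, ref, alt) key
#' whose members carry the recurrent-unconfirmed germline risk flag
#' contributes 1 (not k) to the gene's variant count, so possible residual
#' germline background does not over-score genes. Genes on the spurious
#' list are flagged (retained here, excluded from enrichment downstream).
#'
#' @param calls Somatic call tibble with `germline_risk_flag`.
#' @param spurious_list Character vector of spurious gene symbols (see
#'   [default_spurious_genes()]).
#' @param dedup Apply the considered-just-once rule (default TRUE).
#' @return Tibble with gene, n_samples, n_variants, n_snv, n_indel,
#'   dedup_applied, spurious_flag.
#' @export
gene_recurrence <- function(calls, spurious_list = character(0),
                            dedup = TRUE) {
  x <- calls %>% filter(!is.na(.data$gene))
  if (nrow(x) == 0) {
    return(tibble(gene = character(), n_samples = integer(),
                  n_variants = integer(), n_snv = integer(),
                  n_indel = integer(), dedup_applied = logical(),
                  spurious_flag = logical()))
  }
  x <- x %>% mutate(.key = variant_key(x))
  counted <- if (dedup) {
    flagged <- x %>% filter(.data$germline_risk_flag) %>%
      distinct(.data$gene, .data$.key, .keep_all = TRUE)
    bind_rows(x %>% filter(!.data$germline_risk_flag), flagged)
  } else x
  per_gene <- counted %>%
    group_by(.data$gene) %>%
    summarise(
      n_variants = n(),
      n_snv = sum(.data$variant_class == "snv"),
      n_indel = sum(.data$variant_class != "snv"),
      dedup_applied = any(.data$germline_risk_flag) && dedup,
      .groups = "drop"
    )
  n_samp <- x %>%
    group_by(.data$gene) %>%
    summarise(n_samples = n_distinct(.data$sample_id), .groups = "drop")
  per_gene %>%
    left_join(n_samp, by = "gene") %>%
    mutate(spurious_flag = .data$gene %in% spurious_list) %>%
    select("gene", "n_samples", "n_variants", "n_snv", "n_indel",
           "dedup_applied", "spurious_flag") %>%
    arrange(dplyr::desc(.data$n_samples), dplyr::desc(.data$n_variants),
            .data$gene)
}

#' Default list of potentially spurious genes
#'
#' Genes frequently found mutated in cancer sequencing studies for reasons
#' unrelated to tumor biology (large or late-replicating genes, olfactory
#' receptors). Packaged as an editable text file; replace with your own
#' list via the `path` argument of downstream functions.
#'
#' @return Character vector of gene symbols.
#' @export
default_spurious_genes <- function() {
  path <- system.file("extdata", "spurious_genes.txt", package = "pclexome")
  x <- readLines(path)
  x <- trimws(x)
  x[nzchar(x) & !startsWith(x, "#")]
}

# one-sided (enrichment) Fisher p by direct hypergeometric summation.
# Layout: a = damaging in set, b = other in set, c = damaging out of set,
# d = other out of set; p = P(X >= a), X ~ Hypergeom(K = a+c damaging in
# a universe of N, drawing the a+b in-set calls).
hypergeom_tail <- function(a, b, c, d) {
  n <- a + b + c + d
  k_dmg <- a + c          # damaging variants in the universe
  m_set <- a + b          # variants inside the gene set
  if (n == 0 || m_set == 0 || k_dmg == 0) return(1)
  kmax <- min(k_dmg, m_set)
  ks <- a:kmax
  terms <- exp(lchoose(k_dmg, ks) + lchoose(n - k_dmg, m_set - ks) -
                 lchoose(n, m_set))
  min(1, sum(terms))
}

#' Damaging-variant enrichment of a gene set (Fisher exact test)
#'
#' Builds the 2x2 table {damaging, non-damaging} x {gene in set, gene not
#' in set} over all non-silent calls (spurious genes excluded) and
#' computes the one-sided (enrichment) Fisher exact p as the exact
#' hypergeometric tail, by direct summation.
#'
#' @param calls Somatic call tibble with `damaging` and `gene`.
#' @param gene_set A gene set (list with `name`, `genes`) or character
#'   vector of genes.
#' @param spurious_list Genes excluded from the universe.
#' @return List with `name`, `a`, `b`, `c`, `d`, `odds_ratio` (NULL when
#'   undefined), `p_fisher`, `p_resample` (NA until
#'   [resample_damaging()]), `q_value` (NA until [bh_adjust()]).
#' @export
fisher_damaging <- function(calls, gene_set, spurious_list = character(0)) {
  genes <- if (is.list(gene_set)) gene_set$genes else gene_set
  name <- if (is.list(gene_set) && !is.null(gene_set$name)) gene_set$name
          else NA_character_
  if (length(genes) == 0) stop("empty gene set")
  uni <- calls %>%
    filter(.data$consequence %in% NON_SILENT, !is.na(.data$gene),
           !.data$gene %in% spurious_list)
  in_set <- uni$gene %in% genes
  a <- sum(in_set & uni$damaging)
  b <- sum(in_set & !uni$damaging)
  c_ <- sum(!in_set & uni$damaging)
  d <- sum(!in_set & !uni$damaging)
  p <- hypergeom_tail(a, b, c_, d)
  or <- if (b > 0 && c_ > 0) (a * d) / (b * c_) else NULL
  list(name = name, a = a, b = b, c = c_, d = d, odds_ratio = or,
       p_fisher = p, p_resample = NA_real_, q_value = NA_real_)
}

#' Resampling null for the damaging fraction of a gene set
#'
#' Let m be the number of calls in the set and f_obs their damaging
#' fraction. Draws B random samples of m calls without replacement from
#' the whole call universe and returns the add-one permutation p-value
#' `(1 + #{f_draw >= f_obs}) / (B + 1)`. Because the damaging fraction of
#' a draw depends only on how many damaging calls it contains, draws are
#' generated as hypergeometric counts, which is distributionally identical
#' to resampling the calls themselves.
#'
#' @param calls Somatic call tibble.
#' @param gene_set Gene set (list or character vector).
#' @param B Number of resamples (default 1e5).
#' @param seed Integer seed for reproducibility.
#' @param spurious_list Genes excluded from the universe.
#' @return The resampling p-value.
#' @export
resample_damaging <- function(calls, gene_set, B = 1e5, seed = 1L,
                              spurious_list = character(0)) {
  stopifnot(B >= 1)
  genes <- if (is.list(gene_set)) gene_set$genes else gene_set
  uni <- calls %>%
    filter(.data$consequence %in% NON_SILENT, !is.na(.data$gene),
           !.data$gene %in% spurious_list)
  in_set <- uni$gene %in% genes
  m <- sum(in_set)
  if (m == 0) stop("empty pathway intersection")
  n <- nrow(uni)
  k_dmg <- sum(uni$damaging)
  a_obs <- sum(in_set & uni$damaging)
  set.seed(seed)
  draws <- rhyper(B, k_dmg, n - k_dmg, m)
  (1 + sum(draws >= a_obs)) / (B + 1)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Standard step-up q-values with monotonicity enforcement,
#' order-preserving in the input.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return q-values in the input order.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Damaging-variant enrichment over a gene-set catalog
#'
#' Runs [fisher_damaging()] and [resample_damaging()] for every set and
#' BH-adjusts the Fisher p-values.
#'
#' @param calls Somatic call tibble.
#' @param gene_sets List of gene sets (see [read_gene_sets()]).
#' @param B Resamples per set.
#' @param seed Base seed; set k uses `seed + k`.
#' @param spurious_list Genes excluded from the universe.
#' @return Tibble with one row per set: a, b, c, d, odds_ratio, p_fisher,
#'   p_resample, q_value.
#' @export
enrichment_table <- function(calls, gene_sets, B = 1e4, seed = 1L,
                             spurious_list = default_spurious_genes()) {
  rows <- lapply(seq_along(gene_sets), function(k) {
    fs <- fisher_damaging(calls, gene_sets[[k]], spurious_list)
    fs$p_resample <- tryCatch(
      resample_damaging(calls, gene_sets[[k]], B = B, seed = seed + k,
                        spurious_list = spurious_list),
      error = function(e) NA_real_)
    tibble(name = fs$name, a = fs$a, b = fs$b, c = fs$c, d = fs$d,
           odds_ratio = if (is.null(fs$odds_ratio)) NA_real_
                        else fs$odds_ratio,
           p_fisher = fs$p_fisher, p_resample = fs$p_resample)
  })
  out <- bind_rows(rows)
  out$q_value <- bh_adjust(out$p_fisher)
  out
}
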