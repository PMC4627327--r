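#' Depth filter
#'
#' Retains records with total depth at or above `min_depth` (boundary
#' inclusive: a 10x call passes the default 10x threshold).
#'
#' @param records Variant tibble.
#' @param min_depth Minimum total depth, default 10.
#' @return Filtered tibble.
#' @export
depth_filter <- function(records, min_depth = 10) {
  stopifnot(min_depth >= 1)
  records %>% filter(.data$total_depth >= min_depth)
}

#' Keep coding non-silent variants
#'
#' Retains missense, nonsense, frameshift, inframe indel and splice-site
#' records; synonymous and noncoding positions are removed.
#'
#' @param records Variant tibble.
#' @return Filtered tibble.
#' @export
select_non_silent <- function(records) {
  records %>% filter(.data$consequence %in% NON_SILENT)
}

#' Polymorphism-database filter with COSMIC/ClinVar rescue
#'
#' Removes variants annotated as polymorphisms (dbSNP/1000G/ESP union)
#' unless the same variant is also present in COSMIC or ClinVar, whose
#' membership rescues it for its potential tumor or clinical relevance.
#'
#' @param records Variant tibble.
#' @return Filtered tibble.
#' @export
polymorphism_filter <- function(records) {
  records %>%
    filter(!(.data$in_polymorphism_db & !.data$in_cosmic & !.data$in_clinvar))
}

#' Subtract germline evidence from control samples
#'
#' Removes any tumor variant whose normalized (chrom, pos, ref, alt) key is
#' called in at least one supplied control with control depth at or above
#' `min_control_depth` — a low-coverage control call cannot veto. Matched
#' mode supplies only the matched control; pooled (unpaired) mode supplies
#' the control pool.
#'
#' @param tumor_records Tumor variant tibble.
#' @param control_records Control variant tibble (one or many samples).
#' @param min_control_depth Minimum depth for a control call to count.
#' @return Filtered tumor tibble.
#' @export
subtract_controls <- function(tumor_records, control_records,
                              min_control_depth = 10) {
  if (is.null(control_records) || nrow(control_records) == 0) {
    stop("no controls supplied")
  }
  veto <- control_records %>%
    filter(.data$total_depth >= min_control_depth)
  veto_keys <- unique(variant_key(veto))
  tumor_records[!variant_key(tumor_records) %in% veto_keys, , drop = FALSE]
}

#' Label somatic calls as clonal or sub-clonal
#'
#' Estimates the cancer-cell fraction as `ccf = 2 * VAF / purity` (diploid
#' assumption) and labels a variant sub-clonal when a one-sided exact
#' binomial test rejects (low tail, level `alpha`) the clonal expectation
#' `alt_depth ~ Binomial(total_depth, 0.5 * purity)` AND `ccf` is below
#' `ccf_threshold`. Paired mode only.
#'
#' @param somatic_records Somatic variant tibble (post-subtraction).
#' @param purity Tumor purity in (0, 1].
#' @param alpha One-sided test level, default 0.05.
#' @param ccf_threshold CCF below which a significant call is sub-clonal.
#' @return The input with `vaf`, `ccf`, and `clonality` columns.
#' @export
label_subclonal <- function(somatic_records, purity, alpha = 0.05,
                            ccf_threshold = 0.5) {
  if (!(purity > 0 && purity <= 1)) stop("purity must be in (0, 1]")
  if (nrow(somatic_records) == 0) {
    return(somatic_records %>%
             mutate(vaf = numeric(0), ccf = numeric(0),
                    clonality = character(0)))
  }
  p_clonal <- 0.5 * purity
  vaf <- somatic_records$alt_depth / somatic_records$total_depth
  ccf <- 2 * vaf / purity
  p_low <- pbinom(somatic_records$alt_depth, somatic_records$total_depth,
                  p_clonal)
  somatic_records %>%
    mutate(vaf = vaf, ccf = ccf,
           clonality = if_else(p_low < alpha & ccf < ccf_threshold,
                               "subclonal", "clonal"))
}

#' Run the full somatic filter cascade on one tumor sample
#'
#' Applies, in fixed order: depth filter, coding non-silent selection,
#' polymorphism-database filter (with COSMIC/ClinVar rescue), control
#' subtraction (matched control in paired mode, control pool in unpaired
#' mode), and — in paired mode only — sub-clonal labeling. Returns the
#' surviving calls and the filter funnel (per-stage surviving and removed
#' counts).
#'
#' @param sample_records Variant tibble of one tumor sample.
#' @param controls Control variant tibble: the matched control (paired
#'   mode) or the control pool (unpaired mode).
#' @param mode `"paired"` or `"unpaired"`.
#' @param purity Tumor purity (used for sub-clonal labeling).
#' @param min_depth Tumor depth threshold.
#' @param min_control_depth Control depth threshold for vetoes.
#' @param alpha,ccf_threshold Sub-clonal labeling parameters.
#' @return List with `calls` (with `clonality`, `mode`,
#'   `germline_risk_flag` columns) and `funnel` (stage, survivors, removed).
#' @export
run_cascade <- function(sample_records, controls,
                        mode = c("paired", "unpaired"), purity = 0.9,
                        min_depth = 10, min_control_depth = 10,
                        alpha = 0.05, ccf_threshold = 0.5) {
  mode <- match.arg(mode)
  stages <- character(0)
  survivors <- integer(0)
  n0 <- nrow(sample_records)
  x <- depth_filter(sample_records, min_depth)
  stages <- c(stages, "depth_filter"); survivors <- c(survivors, nrow(x))
  x <- select_non_silent(x)
  stages <- c(stages, "select_non_silent"); survivors <- c(survivors, nrow(x))
  x <- polymorphism_filter(x)
  stages <- c(stages, "polymorphism_filter")
  survivors <- c(survivors, nrow(x))
  x <- subtract_controls(x, controls, min_control_depth)
  stages <- c(stages, "subtract_controls"); survivors <- c(survivors, nrow(x))
  if (mode == "paired") {
    x <- label_subclonal(x, purity, alpha, ccf_threshold)
    stages <- c(stages, "label_subclonal")
    survivors <- c(survivors, nrow(x))
  } else {
    x <- x %>% mutate(vaf = .data$alt_depth / .data$total_depth,
                      ccf = NA_real_, clonality = "clonal")
  }
  calls <- x %>% mutate(mode = mode, germline_risk_flag = FALSE)
  surv_path <- c(n0, survivors)
  funnel <- tibble(
    stage = c("input", stages),
    survivors = surv_path,
    removed = c(0L, -diff(surv_path))
  )
  list(calls = calls, funnel = funnel)
}

#' Audit germline carry-over in unpaired mode
#'
#' For every paired tumor, runs the cascade in paired mode (matched
#' control) and in unpaired mode (pool of the OTHER samples' controls) and
#' reports the calls unique to the unpaired run — the private germline
#' background that would leak through if no matched normal existed.
#'
#' @param variants Cohort variant tibble (tumors and controls).
#' @param metadata Sample metadata tibble.
#' @param ... Cascade parameters passed to [run_cascade()].
#' @return Tibble with one row per paired sample: `n_paired`,
#'   `n_unpaired`, `n_extra`, `extra_fraction`.
#' @export
carryover_audit <- function(variants, metadata, ...) {
  paired <- metadata %>%
    filter(.data$role == "tumor", !is.na(.data$matched_control_id))
  if (nrow(paired) == 0) stop("no paired samples in metadata")
  rows <- lapply(seq_len(nrow(paired)), function(i) {
    sid <- paired$sample_id[i]
    cid <- paired$matched_control_id[i]
    tum <- variants %>% filter(.data$sample_id == sid)
    matched <- variants %>% filter(.data$sample_id == cid)
    other_controls <- variants %>%
      filter(.data$sample_id %in%
               setdiff(paired$matched_control_id, cid))
    pr <- run_cascade(tum, matched, mode = "paired",
                      purity = paired$purity[i], ...)
    up <- run_cascade(tum, other_controls, mode = "unpaired", ...)
    k_paired <- variant_key(pr$calls)
    k_unpaired <- variant_key(up$calls)
    n_extra <- sum(!k_unpaired %in% k_paired)
    tibble(sample_id = sid,
           n_paired = length(k_paired),
           n_unpaired = length(k_unpaired),
           n_extra = n_extra,
           extra_fraction = if (length(k_unpaired) > 0) {
             n_extra / length(k_unpaired)
           } else 0)
  })
  bind_rows(rows)
}

#' Flag recurrent variants without confirmed somatic status
#'
#' Identical variants recurring in two or more unpaired samples that are
#' polymorphism-database members and COSMIC members but NOT confirmed
#' somatic in COSMIC are flagged as possible residual germline background.
#'
#' @param calls Somatic calls across samples (with `mode` column).
#' @return The input with `germline_risk_flag` updated.
#' @export
flag_unconfirmed_recurrent <- function(calls) {
  if (nrow(calls) == 0) return(calls)
  keys <- variant_key(calls)
  unpaired_keys <- keys[calls$mode == "unpaired"]
  recurrent <- tibble(key = unpaired_keys,
                      sample_id = calls$sample_id[calls$mode == "unpaired"]) %>%
    distinct() %>%
    count(.data$key) %>%
    filter(.data$n >= 2) %>%
    pull(.data$key)
  flag <- keys %in% recurrent &
    calls$mode == "unpaired" &
    calls$in_polymorphism_db & calls$in_cosmic &
    !calls$cosmic_confirmed_somatic
  calls %>% mutate(germline_risk_flag = flag)
}

#' Run the cascade for every tumor in a cohort
#'
#' Paired tumors use their matched control; unpaired tumors use the pool
#' of all controls. Recurrent-variant flagging is applied across the
#' unpaired calls afterwards.
#'
#' @param variants Cohort variant tibble.
#' @param metadata Sample metadata tibble.
#' @param ... Cascade parameters passed to [run_cascade()].
#' @return List with `calls` (all samples, flagged) and `funnels` (named
#'   list of per-sample funnels).
#' @export
cohort_cascade <- function(variants, metadata, ...) {
  tumors <- metadata %>% filter(.data$role == "tumor")
  controls_all <- variants %>%
    filter(.data$sample_id %in%
             metadata$sample_id[metadata$role == "control"])
  if (nrow(controls_all) == 0) stop("no controls supplied")
  calls <- list()
  funnels <- list()
  for (i in seq_len(nrow(tumors))) {
    sid <- tumors$sample_id[i]
    tum <- variants %>% filter(.data$sample_id == sid)
    cid <- tumors$matched_control_id[i]
    if (!is.na(cid)) {
      res <- run_cascade(tum,
                         controls_all %>% filter(.data$sample_id == cid),
                         mode = "paired", purity = tumors$purity[i], ...)
    } else {
      res <- run_cascade(tum, controls_all, mode = "unpaired", ...)
    }
    calls[[sid]] <- res$calls
    funnels[[sid]] <- res$funnel
  }
  all_calls <- flag_unconfirmed_recurrent(bind_rows(calls))
  list(calls = all_calls, funnels = funnels)
}
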