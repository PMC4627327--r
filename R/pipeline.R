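#' Assemble a pipeline configuration
#'
#' Collects input paths and every stage parameter into one validated
#' list. Paths may be omitted when the pipeline is run on an in-memory
#' simulated cohort.
#'
#' @param variants,segments,gene_models,metadata Input file paths in the
#'   package formats (see the reader functions).
#' @param expression,expression_meta,signature_matrix,gene_sets Optional
#'   input file paths; stages needing them are skipped when NULL.
#' @param out_dir Output directory.
#' @param min_depth,min_control_depth Depth thresholds.
#' @param alpha,ccf_threshold Sub-clonal labeling parameters.
#' @param distinct_threshold Signature attribution threshold.
#' @param fold Variable-gene fold threshold.
#' @param k Number of expression clusters.
#' @param B_enrich,B_assoc,B_repl Resampling/permutation sizes.
#' @param q_cut DE q-value threshold.
#' @param diploid_baseline Default copy-number baseline.
#' @param baseline_overrides Optional tibble (sample_id, baseline).
#' @param seed Integer seed for every stochastic stage.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(variants = NULL, segments = NULL,
                            gene_models = NULL, metadata = NULL,
                            expression = NULL, expression_meta = NULL,
                            signature_matrix = NULL, gene_sets = NULL,
                            out_dir = "pclexome-out",
                            min_depth = 10, min_control_depth = 10,
                            alpha = 0.05, ccf_threshold = 0.5,
                            distinct_threshold = 0.7, fold = 2, k = 5,
                            B_enrich = 10000, B_assoc = 10000,
                            B_repl = 200, q_cut = 0.05,
                            diploid_baseline = 2L,
                            baseline_overrides = NULL, seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(seed == as.integer(seed))
  structure(cfg, class = "pipeline_config")
}

load_pipeline_inputs <- function(config) {
  list(
    variants = read_variants(config$variants, "tsv"),
    segments = read_segments(config$segments),
    gene_models = read_gene_models(config$gene_models),
    metadata = read_metadata(config$metadata),
    expression = if (!is.null(config$expression)) {
      read_expression(config$expression)
    },
    expression_meta = if (!is.null(config$expression_meta)) {
      readr::read_tsv(config$expression_meta, show_col_types = FALSE,
                      progress = FALSE)
    },
    signature_profiles = if (!is.null(config$signature_matrix)) {
      read_signature_matrix(config$signature_matrix)
    } else make_signature_profiles(),
    gene_sets = if (!is.null(config$gene_sets)) {
      read_gene_sets(config$gene_sets)
    }
  )
}

#' Run the end-to-end analysis pipeline
#'
#' Executes, in order: the somatic filter cascade for every tumor (paired
#' where a matched control exists, pooled-normal otherwise, with
#' recurrent-variant flagging and the carry-over audit), mutational
#' signature spectra and attribution, copy-number integration (gene CN
#' states, two-hit events, burden summary), gene recurrence and — when a
#' gene-set catalog is supplied — damaging-variant enrichment, and — when
#' an expression matrix is supplied — variable-gene clustering with group
#' association and two-class differential expression. Writes every stage
#' table to `out_dir` plus a manifest with parameter values, the seed,
#' and a content hash per file; identical config and seed give identical
#' output.
#'
#' @param config A [pipeline_config()].
#' @param inputs Optional pre-loaded input list (as from
#'   [simulate_cohort()]); when NULL, inputs are read from the paths in
#'   `config`.
#' @return Invisibly, a list with all stage results and the manifest.
#' @export
run_pipeline <- function(config, inputs = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(inputs)) inputs <- load_pipeline_inputs(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  cas <- stage("filtering", cohort_cascade(
    inputs$variants, inputs$metadata, min_depth = config$min_depth,
    min_control_depth = config$min_control_depth, alpha = config$alpha,
    ccf_threshold = config$ccf_threshold))
  funnel_tbl <- bind_rows(lapply(names(cas$funnels), function(s) {
    cas$funnels[[s]] %>% mutate(sample_id = s)
  }))
  audit <- stage("carryover_audit", tryCatch(
    carryover_audit(inputs$variants, inputs$metadata,
                    min_depth = config$min_depth,
                    min_control_depth = config$min_control_depth,
                    alpha = config$alpha,
                    ccf_threshold = config$ccf_threshold),
    error = function(e) NULL))

  tumor_ids <- inputs$metadata$sample_id[inputs$metadata$role == "tumor"]
  spectra <- stage("signatures", lapply(tumor_ids, function(s) {
    build_spectrum(cas$calls %>% filter(.data$sample_id == s))
  }))
  nonzero <- vapply(spectra, function(sp) sum(sp$counts96) > 0, TRUE)
  sig_report <- stage("signatures", cohort_signature_report(
    spectra[nonzero], inputs$signature_profiles, inputs$metadata,
    distinct_threshold = config$distinct_threshold))

  gene_cn <- stage("cna_integration", assign_gene_cn(
    inputs$segments, inputs$gene_models,
    diploid_baseline = config$diploid_baseline,
    baseline_overrides = config$baseline_overrides))
  two_hits <- stage("cna_integration", call_two_hits(gene_cn, cas$calls))
  burden <- stage("cna_integration", burden_summary(
    cas$calls, inputs$segments,
    diploid_baseline = config$diploid_baseline,
    baseline_overrides = config$baseline_overrides))

  spurious <- default_spurious_genes()
  recurrence <- stage("recurrence", gene_recurrence(cas$calls, spurious))
  enrichment <- if (!is.null(inputs$gene_sets)) {
    stage("enrichment", enrichment_table(
      cas$calls, inputs$gene_sets, B = config$B_enrich,
      seed = config$seed, spurious_list = spurious))
  }

  expression_results <- NULL
  if (!is.null(inputs$expression)) {
    mat <- inputs$expression
    emeta <- inputs$expression_meta
    variable <- stage("expression",
                      select_variable_genes(mat, config$fold))
    mutated <- unique(cas$calls$gene[!is.na(cas$calls$gene)])
    focal <- intersect(variable, mutated)
    groups <- stats::setNames(emeta$translocation_group, emeta$sample_id)
    clus <- assoc <- repl <- NULL
    if (length(focal) >= 2) {
      clus <- stage("expression", hcluster(mat, focal, config$k))
      assoc <- stage("expression", group_association(
        clus$labels, groups, B = config$B_assoc, seed = config$seed))
      repl <- stage("expression", tryCatch(
        replication_probability(mat, variable, focal, groups, config$k,
                                B = config$B_repl, seed = config$seed),
        error = function(e) NULL))
    }
    deg <- NULL
    if (!is.null(emeta$disease)) {
      cls <- split(emeta$sample_id, emeta$disease)
      if (length(cls) == 2 && all(lengths(cls) >= 3)) {
        genes_de <- intersect(mutated, rownames(mat))
        if (length(genes_de) >= 2) {
          deg <- stage("expression", differential_expression(
            mat[genes_de, , drop = FALSE],
            cls[["pPCL"]], cls[["MM"]], q_cut = config$q_cut))
        }
      }
    }
    expression_results <- list(variable_genes = variable,
                               focal_genes = focal, clustering = clus,
                               association = assoc, replication = repl,
                               deg = deg)
  }

  # ---- write bundle -------------------------------------------------------
  outfile <- function(name) file.path(config$out_dir, name)
  write_variants(cas$calls %>% select(all_of(VARIANT_COLUMNS)),
                 outfile("calls.tsv"), "tsv")
  readr::write_tsv(cas$calls %>%
                     select("sample_id", "chrom", "pos", "ref", "alt",
                            "clonality", "mode", "germline_risk_flag"),
                   outfile("calls_status.tsv"), progress = FALSE)
  readr::write_tsv(funnel_tbl, outfile("funnel.tsv"), progress = FALSE)
  if (!is.null(audit)) {
    readr::write_tsv(audit, outfile("carryover_audit.tsv"),
                     progress = FALSE)
  }
  readr::write_tsv(sig_report, outfile("signature_report.tsv"),
                   na = ".", progress = FALSE)
  readr::write_tsv(gene_cn, outfile("gene_cn.tsv"), progress = FALSE)
  readr::write_tsv(two_hits, outfile("two_hits.tsv"), na = ".",
                   progress = FALSE)
  readr::write_tsv(burden, outfile("burden.tsv"), progress = FALSE)
  readr::write_tsv(recurrence, outfile("recurrence.tsv"),
                   progress = FALSE)
  if (!is.null(enrichment)) {
    readr::write_tsv(enrichment, outfile("enrichment.tsv"), na = ".",
                     progress = FALSE)
  }
  if (!is.null(expression_results)) {
    if (!is.null(expression_results$clustering)) {
      readr::write_tsv(
        tibble(sample_id = names(expression_results$clustering$labels),
               cluster = unname(expression_results$clustering$labels)),
        outfile("clusters.tsv"), progress = FALSE)
      readr::write_tsv(expression_results$association,
                       outfile("association.tsv"), na = ".",
                       progress = FALSE)
    }
    if (!is.null(expression_results$replication)) {
      writeLines(format(expression_results$replication$p_value,
                        digits = 6), outfile("replication_p.txt"))
    }
    if (!is.null(expression_results$deg)) {
      readr::write_tsv(expression_results$deg, outfile("deg.tsv"),
                       progress = FALSE)
    }
  }

  files <- list.files(config$out_dir, full.names = TRUE)
  files <- files[!grepl("manifest", files)]
  manifest <- tibble(
    file = basename(files),
    md5 = unname(tools::md5sum(files))
  )
  params <- config[!vapply(config, is.null, TRUE)]
  params <- params[vapply(params, function(p) {
    is.numeric(p) || is.character(p) || is.logical(p)
  }, TRUE)]
  manifest_lines <- c(
    paste0("# pclexome ",
           as.character(utils::packageVersion("pclexome"))),
    paste0("# ", names(params), " = ",
           vapply(params, function(p) paste(p, collapse = ","), "")),
    paste(manifest$file, manifest$md5, sep = "\t")
  )
  writeLines(manifest_lines, outfile("manifest.txt"))

  invisible(list(calls = cas$calls, funnels = cas$funnels,
                 carryover = audit, spectra = spectra,
                 signature_report = sig_report, gene_cn = gene_cn,
                 two_hits = two_hits, burden = burden,
                 recurrence = recurrence, enrichment = enrichment,
                 expression = expression_results,
                 manifest = manifest))
}
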