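# small constructors used across the suite; all fixtures are built in code

make_variant <- function(sample_id = "S1", chrom = "chr1", pos = 100L,
                         ref = "C", alt = "T", total_depth = 40L,
                         alt_depth = 20L, variant_class = "snv",
                         consequence = "missense", gene = "G0001",
                         context3 = "ACG", in_polymorphism_db = FALSE,
                         in_cosmic = FALSE, cosmic_confirmed_somatic = FALSE,
                         in_clinvar = FALSE, damaging = FALSE) {
  tibble::tibble(
    sample_id = sample_id, chrom = chrom, pos = as.integer(pos),
    ref = ref, alt = alt, total_depth = as.integer(total_depth),
    alt_depth = as.integer(alt_depth), variant_class = variant_class,
    consequence = consequence, gene = gene, context3 = context3,
    in_polymorphism_db = in_polymorphism_db, in_cosmic = in_cosmic,
    cosmic_confirmed_somatic = cosmic_confirmed_somatic,
    in_clinvar = in_clinvar, damaging = damaging
  )
}

# random valid variant records for round-trip property tests
random_variants <- function(n, seed = 1) {
  set.seed(seed)
  labels <- context96_labels()
  rows <- lapply(seq_len(n), function(i) {
    is_snv <- runif(1) < 0.8
    if (is_snv) {
      lab <- sample(labels, 1)
      ref <- substr(lab, 3, 3); alt <- substr(lab, 5, 5)
      ctx <- paste0(substr(lab, 1, 1), ref, substr(lab, 7, 7))
      if (runif(1) < 0.2) ctx <- NA_character_
      cls <- "snv"
      csq <- sample(c("missense", "nonsense", "synonymous", "splice_site",
                      "noncoding"), 1)
    } else {
      base <- sample(c("A", "C", "G", "T"), 1)
      ext <- paste(sample(c("A", "C", "G", "T"), sample(1:4, 1),
                          replace = TRUE), collapse = "")
      if (runif(1) < 0.5) {
        ref <- base; alt <- paste0(base, ext); cls <- "insertion"
      } else {
        ref <- paste0(base, ext); alt <- base; cls <- "deletion"
      }
      ctx <- NA_character_
      csq <- sample(c("frameshift", "inframe_indel"), 1)
    }
    depth <- sample(5:80, 1)
    polydb <- runif(1) < 0.4
    cosmic <- runif(1) < 0.3
    make_variant(
      sample_id = sample(c("S1", "S2", "S3"), 1),
      chrom = sample(paste0("chr", 1:5), 1),
      pos = sample.int(1e6, 1), ref = ref, alt = alt,
      total_depth = depth, alt_depth = sample.int(depth, 1),
      variant_class = cls, consequence = csq,
      gene = if (runif(1) < 0.9) sprintf("G%04d", sample.int(50, 1))
             else NA_character_,
      context3 = ctx, in_polymorphism_db = polydb, in_cosmic = cosmic,
      cosmic_confirmed_somatic = cosmic & runif(1) < 0.5,
      in_clinvar = runif(1) < 0.1, damaging = runif(1) < 0.4
    )
  })
  dplyr::bind_rows(rows)
}

# tiny deterministic cohort for fast end-to-end tests
small_sim <- function(seed = 42) {
  simulate_cohort(sim_config(
    n_tumors = 6, n_paired = 3, n_germline_per_sample = 300,
    n_somatic_clonal = 60, n_somatic_subclonal = 10, n_genes = 120,
    n_cna_segments = 10, n_expr_mm = 20, n_expr_pcl = 10,
    n_de_genes = 20, n_group_genes = 30, seed = seed))
}

truth_key <- function(x) paste(x$sample_id, x$chrom, x$pos, x$ref, x$alt)
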