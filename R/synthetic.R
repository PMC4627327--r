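#' Configuration for the synthetic cohort generator
#'
#' Defaults reproduce the study design the package models: 12 tumors of
#' which 5 have matched normals, mean sequencing depth 42x, roughly 150
#' clonal somatic events per sample of which 7% are indels, and 20
#' sub-clonal events (paired samples only) at a cancer-cell fraction of
#' 0.2. Germline variation is drawn from a shared polymorphism pool so
#' that sites are shared between individuals (exercising pooled-normal
#' subtraction) while a 2% slice of the pool is absent from polymorphism
#' databases (exercising the carry-over audit).
#'
#' @param n_tumors Number of tumor samples.
#' @param n_paired Number of tumors with a matched normal.
#' @param mean_depth Mean sequencing depth (Poisson, truncated at 1).
#' @param n_germline_per_sample Germline variants per individual.
#' @param n_somatic_clonal Clonal somatic variants per tumor.
#' @param n_somatic_subclonal Sub-clonal somatic variants per paired tumor.
#' @param subclonal_ccf Cancer-cell fraction of sub-clonal variants.
#' @param signature_weights Optional n_tumors x 2 matrix of per-sample
#'   (aging, apobec) weights, rows summing to 1; `NULL` derives weights
#'   from the translocation group (t(14;16) samples APOBEC-dominated).
#' @param indel_fraction Fraction of somatic events that are indels.
#' @param purity Tumor purity (fraction of tumor cells in the specimen).
#' @param germline_db_rate Probability a germline pool site is present in
#'   polymorphism databases.
#' @param germline_cosmic_rate,germline_clinvar_rate Probability a
#'   germline pool site is catalogued in COSMIC / ClinVar (such sites are
#'   rescued by the polymorphism filter and feed the carry-over audit).
#' @param germline_pool_factor Pool size as a multiple of
#'   `n_germline_per_sample` (smaller means more sharing).
#' @param n_cna_segments Target number of copy-number segments per sample.
#' @param n_twohit_mutloss Planted mutation-plus-loss two-hit genes.
#' @param n_twohit_homdel Planted homozygous-deletion two-hit genes.
#' @param n_recurrent_artifacts Planted recurrent germline artifacts
#'   (present in two unpaired tumors, database- and COSMIC-annotated but
#'   not confirmed somatic) feeding the recurrent-variant flagging rule.
#' @param n_genes,n_chromosomes Toy genome size.
#' @param n_expr_mm,n_expr_pcl Expression cohort sizes (myeloma and
#'   leukemia classes).
#' @param n_de_genes,de_effect Planted differentially expressed genes
#'   between the two disease classes and their log2 effect size.
#' @param n_group_genes,group_effect Genes carrying translocation-group
#'   structure in expression and the scale of the group shifts (log2).
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_tumors = 12, n_paired = 5, mean_depth = 42,
                       n_germline_per_sample = 1500,
                       n_somatic_clonal = 150, n_somatic_subclonal = 20,
                       subclonal_ccf = 0.2, signature_weights = NULL,
                       indel_fraction = 0.07, purity = 0.9,
                       germline_db_rate = 0.98, germline_pool_factor = 3,
                       germline_cosmic_rate = 0.02,
                       germline_clinvar_rate = 0.01,
                       n_cna_segments = 20, n_twohit_mutloss = 3,
                       n_twohit_homdel = 2, n_recurrent_artifacts = 2,
                       n_genes = 500, n_chromosomes = 24,
                       n_expr_mm = 55, n_expr_pcl = 21,
                       n_de_genes = 50, de_effect = 1.5,
                       n_group_genes = 60, group_effect = 1.5,
                       seed = 1L) {
  if (n_paired > n_tumors) stop("n_paired cannot exceed n_tumors")
  cfg <- as.list(environment())
  if (!is.null(signature_weights)) {
    signature_weights <- as.matrix(signature_weights)
    if (nrow(signature_weights) != n_tumors || ncol(signature_weights) != 2) {
      stop("signature_weights must be n_tumors x 2")
    }
    if (any(signature_weights < 0) ||
        any(abs(rowSums(signature_weights) - 1) > 1e-9)) {
      stop("signature weights must be non-negative and sum to 1 per sample")
    }
    cfg$signature_weights <- signature_weights
  }
  counts <- c(cfg$n_tumors, cfg$n_paired, cfg$n_germline_per_sample,
              cfg$n_somatic_clonal, cfg$n_somatic_subclonal)
  if (any(counts < 0)) stop("counts must be non-negative")
  structure(cfg, class = "sim_config")
}

CHROM_LENGTH <- 2e6L

sim_chrom_names <- function(n) {
  base <- c(paste0("chr", 1:22), "chrX", "chrY")
  base[seq_len(min(n, 24))]
}

rdepth <- function(n, mean_depth) {
  pmax(1L, rpois(n, mean_depth))
}

ralt <- function(depth, p) {
  pmax(1L, rbinom(length(depth), depth, p))
}

sample_context_labels <- function(n, w_aging, w_apobec, profiles) {
  sig <- sample(c("aging", "apobec"), n, replace = TRUE,
                prob = c(w_aging, w_apobec))
  labels <- character(n)
  for (s in c("aging", "apobec")) {
    idx <- which(sig == s)
    if (length(idx) > 0) {
      labels[idx] <- sample(rownames(profiles), length(idx),
                            replace = TRUE, prob = profiles[, s])
    }
  }
  list(labels = labels, signature = sig)
}

# turn pyrimidine-strand labels into concrete ref/alt/context3 records,
# presenting half of them on the purine strand
labels_to_alleles <- function(labels) {
  n <- length(labels)
  flip <- runif(n) < 0.5
  ref <- substr(labels, 3, 3)
  alt <- substr(labels, 5, 5)
  ctx <- paste0(substr(labels, 1, 1), ref, substr(labels, 7, 7))
  ref[flip] <- chartr("ACGT", "TGCA", ref[flip])
  alt[flip] <- chartr("ACGT", "TGCA", alt[flip])
  ctx[flip] <- revcomp(ctx[flip])
  list(ref = ref, alt = alt, context3 = ctx)
}

random_indel_alleles <- function(n) {
  ins <- runif(n) < 0.5
  base <- sample(BASES, n, replace = TRUE)
  extra <- vapply(sample.int(3, n, replace = TRUE), function(k) {
    paste(sample(BASES, k, replace = TRUE), collapse = "")
  }, "")
  ref <- ifelse(ins, base, paste0(base, extra))
  alt <- ifelse(ins, paste0(base, extra), base)
  list(ref = ref, alt = alt,
       variant_class = ifelse(ins, "insertion", "deletion"))
}

assign_damaging <- function(consequence) {
  auto <- consequence %in% c("nonsense", "frameshift", "splice_site")
  auto | (consequence == "missense" & runif(length(consequence)) < 0.4)
}

#' Simulate a full tumor cohort with known ground truth
#'
#' Generates, from one seed, everything the downstream stages consume:
#' per-sample variant calls (tumors and matched normals), copy-number
#' segments, a toy gene model set, sample metadata, an expression matrix
#' with disease-class and translocation-group structure, and a truth
#' channel labelling every variant (germline / somatic_clonal /
#' somatic_subclonal), its generating signature, the planted two-hit
#' genes, and the planted differentially expressed genes.
#'
#' Germline variants appear in the tumor and, for paired individuals, in
#' the matched normal, at VAF centred on 0.5 (heterozygous) or 1
#' (homozygous). Clonal somatic variants have VAF centred on
#' `0.5 * purity`; sub-clonal ones on `0.5 * purity * subclonal_ccf`.
#' Somatic SNV trinucleotide contexts are drawn from the sample's
#' aging/APOBEC signature mixture; germline contexts are flat.
#'
#' @param config A [sim_config()].
#' @return List with `variants`, `segments`, `gene_models`, `metadata`,
#'   `expression`, `expression_meta`, `signature_profiles`, and `truth`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  chroms <- sim_chrom_names(config$n_chromosomes)

  # ---- toy gene models: 1-3 transcripts per gene --------------------------
  gene_ids <- sprintf("G%04d", seq_len(config$n_genes))
  g_chrom <- sample(chroms, config$n_genes, replace = TRUE)
  g_start <- sample.int(CHROM_LENGTH - 60000L, config$n_genes)
  g_width <- sample(5000:30000, config$n_genes, replace = TRUE)
  n_tx <- sample.int(3, config$n_genes, replace = TRUE)
  g_strand <- sample(c("+", "-"), config$n_genes, replace = TRUE)
  gi <- rep.int(seq_len(config$n_genes), n_tx)
  tx_rank <- sequence(n_tx)
  off <- ifelse(tx_rank == 1, 0L,
                sample.int(2000L, length(gi), replace = TRUE))
  shrink <- ifelse(tx_rank == 1, 0L,
                   sample.int(3000L, length(gi), replace = TRUE))
  gene_models <- tibble(
    gene = gene_ids[gi],
    transcript = sprintf("%s.T%d", gene_ids[gi], tx_rank),
    chrom = g_chrom[gi],
    start = g_start[gi] + off,
    end = pmax(g_start[gi] + off + 500L, g_start[gi] + g_width[gi] - shrink),
    strand = g_strand[gi]
  )
  gene_span <- gene_models %>%
    group_by(.data$gene) %>%
    summarise(chrom = first(.data$chrom), start = min(.data$start),
              end = max(.data$end), .groups = "drop")

  # ---- sample metadata ----------------------------------------------------
  tumor_ids <- sprintf("SIM-T%02d", seq_len(config$n_tumors))
  control_ids <- sprintf("SIM-N%02d", seq_len(config$n_paired))
  groups <- rep(c("t(14;16)", "t(11;14)", "t(4;14)", "t(14;20)", "none"),
                length.out = config$n_tumors)
  metadata <- bind_rows(
    tibble(sample_id = tumor_ids, role = "tumor",
           matched_control_id = c(control_ids,
                                  rep(NA_character_,
                                      config$n_tumors - config$n_paired)),
           translocation_group = groups, purity = config$purity),
    tibble(sample_id = control_ids, role = "control",
           matched_control_id = NA_character_,
           translocation_group = NA_character_, purity = NA_real_)
  )

  # per-sample signature weights: t(14;16) APOBEC-driven, one aging-pure
  # sample, the rest an aging-leaning admixture
  if (is.null(config$signature_weights)) {
    w_apobec <- ifelse(groups == "t(14;16)", 0.9, 0.4)
    w_apobec[which(groups != "t(14;16)")[1]] <- 0.1
    sig_w <- cbind(aging = 1 - w_apobec, apobec = w_apobec)
  } else {
    sig_w <- config$signature_weights
    colnames(sig_w) <- c("aging", "apobec")
  }
  rownames(sig_w) <- tumor_ids
  profiles <- make_signature_profiles()

  # ---- germline pool ------------------------------------------------------
  n_pool <- max(config$n_germline_per_sample,
                round(config$germline_pool_factor *
                        config$n_germline_per_sample))
  pool_is_indel <- runif(n_pool) < 0.10
  pool_chrom <- sample(chroms, n_pool, replace = TRUE)
  pool_pos <- sample.int(CHROM_LENGTH - 100L, n_pool)
  # ~60% of pool sites fall inside genes and get coding consequences
  in_gene <- runif(n_pool) < 0.6
  pool_gene_idx <- sample.int(config$n_genes, n_pool, replace = TRUE)
  pool_chrom[in_gene] <- gene_span$chrom[pool_gene_idx[in_gene]]
  span_w <- gene_span$end - gene_span$start
  pool_pos[in_gene] <- gene_span$start[pool_gene_idx[in_gene]] +
    floor(runif(sum(in_gene)) * span_w[pool_gene_idx[in_gene]]) + 1L
  pool_gene <- ifelse(in_gene, gene_span$gene[pool_gene_idx], NA_character_)
  snv_alleles <- labels_to_alleles(
    sample(rownames(profiles), n_pool, replace = TRUE))   # flat contexts
  indel_alleles <- random_indel_alleles(n_pool)
  pool_ref <- ifelse(pool_is_indel, indel_alleles$ref, snv_alleles$ref)
  pool_alt <- ifelse(pool_is_indel, indel_alleles$alt, snv_alleles$alt)
  pool_class <- ifelse(pool_is_indel, indel_alleles$variant_class, "snv")
  pool_ctx <- ifelse(pool_is_indel, NA_character_, snv_alleles$context3)
  csq_coding_snv <- c("missense", "synonymous", "nonsense", "splice_site")
  csq_coding_indel <- c("frameshift", "inframe_indel")
  pool_csq <- ifelse(
    !in_gene, "noncoding",
    ifelse(pool_is_indel,
           sample(csq_coding_indel, n_pool, replace = TRUE,
                  prob = c(0.7, 0.3)),
           sample(csq_coding_snv, n_pool, replace = TRUE,
                  prob = c(0.55, 0.38, 0.04, 0.03))))
  pool_db <- runif(n_pool) < config$germline_db_rate
  pool_cosmic <- runif(n_pool) < config$germline_cosmic_rate
  pool_cosmic_som <- pool_cosmic & runif(n_pool) < 0.3
  pool_clinvar <- runif(n_pool) < config$germline_clinvar_rate
  pool_damaging <- assign_damaging(pool_csq)
  pool <- tibble(
    chrom = pool_chrom, pos = as.integer(pool_pos), ref = pool_ref,
    alt = pool_alt, variant_class = pool_class, consequence = pool_csq,
    gene = pool_gene, context3 = pool_ctx, in_polymorphism_db = pool_db,
    in_cosmic = pool_cosmic, cosmic_confirmed_somatic = pool_cosmic_som,
    in_clinvar = pool_clinvar, damaging = pool_damaging
  ) %>% distinct(.data$chrom, .data$pos, .keep_all = TRUE)
  n_pool <- nrow(pool)

  variants <- list()
  truth_rows <- list()

  # ---- germline per individual -------------------------------------------
  for (i in seq_len(config$n_tumors)) {
    idx <- sample.int(n_pool, min(config$n_germline_per_sample, n_pool))
    hom <- runif(length(idx)) < 1 / 3
    p_allele <- ifelse(hom, 1, 0.5)
    site <- pool[idx, ]
    t_depth <- rdepth(length(idx), config$mean_depth)
    t_alt <- pmin(t_depth, ralt(t_depth, p_allele))
    tum <- site %>%
      mutate(sample_id = tumor_ids[i], total_depth = t_depth,
             alt_depth = t_alt) %>%
      select(all_of(VARIANT_COLUMNS))
    variants[[length(variants) + 1L]] <- tum
    truth_rows[[length(truth_rows) + 1L]] <- tibble(
      sample_id = tumor_ids[i], chrom = site$chrom, pos = site$pos,
      ref = site$ref, alt = site$alt, label = "germline",
      signature = "flat", in_polymorphism_db = site$in_polymorphism_db,
      pool_index = idx
    )
    if (i <= config$n_paired) {
      c_depth <- rdepth(length(idx), config$mean_depth)
      c_alt <- pmin(c_depth, ralt(c_depth, p_allele))
      ctl <- site %>%
        mutate(sample_id = control_ids[i], total_depth = c_depth,
               alt_depth = c_alt) %>%
        select(all_of(VARIANT_COLUMNS))
      variants[[length(variants) + 1L]] <- ctl
      truth_rows[[length(truth_rows) + 1L]] <- tibble(
        sample_id = control_ids[i], chrom = site$chrom, pos = site$pos,
        ref = site$ref, alt = site$alt, label = "germline",
        signature = "flat", in_polymorphism_db = site$in_polymorphism_db,
        pool_index = idx
      )
    }
  }

  # ---- planted two-hit genes ---------------------------------------------
  n_plant_mut <- min(config$n_twohit_mutloss, config$n_genes)
  n_plant_hd <- min(config$n_twohit_homdel, config$n_genes - n_plant_mut)
  plant_genes <- sample(gene_ids, n_plant_mut + n_plant_hd)
  mutloss_genes <- plant_genes[seq_len(n_plant_mut)]
  homdel_genes <- plant_genes[n_plant_mut + seq_len(n_plant_hd)]
  mutloss_samples <- sample(tumor_ids, n_plant_mut, replace = TRUE)
  homdel_samples <- sample(tumor_ids, n_plant_hd, replace = TRUE)
  two_hit_truth <- bind_rows(
    tibble(sample_id = mutloss_samples, gene = mutloss_genes,
           mechanism = "mutation_plus_loss"),
    tibble(sample_id = homdel_samples, gene = homdel_genes,
           mechanism = "homozygous_deletion")
  )

  # ---- somatic variants ---------------------------------------------------
  # somatic sites never coincide with polymorphism-pool sites: per-site
  # somatic mutation probabilities make such collisions vanishingly rare
  # in real exomes, and the toy genome is far denser than a real one
  pool_site_keys <- paste(pool$chrom, pool$pos)
  somatic_one <- function(sample_id, n, p_allele, label, w) {
    if (n == 0) return(NULL)
    is_indel <- runif(n) < config$indel_fraction
    n_snv <- sum(!is_indel)
    ctx <- sample_context_labels(n_snv, w[1], w[2], profiles)
    alle <- labels_to_alleles(ctx$labels)
    indel <- random_indel_alleles(sum(is_indel))
    gene_idx <- sample.int(config$n_genes, n, replace = TRUE)
    pos <- gene_span$start[gene_idx] +
      floor(runif(n) * (gene_span$end - gene_span$start)[gene_idx]) + 1L
    for (iter in 1:10) {
      clash <- paste(gene_span$chrom[gene_idx], pos) %in% pool_site_keys
      if (!any(clash)) break
      pos[clash] <- gene_span$start[gene_idx[clash]] +
        floor(runif(sum(clash)) *
                (gene_span$end - gene_span$start)[gene_idx[clash]]) + 1L
    }
    ref <- alt <- cls <- csq <- character(n)
    ctx3 <- rep(NA_character_, n)
    signature <- character(n)
    ref[!is_indel] <- alle$ref; alt[!is_indel] <- alle$alt
    cls[!is_indel] <- "snv"; ctx3[!is_indel] <- alle$context3
    signature[!is_indel] <- ctx$signature
    csq[!is_indel] <- sample(c("missense", "nonsense", "splice_site"),
                             n_snv, replace = TRUE,
                             prob = c(0.92, 0.05, 0.03))
    if (sum(is_indel) > 0) {
      ref[is_indel] <- indel$ref; alt[is_indel] <- indel$alt
      cls[is_indel] <- indel$variant_class
      csq[is_indel] <- sample(csq_coding_indel, sum(is_indel),
                              replace = TRUE, prob = c(0.8, 0.2))
      signature[is_indel] <- "flat"
    }
    depth <- rdepth(n, config$mean_depth)
    alt_d <- pmin(depth, ralt(depth, p_allele))
    cosmic <- runif(n) < 0.04
    x <- tibble(
      sample_id = sample_id, chrom = gene_span$chrom[gene_idx],
      pos = as.integer(pos), ref = ref, alt = alt, total_depth = depth,
      alt_depth = alt_d, variant_class = cls, consequence = csq,
      gene = gene_span$gene[gene_idx], context3 = ctx3,
      in_polymorphism_db = FALSE, in_cosmic = cosmic,
      cosmic_confirmed_somatic = cosmic & runif(n) < 0.6,
      in_clinvar = FALSE, damaging = assign_damaging(csq)
    )
    list(variants = x,
         truth = tibble(sample_id = sample_id, chrom = x$chrom, pos = x$pos,
                        ref = x$ref, alt = x$alt, label = label,
                        signature = signature,
                        in_polymorphism_db = FALSE,
                        pool_index = NA_integer_))
  }

  for (i in seq_len(config$n_tumors)) {
    sc <- somatic_one(tumor_ids[i], config$n_somatic_clonal,
                      0.5 * config$purity, "somatic_clonal", sig_w[i, ])
    if (!is.null(sc)) {
      # relocate planted mutation-plus-loss variants into their gene
      hits <- which(mutloss_samples == tumor_ids[i])
      for (h in seq_along(hits)) {
        g <- mutloss_genes[hits[h]]
        row <- gene_span[gene_span$gene == g, ]
        sc$variants$chrom[h] <- row$chrom
        sc$variants$pos[h] <- as.integer(row$start +
          floor((row$end - row$start) / 2)) + h
        sc$variants$gene[h] <- g
        if (!sc$variants$consequence[h] %in% NON_SILENT) {
          sc$variants$consequence[h] <- "missense"
        }
        sc$truth$chrom[h] <- sc$variants$chrom[h]
        sc$truth$pos[h] <- sc$variants$pos[h]
      }
      variants[[length(variants) + 1L]] <- sc$variants
      truth_rows[[length(truth_rows) + 1L]] <- sc$truth
    }
    if (i <= config$n_paired && config$n_somatic_subclonal > 0) {
      sub <- somatic_one(tumor_ids[i], config$n_somatic_subclonal,
                         0.5 * config$purity * config$subclonal_ccf,
                         "somatic_subclonal", sig_w[i, ])
      variants[[length(variants) + 1L]] <- sub$variants
      truth_rows[[length(truth_rows) + 1L]] <- sub$truth
    }
  }

  # ---- planted recurrent germline artifacts (unpaired tumors only) -------
  unpaired_ids <- if (config$n_tumors > config$n_paired) {
    tumor_ids[(config$n_paired + 1):config$n_tumors]
  } else character(0)
  if (config$n_recurrent_artifacts > 0 && length(unpaired_ids) >= 2) {
    for (a in seq_len(config$n_recurrent_artifacts)) {
      gi <- sample.int(config$n_genes, 1)
      pos_a <- as.integer(gene_span$start[gi] + 100L + a)
      alle <- labels_to_alleles(sample(rownames(profiles), 1))
      carriers <- sample(unpaired_ids, 2)
      for (s in carriers) {
        depth <- rdepth(1, config$mean_depth)
        x <- tibble(
          sample_id = s, chrom = gene_span$chrom[gi], pos = pos_a,
          ref = alle$ref, alt = alle$alt, total_depth = depth,
          alt_depth = pmin(depth, ralt(depth, 0.5)),
          variant_class = "snv", consequence = "missense",
          gene = gene_span$gene[gi], context3 = alle$context3,
          in_polymorphism_db = TRUE, in_cosmic = TRUE,
          cosmic_confirmed_somatic = FALSE, in_clinvar = FALSE,
          damaging = FALSE
        )
        variants[[length(variants) + 1L]] <- x
        truth_rows[[length(truth_rows) + 1L]] <- tibble(
          sample_id = s, chrom = x$chrom, pos = x$pos, ref = x$ref,
          alt = x$alt, label = "germline", signature = "flat",
          in_polymorphism_db = TRUE, pool_index = NA_integer_)
      }
    }
  }

  variants <- bind_rows(variants)
  truth_variants <- bind_rows(truth_rows)

  # ---- copy-number segments ----------------------------------------------
  seg_rows <- list()
  planted_seg <- bind_rows(
    tibble(sample_id = mutloss_samples, gene = mutloss_genes,
           copy_number = 1L),
    tibble(sample_id = homdel_samples, gene = homdel_genes,
           copy_number = 0L)
  ) %>% left_join(gene_span, by = "gene")
  planted_seg <- planted_seg %>%
    mutate(start = pmax(0L, as.integer(.data$start - 5000L)),
           end = as.integer(.data$end + 5000L))
  for (i in seq_len(config$n_tumors)) {
    sid <- tumor_ids[i]
    mine <- planted_seg %>% filter(.data$sample_id == sid)
    n_rand <- config$n_cna_segments
    rc <- sample(chroms, n_rand, replace = TRUE)
    rs <- sample.int(CHROM_LENGTH - 600000L, n_rand)
    rw <- sample(20000:500000, n_rand, replace = TRUE)
    cn <- sample(c(0L, 1L, 3L, 4L, 5L), n_rand, replace = TRUE,
                 prob = c(0.05, 0.45, 0.30, 0.15, 0.05))
    rand <- tibble(sample_id = sid, chrom = rc, start = as.integer(rs),
                   end = as.integer(rs + rw), copy_number = cn)
    # planted segments first; later rows overlapping earlier ones dropped
    all_seg <- bind_rows(
      mine %>% select("sample_id", "chrom", "start", "end", "copy_number"),
      rand)
    keep <- rep(TRUE, nrow(all_seg))
    for (j in seq_len(nrow(all_seg))) {
      if (!keep[j]) next
      prev <- which(keep[seq_len(j - 1)])
      if (length(prev) > 0) {
        ov <- all_seg$chrom[prev] == all_seg$chrom[j] &
          all_seg$start[prev] < all_seg$end[j] &
          all_seg$end[prev] > all_seg$start[j]
        if (any(ov)) keep[j] <- FALSE
      }
    }
    seg_rows[[i]] <- all_seg[keep, ]
  }
  segments <- bind_rows(seg_rows) %>%
    arrange(.data$sample_id, .data$chrom, .data$start)

  # ---- expression ---------------------------------------------------------
  expr <- simulate_expression(
    genes = gene_ids,
    cohort_meta = metadata %>% filter(.data$role == "tumor"),
    n_mm = config$n_expr_mm, n_pcl = config$n_expr_pcl,
    n_de = config$n_de_genes, de_effect = config$de_effect,
    n_group_genes = config$n_group_genes,
    group_effect = config$group_effect
  )

  truth <- list(
    variants = truth_variants,
    two_hits = two_hit_truth,
    de_genes = expr$de_truth,
    group_genes = expr$group_truth,
    signature_weights = sig_w,
    planted_segments = planted_seg
  )
  list(variants = variants, segments = segments, gene_models = gene_models,
       metadata = metadata, expression = expr$matrix,
       expression_meta = expr$meta, signature_profiles = profiles,
       truth = truth, config = config)
}

#' Simulate a log2 expression matrix with planted structure
#'
#' Builds a genes x samples matrix with Gaussian noise around a baseline
#' of 8, translocation-group mean shifts on a planted gene set, and a
#' disease-class (pPCL vs MM) effect on a planted set of differentially
#' expressed genes. Per-gene noise scales are heterogeneous (uniform on
#' 0.25-1.1 log2 units), so only part of the genes pass a 2-fold
#' variability cut, as on real arrays.
#'
#' @param genes Gene identifiers (rows).
#' @param cohort_meta Tumor metadata; these samples become the first
#'   leukemia-class columns, keeping their translocation groups.
#' @param n_mm,n_pcl Class sizes (pPCL count includes the cohort tumors).
#' @param n_de,de_effect Planted DE genes and log2 effect size.
#' @param n_group_genes,group_effect Genes carrying group structure and
#'   the scale of the per-group shifts.
#' @return List with `matrix`, `meta`, `de_truth`, `group_truth`.
#' @export
simulate_expression <- function(genes, cohort_meta = NULL, n_mm = 55,
                                n_pcl = 21, n_de = 50, de_effect = 1.5,
                                n_group_genes = 60, group_effect = 1.5) {
  n_genes <- length(genes)
  group_levels <- c("t(14;16)", "t(11;14)", "t(4;14)", "t(14;20)", "none")
  n_cohort <- if (is.null(cohort_meta)) 0L else nrow(cohort_meta)
  if (n_cohort > n_pcl) stop("n_pcl smaller than cohort size")
  pcl_ids <- c(if (n_cohort > 0) cohort_meta$sample_id,
               sprintf("EXP-P%02d", seq_len(n_pcl - n_cohort)))
  mm_ids <- sprintf("EXP-M%02d", seq_len(n_mm))
  pcl_groups <- c(if (n_cohort > 0) cohort_meta$translocation_group,
                  sample(group_levels, n_pcl - n_cohort, replace = TRUE))
  mm_groups <- sample(group_levels, n_mm, replace = TRUE,
                      prob = c(0.15, 0.3, 0.2, 0.05, 0.3))
  meta <- tibble(
    sample_id = c(pcl_ids, mm_ids),
    disease = rep(c("pPCL", "MM"), c(n_pcl, n_mm)),
    translocation_group = c(pcl_groups, mm_groups)
  )
  n_samples <- nrow(meta)
  gene_sd <- stats::runif(n_genes, 0.25, 1.1)
  m <- matrix(stats::rnorm(n_genes * n_samples, mean = 8, sd = gene_sd),
              nrow = n_genes, dimnames = list(genes, meta$sample_id))
  group_genes <- sample(genes, min(n_group_genes, n_genes))
  if (length(group_genes) > 0) {
    shift <- matrix(stats::rnorm(length(group_genes) * length(group_levels),
                                 sd = group_effect),
                    nrow = length(group_genes),
                    dimnames = list(group_genes, group_levels))
    for (g in group_levels) {
      cols <- which(meta$translocation_group == g)
      if (length(cols) > 0) {
        m[group_genes, cols] <- m[group_genes, cols] + shift[, g]
      }
    }
  }
  de_genes <- sample(setdiff(genes, character(0)), min(n_de, n_genes))
  de_dir <- sample(c(1, -1), length(de_genes), replace = TRUE,
                   prob = c(0.4, 0.6))
  pcl_cols <- which(meta$disease == "pPCL")
  m[de_genes, pcl_cols] <- m[de_genes, pcl_cols] + de_dir * de_effect
  list(
    matrix = m, meta = meta,
    de_truth = tibble(gene = de_genes,
                      direction = ifelse(de_dir > 0, "up", "down"),
                      effect = de_dir * de_effect),
    group_truth = tibble(gene = group_genes)
  )
}

#' Write a simulated cohort to disk in the package's external formats
#'
#' Emits `variants.tsv`, `segments.bed`, `genes.bed`, `metadata.tsv`,
#' `expression.tsv`, `expression_meta.tsv`, `signatures.tsv` and
#' `truth.tsv` under `dir`.
#'
#' @param sim Result of [simulate_cohort()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_variants(sim$variants, file.path(dir, "variants.tsv"), "tsv")
  write_segments(sim$segments, file.path(dir, "segments.bed"))
  write_gene_models(sim$gene_models, file.path(dir, "genes.bed"))
  write_metadata(sim$metadata, file.path(dir, "metadata.tsv"))
  write_expression(sim$expression, file.path(dir, "expression.tsv"))
  readr::write_tsv(sim$expression_meta, file.path(dir, "expression_meta.tsv"),
                   progress = FALSE)
  sig <- data.frame(context = rownames(sim$signature_profiles),
                    sim$signature_profiles, check.names = FALSE)
  utils::write.table(sig, file.path(dir, "signatures.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  readr::write_tsv(sim$truth$variants, file.path(dir, "truth.tsv"),
                   na = ".", progress = FALSE)
  invisible(dir)
}

#' Read a 96 x K signature matrix from TSV
#'
#' First column `context` with `"A[C>A]A"`-style labels, one column per
#' signature.
#'
#' @param path Signature TSV.
#' @return Numeric 96 x K matrix.
#' @export
read_signature_matrix <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(x[, -1, drop = FALSE])
  rownames(m) <- x[[1]]
  if (nrow(m) != 96) stop("signature matrix must have 96 rows")
  m[context96_labels(), , drop = FALSE]
}
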