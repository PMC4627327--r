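test_that("largest transcript wins, ties break lexicographically", {
  models <- tibble::tibble(
    gene = c("A", "A", "B", "C", "C"),
    transcript = c("A.T1", "A.T2", "B.T1", "C.T2", "C.T1"),
    chrom = "chr1",
    start = c(0L, 0L, 10L, 100L, 200L),
    end = c(900L, 1500L, 400L, 600L, 700L),
    strand = "+")
  top <- largest_transcript(models)
  expect_equal(top$transcript[top$gene == "A"], "A.T2")   # 1500 beats 900
  expect_equal(top$transcript[top$gene == "B"], "B.T1")   # single
  expect_equal(top$transcript[top$gene == "C"], "C.T1")   # tie at 500
})

test_that("gene CN assignment uses greatest overlap, any-zero homdel rule", {
  models <- tibble::tibble(
    gene = c("G1", "G2", "G3"), transcript = paste0(c("G1","G2","G3"), ".T1"),
    chrom = "chr1", start = c(1000L, 5000L, 9000L),
    end = c(2000L, 6000L, 9500L), strand = "+")
  segs <- tibble::tibble(
    sample_id = "S1", chrom = "chr1",
    start = c(900L, 1700L, 5500L), end = c(1700L, 2500L, 5800L),
    copy_number = c(1L, 2L, 0L))
  got <- assign_gene_cn(segs, models)
  g1 <- got[got$gene == "G1", ]
  expect_equal(g1$copy_number, 1L)       # 700 bp of CN=1 vs 300 bp of CN=2
  expect_true(g1$mixed_flag)
  expect_equal(g1$cn_class, "hemizygous_del")
  g2 <- got[got$gene == "G2", ]
  expect_equal(g2$cn_class, "homozygous_del")  # focal CN=0 inside the gene
  expect_equal(g2$copy_number, 0L)
  g3 <- got[got$gene == "G3", ]
  expect_equal(g3$copy_number, 2L)       # uncovered -> neutral baseline
  expect_equal(g3$cn_class, "neutral")
  expect_false(g3$mixed_flag)
})

test_that("CN classes shift with a per-sample baseline override", {
  models <- tibble::tibble(gene = "G1", transcript = "G1.T1",
                           chrom = "chr1", start = 0L, end = 100L,
                           strand = "+")
  segs <- tibble::tibble(sample_id = c("D", "T"), chrom = "chr1",
                         start = 0L, end = 200L, copy_number = 3L)
  got <- assign_gene_cn(segs, models,
                        baseline_overrides = tibble::tibble(
                          sample_id = "T", baseline = 4L))
  expect_equal(got$cn_class[got$sample_id == "D"], "gain")
  expect_equal(got$cn_class[got$sample_id == "T"], "hemizygous_del")
})

test_that("gene CN assignment matches a per-base oracle on random cohorts", {
  set.seed(91)
  for (rep in 1:10) {
    n_genes <- 12
    models <- tibble::tibble(
      gene = sprintf("G%02d", 1:n_genes),
      transcript = sprintf("G%02d.T1", 1:n_genes),
      chrom = sample(c("chrA", "chrB"), n_genes, replace = TRUE),
      start = sample.int(5000, n_genes),
      strand = "+") |>
      dplyr::mutate(end = start + sample(200:1500, n_genes, replace = TRUE))
    seg_start <- sort(sample.int(6000, 8))
    segs <- tibble::tibble(
      sample_id = "S", chrom = sample(c("chrA", "chrB"), 8, replace = TRUE),
      start = seg_start, end = seg_start + sample(100:1200, 8, replace = TRUE),
      copy_number = sample(c(0L, 1L, 2L, 3L, 5L), 8, replace = TRUE))
    # drop overlaps within a chromosome (keep first)
    keep <- rep(TRUE, nrow(segs))
    for (j in 2:nrow(segs)) {
      prev <- which(keep[1:(j - 1)])
      if (any(segs$chrom[prev] == segs$chrom[j] &
                segs$start[prev] < segs$end[j] &
                segs$end[prev] > segs$start[j])) keep[j] <- FALSE
    }
    segs <- segs[keep, ]
    got <- assign_gene_cn(segs, models)

    # brute-force oracle: per-base scan over each gene interval
    for (i in seq_len(n_genes)) {
      bases <- (models$start[i] + 1):models$end[i]   # 1-based base index
      cn_at <- rep(NA_integer_, length(bases))
      for (k in seq_len(nrow(segs))) {
        if (segs$chrom[k] != models$chrom[i]) next
        hit <- bases > segs$start[k] & bases <= segs$end[k]
        cn_at[hit] <- segs$copy_number[k]
      }
      row <- got[got$gene == models$gene[i], ]
      if (all(is.na(cn_at))) {
        expect_equal(row$copy_number, 2L)
      } else if (any(cn_at == 0L, na.rm = TRUE)) {
        expect_equal(row$cn_class, "homozygous_del")
      } else {
        tab <- table(cn_at)
        modes <- as.integer(names(tab)[tab == max(tab)])
        expect_true(row$copy_number %in% modes)   # ties: any argmax valid
      }
      expect_equal(row$mixed_flag,
                   length(unique(cn_at[!is.na(cn_at)])) > 1)
    }
    # invariance to segment row order
    got2 <- assign_gene_cn(segs[sample.int(nrow(segs)), ], models)
    expect_equal(dplyr::arrange(got, gene), dplyr::arrange(got2, gene))
  }
})

test_that("two-hit calls equal a brute-force join and respect mechanisms", {
  set.seed(101)
  for (rep in 1:20) {
    genes <- sprintf("G%02d", 1:15)
    samples <- sprintf("S%d", 1:4)
    gene_cn <- expand.grid(sample_id = samples, gene = genes,
                           stringsAsFactors = FALSE) |>
      tibble::as_tibble() |>
      dplyr::mutate(
        copy_number = sample(0:5, dplyr::n(), replace = TRUE),
        cn_class = dplyr::case_when(
          copy_number == 0 ~ "homozygous_del",
          copy_number == 1 ~ "hemizygous_del",
          copy_number == 2 ~ "neutral",
          copy_number <= 4 ~ "gain", TRUE ~ "amplification"),
        mixed_flag = FALSE)
    n_calls <- 40
    calls <- make_variant()[rep(1, n_calls), ] |>
      dplyr::mutate(
        sample_id = sample(samples, n_calls, replace = TRUE),
        gene = sample(c(genes, NA), n_calls, replace = TRUE),
        pos = sample.int(1e6, n_calls),
        consequence = sample(c("missense", "synonymous", "frameshift"),
                             n_calls, replace = TRUE))
    got <- call_two_hits(gene_cn, calls)

    oracle <- list()
    for (s in samples) for (g in genes) {
      row <- gene_cn[gene_cn$sample_id == s & gene_cn$gene == g, ]
      has_mut <- any(calls$sample_id == s & !is.na(calls$gene) &
                       calls$gene == g &
                       calls$consequence %in% c("missense", "nonsense",
                                                "frameshift",
                                                "inframe_indel",
                                                "splice_site"))
      if (row$cn_class == "homozygous_del") {
        oracle[[length(oracle) + 1]] <- paste(s, g, "homozygous_deletion")
      }
      if (row$cn_class == "hemizygous_del" && has_mut) {
        oracle[[length(oracle) + 1]] <- paste(s, g, "mutation_plus_loss")
      }
    }
    expect_setequal(paste(got$sample_id, got$gene, got$mechanism),
                    unlist(oracle))
  }
  # mutation on a neutral background is not a two-hit event
  gcn <- tibble::tibble(sample_id = "S", gene = "G1", copy_number = 2L,
                        cn_class = "neutral", mixed_flag = FALSE)
  expect_equal(nrow(call_two_hits(gcn, make_variant(gene = "G1"))), 0L)
})

test_that("multi-mutated genes without loss are reported separately", {
  gcn <- tibble::tibble(sample_id = "S1", gene = c("G1", "G2"),
                        copy_number = c(2L, 1L),
                        cn_class = c("neutral", "hemizygous_del"),
                        mixed_flag = FALSE)
  calls <- dplyr::bind_rows(
    make_variant(gene = "G1", pos = 1L), make_variant(gene = "G1", pos = 2L),
    make_variant(gene = "G2", pos = 3L), make_variant(gene = "G2", pos = 4L))
  mm <- multi_mutated_genes(gcn, calls)
  expect_equal(mm$gene, "G1")
  expect_equal(mm$n_variants, 2L)
})

test_that("burden summary adds variant and CNA counts", {
  calls <- random_variants(169, seed = 7) |> dplyr::mutate(sample_id = "S1")
  segs <- tibble::tibble(sample_id = "S1", chrom = "chr1",
                         start = seq(0L, 1300L, by = 100L),
                         end = seq(50L, 1350L, by = 100L),
                         copy_number = c(rep(1L, 12), 2L, 2L))
  b <- burden_summary(calls, segs)
  expect_equal(b$n_variants, 169L)
  expect_equal(b$n_cna, 12L)
  expect_equal(b$total, 181L)
  expect_equal(burden_summary(calls, segs[0, ])$n_cna, 0L)
})
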