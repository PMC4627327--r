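test_that("depth filter boundary is inclusive at the threshold", {
  x <- dplyr::bind_rows(
    make_variant(pos = 1L, total_depth = 9L, alt_depth = 4L),
    make_variant(pos = 2L, total_depth = 10L, alt_depth = 4L),
    make_variant(pos = 3L, total_depth = 11L, alt_depth = 4L))
  kept <- depth_filter(x, 10)
  expect_equal(kept$pos, c(2L, 3L))
  expect_equal(nrow(depth_filter(x, 1)), 3L)
  # survivors equal a brute-force scan on random input
  r <- random_variants(200, seed = 3)
  expect_equal(nrow(depth_filter(r, 25)), sum(r$total_depth >= 25))
})

test_that("non-silent selection keeps splice sites and drops silent calls", {
  x <- dplyr::bind_rows(lapply(seq_along(c(
    "missense", "nonsense", "synonymous", "frameshift", "inframe_indel",
    "splice_site", "noncoding")), function(i) {
      make_variant(pos = i, consequence = c(
        "missense", "nonsense", "synonymous", "frameshift",
        "inframe_indel", "splice_site", "noncoding")[i])
    }))
  kept <- select_non_silent(x)
  expect_setequal(kept$consequence,
                  c("missense", "nonsense", "frameshift", "inframe_indel",
                    "splice_site"))
  expect_equal(nrow(select_non_silent(x[0, ])), 0L)
})

test_that("polymorphism filter applies the COSMIC/ClinVar rescue rule", {
  rescued_cosmic <- make_variant(in_polymorphism_db = TRUE, in_cosmic = TRUE)
  rescued_clinvar <- make_variant(in_polymorphism_db = TRUE,
                                  in_clinvar = TRUE)
  dropped <- make_variant(in_polymorphism_db = TRUE)
  novel <- make_variant(in_polymorphism_db = FALSE)
  x <- dplyr::bind_rows(rescued_cosmic, rescued_clinvar, dropped, novel)
  kept <- polymorphism_filter(x)
  expect_equal(nrow(kept), 3L)
  expect_false(any(kept$in_polymorphism_db & !kept$in_cosmic &
                     !kept$in_clinvar))
})

test_that("control subtraction equals the set-difference oracle", {
  set.seed(8)
  tum <- random_variants(300, seed = 71)
  ctl <- random_variants(300, seed = 72)
  # force some true overlaps
  shared <- tum[sample.int(nrow(tum), 80), ]
  shared$sample_id <- "N1"
  ctl <- dplyr::bind_rows(ctl, shared)
  got <- subtract_controls(tum, ctl, min_control_depth = 10)
  keyify <- function(x) paste(x$chrom, x$pos, x$ref, x$alt)
  veto <- keyify(ctl[ctl$total_depth >= 10, ])
  expect_equal(keyify(got), setdiff_keep <- keyify(tum)[!keyify(tum) %in% veto])
  # a shallow control call cannot veto
  deep_t <- make_variant(pos = 77L)
  shallow_c <- make_variant(sample_id = "N1", pos = 77L, total_depth = 9L,
                            alt_depth = 4L)
  expect_equal(nrow(subtract_controls(deep_t, shallow_c)), 1L)
  expect_error(subtract_controls(deep_t, deep_t[0, ]), "no controls")
})

test_that("sub-clonal labeling follows the exact binomial + CCF rule", {
  clonal <- make_variant(total_depth = 40L, alt_depth = 20L)
  sub <- make_variant(total_depth = 40L, alt_depth = 3L)
  out <- label_subclonal(dplyr::bind_rows(clonal, sub), purity = 0.9)
  expect_equal(out$clonality, c("clonal", "subclonal"))
  # frozen oracle: direct summation of the binomial low tail
  expect_equal(pbinom(3, 40, 0.45), 2.45629649e-07, tolerance = 1e-6)
  expect_equal(out$ccf[2], 2 * (3 / 40) / 0.9, tolerance = 1e-12)
  # low VAF but high CCF (shallow depth) stays clonal: both conditions needed
  deep <- label_subclonal(
    make_variant(total_depth = 2000L, alt_depth = 820L), purity = 0.9)
  expect_equal(deep$clonality, "clonal")   # ccf = 0.91 >= 0.5
  expect_error(label_subclonal(clonal, purity = 0), "purity")
})

test_that("funnel counts are monotone and conserve removed + surviving", {
  sim <- small_sim(seed = 3)
  tum <- dplyr::filter(sim$variants, sample_id == "SIM-T01")
  ctl <- dplyr::filter(sim$variants, sample_id == "SIM-N01")
  res <- run_cascade(tum, ctl, mode = "paired", purity = 0.9)
  f <- res$funnel
  expect_true(all(diff(f$survivors) <= 0))
  expect_equal(f$survivors[-1] + f$removed[-1],
               f$survivors[-nrow(f)])
  expect_equal(nrow(res$calls), f$survivors[nrow(f)])
  # empty input gives an all-zero funnel and empty output
  empty <- run_cascade(tum[0, ], ctl, mode = "paired", purity = 0.9)
  expect_equal(nrow(empty$calls), 0L)
  expect_true(all(empty$funnel$survivors == 0L))
})

test_that("independent predicate stages commute; the final set is order-free", {
  r <- random_variants(400, seed = 19)
  a <- polymorphism_filter(select_non_silent(depth_filter(r, 10)))
  b <- depth_filter(polymorphism_filter(select_non_silent(r)), 10)
  c_ <- select_non_silent(depth_filter(polymorphism_filter(r), 10))
  key <- function(x) sort(truth_key(x))
  expect_equal(key(a), key(b))
  expect_equal(key(a), key(c_))
})

test_that("paired-mode output is contained in unpaired-mode output", {
  sim <- small_sim(seed = 23)
  meta <- sim$metadata
  paired <- meta[meta$role == "tumor" & !is.na(meta$matched_control_id), ]
  for (i in seq_len(nrow(paired))) {
    tum <- dplyr::filter(sim$variants, sample_id == paired$sample_id[i])
    matched <- dplyr::filter(sim$variants,
                             sample_id == paired$matched_control_id[i])
    others <- dplyr::filter(
      sim$variants,
      sample_id %in% setdiff(paired$matched_control_id,
                             paired$matched_control_id[i]))
    pr <- run_cascade(tum, matched, mode = "paired", purity = 0.9)
    up <- run_cascade(tum, others, mode = "unpaired")
    expect_true(all(truth_key(pr$calls) %in% truth_key(up$calls)))
  }
})

test_that("carry-over audit satisfies n_unpaired = n_paired + n_extra and
           matches the truth channel", {
  sim <- small_sim(seed = 29)
  aud <- carryover_audit(sim$variants, sim$metadata)
  expect_equal(aud$n_unpaired, aud$n_paired + aud$n_extra)

  # oracle: extras are exactly the cascade-surviving germline variants of
  # the sample that are db-absent (or rescued) and uncovered by the other
  # controls but present in the matched control
  meta <- sim$metadata
  paired <- meta[meta$role == "tumor" & !is.na(meta$matched_control_id), ]
  for (i in seq_len(nrow(paired))) {
    sid <- paired$sample_id[i]
    tum <- dplyr::filter(sim$variants, sample_id == sid)
    matched <- dplyr::filter(sim$variants,
                             sample_id == paired$matched_control_id[i])
    others <- dplyr::filter(
      sim$variants,
      sample_id %in% setdiff(paired$matched_control_id,
                             paired$matched_control_id[i]))
    up <- run_cascade(tum, others, mode = "unpaired")
    pr <- run_cascade(tum, matched, mode = "paired", purity = 0.9)
    extra_keys <- setdiff(truth_key(up$calls), truth_key(pr$calls))
    germ <- sim$truth$variants[sim$truth$variants$label == "germline" &
                                 sim$truth$variants$sample_id == sid, ]
    expect_true(all(extra_keys %in% truth_key(germ)))
    expect_equal(length(extra_keys),
                 aud$n_extra[aud$sample_id == sid])
  }

  # nothing to carry over when every germline site is database-present
  # and none is rescued by a cancer/clinical catalogue
  clean <- simulate_cohort(sim_config(
    n_tumors = 4, n_paired = 2, n_germline_per_sample = 200,
    n_somatic_clonal = 30, n_somatic_subclonal = 5, n_genes = 80,
    germline_db_rate = 1, germline_cosmic_rate = 0,
    germline_clinvar_rate = 0, n_recurrent_artifacts = 0, seed = 77))
  aud2 <- carryover_audit(clean$variants, clean$metadata)
  expect_true(all(aud2$n_extra == 0L))
})

test_that("recurrent unconfirmed variants in unpaired samples are flagged", {
  base <- make_variant(pos = 555L, in_polymorphism_db = TRUE,
                       in_cosmic = TRUE, cosmic_confirmed_somatic = FALSE)
  calls <- dplyr::bind_rows(
    dplyr::mutate(base, sample_id = "T1"),
    dplyr::mutate(base, sample_id = "T2"),
    dplyr::mutate(base, sample_id = "T3", pos = 777L),       # singleton
    dplyr::mutate(base, sample_id = "T4", pos = 888L,
                  cosmic_confirmed_somatic = TRUE),
    dplyr::mutate(base, sample_id = "T5", pos = 888L,
                  cosmic_confirmed_somatic = TRUE)
  ) |> dplyr::mutate(mode = "unpaired", germline_risk_flag = FALSE)
  out <- flag_unconfirmed_recurrent(calls)
  expect_true(all(out$germline_risk_flag[out$pos == 555]))
  expect_false(any(out$germline_risk_flag[out$pos == 777]))
  expect_false(any(out$germline_risk_flag[out$pos == 888]))
  # paired calls are never flagged
  paired <- dplyr::mutate(calls, mode = "paired")
  expect_false(any(flag_unconfirmed_recurrent(paired)$germline_risk_flag))
})
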