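test_that("variable-gene selection applies the fold threshold exactly", {
  m <- rbind(
    flat = rep(5, 10),
    near = c(rep(0, 9), 0.9),       # max deviation 0.81 < 1
    hit = c(rep(0, 9), 1.2)         # max deviation 1.08 >= 1
  )
  m["near", ] <- m["near", ] - mean(m["near", ])
  m["hit", ] <- m["hit", ] - mean(m["hit", ])
  colnames(m) <- paste0("s", 1:10)
  got <- select_variable_genes(m, fold = 2)
  expect_false("flat" %in% got)
  expect_false("near" %in% got)
  expect_true("hit" %in% got)
  expect_error(select_variable_genes(m, fold = 1), "exceed 1")

  set.seed(5)
  r <- matrix(rnorm(600), 60, 10,
              dimnames = list(sprintf("g%02d", 1:60), paste0("s", 1:10)))
  got <- select_variable_genes(r, fold = 2)
  oracle <- rownames(r)[apply(abs(r - rowMeans(r)), 1, max) >= 1]
  expect_equal(got, oracle)
})

test_that("clustering merges identical samples first and recovers groups", {
  set.seed(7)
  base <- matrix(rnorm(200), 20, 10)
  rownames(base) <- sprintf("g%02d", 1:20)
  colnames(base) <- paste0("s", 1:10)
  m <- base
  m[, "s2"] <- m[, "s1"]   # identical profiles
  hc <- hcluster(m, rownames(m), k = 3)
  d <- 1 - stats::cor(m[rownames(m), ])
  expect_equal(d["s1", "s2"], 0, tolerance = 1e-12)
  expect_equal(hc$hclust$height[1], 0, tolerance = 1e-12)
  expect_equal(hc$labels[["s1"]], hc$labels[["s2"]])

  # three planted groups recovered exactly
  centers <- matrix(rnorm(20 * 3, sd = 3), 20, 3)
  grp <- rep(1:3, each = 8)
  mm <- sapply(grp, function(g) centers[, g] + rnorm(20, sd = 0.5))
  rownames(mm) <- sprintf("g%02d", 1:20)
  colnames(mm) <- sprintf("x%02d", 1:24)
  hc3 <- hcluster(mm, rownames(mm), k = 3)
  expect_equal(length(unique(paste(hc3$labels, grp))), 3L)

  # invariant to gene order
  hc_perm <- hcluster(mm, sample(rownames(mm)), k = 3)
  expect_equal(hc_perm$labels, hc3$labels)

  mm[, 1] <- 5
  expect_error(hcluster(mm, rownames(mm), k = 3), "x01")
})

test_that("group association gives small p for pure groups, p = 1 at k = 1", {
  set.seed(11)
  labels <- stats::setNames(rep(1:3, each = 8), sprintf("x%02d", 1:24))
  groups <- stats::setNames(rep(c("A", "B", "C"), each = 8),
                            names(labels))
  ga <- group_association(labels, groups, B = 2000, seed = 2)
  expect_true(all(ga$p_value <= 1e-2))
  # single cluster: statistic = group size, p = 1
  one <- stats::setNames(rep(1L, 24), names(labels))
  ga1 <- group_association(one, groups, B = 200, seed = 2)
  expect_equal(ga1$statistic, ga1$n_group)
  expect_true(all(ga1$p_value == 1))
  # tiny group -> NA
  groups2 <- groups; groups2[1:23] <- "A"; groups2[24] <- "Z"
  ga2 <- group_association(labels, groups2, B = 100, seed = 1)
  expect_true(is.na(ga2$p_value[ga2$group == "Z"]))
})

test_that("BHI equals exhaustive pair enumeration and handles edge cases", {
  # class-pure clusters give BHI 1; a mixed pair contributes 0
  expect_equal(bhi(c(1, 1, 2, 2), c("a", "a", "b", "b")), 1)
  expect_equal(bhi(c(1, 1), c("a", "b")), 0)
  expect_equal(bhi(c(1, 1, 1, 2, 2), c("a", "a", "b", "c", "c")),
               mean(c(2 / 6, 1)))   # hand-computed
  expect_error(bhi(c(1, 2), c("a", "b")), "no cluster")

  set.seed(17)
  for (rep in 1:20) {
    n <- sample(10:50, 1)
    labels <- sample.int(5, n, replace = TRUE)
    classes <- sample(c(letters[1:4], NA), n, replace = TRUE)
    keep <- !is.na(classes)
    # brute-force over all ordered pairs
    contrib <- c()
    for (cl in unique(labels[keep])) {
      idx <- which(labels == cl & keep)
      if (length(idx) < 2) next
      same <- 0
      for (i in idx) for (j in idx) {
        if (i != j && classes[i] == classes[j]) same <- same + 1
      }
      contrib <- c(contrib, same / (length(idx) * (length(idx) - 1)))
    }
    if (length(contrib) == 0) {
      expect_error(bhi(labels, classes))
    } else {
      expect_equal(bhi(labels, classes), mean(contrib))
    }
  }
})

test_that("replication probability obeys add-one arithmetic and finds
           planted structure", {
  set.seed(23)
  # planted: a small focal set carries 5-group structure, the large
  # background is pure noise, so random draws rarely replicate
  n_genes <- 500; n_samples <- 40
  grp <- rep(LETTERS[1:5], each = 8)
  m <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples,
              dimnames = list(sprintf("g%03d", 1:n_genes),
                              sprintf("x%02d", 1:n_samples)))
  focal <- rownames(m)[1:12]
  shift <- matrix(rnorm(12 * 5, sd = 1.5), 12, 5)
  for (gi in 1:5) {
    m[focal, grp == LETTERS[gi]] <- m[focal, grp == LETTERS[gi]] +
      shift[, gi]
  }
  classes <- stats::setNames(grp, colnames(m))
  res <- replication_probability(m, rownames(m), focal, classes, k = 5,
                                 B = 999, seed = 3)
  expect_lte(res$p_value, 0.01)
  expect_equal(res$observed_bhi,
               bhi(hcluster(m, focal, 5)$labels, classes))

  # B = 1 can only give 0.5 or 1
  res1 <- replication_probability(m, rownames(m), focal, classes, k = 5,
                                  B = 1, seed = 5)
  expect_true(res1$p_value %in% c(0.5, 1))
  expect_error(replication_probability(m, focal, rownames(m), classes, 5),
               "smaller")
})

test_that("differential expression recovers planted genes and is symmetric", {
  set.seed(29)
  sim <- simulate_expression(sprintf("g%04d", 1:1500), n_mm = 55,
                             n_pcl = 21, n_de = 50, de_effect = 1.5,
                             n_group_genes = 0)
  a <- sim$meta$sample_id[sim$meta$disease == "pPCL"]
  b <- sim$meta$sample_id[sim$meta$disease == "MM"]
  deg <- differential_expression(sim$matrix, a, b, q_cut = 0.05)
  hits <- deg$gene[deg$significant]
  tp <- sum(hits %in% sim$de_truth$gene)
  expect_gte(tp / nrow(sim$de_truth), 0.9)                 # sensitivity
  expect_lte((length(hits) - tp) / max(1, length(hits)), 0.1)  # FDR
  # direction matches the planted effect sign
  m <- match(sim$de_truth$gene, deg$gene)
  called_up <- deg$direction[m] == "up"
  expect_true(all(called_up == (sim$de_truth$direction == "up")))

  # swapping classes flips direction, keeps p
  swap <- differential_expression(sim$matrix, b, a)
  expect_equal(swap$p, deg$p)
  expect_true(all(swap$direction != deg$direction |
                    abs(deg$mean_diff) < 1e-12))

  # null data yield ~no discoveries at q < 0.05
  null <- matrix(rnorm(1000 * 20), 1000, 20,
                 dimnames = list(sprintf("n%04d", 1:1000), paste0("s", 1:20)))
  dn <- differential_expression(null, paste0("s", 1:10), paste0("s", 11:20))
  expect_lte(sum(dn$significant), 5)

  # zero variance in both classes is flagged with p = 1
  cm <- rbind(null[1:5, ], const = rep(3, 20))
  dc <- differential_expression(cm, paste0("s", 1:10), paste0("s", 11:20))
  expect_true(dc$zero_variance[dc$gene == "const"])
  expect_equal(unname(dc$p[dc$gene == "const"]), 1)
  expect_error(differential_expression(null, paste0("s", 1:2),
                                       paste0("s", 3:20)), "at least 3")
})
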