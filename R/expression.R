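#' Select the most variably expressed genes
#'
#' Retains genes whose maximum absolute deviation from the gene's
#' cross-sample mean reaches `log2(fold)` — i.e. at least one sample at or
#' beyond a `fold`-change from the gene's average on the log2 scale.
#'
#' @param mat Log2 expression matrix, genes in rows.
#' @param fold Fold-change threshold (> 1), default 2.
#' @return Character vector of retained gene names.
#' @export
select_variable_genes <- function(mat, fold = 2) {
  if (fold <= 1) stop("fold must exceed 1")
  dev <- abs(mat - rowMeans(mat))
  rownames(mat)[apply(dev, 1, max) >= log2(fold)]
}

#' Hierarchical clustering of samples on a gene subset
#'
#' Distance is 1 - Pearson correlation between sample profiles restricted
#' to `genes`; linkage is average (UPGMA); the tree is cut into `k`
#' clusters. Merge order is deterministic (stats::hclust index-ordered
#' tie-break).
#'
#' @param mat Log2 expression matrix.
#' @param genes Gene subset to cluster on (must be rows of `mat`).
#' @param k Number of clusters, `2 <= k <= ncol(mat)`.
#' @return List of class `hclust_result`: `hclust` (merge order and
#'   heights), `labels` (named cluster assignment), `k`.
#' @export
hcluster <- function(mat, genes, k) {
  if (!all(genes %in% rownames(mat))) stop("genes absent from matrix")
  if (k < 1 || k > ncol(mat)) stop("k out of range")
  sub <- mat[genes, , drop = FALSE]
  sds <- apply(sub, 2, sd)
  if (any(sds == 0)) {
    stop("zero-variance sample profile: ",
         paste(colnames(sub)[sds == 0], collapse = ", "))
  }
  d <- stats::as.dist(1 - stats::cor(sub))
  hc <- stats::hclust(d, method = "average")
  labels <- stats::cutree(hc, k = k)
  structure(list(hclust = hc, labels = labels, k = k),
            class = "hclust_result")
}

#' @export
print.hclust_result <- function(x, ...) {
  cat("Hierarchical clustering of", length(x$labels), "samples into",
      x$k, "clusters\n")
  print(table(x$labels))
  invisible(x)
}

#' Cluster purity per annotated group
#'
#' For each group, the largest number of its samples falling into one
#' cluster, over the group size (the "14/14 in one cluster" reading).
#'
#' @param labels Named cluster assignment (from [hcluster()]).
#' @param groups Named group assignment (NA allowed).
#' @return Tibble with group, n_group, max_in_cluster, purity.
#' @export
cluster_purity <- function(labels, groups) {
  groups <- groups[names(labels)]
  gl <- sort(unique(groups[!is.na(groups)]))
  rows <- lapply(gl, function(g) {
    in_g <- names(labels)[!is.na(groups) & groups == g]
    counts <- table(labels[in_g])
    tibble(group = g, n_group = length(in_g),
           max_in_cluster = if (length(counts)) max(counts) else 0L,
           purity = if (length(in_g)) max(counts) / length(in_g) else NA_real_)
  })
  bind_rows(rows)
}

#' Permutation test of cluster-group association
#'
#' Statistic per group: the maximum, over clusters, of the number of that
#' group's samples in one cluster. The null permutes the cluster labels
#' over samples B times; p is the add-one permutation p-value
#' `(1 + #{perm >= obs}) / (B + 1)`. Groups with fewer than 2 samples get
#' NA.
#'
#' @param labels Named cluster assignment.
#' @param groups Named group assignment (NA allowed).
#' @param B Number of permutations (default 10000).
#' @param seed Integer seed.
#' @return Tibble with group, n_group, statistic, p_value.
#' @export
group_association <- function(labels, groups, B = 10000, seed = 1L) {
  groups <- groups[names(labels)]
  gl <- sort(unique(groups[!is.na(groups)]))
  set.seed(seed)
  lab_int <- match(labels, sort(unique(labels)))
  k <- max(lab_int)
  n <- length(lab_int)
  perms <- vapply(seq_len(B), function(j) sample(lab_int), integer(n))
  offset <- k * (seq_len(B) - 1L)
  rows <- lapply(gl, function(g) {
    members <- which(!is.na(groups) & groups == g)
    obs <- max(tabulate(lab_int[members], nbins = k))
    if (length(members) < 2) {
      return(tibble(group = g, n_group = length(members),
                    statistic = obs, p_value = NA_real_))
    }
    # per-permutation cluster counts of the group members, laid out as a
    # k x B count vector so the max per permutation is one max.col pass
    cnt <- integer(k * B)
    for (i in members) {
      idx <- perms[i, ] + offset
      cnt[idx] <- cnt[idx] + 1L
    }
    Mk <- matrix(cnt, nrow = k)
    stat_perm <- Mk[cbind(max.col(t(Mk), ties.method = "first"),
                          seq_len(B))]
    tibble(group = g, n_group = length(members), statistic = obs,
           p_value = (1 + sum(stat_perm >= obs)) / (B + 1))
  })
  bind_rows(rows)
}

#' Biological homogeneity index (BHI)
#'
#' Mean, over clusters with at least two annotated members, of the
#' fraction of ordered pairs of distinct annotated members sharing a
#' functional class: `BHI = (1/k) * sum_j sum_{x != y in j}
#' 1{class(x) = class(y)} / (n_j (n_j - 1))`.
#'
#' @param labels Cluster assignment (vector; names matched to classes).
#' @param classes Functional class per item (NA = unannotated).
#' @return BHI in \[0, 1\].
#' @export
bhi <- function(labels, classes) {
  if (!is.null(names(labels)) && !is.null(names(classes))) {
    classes <- classes[names(labels)]
  }
  stopifnot(length(labels) == length(classes))
  keep <- !is.na(classes)
  labels <- labels[keep]; classes <- classes[keep]
  contrib <- c()
  for (cl in unique(labels)) {
    cls <- classes[labels == cl]
    n_j <- length(cls)
    if (n_j < 2) next
    same <- sum(outer(cls, cls, "==")) - n_j   # ordered pairs, x != y
    contrib <- c(contrib, same / (n_j * (n_j - 1)))
  }
  if (length(contrib) == 0) stop("no cluster with >= 2 annotated members")
  mean(contrib)
}

#' Probability of replicating a clustering with random gene sets
#'
#' Observed statistic: the BHI of the sample clustering built on
#' `focal_genes`, with the samples' annotation classes (typically
#' translocation groups). For B random draws of `length(focal_genes)`
#' genes from `variable_genes`, the clustering and BHI are recomputed;
#' the add-one p-value `(1 + #{draw >= obs}) / (B + 1)` estimates how
#' special the focal set's clustering ability is.
#'
#' @param mat Log2 expression matrix.
#' @param variable_genes Background gene list (e.g. the most variable
#'   genes); must contain `focal_genes` and be at least as large.
#' @param focal_genes The gene set whose clustering ability is tested.
#' @param classes Named class per sample (e.g. translocation group).
#' @param k Number of clusters.
#' @param B Number of random draws (default 1000).
#' @param seed Integer seed.
#' @return List with `p_value`, `observed_bhi`, `null_bhi` (vector).
#' @export
replication_probability <- function(mat, variable_genes, focal_genes,
                                    classes, k, B = 1000, seed = 1L) {
  if (length(variable_genes) < length(focal_genes)) {
    stop("variable_genes smaller than focal_genes")
  }
  if (!all(focal_genes %in% variable_genes)) {
    stop("focal_genes must be a subset of variable_genes")
  }
  obs <- bhi(hcluster(mat, focal_genes, k)$labels, classes)
  set.seed(seed)
  null_bhi <- vapply(seq_len(B), function(i) {
    g <- sample(variable_genes, length(focal_genes))
    bhi(hcluster(mat, g, k)$labels, classes)
  }, numeric(1))
  list(p_value = (1 + sum(null_bhi >= obs)) / (B + 1),
       observed_bhi = obs, null_bhi = null_bhi)
}

#' Two-class differential expression (Welch t-test, BH FDR)
#'
#' Per-gene Welch t-test on log2 values between class A and class B;
#' BH-adjusted q-values; direction `up` means higher mean in class A.
#' Genes with zero variance in both classes get p = 1 and are flagged.
#'
#' @param mat Log2 expression matrix.
#' @param samples_a,samples_b Column names of the two classes (>= 3 each).
#' @param q_cut q-value threshold for the `significant` column.
#' @return Tibble with gene, mean_a, mean_b, mean_diff, t, df, p, q,
#'   direction, significant, zero_variance.
#' @export
differential_expression <- function(mat, samples_a, samples_b,
                                    q_cut = 0.05) {
  if (length(samples_a) < 3 || length(samples_b) < 3) {
    stop("both classes need at least 3 samples")
  }
  a <- mat[, samples_a, drop = FALSE]
  b <- mat[, samples_b, drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- apply(a, 1, var); vb <- apply(b, 1, var)
  se2 <- va / na + vb / nb
  tt <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(tt), df)
  zero_var <- va == 0 & vb == 0
  p[zero_var] <- 1
  tt[zero_var] <- 0
  q <- bh_adjust(p)
  tibble(
    gene = rownames(mat), mean_a = ma, mean_b = mb,
    mean_diff = ma - mb, t = tt, df = df, p = p, q = q,
    direction = if_else(ma >= mb, "up", "down"),
    significant = q < q_cut,
    zero_variance = zero_var
  )
}
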