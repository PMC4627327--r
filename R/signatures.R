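SUBSTITUTIONS <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
BASES <- c("A", "C", "G", "T")

#' Canonical 96-trinucleotide context labels
#'
#' Labels in the conventional order: the six pyrimidine-reference
#' substitutions alphabetically (C>A, C>G, C>T, T>A, T>C, T>G), and within
#' each substitution the 16 flanking-base combinations with the 5' base
#' cycling slowest, both flanks ordered A, C, G, T. Label style `"A[C>A]A"`.
#'
#' @return Character vector of length 96.
#' @export
context96_labels <- function() {
  out <- character(0)
  for (s in SUBSTITUTIONS) {
    for (p5 in BASES) {
      for (p3 in BASES) {
        out <- c(out, paste0(p5, "[", s, "]", p3))
      }
    }
  }
  out
}

#' Collapse a substitution to the pyrimidine reference strand
#'
#' Substitutions are conventionally reported with a pyrimidine (C or T)
#' reference base. Purine-reference calls are reverse-complemented — ref,
#' alt and the trinucleotide context — before classification.
#'
#' @param ref,alt Single reference and alternate bases (vectors allowed).
#' @param context3 3-mer reference context centered on `ref`.
#' @return Tibble with `substitution`, `five_prime`, `three_prime`, `label`.
#' @export
collapse_to_pyrimidine <- function(ref, alt, context3) {
  if (any(nchar(ref) != 1L | nchar(alt) != 1L)) {
    stop("ref and alt must be single bases")
  }
  if (any(ref == alt)) stop("ref and alt must differ")
  if (!all(c(ref, alt) %in% BASES)) stop("non-ACGT base")
  if (any(nchar(context3) != 3L)) stop("context3 must be a 3-mer")
  if (any(substr(context3, 2, 2) != ref)) {
    stop("context3 center base must equal ref")
  }
  flip <- ref %in% c("A", "G")
  ref2 <- ifelse(flip, chartr("ACGT", "TGCA", ref), ref)
  alt2 <- ifelse(flip, chartr("ACGT", "TGCA", alt), alt)
  ctx2 <- context3
  ctx2[flip] <- revcomp(context3[flip])
  tibble(
    substitution = paste0(ref2, ">", alt2),
    five_prime = substr(ctx2, 1, 1),
    three_prime = substr(ctx2, 3, 3),
    label = paste0(substr(ctx2, 1, 1), "[", ref2, ">", alt2, "]",
                   substr(ctx2, 3, 3))
  )
}

# invert a pyrimidine-strand label into concrete (ref, alt, context3),
# optionally presenting it on the purine strand
label_to_variant <- function(label, purine_strand = FALSE) {
  ref <- substr(label, 3, 3)
  alt <- substr(label, 5, 5)
  ctx <- paste0(substr(label, 1, 1), ref, substr(label, 7, 7))
  if (purine_strand) {
    list(ref = chartr("ACGT", "TGCA", ref),
         alt = chartr("ACGT", "TGCA", alt),
         context3 = revcomp(ctx))
  } else {
    list(ref = ref, alt = alt, context3 = ctx)
  }
}

#' Build a 96-context mutation spectrum for one sample
#'
#' Counts SNVs by pyrimidine-collapsed trinucleotide class. Indels are
#' ignored; SNVs without a resolvable context are tallied in
#' `n_no_context` and excluded from the 96-vector. The 6-class summary is
#' the column sum over contexts.
#'
#' @param calls Variant records (or somatic calls) of one sample.
#' @return List of class `mut_spectrum` with `sample_id`, `counts96`
#'   (named integer vector), `counts6`, `n_no_context`.
#' @export
build_spectrum <- function(calls) {
  sample_id <- if (nrow(calls) > 0) calls$sample_id[1] else NA_character_
  snv <- calls %>% filter(.data$variant_class == "snv")
  labels <- context96_labels()
  counts96 <- stats::setNames(integer(96), labels)
  n_no_context <- sum(is.na(snv$context3))
  snv <- snv %>% filter(!is.na(.data$context3))
  if (nrow(snv) > 0) {
    cls <- collapse_to_pyrimidine(snv$ref, snv$alt, snv$context3)
    tab <- table(factor(cls$label, levels = labels))
    counts96[] <- as.integer(tab)
  }
  counts6 <- vapply(SUBSTITUTIONS, function(s) {
    sum(counts96[grepl(paste0("\\[", s, "\\]"), labels)])
  }, integer(1))
  structure(
    list(sample_id = sample_id, counts96 = counts96, counts6 = counts6,
         n_no_context = n_no_context),
    class = "mut_spectrum"
  )
}

#' @export
print.mut_spectrum <- function(x, ...) {
  cat("Mutation spectrum for", x$sample_id, "\n")
  cat("  SNVs with context:", sum(x$counts96),
      " without context:", x$n_no_context, "\n")
  print(x$counts6)
  invisible(x)
}

#' Reference aging and APOBEC signature profiles
#'
#' Constructs a 96 x 2 signature matrix. The "aging" column concentrates
#' its mass (default 0.96) on the four NpCpG C>T contexts (spontaneous
#' deamination of 5-methylcytosine); the "apobec" column concentrates the
#' same mass on the eight TpCpN C>T and C>G contexts (APOBEC cytidine
#' deaminase activity). The remaining mass is uniform over the other
#' contexts. Columns sum to 1.
#'
#' @param concentration Fraction of each signature's mass on its
#'   characteristic contexts (default 0.96).
#' @return 96 x 2 matrix with rownames from [context96_labels()] and
#'   columns `aging`, `apobec`.
#' @export
make_signature_profiles <- function(concentration = 0.96) {
  stopifnot(concentration > 0, concentration <= 1)
  labels <- context96_labels()
  aging_ctx <- paste0(BASES, "[C>T]G")                       # NpCpG C>T
  apobec_ctx <- c(paste0("T[C>T]", BASES), paste0("T[C>G]", BASES))
  build_col <- function(core) {
    w <- rep((1 - concentration) / (96 - length(core)), 96)
    names(w) <- labels
    w[core] <- concentration / length(core)
    w
  }
  m <- cbind(aging = build_col(aging_ctx), apobec = build_col(apobec_ctx))
  rownames(m) <- labels
  m
}

#' Attribute a spectrum to signatures by non-negative least squares
#'
#' Normalizes the 96-count vector to proportions p and solves
#' min ||p - M e||_2 subject to e >= 0 (NNLS), then renormalizes the
#' exposures to sum to 1. A sample is attributed to a "distinct" signature
#' when its exposure reaches `distinct_threshold`, otherwise it is called
#' an admixture of the processes.
#'
#' @param spectrum A `mut_spectrum` (or bare named 96-count vector).
#' @param signature_matrix 96 x K matrix, columns summing to 1.
#' @param distinct_threshold Exposure above which a single signature is
#'   called distinct (default 0.7).
#' @return List with `sample_id`, `exposures` (named, sums to 1),
#'   `residual_norm`, `attribution`.
#' @export
decompose <- function(spectrum, signature_matrix, distinct_threshold = 0.7) {
  counts <- if (inherits(spectrum, "mut_spectrum")) spectrum$counts96
            else spectrum
  sample_id <- if (inherits(spectrum, "mut_spectrum")) spectrum$sample_id
               else NA_character_
  if (sum(counts) == 0) stop("empty spectrum")
  M <- as.matrix(signature_matrix)
  if (nrow(M) != 96) stop("signature matrix must have 96 rows")
  p <- counts / sum(counts)
  if (!is.null(rownames(M)) && !is.null(names(counts))) {
    M <- M[names(counts), , drop = FALSE]
  }
  if (ncol(M) == 1) {
    e <- sum(M[, 1] * p) / sum(M[, 1]^2)
    e <- max(0, e)
    fit <- M[, 1] * e
    exposures <- stats::setNames(1, colnames(M))
  } else {
    sol <- pracma::lsqnonneg(M, p)
    e <- sol$x
    fit <- as.vector(M %*% e)
    if (sum(e) == 0) stop("degenerate decomposition: all exposures zero")
    exposures <- stats::setNames(e / sum(e), colnames(M))
  }
  residual_norm <- sqrt(sum((p - fit)^2))
  attribution <- if (max(exposures) >= distinct_threshold) {
    paste0("distinct_", names(exposures)[which.max(exposures)])
  } else {
    "admixture"
  }
  list(sample_id = sample_id, exposures = exposures,
       residual_norm = residual_norm, attribution = attribution)
}

#' Per-sample signature report for a cohort
#'
#' One row per tumor sample with SNV count, transition fraction
#' ((C>T + T>C) / total), signature exposures and attribution, joined with
#' the sample's translocation group; a pooled cohort row (element-wise sum
#' of the per-sample spectra) is appended with sample_id `"COHORT"`.
#'
#' @param spectra List of `mut_spectrum`, one per tumor sample.
#' @param signature_matrix 96 x K signature matrix.
#' @param metadata Sample metadata tibble (for translocation groups).
#' @param distinct_threshold Passed to [decompose()].
#' @return Tibble, one row per sample plus the pooled cohort row.
#' @export
cohort_signature_report <- function(spectra, signature_matrix, metadata,
                                    distinct_threshold = 0.7) {
  pooled <- spectra[[1]]
  if (length(spectra) > 1) {
    for (sp in spectra[-1]) {
      pooled$counts96 <- pooled$counts96 + sp$counts96
      pooled$counts6 <- pooled$counts6 + sp$counts6
      pooled$n_no_context <- pooled$n_no_context + sp$n_no_context
    }
  }
  pooled$sample_id <- "COHORT"
  rows <- lapply(c(spectra, list(pooled)), function(sp) {
    n_snv <- sum(sp$counts96) + sp$n_no_context
    transition_fraction <- if (sum(sp$counts6) > 0) {
      (sp$counts6[["C>T"]] + sp$counts6[["T>C"]]) / sum(sp$counts6)
    } else NA_real_
    dec <- if (sum(sp$counts96) > 0) {
      decompose(sp, signature_matrix, distinct_threshold)
    } else {
      list(exposures = stats::setNames(rep(NA_real_, ncol(signature_matrix)),
                                       colnames(signature_matrix)),
           attribution = NA_character_, residual_norm = NA_real_)
    }
    out <- tibble(sample_id = sp$sample_id, n_snv = n_snv,
                  n_no_context = sp$n_no_context,
                  transition_fraction = transition_fraction,
                  residual_norm = dec$residual_norm,
                  attribution = dec$attribution)
    for (k in names(dec$exposures)) {
      out[[paste0("exposure_", k)]] <- unname(dec$exposures[k])
    }
    out
  })
  report <- bind_rows(rows)
  tg <- metadata %>%
    select("sample_id", "translocation_group")
  report %>% left_join(tg, by = "sample_id")
}

#' Plot a 96-context spectrum as a bar chart
#'
#' @param spectrum A `mut_spectrum`.
#' @return A ggplot object (requires ggplot2).
#' @export
plot_spectrum <- function(spectrum) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  labels <- context96_labels()
  df <- data.frame(
    label = factor(labels, levels = labels),
    substitution = rep(SUBSTITUTIONS, each = 16),
    count = as.integer(spectrum$counts96)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data$count,
                                   fill = .data$substitution)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Mutations",
                  title = spectrum$sample_id) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, size = 4))
}
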