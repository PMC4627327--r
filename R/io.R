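#' Read a variant table
#'
#' Reads per-sample variant calls from either the package's TSV dialect or
#' a VCF 4.x file. The TSV dialect has one row per sample-by-allele record
#' with the canonical columns (header order may be permuted); the VCF
#' dialect carries depths in FORMAT (`GT`, `DP`, `AD`), annotation flags in
#' INFO (`POLYDB`, `COSMIC`, `COSMIC_SOM`, `CLINVAR`, `DMG`) and values
#' (`GENE`, `CSQ`, `CTX`). Multi-allelic VCF sites are split into one record
#' per sample-by-alternate-allele; positions stay 1-based.
#'
#' @param path Path to the file.
#' @param dialect `"tsv"` or `"vcf"`.
#' @return A tibble of variant records (see [validate_variants()]).
#' @export
read_variants <- function(path, dialect = c("tsv", "vcf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "tsv") read_variants_tsv(path) else read_variants_vcf(path)
}

read_variants_tsv <- function(path) {
  x <- readr::read_tsv(
    path, na = ".", show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  missing_cols <- setdiff(VARIANT_COLUMNS, names(x))
  if (length(missing_cols) > 0) {
    stop("variant TSV is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  x <- x[, VARIANT_COLUMNS]
  to_int <- c("pos", "total_depth", "alt_depth")
  to_lgl <- c("in_polymorphism_db", "in_cosmic", "cosmic_confirmed_somatic",
              "in_clinvar", "damaging")
  for (cc in to_int) {
    v <- suppressWarnings(as.integer(x[[cc]]))
    bad <- which(is.na(v) & !is.na(x[[cc]]))
    if (length(bad) > 0) {
      stop("malformed integer in column '", cc, "' at line ", bad[1] + 1L)
    }
    if (anyNA(v)) {
      stop("missing depth/position field in column '", cc, "' at line ",
           which(is.na(v))[1] + 1L)
    }
    x[[cc]] <- v
  }
  for (cc in to_lgl) {
    v <- x[[cc]] %in% c("1", "TRUE", "true", "T")
    bad <- which(!x[[cc]] %in% c("0", "1", "TRUE", "FALSE", "true", "false",
                                 "T", "F"))
    if (length(bad) > 0) {
      stop("malformed logical in column '", cc, "' at line ", bad[1] + 1L)
    }
    x[[cc]] <- v
  }
  validate_variants(x)
  x
}

info_flag <- function(info, key) {
  grepl(paste0("(^|;)", key, "(=|;|$)"), info)
}

info_value <- function(info, key) {
  m <- regmatches(info, regexec(paste0("(^|;)", key, "=([^;]*)"), info))
  vapply(m, function(g) if (length(g) >= 3) g[3] else NA_character_, "")
}

read_variants_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  info <- vcf@fix[, "INFO"]
  gt <- vcf@gt
  sample_ids <- colnames(gt)[-1]
  if (length(sample_ids) == 0) stop("VCF carries no sample columns")
  out <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    fmt <- strsplit(gt[i, "FORMAT"], ":", fixed = TRUE)[[1]]
    i_dp <- match("DP", fmt); i_ad <- match("AD", fmt); i_gt <- match("GT", fmt)
    if (is.na(i_dp) || is.na(i_ad)) {
      stop("missing depth fields (DP/AD) in FORMAT at VCF record ", i)
    }
    genes <- info_value(info[i], "GENE")
    csqs <- strsplit(info_value(info[i], "CSQ"), ",", fixed = TRUE)[[1]]
    ctxs <- strsplit(info_value(info[i], "CTX"), ",", fixed = TRUE)[[1]]
    for (s in sample_ids) {
      cell <- gt[i, s]
      if (is.na(cell) || cell %in% c(".", "./.", ".|.")) next
      parts <- strsplit(cell, ":", fixed = TRUE)[[1]]
      gts <- parts[i_gt]
      if (gts %in% c(".", "./.", ".|.")) next
      dp <- suppressWarnings(as.integer(parts[i_dp]))
      ad <- suppressWarnings(as.integer(
        strsplit(parts[i_ad], ",", fixed = TRUE)[[1]]))
      if (is.na(dp) || anyNA(ad)) {
        stop("malformed depth fields for sample ", s, " at VCF record ", i)
      }
      for (k in seq_along(alts)) {
        ref <- fix[i, "REF"]; alt <- alts[k]
        csq <- if (length(csqs) >= k) csqs[k] else csqs[1]
        ctx <- if (length(ctxs) >= k) ctxs[k] else NA_character_
        if (!is.na(ctx) && ctx == ".") ctx <- NA_character_
        vc <- if (nchar(ref) == 1 && nchar(alt) == 1) "snv"
              else if (nchar(alt) > nchar(ref)) "insertion" else "deletion"
        out[[length(out) + 1L]] <- tibble(
          sample_id = s,
          chrom = fix[i, "CHROM"],
          pos = as.integer(fix[i, "POS"]),
          ref = ref, alt = alt,
          total_depth = dp,
          alt_depth = if (length(ad) >= k + 1) ad[k + 1] else 0L,
          variant_class = vc,
          consequence = csq,
          gene = if (is.na(genes) || genes == ".") NA_character_ else genes,
          context3 = ctx,
          in_polymorphism_db = info_flag(info[i], "POLYDB"),
          in_cosmic = info_flag(info[i], "COSMIC"),
          cosmic_confirmed_somatic = info_flag(info[i], "COSMIC_SOM"),
          in_clinvar = info_flag(info[i], "CLINVAR"),
          damaging = info_flag(info[i], "DMG")
        )
      }
    }
  }
  x <- if (length(out) == 0) empty_variants() else bind_rows(out)
  validate_variants(x)
  x
}

empty_variants <- function() {
  tibble(
    sample_id = character(), chrom = character(), pos = integer(),
    ref = character(), alt = character(), total_depth = integer(),
    alt_depth = integer(), variant_class = character(),
    consequence = character(), gene = character(), context3 = character(),
    in_polymorphism_db = logical(), in_cosmic = logical(),
    cosmic_confirmed_somatic = logical(), in_clinvar = logical(),
    damaging = logical()
  )
}

#' Write a variant table
#'
#' Serializes variant records so that `read_variants(write_variants(x))`
#' reproduces `x` field for field. Missing values (`gene`, `context3`) are
#' written as the token `"."`. The VCF dialect writes single-sample VCF 4.2
#' files (one line per record); cohort-level tables use the TSV dialect.
#'
#' @param variants Tibble of variant records.
#' @param path Output path.
#' @param dialect `"tsv"` or `"vcf"`.
#' @return `path`, invisibly.
#' @export
write_variants <- function(variants, path, dialect = c("tsv", "vcf")) {
  dialect <- match.arg(dialect)
  validate_variants(variants)
  if (dialect == "tsv") {
    x <- variants[, VARIANT_COLUMNS]
    lgl <- vapply(x, is.logical, TRUE)
    x[lgl] <- lapply(x[lgl], function(v) as.integer(v))
    readr::write_tsv(x, path, na = ".", progress = FALSE)
  } else {
    if (nrow(variants) > 0 && n_distinct(variants$sample_id) > 1) {
      stop("VCF dialect writes one sample per file; split by sample_id first")
    }
    write_variants_vcf(variants, path)
  }
  invisible(path)
}

write_variants_vcf <- function(variants, path) {
  sample_id <- if (nrow(variants) > 0) variants$sample_id[1] else "SAMPLE"
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=POLYDB,Number=0,Type=Flag,Description=\"In dbSNP/1000G/ESP polymorphism databases\">",
    "##INFO=<ID=COSMIC,Number=0,Type=Flag,Description=\"In COSMIC\">",
    "##INFO=<ID=COSMIC_SOM,Number=0,Type=Flag,Description=\"Confirmed somatic in COSMIC\">",
    "##INFO=<ID=CLINVAR,Number=0,Type=Flag,Description=\"In ClinVar\">",
    "##INFO=<ID=DMG,Number=0,Type=Flag,Description=\"Predicted damaging\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=CSQ,Number=A,Type=String,Description=\"Consequence per alternate allele\">",
    "##INFO=<ID=CTX,Number=A,Type=String,Description=\"Trinucleotide reference context per alternate allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_id, sep = "\t")
  )
  lines <- character(nrow(variants))
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    info <- c(
      if (v$in_polymorphism_db) "POLYDB",
      if (v$in_cosmic) "COSMIC",
      if (v$cosmic_confirmed_somatic) "COSMIC_SOM",
      if (v$in_clinvar) "CLINVAR",
      if (v$damaging) "DMG",
      if (!is.na(v$gene)) paste0("GENE=", v$gene),
      paste0("CSQ=", v$consequence),
      paste0("CTX=", if (is.na(v$context3)) "." else v$context3)
    )
    fmt <- paste("0/1",
                 v$total_depth,
                 paste(v$total_depth - v$alt_depth, v$alt_depth, sep = ","),
                 sep = ":")
    lines[i] <- paste(v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS",
                      paste(info, collapse = ";"), "GT:DP:AD", fmt,
                      sep = "\t")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, lines), con)
  invisible(path)
}

#' Read copy-number segments
#'
#' BED-like file, 0-based half-open, with columns chrom, start, end,
#' copy_number and a fifth sample column (or a single `sample_id` supplied
#' for plain BED4 files). Overlapping segments within one sample and
#' chromosome are rejected.
#'
#' @param path Path to the segment file (no header).
#' @param sample_id Sample id for BED4 files lacking a sample column.
#' @return Tibble with sample_id, chrom, start, end, copy_number.
#' @export
read_segments <- function(path, sample_id = NULL) {
  x <- utils::read.table(path, header = FALSE, sep = "\t",
                         stringsAsFactors = FALSE)
  if (ncol(x) == 4) {
    if (is.null(sample_id)) {
      stop("BED4 segment file needs an explicit sample_id")
    }
    x$V5 <- sample_id
  }
  if (ncol(x) < 5) stop("segment file needs >= 4 columns")
  seg <- tibble(
    sample_id = as.character(x$V5), chrom = as.character(x$V1),
    start = as.integer(x$V2), end = as.integer(x$V3),
    copy_number = as.integer(x$V4)
  )
  validate_segments(seg)
  seg
}

validate_segments <- function(seg) {
  if (any(seg$start >= seg$end)) stop("segment with start >= end")
  if (any(seg$copy_number < 0)) stop("negative copy number")
  bad <- seg %>%
    arrange(.data$sample_id, .data$chrom, .data$start) %>%
    group_by(.data$sample_id, .data$chrom) %>%
    filter(.data$start < dplyr::lag(.data$end, default = -1L)) %>%
    ungroup()
  if (nrow(bad) > 0) {
    stop("overlapping segments within one sample: ",
         paste(utils::head(paste0(bad$sample_id, " ", bad$chrom, ":",
                                  bad$start, "-", bad$end), 5),
               collapse = "; "))
  }
  invisible(seg)
}

#' Write copy-number segments (BED4 + sample column)
#' @param segments Segment tibble.
#' @param path Output path.
#' @export
write_segments <- function(segments, path) {
  utils::write.table(
    segments[, c("chrom", "start", "end", "copy_number", "sample_id")],
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene models (BED6, name = "gene|transcript")
#'
#' All transcripts are retained; selection of the largest transcript per
#' gene happens downstream in [largest_transcript()].
#'
#' @param path BED6 file, 0-based half-open.
#' @return Tibble with gene, transcript, chrom, start, end, strand.
#' @export
read_gene_models <- function(path) {
  x <- utils::read.table(path, header = FALSE, sep = "\t",
                         stringsAsFactors = FALSE)
  if (ncol(x) < 6) stop("gene model file must be BED6")
  nm <- strsplit(as.character(x$V4), "|", fixed = TRUE)
  gm <- tibble(
    gene = vapply(nm, `[`, "", 1),
    transcript = vapply(nm, function(p) if (length(p) > 1) p[2] else p[1], ""),
    chrom = as.character(x$V1),
    start = as.integer(x$V2), end = as.integer(x$V3),
    strand = as.character(x$V6)
  )
  if (any(gm$start >= gm$end)) stop("gene model with start >= end")
  gm
}

#' Write gene models to BED6
#' @param models Gene model tibble.
#' @param path Output path.
#' @export
write_gene_models <- function(models, path) {
  bed <- data.frame(models$chrom, models$start, models$end,
                    paste(models$gene, models$transcript, sep = "|"),
                    0L, models$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT-like file
#'
#' One set per line: name, source, then member genes, tab-separated.
#'
#' @param path GMT file.
#' @return List of lists with `name`, `source`, `genes`.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("GMT line with no genes: ", substr(ln, 1, 40))
    list(name = f[1], source = f[2], genes = unique(f[-(1:2)]))
  })
}

#' Write gene sets to a GMT-like file
#' @param sets List of gene sets as returned by [read_gene_sets()].
#' @param path Output path.
#' @export
write_gene_sets <- function(sets, path) {
  writeLines(vapply(sets, function(s) {
    paste(c(s$name, s$source, s$genes), collapse = "\t")
  }, ""), path)
  invisible(path)
}

#' Read a log2 expression matrix (TSV, genes x samples)
#'
#' First column holds gene identifiers; remaining columns one sample each.
#' Duplicate gene rows and missing values are rejected.
#'
#' @param path Expression TSV.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_expression <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                         stringsAsFactors = FALSE)
  genes <- as.character(x[[1]])
  if (anyDuplicated(genes)) {
    stop("duplicate gene row(s) in expression matrix: ",
         paste(unique(genes[duplicated(genes)])[1:3], collapse = ", "))
  }
  m <- as.matrix(x[, -1, drop = FALSE])
  rownames(m) <- genes
  if (anyNA(m)) stop("missing values in expression matrix")
  storage.mode(m) <- "double"
  m
}

#' Write an expression matrix to TSV
#' @param mat Numeric matrix, genes in rows.
#' @param path Output path.
#' @export
write_expression <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' TSV with columns sample_id, role (tumor/control), matched_control_id,
#' translocation_group, purity. Controls must not name a matched control;
#' purity defaults to 0.9 where missing.
#'
#' @param path Metadata TSV.
#' @return Tibble of sample metadata.
#' @export
read_metadata <- function(path) {
  x <- readr::read_tsv(path, na = ".", show_col_types = FALSE,
                       progress = FALSE,
                       col_types = readr::cols(.default = readr::col_character()))
  need <- c("sample_id", "role", "matched_control_id", "translocation_group",
            "purity")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    stop("metadata missing columns: ", paste(missing_cols, collapse = ", "))
  }
  x$purity <- as.numeric(x$purity)
  x$purity[is.na(x$purity)] <- 0.9
  if (any(x$purity < 0 | x$purity > 1)) stop("purity outside [0,1]")
  if (any(x$role == "control" & !is.na(x$matched_control_id))) {
    stop("control samples must not reference a matched control")
  }
  x[, c(need, setdiff(names(x), need))]
}

#' Write sample metadata
#' @param meta Metadata tibble.
#' @param path Output path.
#' @export
write_metadata <- function(meta, path) {
  readr::write_tsv(meta, path, na = ".", progress = FALSE)
  invisible(path)
}
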