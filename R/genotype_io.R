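# Reading/writing biallelic STR length calls and the call- and sample-level
# quality filters applied before somatic comparison.

call_columns <- c("sample_id", "locus_id", "allele_a", "allele_b", "depth")

#' Read biallelic STR calls from TSV
#'
#' Expected header: sample_id, locus_id, allele_a, allele_b, depth (depth may
#' be empty/NA for synthetic data). Allele lengths are repeat counts in
#' units. The allele pair is unordered; it is stored sorted ascending so
#' genotype identity does not depend on input order.
#'
#' @param path calls TSV path.
#' @return data.frame of calls, input order preserved.
#' @export
read_calls <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, colClasses = "character",
                           check.names = FALSE)
  missing_cols <- setdiff(call_columns[1:4], names(raw))
  if (length(missing_cols)) {
    stopf("calls file %s is missing column(s): %s", path,
          paste(missing_cols, collapse = ", "))
  }
  parse_int <- function(col) {
    x <- suppressWarnings(as.integer(raw[[col]]))
    bad <- which(is.na(x) & !is.na(raw[[col]]) & nzchar(raw[[col]]))
    if (length(bad)) {
      stopf("non-integer %s value '%s' at line %d of %s", col,
            raw[[col]][bad[1]], bad[1] + 1L, path)
    }
    x
  }
  depth <- if ("depth" %in% names(raw)) parse_int("depth") else NA_integer_
  calls <- data.frame(sample_id = raw$sample_id, locus_id = raw$locus_id,
                      allele_a = parse_int("allele_a"),
                      allele_b = parse_int("allele_b"),
                      depth = depth, stringsAsFactors = FALSE)
  sort_allele_pairs(calls)
}

sort_allele_pairs <- function(calls) {
  swap <- calls$allele_a > calls$allele_b
  if (any(swap, na.rm = TRUE)) {
    swap[is.na(swap)] <- FALSE
    tmp <- calls$allele_a[swap]
    calls$allele_a[swap] <- calls$allele_b[swap]
    calls$allele_b[swap] <- tmp
  }
  calls
}

#' Write calls TSV
#' @param calls calls data.frame.
#' @param path output path.
#' @export
write_calls <- function(calls, path) {
  utils::write.table(sort_allele_pairs(calls)[, call_columns], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read STR calls from a GangSTR-style VCF
#'
#' Minimal reader for VCFs carrying a per-sample repeat-copy-number field
#' (REPCN) with the two allele copy numbers. One call is emitted per called
#' sample x site; missing genotypes are skipped. The locus id is derived
#' from CHROM, POS (0-based start), INFO/END and the canonical form of
#' INFO/RU when present, matching panel locus ids.
#'
#' @param path VCF path.
#' @return calls data.frame (sample_id, locus_id, allele_a, allele_b, depth).
#' @export
read_gangstr_vcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  g <- VariantAnnotation::geno(vcf)
  if (!"REPCN" %in% names(g)) {
    stopf("VCF %s lacks the per-sample repeat copy number field REPCN", path)
  }
  repcn <- g$REPCN
  dp <- if ("DP" %in% names(g)) g$DP else NULL
  rr <- SummarizedExperiment::rowRanges(vcf)
  info <- VariantAnnotation::info(vcf)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos0 <- GenomicRanges::start(rr) - 1L
  end_bp <- if ("END" %in% names(info)) as.integer(info$END) else
    GenomicRanges::end(rr)
  motif <- if ("RU" %in% names(info)) {
    vapply(toupper(as.character(info$RU)), canonical_motif, character(1),
           USE.NAMES = FALSE)
  } else rep(NA_character_, length(rr))
  locus_id <- ifelse(is.na(motif),
                     sprintf("%s:%d-%d", chrom, pos0, end_bp),
                     make_locus_id(chrom, pos0, end_bp, motif))
  samples <- colnames(repcn)
  out <- list()
  for (s in samples) {
    if (length(dim(repcn)) == 3L) {
      # Number=2 header: sites x samples x alleles integer array
      a <- suppressWarnings(as.integer(repcn[, s, 1L]))
      b <- suppressWarnings(as.integer(repcn[, s, 2L]))
    } else {
      # Number=1/. string dialect: "12,14" per sample
      val <- repcn[, s]
      if (is.list(val)) {
        val <- vapply(val, function(v) {
          if (length(v) == 0L || all(is.na(v))) NA_character_ else
            paste(v, collapse = ",")
        }, character(1))
      }
      val <- as.character(val)
      val[!is.na(val) & (!nzchar(val) | val == ".")] <- NA_character_
      parts <- strsplit(val, ",", fixed = TRUE)
      a <- suppressWarnings(as.integer(vapply(parts, function(p)
        if (length(p) >= 1L) p[1L] else NA_character_, character(1))))
      b <- suppressWarnings(as.integer(vapply(parts, function(p)
        if (length(p) >= 2L) p[2L] else NA_character_, character(1))))
    }
    keep <- !is.na(a) & !is.na(b)
    if (!any(keep)) next
    depth <- if (!is.null(dp)) as.integer(dp[, s][keep]) else NA_integer_
    out[[s]] <- data.frame(sample_id = s, locus_id = locus_id[keep],
                           allele_a = a[keep], allele_b = b[keep],
                           depth = depth, stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(sample_id = character(0), locus_id = character(0),
               allele_a = integer(0), allele_b = integer(0),
               depth = integer(0), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  sort_allele_pairs(res)
}

#' Filter calls by read depth
#'
#' Keeps calls with depth in [min_depth, max_depth]. Calls without a depth
#' (NA) pass unchanged, so depth-free synthetic calls are unaffected.
#'
#' @param calls calls data.frame.
#' @param min_depth,max_depth inclusive depth bounds.
#' @return filtered calls.
#' @export
filter_call_depth <- function(calls, min_depth = 20L, max_depth = 1000L) {
  keep <- is.na(calls$depth) |
    (calls$depth >= min_depth & calls$depth <= max_depth)
  res <- calls[keep, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Discard samples with too few calls
#'
#' Samples with fewer than \code{min_calls} called loci are dropped.
#'
#' @param calls calls data.frame.
#' @param min_calls minimum number of called loci per sample.
#' @return character vector of surviving sample ids.
#' @export
filter_low_call_samples <- function(calls, min_calls = 10000L) {
  counts <- table(calls$sample_id)
  sort(names(counts)[counts >= min_calls])
}

#' Remove tumour calls overlapping copy-number events
#'
#' A tumour call is removed when its panel locus interval overlaps any CNV
#' segment of the same sample by at least one bp (half-open intervals, no
#' padding). Calls for samples without segments, and any non-tumour calls
#' passed in, are untouched.
#'
#' @param calls tumour calls data.frame.
#' @param panel panel data.frame giving locus intervals.
#' @param cnv_segments data.frame with chrom, start, end, sample_id
#'   (0-based half-open).
#' @return filtered calls.
#' @export
filter_cnv_overlap <- function(calls, panel, cnv_segments) {
  if (is.null(cnv_segments) || nrow(cnv_segments) == 0L) return(calls)
  loc <- panel[match(calls$locus_id, panel$locus_id), c("chrom", "start", "end")]
  keep <- rep(TRUE, nrow(calls))
  for (s in unique(cnv_segments$sample_id)) {
    seg <- cnv_segments[cnv_segments$sample_id == s, , drop = FALSE]
    in_sample <- which(calls$sample_id == s & !is.na(loc$start))
    if (!length(in_sample)) next
    q <- GenomicRanges::GRanges(loc$chrom[in_sample],
                                IRanges::IRanges(loc$start[in_sample] + 1L,
                                                 loc$end[in_sample]))
    subj <- GenomicRanges::GRanges(seg$chrom,
                                   IRanges::IRanges(seg$start + 1L, seg$end))
    keep[in_sample[IRanges::overlapsAny(q, subj, ignore.strand = TRUE)]] <- FALSE
  }
  res <- calls[keep, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Read cohort metadata TSV
#'
#' Columns: sample_id, patient_id, sample_type (primary_tumour /
#' blood_normal / solid_tissue_normal), msi_label (MSS/MSI, tumours only),
#' optional tumour_stage.
#'
#' @param path metadata TSV path.
#' @return metadata data.frame.
#' @export
read_metadata <- function(path) {
  md <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  required <- c("sample_id", "patient_id", "sample_type")
  missing_cols <- setdiff(required, names(md))
  if (length(missing_cols)) {
    stopf("metadata file %s is missing column(s): %s", path,
          paste(missing_cols, collapse = ", "))
  }
  if (!"msi_label" %in% names(md)) md$msi_label <- NA_character_
  if (!"tumour_stage" %in% names(md)) md$tumour_stage <- NA_integer_
  md
}

#' Read per-sample CNV segments from BED4
#' @param path BED4 path (chrom, start, end, sample_id).
#' @return data.frame with chrom, start, end, sample_id.
#' @export
read_cnv_bed <- function(path) {
  seg <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end", "sample_id"))
  seg$start <- as.integer(seg$start)
  seg$end <- as.integer(seg$end)
  seg
}

#' Read a gene-by-sample expression matrix (TPM) from TSV
#' @param path TSV with first column gene_id and one column per sample.
#' @return numeric matrix, genes in rows.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  m
}

#' Write a gene-by-sample expression matrix to TSV
#' @param mat numeric matrix, genes in rows.
#' @param path output path.
#' @export
write_expression_tsv <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
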