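# Shared fixtures built in code.

# Minimal gene-model GRanges: one + strand gene with CDS/UTR/exons on chr1
# at [10000, 20000) (0-based), one - strand gene on chr2.
fixture_gene_models <- function() {
  gr <- GenomicRanges::GRanges(
    seqnames = c("chr1", "chr1", "chr1", "chr1", "chr1",
                 "chr2", "chr2"),
    ranges = IRanges::IRanges(
      start = c(10001, 10001, 10001, 10501, 19001,
                50001, 50001),
      end = c(20000, 11000, 10500, 11000, 20000,
              60000, 60000)),
    strand = c("+", "+", "+", "+", "+", "-", "-"))
  gr$type <- c("gene", "exon", "five_prime_UTR", "CDS", "exon",
               "gene", "exon")
  gr$ID <- c("gene1", NA, NA, NA, NA, "gene2", NA)
  gr$gene_id <- c("gene1", NA, NA, NA, NA, "gene2", NA)
  gr
}

make_locus <- function(chrom, start, end, motif = "A", unit_size = 1L,
                       region = NA_character_) {
  data.frame(chrom = chrom, start = start, end = end,
             locus_id = sprintf("%s:%d-%d:%s", chrom, start, end, motif),
             motif = motif, unit_size = unit_size,
             ref_length = as.integer((end - start) / unit_size),
             region = region, stringsAsFactors = FALSE)
}

make_call <- function(sample_id, locus_id, a, b, depth = NA_integer_) {
  data.frame(sample_id = sample_id, locus_id = locus_id,
             allele_a = as.integer(pmin(a, b)),
             allele_b = as.integer(pmax(a, b)),
             depth = as.integer(depth), stringsAsFactors = FALSE)
}

# Panel of n_types mononucleotide repeat types (distinct reference lengths),
# loci_per_type loci each, with per-locus mutated fractions set by label.
mutability_fixture <- function(n_types, loci_per_type, patients_per_locus,
                               estr_frac = 0.5, p_mut_estr = 1,
                               p_mut_non = 0) {
  panel <- NULL; comparisons <- NULL; estr_ids <- character(0)
  for (t in seq_len(n_types)) {
    for (l in seq_len(loci_per_type)) {
      start <- t * 100000L + l * 200L
      len <- 9L + t
      locus <- make_locus("chr1", start, start + len, "A", 1L)
      locus$ref_length <- len
      panel <- rbind(panel, locus)
      is_estr <- l <= round(estr_frac * loci_per_type)
      if (is_estr) estr_ids <- c(estr_ids, locus$locus_id)
      p <- if (is_estr) p_mut_estr else p_mut_non
      comparisons <- rbind(comparisons, data.frame(
        patient_id = sprintf("P%03d", seq_len(patients_per_locus)),
        locus_id = locus$locus_id, healthy_mean = len,
        mutated = seq_len(patients_per_locus) <=
          round(p * patients_per_locus),
        msi_label = "MSI"))
    }
  }
  list(panel = panel, comparisons = comparisons, estr_ids = estr_ids)
}

# Small deterministic cohort reused across test files.
small_cohort <- function(seed = 11L, ...) {
  args <- utils::modifyList(
    list(n_patients_mss = 12L, n_patients_msi = 6L, n_loci = 150L,
         n_genes = 80L, n_estr = 10L, n_healthy_expression = 6L,
         cnv_segments_per_tumour = 1L, seed = seed),
    list(...))
  generate_cohort(do.call(simulation_config, args))
}
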