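# Panel annotation: detector, canonicalization, redundancy, proximity,
# gene regions, masking.

test_that("detector applies the per-unit-size minimum lengths", {
  # mononucleotide: nine units detectable, eight not
  expect_equal(nrow(detect_perfect_strs(strrep("A", 9))), 1L)
  expect_equal(nrow(detect_perfect_strs(strrep("A", 8))), 0L)
  one <- detect_perfect_strs(strrep("A", 9))
  expect_equal(one$unit_size, 1L)
  expect_equal(one$ref_length, 9L)
  # dinucleotide threshold of four units
  di <- detect_perfect_strs("ACACACAC")
  expect_equal(nrow(di), 1L)
  expect_equal(di$unit_size, 2L)
  expect_equal(di$ref_length, 4L)
  expect_equal(nrow(detect_perfect_strs("ACACAC")), 0L)
  # all six unit sizes at exactly threshold and one unit below
  motifs <- c("A", "AC", "ACG", "ACGT", "AACGT", "AACGTC")
  mins <- c(9, 4, 4, 3, 3, 3)
  for (u in 1:6) {
    at <- detect_perfect_strs(strrep(motifs[u], mins[u]))
    at <- at[at$unit_size == u, ]
    expect_equal(nrow(at), 1L)
    expect_equal(at$ref_length, mins[u])
    below <- detect_perfect_strs(strrep(motifs[u], mins[u] - 1L))
    expect_false(u %in% below$unit_size)
  }
})

test_that("runs are broken at N and partial units are trimmed", {
  # N splits a 13-mer poly-A into 4 + 8: both below threshold
  expect_equal(nrow(detect_perfect_strs("AAAANAAAAAAAA")), 0L)
  # trailing partial unit is not counted
  loc <- detect_perfect_strs("ACGACGACGACGAC")  # 4 units + "AC"
  expect_equal(loc$ref_length, 4L)
  expect_equal(loc$end - loc$start, 12L)
  expect_equal(nrow(detect_perfect_strs("")), 0L)
  expect_error(detect_perfect_strs("ACGTX"), "invalid character")
})

test_that("detector matches the brute-force extension oracle", {
  withr::with_seed(101, {
    for (i in 1:60) {
      s <- random_dna(400, n_repeats = 4L)
      expect_same_loci(detect_perfect_strs(s), oracle_detect_strs(s))
    }
  })
})

test_that("canonical_motif minimises over rotations and reverse complement", {
  expect_equal(canonical_motif("A"), "A")
  expect_equal(canonical_motif("TTC"), "AAG")
  expect_equal(canonical_motif("AT"), "AT")
  withr::with_seed(7, {
    for (i in 1:50) {
      m <- estrpipe:::random_primitive_motif(sample.int(6, 1))
      cm <- canonical_motif(m)
      expect_equal(canonical_motif(cm), cm)
      expect_equal(canonical_motif(estrpipe:::revcomp(m)), cm)
    }
  })
  expect_error(canonical_motif("ANA"), "non-ACGT")
})

test_that("redundancy resolution prefers smaller units, then longer spans", {
  a12 <- make_locus("chr1", 100, 112, "A", 1L)
  aa6 <- make_locus("chr1", 100, 112, "AA", 2L)
  expect_equal(resolve_redundancy(rbind(aa6, a12))$motif, "A")
  # disjoint loci are both kept
  two <- rbind(make_locus("chr1", 0, 12), make_locus("chr1", 500, 512))
  expect_equal(nrow(resolve_redundancy(two)), 2L)
  # equal unit size: longer span wins
  long <- make_locus("chr1", 100, 112, "AC", 2L)
  short <- make_locus("chr1", 104, 114, "AC", 2L)
  kept <- resolve_redundancy(rbind(short, long))
  expect_equal(kept$end - kept$start, 12L)
})

test_that("proximity filter removes both members of close pairs, inclusive", {
  pair_gap <- function(gap) {
    rbind(make_locus("chr1", 100, 110),
          make_locus("chr1", 110 + gap, 120 + gap))
  }
  expect_equal(nrow(proximity_filter(pair_gap(10))), 0L)
  expect_equal(nrow(proximity_filter(pair_gap(50))), 0L)
  expect_equal(nrow(proximity_filter(pair_gap(51))), 2L)
  expect_equal(nrow(proximity_filter(pair_gap(100))), 2L)
})

test_that("region annotation uses the stated priority and promoter window", {
  gm <- fixture_gene_models()
  # fully intronic (between exon1 end 11000 and exon2 start 19001, 1-based)
  intron <- make_locus("chr1", 12000, 12012)
  expect_equal(annotate_regions(intron, gm)$region, "intron")
  # 1 kb upstream of the + strand gene start
  prom <- make_locus("chr1", 9000, 9012)
  expect_equal(annotate_regions(prom, gm)$region, "promoter")
  # spanning the CDS/intron boundary: CDS wins
  cds <- make_locus("chr1", 10995, 11007)
  expect_equal(annotate_regions(cds, gm)$region, "CDS")
  utr <- make_locus("chr1", 10100, 10112)
  expect_equal(annotate_regions(utr, gm)$region, "UTR")
  # promoter window boundary sits exactly 5 kb upstream
  outside <- make_locus("chr1", 4988, 5000)
  expect_equal(nrow(annotate_regions(outside, gm)), 0L)
  inside <- make_locus("chr1", 4989, 5001)
  expect_equal(annotate_regions(inside, gm)$region, "promoter")
  # minus-strand promoter is downstream in reference coordinates
  prom2 <- make_locus("chr2", 60500, 60512)
  expect_equal(annotate_regions(prom2, gm)$region, "promoter")
  # intergenic loci are dropped
  far <- make_locus("chr1", 500000, 500012)
  expect_equal(nrow(annotate_regions(far, gm)), 0L)
})

test_that("malformed GFF records are reported with their line number", {
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               paste(c("chr1", "src", "gene", "1", "100", ".", "+", ".",
                       "ID=g1"), collapse = "\t"),
               "chr1\tbroken"), path)
  expect_error(annotate_regions(make_locus("chr1", 10, 22), path),
               "line 3")
})

test_that("masking removes overlapping and non-autosomal loci", {
  loci <- rbind(make_locus("chr1", 100, 112), make_locus("chr1", 300, 312),
                make_locus("chrX", 100, 112))
  mask <- data.frame(chrom = "chr1", start = 105, end = 200)
  kept <- apply_mask(loci, mask)
  expect_equal(kept$start, 300)
  # adjacent (half-open) intervals do not overlap
  adjacent <- data.frame(chrom = "chr1", start = 112, end = 200)
  expect_equal(nrow(apply_mask(loci[1, ], adjacent)), 1L)
  expect_equal(nrow(apply_mask(loci, NULL)), 2L)
})

test_that("panel construction is idempotent", {
  withr::with_seed(33, {
    s <- random_dna(2000, n_repeats = 8L)
  })
  once <- proximity_filter(resolve_redundancy(detect_perfect_strs(s)))
  twice <- proximity_filter(resolve_redundancy(once))
  expect_identical(once, twice)
})

test_that("panel BED round-trips", {
  cohort <- small_cohort()
  path <- withr::local_tempfile(fileext = ".bed")
  write_panel_bed(cohort$panel, path)
  expect_identical(read_panel_bed(path), cohort$panel)
})
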