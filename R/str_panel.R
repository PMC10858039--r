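# Panel annotation: exhaustive perfect short-tandem-repeat detection plus the
# redundancy, proximity, gene-region and mask filters that yield the
# genotyping panel.

#' Minimum detectable allele lengths per unit size
#'
#' Units (repeat counts), indexed by unit size 1..6 bp: mononucleotide runs
#' must span at least nine units, di- and trinucleotide repeats four, and
#' tetra- to hexanucleotide repeats three.
#'
#' @export
default_min_lengths <- c(9L, 4L, 4L, 3L, 3L, 3L)

#' Sequence names excluded from the panel by default
#' @export
default_non_autosomes <- c("chrX", "chrY", "chrM", "X", "Y", "MT", "M")

str_panel_columns <- c("chrom", "start", "end", "locus_id", "motif",
                       "unit_size", "ref_length", "region")

empty_panel <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
              locus_id = character(0), motif = character(0),
              unit_size = integer(0), ref_length = integer(0),
              region = character(0), stringsAsFactors = FALSE)
}

make_locus_id <- function(chrom, start, end, motif) {
  sprintf("%s:%d-%d:%s", chrom, start, end, motif)
}

is_primitive_motif <- function(motif) {
  u <- nchar(motif)
  if (u == 1L) return(TRUE)
  for (d in seq_len(u - 1L)) {
    if (u %% d == 0L &&
        strrep(substr(motif, 1L, d), u %/% d) == motif) {
      return(FALSE)
    }
  }
  TRUE
}

#' Canonical form of a repeat motif
#'
#' The canonical motif is the lexicographically smallest string among all
#' rotations of the motif and all rotations of its reverse complement, so a
#' locus gets the same identity regardless of strand or phase
#' (e.g. \code{"TTC"} and \code{"AAG"} name the same repeat).
#'
#' @param motif repeat unit, 1--6 bp over A/C/G/T.
#' @return canonical unit string.
#' @export
#' @examples
#' canonical_motif("TTC")  # "AAG"
canonical_motif <- function(motif) {
  if (length(motif) != 1L || !nzchar(motif)) {
    stopf("motif must be a single non-empty string")
  }
  if (grepl("[^ACGT]", motif)) {
    stopf("motif contains non-ACGT characters: %s", motif)
  }
  u <- nchar(motif)
  if (u > 6L) stopf("motif longer than 6 bp: %s", motif)
  rotations <- function(s) {
    n <- nchar(s)
    vapply(seq_len(n), function(i) {
      paste0(substr(s, i, n), substr(s, 1L, i - 1L))
    }, character(1))
  }
  min(c(rotations(motif), rotations(revcomp(motif))))
}

#' Detect maximal perfect short tandem repeats in a sequence
#'
#' Scans a nucleotide sequence exhaustively for maximal perfect tandem runs
#' of unit size 1--6 bp. A run is reported when its repeat count meets the
#' per-unit-size minimum (\code{min_lengths}, units). Runs containing N are
#' broken at the N. Reported loci span whole units only, anchored at the left
#' end of the maximal periodic region, and each region is reported once at
#' its primitive period (so a poly-AC run is never also reported with unit
#' "ACAC"). Coordinates are 0-based half-open.
#'
#' @param sequence nucleotide string over A/C/G/T/N (case-insensitive).
#' @param min_lengths integer vector of length 6: minimum repeat count, in
#'   units, for unit sizes 1..6.
#' @param chrom sequence name used for locus coordinates and ids.
#' @return data.frame of loci with columns chrom, start, end, locus_id,
#'   motif (canonical), unit_size, ref_length, region (NA until annotated).
#' @export
#' @examples
#' detect_perfect_strs("TTAAAAAAAAATT")   # one 9-unit poly-A locus
detect_perfect_strs <- function(sequence, min_lengths = default_min_lengths,
                                chrom = "seq") {
  stopifnot(length(min_lengths) == 6L, all(min_lengths >= 1))
  if (length(sequence) != 1L) stopf("sequence must be a single string")
  if (!nzchar(sequence)) return(empty_panel())
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  bad <- !chars %in% c("A", "C", "G", "T", "N")
  if (any(bad)) {
    stopf("sequence contains invalid character '%s' at position %d",
          chars[which(bad)[1]], which(bad)[1])
  }
  n <- length(chars)
  valid <- chars != "N"
  out <- vector("list", 6L)
  for (u in 1:6) {
    if (n < u * min_lengths[u]) next
    idx <- seq_len(n - u)
    m <- chars[idx] == chars[idx + u] & valid[idx] & valid[idx + u]
    r <- rle(m)
    run_end <- cumsum(r$lengths)
    run_start <- run_end - r$lengths + 1L
    keep <- r$values & (r$lengths + u) >= u * min_lengths[u]
    if (!any(keep)) next
    starts <- run_start[keep]
    region_len <- r$lengths[keep] + u
    units <- region_len %/% u
    ok <- units >= min_lengths[u]
    starts <- starts[ok]; units <- units[ok]
    if (!length(starts)) next
    motifs <- vapply(starts, function(i) {
      paste(chars[i:(i + u - 1L)], collapse = "")
    }, character(1))
    prim <- vapply(motifs, is_primitive_motif, logical(1))
    starts <- starts[prim]; units <- units[prim]; motifs <- motifs[prim]
    if (!length(starts)) next
    start0 <- starts - 1L
    end0 <- start0 + u * units
    canon <- vapply(motifs, canonical_motif, character(1))
    out[[u]] <- data.frame(
      chrom = chrom, start = start0, end = end0,
      locus_id = make_locus_id(chrom, start0, end0, canon),
      motif = canon, unit_size = u, ref_length = as.integer(units),
      region = NA_character_, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) return(empty_panel())
  res <- res[order(res$start, res$unit_size), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Resolve overlapping repeat annotations
#'
#' Among overlapping candidate loci, the representation with the smaller unit
#' size wins; ties go to the longer span, then to the smaller start. The
#' result contains no two overlapping loci.
#'
#' @param loci panel data.frame (one or more sequences).
#' @return non-redundant panel data.frame.
#' @export
resolve_redundancy <- function(loci) {
  if (nrow(loci) < 2L) return(loci)
  pieces <- lapply(split(loci, loci$chrom), function(df) {
    span <- df$end - df$start
    df <- df[order(df$unit_size, -span, df$start), , drop = FALSE]
    kept_start <- integer(0)
    kept_end <- integer(0)
    keep <- logical(nrow(df))
    for (i in seq_len(nrow(df))) {
      if (!any(df$start[i] < kept_end & df$end[i] > kept_start)) {
        keep[i] <- TRUE
        kept_start <- c(kept_start, df$start[i])
        kept_end <- c(kept_end, df$end[i])
      }
    }
    df[keep, , drop = FALSE]
  })
  res <- do.call(rbind, pieces)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Remove loci that lie close to another locus
#'
#' Both members of any pair of loci separated by at most \code{min_gap_bp}
#' are removed ("within 50 bp" is inclusive: a gap of exactly 50 bp still
#' removes the pair). The gap is next start minus previous end, per sequence,
#' on non-overlapping loci.
#'
#' @param loci non-redundant panel data.frame.
#' @param min_gap_bp proximity threshold in bp.
#' @return filtered panel data.frame.
#' @export
proximity_filter <- function(loci, min_gap_bp = 50L) {
  if (nrow(loci) < 2L) return(loci)
  pieces <- lapply(split(loci, loci$chrom), function(df) {
    df <- df[order(df$start), , drop = FALSE]
    if (nrow(df) < 2L) return(df)
    gap <- df$start[-1L] - df$end[-nrow(df)]
    close_pair <- gap <= min_gap_bp
    drop <- c(close_pair, FALSE) | c(FALSE, close_pair)
    df[!drop, , drop = FALSE]
  })
  res <- do.call(rbind, pieces)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Light structural check so a malformed GFF3 record is reported with its
# line number before rtracklayer parses the file.
validate_gff3_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln) || startsWith(ln, "#")) next
    if (length(strsplit(ln, "\t", fixed = TRUE)[[1]]) != 9L) {
      stopf("malformed GFF record at line %d of %s", i, path)
    }
  }
  invisible(TRUE)
}

as_gene_models <- function(gene_models) {
  if (is.character(gene_models)) {
    validate_gff3_lines(gene_models)
    gene_models <- rtracklayer::import(gene_models, format = "gff3")
  }
  if (!methods::is(gene_models, "GRanges")) {
    stopf("gene_models must be a GFF3 path or a GRanges with a 'type' column")
  }
  gene_models
}

panel_granges <- function(loci) {
  GenomicRanges::GRanges(loci$chrom,
                         IRanges::IRanges(start = loci$start + 1L,
                                          end = loci$end))
}

#' Assign gene-region labels to panel loci
#'
#' Labels each locus by the gene feature it overlaps, with priority
#' CDS > UTR > intron > promoter. The promoter is the strand-aware window of
#' \code{promoter_bp} upstream of the gene's 5' end. Any overlap with the
#' gene body that is not CDS or UTR counts as intronic. Loci overlapping no
#' gene-associated region are dropped: the panel covers gene-associated
#' sequence only.
#'
#' @param loci panel data.frame.
#' @param gene_models GFF3 path or GRanges with gene/exon/CDS/UTR features.
#' @param promoter_bp upstream promoter window in bp.
#' @return panel data.frame with the region column filled.
#' @export
annotate_regions <- function(loci, gene_models, promoter_bp = 5000L) {
  gm <- as_gene_models(gene_models)
  if (nrow(loci) == 0L) return(loci)
  types <- as.character(gm$type)
  genes <- gm[types == "gene"]
  cds <- gm[types == "CDS"]
  utr <- gm[types %in% c("UTR", "five_prime_UTR", "three_prime_UTR")]
  prom <- GenomicRanges::promoters(genes, upstream = promoter_bp,
                                   downstream = 0L)
  prom <- GenomicRanges::restrict(prom, start = 1L)
  gr <- panel_granges(loci)
  hits <- function(subject) {
    IRanges::overlapsAny(gr, subject, ignore.strand = TRUE)
  }
  region <- rep(NA_character_, nrow(loci))
  region[hits(prom)] <- "promoter"
  region[hits(genes)] <- "intron"
  region[hits(utr)] <- "UTR"
  region[hits(cds)] <- "CDS"
  loci$region <- region
  res <- loci[!is.na(region), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Remove masked and non-autosomal loci
#'
#' Drops loci overlapping any mask interval by at least one bp (e.g. a
#' segmental-duplication mask) and loci on non-autosomal sequences.
#'
#' @param loci panel data.frame.
#' @param mask BED path, GRanges, or data.frame with chrom/start/end
#'   (0-based half-open); NULL for no mask.
#' @param non_autosomes sequence names to exclude outright.
#' @return filtered panel data.frame.
#' @export
apply_mask <- function(loci, mask = NULL,
                       non_autosomes = default_non_autosomes) {
  keep <- !(loci$chrom %in% non_autosomes)
  if (!is.null(mask)) {
    if (is.character(mask)) {
      mask <- rtracklayer::import(mask, format = "bed")
    }
    if (is.data.frame(mask)) {
      mask <- GenomicRanges::GRanges(mask$chrom,
                                     IRanges::IRanges(start = mask$start + 1L,
                                                      end = mask$end))
    }
    if (length(mask) > 0L) {
      keep <- keep & !IRanges::overlapsAny(panel_granges(loci), mask,
                                           ignore.strand = TRUE)
    }
  }
  res <- loci[keep, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Build the genotyping panel from reference sequence and gene models
#'
#' Runs the full panel pipeline: exhaustive perfect-repeat detection per
#' sequence, redundancy resolution, proximity filtering, masking, and
#' gene-region annotation.
#'
#' @param fasta path to reference FASTA (or a named character vector of
#'   sequences).
#' @param gene_models GFF3 path or GRanges.
#' @param mask optional mask BED path / GRanges / data.frame.
#' @param min_lengths per-unit-size minimum repeat counts (units).
#' @param min_gap_bp proximity threshold in bp.
#' @param promoter_bp promoter window in bp.
#' @param non_autosomes sequence names excluded from the panel.
#' @return annotated panel data.frame.
#' @export
build_str_panel <- function(fasta, gene_models, mask = NULL,
                            min_lengths = default_min_lengths,
                            min_gap_bp = 50L, promoter_bp = 5000L,
                            non_autosomes = default_non_autosomes) {
  if (is.character(fasta) && length(fasta) == 1L && file.exists(fasta)) {
    seqs <- Biostrings::readDNAStringSet(fasta)
    seq_chars <- as.character(seqs)
  } else {
    seq_chars <- fasta
  }
  if (is.null(names(seq_chars))) {
    names(seq_chars) <- paste0("seq", seq_along(seq_chars))
  }
  names(seq_chars) <- sub("\\s.*$", "", names(seq_chars))
  detected <- do.call(rbind, lapply(names(seq_chars), function(nm) {
    detect_perfect_strs(seq_chars[[nm]], min_lengths = min_lengths,
                        chrom = nm)
  }))
  if (is.null(detected)) detected <- empty_panel()
  panel <- resolve_redundancy(detected)
  panel <- proximity_filter(panel, min_gap_bp = min_gap_bp)
  panel <- apply_mask(panel, mask = mask, non_autosomes = non_autosomes)
  annotate_regions(panel, gene_models, promoter_bp = promoter_bp)
}

#' Write a panel to BED6+3
#'
#' Columns: chrom, start, end, locus_id, ref_length (score), strand ".",
#' motif, unit_size, region.
#'
#' @param panel panel data.frame.
#' @param path output path.
#' @export
write_panel_bed <- function(panel, path) {
  bed <- data.frame(panel$chrom, panel$start, panel$end, panel$locus_id,
                    panel$ref_length, ".", panel$motif, panel$unit_size,
                    panel$region, stringsAsFactors = FALSE)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a panel written by \code{write_panel_bed}
#' @param path BED6+3 path.
#' @return panel data.frame.
#' @export
read_panel_bed <- function(path) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end", "locus_id",
                                         "ref_length", "strand", "motif",
                                         "unit_size", "region"))
  data.frame(chrom = as.character(bed$chrom), start = as.integer(bed$start),
             end = as.integer(bed$end), locus_id = bed$locus_id,
             motif = bed$motif, unit_size = as.integer(bed$unit_size),
             ref_length = as.integer(bed$ref_length), region = bed$region,
             stringsAsFactors = FALSE)
}
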