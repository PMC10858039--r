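# eSTR discovery: rank-based inverse-normal expression normalisation,
# per-locus genotype encoding, eligibility filters, per-pair ordinary
# least-squares models, BH FDR control, and the permuted-genotype control.

#' Drop unexpressed genes
#'
#' Removes genes whose median TPM across the discovery samples is zero.
#'
#' @param tpm gene-by-sample TPM matrix.
#' @return filtered matrix.
#' @export
filter_expressed_genes <- function(tpm) {
  if (nrow(tpm) == 0L) return(tpm)
  med <- apply(tpm, 1L, stats::median)
  tpm[med > 0, , drop = FALSE]
}

#' Rank-based inverse normal transform
#'
#' Maps values to standard-normal quantiles of their ranks:
#' score_i = qnorm((rank_i - 0.5)/n), with average ranks for ties. The
#' transform is order-preserving and invariant under strictly monotone
#' transformations of the input.
#'
#' @param values numeric vector, n >= 3.
#' @return numeric vector of normal scores.
#' @export
inverse_normal_transform <- function(values) {
  n <- length(values)
  if (n < 3L) stopf("inverse normal transform needs at least 3 values")
  stats::qnorm((rank(values, ties.method = "average") - 0.5) / n)
}

#' Normalise an expression matrix and keep reference quantiles
#'
#' Applies the inverse normal transform per gene and stores each gene's
#' sorted raw values as reference quantiles, so held-out samples can later
#' be mapped onto the same distribution (\code{normalize_to_reference}).
#'
#' @param tpm gene-by-sample TPM matrix (already expression-filtered).
#' @return list with \code{scores} (same shape as tpm) and \code{reference}
#'   (named list of sorted raw value vectors per gene).
#' @export
normalize_expression <- function(tpm) {
  scores <- t(apply(tpm, 1L, inverse_normal_transform))
  dimnames(scores) <- dimnames(tpm)
  reference <- lapply(seq_len(nrow(tpm)), function(i) sort(unname(tpm[i, ])))
  names(reference) <- rownames(tpm)
  list(scores = scores, reference = reference)
}

#' Mean allele length per call
#'
#' The genotype used in eSTR models: the average of the two allele lengths,
#' in repeat units.
#'
#' @param calls calls data.frame (or a vector pair via allele_a/allele_b).
#' @return numeric vector of mean genotypes.
#' @export
mean_genotype <- function(calls) {
  (calls$allele_a + calls$allele_b) / 2
}

#' Loci eligible for eSTR analysis
#'
#' A locus qualifies when it is called in at least \code{min_patients}
#' discovery samples and shows at least \code{min_distinct} distinct mean
#' genotypes.
#'
#' @param calls discovery tumour calls.
#' @param min_patients minimum number of samples with a call.
#' @param min_distinct minimum number of distinct mean genotypes.
#' @return character vector of eligible locus ids.
#' @export
eligible_loci <- function(calls, min_patients = 50L, min_distinct = 3L) {
  g <- mean_genotype(calls)
  by_locus <- split(data.frame(sample_id = calls$sample_id, g = g,
                               stringsAsFactors = FALSE), calls$locus_id)
  ok <- vapply(by_locus, function(df) {
    length(unique(df$sample_id)) >= min_patients &&
      length(unique(df$g)) >= min_distinct
  }, logical(1))
  sort(names(by_locus)[ok])
}

#' Pair panel loci with genes
#'
#' A pair is made for every gene whose body (optionally extended by the
#' strand-aware upstream promoter window) contains the locus; a locus inside
#' two overlapping genes yields two pairs.
#'
#' @param panel panel data.frame.
#' @param gene_models GFF3 path or GRanges with gene features carrying a
#'   gene_id (or ID) attribute.
#' @param promoter_bp upstream window in bp.
#' @param include_promoter include the promoter window in the gene extent.
#' @return data.frame with locus_id, gene_id.
#' @export
pair_str_gene <- function(panel, gene_models, promoter_bp = 5000L,
                          include_promoter = TRUE) {
  gm <- as_gene_models(gene_models)
  genes <- gm[as.character(gm$type) == "gene"]
  ids <- genes$gene_id %||% genes$ID
  if (is.null(ids)) stopf("gene features lack gene_id/ID attributes")
  extent <- if (include_promoter) {
    GenomicRanges::restrict(
      GenomicRanges::resize(genes,
                            GenomicRanges::width(genes) + promoter_bp,
                            fix = "end"),
      start = 1L)
  } else genes
  hits <- GenomicRanges::findOverlaps(panel_granges(panel), extent,
                                      ignore.strand = TRUE)
  res <- unique(data.frame(
    locus_id = panel$locus_id[S4Vectors::queryHits(hits)],
    gene_id = as.character(ids[S4Vectors::subjectHits(hits)]),
    stringsAsFactors = FALSE))
  rownames(res) <- NULL
  res
}

#' Fit one eSTR linear model
#'
#' Ordinary least squares of normalised expression on mean genotype, with a
#' two-sided t test (n - 2 df) of the slope against zero.
#'
#' @param x mean genotypes.
#' @param y normalised expression, same length.
#' @return one-row data.frame with beta, se_beta, t_stat, p_value,
#'   n_samples and a \code{flagged} column (TRUE with NA statistics when the
#'   genotype has zero variance and no model can be fitted).
#' @export
fit_estr_model <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3L || stats::var(x) == 0) {
    return(data.frame(beta = NA_real_, se_beta = NA_real_, t_stat = NA_real_,
                      p_value = NA_real_, n_samples = n, flagged = TRUE))
  }
  fit <- stats::lm(y ~ x)
  cf <- summary(fit)$coefficients
  data.frame(beta = cf["x", "Estimate"], se_beta = cf["x", "Std. Error"],
             t_stat = cf["x", "t value"], p_value = cf["x", "Pr(>|t|)"],
             n_samples = n, flagged = FALSE)
}

#' Benjamini-Hochberg FDR control
#'
#' Step-up BH adjustment; a pair is significant when its q-value is below
#' \code{alpha}.
#'
#' @param p_values vector of p-values in [0, 1].
#' @param alpha FDR level.
#' @return data.frame with q_value and is_significant.
#' @export
bh_fdr <- function(p_values, alpha = 0.05) {
  q <- stats::p.adjust(p_values, method = "BH")
  data.frame(q_value = q, is_significant = !is.na(q) & q < alpha)
}

# Assemble per-pair model inputs: for each (locus, gene) pair, the samples
# with both a call at the locus and an expression value for the gene.
assemble_pair_data <- function(calls, scores, pairs, loci = NULL,
                               min_samples = 3L) {
  calls$g <- mean_genotype(calls)
  by_locus <- split(calls[, c("sample_id", "g")], calls$locus_id)
  expr_samples <- colnames(scores)
  out <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    lid <- pairs$locus_id[i]; gid <- pairs$gene_id[i]
    if (!is.null(loci) && !(lid %in% loci)) next
    if (!gid %in% rownames(scores) || is.null(by_locus[[lid]])) next
    df <- by_locus[[lid]]
    df <- df[df$sample_id %in% expr_samples, , drop = FALSE]
    if (nrow(df) < min_samples) next
    out[[i]] <- list(locus_id = lid, gene_id = gid, x = df$g,
                     y = unname(scores[gid, df$sample_id]))
  }
  out[!vapply(out, is.null, logical(1))]
}

#' Discover eSTRs in a cohort
#'
#' Full discovery pass: filters unexpressed genes, inverse-normal transforms
#' expression, restricts to eligible loci, fits one linear model per
#' STR-gene pair (mean tumour genotype vs normalised tumour expression), and
#' controls the FDR across all pairs with Benjamini-Hochberg.
#'
#' @param tumour_calls discovery tumour calls.
#' @param tpm gene-by-sample TPM matrix for the discovery tumours.
#' @param pairs STR-gene pairs (from \code{pair_str_gene} or a generator).
#' @param min_patients minimum samples per eligible locus and per fitted pair.
#' @param min_distinct minimum distinct genotypes per eligible locus.
#' @param alpha FDR level.
#' @return list with \code{associations} (EstrAssociation rows),
#'   \code{normalized} (scores + reference quantiles), \code{eligible}
#'   (locus ids) and \code{estr_ids} (significant loci).
#' @export
discover_estrs <- function(tumour_calls, tpm, pairs, min_patients = 50L,
                           min_distinct = 3L, alpha = 0.05) {
  expressed <- filter_expressed_genes(tpm)
  norm <- normalize_expression(expressed)
  eligible <- eligible_loci(tumour_calls, min_patients = min_patients,
                            min_distinct = min_distinct)
  pair_data <- assemble_pair_data(tumour_calls, norm$scores, pairs,
                                  loci = eligible,
                                  min_samples = min_patients)
  fits <- lapply(pair_data, function(pd) {
    cbind(data.frame(locus_id = pd$locus_id, gene_id = pd$gene_id,
                     stringsAsFactors = FALSE),
          fit_estr_model(pd$x, pd$y))
  })
  associations <- if (length(fits)) do.call(rbind, fits) else
    data.frame(locus_id = character(0), gene_id = character(0),
               beta = numeric(0), se_beta = numeric(0), t_stat = numeric(0),
               p_value = numeric(0), n_samples = integer(0),
               flagged = logical(0))
  adj <- bh_fdr(associations$p_value, alpha = alpha)
  associations$q_value <- adj$q_value
  associations$is_significant <- adj$is_significant
  rownames(associations) <- NULL
  list(associations = associations, normalized = norm, eligible = eligible,
       estr_ids = sort(unique(
         associations$locus_id[associations$is_significant])),
       pair_data = pair_data)
}

#' Permuted-genotype negative control
#'
#' Re-runs every fitted STR-gene model after permuting the genotype vector
#' across samples once per pair, returning the permuted p-values for Q-Q
#' comparison against the uniform null.
#'
#' @param discovery result of \code{discover_estrs} (its \code{pair_data}).
#' @param seed integer seed for the permutation stream.
#' @return numeric vector of permuted p-values, one per tested pair.
#' @export
permutation_control <- function(discovery, seed = 1L) {
  pair_data <- discovery$pair_data
  withr::with_seed(seed, {
    vapply(pair_data, function(pd) {
      fit_estr_model(sample(pd$x), pd$y)$p_value
    }, numeric(1))
  })
}

#' Flag associations whose gene is on a user-supplied list
#'
#' @param associations associations data.frame.
#' @param gene_list character vector (or path to a plain-text file, one gene
#'   id per line); duplicates are ignored.
#' @return associations with an \code{in_gene_list} flag.
#' @export
annotate_gene_list <- function(associations, gene_list) {
  if (length(gene_list) == 1L && !is.null(gene_list) &&
      file.exists(gene_list)) {
    gene_list <- readLines(gene_list, warn = FALSE)
  }
  gene_list <- unique(trimws(gene_list))
  gene_list <- gene_list[nzchar(gene_list)]
  associations$in_gene_list <- associations$gene_id %in% gene_list
  associations
}

#' Serialize reference quantiles to JSON
#' @param reference named list of sorted per-gene reference values.
#' @param path output JSON path.
#' @export
write_reference_quantiles <- function(reference, path) {
  jsonlite::write_json(reference, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' Read reference quantiles written by \code{write_reference_quantiles}
#' @param path JSON path.
#' @return named list of numeric vectors.
#' @export
read_reference_quantiles <- function(path) {
  lapply(jsonlite::read_json(path, simplifyVector = TRUE), as.numeric)
}
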