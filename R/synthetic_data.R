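# Synthetic cohort generator: matched healthy/tumour biallelic STR
# genotypes with length-dependent mutability and an MSI deletion bias, CNV
# segments, and expression with planted linear eSTR effects. Gives every
# downstream stage a fully specified, seeded test bed.

#' Construct a simulation configuration
#'
#' Defaults emulate the cohort structure the pipeline targets: 120 MSS and
#' 25 MSI patients with matched healthy/tumour samples, a per-allele MSS
#' mutation rate of 0.5\% that rises with allele length (about 1.4\% of loci
#' mutated per MSS patient), a tenfold MSI bias on the deletion rate only
#' (insertion rates equal between groups), a signed step-size distribution
#' favouring single-unit changes, and planted linear expression effects at
#' \code{n_estr} loci.
#'
#' @param n_patients_mss,n_patients_msi patient counts per MSI group.
#' @param n_loci panel size.
#' @param unit_size_distribution probabilities over unit sizes 1..6.
#' @param reference_length_range list of c(min, max) reference allele
#'   lengths (units) per unit size.
#' @param base_mutation_rate_per_locus per-allele mutation probability at
#'   the minimum reference length (MSS).
#' @param length_rate_slope per-unit multiplier: the rate grows by this
#'   fraction of the base rate per unit of allele length above the minimum.
#' @param msi_deletion_multiplier factor (>= 1) applied to the deletion rate
#'   of MSI alleles only.
#' @param step_size_distribution named probabilities over signed steps
#'   (units), e.g. "-1", "2".
#' @param n_estr number of loci with planted expression effects (each on a
#'   distinct gene).
#' @param beta_range planted |slope| range, normalised-expression units per
#'   repeat unit; signs are random.
#' @param noise_sd residual SD of latent expression.
#' @param n_genes number of genes.
#' @param n_silent_genes extra all-zero genes (exercise the expression
#'   filter).
#' @param population_allele_sd SD of the discretised normal population
#'   variation around the reference allele length.
#' @param dropout_rate fraction of heterozygous healthy loci emitted in the
#'   tumour as homozygous for an unseen allele (allele-dropout artifacts).
#' @param expression_transform "softplus" (default) or "identity" (clamped
#'   at zero) map from latent to TPM-like scale.
#' @param n_healthy_expression number of patients that also get healthy-
#'   sample expression (the validation subset).
#' @param cnv_segments_per_tumour CNV segments emitted per tumour sample.
#' @param seed integer master seed.
#' @return a \code{simulation_config} list.
#' @export
simulation_config <- function(n_patients_mss = 120L, n_patients_msi = 25L,
                              n_loci = 2000L,
                              unit_size_distribution =
                                c(0.45, 0.25, 0.12, 0.08, 0.06, 0.04),
                              reference_length_range =
                                list(c(9L, 20L), c(4L, 15L), c(4L, 10L),
                                     c(3L, 8L), c(3L, 6L), c(3L, 5L)),
                              base_mutation_rate_per_locus = 0.005,
                              length_rate_slope = 0.08,
                              msi_deletion_multiplier = 10,
                              step_size_distribution =
                                c("-5" = 0.025, "-4" = 0.04, "-3" = 0.06,
                                  "-2" = 0.10, "-1" = 0.275, "1" = 0.275,
                                  "2" = 0.10, "3" = 0.06, "4" = 0.04,
                                  "5" = 0.025),
                              n_estr = 100L, beta_range = c(0.5, 1.5),
                              noise_sd = 1, n_genes = 500L,
                              n_silent_genes = 5L,
                              population_allele_sd = 1.2,
                              dropout_rate = 0,
                              expression_transform = c("softplus", "identity"),
                              n_healthy_expression = 16L,
                              cnv_segments_per_tumour = 2L,
                              seed = 1L) {
  config <- list(
    n_patients_mss = n_patients_mss, n_patients_msi = n_patients_msi,
    n_loci = n_loci, unit_size_distribution = unit_size_distribution,
    reference_length_range = reference_length_range,
    base_mutation_rate_per_locus = base_mutation_rate_per_locus,
    length_rate_slope = length_rate_slope,
    msi_deletion_multiplier = msi_deletion_multiplier,
    step_size_distribution = step_size_distribution,
    n_estr = n_estr, beta_range = beta_range, noise_sd = noise_sd,
    n_genes = n_genes, n_silent_genes = n_silent_genes,
    population_allele_sd = population_allele_sd,
    dropout_rate = dropout_rate,
    expression_transform = match.arg(expression_transform),
    n_healthy_expression = n_healthy_expression,
    cnv_segments_per_tumour = cnv_segments_per_tumour,
    seed = seed)
  class(config) <- "simulation_config"
  validate_simulation_config(config)
  config
}

config_error <- function(field, why) {
  stopf("configuration error in field '%s': %s", field, why)
}

validate_simulation_config <- function(config) {
  chk_count <- function(field, min = 0L) {
    v <- config[[field]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < min ||
        v != floor(v)) {
      config_error(field, sprintf("must be an integer >= %d", min))
    }
  }
  chk_count("n_patients_mss"); chk_count("n_patients_msi")
  chk_count("n_loci", 1L); chk_count("n_genes", 1L)
  chk_count("n_estr"); chk_count("n_silent_genes")
  chk_count("n_healthy_expression"); chk_count("cnv_segments_per_tumour")
  chk_count("seed")
  chk_dist <- function(field, exact_len = NULL) {
    v <- config[[field]]
    if (any(v < 0 | v > 1)) config_error(field, "probabilities must be in [0, 1]")
    if (abs(sum(v) - 1) > 1e-9) config_error(field, "probabilities must sum to 1")
    if (!is.null(exact_len) && length(v) != exact_len) {
      config_error(field, sprintf("must have length %d", exact_len))
    }
  }
  chk_dist("unit_size_distribution", 6L)
  chk_dist("step_size_distribution")
  sd_names <- suppressWarnings(as.integer(names(config$step_size_distribution)))
  if (anyNA(sd_names) || any(sd_names == 0L)) {
    config_error("step_size_distribution",
                 "must be named by nonzero signed integer steps")
  }
  if (length(config$reference_length_range) != 6L ||
      any(vapply(config$reference_length_range,
                 function(r) length(r) != 2L || r[1] < 1 || r[2] < r[1],
                 logical(1)))) {
    config_error("reference_length_range",
                 "must list c(min, max) with 1 <= min <= max per unit size")
  }
  rate <- config$base_mutation_rate_per_locus
  if (!is.numeric(rate) || rate < 0 || rate > 1) {
    config_error("base_mutation_rate_per_locus", "must be a probability")
  }
  if (config$length_rate_slope < 0) {
    config_error("length_rate_slope", "must be >= 0")
  }
  if (!(config$msi_deletion_multiplier >= 1)) {
    config_error("msi_deletion_multiplier", "must be >= 1")
  }
  if (config$noise_sd < 0) config_error("noise_sd", "must be >= 0")
  if (config$population_allele_sd < 0) {
    config_error("population_allele_sd", "must be >= 0")
  }
  if (config$dropout_rate < 0 || config$dropout_rate > 1) {
    config_error("dropout_rate", "must be a probability")
  }
  if (config$n_estr > config$n_genes) {
    config_error("n_estr", "cannot exceed n_genes (one planted gene per eSTR)")
  }
  invisible(config)
}

# Vectorised mutation engine: one draw per allele, rate non-decreasing in
# allele length, MSI multiplier applied to the deletion rate only.
mutate_lengths <- function(lengths, unit_sizes, is_msi, config) {
  L0 <- vapply(config$reference_length_range, `[`, numeric(1), 1L)[unit_sizes]
  p <- pmin(1, config$base_mutation_rate_per_locus *
              (1 + config$length_rate_slope * pmax(0, lengths - L0)))
  sdist <- config$step_size_distribution
  steps <- as.integer(names(sdist))
  w_ins <- sum(sdist[steps > 0])
  w_del <- sum(sdist[steps < 0])
  wd <- if (w_del == 0) 0 else
    w_del * (if (is_msi) config$msi_deletion_multiplier else 1)
  total <- if (is.finite(wd)) pmin(1, p * (w_ins + wd)) else
    ifelse(p > 0, 1, 0)
  mutate <- stats::runif(length(lengths)) < total
  p_del <- if (!is.finite(wd)) 1 else if (w_ins + wd == 0) 0 else
    wd / (w_ins + wd)
  del <- mutate & (stats::runif(length(lengths)) < p_del)
  ins <- mutate & !del
  out <- lengths
  pos <- steps[steps > 0]; wpos <- sdist[steps > 0]
  neg <- steps[steps < 0]; wneg <- sdist[steps < 0]
  if (any(ins)) {
    out[ins] <- lengths[ins] +
      pos[sample.int(length(pos), sum(ins), replace = TRUE, prob = wpos)]
  }
  if (any(del)) {
    out[del] <- pmax(1L, lengths[del] +
      neg[sample.int(length(neg), sum(del), replace = TRUE, prob = wneg)])
  }
  out
}

#' Mutate one biallelic genotype
#'
#' Applies the generator's mutation model to a single allele pair: the
#' per-allele mutation probability grows with allele length, the MSI
#' deletion multiplier scales the deletion rate only, step magnitudes come
#' from the signed step-size distribution, and deletions never reduce an
#' allele below one unit. Uses the current RNG state.
#'
#' @param healthy integer pair of allele lengths (units, >= 1).
#' @param locus one panel row (needs unit_size).
#' @param patient_is_msi logical MSI status.
#' @param config simulation configuration.
#' @return integer pair of tumour allele lengths.
#' @export
mutate_alleles <- function(healthy, locus, patient_is_msi, config) {
  stopifnot(length(healthy) == 2L, all(healthy >= 1))
  mutate_lengths(as.integer(healthy), rep(locus$unit_size, 2L),
                 patient_is_msi, config)
}

random_primitive_motif <- function(unit_size) {
  bases <- c("A", "C", "G", "T")
  repeat {
    m <- paste(sample(bases, unit_size, replace = TRUE), collapse = "")
    if (is_primitive_motif(m)) return(m)
  }
}

# Panel, gene table, locus-gene assignment and planted effects; drawn from
# the cohort's panel stream.
build_cohort_frame <- function(config) {
  n_loci <- config$n_loci
  n_genes <- config$n_genes
  gene_ids <- sprintf("G%04d", seq_len(n_genes))
  gene_chrom <- paste0("chr", (seq_len(n_genes) - 1L) %% 22L + 1L)
  within <- stats::ave(seq_len(n_genes), gene_chrom, FUN = seq_along)
  gene_start <- 10000L + (within - 1L) * 30000L
  gene_end <- gene_start + 20000L
  genes <- data.frame(gene_id = gene_ids, chrom = gene_chrom,
                      start = gene_start, end = gene_end,
                      intercept = stats::rnorm(n_genes, 2, 1),
                      stringsAsFactors = FALSE)
  unit_size <- sample.int(6L, n_loci, replace = TRUE,
                          prob = config$unit_size_distribution)
  ref_length <- vapply(unit_size, function(u) {
    r <- config$reference_length_range[[u]]
    sample(seq.int(r[1], r[2]), 1L)
  }, numeric(1))
  motif <- vapply(unit_size, function(u) {
    canonical_motif(random_primitive_motif(u))
  }, character(1))
  gene_of <- sample.int(n_genes, n_loci, replace = TRUE)
  occ <- stats::ave(seq_len(n_loci), gene_of, FUN = seq_along)
  start <- genes$start[gene_of] + 400L + (occ - 1L) * 250L
  end <- as.integer(start + unit_size * ref_length)
  chrom <- genes$chrom[gene_of]
  region <- sample(c("intron", "promoter", "UTR", "CDS"), n_loci,
                   replace = TRUE, prob = c(0.7, 0.1, 0.1, 0.1))
  panel <- data.frame(chrom = chrom, start = start, end = end,
                      locus_id = make_locus_id(chrom, start, end, motif),
                      motif = motif, unit_size = as.integer(unit_size),
                      ref_length = as.integer(ref_length), region = region,
                      stringsAsFactors = FALSE)
  # planted eSTRs on distinct genes
  ord <- sample.int(n_loci)
  planted_idx <- integer(0); seen_genes <- integer(0)
  for (i in ord) {
    if (length(planted_idx) >= config$n_estr) break
    if (!(gene_of[i] %in% seen_genes)) {
      planted_idx <- c(planted_idx, i)
      seen_genes <- c(seen_genes, gene_of[i])
    }
  }
  betas <- stats::runif(length(planted_idx), config$beta_range[1],
                        config$beta_range[2]) *
    sample(c(-1, 1), length(planted_idx), replace = TRUE)
  names(betas) <- panel$locus_id[planted_idx]
  n_pat <- config$n_patients_mss + config$n_patients_msi
  patient_id <- sprintf("P%04d", seq_len(n_pat))
  msi <- rep(c("MSS", "MSI"),
             c(config$n_patients_mss, config$n_patients_msi))
  stage <- sample.int(4L, n_pat, replace = TRUE)
  validation_patients <- sort(sample(patient_id,
                                     min(config$n_healthy_expression, n_pat)))
  list(panel = panel, genes = genes, gene_of = gene_of,
       pairs = data.frame(locus_id = panel$locus_id,
                          gene_id = gene_ids[gene_of],
                          stringsAsFactors = FALSE),
       planted_betas = betas,
       patient_id = patient_id, msi = msi, stage = stage,
       validation_patients = validation_patients)
}

expression_transform_fn <- function(config) {
  switch(config$expression_transform,
         softplus = function(x) ifelse(x > 30, x, log1p(exp(x))),
         identity = function(x) pmax(x, 0))
}

#' Generate expression from genotypes with planted linear effects
#'
#' Latent expression of a gene carrying a planted eSTR is
#' intercept + beta x (mean allele length - reference length) + Gaussian
#' noise; genes without planted effects are genotype-independent. The latent
#' value is mapped to a nonnegative TPM-like scale by a fixed monotone
#' transform (softplus by default), which preserves the planted signs under
#' the rank-based normalisation used downstream.
#'
#' @param genotypes locus-by-sample matrix of mean allele lengths (rownames
#'   locus ids).
#' @param truth cohort truth (gene table, locus-gene map, planted betas,
#'   reference lengths).
#' @param config simulation configuration.
#' @param seed seed for the noise stream.
#' @return gene-by-sample nonnegative expression matrix.
#' @export
generate_expression <- function(genotypes, truth, config,
                                seed = config$seed) {
  genes <- truth$gene_table
  n_s <- ncol(genotypes)
  noise <- withr::with_seed(seed, {
    matrix(stats::rnorm(nrow(genes) * n_s, 0, config$noise_sd),
           nrow = nrow(genes))
  })
  latent <- genes$intercept + noise
  rownames(latent) <- genes$gene_id
  colnames(latent) <- colnames(genotypes)
  for (lid in names(truth$planted_betas)) {
    gid <- truth$locus_gene$gene_id[truth$locus_gene$locus_id == lid]
    if (!lid %in% rownames(genotypes)) {
      stopf("planted eSTR %s has no genotypes", lid)
    }
    latent[gid, ] <- latent[gid, ] + truth$planted_betas[[lid]] *
      (genotypes[lid, ] - truth$locus_ref[[lid]])
  }
  expression_transform_fn(config)(latent)
}

#' Generate a complete synthetic cohort
#'
#' Produces a panel, matched healthy/tumour biallelic calls for every
#' patient, tumour expression (plus healthy expression for the validation
#' subset), metadata, per-tumour CNV segments, STR-gene pairs, and the
#' ground truth (planted eSTRs and betas, realised somatic mutations,
#' planted dropout artifacts). Identical configurations give identical
#' outputs; per-patient RNG streams are derived from the master seed so
#' adding patients never reshuffles earlier ones.
#'
#' @param config simulation configuration from \code{simulation_config}.
#' @return list with panel, calls, expression, metadata, cnv, pairs, truth
#'   and config.
#' @export
generate_cohort <- function(config = simulation_config()) {
  validate_simulation_config(config)
  frame <- withr::with_seed(derive_seed(config$seed, 0L),
                            build_cohort_frame(config))
  panel <- frame$panel
  n_loci <- nrow(panel)
  n_pat <- length(frame$patient_id)
  calls_list <- vector("list", 2L * n_pat)
  cnv_list <- list()
  mut_list <- list()
  drop_list <- list()
  healthy_geno <- matrix(NA_real_, n_loci, n_pat)
  tumour_geno <- matrix(NA_real_, n_loci, n_pat)
  for (i in seq_len(n_pat)) {
    pid <- frame$patient_id[i]
    is_msi <- frame$msi[i] == "MSI"
    draw <- withr::with_seed(derive_seed(config$seed, i), {
      h1 <- pmax(1L, as.integer(panel$ref_length +
        round(stats::rnorm(n_loci, 0, config$population_allele_sd))))
      h2 <- pmax(1L, as.integer(panel$ref_length +
        round(stats::rnorm(n_loci, 0, config$population_allele_sd))))
      t1 <- mutate_lengths(h1, panel$unit_size, is_msi, config)
      t2 <- mutate_lengths(h2, panel$unit_size, is_msi, config)
      # a genuine mutation never yields a genotype homozygous for an allele
      # unseen in the healthy pair (that signature is reserved for planted
      # dropout artifacts): revert the second allele in that rare case
      artifact <- t1 == t2 & t1 != h1 & t1 != h2
      t2[artifact] <- h2[artifact]
      dropped <- rep(FALSE, n_loci)
      if (config$dropout_rate > 0) {
        het <- h1 != h2
        dropped <- het & stats::runif(n_loci) < config$dropout_rate
        unseen <- pmax(h1, h2) + 1L
        t1[dropped] <- unseen[dropped]
        t2[dropped] <- unseen[dropped]
      }
      gsel <- if (config$cnv_segments_per_tumour > 0) {
        sample.int(nrow(frame$genes),
                   min(config$cnv_segments_per_tumour, nrow(frame$genes)))
      } else integer(0)
      list(h1 = h1, h2 = h2, t1 = t1, t2 = t2, dropped = dropped,
           gsel = gsel)
    })
    h1 <- draw$h1; h2 <- draw$h2; t1 <- draw$t1; t2 <- draw$t2
    dropped <- draw$dropped
    if (length(draw$gsel)) {
      cnv_list[[length(cnv_list) + 1L]] <- data.frame(
        chrom = frame$genes$chrom[draw$gsel],
        start = frame$genes$start[draw$gsel],
        end = frame$genes$end[draw$gsel],
        sample_id = paste0(pid, "-T"), stringsAsFactors = FALSE)
    }
    # a mutation is a change of the genotype multiset, not of allele phase
    mutated <- (pmin(t1, t2) != pmin(h1, h2) |
                  pmax(t1, t2) != pmax(h1, h2)) & !dropped
    if (any(mutated)) {
      mut_list[[length(mut_list) + 1L]] <- data.frame(
        patient_id = pid, locus_id = panel$locus_id[mutated],
        healthy_a = pmin(h1, h2)[mutated], healthy_b = pmax(h1, h2)[mutated],
        tumour_a = pmin(t1, t2)[mutated], tumour_b = pmax(t1, t2)[mutated],
        stringsAsFactors = FALSE)
    }
    if (any(dropped)) {
      drop_list[[length(drop_list) + 1L]] <- data.frame(
        patient_id = pid, locus_id = panel$locus_id[dropped],
        stringsAsFactors = FALSE)
    }
    healthy_geno[, i] <- (h1 + h2) / 2
    tumour_geno[, i] <- (t1 + t2) / 2
    calls_list[[2L * i - 1L]] <- data.frame(
      sample_id = paste0(pid, "-N"), locus_id = panel$locus_id,
      allele_a = pmin(h1, h2), allele_b = pmax(h1, h2),
      depth = NA_integer_, stringsAsFactors = FALSE)
    calls_list[[2L * i]] <- data.frame(
      sample_id = paste0(pid, "-T"), locus_id = panel$locus_id,
      allele_a = pmin(t1, t2), allele_b = pmax(t1, t2),
      depth = NA_integer_, stringsAsFactors = FALSE)
  }
  calls <- do.call(rbind, calls_list)
  rownames(calls) <- NULL
  metadata <- rbind(
    data.frame(sample_id = paste0(frame$patient_id, "-N"),
               patient_id = frame$patient_id, sample_type = "blood_normal",
               msi_label = NA_character_, tumour_stage = NA_integer_,
               stringsAsFactors = FALSE),
    data.frame(sample_id = paste0(frame$patient_id, "-T"),
               patient_id = frame$patient_id,
               sample_type = "primary_tumour", msi_label = frame$msi,
               tumour_stage = frame$stage, stringsAsFactors = FALSE))
  metadata <- metadata[order(metadata$patient_id, metadata$sample_id), ]
  rownames(metadata) <- NULL
  locus_ref <- as.list(stats::setNames(panel$ref_length, panel$locus_id))
  truth <- list(
    planted_estr_ids = names(frame$planted_betas),
    planted_betas = as.list(frame$planted_betas),
    planted_mutations = if (length(mut_list)) do.call(rbind, mut_list) else
      NULL,
    planted_dropouts = if (length(drop_list)) do.call(rbind, drop_list) else
      NULL,
    locus_gene = frame$pairs, locus_ref = locus_ref,
    gene_table = frame$genes[, c("gene_id", "intercept")],
    validation_patients = frame$validation_patients)
  rownames(healthy_geno) <- panel$locus_id
  rownames(tumour_geno) <- panel$locus_id
  colnames(healthy_geno) <- paste0(frame$patient_id, "-N")
  colnames(tumour_geno) <- paste0(frame$patient_id, "-T")
  tumour_expr <- generate_expression(tumour_geno, truth, config,
                                     seed = derive_seed(config$seed, n_pat + 1L))
  val_idx <- frame$patient_id %in% frame$validation_patients
  expr <- tumour_expr
  if (any(val_idx)) {
    healthy_expr <- generate_expression(
      healthy_geno[, val_idx, drop = FALSE], truth, config,
      seed = derive_seed(config$seed, n_pat + 2L))
    expr <- cbind(tumour_expr, healthy_expr)
  }
  if (config$n_silent_genes > 0) {
    silent <- matrix(0, config$n_silent_genes, ncol(expr),
                     dimnames = list(sprintf("SILENT%02d",
                                             seq_len(config$n_silent_genes)),
                                     colnames(expr)))
    expr <- rbind(expr, silent)
  }
  cnv <- if (length(cnv_list)) do.call(rbind, cnv_list) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               sample_id = character(0), stringsAsFactors = FALSE)
  rownames(cnv) <- NULL
  list(panel = panel, calls = calls, expression = expr, metadata = metadata,
       cnv = cnv, pairs = frame$pairs, truth = truth, config = config)
}

#' Write a synthetic cohort to disk
#'
#' Emits the same file formats the real pipeline reads: panel BED6+3, calls
#' TSV, expression TSV, metadata TSV, CNV BED4, plus a truth JSON.
#'
#' @param cohort result of \code{generate_cohort}.
#' @param dir output directory (created if needed).
#' @return named vector of file paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(panel = file.path(dir, "panel.bed"),
             calls = file.path(dir, "calls.tsv"),
             expression = file.path(dir, "expression.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             cnv = file.path(dir, "cnv.bed"),
             pairs = file.path(dir, "pairs.tsv"),
             truth = file.path(dir, "truth.json"))
  write_panel_bed(cohort$panel, paths[["panel"]])
  write_calls(cohort$calls, paths[["calls"]])
  write_expression_tsv(cohort$expression, paths[["expression"]])
  utils::write.table(cohort$metadata, paths[["metadata"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$cnv, paths[["cnv"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(cohort$pairs, paths[["pairs"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- cohort$truth
  truth$gene_table <- NULL
  jsonlite::write_json(truth, paths[["truth"]], digits = NA,
                       auto_unbox = TRUE, dataframe = "columns", null = "null")
  invisible(paths)
}
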