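# Stage orchestration over a single declarative YAML config: each stage
# reads its inputs from disk, writes its outputs plus a manifest, and is
# seeded explicitly so reruns are reproducible.

#' Default pipeline configuration
#'
#' Thresholds default to the pipeline's standard operating values: panel
#' minimum lengths 9/4/4/3/3/3 units, 50 bp proximity, 5 kb promoter, call
#' depth bounds [20, 1000], 10,000-call sample floor, 50-patient / 3-
#' genotype eSTR eligibility, FDR alpha 0.05, 25-observation repeat-type
#' floor, 0.05 mutability difference, 10,000 permutations.
#'
#' @return nested configuration list.
#' @export
default_pipeline_config <- function() {
  list(
    output_dir = "estrpipe_output",
    paths = list(fasta = NULL, gene_models = NULL, mask = NULL,
                 panel = NULL, calls = NULL, expression = NULL,
                 metadata = NULL, cnv = NULL, pairs = NULL,
                 gene_list = NULL),
    thresholds = list(min_lengths = c(9, 4, 4, 3, 3, 3), proximity_bp = 50,
                      promoter_bp = 5000, min_depth = 20, max_depth = 1000,
                      min_sample_calls = 10000, min_patients = 50,
                      min_distinct_genotypes = 3, alpha = 0.05,
                      min_repeat_type_obs = 25, mutability_diff = 0.05,
                      n_permutations = 10000),
    simulate = list(),
    seed = 1L)
}

merge_config <- function(base, extra) {
  if (is.null(extra)) return(base)
  utils::modifyList(base, extra)
}

validate_pipeline_config <- function(config) {
  th <- config$thresholds
  positive <- c("proximity_bp", "promoter_bp", "min_depth", "max_depth",
                "min_sample_calls", "min_patients",
                "min_distinct_genotypes", "min_repeat_type_obs",
                "mutability_diff", "n_permutations")
  for (nm in positive) {
    if (is.null(th[[nm]]) || any(th[[nm]] <= 0)) {
      stopf("pipeline configuration: threshold '%s' must be positive", nm)
    }
  }
  if (any(th$min_lengths < 1) || length(th$min_lengths) != 6L) {
    stopf("pipeline configuration: 'min_lengths' must be six positive values")
  }
  if (th$alpha <= 0 || th$alpha >= 1) {
    stopf("pipeline configuration: 'alpha' must be in (0, 1)")
  }
  config
}

load_pipeline_config <- function(config = NULL, overrides = list()) {
  base <- default_pipeline_config()
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(merge_config(base, config), overrides)
  validate_pipeline_config(cfg)
}

resolve_input <- function(config, name, default_file = NULL,
                          required = TRUE) {
  p <- config$paths[[name]]
  if (is.null(p) && !is.null(default_file)) {
    candidate <- file.path(config$output_dir, default_file)
    if (file.exists(candidate)) p <- candidate
  }
  if (required && (is.null(p) || !file.exists(p))) {
    stopf("missing input '%s': set paths$%s or run the producing stage first",
          name, name)
  }
  p
}

write_manifest <- function(config, stage, inputs, outputs) {
  hash_src <- tempfile()
  on.exit(unlink(hash_src))
  jsonlite::write_json(config, hash_src, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  manifest <- list(
    stage = stage,
    seed = config$seed,
    package_version = as.character(utils::packageVersion("estrpipe")),
    config_hash = unname(tools::md5sum(hash_src)),
    inputs = as.list(inputs),
    outputs = lapply(outputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))))
  path <- file.path(config$output_dir, sprintf("manifest_%s.json", stage))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  path
}

run_stage <- function(config, stage, inputs, outputs, body) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  tryCatch(body(), error = function(e) {
    existing <- unlist(outputs)[file.exists(unlist(outputs))]
    unlink(existing)
    stop(e)
  })
  write_manifest(config, stage, inputs, outputs)
  invisible(outputs)
}

out_path <- function(config, file) file.path(config$output_dir, file)

stage_simulate <- function(config) {
  sim_args <- config$simulate
  sim_args$seed <- sim_args$seed %||% config$seed
  sim_config <- do.call(simulation_config, sim_args)
  cohort <- generate_cohort(sim_config)
  paths <- write_cohort(cohort, config$output_dir)
  write_manifest(config, "simulate", character(0), as.list(paths))
  invisible(paths)
}

stage_panel <- function(config) {
  fasta <- resolve_input(config, "fasta")
  gff <- resolve_input(config, "gene_models")
  mask <- resolve_input(config, "mask", required = FALSE)
  outputs <- list(panel = out_path(config, "panel.bed"))
  run_stage(config, "panel", c(fasta = fasta, gene_models = gff),
            outputs, function() {
    th <- config$thresholds
    panel <- build_str_panel(fasta, gff, mask = mask,
                             min_lengths = th$min_lengths,
                             min_gap_bp = th$proximity_bp,
                             promoter_bp = th$promoter_bp)
    write_panel_bed(panel, outputs$panel)
  })
}

stage_filter_calls <- function(config) {
  calls_path <- resolve_input(config, "calls", "calls.tsv")
  panel_path <- resolve_input(config, "panel", "panel.bed")
  metadata_path <- resolve_input(config, "metadata", "metadata.tsv")
  cnv_path <- resolve_input(config, "cnv", "cnv.bed", required = FALSE)
  outputs <- list(calls = out_path(config, "filtered_calls.tsv"),
                  samples = out_path(config, "retained_samples.txt"))
  run_stage(config, "filter-calls",
            c(calls = calls_path, panel = panel_path,
              metadata = metadata_path, cnv = cnv_path %||% NA_character_),
            outputs, function() {
    th <- config$thresholds
    calls <- read_calls(calls_path)
    panel <- read_panel_bed(panel_path)
    metadata <- read_metadata(metadata_path)
    calls <- filter_call_depth(calls, th$min_depth, th$max_depth)
    keep <- filter_low_call_samples(calls, th$min_sample_calls)
    calls <- calls[calls$sample_id %in% keep, , drop = FALSE]
    if (!is.null(cnv_path)) {
      cnv <- read_cnv_bed(cnv_path)
      tumours <- metadata$sample_id[metadata$sample_type == "primary_tumour"]
      is_t <- calls$sample_id %in% tumours
      calls <- rbind(
        filter_cnv_overlap(calls[is_t, , drop = FALSE], panel, cnv),
        calls[!is_t, , drop = FALSE])
    }
    write_calls(calls, outputs$calls)
    writeLines(keep, outputs$samples)
  })
}

stage_call_mutations <- function(config) {
  calls_path <- resolve_input(config, "calls", "filtered_calls.tsv")
  metadata_path <- resolve_input(config, "metadata", "metadata.tsv")
  outputs <- list(events = out_path(config, "mutation_events.tsv"),
                  summaries = out_path(config, "patient_summaries.tsv"),
                  comparisons = out_path(config, "comparisons.tsv"))
  run_stage(config, "call-mutations",
            c(calls = calls_path, metadata = metadata_path), outputs,
            function() {
    calls <- read_calls(calls_path)
    metadata <- read_metadata(metadata_path)
    res <- call_cohort_mutations(calls, metadata)
    for (nm in names(outputs)) {
      utils::write.table(res[[switch(nm, events = "events",
                                     summaries = "summaries",
                                     comparisons = "comparisons")]],
                         outputs[[nm]], sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
  })
}

stage_mutability <- function(config) {
  comparisons_path <- resolve_input(config, "comparisons", "comparisons.tsv")
  events_path <- resolve_input(config, "events", "mutation_events.tsv")
  summaries_path <- resolve_input(config, "summaries",
                                  "patient_summaries.tsv")
  panel_path <- resolve_input(config, "panel", "panel.bed")
  outputs <- list(
    by_unit = out_path(config, "mutability_by_unit_size.tsv"),
    by_length = out_path(config, "mutability_by_allele_length.tsv"),
    summary = out_path(config, "mutability_summary.json"))
  run_stage(config, "mutability",
            c(comparisons = comparisons_path, events = events_path,
              panel = panel_path), outputs, function() {
    comparisons <- utils::read.table(comparisons_path, sep = "\t",
                                     header = TRUE, stringsAsFactors = FALSE)
    events <- utils::read.table(events_path, sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE)
    summaries <- utils::read.table(summaries_path, sep = "\t", header = TRUE,
                                   stringsAsFactors = FALSE)
    panel <- read_panel_bed(panel_path)
    by_unit <- mutability_by_unit_size(comparisons, panel)
    by_length <- mutability_by_allele_length(
      comparisons, panel, min_patients = config$thresholds$min_patients)
    utils::write.table(by_unit$table, outputs$by_unit, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(by_length, outputs$by_length, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    stage_cor <- stage_step_correlation(events)
    rank <- tryCatch(rank_patients_by_deletion(summaries),
                     warning = function(w) list(auc = NA_real_))
    jsonlite::write_json(
      list(unit_size_tests = by_unit$tests,
           stage_correlation = stage_cor[c("rho", "p_value", "n", "flagged")],
           deletion_ranking_auc = rank$auc),
      outputs$summary, auto_unbox = TRUE, digits = NA, dataframe = "columns",
      null = "null", pretty = TRUE)
  })
}

discovery_sample_split <- function(metadata, expr_samples) {
  healthy <- metadata$sample_type %in% healthy_sample_types
  validation_patients <-
    unique(metadata$patient_id[healthy & metadata$sample_id %in% expr_samples])
  tumours <- metadata[metadata$sample_type == "primary_tumour" &
                        metadata$sample_id %in% expr_samples, , drop = FALSE]
  list(discovery = tumours$sample_id[!tumours$patient_id %in%
                                       validation_patients],
       validation_patients = validation_patients)
}

stage_discover <- function(config) {
  calls_path <- resolve_input(config, "calls", "filtered_calls.tsv")
  expression_path <- resolve_input(config, "expression", "expression.tsv")
  metadata_path <- resolve_input(config, "metadata", "metadata.tsv")
  pairs_path <- resolve_input(config, "pairs", "pairs.tsv",
                              required = FALSE)
  panel_path <- resolve_input(config, "panel", "panel.bed")
  gene_list_path <- resolve_input(config, "gene_list", required = FALSE)
  outputs <- list(
    associations = out_path(config, "associations.tsv"),
    reference = out_path(config, "reference_quantiles.json"),
    eligible = out_path(config, "eligible_loci.txt"),
    estr = out_path(config, "estr_ids.txt"),
    permuted = out_path(config, "permuted_pvalues.tsv"))
  run_stage(config, "discover",
            c(calls = calls_path, expression = expression_path,
              metadata = metadata_path), outputs, function() {
    th <- config$thresholds
    calls <- read_calls(calls_path)
    tpm <- read_expression_tsv(expression_path)
    metadata <- read_metadata(metadata_path)
    pairs <- if (!is.null(pairs_path)) {
      utils::read.table(pairs_path, sep = "\t", header = TRUE,
                        stringsAsFactors = FALSE)
    } else {
      pair_str_gene(read_panel_bed(panel_path),
                    resolve_input(config, "gene_models"),
                    promoter_bp = th$promoter_bp)
    }
    split <- discovery_sample_split(metadata, colnames(tpm))
    disc_calls <- calls[calls$sample_id %in% split$discovery, , drop = FALSE]
    disc <- discover_estrs(disc_calls,
                           tpm[, split$discovery, drop = FALSE], pairs,
                           min_patients = th$min_patients,
                           min_distinct = th$min_distinct_genotypes,
                           alpha = th$alpha)
    assoc <- disc$associations
    if (!is.null(gene_list_path)) {
      assoc <- annotate_gene_list(assoc, gene_list_path)
    }
    utils::write.table(assoc, outputs$associations, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_reference_quantiles(disc$normalized$reference, outputs$reference)
    writeLines(disc$eligible, outputs$eligible)
    writeLines(disc$estr_ids, outputs$estr)
    permuted <- permutation_control(disc, seed = derive_seed(config$seed, 999L))
    utils::write.table(data.frame(p_permuted = permuted), outputs$permuted,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  })
}

stage_validate <- function(config) {
  calls_path <- resolve_input(config, "calls", "filtered_calls.tsv")
  expression_path <- resolve_input(config, "expression", "expression.tsv")
  metadata_path <- resolve_input(config, "metadata", "metadata.tsv")
  assoc_path <- resolve_input(config, "associations", "associations.tsv")
  ref_path <- resolve_input(config, "reference", "reference_quantiles.json")
  outputs <- list(records = out_path(config, "validation_records.tsv"),
                  summary = out_path(config, "validation_summary.json"))
  run_stage(config, "validate",
            c(calls = calls_path, expression = expression_path,
              associations = assoc_path), outputs, function() {
    calls <- read_calls(calls_path)
    tpm <- read_expression_tsv(expression_path)
    metadata <- read_metadata(metadata_path)
    associations <- utils::read.table(assoc_path, sep = "\t", header = TRUE,
                                      stringsAsFactors = FALSE)
    reference <- read_reference_quantiles(ref_path)
    split <- discovery_sample_split(metadata, colnames(tpm))
    val_md <- metadata[metadata$patient_id %in% split$validation_patients, ,
                       drop = FALSE]
    val_calls <- calls[calls$sample_id %in% val_md$sample_id, , drop = FALSE]
    mut <- call_cohort_mutations(val_calls, val_md)
    mats <- expression_by_patient(tpm, val_md)
    res <- validate_estrs(mut$events, associations, mats$tumour,
                          mats$healthy, reference)
    utils::write.table(res$records, outputs$records, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(overall = res$overall,
                              by_quartile = res$by_quartile),
                         outputs$summary, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns", pretty = TRUE)
  })
}

stage_estr_mutability <- function(config) {
  comparisons_path <- resolve_input(config, "comparisons", "comparisons.tsv")
  panel_path <- resolve_input(config, "panel", "panel.bed")
  estr_path <- resolve_input(config, "estr_ids", "estr_ids.txt")
  eligible_path <- resolve_input(config, "eligible_loci",
                                 "eligible_loci.txt", required = FALSE)
  outputs <- list(
    table = out_path(config, "repeat_type_mutability.tsv"),
    summary = out_path(config, "estr_mutability_summary.json"))
  run_stage(config, "estr-mutability",
            c(comparisons = comparisons_path, panel = panel_path,
              estr_ids = estr_path), outputs, function() {
    th <- config$thresholds
    comparisons <- utils::read.table(comparisons_path, sep = "\t",
                                     header = TRUE, stringsAsFactors = FALSE)
    panel <- read_panel_bed(panel_path)
    estr_ids <- readLines(estr_path, warn = FALSE)
    loci <- if (!is.null(eligible_path)) {
      readLines(eligible_path, warn = FALSE)
    } else NULL
    tables <- list(); summary <- list()
    for (grp in intersect(c("MSS", "MSI"), unique(comparisons$msi_label))) {
      cmp <- comparisons[comparisons$msi_label == grp, , drop = FALSE]
      res <- estr_mutability_permutation_test(
        panel, cmp, estr_ids, loci = loci,
        n_perm = th$n_permutations,
        seed = derive_seed(config$seed, match(grp, c("MSS", "MSI"))),
        min_obs = th$min_repeat_type_obs,
        diff_threshold = th$mutability_diff)
      tab <- res$table
      tab$msi_group <- grp
      tables[[grp]] <- tab
      summary[[grp]] <- res[c("observed_frac_estr_more",
                              "observed_frac_non_more", "n_tested",
                              "p_estr_more", "p_non_more", "n_perm",
                              "seed")]
    }
    utils::write.table(do.call(rbind, tables), outputs$table, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(summary, outputs$summary, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  })
}

#' Run pipeline stages
#'
#' Orchestrates the analysis stages over a single configuration (a YAML
#' file, a nested list, or NULL for defaults), with per-stage manifests
#' (inputs, config hash, seed, output checksums) written to the output
#' directory. \code{overrides} wins over the config file, which wins over
#' the defaults. Stage \code{"all"} chains simulate (only when no external
#' calls are configured), filter-calls, call-mutations, mutability,
#' discover, validate and estr-mutability.
#'
#' @param config YAML path, nested list, or NULL.
#' @param stage one of "simulate", "panel", "filter-calls",
#'   "call-mutations", "mutability", "discover", "validate",
#'   "estr-mutability", "all".
#' @param overrides nested list of config overrides.
#' @return invisibly, the output paths of the last stage run.
#' @export
run_pipeline <- function(config = NULL, stage = "all", overrides = list()) {
  cfg <- load_pipeline_config(config, overrides)
  stages <- c("simulate", "panel", "filter-calls", "call-mutations",
              "mutability", "discover", "validate", "estr-mutability",
              "all")
  if (!stage %in% stages) {
    stopf("unknown stage '%s' (expected one of %s)", stage,
          paste(stages, collapse = ", "))
  }
  runner <- list(
    "simulate" = stage_simulate, "panel" = stage_panel,
    "filter-calls" = stage_filter_calls,
    "call-mutations" = stage_call_mutations,
    "mutability" = stage_mutability, "discover" = stage_discover,
    "validate" = stage_validate,
    "estr-mutability" = stage_estr_mutability)
  if (stage != "all") return(invisible(runner[[stage]](cfg)))
  if (is.null(cfg$paths$calls)) stage_simulate(cfg)
  last <- NULL
  for (s in c("filter-calls", "call-mutations", "mutability", "discover",
              "validate", "estr-mutability")) {
    last <- runner[[s]](cfg)
  }
  invisible(last)
}

#' Gene-by-patient expression matrices for matched samples
#'
#' Re-keys a gene-by-sample matrix to patient ids, separately for tumour and
#' healthy samples, so matched expression changes can be computed.
#'
#' @param tpm gene-by-sample matrix.
#' @param metadata metadata data.frame.
#' @return list with \code{tumour} and \code{healthy} gene-by-patient
#'   matrices (patients present in both sample types only for healthy).
#' @export
expression_by_patient <- function(tpm, metadata) {
  pick <- function(types) {
    md <- metadata[metadata$sample_type %in% types &
                     metadata$sample_id %in% colnames(tpm), , drop = FALSE]
    md <- md[!duplicated(md$patient_id), , drop = FALSE]
    m <- tpm[, md$sample_id, drop = FALSE]
    colnames(m) <- md$patient_id
    m
  }
  list(tumour = pick("primary_tumour"), healthy = pick(healthy_sample_types))
}
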