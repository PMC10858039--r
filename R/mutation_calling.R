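# Somatic STR mutation calling from patient-matched healthy/tumour biallelic
# genotypes, with allele-dropout filtering and per-patient summaries.

healthy_sample_types <- c("blood_normal", "solid_tissue_normal")

#' Choose the healthy reference sample for a patient
#'
#' When a patient has more than one healthy sample, the one with the most STR
#' calls is used as the reference; ties prefer the blood-derived sample, then
#' the lexicographically smaller sample id.
#'
#' @param samples data.frame with sample_id, sample_type and n_calls for one
#'   patient.
#' @return the chosen sample_id.
#' @export
select_healthy_reference <- function(samples) {
  healthy <- samples[samples$sample_type %in% healthy_sample_types, ,
                     drop = FALSE]
  if (nrow(healthy) == 0L) {
    stopf("no healthy sample available for reference selection")
  }
  blood_first <- match(healthy$sample_type, healthy_sample_types)
  ord <- order(-healthy$n_calls, blood_first, healthy$sample_id)
  healthy$sample_id[ord[1L]]
}

#' Call somatic STR mutations for one healthy/tumour pair
#'
#' Compares biallelic genotypes locus by locus; only loci called in both
#' samples are compared. A locus is mutated when the allele multisets differ.
#' Loci where the tumour is homozygous for an allele absent from the healthy
#' pair are excluded as putative allele dropout and counted separately.
#' Per-allele steps pair the sorted healthy alleles with the sorted tumour
#' alleles positionally, which minimises the total absolute step for a
#' diploid pair.
#'
#' @param healthy_calls,tumour_calls calls data.frames for one sample each.
#' @param patient_id patient identifier attached to the events.
#' @return list with \code{events} (one row per mutated locus: allele pairs,
#'   per-allele steps, delta_mean = mean(tumour) - mean(healthy) in units,
#'   insertion/deletion flags), \code{n_compared} and \code{n_dropout}.
#' @export
call_mutations <- function(healthy_calls, tumour_calls, patient_id = NA_character_) {
  for (nm in c("healthy", "tumour")) {
    calls <- if (nm == "healthy") healthy_calls else tumour_calls
    dup <- duplicated(calls$locus_id)
    if (any(dup)) {
      stopf("duplicate %s call for locus %s", nm, calls$locus_id[which(dup)[1]])
    }
  }
  h <- sort_allele_pairs(healthy_calls)
  t <- sort_allele_pairs(tumour_calls)
  common <- intersect(h$locus_id, t$locus_id)
  h <- h[match(common, h$locus_id), , drop = FALSE]
  t <- t[match(common, t$locus_id), , drop = FALSE]
  step1 <- t$allele_a - h$allele_a
  step2 <- t$allele_b - h$allele_b
  changed <- step1 != 0L | step2 != 0L
  dropout <- changed & t$allele_a == t$allele_b &
    t$allele_a != h$allele_a & t$allele_a != h$allele_b
  is_event <- changed & !dropout
  events <- data.frame(
    patient_id = patient_id,
    locus_id = common[is_event],
    healthy_a = h$allele_a[is_event], healthy_b = h$allele_b[is_event],
    tumour_a = t$allele_a[is_event], tumour_b = t$allele_b[is_event],
    step_1 = step1[is_event], step_2 = step2[is_event],
    delta_mean = (step1[is_event] + step2[is_event]) / 2,
    has_insertion = step1[is_event] > 0L | step2[is_event] > 0L,
    has_deletion = step1[is_event] < 0L | step2[is_event] < 0L,
    stringsAsFactors = FALSE)
  rownames(events) <- NULL
  list(events = events, n_compared = length(common),
       n_dropout = sum(dropout), dropout_loci = common[dropout])
}

#' Normalised histogram of mutation step sizes
#'
#' Counts the nonzero per-allele steps of all events, normalised within each
#' group to sum to one. Groups are MSI labels when \code{by_msi}; otherwise a
#' single group.
#'
#' @param events events data.frame; needs an \code{msi_label} column when
#'   \code{by_msi} (see \code{call_cohort_mutations}).
#' @param by_msi split by MSI status.
#' @return data.frame with group, step, count and mass (masses sum to one
#'   within each group).
#' @export
step_size_histogram <- function(events, by_msi = TRUE) {
  group <- if (by_msi) {
    if (!"msi_label" %in% names(events)) {
      stopf("events lack an msi_label column; run call_cohort_mutations or set by_msi = FALSE")
    }
    rep(events$msi_label, 2L)
  } else rep("all", 2L * nrow(events))
  steps <- c(events$step_1, events$step_2)
  keep <- steps != 0L & !is.na(steps)
  steps <- steps[keep]; group <- group[keep]
  if (!length(steps)) {
    return(data.frame(group = character(0), step = integer(0),
                      count = integer(0), mass = numeric(0)))
  }
  tab <- as.data.frame(table(group = group, step = steps),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0L, , drop = FALSE]
  tab$step <- as.integer(tab$step)
  names(tab)[names(tab) == "Freq"] <- "count"
  totals <- tapply(tab$count, tab$group, sum)
  tab$mass <- tab$count / as.numeric(totals[tab$group])
  tab <- tab[order(tab$group, tab$step), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Summarise one patient's somatic STR mutations
#'
#' Fractions are over the compared loci. A locus counts toward the insertion
#' fraction when it has at least one positive allele step, and toward the
#' deletion fraction when it has at least one negative step; a locus with
#' both (e.g. steps +1/-1) counts in both.
#'
#' @param events events for the patient.
#' @param n_compared number of loci compared between healthy and tumour.
#' @param patient_id,msi_label identifiers carried into the summary.
#' @return one-row data.frame (PatientMutationSummary).
#' @export
summarize_patient <- function(events, n_compared, patient_id = NA_character_,
                              msi_label = NA_character_) {
  if (is.na(n_compared) || n_compared <= 0L) {
    stopf("cannot summarise patient %s: no compared loci", patient_id)
  }
  n_mut <- nrow(events)
  data.frame(
    patient_id = patient_id, msi_label = msi_label,
    n_compared = n_compared, n_mutated = n_mut,
    frac_mutated = n_mut / n_compared,
    frac_with_insertion = sum(events$has_insertion) / n_compared,
    frac_with_deletion = sum(events$has_deletion) / n_compared,
    mean_abs_delta = if (n_mut) mean(abs(events$delta_mean)) else NA_real_,
    stringsAsFactors = FALSE)
}

#' Rank patients by deletion fraction and measure MSI concordance
#'
#' Orders patients by the fraction of STRs with deletions (descending) and
#' reports how well that ranking separates MSI from MSS labels as the AUC of
#' the MSI label against the deletion fraction.
#'
#' @param summaries patient summaries (rows from \code{summarize_patient}).
#' @return list with \code{ranked} (summaries in rank order) and \code{auc}
#'   (NA with a warning for a single-label cohort).
#' @export
rank_patients_by_deletion <- function(summaries) {
  if (nrow(summaries) < 2L) stopf("ranking needs at least two patients")
  ranked <- summaries[order(-summaries$frac_with_deletion,
                            summaries$patient_id), , drop = FALSE]
  rownames(ranked) <- NULL
  labels <- summaries$msi_label
  if (length(unique(labels[!is.na(labels)])) < 2L) {
    warning("single-label cohort: MSI/MSS concordance undefined")
    return(list(ranked = ranked, auc = NA_real_))
  }
  roc <- pROC::roc(response = labels,
                   predictor = summaries$frac_with_deletion,
                   levels = c("MSS", "MSI"), direction = "<", quiet = TRUE)
  list(ranked = ranked, auc = as.numeric(roc$auc))
}

#' Call somatic STR mutations across a cohort
#'
#' For every patient with at least one healthy and one tumour sample, picks
#' the healthy reference (\code{select_healthy_reference}), calls mutations
#' against each tumour sample, and assembles cohort-level events (labelled
#' with the patient's MSI status) and per-patient summaries.
#'
#' @param calls calls data.frame for all samples.
#' @param metadata metadata data.frame (sample_id, patient_id, sample_type,
#'   msi_label, optional tumour_stage).
#' @return list with \code{events}, \code{summaries}, and \code{comparisons}
#'   (one row per compared locus x patient with its mutated flag, healthy
#'   mean allele length and MSI label -- the raw material for the mutability
#'   analyses).
#' @export
call_cohort_mutations <- function(calls, metadata) {
  counts <- table(calls$sample_id)
  metadata$n_calls <- as.integer(counts[metadata$sample_id])
  metadata$n_calls[is.na(metadata$n_calls)] <- 0L
  events_list <- list(); summary_list <- list(); comparison_list <- list()
  for (pid in unique(metadata$patient_id)) {
    md <- metadata[metadata$patient_id == pid, , drop = FALSE]
    tumours <- md[md$sample_type == "primary_tumour" & md$n_calls > 0L, ,
                  drop = FALSE]
    healthy <- md[md$sample_type %in% healthy_sample_types & md$n_calls > 0L, ,
                  drop = FALSE]
    if (nrow(tumours) == 0L || nrow(healthy) == 0L) next
    ref_id <- select_healthy_reference(healthy)
    h_calls <- calls[calls$sample_id == ref_id, , drop = FALSE]
    for (i in seq_len(nrow(tumours))) {
      t_id <- tumours$sample_id[i]
      msi <- tumours$msi_label[i]
      stage <- tumours$tumour_stage[i]
      t_calls <- calls[calls$sample_id == t_id, , drop = FALSE]
      res <- call_mutations(h_calls, t_calls, patient_id = pid)
      ev <- res$events
      if (nrow(ev)) {
        ev$msi_label <- msi
        ev$tumour_stage <- stage
        events_list[[length(events_list) + 1L]] <- ev
      }
      summary_list[[length(summary_list) + 1L]] <-
        summarize_patient(ev, res$n_compared, patient_id = pid,
                          msi_label = msi)
      h2 <- sort_allele_pairs(h_calls)
      common <- setdiff(intersect(h2$locus_id, t_calls$locus_id),
                        res$dropout_loci)
      hm <- h2[match(common, h2$locus_id), , drop = FALSE]
      comparison_list[[length(comparison_list) + 1L]] <- data.frame(
        patient_id = pid, locus_id = common,
        healthy_mean = (hm$allele_a + hm$allele_b) / 2,
        mutated = common %in% ev$locus_id,
        msi_label = msi, stringsAsFactors = FALSE)
    }
  }
  bind <- function(lst, proto) if (length(lst)) do.call(rbind, lst) else proto
  events <- bind(events_list,
                 cbind(call_mutations(data.frame(sample_id = character(0),
                                                 locus_id = character(0),
                                                 allele_a = integer(0),
                                                 allele_b = integer(0),
                                                 depth = integer(0)),
                                      data.frame(sample_id = character(0),
                                                 locus_id = character(0),
                                                 allele_a = integer(0),
                                                 allele_b = integer(0),
                                                 depth = integer(0)))$events,
                       msi_label = character(0), tumour_stage = integer(0)))
  summaries <- bind(summary_list, NULL)
  comparisons <- bind(comparison_list, NULL)
  rownames(events) <- NULL
  list(events = events, summaries = summaries, comparisons = comparisons)
}
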