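# Descriptive and inferential characterization of STR mutability by MSI
# status, repeat unit size and allele length.

join_unit_size <- function(comparisons, panel) {
  idx <- match(comparisons$locus_id, panel$locus_id)
  if (anyNA(idx)) {
    stopf("comparison loci missing from the panel (first: %s)",
          comparisons$locus_id[which(is.na(idx))[1]])
  }
  comparisons$unit_size <- panel$unit_size[idx]
  comparisons
}

#' Mutability by repeat unit size, MSS vs MSI
#'
#' Pools locus x patient comparisons per unit size and MSI group, and tests
#' each unit size's 2x2 table (mutated/not x MSS/MSI) with a two-sided
#' Fisher exact test.
#'
#' @param comparisons comparison table from \code{call_cohort_mutations}.
#' @param panel panel data.frame (for unit sizes).
#' @return list with \code{table} (unit_size, msi_group, n_compared,
#'   n_mutated, frequency; frequency NA for an empty stratum) and
#'   \code{tests} (unit_size, p_value).
#' @export
mutability_by_unit_size <- function(comparisons, panel) {
  cmp <- join_unit_size(comparisons, panel)
  units <- sort(unique(cmp$unit_size))
  rows <- list(); tests <- list()
  for (u in units) {
    sub <- cmp[cmp$unit_size == u, , drop = FALSE]
    cells <- sapply(c("MSS", "MSI"), function(g) {
      grp <- sub[sub$msi_label == g, , drop = FALSE]
      c(n_compared = nrow(grp), n_mutated = sum(grp$mutated))
    })
    rows[[length(rows) + 1L]] <- data.frame(
      unit_size = u, msi_group = c("MSS", "MSI"),
      n_compared = cells["n_compared", ], n_mutated = cells["n_mutated", ],
      frequency = ifelse(cells["n_compared", ] > 0L,
                         cells["n_mutated", ] / cells["n_compared", ],
                         NA_real_),
      stringsAsFactors = FALSE)
    p <- if (any(cells["n_compared", ] == 0L)) NA_real_ else {
      tab <- rbind(mutated = cells["n_mutated", ],
                   not = cells["n_compared", ] - cells["n_mutated", ])
      stats::fisher.test(tab)$p.value
    }
    tests[[length(tests) + 1L]] <- data.frame(unit_size = u, p_value = p)
  }
  table <- do.call(rbind, rows); rownames(table) <- NULL
  list(table = table, tests = do.call(rbind, tests))
}

#' Mutability stratified by healthy allele length
#'
#' Comparisons are stratified by unit size and the healthy mean allele
#' length rounded half-up to integer units. Within each MSI group, only
#' strata in which a healthy/tumour comparison could be made in at least
#' \code{min_patients} patients are reported.
#'
#' @param comparisons comparison table.
#' @param panel panel data.frame.
#' @param min_patients minimum distinct patients per reported stratum.
#' @return data.frame with unit_size, allele_length, msi_group, n_patients,
#'   n_compared, n_mutated, frequency.
#' @export
mutability_by_allele_length <- function(comparisons, panel,
                                        min_patients = 50L) {
  cmp <- join_unit_size(comparisons, panel)
  cmp$allele_length <- as.integer(round_half_up(cmp$healthy_mean))
  key <- interaction(cmp$unit_size, cmp$allele_length, cmp$msi_label,
                     drop = TRUE)
  rows <- lapply(split(cmp, key), function(sub) {
    data.frame(unit_size = sub$unit_size[1L],
               allele_length = sub$allele_length[1L],
               msi_group = sub$msi_label[1L],
               n_patients = length(unique(sub$patient_id)),
               n_compared = nrow(sub), n_mutated = sum(sub$mutated),
               frequency = mean(sub$mutated), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res <- res[res$n_patients >= min_patients, , drop = FALSE]
  res <- res[order(res$unit_size, res$allele_length, res$msi_group), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Correlation between tumour stage and mutation step size
#'
#' Spearman rank correlation between the absolute mean allele-length change
#' of each mutation event and the patient's tumour stage, restricted to MSI
#' tumours with a recorded stage.
#'
#' @param events cohort events (with msi_label and tumour_stage).
#' @return list with rho, p_value, n, and \code{flagged} (TRUE when fewer
#'   than three distinct stages are present, in which case no test is run).
#' @export
stage_step_correlation <- function(events) {
  sub <- events[events$msi_label == "MSI" & !is.na(events$tumour_stage), ,
                drop = FALSE]
  if (length(unique(sub$tumour_stage)) < 3L) {
    return(list(rho = NA_real_, p_value = NA_real_, n = nrow(sub),
                flagged = TRUE))
  }
  ct <- suppressWarnings(stats::cor.test(abs(sub$delta_mean),
                                         as.numeric(sub$tumour_stage),
                                         method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = nrow(sub),
       flagged = FALSE)
}

#' Compare a per-patient fraction between MSS and MSI patients
#'
#' Two-sided Mann-Whitney U test of a per-patient summary column (e.g.
#' frac_mutated or frac_with_insertion) between the MSS and MSI groups.
#'
#' @param summaries patient summaries.
#' @param column summary column to compare.
#' @return list with the group means and the test p-value.
#' @export
compare_patient_fractions <- function(summaries, column = "frac_mutated") {
  mss <- summaries[[column]][summaries$msi_label == "MSS"]
  msi <- summaries[[column]][summaries$msi_label == "MSI"]
  if (!length(mss) || !length(msi)) {
    stopf("both MSS and MSI patients are required to compare %s", column)
  }
  wt <- suppressWarnings(stats::wilcox.test(mss, msi))
  list(mean_mss = mean(mss), mean_msi = mean(msi), p_value = wt$p.value)
}
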