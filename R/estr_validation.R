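# eSTR validation: map held-out expression onto the discovery quantiles and
# test whether each model's slope predicts the direction of expression
# change after a somatic eSTR mutation.

#' Normalise held-out values against stored reference quantiles
#'
#' Maps a raw TPM value to the empirical quantile it occupies within a
#' gene's discovery reference (mid-rank for exact matches, linear
#' interpolation between neighbouring order statistics), clamps the quantile
#' to [0.5/n, 1 - 0.5/n], and applies the standard-normal quantile function.
#' Applied to the discovery values themselves this reproduces the
#' discovery-side inverse normal transform (tie-free case).
#'
#' @param values numeric vector of raw values.
#' @param reference sorted numeric vector of the gene's discovery values.
#' @return numeric vector of normalised scores.
#' @export
normalize_to_reference <- function(values, reference) {
  if (is.null(reference) || !length(reference)) {
    stopf("no reference quantiles available for this gene")
  }
  r <- sort(reference)
  n <- length(r)
  p <- vapply(values, function(v) {
    n_less <- sum(r < v)
    n_eq <- sum(r == v)
    if (n_eq > 0L) {
      (n_less + (n_eq + 1) / 2 - 0.5) / n
    } else if (n_less == 0L) {
      0.5 / n
    } else if (n_less == n) {
      1 - 0.5 / n
    } else {
      pk <- (n_less - 0.5) / n
      pk + (v - r[n_less]) / (r[n_less + 1L] - r[n_less]) / n
    }
  }, numeric(1))
  stats::qnorm(pmin(pmax(p, 0.5 / n), 1 - 0.5 / n))
}

#' Predicted direction of expression change for an eSTR mutation
#'
#' The model slope times the allele-length change: positive predicts an
#' increase, negative a decrease; a zero product (zero slope or a mutation
#' that leaves the mean length unchanged) is undefined and excluded from
#' accuracy.
#'
#' @param beta model slope(s).
#' @param delta_mean signed mean allele-length change(s), units.
#' @return character vector over {"increase", "decrease", "undefined"}.
#' @export
predict_direction <- function(beta, delta_mean) {
  prod <- beta * delta_mean
  ifelse(prod > 0, "increase", ifelse(prod < 0, "decrease", "undefined"))
}

#' Assemble eSTR mutation validation records
#'
#' For every somatic mutation at a significant eSTR in the validation
#' patients, records the model slope, the allele-length change, the expected
#' impact |beta| x |delta|, and the observed normalised expression change
#' (tumour minus matched healthy, both mapped onto the discovery reference
#' quantiles).
#'
#' @param events validation-cohort mutation events (patient_id, locus_id,
#'   delta_mean).
#' @param associations significant associations (locus_id, gene_id, beta).
#' @param tumour_tpm,healthy_tpm gene-by-patient TPM matrices for the
#'   validation patients (columns named by patient_id).
#' @param reference reference quantiles from discovery.
#' @return data.frame of EstrMutationRecord rows; \code{correct} is NA when
#'   the prediction is undefined or the observed change is exactly zero.
#' @export
build_validation_records <- function(events, associations, tumour_tpm,
                                     healthy_tpm, reference) {
  sig <- if ("is_significant" %in% names(associations)) {
    associations[associations$is_significant, , drop = FALSE]
  } else associations
  out <- list()
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    hits <- sig[sig$locus_id == ev$locus_id, , drop = FALSE]
    if (nrow(hits) == 0L) next
    pid <- ev$patient_id
    if (!pid %in% colnames(tumour_tpm) || !pid %in% colnames(healthy_tpm)) next
    for (j in seq_len(nrow(hits))) {
      gid <- hits$gene_id[j]
      ref <- reference[[gid]]
      if (is.null(ref) || !gid %in% rownames(tumour_tpm) ||
          !gid %in% rownames(healthy_tpm)) next
      obs <- normalize_to_reference(tumour_tpm[gid, pid], ref) -
        normalize_to_reference(healthy_tpm[gid, pid], ref)
      beta <- hits$beta[j]
      pred <- predict_direction(beta, ev$delta_mean)
      correct <- if (pred == "undefined" || obs == 0) NA else
        (obs > 0) == (pred == "increase")
      out[[length(out) + 1L]] <- data.frame(
        patient_id = pid, locus_id = ev$locus_id, gene_id = gid,
        beta = beta, delta_mean = ev$delta_mean,
        expected_impact = abs(beta) * abs(ev$delta_mean),
        observed_change = obs, predicted_direction = pred,
        correct = correct, stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(patient_id = character(0), locus_id = character(0),
               gene_id = character(0), beta = numeric(0),
               delta_mean = numeric(0), expected_impact = numeric(0),
               observed_change = numeric(0),
               predicted_direction = character(0), correct = logical(0),
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

usable_records <- function(records) {
  records[!is.na(records$correct), , drop = FALSE]
}

#' Direction-prediction accuracy against chance
#'
#' Proportion of usable records (defined prediction, nonzero observed
#' change) whose observed expression change matches the predicted
#' direction, with an exact one-sided binomial test against guessing with
#' probability 0.5.
#'
#' @param records validation records.
#' @return list with accuracy, n_used, n_correct, n_excluded (ties /
#'   undefined) and p_value.
#' @export
direction_accuracy <- function(records) {
  use <- usable_records(records)
  if (nrow(use) == 0L) stopf("no usable validation records")
  k <- sum(use$correct)
  n <- nrow(use)
  bt <- stats::binom.test(k, n, p = 0.5, alternative = "greater")
  list(accuracy = k / n, n_used = n, n_correct = k,
       n_excluded = nrow(records) - n, p_value = bt$p.value)
}

#' Accuracy by expected-impact quartile
#'
#' Usable records are ordered by expected impact (stable order for ties) and
#' split into four equal-as-possible groups; quartile 4 holds the mutations
#' with the highest expected impact.
#'
#' @param records validation records (>= 4 usable).
#' @return data.frame with quartile, n, n_correct, accuracy.
#' @export
accuracy_by_impact_quartile <- function(records) {
  use <- usable_records(records)
  if (nrow(use) < 4L) stopf("quartile accuracy needs at least 4 usable records")
  use <- use[order(use$expected_impact), , drop = FALSE]
  n <- nrow(use)
  q <- ceiling(4 * seq_len(n) / n)
  res <- do.call(rbind, lapply(1:4, function(k) {
    sub <- use[q == k, , drop = FALSE]
    data.frame(quartile = k, n = nrow(sub), n_correct = sum(sub$correct),
               accuracy = mean(sub$correct))
  }))
  rownames(res) <- NULL
  res
}

#' Validate eSTRs on a held-out cohort
#'
#' Convenience driver: builds validation records and reports overall and
#' per-quartile direction-prediction accuracy.
#'
#' @inheritParams build_validation_records
#' @return list with records, overall (from \code{direction_accuracy}) and
#'   by_quartile.
#' @export
validate_estrs <- function(events, associations, tumour_tpm, healthy_tpm,
                           reference) {
  records <- build_validation_records(events, associations, tumour_tpm,
                                      healthy_tpm, reference)
  by_quartile <- if (nrow(usable_records(records)) >= 4L) {
    accuracy_by_impact_quartile(records)
  } else NULL
  list(records = records,
       overall = direction_accuracy(records),
       by_quartile = by_quartile)
}
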