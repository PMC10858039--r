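# Somatic mutation calling, dropout filtering, summaries and MSI ranking.

test_that("locus comparisons classify events, non-events and dropout", {
  healthy <- make_call("N", c("L1", "L2", "L3", "L4"),
                       c(10, 10, 10, 10), c(10, 12, 12, 12))
  tumour <- make_call("T", c("L1", "L2", "L3", "L4"),
                      c(10, 10, 14, 9), c(12, 12, 14, 12))
  res <- call_mutations(healthy, tumour, patient_id = "P1")
  expect_equal(res$n_compared, 4L)
  # L1: (10,10) -> (10,12): one insertion, steps 0/+2, delta +1
  e1 <- res$events[res$events$locus_id == "L1", ]
  expect_equal(c(e1$step_1, e1$step_2), c(0L, 2L))
  expect_equal(e1$delta_mean, 1)
  expect_true(e1$has_insertion && !e1$has_deletion)
  # L2 identical -> no event
  expect_false("L2" %in% res$events$locus_id)
  # L3: tumour homozygous for unseen allele -> dropout, not an event
  expect_equal(res$n_dropout, 1L)
  expect_equal(res$dropout_loci, "L3")
  expect_false("L3" %in% res$events$locus_id)
  # L4: (10,12) -> (9,12): deletion, delta -0.5
  e4 <- res$events[res$events$locus_id == "L4", ]
  expect_equal(e4$delta_mean, -0.5)
  expect_true(e4$has_deletion && !e4$has_insertion)
  # delta_mean is always half the summed steps
  expect_equal(res$events$delta_mean,
               (res$events$step_1 + res$events$step_2) / 2)
  dup <- rbind(healthy, healthy[1, ])
  expect_error(call_mutations(dup, tumour), "duplicate")
})

test_that("healthy reference selection prefers call count, then blood", {
  samples <- data.frame(
    sample_id = c("S-blood", "S-solid"),
    sample_type = c("blood_normal", "solid_tissue_normal"),
    n_calls = c(12000L, 11000L))
  expect_equal(select_healthy_reference(samples), "S-blood")
  samples$n_calls <- c(10000L, 10000L)
  expect_equal(select_healthy_reference(samples), "S-blood")
  samples$n_calls <- c(9000L, 11000L)
  expect_equal(select_healthy_reference(samples), "S-solid")
  expect_equal(select_healthy_reference(samples[2, ]), "S-solid")
  tumour_only <- data.frame(sample_id = "T", sample_type = "primary_tumour",
                            n_calls = 100L)
  expect_error(select_healthy_reference(tumour_only), "no healthy sample")
})

test_that("step-size histogram normalises within each MSI group", {
  events <- data.frame(
    patient_id = "P1", locus_id = paste0("L", 1:4),
    step_1 = c(1L, -1L, -1L, -1L), step_2 = c(0L, 0L, 0L, 0L),
    msi_label = "MSI")
  hist <- step_size_histogram(events)
  expect_equal(hist$mass[hist$step == 1], 0.25)
  expect_equal(hist$mass[hist$step == -1], 0.75)
  # masses sum to one per group
  two <- rbind(events, transform(events, msi_label = "MSS"))
  hist2 <- step_size_histogram(two)
  expect_equal(as.numeric(tapply(hist2$mass, hist2$group, sum)), c(1, 1))
})

test_that("symmetric mutation model yields a symmetric MSS step histogram", {
  cohort <- small_cohort(n_patients_mss = 40L, n_patients_msi = 0L,
                         n_loci = 600L, base_mutation_rate_per_locus = 0.05,
                         cnv_segments_per_tumour = 0L)
  res <- call_cohort_mutations(cohort$calls, cohort$metadata)
  hist <- step_size_histogram(res$events)
  pos <- hist[hist$step > 0, ]
  neg <- hist[hist$step < 0, ]
  counts <- merge(transform(pos, k = step)[, c("k", "count")],
                  transform(neg, k = -step)[, c("k", "count")], by = "k")
  ct <- suppressWarnings(
    stats::chisq.test(cbind(counts$count.x, counts$count.y)))
  expect_gt(ct$p.value, 0.001)
})

test_that("patient summaries count insertion and deletion loci correctly", {
  events <- data.frame(
    patient_id = "P1", locus_id = paste0("L", 1:5),
    step_1 = c(1L, -1L, 1L, -2L, 0L), step_2 = c(0L, 0L, -1L, 0L, 3L),
    delta_mean = c(0.5, -0.5, 0, -1, 1.5),
    has_insertion = c(TRUE, FALSE, TRUE, FALSE, TRUE),
    has_deletion = c(FALSE, TRUE, TRUE, TRUE, FALSE))
  s <- summarize_patient(events, n_compared = 100L, patient_id = "P1")
  expect_equal(s$frac_mutated, 0.05)
  # the +1/-1 locus counts toward both fractions
  expect_equal(s$frac_with_insertion, 0.03)
  expect_equal(s$frac_with_deletion, 0.03)
  expect_error(summarize_patient(events, 0L), "no compared loci")
  deletion_only <- events[!events$has_insertion, ]
  expect_equal(summarize_patient(deletion_only, 100L)$frac_with_insertion, 0)
})

test_that("deletion ranking separates MSI from MSS, and is null on shuffles", {
  summaries <- data.frame(
    patient_id = sprintf("P%02d", 1:40),
    msi_label = rep(c("MSS", "MSI"), each = 20),
    frac_with_deletion = c(seq(0.01, 0.02, length.out = 20),
                           seq(0.05, 0.10, length.out = 20)))
  res <- rank_patients_by_deletion(summaries)
  expect_equal(res$auc, 1.0)
  expect_equal(res$ranked$frac_with_deletion,
               sort(summaries$frac_with_deletion, decreasing = TRUE))
  # shuffled labels: AUC near 0.5 (3 SE of the Mann-Whitney null)
  withr::with_seed(5, {
    shuffled <- transform(summaries, msi_label = sample(msi_label))
  })
  se <- sqrt((20 + 20 + 1) / (12 * 20 * 20))
  expect_lt(abs(rank_patients_by_deletion(shuffled)$auc - 0.5), 3 * se)
  single <- transform(summaries, msi_label = "MSS")
  expect_warning(res1 <- rank_patients_by_deletion(single), "single-label")
  expect_true(is.na(res1$auc))
})

test_that("cohort calling recovers planted mutations and filters dropout", {
  cohort <- small_cohort(n_patients_mss = 20L, n_patients_msi = 8L,
                         n_loci = 400L, dropout_rate = 0.1,
                         cnv_segments_per_tumour = 0L)
  res <- call_cohort_mutations(cohort$calls, cohort$metadata)
  truth <- cohort$truth$planted_mutations
  called_keys <- paste(res$events$patient_id, res$events$locus_id)
  planted_keys <- paste(truth$patient_id, truth$locus_id)
  expect_setequal(called_keys, planted_keys)
  # allele pairs of every called event match the planted ones
  m <- merge(res$events, truth, by = c("patient_id", "locus_id"))
  expect_equal(m$healthy_a.x, m$healthy_a.y)
  expect_equal(m$tumour_b.x, m$tumour_b.y)
  # no planted dropout artifact leaks into the events
  artifacts <- cohort$truth$planted_dropouts
  expect_gt(nrow(artifacts), 0L)
  expect_equal(sum(paste(artifacts$patient_id, artifacts$locus_id) %in%
                     called_keys), 0L)
})
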