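# Synthetic cohort generator: determinism, mutation model, planted
# expression effects, configuration validation.

test_that("identical configurations give identical cohorts", {
  a <- small_cohort(seed = 77L)
  b <- small_cohort(seed = 77L)
  expect_identical(a$panel, b$panel)
  expect_identical(a$calls, b$calls)
  expect_identical(a$expression, b$expression)
  expect_identical(a$cnv, b$cnv)
  expect_identical(a$truth$planted_mutations, b$truth$planted_mutations)
  # serialized outputs are byte-identical too
  da <- withr::local_tempdir(); db <- withr::local_tempdir()
  write_cohort(a, da); write_cohort(b, db)
  for (f in list.files(da)) {
    expect_identical(readLines(file.path(da, f)),
                     readLines(file.path(db, f)))
  }
  # a different seed changes the calls
  expect_false(identical(small_cohort(seed = 78L)$calls, a$calls))
})

test_that("adding patients does not reshuffle earlier patients", {
  small <- small_cohort(seed = 5L, n_patients_mss = 6L, n_patients_msi = 3L,
                        n_healthy_expression = 0L)
  big <- small_cohort(seed = 5L, n_patients_mss = 6L, n_patients_msi = 4L,
                      n_healthy_expression = 0L)
  shared <- small$calls$sample_id %in% big$calls$sample_id
  first <- small$calls[small$calls$sample_id %in%
                         paste0("P0001", c("-N", "-T")), ]
  again <- big$calls[big$calls$sample_id %in%
                       paste0("P0001", c("-N", "-T")), ]
  rownames(first) <- rownames(again) <- NULL
  expect_identical(first, again)
})

test_that("zero mutation rate leaves tumours identical to healthy", {
  cohort <- small_cohort(base_mutation_rate_per_locus = 0,
                         dropout_rate = 0, seed = 3L)
  calls <- cohort$calls
  n <- calls[grepl("-N$", calls$sample_id), ]
  t <- calls[grepl("-T$", calls$sample_id), ]
  rownames(n) <- rownames(t) <- NULL
  expect_identical(n[, c("locus_id", "allele_a", "allele_b")],
                   t[, c("locus_id", "allele_a", "allele_b")])
  expect_null(cohort$truth$planted_mutations)
})

test_that("mutate_alleles respects rate, direction and the 1-unit floor", {
  locus <- list(unit_size = 1L)
  cfg0 <- simulation_config(base_mutation_rate_per_locus = 0)
  withr::with_seed(1, {
    expect_equal(mutate_alleles(c(10L, 12L), locus, FALSE, cfg0),
                 c(10L, 12L))
  })
  # deletion-only steps at rate 1: every allele strictly shorter
  cfg_del <- simulation_config(
    base_mutation_rate_per_locus = 1, length_rate_slope = 0,
    step_size_distribution = c("-2" = 0.3, "-1" = 0.7))
  withr::with_seed(2, {
    for (i in 1:50) {
      out <- mutate_alleles(c(10L, 12L), locus, FALSE, cfg_del)
      expect_true(all(out < c(10L, 12L)))
    }
    # deletions never go below one unit
    floor_hit <- replicate(50, mutate_alleles(c(2L, 2L), locus, TRUE,
                                              cfg_del))
    expect_true(all(floor_hit >= 1L))
  })
})

test_that("empirical mutation frequency matches the configured rate", {
  cfg <- simulation_config(base_mutation_rate_per_locus = 0.3,
                           length_rate_slope = 0)
  locus <- list(unit_size = 1L)
  withr::with_seed(14, {
    hits <- replicate(5000, any(mutate_alleles(c(10L, 10L), locus, FALSE,
                                               cfg) != c(10L, 10L)))
  })
  # each allele mutates independently at 0.3 (a same-length redraw cannot
  # occur: steps are nonzero), so a pair changes at 1 - 0.7^2 = 0.51
  p_pair <- 1 - 0.7^2
  se <- sqrt(p_pair * (1 - p_pair) / 5000)
  expect_lt(abs(mean(hits) - p_pair), 3 * se)
  # per-allele probability is non-decreasing in allele length
  cfg_slope <- simulation_config(base_mutation_rate_per_locus = 0.05,
                                 length_rate_slope = 0.2)
  withr::with_seed(15, {
    short <- mean(replicate(3000, any(
      mutate_alleles(c(9L, 9L), locus, FALSE, cfg_slope) != c(9L, 9L))))
    long <- mean(replicate(3000, any(
      mutate_alleles(c(18L, 18L), locus, FALSE, cfg_slope) != c(18L, 18L))))
  })
  expect_gt(long, short)
})

test_that("the MSI deletion bias shows in pooled counts, insertions do not", {
  cohort <- small_cohort(n_patients_mss = 10L, n_patients_msi = 10L,
                         n_loci = 2000L, msi_deletion_multiplier = 10,
                         cnv_segments_per_tumour = 0L, seed = 41L)
  res <- call_cohort_mutations(cohort$calls, cohort$metadata)
  msi <- res$events[res$events$msi_label == "MSI", ]
  steps <- c(msi$step_1, msi$step_2)
  n_del <- sum(steps < 0); n_ins <- sum(steps > 0)
  expect_lt(stats::binom.test(n_del, n_del + n_ins, p = 0.5,
                              alternative = "greater")$p.value, 0.01)
  # the generator's expected deletion:insertion odds are multiplier:1
  expect_gt(n_del / n_ins, 5)
})

test_that("MSI/MSS ranking by deletion fraction is concordant at multiplier >= 5", {
  cohort <- small_cohort(n_patients_mss = 24L, n_patients_msi = 12L,
                         n_loci = 800L, msi_deletion_multiplier = 5,
                         cnv_segments_per_tumour = 0L, seed = 43L)
  res <- call_cohort_mutations(cohort$calls, cohort$metadata)
  expect_gte(rank_patients_by_deletion(res$summaries)$auc, 0.9)
})

test_that("expression is exactly linear for planted pairs without noise", {
  cohort <- small_cohort(noise_sd = 0, expression_transform = "identity",
                         n_estr = 8L, n_healthy_expression = 0L, seed = 13L)
  md <- cohort$metadata
  tumours <- md$sample_id[md$sample_type == "primary_tumour"]
  calls <- cohort$calls[cohort$calls$sample_id %in% tumours, ]
  calls$g <- mean_genotype(calls)
  truth <- cohort$truth
  intercepts <- stats::setNames(truth$gene_table$intercept,
                                truth$gene_table$gene_id)
  for (lid in truth$planted_estr_ids) {
    gid <- truth$locus_gene$gene_id[truth$locus_gene$locus_id == lid]
    sub <- calls[calls$locus_id == lid, ]
    expected <- pmax(intercepts[[gid]] + truth$planted_betas[[lid]] *
                       (sub$g - truth$locus_ref[[lid]]), 0)
    expect_equal(unname(cohort$expression[gid, sub$sample_id]),
                 unname(expected), tolerance = 1e-12)
  }
})

test_that("null genotype-expression correlations follow the null r distribution", {
  cohort <- small_cohort(n_patients_mss = 150L, n_patients_msi = 0L,
                         n_loci = 200L, n_genes = 200L, n_estr = 0L,
                         n_healthy_expression = 0L,
                         cnv_segments_per_tumour = 0L, seed = 55L)
  md <- cohort$metadata
  tumours <- md$sample_id[md$sample_type == "primary_tumour"]
  calls <- cohort$calls[cohort$calls$sample_id %in% tumours, ]
  calls$g <- mean_genotype(calls)
  r <- vapply(seq_len(nrow(cohort$pairs)), function(i) {
    sub <- calls[calls$locus_id == cohort$pairs$locus_id[i], ]
    e <- cohort$expression[cohort$pairs$gene_id[i], sub$sample_id]
    if (stats::sd(sub$g) == 0) return(NA_real_)
    stats::cor(sub$g, e)
  }, numeric(1))
  r <- r[!is.na(r)]
  n <- 150
  # expected |r| < 0.1 fraction under the null sampling distribution of r
  expected <- 2 * stats::pnorm(0.1 * sqrt(n - 1)) - 1
  se <- sqrt(expected * (1 - expected) / length(r))
  expect_gt(mean(abs(r) < 0.1), expected - 3 * se)
})

test_that("invalid configurations are rejected naming the field", {
  expect_error(simulation_config(msi_deletion_multiplier = 0.5),
               "msi_deletion_multiplier")
  expect_error(simulation_config(noise_sd = -1), "noise_sd")
  expect_error(simulation_config(unit_size_distribution = rep(0.2, 6)),
               "unit_size_distribution")
  expect_error(simulation_config(step_size_distribution = c("0" = 1)),
               "step_size_distribution")
  expect_error(simulation_config(n_estr = 10, n_genes = 5), "n_estr")
  expect_error(simulation_config(dropout_rate = 1.5), "dropout_rate")
  expect_error(simulation_config(n_loci = 0), "n_loci")
})

test_that("planted eSTRs always appear in the emitted panel and pairs", {
  cohort <- small_cohort(seed = 91L)
  expect_true(all(cohort$truth$planted_estr_ids %in%
                    cohort$panel$locus_id))
  expect_true(all(cohort$truth$planted_estr_ids %in%
                    cohort$pairs$locus_id))
  # planted dropout artifacts are recorded when enabled
  with_drop <- small_cohort(seed = 92L, dropout_rate = 0.2)
  expect_gt(nrow(with_drop$truth$planted_dropouts), 0L)
})
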