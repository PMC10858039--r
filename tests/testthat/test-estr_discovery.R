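# Expression normalisation, eligibility, per-pair models, FDR, permutation
# control.

test_that("expression filter drops genes with median zero", {
  m <- rbind(zero_med = c(0, 0, 5), kept = c(1, 2, 3))
  colnames(m) <- paste0("S", 1:3)
  out <- filter_expressed_genes(m)
  expect_equal(rownames(out), "kept")
  empty <- m[0, , drop = FALSE]
  expect_equal(nrow(filter_expressed_genes(empty)), 0L)
})

test_that("inverse normal transform hits the closed-form quantiles", {
  s <- inverse_normal_transform(c(1, 2, 3))
  expect_equal(s, stats::qnorm(c(1, 3, 5) / 6), tolerance = 1e-12)
  expect_equal(s[2], 0)
  expect_equal(inverse_normal_transform(rep(7, 5)), rep(0, 5))
  # rank invariance under strictly monotone transforms
  x <- c(0.3, 5, 2.2, 9, 1.1, 4)
  expect_equal(inverse_normal_transform(x),
               inverse_normal_transform(exp(x)))
  expect_equal(mean(inverse_normal_transform(x)), 0, tolerance = 1e-6)
  expect_error(inverse_normal_transform(c(1, 2)), "at least 3")
})

test_that("mean genotype averages the allele pair", {
  calls <- make_call("S", c("L1", "L2", "L3"), c(10, 9, 8), c(12, 10, 8))
  expect_equal(mean_genotype(calls), c(11, 9.5, 8))
})

test_that("locus eligibility needs 50 patients and 3 distinct genotypes", {
  calls49 <- make_call(sprintf("S%03d", 1:49), "L1", 10 + (1:49) %% 3, 10)
  expect_equal(length(eligible_loci(calls49)), 0L)
  calls60_2 <- make_call(sprintf("S%03d", 1:60), "L1",
                         10 + (1:60) %% 2, 10)
  expect_equal(length(eligible_loci(calls60_2)), 0L)
  calls60_3 <- make_call(sprintf("S%03d", 1:60), "L1",
                         10 + (1:60) %% 3, 10)
  expect_equal(eligible_loci(calls60_3), "L1")
})

test_that("STR-gene pairing follows gene bodies plus promoter windows", {
  gm <- fixture_gene_models()
  overlapping <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(12001, 18000), strand = "+")
  overlapping$type <- "gene"
  overlapping$ID <- "gene3"
  overlapping$gene_id <- "gene3"
  gm2 <- c(gm, overlapping)
  panel <- rbind(make_locus("chr1", 16000, 16012),  # inside gene1 and gene3
                 make_locus("chr1", 19500, 19512),  # gene1 only
                 make_locus("chr1", 400000, 400012))  # intergenic
  pairs <- pair_str_gene(panel, gm2)
  expect_setequal(pairs$gene_id[pairs$locus_id == panel$locus_id[1]],
                  c("gene1", "gene3"))
  expect_equal(pairs$gene_id[pairs$locus_id == panel$locus_id[2]], "gene1")
  expect_false(panel$locus_id[3] %in% pairs$locus_id)
})

test_that("OLS slope and test match the closed-form oracle", {
  x <- 1:10
  exact <- suppressWarnings(fit_estr_model(x, 2 * x))
  expect_equal(exact$beta, 2, tolerance = 1e-12)
  expect_lt(exact$p_value, 1e-12)
  x5 <- c(1, 2, 3, 4, 5); y5 <- c(2, 1, 4, 3, 5)
  fit <- fit_estr_model(x5, y5)
  beta_hat <- sum((x5 - mean(x5)) * (y5 - mean(y5))) / sum((x5 - mean(x5))^2)
  expect_equal(fit$beta, beta_hat)
  expect_equal(fit$beta, 0.8)
  # full normal-equations oracle on random data
  withr::with_seed(4, {
    xr <- rnorm(20); yr <- rnorm(20)
  })
  f <- fit_estr_model(xr, yr)
  b <- sum((xr - mean(xr)) * (yr - mean(yr))) / sum((xr - mean(xr))^2)
  a <- mean(yr) - b * mean(xr)
  rss <- sum((yr - a - b * xr)^2)
  se <- sqrt(rss / 18 / sum((xr - mean(xr))^2))
  expect_equal(f$beta, b, tolerance = 1e-12)
  expect_equal(f$se_beta, se, tolerance = 1e-12)
  expect_equal(f$p_value, 2 * stats::pt(-abs(b / se), df = 18),
               tolerance = 1e-12)
  flat <- fit_estr_model(rep(3, 10), rnorm(10))
  expect_true(flat$flagged)
  expect_true(is.na(flat$beta))
})

test_that("null p-values are uniform", {
  withr::with_seed(88, {
    p <- vapply(1:400, function(i) {
      fit_estr_model(rnorm(30), rnorm(30))$p_value
    }, numeric(1))
  })
  expect_gt(suppressWarnings(stats::ks.test(p, "punif"))$p.value, 0.01)
})

test_that("BH adjustment matches step-up enumeration", {
  res <- bh_fdr(c(0.01, 0.02, 0.04))
  expect_true(all(res$is_significant))
  expect_true(all(bh_fdr(rep(1, 5))$is_significant == FALSE))
  single <- bh_fdr(0.04)
  expect_equal(single$q_value, 0.04)
  expect_true(single$is_significant)
  withr::with_seed(2, {
    for (i in 1:10) {
      p <- runif(50)^2
      res <- bh_fdr(p)
      expect_equal(res$q_value, oracle_bh_q(p), tolerance = 1e-12)
      expect_true(all(res$q_value >= p))
    }
  })
})

test_that("discovery recovers planted effects with correct signs", {
  cohort <- small_cohort(n_patients_mss = 70L, n_patients_msi = 10L,
                         n_loci = 250L, n_genes = 150L, n_estr = 20L,
                         n_healthy_expression = 0L,
                         cnv_segments_per_tumour = 0L)
  tumours <- cohort$metadata$sample_id[
    cohort$metadata$sample_type == "primary_tumour"]
  calls <- cohort$calls[cohort$calls$sample_id %in% tumours, ]
  disc <- discover_estrs(calls, cohort$expression[, tumours], cohort$pairs)
  sig <- disc$associations[disc$associations$is_significant, ]
  planted <- cohort$truth$planted_estr_ids
  expect_gte(mean(planted %in% sig$locus_id), 0.9)
  b <- unlist(cohort$truth$planted_betas)
  hit <- sig[sig$locus_id %in% names(b), ]
  expect_true(all(sign(hit$beta) == sign(b[hit$locus_id])))
  # q-values never fall below their p-values
  expect_true(all(disc$associations$q_value >= disc$associations$p_value))

  # permuted-genotype control: reproducible and uniform
  p1 <- permutation_control(disc, seed = 5)
  p2 <- permutation_control(disc, seed = 5)
  expect_identical(p1, p2)
  expect_gt(suppressWarnings(stats::ks.test(p1, "punif"))$p.value, 0.01)
  # real planted-effect p-values are depressed relative to uniform
  expect_lt(stats::median(disc$associations$p_value), 0.5)
})

test_that("gene-list annotation flags matching genes, deduplicated", {
  assoc <- data.frame(locus_id = c("L1", "L2"), gene_id = c("G1", "G2"))
  out <- annotate_gene_list(assoc, c("G2", "G2", " G3"))
  expect_equal(out$in_gene_list, c(FALSE, TRUE))
  expect_equal(annotate_gene_list(assoc, character(0))$in_gene_list,
               c(FALSE, FALSE))
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("G1", "G1"), path)
  expect_equal(annotate_gene_list(assoc, path)$in_gene_list, c(TRUE, FALSE))
})

test_that("reference quantiles round-trip through JSON", {
  ref <- list(G1 = c(0.5, 1.2, 3.3), G2 = c(0, 0, 7))
  path <- withr::local_tempfile(fileext = ".json")
  write_reference_quantiles(ref, path)
  expect_equal(read_reference_quantiles(path), ref)
})
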