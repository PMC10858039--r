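# estrpipe

Somatic short-tandem-repeat (STR) mutations are pervasive in colorectal
cancer, especially in microsatellite-instable (MSI) tumours, yet their effect
on gene expression is mostly unexplored. `estrpipe` implements an end-to-end
analysis for this question, aimed at cancer genomicists working with
patient-matched tumour/normal STR genotypes and expression data:

1. **Panel annotation** — exhaustive detection of maximal perfect tandem
   repeats (unit size 1–6 bp; minimum allele lengths 9/4/4/3/3/3 units for
   mono- to hexanucleotide repeats) in gene-associated sequence, with
   redundancy resolution, a 50 bp proximity filter, segmental-duplication
   masking and gene-region labels (CDS > UTR > intron > promoter, 5 kb
   promoter window).
2. **Somatic STR mutation calling** — biallelic genotypes of matched
   healthy/tumour pairs are compared per locus; a locus is mutated when the
   allele multisets differ, and tumour calls homozygous for an allele unseen
   in the healthy sample are excluded as allele dropout. Call-level filters
   mirror standard practice (depth in [20, 1000], ≥10,000 calls per sample,
   CNV-overlapping tumour calls removed).
3. **Mutability characterization** — mutated fractions by MSI status, unit
   size (Fisher exact tests) and allele length, step-size histograms, and
   ranking of patients by deletion fraction (AUC against MSI labels).
4. **eSTR discovery** — gene expression (TPM) is rank-transformed to
   standard-normal scores per gene; for every STR–gene pair with the STR
   called in ≥50 patients and ≥3 distinct genotypes, an ordinary
   least-squares model

   `normalized expression = alpha + beta * (mean allele length) + error`

   is fitted, the slope tested (t test, n−2 df), and the
   Benjamini–Hochberg procedure applied across all pairs at alpha = 0.05.
   A permuted-genotype re-analysis provides the negative control.
5. **eSTR validation** — in held-out matched pairs, each somatic eSTR
   mutation predicts an expression change of sign `sign(beta * delta_l)`
   (`delta_l` = tumour − healthy mean allele length); held-out TPM values
   are mapped onto the discovery quantiles, and prediction accuracy is
   tested against chance (one-sided exact binomial, p = 0.5) overall and by
   quartile of expected impact `|beta| * |delta_l|`.
6. **eSTR mutability** — loci are grouped into repeat types (unit size ×
   reference allele length); for each type with ≥25 observations per label
   the mutated fractions of eSTRs and non-eSTRs are compared (a difference
   must exceed 0.05), and the fraction of types where eSTRs are more mutable
   is tested against a 10,000-fold eSTR-label permutation null with the
   add-one p-value (1 + #{null ≥ observed}) / (1 + n_perm).

Real cohorts of this kind are restricted-access, so the package ships a
seeded synthetic-cohort generator (`generate_cohort()`) with planted somatic
mutations, an MSI deletion bias, allele-dropout artifacts and planted linear
eSTR effects, making every stage testable end to end.

## Worked example

```r
library(estrpipe)

cohort <- generate_cohort(simulation_config(seed = 1))
md <- cohort$metadata

# somatic mutation calling across the cohort
mut <- call_cohort_mutations(cohort$calls, md)
round(100 * tapply(mut$summaries$frac_mutated, mut$summaries$msi_label, mean), 2)
#>  MSI  MSS
#> 7.27 1.39
rank_patients_by_deletion(mut$summaries)$auc
#> [1] 1

# eSTR discovery on the tumour samples
tumours <- md$sample_id[md$sample_type == "primary_tumour"]
calls <- cohort$calls[cohort$calls$sample_id %in% tumours, ]
disc <- discover_estrs(calls, cohort$expression[, tumours], cohort$pairs)
sum(disc$associations$is_significant)
#> [1] 104
mean(cohort$truth$planted_estr_ids %in%
       disc$associations$locus_id[disc$associations$is_significant])
#> [1] 0.99
```

On average 1.39% of compared STR loci are mutated per MSS patient versus
7.27% per MSI patient, with perfect separation of the groups by deletion
fraction — the structure the generator plants. Discovery recovers 99 of the
100 planted eSTRs; the extra significant pairs are additional gene pairings
of true loci or false positives admitted at the controlled FDR.

## Command line

A thin wrapper over `run_pipeline()` lives at `inst/scripts/strpipe.R`:

```sh
Rscript inst/scripts/strpipe.R --stage all --config config.yaml --seed 1
```

Stages (`simulate`, `panel`, `filter-calls`, `call-mutations`, `mutability`,
`discover`, `validate`, `estr-mutability`, `all`) read a single YAML config,
write TSV/JSON/BED artifacts plus a manifest (inputs, config hash, seed,
output checksums) per stage, and are bit-reproducible for a fixed seed.
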