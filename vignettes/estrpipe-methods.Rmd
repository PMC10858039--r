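---
title: "Methods: somatic STR mutations and expression STRs with estrpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: somatic STR mutations and expression STRs with estrpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`estrpipe` analyses somatic short-tandem-repeat (STR) mutations in
colorectal tumours and their association with gene expression. The core
statistical object is, per STR locus and gene, the ordinary least-squares
model

$$ y_s = \alpha + \beta \, g_s + \varepsilon_s, $$

where $g_s$ is the mean of the two allele lengths (repeat units) of the STR
in tumour sample $s$ and $y_s$ is that sample's gene expression after a
rank-based inverse normal transform. A locus whose slope survives
Benjamini–Hochberg control across all tested STR–gene pairs is a putative
expression STR (eSTR). Because a significant slope can reflect a linked
eQTL rather than the repeat itself, the pipeline validates eSTRs
functionally: in held-out patients with matched healthy/tumour samples, a
somatic change $\Delta_l$ in mean allele length should move expression in
the direction of $\operatorname{sign}(\beta\,\Delta_l)$, and more so for
larger expected impact $|\beta|\,|\Delta_l|$.

# Panel annotation

Perfect tandem runs with unit sizes 1–6 bp are detected exhaustively. A run
is annotated when its repeat count reaches the per-unit-size minimum of
9/4/4/3/3/3 units (mono- to hexanucleotide). The scan is vectorised: for
each lag $u$ the sequence is compared against itself shifted by $u$, and
maximal `TRUE` runs of that indicator delimit maximal periodic regions.
Numerical/combinatorial choices worth noting:

* **Whole units, left anchor.** A maximal periodic region is trimmed to
  whole units anchored at its left end, so `ACACACA` is annotated as three
  `AC` units starting at the first base.
* **Primitive motifs only.** A region is reported once, at its primitive
  period (`ACAC` is never a unit). For reportable lengths (≥3 units) the
  periodicity lemma for strings guarantees that primitivity of the leading
  unit suffices.
* **N breaks runs**; any other character is an input error.
* **Redundancy** among overlapping annotations is resolved by smaller unit
  size, then longer span, then smaller start — a poly-A run beats any
  dinucleotide reading of the same bases.
* **Proximity.** Loci within 50 bp of another locus are removed, and the
  rule is inclusive (a gap of exactly 50 bp removes the pair) and symmetric:
  both members go, since either one's genotyping could be corrupted by the
  other. This both-removed reading was a genuinely open choice.
* **Regions.** Loci are labelled CDS > UTR > intron > promoter by overlap
  priority; the promoter is the strand-aware 5 kb window upstream of the
  gene start, and any gene-body overlap that is neither CDS nor UTR counts
  as intronic. Loci outside all gene-associated regions are dropped, and a
  user-supplied mask (e.g. segmental duplications) plus a non-autosome list
  remove unreliable sequence.

The detector is tested for exact set equality against an independent
brute-force per-position scanner on 1,000 random 2 kb sequences with
embedded repeats.

# Mutation calling

Only loci called in both samples of a patient are compared; the healthy
reference is the healthy sample with the most calls (ties prefer blood over
solid tissue). A locus is mutated when the allele multisets differ.
Per-allele steps pair sorted healthy with sorted tumour alleles
positionally, which minimises the total absolute step for a diploid pair —
the parsimonious choice where phasing is unknowable. Mutation detection and
per-patient fractions are locus-level; the step-size histogram is
per-allele. A tumour call homozygous for an allele absent from the healthy
pair is excluded as putative allele dropout and counted separately. Note
the asymmetry this buys: the filter removes essentially all dropout
artifacts while a genuine double-step mutation to an unseen homozygous
genotype is rare enough that planted-truth recovery stays exact in testing.

Mutability tables stratify comparisons by unit size (2×2 Fisher exact tests
of mutated/not × MSS/MSI, pooled over patients) and by allele length, using
the healthy mean rounded half-up — the healthy genotype is the natural
pre-mutation state, and half-up rounding keeps `10.5` in the 11-unit
stratum. Strata reported require comparisons in ≥50 patients. Pooling
treats locus × patient comparisons as independent Bernoulli trials and
ignores per-patient clustering; this mirrors the per-locus framing of the
analysis but is a known limitation for the Fisher p-values.

# eSTR discovery

Genes with median TPM of zero are discarded; the rest are transformed per
gene with $\Phi^{-1}((r_i - 0.5)/n)$ using average ranks for ties — the
symmetric offset, without a Blom-type constant, because the contract is
simply "standard normal scores". The raw per-gene values are retained as
reference quantiles for validation-side normalisation. Loci require ≥50
called patients and ≥3 distinct mean genotypes (slope estimation from two
genotype classes would be a group comparison, not a dose response). Pairs
follow gene bodies plus the promoter window; a locus inside two genes
yields two pairs, and promoter STRs are included because the panel treats
the promoter as gene-associated sequence (a flag disables this). Tumour
genotypes only enter the models, matching tumour expression. BH is applied
across all fitted pairs at $\alpha = 0.05$.

The negative control permutes each pair's genotype vector across samples
once and refits, giving a permuted p-value set for Q–Q comparison; one
permutation per pair (rather than a per-pair permutation p-value) is enough
to show the null behaviour of the whole analysis and keeps the control at
the cost of one extra pass.

# Validation

Held-out TPM values are mapped onto the stored discovery quantiles: exact
matches take the mid-rank position, values between two order statistics
interpolate linearly in quantile space, and values outside the reference
clamp to the extreme plotting positions $0.5/n$ and $1 - 0.5/n$ before
$\Phi^{-1}$. Applied to the discovery samples themselves this reproduces
the discovery transform to numerical precision (tie-free case), which is
tested. Observed changes of exactly zero and undefined predictions
($\beta\,\Delta_l = 0$) are excluded from accuracy but counted. The
binomial test is one-sided (better than guessing). Impact quartiles are
quartiles of records in stable order, so ties split deterministically;
quartile 4 holds the highest expected impact.

# eSTR mutability

Repeat types are unit size × panel reference allele length — the panel
value, not the patient's healthy length, so the stratification is fixed
across patients. One observation is one locus × patient comparison; types
need ≥25 observations for each label. A label is "more mutable" only when
the mutated-fraction difference strictly exceeds 0.05. The test statistic
is the fraction of tested types where eSTRs are more mutable; the null
shuffles eSTR labels globally across the eligible locus set (preserving the
label count; per-type label counts are left free, as the shuffle is of locus
identities, not within-type assignments). The add-one estimator
$(1 + \#\{\text{null} \ge \text{obs}\})/(1 + n_{\text{perm}})$ avoids
zero p-values and makes $1/10001$ the smallest attainable value at 10,000
permutations. MSS and MSI cohorts are analysed separately throughout.

# The synthetic cohort generator

`generate_cohort()` emulates the statistical structure the pipeline
assumes, not sequencing itself:

* **Cohort frame.** Defaults: 120 MSS + 25 MSI patients, one matched
  healthy/tumour pair each; 2,000 loci over 500 genes; unit sizes drawn
  with mononucleotides most common; reference lengths uniform within
  per-unit-size ranges (e.g. 9–20 units for mononucleotides).
* **Population variation.** Healthy alleles are the reference length plus
  discretised Gaussian noise (SD 1.2 units, floor 1) — enough genotype
  spread for eligibility and slope estimation, chosen as a plausible
  population allele-length dispersion.
* **Mutation model.** Each allele mutates with probability
  $\min\{1,\, p_0 (1 + s\,(L - L_0))\}$ ($p_0 = 0.005$ per allele,
  $s = 0.08$ per unit above the unit-size minimum $L_0$), reproducing the
  rise of mutability with allele length and an MSS per-locus mutated
  fraction near 1.4% per patient. Signed step sizes follow a symmetric
  distribution with 55% mass on ±1 (single-step changes most common). For
  MSI patients the deletion rate alone is multiplied by 10, so deletions
  outnumber insertions about tenfold while insertion rates match MSS — the
  deletion-only character of the MSI excess. Deletions never push an
  allele below one unit.
* **Artifacts.** A configurable fraction of heterozygous healthy loci is
  emitted in the tumour as homozygous for an unseen allele (dropout); a
  genuine mutation that would accidentally produce that signature has one
  allele reverted, keeping truth recovery exact. Per-tumour CNV segments
  cover whole genes to exercise the overlap filter; a few all-zero genes
  exercise the expression filter.
* **Expression.** Latent expression is gene intercept (+ planted
  $\beta \times$ (mean allele length − reference) for eSTR loci, each on a
  distinct gene) + Gaussian noise (SD 1), mapped to a nonnegative TPM-like
  scale by softplus — monotone, so planted signs survive the rank
  transform; an identity-on-positives option supports exact-linearity
  tests. Healthy expression is generated for a validation subset (default
  16 patients) from healthy genotypes with independent noise.
* **Reproducibility.** The master seed derives one RNG stream for the
  cohort frame and one per patient, so identical configurations are
  byte-identical and adding patients never reshuffles earlier ones. Within
  a patient, draws are vectorised across loci; a per-locus stream split was
  considered and rejected since it would forbid vectorisation and only adds
  stability under panel-size changes, which nothing requires.

What the generator does **not** model: reads and genotyping error beyond
dropout, linked eQTLs, covariates (purity, population structure), multiple
mutations accumulating per locus (so the MSI step-size histogram stays
close to the MSS shape, unlike real MSI tumours), and any correlation of
tumour stage with step size. Passing tests therefore demonstrate that the
pipeline recovers the structure it assumes — planted effects, rates, and
biases — not that real tumours satisfy those assumptions.

# Test problem sizes

The deeper checks run at sizes chosen to make their statistical claims
resolvable: detector/oracle equivalence on 1,000 × 2 kb sequences;
discovery power and sign agreement on 300 tumours × 2,000 loci with 100
planted slopes $|\beta| \in [0.5, 1.5]$ at noise SD 1 (theoretical slope
t-statistics ≈ 7, so ≥95% sensitivity has margin); planted-null false
discovery pooled over ten 300-tumour cohorts; validation monotonicity over
ten cohorts of 100 validation patients × 300 planted eSTRs with
$|\beta| \in [0.3, 2]$, sized so each impact quartile holds hundreds of
mutations (accuracy $\approx \Phi(|\beta\Delta_l|/\sqrt{2})$ under
noise SD 1, giving inter-quartile gaps several standard errors wide);
permutation-test calibration over 50 label reshuffles at 200 permutations
and the add-one minimum at the full 10,000.

# Known limitations

Fisher pooling ignores patient clustering; the discovery models carry no
covariates; validation accuracy aggregates over eSTRs (individual loci are
not separately tested); imperfect repeats are outside the panel's scope —
only perfect runs are annotated; and the generator's step-size distribution
is qualitative, as no empirical step-size probabilities were available to
calibrate against.
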