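---
title: "Case-only rare-variant discovery: models, estimators, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Case-only rare-variant discovery: models, estimators, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caseonly)
```

## The problem

Rare, highly penetrant risk variants for late-onset dementias are hard to
find with conventional association statistics: when a variant is carried by
a handful of cases and by no controls, contingency-table tests have an
empty cell and effectively no power regardless of cohort size. `caseonly`
implements the complementary strategy of *case-only screening*: enumerate
variants of predicted functional consequence that recur in cases and are
absent from called controls, then characterize the survivors — are the
carriers hidden relatives? do they share an ancestral haplotype? do they
concentrate in an ancestry subcluster? is there an aggregate burden signal
in the implicated gene set? — before any claim is made.

The package operates on standard inputs (VCF genotypes, an annotation
table, a phenotype table, GMT gene sets, PED pedigrees) and includes a
synthetic cohort generator so that every stage can be validated against
planted ground truth.

## Case-only filtering

A *carrier* is a sample with dosage of at least one alternate allele.
"Observed in N participants" counts carrier individuals, not alleles, so
one homozygote counts once. Missing genotypes are excluded from every
denominator, and — deliberately conservative in both directions —
half-calls are treated as missing, while a control with a missing call
never counts against "absent in controls" (absence of a call is not
evidence of absence of the allele).

Four preset schemes cover the usual discovery strata:

| scheme | impacts | case carriers | controls | extra rule |
|---|---|---|---|---|
| `candidate_gene` | HIGH, MODERATE | ≥ 4 | 0 | gene in a prior candidate list |
| `genomewide_moderate_high` | HIGH, MODERATE | ≥ 10 | 0 | — |
| `multi_variant_gene` | HIGH, MODERATE | ≥ 5 each | 0 | ≥ 3 distinct passing variants per gene |
| `genomewide_high` | HIGH | ≥ 7 | 0 | — |

Every threshold is overridable; a population-frequency ceiling
(`max_pop_af`) can be added. A separate advisory flag (`flag_nonrare()`,
default threshold 0.01, matching the usual "rare" burden stratum) marks
retained variants that are in fact common in some reference population and
therefore unlikely to be highly penetrant; it never removes them, because
a common-in-one-population variant can still be informative to report.

The consequence-to-impact mapping (stop/frameshift/splice-disrupting →
HIGH, protein-altering → MODERATE, synonymous → LOW, else MODIFIER) is a
configurable table because annotation pipelines differ in their exact
vocabularies; unknown terms degrade to MODIFIER with a warning rather than
an error so that one exotic term cannot abort a genome-wide scan.

## Haplotype background of a recurrent rare variant

A rare allele seen in several unrelated cases either arose once on a
common ancestral haplotype or recurred by mutation or error. The package
follows the classical workflow: select common SNPs (sample MAF ≥
`min_maf`, default 0.05) within a window (default 100 kb total) around the
focal variant, estimate window haplotype frequencies, and ask which
haplotypes are compatible with *every* carrier.

Frequencies are estimated by the standard EM algorithm for unphased
multilocus genotypes. The E-step distributes each individual's mass over
all haplotype pairs compatible with its genotype proportionally to the
product of current frequencies; the M-step re-estimates frequencies from
expected gamete counts. Numerical details:

* **Initialization** is the linkage-equilibrium product of allele
  frequencies, plus one jittered restart (run on a private RNG stream so
  the caller's seed state is untouched); the run with the higher final
  log-likelihood is returned.
* **Convergence** is declared when the largest frequency change falls
  below `tol` (default 1e-8, at most 1000 iterations); non-convergence is
  returned with `converged = FALSE`, never an error. The observed-data
  log-likelihood trace is stored and is non-decreasing, which the test
  suite asserts at every iteration.
* **Missing genotypes** are marginalized by enumerating both alleles at
  missing sites. Enumeration is bounded by capping windows at 16 SNPs.
* **Degeneracy**: a cohort of only double heterozygotes has a ridge of
  maximum-likelihood solutions with no unique phase. The fit is flagged
  `ambiguous` (detected both by two starts reaching the same likelihood at
  different frequencies and by the explicit all-heterozygous pattern)
  rather than silently broken; the returned point is never
  likelihood-dominated.
* **Pruning**: haplotypes below 1e-4 frequency are pruned and mass
  renormalized, mirroring common haplotype-viewer behaviour.

`shared_haplotype()` assigns a haplotype to a carrier when its posterior
phase mass is at least 0.5 (configurable) and intersects these sets across
carriers; stratum frequencies for the shared haplotypes come from separate
EM runs in cases and controls. A shared background that is *common* in
both strata (e.g. ~15% in cases, ~14% in controls) is the signature of a
single ancient origin rather than close kinship among the carriers.

Two-locus `ld_stats()` reports D′ and r² from the two-SNP EM fit. One
estimator subtlety, verified empirically in the tests: with `n` unphased
individuals the null expectation of this r² is approximately 1/n (the
familiar 1/(2n) applies to 2n phased gametes).

## Relatedness: method-of-moments IBD

Cryptic relatedness is the mundane alternative to a shared ancestral
haplotype, so carrier groups are screened with the classical
method-of-moments identity-by-descent estimator. Observed
identity-by-state counts (IBS 0/1/2 across SNPs where both samples are
called) are equated to their expectations given IBD state; expectations
use unbiased estimators of the required allele-frequency products (e.g.
p²q² estimated by x(x−1)y(y−1)/[s(s−1)(s−2)(s−3)] from allele counts x, y
of s total), the standard small-sample corrections. The linear system is
triangular, so the moment solution is unique; solutions are truncated to
[0, 1] and renormalized, and π̂ = P(IBD=1)/2 + P(IBD=2). Allele
frequencies default to the full sample including the pair (a founders-only
vector can be supplied).

Truncation has a knowable cost: for truly unrelated pairs the raw moment
solution is centred at zero, and clipping its negative excursions biases
π̂ upward by an amount of order the per-pair sampling SD, which shrinks
as 1/√(number of SNPs). Validation therefore sizes the null simulation so
this noise floor sits well below the tolerance being asserted: the
unrelated-bias check runs on 20,000-SNP cohorts (measured mean ≈ 0.011),
while duplicate (π̂ ≥ 0.95) and full-sib (mean within 0.05 of 0.5) checks
run at 2,000 SNPs where the benchmark is far from the floor.

## Substructure and the cluster carrier-enrichment test

Ancestry principal components are computed from the column-standardized
dosage matrix (missing values imputed to the column mean, monomorphic
columns dropped) by SVD. Subclusters can come from k-means on the
components (fixed seed on a private stream), rectangular gates, or
externally supplied labels. Within a subcluster, carrier enrichment in
cases versus controls uses the two-proportion Z test with pooled variance
and no continuity correction, two-sided; with published worked-example
counts (8 of 358 cases versus 0 of 337 controls) it reproduces Z = 2.76,
P = .006. When the pooled proportion is 0 or 1 there is no variance and
the test reports z = 0 with a degenerate flag.

## Collapsed burden regression

Gene-set burden uses the Combined and Multivariate Collapsing idea:
qualifying variants (impact class in the chosen set, gene in the gene set,
sample MAF ≤ `maf_max`, default 0.01) are collapsed per sample. The
default collapse is the per-allele *count* (a published per-unit log-odds
of ~0.06 is consistent with a count scale); the classical 0/1 *indicator*
collapse is an option. Status is regressed on the burden by
maximum-likelihood logistic regression with covariates for sex, age
(linear), sequencing center (one-hot, first level reference; constant
covariates are dropped automatically) and the leading ancestry components
(default 2 — the number visualized in typical ancestry plots; the count is
configurable because there is no single right answer). Complete or
quasi-complete separation — inevitable when a case-only variant set is
tested in a small cohort — is detected and handled by a Firth-penalized
fit (Newton iteration on the leverage-adjusted score), flagged in the
result rather than silently swapped in.

The type-I error of this procedure is validated by a 500-replicate null
simulation at n = 2000 (rejection rate within binomial error of 0.05) and
parameter recovery by simulations with true log-OR 0.3.

## Pathway over-representation

Gene-network enrichment is the hypergeometric upper tail: drawing the
network's genes from a universe of `universe_size` genes of which
`n_annotated` belong to the pathway, P(X ≥ observed). The expected count
is network × annotated / universe and fold enrichment is
observed/expected (so fold × expected = observed exactly). The universe
defaults to 20,996 — the annotated protein-coding gene count consistent
with published expected values (30 × 42 / 20996 ≈ 0.060) — and is
configurable since annotation universes differ. P-values are adjusted by
Benjamini–Hochberg step-up across pathways.

## Pedigree sharing filters

For affected-relative designs, `shared_in_affected()` keeps variants
carried by every genotyped affected member; ungenotyped affecteds are
ignored. A missing call in a genotyped affected member *blocks* sharing by
default (the conservative reading), with a config override to ignore
missing members per site. `apply_family_filters()` then applies
population-frequency (every listed population AF ≤ `max_pop_af`),
impact-class, and gene-relevance filters. Pathogenicity is
operationalized as the impact-class filter, with a hook for an external
score column and threshold, because in-silico predictor choices vary
across pipelines. The three filters are independent predicates, so the
retained set is order-invariant (asserted in the tests); only the
per-step removal counts depend on the stated order. An explicitly empty
relevance gene list is rejected as distinct from "no relevance filter".

## The synthetic cohort generator

`simulate_cohort()` produces the structure the analysis assumes, with
ground truth recorded for every planted feature:

* **Subpopulations** follow a Balding–Nichols model: ancestral background
  frequencies uniform on `maf_range` (default 0.05–0.5), subpopulation
  frequencies Beta(p(1−F)/F, (1−p)(1−F)/F), genotypes Hardy–Weinberg
  within subpopulation. The latent frequencies are returned so tests can
  check the F·p(1−p) variance law exactly.
* **Planted variants** get exactly their specified carrier counts,
  heterozygous by default (recurrent rare risk alleles are seen almost
  exclusively as heterozygotes; homozygous planting is an option).
* **Haplotype backgrounds**: carriers of a variant marked
  `on_shared_haplotype` receive one designated window haplotype on the
  carrier chromosome; all other gametes in the window are drawn from a
  small pool of background haplotypes with Dirichlet weights. The pool —
  rather than per-SNP-independent draws — reflects the limited haplotype
  diversity of real tens-of-kb windows, where recombination is negligible
  (complete linkage within the window); without it, carrier phase would
  be genuinely ambiguous in a way real regional LD is not. Stratum
  frequencies of the designated haplotype default to 15% in cases and 14%
  in controls, the scale on which an old shared background is observed.
* **Cryptic relatives** (duplicate, parent–offspring, full-sib,
  first-cousin pairs) are produced by gamete dropping from shared
  founders, independently per SNP — adequate for moment-based IBD, which
  is itself per-SNP.
* **Covariates** default to the confounding direction of a late-onset
  dementia study: case ages N(76.4, 9.3) versus control ages N(86.5, 4.5)
  (controls must survive dementia-free to an older age), 57%/59% female.
* **Determinism**: the whole cohort is a function of the config including
  its seed; identical configs give byte-identical output files.

What the generator does **not** emulate: a realistic exome site-frequency
spectrum, genotyping or sequencing error, linkage between background SNPs
outside designated windows, or selection of participants by risk score.
Passing tests on these cohorts therefore demonstrate correctness of the
estimators and filters under their stated assumptions, not robustness to
real-data artefacts such as batch-variable call rates or population-scale
LD.

## Validation strategy and problem sizes

The original cohort data behind the published analyses are
access-controlled, so the test suite validates each stage against
independent oracles at sizes chosen to finish in minutes: EM haplotype
frequencies against an exhaustive-simplex grid-plus-polish maximizer
(windows of ≤ 3 SNPs, ≤ 100 individuals, agreement to 1e-4);
hypergeometric p-values against explicit combinatorial enumeration
(universes ≤ 50); the filtering engine against a brute-force re-evaluation
of its definition (100-variant toy cohorts) and exact recovery of planted
truth; burden-test calibration at n = 2000 over 500 null replicates; IBD
benchmarks over 50 simulated sib pairs and 435 unrelated pairs (SNP counts
as discussed above); and shared-haplotype recovery on 400 + 400 cohorts.
Published worked examples with printed inputs (the 8/358 vs 0/337 Z test,
the 4/5617 carrier frequency, the 22-of-42 pathway overlap against a
20,996-gene universe) are reproduced to their printed precision.

## Worked example

```{r example}
cfg <- simulation_config(
  n_cases = 300, n_controls = 300, n_background_snps = 2000,
  planted = list(planted_variant("NOTCH3", "MODERATE", case_carriers = 10)),
  seed = 7)
sim <- simulate_cohort(cfg)

counts <- count_carriers(sim$genotypes, sim$samples)
hits <- apply_scheme(counts, sim$annotations,
                     filter_scheme("genomewide_moderate_high"))
hits[, c("variant_key", "gene", "impact",
         "n_case_carriers", "n_control_carriers")]

carriers <- rownames(sim$genotypes)[
  sim$genotypes[, hits$variant_key[1]] >= 1]
mean_pairwise_pihat(sim$genotypes, carriers)[c("mean", "sd")]
```

## Known limitations

* EM haplotype windows are limited to 16 SNPs by the enumeration bound;
  long windows should be thinned (e.g. by MAF or spacing) first.
* Moment-based π̂ carries the truncation bias discussed above; treat
  small positive means over many pairs as a noise floor, not as evidence
  of relatedness.
* The Firth fallback reports Wald intervals, which are approximate near
  separation; profile-likelihood intervals are not implemented.
* The simulator's unlinked background SNPs make PCA and IBD slightly
  cleaner than real data; effective marker counts in applications should
  be LD-pruned before comparing to the simulated benchmarks.
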