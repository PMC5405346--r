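---
title: "GBSpanel: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{GBSpanel: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`GBSpanel` analyzes germplasm collections genotyped by
genotyping-by-sequencing (GBS): reference-free SNP panels with low,
overdispersed read depth and heavy missingness, scored on hundreds of
mostly-inbred accessions. This vignette records the models the package
implements, the parameters that matter and their defaults, the
numerical choices, and what the synthetic-data tests do and do not
demonstrate.

## Genotype calling from allele read depths

Each cell of an `AlleleDepthMatrix` holds read counts `(a, b)` for the
two alleles of a biallelic tag SNP. Likelihood-based callers are the
norm for whole-genome data, but GBS germplasm panels are commonly
called with transparent fraction thresholds, and that is what
`callGenotypes()` does. With `f` the fraction of reads carrying the
cell's less-sequenced ("alternate") allele:

* `f < 0.05` — homozygous for the cell's majority allele;
* `0.05 ≤ f < 0.10` — missing (the ambiguous band);
* `f ≥ 0.10` — heterozygous;
* zero total depth — missing, before any fraction is formed.

Interval endpoints are deliberately half-open — "fewer than 5%" is
strict, "10% or more" inclusive — so exactly 5% falls in the ambiguous
band. Defining the alternate allele per cell keeps `f ≤ 0.5` and lets
homozygotes for either allele be called symmetrically; an `altMode =
"locus"` option instead fixes the alternate allele per locus (the
allele with the lower total read count) and applies the bands to that
allele's fraction literally, which sends cells homozygous for the
alternate allele into the heterozygous band. We default to the
per-cell reading because the literal per-locus one cannot call an
alternate homozygote at all — a property no working pipeline can have
had.

Per-locus statistics are computed from calls, not reads: minor allele
frequency counts two copies per homozygote and one per heterozygote
over non-missing calls (so `maf ≤ 0.5` by construction), call rate is
the non-missing fraction of accessions, heterozygosity the fraction of
non-missing calls that are heterozygous.

`depthSummary()` reports mean depth over covered cells and percent
missing per SNP. "SNPs with read depth ≥ d" is ambiguous for a
panel — per-cell minimum, or mean? The package exposes both
(`depthCriterion`), defaulting to the stricter per-cell rule (every
cell with a non-missing call has total depth ≥ d).

## Marker filtering and the dual-catalog union

`filterMarkers()` retains a SNP iff `maf ≥ 0.01`, `callRate ≥ 0.2` and
`hetRate ≤ 0.25`. The heterozygosity ceiling is the paralog filter: in
a collection of selfing lines no genuine locus should be 25%
heterozygous, but a collapsed paralog pair will be. Exclusions are
attributed to the *first* failing rule in the fixed order (call rate,
maf, het rate); the rules themselves are unordered, but a fixed
attribution order makes the `FilterReport` deterministic and lets the
counts reconcile exactly: retained + per-rule exclusions = input.

Reference-free pipelines discover SNPs on tag dialects of different
lengths (64-bp and 80-bp truncations here). `unionCatalogs()` pairs a
locus from each side when the shorter tag occurs within the longer one
at ≥ 95% identity over ≥ 60 bp — full-length embedding with at most 3
mismatches — *and* the SNP offsets coincide under the alignment. The
published pipelines used BLASTN with an E-value cutoff for this step;
E-values depend on database size and are not reproducible for
in-memory tag sets, so the package uses explicit identity/overlap
thresholds chosen to accept the same ≤3-mismatch regime the discovery
pipelines tolerate when merging loci. Offset coincidence is our own
assumption: nothing else ties the two SNPs to the same variant.
Ambiguous pairings keep the best identity (ties to the
lexicographically smallest partner id) with a warning. Merged loci take
the 64-bp pipeline's genotypes; unpaired loci pass through unchanged,
so locus membership of the union is symmetric in the two inputs even
though genotype precedence is not.

`firstSnpPerTag()` implements the multi-SNP-tag rule: per tag, SNPs
ordered by offset, the first one passing the marker filter is kept.
`tagTaxaFilter()` mirrors the discovery-side practice of dropping tags
seen in fewer than five accessions.

## Private alleles standardized for missing data

Raw private-allele counts are driven by group size and missingness: a
large, well-covered group "observes" more alleles. The package
standardizes by data content: each accession scores
`1 − (proportion missing)`, and every group is downsampled — accessions
added in uniformly random order — until the cumulative score reaches a
common threshold `T` within a tolerance band `±0.5`, defaulting `T` to
the total score of the group with the least data. Because one addition
can overshoot the band, a draw that exceeds `T + 0.5` is rejected and
restarted with a fresh order (budget 1000 restarts); the accepted
subset's score always lies in `[T − 0.5, T + 0.5]`. This
reject-and-restart rule is our resolution of the band's edge case; the
procedure it standardizes does not say what happens when a single
accession jumps past the band.

`uniqueAlleles()` counts, over all loci and both alleles, the alleles
observed (≥ 1 non-missing call carrying ≥ 1 copy) in the focal subset
and unobserved in the comparison subset. Missing calls carry no
alleles — absence of evidence is treated as absence, which is exactly
why the score standardization matters and why counts are only
comparable *between* groups downsampled to the same score, not as
absolute quantities. `standardizedUniqueAlleles()` repeats the
downsampling (default 100 iterations) for every group, pools the
downsampled members of the comparison groups (both sides are
downsampled by default; `downsampleComparison = FALSE` is available
because the alternative reading is defensible), and reports
per-pair means and standard deviations.

## Probabilistic PCA with missing genotypes

Genotypes are coded as minor-allele dosage (0/1/2) with accessions as
observations. `ppcaGenotypes()` fits the probabilistic PCA latent
model by EM, treating missing cells as latent: each iteration computes
expected scores under the current loadings and residual variance,
re-imputes the missing cells from the low-rank reconstruction, and
re-centers. After convergence (relative change in the observed-cell
reconstruction error and residual variance below `tol = 1e-6`, capped
at `maxIter = 1000`), the completed matrix is decomposed by SVD, so
components are orthogonal, ordered by explained variance, and — when no
data are missing — identical to ordinary PCA, which the tests assert to
`1e-6`. Signs are fixed by making each component's largest-magnitude
loading positive; non-convergence warns and flags rather than errors.
Loadings are initialized from a seeded standard-normal draw
(`seed = 1`), so results are reproducible by default.

## Mixed-model association scan

The trait is binary but is fitted as a 0/1 quantitative response —
the standard practice of the mixed-model GWAS tools this scan mirrors,
not a logistic model. The model is
`y = μ + PCs·b + x·β + u + e`, `u ~ (0, σ²_g K)`, `e ~ (0, σ²_e I)`,
with `K` the VanRaden genomic relationship matrix (centered dosages,
missing values mean-imputed, normalizer `2Σp(1−p)`; monomorphic loci
dropped). On the eigenbasis of `K` the covariance is diagonal, so the
REML profile likelihood depends on one scalar, the variance ratio
`λ = σ²_g/σ²_e`; it is maximized by bounded search over
`log λ ∈ [−10, 10]` (tolerance `1e-8`, boundary candidates checked)
once on the null model, and every SNP is then tested by generalized
least squares at that fixed ratio with a Wald t-test on `n − q` degrees
of freedom — the P3D/EMMAX approximation, chosen for determinism and
speed. `method = "exact"` re-estimates the ratio per marker. With
`K = NULL` the same code path is exactly ordinary least squares, which
the tests assert to `1e-8` against `lm()`. Missing genotypes are
mean-imputed per SNP; SNPs monomorphic after alignment are skipped with
`NA`. The Bonferroni flag uses `α/m` with `m` the number of SNPs
actually tested. `selectPcsBIC()` chooses how many leading PCs enter
the null model by maximum-likelihood BIC with the fixed effects plus
both variance components counted as parameters.

## Core selection as allele set cover

`greedyCore()` treats each of the `2 × nLoci` observed alleles as an
element to cover and each eligible accession as the set of alleles it
carries, then runs the classical greedy set-cover heuristic: add the
accession covering the most uncovered alleles (ties broken by higher
call rate, then lexicographic id), stop at the coverage target, and
make one backward pass dropping members made redundant by later
additions. The published protocol used a stochastic, runtime-bounded
search tool for this step; we substitute the deterministic greedy
heuristic as a deliberate design choice — the scientific contract is
the coverage constraint, not the search trajectory, and greedy set
cover carries the classical `ln(n) + 1` approximation guarantee, which
the tests verify against exhaustive enumeration on small instances.
`intensitySweep()` reproduces the protocol's outer loop: sampling
intensities from 0.95 down to 0.05 cap the core size at
`⌈i × n_eligible⌉`, and the smallest core meeting the target wins.
Each core also reports `mafRetention`, the fraction of SNPs whose
within-core MAF still reaches the 0.01 panel threshold. Eligibility is
a boolean mask (genebank availability in the motivating use case).

## The synthetic collection

`simConfig()` defaults encode the study conditions the package is
aimed at: 431 accessions in five genetic groups, 3000 biallelic loci,
Balding–Nichols group divergence `F = 0.15` (a typical crop-collection
differentiation), residual heterozygosity 0.5% (selfed lines),
negative-binomial read depth with mean 4 and size 0.8 (GBS depth is
strongly overdispersed; a low mean with a heavy right tail), per-read
error 1%, and tag dropout 0.30 — chosen so that, combined with the
depth distribution's own zero mass and the ambiguous-band rule, about
47% of calls per SNP are missing, the missingness regime of the
motivating data. Ancestral frequencies are uniform on (0.05, 0.95);
group frequencies are Beta draws around them; genotypes are drawn with
per-cell autozygosity probability `1 − residualHet/(2q(1−q))` (clipped
to `[0,1]`), so expected heterozygosity equals `residualHet` wherever
attainable. A single seed drives separate derived streams for the
population, depth, catalog and trait stages, so each stage is
independently reproducible. The mechanism behind the missingness —
dropout versus sampling zeros versus the ambiguous band — is not
identifiable from published summaries, so all three knobs are exposed
rather than fixing a split.

`simulateDualCatalogs()` embeds each 64-bp tag in an 80-bp tag for a
chosen overlap fraction (optionally with up to three injected
mismatches) and returns the true pairing, giving `unionCatalogs()` a
ground truth; `simulateBinaryTrait()` draws a phenotype from a
penetrance table at a causal locus, defaulting to a fully penetrant
trait recessive for the minor allele at the locus with realized MAF
closest to 0.3 — an intermediate-frequency major gene, the classic
proof-of-concept target.

What the simulator does *not* model: linkage disequilibrium along a
genetic map (loci are exchangeable), restriction-site polymorphism or
other non-random dropout, allele-specific sequencing bias, and
sequence-level read errors (errors flip alleles, never create third
alleles). Passing tests therefore show the estimators are correct
under a clean, structured, low-coverage regime — not that they are
robust to every artifact of real GBS libraries.

## Problem sizes and runtime choices

The test suite and acceptance script run at deliberately modest sizes:
full-scale runs (431 × 3000) for core selection, 100–200 accessions
and a few hundred loci for calling-accuracy, power and null-calibration
simulations, 20 replicates for detection-rate checks, 2000 SNPs for
p-value uniformity, and exhaustive enumeration (all orderings, all
2^8 subsets) only on instances small enough to enumerate. These sizes
give stable Monte-Carlo margins for the properties being checked while
keeping the whole suite to a few minutes on one CPU.

## Known limitations

* The threshold caller ignores depth-dependent confidence: a (1, 0)
  cell and a (40, 0) cell are both confident homozygotes to it. At the
  mean depth 4 regime this inflates apparent homozygosity of true
  heterozygotes (a 50/50 split at depth 2 lands on one allele half the
  time); the filters, not the caller, are what keep such loci usable.
* Private-allele counts treat "unobserved" as "absent"; they are
  comparative statistics under equalized scores, not estimates of
  population allele counts (no rarefaction model is fitted).
* The P3D approximation understates per-marker variance-ratio
  uncertainty; for strongly structured traits the `"exact"` method is
  available at linear extra cost.
* `greedyCore()` is deterministic and near-optimal, but is not
  guaranteed minimal; the sweep bounds, never below, the sizes a
  stochastic optimizer might find.
* The binary trait is fitted by a linear mixed model; for very rare
  phenotypes a logistic mixed model would be better calibrated, and is
  out of scope here.
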