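---
title: "Methods: testing panmixia with a small SNP panel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: testing panmixia with a small SNP panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

panmix asks one question of a genotype table: do individuals sampled from
putative subgroups of a population — here, fish trapped in the littoral,
benthic and pelagic zones of a single small lake — behave genetically like
one interbreeding unit?  The package approaches the question from four
directions that fail in different ways, so that agreement among them is
informative: overall differentiation (Fst) against a simulated sampling
null, kinship-matrix principal components, within-group pairwise
relatedness against a permutation null, and a Bayesian admixture model.
This vignette records the models, their assumptions, the tunable
parameters, and the numerical and design choices behind the code.

## Data model

Genotypes are unphased biallelic SNP calls for `N` individuals at `L`
unlinked loci, with per-sample habitat (benthic / littoral / pelagic) and
genotyping batch labels.  `GenotypeTable` and `DosageMatrix` extend
`SummarizedExperiment` (loci as rows, samples as columns).  `toDosage()`
orients each locus by the minor allele of the sample at hand; an exact
0.50/0.50 tie resolves to the alphabetically later symbol, a deterministic
convention the downstream estimators are invariant to.  Missing calls are
never imputed at the I/O layer; each analysis declares its own policy
(per-locus complete cases for summaries and Fst, pairwise-complete samples
for r², mean imputation for kinship, pair-wise locus exclusion for
relatedness, zero allele copies for the admixture likelihood).  Two
genotyping batches with partially overlapping SNP panels are reconciled by
`mergeBatches()` as union-of-samples over intersection-of-loci — the
natural reading when all that is known of a two-batch design is the size
of its common SNP set.

## Locus quality control

`qcFilter()` applies the standard small-panel chain: monomorphic loci
(zero minor-allele copies) are dropped first, then loci failing an exact
Hardy-Weinberg test at `hweAlpha`.  The test is the conditional exact
test: given the allele counts, heterozygote counts follow
$P(n_{AB}) \propto n!\,2^{n_{AB}} / (n_{AA}!\,n_{AB}!\,n_{BB}!)$, and the
two-sided P-value sums all configurations whose probability does not
exceed the observed one (probability-ordering convention).  The default
`hweAlpha = 0.001` is meant for genotyping-failure screening: it removes
grossly deviant loci (the kind that show P-values ten orders of magnitude
smaller) while leaving ordinary sampling noise alone, and is
configurable.  Linkage is screened with the composite measure: squared
Pearson correlation of dosage vectors over pairwise-complete samples —
what is computable from unphased data without haplotype EM.  An
all-heterozygote locus is polymorphic (and far out of HWE) but has zero
dosage variance; it is excluded from the r² screen, not from the panel.

## Weir–Cockerham Fst

`wcOverall()` implements the 1984 variance-components estimator with
unequal group sizes: per locus the components a (among populations), b
(among individuals within populations) and c (within individuals) from
the $\bar n$, $n_c$, $\bar p$, $s^2$, $\bar h$ formulation, with
individuals missing at a locus dropped from that locus only.  The overall
estimate is the ratio of sums $\sum_\ell a_\ell / \sum_\ell
(a_\ell+b_\ell+c_\ell)$ — never the mean of per-locus ratios — with
zero-variance loci excluded from both sums, and negative per-locus values
retained for unbiasedness.  The test suite checks the components against
an independent oracle that computes the same quantities through the
nested-ANOVA mean-squares route.

## The island-model null for Fst

An observed theta near zero is only interpretable against the sampling
distribution of theta for this design (159 individuals, 32 SNPs).
`simulateIsland()` provides it: `d = 3` demes of `N = 1500` diploids at
`3150` unlinked loci, symmetric conservative migration at per-generation
rate `m`, Wright-Fisher drift.  The simulator works at the gamete-pool
level — deterministic migration mixes the deme gamete pools, then `2N`
gametes per deme are binomially resampled — which for unlinked loci is
exactly the diploid Wright-Fisher island model marginally per locus;
diploid genotypes are drawn Hardy-Weinberg within demes at sampling time.
Founding frequencies are uniform on [0.05, 0.95] — a choice that
guarantees polymorphism at sampling time without biasing toward rare
alleles — and loci fixed during burn-in are excluded from resampling.

Burn-in runs to "migration-drift equilibrium": realized Fst is monitored
every 50 generations after a 200-generation minimum, and the run stops
when the trailing five-checkpoint trend is statistically indistinguishable
from zero or practically negligible (<5% relative change across the
window), capped at `10 * demeSize` generations.  The practical arm matters
because realized Fst is an autocorrelated drift process whose local slope
never settles exactly at zero; at the migration rates involved the
equilibration time constant is roughly $1/(2m + 1/2N)$ generations, far
inside the cap.  `calibrateMigration()` starts from Wright's closed form
$F_{st} \approx 1/(1 + 4Nm(d/(d-1))^2)$ and bisects on $\log m$ until the
mean realized Fst over three replicate simulations is within a relative
tolerance of the target (5% is used for the reproduction runs; the closed
form alone lands ~10% off).  Calibration simulations use 800 loci — the
realized Fst depends only on the demography, so fewer loci only widen the
estimate's Monte-Carlo error, which the tolerance absorbs.

`resampleFstNull()` then repeats the study design: sample 55/55/49
individuals per deme and 32 polymorphic loci without replacement, compute
overall theta with demes as groups, 10,000 times (2,000 in the test
suite), and report the lower-tail empirical P of the observed theta.  The
plug-in fraction is the default (matching the convention under which the
study printed its P-value); the (count+1)/(reps+1) form is a flag.  A
fast Balding-Nichols shortcut (deme frequencies from
$\mathrm{Beta}(p(1-F)/F,\,(1-p)(1-F)/F)$, Hardy-Weinberg within demes) is
available through the data generator for checks that need speed rather
than a forward demography.

## Kinship and principal components

`standardizeDosage()` mean-imputes missing dosages (an imputed cell is
exactly zero after centering, the least-assumption choice), centers each
locus and scales by the empirical standard deviation — the "standard
score" — or, as an option, by $\sqrt{2p(1-p)}$; under Hardy-Weinberg
proportions the two agree in expectation.  `kinshipMatrix()` forms
$K = MM^T/2L$ with $L$ the number of loci — the divisor is twice the
number of SNPs in use, not twice the sample size.  Rows of K sum to
zero by construction, and with empirical scaling the mean diagonal is
about 0.5.  `kinshipPca()` returns the full eigendecomposition with each
eigenvector's sign fixed so its largest-magnitude loading is positive
(eigenvectors are sign-ambiguous; the convention makes seeded runs
comparable).  Group separation on a component is judged by the one-way
variance ratio of the scores against its label-permutation 95th
percentile — an exact-level 5% test under exchangeability, which is worth
remembering when reading a single run: one panmictic dataset in twenty
will "separate" by construction.

## Pairwise relatedness and the permutation test

Six estimators of pairwise relatedness are implemented from their
published formulas.  All outputs are on the relatedness scale r — twice
the kinship coefficient — a convention worth stating because coancestry
plots in the field are routinely ambiguous between the two scales.  The
estimators: Queller-Goodnight (numerators and denominators summed over loci and
both focal orderings; a heterozygous focal individual contributes nothing
at a biallelic locus, which the ratio-of-sums absorbs), the Li similarity
index, Lynch-Ritland (each ordering weighted by its own locus weights,
then averaged), Ritland's method of moments, Wang's moment estimator, and
the dyadic maximum-likelihood estimator of Milligan.  Reference allele
frequencies default to the full sample including the focal dyad (the
common package default; at n = 159 the resulting bias is inside the
recovery tolerances, and the tests that know the truth pass it
explicitly).

Two implementation notes.  Wang's estimator is coded in its biallelic
specialization: with two alleles the similarity classes reduce to
identical / one-shared / opposite-homozygote, whose expectations given
the IBD-state probabilities $(k_0,k_1,k_2)$ we derive directly —
$P(\text{identical}\mid k_0) = 2a_2^2-a_4$,
$P(\text{one-shared}\mid k_0) = 4(a_3-a_4)$,
$P(\text{one-shared}\mid k_1) = 2(a_2-a_3)$,
$P(\text{opposite}\mid k_0) = 2p^2q^2$, with $a_j = p^j + q^j$ — so the
$1/(2a_2-a_3)$-weighted multilocus moment system is exactly identified
and solved in closed form.  The dyadic ML estimator assumes no inbreeding
(three IBD states, not nine) and maximizes the dyad likelihood by EM on
the state mixture: the log-likelihood is concave on the simplex, EM is
monotone and vectorizes over all dyads simultaneously, and iteration
stops at a 1e-6 change in the state probabilities (convergence is
sublinear when the optimum sits on the simplex boundary, so likelihood
comparisons there carry a ~1e-4 margin).  Being constrained to [0, 1],
dyadml is upward-biased for unrelated pairs — visible in the recovery
tests and expected of constrained estimators.

`coancestryPermTest()` permutes individuals across the groups (sizes
fixed, 2,500 permutations by default), recomputes each group's mean
within-group r from the unchanged pairwise values, and reports
$(1 + \#\{\text{null} \ge \text{obs}\})/(1 + n_{perm})$ — the add-one
form, so P is never zero.  Significance uses a Bonferroni threshold of
familyAlpha / nTests, default 0.05/21 ≈ 0.002 (three groups by seven
estimators in the original design; this implementation ships six of the
seven — the triadic likelihood estimator needs a reference third
individual and a much larger state space, and the permutation machinery
is estimator-agnostic, so it is left as an extension point).  Pairs
sharing no typed locus are dropped with a warning.

## Admixture

`gibbsAdmixture()` fits the classic admixture model for unlinked
biallelic loci with independent cluster frequencies: membership rows
$Q_i \sim \mathrm{Dirichlet}(\alpha)$ with a single inferred
$\alpha \in (0, 10]$ (uniform prior, Metropolis update), cluster
minor-allele frequencies with uniform Beta priors, and per-allele-copy
latent cluster assignments.  One Gibbs cycle resamples assignments, P, Q
and $\alpha$; missing genotypes contribute no copies (exact
marginalization under multinomial sampling).  The source study does not
state its model variant beyond the location prior; independent-frequency
admixture is assumed and documented.  Its location prior is offered only
as a simplified, off-by-default option (group-specific Dirichlet means
with Metropolis updates): under the panmixia result the prior is
immaterial, and the full original prior model is out of scope.

No relabeling is applied within a chain.  Under panmixia the posterior is
exchangeable over cluster labels, so the posterior-mean Q converging to
uniform rows is itself the signal; `symmetryDiagnostic()` operationalizes
it as the maximum L∞ distance of any Q row from $(1/K,\dots,1/K)$, with
0.1 the documented no-structure threshold.  For comparing separate runs,
`alignClusters()` does greedy correlation matching.

Two desk-scale choices.  Default cycles are 5,000 burn-in + 2,000
sampling (study-scale 250,000/50,000 is a matter of passing larger
values); the reproduction runs in the acceptance suite lengthen sampling
to 8,000 cycles because the diagnostic is a max-over-individuals extreme
statistic whose Monte-Carlo error at 2,000 stored cycles is comparable to
the 0.1 threshold.  And the $\alpha$ proposal step (initially 0.05)
adapts during burn-in toward a 0.3-0.5 acceptance rate, frozen once
sampling starts: a fixed 0.05 random walk started at $\alpha = 1$ cannot
reach its stationary region within a desk-scale burn-in, which inflates
the diagnostic for reasons that have nothing to do with the data.

## The synthetic-data generator

`generateGenotypes()` emulates the study conditions: 159 individuals in
groups of 55/55/49 at the 32 panel loci, with per-locus missingness
matching the panel's reported genotype counts (placed uniformly at
random; only per-locus totals are known).  Group labels under panmixia
are assigned in blocks and carry no signal by construction.  The panel
itself is transcribed with its reported frequencies; four rows print
allele-frequency pairs that do not sum to one and are repaired as
minor = 1 − major, flagged in the `repaired` column.  Structured data
come either from the Balding-Nichols shortcut or the forward simulator;
pedigree dyads transmit founder alleles Mendelianly with the identity
coefficients recorded in the truth metadata; the QC fixture plants 22
monomorphic loci and one all-heterozygote HWE violation (re-drawing a
rare allele into any panel locus that comes out monomorphic by sampling,
so the planted counts are exact).

What the generator does not emulate: genotyping error, allelic dropout,
batch-specific missingness patterns, linkage, inbreeding, and any real
pedigree structure in the lake.  Tests passing on these data show that
the estimators and tests behave correctly under their own model
assumptions at the study's sample sizes — not that those assumptions hold
in any particular lake.

## Problem sizes and runtime choices

The test suite runs the full study design where it matters (159 × 32
throughout; 2,000-replicate Fst nulls; 2,500 permutations; 500-dyad
recovery panels; K = 2–4 admixture at 5,000 + 8,000 cycles) and reduced
demographies (demes of 150–500) for the simulator's unit properties.
Stochastic single-draw checks with a nominal false-positive rate (the
PCA separation test, the permutation-calibration check) are asserted as
rates over several independently seeded datasets rather than on one
draw.  All randomness flows through explicit seeds; identical seeds
reproduce every result bit-identically.

## Known limitations

- Biallelic, unphased, unlinked SNPs only; no genotype likelihoods.
- dyadml ignores inbreeding (three IBD states); its constraint biases it
  upward near r = 0.
- The island model is symmetric and conservative; no stepping-stone or
  asymmetric migration.
- The location prior is a simplified stand-in for the original prior
  model, and no model-choice machinery for K is provided.
- The kinship PCA is descriptive; no mixed-model association testing.
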