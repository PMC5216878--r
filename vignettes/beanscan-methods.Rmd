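---
title: "Methods: diversity, divergence and selection scans for domestication panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversity, divergence and selection scans for domestication panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical machinery of `beanscan`: the
estimators, the demographic null model behind the selection scan, the
synthetic-data generator used to validate everything, and the numerical
and design choices a maintainer would want to know about. The study design
the package mirrors is a multi-locus amplicon panel in common bean: ~49
gene fragments of 150–900 bp, sequenced in ~19 Mesoamerican wild (MW) and
~20 Mesoamerican domesticated (MD) highly inbred accessions, with Andean
and congeneric outgroup controls. Inbred lines are treated as haploid
sequences throughout (one row per accession).

## Data model and missing data

Alignments are per-locus character matrices over `A,C,G,T,N,-`;
coordinates are 0-based half-open internally and 1-based inclusive in
annotation files (the GFF convention), which keeps slicing arithmetic
unambiguous. Indels are never counted as polymorphisms: the default policy
is *complete deletion per analyzed subset* — a column is unusable if any
retained accession carries `-` or `N`, so different population subsets can
legitimately use different masks. A pairwise-deletion option exists on
`nucleotide_diversity()` but is off by default; the two differ only on
gapped columns, and the published per-locus tables this package mirrors do
not state which convention produced them, so both are available.

## Diversity estimators

Per usable-site statistics follow the standard definitions: π is the mean
pairwise difference per site; θ~W~ = S/(a~n~L) with the exact harmonic sum
a~n~ = Σ 1/i; haplotype diversity uses Nei's small-sample correction
n/(n−1)·(1 − Σp²), clamped to [0, 1] against floating-point overshoot when
all haplotypes are distinct. θ~W~ uses segregating sites by default, with
an η-based variant (`type = "eta"`) because total mutation counts are
reported separately; which option produced the reference tables is not
determinable, so both are first-class.

Site classification at multi-allelic sites follows one deterministic rule:
a variable site is a *singleton* iff every non-major allele occurs exactly
once; it is *parsimony-informative* iff at least two alleles have count
≥ 2. These classes are disjoint by construction, and `S + Pi ≤ V ≤ η`
holds for every input.

Loss of diversity is reported two ways: `L = 1 − mean(dom)/mean(wild)`
over across-locus means (loci monomorphic in both contribute zeros to both
means and are retained), and `L1 = mean(1 − dom_i/wild_i)` over loci,
excluding — and counting — loci monomorphic in the wild, where the ratio
is undefined.

## Synonymous/nonsynonymous accounting and dN/dS

Site-level classification uses *observed whole-haplotype codons*, not
averaged backgrounds: a site inside a complete, fully usable codon is
synonymous if every pair of observed codons differing there encodes the
same amino acid, nonsynonymous if every such pair changes it, and `mixed`
when both occur (only possible at tri-allelic sites). In the per-region
counts a `mixed` site is tallied as nonsynonymous, since it implies an
amino-acid change; this is deterministic and consistent across
populations. Codons overlapping masked columns, and leading/trailing
partial codons, are excluded.

`nei_gojobori_dn_ds()` implements the modified proportional method:
per-position synonymous site fractions are weighted by the
transition/transversion ratio R (mutations to stop codons excluded from
the weights), pathway counting enumerates all orderings of multi-hit codon
pairs with stop-passing pathways dropped (falling back to all pathways in
the degenerate case where none survives), and proportions averaged over
all sequence pairs are corrected with the Jukes–Cantor transform
d = −(3/4)·ln(1 − 4p/3). A p-distance at or beyond 3/4 is flagged
`jc_undefined` and returned as `NA`, never clipped. R defaults to 1 (the
original proportional method) because the reference analysis does not
state the ratio it used; the value is carried in the output. Standard
errors come from a seeded bootstrap over codons (default 1000 replicates);
per-pair per-codon contributions are cached so resampling is cheap.

The rank tests keep exact tails wherever feasible: the signed-rank test
drops zero differences (Wilcoxon's convention), uses the exact
distribution for ≤ 25 untied pairs, full enumeration of sign assignments
with average ranks for ≤ 14 tied pairs, and the continuity-corrected
normal approximation beyond; the rank-sum test enumerates group
assignments under ties when `choose(n+m, n) ≤ 50000`. The binomial test
for excess private coding mutations is one-sided, `P(X ≥ observed)`, with
the null proportion taken either from the raw private-mutation split of
the reference population (the literal null) or from per-bp private rates
weighted by analyzed region lengths; the two coincide when both
populations were scored over the same regions.

## Shared and private polymorphism

The partition works per mutation, mirroring η: at each usable pooled site,
every allele beyond the pooled-major one is classified *shared* if it
segregates within both populations, otherwise *private* to the population
where it segregates (an allele fixed in one population and absent from the
other — a fixed-difference component at an otherwise variable site — is
assigned to the population carrying it, preserving the conservation
identity). Sites variable in neither population are skipped, so
`SM + P_MW + P_MD` equals pooled η restricted to sites variable in at
least one population, which the test suite asserts on random data.

One note on the transcription fixtures shipped under `inst/extdata`: the
whole-sequence and coding columns of the reference per-locus
FST/mutation table reconcile exactly with their printed footer
(205/213/14 and 70/64/8; per-region means 0.16/0.14/0.17; 26 significant
loci), and the per-locus cells are row-wise consistent
(whole = coding + noncoding). The printed noncoding footer for shared and
wild-private totals, however, disagrees with its own column cells (which
sum to 111 and 137); those two printed values are therefore not asserted
by `replicate_printed_summaries()` — a print inconsistency in the source
table, not a property of the arithmetic.

## Differentiation

Hudson's FST is 1 − H~w~/H~b~ with H~w~ the *equally weighted* average of
the two within-population mean pairwise differences (not weighted by pair
counts); the variants differ only under unequal sample sizes, and the
equal-weight form matches the estimator the reference per-locus tables
were produced with. Monomorphic pooled loci are `NA` ("na" cells);
negative estimates are reported as computed. Permutation p-values use the
add-one estimator `(1 + #{FST* ≥ FST})/(B + 1)` so p is never exactly zero
at finite B; on loci with very few SNPs the permuted statistic takes few
distinct values, making these p-values super-uniform (conservative) —
the calibration test checks uniformity on the anti-conservative side only.

AMOVA uses the haplotypic convention: the squared molecular distance
between two sequences is their number of pairwise differences. Two-level
variance components follow the standard sums-of-squares decomposition with
n₀ weighting; Φ~ST~ = σ²~a~/(σ²~a~+σ²~w~) and its permutation p shuffles
labels. Note the component estimate σ²~a~ can be negative (e.g. one
population duplicated as two), in which case Φ~ST~ ≤ 0; degenerate
all-identical input yields `NA`.

## The coalescent engine and demographic models

The engine (`src/coalescent.cpp`) simulates the structured coalescent over
piecewise-constant epochs: per-deme sizes, a backward per-lineage
migration-rate matrix, and mass moves (population merges) applied at epoch
entry. Conventions: haploid lineages, pair coalescence rate 1/N per
generation (so θ = 2Nμ per site), time in generations, all randomness from
R's RNG so `set.seed()` makes every simulation — and therefore every scan
— byte-reproducible. Mutations are dropped as infinite-sites events
(Poisson per branch). Exponential growth is discretized into a log-linear
staircase (default 12 steps), a standard and numerically safe
approximation at these time scales. Fragments are treated as
non-recombining, appropriate for ≤ 900 bp amplicons in a selfing species;
there is no recombination hook in the engine, which is the main structural
simplification.

Two four-population scenarios are parameterized with the conventional
symbols (T_ANC, T_BMD/T_EMD, N_MW, I_MD, M_WD, ...): both derive the
Andean and Mesoamerican wild pools from one ancestral pool with an
independent domestication bottleneck in each; Model 1 places the Andean
founder bottleneck recently with constant wild sizes, Model 2 pins it to
the split and lets wild pools grow exponentially toward the present.
Bottleneck intensity I (percent) is the bottleneck size as a percentage of
the pre-bottleneck ancestral wild size, applied between the end and
beginning times of the domestication window. Most analyses use the
two-population (MW, MD) reduction; the four-population topology is
exercised by the simulator's own tests.

### Default parameter values

The original prior table behind the published simulations is not public,
so the shipped values are reconstructions at literature scale, chosen to
reproduce the study conditions the package emulates; they are editable via
`demographic_model()`/JSON configs and the wide priors in
`extdata/demography_priors.json` are clearly labeled as reconstructions.

* Times (generations; annual crop, one generation per year): divergence
  T_ANC = 150000; Mesoamerican domestication window T_BMD = 8000 to
  T_EMD = 6000 (domestication beginning ~8000 years ago, lasting ~2000
  years); Andean window analogous.
* Sizes (haploid): wild N_MW = N_MWANC = 250000 — with the intron
  mutation-rate mean of 1×10⁻⁸/site/generation this gives wild noncoding
  diversity θ = 2Nμ = 5×10⁻³ per site, the magnitude observed in such
  panels; domesticated N_MD = 250000 (post-domestication expansion, the
  standard shape of published bean demographic reconstructions, which
  concentrates the diversity loss in the bottleneck window).
* Bottleneck and migration: I_MD = 0.2% with backward wild→domesticated
  migration M_WD = 5×10⁻⁵ and M_DW = 1×10⁻⁵ per lineage per generation.
  Wild–domesticated gene flow is a documented feature of sympatric bean
  populations and is part of the model structure; jointly these values
  calibrate the generator to the study's stated ~50% loss of domesticated
  diversity while keeping the neutral mean differentiation near the
  observed per-locus mean FST (≈ 0.16–0.20). This calibration matters:
  in a migration-free model, a ~50% loss forces all of it to be drift,
  whose tail then mimics selective sweeps (see *Limitations*).
* Mutation rates: intronic mean 1×10⁻⁸, exonic 10-fold lower; priors are
  lognormal around those means (or fixed, the default used in all
  known-truth tests).

## The selection scan

Each annotated gene contributes an exonic and an intronic (all noncoding
classes) fragment; monomorphic fragments and genes are excluded. Three
statistics are computed per fragment between the wild and domesticated
samples: the two-population AMOVA Φ (molecular FST), the branch-length
statistic −ln(1 − FST), and the standardized diversity difference
(π~w~ − π~d~)/(π~w~ + π~d~) (zero when both diversities are zero). The
composite index is the sum of the three z-scores, with means and standard
deviations estimated per fragment class from the *observed* panel and
applied unchanged to the simulated fragments — the only choice that puts
observed and simulated indices on one scale so that "the fraction of
simulated indices larger than the observed value" is well defined. A
component with zero spread contributes nothing; a class with fewer than
two polymorphic observed fragments cannot be normalized and is dropped
with a warning. Each component is separately swappable in code; the
difference form of the diversity component (π~w~ − π~d~, z-scored) was
evaluated and discriminates injected sweeps slightly *worse* than the
ratio form on matched-null experiments, so the ratio form stays.

Numerical choices: FST is clamped to [0, 0.99] inside the branch-length
transform (ε = 0.01), because Φ estimates of 1 arise routinely on one- or
two-SNP fragments and −ln(1 − FST) would otherwise let a single noisy
estimate dominate the composite; the clamp bounds the statistic at
−ln(0.01) ≈ 4.6 while leaving every realistically estimable value
untouched.

The null distribution per fragment class draws, per replicate, parameters
from their priors (or the known truth), a fragment length from the
observed class-specific length multiset (with replacement), and a mutation
rate from the class prior; monomorphic replicates are recorded and
excluded, so the empirical p denominator is the number of polymorphic
simulations. p-values use the literal exceedance fraction (an add-one
variant exists but is off by default), and Benjamini–Hochberg step-up
(hand-implemented, cross-checked against `p.adjust` in the tests) flags
fragments at FDR < 5%; a gene is flagged when any of its fragments is.

## The synthetic-data generator

The generator emulates the study design: 49 loci of 150–900 bp (mean
~450), exon/intron/UTR mosaics with a per-locus noncoding share drawn
between 0.3 and 0.7 (amplicon panels of this kind average roughly half
coding, half noncoding), ~8% of loci without structure information, 19 + 20
haploid samples, and the calibrated demography above as truth. Exon
reference sequences are drawn from non-stop codons, and exon mutations
that would create an internal stop in the reference frame are
rejection-resampled (a small, documented downward bias on exon mutation
counts, ~a few percent). Each locus is one non-recombining genealogy, so
locus-level statistics are strongly correlated across its fragments —
as in the real data.

Sweeps are emulated demographically, not with selection coefficients,
because the scan detects diversity-loss/differentiation signatures and
this keeps the generator engine-agnostic. A swept locus re-runs its
coalescent with (i) the domesticated bottleneck size and recent
domesticated size scaled by the retention fraction (0.05 = strong sweep),
(ii) locus-level migration set to zero (directional selection repelling
introgression at the selected site), and (iii) a *differentiation boost*:
the swept domesticated lineage remains isolated back to a configurable
merge time, anchored by default at the pool split T_ANC — the deepest
divergence available within the species — emulating fixation by
hitchhiking of a rare, deeply diverged standing haplotype. Swept loci are
always drawn from annotated loci, since an unannotated gene is invisible
to the fragment scan by construction.

What the generator does **not** emulate: base-composition and
mutation-spectrum realism, indels and alignment error, intra-locus
recombination, missing accessions per locus, and linked selection on
neutral loci. Passing tests therefore validate the estimators and the
scan's calibration under the assumed demography — not robustness to model
misfit on real data.

## FDIST-style outlier test

SNP panels are filtered (missingness > 5%, MAF ≤ 0.01 dropped;
idempotent), and per-marker unbiased pooled heterozygosity and a
Weir–Cockerham-type haploid FST are computed. The null cloud simulates a
symmetric island model (default 100 demes, two sampled) with one biallelic
mutation placed uniformly on each genealogy — the practical biallelic
approximation of an infinite-alleles run. The migration rate is first set
from the island-model expectation FST = 1/(1 + 2mN·d/(d−1)) (haploid
pairwise-time derivation) and then refined by pilot-cloud secant steps
until the realized mean per-locus FST is within 0.01 of the target, since
SNP ascertainment and the finite-sample estimator shift the realized mean
well below the time-based expectation (by ~30–40% at these sample sizes).
The envelope uses 20 equal-count heterozygosity bins with per-bin
empirical quantiles at (1 ± ci)/2 — piecewise-constant rather than
interpolated, so that at ci = 1 it degenerates exactly to the per-bin
cloud min/max and flags nothing inside support. Markers above/below the
envelope are called directional/balancing; the forced-mean option
iterates: drop current outliers, re-estimate the mean FST, re-simulate,
reclassify (max 5 rounds or convergence). The "FDR 0.01" knob of the
original workbench interface is a per-marker significance setting, not a
BH correction, and is exposed as the `ci` argument.

## Interfaces

Readers and writers cover FASTA alignments, GFF-style annotation TSVs,
two-column manifests, genotype TSVs, JSON demography configs and truth
records, and a dataset directory layout
(`loci/*.fasta`, `annotations.tsv`, `manifest.tsv`, `truth.json`) used by
the external-data adapter. The exported pipeline functions plus this
layout are the interface of the package; `scripts/acceptance.R` is the
only command-line entry point, a thin Rscript over the same functions.

## Problem sizes used in the test suite

The shipped tests run at desk scale, chosen as the package's own
validation design: oracle-equivalence loops over ≥ 200 random small
instances per estimator at 10⁻¹² tolerance; neutral-moment calibration on
2000 replicate loci (3 Monte-Carlo SEs); p-value uniformity on ~350
permutation replicates and ~400 scan fragments (KS at α = 0.01);
sweep-recovery panels of 40 genes with 4 injected sweeps at 5000 null
simulations and three fixed seeds; and a 50000-simulation FDIST cloud
against a 500-marker neutral panel.

## Limitations

* **Power ceiling of the matched-null sweep scan.** With a ~50%
  domesticated diversity loss, the same coalescent quantity that removes
  diversity (lineage coalescence during the domestication history) also
  generates neutral differentiation, so a correctly *matched* null
  produces sweep-like index values at a small but non-negligible rate;
  and a demographically emulated sweep cannot exceed the within-species
  divergence ceiling (a swept haplotype is at most as diverged as the
  deepest wild lineage). Benjamini–Hochberg at FDR 5% over ~45 fragments
  demands per-fragment exceedance probabilities of order 10⁻³, which
  typical strong-sweep fragments only sometimes reach; false positives
  stay rare, but per-panel recovery of all injected sweeps is not
  guaranteed, and the sweep-recovery acceptance test documents exactly
  this behavior. Scans of this family owe much of their real-data yield to
  nulls that are *tighter* than the data-generating process; with a
  faithful null, sensitivity at these panel sizes is intrinsically
  limited. Migration in the null (part of the model structure) mitigates
  but does not remove this.
* The biallelic single-mutation island cloud is an approximation of a
  strict infinite-alleles simulation; multi-allelic markers are outside
  its scope.
* Tri-/tetra-allelic sites are rare under the generator (one mutation per
  column); the multi-allelic code paths are exercised by hand-built
  fixtures instead.
* No recombination within fragments, anywhere; loci are exchangeable only
  as whole units.
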