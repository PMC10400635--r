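---
title: "xenofate: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{xenofate: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xenofate)
```

## The problem

An untargeted LC-MS metabolomics assay of a dosed biological system
measures, in one run, both the endogenous metabolome and everything the
organism did to the administered compound: the parent xenobiotic, its
Phase I and Phase II biotransformation products, and the in-source
artefacts (adducts, isotopologues, dimers) each of them produces in the
ion source. xenofate implements a workflow that (i) pulls those
xenobiotic-related features out of a picked peak matrix without any
prior knowledge of the metabolite structures, (ii) annotates them by
ion form and by rule-predicted molecular formula, (iii) corroborates
annotations with MS² fragment-shift evidence, (iv) characterises their
temporal and dose behaviour, and (v) hands back a cleaned endogenous
matrix in which drug-related signals no longer masquerade as biology.

Everything operates at the level of the peak matrix (features =
m/z–retention-time pairs × samples). Peak picking, retention-time
alignment and gap filling are upstream concerns (XCMS territory) and
out of scope.

## Discovery: the three intensity filters

A feature is called putatively xenobiotic-related when all three of the
following hold, computed over exposed and biological control columns
only (QCs and blanks are ignored here):

1. detected in at least 80% of exposed samples
   (`exposed_presence_min = 0.8`; 0.5 is the appropriate setting for
   human suspect screening where exposure within the cohort is sparse);
2. detected in at most 50% of control samples
   (`control_presence_max = 0.5`) — carry-over and co-eluting peaks make
   a hard 0% requirement too brittle;
3. the ratio of exposed to control median intensity is at least 10
   (`fold_min = 10`). For a genuine xenobiotic this ratio is infinite in
   principle; a feature never detected in controls is therefore assigned
   `fold = Inf` and passes.

"Detected" means a non-missing intensity. Input zeros and empty cells
are both treated as missing on load, because picked matrices encode
non-detection either way. Medians ignore missing values; nothing is
imputed inside the filters. Boundary comparisons are inclusive
(`>=`/`<=`), so a control presence of exactly 0.50 passes.

The only place imputation *is* used is suspect-based exposure
labelling (`label_exposure_by_suspect`): missing values of the suspect
feature are filled with the lowest measured intensity anywhere in the
matrix, and a sample is labelled exposed when the feature exceeds 10×
the median across biological samples and QCs. When several ion forms
match a suspect, the representative defaults to the
highest-median-intensity matching feature.

## Grouping and ion-form annotation

Features of one compound co-elute and differ in m/z by fixed,
rule-determined amounts. `group_features` links two features when they
co-elute within `rt_tol` (5 s) and some pair of ion-form rules maps
both m/z values to the same neutral mass within `ppm_tol` (5 ppm);
compound groups are the connected components of that graph. The default
positive-mode rules are [M+H]+, [M+Na]+, [M+NH4]+, [2M+H]+ and the
¹³C1/¹³C2 isotopologues of [M+H]+ (negative mode: [M−H]−, [M+Cl]−,
[2M−H]−, ¹³C1); the set is a configurable table, since no canonical
library is universal. When one pair fits two rules, the smaller ppm
error wins. The group's neutral mass is the median of member estimates,
and the representative feature is the molecular ion when annotated,
else the highest-median-intensity member.

Features explained by no rule stay singletons; they are annotated as
an *assumed* molecular ion (flagged `assumed = TRUE`) so that
downstream formula matching still has a neutral-mass hypothesis — the
same assumption any suspect search makes for a lone feature.

## Biotransformation prediction

The molecular-formula engine knows C, H, N, O, S, P, F, Cl, Br and Na
with IUPAC monoisotopic masses. The default rule table covers the
common mammalian vocabulary — oxidation, demethylation, de-ethylation,
dehydrogenation, saturation, oxidative defluorination (F→OH),
glucuronidation, sulfation, methylation and glycine conjugation — and
is user-extensible from a delimited file. `enumerate_products` applies
rule sequences breadth-first up to `max_steps = 3` total steps with at
most `max_phase2 = 1` conjugation, mirroring the step limits used by
in-silico metabolite prediction engines, and deduplicates by formula
keeping the shortest path (ties: fewer Phase II steps, then
lexicographic rule names — determinism over chemistry, since a
formula-level engine cannot distinguish the order of commuting steps).
There is no structure handling and no site-of-metabolism scoring; path
length serves as the plausibility proxy, and hydrolysis-type cleavages
must be declared explicitly as fragment formulas.

`match_products` annotates each group with every candidate whose
neutral mass is within 5 ppm, ranked by |ppm error| then path length.

## MS² substructure evidence

For a candidate biotransformation product with mass delta Δ relative
to the parent, each parent fragment is *conserved* if the candidate
spectrum contains a peak within 5 ppm of it (the substructure survived
the modification) and *shifted* if a peak sits within 5 ppm of
fragment + Δ (the substructure carries the modification). Matching is
greedy one-to-one by smallest ppm error — deterministic and adequate at
5 ppm on centroided data. A candidate is accepted as related when at
least `conserved_min = 3` substructures are conserved. When Δ = 0 the
shifted count would duplicate the conserved count and is reported as
zero.

Spectra are consumed from MGF/MSP with an optional `PURITY` annotation;
precursor-purity filtering keeps spectra with purity ≥ 0.5 (purity is
not recomputed from raw scans — we consume centroided data). Replicate
spectra are averaged by single-linkage clustering of pooled fragments
at 5 ppm, each cluster becoming an intensity-weighted mean peak.
Spectra link to matrix features at 5 ppm / 10 s.

## Correlation networks and enrichment

Two network modes mirror two distinct analyses:

* **Co-response** (Pearson): pairwise correlations of PQN-normalised
  xenobiotic-feature intensities, with normalisation coefficients
  computed on the endogenous features and applied to the xenobiotic
  ones. Edges require Holm-adjusted p < 0.05 and R ≥ 0.75. Holm is
  applied over the full family of tested pairs.
* **Dose–response** (Spearman): rank correlation of candidate features
  (e.g. annotated lipids) against the parent compound across exposed
  samples; edges require raw p < 0.05 and |ρ| ≥ 0.9, and the network
  is restricted to nodes with an edge to the parent.

P-values come from the t transform `t = r√((n−2)/(1−r²))` on
pairwise-complete sample sizes; pairs with fewer than 3 complete
observations, or involving a constant vector, are untested.
Over-representation of a class within a selected subset is the
one-sided Fisher exact (hypergeometric upper-tail) p against the full
annotated universe, flagged at p < 0.1.

## Endogenous preprocessing

After removing the putative xenobiotic features, the endogenous branch
applies, in order: blank filter (feature kept only when its biological
median is ≥ 20× its blank median; skipped with a warning when the
study has no blanks), QC-RSD filter (≥ 30% removed), sample
missingness (> 50% drops the sample), feature missingness (missing in
≥ 10% of QCs or ≥ 50% of samples removed). Each rule logs its removals
in a ledger. Statistics (per-feature pooled-variance t-tests with
median-ratio fold changes and Benjamini–Hochberg q-values) run on
PQN-normalised data; the multivariate branch additionally applies kNN
imputation (k = 5; feature-wise neighbours by Euclidean distance on
unit-variance rows over shared-present columns, ties broken by feature
order) and the generalised log transform before PCA.

The glog parameter λ is tuned on QC replicates by a grid search that
minimises the spread (variance of the log) of feature-wise technical
variances after transformation — a variance-stabilisation criterion
chosen here because the upstream tooling does not document its own; a
fixed λ can be supplied instead. PCA is SVD-based on mean-centred
samples with a fixed sign convention (largest-|loading| element
positive per component).

## Temporal analysis

Per compound, the median intensity across exposed replicates at each
timepoint forms a profile that is centred and scaled to unit variance
(constant profiles are flagged out). Profiles are clustered by Lloyd's
k-means with 20 random restarts per k; the number of clusters is read
off the WSS elbow. The automated elbow is the maximum second
difference of **log** WSS: on the raw scale the k = 1→2 drop (the
total sum of squares) always dominates the second difference and the
rule would return k = 2 regardless of structure, whereas relative
flattening identifies the true elbow. Because automation can never
fully substitute for inspecting the curve, the full WSS table is
always returned and `k` can be overridden. Per-compound timepoint
differences are tested by one-way ANOVA with Tukey HSD post-hoc.

## The synthetic data generator

`simulate_dataset` produces the study structure the workflow assumes,
with ground truth: five timepoints with a rise-to-plateau-then-washout
parent dose profile (repeat-dose semantics with a washout endpoint),
3 exposed + 3 control animals per timepoint, 8 pooled QCs and 4
blanks; a parent drug (default formula C22H27FN4O2) as [M+H]+ with
[M+Na]+, [M+NH4]+ and ¹³C satellites at rule-exact offsets co-eluting
within 2 s; eight biotransformation products at formula-exact masses
whose intensities couple to the realised parent level under one of
three kinetic shapes; 500 endogenous features with lognormal baselines,
of which 30 are class-shifted (fold changes capped at 3 — below the
10-fold discovery threshold by design) and 20 are dose-coupled; 10
blank contaminants; and intensity-dependent dropout (detection
probability falls logistically below an intensity threshold), which
reproduces the missing-value pattern that motivates the filters'
leniency. Xenobiotic signals are planted ≥ 50-fold above background in
exposed samples and absent from controls and blanks. All randomness
derives from one seed; identical seeds give identical output.

What it does **not** emulate: chromatographic peak shapes, m/z and RT
measurement error (masses are rule-exact, so grouping tests are exact
round-trips), correlated endogenous modules, batch/injection-order
drift, or in-source fragmentation. Passing the synthetic benchmarks
therefore demonstrates the correctness of the algorithms under the
stated statistical assumptions, not performance on instrument data.

`simulate_time_profiles` separately generates the clustering benchmark:
unit-scaled profiles drawn from three distinct kinetic shapes
(rise-to-plateau, accumulation, early peak) with additive noise
(SD 0.2) after scaling.

## Problem sizes and numerical choices

The bundled verification (tests and `scripts/acceptance.R`) runs the
discovery-vs-oracle comparison on 100 random 200 × 20 matrices,
spike-in recovery over 20 simulated studies (≈ 526 features × 42
samples each), clustering recovery over 10 draws of 60 profiles, and
dose–response recovery over 5 studies — sizes chosen so the whole
suite completes in a few minutes while keeping every estimate stable
across seeds. Tolerances: formula masses are deterministic to 1e-6 Da
(rule deltas verified to 1e-4 Da against an independent atomic-mass
summation); Fisher tail probabilities match brute-force enumeration to
1e-12; PCA reconstruction is exact to 1e-8. Degenerate inputs are
values, not crashes: constant vectors yield untested correlations,
degenerate-variance t-tests yield missing p-values, empty candidate
sets yield empty annotation tables.

## Known limitations

* Formula-level annotation cannot distinguish isomers; confidence
  levels above 3 require external evidence (standards, databases).
* The adduct/isotope rule set is deliberately small; uncommon in-source
  chemistry will leave features as assumed molecular ions.
* The Spearman dose–response mode assumes monotone coupling; saturating
  or hormetic responses weaken rank correlation.
* The elbow rule, like any automated elbow, is a heuristic; always
  inspect the emitted WSS curve for flat or multi-elbow geometries.
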