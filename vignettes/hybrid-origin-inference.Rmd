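---
title: "Coalescent ABC-RF inference of hybrid origins from SNP panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coalescent ABC-RF inference of hybrid origins from SNP panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

`hybridrf` infers how a homoploid hybrid lineage formed from two parental
species, using a reduced-representation biallelic SNP panel. The motivating
system is an alpine alkali grass of hybrid origin in a high-mountain plateau:
a widespread parent (`PAM`) with distinct northern and southern genetic
groups, a second parent (`HIM`) known from a single genotyped herbarium
specimen, and hybrid populations (`HYB`) in both geographic groups. Two
questions drive the design:

1. **How many hybridization events?** Did the parents cross repeatedly in
   different places (the hybrids inheriting the parental north/south
   structure), or once (a single hybrid lineage that diversified on its
   own)?
2. **When, and with what parental contributions?** Event times are compared
   against a regional climate horizon — the local Last Glacial Maximum
   (locLGM) — and the admixture fraction `r1` measures the PAM-side
   contribution.

A complementary chloroplast module determines the *direction* of
hybridization (which species was the maternal parent) from fixed diagnostic
differences between the parental plastid haplotypes.

## The six demographic scenarios

All scenarios act on five sampled demes (`PAM_N`, `PAM_S`, `HYB_N`, `HYB_S`,
`HIM`) and end with the two parental lineages merging into a single ancestor
at time `t5`. Backward in time:

* **Multi-event scenarios (1–3).** Each hybrid deme is admixed locally:
  `HYB_N` draws from `PAM_N` vs `HIM` and `HYB_S` from `PAM_S` vs `HIM`,
  both with the same PAM-side fraction `r1`, at the hybridization time. The
  two PAM lineages then merge at the (older) diversification time. The
  scenarios differ in which climate window each event falls into: both
  recent (S1), both in the locLGM (S2), or recent hybridization after a
  locLGM diversification (S3).
* **Single-event scenarios (4–6).** The two hybrid demes first merge into
  one hybrid ancestor (simultaneously, the PAM demes merge — the
  "independent diversification" of hybrids and parent is encoded as one
  shared diversification time, since the scenario family assigns a single
  time symbol to diversification). The hybrid ancestor is then admixed once
  from the ancestral PAM vs `HIM`. Again the window assignments
  differentiate S4 (all recent), S5 (all locLGM), S6 (recent
  diversification, locLGM hybridization).

Times are in generations with uniform priors: `t1`, `t2` in `[10, 25000]`
(post-locLGM window), `t3`, `t4` in `[25000, 50000]` (locLGM window), and
`t5` in `[100000, 200000]`, with `t1 < t2` and `t3 < t4` enforced by
rejection when both appear in a scenario. Because the parental split is
poorly constrained, `prior_spec(t5_upper = 750000)` and `1250000` are
supported as sensitivity settings. The admixture fraction `r1` is uniform on
`[0.01, 0.99]`. A generation time of 2 years converts estimates to calendar
years (`generations_to_years()`).

**Effective sizes.** The study that motivates the design does not publish
its effective-size priors. The package default is `U[10, 100000]` diploids
per lineage, drawn independently for each of `PAM_N`, `PAM_S`, `HYB_N`,
`HYB_S`, `HIM`, `PAM_anc`, `ANC` (plus `HYB_anc` in S4–S6). This choice
matters: scenario-choice calibration is sensitive to the size prior, which
is why it is a single prominent argument (`prior_spec(n_range = ...)`)
rather than a buried constant.

## The coalescent SNP simulator

Within a deme holding `k` gene copies of a diploid population of size `N`,
the waiting time to the next coalescence is exponential with rate
`k(k-1)/2 × 1/(2N)` per generation (the continuous-time approximation of
the Wright–Fisher model). A merge event moves all lineages of the child deme
into its parent, whose size switches to the ancestral lineage's value; an
admixture event routes each lineage independently to the PAM-side parent
with probability `r1`, else to `HIM`. Ties at identical event times resolve
in list order (admixtures before merges in the built-in scenarios). The core
loop is compiled (Rcpp) and draws all randomness from R's RNG, so a single
`set.seed()` governs everything.

Each SNP locus is one independent gene tree (loci are unlinked by
construction; there is no recombination, sequence mutation model, or
selection). Two levels of ascertainment shape a locus:

* **Length-biased genealogy.** A locus enters a SNP panel only if it is
  variable, and in the low-mutation-rate infinite-sites limit that
  probability is proportional to the genealogy's total branch length. The
  simulator therefore accepts candidate trees with probability proportional
  to total length, implemented as capped-weight rejection: a pilot sample of
  32 trees sets the cap at 1.6× the pilot maximum, and the rare tree
  exceeding the cap is accepted outright (truncation mass on the order of
  0.1%, far below what any test here can resolve). Without this weighting
  the site-frequency spectrum deviates from the neutral `1/i` law by up to
  ~12% for moderate samples. The single mutation is then placed on one
  branch chosen proportionally to branch length; every non-root branch
  yields a polymorphic sample.
* **MAF conditioning.** Mirroring the analyzed panel's `MAF ≥ 0.05`
  ascertainment, a simulated locus is accepted only if its pooled-sample
  minor-allele frequency reaches the threshold, by rejection (resimulating
  the whole locus — the simplest unbiased scheme, rather than importance
  weighting). A per-locus attempt cap (default 10,000) turns pathological
  parameter draws into a classed runtime error; the reference-table builder
  resamples such draws and records how many.

`drop_single_mutation()` is also exposed on its own: given a fixed gene
tree it places one mutation proportionally to branch length (its contract
is per-tree, i.e. it does not re-weight the tree it is handed).

## Summary statistics

The original analysis ran inside a black-box ABC tool whose per-SNP summary
set is not enumerated anywhere in print; exact reproduction of its vote
percentages is therefore impossible from the publication alone. The package
instead defines a compact, admixture-informative registry (version
`hybridrf-ss-1`, recorded in every reference table and checked against the
observed vector):

* per group: proportion of polymorphic loci; mean and variance across loci
  of unbiased expected heterozygosity `2p(1-p)·n/(n-1)` (`n` = non-missing
  gene copies);
* per group pair: Hudson's FST as a ratio of averages,
  `1 - mean(Hw)/mean(Hb)` with `Hb = pA(1-pB) + pB(1-pA)`, and Nei's
  standard distance (capped at 10 where the identity would be 0);
* admixture statistics when all five canonical demes are present:
  `f3(HYB_g; PAM_g, HIM)` for each geographic group `g` (with the
  small-sample correction `p(1-p)/(n-1)` on the target) and
  `f4(PAM_N, PAM_S; HYB_pooled, HIM)`.

`HIM` contributes two gene copies (one diploid herbarium specimen), so its
heterozygosity uses the `n = 2` unbiased correction and every statistic
involving it is high-variance; that is a property of the study design, not
of the estimator. Loci entirely missing in a group are dropped pairwise per
statistic, not globally.

## ABC with random forests

`build_reference_table()` simulates `n_per_scenario` parameter draws per
scenario under the observed design (same sample sizes, locus count and MAF
threshold) and stores `(scenario, parameters, summaries)` rows; 2,000 to
20,000 rows per scenario is the recommended band (a warning flags values
outside it). `fit_model_choice()` trains a 500-tree classification forest
on the summaries; by default the linear-discriminant projections of the
summaries (up to K−1 axes, fitted on the reference table only) are appended
as features, a common ABC-RF convention that is toggleable (`add_lda =
FALSE`) because there is no public record of whether the original run used
it. `classify_scenarios()` reports per-scenario vote fractions and the
plurality winner; the posterior probability of that choice is `1 -` the
prediction of a second regression forest trained on the out-of-bag
misclassification indicator, following the established ABC-RF
posterior-probability scheme; the out-of-bag misclassification rate itself
is reported as the prior error rate.

`estimate_parameters()` uses quantile regression forests (one per
parameter, `ranger(quantreg = TRUE)`, `mtry` defaulting to a third of the
features as in the QRF literature): the posterior at the observed point is
the training responses weighted by leaf co-occurrence, summarised as the
weighted median with 5% and 95% quantiles. `replicate_analysis()` repeats
the whole pipeline R times (10 in the emulated protocol) on independent
reference tables with derived seeds and reports vote means ± SD, the
posterior probability mean ± SD, and combined vote mass for arbitrary
scenario subsets (e.g. the two multi-event scenarios {1, 3}, which are
structurally confusable because they differ only in the depth of the PAM
split).

**Seed policy.** Every public function takes an explicit seed; internally a
master seed derives per-replicate, per-scenario and per-draw streams by a
fixed linear map kept inside 32-bit range, so any single row of any
reference table can be regenerated in isolation and full reruns are
bit-identical.

## Calibration with pseudo-observed datasets

`run_calibration()` simulates PODs of known scenario and parameters,
classifies each against a reference table and reports the confusion matrix,
per-POD vote shares and (optionally) parameter recovery: bias of the
posterior median and coverage of the 90% interval. The package's own checks
run the cluster design scaled to 50 loci with 500 simulations per scenario
and 300-tree forests — sizes chosen so the full calibration completes in
minutes while leaving the forest's error rate clearly below chance; the
vote-share behaviour the full protocol reports is qualitatively stable in
this regime (the multi-event scenarios S1/S3 absorb nearly all votes for
PODs simulated under S1, with S1 the plurality winner in most).

## The synthetic-data generator

`study_design()` encodes the two sampling schemes the pipeline emulates:
a *cluster* design (118 individuals: 41 + 40 PAM north/south, 18 + 18
hybrids, 1 HIM; 338 SNPs) and a *population* design (27 individuals; 181
SNPs). Only the totals (118/27, and 81/36/1 per species) are fixed by the
study; the population design's per-deme split (7+7 north, 6+6 south, 1 HIM)
is a package default recorded in provenance. `make_pod()` draws a dataset
under any scenario; `make_dart_fixture()` writes a DArT-style CSV with
planted, disjoint filter failures so the expected retention count after
every cascade step is known by construction; `make_cpdna_fixture()` writes
an aligned FASTA (default length 926 bp, a typical intergenic-spacer read)
with planted diagnostics — by default four SNPs, one 4 bp deletion in the
PAM class and one 6 bp insertion present only in the PAM class — plus a
22-hybrid cohort (20 HIM-maternal, 2 PAM-maternal in two distinct
localities) and within-class noise sites that are never diagnostic.

What the generator does *not* emulate: DArTseq read-level error profiles,
real allele-frequency spectra of the deposited data, linkage, missing-data
patterns, or polyploid genotypes (inputs are assumed pre-subsampled to
biallelic diploid dosages). Passing tests therefore demonstrate correctness
of the inference machinery under the stated model, not robustness to
artefacts of real reduced-representation data.

## The filtering cascade

`run_filter_cascade()` applies, in order: locus reproducibility and locus
call rate, individual call rate, monomorphic removal, secondary-SNP
thinning (one random SNP per sequenced fragment, the only randomized step),
the group-polymorphism filter and the pooled-MAF filter, recomputing call
rates on the surviving matrix at each step (so step order matters). Two
deliberate conventions, both configurable:

* The MAF boundary is inclusive (`≥ 0.05`), since "minimum allele frequency
  of 5%" does not state strictness.
* "Monomorphic among all PAM and among all hybrids" is grammatically
  ambiguous. The default is the strict reading (keep only loci polymorphic
  within *every* listed group — the reading that maximises polymorphism);
  `mode = "weak"` drops only loci monomorphic in all groups simultaneously.

## Chloroplast direction of hybridization

`find_diagnostics()` scans a pre-aligned parental panel for columns fixed
for different bases in the two classes (no gaps or Ns allowed at the
column) and for maximal runs where one class is entirely gapped — each run
is a single indel event regardless of length. `classify_maternal()` scores
a query by majority vote over scorable events (one vote per SNP and per
indel event; sites with N, a gap at a SNP column, or a partially gapped
indel span are unscorable and count against neither class) and returns
`ambiguous` below `min_sites = 2` scorable events or on a tie, with the
per-event agreement vector kept for audit. How conflicting diagnostic sites
were resolved in the original analysis is not recorded; explicit majority
vote with an audit trail is this package's policy. No de-novo alignment,
tree or haplotype-network construction is attempted.

## Numerical and degenerate-input conventions

* Validation failures raise `hybridrf_validation_error`; simulator-cap
  exhaustion raises `hybridrf_runtime_error`.
* Filters may empty a dataset (warning, not error); statistics on
  degenerate groups return `NA` rather than fabricating values.
* Nei's distance caps at 10 (flagged) where fixed opposite alleles would
  give `+Inf`; Hudson's FST is stored raw and only clipped to `[-0.1, 1]`
  for display.
* Zero-variance summary columns are dropped before LDA and forest training.
* Scenario event ties resolve in list order; the built-in scenarios place
  admixtures before merges at equal times.

## Known limitations

* The reference tool's summary statistics and posterior-probability
  estimator version are unrecoverable from print, so the published vote
  percentages can only be approximated, not matched, even with the deposited
  data.
* With a single HIM specimen, `t5` and all HIM-involving statistics are
  weakly identified; the upstream analysis reports the same caveat.
* The DArT reader targets the dialect documented in `read_dart_csv()`; the
  deposited archive's exact dialect is not described in print, so the
  reader is written to be adapted (all downstream code consumes the
  in-memory `snp_dataset` only).
* v1 reads no VCF and models no continuous migration, growth or
  bottlenecks — the scenario family contains only instantaneous events.
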