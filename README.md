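# hybridrf

Coalescent simulation and random-forest approximate Bayesian computation
(ABC-RF) for inferring the demographic origin of homoploid hybrid lineages
from reduced-representation SNP panels, with a chloroplast-haplotype module
for the maternal direction of hybridization.

The package is built for population geneticists studying hybrid taxa with
spatially structured parents — the motivating system is an alpine alkali
grass formed from two *Puccinellia* species in a Central Asian mountain
plateau, where the widespread parent (PAM) has distinct northern and
southern genetic groups, the second parent (HIM) is known from a single
genotyped specimen, and the hybrids (HYB) occur in both groups.

## What it computes

**Scenario choice.** Six demographic scenarios are encoded as
backward-in-time event lists over the demes `PAM_N`, `PAM_S`, `HYB_N`,
`HYB_S`, `HIM`: three *multi-event* scenarios (each hybrid deme admixed
locally from its PAM neighbour and HIM, then the PAM lineages merge) and
three *single-event* scenarios (the hybrid demes merge first, then one
admixture founds the hybrid ancestor), differing in which of two climate
windows — post-local-LGM (`t1, t2 ~ U[10, 25000]` generations) or local LGM
(`t3, t4 ~ U[25000, 50000]`) — each event falls into. The parental split
`t5 ~ U[100000, 200000]` (sensitivity settings 750k/1.25M supported), the
PAM-side admixture fraction `r1 ~ U[0.01, 0.99]`, effective sizes
`U[10, 100000]` per lineage, generation time 2 years.

A compiled structured-coalescent simulator (pair-coalescence rate
`1/(2N)` per deme; length-biased genealogy sampling so SNP loci follow the
neutral `1/i` site-frequency law; pooled-MAF ascertainment by rejection)
fills a reference table of summary statistics — per-group heterozygosity
and polymorphism, pairwise Hudson FST

```
FST = 1 - mean_loci(Hw) / mean_loci(Hb),  Hb = pA(1-pB) + pB(1-pA)
```

Nei's standard distance, and the admixture statistics
`f3(HYB_g; PAM_g, HIM)` and `f4(PAM_N, PAM_S; HYB, HIM)`. A 500-tree
random forest votes among scenarios; the posterior probability of the
winner is estimated from a second forest trained on the out-of-bag error
(the standard ABC-RF scheme), and parameters are estimated by quantile
regression forests (posterior median with 5%/95% quantiles). The whole
analysis is replicated over independent reference tables (votes reported
as mean ± SD), and calibrated with pseudo-observed datasets (confusion
matrices, interval coverage).

**Filtering.** The standard DArT-style cascade: locus reproducibility,
locus call rate, individual call rate, monomorphic removal, secondary-SNP
thinning to one SNP per sequenced fragment, group-polymorphism filter,
pooled MAF ≥ 0.05 — with call rates recomputed after every step and a
per-step retention report.

**Direction of hybridization.** Fixed diagnostic differences between the
two parental chloroplast haplotype classes (diagnostic SNP columns plus
indel events scored as single events regardless of length) classify each
hybrid's maternal lineage by majority vote with an audit trail.

## Worked example

Simulate a pseudo-observed dataset under the recent multi-event scenario
(balanced admixture, `r1 = 0.5`) at the cluster design scaled to 50 loci,
then run a two-replicate ABC-RF analysis against all six scenarios:

```r
library(hybridrf)

prior  <- prior_spec()                          # priors described above
design <- study_design("cluster", n_loci = 50)  # 118 individuals, 5 demes

pod <- make_pod(1, design, theta = mid_prior_theta(1, prior), seed = 7)
res <- run_inference(pod$dataset, design, prior,
                     n_per_scenario = 500, n_replicates = 2,
                     n_trees = 300, seed = 7)
res
```

```
<replicate_summary> 2 replicates; selected scenario 1
  S1: 72.0 +- 2.8%
  S3: 17.0 +- 1.4%
  S4: 8.7 +- 2.4%
  S6: 1.2 +- 0.2%
  S5: 0.7 +- 0.9%
  S2: 0.5 +- 0.2% 
posterior probability 0.715 +- 0.005
event-time posteriors (years):
# A tibble: 3 × 4
  parameter     q05  median     q95
  <chr>       <dbl>   <dbl>   <dbl>
1 t1           840.   8542.  27547.
2 t2         17637.  37499.  48712.
3 t5        224778. 316573. 391975.
```

The true scenario (S1) wins the forest vote with 72% and the two
multi-event scenarios S1+S3 jointly absorb 89% (they differ only in the
depth of the PAM split and are structurally confusable), and the
hybridization-time posterior (`t1`, in calendar years at 2
years/generation) covers the simulated truth of 12,515 years.
`autoplot(res$summary)` draws the vote bars; `tidy()`/`glance()` return the
same numbers as tibbles.

The cpDNA module runs the maternal-direction analysis on an aligned
parental panel plus hybrid cohort:

```r
fx  <- make_cpdna_fixture(seed = 1)   # 4 diagnostic SNPs, 4 bp + 6 bp indels
par <- subset(fx$truth, role == "parent")
cp  <- run_cpdna(fx$alignment,
                 class_a_ids = par$seq_id[par$class == "PAM"],
                 class_b_ids = par$seq_id[par$class == "HIM"],
                 localities  = fx$truth[, c("seq_id", "locality")])
cp$diagnostics
#> <diagnostic_set> PAM vs HIM: 4 diagnostic SNP(s), 2 indel event(s)
#> indel lengths: 4, 6
subset(cp$directions, locality == "overall")
#> # A tibble: 2 × 3
#>   locality call      n
#>   <chr>    <chr> <int>
#> 1 overall  HIM      20
#> 2 overall  PAM       2
```

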