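# betalactamdiv

Does *how well* an intravenous beta-lactam course hits its pharmacodynamic
target change what happens to the airway microbiome of a person with cystic
fibrosis (CF)? Beta-lactam killing is time-dependent: efficacy tracks the
fraction of the dosing interval during which free plasma concentration exceeds
the pathogen's minimum inhibitory concentration (fT>MIC), with class-specific
targets of 40% (carbapenems), 50% (penicillins) and 60% (cephalosporins).
Because people with CF clear beta-lactams quickly, many courses are
*subtherapeutic* by this criterion, and therapeutic versus subtherapeutic
exposure may drive different longitudinal patterns of airway-community
diversity across the four clinical encounters of an exacerbation cycle:
baseline (B), exacerbation onset (E), end of treatment (T) and post-recovery
(R).

`betalactamdiv` implements that analysis end to end, for microbiome
researchers and clinical pharmacologists who want to study the design at desk
scale or apply it to their own tables:

* **Exposure classification** — closed-form one-compartment
  intermittent-infusion concentration profiles at steady state,
  `C(t) = (R0/kV)(1 - e^{-k min(t,Tinf)}) e^{-k max(0, t - Tinf)}` superposed
  over all prior doses; fT>MIC by root finding; MAP estimation of clearance
  and volume from sparse plasma samples under a lognormal population prior;
  MIC selection (highest isolate MIC, cohort-median *P. aeruginosa* MIC for
  normal-flora-only cultures, literature MIC for MSSA); and the decision rule:
  a course is therapeutic if at least one beta-lactam meets its target, unless
  MRSA grew without directed anti-MRSA therapy.
* **Alpha diversity** — multivariate-hypergeometric rarefaction to a common
  depth, then observed richness, Chao and ACE (q = 0), Shannon (q = 1) and
  inverse Simpson (q = 2).
* **Beta diversity** — Bray-Curtis and Jaccard on ln(1+x) counts and
  Morisita-Horn on raw counts, principal coordinates analysis, and a
  one-factor permutation PERMANOVA (with an exact-enumeration mode and
  optional within-patient strata).
* **Longitudinal statistics** — paired encounter deltas (B-T, B-R, E-T, E-R;
  the prior R sample serves as the next baseline for repeat exacerbations),
  compared between exposure groups with a Gaussian GEE under an exchangeable
  working correlation and robust sandwich variance; a permutation
  differential-abundance test with Benjamini-Hochberg adjustment.
* **Synthetic cohort** — a Dirichlet-multinomial generator producing
  patients, dosing courses with true PK, culture/MIC panels, noisy plasma
  samples and four-encounter count tables with programmed group-dependent
  diversity dynamics, so the whole pipeline is testable without clinical data.

## Worked example

```r
library(betalactamdiv)
res <- run_pipeline(cohort_config(), seed = 1,
                    rarefaction_iterations = 50, n_permutations = 999)
print(res)
#> Exposure-diversity pipeline (seed 1)
#>  courses: 34 (56% therapeutic)
#>  samples analyzed: 108 (rarefied to 3637 reads, 50 iterations)
#>  B-T Shannon delta: therapeutic -0.47 vs subtherapeutic 0.17 (GEE p = 5.92e-10)
#>  PERMANOVA (Bray, group): pseudo-F = 8.93, p = 0.001
```

Reading the output: 34 antibiotic courses were simulated and classified from
their (MAP-estimated) PK, cultures and MICs; 56% met a pharmacodynamic target.
Every sequenced sample was rarefied to the smallest library in the cohort
(here 3,637 reads; the generator enforces a floor of 2,239).
Between baseline and end of treatment the therapeutic group *lost* about 0.47
nats of Shannon diversity on average while the subtherapeutic group was flat
to slightly increasing — the cluster-robust GEE puts the group contrast well
below p = 0.05 — and the two exposure groups occupy distinguishable regions
of Bray-Curtis community space (PERMANOVA p = 0.001, the smallest value 999
permutations can produce).

Individual stages are exposed directly, e.g.

```r
reg <- drug_regimen("ceftazidime", "cephalosporin", dose = 2000,
                    infusion_duration = 0.5, interval_tau = 8)
fraction_time_above_mic(reg, pk_parameters(clearance = 10, volume = 20), mic = 8)
#> [1] 0.6642319   # meets the 60% cephalosporin target
fraction_time_above_mic(reg, pk_parameters(clearance = 10, volume = 20), mic = 32)
#> [1] 0.3062429   # a resistant isolate: well short of it
```

A thin command-line wrapper for full runs lives at
`inst/scripts/run_pipeline.R`.

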