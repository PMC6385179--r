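---
title: "Methods: beta-lactam exposure and airway microbiome diversity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: beta-lactam exposure and airway microbiome diversity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(betalactamdiv)
```

This vignette is the package's account of its own methods: the models, the
tunable parameters and their defaults, the numerical choices, what the
synthetic-cohort generator does and does not emulate, and the known
limitations. Nothing stated here goes beyond what the test suite and
`scripts/acceptance.R` themselves compute.

## 1. The question and the study design

In cystic fibrosis (CF), intravenous beta-lactams are the backbone of
treatment for acute pulmonary exacerbations, and their killing is
time-dependent: what matters is the fraction of the dosing interval during
which plasma concentration exceeds the pathogen's minimum inhibitory
concentration (fT>MIC). Because CF accelerates beta-lactam clearance, a
substantial share of guideline-dosed courses still miss their class-specific
pharmacodynamic target. The analysis implemented here asks whether
*therapeutic* versus *subtherapeutic* exposure, so defined, is associated
with different longitudinal trajectories of airway-microbiome diversity
across four encounters per exacerbation cycle: baseline (**B**), exacerbation
onset (**E**), end of treatment (**T**) and post-recovery (**R**). Patients
can contribute several exacerbations; when a post-recovery visit turns out to
be the next exacerbation's baseline, one physical sample plays both roles.

## 2. Exposure model

**Concentration profile.** Drug disposition is modeled as one compartment
with first-order elimination; every regimen is an intermittent infusion
(rate $R_0 = \mathrm{dose}/T_\mathrm{inf}$). The steady-state concentration
at time $t$ after the start of a dose is the superposition

$$C(t) = \frac{R_0}{kV}\Big[(1 - e^{-k\min(t, T_\mathrm{inf})})\,
e^{-k\max(0, t - T_\mathrm{inf})} +
(1 - e^{-kT_\mathrm{inf}})\,e^{-k(t - T_\mathrm{inf})}\,
\frac{e^{-k\tau}}{1 - e^{-k\tau}}\Big],$$

with clearance $CL$ (L/h), volume $V$ (L), $k = CL/V$ (1/h) and interval
$\tau$ (h); the geometric series collapses all earlier doses. Total (not
free) concentration is modeled — protein binding is not part of the model,
matching the output granularity of routine Bayesian dosing software; whether
the 40/50/60% targets should apply to free drug is genuinely open, and total
drug is the assumption here. Tests verify the closed form against brute-force
superposition of hundreds of individual doses to ~10⁻¹⁵ relative error.

**fT>MIC.** At steady state the profile rises monotonically during the
infusion and decays monotonically afterwards, so $C(t) = \mathrm{MIC}$ has at
most one crossing on each branch; both are located by `uniroot` on the closed
form (tolerance 10⁻¹²) and the fraction is $(t_2 - t_1)/\tau$. The comparison
against the concentration is strict ($C >$ MIC); the comparison against the
class target is inclusive ($f \ge$ target), so exactly meeting a target
counts. Evaluation uses a single steady-state interval: intermittent dosing
is periodic there, and one number per drug is the clinically reported
quantity. A note on the bolus limit: the familiar
$(\ln(C_0/\mathrm{MIC})/k)/\tau$ shortcut must use the *steady-state* initial
concentration $C_0 = (D/V)/(1 - e^{-k\tau})$; ignoring accumulation is
already a ~0.6% error at $k\tau = 4$.

**MAP estimation.** Clearance and volume are estimated from sparse plasma
samples by maximizing a log-posterior in $(\log CL, \log V)$: Gaussian
residuals around the steady-state profile (sd = the configured assay/model
error) plus a lognormal population prior. The optimizer is BFGS started at
the prior mode; convergence is certified by restarting from the optimum and
requiring the parameters to be a fixed point (relative drift < 10⁻⁶). With no
observations the prior mode is returned; with dense noise-free sampling the
truth is recovered to well under 1% (the acceptance suite measures a median
relative error of ~4×10⁻⁶). Which structural model and priors the original
clinical software used is unknowable from outside, so the prior is exposed as
configuration (`pk_prior`).

**MIC selection and the decision rule.** For each drug, the MIC used is the
highest measured MIC across the exacerbation's isolates; a culture growing
only normal respiratory flora falls back to the cohort median
*P. aeruginosa* MIC, and an MSSA isolate without a measured MIC falls back to
a literature value. A course is **therapeutic** when at least one beta-lactam
reaches its class target — 40% (carbapenems), 50% (penicillins), 60%
(cephalosporins) — unless MRSA grew and no directed anti-MRSA therapy was
given, in which case it is **subtherapeutic**. Aminoglycosides and anti-MRSA
agents are metadata only and are never PK-modeled. The full 8-cell decision
table (target met × MRSA × anti-MRSA therapy) is tested exhaustively.

## 3. Alpha diversity

Samples are rarefied to a common depth (default: the smallest library among
retained samples) by sampling reads without replacement — an exact
multivariate-hypergeometric draw implemented by sequential conditional
`rhyper` calls — and the five indices are averaged over `n_iterations`
subsamples (default 100; a single-subsample mode exists because either
convention is defensible and the averaged one has lower Monte-Carlo
variance). Samples below the depth are dropped with a warning, mirroring the
exclusion of failed libraries. The indices span the Hill gradient: observed
genera, ACE and Chao (q = 0), Shannon in natural log units (q = 1), and
inverse Simpson (q = 2). Defaults follow the mothur conventions the field's
count tables usually come from: bias-corrected Chao and the unbiased
(finite-sample) inverse Simpson, with the classic/naive forms behind flags.
Useful invariants, all tested: richness ≥ exp(Shannon) ≥ naive inverse
Simpson; Chao and ACE never fall below observed richness; the naive q = 1, 2
indices are invariant to rescaling all counts.

## 4. Beta diversity and PERMANOVA

Bray-Curtis and (binary) Jaccard dissimilarities are computed on
$\ln(1 + x)$-transformed counts; Morisita-Horn is computed on raw counts
because it is already invariant to library size (whether it should instead
see rarefied counts is unresolved, so a flag exists). Binary Jaccard is the
classical presence/absence definition; vegan's quantitative variant is
available behind `binary = FALSE`. Matrices are built by `vegan::vegdist`,
and the scalar formula implementations are cross-checked against it in the
tests.

PCoA is Gower double-centering of $-d^2/2$ followed by an
eigendecomposition; axes with positive eigenvalues are retained and scaled by
$\sqrt{\lambda}$. Bray-Curtis matrices are generally non-Euclidean, so
negative eigenvalues occur; they are reported alongside a reconstruction
RMSE rather than silently truncated.

PERMANOVA is the one-factor `adonis` decomposition: with $SS_T$ the total
and $SS_W$ the within-group sum of squared dissimilarities (each divided by
its group size), pseudo-$F = \frac{(SS_T - SS_W)/(g-1)}{SS_W/(n-g)}$.
Significance comes from label permutations with the +1 correction, so the
smallest attainable p is $1/(B+1)$; permutations can be restricted within
strata (e.g. patient) — off by default, matching the usual single-factor
`adonis` call. A zero within-group sum of squares yields an infinite
pseudo-F, treated as exceeding every finite permuted value. An
exact-enumeration mode walks all $n!$ relabelings for small $n$; note that
with equal group sizes every labeling has a mirror (group names swapped)
with the identical partition and identical pseudo-F, so the smallest exact
p with two equal groups is $2/\binom{n}{n/2}$ — for two tight pairs among
four samples, exactly 1/3. Only one factor is fitted (exposure group, or
encounter); sequential multi-factor sums of squares are out of scope.

## 5. Longitudinal statistics

**Deltas.** For every exacerbation and every index, the paired change
(later − earlier) is computed for B–T, B–R, E–T and E–R whenever both
samples exist and survive the user-supplied exclusion list; a diversity
decline is therefore negative. For repeat exacerbations without their own
baseline, the previous exacerbation's R sample fills the B role, with
provenance columns recording which sample served where.

**GEE.** Group differences in deltas are tested with a marginal Gaussian
identity-link model estimated by iterated generalized estimating equations:
exchangeable working correlation with a moment estimator of the common
intra-patient correlation, dispersion from the residual sum of squares, and
the robust sandwich covariance (chosen over model-based variance because the
cohorts are small and the working correlation is surely misspecified).
Iteration stops when the coefficient step falls below 10⁻⁸ (cap 100
iterations); non-convergence is flagged, never silent. With singleton
clusters the estimate reduces *exactly* to OLS — a tested identity. A
simulation in the acceptance suite (30 clusters × 2 observations, 500
replicates) shows slope bias < 0.1 and robust-interval coverage within
[0.90, 0.98]. Only the Gaussian arm is implemented; dichotomous baseline
contrasts belong to standard chi-squared machinery, not this package.

**Differential abundance.** A deliberately simple two-group test: per taxon,
the log2 fold change of mean relative abundance (pseudocount 0.5), a
two-sided permutation p-value over label shuffles, and Benjamini-Hochberg
adjustment (`stats::p.adjust`). This is *not* a negative-binomial shrinkage
model and its fold changes are descriptive; it exists to rank taxa and
control FDR under permutation, and the suite verifies its null false-positive
rate stays at or below nominal. One caution: the BH map is a step-up
*transform*, not a projection — re-applying it to already-adjusted values
inflates them again — so the tests assert the hand-computed step-up example,
purity and sorted-order monotonicity.

## 6. The synthetic cohort: what it emulates

Because the clinical dataset cannot ship with a package, `generate_cohort()`
produces a complete, internally consistent study: the default configuration
follows a small pediatric CF cohort — 20 patients whose exacerbation counts
are skewed (probabilities 13/20, 5/20, 1/20, 1/20 for 1, 2, 3, 5
exacerbations), a three-drug beta-lactam menu (ceftazidime 2 g q8h,
meropenem 1 g q8h, piperacillin-tazobactam 4 g q6h, all 30-minute
infusions), lognormal population PK centered at CL 9 L/h and V 18 L with
CF-plausible spread, a log2 MIC grid from 0.25 to 64 mg/L, three plasma
samples per drug with 10% lognormal noise, 8% sample missingness, and
sequencing depths lognormal around 8,000 reads with a floor of 2,239 to
exercise the rarefaction threshold.

**Exposure truth.** Each course draws an intended category
(Bernoulli with `fraction_therapeutic`, default 0.45). Courses with a
measured-MIC isolate are steered by MIC engineering: the achieving drug's
MIC is drawn from the feasible set (fT>MIC at least 2 percentage points
clear of the target, so classifications are never razor-edge), weighted by a
lognormal with mode ~2 mg/L so the cohort's MIC distribution and its median
stay clinically plausible. Courses whose MIC comes from a fallback rule
(normal flora → realized cohort median *P. aeruginosa* MIC; unmeasured
MSSA → literature MIC) are steered through truncated rejection sampling of
the PK draw instead. The *stored truth is always the output of the
classification rules applied to the true PK*, so the closed loop — noise-free
observations, MAP estimation, MIC selection, classification — reproduces it
exactly, which the acceptance suite checks at 100%. A structural bias is
accepted and worth knowing about: under guideline dosing, a normal-flora
course judged at a susceptible median MIC is nearly always therapeutic
whatever the PK draw, so the realized fraction runs ≈ 0.50 ± 0.13 against
the 0.45 target; the same association (normal flora clustering in the
therapeutic group) is a described feature of real cohorts.

**Community model.** Counts are Dirichlet-multinomial: a geometric base
composition over 40 genus-level bins (decay 0.82) named for common CF airway
genera, perturbed once per patient (lognormal, sd 0.4, which both creates
inter-patient variability and induces the within-patient correlation the GEE
is there to absorb). Group-by-encounter structure enters through two knobs:
the Dirichlet concentration θ (evenness) and a multiplicative dominance
boost of a focal taxon — a *Pseudomonas*-like taxon for the therapeutic
group, an *Enterobacteriaceae*-like taxon for the subtherapeutic group. The
defaults were set once, by forward simulation of expected Shannon per cell,
to realize the programmed study conditions: the therapeutic group starts
diverse (expected Shannon ≈ 2.3), drops sharply at T (≈ 1.7) and only
partially recovers at R (≈ 2.1); the subtherapeutic group starts lower
(≈ 1.85, with strong Enterobacteriaceae-like dominance — the confounding
baseline asymmetry is ON by default precisely so it can be studied) and is
flat-to-increasing (T ≈ 2.06, R ≈ 1.93). The R cell is deliberately placed
*between* B and T: because a subtherapeutic patient's R sample becomes the
next exacerbation's baseline, programming R far above T would make chained
B→T deltas systematically negative and silently undo the intended
"flat-to-increasing" condition.

**What it does not emulate.** Read-level error, chimeras, OTU clustering and
taxonomy assignment (counts are born at genus level); within-treatment time
series beyond the four encounters; seasonal or growth-related PK drift;
polymicrobial MIC panels (one MIC-bearing dominant isolate per course);
sample-type effects on composition (sputum/OP/BAL labels exist but do not
shift the community). Consequently, passing tests demonstrate that the
*pipeline* recovers programmed effects from realistically structured counts
— not that real CF airway data behave this way.

## 7. Problem sizes and reproducibility

Default analysis sizes, chosen to keep a laptop run interactive: 100
rarefaction iterations, 999 permutations for PERMANOVA and differential
abundance. The simulation-based checks use 50 random regimens for the
PK-oracle comparison, 100 synthetic patients for MAP recovery, 200 null
datasets for PERMANOVA calibration, 500 replicates for GEE coverage, 20
seeds for end-to-end direction recovery and 200 cohorts for power. All
randomness flows through explicit integer seeds; seeded helpers restore the
caller's RNG state, and `run_pipeline()` records its seed and derived seeds
in a JSON manifest so a run can be reproduced bit-for-bit.

## 8. Known limitations

One-compartment total-drug PK only (no two-compartment or nonlinear
disposition, no renal covariates, MAP point estimates rather than posteriors);
one-factor PERMANOVA; Gaussian-identity GEE only; the differential-abundance
test is a permutation substitute whose fold changes should not be compared
against shrinkage estimators; UniFrac and other phylogeny-aware metrics are
out of scope (no tree); and the generator's structural biases noted above.
The lung-function arm of the original design (normalized FEV₁/FVC trends)
requires external reference equations and clinical data and is deliberately
absent.
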