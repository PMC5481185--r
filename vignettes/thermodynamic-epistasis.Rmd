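---
title: "Thermodynamic epistasis in a repressible promoter: model, estimation, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermodynamic epistasis in a repressible promoter}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epistherm)
```

## The model and its assumptions

`epistherm` models a *cis*-regulatory element (CRE) in which an RNA
polymerase-like activator ("RNAP") and a repressor compete for a
shared binding site. At thermodynamic equilibrium the promoter is in
one of three configurations — empty, RNAP bound, repressor bound —
with Boltzmann weights $1$, $B = [P]e^{-E_P}$ and $A = [R]e^{-E_R}$.
Energies are in kT ($\beta = 1$ throughout) and $[P]$, $[R]$ are
dimensionless activities (exponentials of chemical potentials, treated
as effective concentrations). Expression is proportional to the
occupancy of the transcribing state,

$$p_{ON} = \frac{Be^{-p}}{1 + Ae^{-r} + Be^{-p}},$$

where $(p, r)$ are a mutant's additive perturbations of the two
binding energies (positive = weaker binding; wildtype $(0,0)$; a
double mutant sums its singles' perturbations). Multiplicative
epistasis between two mutations is
$\varepsilon = p_{ON}^{WT} p_{ON}^{m12} / (p_{ON}^{m1} p_{ON}^{m2})$,
which reduces to a ratio of partition sums in which the numerators of
$p_{ON}$ cancel.

Deliberate exclusions: no repressor dimerization or cooperativity, no
multiple operators, no DNA looping, no activator recruitment, no
effects of mutations on DNA structure or site accessibility. Only the
direct, additive effect of each mutation on the two binding energies
enters. These exclusions are what make the sign of epistasis derivable
in closed form; they are also the main gap between the model and a
real lambda-type promoter (see *Limitations*).

### Structural properties used throughout

Three exact consequences of the $\varepsilon$ expression anchor both
the code and the tests:

* **No-repressor sign law.** At $A = 0$,
  $\mathrm{sign}(\varepsilon - 1) =
  -\mathrm{sign}\{(1 - e^{-p_1})(1 - e^{-p_2})\}$: same-sign RNAP
  effects are always negatively epistatic, opposite signs always
  positive, a neutral mutation gives $\varepsilon = 1$. (The intuitive
  route to this rule is the concavity of expression in binding
  energy.) `sign_no_repressor()` implements the rule and is checked
  against brute-force evaluation of $\varepsilon$ on a grid.
* **Saturation.** As $A \to \infty$ with energies additive,
  $\varepsilon \to 1$: at saturating repressor the system is deep in
  the repressed regime on all four genotypes and the deviation decays
  like $1/A$. Trajectories therefore always end in "no epistasis".
* **Symmetric-effect degeneracy.** If every mutation satisfies
  $p_i = r_i$, the weights collapse to $1 + (A+B)e^{-p_i}$ and
  $\varepsilon$ is *exactly* the single-factor expression with weight
  $C = A + B$ — the repressor concentration then never changes the
  sign. Positive epistasis between two mutations that both weaken
  both factors exists only away from this ridge, when one mutation is
  repressor-dominant and the other RNAP-dominant. This observation
  drives the design of `derive_sign_table()` below.

## Sign trajectories across repressor concentration

`sign_trajectory()` holds $E_P$, $E_R$, $P$ fixed, sweeps the
repressor activity over `default_R_grid()` — $R = 0$ plus 241
log-spaced points over $[10^{-12}, 10^{12}]\,e^{E_R}$, wide enough to
bracket every breakpoint for effects up to ~10 kT — and classifies the
collapsed sign sequence into seven categories (`always_positive`,
`always_negative`, `neg_to_pos`, `pos_to_neg`, `zero_then_pos`,
`zero_then_neg`, `no_epistasis`). Numerical conventions:

* the sign at one concentration is `none` when
  $|\varepsilon - 1| \le$ `tol` (default $10^{-9}$, configurable);
* a trailing `none` run is stripped before classification (the
  saturation limit holds for every mutation pair and carries no
  information);
* a `none` run sandwiched between opposite signs is the crossing
  itself and is merged away;
* breakpoints are located by bisection (geometric once both ends are
  positive) to relative precision $10^{-6}$;
* a sequence fitting no category raises an
  `epistherm_unclassified_trajectory` error carrying the sequence —
  never a silent coercion.

All occupancy and $\varepsilon$ arithmetic is done in log space
(log-sum-exp over the three configuration weights), so effects up to
±50 kT and activities up to ~$10^{300}$ stay finite.

### The derived sign table

`derive_sign_table()` enumerates all combinations of per-mutation
effect signs on RNAP and repressor binding, in the binding convention
of such tables ("−" = weakens binding = positive kT perturbation),
and classifies each pair's trajectory. Two design decisions deserve
explanation:

1. **The table is computed, not transcribed.** The sign table is a
   prediction of the model; deriving it numerically from
   `sign_trajectory()` keeps it consistent with the implementation by
   construction and lets the tests assert the table's anchor cells
   (both-weakening → `neg_to_pos`; RNAP-only × repressor-only →
   `zero_then_pos`) against the sweep oracle.
2. **Representative magnitudes.** A sign combination fixes only
   directions, and for some combinations the category is not constant
   over the magnitude region — in particular, by the degeneracy above,
   the both-weakening combination evaluated at fully symmetric
   magnitudes sits exactly on the always-negative ridge. Each cell is
   therefore evaluated at a representative interior configuration in
   which the two mutations primarily target different factors:
   mutation 1 the repressor, mutation 2 the RNAP, with primary effect
   `magnitude` = 4 kT and secondary `minor` = 0.3 kT (a mutation
   touching only one factor gets the primary magnitude on it), at
   `P = 5` (a strong promoter, wildtype occupancy 5/6). The scale
   matches what position-specific energy matrices of specific
   transcription factors show — a few kT for a disruptive operator
   mutation, fractions of a kT for peripheral contacts — and realizes
   the regime in which repressor-binding effects dominate at high
   repressor concentration. Cells are computed once per unordered
   pair, so the table is symmetric under swapping the mutations by
   construction.

## Energy matrices and mutant design

`energy_matrix` stores per-position, per-base kT contributions,
anchored to the CRE by a 0-based, half-open offset on the sense
strand; reverse-strand matrices must be pre-oriented before loading.
Scoring is additive (`sequence_energy`), so a double mutant's
$(p, r)$ is exactly the sum of its singles' — the property that makes
the closed-form $\varepsilon$ applicable to matrix-derived effects.
Matrices are used as supplied, without rescaling; the sign convention
(larger energy = weaker binding) matches $p_{ON}$ decreasing in $E$.

`reduce_spacer_position()` drops, within a user-named spacer region,
the position whose four entries span the smallest range (max − min),
breaking ties toward the 5' end. Range was chosen as the impact metric
because it bounds how much that position can ever change the additive
score; the choice matters only when a published matrix is one position
longer than the element it is applied to. The effect-sign threshold
for calling a matrix-derived effect zero is $|\Delta| > 10^{-9}$ kT.

`design_sign_category_panel()` enumerates every single point mutation,
bins them by $(\mathrm{sign}\,p, \mathrm{sign}\,r)$, and samples
double mutants per requested category uniformly without replacement
under a fixed seed. Categories with no qualifying single mutation are
flagged infeasible rather than erroring: on strong sites sampled by
`sample_energy_matrix()` (reference = strongest binder), mutations
that improve binding of both factors at once do not exist, and the
flag records that fact.

## From fluorescence to epistasis

`normalize_fluorescence()` computes
$f = (\bar{X} - b)/(\bar{X}_{WT} - b)$ per environment, with $b$ the
blank (media autofluorescence) mean. The blank mean is treated as a
known constant in the error propagation; the wildtype's sampling
variance enters each $f$ through the ratio delta method. Non-positive
blank-corrected means are floored at `eps_floor` ($10^{-4}$) times the
corrected wildtype mean — keeping logarithms defined for fully
repressed mutants whose signal falls below the blank — and flagged.

`epistasis_estimates()` forms $\varepsilon = f_{m12}/(f_{m1} f_{m2})$
and works on the log scale internally (expression has a hard lower
bound, making the multiplicative model the natural null):
$\mathrm{var}(\log\varepsilon) = \sum (s_f/f)^2$ over the three
mutants. Because each $f$'s propagated SD already contains the shared
wildtype term, the wildtype variance is counted three times rather
than once net; the resulting test is mildly conservative, which is the
safe direction for an FDR screen, and keeps the per-mutant errors
independent of the pairing structure. The test is a one-sample t on
$\log\varepsilon$ with $df = n - 1$ (5 for the default six
replicates), and q-values are Benjamini–Hochberg within each
environment at $\alpha = 0.05$. `se_floor` ($10^{-12}$) keeps t
defined on noiseless (simulated) data so the oracle-closure check can
run through the identical code path. The sign of epistasis is reported
only for FDR-significant mutants; otherwise `none`.

`classify_epistasis()` applies the background-flip rules: mutation
$i$'s effect is $\mathrm{sign}(f_{mi} - 1)$ on the wildtype and
$\mathrm{sign}(f_{m12}/f_{mj} - 1)$ on the other single's background;
two flips = reciprocal sign, one = sign, none = magnitude (by
$\varepsilon$ vs 1) or no epistasis. An exact $f = 1$ is a zero effect
and cannot flip. Flip-based classes without significant $\varepsilon$
are kept but flagged (`caveat`), so consumers can choose either
reading.

`environment_comparison()` defaults to FDR-called signs, labelling
mutants non-significant in either environment `indeterminate` and
excluding them from the changed/unchanged counts; `lenient = TRUE`
uses point-estimate signs for all mutants, which is what a
whole-cohort switch rate over all pairs requires. `gxgxe_test()` fits
`log epsilon ~ environment` over the per-pair-per-environment
estimates — with $n$ pairs this gives $F_{1,2n-2}$, the natural test
that the pairwise genotype interaction (deviation from
multiplicativity) depends on the environment — with an optional
within-pair permutation p-value as a robustness check.
`conformity_test()` is a Pearson goodness-of-fit of observed category
counts against the predicted distribution, restricted to significant
observations, plus the raw agreement fraction.

## Fitting effective concentrations

Only the weights $A$ and $B$ enter the model, so energy baselines and
activities are not separately identifiable; `fit_concentrations()`
absorbs the baselines and fits effective activities. The objective is
the Pearson correlation between predicted and measured
$\log\varepsilon$, pooled over the two environments ($A = 0$ without
repressor), maximized by a deterministic 25×25 log10 grid over
$[-6, 6]^2$ followed by Nelder-Mead refinement. Correlation (rather
than squared error) makes the fit invariant to monotone rescaling of
measured $\varepsilon$ and robust to an overall gain mismatch;
non-significant mutants are excluded by default, mirroring how such
fits are done on real libraries. A per-environment regression of
measured on predicted $\log\varepsilon$ (slope, intercept, F, p) is
reported as the quality summary; on noiseless matched data it returns
the identity within numerical tolerance.

## What the synthetic generator emulates — and what it does not

`simulation_config()` encodes the study design the pipeline targets: a
43-bp CRE, 141 random double mutants with both corresponding singles,
six replicates per genotype, and two environments (repressor absent /
present). Defaults, with rationale:

* **Footprints**: RNAP positions 0–34, repressor 17–42, overlapping on
  the 3' part of the RNAP site — the qualitative geometry of a
  promoter overlapped by downstream operators. Mutations left of the
  overlap hit only RNAP, right of it only the repressor, inside it
  both.
* **Matrix scales**: mean non-reference entry 1.5 kT (RNAP) and 3 kT
  (repressor), positive-truncated Gaussians with sd = scale/2;
  reference entries 0. A dedicated repressor is the more specific
  binder, and strong sites mean essentially every mutation weakens
  binding — the regime in which most pairs are negatively epistatic
  without repressor and many switch sign with it.
* **Activities**: $P = 5$ (strong promoter, wildtype occupancy 5/6
  without repressor) and $R = 500$ with repressor (~99% repression of
  the wildtype), i.e. a tight but not saturating repressed state.
* **Noise**: replicate fluorescence is the expected mean times
  $e^{N(0, 0.1)}$. Fluorescence is positive and analysed as ratios,
  so multiplicative lognormal noise is the natural family; the 10% CV
  and the blank at 5% of the wildtype signal are plausible
  plate-reader figures, chosen once as stand-ins — no published noise
  model exists for this design.

The generator writes the same formats the pipeline reads, and its
ground truth (model $p_{ON}$, $\varepsilon$, signs) is kept in a
separate table never consumed by the estimation code.

What passing on synthetic data does *not* show: the generator draws
data from the very model the pipeline assumes, with independent
lognormal noise. Real promoter libraries violate both — CI binds
cooperatively as dimers to two operators (sharpening repression and
breaking energy additivity), growth and plate effects correlate
replicates, and mutations can act through DNA structure rather than
direct contacts. Synthetic closure demonstrates correctness of the
implementation and calibration of the statistics under the stated
model, not accuracy of the model for any particular organism.

## Problem sizes and runtime of the checks

The test-suite and acceptance-script sizes were chosen to make the
checks statistically meaningful while staying quick on a laptop: the
no-repressor sign law over $10^5$ random draws; oracle closure on the
full 141-double noiseless cohort (both environments); concentration
recovery over 20 seeded libraries of 30 doubles at 10% noise (median
$|\Delta\log_{10} R|$ well under the 0.3 acceptance bound); and FDR
calibration over 1000 global-null cohorts of 141 pairs (one
environment per cohort). The whole suite runs in about two minutes.

## Known limitations

* The generic model ignores cooperativity, multiple operators and
  looping; for promoters where those dominate, the predicted
  concentration dependence of the sign (especially reciprocal-sign
  enrichment under repression) will be quantitatively off.
* Energy-matrix effects are additive by assumption; matrices are
  trusted as supplied, and effects of mutations outside both
  footprints are exactly zero by construction.
* The sign table is a table of representative behaviors: categories
  for mixed-sign combinations can genuinely depend on relative
  magnitudes, and the table documents one (cross-dominant) regime.
* `fit_concentrations()` profiles only two parameters; it does not
  propagate measurement uncertainty into $P$, $R$ (no posterior), and
  with few significant mutants the repressor activity is weakly
  constrained in the repressor-free environment by design.
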