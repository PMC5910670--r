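---
title: "The siRNA chemistry screening paradigm: models, generators, and design search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The siRNA chemistry screening paradigm: models, generators, and design search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemmap)
```

## The problem

Therapeutic siRNA duplexes delivered to hepatocytes as GalNAc conjugates are
fully 2'-modified: every ribose carries either a 2'-deoxy-2'-fluoro (2'-F) or
a 2'-O-methyl (2'-OMe) group, plus terminal phosphorothioate (PS) linkages.
2'-OMe is bulkier and more stabilizing against nucleases, but placed at the
wrong positions it blocks interaction with the RNA-induced silencing complex
and kills activity. The design question is therefore positional: *which
positions of the 21-nt sense and 23-nt antisense strand tolerate (or prefer)
2'-OMe, and which require 2'-F?* With $2^{21}$ and $2^{23}$ possible
two-chemistry patterns per strand, the space cannot be screened directly;
`chemmap` implements the statistical screening paradigm used to navigate it.

## The positional activity model

Silencing measurements are fractions of control mRNA remaining, modelled on
the natural-log scale. For duplex $i$ measured at site $s(i)$ in species
$c(i)$:

$$\ln y_i = \beta_0 + \sum_{p} \gamma_p\, x_{ip} + u_{s(i)} + v_{c(i)} + \varepsilon_i,$$

where $x_{ip} = 1$ if position $p$ (of the 44 strand positions) carries 2'-F
and $0$ for the 2'-OMe reference, $u_s$ are target-site fixed effects and
$v_c$ species fixed effects. Each $\gamma_p$ is the model-adjusted mean
ln-difference in silencing of 2'-F from 2'-OMe at that position: negative
values mean 2'-F improves silencing. Coefficients with $p < 0.05$ are flagged
significant; no multiplicity correction is applied across the 44 positional
tests, which is a documented caveat of the paradigm rather than an oversight
of the implementation.

Modelling choices that were genuinely open, and how they were settled:

* **Target is absorbed by site.** Site identifiers are nested within
  targets, so a model containing both is rank-deficient in the target
  columns. Site fixed effects absorb target (and, under the synthetic
  generator, species, which is assigned per site); `fit_positional()`
  records absorbed columns rather than warning on every fit. The positional
  contrasts — the quantities of interest — are unaffected.
* **Per-duplex means by default.** Replicate transfections are collapsed to
  the per-duplex geometric mean before fitting (`aggregate = "duplex_mean"`);
  a per-replicate mode is available. Both are supported because the effective
  unit of replication in such screens is ambiguous.
* **Rows with non-positive fractions are rejected at ingest**, never clamped:
  a non-positive fraction of control is a data error, and clamping would bias
  the log-scale fit.
* **Antisense overhang positions 22–23 are modelled** like any other
  position; if a screen never varies them they are reported as inestimable
  rather than silently dropped.
* **Solver.** `fit_ols()` is a pivoted-QR least-squares solver with explicit
  rank detection at relative tolerance $10^{-10}$. Rank-deficient columns are
  dropped with a warning and reported — never silently aliased. Standard
  errors are homoskedastic OLS errors; the tests verify agreement with an
  independent normal-equations oracle to $10^{-8}$.

Sites contribute to the fit only if at least ten distinct designs were
evaluated on them (`min_designs = 10`), enriching the data for positional
contrasts; replicate rows of one duplex count once. The analysis is agnostic
to PS content: PS placement contributes no model column.

## Design-variant comparison

Directed design efforts compare a handful of design variants (DVs) against a
parent across several sequences. `fit_dv_comparison()` fits
$\ln y = \beta_0 + \delta_{d} + \text{dose} + \text{site} + \text{replicate} + \varepsilon$
with the reference design as the dropped level, so each $\delta_d$ is the
model-adjusted mean ln-difference in activity from the parent. Dose enters
as a categorical factor — with two levels (10 and 0.1 nM) this is
assumption-free — and replicate is a categorical blocking factor treated as
batch. Raw quantification reaches this model through
`ddct_relative_expression()`, the standard
$2^{-\Delta\Delta C_t}$ pipeline normalised to a non-targeting control.

## The synthetic-data generators

The raw screen behind the original positional model is not deposited in
machine-readable form, so `chemmap` ships generators that emulate its
statistical structure with planted ground truth. The generator defaults
*are* the study conditions, fixed once:

* **Screen dimensions:** 5 targets × 3 sites/target × 126 duplexes/site
  = 1,890 duplexes; doses 10 and 0.1 nM; quadruplicate transfection.
* **Noise:** multiplicative lognormal on the fraction scale
  (`noise_sd = 0.3` ln units), which keeps observations positive and makes
  the OLS model exactly correct under the generator. Site and target
  baselines are Normal on the ln scale (SD 0.25 and 0.15); species is
  assigned per site, since each site lives in one cell line.
* **Planted positional effects:** strong 2'-F preference at AS2, AS6, AS14
  and S11 (−0.35 to −0.40 ln), opposite moderate effects at AS8/AS9
  (+0.15/−0.15), a mild effect at S6, zero elsewhere. These echo the
  qualitative roles of the field's known critical positions; the exact
  magnitudes are the package's choice of a realistic effect size (about a
  30–50% activity change).
* **In vivo PD:** knockdown follows the surge-decay curve
  $K(t) = K_{\max}(1-e^{-k_{on}t})e^{-k_{off}t}$ with $K_{\max}=0.92$,
  $k_{on}=1.5$/day, $k_{off}=0.05$/day — the simplest form with
  onset/nadir/recovery phases. This PD equation is an invention of the
  generator; no empirical PD law is implied.
* **PK/PD link:** Ago2-loaded antisense strand satisfies the planted
  semilog law $100\,K(t) = a + b\log_{10} L(t)$ with $a = 113$,
  $b = 53.5$ %/log10(ng/g), chosen once so that EC50 ≈ 0.066 ng/g and
  EC80 ≈ 0.24 ng/g — the scale on which such conjugates operate. Sampling is
  3 animals per time point at days 0, 4 h, 3, 7, 14, 21, 35, with lognormal
  noise (SD 0.1) on both mRNA and loading.

What the generators deliberately do **not** emulate: positional interactions
and context effects (the positional model itself omits them), absolute liver
exposure in µg/g, multi-dose regimens, and sequence-specific activity beyond
site/target baselines. Passing recovery tests on synthetic screens therefore
demonstrates that the estimation machinery is correct under the model's own
assumptions — not that real screens satisfy those assumptions.

## In vivo statistics

* **Pre-dose normalization** rescales each animal to 100 at its own day-0
  value; a missing or non-positive pre-dose measurement is an error naming
  the animal.
* **Semilog EC fits** (`fit_semilog_ec()`) regress percent knockdown
  (100 − % of control) on $\log_{10}$ Ago2 loading and invert the line for
  EC50/EC80. EC values outside the observed loading range are flagged
  extrapolated rather than suppressed. A slope of zero within tolerance is
  an error: the EC values are undefined.
* **Extra-sum-of-squares F-test** (`ess_f_test()`) compares one pooled
  semilog line against per-group lines:
  $F = \frac{(SS_p - SS_s)/(df_p - df_s)}{SS_s/df_s}$.
* **Baseline AUC** (`auc_vs_baseline()`) uses a baseline of 100,
  interpolated baseline crossings, and ignores peaks smaller than 10% of the
  observed min-to-max range. Excursions below baseline contribute the
  absolute value of their area. Two conventions required a decision where
  the named commercial software does not document them: baseline *touches*
  (a sampled point exactly at baseline) delimit peaks just like crossings,
  and below-baseline areas are summed in absolute value rather than signed.
* **Recovery slopes** (`recovery_slope_compare()`) are per-group OLS slopes
  (% of control per day) inside a day window, compared by the interaction
  t-test of the pooled two-line model. The default window is days 29–71
  (the window is an argument, because days 22–71 is equally defensible for
  such studies); endpoints are inclusive. Numerically exact fits are
  special-cased so a zero slope difference reports $p = 1$ instead of 0/0
  noise.
* **Two-way ANOVA with post-tests** (`anova2_posttests()`) decomposes
  time × design factorials through `stats::aov` (unbalanced tables fall
  back to sequential SS with a warning). Dunnett comparisons of each design
  against control, per time point, use the pooled residual mean square;
  adjusted p-values come from a seeded Monte Carlo of the joint
  max-|t| null (100,000 draws by default, tolerance about 0.005 on p) and
  are floored at the unadjusted p so adjustment can never appear
  anti-conservative. Sidak uses the closed form $1-(1-p)^m$ over all listed
  comparisons.

## Design search

`propose_variants()` formalizes the minimization goal as: **minimize total
2'-F count subject to predicted activity loss ≤ tolerance** under the fitted
positional map, with constraints fixing critical positions to 2'-F, others
to 2'-OMe, and position pairs (default AS8/AS9) required to share a
chemistry. The historical design process was manual and iterative; this
optimization view reproduces its outcomes as special cases of constraint
sets. The default loss tolerance of 0.1 ln is an arbitrary documented
default — the original effort never quantified "maintaining activity".

Up to 22 free units the search enumerates all patterns exactly; beyond that
a greedy pass converts 2'-F units to 2'-OMe in order of decreasing
coefficient sum (least harmful conversion first) while the budget holds, and
the result is flagged non-exhaustive. With paired positions the problem is a
small knapsack, so the greedy can be mildly suboptimal; the tests document
≥95% agreement with exhaustive enumeration on random instances. Ties in
2'-F count are broken by better predicted activity, then lexicographic
pattern order.

## Fixtures and notation

The modification patterns of the packaged parent and DV duplexes are
**figure-derived reconstructions, not ground truth**: the source graphics
show patterns only as coloured squares. The reconstruction is anchored to
the printed aggregate facts, which are what the tests assert — nine
antisense 2'-F in the parent, six and four in the pair-2'-F and pair-2'-OMe
antisense variants, PS linkages after sense positions 1–2 and antisense
positions 1–2 and 21–22, GalNAc at the sense 3' end. Bases are a synthetic
placeholder sequence built to be self-complementary over the paired region.
The notation dialect (`asusc`, `AfsCfsgu`, `-L96`) mirrors common
modified-siRNA shorthand; complementarity violations in parsed duplexes warn
rather than fail because real tables may carry redacted bases.

## Problem sizes used by the test suite

The suite fits the full default screen (1,890 duplexes) across 20 seeds for
parameter recovery, runs 1,000 reduced screens (two sites × 40 duplexes) for
null calibration of the positional test, 1,000 null simulations each for the
DV comparison and the ESS F-test, 100 random instances against the
exhaustive design-search oracle, and 100 noisy PK/PD time courses for EC50
recovery. These sizes give binomial standard errors comfortably inside the
asserted bands while keeping the suite quick to run.

## Known limitations

* The positional model is additive: no interaction terms between positions,
  so context effects — which the directed SAR rounds exist to catch — are
  invisible to it by construction.
* Homoskedastic OLS standard errors only; no clustered or robust option.
* The DV model is fixed-effects only; no pooling across independent
  experiments beyond the replicate factor.
* No compartmental PK modelling and no four-parameter logistic
  dose-response: the PK/PD analysis is deliberately semilog-linear.
* Only the {2'-F, 2'-OMe} × PS chemistry space is represented; no GNA,
  2'-MOE, or thermodynamic modelling.
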