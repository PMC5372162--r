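---
title: "Null-model inference for coral exosymbiont guilds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Null-model inference for coral exosymbiont guilds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The ecological question

Branching pocilloporid corals host a guild of obligate decapod
exosymbionts — *Trapezia* crabs and the snapping shrimp *Alpheus lottini* —
that defend and clean their host. Several species can share one colony, so
the composition of each colony's assemblage carries information about
species interactions: do particular crab–shrimp partnerships form more
often than chance would produce, and do territorial species exclude one
another? The question is sharpened by cryptic diversity: *A. lottini*
comprises two deeply divergent lineages (L1, L2) that ecological surveys
rarely separate, and several *Trapezia* morphospecies hide further
lineages.

`coralguild` implements the full inferential chain for this problem:

1. a colony-level data model (`colony_set`) with stratified sampling labels
   (region x site x stage x host type) and per-colony assemblages;
2. three Monte-Carlo null models for the binary colonies x species
   occupancy matrix, with a percentile confidence-interval decision rule;
3. the guild statistics those nulls are compared against — the richness
   profile $n_k$ (colonies hosting exactly $k$ of the five key species),
   pairwise co-occurrence counts $c_{ij}$, and solitary counts $s_i$;
4. ordination (correspondence analysis) and the ANOSIM permutation test
   for compositional differences between host types, regions and sites;
5. net nucleotide divergence summaries used to justify treating cryptic
   lineages as distinct species;
6. an exactly enumerable synthetic community generator used to measure the
   decision procedure's type-I error and power.

The package ships a colony-level transcription of a published survey of
234 *Pocillopora damicornis* (types alpha and beta) colonies from Reunion
Island (RI) and New Caledonia (NC) as `coral_survey()`; its provenance and
two ambiguous transcription decisions are documented in
`inst/extdata/fixture_notes.md`.

## The null models

Let $M$ be the $N \times S$ binary occupancy matrix of one analysis
stratum ($N$ colonies, $S = 5$ key species), with grand total
$F = \sum_{is} m_{is}$, column sums $f_s$ (species frequencies) and row
sums $r_i$ (colony richness). The three nulls condition on progressively
more of the observed structure:

* **M1 (unconstrained).** Every species can settle every colony with equal
  chance. We place the observed $F$ presences uniformly at random over the
  $N \times S$ cells without replacement. Only $F$ is conserved.
* **M2 (frequency-constrained).** Common species stay common: each
  column's $f_s$ presences are reassigned to a uniform random subset of
  $f_s$ colonies, independently per species. Column sums are conserved
  exactly; row sums are free.
* **M3 (richness-constrained).** Some colonies are intrinsically better
  hosts: each row's $r_i$ presences are reassigned to a uniform random
  subset of $r_i$ species. Row sums are conserved exactly; column sums are
  free. M3 is used for the co-occurrence family only — under M3 the
  richness profile is conserved by construction, so comparing it would be
  vacuous (a property the test suite asserts).

Strata are always randomized separately (region and host type define
distinct species pools); the package never pools colonies across strata.

**The M1 design choice.** "Randomly assigned to corals" admits several
formalizations. We condition on the observed grand total (uniform
placement of $F$ presences), which keeps every statistic on the observed
prevalence scale while leaving both margins free — the natural
"unconstrained" baseline between nothing-fixed and M2. An alternative that
fills each cell independently with probability $F/(NS)$ is available via
`null_config(m1_variant = "binomial")`; it conserves $F$ only in
expectation. Published interval endpoints for this analysis family are not
generally recoverable without knowing which variant (and which conditioning
level) produced them, which is why the package's benchmarks are the
*observed* counts, never printed interval endpoints.

## The decision rule

For each statistic we simulate `reps` (default 10,000) random communities,
and take the empirical $\alpha/2$ and $1-\alpha/2$ quantiles of the null
samples with the inverse-ECDF (type-1) definition — no interpolation, so
on integer-valued statistics both CI endpoints are attained integer
values. The association hypothesis is rejected only when the observed
value falls strictly outside the interval: observations equal to an
endpoint are flagged `inside`. On discrete counts this makes the rule
conservative (coverage at least the nominal 95%, often more), which the
acceptance suite quantifies: coverage of the M2 interval under M2's own
null is measured at 500 datasets x 2,000 replicates and required to land
in [0.91, 0.99].

Reproducibility: a run is seeded once from the configuration's master
seed and replicates are drawn sequentially from R's Mersenne-Twister
stream, so identical seed + configuration gives bit-identical null
samples. Per-stratum sub-seeds in the pipeline are derived
deterministically from the master seed. (We deliberately use one
sequential stream rather than per-replicate counter-based substreams:
the package has no parallel execution path, and a single stream keeps
the implementation auditable.)

The richness family is reported for $k = 0$ too, although the headline
comparisons concern $k \ge 1$; $n_0$ rows are informational. Empty
colonies stay in the randomized matrices (they can gain presences under
M1/M2) — restricting to occupied colonies would condition the null on an
outcome of the process being tested.

## Ordination and compositional tests

`correspondence_analysis()` is classical CA: with correspondence matrix
$P$, row masses $r$ and column masses $c$, it decomposes
$S = D_r^{-1/2}(P - rc^\top)D_c^{-1/2}$ by SVD; principal inertias are
squared singular values and their sum equals Pearson's $\chi^2/n$, an
identity the tests assert to $10^{-9}$. Colonies without exosymbionts
carry no chi-square information and are dropped, per the field convention
for this analysis.

`anosim()` implements Clarke's rank statistic
$R = (\bar{r}_B - \bar{r}_W)/(M/2)$ with $M = n(n-1)/2$ and midranks for
ties, so $R \in [-1, 1]$ and $R = 1$ under complete separation. The
permutation p-value carries the add-one correction
$p = (1 + \#\{R^* \ge R\})/(1 + n_\text{perm})$ and can never be zero.
The dissimilarity is a configuration choice: Bray–Curtis by default (the
default of the standard vegan implementation), chi-square distance as the
alternative that matches the CA geometry.

Two published headline values — the ANOSIM $R$ for adult alpha-vs-beta
hosts and the CA axis percentages — depend on an input coding (individual
counts vs colony presences, inclusion rules for unresolved shrimp) that is
not recoverable from the packaged presence-level data. The package
computes these quantities and reports them, but treats them as soft
checks, not benchmarks; the acceptance script records the values actually
computed from the packaged coding (presence counts, all 13 taxa, empty
colonies dropped).

## Sequence divergence

`net_divergence()` implements Nei's $D_a = d_{XY} - (d_X + d_Y)/2$ on
uncorrected p-distances with pairwise deletion (sites with a gap or `N`
in either sequence are excluded per pair). Uncorrected distances are the
simplest convention that is reproducible without knowing a MEGA session's
model dialog; a Jukes–Cantor option (`correction = "jc69"`) is provided
for sensitivity analysis, and pairwise deletion is stated explicitly
because complete-deletion defaults differ between tools. A group with one
sequence gets within-group distance 0 by convention and the result is
flagged `within_degenerate`. Published divergence percentages for the
real lineages require the underlying GenBank alignments, so the package
validates $D_a$ against brute-force all-pairs oracles on synthetic
alignments instead (exact agreement), plus a cross-check of the
p-distance engine against `ape::dist.dna(model = "raw")`.

## The synthetic community generator

Validating a null-model decision procedure needs data with *known*
interaction structure. `interaction_model()` defines a pairwise
exponential-family (auto-logistic/Ising) distribution over the
$2^5 = 32$ presence states of the five key species,

$$P(x) \propto \exp\Big(\sum_s \alpha_s x_s +
  \sum_{s<t} \theta_{st} x_s x_t\Big),$$

chosen precisely because 32 states are exactly enumerable:
`state_distribution()` normalizes by full enumeration, so every marginal,
every pairwise moment (`expected_cooccurrence()`) and hence the expected
value of every downstream statistic has a closed-form oracle.
`match_prevalence()` solves $\alpha$ for target marginals by damped
fixed-point on the enumerated marginals (logit closed form when
$\theta = 0$), converging to $10^{-6}$.

`generate_communities()` draws colonies i.i.d. from the state
distribution — the study-condition defaults are $N = 60$ colonies per
stratum (the scale of the survey's adult strata) and prevalence 0.4
(the scale of the commonest key species). Non-key taxa can be added as
independent background presences; they only matter for ordination
realism.

What the generator does **not** emulate — and therefore what passing
tests cannot show about field data: spatial or temporal structure in
recruitment, host-size-dependent occupancy, between-colony heterogeneity
in suitability (every synthetic colony is exchangeable), and
individual-count abundance structure. It validates the statistical
machinery, not the ecology.

`power_experiment()` measures the operating characteristics of the
pairwise test: with $\theta = 0$ the per-pair two-sided flag rate
estimates type-I error (required in [0.01, 0.10] at $N = 60$, prevalence
0.4, M2, 95% CI — the lower bound acknowledging the discreteness-driven
conservatism noted above, measured over 400 datasets x 1,000 replicates
in the acceptance suite); with $\theta_{12} = +2$ and $\alpha$ re-tuned
to prevalence 0.4 it estimates power, required above 70% under the same
conditions. The acceptance script runs a lighter configuration (200
datasets x 500 replicates) chosen to keep a full from-scratch rerun
under a minute while leaving Monte-Carlo error well inside those bands.

## Numerical and degenerate-input conventions

* Type-1 quantiles throughout the CI machinery; `percentile_ci(x, 1)`
  returns the sample range; a single replicate gives a degenerate CI.
* Saturated (all-ones) and empty (all-zero) matrices are fixed points of
  every randomizer; full columns/rows are fixed points of M2/M3.
* CA refuses rank-0 (single non-empty row/column) tables with a named
  error; proportional rows give zero total inertia and zero axis
  percentages rather than 0/0.
* ANOSIM requires at least two groups with two members each and a
  symmetric zero-diagonal input.
* `p_distance()` errors when no site is comparable rather than returning
  `NaN`; Jukes–Cantor is undefined at $p \ge 0.75$ and says so.
* Taxon column order always follows the taxon-set declaration order, and
  colony row order follows the input table, so reports are stable across
  equivalent calls.

## Problem sizes used in validation

The test suite enumerates admissible sets exactly for matrices up to 12
cells (up to 924 admissible configurations, at $\ge 200$ draws per
configuration), runs brute-force oracles for the guild statistics on 200
random matrices up to $8 \times 5$, enumerates all relabellings for
ANOSIM on 6–8 samples, and uses the fixed sizes quoted above for
coverage/type-I/power. These sizes were chosen as the smallest that make
the chi-square goodness-of-fit and binomial tolerances meaningful.

## Known limitations

* The exact randomization behind published interval endpoints for this
  analysis family is not identifiable from a methods description alone;
  this package documents its own semantics precisely instead of chasing
  printed intervals.
* The fixture records presences only; abundance-weighted analyses of the
  packaged survey reduce to presence analyses.
* The null models treat colonies as exchangeable within a stratum; there
  is no covariate-adjusted (e.g. colony-size) null.
* Higher-order (triplet and beyond) interaction statistics are out of
  scope; the synthetic model can generate them, but the tests target
  pairwise structure.

## A minimal session

```{r, eval = FALSE}
library(coralguild)

survey <- coral_survey()
report <- run_guild_analysis(survey, region = "RI", stage = "adult",
                             reps = 10000, seed = 42)
subset(report, flag != "inside" & family == "pairwise")

# full five-stratum reproduction with TSV reports
res <- reproduce_guild_analysis("guild_out", reps = 10000, seed = 42)
res$summary
```
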