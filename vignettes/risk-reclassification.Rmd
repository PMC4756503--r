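---
title: "Methods: genetic risk reclassification as GWAS catalogs grow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genetic risk reclassification as GWAS catalogs grow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riskdrift)
```

## The question and the model

Genetic risk profiles built from genome-wide-significant SNPs change as
catalogs grow: new loci are discovered and effect estimates of known loci
are revised. `riskdrift` quantifies how much an individual's risk *tier*
drifts between successive panel versions, and how much more drift to
expect from the next generation of larger studies.

The risk model is the multiplicative per-allele odds model that underlies
most published genetic risk scores and direct-to-consumer reports. With a
panel of $k_m$ SNPs at time $m$, individual $i$ has

$$\mathrm{Odds}_{i,m} = \prod_{j=1}^{k_m} \mathrm{OR}_{j,m}^{\,g_{ij}},
\qquad O_{i,m} = \frac{\mathrm{Odds}_{i,m}}{\overline{\mathrm{Odds}}_{m}},$$

where $g_{ij} \in \{0,1,2\}$ counts risk alleles and the denominator is
the cohort mean, so $O$ is odds relative to the population average.
Tiers are Lower ($O < 0.5$), Average ($0.5 \le O \le 2$) and Higher
($O > 2$); the boundary values fall in Average. The 0.5/2 thresholds are
a conventional benchmark for "potentially actionable" genetic risk, not a
clinical decision rule; both are arguments (`lo`, `hi`) everywhere.

Assumptions inherited from this model: per-allele (log-additive) effects,
no SNP–SNP interaction, no non-genetic covariates, and the rare-disease
approximation under which odds ratios act as relative risks and the
general population stands in for controls. `control_dist_at_incidence()`
relaxes the last assumption explicitly: given incidence $K$ and
$\Pr(D\mid g) = c\,O_g$ (so $c = K$ because the normalized odds have unit
population mean), the control mass becomes
$(1 - c\,O_g)\Pr(g)/(1-K)$. This is feasible only while
$c \cdot \max_g O_g \le 1$, which the function checks; the incidence
argument is capped at 10 %, the range over which tier proportions barely
move (the package's own guardrail tests assert changes below 0.02).

## Panel construction

Catalog reports become time-$m$ panels in four steps, each with a
deliberate convention:

* **Significance filter.** Only reports with $p < 5\times10^{-8}$ enter
  (argument `alpha`). Reports with OR $< 1$ are re-oriented at ingest
  (OR $\to$ 1/OR, raf $\to$ 1 − raf) so stored ORs are $\ge 1$ and $g$
  always counts risk alleles, which is what the odds product assumes.
* **Locus assignment.** "Within 500 kb" is read as single-linkage
  chaining per chromosome (adjacent gaps ≤ `window_bp`). Pairwise-complete
  grouping is not well defined for chains of SNPs each within 500 kb of
  the next but not of the ends; chaining is deterministic and
  order-independent.
* **LD pruning.** Stepwise by ascending p-value; a candidate is kept only
  if $r^2 <$ `r2_max` against *every* retained SNP. Ties in p-value break
  by smaller position, then lexicographic rsid, so results are
  reproducible. The endpoints short-circuit: `r2_max = 0` keeps exactly
  the top SNP per locus and `r2_max = 1` keeps everything — the two
  sensitivity-analysis extremes, with `r2_max = 1` implemented as "no
  pruning" because a literal strict inequality would drop perfect
  proxies, the opposite of the intended endpoint. $r^2$ comes from a
  user-supplied table; an absent pair is an error, never an assumed 0.
* **OR update.** A SNP's effective OR at time $m$ is the one from its
  most significant report dated ≤ $m$; a later report replaces it only if
  *strictly* more significant, ties keeping the earlier report.

Panels are cumulative in reporting but not necessarily nested after
pruning: a newly reported, more significant neighbour can evict a SNP
that belonged to an earlier panel. This is intended — it is one of the
two mechanisms of reclassification (the other being new loci).

## Cohort simulation and the exact path

One cohort serves all panels: genotypes are simulated once for the union
of SNPs across every time point, so between-panel differences reflect
panel change only, never genotype resampling. Single-SNP loci draw
$g \sim \mathrm{Binomial}(2, q)$ (Hardy–Weinberg); multi-SNP loci draw
two haplotypes independently from a `haplotype_model` (random mating),
either supplied, bootstrapped from a phased pool (equivalent to sampling
with count-proportional probabilities), or estimated from unphased data
by `em_haplotypes()`. The EM uses the standard genotype-to-diplotype
E-step; it initialises at linkage-equilibrium product frequencies
(optionally jittered, default off), collapses identical genotype rows so
cost scales with distinct genotype classes rather than cohort size, and
flags — rather than hides — failure to converge within `max_iter`.
Simulated individuals are i.i.d.; no relatedness filter exists because
none is needed by construction.

For small panels, `exact_distribution()` replaces simulation: per-locus
genotype distributions are collapsed to distinct log-odds values and
convolved across independent loci. Numerical choices: odds accumulate in
log space (hundred-SNP panels overflow naive products); convolution keys
on log-odds rounded to 10 decimals to merge floating-point duplicates
arising from different summation orders; the enumerated space is capped
(default $10^6$ classes) with an error directing users to the
Monte-Carlo path. Normalization on the exact path uses the *exact*
population mean, so enumeration results are seed-free; the cohort path
uses the sample mean, as an empirical analysis would. Case mass is
$O_g \Pr(g)$, which sums to one automatically after normalization.

## Reclassification metrics

`reclassification_metrics()` reports the off-diagonal share of the 3×3
table, the collapsed Higher-vs-rest share (never larger than the 3×3
share), and the share of time-1 Higher individuals demoted — reported as
`NA`, not 0, when nobody was Higher at time 1, since the quantity is
undefined there. The NRI counts any upward tier move once (Lower to
Higher is one move, not two). On the cohort path, cases and controls are
the same individuals reweighted: control weights are uniform and case
weights are proportional to normalized odds at the **earlier** panel by
default. This convention makes the comparison "how does the new model
re-rank the people the old model flagged", and on synthetic timelines it
typically yields *negative* NRIs, because the later model demotes many
provisionally high-risk individuals. The switch
`nri_weights = "later"` — treating the better model as the closer proxy
for true case status — flips the perspective and typically gives the
positive "model improvement" sign. Both are defensible; the default was
fixed once and documented rather than tuned.

The AUC is computed two ways on purpose: `empirical_auc()` is a weighted
Mann–Whitney statistic (ties half-weight) and `analytic_auc()` is the
binormal closed form from log-odds moments. The binormal form is exact
when both log-score distributions are normal and a good approximation
for polygenic panels; keeping both routes lets each validate the other,
and the package's tests compare them on panels where neither is the
oracle for the other.

## Projection of future discoveries

The total number of detectable susceptibility SNPs is estimated by
effect-size binning: each observed SNP, with effect size
$e = \beta^2 2q(1-q)$, is inflated to $M_{T,j} = M_j / p_j$ by the power
$p_j$ to have detected it under the reference design, and
$M_\mathrm{total} = \sum_j M_{T,j}$. One bin per observed SNP is the
default (histogram binning on $e$ is available via `breaks` but off by
default, since per-SNP binning needs no bin-width choice).

Detection power is the two-sided normal-approximation power of the
per-allele trend test,
$\mathrm{SE} = \sqrt{\tfrac{1}{2q(1-q)}\left(\tfrac{1}{n_\mathrm{cases}} +
\tfrac{1}{n_\mathrm{controls}}\right)}$, rejecting when
$|\hat\beta|/\mathrm{SE} > z_{1-\alpha/2}$. This closed form *defines*
power throughout the package. The simulation oracle used in testing
draws $\hat\beta \sim N(\beta, \mathrm{SE}^2)$ (with stratified uniforms
for variance reduction) and checks the tail arithmetic; a fully
data-level simulation of allele counts agrees to about one percentage
point at moderate effects — the residual is approximation error of the
variance model (case-allele variance shifts under the alternative), not
an implementation artefact, and a separate test documents that gap with
its own tolerance. Two-stage designs are treated as single-stage at the
combined sample size.

A future study with multiplied sample size contributes
$\lceil p'_j M_{T,j} \rceil$ SNPs per bin, each in its own locus, with
the bin's $\beta$ and $q$. The observed seed SNP is retained by default
(`mode = "augment"`) so current and future panels share genotypes and
individual-level reclassification is meaningful; `mode = "all_new"`
simulates every future SNP fresh instead. The two readings cannot both
hold literally — new SNPs in unique loci versus reclassifying the same
individuals — so both are implemented and the comparability-preserving
one is the default. Because power is monotone in sample size,
$\lceil p'_j M_{T,j}\rceil \ge M_j$; a guard enforces this regardless.

## The synthetic generator

`make_universe()` + `discovery_schedule()` + `simulate_discovery()`
emulate what a real analysis downloads: a catalog of
genome-wide-significant reports accumulating over four biennial time
points. Defaults, chosen once as field-plausible conditions:

* 300 causal SNPs (pipeline default; arguments everywhere), each its own
  locus (multi-SNP loci are opt-in via `make_ld_fixture()`, keeping
  enumeration oracles exact by default);
* $\beta = \log(1.05) + \mathrm{Exp}(\text{mean } 0.06)$, giving ORs
  mostly 1.05–1.3 with a thin tail of larger effects — the regime where
  GWAS effect sizes concentrate;
* $q \sim U(0.05, 0.95)$ (common variants, as tag-SNP catalogs contain);
* cumulative case counts 5,000 / 12,000 / 25,000 / 50,000 (controls
  equal), a roughly geometric growth that keeps each wave's discoveries
  large relative to the existing panel — the "tipping point" regime in
  which reclassification stays high.

At each wave, each undiscovered SNP is reported with probability equal
to its detection power; its p-value derives from an effect estimate
drawn from the sampling distribution truncated to significance (so
reports are internally consistent with the discovery event), and the
reported OR is the true one unless `winners_curse = TRUE`, in which case
the truncated (upward-biased) estimate is reported. Previously
discovered SNPs are re-reported at later waves, exercising the OR-update
rule. With the curse off, oracle tests can check exact OR recovery; with
it on, the generator reproduces the declining mean effect size of later
discoveries.

What the generator does **not** emulate: realistic genome-wide LD maps,
ancestry-specific frequency spectra, population structure, relatedness,
rare variants, or interacting loci. Passing tests therefore demonstrate
the correctness and internal consistency of the pipeline under the
stated architecture, not that real catalogs would produce the same
numbers — real-catalog results additionally depend on curation
snapshots, winner's curse in published ORs, and LD reference panels.

`make_ld_fixture()` builds haplotype frequencies hitting a target
adjacent-pair $r^2$ through a first-order chain
($D = r\sqrt{q_a(1-q_a)q_b(1-q_b)}$, positive sign); infeasible
$(r^2, q)$ combinations error with the attainable bound. For more than
two SNPs, non-adjacent correlations decay geometrically — adequate for
exercising the pruning and diplotype paths, not a model of real
haplotype blocks.

## Problem sizes and runtime choices

Default analyses use 100,000-individual cohorts (matching the headline
study conditions); package tests use 100,000 where a 3-standard-error
binomial comparison needs it and 10,000–20,000 for structural checks,
which keeps the full suite to a few minutes. Exact enumeration is the
reference for panels of up to ~10 SNPs; beyond the cap the Monte-Carlo
path is the intended route. EM accuracy (mean max-frequency error below
0.01) is established at $n = 10{,}000$ over 50 seeds; the bin-method
recovery check uses a 200-SNP universe and 200 replicates.

## Known limitations

* The rare-disease case weighting is an approximation; explicit-incidence
  adjustment exists for controls only, and no absolute-risk or
  calibration machinery is provided (out of scope by design).
* The binormal AUC degrades for very small panels whose log-odds
  distribution is strongly discrete; the empirical route is preferred
  there.
* NRI and reclassification rates depend on the 0.5/2 thresholds; no
  confidence intervals are computed for either.
* The power formula's normal approximation is slightly conservative at
  large effect sizes (see above); projected future-panel sizes inherit
  that bias in the conservative direction.
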