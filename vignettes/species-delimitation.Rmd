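---
title: "Coalescent species delimitation with coaldelim: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coalescent species delimitation with coaldelim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coaldelim)
library(ape)
```

# The problem

Species complexes with plastic morphology — lichenized fungi are a
canonical case — often cannot be delimited from phenotype alone. Given
multi-locus sequence data, a now-standard inference chain asks four
questions: (1) where on an ultrametric tree does branching switch from a
between-species to a within-species tempo (GMYC)? (2) are the resulting
putative species recovered as monophyletic groups in independent
single-locus gene trees (genealogical concordance)? (3) which partition of
samples into species best explains the gene trees under the multispecies
coalescent (scenario comparison)? (4) do morphological and chemical
characters track the molecular clades (homoplasy and association tests)?
`coaldelim` implements this chain end to end, with seeded simulators so the
whole pipeline is testable without sequence downloads.

# The GMYC model

The general mixed Yule-coalescent model assumes a single ultrametric
chronogram whose branching events are of two kinds: diversification
(speciation) events among species-level lineages, and coalescent events
within species. A threshold age $T$ separates the two regimes. Slicing the
tree at every distinct branching age gives inter-node intervals; in
interval $i$ of width $x_i$, with $n_{Y,i}$ diversification lineages and
$n_{j,i}$ lineages in coalescent cluster $j$, the total branching rate is

$$ b_i = \lambda_Y\, n_{Y,i}^{\,p_Y} \;+\; \lambda_C \sum_j
   \left[n_{j,i}(n_{j,i}-1)\right]^{p_C}, $$

and the log-likelihood is $\sum_i \left[ m_i \log b_i - b_i x_i \right]$,
where $m_i$ counts the branching events terminating the interval
("competing processes" form: every event is scored against the total
rate). The scaling exponents $p_Y, p_C$ absorb departures from strict Yule
($p_Y = 1$) and neutral-coalescent ($p_C = 1$) tempo. The null model — the
entire sample is one population — is the special case of a single all-tips
cluster with no diversification lineages, with rate
$b_i = \lambda\,[n_i(n_i-1)]^p$.

Conventions worth stating:

* **Time.** Node ages are measured back from the tips (age 0 at the
  present). Printed thresholds are negated ages, matching the usual
  lineage-through-time axis on which the present is 0 and the root is
  negative.
* **Zero-length branches.** Chronograms whose polytomies were resolved
  arbitrarily contain zero-length internal branches. Equal branching ages
  are merged into one interval whose terminating multiplicity $m_i$ counts
  all simultaneous events; each contributes one $\log b_i$ term.
* **Sentinels.** An event-terminated interval with zero total rate makes
  the likelihood $-\infty$; this is returned as a value, never thrown.

## Fitting

`fit_null()` exploits the fact that for fixed $p$ the scale has the
closed-form profile maximum $\hat\lambda(p) = E / \sum_i w_i(p)\,x_i$ (with
$E$ the number of events and $w_i = [n_i(n_i-1)]^p$), reducing the fit to a
1-D bounded search over $p \in [0, 2]$.

`fit_single_threshold()` scans all candidate thresholds — midpoints between
successive distinct branching ages, plus one placed beyond the root (which
reproduces the null) — and re-optimizes all four parameters
$(\lambda_Y, p_Y, \lambda_C, p_C)$ at each by bounded quasi-Newton
(L-BFGS-B with analytic gradients, in $\log\lambda$ coordinates, scales in
$[10^{-8}, 10^6]$, exponents in $[0, 2]$, convergence tolerance $10^{-8}$
on the log-likelihood). Start points form a deterministic $3 \times 3$ grid
of (scale multiplier, exponent) values around the events-per-time heuristic
rate. Because adjacent thresholds have nearly identical optima, the scan
applies the full grid at the first candidate and every 8th thereafter and
warm-starts the candidates in between from their neighbour's optimum (plus
a start at the fitted null optimum); the winning threshold is then
re-polished from the full grid. Ties in log-likelihood are broken toward
the *oldest* threshold, i.e. the most inclusive clusters.

The likelihood-ratio test against the null uses $\chi^2_3$ (threshold,
extra scale, extra exponent). The confidence set collects the entity counts
of all candidates within 2 log-likelihood units of the maximum — the
profile-likelihood support convention. Entities are clusters (coalescent
clades with $\ge 2$ tips) plus singletons (tips attaching above every
threshold); both are counted.

## Multiple thresholds

The multiple-threshold state is represented as the antichain of *cluster
roots*: the set of internal nodes whose subtrees are the coalescent
clusters. This is equivalent to subtree-local thresholds (a local threshold
lies anywhere strictly between a cluster root's age and its parent's age),
and it makes the search neighbourhood concrete: a **split** replaces a
cluster root by its internal children; a **merge** promotes a node whose
children are all tips or cluster roots. Moving a local threshold is a split
followed by a merge, so split/merge moves are complete. Starting from the
single-threshold fit, the climb evaluates all neighbours (warm-started
re-optimization of all four parameters), accepts the best one, and repeats.

A move is accepted only if it gains more than `tol_improve` log-likelihood
units, with default 2 — again the profile-likelihood support convention.
This was a genuinely open design point: with an epsilon acceptance gain the
climb is a pure ML hill climb, and on simulated data it accumulates many
switches that each improve the likelihood marginally (a known tendency of
multiple-threshold fitting: extra switches are nearly free when exponents
are flexible). The 2-unit gain keeps only switches with meaningful support
while preserving the monotonicity guarantee (the returned log-likelihood is
never below the single-threshold fit's); `tol_improve = 1e-6` restores the
pure climb. Reported switch ages are the distinct local threshold
midpoints; the multiple-vs-single LRT uses 3 degrees of freedom per
additional switch.

## What the calibration checks do and do not show

On simulated data where the smallest species divergence is $\ge 10\times$
the deepest within-species coalescence, the single-threshold fit recovers
the true number of species in well over 90% of replicates (the acceptance
script measures this at $K = 12$ species, 10 tips each, 50 replicates).

The LRT, however, should be read with care: the statistic maximizes the
mixed likelihood over the whole candidate-threshold grid, a multiple
comparison the $\chi^2_3$ reference does not account for. On
pure-coalescent simulations the rejection rate at $\alpha = 0.05$ therefore
runs *above* nominal (the acceptance script reports it as
`lrt_type1_rate`, around twice the nominal level at 60 tips). This
anticonservativeness is a property of threshold-scan likelihood-ratio
tests generally, not of this implementation — the likelihood itself is
verified against an independent interval-enumeration oracle. Users should
treat marginal GMYC p-values near 0.05 as inconclusive.

# Genealogical concordance

Each putative species is scored in each single-locus gene tree:
**supported** if monophyletic with bootstrap support at or above the
threshold (default 70%), **present** if monophyletic without qualifying
support, **absent** if not monophyletic, **n/a** if fewer than two of its
samples occur in that locus. Missing taxa are handled by judging monophyly
on the *shared* tips only — herbarium data sets routinely lack some loci
for some samples, and requiring the full sample set would make most cells
unassessable. Unrooted inputs are rooted at a declared outgroup, or by
midpoint rooting as a fallback. Support is read from the node label of the
focal clade's MRCA, i.e. the edge subtending the clade.

# Multispecies-coalescent scenario comparison

A delimitation scenario is a tip-to-species map. For each scenario the
species tree is estimated by the **maximum-tree / GLASS** construction:
each species-pair divergence is the minimum coalescence time observed
between the species across loci and tip pairs, and the ultrametric species
tree is the single-linkage clustering of those minima (ties broken by
species-label order). This is the natural estimator here because minimum
cross-species coalescence times are consistent lower-bound estimators of
divergences under the MSC, and it guarantees the estimated tree is
compatible with every gene tree.

Given a species tree and a single shared population-size parameter
$\theta$, the gene-tree log-likelihood is analytic: a population carrying
$j$ lineages over a span $\Delta t$ contributes $-j(j-1)\Delta t/\theta$,
each coalescence inside it $\log(2/\theta)$; lineages pool at species
divergences and the root population extends to the past. A coalescence
between two species younger than their divergence makes the scenario
incompatible ($-\infty$ with a diagnostic). The one-species scenario is a
single panmictic population, independent of any species tree.

The default policy fixes $\theta = 1$ (the user-supplied-$\theta$
convention of this analysis style; gene trees are assumed ultrametric in
coalescent units, and calibration is out of scope); `theta_policy =
"profile"` instead uses the closed-form MLE $\hat\theta = A/C$ where $A =
\sum j(j-1)\Delta t$ and $C$ is the number of coalescences. Scenarios are
reported with $-\ln L$, parameter count $k = \#\text{species} + 1$ (the
$+1$ is $\theta$), $\Delta \ln L$ against the one-species reference, an LRT
p-value with $df = \Delta k$ Bonferroni-corrected by the number of
comparisons against the reference, and $AIC = 2k + 2(-\ln L)$. Ranking
follows $\Delta \ln L$, with the AIC-best scenario flagged separately.
`scenario_table()` exposes the same arithmetic for externally supplied
likelihood scores (e.g. a published table).

# Phenotype-clade association

Characters are unordered categories. Observed steps $s$ come from the Fitch
bottom-up pass (intersect child state sets, else union and count a step;
tips missing the character are pruned per character). With $m =
\#\text{observed states} - 1$ the minimum conceivable steps and $M =
\#\text{scored tips} - \text{modal state frequency}$ the maximum, the
consistency index is $CI = m/s$ and the retention index $RI =
(M-s)/(M-m)$. Invariant characters ($m = 0$) have undefined CI; characters
with $M = m$ (e.g. binary autapomorphies) have undefined RI; both are
reported as `NA` rather than forced.

Association uses the Pearson chi-square on the clade-by-state count table
with $df = (r-1)(c-1)$, matching the df-reporting style of contingency
analyses in this literature; expected counts below 5 raise a flag rather
than switching tests silently. Species (e.g. a morphologically deviating
one) and characters (e.g. organs too rarely sampled) can be excluded
per-test while still being scored for CI/RI.

# The simulators

The generators emulate the structure of a herbarium multi-locus study:
roughly 120 ingroup samples, 4 loci, and about a dozen candidate species —
the default mixed-tree configuration is $K = 12$ species with 10 samples
each and 4 loci.

* `simulate_yule_tree()` — pure-birth species trees. Pure birth (no
  extinction) is deliberate: the fitted diversification component has no
  separate death parameter, so simulating extinction would add a process
  the model cannot see. Root ages follow the analytic expectation
  $\sum_{i=2}^{K} 1/(i\lambda)$.
* `simulate_coalescent_tree()` / `simulate_msc_gene_trees()` — Kingman
  coalescent with pairwise rate $2/\theta$, run within species-tree
  populations, pooled at divergences, continued above the root with the
  same $\theta$.
* `simulate_gmyc_tree()` — a Yule species tree with a coalescent genealogy
  grafted at each species tip, returning the true membership. The
  `separation` control (default ratio 10) rescales the species tree so the
  youngest divergence is that multiple of the deepest within-species
  coalescence: this pins the regime the delimitation model assumes, making
  recovery tests interpretable. `separation = 0` collapses to one
  panmictic coalescent (the null regime).
* `simulate_characters()` — each character is either a deterministic
  function of the species label (perfect association) or iid uniform
  noise; the mix probability is the `association` parameter.
* `simulate_alignment()` — Jukes-Cantor evolution (Poisson substitution
  events per site and branch). JC is intentionally minimal: its only job
  here is to exercise haplotype collapsing (zero-length cherries yield
  identical sequences; rate 0 yields one haplotype).

What the simulators do **not** emulate: among-site rate heterogeneity and
model complexity of real loci (GTR+I+G-style), locus-specific $\theta$ or
rates, gene flow, sequencing error, and the patchy missing-data structure
of real herbarium sampling. Passing the simulation-based checks therefore
demonstrates internal correctness and statistical calibration under the
model's own assumptions, not robustness to violations of them.

# Numerical choices and degenerate inputs

* Ultrametricity: relative tolerance $10^{-6}$ on root-to-tip spread;
  failing trees are rejected, never rescaled (chronogram estimation is out
  of scope).
* Branching ages equal within a $10^{-10}$ relative tolerance are merged
  (zero-length spans from polytomy resolution).
* Haplotype identity under missing data: two sequences are identical iff
  they agree at every mutually unambiguous column (`?`, `N`, `-` wildcard);
  grouping is greedy in input order. Strict equality would never collapse
  herbarium sequences with missing loci; this rule is a declared decision.
* Polytomy resolution: left-to-right caterpillar ordered by each child
  clade's smallest tip label (seed-shuffled on request), inserted branches
  exactly zero, pairwise distances preserved exactly.
* Fewer than 3 distinct branching ages, fewer than 4 tips, single-row or
  single-column contingency tables, and species pairs never co-sampled in
  any locus are errors with dedicated condition classes.

The package's own checks run at these problem sizes: 50 recovery
replicates at 120 tips, 200 null-calibration replicates at 60 tips, 500
contingency replicates, 200 exhaustive Fitch comparisons on trees of up to
8 tips, and 100 loci for $\theta$ recovery.

# Known limitations

* The GMYC LRT is anticonservative (see above); confidence-set reporting is
  the more honest uncertainty summary.
* The multiple-threshold search is a greedy local climb: it cannot cross
  likelihood valleys, and with heterogeneous within-species coalescent
  rates (clusters whose depths differ several-fold at equal sample sizes)
  the shared $(\lambda_C, p_C)$ model may genuinely prefer reclassifying
  slow clusters' coalescences as diversification over the intuitive
  clustering.
* A single $\theta$ is shared across all populations and scenarios;
  per-branch $\theta$ estimation and Bayesian species-tree sampling are out
  of scope.
* Bootstrap supports are consumed, never computed: tree inference belongs
  to upstream tools.
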