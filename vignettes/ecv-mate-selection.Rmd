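---
title: "Expected cross value mate selection: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Expected cross value mate selection: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecvmate)
```

This vignette documents the probabilistic model behind `ecvmate`, the
numerical and algorithmic choices the package makes, and the reasoning
behind the simulator defaults. It is written for a reader who wants to know
*why* the package computes what it computes, not just how to call it.

## 1. The inheritance model

Meiosis over `N` ordered loci is modelled by a binary **source chain**
$J = (J_1, \dots, J_N)$, $J_i \in \{0, 1\}$, that records which of the two
parental gametes each locus of the produced gamete is copied from:

* $\Pr(J_1 = 0) = \alpha_0$ (the probability of starting on the first
  parental gamete);
* $\Pr(J_{i+1} \ne J_i) = r_i$, where $r_i \in [0, 0.5]$ is the
  recombination frequency between adjacent loci $i$ and $i+1$, and
  transitions are Markov.

Given a parent's two gametes as columns of $L \in \{0,1\}^{N \times 2}$
(entry 1 = desirable allele), the produced gamete is
$\mathrm{gam}(L, J)_i = L_{i,\,J_i + 1}$.

Define $\varphi_1 = 0$ and
$\varphi_i = r_{i-1} + (1 - 2 r_{i-1})\, \varphi_{i-1}$. Then by induction

$$\Pr(J_i = 0) = \alpha_0 + (1 - 2\alpha_0)\, \varphi_i(r).$$

Two facts make this chain analytically pleasant:

1. $\varphi_i \in [0, 0.5]$ always, because the map
   $x \mapsto r + (1-2r)x$ sends $[0, 0.5]$ into itself for
   $r \in [0, 0.5]$.
2. At $\alpha_0 = 0.5$ (Mendel's second law: either starting gamete is
   equally likely) the marginal is exactly $0.5$ at *every* locus, for
   *any* recombination map.

`inheritance_params()`, `phi()`, `marginal_prob_zero()`,
`sample_inheritance()` and `gam()` implement this directly. An exhaustive
enumerator `enumerate_inheritance()` (all $2^N$ source vectors with their
exact probabilities, $N \le 20$) is exported and used throughout the test
suite as the ground-truth oracle.

## 2. Expected cross value

The quantity being optimized is two meioses deep. For a candidate pair with
genotype matrices $L^1, L^2$, draw independent source chains
$J^1, J^2, J^3$ and form

$$g^1 = \mathrm{gam}(L^1, J^1),\quad g^2 = \mathrm{gam}(L^2, J^2),\quad
g^3 = \mathrm{gam}([\,g^1\ g^2\,], J^3).$$

$g^1, g^2$ are the gametes a child of the pair receives; $g^3$ is the
gamete that child passes on. The **expected cross value** is
$\mathrm{ECV} = \mathbb{E}\big[\sum_i g^3_i\big]$, the expected count of
desirable alleles a grandchild inherits from this cross.

By linearity, only the per-locus marginals matter:

$$\Pr(g^3_i = 1) = \beta_i\big[\beta_i L^1_{i1} + (1-\beta_i) L^1_{i2}\big]
 + (1-\beta_i)\big[\beta_i L^2_{i1} + (1-\beta_i) L^2_{i2}\big],$$

with $\beta_i = \Pr(J_i = 0) = 1 - \alpha_0 + (2\alpha_0 - 1)\varphi_i$
(note $J^3_i = 0$ selects $g^1$, which came from parent 1). At
$\alpha_0 = 0.5$ every $\beta_i = 0.5$ and the expression collapses to

$$\mathrm{ECV} = \tfrac14 \sum_i
  \big(L^1_{i1} + L^1_{i2} + L^2_{i1} + L^2_{i2}\big).$$

Consequences the package leans on:

* **Exactness.** The Mendelian ECV is a quarter-integer; `ecv_mendel()`
  computes it by integer summation, so there is no floating-point error to
  budget for, and tests can assert exact equality.
* **Map independence.** Recombination frequencies cancel, so the genetic
  map is not needed to *score* pairs under $\alpha_0 = 0.5$ — only to
  simulate meiosis. `ecv_general()` keeps the full $\beta_i$ form for
  non-Mendelian $\alpha_0$.
* **Parent separability.** ECV is a sum of per-parent dosages, which makes
  the pair-selection integer program's objective linear in indicator
  variables and makes the exhaustive backend a vectorized outer sum.

Both closed forms are validated against `cross_moments_bruteforce()`, which
enumerates all $2^{3(N-1)} \cdot 8$ joint source configurations — an oracle
that is slow but independent of every simplification above.

## 3. Predicted cross value

The older criterion $\mathrm{PCV} = \Pr(g^3_i = 1 \text{ for all } i)$ is
*not* linear, so marginals do not suffice: `pcv()` runs an exact forward
dynamic program over the 8-state joint chain $(J^1_i, J^2_i, J^3_i)$,
accumulating only the states whose emitted allele is desirable. This is
$O(64N)$ and exact. Two structural properties are covered by tests:

* **Zero rule:** one locus with no desirable copy in either parent forces
  PCV $= 0$ — the reason PCV degenerates on polygenic targets and the
  motivation for preferring ECV.
* **Fréchet-style bound:** PCV never exceeds the smallest per-locus
  marginal $\Pr(g^3_i = 1)$.

## 4. Pair selection as an integer program

Selection of one cross maximizes ECV over unordered pairs $(k, k')$,
$k < k'$, subject to the **genomic-relationship cap**
$G_{kk'} \le \varepsilon$. The package solves this two ways:

* `backend = "exhaustive"` scans the admissible pairs in vectorized form;
* `backend = "bnb"` runs a depth-first branch-and-bound in C++
  (`src/bnb.cpp`) on the 0/1 formulation, with an additive upper bound from
  the two best per-parent dosages.

Both backends implement the same deterministic **tie rule**: among optimal
pairs, the lexicographically smallest $(k, k')$ wins. That makes results
reproducible and lets the test suite require bit-identical plans across
backends. Crossing blocks of `n_pairs` crosses are built by re-solving with
**conflict constraints** that exclude exactly the already-selected pairs
(`select_pairs_iterative()`); an optional `allow_repeated_parent = FALSE`
adds parent-disjointness. Infeasibility raises classed conditions
(`ecvmate_infeasible`, `ecvmate_partial_plan` with the partial plan
attached) rather than returning silently truncated output.

### Multiple traits: lexicographic stages with tolerance floors

With ordered priorities $t_{(1)} \succ t_{(2)} \succ \dots$ and tolerances
$\tau_j$, each slot of the plan is filled by solving a sequence of
problems: stage $j$ maximizes $\mathrm{ECV}_{t_{(j)}}$ subject to
$\mathrm{ECV}_{t_{(m)}} \ge (1 - \tau_m)\cdot \mathrm{opt}_m$ for all
$m < j$, where $\mathrm{opt}_m$ is the stage-$m$ optimum for this slot. The
last stage is always optimized outright ($\tau$ of the final stage must be
0). `select_pairs_lexicographic()` returns the per-slot stage optima as an
attribute so the contract can be audited.

## 5. Genomic relationship and the GEBV baseline

`vanraden_G()` implements VanRaden method 1 from **neutral markers only**
(QTL are excluded so the constraint does not see the selection targets):
$G = Z Z^\top / \big(2 \sum_j p_j (1 - p_j)\big)$ with
$Z_{kj} = x_{kj} - 2 p_j$. Frequencies default to the observed frequencies
of the supplied population, clipped to $[0.01, 0.99]$; monomorphic markers
are dropped. An `allele_freqs` argument allows centering at any reference
(see §7).

`fit_rrblup()` is a self-contained ridge-regression BLUP: the shrinkage
parameter is chosen by maximizing the REML log-likelihood on a
log-spaced grid refined by `optimize()`, and marker effects follow from the
usual mixed-model equations. It exists to give the simulator a standard
GEBV baseline without external dependencies.

## 6. The simulator

`run_scenario(method, config, seed)` runs a founder population through
repeated rounds of (phenotyping →) selection → crossing → meiosis, for
`method` in `"ecv"` (lexicographic ECV under the $G$ cap),
`"phenotypic"` (rank by summed trait phenotypes) and `"gebv"` (rank by
summed GEBVs). Defaults (`sim_config()`):

* **Genome:** 10 chromosomes, 300 loci — 200 QTL and 100 neutral markers
  interleaved in a fixed `qtl, qtl, marker` pattern so markers tag QTL
  regions; $r = 0.1$ between adjacent loci within a chromosome, $r = 0.5$
  across chromosome boundaries (independent assortment).
* **Founders:** $K_0 = 10{,}000$ individuals, every allele i.i.d.
  Bernoulli(0.5), so founder desirable-allele frequencies start at 0.5 and
  all progress is attributable to selection.
* **Traits:** three traits of 40 / 10 / 70 QTL. Twenty loci are shared
  between Trait 1 and Trait 3 with *opposite* desirable orientation —
  built-in antagonistic pleiotropy, so no strategy can fix both traits.
  Effects are unit-magnitude with the desirable orientation randomized per
  locus. Phenotypes add Gaussian noise calibrated to heritability 0.5
  against the founder genetic variance.
* **Program shape:** 4 rounds; crossing intensities per round are
  scenario-dependent (`scenario_pairs()`): A = (50, 10, 3, 3),
  B = (50, 10, 5, 5), C = (50, 25, 5, 5) pairs, 100 progeny per cross, so
  population sizes run 10,000 → 5,000 → 1,000/2,500 → 300/500 → 300/500.
* **Priorities and tolerances:** multi-trait mode optimizes in the order
  Trait 3 ≻ Trait 1 ≻ Trait 2 (largest and antagonistically-burdened trait
  first), with per-round tolerance rows
  $(0.17, 0.05, 0.05, 0.05)$ for stage 1 and $(0, 0, 0, 0.05)$ for stage 2
  — loose early (explore while populations are large), tight late. The cap
  is $\varepsilon = 0.20$.
* **Prescreen:** with $K_0 = 10{,}000$ there are $\sim 5 \times 10^7$
  candidate pairs, so each round restricts the ILP to the union of the top
  250 individuals per trait by desirable-allele dosage. Because ECV is a
  monotone function of per-parent dosage, the unconstrained optimum is
  always inside this set; only the $G$-cap interaction is approximated, and
  the prescreen is exact whenever the dosage-optimal pairs are admissible.
  Setting `prescreen_per_trait = Inf` disables it.
* **Reproducibility:** replication $j$ of a run with seed $s$ uses seed
  $s + 100{,}000\,j$, so replications are independent but the whole study
  is a pure function of `(method, config, seed)`.

The phenotypic baseline ranks individuals by the sum of their trait
phenotypes and pairs down the ranking, allowing a top individual to appear
in several crosses (reuse-allowed ranking of all unordered pairs). A
parent-disjoint variant is available via
`select_pairs_by_score(..., distinct_parents = TRUE)`; it was not made the
default because it changes the baseline's character (strictly weaker use of
the best individuals) without a compensating benefit in our experiments.

## 7. Centering of $G$: a consequential choice

The one modelling choice with a visible effect on reported relatedness is
the **reference allele frequency** used to center $G$ during the
simulation. `sim_config(g_reference = ...)` offers:

* `"current"` (default): $G$ among the selection candidates is centered at
  the candidates' own observed marker frequencies. This is the standard
  operational choice — each round's constraint is self-contained — and it
  is what the selection constraint actually enforces. Its side effect: as
  the population differentiates, within-generation $G$ values stay near
  zero by construction, so the reported mean relatedness of selected pairs
  in late generations is small (≈ −0.04 in the high-intensity scenario)
  even though the population is far more related to the founders than it
  was.
* `"base"`: $G$ is centered at founder marker frequencies throughout. This
  measures drift/co-ancestry relative to the base population, and the same
  scenario reports ≈ 0.14 for ECV-selected pairs — but it also inflates the
  GEBV baseline's relatedness (≈ 1.05) because that baseline ignores $G$
  entirely.

Both centerings preserve the qualitative ordering the package is designed
to demonstrate (ECV-selected pairs are far less related than GEBV-selected
pairs, with phenotypic selection in between). The default is `"current"`;
`"base"` is one argument away, and `vanraden_G(allele_freqs = ...)` exposes
the same control for direct use.

## 8. What the tests guarantee

The suite is oracle-driven rather than snapshot-driven:

* closed-form ECV vs. full $2^{3N}$ brute force; marginals vs. $2^N$
  enumeration; PCV DP vs. direct summation over enumerated triples;
* both ILP backends vs. an independent rank-all-pairs reference, across
  randomized instances, including conflict constraints, tie cases, and
  the lexicographic tolerance contract;
* simulator mechanics: meiotic validity (every transmitted allele exists in
  the parent), intact haplotype blocks at $r = 0$, exact genome/trait
  layout, phenotype variance calibration, seed reproducibility;
* file formats round-trip bit-exactly, and readers report the offending
  line number on malformed input.

Everything runs CPU-only, offline, in a few minutes.
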