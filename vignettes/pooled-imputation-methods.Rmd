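---
title: "Parent-progeny imputation from pooled samples: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parent-progeny imputation from pooled samples: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolimpute)
```

## The problem

Doubled-haploid (DH) lines from biparental crosses are the workhorse of
many plant breeding programs. Because one meiosis separates a DH from two
fully homozygous, fully genotyped parents, its genome is a mosaic of the
two parental haplotypes, and genotyping it amounts to deciding, at every
locus, *which parent it inherited from*. Genotyping-by-sequencing (GBS) at
low coverage is the cheap way to collect that evidence, but its cost per
individual is dominated by per-sample library construction. Pooling the
DNA of two or more DH into one non-barcoded sample removes that cost —
and with it the information linking each read to an individual.

`poolimpute` recovers the individual genotypes from such pools. The hidden
state of its model is the **inheritance pattern** at a locus: the
combination of parents-of-origin, one per pooled individual. A pool of P
members has $2^P$ patterns (4/8/16 for two-/three-/four-way pools). The
sequence of patterns along a chromosome is a Markov chain whose transition
probabilities come from the genetic map and the pedigree, and the pooled
read counts at each locus are emissions whose probabilities come from the
parental genotypes and the DNA fractions of the members. A
forward-backward pass then yields, per locus, a posterior distribution
over patterns, which converts directly into fractional allele dosages per
individual.

## The model

**States and prior.** Patterns are ordered lexicographically over members
with each member's first-listed parent first. The prior $f_0$ is the
product of expected parental genome contributions: $1/2$ each for
F$_1$-derived DH; $3/4$ (recurrent) and $1/4$ (donor) for BC$_1$-derived
DH. $f_0$ is stationary under every transition matrix the model builds,
which is why chromosomes can be treated as independent chains restarted at
$f_0$ and why the first locus needs no transition step.

**Transitions.** Members recombine independently, so the pattern-level
transition matrix between adjacent loci is the Kronecker product of
per-member $2 \times 2$ matrices in member order. For an F$_1$-derived DH
the member matrix is $[[1-r, r], [r, 1-r]]$ with $r$ the recombination
fraction. For a BC$_1$-derived DH the donor allele survives only if both
the backcross meiosis and the DH-inducing meiosis transmit it, giving
$P(D \to D) = (1-r)^2$; the recurrent-to-donor rate $r(2-r)/3$ then
follows from stationarity of the $(3/4, 1/4)$ genome composition. (The
two-meiosis indicator process is not exactly Markov; the chain used here
matches its one-step transition rates and stationary law, which is the
standard order of approximation for pedigree HMMs.) Distances come from
the genetic map through the inverse Haldane function
$r = (1 - e^{-2d/100})/2$ — the same no-interference model the meiosis
simulator uses, so map and simulator are mutually consistent. $r$ is
computed between *retained* map-adjacent loci after monomorphic-locus
removal.

**Emissions.** Under a pattern, the expected reference-allele frequency in
the pool is $\pi = \sum_d f_d \, [\text{parent}_d \text{ carries ref}]$,
with $f_d$ the DNA fractions. Observing $m$ reference reads out of $n$ is
modelled Beta-Binomially,
$P(m \mid n, \alpha, \beta) = \binom{n}{m} B(m+\alpha, n-m+\beta) / B(\alpha, \beta)$,
with $(\alpha, \beta)$ chosen so the mean is $\pi$ and the smaller shape
equals the dispersion $\nu$ (default 2, allowing moderate deviation of the
realised pool frequency from $\pi$; raise it when DNA quantities are well
controlled, lower it for noisier assays, per-locus overrides are
supported). Patterns with $\pi \in \{0, 1\}$ are point masses; an optional
`error_floor` $e$ softens them to $1-e$ / $e$ to admit a genotyping-error
rate — the default is 0 because the bundled simulator generates error-free
reads. Categorical platform calls become 0/1 indicator rows (a pattern can
emit "heterogeneous" iff $0 < \pi < 1$), and a missing locus is a row of
ones. All Beta-Binomial terms are evaluated in log space; forward and
backward vectors are renormalised at every locus, so no underflow scaling
is needed beyond the model's own normalisation constants.

**Posterior and dosages.** The implementation follows the index
convention in which the backward vector $b_{k+1}$ carries the evidence of
loci $k{+}1..M$ given the state at locus $k$, so the posterior is
$p_k \propto f_k \circ b_{k+1}$. In the backward recursion the transition
matrix is applied *untransposed* ($b_k = a_k^{-1} T_k (b_{k+1} \circ
E_k)$): for the symmetric F$_1$ matrices the transpose makes no
difference, but for the asymmetric BC$_1$ chain only this form agrees with
exhaustive enumeration over pattern sequences, which the test suite
enforces to $10^{-10}$. Dosages are $g_{dk} = 2 (p_k \cdot i_{dk})$ with
$i_{dk}$ indicating the patterns whose parent for member $d$ carries the
reference allele; the hard call is the maximum-posterior genotype, an
exact $0.5$ tie is called reference and is flagged by its call probability
of $0.5$. Downstream analyses should prefer the fractional dosages, which
weight each call by its certainty.

**Shortcuts.** Loci monomorphic for every member carry no linkage
information and impute with certainty; they are removed from the HMM and
filled from the parents directly. A locus monomorphic for only some
members stays in the chain (those members' dosages come out certain
anyway, and the locus still informs the other members).

**DNA fractions.** When not supplied, member DNA fractions are estimated
from loci that are fixed within every member's population but for
alternate alleles between populations: at such a locus, the share of reads
carrying a population's private allele estimates its DNA fraction
directly. The estimator is the read-weighted mean share over a
population's informative loci with add-one smoothing (so a population
whose few informative loci caught no reads cannot receive a hard zero),
normalised across populations; members from the same population split its
share equally. With no informative loci at all the members are assumed
equal, with a warning — the right default for pools built without prior
quantification.

## The simulator

The `simulate` functions reproduce a realistic study design end to end.

* **Founder panel** — `generate_founders()` draws homozygous inbred lines
  in germplasm groups: a panel-level allele frequency per locus from a
  symmetric Beta(2, 2), group frequencies around it from a
  Balding–Nichols-style divergence model (default divergence 0.48), and
  the reference allele set to the panel-wide major allele. The defaults
  were tuned once so two-way pools show a multi-polymorphism rate near
  37% within a group and 22% across groups, the regime reported for
  applied dent/flint maize panels; the within-group rate saturates near
  37% under this two-parameter family, so the pair (37, 22) was preferred
  over hitting 39 within at the cost of the across-group value. The
  default genome is maize-like: 10 chromosomes of 160 cM, 3,000 markers
  placed uniformly.
* **Meiosis** — `simulate_dh()` draws crossover counts Poisson with mean
  the chromosome length in Morgans (no interference — exactly the Haldane
  assumption the map conversion uses), positions uniform, starting
  haplotype a fair coin; a DH is one gamete doubled, and BC$_1$-derived
  DH prepend the backcross meiosis.
* **Traits** — `assign_trait()` samples causal loci (default 200, removed
  from the marker set), standard-Normal substitution effects, and noise
  scaled so the realised heritability equals `h2` (default 0.5) exactly
  in-sample.
* **Pools and reads** — `build_pools()` pairs populations at random under
  the chosen strategy (within-group, or across-group with compositions
  1+1 / 2+1 / 2+2) and members at random within pairings, each individual
  appearing in exactly one pool. `simulate_gbs()` draws per-marker
  sequenceability from Gamma(4, 4) (shared across pools by default,
  mirroring a shared library/flow-cell effect; redrawable per pool), DNA
  contributions from a Dirichlet with concentration 50/29/18 for pool
  sizes 2/3/4 (contribution standard deviation about 0.05), total reads
  Poisson with mean $x \cdot seq_k$ at target coverage $x$, and reference
  reads Binomial with success probability the summed contributions of
  reference carriers.

What the simulator deliberately leaves out: sequencing error and DNA
contamination (reads are error-free draws from the true pool frequency),
differential allele amplification, linkage disequilibrium and pedigree
structure among founders beyond group-level frequency divergence, and
physical-to-genetic map distortion (marker spacing is uniform). Passing
tests therefore demonstrate the method's behaviour under clean GBS
sampling noise, unequal DNA contributions and missing data — not
robustness to assay artefacts, which in practice is handled by the
`error_floor` and by raising or lowering `nu`.

## Numerical and design choices

* Recombination fractions of exactly 0 (co-located markers) are allowed;
  the chain simply cannot switch between them.
* An observation impossible under *every* pattern (e.g. mixed reads where
  all patterns are homogeneous and the floor is 0) stops the run with an
  error naming the locus, rather than silently renormalising.
* `ridge_effects()` is a deliberate closed-form stand-in for the heavier
  Bayesian whole-genome regressions used in selection practice. The
  GEBV-concordance experiments it serves are *comparative* — the same
  estimator is applied to true and to imputed dosages — so the estimator
  choice cancels to first order. Absolute prediction accuracies from it
  should not be quoted.
* Per-individual genotype concordance is computed over the individual's
  own polymorphic loci only; monomorphic loci impute with certainty and
  would inflate the rate. The matching baseline (impute one parental
  genotype everywhere) sits at 50% in expectation in biparental
  populations.
* Selection economics use the printed per-sample GBS cost constants
  ($5.04–$6.20 for 3,000 loci at 0.125x–4x; $8.00 for individual
  high-quality genotyping) divided by pool size; they are configuration
  constants, not re-derived.

## Problem sizes used in the checks

The bundled test suite exercises the pipeline at 1,000 markers with 24–48
populations of 25 DH (300–600 two-way pools), where all qualitative
results — concordance ordering by pool size, monotonicity in coverage,
calibration of the posterior probabilities within 3 percentage points,
negative correlation between multi-polymorphism rate and concordance —
are stable. The acceptance script runs the full 3,000-marker, 600-
individual two-way design at 1x coverage, where mean genotype concordance
exceeds 95% with estimated (not true) DNA fractions, and the 200-
population baseline check. Exhaustive-enumeration cross-checks of the
forward-backward pass cover pools up to three members and eight loci.

## Known limitations

* Parents must be fully homozygous and completely genotyped; heterozygous
  founders, multi-allelic markers and external genotype likelihoods are
  out of scope.
* Cross types beyond F$_1$- and BC$_1$-derived DH (F$_2$-derived DH,
  recombinant inbred lines) are not modelled; more advanced crosses
  weaken marker linkage and would need denser maps.
* The BC$_1$ member chain is the two-meiosis approximation described
  above.
* Imputation quality degrades where the map has large gaps, and the
  posterior reverts to the prior on chromosomes with no observed reads.
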