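---
title: "Models and methods in scphylo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in scphylo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scphylo)
```

## The problem

Single-cell DNA sequencing recovers the somatic mutations that accumulate
as cells divide, and because somatic evolution is clonal (mitotic, without
recombination) the history of a cell sample is a tree. Reconstructing that
tree from single-nucleotide variant (SNV) genotypes is hampered by the two
characteristic artifacts of whole-genome amplification: allelic dropout
(ADO), where one allele of a diploid genotype fails to amplify and a
heterozygote is read as a homozygote, and amplification/sequencing error,
where an allele is read as a different nucleotide. scphylo implements
maximum-likelihood phylogenetic inference for diploid SNV genotypes with an
explicit observation model for both artifacts, plus the simulation and
evaluation machinery needed to validate it.

## The genotype substitution model

The evolutionary state is the phased diploid genotype. With four
nucleotides there are 16 phased genotypes (maternal|paternal), ordered
`A|A, A|C, ..., T|T`. The continuous-time Markov model (GT16) is
time-reversible: the instantaneous rate from genotype $X$ to $Y$ is

$$q_{XY} = r_{ab}\,\pi_Y$$

when $X$ and $Y$ differ at exactly one allele (the changing allele going
$a \to b$), and $0$ when both alleles differ — only one allele can change
in an infinitesimal interval. The allele-level exchangeabilities are the
six nucleotide pair rates $\alpha = r_{AC}$, $\beta = r_{AG}$,
$\gamma = r_{AT}$, $\kappa = r_{CG}$, $\lambda = r_{CT}$, with
$\mu = r_{GT} \equiv 1$ as the reference, and the rate of an allele change
does not depend on the homologous allele. $\pi$ is the stationary genotype
frequency vector (16 values). The matrix is scaled so the expected
substitution rate at stationarity is 1; branch lengths are therefore in
expected mutations per SNV site. The scaling constant is exposed in the
`rate_matrix` object.

Unphased data are handled without changing the model: an observed unphased
heterozygote simply assigns equal tip likelihood to both phasings. A
10-state unphased variant (GT10) is also provided; to stay reversible it
assumes homozygote-to-heterozygote and heterozygote-to-homozygote changes
share one exchangeability (ignoring the factor-two asymmetry between those
directions), using the same single-allele-change rule
$q_{XY} = r_{ab}\pi_Y$ over the ten states. The full exchangeability
layout of the 10-state reduction is a package choice: the six nucleotide
exchangeabilities are shared by all single-allele moves, which is the
simplest completion consistent with reversibility.

Transition probabilities $P(t) = e^{Qt}$ are computed from the
eigendecomposition of the symmetrized matrix
$D^{1/2} Q D^{-1/2}$ ($D = \mathrm{diag}(\pi)$), which is numerically
stable for reversible models; when any frequency falls below $10^{-10}$,
or for the simulator's non-reversible DNA matrix, a dense Padé matrix
exponential is used instead. Frequencies are floored at $10^{-6}$ during
optimization.

## The single-cell error model

Two free parameters describe the observation process: the ADO rate
$\delta$ and the amplification/sequencing error rate $\varepsilon$. At
most one amplification error per genotype is modeled (the two-error
probability $\varepsilon^2$ is negligible at realistic rates), ADO always
drops exactly one allele (a double dropout would produce missing data,
not a genotype), and ADO and an error may co-occur. For a true homozygote
$a|a$:

* correct call: $1 - \varepsilon + \tfrac12\delta\varepsilon$
* heterozygote containing $a$ (six phased states): $(1-\delta)\varepsilon/6$ each
* another homozygote $b|b$: $\delta\varepsilon/6$ each

and for a true heterozygote $a|b$:

* correct (same-phase) call: $(1-\delta)(1-\varepsilon)$
* matching homozygotes $a|a$, $b|b$: $\delta/2 + \varepsilon/6 - \delta\varepsilon/3$ each
* third-allele homozygotes: $\delta\varepsilon/6$ each
* single-error heterozygotes $a|c$, $c|b$: $(1-\delta)\varepsilon/6$ each

All other observations have probability zero; in particular dropout/error
never swaps the maternal/paternal phase, so observing $b|a$ from true
$a|b$ is impossible (unphased observations sum over both phasings, so this
convention is invisible on real unphased data). These entries are
completed over all allele relabelings by symmetry, and the package checks
$\sum_Y P(Y\mid X) = 1$ for every row at kernel construction.

Tip likelihood vectors are initialized from this kernel
(`error model active`), as plain indicators (error model off), from
unphased genotype log10-likelihoods ($L(a|b) = L(b|a) = 10^{G(a/b)}$), or
from Phred-scaled PL triplets ($10^{-PL/10}$ on the REF/ALT genotypes,
zero elsewhere). Missing data gives a vector of ones. GL/PL-derived
vectors are rescaled so their maximum is 1 — relative likelihoods are all
the pruning algorithm needs, and the rescaling guards against underflow.
A printed PL layout ambiguity (the hom-ALT branch condition) is resolved
as $a = ALT \wedge b = ALT$.

## Phylogenetic likelihood

The tree is unrooted and binary, with the likelihood computed by
Felsenstein pruning from a virtual root placed on an arbitrary branch —
the result is placement-invariant under reversibility, which the test
suite verifies rather than assumes. Sites are independent; identical site
patterns are collapsed with multiplicity weights. Conditional likelihood
vectors are rescaled per node and site, with log scaling factors
accumulated, so likelihoods of thousands of cells never underflow. The
hot inner pass is implemented in C++ (RcppArmadillo) with an R reference
implementation retained for non-reversible models; the two paths agree to
floating-point accuracy and are cross-checked in the tests. No
ascertainment-bias correction for SNV-only matrices is applied — the
likelihood is exactly the one described above.

## Optimization and tree search

Within one run the package alternates:

1. **Branch lengths** — per-edge Brent optimization (log scale, bounds
   $10^{-9}$ to $100$) against directed conditional-likelihood messages
   frozen at the start of each sweep; a sweep is reverted if the exact
   log-likelihood decreased, so the reported score is monotone. Brent was
   chosen over Newton–Raphson as the package's single, derivative-free
   1-D optimizer; with message caching an edge evaluation is one 16×16
   matrix product, so the extra iterations are immaterial.
2. **Substitution parameters** — L-BFGS-B over log-exchangeabilities and
   softmax-transformed frequencies (frequencies only in the first outer
   iteration and the final polish; they move little afterwards).
3. **Error rates** — cyclic Brent over $\delta$ then $\varepsilon$,
   rebuilding every tip vector at each candidate rate. This matches the
   conditional (fixed-tree) optimization used during search. Because
   $\varepsilon$ and the pendant branch lengths are weakly confounded on
   nearly error-free data, a profile-likelihood mode
   (`profile_error = TRUE`, branch lengths re-optimized inside each
   evaluation) is available and used by the ancestral-reconstruction
   workflow; the default search keeps the faster conditional scheme.
4. **SPR topology moves** — candidate prune/regraft moves within a radius
   (default schedule 5 then 10 edges) are scored lazily against cached
   messages, with the pruned subtree's vector exact and the remaining-tree
   vector rebuilt incrementally along the walk; promising candidates are
   re-evaluated exactly and accepted only if the true log-likelihood
   improves. Rounds repeat until no move helps.

The outer loop stops when a full iteration gains less than
`loglik_epsilon` (default 0.1 log units), followed by a final polish at
`final_epsilon` (0.001). Starting trees are randomized stepwise-addition
parsimony trees (Fitch over the 10-letter genotype alphabet, via
phangorn) and/or uniform random topologies; the default specification
follows the `pars{N}`/`rand{N}` convention. All randomness flows from a
single seed recorded in run manifests; two runs with the same seed are
identical.

## Branch support and tree comparison

Standard bootstrap support resamples SNV sites with replacement, infers a
tree per replicate and reports the percentage of replicates containing
each internal bipartition exactly. Transfer support (TBE) additionally
credits inexact matches: a branch with lighter side $p$ receives
$1 - d/(p-1)$ per replicate, with $d$ the minimum Hamming distance to any
branch of the replicate tree, so transfer support is never below the
standard value. Accuracy against a reference tree is $1 - \mathrm{nRF}$,
where nRF divides the Robinson–Foulds count by the total number of
internal branches present in the two trees — multifurcating (partially
unresolved) trees reduce the denominator.

## Ancestral reconstruction and mutation mapping

Marginal ancestral reconstruction computes, per node and site, the
posterior over genotypes from upward and downward pruning passes (tips
use the same error-model or GL vectors as the likelihood). The ML
genotype per node is compared across every branch; differing unphased
genotypes predict a mutation on that branch. Posterior ties are broken by
fixed state-order precedence for reproducibility. When the tree is rooted
with a zero-length outgroup branch, mutations on the two root-adjacent
branches are merged onto the ingroup branch.

## The simulator

The generator mirrors the benchmark design of single-cell studies:

* **Genealogy**: coalescent in an exponentially growing population
  (growth rate $10^{-4}$ per generation, present-day size $N = 10{,}000$),
  which yields short internal and long terminal branches — the hard case
  for reconstruction. A stem branch of 0.1 coalescent units is prepended
  above the MRCA (its mutations are shared by every cell), and a healthy
  outgroup cell is attached at the MRCA with branch length zero, so the
  outgroup genotype equals the MRCA genotype. Branch lengths are
  multiplied by Gamma(shape, mean 1) lineage-rate factors; the default
  shape 5 (sd ≈ 0.45) is the package's choice of moderate rate variation,
  and shape `Inf` disables it. Coalescent time converts to expected
  mutations per site via $2N\mu$ with $\mu = 10^{-6}$ per site per
  generation.
* **Mutations**: either the diploid infinite-site model (each SNV mutates
  exactly once, on a branch drawn proportionally to its length, on a
  random haplotype, with uniformly drawn reference and alternative
  bases), or a finite-site non-reversible DNA model whose default rates
  pool COSMIC signature 1 into single-nucleotide rates (G→A dominant),
  with mean-1 Gamma site-rate variation. Finite-site evolution is
  simulated exactly by uniformization (jump chains); at the benchmark
  scale (100 cells, 10,000 sites) it produces on the order of 2,000 true
  SNVs.
* **Observation**: either genotype-level noise — each genotype replaced
  by a draw from the observation kernel at the configured
  $(\delta, \varepsilon)$, which makes simulator and inference share one
  error definition — or read-level simulation: negative-binomial depth
  (dispersion parameter 2 by default; the expectation halves when an
  allele drops), per-read uniform amplification and sequencing errors,
  genotype log10-likelihoods under a symmetric per-read error model
  (total rate capped at 3/4), and ML genotype calls with uniform random
  tie-breaking. The per-read GL emission is deliberately simpler than
  amplification-template models used elsewhere; it is documented as such
  and is consistent between simulation and GL-mode inference.
* **Doublets**: each cell is replaced, with the configured probability,
  by a merge with another random cell — read counts summed in read mode,
  pooled-allele resampling in genotype mode.

Every simulation records its ground truth (tree, genotypes, per-site
mutation branch), and every inference test consumes that truth.

What the simulator does **not** emulate: trinucleotide-context mutational
signatures, copy-number variation, germline polymorphism, mappability or
coverage structure of real genomes, and amplification-template artifacts.
Passing tests therefore demonstrate correctness of the method under its
own generative assumptions and robustness to the modeled noise, not
performance on any particular empirical pipeline.

## Numerical and design notes

* Branch-length bounds $[10^{-9}, 100]$; likelihood-improvement
  thresholds 0.1 (outer loop) and 0.001 (polish) log units.
* Underflow control by per-node, per-site rescaling with accumulated log
  offsets (column sums are used as the scale — any positive per-column
  scalar is valid).
* The error-rate estimate on data *conditioned* to be all-SNV (as
  infinite-site simulations are) carries a small positive bias
  ($\hat\varepsilon$ of a few $10^{-3}$ on error-free input) because the
  infinite-site generator draws alternative alleles uniformly while the
  reversible substitution model weights them by stationary frequency; on
  data generated under the substitution model itself the estimates are
  statistically indistinguishable from zero (likelihood-ratio check) and
  snap to exactly zero when the boundary is the optimum, with a sampling
  variability of a few 10^-3 at a few thousand SNVs. This mismatch is
  inherent to benchmarking a finite-state model on infinite-site data
  and is visible in the tests.
* ADO estimates tend to sit slightly below the simulated rate at
  moderate data sizes (the estimate trades off against pendant branch
  lengths); the error-rate estimate is close to unbiased. Both are well
  within the package's accuracy targets.
* Ties (equal likelihoods, equal parsimony scores, equal posteriors) are
  broken deterministically except where the benchmark design prescribes
  random tie-breaking (ML genotype calls from reads), which uses the run
  seed.

## Problem sizes used in the checks

The automated checks run at desk scale, chosen once: error-rate recovery
uses 20 replicates of 40 cells × 1000 SNVs (the benchmark's smaller
simulation design); the accuracy-vs-noise and genotype-likelihood-vs-
called-genotype comparisons use 20 replicates of 14 cells × 200 SNVs;
search-optimality checks use 5 cells, where the 15 possible topologies
can be enumerated exhaustively; oracle comparisons (exhaustive genotype
summation) use 4 cells × 3 sites. The qualitative conclusions these
checks reproduce — error-rate recovery, monotone accuracy degradation
with noise, the advantage of genotype likelihoods at low depth — are the
ones the method was built to support.

## Limitations

* The model assumes site independence and a shared substitution process
  across sites and lineages (no +G rate heterogeneity during inference).
* Copy-number events, which break diploidy and site independence, are out
  of scope; SNVs in non-diploid regions should be filtered upstream.
* The SPR search is a radius-limited hill climber with lazy scoring; it
  has no simulated-annealing or perturbation phase, so on very flat
  likelihood surfaces (few SNVs, many cells) multiple starting trees are
  advisable (`tree = "pars{5},rand{5}"`).
* Error-rate estimation requires called genotypes; in GL mode the
  uncertainty is already encoded in the input likelihoods and
  $\delta, \varepsilon$ are not identifiable (and not estimated).
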