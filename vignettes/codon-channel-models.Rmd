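---
title: "Markov chain-like models of the codon substitution channel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Markov chain-like models of the codon substitution channel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonchannel)
```

## The model

The transfer of genetic information from DNA to protein is treated here as
a noisy communication channel whose alphabet is the 64 RNA codons. The
channel is applied in *stages*: one stage models one round of
error-introducing processing (storage, replication, transcription,
translation -- or, in the multi-generation reading, one generation). Under
the single-error-per-codon truncation, one stage leaves a codon unchanged
with probability $1-3p$ and turns it into each of its nine single-base
neighbors with probability $p/3$, where $p$ is the per-base error
probability (each of the three positions errs with probability $p$). This
fixes the parameter domain $0 \le p < 1/3$.

Three chain families share this single-stage structure:

* **Classical Markov chain.** Stage probabilities compose:
  $P^{(k)} = P^k$ with $P_{mn} = |a_{mn}|^2$. Standard Markov-chain theory
  applies; the chain is doubly stochastic on the vertex-transitive
  neighbor graph, so its stationary distribution is uniform over the 64
  codons.
* **Amplitude (Markovian-like quantum) chain.** Stage transition
  *amplitudes* compose: $A^{(k)} = A^k$ over the complex amplitudes
  $a_{mn}$ ($a_{mm} = \sqrt{1-3p}$, $a_{mn} = \sqrt{p/3}$ on the nine
  neighbors, real and nonnegative by default). Amplitudes multiply along a
  path and sum over indistinguishable paths, the same composition rule
  that reproduces Malus' law $\cos^2(\phi-\theta)$ for a two-stage
  polarizer-analyzer toy model where the classical composition
  $\cos^2\phi\cos^2\theta + \sin^2\phi\sin^2\theta$ fails. Each composed
  amplitude defines a Kraus operator $E_{mn} = a^{(k)}_{mn}|n\rangle\langle
  m|$ and the stage map is the operator sum
  $\xi(\rho) = \sum_{mn} E_{mn}\,\rho\,E_{mn}^\dagger$.
* **Hybrid chain.** $k_q$ amplitude-composed stages followed by $k_c$
  classical steps of the row-normalized squared-amplitude matrix
  $p_{ij} = |a^{(k_q)}_{ij}|^2 / \sum_n |a^{(k_q)}_{in}|^2$.

At the nucleotide level two textbook references are included: the 4-ary
symmetric channel (uniform substitution $P_s/3$) and the Kimura
two-parameter process, which sends probability $(1-2\gamma/3)P_s$ to one
partner base and $\gamma P_s/3$ to the other two, recovering the symmetric
channel at $\gamma = 1$.

## Capacity

Inputs are amino acids, not codons: the 21 classes of the standard genetic
code (stop included by default; `exclude_stop = TRUE` gives the 20-class
variant). Each class enters as a prior probability and a density matrix
over codon basekets, in one of three preparations -- the uniform synonymous
*mixture*, the equal-amplitude synonymous *superposition* (pure state), or
a single synonymous baseket drawn at random (*random-eigenket*). Capacity
is the maximum of the Holevo quantity
$\chi = S\!\big(\xi(\bar\rho)\big) - \sum_x p_x S\!\big(\xi(\rho_x)\big)$
over the priors with the states held fixed, computed by an
exponentiated-gradient (Blahut--Arimoto type) ascent; for classical chains
this is ordinary Blahut--Arimoto mutual-information maximization with the
classes as inputs (uniform codon usage within a class). Units are
bits/residue for codon-level models (at most $\log_2 21 \approx 4.392$)
and bits/symbol for the 4-state nucleotide models (at most 2); the two are
never mixed.

```{r capacity-example}
classical_codon_capacity(1e-3, stages = 2)$capacity
quantum_codon_capacity(1e-3, stages = 2)$capacity
```

## The normalization question

A structural fact shapes every quantum-vs-classical comparison in this
package, and we state it up front. With the baseket-to-baseket Kraus form
$E_{mn} = a_{mn}|n\rangle\langle m|$ and real nonnegative amplitudes, the
two dominant amplitude paths to any neighbor (err-then-stay and
stay-then-err) always share a phase, so they interfere constructively; so
do the direct self-path and the nine err-then-revert paths, which
compose to self-amplitude exactly 1 after two stages. The composed
operator sum is therefore **not trace preserving**: squared row norms of
$A^k$ grow above 1, by a factor that is uniform across codons because the
neighbor graph (the Hamming graph $H(3,4)$) is vertex-transitive.

Two evaluation conventions are provided:

* `"stochastic"` (default): rows of $A^k$ are renormalized to unit 2-norm
  before the Kraus set is formed. This is the minimal repair that makes
  the map a completely positive trace-preserving channel -- the setting in
  which the HSW capacity formula is actually defined -- and it mirrors the
  per-row normalization the hybrid model itself applies at the
  quantum-to-classical hand-off.
* `"literal"`: the composed operator sum is evaluated exactly as written.
  Because the trace-inflation factor $c(p,k)$ is uniform, this equals the
  stochastic-convention capacity multiplied by $c$; the package computes
  it that way and verifies the uniformity.

The conventions coincide at one stage and diverge for $k \ge 2$, with
consequences worth spelling out honestly:

1. Under the stochastic convention the interference chain is strictly
   *noisier* than the classical chain: constructive interference doubles
   the relative weight of single-neighbor errors. A coherence-preserving
   single-stage operator set (e.g. a mixture of position-wise substitution
   unitaries, or Hamiltonian-derived codon states) could behave
   differently, but no such set is printed in the source model this
   package reconstructs; the baseket Kraus form is what it defines.
2. The output of the baseket operator sum depends only on the diagonal of
   the input state, so the mixture and superposition preparations yield
   identical capacities here, and at a single stage the quantum capacity
   equals the classical one. Claims that distinguish these cases require
   the coherence-preserving reconstruction noted above.
3. Whether and where the quantum and classical capacity curves cross
   depends on the convention. `crossing_threshold()` therefore searches a
   fixed ladder -- stochastic on the default grid, then literal, then
   stochastic on the extended domain up to $p = 0.32$ -- and reports which
   convention produced the crossing. The ladder is part of the method
   definition, not a tuning knob: it is the same for every scenario and
   stage count.

Observed behavior under the default reconstruction, for reference: the
superposition-scenario curves cross only under the literal convention
(near $5\times 10^{-4}$ for two stages); the random-eigenket scenario --
whose single-codon inputs avoid the within-class mixing loss of the
classical comparator and therefore start *above* it -- crosses downward
under the stochastic convention (near $2$--$4\times 10^{-3}$ for two
stages, depending on the draws).

## Ensembles and randomness

The random-eigenket scenario draws one synonymous codon per class,
uniformly, from a seeded stream that leaves the caller's RNG untouched.
Sweeps and crossing searches use the mean capacity over 10 seeded draws by
default (per-draw spread is reported in `capacity_sd`); crossing locations
for this scenario are genuinely draw-dependent -- the capacity-difference
curve is shallow near its zero -- and move by tens of percent between draw
sets. Single-codon classes (Met, Trp) are deterministic.

The superposition scenario accepts an external per-class eigenket table
(CSV, one row per class, 64 complex amplitudes) for users who have
Hamiltonian-derived codon states; the built-in default is the
equal-amplitude synonymous superposition, chosen because it is the unique
phase-free pure state supported on the class.

## Numerical choices

* Blahut--Arimoto and the HSW ascent stop when the upper/lower capacity
  bracket closes below `tol` (default $10^{-9}$ bits, `max_iter` 10000,
  uniform initialization; deterministic). Non-convergence is flagged in
  the result, never silent. Crossing searches tighten `tol` to
  $10^{-11}$--$10^{-12}$ because they compare two capacities whose
  difference can be $10^{-5}$ bits or less.
* Entropies are base 2 throughout; eigenvalues are clipped at $10^{-15}$
  before logs. Density-matrix validation (Hermiticity, unit trace,
  positive semidefiniteness) uses absolute tolerance $10^{-8}$; Kraus
  completeness is enforced at $10^{-8}$ on row norms and holds to
  $10^{-12}$ for freshly built sets.
* Matrix powers use repeated squaring; the channel outputs of the baseket
  operator sum are detected as diagonal and the capacity ascent then runs
  on the exact classical reduction, with the general density-matrix path
  (matrix logarithms via Hermitian eigendecomposition) exercised for
  non-commuting toy ensembles.
* Bisection on the probability axis works in $\log_{10} p$ to relative
  tolerance $10^{-3}$; generation searches use doubling plus integer
  binary search. Degenerate starts (the curves coincide exactly at one
  stage) are skipped by a $10^{-13}$ dead band. When a scanned grid
  contains several sign changes the first bracket is refined and the
  count is reported in the diagnostics.
* The Lindblad discretization uses $E_0 = I + (K - iH)\delta t$,
  $E_k = L_k\sqrt{\delta t}$ with $K = -\tfrac12\sum L_k^\dagger L_k$;
  the square-root scaling is forced by requiring the jump terms to be
  first order in $\delta t$. One superoperator stage then deviates from
  one Euler step of the master equation at $O(\delta t^2)$ -- halving
  $\delta t$ quarters the deviation (asserted within the ratio band
  $[0.2, 0.3]$) -- which is the precise sense in which the master equation
  is the first-order limit of the stage-wise operator-sum chain.
  $\hbar = 1$ throughout.

## Problem sizes used in the shipped studies

The test suite and the reproduction script run entirely on the 64-codon
space: Chapman--Kolmogorov to eight stages, capacity monotonicity on an
8-point grid over $[10^{-6}, 10^{-1}]$, crossing searches on the 40-point
default grid with 10 random-eigenket draws, and generation searches up to
4096 generations. Toy oracles (path enumeration, brute-force operator
sums, two-pure-state capacity) use 2--4-state spaces where exhaustive
computation is exact.

## What the defaults do and do not show

The defaults reproduce the *structure* of the capacity-versus-noise
study: per-residue capacities, class-level inputs, stage and generation
composition, and the reference nucleotide processes. They do not model
real mutational data: error rates are position- and codon-independent,
multi-base errors within a stage are truncated away, codon usage within a
class is uniform, and no selection acts between stages. Passing tests
certify the mathematical properties of the chains (normalization,
interference identities, closed forms, limits), not biological fidelity.

Known limitations worth restating: the hybrid chain with a genuine
quantum part ($k_q \ge 2$) does **not** dominate the equal-length
classical chain under this reconstruction -- it equals it at $k_q = 1$ and
falls below it otherwise, because renormalized interference is pure
noise amplification; and the literal convention, while faithful to the
operator sum as printed, inflates capacity by the trace factor and is
non-monotone in stage count, so it should be read as a diagnostic of the
normalization question rather than as a physical capacity.
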