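---
title: "Automatic generation, contraction and pruning of density-fitting auxiliary basis sets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automatic generation, contraction and pruning of density-fitting auxiliary basis sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(autoabs)
```

## The problem

Density fitting (DF), also called resolution of the identity (RI),
replaces the four-index electron repulsion integrals
$(\mu\nu|\sigma\rho)$ of a quantum-chemical calculation by three- and
two-index Coulomb integrals over an auxiliary basis set (ABS).  The
quality of the approximation is set entirely by how well the ABS spans
the one-center products $\chi_\mu \chi_\nu$ of orbital basis functions.
Hand-optimized auxiliary sets exist only for popular orbital basis
families; for everything else an ABS must be generated from the orbital
basis set (OBS) itself.  `autoabs` does this per element, in three
stages, each with a single accuracy knob:

1. **Generation** (threshold $\tau$): enumerate candidate auxiliary
   radial functions from all one-center products of contracted orbital
   shells and select a spanning subset per angular momentum $L$ by a
   pivoted Cholesky decomposition of the Coulomb-metric Gram matrix
   $(R_I^L|R_J^L)$, stopping when the largest residual diagonal falls
   below $\tau$.  Every rejected candidate is then representable in the
   selected span with residual Coulomb self-overlap at most $\tau$.
2. **Pruning** (increment $l_{inc}$): drop auxiliary shells whose
   angular momentum exceeds
   $l_{keep}^{max} = \max(2\,l_{occ}^{max},\, l_{occ}^{max} +
   l_{OBS}^{max}) + l_{inc}$, where $l_{occ}^{max}$ is the maximum
   angular momentum occupied in the atomic ground state.  The two terms
   keep, respectively, products of occupied orbitals with each other and
   with any orbital-basis function.  A comparator rule
   $l_{OBS}^{max} + l_{inc}$, used by earlier automatic generators, is
   provided for comparison; it ignores the atomic term and therefore
   cuts lower for heavier elements.
3. **Contraction** (threshold $\epsilon$): form the importance matrix
   $W = J^T J$ of orthogonalized three-index integrals
   $J = I\,V^{-1/2}$ over all one-center orbital products, diagonalize
   its per-$l$ radial subblock $L$, keep eigenvectors with
   $\lambda_i \ge \epsilon$, and back-transform with $C = V^{-1/2}U$.
   Because $\|J - J U U^T\|_F^2 = \sum_{dropped}\lambda_i$ exactly, the
   dropped eigenvalues bound the loss in the three-index integrals.

Pruning is applied before contraction; the two operations commute
because contraction acts within one angular momentum at a time (the
suite verifies this on toy systems).

## The angular structure of W

On a single center, $W$ is block diagonal in the angular momentum and
projection $(l, m)$ of the auxiliary functions, and the blocks are
identical across $m$: summing products over all orientations averages
out every direction.  The implementation therefore computes only the
radial $m = 0$ subblock per $l$, with each ordered pair of contracted
orbital functions entering through its angular pair weight
$\sum_{m_1 m_2} G(l_1 m_1, l_2 m_2; l\,0)^2$ (a sum of squared real
Gaunt coefficients).  `build_importance_full()` builds the explicit
all-$m$ matrix with individual Gaunt factors; the test suite checks that
its off-block elements are numerically zero (below $10^{-8}$ of the
largest diagonal) and that it reproduces the radial fast path.

The sum over orbital products runs over *ordered* pairs, the literal
reading of the defining sum; unordered pairs would halve off-diagonal
weights, rescale eigenvalues by up to a factor two, and thereby shift
the effective $\epsilon$.

## Integral engine

All integrals are one-center Coulomb-metric overlaps at multipole order
$L$, with the $4\pi/(2L+1)$ multipole prefactor included, so Gram
matrices are true Coulomb overlaps of $f(r)\,Y_{LM}$ densities.  The
production path is adaptive outer quadrature with the inner cumulative
integrals in closed form (log-scaled incomplete gamma functions), the
radial axis panelled at every Gaussian length scale $1/\sqrt{\alpha}$.
This path never assumes the radial functions are Gaussian-term sums
beyond their evaluation, which keeps the engine open to Slater-type or
numerical radial functions later.  For pure-power Gaussian terms
$c\,r^p e^{-\alpha r^2}$ with $p - L$ even and non-negative — the case
arising from products of spherical Gaussian shells — a fully analytic
closed form (`radial_coulomb_analytic()`, a terminating hypergeometric
sum) serves as the independent oracle; the suite requires agreement to
$10^{-10}$ relative over randomized exponents, powers and $L \le 8$.
Because the two routes agree to that level, the heavier tests and large
Gram constructions may use the analytic route; one pipeline test runs
both end to end and checks identical compositions and matching
coefficients.

Real-spherical-harmonic Gaunt coefficients are evaluated by exact
quadrature: the azimuthal trig-product integral on a uniform grid
(trapezoid is exact for trigonometric polynomials below the node count)
and Gauss–Legendre in $\cos\theta$ complete for the polynomial degree
of the associated-Legendre product.  The independent check is the
$3j$-symbol sum rule for the pair weights.

## Candidate representation

Candidates are represented by primitive exponent sums: the product of
primitives with exponents $\alpha_i$, $\alpha_j$ contributes
$r^L e^{-(\alpha_i+\alpha_j) r^2}$ at every parity-allowed $L$.  This
emits valid primitive GTO shells directly.  The exact products of
contracted shells (which carry $r^{l_1+l_2}$ prefactors and contraction
cross-terms) remain available via
`enumerate_candidates(representation = "product")` for metric studies,
but cannot be emitted as standard primitive shells.  Exponents are
deduplicated per $L$ within a relative tolerance of $10^{-6}$ before
Gram construction; contributing shell-pair weights accumulate.

## Prescreening

The candidate pool may be prescreened by a pivoted Cholesky of the
(angularly weighted) product Gram before the per-$L$ selection.  The
angular pair weights enter as pivot *priorities* — the pivot chosen at
each step maximizes weight times residual diagonal — while the stopping
test uses the unweighted residual diagonal.  This choice keeps the
$\tau$ fidelity guarantee in the plain Coulomb metric, so prescreened
and unprescreened pipelines span the same candidate pool to $\tau$
(mutual projection residuals stay below $2\tau$; asserted on toy sets).
A stopping rule on the weighted diagonal would only bound the weighted
residual and could lose up to the inverse of the smallest weight.
Prescreening reduces the *primitive* count; the suite and the published
analysis agree that the *contracted* composition is unchanged with or
without it.

## Parameters

| parameter | meaning | default | notes |
|---|---|---|---|
| $\tau$ | Cholesky selection threshold (Coulomb-metric residual) | $10^{-7}$ | also the prescreening threshold; no separate value is published |
| $\epsilon$ | absolute eigenvalue cutoff of the importance block | $10^{-5}$ | absolute, as defined; not relative to $\lambda_{max}$ |
| $l_{inc}$ | pruning increment | 1 | 0 is usable for routine work |
| lindep | relative eigenvalue cutoff of $V^{-1/2}$ | $10^{-7}$ | matches the linear-dependence threshold used in the reference calculations |
| dedup | relative exponent merge tolerance per $L$ | $10^{-6}$ | applied before Gram construction |

The preset names bundle the two accuracy knobs:
`small` $(\epsilon, l_{inc}) = (10^{-4}, 0)$,
`large` $(10^{-5}, 1)$, `verylarge` $(10^{-6}, 1)$, and `full`
(no contraction, no pruning).  The occupied-shell convention defaults to
the variant that counts d and f shells already at K/Ca and Cs/Ba.

## Numerical choices

* **Pivot tie-break**: lowest index among diagonals within $10^{-14}$
  (relative) of the maximum, which makes pivot orders deterministic and
  selections at different $\tau$ nested prefixes of one another.
* **Eigenvector degeneracy**: within eigenvalue clusters degenerate to
  $10^{-12}$ relative, the whole cluster is kept if any member passes
  $\epsilon$, so the contracted set never depends on the orientation an
  eigensolver picks inside a degenerate subspace.
* **Tabulation convention**: contraction coefficients from
  $C = V^{-1/2}U$ refer to Coulomb-normalized primitives; files tabulate
  against overlap-normalized primitives.  The conversion scales
  $C_{\mu i}$ by $\sqrt{\alpha_\mu}$ and renormalizes each column to
  unit overlap self-norm.  Whether the reference implementation
  renormalizes after the $\sqrt{\alpha}$ scaling is not documented;
  either choice spans the same fitting space (the suite checks span
  preservation through a file round-trip), and tabulation normalization
  is what basis-set files conventionally carry.
* **Degenerate inputs**: zero radial functions normalize to an error;
  an all-zero metric raises a degenerate-metric error; a $\tau$ above
  every candidate norm empties the shell with a warning rather than an
  error, as does an $\epsilon$ above every eigenvalue.

## Fixtures and what the tests show

The synthetic fixtures are deliberately tiny: a fixed three-primitive
hydrogen-like s contraction (`toy-H`, exponents 13.0, 1.96, 0.444), a
two-shell s+p toy (`toy-sp`), and seeded random bases with up to four
shells, $l \le 2$ and log-uniform exponents.  They exercise every code
path — parity windows, general contractions, degenerate candidates,
rank-deficient metrics — at problem sizes where brute-force oracles
(full-matrix projectors, explicit all-$m$ importance matrices, eigen
decompositions) are exact and fast; the whole suite completes in under
two minutes on one CPU.  What they do not probe is the conditioning of
production-sized basis sets (dozens of near-degenerate exponents per
$L$, angular momenta to $l = 10$) or any molecular DF/RI energy error:
reproducing the published per-element size tables requires the nZaPa-NR
orbital bases (a one-time Basis Set Exchange download, see the test
`test-acceptance.R`), and energy benchmarks require external SCF/MP2
engines and are out of scope here.  Passing tests therefore certify the
mathematical guarantees ($\tau$ spans, $\epsilon$ bounds, block
structure, convention round-trips), not chemical accuracy on real
molecules.

## Known limitations

* Only Gaussian radial functions are generated and emitted, although
  the quadrature engine evaluates any sum of $c\,r^p e^{-\alpha r^2}$
  terms.
* Effective core potentials, Cartesian Gaussian bookkeeping and
  molecular (multi-center) Cholesky decompositions are out of scope.
* The letter table for angular momenta ends at $l = 18$; writing a
  shell beyond it raises an error (orbital bases stop far below that).
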