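# autoabs

Automatic generation of density-fitting (DF / resolution-of-the-identity)
auxiliary basis sets from an arbitrary contracted spherical Gaussian
orbital basis set, per element, with guaranteed-accuracy thresholds.

DF/RI methods factorize the four-index electron repulsion integrals
through an auxiliary basis set (ABS); their accuracy is set by how well
the ABS spans the one-center orbital products χ<sub>μ</sub>χ<sub>ν</sub>.
`autoabs` builds that ABS in three stages, for users of quantum-chemistry
codes whose orbital basis has no hand-optimized auxiliary partner:

1. **Generation (τ)** — enumerate candidate radial functions
   r<sup>L</sup>e<sup>−(α<sub>i</sub>+α<sub>j</sub>)r²</sup> from all
   parity-allowed shell products (|l₁−l₂| ≤ L ≤ l₁+l₂, l₁+l₂+L even),
   optionally prescreen the pool, and select a spanning subset per L by a
   pivoted Cholesky decomposition of the Coulomb Gram matrix
   (R<sub>I</sub><sup>L</sup>|R<sub>J</sub><sup>L</sup>) to threshold τ.
   Every rejected candidate is reproduced by the selection with residual
   Coulomb self-overlap ≤ τ.
2. **Pruning (l<sub>inc</sub>)** — drop shells above
   l<sub>keep</sub><sup>max</sup> = max(2l<sub>occ</sub><sup>max</sup>,
   l<sub>occ</sub><sup>max</sup> + l<sub>OBS</sub><sup>max</sup>) +
   l<sub>inc</sub>, which retains the products of atomic occupied
   orbitals with each other and with any orbital function.
3. **Contraction (ε)** — diagonalize the per-l importance matrix
   **L** (the m = 0 subblock of **W** = **J**ᵀ**J**, **J** =
   **I** **V**<sup>−1/2</sup> the orthogonalized three-index integrals),
   keep eigenvectors with λ ≥ ε, and back-transform with **C** =
   **V**<sup>−1/2</sup>**U**.  The identity ‖**J** −
   **J U U**ᵀ‖²<sub>F</sub> = Σ<sub>dropped</sub> λ<sub>i</sub> makes ε a
   bound on the loss in the three-index integrals.

Presets bundle the knobs: `small` (ε = 1e-4, l_inc = 0), `large`
(1e-5, 1), `verylarge` (1e-6, 1), `full` (primitive set, no reduction).

## Worked example

```r
library(autoabs)

obs <- make_fixture("toy-sp")     # tiny He-like s+p orbital basis
obs
#> <element_basis He (Z=2), role OBS: 1s1p, 4 spherical functions>

res <- generate_abs(obs, preset = "large",
                    config = generation_config(method = "analytic"))
res$report
#> element He: N_obs = 4 (1s1p), N_abs = 10 (2s1p1d), gamma = 2.5
#>   primitive ABS: 4s2p1d

write_basis(res$basis, "He-large-abs.g94")
```

The report says: the orbital basis has 4 spherical functions (1 s shell,
1 p shell); candidate products yield a primitive auxiliary set of
composition 4s2p1d; pruning and contraction at the `large` preset reduce
it to 2s1p1d — 10 spherical functions, i.e. γ = N<sub>ABS</sub> /
N<sub>OBS</sub> = 2.5, the factor that sets DF cost.  The per-l
eigenvalue spectra are in `res$spectra`; for the s block here they are
`3.43e+00 1.50e-01 -9.4e-17 -1.1e-16` — two significant fitting
directions, two numerically null ones, so ε = 1e-5 keeps two s
contractions.

A thin command-line driver wraps the same functions:

```sh
Rscript inst/cli/autoabs.R generate --obs obs.g94 --preset large \
    --out abs.g94 --report report.json
Rscript inst/cli/autoabs.R gamma --obs obs.g94 --abs abs.g94
```

File formats: Gaussian94 text (read/write; the angular letter J is used
for l = 7, not skipped) and Basis Set Exchange JSON (read).

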