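---
title: "Local explicitly correlated MP2 in lmf12: models, parameters, numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local explicitly correlated MP2 in lmf12}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific content of the package: the
models implemented, the tunable parameters and their defaults, the
numerical choices made where the design was genuinely open, and what the
synthetic test systems do and do not probe.

## 1. The methods

### Canonical DF-MP2 and MP2-F12

The package computes the closed-shell MP2 correlation energy from
density-fitted electron repulsion integrals and explicit orbital-energy
denominators.  The explicitly correlated extension follows ansatz 2B
with **fixed geminal amplitudes**: the pair functions are
$Q_{12} f_{12}\,(3/8 + 1/8\,P_{12})\,|ij\rangle$ with
$f_{12} = -(1/\gamma)e^{-\gamma r_{12}}$, the rational generator fixed by
the singlet (1/2) and triplet (1/4) coalescence conditions, and the
strong-orthogonality projector $Q_{12} = (1-\hat o_1)(1-\hat o_2) -
\hat v_1\hat v_2$ resolved in the RI space (occupied + virtual +
complementary orbitals).  The F12 energy is assembled per pair as
$(B - X + C + V)/(1+\delta_{ij})$.

The pair weights used for $V$, $X$ and $B$ were derived from the
closed-shell Hylleraas functional
$E_2 = \sum_{ij} [\,2\langle\tilde u_{ij}|W|ij\rangle +
\langle\tilde u_{ij}|\hat F_1+\hat F_2|u_{ij}\rangle -
\sum_k (f_{ik}\langle\tilde u_{ij}|u_{kj}\rangle +
f_{jk}\langle\tilde u_{ij}|u_{ik}\rangle)\,]$ with
$\tilde u_{ij} = 2u_{ij}-u_{ji}$.  Substituting the fixed-amplitude
geminal and eliminating the conventional amplitudes reproduces exactly
the printed coupling-coefficient pattern $(1/16)[40,-8,7,1]$ of the $C$
intermediate — this was used as an algebraic cross-check of the weights
before implementation.  The resulting per-pair scalars are

* $V_{ij} = \tfrac52 V_d - \tfrac12 V_x$ with
  $V_d = \langle ij|f_{12} Q_{12} r_{12}^{-1}|ij\rangle$,
  $V_x = \langle ij|f_{12} Q_{12} r_{12}^{-1}|ji\rangle$;
* $B_{ij} = \tfrac7{16} B_d + \tfrac1{16} B_x$ with
  $B = \langle\cdot|f_{12} Q_{12}(\hat F_1+\hat F_2)Q_{12} f_{12}|\cdot\rangle$;
* $X_{ij} = \sum_k f_{ik}[\tfrac7{16}X_{ij,kj} + \tfrac1{16}X_{ij,jk}] +
  f_{jk}[\tfrac7{16}X_{ij,ik} + \tfrac1{16}X_{ij,ki}]$ with
  $X = \langle\cdot|f_{12} Q_{12} f_{12}|\cdot\rangle$.

The $X$ term deliberately keeps the **off-diagonal occupied Fock
couplings**: in a canonical basis it reduces to the familiar
$(\varepsilon_i+\varepsilon_j)X_{ij}$, but the general form makes the
geminal energy exactly invariant under occupied rotations, which is what
allows the local method to evaluate $B$, $X$, $V$ directly in the
localized-orbital basis of a domain.  The full-domain equality of the
local and canonical paths is asserted to $10^{-6}$ hartree in the test
suite and in practice holds to $10^{-13}$.

For $B$ the **F+K commutator treatment** is used:
$f(\hat F + \hat K)f = \tfrac12\{f^2,(\hat F+\hat K)\} + (\nabla_1
f_{12})^2$ exactly (the $\hat F+\hat K$ operator commutes with any local
potential), so $B$ needs only $f_{12}^2$ and $(\nabla_1 f_{12})^2$
integrals plus an RI-resolved exchange part $fKf$ and RI-resolved
projector terms.  No double commutators are evaluated numerically.

### The local method

Occupied orbitals are Boys-localized (core and valence separately,
pairwise Jacobi rotations, deterministic row-major sweep order, sign
fixed by the largest coefficient).  The virtual space is spanned by
projected atomic orbitals.  Modified Boughton–Pulay atom lists assign
atoms to each orbital: the greedy growth ranks atoms by descending
Löwdin population and stops when the squared S-norm of the least-squares
projection of the orbital onto the listed atoms' AOs reaches the
threshold.  Primary domains, pair estimates (dipole–dipole multipole, backed by
exact pair-domain evaluation for close pairs near the threshold),
strong/distant classification at $\varepsilon_w$, and extended domains
(with the PAO-center domain, the local fitting domain, the CABS domain,
core-orbital coverage rule and BPtrf transformation lists) follow the
domain-construction rules of the implemented model; the per-CMO MP2 and
F12 contributions are evaluated iteration-free with the shared
Cholesky-factorized denominators, the central-MO index back-transformed
from the pseudocanonical occupied basis, and the coupling intermediate
$C$ through Fock-transformed fitting coefficients
$\bar J_{\tilde a\tilde i,P} = \sum_{a'} f_{\tilde a a'} J_{a'\tilde i,P}$
(and $\bar K$), with the same $\omega$ set as the MP2 part.

The Fock transform of the coupling tensor runs over the **complementary
space only**: this is what the projector algebra of ansatz 2B gives
(contributions through the virtual block vanish by Brillouin's theorem),
and it is what makes the local algorithm consistent with the direct
canonical evaluation.

## 2. Parameters and defaults

| parameter | default | unit | role |
|---|---|---|---|
| `T_PDo` / `T_PDv` | 0.999 / 0.98 | — | BP completeness for primary domains (LMOs / PAOs) |
| `T_EDo` / `T_o` | 0.9999 / 0.985 | — | BP completeness for ED occupieds / PAO-center domain |
| `T_trf` | 0.99999 | — | LMO truncation lists at the integral transformation |
| `eps_w` | 1e-5 | hartree | strong-pair threshold |
| `cabs_domain` | `"BPEDo"` | — | atoms providing a domain's CABS functions |
| `cd_threshold` | 1e-4 | 1/hartree | Cholesky residual stop for denominators |
| `gamma` | 0.9 / 1.0 / 1.1 | 1/bohr | geminal exponent for DZ / TZ / QZ |
| CABS Löwdin cutoffs | 1e-7 / 1e-4 | — | projected-CABS / augmentation overlap eigenvalue drops |

On random gap spectra of fifty 0.2–5 hartree excitations, the 1e-4
Cholesky threshold yields 6–8 vectors; the tests assert at most 8.

## 3. Basis sets

No tabulated literature basis sets are shipped.  The package generates
its own internally consistent family by rule: occupied Slater shells
with Clementi-type exponents, each expanded in the universal
three-Gaussian 1s/2s/2p fits; `MIN` contracts them fully, `DZ` splits
the valence (two tight primitives contracted, the diffuse one free) and
adds one polarization shell on hydrogen, `TZ`/`QZ` uncontract further
and add d shells.  `RI-*` fitting sets and `CABS-*` sets are
even-tempered, derived from the orbital exponent ranges, with lean
higher-l counts.  Every correctness property asserted in the tests is an
internal-consistency statement (oracle comparisons, limits, invariances,
scaling laws), so nothing depends on matching a published basis.

The Slater geminal is expanded in six Gaussians by weighted least
squares on r ∈ [0, 10] bohr (weight $e^{-r/2}$, Levenberg–Marquardt on
log-exponents with linear coefficients solved exactly); the fit is done
once at unit exponent and rescaled analytically.  The stored maximum
pointwise residual is ~2.9e-3 with a 5e-3 acceptance tolerance; the
expansion *defines* the operator family used everywhere (both sides of
every consistency check use the same expansion), while comparisons
against exact-Slater quadrature oracles carry the fit residual as their
tolerance.

## 4. Numerical choices

* **Metric conditioning** — pivoted Cholesky of (P|Q) dropping pivots
  below 1e-10 of the largest diagonal; all fitting systems are solved by
  triangular substitution, never by explicit inversion.
* **Semicanonicalization** — Löwdin orthogonalization with a 1e-7
  relative eigenvalue drop, ties in pseudo-energies broken by original
  column index, signs fixed deterministically.
* **Domain virtuals** — truncated PAOs use a larger 1e-4 redundancy
  cutoff: truncated PAO sets are strongly redundant, and near-null
  directions amplify the residual occupied tails that truncation
  reintroduces.  In addition the in-domain components of occupied
  orbitals with substantial domain weight (overlap eigenvalue above
  1e-2) are projected out of the domain virtuals before
  canonicalization.  Both safeguards are exact no-ops in the full-domain
  limit.
* **Truncated LMOs** are renormalized after atom-list truncation, and
  the BPtrf lists are intersected with the ED *before* the
  half-transformation.
* **Laplace quadrature** (optional alternative to CD) fits nodes and
  weights of $\sum_\omega w_\omega e^{-x t_\omega} \approx 1/x$ on
  [2 gap_min, 2 gap_max] by Levenberg–Marquardt on a log grid from
  log-spaced starting guesses; each factor carries $w_\omega^{1/2}$ so
  that the product of two factors reproduces the weight once.
* **Prescreening** — Cauchy–Schwarz bounds with a 1e-12 threshold on
  all three- and four-center integral batches.
* **Pair classification** — every pair receives the dipole--dipole
  pair-energy estimate, which decides the strong/distant class at
  $\varepsilon_w$; pairs whose primary domains share atoms *and* whose
  centroids lie within 5 bohr have interpenetrating distributions where
  the multipole form is invalid, and are resolved by the exact
  pair-domain evaluation instead (with metric/integral caching per
  pair-domain atom set).  Distant-pair energies in the assembled LMP2
  energy are these same estimates, so near the $\varepsilon_w$ boundary
  the accuracy of the leading multipole order — not the classification
  machinery — is the limiting approximation.  `overlap_policy =
  "strong"` classifies all overlapping-domain pairs strong outright, an
  economical upper-bound setting.
* **Degenerate inputs** — duplicated aux functions are dropped by the
  metric pivoting; duplicated orbital columns by the Löwdin drop;
  non-positive excitation gaps abort with a diagnostic (they indicate a
  non-aufbau or contaminated reference).

## 5. What the fixtures emulate — and what they do not

`generate_fixture()` provides hydrogen-bonded water chains, all-trans
alkanes and noble-gas pairs: deterministic desk-scale stand-ins for the
large benchmark systems of production codes.  They exercise locality
(domain saturation along alkane chains, C4–C12), long-range behaviour
(R⁻⁶ pair-energy decay, strong/distant classification), size
consistency, and rigid-motion invariance.  They do **not** probe
conjugation, dense three-dimensional packing, heavy elements, strong
correlation, or basis sets beyond the built-in family — passing tests
show the machinery is internally correct, not that the default
thresholds reproduce production-quality accuracy for arbitrary
chemistry.  Problem sizes used by the suite: molecules up to C12H26
(238 AO) for domain audits, up to ~25 AO with ~75 RI functions for the
full F12 pipelines.

## 6. Known limitations

* Spin-restricted closed-shell references only; H, He, C, N, O.
* The B intermediate's exchange part and projector terms are RI-resolved
  in the finite CABS space, so B converges with CABS quality like any
  double-RI quantity; the commutator-treated direct part carries the
  fast-converging pieces.
* Distant pairs use the leading dipole–dipole multipole order only.
* The HF provider is dense/DF at desk scale; no local fitting in the
  Fock builds, no iterative CABS singles relaxation.
* Cartesian Gaussians are used throughout (no spherical-harmonic
  contraction); the redundancy is absorbed by the metric and Löwdin
  cutoffs.
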