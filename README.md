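# lmf12

An R implementation of integral-direct, iteration-free **local explicitly
correlated second-order Møller–Plesset perturbation theory (LMP2-F12)**
for closed-shell molecules at desk scale, together with the canonical
DF-MP2 and MP2-F12 methods it approximates.

## Who this is for

Method developers and students who want a transparent, fully inspectable
implementation of the machinery behind modern linear-scaling MP2-F12
codes: orbital localization, correlation domains, density fitting with
robust fitting for geminal integrals, Cholesky/Laplace factorization of
orbital-energy denominators, and complementary-auxiliary-basis (CABS)
construction — each exposed as a testable R function over a compiled
McMurchie–Davidson Gaussian integral engine.

## The model

The conventional MP2 correlation energy

E_c^MP2 = Σ_{ijab} [2(ai|bj) − (aj|bi)] t_ij^ab,  t_ij^ab = (ai|bj)/D_ij^ab

is augmented by explicitly correlated pair functions built from the
Slater geminal f12 = −(1/γ) e^(−γ r12) (ansatz 2B, fixed amplitudes 1/2
and 1/4 from the s- and p-wave cusp conditions, F+K commutator treatment
of the B intermediate):

E_c^MP2-F12 = E_c^MP2 + Σ_{i≤j} (B_ij − X_ij + C_ij + V_ij)/(1 + δ_ij)

plus a second-order CABS singles correction to the HF energy.  The local
variant evaluates per-orbital contributions inside extended domains (EDs)
assembled from Boughton–Pulay atom lists of Boys-localized orbitals and
projected atomic orbitals (PAOs):

E_c^LMP2-F12 = Σ_i δE_i^MP2(E_i) + Σ'_{ij} δE_ij^MP2(P_ij) + Σ_i δE_i^F12(E_i)

with distant pairs handled by a dipole–dipole multipole estimate and no
F12 term.  Energy denominators are removed by a pivoted Cholesky
decomposition of the Cauchy matrix 1/(x_ai + x_bj) (or by Laplace
quadrature), which makes every domain evaluation a fixed sequence of
matrix multiplications — no amplitude iterations.

All two-electron operators (1/r12, f12, f12², f12/r12, (∇₁f12)²) are
reduced to Coulomb, Gaussian-geminal and Gaussian/r kernels through a
six-Gaussian expansion of the Slater factor; three-index integrals are
density fitted, the non-Coulomb ones with robust (first-order-corrected)
fitting.  Basis sets are generated by rule (Slater-expansion valence
sets, even-tempered RI and CABS shells) — see the methods vignette.

## Worked example

```r
library(lmf12)
mol <- generate_fixture("water_chain", 1)       # one water molecule
ref <- load_reference(hf_reference(mol, "DZ"))  # built-in DF-RHF provider
res <- lmp2_f12(ref)                            # local MP2-F12, defaults
print(res)
```

prints (hartree):

```
<lmf12_energy> LMP2-F12
  E_hf                 -75.0313956108 Eh
  E_corr                -0.3065273973 Eh
  E_f12                 -0.1777245774 Eh
  E_cabs_singles        -0.4224422045 Eh
  E_total              -75.7603652126 Eh
```

`E_hf` is the restricted HF energy, `E_corr` the LMP2-F12 correlation
energy (`E_corr = E_lmp2 + E_f12`: the domain MP2 part −0.1288 Eh plus
the explicitly correlated part −0.1777 Eh), `E_cabs_singles` the
second-order basis-set correction to the HF reference, and `E_total`
their sum.  For a single water every extended domain spans the whole
molecule, so these values agree with `canonical_mp2_f12(ref)` to
numerical precision — the first consistency property the test suite
checks.  The F12 term does what it is for: the helium DZ correlation
energy −0.02488 Eh becomes −0.03595 Eh with F12, against −0.03303 Eh
from the much larger QZ basis (the remaining difference reflects the QZ
basis still being incomplete).

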