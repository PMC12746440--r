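---
title: "Rayleigh optical activity: model, measurement simulation, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rayleigh optical activity: model, measurement simulation, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rayoa)
```

## The observable and its model

Rayleigh optical activity arises from interference between light waves
scattered via the ordinary polarizability and via the optical activity
tensors of a chiral molecule. In the scattered circular polarization (SCP)
strategy the observable is the circular intensity differential (CID)

$$\Delta = \frac{I_R - I_L}{I_R + I_L},$$

the normalized difference of the right- and left-circularly polarized
components of the light scattered at right angles, with the incident beam
linearly polarized in the scattering plane (the *depolarized* geometry,
which suppresses isotropic scattering and its polarization artifacts; it is
equivalent to the depolarized right-angle ICP geometry). For an
enantiopure, conformationally rigid molecule illuminated far off resonance,

$$\Delta \;\approx\; \frac{1}{c}\,
  \frac{24\,\beta(G')^2 - 8\,\beta(A)^2}{12\,\beta^2},$$

with $c$ the speed of light and the three rotational invariants computed
from the electric dipole--electric dipole polarizability $\alpha$, the
electric dipole--magnetic dipole optical activity tensor $G'$, and the
electric dipole--electric quadrupole tensor $A$:

$$\beta^2 = \tfrac12\left(3\,\alpha_{ij}\alpha_{ij}
  - \alpha_{ii}\alpha_{jj}\right), \qquad
\beta(G')^2 = \tfrac12\left(3\,\alpha_{ij}G'_{ij}
  - \alpha_{ii}G'_{jj}\right), \qquad
\beta(A)^2 = \tfrac{\omega}{2}\,\alpha_{ij}\,\epsilon_{ikl}\,A_{klj}.$$

$\beta^2 \ge 0$ is parity even (chirally insensitive); $\beta(G')^2$ and
$\beta(A)^2$ are pseudoscalars that flip sign under any improper transform,
which is the tensor-level statement that enantiomers show equal magnitudes
and opposite signs and that achiral molecules show $\Delta = 0$.

Three normalization choices deserve comment, because the literature is not
uniform:

* **Units.** Everything is stored in Hartree atomic units with
  $c = 137.035999084$ a.u. and $1\,\mathrm{nm} = 18.897261246$ bohr;
  conversions happen only at the wavelength boundary. A single internal
  unit system removes any ambiguity in the $1/c$ prefactor.
* **Placement of $\omega$.** Published normalizations of the quadrupole
  invariant differ by factors of 2 and by $\omega$ vs. $\omega/c$
  placement. Here the frequency factor lives inside $\beta(A)^2$, making it
  directly commensurable with $\beta(G')^2$ so that the CID keeps a single
  $1/c$ prefactor. The three formulas above *are* the contract; any tensor
  data fed to the package must be consistent with them.
* **Signs.** The minus sign in $24\beta(G')^2 - 8\beta(A)^2$ is adopted as
  the package's convention; tabulations that differ in the sign attached
  to the quadrupole term correspond to the opposite sign convention for
  $A$. Likewise, sign conventions for $G'$ differ between
  electronic-structure codes, and a globally wrong sign would flip every
  predicted $\Delta$ — hence the `gprime_sign` switch on
  `read_tensor_set()` (default $+1$); the package cannot guess the
  convention of an arbitrary code, so the switch and this note are the
  documentation of that fact.

## Exact transformation behaviour

Three groups of exact identities back the implementation, and the test
suite checks each against independent brute-force index loops:

* **Rotations.** $\alpha$ and $A$ transform as polar tensors,
  $G'$ as an axial tensor with a $\det(R)$ factor. All three invariants are
  invariant under proper rotations; improper transforms (the enantiomer
  map, realized by the inversion $-I$) flip the pseudoscalars and
  $\Delta$ while preserving $\beta^2$.
* **Origin shifts.** $G'$ and $A$ depend on the multipole origin through
  the standard translation rules
  $G'_{ij} \to G'_{ij} - \tfrac{\omega}{2}\epsilon_{jkl} d_k \alpha_{il}$
  and
  $A_{ijk} \to A_{ijk} - \tfrac32 d_j\alpha_{ik} - \tfrac32 d_k\alpha_{ij}
   + \delta_{jk} d_l \alpha_{il}$,
  but for a *symmetric* $\alpha$ the origin-dependent parts cancel exactly
  in $\beta(G')^2$ and $\beta(A)^2$, so the predicted CID is origin
  independent. `shift_origin()` exists to exercise that cancellation and
  therefore refuses an asymmetric $\alpha$, for which the cancellation
  fails.
* **Scaling.** $\Delta$ is linear in a common rescaling of $(G', A)$ at
  fixed $\alpha$ and inverse in a rescaling of $\alpha$ at fixed
  $(G', A)$. The first of these makes the fixture generator's exact
  CID calibration possible.

Because finite-precision quantum-chemistry output rarely satisfies the
index symmetries exactly, the container always projects: $\alpha$ is
symmetrized (valid far off resonance) and $A$ is symmetrized and
de-traced over its quadrupole pair, with a warning once the projection
exceeds a relative Frobenius norm of `sym_tol` ($10^{-6}$ by default).
Different programs print different reduced forms of $A$, so storing the
full 27 components and projecting at load is the robust choice.

## Wavelength dependence

Far off resonance $\Delta \propto 1/\lambda$ to good approximation, so a
532 nm prediction rescales to any other far-off-resonance wavelength by
`rescale_wavelength()`. The package has no excitation-energy data in its
input schema and therefore cannot check validity computationally; instead
a caution is emitted when extrapolating by more than a factor of 2 in
wavelength. Only the depolarized right-angle SCP geometry is implemented;
the geometry tag on every prediction exists so that other CIDs (e.g.
backscattering dual-circular strategies) could be added without breaking
the interface.

## The photon-counting measurement model

A real SCP acquisition is shot-noise limited. `simulate_scp()` draws the
total detected count $N$ from a Poisson law with mean
$\text{count rate} \times \text{exposure}$, splits it into channel means
$N(1 \pm \Delta)/2$, and draws the two channels as independent Poisson
variates on those means — the standard photon-counting model (the
difference from multinomial thinning is negligible at relevant $N$). The
estimator $\Delta_\text{raw} = (n_R - n_L)/(n_R + n_L)$ carries the
shot-noise error $\sigma_\Delta = 1/\sqrt{n_R + n_L}$, so $10^{10}$
accumulated counts give the $\sim 10^{-5}$ precision a CID of a few
$10^{-4}$ needs; `required_exposure()` inverts that budget. Above a mean
of $10^9$ the Poisson draw switches to its Gaussian limit, where the
neglected skewness is below $3\times10^{-5}$ relative — far beneath the
shot noise itself. The count rate is a direct user input rather than being
derived from power and solid angle: that derivation would need a molecular
scattering cross-section and a detector efficiency, which are not part of
this model; power and solid angle are carried as acquisition metadata.

Three corrections connect the raw to the reported CID, applied in order by
`correct_measurement()`:

1. an **enantiomer-independent instrumental offset**, removable by
   measuring both enantiomers: the offset is the symmetric part
   $(\Delta_A + \Delta_B)/2$ and the signal the antisymmetric part;
2. an **enantiomeric-excess** rescaling by $1/\text{ee}$, since the
   observed CID is linear in ee;
3. a multiplicative factor for the **rotation of the incident linear
   polarization** as the beam propagates through the optically active
   sample (default 1).

These are the minimal faithful forms of the three named effects; the
interface deliberately keeps them as three independent, composable linear
steps (with quadrature error propagation) so that instrument-specific
refinements can replace any one of them without changing the API. The
correction-recovery tests inject a known offset and imbalance and verify
unbiased recovery.

## Absolute-configuration assignment

`assign_configuration()` assigns the enantiomer label whose predicted CID
sign matches the corrected measurement, reports `sign_agreement` — the
fraction of ensemble members sharing the ensemble's consensus sign, i.e.
the cross-method robustness of the predicted sign — and flags the
assignment `confident` only when the ensemble is unanimous *and* the
measurement is at least $k\sigma$ from zero ($k = 3$ by default;
conventional significance, and a real measurement at the shot-noise floor
sits an order of magnitude above it). Defining agreement against the
ensemble consensus rather than against the measured sign keeps the
quantity a property of the prediction set: negating the measurement swaps
the assigned label but cannot change how unanimous the methods are. A
measurement within $k\sigma$ of zero returns an explicit `indeterminate`
status rather than an error, because that is a legitimate experimental
outcome.

## What the synthetic generator does and does not emulate

`make_tensor_set()` produces seed-reproducible tensor sets of three kinds:
random chiral sets (symmetric positive-definite $\alpha$, random $G'$,
projected random $A$), mirror-symmetric achiral sets (tensors constrained
to commute with a reflection, forcing both pseudoscalars to vanish
identically), and isotropic sets. Chiral fixtures rescale $G'$ and $A$ by
one common factor so the CID magnitude lands in $10^{-4}$–$10^{-3}$ — the
numerically delicate regime real rigid monoterpenes occupy at visible
wavelengths — or exactly on a requested `target_delta` (the calibration is
exact because $\Delta$ is linear in that scaling). The default tensor
magnitude of 10 a.u. is the order of a small organic molecule's
polarizability anisotropy.

What passing tests on these fixtures demonstrates is the *exactness of the
algebra and the statistics of the measurement model*: invariance,
antisymmetry, calibration, shot-noise scaling and unbiased correction.
What they cannot demonstrate is agreement of any specific molecule's
predicted CID with experiment, because synthetic tensors have no
electronic structure: the relative weight of the $\beta(G')^2$ and
$\beta(A)^2$ contributions, conformational averaging, and solvation are
all outside the generator. Predictions for a real molecule require
response tensors from a quantum-chemistry code. For the canonical rigid
monoterpene benchmark those are obtained by computing $\alpha$, $G'$ and
$A$ at 532 nm (and the other common laser lines between 365 and 1064 nm)
with several density functionals — e.g. CAM-B3LYP, ωB97X-D, LC-ωHPBE,
B3LYP, M06-2X, B3PW91 — in an augmented triple-zeta basis
(aug-cc-pVTZ) on a B3LYP/6-311G(d,p) optimized geometry, exporting each
tensor set to this package's JSON format, and running the `predict`
pipeline; the ensemble spread across functionals is the robustness report.

## Numerical choices and problem sizes

* Orthogonality of transforms is enforced to $10^{-12}$ (Frobenius);
  fixture symmetry projections to machine precision.
* Invariant implementations are vectorized contractions; tests compare
  them to quadruple-loop oracles at $10^{-12}$ relative on over a hundred
  random tensor sets.
* Rotation-invariance tests use 100 Haar-random rotations per fixture at
  $10^{-10}$ relative; origin-invariance tests use random shifts of
  0.1–2 bohr at $10^{-9}$ relative.
* Measurement statistics are validated with 100–1000 replicates at
  $10^4$–$10^{10}$ expected counts: the replicate spread matches
  $1/\sqrt{N}$ (log–log slope $-0.5 \pm 0.05$), and the end-to-end
  correction recovery runs 200 paired replicates at $10^8$ counts. These
  sizes give Monte-Carlo standard errors several times smaller than the
  tolerances they are tested against while the whole suite stays fast.

## Known limitations

* One scattering geometry (depolarized right-angle SCP); resonance RayOA
  and backscattering strategies are out of scope.
* The three corrections are minimal linear models; a specific instrument
  may need a measured transfer function in place of the multiplicative
  rotation factor.
* No parsing of quantum-chemistry log files: tensors enter through the
  JSON interchange format, and conversion from a particular code's output
  (including its $G'$ sign convention) is the user's responsibility.
* Far-off-resonance validity of the $1/\lambda$ law is asserted, not
  checked, since the input schema carries no excitation energies.
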