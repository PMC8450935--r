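---
title: "Hydration-shell density analysis: model, estimators and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hydration-shell density analysis: model, estimators and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Antifreeze proteins (AFPs) adsorb to growing ice nuclei and locally depress
the freezing point (thermal hysteresis, $\Delta T$). The water layer around
an AFP — denser than bulk overall, but inhomogeneous between the flat,
relatively hydrophobic ice-binding surface (IBS) and the rest of the protein
(NIBS) — is central to current mechanistic hypotheses. `hydroshell`
implements the estimators needed to quantify that layer from solvated
configurations: distance-resolved density profiles referenced to a
protein-ellipsoid surface, the whole-shell relative density increment
$\eta$, the partial molar volume $v$, and per-surface local increments
$\eta_{surf}$ together with hydrophobic solvent-accessible-area fractions.

## The model and its estimators

**Reference surface.** Each protein is modelled as an ellipsoid: the centre
is the heavy-atom centroid, the axes are the gyration-tensor eigenvectors,
and the semi-axes are $a_i = \sqrt{5\lambda_i}$, the exact relation for a
uniform solid ellipsoid. This construction is parameter-free, reduces to a
sphere for isotropic clouds and is equivariant under rigid motions (all
properties are tested). Any residual arbitrariness in the reference surface
cancels in the ratio normalisation described below, which is why the
analysis is robust to the precise fit; users can substitute their own
ellipsoid via `ellipsoid()` / `read_ellipsoid()`.

**Signed distance and shell volume.** All densities are functions of the
signed Euclidean distance $d$ to the ellipsoid surface (negative inside),
computed per point by a bracketed bisection of the nearest-point condition
(converged far below $10^{-6}$ nm; exact for spheres). Shell and slab
volumes are outer-parallel-body volumes, which for a convex body are given
*exactly* by the Steiner polynomial
$V(t) = V + S\,t + M\,t^2 + \tfrac{4\pi}{3}t^3$, with the surface area $S$
and integrated mean curvature $M$ evaluated by high-order quadrature. A
quasi-Monte-Carlo estimate over the bounding box is kept as an independent
cross-check (`method = "qmc"`); we made the Steiner form the default because
it is closed-form and noise-free, and verify the two against each other in
the test suite.

**Fictitious bulk-filled shell.** To compare shell water with bulk water
without geometric artefacts from atoms protruding through the ellipsoid,
the protein coordinates of each frame are overlaid on an independent
bulk-water configuration and every water molecule with any atom closer to
any protein atom than the sum of their van der Waals radii is removed
(whole molecules). The density of these fictitious configurations,
$\rho_{b,fict}(d)$, is the denominator of the ratio profile
$\rho(d)/\rho_{b,fict}(d)$, which tends to 1 in the bulk and whose plateau
(diagnosed by `detect_plateau()`, never silently applied) motivates the
1 nm shell thickness.

**Whole-shell statistics.** With $V_{shell}$ the parallel-body volume at the
shell thickness, $V_{ex}$ the volume enclosed by the solvent-accessible
surface (union of spheres $r_i + r_{probe}$, grid-integrated), and
$N_{shell}$ the number of water oxygens with $d \le$ thickness,

$$\rho_{shell} = \frac{\langle N_{shell}\rangle}
                      {\langle V_{shell}\rangle - \langle V_{ex}\rangle},
\qquad \eta = \frac{\rho_{shell}}{\rho_{bulk}} - 1 .$$

The partial molar volume follows from the excess shell water
$\Delta N = \langle N_{shell}\rangle - \rho_{bulk}(\langle V_{shell}\rangle -
\langle V_{ex}\rangle)$ as
$v = N_A\,(V_{ex} - \Delta N/\rho_{bulk})$, reported in l/mol with
1 nm$^3 \equiv 0.6022$ l/mol. Both formulas are validated against all eight
published AFP rows bundled in `afp_reference("shell")` (to $\pm 0.002$ in
$\eta$ and $\pm 0.03$ l/mol in $v$); this arithmetic fixture runs in the
test suite.

**Per-surface densities.** For a residue selection (IBS, NIBS or whole
protein), $\rho_{surf} = \langle N_w\rangle/\langle S\rangle$ counts
distinct water molecules whose oxygen lies within the counting cutoff of
any heavy atom of the selection, per unit of the selection's
solvent-accessible surface area; means are taken separately over frames
(ratio of means, not mean of ratios, following the definition). The same
count on the fictitious configurations, with the real protein's SASA
series, gives $\rho_{surf}^{fict}$ and
$\eta_{surf} = \rho_{surf}/\rho_{surf}^{fict} - 1$. Boundary waters within
the cutoff of both IBS and NIBS atoms are counted by both surfaces — the
two counts are computed independently.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| shell thickness | 1.0 | nm | hydration-shell outer boundary (bulk plateau) |
| probe radius | 0.14 | nm | SASA / excluded-volume probe |
| surface cutoff | 0.55 | nm | first-layer counting distance for $\eta_{surf}$ |
| charge threshold | 0.2 | e | atoms with $|q| \le 0.2$ are nonpolar (inclusive) |
| $\rho_{bulk}$ | 33.33 | nm$^{-3}$ | bulk water number density at 300 K |
| bin width / range | 0.02 / 2.0 | nm | profile binning |
| subtrajectories | 3 | — | contiguous blocks for standard errors |

All are exposed as function arguments and config keys. When a bulk
trajectory is supplied, $\rho_{bulk}$ is measured from it and both the
input and measured values are reported. The vdW radii and partial charges
are always explicit input (a Bondi-style element table with SPC water
parameters ships as a default); no radii are hard-coded in the
computations, and unparameterised atoms are a hard error rather than a
silent default. The charge threshold is inclusive at $\pm 0.2$ e, so
boundary atoms classify as nonpolar. The SPC water hydrogens carry no vdW
radius; one consequence, exploited by the synthetic oracles, is that
overlap removal is decided entirely by the oxygen site (if the oxygen
clears every protein atom by its own radius, the hydrogens — only 0.1 nm
away — necessarily clear them too).

## The synthetic-data generator

The analysis consumes positions only, so the generator emulates the
*statistical* structure of solvated MD frames rather than their dynamics:

- **Bulk boxes.** Water oxygens are placed by sequential hard-core
  insertion (minimum O–O distance 0.26 nm, mimicking water's exclusion
  core) with the per-frame count drawn Poisson at the target density, so the
  mean density is exact by construction. Target densities beyond roughly
  85% of the random-sequential-adsorption jamming fraction ($\phi \approx
  0.384$) are refused; liquid-water density (33.33 nm$^{-3}$) sits safely
  below that. Hydrogens are attached at fixed SPC geometry with random
  orientation.
- **Pseudo-protein.** Atoms uniformly fill a specified ellipsoid, with
  radii in 0.15–0.19 nm and charges drawn from a polar/nonpolar mixture
  whose polar fraction differs between an IBS-like cap and the NIBS-like
  remainder, reproducing the amphipathic character of real AFPs.
- **Hydrated frames.** An elevated-density hard-core bulk frame is thinned
  independently with keep probability
  $(1+\eta_0(d,\text{patch}))/(1+\eta_{max})$, zero inside the protein's
  solvent-accessible surface. Independent thinning scales a point-process
  intensity exactly, so the realised water intensity is
  $\rho_{bulk}(1+\eta_0)$ outside the SAS with no approximation — the
  ground truth for recovery tests. Expectations (`expected_shell_stats()`,
  `expected_surface_stats()`) are computed by quasi-Monte-Carlo integration
  of that specified intensity in a separate code path, never by the
  estimators under test.

What the generator does **not** emulate: hydrogen-bond structure and
orientational order, water–water correlations beyond the hard core,
protein flexibility (the mimic is rigid), and realistic water packing
against the protein surface. In particular, synthetic waters approach the
protein to the SAS (probe distance) whereas fictitious-overlay waters are
excluded at vdW contact; the resulting small positive offset in
$\eta_{surf}$ is real for this substrate, appears identically in the
integration oracle, and therefore does not affect recovery tests — but
absolute synthetic $\eta_{surf}$ values should not be read as predictions
for real proteins. Passing recovery tests demonstrates estimator
correctness (unbiasedness against a known intensity), not force-field
realism.

## Numerical choices

- Ellipsoid distances: bisection in a shifted Lagrange variable avoids
  cancellation at the interior limit; 100 iterations reach machine
  precision; interior points exactly on a principal plane are nudged by
  $10^{-9}$ nm onto the correct branch (distance error bounded by the
  nudge). Points at the exact centre return $-c$.
- Excluded volume: grid counting at 0.01 nm spacing (relative error well
  below 0.5% even for single atoms), processed in z-blocks to bound memory.
- SASA: Shrake–Rupley with a deterministic Fibonacci-spiral point set (960
  points/atom by default; doubling changes a 100-atom total by < 0.3%).
- Distance bins are half-open $[d_{low}, d_{high})$; bins with zero
  fictitious density are flagged undefined rather than infinite; the
  water position is always the oxygen site.
- Standard errors: series are split into 3 contiguous blocks (remainder to
  the last), and the error is the standard error of the block means.
  Derived quantities ($\eta$, $v$, $\eta_{surf}$) are recomputed per block.
- Test problem sizes: recovery tests use a 120-atom mimic in a
  5.4 × 5.2 × 5.0 nm box (about 5,000 waters per frame) with 200 frames for
  the headline recovery checks and 10–40 frames for module-level checks;
  integration oracles use 1.5–2 million Halton points. These sizes hold the
  Monte-Carlo error of each check comfortably below its tolerance.

## Design decisions that were genuinely open

- The ellipsoid construction (gyration mapping) is our documented choice;
  the ratio normalisation makes downstream results insensitive to it, and
  the fit is deliberately replaceable.
- Steiner-exact parallel-body volumes are the default with QMC as the
  cross-check (rather than the reverse): closed form beats sampling noise.
- Matérn-style thinning cannot reach liquid-water density under a 0.26 nm
  hard core (its intensity ceiling is $\sim$13.6 nm$^{-3}$), so the bulk
  generator uses sequential insertion with a Poisson-drawn count, which
  achieves the exact target mean density and the hard core simultaneously.
- "Heavy atoms of the selected surface" means all non-hydrogen atoms of
  the selection's residues, exposed or not: selections are defined by
  residue lists, and buried atoms rarely have waters within the cutoff.
- Triclinic boxes are rejected explicitly; orthorhombic minimum-image logic
  is simple enough to verify exhaustively against brute force.
- XTC input is not supported (no reader in the R stack this package builds
  on); multi-frame GRO/PDB and DCD cover trajectory input.

## Known limitations

- Only orthorhombic periodic boxes; no structure repair or protonation.
- Per-frame excluded volume on a flexible protein is the dominant cost;
  rigid (static) proteins are detected and computed once.
- The plateau detector is a diagnostic; shell thickness is a parameter.
- Correlation reporting (Pearson r, least squares, group means) quantifies
  trends that the source data report only visually; it is intentionally
  minimal.
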