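# hydroshell

Hydration-shell density analysis for antifreeze proteins (AFPs) and other
solvated solutes.

Antifreeze proteins bind growing ice nuclei through a flat, relatively
hydrophobic ice-binding surface (IBS) and depress the local freezing point
(thermal hysteresis ΔT; moderately active AFPs have ΔT < 1 K, hyperactive
ones ΔT > 1 K). The structure of their hydration shell — denser than bulk
overall, but locally depleted at the IBS and enriched at the non-ice-binding
surface (NIBS) — is a key mechanistic quantity. `hydroshell` computes, from
molecular-dynamics-style solvated configurations:

- solvent density as a function of the distance from a protein-ellipsoid
  reference surface, for the real system and for a *fictitious* reference in
  which the protein is overlaid on bulk water and overlapping waters are
  removed, plus their ratio ρ/ρ_b,fict;
- whole-shell statistics: excluded volume V_ex (SAS-enclosed, 0.14 nm
  probe), shell volume V_shell (ellipsoid parallel body at 1 nm), shell
  water count N_shell, and from them

      ρ_shell = ⟨N_shell⟩ / (⟨V_shell⟩ − ⟨V_ex⟩),
      η       = ρ_shell / ρ_bulk − 1,
      v       = N_A · (V_ex − ΔN/ρ_bulk),   ΔN = ⟨N_shell⟩ − ρ_bulk (⟨V_shell⟩ − ⟨V_ex⟩),

  with errors over 3 contiguous subtrajectories;
- per-surface local densities ρ_surf = ⟨N_w⟩/⟨S⟩ (waters within 0.55 nm of
  a selection's heavy atoms per unit SASA) and their relative increments
  η_surf = ρ_surf/ρ_surf^fict − 1 for IBS/NIBS/whole-protein selections,
  together with hydrophobic SASA fractions S_pho/S (atoms with |q| ≤ 0.2 e
  count as nonpolar);
- a synthetic-configuration generator with analytically known density
  structure (inhomogeneous hard-core point process) so every estimator is
  validated against exact integrated expectations, without running MD.

Input formats: PDB and GRO structures, multi-frame GRO/PDB or DCD
trajectories, a TSV table of vdW radii and partial charges, and YAML
selections/configs. Outputs are TSV tables mirroring the usual
shell/SASA/surface-density summaries.

## Worked example

Published whole-shell inputs for the eight AFPs ship with the package;
recomputing η and v from them and correlating:

```r
library(hydroshell)
ref <- afp_reference("shell")
inc <- shell_density_increment(ref$N_shell, ref$V_shell, ref$V_ex, rho_bulk = 33.33)
v   <- partial_molar_volume(ref$N_shell, ref$V_shell, ref$V_ex, rho_bulk = 33.33)
data.frame(protein = ref$protein, eta = round(inc$eta, 3), v = round(v, 2))
#>    protein   eta     v
#> 1  TisAFP6 0.114 16.62
#> 2    PaAFP 0.051  2.31
#> 3    ZaAFP 0.071  5.37
#> 4  TisAFP8 0.102 17.00
#> 5 CfAFP337 0.080  6.41
#> 6    TmAFP 0.083  5.50
#> 7    RiAFP 0.088  9.83
#> 8 CfAFP501 0.088  9.01
correlate_proteins(v, inc$eta, classes = activity_class(ref$delta_T))
#> correlation: r = 0.925 (p = 0.00101, n = 8), fit y = 0.003291 x + 0.05506
#> group means: hyperactive 0.08493, moderate 0.08446
```

The shell density increment rises strongly with protein size (r = 0.925
against v) but is essentially identical between activity classes — the
discriminating signal lives in the per-surface increments, where the NIBS
of hyperactive AFPs is systematically denser.

Running the full estimator on a synthetic system with a designed 10% shell
enhancement recovers it within the subtrajectory error:

```r
spec <- synthetic_spec(amplitude = 0.10, seed = 7)
traj <- generate_hydrated_frames(spec, 50)
prot <- attr(traj, "protein")
shell_summary(traj, prot$E_true, rho_bulk = spec$rho_bulk)
#>     V_ex V_ex_se V_shell N_shell N_shell_se rho_shell rho_bulk    eta eta_se
#> 1 7.3684       0 44.1943 1352.72     2.6832   36.7328    33.33 0.1021 0.0022
#>      pmv pmv_se
#> 1 2.1731 0.0485
```

`analyze_system()` / `run_protein()` chain every stage (ellipsoid fit,
profiles, fictitious overlay, SASA, surface densities) for one protein; a
thin CLI lives at `inst/cli/hydroshell.R` with `synthesize`, `run` and
`report` subcommands.

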