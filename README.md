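# rodgate

A desk-scale continuum simulator of tension-driven gating of the bacterial
mechanosensitive channel MscL, for biophysicists who want to rerun and
extend in-silico gating experiments — wild-type opening, N-terminus
deletion, glycine-linker extension — without an all-atom setup or a
commercial finite-element stack.

## The model

MscL is a homopentamer: per subunit a pore-lining TM1 helix, a
lipid-facing TM2 helix, and a short amphipathic N-terminal helix lying in
the cytoplasmic membrane interface, joined to TM1 by the G14 glycine
hinge. `rodgate` represents each helix as a corotational elastic rod of
5 Å diameter, the G14 junction as a hinge connector releasing one
rotation, and the periplasmic loops as nonlinear hardening wires. The
bilayer enters through a depth-resolved lateral pressure profile whose
zeroth moment carries the applied nondimensional tension
σ\* = stress / *E* (all quantities are expressed in units of the protein
Young's modulus *E*), a Hamaker-type van der Waals surface traction

  S(D) = (A_H / 6π D₀³) · [ (D₀/D)³ − (D₀/D)⁹ ],

between helix surfaces and the bilayer inner rim (A_H ≈ 21 zJ, fitted to
lipid–helix interaction-energy tables), volume-conserving thinning
h = h₀/(1 + σ\*/K_A\*), and elastic embedding of the interfacial
N-terminal helix in the stretching membrane. A quasi-static Newton
solver ramps σ\* in 30 increments and reports helix tilts, the effective
(backbone) pore radius, N-terminal radial displacement, bilayer thinning
and per-element von Mises stress. A sequence module computes hydrophobic
moments (μH), helical wheels, charge statistics and PROSITE-style
consensus-motif scans for amphipathic N-terminal helices.

## Worked example

```r
library(rodgate)

# wild-type pentamer, frozen default calibration, ramp to sigma* = 0.6
sys  <- assemble_system(build_idealized(idealized_params("gating")))
traj <- solve_quasistatic(sys)
rep  <- gating_report(traj)
tail(rep[, c("sigma", "tm1_tilt", "tm2_tilt", "pore_diameter",
             "nterm_radial_displacement", "thinning_percent")], 1)
#>    sigma tm1_tilt tm2_tilt pore_diameter nterm_radial_displacement thinning_percent
#> 31   0.6 46.49605 31.42875      32.26413                  11.17475               15
```

TM1 has tilted from 27° to ≈ 46.5° from the fivefold axis (a ≈ 19.5°
change), TM2 by ≈ 17.4°, the backbone pore has opened from 14 Å to ≈ 32 Å
diameter, the N-terminal helix has moved ≈ 11.2 Å radially outward, and
the bilayer has thinned 15% (≈ 5 Å). At half tension (σ\* = 0.3, row 16 of
the same report) the pore diameter is ≈ 24.2 Å; rebuilding without the
N-terminal helices (`build_idealized(..., has_nterm = FALSE)`) and loading
to the same σ\* = 0.3 gives only ≈ 19.1 Å — the N-terminal helix is the
force-collecting antenna of the channel:

```r
ex <- run_variant_experiment("dNTERM", sigma_max = 0.3,
                             config = solver_config(sigma_max = 0.3,
                                                    n_increments = 15))
print(ex)
#> <variant_experiment> dNTERM: sigma* -> 0.300
#>   pore diameter 19.1 A, TM1 tilt 38.0 deg (change 11.0), thinning 8.1%
#>   matched WT at sigma* 0.300: pore 24.2 A, TM1 tilt 36.8 deg
```

Sequence-level amphipathicity of the EcMscL N terminus:

```r
ec <- peptide_sequence(mscl_nterm_sequences()[["EcMscL"]], id = "EcMscL")
max_hydrophobic_moment(ec, window = 11)$mu_h     # 0.599  (> 0.45: amphipathic)
motif_scan(ec, mscl_consensus_motif())           # F-[K,R]-x-F-[A,I,L]-x-[K,R]-G at position 7
```

A thin command-line driver over the same functions is installed at
`inst/cli/rodgate.R` (subcommands `fixture`, `geometry`, `simulate`,
`compare`, `amphipathy`, `mesh-check`).

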