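# fluorelease

Structure-based scoring of how easily a fluoride ion releases an
organophosphate (OP) from its covalent protein adduct.

## The problem

Nerve agents and OP pesticides phosphylate the catalytic serine of plasma
butyrylcholinesterase (BChE, Ser198) and reactive tyrosines/lysines of human
serum albumin (HSA). Forensic verification of OP exposure treats these adducts
as biomarkers: incubation with potassium fluoride displaces the OP as a
volatile fluoroanhydride that can be detected by GC-MS. Whether that works
depends on the adduct's substituents — the O-alkyl group R1 and the second
substituent R2 control how close the fluoride can approach the phosphorus and
how strongly it is held there. `fluorelease` implements the desk-scale side of
that assessment for analytical chemists and molecular modellers deciding
whether a fluoride-reactivation assay is worth a limited plasma sample.

## The score

Reactivation is an in-line nucleophilic attack of F⁻ on the adduct phosphorus
that breaks the P–Oγ bond. The package's core quantity is a screened-Coulomb
barrier proxy. For each adduct, with AM1-derived partial charges `q_P`, `q_O`,
`q_F` and the distances `d(P–Oγ)` (covalent bond) and `d(P–F)` (productive
complex):

    E_el(i,j) = k q_i q_j / (ε r_ij),   k = 332.0637 kcal·Å/(mol·e²),  ε = 4

    ΔE_el = E_el(P–F) − E_el(P–Oγ)      [kcal/mol]

ΔE_el is the electrostatic price of trading the existing P–Oγ contact for the
incoming P–F contact: the lower it is, the easier the adduct is reactivated.
The effective dielectric ε = 4 is calibrated so that the packaged reference
energies are reproduced from their charges and distances. A complementary
molecular-mechanics criterion ranks adducts by the mean P–F distance over a
stable MD interval (`⟨distP–F⟩`, shorter = easier).

Around the score the package provides the supporting pipeline: PDB reading and
writing (via bio3d), in-line fluoride probe placement anti to the phosphoryl
oxygen, productive-pose filtering at the 4 Å attack cutoff, distance /
residence-time / hydration analysis of multi-model PDB trajectories, a ΔG→K_d
converter, a substituent-based structural classifier, and seeded synthetic
generators (active-site fragments, tethered-ion trajectories, charge tables)
so every stage is testable without MD or quantum-chemistry software.

## Worked example

```r
library(fluorelease)

fit <- read_adduct_table(fluorelease_example("bche_am1_charges")) |>
  score_reactivation()
tidy(fit)[, c("rank", "adduct_id", "r1", "r2", "delta_e_el")]
#>     rank adduct_id r1               r2            delta_e_el
#>  1     1 Ad7       nC4H9            CH3                 14.3
#>  2     2 Ad11      C6H4-CH3         O-CH2-C6H4-OH       17.2
#>  3     3 Ad1       C2H5             N-(CH3)2            17.6
#>  4     4 Ad2       C2H5             O-C2H5              18.1
#>  5     5 Ad4       C2H5             CH3                 21.6
#>  6     6 Ad6       CH2-CH(CH3)2     CH3                 22.1
#>  7     7 Ad3       C2H5             C2H5                25.7
#>  8     8 Ad5       CH(CH3)2         CH3                 25.7
#>  9     9 Ad8       cC6H11           CH3                 35.6
#> 10    10 Ad10      C*H(CH3)-C(CH3)3 CH3                 36.4
#> 11    11 Ad9       C*H(CH3)-C(CH3)3 CH3                 37.6
```

Rank 1 (the n-butyl sarin-type adduct, Ad7) has the lowest barrier — the
easiest OP to recover by fluoride treatment; the branched pinacolyl (soman)
adducts Ad9/Ad10 sit at the bottom, consistent with their notoriously poor
reactivation. Docking poses filter the same way:

```r
read_pose_table(fluorelease_example("hsa_cbdp_poses")) |>
  filter_productive_poses() |> nrow()
#> [1] 11            # of 13 albumin sites; Tyr138/Lys432 have no productive pose
signif(kd_from_dg(-7), 2)
#> [1] 7.4e-06       # -7 kcal/mol ≈ 7 µM dissociation constant
```

And the trajectory stage recovers a synthetic ion's planted behaviour:

```r
site <- make_active_site(n_waters_near = 3, n_waters_far = 2, seed = 42)
traj <- make_trajectory(tether_params(seed = 42), site)   # escape at 1300 ps
ser  <- distance_series(traj, trajectory_atom(traj, 198, "P"),
                        trajectory_atom(traj, 900, "F"))
residence_time(ser); interval_mean(ser, 0, 1000)
#> residence 1300 ps, mean 2.99 Å, hydration 3
```

A command-line front end (`inst/cli/fluorelease`, subcommands `place`,
`analyze`, `score`, `simulate`) wraps the same functions for shell pipelines.
See the vignette (`vignettes/fluoride-reactivation.Rmd`) for the model,
parameter choices and limitations.

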