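---
title: "Scoring fluoride-mediated organophosphate release: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring fluoride-mediated organophosphate release: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluorelease)
```

## The question the package answers

Organophosphates (OPs) phosphylate Ser198 of butyrylcholinesterase and
reactive tyrosines of serum albumin. Treating a plasma sample with potassium
fluoride can cleave these adducts, releasing an OP fluoroanhydride that is
detectable by mass spectrometry — but only for some adducts. `fluorelease`
provides a fast, structure-based estimate of which adducts will yield to the
fluoride, so that the (sample-hungry) assay is attempted where it can succeed.

Reactivation is modelled as an in-line nucleophilic attack: the fluoride
approaches the tetrahedral phosphorus opposite one of its substituents, a new
P–F bond forms and the P–Oγ bond to the protein breaks, through a
trigonal-bipyramidal intermediate. Two observable stages feed the assessment:

1. **Geometry** — can the fluoride get close enough? A conformation is
   *productive* when the attacking and attacked atoms are within 4 Å
   (`is_attack_feasible()`, `filter_productive_poses()`).
2. **Energetics** — how expensive is the P–Oγ → P–F trade? The barrier proxy
   ΔE_el below.

## The electrostatic barrier score

For one adduct, with partial charges (elementary charge units) on the
phosphorus (`q_P`), the attacked serine/tyrosine oxygen (`q_O`) and the
fluoride (`q_F`), the P–Oγ bond length and the P–F distance in the productive
complex:

$$E_{el}(i,j) = \frac{k\,q_i q_j}{\varepsilon\, r_{ij}}, \qquad
\Delta E_{el} = E_{el}(P{-}F) - E_{el}(P{-}O\gamma)$$

with $k = 332.0637$ kcal·Å·mol⁻¹·e⁻². Both pair energies are attractive
(negative); the P–Oγ pair sits at covalent distance (~1.69 Å) while the
fluoride is 2.7–4 Å away, so ΔE_el is positive — it is the electrostatic cost
of giving up the stronger contact for the weaker one, and lower values mean
easier reactivation. The model deliberately neglects van der Waals terms and
covalent-bond energetics: across a series of adducts the atom types at the
reaction center are identical, so the electrostatics is the discriminating
term.

### Why ε = 4

Coulomb interactions inside a protein are screened. The package treats the
screening as a single effective relative dielectric and calibrates it against
the packaged reference energies: with ε = 4 every one of the 22 reference
pair energies (11 adducts × 2 pairs) is reproduced from its printed charges
and distances to better than 0.03 kcal/mol, while ε = 1 overshoots fourfold.
ε = 4 also happens to be the textbook choice for a buried active site. It is
the default of every scoring function and can be overridden (`epsilon =`).

The residual ~0.02 kcal/mol discrepancies are fully explained by the charges
being printed to three decimals; the test suite asserts 0.05 kcal/mol.

### Sign and ranking conventions

ΔE_el is defined as `E_el(P–F) − E_el(P–O)`, the order that makes the
reference values positive. `rank_adducts()` sorts ascending — rank 1 is the
easiest to reactivate — and breaks ties lexicographically by adduct id, which
makes rankings deterministic and permutation-invariant (the mean-distance
table contains one genuine 3.52 Å tie). The complementary
molecular-mechanics criterion (`criterion = "mm_distance"`) ranks by the mean
P–F distance over a stable trajectory interval; under molecular mechanics the
charges are conformation-independent, so distance is the only discriminating
variable.

## Trajectory analysis

Trajectories enter as multi-model PDB files (`read_trajectory()`), the
portable text baseline; binary MD formats are deliberately out of scope. PDB
carries no time stamps, so frame times are supplied as a fixed spacing (`dt`)
or an explicit vector, and all frames are weighted equally.

* `distance_series()` — per-frame P–F distance.
* `interval_mean()` — arithmetic mean over `t0 ≤ t ≤ t1`. The interval is a
  parameter because the stable window is adduct-specific (most adducts are
  stable over the first nanosecond; one n-butyl adduct only stabilizes
  several ns into the run, and published accounts of its window disagree, so
  the package does not hard-code it).
* `residence_time()` — the time of the last frame of the *initial* contiguous
  run at or below the cutoff (default 4 Å), i.e. first-escape time; 0 if the
  first frame is already outside. Re-entries are real (they occur for the
  n-butyl adduct) but are reported separately by `residence_runs()` rather
  than credited, because "remains productive for X ns, then moves away"
  describes first escape.
* `hydration_count()` — number of distinct water molecules whose oxygen is
  within 3.5 Å of the ion. Waters are recognized by residue name
  (HOH/WAT/SOL, configurable: crystal structures and MD engines name them
  differently). The 3.5 Å first-shell cutoff for fluoride is a package
  choice — published hydration counts of this kind were read off structure
  figures without a stated criterion — and is configurable.

## Probe placement

`place_fluoride()` puts the probe at 2.0 Å from the phosphorus, collinear
with the P=O bond and **anti** to the phosphoryl oxygen (beyond P on the O→P
ray). "In line with P=O" admits two orientations; the anti one is the only
one that puts the ion in the catalytic gorge on the attack trajectory rather
than inside the P=O bond, and it is the geometry under which the placed probe
can subsequently be stabilized by the protonated His438. The placement is a
pure vector construction, so it is exactly rigid-motion equivariant and
satisfies |F−P| = 2 to machine precision; the tests assert both on 1000
random geometries.

`detect_hbond()` uses donor–acceptor ≤ 3.5 Å and donor–H–acceptor ≥ 120° —
common literature defaults, stated nowhere in the source analyses —
and both are arguments.

## Thermodynamics

`kd_from_dg()` converts a docking free-energy estimate to a dissociation
constant, $K_d = \exp(\Delta G / RT)$, 1 M standard state,
$R = 1.98720425\times10^{-3}$ kcal/(mol·K), default T = 298.15 K ("room
temperature" is not stated more precisely in the underlying assays; 293–300 K
all give ~7 µM for −7 kcal/mol to one significant figure). The exact inverse
`dg_from_kd()` exists and the pair round-trips to 1e−10.

## The synthetic generators

Nothing in the trajectory stage can be validated against real MD without
running MD, so the package ships generators with known ground truth:

* `make_active_site()` — a toy fragment with the planted geometry of a
  phosphylated serine: P–Oγ at 1.69 Å (the typical covalent bond length in
  the reference series), phosphoryl O at 1.48 Å, tetrahedral substituent
  stubs, a protonated histidine that can donate an ideal H-bond to the probe
  (`plant_hbond`), the fluoride anti to P=O, and waters planted inside
  (2.4–3.2 Å) and outside (6–8 Å) the first shell.
* `make_trajectory()` — the ion's distance from P follows a discrete
  mean-reverting AR(1) process (autocorrelation φ = 0.6) around
  `tether_mean` until a programmed `escape_time`, then drifts outward
  linearly; the P→ion direction random-walks on the sphere so frames are not
  collinear. First-shell waters travel rigidly with the ion, emulating a
  persistent hydration shell. This is a statistical stand-in for the observed
  phenomenology (an ion that stays productive for ~1–8 ns and then leaves),
  not a physical model.
* `make_adduct_records()` — charge/distance records drawn uniformly from the
  ranges spanned by the reference series (q_P ∈ (2.2, 2.4) e, q_O ∈ (−0.65,
  −0.54) e, q_F ∈ (−0.76, −0.70) e, d(P–O) ∈ (1.68, 1.70) Å, d(P–F) ∈
  (2.7, 4.0) Å). Within these ranges the P–O attraction always dominates, so
  every synthetic record scores a positive barrier.

Defaults of `tether_params()` describe the reference test condition, chosen
once to mirror the easiest-reactivated adduct's published trace: tether at
3.0 Å (mid-range of the observed mean P–F distances), spread 0.25 Å, escape
at 1300 ps, drift 1.5 Å/ps, 2000 frames at 1 ps. With these values the
tethered ion crosses the 4 Å cutoff spuriously only ~4% of the time over the
pre-escape window, so first-escape recovery within one frame is expected in
≥95% of seeds — which is what the property test asserts over 50 replicates.
The interval-mean recovery test uses the AR(1)-corrected standard error of
the mean, $SE = \sigma/\sqrt{n(1-\varphi)/(1+\varphi)}$; the naive iid SE
would understate the sampling noise of an autocorrelated series threefold.

All generators take a mandatory seed, are bit-reproducible, and restore the
caller's RNG state.

What passing these tests shows: the *analysis operations* are correct on
series with known structure. What it does not show: anything about force
fields, water models, or real protein dynamics — the generator has no
physics, no periodic boundary conditions, and static protein atoms.

## Structural classifier

`classify_adduct()` reproduces the structural grouping that organizes the
reactivation trends, over the controlled substituent vocabulary of the
studied series (not general SMILES — the grouping is defined only for these
structures): group I (R2 carries N/O: easiest), group II (R1 = CH(X)–X′,
branched: hardest, difficulty grows with branching), group III (R1 =
O–CH2–Y, R2 = CH3), a transitional R2 = C2H5 pattern, and the special
bicyclic aromatic case, which is matched first since its R2 also contains
oxygen. Unknown tokens raise an error rather than guessing.

## Numerical and degenerate-input choices

* Coincident P and phosphoryl O (placement), zero-length H-bond arms,
  non-positive distances in Coulomb terms, empty structures, empty averaging
  intervals: all hard errors, never NaN propagation.
* Charge-table validation enforces the physical sign pattern (q_P > 0,
  q_O < 0, q_F < 0) and a covalent-range P–O distance; `validate = FALSE`
  overrides for exploratory use (e.g. the swap-antisymmetry test).
* The pose-table sentinel `"not found"` (case-insensitive, or blank) maps to
  `NA` distance; filtering drops `NA` (a site with no productive pose cannot
  be attacked), and the 4 Å boundary is inclusive ("does not exceed").
* PDB round-trips are exact to the format's three coordinate decimals; tests
  assert 1e−3 Å.

## Problem sizes

The test suite runs ~50 synthetic 2000-frame trajectories plus 1000-point
geometry property sweeps, and completes in well under a minute on one core;
these sizes give the property tests their statistical resolution (3-SE bands,
≥95% recovery rates) while staying desk-scale.

## Known limitations

* ΔE_el is a barrier *proxy*: no intermediate state, no van der Waals terms,
  no entropic contribution, one effective dielectric for every adduct.
* The AM1 charges are inputs, not computed here; scoring new adducts requires
  externally derived charges at a consistent level of theory.
* Aged (dealkylated) adducts carry a P(O)O⁻ group that resists fluoride
  attack entirely; the score does not model aging, spontaneous reactivation,
  or adduct-formation efficiency, all of which shift real-world yields.
* Albumin-site barrier values ship as reference data only — their underlying
  charges are not published, so they cannot be recomputed — and the HSA/BChE
  comparison rests on them.
* Trajectory analysis assumes pre-imaged coordinates (no periodic-boundary
  handling) and fixed-step frames.
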