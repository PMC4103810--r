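---
title: "Quantifying PIP-Box peptide binding to PCNA by fluorescence polarization"
author: "pipbind authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying PIP-Box peptide binding to PCNA by fluorescence polarization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pipbind)
```

## The assay and its models

PCNA, the homotrimeric sliding clamp of DNA replication and repair, recruits
partner proteins through an eight-residue docking motif, the PIP Box
(Q-x-x-φ-x-x-Ω-Ω, with φ hydrophobic and Ω aromatic). A fluorescence
polarization (FP) assay quantifies these interactions: a fluorescein-labeled
PIP-Box peptide (the *probe*, L\*) tumbles quickly when free and slowly when
bound to PCNA (R), so its anisotropy $r$ rises from $r_f$ (free) to $r_b$
(bound). Unlabeled peptides or small molecules (the *competitor*, I) displace
the probe and lower $r$.

`pipbind` implements the full analysis chain for such data:

1. **Calibration and conversion.** With quantum-yield ratio
   $Q = q_b/q_f$ (the probe is quenched on binding when $Q < 1$),
   $$f_b = \frac{r - r_f}{(r - r_f) + Q\,(r_b - r)}$$
   converts anisotropy to the fraction of probe bound
   (`anisotropy_to_fraction_bound()`); its exact inverse drives the
   simulators. $f_b$ is deliberately not clamped to $[0,1]$: clamping noisy
   values would bias downstream least squares. Defaults mirror a
   FITC-PIP-Box/PCNA system: $r_f = 0.0470$, $r_b = 0.1587$, $Q = 0.70$.

2. **Direct titration.** `fit_direct()` fits replicate-level anisotropy
   against total protein with the Hill model
   $r = r_f + (r_b - r_f)\,P^n/(K_d^n + P^n)$.

3. **Competition.** `fit_ic50()` fits the four-parameter logistic
   $f_b = \mathrm{bottom} + (\mathrm{top}-\mathrm{bottom})/(1 + (I/IC_{50})^{-n})$
   with a *signed* Hill slope, so displacement curves report $n < 0$.
   `fit_competition_complete()` and `fit_competition_incomplete()` replace
   the empirical logistic with exact equilibrium models (below), estimating
   the competitor constant $K_{d2}$ (and, for incomplete displacement, the
   ternary constant $K_{d3}$) with the probe constant $K_{d1}$ held fixed.

4. **Inhibition constants.** `ki_classic()` applies
   $K_i = IC_{50}/(1 + [L]/K_d)$; `ki_modified()` applies the FP-specific
   correction
   $K_i = [I]_{50} / ([L]_{50}/K_d + [P]_0/K_d + 1)$
   with $[L]_{50} = L_{ST}(1 - f_{b0}/2)$ the free probe at 50% inhibition
   and $[P]_0 = R_T - f_{b0} L_{ST}$ the free protein at 0% inhibition
   (the Nikolovska-Coleska reading of those symbols, which the assay
   literature leaves implicit).

5. **Assay QC.** `z_prime()` computes
   $Z' = 1 - 3(\sigma_+ + \sigma_-)/|\mu_+ - \mu_-|$ from control panels;
   `grubbs_filter()` screens replicates (two-sided Grubbs test).

## Exact equilibrium solvers

The logistic IC50 is descriptive; mechanistic constants come from exact mass
balance. Three solvers share the species vocabulary R, L\*, I, RL\*, RI,
RIL\*:

* **Direct** (`solve_direct()`): one-site binding is a quadratic in the
  complex; the physical root is evaluated in a cancellation-free form.
* **Complete competition** (`solve_competition_complete()`): two ligands, one
  site. Free protein is the unique root in $(0, R_T]$ of
  $[R]^3 + d[R]^2 + e[R] + f = 0$ with
  $d = K_{d1}+K_{d2}+L_{ST}+L_T-R_T$,
  $e = K_{d1}K_{d2}+K_{d2}(L_{ST}-R_T)+K_{d1}(L_T-R_T)$,
  $f = -K_{d1}K_{d2}R_T$, and the probe occupancy is $[R]/([R]+K_{d1})$.
  The trigonometric closed form is fast enough to sit inside a fit loop, but
  it loses the smallest root to cancellation when the roots are widely
  separated; the solver therefore polishes with Newton steps and falls back
  to bounded bisection whenever the residual exceeds what the term
  magnitudes can support. Against an independent bisection oracle
  (`oracle_solve()`) the worst relative deviation over $10^4$ random systems
  spanning $10^{-12}$–$10^{-3}$ M is below $10^{-13}$.
* **Incomplete competition** (`solve_competition_incomplete()`): when the
  probe is not fully displaced at saturating competitor, the
  competitor-bound protein is modeled as retaining a weaker probe site
  (four-state model): R + L\* ⇌ RL\* ($K_{d1}$), R + I ⇌ RI ($K_{d2}$),
  RI + L\* ⇌ RIL\* ($K_{d3}$). Given free protein, the inner (I, L\*)
  balances reduce to a closed-form quadratic, leaving a single bounded
  bisection; mass balances close to relative $10^{-9}$. The ternary complex
  is assumed to carry the same anisotropy and quantum yield as the binary
  complex — the source assays cannot distinguish them — so observed
  occupancy is $([RL^*]+[RIL^*])/L_{ST}$, and its high-competitor plateau
  equals the occupancy of a direct titration at $K_{d3}$.

**Model selection.** A competitor that leaves the converted fraction bound
above a threshold (default 0.05, strict inequality; configurable) at the
highest tested concentration is routed to the incomplete model
(`select_competition_model()`). The underlying decision rule in the source
assays was "$f_b \neq 0$ at the maximum"; a strictly positive threshold is
needed for noisy data, and 0.05 is roughly three standard errors of a
4-replicate point mean at the default noise level.

## A quenching subtlety: what the direct fit estimates

Because the Hill fit runs on raw anisotropy while the physical occupancy maps
to anisotropy through the $Q$-weighted conversion, the two parameterizations
describe the *same* curve family with shifted midpoints: an occupancy-space
constant $K_d$ appears in the anisotropy fit as $K_d\,Q^{-1/n}$
(`apparent_kd()`). With $Q = 0.70$ this is a 43% shift at $n = 1$ — invisible
in any single fit, and inherent to fitting unconverted anisotropy (the common
workflow this package reproduces). Parameter-recovery claims in the test
suite are therefore stated against the apparent constant. Competition fits
are immune: they convert to fraction bound first.

Relatedly, the classic Cheng-Prusoff conversion is only trustworthy in its
textbook domain (receptor far below $K_{d1}$, competitor $K_{d2}$ above the
receptor concentration). At the emulated working conditions — 1 µM protein
with a 760 nM probe constant — receptor depletion alone inflates classic
$K_i$ estimates by a factor ≈ 2.2, which is exactly why the modified form is
the one to report.

## Replicate QC at N = 4

The two-sided Grubbs test compares $G = \max_i |x_i - \bar x| / s$ with the
critical value from the $t$ quantile at $\alpha/(2N)$ on $N-2$ degrees of
freedom (1.481 at $N = 4$, $\alpha = 0.05$). Two properties of $N = 4$ shape
the defaults:

* A single arbitrarily large outlier gives $G \to (N-1)/\sqrt{N} = 1.5$,
  barely above the critical value, so detection saturates slowly: gross
  artifacts are caught, mild ones often are not.
* Iterative removal is unstable at such small $N$; the filter removes at
  most one value per pass and runs a single pass by default, applied
  independently per concentration point (`qc_series()`).

## The synthetic-data generators

The source assays' raw data were never deposited, so validation runs on
simulated data with known ground truth (`assay_ground_truth()`,
`simulate_titration()`, `simulate_competition()`). The generator conditions
are fixed to the emulated assay: 50 nM probe, 1 µM protein monomer,
$K_{d1} = 760$ nM, calibration window 0.0470–0.1587 with $Q = 0.70$, $N = 4$
replicates, Gaussian anisotropy noise of SD 0.003 (a few percent of the
window). Concentration grids (`default_assay_grid()`) place 12 log-spaced
points between 10 nM and 100 µM — the published plotting range, bracketing
the ~1 µM midpoints by two decades on each side. Injected outliers
(optional) have magnitude 0.05, a gross-artifact scale chosen so that the
$N = 4$ Grubbs screen can plausibly catch them (see above). All generators
thread an explicit seed and restore the caller's RNG state.

Under these conditions the estimators are efficient (the empirical spread of
$\ln \hat K_d$ matches the Fisher bound), with $SE(\ln \hat K_d) \approx
0.054$ for titrations and $SE(\ln \hat K_{d2}) \approx 0.089$ for complete
competitions; recovery rates quoted by the test suite (200 simulated
datasets per claim) follow directly. What the simulations do *not* emulate:
plate-position and drift effects, non-Gaussian heavy tails beyond the
injected outliers, probe aggregation at high competitor (reported for some
peptides above 50 µM), and any trimer-level cooperativity beyond the
phenomenological Hill slope — passing recovery tests therefore validate the
estimator chain, not those aspects of real plates.

Structural fixtures follow the same philosophy: `make_toy_trajectory()`
builds a gently helical Cα chain with a prescribed per-residue fluctuation
profile (per-axis SD = profile/√3, then a random rigid motion per frame, so
recovering the profile genuinely exercises superposition), and
`make_toy_complex()` builds a bead peptide with icosahedrally caged "buried"
residues; its 12 Å bead spacing exceeds the 6.2 Å carbon–carbon occlusion
range, making per-residue burial ground truth exact by construction.

## Trajectory analytics

* **Superposition** (`superpose()`): Kabsch SVD with reflection correction;
  degenerate (collinear) atom sets are rejected. Verified against a
  quaternion-method oracle to $10^{-9}$.
* **RMSD / RMSF** (`rmsd_series()`, `rmsf()`): per-frame RMSD against a
  reference frame and per-residue fluctuation about the mean structure,
  both after alignment to frame 1 — matching the usual "align to the first
  frame" post-processing of simulation trajectories. Alignment absorbs six
  rigid degrees of freedom, shrinking recovered fluctuations by roughly
  $\sqrt{1 - 6/3N}$; with dozens of residues this stays inside the ~10%
  recovery tolerance the tests use (60 residues × 500 frames).
* **Snapshot PCA** (`pca_snapshots()`): eigendecomposition of the 3N × 3N
  covariance of aligned Cartesian Cα coordinates (frames as observations),
  not pairwise-distance PCA; residues dominated by terminal motions can be
  dropped via `drop_residues`. Eigenvector orthonormality and the trace
  identity hold to $10^{-9}$.
* **SASA** (`sasa()`): Shrake–Rupley with Bondi-type radii and a
  deterministic golden-spiral point lattice, default 960 points/atom
  (per-atom quantization ≈ 0.13 Å², so multi-atom residues converge below
  1% on point doubling; single-atom "residues" sit at the quantization
  limit). The original analyses used an external web service for burial
  analysis; the algorithm here is a from-scratch implementation of the
  standard method, cross-checked against an independent engine to within
  2%. `delta_sasa()` reports per-ligand-residue burial
  $SASA_\mathrm{free} - SASA_\mathrm{complex}$.
* **Anchor/tether classification** (`classify_anchor()`): anchors bury
  > 70 Å² (strict inequality at the boundary); non-anchors with at least
  one polar-contact evidence entry are tethers. Only hydrogen-bond evidence
  is generated automatically (`hbond_presence()`: donor–acceptor ≤ 3.5 Å,
  D–H–A ≥ 120° when the hydrogen is resolved, inclusive bounds); the
  "electrostatic interaction" notion of tethering is never quantified in
  the source analyses, so salt-bridge evidence must be supplied by the user
  (a ≤ 4 Å charged-group rule is a reasonable convention).

## Motif scanning

`compile_pattern()` builds position-wise allowed-residue sets. The `strict`
preset is the canonical Q-x-x-φ-x-x-Ω-Ω with φ = {L,I,M,V,F} (A and C
excluded by common convention) and Ω = {F,Y,W} (H excluded); `relaxed` drops
the position-7 aromatic, accommodating reported partners with non-aromatic
residues there. Both classes are configurable rather than hard-coded because
published screens visibly disagree on how loosely to read "hydrophobic" and
"aromatic" — one reported partner motif (phospholipase Cγ's, ending in E)
matches no aromatic-terminal pattern in either orientation at all.
`scan_sequence()` reports every overlapping window, forward and reverse (a
reverse hit is a window whose reversed sequence matches the forward
pattern — the reverse-PIP-Box convention established by Akt); coordinates
are 0-based half-open in the API, 1-based inclusive in reports. Unknown
letters are tolerated but never match, including at wildcard positions.

## Numerical choices

Positive parameters ($K_d$, $IC_{50}$, $K_{d2}$, $K_{d3}$) are estimated in
log space with Levenberg–Marquardt (via minpack.lm) on replicate-level
residuals with uniform weights; standard errors are delta-method transforms
of the log-space covariance. The two-parameter four-state fit uses three
starts (base start plus seeded jitter) to guard against local minima, and
warns when the plateau is unsampled ($K_{d3}$ weakly identified) or
absent ($K_{d3}$ unbounded above). Solver tolerances are relative
($10^{-9}$ solve, $10^{-12}$ oracle); totals below $10^{-15}$ M are treated
as zero. Fits are flagged rather than errored when the optimizer fails,
when $K_d$/IC50 leaves the tested range, or when a competition curve runs
the wrong way.

## Limitations

* PCNA trimerization is not modeled; the Hill slope is phenomenological.
* The four-state topology is the standard incomplete-inhibition reading;
  FP data cannot distinguish ternary-complex photophysics from the
  equal-signal assumption made here.
* Direct-titration constants from raw anisotropy are apparent constants
  (see the quenching section); reporting occupancy-space constants would
  require trusting the calibration inside the fit.
* The motif scanner scores presence, not affinity.
* SASA radii cover common protein elements only; unknown elements error
  rather than guess.
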