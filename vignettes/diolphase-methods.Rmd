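---
title: "Methods: quantifying alkanediol effects on protein phase separation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying alkanediol effects on protein phase separation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diolphase)
```

# Scope

Alkanediols such as 1,6-hexanediol are the standard tool for dissolving
biomolecular condensates, yet their isomers differ widely in potency.
`diolphase` implements the quantitative analyses used to characterise that
difference across four kinds of readout: single-chain simulation
observables, NMR chemical-shift perturbation and relaxation, bulk and
imaging phase-separation assays, and stability/partition measurements that
are joined into a cross-assay potency ledger. A synthetic-data module
generates every input with known ground truth, so each analysis can be
validated end to end without external data.

This vignette records the models behind each module, the tunable
parameters and their defaults, the numerical choices, and what the
synthetic generators do and do not emulate.

# Trajectory observables

## The contact rule

A contact between two residues (or between a residue and a cosolvent
molecule) is formed in a frame when *any* heavy atom of one is within
4.5 Å of any heavy atom of the other. The comparison is inclusive
(`<= 4.5`); the boundary case is tested explicitly. Distances use the
minimum-image convention in an orthorhombic periodic box; the
`minimum_image_distance()` primitive additionally supports triclinic boxes
through a 27-image search, but all fixtures and the contact kernels use
orthorhombic boxes, which is sufficient for the observables (a box shape
is an engine detail, not an observable).

Contact frequencies are normalised as the fraction of frames in which the
binary per-frame contact event occurs, averaged over frames and then over
replicas. This is the simplest normalisation consistent with a heat map in
[0, 1]; nothing in the analyses depends on a different choice.
Nearest-neighbour pairs (|i - j| = 1) are included and only the diagonal
is masked; a separation-binned view (`contacts_by_separation()`, default
bins 1–10, 11–25, 26–50, 51–100, >100) isolates the long-range contacts
that report chain compaction.

The kernel is a periodic cell-list neighbour search written in C++ (cells
at least one cutoff wide, 27-neighbourhood sweep, all-pairs fallback when
the box is under three cells per axis). Its only correctness claim is
exact agreement with an all-pairs brute force, which the test suite
asserts on random systems and the acceptance suite asserts at the scale of
100 frames of a 50-residue chain with 20 cosolvent molecules.

`cosolvent_contacts()` counts contacting cosolvent *molecules* per residue
per frame (not atom pairs); molecule counting is the interpretation chosen
for the residue-type-binned profiles, and the atomistic map
(`atomistic_contact_map()`) provides the per-atom-pair view with row and
column marginals.

## Chain dimension observables

`intrachain_distances()` reports the mean inter-residue distance matrix
and the separation profile r(s), by default from the backbone site of each
residue (residue centre of mass is available; the choice of site is a
free parameter because real topologies do not dictate one).
`radius_of_gyration()` is mass-weighted by default. With several replicas,
profiles carry the standard error of the mean across replicas
(`replica_sem()`); with a single replica the SEM is reported as `NA`,
never as zero.

## Radial distribution functions

`rdf_sidechain_com()` uses as reference sites the per-instance heavy-atom
centre of mass of the sidechains of one residue type, and as targets all
cosolvent heavy atoms:

$$g(r) = \frac{\langle n(r) \rangle}{4\pi r_{mid}^2\, dr\, \rho_{bulk}},
\qquad \rho_{bulk} = N_{target}/V_{box}.$$

Defaults are dr = 0.1 Å and r_max = 12 Å, with r_max validated against
half the smallest box edge. Bin midpoints are used for the shell surface;
the first bin absorbs exact-zero distances so that binned counts conserve
the total number of pair distances within r_max — an invariant the tests
assert exactly.

`solution_density()` converts total mass over box volume with
1 Da/Å³ = 1.66053906660 g/cm³.

# Synthetic trajectory generators

`gen_chain_ensemble()` builds pseudo-atom chains: one backbone atom per
residue on a random walk with *exactly* `bond_length` (default 3.8 Å)
between consecutive backbone atoms, plus `sidechain_atoms_per_residue`
pseudo-atoms offset by at most one bond length. At
`confinement_strength = 0` the frames are i.i.d. freely jointed chains, so
closed forms are available for validation:

$$\langle R_{ij}^2 \rangle = |i-j|\,b^2, \qquad
  \langle R_g^2 \rangle = \frac{b^2 (N^2-1)}{6N}.$$

Positive confinement blends each step direction with the direction toward
the running centroid (renormalised to preserve the bond length), producing
compact, contact-rich ensembles whose contacts respond to the cutoff and
separation binning the way a self-interacting disordered chain's do.
Residue-type labels are drawn from an S/G/Q/Y-rich low-complexity
composition so that residue-type binning is exercised with realistic
proportions; there is no chemistry behind the labels, which is all the
observables require.

`gen_cosolvent_box()` places rigid 8-heavy-atom molecules (six carbons,
two terminal oxygens, a hexanediol-like zigzag) uniformly in the box, with
independent placements per frame — an i.i.d. stand-in for fast-diffusing
small molecules. With `adsorption_bias` > 0, a fraction
`bias / (1 + bias)` of the molecules is re-placed within
`adsorption_shell` (default 6 Å) of a randomly chosen protein heavy atom,
with the radial offset drawn uniformly in distance (which concentrates
density near the surface). The fraction mapping is a convenience
parameterisation: it is 0 at zero bias, saturates below 1, and is strictly
monotone, which is what the qualitative surface-enrichment contrast
between strongly and weakly adsorbing diols needs. Monotonicity of both
mean contacts and the first RDF shell in the bias is asserted across seeds
with a sign test.

What these generators do *not* emulate: excluded volume, force-field
energetics, solvent, temporal correlation between frames, or real diol
geometry. Passing tests therefore validate the *analysis* code — contact
detection, normalisation, binning, RDF normalisation, SEM handling — not
any simulation physics.

# NMR analysis

Indirect referencing uses the standard frequency-ratio rule
$V_X = V_{1H} \cdot \Xi / 100$ with $\Xi(^{15}N) = 10.132912$ and
$\Xi(^{13}C) = 25.144953$.

Chemical-shift perturbations are per-nucleus signed differences
(condition minus reference) with intensity ratios carried alongside;
residues missing from either list propagate as missing, never imputed or
zero-filled. A combined Euclidean CSP with the customary 0.2 nitrogen
scaling is available (`csp_combined()`) but is not the default, because
the per-nucleus representation is the primary one. Residue-type binning
uses magnitudes by default (a signed option exists) since the binned
question is how strongly each residue chemistry is perturbed.

`cross_condition_slope()` fits one condition's per-residue perturbations
against a reference condition's. The default is ordinary least squares
*with* intercept; a through-origin fit is available. When perturbation
patterns are shared and scaled — the structure the synthetic generator
reproduces as $\Delta\delta_i = \lambda_c p_i + \varepsilon$ — the slope
estimates the relative potency $\lambda$, and both fit forms agree; the
with-intercept default is the safer choice on real data where a small
offset may exist.

Relaxation rates come from a Levenberg–Marquardt fit of
$I(t) = I_0 e^{-Rt}$ initialised from the log-linear fit, with the
uncertainty from the fit covariance. Non-decaying series are fitted and
flagged rather than clamped; exactly constant series return R = 0 with the
flag set. Recovery within 2% at 1% intensity noise is asserted on a
seven-point CPMG delay ladder spanning 16.5–264.4 ms.

The synthetic CSP module ties potencies to ground-truth saturation
concentrations through an affine map with *positive* slope: a more potent
diol dissolves condensates more, leaving more protein in the dilute phase.
The recovered slope-versus-Csat correlation must therefore be positive,
which the acceptance suite checks.

# Phase-separation assays

Saturation concentration uses Beer–Lambert arithmetic on dilute-phase
A280. Protein/RNA mixtures are deconvolved by solving the 2×2 extinction
system at 260/280 nm; extinction coefficients are required inputs (never
guessed), negative solutions are flagged as diagnostics rather than
clipped, and the forward/inverse round trip is asserted to 1e-10 on random
non-singular systems. Turbidity series subtract a matched no-trigger
control elementwise and aggregate replicates as n/mean/sd, preserving
negative corrected values.

Droplet images are segmented by thresholding: Otsu's criterion by default
(on the 256-level histogram of the min-max-normalised image, mapped back
to grey levels), or a fixed threshold for exact control. Constant images
make Otsu undefined and raise an error suggesting the fixed mode. Droplet
counting labels above-threshold pixels with 8-connectivity and discards
components under `min_area` (default 5 px) — ImageJ-like particle-analysis
defaults. The synthetic image generator records the exact bright-pixel
fraction and the number of 8-connected components of the ground-truth
mask, so overlapping disks count as one merged droplet in both truth and
measurement. Segmentation recovery within one percentage point of area
and exact counts is asserted at a signal-to-noise ratio of 10.

# Stability, partitioning and the potency ledger

Melting curves are fitted with the two-state van't Hoff model with linear
folded/unfolded baselines (in Celsius),

$$\theta(T) = \frac{\theta_N(T) + \theta_U(T)K(T)}{1+K(T)}, \qquad
K(T) = \exp\!\left[-\frac{\Delta H_{vH}}{R}\left(\frac{1}{T} -
\frac{1}{T_m}\right)\right],$$

with temperatures in Kelvin internally and Celsius in reports. The fit is
multi-start: the transition guess comes from the steepest smoothed slope,
with additional starts ±5 °C and two enthalpy starts; baselines start from
straight-line fits of the first and last eighth of the curve. A fit only
counts as converged when Tm lies inside the scanned range, the enthalpy is
positive, and the baseline separation at Tm exceeds three residual
standard deviations — flat curves are flagged, never given a fabricated
Tm. Because the extraction method on real data is a free choice, a
model-free cross-check (the temperature where the min-max-normalised
smoothed signal crosses one half) is always reported, and a disagreement
beyond 1 °C raises a flag in the result.

logP is quantified exactly as in the experiment it models: NMR integrals
proportional to concentration × proton count, normalised against an
internal reference standard of known concentration, one integral per
phase, then $\log_{10}(c_{oct}/c_{w})$. The generator enforces the mass
balance $c_w = n_{tot}/(V_w + P V_o)$, $c_o = P c_w$, exact at zero noise.
Which resonance is integrated and how many protons it carries are explicit
inputs, because no universal convention exists.

The potency ledger outer-joins per-compound Csat, CSP slope, logP and
delta-Tm, computing each pairwise Pearson correlation over paired complete
observations only (n >= 3, otherwise flagged unavailable). Outlier
exclusion is always explicit by compound label — mirroring how outlying
diols are named and removed in this field — and both the full and the
excluded correlations are reported side by side.

# Problem sizes and determinism

Every generator is a pure function of its spec plus a seed (verified
bit-identical under repetition). The validation suite uses sizes chosen to
make Monte-Carlo tolerances tight while keeping a laptop-scale run: the
freely-jointed-chain closed forms at N = 100 and 10,000 frames (tolerance
3 frame-level standard errors at every separation), the ideal-gas RDF at
500 atoms × 200 frames, contact-oracle equivalence at 50 residues × 100
frames, adsorption monotonicity over 10 seeds with a sign test, Tm-shift
recovery over 50 noisy melts, and relaxation recovery over 100 noisy
ladders. Statistical recoveries are asserted on the mean and RMS error
across repeats, which is what "recovered within x" means for a noisy
estimator; single-draw assertions at multi-sigma tolerances would fail a
fixed fraction of seeds by construction.

# Known limitations

* The chain generator has no excluded volume, so contact maps from
  confined fixtures are denser than real single-chain ensembles; only
  relative and structural statements (monotonicity, binning, oracle
  equality, closed forms) are validated against it.
* Cosolvent placements are independent across frames; time-correlation
  quantities (residence times, autocorrelations) are out of scope.
* The contact kernels require orthorhombic boxes; triclinic support exists
  only in the distance primitive.
* XTC trajectories are not read; PDB+XYZ (native) and DCD (via bio3d) are.
* Otsu thresholding assumes a bimodal intensity histogram; images without
  droplets should use the fixed-threshold mode.
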