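# diolphase

Quantitative analysis of how alkanediol cosolvents (1,6-hexanediol and its
isomers) disrupt the liquid–liquid phase separation (LLPS) of intrinsically
disordered proteins such as the FUS low-complexity domain.

Alkanediols are the field's standard condensate-dissolving agents, but
their isomers differ strongly in potency, and explaining that difference
requires joining evidence across very different experiments. `diolphase`
implements the full analysis chain:

* **Trajectory observables** for protein + cosolvent simulations:
  residue–residue contact maps under the heavy-atom rule (a contact is
  formed when any heavy atom of one residue is within 4.5 Å of any heavy
  atom of the other, minimum-image convention, cell-list search in C++),
  intrachain distances ⟨R_ij⟩ and their separation profile, radius of
  gyration, per-residue cosolvent contact profiles binned by residue type,
  atomistic sidechain–diol contact maps with marginals, radial
  distribution functions from sidechain centres of mass,
  g(r) = ⟨n(r)⟩ / (4πr²·dr·ρ_bulk), solution density, and replica-level
  standard errors.
* **NMR analysis**: indirect referencing (V_X = V_1H·Ξ/100 with
  Ξ(¹⁵N) = 10.132912, Ξ(¹³C) = 25.144953), per-residue chemical shift
  perturbations Δδ and intensity ratios, residue-type binning,
  cross-condition potency slopes with Pearson correlations, exponential
  relaxation-rate fits I(t) = I₀e^(−Rt), and heteronuclear NOE ratios.
* **Phase-separation assays**: saturation concentration (Csat) from
  dilute-phase A280 (Beer–Lambert), two-wavelength protein/RNA
  deconvolution, no-trigger-control-corrected turbidity, droplet area
  fraction and 8-connected droplet counts from fluorescence images (Otsu
  or fixed threshold), and linear Csat-versus-diol trends.
* **Stability and partitioning**: two-state van't Hoff melting fits
  θ(T) = [θ_N(T) + θ_U(T)K(T)]/[1 + K(T)] with
  K(T) = exp[−(ΔH_vH/R)(1/T − 1/T_m)] for Tm and ΔTm, octanol/water logP
  from proton-normalised NMR integrals, and a cross-assay potency ledger
  with Pearson correlations and explicit, by-label outlier exclusion.

A synthetic-data module generates every input with known ground truth —
freely jointed / confined pseudo-atom chain ensembles, diffusing
diol-like cosolvent with tunable surface adsorption, shared-pattern CSP
peak lists scaled by per-compound potencies, two-state thermal melts,
octanol/water partition equilibria, and droplet images with exact area
fractions — so the whole pipeline is testable end to end.

## Worked example

Simulate a 60-residue disordered chain, add 50 diol-like molecules with
and without surface adsorption, and measure what the diol does:

```r
library(diolphase)

chain <- gen_chain_ensemble(chain_spec(n_residues = 60,
                                       confinement_strength = 0.3,
                                       n_frames = 50, seed = 7,
                                       box_edge = 80))
radius_of_gyration(chain)$mean
#> [1] 7.17  # Angstrom

uniform   <- gen_cosolvent_box(cosolvent_spec(50, box_edge = 80,
                                              adsorption_bias = 0, seed = 8),
                               chain)
adsorbing <- gen_cosolvent_box(cosolvent_spec(50, box_edge = 80,
                                              adsorption_bias = 1, seed = 8),
                               chain)
mean(cosolvent_contacts(uniform)$per_residue$contacts)
#> [1] 0.114   # molecules touching a residue per frame, uniform placement
mean(cosolvent_contacts(adsorbing)$per_residue$contacts)
#> [1] 8.018   # ~70x enrichment when the diol adsorbs to the chain

cm <- residue_contact_map(chain)          # 4.5 A heavy-atom rule
contacts_by_separation(cm)
#>    lo  hi mean_contact n_pairs empty
#> 1   1  10        0.500     545 FALSE
#> 2  11  25        0.269     630 FALSE
#> 3  26  50        0.207     550 FALSE
#> 4  51 100        0.099      45 FALSE
#> 5 101 Inf           NA       0  TRUE
```

Contact frequency decays with sequence separation, and the
adsorption-biased cosolvent shows the surface enrichment that separates
potent from weak diols. On the NMR side, shared-pattern perturbations
recover per-compound potencies as cross-condition slopes, which join the
assay readouts in the potency ledger:

```r
set.seed(11)
pat <- rnorm(60, 0, 0.2)          # per-residue sensitivity pattern
ds  <- gen_csp_dataset(csp_pattern(pat, c(hd16 = 1, hd25 = 0.6, bd14 = 0.3),
                                   noise_sd = 0.01),
                       sequence_of(chain), seed = 9)
tabs   <- lapply(ds$conditions, function(cd) compute_csp(ds$reference, cd))
slopes <- sapply(names(tabs), function(nm)
  cross_condition_slope(tabs[[nm]], tabs$hd16)$slope)
round(slopes, 3)
#>  hd16  hd25  bd14
#> 1.000 0.600 0.297

assemble_potency_ledger(csat = setNames(ds$truth$csat, ds$truth$condition),
                        slope = slopes)
#> potency ledger: 3 compounds
#>  compound csat csp_slope
#>      bd14  160 0.2971868
#>      hd16  300 1.0000000
#>      hd25  220 0.6002942
#>
#> pairwise Pearson correlations (paired complete observations):
#>  var_x     var_y       pcc n pcc_excluded n_excluded
#>   csat csp_slope 0.9999952 3    0.9999952          3
```

The recovered slopes match the constructed potencies, and the
slope-versus-Csat correlation is positive: the more potent the diol, the
more protein remains in the dilute phase.

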