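# graftsite

Transfer of stereoselectivity determinants between homologous enzymes
("homologous grafting"), implemented as an R package for structural
bioinformatics workflows.

## The problem

Many enzymes lack a natural enantiocomplementary counterpart: no known
homolog produces the mirror-image product. One rational-design entry
point is to learn from a pair of homologous, mutually
enantiocomplementary enzymes *which* active-site positions set their
stereopreference, and then graft those positions onto the target
enzyme. `graftsite` implements the computational side of that strategy
for Schiff-base (class I) aldolases and structurally similar systems:

1. **Active-site geometry profiling.** Over a conformational ensemble
   (e.g. MD snapshots read from multi-model PDB), compute for every
   atom of the stereoselectivity-determining region — all atoms within
   a 6 Å radius of the newly formed stereogenic center — the mean and
   standard deviation of its distance to the ε-amino nitrogen (`NZ`) of
   the catalytic lysine, the fixed reference point where the
   nucleophile sits.
2. **Cross-homolog divergence.** Pair residues of the two homologs by
   rigid (Kabsch) superposition and mutual-nearest-neighbour Cα
   matching, then flag residue pairs whose mean distances diverge:
   candidate iff `|μ_A − μ_B| ≥ δ` **and**
   `|μ_A − μ_B| / √(σ_A² + σ_B²) ≥ k` (defaults δ = 1 Å, k = 2), minus
   explicit mechanistic exclusions (e.g. proton-shuttle glutamates).
3. **Conservation filter.** Per-column information content
   `IC = log₂20 − H` (bits, sequence-logo convention) of each homolog
   family's alignment; candidates must be virtually fully conserved
   (IC ≥ 3 bits by default) in **both** families.
4. **Grafting.** Map surviving sites onto the target via the structural
   correspondence, and emit variant designs: degenerate-codon site
   saturation (`NDT` → 12 amino acids, 0 stops), β-strand motif swaps,
   glycine deletions, and residue-disjoint combinations
   (`A203G/ΔG204/ΔG205/T18S`-style naming).
5. **Scoring analytics.** Signed enantiomeric excess from enantiomer
   peak areas, `ee = (A_ref − A_other)/(A_ref + A_other)`; the
   selectivity scale `log E = log₁₀[(1 + ee)/(1 − ee)]`; replicate
   aggregation (mean ± sample SD); and Michaelis–Menten fits
   `v = k_cat·S/(K_M + S)` with curvature-based standard errors and
   propagated `k_cat/K_M`.

A synthetic-data module generates every input with known ground truth
(toy homolog pairs with planted divergences, Gaussian-perturbed
ensembles, alignments with stated per-column conservation, noisy peak
areas and rate data), so the whole pipeline is testable end to end
without any external structure or assay data.

## Worked example

```r
library(graftsite)

# a toy homolog pair with three planted divergent sites (offset 2 Å)
pair <- make_homolog_pair(n_residues = 20,
                          planted = data.frame(res_num = c(4, 9, 15),
                                               offset = 2.0),
                          seed = 1)
ens_a <- sample_ensemble(pair$model_a, sigma = 0.4, n_snapshots = 1000, seed = 1)
ens_b <- sample_ensemble(pair$model_b, sigma = 0.4, n_snapshots = 1000, seed = 102)
spec_a <- region_spec(center = pair$reference_a, radius = 6,
                      reference_atom = pair$reference_a)
spec_b <- region_spec(center = pair$reference_b, radius = 6,
                      reference_atom = pair$reference_b)
rp_a <- aggregate_by_residue(distance_profile(ens_a, spec_a))
rp_b <- aggregate_by_residue(distance_profile(ens_b, spec_b))

ca_a <- subset(pair$model_a$atoms, atom_name == "CA")
ca_b <- subset(pair$model_b$atoms, atom_name == "CA")
sup  <- kabsch_superpose(cbind(ca_a$x, ca_a$y, ca_a$z),
                         cbind(ca_b$x, ca_b$y, ca_b$z))
corr <- build_correspondence(pair$model_a, pair$model_b, sup)
div  <- divergence_table(rp_a, rp_b, corr)
subset(as.data.frame(div), candidate,
       select = c(pair_label, mean_a, mean_b, delta, score))
#>    pair_label mean_a mean_b delta score
#> 4      G4/G11   4.07   2.20  1.88  2.43
#> 9      G9/G16   3.60   1.73  1.87  2.36
#> 15    G15/G22   3.45   1.59  1.86  2.48
```

Exactly the three planted residues (4, 9, 15; B numbering +7) are
called: their mean distances to the catalytic-lysine `NZ` differ by
≈1.9 Å (the planted 2 Å minus a small convexity bias from the
fluctuation model), 2.4 pooled-SD units.

```r
expand_degenerate_codon("NDT")
#> CodonExpansion NDT - 12 codons, 12 amino acids ( C,D,F,G,H,I,L,N,R,S,V,Y ), 0 stop(s)

round(log_e_from_ee(0.91), 2)   # ee = 91% on the log E scale
#> [1] 1.33

d <- simulate_kinetics(0.29, 33.18, 0.29 * 2^seq(-3, 4),
                       noise_cv = 0.01, seed = 5)
fit_michaelis_menten(d$S, d$rate)
#> KineticsFit: K_M = 0.288 +/- 0.0078 mM, k_cat = 33.12 +/- 0.24 1/s, k_cat/K_M = 115 1/s/mM (n = 8)
```

The kinetics fit recovers the generating truth (K_M = 0.29 mM,
k_cat = 33.18 s⁻¹) well within its standard errors.

A command-line front end is installed as `exec/graftsite`
(`graftsite region`, `profile`, `codon`, `ee`, `kinetics`,
`simulate`); see `?graftsite_cli`.

## Documentation

The methods vignette (`vignettes/homologous-grafting.Rmd`) describes
the model and its assumptions, all tunable parameters with their
defaults, what the synthetic generators do and do not emulate, and the
package's numerical conventions and limitations.
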