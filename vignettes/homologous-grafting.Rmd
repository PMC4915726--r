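---
title: "Methods: identifying and grafting stereoselectivity determinants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: identifying and grafting stereoselectivity determinants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(graftsite)
```

## The model

`graftsite` operationalizes a comparative strategy for redesigning
enzyme stereoselectivity. Two homologous enzymes with opposite
enantiopreference but a shared fold (here: TIM-barrel, class I
aldolases) differ, by hypothesis, in the part of the active site that
accommodates the electrophile — the side on which the new stereogenic
center is formed — while the nucleophile-binding side, including the
Schiff-base lysine, is conserved. The package therefore:

1. defines the *stereoselectivity-determining region* as all atoms
   within a radius (default 6 Å, i.e. a 12 Å-diameter sphere) of the
   newly formed stereogenic center;
2. measures, across a conformational ensemble, the distance of every
   region atom to a fixed reference — the ε-amino nitrogen (`NZ`) of
   the catalytic lysine, a proxy for where the covalently bound
   nucleophile sits — and summarizes each atom by mean ± SD;
3. calls residue pairs *divergent* when the homologs' distance
   profiles disagree beyond noise;
4. keeps only divergent sites that are near-invariant within each
   homolog's own sequence family (a residue that truly sets a
   conserved property should itself be conserved); and
5. maps the survivors onto the target enzyme through a structural
   superposition and emits concrete mutagenesis designs.

### Assumptions

* The ensemble is a stationary sample around a mean structure; region
  membership is decided **once**, on a designated reference conformer
  (default: the first snapshot), and kept even if atoms drift across
  the boundary mid-trajectory. This matches the "fixed region"
  reading of the design and makes profiles comparable across
  ensembles.
* Distances to a single reference atom are a sufficient geometric
  summary. This deliberately ignores angular information; it is the
  convention the approach was built on.
* Homology is close enough that mutual-nearest-neighbour Cα pairing
  after rigid superposition yields a one-to-one residue
  correspondence (cutoff 2.5 Å by default).

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| region `radius` | 6.0 | Å | membership sphere around the stereogenic center (inclusive boundary: `distance <= radius`) |
| `reference_atom` | lysine `NZ` | — | distance reference; the residue must be a lysine unless another atom is named explicitly |
| pairing `cutoff` | 2.5 | Å | max Cα–Cα distance for a correspondence pair |
| `score_threshold` (k) | 2.0 | pooled-SD units | divergence call: `delta / sqrt(sd_A^2 + sd_B^2) >= k` |
| `min_delta` | 1.0 | Å | divergence call: absolute mean difference floor |
| `ic_min` | 3.0 | bits | conservation floor in *both* family alignments (log₂20 ≈ 4.32 is full conservation) |
| MM fit `tol` / `max_iter` | 1e-8 / 500 | — | relative-change convergence of the Gauss–Newton iteration |

The divergence criterion deserves emphasis: the original analysis
reports only that some homologous positions had "significantly
different" distances, without a numeric rule. The `(k, δ)` pair above
is this package's own declared convention — chosen so that a 2 Å
planted difference against ~0.5–0.6 Å distance SDs is called cleanly
while sampling noise (SE of a mean over 1000 snapshots ≈ 0.02 Å) never
is — and both knobs are exposed rather than hidden.

Mechanistic exclusions (e.g. glutamates that are part of the essential
proton-shuttling machinery and therefore divergent for reasons
unrelated to the stereogenic center) are **explicit user input** with a
recorded reason, never inferred automatically.

## What the synthetic generators emulate — and what they do not

The package generates every input it consumes, with stored ground
truth:

* `make_homolog_pair()` builds toy structures: a central lysine with
  `NZ` at the reference point and residues (Cα + one sidechain-proxy
  atom) on well-separated rays, 3.8–5.6 Å out. The backbone is
  *identical* between the homologs — real homolog pairs of this kind
  superpose to sub-Å backbone RMSD — while planted residues have their
  sidechain proxy displaced radially by the stated offset in structure
  B. The displaced atom is the residue's closest-approach atom, so the
  planted offset appears exactly (to 1e-9 Å) in residue-level
  profiles, and never disturbs the Cα correspondence. B is renumbered
  (+7) and rigidly moved to exercise the superposition path.
* `sample_ensemble()` adds i.i.d. isotropic Gaussian displacement
  (per-atom, per-coordinate SD σ) to the base coordinates. This
  reproduces the *statistical shape* the profiling assumes — mean
  structure plus stationary fluctuation — and nothing else: no
  covariance between atoms, no collective modes, no kinetics, no
  solvent. It is explicitly not a physical MD surrogate. A green
  recovery test therefore establishes that the statistics and
  bookkeeping are correct, not that the method would work on any
  particular real trajectory.
* `make_msa()` draws alignment columns independently from stated
  distributions (conserved or mixtures, plus uniform gaps); real
  families add phylogenetic correlation between sequences, which this
  deliberately omits — IC estimates on real data are biased up at
  small effective n, which is why the `e(n)` small-sample correction
  exists as an option.
* `simulate_peak_areas()` / `simulate_kinetics()` use multiplicative
  lognormal noise (positivity-preserving, mean 1) on exact peak-area
  splits and Michaelis–Menten rates.

All generators are pure functions of `(config, seed)`; each draws from
its own stream derived from the root seed by a fixed counter scheme
(`derive_seed()`), so adding a generator never perturbs existing
fixtures.

A note on fluctuation bias: if an atom sits at true distance `r` and
both it and the reference fluctuate isotropically with per-coordinate
SD σ, the *mean measured distance* exceeds `r` (convexity), by roughly
`3σ²/r` at these scales. Because the bias depends on `r`, a planted
2.0 Å offset is measured as ≈1.85–1.9 Å at σ = 0.4. The divergence
defaults accommodate this; it is a property of the distance statistic
itself, not an implementation artifact.

## Numerical choices

* **Superposition**: Kabsch via SVD; a reflection is corrected by
  flipping the smallest singular direction, so the rotation is always
  proper (det = +1 within 1e-9). Collinear/degenerate point sets are
  rejected.
* **Profile SD**: sample SD (n − 1). The source material does not say
  whether its error bars are sample or population SD; at n = 10⁴
  snapshots the difference is ~5e-5 relative, i.e. irrelevant, but the
  choice is recorded here rather than guessed silently.
* **Residue aggregation**: closest-approach convention — the atom with
  the smallest mean distance represents the residue (ties: lower atom
  serial). A mean-over-atoms alternative sits behind
  `stat = "mean"`.
* **Logo statistics**: frequencies over non-gap symbols;
  `IC = log₂20 − H` clamped at 0; all-gap columns get `NA` + flag;
  columns >50 % gap are flagged unreliable. No small-sample correction
  by default (families of thousands of sequences make it negligible);
  the standard `e(n) = 19/(2·ln2·n)` correction is available.
* **log E**: base-10. The defining footnote of the reproduced
  selectivity table does not name the base; base 10 reproduces all
  eight printed conversions at 2 decimals, natural log reproduces
  none. `|ee| ≥ 1` raises an "unbounded E" error instead of returning
  ±Inf.
* **Michaelis–Menten fit**: damped Gauss–Newton on
  `(log K_M, log k_cat)` — the log parameterization keeps both
  parameters positive without constraints; initialization
  `K_M₀ = median(S)`, `k_cat₀ = max(v)`; convergence at relative
  parameter change < 1e-8 within 500 iterations. `stats::nls()` was
  deliberately not used: it errors on zero-residual (noiseless) data,
  which the recovery contract requires to succeed. Standard errors
  come from the curvature (`σ̂²(JᵀJ)⁻¹`) in the natural
  parameterization; efficiency SE by first-order propagation,
  covariance term off by default (`use_covariance = TRUE` enables it).
  Saturated-only (constant-rate) designs leave K_M unidentifiable and
  fail with a non-convergence error rather than returning a
  meaningless number.
* **Altloc collapse**: highest occupancy wins; exact ties go to the
  alphabetically first altloc — deterministic by construction.
* **Edit bookkeeping**: edits are stored in the *original* target
  numbering (so `ΔG204`/`ΔG205` can be named alongside `A203G`);
  renumbering happens only in the emitted mutated sequence. Combined
  variant names join component names with `/` in input order, which
  reproduces the conventional `A203G/ΔG204/ΔG205/T18S` style.
* **Serialization**: PDB output quantizes coordinates to 3 decimals
  (format limitation); lossless ground-truth round-trips go through
  the JSON sidecar (`digits = NA`).

## Open design points, decided

* *Center of the region in ligand-free structures.* When no bound
  substrate marks the stereogenic center, there is no canonical
  coordinate for it. The neutral accommodation implemented here is an
  explicit-coordinate center (`region_spec(center = c(x, y, z))`)
  alongside the atom-selector form; toy fixtures center on the
  reference `NZ` itself.
* *Direction of planted offsets.* "Displaced radially by the offset"
  leaves the sign open; the generator displaces the sidechain proxy
  inward (toward the reference). This keeps both homologs' planted
  atoms safely inside the 6 Å sphere under fluctuation, so region
  membership — decided on a noisy reference conformer — is stable,
  and realizes the offset exactly on the residue's representative
  atom. Outward displacement on the backbone was tried first and
  rejected: it breaks the structural correspondence for exactly the
  residues being studied, which no real homolog pair of this kind
  does.
* *Exclusion bookkeeping.* Exclusions are keyed by profile side and
  residue number with a free-text reason, and excluded pairs stay in
  the table (flagged, with the reason) rather than vanishing — an
  audit-friendly mirror of knowledge-based removals.

## Known limitations

* Only PDB-format structures and ensembles (plus a plain-text
  trajectory table) are read; no mmCIF, no binary trajectory formats
  (DCD/XTC), no protonation/hydrogen placement, no symmetry expansion.
* The divergence test treats residues independently; no multiple
  correspondence/alignment uncertainty is propagated.
* The conservation filter needs user-supplied residue→column maps; the
  package does not build family alignments (no homolog harvesting or
  tree inference).
* Library-size accounting of a published 49-variant design is not
  reproduced: the full variant list is not printed in the source
  material and straightforward enumeration of the described sets gives
  a nearby but not identical count; the combination operators are
  instead validated against the printed edit lists and caption names.
* Printed catalytic efficiencies of the reproduced kinetics table were
  evidently computed before rounding of K_M and k_cat; the package
  reports the ratio of its own (unrounded) fitted values, so
  comparisons against the table's efficiency column should allow for
  that rounding difference.
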