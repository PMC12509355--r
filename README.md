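# nucleocensus

Membraneless nuclear organelles — nucleoli, transcriptional condensates,
heterochromatin foci, Polycomb bodies — look alike under the microscope, yet
they can assemble by very different mechanisms: phase separation coupled to
percolation (PSCP/LLPS), which needs a dense network of multivalent contacts
among scaffold molecules, or binding of proteins to clustered chromatin
sites (ICBS), which needs no percolating network at all. `nucleocensus`
implements a "by-the-numbers" approach to telling these apart: it builds an
absolute molecular census of each organelle from proteomics, imaging and
geometry inputs, converts the census into mean intermolecular distances
under explicit conformational models, and compares those distances to the
Debye length — the distance over which intermolecular interactions act.

It is aimed at quantitative cell biologists and biophysicists who have
(i) iBAQ-style abundance data, (ii) imaging-based enrichment estimates and
(iii) organelle geometries, and want a falsifiable statement about which
demixing mechanism a composition supports.

## The model in brief

**Census.** Copies per cell come from a through-origin calibration
N<sub>tot</sub> = a · iBAQ anchored on proteins with independently measured
copy numbers (the theoretical histone H4 total,
ploidy · 2 · G/NRL ≈ 54·10⁶ for a diploid 2.5 Gb genome at NRL = 186 bp,
serves as one anchor). Copies are partitioned into an organelle class by the
enrichment α = (I_org − I_BG)/(I_np − I_BG):

    N_org = α N_tot V_org / ((α − 1) n_org V_org + V_nuc)

RNA is distributed analogously from the nuclear ribonucleotide pool
(M_tot f_nuc / MW · N_A), and nucleosomes from the H4 total (two H4 per
nucleosome), with DAPI-derived enrichments of satellite-rich organelles
divided by 1.5 to correct the AT-preference of the stain.

**Sizes.** Each molecule pervades a sphere. Proteins: the predicted
structure's 2R<sub>g</sub>; a "relaxed" random walk over ordered/disordered
domains, d = 2·√(Σ R<sub>g,i</sub>²); and an "expanded" arrangement,
d = Σ R<sub>g,i</sub> + √(Σ R<sub>g,i</sub>²), capped at the fully
denatured chain. RNAs: folded d = 2·0.55·N^0.33 nm, an expanded worm-like
chain with l_p = 0.15·N^0.33 nm and l_c = 0.696 nm·N, and their mean.

**Distances.** For randomly placed spheres of radius r at volume fraction
φ, the mean center-to-center nearest-neighbor distance is

    Δ_center = 2r + e^(8φ) r / (3 φ^(1/3)) · Γ(1/3, 8φ)

(upper incomplete gamma; surface distance Δ = Δ_center − 2r, set to zero at
φ ≥ 0.65, random dense packing). Mixtures use the count-weighted effective
radius r_avg = (Σ N_i (d_i/2)³ / Σ N_i)^(1/3). Both limits of the formula
are validated in-package against Monte-Carlo oracles (a Poisson point
process and hard-sphere random sequential insertion).

**Scoring.** Each organelle is scored for three scenarios — scaffold
proteins alone, + RNAs, + nucleosomes — via
S_D = 1 if Δ < λ_D, else exp(−(Δ − λ_D)/λ_D), with λ_D = 2.2 nm the
estimated in-cell maximum Debye length. Any scenario with S_D ≥ 0.5 makes
the composition PSCP/LLPS-compatible; three low scores favor ICBS. The
nucleosome:protein ratio indicates whether chromatin offers enough binding
sites for ICBS.

## Worked example

A small synthetic configuration ships with the package: a 450 µm³ nucleus
with ten chromatin-rich foci (3 µm³, DAPI enrichment 4.5, bias-corrected)
and two RNA-rich bodies (40 µm³, RNA enrichment 12):

```r
library(nucleocensus)
cfg <- load_config(system.file("extdata", "synthetic_nucleus.yaml",
                               package = "nucleocensus"))
res <- run_census(cfg)
print(res)
#> <census_result> 2 organelle class(es), 10 census rows
#> <score_card> chromatin_focus: PSCP_LLPS_compatible
#>   S_D = 0.000 / 0.002 / 0.879 (proteins / +RNA / +nucleosomes)
#>   nucleosome:protein ratio = 69.1
#> <score_card> rna_body: PSCP_LLPS_compatible
#>   S_D = 0.000 / 1.000 / 1.000 (proteins / +RNA / +nucleosomes)
#>   nucleosome:protein ratio = 5.04
```

Reading the output: in both organelle classes the candidate scaffold
proteins alone are far too dilute for a percolating interaction network
(S_D ≈ 0 — their mean surface-to-surface distances are tens of nm, far
beyond the 2.2 nm Debye length). The RNA-rich body becomes compatible with
multicomponent phase separation once RNA is included (S_D = 1.0); the
chromatin focus only approaches compatibility when its nucleosomes
themselves are counted as scaffolds (S_D = 0.879 at a 69:1
nucleosome:protein excess), the signature of a chromatin-bound (ICBS-style)
organization. Per-species copies, concentrations and mass densities are in
`res$census`, distances in `res$packing`, and
`write_census_report(res$census, res$scorecards, "out/")` writes the
TSV/JSON reports. A command-line wrapper with `run`, `distances`, `score`
and `render` (virtual-microscopy voxels) subcommands lives at
`inst/cli/census.R`:

```sh
Rscript inst/cli/census.R run --config inst/extdata/synthetic_nucleus.yaml --out census_out
Rscript inst/cli/census.R render --config inst/extdata/synthetic_nucleus.yaml \
    --organelle rna_body --out census_out --seed 1
```

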