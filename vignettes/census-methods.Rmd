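---
title: "From abundances to demixing mechanisms: the census model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From abundances to demixing mechanisms: the census model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucleocensus)
```

`nucleocensus` turns three kinds of inputs — absolute proteomics
intensities (iBAQ), imaging-based enrichment factors, and organelle
geometry — into a per-organelle molecular census and a mechanistic verdict:
is the composition dense enough for phase separation coupled to percolation
(PSCP/LLPS), or is demixing better explained by proteins binding clustered
chromatin sites (ICBS)? This vignette explains each stage of the model, its
assumptions, the tunable parameters, and what the validation machinery does
and does not establish.

## 1. The census

### Calibration

iBAQ intensities are proportional to copy numbers but on an arbitrary
scale. The package fits `N = a * iBAQ` by ordinary least squares through
the origin on anchor proteins whose absolute copies are known
independently. The through-origin form is deliberate: the relation has a
single scale parameter and no physical intercept. One anchor always
available in silico is histone H4: with two H4 per nucleosome,

```{r}
theoretical_h4_total(nucleus_model())
```

molecules in a diploid 2.5 Gb genome at a 186 bp nucleosome repeat length.
Proteins undetected by mass spectrometry are assigned a fixed
detection-limit copy number (default 407, estimated from the shape of
proteome-wide copy-number distributions). We keep this limit a constant
rather than scaling it with the fitted slope: it describes the instrument's
sensitivity floor, not the calibration.

### Partition into organelles

The nuclear pool of a species splits into organelle and nucleoplasm
compartments. With enrichment $\alpha = c_\mathrm{org}/c_\mathrm{np}$
measured from background-subtracted image intensities,

$$N_\mathrm{org} = \frac{\alpha N_\mathrm{tot} V_\mathrm{org}}
{(\alpha - 1)\, n_\mathrm{org} V_\mathrm{org} + V_\mathrm{nuc}}.$$

The partition conserves the total for every $\alpha$ and geometry, which
the test suite checks to $10^{-9}$ relative on random configurations.
Proteins reported to localize exclusively to an organelle get
$\alpha = \infty$, for which the analytic limit
$N_\mathrm{org} = N_\mathrm{tot}/n_\mathrm{org}$ is used (encoded as the
literal `inf` in species tables). RNA follows the same logic at the
ribonucleotide level, starting from the nuclear RNA mass
(20 pg total cellular RNA, 15% nuclear, 340 g/mol per ribonucleotide);
ribonucleotide counts are converted to molecules using a characteristic
length of 14,000 nt for nucleolar (pre-rRNA) compartments and 2790 nt (a
median mRNA) elsewhere. Molecule counts are kept fractional internally and
only rounded in reports. Nucleosomes are partitioned from the H4-derived
total using chromatin (DAPI) enrichments; organelles flagged as rich in
AT-rich satellite repeats have their DAPI enrichment divided by 1.5
beforehand, because DAPI over-reports such sequences. The flag is explicit
per organelle (`dapi_bias_correction`) and defaults to off, since the bias
is only established for heterochromatin-focus-like bodies.

One deliberate interpretation: the organelle sums that appear in the RNA
pool normalization include organelle multiplicity
($\sum_i \alpha_i\, n_{\mathrm{org},i} V_{\mathrm{org},i}$). Without the
multiplicity the ribonucleotide pool would not be conserved when an
organelle class has more than one instance.

### Units

Volumes are carried in µm³, molecular lengths in nm, and conversions are
centralized: 1 µm³ = 10⁹ nm³ = 10⁻¹⁵ L, so 1 µM in 1 µm³ is ~602
molecules. Mass densities use molecular weights in g/mol; the nucleosome
default is the histone octamer (108 kDa) plus NRL × 650 g/mol/bp of DNA,
~229 kDa, configurable because it is a modeling convention rather than a
measured constant.

## 2. Molecular sizes

Each molecule is modeled as pervading a sphere of diameter $d$.

* **Predicted**: $d = 2 R_g$ of the predicted 3D structure (an input).
* **Relaxed**: the protein is a random walk over its ordered and
  disordered domains, $d = 2\sqrt{\sum_i R_{g,i}^2}$, floored at the
  predicted diameter — a flexible chain cannot pervade less than its
  predicted structure.
* **Expanded**: the midpoint between the relaxed walk and a straight-line
  arrangement, $d = \sum_i R_{g,i} + \sqrt{\sum_i R_{g,i}^2}$, capped at
  the fully denatured chain diameter.

Domain decompositions come from per-residue order/disorder annotations,
smoothed with a centered 5-residue majority window (ties resolve to
ordered) and with runs shorter than the window merged into their flanks;
the operation is idempotent. Disordered-domain radii of gyration follow a
power law $R_g = b\,n^\nu$. The coefficients are configurable inputs with
defaults $b = 0.254$ nm, $\nu = 0.522$ (disordered) and $b = 0.19$ nm,
$\nu = 0.588$ (denatured); they are typical literature-scale values and
should be replaced if the user prefers a specific parameterization. The
denatured cap is evaluated on the total residue count, since it represents
the entire chain unfolding. After the floor and cap we additionally enforce
predicted ≤ relaxed ≤ expanded, so the three scenarios remain ordered even
for species whose cap would otherwise undercut the floored relaxed value.
Large assemblies (e.g. a Mediator-class complex) bypass the domain model:
their three diameters are supplied directly in the species table.

RNAs use a folded scaling law $d = 2 \cdot 0.55\,N^{0.33}$ nm and, for the
expanded case, the exact worm-like-chain radius of gyration with
persistence length $l_p = 0.15\,N^{0.33}$ nm and contour length
$l_c = 0.696\,\mathrm{nm} \cdot N$; the relaxed case is the mean of the
two. For chains with $l_c/l_p > 500$ the worm-like chain is within 1% of
its long-chain limit $2\sqrt{l_p l_c / 3}$, which the tests verify.

## 3. Distances and crowding

For $N$ spheres of radius $r$ placed randomly in volume $V$, the mean
center-to-center nearest-neighbor distance is

$$\Delta_\mathrm{center} = 2r + \frac{e^{8\phi}\, r}{3\phi^{1/3}}
\Gamma\!\left(\tfrac13,\, 8\phi\right),$$

with $\phi = \frac{4\pi}{3} r^3 N / V$ and $\Gamma$ the *unnormalized upper*
incomplete gamma function — the convention is pinned down by the dilute
limit, which must reproduce the Poisson nearest-neighbor mean
$\Gamma(4/3)\,(4\pi n/3)^{-1/3} \approx 0.554\, n^{-1/3}$. The surface
distance subtracts the diameter; at $\phi \ge 0.65$ (beyond random dense
packing of rigid spheres) it is clamped to zero, and the clamp is applied
after the analytic evaluation, never folded into it. Mixtures substitute
the count-weighted effective radius
$r_\mathrm{avg} = (\sum_i N_i (d_i/2)^3 / \sum_i N_i)^{1/3}$; the mixture
volume fraction uses $r_\mathrm{avg}$ and the total count rather than a
per-species sum — the two differ only at the third-moment level, and the
substitution keeps the one-component formula exact for single species.

Because the formula is itself an approximation (a Poisson process with a
hard-core hole around the reference molecule), the package carries two
independent Monte-Carlo oracles in compiled code: a periodic-box Poisson
point process and hard-sphere configurations from random sequential
insertion (RSA). On the problem sizes used by the tests and the acceptance
script — $10^5$ Poisson points at $\phi = 10^{-4}$, 4000 RSA spheres at
$\phi = 0.1$, 2000 at $\phi = 0.3$ — the analytic distance agrees with the
oracles to ~0.1%, ~4% and ~6% respectively; the tests enforce 2% (dilute)
and 15% (crowded) bands. RSA is used rather than equilibrated hard-sphere
dynamics because it is simple, exactly reproducible and adequate at these
volume fractions; it is only feasible up to $\phi \approx 0.35$, which the
oracle enforces with an explicit error.

## 4. Scoring and rendering

Surface distances for three cumulative scenarios — candidate scaffold
proteins alone, + RNAs, + nucleosomes — are mapped to scores

$$S_D(\Delta) = \begin{cases} 1 & \Delta < \lambda_D \\
e^{-(\Delta - \lambda_D)/\lambda_D} & \Delta \ge \lambda_D \end{cases}$$

with $\lambda_D = 2.2$ nm, the estimated maximum Debye length in cells
(0.8 nm at physiological ionic strength is carried as a stricter
alternative). $S_D$ is continuous and non-increasing. Scores are computed
from relaxed-conformation distances: relaxed sizes are the intermediate,
least-committal choice between a possibly too-compact prediction and a
fully expanded chain. A scenario passes at $S_D \ge 0.5$; the boundary is
inclusive — the cutoff itself counts as acceptance, a convention that
matters only in the measure-zero case of an exact hit. Any passing scenario
renders the organelle PSCP/LLPS-compatible; three failures favor ICBS,
with the nucleosome:protein ratio reported alongside as an indicator of
chromatin binding-site excess.

Virtual-microscopy voxels (spheres of radius 250 nm, roughly a confocal
observation volume) illustrate the census to scale: per-species counts are
Poisson with mean $c_i V_\mathrm{voxel}$ — a voxel is a random sample of
the organelle, so fixed expected counts would understate its variability —
placed uniformly with hard-sphere rejection up to a bounded attempt budget
(then allowing overlap with a warning, which is routine for crowded
mixtures), and drawn in painter's order. Rendering is byte-deterministic
for a given seed.

## 5. The synthetic cell

`make_synthetic_cell()` defines the conditions under which the pipeline is
validated: a diploid 450 µm³ stem-cell-like nucleus containing ten
chromatin-rich, DAPI-biased foci of 3 µm³ and two RNA-rich nucleolus-like
bodies of 40 µm³; species with ground-truth copies log-uniform between
10³ and 10⁷ (the realistic span from rare silencers to abundant granule
proteins), log-normal enrichments centered near 4, random ordered /
disordered domain decompositions, and iBAQ values generated as
copies / a with optional multiplicative log-normal noise (20% in the noisy
recovery checks, a typical between-replicate spread for label-free
proteomics). Fixtures are written through the package's own writers so
every test also exercises the public I/O surface.

What passing these tests shows: the algebra is implemented correctly
(conservation, exact noise-free recovery, unbiased slope recovery within
OLS error under noise) and the distance model is faithful to its own
assumptions (agreement with the oracles). What it does not show: that real
organelles satisfy those assumptions. In particular the model assumes
molecules are randomly distributed within an organelle (internal
substructure would change distances), that image intensities are linear in
concentration, that enrichment estimates from immunostaining transfer to
living cells, and that candidate scaffold lists — an input — are complete
and correct. Changing the candidate list is the main intended use of the
configurable species table.

## 6. Degenerate inputs and numerical choices

* A scenario that requires a molecular class with zero total copies
  returns a $\phi = 0$ state with infinite distances (score 0) and a
  warning, rather than failing the whole run.
* $\alpha = \infty$ uses the analytic limit; $\alpha = 10^9$ agrees with
  it to $10^{-6}$ relative, which the tests check.
* The incomplete gamma is evaluated as
  `gamma(a) * pgamma(x, a, lower = FALSE)`, accurate across the full
  $\phi$ range used ($e^{8\phi} \le e^{5.2}$ before the clamp).
* Report writers emit full-precision (`%.17g`) numbers so counts
  round-trip exactly and floats to better than $10^{-9}$ relative.
* Tie-breaks: the 5-residue majority window resolves ties toward ordered;
  run-merging flips the shortest run first.

## 7. Known limitations

The approach treats each organelle as well mixed and each molecule as a
sphere; it ignores polymer–polymer phase separation of the chromatin fiber,
spatial substructure (e.g. nucleolar subcompartments must be modeled as
separate organelle classes), and any sequence-specific interaction
chemistry beyond the Debye-length criterion. The mechanism call is
therefore a compatibility statement about compositions, not a proof of
mechanism: a high score says a percolating network is geometrically
possible, and three low scores say it is geometrically implausible for the
given candidate set.
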