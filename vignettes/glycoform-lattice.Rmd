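---
title: "Glycoform lattice analysis of native mass spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Glycoform lattice analysis of native mass spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycolattice)
```

## The problem

Native mass spectrometry of an intact, heavily glycosylated membrane
protein complex — the motivating system is a ~127 kDa heteromeric amino
acid transporter carrying four complex-type N-glycans on its heavy
chain — produces spectra in which hundreds of glycoforms, PTM states and
lipid-bound species overlap across a multi-charge electrospray envelope.
The key structural observation that makes these spectra tractable is
that the three dominant glycan elaborations form an almost-commensurate
mass lattice:

* antennary fucosylation: +146.14 Da per Fuc, spanning 2 lattice units;
* sialylation: +291.26 Da per Neu5Ac, spanning 4 units;
* branch extension (one GlcNAc₁Gal₁ antenna): +365.33 Da, 5 units.

Every combination of these additions therefore lands, to within a
fraction of a dalton, on a grid of spacing ≈ 72.95 Da (146.14/2 = 73.07,
291.26/4 = 72.81, 365.33/5 = 73.07). Resolved "fine structure" within
one charge state at this spacing identifies the heterogeneity as glycan
combinatorics, licenses a repeat-unit filter during deconvolution, and
turns proteoform annotation into lattice bookkeeping. Off-lattice
residuals then isolate adducts: phosphorylation (+79.98), palmitoylation
(+238.41), and phospholipids (PE ≈ 731, PS ≈ 796, PI ≈ 870 Da, weighted
class averages).

The package implements this programme end to end: mass arithmetic and
ladder combinatorics (`residue_mass`, `enumerate_ladder`, `repeat_unit`,
`find_compositions`, `degeneracy_report`), a synthetic-data engine
standing in for the instrument (`sim_config`, `sample_proteoforms`,
`render_spectrum`, `apply_neuraminidase`, `dissociate`,
`sample_mp_events`), deconvolution (`centroid`, `infer_charges`,
`fine_structure_interval`, `fourier_repeat`, `zero_charge`), annotation
and differential comparisons (`infer_base_mass`, `assign_lattice`,
`sialic_census`, `envelope_decompose`, `adduct_share`,
`annotate_adducts`), and oligomer-assembly models (`convolve_assembly`,
`compare_assembly`, `occupancy_expected`, `independence_test`,
`ratio_quantify`, `mp_fit`).

## Mass conventions

Average masses use the IUPAC 2021 standard atomic weights (C 12.011,
H 1.008, N 14.007, O 15.999); monoisotopic masses use the lightest
isotope masses. The two conventions differ by more than half a dalton
per residue, and published work mixes them without labels, so every mass
function takes an explicit `kind = "mono"` or `"average"` argument with
no default. The proton mass for m/z conversion is 1.00728 Da; only
positive ion mode is modelled.

The average branch increment computes to 365.335 Da, which a 2-decimal
display rounds to 365.34 while the conventional printed value is 365.33;
all checks in the package treat agreement within 0.01 Da as exact at
this display precision.

## The repeat-unit estimator

`repeat_unit()` collapses a mass ladder (single-linkage merge of masses
within `merge_tol`, default 1.5 Da — chosen so the 1.03 Da Neu5Ac vs
2×Fuc near-degeneracy always merges) and averages consecutive spacings.
The combinatorial unit lattice has vacancies: unit counts 1 and 3 are
unreachable (no combination of 2a + 4b + 5c produces them), and counts
near the maximum are sparse. A naive mean over all consecutive spacings
of the full enumeration (Fuc ≤ 6, Neu5Ac ≤ 16, branch ≤ 10) is therefore
inflated to 75.3 ± 13.1 Da by a handful of multi-unit gaps. The
estimator instead splits any gap larger than 1.5× the median gap into
its nearest integer number of unit steps before averaging — the same
missing-tooth rule `fine_structure_interval()` applies to measured peak
ladders — and returns 72.94 ± 0.59 Da on the full enumeration. Both the
theoretical-enumeration and measured-spacing routes to the repeat unit
are exposed, since either could underlie a reported value.

```{r repeat-unit}
lad <- enumerate_ladder(c(Fuc = 6, Neu5Ac = 16, branch = 10), "average")
unlist(repeat_unit(lad, merge_tol = 1.5)[c("mean", "sd")])
```

## What the synthetic-data engine emulates

`sim_config()` defaults define the wild-type-like study conditions:

* apoprotein base mass 127027 Da, plus a fixed glycan core of
  4 × (HexNAc₂Hex₃ + core Fuc); with 16 branches this reproduces the
  137028 Da theoretical mass of the tetra-antennary, core-fucosylated
  desialylated complex;
* total branch count 12–21 across the four glycans (the P1–P10 series),
  discretized Gaussian centred near 16;
* antennary fucosylation 0–4 (aF0–aF4), with the tri- and
  tetra-fucosylated forms more abundant than the bi-fucosylated one, as
  observed for this complex;
* total sialylation 9–16 Neu5Ac;
* sub-stoichiometric adducts: phospho occupancy 0.10, palmitoyl 0
  (appears only in mutant scenarios), PE 0/1/2 with probabilities
  0.6/0.3/0.1 (two binding sites, partially occupied);
* charge envelope: discretized Gaussian over integer z, centre 26,
  spread 2; Gaussian peaks of 1.2 m/z FWHM; additive truncated-Gaussian
  noise at a configurable fraction of the base peak; optional
  detergent-monomer satellite tails as a geometric series.

Populations are drawn as `n_molecules` (default 20 000) independent
molecules and aggregated, so abundances are multinomial estimates of the
configured product distribution; a recorded seed makes every population
and spectrum reproducible. What the generator does **not** emulate:
isotope structure (unresolved at 140 kDa under native conditions),
non-Gaussian peak shapes and detector saturation, charge-state-dependent
desolvation artefacts, chemical noise correlated across m/z, and any
coupling between glycosylation state and ionization efficiency. Passing
round-trip tests on these simulations therefore demonstrates the
*bookkeeping* of the analysis — charge inference, mass reconstruction,
lattice assignment — under controlled heterogeneity and noise, not
instrument-level performance on real spectra.

## Deconvolution choices

This is deliberately not a Bayesian joint charge–mass deconvolution in
the UniDec mould: the analytical leverage for resolved glycoform fine
structure is the repeat-unit lattice, so the package reconstructs
per-charge-series histograms and applies the lattice as a filter and
annotation device.

* `centroid()` smooths the profile with a small Gaussian kernel
  (s.d. 2 grid points by default) before local-maximum picking —
  single-point noise spikes vanish while peak centroids stay unbiased —
  then takes intensity-weighted centroids over half-height support.
  Peak "intensity" is summed profile intensity (an area proxy), so
  total intensity is conserved through `zero_charge()`.
* Envelope lobes (one per charge state per species) are delimited by the
  deep valleys of the intensity-weighted kernel density of peak
  positions, via a recursive watershed: a minimum splits a segment when
  both flanks rise to at least twice its depth. Plain gap-clustering
  fails here because stray noise peaks bridge the valleys.
* `infer_charges()` fits mass hypotheses: each candidate charge of the
  strongest unclaimed lobe implies a mass; all lobes get their nearest
  charge under it; lobes within a relative tolerance (0.2%) are kept and
  the mass refit. The hypothesis with the highest residual-weighted
  explained intensity wins. Two physical constraints resolve the
  harmonic ambiguities inherent in this search: an accepted series must
  occupy one contiguous charge run (one vacancy allowed), because an
  electrospray envelope is contiguous — a 2M-at-even-charges alias
  selects every other charge and is rejected — and near-ties prefer the
  assignment with more adjacent charge states.
* `fourier_repeat()` estimates the fine-structure period from the
  zero-padded power spectrum with parabolic peak interpolation. The
  detection threshold is `power_ratio` × median power × log₂(n): the
  maximum of a flat periodogram grows like the median times log₂ of the
  number of independent bins, so a fixed small multiple of the median
  would flag white noise as periodic on any realistically long segment.
* `zero_charge()` maps peaks inside each assigned lobe window to neutral
  mass, accumulates them on a 0.5 Da grid, and collapses reconstructed
  peaks by the same watershed segmentation (bandwidth 5 Da). With a
  `repeat_filter`, a lattice anchored at the most abundant mass flags
  each peak on/off lattice with `lattice_tol` 10 Da — wide enough that
  phospho (+80) and lipid (+731 vs 730.67) adducts stay visible as
  off-lattice or degenerate rather than being silently absorbed.

## Annotation and ambiguity policy

Peak-to-proteoform assignment is exhaustive search over a residue-count
grid (`find_compositions`), optionally combined with adduct
stoichiometries. Candidates are ranked: glycan-only interpretations
before adduct-bearing ones, then fewer adducts, then — within an error
band of 1 Da, below which instrument accuracy cannot distinguish
candidates — fewer residues, then absolute error. The full candidate set
is always reported; degeneracies (Neu5Ac ≈ 2×Fuc at 1.03 Da, 2×branch ≈
5×Fuc at 0.04 Da, PE ≈ 2×branch at 0.33 Da) are flagged, never silently
resolved. P-series indices are relative to the inferred lattice base
(P1 = base peak); aF indices count antennary fucoses above the
core-fucosylated composition folded into the base.

`adduct_share()` models an intact series as
(1 − f)·S + f·shift(S, k steps), with S the adduct-free dissociated
series and k the adduct mass rounded to lattice steps; f is bounded
least squares, and the confidence interval is a seeded 200-resample
residual bootstrap (percentile). The estimator is scale-invariant by
construction (both series are normalized first). An adduct that is not
close to a whole number of lattice steps (e.g. phospho against a 365 Da
lattice) is rejected explicitly rather than fitted meaninglessly.

`sialic_census()` matches each sialylated peak to the desialylated
anchor minimizing the residual to an integer number of Neu5Ac masses.
It is exact on noise-free, adduct-free populations (the acceptance
property); with sub-stoichiometric phospho/PE adducts present, the
adduct degeneracies (79.98 ≈ 291.26 − 3 × 73; 731 ≈ 730.67) contaminate
cross-matching — the census is then meaningful only after adducts are
resolved, which is why the dissociation-based adduct analysis precedes
it in the analysis workflow.

## Assembly models

Under the binomial assumption — an oligomer is assembled from
independent draws of the subunit proteoform distribution — the n-mer
mass distribution is the n-fold self-convolution of the subunit
distribution plus an interface term. `convolve_assembly()` implements
this exactly on the discrete mass support (mean identity exact to float
precision; variance identity to 1e-9 relative). `interface_delta`
defaults to 0, encoding assembly without additional interfacial ligands;
a +731 Da alternative models one interfacial phospholipid and is used as
the counterfactual in `compare_assembly()`, whose verdict flag tests
|Δmean| against the combined standard error.

`independence_test()` checks observed oligomer modification counts
against Binomial(order × sites, p). The exact multinomial branch
(total probability of all outcomes no more probable than the
observation) is used when the outcome space is enumerable — at most
5 × 10⁶ compositions, about n ≤ 3000 for three cells — or whenever a
zero-expected cell has a nonzero observed count; beyond that the
chi-square statistic is asymptotically calibrated (type-I error 0.05 ±
0.02 at n = 5000 over 1000 simulations in the test suite). Exhaustive
enumeration over the full multinomial simplex grows quadratically in n
for three cells, which is why the exact branch is budgeted rather than
switched at a fixed n.

Mass-photometry mixtures are fitted by a fixed-G 1-D Gaussian mixture
(`mclust`), and `ratio_quantify()` reports either integrated window
abundances (mass distributions) or component-weight ratios (MP fits).

## Problem sizes and tolerances

The test suite and analysis scripts use 20 000-molecule populations,
~14 000-point spectra, charge states 15–35, and a 0.5 Da mass grid —
sizes at which the full simulate–deconvolve–annotate round trip runs in
seconds and recovers ≥ 95% of generated proteoform labels
(abundance-weighted; a per-label count would be dominated by species
below any realistic detection limit) at 5% noise. Assignment tolerance
is ±2 Da by default, matching the precision with which intact masses of
this size are reported; round-trip tests on reconstructed peaks use
±8 Da, reflecting reconstruction scatter of weak peaks across charge
states rather than instrument accuracy.

## Known limitations

* Glycan compositions only — no topology or linkage, no isotopic fine
  structure within a residue.
* The charge-inference search assumes at least two charge states per
  species and contiguous envelopes; a species observed at a single
  charge state is reported unassigned.
* Exactly aliased envelopes (a dimer observed precisely at doubled
  charges) share peaks with the monomer; intensity is not apportioned
  between them.
* The detergent-adduct model is a geometric satellite series with free
  parameters; per-detergent distributions are not calibrated.
* Correlated assembly (glycoform-dependent dimerization affinity) is out
  of scope; the binomial model is the null the package tests against.
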