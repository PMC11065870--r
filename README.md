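# glycolattice

Intact-mass analysis of heavily glycosylated membrane-protein complexes
measured by native mass spectrometry, built around one structural fact:
the three dominant N-glycan elaborations — antennary fucosylation
(+146.14 Da, 2 lattice units), sialylation (+291.26 Da, 4 units) and
branch extension by one GlcNAc₁Gal₁ antenna (+365.33 Da, 5 units) — are
almost commensurate, so every glycoform of an intact complex sits on a
mass lattice of spacing ≈ 72.95 Da. Resolved fine structure at that
spacing within a charge state identifies glycan combinatorics as the
source of heterogeneity; the lattice then drives deconvolution,
proteoform annotation (P-series for branch count, aF-series for
antennary fucose), and the isolation of off-lattice adducts
(phospho +79.98, palmitoyl +238.41, phospholipids PE/PS/PI ≈
731/796/870 Da).

The package covers, for a ~140 kDa glycoprotein heterodimer and its
~280 kDa super-dimer:

* **mass arithmetic and combinatorics** — residue/adduct tables from
  atomic compositions (explicit mono/average choice everywhere),
  glycoform ladder enumeration, repeat-unit estimation, composition
  search with full degeneracy reporting;
* **a synthetic-data engine** — proteoform populations, multi-charge
  electrospray spectra with Gaussian peaks, noise and detergent tails,
  neuraminidase treatment, gas-phase subunit dissociation, and
  mass-photometry event streams, all seed-reproducible;
* **deconvolution** — centroiding, charge-state inference by mass
  hypothesis fitting over envelope lobes, fine-structure interval and
  Fourier repeat estimates, lattice-filtered zero-charge
  reconstruction;
* **annotation and differential analysis** — lattice base inference,
  P/aF assignment, sialic acid census from desialylation pairs,
  two-Gaussian envelope decomposition, adduct-bound fraction from
  intact/dissociated comparisons with bootstrap CIs;
* **assembly models** — binomial (self-convolution) super-dimer
  prediction, PTM–oligomerization independence tests,
  dimer/monomer ratio quantification from mass distributions and
  Gaussian-mixture fits of mass-photometry histograms.

## Worked example

Simulate a desialylated complex (P1–P10 branch series with antennary
fucosylation) at 5% noise, deconvolve, and annotate:

```r
library(glycolattice)

cfg <- sim_config(neu5ac_support = 0, neu5ac_prob = 1,
                  p_phospho = 0, pe_prob = c(1, 0, 0),
                  noise_level = 0.05, seed = 7)
pop <- sample_proteoforms(cfg)
sp  <- render_spectrum(pop, cfg)

pl <- centroid(sp)
ca <- infer_charges(pl, z_range = c(15, 35))
ca$series[[1]]$mass
#> [1] 137338.4        # generated abundance-weighted mean: 137338.9

md <- zero_charge(pl, ca, repeat_filter = residue_mass("branch", "average"))
base <- infer_base_mass(md, residue_mass("branch", "average"),
                        window = c(135387, 135747))
base$base
#> [1] 135566.8        # true P1 aF0 mass: 135566.8

res <- assign_lattice(md, base$base, c(branch = 12, Fuc = 6), tol = 8)
head(res$assignments[order(-res$assignments$abundance),
                     c("mass", "label_P", "label_aF", "error_Da")], 3)
#>        mass label_P label_aF    error_Da
#> 16 137028.2       5        0 -0.06306544
#> 21 137393.9       6        0 -0.44386153
#> 11 136662.4       4        0  0.34726354
```

The most abundant reconstructed proteoform lands within 0.1 Da of the
generated P5 aF0 species (137028.2 Da), and the branch series is
labelled P1–P10 with the antennary-fucose satellites aF0–aF4. On this
kind of input the pipeline recovers ≥ 95% of the generated proteoform
labels (abundance-weighted).

The `analysis/` directory holds the full workflow as numbered scripts —
`01_simulate.R` through `05_mass_photometry.R` (simulation,
deconvolution, annotation with sialic census and PE-bound fraction,
binomial super-dimer prediction with independence testing, and
mass-photometry ratio quantification). Each prints what it found and
writes its tables under `results/`; run them in order with
`Rscript analysis/01_simulate.R` etc.

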