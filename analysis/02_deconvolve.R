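#!/usr/bin/env Rscript
# Deconvolve the simulated desialylated spectrum: peak picking, charge
# inference, glycoform fine-structure spacing (both the direct interval
# and the Fourier estimate), and lattice-filtered zero-charge
# reconstruction. Requires 01_simulate.R outputs.

suppressPackageStartupMessages(library(glycolattice))

sp <- read_spectrum("results/spectrum_desial.txt")
pl <- centroid(sp)
cat(sprintf("picked %d peaks\n", nrow(pl)))

ca <- infer_charges(pl, z_range = c(15, 35))
for (s in ca$series) {
  cat(sprintf("charge series: mass %.0f +/- %.0f Da over z %d-%d\n",
              s$mass, s$mass_sd, min(s$z), max(s$z)))
}
main <- ca$series[[which.max(vapply(ca$series, `[[`, 1, "intensity"))]]

# fine structure of the central charge state
zc <- main$lobes$z[which.max(main$lobes$intensity)]
w <- main$lobes[main$lobes$z == zc, ]
fine <- pl[pl$mz >= w$mz_lo & pl$mz <= w$mz_hi, ]
fs <- fine_structure_interval(fine, zc)
cat(sprintf("fine structure at z=+%d: mean dm/z %.2f (sd %.2f), implied %.1f Da\n",
            zc, fs$mean_dmz, fs$sd_dmz, fs$delta_mass))

seg <- new_spectrum(sp$mz[sp$mz >= w$mz_lo & sp$mz <= w$mz_hi],
                    sp$intensity[sp$mz >= w$mz_lo & sp$mz <= w$mz_hi])
fr <- fourier_repeat(seg, zc)
cat(sprintf("Fourier repeat estimate: %.2f Da (detected: %s)\n",
            fr$repeat_mass, fr$detected))

md <- zero_charge(pl, ca, repeat_filter = residue_mass("branch", "average"))
pk <- md_peaks(md, min_frac = 0.02)
cat(sprintf("zero-charge distribution: %d peaks, top at %.1f Da\n",
            nrow(pk), pk$mass[which.max(pk$abundance)]))
write_massdist(md, "results/massdist_desial.csv")
cat("wrote results/massdist_desial.csv\n")
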