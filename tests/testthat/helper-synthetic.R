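# Shared synthetic fixtures. All randomness is seeded through the config
# or an explicit seed argument; nothing is read from disk.

# Desialylated wild-type emulation: P1-P10 branch series with antennary
# fucosylation, no sialylation, no adducts.
desial_config <- function(seed = 7, noise = 0.05, n = 20000) {
  sim_config(neu5ac_support = 0, neu5ac_prob = 1,
             p_phospho = 0, pe_prob = c(1, 0, 0),
             noise_level = noise, n_molecules = n, seed = seed)
}

# Fully sialylated wild-type emulation without sub-stoichiometric adducts
# (used where exact mass bookkeeping is asserted).
wt_glycan_only_config <- function(seed = 5, n = 5000) {
  sim_config(p_phospho = 0, pe_prob = c(1, 0, 0),
             noise_level = 0, n_molecules = n, seed = seed)
}

# A noise-free stick spectrum with Gaussian peaks at given m/z positions.
stick_spectrum <- function(centers, heights = 1, fwhm = 1.2, step = fwhm / 6,
                           pad = 10) {
  mz <- seq(min(centers) - pad, max(centers) + pad, by = step)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  heights <- rep_len(heights, length(centers))
  y <- rowSums(vapply(seq_along(centers), function(i) {
    heights[i] * exp(-0.5 * ((mz - centers[i]) / sigma)^2)
  }, numeric(length(mz))))
  new_spectrum(mz, y, metadata = list(source = "fixture"))
}

# m/z of mass M at charge z (positive mode)
mz_of <- function(M, z) (M + z * PROTON_MASS) / z
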