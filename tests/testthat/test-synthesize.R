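# Synthetic proteoform populations, spectrum rendering, enzymatic and
# gas-phase derivatives, and mass-photometry event sampling.

test_that("sample_proteoforms is seeded, normalized and config-driven", {
  cfg <- desial_config(seed = 3, n = 2000)
  pop <- sample_proteoforms(cfg)
  expect_s3_class(pop, "proteoform_population")
  expect_equal(sum(pop$abundance), 1)
  expect_true(all(pop$abundance > 0))
  # determinism under a fixed seed
  expect_identical(pop, sample_proteoforms(cfg))
  # a point-mass Neu5Ac distribution gives zero Neu5Ac everywhere
  expect_true(all(pop$Neu5Ac == 0))
  # invalid distributions are rejected at construction
  expect_error(sim_config(branch_prob = c(-1, rep(1, 9))), "invalid")
  expect_error(sim_config(p_phospho = 1.5), "probabilities")
})

test_that("desialylated populations live on the Fuc/branch lattice", {
  pop <- sample_proteoforms(desial_config(seed = 11, n = 3000))
  gaps <- diff(pop$mass)
  gaps <- gaps[gaps > 0.5]
  for (g in gaps) {
    hits <- find_compositions(g, 0.05, c(Fuc = 20, branch = 12), "average")
    # every pairwise gap is an integer combination of Fuc and branch
    # increments, allowing the signed combinations of a difference
    hits2 <- find_compositions(g + residue_mass("branch", "average") * 4,
                               0.05, c(Fuc = 24, branch = 16), "average")
    expect_true(nrow(hits) > 0 || nrow(hits2) > 0, info = paste("gap", g))
  }
})

test_that("proteoform masses decompose into base + glycans + adducts", {
  cfg <- sim_config(seed = 2, n_molecules = 500)
  pop <- sample_proteoforms(cfg)
  expected <- cfg$base_mass +
    composition_mass(cfg$core, "average") +
    pop$branch * residue_mass("branch", "average") +
    pop$aFuc * residue_mass("Fuc", "average") +
    pop$Neu5Ac * residue_mass("Neu5Ac", "average") +
    pop$phospho * adduct_mass("phospho") +
    pop$palmitoyl * adduct_mass("palmitoyl") +
    pop$PE * adduct_mass("PE")
  expect_equal(pop$mass, expected)
})

test_that("render_spectrum places peaks at (M + z p)/z and conserves area", {
  cfg <- sim_config(seed = 1, z_center = 26, z_spread = 0.3,
                    noise_level = 0, n_molecules = 10)
  pop <- structure(data.frame(mass = 140454, abundance = 1),
                   class = c("proteoform_population", "data.frame"))
  sp <- render_spectrum(pop, cfg, grid_step = 0.02)
  pl <- centroid(sp, min_snr = 1, smooth_pts = 0)
  apex <- pl$mz[which.max(pl$intensity)]
  expect_lt(abs(apex - (140454 + 26 * 1.00728) / 26), 0.005)
  expect_equal(round(apex, 2), round((140454 + 26 * 1.00728) / 26, 2))
  # two proteoforms one lattice unit apart -> adjacent-peak spacing 2.81
  pop2 <- structure(data.frame(mass = c(140454, 140454 + 72.95),
                               abundance = c(0.5, 0.5)),
                    class = c("proteoform_population", "data.frame"))
  sp2 <- render_spectrum(pop2, cfg, grid_step = 0.02)
  pl2 <- centroid(sp2, min_snr = 1, smooth_pts = 0)
  top2 <- pl2[order(-pl2$intensity), ][1:2, ]
  expect_equal(round(abs(diff(top2$mz)), 2), 2.81)
  # zero-noise spectra integrate to total abundance x charge weights = 1
  grid_step <- diff(sp$mz[1:2])
  sigma <- cfg$peak_fwhm / (2 * sqrt(2 * log(2)))
  area <- sum(sp$intensity) * grid_step / (sigma * sqrt(2 * pi))
  expect_equal(area, 1, tolerance = 1e-3)
  expect_error(render_spectrum(pop[0, ], cfg), "empty")
})

test_that("rendering is deterministic under a fixed seed", {
  cfg <- desial_config(seed = 9, n = 500)
  pop <- sample_proteoforms(cfg)
  s1 <- render_spectrum(pop, cfg)
  s2 <- render_spectrum(pop, cfg)
  expect_identical(s1$intensity, s2$intensity)
})

test_that("neuraminidase removal is mass-exact, aggregating and idempotent", {
  pop <- sample_proteoforms(wt_glycan_only_config(seed = 4, n = 2000))
  des <- apply_neuraminidase(pop)
  expect_true(all(des$Neu5Ac == 0))
  expect_lte(nrow(des), nrow(pop))
  expect_equal(sum(des$abundance), 1)
  # a proteoform with 13 Neu5Ac loses exactly 13 x 291.256 Da
  i <- which(pop$Neu5Ac == 13)[1]
  j <- which(des$branch == pop$branch[i] & des$aFuc == pop$aFuc[i])
  expect_equal(pop$mass[i] - des$mass[j],
               13 * residue_mass("Neu5Ac", "average"))
  expect_equal(pop$mass[i] - des$mass[j], 3786.31, tolerance = 0.05)
  # idempotence
  expect_identical(apply_neuraminidase(des), des)
  # already-desialylated populations pass through unchanged
  pop0 <- sample_proteoforms(desial_config(seed = 4, n = 500))
  expect_equal(apply_neuraminidase(pop0)$mass, pop0$mass)
})

test_that("dissociation conserves mass and routes adducts per subunit", {
  cfg <- sim_config(seed = 6, n_molecules = 3000, p_phospho = 0.3,
                    pe_prob = c(0.5, 0.3, 0.2))
  pop <- sample_proteoforms(cfg)
  dis <- dissociate(pop, light_base = 55000)
  m_in <- sum(pop$mass * pop$abundance)
  m_out <- sum(dis$light$mass * dis$light$abundance) +
    sum(dis$heavy$mass * dis$heavy$abundance)
  expect_equal(m_in, m_out, tolerance = 1e-12)
  # glycans on the heavy subunit only; lipids and phospho on the light
  expect_true(all(dis$light$branch == 0) && all(dis$light$Neu5Ac == 0))
  expect_true(all(dis$heavy$PE == 0) && all(dis$heavy$phospho == 0))
  # the phosphorylated light subunit is +79.98 above the bare one
  lm <- dis$light
  expect_equal(min(lm$mass[lm$phospho == 1]) - min(lm$mass[lm$phospho == 0]),
               79.98, tolerance = 1e-9)
  # an adduct-free, glycan-free light subunit sits exactly at the partition
  expect_equal(min(lm$mass), 55000)
  expect_error(dissociate(pop, light_base = 2e5), "light_base")
})

test_that("mass-photometry events follow the configured mixture", {
  comp <- data.frame(mean = c(177, 341), sigma = c(8, 12),
                     weight = c(0.8, 0.2))
  ev <- sample_mp_events(comp, 5000, seed = 3)
  expect_length(ev, 5000)
  expect_identical(as.numeric(ev),
                   as.numeric(sample_mp_events(comp, 5000, seed = 3)))
  # single component: sample mean within 3 sigma / sqrt(n)
  ev1 <- sample_mp_events(data.frame(mean = 177, sigma = 8, weight = 1),
                          4000, seed = 9)
  expect_lt(abs(mean(ev1) - 177), 3 * 8 / sqrt(4000))
  expect_error(sample_mp_events(comp, 0), "positive")
})
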