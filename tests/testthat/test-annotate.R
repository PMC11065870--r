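# Lattice base inference, P/aF assignment, sialic census, envelope
# decomposition, adduct share and adduct labelling.

make_md <- function(mass, abundance) mass_distribution(mass, abundance)

test_that("infer_base_mass recovers a known lattice base", {
  base <- 135566.8
  sp <- residue_mass("branch", "average")
  masses <- base + sp * (0:9)
  md <- make_md(masses, dnorm(0:9, 4, 2))
  fit <- infer_base_mass(md, sp, window = c(base - 180, base + 180))
  expect_lt(abs(fit$base - base), 1)
  # translation equivariance
  md2 <- make_md(masses + 500, dnorm(0:9, 4, 2))
  fit2 <- infer_base_mass(md2, sp, window = c(base + 320, base + 680))
  expect_equal(fit2$base - fit$base, 500, tolerance = 1e-6)
  expect_error(infer_base_mass(make_md(base, 1), sp), "3 lattice peaks")
})

test_that("assign_lattice labels P and aF series and flags degeneracies", {
  base <- 135566.8
  spb <- residue_mass("branch", "average")
  spf <- residue_mass("Fuc", "average")
  md <- make_md(c(base, base + 3 * spb + 2 * spf, base + 2 * spb),
                c(1, 0.5, 0.8))
  res <- assign_lattice(md, base, c(branch = 10, Fuc = 4), tol = 0.5)
  a <- res$assignments
  expect_equal(nrow(a), 3L)
  i0 <- which.min(abs(a$mass - base))
  expect_equal(a$label_P[i0], 1L)
  expect_equal(a$label_aF[i0], 0L)
  expect_equal(a$error_Da[i0], 0, tolerance = 1e-9)
  i1 <- which.min(abs(a$mass - (base + 3 * spb + 2 * spf)))
  expect_equal(a$label_P[i1], 4L)   # +3 branches above the base
  expect_equal(a$label_aF[i1], 2L)
  # the 2 x branch peak carries the Fuc^5 degeneracy when Fuc range allows
  md2 <- make_md(base + c(730.67, 730.71), c(1, 1))
  res2 <- assign_lattice(md2, base, c(branch = 2, Fuc = 5), tol = 0.5,
                         gap = 0.01)
  expect_true(all(res2$assignments$n_candidates >= 2))
  # primary label prefers the fewest residues among near-ties
  expect_equal(res2$assignments$composition[1], "branch2")
  # every input peak appears exactly once across assigned + unassigned
  expect_equal(nrow(res2$assignments) + nrow(res2$unassigned), 2L)
})

test_that("unmatchable peaks are listed, not dropped", {
  base <- 135566.8
  md <- make_md(c(base, base + 50), c(1, 1))
  res <- assign_lattice(md, base, c(branch = 5, Fuc = 4), tol = 2)
  expect_equal(nrow(res$assignments), 1L)
  expect_equal(nrow(res$unassigned), 1L)
  expect_equal(res$unassigned$mass, base + 50)
})

test_that("sialic census is exact on noise-free synthetic pairs", {
  cfg <- wt_glycan_only_config(seed = 5, n = 5000)
  pop <- sample_proteoforms(cfg)
  des <- apply_neuraminidase(pop)
  cen <- sialic_census(make_md(pop$mass, pop$abundance),
                       make_md(des$mass, des$abundance),
                       tol = 0.5, gap = 0.5)
  expect_equal(cen$range, c(9, 16))
  expect_equal(cen$coverage, 1)
  expect_lt(max(abs(cen$per_peak$residual)), 1e-6)
  # identical inputs -> all k zero
  cen0 <- sialic_census(make_md(des$mass, des$abundance),
                        make_md(des$mass, des$abundance),
                        tol = 0.5, gap = 0.5)
  expect_equal(unique(cen0$per_peak$k), 0)
  # a single pair differing by 13 sialic acids
  cen13 <- sialic_census(make_md(140814.5, 1), make_md(137028.2, 1), tol = 0.5)
  expect_equal(cen13$per_peak$k, 13)
})

test_that("envelope decomposition separates overlapping Gaussians", {
  x <- 1:12
  y2 <- 3 * exp(-0.5 * ((x - 5) / 1.3)^2) + 1.8 * exp(-0.5 * ((x - 8) / 1.2)^2)
  fit <- envelope_decompose(y2, k = 2)
  expect_true(fit$converged)
  expect_equal(fit$components$mean, c(5, 8), tolerance = 0.2)
  expect_true(all(fit$components$present))
  # single-Gaussian data: the second component is flagged absent
  y1 <- 3 * exp(-0.5 * ((x - 6) / 1.5)^2)
  fit1 <- envelope_decompose(y1, k = 2)
  amp <- sort(fit1$components$amplitude)
  expect_lt(amp[1], 0.1 * amp[2])
  expect_false(all(fit1$components$present))
  # nested models: k=1 on bimodal data fits worse than k=2
  fitk1 <- envelope_decompose(y2, k = 1)
  expect_gt(fitk1$residual_norm, fit$residual_norm)
  expect_error(envelope_decompose(y2[1:4], k = 2), "2k\\+1")
})

test_that("adduct_share recovers the bound fraction with CI", {
  S <- dnorm(1:12, 5, 1.5); S <- S / sum(S)
  shift2 <- c(0, 0, S[1:10])
  I <- 0.7 * S + 0.3 * shift2
  fit <- adduct_share(I, S, adduct = 730.67, seed = 11)
  expect_equal(fit$steps, 2L)
  expect_equal(fit$f, 0.3, tolerance = 0.01)
  expect_true(fit$ci[1] <= fit$f && fit$f <= fit$ci[2])
  # null case
  fit0 <- adduct_share(S, S, adduct = 730.67, seed = 11)
  expect_lte(fit0$f, 0.02)
  # scale invariance in both arguments
  fit_sc <- adduct_share(I * 37, S * 0.01, adduct = 730.67, seed = 11)
  expect_equal(fit_sc$f, fit$f, tolerance = 1e-12)
  # PE (731 Da) shifts by exactly two branch lattice steps
  fit_pe <- adduct_share(I, S, adduct = 731, seed = 11)
  expect_equal(fit_pe$steps, 2L)
  # an off-lattice adduct is rejected explicitly
  expect_error(adduct_share(I, S, adduct = 79.98), "lattice")
})

test_that("adduct_share recovery holds on sampled dissociation pairs", {
  # forward model: complex series = (1-f) subunit + f PE-shifted subunit
  f <- 0.3
  S <- dnorm(1:10, 4, 1.6); S <- S / sum(S)
  I <- (1 - f) * S + f * c(0, 0, S[1:8])
  noisy <- with_seed(21, pmax(I + rnorm(10, 0, 0.01 * max(I)), 0))
  fit <- adduct_share(noisy, S, adduct = 731, seed = 21)
  expect_lt(abs(fit$f - 0.3), 0.05)
})

test_that("annotate_adducts matches phospho and palmitoyl residuals", {
  base <- 127027
  spb <- residue_mass("branch", "average")
  md <- make_md(c(base, base + spb + 79.98, base + 238.41, base + 2 * spb),
                c(1, 0.4, 0.3, 0.8))
  out <- annotate_adducts(md, base, adducts = adduct_table()[
    adduct_table()$name %in% c("phospho", "palmitoyl"), ],
    ranges = c(branch = 6), tol = 0.5)
  lab <- out$labelled
  expect_equal(nrow(lab), 4L)
  expect_equal(lab$adducts[which.min(abs(lab$mass - base))], "-")
  expect_equal(lab$adducts[which.min(abs(lab$mass - (base + spb + 79.98)))],
               "phospho1")
  expect_equal(lab$adducts[which.min(abs(lab$mass - (base + 238.41)))],
               "palmitoyl1")
  # glycan-only interpretations win when available
  expect_equal(lab$adducts[which.min(abs(lab$mass - (base + 2 * spb)))], "-")
})
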