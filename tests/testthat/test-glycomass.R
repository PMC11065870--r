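# Residue mass arithmetic, combinatorial ladders, composition search and
# degeneracy grouping.

test_that("average residue masses match the printed glycobiology values", {
  # 2-dp reference values; agreement required within 0.01 Da
  expect_equal(residue_mass("Fuc", "average"), 146.14, tolerance = 1e-4)
  expect_equal(residue_mass("Neu5Ac", "average"), 291.26, tolerance = 1e-4)
  expect_lt(abs(residue_mass("branch", "average") - 365.33), 0.01)
  # branch is HexNAc + Hex (to float addition precision)
  expect_equal(residue_mass("branch", "average"),
               residue_mass("HexNAc", "average") +
                 residue_mass("Hex", "average"), tolerance = 1e-12)
  expect_equal(residue_mass("branch", "mono"),
               residue_mass("HexNAc", "mono") + residue_mass("Hex", "mono"),
               tolerance = 1e-12)
})

test_that("monoisotopic masses come out of the atomic composition", {
  expect_equal(residue_mass("Neu5Ac", "mono"), 291.0954, tolerance = 1e-6)
  expect_equal(formula_mass("C6H10O4", "mono"), residue_mass("Fuc", "mono"))
})

test_that("unknown residues and elements raise lookup errors", {
  expect_error(residue_mass("Xyl", "average"), "unknown residue")
  expect_error(formula_mass("C6Qq2", "mono"), "unknown element|cannot parse")
  expect_error(residue_mass("Fuc"), "missing|kind")
})

test_that("composition mass is additive, order-independent and validated", {
  expect_identical(composition_mass(c(), "average"), 0)
  a <- c(branch = 1L, Neu5Ac = 1L)
  b <- c(Fuc = 3L)
  expect_equal(composition_mass(c(a, b), "average"),
               composition_mass(a, "average") + composition_mass(b, "average"))
  expect_equal(composition_mass(c(Fuc = 3L, branch = 1L, Neu5Ac = 1L), "mono"),
               composition_mass(c(Neu5Ac = 1L, Fuc = 3L, branch = 1L), "mono"))
  expect_equal(composition_mass(c(branch = 1, Neu5Ac = 1, Fuc = 1), "mono"),
               802.3, tolerance = 1e-4)
  expect_equal(composition_mass(c(branch = 2), "average"), 730.67,
               tolerance = 1e-5)
  expect_error(composition_mass(c(Fuc = -1), "average"), "negative")
  expect_error(composition_mass(c(Fuc = 1.5), "average"), "integer")
})

test_that("adding any residue strictly increases the mass", {
  rt <- residue_table()
  base <- c(branch = 2L, Fuc = 1L)
  for (r in rt$name) {
    for (kind in c("mono", "average")) {
      grown <- base
      grown[r] <- (if (r %in% names(grown)) grown[[r]] else 0L) + 1L
      expect_gt(composition_mass(grown, kind, rt),
                composition_mass(base, kind, rt))
    }
  }
})

test_that("enumerate_ladder covers all combinations, sorted, with units", {
  lad <- enumerate_ladder(c(Fuc = 1, Neu5Ac = 1), "average")
  expect_equal(nrow(lad), 4L)
  expect_equal(lad$delta_Da, sort(lad$delta_Da))
  expect_equal(round(lad$delta_Da, 2), c(0, 146.14, 291.26, 437.40))
  expect_equal(lad$units, c(0L, 2L, 4L, 6L))
  # degenerate ranges
  lad0 <- enumerate_ladder(c(Fuc = 0, branch = 0), "average")
  expect_equal(nrow(lad0), 1L)
  expect_equal(lad0$delta_Da, 0)
  # the branch^2 / Fuc^5 near-degeneracy is present and 0.04 Da apart
  lad2 <- enumerate_ladder(c(Fuc = 5, branch = 2), "average")
  m2 <- lad2$delta_Da[lad2$composition %in% c("branch2", "Fuc5")]
  expect_equal(round(sort(m2), 2), c(730.67, 730.71))
  expect_equal(diff(sort(m2)), 0.04, tolerance = 0.005)
})

test_that("unit counts follow the 2/4/5 lattice multiplicities", {
  lad <- enumerate_ladder(c(Fuc = 3, Neu5Ac = 2, branch = 2), "average")
  expect_equal(lad$units, 2L * lad$Fuc + 4L * lad$Neu5Ac + 5L * lad$branch)
  # per-unit spacings of the three addition types
  expect_equal(residue_mass("Fuc", "average") / 2, 73.07, tolerance = 1e-4)
  expect_equal(residue_mass("Neu5Ac", "average") / 4, 72.81, tolerance = 1e-4)
  expect_equal(residue_mass("branch", "average") / 5, 73.07, tolerance = 1e-4)
})

test_that("repeat_unit is exact on a uniform ladder and robust to vacancies", {
  expect_equal(repeat_unit(73 * (0:9), merge_tol = 1.5),
               list(mean = 73, sd = 0, n_spacings = 9L,
                    collapsed = 73 * (0:9)),
               tolerance = 1e-12)
  # a missing tooth is split into integer multiples, leaving mean and sd
  gappy <- 73 * c(0:3, 5:9)
  ru <- repeat_unit(gappy)
  expect_equal(ru$mean, 73, tolerance = 1e-9)
  expect_equal(ru$sd, 0, tolerance = 1e-9)
  expect_error(repeat_unit(c(1, 2)), "3 distinct")
  expect_error(repeat_unit(c(0, 0.5, 1), merge_tol = 1.5), "collapsed")
})

test_that("the full combinatorial ladder repeats at ~72.95 Da", {
  lad <- enumerate_ladder(c(Fuc = 6, Neu5Ac = 16, branch = 10), "average")
  ru <- repeat_unit(lad, merge_tol = 1.5)
  expect_lt(abs(ru$mean - 72.95), 0.69)
  expect_lte(ru$sd, 0.69)
})

test_that("find_compositions is exhaustive, tolerance-bounded and ordered", {
  ranges <- c(Fuc = 4, Neu5Ac = 2, branch = 2)
  # strict tolerance: only the sialylation interpretation
  hit <- find_compositions(291.26, 0.5, ranges, "average")
  expect_equal(hit$composition, "Neu5Ac1")
  expect_lt(abs(hit$error_Da), 0.01)
  # at 1.1 Da the 2xFuc interpretation joins, ordered by |error|
  hit2 <- find_compositions(291.26, 1.1, ranges, "average")
  expect_equal(hit2$composition, c("Neu5Ac1", "Fuc2"))
  expect_equal(hit2$error_Da[2], 1.02, tolerance = 0.01)
  # delta 0 matches only the empty composition
  hit0 <- find_compositions(0, 0.5, ranges, "average")
  expect_equal(hit0$composition, "-")
  # branch + Neu5Ac near 657
  hit3 <- find_compositions(657.0, 1.0, ranges, "average")
  expect_equal(hit3$composition[1], "Neu5Ac1 branch1")
  expect_equal(hit3$error_Da[1], -0.41, tolerance = 0.01)
  # no candidate -> zero rows, not an error
  expect_equal(nrow(find_compositions(50, 0.5, ranges, "average")), 0L)
  expect_error(find_compositions(100, 0, ranges, "average"), "tol")
})

test_that("find_compositions agrees with independent brute-force search", {
  ranges <- c(Fuc = 5, Neu5Ac = 4, branch = 4)
  masses <- c(Fuc = residue_mass("Fuc", "average"),
              Neu5Ac = residue_mass("Neu5Ac", "average"),
              branch = residue_mass("branch", "average"))
  # oracle: direct triple loop
  oracle <- function(delta, tol) {
    out <- 0L
    for (a in 0:5) for (b in 0:4) for (c in 0:4) {
      m <- a * masses[["Fuc"]] + b * masses[["Neu5Ac"]] + c * masses[["branch"]]
      if (abs(m - delta) <= tol) out <- out + 1L
    }
    out
  }
  for (delta in seq(0, 2000, by = 137)) {
    expect_equal(nrow(find_compositions(delta, 1.0, ranges, "average")),
                 oracle(delta, 1.0), info = paste("delta", delta))
  }
})

test_that("degeneracy_report groups transitively by mass proximity", {
  lad <- enumerate_ladder(c(Fuc = 5, Neu5Ac = 1, branch = 2), "average")
  rep1 <- degeneracy_report(lad, tol = 0.1)
  g <- rep1$entries
  expect_equal(g$group_id[g$composition == "branch2"],
               g$group_id[g$composition == "Fuc5"])
  expect_true(all(rep1$groups$span_Da[rep1$groups$n > 1] <=
                    0.1 * (rep1$groups$n[rep1$groups$n > 1] - 1)))
  # tol 0 -> all distinct masses singletons
  rep0 <- degeneracy_report(lad, tol = 0)
  expect_equal(max(rep0$groups$n), 1L)
  # tol 1.1 groups Neu5Ac with 2xFuc
  rep2 <- degeneracy_report(lad, tol = 1.1)
  g2 <- rep2$entries
  expect_equal(g2$group_id[g2$composition == "Neu5Ac1"],
               g2$group_id[g2$composition == "Fuc2"])
})

test_that("adduct table holds the printed adduct masses", {
  at <- adduct_table()
  expect_equal(adduct_mass("phospho"), 79.98)
  expect_equal(adduct_mass("palmitoyl"), 238.41)
  expect_equal(adduct_mass(c("PE", "PS", "PI")), c(731, 796, 870))
  expect_true(all(at$mass > 0))
  expect_error(adduct_mass("cholesterol"), "unknown adduct")
})
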