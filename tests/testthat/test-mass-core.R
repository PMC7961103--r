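test_that("diacyl PC sum formulas follow the C(n+8) H(2n+16-2d) N O8 P rule", {
  expect_equal(format(pc_sum_formula(32, 0)), "C40H80NO8P")
  expect_equal(format(pc_sum_formula(36, 4)), "C44H80NO8P")
  expect_equal(format(pc_sum_formula(32, 1)), "C40H78NO8P")
  # structural properties over a grid of species
  for (n in as.integer(seq(24, 44, 2))) {
    for (d in 0:6) {
      f <- pc_sum_formula(n, d)
      expect_identical(formula_count(f, "C"), n + 8L)
      expect_identical(formula_count(f, "H") %% 2L, 0L)
      expect_identical(formula_count(f, "H"), 2L * n + 16L - 2L * d)
    }
  }
  expect_error(pc_sum_formula(-2, 0), "invalid")
  expect_error(pc_sum_formula(1, 0), "invalid")
  expect_error(pc_sum_formula(8, 12), "infeasible")
})

test_that("label substitution conserves atoms and rejects overflow", {
  f <- pc_sum_formula(32, 0)
  d9 <- apply_label(f, label_spec(nD = 9, name = "D9"))
  expect_identical(formula_count(d9, "D"), 9L)
  expect_identical(formula_count(d9, "H"), 71L)
  u13 <- apply_label(f, label_spec(n13C = 40))
  expect_identical(formula_count(u13, "13C"), 40L)
  expect_identical(formula_count(u13, "C"), 0L)
  part <- apply_label(pc_sum_formula(36, 4), label_spec(n13C = 24))
  expect_identical(formula_count(part, "13C"), 24L)
  expect_identical(formula_count(part, "C"), 20L)
  # total carbon and hydrogen are conserved across any substitution
  for (lab in list(label_spec(5, 0), label_spec(0, 9), label_spec(24, 9))) {
    g <- apply_label(f, lab)
    expect_identical(formula_count(g, "C") + formula_count(g, "13C"), 40L)
    expect_identical(formula_count(g, "H") + formula_count(g, "D"), 80L)
  }
  expect_error(apply_label(f, label_spec(n13C = 41)), "overflow")
  expect_error(apply_label(f, label_spec(nD = 81)), "overflow")
})

test_that("monoisotopic masses match the anchored atomic-mass table", {
  expect_equal(monoisotopic_mass(pc_sum_formula(32, 0)), 733.562153,
               tolerance = 1e-5 / 733)
  expect_identical(monoisotopic_mass(elemental_formula()), 0)
  expect_equal(monoisotopic_mass(elemental_formula("13C" = 1)), 13.003355,
               tolerance = 1e-6)
  expect_error(elemental_formula(Xx = 1), "unsupported")
})

test_that("adduct m/z uses the electron-subtracted cation convention", {
  nm <- monoisotopic_mass(pc_sum_formula(32, 0))
  expect_equal(adduct_mz(nm, "Na"), 756.551374, tolerance = 0.01e-6 * 756)
  expect_equal(adduct_mz(nm, "H"), 734.569429, tolerance = 1e-5 / 734)
  expect_equal(adduct_mz(0, "H"), 1.007276, tolerance = 1e-6)
  expect_error(adduct_mz(-1, "Na"), "non-negative")
})

test_that("ppm error is the signed relative deviation in parts per million", {
  expect_identical(ppm_error(756.5514, 756.5514), 0)
  expect_equal(ppm_error(756.552, 756.551), (0.001 / 756.551) * 1e6)
  expect_error(ppm_error(500, 0), "positive")
  # antisymmetry relation: ppm(a,b) = -ppm(b,a) * a/b exactly, and the
  # plain sign flip holds to first order in the deviation
  for (pair in list(c(756.5514, 756.5517), c(400.1, 400.0), c(828.63, 828.64))) {
    a <- pair[1]; b <- pair[2]
    expect_equal(ppm_error(a, b), -ppm_error(b, a) * (a / b), tolerance = 1e-12)
    expect_equal(ppm_error(a, b), -ppm_error(b, a),
                 tolerance = 2 * abs(ppm_error(a, b)) * 1e-6 + 1e-12)
  }
})

test_that("resolving power uses the FWHM separation criterion", {
  expect_equal(resolving_power_required(765.6079, 765.6179), 76561, tolerance = 1 / 76561)
  expect_equal(resolving_power_required(400.0, 400.1), 400.05 / 0.1, tolerance = 1e-9)
  d9_na <- theoretical_mz("D9-PC32:0")
  expect_equal(resolving_power_required(d9_na, d9_na - 0.009), 85067,
               tolerance = 3 / 85067)
  expect_error(resolving_power_required(500, 500), "resolved")
})

test_that("label mass additivity holds for every species and label", {
  species <- list(pc_sum_formula(32, 0), pc_sum_formula(36, 4),
                  pc_sum_formula(34, 1), pc_sum_formula(38, 6))
  labels <- list(label_spec(0, 9), label_spec(5, 0), label_spec(24, 0),
                 label_spec(13, 4))
  for (f in species) {
    for (lab in labels) {
      for (ad in c("H", "Na", "K")) {
        shift <- adduct_mz(apply_label(f, lab), ad) - adduct_mz(f, ad)
        expect_equal(shift, lab$n13C * 1.0033548 + lab$nD * 1.0062767,
                     tolerance = 1e-6 / max(shift, 1))
      }
    }
  }
})

test_that("mass is additive over formula union", {
  f1 <- pc_sum_formula(32, 0)
  f2 <- elemental_formula(C = 3, H = 9, N = 1)
  expect_equal(monoisotopic_mass(f1) + monoisotopic_mass(f2),
               monoisotopic_mass(f1 + f2), tolerance = 1e-9 / 800)
})

test_that("formula strings parse back to the same object", {
  for (f in list(pc_sum_formula(32, 0),
                 apply_label(pc_sum_formula(36, 4), label_spec(24, 0)),
                 apply_label(pc_sum_formula(32, 0), label_spec(0, 9)))) {
    expect_equal(monoisotopic_mass(parse_formula(format(f))),
                 monoisotopic_mass(f))
  }
  expect_error(parse_formula("C40Zz2"), "parse")
})

test_that("species naming follows the sum/underscore/slash convention", {
  expect_equal(format(lipid_species(36, 4)), "PC36:4")
  sp <- lipid_species(chains = list(c(16, 0), c(20, 4)))
  expect_equal(format(sp), "PC16:0_20:4")
  sp_sn <- lipid_species(chains = list(c(16, 0), c(16, 0)), sn_defined = TRUE)
  expect_equal(format(sp_sn), "PC16:0/16:0")
  expect_equal(format(parse_species("D9-PC32:0")), "D9-PC32:0")
  expect_equal(formula_count(parse_species("U13C-PC32:0")$formula, "13C"), 40L)
  expect_error(lipid_species(chains = list(c(16, 0), c(20, 4)),
                             total_carbons = 38, double_bonds = 4), "sum")
})
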