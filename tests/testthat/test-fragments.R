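test_that("sodiated 13C24 remodelling product yields the 62/188 losses", {
  pred <- predict_pc_fragments("13C24-PC16:0_20:4", adduct = "Na")
  tma <- pred[grepl("N\\(CH3\\)3", pred$name), ]
  pchol <- pred[grepl("^-PC", pred$name), ]
  expect_identical(tma$loss_nominal, 62L)
  expect_identical(pchol$loss_nominal, 188L)
  expect_equal(round(tma$fragment_mz, 4), 766.5483)
  expect_equal(round(pchol$fragment_mz, 4), 640.5491)
  expect_true(all(pred$carries_label))
})

test_that("measured remodelling fragments show -0.6 ppm against prediction", {
  pred <- predict_pc_fragments("13C24-PC16:0_20:4", adduct = "Na")
  spectrum <- tibble::tibble(mz = c(500.1, 640.5487, 766.5479, 828.6321),
                             intensity = c(5, 40, 60, 100))
  ann <- annotate_msms(spectrum, pred, tol_ppm = 5)
  expect_true(all(ann$matched))
  expect_equal(round(ann$ppm, 1), c(-0.6, -0.6))
})

test_that("protonated precursors give the 184/193/189 headgroup cations", {
  unlab <- predict_pc_fragments("PC32:0", adduct = "H")
  d9 <- predict_pc_fragments("D9-PC32:0", adduct = "H")
  c5 <- predict_pc_fragments("13C5-PC32:0", adduct = "H")
  expect_identical(unlab$loss_nominal, 184L)
  expect_identical(d9$loss_nominal, 193L)
  expect_identical(c5$loss_nominal, 189L)
  expect_equal(round(unlab$fragment_mz, 4), 184.0733)
  expect_equal(round(d9$fragment_mz, 4), 193.1298)
  expect_equal(round(c5$fragment_mz, 4), 189.0901)
  expect_identical(unlab$type, "headgroup_cation")
})

test_that("mass closure holds for every neutral-loss prediction", {
  species <- c("PC32:0", "D9-PC32:0", "13C5-PC34:1", "U13C-PC32:0",
               "13C24-PC16:0_20:4", "PC38:6")
  for (sp in species) {
    for (ad in c("Na", "K")) {
      pred <- predict_pc_fragments(sp, adduct = ad)
      expect_true(all(abs(pred$precursor_mz - pred$fragment_mz -
                            pred$loss_mass) < 1e-9))
    }
  }
})

test_that("headgroup labels cancel out of the loss fragments", {
  ref <- predict_pc_fragments("PC32:0", adduct = "Na")
  # D9 sits entirely on the N-methyls: both headgroup losses carry the
  # whole label away, so labelled and unlabelled fragments coincide
  d9 <- predict_pc_fragments("D9-PC32:0", adduct = "Na")
  expect_equal(d9$fragment_mz, ref$fragment_mz, tolerance = 1e-6 / 700)
  # a 13C5 choline label cancels for the phosphocholine loss (all five
  # carbons leave) but not for trimethylamine (the two CH2 carbons stay)
  c5 <- predict_pc_fragments("13C5-PC32:0", adduct = "Na")
  is_pchol <- grepl("^-PC", ref$name)
  expect_equal(c5$fragment_mz[is_pchol], ref$fragment_mz[is_pchol],
               tolerance = 1e-6 / 700)
  expect_gt(c5$fragment_mz[!is_pchol] - ref$fragment_mz[!is_pchol], 2)
  # the trimethylamine-loss fragment of sodiated PC32:0, labelled or not
  expect_equal(round(ref$fragment_mz[grepl("N\\(CH3\\)3", ref$name)], 4),
               697.4779)
})

test_that("nominal loss masses cover the full label table", {
  nominal <- function(sp) {
    p <- predict_pc_fragments(sp, adduct = "Na")
    stats::setNames(p$loss_nominal, c("tma", "pchol"))
  }
  expect_identical(nominal("PC32:0"), c(tma = 59L, pchol = 183L))
  expect_identical(nominal("13C5-PC32:0"), c(tma = 62L, pchol = 188L))
  expect_identical(nominal("D9-PC32:0"), c(tma = 68L, pchol = 192L))
  # each nominal equals the rounded monoisotopic loss mass
  p <- predict_pc_fragments("13C24-PC16:0_20:4", adduct = "Na")
  expect_identical(p$loss_nominal, as.integer(round(p$loss_mass)))
})

test_that("annotation matches the closed tolerance interval and flags misses", {
  pred <- predict_pc_fragments("PC32:0", adduct = "Na")
  empty <- tibble::tibble(mz = numeric(0), intensity = numeric(0))
  ann <- annotate_msms(empty, pred, tol_ppm = 5)
  expect_false(any(ann$matched))
  # peak exactly at the upper tolerance boundary is matched
  target <- pred$fragment_mz[1]
  boundary <- target + target * 5 * 1e-6
  ann2 <- annotate_msms(tibble::tibble(mz = boundary, intensity = 1),
                        pred, tol_ppm = 5)
  expect_true(ann2$matched[1])
  # most intense in-window peak wins
  ann3 <- annotate_msms(
    tibble::tibble(mz = c(target - target * 2e-6, target + target * 1e-6),
                   intensity = c(5, 50)), pred, tol_ppm = 5)
  expect_equal(ann3$observed_mz[1], target + target * 1e-6)
})

test_that("unknown labels need explicit routing and honour it when given", {
  odd <- lipid_species(32, 0, label = label_spec(n13C = 2, name = "13C2-custom"))
  expect_error(predict_pc_fragments(odd, adduct = "Na"), "routing")
  pred <- predict_pc_fragments(odd, adduct = "Na",
    routing = list(tma = c(n13C = 2L, nD = 0L), pchol = c(n13C = 2L, nD = 0L)))
  expect_identical(pred$loss_nominal, c(61L, 185L))
  expect_error(predict_pc_fragments(odd, adduct = "Na",
    routing = list(tma = c(n13C = 4L, nD = 0L), pchol = c(n13C = 2L, nD = 0L))),
    "exceeds")
})
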