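test_that("GRAVY is the mean Kyte-Doolittle hydropathy", {
  expect_equal(round(gravy("AR"), 2), -1.35)
  expect_equal(round(gravy("IL"), 2), 4.15)
  expect_equal(gravy("G"), -0.40) # single residue equals its scale value
  expect_equal(gravy(c("AA", "GG")), c(1.80, -0.40))
})

test_that("aliphatic index follows Ikai's mole-fraction formula", {
  expect_equal(aliphatic_index("IL"), 390.00)
  expect_equal(aliphatic_index("GG"), 0.00)
  expect_equal(aliphatic_index("VF"), 145.00)
  expect_equal(aliphatic_index("AA"), 100.00)
  expect_equal(round(aliphatic_index("PGL"), 2), 130.00)
})

test_that("Boman index is the mean transfer free energy, hydrophilic-positive", {
  expect_equal(round(boman_index("IL"), 2), -4.92)
  expect_equal(boman_index("AR"), (-1.81 + 14.92) / 2)
  expect_equal(round(boman_index("ER"), 2), round((6.81 + 14.92) / 2, 2))
  # homopolymer equals the residue value exactly
  expect_equal(boman_index("RR"), boman_scale()[["R"]])
})

test_that("net charge sums Henderson-Hasselbalch group contributions", {
  expect_equal(round(net_charge("AR", 7)), 1)
  expect_equal(round(net_charge("QH", 7), 1), 0.1)
  expect_equal(round(net_charge("CF", 7), 1), -0.1)
  # only termini ionize: small negative, zero after rounding
  q_gg <- net_charge("GG", 7)
  expect_lt(q_gg, 0)
  expect_equal(round(q_gg, 1), 0)
  expect_error(net_charge("GG", 15), "pH")
})

test_that("pI is the root of the charge curve; closed forms agree", {
  expect_equal(round(isoelectric_point("AR"), 2), 10.55)
  expect_equal(round(isoelectric_point("EK"), 2), 6.41)
  # no ionizable side chain: midpoint of the terminal pKas
  expect_equal(round(isoelectric_point("GL"), 2), (8.6 + 3.6) / 2)
  expect_equal(round(isoelectric_point("QH"), 2), (8.6 + 6.5) / 2)
})

test_that("charge curve is strictly decreasing and vanishes at the pI", {
  peps <- random_peptides(1000, length_range = c(2, 30), seed = 23)
  pkas <- pka_set("pi")
  grid <- seq(0, 14, by = 0.5)
  for (s in peps$sequence[1:200]) {
    q <- net_charge(rep(s, length(grid)), grid, pkas)
    expect_true(all(diff(q) < 0), label = sprintf("monotone charge for %s", s))
  }
  pis <- isoelectric_point(peps$sequence, pkas)
  expect_true(all(abs(net_charge(peps$sequence, pis, pkas)) < 1e-4))
})

test_that("basic residues raise the pI, acidic residues lower it", {
  peps <- random_peptides(50, length_range = c(2, 20), seed = 29)
  for (s in peps$sequence) {
    base_pi <- isoelectric_point(s)
    expect_gte(isoelectric_point(paste0(s, "K")), base_pi - 1e-9)
    expect_gte(isoelectric_point(paste0(s, "R")), base_pi - 1e-9)
    expect_lte(isoelectric_point(paste0(s, "D")), base_pi + 1e-9)
    expect_lte(isoelectric_point(paste0(s, "E")), base_pi + 1e-9)
  }
})

test_that("instability index weights ordered dipeptides", {
  expect_equal(round(instability_index("IL"), 2), 101.30)
  expect_equal(round(instability_index("TF"), 2), 66.70)
  # both PGL dipeptide weights take the default 1.0
  expect_equal(instability_index("PGL"), (10 / 3) * 2)
  expect_error(instability_index("A"), "single residues")
})

test_that("gravy/boman are permutation-invariant, instability is not", {
  s <- "ILTFKW"
  perm <- "WFTKLI"
  expect_equal(gravy(s), gravy(perm))
  expect_equal(boman_index(s), boman_index(perm))
  expect_false(isTRUE(all.equal(instability_index("TF"), instability_index("FT"))))
})

test_that("solubility follows the charged-residue rule", {
  expect_equal(solubility_class("SK"), "good")
  expect_equal(solubility_class("CF"), "poor")
  expect_equal(solubility_class("DD"), "good")
  expect_equal(solubility_class(c("GG", "QH")), c("poor", "good"))
})

test_that("classification flags apply the published thresholds to unrounded values", {
  prof <- physchem_profile(c("ER", "TF", "GL", "AW"))
  expect_true(prof$high_binding[prof$sequence == "ER"])
  expect_true(prof$unstable[prof$sequence == "TF"])
  expect_true(prof$thermostable[prof$sequence == "GL"])
  expect_false(any(unlist(prof[prof$sequence == "AW", c("high_binding", "unstable", "thermostable")])))
  expect_true(all(prof$pept_transportable))
  expect_false(physchem_profile("KKKKK")$pept_transportable)
  # thresholds are tunable
  strict <- physchem_profile("ER", boman_threshold = 20)
  expect_false(strict$high_binding)
})

test_that("profile assembly matches published reference rows", {
  aw <- format_physchem(physchem_profile("AW"))
  expect_equal(aw$boman, -2.07)
  expect_equal(aw$net_charge, 0)
  expect_equal(aw$pi, 6.10)
  expect_equal(aw$instability, 5.0)
  expect_equal(aw$aliphatic, 50)
  expect_equal(aw$gravy, 0.45)
  expect_equal(aw$solubility, "poor")
  expect_equal(format_physchem(physchem_profile("PW"))$instability, -9.40)
})

test_that("the inconsistent GK row recomputes to the method-consistent values", {
  gk <- physchem_profile("GK")
  expect_equal(round(gk$pi, 2), 9.70)
  expect_equal(round(gk$net_charge), 1)
  expect_equal(round(gk$instability, 2), -37.45)
})
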