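core_fuc_topo <- build_topology(2, sialylation = "a23", core_fucose = TRUE)
antenna_fuc_topo <- build_topology(2, sialylation = "a26", antenna_fucose = 1)

test_that("topology composition matches the construction", {
  expect_equal(topology_composition(core_fuc_topo)$composition, "N4H5SF")
  expect_equal(topology_composition(antenna_fuc_topo)$composition, "N4H5SF")
  tri <- build_topology(3, sialylation = c("a23", "a26", "a23"),
                        antenna_fucose = 2)
  expect_equal(topology_composition(tri)$composition, "N5H6S3F2")
  ng <- build_topology(2, sialylation = "a23", lacnac = 1)
  expect_equal(topology_composition(ng)$composition, "N5H6S")
})

test_that("core-fucose Y series reproduces the printed m/z values", {
  y <- enumerate_fragments(core_fuc_topo, types = "Y", max_cleavages = 2)
  for (v in printed_mz$core_y) {
    expect_true(any(abs(y$mz - v) <= 0.01), info = sprintf("m/z %.2f", v))
  }
})

test_that("antenna-fucose Y series reproduces the printed m/z values", {
  y <- enumerate_fragments(antenna_fuc_topo, types = "Y", max_cleavages = 3)
  for (v in printed_mz$antenna_y) {
    expect_true(any(abs(y$mz - v) <= 0.01), info = sprintf("m/z %.2f", v))
  }
})

test_that("sialic linkage diagnostics match print and the residue-sum oracle", {
  d <- diagnostic_sialic_ions()
  expect_equal(d$diagnostic, c("a26", "a23"))
  # independent arithmetic oracle
  expect_equal(d$mz[d$diagnostic == "a26"],
               291.095417 + 60.021129 - 1.007276 - 43.989829, tolerance = 1e-9)
  expect_equal(d$mz[d$diagnostic == "a23"],
               291.095417 + 162.052824 - 1.007276 - 43.989829, tolerance = 1e-9)
  expect_true(abs(d$mz[1] - printed_mz$a26_diag) <= 0.01)
  expect_true(abs(d$mz[2] - printed_mz$a23_diag) <= 0.01)
})

test_that("single-cleavage B and Y ions conserve the precursor mass", {
  for (topo in list(core_fuc_topo, antenna_fuc_topo,
                    build_topology(4, sialylation = rep("a26", 4)))) {
    fr <- enumerate_fragments(topo, types = c("B", "Y"), max_cleavages = 1,
                              dedupe = FALSE)
    fr <- fr[is.na(fr$diagnostic), ]
    prec <- glycan_mass(topology_composition(topo), labeled = TRUE)
    b <- fr[fr$type == "B", ]
    y <- fr[fr$type == "Y", ]
    # every B ion has a complementary Y summing to the precursor
    for (i in seq_len(nrow(b))) {
      expect_true(any(abs(b$neutral_mass[i] + y$neutral_mass - prec) < 1e-6))
    }
    # C/Z analogues are shifted by +/- one water
    frc <- enumerate_fragments(topo, types = c("C", "Z"), max_cleavages = 1,
                               dedupe = FALSE)
    frc <- frc[is.na(frc$diagnostic), ]
    w <- glyco_masses()$water
    expect_equal(sort(frc$neutral_mass[frc$type == "C"]),
                 sort(b$neutral_mass + w), tolerance = 1e-9)
    expect_equal(sort(frc$neutral_mass[frc$type == "Z"]),
                 sort(y$neutral_mass - w), tolerance = 1e-9)
  }
})

test_that("single-cleavage count is 2E for a B/Y pair before deduplication", {
  set.seed(21)
  for (i in 1:10) {
    topo <- random_topology()
    e <- sum(!is.na(topo$parent))
    fr <- enumerate_fragments(topo, types = c("B", "Y"), max_cleavages = 1,
                              dedupe = FALSE)
    expect_equal(sum(is.na(fr$diagnostic)), 2 * e)
  }
})

test_that("max_cleavages outside 1..3 is rejected", {
  expect_error(enumerate_fragments(core_fuc_topo, max_cleavages = 4),
               "max_cleavages")
  expect_error(enumerate_fragments(core_fuc_topo, max_cleavages = 0),
               "max_cleavages")
})

test_that("spectrum matching respects the ppm tolerance", {
  d <- diagnostic_sialic_ions()
  expect_equal(nrow(match_spectrum(spectrum(306.12), d, 10)), 1)
  expect_equal(nrow(match_spectrum(spectrum(306.50), d, 10)), 0)
  expect_equal(nrow(match_spectrum(spectrum(numeric(0)), d, 10)), 0)
})

test_that("matching is monotone in tolerance and flags ambiguity", {
  set.seed(9)
  cand <- enumerate_fragments(core_fuc_topo, max_cleavages = 2)
  for (i in 1:10) {
    pk <- cand$mz * (1 + stats::rnorm(nrow(cand), 0, 8e-6))
    sp <- spectrum(pk)
    m5 <- match_spectrum(sp, cand, 5)
    m20 <- match_spectrum(sp, cand, 20)
    key <- function(m) paste(m$peak_mz, m$label)
    expect_true(all(key(m5) %in% key(m20)))
  }
  # two candidates within tolerance of one peak -> both reported, ambiguous
  twins <- tibble::tibble(label = c("x", "y"), mz = c(500.000, 500.002))
  m <- match_spectrum(spectrum(500.001), twins, 10)
  expect_equal(nrow(m), 2)
  expect_true(all(m$ambiguous))
})

test_that("diagnostic rules call linkage and fucose position from peak lists", {
  # spectrum shaped like the core-fucosylated alpha-2,3 isomer
  # (printed 2-decimal peaks, so a matching-width tolerance of 20 ppm)
  figA <- spectrum(c(487.19, 690.27, 1014.37, 1176.43, 408.15))
  evA <- assign_isomer_features(figA, "N4H5SF", tol_ppm = 20)
  expect_true(evA$a23_evidence)
  expect_false(evA$a26_evidence)
  expect_true(evA$core_fucose_evidence)
  expect_equal(evA$core_fucose_confidence, "high")
  expect_false(evA$antenna_fucose_evidence)

  # reduced Y1/Y2-only spectrum still called core-fucosylated
  figB <- spectrum(c(487.19, 690.27, 306.12))
  evB <- assign_isomer_features(figB, "N4H5SF", tol_ppm = 20)
  expect_true(evB$core_fucose_evidence)
  expect_equal(evB$core_fucose_confidence, "high")
  # Y1 alone, without the corroborating Y2, gives medium confidence
  y1only <- spectrum(c(487.19, 306.12))
  expect_equal(assign_isomer_features(y1only, "N4H5SF",
                                      tol_ppm = 20)$core_fucose_confidence,
               "medium")

  # antenna-fucosylated alpha-2,6 isomer: fucose-free Y series + large Y ions
  figC <- spectrum(c(341.13, 544.21, 1233.45, 1395.51, 306.12))
  evC <- assign_isomer_features(figC, "N4H5SF", tol_ppm = 20)
  expect_true(evC$a26_evidence)
  expect_false(evC$a23_evidence)
  expect_false(evC$core_fucose_evidence)
  expect_true(evC$antenna_fucose_evidence)

  # both diagnostics present -> mixed linkage evidence
  mixed <- spectrum(c(306.12, 408.15))
  evM <- assign_isomer_features(mixed, "N4H5S2", tol_ppm = 20)
  expect_true(evM$a23_evidence && evM$a26_evidence)

  # intensity threshold suppresses weak diagnostic peaks
  weak <- spectrum(c(487.19, 408.15), intensity = c(100, 0.5))
  evW <- assign_isomer_features(weak, "N4H5SF", tol_ppm = 20, min_intensity = 1)
  expect_false(evW$a23_evidence)
  expect_true(evW$core_fucose_evidence)
})

test_that("a precursor inconsistent with the stated composition errors", {
  sp <- spectrum(c(487.19), precursor_mz = 1500.0, charge = 1L)
  expect_error(assign_isomer_features(sp, "N4H5SF"), "precursor")
})

test_that("generated spectra are assigned the tags their topology carries", {
  cases <- list(
    list(topo = build_topology(2, "a23", core_fucose = TRUE),
         a23 = TRUE, a26 = FALSE, core = TRUE, antenna = FALSE),
    list(topo = build_topology(2, "a26", antenna_fucose = 1),
         a23 = FALSE, a26 = TRUE, core = FALSE, antenna = TRUE),
    list(topo = build_topology(2, c("a23", "a26")),
         a23 = TRUE, a26 = TRUE, core = FALSE, antenna = FALSE)
  )
  for (cs in cases) {
    sp <- generate_spectrum(cs$topo, n_noise_peaks = 15, seed = 31)
    ev <- assign_isomer_features(sp, topology_composition(cs$topo))
    expect_equal(ev$a23_evidence, cs$a23)
    expect_equal(ev$a26_evidence, cs$a26)
    expect_equal(ev$core_fucose_evidence, cs$core)
    expect_equal(ev$antenna_fucose_evidence, cs$antenna)
  }
})
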