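test_that("peptide composition is the residue sum plus one water", {
  gg <- composition_of_peptide("GG")
  expect_equal(unclass(gg)[c("C", "H", "N", "O", "S")],
               c(C = 4L, H = 8L, N = 2L, O = 3L, S = 0L))
  # concatenation identity: composition("AB") = composition(A) + composition(B) - water
  a <- unclass(composition_of_peptide("AY"))
  b <- unclass(composition_of_peptide("GR"))
  ab <- unclass(composition_of_peptide("AYGR"))
  water <- c(C = 0L, H = 2L, N = 0L, O = 1L, S = 0L)
  expect_equal(ab, a + b - water)
})

test_that("composition rejects empty and unknown sequences, naming the offender", {
  expect_error(composition_of_peptide(""), "empty")
  expect_error(composition_of_peptide("AXR"), "'X' at position 2")
})

test_that("monoisotopic mass matches independent residue-mass summation", {
  seqs <- c("ASYSAVSLYGNPVR", "GG", "LVEVNPK", "TSYAELLGR")
  for (s in seqs) {
    expected <- sum(RESIDUE_MONO_MASS[strsplit(s, "")[[1]]]) + WATER_MONO_MASS
    expect_equal(monoisotopic_mass(composition_of_peptide(s)), expected,
                 tolerance = 0.001 / expected)
  }
  expect_equal(monoisotopic_mass(composition_of_peptide("ASYSAVSLYGNPVR")),
               1482.74, tolerance = 0.01 / 1482.74)
})

test_that("natural envelope reproduces defining single-element abundances", {
  c1 <- structure(c(C = 1L, H = 0L, N = 0L, O = 0L, S = 0L),
                  class = "elemental_composition")
  env <- natural_envelope(c1, n_peaks = 2)
  expect_equal(as.numeric(env), c(0.9893, 0.0107), tolerance = 1e-12)
  expect_warning(one <- natural_envelope(composition_of_peptide("GG"), 1),
                 "tail mass")
  expect_equal(as.numeric(one), 1)
  expect_error(natural_envelope(structure(c(C = 0L, H = 0L, N = 0L, O = 0L, S = 0L),
                                          class = "elemental_composition")),
               "all-zero")
})

test_that("natural envelope matches the exhaustive-enumeration oracle", {
  cases <- list(
    composition_of_peptide("GG"),                       # C4 H8 N2 O3
    composition_of_peptide("AG"),                       # small mixed
    structure(c(C = 3L, H = 4L, N = 2L, O = 2L, S = 1L),
              class = "elemental_composition"),         # includes sulfur
    structure(c(C = 10L, H = 6L, N = 0L, O = 4L, S = 0L),
              class = "elemental_composition")
  )
  for (comp in cases) {
    got <- as.numeric(natural_envelope(comp, n_peaks = 5))
    want <- oracle_envelope(as.list(unclass(comp)), n_peaks = 5)
    expect_equal(got, want, tolerance = 1e-9)
    expect_equal(sum(got), 1, tolerance = 1e-9)
  }
})

test_that("labeled envelope reduces to natural at p = 0 or zero sites", {
  comp <- composition_of_peptide("ASYSAVSLYGNPVR")
  nat <- as.numeric(natural_envelope(comp))
  expect_equal(as.numeric(labeled_envelope(comp, 10, 0)), nat, tolerance = 1e-12)
  expect_equal(as.numeric(labeled_envelope(comp, 0, 0.055)), nat, tolerance = 1e-12)
  expect_error(labeled_envelope(comp, 10, 0.25), "0, 0.2")
  expect_error(labeled_envelope(comp, 1e5, 0.05), "total H")
})

test_that("labeled envelope matches the enriched-channel enumeration oracle", {
  comp <- composition_of_peptide("GG")
  counts <- as.list(unclass(comp))
  for (n_ex in c(2L, 4L)) {
    for (p in c(0.02, 0.055)) {
      got <- as.numeric(labeled_envelope(comp, n_ex, p))
      want <- oracle_labeled_envelope(counts, n_ex, p, 5)
      expect_equal(got, want, tolerance = 1e-9)
    }
  }
  # larger peptide, M0 strictly below natural
  dcn <- composition_of_peptide("ASYSAVSLYGNPVR")
  lab <- labeled_envelope(dcn, exchangeable_hydrogens("ASYSAVSLYGNPVR"), 0.055)
  expect_lt(lab[1], natural_envelope(dcn)[1])
})

test_that("labeled M0 is strictly decreasing in p and in site count", {
  comp <- composition_of_peptide("LVEVNPK")
  ps <- c(0.01, 0.03, 0.055, 0.08)
  m0p <- vapply(ps, function(p) labeled_envelope(comp, 10, p)[1], numeric(1))
  expect_true(all(diff(m0p) < 0))
  ns <- c(0.5, 2, 5.5, 9, 12.25)
  m0n <- vapply(ns, function(n) labeled_envelope(comp, n, 0.055)[1], numeric(1))
  expect_true(all(diff(m0n) < 0))
})

test_that("expected M0 decay has the right anchors, asymptote and midpoint", {
  nat <- 0.45; plat <- 0.10
  expect_equal(expected_M0(0, 0.02, nat, plat), nat)
  expect_equal(expected_M0(1e6, 0.02, nat, plat), plat, tolerance = 1e-12)
  k <- log(2) / 32.8
  expect_equal(expected_M0(32.8, k, nat, plat), (nat + plat) / 2,
               tolerance = 1e-15)
  ts <- seq(0, 120, by = 7.5)
  expect_true(all(diff(expected_M0(ts, 0.03, nat, plat)) < 0))
  expect_error(expected_M0(-1, 0.02, nat, plat), "negative")
})
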