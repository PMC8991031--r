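test_that("generation is deterministic given (config, seed)", {
  cfg <- tiny_config(noise = list(area_cv = 0.02, ratio_sd = 0.02,
                                  serum_cv = 0.02))
  a <- generate_study(cfg, seed = 7)
  b <- generate_study(cfg, seed = 7)
  expect_identical(a$peptides, b$peptides)
  expect_identical(a$serum, b$serum)
  expect_identical(a$nucleic, b$nucleic)
  d <- generate_study(cfg, seed = 8)
  expect_false(identical(a$peptides$area, d$peptides$area))

  # byte-identical CSV emission
  t1 <- withr::local_tempdir()
  t2 <- withr::local_tempdir()
  generate_study(cfg, seed = 7, dir = t1)
  generate_study(cfg, seed = 7, dir = t2)
  for (f in c("serum.csv", "peptides.csv", "nucleic.csv")) {
    expect_identical(unname(tools::md5sum(file.path(t1, f))),
                     unname(tools::md5sum(file.path(t2, f))))
  }
})

test_that("invalid configurations are rejected listing every violation", {
  cfg <- tiny_config()
  cfg$truth$k_per_d[1] <- -0.1
  cfg$groups$n_animals[1] <- 0
  err <- tryCatch(validate_config(cfg), error = function(e) conditionMessage(e))
  expect_match(err, "rate constants")
  expect_match(err, "group sizes")
})

test_that("noise-free envelopes are emitted normalized per peptide row-set", {
  st <- generate_study(tiny_config(), seed = 1)
  pep <- st$peptides[st$peptides$protein != "BSA_STD", ]
  key <- interaction(pep$protein, pep$peptide, pep$animal_id, drop = TRUE)
  rel_sums <- tapply(pep$area, key, function(a) sum(a / sum(a)))
  expect_true(all(abs(rel_sums - 1) < 1e-12))
})

test_that("generator leaves the global RNG stream untouched", {
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(generate_study(tiny_config(), seed = 99))
  expect_identical(runif(1), before)
})

test_that("reference-seeded truth reproduces the printed kinetic anchors", {
  cfg <- paper_like_truth()
  tr <- cfg$truth
  prg4 <- tr[tr$protein == "PRG4" & tr$group == "25wk", ]
  expect_equal(log(2) / prg4$k_per_d, 32.8, tolerance = 0.02)
  col2 <- tr[tr$protein == "COL2A1", ]
  expect_true(all(col2$k_per_d == 0))
  col1 <- tr[tr$protein == "COL1A1" & tr$group == "25wk", ]
  expect_equal(log(2) / col1$k_per_d, 3081, tolerance = 0.02)
  expect_true(all(cfg$nucleic$F == 0.6))
  # DCN concentration is unreconstructable (fold exactly 1) -> placeholder
  expect_true(all(tr$placeholder[tr$protein == "DCN"]))
  expect_true("ASYSAVSLYGNPVR" %in% cfg$proteins$peptide[cfg$proteins$protein == "DCN"])
})

test_that("YAML configurations map onto study_config with defaults", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "precursor: {p_0: 0.01, p_max: 0.06, k_p: 0.4}",
    "noise: {area_cv: 0.0, ratio_sd: 0.0, serum_cv: 0.0}",
    "n_unlabeled: 2"
  ), f)
  cfg <- study_config_from_yaml(f)
  expect_s3_class(cfg, "study_config")
  expect_equal(cfg$precursor$p_max, 0.06)
  expect_equal(cfg$n_unlabeled, 2L)
  expect_equal(cfg$n_peaks, 5L)  # default retained
  writeLines("bogus_key: 1", f)
  expect_error(study_config_from_yaml(f), "unknown configuration key")
})

test_that("age effects with true fold >= 1.5 are detected by the Welch/BH layer", {
  hits <- vapply(1:3, function(s) {
    st <- generate_study(study_config(), seed = s)
    rep <- run_pipeline(st$peptides, st$serum)
    cmp <- rep$comparisons$concentration
    big <- c("PRG4", "CLU", "FMOD", "ACAN")  # true conc fold 2.02/2.37/0.52/1.96
    flagged <- cmp$bh_significant[match(big, cmp$protein)]
    null_flag <- cmp$bh_significant[cmp$protein == "DCN"]  # true fold 1.00
    mean(flagged) >= 0.75 && !null_flag
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})
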