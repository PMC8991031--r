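test_that("peptide table reader validates rows and reports errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "protein,peptide,animal_id,age_group,label_days,isotopomer_index,area",
    "P1,LVEVNPK,a1,25wk,15,0,1000",
    "P1,LVEVNPK,a1,25wk,15,1,500",
    "P1,LVEVNPK,a2,25wk,30,0,900"
  ), f)
  tab <- read_peptide_table(f)
  expect_equal(nrow(tab), 3L)
  expect_length(attr(tab, "row_errors"), 0L)

  writeLines(c(
    "protein,peptide,animal_id,age_group,label_days,isotopomer_index,area",
    "P1,LVEVNPK,a1,25wk,15,0,1000",
    "P1,LVEVNPK,a1,25wk,15,1,-5",
    "P1,LVEVNPK,a2,25wk,30,0,900"
  ), f)
  tab2 <- read_peptide_table(f)
  expect_equal(nrow(tab2), 2L)
  expect_length(attr(tab2, "row_errors"), 1L)
  expect_match(attr(tab2, "row_errors"), "row 2")

  writeLines("protein,peptide,area\nP1,LVEVNPK,3", f)
  expect_error(read_peptide_table(f), "animal_id")
})

test_that("generated studies round-trip through the CSV writers/readers", {
  dir <- withr::local_tempdir()
  st <- generate_study(tiny_config(), seed = 4, dir = dir)
  pep <- read_peptide_table(file.path(dir, "peptides.csv"))
  ser <- read_serum_table(file.path(dir, "serum.csv"))
  nuc <- read_nucleic_table(file.path(dir, "nucleic.csv"))
  expect_equal(nrow(pep), nrow(st$peptides))
  expect_equal(pep$area, st$peptides$area, tolerance = 1e-12)
  expect_equal(ser$enrichment, st$serum$enrichment, tolerance = 1e-12)
  expect_equal(nuc$ratio, st$nucleic$ratio, tolerance = 1e-12)
})

test_that("noise-free pipeline recovers every generating parameter", {
  cfg <- tiny_config()
  st <- generate_study(cfg, seed = 2)
  rep <- run_pipeline(st$peptides, st$serum, st$nucleic)

  expect_equal(rep$precursor$p_max, cfg$precursor$p_max, tolerance = 1e-6)

  pk <- merge(rep$protein_kinetics, cfg$truth,
              by.x = c("protein", "age_group"), by.y = c("protein", "group"))
  meas <- pk[pk$k_per_d > 0, ]
  expect_true(all(abs(meas$k - meas$k_per_d) / meas$k_per_d < 1e-6))
  expect_true(all(meas$measurable))
  expect_false(any(pk$measurable[pk$k_per_d == 0]))

  cc <- aggregate(concentration_pmol_mg ~ protein + age_group,
                  rep$concentrations, mean)
  cc <- merge(cc, cfg$truth, by.x = c("protein", "age_group"),
              by.y = c("protein", "group"))
  expect_true(all(abs(cc$concentration_pmol_mg - cc$conc_pmol_mg) /
                    cc$conc_pmol_mg < 1e-6))

  expect_true(all(abs(rep$nucleic$F - 0.6) < 0.05))
})

test_that("non-incorporating proteins render as dashes, never numbers", {
  st <- generate_study(tiny_config(), seed = 2)
  rep <- run_pipeline(st$peptides, st$serum)
  tab <- render_kinetics(rep)
  nosyn <- tab[tab$protein == "NOSYN", ]
  expect_true(all(nosyn$half_life_d == "-"))
  expect_true(all(nosyn$k_per_d == "-"))
  fastp <- tab[tab$protein == "FASTP", ]
  expect_false(any(fastp$half_life_d == "-"))
})

test_that("dropping one duration changes noise-free rate estimates by < 1e-6", {
  st <- generate_study(tiny_config(), seed = 3)
  full <- run_pipeline(st$peptides, st$serum)
  sub <- run_pipeline(st$peptides, st$serum, exclude_durations = 30)
  m <- merge(full$protein_kinetics, sub$protein_kinetics,
             by = c("protein", "age_group"), suffixes = c("_full", "_sub"))
  expect_true(all(abs(m$k_full - m$k_sub) < 1e-6))
})

test_that("reports carry a reproducible config hash and mode metadata", {
  st <- generate_study(tiny_config(), seed = 5)
  r1 <- run_pipeline(st$peptides, st$serum, synthesis_mode = "divide")
  r2 <- run_pipeline(st$peptides, st$serum, synthesis_mode = "divide")
  expect_identical(r1$metadata$config_hash, r2$metadata$config_hash)
  expect_identical(r1$metadata$options$synthesis_mode, "divide")
  r3 <- run_pipeline(st$peptides, st$serum, synthesis_mode = "multiply")
  expect_false(identical(r1$metadata$config_hash, r3$metadata$config_hash))
  expect_identical(r1$protein_kinetics, r2$protein_kinetics)
  # multiply and divide absolute rates differ by exactly ln 2
  m <- merge(r3$absolute, r1$absolute,
             by = c("animal_id", "protein"), suffixes = c("_mult", "_div"))
  m <- m[m$measurable_mult, ]
  expect_equal(m$rate_pmol_mg_d_div * log(2), m$rate_pmol_mg_d_mult,
               tolerance = 1e-12)
})
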