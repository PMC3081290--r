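test_that("the shipped model file loads to the built-in model", {
  m <- load_model(coagulation_model_file())
  expect_equal(m$species, coag_base$species)
  expect_equal(m$parameters, coag_base$parameters)
  expect_equal(m$stoichiometric_matrix, coag_base$stoichiometric_matrix)
  expect_equal(lapply(m$reactions, unclass),
               lapply(coag_base$reactions, unclass))
})

test_that("write/load round-trip preserves the model structurally", {
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(coag_base, path)
  m2 <- load_model(path)
  expect_equal(m2$species, coag_base$species)
  expect_equal(m2$parameters, coag_base$parameters)
  expect_equal(lapply(m2$reactions, unclass),
               lapply(coag_base$reactions, unclass))
})

test_that("loading fails totally when a rate constant is missing", {
  doc <- jsonlite::read_json(coagulation_model_file(),
                             simplifyVector = FALSE)
  keep <- vapply(doc$parameters, function(p) p$symbol != "k16", logical(1))
  doc$parameters <- doc$parameters[keep]
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  expect_error(load_model(path), "k16")
})

test_that("unsupported format versions are rejected", {
  doc <- jsonlite::read_json(coagulation_model_file(),
                             simplifyVector = FALSE)
  doc$format_version <- 99
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  expect_error(load_model(path), "format version")
})

test_that("dilution scales every concentration linearly", {
  ini <- initial_state(coag_base)
  d <- dilute(ini, 1 / 3)
  expect_equal(d[["I"]], 7e-6 / 3)           # fibrinogen 7 uM -> 2.333 uM
  expect_equal(d[["Albumin_Factor"]], 1 / 3) # albumin pool dilutes too
  expect_equal(dilute(ini, 1), ini)
  expect_equal(dilute(ini, 2 / 3)[["I"]], 7e-6 * 2 / 3)
  expect_error(dilute(ini, 0), "factor")
  expect_error(dilute(ini, 1.2), "factor")
})

test_that("factor V preactivation moves mass without creating it", {
  ini <- c(V = 20e-9, Va = 0)
  out <- preactivate_factor_v(ini, 0.01)
  expect_equal(out[["V"]], 19.8e-9)
  expect_equal(out[["Va"]], 0.2e-9)
  expect_equal(preactivate_factor_v(ini, 0), ini)
  for (f in c(0.005, 0.3, 1))
    expect_equal(sum(preactivate_factor_v(ini, f)), sum(ini))
})

test_that("dilution commutes with factor V preactivation", {
  ini <- initial_state(coag_base)
  a <- preactivate_factor_v(dilute(ini, 1 / 3), 0.01)
  b <- dilute(preactivate_factor_v(ini, 0.01), 1 / 3)
  expect_equal(a, b)
})

test_that("phospholipid site accounting uses 333 molecules per site", {
  expect_equal(lipid_sites(4e-6), 4e-6 / 333)
  expect_equal(lipid_sites(4e-6) * 1e9, 12.012, tolerance = 1e-4)
  expect_equal(lipid_sites(0), 0)
  expect_equal(lipid_sites(333e-9), 1e-9)
  expect_error(lipid_config(molecules_per_site = 0))
})

test_that("TSV export writes the three tables", {
  stem <- file.path(withr::local_tempdir(), "model")
  paths <- write_model_tsv(coag_base, stem)
  expect_true(all(file.exists(paste0(stem, c("_species.tsv",
                                             "_reactions.tsv",
                                             "_parameters.tsv")))))
  pa <- read.delim(paste0(stem, "_parameters.tsv"))
  expect_true(all(pa$provenance %in%
                    c("supplement", "source-model", "fitted-here",
                      "external-constant")))
})
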