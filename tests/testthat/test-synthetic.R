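test_that("library generation is deterministic and class-covering", {
  lib <- make_library(15, seed = 1)
  expect_equal(nrow(lib$compounds), 15L)
  expect_length(unique(lib$compounds$class), 8L)
  expect_false(any(duplicated(lib$compounds$smiles)))
  lib2 <- make_library(15, seed = 1)
  expect_identical(lib$compounds, lib2$compounds)
  expect_error(make_library(10), class = "ljtyping_config_error")

  # every compound parses, is neutral, and types under every packaged model
  big <- get_library(50, 7)
  for (id in big$compounds$compound_id) {
    mol <- big$molecules[[id]]
    expect_lt(abs(sum(mol$atoms$charge)), 1e-12)
  }
  for (mn in packaged_models()) {
    model <- typing_model(mn)
    for (mol in big$molecules)
      expect_false(anyNA(assign_types(mol, model)))
  }
})

test_that("the oracle is deterministic, monotone and type-separable", {
  study <- get_study(75, 1, noise = FALSE)
  model <- study$truth_model
  mol <- study$library$molecules[[1]]
  a <- oracle_properties(mol, study$truth_params, model)
  b <- oracle_properties(mol, study$truth_params, model)
  expect_identical(a, b)

  # increasing any rmin_half strictly decreases density of compounds
  # containing that type
  p2 <- study$truth_params
  p2$types$rmin_half[p2$types$type_id == "C"] <-
    p2$types$rmin_half[p2$types$type_id == "C"] + 0.2
  for (mol in study$library$molecules[1:8]) {
    d1 <- oracle_properties(mol, study$truth_params, model)$density
    d2 <- oracle_properties(mol, p2, model)$density
    expect_lt(d2, d1)
  }

  # polar-H rmin change: alkanes untouched, alcohol HOV responds
  p3 <- study$truth_params
  p3$types$rmin_half[p3$types$type_id == "H.polar"] <- 1.2
  cls <- study$library$compounds$class
  alkane <- study$library$molecules[[which(cls == "alkane")[1]]]
  alcohol <- study$library$molecules[[which(cls == "alcohol")[1]]]
  expect_identical(oracle_properties(alkane, study$truth_params, model),
                   oracle_properties(alkane, p3, model))
  expect_false(isTRUE(all.equal(
    oracle_properties(alcohol, study$truth_params, model)$hov,
    oracle_properties(alcohol, p3, model)$hov)))

  # properties land in realistic liquid ranges
  refs <- study$references
  expect_true(all(refs$density > 500 & refs$density < 1300))
  expect_true(all(refs$hov > 8 & refs$hov < 80))
  expect_true(all(refs$dielectric >= 1 & refs$dielectric < 100))
})

test_that("noise is reproducible and sized by the stated uncertainties", {
  s1 <- make_study(n = 20, seed = 5)
  s2 <- make_study(n = 20, seed = 5)
  expect_identical(s1$references, s2$references)
  clean <- make_study(n = 20, seed = 5, noise = FALSE)
  dd <- s1$references$density - clean$references$density
  dh <- s1$references$hov - clean$references$hov
  expect_false(all(dd == 0))
  expect_lt(max(abs(dd)), 5 * 1.0)   # 5 sigma of the density noise
  expect_lt(max(abs(dh)), 5 * 0.3)
})

test_that("split designs partition the library at the stated proportions", {
  lib75 <- get_study(75, 1)$library
  s1 <- make_split(lib75, design = 1, seed = 1)
  expect_length(s1$train, 15L)
  expect_length(s1$test, 60L)
  cls <- lib75$compounds$class[match(s1$train, lib75$compounds$compound_id)]
  expect_length(unique(cls), 8L)   # all classes in train
  expect_length(intersect(s1$train, s1$test), 0L)
  expect_setequal(c(s1$train, s1$test), lib75$compounds$compound_id)

  s2 <- make_split(lib75, design = 2, seed = 1)
  expect_length(s2$train, 30L)
  expect_length(s2$test, 45L)
  expect_setequal(c(s2$train, s2$test), lib75$compounds$compound_id)
  # seeded determinism
  expect_identical(make_split(lib75, design = 2, seed = 9),
                   make_split(lib75, design = 2, seed = 9))
  expect_error(make_split(lib75, design = 3), class = "ljtyping_config_error")
})

test_that("study artifacts write to disk in the documented formats", {
  dir <- withr::local_tempdir()
  study <- make_study(n = 15, seed = 3)
  files <- write_study(study, dir)
  expect_true(all(file.exists(files)))
  smiles <- readLines(file.path(dir, "library.smi"))
  expect_length(smiles, 15L)
  refs <- read_reference_csv(file.path(dir, "references.csv"))
  expect_equal(nrow(refs), 15L)
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(manifest$seed, 3L)
  expect_equal(manifest$truth_model, "H2CO3N")
})
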