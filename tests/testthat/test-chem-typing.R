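test_that("parse_compound expands hydrogens with a stable atom order", {
  m <- parse_compound("C")
  expect_s3_class(m, "lj_molecule")
  expect_equal(nrow(m$atoms), 5L)
  expect_equal(m$atoms$element, c("C", "H", "H", "H", "H"))
  expect_equal(m$molar_mass, 16.043, tolerance = 1e-6)

  e <- parse_compound("CCO")
  expect_equal(nrow(e$atoms), 9L)
  o <- which(e$atoms$element == "O")
  expect_equal(e$atoms$n_h[o], 1L)
  expect_equal(e$atoms$degree[o], 2L)
  # heavy atoms first, then hydrogens grouped by parent
  expect_equal(e$atoms$element[1:3], c("C", "C", "O"))

  expect_error(parse_compound("not-a-smiles"), class = "ljtyping_parse_error")
  expect_error(parse_compound("C(C"), class = "ljtyping_parse_error")
  expect_error(parse_compound("C1CC"), class = "ljtyping_parse_error")
})

test_that("charge vectors are validated against the expanded atom count", {
  q <- c(-0.4, 0.1, 0.1, 0.1, 0.1)
  m <- parse_compound("C", charges = q)
  expect_equal(m$atoms$charge, q)
  expect_error(parse_compound("C", charges = q[-1]),
               class = "ljtyping_input_error")
})

test_that("assign_types implements last-match-wins priority", {
  expect_equal(assign_types(parse_compound("C"), "HCON"),
               c("C", "H", "H", "H", "H"))

  tt <- assign_types(parse_compound("CCO"), "H2CON")
  expect_equal(sum(tt == "H.apolar"), 5L)
  expect_equal(sum(tt == "H.polar"), 1L)
  expect_equal(sum(tt == "C"), 2L)
  expect_equal(sum(tt == "O"), 1L)

  # ether O gets the specific X2H0 type, not the general O type
  tt2 <- assign_types(parse_compound("CCOCC"), "HCO3N")
  expect_equal(tt2[3], "O.ether")

  # H on nitrogen follows the [#1:1]-[#7] SMIRKS, not its (swapped) label
  tt3 <- assign_types(parse_compound("CN"), "H4CON")
  nh <- which(parse_compound("CN")$atoms$element == "H")[4:5]
  expect_equal(unique(tt3[6:7]), "H.N")
})

test_that("typing is total over packaged models and matches brute force", {
  lib <- get_library(50, 7)
  models <- lapply(packaged_models(), typing_model)
  for (mol in lib$molecules[seq(1, 50, by = 2)]) {
    for (model in models) {
      tt <- assign_types(mol, model)
      expect_false(anyNA(tt))
      expect_equal(tt, brute_force_types(mol, model))
    }
  }
  # independent hand-rolled matcher agrees for the polar/apolar model
  h2 <- typing_model("H2CON")
  for (mol in lib$molecules) {
    expect_equal(assign_types(mol, h2), hand_type_h2con(mol))
  }
})

test_that("deleting a higher-priority rule leaves unmatched atoms alone", {
  model <- typing_model("HCO3N")
  drop_ether <- ljtyping:::.new_typing_model("custom", Filter(
    function(r) r$type != "O.ether", model$rules))
  probes <- lapply(c("CC(=O)C", "CO", "CCCO", "CC"), parse_compound)
  for (mol in probes) {
    before <- assign_types(mol, model)
    after <- assign_types(mol, drop_ether)
    untouched <- before != "O.ether"
    expect_equal(after[untouched], before[untouched])
  }
})

test_that("count_types reads model names and compound usage", {
  expect_equal(count_types("HC3ON"), 6L)
  expect_equal(count_types("HCON"), 4L)
  expect_equal(count_types("H2CO3N"), 7L)
  expect_equal(count_types("SmirFF"), 15L)
  # over an alkane-only set, polar types are never used
  alkanes <- lapply(c("CC", "CCC", "CCCC"), parse_compound)
  expect_equal(count_types("H2CON", alkanes), 2L)
})

test_that("refinement_relation is a partial order with correct mappings", {
  r <- refinement_relation("HCON", "H2CON")
  expect_true(r$refines)
  expect_equal(unname(r$mapping[c("H.apolar", "H.polar")]), c("H", "H"))

  expect_false(refinement_relation("H2CON", "HCO3N")$refines)

  r_self <- refinement_relation("H2CO3N", "H2CO3N")
  expect_true(r_self$refines)
  expect_mapequal(r_self$mapping, stats::setNames(nm = typing_model("H2CO3N")$types))

  # transitivity along a lattice chain
  expect_true(refinement_relation("HCON", "H2CO3N")$refines)
  expect_true(refinement_relation("H2CON", "H2CO3N")$refines)
  expect_true(refinement_relation("HCO3N", "H4C3O3N2")$refines)
  # antisymmetry on distinct partitions
  expect_false(refinement_relation("H2CON", "HCON")$refines)
})

test_that("typing models round-trip through the offxml-style block", {
  path <- withr::local_tempfile(fileext = ".offxml")
  model <- typing_model("H2CO3N")
  params <- paramset(model)
  write_offxml(model, params, path)
  back <- read_offxml(path)
  expect_equal(back$model$name, "H2CO3N")
  mol <- parse_compound("CCO")
  expect_equal(assign_types(mol, back$model), assign_types(mol, model))
  expect_equal(back$params$types$eps, params$types$eps, tolerance = 1e-7)
})
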