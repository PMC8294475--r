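test_that("fixture parameter tables load on the common 12-row layout", {
  exps <- load_fixture_params()
  expect_named(exps, c("HCON", "HCO3N", "H2CON", "H2CO3N", "H2CO3Nreopt"))
  for (e in exps) {
    expect_equal(nrow(e), 12L)
    expect_equal(e$element_group,
                 c(rep("Hydrogen", 4), rep("Carbon", 3), rep("Nitrogen", 2),
                   rep("Oxygen", 3)))
  }
  # one-type-per-element model duplicates values within element blocks
  expect_equal(length(unique(exps$HCON$eps[1:4])), 1L)
  expect_equal(length(unique(exps$HCO3N$eps[10:12])), 3L)
})

test_that("common-row expansion follows a model's own type assignments", {
  p <- paramset("H2CO3N")
  ex <- common_row_expansion(p)
  expect_equal(nrow(ex), 12L)
  expect_equal(ex$type_id[1:2], c("H.apolar", "H.apolar"))
  expect_equal(ex$type_id[3:4], c("H.polar", "H.polar"))
  expect_equal(length(unique(ex$type_id[5:7])), 1L)    # single C type
  expect_equal(ex$type_id[10:12],
               c("O.carbonyl", "O.hydroxyl", "O.ether"))

  pc <- paramset("HCON")
  exc <- common_row_expansion(pc)
  expect_equal(length(unique(exc$type_id)), 4L)
  expect_error(distance_matrix(list(a = ex[-1, ], b = ex)),
               class = "ljtyping_contract_error")
})

test_that("the epsilon scale factor is the ratio of means over all rows", {
  exps <- load_fixture_params()
  s <- epsilon_scale_factor(exps)
  eps_all <- unlist(lapply(exps, `[[`, "eps"))
  r_all <- unlist(lapply(exps, `[[`, "rmin_half"))
  expect_equal(s, mean(r_all) / mean(eps_all))
  # invariant under duplicating the model list
  expect_equal(epsilon_scale_factor(c(exps, exps)), s)
  # a model with eps == rmin gives exactly 1
  fake <- exps[[1]]; fake$eps <- fake$rmin_half
  expect_equal(epsilon_scale_factor(list(fake)), 1)
})

test_that("distance matrices are symmetric, zero-diagonal, order-invariant", {
  exps <- load_fixture_params()
  rep1 <- distance_matrix(exps)
  d <- rep1$distances
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 5))
  # triangle inequality on every triple
  for (i in 1:5) for (j in 1:5) for (k in 1:5)
    expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
  # consistent row reordering leaves distances unchanged
  perm <- c(4, 1, 12, 3, 2, 5, 6, 7, 9, 8, 11, 10)
  exps_p <- lapply(exps, function(e) e[perm, ])
  rep2 <- distance_matrix(exps_p, scale = rep1$scale)
  expect_equal(rep2$distances, rep1$distances, tolerance = 1e-12)
})

test_that("nearest neighbors recover the published adjacency", {
  rep1 <- distance_matrix(load_fixture_params())
  expect_equal(nearest_neighbor(rep1, "H2CO3N"), "H2CON")
  expect_equal(nearest_neighbor(rep1, "H2CO3Nreopt"), "HCO3N")
  # degenerate tie: duplicated model at distance zero
  exps <- load_fixture_params()[c("HCON", "HCO3N")]
  exps$HCONcopy <- exps$HCON
  rep2 <- distance_matrix(exps)
  expect_true("HCONcopy" %in% nearest_neighbor(rep2, "HCON"))
  expect_equal(rep2$distances["HCON", "HCONcopy"], 0)
})

test_that("rounded vs recomputed scale factors agree to 0.01 in distances", {
  exps <- load_fixture_params()
  d1 <- distance_matrix(exps, scale = 13.7)$distances
  d2 <- distance_matrix(exps)$distances
  expect_lt(max(abs(d1 - d2)), 0.01)
})
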