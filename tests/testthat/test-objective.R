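test_that("molecule_term applies the squared, denominator-scaled error", {
  ref <- property_record("x", density = 800, hov = 40)
  # an error of exactly one denominator contributes 1.0
  expect_equal(molecule_term(property_record("x", density = 895), ref,
                             properties = "density"), 1.0)
  expect_equal(molecule_term(property_record("x", density = 800, hov = 40),
                             ref), 0)
  # 47.5 kg/m^3 and 0.475 kJ/mol are half-denominator errors: 0.25 + 0.25
  expect_equal(molecule_term(property_record("x", density = 847.5,
                                             hov = 40.475), ref), 0.5)
  # missing property on either side is skipped, not an error
  expect_equal(molecule_term(property_record("x", density = 895), ref), 1.0)
  expect_error(
    molecule_term(property_record("x", density = 895), ref,
                  denominators = c(hov = 0.95), properties = "density"),
    class = "ljtyping_config_error")
})

test_that("total_objective assembles data terms and restraint", {
  b <- total_objective(c(1, 2, 3), k = NULL)
  expect_equal(b$total, 6)
  expect_equal(b$restraint, 0)

  # |k|^2 = 10 with w_reg = 0.1 contributes exactly 1.0
  k <- rep(1, 10)
  b2 <- total_objective(c(1, 2), k = k, w_reg = 0.1)
  expect_equal(b2$restraint, 1.0)
  expect_equal(b2$total, 4.0)

  b3 <- total_objective(numeric(0), k = k, w_reg = 0.1)
  expect_equal(b3$total, b3$restraint)
  expect_error(total_objective(c(-1), k), class = "ljtyping_domain_error")
})

test_that("restraint_contribution is the quadratic k-space displacement", {
  ref <- paramset("H2CON")
  expect_equal(restraint_contribution(ref, ref), 0)

  cand <- ref
  cand$types$eps[1] <- cand$types$eps[1] + 0.1   # one prior width
  expect_equal(restraint_contribution(cand, ref), 0.1 * 1.0^2)

  cand2 <- ref
  cand2$types$eps <- cand2$types$eps + 0.05
  cand2$types$rmin_half <- cand2$types$rmin_half + 0.2
  expect_equal(restraint_contribution(cand2, ref, w_reg = 0.3),
               0.3 * (5 * 0.5^2 + 5 * 0.2^2))
  # doubling every displacement quadruples the value
  cand4 <- ref
  cand4$types$eps <- cand4$types$eps + 0.1
  cand4$types$rmin_half <- cand4$types$rmin_half + 0.4
  expect_equal(restraint_contribution(cand4, ref, w_reg = 0.3),
               4 * restraint_contribution(cand2, ref, w_reg = 0.3))

  other <- paramset("HCON")
  expect_error(restraint_contribution(other, ref),
               class = "ljtyping_contract_error")

  # per-display-row counting weights duplicated rows multiply
  expect_gt(restraint_contribution(cand2, ref, per_display_row = TRUE),
            restraint_contribution(cand2, ref))
})

test_that("percent errors aggregate mean absolute relative error", {
  refs <- data.frame(compound_id = c("a", "b"), density = c(100, 200),
                     hov = c(10, 20))
  pred <- data.frame(compound_id = c("a", "b"), density = c(100, 200),
                     hov = c(10, 20))
  expect_equal(unname(percent_errors(pred, refs)[c("density", "hov")]),
               c(0, 0))

  pred$density <- c(105, 230)   # 5% and 15%
  expect_equal(unname(percent_errors(pred, refs)[["density"]]), 10)

  pred1 <- data.frame(compound_id = "a", hov = 11)
  expect_equal(unname(percent_errors(pred1, refs)[["hov"]]), 10)

  refs0 <- data.frame(compound_id = c("a", "b"), density = c(0, 200))
  predx <- data.frame(compound_id = c("a", "b"), density = c(5, 220))
  expect_warning(pe <- percent_errors(predx, refs0, "density"))
  expect_equal(unname(pe[["density"]]), 10)
})

test_that("test-set display scaling does not affect model ranking", {
  set.seed(3)
  objectives <- runif(8, 1, 200)
  expect_equal(order(objectives / 15), order(objectives))
  expect_equal(order(objectives / 3), order(objectives))
})

test_that("reference tables read from CSV with standardized names", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("compound_id,density_kg_m3,hov_kJ_mol,dielectric",
               "a,800,35,12", "b,700,28,2"), path)
  df <- read_reference_csv(path)
  expect_equal(names(df), c("compound_id", "density", "hov", "dielectric"))
  expect_equal(df$density, c(800, 700))
})
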