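test_that("Lorentz-Berthelot combination is correct and symmetric", {
  same <- combine(list(eps = 0.1, rmin_half = 1.5),
                  list(eps = 0.1, rmin_half = 1.5))
  expect_equal(same$eps, 0.1)
  expect_equal(same$rmin, 3.0)

  # published one-type-per-element H and O values
  hx <- list(eps = 0.017, rmin_half = 1.27)
  ox <- list(eps = 0.220, rmin_half = 1.11)
  mix <- combine(hx, ox)
  expect_equal(mix$eps, sqrt(0.017 * 0.220), tolerance = 1e-12)
  expect_equal(mix$eps, 0.06116, tolerance = 1e-4)
  expect_equal(mix$rmin, 2.38)

  set.seed(42)
  for (i in 1:20) {
    a <- list(eps = runif(1, 0, 0.5), rmin_half = runif(1, 0.3, 2.2))
    b <- list(eps = runif(1, 0, 0.5), rmin_half = runif(1, 0.3, 2.2))
    expect_identical(combine(a, b), combine(b, a))
  }
  expect_error(combine(list(eps = -0.1, rmin_half = 1), hx),
               class = "ljtyping_domain_error")
})

test_that("pair energy reproduces the 12-6 well shape", {
  expect_equal(pair_energy(3.0, 0.25, 3.0), -0.25)
  expect_equal(pair_energy(3.0 / 2^(1/6), 0.25, 3.0), 0, tolerance = 1e-12)
  # direct evaluation at r = 2 rmin: 1/4096 - 2/64
  expect_equal(pair_energy(2, 1, 1), 1 / 4096 - 2 / 64, tolerance = 1e-12)
  expect_error(pair_energy(0, 1, 1), class = "ljtyping_domain_error")

  # decreasing on (0, rmin), increasing toward 0 on (rmin, Inf)
  r_in <- seq(0.6, 1, length.out = 60)
  r_out <- seq(1, 6, length.out = 60)
  expect_true(all(diff(pair_energy(r_in, 1, 1)) < 0))
  expect_true(all(diff(pair_energy(r_out, 1, 1)) > 0))
  expect_true(all(pair_energy(r_out, 1, 1) <= 0))
})

test_that("combined tables are symmetric and rmin-additive per model", {
  for (mn in c("HCON", "H2CO3N")) {
    p <- paramset(mn)
    tt <- p$types
    for (i in seq_len(nrow(tt))) for (j in seq_len(nrow(tt))) {
      cij <- combine(list(eps = tt$eps[i], rmin_half = tt$rmin_half[i]),
                     list(eps = tt$eps[j], rmin_half = tt$rmin_half[j]))
      expect_equal(cij$rmin, tt$rmin_half[i] + tt$rmin_half[j])
      expect_equal(cij$eps, sqrt(tt$eps[i] * tt$eps[j]))
    }
  }
})

test_that("the mathematical transform is affine, invertible and centered", {
  p <- paramset("H2CO3N")
  k <- to_math(p)
  expect_length(k, 14L)
  expect_true(all(k == 0))

  # a +0.05 kcal/mol epsilon displacement is k = 0.5 under the 0.1 prior
  p2 <- p
  p2$types$eps[1] <- p2$types$eps[1] + 0.05
  expect_equal(unname(to_math(p2)[1]), 0.5)

  set.seed(1)
  for (i in 1:10) {
    kk <- rnorm(14, 0, 0.7)
    back <- to_math(from_math(kk, p))
    expect_equal(unname(back), kk, tolerance = 1e-12)
  }
  expect_error(from_math(rnorm(13), p), class = "ljtyping_contract_error")

  # |k|^2 = 0 iff parameters sit at the reference
  expect_equal(sum(to_math(p)^2), 0)
  expect_gt(sum(to_math(p2)^2), 0)
})

test_that("parameter CSV round-trips", {
  path <- withr::local_tempfile(fileext = ".csv")
  p <- paramset("HCO3N")
  write_params_csv(p, path)
  back <- read_params_csv(path, "HCO3N")
  expect_equal(back$types$eps, p$types$eps)
  expect_equal(back$types$rmin_half, p$types$rmin_half)
})
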