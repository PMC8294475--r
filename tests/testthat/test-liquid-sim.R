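test_that("density follows n M / (N_A V) with unit conversion", {
  # 700 water-like molecules in 21000 A^3 is liquid-water density
  rho <- density_from_volume(21000, 700, 18.015)
  expect_equal(rho, 700 * 18.015 / (6.02214076e23 * 21000) * 1e27,
               tolerance = 1e-10)
  expect_equal(rho, 997.2, tolerance = 1e-3)
  expect_equal(density_from_volume(42000, 700, 18.015), rho / 2)
  expect_equal(density_from_volume(21000, 0, 18.015), 0)
  expect_error(density_from_volume(0, 1, 18), class = "ljtyping_domain_error")
})

test_that("heat of vaporization is the energy gap plus RT", {
  expect_equal(heat_of_vaporization(0, 0, 298), 8.31446261815324e-3 * 298)
  expect_equal(heat_of_vaporization(0, 0, 298), 2.4777, tolerance = 1e-4)
  expect_equal(heat_of_vaporization(10, -30, 298), 40 + 2.47771,
               tolerance = 1e-4)
  # monotone: increasing in u_gas, decreasing in u_liq
  expect_gt(heat_of_vaporization(11, -30), heat_of_vaporization(10, -30))
  expect_lt(heat_of_vaporization(10, -29), heat_of_vaporization(10, -30))
  expect_error(heat_of_vaporization(0, 0, -1), class = "ljtyping_domain_error")
})

test_that("dielectric estimator matches the fluctuation closed form", {
  expect_equal(dielectric_from_dipoles(matrix(1, 5, 3), 1000), 1)
  expect_error(dielectric_from_dipoles(matrix(1, 1, 3), 1000),
               class = "ljtyping_estimation_error")

  # isotropic Gaussian samples: eps_r = 1 + sigma^2 conv / (eps0 V kB T)
  set.seed(99)
  sigma <- 2.0; V <- 8000; T <- 298
  m <- matrix(rnorm(3 * 40000, 0, sigma), ncol = 3)
  e <- 1.602176634e-19; eps0 <- 8.8541878128e-12; kB <- 1.380649e-23
  expected <- 1 + sigma^2 * e^2 / (eps0 * 1e-10) / (V * kB * T)
  got <- dielectric_from_dipoles(m, V, T)
  expect_equal(got, expected, tolerance = 0.02)

  # doubling all dipoles quadruples eps_r - 1
  expect_equal(dielectric_from_dipoles(2 * m, V, T) - 1,
               4 * (got - 1), tolerance = 1e-6)
})

test_that("rigid geometries have sane bond lengths and no atom collisions", {
  for (smi in c("CC", "CCO", "CC(=O)C", "CC#N", "CCOCC")) {
    mol <- parse_compound(smi)
    xyz <- build_geometry(mol, seed = 3)
    expect_false(anyNA(xyz))
    for (r in seq_len(nrow(mol$bonds))) {
      d <- sqrt(sum((xyz[mol$bonds$i[r], ] - xyz[mol$bonds$j[r], ])^2))
      expect_gt(d, 0.8); expect_lt(d, 1.8)
    }
    dd <- as.matrix(dist(xyz))
    diag(dd) <- Inf
    expect_gt(min(dd), 0.6)   # random dihedrals allow tight gauche contacts
  }
  # seed-deterministic
  expect_identical(build_geometry(parse_compound("CCO"), 5),
                   build_geometry(parse_compound("CCO"), 5))
})

test_that("toy liquid runs are deterministic and keep honest energy books", {
  mol <- parse_compound("C")
  model <- typing_model("HCON")
  p <- paramset(model)
  cfg <- sim_config(n_molecules = 40, cutoff = 6, vol_interval = 0,
                    n_equil_moves = 0, n_prod_moves = 10000,
                    sample_interval = 10, seed = 5)
  r1 <- run_toy_liquid(mol, p, model, cfg)
  # incremental vs full recomputation after 1e4 moves
  expect_lt(abs(r1$liquid$U_incremental - r1$liquid$U_recomputed) /
              abs(r1$liquid$U_recomputed), 1e-8)
  r2 <- run_toy_liquid(mol, p, model, cfg)
  expect_identical(r1$properties, r2$properties)
  expect_identical(r1$liquid$mean_volume, r2$liquid$mean_volume)

  # rigid single conformer: gas-phase energy is constant with zero SE
  expect_equal(r1$gas$se_u, 0)
})

test_that("density rises monotonically with pressure for the LJ toy fluid", {
  mol <- parse_compound("C")
  mol$atoms$charge <- rep(0, 5)
  model <- typing_model("HCON")
  p <- paramset(model)
  # pressures chosen so the expected density gaps dwarf the stochastic
  # standard errors (~150 kg/m^3 steps vs ~8 kg/m^3 SE)
  rhos <- vapply(c(1, 1000, 5000), function(P) {
    cfg <- sim_config(n_molecules = 48, cutoff = 6, pressure = P,
                      n_equil_moves = 30000, n_prod_moves = 60000,
                      sample_interval = 2, seed = 11)
    run_toy_liquid(mol, p, model, cfg)$properties$density
  }, numeric(1))
  expect_true(all(diff(rhos) > 0))
})

test_that("config validation and file parsing work", {
  expect_error(sim_config(temperature = -1), class = "ljtyping_config_error")
  path <- withr::local_tempfile(fileext = ".yml")
  writeLines(c("# toy settings", "temperature: 310", "n_molecules: 20",
               "cutoff: 5"), path)
  cfg <- read_sim_config(path)
  expect_equal(cfg$temperature, 310)
  expect_equal(cfg$n_molecules, 20L)
})
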