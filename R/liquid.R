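# Desk-scale stand-in for the original MD property estimation: property
# definitions (density from mean NPT volume, heat of vaporization from the
# gas/liquid potential-energy difference plus RT, dielectric constant from
# box-dipole fluctuations) on top of a rigid-molecule NPT Metropolis Monte
# Carlo engine. Electrostatics are plainly truncated at the cutoff (no
# Ewald), so dielectric estimates carry bias and are used qualitatively.

#' Simulation configuration for the toy liquid
#'
#' @param temperature Kelvin (default 298).
#' @param pressure Atmospheres (default 1).
#' @param n_molecules Copies of the molecule in the box (default 100; the
#'   original study used 700 with MD).
#' @param cutoff Interaction cutoff, Angstrom; must stay below half the box
#'   edge (default 8).
#' @param n_equil_moves,n_prod_moves Particle-move counts for
#'   equilibration and production (defaults 2e5 and 1e6).
#' @param vol_interval Particle sweeps between volume-move attempts
#'   (default 25, mirroring the barostat attempt interval).
#' @param sample_interval Sweeps between samples (default 5).
#' @param max_trans,max_rot,max_lnv Maximum displacement (Angstrom),
#'   rotation (radians) and log-volume step.
#' @param init_volume Optional starting box volume (Angstrom^3); by default
#'   a loosely packed guess from the molecular half-radii. Dilute systems
#'   (e.g. the ideal-gas limit) equilibrate much faster when started near
#'   the expected volume.
#' @param seed Integer seed; identical seeds give bit-identical runs.
#' @return List of class `lj_sim_config`.
#' @export
sim_config <- function(temperature = 298, pressure = 1, n_molecules = 100,
                       cutoff = 8, n_equil_moves = 2e5, n_prod_moves = 1e6,
                       vol_interval = 25, sample_interval = 5,
                       max_trans = 0.8, max_rot = 0.5, max_lnv = 0.05,
                       init_volume = NULL, seed = 1) {
  if (temperature <= 0 || pressure <= 0) stop_config("T and P must be positive")
  if (cutoff <= 0) stop_config("cutoff must be positive")
  structure(list(temperature = temperature, pressure = pressure,
                 n_molecules = as.integer(n_molecules), cutoff = cutoff,
                 n_equil_moves = as.integer(n_equil_moves),
                 n_prod_moves = as.integer(n_prod_moves),
                 vol_interval = as.integer(vol_interval),
                 sample_interval = as.integer(sample_interval),
                 max_trans = max_trans, max_rot = max_rot, max_lnv = max_lnv,
                 init_volume = init_volume, seed = as.integer(seed)),
            class = "lj_sim_config")
}

#' Density from the mean simulation volume
#'
#' `rho = n M / (N_A V)`, converted to kg/m^3 from Angstrom^3 and g/mol.
#'
#' @param mean_volume Mean box volume, Angstrom^3.
#' @param n Number of molecules.
#' @param molar_mass g/mol.
#' @return Density in kg/m^3 (0 for an empty box).
#' @export
density_from_volume <- function(mean_volume, n, molar_mass) {
  if (mean_volume <= 0) stop_domain("volume must be positive")
  if (molar_mass <= 0) stop_domain("molar mass must be positive")
  if (n == 0) return(0)
  # g per A^3 -> kg/m^3: 1e30 A^3 per m^3, 1e-3 kg per g
  n * molar_mass / (N_AVOGADRO * mean_volume) * 1e30 * 1e-3
}

#' Heat of vaporization
#'
#' Gas/liquid difference of the mean potential energy per molecule plus the
#' pressure-volume term RT: `HOV = u_gas - u_liquid + R T` (all kJ/mol).
#'
#' @param u_gas Mean gas-phase potential energy per molecule, kJ/mol.
#' @param u_liq_per_mol Mean liquid potential energy per molecule, kJ/mol.
#' @param T Temperature, Kelvin.
#' @return kJ/mol.
#' @export
heat_of_vaporization <- function(u_gas, u_liq_per_mol, T = 298) {
  if (T <= 0) stop_domain("temperature must be positive")
  u_gas - u_liq_per_mol + R_GAS_KJ * T
}

#' Dielectric constant from box-dipole fluctuations
#'
#' Conducting-boundary fluctuation formula
#' `eps_r = 1 + (<M^2> - <M>.<M>) / (3 eps_0 V k_B T)` with dipoles in
#' e*Angstrom and volume in Angstrom^3. The mean-subtracted form is the
#' default; `subtract_mean = FALSE` gives the raw `<M^2>` variant.
#'
#' @param dipole_samples Matrix (n x 3) of box dipole vectors, e*Angstrom.
#' @param mean_volume Mean box volume, Angstrom^3.
#' @param T Temperature, Kelvin.
#' @param subtract_mean Subtract `<M>` (default TRUE)?
#' @return Dimensionless relative dielectric constant (>= 1).
#' @export
dielectric_from_dipoles <- function(dipole_samples, mean_volume, T = 298,
                                    subtract_mean = TRUE) {
  m <- as.matrix(dipole_samples)
  if (nrow(m) < 2) ljt_stop("need at least 2 dipole samples",
                            "ljtyping_estimation_error")
  msq <- mean(rowSums(m^2))
  if (subtract_mean) {
    mu <- colMeans(m)
    msq <- msq - sum(mu^2)
  }
  # (e A)^2 / (eps0 A^3 kB T): e = 1.602176634e-19 C, eps0 = 8.8541878128e-12
  # F/m, kB = 1.380649e-23 J/K; lengths in Angstrom (1e-10 m)
  e <- 1.602176634e-19; eps0 <- 8.8541878128e-12; kB <- 1.380649e-23
  conv <- e^2 / (eps0 * 1e-10)   # J * m per (e A)^2 / A^3 ... combined below
  1 + msq * conv / (3 * mean_volume * kB * T)
}

# intramolecular nonbonded energy of the rigid conformer: atom pairs
# separated by three or more bonds interact with full (uncut) LJ + Coulomb;
# 1-2 and 1-3 pairs are excluded
.intra_energy <- function(mol, xyz, eps_a, rmin_a, charges) {
  n <- nrow(xyz)
  if (n < 2) return(0)
  d <- .graph_distances(mol)
  u <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (d[i, j] < 3) next
    r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    e <- sqrt(eps_a[i] * eps_a[j])
    rm <- rmin_a[i] + rmin_a[j]
    u <- u + pair_energy(r, e, rm) + COULOMB_KCAL * charges[i] * charges[j] / r
  }
  u
}

.graph_distances <- function(mol) {
  n <- nrow(mol$atoms)
  d <- matrix(Inf, n, n); diag(d) <- 0
  for (r in seq_len(nrow(mol$bonds))) {
    d[mol$bonds$i[r], mol$bonds$j[r]] <- 1
    d[mol$bonds$j[r], mol$bonds$i[r]] <- 1
  }
  for (k in seq_len(n)) {
    dk <- d[, k]
    cand <- outer(dk, d[k, ], `+`)
    upd <- cand < d
    d[upd] <- cand[upd]
  }
  d
}

.block_se <- function(x, n_blocks = 20) {
  n <- length(x)
  if (n < 2 * n_blocks) n_blocks <- max(2L, floor(n / 2))
  idx <- cut(seq_len(n), n_blocks, labels = FALSE)
  bm <- tapply(x, idx, mean)
  stats::sd(bm) / sqrt(length(bm))
}

#' Run the toy NPT liquid (and gas) simulation
#'
#' Types the molecule, builds one rigid idealized conformer, runs an NPT
#' Metropolis Monte Carlo liquid simulation of `n_molecules` copies
#' (minimum-image LJ + truncated Coulomb within the cutoff, analytic LJ
#' tail correction, log-volume barostat moves accepted with the NPT
#' weight), and evaluates the rigid conformer's constant intramolecular
#' energy as the gas phase. Deterministic for a given config seed.
#'
#' @param mol An `lj_molecule` with partial charges.
#' @param params `lj_paramset` for the typing model.
#' @param model The typing model (or name).
#' @param cfg An [sim_config()].
#' @return List of class `lj_sim_result`: `liquid` (mean volume and
#'   standard error, mean potential energy per molecule kJ/mol and SE,
#'   dipole samples, acceptance rates, energy bookkeeping check), `gas`
#'   (mean potential energy kJ/mol, SE 0 for the rigid conformer), and
#'   derived `properties` (density kg/m^3, HOV kJ/mol, dielectric).
#' @export
run_toy_liquid <- function(mol, params, model, cfg = sim_config()) {
  if (is.character(model)) model <- typing_model(model)
  tt <- assign_types(mol, model)
  look <- match(tt, params$types$type_id)
  if (anyNA(look)) stop_contract("paramset does not cover the molecule's types")
  eps_a <- params$types$eps[look]
  rmin_a <- params$types$rmin_half[look]
  xyz <- build_geometry(mol, seed = cfg$seed)
  charges <- mol$atoms$charge

  # combined type tables over the distinct types present
  utypes <- sort(unique(look))
  t_eps <- params$types$eps[utypes]
  t_rmin <- params$types$rmin_half[utypes]
  nt <- length(utypes)
  epsij <- sqrt(outer(t_eps, t_eps))
  rminij <- outer(t_rmin, t_rmin, `+`)
  type0 <- match(look, utypes) - 1L

  # starting volume: loosely packed hard-core guess from the half-radii
  v_guess <- max(60, 4 * sum((2 * rmin_a)^3 / 8))
  init_volume <- if (!is.null(cfg$init_volume)) cfg$init_volume else
    cfg$n_molecules * v_guess
  if (cfg$cutoff >= 0.5 * init_volume^(1 / 3))
    stop_config("cutoff exceeds half the initial box edge; reduce cutoff or add molecules")

  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(cfg$seed)
  raw <- .run_toy_mc_cpp(xyz, type0, charges, epsij, rminij,
                         cfg$n_molecules, cfg$temperature, cfg$pressure,
                         cfg$cutoff, init_volume, cfg$n_equil_moves,
                         cfg$n_prod_moves, cfg$vol_interval,
                         cfg$sample_interval, cfg$max_trans, cfg$max_rot,
                         cfg$max_lnv)

  e_intra_kcal <- .intra_energy(mol, xyz, eps_a, rmin_a, charges)
  u_gas <- e_intra_kcal * CAL_TO_J     # kJ/mol per molecule

  n_samp <- length(raw$volume)
  mean_v <- mean(raw$volume)
  se_v <- .block_se(raw$volume)
  # liquid potential energy per molecule, kJ/mol (inter + constant intra)
  u_liq_samples <- (raw$energy / cfg$n_molecules + e_intra_kcal) * CAL_TO_J
  u_liq <- mean(u_liq_samples)
  se_u <- .block_se(u_liq_samples)
  dip <- cbind(raw$dipole_x, raw$dipole_y, raw$dipole_z)

  dens <- density_from_volume(mean_v, cfg$n_molecules, mol$molar_mass)
  hov <- heat_of_vaporization(u_gas, u_liq, cfg$temperature)
  diel <- if (n_samp >= 2)
    dielectric_from_dipoles(dip, mean_v, cfg$temperature) else NA_real_

  structure(list(
    liquid = list(mean_volume = mean_v, se_volume = se_v,
                  u_per_mol = u_liq, se_u = se_u,
                  dipole_samples = dip, n_samples = n_samp,
                  acc_particle = raw$acc_particle,
                  acc_volume = raw$acc_volume,
                  U_incremental = raw$U_incremental,
                  U_recomputed = raw$U_recomputed),
    gas = list(u_per_mol = u_gas, se_u = 0),
    properties = property_record(mol$smiles, density = dens, hov = hov,
                                 dielectric = diel),
    cfg = cfg), class = "lj_sim_result")
}

#' @export
print.lj_sim_result <- function(x, ...) {
  p <- x$properties
  cat(sprintf(
    "<lj_sim_result> %s: rho = %.1f kg/m^3, HOV = %.2f kJ/mol, eps_r = %.2f (%d samples)\n",
    p$compound_id, p$density, p$hov, p$dielectric, x$liquid$n_samples))
  invisible(x)
}

#' Read a simulation config from a YAML-style key file
#'
#' Flat `key: value` lines naming [sim_config()] arguments; `#` comments
#' and blank lines ignored.
#'
#' @param path File path.
#' @return An [sim_config()].
#' @export
read_sim_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, ":", fixed = TRUE)
  args <- list()
  for (p in kv) {
    if (length(p) != 2L) stop_input("config lines must be 'key: value'")
    args[[trimws(p[1])]] <- as.numeric(trimws(p[2]))
  }
  do.call(sim_config, args)
}
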