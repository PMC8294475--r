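# LJ parameters: combining rules, the 12-6 pair energy, and the affine
# physical <-> mathematical parameter transform used by the optimizer.
#
# Internal units are fixed: epsilon in kcal/mol, distances in Angstrom.
# Heats of vaporization are reported in kJ/mol and densities in kg/m^3 at
# module boundaries; the 4.184 J/cal constant is applied only there.

CAL_TO_J <- 4.184
R_GAS_KJ <- 8.31446261815324e-3   # kJ/(mol K)
KB_KCAL  <- 1.987204259e-3        # kcal/(mol K)
N_AVOGADRO <- 6.02214076e23
COULOMB_KCAL <- 332.06371         # kcal/mol * Angstrom / e^2

# Prior widths: the scaling constants t converting a physical displacement
# into a dimensionless mathematical coordinate (and setting the soft
# restraint scale).
PRIOR_WIDTH_EPS <- 0.1   # kcal/mol
PRIOR_WIDTH_RMIN <- 1.0  # Angstrom

#' Lorentz-Berthelot combining rules
#'
#' Combines two per-type LJ parameter pairs into the cross-interaction well
#' depth and minimum-energy separation: geometric mean for epsilon,
#' arithmetic sum of the half-radii for r_min.
#'
#' @param a,b Lists (or single rows) with fields `eps` (kcal/mol) and
#'   `rmin_half` (Angstrom).
#' @return List with `eps` (kcal/mol) and `rmin` (Angstrom).
#' @examples
#' combine(list(eps = 0.1, rmin_half = 1.5), list(eps = 0.1, rmin_half = 1.5))
#' @export
combine <- function(a, b) {
  if (a$eps < 0 || b$eps < 0) stop_domain("epsilon must be non-negative")
  if (a$rmin_half <= 0 || b$rmin_half <= 0)
    stop_domain("rmin_half must be positive")
  list(eps = sqrt(a$eps * b$eps), rmin = a$rmin_half + b$rmin_half)
}

#' 12-6 Lennard-Jones pair energy
#'
#' Evaluates `eps * ((rmin/r)^12 - 2 (rmin/r)^6)`, the well-depth form of
#' the 12-6 potential: minimum value `-eps` at `r = rmin`, zero crossing at
#' `rmin / 2^(1/6)`.
#'
#' @param r Interatomic distance, Angstrom (vectorized, all > 0).
#' @param eps Well depth, kcal/mol.
#' @param rmin Minimum-energy separation, Angstrom.
#' @return Energy in kcal/mol.
#' @export
pair_energy <- function(r, eps, rmin) {
  if (any(r <= 0)) stop_domain("pair_energy requires r > 0")
  x6 <- (rmin / r)^6
  eps * (x6 * x6 - 2 * x6)
}

# -- parameter sets -------------------------------------------------------

#' Create an LJ parameter set for a typing model
#'
#' A parameter set maps each type id of a typing model to its `(epsilon,
#' rmin_half)` pair, and carries the reference values K0 and prior widths t
#' for the mathematical transform `k = (K - K0) / t`. Reference values
#' default to the current values (so `k = 0` at creation).
#'
#' @param model An `lj_typing_model` or model name.
#' @param eps Named numeric vector of well depths (kcal/mol) per type id;
#'   defaults to the model's built-in starting values.
#' @param rmin_half Named numeric vector of half-radii (Angstrom) per type.
#' @param ref Optional reference parameter set (an `lj_paramset`) supplying
#'   K0; defaults to self.
#' @return An object of class `lj_paramset` with `model_name`, `types`
#'   (data frame `type_id`, `eps`, `rmin_half`, `eps0`, `rmin0`) and prior
#'   widths `t_eps`, `t_rmin`.
#' @export
paramset <- function(model, eps = NULL, rmin_half = NULL, ref = NULL) {
  if (is.character(model)) model <- typing_model(model)
  tids <- model$types
  # built-in starting values: first rule defining each type
  e0 <- r0 <- stats::setNames(rep(NA_real_, length(tids)), tids)
  for (r in model$rules) {
    if (is.na(e0[[r$type]])) { e0[[r$type]] <- r$eps; r0[[r$type]] <- r$rmin }
  }
  e <- if (is.null(eps)) e0 else { .check_named(eps, tids, "eps"); eps[tids] }
  rh <- if (is.null(rmin_half)) r0 else {
    .check_named(rmin_half, tids, "rmin_half"); rmin_half[tids] }
  if (any(e < 0)) stop_domain("epsilon must be non-negative")
  if (any(rh <= 0)) stop_domain("rmin_half must be positive")
  refs <- if (is.null(ref)) list(eps = e, rmin = rh) else {
    if (!identical(ref$model_name, model$name))
      stop_contract("reference paramset belongs to a different model")
    list(eps = stats::setNames(ref$types$eps, ref$types$type_id)[tids],
         rmin = stats::setNames(ref$types$rmin_half, ref$types$type_id)[tids])
  }
  structure(list(
    model_name = model$name,
    types = data.frame(type_id = tids, eps = as.numeric(e),
                       rmin_half = as.numeric(rh),
                       eps0 = as.numeric(refs$eps), rmin0 = as.numeric(refs$rmin),
                       stringsAsFactors = FALSE),
    t_eps = PRIOR_WIDTH_EPS, t_rmin = PRIOR_WIDTH_RMIN),
    class = "lj_paramset")
}

.check_named <- function(x, tids, what) {
  if (is.null(names(x)) || !all(tids %in% names(x)))
    stop_contract(sprintf("'%s' must be named with all type ids (%s)",
                          what, paste(tids, collapse = ", ")))
}

#' @export
print.lj_paramset <- function(x, ...) {
  cat(sprintf("<lj_paramset> model %s (%d types)\n", x$model_name,
              nrow(x$types)))
  print(x$types, row.names = FALSE)
  invisible(x)
}

#' Physical to mathematical parameter transform
#'
#' Maps a parameter set to the dimensionless vector `k_i = (K_i - K0_i)/t_i`
#' with prior widths t = 0.1 kcal/mol for epsilon and 1.0 Angstrom for
#' rmin_half. Ordering contract: types in model-definition order, `(eps,
#' rmin_half)` interleaved per type; names record the layout so vectors are
#' portable.
#'
#' @param params An `lj_paramset`.
#' @return Named numeric vector of length `2 * n_types`.
#' @seealso [from_math()]
#' @export
to_math <- function(params) {
  stopifnot(inherits(params, "lj_paramset"))
  tt <- params$types
  k <- as.numeric(rbind((tt$eps - tt$eps0) / params$t_eps,
                        (tt$rmin_half - tt$rmin0) / params$t_rmin))
  names(k) <- as.vector(rbind(paste0(tt$type_id, ".eps"),
                              paste0(tt$type_id, ".rmin")))
  k
}

#' Mathematical to physical parameter transform
#'
#' Inverse of [to_math()]: reconstructs a parameter set from a mathematical
#' vector and the reference set supplying K0 and the prior widths.
#'
#' @param k Numeric vector (layout of [to_math()]).
#' @param ref An `lj_paramset` carrying the reference values.
#' @return An `lj_paramset` with the same references.
#' @export
from_math <- function(k, ref) {
  stopifnot(inherits(ref, "lj_paramset"))
  tt <- ref$types
  if (length(k) != 2L * nrow(tt))
    stop_contract(sprintf("mathematical vector length %d != 2 x %d types",
                          length(k), nrow(tt)))
  km <- matrix(as.numeric(k), nrow = 2L)
  out <- ref
  out$types$eps <- tt$eps0 + km[1L, ] * ref$t_eps
  out$types$rmin_half <- tt$rmin0 + km[2L, ] * ref$t_rmin
  out
}

# -- serialization --------------------------------------------------------

#' Write a typing model and parameter set as an offxml-style vdW block
#'
#' Serializes the ordered rules with `smirks=`, `epsilon=`, `rmin_half=`
#' attributes, in ascending priority order, mirroring the SMIRNOFF force
#' field XML layout for the vdW handler.
#'
#' @param model An `lj_typing_model`.
#' @param params An `lj_paramset` for the model (defaults to starting
#'   values).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_offxml <- function(model, params = NULL, path) {
  if (is.character(model)) model <- typing_model(model)
  if (is.null(params)) params <- paramset(model)
  pv <- stats::setNames(seq_len(nrow(params$types)), params$types$type_id)
  doc <- xml2::xml_new_root("SMIRNOFF", version = "0.3")
  vdw <- xml2::xml_add_child(doc, "vdW",
                             potential = "Lennard-Jones-12-6",
                             combining_rules = "Lorentz-Berthelot",
                             model = model$name)
  for (r in model$rules) {
    i <- pv[[r$type]]
    xml2::xml_add_child(
      vdw, "Atom",
      smirks = r$smirks, id = r$type,
      epsilon = sprintf("%.8g * kilocalorie/mole", params$types$eps[i]),
      rmin_half = sprintf("%.8g * angstrom", params$types$rmin_half[i]))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a typing model and parameter set from an offxml-style block
#'
#' @param path File written by [write_offxml()] (or any SMIRNOFF-style vdW
#'   block using `smirks`, `id`, `epsilon`, `rmin_half` attributes with the
#'   units used by [write_offxml()]).
#' @return List with `model` (`lj_typing_model`) and `params`
#'   (`lj_paramset`).
#' @export
read_offxml <- function(path) {
  doc <- xml2::read_xml(path)
  vdw <- xml2::xml_find_first(doc, ".//vdW")
  if (inherits(vdw, "xml_missing")) stop_input("no <vdW> block found")
  name <- xml2::xml_attr(vdw, "model")
  if (is.na(name)) name <- "custom"
  rows <- xml2::xml_find_all(vdw, ".//Atom")
  rules <- lapply(rows, function(nd) {
    list(smirks = xml2::xml_attr(nd, "smirks"),
         type = xml2::xml_attr(nd, "id"),
         eps = as.numeric(sub("\\s*\\*.*$", "", xml2::xml_attr(nd, "epsilon"))),
         rmin = as.numeric(sub("\\s*\\*.*$", "", xml2::xml_attr(nd, "rmin_half"))))
  })
  model <- .new_typing_model(name, rules)
  list(model = model, params = paramset(model))
}

#' Write a parameter set as a flat CSV
#'
#' Columns `type_id`, `epsilon_kcal_mol`, `rmin_half_A` (one row per type).
#'
#' @param params An `lj_paramset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_params_csv <- function(params, path) {
  utils::write.csv(data.frame(type_id = params$types$type_id,
                              epsilon_kcal_mol = params$types$eps,
                              rmin_half_A = params$types$rmin_half),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a flat parameter CSV into a parameter set
#'
#' @param path CSV with columns `type_id`, `epsilon_kcal_mol`,
#'   `rmin_half_A`.
#' @param model Typing model (or name) whose type ids the rows must cover.
#' @return An `lj_paramset` (reference values = the file's values).
#' @export
read_params_csv <- function(path, model) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  paramset(model,
           eps = stats::setNames(df$epsilon_kcal_mol, df$type_id),
           rmin_half = stats::setNames(df$rmin_half_A, df$type_id))
}
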