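# The regularized property-matching objective.
#
# Each training compound m contributes L_m = sum_p |y_p - y_p,ref|^2 / d_p^2
# over its available properties; the total objective adds a Tikhonov
# restraint w_reg * |k|^2 on the mathematical parameter vector. Default
# denominators: 95 kg/m^3 for density and 0.95 kJ/mol for heat of
# vaporization. Training conventionally uses density + HOV only; the
# dielectric constant can enter evaluation with a deliberately large
# denominator (default 10) so it is weighed very little.

DEFAULT_DENOMINATORS <- c(density = 95, hov = 0.95, dielectric = 10)
DEFAULT_W_REG <- 0.1

#' Create a property record
#'
#' One compound's property triple (any subset may be present).
#'
#' @param compound_id Identifier string.
#' @param density kg/m^3 (or `NA`).
#' @param hov Heat of vaporization, kJ/mol (or `NA`).
#' @param dielectric Relative dielectric constant (or `NA`).
#' @param se Optional named numeric vector of standard errors.
#' @return A one-row data frame with class `lj_property_record` columns.
#' @export
property_record <- function(compound_id, density = NA_real_, hov = NA_real_,
                            dielectric = NA_real_, se = NULL) {
  out <- data.frame(compound_id = compound_id, density = density, hov = hov,
                    dielectric = dielectric, stringsAsFactors = FALSE)
  if (!is.null(se)) for (p in names(se)) out[[paste0(p, "_se")]] <- se[[p]]
  out
}

#' Per-compound objective term
#'
#' Sum over the properties present in both prediction and reference of the
#' squared error divided by the squared property denominator.
#'
#' @param predicted,reference One-row data frames (or lists) with fields
#'   among `density`, `hov`, `dielectric`.
#' @param denominators Named vector of property denominators d_p; defaults
#'   to `DEFAULT_DENOMINATORS`.
#' @param properties Which properties to include when shared; default
#'   density + HOV (the training convention).
#' @return The non-negative scalar L_m.
#' @export
molecule_term <- function(predicted, reference,
                          denominators = DEFAULT_DENOMINATORS,
                          properties = c("density", "hov")) {
  total <- 0
  for (p in properties) {
    yp <- suppressWarnings(as.numeric(predicted[[p]]))
    yr <- suppressWarnings(as.numeric(reference[[p]]))
    if (is.null(yp) || is.null(yr) || length(yp) == 0L || length(yr) == 0L ||
        is.na(yp) || is.na(yr)) next
    d <- if (p %in% names(denominators)) denominators[[p]] else NULL
    if (is.null(d) || is.na(d))
      stop_config(sprintf("no denominator configured for property '%s'", p))
    if (d <= 0) stop_config("property denominators must be positive")
    total <- total + (yp - yr)^2 / d^2
  }
  total
}

#' Assemble the total regularized objective
#'
#' `L(k) = sum_m L_m + w_reg |k|^2`.
#'
#' @param terms Numeric vector of per-compound terms L_m (may be empty).
#' @param k Mathematical parameter vector (see [to_math()]); `NULL` or
#'   all-zero means the restraint vanishes.
#' @param w_reg Regularization weight (default 0.1).
#' @return An object of class `lj_objective`: list with `terms`,
#'   `restraint`, `total`, `w_reg`.
#' @export
total_objective <- function(terms, k = NULL, w_reg = DEFAULT_W_REG) {
  if (w_reg < 0) stop_domain("w_reg must be non-negative")
  if (any(terms < 0)) stop_domain("objective terms must be non-negative")
  restraint <- if (is.null(k)) 0 else w_reg * sum(k^2)
  structure(list(terms = as.numeric(terms), restraint = restraint,
                 total = sum(terms) + restraint, w_reg = w_reg),
            class = "lj_objective")
}

#' @export
print.lj_objective <- function(x, ...) {
  cat(sprintf("<lj_objective> total %.4g = data %.4g (%d compounds) + restraint %.4g (w_reg %.3g)\n",
              x$total, sum(x$terms), length(x$terms), x$restraint, x$w_reg))
  invisible(x)
}

#' Restraint contribution of one parameter set relative to another
#'
#' Computes `w_reg * |k|^2` where k is the mathematical displacement of
#' `candidate` from `reference` under the prior widths. By default the sum
#' runs over unique adjustable parameters (one epsilon and one rmin_half
#' term per type); `per_display_row = TRUE` instead sums over the 12-row
#' common expansion, counting duplicated display rows multiply.
#'
#' @param candidate,reference `lj_paramset` objects for the same typing
#'   model.
#' @param w_reg Regularization weight.
#' @param per_display_row Count duplicated display rows multiply?
#' @return Dimensionless non-negative scalar.
#' @export
restraint_contribution <- function(candidate, reference,
                                   w_reg = DEFAULT_W_REG,
                                   per_display_row = FALSE) {
  if (!identical(candidate$model_name, reference$model_name))
    stop_contract("candidate and reference belong to different typing models")
  if (per_display_row) {
    ec <- common_row_expansion(candidate)
    er <- common_row_expansion(reference)
    k <- c((ec$eps - er$eps) / candidate$t_eps,
           (ec$rmin_half - er$rmin_half) / candidate$t_rmin)
  } else {
    k <- c((candidate$types$eps - reference$types$eps) / candidate$t_eps,
           (candidate$types$rmin_half - reference$types$rmin_half) /
             candidate$t_rmin)
  }
  w_reg * sum(k^2)
}

#' Mean absolute percent errors per property
#'
#' For each property present, the mean over compounds of
#' `100 |y_pred - y_ref| / |y_ref|`. Compounds with a zero reference value
#' are excluded from that property's mean with a warning.
#'
#' @param predictions,references Data frames with `compound_id` and
#'   property columns (`density`, `hov`, `dielectric`).
#' @param properties Properties to evaluate.
#' @return Named numeric vector of percent errors (NA when no compound has
#'   the property).
#' @export
percent_errors <- function(predictions, references,
                           properties = c("density", "hov", "dielectric")) {
  m <- match(predictions$compound_id, references$compound_id)
  if (anyNA(m)) stop_input("predictions contain unknown compound ids")
  out <- stats::setNames(rep(NA_real_, length(properties)), properties)
  for (p in properties) {
    if (!p %in% names(predictions) || !p %in% names(references)) next
    yp <- predictions[[p]]
    yr <- references[[p]][m]
    keep <- !is.na(yp) & !is.na(yr)
    zero <- keep & yr == 0
    if (any(zero)) {
      warning(sprintf("%d compound(s) with zero reference %s excluded",
                      sum(zero), p))
      keep <- keep & !zero
    }
    if (any(keep)) out[[p]] <- mean(100 * abs(yp[keep] - yr[keep]) /
                                      abs(yr[keep]))
  }
  out
}

#' Read a property reference table from CSV
#'
#' Expected columns: `compound_id`, `density_kg_m3`, `hov_kJ_mol`,
#' optionally `dielectric` and per-row denominator overrides
#' (`d_density`, `d_hov`, `d_dielectric`).
#'
#' @param path CSV path.
#' @return Data frame with standardized column names (`density`, `hov`,
#'   `dielectric`).
#' @export
read_reference_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  ren <- c(density_kg_m3 = "density", hov_kJ_mol = "hov")
  for (old in names(ren)) {
    if (old %in% names(df)) names(df)[names(df) == old] <- ren[[old]]
  }
  need <- c("compound_id")
  if (!all(need %in% names(df)))
    stop_input("reference table must contain a 'compound_id' column")
  df
}
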