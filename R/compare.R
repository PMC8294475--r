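# Parameter-space geometry of typing models: each model becomes a point in
# 24-dimensional space via a common 12-row SMIRKS expansion (duplicated
# rows within a model carry identical values), epsilon entries are scaled
# onto the r_1/2 footing, and models are compared by Euclidean distance.

# The 12 display rows of the common expansion (4 H, 3 C, 2 N, 3 O), each
# with a probe (SMILES, atom index in documented order) whose typed
# assignment under a model selects the parameter value for that row.
.common_rows <- function() {
  data.frame(
    element_group = c(rep("Hydrogen", 4), rep("Carbon", 3),
                      rep("Nitrogen", 2), rep("Oxygen", 3)),
    smirks = c("[#1:1]-[#6X4]", "[#1:1]-[#6X3]", "[#1:1]-[#7]", "[#1:1]-[#8]",
               "[#6:1]", "[#6X4:1]", "[#6X2:1]",
               "[#7X3:1]", "[#7:1]",
               "[#8:1]", "[#8X2H1+0:1]", "[#8X2H0+0:1]"),
    probe_smiles = c("CC", "C=C", "CN", "CO",
                     "CC(=O)C", "CC", "CC#N",
                     "CN", "CC#N",
                     "CC(=O)C", "CO", "COC"),
    # atom index within the probe after explicit-H expansion
    probe_atom = c(3L, 3L, 7L, 6L,
                   2L, 1L, 2L,
                   2L, 3L,
                   3L, 2L, 2L),
    stringsAsFactors = FALSE)
}

#' Expand a parameter set onto the common 12-row layout
#'
#' Every typing model over CHON chemistry is projected onto the same 12
#' SMIRKS display rows (4 hydrogen, 3 carbon, 2 nitrogen, 3 oxygen
#' environments). The value for each row is the parameter of the type the
#' model assigns to a probe atom in that chemical environment, so rows a
#' model does not distinguish carry duplicated values.
#'
#' @param params An `lj_paramset`.
#' @param model The owning `lj_typing_model` (or name; defaults to
#'   `params$model_name`).
#' @return Data frame with the 12 rows plus `type_id`, `eps`, `rmin_half`.
#' @export
common_row_expansion <- function(params, model = NULL) {
  stopifnot(inherits(params, "lj_paramset"))
  if (is.null(model)) model <- params$model_name
  if (is.character(model)) model <- typing_model(model)
  rows <- .common_rows()
  tid <- character(nrow(rows))
  for (k in seq_len(nrow(rows))) {
    mol <- parse_compound(rows$probe_smiles[k])
    tt <- assign_types(mol, model)
    tid[k] <- tt[rows$probe_atom[k]]
  }
  look <- match(tid, params$types$type_id)
  if (anyNA(look))
    stop_contract("parameter set does not cover all common-row types")
  rows$type_id <- tid
  rows$eps <- params$types$eps[look]
  rows$rmin_half <- params$types$rmin_half[look]
  rows
}

#' Ratio of mean half-radius to mean well depth
#'
#' The dimensionless factor used to scale epsilon values onto the same
#' footing as r_1/2 before computing distances: the mean of all `rmin_half`
#' entries divided by the mean of all `eps` entries, over every row of
#' every supplied expansion (duplicated rows included).
#'
#' @param expansions List of data frames from [common_row_expansion()] (or
#'   a single one).
#' @return The scale factor (about 13.7 for the packaged optimized sets).
#' @export
epsilon_scale_factor <- function(expansions) {
  if (is.data.frame(expansions)) expansions <- list(expansions)
  if (!length(expansions)) stop_input("need at least one expansion")
  eps <- unlist(lapply(expansions, `[[`, "eps"))
  rm2 <- unlist(lapply(expansions, `[[`, "rmin_half"))
  me <- mean(eps)
  if (me == 0) stop_domain("mean epsilon is zero; scale factor undefined")
  mean(rm2) / me
}

.expansion_vector <- function(expansion, scale) {
  # ordering contract: the 12 rmin_half entries, then the 12 scaled eps
  c(expansion$rmin_half, expansion$eps * scale)
}

#' Euclidean distance matrix between typing models in parameter space
#'
#' Each model is a point in 24-dimensional space (12 `rmin_half` values
#' followed by 12 epsilon values scaled by `scale`); distances are plain
#' Euclidean norms of the difference vectors.
#'
#' @param expansions Named list of common-row expansions (names = model
#'   labels).
#' @param scale Epsilon scale factor; default recomputes it from
#'   `expansions` via [epsilon_scale_factor()].
#' @return An object of class `lj_distance_report`: list with `models`,
#'   `scale`, and `distances` (symmetric matrix, zero diagonal).
#' @export
distance_matrix <- function(expansions, scale = NULL) {
  if (is.null(names(expansions)) || any(!nzchar(names(expansions))))
    stop_contract("'expansions' must be a named list")
  ref <- expansions[[1L]]$smirks
  for (e in expansions)
    if (!identical(e$smirks, ref))
      stop_contract("expansions carry inconsistent row lists")
  if (is.null(scale)) scale <- epsilon_scale_factor(expansions)
  vecs <- vapply(expansions, .expansion_vector, numeric(2L * length(ref)),
                 scale = scale)
  n <- length(expansions)
  d <- matrix(0, n, n, dimnames = list(names(expansions), names(expansions)))
  for (i in seq_len(n)) for (j in seq_len(n))
    d[i, j] <- sqrt(sum((vecs[, i] - vecs[, j])^2))
  structure(list(models = names(expansions), scale = scale, distances = d),
            class = "lj_distance_report")
}

#' @export
print.lj_distance_report <- function(x, ...) {
  cat(sprintf("<lj_distance_report> %d models, epsilon scale %.4g\n",
              length(x$models), x$scale))
  print(round(x$distances, 2))
  invisible(x)
}

#' Nearest neighbor of a model in parameter space
#'
#' @param report An `lj_distance_report`.
#' @param model Model label (row of the report).
#' @return Character vector of the closest other model(s); more than one
#'   only on exact ties.
#' @export
nearest_neighbor <- function(report, model) {
  stopifnot(inherits(report, "lj_distance_report"))
  if (!model %in% report$models) stop_input(sprintf("unknown model '%s'", model))
  if (length(report$models) < 2L) stop_input("need at least two models")
  d <- report$distances[model, ]
  d <- d[names(d) != model]
  names(d)[d == min(d)]
}

#' Load the packaged optimized LJ parameter tables
#'
#' The published optimized parameter sets for five typing models (HCON,
#' HCO3N, H2CON, H2CO3N and the reoptimized H2CO3N), laid out on the common
#' 12 display rows, are shipped as a CSV fixture. Returned either as raw
#' rows or as ready-made common-row expansions.
#'
#' @param as How to return the data: `"expansions"` (named list of
#'   common-row data frames, the default) or `"rows"` (the raw data frame).
#' @return See `as`.
#' @export
load_fixture_params <- function(as = c("expansions", "rows")) {
  as <- match.arg(as)
  path <- system.file("extdata", "optimized_lj_params.csv",
                      package = "ljtyping", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (as == "rows") return(df)
  rows <- .common_rows()
  out <- lapply(split(df, df$model), function(sub) {
    sub <- sub[order(sub$row), ]
    if (!identical(sub$smirks, rows$smirks))
      stop_contract("fixture rows do not match the common-row layout")
    data.frame(element_group = sub$element_group, smirks = sub$smirks,
               eps = sub$epsilon_kcal_mol, rmin_half = sub$rmin_half_A,
               stringsAsFactors = FALSE)
  })
  out[unique(df$model)]
}
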