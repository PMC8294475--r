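# Typing models: ordered SMIRKS rules with last-match-wins priority.
#
# A typing model is an ordered list of rules in ascending priority. Each rule
# carries a one-tagged-atom SMIRKS pattern and a type id. Assignment walks the
# list in order: the general (element-wide) pattern assigns first and more
# specific patterns listed later overwrite it, so every atom of a covered
# element ends up with exactly one type. A lowest-priority element-wide
# fallback rule may reuse the type id of one of the specific rules; the
# model's type count is the number of distinct type ids.
#
# Two typeset glitches in the published rule table are resolved in favour of
# the SMIRKS strings over their prose labels: the "[#1:1]-[#7]" row is
# described as H-on-oxygen (it matches H-on-nitrogen; the attached numbers
# and SMIRNOFF source follow the SMIRKS), and "[#8X2H0+0]" is labelled
# "Alcohol" although an X2H0 oxygen carries no hydrogen (it is an ether
# oxygen). Type ids here name what the SMIRKS matches.

# Building blocks: per element, per split level, the ordered rules with the
# published starting parameters (epsilon kcal/mol, rmin_half Angstrom).
# `sp_carbon_h = TRUE` widens the sp2-H rule to [#6X3,#6X2] so hydrogens on
# sp carbons are caught by the specific rule rather than the fallback; the
# strict published pattern ([#6X3] only) is available for fidelity runs.
.typing_blocks <- function(sp_carbon_h = TRUE) {
  h_sp2 <- if (sp_carbon_h) "[#1:1]-[#6X3,#6X2]" else "[#1:1]-[#6X3]"
  list(
    H = list(
      `1` = list(
        list(smirks = "[#1:1]", type = "H", eps = 0.0157, rmin = 1.4870)),
      `2` = list(
        list(smirks = "[#1:1]", type = "H.apolar", eps = 0.0157, rmin = 1.4870),
        list(smirks = "[#1:1]-[#6]", type = "H.apolar", eps = 0.0157, rmin = 1.4870),
        list(smirks = "[#1:1]-[#7,#8]", type = "H.polar", eps = 0.0157, rmin = 0.6000)),
      `4` = list(
        list(smirks = "[#1:1]", type = "H.CX4", eps = 0.0157, rmin = 1.4870),
        list(smirks = "[#1:1]-[#6X4]", type = "H.CX4", eps = 0.0157, rmin = 1.4870),
        list(smirks = h_sp2, type = "H.CX3", eps = 0.0150, rmin = 1.4590),
        list(smirks = "[#1:1]-[#7]", type = "H.N", eps = 0.0157, rmin = 0.6000),
        list(smirks = "[#1:1]-[#8]", type = "H.O", eps = 5.27e-05, rmin = 0.3000))),
    C = list(
      `1` = list(
        list(smirks = "[#6:1]", type = "C", eps = 0.0860, rmin = 1.9080)),
      `3` = list(
        list(smirks = "[#6:1]", type = "C.X3", eps = 0.0860, rmin = 1.9080),
        list(smirks = "[#6X4:1]", type = "C.X4", eps = 0.1094, rmin = 1.9080),
        list(smirks = "[#6X2:1]", type = "C.X2", eps = 0.2100, rmin = 1.9080))),
    O = list(
      `1` = list(
        list(smirks = "[#8:1]", type = "O", eps = 0.2100, rmin = 1.6612)),
      `3` = list(
        list(smirks = "[#8:1]", type = "O.carbonyl", eps = 0.2100, rmin = 1.6612),
        list(smirks = "[#8X2H0+0:1]", type = "O.ether", eps = 0.1700, rmin = 1.6837),
        list(smirks = "[#8X2H1+0:1]", type = "O.hydroxyl", eps = 0.2104, rmin = 1.7210))),
    N = list(
      `1` = list(
        list(smirks = "[#7:1]", type = "N", eps = 0.1700, rmin = 1.8240)),
      `2` = list(
        list(smirks = "[#7:1]", type = "N.X1", eps = 0.1700, rmin = 1.8240),
        list(smirks = "[#7X3:1]", type = "N.X3", eps = 0.1700, rmin = 1.8240))))
}

# 15-type skeleton patterned after the SMIRNOFF force-field subset spanned
# by CHON organic liquids: 8 H, 3 C, 3 O, 1 N. The H-on-carbon-adjacent-to-
# heteroatom rows use a two-bond path pattern.
.smirff_subset_rules <- function() {
  list(
    list(smirks = "[#1:1]", type = "H", eps = 0.0157, rmin = 1.4870),
    list(smirks = "[#1:1]-[#6X4]", type = "H.CX4", eps = 0.0157, rmin = 1.4870),
    list(smirks = "[#1:1]-[#6X4]-[#7,#8]", type = "H.CX4.het", eps = 0.0157, rmin = 1.3870),
    list(smirks = "[#1:1]-[#6X3]", type = "H.CX3", eps = 0.0150, rmin = 1.4590),
    list(smirks = "[#1:1]-[#6X3]-[#7,#8]", type = "H.CX3.het", eps = 0.0150, rmin = 1.4090),
    list(smirks = "[#1:1]-[#6X2]", type = "H.CX2", eps = 0.0150, rmin = 1.4590),
    list(smirks = "[#1:1]-[#7]", type = "H.N", eps = 0.0157, rmin = 0.6000),
    list(smirks = "[#1:1]-[#8]", type = "H.O", eps = 5.27e-05, rmin = 0.3000),
    list(smirks = "[#6:1]", type = "C.X3", eps = 0.0860, rmin = 1.9080),
    list(smirks = "[#6X4:1]", type = "C.X4", eps = 0.1094, rmin = 1.9080),
    list(smirks = "[#6X2:1]", type = "C.X2", eps = 0.2100, rmin = 1.9080),
    list(smirks = "[#8:1]", type = "O.carbonyl", eps = 0.2100, rmin = 1.6612),
    list(smirks = "[#8X2H0+0:1]", type = "O.ether", eps = 0.1700, rmin = 1.6837),
    list(smirks = "[#8X2H1+0:1]", type = "O.hydroxyl", eps = 0.2104, rmin = 1.7210),
    list(smirks = "[#7:1]", type = "N", eps = 0.1700, rmin = 1.8240))
}

#' Construct a typing model from its name
#'
#' Model names follow the element-count grammar of the typing-model family:
#' an element letter followed by an optional count digit, e.g. `"HCON"` (one
#' LJ type per element), `"H2CO3N"` (polar/apolar H split plus a three-way
#' oxygen split), `"H4C3O3N2"` (every split at once). Supported split levels
#' are H in \{1, 2, 4\}, C in \{1, 3\}, O in \{1, 3\}, N in \{1, 2\}. The
#' special name `"SmirFF"` yields the 15-type SMIRNOFF-subset skeleton.
#'
#' Rules are ordered in ascending priority (last match wins); every element
#' has a lowest-priority element-wide fallback so typing is total on CHON
#' molecules.
#'
#' @param name Model name string.
#' @param sp_carbon_h If `TRUE` (default) the sp2-H rule also matches
#'   hydrogens on sp carbons (`[#1:1]-[#6X3,#6X2]`); set `FALSE` for the
#'   strictly published `[#6X3]`-only pattern.
#' @return An object of class `lj_typing_model`: list with `name`, `rules`
#'   (ordered list of `smirks`/`type`/`eps`/`rmin`), and `types` (distinct
#'   type ids in first-appearance order).
#' @examples
#' m <- typing_model("H2CO3N")
#' length(m$types)  # 7
#' @export
typing_model <- function(name, sp_carbon_h = TRUE) {
  if (identical(tolower(name), "smirff"))
    return(.new_typing_model("SmirFF", .smirff_subset_rules()))
  toks <- regmatches(name, gregexpr("[HCON][0-9]*", name))[[1]]
  if (!length(toks) || paste(toks, collapse = "") != name)
    stop_input(sprintf("cannot parse typing-model name '%s'", name))
  blocks <- .typing_blocks(sp_carbon_h)
  rules <- list()
  seen <- character(0)
  for (tok in toks) {
    el <- substr(tok, 1L, 1L)
    lev <- if (nchar(tok) > 1L) substr(tok, 2L, nchar(tok)) else "1"
    if (el %in% seen) stop_input(sprintf("element '%s' repeated in '%s'", el, name))
    seen <- c(seen, el)
    blk <- blocks[[el]][[lev]]
    if (is.null(blk))
      stop_input(sprintf("unsupported split level %s for element %s in '%s'",
                         lev, el, name))
    rules <- c(rules, blk)
  }
  .new_typing_model(name, rules)
}

.new_typing_model <- function(name, rules) {
  types <- unique(vapply(rules, function(r) r$type, ""))
  compiled <- lapply(rules, function(r) parse_smirks(r$smirks))
  structure(list(name = name, rules = rules, types = types,
                 compiled = compiled),
            class = "lj_typing_model")
}

#' @export
print.lj_typing_model <- function(x, ...) {
  cat(sprintf("<lj_typing_model> %s: %d types, %d rules\n",
              x$name, length(x$types), length(x$rules)))
  for (k in seq_along(x$rules))
    cat(sprintf("  %2d. %-22s -> %s\n", k, x$rules[[k]]$smirks,
                x$rules[[k]]$type))
  invisible(x)
}

#' The typing models investigated by the analysis
#'
#' Returns the names of the eleven packaged typing models: the one-type-per-
#' element base model, single-element splits, the everything-split model,
#' the polar/apolar-hydrogen family, and the 15-type SMIRNOFF subset.
#'
#' @return Character vector of model names accepted by [typing_model()].
#' @export
packaged_models <- function() {
  c("HCON", "H4CON", "HC3ON", "HCO3N", "HCON2", "H4C3O3N2",
    "H2CON", "H2C3ON", "H2CO3N", "H2CON2", "SmirFF")
}

#' Assign LJ types to every atom of a molecule
#'
#' Applies the model's ordered rules with last-match-wins semantics: the
#' type of an atom is that of the highest-priority (latest-listed) rule
#' matching it.
#'
#' @param mol An `lj_molecule` from [parse_compound()].
#' @param model An `lj_typing_model` or model name.
#' @return Character vector of type ids, one per atom (in the molecule's
#'   documented atom order).
#' @examples
#' assign_types(parse_compound("C"), typing_model("HCON"))
#' @export
assign_types <- function(mol, model) {
  if (is.character(model)) model <- typing_model(model)
  stopifnot(inherits(mol, "lj_molecule"), inherits(model, "lj_typing_model"))
  n <- nrow(mol$atoms)
  out <- rep(NA_character_, n)
  for (k in seq_along(model$rules)) {
    pat <- model$compiled[[k]]
    tid <- model$rules[[k]]$type
    for (i in seq_len(n)) {
      if (smirks_matches_atom(mol, i, pat)) out[i] <- tid
    }
  }
  if (anyNA(out)) {
    miss <- which(is.na(out))[1L]
    stop_typing(sprintf(
      "atom %d (element %s) of '%s' is matched by no rule of model %s",
      miss, mol$atoms$element[miss], mol$smiles, model$name))
  }
  out
}

#' Count the LJ types of a model
#'
#' With an empty compound list, returns the model's defined type count (the
#' digits of the model name: e.g. HC3ON has 1 + 3 + 1 + 1 = 6). Over a
#' compound set, returns the number of distinct types actually assigned.
#'
#' @param model An `lj_typing_model` or name.
#' @param compounds Optional list of `lj_molecule` objects.
#' @return Integer type count.
#' @export
count_types <- function(model, compounds = list()) {
  if (is.character(model)) model <- typing_model(model)
  if (!length(compounds)) return(length(model$types))
  used <- unique(unlist(lapply(compounds, assign_types, model = model)))
  length(used)
}

#' Test the "more general to more specific" relation between two models
#'
#' Model `fine` refines model `coarse` when, over the probe compound set,
#' the partition of atoms induced by `fine`'s types subdivides the partition
#' induced by `coarse`'s types: every fine type maps into exactly one coarse
#' type. This is the arrow relation of the typing-model lattice.
#'
#' @param coarse,fine `lj_typing_model` objects or names.
#' @param probes List of `lj_molecule` probe compounds; defaults to a small
#'   built-in CHON probe set spanning the packaged chemistries.
#' @return A list with `refines` (logical) and, when `TRUE`, `mapping`
#'   (named character vector fine type -> coarse type over the probes).
#' @export
refinement_relation <- function(coarse, fine, probes = NULL) {
  if (is.character(coarse)) coarse <- typing_model(coarse)
  if (is.character(fine)) fine <- typing_model(fine)
  if (is.null(probes)) probes <- lapply(.default_probe_smiles(), parse_compound)
  pairs <- list()
  for (mol in probes) {
    tc <- assign_types(mol, coarse)
    tf <- assign_types(mol, fine)
    pairs[[length(pairs) + 1L]] <- data.frame(fine = tf, coarse = tc,
                                              stringsAsFactors = FALSE)
  }
  tab <- unique(do.call(rbind, pairs))
  split_map <- split(tab$coarse, tab$fine)
  ok <- all(vapply(split_map, function(v) length(unique(v)) == 1L, NA))
  if (!ok) return(list(refines = FALSE, mapping = NULL))
  mapping <- vapply(split_map, function(v) v[[1L]], "")
  list(refines = TRUE, mapping = mapping)
}

.default_probe_smiles <- function() {
  c("CC", "C=C", "C#CC", "CCO", "CCOCC", "CC(=O)C", "CC(=O)OC", "CC=O",
    "CCN", "CNC", "CC#N", "CCCO", "NCCO")
}
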