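# A small SMIRKS/SMARTS matcher covering the vocabulary used by vdW typing
# rules: one tagged atom, optionally constrained by a short bonded path.
#
# Supported pattern grammar (whitespace tolerated, as some published tables
# typeset "[#8X2H0 + 0:1]"):
#   pattern  := atom ( bond atom )*        (first atom carries the :1 tag)
#   bond     := '-' | '~'                  ('-' single non-aromatic, '~' any)
#   atom     := '[' expr (':' digit)? ']'
#   expr     := alt (',' alt)*             (OR of alternatives)
#   alt      := prim+                      (AND of primitives)
#   prim     := '#'<z> | 'X'<n> | 'H'<n> | '+'<n> | '-'<n> | 'A' | 'a' | '*'
# X counts total connections (including explicit hydrogens), matching the
# convention used after explicit-H expansion of the molecule graph.

parse_smirks <- function(pattern) {
  s <- gsub("[[:space:]]+", "", pattern)
  atoms <- list()
  bonds <- character(0)
  pos <- 1L
  n <- nchar(s)
  expect_bond <- FALSE
  while (pos <= n) {
    ch <- substr(s, pos, pos)
    if (expect_bond) {
      if (!ch %in% c("-", "~"))
        stop_parse(sprintf("expected bond symbol at '%s' in SMIRKS '%s'",
                           substr(s, pos, n), pattern))
      bonds <- c(bonds, ch)
      pos <- pos + 1L
      expect_bond <- FALSE
    } else {
      if (ch != "[")
        stop_parse(sprintf("expected '[' at '%s' in SMIRKS '%s'",
                           substr(s, pos, n), pattern))
      close <- pos
      while (close <= n && substr(s, close, close) != "]") close <- close + 1L
      if (close > n) stop_parse(sprintf("unclosed '[' in SMIRKS '%s'", pattern))
      atoms[[length(atoms) + 1L]] <-
        .parse_smirks_atom(substr(s, pos + 1L, close - 1L), pattern)
      pos <- close + 1L
      expect_bond <- TRUE
    }
  }
  if (!length(atoms))
    stop_parse(sprintf("SMIRKS '%s' contains no atom expression", pattern))
  tags <- which(vapply(atoms, function(a) a$tagged, NA))
  if (length(tags) != 1L || tags != 1L)
    stop_parse(sprintf(
      "SMIRKS '%s' must tag exactly the first atom (one ':1' map)", pattern))
  structure(list(atoms = atoms, bonds = bonds, pattern = pattern),
            class = "lj_smirks")
}

.parse_smirks_atom <- function(body, pattern) {
  tagged <- grepl(":[0-9]+$", body)
  body <- sub(":[0-9]+$", "", body)
  alts <- strsplit(body, ",", fixed = TRUE)[[1]]
  if (!length(alts)) stop_parse(sprintf("empty atom expression in '%s'", pattern))
  parsed <- lapply(alts, function(alt) {
    prims <- list(z = NA_integer_, X = NA_integer_, H = NA_integer_,
                  charge = NA_integer_, aliphatic = FALSE, aromatic = FALSE)
    t <- alt
    while (nzchar(t)) {
      if (grepl("^#[0-9]+", t)) {
        m <- regmatches(t, regexpr("^#[0-9]+", t))
        prims$z <- as.integer(substr(m, 2L, nchar(m)))
      } else if (grepl("^X[0-9]+", t)) {
        m <- regmatches(t, regexpr("^X[0-9]+", t))
        prims$X <- as.integer(substr(m, 2L, nchar(m)))
      } else if (grepl("^H[0-9]+", t)) {
        m <- regmatches(t, regexpr("^H[0-9]+", t))
        prims$H <- as.integer(substr(m, 2L, nchar(m)))
      } else if (grepl("^[+-][0-9]+", t)) {
        m <- regmatches(t, regexpr("^[+-][0-9]+", t))
        prims$charge <- as.integer(m)
      } else if (grepl("^\\*", t)) {
        m <- "*"
      } else if (grepl("^A", t)) {
        m <- "A"; prims$aliphatic <- TRUE
      } else if (grepl("^a", t)) {
        m <- "a"; prims$aromatic <- TRUE
      } else {
        stop_parse(sprintf("unsupported SMIRKS primitive at '%s' in '%s'",
                           t, pattern))
      }
      t <- substr(t, nchar(m) + 1L, nchar(t))
    }
    prims
  })
  list(alts = parsed, tagged = tagged)
}

.atom_matches_expr <- function(mol, idx, expr) {
  a <- mol$atoms[idx, ]
  z <- .ELEMENT_Z[[a$element]]
  for (alt in expr$alts) {
    ok <- TRUE
    if (!is.na(alt$z) && alt$z != z) ok <- FALSE
    if (ok && !is.na(alt$X) && alt$X != a$degree) ok <- FALSE
    if (ok && !is.na(alt$H) && alt$H != a$n_h) ok <- FALSE
    if (ok && !is.na(alt$charge) && alt$charge != a$formal_charge) ok <- FALSE
    if (ok && alt$aliphatic && a$aromatic) ok <- FALSE
    if (ok && alt$aromatic && !a$aromatic) ok <- FALSE
    if (ok) return(TRUE)
  }
  FALSE
}

.bond_matches <- function(mol, i, j, sym) {
  if (sym == "~") return(TRUE)
  # '-': single, non-aromatic
  b <- mol$bonds
  hit <- (b$i == i & b$j == j) | (b$i == j & b$j == i)
  any(hit & b$order == 1 & !b$aromatic)
}

#' Match a SMIRKS typing pattern against one atom
#'
#' Tests whether the tagged (first) atom of a parsed or textual SMIRKS
#' pattern matches atom `idx` of `mol`, walking any bonded-path constraint
#' by depth-first search over simple paths.
#'
#' @param mol An `lj_molecule`.
#' @param idx Atom index (1-based, post explicit-H expansion order).
#' @param pattern A SMIRKS string or an object from [parse_smirks()].
#' @return `TRUE` or `FALSE`.
#' @export
smirks_matches_atom <- function(mol, idx, pattern) {
  if (is.character(pattern)) pattern <- parse_smirks(pattern)
  stopifnot(inherits(pattern, "lj_smirks"))
  if (idx < 1L || idx > nrow(mol$atoms)) stop_input("atom index out of range")
  if (!.atom_matches_expr(mol, idx, pattern$atoms[[1L]])) return(FALSE)
  if (length(pattern$atoms) == 1L) return(TRUE)
  nb <- .mol_neighbors(mol)
  .match_path(mol, nb, pattern, depth = 2L, current = idx, used = idx)
}

.match_path <- function(mol, nb, pattern, depth, current, used) {
  if (depth > length(pattern$atoms)) return(TRUE)
  bond_sym <- pattern$bonds[depth - 1L]
  for (j in nb[[current]]) {
    if (j %in% used) next
    if (!.bond_matches(mol, current, j, bond_sym)) next
    if (!.atom_matches_expr(mol, j, pattern$atoms[[depth]])) next
    if (.match_path(mol, nb, pattern, depth + 1L, j, c(used, j))) return(TRUE)
  }
  FALSE
}
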