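# Molecule graphs and a restricted SMILES reader.
#
# The scope of chemistry here is the CHON organic-liquid space the typing
# models cover: neutral small molecules written in everyday SMILES (organic
# subset atoms, branches, ring closures, -/=/# bonds, lowercase aromatics).
# No stereochemistry, isotopes, or multi-fragment inputs. A full cheminformatics
# toolkit is deliberately not a dependency: the SMIRKS primitives used by the
# typing rules only need elements, connection counts, attached hydrogens and
# formal charges, all of which this reader provides exactly.

.ELEMENT_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                   F = 18.998, P = 30.974, S = 32.06, Cl = 35.45, Br = 79.904)
.ELEMENT_Z    <- c(H = 1, C = 6, N = 7, O = 8, F = 9, P = 15, S = 16,
                   Cl = 17, Br = 35)
.DEFAULT_VALENCE <- c(C = 4, N = 3, O = 2, H = 1, F = 1, Cl = 1, Br = 1,
                      P = 3, S = 2)

#' Parse a SMILES string into a molecule graph
#'
#' Reads a restricted SMILES string (CHON-centric organic subset: `C N O H
#' F S P Cl Br`, lowercase aromatic `c n o`, branches, ring-closure digits,
#' `- = #` bonds, bracket atoms with explicit H counts and formal charges)
#' and returns a molecule graph with all hydrogens made explicit.
#'
#' Atom ordering is stable and documented: heavy atoms appear in their
#' SMILES order (bracket hydrogens such as `[H]` count as written atoms),
#' followed by the implicit/bracket-count hydrogens appended in order of
#' their parent heavy atom. Partial charges, when supplied, must follow
#' this ordering.
#'
#' @param smiles A single SMILES string.
#' @param charges Optional numeric vector of per-atom partial charges (units
#'   of elementary charge e), one per atom *after* explicit-hydrogen
#'   expansion; use `NULL` (default) for typing-only use.
#' @return An object of class `lj_molecule`: a list with `atoms` (data frame:
#'   `element`, `aromatic`, `degree` = total connections including H,
#'   `n_h` = attached hydrogen count, `formal_charge`, `charge` = partial
#'   charge), `bonds` (data frame `i`, `j`, `order`; aromatic bonds carry
#'   order 1 with `aromatic = TRUE`), `smiles`, and `molar_mass` (g/mol).
#' @examples
#' m <- parse_compound("CCO")
#' nrow(m$atoms)  # 9: ethanol with explicit hydrogens
#' @export
parse_compound <- function(smiles, charges = NULL) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(smiles))
    stop_parse("'smiles' must be a single non-empty string")
  g <- .parse_smiles_graph(smiles)
  g <- .add_explicit_hydrogens(g)
  n <- nrow(g$atoms)
  if (!is.null(charges) && length(charges)) {
    if (length(charges) != n)
      stop_input(sprintf(
        "charge vector length %d does not match atom count %d (after explicit-H expansion) for '%s'",
        length(charges), n, smiles))
    if (!is.numeric(charges) || anyNA(charges))
      stop_input("charges must be numeric and non-missing")
    g$atoms$charge <- as.numeric(charges)
  } else {
    g$atoms$charge <- rep(0, n)
  }
  g$molar_mass <- sum(.ELEMENT_MASS[g$atoms$element])
  g$smiles <- smiles
  class(g) <- "lj_molecule"
  g
}

#' @export
print.lj_molecule <- function(x, ...) {
  cat(sprintf("<lj_molecule> %s: %d atoms (%s), M = %.3f g/mol\n",
              x$smiles, nrow(x$atoms),
              paste(sprintf("%s%d", names(table(x$atoms$element)),
                            as.integer(table(x$atoms$element))),
                    collapse = " "),
              x$molar_mass))
  invisible(x)
}

# -- tokenizer + state machine -------------------------------------------

.parse_smiles_graph <- function(smiles) {
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  n_ch <- length(chars)
  atoms <- list()      # each: list(element, aromatic, explicit_h, formal_charge)
  bonds <- list()      # each: c(i, j, order, aromatic)
  stack <- integer(0)
  prev <- 0L
  pending_order <- NA_real_   # NA = default
  pending_arom <- FALSE
  rings <- list()      # digit -> list(atom, order)

  add_atom <- function(el, aromatic, h = NA_integer_, fc = 0L) {
    atoms[[length(atoms) + 1L]] <<- list(element = el, aromatic = aromatic,
                                         explicit_h = h, formal_charge = fc)
    length(atoms)
  }
  add_bond <- function(i, j, order, aromatic) {
    if (i == j) stop_parse("self-bond in SMILES")
    bonds[[length(bonds) + 1L]] <<- list(i = i, j = j, order = order,
                                         aromatic = aromatic)
  }
  connect <- function(idx) {
    if (prev > 0L) {
      arom <- if (!is.na(pending_order)) pending_arom else
        (atoms[[prev]]$aromatic && atoms[[idx]]$aromatic)
      ord <- if (!is.na(pending_order)) pending_order else 1
      add_bond(prev, idx, ord, arom)
    }
    prev <<- idx
    pending_order <<- NA_real_
    pending_arom <<- FALSE
  }

  i <- 1L
  while (i <= n_ch) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n_ch && chars[j] != "]") j <- j + 1L
      if (j > n_ch) stop_parse("unclosed '[' in SMILES")
      body <- substr(smiles, i + 1L, j - 1L)
      at <- .parse_bracket_atom(body, smiles)
      idx <- add_atom(at$element, at$aromatic, at$h, at$fc)
      connect(idx)
      i <- j + 1L
    } else if (grepl("[A-Za-z]", ch)) {
      # organic subset, possibly two-letter (Cl, Br)
      el <- ch
      if (ch %in% c("C", "B") && i < n_ch && chars[i + 1L] %in% c("l", "r")) {
        two <- paste0(ch, chars[i + 1L])
        if (two %in% c("Cl", "Br")) { el <- two; i <- i + 1L }
      }
      aromatic <- el %in% c("c", "n", "o", "s", "p")
      el_up <- if (aromatic) toupper(el) else el
      if (!el_up %in% names(.DEFAULT_VALENCE))
        stop_parse(sprintf("unsupported atom symbol '%s' in '%s'", el, smiles))
      idx <- add_atom(el_up, aromatic)
      connect(idx)
      i <- i + 1L
    } else if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      pending_order <- switch(ch, "-" = 1, "=" = 2, "#" = 3, ":" = 1,
                              "/" = 1, "\\" = 1)
      pending_arom <- identical(ch, ":")
      i <- i + 1L
    } else if (ch == "(") {
      if (prev == 0L) stop_parse("branch before any atom in SMILES")
      stack <- c(stack, prev)
      i <- i + 1L
    } else if (ch == ")") {
      if (!length(stack)) stop_parse("unbalanced ')' in SMILES")
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (grepl("[0-9]", ch)) {
      if (prev == 0L) stop_parse("ring-closure digit before any atom")
      key <- ch
      if (!is.null(rings[[key]])) {
        open <- rings[[key]]
        ord <- if (!is.na(pending_order)) pending_order else open$order
        if (is.na(ord)) ord <- 1
        arom <- atoms[[open$atom]]$aromatic && atoms[[prev]]$aromatic
        add_bond(open$atom, prev, ord, arom)
        rings[[key]] <- NULL
        pending_order <- NA_real_
      } else {
        rings[[key]] <- list(atom = prev, order = pending_order)
        pending_order <- NA_real_
      }
      i <- i + 1L
    } else if (ch == "%") {
      stop_parse("two-digit ring closures ('%') are not supported")
    } else if (ch == ".") {
      stop_parse("multi-fragment SMILES ('.') are not supported")
    } else {
      stop_parse(sprintf("unexpected character '%s' in SMILES '%s'", ch, smiles))
    }
  }
  if (length(stack)) stop_parse("unbalanced '(' in SMILES")
  if (length(rings)) stop_parse("unclosed ring bond in SMILES")
  if (!length(atoms)) stop_parse("SMILES contains no atoms")

  el  <- vapply(atoms, function(a) a$element, "")
  arm <- vapply(atoms, function(a) a$aromatic, NA)
  exh <- vapply(atoms, function(a) as.integer(a$explicit_h), 0L)
  fc  <- vapply(atoms, function(a) as.integer(a$formal_charge), 0L)
  if (length(bonds)) {
    bi <- vapply(bonds, function(b) b$i, 0); bj <- vapply(bonds, function(b) b$j, 0)
    bo <- vapply(bonds, function(b) b$order, 0)
    ba <- vapply(bonds, function(b) b$aromatic, NA)
  } else {
    bi <- bj <- bo <- numeric(0); ba <- logical(0)
  }
  list(atoms = data.frame(element = el, aromatic = arm, explicit_h = exh,
                          formal_charge = fc, stringsAsFactors = FALSE),
       bonds = data.frame(i = as.integer(bi), j = as.integer(bj),
                          order = bo, aromatic = ba))
}

.parse_bracket_atom <- function(body, smiles) {
  # [<isotope?><symbol><H?><count?><charge?><:map?>]
  s <- gsub("^[0-9]+", "", body)             # isotope ignored
  s <- sub(":[0-9]+$", "", s)                # atom map ignored
  m <- regmatches(s, regexpr("^([A-Z][a-z]?|[cnops])", s))
  if (!length(m)) stop_parse(sprintf("cannot read bracket atom '[%s]' in '%s'",
                                     body, smiles))
  sym <- m
  rest <- substr(s, nchar(sym) + 1L, nchar(s))
  aromatic <- sym %in% c("c", "n", "o", "s", "p")
  el <- if (aromatic) toupper(sym) else sym
  if (!el %in% names(.ELEMENT_MASS))
    stop_parse(sprintf("unsupported element '%s' in '%s'", sym, smiles))
  h <- 0L
  hm <- regmatches(rest, regexpr("H[0-9]*", rest))
  if (length(hm) && el != "H") {
    h <- if (nchar(hm) > 1L) as.integer(substr(hm, 2L, nchar(hm))) else 1L
    rest <- sub("H[0-9]*", "", rest)
  }
  fc <- 0L
  cm <- regmatches(rest, regexpr("[+-][0-9]*$|\\++$|-+$", rest))
  if (length(cm)) {
    if (grepl("^[+-][0-9]+$", cm)) {
      fc <- as.integer(cm)
    } else {
      fc <- (if (substr(cm, 1, 1) == "+") 1L else -1L) * nchar(cm)
    }
  }
  list(element = el, aromatic = aromatic, h = h, fc = fc)
}

.add_explicit_hydrogens <- function(g) {
  a <- g$atoms
  n <- nrow(a)
  bond_order_sum <- numeric(n)
  if (nrow(g$bonds)) {
    for (r in seq_len(nrow(g$bonds))) {
      o <- g$bonds$order[r]
      bond_order_sum[g$bonds$i[r]] <- bond_order_sum[g$bonds$i[r]] + o
      bond_order_sum[g$bonds$j[r]] <- bond_order_sum[g$bonds$j[r]] + o
    }
  }
  implicit <- integer(n)
  for (k in seq_len(n)) {
    if (!is.na(a$explicit_h[k])) { implicit[k] <- a$explicit_h[k]; next }
    val <- .DEFAULT_VALENCE[[a$element[k]]]
    used <- bond_order_sum[k] + (if (a$aromatic[k]) 1 else 0)  # aromatic pi
    implicit[k] <- max(0L, as.integer(round(val - used + a$formal_charge[k] *
                                              (if (a$element[k] == "N") 1 else -1))))
    if (a$element[k] == "O" && a$formal_charge[k] < 0) implicit[k] <- 0L
  }
  new_i <- integer(0); new_j <- integer(0)
  h_parent <- integer(0)
  idx <- n
  for (k in seq_len(n)) {
    if (implicit[k] > 0L) {
      for (t in seq_len(implicit[k])) {
        idx <- idx + 1L
        h_parent <- c(h_parent, k)
        new_i <- c(new_i, k); new_j <- c(new_j, idx)
      }
    }
  }
  n_h <- length(h_parent)
  atoms <- data.frame(
    element = c(a$element, rep("H", n_h)),
    aromatic = c(a$aromatic, rep(FALSE, n_h)),
    formal_charge = c(a$formal_charge, rep(0L, n_h)),
    stringsAsFactors = FALSE)
  bonds <- data.frame(
    i = c(g$bonds$i, new_i), j = c(g$bonds$j, new_j),
    order = c(g$bonds$order, rep(1, n_h)),
    aromatic = c(g$bonds$aromatic, rep(FALSE, n_h)))
  deg <- integer(nrow(atoms)); nh <- integer(nrow(atoms))
  if (nrow(bonds)) {
    for (r in seq_len(nrow(bonds))) {
      i <- bonds$i[r]; j <- bonds$j[r]
      deg[i] <- deg[i] + 1L; deg[j] <- deg[j] + 1L
      if (atoms$element[j] == "H") nh[i] <- nh[i] + 1L
      if (atoms$element[i] == "H") nh[j] <- nh[j] + 1L
    }
  }
  atoms$degree <- deg
  atoms$n_h <- nh
  list(atoms = atoms, bonds = bonds)
}

# Adjacency list (heavy use by the SMIRKS matcher and geometry builder).
.mol_neighbors <- function(mol) {
  n <- nrow(mol$atoms)
  nb <- vector("list", n)
  if (nrow(mol$bonds)) {
    for (r in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds$i[r]; j <- mol$bonds$j[r]
      nb[[i]] <- c(nb[[i]], j); nb[[j]] <- c(nb[[j]], i)
    }
  }
  nb
}
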