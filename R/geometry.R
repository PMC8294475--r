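# Idealized rigid 3D geometry from the molecular graph.
#
# Bond lengths and angles come from a small built-in table; acyclic
# dihedrals are chosen pseudo-randomly (seed-controlled) once and the
# conformer is rigid thereafter. This replaces flexible MD with bonded
# terms: the toy simulator's purpose is exercising the optimization and
# comparison machinery, not absolute property accuracy. Rings are laid out
# only approximately and are outside the simulator's validated scope.

.BOND_LENGTHS <- list(
  "C-C" = 1.53, "C=C" = 1.33, "C#C" = 1.20, "C-H" = 1.09, "C-O" = 1.43,
  "C=O" = 1.22, "O-H" = 0.96, "C-N" = 1.47, "C=N" = 1.28, "C#N" = 1.16,
  "N-H" = 1.01, "N-N" = 1.45, "O-O" = 1.48, "N-O" = 1.40, "N=O" = 1.21)

.bond_length <- function(e1, e2, order) {
  sym <- c("-", "=", "#")[min(order, 3)]
  key1 <- paste0(e1, sym, e2); key2 <- paste0(e2, sym, e1)
  v <- .BOND_LENGTHS[[key1]]
  if (is.null(v)) v <- .BOND_LENGTHS[[key2]]
  if (is.null(v)) v <- 1.5
  v
}

#' Build idealized rigid 3D coordinates for a molecule
#'
#' Breadth-first placement with idealized bond lengths and hybridization-
#' based angles (109.47 degrees at 4-coordinate centers, 120 at
#' 3-coordinate, 180 at 2-coordinate), dihedrals drawn from a seeded
#' uniform distribution (acyclic molecules effectively get one random
#' staggered-ish conformer).
#'
#' @param mol An `lj_molecule`.
#' @param seed Integer seed controlling the dihedral draws.
#' @return Numeric matrix `n_atoms x 3` (Angstrom), rows in the molecule's
#'   documented atom order.
#' @export
build_geometry <- function(mol, seed = 1) {
  n <- nrow(mol$atoms)
  xyz <- matrix(NA_real_, n, 3L)
  if (n == 1L) return(matrix(0, 1L, 3L))
  nb <- .mol_neighbors(mol)
  ord <- .bond_order_lookup(mol)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed) %% .Machine$integer.max)

  place_children <- function(p) {
    children <- nb[[p]][is.na(xyz[nb[[p]], 1L])]
    if (!length(children)) return(invisible())
    placed_nb <- nb[[p]][!is.na(xyz[nb[[p]], 1L])]
    deg <- mol$atoms$degree[p]
    el <- mol$atoms$element[p]
    # idealized angles by coordination and element: tetrahedral, trigonal,
    # bent (O/N) or linear (sp carbon / nitrile-like)
    theta <- if (deg >= 4L) 109.47
      else if (deg == 3L) (if (el == "N") 107 else 120)
      else if (el == "O") 104.5
      else if (el == "N") 120
      else 180
    theta <- theta * pi / 180
    dirs <- .ideal_directions(p, placed_nb, length(children), theta, xyz)
    for (ci in seq_along(children)) {
      ch <- children[ci]
      len <- .bond_length(mol$atoms$element[p], mol$atoms$element[ch],
                          ord(p, ch))
      xyz[ch, ] <<- xyz[p, ] + len * dirs[[ci]]
    }
    for (ch in children) place_children(ch)
  }

  xyz[1L, ] <- c(0, 0, 0)
  first <- nb[[1L]][1L]
  len0 <- .bond_length(mol$atoms$element[1L], mol$atoms$element[first],
                       ord(1L, first))
  xyz[first, ] <- c(len0, 0, 0)
  place_children(1L)
  place_children(first)
  # disconnected atoms cannot occur (parser rejects '.')
  while (anyNA(xyz[, 1L])) {
    # rings can leave atoms pending when both anchors were placed; place
    # them from any placed neighbor
    pend <- which(is.na(xyz[, 1L]))[1L]
    anchor <- nb[[pend]][!is.na(xyz[nb[[pend]], 1L])][1L]
    if (is.na(anchor)) stop_domain("cannot embed molecule geometry")
    place_children(anchor)
    if (is.na(xyz[pend, 1L])) {
      xyz[pend, ] <- xyz[anchor, ] + c(1.5, 0, 0)
      place_children(pend)
    }
  }
  xyz - matrix(colMeans(xyz), n, 3L, byrow = TRUE)
}

.bond_order_lookup <- function(mol) {
  b <- mol$bonds
  function(i, j) {
    hit <- (b$i == i & b$j == j) | (b$i == j & b$j == i)
    if (!any(hit)) 1 else b$order[which(hit)[1L]]
  }
}

# Unit vectors from atom p toward n_new children, at angle `theta` from the
# already-placed neighbors where possible, splayed around the parent bond
# with a random starting dihedral.
.ideal_directions <- function(p, placed_nb, n_new, theta, xyz) {
  if (!length(placed_nb)) {
    # isolated start: splay around an arbitrary axis
    axis <- c(0, 0, 1)
    base <- c(1, 0, 0)
    return(lapply(seq_len(n_new), function(k) {
      phi <- 2 * pi * (k - 1) / max(n_new, 1) + stats::runif(1, 0, 2 * pi)
      ct <- cos(theta - pi / 2)
      .normalize(cos(phi) * base + sin(phi) * c(0, 1, 0) + ct * axis)
    }))
  }
  u_parent <- .normalize(xyz[placed_nb[1L], ] - xyz[p, ])
  perp <- .any_perpendicular(u_parent)
  perp2 <- .cross(u_parent, perp)
  phi0 <- stats::runif(1, 0, 2 * pi)
  existing <- length(placed_nb) - 1L
  lapply(seq_len(n_new), function(k) {
    phi <- phi0 + 2 * pi * (existing + k - 1) / max(existing + n_new, 1)
    # the new bond makes angle theta with the existing (p -> placed) bond
    .normalize(cos(theta) * u_parent +
                 sin(theta) * (cos(phi) * perp + sin(phi) * perp2))
  })
}

.normalize <- function(v) v / sqrt(sum(v^2))
.cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])
.any_perpendicular <- function(u) {
  v <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  .normalize(v - sum(v * u) * u)
}
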