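# Shared fixtures, memoized so expensive objects are built once per run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

get_study <- function(n = 75, seed = 1, noise = TRUE) {
  memo(sprintf("study_%d_%d_%d", n, seed, noise),
       make_study(n = n, seed = seed, noise = noise))
}

get_library <- function(n = 50, seed = 7) {
  memo(sprintf("lib_%d_%d", n, seed), make_library(n = n, seed = seed))
}

# mathematical coordinates of a paramset relative to its own references
kvec_of <- function(params) {
  c(rbind((params$types$eps - params$types$eps0) / params$t_eps,
          (params$types$rmin_half - params$types$rmin0) / params$t_rmin))
}

# independent hand-rolled typing for the polar/apolar hydrogen model:
# plain graph logic, no SMIRKS machinery
hand_type_h2con <- function(mol) {
  el <- mol$atoms$element
  nb <- ljtyping:::.mol_neighbors(mol)
  vapply(seq_along(el), function(i) {
    switch(el[i],
           H = if (any(el[nb[[i]]] %in% c("N", "O"))) "H.polar" else "H.apolar",
           C = "C", N = "N", O = "O",
           stop("unexpected element"))
  }, "")
}

# independent brute-force rule application: evaluate every rule on every
# atom and keep the highest-priority (last) match
brute_force_types <- function(mol, model) {
  n <- nrow(mol$atoms)
  out <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    for (k in rev(seq_along(model$rules))) {
      if (smirks_matches_atom(mol, i, model$compiled[[k]])) {
        out[i] <- model$rules[[k]]$type
        break
      }
    }
  }
  out
}
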