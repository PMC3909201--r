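## Pack a cg_topology (+ frustration set) into the flat list the C++ core
## expects.  The repulsion list is every pair with j - i >= min_separation
## that is neither a native contact nor (when frustration is on) a
## frustration pair -- the double-counting rule: a hydrophobic non-native
## pair is governed by the frustration well alone.
topo_for_core <- function(topo, fset = NULL, params = cg_params()) {
  n <- topo$n
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- (idx[, 2] - idx[, 1]) >= topo$min_separation
  pi_ <- idx[keep, 1]; pj_ <- idx[keep, 2]
  key <- pi_ * (n + 1) + pj_
  ckey <- topo$contacts$i * (n + 1) + topo$contacts$j
  is_contact <- key %in% ckey
  fi <- integer(0); fj <- integer(0)
  if (!is.null(fset) && params$frustration && params$eps_f > 0 &&
      nrow(fset$pairs) > 0) {
    fi <- fset$pairs$i; fj <- fset$pairs$j
    fkey <- fi * (n + 1) + fj
    is_frus <- key %in% fkey
  } else is_frus <- rep(FALSE, length(key))
  rep_sel <- !is_contact & !is_frus
  list(n = n, r0 = topo$r0, theta0 = topo$theta0, phi0 = topo$phi0,
       ci = as.integer(topo$contacts$i), cj = as.integer(topo$contacts$j),
       cr0 = topo$contacts$r0, cw = topo$contacts$weight,
       fi = as.integer(fi), fj = as.integer(fj),
       ri = as.integer(pi_[rep_sel]), rj = as.integer(pj_[rep_sel]))
}

term_mask <- c(bond = 1L, angle = 2L, dihedral = 4L, native_contact = 8L,
               repulsion = 16L, frustration = 32L)

energy_terms <- function(x, topo, fset, params, terms) {
  core <- topo_for_core(topo, fset, params)
  res <- cg_energy_forces_cpp(as.matrix(x), core, unclass(params),
                              terms = sum(term_mask[terms]))
  list(energy = res$energy[terms], forces = res$forces)
}

#' Bonded energy and forces
#'
#' Harmonic bond and angle terms plus the 1+3 cosine dihedral term of the
#' Go-model Hamiltonian, with exact analytic gradients.
#'
#' @param x `n x 3` matrix of C-alpha coordinates (Angstrom).
#' @param topo A `cg_topology`.
#' @param params A [cg_params()] object.
#' @return List with `energy` (named vector: bond, angle, dihedral) and
#'   `forces` (`n x 3`, \eqn{-\nabla E}).
#' @export
bonded_energy_forces <- function(x, topo, params = cg_params())
  energy_terms(x, topo, NULL, params, c("bond", "angle", "dihedral"))

#' Native-contact energy and forces
#'
#' One Lennard-Jones well per native contact with its minimum at the native
#' C-alpha distance and depth `weight * epsilon`; at the native state each
#' well contributes exactly `-weight * epsilon`.
#' @inheritParams bonded_energy_forces
#' @return List with `energy` (scalar, named) and `forces`.
#' @export
native_contact_energy_forces <- function(x, topo, params = cg_params())
  energy_terms(x, topo, NULL, params, "native_contact")

#' Excluded-volume repulsion energy and forces
#'
#' \eqn{\epsilon(\sigma/r)^{12}} over all remote pairs that are neither
#' native contacts nor (when frustration is enabled) frustration pairs.
#' @inheritParams bonded_energy_forces
#' @param fset Optional `cg_frustration` set (its pairs are excluded from
#'   repulsion when `params$frustration` is `TRUE`).
#' @return List with `energy` and `forces`.
#' @export
repulsion_energy_forces <- function(x, topo, params = cg_params(),
                                    fset = NULL)
  energy_terms(x, topo, fset, params, "repulsion")

#' Energetic-frustration energy and forces
#'
#' The non-native hydrophobic attraction: a 12--6 Lennard-Jones well of
#' depth `eps_f` with minimum at `c_f` for every frustration pair.
#' @inheritParams repulsion_energy_forces
#' @return List with `energy` and `forces`.
#' @export
frustration_energy_forces <- function(x, fset, topo, params = cg_params()) {
  if (!params$frustration)
    stop("frustration term requested but params$frustration is FALSE",
         call. = FALSE)
  energy_terms(x, topo, fset, params, "frustration")
}

#' Total potential energy, breakdown and forces
#'
#' @inheritParams repulsion_energy_forces
#' @return List with `breakdown` (tibble of per-term energies plus `total`)
#'   and `forces` (`n x 3`, exact negative gradient of the total).
#' @export
total_energy_forces <- function(x, topo, fset = NULL, params = cg_params()) {
  terms <- c("bond", "angle", "dihedral", "native_contact", "repulsion")
  if (params$frustration && params$eps_f > 0 && !is.null(fset) &&
      nrow(fset$pairs) > 0) terms <- c(terms, "frustration")
  res <- energy_terms(x, topo, fset, params, terms)
  e <- res$energy
  breakdown <- tibble::tibble(term = c(names(e), "total"),
                              energy = c(unname(e), sum(e)))
  list(breakdown = breakdown, forces = res$forces)
}
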