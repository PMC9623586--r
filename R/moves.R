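# Structural perturbation moves for basin-hopping.
#
# All torsional moves rotate only the atoms downstream of the chosen
# bond, so bond lengths and angles are preserved exactly; Cartesian
# displacement moves perturb every coordinate independently.  All
# randomness comes from R's global RNG so a single seed reproduces a
# run bit-for-bit.

#' Metropolis acceptance test
#'
#' Accepts whenever `delta <= 0`, otherwise with probability
#' `exp(-delta / temperature)` (temperature in energy units, kcal/mol).
#'
#' @param delta Energy (or free-energy) difference, kcal/mol.
#' @param temperature Sampling temperature in kcal/mol.
#' @return Logical: accept.
#' @export
metropolis_accept <- function(delta, temperature) {
  if (temperature <= 0) stop("sampling temperature must be positive")
  if (delta <= 0) return(TRUE)
  stats::runif(1L) < exp(-delta / temperature)
}

#' Random Cartesian displacement move
#'
#' Each coordinate is displaced by an independent uniform draw in
#' `[-max_displacement, +max_displacement]`, so per-atom displacement
#' norms are at most `sqrt(3)` times the maximum.
#'
#' @param x Coordinate vector.
#' @param max_displacement Maximum per-coordinate displacement in
#'   Angstrom (default 1).
#' @return Displaced coordinate vector.
#' @export
cartesian_displacement_move <- function(x, max_displacement = 1) {
  if (max_displacement < 0) stop("max_displacement must be >= 0")
  if (max_displacement == 0) return(x)
  x + stats::runif(length(x), -max_displacement, max_displacement)
}

.dihedrals_of_type <- function(topology, which) {
  types <- vapply(topology$dihedrals, `[[`, "", "type")
  switch(which,
         all = which(types %in% c("backbone", "chi")),
         backbone = which(types == "backbone"),
         sidechain = which(types == "chi"),
         stop("unknown dihedral class: ", which))
}

.xyz_matrix <- function(x) matrix(x, ncol = 3L, byrow = TRUE)
.xyz_vector <- function(m) as.numeric(t(m))

#' Group rotation move
#'
#' Stochastically selects rotatable dihedrals, each independently with
#' probability `selection_prob`, and rotates every selected dihedral by
#' a uniform draw in `[-max_amplitude, +max_amplitude]`; only the atoms
#' downstream of each rotated bond move.
#'
#' @param x Coordinate vector (length 3 x n_atoms).
#' @param potential A `"bh_potential"` whose topology defines the
#'   rotatable dihedrals.
#' @param selection_prob Per-dihedral selection probability (default
#'   0.025).
#' @param max_amplitude Maximum rotation in degrees (default 180).
#' @param which Dihedral class: "all" (default), "backbone" or
#'   "sidechain".
#' @return Perturbed coordinate vector.
#' @export
group_rotation_move <- function(x, potential, selection_prob = 0.025,
                                max_amplitude = 180, which = "all") {
  idx <- .dihedrals_of_type(potential$topology, which)
  if (length(idx) == 0L) stop("no rotatable dihedrals in topology")
  chosen <- idx[stats::runif(length(idx)) < selection_prob]
  .rotate_dihedral_set(x, potential, chosen, max_amplitude)
}

#' Rotate an exact number of randomly chosen dihedrals
#'
#' Samples exactly `n` distinct dihedrals of the requested class
#' uniformly and rotates each by a uniform draw in
#' `[-max_amplitude, +max_amplitude]`.  This is the move cadence used by
#' the benchmark schemes, where the number of perturbed dihedrals per
#' step is fixed.
#'
#' @inheritParams group_rotation_move
#' @param n Number of dihedrals to rotate.
#' @return Perturbed coordinate vector.
#' @export
dihedral_rotation_move <- function(x, potential, n, max_amplitude = 180,
                                   which = "backbone") {
  idx <- .dihedrals_of_type(potential$topology, which)
  if (length(idx) == 0L) stop("no rotatable dihedrals in topology")
  n <- min(n, length(idx))
  if (n == 0L) return(x)
  chosen <- if (length(idx) == 1L) idx else sample(idx, n)
  .rotate_dihedral_set(x, potential, chosen, max_amplitude)
}

.rotate_dihedral_set <- function(x, potential, chosen, max_amplitude) {
  if (length(chosen) == 0L) return(x)
  xyz <- .xyz_matrix(x)
  for (i in chosen) {
    d <- potential$topology$dihedrals[[i]]
    delta <- stats::runif(1L, -max_amplitude, max_amplitude)
    xyz <- rotate_about_bond(xyz, d$quad[2L], d$quad[3L], d$downstream, delta)
  }
  .xyz_vector(xyz)
}

#' Rotamer move
#'
#' Selects `n_SC` residues uniformly without replacement among residues
#' with chi dihedrals, draws a rotamer for each from the library with
#' probability proportional to its occupation probability (renormalized
#' over the context's entries), and sets all chi dihedrals of the
#' residue to the rotamer means by rotating downstream atoms.  The
#' backbone is untouched.
#'
#' @param x Coordinate vector.
#' @param potential A `"bh_potential"` with residue contexts in its
#'   topology.
#' @param library A `"rotamer_library"`.
#' @param n_SC Number of side chains to perturb.
#' @return Perturbed coordinate vector.
#' @export
rotamer_move <- function(x, potential, library, n_SC = 1L) {
  topo <- potential$topology
  chi_types <- vapply(topo$dihedrals, `[[`, "", "type")
  chi_res <- unique(vapply(topo$dihedrals[chi_types == "chi"],
                           `[[`, numeric(1L), "resno"))
  if (length(chi_res) == 0L) stop("no residues with chi dihedrals")
  n_SC <- min(n_SC, length(chi_res))
  pick <- if (length(chi_res) == 1L) chi_res else sample(chi_res, n_SC)
  xyz <- .xyz_matrix(x)
  for (r in pick) {
    info <- topo$residues[topo$residues$resno == r, ]
    key <- context_key(info$prev, info$code, info$nxt)
    cand <- library_context(library, key)
    if (nrow(cand) == 0L)
      stop("context ", key, " absent from rotamer library")
    row <- if (nrow(cand) == 1L) 1L else
      sample(nrow(cand), 1L, prob = cand$probability / sum(cand$probability))
    target <- as.numeric(.chi_mean_matrix(cand[row, , drop = FALSE]))
    d_idx <- which(chi_types == "chi" &
                   vapply(topo$dihedrals, `[[`, numeric(1L), "resno") == r)
    # chi in canonical order; each rotation updates downstream atoms, so
    # later chi are re-read from the current coordinates
    for (j in seq_along(d_idx)) {
      d <- topo$dihedrals[[d_idx[j]]]
      xyz <- set_dihedral(xyz, d$quad, d$downstream, target[j])
    }
  }
  .xyz_vector(xyz)
}
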