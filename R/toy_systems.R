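# Synthetic data: planted-rotamer ensembles for library recovery tests,
# and a desk-scale bead-chain potential with an enumerable set of minima
# for benchmarking basin-hopping move schemes.

#' Sample a conformational ensemble around planted rotamer centers
#'
#' Draws side-chain conformations around K planted torsional centers
#' with wrapped Gaussian angular noise (truncated at 4 standard
#' deviations), emulating the distinct low-energy minima an exhaustive
#' sampling run would find in each rotameric basin.  Draw counts per
#' center are multinomial with Boltzmann weights of the planted free
#' energies, and each draw carries the free energy of its center plus
#' `kB T log(n_center)` — splitting the basin population among its
#' members, so summing member populations recovers the planted
#' Boltzmann population of each basin — plus a small uniform jitter so
#' members are not exactly degenerate.
#'
#' @param centers Matrix (K x n chi) of planted centers, degrees.  The
#'   centers must be pairwise farther than twice the clustering cutoff
#'   under the torsional metric, else recovery is not identifiable.
#' @param free_energies Numeric length-K planted free energies, kcal/mol.
#' @param n_draws Total number of conformations to draw.
#' @param noise_sd Angular noise standard deviation in degrees (default
#'   5); must be below a quarter of the cutoff.
#' @param temperature Temperature (K) used for the Boltzmann weights
#'   (default 298).
#' @param cutoff Clustering cutoff the ensemble is meant for (default
#'   40); only used to validate identifiability.
#' @param fe_jitter Half-width of the uniform free-energy jitter,
#'   kcal/mol (default 0.05).
#' @return A [conformation_ensemble()]; the planted assignment of each
#'   draw is kept in `attr(, "planted_center")` and the planted
#'   populations in `attr(, "planted_populations")`.
#' @export
sample_planted_ensemble <- function(centers, free_energies, n_draws,
                                    noise_sd = 5, temperature = 298,
                                    cutoff = 40, fe_jitter = 0.05) {
  centers <- .as_torsion_matrix(centers)
  K <- nrow(centers)
  if (length(free_energies) != K) stop("one free energy per center required")
  if (noise_sd < 0 || noise_sd >= cutoff / 4)
    stop("noise_sd must be in [0, cutoff/4) for identifiable recovery")
  if (K > 1L) {
    d <- as.matrix(pairwise_torsion_distances(centers))
    if (min(d[upper.tri(d)]) <= 2 * cutoff)
      stop("planted centers must be pairwise farther than 2 x cutoff")
  }
  pops <- equilibrium_populations(free_energies, temperature)
  counts <- drop(stats::rmultinom(1L, n_draws, pops))
  kT <- .kB * temperature
  torsions <- matrix(NA_real_, n_draws, ncol(centers))
  fe <- numeric(n_draws)
  assignment <- integer(n_draws)
  row <- 0L
  for (c_i in seq_len(K)) {
    n_c <- counts[c_i]
    if (n_c == 0L) next
    for (j in seq_len(n_c)) {
      noise <- if (noise_sd == 0) rep(0, ncol(centers)) else {
        z <- stats::rnorm(ncol(centers), 0, noise_sd)
        while (any(abs(z) > 4 * noise_sd)) {
          bad <- abs(z) > 4 * noise_sd
          z[bad] <- stats::rnorm(sum(bad), 0, noise_sd)
        }
        z
      }
      row <- row + 1L
      torsions[row, ] <- normalize_angle(centers[c_i, ] + noise)
      fe[row] <- free_energies[c_i] + kT * log(n_c) +
        stats::runif(1L, -fe_jitter, fe_jitter)
      assignment[row] <- c_i
    }
  }
  ens <- conformation_ensemble(torsions, fe)
  attr(ens, "planted_center") <- assignment
  attr(ens, "planted_populations") <- pops
  ens
}

# ---------------------------------------------------------------------
# Bead-chain toy potential

.toy_geom <- list(bond = 1.5, bb_angle = 120, side_angle = 109.47,
                  omega0 = 100,
                  bond_k = 100, angle_k = 50,
                  chi_barrier = 6, bb_barrier = 6, attach_k = 10,
                  rep_eps = 0.2, rep_sigma = 1.2)

#' Build the benchmark bead-chain potential
#'
#' A chain of `n_residues + 3` backbone beads; each residue carries a
#' two-bead side chain attached to the backbone, giving one chi dihedral
#' per residue.  Each chi has `wells_per_residue` cosine wells (one,
#' chosen at random, made deepest); each backbone dihedral is a double
#' well with a random preferred side.  Harmonic bonds and angles and a
#' soft repulsion between nonbonded beads complete the potential.  All
#' well placements and depth biases are drawn once from `seed`, so a
#' chain is fully reproducible.
#'
#' At build time every combination of chi and backbone wells is
#' enumerated and locally minimized, the resulting distinct minima are
#' catalogued, and the lowest is recorded as the (verified) global
#' minimum — success of a basin-hopping run is therefore decidable
#' without external references.
#'
#' @param n_residues Number of side-chain-bearing residues (default 4).
#' @param wells_per_residue Number of chi wells per residue (default 3,
#'   minimum 2).
#' @param seed Integer seed for the chain construction (default 1).
#' @param enumerate Catalogue minima by exhaustive well enumeration
#'   (default TRUE; the combination count must not exceed 1e5).
#' @return A `"rotamer_chain"` (also `"bh_potential"`) with elements
#'   `energy`, `gradient`, `topology`, `params`, `wells`, `minima`
#'   (energies, free-energy column added by [toy_library()], coordinates
#'   and dihedral signatures of the distinct enumerated minima),
#'   `global_minimum` and `start_coordinates` (an extended chain).
#' @export
make_rotamer_chain <- function(n_residues = 4L, wells_per_residue = 3L,
                               seed = 1L, enumerate = TRUE) {
  if (wells_per_residue < 2L) stop("wells_per_residue must be >= 2")
  n_combos <- wells_per_residue^n_residues * 2^n_residues
  if (enumerate && n_combos > 1e5)
    stop("well-combination count ", n_combos, " exceeds the enumerability bound")
  g <- .toy_geom
  nb <- n_residues + 3L
  natoms <- nb + 2L * n_residues
  s1 <- function(r) nb + 2L * (r - 1L) + 1L
  s2 <- function(r) nb + 2L * r

  # reproducible construction without disturbing the caller's RNG
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  k <- wells_per_residue
  chi0 <- stats::runif(n_residues, -180, 180)
  chi_pref_well <- sample.int(k, n_residues, replace = TRUE)
  chi_bias <- stats::runif(n_residues, 0.8, 1.6)
  bb0 <- stats::runif(n_residues, -180, 180)
  bb_pref <- sample.int(2L, n_residues, replace = TRUE)
  bb_bias <- stats::runif(n_residues, 1.0, 2.0)
  if (is.null(old_seed)) rm(".Random.seed", envir = globalenv()) else
    assign(".Random.seed", old_seed, envir = globalenv())

  chi_wells <- lapply(seq_len(n_residues), function(r)
    normalize_angle(chi0[r] + (seq_len(k) - 1L) * 360 / k))
  bb_wells <- lapply(seq_len(n_residues), function(r)
    normalize_angle(bb0[r] + c(0, 180)))

  bonds <- rbind(cbind(seq_len(nb - 1L), seq_len(nb - 1L) + 1L),
                 do.call(rbind, lapply(seq_len(n_residues), function(r)
                   rbind(c(r + 2L, s1(r)), c(s1(r), s2(r))))))
  angles <- rbind(
    cbind(seq_len(nb - 2L), seq_len(nb - 2L) + 1L, seq_len(nb - 2L) + 2L),
    do.call(rbind, lapply(seq_len(n_residues), function(r)
      rbind(c(r + 1L, r + 2L, s1(r)), c(r + 2L, s1(r), s2(r))))))
  # theta0 aligned with the angle rows as constructed above
  angle_theta0 <- c(rep(g$bb_angle, nb - 2L), rep(g$side_angle, 2L * n_residues))

  deg2rad <- pi / 180
  tors <- list(); tm <- c(); tk <- c(); td <- c()
  add_term <- function(quad, m, amp, delta_deg) {
    tors[[length(tors) + 1L]] <<- quad
    tm <<- c(tm, m); tk <<- c(tk, amp); td <<- c(td, delta_deg * deg2rad)
  }
  dihedrals <- list()
  for (r in seq_len(n_residues)) {
    quad_bb <- c(r, r + 1L, r + 2L, r + 3L)
    add_term(quad_bb, 2L, -g$bb_barrier / 2, 2 * bb0[r])
    add_term(quad_bb, 1L, -bb_bias[r] / 2, bb_wells[[r]][bb_pref[r]])
    down_bb <- c((r + 3L):nb,
                 unlist(lapply(seq_len(n_residues), function(q)
                   if (q >= r + 1L) c(s1(q), s2(q)))))
    dihedrals[[length(dihedrals) + 1L]] <-
      list(type = "backbone", resno = r, quad = quad_bb,
           downstream = sort(down_bb))
    quad_chi <- c(r + 1L, r + 2L, s1(r), s2(r))
    add_term(quad_chi, k, -g$chi_barrier / 2, k * chi0[r])
    add_term(quad_chi, 1L, -chi_bias[r] / 2, chi_wells[[r]][chi_pref_well[r]])
    dihedrals[[length(dihedrals) + 1L]] <-
      list(type = "chi", resno = r, quad = quad_chi, downstream = s2(r))
    quad_om <- c(r, r + 1L, r + 2L, s1(r))
    add_term(quad_om, 1L, -g$attach_k / 2, g$omega0)
    dihedrals[[length(dihedrals) + 1L]] <-
      list(type = "attachment", resno = r, quad = quad_om,
           downstream = c(s1(r), s2(r)))
  }

  # nonbonded pairs: bond-graph distance >= 3
  adj <- matrix(FALSE, natoms, natoms)
  adj[bonds] <- TRUE; adj[bonds[, 2:1]] <- TRUE
  dist_g <- matrix(Inf, natoms, natoms); diag(dist_g) <- 0
  dist_g[adj] <- 1
  for (via in seq_len(natoms))
    dist_g <- pmin(dist_g, outer(dist_g[, via], dist_g[via, ], `+`))
  nbp <- which(upper.tri(dist_g) & dist_g >= 3, arr.ind = TRUE)

  params <- list(natoms = natoms,
                 bonds = matrix(as.integer(bonds), ncol = 2L),
                 bond_r0 = g$bond, bond_k = g$bond_k,
                 angles = matrix(as.integer(angles), ncol = 3L),
                 angle_theta0 = angle_theta0 * deg2rad, angle_k = g$angle_k,
                 torsions = matrix(as.integer(do.call(rbind, tors)), ncol = 4L),
                 torsion_m = as.integer(tm), torsion_k = tk, torsion_delta = td,
                 nonbonded = matrix(as.integer(nbp), ncol = 2L),
                 rep_eps = g$rep_eps, rep_sigma = g$rep_sigma)

  codes <- sprintf("T%02d", seq_len(n_residues))
  residues <- data.frame(resno = seq_len(n_residues), code = codes,
                         prev = c("CAP", codes[-n_residues]),
                         nxt = c(codes[-1L], "CAP"),
                         stringsAsFactors = FALSE)
  topology <- list(natoms = natoms, bonds = params$bonds,
                   dihedrals = dihedrals, residues = residues)

  build_coords <- function(bb_dih, chi_dih) {
    xyz <- matrix(0, natoms, 3L)
    xyz[2L, ] <- c(g$bond, 0, 0)
    a <- g$bb_angle * deg2rad
    xyz[3L, ] <- xyz[2L, ] + g$bond * c(-cos(a), sin(a), 0)
    for (j in seq_len(nb - 3L))
      xyz[j + 3L, ] <- place_atom(xyz[j, ], xyz[j + 1L, ], xyz[j + 2L, ],
                                  g$bond, g$bb_angle, bb_dih[j])
    for (r in seq_len(n_residues)) {
      xyz[s1(r), ] <- place_atom(xyz[r, ], xyz[r + 1L, ], xyz[r + 2L, ],
                                 g$bond, g$side_angle, g$omega0)
      xyz[s2(r), ] <- place_atom(xyz[r + 1L, ], xyz[r + 2L, ], xyz[s1(r), ],
                                 g$bond, g$side_angle, chi_dih[r])
    }
    .xyz_vector(xyz)
  }

  pot <- bh_potential(
    energy = function(x) toychain_energy(x, params),
    gradient = function(x) toychain_gradient(x, params),
    topology = topology,
    name = sprintf("rotamer chain (%d residues, %d chi wells)",
                   n_residues, wells_per_residue))
  pot$params <- params
  pot$wells <- list(chi = chi_wells, chi_preferred = chi_pref_well,
                    backbone = bb_wells, backbone_preferred = bb_pref)
  pot$n_residues <- n_residues
  pot$wells_per_residue <- k
  pot$build_coords <- build_coords
  pot$start_coordinates <- build_coords(rep(180, n_residues),
                                        rep(60, n_residues))
  class(pot) <- c("rotamer_chain", class(pot))

  if (enumerate) {
    combos_chi <- as.matrix(expand.grid(rep(list(seq_len(k)), n_residues)))
    combos_bb <- as.matrix(expand.grid(rep(list(1:2), n_residues)))
    sig_list <- list(); energies <- c(); coords <- list()
    for (ib in seq_len(nrow(combos_bb))) {
      bb_dih <- vapply(seq_len(n_residues),
                       function(r) bb_wells[[r]][combos_bb[ib, r]], numeric(1L))
      for (ic in seq_len(nrow(combos_chi))) {
        chi_dih <- vapply(seq_len(n_residues),
                          function(r) chi_wells[[r]][combos_chi[ic, r]],
                          numeric(1L))
        rec <- local_minimize(pot, build_coords(bb_dih, chi_dih),
                              rms_force_tol = 1e-6)
        if (!rec$converged) next
        sig <- .chain_dihedral_signature(rec$coordinates, topology)
        dup <- FALSE
        for (u in seq_along(sig_list)) {
          if (abs(energies[u] - rec$energy) < 1e-6 &&
              max(periodic_angle_distance(sig_list[[u]], sig)) < 2) {
            dup <- TRUE; break
          }
        }
        if (!dup) {
          sig_list[[length(sig_list) + 1L]] <- sig
          energies <- c(energies, rec$energy)
          coords[[length(coords) + 1L]] <- rec$coordinates
        }
      }
    }
    ord <- order(energies)
    pot$minima <- list(energy = energies[ord],
                       coordinates = do.call(rbind, coords)[ord, , drop = FALSE],
                       signature = do.call(rbind, sig_list)[ord, , drop = FALSE])
    pot$global_minimum <- list(energy = energies[ord][1L],
                               coordinates = coords[[ord[1L]]])
  }
  pot
}

# backbone + chi dihedral values of a chain conformation, in topology order
.chain_dihedral_signature <- function(x, topology) {
  xyz <- .xyz_matrix(x)
  keep <- vapply(topology$dihedrals, function(d) d$type != "attachment",
                 logical(1L))
  vapply(topology$dihedrals[keep], function(d)
    dihedral_angle(xyz[d$quad[1L], ], xyz[d$quad[2L], ],
                   xyz[d$quad[3L], ], xyz[d$quad[4L], ]), numeric(1L))
}

#' Chi dihedrals of every residue of a chain conformation
#'
#' @param chain A `"rotamer_chain"`.
#' @param x Coordinate vector.
#' @return Numeric vector, one chi per residue.
#' @export
chain_chi <- function(chain, x) {
  xyz <- .xyz_matrix(x)
  chis <- Filter(function(d) d$type == "chi", chain$topology$dihedrals)
  vapply(chis, function(d)
    dihedral_angle(xyz[d$quad[1L], ], xyz[d$quad[2L], ],
                   xyz[d$quad[3L], ], xyz[d$quad[4L], ]), numeric(1L))
}

#' Build a rotamer library from an enumerated toy chain
#'
#' Runs the actual library-construction pipeline — harmonic local free
#' energies, Boltzmann populations, torsional clustering, pruning — on
#' the catalogued minima of a [make_rotamer_chain()] potential, so
#' rotamer moves on the toy system use a library produced by the same
#' code path as for peptide ensembles.
#'
#' @param chain A `"rotamer_chain"` with an enumerated minima catalogue.
#' @param temperature Temperature (K) for populations (default 298).
#' @param prune Pruning threshold (default 0, so every well keeps its
#'   rotamer even when strongly suppressed).
#' @param eig_floor Zero-mode threshold for the finite-difference
#'   Hessians (default 1e-4; the six rigid-body modes of the chain are
#'   well separated from its softest internal mode).
#' @return A `"rotamer_library"` keyed by the chain's residue contexts.
#' @export
toy_library <- function(chain, temperature = 298, prune = 0,
                        eig_floor = 1e-4) {
  stopifnot(inherits(chain, "rotamer_chain"))
  if (is.null(chain$minima)) stop("chain was built without enumeration")
  m <- length(chain$minima$energy)
  fe <- vapply(seq_len(m), function(i)
    harmonic_free_energy(chain, chain$minima$coordinates[i, ],
                         temperature = temperature, eig_floor = eig_floor),
    numeric(1L))
  chi_mat <- t(vapply(seq_len(m), function(i)
    chain_chi(chain, chain$minima$coordinates[i, ]),
    numeric(chain$n_residues)))
  res <- chain$topology$residues
  ensembles <- lapply(seq_len(chain$n_residues), function(r)
    conformation_ensemble(chi_mat[, r, drop = FALSE], fe,
                          potential_energy = chain$minima$energy))
  names(ensembles) <- context_key(res$prev, res$code, res$nxt)
  rotamer_library(ensembles, cutoff = 40, temperature = temperature,
                  prune = prune)
}
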