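# Basin-hopping driver, move schemes and run diagnostics.

#' Define a basin-hopping move scheme
#'
#' A scheme fixes the cadence of side-chain and backbone perturbations:
#' every `f_SC` steps the side chains are perturbed (`n_SC` residues by
#' rotamer moves, or `n_SC` side-chain dihedrals by group rotation) and
#' every `f_BB` steps `n_BB` backbone dihedrals are rotated.  The
#' sampling temperature is in energy units (kcal/mol).
#'
#' @param side_move "rotamer" or "group_rotation".
#' @param n_SC Number of side chains (rotamer moves) or side-chain
#'   dihedrals (group rotation) perturbed per side-chain move.
#' @param f_SC Steps between side-chain moves.
#' @param n_BB Number of backbone dihedrals rotated per backbone move.
#' @param f_BB Steps between backbone moves.
#' @param temperature Sampling temperature, kcal/mol (default 1.3).
#' @param displacement_amplitude Cartesian displacement amplitude in
#'   Angstrom; 0 (default) disables displacements.
#' @param use_free_energy Accept on harmonic local free-energy
#'   differences (FEBH) instead of potential energy (default FALSE).
#' @param name Optional scheme name.
#' @return An object of class `"bh_scheme"`.
#' @export
bh_scheme <- function(side_move = c("rotamer", "group_rotation"),
                      n_SC = 2L, f_SC = 1L, n_BB = 1L, f_BB = 1L,
                      temperature = 1.3, displacement_amplitude = 0,
                      use_free_energy = FALSE, name = NULL) {
  side_move <- match.arg(side_move)
  stopifnot(n_SC >= 0, n_BB >= 0, f_SC >= 1, f_BB >= 1,
            temperature > 0, displacement_amplitude >= 0)
  if (is.null(name)) name <- paste0(side_move, " (", n_SC, ",", f_SC, ",",
                                    n_BB, ",", f_BB, ")")
  structure(list(side_move = side_move, n_SC = as.integer(n_SC),
                 f_SC = as.integer(f_SC), n_BB = as.integer(n_BB),
                 f_BB = as.integer(f_BB), temperature = temperature,
                 displacement_amplitude = displacement_amplitude,
                 use_free_energy = use_free_energy, name = name),
            class = "bh_scheme")
}

#' @export
print.bh_scheme <- function(x, ...) {
  cat(sprintf("BH scheme %s: side=%s n_SC=%d f_SC=%d n_BB=%d f_BB=%d T=%g%s\n",
              x$name, x$side_move, x$n_SC, x$f_SC, x$n_BB, x$f_BB,
              x$temperature, if (x$use_free_energy) " (FEBH)" else ""))
  invisible(x)
}

#' Benchmark move-scheme presets
#'
#' The twelve benchmark schemes: eight rotamer schemes and four group
#' rotation schemes, at a fixed sampling temperature of 1.3 kcal/mol and
#' with no Cartesian displacements.
#'
#' @return Named list of `"bh_scheme"` objects.
#' @export
scheme_presets <- function() {
  spec <- list(
    "rotamer 1"        = c(2, 1, 1, 1),
    "rotamer 2"        = c(2, 1, 2, 2),
    "rotamer 3"        = c(3, 1, 1, 1),
    "rotamer 4"        = c(2, 1, 3, 3),
    "rotamer 5"        = c(2, 2, 2, 2),
    "rotamer 6"        = c(2, 1, 3, 4),
    "rotamer 7"        = c(3, 1, 3, 3),
    "rotamer 8"        = c(3, 2, 2, 2),
    "group rotation 1" = c(4, 1, 1, 1),
    "group rotation 2" = c(4, 1, 2, 2),
    "group rotation 3" = c(6, 1, 1, 1),
    "group rotation 4" = c(6, 1, 2, 1))
  out <- lapply(names(spec), function(nm) {
    p <- spec[[nm]]
    bh_scheme(side_move = if (grepl("^rotamer", nm)) "rotamer"
              else "group_rotation",
              n_SC = p[1L], f_SC = p[2L], n_BB = p[3L], f_BB = p[4L],
              temperature = 1.3, displacement_amplitude = 0, name = nm)
  })
  names(out) <- names(spec)
  out
}

#' Run basin-hopping global optimization
#'
#' Explores the transformed landscape in which every point is mapped to
#' the energy of its locally minimized structure: at each step the
#' current structure is perturbed per the scheme cadence (backbone
#' group rotation first, then the side-chain move, so imposed rotamer
#' angles survive into minimization, then any Cartesian displacement),
#' locally minimized, and accepted or rejected by a Metropolis-like
#' criterion on the energy difference to the current minimum in the
#' Markov chain — the potential energy, or the harmonic local free
#' energy when the scheme requests FEBH.
#'
#' @param potential A `"bh_potential"` with topology when torsional
#'   moves are used.
#' @param start Starting coordinate vector.
#' @param scheme A `"bh_scheme"`.
#' @param n_steps Number of basin-hopping steps.
#' @param seed Optional integer seed for the run's RNG.
#' @param library Rotamer library (required for rotamer schemes).
#' @param reference_energy Optional known global-minimum energy; when
#'   given, `success_step` records the first step at which a minimum
#'   within `success_window` of it is encountered.
#' @param success_window Energy window for success, kcal/mol (default 1).
#' @param fe_temperature Temperature (K) for harmonic free energies
#'   under FEBH (default 298).
#' @param rms_force_tol RMS force convergence criterion passed to
#'   [local_minimize()] (default 1e-6).
#' @param max_amplitude Maximum dihedral rotation for group-rotation
#'   moves, degrees (default 180).
#' @return An object of class `"bh_run"`: `records` data frame (one row
#'   per proposal: step, move, energy, free energy, delta, accepted,
#'   minimizer evaluations, RMS gradient), `coordinates` matrix (one row
#'   per record), `best_energy`, `best_coordinates`, `success_step` (NA
#'   if never within the window), `scheme`, `seed`.
#' @export
run_basin_hopping <- function(potential, start, scheme, n_steps,
                              seed = NULL, library = NULL,
                              reference_energy = NULL, success_window = 1,
                              fe_temperature = 298, rms_force_tol = 1e-6,
                              max_amplitude = 180) {
  stopifnot(inherits(scheme, "bh_scheme"))
  if (scheme$side_move == "rotamer" && is.null(library))
    stop("rotamer schemes require a rotamer library")
  if (!is.null(seed)) set.seed(seed)
  fe <- function(rec) if (scheme$use_free_energy)
    harmonic_free_energy(potential, rec, temperature = fe_temperature)
  else NA_real_

  cur <- local_minimize(potential, start, rms_force_tol = rms_force_tol)
  cur_fe <- fe(cur)
  cur_score <- if (scheme$use_free_energy) cur_fe else cur$energy

  n_rec <- n_steps + 1L
  records <- data.frame(step = integer(n_rec), move = character(n_rec),
                        energy = numeric(n_rec), free_energy = numeric(n_rec),
                        delta = numeric(n_rec), accepted = logical(n_rec),
                        evaluations = integer(n_rec),
                        rms_gradient = numeric(n_rec),
                        stringsAsFactors = FALSE)
  coords <- matrix(NA_real_, n_rec, length(start))
  fill <- function(i, step, move, rec, feval, delta, accepted) {
    records$step[i] <<- step; records$move[i] <<- move
    records$energy[i] <<- rec$energy; records$free_energy[i] <<- feval
    records$delta[i] <<- delta; records$accepted[i] <<- accepted
    records$evaluations[i] <<- rec$evaluations
    records$rms_gradient[i] <<- rec$rms_gradient
    coords[i, ] <<- rec$coordinates
  }
  fill(1L, 0L, "start", cur, cur_fe, 0, TRUE)

  best <- cur
  success_step <- NA_integer_
  in_window <- function(e) !is.null(reference_energy) &&
    e <= reference_energy + success_window
  if (in_window(cur$energy)) success_step <- 0L

  for (s in seq_len(n_steps)) {
    x <- cur$coordinates
    moves <- character(0)
    if (s %% scheme$f_BB == 0L && scheme$n_BB > 0L) {
      x <- dihedral_rotation_move(x, potential, scheme$n_BB,
                                  max_amplitude = max_amplitude,
                                  which = "backbone")
      moves <- c(moves, "BB")
    }
    if (s %% scheme$f_SC == 0L && scheme$n_SC > 0L) {
      x <- if (scheme$side_move == "rotamer")
        rotamer_move(x, potential, library, scheme$n_SC)
      else
        dihedral_rotation_move(x, potential, scheme$n_SC,
                               max_amplitude = max_amplitude,
                               which = "sidechain")
      moves <- c(moves, "SC")
    }
    if (scheme$displacement_amplitude > 0)
      x <- cartesian_displacement_move(x, scheme$displacement_amplitude)
    move_lab <- if (length(moves)) paste(moves, collapse = "+") else "none"

    prop <- local_minimize(potential, x, rms_force_tol = rms_force_tol)
    prop_fe <- fe(prop)
    prop_score <- if (scheme$use_free_energy) prop_fe else prop$energy
    delta <- prop_score - cur_score
    acc <- metropolis_accept(delta, scheme$temperature)
    fill(s + 1L, s, move_lab, prop, prop_fe, delta, acc)
    if (prop$energy < best$energy) best <- prop
    if (is.na(success_step) && in_window(prop$energy)) success_step <- s
    if (acc) { cur <- prop; cur_fe <- prop_fe; cur_score <- prop_score }
  }

  structure(list(records = records, coordinates = coords,
                 best_energy = best$energy,
                 best_coordinates = best$coordinates,
                 success_step = success_step,
                 scheme = scheme, seed = seed),
            class = "bh_run")
}

#' @export
print.bh_run <- function(x, ...) {
  r <- x$records
  cat("Basin-hopping run:", x$scheme$name, "\n")
  cat(sprintf("  steps: %d  accepted: %d (%.1f%%)\n",
              nrow(r) - 1L, sum(r$accepted[-1L]),
              100 * mean(r$accepted[-1L])))
  cat(sprintf("  best energy: %.6f", x$best_energy))
  if (!is.na(x$success_step))
    cat("  (success at step ", x$success_step, ")", sep = "")
  cat("\n")
  invisible(x)
}

#' @export
summary.bh_run <- function(object, ...) {
  r <- object$records[-1L, , drop = FALSE]
  by_move <- if (nrow(r)) tapply(r$evaluations, r$move, mean) else numeric(0)
  out <- list(n_steps = nrow(r),
              acceptance = mean(r$accepted),
              best_energy = object$best_energy,
              success_step = object$success_step,
              mean_minimizer_evaluations_by_move = by_move)
  class(out) <- "summary.bh_run"
  out
}

#' @export
print.summary.bh_run <- function(x, ...) {
  cat(sprintf("steps %d, acceptance %.2f, best energy %.6f\n",
              x$n_steps, x$acceptance, x$best_energy))
  if (!is.na(x$success_step)) cat("success at step", x$success_step, "\n")
  cat("mean minimizer energy evaluations by move type:\n")
  print(round(x$mean_minimizer_evaluations_by_move, 1))
  invisible(x)
}

#' Markov-chain diagnostics of a basin-hopping run
#'
#' Per-proposal energy difference to the current Markov-chain minimum
#' (as recorded during the run), and the structural distance between
#' adjacent accepted minima: for Cartesian systems the least RMSD after
#' optimal rigid-body superposition, otherwise the plain RMS coordinate
#' difference.
#'
#' @param run A `"bh_run"`.
#' @return List with `delta_e` (per proposal), `delta_d` (per adjacent
#'   accepted pair, Angstrom), `median_delta_e`, `median_delta_d`.
#' @export
markov_diagnostics <- function(run) {
  stopifnot(inherits(run, "bh_run"))
  r <- run$records
  delta_e <- r$delta[-1L]
  acc_idx <- which(r$accepted)
  delta_d <- numeric(0)
  if (length(acc_idx) > 1L) {
    cart <- ncol(run$coordinates) %% 3L == 0L && ncol(run$coordinates) >= 9L
    delta_d <- vapply(seq_len(length(acc_idx) - 1L), function(i) {
      a <- run$coordinates[acc_idx[i], ]
      b <- run$coordinates[acc_idx[i + 1L], ]
      if (cart) bio3d::rmsd(a, b, fit = TRUE)
      else sqrt(mean((a - b)^2))
    }, numeric(1L))
  }
  list(delta_e = delta_e, delta_d = delta_d,
       median_delta_e = if (length(delta_e)) stats::median(delta_e) else NA_real_,
       median_delta_d = if (length(delta_d)) stats::median(delta_d) else NA_real_)
}

#' @export
plot.bh_run <- function(x, ...) {
  d <- markov_diagnostics(x)
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::hist(d$delta_e, breaks = 30, main = "Proposal ΔE",
                 xlab = expression(Delta * E ~ "(kcal/mol)"))
  graphics::abline(v = d$median_delta_e, lwd = 2)
  if (length(d$delta_d))
    graphics::plot(d$delta_d, type = "h", main = "Accepted-chain ΔD",
                   xlab = "accepted transition", ylab = "ΔD (Å)")
  invisible(x)
}

#' Write a basin-hopping trajectory table
#'
#' Plain-text, tab-separated record of every proposal (step, move type,
#' energy, free energy, delta, accepted flag, minimizer evaluations).
#'
#' @param run A `"bh_run"`.
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_trajectory <- function(run, path) {
  utils::write.table(format(run$records, digits = 10), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
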