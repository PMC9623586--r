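# Local minimization and harmonic local free energies.

#' Locally minimize a potential with L-BFGS
#'
#' Minimizes from a starting point using the limited-memory BFGS
#' implementation in [stats::optim()], then verifies the root-mean-square
#' gradient against the convergence criterion (1e-6 kcal/mol/Angstrom by
#' default), restarting from the current point until it is met or the
#' attempt budget is exhausted.  Non-convergence is flagged on the
#' returned record, never silent.
#'
#' @param potential A `"bh_potential"`.
#' @param start Starting coordinate vector.
#' @param rms_force_tol RMS gradient convergence criterion (default 1e-6).
#' @param max_iter Iteration cap per L-BFGS attempt (default 2000).
#' @param max_restarts Additional attempts when the tolerance is not yet
#'   met (default 4).
#' @return An object of class `"minimum_record"`: list with
#'   `coordinates`, `energy`, `rms_gradient`, `converged`, `evaluations`
#'   (energy calls), `gradient_evaluations`.
#' @export
local_minimize <- function(potential, start, rms_force_tol = 1e-6,
                           max_iter = 2000L, max_restarts = 4L) {
  if (any(!is.finite(start))) stop("non-finite starting coordinates")
  x <- start
  evals <- gevals <- 0L
  if (inherits(potential, "rotamer_chain")) {
    # compiled L-BFGS path: same algorithm family and the same RMS-force
    # criterion, without per-evaluation callback overhead
    res <- toychain_minimize(start, potential$params, rms_force_tol,
                             as.integer(max_iter))
    if (res$converged && res$value <= potential$energy(start) + 1e-12)
      return(structure(list(coordinates = res$par, energy = res$value,
                            rms_gradient = res$rms, converged = TRUE,
                            evaluations = as.integer(res$evaluations),
                            gradient_evaluations = as.integer(res$evaluations)),
                       class = "minimum_record"))
    x <- res$par
    evals <- gevals <- as.integer(res$evaluations)
  }
  for (attempt in seq_len(max_restarts + 1L)) {
    res <- stats::optim(x, potential$energy, potential$gradient,
                        method = "L-BFGS-B",
                        control = list(maxit = max_iter, factr = 1,
                                       pgtol = rms_force_tol / 10))
    x <- res$par
    evals <- evals + res$counts[1L]
    gevals <- gevals + res$counts[2L]
    g <- potential$gradient(x)
    rms <- sqrt(mean(g^2))
    if (rms <= rms_force_tol) break
  }
  e <- potential$energy(x)
  if (e > potential$energy(start) + 1e-12) {
    # cannot happen for a descent method, but keep the contract explicit
    x <- start
    e <- potential$energy(start)
    g <- potential$gradient(x)
    rms <- sqrt(mean(g^2))
  }
  structure(list(coordinates = x, energy = e, rms_gradient = rms,
                 converged = rms <= rms_force_tol,
                 evaluations = as.integer(evals),
                 gradient_evaluations = as.integer(gevals)),
            class = "minimum_record")
}

#' @export
print.minimum_record <- function(x, ...) {
  cat(sprintf("Minimum: E = %.8g, RMS grad = %.3g (%s, %d energy evals)\n",
              x$energy, x$rms_gradient,
              if (x$converged) "converged" else "NOT converged",
              x$evaluations))
  invisible(x)
}

#' Harmonic local free energy of a minimum
#'
#' Harmonic-superposition estimate of the local free energy of a
#' minimum: `F = V + kB T sum_j log(omega_j)` with `omega_j = sqrt(
#' lambda_j)` over the positive Hessian eigenvalues (unit masses).
#' Eigenvalues inside `[-eig_floor, eig_floor]` are treated as zero
#' modes (rigid translations/rotations) and excluded; any eigenvalue
#' below `-eig_floor` means the point is not a minimum and is an error.
#' The result is defined up to an additive constant shared by all minima
#' of the same system, which cancels in acceptance ratios and
#' populations.
#'
#' @param potential A `"bh_potential"`.
#' @param minimum A `"minimum_record"` (or coordinate vector of a
#'   verified minimum).
#' @param temperature Temperature in Kelvin.
#' @param hessian_step Finite-difference step when no analytic Hessian
#'   is available (default 1e-4).
#' @param eig_floor Zero-mode threshold (default 1e-8).
#' @return Free energy in kcal/mol.
#' @export
harmonic_free_energy <- function(potential, minimum, temperature = 298,
                                 hessian_step = 1e-4, eig_floor = 1e-8) {
  x <- if (inherits(minimum, "minimum_record")) minimum$coordinates else minimum
  V <- potential$energy(x)
  H <- if (!is.null(potential$hessian)) potential$hessian(x) else
    numerical_hessian(potential, x, step = hessian_step)
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -eig_floor))
    stop("not a minimum: negative Hessian eigenvalue ", format(min(ev)))
  pos <- ev[ev > eig_floor]
  V + .kB * temperature * sum(log(sqrt(pos)))
}
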