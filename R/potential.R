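# Potential objects for basin-hopping: callable energy/gradient pairs
# plus the topology needed by torsional moves.

#' Construct a potential for basin-hopping
#'
#' @param energy Function of a coordinate vector returning a scalar
#'   energy (kcal/mol).
#' @param gradient Function returning the gradient vector.
#' @param hessian Optional function returning the Hessian matrix; when
#'   absent, finite differences of the gradient are used where a Hessian
#'   is required.
#' @param topology Optional list describing the molecular topology:
#'   `natoms`, `bonds` (2-column index matrix), `dihedrals` (list of
#'   entries with `type` one of "backbone"/"chi"/"attachment", `resno`,
#'   `quad`, `downstream`), and `residues` (data frame with `resno`,
#'   `code`, `prev`, `nxt`).  Required by torsional moves.
#' @param name Optional display name.
#' @return An object of class `"bh_potential"`.
#' @export
bh_potential <- function(energy, gradient, hessian = NULL, topology = NULL,
                         name = "potential") {
  stopifnot(is.function(energy), is.function(gradient))
  structure(list(energy = energy, gradient = gradient, hessian = hessian,
                 topology = topology, name = name),
            class = "bh_potential")
}

#' @export
print.bh_potential <- function(x, ...) {
  cat("Potential:", x$name, "\n")
  if (!is.null(x$topology))
    cat("  atoms:", x$topology$natoms,
        "  rotatable dihedrals:", length(x$topology$dihedrals), "\n")
  invisible(x)
}

#' Compare the analytic gradient against finite differences
#'
#' @param potential A `"bh_potential"`.
#' @param x Coordinate vector at which to check.
#' @param step Central-difference step.
#' @return Maximum relative error across components (relative to the
#'   gradient norm).
#' @export
check_gradient <- function(potential, x, step = 1e-6) {
  g <- potential$gradient(x)
  fd <- vapply(seq_along(x), function(i) {
    e <- rep(0, length(x)); e[i] <- step
    (potential$energy(x + e) - potential$energy(x - e)) / (2 * step)
  }, numeric(1L))
  max(abs(g - fd)) / max(sqrt(mean(g^2)), 1e-8)
}

#' Numerical Hessian of a potential by central differences of the gradient
#'
#' @param potential A `"bh_potential"`.
#' @param x Coordinate vector.
#' @param step Finite-difference step (default 1e-4).
#' @return Symmetrized Hessian matrix.
#' @export
numerical_hessian <- function(potential, x, step = 1e-4) {
  n <- length(x)
  H <- matrix(0, n, n)
  for (i in seq_len(n)) {
    e <- rep(0, n); e[i] <- step
    H[i, ] <- (potential$gradient(x + e) - potential$gradient(x - e)) / (2 * step)
  }
  (H + t(H)) / 2
}

#' Isotropic or anisotropic quadratic well
#'
#' `V(x) = sum_i k_i (x_i - x0_i)^2 / 2`, with analytic Hessian.  Normal
#' mode frequencies are `sqrt(k_i)` (unit masses).
#'
#' @param k Numeric vector of spring constants.
#' @param x0 Minimum location (default the origin).
#' @return A `"bh_potential"`.
#' @export
toy_quadratic_well <- function(k, x0 = rep(0, length(k))) {
  force(k); force(x0)
  bh_potential(
    energy = function(x) sum(k * (x - x0)^2) / 2,
    gradient = function(x) k * (x - x0),
    hessian = function(x) diag(k, length(k)),
    name = sprintf("quadratic well (%d modes)", length(k)))
}

#' One-dimensional double well x^4 - 2 x^2
#'
#' Minima at x = -1 and x = +1 (energy -1), barrier at x = 0.  An
#' optional linear tilt `-bias * x` makes the +1 well deeper.
#'
#' @param bias Linear tilt coefficient (default 0).
#' @return A `"bh_potential"`.
#' @export
toy_double_well <- function(bias = 0) {
  force(bias)
  bh_potential(
    energy = function(x) x[1L]^4 - 2 * x[1L]^2 - bias * x[1L],
    gradient = function(x) 4 * x[1L]^3 - 4 * x[1L] - bias,
    hessian = function(x) matrix(12 * x[1L]^2 - 4, 1L, 1L),
    name = "1-D double well")
}

#' Two-dimensional double well with basin-dependent transverse stiffness
#'
#' `V(x, y) = x^4 - 2 x^2 - bias x + k(x) y^2 / 2` with
#' `k(x) = k0 (1 + delta tanh(beta x))`.  The two basins (x near -1 and
#' +1) have different transverse curvature, so their harmonic free
#' energies differ even at equal well depth; useful for exercising
#' free-energy acceptance.
#'
#' @param k0 Base transverse stiffness.
#' @param delta Relative stiffness contrast between the basins.
#' @param beta Sharpness of the stiffness switch (default 2).
#' @param bias Linear tilt along x (default 0).
#' @return A `"bh_potential"`.
#' @export
toy_double_well_2d <- function(k0 = 1, delta = 0.6, beta = 2, bias = 0) {
  force(k0); force(delta); force(beta); force(bias)
  kf <- function(x) k0 * (1 + delta * tanh(beta * x))
  bh_potential(
    energy = function(x) x[1L]^4 - 2 * x[1L]^2 - bias * x[1L] +
      kf(x[1L]) * x[2L]^2 / 2,
    gradient = function(x) {
      dk <- k0 * delta * beta / cosh(beta * x[1L])^2
      c(4 * x[1L]^3 - 4 * x[1L] - bias + dk * x[2L]^2 / 2,
        kf(x[1L]) * x[2L])
    },
    name = "2-D double well, basin-dependent stiffness")
}
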