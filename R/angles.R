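#' Boltzmann constant in kcal/mol/K
#'
#' @keywords internal
.kB <- 0.0019872041

#' Normalize an angle to the interval (-180, 180]
#'
#' Angles are reduced modulo 360 degrees into the half-open interval
#' (-180, 180].  The reduction is idempotent and congruence-preserving:
#' `normalize_angle(x + 360)` equals `normalize_angle(x)`.
#'
#' @param raw Numeric vector of angles in degrees.
#' @return Numeric vector of the same length, each value in (-180, 180].
#' @examples
#' normalize_angle(540)   # 180
#' normalize_angle(-180)  # 180
#' @export
normalize_angle <- function(raw) {
  if (!is.numeric(raw) || any(!is.finite(raw)))
    stop("angles must be finite numeric values")
  r <- raw %% 360
  ifelse(r > 180, r - 360, r)
}

#' Shortest signed angular difference a - b on the circle
#'
#' @param a,b Numeric vectors of angles in degrees.
#' @return Signed difference in (-180, 180].
#' @export
angle_difference <- function(a, b) {
  normalize_angle(a - b)
}

#' Periodic distance between two angles
#'
#' The minimum arc between two angles on the circle, accounting for
#' periodicity, so that the distance between -179 and 180 degrees is 1
#' degree, not 359.
#'
#' @param a,b Numeric vectors of angles in degrees.
#' @return Distance in degrees, in `[0, 180]`.
#' @export
periodic_angle_distance <- function(a, b) {
  abs(angle_difference(a, b))
}

#' Euclidean distance between torsion vectors under the periodic metric
#'
#' Side-chain conformations are compared as n-dimensional vectors of chi
#' dihedrals.  The distance is the Euclidean norm of the component-wise
#' periodic angle distances.  Because every component of the sum is
#' bounded by the total, two conformations closer than a cutoff under
#' this metric are also within that cutoff in every individual chi,
#' making a flat-cluster cut under this metric stricter than a per-chi
#' criterion at the same value.
#'
#' @param p,q Numeric vectors of chi angles in degrees, equal length.
#' @return Distance in degrees.
#' @export
torsion_distance <- function(p, q) {
  if (length(p) != length(q))
    stop("torsion vectors have different dimensions: ",
         length(p), " vs ", length(q))
  if (length(p) == 0L) stop("torsion vectors must have at least one angle")
  sqrt(sum(periodic_angle_distance(p, q)^2))
}

#' Circular mean of angles
#'
#' @param x Numeric vector of angles in degrees.
#' @return Mean direction in (-180, 180].
#' @export
circular_mean <- function(x) {
  if (length(x) == 0L) stop("empty angle set")
  r <- x * pi / 180
  s <- mean(sin(r)); c <- mean(cos(r))
  if (sqrt(s^2 + c^2) < 1e-12)
    stop("circular mean undefined: resultant length is zero")
  normalize_angle(atan2(s, c) * 180 / pi)
}

#' Circular (population) standard deviation of angles
#'
#' Root-mean-square of the signed periodic deviations about the circular
#' mean.  For tightly clustered angles this agrees with the ordinary
#' population standard deviation, while remaining correct across the
#' +/-180 wrap.
#'
#' @param x Numeric vector of angles in degrees.
#' @return Standard deviation in degrees.
#' @export
circular_sd <- function(x) {
  mu <- circular_mean(x)
  sqrt(mean(angle_difference(x, mu)^2))
}
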