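#' Wrap angles to the half-open interval (-pi, pi]
#'
#' All headings and relative angles in the package live on (-pi, pi].
#' The interval is half-open so that every angle, including the boundary,
#' has a single-valued mirror image: `-pi` maps to `+pi`.
#'
#' @param a Numeric vector of angles in radians. Must be finite.
#' @return Numeric vector of the same length, congruent to `a` modulo
#'   `2*pi`, with every element in `(-pi, pi]`.
#' @examples
#' wrap_angle(3 * pi / 2) # -pi/2
#' wrap_angle(-pi)        # +pi
#' @export
wrap_angle <- function(a) {
  if (!is.numeric(a)) stop("`a` must be numeric", call. = FALSE)
  if (any(!is.finite(a))) stop("angles must be finite", call. = FALSE)
  a - 2 * pi * ceiling((a - pi) / (2 * pi))
}

#' Odd and even angular shape functions
#'
#' Angular modulations of the turning response are expanded in a short
#' cosine series on top of the leading sine (odd case) or constant (even
#' case):
#' odd: `sin(theta) * (1 + sum_k a_k cos(k theta))`,
#' even: `1 + sum_k b_k cos(k theta)`.
#' With `normalize = TRUE` the result is scaled to unit mean square over
#' the circle, `(1/2pi) * integral(shape^2) = 1`, the convention used
#' throughout for all angular interaction factors.
#'
#' @param theta Angles (rad).
#' @param coefs Numeric vector of cosine coefficients; element `k` is the
#'   coefficient of `cos(k * theta)`.
#' @param normalize Scale to unit mean square over `(-pi, pi]`?
#' @return Numeric vector of shape values.
#' @export
shape_odd <- function(theta, coefs = numeric(), normalize = TRUE) {
  f <- sin(theta) * (1 + cos_series(theta, coefs))
  if (normalize) f / sqrt(mean_square_odd(coefs)) else f
}

#' @rdname shape_odd
#' @export
shape_even <- function(theta, coefs = numeric(), normalize = TRUE) {
  f <- 1 + cos_series(theta, coefs)
  if (normalize) f / sqrt(mean_square_even(coefs)) else f
}

cos_series <- function(theta, coefs) {
  if (length(coefs) == 0) return(rep(0, length(theta)))
  out <- 0
  for (k in seq_along(coefs)) out <- out + coefs[k] * cos(k * theta)
  out
}

# Mean square over the circle, by adaptive quadrature. Closed forms exist
# for short series but quadrature keeps arbitrary harmonic content honest.
circle_mean_square <- function(f) {
  stats::integrate(function(th) f(th)^2, -pi, pi,
                   rel.tol = 1e-12, abs.tol = 1e-14)$value / (2 * pi)
}

mean_square_odd <- function(coefs) {
  circle_mean_square(function(th) sin(th) * (1 + cos_series(th, coefs)))
}

mean_square_even <- function(coefs) {
  circle_mean_square(function(th) 1 + cos_series(th, coefs))
}
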