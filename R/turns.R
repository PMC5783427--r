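#' Heading-change components of the kick-decision rule
#'
#' Each kick changes the heading by the sum of up to four terms.
#' `turn_wall()` is the deterministic wall-avoidance turn
#' `gamma_w * O_w(theta_w) * f_w(r_w)`, with `O_w` the unit-mean-square
#' odd angular shape and `f_w` the Gaussian attenuation
#' [wall_attenuation()]; it is odd in `theta_w`, so its sign always
#' rotates the fish away from the wall. `turn_attraction()` and
#' `turn_alignment()` are the separable social terms
#' `gamma_att * F_att(d) * O_att(psi) * E_att(dphi_pair)` and
#' `gamma_ali * F_ali(d) * O_ali(dphi_pair) * E_ali(psi)`; both are odd
#' under the simultaneous sign flip of `psi` and `dphi_pair`, as
#' required by left/right symmetry. `turn_spontaneous_sd()` gives the
#' standard deviation `gamma_r * (1 - alpha * f_w(r_w))` of the
#' spontaneous Gaussian turn, reduced near the wall where the fish has
#' less room; `turn_spontaneous()` draws from it.
#'
#' @param r_w_mm Distance to the wall (mm).
#' @param theta_w_rad Signed angle to the outward wall normal (rad).
#' @param d_mm Inter-fish distance (mm).
#' @param psi_rad Viewing angle of the neighbour (rad).
#' @param dphi_pair_rad Relative heading of the neighbour (rad).
#' @param params A [model_params()] object.
#' @return Numeric vector of heading changes (rad), or of standard
#'   deviations for `turn_spontaneous_sd()`.
#' @export
turn_wall <- function(r_w_mm, theta_w_rad, params) {
  o <- sin(theta_w_rad) * (1 + cos_series(theta_w_rad, params$eps_w)) /
    params$norm_w
  params$gamma_w * o * wall_attenuation(r_w_mm, params$l_w_mm)
}

#' @rdname turn_wall
#' @export
turn_attraction <- function(d_mm, psi_rad, dphi_pair_rad, params) {
  f <- (d_mm - params$d0_mm) / (1 + (d_mm / params$l_att_mm)^2) /
    params$att_profile_scale
  o <- sin(psi_rad) * (1 + cos_series(psi_rad, params$att_odd)) /
    params$norm_att_odd
  e <- (1 + cos_series(dphi_pair_rad, params$att_even)) / params$norm_att_even
  params$gamma_att * f * o * e
}

#' @rdname turn_wall
#' @export
turn_alignment <- function(d_mm, psi_rad, dphi_pair_rad, params) {
  f <- (d_mm + params$d0p_mm) * exp(-(d_mm / params$l_ali_mm)^2) /
    params$ali_profile_scale
  o <- sin(dphi_pair_rad) * (1 + cos_series(dphi_pair_rad, params$ali_odd)) /
    params$norm_ali_odd
  e <- (1 + cos_series(psi_rad, params$ali_even)) / params$norm_ali_even
  params$gamma_ali * f * o * e
}

#' @rdname turn_wall
#' @export
turn_spontaneous_sd <- function(r_w_mm, params) {
  params$gamma_r * (1 - params$alpha * wall_attenuation(r_w_mm, params$l_w_mm))
}

#' @rdname turn_wall
#' @export
turn_spontaneous <- function(r_w_mm, params) {
  stats::rnorm(length(r_w_mm), 0, turn_spontaneous_sd(r_w_mm, params))
}
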