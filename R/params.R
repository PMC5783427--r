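#' Kick kinematics configuration
#'
#' Peak speed `v_n` and kick length `l_n` of each burst are drawn from
#' log-normal distributions (bell-shaped on the positive axis,
#' consistent with the measured kick statistics); the kick duration
#' follows from the passive-glide relation
#' `l_n = v_n * tau0 * (1 - exp(-tau_n / tau0))`, with `tau0` the
#' viscous dissipation time of the coast phase. Pairs with
#' `l_n >= v_n * tau0` have no finite duration and are resampled.
#'
#' Defaults are calibrated on the in-arena statistics (wall rejections
#' resample kinematics and shorten accepted kicks, so the free-swimming
#' configuration is set higher): a single simulated fish in the 250 mm
#' arena produces a mean kick length close to 70 mm, a mean inter-kick
#' duration close to 0.5 s, and a mean within-kick travel speed of
#' order 150 mm/s.
#'
#' @param v_mean_mm_s Mean peak speed (mm/s).
#' @param v_cv Coefficient of variation of the peak speed.
#' @param l_mean_mm Mean kick length (mm).
#' @param l_cv Coefficient of variation of the kick length.
#' @param tau0_s Dissipation time of the glide (s).
#' @return An object of class `bc_kinematics`.
#' @export
kick_kinematics <- function(v_mean_mm_s = 200, v_cv = 0.15,
                            l_mean_mm = 82, l_cv = 0.25,
                            tau0_s = 0.8) {
  stopifnot(v_mean_mm_s > 0, v_cv > 0, l_mean_mm > 0, l_cv > 0, tau0_s > 0)
  structure(
    list(
      v_mean_mm_s = v_mean_mm_s, v_cv = v_cv,
      l_mean_mm = l_mean_mm, l_cv = l_cv,
      tau0_s = tau0_s,
      v_sdlog = sqrt(log1p(v_cv^2)),
      v_meanlog = log(v_mean_mm_s) - log1p(v_cv^2) / 2,
      l_sdlog = sqrt(log1p(l_cv^2)),
      l_meanlog = log(l_mean_mm) - log1p(l_cv^2) / 2
    ),
    class = "bc_kinematics"
  )
}

#' Model parameters for the kick-decision rule
#'
#' Houses every behavioural parameter of the heading-change model. At
#' each kick the heading change is the sum of four contributions:
#' a spontaneous Gaussian turn whose width `gamma_r` is reduced by a
#' factor up to `1 - alpha` close to the wall; a wall-avoidance turn of
#' amplitude `gamma_w`, range `l_w_mm` and angular anisotropy `eps_w`;
#' and, with a neighbour present, attraction (`gamma_att`) and alignment
#' (`gamma_ali`) turns with separable distance and angular dependences.
#' All angular shape functions are stored as cosine-series coefficients
#' (see [shape_odd()]) and evaluated in the unit-mean-square
#' normalization; the distance profiles are normalized so that the
#' attraction profile equals 1 at `l_att_mm` and the alignment profile
#' equals 1 at its maximum, so `gamma_att` and `gamma_ali` carry the
#' overall scale in radians.
#'
#' @param radius_mm Arena radius (mm).
#' @param gamma_r Spontaneous turn scale far from the wall (rad).
#' @param alpha Fractional reduction of spontaneous turning at the wall,
#'   in `[0, 1]`.
#' @param gamma_w Wall-avoidance amplitude (rad).
#' @param l_w_mm Range of the wall interaction (mm).
#' @param l_c_mm Comfort length added ahead of a proposed kick when
#'   testing for wall collision (mm).
#' @param eps_w Cosine coefficients of the wall angular anisotropy;
#'   the default `c(0, 0.7)` is a pure `cos(2 theta_w)` modulation.
#' @param gamma_att,gamma_ali Amplitudes of attraction and alignment
#'   (rad).
#' @param d0_mm Distance below which attraction turns repulsive (mm).
#' @param l_att_mm Range of the attraction profile (mm).
#' @param d0p_mm Offset of the alignment profile (mm).
#' @param l_ali_mm Gaussian range of the alignment profile (mm).
#' @param att_odd Cosine coefficients of the odd viewing-angle factor of
#'   attraction.
#' @param att_even Cosine coefficients of the even relative-heading
#'   factor of attraction.
#' @param ali_odd Cosine coefficients of the odd relative-heading factor
#'   of alignment.
#' @param ali_even Cosine coefficients of the even viewing-angle factor
#'   of alignment.
#' @param max_rejections Number of rejected kick proposals before the
#'   spontaneous turn falls back to a uniform draw on `[-pi, pi]`.
#' @return An object of class `bc_params`.
#' @seealso [preset_params()] for the calibrated experimental
#'   conditions, [simulate_kicks()].
#' @export
model_params <- function(radius_mm = 250,
                         gamma_r = 0.35,
                         alpha = 2 / 3,
                         gamma_w = 0.12,
                         l_w_mm = 60,
                         l_c_mm = 30,
                         eps_w = c(0, 0.7),
                         gamma_att = 0.30,
                         gamma_ali = 0.16,
                         d0_mm = 30,
                         l_att_mm = 200,
                         d0p_mm = 30,
                         l_ali_mm = 200,
                         att_odd = c(-0.33),
                         att_even = c(0.48, -0.31),
                         ali_odd = c(0, 0.30),
                         ali_even = c(0.60, -0.32),
                         max_rejections = 1000) {
  check_radius(radius_mm)
  stopifnot(
    gamma_r >= 0, alpha >= 0, alpha <= 1,
    l_w_mm > 0, l_c_mm > 0,
    d0_mm >= 0, l_att_mm > 0, d0p_mm >= 0, l_ali_mm > 0,
    max_rejections >= 1
  )
  p <- list(
    radius_mm = radius_mm,
    gamma_r = gamma_r, alpha = alpha,
    gamma_w = gamma_w, l_w_mm = l_w_mm, l_c_mm = l_c_mm, eps_w = eps_w,
    gamma_att = gamma_att, gamma_ali = gamma_ali,
    d0_mm = d0_mm, l_att_mm = l_att_mm,
    d0p_mm = d0p_mm, l_ali_mm = l_ali_mm,
    att_odd = att_odd, att_even = att_even,
    ali_odd = ali_odd, ali_even = ali_even,
    max_rejections = max_rejections
  )
  # cached normalization constants: unit mean square for angular shapes,
  # profile scales for the distance factors
  p$norm_w <- sqrt(mean_square_odd(eps_w))
  p$norm_att_odd <- sqrt(mean_square_odd(att_odd))
  p$norm_att_even <- sqrt(mean_square_even(att_even))
  p$norm_ali_odd <- sqrt(mean_square_odd(ali_odd))
  p$norm_ali_even <- sqrt(mean_square_even(ali_even))
  p$att_profile_scale <- (l_att_mm - d0_mm) / 2
  opt <- stats::optimize(
    function(d) (d + d0p_mm) * exp(-(d / l_ali_mm)^2),
    interval = c(0, 4 * l_ali_mm), maximum = TRUE, tol = 1e-10
  )
  p$ali_profile_scale <- opt$objective
  structure(p, class = "bc_params")
}

#' @export
print.bc_params <- function(x, ...) {
  cat("<bc_params> burst-and-coast model parameters\n")
  cat(sprintf("  arena radius %g mm, comfort length %g mm\n",
              x$radius_mm, x$l_c_mm))
  cat(sprintf("  spontaneous: gamma_r = %.3g rad, alpha = %.3g\n",
              x$gamma_r, x$alpha))
  cat(sprintf("  wall: gamma_w = %.3g rad, l_w = %g mm\n",
              x$gamma_w, x$l_w_mm))
  cat(sprintf("  attraction: gamma_att = %.3g rad, d0 = %g mm, l_att = %g mm\n",
              x$gamma_att, x$d0_mm, x$l_att_mm))
  cat(sprintf("  alignment: gamma_ali = %.3g rad, d0' = %g mm, l_ali = %g mm\n",
              x$gamma_ali, x$d0p_mm, x$l_ali_mm))
  invisible(x)
}

#' Calibrated parameter presets for the four experimental conditions
#'
#' Returns [model_params()] filled with the per-condition calibration
#' used in the original experiments: single fish in arenas of radius
#' 176, 250 and 353 mm, and two fish at radius 250 mm. The wall-noise
#' reduction `alpha` is derived from the near-wall turn scale of each
#' condition via `gamma_r0 = (1 - alpha) * gamma_r`.
#'
#' @param n_fish 1 or 2.
#' @param radius_mm One of 176, 250, 353 (two-fish data exist only at
#'   250 mm).
#' @return A `bc_params` object.
#' @export
preset_params <- function(n_fish = 1, radius_mm = 250) {
  key <- paste(n_fish, radius_mm)
  row <- switch(key,
    "1 176" = list(l_c = 21, gamma_r = 0.35, gamma_r0 = 0.12, gamma_w = 0.40),
    "1 250" = list(l_c = 30, gamma_r = 0.35, gamma_r0 = 0.14, gamma_w = 0.12),
    "1 353" = list(l_c = 45, gamma_r = 0.35, gamma_r0 = 0.11, gamma_w = 0.10),
    "2 250" = list(l_c = 30, gamma_r = 0.45, gamma_r0 = 0.15, gamma_w = 0.15),
    stop("no preset for n_fish = ", n_fish, ", radius_mm = ", radius_mm,
         call. = FALSE)
  )
  model_params(
    radius_mm = radius_mm,
    gamma_r = row$gamma_r,
    alpha = 1 - row$gamma_r0 / row$gamma_r,
    gamma_w = row$gamma_w,
    l_c_mm = row$l_c
  )
}

#' Calibrated kick-kinematics presets
#'
#' Kick lengths are somewhat shorter when two fish swim together than
#' for a fish alone; these presets return [kick_kinematics()] with the
#' per-condition calibration (in-arena mean kick length near 70 mm
#' alone and 55 mm in a pair, mean inter-kick duration close to 0.5 s
#' alone).
#'
#' @param n_fish 1 or 2.
#' @return A `bc_kinematics` object.
#' @export
preset_kinematics <- function(n_fish = 1) {
  if (!n_fish %in% c(1, 2)) stop("`n_fish` must be 1 or 2", call. = FALSE)
  if (n_fish == 1) kick_kinematics() else kick_kinematics(l_mean_mm = 65)
}

#' Distance profiles of the wall, attraction and alignment interactions
#'
#' `wall_attenuation()` is the Gaussian range factor of the wall
#' interaction, `exp(-(r_w / l_w)^2)`, equal to 1 at the wall and
#' decaying over `l_w`. `attraction_profile()` is the normalized
#' attraction distance factor `(d - d0) / (1 + (d / l_att)^2)`, negative
#' (repulsive) below `d0`, scaled to 1 at `d = l_att`.
#' `alignment_profile()` is the normalized alignment distance factor
#' `(d + d0p) * exp(-(d / l_ali)^2)`, scaled to 1 at its maximum.
#'
#' @param r_w_mm Distance to the wall (mm, >= 0).
#' @param l_w_mm Range of the wall interaction (mm, > 0).
#' @param d_mm Inter-fish distance (mm, >= 0).
#' @param d0_mm,l_att_mm,d0p_mm,l_ali_mm Profile parameters (mm).
#' @return Numeric vector of dimensionless profile values.
#' @export
wall_attenuation <- function(r_w_mm, l_w_mm) {
  if (!is.numeric(l_w_mm) || any(l_w_mm <= 0)) {
    stop("`l_w_mm` must be positive", call. = FALSE)
  }
  exp(-(r_w_mm / l_w_mm)^2)
}

#' @rdname wall_attenuation
#' @export
attraction_profile <- function(d_mm, d0_mm = 30, l_att_mm = 200) {
  raw <- (d_mm - d0_mm) / (1 + (d_mm / l_att_mm)^2)
  raw / ((l_att_mm - d0_mm) / 2)
}

#' @rdname wall_attenuation
#' @export
alignment_profile <- function(d_mm, d0p_mm = 30, l_ali_mm = 200) {
  raw <- (d_mm + d0p_mm) * exp(-(d_mm / l_ali_mm)^2)
  opt <- stats::optimize(
    function(d) (d + d0p_mm) * exp(-(d / l_ali_mm)^2),
    interval = c(0, 4 * l_ali_mm), maximum = TRUE, tol = 1e-10
  )
  raw / opt$objective
}
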