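#' Wall frame: distance and orientation relative to the arena wall
#'
#' For each fish pose the wall frame is the pair (`r_w`, `theta_w`):
#' `r_w` is the distance from the fish centre of mass to the circular
#' wall, and `theta_w` the signed angle between the heading and the
#' outward wall normal at the fish's position. The sign convention is
#' such that `dphi * sign(theta_w) > 0` means turning away from the
#' wall. A fish at the exact arena centre has no defined normal; such
#' rows get `theta_w_rad = 0` and `degenerate = TRUE` and are excluded
#' from inference binning.
#'
#' @param data Data frame with columns `x_mm`, `y_mm`, `phi_rad`.
#' @param radius_mm Arena radius (mm), a single positive number.
#' @return The input as a tibble with columns `r_w_mm`, `theta_w_rad`
#'   and logical `degenerate` added.
#' @examples
#' poses <- tibble::tibble(x_mm = 240, y_mm = 0, phi_rad = pi / 2)
#' wall_frame(poses, radius_mm = 250) # r_w = 10, theta_w = pi/2
#' @export
wall_frame <- function(data, radius_mm) {
  check_radius(radius_mm)
  need_cols(data, c("x_mm", "y_mm", "phi_rad"))
  rho <- sqrt(data$x_mm^2 + data$y_mm^2)
  if (any(rho >= radius_mm)) {
    stop("positions must lie strictly inside the arena", call. = FALSE)
  }
  degenerate <- rho == 0
  theta <- ifelse(degenerate, 0,
                  wrap_angle(data$phi_rad - atan2(data$y_mm, data$x_mm)))
  tibble::as_tibble(data) |>
    dplyr::mutate(
      r_w_mm = radius_mm - rho,
      theta_w_rad = theta,
      degenerate = degenerate
    )
}

#' Pair frame: distance, viewing angle and relative heading of a neighbour
#'
#' Computes, for each row, the stimulus variables through which a
#' neighbouring fish influences the focal fish: the inter-fish distance
#' `d`, the signed viewing angle `psi` at which the focal fish sees the
#' neighbour (0 = dead ahead), and the heading difference
#' `dphi_pair = phi_other - phi_focal`. The viewing angle of the
#' neighbour is in general not `-psi`, so the frame is not symmetric
#' under exchanging the two fish. Coincident positions leave `psi`
#' undefined: such rows get `psi_rad = 0` and `degenerate = TRUE`.
#'
#' @param data Data frame with focal columns `x_mm`, `y_mm`, `phi_rad`
#'   and partner columns `partner_x_mm`, `partner_y_mm`,
#'   `partner_phi_rad`, both poses at the same evaluation time.
#' @return The input as a tibble with `d_mm`, `psi_rad`,
#'   `dphi_pair_rad` and logical `degenerate` added.
#' @export
pair_frame <- function(data) {
  need_cols(data, c("x_mm", "y_mm", "phi_rad",
                    "partner_x_mm", "partner_y_mm", "partner_phi_rad"))
  dx <- data$partner_x_mm - data$x_mm
  dy <- data$partner_y_mm - data$y_mm
  d <- sqrt(dx^2 + dy^2)
  degenerate <- d == 0
  psi <- ifelse(degenerate, 0, wrap_angle(atan2(dy, dx) - data$phi_rad))
  tibble::as_tibble(data) |>
    dplyr::mutate(
      d_mm = d,
      psi_rad = psi,
      dphi_pair_rad = wrap_angle(partner_phi_rad - phi_rad),
      degenerate = degenerate
    )
}

#' Mirror kick records across a line through the arena centre
#'
#' Left/right symmetry of swimming in a circular arena means a
#' trajectory viewed from below the tank is as probable as the original
#' viewed from above. Mirroring negates every signed angle of a kick
#' record -- `theta_w`, `psi`, `dphi_pair` and the response `dphi` --
#' while distances (`r_w`, `d`), lengths, durations and speeds are
#' unchanged. Applying `mirror_kicks()` twice is the identity.
#'
#' @param kicks Data frame of kick records; any of the columns
#'   `theta_w_rad`, `psi_rad`, `dphi_pair_rad`, `dphi_rad` present are
#'   negated.
#' @return Tibble of mirrored records, same dimensions.
#' @seealso [symmetrize_kicks()] which appends the mirrored copy.
#' @export
mirror_kicks <- function(kicks) {
  out <- tibble::as_tibble(kicks)
  for (col in c("theta_w_rad", "psi_rad", "dphi_pair_rad", "dphi_rad")) {
    if (col %in% names(out)) out[[col]] <- -out[[col]]
  }
  out
}

#' Correct tracked positions for camera parallax
#'
#' A camera mounted a distance `camera_mm` above the tank bottom images
#' a fish swimming at height `h_mm` with a radial displacement away from
#' the image centre. The corrected position is
#' `(1 + h/(h + D)) * (r - r_ccd) + r_ccd`, the standard thin-lens
#' parallax correction for a target at constant height. With `h_mm = 0`
#' the map is the identity, and the image centre is a fixed point.
#'
#' @param data Data frame with columns `x_mm`, `y_mm`.
#' @param h_mm Swimming height above the tank bottom (mm, >= 0).
#' @param camera_mm Distance from the camera optical centre to the tank
#'   bottom along the optical axis (mm, > 0).
#' @param ccd_x_mm,ccd_y_mm Image centre in arena coordinates (mm).
#' @return Tibble with `x_mm`, `y_mm` replaced by corrected positions.
#' @export
parallax_correct <- function(data, h_mm, camera_mm,
                             ccd_x_mm = 0, ccd_y_mm = 0) {
  need_cols(data, c("x_mm", "y_mm"))
  if (!is.numeric(camera_mm) || length(camera_mm) != 1 || camera_mm <= 0) {
    stop("`camera_mm` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(h_mm) || length(h_mm) != 1 || h_mm < 0) {
    stop("`h_mm` must be a single non-negative number", call. = FALSE)
  }
  fac <- 1 + h_mm / (h_mm + camera_mm)
  tibble::as_tibble(data) |>
    dplyr::mutate(
      x_mm = fac * (x_mm - ccd_x_mm) + ccd_x_mm,
      y_mm = fac * (y_mm - ccd_y_mm) + ccd_y_mm
    )
}

check_radius <- function(radius_mm) {
  if (!is.numeric(radius_mm) || length(radius_mm) != 1 ||
      !is.finite(radius_mm) || radius_mm <= 0) {
    stop("`radius_mm` must be a single positive number", call. = FALSE)
  }
  invisible(radius_mm)
}

need_cols <- function(data, cols) {
  missing <- setdiff(cols, names(data))
  if (length(missing)) {
    stop("missing required columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  invisible(data)
}
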