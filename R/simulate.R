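#' Sample kick kinematics
#'
#' Draws peak speed and kick length from the configured log-normal
#' distributions and derives the kick duration from the glide relation
#' `tau = -tau0 * log(1 - l / (v * tau0))`. Pairs with
#' `l >= v * tau0` (which would glide forever without covering `l`)
#' are resampled.
#'
#' @param n Number of kicks to draw.
#' @param kin A [kick_kinematics()] configuration.
#' @return Tibble with columns `v_peak_mm_s`, `l_mm`, `tau_s`.
#' @export
sample_kick_kinematics <- function(n, kin = kick_kinematics()) {
  stopifnot(inherits(kin, "bc_kinematics"), n >= 0)
  v <- stats::rlnorm(n, kin$v_meanlog, kin$v_sdlog)
  l <- stats::rlnorm(n, kin$l_meanlog, kin$l_sdlog)
  bad <- which(l >= v * kin$tau0_s)
  while (length(bad)) {
    v[bad] <- stats::rlnorm(length(bad), kin$v_meanlog, kin$v_sdlog)
    l[bad] <- stats::rlnorm(length(bad), kin$l_meanlog, kin$l_sdlog)
    bad <- bad[l[bad] >= v[bad] * kin$tau0_s]
  }
  tibble::tibble(
    v_peak_mm_s = v,
    l_mm = l,
    tau_s = -kin$tau0_s * log(1 - l / (v * kin$tau0_s))
  )
}

# one kinematics triple, scalar, consuming the current RNG stream
sample_one_kick <- function(kin) {
  repeat {
    v <- stats::rlnorm(1, kin$v_meanlog, kin$v_sdlog)
    l <- stats::rlnorm(1, kin$l_meanlog, kin$l_sdlog)
    if (l < v * kin$tau0_s) break
  }
  c(v = v, l = l, tau = -kin$tau0_s * log(1 - l / (v * kin$tau0_s)))
}

#' Continuous glide interpolation within a kick
#'
#' During the coast phase the speed decays exponentially with time
#' constant `tau0`, so the position advances along the (straight)
#' heading by the fraction
#' `(1 - exp(-t / tau0)) / (1 - exp(-tau / tau0))` of the kick length.
#' The endpoints reproduce the kick start and end positions exactly, and
#' the instantaneous speed at `t = 0` equals the peak speed.
#'
#' @param x0_mm,y0_mm Kick start position (mm).
#' @param phi_rad Kick heading (rad).
#' @param l_mm Kick length (mm).
#' @param tau_s Kick duration (s).
#' @param t_s Times since kick onset (s), each in `[0, tau_s]`.
#' @param tau0_s Glide dissipation time (s).
#' @return Tibble with columns `t_s`, `x_mm`, `y_mm`.
#' @export
glide_position <- function(x0_mm, y0_mm, phi_rad, l_mm, tau_s, t_s,
                           tau0_s = 0.8) {
  if (any(t_s < 0 | t_s > tau_s)) {
    stop("`t_s` must lie within [0, tau_s]", call. = FALSE)
  }
  frac <- glide_fraction(t_s, tau_s, tau0_s)
  tibble::tibble(
    t_s = t_s,
    x_mm = x0_mm + l_mm * frac * cos(phi_rad),
    y_mm = y0_mm + l_mm * frac * sin(phi_rad)
  )
}

glide_fraction <- function(t, tau, tau0) {
  n <- max(length(t), length(tau))
  t <- rep_len(t, n)
  tau <- rep_len(tau, n)
  out <- numeric(n)
  ok <- tau > 0
  out[ok] <- (1 - exp(-t[ok] / tau0)) / (1 - exp(-tau[ok] / tau0))
  out
}

#' Simulate burst-and-coast kick dynamics for one or two fish
#'
#' Event-driven stochastic simulation of the kick-decision model in a
#' circular arena. At each kick the focal fish draws new kinematics
#' (peak speed, length, duration) and a heading change equal to the sum
#' of a spontaneous Gaussian turn, the wall-avoidance turn and -- with a
#' partner present -- the attraction and alignment turns evaluated at
#' the partner's glide-interpolated pose. Proposals whose look-ahead
#' point `x + (l + l_c) e(phi + dphi)` would leave the arena are
#' rejected and redrawn (kinematics and spontaneous turn); after
#' `max_rejections` failures the spontaneous turn falls back to a
#' uniform draw on `[-pi, pi]`, which guarantees termination. With two
#' fish the one with the earlier next-kick time moves first.
#'
#' @param n_kicks Total number of kicks to record (both fish together).
#' @param params A [model_params()] object (arena radius included).
#' @param kin A [kick_kinematics()] configuration.
#' @param n_fish 1 or 2.
#' @param seed Optional integer seed for reproducibility.
#' @param initial Optional list of per-fish initial poses, each a list
#'   with elements `x_mm`, `y_mm`, `phi_rad`. Default: uniform positions
#'   within half the arena radius and uniform headings.
#' @param n_burn Number of initial kicks to simulate and discard before
#'   recording, letting the dynamics relax to its stationary behaviour.
#' @param angle_sign Either `1` or `-1`; `-1` flips the sign of every
#'   random angular draw. Running with mirrored initial poses and
#'   `angle_sign = -1` yields the exact mirror image of the original
#'   run, which is how the left/right equivariance of the model is
#'   tested.
#' @return Tibble with one row per kick: `t_s`, `fish_id`, start
#'   position `x_mm`/`y_mm`, new heading `phi_rad`, heading change
#'   `dphi_rad` and its components (`dphi_r_rad`, `dphi_w_rad`, and for
#'   pairs `dphi_att_rad`, `dphi_ali_rad`), kinematics (`v_peak_mm_s`,
#'   `l_mm`, `tau_s`), the stimulus frames at the kick (`r_w_mm`,
#'   `theta_w_rad`, and for pairs `d_mm`, `psi_rad`, `dphi_pair_rad`)
#'   and the number of rejected proposals (`rejections`). The arena
#'   radius and glide time are attached as attributes `radius_mm` and
#'   `tau0_s`.
#' @export
simulate_kicks <- function(n_kicks,
                           params = model_params(),
                           kin = kick_kinematics(),
                           n_fish = 1,
                           seed = NULL,
                           initial = NULL,
                           n_burn = 0,
                           angle_sign = 1) {
  stopifnot(inherits(params, "bc_params"), inherits(kin, "bc_kinematics"))
  if (!n_fish %in% c(1L, 2L)) stop("`n_fish` must be 1 or 2", call. = FALSE)
  stopifnot(n_kicks >= 1, n_burn >= 0, angle_sign %in% c(-1, 1))
  if (!is.null(seed)) set.seed(seed)
  R <- params$radius_mm
  tau0 <- kin$tau0_s
  n_total <- n_kicks + n_burn

  # per-fish state: current glide segment and next kick time
  fish <- vector("list", n_fish)
  for (i in seq_len(n_fish)) {
    if (is.null(initial)) {
      rho <- R / 2 * sqrt(stats::runif(1))
      ang <- stats::runif(1, -pi, pi)
      pose <- list(x_mm = rho * cos(ang), y_mm = rho * sin(ang),
                   phi_rad = angle_sign * stats::runif(1, -pi, pi))
    } else {
      pose <- initial[[i]]
    }
    fish[[i]] <- list(
      x0 = pose$x_mm, y0 = pose$y_mm, phi = wrap_angle(pose$phi_rad),
      l = 0, v = 0, tau = 0, t0 = 0,
      next_t = if (i == 1) 0 else stats::runif(1, 0, 0.3)
    )
  }

  cols <- c("t_s", "fish_id", "x_mm", "y_mm", "phi_rad", "dphi_rad",
            "dphi_r_rad", "dphi_w_rad", "dphi_att_rad", "dphi_ali_rad",
            "v_peak_mm_s", "l_mm", "tau_s", "r_w_mm", "theta_w_rad",
            "d_mm", "psi_rad", "dphi_pair_rad", "rejections")
  out <- matrix(NA_real_, nrow = n_total, ncol = length(cols),
                dimnames = list(NULL, cols))

  for (n in seq_len(n_total)) {
    i <- if (n_fish == 1L) 1L else which.min(vapply(fish, `[[`, 0, "next_t"))
    f <- fish[[i]]
    t_now <- f$next_t
    # decision point: end of the current glide segment
    x <- f$x0 + f$l * cos(f$phi)
    y <- f$y0 + f$l * sin(f$phi)
    rho <- sqrt(x^2 + y^2)
    r_w <- R - rho
    theta_w <- if (rho == 0) 0 else wrap_angle(f$phi - atan2(y, x))
    dphi_w <- turn_wall(r_w, theta_w, params)

    dphi_att <- dphi_ali <- 0
    d <- psi <- dphi_pair <- NA_real_
    if (n_fish == 2L) {
      g <- fish[[3L - i]]
      dt <- min(max(t_now - g$t0, 0), g$tau)
      frac <- glide_fraction(dt, g$tau, tau0)
      px <- g$x0 + g$l * frac * cos(g$phi)
      py <- g$y0 + g$l * frac * sin(g$phi)
      d <- sqrt((px - x)^2 + (py - y)^2)
      psi <- if (d == 0) 0 else wrap_angle(atan2(py - y, px - x) - f$phi)
      dphi_pair <- wrap_angle(g$phi - f$phi)
      dphi_att <- turn_attraction(d, psi, dphi_pair, params)
      dphi_ali <- turn_alignment(d, psi, dphi_pair, params)
    }
    dphi_det <- dphi_w + dphi_att + dphi_ali
    sd_r <- turn_spontaneous_sd(r_w, params)

    attempts <- 0L
    repeat {
      kk <- sample_one_kick(kin)
      dphi_r <- if (attempts < params$max_rejections) {
        angle_sign * sd_r * stats::rnorm(1)
      } else {
        angle_sign * stats::runif(1, -pi, pi)
      }
      dphi <- dphi_r + dphi_det
      phi_new <- wrap_angle(f$phi + dphi)
      reach <- kk[["l"]] + params$l_c_mm
      xt <- x + reach * cos(phi_new)
      yt <- y + reach * sin(phi_new)
      if (xt^2 + yt^2 < R^2) break
      attempts <- attempts + 1L
      if (attempts > 1e6) {
        stop("kick rejection did not terminate after 1e6 attempts; ",
             "check the arena and kinematics configuration", call. = FALSE)
      }
    }

    # the recorded heading change is the wrapped difference, exactly
    # what segmentation of the trajectory would measure
    dphi <- wrap_angle(dphi)
    out[n, ] <- c(t_now, i, x, y, phi_new, dphi, dphi_r, dphi_w,
                  dphi_att, dphi_ali, kk[["v"]], kk[["l"]], kk[["tau"]],
                  r_w, theta_w, d, psi, dphi_pair, attempts)
    fish[[i]] <- list(x0 = x, y0 = y, phi = phi_new,
                      l = kk[["l"]], v = kk[["v"]], tau = kk[["tau"]],
                      t0 = t_now, next_t = t_now + kk[["tau"]])
  }

  res <- tibble::as_tibble(as.data.frame(out))
  res$fish_id <- as.integer(res$fish_id)
  res$rejections <- as.integer(res$rejections)
  if (n_fish == 1L) {
    res$d_mm <- res$psi_rad <- res$dphi_pair_rad <- NULL
    res$dphi_att_rad <- res$dphi_ali_rad <- NULL
  }
  if (n_burn > 0) res <- res[-seq_len(n_burn), , drop = FALSE]
  attr(res, "radius_mm") <- R
  attr(res, "tau0_s") <- tau0
  res
}

#' Resample a kick log into a fixed-rate trajectory
#'
#' Reconstructs the continuous-time positions implied by a kick log by
#' glide interpolation within each kick ([glide_position()]) and samples
#' them on a regular clock, optionally adding isotropic Gaussian
#' positional noise to emulate tracking error. The result is the format
#' the segmentation pipeline expects.
#'
#' @param kicks Kick log from [simulate_kicks()].
#' @param rate_hz Sampling rate (Hz).
#' @param noise_mm Standard deviation of additive positional noise per
#'   coordinate (mm).
#' @param tau0_s Glide dissipation time (s); defaults to the value
#'   recorded in the kick log.
#' @return Tibble with columns `time_s`, `fish_id`, `x_mm`, `y_mm`.
#' @export
resample_trajectory <- function(kicks, rate_hz = 50, noise_mm = 0,
                                tau0_s = attr(kicks, "tau0_s")) {
  need_cols(kicks, c("t_s", "fish_id", "x_mm", "y_mm", "phi_rad",
                     "l_mm", "tau_s"))
  if (is.null(tau0_s)) stop("`tau0_s` is required", call. = FALSE)
  dt <- 1 / rate_hz
  res <- dplyr::group_split(dplyr::group_by(tibble::as_tibble(kicks), fish_id))
  traj <- purrr::map(res, function(k) {
    k <- dplyr::arrange(k, t_s)
    t_end <- k$t_s[nrow(k)] + k$tau_s[nrow(k)]
    times <- seq(k$t_s[1], t_end, by = dt)
    seg <- findInterval(times, k$t_s)
    el <- pmin(pmax(times - k$t_s[seg], 0), k$tau_s[seg])
    frac <- glide_fraction(el, k$tau_s[seg], tau0_s)
    tibble::tibble(
      time_s = times,
      fish_id = k$fish_id[1],
      x_mm = k$x_mm[seg] + k$l_mm[seg] * frac * cos(k$phi_rad[seg]),
      y_mm = k$y_mm[seg] + k$l_mm[seg] * frac * sin(k$phi_rad[seg])
    )
  })
  out <- dplyr::bind_rows(traj)
  if (noise_mm > 0) {
    out$x_mm <- out$x_mm + stats::rnorm(nrow(out), 0, noise_mm)
    out$y_mm <- out$y_mm + stats::rnorm(nrow(out), 0, noise_mm)
  }
  attr(out, "radius_mm") <- attr(kicks, "radius_mm")
  attr(out, "rate_hz") <- rate_hz
  out
}
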