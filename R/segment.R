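#' Estimate speed from a fixed-rate trajectory
#'
#' Raw speed is the modulus of the velocity estimated by a centred
#' difference of position over a 0.08 s moving window (4 frames at
#' 50 Hz). The first and last two frames use one-sided differences over
#' the available half-window. The raw series is then smoothed with a
#' degree-3 Savitzky-Golay filter spanning 0.36 s; a centred
#' Savitzky-Golay filter needs an odd frame count, so the span is
#' honoured to the nearest odd number of frames (19 at 50 Hz).
#'
#' @param traj Single-fish trajectory: data frame with columns `time_s`,
#'   `x_mm`, `y_mm`, sampled uniformly.
#' @param rate_hz Sampling rate (Hz).
#' @param window_s Bandwidth of the centred difference (s).
#' @return Tibble with columns `time_s`, `speed_mm_s` (raw) and
#'   `speed_smooth_mm_s`.
#' @export
estimate_speed <- function(traj, rate_hz = 50, window_s = 0.08) {
  need_cols(traj, c("time_s", "x_mm", "y_mm"))
  n <- nrow(traj)
  if (n < 5) stop("need at least 5 samples", call. = FALSE)
  dt <- diff(traj$time_s)
  if (any(abs(dt - 1 / rate_hz) > 1e-4 / rate_hz)) {
    stop("trajectory is not uniformly sampled at `rate_hz`", call. = FALSE)
  }
  half <- max(1L, round(rate_hz * window_s / 2))
  idx <- seq_len(n)
  lo <- pmax(idx - half, 1L)
  hi <- pmin(idx + half, n)
  span <- (hi - lo) / rate_hz
  v <- sqrt((traj$x_mm[hi] - traj$x_mm[lo])^2 +
              (traj$y_mm[hi] - traj$y_mm[lo])^2) / span
  out <- tibble::tibble(time_s = traj$time_s, speed_mm_s = v)
  smooth_speed(out, rate_hz = rate_hz)
}

#' Smooth a raw speed series with a Savitzky-Golay filter
#'
#' @param speed Data frame with columns `time_s`, `speed_mm_s`.
#' @param rate_hz Sampling rate (Hz).
#' @param span_s Filter window span (s); rounded to the nearest odd
#'   frame count.
#' @param degree Polynomial degree of the filter.
#' @return The input tibble with column `speed_smooth_mm_s` added (or
#'   replaced).
#' @export
smooth_speed <- function(speed, rate_hz = 50, span_s = 0.36, degree = 3) {
  need_cols(speed, c("time_s", "speed_mm_s"))
  frames <- round(span_s * rate_hz)
  if (frames %% 2 == 0) frames <- frames + 1
  if (nrow(speed) < frames) {
    stop("series shorter than the smoothing window", call. = FALSE)
  }
  sm <- signal::sgolayfilt(speed$speed_mm_s, p = degree, n = frames)
  out <- tibble::as_tibble(speed)
  out$speed_smooth_mm_s <- sm
  out
}

#' Detect kick onsets from a smoothed speed series
#'
#' Samples are classified as accelerating where the forward difference
#' of the smoothed speed is positive (exact zeros attach to the
#' preceding run). Consecutive accelerations separated by a deceleration
#' shorter than 0.08 s are merged, then accelerations shorter than
#' 0.08 s are discarded as too brief for a body motion. Kick onsets are
#' the first samples of the surviving acceleration runs; onsets within
#' the boundary frames (where the speed estimate is one-sided) are never
#' reported.
#'
#' Because the smoothing window (0.36 s) is wide compared with the
#' speed rise of a burst, the first accelerating sample of the smoothed
#' series systematically precedes the true burst by several frames.
#' With `refine = TRUE` (the default) each onset is therefore moved to
#' the minimum of the *raw* speed within `refine_window_s` of the
#' smoothed acceleration start, which centres the onset on the actual
#' speed minimum.
#'
#' @param speed Output of [estimate_speed()] (needs
#'   `speed_smooth_mm_s`; and `speed_mm_s` when `refine = TRUE`).
#' @param rate_hz Sampling rate (Hz).
#' @param min_run_s Minimum duration of a phase (s) used by both the
#'   merge and the discard rules.
#' @param edge_frames Number of frames at each boundary excluded from
#'   onset detection.
#' @param refine Move each onset to the raw-speed minimum nearby?
#' @param refine_window_s Half-width of the refinement search (s).
#' @return Numeric vector of kick onset times (s), strictly increasing.
#' @export
classify_kicks <- function(speed, rate_hz = 50, min_run_s = 0.08,
                           edge_frames = 9, refine = TRUE,
                           refine_window_s = 0.12) {
  need_cols(speed, c("time_s", "speed_smooth_mm_s"))
  n <- nrow(speed)
  if (n < 3) return(numeric())
  d <- diff(speed$speed_smooth_mm_s)
  lab <- sign(d)
  # zeros continue the previous phase; a leading zero run is decelerating
  for (i in seq_along(lab)) {
    if (lab[i] == 0) lab[i] <- if (i == 1) -1 else lab[i - 1]
  }
  min_frames <- ceiling(min_run_s * rate_hz)   # run shorter than this merges
  r <- rle(lab)
  # merge: deceleration shorter than min_run_s flanked by accelerations
  if (length(r$lengths) >= 3) {
    for (k in 2:(length(r$lengths) - 1)) {
      if (r$values[k] < 0 && r$lengths[k] * (1 / rate_hz) < min_run_s &&
          r$values[k - 1] > 0 && r$values[k + 1] > 0) {
        r$values[k] <- 1
      }
    }
  }
  lab <- inverse.rle(r)
  r <- rle(lab)
  # discard: acceleration shorter than min_run_s is no kick
  short <- r$values > 0 & r$lengths * (1 / rate_hz) < min_run_s
  r$values[short] <- -1
  lab <- inverse.rle(r)
  r <- rle(lab)
  starts <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  # the forward difference at sample i compares i to i+1; the first
  # sample faster than its predecessor (i + 1) opens the acceleration
  onset_idx <- starts[r$values > 0] + 1L
  if (refine && "speed_mm_s" %in% names(speed)) {
    half <- round(refine_window_s * rate_hz)
    # the centred-difference raw speed leads the true minimum by half
    # its bandwidth; compensate after locating the raw minimum
    lag <- as.integer(round(0.08 * rate_hz / 2))
    onset_idx <- vapply(onset_idx, function(i0) {
      win <- max(1L, i0 - half):min(n, i0 + half)
      min(win[which.min(speed$speed_mm_s[win])] + lag, n)[1L]
    }, integer(1))
    onset_idx <- sort(unique(onset_idx))
    # refinement must not defeat the discard rule's minimum spacing
    min_gap <- ceiling(min_run_s * rate_hz)
    keep <- rep(TRUE, length(onset_idx))
    last <- -Inf
    for (ii in seq_along(onset_idx)) {
      if (onset_idx[ii] - last < min_gap) keep[ii] <- FALSE
      else last <- onset_idx[ii]
    }
    onset_idx <- onset_idx[keep]
  }
  onset_idx <- onset_idx[onset_idx > edge_frames & onset_idx <= n - edge_frames]
  speed$time_s[onset_idx]
}

#' Label swimming activity and cut the record into sections
#'
#' The record is classified frame by frame from the speed in body
#' lengths per second: intervals where the (fastest) fish swims slower
#' than `u_min` body lengths per second for more than `tau_stop`
#' seconds are *stopping*; shorter slow intervals are *pausing*; the
#' rest is *swimming*. Stopping frames are removed and the remaining
#' active record is cut into disjoint sections of exactly `tau_section`
#' seconds (the trailing remainder is dropped), so that long recordings
#' contribute comparable, bounded blocks to the statistics.
#'
#' @param speed Data frame with `time_s` and `speed_mm_s`; for a group,
#'   supply the per-frame maximum speed across fish.
#' @param bl_mm Body length (mm).
#' @param u_min Slow-swimming threshold (body lengths per second).
#' @param tau_stop Maximum duration of a pause (s).
#' @param tau_section Section length (s).
#' @param rate_hz Sampling rate (Hz).
#' @return The input tibble with columns `activity` (factor: swimming,
#'   pausing, stopping) and `section_id` (integer, `NA` for frames not
#'   assigned to a section) added.
#' @export
activity_bouts <- function(speed, bl_mm, u_min = 0.5, tau_stop = 4,
                           tau_section = 120, rate_hz = 50) {
  need_cols(speed, c("time_s", "speed_mm_s"))
  if (!is.numeric(bl_mm) || bl_mm <= 0) {
    stop("`bl_mm` must be positive", call. = FALSE)
  }
  slow <- speed$speed_mm_s / bl_mm < u_min
  r <- rle(slow)
  dur <- r$lengths / rate_hz
  phase <- ifelse(!r$values, "swimming",
                  ifelse(dur > tau_stop, "stopping", "pausing"))
  activity <- inverse.rle(list(lengths = r$lengths, values = phase))
  out <- tibble::as_tibble(speed)
  out$activity <- factor(activity, levels = c("swimming", "pausing", "stopping"))
  active <- which(out$activity != "stopping")
  sec_frames <- round(tau_section * rate_hz)
  section <- rep(NA_integer_, nrow(out))
  n_sec <- length(active) %/% sec_frames
  if (n_sec > 0) {
    take <- active[seq_len(n_sec * sec_frames)]
    section[take] <- rep(seq_len(n_sec), each = sec_frames)
  }
  out$section_id <- section
  out
}

#' Build a kick table from a trajectory and its kick onsets
#'
#' Reduces a trajectory to one row per kick: length `l` is the Euclidean
#' distance between consecutive onset positions, duration `tau` the time
#' between onsets, heading `phi` the direction of the inter-onset
#' vector, and the heading change `dphi` the wrapped difference to the
#' next kick's heading (the last kick, having no successor heading, is
#' dropped). The top speed `v` is the maximum smoothed speed between the
#' onsets, and the wall frame is evaluated at the onset position with
#' the kick heading. With a partner present, the pair frame is evaluated
#' at the onset using the partner's interpolated position and its
#' current kick-segment heading.
#'
#' @param traj Single-fish trajectory (`time_s`, `x_mm`, `y_mm`).
#' @param onsets Kick onset times from [classify_kicks()].
#' @param radius_mm Arena radius (mm).
#' @param speed Optional speed series (from [estimate_speed()]) used for
#'   the top-speed column.
#' @param partner_traj,partner_onsets Optional partner trajectory and
#'   onset times for two-fish records.
#' @return Tibble in kick-table format: `t_s`, `x_mm`, `y_mm`,
#'   `phi_rad`, `dphi_rad`, `v_peak_mm_s`, `l_mm`, `tau_s`, `r_w_mm`,
#'   `theta_w_rad` and, for pairs, `d_mm`, `psi_rad`, `dphi_pair_rad`.
#'   Empty when fewer than 3 onsets are supplied.
#' @export
kick_table <- function(traj, onsets, radius_mm, speed = NULL,
                       partner_traj = NULL, partner_onsets = NULL) {
  check_radius(radius_mm)
  need_cols(traj, c("time_s", "x_mm", "y_mm"))
  if (length(onsets) < 3) {
    return(tibble::tibble(
      t_s = numeric(), x_mm = numeric(), y_mm = numeric(),
      phi_rad = numeric(), dphi_rad = numeric(), v_peak_mm_s = numeric(),
      l_mm = numeric(), tau_s = numeric(), r_w_mm = numeric(),
      theta_w_rad = numeric()
    ))
  }
  onsets <- sort(onsets)
  ox <- stats::approx(traj$time_s, traj$x_mm, onsets)$y
  oy <- stats::approx(traj$time_s, traj$y_mm, onsets)$y
  m <- length(onsets)
  phi <- atan2(diff(oy), diff(ox))
  k <- tibble::tibble(
    t_s = onsets[-m],
    x_mm = ox[-m], y_mm = oy[-m],
    phi_rad = phi,
    dphi_rad = c(wrap_angle(diff(phi)), NA_real_),
    l_mm = sqrt(diff(ox)^2 + diff(oy)^2),
    tau_s = diff(onsets)
  )
  if (!is.null(speed)) {
    need_cols(speed, c("time_s", "speed_smooth_mm_s"))
    k$v_peak_mm_s <- vapply(seq_len(m - 1), function(i) {
      sel <- speed$time_s >= onsets[i] & speed$time_s < onsets[i + 1]
      if (any(sel)) max(speed$speed_smooth_mm_s[sel]) else NA_real_
    }, numeric(1))
  } else {
    k$v_peak_mm_s <- NA_real_
  }
  k <- wall_frame(k, radius_mm)
  if (!is.null(partner_traj)) {
    need_cols(partner_traj, c("time_s", "x_mm", "y_mm"))
    k$partner_x_mm <- stats::approx(partner_traj$time_s,
                                    partner_traj$x_mm, k$t_s)$y
    k$partner_y_mm <- stats::approx(partner_traj$time_s,
                                    partner_traj$y_mm, k$t_s)$y
    if (is.null(partner_onsets) || length(partner_onsets) < 2) {
      stop("`partner_onsets` (>= 2) are required with `partner_traj`",
           call. = FALSE)
    }
    partner_onsets <- sort(partner_onsets)
    px <- stats::approx(partner_traj$time_s, partner_traj$x_mm,
                        partner_onsets)$y
    py <- stats::approx(partner_traj$time_s, partner_traj$y_mm,
                        partner_onsets)$y
    pphi <- atan2(diff(py), diff(px))
    seg <- pmin(pmax(findInterval(k$t_s, partner_onsets), 1), length(pphi))
    k$partner_phi_rad <- pphi[seg]
    k <- pair_frame(k)
    k <- dplyr::select(k, -dplyr::starts_with("partner_"))
  }
  k <- dplyr::relocate(k, t_s, x_mm, y_mm, phi_rad, dphi_rad,
                       v_peak_mm_s, l_mm, tau_s)
  attr(k, "radius_mm") <- radius_mm
  k
}

#' Segment one or two tracked fish into a kick table
#'
#' Convenience pipeline chaining [estimate_speed()], [classify_kicks()]
#' and [kick_table()] per fish; with two fish each fish's kick table is
#' completed with the pair frame relative to the other. Activity
#' selection ([activity_bouts()]) is available separately and not
#' applied here.
#'
#' @param traj Trajectory with columns `time_s`, `fish_id`, `x_mm`,
#'   `y_mm`.
#' @param radius_mm Arena radius (mm); defaults to the trajectory
#'   attribute when present.
#' @param rate_hz Sampling rate (Hz).
#' @return Kick-table tibble with a `fish_id` column.
#' @export
segment_trajectory <- function(traj, radius_mm = attr(traj, "radius_mm"),
                               rate_hz = 50) {
  need_cols(traj, c("time_s", "fish_id", "x_mm", "y_mm"))
  check_radius(radius_mm)
  ids <- sort(unique(traj$fish_id))
  if (!length(ids) %in% c(1L, 2L)) {
    stop("`traj` must contain 1 or 2 fish", call. = FALSE)
  }
  per <- lapply(ids, function(id) {
    tr <- traj[traj$fish_id == id, , drop = FALSE]
    sp <- estimate_speed(tr, rate_hz = rate_hz)
    list(traj = tr, speed = sp,
         onsets = classify_kicks(sp, rate_hz = rate_hz))
  })
  names(per) <- as.character(ids)
  tabs <- lapply(seq_along(ids), function(j) {
    p <- per[[j]]
    if (length(ids) == 2L) {
      q <- per[[3L - j]]
      k <- kick_table(p$traj, p$onsets, radius_mm, speed = p$speed,
                      partner_traj = q$traj, partner_onsets = q$onsets)
    } else {
      k <- kick_table(p$traj, p$onsets, radius_mm, speed = p$speed)
    }
    k$fish_id <- ids[j]
    k
  })
  out <- dplyr::bind_rows(tabs)
  attr(out, "radius_mm") <- radius_mm
  out
}
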