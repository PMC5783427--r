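#' Wall-signed heading change
#'
#' The signed turn `dphi_plus = dphi * sign(theta_w)` is positive when
#' the fish turns away from the wall and negative when it turns toward
#' it, whichever side the wall is on. It is even under mirroring, so its
#' distribution is unchanged by symmetrization. Rows with `theta_w = 0`
#' have no defined side and get `NA`.
#'
#' @param kicks Kick table with `dphi_rad` and `theta_w_rad`.
#' @return The input tibble with column `dphi_plus_rad` added.
#' @export
signed_turn <- function(kicks) {
  need_cols(kicks, c("dphi_rad", "theta_w_rad"))
  s <- sign(kicks$theta_w_rad)
  out <- tibble::as_tibble(kicks)
  out$dphi_plus_rad <- ifelse(s == 0, NA_real_, kicks$dphi_rad * s)
  out
}

#' Geometrical leader and follower of a fish pair
#'
#' At any instant the geometrical leader is the fish with the larger
#' absolute viewing angle `|psi|` of its partner -- the one that would
#' have to turn the most to face it (typically the fish in front). Exact
#' ties and degenerate frames (coincident positions) are unresolved.
#'
#' @param poses Data frame with two rows per time: columns `time_s`,
#'   `fish_id`, `x_mm`, `y_mm`, `phi_rad`.
#' @return Tibble with one row per time: `time_s`, `leader_id`,
#'   `follower_id` (both `NA` when unresolved).
#' @export
pair_roles <- function(poses) {
  need_cols(poses, c("time_s", "fish_id", "x_mm", "y_mm", "phi_rad"))
  ids <- sort(unique(poses$fish_id))
  if (length(ids) != 2) stop("`poses` must contain exactly 2 fish",
                             call. = FALSE)
  a <- poses[poses$fish_id == ids[1], , drop = FALSE]
  b <- poses[poses$fish_id == ids[2], , drop = FALSE]
  common <- intersect(a$time_s, b$time_s)
  a <- a[match(common, a$time_s), ]
  b <- b[match(common, b$time_s), ]
  psi_of <- function(p, q) {
    d <- sqrt((q$x_mm - p$x_mm)^2 + (q$y_mm - p$y_mm)^2)
    ifelse(d == 0, NA_real_,
           abs(wrap_angle(atan2(q$y_mm - p$y_mm, q$x_mm - p$x_mm) -
                            p$phi_rad)))
  }
  pa <- psi_of(a, b)
  pb <- psi_of(b, a)
  leader <- dplyr::case_when(
    is.na(pa) | is.na(pb) | pa == pb ~ NA_integer_,
    pa > pb ~ as.integer(ids[1]),
    TRUE ~ as.integer(ids[2])
  )
  tibble::tibble(
    time_s = common,
    leader_id = leader,
    follower_id = ifelse(is.na(leader), NA_integer_,
                         as.integer(ids[1]) + as.integer(ids[2]) - leader)
  )
}

#' Summary distributions of a kick table
#'
#' Computes normalized histograms (densities integrating to 1) and
#' scalar summaries (mean, mode, sd) of the per-kick quantities used to
#' compare model and experiment: duration `tau`, length `l`, wall
#' distance `r_w`, wall angle `theta_w`, the wall-signed turn
#' `dphi_plus`, and for two-fish tables also the pair-frame variables
#' `d`, `psi` and `dphi_pair`. Angular variables use `n_angle` bins over
#' `(-pi, pi]`; `r_w` uses `n_radial` bins over `[0, R]`; unbounded
#' positive variables use `n_radial` bins over their observed range.
#'
#' @param kicks Kick table.
#' @param radius_mm Arena radius (mm); defaults to the kick-table
#'   attribute.
#' @param n_angle,n_radial Bin counts.
#' @return List with `pdf` (tibble: `variable`, `bin_center`,
#'   `density`) and `summary` (tibble: `variable`, `mean`, `mode`,
#'   `sd`, `bin_width`).
#' @export
kick_statistics <- function(kicks, radius_mm = attr(kicks, "radius_mm"),
                            n_angle = 60, n_radial = 40) {
  if (nrow(kicks) == 0) stop("empty kick table", call. = FALSE)
  check_radius(radius_mm)
  k <- signed_turn(tibble::as_tibble(kicks))
  spec <- list(
    tau_s = list(x = k$tau_s, edges = NULL),
    l_mm = list(x = k$l_mm, edges = NULL),
    r_w_mm = list(x = k$r_w_mm,
                  edges = seq(0, radius_mm, length.out = n_radial + 1)),
    theta_w_rad = list(x = k$theta_w_rad,
                       edges = seq(-pi, pi, length.out = n_angle + 1)),
    dphi_plus_rad = list(x = k$dphi_plus_rad,
                         edges = seq(-pi, pi, length.out = n_angle + 1))
  )
  if ("d_mm" %in% names(k)) {
    spec$d_mm <- list(x = k$d_mm, edges = NULL)
    spec$psi_rad <- list(x = k$psi_rad,
                         edges = seq(-pi, pi, length.out = n_angle + 1))
    spec$dphi_pair_rad <- list(x = k$dphi_pair_rad,
                               edges = seq(-pi, pi, length.out = n_angle + 1))
  }
  pdf <- list()
  summary <- list()
  for (nm in names(spec)) {
    x <- spec[[nm]]$x
    x <- x[is.finite(x)]
    if (!length(x)) next
    edges <- spec[[nm]]$edges
    if (is.null(edges)) {
      edges <- seq(0, max(x) * 1.001, length.out = n_radial + 1)
    }
    h <- graphics::hist(x, breaks = edges, plot = FALSE)
    pdf[[nm]] <- tibble::tibble(variable = nm, bin_center = h$mids,
                                density = h$density)
    summary[[nm]] <- tibble::tibble(
      variable = nm, mean = mean(x), mode = h$mids[which.max(h$density)],
      sd = stats::sd(x), bin_width = diff(edges[1:2])
    )
  }
  list(pdf = dplyr::bind_rows(pdf), summary = dplyr::bind_rows(summary))
}

#' Mean speed decay after a kick
#'
#' Averages the instantaneous glide speed `v_n * exp(-t / tau0)` across
#' kicks as a function of time since kick onset, sampled on a regular
#' clock, optionally corrupted by multiplicative measurement noise.
#' Only kicks lasting at least `t_max_s` enter the average: without
#' this conditioning the set of kicks still gliding at `t` changes with
#' `t` (long kicks come from slower, longer draws), which distorts the
#' apparent decay away from the true dissipation time.
#'
#' @param kicks Kick table with `v_peak_mm_s` and `tau_s`.
#' @param tau0_s Glide dissipation time used to generate the decay (s);
#'   defaults to the kick-log attribute.
#' @param rate_hz Sampling rate (Hz).
#' @param noise_cv Coefficient of variation of multiplicative speed
#'   noise (e.g. `0.05` for 5%).
#' @param t_max_s Length of the profile (s).
#' @return Tibble with `time_s`, `speed_mm_s` (mean across kicks) and
#'   `weight` (number of kicks averaged), ready for
#'   [fit_exponential_decay()].
#' @export
speed_decay_profile <- function(kicks, tau0_s = attr(kicks, "tau0_s"),
                                rate_hz = 50, noise_cv = 0,
                                t_max_s = 0.4) {
  need_cols(kicks, c("v_peak_mm_s", "tau_s"))
  if (is.null(tau0_s)) stop("`tau0_s` is required", call. = FALSE)
  keep <- kicks$tau_s >= t_max_s & is.finite(kicks$v_peak_mm_s)
  v <- kicks$v_peak_mm_s[keep]
  if (length(v) < 5) stop("too few kicks outlast `t_max_s`", call. = FALSE)
  t <- seq(0, t_max_s, by = 1 / rate_hz)
  sp <- outer(v, exp(-t / tau0_s))
  if (noise_cv > 0) {
    sp <- sp * matrix(stats::rnorm(length(sp), 1, noise_cv), nrow(sp))
  }
  tibble::tibble(
    time_s = t,
    speed_mm_s = colMeans(sp),
    weight = length(v)
  )
}

#' L1 distance between two binned densities
#'
#' Compares two normalized histograms on the same mesh by the integral
#' of the absolute density difference (0 for identical distributions, 2
#' for disjoint supports) and by the maximum per-bin discrepancy.
#'
#' @param a,b Data frames with columns `bin_center` and `density` on
#'   identical bins.
#' @return List with elements `l1` and `max_bin`.
#' @export
compare_distributions <- function(a, b) {
  need_cols(a, c("bin_center", "density"))
  need_cols(b, c("bin_center", "density"))
  if (nrow(a) != nrow(b) ||
      any(abs(a$bin_center - b$bin_center) > 1e-8)) {
    stop("binning mismatch between `a` and `b`", call. = FALSE)
  }
  width <- diff(a$bin_center[1:2])
  list(
    l1 = sum(abs(a$density - b$density)) * width,
    max_bin = max(abs(a$density - b$density))
  )
}
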