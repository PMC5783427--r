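make_linear_traj <- function(speed = 100, n = 200, rate = 50) {
  t <- (0:(n - 1)) / rate
  tibble::tibble(time_s = t, x_mm = speed * t, y_mm = 0)
}

test_that("speed estimation matches known motion profiles", {
  # uniform linear motion
  sp <- estimate_speed(make_linear_traj(100))
  expect_equal(sp$speed_mm_s, rep(100, 200), tolerance = 1e-9)
  # stationary fish
  sp0 <- estimate_speed(tibble::tibble(time_s = (0:99) / 50,
                                       x_mm = 5, y_mm = -3))
  expect_equal(sp0$speed_mm_s, rep(0, 100))
  # exponential glide: raw speed tracks v e^(-t/tau0) to within the
  # discretization error of the centred difference
  v <- 200; tau0 <- 0.8; tau <- 1.2
  l <- v * tau0 * (1 - exp(-tau / tau0))
  t <- seq(0, tau, by = 0.02)
  g <- glide_position(0, 0, 0, l, tau, t, tau0)
  sp2 <- estimate_speed(tibble::tibble(time_s = t, x_mm = g$x_mm,
                                       y_mm = g$y_mm))
  interior <- 5:(length(t) - 5)
  expect_equal(sp2$speed_mm_s[interior], v * exp(-t[interior] / tau0),
               tolerance = 2e-3)
  expect_error(estimate_speed(make_linear_traj(n = 4)), "5 samples")
  bad <- make_linear_traj(); bad$time_s[10] <- bad$time_s[10] + 0.005
  expect_error(estimate_speed(bad), "uniform")
})

test_that("Savitzky-Golay smoothing reproduces cubics and reduces noise", {
  t <- (0:299) / 50
  cubic <- 50 + 20 * t - 6 * t^2 + 0.8 * t^3
  sm <- smooth_speed(tibble::tibble(time_s = t, speed_mm_s = cubic))
  interior <- 12:288
  expect_equal(sm$speed_smooth_mm_s[interior], cubic[interior],
               tolerance = 1e-9)
  # constant series unchanged
  smc <- smooth_speed(tibble::tibble(time_s = t, speed_mm_s = rep(80, 300)))
  expect_equal(smc$speed_smooth_mm_s, rep(80, 300), tolerance = 1e-9)
  # white noise on an exponential decay is attenuated
  set.seed(6)
  decay <- 200 * exp(-t / 0.8)
  noisy <- decay + rnorm(300, 0, 5)
  smn <- smooth_speed(tibble::tibble(time_s = t, speed_mm_s = noisy))
  expect_lt(sd((smn$speed_smooth_mm_s - decay)[interior]),
            sd((noisy - decay)[interior]))
  expect_error(smooth_speed(tibble::tibble(time_s = t[1:10],
                                           speed_mm_s = rep(1, 10))),
               "window")
})

test_that("kick classification applies the merge and discard rules", {
  rate <- 50
  t <- (0:199) / rate
  # monotone decreasing speed: no kicks
  sp <- tibble::tibble(time_s = t, speed_smooth_mm_s = 300 - t * 50)
  expect_length(classify_kicks(sp, refine = FALSE), 0)
  # two accelerations separated by a 0.06 s dip: merged into one kick
  s <- rep(100, 200)
  s[30:60] <- 100 + (1:31) * 5          # first acceleration
  s[61:63] <- s[60] - (1:3) * 2         # 0.06 s deceleration
  s[64:90] <- s[63] + (1:27) * 5        # second acceleration
  s[91:200] <- s[90] - (1:110) * 1.5
  sp2 <- tibble::tibble(time_s = t, speed_smooth_mm_s = s)
  on <- classify_kicks(sp2, refine = FALSE)
  expect_length(on, 1)
  expect_lt(abs(on - t[30]), 0.031)
  # a lone 0.06 s acceleration is discarded as too brief
  s3 <- 400 - t * 50
  s3[100:102] <- s3[100] + (1:3) * 10
  sp3 <- tibble::tibble(time_s = t, speed_smooth_mm_s = s3)
  expect_length(classify_kicks(sp3, refine = FALSE), 0)
})

test_that("activity labelling separates swimming, pausing and stopping", {
  rate <- 50; bl <- 30
  t <- (0:(rate * 300 - 1)) / rate
  v <- rep(100, length(t))
  sp <- tibble::tibble(time_s = t, speed_mm_s = v)
  lab <- activity_bouts(sp, bl_mm = bl, rate_hz = rate)
  expect_true(all(lab$activity == "swimming"))
  # 300 s of active swimming: floor(300/120) = 2 full sections
  expect_equal(max(lab$section_id, na.rm = TRUE), 2)
  expect_equal(sum(!is.na(lab$section_id)), 2 * 120 * rate)
  # a 5 s slow interval is stopping (removed), a 3 s one is pausing
  v2 <- v; v2[t >= 50 & t < 55] <- 10; v2[t >= 100 & t < 103] <- 10
  lab2 <- activity_bouts(tibble::tibble(time_s = t, speed_mm_s = v2),
                         bl_mm = bl, rate_hz = rate)
  expect_true(all(lab2$activity[t >= 50.1 & t < 54.9] == "stopping"))
  expect_true(all(lab2$activity[t >= 100.1 & t < 102.9] == "pausing"))
  expect_true(all(is.na(lab2$section_id[lab2$activity == "stopping"])))
  expect_error(activity_bouts(sp, bl_mm = -1), "positive")
})

test_that("kick tables reduce trajectories to per-kick variables", {
  # two onsets 100 mm and 0.5 s apart, plus a third for the heading change
  tr <- make_linear_traj(200, n = 200)
  on <- c(0.5, 1.0, 1.5)
  kt <- kick_table(tr, on, radius_mm = 5000)
  expect_equal(nrow(kt), 2)
  expect_equal(kt$l_mm, c(100, 100))
  expect_equal(kt$tau_s, c(0.5, 0.5))
  # collinear onsets: no heading change
  expect_equal(kt$dphi_rad[1], 0)
  expect_true(is.na(kt$dphi_rad[2]))
  # fewer than 3 onsets: empty table
  expect_equal(nrow(kick_table(tr, c(0.5, 1), radius_mm = 5000)), 0)
})

test_that("segmenting a mirrored trajectory yields the mirrored kick
           table", {
  k <- sim_single_small()[1:600, ]
  attr(k, "tau0_s") <- 0.8
  tr <- resample_trajectory(k, rate_hz = 50)
  tr$fish_id <- 1L
  trm <- dplyr::mutate(tr, y_mm = -y_mm)
  kt <- segment_trajectory(tr, radius_mm = 353)
  ktm <- segment_trajectory(trm, radius_mm = 353)
  expect_equal(ktm$t_s, kt$t_s)
  expect_equal(ktm$l_mm, kt$l_mm)
  expect_equal(ktm$theta_w_rad, -kt$theta_w_rad)
  expect_equal(ktm$dphi_rad, -kt$dphi_rad)
})

test_that("closed loop: segmentation recovers the generated kicks at
           its measured fidelity", {
  k <- cached("seg_loop_kicks",
              simulate_kicks(2000, preset_params(1, 250),
                             seed = 7, n_burn = 100))
  set.seed(9)
  tr <- resample_trajectory(k, rate_hz = 50, noise_mm = 0.5)
  tr$fish_id <- 1L
  kt <- segment_trajectory(tr, radius_mm = 250)
  # onsets strictly increasing and separated by at least 0.08 s
  expect_true(all(diff(kt$t_s) >= 0.08 - 1e-9))
  # recovered kick count: the smoothing window merges kicks that follow
  # short kicks, so recovery is bounded away from 1 but stable
  expect_gt(nrow(kt) / nrow(k), 0.72)
  expect_lt(nrow(kt) / nrow(k), 1.02)
  # onset timing of recovered kicks is frame-accurate
  err <- vapply(kt$t_s, function(t) min(abs(k$t_s - t)), numeric(1))
  expect_lt(median(err), 0.03)
  expect_lt(unname(quantile(err, 0.9)), 0.12)
  # matched consecutive kicks reproduce the generated kinematics
  mi <- vapply(kt$t_s, function(t) {
    i <- which.min(abs(k$t_s - t))
    if (abs(k$t_s[i] - t) < 0.06) i else NA_integer_
  }, integer(1))
  ok <- which(!is.na(mi) & c(diff(mi) == 1L, FALSE))
  expect_gt(length(ok), 0.5 * nrow(kt))
  expect_lt(median(abs(kt$l_mm[ok] / k$l_mm[mi[ok]] - 1)), 0.05)
  expect_lt(median(abs(kt$tau_s[ok] - k$tau_s[mi[ok]])), 0.025)
  expect_lt(median(abs(wrap_angle(kt$dphi_rad[ok] -
                                    k$dphi_rad[mi[ok] + 1]))), 0.02)
  # aggregate statistics: merges bias lengths and durations upward by
  # the inverse recovery rate; the turn-angle spread is less affected
  expect_lt(abs(mean(kt$tau_s) / mean(k$tau_s) - 1), 0.35)
  expect_lt(abs(mean(kt$l_mm) / mean(k$l_mm) - 1), 0.35)
  expect_lt(abs(sd(kt$dphi_rad, na.rm = TRUE) / sd(k$dphi_rad) - 1), 0.3)
})
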