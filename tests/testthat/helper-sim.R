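# Shared simulation fixtures, built once per test run.
sim_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, sim_cache)) assign(name, force(expr), sim_cache)
  get(name, sim_cache)
}

sim_single_small <- function() {
  cached("single_small",
         simulate_kicks(4000, preset_params(1, 353), preset_kinematics(1),
                        seed = 101, n_burn = 200))
}

sim_pair_small <- function() {
  cached("pair_small",
         simulate_kicks(6000, preset_params(2, 250), preset_kinematics(2),
                        n_fish = 2, seed = 202, n_burn = 200))
}

# reconstruct both fish poses (position + segment heading) on a regular
# time grid from a two-fish kick log
pair_pose_grid <- function(kicks, by_s = 0.5) {
  tau0 <- attr(kicks, "tau0_s")
  per <- split(kicks, kicks$fish_id)
  t0 <- max(vapply(per, function(k) min(k$t_s), 0))
  t1 <- min(vapply(per, function(k) max(k$t_s), 0))
  tt <- seq(ceiling(t0 / by_s) * by_s, t1, by = by_s)
  out <- lapply(per, function(k) {
    k <- k[order(k$t_s), ]
    seg <- findInterval(tt, k$t_s)
    el <- pmin(pmax(tt - k$t_s[seg], 0), k$tau_s[seg])
    fr <- (1 - exp(-el / tau0)) / (1 - exp(-k$tau_s[seg] / tau0))
    tibble::tibble(
      time_s = tt, fish_id = k$fish_id[1],
      x_mm = k$x_mm[seg] + k$l_mm[seg] * fr * cos(k$phi_rad[seg]),
      y_mm = k$y_mm[seg] + k$l_mm[seg] * fr * sin(k$phi_rad[seg]),
      phi_rad = k$phi_rad[seg]
    )
  })
  dplyr::bind_rows(out)
}
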