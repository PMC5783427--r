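test_that("symmetrization doubles the data with exact antisymmetry", {
  k <- tibble::tibble(theta_w_rad = c(0.4, -1.1), psi_rad = c(0.2, 0.9),
                      dphi_pair_rad = c(-0.5, 0.1), dphi_rad = c(0.3, -0.2),
                      r_w_mm = c(30, 80), d_mm = c(60, 120))
  s <- symmetrize_kicks(k)
  expect_equal(nrow(s), 4)
  expect_equal(sum(s$theta_w_rad), 0)
  expect_equal(sum(s$dphi_rad), 0)
  expect_equal(sum(s$psi_rad), 0)
  # empty in, empty out
  expect_equal(nrow(symmetrize_kicks(k[0, ])), 0)
})

test_that("wall-response binning counts and averages per cell", {
  one <- tibble::tibble(r_w_mm = 10, theta_w_rad = 0.5, dphi_rad = 0.2)
  b <- bin_wall_response(one, radius_mm = 250, n_r = 10, n_theta = 6)
  expect_equal(sum(b$eps), 1)
  expect_equal(sum(b$eps > 0), 1)
  expect_equal(b$dphi[b$eps > 0], 0.2)
  # a mirrored pair lands in mirrored cells with opposite means
  pair <- symmetrize_kicks(one)
  b2 <- bin_wall_response(pair, radius_mm = 250, n_r = 10, n_theta = 6)
  hit <- which(b2$eps > 0, arr.ind = TRUE)
  expect_equal(nrow(hit), 2)
  expect_equal(hit[1, "row"], hit[2, "row"], ignore_attr = TRUE)
  expect_equal(sort(hit[, "col"]), sort(7 - hit[, "col"]),
               ignore_attr = TRUE)
  expect_equal(sum(b2$dphi), 0)
  # conservation over a large synthetic table
  k <- sim_single_small()
  s <- symmetrize_kicks(k)
  b3 <- bin_wall_response(s, radius_mm = 353)
  expect_equal(b3$n_kept + b3$n_dropped, nrow(s))
  expect_equal(b3$n_dropped, sum(is.na(s$dphi_rad)))
})

test_that("pair-response binning applies the wall cutoff", {
  k <- tibble::tibble(
    r_w_mm = c(50, 61, 100), d_mm = c(80, 80, 300),
    psi_rad = c(0.1, 0.1, 0.1), dphi_pair_rad = c(0.2, 0.2, 0.2),
    dphi_rad = c(0.05, 0.05, 0.05)
  )
  b <- bin_pair_response(k, wall_cutoff_mm = 60)
  # r_w = 50 excluded by the cutoff; d = 300 outside the mesh
  expect_equal(sum(b$eps), 1)
  expect_equal(b$n_dropped, 2)
})

test_that("the 2-factor fixed point recovers an exact product", {
  I <- 40; J <- 30
  r <- seq(0 + 353 / 80, 353 - 353 / 80, length.out = I)
  th <- seq(-pi + pi / J, pi - pi / J, length.out = J)
  f_true <- 0.25 * exp(-(r / 60)^2)
  O_true <- shape_odd(th, c(0, 0.7))
  set.seed(11)
  eps <- matrix(rpois(I * J, 20), I, J)
  b <- make_binned_wall(eps, outer(f_true, O_true))
  fx <- factorize_wall(b)
  expect_true(fx$converged)
  f_got <- factor_table(fx, "f_wall")$value
  O_got <- factor_table(fx, "O_wall")$value
  # up to the discrete-vs-continuous normalization convention
  expect_lt(rel_l2(f_got, f_true), 1e-5)
  expect_lt(rel_l2(O_got, O_true), 1e-5)
  # the product itself is convention-free
  expect_equal(outer(f_got, O_got), outer(f_true, O_true),
               tolerance = 1e-6)
  # removing empty cells leaves the result unchanged (cells are emptied
  # in mirror pairs, as symmetrized data guarantee)
  eps2 <- eps; eps2[, c(3, J + 1 - 3)] <- 0; eps2[17, ] <- 0
  d2 <- outer(f_true, O_true); d2[eps2 == 0] <- 0
  fx2 <- factorize_wall(make_binned_wall(eps2, d2))
  keep_c <- -c(3, J + 1 - 3)
  expect_equal(outer(factor_table(fx2, "f_wall")$value[-17],
                     factor_table(fx2, "O_wall")$value[keep_c]),
               outer(f_true, O_true)[-17, keep_c], tolerance = 1e-6)
  expect_error(factorize_wall(make_binned_wall(matrix(0, I, J),
                                               matrix(0, I, J))),
               "empty")
})

test_that("the damped iteration agrees with a brute-force alternating
           least squares oracle on small meshes", {
  set.seed(12)
  for (rep_i in 1:3) {
    I <- sample(4:6, 1); J <- sample(c(4, 6), 1)
    th <- seq(-pi + pi / J, pi - pi / J, length.out = J)
    eps <- matrix(rpois(I * J, 15) + 1, I, J)
    eps <- eps + eps[, J:1]            # mirror-symmetric counts, as
    # symmetrization guarantees; noisy non-product response
    dphi <- outer(runif(I, -0.2, 0.4), sin(th)) +
      matrix(rnorm(I * J, 0, 0.05), I, J)
    dphi <- (dphi - dphi[, J:1]) / 2   # antisymmetric component only
    fx <- factorize_wall(make_binned_wall(eps, dphi, radius_mm = 250),
                         tol = 1e-12, max_iter = 20000)
    or <- oracle_als_2d(eps, dphi, th, iters = 4000)
    expect_equal(factor_table(fx, "f_wall")$value, or$f,
                 tolerance = 1e-8)
    expect_equal(factor_table(fx, "O_wall")$value, or$O,
                 tolerance = 1e-8)
    expect_equal(min(fx$delta_trace), or$delta, tolerance = 1e-8)
  }
})

test_that("factorization enforces parity, normalization and
           non-increasing error", {
  k <- sim_single_small()
  b <- bin_wall_response(symmetrize_kicks(k), radius_mm = 353)
  fx <- factorize_wall(b)
  O <- factor_table(fx, "O_wall")$value
  expect_equal(O, -rev(O))                       # exact odd parity
  expect_equal(mean(O^2), 1, tolerance = 1e-12)  # unit mean square
  tr <- fx$delta_trace
  late <- tr[-(1:5)]
  expect_true(all(diff(late) <= 1e-10 * late[1]))
  expect_lt(tr[length(tr)], tr[1] + 1e-12)
})

test_that("the 6-function fixed point recovers an exact two-term sum", {
  K <- 12; L <- 10; M <- 10
  d <- seq(10, 270, length.out = K)
  psi <- seq(-pi + pi / L, pi - pi / L, length.out = L)
  dph <- seq(-pi + pi / M, pi - pi / M, length.out = M)
  FA <- 0.15 * attraction_profile(d)
  OA <- shape_odd(psi, c(-0.33))
  EA <- shape_even(dph, c(0.48, -0.31))
  FL <- 0.10 * alignment_profile(d)
  OL <- shape_odd(dph, c(0, 0.30))
  EL <- shape_even(psi, c(0.60, -0.32))
  truth <- outer(FA, outer(OA, EA)) +
    outer(FL, outer(EL, OL))
  set.seed(13)
  eps <- array(rpois(K * L * M, 12) + 1, c(K, L, M))
  fx <- factorize_pair(make_binned_pair(eps, truth), tol = 1e-10,
                       max_iter = 20000)
  expect_true(fx$converged)
  expect_false(fx$degenerate)
  expect_lt(rel_l2(factor_table(fx, "F_att")$value, FA), 1e-4)
  expect_lt(rel_l2(factor_table(fx, "O_att")$value, OA), 1e-4)
  expect_lt(rel_l2(factor_table(fx, "E_att")$value, EA), 1e-4)
  expect_lt(rel_l2(factor_table(fx, "F_ali")$value, FL), 1e-4)
  expect_lt(rel_l2(factor_table(fx, "O_ali")$value, OL), 1e-4)
  expect_lt(rel_l2(factor_table(fx, "E_ali")$value, EL), 1e-4)
  # parity and normalization conventions hold exactly
  for (fn in c("O_att", "O_ali")) {
    v <- factor_table(fx, fn)$value
    expect_equal(v, -rev(v))
    expect_equal(mean(v^2), 1, tolerance = 1e-12)
  }
  for (fn in c("E_att", "E_ali")) {
    v <- factor_table(fx, fn)$value
    expect_equal(v, rev(v))
    expect_equal(mean(v^2), 1, tolerance = 1e-12)
  }
})

test_that("without wall interference the closed loop recovers the
           angular coefficients essentially exactly", {
  # same social dynamics in a very large arena with the wall terms off:
  # isolates the inference from wall leakage past the 2 BL cutoff
  p0 <- model_params(radius_mm = 2000, gamma_r = 0.45, alpha = 0,
                     gamma_w = 0, l_c_mm = 30,
                     gamma_att = 0.30, gamma_ali = 0.16)
  k <- simulate_kicks(1e5, p0, preset_kinematics(2), n_fish = 2,
                      seed = 77, n_burn = 300)
  b <- bin_pair_response(symmetrize_kicks(k), wall_cutoff_mm = 60)
  fx <- factorize_pair(b)
  expect_true(fx$converged)
  a1 <- fit_estimate(fit_fourier(factor_table(fx, "O_att"), "odd", 1:2),
                     "a1")
  expect_lt(abs(a1 - (-0.33)), 0.08)
  ea <- fit_fourier(factor_table(fx, "E_att"), "even", 1:2)
  expect_lt(abs(fit_estimate(ea, "b1") - 0.48), 0.08)
  expect_lt(abs(fit_estimate(ea, "b2") - (-0.31)), 0.08)
  a2 <- fit_estimate(fit_fourier(factor_table(fx, "O_ali"), "odd", 2),
                     "a2")
  expect_lt(abs(a2 - 0.30), 0.08)
  el <- fit_fourier(factor_table(fx, "E_ali"), "even", 1:2)
  expect_lt(abs(fit_estimate(el, "b1") - 0.60), 0.08)
  expect_lt(abs(fit_estimate(el, "b2") - (-0.32)), 0.08)
})
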