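# Independent oracles, written with plain loops and no reuse of the
# package's linear-algebra layout, for cross-checking the factorization.

# Brute-force alternating least squares for the 2-factor problem:
# minimize sum_ij eps_ij (dphi_ij - f_i O_j)^2 with O odd on a
# symmetric angular mesh. Exact (undamped) coordinate minimization.
oracle_als_2d <- function(eps, dphi, theta, iters = 2000) {
  I <- nrow(eps); J <- ncol(eps)
  O <- sin(theta)
  f <- rep(0, I)
  for (rep_i in seq_len(iters)) {
    for (i in seq_len(I)) {
      num <- 0; den <- 0
      for (j in seq_len(J)) {
        num <- num + eps[i, j] * dphi[i, j] * O[j]
        den <- den + eps[i, j] * O[j]^2
      }
      f[i] <- if (den > 0) num / den else 0
    }
    for (j in seq_len(J)) {
      num <- 0; den <- 0
      for (i in seq_len(I)) {
        num <- num + eps[i, j] * dphi[i, j] * f[i]
        den <- den + eps[i, j] * f[i]^2
      }
      O[j] <- if (den > 0) num / den else 0
    }
    # odd projection on the symmetric mesh
    O <- (O - rev(O)) / 2
  }
  s <- sqrt(mean(O^2))
  if (s > 0) { O <- O / s; f <- f * s }
  if (mean(O[theta > 0]) < 0) { O <- -O; f <- -f }
  list(f = f, O = O,
       delta = sum(eps * (dphi - outer(f, O))^2))
}

# weighted squared error of a 2-factor model
delta_2d <- function(eps, dphi, f, O) sum(eps * (dphi - outer(f, O))^2)

# build a bc_binned wall object directly from chosen cell values
make_binned_wall <- function(eps, dphi, radius_mm = 353) {
  I <- nrow(eps); J <- ncol(eps)
  r_edges <- seq(0, radius_mm, length.out = I + 1)
  th_edges <- seq(-pi, pi, length.out = J + 1)
  structure(
    list(mode = "wall", eps = eps, dphi = dphi,
         centers = list(r_w_mm = (r_edges[-1] + r_edges[-(I + 1)]) / 2,
                        theta_w_rad = (th_edges[-1] + th_edges[-(J + 1)]) / 2),
         edges = list(r_w_mm = r_edges, theta_w_rad = th_edges),
         n_kept = sum(eps), n_dropped = 0),
    class = "bc_binned"
  )
}

make_binned_pair <- function(eps, dphi, d_max = 280) {
  K <- dim(eps)[1]; L <- dim(eps)[2]; M <- dim(eps)[3]
  d_edges <- seq(0, d_max, length.out = K + 1)
  psi_edges <- seq(-pi, pi, length.out = L + 1)
  dph_edges <- seq(-pi, pi, length.out = M + 1)
  structure(
    list(mode = "pair", eps = eps, dphi = dphi,
         centers = list(d_mm = (d_edges[-1] + d_edges[-(K + 1)]) / 2,
                        psi_rad = (psi_edges[-1] + psi_edges[-(L + 1)]) / 2,
                        dphi_pair_rad = (dph_edges[-1] + dph_edges[-(M + 1)]) / 2),
         edges = list(d_mm = d_edges, psi_rad = psi_edges,
                      dphi_pair_rad = dph_edges),
         n_kept = sum(eps), n_dropped = 0),
    class = "bc_binned"
  )
}

# relative L2 distance between two tabulated functions, after aligning
# overall scale and sign by least squares (the conventions may differ)
rel_l2 <- function(got, want) {
  a <- sum(got * want) / sum(want^2)
  sqrt(sum((got - a * want)^2) / sum((a * want)^2))
}
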