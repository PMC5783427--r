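#' Double a kick table with its mirror image
#'
#' Left/right symmetry in a circular arena implies that every observed
#' trajectory and its mirror are equally probable, so the data set can
#' be doubled by appending the [mirror_kicks()] image of every record.
#' This halves the statistical uncertainty of angle-dependent quantities
#' and enforces the parity structure that the factorization assumes.
#'
#' @param kicks Kick table.
#' @return Tibble with exactly twice as many rows.
#' @export
symmetrize_kicks <- function(kicks) {
  out <- dplyr::bind_rows(tibble::as_tibble(kicks), mirror_kicks(kicks))
  attr(out, "radius_mm") <- attr(kicks, "radius_mm")
  out
}

#' Bin kick responses on the wall-frame mesh
#'
#' Partitions the `(r_w, theta_w)` plane into a regular mesh
#' (`r_w` over `[0, R]`, `theta_w` over `[-pi, pi]`; bins left-closed
#' right-open, last bin closed) and stores per cell the record count
#' `eps` and the mean observed heading change. Records with missing
#' `dphi` (final kicks), degenerate frames, or values outside the mesh
#' are dropped and counted.
#'
#' @param kicks Symmetrized kick table with `r_w_mm`, `theta_w_rad`,
#'   `dphi_rad`.
#' @param radius_mm Arena radius (mm); defaults to the kick-table
#'   attribute.
#' @param n_r,n_theta Number of bins along each dimension.
#' @param min_count Cells with fewer records than this carry no weight.
#'   The default 1 keeps every occupied cell (no regularization of any
#'   kind); small samples may need a floor of a few records, because
#'   the unregularized factorization can otherwise spend its freedom
#'   fitting pure noise in near-empty cells.
#' @return A `bc_binned` object (mode `"wall"`).
#' @export
bin_wall_response <- function(kicks, radius_mm = attr(kicks, "radius_mm"),
                              n_r = 40, n_theta = 30, min_count = 1) {
  need_cols(kicks, c("r_w_mm", "theta_w_rad", "dphi_rad"))
  check_radius(radius_mm)
  keep <- !is.na(kicks$dphi_rad)
  if ("degenerate" %in% names(kicks)) keep <- keep & !kicks$degenerate
  k <- kicks[keep, , drop = FALSE]
  r_edges <- seq(0, radius_mm, length.out = n_r + 1)
  th_edges <- seq(-pi, pi, length.out = n_theta + 1)
  i <- findInterval(k$r_w_mm, r_edges, rightmost.closed = TRUE)
  j <- findInterval(k$theta_w_rad, th_edges, rightmost.closed = TRUE)
  inside <- i >= 1 & i <= n_r & j >= 1 & j <= n_theta
  i <- i[inside]; j <- j[inside]; dphi <- k$dphi_rad[inside]
  lin <- i + (j - 1L) * n_r
  eps <- matrix(tabulate(lin, n_r * n_theta), n_r, n_theta)
  dsum <- matrix(bin_sums(dphi, lin, n_r * n_theta), n_r, n_theta)
  if (min_count > 1) {
    drop <- eps < min_count
    eps[drop] <- 0
    dsum[drop] <- 0
  }
  structure(
    list(
      mode = "wall",
      eps = eps,
      dphi = ifelse(eps > 0, dsum / pmax(eps, 1), 0),
      centers = list(r_w_mm = mids(r_edges), theta_w_rad = mids(th_edges)),
      edges = list(r_w_mm = r_edges, theta_w_rad = th_edges),
      n_kept = sum(eps), n_dropped = nrow(kicks) - sum(eps)
    ),
    class = "bc_binned"
  )
}

#' Bin two-fish kick responses on the pair-frame mesh
#'
#' As [bin_wall_response()] but over `(d, psi, dphi_pair)`. Records with
#' the focal fish closer than `wall_cutoff_mm` to the wall are excluded
#' first, so that the wall interaction does not contaminate the social
#' terms; records beyond `d_max_mm`, where statistics are too thin to
#' measure the interaction, are dropped as out of mesh.
#'
#' @param kicks Symmetrized two-fish kick table with `d_mm`, `psi_rad`,
#'   `dphi_pair_rad`, `dphi_rad` and `r_w_mm`.
#' @param d_max_mm Upper edge of the distance mesh (mm).
#' @param n_d,n_psi,n_dphi Bins along `d`, `psi` and `dphi_pair`.
#' @param wall_cutoff_mm Minimum distance to the wall (mm), about two
#'   body lengths.
#' @param min_count Cells with fewer records than this carry no weight
#'   (see [bin_wall_response()]).
#' @return A `bc_binned` object (mode `"pair"`).
#' @export
bin_pair_response <- function(kicks, d_max_mm = 280, n_d = 40,
                              n_psi = 30, n_dphi = 30,
                              wall_cutoff_mm = 60, min_count = 1) {
  need_cols(kicks, c("d_mm", "psi_rad", "dphi_pair_rad", "dphi_rad",
                     "r_w_mm"))
  keep <- !is.na(kicks$dphi_rad) & kicks$r_w_mm > wall_cutoff_mm
  if ("degenerate" %in% names(kicks)) keep <- keep & !kicks$degenerate
  k <- kicks[keep, , drop = FALSE]
  d_edges <- seq(0, d_max_mm, length.out = n_d + 1)
  psi_edges <- seq(-pi, pi, length.out = n_psi + 1)
  dphi_edges <- seq(-pi, pi, length.out = n_dphi + 1)
  ki <- findInterval(k$d_mm, d_edges, rightmost.closed = TRUE)
  li <- findInterval(k$psi_rad, psi_edges, rightmost.closed = TRUE)
  mi <- findInterval(k$dphi_pair_rad, dphi_edges, rightmost.closed = TRUE)
  inside <- ki >= 1 & ki <= n_d & li >= 1 & li <= n_psi &
    mi >= 1 & mi <= n_dphi
  ki <- ki[inside]; li <- li[inside]; mi <- mi[inside]
  dphi <- k$dphi_rad[inside]
  ncell <- n_d * n_psi * n_dphi
  lin <- ki + (li - 1L) * n_d + (mi - 1L) * n_d * n_psi
  eps <- array(tabulate(lin, ncell), c(n_d, n_psi, n_dphi))
  dsum <- array(bin_sums(dphi, lin, ncell), c(n_d, n_psi, n_dphi))
  if (min_count > 1) {
    drop <- eps < min_count
    eps[drop] <- 0
    dsum[drop] <- 0
  }
  structure(
    list(
      mode = "pair",
      eps = eps,
      dphi = ifelse(eps > 0, dsum / pmax(eps, 1), 0),
      centers = list(d_mm = mids(d_edges), psi_rad = mids(psi_edges),
                     dphi_pair_rad = mids(dphi_edges)),
      edges = list(d_mm = d_edges, psi_rad = psi_edges,
                   dphi_pair_rad = dphi_edges),
      n_kept = sum(eps), n_dropped = nrow(kicks) - sum(eps)
    ),
    class = "bc_binned"
  )
}

mids <- function(edges) (edges[-1] + edges[-length(edges)]) / 2

# sum `x` within integer cells 1..ncell given by `lin`
bin_sums <- function(x, lin, ncell) {
  out <- numeric(ncell)
  if (length(x)) {
    agg <- rowsum(x, lin)
    out[as.integer(rownames(agg))] <- agg[, 1]
  }
  out
}

#' @export
print.bc_binned <- function(x, ...) {
  cat(sprintf("<bc_binned> %s-frame response, %s mesh, %d records kept (%d dropped)\n",
              x$mode, paste(dim(as.array(x$eps)), collapse = "x"),
              x$n_kept, x$n_dropped))
  invisible(x)
}

#' Factorize the binned wall response into a distance and an angular factor
#'
#' Measures the wall interaction directly from data by fitting the
#' binned mean heading change with a product `f(r_w) * O(theta_w)`,
#' where `O` is constrained to be odd, minimizing the count-weighted
#' squared error `Delta = sum_ij eps_ij (dphi_ij - f_i O_j)^2`. The
#' normal equations are solved by damped fixed-point iteration: each
#' step computes the exact weighted least-squares update of one factor
#' given the other and moves a fraction `p` of the way there. After
#' every step `O` is anti-symmetrized across the mesh and rescaled to
#' unit mean square `(1/J) sum O_j^2 = 1` (the factor is absorbed into
#' `f`, which carries the scale in radians), and the overall sign is
#' fixed so that `O` has non-negative count-weighted mean over
#' `(0, pi]`. No smoothing
#' or regularization is applied; empty cells simply carry no weight.
#'
#' @param binned A `bc_binned` object from [bin_wall_response()].
#' @param p Damping parameter in `(0, 1]`.
#' @param tol Convergence tolerance on the maximum relative change of
#'   any tabulated value.
#' @param max_iter Iteration cap; non-convergence is flagged, not an
#'   error.
#' @param init Optional list with elements `f` and `O` to start from;
#'   default `O = sin(theta)` (normalized) with `f` solved from it.
#' @return A `bc_factorization` object; see [tidy.bc_factorization()].
#' @export
factorize_wall <- function(binned, p = 0.25, tol = 1e-6, max_iter = 10000,
                           init = NULL) {
  stopifnot(inherits(binned, "bc_binned"), binned$mode == "wall")
  eps <- binned$eps
  dphi <- binned$dphi
  if (all(eps == 0)) stop("all cells are empty", call. = FALSE)
  th <- binned$centers$theta_w_rad
  ed <- eps * dphi
  upd_f <- function(O) safe_div(ed %*% O, eps %*% O^2)
  upd_O <- function(f) safe_div(crossprod(ed, f), crossprod(eps, f^2))
  if (is.null(init)) {
    O <- sin(th); O <- O / sqrt(mean(O^2))
    f <- upd_f(O)
  } else {
    f <- init$f; O <- init$O
  }
  delta <- function(f, O) sum(eps * (dphi - tcrossprod(f, O))^2)
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    f_old <- f; O_old <- O
    f_hat <- upd_f(O)
    O_hat <- upd_O(f)
    f <- (1 - p) * f + p * f_hat
    O <- (1 - p) * O + p * O_hat
    O <- (O - rev(O)) / 2
    s <- sqrt(mean(O^2))
    if (s > 0) { O <- O / s; f <- f * s }
    if (wmean_sign(O, th > 0, colSums(eps)) < 0) { O <- -O; f <- -f }
    trace[it] <- delta(f, O)
    if (rel_change(c(f, O), c(f_old, O_old)) < tol) { converged <- TRUE; break }
  }
  new_factorization(
    mode = "wall",
    factors = list(
      f_wall = factor_tibble("f_wall", "r_w_mm", binned$centers$r_w_mm,
                             as.numeric(f), rowSums(eps)),
      O_wall = factor_tibble("O_wall", "theta_w_rad", th,
                             as.numeric(O), colSums(eps))
    ),
    delta_trace = trace, iterations = it, converged = converged,
    p = p, tol = tol
  )
}

#' Factorize the binned pair response into attraction and alignment terms
#'
#' Decomposes the binned mean heading change of a focal fish into the
#' sum of two parity-constrained products,
#' `F_att(d) O_att(psi) E_att(dphi_pair) + F_ali(d) O_ali(dphi_pair)
#' E_ali(psi)` (O odd, E even), by minimizing the count-weighted squared
#' error over the six tabulated functions. The six normal equations are
#' iterated cyclically with damping `p`; each update subtracts the
#' current estimate of the *other* term from the data (counter-term), so
#' attraction is measured on the alignment-corrected response and vice
#' versa. After every cycle the four angular functions are parity
#' projected, normalized to unit mean square (scale absorbed into the
#' distance factors, which carry radians) and sign-fixed (odd factors
#' non-negative on `(0, pi]`, even factors non-negative mean).
#'
#' If one distance factor collapses to zero everywhere the result is
#' flagged `degenerate` (the two terms cannot be separated on these
#' data), not an error.
#'
#' @inheritParams factorize_wall
#' @param binned A `bc_binned` object from [bin_pair_response()].
#' @return A `bc_factorization` object with factors `F_att`, `O_att`,
#'   `E_att`, `F_ali`, `O_ali`, `E_ali`.
#' @export
factorize_pair <- function(binned, p = 0.25, tol = 1e-6, max_iter = 10000,
                           init = NULL) {
  stopifnot(inherits(binned, "bc_binned"), binned$mode == "pair")
  eps <- binned$eps
  dphi <- binned$dphi
  if (all(eps == 0)) stop("all cells are empty", call. = FALSE)
  dims <- dim(eps)
  psi <- binned$centers$psi_rad
  dph <- binned$centers$dphi_pair_rad
  # both terms are triples of vectors along dims (d, psi, dphi_pair):
  # attraction = (F_att, O_att, E_att), alignment = (F_ali, E_ali, O_ali)
  if (is.null(init)) {
    att <- list(rep(0, dims[1]), nrm(sin(psi)), rep(1, dims[3]))
    ali <- list(rep(0, dims[1]), rep(1, dims[2]), nrm(sin(dph)))
  } else {
    att <- init$att; ali <- init$ali
  }
  full3 <- function(v) outer(v[[1]], outer(v[[2]], v[[3]]))
  delta <- function() sum(eps * (dphi - full3(att) - full3(ali))^2)
  update_dim <- function(term, other, d) {
    w <- term
    w[[d]] <- rep(1, dims[d])
    W <- full3(w)
    G <- eps * (dphi - full3(other))
    num <- apply(G * W, d, sum)
    den <- apply(eps * W * W, d, sum)
    hat <- safe_div(num, den)
    term[[d]] <- (1 - p) * term[[d]] + p * hat
    term
  }
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    old <- c(att, ali)
    for (d in 1:3) att <- update_dim(att, ali, d)
    for (d in 1:3) ali <- update_dim(ali, att, d)
    # parity projection and unit-mean-square normalization; the distance
    # factor absorbs scale and sign
    att[[2]] <- (att[[2]] - rev(att[[2]])) / 2     # O_att odd in psi
    att[[3]] <- (att[[3]] + rev(att[[3]])) / 2     # E_att even in dphi
    ali[[3]] <- (ali[[3]] - rev(ali[[3]])) / 2     # O_ali odd in dphi
    ali[[2]] <- (ali[[2]] + rev(ali[[2]])) / 2     # E_ali even in psi
    for (d in 2:3) {
      s <- sqrt(mean(att[[d]]^2))
      if (s > 0) { att[[d]] <- att[[d]] / s; att[[1]] <- att[[1]] * s }
      s <- sqrt(mean(ali[[d]]^2))
      if (s > 0) { ali[[d]] <- ali[[d]] / s; ali[[1]] <- ali[[1]] * s }
    }
    w_psi <- apply(eps, 2, sum)
    w_dph <- apply(eps, 3, sum)
    if (wmean_sign(att[[2]], psi > 0, w_psi) < 0) { att[[2]] <- -att[[2]]; att[[1]] <- -att[[1]] }
    if (wmean_sign(att[[3]], rep(TRUE, length(dph)), w_dph) < 0) { att[[3]] <- -att[[3]]; att[[1]] <- -att[[1]] }
    if (wmean_sign(ali[[3]], dph > 0, w_dph) < 0) { ali[[3]] <- -ali[[3]]; ali[[1]] <- -ali[[1]] }
    if (wmean_sign(ali[[2]], rep(TRUE, length(psi)), w_psi) < 0) { ali[[2]] <- -ali[[2]]; ali[[1]] <- -ali[[1]] }
    trace[it] <- delta()
    if (rel_change(unlist(c(att, ali)), unlist(old)) < tol) {
      converged <- TRUE
      break
    }
  }
  w_d <- apply(eps, 1, sum)
  w_psi <- apply(eps, 2, sum)
  w_dph <- apply(eps, 3, sum)
  scale_att <- max(abs(att[[1]]))
  scale_ali <- max(abs(ali[[1]]))
  degenerate <- min(scale_att, scale_ali) < 1e-8 * max(scale_att, scale_ali, 1e-300)
  new_factorization(
    mode = "pair",
    factors = list(
      F_att = factor_tibble("F_att", "d_mm", binned$centers$d_mm,
                            att[[1]], w_d),
      O_att = factor_tibble("O_att", "psi_rad", psi, att[[2]], w_psi),
      E_att = factor_tibble("E_att", "dphi_pair_rad", dph, att[[3]], w_dph),
      F_ali = factor_tibble("F_ali", "d_mm", binned$centers$d_mm,
                            ali[[1]], w_d),
      O_ali = factor_tibble("O_ali", "dphi_pair_rad", dph, ali[[3]], w_dph),
      E_ali = factor_tibble("E_ali", "psi_rad", psi, ali[[2]], w_psi)
    ),
    delta_trace = trace, iterations = it, converged = converged,
    p = p, tol = tol, degenerate = degenerate
  )
}

nrm <- function(v) v / sqrt(mean(v^2))

safe_div <- function(num, den) {
  out <- num / den
  out[!is.finite(out)] <- 0
  out
}

rel_change <- function(new, old) max(abs(new - old) / (abs(old) + 1e-12))

# sign of the count-weighted mean of a factor over selected bins
wmean_sign <- function(v, sel, w) {
  ws <- sum(w[sel])
  if (ws <= 0) return(sign(mean(v[sel])))
  sign(sum(v[sel] * w[sel]) / ws)
}

factor_tibble <- function(fn, variable, centers, value, weight) {
  tibble::tibble(fn = fn, variable = variable, bin_center = centers,
                 value = as.numeric(value), weight = as.numeric(weight))
}

new_factorization <- function(mode, factors, delta_trace, iterations,
                              converged, p, tol, degenerate = FALSE) {
  structure(
    list(mode = mode, factors = factors, delta_trace = delta_trace,
         delta = utils::tail(delta_trace, 1), iterations = iterations,
         converged = converged, p = p, tol = tol, degenerate = degenerate),
    class = "bc_factorization"
  )
}

#' @export
print.bc_factorization <- function(x, ...) {
  cat(sprintf("<bc_factorization> %s response: %s\n", x$mode,
              paste(names(x$factors), collapse = ", ")))
  cat(sprintf("  %d iterations, final error %.6g, %sconverged%s\n",
              x$iterations, x$delta, if (x$converged) "" else "NOT ",
              if (isTRUE(x$degenerate)) " (degenerate)" else ""))
  invisible(x)
}

#' Extract one tabulated factor from a factorization
#'
#' @param x A `bc_factorization` object.
#' @param fn Factor name, e.g. `"f_wall"`, `"F_att"`, `"O_ali"`.
#' @return Tibble with `bin_center`, `value` and `weight` (marginal
#'   record counts), ready for the parametric fits.
#' @export
factor_table <- function(x, fn) {
  stopifnot(inherits(x, "bc_factorization"))
  if (!fn %in% names(x$factors)) {
    stop("unknown factor `", fn, "`; available: ",
         paste(names(x$factors), collapse = ", "), call. = FALSE)
  }
  x$factors[[fn]][c("bin_center", "value", "weight")]
}

#' Tidy and summarize factorization results
#'
#' `tidy()` returns all tabulated factors as one long tibble (`fn`,
#' `variable`, `bin_center`, `value`, `weight`); `glance()` returns a
#' one-row summary with the final weighted squared error, iteration
#' count and convergence flag.
#'
#' @param x A `bc_factorization` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.bc_factorization <- function(x, ...) {
  dplyr::bind_rows(x$factors)
}

#' @rdname tidy.bc_factorization
#' @export
glance.bc_factorization <- function(x, ...) {
  tibble::tibble(
    mode = x$mode, delta = x$delta, iterations = x$iterations,
    converged = x$converged, degenerate = isTRUE(x$degenerate),
    p = x$p, tol = x$tol
  )
}
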