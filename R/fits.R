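#' Fit an exponential decay to post-kick speed relaxation
#'
#' During the coast phase the speed relaxes approximately exponentially,
#' `v(t) = v0 * exp(-t / tau0)`. This fit recovers the dissipation time
#' `tau0` from a table of mean speed versus time since kick onset.
#' Starting values come from a log-linear regression; a non-decaying
#' series (slope >= 0) is returned with `converged = FALSE` and
#' `tau0 = Inf` rather than an error.
#'
#' @param data Data frame with columns `time_s` and `speed_mm_s`
#'   (positive), optionally `weight`.
#' @param weighted Use the `weight` column (if present) in the loss?
#' @return A `bc_fit` object with terms `tau0_s` and `v0_mm_s`.
#' @export
fit_exponential_decay <- function(data, weighted = TRUE) {
  need_cols(data, c("time_s", "speed_mm_s"))
  if (nrow(data) < 5) stop("need at least 5 time points", call. = FALSE)
  if (any(data$speed_mm_s <= 0)) {
    stop("speeds must be positive", call. = FALSE)
  }
  w <- fit_weights(data, weighted)
  lin <- stats::lm(log(speed_mm_s) ~ time_s, data = data, weights = w)
  slope <- stats::coef(lin)[["time_s"]]
  # a non-decaying series has no finite time scale; treat numerically
  # flat series the same way
  if (slope >= -1e-8) {
    return(new_fit("exponential_decay",
                   c(tau0_s = Inf, v0_mm_s = exp(stats::coef(lin)[[1]])),
                   residual = NA_real_, converged = FALSE))
  }
  fit <- minpack.lm::nlsLM(
    speed_mm_s ~ v0 * exp(-time_s / tau0),
    data = data, weights = w,
    start = list(v0 = exp(stats::coef(lin)[[1]]), tau0 = -1 / slope)
  )
  cf <- stats::coef(fit)
  new_fit("exponential_decay",
          c(tau0_s = cf[["tau0"]], v0_mm_s = cf[["v0"]]),
          residual = sqrt(sum(stats::resid(fit)^2)),
          converged = fit$convInfo$isConv)
}

#' Fit the Gaussian range of the wall distance factor
#'
#' Fits `A * exp(-(r / l_w)^2)` with free amplitude to a tabulated
#' distance factor (e.g. `factor_table(x, "f_wall")`), so the result is
#' invariant under rescaling of the input. Returns the range `l_w`.
#'
#' @param data Data frame with columns `bin_center` (mm) and `value`,
#'   optionally `weight` (per-bin record counts).
#' @param weighted Weight bins by their record counts?
#' @return A `bc_fit` object with terms `l_w_mm` and `amplitude`.
#' @export
fit_wall_range <- function(data, weighted = TRUE) {
  need_cols(data, c("bin_center", "value"))
  keep <- is.finite(data$value)
  data <- data[keep, , drop = FALSE]
  if (sum(data$value != 0) < 3) {
    stop("need at least 3 informative bins", call. = FALSE)
  }
  w <- fit_weights(data, weighted)
  a0 <- data$value[which.max(abs(data$value))]
  # start from a weighted log-linear regression on the bins that still
  # carry signal: log|v| = log|A| - r^2 / l^2
  sig <- which(sign(data$value) == sign(a0) &
                 abs(data$value) > 0.05 * abs(a0) & w > 0)
  l0 <- max(data$bin_center) / 2
  if (length(sig) >= 3) {
    lf <- stats::lm(log(abs(data$value[sig])) ~ I(data$bin_center[sig]^2),
                    weights = w[sig])
    sl <- stats::coef(lf)[[2]]
    if (is.finite(sl) && sl < 0) l0 <- sqrt(-1 / sl)
  }
  l0 <- min(max(l0, 0.02 * max(data$bin_center)), 2 * max(data$bin_center))
  fit <- minpack.lm::nlsLM(
    value ~ A * exp(-(bin_center / l)^2),
    data = data, weights = w,
    start = list(A = a0, l = l0),
    lower = c(A = -Inf, l = 1e-6)
  )
  cf <- stats::coef(fit)
  new_fit("wall_range",
          c(l_w_mm = cf[["l"]], amplitude = cf[["A"]]),
          residual = sqrt(sum(stats::resid(fit)^2)),
          converged = fit$convInfo$isConv)
}

#' Fit the attraction distance profile
#'
#' Fits `A * (d - d0) / (1 + (d / l_att)^2)` with free amplitude to a
#' tabulated attraction distance factor. `d0` is the zero crossing
#' separating short-range repulsion from attraction and `l_att` the
#' range of the profile.
#'
#' @inheritParams fit_wall_range
#' @return A `bc_fit` object with terms `d0_mm`, `l_att_mm`,
#'   `amplitude`.
#' @export
fit_attraction_profile <- function(data, weighted = TRUE) {
  need_cols(data, c("bin_center", "value"))
  data <- data[is.finite(data$value), , drop = FALSE]
  if (sum(data$value != 0) < 3) {
    stop("need at least 3 informative bins", call. = FALSE)
  }
  w <- fit_weights(data, weighted)
  # starting zero crossing: first sign change weighted by neighbours
  sgn <- sign(data$value)
  flips <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  d0_0 <- if (length(flips)) {
    mean(data$bin_center[c(flips[1], flips[1] + 1)])
  } else {
    min(data$bin_center)
  }
  # amplitude start with the sign the data imply at its largest value
  l0 <- max(data$bin_center) / 2
  imax <- which.max(abs(data$value))
  shape_at <- (data$bin_center[imax] - d0_0) /
    (1 + (data$bin_center[imax] / l0)^2)
  a0 <- if (abs(shape_at) > 1e-12) data$value[imax] / shape_at else 1e-3
  fit <- minpack.lm::nlsLM(
    value ~ A * (bin_center - d0) / (1 + (bin_center / l)^2),
    data = data, weights = w,
    start = list(A = a0, d0 = d0_0, l = l0),
    lower = c(A = -Inf, d0 = -Inf, l = 1e-6)
  )
  cf <- stats::coef(fit)
  new_fit("attraction_profile",
          c(d0_mm = cf[["d0"]], l_att_mm = cf[["l"]],
            amplitude = cf[["A"]]),
          residual = sqrt(sum(stats::resid(fit)^2)),
          converged = fit$convInfo$isConv)
}

#' Fit the alignment distance profile
#'
#' Fits `A * (d + d0p) * exp(-(d / l_ali)^2)` with free amplitude to a
#' tabulated alignment distance factor; `l_ali` is the Gaussian-envelope
#' range of the alignment interaction.
#'
#' @inheritParams fit_wall_range
#' @return A `bc_fit` object with terms `d0p_mm`, `l_ali_mm`,
#'   `amplitude`.
#' @export
fit_alignment_profile <- function(data, weighted = TRUE) {
  need_cols(data, c("bin_center", "value"))
  data <- data[is.finite(data$value), , drop = FALSE]
  if (sum(data$value != 0) < 3) {
    stop("need at least 3 informative bins", call. = FALSE)
  }
  w <- fit_weights(data, weighted)
  l0 <- max(data$bin_center) / 2
  imax <- which.max(abs(data$value))
  shape_at <- (data$bin_center[imax] + 30) *
    exp(-(data$bin_center[imax] / l0)^2)
  a0 <- data$value[imax] / shape_at
  fit <- minpack.lm::nlsLM(
    value ~ A * (bin_center + d0p) * exp(-(bin_center / l)^2),
    data = data, weights = w,
    start = list(A = a0, d0p = 30, l = l0),
    lower = c(A = -Inf, d0p = -Inf, l = 1e-6)
  )
  cf <- stats::coef(fit)
  new_fit("alignment_profile",
          c(d0p_mm = cf[["d0p"]], l_ali_mm = cf[["l"]],
            amplitude = cf[["A"]]),
          residual = sqrt(sum(stats::resid(fit)^2)),
          converged = fit$convInfo$isConv)
}

#' Fit a short Fourier series to a tabulated angular factor
#'
#' Odd factors are fitted as `A * sin(theta) * (1 + sum_k a_k
#' cos(k*theta))` and even factors as `A * (1 + sum_k b_k
#' cos(k*theta))`. Both models are linear in `(A, A*a_k)`, so the fit is
#' a weighted linear regression and the reported coefficients `a_k` are
#' the ratios to the leading term -- the same normalization-free shape
#' parameters whatever the amplitude of the input. At most two non-zero
#' harmonics are used by default; `harmonics` selects which.
#'
#' When the angular mesh is symmetric the parity of the data is checked
#' first: if the wrong-parity component exceeds `parity_tol` times the
#' root mean square of the values, the declared parity is inconsistent
#' with the data and an error is raised.
#'
#' @param data Data frame with columns `bin_center` (rad) and `value`,
#'   optionally `weight`.
#' @param parity `"odd"` or `"even"`.
#' @param harmonics Integer vector of cosine harmonics to include
#'   (default `1:2`).
#' @param weighted Weight bins by their record counts?
#' @param parity_tol Relative tolerance of the parity check.
#' @return A `bc_fit` object with terms `a1`, `a2`, ... (or `b1`, ...)
#'   and `amplitude`.
#' @export
fit_fourier <- function(data, parity = c("odd", "even"), harmonics = 1:2,
                        weighted = TRUE, parity_tol = 0.2) {
  parity <- match.arg(parity)
  need_cols(data, c("bin_center", "value"))
  data <- data[is.finite(data$value), , drop = FALSE]
  th <- data$bin_center
  v <- data$value
  w <- fit_weights(data, weighted)
  check_parity(th, v, parity, parity_tol)
  lead <- if (parity == "odd") sin(th) else rep(1, length(th))
  X <- cbind(lead, vapply(harmonics, function(k) lead * cos(k * th),
                          numeric(length(th))))
  cf <- stats::coef(stats::lm.wfit(X, v, w))
  A <- cf[1]
  if (abs(A) < 1e-300) stop("leading Fourier term is zero", call. = FALSE)
  ratios <- cf[-1] / A
  prefix <- if (parity == "odd") "a" else "b"
  names(ratios) <- paste0(prefix, harmonics)
  fitted <- X %*% cf
  new_fit(paste0("fourier_", parity),
          c(ratios, amplitude = unname(A)),
          residual = sqrt(sum(w * (v - fitted)^2)),
          converged = TRUE)
}

check_parity <- function(th, v, parity, parity_tol) {
  ord <- order(th)
  th <- th[ord]; v <- v[ord]
  partner <- vapply(th, function(t) {
    hit <- which(abs(th + t) < 1e-8)
    if (length(hit)) hit[1] else NA_integer_
  }, integer(1))
  ok <- !is.na(partner)
  if (sum(ok) < 4) return(invisible())  # mesh not symmetric; skip check
  wrong <- if (parity == "odd") (v[ok] + v[partner[ok]]) / 2 else
    (v[ok] - v[partner[ok]]) / 2
  rms <- sqrt(mean(v^2))
  if (rms > 0 && sqrt(mean(wrong^2)) > parity_tol * rms) {
    stop("data parity is inconsistent with declared `parity = \"",
         parity, "\"`", call. = FALSE)
  }
  invisible()
}

fit_weights <- function(data, weighted) {
  if (weighted && "weight" %in% names(data)) {
    w <- data$weight
    w[!is.finite(w) | w < 0] <- 0
    w
  } else {
    rep(1, nrow(data))
  }
}

new_fit <- function(model, estimates, residual, converged) {
  structure(
    list(model = model,
         estimates = tibble::tibble(term = names(estimates),
                                    estimate = unname(estimates)),
         residual = residual, converged = converged),
    class = "bc_fit"
  )
}

#' @export
print.bc_fit <- function(x, ...) {
  cat(sprintf("<bc_fit> %s (%sconverged)\n", x$model,
              if (isTRUE(x$converged)) "" else "NOT "))
  for (i in seq_len(nrow(x$estimates))) {
    cat(sprintf("  %-12s %.6g\n", x$estimates$term[i],
                x$estimates$estimate[i]))
  }
  invisible(x)
}

#' Tidy and summarize parametric fits
#'
#' `tidy()` returns the parameter estimates as a tibble; `glance()` a
#' one-row summary with the residual norm and convergence flag.
#'
#' @param x A `bc_fit` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.bc_fit <- function(x, ...) x$estimates

#' @rdname tidy.bc_fit
#' @export
glance.bc_fit <- function(x, ...) {
  tibble::tibble(model = x$model, residual = x$residual,
                 converged = x$converged)
}

#' Look up one estimate from a fit
#'
#' @param x A `bc_fit` object.
#' @param term Term name, e.g. `"l_w_mm"`.
#' @return A single number.
#' @export
fit_estimate <- function(x, term) {
  stopifnot(inherits(x, "bc_fit"))
  i <- match(term, x$estimates$term)
  if (is.na(i)) {
    stop("no term `", term, "`; available: ",
         paste(x$estimates$term, collapse = ", "), call. = FALSE)
  }
  x$estimates$estimate[i]
}
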