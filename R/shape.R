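#' Exact derivatives of the pseudogenization rate
#'
#' Writes `h_P(t) = N(t)/D(t)` with `N(t) = e_0 exp(Qstar t) v_P` and
#' `D(t) = 1 - e_0 (exp(Qstar t) - I) Qstar^{-1} v_P`, and uses
#' `N'(t) = e_0 Qstar exp(Qstar t) v_P`, `D'(t) = -N(t)` to evaluate the
#' closed-form quotient-rule derivatives
#' `h' = (N'D + N^2)/D^2` and
#' `h'' = (N''D^2 + 3 N N' D + 2 N^3)/D^3`.
#' No finite differences are involved.
#'
#' @inheritParams pseudo_rate
#' @param order derivative order, 1 or 2.
#' @export
pseudo_rate_derivatives <- function(model, t, order = 1,
                                    dimensionless = FALSE) {
  if (!order %in% c(1, 2)) stop("`order` must be 1 or 2")
  blocks <- nondim_blocks(model, dimensionless)
  if (any(!is.finite(t))) stop("`t` must be finite")
  Q <- blocks$Qstar
  vP <- blocks$v_P
  w <- backsolve(Q, vP)
  Qv <- as.numeric(Q %*% vP)
  QQv <- as.numeric(Q %*% Qv)
  vapply(t, function(ti) {
    e0 <- if (ti == 0) c(1, numeric(nrow(Q) - 1)) else expm_mat(Q * ti)[1, ]
    N <- sum(e0 * vP)
    D <- 1 - (sum(e0 * w) - w[1])
    if (D <= 0)
      stop(sprintf("denominator %g <= 0 at t = %g", D, ti))
    N1 <- sum(e0 * Qv)
    if (order == 1) {
      (N1 * D + N^2) / D^2
    } else {
      N2 <- sum(e0 * QQv)
      (N2 * D^2 + 3 * N * N1 * D + 2 * N^3) / D^3
    }
  }, numeric(1))
}

#' Critical mutation-rate ratio
#'
#' The ratio `gamma = u_r/u_c` at which the second derivative of the
#' pseudogenization rate vanishes exactly at `t = 0`. Below this value the
#' change of concavity of `h_P` sits at positive time and the rate curve is
#' visibly sigmoidal; above it the inflection moves to negative time and
#' the curve is exponential-like for `t >= 0`. Found by bisection of
#' `gamma -> h_P''(0; gamma)` on the bracket `(1e-6, 0.999)`; the result is
#' dimensionless and does not depend on `u_c`.
#'
#' For `z >= 3` the root is unique in the bracket; for `z = 2` the
#' function `h_P''(0; gamma)` is cubic in `gamma` with two interior roots
#' (at 1/3 and 1/2), in which case the smallest is returned and all roots
#' found are attached as the `"all_roots"` attribute.
#'
#' @param z number of regulatory regions, `>= 2`.
#' @param u_c coding rate (the result is invariant to it).
#' @param tol absolute bisection tolerance on gamma.
#' @export
gamma_crit <- function(z, u_c = 1, tol = 1e-10) {
  f <- function(g) pseudo_rate_derivatives(duplicate_model(z, u_c, g * u_c),
                                           0, order = 2, dimensionless = TRUE)
  grid <- seq(1e-6, 0.999, length.out = 256)
  vals <- vapply(grid, f, numeric(1))
  flips <- which(vals[-1] * vals[-length(vals)] < 0)
  if (!length(flips))
    stop(sprintf("no sign change of h_P''(0) on (%g, %g): f = %g and %g",
                 grid[1], grid[length(grid)], vals[1], vals[length(vals)]))
  bisect <- function(lo, hi) {
    flo <- f(lo)
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (sign(f(mid)) == sign(flo)) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  roots <- vapply(flips, function(i) bisect(grid[i], grid[i + 1]),
                  numeric(1))
  out <- roots[1]
  if (length(roots) > 1) attr(out, "all_roots") <- roots
  out
}

#' Inflection points of the pseudogenization rate
#'
#' Roots of the second derivative of `h_P`. Physical time `t > 0` is
#' scanned first on a log-spaced grid up to `50/u_c` with bisection at each
#' sign change; if no positive root exists, the analytic continuation to
#' negative `t` is scanned outward from 0. For `0 < u_r < u_c` there is a
#' single inflection; it sits at positive time iff
#' `gamma < gamma_crit(z)`. For `u_r > u_c` several roots can exist, in
#' which case all found are returned with a warning. The scan on either
#' side stops where the continuation becomes ill-conditioned (denominator
#' <= 0, or second derivative beyond 1e12 in magnitude, both possible at
#' very negative `t`).
#'
#' @inheritParams pseudo_rate
#' @return Numeric vector of roots (usually length 1), in the time units of
#'   the model; `numeric(0)` if no root is found in the scanned window.
#' @export
inflection_time <- function(model, dimensionless = FALSE) {
  blocks <- nondim_blocks(model, dimensionless)
  m <- blocks$model
  f <- function(t) tryCatch(pseudo_rate_derivatives(blocks, t, order = 2),
                            error = function(e) NA_real_)
  # ordered sign-change scan. The scan ends on a side once the matrix
  # exponential mixes magnitudes ~exp(|t| max|diag|): beyond ~e^30 the
  # double-precision cancellation leaves pure noise in h''.
  t_cond <- 30 / max(abs(diag(blocks$Qstar)))
  scan <- function(grid) {
    roots <- numeric(0)
    prev_t <- NA_real_; prev_v <- NA_real_
    for (t in grid) {
      if (abs(t) > t_cond) break
      v <- f(t)
      if (!is.finite(v) || abs(v) > 1e12) break
      if (v == 0) roots <- c(roots, t)
      else if (is.finite(prev_v) && prev_v * v < 0)
        roots <- c(roots, stats::uniroot(f, sort(c(prev_t, t)),
                                         tol = 1e-12)$root)
      prev_t <- t; prev_v <- v
    }
    roots
  }
  g <- exp(seq(log(1e-4 / m$u_c), log(50 / m$u_c), length.out = 120))
  roots <- scan(c(0, g))                       # physical time first
  if (!length(roots)) roots <- scan(c(0, -g))  # then the continuation
  roots <- sort(unique(roots))
  if (length(roots) > 1)
    warning(sprintf(
      "multiple inflection points found (%s); u_r > u_c regimes can have several turning points",
      paste(signif(roots, 6), collapse = ", ")))
  roots
}

#' Shape diagnostics of the pseudogenization rate
#'
#' Summarizes the qualitative regime of `h_P` for a given `z` and
#' `gamma = u_r/u_c`: the critical ratio, the inflection location (in
#' units of `1/u_c`) and the regime classification.
#'
#' @param z number of regulatory regions.
#' @param gamma ratio `u_r/u_c`.
#' @param u_c coding rate; the report is expressed in `1/u_c` time units.
#' @return An object of class `"shape_report"`: a list with `z`, `gamma`,
#'   `gamma_crit`, `inflection_time` (possibly several, `NA` if none found)
#'   and `regime` (`"sigmoidal-visible"`, `"boundary"` or
#'   `"exponential-like"`).
#' @export
shape_report <- function(z, gamma, u_c = 1) {
  stopifnot(gamma >= 0)
  gc <- gamma_crit(z)
  m <- duplicate_model(z, u_c, gamma * u_c)
  infl <- inflection_time(m, dimensionless = TRUE)
  regime <- if (abs(gamma - gc) < 1e-8) "boundary"
            else if (gamma < gc) "sigmoidal-visible"
            else "exponential-like"
  structure(list(z = z, gamma = gamma, gamma_crit = gc,
                 inflection_time = if (length(infl)) infl else NA_real_,
                 regime = regime),
            class = "shape_report")
}

#' @export
print.shape_report <- function(x, ...) {
  cat("Pseudogenization-rate shape report\n")
  cat(sprintf("  z           = %d\n", x$z))
  cat(sprintf("  gamma       = %g\n", x$gamma))
  cat(sprintf("  gamma_crit  = %.4g\n", x$gamma_crit))
  cat(sprintf("  inflection  = %s (units 1/u_c)\n",
              paste(signif(x$inflection_time, 4), collapse = ", ")))
  cat(sprintf("  regime      = %s\n", x$regime))
  invisible(x)
}
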