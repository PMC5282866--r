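#' Hazard rate of the absorption time
#'
#' The classical hazard of `T` (time to absorption into either fate),
#' `lambda_i(t) = -e_i exp(Qstar t) Qstar 1 / (e_i exp(Qstar t) 1)`,
#' conditional on starting in transient state `i`.
#'
#' @param model a [duplicate_model()] or prebuilt [build_generator()] blocks.
#' @param t vector of times, `>= 0`.
#' @param start 0-based starting transient state.
#' @param dimensionless if `TRUE`, re-express the model with `u_c = 1`
#'   (rates are then in units of `u_c`, time in units of `1/u_c`).
#' @return Numeric vector of rates, one per time.
#' @export
hazard <- function(model, t, start = 0, dimensionless = FALSE) {
  blocks <- nondim_blocks(model, dimensionless)
  if (any(!is.finite(t)) || any(t < 0)) stop("`t` must be finite and >= 0")
  vapply(t, function(ti) {
    row <- transient_distribution(blocks, ti, start)
    den <- sum(row)
    guard_survival(den)
    -sum((row %*% blocks$Qstar)) / den
  }, numeric(1))
}

#' Cause-specific hazard rates
#'
#' Instantaneous rate of absorption into one named fate given no absorption
#' of any kind so far:
#' `lambda_{ij}(t) = [e_i exp(Qstar t) V]_j / (e_i exp(Qstar t) 1)` for
#' `j` in `{S, P}`. The two cause-specific rates sum to [hazard()].
#'
#' @inheritParams hazard
#' @param target `"S"` (subfunctionalization) or `"P"` (pseudogenization).
#' @export
cause_specific_hazard <- function(model, t, start = 0, target = c("P", "S"),
                                  dimensionless = FALSE) {
  target <- match.arg(target)
  blocks <- nondim_blocks(model, dimensionless)
  if (any(!is.finite(t)) || any(t < 0)) stop("`t` must be finite and >= 0")
  v <- if (target == "S") blocks$v_S else blocks$v_P
  vapply(t, function(ti) {
    row <- transient_distribution(blocks, ti, start)
    den <- sum(row)
    guard_survival(den)
    sum(row * v) / den
  }, numeric(1))
}

#' Distribution of the pseudogenization time
#'
#' `pseudo_cdf` returns `F(t) = P(T_P <= t) =
#' e_0 (exp(Qstar t) - I) Qstar^{-1} v_P`, the (defective) cumulative
#' distribution of the pseudogenization time `T_P`; its limit as
#' `t -> Inf` is the pseudogenization probability `p_P < 1`, because with
#' probability `p_S` the pair subfunctionalizes and is never lost.
#' `pseudo_survival` is `1 - F(t)`.
#'
#' @inheritParams hazard
#' @export
pseudo_cdf <- function(model, t, dimensionless = FALSE) {
  blocks <- nondim_blocks(model, dimensionless)
  if (any(!is.finite(t)) || any(t < 0)) stop("`t` must be finite and >= 0")
  w <- backsolve(blocks$Qstar, blocks$v_P)
  vapply(t, function(ti) {
    E <- expm_mat(blocks$Qstar * ti)
    sum(E[1, ] * w) - w[1]
  }, numeric(1))
}

#' @rdname pseudo_cdf
#' @export
pseudo_survival <- function(model, t, dimensionless = FALSE) {
  1 - pseudo_cdf(model, t, dimensionless)
}

#' Pseudogenization rate
#'
#' The instantaneous rate of pseudogenization conditioning only on
#' pseudogenization not having occurred — subfunctionalized pairs stay in
#' the risk-set denominator forever:
#' `h_P(t) = e_0 exp(Qstar t) v_P / (1 - e_0 (exp(Qstar t) - I) Qstar^{-1} v_P)`.
#' Unlike the cause-specific hazard, `h_P(t) -> 0` as `t -> Inf` whenever
#' `u_r > 0`: conditional on no loss, subfunctionalization eventually
#' protects both copies. Negative `t` is allowed as an analytic
#' continuation used by the shape diagnostics; the denominator can reach 0
#' there, which is reported as an error rather than clipped.
#'
#' @inheritParams hazard
#' @param t vector of times; any real value is accepted.
#' @export
pseudo_rate <- function(model, t, dimensionless = FALSE) {
  blocks <- nondim_blocks(model, dimensionless)
  if (any(!is.finite(t))) stop("`t` must be finite")
  w <- backsolve(blocks$Qstar, blocks$v_P)
  vapply(t, function(ti) {
    E <- expm_mat(blocks$Qstar * ti)
    num <- sum(E[1, ] * blocks$v_P)
    den <- 1 - (sum(E[1, ] * w) - w[1])
    if (den <= 0)
      stop(sprintf("pseudo-rate denominator is %g <= 0 at t = %g (outside the
  domain of the analytic continuation)", den, ti))
    guard_survival(den)
    num / den
  }, numeric(1))
}

#' Pseudogenization rate averaged over a prior on z
#'
#' Mixture `H_P(t) = sum_z p_z h_P^z(t)` over a [z_prior()] distribution on
#' the number of regulatory regions, all components sharing `u_c`, `u_r`.
#'
#' @param prior a [z_prior()].
#' @param u_c,u_r shared mutation-fixation rates.
#' @inheritParams pseudo_rate
#' @export
avg_pseudo_rate <- function(prior, u_c, u_r, t, dimensionless = FALSE) {
  stopifnot(inherits(prior, "z_prior"))
  if (length(prior$support) == 0) stop("z prior has empty support")
  out <- 0
  for (j in seq_along(prior$support)) {
    m <- duplicate_model(prior$support[j], u_c, u_r)
    out <- out + prior$weights[j] * pseudo_rate(m, t, dimensionless)
  }
  out
}

#' Piecewise-constant hazard approximation
#'
#' Historical piecewise-constant approximation of the pseudogenization
#' cause-specific hazard, on breakpoints `t_i = t_{i-1} + E(dT_i)` where
#' `E(dT_i) = 1/|Qstar[i-1, i-1]|` is the expected sojourn of transient
#' state `i-1`. The corrected form is `2 u_c` on `[0, t_1)`, `u_c` on
#' `[t_1, t_{z-1})` and `u_c + u_r` for `t >= t_{z-1}`. The uncorrected
#' (erroneous) variant instead drops to 0 for `t >= t_z`, i.e. it assumes
#' subfunctionalization happens at exactly the z-th mutation time; it is
#' kept for comparison.
#'
#' @inheritParams hazard
#' @param corrected logical; `FALSE` gives the historical erroneous form.
#' @export
piecewise_hazard_approx <- function(model, t, corrected = TRUE,
                                    dimensionless = FALSE) {
  blocks <- nondim_blocks(model, dimensionless)
  if (any(!is.finite(t)) || any(t < 0)) stop("`t` must be finite and >= 0")
  m <- blocks$model
  sojourn <- 1 / abs(diag(blocks$Qstar))
  tk <- cumsum(sojourn)           # t_1 .. t_z
  t1 <- tk[1]; tzm1 <- tk[m$z - 1]; tz <- tk[m$z]
  out <- ifelse(t < t1, 2 * m$u_c, ifelse(t < tzm1, m$u_c, m$u_c + m$u_r))
  if (!corrected) out[t >= tz] <- 0
  out
}

#' Reference exponential survival for the no-subfunctionalization case
#'
#' With `z = 1` or `u_r = 0` subfunctionalization is impossible and the
#' duplicate-pair survival reduces to `exp(-2 (u_c + u_r) t)`.
#'
#' @param t times.
#' @param u_c,u_r rates as in [duplicate_model()].
#' @export
exponential_survival <- function(t, u_c, u_r = 0) exp(-2 * (u_c + u_r) * t)

#' Tabulate a rate function over a time grid
#'
#' @inheritParams hazard
#' @param times strictly increasing evaluation times.
#' @param which one of `"hazard"`, `"cause_specific_S"`,
#'   `"cause_specific_P"`, `"pseudo_rate"`, `"piecewise"`.
#' @return A data frame `(time, rate)` of class `"rate_curve"` carrying the
#'   producing model and rate name as attributes.
#' @export
rate_curve <- function(model, times,
                       which = c("pseudo_rate", "hazard", "cause_specific_S",
                                 "cause_specific_P", "piecewise"),
                       start = 0, dimensionless = FALSE) {
  which <- match.arg(which)
  if (any(diff(times) <= 0)) stop("`times` must be strictly increasing")
  blocks <- as_blocks(model)
  vals <- switch(which,
    hazard = hazard(blocks, times, start, dimensionless),
    cause_specific_S = cause_specific_hazard(blocks, times, start, "S",
                                             dimensionless),
    cause_specific_P = cause_specific_hazard(blocks, times, start, "P",
                                             dimensionless),
    pseudo_rate = pseudo_rate(blocks, times, dimensionless),
    piecewise = piecewise_hazard_approx(blocks, times, TRUE, dimensionless))
  out <- data.frame(time = times, rate = vals)
  attr(out, "meta") <- list(which = which, model = blocks$model)
  class(out) <- c("rate_curve", "data.frame")
  out
}

#' Write a rate curve as a two-column TSV
#'
#' @param curve a [rate_curve()].
#' @param path output file path.
#' @export
write_rate_curve <- function(curve, path) {
  stopifnot(inherits(curve, "rate_curve"))
  meta <- attr(curve, "meta")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# rate: %s  z: %d  u_c: %.12g  u_r: %.12g",
                     meta$which, meta$model$z, meta$model$u_c,
                     meta$model$u_r), con)
  writeLines("time\trate", con)
  writeLines(sprintf("%.12g\t%.12g", curve$time, curve$rate), con)
  invisible(path)
}

# shared internals ----------------------------------------------------------

nondim_blocks <- function(model, dimensionless) {
  blocks <- as_blocks(model)
  if (isTRUE(dimensionless)) {
    m <- blocks$model
    blocks <- build_generator(duplicate_model(m$z, 1, m$u_r / m$u_c))
  }
  blocks
}

guard_survival <- function(den) {
  if (den < 1e-300)
    stop("survival probability underflowed below 1e-300; the rate cannot be ",
         "evaluated this deep in the tail")
  invisible(den)
}
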