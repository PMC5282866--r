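#' Parameterize the duplicate-pair subfunctionalization chain
#'
#' A pair of perfect gene duplicates carries `z` mutable regulatory regions
#' per gene. Null mutations fix in each coding region at Poisson rate `u_c`
#' and in each regulatory region at rate `u_r` (time is measured in units of
#' silent substitutions per silent site unless the caller non-dimensionalizes
#' by setting `u_c = 1`). The pair evolves as an absorbing continuous-time
#' Markov chain on states `{0, 1, ..., z-1}` (number of fixed null mutations
#' while the fate is undecided) plus two absorbing states: `S`
#' (subfunctionalization, both copies preserved) and `P` (pseudogenization,
#' one copy lost).
#'
#' `z = 1` is rejected: a single-function gene cannot subfunctionalize, and
#' the time to loss is then exponential with rate `2*(u_c + u_r)`; see
#' [exponential_survival()] for that reference model. `u_r = 0` is accepted
#' and collapses to the same exponential special case.
#'
#' @param z integer number of regulatory regions per gene, `z >= 2`.
#' @param u_c rate of fixation of null mutations in one coding region, `> 0`.
#' @param u_r rate of fixation of null mutations per regulatory region, `>= 0`.
#' @return An object of class `"duplicate_model"`.
#' @examples
#' m <- duplicate_model(z = 2, u_c = 1, u_r = 1)
#' build_generator(m)
#' @export
duplicate_model <- function(z, u_c, u_r) {
  if (length(z) != 1L || !is.finite(z) || z != round(z))
    stop("`z` must be a single integer")
  if (z < 2)
    stop("`z` must be at least 2: with z = 1 subfunctionalization cannot ",
         "occur and the loss time is exponential with rate 2*(u_c + u_r); ",
         "see exponential_survival()")
  if (length(u_c) != 1L || !is.finite(u_c) || u_c <= 0)
    stop("`u_c` must be a single positive finite rate")
  if (length(u_r) != 1L || !is.finite(u_r) || u_r < 0)
    stop("`u_r` must be a single non-negative finite rate")
  structure(list(z = as.integer(z), u_c = as.numeric(u_c),
                 u_r = as.numeric(u_r)),
            class = "duplicate_model")
}

#' @export
print.duplicate_model <- function(x, ...) {
  cat("Duplicate-pair subfunctionalization model\n")
  cat(sprintf("  z   = %d regulatory regions per gene\n", x$z))
  cat(sprintf("  u_c = %g (coding-region null fixation rate)\n", x$u_c))
  cat(sprintf("  u_r = %g (per-regulatory-region null fixation rate)\n", x$u_r))
  cat(sprintf("  gamma = u_r/u_c = %g\n", x$u_r / x$u_c))
  invisible(x)
}

#' Block decomposition of the chain's generator
#'
#' Builds the generator of the duplicate-pair chain in block form: `Qstar`
#' holds the rates among the transient states `0..z-1` (upper bidiagonal),
#' and the columns `v_S`, `v_P` hold the rates into the absorbing states.
#' Transition rates: `0 -> P` at `2*u_c`, `0 -> 1` at `2*z*u_r`; for
#' `1 <= i <= z-2`, `i -> P` at `u_c` and `i -> S`, `i -> i+1` each at
#' `(z-i)*u_r`; from `z-1`, `-> P` at `u_r + u_c` and `-> S` at `u_r`.
#' Each row of `Qstar` sums with the matching entries of `v_S` and `v_P`
#' to zero.
#'
#' @param model a [duplicate_model()].
#' @return An object of class `"generator_blocks"` with components `Qstar`
#'   (`z x z` matrix), `v_S`, `v_P` (length-`z` vectors) and `model`.
#' @export
build_generator <- function(model) {
  stopifnot(inherits(model, "duplicate_model"))
  z <- model$z; u_c <- model$u_c; u_r <- model$u_r
  Q <- matrix(0, z, z)
  v_S <- numeric(z)
  v_P <- numeric(z)
  # state 0 (row 1)
  Q[1, 1] <- -(2 * u_c + 2 * z * u_r)
  Q[1, 2] <- 2 * z * u_r
  v_P[1] <- 2 * u_c
  # states 1 .. z-2
  if (z > 2) {
    for (i in seq_len(z - 2)) {
      r <- i + 1L
      Q[r, r] <- -(u_c + 2 * (z - i) * u_r)
      Q[r, r + 1L] <- (z - i) * u_r
      v_S[r] <- (z - i) * u_r
      v_P[r] <- u_c
    }
  }
  # state z-1 (last row)
  Q[z, z] <- -(u_c + 2 * u_r)
  v_S[z] <- u_r
  v_P[z] <- u_r + u_c
  structure(list(Qstar = Q, v_S = v_S, v_P = v_P, model = model),
            class = "generator_blocks")
}

#' @export
print.generator_blocks <- function(x, ...) {
  cat(sprintf("Generator blocks for z = %d transient states\n", x$model$z))
  cat("Qstar:\n"); print(x$Qstar)
  cat("v_S:", format(x$v_S), "\n")
  cat("v_P:", format(x$v_P), "\n")
  invisible(x)
}

# Accept either a model or prebuilt blocks everywhere downstream.
as_blocks <- function(x) {
  if (inherits(x, "generator_blocks")) return(x)
  if (inherits(x, "duplicate_model")) return(build_generator(x))
  stop("expected a `duplicate_model` or `generator_blocks` object")
}

# Dense matrix exponential (scaling-and-squaring via Matrix).
expm_mat <- function(M) as.matrix(Matrix::expm(Matrix::Matrix(M)))

check_start <- function(start, z) {
  if (length(start) != 1L || !is.finite(start) || start != round(start) ||
      start < 0 || start > z - 1)
    stop("`start` must be a transient state index in 0..z-1")
  as.integer(start) + 1L
}

#' Occupancy distribution over transient states
#'
#' Row `start` of `exp(Qstar * t)`: the probability of occupying each
#' transient state at time `t` given the chain started in `start` (0-based).
#' The entries sum to at most 1; the deficit is the probability of having
#' been absorbed by time `t`. Negative `t` is permitted as an analytic
#' continuation for shape analysis and carries no probabilistic meaning.
#'
#' @param blocks a [build_generator()] result (or a `duplicate_model`).
#' @param t a single finite time.
#' @param start 0-based transient state index.
#' @return Numeric vector of length `z`.
#' @export
transient_distribution <- function(blocks, t, start = 0) {
  blocks <- as_blocks(blocks)
  if (length(t) != 1L || !is.finite(t)) stop("`t` must be a single finite time")
  row <- check_start(start, nrow(blocks$Qstar))
  expm_mat(blocks$Qstar * t)[row, ]
}

#' Probabilities of ultimate subfunctionalization and pseudogenization
#'
#' Exit probabilities of the absorbing chain:
#' `p_S = e_start (-Qstar)^{-1} v_S` and likewise for `p_P`. They sum to 1.
#'
#' @inheritParams transient_distribution
#' @return Named numeric vector `c(p_S =, p_P =)`.
#' @export
absorption_probabilities <- function(blocks, start = 0) {
  blocks <- as_blocks(blocks)
  z <- nrow(blocks$Qstar)
  row <- check_start(start, z)
  # -Qstar is upper triangular with positive diagonal: backsolve is exact
  p_S <- backsolve(-blocks$Qstar, blocks$v_S)[row]
  p_P <- backsolve(-blocks$Qstar, blocks$v_P)[row]
  c(p_S = p_S, p_P = p_P)
}

#' Moments of the time to absorption
#'
#' `E[T^k] = (-1)^k k! e_start Qstar^{-k} 1` for the time `T` until the
#' chain is absorbed (into either `S` or `P`).
#'
#' @inheritParams transient_distribution
#' @param k moment order, integer `>= 1`.
#' @return The k-th raw moment of the absorption time.
#' @export
absorption_moments <- function(blocks, k = 1, start = 0) {
  blocks <- as_blocks(blocks)
  if (length(k) != 1L || !is.finite(k) || k != round(k) || k < 1)
    stop("moment order `k` must be an integer >= 1")
  z <- nrow(blocks$Qstar)
  row <- check_start(start, z)
  x <- rep(1, z)
  for (i in seq_len(k)) x <- backsolve(-blocks$Qstar, x)
  factorial(k) * x[row]
}

#' Absorption by the n-th mutation (embedded jump chain)
#'
#' Probability that the embedded discrete-time jump chain (each jump is one
#' fixed null mutation; jump probabilities are the rates normalized by the
#' total exit rate of the current state) has been absorbed in `S`
#' (respectively `P`) at or before the n-th jump, starting from state 0.
#'
#' @param model a [duplicate_model()].
#' @param n number of mutations (jumps), integer `>= 0`.
#' @return Named numeric vector `c(q_S =, q_P =)`.
#' @export
embedded_absorption_by_n <- function(model, n) {
  blocks <- as_blocks(model)
  if (length(n) != 1L || !is.finite(n) || n != round(n) || n < 0)
    stop("`n` must be a non-negative integer")
  z <- nrow(blocks$Qstar)
  exit <- -diag(blocks$Qstar)
  # jump matrix over transient states, plus absorbing columns
  J <- blocks$Qstar / exit
  diag(J) <- 0
  jS <- blocks$v_S / exit
  jP <- blocks$v_P / exit
  p <- c(1, rep(0, z - 1))  # start in state 0
  q_S <- 0; q_P <- 0
  if (n > 0) for (i in seq_len(n)) {
    q_S <- q_S + sum(p * jS)
    q_P <- q_P + sum(p * jP)
    p <- as.numeric(p %*% J)
  }
  c(q_S = q_S, q_P = q_P)
}
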