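#' Simulate one duplicate-pair trajectory
#'
#' Exact stochastic simulation of the absorbing chain: exponential holding
#' times at each transient state's total exit rate, next state drawn with
#' probabilities proportional to the outgoing rates. The transient state
#' index is strictly increasing along any path, so every trajectory ends in
#' `S` or `P` after at most `z` jumps.
#'
#' @param model a [duplicate_model()].
#' @param seed integer seed; identical seeds give identical trajectories.
#' @return An object of class `"subfun_trajectory"`: list with
#'   `jump_times`, `states` (visited states, 0-based, ending in `"S"` or
#'   `"P"`), `outcome` and `absorption_time`.
#' @export
simulate_trajectory <- function(model, seed) {
  stopifnot(inherits(model, "duplicate_model"))
  blocks <- build_generator(model)
  sim <- function() {
    state <- 0L
    t <- 0
    times <- numeric(0)
    states <- character(0)
    repeat {
      r <- state + 1L
      exit <- -blocks$Qstar[r, r]
      t <- t + stats::rexp(1, exit)
      nxt_rates <- c(S = blocks$v_S[r], P = blocks$v_P[r],
                     up = if (r < model$z) blocks$Qstar[r, r + 1L] else 0)
      nxt <- sample(names(nxt_rates), 1, prob = nxt_rates)
      times <- c(times, t)
      if (nxt == "up") {
        state <- state + 1L
        states <- c(states, as.character(state))
      } else {
        states <- c(states, nxt)
        return(structure(list(jump_times = times, states = states,
                              outcome = nxt, absorption_time = t),
                         class = "subfun_trajectory"))
      }
    }
  }
  with_seed(seed, sim())
}

#' @export
print.subfun_trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: 0 -> %s; absorbed in %s at t = %g (%d jumps)\n",
              paste(x$states, collapse = " -> "), x$outcome,
              x$absorption_time, length(x$jump_times)))
  invisible(x)
}

#' Simulate many trajectories at once
#'
#' Vectorized version of [simulate_trajectory()] returning only the fate
#' and absorption time of each replicate pair; the workhorse behind the
#' Monte-Carlo cross-checks of the analytic phase-type formulas.
#'
#' @param model a [duplicate_model()].
#' @param n number of independent duplicate pairs.
#' @param seed integer seed.
#' @return Data frame with columns `outcome` (factor `S`/`P`) and
#'   `absorption_time`.
#' @export
simulate_ensemble <- function(model, n, seed) {
  stopifnot(inherits(model, "duplicate_model"), n >= 1)
  blocks <- build_generator(model)
  z <- model$z
  with_seed(seed, {
    time <- numeric(n)
    outcome <- character(n)
    alive <- seq_len(n)          # indices still unabsorbed, all in state 0
    for (state in 0:(z - 1L)) {
      if (!length(alive)) break
      r <- state + 1L
      exit <- -blocks$Qstar[r, r]
      time[alive] <- time[alive] + stats::rexp(length(alive), exit)
      up_rate <- if (r < z) blocks$Qstar[r, r + 1L] else 0
      pr <- c(blocks$v_S[r], blocks$v_P[r], up_rate) / exit
      u <- stats::runif(length(alive))
      to_S <- u < pr[1]
      to_P <- !to_S & u < pr[1] + pr[2]
      outcome[alive[to_S]] <- "S"
      outcome[alive[to_P]] <- "P"
      alive <- alive[!(to_S | to_P)]
    }
    data.frame(outcome = factor(outcome, levels = c("S", "P")),
               absorption_time = time)
  })
}

#' Simulate a binned count data set
#'
#' Draws independent Poisson counts `D_i ~ Poisson(beta0 * S(s_i))` on the
#' grid `s_i = bin_width * i`, exactly the generative law the likelihood
#' assumes for genome duplicate-pair data.
#'
#' @param model a [duplicate_model()].
#' @param dup a [duplication_model()] or bare `beta0`.
#' @param n_bins number of bins.
#' @param bin_width bin width on the `s` axis (default 0.01).
#' @param seed integer seed.
#' @return A [binned_counts()] object.
#' @export
simulate_counts <- function(model, dup, n_bins, bin_width = 0.01, seed) {
  stopifnot(inherits(model, "duplicate_model"), n_bins >= 1)
  beta0 <- as_beta0(dup)
  s <- bin_width * seq_len(n_bins)
  mu <- beta0 * surv_grid(model$z, model$u_c, model$u_r, s)
  counts <- with_seed(seed, stats::rpois(n_bins, pmax(mu, 0)))
  binned_counts(counts, s = s, bin_width = bin_width)
}

#' Parameter-recovery experiment
#'
#' Simulates replicate binned data sets from known truth, refits each with
#' [fit_mle()], computes e2 profile intervals at the fitted `z`, and
#' tallies how often each continuous parameter's interval covers its true
#' value. Also records the spread of the fitted `z` and `gamma = u_r/u_c`
#' across replicates — with few bins the `z` estimate is unstable even
#' though the truth stays inside the likelihood intervals.
#'
#' @param truth named list or vector with `z`, `u_c`, `u_r`, `beta0`.
#'   Defaults to a rat-genome-like parameter set.
#' @param n_bins bins per simulated data set.
#' @param replicates number of simulated data sets.
#' @param seed base seed; replicate `r` uses `seed + r`.
#' @param z_grid grid for the refit (default 2:20).
#' @param n_starts optimizer starts per `z` per replicate.
#' @param fix_z if `TRUE`, condition the refit and intervals on the true `z`
#'   instead of the grid-selected one.
#' @param intervals if `FALSE`, skip the profile intervals (and hence the
#'   coverage tally), reporting only the `z`/`gamma` estimate spread; much
#'   faster when only the selection instability is of interest.
#' @return An object of class `"recovery_report"`: coverage proportions,
#'   per-replicate estimates, interval widths and failure tally.
#' @export
recovery_experiment <- function(truth = list(z = 2, u_c = 3.04, u_r = 0.67,
                                             beta0 = 204.04),
                                n_bins = 30, replicates = 20, seed = 1L,
                                z_grid = 2:20, n_starts = 6,
                                fix_z = FALSE, intervals = TRUE) {
  stopifnot(replicates >= 1)
  truth <- as.list(truth)
  m <- duplicate_model(truth$z, truth$u_c, truth$u_r)
  pars <- c("u_r", "u_c", "beta0")
  covered <- matrix(NA, replicates, 3, dimnames = list(NULL, pars))
  widths <- matrix(NA, replicates, 3, dimnames = list(NULL, pars))
  z_hat <- integer(replicates)
  gamma_hat <- numeric(replicates)
  failures <- 0L
  for (r in seq_len(replicates)) {
    sr <- seed + r
    dat <- simulate_counts(m, truth$beta0, n_bins, seed = sr)
    res <- tryCatch({
      grid <- if (fix_z) truth$z else z_grid
      fit <- fit_mle(dat, z_grid = grid, n_starts = n_starts, seed = sr)
      ivs <- if (intervals)
        lapply(stats::setNames(nm = pars), function(p)
          profile_interval(dat, fit$z_hat, p, fit = fit, seed = sr))
      list(fit = fit, ivs = ivs)
    }, error = function(e) NULL)
    if (is.null(res)) { failures <- failures + 1L; next }
    z_hat[r] <- res$fit$z_hat
    gamma_hat[r] <- res$fit$mle["u_r"] / res$fit$mle["u_c"]
    if (intervals) for (p in pars) {
      iv <- res$ivs[[p]]
      covered[r, p] <- iv$lower <= truth[[p]] && truth[[p]] <= iv$upper
      widths[r, p] <- iv$upper - iv$lower
    }
  }
  structure(list(truth = truth, n_bins = n_bins, replicates = replicates,
                 coverage = colMeans(covered, na.rm = TRUE),
                 covered = covered, interval_widths = widths,
                 z_hat = z_hat, gamma_hat = gamma_hat,
                 failures = failures, fix_z = fix_z, seed = seed),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("Recovery experiment: %d replicates, %d bins, truth z = %d\n",
              x$replicates, x$n_bins, x$truth$z))
  if (all(is.finite(x$coverage)))
    cat("  e2-interval coverage:",
        paste(sprintf("%s %.0f%%", names(x$coverage), 100 * x$coverage),
              collapse = ", "), "\n")
  cat("  z_hat distribution:",
      paste(sprintf("%d (x%d)", as.integer(names(table(x$z_hat))),
                    as.integer(table(x$z_hat))), collapse = ", "), "\n")
  cat(sprintf("  gamma_hat range: [%.3g, %.3g] (truth %.3g)\n",
              min(x$gamma_hat), max(x$gamma_hat),
              x$truth$u_r / x$truth$u_c))
  if (x$failures) cat(sprintf("  %d replicate fits failed\n", x$failures))
  invisible(x)
}
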