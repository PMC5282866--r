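# Fast evaluation of the pseudogenization-time survival on a time grid.
#
# The generator block Qstar is upper bidiagonal, so its eigenvalues are the
# diagonal entries. When they are pairwise distinct the survival
#   S(t) = 1 - e_0 (exp(Qstar t) - I) Qstar^{-1} v_P
# is a plain exponential mixture, evaluated for a whole grid of times with
# one eigendecomposition. Confluent (or nearly confluent, relative gap
# < 1e-9) eigenvalues make the eigenvector basis ill-conditioned; then we
# fall back to a dense matrix exponential per time point. Correctness over
# micro-optimization: the fallback is exact, just slower.

surv_grid <- function(z, u_c, u_r, times) {
  # inline generator construction: this sits inside optimizer loops
  Q <- matrix(0, z, z)
  v_P <- c(2 * u_c, rep(u_c, max(z - 2, 0)), u_r + u_c)
  diag(Q) <- -c(2 * u_c + 2 * z * u_r,
                if (z > 2) u_c + 2 * ((z - 1):2) * u_r,
                u_c + 2 * u_r)
  Q[cbind(1:(z - 1), 2:z)] <- c(2 * z * u_r,
                                if (z > 2) ((z - 1):2) * u_r)
  w <- backsolve(Q, v_P)
  d <- diag(Q)
  gap <- min(abs(diff(sort(d)))) / max(abs(d))
  if (is.finite(gap) && gap > 1e-9) {
    ev <- eigen(Q, symmetric = FALSE)
    coef <- ev$vectors[1, ] * solve(ev$vectors, w)
    s <- 1 + w[1] - as.numeric(exp(outer(times, ev$values)) %*% coef)
  } else {
    s <- vapply(times, function(ti) {
      E <- expm_mat(Q * ti)
      1 + w[1] - sum(E[1, ] * w)
    }, numeric(1))
  }
  s
}

# Mixture survival over a z prior with shared rates.
surv_grid_mixture <- function(weights, support, u_c, u_r, times) {
  s <- numeric(length(times))
  for (j in seq_along(support))
    s <- s + weights[j] * surv_grid(support[j], u_c, u_r, times)
  s
}
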