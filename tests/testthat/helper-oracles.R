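# Independent oracles used across the suite. Everything here is deliberately
# written from first principles (closed-form 2x2 algebra, path enumeration,
# finite differences) and never calls the package's matrix-exponential code
# paths it is meant to check.

# Closed-form row 0 of exp(M t) for upper-triangular 2x2 M = [[a, b], [0, d]]
# with distinct diagonal entries.
expm2_row0 <- function(a, b, d, t) {
  c(exp(a * t), b * (exp(d * t) - exp(a * t)) / (d - a))
}

# Brute-force absorption probabilities by enumerating all embedded-chain
# paths (the transient state index strictly increases, so the path tree is
# finite). Works for any z, intended for small z.
enumerate_absorption <- function(model) {
  blocks <- build_generator(model)
  z <- model$z
  p_S <- 0; p_P <- 0
  recurse <- function(state, prob) {
    r <- state + 1L
    exit <- -blocks$Qstar[r, r]
    p_S <<- p_S + prob * blocks$v_S[r] / exit
    p_P <<- p_P + prob * blocks$v_P[r] / exit
    if (r < z) recurse(state + 1L, prob * blocks$Qstar[r, r + 1L] / exit)
  }
  recurse(0L, 1)
  c(p_S = p_S, p_P = p_P)
}

# Central finite differences of the pseudogenization rate.
fd_pseudo_rate <- function(model, t, order = 1, h = 1e-5) {
  if (order == 1)
    (pseudo_rate(model, t + h) - pseudo_rate(model, t - h)) / (2 * h)
  else
    (pseudo_rate(model, t + h) - 2 * pseudo_rate(model, t) +
       pseudo_rate(model, t - h)) / h^2
}

# Hand-derived closed forms for h_P''(0) as a function of gamma (u_c = 1):
# obtained by expanding e_0 Q^k v_P for the first two rows of the generator.
h2_at_zero <- function(z, gamma) {
  if (z == 2) -4 * gamma * (3 * gamma - 1) * (2 * gamma - 1)
  else if (z == 3) 6 * gamma * (2 * gamma^2 + 4 * gamma - 1)
  else 2 * z * gamma * ((z + 1) * gamma - 1)
}

# Survival P(T > t) of the total absorption time, via the eigenstructure of
# the (distinct-diagonal) triangular generator; independent of expm.
surv_T_mix <- function(model, times) {
  blocks <- build_generator(model)
  ev <- eigen(blocks$Qstar, symmetric = FALSE)
  coef <- ev$vectors[1, ] * solve(ev$vectors, rep(1, model$z))
  as.numeric(exp(outer(times, ev$values)) %*% coef)
}

rand_model <- function(z = sample(2:12, 1), u_c = runif(1, 0.2, 5),
                       gamma = runif(1, 0.01, 0.9)) {
  duplicate_model(z, u_c, gamma * u_c)
}
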