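# small cohorts and an independent RK4 oracle used across tests

small_cohort <- function(n = 4, seed = 1, ...) {
  generate_cohort(cohort_config(n_hd = n, n_control = n, seed = seed, ...))
}

# independent fixed-step RK4 oracle (pure R, step h), integrating
# dx/dt = A x + c * u(t) outward from t = 0
rk4_oracle <- function(x0, A, cfun = NULL, times, h = 0.01) {
  rhs <- function(t, x) {
    dx <- drop(A %*% x)
    if (!is.null(cfun)) dx <- dx + cfun(t)
    dx
  }
  one <- function(tt) {
    x <- x0; t <- 0
    while (abs(tt - t) > 1e-12) {
      s <- sign(tt - t) * min(h, abs(tt - t))
      k1 <- rhs(t, x)
      k2 <- rhs(t + s / 2, x + s / 2 * k1)
      k3 <- rhs(t + s / 2, x + s / 2 * k2)
      k4 <- rhs(t + s, x + s * k3)
      x <- x + s / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t + s
    }
    x
  }
  t(vapply(times, one, numeric(length(x0))))
}

# analytic log evidence of y ~ N(X mu0, lam^-1 I + X S0 X')
linear_evidence <- function(y, X, mu0, v0, lam) {
  S <- diag(length(y)) / lam + X %*% (v0 * t(X))
  r <- y - drop(X %*% mu0)
  L <- chol(S)
  -length(y) / 2 * log(2 * pi) - sum(log(diag(L))) -
    0.5 * sum(backsolve(L, r, transpose = TRUE)^2)
}

# design matrix of the constant-rate model (y = X theta), matching the
# parameter layout of prior_spec(state_model_spec("constant_rate"))
constant_design <- function(times) {
  tab <- hd_region_table()
  nm <- names(prior_spec(state_model_spec("constant_rate"))$mean)
  X <- matrix(0, length(times) * 55, length(nm), dimnames = list(NULL, nm))
  for (col in 1:55) {
    i <- tab$state[col]
    rows <- (col - 1) * length(times) + seq_along(times)
    X[rows, paste0("x0.", hd_state_names()[i])] <- 1
    X[rows, paste0("c0.", hd_state_names()[i])] <- times
  }
  X
}
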