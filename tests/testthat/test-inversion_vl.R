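test_that("variational Laplace equals the conjugate posterior for linear
           models with fixed noise precision", {
  coh <- small_cohort(2, seed = 11, dynamics_form = "constant_rate")
  ss <- subject_series(coh, "HD01")
  spec <- state_model_spec("constant_rate")
  priors <- prior_spec(spec)
  fit <- fit_subject(ss, spec, priors,
                     vl_settings(fixed_gamma = list(volumes = 0)))
  X <- constant_design(ss$times)
  y <- as.vector(ss$volumes)
  P0 <- 1 / priors$var
  Ppost <- crossprod(X); diag(Ppost) <- diag(Ppost) + P0
  mpost <- solve(Ppost, crossprod(X, y) + P0 * priors$mean)
  expect_lt(max(abs(fit$mean - drop(mpost))), 1e-6)
  expect_lt(max(abs(fit$covariance - solve(Ppost))), 1e-6)
  # free energy equals the analytic log marginal likelihood
  expect_equal(fit$free_energy,
               linear_evidence(y, X, priors$mean, priors$var, 1),
               tolerance = 1e-6)
  # and the standalone evaluator agrees at the fitted posterior
  expect_equal(free_energy(fit, ss, spec, priors), fit$free_energy,
               tolerance = 1e-6)
})

test_that("free energy behaves like a log evidence", {
  coh <- small_cohort(2, seed = 12, dynamics_form = "constant_rate")
  ss <- subject_series(coh, "HD01")
  spec <- state_model_spec("constant_rate")
  st <- vl_settings(fixed_gamma = list(volumes = 0))
  X <- constant_design(ss$times)
  y <- as.vector(ss$volumes)

  # widening a redundant parameter's prior strictly decreases F on data
  # that does not use it (flat control-like series)
  flat <- ss
  flat$volumes <- matrix(100, nrow(ss$volumes), 55,
                         dimnames = dimnames(ss$volumes))
  pr1 <- prior_spec(spec)
  pr2 <- prior_spec(spec, var = c("c0.putamen" = 25))
  f1 <- fit_subject(flat, spec, pr1, st)
  f2 <- fit_subject(flat, spec, pr2, st)
  expect_lt(f2$free_energy, f1$free_energy)
  expect_equal(f1$free_energy,
               linear_evidence(as.vector(flat$volumes), X, pr1$mean,
                               pr1$var, 1), tolerance = 1e-6)

  # permutation of observations leaves F unchanged
  perm <- sample(nrow(ss$volumes))
  ssp <- list(id = ss$id, times = ss$times[perm],
              volumes = ss$volumes[perm, , drop = FALSE])
  fa <- fit_subject(ss, spec, pr1, st)
  fb <- fit_subject(ssp, spec, pr1, st)
  expect_equal(fa$free_energy, fb$free_energy, tolerance = 1e-6)
})

test_that("the optimizer is monotone, converges, and flags failure", {
  coh <- small_cohort(3, seed = 14)
  spec <- state_model_spec("dynamic")
  for (id in c("HD01", "HD02", "C01")) {
    fit <- fit_subject(subject_series(coh, id), spec)
    expect_true(fit$converged)
    expect_true(all(diff(fit$F_trace) > -1e-6))  # monotone accepted steps
  }
  # hitting max_iter is reported, never silent
  f0 <- fit_subject(subject_series(coh, "HD01"), spec,
                    settings = vl_settings(max_iter = 2))
  expect_false(f0$converged)
  expect_error(fit_subject(list(times = 0:4,
                                volumes = matrix(NA_real_, 5, 55)),
                           spec), "non-finite|match")
  ss3 <- subject_series(coh, "HD01")
  expect_error(fit_subject(list(times = ss3$times[1:2],
                                volumes = ss3$volumes[1:2, ]), spec),
               "3 visits")
})

test_that("noise-free data recovers generative parameters and the prior
           mean is a fixed point", {
  states <- hd_state_names()
  zero <- setNames(numeric(28), states)
  cfg <- cohort_config(n_hd = 2, n_control = 2, noise_sd = 1e-8,
                       cag_slope = zero, behavior = FALSE, seed = 15)
  coh <- generate_cohort(cfg)
  spec <- state_model_spec("dynamic")
  fit <- fit_subject(subject_series(coh, "HD01"), spec)
  truth <- coh$truth[["HD01"]]$params
  expect_lt(max(abs(fit$mean[paste0("x0.", states)] - truth$x0) /
                  truth$x0), 1e-3)
  # identifiable decays (striatal + occipital, decay >= 0.3%/yr)
  ident <- states[cfg$true_decay$hd >= 0.003]
  expect_lt(max(abs(fit$mean[paste0("lambda.", ident)] -
                      truth$log_decay[match(ident, states)]) /
                  abs(truth$log_decay[match(ident, states)])), 1e-3)

  # data generated exactly at the prior mean: posterior stays there
  pr <- prior_spec(spec)
  pl <- hdprog:::.unpack_params(pr$mean, spec)
  tt <- -3:3
  y <- observe_states(integrate_states(spec, pl, tt), spec, pl)
  f2 <- fit_subject(list(times = tt, volumes = y), spec, pr)
  expect_lt(max(abs(f2$mean - pr$mean)), 1e-4)
  expect_true(is.finite(f2$free_energy))
})

test_that("posterior intervals cover the truth and tighten with visits", {
  # coverage: 95% central intervals on log decay across HD subjects
  cfg <- cohort_config(n_hd = 25, n_control = 1, seed = 16,
                       behavior = FALSE)
  coh <- generate_cohort(cfg)
  spec <- state_model_spec("dynamic")
  states <- hd_state_names()
  hits <- total <- 0
  for (id in coh$subjects$id[coh$subjects$group == "HD"]) {
    fit <- fit_subject(subject_series(coh, id), spec)
    truth <- coh$truth[[id]]$params$log_decay
    idx <- match(paste0("lambda.", states), names(fit$mean))
    sd_ <- sqrt(diag(fit$covariance)[idx])
    inside <- abs(fit$mean[idx] - truth) < 1.96 * sd_
    hits <- hits + sum(inside); total <- total + length(inside)
  }
  expect_gte(hits / total, 0.90)

  # covariance trace shrinks as visits grow from 3 to 7
  cfg3 <- cohort_config(n_hd = 1, n_control = 1, seed = 17,
                        visit_count_law = c(`3` = 1), visit_start = -1,
                        behavior = FALSE)
  cfg7 <- cohort_config(n_hd = 1, n_control = 1, seed = 17,
                        visit_count_law = c(`7` = 1), visit_start = -3,
                        behavior = FALSE)
  f3 <- fit_subject(subject_series(generate_cohort(cfg3), "HD01"), spec)
  f7 <- fit_subject(subject_series(generate_cohort(cfg7), "HD01"), spec)
  expect_lt(sum(diag(f7$covariance)), sum(diag(f3$covariance)))
})

test_that("behavioural channels are fitted with their own noise precision", {
  cfg <- cohort_config(n_hd = 2, n_control = 2, seed = 18,
                       behavior_noise_sd = 2)
  coh <- generate_cohort(cfg)
  spec <- state_model_spec("dynamic", behavior_channels = c("tms", "sdmt"))
  ss <- subject_series(coh, "HD01")
  fit <- fit_subject(ss, spec)
  expect_length(fit$gamma$mean, 2)
  expect_true(fit$converged)
  # score predictions at the posterior track the observations
  pl <- hdprog:::.unpack_params(fit$mean, spec)
  y <- observe_states(integrate_states(spec, pl, ss$times), spec, pl)
  expect_lt(sqrt(mean((y[, "tms"] - ss$behavior[, "tms"])^2)), 6)
  expect_error(fit_subject(list(times = ss$times, volumes = ss$volumes),
                           spec), "behaviour")
})
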