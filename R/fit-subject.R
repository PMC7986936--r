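#' Settings for variational-Laplace model inversion
#'
#' @param max_iter Maximum outer iterations.
#' @param tol Free-energy convergence tolerance; convergence is declared when
#'   `|dF| < tol` for `tol_run` consecutive accepted iterations.
#' @param tol_run Length of the converged run.
#' @param fd_step Relative finite-difference step for numerical Jacobians.
#' @param fixed_gamma Optional named list freezing log noise precisions,
#'   e.g. `list(volumes = 0)` or `list(volumes = 0, behavior = -3)`; frozen
#'   blocks contribute no hyperparameter uncertainty to the free energy.
#' @param gamma_bounds Bounds on log noise precisions.
#' @param init_from_data Initialize `x0` from the visit closest to `t = 0`?
#' @return List of settings.
#' @export
vl_settings <- function(max_iter = 128, tol = 1e-3, tol_run = 4,
                        fd_step = 1e-4, fixed_gamma = NULL,
                        gamma_bounds = c(-20, 25), init_from_data = TRUE) {
  list(max_iter = max_iter, tol = tol, tol_run = tol_run, fd_step = fd_step,
       fixed_gamma = fixed_gamma, gamma_bounds = gamma_bounds,
       init_from_data = init_from_data)
}

# prediction matrix [T x (55 + channels)] for packed parameters
.predict_obs <- function(theta, spec, times) {
  pl <- .unpack_params(theta, spec)
  traj <- integrate_states(spec, pl, times)
  observe_states(traj, spec, pl)
}

# Prediction and Jacobian together, using the cheapest available route:
# exact design matrices for the linear-in-parameter forms, analytic
# derivatives for the diagonal dynamic form, batched C++ finite differences
# for the sigmoid-input and edged dynamic forms, and generic elementwise
# finite differences otherwise.
.model_eval_pred_jac <- function(theta, spec, times, fd_step = 1e-4) {
  nT <- length(times)
  st <- hd_state_names()
  n <- spec$n_states
  map_state_jac <- function(Jst) {
    # Jst: rows vec([T x state]), cols = dynamic params; expand to regions
    ncolumns <- length(spec$region_labels)
    J <- matrix(0, nT * ncolumns, ncol(Jst))
    for (col in seq_len(ncolumns)) {
      i <- spec$state_to_region[col]
      J[(col - 1L) * nT + seq_len(nT), ] <-
        Jst[(i - 1L) * nT + seq_len(nT), ]
    }
    J
  }
  if (spec$form == "dynamic_sigmoid" && is.null(spec$connectivity) &&
      is.null(spec$behavior_channels)) {
    res <- .traj_rk4_jac(theta[paste0("lambda.", st)],
                         theta[paste0("c0.", st)],
                         theta[["t0"]], theta[["log_tau"]],
                         theta[paste0("x0.", st)], times,
                         h = 0.05, fd = fd_step)
    X <- matrix(res[, 1], nT, n)
    pred <- X[, spec$state_to_region, drop = FALSE]
    colnames(pred) <- spec$region_labels
    J <- map_state_jac(res[, -1, drop = FALSE])
    colnames(J) <- names(theta)
    return(list(pred = pred, J = J))
  }
  if (spec$form == "dynamic" && !is.null(spec$connectivity) &&
      is.null(spec$behavior_channels)) {
    enm <- sprintf("edge.%d->%d", spec$connectivity[, 1],
                   spec$connectivity[, 2])
    res <- .traj_lingen_jac(theta[paste0("lambda.", st)],
                            spec$connectivity, theta[enm],
                            theta[paste0("x0.", st)], times, fd = fd_step)
    X <- matrix(res[, 1], nT, n)
    pred <- X[, spec$state_to_region, drop = FALSE]
    colnames(pred) <- spec$region_labels
    J <- map_state_jac(res[, -1, drop = FALSE])
    colnames(J) <- names(theta)
    return(list(pred = pred, J = J))
  }
  list(pred = .predict_obs(theta, spec, times),
       J = .jacobian_obs(theta, spec, times, fd_step))
}

# Jacobian of the vectorized prediction (column-major stacking of the
# observation matrix) with respect to theta.  Analytic for the linear-in-
# parameter forms and the diagonal dynamic form; finite differences
# otherwise (relative step fd_step).
.jacobian_obs <- function(theta, spec, times, fd_step = 1e-4,
                          pred0 = NULL) {
  nT <- length(times)
  nm <- names(theta)
  ncolumns <- length(spec$region_labels) + length(spec$behavior_channels)
  analytic_linear <- spec$form %in% c("constant_rate", "quadratic_rate") &&
    is.null(spec$behavior_channels)
  analytic_dyn <- spec$form == "dynamic" && is.null(spec$connectivity)
  J <- matrix(0, nT * ncolumns, length(theta), dimnames = list(NULL, nm))
  st_of_col <- spec$state_to_region
  row_idx <- function(col) (col - 1L) * nT + seq_len(nT)
  if (analytic_linear) {
    for (col in seq_along(st_of_col)) {
      i <- st_of_col[col]
      rows <- row_idx(col)
      J[rows, paste0("x0.", hd_state_names()[i])] <- 1
      J[rows, paste0("c0.", hd_state_names()[i])] <- times
      if (spec$form == "quadratic_rate")
        J[rows, paste0("c1.", hd_state_names()[i])] <- times^2 / 2
    }
    return(J)
  }
  if (analytic_dyn) {
    st <- hd_state_names()
    x0 <- theta[paste0("x0.", st)]
    a <- -exp(theta[paste0("lambda.", st)])
    E <- exp(outer(times, a))                       # [T x 28]
    X <- sweep(E, 2, x0, `*`)                       # states
    dX_dl <- X * outer(times, a)                    # d x / d lambda
    for (col in seq_along(st_of_col)) {
      i <- st_of_col[col]
      rows <- row_idx(col)
      J[rows, paste0("x0.", st[i])] <- E[, i]
      J[rows, paste0("lambda.", st[i])] <- dX_dl[, i]
    }
    for (ch in spec$behavior_channels) {
      col <- length(st_of_col) + match(ch, spec$behavior_channels)
      rows <- row_idx(col)
      w <- theta[paste0("w.", ch, ".", st)]
      J[rows, paste0("w.", ch, ".", st)] <- X
      J[rows, paste0("b.", ch)] <- 1
      J[rows, paste0("x0.", st)] <- sweep(E, 2, w, `*`)
      J[rows, paste0("lambda.", st)] <- sweep(dX_dl, 2, w, `*`)
    }
    return(J)
  }
  # generic finite differences
  if (is.null(pred0)) pred0 <- .predict_obs(theta, spec, times)
  for (j in seq_along(theta)) {
    h <- fd_step * max(1, abs(theta[j]))
    th <- theta; th[j] <- th[j] + h
    J[, j] <- (as.vector(.predict_obs(th, spec, times)) -
                 as.vector(pred0)) / h
  }
  J
}

# Free energy and Gauss-Newton posterior at a given expansion point.
# Returns F plus the ingredients reused by the optimizer.
.vl_eval <- function(theta, gamma, data_y, spec, times, priors, settings,
                     J = NULL) {
  mu0 <- priors$mean; v0 <- priors$var
  if (is.null(J)) {
    pj <- .model_eval_pred_jac(theta, spec, times, settings$fd_step)
    J <- pj$J
    pred <- pj$pred
  } else {
    pred <- .predict_obs(theta, spec, times)
  }
  r <- as.vector(data_y) - as.vector(pred)
  nT <- length(times)
  n_reg <- length(spec$region_labels)
  n_ch <- length(spec$behavior_channels)
  block <- rep(c(rep(1L, n_reg), rep(2L, n_ch)), each = nT)
  lam_obs <- exp(gamma)[block]
  P0 <- 1 / v0
  H <- crossprod(J * lam_obs, J)
  diag(H) <- diag(H) + P0
  R <- tryCatch(chol(H), error = function(e) NULL)
  if (is.null(R)) return(list(F = -Inf))
  Sigma <- chol2inv(R)
  # E_q log-likelihood (quadratic expansion) and KL against the prior
  JS <- J %*% Sigma
  tr_obs <- rowSums(JS * J)                       # per-observation tr(J S J')
  S_block <- vapply(seq_along(gamma), function(b) {
    sel <- block == b
    sum(r[sel]^2) + sum(tr_obs[sel])
  }, numeric(1))
  N_block <- tabulate(block, nbins = length(gamma))
  Eacc <- sum(-N_block / 2 * log(2 * pi) + N_block / 2 * gamma -
                exp(gamma) / 2 * S_block)
  dm <- theta - mu0
  KLth <- 0.5 * (sum(diag(Sigma) * P0) + sum(dm^2 * P0) - length(theta) +
                   sum(log(v0)) + 2 * sum(log(diag(R))))
  # hyperparameter factors (Laplace)
  gpri <- list(priors$noise, priors$behavior_noise)
  KLg <- 0
  vg <- numeric(length(gamma))
  for (b in seq_along(gamma)) {
    if (.gamma_fixed(settings, b)) { vg[b] <- 0; next }
    g0 <- gpri[[b]]$mean; vv0 <- gpri[[b]]$var
    vg[b] <- 1 / (exp(gamma[b]) * S_block[b] / 2 + 1 / vv0)
    KLg <- KLg + 0.5 * (vg[b] / vv0 + (gamma[b] - g0)^2 / vv0 - 1 +
                          log(vv0 / vg[b]))
  }
  list(F = Eacc - KLth - KLg, Sigma = Sigma, J = J, r = r,
       S_block = S_block, N_block = N_block, block = block,
       gamma_var = vg, logdetH = 2 * sum(log(diag(R))))
}

.gamma_fixed <- function(settings, b) {
  fg <- settings$fixed_gamma
  if (is.null(fg)) return(FALSE)
  nm <- c("volumes", "behavior")[b]
  !is.null(fg[[nm]])
}

#' Invert a subject-level state model by variational Laplace
#'
#' Fits one subject's regional volume time series (and optional behavioural
#' channels) under a Gaussian likelihood with shared log noise precision(s),
#' maximizing the variational free energy F (an accuracy-minus-complexity
#' bound on log model evidence, exact for linear-Gaussian models) by
#' Gauss-Newton ascent with Levenberg-Marquardt damping. Steps are accepted
#' only when they increase F, so F is nondecreasing across accepted
#' iterations; log noise precisions are updated by damped Newton steps with
#' their own Laplace factors.
#'
#' @param data A [subject_series()] or list with `times`, `volumes`
#'   (visits x 55, columns in region-table order) and optionally `behavior`.
#' @param spec A [state_model_spec()].
#' @param priors A [prior_spec()] (defaults to `prior_spec(spec)`).
#' @param settings A [vl_settings()].
#' @return Object of class `subject_posterior`: `mean` (named), `covariance`,
#'   `free_energy`, `gamma` (posterior mean/var of log noise precisions),
#'   `n_iterations`, `converged`, plus bookkeeping (`spec`, `priors`, `id`).
#' @examples
#' cfg <- cohort_config(n_hd = 2, n_control = 2, seed = 5)
#' coh <- generate_cohort(cfg)
#' fit <- fit_subject(subject_series(coh, "HD01"), state_model_spec("dynamic"))
#' fit$converged
#' @export
fit_subject <- function(data, spec, priors = prior_spec(spec),
                        settings = vl_settings()) {
  stopifnot(inherits(spec, "state_model_spec"))
  times <- as.numeric(data$times)
  if (length(times) < 3) stop("at least 3 visits are required")
  vols <- as.matrix(data$volumes)
  if (!is.null(colnames(vols))) {
    if (!all(spec$region_labels %in% colnames(vols)))
      stop("data columns do not match the model's region mapping")
    vols <- vols[, spec$region_labels, drop = FALSE]
  } else if (ncol(vols) != length(spec$region_labels)) {
    stop("data columns do not match the model's region mapping")
  }
  y <- vols
  if (!is.null(spec$behavior_channels)) {
    if (is.null(data$behavior))
      stop("spec requests behaviour channels but data has none")
    y <- cbind(y, as.matrix(data$behavior))
  }
  if (any(!is.finite(y))) stop("non-finite data")

  nm <- .param_names(spec)
  if (!identical(names(priors$mean), nm))
    stop("priors do not match the model's parameter layout")
  theta <- priors$mean
  if (isTRUE(settings$init_from_data)) {
    anchor <- which.min(abs(times))
    st_means <- tapply(vols[anchor, ], spec$state_to_region, mean)
    theta[paste0("x0.", hd_state_names())] <- as.numeric(st_means)
  }
  gamma <- c(priors$noise$mean,
             if (!is.null(spec$behavior_channels))
               priors$behavior_noise$mean else NULL)
  fg <- settings$fixed_gamma
  if (!is.null(fg$volumes)) gamma[1] <- fg$volumes
  if (length(gamma) > 1 && !is.null(fg$behavior)) gamma[2] <- fg$behavior

  # for linear-in-parameter forms the Jacobian is a constant design matrix
  J_fix <- if (spec$form %in% c("constant_rate", "quadratic_rate") &&
               is.null(spec$behavior_channels))
    .jacobian_obs(theta, spec, times) else NULL
  ev <- .vl_eval(theta, gamma, y, spec, times, priors, settings, J = J_fix)
  if (!is.finite(ev$F)) stop("initial free energy is not finite")
  P0 <- 1 / priors$var
  nu <- 1e-4                                  # LM damping
  F_trace <- ev$F
  run <- 0L; converged <- FALSE; it <- 0L
  while (it < settings$max_iter) {
    it <- it + 1L
    F_old <- ev$F
    # --- Gauss-Newton / LM step on theta
    lam_obs <- exp(gamma)[ev$block]
    g <- drop(crossprod(ev$J, lam_obs * ev$r)) - P0 * (theta - priors$mean)
    H <- crossprod(ev$J * lam_obs, ev$J)
    diag(H) <- diag(H) + P0
    accepted <- FALSE
    for (trial in 1:8) {
      Hd <- H
      diag(Hd) <- diag(Hd) * (1 + nu)
      step <- tryCatch(solve(Hd, g), error = function(e) NULL)
      if (!is.null(step)) {
        cand <- theta + step
        ev_c <- .vl_eval(cand, gamma, y, spec, times, priors, settings,
                         J = J_fix)
        if (is.finite(ev_c$F) && ev_c$F > ev$F) {
          theta <- cand; ev <- ev_c
          nu <- max(nu / 4, 1e-8)
          accepted <- TRUE
          break
        }
      }
      nu <- nu * 8
    }
    # --- Newton step(s) on the log noise precisions
    gpri <- list(priors$noise, priors$behavior_noise)
    for (b in seq_along(gamma)) {
      if (.gamma_fixed(settings, b)) next
      g0 <- gpri[[b]]$mean; vv0 <- gpri[[b]]$var
      gb <- gamma[b]
      for (k in 1:3) {
        d1 <- ev$N_block[b] / 2 - exp(gb) * ev$S_block[b] / 2 -
          (gb - g0) / vv0
        d2 <- -exp(gb) * ev$S_block[b] / 2 - 1 / vv0
        stp <- max(min(-d1 / d2, 2), -2)
        gb <- min(max(gb + stp, settings$gamma_bounds[1]),
                  settings$gamma_bounds[2])
      }
      if (abs(gb - gamma[b]) > 1e-12) {
        gam_c <- gamma; gam_c[b] <- gb
        ev_c <- .vl_eval(theta, gam_c, y, spec, times, priors, settings,
                         J = ev$J)
        if (is.finite(ev_c$F) && ev_c$F > ev$F) {
          gamma <- gam_c; ev <- ev_c
          accepted <- TRUE
        }
      }
    }
    F_trace <- c(F_trace, ev$F)
    dF <- ev$F - F_old
    run <- if (abs(dF) < settings$tol) run + 1L else 0L
    if (run >= settings$tol_run) { converged <- TRUE; break }
    if (!accepted && nu > 1e6) {
      # even heavily damped (tiny) steps cannot improve F: local maximum
      converged <- abs(dF) < settings$tol
      break
    }
  }
  structure(list(
    mean = theta,
    covariance = ev$Sigma,
    free_energy = ev$F,
    gamma = list(mean = gamma, var = ev$gamma_var),
    n_iterations = it,
    converged = converged,
    F_trace = F_trace,
    spec = spec,
    priors = priors,
    times = times,
    id = if (!is.null(data$id)) data$id else NA_character_
  ), class = "subject_posterior")
}

#' @export
print.subject_posterior <- function(x, ...) {
  cat(sprintf(
    "Subject-level posterior (%s): %d parameters, F = %.2f, %s in %d it.\n",
    x$spec$form, length(x$mean), x$free_energy,
    if (x$converged) "converged" else "NOT converged", x$n_iterations))
  invisible(x)
}

#' Variational free energy of a candidate posterior
#'
#' Evaluates the free energy (evidence lower bound) of a Gaussian candidate
#' posterior for a subject's data under a model and priors: expected
#' log-likelihood under the quadratic expansion minus the KL divergence from
#' the prior. For a linear-Gaussian model evaluated at the exact conjugate
#' posterior this equals the log marginal likelihood exactly.
#'
#' @param posterior_candidate List/`subject_posterior` with `mean`,
#'   `covariance` and `gamma` (`gamma$mean`, optionally `gamma$var`).
#' @param data Subject data as in [fit_subject()].
#' @param spec,priors Model specification and priors.
#' @return Scalar free energy.
#' @export
free_energy <- function(posterior_candidate, data, spec,
                        priors = prior_spec(spec)) {
  theta <- posterior_candidate$mean
  Sigma <- posterior_candidate$covariance
  gamma <- posterior_candidate$gamma$mean
  gvar <- posterior_candidate$gamma$var
  if (is.null(gvar)) gvar <- rep(0, length(gamma))
  times <- as.numeric(data$times)
  y <- as.matrix(data$volumes)
  if (!is.null(colnames(y))) y <- y[, spec$region_labels, drop = FALSE]
  if (!is.null(spec$behavior_channels))
    y <- cbind(y, as.matrix(data$behavior))
  R <- tryCatch(chol(Sigma), error = function(e)
    stop("singular or non-PD posterior covariance"))
  J <- .jacobian_obs(theta, spec, times)
  pred <- .predict_obs(theta, spec, times)
  r <- as.vector(y) - as.vector(pred)
  nT <- length(times)
  n_reg <- length(spec$region_labels)
  n_ch <- length(spec$behavior_channels)
  block <- rep(c(rep(1L, n_reg), rep(2L, n_ch)), each = nT)
  JS <- J %*% Sigma
  tr_obs <- rowSums(JS * J)
  S_block <- vapply(seq_along(gamma), function(b) {
    sel <- block == b
    sum(r[sel]^2) + sum(tr_obs[sel])
  }, numeric(1))
  N_block <- tabulate(block, nbins = length(gamma))
  Eacc <- sum(-N_block / 2 * log(2 * pi) + N_block / 2 * gamma -
                exp(gamma) / 2 * S_block)
  P0 <- 1 / priors$var
  dm <- theta - priors$mean
  KLth <- 0.5 * (sum(diag(Sigma) * P0) + sum(dm^2 * P0) - length(theta) +
                   sum(log(priors$var)) - 2 * sum(log(diag(R))))
  gpri <- list(priors$noise, priors$behavior_noise)
  KLg <- 0
  for (b in seq_along(gamma)) {
    if (gvar[b] <= 0) next
    KLg <- KLg + 0.5 * (gvar[b] / gpri[[b]]$var +
                          (gamma[b] - gpri[[b]]$mean)^2 / gpri[[b]]$var - 1 +
                          log(gpri[[b]]$var / gvar[b]))
  }
  Eacc - KLth - KLg
}

#' Serialize a subject posterior to text files
#'
#' Writes a tabular summary (parameter, posterior mean, posterior sd) as TSV
#' and, optionally, the full posterior covariance plus noise hyperparameters
#' as JSON.
#'
#' @param posterior A `subject_posterior`.
#' @param tsv_path Path of the summary table.
#' @param json_path Optional path of the JSON dump (covariance included).
#' @return Invisibly, the paths written.
#' @export
write_subject_posterior <- function(posterior, tsv_path,
                                    json_path = NULL) {
  stopifnot(inherits(posterior, "subject_posterior"))
  tab <- data.frame(parameter = names(posterior$mean),
                    mean = unname(posterior$mean),
                    sd = sqrt(diag(posterior$covariance)))
  utils::write.table(tab, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(list(
      id = posterior$id,
      form = posterior$spec$form,
      free_energy = posterior$free_energy,
      converged = posterior$converged,
      parameters = names(posterior$mean),
      mean = unname(posterior$mean),
      covariance = unname(posterior$covariance),
      log_noise_precision = posterior$gamma
    ), json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(c(tsv_path, json_path))
}
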