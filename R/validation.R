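# Validation and summary analyses: leave-one-out covariate prediction,
# nonhierarchical decade-loss summaries, CAG variance-explained-over-time,
# and the brain-behaviour readout metrics.

# log evidence of one subject's data under an arbitrary Gaussian prior on
# its parameters, from the stored Gaussian summary (no refitting)
.evidence_under_prior <- function(summ_s, mu2, S2) {
  P2 <- chol2inv(chol(S2))
  M <- summ_s$Pt + P2
  R <- chol(M)
  rhs <- summ_s$h + drop(P2 %*% mu2)
  v <- backsolve(R, forwardsolve(t(R), rhs))
  summ_s$c + 0.5 * (-2 * sum(log(diag(chol(S2))))) - sum(log(diag(R))) -
    0.5 * drop(crossprod(mu2, P2 %*% mu2)) + 0.5 * sum(rhs * v)
}

# empirical prior implied by a PEB fit for a subject with design row x:
# mean B x, covariance = random-effects variance + propagated beta posterior
.empirical_prior <- function(peb, x) {
  p <- length(peb$param_names); k <- length(peb$column_labels)
  mu <- drop(peb$beta %*% x)
  Sb <- peb$beta_covariance
  S <- diag(1 / peb$qdiag, p)
  for (j in seq_len(k)) for (l in seq_len(k)) {
    blk <- Sb[(j - 1) * p + seq_len(p), (l - 1) * p + seq_len(p)]
    S <- S + x[j] * x[l] * blk
  }
  list(mean = mu, cov = (S + t(S)) / 2)
}

.subset_design <- function(X, keep) {
  structure(list(values = X$values[keep, , drop = FALSE],
                 column_labels = X$column_labels,
                 subject_ids = X$subject_ids[keep]),
            class = "design_matrix")
}

#' Leave-one-out prediction of subject covariates
#'
#' For each subject in turn, the hierarchical model is fitted to all other
#' subjects (the subject-level inversions are reused; the group stage is
#' refitted without the held-out subject) and the held-out subject's
#' covariate is inferred from the evidence its data assigns to candidate
#' covariate values under the group empirical prior. Group membership is
#' predicted by comparing candidate values +1 (HD) and -1 (control) with the
#' CAG column neutralized; the reported posterior probability converts to a
#' predicted group value `2 p(HD) - 1`. CAG (HD subjects) has an exactly
#' quadratic log evidence in the candidate value, yielding a closed-form
#' Gaussian posterior combined with a standard-normal prior on the z scale.
#'
#' @param cohort An `hd_cohort`.
#' @param covariate `"group"` or `"cag"`.
#' @param priors,settings Subject-level priors and [vl_settings()].
#' @param fits Optional precomputed list of `subject_posterior`s (in
#'   `cohort$subjects` order) to reuse.
#' @param peb_opts A [peb_settings()].
#' @return Object of class `loo_result`: per-subject table, `accuracy`
#'   (group prediction; `NA` for CAG) and Pearson `r` between predicted and
#'   true values.
#' @export
loo_predict <- function(cohort, covariate = c("group", "cag"),
                        priors = NULL, settings = vl_settings(),
                        fits = NULL, peb_opts = peb_settings()) {
  covariate <- match.arg(covariate)
  subjects <- cohort$subjects
  n <- nrow(subjects)
  if (n < 10) stop("leave-one-out prediction refused for n < 10 (unstable)")
  spec <- state_model_spec("dynamic")
  if (is.null(priors)) priors <- prior_spec(spec)
  if (is.null(fits)) {
    fits <- lapply(subjects$id, function(id)
      fit_subject(subject_series(cohort, id), spec, priors, settings))
  }
  X <- build_design_matrix(subjects)
  summ <- .subject_summaries(fits, priors)
  gcol <- match("group", X$column_labels)
  ccol <- match("cag", X$column_labels)
  if (covariate == "group" && is.na(gcol)) stop("no group column in design")
  if (covariate == "cag" && is.na(ccol)) stop("no cag column in design")
  hd_cag <- subjects$cag[subjects$group == "HD"]
  cag_m <- mean(hd_cag); cag_s <- stats::sd(hd_cag)

  pred <- rep(NA_real_, n); unc <- rep(NA_real_, n)
  for (s in seq_len(n)) {
    peb_s <- fit_peb(fits[-s], .subset_design(X, -s), peb_opts)
    x <- X$values[s, ]
    if (covariate == "group") {
      if (!is.na(ccol)) x[ccol] <- 0          # neutralize CAG for group
      xp <- x; xp[gcol] <- 1
      xm <- x; xm[gcol] <- -1
      ep <- .empirical_prior(peb_s, xp)
      em <- .empirical_prior(peb_s, xm)
      Fp <- .evidence_under_prior(summ[[s]], ep$mean, ep$cov)
      Fm <- .evidence_under_prior(summ[[s]], em$mean, em$cov)
      pr <- posterior_model_probs(c(Fp, Fm))[1]
      pred[s] <- 2 * pr - 1
      unc[s] <- pr
    } else {
      x0 <- x; x0[ccol] <- 0
      e0 <- .empirical_prior(peb_s, x0)       # covariance at reference value
      fz <- vapply(c(-1, 0, 1), function(cz) {
        xc <- x; xc[ccol] <- cz
        .evidence_under_prior(summ[[s]], drop(peb_s$beta %*% xc), e0$cov)
      }, numeric(1))
      A2 <- (fz[3] + fz[1] - 2 * fz[2]) / 2   # curvature in the z value
      A1 <- (fz[3] - fz[1]) / 2
      prec <- max(1 - 2 * A2, 1e-6)           # + standard-normal prior
      zhat <- A1 / prec
      pred[s] <- cag_m + cag_s * zhat
      unc[s] <- cag_s / sqrt(prec)
    }
  }
  if (covariate == "group") {
    truth <- ifelse(subjects$group == "HD", 1, -1)
    acc <- mean(sign(pred) == truth)
    r <- stats::cor(pred, truth)
    tab <- data.frame(id = subjects$id, true = truth, predicted = pred,
                      prob_hd = unc)
  } else {
    hd <- subjects$group == "HD"
    truth <- subjects$cag
    acc <- NA_real_
    r <- stats::cor(pred[hd], truth[hd])
    tab <- data.frame(id = subjects$id, true = truth, predicted = pred,
                      sd = unc)
  }
  structure(list(covariate = covariate, table = tab,
                 accuracy = acc, r = r),
            class = "loo_result")
}

#' @export
print.loo_result <- function(x, ...) {
  cat(sprintf("Leave-one-out prediction of %s:", x$covariate))
  if (!is.na(x$accuracy)) cat(sprintf(" accuracy %.3f,", x$accuracy))
  cat(sprintf(" r = %.3f (n = %d)\n", x$r, nrow(x$table)))
  invisible(x)
}

#' Nonhierarchical decade-loss summary
#'
#' Model-free summary of total atrophy: for every subject and latent-state
#' region (bilateral pairs pooled), an ordinary least-squares line is fitted
#' to volume against time; the slope times ten, expressed as a percentage of
#' the fitted volume at the study window start, is the percent loss per
#' decade. Group summaries are medians across subjects. Subjects with fewer
#' than two distinct visit times are skipped with a notice.
#'
#' @param cohort An `hd_cohort`.
#' @param window_start Anchor for the baseline volume (default: the config
#'   window start, else -6 years).
#' @return `data.frame` with `state`, `group`, `median_loss` (percent per
#'   decade; positive = loss) and `n`.
#' @export
decade_loss_summary <- function(cohort, window_start = NULL) {
  if (is.null(window_start))
    window_start <- if (!is.null(cohort$config))
      cohort$config$time_window[1] else -6
  tab <- hd_region_table()
  states <- hd_state_names()
  subjects <- cohort$subjects
  loss <- matrix(NA_real_, nrow(subjects), length(states),
                 dimnames = list(subjects$id, states))
  for (i in seq_len(nrow(subjects))) {
    v <- cohort$visits[cohort$visits$id == subjects$id[i], , drop = FALSE]
    if (length(unique(v$time_years)) < 2) {
      message("subject ", subjects$id[i],
              " skipped: fewer than 2 distinct visit times")
      next
    }
    tt <- v$time_years
    for (st in seq_along(states)) {
      cols <- tab$region[tab$state == st]
      y <- as.vector(as.matrix(v[, cols]))
      x <- rep(tt, times = length(cols))
      b1 <- stats::cov(x, y) / stats::var(x)
      b0 <- mean(y) - b1 * mean(x)
      base <- b0 + b1 * window_start
      loss[i, st] <- -10 * b1 / base * 100
    }
  }
  out <- do.call(rbind, lapply(unique(subjects$group), function(g) {
    sel <- subjects$group == g
    data.frame(state = states,
               group = g,
               median_loss = apply(loss[sel, , drop = FALSE], 2,
                                   stats::median, na.rm = TRUE),
               n = sum(sel & rowSums(!is.na(loss)) > 0),
               row.names = NULL)
  }))
  out
}

#' Variance of regional volume explained by CAG-repeat length over time
#'
#' At each integer time point of the study window, regresses model-predicted
#' (denoised) volumes across HD subjects on CAG-repeat length and reports
#' R-squared. Time points where fewer than `min_subjects` HD subjects have a
#' visit within half a year are omitted.
#'
#' @param cohort An `hd_cohort` with HD subjects carrying CAG.
#' @param fits Optional list of dynamic-form `subject_posterior`s aligned to
#'   `cohort$subjects` (fitted on demand otherwise).
#' @param states State names to report (default caudate, putamen,
#'   white matter).
#' @param use_fitted Use model-predicted volumes (default); `FALSE` uses raw
#'   observed volumes at the nearest visit instead.
#' @param min_subjects Minimum HD subjects observed near a time point.
#' @param priors,settings Passed to [fit_subject()] when fitting on demand.
#' @return `data.frame` with `t`, `state`, `r2`, `n`.
#' @export
variance_explained_over_time <- function(cohort, fits = NULL,
                                         states = c("caudate", "putamen",
                                                    "white_matter"),
                                         use_fitted = TRUE,
                                         min_subjects = 3,
                                         priors = NULL,
                                         settings = vl_settings()) {
  subjects <- cohort$subjects
  hd_idx <- which(subjects$group == "HD" & !is.na(subjects$cag))
  if (length(hd_idx) < min_subjects) stop("not enough HD subjects with CAG")
  win <- if (!is.null(cohort$config)) cohort$config$time_window else c(-6, 5)
  tgrid <- seq(ceiling(win[1]), floor(win[2]))
  spec <- state_model_spec("dynamic")
  st_idx <- match(states, hd_state_names())
  if (anyNA(st_idx)) stop("unknown state name")
  cag <- subjects$cag[hd_idx]

  if (use_fitted) {
    if (is.null(fits)) {
      if (is.null(priors)) priors <- prior_spec(spec)
      fits <- stats::setNames(vector("list", nrow(subjects)), subjects$id)
      for (i in hd_idx)
        fits[[i]] <- fit_subject(subject_series(cohort, subjects$id[i]),
                                 spec, priors, settings)
    }
    predv <- array(NA_real_, c(length(hd_idx), length(tgrid),
                               length(st_idx)))
    for (a in seq_along(hd_idx)) {
      po <- fits[[hd_idx[a]]]
      traj <- integrate_states(spec, .unpack_params(po$mean, po$spec), tgrid)
      predv[a, , ] <- traj$states[, st_idx]
    }
  } else {
    tab <- hd_region_table()
    predv <- array(NA_real_, c(length(hd_idx), length(tgrid),
                               length(st_idx)))
    for (a in seq_along(hd_idx)) {
      v <- cohort$visits[cohort$visits$id == subjects$id[hd_idx[a]], ,
                         drop = FALSE]
      for (ti in seq_along(tgrid)) {
        j <- which.min(abs(v$time_years - tgrid[ti]))
        if (abs(v$time_years[j] - tgrid[ti]) <= 0.5) {
          for (b in seq_along(st_idx)) {
            cols <- tab$region[tab$state == st_idx[b]]
            predv[a, ti, b] <- mean(as.numeric(v[j, cols]))
          }
        }
      }
    }
  }
  observed_near <- vapply(tgrid, function(t0) {
    sum(vapply(hd_idx, function(i) {
      any(abs(cohort$visits$time_years[cohort$visits$id == subjects$id[i]] -
                t0) <= 0.5)
    }, logical(1)))
  }, numeric(1))
  out <- NULL
  for (ti in seq_along(tgrid)) {
    if (observed_near[ti] < min_subjects) next
    for (b in seq_along(st_idx)) {
      yy <- predv[, ti, b]
      ok <- !is.na(yy)
      if (sum(ok) < min_subjects) next
      r2 <- if (stats::sd(yy[ok]) > 0)
        stats::cor(yy[ok], cag[ok])^2 else 0
      out <- rbind(out, data.frame(t = tgrid[ti], state = states[b],
                                   r2 = r2, n = sum(ok)))
    }
  }
  out
}

# empirical-Bayes ridge regression: y = Z w + e, w ~ N(0, diag(v_w)),
# e ~ N(0, s2); s2 chosen by marginal likelihood
.eb_ridge <- function(Z, y, v_w) {
  n <- length(y)
  evidence <- function(log_s2) {
    s2 <- exp(log_s2)
    P <- crossprod(Z) / s2
    diag(P) <- diag(P) + 1 / v_w
    R <- chol(P)
    w <- backsolve(R, forwardsolve(t(R), crossprod(Z, y) / s2))
    -n / 2 * log(2 * pi * s2) - sum(y^2) / (2 * s2) -
      0.5 * sum(log(v_w)) - sum(log(diag(R))) +
      0.5 * sum(crossprod(Z, y) / s2 * w)
  }
  opt <- stats::optimize(evidence, c(-8, 8), maximum = TRUE, tol = 1e-3)
  s2 <- exp(opt$maximum)
  P <- crossprod(Z) / s2
  diag(P) <- diag(P) + 1 / v_w
  w <- drop(solve(P, crossprod(Z, y) / s2))
  list(w = w, s2 = s2, evidence = opt$objective)
}

#' Brain-behaviour readout fit and decade-change metrics
#'
#' Fits the longitudinal brain-behaviour model: subject-level latent atrophy
#' states (posterior means of the dynamic model) are pooled across HD
#' subjects and visits, and each behavioural channel is regressed on the 28
#' states plus an intercept with an empirical-Bayes ridge (shared readout
#' weights across subjects; the generator's behavioural model is of exactly
#' this form). Reports the pooled determination coefficient, the mean
#' per-subject R-squared, and the mean model-implied score change over a
#' ten-year span computed from each subject's fitted latent trajectory.
#'
#' @param cohort An `hd_cohort` with behavioural channels.
#' @param fits Optional list of dynamic-form `subject_posterior`s aligned to
#'   `cohort$subjects`.
#' @param channels Behavioural channels (default TMS and SDMT).
#' @param span_from Start of the ten-year span (default: window start).
#' @param span Span length in years (default 10).
#' @param weight_prior_var Prior variance of the readout weights.
#' @param priors,settings Passed to [fit_subject()] when fitting on demand.
#' @return Object of class `behavior_fit`: `r2` (pooled, per channel),
#'   `r2_subject` (mean per-subject), `decade_change` (points on the
#'   `[0,100]` scale), `weights`, `sigma2`.
#' @export
behavior_fit_metrics <- function(cohort, fits = NULL,
                                 channels = c("tms", "sdmt"),
                                 span_from = NULL, span = 10,
                                 weight_prior_var = 1,
                                 priors = NULL, settings = vl_settings()) {
  if (!all(channels %in% names(cohort$visits)))
    stop("cohort carries no behavioural channels")
  subjects <- cohort$subjects
  hd_idx <- which(subjects$group == "HD")
  if (is.null(span_from))
    span_from <- if (!is.null(cohort$config))
      cohort$config$time_window[1] else -6
  spec <- state_model_spec("dynamic")
  if (is.null(priors)) priors <- prior_spec(spec)
  if (is.null(fits)) {
    # two-pass empirical-Bayes inversion of the HD subjects (their own
    # group model: mean + covariates, no group column), as in hdprog()
    hd_cohort <- structure(list(
      subjects = subjects[hd_idx, , drop = FALSE],
      visits = cohort$visits[cohort$visits$id %in% subjects$id[hd_idx], ,
                             drop = FALSE],
      truth = NULL, config = cohort$config), class = "hd_cohort")
    h <- .fit_hierarchy(hd_cohort, spec, priors, settings, eb_passes = 2)
    fits <- stats::setNames(vector("list", nrow(subjects)), subjects$id)
    fits[hd_idx] <- h$fits
  }
  n_states <- spec$n_states
  Zs <- list(); ys <- list(); sid <- list()
  x_lo <- x_hi <- matrix(NA_real_, length(hd_idx), n_states)
  for (a in seq_along(hd_idx)) {
    i <- hd_idx[a]
    po <- fits[[i]]
    v <- cohort$visits[cohort$visits$id == subjects$id[i], , drop = FALSE]
    pl <- .unpack_params(po$mean, po$spec)
    traj <- integrate_states(spec, pl, v$time_years)
    Zs[[a]] <- traj$states
    ys[[a]] <- as.matrix(v[, channels])
    sid[[a]] <- rep(subjects$id[i], nrow(v))
    span_states <- integrate_states(spec, pl,
                                    c(span_from, span_from + span))$states
    x_lo[a, ] <- span_states[1, ]
    x_hi[a, ] <- span_states[2, ]
  }
  Z <- cbind(do.call(rbind, Zs), 1)
  Y <- do.call(rbind, ys)
  sid <- unlist(sid)
  v_w <- c(rep(weight_prior_var, n_states), 2500)
  r2 <- r2s <- dchg <- stats::setNames(numeric(length(channels)), channels)
  W <- matrix(0, n_states, length(channels),
              dimnames = list(hd_state_names(), channels))
  icpt <- s2 <- stats::setNames(numeric(length(channels)), channels)
  for (ch in seq_along(channels)) {
    fitc <- .eb_ridge(Z, Y[, ch], v_w)
    w <- fitc$w[seq_len(n_states)]
    W[, ch] <- w
    icpt[ch] <- fitc$w[n_states + 1]
    s2[ch] <- fitc$s2
    yhat <- drop(Z %*% fitc$w)
    r2[ch] <- 1 - sum((Y[, ch] - yhat)^2) / sum((Y[, ch] - mean(Y[, ch]))^2)
    per <- vapply(unique(sid), function(id) {
      sel <- sid == id
      den <- sum((Y[sel, ch] - mean(Y[sel, ch]))^2)
      if (den > 0) 1 - sum((Y[sel, ch] - yhat[sel])^2) / den else NA_real_
    }, numeric(1))
    r2s[ch] <- mean(per, na.rm = TRUE)
    dchg[ch] <- mean(drop((x_hi - x_lo) %*% w))
  }
  structure(list(r2 = r2, r2_subject = r2s, decade_change = dchg,
                 weights = W, intercept = icpt, sigma2 = s2,
                 n_obs = nrow(Z), n_subjects = length(hd_idx)),
            class = "behavior_fit")
}

#' @export
print.behavior_fit <- function(x, ...) {
  cat("Brain-behaviour readout fit (HD subjects)\n")
  for (ch in names(x$r2))
    cat(sprintf("  %s: pooled R2 = %.3f, decade change = %+.2f points\n",
                ch, x$r2[ch], x$decade_change[ch]))
  invisible(x)
}
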