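#' Fit the hierarchical disease-progression model
#'
#' The front door of the package: fits the two-level Bayesian model of
#' regional atrophy to a conversion-aligned cohort. Each subject's 55
#' regional volume trajectories are inverted under the chosen state model by
#' variational Laplace ([fit_subject()]), and the subject posteriors are
#' embedded in a parametric-empirical-Bayes group model over the covariate
#' design matrix (overall mean, diagnostic group, CAG, gender, age
#' orthogonalized to CAG, TIV, site; [build_design_matrix()], [fit_peb()]).
#' The returned free energy approximates the log evidence of the whole
#' hierarchy and is the quantity compared across candidate models.
#'
#' @param cohort An `hd_cohort` from [generate_cohort()] or [read_cohort()].
#' @param form State model form (see [state_model_spec()]).
#' @param connectivity Optional interregional edge matrix or the name of a
#'   [connectivity_presets()] entry.
#' @param priors A [prior_spec()]; defaults to the weakly informative
#'   package priors.
#' @param settings A [vl_settings()].
#' @param peb_opts A [peb_settings()].
#' @param design Optional precomputed [build_design_matrix()] result.
#' @param eb_passes Number of empirical-Bayes passes: after the first group
#'   fit, subjects are re-inverted under the PEB-implied empirical priors and
#'   the group model is re-estimated (iterated hierarchical inversion). The
#'   default 2 substantially reduces the sensitivity of the group evidence to
#'   the placement of the initial subject priors.
#' @return Object of class `hdprog` with components `subject_fits`, `peb`,
#'   `design`, `spec`, `priors`, `free_energy`, `unconverged`, `cohort`.
#' @examples
#' \donttest{
#' coh <- generate_cohort(cohort_config(n_hd = 6, n_control = 6, seed = 2))
#' fit <- hdprog(coh)
#' fit
#' coef(fit)[1:3, 1:3]
#' }
#' @export
hdprog <- function(cohort, form = "dynamic", connectivity = NULL,
                   priors = NULL, settings = vl_settings(),
                   peb_opts = peb_settings(), design = NULL,
                   eb_passes = 2) {
  stopifnot(inherits(cohort, "hd_cohort"))
  if (is.character(connectivity) && length(connectivity) == 1)
    connectivity <- connectivity_presets()[[connectivity]]
  spec <- state_model_spec(form, connectivity = connectivity)
  h <- .fit_hierarchy(cohort, spec, priors, settings, peb_opts,
                      X = design, eb_passes = eb_passes)
  structure(list(
    call = match.call(),
    form = form,
    spec = spec,
    subject_fits = h$fits,
    subject_fits_pass1 = h$fits_pass1,
    peb = h$peb,
    design = h$X,
    priors = h$priors,
    free_energy = h$free_energy,
    unconverged = h$unconverged,
    cohort = cohort
  ), class = "hdprog")
}

#' @export
print.hdprog <- function(x, ...) {
  ns <- table(x$cohort$subjects$group)
  cat("Hierarchical disease-progression model\n")
  cat(sprintf("  state model: %s (%d parameters/subject)\n",
              x$form, length(x$peb$param_names)))
  cat(sprintf("  subjects: %d HD + %d control; group free energy F = %.2f\n",
              ns[["HD"]], ns[["control"]], x$free_energy))
  if (length(x$unconverged))
    cat("  non-converged subjects:",
        paste(x$unconverged, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.hdprog <- function(object, ...) object$peb$beta

#' @export
logLik.hdprog <- function(object, ...) {
  structure(object$free_energy, df = NA_integer_, class = "logLik")
}

#' Summarize group-level effects of a fitted hierarchy
#'
#' Tabulates the group-level effect estimates for selected design columns
#' together with posterior sds and the posterior probability that each
#' effect is nonzero, obtained by per-entry Bayesian model reduction
#' (evidence for the entry free versus pinned at its prior expectation).
#'
#' @param object An [hdprog()] fit.
#' @param columns Design columns to tabulate (default `group` and `cag`).
#' @param threshold Posterior-probability threshold used for flagging.
#' @param ... Unused.
#' @return `summary.hdprog` object: data.frame with `parameter`,
#'   `covariate`, `estimate`, `sd`, `Pp`, `surviving`.
#' @export
summary.hdprog <- function(object, columns = c("group", "cag"),
                           threshold = 0.95, ...) {
  peb <- object$peb
  columns <- intersect(columns, peb$column_labels)
  p <- length(peb$param_names)
  Sb <- peb$beta_covariance
  rows <- list()
  for (colnm in columns) {
    j <- match(colnm, peb$column_labels)
    for (i in seq_len(p)) {
      bmr <- bayesian_model_reduction(
        peb, data.frame(parameter = peb$param_names[i], covariate = colnm))
      Pp <- 1 / (1 + exp(bmr$delta_F))
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = peb$param_names[i],
        covariate = colnm,
        estimate = peb$beta[i, j],
        sd = sqrt(Sb[(j - 1) * p + i, (j - 1) * p + i]),
        Pp = Pp)
    }
  }
  out <- do.call(rbind, rows)
  out$surviving <- out$Pp > threshold
  structure(list(table = out, threshold = threshold,
                 free_energy = object$free_energy, form = object$form),
            class = "summary.hdprog")
}

#' @export
print.summary.hdprog <- function(x, ...) {
  cat(sprintf("Group-level effects (%s model, F = %.2f)\n",
              x$form, x$free_energy))
  surv <- x$table[x$table$surviving, , drop = FALSE]
  cat(sprintf("  %d of %d tested effects exceed Pp > %.2f\n",
              nrow(surv), nrow(x$table), x$threshold))
  if (nrow(surv)) {
    surv$estimate <- round(surv$estimate, 3)
    surv$sd <- round(surv$sd, 3)
    surv$Pp <- round(surv$Pp, 3)
    print(utils::head(surv[order(-abs(surv$estimate)), ], 20),
          row.names = FALSE)
  }
  invisible(x)
}

#' Predict subject trajectories from a fitted hierarchy
#'
#' @param object An [hdprog()] fit.
#' @param ids Subject ids (default: all).
#' @param times Prediction times (default: the study-window integer grid).
#' @param type `"volumes"` (observed-region predictions) or `"states"`.
#' @param ... Unused.
#' @return Long `data.frame`: `id`, `time_years`, and predicted columns.
#' @export
predict.hdprog <- function(object, ids = NULL, times = NULL,
                           type = c("volumes", "states"), ...) {
  type <- match.arg(type)
  if (is.null(ids)) ids <- object$cohort$subjects$id
  if (is.null(times)) {
    win <- if (!is.null(object$cohort$config))
      object$cohort$config$time_window else c(-6, 5)
    times <- seq(ceiling(win[1]), floor(win[2]))
  }
  out <- lapply(ids, function(id) {
    po <- object$subject_fits[[id]]
    pl <- .unpack_params(po$mean, object$spec)
    traj <- integrate_states(object$spec, pl, times)
    m <- if (type == "states") {
      colnames(traj$states) <- hd_state_names()
      traj$states
    } else observe_states(traj, object$spec, pl)
    cbind(data.frame(id = id, time_years = times), as.data.frame(m))
  })
  do.call(rbind, out)
}

#' @export
fitted.hdprog <- function(object, ...) {
  out <- lapply(object$cohort$subjects$id, function(id) {
    po <- object$subject_fits[[id]]
    pl <- .unpack_params(po$mean, object$spec)
    traj <- integrate_states(object$spec, pl, po$times)
    cbind(data.frame(id = id, time_years = po$times),
          as.data.frame(observe_states(traj, object$spec, pl)))
  })
  do.call(rbind, out)
}

#' @export
residuals.hdprog <- function(object, ...) {
  fit <- fitted.hdprog(object)
  obs <- object$cohort$visits
  regions <- object$spec$region_labels
  stopifnot(identical(fit$id, obs$id))
  res <- obs[, c("id", "time_years")]
  res[, regions] <- obs[, regions] - fit[, regions]
  res
}

#' Plot observed and fitted regional trajectories
#'
#' Spaghetti plot of observed volumes (points) and fitted subject
#' trajectories (lines, red for HD, blue for controls) for one latent-state
#' region.
#'
#' @param x An [hdprog()] fit.
#' @param state State name (default `"putamen"`).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.hdprog <- function(x, state = "putamen", ...) {
  tab <- hd_region_table()
  si <- match(state, hd_state_names())
  if (is.na(si)) stop("unknown state name")
  cols <- tab$region[tab$state == si]
  obs <- x$cohort$visits
  win <- if (!is.null(x$cohort$config)) x$cohort$config$time_window
    else c(-6, 5)
  tt <- seq(win[1], win[2], by = 0.25)
  yobs <- rowMeans(as.matrix(obs[, cols, drop = FALSE]))
  graphics::plot(obs$time_years, yobs, pch = 16, cex = 0.4,
                 col = "grey60",
                 xlab = "years relative to motor conversion",
                 ylab = sprintf("%s volume (%% of mean at diagnosis)",
                                state), ...)
  for (id in x$cohort$subjects$id) {
    po <- x$subject_fits[[id]]
    pl <- .unpack_params(po$mean, x$spec)
    traj <- integrate_states(x$spec, pl, tt)
    grp <- x$cohort$subjects$group[x$cohort$subjects$id == id]
    graphics::lines(tt, traj$states[, si],
                    col = if (grp == "HD") "#c0392bAA" else "#2980b9AA",
                    lwd = 0.8)
  }
  graphics::legend("bottomleft", legend = c("HD", "control"),
                   col = c("#c0392b", "#2980b9"), lwd = 2, bty = "n")
  invisible(x)
}

#' Simulate new cohorts from a fitted hierarchy
#'
#' Parametric simulation: regenerates visit tables from the fitted subject
#' posterior means with the estimated measurement noise.
#'
#' @param object An [hdprog()] fit.
#' @param nsim Number of simulated cohorts.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return List of visit `data.frame`s (length `nsim`).
#' @export
simulate.hdprog <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  sims <- vector("list", nsim)
  sd_hat <- exp(-mean(vapply(object$subject_fits, function(po)
    po$gamma$mean[1], numeric(1))) / 2)
  for (k in seq_len(nsim)) {
    fit <- fitted.hdprog(object)
    regions <- object$spec$region_labels
    fit[, regions] <- fit[, regions] +
      matrix(stats::rnorm(nrow(fit) * length(regions), 0, sd_hat),
             nrow(fit))
    sims[[k]] <- fit
  }
  sims
}
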