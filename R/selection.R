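#' Posterior model probabilities from free energies
#'
#' Softmax of free energies under equal prior model probabilities
#' (differences in F are log Bayes factors); invariant to adding a constant
#' to all free energies.
#'
#' @param free_energies Numeric vector (>= 2 finite values).
#' @return Probabilities summing to 1.
#' @examples
#' posterior_model_probs(c(0, -3))
#' @export
posterior_model_probs <- function(free_energies) {
  f <- as.numeric(free_energies)
  if (length(f) < 2 || any(!is.finite(f)))
    stop("need >= 2 finite free energies")
  e <- exp(f - max(f))
  e / sum(e)
}

# Fit one hierarchical model (all subjects + PEB) and return total group F;
# the front-door wrapper hdprog() adds the S3 interface on top of this.
# With eb_passes > 1 the inversion is iterated: after each group pass the
# subjects are re-inverted under the PEB-implied empirical priors
# (group prediction B x_s with the random-effects/posterior covariance), so
# the Laplace linearization point moves to where the hierarchy expects the
# subject to sit.  The group-level prior stays the original model prior.
.fit_hierarchy <- function(cohort, spec, priors = NULL,
                           settings = vl_settings(),
                           peb_opts = peb_settings(), X = NULL,
                           eb_passes = 2) {
  if (is.null(priors)) priors <- prior_spec(spec)
  if (is.null(X)) X <- build_design_matrix(cohort$subjects)
  series <- lapply(cohort$subjects$id, function(id)
    subject_series(cohort, id))
  fits <- lapply(series, fit_subject, spec = spec, priors = priors,
                 settings = settings)
  names(fits) <- cohort$subjects$id
  fits_pass1 <- fits
  peb <- fit_peb(fits, X, peb_opts, priors = priors)
  if (eb_passes > 1) {
    for (pass in seq_len(eb_passes - 1)) {
      fits <- lapply(seq_along(series), function(s) {
        ep <- .empirical_prior(peb, X$values[s, ])
        pr_s <- priors
        pr_s$mean[] <- ep$mean
        pr_s$var[] <- pmax(diag(ep$cov), 1e-8)
        fit_subject(series[[s]], spec, pr_s, settings)
      })
      names(fits) <- cohort$subjects$id
      peb <- fit_peb(fits, X, peb_opts, priors = priors)
    }
  }
  unconverged <- names(fits)[!vapply(fits, `[[`, logical(1), "converged")]
  list(fits = fits, fits_pass1 = fits_pass1, peb = peb, X = X,
       priors = priors, free_energy = peb$free_energy,
       unconverged = unconverged)
}

#' Compare the four candidate state models on a cohort
#'
#' Fits the full hierarchy (per-subject variational Laplace followed by PEB)
#' under each candidate form and compares total group-level free energies by
#' Bayesian model selection.
#'
#' @param cohort An `hd_cohort`.
#' @param priors Optional named list of [prior_spec()]s per form.
#' @param settings A [vl_settings()].
#' @param forms Candidate forms (default: all four).
#' @param keep_fits Keep the fitted hierarchies in the result?
#' @param eb_passes Empirical-Bayes passes (see [hdprog()]).
#' @return Object of class `model_comparison`: `model_ids`, `free_energies`,
#'   `posterior_probs`, `exclusion_note` (subjects that failed to converge
#'   under some model, if any) and optionally `fits`.
#' @export
select_state_model <- function(cohort, priors = NULL,
                               settings = vl_settings(),
                               forms = c("constant_rate", "quadratic_rate",
                                         "dynamic", "dynamic_sigmoid"),
                               keep_fits = FALSE, eb_passes = 2) {
  X <- build_design_matrix(cohort$subjects)
  res <- lapply(forms, function(fm) {
    spec <- state_model_spec(fm)
    pr <- if (!is.null(priors)) priors[[fm]] else NULL
    .fit_hierarchy(cohort, spec, pr, settings, X = X, eb_passes = eb_passes)
  })
  names(res) <- forms
  Fs <- vapply(res, `[[`, numeric(1), "free_energy")
  notes <- unlist(lapply(forms, function(fm) {
    u <- res[[fm]]$unconverged
    if (length(u)) paste0(fm, ": ", paste(u, collapse = ",")) else NULL
  }))
  structure(list(
    model_ids = forms,
    free_energies = unname(Fs),
    posterior_probs = posterior_model_probs(Fs),
    exclusion_note = if (length(notes)) notes else NULL,
    fits = if (keep_fits) res else NULL
  ), class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Bayesian model comparison (group free energy):\n")
  df <- data.frame(model = x$model_ids,
                   F = round(x$free_energies, 2),
                   prob = round(x$posterior_probs, 4))
  print(df, row.names = FALSE)
  if (!is.null(x$exclusion_note))
    cat("note: non-converged subjects -", x$exclusion_note, "\n")
  invisible(x)
}

# resolve an entry specification (data.frame parameter/covariate, 2-col
# character matrix, or logical p x k matrix) to linear indices into vec(beta)
.entry_index <- function(peb, entries) {
  p <- length(peb$param_names); k <- length(peb$column_labels)
  if (is.logical(entries)) {
    stopifnot(dim(entries) == c(p, k))
    return(which(entries))
  }
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  i <- match(entries[[1]], peb$param_names)
  j <- match(entries[[2]], peb$column_labels)
  if (anyNA(i) || anyNA(j))
    stop("entries reference unknown parameters or covariates")
  (j - 1L) * p + i
}

#' Bayesian model reduction of the group-level posterior
#'
#' Computes, without refitting, the evidence and posterior of a reduced PEB
#' model in which selected (parameter, covariate) entries of the effect
#' matrix are switched off -- their prior variance collapsed to 1e-8 so they
#' are pinned at the prior expectation.
#'
#' @param peb A [fit_peb()] result.
#' @param off_mask Entries to switch off: a data.frame/matrix with columns
#'   (parameter, covariate), or a logical parameters x columns matrix.
#' @return List with `delta_F` (`F_reduced - F_full`), `beta_reduced` and
#'   `free_energy_reduced`.
#' @export
bayesian_model_reduction <- function(peb, off_mask) {
  stopifnot(inherits(peb, "peb_result"))
  p <- length(peb$param_names)
  idx <- if (is.null(off_mask) || (is.data.frame(off_mask) &&
                                   nrow(off_mask) == 0)) integer(0)
    else .entry_index(peb, off_mask)
  mean_col <- seq_len(p)   # column 1 is the overall mean
  if (length(idx) && all(mean_col %in% idx))
    stop("masking the entire mean column is degenerate")
  vb <- peb$vb
  vb[idx] <- 1e-8
  full <- .peb_evidence(peb, peb$b0, peb$vb)
  red <- .peb_evidence(peb, peb$b0, vb)
  beta_red <- matrix(red$mean, p, length(peb$column_labels),
                     dimnames = dimnames(peb$beta))
  list(delta_F = red$F - full$F,
       free_energy_reduced = red$F,
       beta_reduced = beta_red)
}

#' Bayesian model averaging over reduced group models
#'
#' Searches a family of reduced PEB models in which switchable
#' (parameter, covariate) entries are on (free) or off (pinned at prior
#' expectation), and averages parameter estimates over the family weighted
#' by model evidence. Each entry's posterior probability Pp is the
#' evidence-weighted probability of being on; entries with `Pp > 0.95`
#' survive thresholding. `search = "greedy"` iteratively switches off the
#' entries whose removal increases evidence (batch with single-entry
#' fallback) and averages over all models visited; `search = "exhaustive"`
#' enumerates all on/off combinations (refused above 20 switchable entries).
#'
#' @param peb A [fit_peb()] result.
#' @param switchable Entries to search over (format as in
#'   [bayesian_model_reduction()]); default: every entry of the `group` and
#'   `cag` columns present in the design.
#' @param search `"greedy"` or `"exhaustive"`.
#' @param threshold Posterior-probability threshold (default 0.95).
#' @return Object of class `bma_result` with matrices `estimates`, `sd`,
#'   `Pp`, logical `surviving`, the `threshold`, and the number of models
#'   visited.
#' @export
bma_average <- function(peb, switchable = NULL,
                        search = c("greedy", "exhaustive"),
                        threshold = 0.95) {
  stopifnot(inherits(peb, "peb_result"))
  search <- match.arg(search)
  p <- length(peb$param_names); k <- length(peb$column_labels)
  if (is.null(switchable)) {
    cols <- intersect(c("group", "cag"), peb$column_labels)
    if (!length(cols)) stop("no default switchable columns in this design")
    m <- matrix(FALSE, p, k,
                dimnames = list(peb$param_names, peb$column_labels))
    m[, cols] <- TRUE
    switchable <- m
  }
  sw <- .entry_index(peb, switchable)
  K <- length(sw)
  if (K == 0) stop("no switchable entries")
  if (search == "exhaustive" && K > 20)
    stop("exhaustive search refused over >20 switchable entries; use greedy")

  ev_cache <- new.env(parent = emptyenv())
  evaluate <- function(off) {            # off: logical over sw
    key <- paste(as.integer(off), collapse = "")
    if (!is.null(ev_cache[[key]])) return(ev_cache[[key]])
    vb <- peb$vb
    vb[sw[off]] <- 1e-8
    r <- .peb_evidence(peb, peb$b0, vb)
    out <- list(off = off, F = r$F, mean = r$mean, Pb = r$Pb)
    ev_cache[[key]] <- out
    out
  }

  visited <- list()
  push <- function(m) visited[[length(visited) + 1L]] <<- m

  if (search == "exhaustive") {
    for (i in 0:(2^K - 1))
      push(evaluate(as.logical(bitwAnd(i, 2^(seq_len(K) - 1)) > 0)))
  } else {
    cur <- evaluate(rep(FALSE, K)); push(cur)
    repeat {
      cand_idx <- which(!cur$off)
      if (!length(cand_idx)) break
      cands <- lapply(cand_idx, function(j) {
        off <- cur$off; off[j] <- TRUE
        evaluate(off)
      })
      for (cm in cands) push(cm)
      Fs <- vapply(cands, `[[`, numeric(1), "F")
      improving <- Fs > cur$F
      if (!any(improving)) break
      if (sum(improving) > 1) {
        off_b <- cur$off; off_b[cand_idx[improving]] <- TRUE
        batch <- evaluate(off_b); push(batch)
        if (batch$F >= max(Fs)) { cur <- batch; next }
      }
      cur <- cands[[which.max(Fs)]]
    }
  }

  keys <- vapply(visited, function(m)
    paste(as.integer(m$off), collapse = ""), character(1))
  visited <- visited[!duplicated(keys)]
  Fs <- vapply(visited, `[[`, numeric(1), "F")
  wts <- posterior_model_probs(Fs)

  Pp_vec <- rep(1, p * k)
  for (jj in seq_len(K))
    Pp_vec[sw[jj]] <- sum(wts[!vapply(visited, function(m) m$off[jj],
                                      logical(1))])
  est <- Reduce(`+`, Map(function(m, w) w * m$mean, visited, wts))
  second <- rep(0, p * k)
  for (ii in seq_along(visited)) {
    w <- wts[ii]
    m2 <- visited[[ii]]$mean^2
    if (w > 1e-6) {
      v <- diag(chol2inv(chol(visited[[ii]]$Pb)))
      m2 <- m2 + v
    }
    second <- second + w * m2
  }
  sdv <- sqrt(pmax(second - est^2, 0))
  dimn <- list(peb$param_names, peb$column_labels)
  Pp <- matrix(Pp_vec, p, k, dimnames = dimn)
  structure(list(
    estimates = matrix(est, p, k, dimnames = dimn),
    sd = matrix(sdv, p, k, dimnames = dimn),
    Pp = Pp,
    threshold = threshold,
    surviving = Pp > threshold,
    n_models = length(visited),
    search = search
  ), class = "bma_result")
}

#' @export
print.bma_result <- function(x, ...) {
  cat(sprintf(
    "Bayesian model average over %d reduced models (%s search)\n",
    x$n_models, x$search))
  surv <- which(x$surviving & x$Pp < 1, arr.ind = TRUE)
  cat(sprintf("  %d searched entries survive Pp > %.2f\n",
              nrow(surv), x$threshold))
  invisible(x)
}

#' Compare interregional-connectivity hypotheses
#'
#' Fits the hierarchical dynamic model with no interregional edges and with
#' each supplied edge preset, and compares total group free energies.
#'
#' @param cohort An `hd_cohort`.
#' @param edge_presets Named list of edge matrices
#'   (default [connectivity_presets()]).
#' @param priors Optional named list of [prior_spec()]s (`diagonal` plus one
#'   per preset).
#' @param settings A [vl_settings()].
#' @param eb_passes Empirical-Bayes passes (see [hdprog()]).
#' @return A `model_comparison` over `c("diagonal", names(edge_presets))`.
#' @export
compare_connectivity_models <- function(cohort,
                                        edge_presets = connectivity_presets(),
                                        priors = NULL,
                                        settings = vl_settings(),
                                        eb_passes = 2) {
  X <- build_design_matrix(cohort$subjects)
  ids <- c("diagonal", names(edge_presets))
  res <- lapply(ids, function(nm) {
    spec <- state_model_spec("dynamic",
                             connectivity = if (nm == "diagonal") NULL
                               else edge_presets[[nm]])
    pr <- if (!is.null(priors)) priors[[nm]] else NULL
    .fit_hierarchy(cohort, spec, pr, settings, X = X, eb_passes = eb_passes)
  })
  names(res) <- ids
  Fs <- vapply(res, `[[`, numeric(1), "free_energy")
  notes <- unlist(lapply(ids, function(nm) {
    u <- res[[nm]]$unconverged
    if (length(u)) paste0(nm, ": ", paste(u, collapse = ",")) else NULL
  }))
  structure(list(model_ids = ids,
                 free_energies = unname(Fs),
                 posterior_probs = posterior_model_probs(Fs),
                 exclusion_note = if (length(notes)) notes else NULL,
                 fits = NULL),
            class = "model_comparison")
}
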