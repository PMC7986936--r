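# Synthetic conversion-aligned cohort generation.  All randomness flows from
# the config seed through named substreams so stages are independently
# reproducible.

.substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483629) + 1L
}

#' Sample annual visit schedules
#'
#' Draws a visit count from the configured law and places the annual visit
#' block uniformly among the alignments that keep every visit inside the
#' time window and include the conversion year `t = 0`.
#'
#' @param config A [cohort_config()].
#' @param n Number of subjects.
#' @param seed Integer seed (default: the config seed).
#' @param group `"hd"` or `"control"` (selects the visit-count law).
#' @return List of `n` strictly increasing annual visit-time vectors.
#' @examples
#' sched <- sample_visit_schedule(cohort_config(seed = 1), n = 3)
#' lengths(sched)
#' @export
sample_visit_schedule <- function(config, n, seed = config$seed,
                                  group = c("hd", "control")) {
  stopifnot(inherits(config, "cohort_config"), n >= 1)
  group <- match.arg(group)
  law <- if (group == "hd") config$visit_count_law else
    config$control_visit_count_law
  win <- config$time_window
  if (diff(win) < max(as.integer(names(law))) - 1)
    stop("invalid config: window too short to host the drawn visit count")
  set.seed(.substream_seed(seed, paste0("visits_", group)))
  # index into the support (sample() treats a scalar first argument as 1:n)
  counts <- as.integer(names(law))[sample.int(length(law), n,
                                              replace = TRUE, prob = law)]
  lapply(counts, function(k) {
    lo <- max(ceiling(win[1]), 1L - k)
    hi <- min(0L, floor(win[2]) - k + 1L)
    if (lo > hi) stop("invalid config: no admissible visit placement")
    s <- if (!is.null(config$visit_start)) config$visit_start else
      lo + sample.int(hi - lo + 1L, 1L) - 1L
    seq(s, by = 1, length.out = k)
  })
}

#' Sample subject covariates
#'
#' HD subjects receive an integer CAG-repeat length and an age at conversion
#' drawn from a Gaussian copula targeting the configured (negative)
#' CAG--onset-age correlation; each control mirrors the age of its matched HD
#' subject (age-matched alignment). Gender, site and TIV are drawn per group.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed (default: the config seed).
#' @return `data.frame` with one row per subject: `id`, `group`, `cag`
#'   (`NA` for controls), `gender`, `age`, `tiv`, `site`.
#' @export
sample_covariates <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  if (abs(config$cag_onset_corr) >= 1)
    stop("invalid config: infeasible correlation request")
  set.seed(.substream_seed(seed, "covariates"))
  n_hd <- config$n_hd; n_c <- config$n_control
  cag_vals <- as.integer(names(config$cag_law))
  cum <- cumsum(config$cag_law)

  # Gaussian copula; discretizing the CAG marginal attenuates the Pearson
  # correlation by ~1.5%, compensated here (calibrated once)
  rho <- max(config$cag_onset_corr / 0.985, -0.999)
  z1 <- stats::rnorm(n_hd)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n_hd)
  cag <- cag_vals[findInterval(stats::pnorm(z1), cum, left.open = TRUE) + 1L]
  plo <- stats::pnorm(config$age_range[1], config$age_mean, config$age_sd)
  phi <- stats::pnorm(config$age_range[2], config$age_mean, config$age_sd)
  age_hd <- stats::qnorm(stats::pnorm(z2) * (phi - plo) + plo,
                         config$age_mean, config$age_sd)
  # controls are age-matched to HD subjects (recycled if group sizes differ)
  age_c <- rep_len(age_hd, n_c)

  draw_group <- function(n, prefix, group, cag, age, female_p, site_probs) {
    gender <- ifelse(stats::runif(n) < female_p, "F", "M")
    tiv <- stats::rnorm(n, config$tiv_mean, config$tiv_sd) +
      ifelse(gender == "M", config$tiv_male_shift, 0)
    site <- sample(config$site_levels, n, replace = TRUE, prob = site_probs)
    data.frame(id = sprintf("%s%02d", prefix, seq_len(n)),
               group = group, cag = cag, gender = gender,
               age = age, tiv = tiv, site = site,
               stringsAsFactors = FALSE)
  }
  rbind(
    draw_group(n_hd, "HD", "HD", cag, age_hd,
               config$female_p_hd, config$site_probs_hd),
    draw_group(n_c, "C", "control", NA_integer_, age_c,
               config$female_p_control, config$site_probs_control)
  )
}

# true generative subject parameters for a given form (internal, also used
# by tests through cohort$truth)
.true_subject_params <- function(config, group, cag) {
  states <- hd_state_names()
  if (group == "HD") {
    decay <- config$true_decay$hd +
      config$cag_slope * (cag - .cag_center)
    x0 <- 100 + config$group_offset
  } else {
    decay <- config$true_decay$control
    x0 <- stats::setNames(rep(100, length(states)), states)
  }
  a <- -decay
  p <- list(x0 = x0)
  switch(config$dynamics_form,
    dynamic = {
      p$log_decay <- log(pmax(decay, 1e-12))
      if (!is.null(config$connectivity) && group == "HD")
        p$edge_weights <- config$edge_weights
    },
    constant_rate = {
      p$rate_c0 <- x0 * a
    },
    quadratic_rate = {
      # accelerating decline: curvature opposite in sign to the exponential
      p$rate_c0 <- x0 * a
      p$accel_c1 <- -3 * x0 * a^2
    },
    dynamic_sigmoid = {
      # half the decline endogenous, half switched on at conversion
      p$log_decay <- log(pmax(decay / 2, 1e-12))
      p$rate_c0 <- -x0 * decay
      p$input_params <- c(t0 = 0, log_tau = 0)
    })
  p
}

#' Generate behavioural scores from latent state trajectories
#'
#' Each channel is a weighted sum of the 28 latent states plus an intercept
#' and i.i.d. Gaussian noise, clipped to the bounded `[0, 100]` scale; an
#' increase indicates worsening.
#'
#' @param states Matrix `[time x 28]` of latent states (or a
#'   `state_trajectory`).
#' @param config A [cohort_config()] with behavioural weights.
#' @param noise Add Gaussian noise (uses the current RNG stream)?
#' @return Matrix `[time x 2]` with columns `tms`, `sdmt`.
#' @export
generate_behavior <- function(states, config, noise = TRUE) {
  if (inherits(states, "state_trajectory")) states <- states$states
  bw <- config$behavior_weights
  if (is.null(bw)) stop("config carries no behavioural weights")
  if (!all(rownames(bw$weights) %in% hd_state_names()) ||
      nrow(bw$weights) != ncol(states))
    stop("invalid config: behaviour weight map references unknown state")
  sc <- states %*% bw$weights
  sc <- sweep(sc, 2, bw$intercept, `+`)
  if (noise && config$behavior_noise_sd > 0)
    sc <- sc + stats::rnorm(length(sc), 0, config$behavior_noise_sd)
  sc[] <- pmin(pmax(sc, 0), 100)
  colnames(sc) <- c("tms", "sdmt")
  sc
}

#' Generate a synthetic conversion-aligned cohort
#'
#' Composes covariate sampling, visit scheduling, latent-state integration
#' under the configured generative form, the bilateral observation map and
#' i.i.d. Gaussian measurement noise into a complete two-group longitudinal
#' cohort. Deterministic given the config (seed included).
#'
#' @param config A [cohort_config()].
#' @return An object of class `hd_cohort`: list with `subjects` (one row per
#'   subject), `visits` (long table: `id`, `time_years`, 55 region columns,
#'   optional `tms`/`sdmt`), `truth` (per-subject true generative parameters
#'   and noise-free trajectories; available because the cohort is synthetic)
#'   and `config`.
#' @examples
#' coh <- generate_cohort(cohort_config(n_hd = 3, n_control = 3, seed = 7))
#' dim(coh$visits)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  validate_cohort_config(config)
  subjects <- sample_covariates(config)
  sched_hd <- sample_visit_schedule(config, config$n_hd, group = "hd")
  sched_c <- sample_visit_schedule(config, config$n_control,
                                   group = "control")
  schedules <- c(sched_hd, sched_c)
  spec <- state_model_spec(config$dynamics_form,
                           connectivity = config$connectivity)
  set.seed(.substream_seed(config$seed, "noise"))
  rows <- vector("list", nrow(subjects))
  truth <- vector("list", nrow(subjects))
  for (i in seq_len(nrow(subjects))) {
    s <- subjects[i, ]
    tt <- schedules[[i]]
    pp <- .true_subject_params(config, s$group, s$cag)
    traj <- integrate_states(spec, pp, tt)
    if (any(traj$states <= 0))
      stop("invalid config: decay produces non-positive volumes in window")
    y <- observe_states(traj, spec, pp)
    yn <- y + stats::rnorm(length(y), 0, config$noise_sd)
    if (any(yn <= 0))
      stop("invalid config: noise drives volumes non-positive")
    df <- data.frame(id = s$id, time_years = tt, stringsAsFactors = FALSE)
    df <- cbind(df, as.data.frame(yn))
    if (config$behavior) {
      beh <- generate_behavior(traj$states, config, noise = TRUE)
      df$tms <- beh[, "tms"]; df$sdmt <- beh[, "sdmt"]
    }
    rows[[i]] <- df
    truth[[i]] <- list(params = pp, states = traj$states, times = tt)
  }
  names(truth) <- subjects$id
  structure(list(subjects = subjects,
                 visits = do.call(rbind, rows),
                 truth = truth,
                 config = config),
            class = "hd_cohort")
}

#' @export
print.hd_cohort <- function(x, ...) {
  ns <- table(x$subjects$group)
  cat(sprintf(
    "Conversion-aligned cohort: %d HD + %d control subjects, %d visits\n",
    ns[["HD"]], ns[["control"]], nrow(x$visits)))
  cat(sprintf("  generative form: %s; behaviour channels: %s\n",
              x$config$dynamics_form,
              if (!is.null(x$visits$tms)) "tms, sdmt" else "none"))
  invisible(x)
}

#' Extract one subject's time series from a cohort
#'
#' @param cohort An `hd_cohort` (or a list with `subjects` and `visits`).
#' @param id Subject identifier.
#' @return List with `id`, `times`, `volumes` (visits x 55 matrix) and
#'   `behavior` (visits x 2 matrix or `NULL`), class `subject_series`.
#' @export
subject_series <- function(cohort, id) {
  v <- cohort$visits[cohort$visits$id == id, , drop = FALSE]
  if (nrow(v) == 0) stop("unknown subject id: ", id)
  regions <- hd_region_table()$region
  beh <- NULL
  if (all(c("tms", "sdmt") %in% names(v)) && !anyNA(v$tms))
    beh <- as.matrix(v[, c("tms", "sdmt")])
  structure(list(id = id,
                 times = v$time_years,
                 volumes = as.matrix(v[, regions]),
                 behavior = beh),
            class = "subject_series")
}

#' Rescale raw clinical scores to the bounded worsening scale
#'
#' Affine map of raw scores onto `[0, 100]` anchored at the minimum and
#' maximum observed in the HD sample, oriented so that an increase always
#' indicates worsening: scores where higher raw values are worse (TMS) map
#' min to 0 and max to 100; scores where higher raw values are better (SDMT)
#' are inverted.
#'
#' @param raw_scores Numeric raw scores.
#' @param hd_sample_min,hd_sample_max Anchors from the HD sample only.
#' @param higher_is_worse Logical orientation flag.
#' @return Rescaled scores (values for raw inputs inside the HD range lie in
#'   `[0, 100]`).
#' @examples
#' rescale_scores(c(10, 30, 50), 10, 50, higher_is_worse = TRUE)
#' rescale_scores(c(10, 30, 50), 10, 50, higher_is_worse = FALSE)
#' @export
rescale_scores <- function(raw_scores, hd_sample_min, hd_sample_max,
                           higher_is_worse = TRUE) {
  if (!(hd_sample_max > hd_sample_min))
    stop("degenerate range: hd_sample_max must exceed hd_sample_min")
  u <- (raw_scores - hd_sample_min) / (hd_sample_max - hd_sample_min)
  if (!higher_is_worse) u <- 1 - u
  100 * u
}
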