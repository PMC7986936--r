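#' Convert a percent decade loss into a per-year exponential decay rate
#'
#' Under exponential atrophy `x(t) = x(0) exp(a t)` a loss of `loss` percent
#' over a 10-year span corresponds to `a = log(1 - loss/100) / 10`.
#'
#' @param loss Percent volume loss over a decade (e.g. 18.7).
#' @return Positive per-year decay magnitude (the self-connection is `-decay`).
#' @export
decay_from_decade_loss <- function(loss) {
  stopifnot(is.numeric(loss), loss < 100)
  -log(1 - loss / 100) / 10
}

# discretized truncated-normal CAG marginal on 39..50; (mu, sigma) calibrated
# once so the discretized mean/sd equal the reported 43.67 / 2.77
.default_cag_law <- function() {
  k <- 39:50
  p <- stats::pnorm(k + 0.5, 43.2423, 3.4367) -
    stats::pnorm(k - 0.5, 43.2423, 3.4367)
  stats::setNames(p / sum(p), k)
}

.cag_law_mean <- function(law) {
  sum(as.integer(names(law)) * law)
}

# reference CAG at which group-level decay defaults are anchored
.cag_center <- 42

#' Configuration of the synthetic conversion-aligned cohort
#'
#' Builds the full configuration of the synthetic two-group cohort generator.
#' Defaults encode the study design being emulated: 49 converters + 49
#' age-matched controls, 3--7 annual visits inside the window `[-6, 5]` years
#' around motor conversion, a visit-count law with mean 5.84 scans for the
#' HD group, a CAG marginal with mean 43.67 and sd 2.77 on 39..50, a
#' CAG--onset-age correlation of -0.85, region-specific exponential atrophy
#' with striatal losses of 18.7% (putamen) and 15.4% (caudate) of baseline
#' per decade at the median CAG, near-flat control dynamics (1% per decade),
#' and behavioural readouts calibrated so the noise-free TMS and SDMT
#' channels worsen by 57.80 and 16.78 points over the decade `[-6, 4]`.
#'
#' @param n_hd,n_control Group sizes.
#' @param visit_count_law,control_visit_count_law Named probability vectors
#'   over visit counts 3..7.
#' @param time_window Two-element numeric window (years around conversion).
#' @param true_decay Named list with elements `hd` and `control`, each a
#'   28-vector of per-year decay magnitudes in state order (group-level value
#'   at `CAG = 42 + cag_slope` centring; see `cag_slope`).
#' @param group_offset 28-vector: HD minus control volume offset (% points)
#'   of the initial state at `t = 0`.
#' @param cag_slope 28-vector: additional per-year decay per CAG unit above
#'   42 (HD subjects only).
#' @param cag_law Named probability vector over integer CAG values 39..50.
#' @param cag_onset_corr Target Pearson correlation between CAG and age at
#'   conversion, in `(-1, 0]`.
#' @param age_mean,age_sd,age_range Age-at-alignment marginal (years).
#' @param noise_sd Measurement noise sd on the volume % scale.
#' @param behavior Logical: generate TMS/SDMT behavioural channels.
#' @param behavior_targets Decade worsening (points on the `[0,100]` scale)
#'   of the noise-free TMS and SDMT channels for the reference subject;
#'   readout weights are scaled to meet these.
#' @param behavior_baseline Reference scores at `t = -6` for TMS and SDMT.
#' @param behavior_noise_sd Behavioural noise sd (score points).
#' @param dynamics_form Generative state model: `"dynamic"` (exponential
#'   decay; the default), `"constant_rate"`, `"quadratic_rate"` or
#'   `"dynamic_sigmoid"`.
#' @param connectivity Optional two-column matrix of directed
#'   (source state, target state) edges driving interregional dynamics.
#' @param edge_weights Numeric vector of per-year edge weights, one per row
#'   of `connectivity`.
#' @param site_levels,site_probs_hd,site_probs_control Site labels and
#'   per-group sampling probabilities.
#' @param female_p_hd,female_p_control Probability of female gender.
#' @param tiv_mean,tiv_sd TIV marginal (ml); males get `tiv_male_shift` more.
#' @param tiv_male_shift Additive male TIV shift (ml).
#' @param visit_start Optional fixed integer first-visit time overriding the
#'   uniform draw over admissible window placements.
#' @param seed Integer seed; all generator randomness flows from it.
#' @return An object of class `cohort_config` (a validated list).
#' @examples
#' cfg <- cohort_config(n_hd = 4, n_control = 4, seed = 1)
#' cfg$true_decay$hd[["putamen"]]
#' @export
cohort_config <- function(n_hd = 49,
                          n_control = 49,
                          visit_count_law = c(`3` = 0.14, `4` = 0.14,
                                              `5` = 0.07, `6` = 0.04,
                                              `7` = 0.61),
                          control_visit_count_law = c(`3` = 0.10, `4` = 0.11,
                                                      `5` = 0.08, `6` = 0.037,
                                                      `7` = 0.673),
                          time_window = c(-6, 5),
                          true_decay = NULL,
                          group_offset = NULL,
                          cag_slope = NULL,
                          cag_law = .default_cag_law(),
                          cag_onset_corr = -0.85,
                          age_mean = 44.59, age_sd = 9.28,
                          age_range = c(28, 66),
                          noise_sd = 1.0,
                          behavior = TRUE,
                          behavior_targets = c(tms = 57.80, sdmt = 16.78),
                          behavior_baseline = c(tms = 20, sdmt = 35),
                          behavior_noise_sd = 5.0,
                          dynamics_form = "dynamic",
                          connectivity = NULL,
                          edge_weights = NULL,
                          site_levels = c("Leiden", "London", "Paris",
                                          "Vancouver"),
                          site_probs_hd = c(0.449, 0.204, 0.204, 0.143),
                          site_probs_control = c(0.286, 0.204, 0.286, 0.224),
                          female_p_hd = 0.551,
                          female_p_control = 0.61,
                          tiv_mean = 1420, tiv_sd = 120, tiv_male_shift = 110,
                          visit_start = NULL,
                          seed = 1L) {
  states <- hd_state_names()
  lobes <- .state_lobes()
  n_states <- length(states)

  if (is.null(cag_slope)) {
    cag_slope <- stats::setNames(numeric(n_states), states)
    cag_slope[c("putamen", "caudate")] <- c(0.0012, 0.0010)
    cag_slope[lobes == "occipital"] <- 0.0010
    cag_slope[lobes == "parietal"] <- 0.0007
  }

  if (is.null(true_decay)) {
    hd <- stats::setNames(numeric(n_states), states)
    hd[lobes == "frontal"] <- 0.003
    hd[lobes == "limbic"] <- 0.003
    hd[lobes == "temporal"] <- 0.003
    hd[lobes == "parietal"] <- 0.006
    hd[lobes == "occipital"] <- 0.008
    hd["white_matter"] <- 0.005
    # striatal decays anchored so the subject at the mean CAG (43.67) has
    # exactly the reported decade losses (group value lives at CAG = 42)
    anchor <- .cag_law_mean(cag_law)
    hd["putamen"] <- decay_from_decade_loss(18.7) -
      cag_slope[["putamen"]] * (anchor - .cag_center)
    hd["caudate"] <- decay_from_decade_loss(15.4) -
      cag_slope[["caudate"]] * (anchor - .cag_center)
    ctl <- stats::setNames(rep(decay_from_decade_loss(1.0), n_states), states)
    true_decay <- list(hd = hd, control = ctl)
  }

  if (is.null(group_offset)) {
    group_offset <- stats::setNames(rep(-2, n_states), states)
    group_offset[c("putamen", "caudate")] <- c(-8, -7)
    group_offset[lobes %in% c("occipital", "parietal")] <- -3
  }

  cfg <- list(
    n_hd = as.integer(n_hd), n_control = as.integer(n_control),
    visit_count_law = visit_count_law,
    control_visit_count_law = control_visit_count_law,
    time_window = as.numeric(time_window),
    region_labels = hd_region_table()$region,
    true_decay = lapply(true_decay, function(v)
      stats::setNames(as.numeric(v), states)),
    group_offset = stats::setNames(as.numeric(group_offset), states),
    cag_slope = stats::setNames(as.numeric(cag_slope), states),
    cag_law = cag_law,
    cag_onset_corr = cag_onset_corr,
    age_mean = age_mean, age_sd = age_sd, age_range = age_range,
    noise_sd = noise_sd,
    behavior = isTRUE(behavior),
    behavior_targets = behavior_targets,
    behavior_baseline = behavior_baseline,
    behavior_noise_sd = behavior_noise_sd,
    dynamics_form = match.arg(dynamics_form,
                              c("dynamic", "constant_rate", "quadratic_rate",
                                "dynamic_sigmoid")),
    connectivity = connectivity,
    edge_weights = edge_weights,
    site_levels = site_levels,
    site_probs_hd = site_probs_hd,
    site_probs_control = site_probs_control,
    female_p_hd = female_p_hd, female_p_control = female_p_control,
    tiv_mean = tiv_mean, tiv_sd = tiv_sd, tiv_male_shift = tiv_male_shift,
    visit_start = visit_start,
    seed = as.integer(seed)
  )
  cfg$behavior_weights <- if (cfg$behavior) .behavior_weights(cfg) else NULL
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic conversion-aligned cohort configuration\n")
  cat(sprintf("  %d HD + %d control subjects, window [%g, %g] years\n",
              x$n_hd, x$n_control, x$time_window[1], x$time_window[2]))
  cat(sprintf("  generative form: %s; noise sd %.2f%%; behaviour: %s\n",
              x$dynamics_form, x$noise_sd,
              if (x$behavior) "TMS+SDMT" else "none"))
  cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}

validate_cohort_config <- function(cfg) {
  stop_cfg <- function(msg) stop("invalid cohort config: ", msg, call. = FALSE)
  states <- hd_state_names()
  counts <- as.integer(names(cfg$visit_count_law))
  if (!all(counts %in% 3:7)) stop_cfg("visit_count_law support must be in 3..7")
  counts_c <- as.integer(names(cfg$control_visit_count_law))
  if (!all(counts_c %in% 3:7))
    stop_cfg("control_visit_count_law support must be in 3..7")
  if (any(cfg$visit_count_law < 0) || abs(sum(cfg$visit_count_law) - 1) > 1e-8)
    stop_cfg("visit_count_law must be a probability vector")
  if (cfg$noise_sd < 0) stop_cfg("noise_sd must be >= 0")
  if (cfg$behavior_noise_sd < 0) stop_cfg("behavior_noise_sd must be >= 0")
  cag_vals <- as.integer(names(cfg$cag_law))
  if (!all(cag_vals %in% 39:50) || any(cfg$cag_law < 0))
    stop_cfg("cag_law must be a distribution over integers in 39..50")
  if (!(cfg$cag_onset_corr > -1 && cfg$cag_onset_corr <= 0))
    stop_cfg("cag_onset_corr must be in (-1, 0]")
  if (diff(cfg$time_window) < max(counts) - 1)
    stop_cfg("time window too short to host the largest visit count")
  for (g in c("hd", "control")) {
    if (!identical(names(cfg$true_decay[[g]]), states))
      stop_cfg("true_decay must be named by the 28 states")
  }
  if (!is.null(cfg$connectivity)) {
    ce <- cfg$connectivity
    if (ncol(ce) != 2 || any(ce[, 1] == ce[, 2]))
      stop_cfg("connectivity edges must be (source, target) pairs, no self")
    if (length(cfg$edge_weights) != nrow(ce))
      stop_cfg("edge_weights must match connectivity rows")
  }
  if (cfg$behavior) {
    w <- cfg$behavior_weights
    if (!all(rownames(w$weights) %in% states))
      stop_cfg("behaviour weight map references unknown state")
  }
  # volumes must stay positive over the window for the reference subject
  worst <- max(cfg$true_decay$hd + pmax(cfg$cag_slope, 0) * (50 - .cag_center))
  span <- max(abs(cfg$time_window))
  if (100 * exp(-worst * -min(cfg$time_window)) <= 0 || worst * span >= 5)
    stop_cfg("decay produces non-positive volumes within the window")
  invisible(cfg)
}

# Behavioural readout calibration. The reference subject is an HD subject at
# the mean CAG with x0 = 100 + group offset and the default exponential
# decays; raw support patterns are scaled so the noise-free decade change
# (t = -6 -> +4) of each channel equals the configured target, and the
# intercept puts the reference score at `behavior_baseline` at t = -6.
.behavior_weights <- function(cfg) {
  states <- hd_state_names()
  anchor <- .cag_law_mean(cfg$cag_law)
  a <- -(cfg$true_decay$hd + cfg$cag_slope * (anchor - .cag_center))
  x0 <- 100 + cfg$group_offset
  x_lo <- x0 * exp(a * -6)   # window start
  x_hi <- x0 * exp(a * 4)    # a decade later
  raw <- matrix(0, length(states), 2,
                dimnames = list(states, c("tms", "sdmt")))
  tms_support <- c("caudate", "cingulate", "entorhinal", "parahippocampal",
                   "calcarine", "supplementary_motor", "temporal_pole",
                   "inferior_frontal", "lingual", "cuneus", "planum_temporale")
  raw[tms_support, "tms"] <- -1
  sdmt_support <- c("cingulate", "orbital_gyrus", "middle_occipital",
                    "lingual", "entorhinal")
  raw[sdmt_support, "sdmt"] <- -1
  raw["putamen", "sdmt"] <- 0.4
  change <- drop(crossprod(raw, x_hi - x_lo))  # raw score change per channel
  scale <- cfg$behavior_targets[c("tms", "sdmt")] / change
  w <- sweep(raw, 2, scale, `*`)
  b <- cfg$behavior_baseline[c("tms", "sdmt")] - drop(crossprod(w, x_lo))
  list(weights = w, intercept = stats::setNames(as.numeric(b),
                                                c("tms", "sdmt")))
}
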