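#' Specify a candidate generative state model
#'
#' Four candidate subject-level state models describe regional volume
#' progression `dx/dt = A x + C u(t)` with observation `y = g(x) + e`:
#' \describe{
#'   \item{`constant_rate`}{`A = 0`, constant input: `x(t) = x0 + c0 t`.}
#'   \item{`quadratic_rate`}{`A = 0`, ramp input: `x(t) = x0 + c0 t + c1 t^2/2`.}
#'   \item{`dynamic`}{negative self-connections only: `x_i(t) = x0_i exp(a_i t)`
#'     with `a_i = -exp(lambda_i)`; optional interregional edges make `A`
#'     non-diagonal, solved by eigendecomposition.}
#'   \item{`dynamic_sigmoid`}{self-connections plus a logistic input
#'     `u(t) = 1/(1+exp(-(t-t0)/tau))` scaled by per-state sensitivities,
#'     integrated by fixed-step RK4 (step 0.05 years) outward from `t = 0`.}
#' }
#' Bilateral region pairs share a latent state; both hemisphere columns are
#' predicted by the shared state.
#'
#' @param form One of `"constant_rate"`, `"quadratic_rate"`, `"dynamic"`,
#'   `"dynamic_sigmoid"`.
#' @param connectivity Optional two-column integer matrix of directed
#'   (source state, target state) edges (dynamic forms only). Self-pairs are
#'   rejected; self-connections are always present in dynamic forms.
#' @param behavior_channels Character vector of behavioural channel names
#'   read out from the states (e.g. `c("tms", "sdmt")`), or `NULL`.
#' @return An object of class `state_model_spec`.
#' @examples
#' spec <- state_model_spec("dynamic")
#' spec$n_states
#' @export
state_model_spec <- function(form = c("dynamic", "constant_rate",
                                      "quadratic_rate", "dynamic_sigmoid"),
                             connectivity = NULL,
                             behavior_channels = NULL) {
  form <- match.arg(form)
  tab <- hd_region_table()
  n_states <- max(tab$state)
  if (anyDuplicated(tab$region) || nrow(tab) != 55)
    stop("region table must map each of the 55 region columns exactly once")
  if (!is.null(connectivity)) {
    if (!form %in% c("dynamic", "dynamic_sigmoid"))
      stop("connectivity edges require a dynamic form")
    connectivity <- as.matrix(connectivity)
    storage.mode(connectivity) <- "integer"
    if (ncol(connectivity) != 2)
      stop("connectivity must be a two-column (source, target) matrix")
    if (any(connectivity[, 1] == connectivity[, 2]))
      stop("connectivity edges must exclude self-pairs")
    if (any(connectivity < 1 | connectivity > n_states))
      stop("connectivity edges reference unknown states")
    if (anyDuplicated(connectivity))
      stop("duplicate connectivity edges")
  }
  structure(list(form = form,
                 n_states = n_states,
                 state_to_region = tab$state,
                 region_labels = tab$region,
                 connectivity = connectivity,
                 behavior_channels = behavior_channels),
            class = "state_model_spec")
}

#' @export
print.state_model_spec <- function(x, ...) {
  cat(sprintf("State model '%s': %d states -> %d region columns",
              x$form, x$n_states, length(x$region_labels)))
  if (!is.null(x$connectivity))
    cat(sprintf(", %d interregional edges", nrow(x$connectivity)))
  if (!is.null(x$behavior_channels))
    cat(sprintf(", behaviour channels: %s",
                paste(x$behavior_channels, collapse = ", ")))
  cat("\n")
  invisible(x)
}

#' Preset interregional connectivity edge sets
#'
#' Two edge families probing atrophy spread: `striatal_cortical` connects the
#' caudate and putamen states to every cortical state; `cortical_cortical`
#' chains neighbouring cortical states within each lobe in both directions.
#'
#' @return Named list of two-column (source, target) edge matrices.
#' @export
connectivity_presets <- function() {
  tab <- hd_region_table()
  st <- tab[!duplicated(tab$state), c("state", "state_name", "lobe")]
  cortical <- st$state[!st$lobe %in% c("subcortical", "white_matter")]
  striatal <- st$state[st$state_name %in% c("caudate", "putamen")]
  sc <- cbind(rep(striatal, each = length(cortical)),
              rep(cortical, times = length(striatal)))
  cc <- NULL
  for (lb in unique(st$lobe[st$state %in% cortical])) {
    s <- st$state[st$lobe == lb]
    if (length(s) > 1) {
      pairs <- cbind(s[-length(s)], s[-1])
      cc <- rbind(cc, pairs, pairs[, 2:1, drop = FALSE])
    }
  }
  list(striatal_cortical = unname(sc), cortical_cortical = unname(cc))
}

#' Logistic input driving accelerated progression
#'
#' `u(t) = 1 / (1 + exp(-(t - t0)/tau))`, a smooth 0-to-1 transition centred
#' at `t0` with time constant `tau` (years).
#'
#' @param t Time(s) in years relative to conversion.
#' @param t0 Transition midpoint (years).
#' @param tau Transition time constant, `> 0`.
#' @return Values in `(0, 1)`.
#' @examples
#' sigmoid_input(0, 0, 1)      # 0.5 at the midpoint
#' @export
sigmoid_input <- function(t, t0, tau) {
  if (!is.numeric(tau) || tau <= 0) stop("tau must be > 0")
  stats::plogis((t - t0) / tau)
}

# default subject parameter skeleton for a spec (internal)
.empty_params <- function(spec) {
  n <- spec$n_states
  p <- list(x0 = rep(100, n))
  if (spec$form %in% c("constant_rate", "quadratic_rate"))
    p$rate_c0 <- numeric(n)
  if (spec$form == "quadratic_rate") p$accel_c1 <- numeric(n)
  if (spec$form %in% c("dynamic", "dynamic_sigmoid"))
    p$log_decay <- rep(log(0.01), n)
  if (spec$form == "dynamic_sigmoid") {
    p$rate_c0 <- numeric(n)
    p$input_params <- c(t0 = 0, log_tau = 0)
  }
  if (!is.null(spec$connectivity))
    p$edge_weights <- numeric(nrow(spec$connectivity))
  p
}

# dense dynamics matrix A from params (dynamic forms)
.dyn_matrix <- function(spec, params) {
  A <- diag(-exp(params$log_decay), spec$n_states)
  if (!is.null(spec$connectivity)) {
    A[spec$connectivity[, 2:1, drop = FALSE]] <- params$edge_weights
  }
  A
}

#' Integrate latent atrophy states over time
#'
#' Exact (closed-form or eigendecomposition) trajectories for the
#' polynomial-rate and pure dynamic forms; fixed-step RK4 (0.05 years,
#' integrating forward and backward from the anchor `t = 0`) for the
#' sigmoid-input form. `x(0) = x0` for every form.
#'
#' @param spec A [state_model_spec()].
#' @param params Named list of subject parameters: `x0` (28), and depending
#'   on the form `rate_c0`, `accel_c1`, `log_decay`,
#'   `input_params = c(t0, log_tau)`, `edge_weights`.
#' @param times Numeric vector of times (years) at which states are returned.
#' @return Object of class `state_trajectory`: list with `times` and
#'   `states` (`length(times)` by 28 matrix).
#' @examples
#' spec <- state_model_spec("dynamic")
#' pp <- list(x0 = rep(100, 28), log_decay = rep(log(0.02), 28))
#' tr <- integrate_states(spec, pp, -6:5)
#' tr$states[tr$times == 0, 1]   # anchored at x0
#' @export
integrate_states <- function(spec, params, times) {
  stopifnot(inherits(spec, "state_model_spec"))
  times <- as.numeric(times)
  pl <- utils::modifyList(.empty_params(spec), params)
  if (!all(vapply(pl, function(v) all(is.finite(v)), logical(1))))
    stop("non-finite parameters")
  n <- spec$n_states
  if (length(pl$x0) != n) stop("x0 must have one value per state")
  states <- switch(
    spec$form,
    constant_rate = outer(times, rep(1, n)) *
      rep(pl$rate_c0, each = length(times)) +
      rep(pl$x0, each = length(times)),
    quadratic_rate = rep(pl$x0, each = length(times)) +
      outer(times, pl$rate_c0) + outer(times^2 / 2, pl$accel_c1),
    dynamic = {
      if (is.null(spec$connectivity)) {
        a <- -exp(pl$log_decay)
        t(pl$x0 * exp(outer(a, times)))
      } else {
        .traj_lingen(.dyn_matrix(spec, pl), pl$x0, times)
      }
    },
    dynamic_sigmoid = {
      tau <- exp(pl$input_params[["log_tau"]])
      .traj_rk4(.dyn_matrix(spec, pl), pl$rate_c0,
                pl$input_params[["t0"]], tau, pl$x0, times,
                h = 0.05, has_input = TRUE)
    },
    stop("unknown model form")
  )
  structure(list(times = times, states = states), class = "state_trajectory")
}

#' Map latent states to predicted observations
#'
#' Each observed region column is predicted by its latent state (bilateral
#' pairs read the same shared state); behavioural channels, when configured,
#' are weighted state sums plus an intercept. No noise is added: noise
#' belongs to the likelihood.
#'
#' @param traj A `state_trajectory` from [integrate_states()].
#' @param spec The [state_model_spec()].
#' @param params Subject parameters; when `spec$behavior_channels` is set,
#'   must carry `behavior_weights` (28 x channels matrix) and
#'   `behavior_intercept` (per channel).
#' @return Matrix `[time x (55 + n channels)]` with region (and channel)
#'   column names.
#' @export
observe_states <- function(traj, spec, params) {
  stopifnot(inherits(traj, "state_trajectory"))
  y <- traj$states[, spec$state_to_region, drop = FALSE]
  colnames(y) <- spec$region_labels
  if (!is.null(spec$behavior_channels)) {
    if (is.null(params$behavior_weights) ||
        is.null(params$behavior_intercept))
      stop("behaviour channels requested without weights")
    w <- as.matrix(params$behavior_weights)
    if (nrow(w) != spec$n_states)
      stop("behaviour weights must have one row per state")
    b <- traj$states %*% w
    b <- sweep(b, 2, params$behavior_intercept, `+`)
    colnames(b) <- spec$behavior_channels
    y <- cbind(y, b)
  }
  y
}

#' Percent volume loss over a ten-year span implied by a decay rate
#'
#' For the dynamic (exponential) forms, the self-connection `a = -exp(lambda)`
#' implies a loss of `100 (1 - exp(10 a))` percent of the span-start volume
#' over 10 years.
#'
#' @param params Subject parameter list carrying `log_decay`.
#' @param state State index (1..28) or state name.
#' @param span Span in years (default 10).
#' @return Percent loss (positive for decay).
#' @examples
#' p <- list(log_decay = log(0.0207))
#' predict_decade_loss(p, 1)    # ~18.7
#' @export
predict_decade_loss <- function(params, state, span = 10) {
  if (is.null(params$log_decay))
    stop("decade loss requires a dynamic-form parameterization (log_decay)")
  if (is.character(state)) state <- match(state, hd_state_names())
  a <- -exp(params$log_decay[state])
  100 * (1 - exp(span * a))
}
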