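# Parameter packing and prior specification for subject-level models.
# Parameter vector layout (names are stable and used by the group level):
#   x0.<state>          initial states (% volume at t = 0)
#   c0.<state>          constant rate / input sensitivity
#   c1.<state>          quadratic acceleration
#   lambda.<state>      log decay; self-connection a = -exp(lambda)
#   t0, log_tau         sigmoid input parameters
#   edge.<src>-><tgt>   interregional edge weights
#   w.<channel>.<state>, b.<channel>   behavioural readout
# The log noise precision(s) are handled as separate variational factors,
# not entries of this vector.

.param_names <- function(spec) {
  st <- hd_state_names()
  nm <- paste0("x0.", st)
  if (spec$form %in% c("constant_rate", "quadratic_rate", "dynamic_sigmoid"))
    nm <- c(nm, if (spec$form != "dynamic_sigmoid") paste0("c0.", st))
  if (spec$form == "quadratic_rate") nm <- c(nm, paste0("c1.", st))
  if (spec$form %in% c("dynamic", "dynamic_sigmoid"))
    nm <- c(nm, paste0("lambda.", st))
  if (spec$form == "dynamic_sigmoid")
    nm <- c(nm, paste0("c0.", st), "t0", "log_tau")
  if (!is.null(spec$connectivity))
    nm <- c(nm, sprintf("edge.%d->%d", spec$connectivity[, 1],
                        spec$connectivity[, 2]))
  for (ch in spec$behavior_channels)
    nm <- c(nm, paste0("w.", ch, ".", st), paste0("b.", ch))
  nm
}

# unpack a named parameter vector into the list form used by
# integrate_states()/observe_states()
.unpack_params <- function(theta, spec) {
  st <- hd_state_names()
  n <- length(st)
  take <- function(prefix) unname(theta[paste0(prefix, ".", st)])
  p <- list(x0 = take("x0"))
  if (spec$form %in% c("constant_rate", "quadratic_rate", "dynamic_sigmoid"))
    p$rate_c0 <- take("c0")
  if (spec$form == "quadratic_rate") p$accel_c1 <- take("c1")
  if (spec$form %in% c("dynamic", "dynamic_sigmoid"))
    p$log_decay <- take("lambda")
  if (spec$form == "dynamic_sigmoid")
    p$input_params <- c(t0 = unname(theta["t0"]),
                        log_tau = unname(theta["log_tau"]))
  if (!is.null(spec$connectivity)) {
    enm <- sprintf("edge.%d->%d", spec$connectivity[, 1],
                   spec$connectivity[, 2])
    p$edge_weights <- unname(theta[enm])
  }
  if (!is.null(spec$behavior_channels)) {
    w <- sapply(spec$behavior_channels,
                function(ch) unname(theta[paste0("w.", ch, ".", st)]))
    p$behavior_weights <- matrix(w, nrow = n,
                                 dimnames = list(st, spec$behavior_channels))
    p$behavior_intercept <- stats::setNames(
      unname(theta[paste0("b.", spec$behavior_channels)]),
      spec$behavior_channels)
  }
  p
}

#' Prior specification for subject-level model inversion
#'
#' Weakly informative Gaussian priors on the subject parameter vector, on the
#' volume % scale: `x0 ~ N(100, 10^2)`, `lambda ~ N(log 0.01, 1)` (decade-
#' plausible decay magnitudes), `c0 ~ N(0, 1)`, `c1 ~ N(0, 0.5^2)`,
#' `t0 ~ N(0, 2^2)`, `log tau ~ N(0, 0.5^2)`, edge weights `N(0, 0.1^2)`,
#' behavioural weights `N(0, 1)` and intercepts `N(50, 50^2)`. The shared
#' log noise precision has prior `N(0, 1)` for volumes and `N(0, 2^2)` for
#' behavioural channels (scores live on a different scale).
#'
#' @param spec A [state_model_spec()].
#' @param ... Named overrides of individual prior means/variances, e.g.
#'   `mean = c("x0.putamen" = 95)` or `var = c("lambda.caudate" = 4)`.
#' @return Object of class `prior_spec`: list with `mean`, `var` (named
#'   vectors over the parameter layout), `noise` and `behavior_noise`
#'   (each `list(mean, var)` for the log precision).
#' @export
prior_spec <- function(spec, ...) {
  nm <- .param_names(spec)
  mu <- stats::setNames(numeric(length(nm)), nm)
  v <- stats::setNames(rep(1, length(nm)), nm)
  mu[startsWith(nm, "x0.")] <- 100
  v[startsWith(nm, "x0.")] <- 100
  mu[startsWith(nm, "lambda.")] <- log(0.01)
  v[startsWith(nm, "lambda.")] <- 1
  v[startsWith(nm, "c0.")] <- 1
  v[startsWith(nm, "c1.")] <- 0.25
  if ("t0" %in% nm) v["t0"] <- 4
  if ("log_tau" %in% nm) v["log_tau"] <- 0.25
  v[startsWith(nm, "edge.")] <- 0.01
  v[startsWith(nm, "w.")] <- 1
  mu[startsWith(nm, "b.")] <- 50
  v[startsWith(nm, "b.")] <- 2500
  out <- list(mean = mu, var = v,
              noise = list(mean = 0, var = 1),
              behavior_noise = list(mean = 0, var = 4))
  dots <- list(...)
  for (fld in intersect(names(dots), c("mean", "var"))) {
    ov <- dots[[fld]]
    if (!all(names(ov) %in% nm)) stop("unknown parameter in prior override")
    out[[fld]][names(ov)] <- ov
  }
  if (!is.null(dots$noise)) out$noise <- dots$noise
  if (!is.null(dots$behavior_noise)) out$behavior_noise <- dots$behavior_noise
  if (any(out$var <= 0)) stop("prior variances must be positive")
  class(out) <- "prior_spec"
  out
}
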