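#' Orthogonalize one covariate with respect to another
#'
#' Mean-centres both vectors and removes from `v` its projection onto `w`
#' (equivalently, returns the residual of the least-squares regression of
#' centred `v` on centred `w`).
#'
#' @param v,w Numeric vectors of equal length.
#' @return The component of centred `v` orthogonal to centred `w`.
#' @export
orthogonalize <- function(v, w) {
  stopifnot(length(v) == length(w), length(v) > 0)
  v <- v - mean(v); w <- w - mean(w)
  if (sum(w^2) < 1e-24) stop("cannot orthogonalize against a constant vector")
  v - w * sum(v * w) / sum(w^2)
}

#' Build the second-level design matrix
#'
#' Columns, in fixed order: overall mean (all ones), diagnostic group
#' (+1 HD / -1 control, included when both groups are present), CAG-repeat
#' length (z-scored over HD subjects; controls enter at the column centre 0),
#' gender (+1 F / -1 M, centred), age at conversion (z-scored, then
#' orthogonalized with respect to the CAG column because of their high
#' correlation), TIV (z-scored) and centred site indicator columns (reference
#' level dropped; a single-site cohort drops the site block with a notice).
#'
#' @param subjects Subject table (as in an `hd_cohort`).
#' @param center Kept for interface clarity; continuous covariates are always
#'   centred and unit-scaled.
#' @param extra Optional named list/data.frame of additional numeric
#'   covariates (z-scored and appended).
#' @return Object of class `design_matrix`: list with `values`
#'   (subjects x columns), `column_labels` and `subject_ids`.
#' @export
build_design_matrix <- function(subjects, center = TRUE, extra = NULL) {
  n <- nrow(subjects)
  if (n < 2) stop("at least 2 subjects are required")
  zscore <- function(x) {
    x <- x - mean(x)
    s <- stats::sd(x)
    if (s > 0) x / s else x
  }
  cols <- list(mean = rep(1, n))
  groups <- unique(subjects$group)
  if (length(groups) > 1)
    cols$group <- ifelse(subjects$group == "HD", 1, -1)
  hd <- subjects$group == "HD"
  cag <- rep(0, n)
  if (any(hd) && !all(is.na(subjects$cag[hd]))) {
    cag[hd] <- (subjects$cag[hd] - mean(subjects$cag[hd]))
    s <- stats::sd(subjects$cag[hd])
    if (s > 0) cag <- cag / s
    cols$cag <- cag
  }
  g <- ifelse(subjects$gender == "F", 1, -1)
  cols$gender <- g - mean(g)
  age <- zscore(subjects$age)
  cols$age_orth <- if (!is.null(cols$cag) && stats::sd(cag) > 0)
    orthogonalize(age, cag) else age
  cols$tiv <- zscore(subjects$tiv)
  sites <- sort(unique(subjects$site))
  if (length(sites) > 1) {
    for (s in sites[-1]) {
      d <- as.numeric(subjects$site == s)
      cols[[paste0("site_", s)]] <- d - mean(d)
    }
  } else {
    message("single site: site columns dropped from the design matrix")
  }
  if (!is.null(extra)) {
    for (nmx in names(extra)) cols[[nmx]] <- zscore(as.numeric(extra[[nmx]]))
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  structure(list(values = X, column_labels = colnames(X),
                 subject_ids = subjects$id),
            class = "design_matrix")
}

#' Settings for parametric empirical Bayes
#'
#' @param alpha_range Search interval for the log between-subject precision
#'   scalar.
#' @param tol Tolerance of the 1-d evidence optimization.
#' @param re_scale Prior expectation of the random-effects variance is the
#'   first-level prior variance divided by `re_scale` (componentwise).
#' @return Settings list.
#' @export
peb_settings <- function(alpha_range = c(-4, 6), tol = 0.1, re_scale = 16) {
  list(alpha_range = alpha_range, tol = tol, re_scale = re_scale)
}

# Per-subject Gaussian "likelihood over parameters" summaries obtained from
# the variational posterior via the Bayesian-model-reduction identity:
#   p(y_s | theta) ~ exp(F_s) N(theta; m_s, S_s) / N(theta; mu0, S0)
# giving exp(c_s - theta' Pt_s theta / 2 + h_s' theta).  Each posterior is
# divided by the prior it was actually fitted under (which may be a subject-
# specific empirical prior from an earlier group pass).
.subject_summaries <- function(posteriors, priors = NULL) {
  lapply(posteriors, function(po) {
    pr <- if (!is.null(po$priors)) po$priors else priors
    mu0 <- pr$mean; v0 <- pr$var
    P0 <- 1 / v0
    R <- chol(po$covariance)
    P <- chol2inv(R)
    Pt <- P; diag(Pt) <- diag(Pt) - P0
    Pt <- (Pt + t(Pt)) / 2
    # guard against slightly indefinite differences
    ee <- eigen(Pt, symmetric = TRUE)
    ee$values <- pmax(ee$values, 0)
    Pt <- ee$vectors %*% (ee$values * t(ee$vectors))
    h <- drop(P %*% po$mean) - P0 * mu0
    cs <- po$free_energy -
      0.5 * (drop(crossprod(po$mean, P %*% po$mean)) - sum(mu0^2 * P0)) +
      0.5 * (-2 * sum(log(diag(R))) - sum(log(P0)))
    list(Pt = Pt, h = h, c = cs)
  })
}

# evidence and sufficient statistics of the second-level linear model at a
# given log precision scalar alpha.  The (p*k) x (p*k) data precision
# D = sum_s (x_s x_s') kron W_s is assembled by one matrix product over the
# stacked vec(W_s) columns (kronecker() per subject is far too slow here).
.peb_at_alpha <- function(alpha, summ, X, qdiag0, b0, vb) {
  p <- length(summ[[1]]$h)
  k <- ncol(X)
  n <- length(summ)
  qd <- exp(alpha) * qdiag0
  Wmat <- matrix(0, p * p, n)
  Gmat <- matrix(0, p, n)
  const <- 0
  for (s in seq_len(n)) {
    M <- summ[[s]]$Pt
    diag(M) <- diag(M) + qd
    R <- chol(M)
    Minv <- chol2inv(R)
    Mh <- Minv %*% summ[[s]]$h
    W <- -(qd * t(qd * Minv))            # - Q Minv Q
    diag(W) <- diag(W) + qd              # Q - Q Minv Q
    Wmat[, s] <- W
    Gmat[, s] <- qd * drop(Mh)
    const <- const + summ[[s]]$c + 0.5 * sum(log(qd)) -
      sum(log(diag(R))) + 0.5 * sum(summ[[s]]$h * Mh)
  }
  xx <- X[, rep(seq_len(k), k), drop = FALSE] *
    X[, rep(seq_len(k), each = k), drop = FALSE]   # n x k^2
  blocks <- Wmat %*% xx                            # p^2 x k^2
  D <- array(blocks, c(p, p, k, k))
  D <- aperm(D, c(1, 3, 2, 4))
  dim(D) <- c(p * k, p * k)
  d <- as.vector(Gmat %*% X)
  Pb <- D
  diag(Pb) <- diag(Pb) + 1 / vb
  Rb <- chol(Pb)
  eta <- b0 / vb + d
  mb <- backsolve(Rb, forwardsolve(t(Rb), eta))
  Fpeb <- const - 0.5 * sum(log(vb)) - 0.5 * sum(b0^2 / vb) -
    sum(log(diag(Rb))) + 0.5 * sum(eta * mb)
  list(F = Fpeb, D = D, d = d, Pb = Pb, mb = mb, const = const)
}

#' Fit the parametric-empirical-Bayes group model
#'
#' Embeds the subject-level posteriors in a second-level linear model
#' `theta_s = B x_s + xi_s` over the design matrix rows `x_s`, with Gaussian
#' random effects whose precision is a single estimated scalar on the
#' prior-scaled metric (random-effects variance = first-level prior variance
#' / (`re_scale` * lambda)). First-level uncertainty is propagated exactly
#' through the Gaussian summaries, so subjects with tighter posteriors (more
#' visits) carry more weight. The scalar is estimated by maximizing the
#' second-level free energy with a standard-normal prior on its log.
#'
#' @param posteriors List of `subject_posterior` objects over identical
#'   parameter vectors.
#' @param X A [build_design_matrix()] result (rows aligned to `posteriors`).
#' @param settings A [peb_settings()].
#' @param priors The group-level [prior_spec()] defining the prior over the
#'   effect matrix and the random-effects scale. Defaults to the first
#'   posterior's prior; pass the original model priors explicitly when the
#'   posteriors were re-fitted under subject-specific empirical priors.
#' @return Object of class `peb_result`: `beta` (parameters x design
#'   columns), `beta_covariance`, `free_energy`, `random_effects_precision`
#'   (lambda, on the prior-scaled metric), plus reusable evidence statistics
#'   for Bayesian model reduction.
#' @export
fit_peb <- function(posteriors, X, settings = peb_settings(),
                    priors = NULL) {
  stopifnot(inherits(X, "design_matrix"), length(posteriors) >= 2)
  pn <- names(posteriors[[1]]$mean)
  for (po in posteriors)
    if (!identical(names(po$mean), pn))
      stop("posteriors are not over identical parameter vectors")
  if (nrow(X$values) != length(posteriors))
    stop("design matrix rows do not align with posteriors")
  if (is.null(priors)) priors <- posteriors[[1]]$priors
  summ <- .subject_summaries(posteriors, priors)
  p <- length(pn); k <- ncol(X$values)
  qdiag0 <- settings$re_scale / priors$var        # precision at lambda = 1
  b0 <- c(priors$mean, rep(0, p * (k - 1)))       # mean column carries mu0
  vb <- rep(priors$var, k)
  obj <- function(alpha)
    .peb_at_alpha(alpha, summ, X$values, qdiag0, b0, vb)$F +
      stats::dnorm(alpha, 0, 1, log = TRUE)
  opt <- stats::optimize(obj, settings$alpha_range, maximum = TRUE,
                         tol = settings$tol)
  fit <- .peb_at_alpha(opt$maximum, summ, X$values, qdiag0, b0, vb)
  Sb <- chol2inv(chol(fit$Pb))
  beta <- matrix(fit$mb, p, k,
                 dimnames = list(pn, X$column_labels))
  structure(list(
    beta = beta,
    beta_covariance = Sb,
    free_energy = fit$F,
    random_effects_precision = exp(opt$maximum),
    alpha = opt$maximum,
    D = fit$D, d = fit$d, loglik_const = fit$const,
    b0 = b0, vb = vb,
    param_names = pn, column_labels = X$column_labels,
    X = X, priors = priors, settings = settings,
    qdiag = exp(opt$maximum) * qdiag0,
    summaries = summ
  ), class = "peb_result")
}

#' @export
print.peb_result <- function(x, ...) {
  cat(sprintf(
    "PEB group model: %d parameters x %d design columns, F = %.2f\n",
    length(x$param_names), length(x$column_labels), x$free_energy))
  cat(sprintf("  random-effects precision scalar: %.3f\n",
              x$random_effects_precision))
  invisible(x)
}

# evidence of the second-level model under an arbitrary Gaussian prior on
# beta, reusing the data statistics (no subject-level refitting)
.peb_evidence <- function(peb, b0, vb) {
  Pb <- peb$D
  diag(Pb) <- diag(Pb) + 1 / vb
  Rb <- chol(Pb)
  eta <- b0 / vb + peb$d
  mb <- backsolve(Rb, forwardsolve(t(Rb), eta))
  F_ <- peb$loglik_const - 0.5 * sum(log(vb)) - 0.5 * sum(b0^2 / vb) -
    sum(log(diag(Rb))) + 0.5 * sum(eta * mb)
  list(F = F_, mean = mb, Pb = Pb)
}

#' Empirically updated subject-level estimates under the group model
#'
#' The PEB conditional posterior of each subject's parameters combines the
#' subject's first-level summary with the group prediction `B x_s`; in the
#' diagonal-precision setting every component lies between the first-level
#' posterior mean and the group prediction (shrinkage).
#'
#' @param peb A [fit_peb()] result.
#' @return Matrix (subjects x parameters) of updated estimates.
#' @export
peb_subject_estimates <- function(peb) {
  X <- peb$X$values
  p <- length(peb$param_names)
  out <- matrix(NA_real_, nrow(X), p,
                dimnames = list(peb$X$subject_ids, peb$param_names))
  for (s in seq_len(nrow(X))) {
    mu_s <- drop(peb$beta %*% X[s, ])
    M <- peb$summaries[[s]]$Pt
    diag(M) <- diag(M) + peb$qdiag
    out[s, ] <- drop(solve(M, peb$summaries[[s]]$h + peb$qdiag * mu_s))
  }
  out
}
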