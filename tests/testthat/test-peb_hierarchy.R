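test_that("orthogonalization removes the projection and matches OLS", {
  set.seed(1)
  w <- rnorm(20); v <- 2 * w
  expect_equal(orthogonalize(v, w), rep(0, 20), tolerance = 1e-12)
  v2 <- rnorm(20)
  v2p <- orthogonalize(v2, w)
  expect_lt(abs(sum(v2p * (w - mean(w)))), 1e-10)
  # equals the residual of lm(centered v ~ centered w)
  res <- resid(lm(I(v2 - mean(v2)) ~ 0 + I(w - mean(w))))
  expect_equal(v2p, unname(res), tolerance = 1e-10)
  expect_error(orthogonalize(v2, rep(3, 20)), "constant")
})

test_that("the design matrix has the documented structure", {
  coh <- small_cohort(8, seed = 21)
  X <- build_design_matrix(coh$subjects)
  expect_equal(unname(X$values[, "mean"]), rep(1, 16))
  expect_setequal(unique(X$values[, "group"]), c(1, -1))
  # age orthogonal to CAG
  expect_lt(abs(sum(X$values[, "age_orth"] * X$values[, "cag"])), 1e-8)
  # controls at the CAG column centre
  expect_true(all(X$values[coh$subjects$group == "control", "cag"] == 0))
  # k - 1 centred site columns
  n_sites <- length(unique(coh$subjects$site))
  expect_equal(sum(startsWith(X$column_labels, "site_")), n_sites - 1)
  expect_equal(qr(X$values)$rank, ncol(X$values))
  # single site drops the block with a notice
  sub1 <- coh$subjects; sub1$site <- "Leiden"
  expect_message(X1 <- build_design_matrix(sub1), "single site")
  expect_false(any(startsWith(X1$column_labels, "site_")))
})

test_that("PEB with identical subjects and an intercept-only design returns
           the shared posterior mean", {
  # near-flat first-level priors so the posterior equals the likelihood
  # summary; with identical subjects and an intercept-only design the
  # group mean must sit at the shared posterior mean
  spec <- state_model_spec("constant_rate")
  pr <- prior_spec(spec)
  pr$var[] <- 1e8
  set.seed(22)
  m <- pr$mean + rnorm(length(pr$mean), 0, 3)
  post <- structure(list(mean = m,
                         covariance = diag(rep(0.4, length(m))),
                         free_energy = -500, priors = pr,
                         gamma = list(mean = 0, var = 0.1)),
                    class = "subject_posterior")
  posts <- list(post, post, post, post)
  X <- structure(list(values = matrix(1, 4, 1,
                                      dimnames = list(NULL, "mean")),
                      column_labels = "mean",
                      subject_ids = paste0("s", 1:4)),
                 class = "design_matrix")
  peb <- fit_peb(posts, X)
  expect_lt(max(abs(peb$beta[, "mean"] - m) / pmax(abs(m), 1)), 0.01)
})

test_that("PEB recovers configured group and CAG effects within 25%", {
  # oracle: projection of the true generative subject parameters onto the
  # design (what a second-level linear model can at best recover)
  errs_grp <- errs_cag <- NULL
  for (s in 1:3) {
    coh <- generate_cohort(cohort_config(seed = 330 + s, behavior = FALSE))
    fit <- hdprog(coh)
    X <- fit$design$values
    truth <- t(vapply(coh$subjects$id, function(id) {
      p <- coh$truth[[id]]$params
      c(x0p = p$x0[["putamen"]],
        lmo = p$log_decay[[match("middle_occipital", hd_state_names())]])
    }, numeric(2)))
    bx <- coef(lm(truth[, "x0p"] ~ 0 + X))
    bl <- coef(lm(truth[, "lmo"] ~ 0 + X))
    errs_grp <- c(errs_grp, (coef(fit)["x0.putamen", "group"] -
                               bx[["Xgroup"]]) / bx[["Xgroup"]])
    errs_cag <- c(errs_cag, (coef(fit)["lambda.middle_occipital", "cag"] -
                               bl[["Xcag"]]) / bl[["Xcag"]])
    # signs match the configured effects
    expect_lt(coef(fit)["x0.putamen", "group"], 0)
    expect_gt(coef(fit)["lambda.middle_occipital", "cag"], 0)
  }
  expect_lt(abs(mean(errs_grp)), 0.25)
  expect_lt(abs(mean(errs_cag)), 0.25)
})

test_that("true group labels beat permuted labels in PEB free energy", {
  coh <- small_cohort(10, seed = 23, behavior = FALSE)
  spec <- state_model_spec("dynamic")
  fits <- lapply(coh$subjects$id, function(id)
    fit_subject(subject_series(coh, id), spec))
  X <- build_design_matrix(coh$subjects)
  f_true <- fit_peb(fits, X)$free_energy
  set.seed(99)
  wins <- vapply(1:20, function(k) {
    Xp <- X
    Xp$values[, "group"] <- sample(Xp$values[, "group"])
    fit_peb(fits, Xp)$free_energy < f_true
  }, logical(1))
  expect_gte(mean(wins), 0.90)
})

test_that("PEB shrinkage, noise-covariate penalty and ordering invariance", {
  coh <- small_cohort(6, seed = 24, behavior = FALSE)
  spec <- state_model_spec("dynamic")
  fits <- lapply(coh$subjects$id, function(id)
    fit_subject(subject_series(coh, id), spec))
  X <- build_design_matrix(coh$subjects)
  peb <- fit_peb(fits, X)

  # an added pure-noise covariate lowers the free energy
  set.seed(7)
  Xn <- build_design_matrix(coh$subjects,
                            extra = list(junk = rnorm(12)))
  expect_lt(fit_peb(fits, Xn)$free_energy, peb$free_energy)

  # estimates invariant to subject ordering
  perm <- sample(length(fits))
  Xp <- structure(list(values = X$values[perm, , drop = FALSE],
                       column_labels = X$column_labels,
                       subject_ids = X$subject_ids[perm]),
                  class = "design_matrix")
  peb_p <- fit_peb(fits[perm], Xp)
  expect_equal(peb_p$beta, peb$beta, tolerance = 1e-6)

  # mismatched parameter spaces are rejected
  bad <- fits
  bad[[1]] <- fit_subject(subject_series(coh, coh$subjects$id[1]),
                          state_model_spec("constant_rate"))
  expect_error(fit_peb(bad, X), "identical parameter")
})

test_that("PEB-updated subject estimates shrink between the subject mean
           and the group prediction in the diagonal setting", {
  # synthetic diagonal-precision toy with near-flat first-level priors,
  # so the Gaussian likelihood summary coincides with the posterior and
  # the conditional estimate interpolates subject mean and group prediction
  spec <- state_model_spec("dynamic")
  pr <- prior_spec(spec)
  pr$var[] <- 1e6
  p <- length(pr$mean)
  set.seed(31)
  posts <- lapply(1:6, function(s) {
    m <- pr$mean + rnorm(p, 0, 2)
    v <- rep(0.5 + 0.1 * s, p)    # far tighter than the prior, diagonal
    structure(list(mean = m, covariance = diag(v),
                   free_energy = -100 - s, priors = pr,
                   gamma = list(mean = 0, var = 0.1)),
              class = "subject_posterior")
  })
  X <- structure(list(values = cbind(mean = rep(1, 6),
                                     grp = rep(c(1, -1), 3)),
                      column_labels = c("mean", "grp"),
                      subject_ids = paste0("s", 1:6)),
                 class = "design_matrix")
  peb <- fit_peb(posts, X)
  est <- peb_subject_estimates(peb)
  for (s in 1:6) {
    lo <- pmin(posts[[s]]$mean, drop(peb$beta %*% X$values[s, ]))
    hi <- pmax(posts[[s]]$mean, drop(peb$beta %*% X$values[s, ]))
    expect_true(all(est[s, ] >= lo - 1e-8 & est[s, ] <= hi + 1e-8))
  }
})
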