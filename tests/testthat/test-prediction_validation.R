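test_that("decade-loss summary matches closed forms", {
  states <- hd_state_names()
  zero <- setNames(numeric(28), states)

  # zero-slope noise-free data: zero loss everywhere
  cfg0 <- cohort_config(n_hd = 3, n_control = 3, noise_sd = 0,
                        true_decay = list(hd = zero, control = zero),
                        group_offset = zero, cag_slope = zero,
                        behavior = FALSE, seed = 51)
  dl0 <- decade_loss_summary(generate_cohort(cfg0))
  expect_lt(max(abs(dl0$median_loss)), 1e-6)

  # noise-free exponential decay: within 1 percentage point of the
  # closed form 100 (1 - exp(10 a))
  put <- zero; put[] <- 1e-12; put["putamen"] <- 0.0207
  cfg <- cohort_config(n_hd = 8, n_control = 2, noise_sd = 0,
                       true_decay = list(hd = put, control = zero + 1e-12),
                       group_offset = zero, cag_slope = zero,
                       behavior = FALSE, seed = 52)
  dl <- decade_loss_summary(generate_cohort(cfg))
  target <- 100 * (1 - exp(-0.207))
  got <- dl$median_loss[dl$state == "putamen" & dl$group == "HD"]
  expect_lt(abs(got - target), 1)

  # invariance to appending an exactly collinear visit (linear-in-time
  # generator, so the observed volumes lie exactly on a line)
  cfg_lin <- cohort_config(n_hd = 4, n_control = 2, noise_sd = 0,
                           group_offset = zero, cag_slope = zero,
                           behavior = FALSE, seed = 53,
                           dynamics_form = "constant_rate")
  coh <- generate_cohort(cfg_lin)
  v1 <- coh$visits[coh$visits$id == "HD01", ]
  newrow <- v1[1, ]
  newrow$time_years <- max(v1$time_years) + 1
  regions <- hd_region_table()$region
  for (rg in regions) {
    f <- lm(v1[[rg]] ~ v1$time_years)
    newrow[[rg]] <- coef(f)[1] + coef(f)[2] * newrow$time_years
  }
  coh2 <- coh
  coh2$visits <- rbind(coh$visits, newrow)
  dl_lin <- decade_loss_summary(coh)
  dl2 <- decade_loss_summary(coh2)
  i <- dl_lin$state == "putamen" & dl_lin$group == "HD"
  expect_equal(dl2$median_loss[i], dl_lin$median_loss[i],
               tolerance = 1e-6)
})

test_that("CAG variance-explained curves behave across the window", {
  states <- hd_state_names()
  zero <- setNames(numeric(28), states)

  # null CAG effect: R2 stays at the chance level ~ 1/(n-1)
  r2s <- NULL
  for (s in 1:2) {
    cfg0 <- cohort_config(n_hd = 40, n_control = 2, cag_slope = zero,
                          behavior = FALSE, seed = 60 + s)
    ve <- variance_explained_over_time(generate_cohort(cfg0),
                                       states = "putamen")
    r2s <- c(r2s, ve$r2)
  }
  expect_lt(mean(r2s), 0.05)
  expect_true(all(r2s >= 0 & r2s <= 1))

  # deterministic construction: decay linear in CAG, common x0, no noise:
  # R2 = 1 away from t = 0 and 0 at the common anchor (raw volumes)
  cfg1 <- cohort_config(n_hd = 15, n_control = 2, noise_sd = 0,
                        group_offset = zero, behavior = FALSE,
                        visit_count_law = c(`7` = 1), visit_start = -3,
                        seed = 63)
  ve1 <- variance_explained_over_time(generate_cohort(cfg1),
                                      states = "putamen",
                                      use_fitted = FALSE)
  expect_equal(ve1$r2[ve1$t == 0], 0, tolerance = 1e-9)
  expect_gt(ve1$r2[ve1$t == -3], 0.99)
  expect_gt(ve1$r2[ve1$t == 3], 0.99)
})

test_that("behavioural metrics hit the perfect-fit and permutation limits", {
  states <- hd_state_names()
  # noise-free generation, correctly specified readout: R2 = 1
  cfg <- cohort_config(n_hd = 12, n_control = 2, noise_sd = 1e-8,
                       behavior_noise_sd = 0, seed = 71)
  coh <- generate_cohort(cfg)
  bm <- behavior_fit_metrics(coh)
  expect_gt(min(bm$r2), 1 - 1e-6)

  # permuting scores across subjects destroys the fit
  coh_perm <- coh
  hd_ids <- coh$subjects$id[coh$subjects$group == "HD"]
  set.seed(1)
  remap <- setNames(sample(hd_ids), hd_ids)
  for (ch in c("tms", "sdmt")) {
    shuffled <- coh$visits[[ch]]
    for (id in hd_ids) {
      src <- which(coh$visits$id == remap[[id]])
      dst <- which(coh$visits$id == id)
      k <- min(length(src), length(dst))
      shuffled[dst[seq_len(k)]] <- coh$visits[[ch]][src[seq_len(k)]]
    }
    coh_perm$visits[[ch]] <- shuffled
  }
  # subjects share the cohort-level time trend, so permutation leaves a
  # moderate common-trend fit; what collapses is the subject-level fit
  bm_perm <- behavior_fit_metrics(coh_perm)
  expect_lt(max(bm_perm$r2), min(bm$r2) - 0.3)
  expect_lt(max(bm_perm$r2), 0.7)
  expect_error(behavior_fit_metrics(
    generate_cohort(cohort_config(n_hd = 3, n_control = 2,
                                  behavior = FALSE, seed = 1))),
    "behavioural")
})

test_that("leave-one-out group prediction separates a separable cohort and
           stays at chance under the null", {
  states <- hd_state_names()
  zero <- setNames(numeric(28), states)
  # separable: large offsets, near-zero noise
  cfg <- cohort_config(n_hd = 6, n_control = 6, noise_sd = 0.1,
                       behavior = FALSE, seed = 81)
  coh <- generate_cohort(cfg)
  loo <- loo_predict(coh, "group")
  expect_equal(loo$accuracy, 1.0)
  expect_gte(loo$r, 0.99)

  # null: identical groups -> accuracy within binomial noise of 0.5
  cfg0 <- cohort_config(n_hd = 7, n_control = 7,
                        true_decay = list(hd = zero + 0.002,
                                          control = zero + 0.002),
                        group_offset = zero, cag_slope = zero,
                        behavior = FALSE, seed = 82)
  loo0 <- loo_predict(generate_cohort(cfg0), "group")
  expect_gte(loo0$accuracy, 0.15)
  expect_lte(loo0$accuracy, 0.85)

  # the left-out subject's data never enters the group stage: corrupting
  # it leaves the fold's group model untouched
  spec <- state_model_spec("dynamic")
  fits <- lapply(coh$subjects$id, function(id)
    fit_subject(subject_series(coh, id), spec))
  X <- build_design_matrix(coh$subjects)
  peb_a <- fit_peb(fits[-1], hdprog:::.subset_design(X, -1))
  corrupted <- coh
  corrupted$visits[corrupted$visits$id == coh$subjects$id[1],
                   hd_region_table()$region] <- 150
  fits_b <- fits
  fits_b[[1]] <- fit_subject(subject_series(corrupted, coh$subjects$id[1]),
                             spec)
  peb_b <- fit_peb(fits_b[-1], hdprog:::.subset_design(X, -1))
  expect_identical(peb_a$beta, peb_b$beta)

  expect_error(loo_predict(small_cohort(2, seed = 1)), "n < 10")
})

test_that("CAG prediction recovers a strong genetic gradient", {
  coh <- small_cohort(8, seed = 83, behavior = FALSE)
  loo <- loo_predict(coh, "cag")
  expect_true(all(abs(loo$table$predicted) < 100))
  expect_gt(loo$r, 0.3)
})
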