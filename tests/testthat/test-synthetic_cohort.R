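test_that("visit schedules are annual, inside the window, and reproducible", {
  cfg <- cohort_config(n_hd = 10, n_control = 10, seed = 3)
  sched <- sample_visit_schedule(cfg, 30, seed = 11)
  expect_length(sched, 30)
  for (s in sched) {
    expect_true(all(diff(s) == 1))
    expect_gte(length(s), 3)
    expect_lte(length(s), 7)
    expect_true(all(s >= -6 & s <= 5))
    expect_true(s[1] <= 0 && s[length(s)] >= 0)  # conversion year included
  }
  expect_identical(sched, sample_visit_schedule(cfg, 30, seed = 11))
  # forcing a 7-visit block starting at -3 pins the whole schedule
  cfg7 <- cohort_config(visit_count_law = c(`7` = 1), visit_start = -3,
                        seed = 1)
  expect_equal(sample_visit_schedule(cfg7, 1)[[1]], -3:3)
  # a window too short for the requested counts is an invalid config
  expect_error(cohort_config(time_window = c(-2, 2), seed = 1),
               "window too short")
})

test_that("covariate sampling matches the targeted demographic structure", {
  cfg <- cohort_config(seed = 1)
  cors <- cags <- NULL
  ages_diff <- NULL
  for (s in 1:60) {
    sub <- sample_covariates(cfg, seed = s)
    hd <- sub$group == "HD"
    expect_true(all(sub$cag[hd] %in% 39:50))
    expect_true(all(is.na(sub$cag[!hd])))
    cors <- c(cors, cor(sub$cag[hd], sub$age[hd]))
    cags <- c(cags, sub$cag[hd])
    ages_diff <- c(ages_diff, mean(sub$age[hd]) - mean(sub$age[!hd]))
  }
  expect_lt(abs(mean(cors) - (-0.85)), 0.05)
  # printed moments: mean 43.67, sd 2.77, within 2 standard errors
  se_m <- sd(cags) / sqrt(length(cags))
  expect_lt(abs(mean(cags) - 43.67), 2 * se_m + 0.02)
  expect_lt(abs(sd(cags) - 2.77), 0.15)
  # controls mirror HD ages by construction
  expect_true(all(abs(ages_diff) < 0.5))
  # independence case
  cfg0 <- cohort_config(cag_onset_corr = 0, seed = 1)
  c0 <- mean(vapply(1:20, function(s) {
    sub <- sample_covariates(cfg0, seed = s)
    cor(sub$cag[sub$group == "HD"], sub$age[sub$group == "HD"])
  }, numeric(1)))
  expect_lt(abs(c0), 0.15)
})

test_that("generated volumes follow the configured exponential dynamics", {
  # identity dynamics: no decay, no offsets, no noise -> flat 100%
  states <- hd_state_names()
  zero <- setNames(numeric(28), states)
  cfg_id <- cohort_config(n_hd = 2, n_control = 2, noise_sd = 0,
                          true_decay = list(hd = zero, control = zero),
                          group_offset = zero, cag_slope = zero,
                          behavior = FALSE, seed = 5)
  coh <- generate_cohort(cfg_id)
  vols <- as.matrix(coh$visits[, hd_region_table()$region])
  expect_equal(max(abs(vols - 100)), 0, tolerance = 1e-8)

  # closed form: putamen volume equals 100 exp(a t) to machine precision
  cfg <- cohort_config(n_hd = 3, n_control = 3, noise_sd = 0,
                       group_offset = zero, cag_slope = zero,
                       behavior = FALSE, seed = 6)
  coh <- generate_cohort(cfg)
  a <- -cfg$true_decay$hd[["putamen"]]
  v <- coh$visits[coh$visits$id == "HD01", ]
  expect_equal(v$putamen_L, 100 * exp(a * v$time_years), tolerance = 1e-12)
  # both hemispheres generated from the shared bilateral state
  expect_equal(v$putamen_L, v$putamen_R, tolerance = 1e-12)

  # decade loss of the calibrated putamen decay: 1 - exp(10a) ~ 0.187,
  # cross-checked against an independent RK4 integration
  a187 <- log(1 - 0.187) / 10
  expect_equal(1 - exp(10 * a187), 0.187, tolerance = 1e-12)
  x10 <- rk4_oracle(100, matrix(a187, 1, 1), times = 10, h = 0.005)
  expect_equal(1 - x10 / 100, 0.187, tolerance = 1e-8,
               ignore_attr = TRUE)

  # HD/control group means at t = 0 differ by the configured offset
  cfg_off <- cohort_config(n_hd = 6, n_control = 6, noise_sd = 0,
                           cag_slope = zero, behavior = FALSE,
                           visit_count_law = c(`7` = 1), visit_start = -3,
                           seed = 8)
  coh <- generate_cohort(cfg_off)
  at0 <- coh$visits[coh$visits$time_years == 0, ]
  grp <- coh$subjects$group[match(at0$id, coh$subjects$id)]
  diff0 <- mean(at0$putamen_L[grp == "HD"]) -
    mean(at0$putamen_L[grp == "control"])
  expect_equal(diff0, cfg_off$group_offset[["putamen"]], tolerance = 1e-8)
})

test_that("cohort generation is deterministic given the config seed", {
  c1 <- small_cohort(3, seed = 42)
  c2 <- small_cohort(3, seed = 42)
  expect_identical(c1$visits, c2$visits)
  expect_identical(c1$subjects, c2$subjects)
  c3 <- small_cohort(3, seed = 43)
  expect_false(identical(c1$visits, c3$visits))
})

test_that("behavioural generation is a clipped linear readout", {
  cfg <- cohort_config(n_hd = 2, n_control = 2, behavior_noise_sd = 0,
                       seed = 9)
  st <- matrix(100, 4, 28)
  # zero weights, zero noise -> the intercept at every visit
  cfg0 <- cfg
  cfg0$behavior_weights$weights[] <- 0
  cfg0$behavior_weights$intercept <- c(tms = 40, sdmt = 40)
  beh <- generate_behavior(st, cfg0, noise = FALSE)
  expect_true(all(beh == 40))
  # zero noise -> exact weighted state sum (+ intercept), clipped to [0,100]
  beh2 <- generate_behavior(st, cfg, noise = FALSE)
  raw <- drop(st %*% cfg$behavior_weights$weights) +
    rep(cfg$behavior_weights$intercept, each = 4)
  expect_equal(beh2, pmin(pmax(raw, 0), 100), tolerance = 1e-12,
               ignore_attr = TRUE)
  # unknown state in the weight map is rejected
  cfg_bad <- cfg
  rownames(cfg_bad$behavior_weights$weights)[1] <- "not_a_state"
  expect_error(generate_behavior(st, cfg_bad), "unknown state")
})

test_that("score rescaling is an oriented affine map onto [0, 100]", {
  expect_equal(rescale_scores(10, 10, 50, higher_is_worse = TRUE), 0)
  expect_equal(rescale_scores(10, 10, 50, higher_is_worse = FALSE), 100)
  expect_equal(rescale_scores(30, 10, 50, higher_is_worse = TRUE), 50)
  expect_equal(rescale_scores(30, 10, 50, higher_is_worse = FALSE), 50)
  expect_error(rescale_scores(1, 5, 5), "degenerate")
})

test_that("cohort tables round-trip through TSV and are validated on read", {
  coh <- small_cohort(3, seed = 13)
  sdir <- withr::local_tempdir()
  sp <- file.path(sdir, "subjects.tsv"); vp <- file.path(sdir, "visits.tsv")
  write_cohort(coh, sp, vp)
  back <- read_cohort(sp, vp)
  expect_equal(back$visits$putamen_L, coh$visits$putamen_L,
               tolerance = 1e-10)
  expect_identical(back$subjects$id, coh$subjects$id)
  expect_true(all(is.na(back$subjects$cag[back$subjects$group ==
                                            "control"])))

  # a negative volume is rejected with region and row identified
  bad <- coh
  bad$visits$putamen_L[2] <- -1
  write_cohort(bad, sp, vp)
  expect_error(read_cohort(sp, vp), "putamen_L.*row 2")

  # irregular but increasing times are accepted
  irr <- coh
  irr$visits$time_years[irr$visits$id == "HD01"] <-
    seq_along(irr$visits$time_years[irr$visits$id == "HD01"]) * 0.7
  write_cohort(irr, sp, vp)
  expect_s3_class(read_cohort(sp, vp), "hd_cohort")

  # schema violations name the offending column
  sub2 <- coh$subjects; sub2$tiv <- NULL
  utils::write.table(sub2, sp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_cohort(sp, vp), "tiv")
})
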