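test_that("long table has one row per subject x task and catches malformed input", {
  tab <- simulate_outcome_table(250, seed = 1)
  expect_equal(nrow(tab), 750)
  expect_equal(levels(tab$task),
               c("baseline", "long_interval", "short_interval"))
  expect_error(build_long_table(tab[0, ]), class = "sighstress_data_error")
  expect_error(build_long_table(rbind(tab, tab[1, ])),
               class = "sighstress_data_error")
})

test_that("rows missing an outcome leave other models unaffected", {
  tab <- simulate_outcome_table(30, seed = 2)
  tab$pttv_like <- tab$y + stats::rnorm(nrow(tab))
  tab$pttv_like[5] <- NA
  full <- fit_mixed_model(tab, "y", "c1")
  expect_equal(full$n_dropped, 0)
  part <- fit_mixed_model(tab, "pttv_like", "c1")
  expect_equal(part$n_dropped, 1)
  expect_equal(part$n_obs, 89)
})

test_that("REML fit recovers programmed task, sex, and interaction effects", {
  tab <- simulate_outcome_table(
    200, task_effects = c(long = 2, short = 5), sex_effect = 1.5,
    interaction = c(long = 0.5, short = 1), covariate_effects = c(0.8, -0.4),
    seed = 13)
  ft <- fit_mixed_model(tab, "y", c("c1", "c2"))
  fe <- lme4::fixef(ft$fit)
  se <- summary(ft$fit)$coefficients[, "Std. Error"]
  for (chk in list(c("tasklong_interval", 2), c("taskshort_interval", 5),
                   c("sexM", 1.5), c("tasklong_interval:sexM", 0.5),
                   c("taskshort_interval:sexM", 1), c("c1", 0.8),
                   c("c2", -0.4))) {
    nm <- chk[1]; truth <- as.numeric(chk[2])
    expect_lt(abs(fe[[nm]] - truth), 2 * se[[nm]])
  }
  expect_lt(ft$anova["task", "Pr(>F)"], 1e-10)
})

test_that("degenerate designs are rejected; singular fits are kept with a warning", {
  tab <- simulate_outcome_table(30, seed = 5)
  tab$same <- tab$y
  expect_error(fit_mixed_model(tab, "y", "same"),
               class = "sighstress_data_error")
  tab$dup <- tab$c1
  expect_error(fit_mixed_model(transform(tab, c2 = c1), "y", c("c1", "c2")),
               class = "sighstress_data_error")
  flat <- simulate_outcome_table(40, sd_subject = 0, seed = 8)
  expect_warning(ftf <- fit_mixed_model(flat, "y", "c1"), "singular")
  expect_true(ftf$singular)
})

test_that("task contrasts recover a graded effect and satisfy linearity", {
  tab <- simulate_outcome_table(200, task_effects = c(long = 1, short = 3),
                                seed = 7)
  ft <- fit_mixed_model(tab, "y", c("c1", "c2"))
  tc <- task_contrasts(ft)
  expect_true(all(tc$estimate > 0))
  expect_true(all(tc$p < 0.05))
  expect_lt(abs(tc$estimate[tc$contrast == "BL vs short"] -
                  tc$estimate[tc$contrast == "BL vs long"] -
                  tc$estimate[tc$contrast == "long vs short"]), 1e-8)
})

test_that("null task contrasts stay below |t| = 4 in nearly all replicates", {
  n_big <- 0; n_tot <- 0
  for (s in 1:40) {
    tab <- simulate_outcome_table(30, seed = 300 + s)
    tc <- task_contrasts(fit_mixed_model(tab, "y", character(0)))
    n_big <- n_big + sum(abs(tc$t) >= 4)
    n_tot <- n_tot + nrow(tc)
  }
  expect_gte(1 - n_big / n_tot, 0.99)
})

test_that("sex-by-task contrasts detect a doubled male response", {
  tab <- simulate_outcome_table(
    250, task_effects = c(long = 2, short = 4), fraction_female = 0.65,
    interaction = c(long = 2, short = 4), seed = 8)
  ft <- fit_mixed_model(tab, "y", character(0))
  sc <- sex_task_contrasts(ft)
  short <- sc[sc$contrast == "sex x (BL vs short)", ]
  expect_gt(short$estimate, 0)                   # males change more
  expect_lt(short$p, 0.05)
  # single-sex cohort cannot estimate sex effects
  onesex <- tab[tab$sex == "F", ]
  expect_error(fit_mixed_model(droplevels(onesex), "y", character(0)),
               class = "sighstress_data_error")
})

test_that("null task-by-sex interactions are rarely declared significant", {
  hits <- 0
  for (s in 1:30) {
    tab <- simulate_outcome_table(40, seed = 900 + s)
    ft <- fit_mixed_model(tab, "y", character(0))
    if (ft$anova["task:sex", "Pr(>F)"] < 0.05) hits <- hits + 1
  }
  expect_lte(hits / 30, 0.10)
})

test_that("influence downdates equal brute-force leave-one-out refits", {
  tab <- simulate_outcome_table(15, task_effects = c(long = 1, short = 2),
                                seed = 9)
  ft <- fit_mixed_model(tab, "y", c("c1", "c2"))
  fast <- influence_diagnostics(ft)
  slow <- influence_brute_force(ft)
  expect_lt(max(abs(fast$cooks_d - slow$cooks_d)), 1e-8)
  expect_lt(max(abs(fast$studentized - slow$studentized)), 1e-8)
  expect_lt(max(abs(fast$rld - slow$rld)), 1e-8)
})

test_that("a gross outlier is always flagged and its removal restores the fit", {
  flagged_all <- TRUE
  for (s in 1:5) {
    tab <- simulate_outcome_table(20, task_effects = c(long = 1, short = 2),
                                  seed = 20 + s)
    i <- 7 + s
    tab$y[i] <- tab$y[i] + 20 * stats::sd(tab$y)
    # the outlier can push the between-subject variance to the boundary
    ft <- suppressWarnings(fit_mixed_model(tab, "y", character(0)))
    scr <- suppressWarnings(influence_screen(ft))
    flagged_all <- flagged_all && scr$report$flagged[i]
    expect_true(abs(scr$report$studentized[i]) > 4)
    if (s == 1) {
      truth_short <- 2
      raw_est <- lme4::fixef(ft$fit)[["taskshort_interval"]]
      new_est <- lme4::fixef(scr$refit$fit)[["taskshort_interval"]]
      expect_lt(abs(new_est - truth_short), abs(raw_est - truth_short))
    }
  }
  expect_true(flagged_all)
})

test_that("clean simulations rarely lose observations to the influence screen", {
  removed <- integer(20)
  for (s in 1:20) {
    tab <- simulate_outcome_table(25, seed = 500 + s)
    ft <- fit_mixed_model(tab, "y", character(0))
    removed[s] <- suppressWarnings(influence_screen(ft))$n_removed
  }
  expect_gte(mean(removed == 0), 0.95)
})

test_that("zero-effect outcomes dissect to flat direction labels", {
  tab <- simulate_outcome_table(60, seed = 33)
  tab$y <- NULL
  subj_ids <- unique(tab$subject)
  set.seed(34)
  for (oc in c("hr", "ln_lf_hrv", "ln_hf_hrv", "pttv", "map",
               "ln_lf_bpv", "ln_hf_bpv")) {
    b <- stats::rnorm(length(subj_ids))
    tab[[oc]] <- stats::rnorm(nrow(tab), 10, 1) + b[match(tab$subject, subj_ids)]
  }
  tab$rsa <- stats::rnorm(nrow(tab), 1, 0.1)
  tab$pwv <- stats::rnorm(nrow(tab), 3, 0.2)
  dis <- dissect_all_outcomes(tab, influence = FALSE, alpha = 0.01)
  expect_equal(nrow(dis$summary), 7)
  expect_true(all(dis$summary$task_pattern == "BL = long = short"))
  # dropping one outcome column skips that model but runs the others
  expect_warning(d2 <- dissect_all_outcomes(tab[, names(tab) != "map"],
                                            influence = FALSE, alpha = 0.01),
                 "skipped")
  expect_equal(nrow(d2$summary), 6)
})

test_that("a default cohort reproduces the encoded task direction pattern", {
  co <- simulate_process_cohort(60, seed = 21)
  dis <- dissect_all_outcomes(co$summary)
  expected <- c(hr = "BL < long < short",
                ln_lf_hrv = "BL < long < short",
                ln_hf_hrv = "BL = long > short",
                pttv = "BL < long < short",
                map = "BL = long < short",
                ln_lf_bpv = "BL < long < short",
                ln_hf_bpv = "BL < long = short")
  got <- setNames(dis$summary$task_pattern, dis$summary$outcome)
  matches <- sum(got[names(expected)] == expected)
  expect_gte(matches, 6)
  # females respond less on heart rate yet run faster overall
  hr_sex <- dis$summary$sex_effect[dis$summary$outcome == "hr"]
  expect_equal(hr_sex, "M < F")
})
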