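pred6 <- data.frame(pair_label = paste0("P", 1:6),
                    dSS = c(13.9, 6.25, 7.64, 9.72, 16.7, 21.5),
                    dSp = c(2.78, 9.72, 9.72, 1.39, 5.56, 12.5))

test_that("tabulation yields one row per subject-pair with joined predictors", {
  tab <- synth_behavior(stats::setNames(pred6$dSS, pred6$pair_label),
                        beta0 = 0, beta1 = 0.05, sigma_subject = 0.3,
                        n_subjects = 10, n_trials_per_pair = 10, seed = 14)
  expect_equal(nrow(tab), 600L)
  summ <- tabulate_behavior(tab, pred6)
  expect_equal(nrow(summ), 60L)
  expect_true(all(summ$n_trials == 10L))
  expect_true(all(summ$accuracy >= 0 & summ$accuracy <= 1))
  expect_equal(summ$dSS[summ$pair_label == "P6"][1], 21.5)

  # a perfect subject-pair cell scores accuracy 1
  tab2 <- synth_behavior(stats::setNames(0, "P1"), beta0 = 20, beta1 = 0,
                         sigma_subject = 0, n_subjects = 2,
                         n_trials_per_pair = 10, seed = 1)
  summ2 <- tabulate_behavior(tab2, data.frame(pair_label = "P1", dSS = 1))
  expect_true(all(summ2$accuracy == 1))

  # unmatched pair labels are a join error
  expect_error(tabulate_behavior(tab, pred6[-6, ]),
               class = "frinstab_join_error")
})

test_that("a chance-constructed table has grand accuracy near 1/3", {
  tab <- synth_behavior(stats::setNames(pred6$dSS, pred6$pair_label),
                        beta0 = stats::qlogis(1 / 3), beta1 = 0,
                        sigma_subject = 0, n_subjects = 10,
                        n_trials_per_pair = 10, seed = 8)
  se <- sqrt(1 / 3 * 2 / 3 / 600)
  expect_lt(abs(mean(tab$correct) - 1 / 3), 3 * se)
})

test_that("chance testing matches the textbook t statistic and handles
           degenerate samples", {
  acc <- c(0.5, 0.6, 0.7, 0.8)
  ct <- chance_test(acc)
  t_hand <- (mean(acc) - 1 / 3) / (stats::sd(acc) / sqrt(4))
  expect_equal(ct$t, t_hand)
  expect_equal(ct$p, 2 * stats::pt(-abs(t_hand), df = 3))

  flat <- chance_test(rep(1 / 3, 10))
  expect_equal(flat$t, 0)
  expect_equal(flat$p, 1)

  high <- chance_test(rep(0.6, 10))
  expect_equal(high$p, 0)
  expect_gt(high$t, 0)
})

test_that("chance test is invariant to subject relabelling", {
  set.seed(3)
  acc <- runif(10, 0.3, 0.9)
  expect_equal(chance_test(acc)$p, chance_test(sample(acc))$p)
})

test_that("rank-sum test equals exact enumeration, including mid-rank ties", {
  # fully separated n = m = 5: p = 2 / choose(10, 5)
  rs <- rank_sum_test(1:5, 11:15)
  expect_equal(rs$p, 2 / choose(10, 5))

  # identical samples
  expect_equal(rank_sum_test(c(1, 1, 2, 2), c(1, 1, 2, 2))$p, 1)

  # tied data, n = m = 4: against brute-force enumeration of all 70 splits
  set.seed(21)
  for (rep in seq_len(10)) {
    a <- sample(1:4, 4, replace = TRUE)
    b <- sample(1:4, 4, replace = TRUE)
    if (stats::sd(c(a, b)) == 0) next
    expect_equal(rank_sum_test(a, b)$p, rank_sum_oracle(a, b))
  }

  # tie-free case agrees with the exact Wilcoxon distribution
  set.seed(22)
  x <- rnorm(6); y <- rnorm(7) + 0.4
  expect_equal(rank_sum_test(x, y)$p,
               stats::wilcox.test(x, y, exact = TRUE)$p.value)
})

test_that("accuracy GLMM with zero subject variance matches plain logistic
           regression", {
  tab <- synth_behavior(stats::setNames(pred6$dSS - mean(pred6$dSS),
                                        pred6$pair_label),
                        beta0 = 0.3, beta1 = 0.1, sigma_subject = 0,
                        n_subjects = 10, n_trials_per_pair = 10, seed = 17)
  fit <- fit_accuracy_glmm(tab, pred6, "dSS")
  glm_fit <- stats::glm(correct ~ dSS,
                        data = merge(as.data.frame(tab), pred6),
                        family = stats::binomial())
  expect_lt(fit$random$subject_sd, 0.05)
  expect_equal(fit$fixed$slope, unname(stats::coef(glm_fit)["dSS"]),
               tolerance = 1e-3)
  expect_equal(fit$family, "binomial-logit")
  expect_true(abs(fit$descriptive_r) <= 1)
})

test_that("GLMM estimates are invariant to trial order", {
  tab <- synth_behavior(stats::setNames(pred6$dSS, pred6$pair_label),
                        beta0 = -0.5, beta1 = 0.08, sigma_subject = 0.4,
                        n_subjects = 8, n_trials_per_pair = 8, seed = 19)
  fit1 <- fit_accuracy_glmm(tab, pred6, "dSS")
  shuffled <- tab[sample(nrow(tab)), ]
  fit2 <- fit_accuracy_glmm(behavioral_table(as.data.frame(shuffled)),
                            pred6, "dSS")
  expect_equal(fit1$fixed$slope, fit2$fixed$slope, tolerance = 1e-6)
})

test_that("deterministic log-linear response times recover the slope exactly", {
  tab <- synth_behavior(stats::setNames(pred6$dSS, pred6$pair_label),
                        beta0 = 1, beta1 = 0, sigma_subject = 0.2, seed = 23,
                        rt_predictors = stats::setNames(pred6$dSp,
                                                        pred6$pair_label),
                        rt_beta0 = 1.2, rt_beta1 = 0.05, rt_sigma = 0,
                        rt_subject_sd = 0)
  fit <- suppressWarnings(fit_rt_model(tab, pred6, "dSp"))
  expect_equal(fit$fixed$slope, 0.05, tolerance = 1e-6)
  expect_equal(fit$family, "gaussian-identity-on-logRT")
})

test_that("log-normal response times with a known slope are recovered
           within the Wald interval most of the time", {
  hits <- 0L
  for (s in 1:10) {
    tab <- synth_behavior(stats::setNames(pred6$dSS, pred6$pair_label),
                          beta0 = 0, beta1 = 0, sigma_subject = 0.2,
                          seed = 400 + s,
                          rt_predictors = stats::setNames(pred6$dSp,
                                                          pred6$pair_label),
                          rt_beta0 = 2, rt_beta1 = -0.03, rt_sigma = 0.3,
                          rt_subject_sd = 0.15)
    fit <- fit_rt_model(tab, pred6, "dSp")
    lo <- fit$fixed$slope - 1.96 * fit$fixed$slope_se
    hi <- fit$fixed$slope + 1.96 * fit$fixed$slope_se
    if (lo <= -0.03 && -0.03 <= hi) hits <- hits + 1L
  }
  expect_gte(hits, 8L)
})

test_that("pair-level correlation carries the sign of the generating slope
           at study-scale effect sizes", {
  x <- stats::setNames(pred6$dSS - mean(pred6$dSS), pred6$pair_label)
  right_sign <- 0L
  for (s in 1:20) {
    tab <- synth_behavior(x,
                          beta0 = 0.2, beta1 = 0.15, sigma_subject = 0.5,
                          n_subjects = 10, n_trials_per_pair = 10,
                          seed = 600 + s)
    acc <- tapply(tab$correct, tab$pair_label, mean)
    if (stats::cor(acc, x[names(acc)]) > 0) right_sign <- right_sign + 1L
  }
  expect_gte(right_sign, 19L)
})

test_that("nonpositive response times are rejected", {
  tab <- synth_behavior(stats::setNames(1, "P1"), beta0 = 0, beta1 = 0,
                        sigma_subject = 0, n_subjects = 3,
                        n_trials_per_pair = 4, seed = 2)
  tab$response_time[1] <- -1
  expect_error(fit_rt_model(tab, data.frame(pair_label = "P1", dSp = 1),
                            "dSp"),
               class = "frinstab_validation_error")
})
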