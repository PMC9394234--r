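test_that("Gini importance is zero for constants and maximal for separators", {
  set.seed(51)
  n <- 16
  labels <- rep(c("CR", "REL"), each = n / 2)
  feats <- cbind("18" = ifelse(labels == "CR", 70, 20) + stats::rnorm(n, 0, 2),
                 "10" = stats::runif(n, 0, 100),
                 "21" = rep(50, n),
                 "X" = stats::runif(n, 0, 100))
  gi <- gini_importance_loocv(feats, labels, ntree = 200, seed = 3)
  expect_true(all(gi$importance[, "21"] == 0))       # constant feature
  expect_true(all(gi$importance[, "18"] ==
                    apply(gi$importance, 1, max)))   # separator tops each fold
  expect_equal(gi$ranking[1], "18")
  expect_error(gini_importance_loocv(feats, rep("CR", n)), "class")
})

test_that("Gini ranking surfaces the chromosomes with planted group shifts", {
  set.seed(52)
  n <- 22
  labels <- rep(c("CR", "REL"), c(10, 12))
  shift <- c("18" = 35, "10" = 25, "X" = 0, "4" = 0, "6" = 0, "14" = 0,
             "17" = 0, "21" = 0)
  feats <- sapply(names(shift), function(ch)
    50 + ifelse(labels == "CR", shift[ch], 0) + stats::rnorm(n, 0, 10))
  gi <- gini_importance_loocv(feats, labels, ntree = 300, seed = 5)
  expect_true(all(c("18", "10") %in% gi$ranking[1:3]))
})

test_that("pair-rule fitting recovers a planted 40/40 threshold rule", {
  set.seed(53)
  ch <- planted_rule_cohort(n = 200)
  fit <- fit_pair_rule(ch$features[, "18"], ch$features[, "10"], ch$labels)
  expect_lte(abs(fit$t1 - 40), 5)
  expect_lte(abs(fit$t2 - 40), 5)
  expect_gte(fit$accuracy, 0.9)
})

test_that("pair-rule evaluation ranks the informative pair first", {
  set.seed(54)
  ch <- planted_rule_cohort(n = 120)
  res <- evaluate_pair_rules(ch$features, ch$labels,
                             pairs = list(c("21", "14"), c("21", "10"),
                                          c("18", "10")))
  expect_equal(paste(res$f1[1], res$f2[1]), "18 10")

  # random labels: LOOCV accuracy close to the majority rate
  set.seed(55)
  lab_rand <- sample(rep(c("CR", "REL"), c(72, 48)))
  res_r <- evaluate_pair_rules(ch$features, lab_rand,
                               pairs = list(c("18", "10")))
  expect_lte(res_r$loocv_accuracy, 0.72)

  # single-feature-separable labels: any pair containing it is perfect
  lab_one <- ifelse(ch$features[, "21"] > 50, "CR", "REL")
  res_1 <- evaluate_pair_rules(ch$features, lab_one,
                               pairs = list(c("21", "14"), c("18", "10")))
  expect_equal(res_1$loocv_accuracy[res_1$f1 == "21"], 1)
  expect_gt(res_1$loocv_accuracy[res_1$f1 == "21"],
            res_1$loocv_accuracy[res_1$f1 == "18"])
})

test_that("the chr18-chr10 two-step rule follows the printed decision path", {
  expect_equal(chr18_chr10_rule(c("18" = 80, "10" = 80))$label, "favorable")
  r1 <- chr18_chr10_rule(c("18" = 30, "10" = 90))
  expect_equal(r1$label, "unfavorable")
  expect_match(r1$trace, "step 1")
  r2 <- chr18_chr10_rule(c("18" = 90, "10" = 30))
  expect_equal(r2$label, "unfavorable")
  expect_match(r2$trace, "step 2")
  # boundary: exactly at both thresholds is unfavorable (strict-greater rule)
  expect_equal(chr18_chr10_rule(c("18" = 40, "10" = 40))$label, "unfavorable")
  expect_error(chr18_chr10_rule(c("18" = 50)), "18 and 10")
  # works straight off a TrisomyProfile (here 100% +18 and +10: favorable)
  expect_equal(chr18_chr10_rule(gain_rates(rep("00010011", 10)))$label,
               "favorable")
})

test_that("classification reports count confusions per class", {
  calls <- c("favorable", "favorable", "unfavorable")
  truth <- c("CR", "REL", "REL")
  rep1 <- classification_report(calls, truth)
  expect_equal(rep1$overall, 2 / 3)
  expect_equal(rep1$favorable, 1)
  expect_equal(rep1$unfavorable, 0.5)
  # one favorable miscalled among 10 + 12
  calls2 <- c(rep("favorable", 9), "unfavorable", rep("unfavorable", 12))
  truth2 <- rep(c("CR", "REL"), c(10, 12))
  expect_equal(classification_report(calls2, truth2)$overall, 21 / 22)
  # degenerate all-unfavorable caller
  rep3 <- classification_report(rep("unfavorable", 4),
                                c("CR", "CR", "REL", "REL"))
  expect_equal(rep3$favorable, 0)
  expect_equal(rep3$unfavorable, 1)
  expect_error(classification_report("favorable", c("CR", "REL")), "length")
})

test_that("stress test at level 0 reproduces the noiseless confusion exactly", {
  set.seed(56)
  feats <- cbind("18" = c(80, 30, 90, 41), "10" = c(80, 90, 30, 80))
  labels <- c("CR", "CR", "REL", "REL")
  st <- stress_test(feats, labels, levels = 0, reps = 20, seed = 9)
  noiseless <- sum(vapply(1:4, function(i)
    chr18_chr10_rule(feats[i, ])$label, "") ==
      ifelse(labels == "CR", "favorable", "unfavorable"))
  expect_equal(st$mean_correct, noiseless)
  expect_equal(st$sd_correct, 0)
  expect_error(stress_test(feats, labels, levels = -5), "non-negative")
})

test_that("stress test is reproducible and respects safety margins", {
  set.seed(57)
  feats <- cbind("18" = c(80, 75, 20, 15), "10" = c(80, 85, 90, 10))
  labels <- c("CR", "CR", "REL", "REL")
  a <- stress_test(feats, labels, levels = c(0, 10), reps = 50, seed = 4)
  b <- stress_test(feats, labels, levels = c(0, 10), reps = 50, seed = 4)
  expect_identical(a$mean_correct, b$mean_correct)
  # every feature at least L away from its threshold: no flips at all
  st <- stress_test(feats, labels, levels = 10, reps = 50, seed = 4)
  expect_equal(st$mean_correct, 4)
})

test_that("flip probability at margin 1 with L = 10 matches the closed form", {
  # favorable sample at %+18 = 41: flips iff the sign is negative (1/2) and
  # u > 1 (9/10): per-rep probability 0.45
  feats <- cbind("18" = 41, "10" = 90)
  st <- stress_test(feats, "CR", levels = 10, reps = 400, seed = 11)
  flip_rate <- st$mean_misclassified
  se <- sqrt(0.45 * 0.55 / 400)
  expect_lt(abs(flip_rate - 0.45), 3 * se)
})

test_that("misclassification grows with the noise level on seed averages", {
  set.seed(58)
  feats <- cbind("18" = stats::runif(30, 20, 70),
                 "10" = stats::runif(30, 20, 70))
  labels <- ifelse(feats[, "18"] > 40 & feats[, "10"] > 40, "CR", "REL")
  mis <- sapply(1:10, function(s) {
    st <- stress_test(feats, labels, levels = seq(0, 30, 10), reps = 40,
                      seed = s)
    st$mean_misclassified
  })
  avg <- rowMeans(mis)
  expect_true(all(diff(avg) >= 0))
  expect_equal(avg[1], 0)
})
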