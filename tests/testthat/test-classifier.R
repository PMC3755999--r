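# two fitted networks with controllable separation: no-edge unit-variance
# models whose means differ by `delta` on every ROI
separated_models <- function(delta) {
  nodes <- dmn_nodes()
  tab <- random_table(50, nodes)
  bn_nc <- fit_gbn(tab, dag_structure(nodes), standardize = FALSE)
  bn_ad <- fit_gbn(tab, dag_structure(nodes), standardize = FALSE)
  for (v in nodes) {
    bn_nc$params[[v]]$intercept <- 0
    bn_nc$params[[v]]$noise_variance <- 1
    bn_ad$params[[v]]$intercept <- delta
    bn_ad$params[[v]]$noise_variance <- 1
  }
  list(NC = bn_nc, AD = bn_ad)
}

sample_from <- function(mean, n, group) {
  tab <- random_table(n, dmn_nodes(), group = group)
  for (v in dmn_nodes()) tab[[v]] <- tab[[v]] + mean
  tab
}

test_that("identical models give zero difference and all-NC labels (tie rule)", {
  gens <- dmn_reference_generators(30, 30)
  tab <- sample_sem(gens$NC)
  bn <- fit_gbn(tab, gens$NC$dag)
  expect_equal(log_density_difference(bn, bn, tab), rep(0, nrow(tab)))
  expect_identical(unique(classify_subjects(bn, bn, tab)), "NC")
})

test_that("difference is linear in the node values for two shifted Gaussians", {
  # log N(x; delta, 1) - log N(x; 0, 1) = delta * x - delta^2 / 2 per node
  delta <- 0.7
  models <- separated_models(delta)
  withr::with_seed(81, {
    tab <- random_table(20, dmn_nodes())
  })
  got <- log_density_difference(models$NC, models$AD, tab)
  want <- delta * rowSums(tab[, dmn_nodes()]) - 8 * delta^2 / 2
  expect_equal(got, want)
})

test_that("samples from each model score higher under their own model", {
  gens <- dmn_reference_generators(200, 200)
  bn_nc <- fit_gbn(sample_sem(gens$NC), gens$NC$dag)
  bn_ad <- fit_gbn(sample_sem(gens$AD), gens$AD$dag)
  gens2 <- dmn_reference_generators(300, 300, seed_nc = 7, seed_ad = 8)
  new_nc <- sample_sem(gens2$NC, "NC")
  new_ad <- sample_sem(gens2$AD, "AD")
  d_nc <- mean(log_density_difference(bn_nc, bn_ad, new_nc))
  d_ad <- mean(log_density_difference(bn_nc, bn_ad, new_ad))
  expect_gt(d_ad, d_nc)   # Kullback-Leibler positivity
})

test_that("classification reproduces the Bayes rule and separates when far apart", {
  models <- separated_models(5)   # means 5 sd apart per ROI
  withr::with_seed(82, {
    tab <- rbind(sample_from(0, 1000, "NC"), sample_from(5, 1000, "AD"))
  })
  labels <- classify_subjects(models$NC, models$AD, tab)
  expect_identical(labels, tab$group)   # Bayes error ~ 0
  # equals the Bayes rule with equal priors: sign of the density ratio
  scores <- log_density_difference(models$NC, models$AD, tab)
  expect_identical(labels, ifelse(scores > 0, "AD", "NC"))
  # explicit priors shift the threshold by log(prior ratio)
  shifted <- classify_subjects(models$NC, models$AD, tab,
                               priors = c(NC = 0.9, AD = 0.1))
  expect_identical(shifted, ifelse(scores > log(0.9 / 0.1), "AD", "NC"))
})

test_that("confusion counts and rates follow their definitions", {
  truth <- c("AD", "AD", "AD", "NC", "NC", "NC")
  scores <- c(2, 1, -1, -2, -1, 1)   # TP 2, FN 1, TN 2, FP 1
  rep <- evaluate_classifier(truth, scores)
  expect_identical(rep$n_true_positive, 2L)
  expect_identical(rep$n_false_negative, 1L)
  expect_identical(rep$n_true_negative, 2L)
  expect_identical(rep$n_false_positive, 1L)
  expect_equal(rep$accuracy, 4 / 6)
  expect_equal(rep$sensitivity, 2 / 3)
  expect_equal(rep$specificity, 2 / 3)
  # all-correct and all-NC degenerate calls
  perfect <- evaluate_classifier(truth, c(1, 1, 1, -1, -1, -1))
  expect_equal(c(perfect$accuracy, perfect$sensitivity, perfect$specificity),
               c(1, 1, 1))
  none <- evaluate_classifier(truth, rep(-1, 6))
  expect_equal(none$sensitivity, 0)
  expect_equal(none$specificity, 1)
  expect_error(evaluate_classifier(c("AD", "??"), c(1, 2)), "labels")
  expect_error(evaluate_classifier(truth, 1:3), "equal length")
})

test_that("the ROC curve is a monotone step function through the operating point", {
  withr::with_seed(83, {
    truth <- sample(c("NC", "AD"), 60, replace = TRUE)
    scores <- stats::rnorm(60) + (truth == "AD")
  })
  rep <- evaluate_classifier(truth, scores, threshold = 0)
  roc <- rep$roc_points
  expect_equal(c(roc$fpr[1], roc$tpr[1]), c(0, 0))
  expect_equal(c(roc$fpr[nrow(roc)], roc$tpr[nrow(roc)]), c(1, 1))
  expect_true(all(diff(roc$fpr) >= 0))
  expect_true(all(diff(roc$tpr) >= 0))
  # the threshold-0 operating point lies on the curve
  op <- c(1 - rep$specificity, rep$sensitivity)
  on_curve <- any(abs(roc$fpr - op[1]) < 1e-12 & abs(roc$tpr - op[2]) < 1e-12)
  expect_true(on_curve)
})

test_that("AUC matches pROC and approaches its limits", {
  withr::with_seed(84, {
    truth <- rep(c("NC", "AD"), each = 50)
    scores <- stats::rnorm(100) + 1.2 * (truth == "AD")
  })
  rep <- evaluate_classifier(truth, scores)
  ref <- suppressMessages(pROC::auc(pROC::roc(
    response = truth, predictor = scores, levels = c("NC", "AD"),
    direction = "<")))
  expect_equal(rep$auc, as.numeric(ref), tolerance = 1e-10)
  # well separated -> AUC ~ 1; identical models -> AUC ~ 0.5
  far <- evaluate_classifier(rep(c("NC", "AD"), each = 200),
                             c(stats::rnorm(200), stats::rnorm(200) + 10))
  expect_gt(far$auc, 0.999)
  withr::with_seed(85, {
    null <- evaluate_classifier(rep(c("NC", "AD"), each = 500),
                                stats::rnorm(1000))
  })
  expect_lt(abs(null$auc - 0.5), 0.06)
})

test_that("models generalize to an independently seeded cohort", {
  gens_train <- dmn_reference_generators(150, 150, seed_nc = 1, seed_ad = 2)
  gens_test <- dmn_reference_generators(150, 150, seed_nc = 3, seed_ad = 4)
  train <- rbind(sample_sem(gens_train$NC, "NC", "N"),
                 sample_sem(gens_train$AD, "AD", "A"))
  test <- rbind(sample_sem(gens_test$NC, "NC", "N"),
                sample_sem(gens_test$AD, "AD", "A"))
  models <- fit_group_models(train)
  acc_of <- function(tab) {
    s <- log_density_difference(models$NC, models$AD, tab)
    evaluate_classifier(tab$group, s)$accuracy
  }
  acc_train <- acc_of(train)
  acc_test <- acc_of(test)
  expect_gt(acc_test, 0.5)                   # clearly better than chance
  expect_lt(acc_train - acc_test, 0.10)      # little generalization loss
})
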