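test_that("Youden rules match the specification's worked examples", {
  # perfect separation: J = 1 at an observed-value cutoff with the mutant
  # side high
  r <- youden_rule(c(0.8, 0.9), c(0.1, 0.2))
  expect_equal(r$youden, 1)
  expect_identical(r$orientation, ">")
  expect_equal(r$cutoff, 0.8)
  expect_false(r$uninformative)
  expect_equal(r$auc, 1)
  # overlapping groups: exhaustive scan gives J = 2/3 at cutoff 0.7, ">"
  r2 <- youden_rule(c(0.9, 0.7, 0.4), c(0.6, 0.3, 0.2))
  expect_equal(r2$youden, 2 / 3, tolerance = 1e-12)
  expect_identical(r2$orientation, ">")
  expect_equal(r2$cutoff, 0.7)
  expect_equal(r2$sensitivity, 2 / 3, tolerance = 1e-12)
  expect_equal(r2$specificity, 1)
  # swapping the groups flips the orientation but not J
  r3 <- youden_rule(c(0.6, 0.3, 0.2), c(0.9, 0.7, 0.4))
  expect_identical(r3$orientation, "<=")
  expect_equal(r3$youden, r2$youden, tolerance = 1e-12)
  # all values identical: J = 0 and flagged uninformative
  r4 <- youden_rule(rep(1, 3), rep(1, 4))
  expect_equal(r4$youden, 0)
  expect_true(r4$uninformative)
})

test_that("Youden search equals exhaustive cutoff x orientation enumeration", {
  set.seed(12)
  for (rep in 1:100) {
    nm <- sample(3:12, 1); nw <- sample(3:12, 1)
    vm <- round(rnorm(nm, mean = sample(c(0, 0.5, 1), 1)), 2)
    vw <- round(rnorm(nw), 2)
    r <- youden_rule(vm, vw)
    expect_equal(r$youden, oracle_youden_max(vm, vw), tolerance = 1e-12)
    # the returned (cutoff, orientation) attains the reported J
    sens <- if (r$orientation == ">") mean(vm >= r$cutoff) else mean(vm <= r$cutoff)
    spec <- if (r$orientation == ">") mean(vw < r$cutoff) else mean(vw > r$cutoff)
    expect_equal(sens + spec - 1, r$youden, tolerance = 1e-12)
  }
})

test_that("rule AUC agrees with the reference ROC implementation", {
  set.seed(14)
  for (rep in 1:10) {
    vm <- rnorm(8, mean = 0.5); vw <- rnorm(10)
    r <- youden_rule(vm, vw)
    ref <- pROC::auc(pROC::roc(
      response = c(rep(0, 10), rep(1, 8)), predictor = c(vw, vm),
      direction = "<", quiet = TRUE
    ))
    expect_equal(r$auc, as.numeric(ref), tolerance = 1e-12)
    # the optimum over both orientations can only improve on the
    # fixed-direction ROC's best Youden index
    roc <- pROC::roc(response = c(rep(0, 10), rep(1, 8)),
                     predictor = c(vw, vm), direction = "<", quiet = TRUE)
    co <- pROC::coords(roc, "all", ret = c("sensitivity", "specificity"))
    expect_gte(r$youden + 1e-12, max(co$sensitivity + co$specificity - 1))
  }
})

test_that("J = 1 exactly when a single cutoff separates the groups", {
  set.seed(13)
  for (rep in 1:20) {
    vm <- runif(5); vw <- runif(5)
    r <- youden_rule(vm, vw)
    separable <- max(vw) < min(vm) || max(vm) < min(vw)
    expect_identical(r$youden == 1, separable)
  }
})

test_that("majority voting assigns pseudo-labels with the documented ties", {
  m <- matrix(c(0.9, 0.1,
                0.8, 0.2,
                0.7, 0.6), nrow = 2,
              dimnames = list(c("u1", "u2"), c("f1", "f2", "f3")))
  rules <- list(
    structure(list(feature = "f1", cutoff = 0.5, orientation = ">"),
              class = "threshold_rule"),
    structure(list(feature = "f2", cutoff = 0.5, orientation = ">"),
              class = "threshold_rule"),
    structure(list(feature = "f3", cutoff = 0.5, orientation = ">"),
              class = "threshold_rule")
  )
  pl <- assign_pseudo_labels(m, rules)
  # u1: all three rules vote mutant
  expect_identical(pl$pseudo_label[1], "mutant")
  expect_equal(pl$vote_fraction[1], 1)
  # u2: votes (wild, wild, mutant) -> wild with 2/3
  expect_identical(pl$pseudo_label[2], "wild")
  expect_equal(pl$vote_fraction[2], 2 / 3, tolerance = 1e-12)
  expect_true(all(pl$vote_fraction >= 0.5))
  # an exact 1-1 tie goes to wild type
  pl2 <- assign_pseudo_labels(m, rules[c(1, 3)])
  expect_identical(pl2$pseudo_label[2], "wild")
  expect_equal(pl2$vote_fraction[2], 0.5)
  expect_error(assign_pseudo_labels(m, list()), "empty")
  bad <- rules
  bad[[1]]$feature <- "nope"
  expect_error(assign_pseudo_labels(m, bad), "nope")
})

test_that("rule evaluation reproduces confusion-matrix arithmetic", {
  # single rule, engineered 2x2 table: TP=2 FN=1 TN=3 FP=0
  m <- matrix(c(0.9, 0.8, 0.2, 0.3, 0.1, 0.2), ncol = 1,
              dimnames = list(paste0("p", 1:6), "f"))
  labels <- c("mutant", "mutant", "mutant", "wild", "wild", "wild")
  rules <- list(structure(list(feature = "f", cutoff = 0.5, orientation = ">"),
                          class = "threshold_rule"))
  ev <- evaluate_rules(m, labels, rules)
  expect_equal(ev$sensitivity, 2 / 3, tolerance = 1e-12)
  expect_equal(ev$specificity, 1)
  expect_equal(ev$accuracy, 5 / 6, tolerance = 1e-12)
  # perfect prediction
  labels2 <- c(rep("mutant", 2), rep("wild", 4))
  ev2 <- evaluate_rules(m, labels2, rules)
  expect_equal(ev2$accuracy, 1)
  expect_equal(ev2$sensitivity, 1)
  expect_equal(ev2$specificity, 1)
  # single-class holdout: AUROC reported as undefined
  ev3 <- evaluate_rules(m, rep("wild", 6), rules)
  expect_true(is.na(ev3$auroc))
  expect_match(ev3$auroc_note, "single-class")
})

test_that("pseudo-labeling recovers hidden labels on separable cohorts", {
  coh <- test_cohort(effect = 2, n = 20, n_unlabeled = 16, seed = 31,
                     slices = 2, hw = 48)
  ft_all <- extract_feature_table(coh, texture_config())
  lab <- !is.na(ft_all$label)
  ft <- ft_all[lab, ]
  tt <- ttest_filter(ft)
  red <- reduce_attributes(discretize(tt$table), t_stats = tt$stats)
  rules <- build_rules(ft, features = red$attributes)
  # composition: rules only ever use reduct attributes, which survived the
  # t-test screen
  expect_true(all(vapply(rules, function(r) r$feature, "") %in% red$attributes))
  expect_true(all(red$attributes %in% tt$kept))
  pl <- assign_pseudo_labels(ft_all[!lab, ], rules)
  hidden <- vapply(coh[!lab], function(v) v$hidden_label, "")
  expect_gte(mean(pl$pseudo_label == hidden), 0.9)
})
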