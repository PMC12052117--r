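test_that("t-test screen matches hand-computed pooled statistics", {
  m <- cbind(sep = c(1, 2, 3, 5, 6, 7), flat = c(1, 2, 3, 1, 2, 3))
  rownames(m) <- paste0("p", 1:6)
  labels <- c("mutant", "mutant", "mutant", "wild", "wild", "wild")
  res <- ttest_filter(m, labels, alpha = 0.05)
  row <- res$stats[res$stats$feature == "sep", ]
  # pooled t = (2 - 6) / (1 * sqrt(2/3))
  expect_equal(row$t, -4 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(row$df, 4)
  expect_equal(row$p, 2 * pt(-abs(row$t), 4), tolerance = 1e-12)
  expect_lt(row$p, 0.01)
  expect_identical(res$kept, "sep")
  # strict inequality: alpha equal to the feature's p-value drops it
  res2 <- ttest_filter(m, labels, alpha = row$p)
  expect_false("sep" %in% res2$kept)
  # identically constant feature in both groups is dropped (p undefined)
  m2 <- cbind(m, const = rep(5, 6))
  res3 <- ttest_filter(m2, labels)
  expect_false("const" %in% res3$kept)
  expect_true(is.na(res3$stats$p[res3$stats$feature == "const"]))
})

test_that("t-test p-values agree with the reference implementation", {
  set.seed(8)
  m <- matrix(rnorm(40 * 20), 40, 20,
              dimnames = list(NULL, paste0("f", 1:20)))
  labels <- rep(c("mutant", "wild"), each = 20)
  res <- ttest_filter(m, labels)
  for (f in colnames(m)) {
    ref <- t.test(m[labels == "mutant", f], m[labels == "wild", f],
                  var.equal = TRUE)$p.value
    expect_equal(res$stats$p[res$stats$feature == f], ref, tolerance = 1e-9)
  }
})

test_that("quantile discretization bins as specified and replays stored edges", {
  m <- cbind(x = as.numeric(1:10), k = rep(3, 10))
  rownames(m) <- paste0("p", 1:10)
  labels <- rep(c("mutant", "wild"), 5)
  dt <- discretize(m, labels, n_bins = 2)
  expect_identical(dt$conditions$x, c(rep(1L, 5), rep(2L, 5)))
  expect_identical(unname(dt$n_bins_used["x"]), 2L)
  expect_identical(unname(dt$n_bins_used["k"]), 1L) # constant -> single bin
  m_new <- cbind(x = c(0.5, 5.4, 5.6, 99), k = rep(3, 4))
  dt2 <- discretize(m_new, edges = dt$edges)
  expect_identical(dt2$conditions$x, c(1L, 1L, 2L, 2L))
  expect_identical(discretize(m_new, edges = dt$edges)$conditions,
                   dt2$conditions)
})

test_that("positive region matches the equivalence-class oracle", {
  # attributes fully determine the decision -> every object is positive
  dt <- decision_table(data.frame(a = c(1, 1, 2, 2), b = c(1, 2, 1, 2)),
                       decision = c("x", "x", "y", "y"))
  expect_setequal(positive_region(dt, c("a", "b")), dt$objects)
  # identical conditions, conflicting decisions -> both excluded
  dt2 <- decision_table(data.frame(a = c(1, 1, 2)), c("x", "y", "y"))
  expect_setequal(positive_region(dt2, "a"), "3")
  # empty attribute set: positive only for a pure table
  expect_length(positive_region(dt2, character(0)), 0)
  dt3 <- decision_table(data.frame(a = 1:3), rep("x", 3))
  expect_setequal(positive_region(dt3, character(0)), dt3$objects)
  # randomized agreement with the brute-force oracle
  set.seed(9)
  for (rep in 1:10) {
    n <- sample(6:30, 1); k <- sample(2:5, 1)
    conds <- as.data.frame(matrix(sample(1:3, n * k, replace = TRUE), n, k))
    names(conds) <- paste0("a", seq_len(k))
    dtr <- decision_table(conds, sample(c("x", "y"), n, replace = TRUE))
    for (j in 1:3) {
      attrs <- sample(names(conds), sample(seq_len(k), 1))
      expect_identical(sort(positive_region(dtr, attrs)),
                       oracle_positive_region(dtr, attrs))
    }
  }
})

test_that("positive region is anti-monotone under attribute deletion", {
  set.seed(10)
  for (rep in 1:5) {
    n <- 20
    conds <- as.data.frame(matrix(sample(1:3, n * 4, replace = TRUE), n, 4))
    names(conds) <- paste0("a", 1:4)
    dtr <- decision_table(conds, sample(c("x", "y"), n, replace = TRUE))
    full <- names(conds)
    pos_full <- positive_region(dtr, full)
    for (a in full) {
      expect_true(all(positive_region(dtr, setdiff(full, a)) %in% pos_full))
    }
  }
})

test_that("attribute reduction preserves POS and is 1-minimal", {
  # a duplicated column is always removed
  set.seed(11)
  base <- data.frame(a = sample(1:3, 12, replace = TRUE),
                     b = sample(1:2, 12, replace = TRUE))
  base$c <- base$a
  dec <- ifelse(base$a == 1, "x", "y")
  dt <- decision_table(base, dec)
  red <- reduce_attributes(dt, order_policy = "given")
  expect_false(all(c("a", "c") %in% red$attributes))
  expect_identical(oracle_check_reduct(dt, red$attributes), "ok")
  # single-attribute table returns that attribute
  dt1 <- decision_table(data.frame(a = c(1, 2)), c("x", "y"))
  expect_identical(reduce_attributes(dt1)$attributes, "a")
  # randomized 1-minimality + POS preservation against the oracle
  for (rep in 1:8) {
    n <- sample(10:30, 1); k <- sample(3:10, 1)
    conds <- as.data.frame(matrix(sample(1:2, n * k, replace = TRUE), n, k))
    names(conds) <- paste0("a", seq_len(k))
    dec <- sample(c("x", "y"), n, replace = TRUE)
    dtr <- decision_table(conds, dec)
    if (length(positive_region(dtr, names(conds))) == 0) next
    for (policy in c("given", "random")) {
      red <- reduce_attributes(dtr, order_policy = policy, seed = rep)
      expect_identical(oracle_check_reduct(dtr, red$attributes), "ok")
      expect_identical(red$pos_size,
                       length(positive_region(dtr, names(conds))))
    }
  }
})
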