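# Independent brute-force oracles used to validate the texture, rough-set
# and Youden implementations. These deliberately use naive enumeration and
# never share code with the package internals.

# naive GLCM: loop over every pixel pair at the displacement
naive_glcm <- function(level_img, direction, offset, num_levels,
                       symmetric = TRUE, normalize = TRUE) {
  d <- switch(as.character(direction),
              "0" = c(0, offset), "45" = c(-offset, offset),
              "90" = c(-offset, 0), "135" = c(-offset, -offset))
  P <- matrix(0, num_levels, num_levels)
  nr <- nrow(level_img); nc <- ncol(level_img)
  for (r in seq_len(nr)) {
    for (cc in seq_len(nc)) {
      r2 <- r + d[1]; c2 <- cc + d[2]
      if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc) {
        i <- level_img[r, cc]; j <- level_img[r2, c2]
        P[i, j] <- P[i, j] + 1
        if (symmetric) P[j, i] <- P[j, i] + 1
      }
    }
  }
  if (normalize && sum(P) > 0) P <- P / sum(P)
  P
}

# naive GLRLM: explicit line walking with run-length counting
naive_glrlm <- function(level_img, direction, num_levels) {
  nr <- nrow(level_img); nc <- ncol(level_img)
  lines <- list()
  if (direction == 0) {
    for (r in seq_len(nr)) lines[[length(lines) + 1]] <- level_img[r, ]
  } else if (direction == 90) {
    for (cc in seq_len(nc)) lines[[length(lines) + 1]] <- level_img[, cc]
  } else if (direction == 45) {
    for (k in (1 + 1):(nr + nc)) {
      rs <- intersect(seq_len(nr), k - seq_len(nc))
      lines[[length(lines) + 1]] <-
        sapply(sort(rs, decreasing = TRUE), function(r) level_img[r, k - r])
    }
  } else if (direction == 135) {
    for (k in (1 - nr):(nc - 1)) {
      rs <- intersect(seq_len(nr), seq_len(nc) - k)
      lines[[length(lines) + 1]] <-
        sapply(sort(rs), function(r) level_img[r, r + k])
    }
  }
  max_run <- max(lengths(lines))
  R <- matrix(0, num_levels, max_run)
  for (ln in lines) {
    pos <- 1
    while (pos <= length(ln)) {
      run <- 1
      while (pos + run <= length(ln) && ln[pos + run] == ln[pos]) run <- run + 1
      R[ln[pos], run] <- R[ln[pos], run] + 1
      pos <- pos + run
    }
  }
  R
}

# equivalence-class positive-region oracle: group objects by the exact
# attribute tuple and keep groups with a single decision value
oracle_positive_region <- function(dt, attrs) {
  n <- length(dt$objects)
  keys <- apply(dt$conditions[, attrs, drop = FALSE], 1, paste, collapse = "|")
  if (length(attrs) == 0) keys <- rep("", n)
  keep <- logical(n)
  for (k in unique(keys)) {
    members <- which(keys == k)
    if (length(unique(dt$decision[members])) == 1) keep[members] <- TRUE
  }
  sort(dt$objects[keep])
}

# exhaustive reduct checker: the returned subset preserves |POS| and no
# single attribute can be dropped from it
oracle_check_reduct <- function(dt, reduct_attrs) {
  full <- oracle_positive_region(dt, names(dt$conditions))
  here <- oracle_positive_region(dt, reduct_attrs)
  if (!identical(full, here)) return("POS not preserved")
  for (a in reduct_attrs) {
    if (length(reduct_attrs) == 1) break
    smaller <- oracle_positive_region(dt, setdiff(reduct_attrs, a))
    if (identical(smaller, full)) return(paste("not 1-minimal: can drop", a))
  }
  "ok"
}

# exhaustive Youden search over every (cutoff, orientation) pair
oracle_youden_max <- function(vm, vw) {
  best <- -Inf
  for (cut in unique(c(vm, vw))) {
    for (orient in c("ge", "le")) {
      sens <- if (orient == "ge") mean(vm >= cut) else mean(vm <= cut)
      spec <- if (orient == "ge") mean(vw < cut) else mean(vw > cut)
      best <- max(best, sens + spec - 1)
    }
  }
  best
}

# small labeled phantom cohort shared by several tests (memoised per options)
test_cohort <- local({
  cache <- list()
  function(effect = 2, n = 10, n_unlabeled = 0, seed = 101, slices = 2,
           hw = 48, sequences = "T2") {
    key <- paste(effect, n, n_unlabeled, seed, slices, hw,
                 paste(sequences, collapse = ","), sep = "_")
    if (is.null(cache[[key]])) {
      spec <- cohort_spec(
        n_labeled_mutant = n, n_labeled_wild = n, n_unlabeled = n_unlabeled,
        slices = slices, height = hw, width = hw,
        sequence_names = sequences, class_texture_effect = effect, seed = seed
      )
      cache[[key]] <<- generate_cohort(spec)
    }
    cache[[key]]
  }
})

empirical_feature_auc <- function(ft, feature) {
  m <- feature_matrix(ft)
  a <- m[ft$label == "mutant", feature]
  b <- m[ft$label == "wild", feature]
  mean(outer(a, b, ">") + 0.5 * outer(a, b, "=="))
}
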