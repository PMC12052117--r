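#' Screen features by independent two-sample t-test
#'
#' Performs a per-feature independent two-sample t-test between the two
#' classes and retains exactly the features with two-sided `p < alpha`
#' (strict inequality; `p == alpha` is dropped). The default is the
#' classical pooled-variance Student test; Welch is available. No
#' multiple-testing correction is applied (raw p-values are screened).
#'
#' @param ft Feature table from [extract_feature_table()] (or a numeric
#'   matrix, patients x features).
#' @param labels Character/factor vector of class labels (`mutant`/`wild`)
#'   for the rows; taken from `ft$label` when omitted.
#' @param alpha Significance level (default 0.05).
#' @param var_equal Pooled-variance Student test (`TRUE`, default) or Welch.
#' @return List with `table` (the retained columns of `ft`), `stats` (a
#'   data.frame of feature, t, df, p, retained) and `kept` (feature names).
#'   Features whose test is undefined (zero variance in both groups with
#'   equal means) are dropped.
#' @export
ttest_filter <- function(ft, labels = NULL, alpha = 0.05, var_equal = TRUE) {
  m <- if (is.matrix(ft)) ft else feature_matrix(ft)
  if (is.null(labels)) {
    if (is.matrix(ft)) stop("labels are required when ft is a matrix")
    labels <- ft$label
  }
  labels <- as.character(labels)
  classes <- sort(unique(stats::na.omit(labels)))
  if (length(classes) != 2) stop("exactly two classes are required")
  g1 <- labels == classes[1]; g2 <- labels == classes[2]
  if (sum(g1) < 2 || sum(g2) < 2) stop("need >= 2 samples per class")
  stats_df <- do.call(rbind, lapply(colnames(m), function(f) {
    x <- m[g1, f]; y <- m[g2, f]
    res <- tryCatch(
      stats::t.test(x, y, var.equal = var_equal),
      error = function(e) NULL
    )
    if (is.null(res)) {
      data.frame(feature = f, t = NA_real_, df = NA_real_, p = NA_real_)
    } else {
      data.frame(feature = f, t = unname(res$statistic),
                 df = unname(res$parameter), p = res$p.value)
    }
  }))
  stats_df$retained <- !is.na(stats_df$p) & stats_df$p < alpha
  kept <- stats_df$feature[stats_df$retained]
  table_out <- if (is.matrix(ft)) ft[, kept, drop = FALSE] else {
    ft[, c(intersect(c("patient_id", "label"), names(ft)), kept), drop = FALSE]
  }
  list(table = table_out, stats = stats_df, kept = kept)
}

#' Discretize continuous features into a rough-set decision table
#'
#' Maps each feature to quantile bins computed on the supplied (labeled)
#' data so the indiscernibility relation of the rough-set reduction is
#' defined. Bin edges are stored and can be re-applied to new (unlabeled)
#' data deterministically. Features with fewer than `n_bins` distinct
#' quantile edges receive fewer bins (recorded in `n_bins_used`).
#'
#' @param ft Feature table (or numeric matrix) of the labeled data.
#' @param labels Class labels per row (from `ft$label` when omitted).
#' @param n_bins Number of quantile bins (>= 2, default 4).
#' @param edges Optional list of precomputed bin edges (from a previous
#'   call) to re-apply instead of fitting new ones.
#' @return An object of class `decision_table`: list with `objects`,
#'   `conditions` (data.frame of integer bins), `decision` (character),
#'   `edges`, `n_bins_used`.
#' @export
discretize <- function(ft, labels = NULL, n_bins = 4, edges = NULL) {
  if (is.null(edges) && n_bins < 2) stop("n_bins must be >= 2")
  m <- if (is.matrix(ft)) ft else feature_matrix(ft)
  if (is.null(labels) && !is.matrix(ft)) labels <- ft$label
  fit <- is.null(edges)
  if (fit) {
    edges <- lapply(colnames(m), function(f) {
      x <- m[, f]
      q <- stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1),
                           names = FALSE, type = 7)
      e <- unique(q[-c(1, length(q))])
      e <- e[e > min(x) & e < max(x)] # constant features get a single bin
      c(-Inf, e, Inf)
    })
    names(edges) <- colnames(m)
  }
  conds <- as.data.frame(lapply(colnames(m), function(f) {
    e <- edges[[f]]
    if (is.null(e)) stop("no stored edges for feature: ", f)
    as.integer(cut(m[, f], breaks = e, labels = FALSE, right = TRUE))
  }), check.names = FALSE)
  names(conds) <- colnames(m)
  structure(
    list(
      objects = rownames(m) %||% as.character(seq_len(nrow(m))),
      conditions = conds,
      decision = if (is.null(labels)) rep(NA_character_, nrow(m)) else as.character(labels),
      edges = edges,
      n_bins_used = vapply(edges, function(e) length(e) - 1L, 1L)
    ),
    class = "decision_table"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a decision table directly
#'
#' @param conditions data.frame of discrete condition attributes.
#' @param decision Vector of decision values (binary in this pipeline).
#' @param objects Optional object identifiers.
#' @return A `decision_table`.
#' @export
decision_table <- function(conditions, decision, objects = NULL) {
  stopifnot(nrow(conditions) == length(decision))
  if (anyNA(conditions) || anyNA(decision)) stop("decision tables must be complete")
  structure(
    list(
      objects = objects %||% as.character(seq_len(nrow(conditions))),
      conditions = as.data.frame(conditions, check.names = FALSE),
      decision = as.character(decision),
      edges = NULL, n_bins_used = NULL
    ),
    class = "decision_table"
  )
}

#' Positive region of a decision table under an attribute subset
#'
#' The positive region is the union of the indiscernibility classes (groups
#' of objects with identical values on `attrs`) whose members all share one
#' decision value. Under the empty attribute set all objects form one class,
#' so the positive region is non-empty only for a decision-pure table.
#'
#' @param dt A `decision_table`.
#' @param attrs Character vector of condition attribute names.
#' @return Character vector of object ids in the positive region.
#' @export
positive_region <- function(dt, attrs) {
  stopifnot(inherits(dt, "decision_table"))
  bad <- setdiff(attrs, names(dt$conditions))
  if (length(bad)) stop("unknown attribute(s): ", paste(bad, collapse = ", "))
  n <- length(dt$objects)
  if (length(attrs) == 0) {
    # all objects form one indiscernibility class
    return(if (length(unique(dt$decision)) == 1L) dt$objects else character(0))
  }
  key <- do.call(paste, c(dt$conditions[attrs], sep = "\r"))
  pure <- vapply(split(dt$decision, key), function(d) length(unique(d)) == 1L,
                 TRUE)
  dt$objects[pure[key]]
}

#' Rough-set attribute reduction by one-by-one deletion
#'
#' Starting from the full condition attribute set, repeatedly sweeps over
#' the attributes (in the chosen order) and permanently deletes any
#' attribute whose removal leaves the positive region unchanged; sweeps
#' repeat until a full pass deletes nothing. The result preserves the
#' positive region of the full table exactly and is 1-minimal: removing any
#' single remaining attribute changes the positive region. Reducts are not
#' unique; the deletion order selects among them.
#'
#' @param dt A `decision_table`.
#' @param order_policy `"weakest_first"` (default; requires `t_stats`),
#'   `"random"` (seeded) or `"given"` (table column order).
#' @param t_stats Optional data.frame with columns `feature`, `t` (from
#'   [ttest_filter()]); with `"weakest_first"`, attributes with smaller
#'   absolute t are tried for deletion first so discriminative features tend
#'   to be retained.
#' @param seed Seed for `"random"` ordering.
#' @return Object of class `reduct`: list with `attributes`, `pos_size`,
#'   `pos_objects`, and `trace` (per-pass deletions).
#' @export
reduce_attributes <- function(dt, order_policy = c("weakest_first", "random", "given"),
                              t_stats = NULL, seed = 1L) {
  order_policy <- match.arg(order_policy)
  stopifnot(inherits(dt, "decision_table"))
  attrs <- names(dt$conditions)
  full_pos <- positive_region(dt, attrs)
  if (length(full_pos) == 0) {
    stop("positive region under the full attribute set is empty")
  }
  order_attrs <- switch(order_policy,
    given = attrs,
    random = with_seed(seed, sample(attrs)),
    weakest_first = {
      if (is.null(t_stats)) attrs else {
        tt <- t_stats$t[match(attrs, t_stats$feature)]
        attrs[order(abs(tt), na.last = FALSE)]
      }
    }
  )
  current <- order_attrs
  target <- sort(full_pos)
  trace <- list()
  pass <- 0L
  repeat {
    pass <- pass + 1L
    deleted <- character(0)
    for (a in intersect(order_attrs, current)) {
      if (length(current) == 1L) break
      trial <- setdiff(current, a)
      if (identical(sort(positive_region(dt, trial)), target)) {
        current <- trial
        deleted <- c(deleted, a)
      }
    }
    trace[[pass]] <- deleted
    if (length(deleted) == 0) break
  }
  kept <- attrs[attrs %in% current] # restore original column order
  structure(
    list(attributes = kept, pos_size = length(target),
         pos_objects = target, trace = trace),
    class = "reduct"
  )
}

#' @export
print.reduct <- function(x, ...) {
  cat(sprintf("<reduct> %d attribute(s), |POS| = %d\n",
              length(x$attributes), x$pos_size))
  invisible(x)
}

#' Serialize a reduction report to JSON
#'
#' @param red A `reduct`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_reduct <- function(red, path) {
  jsonlite::write_json(
    list(attributes = red$attributes, pos_size = red$pos_size,
         deletions_per_pass = red$trace),
    path, auto_unbox = FALSE, pretty = TRUE
  )
  invisible(path)
}
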