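# Does a value fall on the mutant side of a rule?
# Orientation ">" votes mutant for values at or above the cutoff (the high
# side, inclusive); orientation "<=" votes mutant at or below it.
rule_votes_mutant <- function(values, cutoff, orientation) {
  if (orientation == ">") values >= cutoff else values <= cutoff
}

# Empirical (rank / Mann-Whitney) AUC of mutant vs wild values.
empirical_auc <- function(values_mutant, values_wild) {
  cmp <- outer(values_mutant, values_wild, function(a, b) {
    (a > b) + 0.5 * (a == b)
  })
  mean(cmp)
}

#' Build a Youden-index threshold rule for one feature
#'
#' Scans every observed value as a candidate cutoff, in both orientations
#' (mutant side high, glyph `">"`, or mutant side low, glyph `"<="`), and
#' returns the rule maximizing Youden's J = sensitivity + specificity - 1.
#' Ties in J are broken toward the rule with higher specificity, then the
#' smallest cutoff, then orientation `"<="`. The rule also records the
#' empirical (rank) AUC and the pooled two-sample t-test p-value of the
#' feature.
#'
#' @param values_mutant,values_wild Feature values of the two labeled groups
#'   (both non-empty).
#' @param feature Feature descriptor stored in the rule.
#' @return Object of class `threshold_rule`: feature, cutoff, orientation,
#'   youden, sensitivity, specificity, auc, p_value, uninformative flag.
#' @export
youden_rule <- function(values_mutant, values_wild, feature = "feature") {
  if (length(values_mutant) == 0 || length(values_wild) == 0) {
    stop("both groups must be non-empty")
  }
  all_vals <- sort(unique(c(values_mutant, values_wild)))
  best <- NULL
  for (orientation in c("<=", ">")) {
    for (cut in all_vals) {
      sens <- mean(rule_votes_mutant(values_mutant, cut, orientation))
      spec <- mean(!rule_votes_mutant(values_wild, cut, orientation))
      j <- sens + spec - 1
      cand <- list(cutoff = cut, orientation = orientation, youden = j,
                   sensitivity = sens, specificity = spec)
      if (is.null(best) ||
          j > best$youden + 1e-12 ||
          (abs(j - best$youden) <= 1e-12 &&
           (cand$specificity > best$specificity + 1e-12 ||
            (abs(cand$specificity - best$specificity) <= 1e-12 &&
             (cut < best$cutoff ||
              (cut == best$cutoff && orientation == "<=" &&
               best$orientation == ">")))))) {
        best <- cand
      }
    }
  }
  pv <- if (length(values_mutant) >= 2 && length(values_wild) >= 2 &&
            (stats::var(values_mutant) > 0 || stats::var(values_wild) > 0)) {
    stats::t.test(values_mutant, values_wild, var.equal = TRUE)$p.value
  } else NA_real_
  structure(
    list(feature = feature, cutoff = best$cutoff,
         orientation = best$orientation, youden = best$youden,
         sensitivity = best$sensitivity, specificity = best$specificity,
         auc = empirical_auc(values_mutant, values_wild), p_value = pv,
         uninformative = best$youden <= 0),
    class = "threshold_rule"
  )
}

#' @export
print.threshold_rule <- function(x, ...) {
  cat(sprintf("<threshold_rule> %s %s%.4g  J=%.3f AUC=%.3f%s\n",
              x$feature, ifelse(x$orientation == ">", ">", "≤"),
              x$cutoff, x$youden, x$auc,
              if (x$uninformative) " (uninformative)" else ""))
  invisible(x)
}

#' Build threshold rules for a set of features
#'
#' @param ft Labeled feature table (or numeric matrix).
#' @param labels Class labels (`mutant`/`wild`); from `ft$label` if omitted.
#' @param features Feature names to build rules for (typically the reduct).
#' @param j_floor Rules with Youden index below this floor are dropped
#'   (default 0 keeps J = 0 rules out only if negative; all reduct features
#'   are used by default since J is never negative at the optimum).
#' @return List of `threshold_rule` objects.
#' @export
build_rules <- function(ft, labels = NULL, features = NULL, j_floor = 0) {
  m <- if (is.matrix(ft)) ft else feature_matrix(ft)
  if (is.null(labels) && !is.matrix(ft)) labels <- ft$label
  labels <- as.character(labels)
  if (is.null(features)) features <- colnames(m)
  rules <- lapply(features, function(f) {
    youden_rule(m[labels == "mutant", f], m[labels == "wild", f], feature = f)
  })
  rules[vapply(rules, function(r) r$youden >= j_floor, TRUE)]
}

#' Assign pseudo-labels by per-feature threshold votes
#'
#' Every rule votes per patient (value on the mutant side of its cutoff is
#' a mutant vote); the majority of votes assigns the pseudo-label, with
#' ties going to the configured default class (wild type, the majority
#' class in typical cohorts). Under `policy = "youden_weighted"` votes are
#' weighted by each rule's Youden index.
#'
#' @param ft Feature table (or numeric matrix) of unlabeled patients.
#' @param rules Non-empty list of `threshold_rule` objects; every rule's
#'   feature must be a column of `ft`.
#' @param policy `"majority"` (default) or `"youden_weighted"`.
#' @param tie_break Class assigned on an exact tie (default `"wild"`).
#' @return data.frame with `patient_id`, `pseudo_label`, `vote_fraction`
#'   (fraction of [weighted] votes for the assigned class) and `n_rules`.
#' @export
assign_pseudo_labels <- function(ft, rules,
                                 policy = c("majority", "youden_weighted"),
                                 tie_break = "wild") {
  policy <- match.arg(policy)
  if (length(rules) == 0) stop("empty rule list")
  m <- if (is.matrix(ft)) ft else feature_matrix(ft)
  feats <- vapply(rules, function(r) r$feature, "")
  missing <- setdiff(feats, colnames(m))
  if (length(missing)) {
    stop("rule feature(s) absent from table: ", paste(missing, collapse = ", "))
  }
  votes <- vapply(rules, function(r) {
    rule_votes_mutant(m[, r$feature], r$cutoff, r$orientation)
  }, logical(nrow(m)))
  votes <- matrix(votes, nrow = nrow(m))
  w <- if (policy == "majority") rep(1, length(rules)) else {
    vapply(rules, function(r) max(r$youden, 0), 0)
  }
  if (sum(w) == 0) w <- rep(1, length(rules))
  mutant_score <- as.vector(votes %*% w) / sum(w)
  label <- ifelse(mutant_score > 0.5, "mutant",
                  ifelse(mutant_score < 0.5, "wild", tie_break))
  vote_fraction <- ifelse(label == "mutant", mutant_score, 1 - mutant_score)
  data.frame(
    patient_id = rownames(m) %||% as.character(seq_len(nrow(m))),
    pseudo_label = label,
    vote_fraction = vote_fraction,
    mutant_score = mutant_score,
    n_rules = length(rules),
    stringsAsFactors = FALSE
  )
}

#' Evaluate threshold rules on a labeled holdout
#'
#' @param ft Labeled holdout feature table (or matrix).
#' @param labels True labels; from `ft$label` if omitted.
#' @param rules List of `threshold_rule` objects.
#' @param policy Vote policy, see [assign_pseudo_labels()].
#' @return List with `accuracy`, `sensitivity`, `specificity` (mutant is the
#'   positive class), `auroc` of the mutant vote score (`NA` with a note for
#'   a single-class holdout), and the confusion `table`.
#' @export
evaluate_rules <- function(ft, labels = NULL, rules,
                           policy = c("majority", "youden_weighted")) {
  policy <- match.arg(policy)
  if (is.null(labels) && !is.matrix(ft)) labels <- ft$label
  labels <- as.character(labels)
  pl <- assign_pseudo_labels(ft, rules, policy = policy)
  pred <- pl$pseudo_label
  tp <- sum(pred == "mutant" & labels == "mutant")
  fn <- sum(pred == "wild" & labels == "mutant")
  tn <- sum(pred == "wild" & labels == "wild")
  fp <- sum(pred == "mutant" & labels == "wild")
  auroc <- if (length(unique(labels)) < 2) NA_real_ else {
    empirical_auc(pl$mutant_score[labels == "mutant"],
                  pl$mutant_score[labels == "wild"])
  }
  list(
    accuracy = (tp + tn) / length(labels),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    auroc = auroc,
    auroc_note = if (is.na(auroc)) "AUROC undefined: single-class holdout" else NULL,
    table = matrix(c(tp, fp, fn, tn), 2, 2,
                   dimnames = list(pred = c("mutant", "wild"),
                                   truth = c("mutant", "wild")))
  )
}

#' Write threshold rules as a CSV table
#'
#' Columns mirror the usual per-feature rule report: Attributes,
#' YoudenIndex, Threshold (orientation glyph plus cutoff), AUC, P.
#'
#' @param rules List of `threshold_rule` objects.
#' @param path Output CSV path.
#' @return Invisibly, the data.frame written.
#' @export
write_rules <- function(rules, path) {
  df <- do.call(rbind, lapply(rules, function(r) {
    data.frame(
      Attributes = r$feature,
      YoudenIndex = r$youden,
      Threshold = sprintf("%s%g", ifelse(r$orientation == ">", ">", "<="), r$cutoff),
      AUC = r$auc,
      P = r$p_value,
      stringsAsFactors = FALSE
    )
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
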