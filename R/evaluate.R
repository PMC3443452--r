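#' Area under the ROC curve
#'
#' Rank-based AUC: the probability that a random disease sample's score
#' exceeds a random control sample's score, with ties counted one-half
#' (the normalized Mann-Whitney U statistic).
#'
#' @param scores Numeric vector of classifier scores (higher = more disease).
#' @param labels Character vector (`disease`/`control`), logical vector
#'   (`TRUE` = disease), or 0/1 vector aligned with `scores`.
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(scores, labels) {
  pos <- if (is.character(labels) || is.factor(labels)) {
    as.character(labels) == "disease"
  } else {
    as.logical(labels)
  }
  stopifnot(length(scores) == length(pos), !anyNA(scores), !anyNA(pos))
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L) {
    abort("AUC is undefined with a single class")
  }
  r <- rank(scores) # midranks handle ties as 1/2
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Cross-validation and search settings
#'
#' Bundles the evaluation protocol: stratified k-fold cross-validation of an
#' RBF-kernel SVM, repeated with fresh random partitions, scored by the AUC
#' of the pooled out-of-fold decision values of each repeat. Defaults follow
#' the five-fold, 100-repeat protocol; during the greedy search a lighter
#' `search_repeats` is used for candidate screening, with the final marker
#' set re-scored at the full `n_repeats` (set `faithful = TRUE` to screen at
#' the full repeat count too).
#'
#' @param n_folds Number of CV folds (>= 2; default 5).
#' @param n_repeats Repeats for the final evaluation (default 100).
#' @param search_repeats Repeats per candidate during greedy screening
#'   (default 10).
#' @param cost SVM soft-margin cost C (default 1).
#' @param gamma RBF kernel width, or `"auto"` for 1 / n_features.
#' @param seed Base seed; repeat r uses seed + r for its fold assignment, so
#'   all candidates compared in a step see identical partitions.
#' @param improvement_tol Minimum mean-AUC gain to accept a new pathway
#'   (default 1e-3, guarding against Monte-Carlo jitter).
#' @param stratified Preserve class proportions per fold (default TRUE).
#' @param frontier `"all-selected"` (candidates adjacent to any selected
#'   pathway; default) or `"first-only"` (adjacent to the first marker only).
#' @param faithful If TRUE, screen candidates at `n_repeats` as well.
#' @return An `eval_config` list.
#' @export
eval_config <- function(n_folds = 5L, n_repeats = 100L, search_repeats = 10L,
                        cost = 1, gamma = "auto", seed = 1L,
                        improvement_tol = 1e-3, stratified = TRUE,
                        frontier = c("all-selected", "first-only"),
                        faithful = FALSE) {
  frontier <- match.arg(frontier)
  stopifnot(n_folds >= 2L, n_repeats >= 1L, search_repeats >= 1L,
            cost > 0, improvement_tol >= 0)
  if (faithful) search_repeats <- n_repeats
  structure(
    list(n_folds = as.integer(n_folds), n_repeats = as.integer(n_repeats),
         search_repeats = as.integer(search_repeats), cost = cost,
         gamma = gamma, seed = as.integer(seed),
         improvement_tol = improvement_tol, stratified = stratified,
         frontier = frontier),
    class = "eval_config"
  )
}

# Fold assignment for one repeat: depends only on (labels, n_folds, seed,
# stratified), never on the features, so every candidate evaluated with the
# same seed sees the same partition.
assign_folds <- function(is_disease, n_folds, seed, stratified = TRUE) {
  n <- length(is_disease)
  withr::with_seed(seed, {
    fold <- integer(n)
    if (stratified) {
      for (cls in c(TRUE, FALSE)) {
        idx <- which(is_disease == cls)
        fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
      }
    } else {
      fold <- sample(rep_len(seq_len(n_folds), n))
    }
    fold
  })
}

# Decision values oriented so larger = more disease-like, regardless of the
# factor level order libsvm happened to see first.
svm_decision_values <- function(fit, newdata) {
  pred <- stats::predict(fit, newdata, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  sign <- if (startsWith(colnames(dv)[1L], "disease")) 1 else -1
  sign * dv[, 1L]
}

# One repeat of k-fold CV for a samples x features matrix; returns the AUC of
# the pooled out-of-fold decision values.
cv_auc_once <- function(x, is_disease, n_folds, seed, cost, gamma, stratified) {
  fold <- assign_folds(is_disease, n_folds, seed, stratified)
  dv <- numeric(length(is_disease))
  y <- factor(ifelse(is_disease, "disease", "control"),
              levels = c("control", "disease"))
  for (k in seq_len(n_folds)) {
    test <- fold == k
    fit <- e1071::svm(
      x = x[!test, , drop = FALSE], y = y[!test],
      kernel = "radial", cost = cost, gamma = gamma, scale = FALSE
    )
    dv[test] <- svm_decision_values(fit, x[test, , drop = FALSE])
  }
  auc_score(dv, is_disease)
}

#' Score a feature set by repeated cross-validated SVM AUC
#'
#' Trains an RBF-kernel SVM on the given feature rows and evaluates it by
#' stratified k-fold cross-validation, repeated with independent random
#' partitions; each repeat pools its out-of-fold decision values into one
#' ROC, and the mean and standard deviation of the per-repeat AUCs are
#' returned.
#'
#' @param features Wide feature tibble (first column = feature id, one column
#'   per sample) or a `pathway_activity` object.
#' @param labels Labels tibble (`sample`, `label`).
#' @param feature_ids Feature (pathway or gene) ids to use as predictors.
#' @param cfg An [eval_config()].
#' @param n_repeats Override of `cfg$n_repeats` (used internally during
#'   greedy screening).
#' @return Tibble with `mean_auc`, `auc_sd`, `n_repeats`.
#' @export
evaluate_feature_set <- function(features, labels, feature_ids,
                                 cfg = eval_config(), n_repeats = NULL) {
  if (inherits(features, "pathway_activity")) {
    features <- features$scores
  }
  m <- as_feature_matrix(features)
  missing <- setdiff(feature_ids, rownames(m))
  if (length(missing) > 0L) {
    abort(paste0("feature(s) not found: ", paste(missing, collapse = ", ")))
  }
  if (length(feature_ids) == 0L) {
    abort("feature set must be non-empty")
  }
  x <- t(m[feature_ids, , drop = FALSE])
  lab <- align_labels(labels, rownames(x))
  is_disease <- lab == "disease"
  if (min(sum(is_disease), sum(!is_disease)) < cfg$n_folds) {
    abort("each class needs at least n_folds samples")
  }
  gamma <- if (identical(cfg$gamma, "auto")) 1 / ncol(x) else cfg$gamma
  reps <- n_repeats %||% cfg$n_repeats
  aucs <- vapply(seq_len(reps), function(r) {
    cv_auc_once(x, is_disease, cfg$n_folds, cfg$seed + r,
                cfg$cost, gamma, cfg$stratified)
  }, numeric(1L))
  tibble::tibble(
    mean_auc = mean(aucs),
    auc_sd = sd(aucs),
    n_repeats = reps
  )
}
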