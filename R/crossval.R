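#' Plan for double (nested) cross-validation
#'
#' @param outer_folds folds of the outer loop (default 5, i.e. 20% held out
#'   at a time for external validation).
#' @param inner_folds folds of the inner loop (default 4, i.e. 25% of the
#'   retained samples held out at a time).
#' @param a_grid candidate numbers of PLS components (capped by rank at fit
#'   time).
#' @param seed RNG seed for fold assignment.
#' @param stratified keep the group proportions in every fold (default
#'   TRUE, so a 10+10 group structure survives 5-fold splitting).
#' @return A \code{cv_plan} list.
#' @export
cv_plan <- function(outer_folds = 5, inner_folds = 4, a_grid = 1:5,
                    seed = 1, stratified = TRUE) {
  stopifnot(outer_folds >= 2, inner_folds >= 2, length(a_grid) >= 1,
            all(a_grid >= 1))
  structure(list(outer_folds = as.integer(outer_folds),
                 inner_folds = as.integer(inner_folds),
                 a_grid = sort(unique(as.integer(a_grid))),
                 seed = as.integer(seed), stratified = isTRUE(stratified)),
            class = "cv_plan")
}

# Fold ids 1..k covering all of idx exactly once; stratified by y.
# Retries with incremented seed until every fold's complement contains both
# classes; errors after 10 attempts.
make_folds <- function(y, k, stratified, seed) {
  n <- length(y)
  for (attempt in 0:9) {
    folds <- with_seed(seed + attempt, {
      f <- integer(n)
      if (stratified) {
        for (g in unique(y)) {
          idx <- which(y == g)
          f[idx] <- sample(rep_len(seq_len(k), length(idx)))
        }
      } else {
        f <- sample(rep_len(seq_len(k), n))
      }
      f
    })
    ok <- all(vapply(seq_len(k), function(i)
      length(unique(y[folds != i])) == 2, logical(1)))
    if (ok) return(folds)
  }
  stop("could not build folds with two classes in every training set ",
       "after 10 reshuffles", call. = FALSE)
}

#' Double cross-validation of the TP classifier
#'
#' Two-loop (nested) cross-validation. The outer loop holds out each fold
#' once for honest performance estimation; on the retained samples, the
#' inner loop selects the number of PLS components A from \code{a_grid} by
#' held-out misclassification of the TP-score sign (positive score predicts
#' persistence), ties going to the smaller A. A TP model with the selected
#' A is then refitted on the whole outer-training set and used to classify
#' the outer held-out fold. The pooled correct classification rate is
#' computed from the concatenated held-out predictions, not from fold
#' averages.
#'
#' @param x an \code{spc_norm} (or samples x proteins matrix).
#' @param y group labels; taken from \code{x} when it carries them.
#' @param plan a \code{\link{cv_plan}}.
#' @return A \code{cv_report}: \code{chosen_a_per_fold},
#'   \code{outer_scores} (per-fold correct fractions), \code{pooled_ccr}
#'   (percent), \code{chosen_a_final} (modal A, ties to the smaller),
#'   \code{predictions} (named, all samples), \code{outer_fold} assignment.
#' @export
double_cv <- function(x, y = NULL, plan = cv_plan()) {
  group <- group_from(x, y)
  X <- as_sample_matrix(x)
  n <- nrow(X)
  sizes <- table(group)
  if (plan$stratified && any(sizes < plan$outer_folds))
    stop("stratified folds need every group size >= outer_folds",
         call. = FALSE)

  outer_fold <- make_folds(group, plan$outer_folds, plan$stratified,
                           plan$seed)
  predictions <- rep(NA_character_, n)
  chosen_a <- integer(plan$outer_folds)
  outer_scores <- numeric(plan$outer_folds)

  for (f in seq_len(plan$outer_folds)) {
    tr <- which(outer_fold != f)
    te <- which(outer_fold == f)
    a_grid <- plan$a_grid
    inner_fold <- make_folds(group[tr], plan$inner_folds, plan$stratified,
                             plan$seed * 131 + f)
    inner_err <- vapply(a_grid, function(a) {
      errs <- 0L
      for (g in seq_len(plan$inner_folds)) {
        itr <- tr[inner_fold != g]
        ite <- tr[inner_fold == g]
        amax <- min(length(itr) - 1, ncol(X))
        if (a > amax) return(Inf)
        tp <- tryCatch(plsda_tp(X[itr, , drop = FALSE], group[itr], a),
                       error = function(e) NULL)
        if (is.null(tp)) return(Inf)
        pred <- tp_class(predict(tp, X[ite, , drop = FALSE]))
        errs <- errs + sum(pred != as.character(group[ite]))
      }
      as.numeric(errs)
    }, numeric(1))
    a_star <- a_grid[which.min(inner_err)]  # ties -> smaller A (sorted grid)

    tp <- plsda_tp(X[tr, , drop = FALSE], group[tr], a_star)
    pred <- tp_class(predict(tp, X[te, , drop = FALSE]))
    predictions[te] <- pred
    chosen_a[f] <- a_star
    outer_scores[f] <- mean(pred == as.character(group[te]))
  }

  tab <- table(factor(chosen_a, levels = sort(unique(chosen_a))))
  chosen_a_final <- as.integer(names(tab)[which.max(tab)])
  structure(list(chosen_a_per_fold = chosen_a,
                 outer_scores = outer_scores,
                 pooled_ccr = 100 * mean(predictions ==
                                           as.character(group)),
                 chosen_a_final = chosen_a_final,
                 predictions = stats::setNames(predictions, rownames(X)),
                 outer_fold = stats::setNames(outer_fold, rownames(X)),
                 plan = plan),
            class = "cv_report")
}

tp_class <- function(scores) {
  ifelse(scores > 0, "persistence", "regression")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("double cross-validation (", x$plan$outer_folds, " outer x ",
      x$plan$inner_folds, " inner folds)\n", sep = "")
  cat("  components per outer fold:",
      paste(x$chosen_a_per_fold, collapse = " "), "\n")
  cat("  pooled held-out CCR: ", round(x$pooled_ccr, 1), "% (final A = ",
      x$chosen_a_final, ")\n", sep = "")
  invisible(x)
}
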