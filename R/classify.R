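#' ROC-derived decision stump for one protein
#'
#' Chooses the threshold maximizing Youden's J (sensitivity + specificity -
#' 1) over the midpoints between consecutive distinct sorted values plus
#' one candidate below and one above all values, with ties broken toward
#' the lower threshold. The direction records which side predicts which
#' group: \code{"gt_is_regression"} means values above the threshold are
#' called regression. On offset (+1) spectral counts of a protein detected
#' only in regression samples this reproduces the detection rule
#' \dQuote{<= 1 versus > 1}.
#'
#' @param values numeric vector, one value per sample (typically offset
#'   counts).
#' @param y group labels.
#' @param accession optional protein id stored on the rule.
#' @return A \code{classifier_rule}: \code{accession}, \code{threshold},
#'   \code{direction}, \code{youden_j}, \code{uninformative} flag (J = 0),
#'   \code{source = "roc"}.
#' @export
roc_threshold <- function(values, y, accession = NULL) {
  y <- check_group(y)
  if (!all(GROUP_LEVELS %in% y))
    stop("both groups must be present", call. = FALSE)
  vs <- unname(sort(unique(values)))
  cand <- if (length(vs) == 1) vs - 0.5
          else c(vs[1] - 0.5, (vs[-length(vs)] + vs[-1]) / 2,
                 vs[length(vs)] + 0.5)
  is_reg <- y == "regression"
  best <- list(j = -Inf, thr = NA_real_, dir = NA_character_)
  for (thr in cand) {
    gt <- values > thr
    for (dir in c("gt_is_regression", "gt_is_persistence")) {
      pred_reg <- if (dir == "gt_is_regression") gt else !gt
      sens <- mean(pred_reg[is_reg])
      spec <- mean(!pred_reg[!is_reg])
      j <- sens + spec - 1
      if (j > best$j + 1e-12)  # strict improvement: ties keep lower thr
        best <- list(j = j, thr = thr, dir = dir)
    }
  }
  structure(list(accession = accession, threshold = best$thr,
                 direction = best$dir, youden_j = best$j,
                 uninformative = best$j <= 1e-12, source = "roc"),
            class = "classifier_rule")
}

#' @export
print.classifier_rule <- function(x, ...) {
  side <- if (x$direction == "gt_is_regression") "regression" else
    "persistence"
  cat("rule [", x$source, "]: ", x$accession %||% "(variable)", " > ",
      format(x$threshold), " -> ", side,
      if (x$uninformative) "  (uninformative, J = 0)", "\n", sep = "")
  invisible(x)
}

rule_predict <- function(rule, v) {
  gt <- v > rule$threshold
  if (rule$direction == "gt_is_regression")
    ifelse(gt, "regression", "persistence")
  else
    ifelse(gt, "persistence", "regression")
}

#' Apply a stump or a two-node tree to a count matrix
#'
#' @param rules a \code{classifier_rule} or a \code{tree_model}.
#' @param m an \code{\link{spc_matrix}} (offset counts), \code{spc_norm} or
#'   proteins x samples matrix containing the rule accessions.
#' @param y optional group labels for the confusion table; taken from
#'   \code{m} when it carries them.
#' @return List with \code{predictions} (named), \code{confusion} (2 x 2
#'   actual x predicted table when labels are known), \code{correct_total},
#'   \code{correct_by_group} and, when split labels exist,
#'   \code{correct_by_split}.
#' @export
apply_rules <- function(rules, m, y = NULL) {
  mat <- t(as_sample_matrix(m))  # proteins x samples
  get_values <- function(acc) {
    if (is.null(acc) || !acc %in% rownames(mat))
      stop("accession not present in matrix: ", acc %||% "<NULL>",
           call. = FALSE)
    mat[acc, ]
  }
  if (inherits(rules, "classifier_rule")) {
    pred <- rule_predict(rules, get_values(rules$accession))
  } else if (inherits(rules, "tree_model")) {
    pred <- tree_predict(rules, mat, get_values)
  } else stop("rules must be a classifier_rule or a tree_model",
              call. = FALSE)
  names(pred) <- colnames(mat)

  out <- list(predictions = pred)
  group <- tryCatch(group_from(m, y), error = function(e) NULL)
  if (!is.null(group)) {
    group <- stats::setNames(as.character(group), colnames(mat))
    out$confusion <- table(actual = factor(group, GROUP_LEVELS),
                           predicted = factor(pred, GROUP_LEVELS))
    correct <- pred == group
    out$correct_total <- sum(correct)
    out$correct_by_group <- tapply(correct, factor(group, GROUP_LEVELS),
                                   sum)
    split <- if (inherits(m, c("spc_matrix", "spc_norm"))) m$split else NULL
    if (!is.null(split))
      out$correct_by_split <- tapply(correct, split, sum)
  }
  out
}

tree_predict <- function(tree, mat, get_values) {
  if (is.null(tree$root)) {
    # degenerate tree: one class
    return(rep(tree$leaf_class, ncol(mat)))
  }
  v <- get_values(tree$root$accession)
  side <- ifelse(v > tree$root$threshold, "gt", "le")
  pred <- unname(tree$root_classes[side])
  if (!is.null(tree$child)) {
    refine <- side == tree$child$branch
    if (any(refine)) {
      vc <- get_values(tree$child$accession)[refine]
      pred[refine] <- unname(
        tree$child$classes[ifelse(vc > tree$child$threshold, "gt", "le")])
    }
  }
  pred
}

# Exhaustive best Gini split for one node. Returns NULL when no split
# reduces impurity, else list(accession, threshold, decrease, classes).
best_gini_split <- function(mat, y1) {
  n <- length(y1)
  gini <- function(k1, m) if (m == 0) 0 else 2 * (k1 / m) * (1 - k1 / m)
  parent <- gini(sum(y1), n)
  best <- NULL
  accs <- rownames(mat)
  accs <- accs[order(accs, method = "radix")]  # lexicographic tie order
  for (acc in accs) {
    v <- mat[acc, ]
    o <- order(v)
    vs <- v[o]
    ys <- y1[o]
    k <- which(diff(vs) > 0)
    if (length(k) == 0) next
    c1 <- cumsum(ys)
    for (i in k) {                 # ascending -> lower threshold wins ties
      nl <- i
      kl <- c1[i]
      dec <- parent - (nl / n) * gini(kl, nl) -
        ((n - nl) / n) * gini(sum(y1) - kl, n - nl)
      if (is.null(best) || dec > best$decrease + 1e-12) {
        thr <- unname((vs[i] + vs[i + 1]) / 2)
        le <- v <= thr
        best <- list(accession = acc, threshold = thr, decrease = dec,
                     classes = c(le = majority_class(y1[le]),
                                 gt = majority_class(y1[!le])))
      }
    }
  }
  if (!is.null(best) && best$decrease <= 1e-12) best <- NULL
  best
}

majority_class <- function(y1) {
  if (length(y1) == 0) return("persistence")
  k1 <- sum(y1)
  # ties go to persistence (the "no detection" default of this assay)
  if (k1 >= length(y1) - k1) "persistence" else "regression"
}

#' Fit a two-node classification tree
#'
#' CART-style exhaustive search: the root split is the (protein, threshold)
#' pair maximizing the Gini impurity decrease, ties broken by row order of
#' the matrix (sort rows by accession for a lexicographic rule) and then by
#' the lower threshold; a second (child) split is fitted on the impure
#' branch -- when both branches are impure, on the one where a split buys
#' the larger within-branch weighted decrease -- and kept only if it
#' reduces impurity. Depth is capped at two nodes. All proteins are ranked
#' as root competitors by their own best root decrease.
#'
#' @param x an \code{\link{spc_matrix}}, \code{spc_norm} or proteins x
#'   samples matrix.
#' @param y group labels; taken from \code{x} when it carries them.
#' @return A \code{tree_model}: \code{root} (accession, threshold),
#'   \code{root_classes} (predicted class per side), optional \code{child}
#'   (accession, threshold, branch, classes), \code{competitor_ranking}
#'   data frame, \code{degenerate} flag for pure input.
#' @export
fit_two_node_tree <- function(x, y = NULL) {
  group <- group_from(x, y)
  mat <- t(as_sample_matrix(x))
  if (nrow(mat) < 2) stop("need at least 2 proteins", call. = FALSE)
  y1 <- group == "persistence"

  if (length(unique(y1)) == 1)
    return(structure(list(root = NULL, child = NULL,
                          leaf_class = majority_class(y1),
                          degenerate = TRUE,
                          competitor_ranking =
                            data.frame(accession = character(0),
                                       decrease = numeric(0))),
                     class = "tree_model"))

  per_protein <- vapply(rownames(mat), function(acc) {
    b <- best_gini_split(mat[acc, , drop = FALSE], y1)
    if (is.null(b)) 0 else b$decrease
  }, numeric(1))
  ranking <- data.frame(accession = rownames(mat),
                        decrease = unname(per_protein),
                        stringsAsFactors = FALSE)
  ranking <- ranking[order(-ranking$decrease, ranking$accession), ]
  rownames(ranking) <- NULL

  root <- best_gini_split(mat, y1)
  if (is.null(root))
    return(structure(list(root = NULL, child = NULL,
                          leaf_class = majority_class(y1),
                          degenerate = TRUE, competitor_ranking = ranking),
                     class = "tree_model"))

  le <- mat[root$accession, ] <= root$threshold
  child <- NULL
  cand <- list()
  for (branch in c("le", "gt")) {
    in_branch <- if (branch == "le") le else !le
    yb <- y1[in_branch]
    if (length(unique(yb)) < 2) next
    b <- best_gini_split(mat[, in_branch, drop = FALSE], yb)
    if (is.null(b)) next
    b$branch <- branch
    b$weighted_decrease <- b$decrease * mean(in_branch)
    cand[[branch]] <- b
  }
  if (length(cand) > 0) {
    wd <- vapply(cand, `[[`, numeric(1), "weighted_decrease")
    child <- cand[[which.max(wd)]]  # ties -> "le" (first in order)
    child <- child[c("accession", "threshold", "branch", "classes")]
  }

  structure(list(root = root[c("accession", "threshold", "decrease")],
                 root_classes = root$classes, child = child,
                 degenerate = FALSE, competitor_ranking = ranking),
            class = "tree_model")
}

#' @export
print.tree_model <- function(x, ...) {
  if (is.null(x$root)) {
    cat("tree_model: degenerate (no split); predicts", x$leaf_class, "\n")
    return(invisible(x))
  }
  cat("tree_model (depth <= 2):\n  root: ", x$root$accession, " > ",
      format(x$root$threshold), " (Gini decrease ",
      format(x$root$decrease, digits = 3), ")\n", sep = "")
  if (!is.null(x$child))
    cat("  child on '", x$child$branch, "' branch: ", x$child$accession,
        " > ", format(x$child$threshold), "\n", sep = "")
  invisible(x)
}

#' Rank proteins by single-variable logistic fit
#'
#' Fits a one-protein binary logistic regression (intercept + slope) per
#' protein and ranks proteins by the likelihood-ratio statistic against the
#' intercept-only model. Complete separation (some threshold splits the
#' groups perfectly) is detected directly from the group-wise value ranges
#' and reported as a flag; separated proteins rank above all non-separated
#' ones. Constant proteins get a statistic of zero.
#'
#' @param x an \code{spc_norm}, \code{spc_matrix} or proteins x samples
#'   matrix.
#' @param y group labels; taken from \code{x} when it carries them.
#' @return Data frame sorted by rank: \code{accession}, \code{lr_stat},
#'   \code{separation}, \code{rank}.
#' @export
logistic_rank <- function(x, y = NULL) {
  group <- group_from(x, y)
  mat <- t(as_sample_matrix(x))
  y1 <- as.numeric(group == "persistence")
  res <- lapply(rownames(mat), function(acc) {
    v <- mat[acc, ]
    if (stats::var(v) == 0)
      return(list(acc = acc, lr = 0, sep = FALSE))
    sep <- max(v[y1 == 0]) < min(v[y1 == 1]) ||
      max(v[y1 == 1]) < min(v[y1 == 0])
    fit <- suppressWarnings(stats::glm(y1 ~ v, family = stats::binomial(),
                                       control = list(maxit = 50)))
    list(acc = acc, lr = fit$null.deviance - fit$deviance, sep = sep)
  })
  out <- data.frame(accession = vapply(res, `[[`, character(1), "acc"),
                    lr_stat = vapply(res, `[[`, numeric(1), "lr"),
                    separation = vapply(res, `[[`, logical(1), "sep"),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$separation, -out$lr_stat, out$accession), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
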