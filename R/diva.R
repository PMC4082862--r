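#' Correct classification rate of a single variable
#'
#' The per-variable statistic of the discriminating-variable (DIVA) test.
#' Over \code{n_splits} seeded stratified Monte-Carlo splits, about a
#' quarter of each group is held out; on the training part the threshold
#' (midpoint between consecutive distinct sorted values) and side
#' maximizing balanced accuracy are chosen, ties broken toward the lower
#' midpoint; the held-out part is then scored with balanced accuracy (mean
#' of per-group accuracies, so unequal group sizes cannot inflate the
#' rate). The CCR is \code{100 * max(m, 1 - m)} where \code{m} is the mean
#' held-out balanced accuracy: a variable carrying no information scores
#' about 50, a completely separating variable scores 100, and the direction
#' of separation is irrelevant.
#'
#' @param values numeric vector, one value per sample.
#' @param y group labels.
#' @param n_splits number of Monte-Carlo splits.
#' @param seed RNG seed for the splits.
#' @param holdout_frac fraction of each group held out per split.
#' @return CCR in percent, a scalar in [50, 100].
#' @export
variable_ccr <- function(values, y, n_splits = 100, seed = 1,
                         holdout_frac = 0.25) {
  y <- check_group(y)
  splits <- make_mc_splits(y, n_splits, seed, holdout_frac)
  ccr_from_splits(values, y, splits)
}

# Stratified Monte-Carlo splits shared across variables: list of logical
# held-out masks.
make_mc_splits <- function(y, n_splits, seed, holdout_frac = 0.25) {
  if (n_splits < 1) stop("n_splits must be >= 1", call. = FALSE)
  idx_by_group <- lapply(GROUP_LEVELS, function(g) which(y == g))
  if (any(vapply(idx_by_group, length, integer(1)) < 2))
    stop("each group needs at least 2 samples", call. = FALSE)
  n <- length(y)
  with_seed(seed, lapply(seq_len(n_splits), function(s) {
    held <- rep(FALSE, n)
    for (idx in idx_by_group) {
      h <- max(1L, round(holdout_frac * length(idx)))
      h <- min(h, length(idx) - 1L)  # keep both groups in training
      held[sample(idx, h)] <- TRUE
    }
    held
  }))
}

ccr_from_splits <- function(values, y, splits) {
  y1 <- y == "persistence"
  acc <- vapply(splits, function(held) {
    split_balanced_accuracy(values, y1, held)
  }, numeric(1))
  m <- mean(acc)
  100 * max(m, 1 - m)
}

# Train a threshold on !held, return balanced accuracy on held.
split_balanced_accuracy <- function(v, y1, held) {
  vtr <- v[!held]
  ytr <- y1[!held]
  cut <- best_bacc_cut(vtr, ytr)
  yte <- y1[held]
  vte <- v[held]
  if (is.null(cut)) return(0.5)  # constant training values: chance
  pred1 <- if (cut$low_is_persistence) vte <= cut$thr else vte > cut$thr
  groups_acc <- c(if (any(!yte)) mean(pred1[!yte] == FALSE),
                  if (any(yte)) mean(pred1[yte] == TRUE))
  mean(groups_acc)
}

# Best balanced-accuracy midpoint threshold on training data. Returns
# list(thr, low_is_persistence) or NULL when no cut exists.
best_bacc_cut <- function(v, y1) {
  o <- order(v)
  vs <- v[o]
  ys <- y1[o]
  n1 <- sum(ys)
  n0 <- length(ys) - n1
  k <- which(diff(vs) > 0)
  if (length(k) == 0 || n1 == 0 || n0 == 0) return(NULL)
  c1 <- cumsum(ys)
  c0 <- cumsum(!ys)
  # low side predicted regression (class 0)
  bacc_reg_low <- (c0[k] / n0 + (n1 - c1[k]) / n1) / 2
  bacc_per_low <- 1 - bacc_reg_low
  thr <- (vs[k] + vs[k + 1]) / 2
  i0 <- which.max(bacc_reg_low)  # which.max -> lowest midpoint on ties
  i1 <- which.max(bacc_per_low)
  if (bacc_reg_low[i0] >= bacc_per_low[i1])
    list(thr = thr[i0], low_is_persistence = FALSE)
  else
    list(thr = thr[i1], low_is_persistence = TRUE)
}

#' Selectivity-ratio limit for a CCR objective
#'
#' Converts a correct-classification-rate objective into a significance
#' limit on the selectivity ratio: the limit is the smallest \code{|SR|}
#' among variables whose CCR reaches the objective, and a variable is
#' significant exactly when \code{|SR| >= limit}. When no variable reaches
#' the objective the limit is \code{+Inf} and nothing is significant.
#'
#' @param sr named vector of signed selectivity ratios.
#' @param ccr vector of CCR percentages aligned with \code{sr}.
#' @param objective CCR objective in percent (e.g. 90).
#' @return List with \code{sr_limit} and logical \code{significant}.
#' @export
sr_limit_for_ccr <- function(sr, ccr, objective = 90) {
  if (length(sr) != length(ccr))
    stop("sr and ccr must align over the same proteins", call. = FALSE)
  qualifying <- which(ccr >= objective)
  if (length(qualifying) == 0) {
    sr_limit <- Inf
    significant <- rep(FALSE, length(sr))
  } else {
    sr_limit <- min(abs(sr[qualifying]))
    significant <- abs(sr) >= sr_limit
  }
  names(significant) <- names(sr)
  list(sr_limit = sr_limit, significant = significant)
}

#' DIVA test over a matrix
#'
#' Runs the discriminating-variable test: fits the target-projection model,
#' computes signed selectivity ratios, a Monte-Carlo CCR for every protein
#' (all proteins share the same splits), and the SR significance limit for
#' the requested CCR objective.
#'
#' @param x an \code{spc_norm} (or samples x proteins matrix).
#' @param y group labels; taken from \code{x} when it carries them.
#' @param objective CCR objective in percent.
#' @param n_splits Monte-Carlo splits per protein.
#' @param seed RNG seed.
#' @param n_components PLS components for the TP model.
#' @param tp optionally, a pre-fitted \code{tp_model} on \code{x}.
#' @return A \code{diva_result}: named \code{ccr}, \code{sr},
#'   \code{sr_limit}, logical \code{significant}, \code{objective_ccr},
#'   \code{n_splits}, \code{seed}.
#' @export
diva_test <- function(x, y = NULL, objective = 90, n_splits = 100, seed = 1,
                      n_components = 2, tp = NULL) {
  group <- group_from(x, y)
  X <- as_sample_matrix(x)
  if (is.null(tp)) tp <- plsda_tp(X, group, n_components)
  sr <- tp$selectivity_ratio
  splits <- make_mc_splits(group, n_splits, seed)
  ccr <- vapply(seq_len(ncol(X)), function(j)
    ccr_from_splits(X[, j], group, splits), numeric(1))
  names(ccr) <- colnames(X)
  lim <- sr_limit_for_ccr(sr, ccr, objective)
  structure(list(ccr = ccr, sr = sr, sr_limit = lim$sr_limit,
                 significant = lim$significant, objective_ccr = objective,
                 n_splits = n_splits, seed = seed),
            class = "diva_result")
}

#' @export
print.diva_result <- function(x, ...) {
  cat("DIVA test: objective CCR ", x$objective_ccr, "%, ", x$n_splits,
      " splits\n", sep = "")
  cat("  SR significance limit: +/-", format(x$sr_limit, digits = 4), "\n")
  cat("  significant proteins: ", sum(x$significant), " of ",
      length(x$significant), "\n", sep = "")
  invisible(x)
}
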