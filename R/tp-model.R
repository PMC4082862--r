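#' Fit a PLS-DA model (PLS1, NIPALS)
#'
#' Partial least-squares regression of a binary class variable on the
#' normalized spectral counts. The class is coded regression = 0,
#' persistence = 1 and centered; the predictor matrix is column mean
#' centered (optionally autoscaled). Components are extracted by NIPALS for
#' a single response (PLS1), deflating the predictor matrix only.
#'
#' @param x an \code{spc_norm}, \code{spc_matrix}, or a samples x proteins
#'   numeric matrix.
#' @param y group labels (\code{"regression"} / \code{"persistence"});
#'   taken from \code{x} when it carries them.
#' @param n_components number of PLS components A, \code{1 <= A <=
#'   min(samples - 1, proteins)} and at most the rank of the centered
#'   predictor matrix.
#' @param scale autoscale columns to unit variance? Default \code{FALSE}:
#'   spectral counts share a common scale, so only centering is applied.
#' @return A \code{plsda_fit} list: centered matrix \code{X}, centering
#'   vectors, matrices \code{W}, \code{scores}, \code{P}, response loadings
#'   \code{q}, and the A-component regression coefficient vector \code{b}.
#' @export
fit_plsda <- function(x, y = NULL, n_components = 2, scale = FALSE) {
  group <- group_from(x, y)
  X <- as_sample_matrix(x)
  n <- nrow(X)
  p <- ncol(X)
  if (length(group) != n)
    stop("length of group labels does not match the number of samples",
         call. = FALSE)
  if (length(unique(group[!is.na(group)])) < 2)
    stop("both groups must be represented", call. = FALSE)
  A <- as.integer(n_components)
  if (A < 1 || A > min(n - 1, p))
    stop("n_components must be in [1, min(samples - 1, proteins)]",
         call. = FALSE)

  y01 <- as.numeric(group == "persistence")
  x_means <- colMeans(X)
  x_sds <- if (scale) apply(X, 2, stats::sd) else rep(1, p)
  x_sds[x_sds == 0] <- 1
  Xc <- sweep(sweep(X, 2, x_means), 2, x_sds, `/`)
  y_mean <- mean(y01)
  yc <- y01 - y_mean

  W <- matrix(0, p, A)
  Tm <- matrix(0, n, A)
  P <- matrix(0, p, A)
  q <- numeric(A)
  Xa <- Xc
  tol <- 1e-12 * max(1, sum(Xc^2))
  for (a in seq_len(A)) {
    w <- crossprod(Xa, yc)[, 1]
    nw <- sqrt(sum(w^2))
    if (nw^2 < tol)
      stop("n_components exceeds the rank of the discriminative subspace ",
           "(component ", a, " has no signal)", call. = FALSE)
    w <- w / nw
    t_a <- Xa %*% w
    tt <- sum(t_a^2)
    if (tt < tol)
      stop("n_components exceeds the rank of X (degenerate component ", a,
           ")", call. = FALSE)
    p_a <- crossprod(Xa, t_a)[, 1] / tt
    q[a] <- sum(yc * t_a) / tt
    W[, a] <- w
    Tm[, a] <- t_a
    P[, a] <- p_a
    Xa <- Xa - t_a %*% t(p_a)
  }
  # A-component regression vector: b = W (P'W)^{-1} q
  b <- W %*% solve(crossprod(P, W), q)

  structure(list(X = Xc, x_means = x_means, x_sds = x_sds, scaled = scale,
                 y01 = y01, y_mean = y_mean, group = group,
                 W = W, scores = Tm, P = P, q = q, b = b[, 1],
                 n_components = A,
                 sample_ids = rownames(X), protein_ids = colnames(X)),
            class = "plsda_fit")
}

#' Collapse a PLS-DA model to its target-projection component
#'
#' Projects the fitted A-component PLS model onto the single latent
#' direction predictive of the class variable: the target-projection (TP)
#' weight is the normalized regression coefficient vector, the TP score of
#' each sample is the projection of its centered profile on that weight, and
#' the TP loadings are the least-squares regression of each protein on the
#' TP scores. The component is oriented so that the mean score of the
#' persistence group is positive; signed selectivity ratios are attached
#' (see \code{\link{selectivity_ratio}}).
#'
#' @param pls a \code{plsda_fit}.
#' @return A \code{tp_model}: \code{weight_tp} (unit norm), \code{scores_tp}
#'   (named per sample), \code{loadings_tp}, \code{selectivity_ratio},
#'   \code{explained_var}, \code{residual_var}, \code{sr_infinite} flags,
#'   \code{y_coding}, centering information and the group labels.
#' @export
target_projection <- function(pls) {
  stopifnot(inherits(pls, "plsda_fit"))
  b <- pls$b
  nb <- sqrt(sum(b^2))
  if (nb == 0 || !is.finite(nb))
    stop("regression vector is zero: no discriminative signal", call. = FALSE)
  w_tp <- b / nb
  t_tp <- (pls$X %*% w_tp)[, 1]
  tt <- sum(t_tp^2)
  p_tp <- crossprod(pls$X, t_tp)[, 1] / tt

  flip <- mean(t_tp[pls$group == "persistence"]) <
    mean(t_tp[pls$group == "regression"])
  if (flip) {
    w_tp <- -w_tp
    t_tp <- -t_tp
    p_tp <- -p_tp
  }

  tp <- structure(list(weight_tp = stats::setNames(w_tp, pls$protein_ids),
                       scores_tp = stats::setNames(t_tp, pls$sample_ids),
                       loadings_tp = stats::setNames(p_tp, pls$protein_ids),
                       n_components = pls$n_components,
                       y_coding = c(regression = 0, persistence = 1),
                       centering = list(x_means = pls$x_means,
                                        x_sds = pls$x_sds,
                                        scaled = pls$scaled,
                                        y_mean = pls$y_mean),
                       group = pls$group),
                  class = "tp_model")
  sr <- selectivity_ratio(tp, pls$X, centered = TRUE)
  tp$selectivity_ratio <- sr
  tp$explained_var <- attr(sr, "explained_var")
  tp$residual_var <- attr(sr, "residual_var")
  tp$sr_infinite <- attr(sr, "infinite")
  tp
}

#' Signed selectivity ratios
#'
#' For each protein, the ratio of the variance explained by the
#' target-projection component to the residual variance, signed by the TP
#' loading: with centered column \eqn{x_i}, explained
#' \eqn{= ||t_{TP} p_i||^2}, residual \eqn{= ||x_i - t_{TP} p_i||^2}, and
#' \eqn{SR_i = sign(p_i) \cdot explained_i / residual_i}. Proteins
#' exactly collinear with the TP scores have zero residual variance; they
#' are reported as a signed infinite sentinel and flagged in the
#' \code{"infinite"} attribute rather than folded into the ranking silently.
#'
#' @param tp a \code{tp_model}.
#' @param x the matrix the model was fitted on (\code{spc_norm} or samples x
#'   proteins matrix).
#' @param centered is \code{x} already centered/scaled as in the fit?
#' @return Named numeric vector of signed SR values with attributes
#'   \code{explained_var}, \code{residual_var} and \code{infinite}.
#' @export
selectivity_ratio <- function(tp, x, centered = FALSE) {
  stopifnot(inherits(tp, "tp_model"))
  X <- as_sample_matrix(x)
  if (!centered) {
    # centering vectors are defined per model protein, so the protein set
    # must match; pre-centered columns may be any set of variables
    if (ncol(X) != length(tp$loadings_tp))
      stop("matrix has ", ncol(X), " proteins but the model has ",
           length(tp$loadings_tp), call. = FALSE)
    X <- sweep(X, 2, tp$centering$x_means)
    X <- sweep(X, 2, tp$centering$x_sds, `/`)
  }
  t_tp <- tp$scores_tp
  if (nrow(X) != length(t_tp))
    stop("matrix has ", nrow(X), " samples but the model has ",
         length(t_tp), call. = FALSE)
  tt <- sum(t_tp^2)
  p_tp <- crossprod(X, t_tp)[, 1] / tt
  explained <- p_tp^2 * tt
  resid <- colSums((X - tcrossprod(t_tp, p_tp))^2)
  total <- colSums(X^2)

  is_inf <- resid <= 1e-12 * pmax(total, .Machine$double.eps) & explained > 0
  sr <- numeric(length(p_tp))
  pos <- !is_inf & resid > 0
  sr[pos] <- sign(p_tp[pos]) * explained[pos] / resid[pos]
  sr[is_inf] <- sign(p_tp[is_inf]) * Inf
  # constant (all-zero centered) columns: explained = residual = 0 -> SR 0
  structure(stats::setNames(sr, colnames(X)),
            explained_var = stats::setNames(explained, colnames(X)),
            residual_var = stats::setNames(resid, colnames(X)),
            infinite = stats::setNames(is_inf, colnames(X)))
}

#' Convenience: fit PLS-DA and collapse to the TP component
#'
#' @inheritParams fit_plsda
#' @return A \code{tp_model}.
#' @export
plsda_tp <- function(x, y = NULL, n_components = 2, scale = FALSE) {
  target_projection(fit_plsda(x, y, n_components, scale))
}

#' TP scores for new samples
#'
#' @param object a \code{tp_model}.
#' @param newdata samples x proteins matrix (or \code{spc_norm}) with the
#'   model's proteins in the same order.
#' @param ... unused.
#' @return Named numeric vector of oriented TP scores; a positive score
#'   predicts persistence.
#' @export
predict.tp_model <- function(object, newdata, ...) {
  X <- as_sample_matrix(newdata)
  if (ncol(X) != length(object$weight_tp))
    stop("newdata protein count does not match the model", call. = FALSE)
  X <- sweep(X, 2, object$centering$x_means)
  X <- sweep(X, 2, object$centering$x_sds, `/`)
  stats::setNames((X %*% object$weight_tp)[, 1], rownames(X))
}

#' @export
print.tp_model <- function(x, ...) {
  cat("tp_model: ", x$n_components, "-component PLS-DA collapsed to one ",
      "target-projection component\n", sep = "")
  cat("  proteins:", length(x$weight_tp), " samples:", length(x$scores_tp),
      "\n")
  sgn <- sign(x$scores_tp) == ifelse(x$group == "persistence", 1, -1)
  cat("  score-sign agreement with groups: ",
      round(100 * mean(sgn), 1), "%\n", sep = "")
  inf_n <- sum(x$sr_infinite)
  cat("  |SR| range: ",
      paste(round(range(abs(x$selectivity_ratio[!x$sr_infinite])), 3),
            collapse = " .. "),
      if (inf_n > 0) paste0(" (+", inf_n, " infinite)"), "\n", sep = "")
  invisible(x)
}
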