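# Independent oracles used across the suite. Each reimplements the checked
# quantity from first principles (explicit loops, lm fits, exhaustive
# enumeration) so it shares no code path with the package functions.

# Selectivity ratio by explicit per-protein regression on the TP scores:
# explained/residual variance from lm() fitted values and residuals.
oracle_sr <- function(X, scores) {
  Xc <- scale(X, center = TRUE, scale = FALSE)
  vapply(seq_len(ncol(Xc)), function(j) {
    fit <- stats::lm(Xc[, j] ~ scores - 1)
    expl <- sum(stats::fitted(fit)^2)
    res <- sum(stats::residuals(fit)^2)
    sign(stats::coef(fit)[1]) * expl / res
  }, numeric(1))
}

# Closed-form first PLS1 component: w1 proportional to X_c' y_c.
oracle_pls1_first <- function(X, y01) {
  Xc <- scale(X, center = TRUE, scale = FALSE)
  yc <- y01 - mean(y01)
  w <- drop(crossprod(Xc, yc))
  w <- w / sqrt(sum(w^2))
  list(w = w, scores = drop(Xc %*% w))
}

# Balanced accuracy of the threshold classifier, by explicit loops.
oracle_bacc <- function(v_tr, y_tr, v_te, y_te) {
  thrs <- NULL
  sv <- sort(unique(v_tr))
  if (length(sv) >= 2) thrs <- (sv[-length(sv)] + sv[-1]) / 2
  if (is.null(thrs)) return(0.5)
  best <- list(bacc = -1, thr = NA, low = NA)
  for (thr in thrs) {
    for (low_is_per in c(FALSE, TRUE)) {
      pred_per <- if (low_is_per) v_tr <= thr else v_tr > thr
      accs <- c(mean(pred_per[y_tr]), mean(!pred_per[!y_tr]))
      bacc <- mean(accs)
      if (bacc > best$bacc + 1e-12)
        best <- list(bacc = bacc, thr = thr, low = low_is_per)
    }
  }
  pred_per <- if (best$low) v_te <= best$thr else v_te > best$thr
  accs <- c(if (any(y_te)) mean(pred_per[y_te]),
            if (any(!y_te)) mean(!pred_per[!y_te]))
  mean(accs)
}

# Exact expected CCR at small n by enumerating every stratified
# one-per-group holdout split.
oracle_ccr_exhaustive <- function(v, y1) {
  idx0 <- which(!y1)
  idx1 <- which(y1)
  accs <- c()
  for (i in idx0) for (j in idx1) {
    held <- c(i, j)
    accs <- c(accs, oracle_bacc(v[-held], y1[-held], v[held], y1[held]))
  }
  m <- mean(accs)
  100 * max(m, 1 - m)
}

# Exhaustive Youden's J over every distinct threshold and both directions.
oracle_best_youden <- function(v, is_reg) {
  cand <- c(min(v) - 1, sort(unique(v)), max(v) + 1)
  best <- -Inf
  for (thr in cand) {
    for (gt_is_reg in c(TRUE, FALSE)) {
      pred_reg <- if (gt_is_reg) v > thr else v <= thr
      j <- mean(pred_reg[is_reg]) + mean(!pred_reg[!is_reg]) - 1
      best <- max(best, j)
    }
  }
  best
}

# Exhaustive Gini root split over all proteins and all cutpoints.
oracle_tree_root <- function(mat, y1) {
  n <- length(y1)
  gini <- function(y) if (length(y) == 0) 0 else
    1 - mean(y)^2 - (1 - mean(y))^2
  parent <- gini(y1)
  best <- list(decrease = -Inf)
  for (acc in sort(rownames(mat))) {
    v <- mat[acc, ]
    sv <- sort(unique(v))
    if (length(sv) < 2) next
    for (thr in (sv[-1] + sv[-length(sv)]) / 2) {
      le <- v <= thr
      if (!any(le) || all(le)) next
      dec <- parent - mean(le) * gini(y1[le]) - mean(!le) * gini(y1[!le])
      if (dec > best$decrease + 1e-12)
        best <- list(accession = acc, threshold = thr, decrease = dec)
    }
  }
  best
}

# Brute-force protein acceptance: checks every rule for every protein with
# nested loops over its PSMs.
oracle_accept <- function(psms, policy) {
  out <- character(0)
  for (acc in unique(psms$accession)) {
    rows <- which(psms$accession == acc)
    xc_ok <- logical(0)
    for (i in rows) {
      z <- psms$charge[i]
      cut <- if (z >= 4) policy$xcorr_by_charge[["4plus"]]
             else if (z == 3) policy$xcorr_by_charge[["3"]]
             else policy$xcorr_by_charge[["2"]]
      xc_ok <- c(xc_ok, psms$xcorr[i] >= cut)
    }
    kept <- rows[xc_ok]
    if (length(kept) == 0) next
    if (length(unique(psms$peptide[kept])) >= 2) {
      out <- c(out, acc)
      next
    }
    run_len <- function(ix) {
      if (length(ix) == 0) return(0)
      s <- sort(ix)
      best <- cur <- 1
      for (k in seq_along(s)[-1]) {
        cur <- if (s[k] == s[k - 1] + 1) cur + 1 else 1
        best <- max(best, cur)
      }
      best
    }
    good <- c()
    for (i in kept) {
      if (nchar(psms$peptide[i]) < policy$min_peptide_length) next
      rb <- run_len(psms$b_ions[[i]])
      ry <- run_len(psms$y_ions[[i]])
      ok <- if (policy$consecutive_ion_mode == "either_series")
        max(rb, ry) >= policy$min_consecutive_ions
      else rb >= policy$min_consecutive_ions &&
        ry >= policy$min_consecutive_ions
      if (ok) good <- c(good, i)
    }
    if (length(good) == 0) next
    best_occ <- 0
    for (s in unique(psms$sample_id[good]))
      best_occ <- max(best_occ, sum(psms$sample_id[good] == s))
    if (best_occ >= policy$min_occurrences_per_sample) out <- c(out, acc)
  }
  out
}

# Random PSM instances for the acceptance-oracle property.
random_psm_table <- function(n = 50, seed = 1) {
  set.seed(seed)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  peps <- vapply(1:8, function(i)
    paste(sample(aa, sample(5:10, 1), replace = TRUE), collapse = ""),
    character(1))
  rows <- lapply(seq_len(n), function(i) {
    pep <- sample(peps, 1)
    lim <- nchar(pep) - 1
    list(sample_id = sample(c("S1", "S2", "S3"), 1),
         accession = sample(sprintf("P%d", 1:6), 1),
         peptide = pep,
         charge = sample(1:5, 1),
         xcorr = round(stats::runif(1, 0, 4), 2),
         b = sort(sample(seq_len(lim), sample(0:lim, 1))),
         y = sort(sample(seq_len(lim), sample(0:lim, 1))))
  })
  psms <- data.frame(
    sample_id = vapply(rows, `[[`, character(1), "sample_id"),
    accession = vapply(rows, `[[`, character(1), "accession"),
    peptide = vapply(rows, `[[`, character(1), "peptide"),
    charge = vapply(rows, `[[`, integer(1), "charge"),
    xcorr = vapply(rows, `[[`, numeric(1), "xcorr"),
    stringsAsFactors = FALSE)
  psms$b_ions <- lapply(rows, `[[`, "b")
  psms$y_ions <- lapply(rows, `[[`, "y")
  class(psms) <- c("psm_table", "data.frame")
  psms
}

# Small labelled count matrix builders used in several files.
toy_spc <- function(counts, n_reg, n_per, proteins = NULL) {
  counts <- as.matrix(counts)
  samples <- c(sprintf("R%02d", seq_len(n_reg)),
               sprintf("P%02d", seq_len(n_per)))
  dimnames(counts) <- list(proteins %||% sprintf("PROT%d",
                                                 seq_len(nrow(counts))),
                           samples)
  spc_matrix(counts, group = rep(c("regression", "persistence"),
                                 c(n_reg, n_per)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Offset presence matrix from printed per-group detection counts:
# detected samples get raw count 1 (offset 2), absent 0 (offset 1).
printed_detection_matrix <- function(znf_reg_detected, pld_reg_detected) {
  counts <- matrix(0L, 2, 20,
                   dimnames = list(c("ZNF441", "PLD6"),
                                   c(sprintf("R%02d", 1:10),
                                     sprintf("P%02d", 1:10))))
  counts["ZNF441", seq_len(znf_reg_detected)] <- 1L
  counts["PLD6", seq_len(pld_reg_detected)] <- 1L
  add_offset(spc_matrix(counts,
                        group = rep(c("regression", "persistence"),
                                    each = 10)))
}
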