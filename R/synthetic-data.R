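#' Simulation configuration for synthetic spectral-count data
#'
#' Describes a two-group study with learning/validation halves, a block of
#' background proteins whose presence probability is shared between groups
#' (no class signal), and planted discriminator proteins with group-specific
#' presence probabilities. The defaults mirror the study design this
#' package targets: 20 + 20 samples split 10/10 into learning and
#' validation per group, 163 background proteins plus two planted markers
#' (so the matrix is 165 proteins wide), one strong discriminator present
#' in 95% of regression samples and never in persistence, and one weaker
#' discriminator at 60% versus never.
#'
#' When present, a protein's count in a sample is drawn as
#' \code{1 + NegBin(mu = mean x depth - 1, size = count_dispersion)}, so a
#' present protein is always detected (count >= 1), the configured mean is
#' preserved, and counts are overdispersed (Poisson is recovered as
#' \code{count_dispersion} grows large). Per-sample depth factors are
#' log-normal with \code{sdlog = depth_sigma}.
#'
#' @param n_regression,n_persistence samples per group (split into equal
#'   learning/validation halves).
#' @param n_background_proteins background (null) proteins.
#' @param planted list of planted markers, each a list with
#'   \code{accession}, \code{presence_prob_regression},
#'   \code{presence_prob_persistence}, \code{mean_count_when_present}.
#' @param background_presence_prob shared presence probability of
#'   background proteins.
#' @param background_mean_count mean count of a background protein when
#'   present.
#' @param count_dispersion negative-binomial size parameter (> 0).
#' @param depth_sigma sdlog of the per-sample log-normal depth factor.
#' @param seed RNG seed.
#' @return A \code{sim_config} list.
#' @export
sim_config <- function(n_regression = 20, n_persistence = 20,
                       n_background_proteins = 163,
                       planted = list(
                         list(accession = "PLANTED_ZNF441_LIKE",
                              presence_prob_regression = 0.95,
                              presence_prob_persistence = 0.0,
                              mean_count_when_present = 3),
                         list(accession = "PLANTED_PLD6_LIKE",
                              presence_prob_regression = 0.60,
                              presence_prob_persistence = 0.0,
                              mean_count_when_present = 3)),
                       background_presence_prob = 0.6,
                       background_mean_count = 2,
                       count_dispersion = 2,
                       depth_sigma = 0.3,
                       seed = 1) {
  for (pl in planted) {
    probs <- c(pl$presence_prob_regression, pl$presence_prob_persistence)
    if (any(probs < 0 | probs > 1))
      stop("presence probabilities must be in [0, 1]", call. = FALSE)
    if (pl$mean_count_when_present < 1)
      stop("mean_count_when_present must be >= 1", call. = FALSE)
  }
  if (background_presence_prob < 0 || background_presence_prob > 1)
    stop("background_presence_prob must be in [0, 1]", call. = FALSE)
  if (count_dispersion <= 0) stop("count_dispersion must be > 0",
                                  call. = FALSE)
  if (depth_sigma < 0) stop("depth_sigma must be >= 0", call. = FALSE)
  structure(list(n_regression = as.integer(n_regression),
                 n_persistence = as.integer(n_persistence),
                 n_background_proteins = as.integer(n_background_proteins),
                 planted = planted,
                 background_presence_prob = background_presence_prob,
                 background_mean_count = background_mean_count,
                 count_dispersion = count_dispersion,
                 depth_sigma = depth_sigma,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# present ? 1 + NB(mu - 1) : 0 ; vectorized over mu
draw_counts <- function(present, mu, size) {
  out <- integer(length(present))
  if (any(present)) {
    mu_shift <- pmax(mu[present] - 1, 0)
    out[present] <- 1L + stats::rnbinom(sum(present), size = size,
                                        mu = mu_shift)
  }
  out
}

#' Generate a synthetic spectral-count dataset
#'
#' Draws presence indicators per protein and sample from the group-specific
#' (planted) or shared (background) Bernoulli probabilities, then counts
#' from the shifted negative binomial scaled by each sample's depth factor.
#' Group and learning/validation labels are attached; the result is fully
#' reproducible from \code{cfg$seed}.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return An \code{\link{spc_matrix}} (raw counts, offset not applied);
#'   planted proteins occupy the first rows.
#' @export
generate_spc_dataset <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  n_r <- cfg$n_regression
  n_p <- cfg$n_persistence
  samples <- c(sprintf("REG%02d", seq_len(n_r)),
               sprintf("PER%02d", seq_len(n_p)))
  group <- stats::setNames(rep(GROUP_LEVELS, c(n_r, n_p)), samples)
  half <- function(n) rep(SPLIT_LEVELS, c(ceiling(n / 2), floor(n / 2)))
  split <- stats::setNames(c(half(n_r), half(n_p)), samples)

  n_planted <- length(cfg$planted)
  proteins <- c(vapply(cfg$planted, `[[`, character(1), "accession"),
                sprintf("BG%04d", seq_len(cfg$n_background_proteins)))
  n_prot <- length(proteins)
  n_samp <- length(samples)
  is_reg <- group == "regression"

  counts <- with_seed(cfg$seed, {
    depth <- exp(stats::rnorm(n_samp, 0, cfg$depth_sigma))
    m <- matrix(0L, n_prot, n_samp, dimnames = list(proteins, samples))
    for (i in seq_len(n_prot)) {
      if (i <= n_planted) {
        pl <- cfg$planted[[i]]
        prob <- ifelse(is_reg, pl$presence_prob_regression,
                       pl$presence_prob_persistence)
        mu <- pl$mean_count_when_present * depth
      } else {
        prob <- rep(cfg$background_presence_prob, n_samp)
        mu <- cfg$background_mean_count * depth
      }
      present <- stats::runif(n_samp) < prob
      m[i, ] <- draw_counts(present, mu, cfg$count_dispersion)
    }
    m
  })
  spc_matrix(counts, group = group, split = split)
}

#' Generate a PSM boundary battery with its expected outcome
#'
#' Emits a table of engineered peptide-spectrum matches that probe every
#' acceptance-rule boundary (Xcorr at and just below each charge class's
#' threshold, peptide lengths at and below the minimum, fragment-ion runs
#' at and below the minimum in one or both series, per-sample occurrences
#' at and below the minimum, and multi- versus single-peptide acceptance
#' paths), together with the set of accessions the identification filter
#' must accept. The expectation is computed at generation time by a
#' plain rule-by-rule evaluator over the emitted records, so it responds to
#' the policy actually supplied (e.g. a degenerate all-zero policy accepts
#' every engineered protein).
#'
#' @param policy the \code{\link{filter_policy}} the battery is built
#'   against.
#' @return List with \code{psms} (a \code{psm_table}),
#'   \code{expected_accepted} and \code{expected_rejected} (character
#'   vectors of accessions).
#' @export
generate_psm_table <- function(policy = filter_policy()) {
  thr <- policy$xcorr_by_charge
  len <- max(policy$min_peptide_length, 2L)
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P",
          "Q", "R", "S", "T", "V", "W", "Y")
  pep_of <- function(n, salt = 0) {
    paste(aa[((seq_len(n) + salt - 1) %% 20) + 1], collapse = "")
  }
  run_ions <- function(run, pep_len) {
    if (run == 0) return(integer(0))
    seq_len(min(run, pep_len - 1))
  }
  rows <- list()
  emit <- function(accession, sample_id, peptide, charge, xcorr,
                   b_run, y_run, times = 1) {
    for (k in seq_len(times))
      rows[[length(rows) + 1]] <<- list(
        sample_id = sample_id, accession = accession, peptide = peptide,
        charge = charge, xcorr = xcorr,
        b = run_ions(b_run, nchar(peptide)),
        y = run_ions(y_run, nchar(peptide)))
  }
  good_run <- max(policy$min_consecutive_ions, 1L)
  occ <- max(policy$min_occurrences_per_sample, 1L)

  # Xcorr boundaries, one single-peptide protein per charge class
  xc_cases <- list(list("XC2_PASS", 2L, thr[["2"]]),
                   list("XC2_FAIL", 2L, max(thr[["2"]] - 0.01, 0)),
                   list("XC3_PASS", 3L, thr[["3"]]),
                   list("XC3_FAIL", 3L, max(thr[["3"]] - 0.01, 0)),
                   list("XC4_PASS", 4L, thr[["4plus"]]),
                   list("XC4_FAIL", 4L, max(thr[["4plus"]] - 0.01, 0)),
                   list("XC5_PASS", 5L, thr[["4plus"]]),
                   list("XC1_PASS", 1L, thr[["2"]]))
  for (ci in seq_along(xc_cases)) {
    cs <- xc_cases[[ci]]
    emit(cs[[1]], "S1", pep_of(len + 2, salt = 20 + ci), cs[[2]], cs[[3]],
         good_run, good_run, times = occ)
  }

  # peptide length boundary
  if (policy$min_peptide_length > 1)
    emit("LEN_BELOW", "S1", pep_of(policy$min_peptide_length - 1, 3),
         2L, thr[["2"]] + 1, good_run, good_run, times = occ)
  emit("LEN_AT", "S1", pep_of(max(policy$min_peptide_length, 2), 4),
       2L, thr[["2"]] + 1, good_run, good_run, times = occ)

  # consecutive-ion boundaries
  if (policy$min_consecutive_ions > 1)
    emit("RUN_BELOW", "S1", pep_of(len + 3, 5), 2L, thr[["2"]] + 1,
         policy$min_consecutive_ions - 1, policy$min_consecutive_ions - 1,
         times = occ)
  emit("RUN_B_ONLY", "S1", pep_of(len + 3, 6), 2L, thr[["2"]] + 1,
       good_run, max(good_run - 1, 0), times = occ)
  emit("RUN_BOTH", "S1", pep_of(len + 3, 7), 2L, thr[["2"]] + 1,
       good_run, good_run, times = occ)

  # occurrence boundaries (spread below-threshold counts over two samples)
  if (occ > 1) {
    emit("OCC_BELOW", "S1", pep_of(len + 4, 8), 2L, thr[["2"]] + 1,
         good_run, good_run, times = occ - 1)
    emit("OCC_BELOW", "S2", pep_of(len + 4, 8), 2L, thr[["2"]] + 1,
         good_run, good_run, times = occ - 1)
  }
  emit("OCC_AT", "S2", pep_of(len + 4, 9), 2L, thr[["2"]] + 1,
       good_run, good_run, times = occ)

  # multi-peptide path: two unique peptides, one violating length/run rules
  emit("MULTI_OK", "S1", pep_of(len + 5, 10), 2L, thr[["2"]] + 1,
       good_run, good_run)
  emit("MULTI_OK", "S1",
       pep_of(max(policy$min_peptide_length - 1, 2), 11), 2L,
       thr[["2"]] + 1, max(good_run - 1, 0), 0)
  # two peptides but one fails Xcorr; survivor occurs only once
  emit("MULTI_XCFAIL", "S1", pep_of(len + 6, 12), 2L, thr[["2"]] + 1,
       good_run, good_run)
  emit("MULTI_XCFAIL", "S1", pep_of(len + 6, 13), 2L,
       max(thr[["2"]] - 0.01, 0), good_run, good_run)

  psms <- data.frame(
    sample_id = vapply(rows, `[[`, character(1), "sample_id"),
    accession = vapply(rows, `[[`, character(1), "accession"),
    peptide = vapply(rows, `[[`, character(1), "peptide"),
    charge = vapply(rows, `[[`, integer(1), "charge"),
    xcorr = vapply(rows, `[[`, numeric(1), "xcorr"),
    stringsAsFactors = FALSE
  )
  psms$b_ions <- lapply(rows, `[[`, "b")
  psms$y_ions <- lapply(rows, `[[`, "y")
  class(psms) <- c("psm_table", "data.frame")

  expected <- psm_expectation(psms, policy)
  list(psms = psms,
       expected_accepted = expected,
       expected_rejected = setdiff(unique(psms$accession), expected))
}

# Straight-line reference evaluator of the acceptance rules, written as
# explicit per-protein loops (independent of the set-based implementation
# in accept_proteins); used to stamp the battery with its expected outcome.
psm_expectation <- function(psms, policy) {
  thr <- policy$xcorr_by_charge
  accepted <- character(0)
  for (acc in unique(psms$accession)) {
    rows <- which(psms$accession == acc)
    pass_xc <- c()
    for (i in rows) {
      z <- psms$charge[i]
      cutoff <- if (z >= 4) thr[["4plus"]] else if (z == 3) thr[["3"]] else
        thr[["2"]]
      if (psms$xcorr[i] >= cutoff) pass_xc <- c(pass_xc, i)
    }
    if (length(pass_xc) == 0) next
    if (length(unique(psms$peptide[pass_xc])) >= 2) {
      accepted <- c(accepted, acc)
      next
    }
    ok <- c()
    for (i in pass_xc) {
      if (nchar(psms$peptide[i]) < policy$min_peptide_length) next
      rb <- longest_consecutive_run(psms$b_ions[[i]])
      ry <- longest_consecutive_run(psms$y_ions[[i]])
      run <- if (policy$consecutive_ion_mode == "either_series")
        max(rb, ry) else min(rb, ry)
      if (run < policy$min_consecutive_ions) next
      ok <- c(ok, i)
    }
    if (length(ok) == 0) next
    counts <- table(psms$sample_id[ok])
    if (max(counts) >= policy$min_occurrences_per_sample)
      accepted <- c(accepted, acc)
  }
  accepted
}
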