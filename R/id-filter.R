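#' Peptide/protein acceptance policy
#'
#' Bundles the thresholds of the multistep identification filter:
#' charge-dependent Xcorr gates (the "high significance" SEQUEST filter),
#' minimum peptide length, minimum run of consecutive matched fragment ions,
#' minimum per-sample occurrence of a peptide, and the minimum fraction of
#' samples of at least one group in which a protein must be detected.
#'
#' All thresholds are inclusive (\dQuote{at least}). Charge-1 PSMs are gated
#' at the charge-2 Xcorr threshold (a defensive choice: data-dependent MS/MS
#' acquisition selects z >= 2 precursors, so this path is rarely exercised);
#' charge >= 4 uses the \code{"4plus"} threshold.
#'
#' @param xcorr_by_charge named numeric vector with entries \code{"2"},
#'   \code{"3"}, \code{"4plus"}.
#' @param min_peptide_length minimum amino acids in an accepted peptide.
#' @param min_consecutive_ions minimum run of consecutive matched b- or
#'   y-ion indices.
#' @param min_occurrences_per_sample minimum number of times a peptide must
#'   occur in one sample.
#' @param min_group_presence_fraction fraction in (0, 1] of one group's
#'   samples in which a protein must be detected.
#' @param consecutive_ion_mode \code{"either_series"} (the run may be in the
#'   b- or the y-series) or \code{"both_series"} (required in both).
#' @return A \code{filter_policy} list.
#' @export
filter_policy <- function(xcorr_by_charge = c("2" = 1.9, "3" = 2.3,
                                              "4plus" = 2.6),
                          min_peptide_length = 7L,
                          min_consecutive_ions = 3L,
                          min_occurrences_per_sample = 3L,
                          min_group_presence_fraction = 0.30,
                          consecutive_ion_mode = c("either_series",
                                                   "both_series")) {
  consecutive_ion_mode <- match.arg(consecutive_ion_mode)
  need <- c("2", "3", "4plus")
  if (!all(need %in% names(xcorr_by_charge)))
    stop("xcorr_by_charge needs entries named: ",
         paste(need, collapse = ", "), call. = FALSE)
  if (any(xcorr_by_charge < 0)) stop("Xcorr thresholds must be nonnegative",
                                     call. = FALSE)
  if (min_group_presence_fraction <= 0 || min_group_presence_fraction > 1)
    stop("min_group_presence_fraction must be in (0, 1]", call. = FALSE)
  structure(list(xcorr_by_charge = xcorr_by_charge[need],
                 min_peptide_length = as.integer(min_peptide_length),
                 min_consecutive_ions = as.integer(min_consecutive_ions),
                 min_occurrences_per_sample =
                   as.integer(min_occurrences_per_sample),
                 min_group_presence_fraction = min_group_presence_fraction,
                 consecutive_ion_mode = consecutive_ion_mode),
            class = "filter_policy")
}

#' Charge-dependent Xcorr gate
#'
#' @param charge integer vector of PSM charge states (>= 1).
#' @param xcorr numeric vector of SEQUEST cross-correlation scores.
#' @param policy a \code{\link{filter_policy}}.
#' @return Logical vector: does each PSM meet its charge class's Xcorr
#'   threshold (inclusive)?
#' @export
passes_xcorr <- function(charge, xcorr, policy = filter_policy()) {
  if (any(charge < 1)) stop("charge must be >= 1", call. = FALSE)
  thr <- policy$xcorr_by_charge
  cutoff <- ifelse(charge >= 4, thr[["4plus"]],
                   ifelse(charge == 3, thr[["3"]], thr[["2"]]))
  xcorr >= cutoff
}

#' Longest run of consecutive integers
#'
#' Length of the longest run of consecutive values in a set of matched
#' fragment-ion indices; 0 for an empty set.
#'
#' @param indices integer vector of distinct positive indices (any order).
#' @return Integer run length.
#' @examples
#' longest_consecutive_run(c(2, 4, 5, 6, 9, 10))  # 3
#' @export
longest_consecutive_run <- function(indices) {
  if (length(indices) == 0) return(0L)
  s <- sort(unique(as.integer(indices)))
  if (length(s) == 1) return(1L)
  breaks <- c(0L, which(diff(s) != 1L), length(s))
  max(diff(breaks))
}

ion_run_ok <- function(b_ions, y_ions, policy) {
  need <- policy$min_consecutive_ions
  rb <- longest_consecutive_run(b_ions)
  ry <- longest_consecutive_run(y_ions)
  if (policy$consecutive_ion_mode == "either_series") max(rb, ry) >= need
  else rb >= need && ry >= need
}

#' Filter PSMs by the identification rules
#'
#' Applies the acceptance rules to a PSM table. With
#' \code{strict_paper_mode = TRUE} (the default) only the Xcorr gate is
#' applied here, because the length / consecutive-ion / occurrence rules
#' belong to single-peptide protein acceptance and are enforced in
#' \code{\link{accept_proteins}}. With \code{strict_paper_mode = FALSE} all
#' rules are applied to every PSM, in the order Xcorr, length, ion run,
#' per-sample occurrence; a PSM is charged to the first rule it fails, and
#' the occurrence rule counts only PSMs that survived the earlier rules.
#'
#' @param psms a \code{psm_table} from \code{\link{read_psm_table}} (or any
#'   data frame with the same columns).
#' @param policy a \code{\link{filter_policy}}.
#' @param strict_paper_mode see Description.
#' @return List with \code{kept} (the surviving rows, order preserved) and
#'   \code{audit}, a named integer vector of per-rule rejection counts plus
#'   \code{kept}; the audit always sums to \code{nrow(psms)}.
#' @export
filter_psms <- function(psms, policy = filter_policy(),
                        strict_paper_mode = TRUE) {
  n <- nrow(psms)
  audit <- c(xcorr = 0L, length = 0L, ion_run = 0L, occurrence = 0L,
             kept = 0L)
  if (n == 0)
    return(list(kept = psms, audit = audit))

  ok <- passes_xcorr(psms$charge, psms$xcorr, policy)
  audit[["xcorr"]] <- sum(!ok)
  if (!strict_paper_mode) {
    len_ok <- nchar(psms$peptide) >= policy$min_peptide_length
    fail_len <- ok & !len_ok
    audit[["length"]] <- sum(fail_len)
    ok <- ok & len_ok
    run_ok <- vapply(seq_len(n), function(i)
      ion_run_ok(psms$b_ions[[i]], psms$y_ions[[i]], policy), logical(1))
    audit[["ion_run"]] <- sum(ok & !run_ok)
    ok <- ok & run_ok
    key <- paste(psms$sample_id, psms$peptide, sep = "\r")
    occ <- stats::ave(as.integer(ok), key, FUN = sum)
    occ_ok <- occ >= policy$min_occurrences_per_sample
    audit[["occurrence"]] <- sum(ok & !occ_ok)
    ok <- ok & occ_ok
  }
  audit[["kept"]] <- sum(ok)
  kept <- psms[ok, , drop = FALSE]
  attr(kept, "rejections") <- NULL
  list(kept = kept, audit = audit)
}

#' Accept proteins from Xcorr-passing PSMs
#'
#' Implements the two acceptance paths: a protein identified by two or more
#' unique peptide sequences is accepted on the Xcorr gate alone; a protein
#' identified by a single unique peptide is accepted only when that peptide
#' (i) has at least \code{min_peptide_length} amino acids, (ii) has a run of
#' at least \code{min_consecutive_ions} consecutive matched fragment ions in
#' a PSM, and (iii) such rule-passing PSMs occur at least
#' \code{min_occurrences_per_sample} times in at least one sample. The
#' spectral count per sample is the number of Xcorr-passing PSMs mapped to
#' the accession.
#'
#' Single-peptide identifications would additionally be confirmed by a
#' sequence-database (BLAST) lookup in a full workflow; this package records
#' them with \code{single_peptide_flag = TRUE} as pending that external
#' annotation rather than performing it.
#'
#' @param psms_kept PSMs that already passed the Xcorr gate
#'   (\code{\link{filter_psms}}).
#' @param policy a \code{\link{filter_policy}}.
#' @param strict_paper_mode if \code{FALSE}, \code{psms_kept} is assumed
#'   fully filtered (all rules applied globally) and every protein with at
#'   least one remaining peptide is accepted.
#' @return An \code{accepted_proteins} data frame with columns
#'   \code{accession}, \code{single_peptide_flag}, list-columns
#'   \code{unique_peptides} and \code{spc_by_sample} (named integer
#'   vectors).
#' @export
accept_proteins <- function(psms_kept, policy = filter_policy(),
                            strict_paper_mode = TRUE) {
  empty <- data.frame(accession = character(0),
                      single_peptide_flag = logical(0),
                      stringsAsFactors = FALSE)
  empty$unique_peptides <- list()
  empty$spc_by_sample <- list()
  class(empty) <- c("accepted_proteins", "data.frame")
  if (nrow(psms_kept) == 0) return(empty)

  acc_list <- split(seq_len(nrow(psms_kept)), psms_kept$accession)
  rows <- lapply(names(acc_list), function(acc) {
    idx <- acc_list[[acc]]
    peps <- unique(psms_kept$peptide[idx])
    if (length(peps) == 1 && strict_paper_mode) {
      pass <- idx[nchar(psms_kept$peptide[idx]) >= policy$min_peptide_length]
      pass <- pass[vapply(pass, function(i)
        ion_run_ok(psms_kept$b_ions[[i]], psms_kept$y_ions[[i]], policy),
        logical(1))]
      if (length(pass) == 0) return(NULL)
      per_sample <- table(psms_kept$sample_id[pass])
      if (max(per_sample) < policy$min_occurrences_per_sample) return(NULL)
    }
    spc <- table(psms_kept$sample_id[idx])
    list(accession = acc, peps = peps,
         spc = stats::setNames(as.integer(spc), names(spc)))
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0) return(empty)

  out <- data.frame(
    accession = vapply(rows, `[[`, character(1), "accession"),
    single_peptide_flag = vapply(rows, function(r) length(r$peps) == 1,
                                 logical(1)),
    stringsAsFactors = FALSE
  )
  out$unique_peptides <- lapply(rows, `[[`, "peps")
  out$spc_by_sample <- lapply(rows, `[[`, "spc")
  class(out) <- c("accepted_proteins", "data.frame")
  out
}

#' Keep proteins detected in enough samples of one group
#'
#' Retains proteins detected (count >= 1) in at least
#' \code{ceiling(min_group_presence_fraction x group size)} samples of at
#' least one group. Group sizes come from the label map, so samples with no
#' detections still count toward the denominator.
#'
#' @param x an \code{accepted_proteins} data frame or an
#'   \code{\link{spc_matrix}} (raw counts, before the offset).
#' @param labels named vector mapping sample ids to groups; defaults to the
#'   matrix's own labels when \code{x} is an \code{spc_matrix}.
#' @param policy a \code{\link{filter_policy}}.
#' @return The filtered object of the same class.
#' @export
group_presence_filter <- function(x, labels = NULL,
                                  policy = filter_policy()) {
  UseMethod("group_presence_filter")
}

#' @export
group_presence_filter.spc_matrix <- function(x, labels = NULL,
                                             policy = filter_policy()) {
  if (x$offset_applied)
    stop("presence is defined on raw counts; filter before add_offset()",
         call. = FALSE)
  if (is.null(labels)) labels <- x$group
  keep <- presence_keep(x$counts >= 1, labels, policy)
  x$counts <- x$counts[keep, , drop = FALSE]
  x
}

#' @export
group_presence_filter.accepted_proteins <- function(x, labels = NULL,
                                                    policy = filter_policy()) {
  if (is.null(labels))
    stop("labels (sample id -> group) are required", call. = FALSE)
  samples <- names(labels)
  det <- t(vapply(x$spc_by_sample, function(spc) {
    v <- stats::setNames(rep(FALSE, length(samples)), samples)
    unlabeled <- setdiff(names(spc), samples)
    if (length(unlabeled) > 0)
      stop("sample(s) with counts but no group label: ",
           paste(unlabeled, collapse = ", "), call. = FALSE)
    v[names(spc)] <- spc >= 1
    v
  }, logical(length(samples))))
  x[presence_keep(det, labels, policy), , drop = FALSE]
}

presence_keep <- function(detected, labels, policy) {
  labels <- check_group(labels[colnames(detected) %||% names(labels)])
  frac <- policy$min_group_presence_fraction
  keep <- rep(FALSE, nrow(detected))
  for (g in GROUP_LEVELS) {
    idx <- which(labels == g)
    if (length(idx) == 0) next
    need <- ceil_frac(frac, length(idx))
    keep <- keep | rowSums(detected[, idx, drop = FALSE]) >= need
  }
  keep
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Spectral-count matrix from accepted proteins
#'
#' @param accepted an \code{accepted_proteins} data frame.
#' @param group named vector of group labels (names are the sample ids and
#'   define the sample set and order).
#' @param split optional named split labels.
#' @return An \code{\link{spc_matrix}} with zero counts where a protein was
#'   not observed in a sample.
#' @export
spc_from_accepted <- function(accepted, group, split = NULL) {
  samples <- names(group)
  if (is.null(samples)) stop("group must be a named vector", call. = FALSE)
  counts <- matrix(0L, nrow(accepted), length(samples),
                   dimnames = list(accepted$accession, samples))
  for (i in seq_len(nrow(accepted))) {
    spc <- accepted$spc_by_sample[[i]]
    known <- intersect(names(spc), samples)
    counts[i, known] <- spc[known]
  }
  spc_matrix(counts, group = group, split = split)
}
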