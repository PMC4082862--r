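make_psms <- function(...) {
  rows <- list(...)
  psms <- data.frame(
    sample_id = vapply(rows, `[[`, character(1), 1),
    accession = vapply(rows, `[[`, character(1), 2),
    peptide = vapply(rows, `[[`, character(1), 3),
    charge = vapply(rows, function(r) as.integer(r[[4]]), integer(1)),
    xcorr = vapply(rows, function(r) as.numeric(r[[5]]), numeric(1)),
    stringsAsFactors = FALSE)
  psms$b_ions <- lapply(rows, function(r) as.integer(r[[6]]))
  psms$y_ions <- lapply(rows, function(r) as.integer(r[[7]]))
  class(psms) <- c("psm_table", "data.frame")
  psms
}

test_that("Xcorr gate is inclusive and charge-class dependent", {
  pol <- filter_policy()
  expect_true(passes_xcorr(2L, 1.9, pol))    # inclusive boundary
  expect_false(passes_xcorr(2L, 1.89, pol))
  expect_false(passes_xcorr(3L, 2.29, pol))  # just below z = 3 threshold
  expect_true(passes_xcorr(3L, 2.3, pol))
  expect_true(passes_xcorr(5L, 2.6, pol))    # z >= 4 class
  expect_false(passes_xcorr(4L, 2.59, pol))
  expect_true(passes_xcorr(1L, 1.9, pol))    # z = 1 gated as z = 2
  expect_error(passes_xcorr(0L, 3, pol), "charge")
})

test_that("longest consecutive run matches brute-force enumeration", {
  expect_equal(longest_consecutive_run(c(1, 2, 3, 7)), 3L)
  expect_equal(longest_consecutive_run(integer(0)), 0L)
  expect_equal(longest_consecutive_run(5), 1L)
  # brute-force scan over all runs for random index sets
  brute <- function(ix) {
    if (length(ix) == 0) return(0L)
    best <- 0L
    for (start in ix) {
      len <- 0L
      while ((start + len) %in% ix) len <- len + 1L
      best <- max(best, len)
    }
    best
  }
  set.seed(4)
  for (i in 1:25) {
    ix <- sample(1:15, sample(0:10, 1))
    expect_equal(longest_consecutive_run(ix), brute(ix))
  }
  expect_equal(longest_consecutive_run(c(2, 4, 5, 6, 9, 10)),
               brute(c(2, 4, 5, 6, 9, 10)))
})

test_that("filter_psms applies the occurrence rule to (sample, peptide) pairs", {
  # 6 PSMs, all passing Xcorr/length/runs; peptide A occurs 3x in S1
  # (kept), peptide B occurs 2x in S1 (removed by the occurrence rule),
  # peptide A once in S2 (removed).
  psms <- make_psms(
    list("S1", "P1", "ACDEFGHIK", 2, 2.5, 1:3, 4:6),
    list("S1", "P1", "ACDEFGHIK", 2, 2.6, 1:3, 4:6),
    list("S1", "P1", "ACDEFGHIK", 2, 2.7, 1:3, 4:6),
    list("S1", "P2", "LMNPQRSTV", 2, 2.5, 1:3, 4:6),
    list("S1", "P2", "LMNPQRSTV", 2, 2.5, 1:3, 4:6),
    list("S2", "P1", "ACDEFGHIK", 2, 2.5, 1:3, 4:6))
  res <- filter_psms(psms, strict_paper_mode = FALSE)
  expect_equal(nrow(res$kept), 3)
  expect_true(all(res$kept$peptide == "ACDEFGHIK" &
                    res$kept$sample_id == "S1"))
  expect_equal(res$audit[["occurrence"]], 3L)
  expect_equal(sum(res$audit), 6L)  # per-rule rejections + kept = n

  # length rule rejects a 6-mer with perfect ion series
  short <- make_psms(list("S1", "P1", "ACDEFG", 2, 3.5, 1:5, 1:5))
  res2 <- filter_psms(short, strict_paper_mode = FALSE)
  expect_equal(res2$audit[["length"]], 1L)
  expect_equal(nrow(res2$kept), 0)

  # strict mode applies only the Xcorr gate here
  res3 <- filter_psms(short, strict_paper_mode = TRUE)
  expect_equal(nrow(res3$kept), 1)

  empty <- filter_psms(make_psms()[0, ], strict_paper_mode = FALSE)
  expect_equal(nrow(empty$kept), 0)
  expect_true(all(empty$audit == 0))
})

test_that("audit conservation holds on random PSM instances", {
  for (seed in 1:5) {
    psms <- random_psm_table(50, seed)
    for (strict in c(TRUE, FALSE)) {
      res <- filter_psms(psms, strict_paper_mode = strict)
      rejected <- sum(res$audit[names(res$audit) != "kept"])
      expect_equal(rejected + res$audit[["kept"]], nrow(psms))
      expect_equal(res$audit[["kept"]], nrow(res$kept))
    }
  }
})

test_that("acceptance paths: multi-peptide on Xcorr alone, single-peptide under full rules", {
  # protein with 2 unique passing peptides, one of length 6 -> accepted
  multi <- make_psms(
    list("S1", "P1", "ACDEFGHIK", 2, 2.5, 1:3, 4:6),
    list("S1", "P1", "ACDEFG", 2, 2.5, 1:2, integer(0)))
  acc <- accept_proteins(multi)
  expect_equal(acc$accession, "P1")
  expect_false(acc$single_peptide_flag)
  expect_equal(acc$spc_by_sample[[1]], c(S1 = 2L))

  # single peptide occurring twice in every sample -> rejected
  twice <- make_psms(
    list("S1", "P2", "LMNPQRSTV", 2, 2.5, 1:3, 4:6),
    list("S1", "P2", "LMNPQRSTV", 2, 2.5, 1:3, 4:6),
    list("S2", "P2", "LMNPQRSTV", 2, 2.5, 1:3, 4:6),
    list("S2", "P2", "LMNPQRSTV", 2, 2.5, 1:3, 4:6))
  expect_equal(nrow(accept_proteins(twice)), 0)

  # three times in one sample -> accepted, flagged single-peptide
  thrice <- make_psms(
    list("S1", "P3", "LMNPQRSTV", 2, 2.5, 1:3, 4:6),
    list("S1", "P3", "LMNPQRSTV", 2, 2.5, 1:3, 4:6),
    list("S1", "P3", "LMNPQRSTV", 2, 2.5, 1:3, 4:6))
  acc3 <- accept_proteins(thrice)
  expect_true(acc3$single_peptide_flag)
  expect_equal(acc3$spc_by_sample[[1]], c(S1 = 3L))

  expect_equal(nrow(accept_proteins(make_psms()[0, ])), 0)
})

test_that("accept_proteins agrees with the brute-force rule evaluator on random instances", {
  pol_variants <- list(
    filter_policy(),
    filter_policy(consecutive_ion_mode = "both_series"),
    filter_policy(xcorr_by_charge = c("2" = 1, "3" = 1.5, "4plus" = 2),
                  min_peptide_length = 6, min_occurrences_per_sample = 2))
  for (seed in 1:8) {
    psms <- random_psm_table(50, seed)
    for (pol in pol_variants) {
      kept <- filter_psms(psms, pol)$kept
      got <- accept_proteins(kept, pol)$accession
      expect_setequal(got, oracle_accept(psms, pol))
    }
  }
})

test_that("raising any threshold never increases kept PSMs or accepted proteins", {
  base <- filter_policy()
  stricter <- list(
    filter_policy(xcorr_by_charge = c("2" = 2.4, "3" = 2.8, "4plus" = 3.1)),
    filter_policy(min_peptide_length = 9),
    filter_policy(min_consecutive_ions = 4),
    filter_policy(min_occurrences_per_sample = 4),
    filter_policy(consecutive_ion_mode = "both_series"))
  for (seed in 1:4) {
    psms <- random_psm_table(60, seed)
    n_base_psm <- nrow(filter_psms(psms, base, FALSE)$kept)
    n_base_acc <- nrow(accept_proteins(filter_psms(psms, base)$kept, base))
    for (pol in stricter) {
      expect_lte(nrow(filter_psms(psms, pol, FALSE)$kept), n_base_psm)
      expect_lte(nrow(accept_proteins(filter_psms(psms, pol)$kept, pol)),
                 n_base_acc)
    }
  }
})

test_that("group-presence rule keeps proteins reaching 30% of either group", {
  counts <- rbind(
    IN3OF10 = c(rep(1, 3), rep(0, 7), rep(0, 10)),  # 3/10 regression
    IN2BOTH = c(rep(1, 2), rep(0, 8), rep(1, 2), rep(0, 8)),
    EVERYWHERE = rep(1, 20))
  m <- toy_spc(counts, 10, 10, proteins = rownames(counts))
  kept <- group_presence_filter(m)
  expect_setequal(rownames(kept$counts), c("IN3OF10", "EVERYWHERE"))

  # presence fraction 1.0: only the ubiquitous protein survives
  all_pol <- filter_policy(min_group_presence_fraction = 1.0)
  expect_equal(rownames(group_presence_filter(m, policy = all_pol)$counts),
               "EVERYWHERE")

  # works identically on accepted_proteins
  acc <- accept_proteins(make_psms(
    list("S1", "P1", "ACDEFGHIK", 2, 2.5, 1:3, 4:6),
    list("S1", "P1", "LMNPQRSTV", 2, 2.5, 1:3, 4:6)))
  labels <- setNames(rep(c("regression", "persistence"), each = 2),
                     c("S1", "S2", "S3", "S4"))
  expect_equal(nrow(group_presence_filter(acc, labels)), 1)
  bad <- setNames("persistence", "S9")
  expect_error(group_presence_filter(acc, bad), "S1")
})
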