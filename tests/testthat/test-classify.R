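test_that("the ROC stump on offset detection counts reproduces the <=1 vs >1 rule", {
  m <- printed_detection_matrix(10, 7)
  rule <- roc_threshold(m$counts["ZNF441", ], m$group,
                        accession = "ZNF441")
  expect_false(rule$uninformative)
  # any threshold in [1, 2) is the same rule on integer counts
  expect_true(rule$threshold >= 1 && rule$threshold < 2)
  expect_equal(rule$direction, "gt_is_regression")
  pred <- rule_applied <- apply_rules(rule, m)
  manual <- ifelse(m$counts["ZNF441", ] <= 1, "persistence", "regression")
  expect_equal(unname(pred$predictions), unname(manual))
})

test_that("constant values yield an uninformative rule", {
  y <- rep(c("regression", "persistence"), each = 5)
  r <- roc_threshold(rep(3, 10), y)
  expect_true(r$uninformative)
  expect_equal(r$youden_j, 0)
})

test_that("Youden's J matches exhaustive enumeration and pROC on random instances", {
  for (seed in 1:8) {
    set.seed(seed)
    y <- sample(rep(c("regression", "persistence"), 10))
    v <- round(rnorm(20), 1)
    rule <- roc_threshold(v, y)
    expect_equal(rule$youden_j, oracle_best_youden(v, y == "regression"),
                 tolerance = 1e-12)
  }
  # independent library check on one instance with a clear optimum
  set.seed(99)
  y <- rep(c("regression", "persistence"), each = 10)
  v <- c(rnorm(10, 2), rnorm(10, 0))
  rule <- roc_threshold(v, y)
  roc <- pROC::roc(response = y, predictor = v,
                   levels = c("persistence", "regression"), quiet = TRUE)
  best <- pROC::coords(roc, "best", best.method = "youden",
                       ret = c("sensitivity", "specificity"))
  expect_equal(rule$youden_j, best$sensitivity + best$specificity - 1,
               tolerance = 1e-12)
})

test_that("printed detection patterns classify 20/20 learning and 19/20 validation", {
  learn <- printed_detection_matrix(10, 7)
  rule <- roc_threshold(learn$counts["ZNF441", ], learn$group, "ZNF441")
  res_l <- apply_rules(rule, learn)
  expect_equal(res_l$correct_total, 20)

  valid <- printed_detection_matrix(9, 5)
  res_v <- apply_rules(rule, valid)
  expect_equal(res_v$correct_total, 19)
  expect_equal(unname(res_v$correct_by_group["regression"]), 9)
  expect_equal(unname(res_v$correct_by_group["persistence"]), 10)
  expect_equal(sum(res_v$confusion), 20)

  # protein absent everywhere: every sample called persistence
  absent <- printed_detection_matrix(0, 0)
  res_a <- apply_rules(rule, absent)
  expect_true(all(res_a$predictions == "persistence"))
  expect_error(apply_rules(
    roc_threshold(learn$counts["ZNF441", ], learn$group, "NOPE"), learn),
    "NOPE")
})

test_that("tree root and competitor ranking follow the planted structure", {
  set.seed(17)
  y <- rep(c("regression", "persistence"), each = 10)
  perfect <- ifelse(y == "regression", 3, 1)
  partial <- c(rep(3, 6), rep(1, 4), rep(1, 10))  # 6/10 regression only
  noise <- matrix(rpois(3 * 20, 2), 3)
  m <- toy_spc(rbind(PERFECT = perfect, PARTIAL = partial, noise), 10, 10,
               proteins = c("PERFECT", "PARTIAL", "N1", "N2", "N3"))
  tree <- fit_two_node_tree(m)
  expect_equal(tree$root$accession, "PERFECT")
  expect_equal(tree$competitor_ranking$accession[2], "PARTIAL")
  res <- apply_rules(tree, m)
  expect_equal(res$correct_total, 20)
})

test_that("tree root equals exhaustive split search on small random instances", {
  for (seed in 1:10) {
    set.seed(seed)
    n_p <- sample(3:8, 1)
    y <- sample(rep(c("regression", "persistence"), 10))
    counts <- matrix(rpois(n_p * 20, 2), n_p)
    m <- toy_spc(counts, 10, 10)
    m$group <- factor(y, levels = c("regression", "persistence"))
    names(m$group) <- colnames(m$counts)
    tree <- fit_two_node_tree(m)
    ora <- oracle_tree_root(m$counts, y == "persistence")
    if (is.null(tree$root)) {
      expect_true(!is.finite(ora$decrease) || ora$decrease <= 1e-12)
    } else {
      expect_equal(tree$root$decrease, ora$decrease, tolerance = 1e-10)
      expect_equal(tree$root$accession, ora$accession)
      expect_equal(tree$root$threshold, ora$threshold)
    }
  }
})

test_that("tree degeneracies: pure input and exact duplicate separators", {
  m <- toy_spc(matrix(rpois(8, 2), 2, 4), 4, 0)
  m$group <- factor(rep("regression", 4),
                    levels = c("regression", "persistence"))
  names(m$group) <- colnames(m$counts)
  tree <- fit_two_node_tree(m)
  expect_true(tree$degenerate)
  expect_null(tree$root)

  y <- rep(c("regression", "persistence"), each = 5)
  v <- ifelse(y == "regression", 4, 1)
  m2 <- toy_spc(rbind(v, v), 5, 5, proteins = c("AAA", "BBB"))
  tree2 <- fit_two_node_tree(m2)
  expect_equal(tree2$root$accession, "AAA")  # lexicographic tie-break
})

test_that("rpart agrees with the root split on a clear-signal instance", {
  set.seed(71)
  y <- rep(c("regression", "persistence"), each = 10)
  X <- rbind(GOOD = ifelse(y == "regression", 5, 1) + rpois(20, 1),
             MED = rpois(20, 3) + 2 * (y == "persistence"),
             JUNK = rpois(20, 3))
  m <- toy_spc(X, 10, 10, proteins = rownames(X))
  tree <- fit_two_node_tree(m)
  rp <- rpart::rpart(y ~ ., data = data.frame(t(m$counts), y = factor(y)),
                     method = "class",
                     control = rpart::rpart.control(maxdepth = 1,
                                                    minsplit = 2, cp = 0))
  expect_equal(tree$root$accession,
               as.character(rp$frame$var[1]))
})

test_that("logistic ranking: separation tops the list, constants score zero", {
  y <- rep(c("regression", "persistence"), each = 8)
  set.seed(23)
  m <- toy_spc(rbind(SEP = ifelse(y == "persistence", 6, 1),
                     WEAK = rpois(16, 2) + (y == "persistence"),
                     CONST = rep(2, 16)), 8, 8,
               proteins = c("SEP", "WEAK", "CONST"))
  lr <- logistic_rank(m)
  expect_equal(lr$accession[1], "SEP")
  expect_true(lr$separation[1])
  expect_equal(lr$lr_stat[lr$accession == "CONST"], 0)
  expect_false(any(lr$separation[-1]))
})

test_that("a planted discriminator outranks a permuted null in nearly all replicates", {
  wins <- 0
  for (seed in 1:100) {
    set.seed(seed)
    y <- rep(c("regression", "persistence"), each = 8)
    planted <- rpois(16, 2) + 3 * (y == "persistence")
    null_var <- sample(planted)  # same values, label link destroyed
    m <- toy_spc(rbind(PLANTED = planted, NULLV = null_var), 8, 8,
                 proteins = c("PLANTED", "NULLV"))
    lr <- logistic_rank(m)
    if (lr$lr_stat[lr$accession == "PLANTED"] >
          lr$lr_stat[lr$accession == "NULLV"]) wins <- wins + 1
  }
  expect_gte(wins, 95)
})
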