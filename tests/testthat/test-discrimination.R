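# O(n^2) concordant-pair oracle for the AUC
.auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  cmp <- outer(pos, neg, FUN = function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

test_that("rank-based AUC equals the pair-counting oracle exactly", {
  set.seed(101)
  for (rep in 1:200) {
    n <- sample(6:40, 1)
    scores <- sample(round(rnorm(n), sample(0:2, 1)))  # induce ties
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(labels) || all(labels)) labels[1:2] <- c(TRUE, FALSE)
    expect_identical(roc_auc(scores, labels)$auc,
                     .auc_bruteforce(scores, labels))
  }
})

test_that("AUC hits the separation and null anchors", {
  expect_equal(roc_auc(c(5, 6, 7, 1, 2, 3),
                       c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))$auc, 1)
  set.seed(7)
  sc <- rnorm(4000)
  lab <- rep(c(TRUE, FALSE), 2000)
  expect_equal(roc_auc(sc, lab)$auc, 0.5, tolerance = 0.03)
  expect_error(roc_auc(1:5, rep(TRUE, 5)), "non-empty")
})

test_that("AUC is invariant under monotone transforms and flips with labels", {
  set.seed(11)
  sc <- rnorm(50); lab <- sample(c(TRUE, FALSE), 50, replace = TRUE,
                                 prob = c(.4, .6))
  a <- roc_auc(sc, lab)$auc
  expect_equal(roc_auc(exp(sc), lab)$auc, a)
  expect_equal(roc_auc(rank(sc), lab)$auc, a)
  expect_equal(roc_auc(sc, !lab)$auc, 1 - a)
})

test_that("chi-square significance behaves at its anchors and is monotone", {
  r <- roc_auc(c(1, 2, 1, 2), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$auc, 0.5)
  s <- auc_significance(r)
  expect_equal(s$chi_square, 0)
  expect_equal(s$p_value, 1)

  # chi-square strictly increases in A on [0.5, 1) at fixed n
  chis <- vapply(seq(0.5, 0.99, by = 0.01), function(A)
    auc_significance(list(auc = A, n_in = 20L, n_out = 20L))$chi_square, 0)
  expect_true(all(diff(chis) > 0))

  # single-member class flagged degenerate
  expect_true(auc_significance(list(auc = 0.8, n_in = 1L,
                                    n_out = 10L))$degenerate)
})

test_that("one-vs-rest scan ranks components and skips small groups", {
  set.seed(19)
  n <- 40
  groups <- rep(c("A", "B"), each = n / 2)
  scores <- cbind(PC1 = rnorm(n) + 3 * (groups == "A"), PC2 = rnorm(n))
  out <- one_vs_rest_scan(scores, groups, components = 1:2, alpha = 0.001,
                          min_n = 5)
  expect_equal(nrow(out), 4L)
  a1 <- out$auc[out$group == "A" & out$component == 1]
  expect_gt(a1, 0.9)
  expect_equal(out$rank_in_group[out$group == "A" & out$component == 1], 1L)
  expect_true(out$significant[out$group == "A" & out$component == 1])
  # complement symmetry: B's AUC on PC1 is 1 - A's
  expect_equal(out$auc[out$group == "B" & out$component == 1], 1 - a1,
               tolerance = 1e-12)

  groups2 <- c(rep("A", 36), rep("tiny", 4))
  expect_message(
    out2 <- one_vs_rest_scan(scores, groups2, components = 1:2, min_n = 5),
    "tiny")
  expect_false("tiny" %in% out2$group)
  expect_equal(attr(out2, "skipped_groups"), "tiny")
})

test_that("AUC agrees with an independent ROC implementation", {
  set.seed(23)
  for (rep in 1:20) {
    sc <- rnorm(60) + rep(c(0.8, 0), c(25, 35))
    lab <- rep(c(1, 0), c(25, 35))
    ref <- suppressMessages(as.numeric(pROC::auc(lab, sc,
                                                 direction = "<")))
    expect_equal(roc_auc(sc, lab == 1)$auc, ref, tolerance = 1e-12)
  }
})

test_that("representative selection matches the brute-force distances", {
  set.seed(29)
  X <- matrix(rnorm(15, 10, 3), 5, 3,
              dimnames = list(paste0("s", 1:5), NULL))
  pops <- c("P", "P", "P", "Q", "Q")
  out <- select_representatives(X, pops, k = 2)
  # exhaustive oracle for population P
  muP <- colMeans(X[1:3, ])
  dP <- sqrt(colSums((t(X[1:3, ]) - muP)^2))
  expect_equal(out$specimen_id[out$population == "P"],
               names(sort(dP))[1:2])
  expect_equal(sort(out$distance[out$population == "P"]),
               unname(sort(dP)[1:2]), tolerance = 1e-12)

  # a specimen equal to the population mean ranks first with distance 0
  X2 <- rbind(X, mean_spec = colMeans(X[4:5, ]))
  pops2 <- c(pops, "Q")
  out2 <- select_representatives(X2, pops2, k = 1)
  expect_equal(out2$specimen_id[out2$population == "Q"], "mean_spec")
  expect_equal(out2$distance[out2$population == "Q"], 0, tolerance = 1e-9)

  # duplicated rows tie-break by id; k overflow returns all, flagged
  X3 <- rbind(a = c(1, 1, 1), b = c(1, 1, 1), c = c(5, 5, 5))
  out3 <- select_representatives(X3, rep("Z", 3), k = 5)
  expect_equal(nrow(out3), 3L)
  expect_true(all(out3$short_population))
  expect_equal(out3$specimen_id[1:2], c("a", "b"))
  expect_error(select_representatives(rbind(c(1, NA)), "Z", 1), "missing")
})
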