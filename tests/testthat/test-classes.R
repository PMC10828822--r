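test_that("peptide featurization counts residues, labels, and extra charge", {
  d <- data.frame(
    sequence = c("PEPTIDEK", "HHAR", "PEPTIDE", "GGRK"),
    modifications = c("TMTpro (N-term);TMTpro (K8)", "TMTpro (N-term)",
                      "TMTpro (N-term)", "TMTpro (N-term);TMTpro (K4);Phospho (S1)"),
    charge = c(2, 2, 2, 4))
  f <- featurize_peptides(d)
  expect_equal(f$n_labels, c(2L, 1L, 1L, 2L))
  expect_identical(f$has_K, c(TRUE, FALSE, FALSE, TRUE))
  expect_identical(f$has_R, c(FALSE, TRUE, FALSE, TRUE))
  expect_identical(f$has_E, c(TRUE, FALSE, TRUE, FALSE))
  # allowance #R + #H + 1: HHAR (4 >= 2) no extra; PEPTIDE (1 < 2) extra
  expect_identical(f$extra_charge, c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(f$charge_cat, c(2L, 2L, 2L, 3L))  # charge 4 capped at 3
  expect_identical(f$has_mod_Phospho, c(FALSE, FALSE, FALSE, TRUE))

  bad <- data.frame(sequence = "AAK", modifications = "Gremlin (K1)",
                    charge = 2)
  expect_error(featurize_peptides(bad), "Gremlin")
})

test_that("two planted response populations give exactly the R split", {
  set.seed(101)
  n <- 500
  feats <- data.frame(
    charge_cat = sample(2:3, 2 * n, TRUE),
    n_labels = sample(1:2, 2 * n, TRUE),
    has_H = sample(c(TRUE, FALSE), 2 * n, TRUE),
    has_R = rep(c(TRUE, FALSE), each = n),
    has_K = sample(c(TRUE, FALSE), 2 * n, TRUE),
    has_E = sample(c(TRUE, FALSE), 2 * n, TRUE),
    has_D = sample(c(TRUE, FALSE), 2 * n, TRUE),
    extra_charge = sample(c(TRUE, FALSE), 2 * n, TRUE))
  resp <- ifelse(feats$has_R, 0.1, 0.6) + stats::rnorm(2 * n, 0, 0.05)
  tree <- fit_class_tree(feats, resp)
  leaves <- class_tree_leaves(tree)
  expect_identical(nrow(leaves), 2L)
  expect_setequal(leaves$label, c("R+", "R-"))
  cls <- assign_class(tree, feats)
  expect_identical(cls == "R+", feats$has_R)
  # every leaf respects the floor
  expect_true(all(leaves$n > 100))
})

test_that("homogeneous responses and tiny cohorts yield a single class", {
  feats <- data.frame(charge_cat = rep(2:3, 250),
                      has_R = rep(c(TRUE, FALSE), 250))
  tree <- fit_class_tree(feats, rep(1.5, 500))
  expect_identical(nrow(class_tree_leaves(tree)), 1L)
  expect_identical(class_tree_leaves(tree)$label, "all")
  expect_identical(unique(assign_class(tree, feats)), "all")

  # 150 PSMs with a perfect binary signal: children would fall below the
  # floor, so the split is refused
  set.seed(5)
  f150 <- data.frame(has_R = rep(c(TRUE, FALSE), each = 75))
  r150 <- ifelse(f150$has_R, 0, 10) + stats::rnorm(150, 0, 0.01)
  expect_warning(t150 <- fit_class_tree(f150, r150), "single-class")
  expect_identical(nrow(class_tree_leaves(t150)), 1L)

  # 300 PSMs: above 2*min_leaf but a 150/150 split still violates > 100?
  # no - 150 > 100, so this one SHOULD split
  f300 <- data.frame(has_R = rep(c(TRUE, FALSE), each = 150))
  r300 <- ifelse(f300$has_R, 0, 10) + stats::rnorm(300, 0, 0.01)
  expect_identical(nrow(class_tree_leaves(fit_class_tree(f300, r300))), 2L)
})

test_that("tree fitting is deterministic and variance never increases", {
  set.seed(77)
  n <- 1200
  feats <- data.frame(
    charge_cat = sample(1:3, n, TRUE),
    n_labels = sample(1:3, n, TRUE),
    has_R = sample(c(TRUE, FALSE), n, TRUE),
    has_K = sample(c(TRUE, FALSE), n, TRUE))
  resp <- 0.5 * feats$charge_cat + ifelse(feats$has_R, -0.8, 0.4) +
    stats::rnorm(n, 0, 0.1)
  t1 <- fit_class_tree(feats, resp)
  t2 <- fit_class_tree(feats, resp)
  expect_identical(t1, t2)

  cls <- assign_class(t1, feats)
  sse <- function(v) sum((v - mean(v))^2)
  within <- sum(tapply(resp, cls, sse))
  expect_lte(within, sse(resp))
  expect_true(all(class_tree_leaves(t1)$n > 100))
})

test_that("planted four-class structure is recovered with high agreement", {
  set.seed(303)
  n <- 400  # per class
  feats <- data.frame(
    charge_cat = sample(2:3, 4 * n, TRUE),
    has_R = rep(c(TRUE, TRUE, FALSE, FALSE), each = n),
    has_K = rep(c(TRUE, FALSE, TRUE, FALSE), each = n),
    has_E = sample(c(TRUE, FALSE), 4 * n, TRUE))
  mu <- rep(c(0, 1, 2, 3), each = n)
  resp <- mu + stats::rnorm(4 * n, 0, 0.15)  # sd well under between-class spread
  tree <- fit_class_tree(feats, resp)
  cls <- assign_class(tree, feats)
  ari <- mclust::adjustedRandIndex(cls, mu)
  expect_gte(ari, 0.9)
})

test_that("gross response outliers do not mask class structure", {
  set.seed(404)
  n <- 600
  feats <- data.frame(has_R = rep(c(TRUE, FALSE), each = n),
                      has_K = sample(c(TRUE, FALSE), 2 * n, TRUE))
  resp <- ifelse(feats$has_R, 0.1, 0.8) + stats::rnorm(2 * n, 0, 0.2)
  resp[sample(2 * n, 60)] <- resp[sample(2 * n, 60)] + log(100)
  tree <- fit_class_tree(feats, resp)
  expect_setequal(class_tree_leaves(tree)$label, c("R+", "R-"))
})
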