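test_that("correlation ranking orders by absolute correlation with rank/N p-values", {
  set.seed(21)
  n <- 200
  tf1 <- rnorm(n); tf2 <- rnorm(n)
  ds <- expression_dataset(
    cbind(TF1 = tf1, TF2 = tf2,
          GA = 3 * tf1,                       # |r| = 1, ranked first
          GB = -0.9 * tf2 + 0.25 * rnorm(n)), # strong negative correlation
    is_tf = c(TRUE, TRUE, FALSE, FALSE)
  )
  ranked <- correlation_ranking(ds)
  expect_equal(nrow(ranked), 4L)
  expect_equal(ranked$p_value, c(0.25, 0.5, 0.75, 1))
  expect_equal(ranked$tf[1], "TF1")
  expect_equal(ranked$target[1], "GA")
  # sign is ignored: the strong negative TF2-GB edge outranks weak pairs
  expect_equal(edge_key_test <- paste(ranked$tf[2], ranked$target[2]), "TF2 GB")
  # zero-variance gene ranks last
  ds0 <- expression_dataset(
    cbind(TF1 = tf1, TF2 = tf2, GA = 3 * tf1, GC = rep(1, n)),
    is_tf = c(TRUE, TRUE, FALSE, FALSE))
  r0 <- correlation_ranking(ds0)
  expect_true(all(r0$confidence[r0$target == "GC"] == 0))
  expect_true(all(which(r0$target == "GC") >= 3))
})

test_that("the subnetwork module test separates mediated from unmediated structure", {
  set.seed(22)
  p_chain <- replicate(30, subnetwork_module_pvalue(
    grn_chain_dataset(800), c("t1", "t2"), c("g1", "g2")))
  expect_gt(median(p_chain), 0.1)

  set.seed(23)
  rej <- vapply(c(200, 1600), function(n) {
    mean(replicate(50, subnetwork_module_pvalue(
      grn_two_regulator_dataset(n), c("t1", "t2"), c("g1", "g2")) < 0.05))
  }, numeric(1))
  expect_gt(rej[1], 0.05)
  expect_gte(rej[2], rej[1])
  expect_gt(rej[2], 0.8)

  # destroyed dependencies: conservative, never evidence against the module
  set.seed(24)
  p_null <- replicate(200, {
    n <- 400
    ds <- expression_dataset(
      matrix(rnorm(4 * n), n, 4,
             dimnames = list(NULL, c("t1", "t2", "g1", "g2"))),
      is_tf = c(TRUE, TRUE, FALSE, FALSE))
    subnetwork_module_pvalue(ds, c("t1", "t2"), c("g1", "g2"))
  })
  expect_lte(mean(p_null <= 0.05), 0.05)
  expect_error(subnetwork_module_pvalue(grn_chain_dataset(100),
                                        c("t1", "nope"), c("g1", "g2")),
               "unknown gene")
})

test_that("re-ranking corrections are monotone and respect sufficient connectivity", {
  sim <- simulate_grn_motifs(600, 3, seed = 25)
  ranked <- correlation_ranking(sim$ds)
  rr <- rerank(sim$ds, ranked, set_size = 18)
  key <- function(df) paste(df$tf, df$target)
  m <- match(key(ranked), key(rr))
  expect_true(all(rr$p_value[m] >= ranked$p_value - 1e-12))
  expect_setequal(key(rr), key(ranked))

  # a most-likely set too small to make any subnetwork sufficiently
  # connected leaves every p-value unchanged
  rr2 <- rerank(sim$ds, ranked, set_size = 2)
  m2 <- match(key(ranked), key(rr2))
  expect_equal(rr2$p_value[m2], ranked$p_value)
})

test_that("corrections from multiple subnetworks combine by taking the maximum", {
  set.seed(26)
  n <- 600
  a <- 1 + (runif(n) < 0.5)
  b <- ifelse(runif(n) < 0.85, a, 3 - a)
  vals <- cbind(TFa = a + rnorm(n, sd = 0.3),
                TFb = b + rnorm(n, sd = 0.3),
                G1 = b + rnorm(n, sd = 0.8),
                G2 = b + rnorm(n, sd = 0.8),
                G3 = b + rnorm(n, sd = 2.0))
  ds <- expression_dataset(vals, is_tf = c(TRUE, TRUE, FALSE, FALSE, FALSE))
  ranked <- correlation_ranking(ds)
  rr <- rerank(ds, ranked, set_size = 6)
  c_scale <- max(ranked$p_value[1:6])
  # expected correction for the indirect edge (TFa, G1): the maximum over
  # the subnetworks pairing G1 with G2 and with G3
  p12 <- subnetwork_module_pvalue(ds, c("TFb", "TFa"), c("G1", "G2"))
  p13 <- subnetwork_module_pvalue(ds, c("TFb", "TFa"), c("G1", "G3"))
  orig <- ranked$p_value[ranked$tf == "TFa" & ranked$target == "G1"]
  expected <- max(orig, c_scale * p12, c_scale * p13)
  got <- rr$p_value[rr$tf == "TFa" & rr$target == "G1"]
  expect_equal(got, expected, tolerance = 1e-12)
})

test_that("precision-recall and ROC areas match closed-form cases", {
  gold <- data.frame(tf = rep("T1", 4), target = paste0("G", 1:4),
                     label = c(1, 1, 0, 0))
  perfect <- structure(
    data.frame(tf = rep("T1", 4), target = paste0("G", 1:4),
               confidence = 4:1, p_value = (1:4) / 4),
    class = c("ranked_edges", "data.frame"))
  ev <- evaluate_pr_roc(perfect, gold)
  expect_equal(ev$aupr, 1)
  expect_equal(ev$auroc, 1)
  reversed <- perfect[4:1, ]
  reversed$p_value <- (1:4) / 4
  ev2 <- evaluate_pr_roc(reversed, gold)
  expect_equal(ev2$auroc, 0)
  # random ranking: expected area under PR approaches the prevalence
  set.seed(27)
  gold2 <- data.frame(tf = "T1", target = paste0("G", 1:400),
                      label = rep(c(1, 0), c(40, 360)))
  auprs <- replicate(200, {
    ord <- sample(400)
    rk <- structure(
      data.frame(tf = "T1", target = paste0("G", ord),
                 confidence = 400:1, p_value = (1:400) / 400),
      class = c("ranked_edges", "data.frame"))
    evaluate_pr_roc(rk, gold2)$aupr
  })
  expect_equal(mean(auprs), 0.1, tolerance = 0.2)
  # unranked gold pairs are appended reproducibly
  partial <- perfect[1:2, ]
  e1 <- evaluate_pr_roc(partial, gold, seed = 5)
  e2 <- evaluate_pr_roc(partial, gold, seed = 5)
  expect_equal(e1, e2)
  expect_error(evaluate_pr_roc(perfect, transform(gold, label = 0)),
               "no positives")
})

test_that("challenge scores follow the log-transformed p-value formulas", {
  expect_equal(overall_score(c(1, 1), c(1, 1))$score, 0)
  sc <- overall_score(c(1e-2, 1e-4), c(1, 1))
  expect_equal(sc$score_roc, 3)
  expect_equal(sc$score_pr, 0)
  expect_equal(sc$score, 1.5)
  half <- overall_score(c(5e-3, 5e-5), c(0.5, 0.5))
  expect_gt(half$score, sc$score)
  expect_error(overall_score(c(0, 0.5), c(1, 1)), "p-values")
})

test_that("indirect dependencies are labelled removable or nonremovable", {
  chain <- data.frame(tf = c("A", "B"), target = c("B", "G"))
  lab <- classify_indirect(chain, tf_set = c("A", "B"))
  expect_equal(nrow(lab), 1)
  expect_equal(lab$label, "removable")
  expect_equal(lab$tf, "A")
  expect_equal(lab$target, "G")

  # Z regulates two interdependent TFs U and W that both regulate G:
  # the Z -> G dependency is mediated by two TFs sharing a regulator
  shared <- data.frame(tf = c("Z", "Z", "U", "W"),
                       target = c("U", "W", "G", "G"))
  lab2 <- classify_indirect(shared, tf_set = c("Z", "U", "W"))
  zg <- lab2[lab2$tf == "Z" & lab2$target == "G", ]
  expect_equal(zg$label, "nonremovable")

  empty <- classify_indirect(data.frame(tf = character(), target = character()))
  expect_equal(nrow(empty), 0)
})

test_that("holdout selection uses every 8th sample and returns a candidate size", {
  sim <- simulate_grn_motifs(640, 3, seed = 28)
  expect_equal(holdout_size_selection(sim$ds, correlation_ranking(sim$ds),
                                      17, sim$gold), 17)
  ranked <- correlation_ranking(sim$ds)
  sel <- holdout_size_selection(sim$ds, ranked, c(6, 18, 36), sim$gold,
                                seed = 2)
  expect_true(sel %in% c(6, 18, 36))
  expect_error(holdout_size_selection(sim$ds, ranked, c(6, 18),
                                      data.frame()[0, ]),
               "gold")
})
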