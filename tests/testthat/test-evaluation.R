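test_that("entropy has its closed forms", {
  expect_equal(entropy_bits(c(0.5, 0.5)), 1)
  expect_equal(entropy_bits(c(1, 0)), 0)
  p <- 0.0307
  expect_equal(entropy_bits(c(p, 1 - p)),
               -p * log2(p) - (1 - p) * log2(1 - p))
  expect_equal(entropy_bits(c(p, 1 - p)), 0.1978903, tolerance = 1e-6)
  expect_error(entropy_bits(c(0.5, 0.6)), "valid")
})

test_that("association table computes the MI percentages, G-test and ordering", {
  cfg <- generator_config(schema = toy_schema(6), effect_target = 0.2,
                          missingness = 0, seed = 51)
  sim <- forward_sample(build_ground_truth(cfg), 30000, seed = 52)
  tab <- association_table(sim, "C")
  expect_equal(nrow(tab), 6)
  # sorted by MI descending
  expect_true(all(diff(tab$mutual_information) <= 0))
  # binary target: normalized MI is exactly 100 * MI
  expect_equal(tab$normalized_mi_pct, 100 * tab$mutual_information)
  # relative MI = 100 * MI / H(target), bounded by 100
  ct <- contingency_counts(sim, "C")
  ht <- strokebbn:::entropy_counts(ct$counts)
  expect_equal(tab$relative_mi_pct,
               100 * tab$mutual_information / ht, tolerance = 1e-9)
  expect_true(all(tab$relative_mi_pct >= 0 & tab$relative_mi_pct <= 100))
  # df = (r_x - 1)(r_target - 1): 3-state features vs binary target
  expect_true(all(tab$df == 2))
  # G-test arithmetic: G = 2 N ln(2) MI at the upper chi-square tail
  g <- 2 * 30000 * log(2) * tab$mutual_information
  expect_equal(tab$p_value, pchisq(g, 2, lower.tail = FALSE), tolerance = 1e-12)
  # cross-check one cell against stats::chisq.test's G-free analogue:
  # independence gives p near uniform, dependence tiny p
  expect_lt(tab$p_value[1], 1e-6)
})

test_that("relative MI reaches 100 exactly when the covariate determines the target", {
  sch <- bn_schema(list(variable_spec("X", c("a", "b")),
                        variable_spec("C", c("no", "yes"), role = "target")))
  x <- cbind(X = rep(1:2, 50), C = rep(1:2, 50))
  tab <- association_table(bn_dataset(sch, x), "C")
  expect_equal(tab$relative_mi_pct, 100, tolerance = 1e-9)
})

test_that("Pearson correlation uses ordinal state codes and flags constants", {
  sch <- bn_schema(list(variable_spec("X", c("low", "mid", "high")),
                        variable_spec("K", c("a", "b")),
                        variable_spec("C", c("no", "yes"), role = "target")))
  set.seed(61)
  n <- 5000
  xs <- sample.int(3, n, replace = TRUE)
  cs <- rbinom(n, 1, prob = c(0.6, 0.3, 0.1)[xs]) + 1L  # decreasing in X
  ds <- bn_dataset(sch, cbind(X = xs, K = rep(1L, n), C = cs))
  tab <- association_table(ds, "C")
  expect_lt(tab$pearson_r[tab$node == "X"], -0.3)
  expect_equal(tab$pearson_r[tab$node == "X"],
               cor(xs, cs), tolerance = 1e-9)
  krow <- tab[tab$node == "K", ]
  expect_equal(krow$mutual_information, 0)
  expect_equal(krow$pearson_r, 0)
  expect_identical(krow$flag, "constant")
})

test_that("classification is the exact target posterior given the features", {
  # target independent of features: every score equals the prior
  cfg0 <- generator_config(schema = toy_schema(3), effect_target = 0,
                           effect_tree = 0, missingness = 0, seed = 71)
  gt0 <- build_ground_truth(cfg0)
  ds0 <- forward_sample(gt0, 100, seed = 72)
  cl0 <- classify(gt0, ds0, "C")
  expect_equal(cl0$score, rep(0.0307, 100), tolerance = 1e-9)
  expect_true(all(cl0$prediction == "no"))

  # deterministic feature pins the score to 0/1
  sch <- bn_schema(list(variable_spec("F", c("0", "1")),
                        variable_spec("C", c("no", "yes"), role = "target")))
  det <- bayes_net(sch, rbind(c("C", "F")), list(
    C = cpt_table("C", character(0), matrix(c(0.7, 0.3), 1)),
    F = cpt_table("F", "C", rbind(c(1, 0), c(0, 1)))))
  dsd <- forward_sample(det, 50, seed = 73)
  cld <- classify(det, dsd, "C")
  expect_equal(sort(unique(cld$score)), c(0, 1))
  expect_identical(cld$prediction,
                   c("no", "yes")[dsd$x[, "C"]])

  # scores equal the brute-force posterior on small random nets
  for (s in c(5, 21)) {
    net <- random_net(s)
    vars <- schema_names(net$schema)
    target <- vars[length(vars)]
    ds <- forward_sample(net, 30, seed = 80 + s)
    cl <- classify(net, ds, target)
    states <- schema_states(net$schema, target)
    for (i in 1:10) {
      ev <- lapply(setdiff(vars, target), function(v)
        schema_states(net$schema, v)[ds$x[i, v]])
      names(ev) <- setdiff(vars, target)
      bf <- brute_force_posterior(net, target, ev)$p
      expect_equal(cl$score[i], unname(bf[[states[length(states)]]]),
                   tolerance = 1e-9)
    }
  }
  expect_error(classify(gt0, inject_missingness(ds0, 0.5, seed = 1), "C"),
               "impute")
})

test_that("validation metrics hit their closed forms", {
  # perfect classifier
  truth <- rep(c("no", "yes"), c(90, 10))
  perfect <- validation_metrics(truth, truth, c(rep(0, 90), rep(1, 10)),
                                positive = "yes")
  expect_equal(perfect$precision_pct, 100)
  expect_equal(perfect$reliability_pct, 100)
  expect_equal(perfect$roc_index_pct, 100)
  expect_equal(perfect$lift_index_pct, 100)

  # all-negative predictor at 3.07% prevalence: precision = 96.93%
  n <- 10000
  truth2 <- rep(c("yes", "no"), c(307, n - 307))
  all_neg <- validation_metrics(truth2, rep("no", n), rep(0.01, n),
                                positive = "yes")
  expect_equal(all_neg$precision_pct, 96.93)
  # reliability: the only predicted class has PPV 0.9693, truth-weighted
  expect_equal(all_neg$reliability_pct, 100 * (0.9693 * 0.9693), tolerance = 1e-9)

  # random scores on balanced classes: ROC index near 50
  set.seed(91)
  truth3 <- rep(c("no", "yes"), each = 5000)
  rnd <- validation_metrics(truth3, rep("no", 10000), runif(10000),
                            positive = "yes")
  se_auc <- sqrt(1 / 12 * (1 / 5000 + 1 / 5000))  # null AUC variance approx.
  expect_lt(abs(rnd$roc_index_pct - 50), 100 * 3 * se_auc)

  # single-class truth: ROC undefined and flagged
  flagged <- validation_metrics(rep("no", 5), rep("no", 5), runif(5))
  expect_true(is.na(flagged$roc_index_pct))
  expect_match(flagged$flag, "single-class")
})

test_that("ROC index is invariant under monotone score transforms and matches pROC", {
  set.seed(95)
  truth <- rbinom(500, 1, 0.3)
  score <- runif(500) + truth * 0.4
  m1 <- validation_metrics(c("no", "yes")[truth + 1],
                           rep("no", 500), score, positive = "yes")
  m2 <- validation_metrics(c("no", "yes")[truth + 1],
                           rep("no", 500), qlogis(score / 2), positive = "yes")
  expect_equal(m1$roc_index_pct, m2$roc_index_pct, tolerance = 1e-12)
  skip_if_not_installed("pROC")
  auc_ref <- as.numeric(pROC::auc(pROC::roc(truth, score, quiet = TRUE,
                                            direction = "<")))
  expect_equal(m1$roc_index_pct, 100 * auc_ref, tolerance = 1e-9)
})
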