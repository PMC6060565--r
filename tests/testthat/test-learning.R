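test_that("contingency counting is weighted and complete-case", {
  sch <- bn_schema(list(variable_spec("A", c("0", "1")),
                        variable_spec("B", c("0", "1"))))
  x <- cbind(A = c(1L, 1L, 2L, 2L), B = c(1L, 2L, 1L, 2L))
  ds <- bn_dataset(sch, x)
  ct <- contingency_counts(ds, c("A", "B"))
  expect_equal(ct$counts, rep(1, 4))
  expect_equal(ct$n, 4)

  ds2 <- bn_dataset(sch, x, weights = 2)
  expect_equal(contingency_counts(ds2, c("A", "B"))$counts, rep(2, 4))

  x[1, "A"] <- NA
  ds3 <- bn_dataset(sch, x)
  expect_equal(contingency_counts(ds3, c("A", "B"))$n, 3)
  expect_equal(contingency_counts(ds3, "B")$n, 4)  # B fully observed
  expect_error(contingency_counts(ds, "nope"), "unknown")
})

test_that("mutual information matches closed forms", {
  mk <- function(p) structure(list(vars = c("X", "Y"), cards = c(2L, 2L),
                                   counts = p, n = sum(p)),
                              class = "bbn_contingency")
  expect_equal(mutual_information(mk(c(25, 25, 25, 25))), 0)
  expect_equal(mutual_information(mk(c(50, 0, 0, 50))), 1)   # I(X;X) = H(X)
  # joint (0.4, 0.1, 0.1, 0.4): direct formula evaluation gives 0.27807 bits
  expect_equal(mutual_information(mk(c(0.4, 0.1, 0.1, 0.4))),
               2 * 0.4 * log2(0.4 / 0.25) + 2 * 0.1 * log2(0.1 / 0.25))
  expect_equal(round(mutual_information(mk(c(0.4, 0.1, 0.1, 0.4))), 3), 0.278)
  expect_error(mutual_information(mk(c(0, 0, 0, 0))), "empty")
})

test_that("conditional mutual information obeys its identities", {
  # I(X;X|C) = H(X|C)
  sch <- bn_schema(list(variable_spec("X", c("a", "b", "c")),
                        variable_spec("X2", c("a", "b", "c")),
                        variable_spec("C", c("0", "1"))))
  set.seed(31)
  xs <- sample.int(3, 3000, replace = TRUE, prob = c(0.5, 0.3, 0.2))
  cs <- sample.int(2, 3000, replace = TRUE)
  ds <- bn_dataset(sch, cbind(X = xs, X2 = xs, C = cs))
  hxc <- {
    ct <- contingency_counts(ds, c("X", "C"))
    arr <- strokebbn:::ct_array(ct)
    sum(vapply(1:2, function(k) sum(arr[, k]) / ct$n *
                 strokebbn:::entropy_counts(arr[, k]), numeric(1)))
  }
  expect_equal(conditional_mutual_information(ds, "X", "X2", "C"), hxc,
               tolerance = 1e-12)

  # conditionally independent features given C stay near zero at n = 1e5
  cfg <- generator_config(schema = toy_schema(3), effect_target = 0.3,
                          effect_tree = 0, missingness = 0, seed = 17)
  sim <- forward_sample(build_ground_truth(cfg), 1e5, seed = 18)
  expect_lt(conditional_mutual_information(sim, "f01", "f02", "C"), 0.002)

  # sampled CMI tracks the exact CMI of a known chain C -> Xi -> Xj
  sch2 <- bn_schema(list(variable_spec("C", c("0", "1")),
                         variable_spec("Xi", c("0", "1")),
                         variable_spec("Xj", c("0", "1"))))
  net <- bayes_net(sch2, tables = list(
    C = cpt_table("C", character(0), matrix(c(0.6, 0.4), 1)),
    Xi = cpt_table("Xi", "C", rbind(c(0.8, 0.2), c(0.3, 0.7))),
    Xj = cpt_table("Xj", "Xi", rbind(c(0.9, 0.1), c(0.25, 0.75)))))
  # closed form: within each C stratum Xi determines Xj's mixture
  exact <- local({
    cmi <- 0
    for (c_ in 1:2) {
      pc <- net$tables$C$prob[1, c_]
      pxi <- net$tables$Xi$prob[c_, ]
      j <- outer(pxi, c(1, 1)) * net$tables$Xj$prob  # P(xi, xj | c)
      ct <- structure(list(vars = c("Xi", "Xj"), cards = c(2L, 2L),
                           counts = as.numeric(j), n = 1),
                      class = "bbn_contingency")
      cmi <- cmi + pc * mutual_information(ct)
    }
    cmi
  })
  sim2 <- forward_sample(net, 1e5, seed = 19)
  expect_lt(abs(conditional_mutual_information(sim2, "Xi", "Xj", "C") - exact),
            0.01)   # within 0.01 bits
})

test_that("naive Bayes has the fixed star topology", {
  cfg <- generator_config(schema = toy_schema(2), missingness = 0, seed = 1)
  sim <- forward_sample(build_ground_truth(cfg), 500, seed = 2)
  nb <- learn_naive_bayes(sim, "C")
  expect_equal(nrow(nb$edges), 2)
  expect_true(all(nb$edges[, 1] == "C"))
  expect_error(learn_naive_bayes(bn_dataset(sim$schema,
                                            sim$x[0, , drop = FALSE]), "C"),
               "empty")
})

test_that("TAN adds a spanning feature tree and recovers a known skeleton", {
  cfg <- generator_config(schema = toy_schema(2), missingness = 0, seed = 3)
  sim <- forward_sample(build_ground_truth(cfg), 2000, seed = 4)
  tan <- learn_tan(sim, "C")
  aug <- feature_tree(tan, "C")
  expect_equal(nrow(aug), 1)                   # 2 features -> 1 augmenting edge
  expect_setequal(as.character(aug), c("f01", "f02"))

  cfg8 <- generator_config(schema = toy_schema(8), effect_tree = 0.3,
                           missingness = 0, seed = 5)
  gt <- build_ground_truth(cfg8)
  sim8 <- forward_sample(gt, 50000, seed = 6)
  tan8 <- learn_tan(sim8, "C")
  expect_identical(undirected_key(feature_tree(tan8, "C")),
                   undirected_key(feature_tree(gt, "C")))
  expect_equal(nrow(feature_tree(tan8, "C")), 7)
  expect_identical(validate_network(tan8), character(0))
  # every feature has the target plus at most one feature parent
  npar <- table(factor(tan8$edges[, 2], sprintf("f%02d", 1:8)))
  expect_true(all(npar <= 2))
  # determinism (ties broken lexicographically)
  tan8b <- learn_tan(sim8, "C")
  expect_identical(tan8$edges, tan8b$edges)
})

test_that("CPT fitting matches empirical frequencies and smooths empty rows", {
  sch <- bn_schema(list(variable_spec("A", c("0", "1")),
                        variable_spec("B", c("0", "1", "2"))))
  x <- cbind(A = c(1L, 1L, 1L, 2L), B = c(1L, 1L, 2L, 3L))
  ds <- bn_dataset(sch, x)
  net <- fit_cpts(rbind(c("A", "B")), ds, alpha = 0)
  expect_equal(net$tables$B$prob[1, ], c(2 / 3, 1 / 3, 0))
  expect_equal(net$tables$B$prob[2, ], c(0, 0, 1))
  expect_equal(net$tables$A$prob[1, ], c(0.75, 0.25))

  # alpha = 1 on a never-seen parent row gives the uniform distribution
  x2 <- cbind(A = c(1L, 1L), B = c(1L, 2L))
  net2 <- fit_cpts(rbind(c("A", "B")), bn_dataset(sch, x2), alpha = 1)
  expect_equal(net2$tables$B$prob[2, ], rep(1 / 3, 3))
  expect_error(fit_cpts(rbind(c("A", "B")), bn_dataset(sch, x2), alpha = 0),
               "alpha")

  # parameter recovery from the generator at large n
  cfg <- generator_config(prevalence = 0.5, schema = toy_schema(6, rep(2, 6)),
                          effect_target = 0.15, effect_tree = 0.15,
                          missingness = 0, seed = 11)
  gt <- build_ground_truth(cfg)
  sim <- forward_sample(gt, 200000, seed = 12)
  fit <- fit_cpts(gt$edges, sim, alpha = 1)
  err <- max(vapply(schema_names(gt$schema), function(v)
    max(abs(fit$tables[[v]]$prob - gt$tables[[v]]$prob)), numeric(1)))
  expect_lt(err, 0.01)
})

test_that("MDL decomposes exactly and has the single-node closed form", {
  sch <- bn_schema(list(variable_spec("A", c("0", "1"))))
  ds <- bn_dataset(sch, matrix(rep(1:2, 50), ncol = 1,
                               dimnames = list(NULL, "A")))
  net <- bayes_net(sch, tables = list(
    A = cpt_table("A", character(0), matrix(c(0.5, 0.5), 1))))
  sc <- mdl_score(net, ds)
  expect_equal(sc$data_dl, 100)                # 100 records x 1 bit
  expect_equal(sc$k, 1)
  expect_equal(sc$model_dl, 0.5 * log2(100))
  expect_equal(sc$total, sc$model_dl + sc$data_dl)

  # zero-probability record under an unsmoothed fit is a clear error
  net0 <- bayes_net(sch, tables = list(
    A = cpt_table("A", character(0), matrix(c(1, 0), 1))))
  expect_error(mdl_score(net0, ds), "alpha")
})

test_that("adding an edge never increases the data description length", {
  cfg <- generator_config(schema = toy_schema(3), missingness = 0, seed = 13)
  sim <- forward_sample(build_ground_truth(cfg), 2000, seed = 14)
  nb_edges <- cbind(rep("C", 3), sprintf("f%02d", 1:3))
  bigger <- rbind(nb_edges, c("f01", "f02"))
  dl1 <- mdl_score(fit_cpts(nb_edges, sim, alpha = 0), sim)$data_dl
  dl2 <- mdl_score(fit_cpts(bigger, sim, alpha = 0), sim)$data_dl
  expect_lte(dl2, dl1 + 1e-9)
})

test_that("MDL model selection prefers the generating structure", {
  sc <- toy_schema(6)
  pick <- function(effect_tree, seed) {
    cfg <- generator_config(0.0307, sc, effect_target = 0.15,
                            effect_tree = effect_tree, missingness = 0,
                            seed = seed)
    sim <- forward_sample(build_ground_truth(cfg), 20000, seed = seed + 1000)
    select_structure(sim, "C")
  }
  tan_run <- pick(0.3, 301)
  expect_identical(tan_run$best, "tan")
  expect_equal(nrow(tan_run$scores), 2)
  nb_run <- pick(0, 302)
  expect_identical(nb_run$best, "nb")
  # single candidate returns itself
  solo <- select_structure(forward_sample(build_ground_truth(
    generator_config(schema = sc, missingness = 0, seed = 9)), 500, seed = 10),
    "C", candidates = list(nb = learn_naive_bayes))
  expect_identical(solo$best, "nb")
})

test_that("imputation returns the exact posterior mode and beats marginals", {
  # no missing cells: unchanged
  cfg <- generator_config(schema = toy_schema(3), missingness = 0, seed = 21)
  gt <- build_ground_truth(cfg)
  full <- forward_sample(gt, 200, seed = 22)
  expect_identical(impute_missing(full, gt)$x, full$x)

  # single missing cell equals the brute-force posterior mode
  net <- confounded_net()
  ds <- forward_sample(net, 300, seed = 23)
  x <- ds$x
  x[, "Z"] <- NA
  holey <- bn_dataset(net$schema, x)
  imp <- impute_missing(holey, net)
  for (i in sample.int(300, 25)) {
    ev <- list(E = schema_states(net$schema, "E")[x[i, "E"]],
               T = schema_states(net$schema, "T")[x[i, "T"]])
    mode_bf <- which.max(brute_force_posterior(net, "Z", ev)$p)
    expect_equal(unname(imp$x[i, "Z"]), unname(mode_bf))
  }

  # an all-missing record is filled from marginal modes and flagged
  x2 <- ds$x
  x2[1, ] <- NA
  imp2 <- impute_missing(bn_dataset(net$schema, x2), net)
  expect_equal(attr(imp2, "diagnostics")$records_all_missing, 1L)
  expect_false(anyNA(imp2$x))

  # model-based accuracy strictly beats the marginal-mode baseline
  cfg8 <- generator_config(schema = toy_schema(8), effect_tree = 0.3,
                           missingness = 0, seed = 24)
  gt8 <- build_ground_truth(cfg8)
  full8 <- forward_sample(gt8, 20000, seed = 25)
  holey8 <- inject_missingness(full8, 0.1, seed = 26)
  tan8 <- learn_tan(holey8, "C")
  imp8 <- impute_missing(holey8, tan8)
  miss <- is.na(holey8$x)
  modes <- strokebbn:::marginal_modes(tan8)
  base <- holey8$x
  for (v in colnames(base)) base[is.na(base[, v]), v] <- modes[[v]]
  expect_gt(mean(imp8$x[miss] == full8$x[miss]),
            mean(base[miss] == full8$x[miss]))
})
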