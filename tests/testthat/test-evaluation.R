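pred_table <- function(fitness, essential,
                       carbon = rep("c1", length(fitness))) {
  out <- data.frame(gene = sprintf("g%03d", seq_along(fitness)),
                    carbon = carbon,
                    biomass_flux = ifelse(essential, 0, 1),
                    grows = !essential,
                    fitness = fitness, stringsAsFactors = FALSE)
  class(out) <- c("prediction_table", "data.frame")
  out
}

test_that("PR-AUC separates the canonical perfect and inverted orderings", {
  perfect <- evaluate_predictions(pred_table(c(-5, -4, 0, 1),
                                             c(TRUE, TRUE, FALSE, FALSE)))
  expect_equal(perfect$auc_pr, 1.0)
  expect_equal(perfect$auc_roc, 1.0)

  worst <- evaluate_predictions(pred_table(c(-5, -4, 0, 1),
                                           c(FALSE, FALSE, TRUE, TRUE)))
  expect_equal(worst$auc_pr,
               oracle_pr_auc(c(-5, -4, 0, 1), c(FALSE, FALSE, TRUE, TRUE)),
               tolerance = 1e-12)
})

test_that("PR-AUC equals the brute-force threshold oracle on random tables", {
  set.seed(7)
  for (i in 1:30) {
    n <- sample(c(20, 200), 1)
    fitness <- round(rnorm(n, -1, 2), sample(c(1, 3), 1))  # force ties sometimes
    essential <- runif(n) < 0.3
    if (!any(essential)) essential[1] <- TRUE
    rep_ <- evaluate_predictions(pred_table(fitness, essential))
    expect_equal(rep_$auc_pr, oracle_pr_auc(fitness, essential),
                 tolerance = 1e-12)
  }
})

test_that("PR-AUC is invariant under strictly monotone fitness transforms", {
  set.seed(8)
  fitness <- rnorm(100, -1, 2)
  essential <- runif(100) < 0.3
  base <- evaluate_predictions(pred_table(fitness, essential))$auc_pr
  for (f in list(function(x) 2 * x + 3, function(x) x^3,
                 function(x) -exp(-x))) {
    tr <- evaluate_predictions(pred_table(f(fitness), essential))$auc_pr
    expect_equal(tr, base, tolerance = 1e-12)
  }
})

test_that("undefined metrics are NaN with a warning, never zero", {
  expect_warning(r <- evaluate_predictions(
    pred_table(c(-1, 0), c(FALSE, FALSE))), "undefined")
  expect_true(is.nan(r$auc_pr))
})

test_that("fixed-threshold metrics use a strict fitness cutoff", {
  # a row exactly at the threshold counts as experimental growth
  r <- evaluate_predictions(pred_table(c(-2, -3, 0), c(FALSE, TRUE, FALSE)),
                            accuracy_threshold = -2)
  expect_equal(unname(r$confusion), c(1, 0, 2, 0))  # tp fp tn fn
  expect_equal(r$overall_accuracy, 1)
  expect_equal(r$balanced_accuracy, 1)
})

test_that("null padding appends growth rows with zero fitness", {
  tab <- pred_table(rnorm(100), runif(100) < 0.3,
                    carbon = rep(c("c1", "c2"), 50))
  padded <- pad_null(tab, 150)
  expect_equal(sum(padded$gene != "WT"), 150)
  extra <- padded[101:150, ]
  expect_true(all(extra$fitness == 0))
  expect_true(all(extra$grows))
  expect_identical(pad_null(tab, 100), tab)
  expect_error(pad_null(tab, 50), "below the current")
})

test_that("PR-AUC is more robust to null padding than the accuracy metrics", {
  set.seed(9)
  toy <- toy_fixture()
  fit <- simulate_fitness(toy$truth, fitness_gen_config(seed = 3))
  sim <- simulate_predictions(toy$model, fit,
                              scenario_spec(medium = toy$medium))
  before <- evaluate_predictions(sim$predictions)
  n <- sum(sim$predictions$gene != "WT")
  after <- evaluate_predictions(pad_null(sim$predictions, 2 * n))
  d_pr <- abs(after$auc_pr - before$auc_pr)
  expect_lt(d_pr, abs(after$overall_accuracy - before$overall_accuracy))
  expect_lt(d_pr, abs(after$balanced_accuracy - before$balanced_accuracy))
})

test_that("per-carbon AUC decomposes the global evaluation", {
  set.seed(10)
  # same subtable on both carbons: equal AUCs, equal to the global value
  fitness <- rnorm(50); essential <- runif(50) < 0.4
  tab <- pred_table(c(fitness, fitness), c(essential, essential),
                    carbon = rep(c("c1", "c2"), each = 50))
  pc <- per_carbon_auc(tab)
  expect_equal(unname(pc["c1"]), unname(pc["c2"]))
  expect_equal(unname(pc["c1"]),
               evaluate_predictions(pred_table(fitness, essential))$auc_pr)

  # errors injected on one carbon only lower that carbon's AUC
  ess2 <- essential
  flip <- which(essential)[1:5]
  tab2 <- pred_table(c(fitness, ifelse(seq_along(fitness) %in% flip,
                                       0.5, fitness)),
                     c(essential, essential),
                     carbon = rep(c("c1", "c2"), each = 50))
  pc2 <- per_carbon_auc(tab2)
  expect_lt(pc2["c2"], pc2["c1"])

  single <- per_carbon_auc(pred_table(fitness, essential))
  expect_length(single, 1)
})

test_that("recall at any threshold never drops when the lowest-fitness growth row flips to essential", {
  set.seed(12)
  fitness <- rnorm(60); essential <- runif(60) < 0.3
  essential[1] <- FALSE
  fitness[1] <- min(fitness) - 1     # the lowest-fitness model-growth row
  r1 <- evaluate_predictions(pred_table(fitness, essential))
  essential[1] <- TRUE
  r2 <- evaluate_predictions(pred_table(fitness, essential))
  common <- intersect(r1$pr_points$threshold, r2$pr_points$threshold)
  rec1 <- r1$pr_points$recall[match(common, r1$pr_points$threshold)]
  rec2 <- r2$pr_points$recall[match(common, r2$pr_points$threshold)]
  expect_true(all(rec2 >= rec1 - 1e-12))
})

test_that("error rankings recover injected misprediction classes", {
  toy <- toy_fixture()
  fit <- simulate_fitness(toy$truth, fitness_gen_config(seed = 4))
  sim <- simulate_predictions(toy$model, fit,
                              scenario_spec(medium = toy$medium))
  rk <- rank_errors(sim$predictions)
  fn_genes <- unique(toy$truth$gene[toy$truth$error_class == "vitamin_carryover"])
  fp_genes <- unique(toy$truth$gene[toy$truth$error_class %in%
                                      c("isoenzyme_fp", "bypass_fp")])
  expect_true(all(fn_genes %in% head(rk$false_negative_genes$gene,
                                     length(fn_genes))))
  expect_true(all(fp_genes %in% head(rk$false_positive_genes$gene,
                                     length(fp_genes))))
  # rankings partition the matched genes by prediction class
  expect_false(any(duplicated(rk$false_negative_genes$gene)))
  expect_false(any(duplicated(rk$false_positive_genes$gene)))
})
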