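fake_flux_matrix <- function(n_genes = 30, n_carbons = 5, n_rxn = 12,
                             seed = 1) {
  set.seed(seed)
  samples <- expand.grid(gene = sprintf("g%02d", 1:n_genes),
                         carbon = sprintf("c%d", 1:n_carbons),
                         stringsAsFactors = FALSE)
  values <- matrix(rnorm(nrow(samples) * n_rxn), nrow(samples), n_rxn,
                   dimnames = list(NULL, sprintf("R%02d", 1:n_rxn)))
  wt <- matrix(rnorm(n_carbons * n_rxn), n_carbons, n_rxn,
               dimnames = list(sprintf("c%d", 1:n_carbons),
                               sprintf("R%02d", 1:n_rxn)))
  structure(list(samples = data.frame(samples,
                                      fitness = rnorm(nrow(samples))),
                 values = values, wild_type = wt),
            class = "flux_matrix")
}

test_that("flux matrix assembly keeps only growth-predicted rows", {
  fx <- ml_fixture()
  pred <- fx$sim$predictions
  n_growth <- sum(pred$grows & pred$gene != "WT")
  expect_equal(nrow(fx$fm$values), n_growth)
  # columns follow the simulated model's reaction order: every base
  # reaction, plus any exchange the scenario created (here one
  # intracellular supplement uptake)
  expect_true(all(fx$toy$model$reactions$id %in% colnames(fx$fm$values)))
  extra <- setdiff(colnames(fx$fm$values), fx$toy$model$reactions$id)
  expect_true(all(grepl("_supplement$", extra)))
  expect_equal(sort(rownames(fx$fm$wild_type)),
               sort(unique(pred$carbon)))
  # every sample's biomass flux is at or above the growth cutoff
  expect_true(all(fx$fm$values[, "BIOMASS"] >= 0.001))
})

test_that("variance filter and covariation clustering match the union-find oracle", {
  set.seed(31)
  for (trial in 1:10) {
    n <- 40; p <- 20
    x <- matrix(rnorm(n * p), n, p)
    # inject duplicate, anti-correlated and constant columns
    x[, 2] <- x[, 1]
    x[, 3] <- -x[, 1] + rnorm(n, sd = 1e-4)
    x[, 4] <- 0
    x[, 5] <- x[, 6] * 3 + rnorm(n, sd = 1e-4)
    colnames(x) <- sprintf("C%02d", 1:p)
    cm <- filter_and_cluster(x, var_min = 1e-7, corr_min = 0.99)
    expect_false("C04" %in% cm$retained_columns)
    oracle <- oracle_corr_components(x[, cm$retained_columns], 0.99)
    canon <- function(cl) unname(sort(vapply(cl, function(v)
      paste(sort(v), collapse = "|"), character(1))))
    expect_equal(canon(cm$clusters), canon(oracle))
    # anti-correlated columns share a cluster; representatives are members
    in_same <- any(vapply(cm$clusters, function(cl)
      all(c("C01", "C03") %in% cl), logical(1)))
    expect_true(in_same)
    expect_true(all(mapply(function(r, cl) r %in% cl,
                           cm$representatives, cm$clusters)))
  }
})

test_that("wild-type distance is Euclidean per carbon and recovers planted coupling", {
  fm <- fake_flux_matrix(n_rxn = 2)
  # hand-computed two-reaction case
  d <- wildtype_distance(fm)$distance
  i <- 5
  wt <- fm$wild_type[fm$samples$carbon[i], ]
  expect_equal(d[i], sqrt(sum((fm$values[i, ] - wt)^2)))
  # identical fluxes give distance zero
  fm$values[1, ] <- fm$wild_type[fm$samples$carbon[1], ]
  expect_equal(wildtype_distance(fm)$distance[1], 0)

  # plant fitness = -0.4 * distance + noise and recover the negative slope
  set.seed(32)
  fm2 <- fake_flux_matrix(n_genes = 60, n_rxn = 8, seed = 33)
  d2 <- wildtype_distance(fm2)$distance
  fm2$samples$fitness <- -0.4 * d2 + rnorm(length(d2), sd = 0.5)
  res <- wildtype_distance(fm2)
  expect_lt(res$correlation, -0.5)
  expect_equal(unname(coef(res$fit)["distance"]), -0.4, tolerance = 0.15)
})

test_that("splits are disjoint, stratified by carbon and gene, and seeded", {
  fm <- fake_flux_matrix(n_genes = 100, n_carbons = 10)
  for (seed in c(0, 1, 17)) {
    sp <- make_split(fm, seed)
    expect_length(sp$train_carbons, 8)
    expect_length(sp$train_genes, 80)
    expect_length(intersect(sp$train_rows, sp$test_rows_full), 0)
    s <- fm$samples
    expect_true(all(s$gene[sp$train_rows] %in% sp$train_genes))
    expect_true(all(s$carbon[sp$train_rows] %in% sp$train_carbons))
    expect_false(any(s$gene[sp$test_rows_unseen] %in% sp$train_genes))
    expect_false(any(s$carbon[sp$test_rows_unseen] %in% sp$train_carbons))
    expect_true(all(sp$test_rows_unseen %in% sp$test_rows_full))
    # deterministic given the seed
    sp2 <- make_split(fm, seed)
    expect_identical(sp, sp2)
  }
  # unseen subset size: rows over 2 carbons x 20 genes
  sp <- make_split(fm, 3)
  expect_length(sp$test_rows_unseen, 2 * 20)
})

test_that("the classifier separates a linearly separable flux feature", {
  set.seed(34)
  fm <- fake_flux_matrix(n_genes = 40, n_carbons = 5)
  labels <- fm$values[, "R01"] > 0
  clf <- train_fp_classifier(fm$values, labels, seed = 1)
  p <- predict(clf, fm$values)
  expect_gt(score_pr_auc(p, labels), 0.99)
  expect_error(train_fp_classifier(fm$values, rep(TRUE, nrow(fm$values))),
               "single class")
})

test_that("Shapley attribution is additive and ignores unused features", {
  set.seed(35)
  fm <- fake_flux_matrix(n_genes = 30, n_carbons = 5, n_rxn = 6)
  labels <- fm$values[, "R02"] - fm$values[, "R05"] + rnorm(150, sd = 0.2) > 0
  clf <- train_fp_classifier(fm$values, labels, seed = 2)

  fast <- attribute_features(clf, fm$values, engine = "fast")
  exact <- attribute_features(clf, fm$values, engine = "exact64")
  # the two engines implement the same algorithm (fast one in single precision)
  expect_equal(exact$shap, fast$shap, tolerance = 1e-4)
  # double-precision additivity: bias + contributions reconstruct the margin
  expect_lt(max(abs(exact$bias + rowSums(exact$shap) - exact$margin)), 1e-9)
  # margins agree with the booster itself
  expect_equal(exact$margin,
               -predict(clf, fm$values, outputmargin = TRUE),
               tolerance = 1e-5)
  # a feature no tree uses gets zero attribution everywhere
  dump <- xgboost::xgb.model.dt.tree(model = clf)
  unused <- setdiff(colnames(fm$values), unique(dump$Feature))
  for (u in unused) expect_true(all(exact$shap[, u] == 0))
})

test_that("feature attribution is stable across the labeling threshold", {
  fx <- ml_fixture()
  h2 <- run_split_harness(fx$fm, fx$clusters, seeds = 0:19, threshold = -2)
  h1 <- run_split_harness(fx$fm, fx$clusters, seeds = 0:19, threshold = -1)
  common <- intersect(h1$attribution$feature, h2$attribution$feature)
  r1 <- h1$attribution$mean_abs_shap[match(common, h1$attribution$feature)]
  r2 <- h2$attribution$mean_abs_shap[match(common, h2$attribution$feature)]
  expect_gt(cor(r1, r2, method = "spearman"), 0.8)
})
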