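#' Assemble the flux matrix of growth-predicted simulations
#'
#' Rows are restricted to experiments the model predicts to grow (biomass
#' flux at or above the cutoff), since only those have meaningful flux
#' profiles; per-carbon wild-type flux vectors are kept alongside. Column
#' order equals the model reaction order used during simulation.
#'
#' @param grid the \code{list(predictions=, fluxes=)} returned by
#'   [knockout_grid()] with \code{record_fluxes = TRUE}.
#' @return a \code{flux_matrix}: list with \code{samples} (data.frame
#'   \code{gene}, \code{carbon}, \code{fitness}), \code{values}
#'   (samples x reactions matrix), \code{wild_type} (carbon -> flux matrix).
#' @export
assemble_flux_matrix <- function(grid) {
  pred <- grid$predictions
  fx <- grid$fluxes
  ko <- pred[pred$gene != "WT" & pred$grows, , drop = FALSE]
  if (nrow(ko) == 0L) stop("no growth-predicted knockout simulations to assemble")
  keys <- paste(ko$gene, ko$carbon, sep = "\r")
  miss <- !(keys %in% rownames(fx))
  if (any(miss)) stop("flux vectors missing for ", sum(miss), " growth rows")
  wt_pred <- pred[pred$gene == "WT", , drop = FALSE]
  wt_keys <- paste("WT", wt_pred$carbon, sep = "\r")
  wt <- fx[wt_keys[wt_keys %in% rownames(fx)], , drop = FALSE]
  rownames(wt) <- sub("^WT\r", "", rownames(wt))
  structure(list(samples = data.frame(gene = ko$gene, carbon = ko$carbon,
                                      fitness = ko$fitness,
                                      stringsAsFactors = FALSE),
                 values = unname(fx[keys, , drop = FALSE]) |>
                   `dimnames<-`(list(keys, colnames(fx))),
                 wild_type = wt),
            class = "flux_matrix")
}

#' Variance-filter and cluster covarying fluxes
#'
#' Columns with variance below \code{var_min} are discarded; the remaining
#' columns are joined by an edge whenever the absolute Pearson correlation
#' exceeds \code{corr_min} (sign-agnostic: a reaction and its exactly
#' opposite partner covary perfectly), and clusters are the connected
#' components. The representative of a cluster is its lowest-index column.
#'
#' @param values samples x reactions numeric matrix (or a
#'   \code{flux_matrix}, whose \code{values} are used).
#' @param var_min variance cutoff (default 1e-7).
#' @param corr_min absolute-correlation cutoff (default 0.99).
#' @return a \code{cluster_map}: list with \code{retained_columns},
#'   \code{clusters} (list of character vectors) and \code{representatives}.
#' @export
filter_and_cluster <- function(values, var_min = 1e-7, corr_min = 0.99) {
  if (inherits(values, "flux_matrix")) values <- values$values
  if (nrow(values) < 2L) stop("need at least two samples to cluster fluxes")
  v <- apply(values, 2, stats::var)
  retained <- colnames(values)[v >= var_min]
  if (length(retained) == 0L)
    return(structure(list(retained_columns = character(),
                          clusters = list(), representatives = character()),
                     class = "cluster_map"))
  x <- values[, retained, drop = FALSE]
  cm <- suppressWarnings(abs(stats::cor(x)))
  cm[is.na(cm)] <- 0
  adj <- cm > corr_min
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  clusters <- split(retained, comp)
  names(clusters) <- NULL
  reps <- vapply(clusters, function(cl)
    cl[which.min(match(cl, retained))], character(1))
  ord <- order(match(reps, retained))
  structure(list(retained_columns = retained,
                 clusters = clusters[ord],
                 representatives = reps[ord]),
            class = "cluster_map")
}

#' @export
print.cluster_map <- function(x, ...) {
  cat("Flux clustering:", length(x$retained_columns), "columns retained ->",
      length(x$clusters), "clusters\n")
  invisible(x)
}

#' Distance of each knockout flux vector from its wild type
#'
#' Euclidean distance of every sample to the wild-type flux vector on the
#' same carbon source, with its Pearson correlation against fitness and a
#' least-squares linear fit of fitness on distance.
#'
#' @param fm a \code{flux_matrix}.
#' @return list with \code{distance} (per-sample), \code{correlation}
#'   (Pearson, against fitness), and \code{fit} (the \code{lm} object).
#' @export
wildtype_distance <- function(fm) {
  wt <- fm$wild_type
  missing_wt <- setdiff(unique(fm$samples$carbon), rownames(wt))
  if (length(missing_wt))
    stop("no wild-type flux vector for carbon(s): ",
         paste(missing_wt, collapse = ", "))
  d <- vapply(seq_len(nrow(fm$values)), function(i) {
    sqrt(sum((fm$values[i, ] - wt[fm$samples$carbon[i], ])^2))
  }, numeric(1))
  keep <- !is.na(fm$samples$fitness)
  fit <- stats::lm(fitness ~ distance,
                   data = data.frame(fitness = fm$samples$fitness[keep],
                                     distance = d[keep]))
  list(distance = d,
       correlation = stats::cor(d[keep], fm$samples$fitness[keep]),
       fit = fit)
}

#' Draw a carbon/gene-stratified train/test split
#'
#' A uniform random 80\% of the carbon sources and 80\% of the genes (floor
#' rounding, minimum one) form the training pool; training rows are those
#' whose gene AND carbon are both in their pools. The full test set is every
#' other row; the unseen test set is the subset whose gene and carbon both
#' never appear in training.
#'
#' @param fm a \code{flux_matrix} (only its \code{samples} are used).
#' @param seed integer seed; the split is deterministic given it.
#' @param train_fraction fraction of carbons and of genes trained on.
#' @return a \code{split_spec}: list with \code{seed}, \code{train_carbons},
#'   \code{train_genes}, \code{train_rows}, \code{test_rows_full},
#'   \code{test_rows_unseen} (row indices into \code{fm$samples}).
#' @export
make_split <- function(fm, seed, train_fraction = 0.8) {
  s <- fm$samples
  carbons <- sort(unique(s$carbon))
  genes <- sort(unique(s$gene))
  if (length(carbons) < 2L || length(genes) < 2L)
    stop("need at least two carbons and two genes to split")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  tc <- sort(sample(carbons, max(1L, floor(train_fraction * length(carbons)))))
  tg <- sort(sample(genes, max(1L, floor(train_fraction * length(genes)))))
  in_tc <- s$carbon %in% tc
  in_tg <- s$gene %in% tg
  train <- which(in_tc & in_tg)
  test_full <- which(!(in_tc & in_tg))
  test_unseen <- which(!in_tc & !in_tg)
  structure(list(seed = seed, train_carbons = tc, train_genes = tg,
                 train_rows = train, test_rows_full = test_full,
                 test_rows_unseen = test_unseen),
            class = "split_spec")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Label growth-predicted samples as false or true positives
#'
#' A growth-predicted experiment is a false positive when its experimental
#' fitness shows a strong defect (strictly below the threshold) despite the
#' predicted growth, and a true positive otherwise.
#'
#' @param fm a \code{flux_matrix}.
#' @param threshold fitness cutoff, default -2 (a -1 sensitivity run is
#'   supported by changing it).
#' @return logical vector: TRUE = false positive.
#' @export
label_false_positives <- function(fm, threshold = -2) {
  fm$samples$fitness < threshold
}

#' Train the misprediction classifier
#'
#' Gradient-boosted decision trees on cluster-representative fluxes,
#' classifying growth-predicted samples into false positives versus true
#' positives: 100 trees, at most 5 leaves each, learning rate 0.1,
#' no row/column subsampling, deterministic given the seed.
#'
#' @param features numeric matrix (rows = samples, columns = representative
#'   fluxes).
#' @param labels logical or 0/1; TRUE/1 = false positive (the positive
#'   class).
#' @param seed integer seed.
#' @param num_leaves,n_trees,learning_rate ensemble hyperparameters.
#' @return an \code{xgb.Booster}.
#' @export
train_fp_classifier <- function(features, labels, seed = 0,
                                num_leaves = 5, n_trees = 100,
                                learning_rate = 0.1) {
  y <- as.numeric(labels)
  if (length(unique(y)) < 2L)
    stop("training labels contain a single class")
  dtrain <- xgboost::xgb.DMatrix(as.matrix(features), label = y, nthread = 1)
  xgboost::xgb.train(
    params = list(objective = "binary:logistic",
                  tree_method = "hist",
                  grow_policy = "lossguide",
                  max_leaves = num_leaves,
                  max_depth = 0,
                  eta = learning_rate,
                  subsample = 1, colsample_bytree = 1,
                  lambda = 0, alpha = 0,
                  min_child_weight = 1e-3,
                  nthread = 1,
                  seed = seed),
    data = dtrain, nrounds = n_trees, verbose = 0)
}

#' Precision-recall AUC of classifier scores
#'
#' @param scores predicted probabilities (or any monotone score) for the
#'   positive class.
#' @param labels logical/0-1 ground truth.
#' @return PR-AUC by the same threshold-enumeration and trapezoid rule used
#'   for the fitness evaluation.
#' @export
score_pr_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (sum(labels) == 0L) return(NaN)
  pr_auc_from_points(pr_curve_points(scores, labels))
}

#' Run the repeated-split classification and attribution harness
#'
#' For each seed: draw a carbon/gene-stratified split, train the classifier
#' on the training rows, and score the false-positive class PR-AUC on the
#' full test set, the unseen-carbon/gene test subset, and the full test set
#' with permuted labels. Per-sample Shapley values (exact tree-path
#' attribution) for the true-positive class are computed on all samples and
#' averaged across splits.
#'
#' @param fm a \code{flux_matrix}.
#' @param clusters a \code{cluster_map} (its representatives become the
#'   features).
#' @param labels logical vector, TRUE = false positive; default derives from
#'   fitness at -2 via [label_false_positives()].
#' @param seeds integer vector of split seeds (default 0:99).
#' @param threshold fitness threshold used when \code{labels} is NULL.
#' @return list with \code{results} (data.frame seed, auc_full, auc_unseen,
#'   auc_permuted, fp_rate_test), \code{attribution} (data.frame feature,
#'   mean_abs_shap, rank), \code{shap_mean} (samples x features matrix of
#'   split-averaged TP-class Shapley values), and \code{per_split_rank}
#'   (splits x features matrix of each feature's importance rank within a
#'   split).
#' @export
run_split_harness <- function(fm, clusters, labels = NULL, seeds = 0:99,
                              threshold = -2) {
  if (is.null(labels)) labels <- label_false_positives(fm, threshold)
  feats <- fm$values[, clusters$representatives, drop = FALSE]
  res <- vector("list", length(seeds))
  shap_sum <- matrix(0, nrow(feats), ncol(feats),
                     dimnames = dimnames(feats))
  rank_mat <- matrix(NA_integer_, length(seeds), ncol(feats),
                     dimnames = list(as.character(seeds), colnames(feats)))
  n_shap <- 0L
  for (k in seq_along(seeds)) {
    sd <- seeds[k]
    sp <- make_split(fm, sd)
    ytr <- labels[sp$train_rows]
    if (length(unique(ytr)) < 2L) {
      res[[k]] <- data.frame(seed = sd, auc_full = NA, auc_unseen = NA,
                             auc_permuted = NA, fp_rate_test = NA)
      next
    }
    clf <- train_fp_classifier(feats[sp$train_rows, , drop = FALSE], ytr,
                               seed = sd)
    p_full <- stats::predict(clf, feats[sp$test_rows_full, , drop = FALSE])
    p_unseen <- if (length(sp$test_rows_unseen))
      stats::predict(clf, feats[sp$test_rows_unseen, , drop = FALSE]) else numeric(0)
    y_full <- labels[sp$test_rows_full]
    y_unseen <- labels[sp$test_rows_unseen]
    old <- .Random.seed_save(); set.seed(sd + 1000003L)
    y_perm <- sample(y_full)
    .Random.seed_restore(old)
    res[[k]] <- data.frame(
      seed = sd,
      auc_full = score_pr_auc(p_full, y_full),
      auc_unseen = if (length(y_unseen) && sum(y_unseen) > 0)
        score_pr_auc(p_unseen, y_unseen) else NA_real_,
      auc_permuted = score_pr_auc(p_full, y_perm),
      fp_rate_test = mean(y_full))
    shap_split <- attribute_features(clf, feats)$shap
    shap_sum <- shap_sum + shap_split
    imp_split <- colMeans(abs(shap_split))
    rank_mat[k, ] <- rank(-imp_split, ties.method = "first")
    n_shap <- n_shap + 1L
  }
  shap_mean <- shap_sum / max(n_shap, 1L)
  imp <- data.frame(feature = colnames(feats),
                    mean_abs_shap = colMeans(abs(shap_mean)),
                    stringsAsFactors = FALSE)
  imp <- imp[order(-imp$mean_abs_shap, imp$feature), , drop = FALSE]
  imp$rank <- seq_len(nrow(imp))
  rownames(imp) <- NULL
  list(results = do.call(rbind, res),
       attribution = imp,
       shap_mean = shap_mean,
       per_split_rank = rank_mat)
}

#' Shapley attribution of the classifier
#'
#' Exact tree-path Shapley values per sample and feature for the
#' true-positive class (the booster is trained on the false-positive class,
#' so TP-class values are the negated contributions). The default "fast"
#' engine uses the booster's built-in contribution pass (single-precision
#' output); the "exact64" engine re-evaluates the same algorithm in double
#' precision from the dumped tree structure, so that additivity -- bias plus
#' per-feature contributions reconstructing each sample's margin -- holds to
#' numerical round-off.
#'
#' @param classifier an \code{xgb.Booster} from [train_fp_classifier()].
#' @param features samples x features matrix.
#' @param engine "fast" or "exact64".
#' @return list with \code{shap} (samples x features, TP-class values),
#'   \code{bias} (per-sample base value, TP class), \code{margin}
#'   (per-sample TP-class margin, equal to bias + rowSums(shap)).
#' @export
attribute_features <- function(classifier, features,
                               engine = c("fast", "exact64")) {
  engine <- match.arg(engine)
  features <- as.matrix(features)
  if (engine == "exact64") {
    res <- treeshap_exact(classifier, features)
    return(list(shap = -res$shap, bias = -res$bias, margin = -res$margin))
  }
  contrib <- stats::predict(classifier, features, predcontrib = TRUE)
  bias_col <- which(colnames(contrib) %in% c("BIAS", "(Intercept)"))
  shap_fp <- contrib[, -bias_col, drop = FALSE]
  bias_fp <- contrib[, bias_col]
  margin_fp <- stats::predict(classifier, features, outputmargin = TRUE)
  list(shap = -shap_fp, bias = -bias_fp, margin = -margin_fp)
}

#' Principal-component coordinates of the flux matrix
#'
#' @param fm a \code{flux_matrix}.
#' @param n_components number of components to return.
#' @param scale. standardize columns first (default FALSE: raw fluxes).
#' @return data.frame of sample coordinates with the sample metadata bound.
#' @export
flux_pca <- function(fm, n_components = 2, scale. = FALSE) {
  keep <- apply(fm$values, 2, stats::var) > 0
  pc <- stats::prcomp(fm$values[, keep, drop = FALSE], scale. = scale.)
  k <- min(n_components, ncol(pc$x))
  cbind(fm$samples, as.data.frame(pc$x[, seq_len(k), drop = FALSE]))
}
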