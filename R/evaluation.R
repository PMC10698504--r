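# Precision-recall machinery shared by the fitness-thresholded evaluation
# and the misprediction classifier: scores rank the evidence for the
# positive class, thresholds enumerate the unique score values, and the
# area is integrated by trapezoid with the conventional (recall 0,
# precision 1) anchor.
pr_curve_points <- function(scores, positive) {
  stopifnot(length(scores) == length(positive))
  n_pos <- sum(positive)
  thr <- sort(unique(scores), decreasing = TRUE)  # most positive-like first
  recall <- precision <- numeric(length(thr))
  ord <- order(scores, decreasing = TRUE)
  s_sorted <- scores[ord]
  p_sorted <- positive[ord]
  cum_tp <- cumsum(p_sorted)
  # last index with score >= threshold
  idx <- findInterval(-thr, -s_sorted)
  tp <- cum_tp[idx]
  called <- idx
  precision <- tp / called
  recall <- tp / n_pos
  data.frame(threshold = thr, recall = recall, precision = precision)
}

pr_auc_from_points <- function(points) {
  r <- c(0, points$recall)
  p <- c(1, points$precision)
  sum(diff(r) * (utils::head(p, -1) + utils::tail(p, -1)) / 2)
}

roc_auc_score <- function(scores, positive) {
  n_pos <- sum(positive); n_neg <- sum(!positive)
  if (n_pos == 0 || n_neg == 0) return(NaN)
  rk <- rank(scores)  # ties averaged
  (sum(rk[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Evaluate growth predictions against fitness values
#'
#' The positive class is simulated essentiality (model no-growth); the
#' negated fitness value is the sliding score, so lower fitness counts as
#' stronger evidence of essentiality. A gene-condition pair is called
#' "experimentally essential" at threshold t when its fitness is <= t.
#' Precision and recall are traced over every unique fitness value and the
#' area is integrated by trapezoid with a (recall 0, precision 1) anchor.
#' Alternative metrics (ROC AUC, balanced accuracy, overall accuracy and the
#' confusion matrix) are computed at a fixed experimental growth/no-growth
#' fitness threshold (default -2, strict: fitness < -2 is experimental
#' no-growth).
#'
#' @param table a \code{prediction_table}; wild-type rows and rows without a
#'   fitness value are excluded.
#' @param accuracy_threshold fitness cutoff for the fixed-threshold metrics.
#' @return an \code{evaluation_report}: list with \code{pr_points}
#'   (threshold, recall, precision), \code{auc_pr}, \code{auc_roc},
#'   \code{balanced_accuracy}, \code{overall_accuracy}, \code{confusion}
#'   (tp, fp, tn, fn), \code{n_records}. Metrics that are undefined (for
#'   example with zero model-essential rows) are NaN with a warning, never
#'   silently 0.
#' @export
evaluate_predictions <- function(table, accuracy_threshold = -2) {
  tab <- table[table$gene != "WT" & !is.na(table$fitness), , drop = FALSE]
  n <- nrow(tab)
  essential <- !tab$grows
  if (n == 0L || sum(essential) == 0L) {
    warning("no model-essential rows with fitness: PR-AUC is undefined (NaN)")
    pts <- data.frame(threshold = numeric(), recall = numeric(),
                      precision = numeric())
    return(structure(list(pr_points = pts, auc_pr = NaN, auc_roc = NaN,
                          balanced_accuracy = NaN, overall_accuracy = NaN,
                          confusion = c(tp = 0, fp = 0, tn = 0, fn = 0),
                          n_records = n),
                     class = "evaluation_report"))
  }
  # score = -fitness: "fitness <= t" is "score >= -t"
  pts_raw <- pr_curve_points(-tab$fitness, essential)
  pts <- data.frame(threshold = -pts_raw$threshold,
                    recall = pts_raw$recall,
                    precision = pts_raw$precision)
  auc_pr <- pr_auc_from_points(pts_raw)
  auc_roc <- roc_auc_score(-tab$fitness, essential)

  exp_ess <- tab$fitness < accuracy_threshold
  tp <- sum(essential & exp_ess)
  fp <- sum(essential & !exp_ess)
  fn <- sum(!essential & exp_ess)
  tn <- sum(!essential & !exp_ess)
  tpr <- if (tp + fn > 0) tp / (tp + fn) else NaN
  tnr <- if (tn + fp > 0) tn / (tn + fp) else NaN
  structure(list(pr_points = pts,
                 auc_pr = auc_pr,
                 auc_roc = auc_roc,
                 balanced_accuracy = (tpr + tnr) / 2,
                 overall_accuracy = (tp + tn) / n,
                 confusion = c(tp = tp, fp = fp, tn = tn, fn = fn),
                 n_records = n),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Evaluation of", x$n_records, "gene x carbon predictions\n")
  cat(sprintf("  PR-AUC %.4f | ROC-AUC %.4f | balanced acc %.4f | overall acc %.4f\n",
              x$auc_pr, x$auc_roc, x$balanced_accuracy, x$overall_accuracy))
  cat(sprintf("  confusion at the fitness threshold: TP %d FP %d TN %d FN %d\n",
              x$confusion["tp"], x$confusion["fp"],
              x$confusion["tn"], x$confusion["fn"]))
  invisible(x)
}

#' Pad a prediction table with null experiments
#'
#' Appends nonfunctional-gene experiments -- fitness exactly 0, predicted
#' growth -- until the table reaches the target experiment count. Used to
#' compare accuracy metrics across models of different gene counts on an
#' equal footing and to probe a metric's robustness to trivially correct
#' predictions.
#'
#' @param table a \code{prediction_table}.
#' @param target_n_experiments total number of non-wild-type rows after
#'   padding; must be >= the current count.
#' @return the padded \code{prediction_table}.
#' @export
pad_null <- function(table, target_n_experiments) {
  cur <- sum(table$gene != "WT")
  if (target_n_experiments < cur)
    stop("target_n_experiments (", target_n_experiments,
         ") is below the current experiment count (", cur, ")")
  extra <- target_n_experiments - cur
  if (extra == 0L) return(table)
  carbons <- unique(table$carbon)
  n_genes <- ceiling(extra / length(carbons))
  pad <- expand.grid(gene = sprintf("null_%05d", seq_len(n_genes)),
                     carbon = carbons, stringsAsFactors = FALSE)
  pad <- pad[seq_len(extra), , drop = FALSE]
  pad <- data.frame(gene = pad$gene, carbon = pad$carbon,
                    biomass_flux = Inf, grows = TRUE, fitness = 0,
                    stringsAsFactors = FALSE)
  pad$biomass_flux <- max(table$biomass_flux[table$grows], 1)
  out <- rbind(as.data.frame(table), pad)
  class(out) <- c("prediction_table", "data.frame")
  out
}

#' Per-carbon-source PR-AUC
#'
#' @param table a \code{prediction_table}.
#' @param accuracy_threshold passed to [evaluate_predictions()].
#' @return named numeric vector carbon -> PR-AUC (NaN, with a warning, for
#'   carbons without any model-essential prediction).
#' @export
per_carbon_auc <- function(table, accuracy_threshold = -2) {
  carbons <- unique(table$carbon[table$gene != "WT"])
  vapply(stats::setNames(carbons, carbons), function(cb) {
    evaluate_predictions(table[table$carbon == cb, , drop = FALSE],
                         accuracy_threshold = accuracy_threshold)$auc_pr
  }, numeric(1))
}

#' Rank candidate mispredicted genes
#'
#' Within the model-essential prediction class, genes with high mean fitness
#' are false-negative candidates (predicted essential, no experimental
#' phenotype); within the model-growth class, genes with low mean fitness
#' are false-positive candidates (predicted nonessential, strong fitness
#' defect). Ties break by gene id for determinism.
#'
#' @param table a \code{prediction_table}.
#' @return list with data.frames \code{false_negative_genes} (descending
#'   mean fitness over model-essential rows) and \code{false_positive_genes}
#'   (ascending mean fitness over model-growth rows), each with columns
#'   \code{gene}, \code{mean_fitness}, \code{n}.
#' @export
rank_errors <- function(table) {
  tab <- table[table$gene != "WT" & !is.na(table$fitness), , drop = FALSE]
  agg <- function(rows) {
    if (nrow(rows) == 0L)
      return(data.frame(gene = character(), mean_fitness = numeric(),
                        n = integer(), stringsAsFactors = FALSE))
    sp <- split(rows$fitness, rows$gene)
    data.frame(gene = names(sp),
               mean_fitness = vapply(sp, mean, numeric(1)),
               n = vapply(sp, length, integer(1)),
               row.names = NULL, stringsAsFactors = FALSE)
  }
  fn <- agg(tab[!tab$grows, , drop = FALSE])
  fn <- fn[order(-fn$mean_fitness, fn$gene), , drop = FALSE]
  fp <- agg(tab[tab$grows, , drop = FALSE])
  fp <- fp[order(fp$mean_fitness, fp$gene), , drop = FALSE]
  rownames(fn) <- rownames(fp) <- NULL
  list(false_negative_genes = fn, false_positive_genes = fp)
}
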