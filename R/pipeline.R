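#' Simulate growth predictions for a fitness dataset
#'
#' End-to-end simulation stage: matches the dataset to the model, optionally
#' removes unconditionally essential genes from the evaluation (pooled
#' fitness assays cannot phenotype them reliably), and runs the knockout
#' grid under the given scenario.
#'
#' @param model a \code{metabolic_model}.
#' @param dataset a \code{fitness_dataset}.
#' @param scenario a [scenario_spec()].
#' @param carbon_map override map for irregular carbon ids (see
#'   [match_dataset_to_model()]).
#' @param filter_unconditional drop unconditionally essential genes
#'   (default TRUE).
#' @param record_fluxes record parsimonious flux vectors (default FALSE).
#' @param growth_cutoff biomass growth cutoff (default 0.001).
#' @return list with \code{predictions} (a \code{prediction_table}),
#'   \code{fluxes} (matrix or NULL), \code{matched} (the match report) and
#'   \code{excluded_genes} (unconditionally essential genes dropped).
#' @export
simulate_predictions <- function(model, dataset, scenario = scenario_spec(),
                                 carbon_map = character(),
                                 filter_unconditional = TRUE,
                                 record_fluxes = FALSE,
                                 growth_cutoff = 0.001) {
  matched <- match_dataset_to_model(model, dataset, carbon_map = carbon_map)
  genes <- matched$genes
  excluded <- character()
  if (filter_unconditional) {
    excluded <- intersect(find_unconditional_essentials(
      model, growth_cutoff = growth_cutoff), genes)
    genes <- setdiff(genes, excluded)
  }
  if (length(genes) == 0L) stop("no matched genes to simulate")
  res <- knockout_grid(model, genes, matched$carbons, scenario = scenario,
                       fitness = dataset, record_fluxes = record_fluxes,
                       growth_cutoff = growth_cutoff)
  if (record_fluxes)
    list(predictions = res$predictions, fluxes = res$fluxes,
         matched = matched, excluded_genes = excluded)
  else
    list(predictions = res, fluxes = NULL, matched = matched,
         excluded_genes = excluded)
}

#' Evaluate several models on a shared dataset with null padding
#'
#' Each prediction table is padded with null experiments (nonfunctional
#' genes: fitness 0, predicted growth) up to the largest experiment count,
#' then evaluated, so that models with different gene coverage are compared
#' on an equal footing.
#'
#' @param tables named list of \code{prediction_table}s.
#' @param accuracy_threshold fitness threshold for the fixed-threshold
#'   metrics (default -2).
#' @return data.frame with one row per model: experiment counts and the
#'   raw and null-padded PR-AUC, balanced accuracy and overall accuracy.
#' @export
compare_models <- function(tables, accuracy_threshold = -2) {
  stopifnot(length(tables) >= 1)
  if (is.null(names(tables)))
    names(tables) <- sprintf("model_%d", seq_along(tables))
  counts <- vapply(tables, function(t) sum(t$gene != "WT"), numeric(1))
  target <- max(counts)
  do.call(rbind, lapply(names(tables), function(nm) {
    raw <- evaluate_predictions(tables[[nm]],
                                accuracy_threshold = accuracy_threshold)
    pad <- evaluate_predictions(pad_null(tables[[nm]], target),
                                accuracy_threshold = accuracy_threshold)
    data.frame(model = nm, n_experiments = counts[[nm]],
               n_padded = target,
               auc_pr = raw$auc_pr, auc_pr_padded = pad$auc_pr,
               balanced_accuracy = raw$balanced_accuracy,
               balanced_accuracy_padded = pad$balanced_accuracy,
               overall_accuracy = raw$overall_accuracy,
               overall_accuracy_padded = pad$overall_accuracy,
               stringsAsFactors = FALSE)
  }))
}

#' Write a prediction table to TSV
#' @param table a \code{prediction_table}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_predictions <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an evaluation report to JSON (PR points inline)
#' @param report an \code{evaluation_report}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_evaluation <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

#' Write a synthetic benchmark to disk
#'
#' Writes the toy model (JSON), the replicate-level fitness table (TSV) and
#' the ground-truth table (TSV) into a directory, giving a self-contained
#' on-disk fixture for the full pipeline.
#'
#' @param toy result of [build_toy_gem()].
#' @param fitness a \code{fitness_dataset} from [simulate_fitness()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_synthetic_benchmark <- function(toy, fitness, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_model(toy$model, file.path(dir, "model.json"))
  utils::write.table(fitness$replicates, file.path(dir, "fitness.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(toy$truth, file.path(dir, "ground_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
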