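#' Build a fitness dataset from replicate-level rows
#'
#' Pooled mutant fitness assays report one fitness value per gene, condition
#' and replicate; replicates are averaged before comparison with model
#' predictions. Rows with missing fitness are dropped and counted; excluded
#' carbon sources (for example conditions with known media problems) are
#' removed entirely.
#'
#' @param rows data.frame with columns \code{gene}, \code{carbon},
#'   \code{fitness} (one row per replicate).
#' @param exclusions character vector of carbon ids to drop.
#' @return an object of class \code{fitness_dataset}: \code{records}
#'   (data.frame \code{gene}, \code{carbon}, \code{mean_fitness},
#'   \code{n_replicates}), \code{replicates} (the retained raw rows),
#'   \code{genes}, \code{carbon_sources}, \code{exclusions},
#'   \code{n_dropped_missing}.
#' @export
fitness_dataset <- function(rows, exclusions = character()) {
  required <- c("gene", "carbon", "fitness")
  missing_cols <- setdiff(required, names(rows))
  if (length(missing_cols))
    stop("schema error: fitness table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  rows <- rows[, required, drop = FALSE]
  rows$gene <- as.character(rows$gene)
  rows$carbon <- as.character(rows$carbon)
  rows$fitness <- as.numeric(rows$fitness)

  n_missing <- sum(is.na(rows$fitness))
  rows <- rows[!is.na(rows$fitness), , drop = FALSE]
  rows <- rows[!(rows$carbon %in% exclusions), , drop = FALSE]

  if (nrow(rows) == 0L) {
    warning("fitness dataset is empty after filtering")
    records <- data.frame(gene = character(), carbon = character(),
                          mean_fitness = numeric(), n_replicates = integer(),
                          stringsAsFactors = FALSE)
  } else {
    key <- interaction(rows$gene, rows$carbon, drop = TRUE, sep = "\r")
    records <- do.call(rbind, lapply(split(rows, key), function(d) {
      data.frame(gene = d$gene[1L], carbon = d$carbon[1L],
                 mean_fitness = mean(d$fitness),
                 n_replicates = nrow(d), stringsAsFactors = FALSE)
    }))
    records <- records[order(records$gene, records$carbon), , drop = FALSE]
    rownames(records) <- NULL
  }
  structure(list(records = records,
                 replicates = rows,
                 genes = sort(unique(records$gene)),
                 carbon_sources = sort(unique(records$carbon)),
                 exclusions = exclusions,
                 n_dropped_missing = n_missing),
            class = "fitness_dataset")
}

#' @export
print.fitness_dataset <- function(x, ...) {
  cat("Fitness dataset:", nrow(x$records), "gene x carbon records,",
      length(x$genes), "genes,", length(x$carbon_sources), "carbon sources\n")
  if (x$n_dropped_missing > 0)
    cat("  (", x$n_dropped_missing, "replicate rows dropped for missing fitness)\n")
  invisible(x)
}

#' Read a replicate-level fitness TSV
#'
#' Expects a tab-separated file with header columns \code{gene},
#' \code{carbon}, \code{fitness}, one row per replicate measurement.
#'
#' @param path TSV file path.
#' @param exclusions carbon ids to exclude from the analysis.
#' @return a [fitness_dataset()].
#' @export
read_fitness <- function(path, exclusions = character()) {
  if (!file.exists(path)) stop("fitness file not found: ", path)
  rows <- utils::read.delim(path, stringsAsFactors = FALSE, sep = "\t")
  fitness_dataset(rows, exclusions = exclusions)
}

#' Match a fitness dataset against a metabolic model
#'
#' Genes match by identity of identifiers. A carbon source id \code{X}
#' matches the extracellular metabolite \code{X_e}; irregular names are
#' resolved through an explicit override map.
#'
#' @param model a \code{metabolic_model}.
#' @param dataset a \code{fitness_dataset}.
#' @param carbon_map named character vector mapping carbon ids to metabolite
#'   ids, overriding the default \code{X -> X_e} rule.
#' @return list with \code{genes} (matched gene ids), \code{carbons}
#'   (data.frame \code{carbon}, \code{metabolite}) and \code{unmatched}
#'   (data.frame \code{id}, \code{kind}, \code{reason}).
#' @export
match_dataset_to_model <- function(model, dataset, carbon_map = character()) {
  genes <- intersect(dataset$genes, model$genes)
  un_genes <- setdiff(dataset$genes, model$genes)

  carbons <- character(0); met_ids <- character(0)
  un_carbons <- character(0); reasons <- character(0)
  for (cb in dataset$carbon_sources) {
    target <- if (cb %in% names(carbon_map)) carbon_map[[cb]] else paste0(cb, "_e")
    if (target %in% model$metabolites$id) {
      carbons <- c(carbons, cb); met_ids <- c(met_ids, target)
    } else {
      un_carbons <- c(un_carbons, cb)
      reasons <- c(reasons, paste0("no metabolite '", target, "' in model"))
    }
  }
  unmatched <- rbind(
    if (length(un_genes))
      data.frame(id = un_genes, kind = "gene",
                 reason = "gene absent from model", stringsAsFactors = FALSE),
    if (length(un_carbons))
      data.frame(id = un_carbons, kind = "carbon",
                 reason = reasons, stringsAsFactors = FALSE))
  if (is.null(unmatched))
    unmatched <- data.frame(id = character(), kind = character(),
                            reason = character(), stringsAsFactors = FALSE)
  list(genes = genes,
       carbons = data.frame(carbon = carbons, metabolite = met_ids,
                            stringsAsFactors = FALSE),
       unmatched = unmatched)
}
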