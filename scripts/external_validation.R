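#!/usr/bin/env Rscript
# Optional integration run against real inputs (not part of the test suite):
# a user-downloaded genome-scale E. coli model in the constraint-based JSON
# dialect and a replicate-level mutant fitness TSV (columns: gene, carbon,
# fitness). Carbon ids that do not follow the `X -> X_e` metabolite rule
# need an override map (CSV: carbon,metabolite).
#
# Usage:
#   Rscript scripts/external_validation.R --model iML1515.json \
#     --fitness fitness.tsv [--carbon-map map.csv] [--exclude sucrose,mannitol]
#
# Note: a genome-scale run solves tens of thousands of LPs with the
# package's dense simplex; expect hours, not minutes. The pipeline is
# exercised end to end on synthetic models by tests and scripts/acceptance.R.

suppressMessages({
  library(optparse)
  library(gemscreen)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--model", type = "character"),
  make_option("--fitness", type = "character"),
  make_option("--carbon-map", type = "character", default = NULL,
              dest = "carbon_map"),
  make_option("--exclude", type = "character", default = "sucrose,mannitol"),
  make_option("--out", type = "character", default = "results/external")
)))
stopifnot(!is.null(opts$model), !is.null(opts$fitness))

model <- read_model(opts$model)
exclusions <- strsplit(opts$exclude, ",")[[1]]
dataset <- read_fitness(opts$fitness, exclusions = exclusions)
carbon_map <- character()
if (!is.null(opts$carbon_map)) {
  cm <- utils::read.csv(opts$carbon_map, stringsAsFactors = FALSE)
  carbon_map <- stats::setNames(cm$metabolite, cm$carbon)
}

# minimal M9-style base medium; adjust the component list to the model
base_components <- c("EX_pi_e", "EX_co2_e", "EX_fe3_e", "EX_h_e", "EX_mn2_e",
                     "EX_fe2_e", "EX_zn2_e", "EX_mg2_e", "EX_ca2_e",
                     "EX_ni2_e", "EX_cu2_e", "EX_sel_e", "EX_cobalt2_e",
                     "EX_h2o_e", "EX_mobd_e", "EX_so4_e", "EX_nh4_e",
                     "EX_k_e", "EX_na1_e", "EX_cl_e", "EX_o2_e",
                     "EX_tungs_e", "EX_slnt_e")
base_components <- intersect(base_components, model$reactions$id)
medium <- medium_spec(components = stats::setNames(
  rep(-1000, length(base_components)), base_components))

scen <- scenario_spec(medium = medium)
res <- simulate_predictions(model, dataset, scen, carbon_map = carbon_map)
report <- evaluate_predictions(res$predictions)
dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
write_predictions(res$predictions, file.path(opts$out, "predictions.tsv"))
write_evaluation(report, file.path(opts$out, "evaluation.json"))
print(report)
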