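#' Specify a growth medium
#'
#' A medium closes every exchange, reopens the listed non-carbon components
#' (unlimited uptake, lower bound -1000 by convention) and opens the carbon
#' source at the carbon uptake bound (-10 by default). When the carbon source
#' coincides with a base component the carbon bound wins, since carbon
#' limitation is the experimentally meaningful constraint.
#'
#' @param components named numeric vector: exchange reaction id -> lower
#'   bound (all must be <= 0).
#' @param carbon_source extracellular metabolite id of the carbon source
#'   (may be NULL here and supplied at application time).
#' @param carbon_uptake_bound uptake bound for the carbon source, default -10
#'   mmol/(gdw x h).
#' @return an object of class \code{medium_spec}.
#' @export
medium_spec <- function(components = numeric(), carbon_source = NULL,
                        carbon_uptake_bound = -10) {
  if (length(components) && any(components > 0))
    stop("medium component lower bounds must be <= 0")
  structure(list(components = components,
                 carbon_source = carbon_source,
                 carbon_uptake_bound = carbon_uptake_bound),
            class = "medium_spec")
}

exchange_for_metabolite <- function(model, metabolite_id) {
  ex <- which(model$reactions$is_exchange)
  for (j in ex) {
    col <- model$S[, j]
    if (names(col[col != 0]) == metabolite_id) return(model$reactions$id[j])
  }
  NA_character_
}

add_exchange_reaction <- function(model, metabolite_id, lower = -1000,
                                  upper = 0, id = NULL) {
  if (!metabolite_id %in% model$metabolites$id)
    stop("no metabolite '", metabolite_id, "' in model")
  if (is.null(id)) id <- paste0("EX_", metabolite_id)
  if (id %in% model$reactions$id)
    stop("reaction id '", id, "' already exists")
  model$reactions <- rbind(model$reactions,
    data.frame(id = id, name = paste("Exchange of", metabolite_id),
               lower_bound = lower, upper_bound = upper,
               gene_reaction_rule = "", is_exchange = TRUE,
               stringsAsFactors = FALSE))
  newcol <- Matrix::sparseMatrix(
    i = match(metabolite_id, model$metabolites$id), j = 1L, x = -1,
    dims = c(nrow(model$metabolites), 1L),
    dimnames = list(model$metabolites$id, id))
  model$S <- cbind(model$S, newcol)
  model$gpr[[id]] <- NULL
  model$gpr[id] <- list(NULL)
  model
}

#' Apply a medium to a model
#'
#' All exchange lower bounds are first closed to 0, then the listed
#' components are opened to their stated bounds, and finally the carbon
#' source exchange is set to the carbon uptake bound (an exchange reaction is
#' created if the extracellular metabolite has none).
#'
#' @param model a \code{metabolic_model}.
#' @param medium a [medium_spec()].
#' @param carbon_metabolite optional metabolite id overriding
#'   \code{medium$carbon_source}.
#' @return the adjusted model.
#' @export
apply_medium <- function(model, medium, carbon_metabolite = NULL) {
  model$reactions$lower_bound[model$reactions$is_exchange] <- 0
  comp <- medium$components
  unknown <- setdiff(names(comp), model$reactions$id)
  if (length(unknown))
    stop("medium component exchange(s) not in model: ",
         paste(unknown, collapse = ", "))
  if (length(comp)) {
    idx <- match(names(comp), model$reactions$id)
    model$reactions$lower_bound[idx] <- unname(comp)
  }
  carbon <- if (!is.null(carbon_metabolite)) carbon_metabolite else
    medium$carbon_source
  if (!is.null(carbon)) {
    ex_id <- exchange_for_metabolite(model, carbon)
    if (is.na(ex_id)) {
      if (!carbon %in% model$metabolites$id)
        stop("carbon source metabolite '", carbon, "' not in model")
      model <- add_exchange_reaction(model, carbon,
                                     lower = medium$carbon_uptake_bound,
                                     upper = 1000)
      ex_id <- paste0("EX_", carbon)
    }
    idx <- match(ex_id, model$reactions$id)
    if (ex_id %in% names(comp) &&
        comp[[ex_id]] != medium$carbon_uptake_bound)
      message("carbon source exchange '", ex_id,
              "' also listed as medium component; carbon bound (",
              medium$carbon_uptake_bound, ") takes precedence")
    model$reactions$lower_bound[idx] <- medium$carbon_uptake_bound
  }
  model
}

#' Supplement the medium with a vitamin or cofactor
#'
#' Extracellular mode opens (or creates) the exchange of the extracellular
#' species to unlimited uptake. Intracellular mode creates an uptake-only
#' exchange directly on the cytoplasmic species, bounds (-1000, 0) -- the
#' minimal mechanism for a metabolite the model cannot transport, and
#' uptake-only so no spurious secretion credit arises.
#'
#' @param model a \code{metabolic_model}.
#' @param metabolite_id metabolite to supply (the extracellular species for
#'   extracellular mode, the cytoplasmic species for intracellular mode).
#' @param mode "extracellular" or "intracellular".
#' @return the adjusted model.
#' @export
add_supplement <- function(model, metabolite_id,
                           mode = c("extracellular", "intracellular")) {
  mode <- match.arg(mode)
  if (!metabolite_id %in% model$metabolites$id)
    stop("no metabolite '", metabolite_id, "' in model")
  if (mode == "extracellular") {
    ex_id <- exchange_for_metabolite(model, metabolite_id)
    if (is.na(ex_id))
      stop("metabolite '", metabolite_id, "' has no exchange reaction; ",
           "consider mode = 'intracellular'")
    idx <- match(ex_id, model$reactions$id)
    model$reactions$lower_bound[idx] <- min(model$reactions$lower_bound[idx],
                                            -1000)
  } else {
    ex_id <- paste0("EX_", metabolite_id, "_supplement")
    if (!ex_id %in% model$reactions$id) {
      model <- add_exchange_reaction(model, metabolite_id, lower = -1000,
                                     upper = 0, id = ex_id)
    } else {
      # re-applying a scenario must reopen the uptake the medium reset
      idx <- match(ex_id, model$reactions$id)
      model$reactions$lower_bound[idx] <- -1000
    }
  }
  model
}

#' Make a reaction irreversible
#'
#' Sets the lower bound to 0, leaving the upper bound unchanged. Used for
#' reactions whose reverse direction does not operate in vivo but lets the
#' model bypass a biosynthesis pathway.
#'
#' @param model a \code{metabolic_model}.
#' @param reaction_id reaction to constrain.
#' @return the adjusted model.
#' @export
set_irreversible <- function(model, reaction_id) {
  idx <- match(reaction_id, model$reactions$id)
  if (is.na(idx)) stop("unknown reaction id: ", reaction_id)
  if (reaction_id == model$biomass_reaction_id)
    warning("making the biomass reaction irreversible")
  model$reactions$lower_bound[idx] <- max(model$reactions$lower_bound[idx], 0)
  model
}

#' Reassign an isoenzyme rule to a single gene
#'
#' Rewrites the reaction's GPR to the single literal of the given gene,
#' removing OR alternatives that rescue its knockout in silico although the
#' alternative enzyme is not expressed under the assay conditions.
#'
#' @param model a \code{metabolic_model}.
#' @param gene_id gene made solely responsible.
#' @param reaction_id the reaction whose rule is rewritten.
#' @return the adjusted model.
#' @export
reassign_isoenzyme <- function(model, gene_id, reaction_id) {
  idx <- match(reaction_id, model$reactions$id)
  if (is.na(idx)) stop("unknown reaction id: ", reaction_id)
  if (!gene_id %in% gpr_genes(model$gpr[[reaction_id]]))
    stop("gene '", gene_id, "' does not appear in the GPR of '",
         reaction_id, "'")
  model$gpr[[reaction_id]] <- list(type = "gene", gene = gene_id)
  model$reactions$gene_reaction_rule[idx] <- gene_id
  model
}

#' Remove strain-absent genes and their orphaned reactions
#'
#' Models a strain difference: the listed genes are deleted from the gene
#' set and any reaction whose GPR evaluates FALSE without them is removed
#' from the model entirely (unlike [apply_knockout()], which zero-bounds).
#'
#' @param model a \code{metabolic_model}.
#' @param genes gene ids absent from the assayed strain; unknown ids are
#'   skipped with a message.
#' @return the reduced model.
#' @export
remove_strain_genes <- function(model, genes) {
  if (length(genes) == 0L) return(model)
  unknown <- setdiff(genes, model$genes)
  if (length(unknown))
    message("skipping gene(s) not in model: ", paste(unknown, collapse = ", "))
  genes <- intersect(genes, model$genes)
  if (length(genes) == 0L) return(model)
  gone <- knockout_disabled_reactions(model, genes)
  keep <- !(model$reactions$id %in% gone)
  model$reactions <- model$reactions[keep, , drop = FALSE]
  model$S <- model$S[, keep, drop = FALSE]
  model$gpr <- model$gpr[keep]
  model$genes <- setdiff(model$genes, genes)
  # prune deleted genes from surviving OR rules by re-serializing
  model
}

#' Fix the flux of a reaction
#'
#' Overwrites (does not intersect) the reaction's bounds with
#' \code{(lower, upper)}. Used, for example, to pin an exchange flux to a
#' constant or to shut a reaction off entirely.
#'
#' @param model a \code{metabolic_model}.
#' @param reaction_id reaction to constrain.
#' @param lower,upper new bounds, \code{lower <= upper}.
#' @return the adjusted model.
#' @export
fix_flux <- function(model, reaction_id, lower, upper) {
  if (lower > upper) stop("fix_flux: lower > upper")
  idx <- match(reaction_id, model$reactions$id)
  if (is.na(idx)) stop("unknown reaction id: ", reaction_id)
  model$reactions$lower_bound[idx] <- lower
  model$reactions$upper_bound[idx] <- upper
  model
}

#' Bundle a simulation scenario
#'
#' Collects the environment and every model correction into one idempotent
#' specification: applying the same scenario twice yields an identical model.
#'
#' @param medium a [medium_spec()].
#' @param supplements data.frame with columns \code{metabolite},
#'   \code{mode}, or NULL.
#' @param irreversible character vector of reaction ids to irreversibilize.
#' @param isoenzyme_reassign data.frame with columns \code{gene},
#'   \code{reaction}, or NULL.
#' @param remove_genes gene ids absent from the assayed strain.
#' @param fixed_fluxes data.frame with columns \code{reaction},
#'   \code{lower}, \code{upper}, or NULL.
#' @return an object of class \code{scenario_spec}.
#' @export
scenario_spec <- function(medium = medium_spec(),
                          supplements = NULL,
                          irreversible = character(),
                          isoenzyme_reassign = NULL,
                          remove_genes = character(),
                          fixed_fluxes = NULL) {
  structure(list(medium = medium,
                 supplements = supplements,
                 irreversible = irreversible,
                 isoenzyme_reassign = isoenzyme_reassign,
                 remove_genes = remove_genes,
                 fixed_fluxes = fixed_fluxes),
            class = "scenario_spec")
}

#' Apply a scenario to a model
#'
#' Order of application: strain gene removal, isoenzyme reassignment,
#' irreversibilization, medium (with the given carbon source), supplements,
#' fixed fluxes. The edits are independent, so this order is stable and the
#' whole operation is idempotent.
#'
#' @param model a \code{metabolic_model}.
#' @param scenario a [scenario_spec()].
#' @param carbon_metabolite carbon source metabolite id for the medium step
#'   (optional if the medium already names one).
#' @return the adjusted model.
#' @export
apply_scenario <- function(model, scenario, carbon_metabolite = NULL) {
  model <- remove_strain_genes(model, scenario$remove_genes)
  if (!is.null(scenario$isoenzyme_reassign))
    for (i in seq_len(nrow(scenario$isoenzyme_reassign)))
      model <- reassign_isoenzyme(model,
                                  scenario$isoenzyme_reassign$gene[i],
                                  scenario$isoenzyme_reassign$reaction[i])
  for (rid in scenario$irreversible)
    model <- set_irreversible(model, rid)
  model <- apply_medium(model, scenario$medium,
                        carbon_metabolite = carbon_metabolite)
  if (!is.null(scenario$supplements))
    for (i in seq_len(nrow(scenario$supplements)))
      model <- add_supplement(model,
                              scenario$supplements$metabolite[i],
                              scenario$supplements$mode[i])
  if (!is.null(scenario$fixed_fluxes))
    for (i in seq_len(nrow(scenario$fixed_fluxes)))
      model <- fix_flux(model,
                        scenario$fixed_fluxes$reaction[i],
                        scenario$fixed_fluxes$lower[i],
                        scenario$fixed_fluxes$upper[i])
  model
}
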