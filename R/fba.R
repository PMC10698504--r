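#' Flux balance analysis
#'
#' Maximizes biomass flux subject to steady state (S v = 0) and the
#' reaction bounds. An infeasible program is returned as
#' \code{status = "infeasible"} with no fluxes; an unbounded objective is an
#' error because it indicates a missing bound.
#'
#' @param model a \code{metabolic_model}.
#' @return a \code{flux_solution}: list with \code{status}
#'   ("optimal"/"infeasible"), \code{objective_value} (biomass flux, 1/h)
#'   and \code{fluxes} (named vector over reaction ids; empty if infeasible).
#' @export
solve_fba <- function(model) {
  rx <- model$reactions
  obj <- as.numeric(rx$id == model$biomass_reaction_id)
  sol <- lp_solve(obj, model$S, rep(0, nrow(model$S)),
                  rx$lower_bound, rx$upper_bound, maximize = TRUE)
  if (sol$status == "unbounded")
    stop("FBA objective is unbounded; check bounds on reaction(s) near ",
         rx$id[min(sol$unbounded_var, nrow(rx))])
  if (sol$status != "optimal")
    return(structure(list(status = "infeasible",
                          objective_value = NA_real_,
                          fluxes = numeric(0)), class = "flux_solution"))
  structure(list(status = "optimal",
                 objective_value = sol$objective,
                 fluxes = stats::setNames(sol$x, rx$id)),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("Flux solution:", x$status)
  if (x$status == "optimal")
    cat(", biomass flux", format(x$objective_value, digits = 6))
  cat("\n")
  invisible(x)
}

#' Parsimonious flux balance analysis
#'
#' Two-stage procedure: fix the biomass flux at the FBA optimum, then
#' minimize the total absolute flux by splitting every reaction into
#' non-negative forward and reverse parts. The returned solution keeps the
#' optimal biomass within 1e-6 while carrying no more total flux than any
#' alternative optimum.
#'
#' @param model a \code{metabolic_model}.
#' @return a \code{flux_solution} with an extra component
#'   \code{total_flux} = sum(|v|).
#' @export
solve_pfba <- function(model) {
  first <- solve_fba(model)
  if (first$status != "optimal") return(first)
  mu <- first$objective_value

  rx <- model$reactions
  n <- nrow(rx)
  S <- as.matrix(model$S)
  lb <- rx$lower_bound; ub <- rx$upper_bound
  bio <- match(model$biomass_reaction_id, rx$id)
  # pin biomass at its optimum (tolerance absorbed by the solver's arithmetic)
  lb[bio] <- mu; ub[bio] <- mu

  # v = f - r with f, r >= 0; a direction variable is only created where the
  # bounds actually allow it, which keeps the LP near size n for the mostly
  # irreversible networks this package simulates
  fwd <- which(ub > 0)
  rev <- which(lb < 0)
  A <- cbind(S[, fwd, drop = FALSE], -S[, rev, drop = FALSE])
  obj <- rep(-1, length(fwd) + length(rev))  # maximize -(sum f + sum r)
  sol <- lp_solve(obj, A, rep(0, nrow(S)),
                  c(pmax(lb[fwd], 0), pmax(-ub[rev], 0)),
                  c(ub[fwd], -lb[rev]), maximize = TRUE)
  if (sol$status != "optimal")
    stop("pFBA stage-2 LP unexpectedly ", sol$status)
  v <- numeric(n)
  v[fwd] <- sol$x[seq_along(fwd)]
  v[rev] <- v[rev] - sol$x[length(fwd) + seq_along(rev)]
  structure(list(status = "optimal",
                 objective_value = v[bio],
                 fluxes = stats::setNames(v, rx$id),
                 total_flux = sum(abs(v))),
            class = "flux_solution")
}

#' Propagate a gene knockout through the GPR rules
#'
#' A reaction is disabled (both bounds zeroed) iff its GPR rule evaluates to
#' FALSE with the knocked-out genes FALSE and every other gene TRUE.
#' Reactions with an empty rule are never disabled. Zeroing bounds (rather
#' than deleting reactions) keeps the reaction index identical across
#' simulations, which the flux-matrix machinery relies on.
#'
#' @param model a \code{metabolic_model} (not mutated).
#' @param genes character vector of gene ids to knock out.
#' @return a new \code{metabolic_model} with the affected bounds zeroed.
#' @export
apply_knockout <- function(model, genes) {
  unknown <- setdiff(genes, model$genes)
  if (length(unknown))
    stop("unknown gene id(s): ", paste(unknown, collapse = ", "))
  hit <- knockout_disabled_reactions(model, genes)
  if (length(hit)) {
    idx <- match(hit, model$reactions$id)
    model$reactions$lower_bound[idx] <- 0
    model$reactions$upper_bound[idx] <- 0
  }
  model
}

#' Reactions disabled by a gene knockout
#'
#' @param model a \code{metabolic_model}.
#' @param genes gene ids knocked out together.
#' @return character vector of reaction ids whose GPR evaluates FALSE.
#' @export
knockout_disabled_reactions <- function(model, genes) {
  if (length(genes) == 0L) return(character())
  touches <- vapply(model$gpr, function(tr) any(gpr_genes(tr) %in% genes),
                    logical(1))
  cand <- which(touches)
  dis <- cand[!vapply(model$gpr[cand], eval_gpr, logical(1),
                      knocked_out = genes)]
  model$reactions$id[dis]
}

#' Simulate a knockout grid across carbon sources
#'
#' For every carbon source the scenario is applied to the model (medium,
#' supplements, corrections), the wild type is simulated, and every listed
#' gene is knocked out and re-simulated. Growth is called at
#' \code{biomass >= growth_cutoff}; an infeasible knockout LP is recorded as
#' biomass 0 / no-growth. When a knockout disables only reactions that carry
#' zero flux in the wild-type parsimonious solution, that solution is reused
#' unchanged (the optimum cannot improve under extra constraints and the
#' wild-type solution remains feasible and minimal).
#'
#' @param model a \code{metabolic_model} (uncorrected; scenario applied here).
#' @param genes gene ids to knock out one at a time.
#' @param carbons data.frame with columns \code{carbon}, \code{metabolite}
#'   (as from [match_dataset_to_model()]), or a character vector of carbon
#'   ids resolved by the default \code{X -> X_e} rule.
#' @param scenario a [scenario_spec()] (or NULL for medium-only defaults).
#' @param fitness optional \code{fitness_dataset}; mean fitness is joined
#'   onto the prediction rows.
#' @param record_fluxes logical; also return the parsimonious flux vectors of
#'   every growth-predicted simulation (and the wild types).
#' @param growth_cutoff biomass flux cutoff separating growth from no-growth.
#' @return a \code{prediction_table}: data.frame with columns \code{gene}
#'   (or \code{"WT"}), \code{carbon}, \code{biomass_flux}, \code{grows},
#'   \code{fitness} (NA for wild type). With \code{record_fluxes}, an
#'   attribute-free list \code{list(predictions=, fluxes=)} where
#'   \code{fluxes} is a matrix with one row per simulated (gene, carbon).
#' @export
knockout_grid <- function(model, genes, carbons, scenario = NULL,
                          fitness = NULL, record_fluxes = FALSE,
                          growth_cutoff = 0.001) {
  if (is.character(carbons))
    carbons <- data.frame(carbon = carbons,
                          metabolite = paste0(carbons, "_e"),
                          stringsAsFactors = FALSE)
  if (is.null(scenario)) scenario <- scenario_spec()

  fit_lookup <- NULL
  if (!is.null(fitness)) {
    fit_lookup <- stats::setNames(fitness$records$mean_fitness,
                                  paste(fitness$records$gene,
                                        fitness$records$carbon, sep = "\r"))
  }

  rows <- list()
  flux_rows <- list()
  for (ci in seq_len(nrow(carbons))) {
    cb <- carbons$carbon[ci]
    env_model <- apply_scenario(model, scenario,
                                carbon_metabolite = carbons$metabolite[ci])
    wt <- if (record_fluxes) solve_pfba(env_model) else solve_fba(env_model)
    wt_flux <- if (wt$status == "optimal") wt$fluxes else
      stats::setNames(rep(0, nrow(env_model$reactions)),
                      env_model$reactions$id)
    wt_mu <- if (wt$status == "optimal") wt$objective_value else 0
    if (wt_mu < growth_cutoff)
      message("wild type does not grow on carbon source '", cb, "'")
    rows[[length(rows) + 1L]] <- data.frame(
      gene = "WT", carbon = cb, biomass_flux = wt_mu,
      grows = wt_mu >= growth_cutoff, fitness = NA_real_,
      stringsAsFactors = FALSE)
    if (record_fluxes)
      flux_rows[[paste("WT", cb, sep = "\r")]] <- wt_flux

    for (g in genes) {
      dis <- knockout_disabled_reactions(env_model, g)
      active <- dis[abs(wt_flux[dis]) > 1e-9]
      if (length(active) == 0L) {
        mu <- wt_mu; flx <- wt_flux
      } else {
        ko <- apply_knockout(env_model, g)
        s <- if (record_fluxes) solve_pfba(ko) else solve_fba(ko)
        if (s$status == "optimal") {
          mu <- s$objective_value; flx <- s$fluxes
        } else {
          mu <- 0; flx <- NULL
        }
      }
      grows <- mu >= growth_cutoff
      fit <- if (!is.null(fit_lookup))
        unname(fit_lookup[paste(g, cb, sep = "\r")]) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, carbon = cb, biomass_flux = mu, grows = grows,
        fitness = if (length(fit)) fit else NA_real_,
        stringsAsFactors = FALSE)
      if (record_fluxes && !is.null(flx))
        flux_rows[[paste(g, cb, sep = "\r")]] <- flx
    }
  }
  predictions <- do.call(rbind, rows)
  rownames(predictions) <- NULL
  class(predictions) <- c("prediction_table", class(predictions))
  if (!record_fluxes) return(predictions)
  fluxes <- do.call(rbind, flux_rows)
  list(predictions = predictions, fluxes = fluxes)
}

#' Find unconditionally essential genes
#'
#' Genes whose single knockout drives the biomass flux below the growth
#' cutoff even when every exchange reaction is fully open (lower bound
#' -1000), i.e. essential regardless of the environment. These are excluded
#' from condition-specific evaluation because pooled fitness assays cannot
#' phenotype them reliably.
#'
#' @param model a \code{metabolic_model}.
#' @param growth_cutoff biomass cutoff (default 0.001).
#' @param open_bound lower bound applied to every exchange (default -1000).
#' @return character vector of unconditionally essential gene ids.
#' @export
find_unconditional_essentials <- function(model, growth_cutoff = 0.001,
                                          open_bound = -1000) {
  open <- model
  ex <- open$reactions$is_exchange
  open$reactions$lower_bound[ex] <- open_bound
  wt <- solve_pfba(open)
  if (wt$status != "optimal" || wt$objective_value < growth_cutoff)
    return(sort(model$genes))  # nothing grows: every knockout is "essential"
  wt_flux <- wt$fluxes
  out <- character(0)
  for (g in model$genes) {
    dis <- knockout_disabled_reactions(open, g)
    if (length(dis) == 0L) next
    if (all(abs(wt_flux[dis]) <= 1e-9)) next  # wild-type optimum survives
    s <- solve_fba(apply_knockout(open, g))
    mu <- if (s$status == "optimal") s$objective_value else 0
    if (mu < growth_cutoff) out <- c(out, g)
  }
  sort(out)
}
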