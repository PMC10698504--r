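#' Configure a synthetic toy metabolic model
#'
#' The generated model emulates the structures that drive misprediction in
#' real genome-scale models: per-carbon uptake and catabolic chains (so
#' knockouts are carbon-specific), vitamin biosynthesis pathways feeding a
#' biomass precursor (whose knockouts look essential in silico but show no
#' fitness defect when the vitamin carries over from rich pre-culture),
#' isoenzyme OR-pairs whose second member is regulatorily silent (rescuing
#' knockouts in silico that are lethal in vivo), and a reversible bypass
#' that rescues a biosynthesis pathway only when run backwards.
#'
#' @param n_carbons number of carbon sources (default 6).
#' @param n_pathway_genes catabolic chain length per carbon, excluding the
#'   transporter gene (default 3).
#' @param n_vitamin_pathways number of vitamin biosynthesis chains
#'   (default 2).
#' @param vitamin_chain_length genes per vitamin chain (2-4; default 3).
#' @param n_isoenzyme_pairs OR-pairs on the central pathway (default 2).
#' @param include_reversible_bypass include the reversible-bypass motif
#'   (default TRUE).
#' @param n_yield_motifs number of efficient/wasteful parallel-route pairs
#'   (default 2). Knocking out the efficient route forces flux through a
#'   lower-yield alternative, so the biomass flux and the whole flux
#'   profile shift continuously across such knockouts -- the kind of
#'   within-carbon flux diversity real knockout simulations show.
#' @param include_maintenance give every gene a small forced
#'   expression-burden flux on the free nutrient (default FALSE). A knockout
#'   then relieves its gene's burden, so every knockout's parsimonious flux
#'   vector differs from every other -- emulating the fact that real
#'   knockout flux profiles are all distinct -- at the cost of disabling the
#'   wild-type-reuse shortcut during grid simulation.
#' @param seed retained for provenance; the model structure is
#'   deterministic.
#' @return a \code{toy_gem_config} list.
#' @export
toy_gem_config <- function(n_carbons = 6, n_pathway_genes = 3,
                           n_vitamin_pathways = 2, vitamin_chain_length = 3,
                           n_isoenzyme_pairs = 2,
                           include_reversible_bypass = TRUE,
                           n_yield_motifs = 2,
                           include_maintenance = FALSE, seed = 0) {
  stopifnot(n_carbons >= 1, n_pathway_genes >= 1, n_vitamin_pathways >= 0,
            vitamin_chain_length >= 2, vitamin_chain_length <= 4,
            n_isoenzyme_pairs >= 0, n_yield_motifs >= 0)
  structure(list(n_carbons = n_carbons,
                 n_pathway_genes = n_pathway_genes,
                 n_vitamin_pathways = n_vitamin_pathways,
                 vitamin_chain_length = vitamin_chain_length,
                 n_isoenzyme_pairs = n_isoenzyme_pairs,
                 include_reversible_bypass = include_reversible_bypass,
                 n_yield_motifs = n_yield_motifs,
                 include_maintenance = include_maintenance,
                 seed = seed),
            class = "toy_gem_config")
}

#' Build a toy metabolic model with known ground truth
#'
#' Constructs the model described by [toy_gem_config()] together with a
#' per-(gene, carbon) ground-truth table and the matching correction
#' scenario. Ground truth is derived constructively and then verified by
#' exhaustive single-knockout FBA on every carbon source (generation fails
#' rather than returning an inconsistent fixture).
#'
#' @param config a [toy_gem_config()].
#' @param verify run the exhaustive FBA self-consistency check
#'   (default TRUE).
#' @return list with \code{model} (a \code{metabolic_model}),
#'   \code{truth} (data.frame \code{gene}, \code{carbon},
#'   \code{model_essential}, \code{exp_essential}, \code{error_class}),
#'   \code{carbons} (carbon id -> extracellular metabolite map),
#'   \code{medium} (the base [medium_spec()]), and \code{corrections}
#'   (list \code{supplements}, \code{isoenzyme_reassign},
#'   \code{irreversible} mirroring the injected error classes).
#' @export
build_toy_gem <- function(config = toy_gem_config(), verify = TRUE) {
  K <- config$n_vitamin_pathways
  P <- config$n_isoenzyme_pairs
  L <- config$n_pathway_genes
  VL <- config$vitamin_chain_length
  carbons <- sprintf("carb%d", seq_len(config$n_carbons))

  mets <- list(); rxns <- list(); sto <- list()
  met <- function(id, comp) mets[[length(mets) + 1L]] <<-
    data.frame(id = id, name = id, compartment = comp, stringsAsFactors = FALSE)
  rxn <- function(id, coef, lb, ub, gpr = "") {
    rxns[[length(rxns) + 1L]] <<- data.frame(
      id = id, name = id, lower_bound = lb, upper_bound = ub,
      gene_reaction_rule = gpr, stringsAsFactors = FALSE)
    sto[[id]] <<- coef
  }

  # base nutrient, freely available in the minimal medium
  met("nut1_e", "e"); met("nut1_c", "c")
  rxn("EX_nut1_e", c(nut1_e = -1), 0, 1000)
  rxn("TNUT1", c(nut1_e = -1, nut1_c = 1), 0, 1000)

  biomass_needs <- c(nut1_c = -1)

  # carbon uptake and catabolism: transporter + chain into central carbon
  met("cx_c", "c")
  for (cb in carbons) {
    met(paste0(cb, "_e"), "e"); met(paste0(cb, "_c"), "c")
    rxn(paste0("EX_", cb, "_e"),
        stats::setNames(-1, paste0(cb, "_e")), 0, 1000)
    rxn(paste0("TRANS_", cb),
        stats::setNames(c(-1, 1), paste0(cb, c("_e", "_c"))), 0, 1000,
        gpr = paste0("tr_", cb))
    prev <- paste0(cb, "_c")
    for (j in seq_len(L)) {
      nxt <- if (j == L) "cx_c" else paste0("ci_", cb, "_", j)
      if (nxt != "cx_c") met(nxt, "c")
      rxn(paste0("CAT_", cb, "_", j),
          stats::setNames(c(-1, 1), c(prev, nxt)), 0, 1000,
          gpr = paste0("cat_", cb, "_", j))
      prev <- nxt
    }
  }

  # central pathway with isoenzyme OR-pairs; its end product feeds biomass
  prev <- "cx_c"
  for (p in seq_len(P)) {
    nxt <- paste0("iso", p, "_c")
    met(nxt, "c")
    rxn(paste0("ISO_", p), stats::setNames(c(-1, 1), c(prev, nxt)), 0, 1000,
        gpr = paste0("isoA_", p, " or isoB_", p))
    prev <- nxt
  }
  biomass_needs[prev] <- -1

  # vitamin pathways: biosynthesis from central carbon, importable product
  supplements <- NULL
  for (k in seq_len(K)) {
    vc <- paste0("vit", k, "_c"); ve <- paste0("vit", k, "_e")
    met(ve, "e"); met(vc, "c")
    rxn(paste0("EX_", ve), stats::setNames(-1, ve), 0, 1000)
    rxn(paste0("TVIT_", k), stats::setNames(c(-1, 1), c(ve, vc)), 0, 1000)
    prev_v <- "cx_c"
    for (j in seq_len(VL)) {
      nxt <- if (j == VL) vc else paste0("vi_", k, "_", j)
      if (nxt != vc) met(nxt, "c")
      rxn(paste0("VITSYN_", k, "_", j),
          stats::setNames(c(-1, 1), c(prev_v, nxt)), 0, 1000,
          gpr = paste0("vit_", k, "_", j))
      prev_v <- nxt
    }
    biomass_needs[vc] <- -1
    mode <- if (k %% 2L == 1L) "extracellular" else "intracellular"
    supplements <- rbind(supplements, data.frame(
      metabolite = if (mode == "extracellular") ve else vc,
      mode = mode, stringsAsFactors = FALSE))
  }

  # reversible bypass: serine-pathway analogue rescued by a backwards
  # reaction from a side metabolite
  if (config$include_reversible_bypass) {
    met("ser1_c", "c"); met("ser2_c", "c"); met("byp_c", "c")
    rxn("SER_1", c(cx_c = -1, ser1_c = 1), 0, 1000, gpr = "serA_1")
    rxn("SER_2", c(ser1_c = -1, ser2_c = 1), 0, 1000, gpr = "serA_2")
    rxn("GLY_BYP", c(cx_c = -1, byp_c = 1), 0, 1000, gpr = "glyA")
    rxn("BYP", c(ser2_c = -1, byp_c = 1), -1000, 1000)
    biomass_needs["ser2_c"] <- -1
  }

  # yield motifs: an efficient route and a wasteful (2x carbon) alternative
  # to the same biomass precursor; knocking out the efficient gene lowers
  # the growth yield instead of abolishing growth
  for (q in seq_len(config$n_yield_motifs)) {
    yl <- paste0("yl", q, "_c")
    met(yl, "c")
    rxn(paste0("YLDA_", q), stats::setNames(c(-1, 1), c("cx_c", yl)),
        0, 1000, gpr = paste0("yldA_", q))
    rxn(paste0("YLDB_", q), stats::setNames(c(-(1 + q), 1), c("cx_c", yl)),
        0, 1000, gpr = paste0("yldB_", q))
    biomass_needs[yl] <- -1
  }

  # per-gene expression burden: a small forced drain on the free nutrient,
  # removed when the gene is knocked out
  if (isTRUE(config$include_maintenance)) {
    all_genes <- sort(unique(unlist(lapply(
      vapply(rxns, function(r) r$gene_reaction_rule, character(1)),
      function(s) gpr_genes(parse_gpr(s))))))
    for (i in seq_along(all_genes)) {
      m <- 0.01 + 0.002 * i
      rxn(paste0("MAINT_", all_genes[i]), c(nut1_c = -1), m, m,
          gpr = all_genes[i])
    }
  }

  rxn("BIOMASS", biomass_needs, 0, 1000)

  model <- metabolic_model(
    id = sprintf("toy_gem_c%d_v%d_p%d", config$n_carbons, K, P),
    metabolites = do.call(rbind, mets),
    reactions = do.call(rbind, rxns),
    stoichiometry = sto,
    biomass_reaction_id = "BIOMASS")

  # constructive ground truth over the gene x carbon grid
  genes <- model$genes
  truth <- expand.grid(gene = genes, carbon = carbons,
                       stringsAsFactors = FALSE)
  truth <- truth[order(truth$gene, truth$carbon), , drop = FALSE]
  own_carbon <- function(g) {
    m <- regmatches(g, regexec("^(?:tr|cat)_(carb[0-9]+)", g))[[1]]
    if (length(m) == 2L) m[2] else NA_character_
  }
  truth$model_essential <- FALSE
  truth$exp_essential <- FALSE
  truth$error_class <- "none"
  for (i in seq_len(nrow(truth))) {
    g <- truth$gene[i]; cb <- truth$carbon[i]
    oc <- own_carbon(g)
    if (!is.na(oc)) {                       # carbon-specific catabolism
      truth$model_essential[i] <- (oc == cb)
      truth$exp_essential[i] <- (oc == cb)
    } else if (grepl("^vit_", g)) {         # vitamin carry-over FN
      truth$model_essential[i] <- TRUE
      truth$exp_essential[i] <- FALSE
      truth$error_class[i] <- "vitamin_carryover"
    } else if (grepl("^isoA_", g)) {        # silent isoenzyme FP
      truth$model_essential[i] <- FALSE
      truth$exp_essential[i] <- TRUE
      truth$error_class[i] <- "isoenzyme_fp"
    } else if (grepl("^serA_", g)) {        # reversible-bypass FP
      truth$model_essential[i] <- FALSE
      truth$exp_essential[i] <- TRUE
      truth$error_class[i] <- "bypass_fp"
    }                                       # isoB_*, glyA: no phenotype
  }
  rownames(truth) <- NULL

  carbons_map <- data.frame(carbon = carbons,
                            metabolite = paste0(carbons, "_e"),
                            stringsAsFactors = FALSE)
  medium <- medium_spec(components = c(EX_nut1_e = -1000),
                        carbon_uptake_bound = -10)
  corrections <- list(
    supplements = supplements,
    isoenzyme_reassign = if (P > 0)
      data.frame(gene = paste0("isoA_", seq_len(P)),
                 reaction = paste0("ISO_", seq_len(P)),
                 stringsAsFactors = FALSE) else NULL,
    irreversible = if (config$include_reversible_bypass) "BYP"
      else character())

  out <- list(model = model, truth = truth, carbons = carbons_map,
              medium = medium, corrections = corrections, config = config)
  if (verify) verify_toy_gem(out)
  out
}

# exhaustive single-knockout FBA across carbons must reproduce the
# constructive essentiality labels, and the wild type must grow everywhere
verify_toy_gem <- function(toy, growth_cutoff = 0.001) {
  scen <- scenario_spec(medium = toy$medium)
  grid <- knockout_grid(toy$model, unique(toy$truth$gene), toy$carbons,
                        scenario = scen, growth_cutoff = growth_cutoff)
  wt <- grid[grid$gene == "WT", , drop = FALSE]
  if (!all(wt$grows))
    stop("toy model generation error: wild type fails to grow on ",
         paste(wt$carbon[!wt$grows], collapse = ", "))
  ko <- grid[grid$gene != "WT", , drop = FALSE]
  key <- paste(ko$gene, ko$carbon)
  sim_ess <- stats::setNames(!ko$grows, key)
  tkey <- paste(toy$truth$gene, toy$truth$carbon)
  bad <- which(sim_ess[tkey] != toy$truth$model_essential)
  if (length(bad))
    stop("toy model generation error: simulated essentiality disagrees ",
         "with constructive ground truth for ",
         paste(utils::head(tkey[bad], 5), collapse = "; "))
  invisible(TRUE)
}

#' Configure the synthetic fitness generator
#'
#' @param mu_essential mean fitness of experimentally essential
#'   gene-carbon pairs (default -4; nonessential pairs have mean 0).
#' @param sigma replicate noise standard deviation (default 0.5).
#' @param n_replicates replicates per gene x carbon (default 2, matching
#'   duplicate assay designs).
#' @param seed integer seed.
#' @return a \code{fitness_gen_config} list.
#' @export
fitness_gen_config <- function(mu_essential = -4, sigma = 0.5,
                               n_replicates = 2, seed = 0) {
  stopifnot(sigma > 0, n_replicates >= 1)
  structure(list(mu_essential = mu_essential, sigma = sigma,
                 n_replicates = n_replicates, seed = seed),
            class = "fitness_gen_config")
}

#' Simulate replicate-level fitness data from ground truth
#'
#' Experimentally essential pairs draw replicate fitness from
#' Normal(mu_essential, sigma), all others from Normal(0, sigma). The
#' experimental truth already incorporates the injected error classes
#' (vitamin carry-over genes are experimentally nonessential although the
#' model predicts essentiality; silent-isoenzyme and reversible-bypass
#' genes are experimentally essential although the model predicts growth).
#' Deterministic given the seed.
#'
#' @param truth the \code{truth} data.frame from [build_toy_gem()].
#' @param config a [fitness_gen_config()].
#' @return a [fitness_dataset()] built from the replicate rows.
#' @export
simulate_fitness <- function(truth, config = fitness_gen_config()) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  n <- nrow(truth)
  rows <- do.call(rbind, lapply(seq_len(config$n_replicates), function(r) {
    mu <- ifelse(truth$exp_essential, config$mu_essential, 0)
    data.frame(gene = truth$gene, carbon = truth$carbon,
               fitness = stats::rnorm(n, mean = mu, sd = config$sigma),
               stringsAsFactors = FALSE)
  }))
  fitness_dataset(rows)
}

#' Plant a flux-linked misprediction signal
#'
#' Assigns false-positive labels to flux-matrix samples through a logistic
#' link on a chosen (standardized) flux column, optionally with per-carbon
#' offsets so the signal is carbon-specific. With \code{effect = 0} labels
#' are independent of the feature. Used to test that the classifier and the
#' Shapley attribution recover a known informative flux.
#'
#' @param fm a \code{flux_matrix}.
#' @param planted_feature column name of the informative flux.
#' @param effect log-odds slope per standard deviation of the feature.
#' @param base_rate marginal false-positive rate at feature mean
#'   (default 0.3).
#' @param carbon_sd standard deviation of per-carbon log-odds offsets
#'   (default 0: no carbon effect).
#' @param seed integer seed.
#' @return logical label vector (TRUE = false positive).
#' @export
make_flux_signal <- function(fm, planted_feature, effect, base_rate = 0.3,
                             carbon_sd = 0, seed = 0) {
  stopifnot(planted_feature %in% colnames(fm$values))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  x <- fm$values[, planted_feature]
  z <- if (stats::sd(x) > 0) (x - mean(x)) / stats::sd(x) else x * 0
  carbons <- sort(unique(fm$samples$carbon))
  off <- stats::setNames(stats::rnorm(length(carbons), 0, carbon_sd), carbons)
  eta <- stats::qlogis(base_rate) + effect * z + off[fm$samples$carbon]
  stats::runif(length(eta)) < stats::plogis(eta)
}
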