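#' Build the bipartite metabolite-reaction graph of a model
#'
#' One node per metabolite and per reaction; an undirected edge joins a
#' metabolite and a reaction whenever the metabolite has nonzero
#' stoichiometry in that reaction. Reaction node names are prefixed with
#' \code{"rxn:"} and metabolite nodes with \code{"met:"} so the two id
#' spaces cannot collide.
#'
#' @param model a \code{metabolic_model}.
#' @return an \code{igraph} graph with vertex attributes \code{kind}
#'   ("metabolite"/"reaction") and \code{id} (the bare model id).
#' @export
build_bipartite_graph <- function(model) {
  trip <- Matrix::summary(model$S)
  met <- paste0("met:", model$metabolites$id[trip$i])
  rxn <- paste0("rxn:", model$reactions$id[trip$j])
  g <- igraph::graph_from_data_frame(
    data.frame(from = met, to = rxn, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(
      name = c(paste0("met:", model$metabolites$id),
               paste0("rxn:", model$reactions$id)),
      kind = c(rep("metabolite", nrow(model$metabolites)),
               rep("reaction", nrow(model$reactions))),
      id = c(model$metabolites$id, model$reactions$id),
      stringsAsFactors = FALSE))
  g
}

#' Remove hub nodes from the bipartite graph
#'
#' Hub nodes -- currency metabolites such as water, ATP or protons, and the
#' biomass reaction -- create shortcut paths that make every pair of nodes
#' artificially close. Any node with degree above the threshold is removed
#' together with its incident edges, except nodes in the keep set (a carbon
#' source used in the analysis must survive even if it is a hub).
#'
#' @param graph an igraph from [build_bipartite_graph()].
#' @param degree_threshold nodes with more than this many connections are
#'   removed (default 50).
#' @param keep character vector of bare metabolite/reaction ids to retain
#'   regardless of degree.
#' @return the reduced graph.
#' @export
remove_hubs <- function(graph, degree_threshold = 50, keep = character()) {
  deg <- igraph::degree(graph)
  ids <- igraph::V(graph)$id
  drop <- deg > degree_threshold & !(ids %in% keep)
  igraph::delete_vertices(graph, which(drop))
}

#' Reactions a single-gene knockout removes
#'
#' A reaction counts as "essentially encoded" by a gene when knocking out
#' that gene alone disables it under the GPR rules.
#'
#' @param model a \code{metabolic_model}.
#' @param gene_id a single gene id.
#' @return character vector of reaction ids.
#' @export
gene_removed_reactions <- function(model, gene_id) {
  knockout_disabled_reactions(model, gene_id)
}

#' Network distance from a carbon source to a set of reactions
#'
#' Shortest-path distance on the (hub-removed) bipartite graph from the
#' extracellular carbon metabolite to the nearest target reaction, reported
#' as the number of reactions traversed before the target: a reaction
#' directly consuming the carbon metabolite is at distance 0, a reaction one
#' metabolite further is at distance 1, and so on. Edges have unit weight,
#' so Dijkstra reduces to breadth-first search.
#'
#' @param graph hub-removed bipartite graph.
#' @param carbon_metabolite_id bare metabolite id of the carbon source.
#' @param reactions character vector of target reaction ids.
#' @return integer distance, or \code{Inf} when no target is reachable.
#' @export
carbon_gene_distance <- function(graph, carbon_metabolite_id, reactions) {
  src <- paste0("met:", carbon_metabolite_id)
  if (!src %in% igraph::V(graph)$name)
    stop("carbon metabolite '", carbon_metabolite_id,
         "' is not in the graph; if it was removed as a hub, add it to the ",
         "keep set of remove_hubs()")
  targets <- paste0("rxn:", reactions)
  targets <- targets[targets %in% igraph::V(graph)$name]
  if (length(targets) == 0L) return(Inf)
  d <- igraph::distances(graph, v = src, to = targets)
  d <- suppressWarnings(min(d))
  if (!is.finite(d)) return(Inf)
  # a metabolite-to-reaction path of 2k+1 edges traverses k prior reactions
  (d - 1) / 2
}

#' Carbon-source-to-gene distance table with subset flags
#'
#' For every (gene, carbon) experiment whose gene disrupts at least one
#' reaction, computes the network distance from the carbon source to the
#' nearest disrupted reaction and flags three nested subsets: all such
#' experiments; those with simulated no-growth; and those whose no-growth is
#' carbon-source specific (the gene shows no-growth in at most
#' \code{carbon_specific_fraction} of its carbons).
#'
#' @param model a \code{metabolic_model} (used for knockouts and, unless
#'   \code{graph} is given, the bipartite graph).
#' @param table a \code{prediction_table} over a gene x carbon grid.
#' @param carbons data.frame \code{carbon}, \code{metabolite} mapping carbon
#'   ids to extracellular metabolites (default: the \code{X -> X_e} rule).
#' @param graph optional pre-built, hub-removed graph.
#' @param degree_threshold,keep passed to [remove_hubs()] when building the
#'   graph; the carbon metabolites are always kept.
#' @param carbon_specific_fraction no-growth in at most this fraction of a
#'   gene's carbons counts as carbon-specific (default 0.8).
#' @return a data.frame (class \code{distance_table}) with columns
#'   \code{gene}, \code{carbon}, \code{distance} (Inf = unreachable),
#'   \code{subset_all}, \code{subset_no_growth},
#'   \code{subset_carbon_specific}.
#' @export
distance_distributions <- function(model, table, carbons = NULL,
                                   graph = NULL, degree_threshold = 50,
                                   keep = character(),
                                   carbon_specific_fraction = 0.8) {
  tab <- table[table$gene != "WT", , drop = FALSE]
  if (is.null(carbons)) {
    cb <- unique(tab$carbon)
    carbons <- data.frame(carbon = cb, metabolite = paste0(cb, "_e"),
                          stringsAsFactors = FALSE)
  }
  if (is.null(graph)) {
    graph <- build_bipartite_graph(model)
    graph <- remove_hubs(graph, degree_threshold,
                         keep = unique(c(keep, carbons$metabolite)))
  }
  genes <- unique(tab$gene)
  removed <- lapply(stats::setNames(genes, genes), function(g)
    gene_removed_reactions(model, g))
  disrupts <- vapply(removed, function(r) length(r) > 0, logical(1))

  frac_ng <- vapply(stats::setNames(genes, genes), function(g) {
    rows <- tab[tab$gene == g, , drop = FALSE]
    mean(!rows$grows)
  }, numeric(1))

  out <- tab[tab$gene %in% genes[disrupts], c("gene", "carbon"), drop = FALSE]
  met_of <- stats::setNames(carbons$metabolite, carbons$carbon)
  out$distance <- mapply(function(g, cb) {
    carbon_gene_distance(graph, met_of[[cb]], removed[[g]])
  }, out$gene, out$carbon)
  ng <- !tab$grows[match(paste(out$gene, out$carbon),
                         paste(tab$gene, tab$carbon))]
  out$subset_all <- TRUE
  out$subset_no_growth <- ng
  out$subset_carbon_specific <- ng &
    (frac_ng[out$gene] <= carbon_specific_fraction)
  rownames(out) <- NULL
  class(out) <- c("distance_table", "data.frame")
  out
}

#' Mean distances per experiment subset
#'
#' @param dt a \code{distance_table}; unreachable rows are excluded from the
#'   means.
#' @return named numeric vector with the mean distance of the \code{all},
#'   \code{no_growth} and \code{carbon_specific} subsets.
#' @export
distance_subset_means <- function(dt) {
  fin <- is.finite(dt$distance)
  c(all = mean(dt$distance[fin & dt$subset_all]),
    no_growth = mean(dt$distance[fin & dt$subset_no_growth]),
    carbon_specific = mean(dt$distance[fin & dt$subset_carbon_specific]))
}
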