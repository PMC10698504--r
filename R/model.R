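#' Construct a constraint-based metabolic model
#'
#' The in-memory representation used throughout the package: a stoichiometric
#' matrix over compartment-suffixed metabolite ids, per-reaction flux bounds
#' in mmol/(gdw x h) (1/h for the biomass reaction), parsed GPR rules and a
#' designated biomass reaction. Exchange reactions (boundary reactions
#' touching exactly one metabolite) are auto-flagged.
#'
#' @param id model identifier.
#' @param metabolites data.frame with columns \code{id}, \code{name},
#'   \code{compartment}.
#' @param reactions data.frame with columns \code{id}, \code{name},
#'   \code{lower_bound}, \code{upper_bound}, \code{gene_reaction_rule}.
#' @param stoichiometry named list: per reaction id, a named numeric vector of
#'   signed coefficients over metabolite ids (negative = consumed).
#' @param genes character vector of declared gene ids (GPR genes are added).
#' @param biomass_reaction_id id of the biomass reaction.
#' @return an object of class \code{metabolic_model} with components
#'   \code{metabolites}, \code{reactions} (gains \code{is_exchange}),
#'   \code{S} (sparse metabolite x reaction matrix), \code{gpr} (named list
#'   of parsed trees), \code{genes}, \code{biomass_reaction_id}.
#' @export
metabolic_model <- function(id, metabolites, reactions, stoichiometry,
                            genes = character(), biomass_reaction_id) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  if (!"name" %in% names(metabolites)) metabolites$name <- metabolites$id
  if (!"name" %in% names(reactions)) reactions$name <- reactions$id
  if (!"gene_reaction_rule" %in% names(reactions)) reactions$gene_reaction_rule <- ""
  reactions$gene_reaction_rule[is.na(reactions$gene_reaction_rule)] <- ""

  if (anyDuplicated(metabolites$id))
    stop("duplicate metabolite ids: ",
         paste(unique(metabolites$id[duplicated(metabolites$id)]), collapse = ", "))
  if (anyDuplicated(reactions$id))
    stop("duplicate reaction ids: ",
         paste(unique(reactions$id[duplicated(reactions$id)]), collapse = ", "))

  bad <- reactions$lower_bound > reactions$upper_bound
  if (any(bad))
    stop("integrity error: lower_bound > upper_bound for reaction(s) ",
         paste(reactions$id[bad], collapse = ", "))

  stoichiometry <- stoichiometry[reactions$id]
  trip <- do.call(rbind, lapply(seq_along(stoichiometry), function(j) {
    sto <- stoichiometry[[j]]
    sto <- sto[sto != 0]
    if (length(sto) == 0L)
      stop("integrity error: reaction ", reactions$id[j],
           " has no nonzero stoichiometry")
    unknown <- setdiff(names(sto), metabolites$id)
    if (length(unknown))
      stop("integrity error: reaction ", reactions$id[j],
           " references unknown metabolite(s): ", paste(unknown, collapse = ", "))
    data.frame(i = match(names(sto), metabolites$id), j = j, x = as.numeric(sto))
  }))
  S <- Matrix::sparseMatrix(i = trip$i, j = trip$j, x = trip$x,
                            dims = c(nrow(metabolites), nrow(reactions)),
                            dimnames = list(metabolites$id, reactions$id))

  gpr <- lapply(reactions$gene_reaction_rule, parse_gpr)
  names(gpr) <- reactions$id
  gpr_gene_set <- unique(unlist(lapply(gpr, gpr_genes)))
  genes <- sort(unique(c(genes, gpr_gene_set)))

  if (!biomass_reaction_id %in% reactions$id)
    stop("biomass_reaction_id '", biomass_reaction_id, "' is not a reaction id")

  # exchanges: boundary reactions touching exactly one metabolite on the
  # extracellular side (or carrying the conventional EX_ prefix)
  n_mets <- Matrix::colSums(S != 0)
  single <- as.vector(n_mets == 1L)
  ext_comp <- metabolites$compartment %in% c("e", "extracellular")
  touches_ext <- as.vector(Matrix::colSums(S[ext_comp, , drop = FALSE] != 0) > 0)
  reactions$is_exchange <- single &
    (touches_ext | grepl("^EX_", reactions$id))

  structure(list(id = id,
                 metabolites = metabolites,
                 reactions = reactions,
                 S = S,
                 gpr = gpr,
                 genes = genes,
                 biomass_reaction_id = biomass_reaction_id),
            class = "metabolic_model")
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("Metabolic model '", x$id, "'\n", sep = "")
  cat("  metabolites:", nrow(x$metabolites),
      " reactions:", nrow(x$reactions),
      " (", sum(x$reactions$is_exchange), "exchanges)",
      " genes:", length(x$genes), "\n")
  cat("  biomass reaction:", x$biomass_reaction_id, "\n")
  invisible(x)
}

#' Read a metabolic model from file
#'
#' Supports the constraint-based JSON dialect (\code{id}, \code{metabolites},
#' \code{reactions} with \code{metabolites}/\code{lower_bound}/
#' \code{upper_bound}/\code{gene_reaction_rule}, \code{genes}) and SBML
#' Level 3 with flux-bound and GPR (fbc) annotations. The biomass reaction is
#' the one carrying a positive objective coefficient, falling back to an id
#' matching "biomass" (case-insensitive).
#'
#' @param path file path.
#' @param format "json", "sbml", or "auto" (by file extension).
#' @return a \code{metabolic_model}.
#' @export
read_model <- function(path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "json"
  }
  if (!file.exists(path)) stop("model file not found: ", path)
  switch(format,
         json = read_model_json(path),
         sbml = read_model_sbml(path))
}

read_model_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(doc$metabolites) || is.null(doc$reactions))
    stop("parse error: JSON model lacks 'metabolites' or 'reactions'")
  mets <- do.call(rbind, lapply(doc$metabolites, function(m) {
    data.frame(id = m$id,
               name = if (!is.null(m$name)) m$name else m$id,
               compartment = if (!is.null(m$compartment)) m$compartment else "",
               stringsAsFactors = FALSE)
  }))
  rxn_rows <- list(); sto <- list(); obj <- numeric(0)
  for (r in doc$reactions) {
    rxn_rows[[length(rxn_rows) + 1L]] <-
      data.frame(id = r$id,
                 name = if (!is.null(r$name)) r$name else r$id,
                 lower_bound = as.numeric(r$lower_bound),
                 upper_bound = as.numeric(r$upper_bound),
                 gene_reaction_rule =
                   if (!is.null(r$gene_reaction_rule)) r$gene_reaction_rule else "",
                 stringsAsFactors = FALSE)
    sto[[r$id]] <- unlist(r$metabolites)
    obj[r$id] <- if (!is.null(r$objective_coefficient))
      as.numeric(r$objective_coefficient) else 0
  }
  reactions <- do.call(rbind, rxn_rows)
  genes <- vapply(doc$genes, function(g)
    if (is.list(g)) g$id else as.character(g), character(1))
  biomass <- find_biomass_id(reactions$id, obj)
  metabolic_model(id = if (!is.null(doc$id)) doc$id else basename(path),
                  metabolites = mets, reactions = reactions,
                  stoichiometry = sto, genes = genes,
                  biomass_reaction_id = biomass)
}

find_biomass_id <- function(rxn_ids, obj_coefs) {
  pos <- names(obj_coefs)[obj_coefs > 0]
  if (length(pos) >= 1L) return(pos[1L])
  hit <- grep("biomass", rxn_ids, ignore.case = TRUE, value = TRUE)
  if (length(hit) >= 1L) return(hit[1L])
  stop("integrity error: no biomass reaction (objective coefficient or ",
       "'biomass' in a reaction id) found")
}

read_model_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)

  species <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  if (length(species) == 0L) stop("parse error: SBML file has no species")
  strip_prefix <- function(x, p) sub(paste0("^", p), "", x)
  mets <- data.frame(
    id = strip_prefix(xml2::xml_attr(species, "id"), "M_"),
    name = ifelse(is.na(xml2::xml_attr(species, "name")),
                  strip_prefix(xml2::xml_attr(species, "id"), "M_"),
                  xml2::xml_attr(species, "name")),
    compartment = xml2::xml_attr(species, "compartment"),
    stringsAsFactors = FALSE)
  boundary <- xml2::xml_attr(species, "boundaryCondition") %in% "true"
  mets <- mets[!boundary, , drop = FALSE]

  params <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  pval <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                          xml2::xml_attr(params, "id"))

  gprods <- xml2::xml_find_all(doc, ".//*[local-name()='geneProduct']")
  gmap <- stats::setNames(
    ifelse(is.na(xml2::xml_attr(gprods, "label")),
           strip_prefix(xml2::xml_attr(gprods, "id"), "G_"),
           xml2::xml_attr(gprods, "label")),
    xml2::xml_attr(gprods, "id"))

  gpa_to_string <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef") {
      ref <- xml2::xml_attr(node, "geneProduct")
      g <- if (ref %in% names(gmap)) gmap[[ref]] else strip_prefix(ref, "G_")
      return(g)
    }
    kids <- xml2::xml_children(node)
    parts <- vapply(kids, gpa_to_string, character(1))
    op <- if (nm == "and") " and " else " or "
    paste0("(", paste(parts, collapse = op), ")")
  }

  rxns <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  rxn_rows <- list(); sto <- list(); obj <- numeric(0)
  for (rx in rxns) {
    rid <- strip_prefix(xml2::xml_attr(rx, "id"), "R_")
    lb_ref <- xml2::xml_attr(rx, "lowerFluxBound")
    ub_ref <- xml2::xml_attr(rx, "upperFluxBound")
    rev <- xml2::xml_attr(rx, "reversible") %in% "true"
    lb <- if (!is.na(lb_ref) && lb_ref %in% names(pval)) pval[[lb_ref]]
          else if (rev) -1000 else 0
    ub <- if (!is.na(ub_ref) && ub_ref %in% names(pval)) pval[[ub_ref]] else 1000

    coef <- numeric(0)
    for (sr in xml2::xml_find_all(rx, "./listOfReactants/speciesReference")) {
      mid <- strip_prefix(xml2::xml_attr(sr, "species"), "M_")
      coef[mid] <- (if (mid %in% names(coef)) coef[[mid]] else 0) -
        as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    }
    for (sr in xml2::xml_find_all(rx, "./listOfProducts/speciesReference")) {
      mid <- strip_prefix(xml2::xml_attr(sr, "species"), "M_")
      coef[mid] <- (if (mid %in% names(coef)) coef[[mid]] else 0) +
        as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    }
    coef <- coef[names(coef) %in% mets$id]  # drop boundary species
    if (length(coef) == 0L) next            # pure boundary reaction

    gpa <- xml2::xml_find_first(rx, "./*[local-name()='geneProductAssociation']")
    gpr_str <- if (inherits(gpa, "xml_missing")) "" else {
      kids <- xml2::xml_children(gpa)
      if (length(kids) == 0L) "" else gpa_to_string(kids[[1L]])
    }
    rxn_rows[[length(rxn_rows) + 1L]] <-
      data.frame(id = rid,
                 name = ifelse(is.na(xml2::xml_attr(rx, "name")), rid,
                               xml2::xml_attr(rx, "name")),
                 lower_bound = lb, upper_bound = ub,
                 gene_reaction_rule = gpr_str, stringsAsFactors = FALSE)
    sto[[rid]] <- coef
    obj[rid] <- 0
  }
  reactions <- do.call(rbind, rxn_rows)

  fobj <- xml2::xml_find_all(doc, ".//*[local-name()='fluxObjective']")
  for (fo in fobj) {
    rid <- strip_prefix(xml2::xml_attr(fo, "reaction"), "R_")
    if (rid %in% names(obj)) obj[rid] <- as.numeric(xml2::xml_attr(fo, "coefficient"))
  }
  biomass <- find_biomass_id(reactions$id, obj)
  mid <- xml2::xml_attr(xml2::xml_find_first(doc, ".//model"), "id")
  metabolic_model(id = if (is.na(mid)) basename(path) else mid,
                  metabolites = mets, reactions = reactions,
                  stoichiometry = sto, genes = unname(gmap),
                  biomass_reaction_id = biomass)
}

#' Write a metabolic model to the constraint-based JSON dialect
#'
#' Round-trips everything [read_model()] consumes: stoichiometry, bounds,
#' GPR rules (serialized from the parsed trees), genes and the biomass
#' objective.
#'
#' @param model a \code{metabolic_model}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_model <- function(model, path) {
  S <- model$S
  rxns <- lapply(seq_len(nrow(model$reactions)), function(j) {
    col <- S[, j]
    col <- col[col != 0]
    list(id = model$reactions$id[j],
         name = model$reactions$name[j],
         metabolites = as.list(col),
         lower_bound = model$reactions$lower_bound[j],
         upper_bound = model$reactions$upper_bound[j],
         gene_reaction_rule = serialize_gpr(model$gpr[[j]]),
         objective_coefficient =
           if (model$reactions$id[j] == model$biomass_reaction_id) 1 else 0)
  })
  mets <- lapply(seq_len(nrow(model$metabolites)), function(i) {
    list(id = model$metabolites$id[i],
         name = model$metabolites$name[i],
         compartment = model$metabolites$compartment[i])
  })
  doc <- list(id = model$id,
              metabolites = mets,
              reactions = rxns,
              genes = lapply(model$genes, function(g) list(id = g)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
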