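#' Parse a gene-protein-reaction (GPR) rule
#'
#' GPR rules state which gene combinations enable a reaction: \code{and}
#' joins members of an enzyme complex, \code{or} joins isoenzymes. The
#' grammar accepts gene tokens, \code{and}/\code{or} (case-insensitive) and
#' parentheses; \code{and} binds tighter than \code{or}. An empty string
#' yields \code{NULL}, the empty rule: the reaction has no gene requirement
#' and is never disabled by a knockout.
#'
#' @param expr character scalar, e.g. \code{"(b0001 and b0002) or b0003"}.
#' @return a GPR expression tree: \code{NULL}, or nested lists with
#'   \code{type} in \code{"gene"}, \code{"and"}, \code{"or"}; gene nodes
#'   carry \code{gene}, operator nodes carry \code{args}.
#' @examples
#' parse_gpr("gA or gB and gC")   # OR(gA, AND(gB, gC))
#' parse_gpr("")                  # NULL: no gene requirement
#' @export
parse_gpr <- function(expr) {
  if (is.null(expr) || is.na(expr)) expr <- ""
  stopifnot(is.character(expr), length(expr) == 1L)
  raw <- gsub("\\(", " ( ", expr)
  raw <- gsub("\\)", " ) ", raw)
  toks <- strsplit(trimws(raw), "\\s+")[[1]]
  toks <- toks[nzchar(toks)]
  if (length(toks) == 0L) return(NULL)

  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  advance <- function() { pos <<- pos + 1L }
  fail <- function(msg) stop(sprintf("GPR parse error at token %d ('%s'): %s",
                                     pos, ifelse(is.na(peek()), "<end>", peek()), msg),
                             call. = FALSE)

  parse_or <- function() {
    args <- list(parse_and())
    while (!is.na(peek()) && tolower(peek()) == "or") {
      advance()
      args[[length(args) + 1L]] <- parse_and()
    }
    if (length(args) == 1L) args[[1L]] else list(type = "or", args = args)
  }
  parse_and <- function() {
    args <- list(parse_atom())
    while (!is.na(peek()) && tolower(peek()) == "and") {
      advance()
      args[[length(args) + 1L]] <- parse_atom()
    }
    if (length(args) == 1L) args[[1L]] else list(type = "and", args = args)
  }
  parse_atom <- function() {
    tk <- peek()
    if (is.na(tk)) fail("expression ends where a gene or '(' was expected")
    if (tk == "(") {
      advance()
      inner <- parse_or()
      if (is.na(peek()) || peek() != ")") fail("unbalanced parentheses: expected ')'")
      advance()
      return(inner)
    }
    if (tk == ")" || tolower(tk) %in% c("and", "or"))
      fail("expected a gene identifier")
    advance()
    list(type = "gene", gene = tk)
  }

  tree <- parse_or()
  if (!is.na(peek())) fail("trailing input after a complete expression")
  tree
}

#' Serialize a GPR expression tree back to a rule string
#'
#' Inverse of [parse_gpr()] up to whitespace and redundant parentheses:
#' the result re-parses to an identical tree.
#'
#' @param tree a GPR tree as returned by [parse_gpr()].
#' @return character scalar ("" for the empty rule).
#' @export
serialize_gpr <- function(tree) {
  if (is.null(tree)) return("")
  if (tree$type == "gene") return(tree$gene)
  parts <- vapply(tree$args, function(a) {
    s <- serialize_gpr(a)
    # parenthesize an OR under an AND to preserve precedence
    if (tree$type == "and" && !is.null(a$type) && a$type == "or")
      s <- paste0("(", s, ")")
    s
  }, character(1))
  paste(parts, collapse = paste0(" ", tree$type, " "))
}

#' Evaluate a GPR tree under a gene knockout
#'
#' Knocked-out genes are FALSE, all other genes TRUE; the empty rule is TRUE.
#'
#' @param tree GPR tree.
#' @param knocked_out character vector of knocked-out gene ids.
#' @return logical scalar: is the reaction still catalysable?
#' @export
eval_gpr <- function(tree, knocked_out = character()) {
  if (is.null(tree)) return(TRUE)
  switch(tree$type,
         gene = !(tree$gene %in% knocked_out),
         and  = all(vapply(tree$args, eval_gpr, logical(1), knocked_out = knocked_out)),
         or   = any(vapply(tree$args, eval_gpr, logical(1), knocked_out = knocked_out)),
         stop("malformed GPR tree node"))
}

#' List the genes referenced by a GPR tree
#' @param tree GPR tree.
#' @return character vector of unique gene ids (empty for the empty rule).
#' @export
gpr_genes <- function(tree) {
  if (is.null(tree)) return(character())
  if (tree$type == "gene") return(tree$gene)
  unique(unlist(lapply(tree$args, gpr_genes)))
}
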