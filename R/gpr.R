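# Gene-protein-reaction (GPR) boolean rules.
#
# Grammar (case-insensitive keywords, whitespace-delimited gene tokens):
#   or_expr  := and_expr ( "or" and_expr )*
#   and_expr := atom ( "and" atom )*
#   atom     := "(" or_expr ")" | gene
# "and" binds tighter than "or", the usual boolean convention. Under the
# expression semantics used for E-flux, "or" (isozymes) takes the maximum of
# its operands' ratios and "and" (complex subunits) the minimum.

gpr_tokenize <- function(gpr) {
  spaced <- gsub("\\)", " ) ", gsub("\\(", " ( ", gpr))
  tokens <- strsplit(trimws(spaced), "\\s+")[[1]]
  tokens[nzchar(tokens)]
}

#' Parse a GPR rule into an and/or tree
#'
#' @param gpr Rule string, e.g. `"(g1 and g2) or g3"`. Keywords `and`/`or`
#'   are matched case-insensitively; any other token is a gene id.
#' @return A tree: either a gene id (character scalar) or a list with fields
#'   `op` (`"and"`/`"or"`) and `args` (list of subtrees). An empty rule
#'   returns `NULL`.
#' @export
parse_gpr <- function(gpr) {
  if (is.na(gpr) || !nzchar(trimws(gpr))) return(NULL)
  tokens <- gpr_tokenize(gpr)
  pos <- 1L

  peek <- function() if (pos <= length(tokens)) tokens[pos] else NA_character_
  advance <- function() {
    tok <- peek()
    pos <<- pos + 1L
    tok
  }
  fail <- function(msg) {
    stop("malformed GPR '", gpr, "' at token ", pos, ": ", msg, call. = FALSE)
  }
  is_kw <- function(tok, kw) !is.na(tok) && tolower(tok) == kw

  parse_atom <- function() {
    tok <- peek()
    if (is.na(tok)) fail("unexpected end of rule")
    if (tok == "(") {
      advance()
      node <- parse_or()
      if (!identical(peek(), ")")) fail("expected ')'")
      advance()
      return(node)
    }
    if (tok == ")" || is_kw(tok, "and") || is_kw(tok, "or")) {
      fail(paste0("unexpected '", tok, "'"))
    }
    advance()
  }
  parse_and <- function() {
    args <- list(parse_atom())
    while (is_kw(peek(), "and")) {
      advance()
      args <- c(args, list(parse_atom()))
    }
    if (length(args) == 1L) args[[1]] else list(op = "and", args = args)
  }
  parse_or <- function() {
    args <- list(parse_and())
    while (is_kw(peek(), "or")) {
      advance()
      args <- c(args, list(parse_and()))
    }
    if (length(args) == 1L) args[[1]] else list(op = "or", args = args)
  }

  tree <- parse_or()
  if (pos <= length(tokens)) fail(paste0("trailing token '", peek(), "'"))
  tree
}

#' Gene ids appearing in a GPR rule
#' @param gpr Rule string.
#' @return Character vector of unique gene ids (empty for an empty rule).
#' @export
gpr_genes <- function(gpr) {
  tree <- if (is.character(gpr) && length(gpr) == 1L && !is.list(gpr)) {
    parse_gpr(gpr)
  } else {
    gpr
  }
  walk <- function(node) {
    if (is.null(node)) return(character(0))
    if (is.character(node)) return(node)
    unique(unlist(lapply(node$args, walk)))
  }
  unique(walk(tree))
}

#' Evaluate a GPR rule over gene expression ratios
#'
#' Isozymes (`or`) contribute the largest ratio among alternatives; complex
#' subunits (`and`) are limited by the scarcest component and contribute the
#' smallest. Genes absent from `gene_ratios` evaluate as 1 (unconstrained).
#' An empty rule evaluates to 1.
#'
#' @param gpr Rule string or a tree from [parse_gpr()].
#' @param gene_ratios Named numeric vector of per-gene expression ratios in
#'   \[0, 1\].
#' @return A single ratio in \[0, 1\].
#' @export
evaluate_gpr <- function(gpr, gene_ratios) {
  tree <- if (is.character(gpr) && !is.list(gpr)) parse_gpr(gpr) else gpr
  if (is.null(tree)) return(1)
  evaluate_tree <- function(node) {
    if (is.character(node)) {
      r <- gene_ratios[node]
      return(if (is.na(r)) 1 else unname(r))
    }
    vals <- vapply(node$args, evaluate_tree, numeric(1))
    if (node$op == "or") max(vals) else min(vals)
  }
  evaluate_tree(tree)
}

#' Render a GPR tree back to a rule string
#' @param tree Tree from [parse_gpr()].
#' @return Rule string (empty for `NULL`).
#' @export
deparse_gpr <- function(tree) {
  if (is.null(tree)) return("")
  render <- function(node, parent_op = NULL) {
    if (is.character(node)) return(node)
    body <- paste(vapply(node$args, render, character(1), parent_op = node$op),
                  collapse = paste0(" ", node$op, " "))
    if (!is.null(parent_op) && parent_op == "and" && node$op == "or") {
      paste0("(", body, ")")
    } else if (!is.null(parent_op)) {
      paste0("(", body, ")")
    } else {
      body
    }
  }
  render(tree)
}
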