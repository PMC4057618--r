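# Gene-protein-reaction rules: boolean expressions over gene identifiers
# with AND (complex subunits), OR (isozymes) and parentheses. Parsed by a
# small recursive-descent parser into a nested list; OR binds weaker than
# AND, both left-associative. An empty rule means "always active".

tokenize_gpr <- function(expr) {
  toks <- list()
  i <- 1L
  n <- nchar(expr)
  while (i <= n) {
    ch <- substr(expr, i, i)
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (ch == "(") { toks[[length(toks) + 1L]] <- list(type = "lparen", pos = i); i <- i + 1L; next }
    if (ch == ")") { toks[[length(toks) + 1L]] <- list(type = "rparen", pos = i); i <- i + 1L; next }
    if (ch == "&") { toks[[length(toks) + 1L]] <- list(type = "and", pos = i); i <- i + 1L; next }
    if (ch == "|") { toks[[length(toks) + 1L]] <- list(type = "or", pos = i); i <- i + 1L; next }
    m <- regmatches(substr(expr, i, n),
                    regexpr("^[A-Za-z0-9_.:\\-]+", substr(expr, i, n)))
    if (!length(m))
      stop("GPR syntax error at position ", i, ": unexpected character '",
           ch, "' in \"", expr, "\"")
    word <- m[[1]]
    type <- switch(tolower(word), "and" = "and", "or" = "or", "gene")
    toks[[length(toks) + 1L]] <- list(type = type, value = word, pos = i)
    i <- i + nchar(word)
  }
  toks
}

#' Parse a gene-protein-reaction rule
#'
#' @param expr GPR string (genes, `AND`/`and`/`&`, `OR`/`or`/`|`,
#'   parentheses). Empty or all-whitespace rules parse to `NULL` (always
#'   active).
#' @return Parse tree: a gene id (character), or a list
#'   `list(op = "and"|"or", args = list(...))`; `NULL` for the empty rule.
#' @export
parse_gpr <- function(expr) {
  if (is.null(expr) || is.na(expr) || !nzchar(trimws(expr))) return(NULL)
  toks <- tokenize_gpr(expr)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[[pos]] else NULL
  advance <- function() { t <- toks[[pos]]; pos <<- pos + 1L; t }
  expect_err <- function(what) {
    t <- peek()
    at <- if (is.null(t)) paste0("end of expression (position ", nchar(expr) + 1L, ")")
          else paste0("position ", t$pos)
    stop("GPR syntax error at ", at, ": expected ", what, " in \"", expr, "\"")
  }
  parse_primary <- function() {
    t <- peek()
    if (is.null(t)) expect_err("a gene or '('")
    if (t$type == "gene") { advance(); return(t$value) }
    if (t$type == "lparen") {
      advance()
      node <- parse_or()
      t2 <- peek()
      if (is.null(t2) || t2$type != "rparen") expect_err("')'")
      advance()
      return(node)
    }
    expect_err("a gene or '('")
  }
  parse_and <- function() {
    args <- list(parse_primary())
    while (!is.null(peek()) && peek()$type == "and") {
      advance()
      args[[length(args) + 1L]] <- parse_primary()
    }
    if (length(args) == 1L) args[[1L]] else list(op = "and", args = args)
  }
  parse_or <- function() {
    args <- list(parse_and())
    while (!is.null(peek()) && peek()$type == "or") {
      advance()
      args[[length(args) + 1L]] <- parse_and()
    }
    if (length(args) == 1L) args[[1L]] else list(op = "or", args = args)
  }
  node <- parse_or()
  if (!is.null(peek())) expect_err("end of expression")
  node
}

#' Genes referenced by a GPR
#'
#' @param expr GPR string or parse tree from [parse_gpr()].
#' @return Character vector of gene ids (unique, in order of appearance).
#' @export
gpr_genes <- function(expr) {
  tree <- if (is.character(expr) && !is.list(expr)) parse_gpr(expr) else expr
  walk <- function(node) {
    if (is.null(node)) character()
    else if (is.character(node)) node
    else unlist(lapply(node$args, walk))
  }
  unique(walk(tree))
}

#' Evaluate a GPR under a set of gene deletions
#'
#' Standard boolean semantics with deleted genes mapped to `FALSE`: a
#' reaction stays active iff the rule still evaluates true. The empty rule
#' is always active (spontaneous or unannotated reactions survive any
#' knockout).
#'
#' @param expr GPR string or parse tree from [parse_gpr()].
#' @param deleted_genes Character vector of deleted gene ids.
#' @return `TRUE` if the reaction remains active.
#' @export
evaluate_gpr <- function(expr, deleted_genes = character()) {
  tree <- if (is.character(expr) && !is.list(expr)) parse_gpr(expr) else expr
  if (is.null(tree)) return(TRUE)
  ev <- function(node) {
    if (is.character(node)) return(!(node %in% deleted_genes))
    vals <- vapply(node$args, ev, logical(1))
    if (node$op == "and") all(vals) else any(vals)
  }
  ev(tree)
}

# Render a parse tree back to a canonical GPR string (used by the SBML and
# JSON writers).
deparse_gpr <- function(tree) {
  if (is.null(tree)) return("")
  render <- function(node, parent_op = NULL) {
    if (is.character(node)) return(node)
    sep <- if (node$op == "and") " and " else " or "
    s <- paste(vapply(node$args, render, character(1), parent_op = node$op),
               collapse = sep)
    if (!is.null(parent_op) && parent_op == "and" && node$op == "or")
      s <- paste0("(", s, ")")
    s
  }
  render(tree)
}
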