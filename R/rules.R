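#' @include AllClasses.R
NULL

#' Parse a boolean gene-reaction rule
#'
#' Grammar: \code{expr := term ('or' term)*}, \code{term := factor ('and'
#' factor)*}, \code{factor := gene | '(' expr ')'}. Operators are
#' case-insensitive. The parsed form is a nested list with \code{op} one of
#' \code{"gene"}, \code{"and"}, \code{"or"}.
#'
#' @param text rule string, e.g. \code{"(HXT1 and HXT2) or GAL2"}.
#' @return parsed rule (a list), or \code{NULL} for empty input.
#' @examples
#' r <- parseGeneRule("(A and B) or C")
#' evalGeneRule(r, c(A = 0.8, B = 0.2, C = 0.1))  # max(min(.8,.2), .1) = 0.2
#' @export
parseGeneRule <- function(text) {
  if (is.null(text) || !nzchar(trimws(text))) return(NULL)
  toks <- regmatches(text, gregexpr("\\(|\\)|[^()[:space:]]+", text))[[1]]
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  take <- function() { t <- peek(); pos <<- pos + 1L; t }
  parseExpr <- function() {
    terms <- list(parseTerm())
    while (!is.na(peek()) && tolower(peek()) == "or") {
      take()
      terms <- c(terms, list(parseTerm()))
    }
    if (length(terms) == 1L) terms[[1]] else list(op = "or", args = terms)
  }
  parseTerm <- function() {
    facs <- list(parseFactor())
    while (!is.na(peek()) && tolower(peek()) == "and") {
      take()
      facs <- c(facs, list(parseFactor()))
    }
    if (length(facs) == 1L) facs[[1]] else list(op = "and", args = facs)
  }
  parseFactor <- function() {
    t <- take()
    if (is.na(t)) stop("gene rule ended unexpectedly: ", text)
    if (t == "(") {
      e <- parseExpr()
      if (!identical(take(), ")")) stop("unbalanced parentheses in gene rule: ", text)
      return(e)
    }
    if (t == ")" || tolower(t) %in% c("and", "or")) {
      stop("unexpected token '", t, "' in gene rule: ", text)
    }
    list(op = "gene", gene = t)
  }
  out <- parseExpr()
  if (!is.na(peek())) stop("trailing tokens in gene rule: ", text)
  out
}

#' @rdname parseGeneRule
#' @param rule a parsed rule.
#' @export
deparseGeneRule <- function(rule) {
  if (is.null(rule)) return("")
  rec <- function(r, parentOp) {
    if (r$op == "gene") return(r$gene)
    inner <- vapply(r$args, rec, "", parentOp = r$op)
    s <- paste(inner, collapse = paste0(" ", r$op, " "))
    if (!is.null(parentOp) && parentOp != r$op) paste0("(", s, ")") else s
  }
  rec(rule, NULL)
}

#' Genes referenced by a parsed rule
#' @param rule a parsed rule (or NULL).
#' @return character vector of gene ids.
#' @export
ruleGenes <- function(rule) {
  if (is.null(rule)) return(character(0))
  if (rule$op == "gene") return(rule$gene)
  unique(unlist(lapply(rule$args, ruleGenes)))
}

#' Evaluate a gene-reaction rule on gene activities
#'
#' Fuzzy-boolean semantics: AND is min, OR is max, literals are the gene
#' activities clipped to [0, 1]. Knocked-out genes evaluate to 0.
#'
#' @param rule a parsed rule.
#' @param activity named numeric vector of gene activities.
#' @param knockouts character vector of deleted genes.
#' @return activity scale in [0, 1]; 1 for a NULL (absent) rule.
#' @export
evalGeneRule <- function(rule, activity, knockouts = character(0)) {
  if (is.null(rule)) return(1)
  rec <- function(r) {
    if (r$op == "gene") {
      if (r$gene %in% knockouts) return(0)
      a <- activity[[r$gene]]
      if (is.null(a) || is.na(a)) stop("gene rule references missing gene: ", r$gene)
      return(min(max(a, 0), 1))
    }
    vals <- vapply(r$args, rec, 0)
    if (r$op == "and") min(vals) else max(vals)
  }
  rec(rule)
}

#' Which metabolite rules fire on a culture state?
#'
#' @param rules metabolite-rule data.frame (see [hybridModel()]).
#' @param conc named vector of medium concentrations (mM).
#' @return the rule rows whose comparator holds, in file order (on
#'   conflicting targets the caller applies rows in order, so the latest
#'   wins).
#' @export
firingRules <- function(rules, conc) {
  if (!nrow(rules)) return(rules[0, ])
  c0 <- conc[rules$metabolite]
  holds <- ifelse(rules$comparator == "lt", c0 < rules$threshold, c0 >= rules$threshold)
  rules[which(holds), , drop = FALSE]
}
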