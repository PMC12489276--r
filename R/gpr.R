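# Gene-protein-reaction boolean rules. A rule is a nested list tree:
# list(op = "and"|"or", args = list(...)) with character leaves (gene ids),
# or NULL for the empty rule.

#' Parse a GPR rule
#'
#' Parses a boolean gene-protein-reaction rule such as
#' \code{"g1 and (g2 or g3)"} into an expression tree. \code{and}/\code{or}
#' are case-insensitive; \code{&}/\code{|} are accepted as synonyms. An empty
#' string yields the empty rule (\code{NULL}).
#'
#' @param text rule text.
#' @return a rule tree (nested list with character gene leaves), or
#'   \code{NULL} for the empty rule.
#' @examples
#' r <- parseGPR("g1 and (g2 or g3)")
#' gprGenes(r)
#' evalGPR(r, knocked = c("g2", "g3"))
#' @export
parseGPR <- function(text) {
  if (is.null(text) || is.na(text) || !nzchar(trimws(text))) return(NULL)
  toks <- .gprTokens(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  rule <- .gprParseOr(st)
  if (st$pos <= length(st$toks)) {
    stop("GPR parse error near '", st$toks[st$pos], "' in rule: ", text)
  }
  rule
}

.gprTokens <- function(text) {
  text <- gsub("&&?", " and ", text)
  text <- gsub("\\|\\|?", " or ", text)
  text <- gsub("([()])", " \\1 ", text)
  toks <- strsplit(trimws(text), "[[:space:]]+")[[1]]
  toks[nzchar(toks)]
}

.gprPeek <- function(st) if (st$pos <= length(st$toks)) st$toks[st$pos] else NA_character_

.gprParseOr <- function(st) {
  args <- list(.gprParseAnd(st))
  while (!is.na(tk <- .gprPeek(st)) && tolower(tk) == "or") {
    st$pos <- st$pos + 1L
    args <- c(args, list(.gprParseAnd(st)))
  }
  if (length(args) == 1L) args[[1L]] else list(op = "or", args = args)
}

.gprParseAnd <- function(st) {
  args <- list(.gprParseAtom(st))
  while (!is.na(tk <- .gprPeek(st)) && tolower(tk) == "and") {
    st$pos <- st$pos + 1L
    args <- c(args, list(.gprParseAtom(st)))
  }
  if (length(args) == 1L) args[[1L]] else list(op = "and", args = args)
}

.gprParseAtom <- function(st) {
  tk <- .gprPeek(st)
  if (is.na(tk)) stop("GPR parse error: unexpected end of rule")
  if (tk == "(") {
    st$pos <- st$pos + 1L
    inner <- .gprParseOr(st)
    if (is.na(.gprPeek(st)) || .gprPeek(st) != ")") {
      stop("GPR parse error: unbalanced parentheses")
    }
    st$pos <- st$pos + 1L
    return(inner)
  }
  if (tk == ")" || tolower(tk) %in% c("and", "or")) {
    stop("GPR parse error near '", tk, "'")
  }
  st$pos <- st$pos + 1L
  tk
}

#' Genes referenced by a GPR rule
#'
#' @param rule a parsed rule (see \code{\link{parseGPR}}) or rule text.
#' @return character vector of unique gene ids (empty for the empty rule).
#' @export
gprGenes <- function(rule) {
  if (is.character(rule) && length(rule) == 1L && !is.list(rule)) {
    if (!nzchar(trimws(if (is.na(rule)) "" else rule))) return(character(0))
    # a bare token is itself a gene unless it parses as a composite rule
    rule <- parseGPR(rule)
  }
  if (is.null(rule)) return(character(0))
  if (is.character(rule)) return(rule)
  unique(unlist(lapply(rule$args, gprGenes)))
}

#' Evaluate a GPR rule under gene knockouts
#'
#' @param rule parsed rule or rule text.
#' @param knocked character vector of knocked-out gene ids.
#' @return logical; the empty rule evaluates \code{TRUE} (no gene dependency).
#' @export
evalGPR <- function(rule, knocked = character(0)) {
  if (is.character(rule) && !is.list(rule)) {
    if (length(rule) == 1L && (is.na(rule) || !nzchar(trimws(rule)))) return(TRUE)
    if (length(rule) == 1L) rule <- parseGPR(rule)
  }
  if (is.null(rule)) return(TRUE)
  if (is.character(rule)) return(!rule %in% knocked)
  vals <- vapply(rule$args, evalGPR, logical(1), knocked = knocked)
  if (rule$op == "and") all(vals) else any(vals)
}

#' Deparse a rule tree back to text
#' @param rule parsed rule.
#' @return rule text ("" for the empty rule).
#' @export
deparseGPR <- function(rule) {
  if (is.null(rule)) return("")
  if (is.character(rule)) return(rule)
  sep <- if (rule$op == "and") " and " else " or "
  parts <- vapply(rule$args, function(a) {
    txt <- deparseGPR(a)
    if (is.list(a) && a$op != rule$op) paste0("(", txt, ")") else txt
  }, character(1))
  paste(parts, collapse = sep)
}
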