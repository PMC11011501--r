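#' Select atoms by expression
#'
#' A small selection language resolves the atom subsets used by every
#' analysis. Supported predicates:
#'
#' * `resname <values>` — residue name(s), e.g. `resname G3P`
#' * `resid <values>` — author residue number(s); ranges as `427:430`
#' * `name <values>` — atom name(s), e.g. `name CZ`
#' * `chain <values>` — chain identifier(s)
#' * `element <values>` — element symbol(s)
#' * `heavy` — element != H
#' * `hydrogen` — element == H
#' * `all` — every atom
#'
#' combined with `and`, `or`, `not` and parentheses. Matching is
#' case-sensitive for values (PDB conventions are upper case). The result is
#' a deterministic ascending index list; the empty selection is legal.
#'
#' @param st an [md_structure].
#' @param expression selection string, e.g. `"resname G3P and name P"`.
#' @return an `atom_selection`: list with `indices` (ascending integer
#'   vector) and `expression`.
#' @export
#' @examples
#' rec <- make_reference_receptor()
#' select_atoms(rec, "resid 427 and name CZ")
select_atoms <- function(st, expression) {
  stopifnot(inherits(st, "md_structure"))
  mask <- eval_selection(st, expression)
  structure(list(indices = which(mask), expression = expression),
            class = "atom_selection")
}

#' @export
print.atom_selection <- function(x, ...) {
  cat("atom_selection: ", length(x$indices), " atom(s) from \"",
      x$expression, "\"\n", sep = "")
  invisible(x)
}

# Accept either an expression string or a ready-made atom_selection.
resolve_selection <- function(st, sel) {
  if (inherits(sel, "atom_selection")) {
    idx <- sel$indices
    if (length(idx) && (max(idx) > nrow(st$atoms) || min(idx) < 1L)) {
      stop("selection indices out of bounds for this structure")
    }
    return(idx)
  }
  if (is.character(sel) && length(sel) == 1L) {
    return(select_atoms(st, sel)$indices)
  }
  if (is.numeric(sel)) return(as.integer(sort(unique(sel))))
  stop("selection must be an expression string, atom_selection or indices")
}

SEL_KEYWORDS <- c("resname", "resid", "name", "chain", "element",
                  "heavy", "hydrogen", "all", "and", "or", "not")

tokenize_selection <- function(expression) {
  if (!is.character(expression) || length(expression) != 1L) {
    stop("selection expression must be a single string")
  }
  toks <- list()
  i <- 1L
  n <- nchar(expression)
  while (i <= n) {
    ch <- substr(expression, i, i)
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (ch %in% c("(", ")")) {
      toks[[length(toks) + 1L]] <- list(text = ch, pos = i)
      i <- i + 1L
      next
    }
    m <- regmatches(substr(expression, i, n),
                    regexpr("^[A-Za-z0-9_:'*+-]+", substr(expression, i, n)))
    if (length(m) == 0L) {
      stop("selection syntax error at position ", i, ": unexpected '",
           ch, "'")
    }
    toks[[length(toks) + 1L]] <- list(text = m, pos = i)
    i <- i + nchar(m)
  }
  toks
}

eval_selection <- function(st, expression) {
  toks <- tokenize_selection(expression)
  if (length(toks) == 0L) stop("selection expression is empty")
  pos <- 1L
  atoms <- st$atoms

  peek <- function() if (pos <= length(toks)) toks[[pos]] else NULL
  advance <- function() { t <- toks[[pos]]; pos <<- pos + 1L; t }
  fail <- function(tok, why) {
    at <- if (is.null(tok)) nchar(expression) + 1L else tok$pos
    stop("selection syntax error at position ", at, ": ", why)
  }
  is_keyword <- function(tok) !is.null(tok) && tok$text %in% SEL_KEYWORDS
  is_value <- function(tok) {
    !is.null(tok) && !(tok$text %in% c(SEL_KEYWORDS, "(", ")"))
  }

  parse_values <- function(field) {
    vals <- character(0)
    while (is_value(peek())) vals <- c(vals, advance()$text)
    if (length(vals) == 0L) fail(peek(), paste0("'", field, "' needs at least one value"))
    vals
  }

  parse_primary <- function() {
    tok <- peek()
    if (is.null(tok)) fail(tok, "unexpected end of expression")
    if (tok$text == "(") {
      advance()
      m <- parse_or()
      closer <- peek()
      if (is.null(closer) || closer$text != ")") fail(closer, "expected ')'")
      advance()
      return(m)
    }
    if (tok$text == ")") fail(tok, "unexpected ')'")
    advance()
    switch(tok$text,
      all = rep(TRUE, nrow(atoms)),
      heavy = atoms$elem != "H",
      hydrogen = atoms$elem == "H",
      resname = atoms$resname %in% parse_values("resname"),
      name = atoms$name %in% parse_values("name"),
      chain = atoms$chain %in% parse_values("chain"),
      element = atoms$elem %in% toupper(parse_values("element")),
      resid = {
        vals <- parse_values("resid")
        ids <- integer(0)
        for (v in vals) {
          if (grepl("^-?[0-9]+:-?[0-9]+$", v)) {
            rr <- as.integer(strsplit(v, ":")[[1]])
            ids <- c(ids, seq(rr[1], rr[2]))
          } else if (grepl("^-?[0-9]+$", v)) {
            ids <- c(ids, as.integer(v))
          } else {
            fail(tok, paste0("'", v, "' is not a residue number or range"))
          }
        }
        atoms$resno %in% ids
      },
      fail(tok, paste0("unknown predicate '", tok$text, "'"))
    )
  }

  parse_not <- function() {
    tok <- peek()
    if (!is.null(tok) && tok$text == "not") {
      advance()
      return(!parse_not())
    }
    parse_primary()
  }

  parse_and <- function() {
    m <- parse_not()
    while (!is.null(peek()) && peek()$text == "and") {
      advance()
      m <- m & parse_not()
    }
    m
  }

  parse_or <- function() {
    m <- parse_and()
    while (!is.null(peek()) && peek()$text == "or") {
      advance()
      m <- m | parse_and()
    }
    m
  }

  mask <- parse_or()
  leftover <- peek()
  if (!is.null(leftover)) fail(leftover, paste0("unexpected '", leftover$text, "'"))
  mask
}
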