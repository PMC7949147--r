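# Atom-selection mini-language.
#
# Grammar (whitespace-separated tokens; parentheses allowed):
#   expr    := or_expr
#   or_expr := and_expr ('or' and_expr)*
#   and_expr:= not_expr ('and' not_expr)*
#   not_expr:= 'not' not_expr | '(' expr ')' | term
#   term    := 'chain' <id> | 'resid' <n>[-<m>] | 'resname' <s>
#            | 'name' <s> | 'element' <s>
#
# 'and' binds tighter than 'or'; 'not' binds tightest.

.sel_keywords <- c("chain", "resid", "resname", "name", "element")

.tokenize_selection <- function(expression) {
  # pad parens so they split as their own tokens, but keep character
  # positions of the original string for error messages
  chars <- strsplit(expression, "")[[1]]
  tokens <- list()
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (grepl("[[:space:]]", ch)) { i <- i + 1L; next }
    if (ch %in% c("(", ")")) {
      tokens[[length(tokens) + 1L]] <- list(text = ch, pos = i)
      i <- i + 1L
      next
    }
    j <- i
    while (j <= n && !grepl("[[:space:]()]", chars[j])) j <- j + 1L
    tokens[[length(tokens) + 1L]] <-
      list(text = paste(chars[i:(j - 1L)], collapse = ""), pos = i)
    i <- j
  }
  tokens
}

.sel_error <- function(msg, pos) {
  stop(sprintf("selection syntax error at position %d: %s", pos, msg),
       call. = FALSE)
}

# Recursive-descent parser; returns a logical mask over atoms.
.parse_selection <- function(tokens, atoms) {
  k <- 1L
  n_tok <- length(tokens)
  peek <- function() if (k <= n_tok) tokens[[k]] else NULL
  advance <- function() { t <- tokens[[k]]; k <<- k + 1L; t }
  end_pos <- if (n_tok > 0)
    tokens[[n_tok]]$pos + nchar(tokens[[n_tok]]$text) else 1L

  parse_term <- function(tok) {
    kw <- tok$text
    arg <- peek()
    if (is.null(arg) || arg$text %in% c("(", ")", "and", "or", "not"))
      .sel_error(sprintf("keyword '%s' needs a value", kw), tok$pos)
    advance()
    val <- arg$text
    switch(kw,
      chain   = atoms$chain == val,
      resname = atoms$resname == val,
      name    = atoms$name == val,
      element = atoms$element == val,
      resid   = {
        if (grepl("^-?[0-9]+$", val)) {
          atoms$resid == as.integer(val)
        } else if (grepl("^[0-9]+-[0-9]+$", val)) {
          rng <- as.integer(strsplit(val, "-")[[1]])
          atoms$resid >= rng[1] & atoms$resid <= rng[2]
        } else {
          .sel_error(sprintf("bad resid value '%s' (want n or n-m)", val),
                     arg$pos)
        }
      }
    )
  }

  parse_not <- function() {
    tok <- peek()
    if (is.null(tok)) .sel_error("unexpected end of expression", end_pos)
    if (tok$text == "not") { advance(); return(!parse_not()) }
    if (tok$text == "(") {
      advance()
      v <- parse_or()
      cl <- peek()
      if (is.null(cl) || cl$text != ")")
        .sel_error("missing closing parenthesis", tok$pos)
      advance()
      return(v)
    }
    if (tok$text %in% .sel_keywords) { advance(); return(parse_term(tok)) }
    .sel_error(sprintf("unexpected token '%s'", tok$text), tok$pos)
  }

  parse_and <- function() {
    v <- parse_not()
    repeat {
      tok <- peek()
      if (is.null(tok) || tok$text != "and") return(v)
      advance()
      v <- v & parse_not()
    }
  }

  parse_or <- function() {
    v <- parse_and()
    repeat {
      tok <- peek()
      if (is.null(tok) || tok$text != "or") return(v)
      advance()
      v <- v | parse_and()
    }
  }

  if (n_tok == 0) .sel_error("empty expression", 1L)
  v <- parse_or()
  trailing <- peek()
  if (!is.null(trailing))
    .sel_error(sprintf("unexpected token '%s' after complete expression",
                       trailing$text), trailing$pos)
  v
}

#' Select atoms by expression
#'
#' Evaluates a selection expression against a topology. Terms are
#' `chain <id>`, `resid <n>` or `resid <n>-<m>`, `resname <s>`, `name <s>`,
#' `element <s>`, combined with `and`, `or`, `not` and parentheses
#' (`and` binds tighter than `or`). Re-evaluation on the same topology is
#' deterministic; an empty match is legal.
#'
#' @param topology a [topology()].
#' @param expression selection string, e.g. `"chain A and resid 359 and name OE1"`.
#' @return an object of class `"atom_selection"`: sorted unique `indices`
#'   (1-based), the source `expression`, and `n`.
#' @export
select_atoms <- function(topology, expression) {
  stopifnot(inherits(topology, "topology"), is.character(expression),
            length(expression) == 1)
  mask <- .parse_selection(.tokenize_selection(expression), topology$atoms)
  structure(
    list(indices = which(mask), expression = expression, n = sum(mask)),
    class = "atom_selection"
  )
}

#' @export
print.atom_selection <- function(x, ...) {
  cat(sprintf("atom selection '%s': %d atom(s)\n", x$expression, x$n))
  invisible(x)
}

# Coerce a selection-or-expression argument to an atom_selection.
.as_selection <- function(topology, sel) {
  if (inherits(sel, "atom_selection")) {
    if (length(sel$indices) > 0 && max(sel$indices) > topology$n_atoms)
      stop("selection indices exceed topology size")
    return(sel)
  }
  if (is.character(sel)) return(select_atoms(topology, sel))
  if (is.numeric(sel)) {
    idx <- sort(unique(as.integer(sel)))
    if (length(idx) > 0 && (min(idx) < 1 || max(idx) > topology$n_atoms))
      stop("selection indices exceed topology size")
    return(structure(list(indices = idx, expression = "<indices>",
                          n = length(idx)),
                     class = "atom_selection"))
  }
  stop("cannot interpret selection of class ", class(sel)[1])
}
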