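# Recursive-descent parser for the BEL subset used by the curated interaction
# table: term := f(args) with f in {p, r, act, comp, ma}; a relation keyword
# separates subject and object at the top level. Namespace prefixes
# ("HGNC:ESR1") are stripped and free-text names are resolved through a
# configurable alias table. Parse errors carry the offending token and its
# 1-based character offset.

bel_parse_error <- function(msg, token, offset) {
  cond <- structure(
    class = c("bel_parse_error", "error", "condition"),
    list(
      message = sprintf("%s (token '%s' at character %d)", msg, token, offset),
      call = NULL, token = token, offset = offset
    )
  )
  stop(cond)
}

# check parenthesis balance; error at the first offending character
check_balanced <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  stack <- integer(0)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") stack <- c(stack, i)
    else if (chars[i] == ")") {
      if (!length(stack))
        bel_parse_error("unbalanced parentheses", ")", i)
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack))
    bel_parse_error("unbalanced parentheses", "(", stack[length(stack)])
  invisible(TRUE)
}

# split `text` on `sep` characters at parenthesis depth 0; returns a
# data.frame of piece start/end offsets (1-based, inclusive), empty pieces
# dropped
top_level_split <- function(text, sep) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  cuts <- integer(0)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    else if (chars[i] == ")") depth <- depth - 1L
    else if (depth == 0L && chars[i] %in% sep) cuts <- c(cuts, i)
  }
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts - 1L, nchar(text))
  keep <- starts <= ends & nzchar(trimws(substring(text, starts, ends)))
  data.frame(start = starts[keep], end = ends[keep])
}

# trim a piece while keeping track of its absolute start offset
trim_piece <- function(text, start, end) {
  piece <- substring(text, start, end)
  lead <- nchar(piece) - nchar(sub("^\\s+", "", piece))
  list(text = trimws(piece), start = start + lead)
}

#' Load the BEL alias table
#'
#' Maps free-text entity names (for example `"ets-Domain Protein Elk-4"`) to
#' gene symbols. Lookup is case-insensitive. The packaged default can be
#' replaced with any TSV holding `name` and `symbol` columns.
#'
#' @param path path to an alias TSV; `NULL` for the packaged table.
#' @return named character vector, names lowercased.
#' @export
bel_aliases <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "bel_aliases.tsv", package = "rcrnet",
                        mustWork = TRUE)
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stats::setNames(as.character(tab$symbol), tolower(trimws(tab$name)))
}

normalize_symbol <- function(raw, aliases, offset) {
  txt <- trimws(raw)
  if (!nzchar(txt)) bel_parse_error("empty entity name", raw, offset)
  hit <- aliases[tolower(txt)]
  if (!is.na(hit)) return(unname(hit))
  # strip a namespace prefix such as "HGNC:" (also a bare leading ":")
  stripped <- sub("^[^:(),]*:", "", txt)
  hit <- aliases[tolower(trimws(stripped))]
  if (!is.na(hit)) return(unname(hit))
  sym <- toupper(trimws(stripped))
  if (!nzchar(sym)) bel_parse_error("empty entity name after namespace", raw, offset)
  sym
}

looks_like_term <- function(s) grepl("^\\s*[A-Za-z]+\\s*\\(", s)

# parse one term occupying all of `s`; `base` is the absolute offset of the
# character before s[1] in the original statement text
parse_term <- function(s, base, aliases) {
  m <- regexec("^(\\s*)([A-Za-z]+)(\\s*)\\(", s)[[1]]
  if (m[1] == -1L)
    bel_parse_error("expected a BEL term 'f(...)'", trimws(s), base + 1L)
  lens <- attr(m, "match.length")
  fn <- substring(s, m[3], m[3] + lens[3] - 1L)
  fn_off <- base + m[3]
  if (!fn %in% bel_functions)
    bel_parse_error("unknown function symbol", fn, fn_off)
  open_pos <- m[1] + lens[1] - 1L
  # find the matching close paren
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  depth <- 0L
  close_pos <- NA_integer_
  for (i in open_pos:length(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    else if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth == 0L) { close_pos <- i; break }
    }
  }
  if (is.na(close_pos))
    bel_parse_error("unbalanced parentheses", "(", base + open_pos)
  tail_txt <- trimws(substring(s, close_pos + 1L))
  if (nzchar(tail_txt))
    bel_parse_error("unexpected text after term", tail_txt, base + close_pos + 1L)
  inner <- substring(s, open_pos + 1L, close_pos - 1L)
  pieces <- top_level_split(inner, ",")
  if (!nrow(pieces))
    bel_parse_error("empty argument list", fn, fn_off)
  args <- lapply(seq_len(nrow(pieces)), function(i)
    trim_piece(inner, pieces$start[i], pieces$end[i]))
  arg_base <- base + open_pos  # absolute offset of char before inner[1]

  parse_arg_term <- function(a) parse_term(a$text, arg_base + a$start - 1L, aliases)

  switch(fn,
    p = ,
    r = {
      if (length(args) != 1L || looks_like_term(args[[1]]$text))
        bel_parse_error(sprintf("%s() expects a single entity name", fn),
                        args[[1]]$text, arg_base + args[[1]]$start)
      bel_entity(if (fn == "p") "protein" else "rna",
                 symbol = normalize_symbol(args[[1]]$text, aliases,
                                           arg_base + args[[1]]$start))
    },
    ma = structure(list(note = args[[1]]$text), class = "bel_ma"),
    act = {
      inner_ent <- parse_arg_term(args[[1]])
      if (inherits(inner_ent, "bel_ma"))
        bel_parse_error("act() cannot wrap ma()", args[[1]]$text,
                        arg_base + args[[1]]$start)
      ma_note <- NA_character_
      for (a in args[-1]) {
        ann <- parse_arg_term(a)
        if (!inherits(ann, "bel_ma"))
          bel_parse_error("only ma() annotations are allowed after the entity in act()",
                          a$text, arg_base + a$start)
        ma_note <- ann$note
      }
      bel_entity("activity", inner = inner_ent, ma = ma_note)
    },
    comp = {
      members <- lapply(args, parse_arg_term)
      bad <- vapply(members, function(x)
        inherits(x, "bel_ma") || !x$form %in% c("protein", "rna"), logical(1))
      if (any(bad) || length(members) < 2L)
        bel_parse_error("comp() expects two or more protein/rna members",
                        args[[which(bad)[1] %||% 1L]]$text, fn_off)
      bel_entity("complex", members = members)
    }
  )
}

`%||%` <- function(a, b) if (is.null(a) || !length(a) || is.na(a[1])) b else a

#' Parse a BEL-subset causal statement
#'
#' Parses text of the form `term relation term`, where terms use the
#' `p()`/`r()`/`act()`/`comp()` functions (with optional `ma()`
#' molecular-activity annotations inside `act()`) and the relation is one of
#' the four signed keywords. Namespace prefixes are stripped and free-text
#' names are resolved via the alias table; symbols are uppercase-normalized.
#'
#' @param text the statement text, e.g. `"p(CD82) increases r(BRMS1)"`.
#' @param evidence reference string(s) attached to the statement.
#' @param provenance `"curated"` or `"data_driven"`.
#' @param aliases alias table from [bel_aliases()].
#' @return a [causal_statement()].
#' @examples
#' parse_statement("p(CD82) increases r(BRMS1)", evidence = "B38")
#' @export
parse_statement <- function(text, evidence = character(0),
                            provenance = "curated", aliases = bel_aliases()) {
  stopifnot(is.character(text), length(text) == 1L)
  check_balanced(text)
  toks <- top_level_split(text, c(" ", "\t"))
  tok_text <- trimws(substring(text, toks$start, toks$end))
  rel_i <- which(tok_text %in% names(bel_relations))
  if (length(rel_i) != 1L) {
    bad_i <- if (nrow(toks) >= 2L) 2L else 1L
    bel_parse_error(
      if (length(rel_i)) "multiple relation keywords" else "unknown relation keyword",
      tok_text[bad_i], toks$start[bad_i]
    )
  }
  if (rel_i == 1L || rel_i == nrow(toks))
    bel_parse_error("relation keyword must separate subject and object",
                    tok_text[rel_i], toks$start[rel_i])
  subj_piece <- trim_piece(text, 1L, toks$start[rel_i] - 1L)
  obj_piece <- trim_piece(text, toks$end[rel_i] + 1L, nchar(text))
  subject <- parse_term(subj_piece$text, subj_piece$start - 1L, aliases)
  object <- parse_term(obj_piece$text, obj_piece$start - 1L, aliases)
  if (inherits(subject, "bel_ma") || inherits(object, "bel_ma"))
    bel_parse_error("ma() cannot stand alone as subject or object",
                    "ma", 1L)
  causal_statement(subject, tok_text[rel_i], object,
                   evidence = evidence, provenance = provenance)
}
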