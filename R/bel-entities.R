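# BEL-subset entity and statement model. Entities are gene products with a
# form (protein, rna, activity, complex); statements relate a subject entity
# to an object entity through one of four signed causal relation keywords.

bel_relations <- c(
  increases = 1L, directlyIncreases = 1L,
  decreases = -1L, directlyDecreases = -1L
)

bel_functions <- c("p", "r", "act", "comp", "ma")

#' Construct a BEL entity
#'
#' An entity is a gene product in one of four forms: `protein` (`p()`),
#' `rna` (`r()`), `activity` (`act()`, wrapping another entity with an
#' optional molecular-activity note), or `complex` (`comp()`, holding two or
#' more non-complex members).
#'
#' @param form one of `"protein"`, `"rna"`, `"activity"`, `"complex"`.
#' @param symbol uppercase gene symbol (protein/rna forms only).
#' @param members list of member entities (complex form only).
#' @param inner wrapped entity (activity form only).
#' @param ma molecular-activity note such as `"kin"`, or `NA`.
#' @return an object of class `bel_entity`.
#' @export
bel_entity <- function(form, symbol = NA_character_, members = list(),
                       inner = NULL, ma = NA_character_) {
  form <- match.arg(form, c("protein", "rna", "activity", "complex"))
  ent <- structure(
    list(form = form, symbol = symbol, members = members, inner = inner, ma = ma),
    class = "bel_entity"
  )
  validate_bel_entity(ent)
  ent
}

validate_bel_entity <- function(ent) {
  switch(ent$form,
    protein = ,
    rna = {
      if (!is.character(ent$symbol) || is.na(ent$symbol) || !nzchar(ent$symbol))
        stop("protein/rna entity requires a non-empty symbol", call. = FALSE)
      if (ent$symbol != toupper(ent$symbol))
        stop("entity symbols must be uppercase-normalized: ", ent$symbol, call. = FALSE)
      if (length(ent$members))
        stop("members are only allowed for complex entities", call. = FALSE)
    },
    complex = {
      if (length(ent$members) < 2L)
        stop("a complex requires at least two members", call. = FALSE)
      ok <- vapply(ent$members, function(m)
        inherits(m, "bel_entity") && m$form %in% c("protein", "rna"), logical(1))
      if (!all(ok))
        stop("complex members must be non-complex protein/rna entities", call. = FALSE)
    },
    activity = {
      if (!inherits(ent$inner, "bel_entity") || ent$inner$form == "activity")
        stop("activity must wrap a non-activity entity", call. = FALSE)
    }
  )
  invisible(ent)
}

#' Gene symbols covered by an entity
#'
#' Collapses an entity to the gene level: a protein/rna entity yields its own
#' symbol, an activity yields the symbols of the wrapped entity, and a complex
#' yields all member symbols.
#'
#' @param ent a [bel_entity()].
#' @return character vector of gene symbols.
#' @export
entity_symbols <- function(ent) {
  stopifnot(inherits(ent, "bel_entity"))
  switch(ent$form,
    protein = ,
    rna = ent$symbol,
    activity = entity_symbols(ent$inner),
    complex = vapply(ent$members, entity_symbols, character(1))
  )
}

#' @export
format.bel_entity <- function(x, ...) {
  switch(x$form,
    protein = sprintf("p(%s)", x$symbol),
    rna = sprintf("r(%s)", x$symbol),
    complex = sprintf("comp(%s)",
                      paste(vapply(x$members, format, character(1)), collapse = ", ")),
    activity = if (is.na(x$ma)) sprintf("act(%s)", format(x$inner))
               else sprintf("act(%s, ma(%s))", format(x$inner), x$ma)
  )
}

#' @export
print.bel_entity <- function(x, ...) {
  cat("<bel_entity> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Construct a causal statement
#'
#' One parsed BEL-subset assertion: a subject entity produces a signed effect
#' on an object entity. The relation keyword determines the edge sign (+1 for
#' `increases`/`directlyIncreases`, -1 for the `decreases` pair) and the
#' direct flag (`TRUE` iff the keyword starts with "directly").
#'
#' @param subject,object [bel_entity()] objects.
#' @param relation one of `increases`, `decreases`, `directlyIncreases`,
#'   `directlyDecreases`.
#' @param evidence character vector of reference strings.
#' @param provenance `"curated"` (literature) or `"data_driven"` (inferred
#'   from knockdown expression).
#' @return an object of class `causal_statement` with derived fields `sign`
#'   and `direct`.
#' @export
causal_statement <- function(subject, relation, object,
                             evidence = character(0),
                             provenance = c("curated", "data_driven")) {
  stopifnot(inherits(subject, "bel_entity"), inherits(object, "bel_entity"))
  if (!relation %in% names(bel_relations))
    stop("unknown relation keyword: ", relation, call. = FALSE)
  provenance <- match.arg(provenance)
  structure(
    list(
      subject = subject,
      relation = relation,
      object = object,
      evidence = as.character(evidence),
      provenance = provenance,
      sign = unname(bel_relations[[relation]]),
      direct = startsWith(relation, "directly")
    ),
    class = "causal_statement"
  )
}

#' Canonical BEL-subset text of a statement
#'
#' Serializes a parsed statement back to its canonical textual form (namespace
#' prefixes stripped, aliases resolved). Re-parsing the canonical text yields
#' an identical statement.
#'
#' @param s a [causal_statement()].
#' @return a single string.
#' @export
bel_text <- function(s) {
  stopifnot(inherits(s, "causal_statement"))
  paste(format(s$subject), s$relation, format(s$object))
}

#' @export
format.causal_statement <- function(x, ...) bel_text(x)

#' @export
print.causal_statement <- function(x, ...) {
  cat("<causal_statement> ", bel_text(x),
      "  [sign ", sprintf("%+d", x$sign),
      if (x$direct) ", direct" else "",
      "; ", x$provenance, "]\n", sep = "")
  invisible(x)
}
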