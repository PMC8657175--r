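# Signed directed functional-layer graph built from causal statements.
# A backbone holds a node table (symbol + role: MSG, TF or other) and an edge
# table with one row per ordered (source, target) pair, each carrying a sign,
# a direct flag, provenance and pooled evidence references ('|'-separated).

#' Expand a causal statement into signed edges
#'
#' Entity forms are collapsed to the gene level: a complex subject with k
#' members yields k edges, all inheriting the statement's sign and direct
#' flag. Self-loops are rejected.
#'
#' @param s a [causal_statement()].
#' @return data.frame with columns `source`, `target`, `sign`, `direct`,
#'   `provenance`, `evidence`.
#' @export
statement_to_edges <- function(s) {
  stopifnot(inherits(s, "causal_statement"))
  grid <- expand.grid(source = entity_symbols(s$subject),
                      target = entity_symbols(s$object),
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  loops <- grid$source == grid$target
  if (any(loops))
    stop("self-loop edge not allowed: ", grid$source[loops][1], " -> ",
         grid$target[loops][1], " (", bel_text(s), ")", call. = FALSE)
  data.frame(
    source = grid$source, target = grid$target,
    sign = s$sign, direct = s$direct, provenance = s$provenance,
    evidence = paste(s$evidence, collapse = "|"),
    stringsAsFactors = FALSE
  )
}

new_backbone <- function(nodes, edges) {
  rownames(nodes) <- rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "backbone")
}

#' Build the signed backbone graph from causal statements
#'
#' Statements are expanded to the gene level and deduplicated by ordered
#' (source, target, sign) with pooled evidence; duplicate rows such as the
#' repeated GATA3 -> CD44 statements collapse to one edge. The same ordered
#' pair carrying both +1 and -1 among the statements is a curation error and
#' raises a hard error listing the conflicting evidence.
#'
#' @param statements non-empty list of [causal_statement()] objects.
#' @param roles optional named character vector mapping symbols to roles
#'   (`"MSG"`, `"TF"`, anything else becomes `"other"`).
#' @return an object of class `backbone`.
#' @export
build_backbone <- function(statements, roles = NULL) {
  if (!length(statements)) stop("no causal statements supplied", call. = FALSE)
  edf <- do.call(rbind, lapply(statements, statement_to_edges))
  key <- paste(edf$source, edf$target, sep = "\r")
  nsigns <- tapply(edf$sign, key, function(x) length(unique(x)))
  if (any(nsigns > 1L)) {
    bad <- names(nsigns)[nsigns > 1L][1]
    rows <- edf[key == bad, ]
    stop(sprintf(
      "conflicting signs for edge %s -> %s among curated statements: %s",
      rows$source[1], rows$target[1],
      paste(sprintf("[sign %+d, evidence %s]", rows$sign, rows$evidence),
            collapse = " vs ")
    ), call. = FALSE)
  }
  pieces <- lapply(split(edf, key), function(x) data.frame(
    source = x$source[1], target = x$target[1], sign = x$sign[1],
    direct = any(x$direct),
    provenance = if (any(x$provenance == "curated")) "curated" else "data_driven",
    evidence = paste(unlist(strsplit(x$evidence, "|", fixed = TRUE)),
                     collapse = "|"),
    stringsAsFactors = FALSE
  ))
  edges <- do.call(rbind, pieces)
  edges <- edges[order(edges$source, edges$target), , drop = FALSE]
  symbols <- sort(unique(c(edges$source, edges$target)))
  role <- rep("other", length(symbols))
  if (!is.null(roles)) {
    hit <- roles[symbols]
    role[!is.na(hit)] <- unname(hit[!is.na(hit)])
  }
  new_backbone(data.frame(symbol = symbols, role = role, stringsAsFactors = FALSE),
               edges)
}

#' @rdname build_backbone
#' @param bb a `backbone` object.
#' @export
backbone_nodes <- function(bb) {
  stopifnot(inherits(bb, "backbone"))
  bb$nodes
}

#' @rdname build_backbone
#' @export
backbone_edges <- function(bb) {
  stopifnot(inherits(bb, "backbone"))
  bb$edges
}

#' Add edges to a backbone
#'
#' Used to merge data-driven edges into a curated backbone. New edges must
#' not duplicate an existing ordered pair; endpoints already present keep
#' their roles, new endpoints get role `"other"`.
#'
#' @param bb a `backbone`.
#' @param edges data.frame with the backbone edge columns.
#' @return the augmented `backbone`.
#' @export
add_edges <- function(bb, edges) {
  stopifnot(inherits(bb, "backbone"))
  if (!nrow(edges)) return(bb)
  old <- paste(bb$edges$source, bb$edges$target)
  new <- paste(edges$source, edges$target)
  if (any(new %in% old))
    stop("edge already present: ", new[new %in% old][1], call. = FALSE)
  if (anyDuplicated(new))
    stop("duplicate edges in addition set", call. = FALSE)
  out <- rbind(bb$edges, edges[, names(bb$edges)])
  out <- out[order(out$source, out$target), , drop = FALSE]
  extra <- setdiff(unique(c(edges$source, edges$target)), bb$nodes$symbol)
  nodes <- bb$nodes
  if (length(extra))
    nodes <- rbind(nodes, data.frame(symbol = extra, role = "other",
                                     stringsAsFactors = FALSE))
  nodes <- nodes[order(nodes$symbol), , drop = FALSE]
  new_backbone(nodes, out)
}

#' Drop edges from a backbone by row index
#' @param bb a `backbone`.
#' @param idx integer or logical index into the edge table.
#' @return the reduced `backbone` (node set unchanged).
#' @export
drop_edges <- function(bb, idx) {
  stopifnot(inherits(bb, "backbone"))
  new_backbone(bb$nodes, bb$edges[setdiff(seq_len(nrow(bb$edges)),
                                          seq_len(nrow(bb$edges))[idx]), ,
                                  drop = FALSE])
}

#' @export
print.backbone <- function(x, ...) {
  cat(sprintf("<backbone> %d nodes (%s), %d signed edges (%d activating, %d repressing)\n",
              nrow(x$nodes),
              paste(sprintf("%d %s", table(x$nodes$role),
                            names(table(x$nodes$role))), collapse = ", "),
              nrow(x$edges), sum(x$edges$sign > 0), sum(x$edges$sign < 0)))
  invisible(x)
}

#' Convert a backbone to an igraph graph
#' @param bb a `backbone`.
#' @return a directed [igraph::igraph] with `sign`, `direct`, `provenance`
#'   and `evidence` edge attributes and a `role` vertex attribute.
#' @export
as_igraph <- function(bb) {
  stopifnot(inherits(bb, "backbone"))
  igraph::graph_from_data_frame(bb$edges, directed = TRUE,
                                vertices = bb$nodes)
}

#' Write a backbone as SIF
#'
#' Simple interaction format: `source<TAB>relation<TAB>target`, the relation
#' written as `activates` (+1) or `represses` (-1).
#'
#' @param bb a `backbone`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sif <- function(bb, path) {
  stopifnot(inherits(bb, "backbone"))
  lines <- sprintf("%s\t%s\t%s", bb$edges$source,
                   ifelse(bb$edges$sign > 0, "activates", "represses"),
                   bb$edges$target)
  writeLines(lines, path)
  invisible(path)
}

#' Write a backbone as GraphML
#' @inheritParams write_sif
#' @export
write_graphml <- function(bb, path) {
  igraph::write_graph(as_igraph(bb), path, format = "graphml")
  invisible(path)
}
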