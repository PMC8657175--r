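# Enumeration of simple directed paths terminating at a target node, ranking
# by mean coherence across drug perturbations, and extraction of the
# top-coherent regulatory model.

#' Construct a directed path
#'
#' @param nodes ordered node symbols v_0 ... v_k (distinct, k >= 1).
#' @param signs edge signs s_1 ... s_k, one per consecutive pair.
#' @return an object of class `directed_path`.
#' @export
directed_path <- function(nodes, signs) {
  stopifnot(length(nodes) >= 2L, length(signs) == length(nodes) - 1L,
            all(signs %in% c(-1L, 1L)), !anyDuplicated(nodes))
  structure(list(nodes = nodes, signs = as.integer(signs)),
            class = "directed_path")
}

#' @export
format.directed_path <- function(x, ...) paste(x$nodes, collapse = ">")

#' @export
print.directed_path <- function(x, ...) {
  cat("<directed_path> ",
      paste0(x$nodes[1],
             paste0(ifelse(x$signs > 0, " -> ", " -| "), x$nodes[-1],
                    collapse = "")),
      "\n", sep = "")
  invisible(x)
}

#' Enumerate simple directed paths ending at a target
#'
#' Depth-bounded reverse traversal from the target: all simple directed paths
#' of length 1 to `max_len` whose terminal node is `target` (the target never
#' reappears inside a path, and no node repeats). Ordering is deterministic:
#' lexicographic by node sequence.
#'
#' @param bb a `backbone` (or [two_layer_network()]).
#' @param target terminal node symbol; must be in the backbone.
#' @param max_len maximum path length in edges (>= 1).
#' @return list of [directed_path()] objects.
#' @export
paths_to <- function(bb, target, max_len = 5) {
  if (inherits(bb, "two_layer_network")) bb <- bb$backbone
  stopifnot(inherits(bb, "backbone"), max_len >= 1)
  if (!target %in% bb$nodes$symbol)
    stop("target not in backbone: ", target, call. = FALSE)
  inc <- split(bb$edges[, c("source", "sign")], bb$edges$target)
  res <- list()
  grow <- function(nodes, signs) {
    # nodes[1] is the current front; extend backwards
    edges_in <- inc[[nodes[1]]]
    if (is.null(edges_in)) return()
    for (j in seq_len(nrow(edges_in))) {
      src <- edges_in$source[j]
      if (src %in% nodes) next  # simplicity: no revisits
      path_nodes <- c(src, nodes)
      path_signs <- c(edges_in$sign[j], signs)
      res[[length(res) + 1L]] <<- directed_path(path_nodes, path_signs)
      if (length(path_signs) < max_len) grow(path_nodes, path_signs)
    }
  }
  grow(target, integer(0))
  keys <- vapply(res, format, character(1))
  res[order(keys, method = "radix")]
}

#' Rank paths by mean coherence across drugs
#'
#' Per-path mean of the defined per-drug coherence rates, sorted descending;
#' ties broken by shorter path, then lexicographically. Paths undefined for
#' every drug are dropped and listed in attribute `"dropped"`.
#'
#' @param paths list of `directed_path` objects.
#' @param results list of `perturbation_result` objects (>= 1 drug), or a
#'   named list of pre-binarized states.
#' @param zero_policy passed to [binarize()].
#' @param anchor passed to [coherence()].
#' @return a `ranked_paths` data.frame (`path`, `length`, `mean_coherence`,
#'   `n_drugs`) with attributes `"paths"` (reordered list), `"per_drug"`
#'   (path x drug rate matrix) and `"dropped"`.
#' @export
rank_paths <- function(paths, results, zero_policy = "exclude",
                       anchor = "observed") {
  stopifnot(length(paths) >= 1, length(results) >= 1)
  states <- lapply(results, function(r)
    if (inherits(r, "binarized_state")) r else binarize(r, zero_policy))
  drugs <- vapply(seq_along(states), function(i)
    attr(states[[i]], "drug") %||% names(states)[i] %||% paste0("drug", i),
    character(1))
  per_drug <- vapply(states, function(st)
    vapply(paths, function(p) coherence(p, st, anchor = anchor)$rate,
           numeric(1)),
    numeric(length(paths)))
  per_drug <- matrix(per_drug, nrow = length(paths),
                     dimnames = list(vapply(paths, format, character(1)), drugs))
  mean_coh <- apply(per_drug, 1, function(x) mean(x[!is.na(x)]))
  n_drugs <- apply(per_drug, 1, function(x) sum(!is.na(x)))
  keep <- n_drugs > 0
  df <- data.frame(
    path = rownames(per_drug)[keep],
    length = vapply(paths[keep], function(p) length(p$signs), integer(1)),
    mean_coherence = unname(mean_coh[keep]),
    n_drugs = unname(n_drugs[keep]),
    stringsAsFactors = FALSE
  )
  ord <- order(-df$mean_coherence, df$length, df$path, method = "radix")
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  structure(df,
            paths = paths[keep][ord],
            per_drug = per_drug[keep, , drop = FALSE][ord, , drop = FALSE],
            dropped = rownames(per_drug)[!keep],
            class = c("ranked_paths", "data.frame"))
}

#' Extract the top-coherent path model
#'
#' Union of the edges of the `top_k` best-ranked paths with mean coherence
#' strictly above `min_coherence`. Each retained edge is annotated with the
#' maximum mean coherence among the retained paths that use it (suitable for
#' driving edge thickness in exports). An empty selection yields an empty
#' graph with a warning.
#'
#' @param ranked a `ranked_paths` object from [rank_paths()].
#' @param min_coherence threshold on mean coherence (strict `>`), default 0.6.
#' @param top_k number of top paths to retain, default 5.
#' @param roles optional symbol -> role mapping for the model's node table.
#' @return a `backbone` whose edge table has an extra `coherence` column.
#' @export
extract_model <- function(ranked, min_coherence = 0.6, top_k = 5,
                          roles = NULL) {
  stopifnot(inherits(ranked, "ranked_paths"), nrow(ranked) >= 1)
  sel <- which(ranked$mean_coherence > min_coherence)
  sel <- sel[sel <= top_k]
  if (!length(sel)) {
    warning("no path exceeds the coherence threshold; returning an empty model",
            call. = FALSE)
    return(new_backbone(
      data.frame(symbol = character(0), role = character(0),
                 stringsAsFactors = FALSE),
      data.frame(source = character(0), target = character(0),
                 sign = integer(0), direct = logical(0),
                 provenance = character(0), evidence = character(0),
                 coherence = numeric(0), stringsAsFactors = FALSE)))
  }
  paths <- attr(ranked, "paths")[sel]
  rows <- list()
  for (i in seq_along(paths)) {
    p <- paths[[i]]
    for (j in seq_along(p$signs))
      rows[[length(rows) + 1L]] <- data.frame(
        source = p$nodes[j], target = p$nodes[j + 1L], sign = p$signs[j],
        coherence = ranked$mean_coherence[sel[i]],
        path = ranked$path[sel[i]], stringsAsFactors = FALSE)
  }
  edf <- do.call(rbind, rows)
  key <- paste(edf$source, edf$target)
  agg <- lapply(split(edf, key), function(x) data.frame(
    source = x$source[1], target = x$target[1], sign = x$sign[1],
    direct = NA, provenance = "model",
    evidence = paste(unique(x$path), collapse = "|"),
    coherence = max(x$coherence), stringsAsFactors = FALSE))
  edges <- do.call(rbind, agg)
  edges <- edges[order(edges$source, edges$target), , drop = FALSE]
  symbols <- sort(unique(c(edges$source, edges$target)))
  role <- rep("other", length(symbols))
  if (!is.null(roles)) {
    hit <- roles[symbols]
    role[!is.na(hit)] <- unname(hit[!is.na(hit)])
  }
  new_backbone(data.frame(symbol = symbols, role = role,
                          stringsAsFactors = FALSE), edges)
}

#' Write a ranked-path table
#'
#' Long-format TSV: one row per path with its signs, mean coherence and the
#' per-drug rates.
#'
#' @param ranked a `ranked_paths` object.
#' @param path output TSV.
#' @export
write_ranked_paths <- function(ranked, path) {
  per_drug <- attr(ranked, "per_drug")
  signs <- vapply(attr(ranked, "paths"), function(p)
    paste(sprintf("%+d", p$signs), collapse = ","), character(1))
  out <- cbind(ranked, signs = signs, as.data.frame(per_drug))
  write_tsv(out, path,
            comment = "ranked directed paths; coherence rates in [0,1], chance level 0.5")
}
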