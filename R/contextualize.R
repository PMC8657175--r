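# Contextualization of the curated backbone against knockdown differential
# expression in a single cell context. Convention: a knockdown lowers its
# target, so an edge u -> v with sign s predicts that v moves in direction -s
# when u is knocked down. Curated edges contradicted by a significant change
# in the opposite direction are removed; significant changes on backbone
# nodes with no curated edge become data-driven edges; significant changes on
# non-backbone genes form the transcript (terminal) layer.

#' Construct a knockdown dataset
#'
#' @param target the knocked-down gene symbol.
#' @param records data.frame with columns `gene`, `log2fc`, `pvalue`
#'   (one row per gene; the target itself must be present — its own
#'   fold-change is the efficiency check).
#' @return an object of class `knockdown_dataset`.
#' @export
knockdown_dataset <- function(target, records) {
  stopifnot(is.character(target), length(target) == 1L,
            all(c("gene", "log2fc", "pvalue") %in% names(records)))
  if (anyDuplicated(records$gene))
    stop("duplicate genes in knockdown records for ", target, call. = FALSE)
  if (any(!is.finite(records$log2fc)))
    stop("non-finite log2fc in knockdown records for ", target, call. = FALSE)
  if (any(records$pvalue < 0 | records$pvalue > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  if (!target %in% records$gene)
    stop("knockdown target ", target, " missing from its own records",
         call. = FALSE)
  structure(list(target = target, records = records),
            class = "knockdown_dataset")
}

kd_lookup <- function(kd, gene) {
  i <- match(gene, kd$records$gene)
  if (is.na(i)) NULL else kd$records[i, ]
}

#' Knockdown efficiency check
#'
#' A knockdown is efficient when the target's own expression drops
#' significantly: log2 fold-change below `fc_max` (default -1) at p-value
#' below `p_max` (default 0.05).
#'
#' @param kd a [knockdown_dataset()].
#' @param fc_max log2FC threshold (strict `<`).
#' @param p_max p-value threshold (strict `<`).
#' @return logical scalar.
#' @export
check_efficiency <- function(kd, fc_max = -1, p_max = 0.05) {
  stopifnot(inherits(kd, "knockdown_dataset"))
  self <- kd_lookup(kd, kd$target)
  self$log2fc < fc_max && self$pvalue < p_max
}

# apply the efficiency gate to a list of knockdowns; inefficient ones are
# excluded (default) or kept with a warning
efficient_knockdowns <- function(kds, fc_max = -1, p_max = 0.05,
                                 action = c("exclude", "warn")) {
  action <- match.arg(action)
  ok <- vapply(kds, check_efficiency, logical(1), fc_max = fc_max, p_max = p_max)
  if (any(!ok)) {
    msg <- paste("inefficient knockdowns:", paste(names(kds)[!ok], collapse = ", "))
    if (action == "exclude") {
      message(msg, " (excluded)")
      kds <- kds[ok]
    } else warning(msg, call. = FALSE)
  }
  kds
}

#' Remove curated edges contradicted by knockdown expression
#'
#' For a curated edge u -> v with sign s, knocking down u predicts v moves in
#' direction -s. The edge is removed iff the observed log2FC of v in the
#' knockdown of u has sign +s with |log2FC| > `fc_abs` and p-value < `p_max`.
#' Edges whose source has no knockdown data are kept unchanged; this
#' operation never adds edges. The decision table is attached as attribute
#' `"filter_report"`.
#'
#' @param bb a `backbone`.
#' @param kds named list of [knockdown_dataset()] (names = targets).
#' @param fc_abs absolute log2FC threshold (strict `>`), default 1.
#' @param p_max p-value threshold (strict `<`), default 0.05.
#' @return the filtered `backbone` with attribute `"filter_report"`.
#' @export
filter_conflicts <- function(bb, kds, fc_abs = 1, p_max = 0.05) {
  stopifnot(inherits(bb, "backbone"))
  e <- bb$edges
  action <- rep("kept", nrow(e))
  reason <- rep("no knockdown data for source", nrow(e))
  obs_fc <- obs_p <- rep(NA_real_, nrow(e))
  for (i in seq_len(nrow(e))) {
    if (e$provenance[i] != "curated") { reason[i] <- "data-driven edge"; next }
    kd <- kds[[e$source[i]]]
    if (is.null(kd)) next
    rec <- kd_lookup(kd, e$target[i])
    if (is.null(rec)) { reason[i] <- "target absent from knockdown table"; next }
    obs_fc[i] <- rec$log2fc
    obs_p[i] <- rec$pvalue
    contradicted <- sign(rec$log2fc) == e$sign[i] &&
      abs(rec$log2fc) > fc_abs && rec$pvalue < p_max
    if (contradicted) {
      action[i] <- "removed"
      reason[i] <- "significant change opposite to prediction"
    } else {
      reason[i] <- "consistent or evidence insufficient"
    }
  }
  report <- data.frame(source = e$source, target = e$target, sign = e$sign,
                       log2fc = obs_fc, pvalue = obs_p,
                       action = action, reason = reason,
                       stringsAsFactors = FALSE)
  out <- drop_edges(bb, which(action == "removed"))
  attr(out, "filter_report") <- report
  out
}

#' Infer data-driven edges from knockdown expression
#'
#' For each knockdown of u and each other backbone node v carrying a
#' significant change (|log2FC| > `fc_abs`, p < `p_max`) with no existing
#' u -> v edge, an edge u -> v is added with sign = -sign(log2FC): v falling
#' when u is knocked down implies u activates v. Inferred edges are typed
#' direct, provenance `data_driven`. This operation never removes edges.
#'
#' @inheritParams filter_conflicts
#' @return data.frame of new edges (possibly empty), same columns as
#'   [backbone_edges()].
#' @export
infer_edges <- function(bb, kds, fc_abs = 1, p_max = 0.05) {
  stopifnot(inherits(bb, "backbone"))
  existing <- paste(bb$edges$source, bb$edges$target)
  rows <- list()
  for (u in intersect(names(kds), bb$nodes$symbol)) {
    rec <- kds[[u]]$records
    rec <- rec[rec$gene %in% setdiff(bb$nodes$symbol, u), , drop = FALSE]
    sig <- abs(rec$log2fc) > fc_abs & rec$pvalue < p_max
    rec <- rec[sig & !paste(u, rec$gene) %in% existing, , drop = FALSE]
    if (nrow(rec))
      rows[[u]] <- data.frame(
        source = u, target = rec$gene, sign = as.integer(-sign(rec$log2fc)),
        direct = TRUE, provenance = "data_driven",
        evidence = paste0("knockdown:", u), stringsAsFactors = FALSE
      )
  }
  if (!length(rows))
    return(data.frame(source = character(0), target = character(0),
                      sign = integer(0), direct = logical(0),
                      provenance = character(0), evidence = character(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build the transcript (terminal) layer
#'
#' For each backbone node u with knockdown data, the terminal set is every
#' non-backbone gene g with |log2FC| > `fc_abs` (default 0.5) and p-value <
#' `p_max` (default 0.01) in the knockdown of u, signed -sign(log2FC) (same
#' direction logic as [infer_edges()]). Backbone nodes with no knockdown data
#' get an empty terminal set and are listed in attribute `"uncovered"`.
#'
#' @inheritParams filter_conflicts
#' @param fc_abs absolute log2FC threshold, default 0.5.
#' @param p_max p-value threshold, default 0.01.
#' @return data.frame with columns `node`, `gene`, `sign` (the terminal
#'   layer, long format) and attribute `"uncovered"`.
#' @export
build_terminal <- function(bb, kds, fc_abs = 0.5, p_max = 0.01) {
  stopifnot(inherits(bb, "backbone"))
  nodes <- bb$nodes$symbol
  rows <- list()
  for (u in intersect(names(kds), nodes)) {
    rec <- kds[[u]]$records
    rec <- rec[!rec$gene %in% nodes, , drop = FALSE]
    sig <- abs(rec$log2fc) > fc_abs & rec$pvalue < p_max
    rec <- rec[sig, , drop = FALSE]
    if (nrow(rec))
      rows[[u]] <- data.frame(node = u, gene = rec$gene,
                              sign = as.integer(-sign(rec$log2fc)),
                              stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(node = character(0), gene = character(0), sign = integer(0),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  uncovered <- setdiff(nodes, names(kds))
  if (length(uncovered)) attr(out, "uncovered") <- uncovered
  out
}

#' Construct a two-layer network
#'
#' Bundles the signed backbone (functional layer) with the transcript layer
#' mapping each backbone node to its signed downstream genes. Every terminal
#' node key must be a backbone node.
#'
#' @param bb a `backbone`.
#' @param terminal terminal-layer data.frame from [build_terminal()].
#' @return an object of class `two_layer_network`.
#' @export
two_layer_network <- function(bb, terminal) {
  stopifnot(inherits(bb, "backbone"),
            all(c("node", "gene", "sign") %in% names(terminal)))
  stray <- setdiff(unique(terminal$node), bb$nodes$symbol)
  if (length(stray))
    stop("terminal-layer keys not in backbone: ", paste(stray, collapse = ", "),
         call. = FALSE)
  if (!all(terminal$sign %in% c(-1L, 1L)))
    stop("terminal signs must be -1 or +1", call. = FALSE)
  structure(list(backbone = bb, terminal = terminal),
            class = "two_layer_network")
}

#' @export
print.two_layer_network <- function(x, ...) {
  cat(sprintf("<two_layer_network> backbone: %d nodes / %d edges; terminal: %d signed genes over %d nodes\n",
              nrow(x$backbone$nodes), nrow(x$backbone$edges),
              nrow(x$terminal), length(unique(x$terminal$node))))
  invisible(x)
}

#' Contextualize a curated backbone end to end
#'
#' Applies the efficiency gate, removes contradicted curated edges, adds
#' data-driven edges, and builds the transcript layer, returning the
#' two-layer network ready for perturbation scoring. Filtering and inference
#' use the (`edge_fc`, `edge_p`) thresholds; the terminal layer uses the
#' stricter (`term_fc`, `term_p`) pair.
#'
#' @param bb curated `backbone`.
#' @param kds named list of [knockdown_dataset()].
#' @param edge_fc,edge_p thresholds for edge filtering/addition (1, 0.05).
#' @param term_fc,term_p thresholds for the terminal layer (0.5, 0.01).
#' @param efficiency_action `"exclude"` inefficient knockdowns or `"warn"`.
#' @param add_inferred add data-driven edges (default TRUE).
#' @return a [two_layer_network()] with attributes `"filter_report"` and
#'   `"inferred_edges"`.
#' @export
contextualize_network <- function(bb, kds, edge_fc = 1, edge_p = 0.05,
                                  term_fc = 0.5, term_p = 0.01,
                                  efficiency_action = c("exclude", "warn"),
                                  add_inferred = TRUE) {
  kds <- efficient_knockdowns(kds, action = match.arg(efficiency_action))
  filtered <- filter_conflicts(bb, kds, fc_abs = edge_fc, p_max = edge_p)
  report <- attr(filtered, "filter_report")
  # existence is checked against the ORIGINAL curated set so that an edge
  # removed as contradicted is not re-added from the same knockdown evidence
  inferred <- if (add_inferred) infer_edges(bb, kds, fc_abs = edge_fc,
                                            p_max = edge_p)
              else backbone_edges(filtered)[0, ]
  augmented <- add_edges(filtered, inferred)
  terminal <- build_terminal(augmented, kds, fc_abs = term_fc, p_max = term_p)
  net <- two_layer_network(augmented, terminal)
  attr(net, "filter_report") <- report
  attr(net, "inferred_edges") <- inferred
  attr(net, "uncovered") <- attr(terminal, "uncovered")
  net
}
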