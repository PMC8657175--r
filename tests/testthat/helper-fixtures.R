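# Shared builders for in-code fixtures: small backbones from edge lists,
# binarized states, two-layer networks and random signed graphs.

bb_from_edges <- function(src, tgt, sign, roles = NULL) {
  sts <- mapply(function(s, t, g) parse_statement(
    sprintf("r(%s) %s r(%s)", s, if (g > 0) "increases" else "decreases", t),
    evidence = "test"),
    src, tgt, sign, SIMPLIFY = FALSE)
  build_backbone(sts, roles)
}

state_of <- function(vals, drug = "d1") {
  structure(as.integer(vals), names = names(vals), drug = drug,
            class = "binarized_state")
}

net_with_terminal <- function(bb, node, gene, sign) {
  two_layer_network(bb, data.frame(node = node, gene = gene,
                                   sign = as.integer(sign),
                                   stringsAsFactors = FALSE))
}

# random signed directed graph with unique ordered pairs (no conflicts)
rand_backbone <- function(n_nodes, n_edges, seed) {
  withr::with_seed(seed, {
    nodes <- sprintf("G%02d", seq_len(n_nodes))
    pairs <- expand.grid(s = nodes, t = nodes, stringsAsFactors = FALSE)
    pairs <- pairs[pairs$s != pairs$t, , drop = FALSE]
    pick <- pairs[sample(nrow(pairs), min(n_edges, nrow(pairs))), , drop = FALSE]
    bb_from_edges(pick$s, pick$t, sample(c(-1L, 1L), nrow(pick), replace = TRUE))
  })
}

# random two-layer network where every node is anchored by terminal genes
rand_two_layer <- function(n_nodes, n_edges, genes_per_node, seed) {
  bb <- rand_backbone(n_nodes, n_edges, seed)
  withr::with_seed(seed + 1000L, {
    nodes <- bb$nodes$symbol
    term <- do.call(rbind, lapply(nodes, function(u) data.frame(
      node = u, gene = sprintf("T_%s_%d", u, seq_len(genes_per_node)),
      sign = sample(c(-1L, 1L), genes_per_node, replace = TRUE),
      stringsAsFactors = FALSE)))
    list(net = two_layer_network(bb, term),
         profile = stats::setNames(stats::rnorm(nrow(term)), term$gene))
  })
}

# independent oracle for the NPA-style coefficient solver: minimize the
# quadratic objective using only its value, via finite-difference
# gradient/Hessian (exact for quadratics up to rounding) and a dense solve
oracle_coefficients <- function(net, profile, lambda = 1) {
  bb <- net$backbone
  nodes <- bb$nodes$symbol
  tset <- split(net$terminal, net$terminal$node)
  tval <- vapply(nodes, function(u) {
    tg <- tset[[u]]
    if (is.null(tg)) return(NA_real_)
    v <- profile[tg$gene]
    if (all(is.na(v))) NA_real_ else mean(tg$sign[!is.na(v)] * v[!is.na(v)])
  }, numeric(1))
  w <- vapply(nodes, function(u) if (is.na(tval[u])) 0 else
    nrow(tset[[u]]), numeric(1))
  obj <- function(f) {
    names(f) <- nodes
    e <- bb$edges
    sum((f[e$source] - e$sign * f[e$target])^2) +
      lambda * sum(w * (f - ifelse(is.na(tval), 0, tval))^2, na.rm = TRUE)
  }
  n <- length(nodes)
  h <- 1e-4
  grad <- function(f) vapply(seq_len(n), function(i) {
    ei <- replace(numeric(n), i, h)
    (obj(f + ei) - obj(f - ei)) / (2 * h)
  }, numeric(1))
  g0 <- grad(numeric(n))
  H <- vapply(seq_len(n), function(i) {
    ei <- replace(numeric(n), i, 1)
    grad(ei) - g0
  }, numeric(n))
  stats::setNames(solve((H + t(H)) / 2, -g0), nodes)
}

# independent exhaustive enumeration of simple paths ending at `target`
# (plain recursion over the edge table, no shared code with paths_to)
oracle_paths_to <- function(bb, target, max_len) {
  e <- backbone_edges(bb)
  out <- list()
  visit <- function(chain) {
    front <- chain[1]
    for (j in which(e$target == front)) {
      s <- e$source[j]
      if (s %in% chain) next
      out[[length(out) + 1L]] <<- c(s, chain)
      if (length(chain) < max_len) visit(c(s, chain))
    }
  }
  visit(target)
  sort(vapply(out, paste, character(1), collapse = ">"))
}
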