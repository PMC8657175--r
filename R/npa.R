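# NPA-style perturbation scoring of the two-layer network. Backbone node
# coefficients f minimize a data-anchored signed-graph smoothing objective
#
#   sum over backbone edges (u,v):  (f_u - s_uv * f_v)^2
# + lambda * sum over nodes u:      w_u * (f_u - t_u)^2
#
# where t_u is the terminal score of u (mean signed downstream log2FC), w_u
# the size of u's terminal set (0 when the score is undefined), s_uv the edge
# sign and lambda a coupling weight. The objective is quadratic, so the
# minimizer solves a linear system; the data term anchors each weakly
# connected component that has at least one scored node.

#' Terminal score of a backbone node
#'
#' Mean over the node's terminal genes g of sign(node -> g) x log2FC(g) under
#' the given expression profile. Genes absent from the profile are skipped;
#' when the terminal set is empty or entirely absent the score is undefined
#' (`NA`) and the node is flagged rather than raising an error.
#'
#' @param net a [two_layer_network()].
#' @param profile named numeric vector, gene -> log2 fold-change vs control.
#' @param node backbone node symbol.
#' @return numeric scalar, or `NA_real_` when undefined.
#' @export
terminal_score <- function(net, profile, node) {
  stopifnot(inherits(net, "two_layer_network"))
  if (!node %in% net$backbone$nodes$symbol)
    stop("not a backbone node: ", node, call. = FALSE)
  tg <- net$terminal[net$terminal$node == node, , drop = FALSE]
  vals <- profile[tg$gene]
  ok <- !is.na(vals)
  if (!nrow(tg) || !any(ok)) return(NA_real_)
  mean(tg$sign[ok] * vals[ok])
}

#' @rdname terminal_score
#' @export
terminal_scores <- function(net, profile) {
  nodes <- net$backbone$nodes$symbol
  stats::setNames(vapply(nodes, function(u) terminal_score(net, profile, u),
                         numeric(1)), nodes)
}

# Pre-factorized solver for the quadratic objective. Returns a function
# mapping a terminal-score vector t (NA = undefined) to coefficients f.
# Weights w = terminal-set sizes are fixed by the network, so the system
# matrix is built and inverted once and reused across bootstrap replicates.
backbone_solver <- function(net, lambda = 1) {
  bb <- net$backbone
  nodes <- bb$nodes$symbol
  n <- length(nodes)
  w <- stats::setNames(as.numeric(table(factor(net$terminal$node,
                                               levels = nodes))), nodes)
  e <- bb$edges
  si <- match(e$source, nodes)
  ti <- match(e$target, nodes)
  G <- matrix(0, n, n)  # graph smoothing term
  for (k in seq_len(nrow(e))) {
    s <- e$sign[k]
    G[si[k], si[k]] <- G[si[k], si[k]] + 1
    G[ti[k], ti[k]] <- G[ti[k], ti[k]] + 1
    G[si[k], ti[k]] <- G[si[k], ti[k]] - s
    G[ti[k], si[k]] <- G[ti[k], si[k]] - s
  }
  comp <- igraph::components(as_igraph(bb), mode = "weak")$membership[nodes]
  function(tvec) {
    wt <- ifelse(is.na(tvec[nodes]), 0, w)  # undefined score => no anchor
    t0 <- ifelse(is.na(tvec[nodes]), 0, tvec[nodes])
    f <- stats::setNames(numeric(n), nodes)
    unanchored <- character(0)
    for (cc in unique(comp)) {
      idx <- which(comp == cc)
      if (all(wt[idx] == 0)) { unanchored <- c(unanchored, nodes[idx]); next }
      A <- G[idx, idx, drop = FALSE] + lambda * diag(wt[idx], nrow = length(idx))
      b <- lambda * wt[idx] * t0[idx]
      f[idx] <- solve(A, b)
    }
    if (length(unanchored)) attr(f, "unanchored") <- unanchored
    f
  }
}

#' Infer backbone perturbation coefficients
#'
#' Solves the quadratic data-anchored smoothing objective (see the package
#' vignette) for the node coefficients given one expression profile.
#' Connected components with no scored node get coefficient 0 and are listed
#' in attribute `"unanchored"`.
#'
#' @inheritParams terminal_score
#' @param lambda coupling weight between the data term and the graph
#'   smoothing term (default 1).
#' @return named numeric vector of coefficients over backbone nodes.
#' @export
infer_backbone <- function(net, profile, lambda = 1) {
  stopifnot(inherits(net, "two_layer_network"))
  backbone_solver(net, lambda)(terminal_scores(net, profile))
}

#' Network perturbation amplitude
#'
#' The mean squared co-perturbation across backbone edges,
#' `(1/|E|) sum (f_u + s_uv f_v)^2 / 4`; zero iff every edge is exactly
#' anti-coherent or all coefficients vanish. Zero when the backbone has no
#' edges.
#'
#' @param f named coefficient vector from [infer_backbone()].
#' @param net a [two_layer_network()].
#' @return non-negative scalar.
#' @export
network_amplitude <- function(f, net) {
  e <- net$backbone$edges
  if (!nrow(e)) return(0)
  mean((f[e$source] + e$sign * f[e$target])^2) / 4
}

#' Score a drug profile with uncertainty
#'
#' Point coefficients and amplitude, per-node percentile-bootstrap confidence
#' intervals (resampling terminal genes within each node's terminal set), and
#' a network-level permutation p-value (shuffling the gene labels of the
#' profile and recomputing the amplitude). Deterministic given `seed`.
#'
#' @inheritParams infer_backbone
#' @param drug drug identifier attached to the result.
#' @param n_boot bootstrap replicates (minimum 100, enforced).
#' @param n_perm label permutations (>= 1).
#' @param seed integer seed (mandatory).
#' @param conf confidence level of the bootstrap intervals.
#' @return an object of class `perturbation_result`: fields `drug`,
#'   `coefficients`, `ci_low`, `ci_high`, `amplitude`, `pvalue`,
#'   `unanchored`.
#' @export
npa_score <- function(net, profile, drug = "drug", lambda = 1,
                      n_boot = 200, n_perm = 100, seed, conf = 0.95) {
  stopifnot(inherits(net, "two_layer_network"))
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  if (n_boot < 100) stop("n_boot must be at least 100", call. = FALSE)
  if (n_perm < 1) stop("n_perm must be at least 1", call. = FALSE)
  solver <- backbone_solver(net, lambda)
  nodes <- net$backbone$nodes$symbol
  tvec <- terminal_scores(net, profile)
  f <- solver(tvec)
  amp <- network_amplitude(f, net)
  term_split <- split(net$terminal, net$terminal$node)

  withr::with_seed(seed, {
    boot <- matrix(NA_real_, n_boot, length(nodes),
                   dimnames = list(NULL, nodes))
    for (b in seq_len(n_boot)) {
      tb <- tvec
      for (u in names(term_split)) {
        tg <- term_split[[u]]
        vals <- profile[tg$gene]
        ok <- which(!is.na(vals))
        if (!length(ok)) next
        pick <- ok[sample.int(length(ok), length(ok), replace = TRUE)]
        tb[u] <- mean(tg$sign[pick] * vals[pick])
      }
      boot[b, ] <- solver(tb)
    }
    alpha <- (1 - conf) / 2
    ci_low <- apply(boot, 2, stats::quantile, probs = alpha, na.rm = TRUE)
    ci_high <- apply(boot, 2, stats::quantile, probs = 1 - alpha, na.rm = TRUE)
    # percentile intervals are widened, if needed, to contain the point value
    ci_low <- pmin(ci_low, f)
    ci_high <- pmax(ci_high, f)
    perm_amp <- vapply(seq_len(n_perm), function(k) {
      pp <- profile
      names(pp) <- sample(names(pp))
      network_amplitude(solver(terminal_scores(net, pp)), net)
    }, numeric(1))
  })
  structure(
    list(drug = drug, coefficients = f, ci_low = ci_low, ci_high = ci_high,
         amplitude = amp,
         pvalue = (1 + sum(perm_amp >= amp)) / (n_perm + 1),
         unanchored = attr(f, "unanchored")),
    class = "perturbation_result"
  )
}

#' @rdname npa_score
#' @param profiles named list of profiles (one per drug); each drug gets a
#'   sub-seed `seed + i - 1`.
#' @export
npa_scores <- function(net, profiles, lambda = 1, n_boot = 200, n_perm = 100,
                       seed, conf = 0.95) {
  stopifnot(!is.null(names(profiles)))
  res <- lapply(seq_along(profiles), function(i)
    npa_score(net, profiles[[i]], drug = names(profiles)[i], lambda = lambda,
              n_boot = n_boot, n_perm = n_perm, seed = seed + i - 1L,
              conf = conf))
  stats::setNames(res, names(profiles))
}

#' @export
print.perturbation_result <- function(x, ...) {
  cat(sprintf("<perturbation_result> %s: amplitude %.4g (p = %.3g), %d node coefficients in [%.3g, %.3g]\n",
              x$drug, x$amplitude, x$pvalue, length(x$coefficients),
              min(x$coefficients), max(x$coefficients)))
  invisible(x)
}

#' Flatten perturbation results to a long table
#' @param results list of `perturbation_result` objects.
#' @return data.frame with one row per (drug, node).
#' @export
npa_table <- function(results) {
  do.call(rbind, lapply(results, function(r) data.frame(
    drug = r$drug, node = names(r$coefficients),
    coefficient = unname(r$coefficients),
    ci_low = unname(r$ci_low), ci_high = unname(r$ci_high),
    amplitude = r$amplitude, pvalue = r$pvalue,
    stringsAsFactors = FALSE, row.names = NULL
  )))
}
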