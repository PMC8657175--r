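# Agreement statistics between expected and observed perturbation directions.
# Concordance: per upstream node, compare the expected sign of each one-edge
# downstream neighbor (upstream state x edge sign) with its observed state.
# Coherence: the same per-edge comparison along a directed path, re-reading
# the OBSERVED upstream state at each step. Rates are chance-corrected with
# Cohen's kappa at a fixed 50% chance level, and compared to a random +-1
# baseline with the one-sided two-sample KS statistic D+.

#' Binarize perturbation coefficients
#'
#' Coefficient > 0 becomes +1 (activation), < 0 becomes -1 (repression);
#' exactly 0 is excluded (`NA`) under the default policy, or mapped to +1
#' under `zero_policy = "positive"`.
#'
#' @param result a `perturbation_result` or a named numeric vector of
#'   coefficients.
#' @param zero_policy `"exclude"` (default) or `"positive"`.
#' @return named integer vector in \{-1, +1, NA\} of class `binarized_state`,
#'   with attribute `"drug"` when available.
#' @export
binarize <- function(result, zero_policy = c("exclude", "positive")) {
  zero_policy <- match.arg(zero_policy)
  coef <- if (inherits(result, "perturbation_result")) result$coefficients
          else result
  stopifnot(is.numeric(coef), !is.null(names(coef)))
  out <- ifelse(coef > 0, 1L, ifelse(coef < 0, -1L,
                if (zero_policy == "positive") 1L else NA_integer_))
  out <- stats::setNames(as.integer(out), names(coef))
  structure(out, drug = if (inherits(result, "perturbation_result"))
    result$drug else attr(result, "drug"), class = "binarized_state")
}

#' Cohen's kappa for binary agreement
#'
#' `kappa = (observed - expected) / (1 - expected)`. The chance level used
#' throughout the package is 0.5, for which `kappa = 2 * rate - 1`.
#'
#' @param observed observed agreement rate in \[0, 1\].
#' @param expected expected (chance) agreement rate in \[0, 1).
#' @return numeric in \[-1, 1\].
#' @export
cohens_kappa <- function(observed, expected = 0.5) {
  if (any(expected >= 1)) stop("expected agreement must be < 1", call. = FALSE)
  (observed - expected) / (1 - expected)
}

#' One-edge subnetworks of a backbone
#'
#' One subnetwork per node with outgoing edges: the upstream node plus its
#' direct downstream neighbors with the connecting edge signs.
#'
#' @param bb a `backbone`.
#' @return named list of objects of class `subnetwork` (fields `upstream`,
#'   `downstream` — a data.frame of `node`, `sign`).
#' @export
subnetworks <- function(bb) {
  stopifnot(inherits(bb, "backbone"))
  by_src <- split(bb$edges, bb$edges$source)
  out <- lapply(names(by_src), function(u) structure(
    list(upstream = u,
         downstream = data.frame(node = by_src[[u]]$target,
                                 sign = by_src[[u]]$sign,
                                 stringsAsFactors = FALSE)),
    class = "subnetwork"))
  stats::setNames(out, names(by_src))
}

agreement_result <- function(unit, unit_id, drug, rate, n) {
  structure(list(unit = unit, unit_id = unit_id, drug = drug,
                 rate = rate,
                 kappa = if (is.na(rate)) NA_real_ else cohens_kappa(rate),
                 n_comparisons = n),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("<agreement_result> %s %s (drug %s): rate %.3f, kappa %.3f over %d comparisons\n",
              x$unit, x$unit_id, x$drug %||% "-", x$rate, x$kappa,
              x$n_comparisons))
  invisible(x)
}

#' Subnetwork concordance
#'
#' For each non-excluded downstream node i, agreement x_i = 1 iff the
#' expected sign (upstream state x edge sign) equals the observed state of i.
#' The rate is the mean of x_i; kappa is chance-corrected at the 50% level.
#' When the upstream state or every downstream state is excluded the result
#' is undefined (`rate = NA`) and is skipped in aggregation.
#'
#' @param sub a `subnetwork` from [subnetworks()].
#' @param state a `binarized_state` from [binarize()].
#' @return an `agreement_result` with `unit = "node"`.
#' @export
concordance <- function(sub, state) {
  stopifnot(inherits(sub, "subnetwork"))
  u <- unname(state[sub$upstream])  # missing name yields NA
  ds <- unname(state[sub$downstream$node])
  usable <- !is.na(ds)
  if (is.na(u) || !any(usable))
    return(agreement_result("node", sub$upstream, attr(state, "drug"),
                            NA_real_, 0L))
  agree <- (u * sub$downstream$sign[usable]) == ds[usable]
  agreement_result("node", sub$upstream, attr(state, "drug"),
                   mean(agree), sum(usable))
}

#' Path coherence
#'
#' For each path edge (v_{i-1}, v_i) with sign s_i where both endpoints are
#' non-excluded, the expected sign of v_i is the OBSERVED state of v_{i-1}
#' times s_i (re-read at every step); agreement is 1 iff it matches the
#' observed state of v_i. `anchor = "root"` instead propagates the root
#' state through the cumulative edge-sign product (sensitivity variant).
#'
#' @param path a `directed_path` from [paths_to()].
#' @param state a `binarized_state`.
#' @param anchor `"observed"` (default) or `"root"`.
#' @return an `agreement_result` with `unit = "path"`.
#' @export
coherence <- function(path, state, anchor = c("observed", "root")) {
  stopifnot(inherits(path, "directed_path"))
  anchor <- match.arg(anchor)
  v <- path$nodes
  s <- path$signs
  st <- unname(state[v])
  k <- length(s)
  agree <- rep(NA, k)
  cum <- if (!is.na(st[1])) st[1] else NA_integer_
  for (i in seq_len(k)) {
    expected <- if (anchor == "observed") {
      if (is.na(st[i])) NA_integer_ else st[i] * s[i]
    } else {
      cum <- if (is.na(cum)) NA_integer_ else cum * s[i]
      cum
    }
    if (!is.na(expected) && !is.na(st[i + 1]))
      agree[i] <- expected == st[i + 1]
  }
  usable <- !is.na(agree)
  rate <- if (any(usable)) mean(agree[usable]) else NA_real_
  agreement_result("path", format(path), attr(state, "drug"),
                   rate, sum(usable))
}

#' Tabulate concordance across drugs
#'
#' @param bb a `backbone` (or [two_layer_network()], whose backbone is used).
#' @param states named list of `binarized_state`, one per drug.
#' @return long data.frame (unit, unit_id, drug, rate, kappa, n_comparisons);
#'   undefined results are kept as `NA` rows so exclusions stay visible, and
#'   are dropped by [aggregate_agreement()].
#' @export
concordance_table <- function(bb, states) {
  if (inherits(bb, "two_layer_network")) bb <- bb$backbone
  subs <- subnetworks(bb)
  rows <- list()
  for (d in names(states))
    for (sub in subs)
      rows[[length(rows) + 1L]] <- concordance(sub, states[[d]])
  agreement_df(rows)
}

#' Tabulate coherence across drugs
#'
#' @param paths list of `directed_path` objects.
#' @param states named list of `binarized_state`, one per drug.
#' @param anchor see [coherence()].
#' @return long data.frame as in [concordance_table()].
#' @export
coherence_table <- function(paths, states, anchor = "observed") {
  rows <- list()
  for (d in names(states))
    for (p in paths)
      rows[[length(rows) + 1L]] <- coherence(p, states[[d]], anchor = anchor)
  agreement_df(rows)
}

agreement_df <- function(results) {
  do.call(rbind, lapply(results, function(r) data.frame(
    unit = r$unit, unit_id = r$unit_id, drug = r$drug %||% NA_character_,
    rate = r$rate, kappa = r$kappa, n_comparisons = r$n_comparisons,
    stringsAsFactors = FALSE
  )))
}

#' Aggregate agreement rates
#'
#' Plain mean of the defined rates (and kappas) grouped by a column of the
#' long agreement table; excluded (undefined) units never contribute zeros.
#'
#' @param tbl long table from [concordance_table()] / [coherence_table()].
#' @param by grouping column: `"drug"`, `"unit_id"` or `"cell_line"`.
#' @return data.frame with mean `rate`, mean `kappa` and `n` per group.
#' @export
aggregate_agreement <- function(tbl, by = c("drug", "unit_id", "cell_line")) {
  by <- match.arg(by)
  tbl <- tbl[!is.na(tbl$rate), , drop = FALSE]
  if (!nrow(tbl))
    return(data.frame(group = character(0), rate = numeric(0),
                      kappa = numeric(0), n = integer(0)))
  sp <- split(tbl, tbl[[by]])
  out <- data.frame(
    group = names(sp),
    rate = vapply(sp, function(x) mean(x$rate), numeric(1)),
    kappa = vapply(sp, function(x) mean(x$kappa), numeric(1)),
    n = vapply(sp, nrow, integer(1)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' One-sided two-sample KS statistic D+
#'
#' `D+ = max_t [ ECDF_baseline(t) - ECDF_sample(t) ]`, clamped at 0, large
#' when the sample is stochastically greater than the baseline. The p-value
#' uses the asymptotic one-sided formula `exp(-2 D^2 n m / (n + m))` on the
#' unscaled statistic. With `scaled = TRUE` the returned statistic is
#' multiplied by `sqrt(n m / (n + m))` (magnitudes comparable to scaled
#' reports; the unscaled statistic always lies in \[0, 1\]).
#'
#' @param sample,baseline non-empty numeric vectors.
#' @param scaled report the sqrt(nm/(n+m))-scaled statistic.
#' @return an object of class `ks_result`: `d_plus`, `pvalue`, `scaled`.
#' @export
ks_dplus <- function(sample, baseline, scaled = FALSE) {
  if (!length(sample) || !length(baseline))
    stop("both samples must be non-empty", call. = FALSE)
  stopifnot(all(is.finite(sample)), all(is.finite(baseline)))
  n <- length(sample)
  m <- length(baseline)
  breaks <- sort(unique(c(sample, baseline)))
  d <- max(0, vapply(breaks, function(t)
    mean(baseline <= t) - mean(sample <= t), numeric(1)))
  pval <- min(1, exp(-2 * d^2 * n * m / (n + m)))
  structure(
    list(d_plus = if (scaled) d * sqrt(n * m / (n + m)) else d,
         pvalue = pval, scaled = scaled),
    class = "ks_result"
  )
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("<ks_result> D+ = %.4g%s, p = %.4g\n", x$d_plus,
              if (x$scaled) " (scaled)" else "", x$pvalue))
  invisible(x)
}

#' Random agreement baseline
#'
#' Draws i.i.d. uniform +-1 states for all nodes involved in the given
#' subnetworks or paths and recomputes the corresponding agreement rates,
#' `n_rep` times. Deterministic given `seed`.
#'
#' @param structures list of `subnetwork` and/or `directed_path` objects.
#' @param n_rep number of replicates (>= 1).
#' @param seed integer seed.
#' @return numeric vector of rates, length `n_rep * length(structures)`.
#' @export
random_baseline <- function(structures, n_rep, seed) {
  stopifnot(n_rep >= 1, length(structures) >= 1)
  nodes <- unique(unlist(lapply(structures, function(x)
    if (inherits(x, "subnetwork")) c(x$upstream, x$downstream$node)
    else x$nodes)))
  withr::with_seed(seed, {
    rates <- numeric(0)
    for (r in seq_len(n_rep)) {
      st <- structure(stats::setNames(sample(c(-1L, 1L), length(nodes),
                                             replace = TRUE), nodes),
                      class = "binarized_state")
      rates <- c(rates, vapply(structures, function(x) {
        res <- if (inherits(x, "subnetwork")) concordance(x, st)
               else coherence(x, st)
        res$rate
      }, numeric(1)))
    }
    rates
  })
}
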