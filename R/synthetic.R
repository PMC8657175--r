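# Synthetic data generators with a recorded ground truth. They emulate the
# statistical structure the pipeline assumes: knockdown DE tables with
# planted direct effects and null genes, drug profiles generated from planted
# per-drug node activations propagated one signed step along the backbone,
# and growth (GRmax) values straddling the effective-dose threshold.
# P-values come from a two-sided z-test against the known noise model, so
# threshold behavior at p < 0.05 / p < 0.01 is calibrated by construction.

#' Generator configuration
#'
#' Defaults describe a realistic single-cell-line knockdown screen: each
#' backbone node regulates `genes_per_node` downstream transcripts, measured
#' among `n_null_genes` unaffected genes; true effects average `effect_size`
#' log2FC units against measurement noise `noise_sd`; a knockdown lowers its
#' own target by `knockdown_depth` log2FC.
#'
#' @param backbone a `backbone`; defaults to the packaged curated network.
#' @param genes_per_node terminal genes planted per backbone node.
#' @param n_null_genes unaffected genes per dataset.
#' @param effect_size mean |log2FC| of true effects.
#' @param noise_sd standard deviation of measurement noise (log2FC units).
#' @param knockdown_depth log2FC applied to a knocked-down target.
#' @param seed integer seed (mandatory; all generators derive their draws
#'   from it).
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(backbone = metastasis_backbone(),
                             genes_per_node = 20, n_null_genes = 500,
                             effect_size = 2, noise_sd = 0.3,
                             knockdown_depth = -2, seed) {
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  stopifnot(inherits(backbone, "backbone"), genes_per_node >= 0,
            n_null_genes >= 0, noise_sd >= 0)
  structure(list(backbone = backbone, genes_per_node = genes_per_node,
                 n_null_genes = n_null_genes, effect_size = effect_size,
                 noise_sd = noise_sd, knockdown_depth = knockdown_depth,
                 seed = as.integer(seed)),
            class = "generator_config")
}

# planted terminal truth: per-node terminal gene sets with signs, drawn
# deterministically from cfg$seed (shared by all generators built on cfg)
terminal_truth <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  nodes <- cfg$backbone$nodes$symbol
  if (cfg$genes_per_node == 0)
    return(data.frame(node = character(0), gene = character(0),
                      sign = integer(0), stringsAsFactors = FALSE))
  withr::with_seed(cfg$seed, {
    do.call(rbind, lapply(nodes, function(u) data.frame(
      node = u,
      gene = sprintf("T_%s_%02d", u, seq_len(cfg$genes_per_node)),
      sign = sample(c(-1L, 1L), cfg$genes_per_node, replace = TRUE),
      stringsAsFactors = FALSE
    )))
  })
}

null_gene_names <- function(cfg) {
  if (cfg$n_null_genes == 0) character(0)
  else sprintf("N%04d", seq_len(cfg$n_null_genes))
}

#' Two-layer network implied by the generator truth
#'
#' The backbone plus the planted terminal layer — the network a noiseless
#' contextualization run reconstructs exactly.
#'
#' @param cfg a [generator_config()].
#' @return a [two_layer_network()].
#' @export
synthetic_two_layer <- function(cfg) {
  two_layer_network(cfg$backbone, terminal_truth(cfg))
}

# two-sided z-test p-value of an observed log2FC against the noise model
noise_pvalue <- function(x, noise_sd) {
  if (noise_sd <= 0) return(ifelse(abs(x) > 0, 0, 1))
  2 * stats::pnorm(-abs(x) / noise_sd)
}

#' Generate knockdown differential-expression datasets
#'
#' One dataset per backbone node u: u's own record gets
#' `knockdown_depth` + noise; each curated direct downstream v of u (edge
#' sign s) gets `-s * effect_size` + noise; u's planted terminal genes get
#' sign-consistent effects; all other genes get pure noise. P-values are
#' two-sided z-tests of the observed log2FC against the noise model.
#' Deterministic given `cfg$seed`.
#'
#' @param cfg a [generator_config()].
#' @return list with `datasets` (named list of [knockdown_dataset()]) and
#'   `truth` (the planted terminal layer).
#' @export
gen_knockdowns <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  bb <- cfg$backbone
  nodes <- bb$nodes$symbol
  tt <- terminal_truth(cfg)
  genes <- c(nodes, tt$gene, null_gene_names(cfg))
  withr::with_seed(cfg$seed + 1L, {
    datasets <- lapply(nodes, function(u) {
      fc <- stats::setNames(numeric(length(genes)), genes)
      fc[u] <- cfg$knockdown_depth
      down <- bb$edges[bb$edges$source == u, , drop = FALSE]
      fc[down$target] <- -down$sign * cfg$effect_size
      tu <- tt[tt$node == u, , drop = FALSE]
      fc[tu$gene] <- -tu$sign * cfg$effect_size
      fc <- fc + stats::rnorm(length(fc), 0, cfg$noise_sd)
      knockdown_dataset(u, data.frame(
        gene = genes, log2fc = unname(fc),
        pvalue = noise_pvalue(unname(fc), cfg$noise_sd),
        stringsAsFactors = FALSE))
    })
  })
  list(datasets = stats::setNames(datasets, nodes), truth = tt)
}

#' Generate drug perturbation profiles
#'
#' Per drug, `nodes_per_drug` backbone nodes are planted with random +-1
#' activities (or, when `pathway` is given, the path's nodes are planted with
#' sign-consistent activities propagated along its edges, making that path
#' fully coherent by construction). Planted activities propagate one signed
#' step along backbone edges to non-planted nodes with `attenuation` 0.5;
#' each active node's terminal genes get
#' `activity x terminal sign x effect_size` + noise, null genes noise only.
#'
#' @param cfg a [generator_config()].
#' @param n_drugs number of drugs (>= 1).
#' @param nodes_per_drug planted nodes per drug (ignored when `pathway` is
#'   given).
#' @param pathway optional `directed_path` the drugs act strictly through.
#' @param attenuation one-step propagation factor (default 0.5).
#' @return list with `profiles` (named list of named numeric vectors) and
#'   `truth` (data.frame drug, node, sign, magnitude of planted effects, plus
#'   attribute `"activity"` — the full post-propagation activity matrix).
#' @export
gen_drug_profiles <- function(cfg, n_drugs, nodes_per_drug = 3,
                              pathway = NULL, attenuation = 0.5) {
  stopifnot(inherits(cfg, "generator_config"), n_drugs >= 1)
  bb <- cfg$backbone
  nodes <- bb$nodes$symbol
  tt <- terminal_truth(cfg)
  genes <- c(tt$gene, null_gene_names(cfg))
  truth <- list()
  activity_mat <- matrix(0, n_drugs, length(nodes),
                         dimnames = list(NULL, nodes))
  withr::with_seed(cfg$seed + 2L, {
    profiles <- lapply(seq_len(n_drugs), function(d) {
      act <- stats::setNames(numeric(length(nodes)), nodes)
      if (is.null(pathway)) {
        planted <- sample(nodes, min(nodes_per_drug, length(nodes)))
        act[planted] <- sample(c(-1, 1), length(planted), replace = TRUE)
      } else {
        stopifnot(inherits(pathway, "directed_path"),
                  all(pathway$nodes %in% nodes))
        planted <- pathway$nodes
        a <- sample(c(-1, 1), 1)
        act[planted] <- a * cumprod(c(1, pathway$signs))
      }
      # one-step signed propagation to non-planted neighbors
      prop <- stats::setNames(numeric(length(nodes)), nodes)
      for (k in seq_len(nrow(bb$edges))) {
        u <- bb$edges$source[k]; v <- bb$edges$target[k]
        if (act[u] != 0 && !(v %in% planted))
          prop[v] <- prop[v] + attenuation * bb$edges$sign[k] * act[u]
      }
      act <- act + prop
      activity_mat[d, ] <<- act
      truth[[d]] <<- data.frame(drug = sprintf("drug%02d", d), node = planted,
                                sign = as.integer(sign(act[planted])),
                                magnitude = abs(act[planted]),
                                stringsAsFactors = FALSE)
      fc <- stats::setNames(numeric(length(genes)), genes)
      on_nodes <- nodes[act != 0]
      for (u in on_nodes) {
        tu <- tt[tt$node == u, , drop = FALSE]
        fc[tu$gene] <- fc[tu$gene] + act[u] * tu$sign * cfg$effect_size
      }
      fc + stats::rnorm(length(fc), 0, cfg$noise_sd)
    })
  })
  truth_df <- do.call(rbind, truth)
  rownames(truth_df) <- NULL
  attr(truth_df, "activity") <- activity_mat
  list(profiles = stats::setNames(profiles, sprintf("drug%02d", seq_len(n_drugs))),
       truth = truth_df)
}

#' Generate growth inhibition values
#'
#' GRmax per (drug, dose) drawn in \[-1, 1.3\]. A configurable fraction of
#' drugs is ineffective: all their doses sit at or above 1 (no growth
#' inhibition), exercising the strict `GRmax < 1` filter. The count of
#' ineffective drugs is exactly `round(fraction_ineffective * n_drugs)`.
#'
#' @param cfg a [generator_config()].
#' @param n_drugs,n_doses counts (>= 1).
#' @param fraction_ineffective fraction of drugs with no effective dose.
#' @return data.frame with columns `drug`, `dose`, `GRmax`.
#' @export
gen_growth <- function(cfg, n_drugs, n_doses = 4, fraction_ineffective = 0.2) {
  stopifnot(inherits(cfg, "generator_config"), n_drugs >= 1, n_doses >= 1)
  n_ineff <- round(fraction_ineffective * n_drugs)
  withr::with_seed(cfg$seed + 3L, {
    ineff <- sample(n_drugs, n_ineff)
    rows <- lapply(seq_len(n_drugs), function(d) {
      gr <- if (d %in% ineff) stats::runif(n_doses, 1, 1.3)
            else stats::runif(n_doses, -1, 1.3)
      if (!d %in% ineff && all(gr >= 1))
        gr[sample.int(n_doses, 1)] <- stats::runif(1, -1, 0.999)
      data.frame(drug = sprintf("drug%02d", d), dose = seq_len(n_doses),
                 GRmax = gr, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
  })
  rownames(out) <- NULL
  out
}

#' Write a complete synthetic input bundle
#'
#' Emits the exact file dialects the pipeline reads: one knockdown TSV per
#' backbone node plus a manifest, a drug-by-gene matrix TSV, a growth TSV,
#' and the ground truth as JSON.
#'
#' @param cfg a [generator_config()].
#' @param dir output directory (created if needed).
#' @param n_drugs,nodes_per_drug,n_doses,fraction_ineffective passed to the
#'   generators.
#' @return `dir`, invisibly; files: `knockdowns/<node>.tsv`,
#'   `knockdown_manifest.tsv`, `drug_matrix.tsv`, `growth.tsv`, `truth.json`.
#' @export
write_synthetic_bundle <- function(cfg, dir, n_drugs = 5, nodes_per_drug = 3,
                                   n_doses = 4, fraction_ineffective = 0.2) {
  dir.create(file.path(dir, "knockdowns"), recursive = TRUE,
             showWarnings = FALSE)
  kd <- gen_knockdowns(cfg)
  for (u in names(kd$datasets))
    write_tsv(kd$datasets[[u]]$records,
              file.path(dir, "knockdowns", paste0(u, ".tsv")))
  write_tsv(data.frame(target = names(kd$datasets),
                       path = file.path("knockdowns",
                                        paste0(names(kd$datasets), ".tsv")),
                       stringsAsFactors = FALSE),
            file.path(dir, "knockdown_manifest.tsv"))
  dp <- gen_drug_profiles(cfg, n_drugs, nodes_per_drug)
  write_drug_matrix(dp$profiles, file.path(dir, "drug_matrix.tsv"))
  growth <- gen_growth(cfg, n_drugs, n_doses, fraction_ineffective)
  write_tsv(growth, file.path(dir, "growth.tsv"))
  jsonlite::write_json(
    list(terminal = kd$truth, drugs = dp$truth,
         config = cfg[c("genes_per_node", "n_null_genes", "effect_size",
                        "noise_sd", "knockdown_depth", "seed")]),
    file.path(dir, "truth.json"), dataframe = "columns", auto_unbox = TRUE,
    digits = NA)
  invisible(dir)
}
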