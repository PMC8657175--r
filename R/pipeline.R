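# End-to-end orchestration: parse -> contextualize -> score -> agree ->
# extract, reading the declared file dialects and writing all report tables
# plus a machine-readable run manifest. Stage-level logging records the
# counts (edges kept/removed/added, drugs filtered, paths enumerated) that
# summarize a run.

#' Pipeline run configuration
#'
#' Every threshold appears exactly once with its documented default: edge
#' filtering/addition (1, 0.05); terminal layer (0.5, 0.01); growth filter
#' GRmax < 1; coherence > 0.6 with top_k 5; path length bound `max_len`;
#' scorer coupling `lambda`; bootstrap/permutation sizes; the zero-coefficient
#' policy; and the run seed. Accepts a YAML file or a list of overrides.
#'
#' @param config path to a YAML config, or a named list of overrides.
#' @param ... further overrides (take precedence over `config`).
#' @return a `run_config` list.
#' @export
run_config <- function(config = NULL, ...) {
  defaults <- list(
    statements = NULL,          # NULL = packaged curated table
    knockdown_manifest = NULL,
    drug_matrix = NULL,
    growth = NULL,
    target = "PEBP1",
    edge_fc = 1, edge_p = 0.05,
    term_fc = 0.5, term_p = 0.01,
    grmax_threshold = 1,
    min_coherence = 0.6, top_k = 5, max_len = 5,
    lambda = 1, n_boot = 200, n_perm = 100,
    zero_policy = "exclude",
    efficiency_action = "exclude",
    add_inferred = TRUE,
    seed = 1L
  )
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(defaults, c(config %||% list(), list(...)))
  stopifnot(cfg$edge_p > 0, cfg$edge_p <= 1, cfg$term_p > 0, cfg$term_p <= 1,
            cfg$min_coherence >= 0, cfg$min_coherence <= 1,
            cfg$top_k >= 1, cfg$max_len >= 1, cfg$n_boot >= 100,
            cfg$n_perm >= 1, !is.null(cfg$seed))
  structure(cfg, class = "run_config")
}

#' Filter drugs by growth inhibition
#'
#' Keeps a drug iff it has at least one effective dose: min over doses of
#' GRmax strictly below `threshold` (default 1, i.e. any growth inhibition).
#' Drugs with no usable dose rows are dropped with a warning.
#'
#' @param growth data.frame with columns `drug`, `dose`, `GRmax`.
#' @param threshold GRmax cutoff (strict `<`).
#' @return character vector of kept drug identifiers.
#' @export
filter_drugs <- function(growth, threshold = 1) {
  stopifnot(nrow(growth) >= 1,
            all(c("drug", "GRmax") %in% names(growth)))
  sp <- split(growth$GRmax, growth$drug)
  usable <- vapply(sp, function(x) any(is.finite(x)), logical(1))
  if (any(!usable))
    warning("drugs with no usable dose values dropped: ",
            paste(names(sp)[!usable], collapse = ", "), call. = FALSE)
  kept <- vapply(sp[usable], function(x) min(x, na.rm = TRUE) < threshold,
                 logical(1))
  names(sp[usable])[kept]
}

pipeline_log <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(fmt, ...))
}

#' Run the full pipeline
#'
#' Stages: parse the statement table and build the backbone; contextualize
#' against the knockdown datasets (filter conflicts, add data-driven edges,
#' build the terminal layer); filter drugs by growth inhibition and score the
#' kept drug profiles; tabulate subnetwork concordance and target-path
#' coherence with random baselines and one-sided KS statistics; rank paths
#' and extract the top-coherent model. All outputs land in `out_dir`;
#' reruns with identical inputs and seeds are byte-identical.
#'
#' @param config a [run_config()] (or list/YAML path coerced through it).
#' @param out_dir output directory, created if needed.
#' @param verbose log stage counts via `message()`.
#' @return invisibly, a list with the main in-memory objects (`network`,
#'   `results`, `concordance`, `coherence`, `ranked`, `model`, `summary`).
#' @export
run_pipeline <- function(config, out_dir, verbose = TRUE) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  # fail before any computation if inputs are missing
  for (key in c("knockdown_manifest", "drug_matrix", "growth")) {
    if (is.null(config[[key]]))
      stop("config$", key, " is required", call. = FALSE)
    if (!file.exists(config[[key]]))
      stop("input not found: ", config[[key]], call. = FALSE)
  }
  if (!is.null(config$statements) && !file.exists(config$statements))
    stop("input not found: ", config$statements, call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  # stage 1: curated backbone
  statements <- if (is.null(config$statements)) metastasis_statements()
                else read_bel_statements(config$statements)
  bb <- build_backbone(statements, gene_roles())
  pipeline_log(verbose, "backbone: %d statements -> %d nodes, %d edges",
               length(statements), nrow(bb$nodes), nrow(bb$edges))

  # stage 2: contextualization
  kds <- read_knockdown_manifest(config$knockdown_manifest)
  net <- contextualize_network(
    bb, kds, edge_fc = config$edge_fc, edge_p = config$edge_p,
    term_fc = config$term_fc, term_p = config$term_p,
    efficiency_action = config$efficiency_action,
    add_inferred = config$add_inferred)
  report <- attr(net, "filter_report")
  inferred <- attr(net, "inferred_edges")
  pipeline_log(verbose,
               "contextualize: %d edges kept, %d removed, %d added; terminal layer %d genes",
               sum(report$action == "kept") , sum(report$action == "removed"),
               nrow(inferred), nrow(net$terminal))
  write_sif(net$backbone, file.path(out_dir, "network.sif"))
  write_graphml(net$backbone, file.path(out_dir, "network.graphml"))
  write_tsv(report, file.path(out_dir, "filter_report.tsv"),
            comment = "curated-edge filtering decisions against source-node knockdowns")
  write_tsv(net$terminal, file.path(out_dir, "terminal_layer.tsv"),
            comment = "transcript layer: backbone_node, gene, sign (+1 activation / -1 repression)")

  # stage 3: drug filtering and NPA-style scoring
  growth <- read_growth_table(config$growth)
  kept <- filter_drugs(growth, config$grmax_threshold)
  profiles <- read_drug_matrix(config$drug_matrix)
  profiles <- profiles[intersect(names(profiles), kept)]
  if (!length(profiles))
    stop("no drug passed the growth filter with an expression profile",
         call. = FALSE)
  pipeline_log(verbose, "drugs: %d of %d pass GRmax < %g and have profiles",
               length(profiles), length(unique(growth$drug)),
               config$grmax_threshold)
  results <- npa_scores(net, profiles, lambda = config$lambda,
                        n_boot = config$n_boot, n_perm = config$n_perm,
                        seed = config$seed)
  write_tsv(npa_table(results), file.path(out_dir, "npa_coefficients.tsv"),
            comment = "per-drug backbone coefficients (dimensionless; >0 activation) with bootstrap CIs and permutation p")
  jsonlite::write_json(
    lapply(results, function(r) list(
      drug = r$drug, coefficients = as.list(r$coefficients),
      ci_low = as.list(r$ci_low), ci_high = as.list(r$ci_high),
      amplitude = r$amplitude, pvalue = r$pvalue)),
    file.path(out_dir, "npa_results.json"), auto_unbox = TRUE, digits = NA)

  # stage 4: agreement
  states <- lapply(results, binarize, zero_policy = config$zero_policy)
  conc <- concordance_table(net, states)
  paths <- paths_to(net, config$target, max_len = config$max_len)
  pipeline_log(verbose, "paths: %d simple paths of length <= %d end at %s",
               length(paths), config$max_len, config$target)
  coh <- coherence_table(paths, states)
  write_tsv(conc, file.path(out_dir, "concordance.tsv"),
            comment = "subnetwork concordance per (drug, upstream node); rate in [0,1], kappa = 2*rate-1")
  write_tsv(coh, file.path(out_dir, "coherence.tsv"),
            comment = paste0("path coherence per (drug, path to ", config$target,
                             "); rate in [0,1], kappa = 2*rate-1"))
  subs <- subnetworks(net$backbone)
  summary <- list()
  base_conc <- random_baseline(subs, n_rep = 200, seed = config$seed + 101L)
  base_coh <- if (length(paths))
    random_baseline(paths, n_rep = 200, seed = config$seed + 102L) else numeric(0)
  for (lv in c("drug", "unit_id")) {
    agg_c <- aggregate_agreement(conc, by = lv)
    ks_c <- ks_dplus(agg_c$rate, base_conc)
    entry <- list(concordance = list(
      mean_rate = mean(agg_c$rate), mean_kappa = mean(agg_c$kappa),
      n = nrow(agg_c), d_plus = ks_c$d_plus, pvalue = ks_c$pvalue))
    agg_h <- aggregate_agreement(coh, by = lv)
    if (nrow(agg_h) && length(base_coh)) {
      ks_h <- ks_dplus(agg_h$rate, base_coh)
      entry$coherence <- list(
        mean_rate = mean(agg_h$rate), mean_kappa = mean(agg_h$kappa),
        n = nrow(agg_h), d_plus = ks_h$d_plus, pvalue = ks_h$pvalue)
    }
    summary[[if (lv == "drug") "by_drug" else "by_unit"]] <- entry
  }
  jsonlite::write_json(summary, file.path(out_dir, "agreement_summary.json"),
                       auto_unbox = TRUE, digits = NA)

  # stage 5: path ranking and model extraction
  ranked <- rank_paths(paths, results, zero_policy = config$zero_policy)
  write_ranked_paths(ranked, file.path(out_dir, "ranked_paths.tsv"))
  model <- withCallingHandlers(
    extract_model(ranked, min_coherence = config$min_coherence,
                  top_k = config$top_k, roles = gene_roles()),
    warning = function(w) {
      pipeline_log(verbose, "model: %s", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  pipeline_log(verbose, "model: %d edges from top-%d paths above coherence %g",
               nrow(model$edges), config$top_k, config$min_coherence)
  write_sif(model, file.path(out_dir, "model.sif"))
  if (nrow(model$edges)) {
    write_graphml(model, file.path(out_dir, "model.graphml"))
    # DOT has no boolean attribute type; igraph warns on coercion
    suppressWarnings(
      igraph::write_graph(as_igraph(model), file.path(out_dir, "model.dot"),
                          format = "dot"))
  }

  manifest <- list(
    package = "rcrnet",
    version = as.character(utils::packageVersion("rcrnet")),
    config = unclass(config),
    counts = list(
      statements = length(statements),
      backbone_nodes = nrow(net$backbone$nodes),
      backbone_edges = nrow(net$backbone$edges),
      edges_removed = sum(report$action == "removed"),
      edges_added = nrow(inferred),
      terminal_genes = nrow(net$terminal),
      drugs_scored = length(profiles),
      paths = length(paths),
      model_edges = nrow(model$edges)
    )
  )
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(network = net, results = results, concordance = conc,
                 coherence = coh, ranked = ranked, model = model,
                 summary = summary, manifest = manifest))
}
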