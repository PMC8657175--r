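# Readers and writers for the file dialects the pipeline consumes and emits:
# the curated statement table, per-knockdown differential expression TSVs with
# a manifest, the drug-by-gene expression matrix, growth (GRmax) tables, and
# commented TSV report output.

rcrnet_file <- function(...) {
  system.file("extdata", ..., package = "rcrnet", mustWork = TRUE)
}

#' Read a table of BEL-subset causal statements
#'
#' The file is a UTF-8 TSV with columns `subject`, `object`, `reference` and
#' `statement` (the BEL text, which is authoritative for the parse); `#`
#' comment lines are allowed. The `subject`/`object` index columns are
#' retained only as metadata.
#'
#' @param path TSV path.
#' @param aliases alias table from [bel_aliases()].
#' @return list of [causal_statement()] objects.
#' @export
read_bel_statements <- function(path, aliases = bel_aliases()) {
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("subject", "object", "reference", "statement")
  if (!all(need %in% names(tab)))
    stop("statement table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  lapply(seq_len(nrow(tab)), function(i)
    parse_statement(tab$statement[i], evidence = tab$reference[i],
                    aliases = aliases))
}

#' Packaged curated interaction table and gene roles
#'
#' `metastasis_statements()` parses the packaged table of curated causal
#' interactions among seventeen metastasis suppressor genes and eleven
#' transcription factors; `msg_symbols()` and `tf_symbols()` return the two
#' role lists; `gene_roles()` combines them into a symbol -> role mapping;
#' `metastasis_backbone()` builds the functional-layer graph.
#'
#' @return see individual descriptions.
#' @export
metastasis_statements <- function() {
  read_bel_statements(rcrnet_file("table3_statements.tsv"))
}

#' @rdname metastasis_statements
#' @export
msg_symbols <- function() {
  utils::read.delim(rcrnet_file("msg_genes.tsv"), comment.char = "#",
                    stringsAsFactors = FALSE)$symbol
}

#' @rdname metastasis_statements
#' @export
tf_symbols <- function() {
  utils::read.delim(rcrnet_file("tf_genes.tsv"), comment.char = "#",
                    stringsAsFactors = FALSE)$symbol
}

#' @rdname metastasis_statements
#' @export
gene_roles <- function() {
  c(stats::setNames(rep("MSG", length(msg_symbols())), msg_symbols()),
    stats::setNames(rep("TF", length(tf_symbols())), tf_symbols()))
}

#' @rdname metastasis_statements
#' @export
metastasis_backbone <- function() {
  build_backbone(metastasis_statements(), gene_roles())
}

#' Read a knockdown differential expression table
#'
#' A TSV with columns `gene`, `log2FC` and `pvalue` (case-insensitive,
#' `log2fc` accepted), one row per gene, including the knocked-down target
#' itself.
#'
#' @param path TSV path.
#' @param target the knocked-down gene symbol.
#' @return a [knockdown_dataset()].
#' @export
read_knockdown_table <- function(path, target) {
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  names(tab) <- tolower(names(tab))
  need <- c("gene", "log2fc", "pvalue")
  if (!all(need %in% names(tab)))
    stop("knockdown table must have columns gene, log2FC, pvalue: ", path,
         call. = FALSE)
  knockdown_dataset(target,
                    data.frame(gene = tab$gene, log2fc = tab$log2fc,
                               pvalue = tab$pvalue, stringsAsFactors = FALSE))
}

#' Read a knockdown manifest
#'
#' A TSV with columns `target` and `path` (paths resolved relative to the
#' manifest's directory), one row per knockdown experiment.
#'
#' @param path manifest TSV path.
#' @return named list of [knockdown_dataset()] objects, names = targets.
#' @export
read_knockdown_manifest <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("target", "path") %in% names(tab)))
  base <- dirname(path)
  kds <- lapply(seq_len(nrow(tab)), function(i) {
    p <- tab$path[i]
    if (!file.exists(p)) p <- file.path(base, p)
    read_knockdown_table(p, tab$target[i])
  })
  stats::setNames(kds, tab$target)
}

#' Read a drug-by-gene expression matrix
#'
#' A TSV with genes in rows (first column `gene`) and one column of log2
#' fold-changes per drug.
#'
#' @param path TSV path.
#' @return named list of drug profiles (named numeric vectors, gene -> log2FC).
#' @export
read_drug_matrix <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                           stringsAsFactors = FALSE)
  stopifnot(names(tab)[1] == "gene")
  genes <- tab$gene
  profiles <- lapply(names(tab)[-1], function(d)
    stats::setNames(as.numeric(tab[[d]]), genes))
  stats::setNames(profiles, names(tab)[-1])
}

#' Write a drug-by-gene expression matrix
#' @param profiles named list of named numeric vectors.
#' @param path output TSV.
#' @export
write_drug_matrix <- function(profiles, path) {
  genes <- sort(unique(unlist(lapply(profiles, names))))
  mat <- vapply(profiles, function(p) unname(p[genes]), numeric(length(genes)))
  out <- data.frame(gene = genes, mat, check.names = FALSE,
                    stringsAsFactors = FALSE)
  names(out) <- c("gene", names(profiles))
  write_tsv(out, path)
}

#' Read a growth table
#'
#' A TSV with columns `drug`, `dose` and `GRmax` (growth-rate-corrected
#' maximum inhibition; values < 1 indicate growth inhibition).
#'
#' @param path TSV path.
#' @return data.frame with those three columns.
#' @export
read_growth_table <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  names(tab)[tolower(names(tab)) == "grmax"] <- "GRmax"
  stopifnot(all(c("drug", "dose", "GRmax") %in% names(tab)))
  tab[, c("drug", "dose", "GRmax")]
}

# write a TSV with optional '#' comment header lines
write_tsv <- function(df, path, comment = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
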