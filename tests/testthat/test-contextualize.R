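# Contextualization rules: efficiency gate, conflict removal, data-driven
# edge inference, terminal layer, and their invariants.

kd_of <- function(target, genes, log2fc, pvalue) {
  knockdown_dataset(target, data.frame(gene = genes, log2fc = log2fc,
                                       pvalue = pvalue,
                                       stringsAsFactors = FALSE))
}

test_that("knockdown efficiency requires a deep, significant self fold-change", {
  expect_true(check_efficiency(kd_of("A1", "A1", -2.3, 0.001)))
  expect_false(check_efficiency(kd_of("A1", "A1", -0.4, 0.2)))
  expect_false(check_efficiency(kd_of("A1", "A1", -2.3, 0.2)))
  # the target must be present in its own records
  expect_error(kd_of("A1", "B1", -2.3, 0.001), "missing from its own records")
})

test_that("conflict filtering removes exactly the contradicted curated edges", {
  bb <- bb_from_edges("A1", "B1", 1)
  base <- function(b_fc, b_p) list(A1 = kd_of(
    "A1", c("A1", "B1"), c(-2, b_fc), c(0.001, b_p)))

  # B rose significantly when its activator fell -> removed
  out <- filter_conflicts(bb, base(1.5, 0.01))
  expect_equal(nrow(backbone_edges(out)), 0)
  expect_equal(attr(out, "filter_report")$action, "removed")

  # consistent response -> kept
  out <- filter_conflicts(bb, base(-2.0, 0.001))
  expect_equal(nrow(backbone_edges(out)), 1)

  # insufficient evidence -> kept
  out <- filter_conflicts(bb, base(0.4, 0.3))
  expect_equal(nrow(backbone_edges(out)), 1)

  # significant but in the predicted direction -> kept
  out <- filter_conflicts(bb, base(-1.5, 0.01))
  expect_equal(nrow(backbone_edges(out)), 1)

  # no knockdown of the source -> kept unchanged
  out <- filter_conflicts(bb, list())
  expect_equal(nrow(backbone_edges(out)), 1)

  # an infinite threshold is the identity
  out <- filter_conflicts(bb, base(50, 1e-10), fc_abs = Inf)
  expect_equal(backbone_edges(out), backbone_edges(bb))
})

test_that("data-driven edges follow the knockdown direction logic", {
  bb <- bb_from_edges(c("X1", "X1"), c("Y1", "Z1"), c(1, 1))
  # W1 is a backbone node with no X1 edge yet
  bb <- add_edges(bb, data.frame(source = "W1", target = "Z1", sign = 1L,
                                 direct = FALSE, provenance = "curated",
                                 evidence = "ref", stringsAsFactors = FALSE))
  kds <- list(X1 = kd_of("X1", c("X1", "Y1", "W1"),
                         c(-2, -1.8, 1.2), c(1e-4, 0.003, 0.01)))
  new <- infer_edges(bb, kds)
  # Y1 already has a curated X1 edge; W1 rose -> repression edge
  expect_equal(nrow(new), 1)
  expect_equal(new$source, "X1")
  expect_equal(new$target, "W1")
  expect_equal(new$sign, -1L)
  expect_true(new$direct)
  expect_equal(new$provenance, "data_driven")

  # falling node -> activation edge
  kds2 <- list(X1 = kd_of("X1", c("X1", "W1"), c(-2, -1.8), c(1e-4, 0.003)))
  new2 <- infer_edges(bb, kds2)
  expect_equal(new2$sign, 1L)

  # insignificant changes add nothing
  kds3 <- list(X1 = kd_of("X1", c("X1", "W1"), c(-2, -0.8), c(1e-4, 0.2)))
  expect_equal(nrow(infer_edges(bb, kds3)), 0)
})

test_that("the terminal layer collects signed non-backbone responders", {
  bb <- bb_from_edges("U1", "V1", 1)
  kds <- list(U1 = kd_of("U1", c("U1", "V1", "g1", "g2", "g3"),
                         c(-2, -1.5, -0.8, 0.9, -0.8),
                         c(1e-4, 1e-3, 0.005, 0.002, 0.05)))
  term <- build_terminal(bb, kds)
  # V1 is a backbone node: excluded; g3 fails p < 0.01; g1 fell -> +1
  expect_equal(sort(term$gene), c("g1", "g2"))
  expect_equal(term$sign[term$gene == "g1"], 1L)
  expect_equal(term$sign[term$gene == "g2"], -1L)
  expect_equal(unique(term$node), "U1")
  expect_equal(attr(term, "uncovered"), "V1")

  # flipping every fold-change flips every terminal sign
  kds_neg <- list(U1 = kd_of("U1", c("U1", "V1", "g1", "g2", "g3"),
                             -c(-2, -1.5, -0.8, 0.9, -0.8),
                             c(1e-4, 1e-3, 0.005, 0.002, 0.05)))
  term_neg <- build_terminal(bb, kds_neg)
  expect_equal(term_neg$sign, -term$sign)
})

test_that("two-layer assembly rejects stray terminal keys and bad signs", {
  bb <- bb_from_edges("U1", "V1", 1)
  expect_error(two_layer_network(bb, data.frame(node = "Q1", gene = "g",
                                                sign = 1L)),
               "not in backbone")
  expect_error(two_layer_network(bb, data.frame(node = "U1", gene = "g",
                                                sign = 0L)),
               "signs must be")
})

test_that("noiseless synthetic knockdowns reconstruct the planted truth exactly", {
  bb <- rand_backbone(8, 14, seed = 42)
  cfg <- generator_config(backbone = bb, genes_per_node = 6, n_null_genes = 50,
                          noise_sd = 0, seed = 7)
  kd <- gen_knockdowns(cfg)
  for (u in names(kd$datasets))
    expect_true(check_efficiency(kd$datasets[[u]]))

  net <- contextualize_network(bb, kd$datasets)
  expect_equal(sum(attr(net, "filter_report")$action == "removed"), 0)
  expect_equal(nrow(attr(net, "inferred_edges")), 0)

  got <- net$terminal[order(net$terminal$node, net$terminal$gene), ]
  want <- kd$truth[order(kd$truth$node, kd$truth$gene), ]
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want)
})

test_that("filtering and inference commute on disjoint evidence and never overlap", {
  bb <- bb_from_edges(c("A1", "B1"), c("B1", "C1"), c(1, -1))
  kds <- list(A1 = kd_of("A1", c("A1", "B1", "C1"),
                         c(-2, 1.6, -1.4), c(1e-4, 0.01, 0.02)))
  filtered <- filter_conflicts(bb, kds)       # removes A1 -> B1
  inferred <- infer_edges(bb, kds)            # adds A1 -> C1 only
  expect_equal(nrow(backbone_edges(filtered)), 1)
  expect_equal(inferred$target, "C1")
  # filtering never adds; inference never removes; order does not matter
  expect_true(all(paste(backbone_edges(filtered)$source,
                        backbone_edges(filtered)$target) %in%
                  paste(backbone_edges(bb)$source, backbone_edges(bb)$target)))
  a <- add_edges(filtered, inferred)
  b <- filter_conflicts(add_edges(bb, inferred), kds)
  expect_equal(backbone_edges(a), backbone_edges(b))
})
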