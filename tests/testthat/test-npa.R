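# NPA-style scorer: terminal scores, the quadratic coefficient solver
# (checked against an independent derivative-free oracle), the amplitude,
# and the bootstrap/permutation uncertainty machinery.

test_that("terminal scores average signed downstream fold-changes", {
  bb <- bb_from_edges("U1", "V1", 1)
  net <- net_with_terminal(bb, rep("U1", 3), c("g1", "g2", "g3"), c(1, 1, 1))
  expect_equal(terminal_score(net, c(g1 = 2, g2 = 2, g3 = 2), "U1"), 2)
  expect_equal(terminal_score(net, c(g1 = 1, g2 = 1, g3 = -1), "U1"), 1 / 3)
  expect_equal(terminal_score(net, c(g1 = 0, g2 = 0, g3 = 0), "U1"), 0)
  # mixed signs weight the mean
  net2 <- net_with_terminal(bb, rep("U1", 2), c("g1", "g2"), c(1, -1))
  expect_equal(terminal_score(net2, c(g1 = 1, g2 = 1), "U1"), 0)
  # absent genes are skipped; all absent / empty set are undefined flags
  expect_equal(terminal_score(net, c(g1 = 2, zz = 9), "U1"), 2)
  expect_true(is.na(terminal_score(net, c(zz = 9), "U1")))
  expect_true(is.na(terminal_score(net, c(g1 = 1), "V1")))
  expect_error(terminal_score(net, c(g1 = 1), "QQ"), "not a backbone node")
})

test_that("coefficients solve the anchored smoothing objective", {
  # single node: data term only
  bb1 <- build_backbone(list(parse_statement("p(A1) increases p(B1)")))
  net1 <- net_with_terminal(bb1, c("A1", "B1"), c("ga", "gb"), c(1, 1))
  f <- infer_backbone(net1, c(ga = 1, gb = 1))
  expect_equal(unname(f), c(1, 1), tolerance = 1e-12)  # consistent fixed point

  # an isolated anchored node reproduces its own terminal score
  bbi <- bb_from_edges(c("A1", "C1"), c("B1", "D1"), c(1, 1))
  neti <- net_with_terminal(bbi, c("A1", "B1", "C1", "D1"),
                            c("ga", "gb", "gc", "gd"), c(1, 1, 1, 1))
  # C1/D1 component has no profile coverage -> zeroed and reported
  f2 <- infer_backbone(neti, c(ga = 0.5, gb = 0.5))
  expect_equal(unname(f2[c("A1", "B1")]), c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(unname(f2[c("C1", "D1")]), c(0, 0))
  expect_setequal(attr(f2, "unanchored"), c("C1", "D1"))

  # repression edge: consistent input has opposite signs
  bbr <- bb_from_edges("A1", "B1", -1)
  netr <- net_with_terminal(bbr, c("A1", "B1"), c("ga", "gb"), c(1, 1))
  fr <- infer_backbone(netr, c(ga = 1, gb = -1))
  expect_equal(unname(fr), c(1, -1), tolerance = 1e-12)
})

test_that("the solver matches the independent quadratic oracle", {
  for (seed in 1:5) {
    tl <- rand_two_layer(5, 8, genes_per_node = 4, seed = seed)
    f <- infer_backbone(tl$net, tl$profile)
    f0 <- oracle_coefficients(tl$net, tl$profile)
    expect_equal(unname(f[names(f0)]), unname(f0), tolerance = 1e-8)
  }
})

test_that("amplitude is the mean squared edge co-perturbation", {
  bb <- bb_from_edges("A1", "B1", 1)
  net <- net_with_terminal(bb, c("A1", "B1"), c("ga", "gb"), c(1, 1))
  f <- stats::setNames(c(1, 1), c("A1", "B1"))
  expect_equal(network_amplitude(f, net), 1)
  expect_equal(network_amplitude(f * 0, net), 0)
  # anti-coherent pair on an activation edge scores zero
  expect_equal(network_amplitude(stats::setNames(c(1, -1), c("A1", "B1")), net), 0)
  # even in f
  expect_equal(network_amplitude(-f, net), network_amplitude(f, net))
  # no edges -> 0
  bb0 <- drop_edges(bb, 1)
  net0 <- two_layer_network(bb0, net$terminal)
  expect_equal(network_amplitude(f, net0), 0)
})

test_that("linearity and antisymmetry hold to machine precision", {
  tl <- rand_two_layer(6, 10, genes_per_node = 5, seed = 11)
  f1 <- infer_backbone(tl$net, tl$profile)
  f3 <- infer_backbone(tl$net, 3 * tl$profile)
  fneg <- infer_backbone(tl$net, -tl$profile)
  expect_equal(unname(3 * f1), unname(f3), tolerance = 1e-12)
  expect_equal(unname(fneg), unname(-f1), tolerance = 1e-12)
  expect_equal(network_amplitude(f3, tl$net),
               9 * network_amplitude(f1, tl$net), tolerance = 1e-10)
  expect_equal(network_amplitude(fneg, tl$net),
               network_amplitude(f1, tl$net), tolerance = 1e-12)
})

test_that("uncertainty is seeded, bounded and guards its sample sizes", {
  tl <- rand_two_layer(5, 8, genes_per_node = 8, seed = 3)
  expect_error(npa_score(tl$net, tl$profile, n_boot = 1, seed = 1),
               "at least 100")
  expect_error(npa_score(tl$net, tl$profile, n_perm = 0, seed = 1),
               "at least 1")
  expect_error(npa_score(tl$net, tl$profile), "seed is required")

  r1 <- npa_score(tl$net, tl$profile, n_boot = 100, n_perm = 20, seed = 5)
  r2 <- npa_score(tl$net, tl$profile, n_boot = 100, n_perm = 20, seed = 5)
  expect_identical(r1, r2)
  expect_true(all(r1$ci_low <= r1$coefficients + 1e-12))
  expect_true(all(r1$ci_high >= r1$coefficients - 1e-12))
  expect_gte(r1$amplitude, 0)
  expect_gt(r1$pvalue, 0)
  expect_lte(r1$pvalue, 1)

  r3 <- npa_score(tl$net, tl$profile, n_boot = 100, n_perm = 20, seed = 6)
  expect_false(identical(r1$ci_low, r3$ci_low))
})

test_that("bootstrap intervals tighten as terminal sets grow (noiseless profile)", {
  widths <- vapply(c(5, 40), function(k) {
    bb <- bb_from_edges("A1", "B1", 1)
    term <- data.frame(node = rep(c("A1", "B1"), each = k),
                       gene = sprintf("g%03d", seq_len(2 * k)),
                       sign = 1L, stringsAsFactors = FALSE)
    net <- two_layer_network(bb, term)
    # signal plus small heterogeneity so resampling has something to vary
    prof <- stats::setNames(1 + 0.1 * sin(seq_len(2 * k)), term$gene)
    r <- npa_score(net, prof, n_boot = 200, n_perm = 1, seed = 9)
    mean(r$ci_high - r$ci_low)
  }, numeric(1))
  expect_lt(widths[2], widths[1])
})
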