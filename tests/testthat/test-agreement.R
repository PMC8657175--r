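# Agreement statistics: binarization, concordance, coherence (both anchor
# conventions), Cohen's kappa, the one-sided KS D+, and the random baseline.

test_that("binarization maps signs and applies the zero policy", {
  st <- binarize(c(A1 = 0.12, B1 = -0.05))
  expect_equal(unname(st[c("A1", "B1")]), c(1L, -1L))
  expect_true(is.na(binarize(c(A1 = 0))[["A1"]]))
  expect_equal(binarize(c(A1 = 0), zero_policy = "positive")[["A1"]], 1L)
})

test_that("concordance follows the u x e = x' rule with exclusions", {
  sub <- subnetworks(bb_from_edges(c("U1", "U1"), c("A1", "B1"), c(1, -1)))$U1
  r <- concordance(sub, state_of(c(U1 = 1, A1 = 1, B1 = -1)))
  expect_equal(r$rate, 1)
  expect_equal(r$kappa, 1)
  expect_equal(r$n_comparisons, 2)

  sub2 <- subnetworks(bb_from_edges(c("U1", "U1"), c("A1", "B1"), c(1, 1)))$U1
  r2 <- concordance(sub2, state_of(c(U1 = 1, A1 = 1, B1 = -1)))
  expect_equal(r2$rate, 0.5)
  expect_equal(r2$kappa, 0)

  sub3 <- subnetworks(bb_from_edges("U1", "A1", 1))$U1
  r3 <- concordance(sub3, state_of(c(U1 = -1, A1 = 1)))
  expect_equal(r3$rate, 0)
  expect_equal(r3$kappa, -1)

  # excluded downstream nodes drop out of the mean
  r4 <- concordance(sub, state_of(c(U1 = 1, A1 = 1, B1 = NA)))
  expect_equal(r4$rate, 1)
  expect_equal(r4$n_comparisons, 1)
  # excluded upstream or all-excluded downstream are undefined
  expect_true(is.na(concordance(sub, state_of(c(U1 = NA, A1 = 1, B1 = 1)))$rate))
  expect_true(is.na(concordance(sub, state_of(c(U1 = 1, A1 = NA, B1 = NA)))$rate))
})

test_that("concordance is invariant under global state negation", {
  bb <- rand_backbone(6, 12, seed = 21)
  subs <- subnetworks(bb)
  withr::with_seed(1, {
    for (rep in 1:20) {
      st <- state_of(stats::setNames(sample(c(-1L, 1L), 6, TRUE),
                                     bb$nodes$symbol))
      stn <- state_of(-unclass(st))
      for (sub in subs)
        expect_equal(concordance(sub, st)$rate, concordance(sub, stn)$rate)
    }
  })
})

test_that("coherence re-reads the observed upstream state at every step", {
  p <- directed_path(c("R1", "S1", "T1"), c(-1, -1))
  r <- coherence(p, state_of(c(R1 = 1, S1 = -1, T1 = 1)))
  expect_equal(r$rate, 1)
  expect_equal(r$kappa, 1)

  # observed anchoring: edge1 expects S=-1 (miss), edge2 expects T=S_obs*s2=-1 (miss)
  r2 <- coherence(p, state_of(c(R1 = 1, S1 = 1, T1 = 1)))
  expect_equal(r2$rate, 0)
  # root anchoring instead propagates the expectation: edge2 expects +1 (hit)
  r3 <- coherence(p, state_of(c(R1 = 1, S1 = 1, T1 = 1)), anchor = "root")
  expect_equal(r3$rate, 0.5)
  expect_equal(r3$kappa, 0)

  # edges with an excluded endpoint are unusable
  r4 <- coherence(p, state_of(c(R1 = 1, S1 = NA, T1 = 1)))
  expect_true(is.na(r4$rate))
  expect_equal(r4$n_comparisons, 0)

  # a length-1 path equals the single-edge concordance term
  bb <- bb_from_edges("U1", "A1", -1)
  p1 <- paths_to(bb, "A1", max_len = 1)[[1]]
  st <- state_of(c(U1 = 1, A1 = -1))
  expect_equal(coherence(p1, st)$rate,
               concordance(subnetworks(bb)$U1, st)$rate)
})

test_that("coherence matches exhaustive stepwise recomputation on random graphs", {
  cases <- 0
  for (seed in 1:3) {
    bb <- rand_backbone(6, 10, seed = 100 + seed)
    nodes <- bb$nodes$symbol
    paths <- paths_to(bb, nodes[1], max_len = 3)
    if (!length(paths)) next
    states <- expand.grid(rep(list(c(-1L, 1L)), length(nodes)))
    for (k in seq_len(nrow(states))) {
      st <- state_of(stats::setNames(unlist(states[k, ]), nodes))
      for (p in paths) {
        # independent recomputation: plain loop over edges
        hits <- integer(0)
        for (i in seq_along(p$signs)) {
          a <- st[[p$nodes[i]]]; b <- st[[p$nodes[i + 1]]]
          hits <- c(hits, as.integer(a * p$signs[i] == b))
        }
        expect_equal(coherence(p, st)$rate, mean(hits))
        cases <- cases + 1
      }
    }
  }
  expect_gte(cases, 500)
})

test_that("Cohen's kappa is the chance-corrected agreement", {
  expect_equal(cohens_kappa(0.75, 0.5), 0.5)
  expect_equal(cohens_kappa(1.0, 0.5), 1.0)
  expect_equal(cohens_kappa(0.5, 0.5), 0.0)
  expect_equal(cohens_kappa(0.25, 0.5), -0.5)
  expect_equal(cohens_kappa(0.9, 0.8), 0.5)
  expect_error(cohens_kappa(0.9, 1), "must be < 1")
})

test_that("D+ equals the maximal ECDF excess and handles the extremes", {
  expect_equal(ks_dplus(c(1, 2, 3), c(1, 2, 3))$d_plus, 0)
  expect_equal(ks_dplus(rep(1, 5), rep(0, 5))$d_plus, 1)
  # p-value formula on the unscaled statistic
  r <- ks_dplus(rep(1, 5), rep(0, 5))
  expect_equal(r$pvalue, exp(-2 * 1 * 25 / 10))
  # scaling multiplies by sqrt(nm/(n+m)) and can exceed 1
  rs <- ks_dplus(rep(1, 50), rep(0, 50), scaled = TRUE)
  expect_equal(rs$d_plus, sqrt(2500 / 100))
  expect_gt(rs$d_plus, 1)
  expect_error(ks_dplus(numeric(0), 1), "non-empty")
})

test_that("D+ agrees with brute force and with the reference implementation", {
  withr::with_seed(7, {
    for (i in 1:30) {
      x <- stats::rnorm(sample(5:40, 1))
      y <- stats::rnorm(sample(5:40, 1), mean = stats::runif(1, -1, 1))
      d <- ks_dplus(x, y)$d_plus
      # brute force over all breakpoints with hand-counted ECDFs
      brute <- max(0, max(vapply(c(x, y), function(t)
        sum(y <= t) / length(y) - sum(x <= t) / length(x), numeric(1))))
      expect_equal(d, brute)
      # cross-check against stats::ks.test's one-sided statistic
      ref <- suppressWarnings(stats::ks.test(y, x, alternative = "greater"))
      expect_equal(d, unname(ref$statistic))
    }
  })
})

test_that("the random baseline is seeded, bounded, and centered at chance", {
  bb <- bb_from_edges(c("U1", "U1", "V1"), c("A1", "B1", "A1"), c(1, -1, 1))
  subs <- subnetworks(bb)
  b1 <- random_baseline(subs, n_rep = 50, seed = 4)
  b2 <- random_baseline(subs, n_rep = 50, seed = 4)
  expect_identical(b1, b2)
  expect_true(all(b1 >= 0 & b1 <= 1))

  # single-downstream subnetworks only hit 0 or 1
  single <- subnetworks(bb_from_edges("V1", "A1", 1))
  expect_true(all(random_baseline(single, n_rep = 200, seed = 1) %in% c(0, 1)))

  # law of large numbers at chance level 0.5
  big <- random_baseline(subs["U1"], n_rep = 10000, seed = 2)
  expect_equal(mean(big), 0.5, tolerance = 0.02)
})

test_that("kappa = 2*rate - 1 for every emitted agreement row", {
  bb <- rand_backbone(7, 14, seed = 31)
  states <- withr::with_seed(8, lapply(stats::setNames(1:4, paste0("d", 1:4)),
    function(i) state_of(stats::setNames(sample(c(-1L, 1L), 7, TRUE),
                                         bb$nodes$symbol), drug = paste0("d", i))))
  conc <- concordance_table(bb, states)
  target <- backbone_edges(bb)$target[1]  # guaranteed incoming edge
  coh <- coherence_table(paths_to(bb, target, max_len = 3), states)
  for (tbl in list(conc, coh)) {
    ok <- !is.na(tbl$rate)
    expect_true(any(ok))
    expect_equal(tbl$kappa[ok], 2 * tbl$rate[ok] - 1)
  }
  # aggregation means only defined rows
  agg <- aggregate_agreement(conc, by = "drug")
  expect_true(all(agg$rate >= 0 & agg$rate <= 1))
  expect_equal(agg$kappa, 2 * agg$rate - 1, tolerance = 1e-12)
})
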