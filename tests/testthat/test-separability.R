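test_that("shortest paths agree with a breadth-first-search oracle on random graphs", {
  # hand-checked toys first
  net <- toy_network()                      # path da-db-dc, dd isolated
  d <- all_pairs_shortest_paths(net)
  expect_equal(d["da", "dc"], 2)
  expect_equal(d["da", "dd"], Inf)          # cross-component
  expect_equal(unname(diag(d)), rep(0, 4))

  # 5-cycle: eccentricity 2
  ids <- sprintf("c%d", 1:5)
  adj <- matrix(0, 5, 5, dimnames = list(ids, ids))
  for (i in 1:5) {
    j <- i %% 5 + 1
    adj[i, j] <- adj[j, i] <- 1
  }
  d5 <- all_pairs_shortest_paths(ddi_network(adj, ids))
  expect_equal(max(d5), 2)

  set.seed(55)
  for (rep in 1:20) {
    m <- sample(4:20, 1)
    ids <- sprintf("g%02d", 1:m)
    a <- matrix(0, m, m, dimnames = list(ids, ids))
    ut <- which(upper.tri(a))
    a[ut] <- rbinom(length(ut), 1, 0.2)
    a <- a + t(a)
    d <- all_pairs_shortest_paths(ddi_network(a, ids))
    for (src in sample(m, 2)) {
      expect_equal(unname(d[src, ]), bfs_distances(a, src))
    }
  }
})

test_that("DDI distance separability combines class fractions by the ratio rule", {
  # printed-fraction arithmetic of the benchmark analysis
  expect_equal(round(ratio_separability(0.7373, 0.4201), 4), 0.6370)
  expect_equal(ratio_separability(0.3, 0.3), 0.5)
  expect_equal(ratio_separability(0.2, 0), 1.0)
  expect_error(ratio_separability(0, 0), "undefined")

  # end-to-end on the toy: positive (da,dc) at distance 2, (db,dd) unreachable
  d <- all_pairs_shortest_paths(toy_network())
  res <- ddi_separability(d, toy_labels())
  expect_equal(res$pos_frac, 0.5)            # 1 of 2 positives at distance 2
  expect_equal(res$neg_frac, 0)              # no negative at distance 2
  expect_equal(res$separability, 1)
  # at_most mode counts distances <= step
  res2 <- ddi_separability(d, toy_labels(), at_most = TRUE)
  expect_equal(res2$neg_frac, 0.5)           # adjacent pairs now count
})

test_that("swapping the class statistics complements the ratio separability", {
  set.seed(6)
  for (i in 1:10) {
    p <- runif(1, 0.01, 1)
    q <- runif(1, 0.01, 1)
    expect_equal(ratio_separability(p, q), 1 - ratio_separability(q, p))
  }
})

test_that("ATC sharing separability averages the two printed benchmark ratios", {
  expect_equal(round(mean_separability(120 / 132, 947 / 1772), 4), 0.7218)
  expect_equal(mean_separability(1, 1), 1)
  expect_equal(mean_separability(0.5, 0.5), 0.5)

  # toy: positive (da,dc) disjoint codes, (db,dd) empty set -> no share;
  # negatives sharing only (da,db)
  res <- atc_separability(toy_universe(), toy_labels())
  expect_equal(res$pos_share_frac, 0)
  expect_equal(res$neg_noshare_frac, 3 / 4)
  expect_equal(res$separability, 3 / 8)
})

test_that("frequency separability classifies features by relative class frequency", {
  # printed-count arithmetic: SE 5602/(5602+1344), DTI 177/(177+127)
  expect_equal(round(ratio_separability(5602, 1344), 4), 0.8065)
  expect_equal(round(ratio_separability(177, 127), 4), 0.5822)

  # constructed toy with known enrichment classes
  ids <- c("w", "x", "y", "z")
  prof <- matrix(c(1, 1, 0, 0,
                   1, 0, 0, 0,
                   0, 1, 0, 0,
                   0, 0, 0, 0), 4, 4, byrow = TRUE,
                 dimnames = list(ids, c("f1", "f2", "f3", "f4")))
  u <- drug_universe(ids, stats::setNames(rep(list("A"), 4), ids),
                     prof, prof)
  lab <- pair_labels(rbind(c("w", "x")), ids)   # 1 positive, 5 negatives
  res <- frequency_separability(binary_profiles(u, "DTI"), lab)
  # f1 and f2 occur in the positive pair (freq 1) but only in 4/5 of the
  # negatives -> both pos-enriched; f3, f4 occur nowhere -> neither
  expect_equal(res$n_pos_enriched, 2)
  expect_equal(res$n_neg_enriched, 0)
  expect_equal(res$n_neither, 2)
  expect_equal(res$separability, 0)

  # all features equally frequent in both classes -> undefined
  flat <- matrix(1, 4, 2, dimnames = list(ids, c("f1", "f2")))
  uf <- drug_universe(ids, stats::setNames(rep(list("A"), 4), ids), flat, flat)
  expect_error(frequency_separability(binary_profiles(uf, "SE"), lab),
               "no feature is enriched")
})

test_that("shared-target counts split by label and are conserved", {
  u <- toy_universe()
  res <- shared_target_counts(u, toy_labels())
  # positive (da,dc) shares t1; (db,dd) shares nothing (dd empty)
  expect_equal(res$n_pos_sharing, 1)
  # negatives: (da,db) none, (da,dd) none, (db,dc) t2, (dc,dd) none
  expect_equal(res$n_neg_sharing, 1)
  expect_equal(res$n_total_sharing, res$n_pos_sharing + res$n_neg_sharing)

  # all-disjoint profiles count nothing
  ids <- c("m", "n")
  up <- drug_universe(ids, stats::setNames(rep(list("A"), 2), ids),
                      matrix(c(1, 0, 0, 1), 2, 2, dimnames = list(ids, c("t1", "t2"))),
                      matrix(0, 2, 1, dimnames = list(ids, "s1")))
  res0 <- shared_target_counts(up, pair_labels(rbind(c("m", "n")), ids))
  expect_equal(res0$n_total_sharing, 0)
})

test_that("planted synthetic signals push every separability above chance", {
  seps <- sapply(101:105, function(seed) {
    ds <- generate_synthetic(synthetic_config(seed = seed))
    r <- separability_report(ds$universe, ds$network, ds$labels)
    c(ddi = r$ddi$separability, atc = r$atc$separability,
      se = r$se$separability, dti = r$dti$separability)
  })
  expect_true(all(rowMeans(seps) > 0.5))
  expect_true(all(rowMeans(seps)[c("ddi", "atc")] > 0.55))

  # label permutation collapses the diagnostics toward 0.5
  ds <- generate_synthetic(synthetic_config(seed = 31L))
  set.seed(31)
  fake <- ds$labels$scope[sample(nrow(ds$labels$scope), 100), ]
  rp <- separability_report(ds$universe, ds$network,
                            pair_labels(fake, ds$universe$drug_ids))
  expect_lt(abs(rp$se$separability - 0.5), 0.12)
  expect_lt(abs(rp$dti$separability - 0.5), 0.12)
})
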