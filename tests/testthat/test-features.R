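test_that("DDI embedding matches closed-form SVD on the 2-drug exchange graph", {
  ids <- c("p", "q")
  adj <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(ids, ids))
  net <- ddi_network(adj, ids)
  f <- ddi_embedding(net)
  # both singular values of the exchange matrix are 1
  expect_equal(ncol(f), 2)
  expect_equal(unname(rowSums(unclass(f)^2)), c(1, 1))
  expect_equal(sum(f^2), 2)  # sum of retained singular values
})

test_that("DDI embedding conserves the nuclear norm and reconstructs PSD adjacency", {
  # 4-node path graph: total squared embedding mass = sum of singular values
  ids <- letters[1:4]
  adj <- matrix(0, 4, 4, dimnames = list(ids, ids))
  adj[cbind(1:3, 2:4)] <- 1
  adj <- adj + t(adj)
  net <- ddi_network(adj, ids)
  f <- ddi_embedding(net, n_keep = 4L)
  expect_equal(sum(f^2), sum(svd(adj)$d), tolerance = 1e-10)

  # a symmetric adjacency is generally indefinite, so the Gram matrix of the
  # untruncated embedding reconstructs the adjacency up to eigenvalue sign:
  # the two spectra agree in absolute value (exact equality holds for PSD T)
  recon <- unclass(f) %*% t(unclass(f))
  expect_equal(sort(abs(eigen(recon, symmetric = TRUE)$values)),
               sort(abs(eigen(adj, symmetric = TRUE)$values)),
               tolerance = 1e-8)
})

test_that("degenerate and truncated embeddings behave as documented", {
  ids <- c("p", "q", "r")
  zero <- ddi_network(matrix(0, 3, 3, dimnames = list(ids, ids)), ids)
  expect_warning(f0 <- ddi_embedding(zero), "degenerate")
  expect_equal(ncol(f0), 0)

  ds <- generate_synthetic(synthetic_config(m = 30L, n_targets = 40L, n_se = 50L,
                                            n_pos = 10L, seed = 2L))
  f5 <- ddi_embedding(ds$network, n_keep = 5L)
  expect_equal(ncol(f5), 5)
  fall <- ddi_embedding(ds$network, n_keep = 1000L)
  # isolated drugs get all-zero rows
  iso <- rowSums(ds$network$adjacency) == 0
  if (any(iso)) {
    expect_true(all(abs(unclass(fall)[iso, ]) < 1e-8))
  }
  # columns ordered by descending singular value => descending column norms
  norms <- colSums(unclass(fall)^2)
  expect_true(all(diff(norms) < 1e-10))
})

test_that("ATC Tanimoto similarity reproduces the worked one-vs-six-letter example", {
  ids <- c("ondansetron", "dexamethasone")
  u <- drug_universe(ids,
                     list(ondansetron = "A",
                          dexamethasone = c("A", "C", "D", "H", "R", "S")),
                     matrix(0, 2, 0, dimnames = list(ids, NULL)),
                     matrix(0, 2, 0, dimnames = list(ids, NULL)))
  s <- atc_similarity(u)
  expect_equal(s["ondansetron", "dexamethasone"], 1 / 6)
  expect_equal(diag(s), c(ondansetron = 1, dexamethasone = 1))
})

test_that("ATC similarity is a symmetric [0,1] Tanimoto with documented edge cases", {
  u <- toy_universe()
  expect_message(atc_similarity(u), "empty ATC set")
  s <- suppressMessages(atc_similarity(u))
  expect_true(all(s >= 0 & s <= 1))
  expect_equal(s, t(s))
  expect_equal(s["da", "db"], 1 / 2)   # {A} vs {A,C}
  expect_equal(s["da", "dc"], 0)       # disjoint
  expect_equal(s["dd", "dd"], 0)       # empty set: similarity defaults to 0
  # identical non-empty sets give exactly 1
  ids <- c("x", "y")
  u2 <- drug_universe(ids, list(x = c("A", "N"), y = c("A", "N")),
                      matrix(0, 2, 0, dimnames = list(ids, NULL)),
                      matrix(0, 2, 0, dimnames = list(ids, NULL)))
  expect_equal(suppressMessages(atc_similarity(u2))["x", "y"], 1)
})

test_that("binary profiles surface the stored matrices with channel tags", {
  u <- toy_universe()
  dti <- binary_profiles(u, "DTI")
  se <- binary_profiles(u, "SE")
  expect_identical(attr(dti, "channel"), "DTI")
  expect_equal(unname(unclass(dti)["da", ]), c(1, 0, 1))
  expect_equal(sum(unclass(se)["dc", c("s1", "s2", "s4")]), 0)
})

test_that("reduce_pca matches a covariance eigendecomposition oracle up to sign", {
  set.seed(31)
  x <- matrix(rnorm(20), 5, 4)
  fm <- combifuse:::new_feature_matrix(x, "SE", sprintf("d%d", 1:5))
  scores <- reduce_pca(fm, n_components = 4L)

  # oracle: eigendecomposition of the sample covariance of centered data
  xc <- scale(x, center = TRUE, scale = FALSE)
  eig <- eigen(cov(xc), symmetric = TRUE)
  oracle <- xc %*% eig$vectors
  for (j in 1:4) {
    expect_true(
      isTRUE(all.equal(unname(unclass(scores)[, j]), unname(oracle[, j]),
                       tolerance = 1e-8)) ||
      isTRUE(all.equal(unname(unclass(scores)[, j]), -unname(oracle[, j]),
                       tolerance = 1e-8)),
      label = sprintf("component %d equals the oracle up to sign", j)
    )
  }
})

test_that("PCA scores are uncorrelated, rank-limited, and variance-complete for rank-1 data", {
  # rank-1 data: one component explains everything
  v <- c(1, 2, 3)
  x <- outer(c(1, 2, 4, 8), v) + 5
  fm <- combifuse:::new_feature_matrix(x, "DTI", sprintf("d%d", 1:4))
  expect_warning(s1 <- reduce_pca(fm, n_components = 3L), "rank")
  expect_equal(ncol(s1), 1)
  total_var <- sum(apply(scale(x, scale = FALSE), 2, var))
  expect_equal(var(as.numeric(unclass(s1))), total_var, tolerance = 1e-10)

  # wide binary matrix: at most m-1 informative components, off-diagonal
  # covariance of the scores vanishes
  ds <- generate_synthetic(synthetic_config(m = 12L, n_targets = 40L, n_se = 200L,
                                            n_pos = 6L, seed = 3L))
  se <- binary_profiles(ds$universe, "SE")
  red <- suppressWarnings(reduce_pca(se, n_components = 25L))
  expect_lte(ncol(red), 11)
  cv <- cov(unclass(red))
  expect_true(all(abs(cv[upper.tri(cv)]) < 1e-8))
})
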