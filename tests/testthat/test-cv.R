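test_that("S1 folds partition the scope into near-equal disjoint test sets", {
  ids <- sprintf("d%02d", 1:5)
  lab <- pair_labels(rbind(ids[1:2], ids[2:3]), ids)   # 10 scope pairs
  sp <- suppressWarnings(split_s1(lab, k = 5, seed = 3))
  test_sets <- lapply(sp, `[[`, "test_idx")
  expect_true(all(lengths(test_sets) == 2))
  expect_equal(sort(unlist(test_sets)), 1:10)
  for (s in sp) expect_length(intersect(s$train_idx, s$test_idx), 0)
  # determinism under the seed
  sp2 <- suppressWarnings(split_s1(lab, k = 5, seed = 3))
  expect_identical(lapply(sp2, `[[`, "test_idx"), test_sets)

  # fold-size arithmetic at benchmark scale: 1904 pairs, k = 10
  ids64 <- sprintf("d%03d", 1:64)          # C(64,2) = 2016 pairs available
  scope <- all_pairs(ids64)[1:1904, ]
  lab_big <- pair_labels(scope[1:50, , drop = FALSE], ids64, scope = scope)
  spb <- split_s1(lab_big, k = 10, seed = 1)
  sizes <- sort(lengths(lapply(spb, `[[`, "test_idx")))
  expect_true(all(sizes %in% c(190, 191)))
  expect_equal(sum(sizes), 1904)
})

test_that("S2 folds test exactly-one-new-drug pairs and keep test drugs out of training", {
  ids <- c("a", "b", "c", "d")
  lab <- pair_labels(rbind(c("a", "b")), ids)
  sp <- split_s2(lab, toy_universe4(ids), k = 4, seed = 2)
  for (s in sp) {
    expect_length(s$test_drugs, 1)
    tr <- lab$scope[s$train_idx, , drop = FALSE]
    te <- lab$scope[s$test_idx, , drop = FALSE]
    expect_false(any(s$test_drugs %in% tr))
    expect_true(all(rowSums(matrix(te %in% s$test_drugs, ncol = 2)) == 1))
  }
  # enumeration: test drugs {d} leave train = pairs among {a,b,c}
  f_d <- Filter(function(s) identical(s$test_drugs, "d"), sp)[[1]]
  expect_setequal(apply(lab$scope[f_d$test_idx, , drop = FALSE], 1, paste, collapse = "-"),
                  c("a-d", "b-d", "c-d"))
  expect_setequal(apply(lab$scope[f_d$train_idx, , drop = FALSE], 1, paste, collapse = "-"),
                  c("a-b", "a-c", "b-c"))
})

test_that("S2 test sets cover every cross-fold pair exactly once on a 12-drug toy", {
  ids <- sprintf("d%02d", 1:12)
  lab <- pair_labels(rbind(ids[1:2]), ids)
  u <- toy_universe4(ids)
  sp <- split_s2(lab, u, k = 4, seed = 5)
  folds <- lapply(sp, `[[`, "test_drugs")
  fold_of <- function(d) which(vapply(folds, function(f) d %in% f, logical(1)))
  covered <- unlist(lapply(sp, `[[`, "test_idx"))
  cross <- which(apply(lab$scope, 1, function(p) fold_of(p[1]) != fold_of(p[2])))
  # every cross-fold pair is tested exactly twice: once from each side
  expect_equal(sort(unique(covered)), sort(cross))
  expect_true(all(table(covered) == 2))
})

test_that("S3 folds test pairs among test drugs only, disjoint from S2's", {
  ids <- c("a", "b", "c", "d")
  lab <- pair_labels(rbind(c("a", "b")), ids)
  u <- toy_universe4(ids)
  sp3 <- suppressWarnings(split_s3(lab, u, k = 2, seed = 7))
  sp2 <- suppressWarnings(split_s2(lab, u, k = 2, seed = 7))
  for (i in seq_along(sp3)) {
    expect_identical(sp3[[i]]$test_drugs, sp2[[i]]$test_drugs)
    expect_length(intersect(sp3[[i]]$test_idx, sp2[[i]]$test_idx), 0)
    te <- lab$scope[sp3[[i]]$test_idx, , drop = FALSE]
    expect_true(all(te %in% sp3[[i]]$test_drugs))
  }
  # enumeration for test drugs {c,d}
  f_cd <- Filter(function(s) setequal(s$test_drugs, c("c", "d")), sp3)
  if (length(f_cd) > 0) {
    s <- f_cd[[1]]
    expect_setequal(apply(lab$scope[s$test_idx, , drop = FALSE], 1, paste, collapse = "-"),
                    "c-d")
    expect_setequal(apply(lab$scope[s$train_idx, , drop = FALSE], 1, paste, collapse = "-"),
                    "a-b")
  }
  # singleton drug folds yield no new-new pairs and warn
  ids6 <- sprintf("d%d", 1:6)
  lab6 <- pair_labels(rbind(ids6[1:2]), ids6)
  w <- capture_warnings(split_s3(lab6, toy_universe4(ids6), k = 6, seed = 1))
  expect_gt(length(w), 0)
  expect_true(all(grepl("no test instances", w)))
})

test_that("AUC equals the brute-force pairwise estimator", {
  expect_equal(auc_score(c(0.9, 0.8, 0.4, 0.2), c(1, 0, 1, 0)), 0.75)
  expect_equal(auc_score(c(5, 4, 3), c(1, 1, 0)), 1)
  expect_equal(auc_score(rep(0.3, 6), c(1, 0, 1, 0, 0, 1)), 0.5)
  expect_error(auc_score(1:3, c(1, 1, 1)), "both classes")
  set.seed(77)
  for (i in 1:25) {
    n <- sample(5:30, 1)
    s <- sample(round(runif(n), 2))  # rounded => frequent ties
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    expect_equal(auc_score(s, y), brute_auc(s, y), tolerance = 1e-12)
  }
})

test_that("AUPR equals the brute-force threshold-enumeration oracle", {
  expect_equal(aupr_score(c(5, 4, 3, 2), c(1, 1, 0, 0)), 1)
  expect_equal(aupr_score(c(9, 1, 2, 3), c(1, 0, 0, 0)), 1)
  expect_equal(aupr_score(c(0.9, 0.8, 0.4, 0.2), c(1, 0, 1, 0)),
               brute_aupr(c(0.9, 0.8, 0.4, 0.2), c(1, 0, 1, 0)))
  expect_error(aupr_score(1:3, c(0, 0, 0)), "no positive")
  set.seed(78)
  for (i in 1:25) {
    n <- sample(5:30, 1)
    s <- sample(round(runif(n), 1))
    y <- rbinom(n, 1, 0.4)
    if (sum(y) == 0) next
    expect_equal(aupr_score(s, y), brute_aupr(s, y), tolerance = 1e-12)
  }
})

test_that("run_cv detects planted signal in S1 and is seed-reproducible", {
  ds <- generate_synthetic(synthetic_config(m = 60L, n_targets = 80L, n_se = 160L,
                                            n_pos = 50L, seed = 17L))
  res <- run_cv(ds$universe, ds$network, ds$labels, scenario = "s1", k = 5, seed = 17)
  se_fold <- sd(res$folds$auc_fused) / sqrt(nrow(res$folds))
  expect_gt(res$means[["auc_fused"]], 0.5 + 3 * se_fold)
  res2 <- run_cv(ds$universe, ds$network, ds$labels, scenario = "s1", k = 5, seed = 17)
  expect_identical(res$folds, res2$folds)
  expect_equal(nrow(res$folds), 5)
  # pooled metrics are available on request
  resp <- run_cv(ds$universe, ds$network, ds$labels, scenario = "s1", k = 5,
                 seed = 17, pooled = TRUE)
  expect_true(all(c("auc", "aupr") %in% names(resp$pooled)))
})
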