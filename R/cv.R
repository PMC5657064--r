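# Scenario-aware cross-validation.
#
# S1 (known-known): candidate pairs are partitioned into k folds; every
#     drug can appear on both sides, so this measures in-fill among drugs
#     that already have combination evidence.
# S2 (known-new): DRUGS are partitioned into k folds; a fold's drugs are
#     treated as new, test instances are pairs with exactly one new member,
#     and no training pair may touch a new drug.
# S3 (new-new): as S2 but test instances are pairs with both members new.
#
# Pair-level splitting (S1) is optimistic for cold-start screening; S2/S3
# quantify the harder realistic scenarios.

new_cv_split <- function(scenario, fold, train_idx, test_idx, test_drugs) {
  structure(
    list(scenario = scenario, fold = fold, train_idx = train_idx,
         test_idx = test_idx, test_drugs = test_drugs),
    class = "cv_split"
  )
}

#' S1 pair-level k-fold splits
#'
#' Randomly partitions the scope pairs into k near-equal folds; each fold
#' serves once as the test set, the rest train.
#'
#' @param labels a [pair_labels()].
#' @param k number of folds (default 10).
#' @param seed integer seed; identical seeds give identical folds.
#' @return List of \code{cv_split} objects (test_drugs empty for S1).
#' @export
split_s1 <- function(labels, k = 10L, seed = 1L) {
  n <- nrow(labels$scope)
  stopifnot(k >= 2L, n >= k)
  if (nrow(labels$positives) < k) {
    warning("fewer positives than folds: some S1 folds may lack positives")
  }
  assign_fold <- with_seed(seed, sample(rep(seq_len(k), length.out = n)))
  lapply(seq_len(k), function(f) {
    new_cv_split("s1", f, which(assign_fold != f), which(assign_fold == f),
                 character(0))
  })
}

drug_folds <- function(drug_ids, k, seed) {
  m <- length(drug_ids)
  stopifnot(k >= 2L, m >= k)
  with_seed(seed, {
    fold <- sample(rep(seq_len(k), length.out = m))
  })
  split(drug_ids, fold)
}

split_drugwise <- function(labels, universe, k, seed, scenario) {
  folds <- drug_folds(universe$drug_ids, k, seed)
  scope <- labels$scope
  out <- lapply(seq_len(k), function(f) {
    test_drugs <- folds[[f]]
    in_test_a <- scope[, 1L] %in% test_drugs
    in_test_b <- scope[, 2L] %in% test_drugs
    n_test_members <- in_test_a + in_test_b
    train_idx <- which(n_test_members == 0L)
    test_idx <- if (scenario == "s2") which(n_test_members == 1L) else which(n_test_members == 2L)
    if (length(test_idx) == 0L) {
      warning(sprintf("%s fold %d has no test instances and will be skipped",
                      toupper(scenario), f))
    }
    new_cv_split(scenario, f, train_idx, test_idx, test_drugs)
  })
  out
}

#' S2 drug-level splits (known-new pairs)
#'
#' Drugs are partitioned into k folds; per fold, training instances are
#' scope pairs among training drugs only, test instances are scope pairs
#' with exactly one member among the fold's (new) test drugs.
#'
#' @inheritParams split_s1
#' @param universe a [drug_universe()].
#' @export
split_s2 <- function(labels, universe, k = 10L, seed = 1L) {
  split_drugwise(labels, universe, k, seed, "s2")
}

#' S3 drug-level splits (new-new pairs)
#'
#' As [split_s2()] but test instances have both members among the test
#' drugs.
#'
#' @inheritParams split_s2
#' @export
split_s3 <- function(labels, universe, k = 10L, seed = 1L) {
  split_drugwise(labels, universe, k, seed, "s3")
}

#' Scenario-aware cross-validated evaluation of the full pipeline
#'
#' Per fold: the DTI/SE PCA reducers and the three per-channel logistic
#' scorers are fitted on training data only (for S2/S3, on training drugs
#' only); test pairs are scored per channel, the ATC similarity entry is
#' used directly as the fourth channel, the channels are fused by the
#' chosen rule, and AUC/AUPR are computed on the fold's test instances.
#' The DDI spectral embedding and the ATC similarity are computed once on
#' the full pharmaceutical network / code sets: both derive from
#' combination-label-free drug attributes that new drugs also possess, so
#' no label leaks into them.
#'
#' @param universe a [drug_universe()].
#' @param network a [ddi_network()].
#' @param labels a [pair_labels()].
#' @param scenario \code{"s1"}, \code{"s2"} or \code{"s3"}.
#' @param k folds (default 10).
#' @param seed integer seed driving fold assignment (and the internal
#'   weight-selection split under \code{rule = "greedy"}).
#' @param rule fusion rule: \code{"mean"}, \code{"direct"} (training-AUC
#'   weights) or \code{"greedy"} (grid-searched weights on an internal
#'   training split).
#' @param lambda L2 strength for the logistic scorers.
#' @param n_keep,sv_threshold DDI embedding controls.
#' @param pca_components PCA dimensions for the DTI/SE channels.
#' @param pooled also compute metrics on all folds' test scores pooled
#'   together (default FALSE; per-fold averaging is the primary report).
#' @return An object of class \code{combo_cv}: per-fold metric table,
#'   fold means, and the fusion weights used per fold.
#' @export
run_cv <- function(universe, network, labels,
                   scenario = c("s1", "s2", "s3"), k = 10L, seed = 1L,
                   rule = c("mean", "direct", "greedy"), lambda = 1e-4,
                   n_keep = 25L, sv_threshold = 1e-6, pca_components = 25L,
                   pooled = FALSE) {
  scenario <- match.arg(scenario)
  rule <- match.arg(rule)
  ids <- universe$drug_ids
  scope <- labels$scope
  ia <- match(scope[, 1L], ids)
  ib <- match(scope[, 2L], ids)
  if (anyNA(ia) || anyNA(ib)) stop("label scope references drugs outside the universe")
  y <- scope_labels(labels)

  embed <- ddi_embedding(network, n_keep = n_keep, sv_threshold = sv_threshold)
  sim <- suppressMessages(atc_similarity(universe))
  atc_all <- similarity_as_score(sim, scope)

  splits <- switch(scenario,
    s1 = split_s1(labels, k, seed),
    s2 = split_s2(labels, universe, k, seed),
    s3 = split_s3(labels, universe, k, seed)
  )

  fold_rows <- list()
  fold_weights <- list()
  pooled_scores <- numeric(0)
  pooled_labels <- integer(0)

  for (sp in splits) {
    if (length(sp$test_idx) == 0L) next
    train_drugs <- setdiff(ids, sp$test_drugs)
    feats <- fold_features(universe, embed, train_drugs, pca_components)
    ch <- score_fold(feats, atc_all, ia, ib, y, sp, lambda)
    if (is.null(ch)) {
      warning(sprintf("%s fold %d skipped: single-class training set",
                      toupper(scenario), sp$fold))
      next
    }
    w <- fold_weights_for_rule(rule, ch, y, sp, seed, lambda, feats, atc_all,
                               ia, ib)
    tab <- score_table(scope[sp$test_idx, , drop = FALSE],
                       ch$test[, "ddi"], ch$test[, "dti"], ch$test[, "se"],
                       ch$test[, "atc"], label = y[sp$test_idx])
    tab <- fuse_weighted(tab, w)
    y_test <- y[sp$test_idx]
    if (length(unique(y_test)) < 2L) {
      warning(sprintf("%s fold %d skipped in averaging: test set has a single class",
                      toupper(scenario), sp$fold))
      pooled_scores <- c(pooled_scores, tab$fused)
      pooled_labels <- c(pooled_labels, y_test)
      next
    }
    row <- data.frame(fold = sp$fold, n_test = length(y_test),
                      n_test_pos = sum(y_test))
    for (cn in SCORE_CHANNELS) {
      row[[paste0("auc_", cn)]] <- auc_score(tab[[cn]], y_test)
      row[[paste0("aupr_", cn)]] <- aupr_score(tab[[cn]], y_test)
    }
    row$auc_fused <- auc_score(tab$fused, y_test)
    row$aupr_fused <- aupr_score(tab$fused, y_test)
    fold_rows[[length(fold_rows) + 1L]] <- row
    fold_weights[[length(fold_weights) + 1L]] <- w
    pooled_scores <- c(pooled_scores, tab$fused)
    pooled_labels <- c(pooled_labels, y_test)
  }

  if (length(fold_rows) == 0L) {
    stop("no fold produced a two-class test set; cannot evaluate")
  }
  folds <- do.call(rbind, fold_rows)
  metric_cols <- setdiff(names(folds), c("fold", "n_test", "n_test_pos"))
  means <- colMeans(folds[, metric_cols, drop = FALSE])
  out <- list(scenario = scenario, k = k, seed = seed, rule = rule,
              folds = folds, means = means, weights = fold_weights)
  if (pooled) {
    out$pooled <- c(auc = auc_score(pooled_scores, pooled_labels),
                    aupr = aupr_score(pooled_scores, pooled_labels))
  }
  class(out) <- "combo_cv"
  out
}

# Per-fold drug-level feature matrices; PCA reducers are fitted on the
# training drugs only and used to project every drug.
fold_features <- function(universe, embed, train_drugs, pca_components) {
  proj <- function(raw) {
    kc <- min(pca_components, nrow(raw) - 1L, ncol(raw))
    fit <- suppressWarnings(pca_fit(raw[train_drugs, , drop = FALSE], kc))
    out <- pca_project(fit, raw)
    rownames(out) <- rownames(raw)
    out
  }
  list(ddi = unclass(embed),
       dti = proj(universe$dti),
       se = proj(universe$se))
}

# Train the three logistic channels on the fold's training pairs and score
# both train and test instances. Returns NULL when training labels are
# degenerate.
score_fold <- function(feats, atc_all, ia, ib, y, sp, lambda) {
  y_train <- y[sp$train_idx]
  if (length(unique(y_train)) < 2L) return(NULL)
  train_scores <- matrix(NA_real_, length(sp$train_idx), 4L,
                         dimnames = list(NULL, SCORE_CHANNELS))
  test_scores <- matrix(NA_real_, length(sp$test_idx), 4L,
                        dimnames = list(NULL, SCORE_CHANNELS))
  models <- list()
  for (cn in c("ddi", "dti", "se")) {
    f <- feats[[cn]]
    x_train <- pair_feature_rows(f, ia[sp$train_idx], ib[sp$train_idx])
    x_test <- pair_feature_rows(f, ia[sp$test_idx], ib[sp$test_idx])
    mod <- train_logistic(x_train, y_train, lambda = lambda, channel = toupper(cn))
    models[[cn]] <- mod
    train_scores[, cn] <- score_pairs(mod, x_train)
    test_scores[, cn] <- score_pairs(mod, x_test)
  }
  train_scores[, "atc"] <- atc_all[sp$train_idx]
  test_scores[, "atc"] <- atc_all[sp$test_idx]
  list(models = models, train = train_scores, test = test_scores)
}

fold_weights_for_rule <- function(rule, ch, y, sp, seed, lambda, feats,
                                  atc_all, ia, ib) {
  if (rule == "mean") {
    return(as_weight_vector(rep(1, 4L)))
  }
  y_train <- y[sp$train_idx]
  if (rule == "direct") {
    aucs <- vapply(SCORE_CHANNELS, function(cn) {
      auc_score(ch$train[, cn], y_train)
    }, numeric(1))
    return(direct_weights(aucs))
  }
  # greedy: choose weights on an internal selection split of the training
  # fold so that no test instance influences the weights
  n_tr <- length(sp$train_idx)
  sel <- with_seed(seed * 1000L + sp$fold,
                   sample(n_tr, size = max(1L, floor(n_tr / 2))))
  sub_idx <- sp$train_idx[-sel]
  sel_idx <- sp$train_idx[sel]
  if (length(unique(y[sub_idx])) < 2L || length(unique(y[sel_idx])) < 2L) {
    return(as_weight_vector(rep(1, 4L)))
  }
  sel_scores <- matrix(NA_real_, length(sel_idx), 4L,
                       dimnames = list(NULL, SCORE_CHANNELS))
  for (cn in c("ddi", "dti", "se")) {
    f <- feats[[cn]]
    mod <- train_logistic(pair_feature_rows(f, ia[sub_idx], ib[sub_idx]),
                          y[sub_idx], lambda = lambda, channel = toupper(cn))
    sel_scores[, cn] <- score_pairs(mod, pair_feature_rows(f, ia[sel_idx], ib[sel_idx]))
  }
  sel_scores[, "atc"] <- atc_all[sel_idx]
  tab <- data.frame(sel_scores)
  tab$label <- y[sel_idx]
  greedy_weight_search(tab)
}

#' @export
print.combo_cv <- function(x, ...) {
  cat(sprintf("Cross-validated evaluation [%s, k = %d, rule = %s, seed = %d]\n",
              toupper(x$scenario), x$k, x$rule, x$seed))
  cat(sprintf("  folds evaluated: %d\n", nrow(x$folds)))
  m <- x$means
  cat(sprintf("  mean AUC : ddi %.3f  dti %.3f  se %.3f  atc %.3f  fused %.3f\n",
              m[["auc_ddi"]], m[["auc_dti"]], m[["auc_se"]], m[["auc_atc"]],
              m[["auc_fused"]]))
  cat(sprintf("  mean AUPR: ddi %.3f  dti %.3f  se %.3f  atc %.3f  fused %.3f\n",
              m[["aupr_ddi"]], m[["aupr_dti"]], m[["aupr_se"]], m[["aupr_atc"]],
              m[["aupr_fused"]]))
  if (!is.null(x$pooled)) {
    cat(sprintf("  pooled   : AUC %.3f  AUPR %.3f\n", x$pooled[["auc"]],
                x$pooled[["aupr"]]))
  }
  invisible(x)
}

#' @export
as.data.frame.combo_cv <- function(x, ...) x$folds
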