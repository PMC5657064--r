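#' Fit the combinative-pair prediction model
#'
#' The full drug-driven predictor: builds the four heterogeneous drug
#' feature channels (DDI spectral embedding, PCA-reduced DTI and SE
#' profiles, first-level ATC similarity), featurizes the labelled pairs
#' symmetrically (elementwise sum of the member vectors), trains one
#' logistic scorer per real-valued channel, and fixes the fusion weights
#' by the chosen rule. The returned object scores arbitrary drug pairs of
#' the universe via [predict.combifuse()].
#'
#' @param universe a [drug_universe()].
#' @param network a [ddi_network()] over the same drugs.
#' @param labels a [pair_labels()]; scope pairs outside the positives are
#'   the negative training instances.
#' @param rule fusion rule: \code{"mean"} (default), \code{"direct"}
#'   (training-AUC-proportional weights) or \code{"greedy"} (exhaustive
#'   0.1-step grid search on an internal held-out split of the training
#'   pairs).
#' @param n_keep,sv_threshold DDI embedding controls (leading components,
#'   singular-value cutoff).
#' @param pca_components PCA dimensions for the DTI/SE channels.
#' @param lambda L2 strength of the logistic scorers (0 = plain MLE).
#' @param fit_drugs drugs whose profiles fit the PCA reducers and whose
#'   pairs may train the scorers; defaults to every drug. Restrict this to
#'   the training drugs when held-out drugs must not influence the
#'   reducers (cold-start evaluation).
#' @param seed seed for the internal weight-selection split under
#'   \code{rule = "greedy"}.
#' @return An object of class \code{combifuse}.
#' @seealso [run_cv()] for scenario-aware cross-validated evaluation.
#' @export
combifuse <- function(universe, network, labels, rule = c("mean", "direct", "greedy"),
                      n_keep = 25L, sv_threshold = 1e-6, pca_components = 25L,
                      lambda = 1e-4, fit_drugs = universe$drug_ids, seed = 1L) {
  rule <- match.arg(rule)
  ids <- universe$drug_ids
  stopifnot(identical(network$drug_ids, ids))
  fit_drugs <- intersect(ids, fit_drugs)

  embed <- ddi_embedding(network, n_keep = n_keep, sv_threshold = sv_threshold)
  sim <- suppressMessages(atc_similarity(universe))
  feats <- fold_features(universe, embed, fit_drugs, pca_components)

  scope <- labels$scope
  train_ok <- scope[, 1L] %in% fit_drugs & scope[, 2L] %in% fit_drugs
  train_pairs <- scope[train_ok, , drop = FALSE]
  y <- scope_labels(labels)[train_ok]
  ia <- match(train_pairs[, 1L], ids)
  ib <- match(train_pairs[, 2L], ids)

  models <- list()
  train_scores <- matrix(NA_real_, nrow(train_pairs), 4L,
                         dimnames = list(NULL, SCORE_CHANNELS))
  for (cn in c("ddi", "dti", "se")) {
    x <- pair_feature_rows(feats[[cn]], ia, ib)
    models[[cn]] <- train_logistic(x, y, lambda = lambda, channel = toupper(cn))
    train_scores[, cn] <- score_pairs(models[[cn]], x)
  }
  train_scores[, "atc"] <- similarity_as_score(sim, train_pairs)

  weights <- switch(rule,
    mean = as_weight_vector(rep(1, 4L)),
    direct = direct_weights(vapply(SCORE_CHANNELS, function(cn) {
      auc_score(train_scores[, cn], y)
    }, numeric(1))),
    greedy = {
      sel <- with_seed(seed, sample(length(y), size = max(1L, floor(length(y) / 2))))
      tab <- data.frame(train_scores[sel, , drop = FALSE])
      tab$label <- y[sel]
      if (length(unique(tab$label)) < 2L) as_weight_vector(rep(1, 4L))
      else greedy_weight_search(tab)
    }
  )

  structure(
    list(universe = universe, features = feats, similarity = sim,
         models = models, weights = weights, rule = rule,
         train_pairs = train_pairs, train_labels = y,
         train_scores = train_scores, lambda = lambda,
         n_keep = n_keep, pca_components = pca_components),
    class = "combifuse"
  )
}

#' Score drug pairs with a fitted combination model
#'
#' @param object a fitted [combifuse()] model.
#' @param pairs two-column matrix/data.frame of drug-id pairs; defaults to
#'   the model's training scope.
#' @param ... unused.
#' @return A [score_table()] with the four channel scores and the fused
#'   confidence score per pair.
#' @export
predict.combifuse <- function(object, pairs = NULL, ...) {
  if (is.null(pairs)) {
    pairs <- object$train_pairs
  }
  pairs <- canonical_pairs(as.matrix(pairs)[, 1L], as.matrix(pairs)[, 2L])
  ids <- object$universe$drug_ids
  ia <- match(pairs[, 1L], ids)
  ib <- match(pairs[, 2L], ids)
  if (anyNA(ia) || anyNA(ib)) stop("pair references a drug outside the universe")
  ch <- vapply(c("ddi", "dti", "se"), function(cn) {
    score_pairs(object$models[[cn]],
                pair_feature_rows(object$features[[cn]], ia, ib))
  }, numeric(nrow(pairs)))
  if (nrow(pairs) == 1L) ch <- matrix(ch, 1L, dimnames = list(NULL, c("ddi", "dti", "se")))
  tab <- score_table(pairs, ch[, "ddi"], ch[, "dti"], ch[, "se"],
                     similarity_as_score(object$similarity, pairs))
  fuse_weighted(tab, object$weights)
}

#' @export
print.combifuse <- function(x, ...) {
  cat("Combinative-pair prediction model\n")
  cat(sprintf("  drugs: %d   training pairs: %d (%d positive)\n",
              length(x$universe$drug_ids), nrow(x$train_pairs),
              sum(x$train_labels)))
  cat(sprintf("  channels: DDI %dd, DTI %dd, SE %dd, ATC similarity\n",
              ncol(x$features$ddi), ncol(x$features$dti), ncol(x$features$se)))
  cat(sprintf("  fusion: %s rule, weights (ddi %.2g, dti %.2g, se %.2g, atc %.2g)\n",
              x$rule, x$weights[["ddi"]], x$weights[["dti"]],
              x$weights[["se"]], x$weights[["atc"]]))
  invisible(x)
}

#' @export
summary.combifuse <- function(object, ...) {
  y <- object$train_labels
  tr_auc <- vapply(SCORE_CHANNELS, function(cn) {
    auc_score(object$train_scores[, cn], y)
  }, numeric(1))
  fused <- drop(object$train_scores %*% object$weights) / sum(object$weights)
  out <- list(model = object, train_auc = c(tr_auc, fused = auc_score(fused, y)),
              n_pos = sum(y), n_neg = sum(y == 0))
  class(out) <- "summary.combifuse"
  out
}

#' @export
print.summary.combifuse <- function(x, ...) {
  print(x$model)
  cat(sprintf("  training AUC (in-sample): ddi %.3f  dti %.3f  se %.3f  atc %.3f  fused %.3f\n",
              x$train_auc[["ddi"]], x$train_auc[["dti"]], x$train_auc[["se"]],
              x$train_auc[["atc"]], x$train_auc[["fused"]]))
  invisible(x)
}

#' @export
coef.combifuse <- function(object, ...) {
  lapply(object$models, function(m) {
    c(intercept = m$intercept, stats::setNames(m$weights,
        paste0("w", seq_along(m$weights))))
  })
}

#' ROC curves of the fitted channels on the training pairs
#'
#' @param x a fitted [combifuse()] model.
#' @param ... passed to [graphics::plot()].
#' @export
plot.combifuse <- function(x, ...) {
  y <- x$train_labels
  fused <- drop(x$train_scores %*% x$weights) / sum(x$weights)
  cols <- c(ddi = "#1b9e77", dti = "#d95f02", se = "#7570b3", atc = "#e7298a",
            fused = "black")
  graphics::plot(c(0, 1), c(0, 1), type = "n", xlab = "False positive rate",
                 ylab = "True positive rate",
                 main = "Per-channel and fused ROC (training pairs)", ...)
  graphics::abline(0, 1, lty = 3, col = "grey60")
  curves <- c(as.list(data.frame(x$train_scores)), list(fused = fused))
  for (cn in names(curves)) {
    r <- roc_points(curves[[cn]], y)
    graphics::lines(r$fpr, r$tpr, col = cols[[cn]],
                    lwd = if (cn == "fused") 2.5 else 1.2)
  }
  graphics::legend("bottomright", legend = toupper(names(curves)),
                   col = cols[names(curves)], lwd = 2, bty = "n", cex = 0.8)
  invisible(x)
}

roc_points <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  s <- scores[ord]
  last <- c(s[-1L] != s[-length(s)], TRUE)
  tp <- cumsum(y)[last]
  fp <- cumsum(1L - y)[last]
  list(fpr = c(0, fp / max(fp[length(fp)], 1)),
       tpr = c(0, tp / max(tp[length(tp)], 1)))
}
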