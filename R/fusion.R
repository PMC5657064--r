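# Late fusion of per-channel confidence scores.
#
# A score table carries one row per candidate pair with the four channel
# scores (DDI, DTI, SE, ATC) and a fused column. Fusion is a (possibly
# weighted) mean; weights are normalized by their sum so fused scores stay
# in [0,1] and uniform weights recover the plain mean rule exactly.

SCORE_CHANNELS <- c("ddi", "dti", "se", "atc")

#' Assemble a score table
#'
#' @param pairs two-column matrix of drug-id pairs.
#' @param ddi,dti,se,atc per-channel scores in \eqn{[0,1]}, one per pair.
#' @param label optional 0/1 labels.
#' @return A data frame of class \code{score_table}.
#' @export
score_table <- function(pairs, ddi, dti, se, atc, label = NULL) {
  pairs <- as.matrix(pairs)
  df <- data.frame(drug_a = pairs[, 1L], drug_b = pairs[, 2L],
                   ddi = ddi, dti = dti, se = se, atc = atc,
                   fused = NA_real_, stringsAsFactors = FALSE)
  if (!is.null(label)) df$label <- as.integer(label)
  for (ch in SCORE_CHANNELS) {
    if (any(df[[ch]] < -1e-12 | df[[ch]] > 1 + 1e-12, na.rm = TRUE)) {
      stop("channel '", ch, "' scores outside [0,1]")
    }
  }
  class(df) <- c("score_table", "data.frame")
  df
}

check_channels <- function(table) {
  miss <- SCORE_CHANNELS[!SCORE_CHANNELS %in% names(table)]
  if (length(miss) > 0L) {
    stop("score table is missing channel column(s): ", paste(miss, collapse = ", "))
  }
  if (anyNA(table[, SCORE_CHANNELS])) {
    stop("score table has missing channel values")
  }
  invisible(table)
}

#' Mean-rule fusion
#'
#' Fused score = arithmetic mean of the four channel scores.
#'
#' @param table a [score_table()].
#' @return The table with its \code{fused} column filled.
#' @export
fuse_average <- function(table) {
  check_channels(table)
  table$fused <- rowMeans(as.matrix(table[, SCORE_CHANNELS]))
  table
}

#' Weighted-mean fusion
#'
#' Fused score = \eqn{\sum_c w_c s_c / \sum_c w_c}. Uniform weights
#' reproduce [fuse_average()] exactly.
#'
#' @param table a [score_table()].
#' @param weights nonnegative numeric weights for (ddi, dti, se, atc), not
#'   all zero; the normalization makes their scale irrelevant. A named
#'   vector is matched by name.
#' @return The table with its \code{fused} column filled.
#' @export
fuse_weighted <- function(table, weights) {
  check_channels(table)
  w <- as_weight_vector(weights)
  s <- as.matrix(table[, SCORE_CHANNELS])
  table$fused <- drop(s %*% w) / sum(w)
  table
}

as_weight_vector <- function(weights) {
  if (!is.null(names(weights))) {
    if (!all(SCORE_CHANNELS %in% names(weights))) {
      stop("named weights must cover ddi, dti, se, atc")
    }
    weights <- weights[SCORE_CHANNELS]
  }
  w <- as.numeric(weights)
  if (length(w) != 4L) stop("weights must have four entries (ddi, dti, se, atc)")
  if (any(!is.finite(w)) || any(w < 0)) stop("weights must be finite and nonnegative")
  if (sum(w) == 0) stop("weights must not all be zero")
  names(w) <- SCORE_CHANNELS
  w
}

#' Direct AUC-proportional fusion weights
#'
#' Each channel's weight is its own AUC measured on training data, used
#' as-is inside the normalized weighted mean.
#'
#' @param per_channel_auc numeric vector of four training AUCs
#'   (ddi, dti, se, atc).
#' @return Named weight vector.
#' @export
direct_weights <- function(per_channel_auc) {
  as_weight_vector(per_channel_auc)
}

# Candidate grid {0, 0.1, ..., 1}^4 minus the all-zero vector, ordered
# lexicographically by (ddi, dti, se, atc) so that which.max tie-breaks
# toward the smallest weights.
weight_grid <- function(step = 0.1) {
  vals <- seq(0, 1, by = step)
  g <- expand.grid(atc = vals, se = vals, dti = vals, ddi = vals,
                   KEEP.OUT.ATTRS = FALSE)
  g <- as.matrix(g[, c("ddi", "dti", "se", "atc")])
  g <- g[order(g[, 1L], g[, 2L], g[, 3L], g[, 4L]), , drop = FALSE]
  g[rowSums(g) > 0, , drop = FALSE]
}

#' Exhaustive grid search for fusion weights
#'
#' Evaluates every weight vector on the grid \eqn{\{0, 0.1, \dots, 1\}^4}
#' (all-zero excluded) by the AUC of the normalized weighted-mean fused
#' score on labelled selection data, and returns the best; ties break
#' toward the lexicographically smallest weights. The grid is a superset
#' of any greedy coordinate path over the same steps.
#'
#' @param train_scores a labelled [score_table()] (column \code{label}).
#' @param grid_step grid resolution (default 0.1).
#' @return Named weight vector (ddi, dti, se, atc).
#' @export
greedy_weight_search <- function(train_scores, grid_step = 0.1) {
  check_channels(train_scores)
  if (is.null(train_scores$label)) stop("greedy_weight_search needs a label column")
  y <- train_scores$label
  if (length(unique(y)) < 2L) {
    stop("degenerate labels: weight search needs both classes")
  }
  s <- as.matrix(train_scores[, SCORE_CHANNELS])
  grid <- weight_grid(grid_step)
  fused <- s %*% t(grid)                       # n x n_candidates
  pos <- y == 1
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  aucs <- apply(fused, 2L, function(col) {
    (sum(rank(col)[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  })
  best <- which.max(aucs)
  w <- grid[best, ]
  names(w) <- SCORE_CHANNELS
  w
}
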