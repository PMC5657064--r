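# Channel-wise separability diagnostics.
#
# Each channel gets a heuristic [0,1] statistic estimating how well it
# distinguishes approved combinative pairs (positives) from the remaining
# candidate pairs (negatives): graph distance on the DDI network, shared
# first-level ATC codes, and enrichment direction of individual binary
# DTI/SE features.

#' Ratio combination rule for separability
#'
#' \eqn{p / (p + q)}: the share of the "positive-direction" statistic in
#' the total. Used by the DDI-distance and feature-frequency diagnostics.
#'
#' @param pos positive-class statistic (fraction or count), nonnegative.
#' @param neg negative-class statistic, nonnegative.
#' @return Value in \eqn{[0,1]}.
#' @export
ratio_separability <- function(pos, neg) {
  if (pos < 0 || neg < 0) stop("separability inputs must be nonnegative")
  if (pos + neg == 0) stop("separability undefined: both statistics are zero")
  pos / (pos + neg)
}

#' Mean combination rule for separability
#'
#' Arithmetic mean of a positive-class fraction and a complementary
#' negative-class fraction. Used by the ATC-sharing diagnostic.
#'
#' @param pos_frac fraction of positives with the property.
#' @param neg_frac fraction of negatives with the complementary property.
#' @return Value in \eqn{[0,1]}.
#' @export
mean_separability <- function(pos_frac, neg_frac) {
  stopifnot(pos_frac >= 0, pos_frac <= 1, neg_frac >= 0, neg_frac <= 1)
  (pos_frac + neg_frac) / 2
}

#' All-pairs shortest path lengths on the DDI network
#'
#' Unweighted shortest distances between every drug pair (the classical
#' all-pairs problem; computed via igraph). Unreachable pairs are
#' \code{Inf}; the diagonal is 0.
#'
#' @param network a [ddi_network()].
#' @return m x m numeric distance matrix.
#' @export
all_pairs_shortest_paths <- function(network) {
  g <- igraph::graph_from_adjacency_matrix(network$adjacency, mode = "undirected")
  d <- igraph::distances(g)
  dimnames(d) <- list(network$drug_ids, network$drug_ids)
  d
}

scope_split <- function(labels) {
  y <- scope_labels(labels)
  list(pos = labels$scope[y == 1L, , drop = FALSE],
       neg = labels$scope[y == 0L, , drop = FALSE])
}

#' DDI graph-distance separability
#'
#' Fraction of positive pairs whose members lie at shortest DDI distance
#' exactly \code{step} (default 2), versus the same fraction among
#' negatives; combined as \code{pos / (pos + neg)}. \code{at_most = TRUE}
#' counts distances \eqn{\le} \code{step} instead.
#'
#' @param distances matrix from [all_pairs_shortest_paths()].
#' @param labels a [pair_labels()].
#' @param step graph distance defining the property (default 2).
#' @param at_most count distances up to \code{step} rather than exactly.
#' @return List with \code{pos_frac}, \code{neg_frac}, \code{separability}.
#' @export
ddi_separability <- function(distances, labels, step = 2L, at_most = FALSE) {
  sp <- scope_split(labels)
  frac_at <- function(pairs) {
    if (nrow(pairs) == 0L) return(0)
    d <- distances[cbind(match(pairs[, 1L], rownames(distances)),
                         match(pairs[, 2L], colnames(distances)))]
    if (at_most) mean(d <= step) else mean(d == step)
  }
  pos_frac <- frac_at(sp$pos)
  neg_frac <- frac_at(sp$neg)
  list(pos_frac = pos_frac, neg_frac = neg_frac,
       separability = ratio_separability(pos_frac, neg_frac))
}

#' ATC code-sharing separability
#'
#' Mean of (fraction of positive pairs sharing at least one first-level
#' code) and (fraction of negative pairs sharing none).
#'
#' @param universe a [drug_universe()].
#' @param labels a [pair_labels()].
#' @return List with \code{pos_share_frac}, \code{neg_noshare_frac},
#'   \code{separability}.
#' @export
atc_separability <- function(universe, labels) {
  sp <- scope_split(labels)
  if (nrow(sp$pos) == 0L || nrow(sp$neg) == 0L) {
    stop("ATC separability needs both positive and negative pairs")
  }
  shares <- function(pairs) {
    vapply(seq_len(nrow(pairs)), function(i) {
      length(intersect(universe$atc_sets[[pairs[i, 1L]]],
                       universe$atc_sets[[pairs[i, 2L]]])) > 0L
    }, logical(1))
  }
  pos_share <- mean(shares(sp$pos))
  neg_noshare <- mean(!shares(sp$neg))
  list(pos_share_frac = pos_share, neg_noshare_frac = neg_noshare,
       separability = mean_separability(pos_share, neg_noshare))
}

#' Feature-frequency separability for a binary channel
#'
#' A feature "occurs" in a pair iff it is present in at least one member
#' drug. Per feature, the relative occurrence frequency (occurrences /
#' class size, normalizing the class imbalance) is compared between
#' positive and negative pairs: features are classed as pos-enriched
#' (strictly more frequent in positives), neg-enriched (strictly more
#' frequent in negatives), or neither (absent from both classes, or tied).
#' Separability = n_neg_enriched / (n_neg_enriched + n_pos_enriched).
#'
#' @param profiles binary \code{feature_matrix} (DTI or SE channel).
#' @param labels a [pair_labels()].
#' @return List with \code{n_neither}, \code{n_pos_enriched},
#'   \code{n_neg_enriched}, \code{n_tied}, \code{separability}.
#' @export
frequency_separability <- function(profiles, labels) {
  p <- as.matrix(profiles)
  if (!all(p %in% c(0, 1))) stop("frequency_separability needs binary profiles")
  sp <- scope_split(labels)
  if (nrow(sp$pos) == 0L || nrow(sp$neg) == 0L) {
    stop("frequency separability needs both positive and negative pairs")
  }
  pair_freq <- function(pairs) {
    a <- p[pairs[, 1L], , drop = FALSE]
    b <- p[pairs[, 2L], , drop = FALSE]
    colMeans((a + b) > 0)
  }
  f_pos <- pair_freq(sp$pos)
  f_neg <- pair_freq(sp$neg)
  neither <- f_pos == 0 & f_neg == 0
  pos_enr <- f_pos > f_neg
  neg_enr <- f_neg > f_pos
  tied <- !neither & !pos_enr & !neg_enr
  n_pos <- sum(pos_enr)
  n_neg <- sum(neg_enr)
  if (n_pos + n_neg == 0L) {
    stop("frequency separability undefined: no feature is enriched in either class")
  }
  list(n_neither = sum(neither), n_pos_enriched = n_pos,
       n_neg_enriched = n_neg, n_tied = sum(tied),
       separability = ratio_separability(n_neg, n_pos))
}

#' Shared-target pair counts
#'
#' How many candidate pairs have intersecting DTI profiles, split by
#' label; a companion diagnostic showing that raw target sharing alone is
#' a weak separator.
#'
#' @param universe a [drug_universe()].
#' @param labels a [pair_labels()].
#' @return List with \code{n_pos_sharing}, \code{n_neg_sharing},
#'   \code{n_total_sharing}.
#' @export
shared_target_counts <- function(universe, labels) {
  sp <- scope_split(labels)
  sharing <- function(pairs) {
    if (nrow(pairs) == 0L) return(0L)
    a <- universe$dti[pairs[, 1L], , drop = FALSE]
    b <- universe$dti[pairs[, 2L], , drop = FALSE]
    sum(rowSums(a * b) > 0)
  }
  n_pos <- sharing(sp$pos)
  n_neg <- sharing(sp$neg)
  list(n_pos_sharing = n_pos, n_neg_sharing = n_neg,
       n_total_sharing = n_pos + n_neg)
}

#' Full separability report
#'
#' Computes the four channel diagnostics on one dataset.
#'
#' @param universe a [drug_universe()].
#' @param network a [ddi_network()].
#' @param labels a [pair_labels()].
#' @return List of class \code{separability_report} with one entry per
#'   channel plus the shared-target counts.
#' @export
separability_report <- function(universe, network, labels) {
  d <- all_pairs_shortest_paths(network)
  out <- list(
    ddi = ddi_separability(d, labels),
    atc = atc_separability(universe, labels),
    se = frequency_separability(binary_profiles(universe, "SE"), labels),
    dti = frequency_separability(binary_profiles(universe, "DTI"), labels),
    shared_targets = shared_target_counts(universe, labels)
  )
  class(out) <- "separability_report"
  out
}

#' @export
print.separability_report <- function(x, ...) {
  cat("Channel separability (positives vs negatives):\n")
  cat(sprintf("  DDI distance-2 : %.4f  (pos %.4f / neg %.4f)\n",
              x$ddi$separability, x$ddi$pos_frac, x$ddi$neg_frac))
  cat(sprintf("  ATC sharing    : %.4f  (pos share %.4f / neg no-share %.4f)\n",
              x$atc$separability, x$atc$pos_share_frac, x$atc$neg_noshare_frac))
  cat(sprintf("  SE frequency   : %.4f  (%d pos- / %d neg-enriched, %d neither)\n",
              x$se$separability, x$se$n_pos_enriched, x$se$n_neg_enriched,
              x$se$n_neither))
  cat(sprintf("  DTI frequency  : %.4f  (%d pos- / %d neg-enriched, %d neither)\n",
              x$dti$separability, x$dti$n_pos_enriched, x$dti$n_neg_enriched,
              x$dti$n_neither))
  cat(sprintf("  shared targets : %d pairs (%d positive, %d negative)\n",
              x$shared_targets$n_total_sharing, x$shared_targets$n_pos_sharing,
              x$shared_targets$n_neg_sharing))
  invisible(x)
}
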