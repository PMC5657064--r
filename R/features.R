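# Heterogeneous per-drug feature channels.
#
# DDI: spectral embedding of the pharmaceutical interaction graph. The
#      adjacency is decomposed as T = U S V', singular values below a
#      threshold are discarded, and each drug is represented by a row of
#      U sqrt(S) so that the embedding Gram matrix reconstructs T (exactly
#      for PSD T). Using SVD rather than an eigendecomposition keeps S
#      nonnegative and sqrt(S) well defined for indefinite adjacencies.
# ATC: Tanimoto (Jaccard) similarity of first-level code sets, used
#      directly as a pairwise confidence channel.
# DTI/SE: sparse binary profiles, optionally PCA-reduced.

new_feature_matrix <- function(values, channel, drug_ids) {
  values <- as.matrix(values)
  rownames(values) <- drug_ids
  if (!all(is.finite(values))) stop("feature matrix entries must be finite")
  structure(values, channel = channel, class = c("feature_matrix", "matrix", "array"))
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("Feature matrix [%s]: %d drugs x %d dimensions\n",
              attr(x, "channel"), nrow(x), ncol(x)))
  invisible(x)
}

# Deterministic sign convention: flip each column so its largest-magnitude
# entry is positive (ties broken by the first such entry).
fix_signs <- function(u) {
  if (ncol(u) == 0L) return(u)
  for (j in seq_len(ncol(u))) {
    i <- which.max(abs(u[, j]))
    if (u[i, j] < 0) u[, j] <- -u[, j]
  }
  u
}

#' Spectral (SVD) embedding of the DDI network
#'
#' Decomposes the symmetric binary adjacency by singular value
#' decomposition, discards singular values below \code{sv_threshold}, and
#' returns per-drug embedding rows \eqn{U \sqrt{\Sigma}} truncated to the
#' leading \code{n_keep} components (descending singular value). Isolated
#' drugs receive all-zero rows. Component signs are fixed so the
#' largest-magnitude loading of each component is positive.
#'
#' @param network a [ddi_network()].
#' @param n_keep number of leading components to retain (default 25).
#' @param sv_threshold singular values below this are discarded
#'   (default 1e-6).
#' @return A \code{feature_matrix} with channel \code{"DDI"}.
#' @export
ddi_embedding <- function(network, n_keep = 25L, sv_threshold = 1e-6) {
  stopifnot(n_keep >= 1L, sv_threshold >= 0)
  adj <- network$adjacency
  dec <- svd(adj)
  keep <- which(dec$d >= sv_threshold)
  if (length(keep) == 0L) {
    warning("all singular values below threshold; DDI embedding is degenerate (0 columns)")
    return(new_feature_matrix(matrix(0, nrow(adj), 0L), "DDI", network$drug_ids))
  }
  keep <- keep[seq_len(min(n_keep, length(keep)))]
  u <- fix_signs(dec$u[, keep, drop = FALSE])
  f <- sweep(u, 2L, sqrt(dec$d[keep]), `*`)
  colnames(f) <- sprintf("sv%02d", seq_along(keep))
  new_feature_matrix(f, "DDI", network$drug_ids)
}

#' First-level ATC Tanimoto similarity matrix
#'
#' \eqn{s_{ij} = |A_i \cap A_j| / |A_i \cup A_j|} over the drugs'
#' first-level ATC code sets. The diagonal is 1 for drugs with a non-empty
#' set; pairs where both sets are empty get similarity 0 (reported via a
#' message).
#'
#' @param universe a [drug_universe()].
#' @return Symmetric m x m similarity matrix in \eqn{[0,1]}.
#' @export
atc_similarity <- function(universe) {
  sets <- universe$atc_sets
  m <- length(sets)
  # code-indicator matrix makes intersections/unions a matrix product
  ind <- matrix(0, m, length(ATC_ALPHABET),
                dimnames = list(universe$drug_ids, ATC_ALPHABET))
  for (i in seq_len(m)) ind[i, sets[[i]]] <- 1
  inter <- ind %*% t(ind)
  sizes <- rowSums(ind)
  uni <- outer(sizes, sizes, `+`) - inter
  s <- ifelse(uni > 0, inter / uni, 0)
  n_empty <- sum(sizes == 0)
  if (n_empty > 0L) {
    message(n_empty, " drug(s) have an empty ATC set; their similarities default to 0")
  }
  dimnames(s) <- list(universe$drug_ids, universe$drug_ids)
  s
}

#' Binary profile feature matrix for one channel
#'
#' @param universe a [drug_universe()].
#' @param channel \code{"DTI"} or \code{"SE"}.
#' @return A \code{feature_matrix} of the stored binary profiles, columns
#'   in lexicographic item order.
#' @export
binary_profiles <- function(universe, channel = c("DTI", "SE")) {
  channel <- match.arg(channel)
  vals <- if (channel == "DTI") universe$dti else universe$se
  new_feature_matrix(vals, channel, universe$drug_ids)
}

# Fit a PCA on x (rows = drugs used for fitting); returns center, rotation
# and the rank actually retained. Scores for arbitrary drugs come from
# pca_project().
pca_fit <- function(x, n_components, center = TRUE) {
  x <- as.matrix(x)
  stopifnot(n_components >= 1L)
  ctr <- if (center) colMeans(x) else rep(0, ncol(x))
  xc <- sweep(x, 2L, ctr)
  dec <- svd(xc, nu = 0)
  tol <- max(dim(xc)) * max(dec$d, 0) * .Machine$double.eps
  rank <- sum(dec$d > max(tol, 1e-12))
  if (n_components > rank) {
    warning(sprintf("requested %d components but rank is %d; retaining %d",
                    n_components, rank, rank))
    n_components <- max(rank, 1L)
  }
  k <- min(n_components, ncol(xc))
  rot <- fix_signs(dec$v[, seq_len(k), drop = FALSE])
  list(center = ctr, rotation = rot,
       sdev = dec$d[seq_len(k)] / sqrt(max(nrow(x) - 1L, 1L)))
}

pca_project <- function(fit, x) {
  sweep(as.matrix(x), 2L, fit$center) %*% fit$rotation
}

#' PCA reduction of a feature channel
#'
#' Mean-centered projection onto the leading principal components
#' (descending explained variance). Components beyond the matrix rank are
#' dropped with a warning. Component signs follow the same
#' largest-loading-positive convention as [ddi_embedding()], making the
#' output reproducible.
#'
#' @param features a \code{feature_matrix}.
#' @param n_components number of components (default 25).
#' @param center subtract column means before projecting (default TRUE).
#' @return A \code{feature_matrix} of PCA scores with the same channel tag.
#' @export
reduce_pca <- function(features, n_components = 25L, center = TRUE) {
  fit <- pca_fit(features, n_components, center = center)
  scores <- pca_project(fit, features)
  colnames(scores) <- sprintf("pc%02d", seq_len(ncol(scores)))
  new_feature_matrix(scores, attr(features, "channel"), rownames(features))
}
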