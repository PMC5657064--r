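# WHO ATC anatomical main groups (first level).
ATC_ALPHABET <- c("A", "B", "C", "D", "G", "H", "J", "L", "M", "N", "P", "R", "S", "V")

#' Construct a drug universe
#'
#' A drug universe bundles, for a common ordered set of drug identifiers, the
#' three per-drug attribute sources used by the predictor: first-level ATC
#' code sets, a binary drug-target interaction (DTI) profile and a binary
#' side-effect (SE) profile. Profiles share their column vocabulary across
#' drugs; columns are kept in lexicographic order of item id.
#'
#' @param drug_ids character vector of unique drug identifiers.
#' @param atc_sets named list (one entry per drug) of character vectors of
#'   first-level ATC codes; each code is a single letter from the 14-letter
#'   WHO alphabet \code{A B C D G H J L M N P R S V}. Empty sets are allowed.
#' @param dti binary matrix, drugs in rows (rownames = \code{drug_ids}),
#'   targets in columns.
#' @param se binary matrix, drugs in rows, side effects in columns.
#' @return An object of class \code{drug_universe}.
#' @export
drug_universe <- function(drug_ids, atc_sets, dti, se) {
  drug_ids <- as.character(drug_ids)
  if (anyDuplicated(drug_ids)) {
    stop("drug_ids must be unique")
  }
  if (length(drug_ids) == 0L) {
    stop("empty universe: no drugs")
  }
  atc_sets <- atc_sets[drug_ids]
  if (any(vapply(atc_sets, is.null, logical(1)))) {
    stop("atc_sets must contain an entry for every drug id")
  }
  atc_sets <- lapply(atc_sets, function(a) sort(unique(as.character(a))))
  bad <- unique(unlist(atc_sets))
  bad <- bad[!bad %in% ATC_ALPHABET]
  if (length(bad) > 0L) {
    stop("ATC codes outside the 14-letter first-level alphabet: ",
         paste(bad, collapse = ", "))
  }
  dti <- check_profile_matrix(dti, drug_ids, "dti")
  se <- check_profile_matrix(se, drug_ids, "se")
  structure(
    list(drug_ids = drug_ids, atc_sets = atc_sets, dti = dti, se = se),
    class = "drug_universe"
  )
}

check_profile_matrix <- function(x, drug_ids, what) {
  x <- as.matrix(x)
  if (is.null(rownames(x)) || !setequal(rownames(x), drug_ids)) {
    stop(what, " profile rownames must match drug_ids")
  }
  x <- x[drug_ids, , drop = FALSE]
  if (!all(x %in% c(0, 1))) {
    stop(what, " profiles must be strictly binary (0/1)")
  }
  storage.mode(x) <- "double"
  if (ncol(x) > 0L) {
    if (is.null(colnames(x))) {
      colnames(x) <- sprintf("%s_%d", what, seq_len(ncol(x)))
    }
    x <- x[, order(colnames(x)), drop = FALSE]
  }
  x
}

#' @export
print.drug_universe <- function(x, ...) {
  cat("Drug universe:", length(x$drug_ids), "drugs\n")
  cat("  ATC: ", sum(lengths(x$atc_sets) > 0L), " drugs with >=1 first-level code\n", sep = "")
  cat("  DTI: ", ncol(x$dti), " targets\n", sep = "")
  cat("  SE:  ", ncol(x$se), " side effects\n", sep = "")
  invisible(x)
}

#' Construct a pharmaceutical drug-drug interaction network
#'
#' The DDI network records unwanted pharmaceutical (physical / chemical /
#' pharmacokinetic) interactions between drugs. It is a feature source for
#' the combination predictor, not a label: combination status is carried by
#' [pair_labels()].
#'
#' @param adjacency symmetric binary matrix with zero diagonal; row/column
#'   names are drug ids in the universe order.
#' @param drug_ids optional drug id vector; defaults to the adjacency
#'   dimnames.
#' @return An object of class \code{ddi_network}.
#' @export
ddi_network <- function(adjacency, drug_ids = rownames(adjacency)) {
  adjacency <- as.matrix(adjacency)
  drug_ids <- as.character(drug_ids)
  if (nrow(adjacency) != ncol(adjacency) || nrow(adjacency) != length(drug_ids)) {
    stop("adjacency must be square with one row per drug id")
  }
  dimnames(adjacency) <- list(drug_ids, drug_ids)
  if (!all(adjacency %in% c(0, 1))) {
    stop("adjacency entries must be 0/1")
  }
  if (!isTRUE(all.equal(adjacency, t(adjacency)))) {
    stop("adjacency must be symmetric")
  }
  if (any(diag(adjacency) != 0)) {
    stop("adjacency must have a zero diagonal (no self-interactions)")
  }
  storage.mode(adjacency) <- "double"
  structure(list(adjacency = adjacency, drug_ids = drug_ids), class = "ddi_network")
}

#' @export
print.ddi_network <- function(x, ...) {
  m <- length(x$drug_ids)
  cat("DDI network:", m, "drugs,", sum(x$adjacency) / 2, "interactions\n")
  invisible(x)
}

canonical_pairs <- function(a, b) {
  a <- as.character(a)
  b <- as.character(b)
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  cbind(drug_a = lo, drug_b = hi)
}

pair_keys <- function(pairs) paste(pairs[, 1L], pairs[, 2L], sep = "\r")

#' All unordered drug pairs of a universe
#'
#' @param drug_ids character vector of drug ids.
#' @return Two-column character matrix of the \eqn{m(m-1)/2} canonical
#'   unordered pairs.
#' @export
all_pairs <- function(drug_ids) {
  drug_ids <- sort(as.character(drug_ids))
  m <- length(drug_ids)
  if (m < 2L) {
    return(cbind(drug_a = character(0), drug_b = character(0)))
  }
  idx <- utils::combn(m, 2L)
  cbind(drug_a = drug_ids[idx[1L, ]], drug_b = drug_ids[idx[2L, ]])
}

#' Construct a pair label set
#'
#' Holds the approved combinative drug pairs (positives) and the scope of
#' candidate pairs treated as instances; scope pairs outside the positives
#' are the negatives. Pairs are stored canonically (lexicographic id order)
#' and self-pairs are disallowed.
#'
#' @param positives two-column matrix/data.frame of positive pairs.
#' @param drug_ids drug ids of the universe the pairs live in.
#' @param scope optional two-column matrix of candidate pairs; defaults to
#'   all \eqn{m(m-1)/2} pairs over \code{drug_ids}.
#' @return An object of class \code{pair_labels}.
#' @export
pair_labels <- function(positives, drug_ids, scope = NULL) {
  drug_ids <- sort(as.character(drug_ids))
  positives <- as.matrix(positives)
  if (nrow(positives) > 0L) {
    keep <- positives[, 1L] %in% drug_ids & positives[, 2L] %in% drug_ids
    if (!all(keep)) {
      warning(sum(!keep), " positive pair(s) referencing unknown drugs dropped")
      positives <- positives[keep, , drop = FALSE]
    }
    self <- positives[, 1L] == positives[, 2L]
    if (any(self)) {
      warning(sum(self), " self-pair(s) dropped from positives")
      positives <- positives[!self, , drop = FALSE]
    }
  }
  positives <- canonical_pairs(positives[, 1L], positives[, 2L])
  positives <- positives[!duplicated(pair_keys(positives)), , drop = FALSE]
  positives <- positives[order(positives[, 1L], positives[, 2L]), , drop = FALSE]
  if (is.null(scope)) {
    scope <- all_pairs(drug_ids)
  } else {
    scope <- as.matrix(scope)
    keep <- scope[, 1L] %in% drug_ids & scope[, 2L] %in% drug_ids &
      scope[, 1L] != scope[, 2L]
    if (!all(keep)) {
      warning(sum(!keep), " scope pair(s) dropped (unknown drug or self-pair)")
      scope <- scope[keep, , drop = FALSE]
    }
    scope <- canonical_pairs(scope[, 1L], scope[, 2L])
    scope <- scope[!duplicated(pair_keys(scope)), , drop = FALSE]
    scope <- scope[order(scope[, 1L], scope[, 2L]), , drop = FALSE]
  }
  if (!all(pair_keys(positives) %in% pair_keys(scope))) {
    stop("positives must be a subset of the pair scope")
  }
  structure(
    list(positives = positives, scope = scope, drug_ids = drug_ids),
    class = "pair_labels"
  )
}

#' @export
print.pair_labels <- function(x, ...) {
  cat("Pair labels:", nrow(x$positives), "positives /",
      nrow(x$scope), "candidate pairs over", length(x$drug_ids), "drugs\n")
  invisible(x)
}

#' Binary label vector over the scope of a pair label set
#'
#' @param labels a [pair_labels()] object.
#' @return Integer 0/1 vector, one entry per scope pair (1 = positive).
#' @export
scope_labels <- function(labels) {
  as.integer(pair_keys(labels$scope) %in% pair_keys(labels$positives))
}
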