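# Readers and writers for the on-disk TSV dialects.
#
# ATC file:    drug_id <TAB> code1;code2;...   (full or first-level codes)
# DTI/SE file: drug_id <TAB> item_id           (long format, one per line;
#              a line with an empty item registers a drug with no items)
# DDI file:    drug_a <TAB> drug_b             (edge list)
# Labels file: drug_a <TAB> drug_b             (positive pair list)
#
# Writers emit an optional "# items: ..." comment header carrying the full
# column vocabulary so that profiles with all-zero columns round-trip.

read_tsv_lines <- function(path) {
  lines <- readLines(path)
  lines[nzchar(trimws(lines))]
}

parse_two_col <- function(path, allow_empty_second = FALSE) {
  lines <- read_tsv_lines(path)
  items <- character(0)
  keep <- !startsWith(lines, "#")
  for (h in lines[!keep]) {
    if (grepl("^#\\s*items:", h)) {
      toks <- strsplit(sub("^#\\s*items:\\s*", "", h), ";", fixed = TRUE)[[1L]]
      items <- c(items, toks[nzchar(toks)])
    }
  }
  lines <- lines[keep]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- lengths(fields)
  bad <- which(n < 1L | n > 2L | (n == 1L & !allow_empty_second))
  if (length(bad) > 0L) {
    stop(sprintf("malformed line %d in %s: expected two tab-separated fields",
                 bad[1L], path))
  }
  a <- vapply(fields, `[[`, character(1), 1L)
  b <- vapply(fields, function(f) if (length(f) >= 2L) f[[2L]] else "", character(1))
  list(a = trimws(a), b = trimws(b), items = unique(trimws(items)), path = path)
}

parse_atc_file <- function(path) {
  tab <- parse_two_col(path, allow_empty_second = TRUE)
  if (anyDuplicated(tab$a)) {
    dup <- tab$a[duplicated(tab$a)][1L]
    stop(sprintf("duplicate drug id '%s' in %s", dup, path))
  }
  sets <- lapply(tab$b, function(codes) {
    if (!nzchar(codes)) return(character(0))
    toks <- strsplit(codes, ";", fixed = TRUE)[[1L]]
    toks <- trimws(toks)
    toks <- toks[nzchar(toks)]
    # full ATC codes are accepted; only the first-level letter is retained
    sort(unique(toupper(substr(toks, 1L, 1L))))
  })
  names(sets) <- tab$a
  sets
}

parse_long_profile <- function(path) {
  tab <- parse_two_col(path, allow_empty_second = TRUE)
  drugs <- unique(tab$a)
  real <- nzchar(tab$b)
  items <- sort(unique(c(tab$b[real], tab$items)))
  mat <- matrix(0, length(drugs), length(items),
                dimnames = list(drugs, items))
  if (any(real)) {
    mat[cbind(match(tab$a[real], drugs), match(tab$b[real], items))] <- 1
  }
  mat
}

#' Read a drug universe from ATC, DTI and SE files
#'
#' The returned universe is restricted to drugs present in all three
#' sources (set intersection), mirroring the benchmark practice of keeping
#' only drugs with a complete feature complement; set
#' \code{require_all = FALSE} to keep the union instead (absent profiles
#' become empty). Drug order is lexicographic by id.
#'
#' @param atc_path TSV of \code{drug_id<TAB>code1;code2;...}.
#' @param dti_path long-format TSV of \code{drug_id<TAB>target_id}.
#' @param se_path long-format TSV of \code{drug_id<TAB>side_effect_id}.
#' @param require_all restrict to drugs present in every source (default).
#' @return A [drug_universe()].
#' @export
read_universe <- function(atc_path, dti_path, se_path, require_all = TRUE) {
  atc <- parse_atc_file(atc_path)
  dti <- parse_long_profile(dti_path)
  se <- parse_long_profile(se_path)
  if (require_all) {
    ids <- intersect(intersect(names(atc), rownames(dti)), rownames(se))
  } else {
    ids <- union(union(names(atc), rownames(dti)), rownames(se))
  }
  ids <- sort(ids)
  if (length(ids) == 0L) {
    stop("empty universe: no drug appears in all of the ATC, DTI and SE sources")
  }
  atc_sets <- lapply(ids, function(d) if (d %in% names(atc)) atc[[d]] else character(0))
  names(atc_sets) <- ids
  dti_m <- expand_profile(dti, ids)
  se_m <- expand_profile(se, ids)
  drug_universe(ids, atc_sets, dti_m, se_m)
}

expand_profile <- function(mat, ids) {
  out <- matrix(0, length(ids), ncol(mat), dimnames = list(ids, colnames(mat)))
  common <- intersect(ids, rownames(mat))
  out[common, ] <- mat[common, , drop = FALSE]
  out
}

#' Read a DDI edge list into a network over a universe
#'
#' Edges referencing drugs outside the universe are dropped (with a count
#' reported); self-loops are rejected with a warning. Duplicate and
#' reversed edges collapse to one symmetric entry.
#'
#' @param edge_path TSV edge list \code{drug_a<TAB>drug_b}.
#' @param universe a [drug_universe()].
#' @return A [ddi_network()] in the universe's drug order.
#' @export
read_ddi <- function(edge_path, universe) {
  tab <- parse_two_col(edge_path)
  ids <- universe$drug_ids
  inside <- tab$a %in% ids & tab$b %in% ids
  if (any(!inside)) {
    message(sum(!inside), " DDI edge(s) outside the universe dropped")
  }
  a <- tab$a[inside]
  b <- tab$b[inside]
  self <- a == b
  if (any(self)) {
    warning(sum(self), " self-loop DDI edge(s) rejected")
    a <- a[!self]
    b <- b[!self]
  }
  adj <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  if (length(a) > 0L) {
    adj[cbind(match(a, ids), match(b, ids))] <- 1
    adj[cbind(match(b, ids), match(a, ids))] <- 1
  }
  ddi_network(adj, ids)
}

#' Read positive (and optionally scoped) pair labels
#'
#' @param pair_path TSV pair list of approved combinative pairs.
#' @param universe a [drug_universe()].
#' @param scope_path optional TSV pair list restricting the candidate
#'   instances; default scope is every unordered pair of universe drugs.
#' @return A [pair_labels()].
#' @export
read_labels <- function(pair_path, universe, scope_path = NULL) {
  tab <- parse_two_col(pair_path)
  scope <- NULL
  if (!is.null(scope_path)) {
    st <- parse_two_col(scope_path)
    scope <- cbind(st$a, st$b)
  }
  pair_labels(cbind(tab$a, tab$b), universe$drug_ids, scope = scope)
}

#' Write a drug universe to the three standard TSV files
#'
#' @param universe a [drug_universe()].
#' @param atc_path,dti_path,se_path output paths.
#' @return Invisibly, the three paths.
#' @export
write_universe <- function(universe, atc_path, dti_path, se_path) {
  ids <- universe$drug_ids
  atc_lines <- vapply(ids, function(d) {
    paste0(d, "\t", paste(universe$atc_sets[[d]], collapse = ";"))
  }, character(1))
  writeLines(atc_lines, atc_path)
  write_long_profile(universe$dti, dti_path)
  write_long_profile(universe$se, se_path)
  invisible(c(atc_path, dti_path, se_path))
}

write_long_profile <- function(mat, path) {
  lines <- paste0("# items: ", paste(colnames(mat), collapse = ";"))
  for (d in rownames(mat)) {
    items <- colnames(mat)[mat[d, ] == 1]
    if (length(items) == 0L) {
      lines <- c(lines, paste0(d, "\t"))
    } else {
      lines <- c(lines, paste0(d, "\t", items))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a DDI network as a TSV edge list
#'
#' @param network a [ddi_network()].
#' @param path output path.
#' @export
write_ddi <- function(network, path) {
  adj <- network$adjacency
  idx <- which(upper.tri(adj) & adj == 1, arr.ind = TRUE)
  lines <- paste0(rownames(adj)[idx[, 1L]], "\t", colnames(adj)[idx[, 2L]])
  writeLines(lines, path)
  invisible(path)
}

#' Write positive pair labels as a TSV pair list
#'
#' @param labels a [pair_labels()].
#' @param path output path for the positives.
#' @param scope_path optional output path for the full candidate scope.
#' @export
write_labels <- function(labels, path, scope_path = NULL) {
  writeLines(paste0(labels$positives[, 1L], "\t", labels$positives[, 2L]), path)
  if (!is.null(scope_path)) {
    writeLines(paste0(labels$scope[, 1L], "\t", labels$scope[, 2L]), scope_path)
  }
  invisible(path)
}
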