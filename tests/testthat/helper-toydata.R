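# Small in-code fixtures shared across test files.

# A 4-drug toy universe with hand-picked attributes.
toy_universe <- function() {
  ids <- c("da", "db", "dc", "dd")
  atc <- list(da = c("A"), db = c("A", "C"), dc = c("N"), dd = character(0))
  dti <- matrix(c(1, 0, 1,
                  0, 1, 0,
                  1, 1, 0,
                  0, 0, 0), 4, 3, byrow = TRUE,
                dimnames = list(ids, c("t1", "t2", "t3")))
  se <- matrix(c(1, 0, 0, 1,
                 1, 1, 0, 0,
                 0, 0, 1, 0,
                 0, 1, 1, 1), 4, 4, byrow = TRUE,
               dimnames = list(ids, c("s1", "s2", "s3", "s4")))
  drug_universe(ids, atc, dti, se)
}

# Path graph da - db - dc, dd isolated.
toy_network <- function() {
  ids <- c("da", "db", "dc", "dd")
  adj <- matrix(0, 4, 4, dimnames = list(ids, ids))
  adj["da", "db"] <- adj["db", "da"] <- 1
  adj["db", "dc"] <- adj["dc", "db"] <- 1
  ddi_network(adj, ids)
}

toy_labels <- function() {
  pair_labels(rbind(c("da", "dc"), c("db", "dd")), c("da", "db", "dc", "dd"))
}

# Write a tiny fixture set of the on-disk dialects into a temp dir.
write_toy_files <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  writeLines(c("da\tA.04.A.D.12", "db\tA;C05AA09", "dc\tN", "dd\t"),
             file.path(dir, "atc.tsv"))
  writeLines(c("da\tt1", "da\tt3", "db\tt2", "dc\tt1", "dc\tt2", "dd\t"),
             file.path(dir, "dti.tsv"))
  writeLines(c("da\ts1", "db\ts1", "db\ts2", "dc\ts3", "dd\ts2"),
             file.path(dir, "se.tsv"))
  writeLines(c("da\tdb", "db\tdc"), file.path(dir, "ddi.tsv"))
  writeLines(c("da\tdc", "db\tdd"), file.path(dir, "labels.tsv"))
  dir
}

# Minimal universe over arbitrary ids (profiles immaterial; used by the
# splitter tests).
toy_universe4 <- function(ids) {
  drug_universe(ids,
                stats::setNames(rep(list("A"), length(ids)), ids),
                matrix(0, length(ids), 1, dimnames = list(ids, "t1")),
                matrix(0, length(ids), 1, dimnames = list(ids, "s1")))
}

# Brute-force Mann-Whitney AUC: explicit loop over positive-negative pairs.
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    for (n in neg) {
      total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# Brute-force step-wise PR curve: enumerate every unique threshold.
brute_aupr <- function(scores, labels) {
  ths <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels == 1)
  prev_recall <- 0
  area <- 0
  for (t in ths) {
    sel <- scores >= t
    tp <- sum(labels[sel] == 1)
    fp <- sum(labels[sel] == 0)
    precision <- tp / (tp + fp)
    recall <- tp / n_pos
    area <- area + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  area
}

# Breadth-first-search single-source shortest paths on an adjacency matrix.
bfs_distances <- function(adj, src) {
  m <- nrow(adj)
  dist <- rep(Inf, m)
  dist[src] <- 0
  frontier <- src
  d <- 0
  while (length(frontier) > 0) {
    d <- d + 1
    nxt <- integer(0)
    for (v in frontier) {
      nbrs <- which(adj[v, ] == 1)
      nbrs <- nbrs[dist[nbrs] == Inf]
      dist[nbrs] <- d
      nxt <- c(nxt, nbrs)
    }
    frontier <- unique(nxt)
  }
  dist
}
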