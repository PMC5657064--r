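# Synthetic benchmark generator.
#
# Emulates the structure of the approved-combination benchmark: a sparse
# symmetric pharmaceutical DDI graph, small first-level ATC code sets over
# the 14-letter alphabet, sparse high-dimensional binary DTI/SE profiles,
# and a small positive class with four planted channel signals:
#   (i)   positive pairs prefer DDI shortest distance 2 (and avoid direct
#         interaction),
#   (ii)  positive pairs tend to share a first-level ATC code,
#   (iii) positive-pair drugs carry "beneficial" side effects and avoid
#         "adverse" ones,
#   (iv)  positive-pair drugs hit planted positive-pattern targets and
#         avoid negative-pattern ones.
# SE/DTI signals are graded: each drug gets a latent channel propensity
# that scales its rates on the planted feature sets, and positive pairs
# are sampled with weight effect_strength^z where z standardizes the
# pair's planted-set load. With effect_strength = 1 every planting
# switches off and labels are exchangeable with the background (null).

#' Synthetic benchmark configuration
#'
#' Defaults describe a desk-scale benchmark whose class fractions and
#' channel strengths mirror an approved-combination screening set: 120
#' drugs, 100 positive pairs among all 7140 candidates, ~2:1 to 3:1
#' adverse:beneficial planted feature sets so the frequency diagnostics
#' point the same way as on real data.
#'
#' @param m number of drugs.
#' @param n_targets,n_se DTI / SE profile dimensions.
#' @param n_pos number of positive (combinative) pairs.
#' @param ddi_density edge probability of the DDI graph.
#' @param p_atc_share probability (at full planting strength) that a
#'   positive pair gets a shared first-level code injected.
#' @param p_dist2 probability (at full planting strength) that a positive
#'   pair is drawn from the distance-2 pool.
#' @param n_beneficial_se,n_adverse_se planted SE pattern set sizes
#'   (defaults scale with \code{n_se}: 1/16 beneficial, 3/16 adverse, i.e.
#'   50 and 150 at the default dimension — the adverse set dominates, as on
#'   real benchmarks).
#' @param n_pos_targets,n_neg_targets planted DTI pattern set sizes
#'   (defaults 1/10 and 1/5 of \code{n_targets}).
#' @param effect_strength >= 1; 1 = null (no planted signal), larger =
#'   stronger enrichment odds.
#' @param base_rate_se,base_rate_dti background Bernoulli rates of the
#'   binary profiles.
#' @param seed integer seed; generation is deterministic given the config.
#' @return A list of class \code{synthetic_config}.
#' @export
synthetic_config <- function(m = 120L, n_targets = 300L, n_se = 800L,
                             n_pos = 100L, ddi_density = 0.04,
                             p_atc_share = 0.9, p_dist2 = 0.75,
                             n_beneficial_se = round(n_se / 16),
                             n_adverse_se = round(3 * n_se / 16),
                             n_pos_targets = round(n_targets / 10),
                             n_neg_targets = round(n_targets / 5),
                             effect_strength = 4, base_rate_se = 0.05,
                             base_rate_dti = 0.02, seed = 1L) {
  cfg <- list(m = as.integer(m), n_targets = as.integer(n_targets),
              n_se = as.integer(n_se), n_pos = as.integer(n_pos),
              ddi_density = ddi_density, p_atc_share = p_atc_share,
              p_dist2 = p_dist2,
              n_beneficial_se = as.integer(n_beneficial_se),
              n_adverse_se = as.integer(n_adverse_se),
              n_pos_targets = as.integer(n_pos_targets),
              n_neg_targets = as.integer(n_neg_targets),
              effect_strength = effect_strength,
              base_rate_se = base_rate_se, base_rate_dti = base_rate_dti,
              seed = as.integer(seed))
  stopifnot(cfg$m >= 4L,
            cfg$ddi_density >= 0, cfg$ddi_density <= 1,
            cfg$p_atc_share >= 0, cfg$p_atc_share <= 1,
            cfg$p_dist2 >= 0, cfg$p_dist2 <= 1,
            cfg$effect_strength >= 1,
            cfg$n_beneficial_se + cfg$n_adverse_se <= cfg$n_se,
            cfg$n_pos_targets + cfg$n_neg_targets <= cfg$n_targets)
  if (cfg$n_pos > cfg$m * (cfg$m - 1) / 2) {
    stop("infeasible config: n_pos exceeds the number of unordered pairs")
  }
  if (cfg$n_pos < 1L) stop("infeasible config: need at least one positive pair")
  class(cfg) <- "synthetic_config"
  cfg
}

# Graded per-drug rate on a planted feature set: propensity v in [0,1]
# tilts the base rate between 0.2x and 1.8x (mean preserved).
graded_rate <- function(base, v) pmin(1, base * (0.2 + 1.6 * v))

#' Generate a synthetic benchmark dataset
#'
#' @param config a [synthetic_config()].
#' @return A list of class \code{synthetic_dataset} with elements
#'   \code{universe}, \code{network}, \code{labels}, \code{config} and
#'   \code{planted} (the planted feature index sets).
#' @export
generate_synthetic <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, generate_synthetic_impl(config))
}

generate_synthetic_impl <- function(cfg) {
  m <- cfg$m
  ids <- sprintf("d%04d", seq_len(m))
  gamma <- 1 - 1 / cfg$effect_strength

  # --- DDI graph ---------------------------------------------------------
  adj <- matrix(0, m, m, dimnames = list(ids, ids))
  ut <- which(upper.tri(adj))
  adj[ut] <- as.numeric(stats::runif(length(ut)) < cfg$ddi_density)
  adj <- adj + t(adj)
  network <- ddi_network(adj, ids)

  # --- background ATC sets (1-3 first-level codes per drug) -------------
  atc_sets <- lapply(seq_len(m), function(i) {
    sort(sample(ATC_ALPHABET, sample(1:3, 1L)))
  })
  names(atc_sets) <- ids

  # --- latent channel propensities and binary profiles ------------------
  v_se <- stats::runif(m)
  v_dti <- stats::runif(m)
  se_idx <- list(beneficial = seq_len(cfg$n_beneficial_se),
                 adverse = cfg$n_beneficial_se + seq_len(cfg$n_adverse_se))
  dti_idx <- list(positive = seq_len(cfg$n_pos_targets),
                  negative = cfg$n_pos_targets + seq_len(cfg$n_neg_targets))

  se <- fill_profile(m, cfg$n_se, cfg$base_rate_se,
                     up = se_idx$beneficial, down = se_idx$adverse, v = v_se)
  dti <- fill_profile(m, cfg$n_targets, cfg$base_rate_dti,
                      up = dti_idx$positive, down = dti_idx$negative, v = v_dti)
  rownames(se) <- ids
  colnames(se) <- sprintf("se%04d", seq_len(cfg$n_se))
  rownames(dti) <- ids
  colnames(dti) <- sprintf("t%04d", seq_len(cfg$n_targets))

  # --- pair-level planted score and positive sampling -------------------
  pairs <- all_pairs(ids)
  pa <- match(pairs[, 1L], ids)
  pb <- match(pairs[, 2L], ids)
  load_se <- rowSums(se[, se_idx$beneficial, drop = FALSE]) -
    rowSums(se[, se_idx$adverse, drop = FALSE])
  load_dti <- rowSums(dti[, dti_idx$positive, drop = FALSE]) -
    rowSums(dti[, dti_idx$negative, drop = FALSE])
  z_se <- pmin(pmax(standardize(load_se[pa] + load_se[pb]), -3), 3)
  z_dti <- pmin(pmax(standardize(load_dti[pa] + load_dti[pb]), -3), 3)
  # independent per-channel tilts; effect_strength = 1 gives uniform weights
  w_pair <- cfg$effect_strength^z_se * cfg$effect_strength^z_dti

  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  dmat <- igraph::distances(g)
  pair_dist <- dmat[cbind(pa, pb)]
  dist2_pool <- which(pair_dist == 2)

  available <- rep(TRUE, nrow(pairs))
  chosen <- integer(0)
  for (i in seq_len(cfg$n_pos)) {
    use_dist2 <- stats::runif(1) < gamma * cfg$p_dist2
    cand <- if (use_dist2) dist2_pool[available[dist2_pool]] else which(available)
    if (length(cand) == 0L) cand <- which(available)
    if (length(cand) == 0L) stop("infeasible config: ran out of candidate pairs")
    pick <- if (length(cand) == 1L) cand else
      sample(cand, 1L, prob = w_pair[cand])
    chosen <- c(chosen, pick)
    available[pick] <- FALSE
  }
  positives <- pairs[chosen, , drop = FALSE]

  # --- ATC shared-code injection for positives --------------------------
  for (i in seq_len(nrow(positives))) {
    if (stats::runif(1) < gamma * cfg$p_atc_share) {
      a <- positives[i, 1L]
      b <- positives[i, 2L]
      shared <- intersect(atc_sets[[a]], atc_sets[[b]])
      if (length(shared) == 0L) {
        code <- sample(ATC_ALPHABET, 1L)
        atc_sets[[a]] <- sort(unique(c(atc_sets[[a]], code)))
        atc_sets[[b]] <- sort(unique(c(atc_sets[[b]], code)))
      }
    }
  }

  universe <- drug_universe(ids, atc_sets, dti, se)
  labels <- pair_labels(positives, ids)
  structure(
    list(universe = universe, network = network, labels = labels,
         config = cfg, planted = list(se = se_idx, dti = dti_idx)),
    class = "synthetic_dataset"
  )
}

fill_profile <- function(m, n_feat, base, up, down, v) {
  rates <- matrix(base, m, n_feat)
  if (length(up) > 0L) rates[, up] <- graded_rate(base, v)
  if (length(down) > 0L) rates[, down] <- graded_rate(base, 1 - v)
  matrix(as.numeric(stats::runif(m * n_feat) < rates), m, n_feat)
}

standardize <- function(x) {
  s <- stats::sd(x)
  if (s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic benchmark:", x$config$m, "drugs,",
      nrow(x$labels$positives), "positive pairs, effect strength",
      x$config$effect_strength, "\n")
  invisible(x)
}

#' Write a synthetic dataset as the five standard TSV files
#'
#' Emits \code{atc.tsv}, \code{dti.tsv}, \code{se.tsv}, \code{ddi.tsv} and
#' \code{labels.tsv} in the package's dialects; reading them back
#' reproduces the in-memory objects exactly.
#'
#' @param dataset a \code{synthetic_dataset} (or any list with
#'   \code{universe}, \code{network}, \code{labels}).
#' @param out_dir output directory (created if missing).
#' @return Invisibly, the named vector of the five file paths.
#' @export
write_fixture <- function(dataset, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- c(atc = file.path(out_dir, "atc.tsv"),
             dti = file.path(out_dir, "dti.tsv"),
             se = file.path(out_dir, "se.tsv"),
             ddi = file.path(out_dir, "ddi.tsv"),
             labels = file.path(out_dir, "labels.tsv"))
  write_universe(dataset$universe, paths["atc"], paths["dti"], paths["se"])
  write_ddi(dataset$network, paths["ddi"])
  write_labels(dataset$labels, paths["labels"])
  invisible(paths)
}

#' Read a fixture directory written by [write_fixture()]
#'
#' @param dir directory containing the five standard TSVs.
#' @return List with \code{universe}, \code{network}, \code{labels}.
#' @export
read_fixture <- function(dir) {
  universe <- read_universe(file.path(dir, "atc.tsv"),
                            file.path(dir, "dti.tsv"),
                            file.path(dir, "se.tsv"))
  network <- read_ddi(file.path(dir, "ddi.tsv"), universe)
  labels <- read_labels(file.path(dir, "labels.tsv"), universe)
  list(universe = universe, network = network, labels = labels)
}
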