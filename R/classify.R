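# Pair-level featurization and probabilistic scoring.
#
# A pair is featurized by the elementwise sum of its members' drug-level
# vectors, which is symmetric in the two drugs and reflects their joint
# (synergistic) profile. Each channel gets its own binary logistic model;
# the posterior probability of the positive class is the channel's
# confidence score.

#' Symmetric pair feature
#'
#' @param f_i,f_j numeric drug feature vectors of equal length.
#' @return Their elementwise sum (symmetric in the two drugs).
#' @export
pair_feature <- function(f_i, f_j) {
  if (length(f_i) != length(f_j)) {
    stop("pair_feature: drug feature vectors have different dimensions (",
         length(f_i), " vs ", length(f_j), ")")
  }
  as.numeric(f_i) + as.numeric(f_j)
}

# Vectorized pair featurization: rows ia/ib index the drug feature matrix.
pair_feature_rows <- function(features, ia, ib) {
  features[ia, , drop = FALSE] + features[ib, , drop = FALSE]
}

#' Fit a logistic (binomial) scorer on labelled pair instances
#'
#' Maximizes the binomial log-likelihood of the linear logit
#' \eqn{w^T f + b}, with an optional weak L2 (ridge) penalty on \eqn{w}
#' (never on the intercept) for numerical stability on collinear or
#' separable pair features. \code{lambda = 0} gives the plain maximum
#' likelihood fit via [stats::glm()]; \code{lambda > 0} uses a penalized
#' Newton (IRLS) solver. The fit is deterministic given its inputs.
#'
#' @param x numeric matrix of pair feature vectors (instances in rows).
#' @param y binary labels (0/1), one per row of \code{x}.
#' @param lambda L2 penalty strength on the weights (default \code{1e-4};
#'   set to 0 for the unpenalized MLE).
#' @param channel optional channel tag carried in the model.
#' @param max_iter,tol Newton iteration controls.
#' @return An object of class \code{combo_classifier} with elements
#'   \code{weights}, \code{intercept}, \code{channel}, \code{lambda},
#'   \code{converged}, \code{iterations}.
#' @export
train_logistic <- function(x, y, lambda = 1e-4, channel = NULL,
                           max_iter = 100L, tol = 1e-10) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  stopifnot(nrow(x) == length(y), all(y %in% c(0, 1)))
  if (all(y == 1)) stop("training set has no negative instances")
  if (all(y == 0)) stop("training set has no positive instances")
  if (lambda == 0) {
    if (ncol(x) == 0L || all(apply(x, 2L, function(col) all(col == col[1L])))) {
      # intercept-only model: closed-form Bernoulli MLE
      p <- mean(y)
      fit_w <- rep(0, ncol(x))
      b <- stats::qlogis(p)
      conv <- TRUE
      iters <- 0L
    } else {
      fit <- suppressWarnings(stats::glm.fit(cbind(1, x), y,
                                             family = stats::binomial()))
      coefs <- fit$coefficients
      coefs[is.na(coefs)] <- 0
      b <- coefs[1L]
      fit_w <- coefs[-1L]
      conv <- fit$converged
      iters <- fit$iter
      if (!conv) {
        warning("logistic fit did not converge after ", iters, " iterations")
      }
    }
  } else {
    res <- irls_ridge_logistic(x, y, lambda, max_iter, tol)
    fit_w <- res$w
    b <- res$b
    conv <- res$converged
    iters <- res$iterations
    if (!conv) {
      warning("penalized logistic fit did not converge after ", iters, " iterations")
    }
  }
  structure(
    list(weights = unname(fit_w), intercept = unname(b), channel = channel,
         lambda = lambda, converged = conv, iterations = iters),
    class = "combo_classifier"
  )
}

# Newton/IRLS for the ridge-penalized binomial log-likelihood:
#   maximize sum_i [y_i eta_i - log(1 + e^{eta_i})] - lambda/2 ||w||^2,
# eta = X w + b, intercept unpenalized.
irls_ridge_logistic <- function(x, y, lambda, max_iter, tol) {
  n <- nrow(x)
  d <- ncol(x)
  beta <- rep(0, d + 1L)               # (b, w)
  xx <- cbind(1, x)
  pen <- diag(c(0, rep(lambda, d)), d + 1L)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    eta <- drop(xx %*% beta)
    p <- stats::plogis(eta)
    wgt <- pmax(p * (1 - p), 1e-10)
    grad <- drop(crossprod(xx, y - p)) - drop(pen %*% beta)
    hess <- crossprod(xx * wgt, xx) + pen
    step <- solve(hess, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) {
      converged <- TRUE
      break
    }
  }
  list(b = beta[1L], w = beta[-1L], converged = converged, iterations = it)
}

#' @export
print.combo_classifier <- function(x, ...) {
  cat(sprintf("Logistic pair scorer%s: %d features, lambda = %g\n",
              if (!is.null(x$channel)) paste0(" [", x$channel, "]") else "",
              length(x$weights), x$lambda))
  invisible(x)
}

#' Posterior probability scores for pair instances
#'
#' \eqn{P(\mathrm{positive} \mid f) = 1 / (1 + e^{-(w^T f + b)})}.
#'
#' @param model a \code{combo_classifier}.
#' @param x matrix of pair feature vectors.
#' @return Numeric vector of probabilities in \eqn{(0,1)}.
#' @export
score_pairs <- function(model, x) {
  x <- as.matrix(x)
  if (ncol(x) != length(model$weights)) {
    stop("score_pairs: feature dimension (", ncol(x),
         ") does not match model (", length(model$weights), ")")
  }
  eta <- drop(x %*% model$weights) + model$intercept
  stats::plogis(eta)
}

#' ATC similarity entries as a confidence channel
#'
#' The Tanimoto similarity of a pair's first-level ATC sets already lives
#' in \eqn{[0,1]} and is used directly as that pair's ATC-channel score
#' (the decision value of the simplest similarity-based classifier).
#'
#' @param sim similarity matrix from [atc_similarity()].
#' @param pairs two-column matrix of drug-id pairs.
#' @return Numeric score vector, one per pair.
#' @export
similarity_as_score <- function(sim, pairs) {
  pairs <- as.matrix(pairs)
  if (!all(pairs %in% rownames(sim))) {
    stop("similarity_as_score: pair references a drug outside the similarity matrix")
  }
  sim[cbind(match(pairs[, 1L], rownames(sim)), match(pairs[, 2L], colnames(sim)))]
}
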