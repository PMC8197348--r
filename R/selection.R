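#' Two-sample Student's t-test p-values per feature
#'
#' Two-sided pooled-variance (classical Student) t-test of each feature
#' between the two CBF groups.  A feature with zero variance in both
#' groups is assigned p = 1 by convention, with a warning.
#'
#' @param X numeric matrix, instances x features (column names required).
#' @param y binary group labels (0/1), length `nrow(X)`.
#' @return named numeric vector of p-values.
#' @export
ttestPvalues <- function(X, y) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (length(unique(y)) < 2L || min(table(y)) < 2L)
    stop("need at least 2 samples per class", call. = FALSE)
  apply(X, 2, function(col) {
    a <- col[y == 0]
    b <- col[y == 1]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      warning("feature with zero variance in both groups; p = 1")
      return(1)
    }
    stats::t.test(a, b, var.equal = TRUE)$p.value
  })
}

#' Neighborhood component analysis feature ranking
#'
#' Diagonal NCA for feature selection: one nonnegative weight per feature
#' is learned by maximizing the expected leave-one-out soft classification
#' accuracy under a stochastic nearest-neighbor rule with the weighted
#' Manhattan metric `d_w(x_i, x_j) = sum_l w_l^2 |x_il - x_jl|`, minus an
#' l2 penalty `lambda * sum(w^2)`.  Features are z-scored internally;
#' weights are initialized at 1 and fitted by adaptive-step gradient
#' ascent, so the result is deterministic for a given input.  Large
#' `lambda` shrinks all weights toward zero.
#'
#' @param X numeric matrix, instances x features, with column names.
#' @param y binary labels (0/1).
#' @param lambda regularization; default `1 / nrow(X)`.
#' @param maxit maximum gradient-ascent iterations.
#' @param tol stop when the objective improves by less than this.
#' @return list with `weights` (squared fitted weights, one per feature),
#'   `ranking` (feature names by descending weight) and `objective` (the
#'   final penalized objective).
#' @export
ncaRank <- function(X, y, lambda = NULL, maxit = 150, tol = 1e-7) {
  X <- as.matrix(X)
  y <- as.integer(y)
  n <- nrow(X)
  d <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(d))
  if (length(unique(y)) < 2L)
    stop("single-class input: NCA needs both groups", call. = FALSE)
  if (is.null(lambda)) lambda <- 1 / n
  # standardize
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")

  # cache per-feature absolute-difference matrices (n x n each)
  D <- lapply(seq_len(d), function(l) abs(outer(Xs[, l], Xs[, l], "-")))
  same <- outer(y, y, "==")
  diag(same) <- FALSE

  objective <- function(w) {
    dist <- Reduce(`+`, Map(function(Dl, wl) wl^2 * Dl, D, as.list(w)))
    diag(dist) <- Inf
    K <- exp(-(dist - apply(dist, 1, min)))   # row-stabilized kernel
    diag(K) <- 0
    P <- K / rowSums(K)
    pi <- rowSums(P * same)
    list(F = mean(pi) - lambda * sum(w^2), P = P, pi = pi)
  }
  gradient <- function(w, P, pi) {
    g <- numeric(d)
    for (l in seq_len(d)) {
      Dl <- D[[l]]
      expect <- rowSums(P * Dl)               # E_k[p_ik D_l(i,k)]
      inClass <- rowSums(P * same * Dl)
      g[l] <- 2 * w[l] * mean(pi * expect - inClass) - 2 * lambda * w[l]
    }
    g
  }

  w <- rep(1, d)
  ob <- objective(w)
  step <- 0.5
  for (it in seq_len(maxit)) {
    g <- gradient(w, ob$P, ob$pi)
    wNew <- w + step * g
    obNew <- objective(wNew)
    if (obNew$F > ob$F) {
      improved <- obNew$F - ob$F
      w <- wNew
      ob <- obNew
      step <- step * 1.1
      if (improved < tol) break
    } else {
      step <- step / 2
      if (step < 1e-8) break
    }
  }
  weights <- stats::setNames(w^2, colnames(X))
  list(weights = weights,
       ranking = names(sort(weights, decreasing = TRUE)),
       objective = ob$F)
}

#' Select the top-ranked significant features
#'
#' Significance (p below `alpha`) is a hard filter: features at or above
#' it are discarded regardless of their NCA rank.  The survivors are
#' ordered by the NCA ranking and the top `K` kept.
#'
#' @param ranking character vector of feature names, best first (e.g.,
#'   `ncaRank(...)$ranking`).
#' @param pValues named numeric p-values covering every ranked feature.
#' @param K number of features to keep.
#' @param alpha significance level.
#' @return character vector of up to `K` selected feature names, in rank
#'   order; errors if no feature is significant.
#' @export
selectFeatures <- function(ranking, pValues, K = 10, alpha = 0.05) {
  if (!all(ranking %in% names(pValues)))
    stop("every ranked feature needs a p-value", call. = FALSE)
  significant <- ranking[pValues[ranking] < alpha]
  if (!length(significant))
    stop("no feature is significant at the chosen level; cannot select",
         call. = FALSE)
  utils::head(significant, K)
}
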