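#' The five reference classifier specifications
#'
#' Returns the pinned hyperparameter sets used throughout the pipeline:
#' \describe{
#'   \item{LR}{binomial generalized linear model (logistic regression).}
#'   \item{SVM}{polynomial kernel of degree 3, box constraint (cost) 1,
#'     automatic kernel scale `sqrt(d)` on z-scored features (implemented
#'     as kernel coefficient `gamma = 1/d`), Platt-calibrated scores.}
#'   \item{KNN}{k = 9 neighbors, Euclidean distance, squared-inverse
#'     distance weights with a 1e-12 floor on zero distances.}
#'   \item{RF}{random-subspace ensemble of 30 decision trees, each grown
#'     on a random feature subset of size `ceiling(sqrt(d))`.}
#'   \item{MLP}{multilayer perceptron with one hidden layer of 10 units,
#'     trained by gradient-based backpropagation.}
#' }
#'
#' @return named list of specification lists (`kind` plus
#'   hyperparameters).
#' @export
defaultClassifierSpecs <- function() {
  list(
    LR  = list(kind = "LR"),
    SVM = list(kind = "SVM", degree = 3, cost = 1, coef0 = 1),
    KNN = list(kind = "KNN", k = 9),
    RF  = list(kind = "RF", nTrees = 30),
    MLP = list(kind = "MLP", hidden = 10, maxit = 300, decay = 1e-4))
}

.zscoreFit <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1   # constant-feature guard
  list(center = ctr, scale = scl)
}

.zscoreApply <- function(X, ctr, scl) {
  sweep(sweep(X, 2, ctr), 2, scl, "/")
}

#' Train one classifier
#'
#' Fits the requested classifier on a feature matrix after z-scoring with
#' training-set statistics (stored in the returned object; scoring always
#' reuses them).  Training is deterministic for a fixed seed.
#'
#' @param spec one element of [defaultClassifierSpecs()] (or a compatible
#'   list with a `kind` field).
#' @param X numeric training matrix, instances x features, with column
#'   names.
#' @param y binary labels (0/1).
#' @param seed seed for the stochastic learners (RF subspaces, MLP
#'   initialization, SVM score calibration).
#' @return a [TrainedClassifier-class].
#' @export
trainClassifier <- function(spec, X, y, seed = 1L) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  y <- as.integer(y)
  if (length(unique(y)) < 2L)
    stop("training data contain a single class", call. = FALSE)
  if (!all(is.finite(X)))
    stop("features must be finite", call. = FALSE)
  z <- .zscoreFit(X)
  Xs <- .zscoreApply(X, z$center, z$scale)
  kind <- spec$kind
  fit <- .withSeed(seed, switch(kind,
    LR = {
      beta <- suppressWarnings(
        stats::glm.fit(cbind(`(Intercept)` = 1, Xs), y,
                       family = stats::binomial()))$coefficients
      beta[!is.finite(beta)] <- 0   # aliased (collinear) columns
      beta
    },
    SVM = e1071::svm(x = Xs, y = factor(y, levels = c(0, 1)),
                     kernel = "polynomial", degree = spec$degree,
                     coef0 = spec$coef0, gamma = 1 / ncol(Xs),
                     cost = spec$cost, probability = TRUE, scale = FALSE),
    KNN = list(X = Xs, y = y, k = spec$k),
    RF = {
      m <- ceiling(sqrt(ncol(Xs)))
      df <- data.frame(Xs, check.names = TRUE)
      cn <- colnames(df)
      lapply(seq_len(spec$nTrees), function(b) {
        feats <- sample(ncol(Xs), m)
        form <- stats::as.formula(
          paste(".y ~", paste(cn[feats], collapse = " + ")))
        dfb <- df
        dfb$.y <- factor(y, levels = c(0, 1))
        rpart::rpart(form, data = dfb, method = "class",
                     control = rpart::rpart.control(minsplit = 10,
                                                    cp = 0.005))
      })
    },
    MLP = nnet::nnet(x = Xs, y = y, size = spec$hidden, entropy = TRUE,
                     decay = spec$decay, maxit = spec$maxit,
                     trace = FALSE, MaxNWts = 5000),
    stop(sprintf("unknown classifier kind '%s'", kind), call. = FALSE)))
  new("TrainedClassifier", kind = kind,
      params = spec[setdiff(names(spec), "kind")], fit = fit,
      center = z$center, scale = z$scale, featureNames = colnames(X),
      seed = as.integer(seed))
}

#' @rdname predictScores
setMethod("predictScores", "TrainedClassifier", function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(model@featureNames))
    stop(sprintf("model expects %d features, got %d",
                 length(model@featureNames), ncol(X)), call. = FALSE)
  if (!is.null(colnames(X)) &&
      !identical(colnames(X), model@featureNames))
    X <- X[, model@featureNames, drop = FALSE]
  Xs <- .zscoreApply(X, model@center, model@scale)
  scores <- switch(model@kind,
    LR = as.numeric(stats::plogis(cbind(1, Xs) %*% model@fit)),
    SVM = {
      pr <- predict(model@fit, Xs, probability = TRUE)
      attr(pr, "probabilities")[, "1"]
    },
    KNN = .knnScores(model@fit, Xs),
    RF = {
      df <- data.frame(Xs, check.names = TRUE)
      probs <- vapply(model@fit, function(tree)
        predict(tree, df, type = "prob")[, "1"],
        numeric(nrow(Xs)))
      if (nrow(Xs) == 1L) mean(probs) else rowMeans(probs)
    },
    MLP = as.numeric(predict(model@fit, Xs, type = "raw")))
  pmin(pmax(as.numeric(scores), 0), 1)
})

# squared-inverse distance-weighted KNN class-1 score
.knnScores <- function(fit, Xq) {
  vapply(seq_len(nrow(Xq)), function(i) {
    d2 <- colSums((t(fit$X) - Xq[i, ])^2)
    idx <- order(d2)[seq_len(fit$k)]
    w <- 1 / pmax(d2[idx], .EPS)
    sum(w[fit$y[idx] == 1L]) / sum(w)
  }, numeric(1))
}
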