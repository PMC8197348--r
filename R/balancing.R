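#' SMOTE oversampling of the minority class
#'
#' Equalizes the class counts of a training table by synthesizing new
#' minority-class instances along the segments between randomly chosen
#' minority points and their k nearest minority neighbors:
#' `x_new = x + u * (neighbor - x)` with `u ~ Uniform(0, 1)`.  Majority
#' rows and all original rows are preserved verbatim; synthetic rows are
#' appended and flagged.  Intended to be applied inside each training
#' fold only, never to held-out data.
#'
#' @param X numeric matrix, instances x features.
#' @param y binary labels (0/1) of length `nrow(X)`.
#' @param k number of nearest minority neighbors (default 5); must be
#'   smaller than the minority count.
#' @param seed optional seed for reproducible augmentation.
#' @return list with `X` (original rows first, then synthetic), `y`, and
#'   `synthetic` (logical provenance flag per row).
#' @examples
#' X <- rbind(matrix(rnorm(40), 20), matrix(rnorm(10, 3), 5))
#' y <- rep(c(0, 1), c(20, 5))
#' aug <- smoteAugment(X, y, k = 2, seed = 1)
#' table(aug$y)
#' @export
smoteAugment <- function(X, y, k = 5, seed = NULL) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (nrow(X) != length(y))
    stop("'X' and 'y' sizes disagree", call. = FALSE)
  counts <- table(factor(y, levels = c(0, 1)))
  if (any(counts == 0))
    stop("both classes must be present", call. = FALSE)
  minority <- as.integer(names(which.min(counts)))
  nMin <- min(counts)
  nNeeded <- max(counts) - nMin
  if (nNeeded == 0)
    return(list(X = X, y = y, synthetic = rep(FALSE, nrow(X))))
  if (nMin <= k)
    stop(sprintf(
      "minority class has %d instances but k = %d; decrease 'k' below the minority count",
      nMin, k), call. = FALSE)
  minIdx <- which(y == minority)
  Xm <- X[minIdx, , drop = FALSE]
  # k nearest minority neighbors of each minority point (Euclidean)
  dm <- as.matrix(stats::dist(Xm))
  diag(dm) <- Inf
  nn <- matrix(apply(dm, 1, function(row) order(row)[seq_len(k)]),
               nrow = nMin, ncol = k, byrow = TRUE)
  synth <- .withSeed(seed, {
    base <- sample(nMin, nNeeded, replace = TRUE)
    pick <- sample.int(k, nNeeded, replace = TRUE)
    u <- stats::runif(nNeeded)
    out <- matrix(NA_real_, nNeeded, ncol(X))
    for (i in seq_len(nNeeded)) {
      xi <- Xm[base[i], ]
      xj <- Xm[nn[base[i], pick[i]], ]
      out[i, ] <- xi + u[i] * (xj - xi)
    }
    out
  })
  colnames(synth) <- colnames(X)
  list(X = rbind(X, synth),
       y = c(y, rep(minority, nNeeded)),
       synthetic = c(rep(FALSE, nrow(X)), rep(TRUE, nNeeded)))
}
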