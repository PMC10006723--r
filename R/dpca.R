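#' Dihedral principal component analysis
#'
#' Fits a PCA to a sin/cos dihedral feature matrix (see
#' \code{\link{encode_sincos}}): the mean-centred sample covariance
#' (1/(N-1) normalisation) is eigendecomposed and components are ordered by
#' descending eigenvalue. Eigenvector signs are fixed so that each vector's
#' largest-magnitude entry is positive, making projections, landscapes and
#' cluster labels reproducible run to run.
#'
#' @param features Numeric frames x p matrix, typically from
#'   \code{\link{encode_sincos}}.
#' @return Object of class \code{"dpca"}: list with \code{mean} (length p),
#'   \code{values} (eigenvalues, descending), \code{vectors} (p x p
#'   orthonormal), \code{var_frac} (variance fractions) and \code{n}.
#' @examples
#' f <- matrix(c(1, 0, -1, 0), 2, byrow = TRUE)
#' m <- dpca(f)
#' m$values   # 2, 0
#' @export
dpca <- function(features) {
  features <- as.matrix(features)
  if (nrow(features) < 2L) stop("need at least 2 frames to fit a PCA")
  if (any(!is.finite(features))) stop("non-finite values in feature matrix")
  mu <- colMeans(features)
  cv <- stats::cov(features)
  eg <- eigen(cv, symmetric = TRUE)
  vals <- pmax(eg$values, 0)  # clip tiny negative round-off
  vecs <- eg$vectors
  # deterministic sign: largest-|entry| of each eigenvector made positive
  for (j in seq_len(ncol(vecs))) {
    i <- which.max(abs(vecs[, j]))
    if (vecs[i, j] < 0) vecs[, j] <- -vecs[, j]
  }
  tot <- sum(vals)
  structure(
    list(mean = mu, values = vals, vectors = vecs,
         var_frac = if (tot > 0) vals / tot else rep(0, length(vals)),
         n = nrow(features)),
    class = "dpca"
  )
}

#' @export
print.dpca <- function(x, ...) {
  cat(sprintf("dPCA model: %d features, fitted on %d frames\n",
              length(x$mean), x$n))
  k <- min(5L, length(x$values))
  cat("  leading variance fractions:",
      paste(sprintf("%.3f", x$var_frac[seq_len(k)]), collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.dpca <- function(object, ...) {
  d <- data.frame(component = seq_along(object$values),
                  eigenvalue = object$values,
                  var_frac = object$var_frac,
                  cum_var = cumsum(object$var_frac))
  class(d) <- c("summary.dpca", "data.frame")
  d
}

#' Project frames onto leading principal components
#'
#' @param object A \code{"dpca"} model.
#' @param features Frames x p matrix in the same feature space the model was
#'   fitted on; defaults are not kept, so pass the data explicitly.
#' @param d Number of leading components to retain (>= 1).
#' @param ... Unused.
#' @return Frames x d matrix of PC coordinates, columns \code{PC1..PCd},
#'   with the model's variance fractions attached as attribute
#'   \code{"var_frac"}.
#' @export
predict.dpca <- function(object, features, d = 2L, ...) {
  features <- as.matrix(features)
  p <- length(object$mean)
  if (ncol(features) != p) {
    stop("feature dimension ", ncol(features), " does not match model (", p, ")")
  }
  d <- as.integer(d)
  if (d < 1L || d > p) stop("d must lie in 1..", p)
  pcs <- sweep(features, 2L, object$mean) %*% object$vectors[, seq_len(d),
                                                             drop = FALSE]
  colnames(pcs) <- paste0("PC", seq_len(d))
  attr(pcs, "var_frac") <- object$var_frac[seq_len(d)]
  pcs
}

#' @rdname predict.dpca
#' @export
project_dpca <- function(object, features, d = 2L) {
  predict(object, features, d = d)
}
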