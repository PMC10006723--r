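#' Boltzmann constant times temperature, kcal/mol
#'
#' kT at the default simulation temperature of 300 K with
#' kB = 0.0019872 kcal mol^-1 K^-1, giving 0.59616 kcal/mol.
#'
#' @param temperature_K Temperature in kelvin.
#' @return kT in kcal/mol.
#' @export
kT_kcal <- function(temperature_K = 300) 0.0019872 * temperature_K

#' Construct a boost-energy series
#'
#' Per-frame accelerated-MD boost energies, aligned with the recorded
#' trajectory frames. The boost potential is non-negative by construction.
#'
#' @param dV_total Per-frame total boost energy, kcal/mol (>= 0).
#' @param dV_dihedral Optional per-frame dihedral boost component, kcal/mol.
#' @param stride_steps MD steps between records (metadata).
#' @return Object of class \code{"boost_series"}.
#' @export
boost_series <- function(dV_total, dV_dihedral = NULL, stride_steps = 1000L) {
  dV_total <- as.numeric(dV_total)
  if (length(dV_total) == 0L) stop("boost series has zero frames")
  if (any(!is.finite(dV_total))) stop("non-finite boost energies")
  neg <- which(dV_total < 0)
  if (length(neg) > 0L) {
    stop("negative total boost at frame ", neg[1L],
         " (aMD boost must be non-negative)")
  }
  if (!is.null(dV_dihedral)) {
    dV_dihedral <- as.numeric(dV_dihedral)
    if (length(dV_dihedral) != length(dV_total)) {
      stop("dihedral and total boost lengths differ")
    }
  }
  structure(list(dV_total = dV_total, dV_dihedral = dV_dihedral,
                 stride_steps = as.integer(stride_steps)),
            class = "boost_series")
}

#' @export
print.boost_series <- function(x, ...) {
  cat(sprintf(
    "Boost series: %d frames, mean dV_total = %.3f kcal/mol (stride %d)\n",
    length(x$dV_total), mean(x$dV_total), x$stride_steps))
  invisible(x)
}

#' Read a per-frame boost-energy log
#'
#' Two dialects. \code{"canonical"}: whitespace-separated columns
#' \code{frame dV_dihedral dV_total}, comment lines starting with \code{#}.
#' \code{"amd"}: tolerant of Amber-style amd.log files — any line that is not
#' fully numeric is skipped, and the last two numeric columns of each data
#' line are taken as (dihedral, total) boost.
#'
#' @param path File path.
#' @param dialect \code{"canonical"} (default) or \code{"amd"}.
#' @param stride_steps Stride metadata.
#' @return A \code{"boost_series"} with frame count set from the data lines.
#' @export
read_boost_log <- function(path, dialect = c("canonical", "amd"),
                           stride_steps = 1000L) {
  dialect <- match.arg(dialect)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  rows <- lapply(lines, function(ln) {
    suppressWarnings(as.numeric(strsplit(ln, "[[:space:]]+")[[1]]))
  })
  numeric_ok <- vapply(rows, function(r) length(r) >= 2L && !anyNA(r),
                       logical(1))
  if (dialect == "canonical") {
    if (!all(numeric_ok)) {
      stop("non-numeric data line ", which(!numeric_ok)[1L], " in ", path)
    }
  } else {
    rows <- rows[numeric_ok]
  }
  if (length(rows) == 0L) stop("no data lines in boost log ", path)
  dih <- vapply(rows, function(r) r[length(r) - 1L], numeric(1))
  tot <- vapply(rows, function(r) r[length(r)], numeric(1))
  bad <- which(tot < 0)
  if (length(bad) > 0L) {
    stop("negative total boost on data line ", bad[1L], " of ", path)
  }
  boost_series(tot, dih, stride_steps = stride_steps)
}

#' Statistical reweighting of aMD frames
#'
#' Turns per-frame boost energies dV into normalised ensemble weights that
#' undo the bias of the boost potential. Two estimators:
#' \describe{
#'   \item{exponential}{w_i proportional to exp(dV_i / kT), the exact
#'     canonical reweighting factor; computed with a max-shift (log-sum-exp)
#'     so large boosts cannot overflow. Exact but noisy when dV fluctuates
#'     by many kT.}
#'   \item{maclaurin}{w_i proportional to the Maclaurin series of the
#'     exponential truncated at order k,
#'     \eqn{\sum_{j=0}^{k} (dV_i/kT)^j / j!}. The standard noise-robust
#'     approximation for aMD reweighting; default order 2.}
#' }
#'
#' @param boost A \code{"boost_series"} (or numeric vector of dV, kcal/mol).
#' @param method \code{"maclaurin"} (default) or \code{"exponential"}.
#' @param k_order Truncation order for the Maclaurin estimator (>= 1).
#' @param kT Thermal energy in kcal/mol; default 300 K.
#' @param component Which boost feeds the weights under dual boost:
#'   \code{"total"} (default, both terms biased) or \code{"dihedral"}.
#' @return Object of class \code{"amd_weights"}: list with \code{w}
#'   (non-negative, sums to 1), \code{method} and \code{kT}.
#' @examples
#' compute_weights(boost_series(c(0.59616, 0)), method = "exponential",
#'                 kT = 0.59616)$w
#' @export
compute_weights <- function(boost, method = c("maclaurin", "exponential"),
                            k_order = 2L, kT = kT_kcal(),
                            component = c("total", "dihedral")) {
  method <- match.arg(method)
  component <- match.arg(component)
  if (inherits(boost, "boost_series")) {
    dV <- if (component == "dihedral") {
      if (is.null(boost$dV_dihedral)) stop("no dihedral boost recorded")
      boost$dV_dihedral
    } else boost$dV_total
  } else {
    dV <- as.numeric(boost)
  }
  if (length(dV) < 1L) stop("need at least one frame")
  if (!is.numeric(kT) || kT <= 0) stop("kT must be positive")
  x <- dV / kT
  if (method == "exponential") {
    lw <- x - max(x)
    w <- exp(lw)
  } else {
    k_order <- as.integer(k_order)
    if (k_order < 1L) stop("k_order must be >= 1")
    w <- rep(1, length(x))
    term <- rep(1, length(x))
    for (j in seq_len(k_order)) {
      term <- term * x / j
      w <- w + term
    }
  }
  w <- w / sum(w)
  structure(list(w = w, method = if (method == "maclaurin")
                   sprintf("maclaurin-%d", k_order) else "exponential",
                 kT = kT),
            class = "amd_weights")
}

#' @export
print.amd_weights <- function(x, ...) {
  cat(sprintf("aMD weights: %d frames, method %s, kT = %.5f kcal/mol\n",
              length(x$w), x$method, x$kT))
  cat(sprintf("  effective sample size: %.0f\n", 1 / sum(x$w^2)))
  invisible(x)
}

# Shared d-dimensional histogram: equal-width bins spanning [min, max] per
# dimension, last bin right-closed so the maximum lands in the final bin.
# Returns list(edges, mids, array of per-bin sums of `weights`).
.nd_histogram <- function(coords, bins, weights = NULL) {
  coords <- as.matrix(coords)
  d <- ncol(coords)
  n <- nrow(coords)
  if (n < 1L) stop("no frames to histogram")
  bins <- rep_len(as.integer(bins), d)
  if (any(bins < 2L)) stop("need at least 2 bins per dimension")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n) stop("weights length does not match frames")
  edges <- vector("list", d)
  idx <- matrix(0L, n, d)
  for (j in seq_len(d)) {
    lo <- min(coords[, j]); hi <- max(coords[, j])
    if (lo == hi) { lo <- lo - 0.5; hi <- hi + 0.5 }  # degenerate spread
    edges[[j]] <- seq(lo, hi, length.out = bins[j] + 1L)
    idx[, j] <- findInterval(coords[, j], edges[[j]],
                             rightmost.closed = TRUE, all.inside = TRUE)
  }
  # linear index into the d-dimensional array (column-major)
  lin <- idx[, 1L]
  mult <- 1L
  for (j in seq_len(d - 1L)) {
    mult <- mult * bins[j]
    lin <- lin + (idx[, j + 1L] - 1L) * mult
  }
  acc <- numeric(prod(bins))
  sums <- rowsum(weights, group = lin)
  acc[as.integer(rownames(sums))] <- sums[, 1L]
  list(edges = edges,
       mids = lapply(edges, function(e) (e[-1L] + e[-length(e)]) / 2),
       values = array(acc, dim = bins))
}

#' Weighted probability density over PC coordinates
#'
#' d-dimensional weighted histogram over equal-width bins spanning the data
#' range in each dimension (the last bin is right-closed so maximal frames
#' are counted). Bin mass is the sum of frame weights; total mass 1.
#'
#' @param pcs Frames x >=d matrix of PC coordinates (leading d are used).
#' @param weights An \code{"amd_weights"} object or numeric weight vector;
#'   \code{NULL} gives uniform weights.
#' @param bins Bins per dimension (scalar or length-d); default 100.
#' @param d Number of dimensions; default 2.
#' @return Object of class \code{"density_grid"}: list with \code{edges},
#'   \code{mids}, \code{P} (d-dim array summing to 1) and \code{d}.
#' @export
weighted_histogram <- function(pcs, weights = NULL, bins = 100L, d = 2L) {
  pcs <- as.matrix(pcs)
  d <- as.integer(d)
  if (d > ncol(pcs)) stop("d exceeds available PC dimensions")
  w <- if (inherits(weights, "amd_weights")) weights$w else weights
  if (!is.null(w) && length(w) != nrow(pcs)) {
    stop("weights and PC trajectory have different frame counts")
  }
  h <- .nd_histogram(pcs[, seq_len(d), drop = FALSE], bins, w)
  P <- h$values / sum(h$values)
  structure(list(edges = h$edges, mids = h$mids, P = P, d = d),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf("Density grid: %s bins, %d occupied, total mass %.6f\n",
              paste(dim(x$P), collapse = " x "), sum(x$P > 0), sum(x$P)))
  invisible(x)
}

#' Free-energy landscape from a probability density
#'
#' Converts a (possibly reweighted) probability density P over PC
#' coordinates into a free-energy surface mu = -kT ln P, shifted so the
#' minimum over occupied bins is 0. Empty bins are NA in \code{mu}; for
#' plotting, \code{mu_plot} fills them with max(mu) + kT so they render as
#' a uniform high-energy background.
#'
#' @param density A \code{"density_grid"}.
#' @param kT Thermal energy, kcal/mol.
#' @return Object of class \code{"fel_grid"}: list with \code{edges},
#'   \code{mids}, \code{mu} (NA where empty), \code{mu_plot}, \code{kT},
#'   \code{d}.
#' @examples
#' g <- weighted_histogram(matrix(c(0, 0, 0, 1, 1, 0), 3, 2), bins = 2)
#' fel_from_density(g, kT = 0.59616)$mu
#' @export
fel_from_density <- function(density, kT = kT_kcal()) {
  stopifnot(inherits(density, "density_grid"))
  if (kT <= 0) stop("kT must be positive")
  P <- density$P
  occ <- P > 0
  if (!any(occ)) stop("density grid is entirely empty")
  mu <- array(NA_real_, dim = dim(P))
  mu[occ] <- -kT * log(P[occ])
  mu <- mu - min(mu[occ])
  mu_plot <- mu
  mu_plot[!occ] <- max(mu[occ]) + kT
  structure(list(edges = density$edges, mids = density$mids, mu = mu,
                 mu_plot = mu_plot, kT = kT, d = density$d),
            class = "fel_grid")
}

#' @export
print.fel_grid <- function(x, ...) {
  occ <- !is.na(x$mu)
  cat(sprintf(
    "Free-energy landscape: %s bins, mu in [0, %.3f] kcal/mol (kT = %.5f)\n",
    paste(dim(x$mu), collapse = " x "), max(x$mu[occ]), x$kT))
  invisible(x)
}

#' Plot a 2-D free-energy landscape
#'
#' Filled image of mu over the first two PC dimensions; empty bins render at
#' the uniform high-energy background level.
#'
#' @param x A \code{"fel_grid"} with d = 2.
#' @param xlab,ylab Axis labels.
#' @param ... Passed to \code{\link[graphics]{image}}.
#' @export
plot.fel_grid <- function(x, xlab = "PC1", ylab = "PC2", ...) {
  if (x$d != 2L) stop("plotting implemented for 2-D landscapes")
  cols <- grDevices::hcl.colors(64, "Viridis", rev = TRUE)
  graphics::image(x$mids[[1L]], x$mids[[2L]], x$mu_plot, col = cols,
                  xlab = xlab, ylab = ylab, ...)
  graphics::box()
  invisible(x)
}
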