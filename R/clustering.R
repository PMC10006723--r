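#' Frame-count density map over leading principal components
#'
#' Unweighted d-dimensional histogram of frame counts over the leading d PC
#' coordinates. Counts (not normalised mass) are kept because cluster
#' occupancy bookkeeping is done in frames.
#'
#' @param pcs Frames x >=d matrix of PC coordinates.
#' @param d Dimensions used for clustering, 2..5; default 3.
#' @param bins Bins per dimension; default 24 (a 12-bin default is sensible
#'   at d = 5 to bound grid memory).
#' @param weights Optional frame weights for a reweighted (mass) map;
#'   default NULL keeps raw counts.
#' @return Object of class \code{"density_grid"} whose \code{P} holds counts
#'   (or weighted mass) per bin, plus \code{total} frames.
#' @export
density_map <- function(pcs, d = 3L, bins = 24L, weights = NULL) {
  pcs <- as.matrix(pcs)
  d <- as.integer(d)
  if (!d %in% 2:5) stop("d must be one of 2, 3, 4, 5")
  if (d > ncol(pcs)) stop("d exceeds the available PC dimensions")
  if (nrow(pcs) < 1L) stop("no frames")
  w <- if (inherits(weights, "amd_weights")) weights$w else weights
  h <- .nd_histogram(pcs[, seq_len(d), drop = FALSE], bins, w)
  structure(list(edges = h$edges, mids = h$mids, P = h$values, d = d,
                 total = nrow(pcs)),
            class = "density_grid")
}

# Moore-neighbourhood offsets for a d-dimensional grid: all 3^d - 1
# non-zero offset vectors in {-1, 0, 1}^d.
.moore_offsets <- function(d) {
  g <- as.matrix(expand.grid(rep(list(-1:1), d)))
  g[rowSums(g != 0) > 0, , drop = FALSE]
}

#' Find density peaks on a grid
#'
#' A bin is a peak when its count is >= every count in its full
#' d-dimensional Moore neighbourhood and exceeds
#' \code{threshold_fraction * max(count)}. Plateaus are not double-counted:
#' on ties, a bin qualifies only if it is strictly greater than every tied
#' neighbour with a lower linear (column-major) index, so a flat region
#' yields exactly one peak.
#'
#' @param grid A \code{"density_grid"} (counts or mass).
#' @param threshold_fraction Density threshold as a fraction of the maximum
#'   bin count, in (0, 1); default 0.10.
#' @return Object of class \code{"peak_set"}: data.frame with one row per
#'   peak (rank, linear bin index, per-dimension bin indices, center
#'   coordinates, density), ordered by descending density; may have 0 rows.
#' @export
find_peaks <- function(grid, threshold_fraction = 0.10) {
  stopifnot(inherits(grid, "density_grid"))
  if (threshold_fraction <= 0 || threshold_fraction >= 1) {
    stop("threshold_fraction must lie strictly between 0 and 1")
  }
  P <- grid$P
  dims <- dim(P)
  d <- length(dims)
  if (all(P == 0)) stop("grid has no occupied bins")
  thr <- threshold_fraction * max(P)
  cand <- which(P > thr)
  offs <- .moore_offsets(d)
  sub <- arrayInd(cand, dims)
  keep <- logical(length(cand))
  for (i in seq_along(cand)) {
    ci <- sub[i, ]
    v <- P[cand[i]]
    ok <- TRUE
    for (r in seq_len(nrow(offs))) {
      nb <- ci + offs[r, ]
      if (any(nb < 1L) || any(nb > dims)) next
      nlin <- 1L + sum((nb - 1L) * cumprod(c(1L, dims[-d])))
      nv <- P[nlin]
      if (nv > v || (nv == v && nlin < cand[i])) { ok <- FALSE; break }
    }
    keep[i] <- ok
  }
  lin <- cand[keep]
  ord <- order(P[lin], decreasing = TRUE, method = "radix")
  lin <- lin[ord]
  sub <- arrayInd(lin, dims)
  centers <- matrix(0, nrow = length(lin), ncol = d)
  for (j in seq_len(d)) centers[, j] <- grid$mids[[j]][sub[, j]]
  colnames(centers) <- paste0("PC", seq_len(d))
  out <- data.frame(rank = seq_along(lin), bin = lin, density = P[lin])
  out <- cbind(out, as.data.frame(centers))
  structure(out, class = c("peak_set", "data.frame"),
            d = d, dims = dims, mids = grid$mids)
}

#' Assign frames to density peaks
#'
#' Every frame joins the cluster of the nearest peak (Euclidean distance in
#' the d leading PCs; ties go to the lower-rank, i.e. denser, peak). Cluster
#' occupancy is 100 * frames / total; the representative frame of a cluster
#' is the assigned frame closest to the peak center (ties: lowest index).
#'
#' @param pcs Frames x >=d matrix of PC coordinates.
#' @param peaks A \code{"peak_set"} with at least one peak.
#' @param d Dimensions used for the distance; defaults to the peak set's.
#' @return Object of class \code{"fel_clusters"}: list with
#'   \code{cluster} (per-frame rank), \code{counts}, \code{occupancy}
#'   (percent), \code{representative} (frame index per cluster),
#'   \code{peaks}, \code{total}.
#' @export
assign_frames <- function(pcs, peaks, d = attr(peaks, "d")) {
  stopifnot(inherits(peaks, "peak_set"))
  if (nrow(peaks) == 0L) stop("no clusters above threshold")
  pcs <- as.matrix(pcs)
  d <- as.integer(d)
  if (d > ncol(pcs)) stop("d exceeds the available PC dimensions")
  X <- pcs[, seq_len(d), drop = FALSE]
  C <- as.matrix(peaks[, paste0("PC", seq_len(d)), drop = FALSE])
  K <- nrow(C)
  n <- nrow(X)
  # squared distances frame x peak; K is small so loop over peaks
  d2 <- matrix(0, n, K)
  for (k in seq_len(K)) {
    d2[, k] <- rowSums(sweep(X, 2L, C[k, ])^2)
  }
  # first minimum wins, so distance ties resolve to the lower (denser) rank
  cl <- max.col(-d2, ties.method = "first")
  counts <- tabulate(cl, nbins = K)
  occupancy <- occupancy_percent(counts, n)
  rep_frame <- integer(K)
  for (k in seq_len(K)) {
    idx <- which(cl == k)
    rep_frame[k] <- if (length(idx)) idx[which.min(d2[idx, k])] else NA_integer_
  }
  structure(list(cluster = cl, counts = counts, occupancy = occupancy,
                 representative = rep_frame, peaks = peaks, total = n,
                 d = d),
            class = "fel_clusters")
}

#' Cluster occupancy percentage
#'
#' Exact occupancy bookkeeping: 100 * count / total, e.g. 78,248 frames of
#' 500,000 give 15.6496 percent.
#'
#' @param counts Per-cluster frame counts.
#' @param total Total frame count.
#' @return Numeric vector of percentages.
#' @examples
#' occupancy_percent(78248, 500000)
#' @export
occupancy_percent <- function(counts, total) {
  stopifnot(total > 0, all(counts >= 0))
  100 * counts / total
}

#' @export
print.fel_clusters <- function(x, ...) {
  cat(sprintf("Conformational clusters: %d clusters over %d frames (d = %d)\n",
              length(x$counts), x$total, x$d))
  print(summary(x), row.names = FALSE)
  invisible(x)
}

#' @export
summary.fel_clusters <- function(object, ...) {
  data.frame(cluster = seq_along(object$counts),
             frames = object$counts,
             percent = round(object$occupancy, 4),
             representative = object$representative)
}

#' Cluster membership along the trajectory
#'
#' The per-frame cluster series plus its run-length encoding, the form used
#' to draw cluster-occupancy bars along the simulation time axis.
#'
#' @param assignment A \code{"fel_clusters"} object.
#' @return List with \code{series} (per-frame ranks) and \code{segments}
#'   (data.frame: cluster, start frame, length).
#' @export
cluster_timeline <- function(assignment) {
  stopifnot(inherits(assignment, "fel_clusters"))
  r <- rle(assignment$cluster)
  start <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  list(series = assignment$cluster,
       segments = data.frame(cluster = r$values, start = start,
                             length = r$lengths))
}

#' Plot cluster membership along the trajectory
#'
#' @param x A \code{"fel_clusters"} object.
#' @param ... Passed to \code{\link[graphics]{plot}}.
#' @export
plot.fel_clusters <- function(x, ...) {
  tl <- cluster_timeline(x)
  K <- length(x$counts)
  cols <- grDevices::hcl.colors(max(K, 2L), "Dark 3")
  graphics::plot(NA, xlim = c(0, x$total), ylim = c(0.5, K + 0.5),
                 xlab = "frame", ylab = "cluster", yaxt = "n", ...)
  graphics::axis(2, at = seq_len(K))
  with(tl$segments, graphics::segments(start, cluster, start + length - 1L,
                                       cluster, col = cols[cluster], lwd = 4))
  invisible(x)
}
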