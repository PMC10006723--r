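# union-find with path halving, used by the saddle flood
.uf_find <- function(parent, i) {
  while (parent[i] != i) {
    parent[i] <- parent[parent[i]]
    i <- parent[i]
  }
  i
}

#' Lowest saddle between the two deepest free-energy wells
#'
#' Estimates the barrier separating the two highest-density basins of a
#' free-energy landscape: the minimum over all grid paths (Moore
#' connectivity through occupied bins) of the maximum mu encountered between
#' the two deepest local minima. Computed by a flooding search: occupied
#' bins are added in order of increasing mu and merged with added
#' neighbours; the mu level at which the two wells first connect is the
#' saddle height.
#'
#' @param fel A \code{"fel_grid"}.
#' @param threshold_fraction Density threshold for identifying wells, as in
#'   \code{\link{find_peaks}}.
#' @return Saddle height in kcal/mol, or NA if fewer than two wells exist
#'   or the wells are not connected through occupied bins.
#' @examples
#' g <- structure(list(edges = list(0:3), mids = list(c(0.5, 1.5, 2.5)),
#'                     P = array(c(0.6, 0.1, 0.3)), d = 1L),
#'                class = "density_grid")
#' fel_saddle(fel_from_density(g, kT = 0.59616))
#' @export
fel_saddle <- function(fel, threshold_fraction = 0.10) {
  stopifnot(inherits(fel, "fel_grid"))
  mu <- fel$mu
  dims <- dim(mu)
  if (is.null(dims)) dims <- length(mu)
  d <- length(dims)
  # wells = density peaks: reuse the peak finder on exp(-mu/kT)
  dens <- structure(list(edges = fel$edges, mids = fel$mids,
                         P = array(ifelse(is.na(mu), 0,
                                          exp(-mu / fel$kT)), dim = dims),
                         d = d),
                    class = "density_grid")
  pk <- find_peaks(dens, threshold_fraction = threshold_fraction)
  if (nrow(pk) < 2L) return(NA_real_)
  a <- pk$bin[1L]; b <- pk$bin[2L]
  occ <- which(!is.na(mu))
  ord <- occ[order(mu[occ], method = "radix")]
  parent <- seq_len(prod(dims))
  added <- logical(prod(dims))
  offs <- .moore_offsets(d)
  stride <- cumprod(c(1L, dims[-d]))
  for (lin in ord) {
    added[lin] <- TRUE
    ci <- arrayInd(lin, dims)[1L, ]
    for (r in seq_len(nrow(offs))) {
      nb <- ci + offs[r, ]
      if (any(nb < 1L) || any(nb > dims)) next
      nlin <- 1L + sum((nb - 1L) * stride)
      if (added[nlin]) {
        ra <- .uf_find(parent, lin); rb <- .uf_find(parent, nlin)
        if (ra != rb) parent[rb] <- ra
      }
    }
    if (.uf_find(parent, a) == .uf_find(parent, b)) return(mu[lin])
  }
  NA_real_
}

#' Folding metrics for one peptide run
#'
#' Summarises a clustered trajectory into the quantities used for
#' structure-activity comparison: cluster count, top-1/2/3 occupancies (by
#' occupancy rank), the Shannon entropy of the occupancy distribution in
#' bits, and the lowest saddle separating the two main free-energy wells.
#'
#' @param assignment A \code{"fel_clusters"} object.
#' @param fel The \code{"fel_grid"} from the same trajectory (used for the
#'   saddle estimate); may be NULL to skip it.
#' @param name Peptide name.
#' @param group Group label ("A", "B" or "unknown").
#' @return One-row data.frame of class \code{"folding_metrics"}: name,
#'   group, n_clusters, top1/top2/top3 (percent), entropy_bits, saddle
#'   (kcal/mol, NA when fewer than 2 clusters).
#' @export
folding_metrics <- function(assignment, fel = NULL, name = "", group = "unknown") {
  stopifnot(inherits(assignment, "fel_clusters"))
  occ <- sort(assignment$occupancy, decreasing = TRUE)
  f <- assignment$counts / assignment$total
  f <- f[f > 0]
  entropy <- -sum(f * log2(f))
  saddle <- NA_real_
  if (length(assignment$counts) >= 2L && !is.null(fel)) {
    saddle <- fel_saddle(fel)
  }
  top <- function(k) if (length(occ) >= k) occ[k] else NA_real_
  structure(data.frame(name = name, group = group,
                       n_clusters = length(assignment$counts),
                       top1 = top(1L), top2 = top(2L), top3 = top(3L),
                       entropy_bits = entropy, saddle = saddle,
                       stringsAsFactors = FALSE),
            class = c("folding_metrics", "data.frame"))
}

#' Build a structure-activity comparison report
#'
#' Joins per-peptide folding metrics into one table and summarises each
#' group (mean/min/max of every metric). No statistical test is performed:
#' the comparison is descriptive, optionally juxtaposed with externally
#' measured bioactivity annotations (e.g. MIC values) that are carried
#' through untouched.
#'
#' @param metrics List of \code{\link{folding_metrics}} rows (or one
#'   data.frame of them).
#' @param annotations Optional data.frame keyed by \code{name}, merged onto
#'   the peptide table as-is.
#' @return Object of class \code{"sar_report"}: list with \code{peptides}
#'   (one row per peptide) and \code{groups} (per-group summaries).
#' @export
build_report <- function(metrics, annotations = NULL) {
  df <- if (is.data.frame(metrics)) as.data.frame(metrics)
        else do.call(rbind, lapply(metrics, as.data.frame))
  if (nrow(df) == 0L) stop("no metrics supplied")
  if (anyDuplicated(df$name)) {
    stop("duplicate peptide names: ",
         paste(unique(df$name[duplicated(df$name)]), collapse = ", "))
  }
  if (!is.null(annotations)) {
    df <- merge(df, annotations, by = "name", all.x = TRUE, sort = FALSE)
  }
  num <- c("n_clusters", "top1", "top2", "top3", "entropy_bits", "saddle")
  groups <- do.call(rbind, lapply(split(df, df$group), function(g) {
    s <- lapply(num, function(v) {
      x <- g[[v]][!is.na(g[[v]])]
      if (length(x) == 0L) c(NA_real_, NA_real_, NA_real_)
      else c(mean(x), min(x), max(x))
    })
    out <- data.frame(group = g$group[1L], n_peptides = nrow(g))
    for (i in seq_along(num)) {
      out[[paste0(num[i], "_mean")]] <- s[[i]][1L]
      out[[paste0(num[i], "_min")]]  <- s[[i]][2L]
      out[[paste0(num[i], "_max")]]  <- s[[i]][3L]
    }
    out
  }))
  rownames(groups) <- NULL
  structure(list(peptides = df, groups = groups), class = "sar_report")
}

#' @export
print.sar_report <- function(x, ...) {
  cat("Structure-activity folding report\n")
  pep <- x$peptides
  pep$top1 <- round(pep$top1, 4); pep$top2 <- round(pep$top2, 4)
  pep$top3 <- round(pep$top3, 4)
  pep$entropy_bits <- round(pep$entropy_bits, 3)
  pep$saddle <- round(pep$saddle, 2)
  print(pep, row.names = FALSE)
  cat("\nGroup summaries (mean over peptides):\n")
  cols <- c("group", "n_peptides", "n_clusters_mean", "top1_mean",
            "entropy_bits_mean", "saddle_mean")
  g <- x$groups[, intersect(cols, names(x$groups)), drop = FALSE]
  for (v in setdiff(names(g), c("group", "n_peptides"))) g[[v]] <- round(g[[v]], 3)
  print(g, row.names = FALSE)
  invisible(x)
}
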