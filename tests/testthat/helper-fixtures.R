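# Build a density_grid directly from an array of bin values, with unit-width
# bins centred on 0.5, 1.5, ... per dimension. Used to probe the peak finder
# and FEL code on hand-constructed landscapes.
make_grid <- function(values) {
  values <- as.array(values)
  dims <- dim(values)
  structure(list(
    edges = lapply(dims, function(k) seq(0, k)),
    mids  = lapply(dims, function(k) seq_len(k) - 0.5),
    P = values, d = length(dims)),
    class = "density_grid")
}

# Exhaustive peak-finding oracle: for every bin, compare against every Moore
# neighbour by explicit subscript arithmetic; same tie rule as the spec
# (>= all neighbours, strictly > tied neighbours of lower linear index).
oracle_peaks <- function(values, threshold_fraction) {
  values <- as.array(values)
  dims <- dim(values)
  d <- length(dims)
  thr <- threshold_fraction * max(values)
  offs <- as.matrix(expand.grid(rep(list(-1:1), d)))
  offs <- offs[rowSums(offs != 0) > 0, , drop = FALSE]
  peaks <- integer(0)
  for (lin in seq_along(values)) {
    if (values[lin] <= thr) next
    ci <- arrayInd(lin, dims)[1, ]
    is_peak <- TRUE
    for (r in seq_len(nrow(offs))) {
      nb <- ci + offs[r, ]
      if (any(nb < 1) || any(nb > dims)) next
      nlin <- 1 + sum((nb - 1) * cumprod(c(1, dims[-d])))
      if (values[nlin] > values[lin] ||
          (values[nlin] == values[lin] && nlin < lin)) {
        is_peak <- FALSE
        break
      }
    }
    if (is_peak) peaks <- c(peaks, lin)
  }
  peaks[order(values[peaks], decreasing = TRUE)]
}

fixture_sequences <- function() {
  read_sequences(system.file("extdata", "peptaibol_sequences.tsv",
                             package = "peptaifold"))
}

published_ions <- function() {
  utils::read.delim(system.file("extdata", "published_ions.tsv",
                                package = "peptaifold"))
}
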