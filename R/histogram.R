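## Weight-distribution histograms: the diagnostic used to compare how
## much representational mass survives in the first convolution versus the
## final fully connected layer before and after compression.

#' Histogram of a layer's weight values
#'
#' Deterministic for fixed weights: bin edges span [min, max] of the
#' selected layer's trainable values with \code{bins} equal-width bins
#' (degenerate all-equal layers get a single unit-width bin).  Frequencies
#' always sum to the layer's weight-element count.
#'
#' @param weights weight list (see \code{\link{initWeights}}).
#' @param layer layer id, or one of the selectors \code{"first_conv"} /
#'   \code{"final_fc"} (resolved against \code{graph}).
#' @param bins number of bins.
#' @param graph the \code{LayerGraph} the weights belong to (needed for
#'   the named selectors).
#' @return a \code{weightHistogram} list: layer, breaks, counts, min, max,
#'   n, sparsity (fraction of |w| < 1e-3).
#' @export
weightHistogram <- function(weights, layer, bins = 100L, graph = NULL) {
  id <- layer
  if (layer %in% c("first_conv", "final_fc")) {
    if (is.null(graph)) stop("named selectors need `graph`")
    ly <- graph@layers
    id <- if (layer == "first_conv") ly$id[ly$kind == "conv"][1L]
          else utils::tail(ly$id[ly$kind == "dense" & ly$section == "head"], 1L)
  }
  if (is.null(weights[[id]]))
    stop(sprintf("selector matches no weighted layer (id '%s')", id))
  v <- weightValues(weights, id)
  rng <- range(v)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = bins + 1L)
  h <- graphics::hist(v, breaks = breaks, plot = FALSE)
  structure(list(layer = id, breaks = h$breaks, counts = h$counts,
                 min = min(v), max = max(v), n = length(v),
                 sparsity = mean(abs(v) < 1e-3)),
            class = "weightHistogram")
}

#' @export
print.weightHistogram <- function(x, ...) {
  cat(sprintf("weightHistogram['%s']: %d values in [%.4g, %.4g], %d bins, sparsity %.3f\n",
              x$layer, x$n, x$min, x$max, length(x$counts), x$sparsity))
  invisible(x)
}

#' Write a histogram as CSV (bin mid, count)
#'
#' @param x a \code{weightHistogram}.
#' @param path output CSV.
#' @return the path, invisibly.
#' @export
writeHistogramCSV <- function(x, path) {
  mids <- (utils::head(x$breaks, -1) + utils::tail(x$breaks, -1)) / 2
  utils::write.csv(data.frame(mid = mids, count = x$counts), path,
                   row.names = FALSE)
  invisible(path)
}
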