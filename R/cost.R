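## Exact integer parameter and MAC accounting.
##
## Conventions (calibrated once against the OMNet baseline and frozen):
##   conv params  = k^2 * (Cin/groups) * Cout  (+ Cout if bias)
##   conv MACs    = k^2 * (Cin/groups) * Cout * Hout * Wout
##   dense params = in * out (+ out if bias);  dense MACs = in * out
##   batchnorm    = 2*C params, 0 MACs
##   activations, pooling, junctions: 0 params, 0 MACs
## Counts are held as doubles; every quantity involved is far below 2^53 so
## the arithmetic stays exact.

.layer_params <- function(ly) {
  p <- numeric(nrow(ly))
  cv <- ly$kind == "conv"
  p[cv] <- ly$kernel[cv]^2 * (ly$in_channels[cv] / ly$groups[cv]) *
    ly$out_channels[cv] + ifelse(ly$bias[cv], ly$out_channels[cv], 0)
  bn <- ly$kind == "batchnorm"
  p[bn] <- 2 * ly$out_channels[bn]
  de <- ly$kind == "dense"
  p[de] <- ly$in_channels[de] * ly$out_channels[de] +
    ifelse(ly$bias[de], ly$out_channels[de], 0)
  p
}

#' Count parameters and multiply-accumulate operations
#'
#' \code{countParams} returns the exact integer parameter total of a layer
#' graph; \code{countMacs} the exact multiply-accumulate total at a stated
#' input resolution (batch 1); \code{costReport} bundles both with a
#' per-layer breakdown.
#'
#' @param g a \code{LayerGraph}.
#' @param input_size input resolution for the MAC count (defaults to the
#'   graph's own).
#' @return \code{countParams}/\code{countMacs}: a number;
#'   \code{costReport}: a \code{\linkS4class{CostReport}}.
#' @examples
#' g <- buildResNet101(61)
#' countParams(g)            # 42625149, prints as 42.63 M
#' @export
countParams <- function(g) {
  sum(.layer_params(g@layers))
}

#' @rdname countParams
#' @export
countMacs <- function(g, input_size = inputSize(g)) {
  sum(costReport(g, input_size)@per_layer$macs)
}

#' @rdname countParams
#' @export
costReport <- function(g, input_size = inputSize(g)) {
  ly <- g@layers
  sh <- propagateShapes(g, input_size)
  p <- .layer_params(ly)
  m <- numeric(nrow(ly))
  cv <- ly$kind == "conv"
  m[cv] <- ly$kernel[cv]^2 * (ly$in_channels[cv] / ly$groups[cv]) *
    ly$out_channels[cv] * sh$side[cv]^2
  de <- ly$kind == "dense"
  m[de] <- ly$in_channels[de] * ly$out_channels[de]
  new("CostReport", param_count = sum(p), mac_count = sum(m),
      per_layer = data.frame(id = ly$id, kind = ly$kind, params = p,
                             macs = m, side = sh$side,
                             stringsAsFactors = FALSE),
      input_size = as.integer(input_size),
      class_count = g@num_classes)
}

#' Cost ratio of a compressed variant relative to its baseline
#'
#' Returns \code{100 * variant / base} for parameters and MACs, rounded to
#' two decimals (the convention used when quoting "x% of the parameters").
#'
#' @param base,variant \code{CostReport} objects.
#' @return named numeric vector \code{c(param_pct, mac_pct)}.
#' @examples
#' base <- costReport(buildResNet101(61))
#' small <- costReport(applyLmpPm(buildResNet101(61), N = 4, E = 1))
#' reductionRatios(base, small)
#' @export
reductionRatios <- function(base, variant) {
  stopifnot(base@param_count > 0, base@mac_count > 0)
  c(param_pct = round2(100 * variant@param_count / base@param_count, 2L),
    mac_pct   = round2(100 * variant@mac_count / base@mac_count, 2L))
}

#' Round half away from zero
#'
#' Plain \code{round} rounds half to even; printed "M" figures use
#' half-up, so 0.005 -> 0.01.
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric.
#' @export
round2 <- function(x, digits = 0L) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Format a parameter count in millions
#'
#' @param x count.
#' @param digits decimals (default 2, matching printed tables).
#' @return character, e.g. \code{"42.63"}.
#' @export
formatMillions <- function(x, digits = 2L) {
  formatC(round2(x / 1e6, digits), format = "f", digits = digits)
}
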