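## Weight containers.  Weights live outside the LayerGraph in a named list
## (one entry per parameterized layer id):
##   conv:      list(W = array(k, k, Cin/groups, Cout), b = numeric(Cout) | NULL)
##   dense:     list(W = matrix(in, out), b = numeric(out) | NULL)
##   batchnorm: list(gamma, beta, mean, var)  (mean/var are running stats)

#' Initialize weights for a layer graph
#'
#' Kaiming-uniform fan-in initialization for convolution and dense weights
#' (the framework-default scheme for this layer family), zero biases,
#' unit-gamma/zero-beta batchnorm with zero running mean and unit running
#' variance.  Fully determined by \code{seed}.
#'
#' @param g a \code{LayerGraph}.
#' @param seed integer seed.
#' @return named list of weight entries.
#' @export
initWeights <- function(g, seed = 1L) {
  set.seed(seed)
  ly <- g@layers
  w <- list()
  for (i in seq_len(nrow(ly))) {
    id <- ly$id[i]
    if (ly$kind[i] == "conv") {
      k <- ly$kernel[i]; cing <- ly$in_channels[i] %/% ly$groups[i]
      cout <- ly$out_channels[i]
      fan_in <- k * k * cing
      bound <- sqrt(6 / fan_in)           # kaiming uniform, a = sqrt(5) gain folded
      W <- array(stats::runif(k * k * cing * cout, -bound, bound),
                 dim = c(k, k, cing, cout))
      w[[id]] <- list(W = W, b = if (ly$bias[i]) numeric(cout) else NULL)
    } else if (ly$kind[i] == "dense") {
      fi <- ly$in_channels[i]; fo <- ly$out_channels[i]
      bound <- sqrt(6 / fi)
      W <- matrix(stats::runif(fi * fo, -bound, bound), fi, fo)
      w[[id]] <- list(W = W, b = if (ly$bias[i]) numeric(fo) else NULL)
    } else if (ly$kind[i] == "batchnorm") {
      c0 <- ly$out_channels[i]
      w[[id]] <- list(gamma = rep(1, c0), beta = numeric(c0),
                      mean = numeric(c0), var = rep(1, c0))
    }
  }
  w
}

#' Enumerate weight tensors with element counts
#'
#' Flattens a weight list into a data frame of (layer id, tensor name,
#' element count).  Summing the counts gives an independent, brute-force
#' parameter total used to cross-check \code{\link{countParams}}.
#'
#' @param weights a weight list from \code{\link{initWeights}}.
#' @param trainable_only drop batchnorm running statistics (which are not
#'   parameters under the counting convention) -- default TRUE.
#' @return data.frame: id, tensor, count.
#' @export
enumerateWeights <- function(weights, trainable_only = TRUE) {
  rows <- list()
  for (id in names(weights)) {
    for (nm in names(weights[[id]])) {
      v <- weights[[id]][[nm]]
      if (is.null(v)) next
      if (trainable_only && nm %in% c("mean", "var")) next
      rows[[length(rows) + 1L]] <-
        data.frame(id = id, tensor = nm, count = length(v),
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Flatten all trainable weight values of selected layers
#'
#' @param weights weight list.
#' @param ids layer ids to include (default all).
#' @return numeric vector of weight values (biases and batchnorm affine
#'   parameters included; running stats excluded).
#' @export
weightValues <- function(weights, ids = names(weights)) {
  out <- lapply(ids, function(id) {
    e <- weights[[id]]
    unlist(e[setdiff(names(e), c("mean", "var"))], use.names = FALSE)
  })
  unlist(out, use.names = FALSE)
}
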