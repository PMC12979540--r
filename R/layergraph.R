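## Core plumbing for building and interrogating LayerGraph objects.

.split_preds <- function(x) {
  lapply(strsplit(x, ",", fixed = TRUE),
         function(p) p[nzchar(p)])
}

.empty_layers <- function() {
  data.frame(id = character(), kind = character(),
             in_channels = integer(), out_channels = integer(),
             kernel = integer(), stride = integer(), padding = integer(),
             groups = integer(), bias = logical(),
             predecessors = character(), section = character(),
             convertible = logical(), path = integer(),
             stringsAsFactors = FALSE)
}

#' Low-level layer-row constructor
#'
#' Builders accumulate rows with this helper; users normally go through
#' \code{\link{buildOMNet}} and friends.
#'
#' @param id unique layer id.
#' @param kind layer kind (see \code{\linkS4class{LayerGraph}}).
#' @param inc,outc in/out channel counts.
#' @param kernel,stride,padding,groups geometry (kernel doubles as the
#'   output side for \code{adaptivepool}).
#' @param bias logical.
#' @param preds character vector of predecessor ids.
#' @param section stem/features/head.
#' @param convertible may depthwise conversion rewrite this conv.
#' @param path parallel path index (0 = shared).
#' @return one-row data.frame.
#' @keywords internal
layerRow <- function(id, kind, inc, outc, kernel = 1L, stride = 1L,
                     padding = 0L, groups = 1L, bias = FALSE,
                     preds = character(), section = "features",
                     convertible = TRUE, path = 0L) {
  data.frame(id = id, kind = kind, in_channels = as.integer(inc),
             out_channels = as.integer(outc), kernel = as.integer(kernel),
             stride = as.integer(stride), padding = as.integer(padding),
             groups = as.integer(groups), bias = bias,
             predecessors = paste(preds, collapse = ","),
             section = section, convertible = convertible,
             path = as.integer(path), stringsAsFactors = FALSE)
}

newLayerGraph <- function(layers, entry, exit, input_size, num_classes) {
  new("LayerGraph", layers = layers, entry = entry, exit = exit,
      input_size = as.integer(input_size),
      num_classes = as.integer(num_classes))
}

#' Accessors for LayerGraph objects
#'
#' \code{layerTable} returns the layer data frame; \code{nLayers} the layer
#' count; \code{inputSize} and \code{numClasses} the graph metadata.
#'
#' @param g a \code{LayerGraph}.
#' @return see description.
#' @export
layerTable <- function(g) g@layers

#' @rdname layerTable
#' @export
nLayers <- function(g) nrow(g@layers)

#' @rdname layerTable
#' @export
inputSize <- function(g) g@input_size

#' @rdname layerTable
#' @export
numClasses <- function(g) g@num_classes

.conv_out_side <- function(h, k, s, p) {
  out <- (h + 2L * p - k) %/% s + 1L
  if (out < 1L) stop("non-positive spatial size after convolution/pool")
  out
}

#' Propagate channel widths and spatial sizes through a graph
#'
#' Walks the (already topologically ordered) layer table from the input,
#' assigning each layer its input/output spatial side and checking channel
#' bookkeeping at every junction.  Used by the validity machinery, the MAC
#' counter and the forward pass.
#'
#' @param g a \code{LayerGraph}.
#' @param input_size optional override of the graph's input resolution.
#' @return data.frame: id, kind, out_channels, side (output spatial side).
#' @export
propagateShapes <- function(g, input_size = inputSize(g)) {
  ly <- g@layers
  pred <- .split_preds(ly$predecessors)
  side <- integer(nrow(ly))
  chan <- integer(nrow(ly))
  idx <- seq_len(nrow(ly)); names(idx) <- ly$id
  for (i in idx) {
    k <- ly$kind[i]
    if (k == "input") {
      side[i] <- as.integer(input_size); chan[i] <- ly$out_channels[i]
      next
    }
    pi <- idx[pred[[i]]]
    ins <- unique(side[pi])
    inc <- chan[pi]
    if (k %in% c("add", "multiply", "concat") && length(ins) != 1L) {
      if (k == "multiply" && length(setdiff(ins, 1L)) == 1L)
        ins <- setdiff(ins, 1L)    # channel gate broadcast over the map
      else stop(sprintf("junction '%s': input spatial sides differ (%s)",
                        ly$id[i], paste(side[pi], collapse = ",")))
    }
    s <- ins[1L]
    side[i] <- switch(k,
      conv    = .conv_out_side(s, ly$kernel[i], ly$stride[i], ly$padding[i]),
      maxpool = .conv_out_side(s, ly$kernel[i], ly$stride[i], ly$padding[i]),
      adaptivepool = ly$kernel[i],
      globalavgpool = 1L,
      flatten = 1L,
      dense = 1L,
      output = s,
      s)
    chan[i] <- switch(k,
      conv = ly$out_channels[i],
      dense = ly$out_channels[i],
      concat = sum(inc),
      flatten = inc[1L] * s * s,
      inc[1L])
    if (k == "conv" && sum(inc) != ly$in_channels[i])
      stop(sprintf("conv '%s': declared in_channels %d but receives %d",
                   ly$id[i], ly$in_channels[i], sum(inc)))
    if (k == "dense" && inc[1L] * (if (ly$kind[pi[1L]] == "dense") 1L else 1L) != ly$in_channels[i] &&
        sum(inc) != ly$in_channels[i])
      stop(sprintf("dense '%s': declared in_features %d but receives %d",
                   ly$id[i], ly$in_channels[i], sum(inc)))
  }
  data.frame(id = ly$id, kind = ly$kind, out_channels = chan,
             side = side, stringsAsFactors = FALSE)
}

#' Serialize a layer graph
#'
#' \code{writeLayerGraphCSV} dumps one layer descriptor per row;
#' \code{writeLayerGraphJSON} writes the same table plus graph metadata.
#'
#' @param g a \code{LayerGraph}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeLayerGraphCSV <- function(g, path) {
  utils::write.csv(g@layers, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeLayerGraphCSV
#' @export
writeLayerGraphJSON <- function(g, path) {
  jsonlite::write_json(
    list(entry = g@entry, exit = g@exit, input_size = g@input_size,
         num_classes = g@num_classes, layers = g@layers),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a layer graph written by \code{writeLayerGraphCSV}/\code{JSON}
#'
#' The adapter for arbitrary architectures: any network expressed as a
#' layer table (one descriptor per row, with graph metadata for the JSON
#' form) can be loaded and fed to the transforms and cost accounting.
#' The CSV form carries no metadata, so entry/exit default to the first
#' and last row and the class count to the classifier's width.
#'
#' @param path file written by the corresponding writer (or by hand).
#' @param input_size input resolution (CSV form only).
#' @return a validated \code{\linkS4class{LayerGraph}}.
#' @export
readLayerGraphCSV <- function(path, input_size = 224L) {
  ly <- utils::read.csv(path, stringsAsFactors = FALSE)
  ly$predecessors[is.na(ly$predecessors)] <- ""
  cls <- ly$out_channels[ly$kind == "dense" & ly$section == "head"]
  if (!length(cls)) stop("no classifier dense layer in ", path)
  g <- newLayerGraph(ly, ly$id[1L], ly$id[nrow(ly)], input_size,
                     utils::tail(cls, 1L))
  validObject(g)
  g
}

#' @rdname readLayerGraphCSV
#' @export
readLayerGraphJSON <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  ly <- js$layers
  ly$predecessors[is.na(ly$predecessors)] <- ""
  g <- newLayerGraph(ly, js$entry, js$exit, js$input_size, js$num_classes)
  validObject(g)
  g
}
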