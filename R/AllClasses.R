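#' @import methods
NULL

#' Layer graph description of a convolutional network
#'
#' A \code{LayerGraph} is an ordered, acyclic description of a network's
#' layers on which the structural rewrites (\code{\link{pruneChannels}},
#' \code{\link{toDepthwiseSeparable}}, \code{\link{expandPaths}}) and the
#' cost accounting (\code{\link{countParams}}, \code{\link{countMacs}}) are
#' defined.  Each row of the \code{layers} data frame is one layer
#' descriptor with columns:
#' \describe{
#'   \item{id}{unique character token}
#'   \item{kind}{one of \code{conv}, \code{batchnorm}, \code{dense},
#'     \code{relu}, \code{sigmoid}, \code{maxpool}, \code{globalavgpool},
#'     \code{adaptivepool}, \code{flatten}, \code{add}, \code{concat},
#'     \code{multiply}, \code{input}, \code{output}}
#'   \item{in_channels, out_channels}{positive integer channel counts}
#'   \item{kernel, stride, padding, groups}{convolution/pool geometry
#'     (kernel 1, stride 1, padding 0, groups 1 for layers where they do
#'     not apply); for \code{adaptivepool}, \code{kernel} stores the output
#'     side}
#'   \item{bias}{logical; whether the layer carries a bias vector}
#'   \item{predecessors}{comma-separated ids feeding this layer}
#'   \item{section}{\code{stem}, \code{features} or \code{head}; the
#'     partition used by path expansion}
#'   \item{convertible}{logical; whether depthwise-separable conversion may
#'     rewrite this convolution (the OMNet family keeps its downsampling
#'     stem as a standard convolution, outside the compressed feature
#'     extractor)}
#'   \item{path}{integer parallel-path index (0 = shared)}
#' }
#'
#' @slot layers data.frame of layer descriptors (see above).
#' @slot entry id of the input layer.
#' @slot exit id of the output layer.
#' @slot input_size integer input resolution (images are
#'   \code{input_size x input_size x 3}).
#' @slot num_classes integer classifier width.
#'
#' @seealso \code{\link{buildOMNet}}, \code{\link{buildResNet101}},
#'   \code{\link{applyLmpPm}}
#' @export
setClass("LayerGraph",
  representation(layers = "data.frame", entry = "character",
                 exit = "character", input_size = "integer",
                 num_classes = "integer"))

.layer_kinds <- c("conv", "batchnorm", "dense", "relu", "sigmoid",
                  "maxpool", "globalavgpool", "adaptivepool", "flatten",
                  "add", "concat", "multiply", "input", "output")

setValidity("LayerGraph", function(object) {
  ly <- object@layers
  need <- c("id", "kind", "in_channels", "out_channels", "kernel", "stride",
            "padding", "groups", "bias", "predecessors", "section",
            "convertible", "path")
  if (!all(need %in% names(ly)))
    return(paste("missing layer columns:",
                 paste(setdiff(need, names(ly)), collapse = ", ")))
  if (anyDuplicated(ly$id)) return("duplicate layer ids")
  if (!all(ly$kind %in% .layer_kinds))
    return(paste("unknown layer kind:",
                 paste(setdiff(ly$kind, .layer_kinds), collapse = ", ")))
  if (!object@entry %in% ly$id || !object@exit %in% ly$id)
    return("entry/exit not among layer ids")
  pred <- .split_preds(ly$predecessors)
  known <- unlist(pred)
  if (length(known) && !all(known %in% ly$id))
    return("predecessor refers to unknown layer id")
  ## ordered: every predecessor must appear earlier (guarantees acyclicity)
  pos <- seq_along(ly$id); names(pos) <- ly$id
  for (i in seq_along(pred)) {
    if (ly$kind[i] != "input" && length(pred[[i]]) == 0L)
      return(sprintf("layer '%s' has no predecessor", ly$id[i]))
    if (length(pred[[i]]) && any(pos[pred[[i]]] >= i))
      return(sprintf("layer '%s' precedes one of its inputs", ly$id[i]))
  }
  conv <- ly$kind == "conv"
  if (any(conv & (ly$in_channels %% ly$groups != 0L)))
    return("conv in_channels not divisible by groups")
  ## concat bookkeeping: out = sum of predecessors' out
  for (i in which(ly$kind == "concat")) {
    w <- sum(ly$out_channels[match(pred[[i]], ly$id)])
    if (w != ly$out_channels[i])
      return(sprintf("concat '%s': out_channels %d != sum of inputs %d",
                     ly$id[i], ly$out_channels[i], w))
  }
  for (i in which(ly$kind %in% c("add", "multiply"))) {
    w <- unique(ly$out_channels[match(pred[[i]], ly$id)])
    if (length(w) != 1L)
      return(sprintf("junction '%s': input widths differ", ly$id[i]))
  }
  cls <- which(ly$kind == "dense" & ly$out_channels == object@num_classes &
               ly$section == "head")
  if (length(cls) != 1L)
    return("expected exactly one classifier dense layer in the head")
  TRUE
})

#' Exact parameter and multiply-accumulate cost of a network
#'
#' @slot param_count exact integer (stored as double to avoid 32-bit
#'   overflow) total parameter count.
#' @slot mac_count exact multiply-accumulate count at \code{input_size},
#'   batch 1.
#' @slot per_layer data.frame with one row per layer: id, kind, params,
#'   macs, output spatial side.
#' @slot input_size input resolution used for the MAC count.
#' @slot class_count classifier width the counts refer to.
#' @export
setClass("CostReport",
  representation(param_count = "numeric", mac_count = "numeric",
                 per_layer = "data.frame", input_size = "integer",
                 class_count = "integer"))

setValidity("CostReport", function(object) {
  if (abs(object@param_count - sum(object@per_layer$params)) > 0.5)
    return("param_count != sum of per-layer breakdown")
  if (abs(object@mac_count - sum(object@per_layer$macs)) > 0.5)
    return("mac_count != sum of per-layer breakdown")
  TRUE
})

#' Record of a structural rewrite
#'
#' @slot op character; which rewrite produced the report.
#' @slot channel_map data.frame of per-layer before/after channel counts.
#' @slot converted character vector of layer ids rewritten to
#'   depthwise+pointwise pairs.
#' @slot paths integer path count after expansion.
#' @slot params_before,params_after exact parameter counts.
#' @export
setClass("TransformReport",
  representation(op = "character", channel_map = "data.frame",
                 converted = "character", paths = "integer",
                 params_before = "numeric", params_after = "numeric"))

#' Classification quality report
#'
#' Holds overall accuracy, one-vs-rest per-class counts, macro-averaged
#' precision/recall/F1, the confusion matrix, and per-class ROC/PR curves.
#'
#' @slot accuracy overall sample accuracy.
#' @slot macro_precision,macro_recall,macro_f1 unweighted class means.
#' @slot per_class data.frame: class, tp, fp, fn, tn, precision, recall,
#'   f1, auc.
#' @slot confusion integer matrix (true x predicted).
#' @slot roc,pr lists of per-class curve data frames.
#' @export
setClass("MetricsReport",
  representation(accuracy = "numeric", macro_precision = "numeric",
                 macro_recall = "numeric", macro_f1 = "numeric",
                 per_class = "data.frame", confusion = "matrix",
                 roc = "list", pr = "list"))

setMethod("show", "LayerGraph", function(object) {
  ly <- object@layers
  cat(sprintf("LayerGraph: %d layers (%d conv, %d dense), %dx%dx3 input, %d classes\n",
              nrow(ly), sum(ly$kind == "conv"), sum(ly$kind == "dense"),
              object@input_size, object@input_size, object@num_classes))
  np <- max(ly$path)
  if (np > 1L) cat(sprintf("  %d parallel feature paths\n", np))
  cat(sprintf("  sections: stem %d | features %d | head %d layers\n",
              sum(ly$section == "stem"), sum(ly$section == "features"),
              sum(ly$section == "head")))
  invisible(object)
})

setMethod("show", "CostReport", function(object) {
  cat(sprintf("CostReport: %s parameters (%s M), %s MACs at %dx%d, %d classes\n",
              format(object@param_count, big.mark = ",", scientific = FALSE),
              formatMillions(object@param_count),
              format(object@mac_count, big.mark = ",", scientific = FALSE),
              object@input_size, object@input_size, object@class_count))
  invisible(object)
})

setMethod("show", "TransformReport", function(object) {
  cat(sprintf("TransformReport [%s]: params %s -> %s (%d path%s, %d layers converted)\n",
              object@op,
              format(object@params_before, big.mark = ","),
              format(object@params_after, big.mark = ","),
              object@paths, if (object@paths > 1L) "s" else "",
              length(object@converted)))
  invisible(object)
})

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf("MetricsReport: accuracy %.4f | macro P %.4f R %.4f F1 %.4f (%d classes, %d samples)\n",
              object@accuracy, object@macro_precision, object@macro_recall,
              object@macro_f1, nrow(object@per_class), sum(object@confusion)))
  invisible(object)
})
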