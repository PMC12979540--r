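## The compression engine: three independent, composable LayerGraph
## rewrites -- global channel pruning, depthwise-separable conversion and
## multi-path expansion -- plus their composition.

## Re-derive every layer's input width (and pass-through output widths)
## after out_channels of convs/denses changed.  Junction mismatches signal
## an unsupported topology and abort.
.repropagate <- function(g) {
  ly <- g@layers
  pred <- .split_preds(ly$predecessors)
  idx <- seq_len(nrow(ly)); names(idx) <- ly$id
  side <- integer(nrow(ly))
  for (i in idx) {
    k <- ly$kind[i]
    if (k == "input") { side[i] <- g@input_size; next }
    pi <- idx[pred[[i]]]
    inc <- ly$out_channels[pi]
    s <- unique(side[pi])
    if (length(s) != 1L) {
      if (k == "multiply" && length(setdiff(s, 1L)) == 1L) s <- setdiff(s, 1L)
      else stop(sprintf("junction '%s': input spatial sides differ after rewrite",
                        ly$id[i]))
    }
    side[i] <- switch(k,
      conv = .conv_out_side(s, ly$kernel[i], ly$stride[i], ly$padding[i]),
      maxpool = .conv_out_side(s, ly$kernel[i], ly$stride[i], ly$padding[i]),
      adaptivepool = ly$kernel[i], globalavgpool = 1L,
      flatten = 1L, dense = 1L, s)
    if (k %in% c("add", "multiply")) {
      if (length(unique(inc)) != 1L)
        stop(sprintf("add/multiply junction '%s': widths %s differ after rewrite; unsupported topology",
                     ly$id[i], paste(unique(inc), collapse = "/")))
      ly$in_channels[i] <- inc[1L]; ly$out_channels[i] <- inc[1L]
    } else if (k == "concat") {
      ly$in_channels[i] <- sum(inc); ly$out_channels[i] <- sum(inc)
    } else if (k == "flatten") {
      ly$in_channels[i] <- inc[1L]
      ly$out_channels[i] <- inc[1L] * s * s
    } else if (k %in% c("conv", "dense")) {
      ly$in_channels[i] <- sum(inc)
      if (k == "conv" && ly$groups[i] > 1L) {
        ## depthwise layers keep groups == channels
        ly$groups[i] <- ly$in_channels[i]
        ly$out_channels[i] <- ly$in_channels[i]
      }
    } else {
      ly$in_channels[i] <- inc[1L]; ly$out_channels[i] <- inc[1L]
    }
  }
  g@layers <- ly
  validObject(g)
  g
}

#' Global channel pruning by an integer divisor
#'
#' Every convolution (and every dense layer except the classifier) whose
#' output width \eqn{C} satisfies the guard \eqn{C/N > 1} has its width
#' reduced to \eqn{\lfloor C/N \rfloor}; layers failing the guard are left
#' untouched, preventing excessive compression.  All downstream widths
#' (consumer in-channels, batchnorm widths, dense in-features, junction
#' widths) are repropagated.  The classifier's output width is never
#' changed.  Purely structural: no data or weight magnitudes are involved,
#' and weights are not carried over (re-initialize after pruning).
#'
#' @param g a \code{LayerGraph}.
#' @param N integer divisor >= 1 (\code{N = 1} is a no-op).
#' @return the pruned \code{LayerGraph}.
#' @examples
#' g <- buildResNet101(61)
#' formatMillions(countParams(toDepthwiseSeparable(pruneChannels(g, 2))))  # "6.01"
#' @export
pruneChannels <- function(g, N) {
  N <- as.integer(N)
  stopifnot(N >= 1L)
  if (N == 1L) return(g)
  ly <- g@layers
  target <- (ly$kind == "conv" & ly$groups == 1L) |
            (ly$kind == "dense" & ly$id != .classifier_id(g))
  hit <- target & (ly$out_channels / N > 1)
  ly$out_channels[hit] <- ly$out_channels[hit] %/% N
  if (any(ly$out_channels[hit] < 1L))
    stop("pruning produced a layer below width 1")   # unreachable by guard
  g@layers <- ly
  .repropagate(g)
}

.classifier_id <- function(g) {
  ly <- g@layers
  ly$id[ly$kind == "dense" & ly$section == "head" &
        ly$out_channels == g@num_classes][1L]
}

#' Rewrite standard convolutions as depthwise + pointwise pairs
#'
#' Every standard convolution with kernel > 1 and \code{groups = 1} (and
#' not flagged non-convertible by its builder) is replaced by a depthwise
#' convolution (\eqn{C_{in} \to C_{in}}, original kernel/stride/padding,
#' \code{groups = C_{in}}, bias-free) followed by a 1x1 pointwise
#' convolution (\eqn{C_{in} \to C_{out}}, stride 1, inheriting the original
#' bias flag).  1x1 convolutions are left unchanged (converting them would
#' add parameters), and no batchnorm is inserted inside the pair.  This is
#' an architecture rewrite, not a factorization: the function computed by
#' trained weights is not preserved.
#'
#' @param g a \code{LayerGraph}.
#' @return the converted \code{LayerGraph}.
#' @export
toDepthwiseSeparable <- function(g) {
  ly <- g@layers
  bad <- ly$kind == "conv" & ly$groups > 1L & ly$groups < ly$in_channels
  if (any(bad))
    stop(sprintf("unsupported grouped convolution(s): %s",
                 paste(ly$id[bad], collapse = ", ")))
  hit <- which(ly$kind == "conv" & ly$kernel > 1L & ly$groups == 1L &
               ly$convertible)
  if (!length(hit)) return(g)
  out <- vector("list", nrow(ly))
  for (i in seq_len(nrow(ly))) {
    r <- ly[i, , drop = FALSE]
    if (i %in% hit) {
      dw <- r
      dw$id <- paste0(r$id, "_dw")
      dw$out_channels <- r$in_channels
      dw$groups <- r$in_channels
      dw$bias <- FALSE
      pw <- r                     # keeps the original id: successors intact
      pw$kernel <- 1L; pw$stride <- 1L; pw$padding <- 0L
      pw$predecessors <- dw$id
      out[[i]] <- rbind(dw, pw)
    } else out[[i]] <- r
  }
  g@layers <- do.call(rbind, out)
  .repropagate(g)
}

#' Expand the feature extractor into E parallel paths
#'
#' Builds \code{E} structurally identical copies of everything before the
#' classifier (optionally sharing the stem), concatenates the path outputs
#' on the channel dimension, and rebuilds the single classifier dense layer
#' on the E-fold input width with the original class count.  With weights
#' attached, path 1 keeps the original weights verbatim and paths 2..E are
#' freshly initialized under \code{seed} (disable with
#' \code{reinit = FALSE} to obtain E numerically identical paths).
#'
#' @param g a \code{LayerGraph}.
#' @param E integer path count >= 1 (\code{E = 1} returns \code{g}
#'   unchanged).
#' @param shared_stem logical; keep the stem section single and feed all
#'   paths from it (the OMNet/LMNet convention).  With \code{FALSE} the
#'   stem is replicated into every path.
#' @param weights optional weight list (as from \code{\link{initWeights}});
#'   if supplied, the transformed weights are returned in attribute
#'   \code{"weights"}.
#' @param reinit logical; re-initialize paths 2..E (default TRUE).
#' @param seed integer seed for the re-initialization.
#' @return the expanded \code{LayerGraph} (with a \code{"weights"}
#'   attribute when \code{weights} was supplied).
#' @export
expandPaths <- function(g, E, shared_stem = TRUE, weights = NULL,
                        reinit = TRUE, seed = 1L) {
  E <- as.integer(E)
  if (E < 1L) stop("E must be >= 1")
  if (E == 1L) {
    if (!is.null(weights)) attr(g, "weights") <- weights
    return(g)
  }
  ly <- g@layers
  cid <- .classifier_id(g)
  ci <- match(cid, ly$id)
  shared_pre <- if (shared_stem) ly$section == "stem" else rep(FALSE, nrow(ly))
  shared_pre[ly$kind == "input"] <- TRUE
  rep_rows <- seq_len(nrow(ly)) < ci & !shared_pre
  feat_ids <- ly$id[rep_rows]
  tail_id <- .split_preds(ly$predecessors[ci])[[1L]]
  stopifnot(length(tail_id) == 1L)
  rename <- function(rows, p) {
    rows$id <- ifelse(rows$id %in% feat_ids, paste0(rows$id, "_p", p), rows$id)
    rows$predecessors <- vapply(.split_preds(rows$predecessors), function(pp)
      paste(ifelse(pp %in% feat_ids, paste0(pp, "_p", p), pp), collapse = ","),
      "")
    rows$path <- p
    rows
  }
  paths <- lapply(seq_len(E), function(p) rename(ly[rep_rows, , drop = FALSE], p))
  width <- ly$out_channels[match(tail_id, ly$id)]
  concat <- layerRow("path_concat", "concat", E * width, E * width,
                     preds = paste0(tail_id, "_p", seq_len(E)),
                     section = "head")
  head_rows <- ly[seq_len(nrow(ly)) >= ci, , drop = FALSE]
  head_rows$predecessors[1L] <- "path_concat"
  head_rows$in_channels[1L] <- E * width
  new_ly <- rbind(ly[shared_pre & seq_len(nrow(ly)) < ci, , drop = FALSE],
                  do.call(rbind, paths), concat, head_rows)
  g2 <- newLayerGraph(new_ly, g@entry, g@exit, g@input_size, g@num_classes)
  g2 <- .repropagate(g2)
  if (!is.null(weights)) {
    w2 <- list()
    for (id in names(weights)) if (!id %in% feat_ids && id != cid)
      w2[[id]] <- weights[[id]]
    for (p in seq_len(E)) {
      for (id in feat_ids) if (!is.null(weights[[id]]))
        w2[[paste0(id, "_p", p)]] <- weights[[id]]
    }
    if (reinit) {
      fresh <- initWeights(g2, seed = seed)
      for (p in 2:E) for (id in feat_ids) {
        nid <- paste0(id, "_p", p)
        if (!is.null(fresh[[nid]])) w2[[nid]] <- fresh[[nid]]
      }
      w2[[cid]] <- fresh[[cid]]
    } else {
      ## head must still match the widened input: tile the old weights
      fresh <- initWeights(g2, seed = seed)
      w2[[cid]] <- fresh[[cid]]
    }
    attr(g2, "weights") <- w2
  }
  g2
}

#' Apply the full compression pipeline: prune, convert, expand
#'
#' Composes the three rewrites in their canonical order:
#' \code{expandPaths(toDepthwiseSeparable(pruneChannels(g, N)), E)}.
#' Conversion can be skipped with \code{convert = FALSE} (the baseline
#' "N=1, E=1" rows of the OMNet cost tables are unconverted, whereas the
#' residual-network table treats "N=1, E=1" as the converted model, so the
#' flag is explicit rather than inferred).
#'
#' @param g a \code{LayerGraph}.
#' @param N pruning divisor >= 1.
#' @param E path count >= 1.
#' @param convert apply depthwise-separable conversion (default TRUE).
#' @param shared_stem passed to \code{\link{expandPaths}}; defaults to TRUE
#'   when the graph has a stem section, which matches both the OMNet family
#'   and the replicate-everything residual-network convention only when a
#'   builder marked a stem.
#' @return the transformed \code{LayerGraph}.
#' @examples
#' formatMillions(countParams(applyLmpPm(buildResNet101(61), N = 4, E = 4)))  # "6.16"
#' @export
applyLmpPm <- function(g, N, E, convert = TRUE,
                       shared_stem = any(g@layers$section == "stem" &
                                         !g@layers$convertible)) {
  g <- pruneChannels(g, N)
  if (convert) g <- toDepthwiseSeparable(g)
  expandPaths(g, E, shared_stem = shared_stem)
}

#' Summarize a rewrite as a TransformReport
#'
#' @param before,after \code{LayerGraph}s around a rewrite.
#' @param op label for the rewrite.
#' @return a \code{\linkS4class{TransformReport}}.
#' @export
transformReport <- function(before, after, op = "lmp-pm") {
  lb <- before@layers; la <- after@layers
  common <- intersect(lb$id, la$id)
  cm <- data.frame(id = common,
                   before = lb$out_channels[match(common, lb$id)],
                   after = la$out_channels[match(common, la$id)],
                   stringsAsFactors = FALSE)
  conv <- la$id[endsWith(la$id, "_dw")]
  new("TransformReport", op = op, channel_map = cm,
      converted = sub("_dw$", "", conv), paths = max(la$path, 1L),
      params_before = countParams(before), params_after = countParams(after))
}
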