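## The OMNet family: a deliberately high-capacity baseline classifier
## built from three-branch-parallel (TBP) blocks, residual units and
## squeeze-excitation gates, plus its compressed derivative LMNet.

#' Configuration of the OMNet family
#'
#' Captures every degree of freedom of the architecture: stem width, the
#' four stage widths, TBP branch kernels and identity branch, residual
#' repeats, which stages carry an SE gate, the head width and adaptive
#' pool size, and where downsampling happens.  The default values are the
#' single calibration point from which all printed cost-table entries of
#' the family follow (see the package vignette).
#'
#' @param stem_channels width of the stem convolution output.
#' @param stage_widths integer(4): output width of each stage's fusion
#'   convolution.
#' @param residual_repeats integer(4): residual units per stage.
#' @param tbp_kernels middle kernels of the TBP convolution branches
#'   (each branch is 1x1 -> kxk -> 1x1 -> batchnorm -> relu).
#' @param tbp_identity include the normalization-only identity branch.
#' @param tbp_width one of \code{"input"} (branch width = block input
#'   width) or \code{"half"}.
#' @param tbp2_width second stage-4 TBP branch width rule: \code{"concat"}
#'   (width of its concatenated input), \code{"input"} (stage input
#'   width) or \code{"branch"}.
#' @param se_stages stages carrying a squeeze-excitation gate.
#' @param tbp_repeats_stage4 TBP applications in stage 4.
#' @param stage_strides integer(4): stride of each stage's fusion conv.
#' @param head_channels width of the 1x1 head convolution.
#' @param pool_output adaptive average pool output side.
#' @param num_classes classifier width.
#' @param input_size input resolution.
#' @param conv_bias logical: convolutions carry biases (the family keeps
#'   the framework default of biased convolutions even before batchnorm).
#' @param head_bn batchnorm after the head convolution.
#' @return an \code{omnetConfig} list.
#' @export
omnetConfig <- function(stem_channels = 64L,
                        stage_widths = c(128L, 256L, 512L, 1024L),
                        residual_repeats = c(1L, 1L, 1L, 1L),
                        tbp_kernels = c(3L, 3L),
                        tbp_identity = TRUE,
                        tbp_width = c("input", "half"),
                        tbp2_width = c("concat", "input", "branch"),
                        se_stages = c(3L, 4L),
                        tbp_repeats_stage4 = 2L,
                        stage_strides = c(2L, 2L, 2L, 1L),
                        head_channels = 2048L,
                        pool_output = 1L,
                        num_classes = 1000L,
                        input_size = 224L,
                        conv_bias = TRUE,
                        head_bn = FALSE) {
  tbp_width <- match.arg(tbp_width)
  tbp2_width <- match.arg(tbp2_width)
  stopifnot(length(stage_widths) == 4L, length(residual_repeats) == 4L,
            length(stage_strides) == 4L, stem_channels > 0,
            all(stage_widths > 0), pool_output >= 1L, num_classes >= 2L)
  structure(list(stem_channels = as.integer(stem_channels),
                 stage_widths = as.integer(stage_widths),
                 residual_repeats = as.integer(residual_repeats),
                 tbp_kernels = as.integer(tbp_kernels),
                 tbp_identity = tbp_identity, tbp_width = tbp_width,
                 tbp2_width = tbp2_width, se_stages = as.integer(se_stages),
                 tbp_repeats_stage4 = as.integer(tbp_repeats_stage4),
                 stage_strides = as.integer(stage_strides),
                 head_channels = as.integer(head_channels),
                 pool_output = as.integer(pool_output),
                 num_classes = as.integer(num_classes),
                 input_size = as.integer(input_size),
                 conv_bias = conv_bias, head_bn = head_bn),
            class = "omnetConfig")
}

## append one TBP block to builder e, fed from `from` of width `inc`;
## returns the id and width of the concat output
.add_tbp <- function(e, from, inc, cfg, branch_width) {
  outs <- character(); widths <- integer()
  for (k in cfg$tbp_kernels) {
    t <- branch_width
    x <- .gb_conv(e, from, inc, t, 1L, bias = cfg$conv_bias, prefix = "tbp_c1")
    x <- .gb_conv(e, x, t, t, k, bias = cfg$conv_bias, prefix = "tbp_mid")
    x <- .gb_conv(e, x, t, t, 1L, bias = cfg$conv_bias, prefix = "tbp_c3")
    x <- .gb_bn(e, x, t)
    x <- .gb_relu(e, x, t)
    outs <- c(outs, x); widths <- c(widths, t)
  }
  if (cfg$tbp_identity) {
    x <- .gb_bn(e, from, inc)
    x <- .gb_relu(e, x, inc)
    outs <- c(outs, x); widths <- c(widths, inc)
  }
  w <- sum(widths)
  id <- .gb_add(e, layerRow(.gb_id(e, "tbp_cat"), "concat", w, w,
                            preds = outs))
  list(id = id, width = w)
}

.add_se <- function(e, from, width) {
  g0 <- .gb_add(e, layerRow(.gb_id(e, "se_gap"), "globalavgpool", width,
                            width, preds = from))
  fl <- .gb_add(e, layerRow(.gb_id(e, "se_flat"), "flatten", width, width,
                            preds = g0))
  d0 <- .gb_add(e, layerRow(.gb_id(e, "se_fc"), "dense", width, width,
                            bias = TRUE, preds = fl))
  sg <- .gb_add(e, layerRow(.gb_id(e, "se_sig"), "sigmoid", width, width,
                            preds = d0))
  .gb_add(e, layerRow(.gb_id(e, "se_mul"), "multiply", width, width,
                      preds = c(from, sg)))
}

.add_residual <- function(e, from, width, bias) {
  y <- .gb_conv(e, from, width, width, 3L, bias = bias, prefix = "res_conv")
  y <- .gb_bn(e, y, width)
  y <- .gb_relu(e, y, width)
  y <- .gb_conv(e, y, width, width, 3L, bias = bias, prefix = "res_conv")
  y <- .gb_bn(e, y, width)
  x <- .gb_add(e, layerRow(.gb_id(e, "res_add"), "add", width, width,
                           preds = c(y, from)))
  .gb_relu(e, x, width)
}

#' Build a standalone TBP block as a LayerGraph fragment
#'
#' Two (or more) stacked-convolution branches (1x1 -> kxk -> 1x1 ->
#' batchnorm -> relu) plus an optional normalization-only identity branch,
#' concatenated on the channel dimension.  With channel-preserving
#' branches and the identity branch the concat width is 3x the input
#' width.  Exposed standalone mainly for inspection and testing; the stage
#' builders embed the same structure.
#'
#' @param in_channels input width.
#' @param channels branch width (default: \code{in_channels}).
#' @param kernels middle kernels of the convolution branches.
#' @param identity_branch include the identity branch.
#' @param bias convolution bias flag.
#' @param stride convolution stride; only 1 is allowed together with the
#'   identity branch (spatial mismatch at the concat otherwise).
#' @param input_size spatial side for MAC accounting.
#' @return a \code{\linkS4class{LayerGraph}} wrapping the fragment
#'   (classifier-free; for cost inspection use \code{costReport}).
#' @export
buildTbpBlock <- function(in_channels, channels = in_channels,
                          kernels = c(3L, 3L), identity_branch = TRUE,
                          bias = FALSE, stride = 1L, input_size = 32L) {
  stopifnot(in_channels > 0)
  if (stride != 1L && identity_branch)
    stop("stride != 1 with an identity branch: spatial mismatch at concat")
  cfg <- list(tbp_kernels = as.integer(kernels),
              tbp_identity = identity_branch, conv_bias = bias)
  e <- .gb_new()
  inp <- .gb_add(e, layerRow("input", "input", in_channels, in_channels))
  tb <- .add_tbp(e, inp, in_channels, cfg, channels)
  w <- tb$width
  fl <- .gb_add(e, layerRow(.gb_id(e, "flatten"), "flatten", w, w,
                            preds = tb$id))
  cl <- .gb_add(e, layerRow("classifier", "dense", w * input_size^2, 2L,
                            bias = FALSE, preds = fl, section = "head"))
  .gb_add(e, layerRow("output", "output", 2L, 2L, preds = cl,
                      section = "head"))
  newLayerGraph(.gb_table(e), "input", "output", input_size, 2L)
}

#' Build a standalone squeeze-excitation gate as a LayerGraph fragment
#'
#' Global average pool, a single dense layer (width-preserving, as the
#' family uses it), sigmoid, channel-wise multiply with the block input.
#'
#' @param channels feature width.
#' @param input_size spatial side for MAC accounting.
#' @return a \code{\linkS4class{LayerGraph}} wrapping the fragment.
#' @export
buildSeBlock <- function(channels, input_size = 8L) {
  stopifnot(channels > 0)
  e <- .gb_new()
  inp <- .gb_add(e, layerRow("input", "input", channels, channels))
  x <- .add_se(e, inp, channels)
  fl <- .gb_add(e, layerRow(.gb_id(e, "flatten"), "flatten", channels,
                            channels, preds = x))
  cl <- .gb_add(e, layerRow("classifier", "dense", channels * input_size^2,
                            2L, bias = FALSE, preds = fl, section = "head"))
  .gb_add(e, layerRow("output", "output", 2L, 2L, preds = cl,
                      section = "head"))
  newLayerGraph(.gb_table(e), "input", "output", input_size, 2L)
}

#' Build the OMNet baseline classifier
#'
#' Stem (one 3x3 stride-2 convolution followed by 2x2 max pooling, so the
#' feature map entering the main structure is a quarter of the input side),
#' then four stages of TBP block(s) -> 3x3 fusion convolution -> residual
#' unit(s), with SE gates on the configured stages and two TBP blocks in
#' stage 4; finally a 1x1 head convolution, adaptive average pooling,
#' flatten and a dense classifier.  The stem is outside the compressed
#' feature extractor: it is pruned but never depthwise-converted, and it
#' is shared when paths are expanded.
#'
#' @param cfg an \code{\link{omnetConfig}}.
#' @return a \code{\linkS4class{LayerGraph}}.
#' @export
buildOMNet <- function(cfg = omnetConfig()) {
  e <- .gb_new()
  inp <- .gb_add(e, layerRow("input", "input", 3L, 3L, section = "stem"))
  x <- .gb_conv(e, inp, 3L, cfg$stem_channels, 3L, stride = 2L,
                padding = 1L, bias = TRUE, section = "stem",
                convertible = FALSE, prefix = "stem_conv")
  x <- .gb_add(e, layerRow(.gb_id(e, "stem_pool"), "maxpool",
                           cfg$stem_channels, cfg$stem_channels, kernel = 2L,
                           stride = 2L, preds = x, section = "stem"))
  width <- cfg$stem_channels
  for (s in 1:4) {
    bw <- function(w) if (cfg$tbp_width == "input") w else max(1L, w %/% 2L)
    tb <- .add_tbp(e, x, width, cfg, bw(width))
    x <- tb$id; w <- tb$width
    if (s == 4L && cfg$tbp_repeats_stage4 >= 2L) {
      for (rep2 in seq_len(cfg$tbp_repeats_stage4 - 1L)) {
        t2 <- switch(cfg$tbp2_width, concat = w, input = width,
                     branch = bw(width))
        tb <- .add_tbp(e, x, w, cfg, t2)
        x <- tb$id; w <- tb$width
      }
    }
    x <- .gb_conv(e, x, w, cfg$stage_widths[s], 3L,
                  stride = cfg$stage_strides[s], bias = cfg$conv_bias,
                  prefix = sprintf("stage%d_conv", s))
    x <- .gb_bn(e, x, cfg$stage_widths[s])
    x <- .gb_relu(e, x, cfg$stage_widths[s])
    for (r in seq_len(cfg$residual_repeats[s]))
      x <- .add_residual(e, x, cfg$stage_widths[s], cfg$conv_bias)
    if (s %in% cfg$se_stages) x <- .add_se(e, x, cfg$stage_widths[s])
    width <- cfg$stage_widths[s]
  }
  x <- .gb_conv(e, x, width, cfg$head_channels, 1L, bias = cfg$conv_bias,
                prefix = "head_conv")
  if (cfg$head_bn) x <- .gb_bn(e, x, cfg$head_channels)
  x <- .gb_add(e, layerRow(.gb_id(e, "head_pool"), "adaptivepool",
                           cfg$head_channels, cfg$head_channels,
                           kernel = cfg$pool_output, preds = x))
  x <- .gb_add(e, layerRow(.gb_id(e, "head_flat"), "flatten",
                           cfg$head_channels,
                           cfg$head_channels * cfg$pool_output^2, preds = x))
  x <- .gb_add(e, layerRow("classifier", "dense",
                           cfg$head_channels * cfg$pool_output^2,
                           cfg$num_classes, bias = TRUE, preds = x,
                           section = "head"))
  out <- .gb_add(e, layerRow("output", "output", cfg$num_classes,
                             cfg$num_classes, preds = x, section = "head"))
  g <- newLayerGraph(.gb_table(e), "input", "output", cfg$input_size,
                     cfg$num_classes)
  g <- .repropagate(g)   # fills derived widths (flatten etc.) consistently
  g
}

#' Build LMNet: the compressed two-path derivative of OMNet
#'
#' Equals \code{applyLmpPm(buildOMNet(cfg), N = 4, E = 2)} with the stem
#' shared across both paths: global channel pruning by 4, depthwise
#' conversion of the feature extractor, and two structurally identical
#' parallel paths concatenated under a single classifier.
#'
#' @param cfg an \code{\link{omnetConfig}} for the baseline.
#' @param N pruning divisor (default 4).
#' @param E path count (default 2).
#' @return a \code{\linkS4class{LayerGraph}}.
#' @export
buildLMNet <- function(cfg = omnetConfig(), N = 4L, E = 2L) {
  applyLmpPm(buildOMNet(cfg), N = N, E = E, convert = TRUE,
             shared_stem = TRUE)
}

#' Desk-scale OMNet configuration for smoke training
#'
#' A small member of the OMNet family sized for CPU training on the
#' synthetic leaf sets: 16-channel stem, stage widths 16/16/32/32, no
#' residual repeats, a 256-wide head pooled to 2x2.  Its N=2, E=2
#' derivative (\code{buildLMNet(omnetTinyConfig(), N = 2, E = 2)}) is the
#' "smallest LMNet-style" model the smoke tests train.
#'
#' @param num_classes classifier width.
#' @param input_size input resolution (default 64).
#' @return an \code{\link{omnetConfig}}.
#' @export
omnetTinyConfig <- function(num_classes = 4L, input_size = 64L) {
  omnetConfig(stem_channels = 16L, stage_widths = c(16L, 16L, 32L, 32L),
              residual_repeats = c(0L, 0L, 0L, 0L), head_channels = 256L,
              pool_output = 2L, num_classes = num_classes,
              input_size = input_size)
}
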