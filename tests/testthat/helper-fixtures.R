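## Small graphs and datasets shared across test files.

tiny_omnet_cfg <- function(classes = 4L, input = 32L)
  omnetConfig(stem_channels = 8L, stage_widths = c(8L, 8L, 16L, 16L),
              residual_repeats = c(0L, 0L, 0L, 0L), head_channels = 32L,
              num_classes = classes, input_size = input)

## a minimal plain conv net: input -> conv3x3 -> bn -> relu -> conv3x3 ->
## gap -> flatten -> dense
chain_graph <- function(widths = c(8L, 16L), classes = 3L, input = 16L,
                        bias = FALSE) {
  rows <- list(lmppm:::layerRow("input", "input", 3L, 3L, section = "stem"))
  from <- "input"; inc <- 3L; i <- 0L
  for (w in widths) {
    i <- i + 1L
    cid <- sprintf("conv%d", i)
    rows <- c(rows, list(
      lmppm:::layerRow(cid, "conv", inc, w, 3L, padding = 1L, bias = bias,
                       preds = from),
      lmppm:::layerRow(sprintf("bn%d", i), "batchnorm", w, w, preds = cid),
      lmppm:::layerRow(sprintf("relu%d", i), "relu", w, w,
                       preds = sprintf("bn%d", i))))
    from <- sprintf("relu%d", i); inc <- w
  }
  rows <- c(rows, list(
    lmppm:::layerRow("gap", "globalavgpool", inc, inc, preds = from),
    lmppm:::layerRow("flat", "flatten", inc, inc, preds = "gap"),
    lmppm:::layerRow("classifier", "dense", inc, classes, bias = TRUE,
                     preds = "flat", section = "head"),
    lmppm:::layerRow("output", "output", classes, classes,
                     preds = "classifier", section = "head")))
  lmppm:::newLayerGraph(do.call(rbind, rows), "input", "output", input, classes)
}

## brute-force parameter oracle: instantiate weights and count elements
oracle_params <- function(g) {
  sum(enumerateWeights(initWeights(g, 1L))$count)
}

## brute-force confusion-matrix oracle by exhaustive pair counting
oracle_confusion <- function(labels, predicted, K) {
  cm <- matrix(0L, K, K)
  for (i in seq_along(labels))
    for (t in 1:K) for (p in 1:K)
      if (labels[i] == t && predicted[i] == p) cm[t, p] <- cm[t, p] + 1L
  cm
}

small_leaf_dir <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      d <- file.path(tempdir(), "lmppm_leaves_small")
      if (!dir.exists(d))
        generateLeafDataset(leafSpec(n_classes = 3L, images_per_class = 10L,
                                     image_size = 32L, seed = 11L), d)
      cache <<- d
    }
    cache
  }
})
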