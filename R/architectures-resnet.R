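## Canonical 101-layer bottleneck residual classifier (He et al. 2016
## configuration), used to demonstrate that the compression pipeline
## generalizes beyond the OMNet family.

## Mutable builder state: an environment holding the growing layer table
## and a name counter.  All builders in the package share these helpers.
.gb_new <- function() {
  e <- new.env(parent = emptyenv())
  e$rows <- list(); e$n <- 0L
  e
}
.gb_add <- function(e, row) {
  e$rows[[length(e$rows) + 1L]] <- row
  row$id
}
.gb_id <- function(e, prefix) {
  e$n <- e$n + 1L
  sprintf("%s_%03d", prefix, e$n)
}
.gb_table <- function(e) do.call(rbind, e$rows)

.gb_conv <- function(e, from, inc, outc, k, stride = 1L, padding = (k - 1L) %/% 2L,
                     bias = FALSE, section = "features", convertible = TRUE,
                     prefix = "conv") {
  .gb_add(e, layerRow(.gb_id(e, prefix), "conv", inc, outc, k, stride,
                      padding, bias = bias, preds = from, section = section,
                      convertible = convertible))
}
.gb_bn <- function(e, from, c, section = "features") {
  .gb_add(e, layerRow(.gb_id(e, "bn"), "batchnorm", c, c, preds = from,
                      section = section))
}
.gb_relu <- function(e, from, c, section = "features") {
  .gb_add(e, layerRow(.gb_id(e, "relu"), "relu", c, c, preds = from,
                      section = section))
}

#' Build the canonical 101-layer bottleneck residual classifier
#'
#' The standard deep residual network of depth 101: a 7x7 stride-2 stem
#' convolution, 3x3 stride-2 max pooling, four stages of 3/4/23/3
#' bottleneck units with mid-widths 64/128/256/512 (output expansion 4),
#' batch normalization after every convolution, bias-free convolutions,
#' global average pooling and a dense classifier.  With a 1000-way head
#' this counts 44,549,160 parameters.
#'
#' @param num_classes classifier width (>= 2).
#' @param input_size input resolution (default 224).
#' @return a \code{\linkS4class{LayerGraph}}.
#' @examples
#' formatMillions(countParams(buildResNet101(61)))   # "42.63"
#' @export
buildResNet101 <- function(num_classes, input_size = 224L) {
  stopifnot(num_classes >= 2)
  e <- .gb_new()
  inp <- .gb_add(e, layerRow("input", "input", 3L, 3L, section = "stem"))
  x <- .gb_conv(e, inp, 3L, 64L, 7L, stride = 2L, padding = 3L,
                section = "stem", prefix = "stem_conv")
  x <- .gb_bn(e, x, 64L, section = "stem")
  x <- .gb_relu(e, x, 64L, section = "stem")
  x <- .gb_add(e, layerRow(.gb_id(e, "maxpool"), "maxpool", 64L, 64L,
                           kernel = 3L, stride = 2L, padding = 1L,
                           preds = x, section = "stem"))
  cin <- 64L
  reps <- c(3L, 4L, 23L, 3L); mids <- c(64L, 128L, 256L, 512L)
  for (s in 1:4) {
    mid <- mids[s]; outc <- mid * 4L
    for (r in seq_len(reps[s])) {
      stride <- if (r == 1L && s > 1L) 2L else 1L
      skip_from <- x
      y <- .gb_conv(e, x, cin, mid, 1L); y <- .gb_bn(e, y, mid)
      y <- .gb_relu(e, y, mid)
      y <- .gb_conv(e, y, mid, mid, 3L, stride = stride)
      y <- .gb_bn(e, y, mid); y <- .gb_relu(e, y, mid)
      y <- .gb_conv(e, y, mid, outc, 1L); y <- .gb_bn(e, y, outc)
      if (r == 1L) {
        sk <- .gb_conv(e, skip_from, cin, outc, 1L, stride = stride,
                       prefix = "proj")
        sk <- .gb_bn(e, sk, outc)
      } else sk <- skip_from
      x <- .gb_add(e, layerRow(.gb_id(e, "add"), "add", outc, outc,
                               preds = c(y, sk)))
      x <- .gb_relu(e, x, outc)
      cin <- outc
    }
  }
  x <- .gb_add(e, layerRow(.gb_id(e, "gap"), "globalavgpool", cin, cin,
                           preds = x))
  x <- .gb_add(e, layerRow(.gb_id(e, "flatten"), "flatten", cin, cin,
                           preds = x))
  x <- .gb_add(e, layerRow("classifier", "dense", cin, num_classes,
                           bias = TRUE, preds = x, section = "head"))
  out <- .gb_add(e, layerRow("output", "output", num_classes, num_classes,
                             preds = x, section = "head"))
  g <- newLayerGraph(.gb_table(e), "input", "output", input_size, num_classes)
  validObject(g)
  g
}
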