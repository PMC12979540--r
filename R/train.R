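## Training recipe and evaluation harness.  Defaults follow the study
## conditions: AdamW, learning rate 1e-4, weight decay 5e-2, cross-entropy,
## 100 epochs (overridable for smoke runs), batch 32, no pre-trained
## weights; augmentations are random resized crop, random rotation in
## [-10, 10] degrees, horizontal flip with probability 0.5, and plain
## scaling of pixel values to [0, 1] (no mean/std standardization).

#' Training configuration
#'
#' @param lr learning rate.
#' @param weight_decay decoupled weight decay.
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param augment apply the standard augmentations to training images.
#' @param rotation max absolute rotation in degrees.
#' @param crop_scale min area fraction for the random resized crop.
#' @param seed integer seed controlling all randomness.
#' @return a \code{trainConfig} list.
#' @export
trainConfig <- function(lr = 1e-4, weight_decay = 5e-2, epochs = 100L,
                        batch_size = 32L, augment = TRUE, rotation = 10,
                        crop_scale = 0.7, seed = 1L) {
  structure(list(lr = lr, weight_decay = weight_decay,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), augment = augment,
                 rotation = rotation, crop_scale = crop_scale,
                 seed = as.integer(seed), optimizer = "adamw",
                 loss = "cross-entropy"),
            class = "trainConfig")
}

#' @rdname trainConfig
#' @param path YAML file.
#' @export
writeTrainConfig <- function(x, path) {
  yaml::write_yaml(unclass(x), path); invisible(path)
}

#' @rdname trainConfig
#' @export
readTrainConfig <- function(path) {
  v <- yaml::read_yaml(path)
  cfg <- trainConfig()
  for (nm in names(v)) cfg[[nm]] <- v[[nm]]
  cfg$epochs <- as.integer(cfg$epochs)
  cfg$batch_size <- as.integer(cfg$batch_size)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

.list_split <- function(data_dir, split) {
  d <- file.path(data_dir, split)
  if (!dir.exists(d)) stop(sprintf("missing split directory '%s'", d))
  classes <- sort(list.dirs(d, recursive = FALSE, full.names = FALSE))
  if (!length(classes)) stop(sprintf("no class folders under '%s'", d))
  files <- lapply(classes, function(cl)
    sort(list.files(file.path(d, cl), pattern = "\\.png$", full.names = TRUE)))
  if (any(lengths(files) == 0L))
    stop(sprintf("empty class folder in split '%s'", split))
  data.frame(path = unlist(files),
             label = rep(seq_along(classes), lengths(files)),
             class = rep(classes, lengths(files)),
             stringsAsFactors = FALSE)
}

.nn_resize <- function(img, size) {
  d <- dim(img)
  ix <- pmin(d[1], pmax(1L, round(seq(1, d[1], length.out = size))))
  iy <- pmin(d[2], pmax(1L, round(seq(1, d[2], length.out = size))))
  img[ix, iy, , drop = FALSE]
}

.rotate_nn <- function(img, deg) {
  if (abs(deg) < 1e-8) return(img)
  d <- dim(img); n <- d[1]
  th <- deg * pi / 180
  c0 <- (n + 1) / 2
  gx <- matrix(seq_len(n) - c0, n, n)
  gy <- matrix(seq_len(n) - c0, n, n, byrow = TRUE)
  sx <- pmin(n, pmax(1L, round(c0 + gx * cos(th) - gy * sin(th))))
  sy <- pmin(n, pmax(1L, round(c0 + gx * sin(th) + gy * cos(th))))
  idx <- cbind(as.vector(sx), as.vector(sy))
  out <- img
  for (ch in seq_len(d[3])) {
    m <- img[, , ch]
    out[, , ch] <- matrix(m[idx], n, n)
  }
  out
}

.augment_img <- function(img, size, cfg) {
  d <- dim(img)
  ## random resized crop
  ar <- stats::runif(1, 3 / 4, 4 / 3)
  area <- stats::runif(1, cfg$crop_scale, 1) * d[1] * d[2]
  ch <- round(sqrt(area / ar)); cw <- round(sqrt(area * ar))
  ch <- min(ch, d[1]); cw <- min(cw, d[2])
  ox <- sample.int(d[1] - ch + 1L, 1L); oy <- sample.int(d[2] - cw + 1L, 1L)
  img <- img[ox:(ox + ch - 1L), oy:(oy + cw - 1L), , drop = FALSE]
  img <- .nn_resize(img, size)
  img <- .rotate_nn(img, stats::runif(1, -cfg$rotation, cfg$rotation))
  if (stats::runif(1) < 0.5) img <- img[, rev(seq_len(dim(img)[2])), , drop = FALSE]
  img
}

.load_batch <- function(rows, size, cfg = NULL) {
  B <- nrow(rows)
  x <- array(0, dim = c(size, size, 3, B))
  for (i in seq_len(B)) {
    img <- png::readPNG(rows$path[i])
    if (length(dim(img)) == 2L) img <- array(rep(img, 3), dim = c(dim(img), 3))
    img <- img[, , 1:3, drop = FALSE]
    img <- if (!is.null(cfg) && cfg$augment) .augment_img(img, size, cfg)
           else .nn_resize(img, size)
    x[, , , i] <- img
  }
  x
}

#' Train a network on an image-folder dataset
#'
#' Runs the standard recipe on \code{data_dir} (expected to contain
#' \code{train/<class>/} and \code{val/<class>/} PNG folders, as produced
#' by \code{\link{generateLeafDataset}}).  Logs per-epoch train/val loss
#' and accuracy to \code{log.csv} in \code{run_dir} and keeps the weights
#' of the best validation accuracy.  Fully seeded: identical seed and data
#' give identical epoch-0 loss.
#'
#' @param g a \code{LayerGraph}.
#' @param data_dir dataset root.
#' @param cfg a \code{\link{trainConfig}}.
#' @param run_dir output directory for the log (default: tempdir subdir).
#' @param input_size image side fed to the network (defaults to the
#'   graph's input size).
#' @param weights optional starting weights (default: fresh init, i.e. no
#'   pre-training).
#' @return list: \code{weights} (best-validation), \code{final_weights},
#'   \code{log} (data.frame), \code{classes}, \code{run_dir}.
#' @export
trainNetwork <- function(g, data_dir, cfg = trainConfig(), run_dir = NULL,
                         input_size = inputSize(g), weights = NULL) {
  if (is.null(run_dir)) run_dir <- file.path(tempdir(), "lmp_run")
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  tr <- .list_split(data_dir, "train")
  va <- .list_split(data_dir, "val")
  if (!identical(sort(unique(tr$class)), sort(unique(va$class))))
    stop("class mismatch between train and val splits")
  n_classes <- max(tr$label)
  if (n_classes != numClasses(g))
    stop(sprintf("data has %d classes but the model head has %d",
                 n_classes, numClasses(g)))
  set.seed(cfg$seed)
  if (is.null(weights)) weights <- initWeights(g, seed = cfg$seed)
  state <- NULL
  log <- data.frame(epoch = integer(), train_loss = numeric(),
                    train_acc = numeric(), val_loss = numeric(),
                    val_acc = numeric())
  utils::write.csv(log, file.path(run_dir, "log.csv"), row.names = FALSE)
  best <- list(acc = -Inf, weights = weights)
  if (cfg$epochs == 0L)
    return(list(weights = weights, final_weights = weights, log = log,
                classes = sort(unique(tr$class)), run_dir = run_dir))
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(nrow(tr))
    bs <- cfg$batch_size
    tl <- 0; tc <- 0L
    for (b0 in seq(1L, nrow(tr), by = bs)) {
      rows <- tr[ord[b0:min(b0 + bs - 1L, nrow(tr))], , drop = FALSE]
      x <- .load_batch(rows, input_size, cfg)
      fw <- forwardPass(g, weights, x, training = TRUE, keep_cache = TRUE)
      weights <- fw$weights
      ls <- softmaxCrossEntropy(fw$logits, rows$label)
      gr <- backwardPass(g, weights, fw, ls$dlogits)
      st <- adamwStep(weights, gr, state, lr = cfg$lr, wd = cfg$weight_decay)
      weights <- st$weights; state <- st$state
      tl <- tl + ls$loss * nrow(rows)
      tc <- tc + sum(apply(ls$probs, 2L, which.max) == rows$label)
    }
    ev <- .eval_split(g, weights, va, input_size)
    log <- rbind(log, data.frame(epoch = ep, train_loss = tl / nrow(tr),
                                 train_acc = tc / nrow(tr),
                                 val_loss = ev$loss, val_acc = ev$acc))
    utils::write.csv(log, file.path(run_dir, "log.csv"), row.names = FALSE)
    if (ev$acc >= best$acc) best <- list(acc = ev$acc, weights = weights)
  }
  list(weights = best$weights, final_weights = weights, log = log,
       classes = sort(unique(tr$class)), run_dir = run_dir)
}

.eval_split <- function(g, weights, rows, input_size, batch = 32L) {
  loss <- 0; correct <- 0L
  scores <- matrix(0, numClasses(g), nrow(rows))
  for (b0 in seq(1L, nrow(rows), by = batch)) {
    sel <- b0:min(b0 + batch - 1L, nrow(rows))
    x <- .load_batch(rows[sel, , drop = FALSE], input_size)
    fw <- forwardPass(g, weights, x, training = FALSE)
    ls <- softmaxCrossEntropy(fw$logits, rows$label[sel])
    loss <- loss + ls$loss * length(sel)
    scores[, sel] <- ls$probs
    correct <- correct + sum(apply(ls$probs, 2L, which.max) == rows$label[sel])
  }
  list(loss = loss / nrow(rows), acc = correct / nrow(rows), scores = scores)
}

#' Evaluate a trained network on a dataset split
#'
#' @param g a \code{LayerGraph}.
#' @param weights weight list.
#' @param data_dir dataset root.
#' @param split \code{"test"}, \code{"val"} or \code{"train"}.
#' @param input_size image side (defaults to the graph's).
#' @param average macro (default) or micro metric averaging.
#' @return a \code{\linkS4class{MetricsReport}}.
#' @export
evaluateNetwork <- function(g, weights, data_dir, split = "test",
                            input_size = inputSize(g),
                            average = c("macro", "micro")) {
  rows <- .list_split(data_dir, split)
  if (max(rows$label) != numClasses(g))
    stop("class present in data but absent from the model head")
  ev <- .eval_split(g, weights, rows, input_size)
  pred <- apply(ev$scores, 2L, which.max)
  classificationMetrics(rows$label, pred, ev$scores,
                        n_classes = numClasses(g),
                        average = match.arg(average))
}

#' Transform/train/evaluate over a grid of (N, E)
#'
#' For each pair: apply the compression pipeline to \code{base}, count
#' costs, train with \code{cfg}, evaluate on the test split, and collect a
#' table shaped like the study's comparison tables.
#'
#' @param base baseline \code{LayerGraph}.
#' @param N_values,E_values integer vectors.
#' @param data_dir dataset root.
#' @param cfg a \code{\link{trainConfig}}.
#' @param input_size image side for training/eval.
#' @param convert apply depthwise conversion (default TRUE).
#' @return data.frame: N, E, test_acc, precision, recall, f1, parameters,
#'   flops.
#' @export
gridExperiment <- function(base, N_values, E_values, data_dir,
                           cfg = trainConfig(), input_size = inputSize(base),
                           convert = TRUE) {
  out <- list()
  for (N in N_values) for (E in E_values) {
    gg <- applyLmpPm(base, N = N, E = E, convert = convert)
    cr <- costReport(gg)
    tr <- trainNetwork(gg, data_dir, cfg, input_size = input_size)
    mr <- evaluateNetwork(gg, tr$weights, data_dir, "test", input_size)
    out[[length(out) + 1L]] <- data.frame(
      N = N, E = E, test_acc = mr@accuracy, precision = mr@macro_precision,
      recall = mr@macro_recall, f1 = mr@macro_f1,
      parameters = cr@param_count, flops = cr@mac_count)
  }
  do.call(rbind, out)
}
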