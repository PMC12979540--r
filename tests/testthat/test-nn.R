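test_that("analytic gradients match numeric differentiation", {
  set.seed(42)
  cfg <- omnetConfig(stem_channels = 4L, stage_widths = c(4L, 4L, 6L, 6L),
                     residual_repeats = c(1L, 0L, 0L, 0L),
                     head_channels = 8L, num_classes = 3L, input_size = 16L)
  g <- toDepthwiseSeparable(buildOMNet(cfg))   # covers dw convs too
  w <- initWeights(g, 3)
  x <- array(stats::runif(16 * 16 * 3 * 2), dim = c(16, 16, 3, 2))
  lab <- c(1L, 3L)
  lossAt <- function(w)
    softmaxCrossEntropy(forwardPass(g, w, x, training = TRUE)$logits, lab)$loss
  fw <- forwardPass(g, w, x, training = TRUE, keep_cache = TRUE)
  gr <- backwardPass(g, w, fw, softmaxCrossEntropy(fw$logits, lab)$dlogits)
  eps <- 1e-5
  ids <- sample(names(gr), 10L)
  for (id in ids) for (nm in names(gr[[id]])) {
    if (is.null(gr[[id]][[nm]])) next
    i <- sample(length(w[[id]][[nm]]), 1L)
    wp <- w; wp[[id]][[nm]][i] <- wp[[id]][[nm]][i] + eps
    wm <- w; wm[[id]][[nm]][i] <- wm[[id]][[nm]][i] - eps
    num <- (lossAt(wp) - lossAt(wm)) / (2 * eps)
    expect_equal(gr[[id]][[nm]][i], num, tolerance = 1e-3,
                 label = paste("grad", id, nm))
  }
})

test_that("softmax cross-entropy: loss value and gradient structure", {
  logits <- matrix(c(2, 0, -1, 0, 3, 0), 3, 2)
  ls <- softmaxCrossEntropy(logits, c(1L, 2L))
  p1 <- exp(2) / (exp(2) + 1 + exp(-1))
  p2 <- exp(3) / (1 + exp(3) + 1)
  expect_equal(ls$loss, -(log(p1) + log(p2)) / 2)
  expect_equal(colSums(ls$probs), c(1, 1))
  expect_equal(colSums(ls$dlogits), c(0, 0), tolerance = 1e-12)
})

test_that("AdamW decays weights but not biases or batchnorm parameters", {
  g <- chain_graph(widths = 4L, classes = 2L, bias = FALSE)
  w <- initWeights(g, 1)
  zero_gr <- list(conv1 = list(W = w$conv1$W * 0),
                  classifier = list(W = w$classifier$W * 0,
                                    b = w$classifier$b * 0),
                  bn1 = list(gamma = w$bn1$gamma * 0, beta = w$bn1$beta * 0))
  st <- adamwStep(w, zero_gr, lr = 0.1, wd = 0.5)
  expect_equal(st$weights$conv1$W, w$conv1$W * (1 - 0.1 * 0.5))
  expect_equal(st$weights$bn1$gamma, w$bn1$gamma)     # no decay
  expect_equal(st$weights$classifier$b, w$classifier$b)
})

test_that("zero-epoch training returns initial weights and an empty log", {
  d <- small_leaf_dir()
  g <- buildLMNet(tiny_omnet_cfg(classes = 3L, input = 32L), N = 2L, E = 2L)
  cfg <- trainConfig(epochs = 0L, seed = 5L)
  r <- trainNetwork(g, d, cfg)
  expect_equal(nrow(r$log), 0L)
  expect_identical(r$weights, initWeights(g, seed = 5L))
})

test_that("identical seeds reproduce the epoch-0 loss exactly", {
  d <- small_leaf_dir()
  g <- buildLMNet(tiny_omnet_cfg(classes = 3L, input = 32L), N = 2L, E = 2L)
  cfg <- trainConfig(epochs = 1L, seed = 21L, batch_size = 16L)
  r1 <- trainNetwork(g, d, cfg)
  r2 <- trainNetwork(g, d, cfg)
  expect_identical(r1$log$train_loss[1], r2$log$train_loss[1])
  expect_identical(r1$log$val_loss[1], r2$log$val_loss[1])
})

test_that("training loss decreases over the first epochs on separable data", {
  d <- small_leaf_dir()
  g <- buildLMNet(tiny_omnet_cfg(classes = 3L, input = 32L), N = 2L, E = 2L)
  cfg <- trainConfig(epochs = 5L, seed = 3L, batch_size = 16L, lr = 3e-4)
  r <- trainNetwork(g, d, cfg)
  expect_lt(r$log$train_loss[5], r$log$train_loss[1])
  expect_true(file.exists(file.path(r$run_dir, "log.csv")))
})

test_that("evaluation produces a coherent report on a trained model", {
  d <- small_leaf_dir()
  g <- buildLMNet(tiny_omnet_cfg(classes = 3L, input = 32L), N = 2L, E = 2L)
  cfg <- trainConfig(epochs = 3L, seed = 3L, batch_size = 16L, lr = 3e-4)
  r <- trainNetwork(g, d, cfg)
  m <- evaluateNetwork(g, r$weights, d, "test", input_size = 32L)
  expect_s4_class(m, "MetricsReport")
  expect_equal(sum(m@confusion), 6L)      # 3 classes x 2 test images
  expect_true(m@accuracy >= 0 && m@accuracy <= 1)
  expect_length(m@roc, 3L)
})

test_that("training rejects mismatched heads and missing folders", {
  d <- small_leaf_dir()
  g <- buildLMNet(tiny_omnet_cfg(classes = 5L, input = 32L), N = 2L, E = 2L)
  expect_error(trainNetwork(g, d, trainConfig(epochs = 1L)), "classes")
  expect_error(trainNetwork(g, tempfile(), trainConfig(epochs = 1L)),
               "missing split")
})
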