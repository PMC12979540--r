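test_that("pruning divides widths with the C/N > 1 guard", {
  g <- chain_graph(widths = c(64L, 3L), classes = 3L)
  p <- pruneChannels(g, 4L)
  ly <- layerTable(p)
  expect_equal(ly$out_channels[ly$id == "conv1"], 16L)   # 64/4
  expect_equal(ly$out_channels[ly$id == "conv2"], 3L)    # 3/4 <= 1: untouched
  ## batchnorm widths and dense in-features repropagated
  expect_equal(ly$out_channels[ly$id == "bn1"], 16L)
  expect_equal(ly$in_channels[ly$id == "classifier"], 3L)
  ## classifier out is invariant
  expect_equal(ly$out_channels[ly$id == "classifier"], 3L)
  ## N = 1 is the identity
  expect_identical(layerTable(pruneChannels(g, 1L)), layerTable(g))
})

test_that("guard safety: no conv ever drops below width 1, others scale", {
  for (N in c(2L, 8L, 16L, 64L)) {
    p <- pruneChannels(buildResNet101(61), N)
    ly <- layerTable(p)
    expect_true(all(ly$out_channels[ly$kind == "conv"] >= 1L))
    base <- layerTable(buildResNet101(61))
    unpruned <- base$out_channels / N <= 1
    expect_equal(ly$out_channels[base$kind == "conv" & unpruned],
                 base$out_channels[base$kind == "conv" & unpruned])
  }
})

test_that("depthwise conversion arithmetic and scope", {
  ## 3x3 conv 64 -> 128 bias-free: 73728 -> 9*64 + 64*128 = 8768
  g <- chain_graph(widths = c(64L, 128L), classes = 2L)
  before <- costReport(g)@per_layer
  expect_equal(before$params[before$id == "conv2"], 73728)
  cg <- toDepthwiseSeparable(g)
  after <- costReport(cg)@per_layer
  expect_equal(after$params[after$id == "conv2_dw"], 9 * 64)
  expect_equal(after$params[after$id == "conv2"], 64 * 128)
  ## no batchnorm inserted inside the pair
  ly <- layerTable(cg)
  expect_false(any(grepl("conv2.*bn", ly$id)))
  ## 1x1 convs stay: resnet projection shortcuts survive conversion
  rg <- toDepthwiseSeparable(buildResNet101(61))
  rly <- layerTable(rg)
  expect_true(all(rly$kernel[rly$kind == "conv" & rly$groups == 1L] == 1L |
                  !rly$convertible[rly$kind == "conv" & rly$groups == 1L]))
  ## the 7x7 stem of the residual network is converted
  expect_true("stem_conv_001_dw" %in% rly$id)
  ## depthwise stage keeps stride/padding; pointwise is stride 1
  expect_equal(rly$stride[rly$id == "stem_conv_001_dw"], 2L)
  expect_equal(rly$stride[rly$id == "stem_conv_001"], 1L)
  ## grouped (non-depthwise) convs are rejected
  bad <- g
  bly <- layerTable(bad)
  bly$groups[bly$id == "conv2"] <- 2L
  bad@layers <- bly
  expect_error(toDepthwiseSeparable(bad), "unsupported grouped")
})

test_that("expansion: E = 1 identity, E-fold structure, fresh shared head", {
  g <- toDepthwiseSeparable(pruneChannels(buildResNet101(61), 4L))
  expect_identical(layerTable(expandPaths(g, 1L)), layerTable(g))
  e3 <- expandPaths(g, 3L, shared_stem = FALSE)
  ly <- layerTable(e3)
  expect_equal(max(ly$path), 3L)
  ## classifier input width is E-fold
  expect_equal(ly$in_channels[ly$id == "classifier"],
               3L * layerTable(g)$in_channels[layerTable(g)$id == "classifier"])
  expect_equal(numClasses(e3), 61L)
  expect_error(expandPaths(g, 0L), "E must be")
})

test_that("parameter counts are monotone: non-increasing in N, increasing in E", {
  g <- buildResNet101(61)
  pN <- vapply(c(1L, 2L, 4L, 8L, 16L),
               function(N) countParams(applyLmpPm(g, N, 1L)), 0)
  expect_true(all(diff(pN) < 0))
  pE <- vapply(1:4, function(E) countParams(applyLmpPm(g, 4L, E)), 0)
  expect_true(all(diff(pE) > 0))
  ## affine in E: constant per-path increment for E >= 2
  expect_equal(diff(pE)[2], diff(pE)[3])
})

test_that("pre-reinitialization path equality holds on random inputs", {
  cfg <- tiny_omnet_cfg(classes = 3L, input = 32L)
  g1 <- toDepthwiseSeparable(pruneChannels(buildOMNet(cfg), 2L))
  w1 <- initWeights(g1, 9)
  g2 <- expandPaths(g1, 3L, shared_stem = TRUE, weights = w1, reinit = FALSE)
  w2 <- attr(g2, "weights")
  set.seed(1)
  x <- array(stats::runif(32 * 32 * 3 * 2), dim = c(32, 32, 3, 2))
  fw <- forwardPass(g2, w2, x, training = FALSE, keep_cache = TRUE)
  ly <- layerTable(g2)
  tails <- ly$predecessors[ly$id == "path_concat"]
  tails <- strsplit(tails, ",")[[1]]
  f1 <- fw$acts[[tails[1]]]
  for (t in tails[-1]) expect_equal(fw$acts[[t]], f1, tolerance = 0)
  ## with reinitialization the copies diverge
  g3 <- expandPaths(g1, 2L, shared_stem = TRUE, weights = w1, reinit = TRUE,
                    seed = 4L)
  w3 <- attr(g3, "weights")
  fw3 <- forwardPass(g3, w3, x, training = FALSE, keep_cache = TRUE)
  t3 <- strsplit(layerTable(g3)$predecessors[layerTable(g3)$id == "path_concat"], ",")[[1]]
  expect_gt(max(abs(fw3$acts[[t3[1]]] - fw3$acts[[t3[2]]])), 0)
})

test_that("the full pipeline composes prune -> convert -> expand", {
  g <- buildResNet101(61)
  direct <- expandPaths(toDepthwiseSeparable(pruneChannels(g, 4L)), 4L,
                        shared_stem = FALSE)
  via <- applyLmpPm(g, 4L, 4L)
  expect_equal(countParams(via), countParams(direct))
  expect_equal(formatMillions(countParams(via)), "6.16")
})

test_that("transform report cross-checks against the weight-element oracle", {
  g <- buildResNet101(61)
  t <- applyLmpPm(g, 8L, 2L)
  rep <- transformReport(g, t)
  expect_equal(rep@params_after, countParams(t))
  expect_equal(rep@params_after, oracle_params(t))
  expect_equal(rep@paths, 2L)
  expect_gt(rep@params_before, rep@params_after)
})
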