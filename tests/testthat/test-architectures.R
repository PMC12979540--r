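test_that("the 101-layer bottleneck classifier matches canonical counts", {
  expect_equal(countParams(buildResNet101(1000)), 44549160)
  g61 <- buildResNet101(61)
  ## head swap arithmetic from the canonical 1000-class total
  expect_equal(countParams(g61),
               44549160 - (2048 * 1000 + 1000) + (2048 * 61 + 61))
  expect_equal(formatMillions(countParams(g61)), "42.63")
  ## independent brute-force weight-element oracle
  expect_equal(oracle_params(g61), countParams(g61))
})

test_that("TBP block arithmetic: concat width and branch parameter sums", {
  g <- buildTbpBlock(8L, bias = FALSE)
  ly <- layerTable(g)
  cat_row <- ly[ly$kind == "concat", ]
  expect_equal(cat_row$out_channels, 3L * 8L)   # 2 conv branches + identity
  ## branch 1 (first conv triplet + its batchnorm), C = 8, bias-free:
  ## 1*8*8 + 9*8*8 + 1*8*8 + 2*8 = 720
  pl <- costReport(g)@per_layer
  b1 <- pl[pl$id %in% c("tbp_c1_001", "tbp_mid_002", "tbp_c3_003", "bn_004"), ]
  expect_equal(sum(b1$params), 720)
  ## stride != 1 with identity branch is rejected
  expect_error(buildTbpBlock(8L, stride = 2L), "spatial mismatch")
})

test_that("identity-normalization batchnorm reduces a TBP branch to plain relu", {
  g <- buildTbpBlock(4L, kernels = 3L, identity_branch = FALSE, bias = FALSE,
                     input_size = 6L)
  w <- initWeights(g, 5)
  ## gamma=1, beta=0, mean=0, var=1 is exactly the initial state; eval mode
  x <- array(stats::rnorm(6 * 6 * 4 * 2), dim = c(6, 6, 4, 2))
  fw <- forwardPass(g, w, x, training = FALSE, keep_cache = TRUE)
  pre_bn <- fw$acts[["tbp_c3_003"]]
  post <- fw$acts[[layerTable(g)$id[layerTable(g)$kind == "relu"][1]]]
  ## equality up to the batchnorm epsilon (exact in the eps -> 0 limit)
  expect_equal(post, pmax(pre_bn, 0), tolerance = 1e-4)
})

test_that("SE block: parameter count, gating bounds, zero fixed point", {
  g <- buildSeBlock(16L)
  pl <- costReport(g)@per_layer
  se_fc <- pl[grepl("se_fc", pl$id), ]
  expect_equal(se_fc$params, 16 * 16 + 16)      # 272
  w <- initWeights(g, 2)
  x <- array(stats::runif(8 * 8 * 16 * 2), dim = c(8, 8, 16, 2))
  fw <- forwardPass(g, w, x, keep_cache = TRUE)
  ly <- layerTable(g)
  gate <- fw$acts[[ly$id[ly$kind == "sigmoid"]]]
  expect_true(all(gate > 0 & gate < 1))
  out <- fw$acts[[ly$id[ly$kind == "multiply"]]]
  ## output = input * gate, within sigmoid range of the input
  expect_true(all(abs(out) <= abs(x) + 1e-12))
  ## zero input -> zero output (multiplicative gating)
  fw0 <- forwardPass(g, w, x * 0, keep_cache = TRUE)
  expect_equal(max(abs(fw0$acts[[ly$id[ly$kind == "multiply"]]])), 0)
})

test_that("OMNet-family graphs are shape-sound end to end", {
  cfg <- tiny_omnet_cfg(classes = 5L, input = 32L)
  g <- buildOMNet(cfg)
  ## stem quarters the spatial size
  sh <- propagateShapes(g)
  expect_equal(sh$side[grepl("stem_pool", sh$id)], 8L)
  w <- initWeights(g, 1)
  x <- array(stats::runif(32 * 32 * 3 * 2), dim = c(32, 32, 3, 2))
  fw <- forwardPass(g, w, x, training = TRUE)
  expect_equal(dim(fw$logits), c(5L, 2L))
  expect_true(all(is.finite(fw$logits)))
  ## parameter oracle holds for the composite architecture too
  expect_equal(oracle_params(g), countParams(g))
})

test_that("LMNet is the two-path compressed rewrite with a shared stem", {
  cfg <- tiny_omnet_cfg()
  lm <- buildLMNet(cfg, N = 2L, E = 2L)
  ly <- layerTable(lm)
  expect_equal(max(ly$path), 2L)
  expect_true(all(ly$section[ly$path > 0] != "stem"))
  ## both paths are structurally identical
  p1 <- ly[ly$path == 1L, ]; p2 <- ly[ly$path == 2L, ]
  expect_equal(p1$kind, p2$kind)
  expect_equal(p1$out_channels, p2$out_channels)
  expect_equal(p1$kernel, p2$kernel)
  ## concat feeds the single classifier with 2x per-path features
  cat_w <- ly$out_channels[ly$id == "path_concat"]
  expect_equal(ly$in_channels[ly$id == "classifier"], cat_w)
  expect_equal(cat_w, 2L * p1$out_channels[p1$id == utils::tail(p1$id[p1$kind == "flatten"], 1)])
})
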