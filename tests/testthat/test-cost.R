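test_that("parameter formulas for each layer kind", {
  rows <- rbind(
    lmppm:::layerRow("input", "input", 3L, 3L),
    lmppm:::layerRow("c", "conv", 3L, 8L, 3L, padding = 1L, bias = TRUE,
                     preds = "input"),
    lmppm:::layerRow("b", "batchnorm", 8L, 8L, preds = "c"),
    lmppm:::layerRow("gap", "globalavgpool", 8L, 8L, preds = "b"),
    lmppm:::layerRow("f", "flatten", 8L, 8L, preds = "gap"),
    lmppm:::layerRow("classifier", "dense", 8L, 4L, bias = TRUE,
                     preds = "f", section = "head"),
    lmppm:::layerRow("output", "output", 4L, 4L, preds = "classifier",
                     section = "head"))
  g <- lmppm:::newLayerGraph(rows, "input", "output", 8L, 4L)
  pl <- costReport(g)@per_layer
  expect_equal(pl$params[pl$id == "c"], 9 * 3 * 8 + 8)
  expect_equal(pl$params[pl$id == "b"], 16)
  expect_equal(pl$params[pl$id == "classifier"], 8 * 4 + 4)
  expect_equal(pl$params[pl$kind %in% c("globalavgpool", "flatten")], c(0, 0))
})

test_that("dense layer example: 512 -> 61 with bias counts 31293", {
  g <- chain_graph(widths = 512L, classes = 61L)
  pl <- costReport(g)@per_layer
  expect_equal(pl$params[pl$id == "classifier"], 512 * 61 + 61)
})

test_that("MAC convention: conv scales with output area, dense with in*out", {
  ## 1x1 conv 8 -> 8 on a 4x4 map: 1*8*8*16 = 1024 MACs
  rows <- rbind(
    lmppm:::layerRow("input", "input", 8L, 8L),
    lmppm:::layerRow("c", "conv", 8L, 8L, 1L, preds = "input"),
    lmppm:::layerRow("f", "flatten", 8L, 8L, preds = "c"),
    lmppm:::layerRow("classifier", "dense", 8L * 16L, 2L, bias = TRUE,
                     preds = "f", section = "head"),
    lmppm:::layerRow("output", "output", 2L, 2L, preds = "classifier",
                     section = "head"))
  g <- lmppm:::newLayerGraph(rows, "input", "output", 4L, 2L)
  pl <- costReport(g)@per_layer
  expect_equal(pl$macs[pl$id == "c"], 1024)
  ## MAC/param consistency for a 1x1 conv: macs = weight params * H * W
  expect_equal(pl$macs[pl$id == "c"], pl$params[pl$id == "c"] * 16)
  expect_equal(pl$macs[pl$id == "classifier"], 8 * 16 * 2)
  ## parameter-free layers cost 0 MACs under the convention
  expect_true(all(pl$macs[pl$kind %in% c("flatten", "input", "output")] == 0))
})

test_that("report invariants and oracle equivalence on transformed models", {
  for (g in list(buildResNet101(61),
                 applyLmpPm(buildResNet101(61), 8L, 2L),
                 buildOMNet(tiny_omnet_cfg()),
                 buildLMNet(tiny_omnet_cfg(), N = 2L, E = 2L))) {
    cr <- costReport(g)
    expect_equal(cr@param_count, sum(cr@per_layer$params))
    expect_equal(cr@mac_count, sum(cr@per_layer$macs))
    expect_equal(cr@param_count, oracle_params(g))
  }
})

test_that("halving conv widths quarters conv parameters (scaling law)", {
  g1 <- chain_graph(widths = c(32L, 64L), classes = 2L)
  g2 <- chain_graph(widths = c(16L, 32L), classes = 2L)
  p1 <- costReport(g1)@per_layer; p2 <- costReport(g2)@per_layer
  ## conv2 has both ends halved -> exactly 1/4
  expect_equal(p1$params[p1$id == "conv2"] / 4, p2$params[p2$id == "conv2"])
  ## conv1 keeps its fixed 3-channel input -> exactly 1/2
  expect_equal(p1$params[p1$id == "conv1"] / 2, p2$params[p2$id == "conv1"])
})

test_that("reduction ratios and M-format rounding", {
  b <- costReport(buildResNet101(61))
  expect_equal(unname(reductionRatios(b, b)), c(100, 100))
  v <- costReport(applyLmpPm(buildResNet101(61), 4L, 1L))
  rr <- reductionRatios(b, v)
  expect_equal(unname(rr["param_pct"]), round(100 * v@param_count / b@param_count, 2))
  ## half-up rounding at the second decimal
  expect_equal(round2(0.005, 2), 0.01)
  expect_equal(round2(2.675, 2), 2.68)
  expect_equal(formatMillions(1536000), "1.54")
})
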