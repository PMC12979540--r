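test_that("generation is deterministic and conserves the manifest", {
  sp <- leafSpec(n_classes = 3L, images_per_class = 6L, image_size = 32L,
                 seed = 7L)
  d1 <- file.path(tempdir(), "leafdet1"); d2 <- file.path(tempdir(), "leafdet2")
  unlink(c(d1, d2), recursive = TRUE)
  m1 <- generateLeafDataset(sp, d1)
  m2 <- generateLeafDataset(sp, d2)
  expect_equal(nrow(m1), 3L * 6L)
  expect_equal(m1$class, m2$class)
  h1 <- unname(tools::md5sum(m1$path))
  h2 <- unname(tools::md5sum(m2$path))
  expect_identical(h1, h2)                 # bit-identical images
  ## a different seed changes the images
  m3 <- generateLeafDataset(leafSpec(n_classes = 3L, images_per_class = 6L,
                                     image_size = 32L, seed = 8L),
                            file.path(tempdir(), "leafdet3"))
  expect_false(identical(h1, unname(tools::md5sum(m3$path))))
})

test_that("split fractions and image size are validated", {
  expect_error(leafSpec(split = c(0.5, 0.2, 0.2)), "sum to 1")
  expect_error(leafSpec(image_size = 16L), ">= 32")
  expect_error(leafSpec(n_classes = 1L))
})

test_that("splits follow the configured fractions and images are readable", {
  sp <- leafSpec(n_classes = 2L, images_per_class = 10L, image_size = 32L,
                 seed = 3L, split = c(0.6, 0.2, 0.2))
  d <- file.path(tempdir(), "leafsplit"); unlink(d, recursive = TRUE)
  m <- generateLeafDataset(sp, d)
  expect_equal(as.integer(table(m$split)["train"]), 12L)
  expect_equal(as.integer(table(m$split)["val"]), 4L)
  img <- png::readPNG(m$path[1])
  expect_equal(dim(img), c(32L, 32L, 3L))
  expect_true(all(img >= 0 & img <= 1))
})

test_that("class imbalance via per-class count vectors", {
  sp <- leafSpec(n_classes = 3L, images_per_class = c(12L, 6L, 3L),
                 image_size = 32L, seed = 2L)
  d <- file.path(tempdir(), "leafimb"); unlink(d, recursive = TRUE)
  m <- generateLeafDataset(sp, d)
  expect_equal(as.integer(table(m$class)), c(12L, 6L, 3L))
})

test_that("separability: zero for identical motifs, monotone in contrast", {
  sp <- leafSpec(n_classes = 3L, seed = 1L)
  same <- sp
  same$motifs <- sp$motifs[rep(1L, 3L), ]
  expect_equal(classSeparability(same), 0)
  s0 <- classSeparability(leafSpec(n_classes = 4L, lesion_contrast = 0))
  s1 <- classSeparability(leafSpec(n_classes = 4L, lesion_contrast = 0.5))
  s2 <- classSeparability(leafSpec(n_classes = 4L, lesion_contrast = 1))
  expect_true(s0 <= s1 && s1 <= s2)
  ## doubling contrast never decreases the score over a grid of specs
  for (k in c(2L, 3L, 6L)) for (ct in c(0.2, 0.4)) {
    lo <- classSeparability(leafSpec(n_classes = k, lesion_contrast = ct))
    hi <- classSeparability(leafSpec(n_classes = k, lesion_contrast = 2 * ct))
    expect_gte(hi, lo)
  }
  expect_lte(classSeparability(leafSpec(n_classes = 8L)), 1)
})

test_that("zero lesion contrast removes the class signal from pixels", {
  sp0 <- leafSpec(n_classes = 2L, images_per_class = 2L, image_size = 32L,
                  seed = 5L, lesion_contrast = 0)
  d <- file.path(tempdir(), "leafflat"); unlink(d, recursive = TRUE)
  m <- generateLeafDataset(sp0, d)
  ## same per-image seed stream differs only through the class index, which
  ## with contrast 0 influences nothing but the spot draw; class means of
  ## pixel statistics should be statistically indistinguishable
  a <- sapply(m$path[m$class == "class01"], function(p) mean(png::readPNG(p)))
  b <- sapply(m$path[m$class == "class02"], function(p) mean(png::readPNG(p)))
  expect_lt(abs(mean(a) - mean(b)), 0.05)
})

test_that("maximally separated two-class motifs reach the score ceiling", {
  sp <- leafSpec(n_classes = 2L,
                 motifs = data.frame(spot_mean = c(0, 20), r_min = c(0, 16),
                                     r_max = c(0, 16), hue = c(0, 0.5),
                                     sat = c(0, 1), ring = c(FALSE, TRUE)))
  expect_equal(classSeparability(sp), 1, tolerance = 1e-8)
})

test_that("without lesions a trained classifier stays at chance level", {
  d <- file.path(tempdir(), "leafzero"); unlink(d, recursive = TRUE)
  sp <- leafSpec(n_classes = 4L, images_per_class = 25L, image_size = 32L,
                 seed = 7L, lesion_contrast = 0)
  generateLeafDataset(sp, d)
  g <- buildLMNet(omnetTinyConfig(input_size = 32L), N = 2L, E = 2L)
  r <- trainNetwork(g, d, trainConfig(epochs = 3L, seed = 7L,
                                      batch_size = 4L, augment = FALSE))
  m <- evaluateNetwork(g, r$final_weights, d, "test")
  n <- sum(m@confusion)
  bt <- stats::binom.test(sum(diag(m@confusion)), n, p = 0.25,
                          alternative = "greater")
  expect_gt(bt$p.value, 0.05)   # cannot distinguish from chance
})
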