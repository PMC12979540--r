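## Deterministic generator of directory-per-class leaf-like disease images.
## Stands in for downloaded leaf-disease photo collections so training,
## evaluation and the command line are fully testable offline: multi-class,
## single-label image folders whose classes differ in local lesion texture
## and color, with optional class imbalance.

#' Specification of a synthetic leaf-disease image set
#'
#' Each class is defined by a lesion motif: expected spot count, spot
#' radius range (pixels at the 64-pixel reference scale), lesion hue and
#' saturation, and whether lesions are rings or filled blotches.  The
#' background is a leaf-hued ellipse with seeded value-noise texture and
#' vein strokes over a dark soil-like backdrop.
#'
#' @param n_classes number of classes (>= 2).
#' @param images_per_class images per class, or a vector of per-class
#'   counts to emulate class imbalance.
#' @param image_size square image side in pixels (>= 32; default 64).
#' @param seed integer; the same spec and seed give a bit-identical set.
#' @param lesion_contrast multiplier on lesion color contrast (0 removes
#'   the class signal entirely).
#' @param split train/val/test fractions summing to 1.
#' @param motifs optional data.frame overriding the auto-generated per-class
#'   motifs (columns spot_mean, r_min, r_max, hue, sat, ring).
#' @return an object of class \code{leafSpec} (a validated list).
#' @export
leafSpec <- function(n_classes = 4L, images_per_class = 50L, image_size = 64L,
                     seed = 7L, lesion_contrast = 1, split = c(0.6, 0.2, 0.2),
                     motifs = NULL) {
  stopifnot(n_classes >= 2L)
  if (image_size < 32L) stop("image_size must be >= 32")
  if (abs(sum(split) - 1) > 1e-8) stop("split fractions must sum to 1")
  if (length(images_per_class) == 1L)
    images_per_class <- rep(as.integer(images_per_class), n_classes)
  stopifnot(length(images_per_class) == n_classes, all(images_per_class > 0))
  if (is.null(motifs)) {
    i <- seq_len(n_classes)
    ## severe-disease appearance: many large, strongly colored lesions with
    ## well-separated hues, so classes differ as visibly as the species/
    ## disease classes of real leaf photo benchmarks
    motifs <- data.frame(
      spot_mean = 8 + (i - 1) %% 4 * 3,
      r_min = 4 + (i - 1) %% 3,
      r_max = 9 + (i - 1) %% 4 * 2,
      hue = (0.85 * (i - 1) / max(1, n_classes - 1) + 0.55) %% 1,
      sat = 0.8 + 0.2 * ((i - 1) %% 2),
      ring = (i %% 2) == 0)
  }
  stopifnot(nrow(motifs) == n_classes)
  if (anyDuplicated(motifs)) stop("class motifs must be pairwise distinct")
  structure(list(n_classes = as.integer(n_classes),
                 images_per_class = images_per_class,
                 image_size = as.integer(image_size), seed = as.integer(seed),
                 lesion_contrast = lesion_contrast, split = split,
                 motifs = motifs),
            class = "leafSpec")
}

## seeded value noise: bilinear interpolation of a coarse random lattice
.value_noise <- function(n, cells, rng) {
  lat <- matrix(rng(cells * cells), cells, cells)
  ix <- seq(1, cells, length.out = n)
  i0 <- pmin(floor(ix), cells - 1L); f <- ix - i0
  a <- lat[i0, , drop = FALSE]; b <- lat[i0 + 1L, , drop = FALSE]
  row <- a * (1 - f) + b * f
  a2 <- row[, i0, drop = FALSE]; b2 <- row[, i0 + 1L, drop = FALSE]
  a2 * matrix(1 - f, n, n, byrow = TRUE) + b2 * matrix(f, n, n, byrow = TRUE)
}

.hsv2rgb <- function(h, s, v) {
  h <- (h %% 1) * 6
  i <- floor(h); f <- h - i
  p <- v * (1 - s); q <- v * (1 - s * f); t <- v * (1 - s * (1 - f))
  r <- switch(as.integer(i %% 6) + 1L, v, q, p, p, t, v)
  g <- switch(as.integer(i %% 6) + 1L, t, v, v, q, p, p)
  b <- switch(as.integer(i %% 6) + 1L, p, p, t, v, v, q)
  c(r, g, b)
}

## render one leaf image: returns array (n, n, 3) in [0,1]
.render_leaf <- function(spec, class_i, img_seed) {
  n <- spec$image_size
  set.seed(img_seed)
  rng <- stats::runif
  xy <- expand.grid(x = seq_len(n), y = seq_len(n))
  cx <- n / 2 + stats::runif(1, -2, 2); cy <- n / 2 + stats::runif(1, -2, 2)
  ang <- stats::runif(1, 0, pi)
  rx <- n * stats::runif(1, 0.32, 0.42); ry <- n * stats::runif(1, 0.2, 0.3)
  dx <- (xy$x - cx); dy <- (xy$y - cy)
  u <- dx * cos(ang) + dy * sin(ang); v <- -dx * sin(ang) + dy * cos(ang)
  mask <- matrix((u / rx)^2 + (v / ry)^2 <= 1, n, n)
  tex <- .value_noise(n, 8L, rng)
  leaf_h <- 0.26 + stats::runif(1, -0.03, 0.03)     # green hue
  img <- array(0, dim = c(n, n, 3))
  bg <- .value_noise(n, 4L, rng) * 0.06 + 0.08      # dark soil backdrop
  for (ch in 1:3) img[, , ch] <- bg
  leaf_v <- 0.35 + 0.35 * tex
  for (i in which(mask)) {
    col <- .hsv2rgb(leaf_h, 0.7, leaf_v[i])
    img[, , 1][i] <- col[1]; img[, , 2][i] <- col[2]; img[, , 3][i] <- col[3]
  }
  ## veins: central rib plus side strokes, slightly darker
  tt <- seq(-1, 1, length.out = 2 * n)
  vx <- round(cx + tt * rx * cos(ang)); vy <- round(cy + tt * rx * sin(ang))
  ok <- vx >= 1 & vx <= n & vy >= 1 & vy <= n
  for (ch in 1:3) img[, , ch][cbind(vx[ok], vy[ok])] <-
    img[, , ch][cbind(vx[ok], vy[ok])] * 0.75
  for (sv in seq_len(4L)) {
    t0 <- stats::runif(1, -0.6, 0.6)
    bx <- cx + t0 * rx * cos(ang); by <- cy + t0 * rx * sin(ang)
    sa <- ang + pi / 2 + stats::runif(1, -0.4, 0.4)
    ss <- seq(0, 0.8 * ry, length.out = n %/% 2)
    sx <- round(bx + ss * cos(sa)); sy <- round(by + ss * sin(sa))
    ok <- sx >= 1 & sx <= n & sy >= 1 & sy <= n & mask[cbind(pmax(pmin(sx, n), 1), pmax(pmin(sy, n), 1))]
    for (ch in 1:3) img[, , ch][cbind(sx[ok], sy[ok])] <-
      img[, , ch][cbind(sx[ok], sy[ok])] * 0.8
  }
  ## class-motif lesions
  mt <- spec$motifs[class_i, ]
  scale <- n / 64
  nspots <- max(0L, stats::rpois(1, mt$spot_mean))
  inside <- which(mask)
  if (length(inside) && nspots > 0 && spec$lesion_contrast > 0) {
    for (s0 in seq_len(nspots)) {
      ctr <- inside[sample.int(length(inside), 1L)]
      px <- (ctr - 1L) %% n + 1L; py <- (ctr - 1L) %/% n + 1L
      r <- stats::runif(1, mt$r_min, mt$r_max) * scale
      dd <- sqrt((xy$x - px)^2 + (xy$y - py)^2)
      sel <- if (mt$ring) dd <= r & dd >= r * 0.55 else dd <= r
      sel <- sel & as.vector(mask)
      if (!any(sel)) next
      lcol <- .hsv2rgb(mt$hue, mt$sat, 0.55)
      a <- pmin(1, spec$lesion_contrast)
      for (ch in 1:3) img[, , ch][sel] <-
        (1 - a) * img[, , ch][sel] + a * lcol[ch]
    }
  }
  ## pixel noise
  img <- img + array(stats::rnorm(n * n * 3, 0, 0.02), dim = c(n, n, 3))
  pmin(pmax(img, 0), 1)
}

#' Generate a synthetic leaf-disease image folder
#'
#' Writes PNG images into \code{train/<class>/}, \code{val/<class>/} and
#' \code{test/<class>/} under \code{out_dir} and returns (and writes) a
#' manifest.  Identical spec + seed produce bit-identical images.
#'
#' @param spec a \code{\link{leafSpec}}.
#' @param out_dir output directory (created if needed).
#' @return data.frame manifest: path, class, split, seed; also written to
#'   \code{manifest.csv} in \code{out_dir}.
#' @examples
#' \donttest{
#' d <- file.path(tempdir(), "leaves")
#' m <- generateLeafDataset(leafSpec(n_classes = 2, images_per_class = 4,
#'                                   seed = 7), d)
#' nrow(m)   # 8
#' }
#' @export
generateLeafDataset <- function(spec, out_dir) {
  stopifnot(inherits(spec, "leafSpec"))
  classes <- sprintf("class%02d", seq_len(spec$n_classes))
  rows <- list()
  for (ci in seq_len(spec$n_classes)) {
    nimg <- spec$images_per_class[ci]
    ntr <- round(spec$split[1] * nimg)
    nva <- round(spec$split[2] * nimg)
    splits <- rep(c("train", "val", "test"),
                  c(ntr, nva, nimg - ntr - nva))
    for (ii in seq_len(nimg)) {
      img_seed <- spec$seed * 100003L + ci * 1009L + ii
      img <- .render_leaf(spec, ci, img_seed)
      dir <- file.path(out_dir, splits[ii], classes[ci])
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      fn <- file.path(dir, sprintf("%s_%03d.png", classes[ci], ii))
      png::writePNG(img, fn)
      rows[[length(rows) + 1L]] <-
        data.frame(path = fn, class = classes[ci], split = splits[ii],
                   seed = img_seed, stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  ## the on-disk manifest uses paths relative to out_dir so that two
  ## generations of the same spec are byte-identical wherever they land
  rel <- manifest
  rel$path <- substring(rel$path, nchar(out_dir) + 2L)
  utils::write.csv(rel, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}

#' Scalar difficulty score of a synthetic spec
#'
#' Mean pairwise Euclidean distance between the per-class motif parameter
#' vectors (each dimension scaled to its feasible range, lesion contrast
#' folded into the color dimensions), normalized to [0, 1].  Identical
#' motifs score 0; maximal hue/size separation scores 1.  Monotone
#' non-decreasing in \code{lesion_contrast}.
#'
#' @param spec a \code{\link{leafSpec}}.
#' @return a number in [0, 1].
#' @export
classSeparability <- function(spec) {
  m <- spec$motifs
  a <- pmin(1, spec$lesion_contrast)
  ## each coordinate spans at most 1; hue is circular, embedded on a
  ## half-unit circle so antipodal hues are distance 1 apart
  v <- cbind(pmin(m$spot_mean / 20, 1), pmin((m$r_min + m$r_max) / 2 / 16, 1),
             a * cos(2 * pi * m$hue) / 2, a * sin(2 * pi * m$hue) / 2,
             a * m$sat, a * as.numeric(m$ring))
  d <- stats::dist(v)
  if (!length(d)) return(0)
  mean(d) / sqrt(ncol(v) - 1)
}
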