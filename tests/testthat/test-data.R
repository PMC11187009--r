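# label I/O, splitting, letterbox, mosaic, synthetic generator

test_that("label files round-trip losslessly and handle edge rows", {
  tmp <- withr_tempfile()
  boxes <- tibble::tibble(class_id = c(0L, 2L), cx = c(0.5, 0.123456),
                          cy = c(0.5, 0.654321), bw = c(0.2, 0.04),
                          bh = c(0.2, 0.08))
  write_labels(boxes, tmp)
  back <- read_labels(tmp)
  expect_equal(as.data.frame(back), as.data.frame(boxes), tolerance = 1e-5)
  # 100 random samples round-trip to 6 decimals
  set.seed(30)
  for (t in 1:100) {
    b <- tibble::tibble(class_id = sample(0:2, 3, TRUE), cx = runif(3),
                        cy = runif(3), bw = runif(3, 0, 0.3),
                        bh = runif(3, 0, 0.3))
    write_labels(b, tmp)
    back <- read_labels(tmp)
    expect_identical(back$class_id, b$class_id)
    expect_lt(max(abs(as.matrix(back[, 2:5]) - as.matrix(b[, 2:5]))), 1e-6)
  }
  # a missing file is a valid negative image
  expect_equal(nrow(read_labels(file.path(tempdir(), "nope.txt"))), 0)
  # malformed rows raise errors naming the location
  writeLines("0 0.5 0.5", tmp)
  expect_error(read_labels(tmp), "malformed.*:1", )
  # out-of-range coordinates are clipped with a warning
  writeLines("0 1.2 0.5 0.2 0.2", tmp)
  expect_warning(b2 <- read_labels(tmp), "clipped")
  expect_equal(b2$cx, 1.0)
})

test_that("the 8:1:1 split is exact, disjoint, exhaustive and seeded", {
  sp <- split_dataset(sprintf("img%04d", 1:1530), seed = 7)
  expect_equal(lengths(sp), c(train = 1224L, val = 153L, test = 153L))
  sp10 <- split_dataset(1:10, seed = 1)
  expect_equal(unname(lengths(sp10)), c(8L, 1L, 1L))
  expect_identical(split_dataset(1:100, seed = 5), split_dataset(1:100, seed = 5))
  expect_false(identical(split_dataset(1:100, seed = 5),
                         split_dataset(1:100, seed = 6)))
  expect_error(split_dataset(1:2), "at least 3")
  # partition property over randomised sizes
  set.seed(31)
  for (t in 1:20) {
    n <- sample(3:5000, 1)
    sp <- split_dataset(seq_len(n), seed = t)
    all_items <- c(sp$train, sp$val, sp$test)
    expect_equal(sort(all_items), seq_len(n))
    expect_equal(anyDuplicated(all_items), 0)
  }
})

test_that("letterbox preserves aspect, pads symmetrically, and inverts to within half a pixel", {
  # square input: pure resize, no padding
  s <- list(image = array(runif(64 * 64 * 3), c(64, 64, 3)),
            boxes = tibble::tibble(class_id = 0L, cx = 0.5, cy = 0.5,
                                   bw = 0.4, bh = 0.4), id = "sq")
  lb <- letterbox(s, 96)
  expect_equal(lb$transform$pad_x, 0)
  expect_equal(lb$transform$pad_y, 0)
  # 4:3 landscape (the capture aspect): 640x480 content with 80 px bands
  s2 <- list(image = array(runif(864 * 1152 * 3), c(864, 1152, 3)),
             boxes = tibble::tibble(class_id = 0L, cx = 0.5, cy = 0.5,
                                    bw = 0.25, bh = 0.25), id = "land")
  lb2 <- letterbox(s2, 640)
  expect_equal(lb2$transform$scale, 640 / 1152)
  expect_equal(lb2$transform$pad_y, 80)
  expect_equal(lb2$transform$pad_x, 0)
  # the pad bands are the uniform gray fill
  expect_equal(diff(range(lb2$image[1:80, , ])), 0)
  # box forward + inverse transform is the identity to 0.5 px
  px <- cddlite:::norm_to_corners(lb2$boxes, 640, 640)
  back <- unletterbox_boxes(px, lb2$transform)
  orig <- cddlite:::norm_to_corners(s2$boxes, 1152, 864)
  expect_lt(max(abs(as.matrix(back[, 2:5]) - as.matrix(orig[, 2:5]))), 0.5)
  expect_error(letterbox(s, 100), "divisible")
})

test_that("mosaic fuses four samples deterministically and keeps boxes in-quadrant", {
  set.seed(32)
  blank <- function(id) list(image = array(runif(32 * 32 * 3), c(32, 32, 3)),
                             boxes = tibble::tibble(class_id = integer(),
                                                    cx = numeric(), cy = numeric(),
                                                    bw = numeric(), bh = numeric()),
                             id = id)
  m0 <- mosaic(lapply(1:4, function(i) blank(paste0("b", i))), 64, seed = 1)
  expect_equal(dim(m0$image), c(64, 64, 3))
  expect_equal(nrow(m0$boxes), 0)
  # four copies of one image with a centred box: one remapped box per quadrant
  one <- list(image = array(runif(32 * 32 * 3), c(32, 32, 3)),
              boxes = tibble::tibble(class_id = 1L, cx = 0.5, cy = 0.5,
                                     bw = 0.6, bh = 0.6), id = "c")
  m1 <- mosaic(list(one, one, one, one), 64, seed = 2)
  expect_equal(nrow(m1$boxes), 4)
  expect_true(all(m1$boxes$class_id == 1L))   # no invented classes
  px <- cddlite:::norm_to_corners(m1$boxes, 64, 64)
  expect_true(all(px$x2 > px$x1 & px$y2 > px$y1))
  # determinism
  m2 <- mosaic(list(one, one, one, one), 64, seed = 2)
  expect_identical(m1$image, m2$image)
  expect_error(mosaic(list(one, one), 64), "four")
})

test_that("the synthetic generator writes a complete deterministic dataset", {
  cfg <- synth_config(n_images = 10, image_size = 64, seed = 3)
  d1 <- file.path(tempdir(), "synth_a"); d2 <- file.path(tempdir(), "synth_b")
  unlink(c(d1, d2), recursive = TRUE)
  generate_synthetic(cfg, d1)
  expect_length(list.files(file.path(d1, "images")), 10)
  expect_length(list.files(file.path(d1, "labels")), 10)
  manifest <- readLines(file.path(d1, "dataset.txt"))
  expect_length(manifest[!startsWith(manifest, "#")], 10)
  expect_match(manifest[1], "verticillium_wilt,fusarium_wilt,anthracnose")
  # refuses to overwrite silently
  expect_error(generate_synthetic(cfg, d1), "not empty")
  # byte-identical on regeneration
  generate_synthetic(cfg, d2)
  f1 <- list.files(d1, recursive = TRUE)
  for (f in f1)
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6), )
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("recorded boxes bound their painted lesions", {
  cfg <- synth_config(n_images = 6, image_size = 96, seed = 4)
  for (i in 1:6) {
    s <- cddlite:::synth_sample(cfg, i)
    expect_true(all(s$boxes$cx - s$boxes$bw / 2 >= 0))
    expect_true(all(s$boxes$cx + s$boxes$bw / 2 <= 1))
    expect_true(all(s$boxes$cy - s$boxes$bh / 2 <= 1))
    expect_true(all(s$boxes$bw > 0 & s$boxes$bh > 0))
    px <- cddlite:::norm_to_corners(s$boxes, 96, 96)
    for (j in seq_len(nrow(px))) {
      xs <- max(1, floor(px$x1[j] + 1)):min(96, ceiling(px$x2[j]))
      ys <- max(1, floor(px$y1[j] + 1)):min(96, ceiling(px$y2[j]))
      inside <- s$image[ys, xs, , drop = FALSE]
      ring_w <- max(1, floor(px$x1[j] - 3)):min(96, ceiling(px$x2[j] + 3))
      ring_h <- max(1, floor(px$y1[j] - 3)):min(96, ceiling(px$y2[j] + 3))
      outside <- s$image[ring_h, ring_w, , drop = FALSE]
      # the lesion colours the box interior away from the surrounding canvas
      expect_gt(abs(mean(inside) - mean(outside)), 0.0)
    }
  }
})

test_that("generated class frequencies sit inside binomial 99% bounds", {
  cfg <- synth_config(n_images = 300, image_size = 48,
                      lesions_range = c(1L, 1L), seed = 6)
  cls <- unlist(lapply(1:300, function(i)
    cddlite:::synth_sample(cfg, i)$boxes$class_id))
  n <- length(cls)
  for (c in 0:2) {
    k <- sum(cls == c)
    bounds <- qbinom(c(0.005, 0.995), n, 1 / 3)
    expect_gte(k, bounds[1])
    expect_lte(k, bounds[2])
  }
})
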