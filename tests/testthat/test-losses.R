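# IoU family, MPDIoU properties, gradients, assignment, composite loss

img100 <- image_size(100, 100)

test_that("IoU and MPDIoU reproduce the hand-computed examples", {
  expect_equal(iou(c(0, 0, 10, 10), c(0, 0, 10, 10)), 1)
  expect_equal(iou(c(0, 0, 10, 10), c(20, 20, 30, 30)), 0)
  expect_equal(iou(c(0, 0, 10, 10), c(0, 0, 20, 20)), 0.25)
  expect_equal(iou(c(5, 5, 5, 5), c(5, 5, 5, 5)), 0)  # both zero-area
  expect_equal(mpdiou(c(0, 0, 10, 10), c(0, 0, 10, 10), img100), 1)
  expect_equal(mpdiou(c(0, 0, 10, 10), c(0, 0, 20, 20), img100), 0.24)
  expect_equal(mpdiou(c(0, 0, 10, 10), c(90, 90, 100, 100), img100), -1.62)
})

test_that("all family members equal 1 on identical boxes and GIoU penalises disjointness", {
  b <- c(3, 7, 25, 30)
  for (nm in c("iou", "giou", "ciou", "siou", "wiou"))
    expect_equal(iou_family(nm, b, b), 1, tolerance = 1e-7, info = nm)
  expect_equal(iou_family("mpdiou", b, b, img100), 1, tolerance = 1e-7)
  expect_lt(iou_family("giou", c(0, 0, 10, 10), c(50, 50, 60, 60)), 0)
  expect_error(iou_family("bogus", b, b), "unknown")
})

test_that("CIoU matches an independently coded closed form on random pairs", {
  # independent oracle: the published CIoU formula, written directly
  oracle_ciou <- function(a, b) {
    inter <- max(0, min(a[3], b[3]) - max(a[1], b[1])) *
             max(0, min(a[4], b[4]) - max(a[2], b[2]))
    u <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
    i <- inter / (u + 1e-9)
    cw <- max(a[3], b[3]) - min(a[1], b[1])
    ch <- max(a[4], b[4]) - min(a[2], b[2])
    rho2 <- ((a[1] + a[3] - b[1] - b[3])^2 + (a[2] + a[4] - b[2] - b[4])^2) / 4
    v <- 4 / pi^2 * (atan((b[3] - b[1]) / (b[4] - b[2] + 1e-9)) -
                     atan((a[3] - a[1]) / (a[4] - a[2] + 1e-9)))^2
    i - rho2 / (cw^2 + ch^2 + 1e-9) - v^2 / (1 - i + v + 1e-9)
  }
  set.seed(10)
  for (t in 1:100) {
    a <- rand_box(); b <- rand_box()
    expect_equal(iou_family("ciou", a, b), oracle_ciou(a, b),
                 tolerance = 1e-6)
  }
})

test_that("box losses are zero at the optimum and match the worked example", {
  expect_equal(box_loss("mpdiou", c(0, 0, 10, 10), c(0, 0, 10, 10), img100), 0)
  expect_equal(box_loss("mpdiou", c(0, 0, 10, 10), c(0, 0, 20, 20), img100), 0.76)
  for (nm in c("iou", "giou", "ciou", "siou", "wiou"))
    expect_equal(box_loss(nm, c(1, 2, 9, 11), c(1, 2, 9, 11)), 0,
                 tolerance = 1e-7)
})

test_that("loss gradients match central finite differences for every family member", {
  set.seed(11)
  for (nm in c("iou", "giou", "ciou", "siou", "wiou", "mpdiou")) {
    worst <- 0
    for (t in 1:12) {
      p <- rand_box(0, 60); tg <- rand_box(10, 80)
      bg <- box_loss_grad(nm, p, tg, img100)
      for (i in 1:4) {
        e <- 1e-5
        p1 <- p; p1[i] <- p1[i] + e
        p2 <- p; p2[i] <- p2[i] - e
        num <- (box_loss(nm, matrix(p1, 1), matrix(tg, 1), img100) -
                box_loss(nm, matrix(p2, 1), matrix(tg, 1), img100)) / (2 * e)
        worst <- max(worst, abs(num - bg$grad[i]) / max(abs(num), 1e-3))
      }
    }
    expect_lt(worst, 1e-4)
  }
})

test_that("MPDIoU is bounded by IoU, symmetric, translation-invariant, and separation-monotone", {
  set.seed(12)
  for (t in 1:200) {
    a <- rand_box(); b <- rand_box()
    m <- mpdiou(a, b, img100)
    expect_lte(m, iou(a, b) + 1e-12)
    expect_equal(m, mpdiou(b, a, img100))           # symmetry
    sh <- runif(2, -5, 5)
    expect_equal(m, mpdiou(a + sh[c(1, 2, 1, 2)], b + sh[c(1, 2, 1, 2)],
                           img100), tolerance = 1e-12)  # joint translation
  }
  # equality holds exactly when the corners coincide
  expect_equal(mpdiou(c(1, 1, 9, 9), c(1, 1, 9, 9), img100),
               iou(c(1, 1, 9, 9), c(1, 1, 9, 9)))
  expect_lt(mpdiou(c(1, 1, 9, 9), c(1, 1, 9, 10), img100),
            iou(c(1, 1, 9, 9), c(1, 1, 9, 10)))
  # monotone along a separation ray while plain IoU is flat at zero
  tgt <- c(0, 0, 10, 10)
  vals <- sapply(seq(15, 60, by = 5), function(d)
    mpdiou(c(d, 0, d + 10, 10), tgt, img100))
  expect_true(all(diff(vals) < 0))
  expect_true(all(sapply(seq(15, 60, by = 5), function(d)
    iou(c(d, 0, d + 10, 10), tgt)) == 0))
})

test_that("for nested same-aspect boxes the smaller-error pair scores higher", {
  tgt <- c(40, 40, 60, 60)
  near <- c(38, 38, 62, 62)   # same aspect ratio, small deviation
  far <- c(30, 30, 70, 70)    # same aspect ratio, large deviation
  expect_gt(mpdiou(near, tgt, img100), mpdiou(far, tgt, img100))
})

test_that("task-aligned assignment matches a brute-force assigner on a toy grid", {
  # 4x4 grid of cells, stride 8 (centres 4, 12, 20, 28)
  anchors <- as.matrix(expand.grid(cx = c(4, 12, 20, 28),
                                   cy = c(4, 12, 20, 28)))
  ncell <- nrow(anchors)
  set.seed(13)
  pred_boxes <- cbind(anchors[, 1] - 6, anchors[, 2] - 6,
                      anchors[, 1] + 6, anchors[, 2] + 6)
  scores <- matrix(runif(ncell * 2, 0.1, 0.9), ncell, 2)
  # single gt covering exactly one cell centre
  gt1 <- data.frame(class_id = 0L, x1 = 10, y1 = 10, x2 = 14, y2 = 14)
  a1 <- tal_assign(scores, pred_boxes, anchors, gt1)
  expect_equal(which(a1$fg), which(anchors[, 1] == 12 & anchors[, 2] == 12))
  # zero gts: everything background, zero class targets
  a0 <- tal_assign(scores, pred_boxes, anchors,
                   data.frame(class_id = integer(), x1 = numeric(),
                              y1 = numeric(), x2 = numeric(), y2 = numeric()))
  expect_false(any(a0$fg))
  expect_equal(sum(a0$target_scores), 0)
  # two overlapping gts competing for cells: conflict goes to higher alignment
  gts <- data.frame(class_id = c(0L, 1L), x1 = c(2, 6), y1 = c(2, 6),
                    x2 = c(22, 26), y2 = c(22, 26))
  a2 <- tal_assign(scores, pred_boxes, anchors, gts, alpha = 0.5, beta = 6,
                   topk = 10)
  # brute force: same rule, written independently
  for (i in seq_len(ncell)) {
    al <- sapply(1:2, function(j) {
      inside <- anchors[i, 1] > gts$x1[j] && anchors[i, 1] < gts$x2[j] &&
                anchors[i, 2] > gts$y1[j] && anchors[i, 2] < gts$y2[j]
      if (!inside) return(0)
      v <- cddlite::iou(pred_boxes[i, ], as.numeric(gts[j, 2:5]))
      scores[i, gts$class_id[j] + 1]^0.5 * v^6
    })
    if (all(al == 0)) {
      expect_false(a2$fg[i])
    } else if (a2$fg[i]) {
      expect_equal(a2$gt_idx[i], which.max(al))
    }
  }
})

test_that("distribution focal loss has its closed two-bin form and vanishes on point masses", {
  z <- rep(-20, 16); z[4] <- 20  # point mass at bin 3
  expect_lt(cddlite:::dfl_pair(z, 3)$loss, 1e-6)
  # target 3.4: weighted CE of bins 3 and 4, checked against direct evaluation
  set.seed(14)
  z <- rnorm(16)
  lp <- z - (max(z) + log(sum(exp(z - max(z)))))
  direct <- -(0.6 * lp[4] + 0.4 * lp[5])
  expect_equal(cddlite:::dfl_pair(z, 3.4)$loss, direct, tolerance = 1e-12)
})

test_that("a perfect prediction drives every loss component below 1e-3", {
  cfg <- model_config(num_classes = 2, input_size = 64)
  sizes <- c(8L, 4L, 2L)
  raw <- list(reg = lapply(sizes, function(s) array(0, c(64, s, s, 1))),
              cls = lapply(sizes, function(s) array(-15, c(2, s, s, 1))),
              strides = c(8L, 16L, 32L))
  # gt spans (4, 4) - (20, 20); only P3 centre (12, 12) is strictly inside
  gt <- data.frame(class_id = 0L, x1 = 4, y1 = 4, x2 = 20, y2 = 20)
  for (side in 1:4) {
    raw$reg[[1]][(side - 1) * 16 + 1:16, 2, 2, 1] <- -30
    raw$reg[[1]][(side - 1) * 16 + 2, 2, 2, 1] <- 30  # distance 1 stride
  }
  raw$cls[[1]][1, 2, 2, 1] <- 15
  ls <- total_loss(raw, list(gt), cfg, with_grad = FALSE)
  expect_lt(ls$box, 1e-3)
  expect_lt(ls$cls, 1e-3)
  expect_lt(ls$dfl, 1e-3)
  expect_gte(ls$n_pos, 1)
})

test_that("an image without ground truth keeps only the classification term", {
  cfg <- model_config(num_classes = 2, input_size = 64)
  sizes <- c(8L, 4L, 2L)
  raw <- list(reg = lapply(sizes, function(s) array(0.1, c(64, s, s, 1))),
              cls = lapply(sizes, function(s) array(-2, c(2, s, s, 1))),
              strides = c(8L, 16L, 32L))
  empty <- data.frame(class_id = integer(), x1 = numeric(), y1 = numeric(),
                      x2 = numeric(), y2 = numeric())
  ls <- total_loss(raw, list(empty), cfg, with_grad = TRUE)
  expect_equal(ls$box, 0)
  expect_equal(ls$dfl, 0)
  expect_gt(ls$cls, 0)
  expect_true(all(vapply(ls$grads$reg, function(a) all(a == 0), TRUE)))
})
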