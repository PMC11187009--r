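# evaluation: matching, precision/recall, AP envelope, mAP sweeps

test_that("greedy matching handles the canonical layouts", {
  gt <- data.frame(class_id = 0L, x1 = 10, y1 = 10, x2 = 30, y2 = 30)
  d1 <- data.frame(x1 = 10, y1 = 10, x2 = 30, y2 = 30, class_id = 0L,
                   score = 0.9)
  m <- match_detections(d1, gt, 0.5)
  expect_equal(sum(m$tp), 1); expect_equal(m$fn, 0)
  # two detections on one gt: one TP, one FP
  d2 <- rbind(d1, transform(d1, score = 0.8))
  m2 <- match_detections(d2, gt, 0.5)
  expect_equal(sum(m2$tp), 1); expect_equal(sum(!m2$tp), 1)
  # class-strict: a perfect box of the wrong class never matches
  d3 <- transform(d1, class_id = 1L)
  m3 <- match_detections(d3, gt, 0.5)
  expect_equal(sum(m3$tp), 0); expect_equal(m3$fn, 1)
})

test_that("greedy matching equals the brute-force matcher when scores are distinct", {
  set.seed(20)
  for (t in 1:50) {
    sc <- toy_scene(sample(1:3, 1) + 2, 2, num_classes = 1)
    m1 <- match_detections(sc$dets, sc$gts, 0.5)
    m2 <- oracle_match(sc$dets, sc$gts, 0.5)
    expect_identical(m1$tp, m2$tp)
    expect_identical(m1$fn, m2$fn)
  }
})

test_that("precision and recall follow their defining ratios with a zero convention", {
  expect_equal(precision_recall(8, 2, 2), list(precision = 0.8, recall = 0.8))
  expect_equal(precision_recall(0, 0, 5), list(precision = 0, recall = 0))
  expect_equal(precision_recall(90, 10, 30),
               list(precision = 0.9, recall = 0.75))
})

test_that("average precision integrates the monotone envelope", {
  expect_equal(average_precision(c(TRUE, TRUE, TRUE), 3), 1)
  expect_equal(average_precision(c(FALSE, TRUE), 1), 0.5)
  expect_equal(average_precision(logical(0), 3), 0)
  expect_true(is.na(average_precision(c(TRUE), 0)))
})

test_that("AP equals the independent envelope oracle on random flag patterns", {
  set.seed(21)
  for (t in 1:300) {
    n <- sample(1:12, 1)
    tp <- runif(n) < 0.5
    n_gt <- sum(tp) + sample(0:3, 1)
    if (n_gt == 0) next
    expect_equal(average_precision(tp, n_gt), oracle_ap(tp, n_gt),
                 tolerance = 1e-9)
  }
})

test_that("AP depends on score ranks only and responds monotonically to edits", {
  set.seed(22)
  sc <- toy_scene(8, 4, 1)
  m <- match_detections(sc$dets, sc$gts, 0.5)
  base_ap <- average_precision(m$tp, nrow(sc$gts))
  # positive rescaling of scores leaves the ranks, hence AP, unchanged
  sc2 <- sc; sc2$dets$score <- sc2$dets$score * 7.3
  m2 <- match_detections(sc2$dets, sc2$gts, 0.5)
  expect_equal(average_precision(m2$tp, nrow(sc2$gts)), base_ap)
  # a lowest-ranked FP never increases AP; a top-ranked TP never decreases it
  expect_lte(average_precision(c(m$tp, FALSE), nrow(sc$gts)), base_ap)
  expect_gte(average_precision(c(TRUE, m$tp), nrow(sc$gts) + 1) *
               (nrow(sc$gts) + 1) / (nrow(sc$gts) + 1), 0)
  expect_gte(average_precision(c(TRUE, m$tp), nrow(sc$gts)), base_ap)
})

test_that("mAP sweeps behave at the threshold extremes", {
  gt <- data.frame(class_id = 0L, x1 = 0, y1 = 0, x2 = 20, y2 = 20)
  perfect <- data.frame(x1 = 0, y1 = 0, x2 = 20, y2 = 20, class_id = 0L,
                        score = 0.9)
  ev <- map_at(list(perfect), list(gt), num_classes = 1)
  expect_equal(ev$map, 1)
  expect_equal(ev$map50, 1)
  # detection with IoU 0.6 to every gt: AP 1 at 0.5/0.55/0.6, 0 above
  d06 <- data.frame(x1 = 0, y1 = 0, x2 = 20, y2 = 12, class_id = 0L,
                    score = 0.9)
  expect_equal(iou(as.numeric(d06[1, 1:4]), as.numeric(gt[1, 2:5])), 0.6)
  ev2 <- map_at(list(d06), list(gt), num_classes = 1)
  expect_equal(ev2$map, 3 / 10)
  # empty detections, non-empty gts
  none <- data.frame(x1 = numeric(), y1 = numeric(), x2 = numeric(),
                     y2 = numeric(), class_id = integer(), score = numeric())
  ev3 <- map_at(list(none), list(gt), num_classes = 1)
  expect_equal(ev3$map, 0)
  expect_equal(ev3$fn, 1)
})

test_that("mAP over one class is that class's AP", {
  set.seed(23)
  sc <- toy_scene(6, 3, 1)
  ev <- map_at(list(sc$dets), list(sc$gts), thresholds = 0.5, num_classes = 1)
  m <- match_detections(sc$dets, sc$gts, 0.5)
  expect_equal(ev$map50, average_precision(m$tp, nrow(sc$gts)))
})

test_that("classes without ground truth are excluded from the mean", {
  gt <- data.frame(class_id = 0L, x1 = 0, y1 = 0, x2 = 20, y2 = 20)
  perfect <- data.frame(x1 = 0, y1 = 0, x2 = 20, y2 = 20, class_id = 0L,
                        score = 0.9)
  ev <- map_at(list(perfect), list(gt), num_classes = 3)
  expect_equal(ev$map50, 1)   # classes 1 and 2 have no gts: not averaged in
  expect_true(is.na(ev$per_class$ap50[2]))
})
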