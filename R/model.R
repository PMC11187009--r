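# ---------------------------------------------------------------------------
# Model assembly: the n-scale one-stage detector baseline and its ablation
# variants, culminating in the full lightweight configuration
# (C2f-Faster backbone + slim neck + PCDetect head).
# ---------------------------------------------------------------------------

#' Model configuration
#'
#' Describes one detector variant: class count, input size, the ablation
#' toggles (C2f-Faster backbone, slim neck, PCDetect head), the IoU loss
#' family member used for box regression, and the number of distribution
#' focal loss bins. With all toggles off this is the n-scale baseline.
#'
#' @param num_classes Number of object classes (default 3: verticillium wilt,
#'   fusarium wilt, anthracnose).
#' @param input_size Square network input in pixels, divisible by 32.
#' @param use_c2f_faster Replace every backbone C2f bottleneck with a
#'   Faster block (partial convolution).
#' @param use_slim_neck Replace neck C2f modules with VoVGSCSP and the two
#'   PAN downsampling convolutions with GSConv.
#' @param head `"detect"` (two 3x3 CBS per branch) or `"pcdetect"` (a PCD
#'   unit: 3x3 partial conv + 1x1 CBS per branch).
#' @param loss_iou Box-similarity used in the regression loss: one of
#'   `"ciou"`, `"giou"`, `"siou"`, `"wiou"`, `"mpdiou"`.
#' @param reg_max Number of discrete distance bins per box side.
#' @param conf_threshold,nms_iou Default decode thresholds for prediction.
#' @return An object of class `cdd_model_config`.
#' @export
model_config <- function(num_classes = 3L, input_size = 640L,
                         use_c2f_faster = FALSE, use_slim_neck = FALSE,
                         head = c("detect", "pcdetect"),
                         loss_iou = c("ciou", "giou", "siou", "wiou", "mpdiou"),
                         reg_max = 16L, conf_threshold = 0.25, nms_iou = 0.45) {
  head <- match.arg(head)
  loss_iou <- match.arg(loss_iou)
  if (num_classes < 1L) stop("num_classes must be >= 1", call. = FALSE)
  if (input_size %% 32L != 0L)
    stop("input_size must be divisible by 32", call. = FALSE)
  structure(list(num_classes = as.integer(num_classes),
                 input_size = as.integer(input_size),
                 use_c2f_faster = isTRUE(use_c2f_faster),
                 use_slim_neck = isTRUE(use_slim_neck), head = head,
                 loss_iou = loss_iou, reg_max = as.integer(reg_max),
                 conf_threshold = conf_threshold, nms_iou = nms_iou),
            class = "cdd_model_config")
}

#' Named ablation variants
#'
#' Maps a variant name to its [model_config()]: `"baseline"`,
#' `"c2f_faster"`, `"slim_neck"`, `"c2f_faster+slim_neck"`, `"mpdiou"`,
#' `"pcdetect"` and `"cddlite"` (all toggles on, MPDIoU loss).
#'
#' @param name Variant name.
#' @param num_classes,input_size Passed through to [model_config()].
#' @return A `cdd_model_config`.
#' @export
variant_config <- function(name, num_classes = 3L, input_size = 640L) {
  switch(name,
    baseline = model_config(num_classes, input_size),
    c2f_faster = model_config(num_classes, input_size, use_c2f_faster = TRUE),
    slim_neck = model_config(num_classes, input_size, use_slim_neck = TRUE),
    `c2f_faster+slim_neck` = model_config(num_classes, input_size,
                                          use_c2f_faster = TRUE,
                                          use_slim_neck = TRUE),
    mpdiou = model_config(num_classes, input_size, loss_iou = "mpdiou"),
    pcdetect = model_config(num_classes, input_size, head = "pcdetect"),
    cddlite = model_config(num_classes, input_size, use_c2f_faster = TRUE,
                           use_slim_neck = TRUE, head = "pcdetect",
                           loss_iou = "mpdiou"),
    stop("unknown variant: ", name, call. = FALSE)
  )
}

# one detection-head branch; returns the final projection node id
bld_head_branch <- function(g, from, cin, mid, cfin, pcd, name) {
  if (pcd) {
    id <- bld_pconv(g, from, cin, 4L, 3L, name = paste0(name, ".pcd.pconv"))
    id <- bld_cbs(g, id, cin, mid, 1L, 1L, name = paste0(name, ".pcd.pw"))
  } else {
    id <- bld_cbs(g, from, cin, mid, 3L, 1L, name = paste0(name, ".cv0"))
    id <- bld_cbs(g, id, mid, mid, 3L, 1L, name = paste0(name, ".cv1"))
  }
  g_conv(g, id, mid, cfin, 1L, 1L, bias = TRUE, name = paste0(name, ".proj"))
}

#' Assemble a detector
#'
#' Builds the full layer graph for a configuration: the CSP backbone
#' (optionally with Faster blocks), the FPN+PAN neck (optionally slim),
#' and the anchor-free decoupled head (optionally PCDetect). Weight
#' initialisation is Kaiming-normal, seeded; classification projection
#' biases start at a low-prior logit and regression projection biases at 1,
#' the usual one-stage stabilisation.
#'
#' @param config A [model_config()].
#' @param seed Integer seed for the weight initialisation.
#' @return An object of class `cdd_model`: the graph, the config, the level
#'   strides, and the ids of the six head output nodes.
#' @export
build_model <- function(config, seed = 0L) {
  stopifnot(inherits(config, "cdd_model_config"))
  set.seed(seed)
  g <- new_graph()
  fast <- config$use_c2f_faster
  inp <- g_input(g, 3L, name = "images")
  # backbone
  x <- bld_cbs(g, inp, 3L, 16L, 3L, 2L, name = "b0")
  x <- bld_cbs(g, x, 16L, 32L, 3L, 2L, name = "b1")
  x <- bld_c2f(g, x, 32L, 32L, 1L, TRUE, fast, name = "b2")
  x <- bld_cbs(g, x, 32L, 64L, 3L, 2L, name = "b3")
  p3 <- bld_c2f(g, x, 64L, 64L, 2L, TRUE, fast, name = "b4")
  x <- bld_cbs(g, p3, 64L, 128L, 3L, 2L, name = "b5")
  p4 <- bld_c2f(g, x, 128L, 128L, 2L, TRUE, fast, name = "b6")
  x <- bld_cbs(g, p4, 128L, 256L, 3L, 2L, name = "b7")
  x <- bld_c2f(g, x, 256L, 256L, 1L, TRUE, fast, name = "b8")
  p5 <- bld_sppf(g, x, 256L, name = "b9")
  # neck: FPN top-down then PAN bottom-up
  slim <- config$use_slim_neck
  fuse <- function(from, cin, cout, name) {
    if (slim) bld_vovgscsp(g, from, cin, cout, 1L, name = name)
    else bld_c2f(g, from, cin, cout, 1L, FALSE, FALSE, name = name)
  }
  down <- function(from, c, name) {
    if (slim) bld_gsconv(g, from, c, c, 3L, 2L, name = name)
    else bld_cbs(g, from, c, c, 3L, 2L, name = name)
  }
  u1 <- g_upsample(g, p5, name = "n10.up")
  t4 <- fuse(g_concat(g, c(u1, p4), name = "n11.cat"), 384L, 128L, "n12")
  u2 <- g_upsample(g, t4, name = "n13.up")
  o3 <- fuse(g_concat(g, c(u2, p3), name = "n14.cat"), 192L, 64L, "n15")
  d1 <- down(o3, 64L, "n16")
  o4 <- fuse(g_concat(g, c(d1, t4), name = "n17.cat"), 192L, 128L, "n18")
  d2 <- down(o4, 128L, "n19")
  o5 <- fuse(g_concat(g, c(d2, p5), name = "n20.cat"), 384L, 256L, "n21")
  # head: decoupled regression / classification branches on (64, 128, 256)
  nc <- config$num_classes
  mid_reg <- max(16L, 64L %/% 4L, 4L * config$reg_max)
  mid_cls <- max(64L, min(nc, 100L))
  pcd <- config$head == "pcdetect"
  feats <- c(o3, o4, o5)
  chs <- c(64L, 128L, 256L)
  reg_ids <- cls_ids <- integer(3)
  for (i in 1:3) {
    reg_ids[i] <- bld_head_branch(g, feats[i], chs[i], mid_reg,
                                  4L * config$reg_max, pcd,
                                  sprintf("head.l%d.reg", i))
    cls_ids[i] <- bld_head_branch(g, feats[i], chs[i], mid_cls, nc, pcd,
                                  sprintf("head.l%d.cls", i))
  }
  g$outputs <- c(reg_ids, cls_ids)
  g_init(g)
  # prior-aware projection bias init
  strides <- c(8L, 16L, 32L)
  for (i in 1:3) {
    # decaying ramp over distance bins: initial boxes ~1.5 strides per side,
    # a lesion-scale prior that lets small objects bootstrap their IoU
    g$nodes[[reg_ids[i]]]$b <- rep(-0.5 * (seq_len(config$reg_max) - 1), 4L)
    g$nodes[[cls_ids[i]]]$b <-
      rep(log(5 / nc / (config$input_size / strides[i])^2), nc)
  }
  structure(list(graph = g, config = config, strides = strides,
                 reg_ids = reg_ids, cls_ids = cls_ids),
            class = "cdd_model")
}

#' @export
print.cdd_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<cdd_model> nc=%d input=%d c2f_faster=%s slim_neck=%s head=%s loss=%s\n",
              cfg$num_classes, cfg$input_size, cfg$use_c2f_faster,
              cfg$use_slim_neck, cfg$head, cfg$loss_iou))
  p <- count_params(x)
  cat(sprintf("  %d nodes, %s parameters\n", length(x$graph$nodes),
              format(p, big.mark = ",")))
  invisible(x)
}

#' Raw multi-level head outputs
#'
#' Runs the network on a batch and returns, per feature level P3/P4/P5
#' (strides 8/16/32), the regression logits (`4 * reg_max` per cell) and
#' classification logits (`num_classes` per cell).
#'
#' @param model A [build_model()] result.
#' @param x Image array `(3, H, W)` or `(3, H, W, N)`, values in `[0, 1]`.
#' @param train Use batch statistics in batch norm (training mode).
#' @return A list with `reg` and `cls` (lists of three arrays), `strides`,
#'   and the forward cache (used internally for backprop).
#' @export
model_forward <- function(model, x, train = FALSE) {
  fw <- graph_forward(model$graph, x, train = train)
  list(reg = lapply(model$reg_ids, function(i) fw$cache[[i]]),
       cls = lapply(model$cls_ids, function(i) fw$cache[[i]]),
       strides = model$strides, fw = fw)
}

# anchor-cell centres (pixels) for each level of an input size; rows are
# cells in column-major (h fastest) order matching array flattening
anchor_centers <- function(input_size, strides) {
  lapply(strides, function(s) {
    n <- input_size %/% s
    hw <- expand.grid(h = seq_len(n), w = seq_len(n))
    cbind(cx = (hw$w - 0.5) * s, cy = (hw$h - 0.5) * s)
  })
}

# decode one image's raw outputs into candidate boxes + scores
decode_candidates <- function(raw, config, img = 1L) {
  reg_max <- config$reg_max
  anchors <- anchor_centers(config$input_size, raw$strides)
  boxes <- NULL; scores <- NULL
  for (l in 1:3) {
    rg <- raw$reg[[l]][, , , img, drop = FALSE]
    cl <- raw$cls[[l]][, , , img, drop = FALSE]
    d <- dim(rg)
    ncell <- d[2] * d[3]
    # channels are ordered side-major: 4 groups of reg_max bins
    rm <- matrix(rg, nrow = d[1])           # (4*reg_max) x cells
    dist <- matrix(0, nrow = ncell, ncol = 4)
    for (side in 1:4) {
      bins <- rm[(side - 1) * reg_max + seq_len(reg_max), , drop = FALSE]
      bins <- exp(sweep(bins, 2, apply(bins, 2, max)))
      bins <- sweep(bins, 2, colSums(bins), "/")
      dist[, side] <- colSums(bins * (seq_len(reg_max) - 1))
    }
    s <- raw$strides[l]
    ctr <- anchors[[l]]
    bx <- cbind(x1 = ctr[, 1] - dist[, 1] * s, y1 = ctr[, 2] - dist[, 2] * s,
                x2 = ctr[, 1] + dist[, 3] * s, y2 = ctr[, 2] + dist[, 4] * s)
    sc <- t(matrix(cl, nrow = dim(cl)[1]))  # cells x nc
    boxes <- rbind(boxes, bx)
    scores <- rbind(scores, 1 / (1 + exp(-sc)))
  }
  list(boxes = boxes, scores = scores)
}

# class-wise greedy non-maximum suppression; returns kept row indices
nms_classwise <- function(boxes, scores, classes, iou_thr) {
  keep <- integer()
  for (cl in unique(classes)) {
    idx <- which(classes == cl)
    idx <- idx[order(scores[idx], decreasing = TRUE)]
    while (length(idx) > 0) {
      i <- idx[1]
      keep <- c(keep, i)
      if (length(idx) == 1) break
      rest <- idx[-1]
      ious <- iou(matrix(boxes[i, ], nrow = 1)[rep(1, length(rest)), , drop = FALSE],
                  boxes[rest, , drop = FALSE])
      idx <- rest[!is.na(ious) & ious <= iou_thr]
    }
  }
  sort(keep)
}

#' Decode raw predictions into detections
#'
#' Per cell, the box is the softmax expectation over the `reg_max` distance
#' bins scaled by the level stride and anchored at the cell centre; the class
#' score is the sigmoid of the class logit. Candidates below the confidence
#' threshold are dropped, class-wise greedy non-maximum suppression is
#' applied, and boxes are clipped to the image.
#'
#' @param raw A [model_forward()] result (single image, or give `img`).
#' @param config The model's [model_config()].
#' @param conf_threshold Minimum class score.
#' @param nms_iou IoU threshold for suppression.
#' @param img Image index within the batch.
#' @return A tibble with columns `x1, y1, x2, y2, class_id, score`
#'   (pixel corner coordinates, 0-based class ids).
#' @export
decode <- function(raw, config, conf_threshold = config$conf_threshold,
                   nms_iou = config$nms_iou, img = 1L) {
  stopifnot(conf_threshold >= 0, conf_threshold <= 1,
            nms_iou >= 0, nms_iou <= 1)
  cand <- decode_candidates(raw, config, img)
  # guard against non-finite candidates (e.g. an untrained net in eval mode)
  ok <- rowSums(!is.finite(cand$boxes)) == 0 &
        rowSums(!is.finite(cand$scores)) == 0
  cand$boxes <- cand$boxes[ok, , drop = FALSE]
  cand$scores <- cand$scores[ok, , drop = FALSE]
  if (nrow(cand$scores) == 0)
    return(tibble::tibble(x1 = numeric(), y1 = numeric(), x2 = numeric(),
                          y2 = numeric(), class_id = integer(),
                          score = numeric()))
  best <- max.col(cand$scores, ties.method = "first")
  score <- cand$scores[cbind(seq_len(nrow(cand$scores)), best)]
  sel <- which(score >= conf_threshold)
  if (length(sel) == 0)
    return(tibble::tibble(x1 = numeric(), y1 = numeric(), x2 = numeric(),
                          y2 = numeric(), class_id = integer(),
                          score = numeric()))
  boxes <- cand$boxes[sel, , drop = FALSE]
  classes <- best[sel] - 1L
  score <- score[sel]
  keep <- nms_classwise(boxes, score, classes, nms_iou)
  boxes <- boxes[keep, , drop = FALSE]
  sz <- config$input_size
  boxes[, c(1, 3)] <- pmin(pmax(boxes[, c(1, 3)], 0), sz)
  boxes[, c(2, 4)] <- pmin(pmax(boxes[, c(2, 4)], 0), sz)
  tibble::tibble(x1 = boxes[, 1], y1 = boxes[, 2], x2 = boxes[, 3],
                 y2 = boxes[, 4], class_id = classes[keep],
                 score = score[keep])
}
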