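# ---------------------------------------------------------------------------
# Training objective: IoU-family box similarities (CIoU, GIoU, SIoU, WIoU,
# MPDIoU), distribution focal loss, binary cross-entropy classification, and
# task-aligned assignment. Gradients w.r.t. predicted box corners are exact
# forward-mode derivatives computed with a small dual-number type, so every
# family member is differentiable end to end (no detached terms).
# ---------------------------------------------------------------------------

EPS <- 1e-9

as_box_matrix <- function(b) {
  if (is.data.frame(b)) b <- as.matrix(b[, c("x1", "y1", "x2", "y2")])
  if (is.null(dim(b))) b <- matrix(b, ncol = 4, byrow = TRUE)
  b
}

#' Intersection over union
#'
#' Row-wise IoU of two sets of corner-form boxes. Zero for disjoint pairs
#' and, by convention, zero when both boxes have zero area.
#'
#' @param a,b Numeric matrices (or length-4 vectors / data frames with
#'   columns `x1, y1, x2, y2`) of corner-form boxes; rows are paired.
#' @return Numeric vector of IoU values in `[0, 1]`.
#' @export
iou <- function(a, b) {
  a <- as_box_matrix(a); b <- as_box_matrix(b)
  iw <- pmax(pmin(a[, 3], b[, 3]) - pmax(a[, 1], b[, 1]), 0)
  ih <- pmax(pmin(a[, 4], b[, 4]) - pmax(a[, 2], b[, 2]), 0)
  inter <- iw * ih
  u <- (a[, 3] - a[, 1]) * (a[, 4] - a[, 2]) +
       (b[, 3] - b[, 1]) * (b[, 4] - b[, 2]) - inter
  ifelse(u > 0, inter / u, 0)  # exact; 0 when both boxes are degenerate
}

# full cross IoU matrix: nrow(a) x nrow(b)
iou_matrix <- function(a, b) {
  a <- as_box_matrix(a); b <- as_box_matrix(b)
  out <- matrix(0, nrow(a), nrow(b))
  for (j in seq_len(nrow(b)))
    out[, j] <- iou(a, matrix(b[j, ], nrow(a), 4, byrow = TRUE))
  out
}

#' Minimum-point-distance IoU
#'
#' IoU minus the squared distances between the two top-left corners and
#' between the two bottom-right corners, each normalised by the squared
#' image diagonal `w^2 + h^2`. Equals 1 only for identical boxes; can be
#' negative (down to values below -1) for distant pairs, which is what makes
#' it informative for non-overlapping boxes.
#'
#' @inheritParams iou
#' @param img Image size: a list or named vector with `w` and `h` (pixels).
#' @return Numeric vector of MPDIoU values, each `<= 1`.
#' @export
mpdiou <- function(a, b, img) {
  a <- as_box_matrix(a); b <- as_box_matrix(b)
  stopifnot(img$w > 0, img$h > 0)
  d1 <- (b[, 1] - a[, 1])^2 + (b[, 2] - a[, 2])^2
  d2 <- (b[, 3] - a[, 3])^2 + (b[, 4] - a[, 4])^2
  iou(a, b) - d1 / (img$w^2 + img$h^2) - d2 / (img$w^2 + img$h^2)
}

#' Image size helper
#' @param w,h Width and height in pixels, both positive.
#' @return A list with elements `w` and `h`.
#' @export
image_size <- function(w, h) {
  if (w <= 0 || h <= 0) stop("image size must be positive", call. = FALSE)
  list(w = w, h = h)
}

# --- vectorised family members --------------------------------------------

giou_vec <- function(a, b) {
  i <- iou(a, b)
  iw <- pmax(pmin(a[, 3], b[, 3]) - pmax(a[, 1], b[, 1]), 0)
  ih <- pmax(pmin(a[, 4], b[, 4]) - pmax(a[, 2], b[, 2]), 0)
  u <- (a[, 3] - a[, 1]) * (a[, 4] - a[, 2]) +
       (b[, 3] - b[, 1]) * (b[, 4] - b[, 2]) - iw * ih
  cw <- pmax(a[, 3], b[, 3]) - pmin(a[, 1], b[, 1])
  ch <- pmax(a[, 4], b[, 4]) - pmin(a[, 2], b[, 2])
  i - (cw * ch - u) / (cw * ch + EPS)
}

ciou_vec <- function(a, b) {
  i <- iou(a, b)
  cw <- pmax(a[, 3], b[, 3]) - pmin(a[, 1], b[, 1])
  ch <- pmax(a[, 4], b[, 4]) - pmin(a[, 2], b[, 2])
  rho2 <- ((a[, 1] + a[, 3] - b[, 1] - b[, 3])^2 +
           (a[, 2] + a[, 4] - b[, 2] - b[, 4])^2) / 4
  c2 <- cw^2 + ch^2 + EPS
  wa <- a[, 3] - a[, 1]; ha <- a[, 4] - a[, 2]
  wb <- b[, 3] - b[, 1]; hb <- b[, 4] - b[, 2]
  v <- (4 / pi^2) * (atan(wb / (hb + EPS)) - atan(wa / (ha + EPS)))^2
  alpha <- v / (1 - i + v + EPS)
  i - rho2 / c2 - alpha * v
}

siou_vec <- function(a, b) {
  i <- iou(a, b)
  cw <- pmax(a[, 3], b[, 3]) - pmin(a[, 1], b[, 1]) + EPS
  ch <- pmax(a[, 4], b[, 4]) - pmin(a[, 2], b[, 2]) + EPS
  s_cw <- (b[, 1] + b[, 3] - a[, 1] - a[, 3]) / 2
  s_ch <- (b[, 2] + b[, 4] - a[, 2] - a[, 4]) / 2
  sigma <- sqrt(s_cw^2 + s_ch^2) + EPS
  sin_a <- abs(s_ch) / sigma
  sin_b <- abs(s_cw) / sigma
  sin_best <- ifelse(sin_a > sin(pi / 4), sin_b, sin_a)
  angle <- cos(asin(sin_best) * 2 - pi / 2)
  rho_x <- (s_cw / cw)^2
  rho_y <- (s_ch / ch)^2
  gamma <- angle - 2
  dist <- 2 - exp(gamma * rho_x) - exp(gamma * rho_y)
  wa <- a[, 3] - a[, 1]; ha <- a[, 4] - a[, 2]
  wb <- b[, 3] - b[, 1]; hb <- b[, 4] - b[, 2]
  om_w <- abs(wa - wb) / (pmax(wa, wb) + EPS)
  om_h <- abs(ha - hb) / (pmax(ha, hb) + EPS)
  shape <- (1 - exp(-om_w))^4 + (1 - exp(-om_h))^4
  i - (dist + shape) / 2
}

wiou_vec <- function(a, b) {
  i <- iou(a, b)
  cw <- pmax(a[, 3], b[, 3]) - pmin(a[, 1], b[, 1])
  ch <- pmax(a[, 4], b[, 4]) - pmin(a[, 2], b[, 2])
  rho2 <- ((a[, 1] + a[, 3] - b[, 1] - b[, 3])^2 +
           (a[, 2] + a[, 4] - b[, 2] - b[, 4])^2) / 4
  r <- exp(rho2 / (cw^2 + ch^2 + EPS))
  1 - r * (1 - i)
}

#' IoU-family box similarity
#'
#' Dispatches to one of the five supported similarities. All equal 1 on
#' identical boxes and are bounded above by 1; `"mpdiou"` additionally
#' needs the image size for its corner-distance normalisation.
#'
#' @param name One of `"iou"`, `"giou"`, `"ciou"`, `"siou"`, `"wiou"`,
#'   `"mpdiou"`.
#' @inheritParams iou
#' @param img Image size (required for `"mpdiou"`, ignored otherwise).
#' @return Numeric vector of similarity values.
#' @export
iou_family <- function(name, a, b, img = NULL) {
  a <- as_box_matrix(a); b <- as_box_matrix(b)
  switch(name,
    iou = iou(a, b),
    giou = giou_vec(a, b),
    ciou = ciou_vec(a, b),
    siou = siou_vec(a, b),
    wiou = wiou_vec(a, b),
    mpdiou = {
      if (is.null(img)) stop("mpdiou requires the image size", call. = FALSE)
      mpdiou(a, b, img)
    },
    stop("unknown IoU family member: ", name, call. = FALSE)
  )
}

#' Box regression loss
#'
#' `1 - similarity` for the chosen family member; 0 for a perfect
#' prediction. For MPDIoU the loss lies in `[0, 3)`.
#'
#' @inheritParams iou_family
#' @param predicted,target Boxes, rows paired.
#' @return Numeric vector of non-negative losses.
#' @export
box_loss <- function(name, predicted, target, img = NULL) {
  1 - iou_family(name, predicted, target, img)
}

# --- dual numbers: exact forward-mode gradients over the 4 pred corners ----

new_dual <- function(v, g = numeric(4)) {
  structure(list(v = v, g = g), class = "cdd_dual")
}
as_dual <- function(x) if (inherits(x, "cdd_dual")) x else new_dual(x)
dval <- function(x) if (inherits(x, "cdd_dual")) x$v else x

#' @export
Ops.cdd_dual <- function(e1, e2) {
  if (missing(e2)) {
    if (.Generic == "-") return(new_dual(-e1$v, -e1$g))
    if (.Generic == "+") return(e1)
    stop("unsupported unary op on dual: ", .Generic)
  }
  a <- as_dual(e1); b <- as_dual(e2)
  switch(.Generic,
    "+" = new_dual(a$v + b$v, a$g + b$g),
    "-" = new_dual(a$v - b$v, a$g - b$g),
    "*" = new_dual(a$v * b$v, a$g * b$v + b$g * a$v),
    "/" = new_dual(a$v / b$v, (a$g * b$v - b$g * a$v) / (b$v * b$v)),
    "^" = new_dual(a$v^b$v, a$v^(b$v - 1) * (b$v * a$g +
                     a$v * log(max(a$v, EPS)) * b$g)),
    ">" = a$v > b$v, "<" = a$v < b$v, ">=" = a$v >= b$v, "<=" = a$v <= b$v,
    "==" = a$v == b$v,
    stop("unsupported op on dual: ", .Generic)
  )
}

#' @export
Math.cdd_dual <- function(x, ...) {
  switch(.Generic,
    sqrt = new_dual(sqrt(x$v), x$g / (2 * sqrt(x$v) + EPS)),
    exp = new_dual(exp(x$v), x$g * exp(x$v)),
    abs = new_dual(abs(x$v), x$g * ifelse(x$v >= 0, 1, -1)),
    atan = new_dual(atan(x$v), x$g / (1 + x$v^2)),
    asin = new_dual(asin(x$v), x$g / sqrt(max(1 - x$v^2, EPS))),
    sin = new_dual(sin(x$v), x$g * cos(x$v)),
    cos = new_dual(cos(x$v), -x$g * sin(x$v)),
    log = new_dual(log(x$v), x$g / x$v),
    stop("unsupported math fn on dual: ", .Generic)
  )
}

dmax2 <- function(a, b) {
  if (!inherits(a, "cdd_dual") && !inherits(b, "cdd_dual")) return(max(a, b))
  if (dval(a) >= dval(b)) as_dual(a) else as_dual(b)
}
dmin2 <- function(a, b) {
  if (!inherits(a, "cdd_dual") && !inherits(b, "cdd_dual")) return(min(a, b))
  if (dval(a) <= dval(b)) as_dual(a) else as_dual(b)
}

# scalar metric on dual/numeric corners; a and b are length-4 lists
pair_metric <- function(name, a, b, img = NULL) {
  iw <- dmax2(dmin2(a[[3]], b[[3]]) - dmax2(a[[1]], b[[1]]), 0)
  ih <- dmax2(dmin2(a[[4]], b[[4]]) - dmax2(a[[2]], b[[2]]), 0)
  inter <- iw * ih
  u <- (a[[3]] - a[[1]]) * (a[[4]] - a[[2]]) +
       (b[[3]] - b[[1]]) * (b[[4]] - b[[2]]) - inter
  i <- inter / (u + EPS)
  if (name == "iou") return(i)
  cw <- dmax2(a[[3]], b[[3]]) - dmin2(a[[1]], b[[1]])
  ch <- dmax2(a[[4]], b[[4]]) - dmin2(a[[2]], b[[2]])
  if (name == "giou") return(i - (cw * ch - u) / (cw * ch + EPS))
  if (name == "mpdiou") {
    d1 <- (b[[1]] - a[[1]])^2 + (b[[2]] - a[[2]])^2
    d2 <- (b[[3]] - a[[3]])^2 + (b[[4]] - a[[4]])^2
    return(i - d1 / (img$w^2 + img$h^2) - d2 / (img$w^2 + img$h^2))
  }
  rho2 <- ((a[[1]] + a[[3]] - b[[1]] - b[[3]])^2 +
           (a[[2]] + a[[4]] - b[[2]] - b[[4]])^2) / 4
  if (name == "wiou") {
    r <- exp(rho2 / (cw^2 + ch^2 + EPS))
    return(1 - r * (1 - i))
  }
  wa <- a[[3]] - a[[1]]; ha <- a[[4]] - a[[2]]
  wb <- b[[3]] - b[[1]]; hb <- b[[4]] - b[[2]]
  if (name == "ciou") {
    c2 <- cw^2 + ch^2 + EPS
    v <- (4 / pi^2) * (atan(wb / (hb + EPS)) - atan(wa / (ha + EPS)))^2
    alpha <- v / (1 - i + v + EPS)
    return(i - rho2 / c2 - alpha * v)
  }
  if (name == "siou") {
    s_cw <- (b[[1]] + b[[3]] - a[[1]] - a[[3]]) / 2
    s_ch <- (b[[2]] + b[[4]] - a[[2]] - a[[4]]) / 2
    sigma <- sqrt(s_cw^2 + s_ch^2) + EPS
    sin_a <- abs(s_ch) / sigma
    sin_b <- abs(s_cw) / sigma
    sin_best <- if (dval(sin_a) > sin(pi / 4)) sin_b else sin_a
    angle <- cos(asin(sin_best) * 2 - pi / 2)
    gamma <- angle - 2
    dist <- 2 - exp(gamma * (s_cw / cw)^2) - exp(gamma * (s_ch / ch)^2)
    om_w <- abs(wa - wb) / (dmax2(wa, wb) + EPS)
    om_h <- abs(ha - hb) / (dmax2(ha, hb) + EPS)
    shape <- (1 - exp(-om_w))^4 + (1 - exp(-om_h))^4
    return(i - (dist + shape) / 2)
  }
  stop("unknown IoU family member: ", name, call. = FALSE)
}

#' Box loss with exact corner gradients
#'
#' Evaluates `1 - similarity` for one predicted/target pair and returns the
#' exact gradient of the loss with respect to the four predicted corners
#' (forward-mode differentiation; every term, including the CIoU aspect
#' trade-off coefficient, is differentiated).
#'
#' @inheritParams box_loss
#' @return `list(loss = scalar, grad = numeric(4))`, gradient ordered
#'   `(x1, y1, x2, y2)`.
#' @export
box_loss_grad <- function(name, predicted, target, img = NULL) {
  p <- as.numeric(as_box_matrix(predicted)[1, ])
  t <- as.numeric(as_box_matrix(target)[1, ])
  a <- lapply(1:4, function(i) {
    g <- numeric(4); g[i] <- 1
    new_dual(p[i], g)
  })
  b <- as.list(t)
  m <- pair_metric(name, a, b, img)
  list(loss = 1 - m$v, grad = -m$g)
}

# --- distribution focal loss -----------------------------------------------

# target t in [0, reg_max - 1]; logits z length reg_max
# CE against the two adjacent bins, linearly weighted
dfl_pair <- function(z, t) {
  lo <- floor(t); hi <- lo + 1
  wl <- hi - t; wr <- t - lo
  logp <- z - (max(z) + log(sum(exp(z - max(z)))))
  tv <- numeric(length(z))
  tv[lo + 1] <- wl
  if (hi < length(z)) tv[hi + 1] <- wr
  list(loss = -(wl * logp[lo + 1] + if (hi < length(z)) wr * logp[hi + 1] else 0),
       grad = exp(logp) - tv)
}

# --- task-aligned assignment -----------------------------------------------

#' Task-aligned assignment
#'
#' Matches predicted cells to ground-truth boxes with the alignment metric
#' `score^alpha * iou^beta`, restricted to cells whose anchor centre lies
#' inside the box; the `topk` best cells per ground truth are positive, and
#' a cell claimed by several ground truths goes to the one with the highest
#' alignment. Classification targets are the alignment scores normalised per
#' ground truth so that the best cell's target equals that ground truth's
#' best IoU.
#'
#' @param scores Matrix (cells x classes) of predicted class probabilities.
#' @param pred_boxes Matrix (cells x 4) of decoded boxes, pixel corners.
#' @param anchors Matrix (cells x 2) of anchor centres (pixels).
#' @param gts Data frame with `class_id, x1, y1, x2, y2` (may have 0 rows).
#' @param alpha,beta Alignment exponents.
#' @param topk Positive cells per ground truth.
#' @return A list: `fg` (logical per cell), `gt_idx` (matched row in `gts`,
#'   NA for background), `target_scores` (cells x classes),
#'   `target_boxes` (cells x 4, rows defined only for foreground cells).
#' @export
tal_assign <- function(scores, pred_boxes, anchors, gts, alpha = 0.5,
                       beta = 6.0, topk = 10L) {
  ncell <- nrow(scores)
  res <- list(fg = rep(FALSE, ncell), gt_idx = rep(NA_integer_, ncell),
              target_scores = matrix(0, ncell, ncol(scores)),
              target_boxes = matrix(0, ncell, 4))
  if (is.null(gts) || nrow(gts) == 0) return(res)
  g <- as.matrix(gts[, c("x1", "y1", "x2", "y2")])
  ng <- nrow(g)
  align <- matrix(0, ncell, ng)
  ious <- matrix(0, ncell, ng)
  for (j in seq_len(ng)) {
    gb <- matrix(g[j, ], ncell, 4, byrow = TRUE)
    inside <- anchors[, 1] > g[j, 1] & anchors[, 1] < g[j, 3] &
              anchors[, 2] > g[j, 2] & anchors[, 2] < g[j, 4]
    iou_j <- iou(pred_boxes, gb)
    ious[, j] <- iou_j
    cls <- gts$class_id[j] + 1L
    align[, j] <- ifelse(inside, pmax(scores[, cls], 0)^alpha *
                           pmax(iou_j, 0)^beta, 0)
  }
  # top-k candidates per gt
  cand <- matrix(FALSE, ncell, ng)
  for (j in seq_len(ng)) {
    pos <- which(align[, j] > 0)
    if (length(pos) == 0) next
    ord <- pos[order(align[pos, j], decreasing = TRUE)]
    cand[utils::head(ord, topk), j] <- TRUE
  }
  # resolve conflicts by the highest alignment
  assigned <- rep(NA_integer_, ncell)
  for (i in which(rowSums(cand) > 0)) {
    js <- which(cand[i, ])
    assigned[i] <- js[which.max(align[i, js])]
  }
  fg <- !is.na(assigned)
  # per-gt normalisation: best cell's target equals the gt's best IoU
  for (j in seq_len(ng)) {
    cells <- which(fg & assigned == j)
    if (length(cells) == 0) next
    amax <- max(align[cells, j])
    imax <- max(ious[cells, j])
    t <- align[cells, j] * imax / (amax + EPS)
    cls <- gts$class_id[j] + 1L
    res$target_scores[cells, cls] <- t
    res$target_boxes[cells, ] <- matrix(g[j, ], length(cells), 4, byrow = TRUE)
  }
  res$fg <- fg
  res$gt_idx <- assigned
  res
}

# --- composite objective ---------------------------------------------------

# flatten one image's raw outputs to cell-major matrices
flatten_levels <- function(raw, config, img = 1L) {
  anchors <- anchor_centers(config$input_size, raw$strides)
  cls <- NULL; reg <- NULL; stride <- NULL; ctr <- NULL
  sizes <- integer(3)
  for (l in 1:3) {
    cl <- raw$cls[[l]][, , , img, drop = FALSE]
    rg <- raw$reg[[l]][, , , img, drop = FALSE]
    ncell <- dim(cl)[2] * dim(cl)[3]
    sizes[l] <- ncell
    cls <- rbind(cls, t(matrix(cl, nrow = dim(cl)[1])))
    reg <- rbind(reg, t(matrix(rg, nrow = dim(rg)[1])))
    stride <- c(stride, rep(raw$strides[l], ncell))
    ctr <- rbind(ctr, anchors[[l]])
  }
  list(cls = cls, reg = reg, stride = stride, anchors = ctr, sizes = sizes)
}

# softmax distances and probabilities per cell/side
reg_expectation <- function(reg, reg_max) {
  ncell <- nrow(reg)
  dist <- matrix(0, ncell, 4)
  probs <- vector("list", 4)
  for (side in 1:4) {
    z <- reg[, (side - 1) * reg_max + seq_len(reg_max), drop = FALSE]
    z <- exp(z - apply(z, 1, max))
    p <- z / rowSums(z)
    probs[[side]] <- p
    dist[, side] <- as.vector(p %*% (seq_len(reg_max) - 1))
  }
  list(dist = dist, probs = probs)
}

#' Composite detection loss
#'
#' The weighted sum of the box-regression loss (chosen IoU family member),
#' binary cross-entropy classification against alignment-weighted targets,
#' and distribution focal loss over the distance bins, averaged over the
#' batch's positive mass. Returns the loss components, and the gradients
#' with respect to the six raw head outputs for the backward pass.
#'
#' @param raw A [model_forward()] result for a batch.
#' @param gts A list (one entry per image) of ground-truth data frames with
#'   columns `class_id, x1, y1, x2, y2` in input pixels.
#' @param config The model's [model_config()].
#' @param lambda_box,lambda_cls,lambda_dfl Component weights.
#' @param with_grad Also compute gradients w.r.t. the raw outputs.
#' @return `list(loss, box, cls, dfl, n_pos, grads)`; `grads` has `reg` and
#'   `cls` lists of arrays shaped like the raw outputs.
#' @export
total_loss <- function(raw, gts, config, lambda_box = 7.5, lambda_cls = 0.5,
                       lambda_dfl = 1.5, with_grad = TRUE) {
  reg_max <- config$reg_max
  n_img <- dim(raw$cls[[1]])[4]
  img <- image_size(config$input_size, config$input_size)
  per_img <- vector("list", n_img)
  s_sum <- 0
  # first pass: assignment and positive mass
  for (n in seq_len(n_img)) {
    fl <- flatten_levels(raw, config, n)
    ex <- reg_expectation(fl$reg, reg_max)
    pb <- cbind(fl$anchors[, 1] - ex$dist[, 1] * fl$stride,
                fl$anchors[, 2] - ex$dist[, 2] * fl$stride,
                fl$anchors[, 1] + ex$dist[, 3] * fl$stride,
                fl$anchors[, 2] + ex$dist[, 4] * fl$stride)
    probs <- 1 / (1 + exp(-fl$cls))
    asn <- tal_assign(probs, pb, fl$anchors, gts[[n]])
    per_img[[n]] <- list(fl = fl, ex = ex, pb = pb, probs = probs, asn = asn)
    s_sum <- s_sum + sum(asn$target_scores)
  }
  s_sum <- max(s_sum, 1)
  loss_box <- loss_cls <- loss_dfl <- 0
  n_pos <- 0
  grads <- if (with_grad) list(
    reg = lapply(raw$reg, function(a) array(0, dim(a))),
    cls = lapply(raw$cls, function(a) array(0, dim(a)))) else NULL
  for (n in seq_len(n_img)) {
    st <- per_img[[n]]
    fl <- st$fl; asn <- st$asn
    # classification BCE with logits, summed over all cells/classes
    z <- fl$cls; t <- asn$target_scores
    bce <- sum(pmax(z, 0) - z * t + log1p(exp(-abs(z))))
    loss_cls <- loss_cls + bce / s_sum
    dcls_flat <- if (with_grad) (st$probs - t) * (lambda_cls / s_sum)
    dreg_flat <- if (with_grad) matrix(0, nrow(fl$reg), ncol(fl$reg))
    fg_cells <- which(asn$fg)
    n_pos <- n_pos + length(fg_cells)
    for (i in fg_cells) {
      w <- sum(asn$target_scores[i, ])
      tb <- asn$target_boxes[i, ]
      s <- fl$stride[i]
      pbi <- st$pb[i, ]
      # box loss with corner gradients
      bg <- box_loss_grad(config$loss_iou, pbi, tb, img)
      loss_box <- loss_box + w * bg$loss / s_sum
      # dfl targets: gt side distances in stride units
      td <- c(fl$anchors[i, 1] - tb[1], fl$anchors[i, 2] - tb[2],
              tb[3] - fl$anchors[i, 1], tb[4] - fl$anchors[i, 2]) / s
      td <- pmin(pmax(td, 0), reg_max - 1 - 0.01)
      for (side in 1:4) {
        zb <- fl$reg[i, (side - 1) * reg_max + seq_len(reg_max)]
        dp <- dfl_pair(zb, td[side])
        loss_dfl <- loss_dfl + w * dp$loss / (4 * s_sum)
        if (with_grad) {
          # corner derivative wrt this side's distance (sign by side)
          sgn <- c(-1, -1, 1, 1)[side]
          dcorner <- bg$grad[side] * sgn * s  # d loss / d dist_side
          p <- st$ex$probs[[side]][i, ]
          dz_box <- dcorner * p * ((seq_len(reg_max) - 1) - st$ex$dist[i, side])
          dz_dfl <- dp$grad * (w / (4 * s_sum))
          cols <- (side - 1) * reg_max + seq_len(reg_max)
          dreg_flat[i, cols] <- dreg_flat[i, cols] +
            lambda_box * (w / s_sum) * dz_box + lambda_dfl * dz_dfl
        }
      }
    }
    if (with_grad) {
      # scatter flat per-cell grads back into the level arrays
      off <- 0L
      for (l in 1:3) {
        ncell <- fl$sizes[l]
        rows <- off + seq_len(ncell)
        d <- dim(grads$cls[[l]])
        grads$cls[[l]][, , , n] <- array(t(dcls_flat[rows, , drop = FALSE]),
                                         d[1:3])
        dr <- dim(grads$reg[[l]])
        grads$reg[[l]][, , , n] <- array(t(dreg_flat[rows, , drop = FALSE]),
                                         dr[1:3])
        off <- off + ncell
      }
    }
  }
  loss_box <- lambda_box * loss_box
  loss_cls <- lambda_cls * loss_cls
  loss_dfl <- lambda_dfl * loss_dfl
  list(loss = loss_box + loss_cls + loss_dfl, box = loss_box, cls = loss_cls,
       dfl = loss_dfl, n_pos = n_pos, grads = grads)
}
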