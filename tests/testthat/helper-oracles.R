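# Independent oracles and small fixture builders used across the suite.

# naive direct convolution (triple loop), the reference for the C++ kernel
naive_conv <- function(x, w, k, s, pad, groups = 1, b = NULL) {
  d <- dim(x); C <- d[1]; H <- d[2]; W <- d[3]
  Cout <- nrow(w); Cg <- C / groups; CoutG <- Cout / groups
  Ho <- (H + 2 * pad - k) %/% s + 1; Wo <- (W + 2 * pad - k) %/% s + 1
  y <- array(0, c(Cout, Ho, Wo, 1))
  for (co in 1:Cout) {
    g <- (co - 1) %/% CoutG
    for (oh in 1:Ho) for (ow in 1:Wo) {
      acc <- 0
      for (ci in 1:Cg) for (kh in 1:k) for (kw in 1:k) {
        ih <- (oh - 1) * s - pad + kh; iw <- (ow - 1) * s - pad + kw
        if (ih >= 1 && ih <= H && iw >= 1 && iw <= W)
          acc <- acc + x[g * Cg + ci, ih, iw, 1] *
            w[co, (ci - 1) * k * k + (kh - 1) * k + kw]
      }
      y[co, oh, ow, 1] <- acc + if (!is.null(b)) b[co] else 0
    }
  }
  y
}

# independent all-point-interpolation AP: for each recall step, the maximum
# precision at any recall >= r (coded differently from the package's
# cumulative-envelope form)
oracle_ap <- function(tp, n_gt) {
  if (n_gt == 0) return(NA_real_)
  if (length(tp) == 0) return(0)
  cum_tp <- cumsum(tp); cum_fp <- cumsum(!tp)
  prec <- cum_tp / (cum_tp + cum_fp)
  rec <- cum_tp / n_gt
  ap <- 0; r_prev <- 0
  for (i in seq_along(rec)) {
    if (rec[i] > r_prev) {
      p_max <- max(prec[rec >= rec[i]])
      ap <- ap + (rec[i] - r_prev) * p_max
      r_prev <- rec[i]
    }
  }
  ap
}

# exhaustive best-score one-to-one matching for tiny scenes
oracle_match <- function(dets, gts, iou_thr) {
  ord <- order(dets$score, decreasing = TRUE)
  n <- nrow(dets)
  tp <- logical(n)
  used <- rep(FALSE, nrow(gts))
  for (k in seq_len(n)) {
    i <- ord[k]
    best <- 0; bj <- NA
    for (j in seq_len(nrow(gts))) {
      if (used[j] || gts$class_id[j] != dets$class_id[i]) next
      v <- cddlite::iou(as.numeric(dets[i, c("x1", "y1", "x2", "y2")]),
                        as.numeric(gts[j, c("x1", "y1", "x2", "y2")]))
      if (v > best) { best <- v; bj <- j }
    }
    if (!is.na(bj) && best >= iou_thr) { tp[k] <- TRUE; used[bj] <- TRUE }
  }
  list(tp = tp, fn = sum(!used))
}

rand_box <- function(lo = 0, hi = 90, min_side = 2) {
  x <- sort(stats::runif(2, lo, hi)); y <- sort(stats::runif(2, lo, hi))
  c(x[1], y[1], x[2] + min_side, y[2] + min_side)
}

toy_scene <- function(n_det, n_gt, num_classes = 2) {
  gts <- do.call(rbind, lapply(seq_len(n_gt), function(i) {
    b <- rand_box()
    data.frame(class_id = sample.int(num_classes, 1) - 1L,
               x1 = b[1], y1 = b[2], x2 = b[3], y2 = b[4])
  }))
  dets <- do.call(rbind, lapply(seq_len(n_det), function(i) {
    if (n_gt > 0 && stats::runif(1) < 0.6) {
      g <- gts[sample.int(n_gt, 1), ]
      jit <- stats::rnorm(4, 0, 6)
      b <- c(g$x1 + jit[1], g$y1 + jit[2], g$x2 + jit[3], g$y2 + jit[4])
      b <- c(min(b[1], b[3] - 1), min(b[2], b[4] - 1),
             max(b[3], b[1] + 1), max(b[4], b[2] + 1))
      cl <- g$class_id
    } else {
      b <- rand_box(); cl <- sample.int(num_classes, 1) - 1L
    }
    data.frame(x1 = b[1], y1 = b[2], x2 = b[3], y2 = b[4], class_id = cl,
               score = stats::runif(1))
  }))
  if (is.null(dets)) dets <- data.frame(x1 = numeric(), y1 = numeric(),
                                        x2 = numeric(), y2 = numeric(),
                                        class_id = integer(),
                                        score = numeric())
  if (is.null(gts)) gts <- data.frame(class_id = integer(), x1 = numeric(),
                                      y1 = numeric(), x2 = numeric(),
                                      y2 = numeric())
  list(dets = dets, gts = gts)
}

tiny_samples <- function(n, size = 32, seed = 11) {
  cfg <- cddlite::synth_config(n_images = n, image_size = size,
                               lesions_range = c(1, 2), seed = seed)
  lapply(seq_len(n), function(i) cddlite:::synth_sample(cfg, i))
}

withr_tempfile <- function() tempfile(fileext = ".txt")
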