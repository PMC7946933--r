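# Nucleus detection from the fused DAPI + pan-histone channel.
#
# DAPI labeling varies regionally and can be weak or absent for many cells;
# the pan-histone stain complements it, and the pixelwise sum of the two
# channels reveals nuclei far more reliably than either alone. Detection
# proceeds from a classical bootstrap segmenter (multiscale
# Laplacian-of-Gaussian blob seeds + seeded region growing) that can also
# auto-label training corpora for a learned two-stage region-proposal
# detector (blob proposals re-scored by a trained head). Large mosaics are
# processed with an overlap-window strategy and duplicate boxes in tile
# margins are removed by non-maximum suppression.

#' Detection parameters
#' @param iou_threshold IOU above which a detection matches a truth box.
#' @param nms_iou IOU above which two detections are duplicates.
#' @param score_threshold minimum score for an emitted detection.
#' @param tile,overlap overlap-window size and margin in pixels.
#' @return a `detection_params` list.
#' @export
detection_params <- function(iou_threshold = 0.5, nms_iou = 0.3,
                             score_threshold = 0.1, tile = 512L,
                             overlap = 64L) {
  stopifnot(iou_threshold > 0, iou_threshold < 1, nms_iou > 0, nms_iou < 1,
            overlap < tile)
  structure(list(iou_threshold = iou_threshold, nms_iou = nms_iou,
                 score_threshold = score_threshold, tile = as.integer(tile),
                 overlap = as.integer(overlap)), class = "detection_params")
}

#' Fuse the DAPI and pan-histone nuclear channels
#'
#' Pixelwise sum, clipped at the 16-bit maximum (no wraparound).
#'
#' @param dapi,histone registered, corrected [channel_image()]s.
#' @return fused [channel_image()].
#' @export
fuse_nuclear_channels <- function(dapi, histone) {
  dp <- pixels_of(dapi); hp <- pixels_of(histone)
  if (!identical(dim(dp), dim(hp)))
    stop("fuse_nuclear_channels: geometry mismatch")
  fused <- pmin(dp + hp, uint16_max)
  if (inherits(dapi, "channel_image")) {
    out <- set_pixels(dapi, fused)
    out$biomarker <- "DAPI+Histone"
    out
  } else channel_image(fused, biomarker = "DAPI+Histone")
}

# Multiscale LoG (difference-of-Gaussian) blob response.
log_response <- function(px, sigma_range) {
  sigmas <- exp(seq(log(sigma_range[1]), log(sigma_range[2]), length.out = 3))
  resp <- matrix(-Inf, nrow(px), ncol(px))
  for (s in sigmas) {
    dog <- as_matrix(EBImage::gblur(px, s)) - as_matrix(EBImage::gblur(px, 1.6 * s))
    resp <- pmax(resp, dog * s)
  }
  resp
}

# Blob seeds: local maxima of the LoG response above an absolute threshold
# (abs_threshold = NULL uses 10% of the response maximum).
log_blob_seeds <- function(px, sigma_range, abs_threshold = NULL) {
  resp <- log_response(px, sigma_range)
  is_max <- matrix(TRUE, nrow(px), ncol(px))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    is_max <- is_max & resp >= shift_matrix(resp, dr, dc, fill = -Inf)
  }
  thr <- abs_threshold %||% (0.1 * max(resp))
  peaks <- which(is_max & resp > thr, arr.ind = TRUE)
  # enforce a minimum seed spacing of sigma_min (greedy by response)
  if (nrow(peaks) > 1) {
    ord <- order(-resp[peaks])
    peaks <- peaks[ord, , drop = FALSE]
    keep <- rep(TRUE, nrow(peaks))
    for (i in seq_len(nrow(peaks))) {
      if (!keep[i]) next
      if (i < nrow(peaks)) {
        d2 <- rowSums((peaks[(i + 1):nrow(peaks), , drop = FALSE] -
                         matrix(peaks[i, ], nrow(peaks) - i, 2, byrow = TRUE))^2)
        keep[(i + 1):nrow(peaks)][d2 < sigma_range[1]^2] <- FALSE
      }
    }
    peaks <- peaks[keep, , drop = FALSE]
  }
  peaks
}

#' Classical bootstrap nucleus segmenter
#'
#' Multiscale LoG blob seeds followed by seeded region growing
#' ([EBImage::propagate()]) inside the Otsu foreground; each instance yields
#' a scored bounding box. Works well on well-separated nuclei, degrades on
#' densely packed ensembles (which motivates the learned re-scoring stage);
#' also used to auto-label training corpora.
#'
#' @param fused fused nuclear [channel_image()] or matrix.
#' @param sigma_range expected nucleus radius range in pixels.
#' @param min_area minimum object area in pixels.
#' @param threshold,seed_threshold absolute foreground / seed-response
#'   thresholds; `NULL` derives them from this image (tiled callers pass
#'   global values so tiles behave identically to whole-image processing).
#'   The default foreground cut is half the Otsu threshold: nuclei with one
#'   dropped-out stain sit well below the bright mode, and the background
#'   after intra-channel correction is near zero, so halving Otsu keeps dim
#'   nuclei without admitting background.
#' @param normalize_scores rescale mean-intensity scores into (0, 1).
#' @return data.frame `cell_id, r0, c0, r1, c1, row, col, score` (boxes
#'   half-open, 0-based; scores in `[0, 1]`).
#' @export
bootstrap_segment <- function(fused, sigma_range = c(3, 8), min_area = 9L,
                              threshold = NULL, seed_threshold = NULL,
                              normalize_scores = TRUE) {
  px <- pixels_of(fused)
  empty <- data.frame(cell_id = integer(0), r0 = integer(0), c0 = integer(0),
                      r1 = integer(0), c1 = integer(0), row = numeric(0),
                      col = numeric(0), score = numeric(0))
  if (diff(range(px)) == 0 && is.null(threshold)) return(empty)
  thr <- threshold %||% (0.5 * otsu_threshold(as.numeric(px)))
  bw <- px > thr
  if (!any(bw)) return(empty)
  peaks <- log_blob_seeds(px, sigma_range, seed_threshold)
  peaks <- peaks[bw[peaks], , drop = FALSE]
  if (nrow(peaks) == 0) return(empty)
  seeds <- matrix(0L, nrow(px), ncol(px))
  seeds[peaks] <- seq_len(nrow(peaks))
  lab <- as_matrix(EBImage::propagate(px / uint16_max, seeds, mask = bw))
  ids <- sort(unique(lab[lab > 0]))
  rows <- lapply(ids, function(i) {
    idx <- which(lab == i, arr.ind = TRUE)
    if (nrow(idx) < min_area) return(NULL)
    data.frame(cell_id = i,
               r0 = min(idx[, 1]) - 1L, c0 = min(idx[, 2]) - 1L,
               r1 = max(idx[, 1]), c1 = max(idx[, 2]),
               row = mean(idx[, 1]) - 1, col = mean(idx[, 2]) - 1,
               score = mean(px[idx]))
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0) return(empty)
  # normalized mean-intensity score, strictly inside (0, 1)
  if (normalize_scores) out$score <- out$score / (max(out$score) * (1 + 1e-6))
  out$cell_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

# -- learned two-stage detector ---------------------------------------------

detector_features <- function(dapi, histone, props, patch = 24L, ds = 2L) {
  dp <- pixels_of(dapi); hp <- pixels_of(histone)
  H <- nrow(dp); W <- ncol(dp)
  half <- patch %/% 2L
  n <- nrow(props)
  grid <- seq(-half, half - 1, by = ds)
  feats <- matrix(0, n, 2 * length(grid)^2 + 4)
  for (i in seq_len(n)) {
    r <- pmin(H, pmax(1, round(props$row[i]) + 1 + grid))
    c <- pmin(W, pmax(1, round(props$col[i]) + 1 + grid))
    pd <- dp[r, c]; ph <- hp[r, c]
    feats[i, ] <- c(as.numeric(pd), as.numeric(ph),
                    log1p((props$r1[i] - props$r0[i]) *
                            (props$c1[i] - props$c0[i])),
                    (props$r1[i] - props$r0[i]) /
                      max(1, props$c1[i] - props$c0[i]),
                    mean(pd), mean(ph))
  }
  feats
}

#' Train the learned nucleus detector
#'
#' A two-stage region-proposal detector at desk scale: stage one generates
#' candidate boxes with the classical bootstrap segmenter; stage two is a
#' trained scoring head over two-channel (DAPI, pan-histone) patch features.
#' Proposals with IOU >= 0.5 against a labeled box are positives, IOU < 0.2
#' negatives. Training is deterministic given `seed`.
#'
#' @param images list of `list(dapi, histone)` training scenes.
#' @param boxes list of data.frames of labeled boxes (`r0, c0, r1, c1`).
#' @param config list; `sigma_range` for proposals, `lambda` ridge penalty.
#' @param seed RNG seed.
#' @return a `nucleus_detector` state (serializable with `saveRDS`).
#' @export
train_detector <- function(images, boxes, config = list(), seed = 1L) {
  if (length(boxes) == 0 || all(vapply(boxes, nrow, 1L) == 0))
    stop("train_detector: empty label set")
  sigma_range <- config$sigma_range %||% c(3, 8)
  lambda <- config$lambda %||% 1e-3
  if (!is.null(config$backbone_weights) && !file.exists(config$backbone_weights))
    warning("pretrained backbone weights not found; cold start")
  X <- NULL; yv <- integer(0)
  for (k in seq_along(images)) {
    dapi <- images[[k]]$dapi; histone <- images[[k]]$histone
    fused <- fuse_nuclear_channels(dapi, histone)
    props <- bootstrap_segment(fused, sigma_range)
    # augment with random boxes so the scoring head sees negatives
    # (clean proposal sets contain few background examples)
    H <- nrow(pixels_of(fused)); W <- ncol(pixels_of(fused))
    n_rand <- max(20L, nrow(props))
    props <- with_seed(seed + k, {
      sz <- pmax(6, round(runif(n_rand, 1.5, 3) * mean(sigma_range)))
      r0 <- floor(runif(n_rand, 0, H - sz)); c0 <- floor(runif(n_rand, 0, W - sz))
      rand <- data.frame(cell_id = 0L, r0 = r0, c0 = c0, r1 = r0 + sz,
                         c1 = c0 + sz, row = r0 + sz / 2, col = c0 + sz / 2,
                         score = 0)
      rbind(props, rand)
    })
    tb <- as_box_matrix(boxes[[k]][, c("r0", "c0", "r1", "c1")])
    if (nrow(props) == 0) next
    iou_best <- vapply(seq_len(nrow(props)), function(i)
      max(box_iou(unlist(props[i, c("r0", "c0", "r1", "c1")]), tb)), 0)
    lab <- ifelse(iou_best >= 0.5, 1L, ifelse(iou_best < 0.2, 0L, NA_integer_))
    sel <- !is.na(lab)
    if (!any(sel)) next
    X <- rbind(X, detector_features(dapi, histone, props[sel, , drop = FALSE]))
    yv <- c(yv, lab[sel])
  }
  if (is.null(X) || length(unique(yv)) < 2)
    stop("train_detector: need both positive and negative proposals")
  mu <- colMeans(X); sdv <- pmax(apply(X, 2, sd), 1e-8)
  Xs <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  fit <- with_seed(seed,
    glmnet::glmnet(Xs, yv, family = "binomial", alpha = 0, lambda = lambda))
  structure(list(coef = as.numeric(coef(fit)), mu = mu, sd = sdv,
                 sigma_range = sigma_range, lambda = lambda),
            class = "nucleus_detector")
}

score_proposals <- function(detector, dapi, histone, props) {
  if (nrow(props) == 0) return(props)
  X <- detector_features(dapi, histone, props)
  Xs <- sweep(sweep(X, 2, detector$mu), 2, detector$sd, "/")
  eta <- detector$coef[1] + Xs %*% detector$coef[-1]
  props$score <- as.numeric(1 / (1 + exp(-eta)))
  props
}

#' Detect nuclei with tiled inference
#'
#' Runs proposal generation (and the learned scoring head, when a detector
#' is supplied) tile by tile with overlapping windows; proposals touching an
#' interior tile boundary are deferred to the neighboring tile that contains
#' them fully, and residual duplicates in overlap margins are removed by
#' NMS. Cell ids are unique and ascend in reading order.
#'
#' @param dapi,histone registered, corrected nuclear channels.
#' @param detector optional trained [train_detector()] state; `NULL` uses
#'   the classical segmenter scores.
#' @param params a [detection_params()].
#' @param sigma_range nucleus radius range for proposals.
#' @return data.frame of detections (`cell_id, r0, c0, r1, c1, row, col,
#'   score`).
#' @export
detect_nuclei <- function(dapi, histone = NULL, detector = NULL,
                          params = detection_params(),
                          sigma_range = c(3, 8)) {
  if (params$tile < 8 * sigma_range[2])
    stop("tile smaller than the largest proposal scale")
  fused <- if (is.null(histone)) dapi else fuse_nuclear_channels(dapi, histone)
  fp <- pixels_of(fused)
  H <- nrow(fp); W <- ncol(fp)
  # global thresholds so tiled and whole-image inference agree exactly
  global_thr <- 0.5 * otsu_threshold(as.numeric(fp))
  global_seed_thr <- 0.1 * max(log_response(fp, sigma_range))
  tiles <- image_tiles(fp, params$tile, params$overlap)
  all_props <- list()
  for (tl in tiles) {
    props <- bootstrap_segment(tl$pixels, sigma_range,
                               threshold = global_thr,
                               seed_threshold = global_seed_thr,
                               normalize_scores = FALSE)
    if (nrow(props) == 0) next
    th <- nrow(tl$pixels); tw <- ncol(tl$pixels)
    # drop boxes cut by an interior tile boundary (they are complete in a
    # neighboring tile because overlap exceeds the object size)
    inner <- (props$r0 > 0 | tl$r0 == 0) & (props$c0 > 0 | tl$c0 == 0) &
      (props$r1 < th | tl$r0 + th == H) & (props$c1 < tw | tl$c0 + tw == W)
    props <- props[inner, , drop = FALSE]
    if (nrow(props) == 0) next
    props$r0 <- props$r0 + tl$r0; props$r1 <- props$r1 + tl$r0
    props$c0 <- props$c0 + tl$c0; props$c1 <- props$c1 + tl$c0
    props$row <- props$row + tl$r0; props$col <- props$col + tl$c0
    all_props[[length(all_props) + 1L]] <- props
  }
  props <- do.call(rbind, all_props)
  if (is.null(props) || nrow(props) == 0)
    return(data.frame(cell_id = integer(0), r0 = integer(0), c0 = integer(0),
                      r1 = integer(0), c1 = integer(0), row = numeric(0),
                      col = numeric(0), score = numeric(0)))
  if (!is.null(detector)) {
    stopifnot(!is.null(histone))
    props <- score_proposals(detector, dapi, histone, props)
  } else {
    props$score <- props$score / (max(props$score) * (1 + 1e-6))
  }
  keep <- nms_boxes(props[, c("r0", "c0", "r1", "c1")], props$score,
                    params$nms_iou)
  props <- props[keep, , drop = FALSE]
  props <- props[props$score >= params$score_threshold, , drop = FALSE]
  props <- props[order(props$r0, props$c0), , drop = FALSE]
  props$cell_id <- seq_len(nrow(props))
  rownames(props) <- NULL
  props
}

#' Evaluate detections against ground truth
#'
#' Greedy score-ordered one-to-one matching at `IOU >= iou_threshold` (ties
#' broken by higher IOU, then lower id). The ROC curve is swept over the
#' detection score; the false-positive rate is relative to the total number
#' of false detections and the curve is extended horizontally to FPR = 1
#' when recall saturates below 1 (missed objects are never recovered by
#' lowering the threshold). AUC is computed by the trapezoid rule.
#'
#' @param pred data.frame of detections with `r0, c0, r1, c1, score`.
#' @param truth data.frame of truth boxes with `r0, c0, r1, c1`.
#' @param params a [detection_params()].
#' @return list with `precision`, `recall`, `f1`, `roc` (data.frame fpr,
#'   tpr), `auc`, and the per-detection `matched` flags.
#' @export
evaluate_detection <- function(pred, truth, params = detection_params()) {
  if (nrow(truth) == 0) {
    warning("empty truth set: recall undefined")
    return(list(precision = NA_real_, recall = NaN, f1 = NA_real_,
                roc = data.frame(fpr = numeric(0), tpr = numeric(0)),
                auc = NA_real_, matched = logical(nrow(pred))))
  }
  tb <- as_box_matrix(truth[, c("r0", "c0", "r1", "c1")])
  np <- nrow(pred)
  matched <- logical(np)
  truth_used <- logical(nrow(tb))
  ord <- order(-pred$score, seq_len(np))
  for (i in ord) {
    iou <- box_iou(unlist(pred[i, c("r0", "c0", "r1", "c1")]), tb)
    iou[truth_used] <- -1
    j <- which.max(iou)
    if (length(j) && iou[j] >= params$iou_threshold) {
      matched[i] <- TRUE
      truth_used[j] <- TRUE
    }
  }
  tp <- sum(matched); fp <- np - tp
  precision <- if (np) tp / np else NA_real_
  recall <- tp / nrow(tb)
  f1 <- if (is.na(precision) || precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  # ROC over score thresholds
  sc <- sort(unique(pred$score), decreasing = TRUE)
  tpr <- fpr <- numeric(length(sc))
  total_fp <- max(fp, 1L)
  for (k in seq_along(sc)) {
    sel <- pred$score >= sc[k]
    tpr[k] <- sum(matched & sel) / nrow(tb)
    fpr[k] <- sum(!matched & sel) / total_fp
  }
  roc <- data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, max(tpr, 0)))
  roc <- roc[order(roc$fpr, roc$tpr), ]
  auc <- sum(diff(roc$fpr) * (head(roc$tpr, -1) + tail(roc$tpr, -1)) / 2)
  list(precision = precision, recall = recall, f1 = f1, roc = roc,
       auc = auc, matched = matched)
}

#' Write / read detections as JSON or CSV
#' @param detections detection data.frame.
#' @param path output path (`.json` or `.csv`).
#' @export
write_detections <- function(detections, path) {
  if (grepl("\\.json$", path))
    jsonlite::write_json(detections, path, digits = NA)
  else write.csv(detections, path, row.names = FALSE)
  invisible(path)
}
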